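#' Construct a binding-pocket similarity matrix
#'
#' Wraps a square symmetric similarity matrix (unit diagonal, values in
#' \[0, 1\]) over named protein structures. Pocket similarities are
#' produced by external binding-site comparison tools; this toolkit
#' consumes them for representative-structure selection.
#'
#' @param values Square numeric matrix.
#' @param ids Structure identifiers (default: matrix dimnames).
#' @return Object of class `pocket_sim_matrix`.
#' @export
pocket_sim_matrix <- function(values, ids = rownames(values)) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  stopifnot(ncol(values) == n, length(ids) == n, n >= 1)
  if (max(abs(values - t(values))) > 1e-9) {
    stop("similarity matrix must be symmetric within 1e-9", call. = FALSE)
  }
  if (max(abs(diag(values) - 1)) > 1e-9) {
    stop("similarity matrix must have unit diagonal", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  dimnames(values) <- list(ids, ids)
  structure(list(ids = as.character(ids), values = values),
            class = "pocket_sim_matrix")
}

#' @export
print.pocket_sim_matrix <- function(x, ...) {
  cat(sprintf("<pocket_sim_matrix> %d structures\n", length(x$ids)))
  invisible(x)
}

#' Read / write a pocket similarity matrix as delimited text
#'
#' Square table with a header row of structure ids and the ids repeated
#' in the first column; tab- or comma-separated by extension.
#'
#' @param path File path (`.tsv`/`.txt` tab, `.csv` comma).
#' @return [pocket_sim_matrix()] for the reader; `path` invisibly for
#'   the writer.
#' @export
read_sim_matrix <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                         check.names = FALSE)
  pocket_sim_matrix(as.matrix(d), ids = rownames(d))
}

#' @rdname read_sim_matrix
#' @param mat A [pocket_sim_matrix()].
#' @export
write_sim_matrix <- function(mat, path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  utils::write.table(mat$values, path, sep = sep, quote = FALSE,
                     col.names = NA)
  invisible(path)
}

sim_to_dist <- function(mat) 1 - mat$values

new_ensemble_selection <- function(mat, exemplars, strategy,
                                   medoids = exemplars) {
  d <- sim_to_dist(mat)
  n <- length(mat$ids)
  md_idx <- match(medoids, mat$ids)
  ex_idx <- match(exemplars, mat$ids)
  # partition (and objective) defined by the medoids; exemplars may be
  # relabeled within clusters but stay members of their own cluster
  assign <- md_idx[apply(d[, md_idx, drop = FALSE], 1, which.min)]
  assign[md_idx] <- md_idx
  objective <- mean(d[cbind(seq_len(n), assign)])
  exemplar_of <- stats::setNames(exemplars, mat$ids[md_idx])
  structure(list(exemplar_ids = exemplars,
                 assignment = stats::setNames(
                   unname(exemplar_of[mat$ids[assign]]), mat$ids),
                 strategy = strategy, objective = objective,
                 matrix = mat),
            class = "ensemble_selection")
}

#' @export
print.ensemble_selection <- function(x, ...) {
  cat(sprintf("<ensemble_selection> %s: k=%d of %d, objective %.4f\n",
              x$strategy, length(x$exemplar_ids),
              length(x$assignment), x$objective))
  cat("  exemplars:", paste(x$exemplar_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy an ensemble selection
#'
#' @param x An `ensemble_selection`.
#' @param ... Unused.
#' @return Tibble with one row per structure: `id`, `exemplar` (cluster
#'   representative id), `is_exemplar`, `dist_to_exemplar`.
#' @export
tidy.ensemble_selection <- function(x, ...) {
  d <- sim_to_dist(x$matrix)
  ids <- x$matrix$ids
  tibble::tibble(
    id = ids,
    exemplar = unname(x$assignment),
    is_exemplar = ids %in% x$exemplar_ids,
    dist_to_exemplar = d[cbind(seq_along(ids),
                               match(x$assignment, ids))])
}

#' @rdname tidy.ensemble_selection
#' @export
glance.ensemble_selection <- function(x, ...) {
  tibble::tibble(strategy = x$strategy, k = length(x$exemplar_ids),
                 n = length(x$assignment), objective = x$objective)
}

# assign items to nearest medoid and return mean distance
kmedoid_objective <- function(d, med) {
  mean(apply(d[, med, drop = FALSE], 1, min))
}

#' Choose K representative structures by K-medoids
#'
#' Partitions the structures around K medoids on the distance
#' `1 - similarity` (seeded multi-restart with PAM-style swap
#' refinement), then reports as each cluster's exemplar the member with
#' the highest mean similarity to its co-members — the structure
#' "closest to all cluster members". Deterministic given the seed; ties
#' are broken by identifier sort order.
#'
#' @param mat A [pocket_sim_matrix()].
#' @param k Number of representatives, `1 <= k <= N`.
#' @param seed Integer seed for the restarts.
#' @param restarts Number of random initializations (default 100).
#' @return An `ensemble_selection` (see [tidy.ensemble_selection()]).
#' @export
choose_exemplars <- function(mat, k, seed = 1L, restarts = 100L) {
  n <- length(mat$ids)
  if (k < 1 || k > n) stop("k must be in 1..N", call. = FALSE)
  d <- sim_to_dist(mat)
  if (k == n) {
    return(new_ensemble_selection(mat, mat$ids, "kmedoid"))
  }
  best_med <- NULL
  best_obj <- Inf
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      med <- sort(sample.int(n, k))
      repeat {
        obj <- kmedoid_objective(d, med)
        improved <- FALSE
        for (mi in seq_along(med)) {
          for (cand in setdiff(seq_len(n), med)) {
            trial <- med
            trial[mi] <- cand
            tobj <- kmedoid_objective(d, trial)
            if (tobj < obj - 1e-15) {
              med <- sort(trial)
              obj <- tobj
              improved <- TRUE
            }
          }
        }
        if (!improved) break
      }
      if (obj < best_obj - 1e-15) {
        best_obj <- obj
        best_med <- med
      }
    }
  })
  # relabel each cluster's exemplar as the member with maximal mean
  # similarity to co-members (ties by id order)
  assign <- best_med[apply(d[, best_med, drop = FALSE], 1, which.min)]
  assign[best_med] <- best_med
  exemplars <- vapply(best_med, function(m) {
    cl <- which(assign == m)
    if (length(cl) == 1) return(mat$ids[cl])
    ms <- vapply(cl, function(i) mean(mat$values[i, setdiff(cl, i)]),
                 numeric(1))
    ord <- order(-ms, mat$ids[cl])
    mat$ids[cl[ord[1]]]
  }, character(1))
  new_ensemble_selection(mat, exemplars, "kmedoid",
                         medoids = mat$ids[best_med])
}

#' Choose K maximally diverse structures
#'
#' Greedy max-min-distance selection: starts from the structure with
#' the lowest mean similarity to all others (the most dissimilar
#' pocket) and repeatedly adds the structure whose minimum distance to
#' the already-chosen set is largest. This is the comparison strategy
#' that, by construction, picks outliers first.
#'
#' @inheritParams choose_exemplars
#' @return An `ensemble_selection`.
#' @export
choose_diverse <- function(mat, k) {
  n <- length(mat$ids)
  if (k < 1 || k > n) stop("k must be in 1..N", call. = FALSE)
  d <- sim_to_dist(mat)
  mean_sim <- vapply(seq_len(n), function(i) {
    if (n == 1) 1 else mean(mat$values[i, -i])
  }, numeric(1))
  chosen <- order(mean_sim, mat$ids)[1]
  while (length(chosen) < k) {
    rest <- setdiff(seq_len(n), chosen)
    min_d <- apply(d[rest, chosen, drop = FALSE], 1, min)
    ord <- order(-min_d, mat$ids[rest])
    chosen <- c(chosen, rest[ord[1]])
  }
  new_ensemble_selection(mat, mat$ids[sort(chosen)], "diverse")
}

#' Choose K structures uniformly at random
#'
#' @inheritParams choose_exemplars
#' @return An `ensemble_selection`.
#' @export
choose_random <- function(mat, k, seed = 1L) {
  n <- length(mat$ids)
  if (k < 1 || k > n) stop("k must be in 1..N", call. = FALSE)
  idx <- withr::with_seed(seed, sort(sample.int(n, k)))
  new_ensemble_selection(mat, mat$ids[idx], "random")
}

#' Single-linkage similarity tree over structures
#'
#' Agglomerates the structures by single linkage on the distance
#' `1 - similarity`; each merge is annotated with the pocket similarity
#' at which it occurs (non-increasing toward the root). The tree serves
#' as the mutual-alignment guide and as a visual map of variant
#' redundancy.
#'
#' @param mat A [pocket_sim_matrix()].
#' @return Object of class `similarity_tree` wrapping the `hclust`
#'   result, with `merge_similarity` per merge and the structure ids.
#' @export
single_linkage_tree <- function(mat) {
  n <- length(mat$ids)
  if (n == 1) {
    return(structure(list(hclust = NULL, ids = mat$ids,
                          merge_similarity = numeric()),
                     class = "similarity_tree"))
  }
  hc <- stats::hclust(stats::as.dist(sim_to_dist(mat)), method = "single")
  hc$labels <- mat$ids
  structure(list(hclust = hc, ids = mat$ids,
                 merge_similarity = 1 - hc$height),
            class = "similarity_tree")
}

#' @export
print.similarity_tree <- function(x, ...) {
  cat(sprintf("<similarity_tree> %d leaves\n", length(x$ids)))
  invisible(x)
}

#' Tidy a similarity tree
#'
#' @param x A [single_linkage_tree()] result.
#' @param ... Unused.
#' @return Tibble with one row per merge: `merge`, `height` (distance)
#'   and `similarity`.
#' @export
tidy.similarity_tree <- function(x, ...) {
  if (is.null(x$hclust)) {
    return(tibble::tibble(merge = integer(), height = numeric(),
                          similarity = numeric()))
  }
  tibble::tibble(merge = seq_along(x$hclust$height),
                 height = x$hclust$height,
                 similarity = x$merge_similarity)
}

#' Export a similarity tree to Newick
#'
#' Branch lengths derive from the merge distances (via [ape::as.phylo()]
#' on the underlying `hclust`); internal node labels carry the merge
#' similarity.
#'
#' @param tree A [single_linkage_tree()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  if (is.null(tree$hclust)) {
    writeLines(paste0(tree$ids, ";"), path)
    return(invisible(path))
  }
  phy <- ape::as.phylo(tree$hclust)
  # hclust merge h corresponds to phylo internal node; annotate with the
  # similarity at merge in the order as.phylo assigns internal nodes
  phy$node.label <- sprintf("sim=%.4f", rev(sort(tree$merge_similarity)))
  ape::write.tree(phy, file = path)
  invisible(path)
}
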