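#' Construct a complex record for curation
#'
#' One protein-ligand complex as needed by the benchmark curation
#' filters: an identifier, a deposition date, the bound ligand pose, and
#' (optionally) the positions and elements of the protein contact-shell
#' atoms around the site.
#'
#' @param id Structure identifier.
#' @param deposition_date Date (or string parseable as `YYYY-MM-DD`).
#' @param ligand A [pose()].
#' @param protein_atoms Optional data frame with columns `x`, `y`, `z`,
#'   `element` for protein atoms near the site.
#' @return Object of class `complex_record`.
#' @export
complex_record <- function(id, deposition_date, ligand,
                           protein_atoms = NULL) {
  date <- tryCatch(as.Date(deposition_date), error = function(e) NA)
  if (is.na(date)) {
    stop("record ", id, ": unparseable deposition date: ",
         deposition_date, call. = FALSE)
  }
  stopifnot(inherits(ligand, "pose"))
  if (!is.null(protein_atoms)) {
    protein_atoms <- tibble::as_tibble(protein_atoms)
    stopifnot(all(c("x", "y", "z", "element") %in% names(protein_atoms)))
  }
  structure(list(id = as.character(id), deposition_date = date,
                 ligand = ligand, protein_atoms = protein_atoms),
            class = "complex_record")
}

#' Curation filters for a protein-ligand complex
#'
#' Applies the four independent ligand-curation rules used to build
#' benchmark sets from crystallographic complexes:
#' \describe{
#'   \item{element}{the ligand contains only whitelisted elements
#'     (default H, C, N, O, S, P, F, Cl, Br, I);}
#'   \item{weight}{molecular weight below `mw_max` (default 1000 Da);}
#'   \item{contacts}{at least `min_contacts` (default 3) ligand heavy
#'     atoms have a van der Waals surface-to-surface distance below
#'     `contact_dist` (default 1.0 Angstrom) to some protein atom;}
#'   \item{buriedness}{the ratio of protein atoms within
#'     `buried_shell` (default 4.0 Angstrom) of any ligand heavy atom to
#'     the number of ligand heavy atoms is at least `buried_min`
#'     (default 0.3), rejecting surface-grazing ligands.}
#' }
#' Without protein atoms only the two ligand-intrinsic rules are
#' evaluated and the result is flagged.
#'
#' @param rec A [complex_record()].
#' @param whitelist Allowed element symbols.
#' @param mw_max Maximum molecular weight (Da).
#' @param contact_dist,min_contacts Contact rule parameters.
#' @param buried_shell,buried_min Buriedness rule parameters.
#' @return One-row tibble: `id`, logical columns `element`, `weight`,
#'   `contacts`, `buriedness`, `pass` (all evaluated rules true),
#'   `partial` (protein shell missing), and `reasons` (comma-separated
#'   failed rules, `""` if none).
#' @export
ligand_passes_filters <- function(rec,
                                  whitelist = c("H", "C", "N", "O", "S",
                                                "P", "F", "Cl", "Br", "I"),
                                  mw_max = 1000,
                                  contact_dist = 1.0, min_contacts = 3L,
                                  buried_shell = 4.0, buried_min = 0.3) {
  mol <- rec$ligand$mol
  r_elem <- all(mol$atoms$element %in% whitelist)
  r_mw <- molecular_weight(mol) < mw_max
  heavy <- heavy_atoms(mol)
  lig_xyz <- rec$ligand$coords[heavy, , drop = FALSE]
  lig_r <- vdw_radii()[mol$atoms$element[heavy]]
  partial <- is.null(rec$protein_atoms)
  if (partial) {
    r_contact <- NA
    r_buried <- NA
  } else {
    pa <- rec$protein_atoms
    pr_xyz <- as.matrix(pa[, c("x", "y", "z")])
    pr_r <- vdw_radii()[pa$element]
    d <- sqrt(outer(rowSums(lig_xyz^2), rowSums(pr_xyz^2), "+") -
                2 * lig_xyz %*% t(pr_xyz))
    # surface-to-surface distance
    surf <- d - outer(lig_r, pr_r, "+")
    r_contact <- sum(apply(surf, 1, min) < contact_dist) >= min_contacts
    near <- colSums(d <= buried_shell) > 0
    r_buried <- (sum(near) / length(heavy)) >= buried_min
  }
  evaluated <- c(element = r_elem, weight = r_mw,
                 contacts = r_contact, buriedness = r_buried)
  failed <- names(evaluated)[!is.na(evaluated) & !evaluated]
  tibble::tibble(id = rec$id, element = r_elem, weight = r_mw,
                 contacts = r_contact, buriedness = r_buried,
                 pass = all(evaluated[!is.na(evaluated)]),
                 partial = partial,
                 reasons = paste(failed, collapse = ","))
}

#' Curate a set of complex records
#'
#' Convenience wrapper applying [ligand_passes_filters()] to each record.
#'
#' @param records List of [complex_record()]s.
#' @param ... Passed to [ligand_passes_filters()].
#' @return Tibble with one row per record.
#' @export
curate_records <- function(records, ...) {
  dplyr::bind_rows(lapply(records, ligand_passes_filters, ...))
}

#' Temporal split of complexes into early (knowledge) and test sets
#'
#' Sorts the records by deposition date (ties by id) and partitions the
#' earliest `ceiling(early_fraction * N)` into the early set — the
#' complexes whose ligands and structures may inform predictions — with
#' the remainder reserved for testing. The split is disjoint and
#' exhaustive.
#'
#' @param records List of [complex_record()]s (N >= 4).
#' @param early_fraction Fraction assigned to the early set (default
#'   0.25).
#' @return List with elements `early` and `test` (lists of records, in
#'   date order) and `cutoff_date` (latest early deposition date).
#' @export
temporal_split <- function(records, early_fraction = 0.25) {
  if (length(records) < 4) stop("need at least 4 records", call. = FALSE)
  dates <- as.Date(vapply(records, function(r) {
    as.character(r$deposition_date)
  }, character(1)))
  ids <- vapply(records, function(r) r$id, character(1))
  ord <- order(dates, ids)
  n_early <- ceiling(early_fraction * length(records))
  early <- records[ord[seq_len(n_early)]]
  test <- records[ord[-seq_len(n_early)]]
  list(early = early, test = test,
       cutoff_date = max(dates[ord[seq_len(n_early)]]))
}

#' Drop ligands far from the common site centroid
#'
#' Ligands for one target must bind in roughly the same place; ligands
#' whose heavy-atom centroid deviates from the centroid of all ligands
#' by more than `max_dist` are removed. The boundary is closed: a
#' ligand at exactly `max_dist` is retained.
#'
#' @param ligands List of [pose()]s.
#' @param max_dist Maximum centroid deviation in Angstrom (default 10).
#' @return The retained sub-list, with attribute `dropped` (indices).
#' @export
centroid_filter <- function(ligands, max_dist = 10) {
  cents <- t(vapply(ligands, pose_centroid, numeric(3)))
  overall <- colMeans(cents)
  dev <- sqrt(rowSums((cents - matrix(overall, nrow(cents), 3,
                                      byrow = TRUE))^2))
  # closed boundary, robust to floating-point noise at the threshold
  keep <- dev - max_dist <= 1e-9
  out <- ligands[keep]
  attr(out, "dropped") <- which(!keep)
  out
}

#' Evaluate ranked pose families against reference poses
#'
#' For each ligand, computes per family the minimum symmetry-corrected
#' RMSD over member poses to the reference pose (minimum over alternate
#' references when several are given), in family rank order, and derives
#' the best deviation within the top k families for k in 1, 2, 5, 10 and
#' all.
#'
#' @param families_per_ligand Named list; per ligand a
#'   [build_pose_families()] tibble.
#' @param poses_per_ligand Named list; per ligand the pose pool the
#'   families index into.
#' @param references Named list; per ligand a reference `pose` or list
#'   of alternates.
#' @param ops Optional [site_ops()] (e.g. [site_c2()]).
#' @return Tibble of class `pose_eval`, one row per ligand: `ligand`,
#'   `family_rmsd` (list, per family minimum RMSD in rank order), and
#'   `top1`, `top2`, `top5`, `top10`, `top_all` (best RMSD within the
#'   top k families; non-increasing in k).
#' @export
evaluate_families <- function(families_per_ligand, poses_per_ligand,
                              references, ops = NULL) {
  ligs <- names(families_per_ligand)
  rows <- lapply(ligs, function(lg) {
    fam <- families_per_ligand[[lg]]
    poses <- poses_per_ligand[[lg]]
    refs <- references[[lg]]
    if (inherits(refs, "pose")) refs <- list(refs)
    auto <- enumerate_automorphisms(poses[[1]]$mol)
    fr <- vapply(seq_len(nrow(fam)), function(f) {
      min(vapply(fam$members[[f]], function(i) {
        symmetry_rmsd_multi(poses[[i]], refs, ops = ops,
                            automorphisms = auto)
      }, numeric(1)))
    }, numeric(1))
    best_at <- function(k) min(fr[seq_len(min(k, length(fr)))])
    tibble::tibble(ligand = lg, family_rmsd = list(fr),
                   top1 = best_at(1), top2 = best_at(2),
                   top5 = best_at(5), top10 = best_at(10),
                   top_all = min(fr))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pose_eval", class(out))
  out
}

#' Success rate at an RMSD threshold and family rank
#'
#' @param eval_tbl An [evaluate_families()] result.
#' @param threshold RMSD success threshold in Angstrom (default 2.0).
#' @param k Family rank depth: 1, 2, 5, 10 or `Inf`.
#' @return Fraction of ligands whose best deviation within the top k
#'   families is at or below the threshold.
#' @export
success_rate <- function(eval_tbl, threshold = 2.0, k = 1) {
  col <- switch(as.character(k), `1` = "top1", `2` = "top2",
                `5` = "top5", `10` = "top10", "top_all")
  mean(eval_tbl[[col]] <= threshold)
}

#' Cumulative histogram of deviations
#'
#' Numerical integration of the standard histogram: for each edge, the
#' proportion of values at or below it. Non-decreasing and reaching 1
#' once the last edge passes the maximum value.
#'
#' @param values Numeric deviations (Angstrom), nonempty.
#' @param edges Increasing numeric bin edges.
#' @return Tibble of class `cumulative_histogram` with `edge` and
#'   `proportion`.
#' @export
cumulative_histogram <- function(values, edges = seq(0, 10, by = 0.25)) {
  if (length(values) == 0) stop("no values supplied", call. = FALSE)
  stopifnot(!is.unsorted(edges))
  out <- tibble::tibble(
    edge = edges,
    proportion = vapply(edges, function(e) mean(values <= e), numeric(1)))
  class(out) <- c("cumulative_histogram", class(out))
  out
}

#' Fraction of novel test items
#'
#' An item is novel when its maximal similarity to every known item
#' falls strictly below the threshold. Applied to protein pockets (via
#' a pocket similarity) and to ligand binding modes (via in-frame 3D
#' similarity of bound poses).
#'
#' @param test_items,knowns Lists of items.
#' @param similarity Function of two items returning a similarity.
#' @param threshold Novelty threshold; items strictly below are novel.
#' @return Fraction in \[0, 1\], with attribute `max_sim` (per test
#'   item). With no knowns every item is vacuously novel (warning).
#' @export
novelty_fraction <- function(test_items, knowns, similarity, threshold) {
  if (length(knowns) == 0) {
    warning("no known items: every test item is vacuously novel",
            call. = FALSE)
    out <- 1
    attr(out, "max_sim") <- rep(-Inf, length(test_items))
    return(out)
  }
  max_sim <- vapply(test_items, function(t) {
    max(vapply(knowns, function(k) similarity(t, k), numeric(1)))
  }, numeric(1))
  out <- mean(max_sim < threshold)
  attr(out, "max_sim") <- max_sim
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of deviation distributions
#'
#' @param a,b Numeric samples (e.g. per-ligand best RMSD under two
#'   protocols).
#' @return Tibble with `statistic` (D) and `p_value` (asymptotic).
#' @export
ks_compare <- function(a, b) {
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  tibble::tibble(statistic = unname(kt$statistic),
                 p_value = kt$p.value)
}

#' Exact two-sided binomial test
#'
#' @param successes Number of successes.
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @return Tibble with `estimate` and `p_value` (exact, two-sided).
#' @export
exact_binomial <- function(successes, n, p0 = 0.5) {
  bt <- stats::binom.test(successes, n, p = p0)
  tibble::tibble(estimate = unname(bt$estimate), p_value = bt$p.value)
}
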