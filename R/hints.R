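#' Search budget for the depth-first substructure search
#'
#' The common-substructure search is non-exhaustive: it terminates either
#' by exhaustion or once more than `recurrence_limit` recurrence
#' initiations (entries into the depth-first extend step) have occurred
#' since the last discovery of a larger matching substructure.
#'
#' @param recurrence_limit Integer budget (default 10000).
#' @return Object of class `search_budget`.
#' @export
search_budget <- function(recurrence_limit = 10000L) {
  stopifnot(recurrence_limit >= 0)
  structure(list(recurrence_limit = as.integer(recurrence_limit)),
            class = "search_budget")
}

# Compatibility rules (conservative, to keep hint geometry chemically
# meaningful): atoms match on element + aromatic flag; bonds match on
# aromatic flag, and on order when not aromatic.
atoms_compatible <- function(la, ka) {
  la$element == ka$element & la$aromatic == ka$aromatic
}

bond_compatible <- function(o1, ar1, o2, ar2) {
  ar1 == ar2 & (ar1 | o1 == o2)
}

#' Common connected substructures between a ligand and a known bound pose
#'
#' Depth-first search for connected common subgraphs between the
#' heavy-atom graphs of `ligand` and the molecule of `known`, with a
#' recurrence budget. A mapping must preserve atom compatibility
#' (element + aromatic flag) and be mutually bond-consistent: two mapped
#' ligand atoms are bonded iff their images are, with compatible bond
#' type. Only maximal (non-extendable) matches with at least
#' `min_atoms` heavy atoms are kept; matches on the same known ligand
#' with identical or subset ligand atom sets are pruned as redundant.
#'
#' @param ligand A [molecule()] (or pose) to be docked.
#' @param known A [pose()] of a known bound ligand (coordinates used for
#'   hint fragments downstream).
#' @param budget A [search_budget()].
#' @param min_atoms Minimum heavy atoms per match (default 4).
#' @return Tibble with one row per match: `known_id`, `size`,
#'   `ligand_atoms` and `known_atoms` (list columns of matched atom
#'   indices, aligned), plus attribute `exhausted` (`FALSE` when the
#'   budget truncated the search).
#' @details The enumeration visits each connected ligand atom subset
#'   exactly once (exclusive-neighborhood extension) while branching over
#'   the consistent images in the known molecule, so with an unlimited
#'   budget every maximal common connected subgraph is found.
#' @export
common_substructures <- function(ligand, known, budget = search_budget(),
                                 min_atoms = 4L) {
  if (inherits(ligand, "pose")) ligand <- ligand$mol
  kmol <- known$mol
  lh <- heavy_atoms(ligand)
  kh <- heavy_atoms(kmol)
  ladj <- adjacency(ligand, keep = lh)
  kadj <- adjacency(kmol, keep = kh)
  lat <- ligand$atoms
  kat <- kmol$atoms

  since_best <- 0L
  best_size <- 0L
  exhausted <- TRUE
  matches <- list()

  bond_between <- function(adjl, v, u) {
    hit <- which(adjl[[v]]$nbr == u)
    if (length(hit) == 0) return(NULL)
    list(order = adjl[[v]]$order[hit], aromatic = adjl[[v]]$aromatic[hit])
  }

  record <- function(sub_l, sub_k) {
    sz <- length(sub_l)
    if (sz < min_atoms) return()
    if (sz > best_size) {
      best_size <<- sz
      since_best <<- 0L
    }
    matches[[length(matches) + 1L]] <<- list(l = sub_l, k = sub_k)
  }

  # ESU-style recursion: sub_l grows only through `ext` (neighbors of the
  # subset with index > root, discovered exclusively), so each connected
  # ligand subset is generated once; sub_k carries the aligned image.
  extend <- function(sub_l, sub_k, ext, root) {
    since_best <<- since_best + 1L
    if (since_best > budget$recurrence_limit) {
      exhausted <<- FALSE
      return()
    }
    record(sub_l, sub_k)
    while (length(ext) > 0) {
      w <- ext[1]
      ext <- ext[-1]
      # exclusive new neighbors of w (not in sub, not adjacent to sub)
      nb_sub <- unique(unlist(lapply(sub_l, function(v) ladj[[v]]$nbr)))
      new_ext <- setdiff(ladj[[w]]$nbr[ladj[[w]]$nbr > root],
                         c(sub_l, nb_sub))
      for (b in kh) {
        if (b %in% sub_k) next
        if (!(lat$element[w] == kat$element[b] &&
              lat$aromatic[w] == kat$aromatic[b])) next
        ok <- TRUE
        linked <- FALSE
        for (p in seq_along(sub_l)) {
          bl <- bond_between(ladj, sub_l[p], w)
          bk <- bond_between(kadj, sub_k[p], b)
          if (is.null(bl) != is.null(bk)) { ok <- FALSE; break }
          if (!is.null(bl)) {
            if (!bond_compatible(bl$order, bl$aromatic,
                                 bk$order, bk$aromatic)) {
              ok <- FALSE; break
            }
            linked <- TRUE
          }
        }
        if (!ok || !linked) next
        extend(c(sub_l, w), c(sub_k, b), c(ext, new_ext), root)
        if (since_best > budget$recurrence_limit) return()
      }
    }
  }

  for (a in lh) {
    for (b in kh) {
      if (lat$element[a] == kat$element[b] &&
          lat$aromatic[a] == kat$aromatic[b]) {
        extend(a, b, ladj[[a]]$nbr[ladj[[a]]$nbr > a], a)
        if (since_best > budget$recurrence_limit) break
      }
    }
    if (since_best > budget$recurrence_limit) break
  }

  if (length(matches) == 0) {
    out <- tibble::tibble(known_id = character(), size = integer(),
                          ligand_atoms = list(), known_atoms = list())
    attr(out, "exhausted") <- exhausted
    return(out)
  }
  # order atoms within each match for stable set comparison
  keyed <- vapply(matches, function(m) {
    paste(sort(m$l), collapse = ",")
  }, character(1))
  keep <- !duplicated(keyed)
  matches <- matches[keep]
  sets <- lapply(matches, function(m) sort(m$l))
  sizes <- lengths(sets)
  # prune matches whose ligand atom set is a subset of another match's
  subset_of_other <- vapply(seq_along(sets), function(i) {
    any(vapply(seq_along(sets), function(j) {
      j != i && sizes[j] >= sizes[i] && all(sets[[i]] %in% sets[[j]]) &&
        !(sizes[j] == sizes[i] && j > i)
    }, logical(1)))
  }, logical(1))
  matches <- matches[!subset_of_other]
  out <- tibble::tibble(
    known_id = kmol$name,
    size = vapply(matches, function(m) length(m$l), integer(1)),
    ligand_atoms = lapply(matches, function(m) m$l),
    known_atoms = lapply(matches, function(m) m$k))
  out <- out[order(-out$size), ]
  attr(out, "exhausted") <- exhausted
  out
}

#' Extract ranked, positioned substructure hints from known bound ligands
#'
#' Mines common substructures between a ligand to be docked and each
#' known bound ligand pose ([common_substructures()]), turns each match
#' into a positioned fragment pose (coordinates copied verbatim from the
#' known bound pose), scores every fragment by its 2D similarity
#' ([gsim()]) to the whole ligand, and returns the top `max_hints`
#' fragments. These are the knowledge fragments a docking engine can use
#' as additional alignment seeds; injecting them into a search engine is
#' outside this toolkit.
#'
#' @param ligand [molecule()] or pose to be docked.
#' @param knowns List of known bound ligand [pose()]s (may be empty).
#' @param max_hints Maximum number of hints retained (default 50).
#' @param budget A [search_budget()].
#' @param min_atoms Minimum heavy atoms per hint (default 4).
#' @return Tibble sorted by descending `gsim` (ties: larger `size`
#'   first, then `known_id`): columns `known_id`, `size`, `gsim`,
#'   `ligand_atoms`, `known_atoms`, `fragment` (list of fragment poses).
#' @export
extract_hints <- function(ligand, knowns, max_hints = 50L,
                          budget = search_budget(), min_atoms = 4L) {
  if (inherits(ligand, "pose")) ligand <- ligand$mol
  if (length(knowns) == 0) {
    return(tibble::tibble(known_id = character(), size = integer(),
                          gsim = numeric(), ligand_atoms = list(),
                          known_atoms = list(), fragment = list()))
  }
  per_known <- lapply(knowns, function(kp) {
    m <- common_substructures(ligand, kp, budget = budget,
                              min_atoms = min_atoms)
    if (nrow(m) == 0) return(m)
    m$fragment <- lapply(seq_len(nrow(m)), function(r) {
      idx <- m$known_atoms[[r]]
      frag <- induced_subgraph(kp$mol, idx,
                               name = paste0(kp$mol$name, "-frag"))
      pose(frag, kp$coords[sort(idx), , drop = FALSE])
    })
    m
  })
  hints <- dplyr::bind_rows(per_known)
  if (nrow(hints) == 0) {
    hints$gsim <- numeric()
    hints$fragment <- list()
    return(hints)
  }
  hints$gsim <- vapply(hints$fragment, function(f) gsim(f$mol, ligand),
                       numeric(1))
  ord <- order(-hints$gsim, -hints$size, hints$known_id)
  hints <- hints[ord, ]
  utils::head(hints, max_hints)
}
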