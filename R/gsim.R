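#' Enumerate rooted subgraph keys of a molecule
#'
#' For every heavy atom, the neighborhood "ball" of graph radius 0..
#' `max_depth` (atoms and bonds within that graph distance over the
#' heavy-atom graph) is encoded as a canonical string, invariant to atom
#' input order. Per root, balls that stop growing are deduplicated: once
#' the depth-d ball equals the depth-(d-1) ball the key is emitted only
#' once. The multiset of keys underlies the 2D similarity [gsim()].
#'
#' Canonicalization uses iterated color refinement inside each ball with
#' the root marked, so two keys are equal exactly when the rooted balls
#' are refinement-equivalent (identical for chemical graphs of this
#' size).
#'
#' @param mol A [molecule()].
#' @param max_depth Maximum ball radius (default 3).
#' @return Tibble with one row per retained (root, depth) key: `key`
#'   (canonical string), `depth`, `root` (atom index), `hetero` (root is
#'   a non-carbon heavy atom).
#' @export
enumerate_subgraphs <- function(mol, max_depth = 3L) {
  heavy <- heavy_atoms(mol)
  adj <- adjacency(mol, keep = heavy)
  rows <- list()
  for (root in heavy) {
    d <- graph_distances(adj, root, n_atoms(mol))
    seen <- character()
    for (depth in 0:max_depth) {
      ball <- heavy[!is.na(d[heavy]) & d[heavy] <= depth]
      key <- canonical_ball_key(mol, adj, ball, root)
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        key = key, depth = depth, root = root,
        hetero = mol$atoms$element[root] != "C")
    }
  }
  dplyr::bind_rows(rows)
}

# Deterministic content hash of a string: two polynomial hashes over
# different moduli, molecule-independent, so equal signatures give equal
# compressed labels across molecules.
label_hash <- function(s) {
  vapply(s, function(x) {
    v <- utf8ToInt(x)
    h1 <- 0; h2 <- 0
    for (c in v) {
      h1 <- (h1 * 131 + c) %% 1000000007
      h2 <- (h2 * 137 + c) %% 998244353
    }
    sprintf("%d.%d", h1, h2)
  }, character(1), USE.NAMES = FALSE)
}

# Canonical string of the induced rooted subgraph on `ball`. Labels start
# from atom type (+ root marker) and are refined |ball| rounds by sorted
# neighbor (bond type, label) multisets, compressing each round's
# signature with a content hash so strings stay bounded while remaining
# a pure function of the rooted ball. The key combines ball size, the
# root's final label, and the sorted multiset of all final labels.
canonical_ball_key <- function(mol, adj, ball, root) {
  at <- atom_type(mol, ball)
  lab <- ifelse(ball == root, paste0("*", at), at)
  for (round in seq_len(max(1L, length(ball)))) {
    lab_of <- stats::setNames(lab, ball)
    sig <- vapply(seq_along(ball), function(k) {
      v <- ball[k]
      keep <- adj[[v]]$nbr %in% ball
      parts <- sort(paste0(bond_type(adj[[v]]$order[keep],
                                     adj[[v]]$aromatic[keep]),
                           ">", lab_of[as.character(adj[[v]]$nbr[keep])]))
      paste0(lab_of[as.character(v)], "(", paste(parts, collapse = ","), ")")
    }, character(1))
    lab <- label_hash(sig)
    # keep the root marker alive through the hashing
    lab[ball == root] <- paste0("*", lab[ball == root])
  }
  paste0(length(ball), "|", lab[ball == root], "|",
         paste(sort(lab), collapse = ";"))
}

#' 2D graph similarity between two molecules
#'
#' Rooted-subgraph similarity on the heavy-atom graphs: all neighborhood
#' balls up to `max_depth` are enumerated for both molecules
#' ([enumerate_subgraphs()]); the tally of keys of one molecule found in
#' the other is computed bidirectionally, weighted to favor keys rooted
#' at heteroatoms, and normalized to \[0, 1\] so that identical molecules
#' score exactly 1.
#'
#' The score is `(matched(A in B) + matched(B in A)) / (total(A) +
#' total(B))` on weighted key counts, with multiset matching (a key
#' occurring a times in A and b times in B contributes `min(a, b)` per
#' direction).
#'
#' @param a,b [molecule()] (or `pose`; the graph is used).
#' @param max_depth Ball radius limit, default 3.
#' @param hetero_weight Weight of keys rooted at non-carbon atoms
#'   (carbon-rooted keys weigh 1); default 2.
#' @return Similarity in \[0, 1\]; symmetric; 1 for identical graphs.
#' @export
gsim <- function(a, b, max_depth = 3L, hetero_weight = 2) {
  if (inherits(a, "pose")) a <- a$mol
  if (inherits(b, "pose")) b <- b$mol
  ka <- enumerate_subgraphs(a, max_depth)
  kb <- enumerate_subgraphs(b, max_depth)
  gsim_from_keys(ka, kb, hetero_weight)
}

gsim_from_keys <- function(ka, kb, hetero_weight = 2) {
  wa <- ifelse(ka$hetero, hetero_weight, 1)
  wb <- ifelse(kb$hetero, hetero_weight, 1)
  ca <- tapply(wa, ka$key, sum)      # weighted count per key
  cb <- tapply(wb, kb$key, sum)
  shared <- intersect(names(ca), names(cb))
  matched <- sum(pmin(ca[shared], cb[shared]))
  (matched + matched) / (sum(ca) + sum(cb))
}

#' Pairwise 2D similarity matrix
#'
#' @param as,bs Lists of molecules or poses.
#' @inheritParams gsim
#' @return Numeric `length(as)` x `length(bs)` matrix of [gsim()] values.
#' @export
gsim_matrix <- function(as, bs, max_depth = 3L, hetero_weight = 2) {
  keys <- function(x) {
    if (inherits(x, "pose")) x <- x$mol
    enumerate_subgraphs(x, max_depth)
  }
  ka <- lapply(as, keys)
  kb <- lapply(bs, keys)
  out <- matrix(0, length(as), length(bs))
  for (i in seq_along(as)) {
    for (j in seq_along(bs)) {
      out[i, j] <- gsim_from_keys(ka[[i]], kb[[j]], hetero_weight)
    }
  }
  out
}
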