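#' Enumerate graph automorphisms of a molecule's heavy-atom graph
#'
#' Finds all permutations of the heavy atoms that preserve atom types
#' (element, formal charge, aromatic flag) and bonds (order and aromatic
#' flag). Hydrogens are ignored: the automorphisms feed the heavy-atom
#' RMSD correction. The search uses iterated neighborhood color
#' refinement to partition atoms into equivalence candidates, then
#' backtracks over consistent assignments.
#'
#' @param mol A [molecule()] with a connected heavy-atom graph.
#' @param max_count Hard cap on the number of automorphisms returned.
#'   Pathologically symmetric graphs are truncated at the cap with a
#'   warning of class `poseguide_truncated`.
#' @return List of integer permutations over the heavy atoms of `mol`
#'   (values and positions index into `heavy_atoms(mol)`); the identity
#'   permutation is always first. Attribute `truncated` is `TRUE` when
#'   the cap was hit.
#' @examples
#' benzene <- ring_molecule(6, aromatic = TRUE)
#' length(enumerate_automorphisms(benzene))  # 12: rotations x reflections
#' @export
enumerate_automorphisms <- function(mol, max_count = 10000L) {
  heavy <- heavy_atoms(mol)
  n <- length(heavy)
  if (!is_connected(mol)) {
    stop("heavy-atom graph must be connected", call. = FALSE)
  }
  adj <- adjacency(mol, keep = heavy)
  # local (1..n) view of the heavy-atom graph
  loc <- match(seq_len(n_atoms(mol)), heavy)
  nbr <- lapply(heavy, function(v) loc[adj[[v]]$nbr])
  btyp <- lapply(heavy, function(v) bond_type(adj[[v]]$order,
                                              adj[[v]]$aromatic))
  # color refinement: start from atom type + degree, refine by sorted
  # multiset of (bond type, neighbor color) until stable
  col <- paste0(atom_type(mol, heavy), "/", lengths(nbr))
  repeat {
    sig <- vapply(seq_len(n), function(v) {
      paste0(col[v], "|",
             paste(sort(paste0(btyp[[v]], ">", col[nbr[[v]]])),
                   collapse = ","))
    }, character(1))
    new_col <- as.character(match(sig, sort(unique(sig))))
    # refinement is stable once the partition stops splitting
    if (length(unique(new_col)) == length(unique(col))) {
      col <- new_col
      break
    }
    col <- new_col
  }
  perms <- list()
  truncated <- FALSE
  # order vertices most-constrained first (rarest color, highest degree)
  col_freq <- table(col)
  ord <- order(as.integer(col_freq[col]), -lengths(nbr))
  mapping <- integer(n)
  used <- logical(n)
  extend <- function(pos) {
    if (truncated) return()
    if (pos > n) {
      perms[[length(perms) + 1L]] <<- mapping
      if (length(perms) >= max_count) truncated <<- TRUE
      return()
    }
    v <- ord[pos]
    # candidates: same color, unused, consistent with already-mapped nbrs
    for (w in which(col == col[v] & !used)) {
      ok <- TRUE
      for (t in seq_along(nbr[[v]])) {
        u <- nbr[[v]][t]
        if (mapping[u] != 0L) {
          hit <- which(nbr[[w]] == mapping[u])
          if (length(hit) != 1 || btyp[[w]][hit] != btyp[[v]][t]) {
            ok <- FALSE
            break
          }
        }
      }
      if (!ok) next
      # degree must match (colors encode it, but keep the guard cheap)
      if (length(nbr[[w]]) != length(nbr[[v]])) next
      mapping[v] <<- w
      used[w] <<- TRUE
      extend(pos + 1L)
      mapping[v] <<- 0L
      used[w] <<- FALSE
      if (truncated) return()
    }
  }
  extend(1L)
  if (truncated) {
    warning(warningCondition(
      sprintf("automorphism enumeration truncated at %d", max_count),
      class = "poseguide_truncated"))
  }
  ident <- which(vapply(perms, function(p) all(p == seq_len(n)), logical(1)))
  perms <- c(perms[ident], perms[-ident])
  attr(perms, "truncated") <- truncated
  perms
}

#' Rigid site symmetry operations
#'
#' Builds a set of rigid transforms describing a binding-site symmetry,
#' e.g. the C2 axis of the HIV protease site. The identity transform is
#' always included.
#'
#' @param rotations List of 3x3 proper rotation matrices (det +1).
#' @param translations List of length-3 vectors, one per rotation.
#' @param centers Optional list of rotation centers; a rotation about a
#'   center c is expanded to `x -> R (x - c) + c`.
#' @return Object of class `site_ops`: list of `list(R, t)` transforms,
#'   identity first.
#' @export
site_ops <- function(rotations = list(), translations = NULL,
                     centers = NULL) {
  ops <- list(list(R = diag(3), t = c(0, 0, 0)))
  for (k in seq_along(rotations)) {
    R <- rotations[[k]]
    stopifnot(all(dim(R) == c(3, 3)))
    if (abs(det(R) - 1) > 1e-8 || max(abs(t(R) %*% R - diag(3))) > 1e-8) {
      stop("site operation must be a proper rigid rotation", call. = FALSE)
    }
    t <- if (is.null(translations)) c(0, 0, 0) else translations[[k]]
    if (!is.null(centers)) {
      c0 <- centers[[k]]
      t <- t + as.numeric(c0 - R %*% c0)
    }
    ops[[length(ops) + 1L]] <- list(R = R, t = as.numeric(t))
  }
  structure(ops, class = "site_ops")
}

#' C2 site symmetry about an axis
#'
#' Convenience constructor for a two-fold (180 degree) site symmetry such
#' as the HIV protease active site.
#'
#' @param axis Length-3 axis direction.
#' @param center Length-3 point on the axis.
#' @return A [site_ops()] object with the identity and the C2 rotation.
#' @export
site_c2 <- function(axis = c(0, 0, 1), center = c(0, 0, 0)) {
  site_ops(rotations = list(rotation_about_axis(axis, pi)),
           centers = list(center))
}

plain_rmsd <- function(a, b) {
  sqrt(mean(rowSums((a - b)^2)))
}

#' Symmetry-corrected RMSD between two poses
#'
#' Heavy-atom RMSD between a predicted and a reference pose sharing the
#' same molecular graph, minimized over all graph automorphisms of the
#' molecule and over any supplied rigid site symmetry operations. The
#' poses are compared in their shared site frame; no superposition is
#' performed.
#'
#' @param pred,ref `pose` objects with identical molecular graphs (same
#'   atom order).
#' @param ops Optional [site_ops()]; identity is always considered.
#' @param automorphisms Optional precomputed result of
#'   [enumerate_automorphisms()] (saves recomputation in loops).
#' @return Minimum RMSD in Angstrom (non-negative scalar).
#' @examples
#' m <- chain_molecule(c("C", "N", "O"))
#' p <- pose(m, matrix(c(0, 0, 0, 1.5, 0, 0, 3, 0, 0), 3, 3, byrow = TRUE))
#' symmetry_rmsd(p, transform_pose(p, translation = c(2, 0, 0)))  # 2.0
#' @export
symmetry_rmsd <- function(pred, ref, ops = NULL, automorphisms = NULL) {
  if (!same_graph(pred$mol, ref$mol)) {
    stop("poses do not share the same molecular graph", call. = FALSE)
  }
  heavy <- heavy_atoms(pred$mol)
  P <- pred$coords[heavy, , drop = FALSE]
  R0 <- ref$coords[heavy, , drop = FALSE]
  if (is.null(automorphisms)) {
    automorphisms <- enumerate_automorphisms(pred$mol)
  }
  if (is.null(ops)) ops <- site_ops()
  best <- Inf
  for (op in ops) {
    Rt <- R0 %*% t(op$R) + matrix(op$t, nrow(R0), 3, byrow = TRUE)
    for (perm in automorphisms) {
      # perm maps heavy position v of pred onto heavy position perm[v]
      best <- min(best, plain_rmsd(P[order(perm), , drop = FALSE], Rt))
    }
  }
  best
}

#' Minimum symmetry-corrected RMSD to a set of reference alternates
#'
#' Crystal structures occasionally report more than one alternate ligand
#' pose; the deviation of a prediction is then the minimum over the
#' alternates.
#'
#' @param pred A `pose`.
#' @param refs A `pose` or list of alternate reference poses.
#' @inheritParams symmetry_rmsd
#' @return Minimum RMSD in Angstrom.
#' @export
symmetry_rmsd_multi <- function(pred, refs, ops = NULL,
                                automorphisms = NULL) {
  if (inherits(refs, "pose")) refs <- list(refs)
  if (is.null(automorphisms)) {
    automorphisms <- enumerate_automorphisms(pred$mol)
  }
  min(vapply(refs, function(r) {
    symmetry_rmsd(pred, r, ops = ops, automorphisms = automorphisms)
  }, numeric(1)))
}
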