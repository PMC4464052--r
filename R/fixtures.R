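#' Simple molecule builders
#'
#' `chain_molecule()` builds a linear chain of the given elements with
#' single bonds; `ring_molecule()` builds a simple ring (aromatic by
#' default). Handy for tests and examples.
#'
#' @param elements Character vector of element symbols.
#' @param name Molecule name.
#' @return A [molecule()].
#' @export
chain_molecule <- function(elements, name = paste(elements, collapse = "")) {
  n <- length(elements)
  molecule(atoms = tibble::tibble(element = elements),
           bonds = if (n > 1) tibble::tibble(i = seq_len(n - 1),
                                             j = 2:n) else NULL,
           name = name)
}

#' @rdname chain_molecule
#' @param n Ring size.
#' @param aromatic Aromatic ring flag.
#' @param element Ring atom element.
#' @export
ring_molecule <- function(n = 6, aromatic = TRUE, element = "C",
                          name = sprintf("%s%d-ring", element, n)) {
  molecule(
    atoms = tibble::tibble(element = rep(element, n),
                           aromatic = rep(aromatic, n)),
    bonds = tibble::tibble(i = seq_len(n), j = c(2:n, 1L),
                           order = 1L, aromatic = aromatic),
    name = name)
}

#' Planar ring coordinates
#'
#' Regular polygon coordinates in the z = 0 plane, for building ring
#' poses.
#'
#' @param n Ring size.
#' @param bond_length Edge length in Angstrom (default 1.4).
#' @return n x 3 coordinate matrix.
#' @export
ring_coords <- function(n = 6, bond_length = 1.4) {
  r <- bond_length / (2 * sin(pi / n))
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(r * cos(th), r * sin(th), 0)
}

#' Specification for the synthetic docking fixtures
#'
#' Describes the statistical situation the guided-vs-unguided
#' experiment emulates: a pool of `n_poses` candidate poses per ligand
#' in which near-native poses (a `native_fraction` of the pool, within
#' `rmsd_spread` of the reference) are out-scored by decoy placements by
#' at least `score_gap` pKd — the regime where raw docking scores pick
#' the wrong binding mode and knowledge of `n_knowns` previously solved
#' ligands must rescue the ranking.
#'
#' @param seed Integer seed; every fixture is a pure function of its
#'   spec.
#' @param n_knowns Number of known bound ligands m (default 5).
#' @param n_poses Candidate pool size n per ligand (default 100).
#' @param native_fraction Fraction of near-native poses (default 0.1).
#' @param rmsd_spread Maximum RMSD of near-native poses to the
#'   reference, Angstrom (default and cap 1.0).
#' @param score_gap pKd margin by which every decoy out-scores every
#'   near-native pose (default 0.5).
#' @param scaffold_size Heavy atoms in the shared scaffold (default 8).
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_knowns = 5L, n_poses = 100L,
                         native_fraction = 0.1, rmsd_spread = 1.0,
                         score_gap = 0.5, scaffold_size = 8L) {
  stopifnot(n_knowns >= 1, n_poses >= 1, native_fraction > 0,
            rmsd_spread > 0, scaffold_size >= 6)
  structure(list(seed = as.integer(seed), n_knowns = as.integer(n_knowns),
                 n_poses = as.integer(n_poses),
                 native_fraction = native_fraction,
                 rmsd_spread = rmsd_spread, score_gap = score_gap,
                 scaffold_size = as.integer(scaffold_size)),
            class = "fixture_spec")
}

# embed one atom at distance 1.5 from parent, away from existing atoms
place_atom <- function(coords, parent, min_sep = 1.2) {
  for (try in 1:200) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    cand <- coords[parent, ] + 1.5 * u
    d <- sqrt(rowSums((coords - matrix(cand, nrow(coords), 3,
                                       byrow = TRUE))^2))
    d[parent] <- Inf
    if (all(d >= min_sep)) return(cand)
  }
  cand
}

#' Generate a series of ligands sharing a scaffold
#'
#' Builds `n_molecules` ligand poses around one connected random
#' scaffold (tree of `scaffold_size` heavy atoms with at least one
#' heteroatom), each decorated with 1-3 extra atoms including at least
#' one heteroatom. All poses share the scaffold coordinates, i.e. they
#' are mutually aligned in a common site frame, so any pair shares a
#' positioned common substructure of at least `scaffold_size` >= 4
#' atoms — the situation in which substructure hints and 3D similarity
#' to knowns are informative.
#'
#' @param spec A [fixture_spec()].
#' @param n_molecules Number of ligands (default `n_knowns + 1`; the
#'   first is conventionally the ligand under study).
#' @return List of [pose()]s (scores `NA`).
#' @export
make_ligand_series <- function(spec, n_molecules = spec$n_knowns + 1L) {
  withr::with_seed(spec$seed, {
    ns <- spec$scaffold_size
    # scaffold: random tree, mostly carbon with guaranteed heteroatoms
    elems <- rep("C", ns)
    elems[sample.int(ns, 2)] <- sample(c("N", "O"), 2, replace = TRUE)
    # random tree grown sequentially, total degree capped at 4
    parent <- rep(NA_integer_, ns)
    deg <- integer(ns)
    for (t in 2:ns) {
      cand <- which(deg[seq_len(t - 1)] < 4)
      parent[t] <- cand[sample.int(length(cand), 1L)]
      deg[parent[t]] <- deg[parent[t]] + 1L
      deg[t] <- 1L
    }
    sc_coords <- matrix(0, ns, 3)
    for (t in 2:ns) {
      sc_coords[t, ] <- place_atom(sc_coords[seq_len(t - 1), ,
                                             drop = FALSE], parent[t])
    }
    sc_deg <- deg
    lapply(seq_len(n_molecules), function(k) {
      n_dec <- sample(1:3, 1)
      dec_el <- c(sample(c("N", "O", "F"), 1),
                  sample(c("C", "C", "N", "O"), max(0, n_dec - 1),
                         replace = TRUE))
      open <- which(sc_deg < 4)
      att <- open[sample.int(length(open), n_dec)]
      atoms <- tibble::tibble(element = c(elems, dec_el))
      bonds <- tibble::tibble(i = c(parent[-1], att),
                              j = c(2:ns, ns + seq_len(n_dec)))
      coords <- sc_coords
      for (q in seq_len(n_dec)) {
        coords <- rbind(coords, place_atom(coords, att[q]))
      }
      pose(molecule(atoms, bonds, name = sprintf("lig%02d", k)), coords)
    })
  })
}

#' Generate a scored candidate pose cloud around a reference
#'
#' Near-native poses are seeded rigid perturbations of the reference
#' rescaled to an exact target RMSD at or below
#' `min(1, spec$rmsd_spread)` Angstrom; decoys are flipped (180 degree)
#' and translated placements pushed until their symmetry-corrected RMSD
#' to the reference is at least 4 Angstrom. Decoy docking scores exceed
#' every near-native score by at least `spec$score_gap` pKd, so the raw
#' ranking always prefers a decoy.
#'
#' @param reference A reference [pose()].
#' @param spec A [fixture_spec()].
#' @return List of scored poses (natives first), with attribute
#'   `native` (logical vector).
#' @export
make_pose_cloud <- function(reference, spec) {
  n <- spec$n_poses
  n_native <- max(1L, round(spec$native_fraction * n))
  auto <- enumerate_automorphisms(reference$mol)
  base <- 5.0
  withr::with_seed(spec$seed + 1L, {
    natives <- lapply(seq_len(n_native), function(i) {
      axis <- stats::rnorm(3)
      ctr <- pose_centroid(reference)
      pert <- transform_pose(
        transform_pose(reference, translation = -ctr),
        rotation = rotation_about_axis(axis, stats::runif(1, 0, 0.25)),
        translation = ctr + stats::runif(3, -0.3, 0.3))
      delta <- pert$coords - reference$coords
      r0 <- sqrt(mean(rowSums(delta^2)))
      target <- stats::runif(1, 0.15, min(1, spec$rmsd_spread))
      pose(reference$mol, reference$coords + (target / r0) * delta,
           score = base - stats::runif(1, 0, 0.3))
    })
    decoys <- lapply(seq_len(n - n_native), function(i) {
      ctr <- pose_centroid(reference)
      flip <- rotation_about_axis(stats::rnorm(3), pi)
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      shift <- stats::runif(1, 6, 10)
      p <- transform_pose(
        transform_pose(reference, translation = -ctr),
        rotation = flip, translation = ctr + shift * dir)
      while (symmetry_rmsd(p, reference, automorphisms = auto) < 4) {
        p <- transform_pose(p, translation = 2 * dir)
      }
      pose(p$mol, p$coords,
           score = base + spec$score_gap + stats::runif(1, 0, 0.3))
    })
  })
  out <- c(natives, decoys)
  attr(out, "native") <- c(rep(TRUE, n_native), rep(FALSE, n - n_native))
  out
}

#' Planted-block pocket similarity matrix
#'
#' Builds a symmetric unit-diagonal similarity matrix with planted
#' blocks (`within` similarity inside a block, `between` across blocks)
#' plus seeded symmetric noise, clipped to \[0, 1\].
#'
#' @param block_sizes Integer vector of block sizes.
#' @param within,between Block similarity levels.
#' @param noise Noise standard deviation (default 0).
#' @param seed Integer seed.
#' @param ids Optional structure ids.
#' @return A [pocket_sim_matrix()], with attribute `blocks` (planted
#'   labels).
#' @export
make_clustered_simmatrix <- function(block_sizes, within = 0.9,
                                     between = 0.1, noise = 0,
                                     seed = 1L, ids = NULL) {
  n <- sum(block_sizes)
  lab <- rep(seq_along(block_sizes), block_sizes)
  v <- ifelse(outer(lab, lab, "=="), within, between)
  if (noise > 0) {
    e <- withr::with_seed(seed, matrix(stats::rnorm(n * n, 0, noise), n, n))
    e <- (e + t(e)) / 2
    v <- v + e
  }
  v <- pmin(pmax(v, 0), 1)
  diag(v) <- 1
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(n))
  out <- pocket_sim_matrix(v, ids)
  attr(out, "blocks") <- lab
  out
}

# bonds whose removal disconnects the heavy graph (acyclic bonds)
is_bridge <- function(mol, bi) {
  b <- mol$bonds[bi, ]
  bonds2 <- mol$bonds[-bi, ]
  keep <- seq_len(n_atoms(mol))
  adj <- adjacency(molecule(mol$atoms[, c("element", "charge", "aromatic")],
                            bonds2, mol$name), keep)
  d <- graph_distances(adj, b$i, n_atoms(mol))
  is.na(d[b$j])
}

#' Randomize torsional angles of a pose
#'
#' Assigns seeded random dihedral rotations about every rotatable bond
#' (single, non-aromatic, acyclic, with both endpoints non-terminal),
#' rotating the smaller side of the molecule about the bond axis. Bond
#' lengths and angles are preserved exactly; this removes conformational
#' memory from input ligands without any minimization.
#'
#' @param p A [pose()].
#' @param seed Integer seed.
#' @return The torsion-randomized pose.
#' @export
randomize_torsions <- function(p, seed = 1L) {
  mol <- p$mol
  deg <- tabulate(c(mol$bonds$i, mol$bonds$j), n_atoms(mol))
  rot <- which(mol$bonds$order == 1L & !mol$bonds$aromatic &
                 deg[mol$bonds$i] > 1 & deg[mol$bonds$j] > 1)
  rot <- rot[vapply(rot, function(bi) is_bridge(mol, bi), logical(1))]
  if (length(rot) == 0) return(p)
  coords <- p$coords
  withr::with_seed(seed, {
    for (bi in rot) {
      i <- mol$bonds$i[bi]; j <- mol$bonds$j[bi]
      bonds2 <- mol$bonds[-bi, ]
      adj <- adjacency(molecule(mol$atoms[, c("element", "charge",
                                              "aromatic")],
                                bonds2, mol$name))
      dj <- graph_distances(adj, j, n_atoms(mol))
      side <- which(!is.na(dj))   # component containing j
      axis <- coords[j, ] - coords[i, ]
      R <- rotation_about_axis(axis, stats::runif(1, 0, 2 * pi))
      pivot <- coords[i, ]
      moved <- setdiff(side, i)
      coords[moved, ] <- sweep(coords[moved, , drop = FALSE], 2, pivot) %*%
        t(R) + matrix(pivot, length(moved), 3, byrow = TRUE)
    }
  })
  pose(mol, coords, p$score)
}

#' One ligand's guided-docking fixture
#'
#' Builds a complete single-ligand experiment from a [fixture_spec()]:
#' a ligand series sharing a scaffold ([make_ligand_series()]), the
#' first member as the ligand under study with its reference pose, the
#' remaining members as the known bound ligands, and a scored candidate
#' pose cloud ([make_pose_cloud()]) in which decoys out-score the
#' near-native poses.
#'
#' @param spec A [fixture_spec()].
#' @return List with `ligand` (molecule), `reference` (pose), `knowns`
#'   (list of poses), `poses` (scored pose pool), `native` (logical
#'   vector over the pool), and `spec`.
#' @export
guided_fixture <- function(spec) {
  series <- make_ligand_series(spec)
  reference <- series[[1]]
  knowns <- series[-1]
  poses <- make_pose_cloud(reference, spec)
  list(ligand = reference$mol, reference = reference, knowns = knowns,
       poses = poses, native = attr(poses, "native"), spec = spec)
}

#' Guided versus unguided pose-family ranking experiment
#'
#' The end-to-end desk-scale experiment: for `n_ligands` independently
#' seeded fixtures, pose families are ranked once from raw docking
#' scores (unguided) and once from knowledge-rescored scores
#' ([rescore()] with the fixture's known bound ligands), and the
#' top-ranked family is scored against the reference pose by
#' symmetry-corrected RMSD. By construction the raw scores always put a
#' decoy family first; the experiment measures how often similarity to
#' known ligands recovers the native family at rank 1.
#'
#' @param n_ligands Number of seeded fixture ligands (default 100).
#' @param spec Base [fixture_spec()]; ligand i runs with seed
#'   `spec$seed + 1000 + i`.
#' @param rmsd_threshold Family radius in Angstrom (default 2.0).
#' @param success_rmsd Success threshold in Angstrom (default 2.0).
#' @return Tibble of class `guided_experiment`, one row per ligand:
#'   `ligand`, `unguided_top1`, `guided_top1` (minimum RMSD of the
#'   top-ranked family), `unguided_success`, `guided_success`,
#'   `prob_sum_unguided`, `prob_sum_guided` (family probability sums),
#'   `max_w` (largest applied bonus, pKd).
#' @export
guided_experiment <- function(n_ligands = 100L, spec = fixture_spec(),
                              rmsd_threshold = 2.0, success_rmsd = 2.0) {
  rows <- lapply(seq_len(n_ligands), function(i) {
    sp <- spec
    sp$seed <- spec$seed + 1000L + i
    fx <- guided_fixture(sp)
    auto <- enumerate_automorphisms(fx$ligand)
    scores <- vapply(fx$poses, function(p) p$score, numeric(1))
    fam_u <- build_pose_families(fx$poses, scores,
                                 rmsd_threshold = rmsd_threshold)
    rs <- rescore(fx$poses, fx$knowns)
    fam_g <- build_pose_families(fx$poses, rs$adjusted_score,
                                 rmsd_threshold = rmsd_threshold)
    fam_min_rmsd <- function(fam) {
      min(vapply(fam$members[[1]], function(ix) {
        symmetry_rmsd(fx$poses[[ix]], fx$reference, automorphisms = auto)
      }, numeric(1)))
    }
    u1 <- fam_min_rmsd(fam_u)
    g1 <- fam_min_rmsd(fam_g)
    tibble::tibble(ligand = i, unguided_top1 = u1, guided_top1 = g1,
                   unguided_success = u1 <= success_rmsd,
                   guided_success = g1 <= success_rmsd,
                   prob_sum_unguided = sum(fam_u$probability),
                   prob_sum_guided = sum(fam_g$probability),
                   max_w = max(rs$w))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("guided_experiment", class(out))
  out
}

#' @describeIn guided_experiment One-row summary with the two success
#'   rates (as fractions).
#' @param x A `guided_experiment` tibble.
#' @param ... Unused.
#' @export
glance.guided_experiment <- function(x, ...) {
  tibble::tibble(n = nrow(x),
                 unguided_success = mean(x$unguided_success),
                 guided_success = mean(x$guided_success),
                 mean_guided_top1 = mean(x$guided_top1),
                 mean_unguided_top1 = mean(x$unguided_top1))
}
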