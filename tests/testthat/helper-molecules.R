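# Small named molecules used across tests --------------------------------

ethanol_heavy <- function() chain_molecule(c("C", "C", "O"), "ethanol")
propanol_heavy <- function() chain_molecule(c("C", "C", "C", "O"), "propanol")

methanol_pose <- function() {
  # C-O with explicit hydroxyl hydrogen
  m <- molecule(
    atoms = data.frame(element = c("C", "O", "H")),
    bonds = data.frame(i = c(1, 2), j = c(2, 3)),
    name = "methanol")
  pose(m, matrix(c(0, 0, 0, 1.4, 0, 0, 1.9, 0.9, 0), 3, 3, byrow = TRUE))
}

acetate_pose <- function() {
  m <- molecule(
    atoms = data.frame(element = c("C", "C", "O", "O"),
                       charge = c(0, 0, 0, -1)),
    bonds = data.frame(i = c(1, 2, 2), j = c(2, 3, 4),
                       order = c(1, 2, 1)),
    name = "acetate")
  pose(m, matrix(c(0, 0, 0, 1.5, 0, 0, 2.2, 1.1, 0, 2.2, -1.1, 0),
                 4, 3, byrow = TRUE))
}

toluene_mol <- function() {
  molecule(
    atoms = data.frame(element = rep("C", 7),
                       aromatic = c(rep(TRUE, 6), FALSE)),
    bonds = data.frame(i = c(1:6, 1), j = c(2:6, 1, 7),
                       order = 1, aromatic = c(rep(TRUE, 6), FALSE)),
    name = "toluene")
}

phenol_pose <- function() {
  m <- molecule(
    atoms = data.frame(element = c(rep("C", 6), "O"),
                       aromatic = c(rep(TRUE, 6), FALSE)),
    bonds = data.frame(i = c(1:6, 1), j = c(2:6, 1, 7),
                       order = 1, aromatic = c(rep(TRUE, 6), FALSE)),
    name = "phenol")
  pose(m, rbind(ring_coords(6), c(2.8, 0, 0)))
}

benzene_pose <- function() pose(ring_molecule(6), ring_coords(6))

# Random seeded tree molecules (heavy atoms only) --------------------------

random_tree_molecule <- function(n, seed, elements = c("C", "C", "C",
                                                       "N", "O")) {
  withr::with_seed(seed, {
    el <- sample(elements, n, replace = TRUE)
    parent <- if (n > 1) {
      vapply(2:n, function(t) sample.int(t - 1L, 1L), integer(1))
    } else integer()
    ord <- if (n > 1) sample(1:3, n - 1, replace = TRUE,
                             prob = c(0.7, 0.2, 0.1)) else integer()
    molecule(atoms = data.frame(element = el),
             bonds = if (n > 1) data.frame(i = parent, j = 2:n,
                                           order = ord) else NULL,
             name = sprintf("rand%d", seed))
  })
}

# permute atoms of a molecule; returns the permuted molecule
permute_molecule <- function(mol, perm) {
  inv <- order(perm)   # inv[old] = new position
  molecule(
    atoms = mol$atoms[perm, c("element", "charge", "aromatic")],
    bonds = data.frame(i = inv[mol$bonds$i], j = inv[mol$bonds$j],
                       order = mol$bonds$order,
                       aromatic = mol$bonds$aromatic),
    name = paste0(mol$name, "-perm"))
}

# Independent oracles ------------------------------------------------------

# brute-force automorphisms: all permutations preserving atom types and
# the typed adjacency (for tiny molecules only)
brute_force_automorphisms <- function(mol) {
  heavy <- heavy_atoms(mol)
  n <- length(heavy)
  at <- poseguide:::atom_type(mol, heavy)
  A <- matrix("", n, n)
  b <- mol$bonds
  loc <- match(seq_len(n_atoms(mol)), heavy)
  for (r in seq_len(nrow(b))) {
    i <- loc[b$i[r]]; j <- loc[b$j[r]]
    if (is.na(i) || is.na(j)) next
    t <- if (b$aromatic[r]) "ar" else as.character(b$order[r])
    A[i, j] <- t; A[j, i] <- t
  }
  perms <- asplit(do.call(expand.grid, rep(list(seq_len(n)), n)), 1)
  keep <- Filter(function(p) {
    p <- as.integer(p)
    if (anyDuplicated(p)) return(FALSE)
    if (!all(at[p] == at)) return(FALSE)
    all(A[p, p] == A)
  }, perms)
  lapply(keep, as.integer)
}

# exhaustive maximum common connected subgraph size between two molecules
# (heavy atoms; same atom/bond compatibility rules as the search):
# enumerate connected subsets of A largest-first and test embedding in B
mcs_oracle_size <- function(a, b, min_atoms = 4L) {
  ah <- heavy_atoms(a); bh <- heavy_atoms(b)
  aadj <- poseguide:::adjacency(a, keep = ah)
  badj <- poseguide:::adjacency(b, keep = bh)
  atyp <- function(mol, v) paste0(mol$atoms$element[v], "/",
                                  mol$atoms$aromatic[v])
  btyp <- function(adj, v, u) {
    h <- which(adj[[v]]$nbr == u)
    if (length(h) == 0) return(NA_character_)
    if (adj[[v]]$aromatic[h]) "ar" else as.character(adj[[v]]$order[h])
  }
  bcomp <- function(t1, t2) {
    if (is.na(t1) || is.na(t2)) return(is.na(t1) && is.na(t2))
    t1 == t2 || (t1 != "ar" && t2 != "ar" && FALSE)
  }
  # all connected subsets of A's heavy atoms, by growth from each seed
  subsets <- new.env(hash = TRUE)
  grow <- function(set) {
    key <- paste(sort(set), collapse = ",")
    if (!is.null(subsets[[key]])) return()
    subsets[[key]] <- sort(set)
    frontier <- setdiff(unique(unlist(lapply(set,
                                             function(v) aadj[[v]]$nbr))),
                        set)
    for (u in frontier) grow(c(set, u))
  }
  for (v in ah) grow(v)
  all_sets <- as.list(subsets)
  sizes <- vapply(all_sets, length, integer(1))
  ord <- order(-sizes)
  # embed induced subgraph A[set] into B (exact induced match)
  embeds <- function(set) {
    set <- sort(set)
    k <- length(set)
    used <- logical(max(bh))
    assign_next <- function(pos, map) {
      if (pos > k) return(TRUE)
      v <- set[pos]
      for (w in bh) {
        if (used[w]) next
        if (atyp(a, v) != atyp(b, w)) next
        ok <- TRUE
        for (q in seq_len(pos - 1)) {
          ta <- btyp(aadj, v, set[q])
          tb <- btyp(badj, w, map[q])
          if (!bcomp(ta, tb)) { ok <- FALSE; break }
        }
        if (!ok) next
        used[w] <<- TRUE
        if (assign_next(pos + 1, c(map, w))) {
          used[w] <<- FALSE
          return(TRUE)
        }
        used[w] <<- FALSE
      }
      FALSE
    }
    assign_next(1, integer())
  }
  for (i in ord) {
    if (sizes[i] < min_atoms) break
    if (embeds(all_sets[[i]])) return(as.integer(sizes[i]))
  }
  0L
}

# independent gsim recomputation: explicit double loop over key multisets
gsim_oracle <- function(a, b, max_depth = 3L, hetero_weight = 2) {
  ka <- enumerate_subgraphs(a, max_depth)
  kb <- enumerate_subgraphs(b, max_depth)
  w <- function(k) ifelse(k$hetero, hetero_weight, 1)
  matched_in <- function(x, y) {
    tot <- 0
    ytab <- table(y$key)
    used <- stats::setNames(rep(0, length(ytab)), names(ytab))
    for (r in seq_len(nrow(x))) {
      k <- x$key[r]
      if (!is.na(ytab[k]) && !is.null(ytab[k]) && !is.na(used[k]) &&
          used[k] < ytab[k]) {
        used[k] <- used[k] + 1
        tot <- tot + w(x)[r]
      }
    }
    tot
  }
  (matched_in(ka, kb) + matched_in(kb, ka)) /
    (sum(w(ka)) + sum(w(kb)))
}

# random rigid transform
random_rigid <- function(seed) {
  withr::with_seed(seed, {
    list(R = poseguide:::rotation_about_axis(stats::rnorm(3),
                                             stats::runif(1, 0, 2 * pi)),
         t = stats::runif(3, -5, 5))
  })
}

# a curation record: 4-atom ligand chain inside a synthetic protein shell
make_record <- function(id, date, offset = c(0, 0, 0), element4 = "O",
                        shell = TRUE, shell_atoms = 12L) {
  m <- molecule(data.frame(element = c("C", "C", "C", element4)),
                data.frame(i = 1:3, j = 2:4), name = id)
  co <- matrix(c(0, 0, 0, 1.5, 0, 0, 3, 0, 0, 4.5, 0, 0), 4, 3,
               byrow = TRUE)
  co <- co + matrix(offset, 4, 3, byrow = TRUE)
  prot <- NULL
  if (shell) {
    # ring of protein carbons 3.4 A from the chain axis (vdW surfaces
    # within 1 A of the ligand's)
    th <- seq(0, 2 * pi, length.out = shell_atoms + 1)[-1]
    prot <- data.frame(x = rep(c(0.5, 2.5, 4.0), length.out = shell_atoms),
                       y = 3.4 * cos(th), z = 3.4 * sin(th),
                       element = "C")
  }
  complex_record(id, date, pose(m, co), prot)
}
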