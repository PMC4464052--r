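#' Construct a molecule
#'
#' A molecule is a chemical graph without coordinates: an ordered atom list
#' (element, formal charge, aromatic flag) and an undirected bond list
#' (atom index pair, integer order, aromatic flag). Atom order is
#' significant — poses and file I/O preserve it.
#'
#' @param atoms Data frame with columns `element` (symbol, e.g. `"C"`),
#'   and optionally `charge` (integer formal charge, default 0) and
#'   `aromatic` (logical, default `FALSE`).
#' @param bonds Data frame with columns `i`, `j` (1-based atom indices),
#'   and optionally `order` (integer bond order, default 1) and `aromatic`
#'   (logical, default `FALSE`). May have zero rows for a single atom.
#' @param name Identifier string.
#' @return An object of class `molecule` with tibble fields `atoms`
#'   (element, charge, aromatic, hydrogen) and `bonds` (i, j, order,
#'   aromatic; always `i < j`), plus `name`.
#' @examples
#' ethanol <- molecule(
#'   atoms = data.frame(element = c("C", "C", "O")),
#'   bonds = data.frame(i = c(1, 2), j = c(2, 3)),
#'   name  = "ethanol-heavy"
#' )
#' n_atoms(ethanol)
#' @export
molecule <- function(atoms, bonds = NULL, name = "mol") {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(nrow(atoms) >= 1, "element" %in% names(atoms))
  if (!"charge" %in% names(atoms)) atoms$charge <- 0L
  if (!"aromatic" %in% names(atoms)) atoms$aromatic <- FALSE
  atoms$element <- as.character(atoms$element)
  bad <- setdiff(unique(atoms$element), names(atomic_masses()))
  if (length(bad) > 0) {
    stop("unsupported element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  atoms <- tibble::tibble(
    element  = atoms$element,
    charge   = as.integer(atoms$charge),
    aromatic = as.logical(atoms$aromatic),
    hydrogen = atoms$element == "H"
  )
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0) {
    bonds <- tibble::tibble(i = integer(), j = integer(),
                            order = integer(), aromatic = logical())
  } else {
    bonds <- tibble::as_tibble(bonds)
    if (!"order" %in% names(bonds)) bonds$order <- 1L
    if (!"aromatic" %in% names(bonds)) bonds$aromatic <- FALSE
    i <- pmin(as.integer(bonds$i), as.integer(bonds$j))
    j <- pmax(as.integer(bonds$i), as.integer(bonds$j))
    if (any(i == j)) stop("self-bond in bond list", call. = FALSE)
    if (any(i < 1L) || any(j > nrow(atoms))) {
      stop("bond indices reference non-existent atoms", call. = FALSE)
    }
    if (anyDuplicated(paste(i, j))) {
      stop("duplicate bond in bond list", call. = FALSE)
    }
    bonds <- tibble::tibble(i = i, j = j,
                            order = as.integer(bonds$order),
                            aromatic = as.logical(bonds$aromatic))
  }
  if (sum(!atoms$hydrogen) < 1) stop("molecule needs >= 1 heavy atom",
                                     call. = FALSE)
  structure(list(atoms = atoms, bonds = bonds, name = as.character(name)),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d atoms (%d heavy), %d bonds\n",
              x$name, n_atoms(x), length(heavy_atoms(x)), nrow(x$bonds)))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol A `molecule`.
#' @return Integer count (hydrogens included).
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Indices of heavy (non-hydrogen) atoms
#' @param mol A `molecule`.
#' @return Integer vector of atom indices.
#' @export
heavy_atoms <- function(mol) which(!mol$atoms$hydrogen)

#' Molecular weight in Daltons
#' @param mol A `molecule`.
#' @return Numeric weight including hydrogens.
#' @export
molecular_weight <- function(mol) {
  sum(atomic_masses()[mol$atoms$element])
}

# Atom type string used in graph matching and subgraph keys: element,
# formal charge, aromatic flag.
atom_type <- function(mol, idx = seq_len(n_atoms(mol))) {
  a <- mol$atoms
  paste0(a$element[idx], "^", a$charge[idx],
         ifelse(a$aromatic[idx], ":ar", ""))
}

bond_type <- function(order, aromatic) {
  ifelse(aromatic, "ar", as.character(order))
}

# Neighbor list over selected atoms (default: all). Returns, per atom index,
# a data frame of (nbr, order, aromatic) restricted to `keep`.
adjacency <- function(mol, keep = seq_len(n_atoms(mol))) {
  keep_set <- logical(n_atoms(mol))
  keep_set[keep] <- TRUE
  adj <- vector("list", n_atoms(mol))
  for (v in keep) adj[[v]] <- list(nbr = integer(), order = integer(),
                                   aromatic = logical())
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    i <- b$i[r]; j <- b$j[r]
    if (!keep_set[i] || !keep_set[j]) next
    adj[[i]]$nbr <- c(adj[[i]]$nbr, j)
    adj[[i]]$order <- c(adj[[i]]$order, b$order[r])
    adj[[i]]$aromatic <- c(adj[[i]]$aromatic, b$aromatic[r])
    adj[[j]]$nbr <- c(adj[[j]]$nbr, i)
    adj[[j]]$order <- c(adj[[j]]$order, b$order[r])
    adj[[j]]$aromatic <- c(adj[[j]]$aromatic, b$aromatic[r])
  }
  adj
}

# BFS graph distances from `root` over the heavy-atom graph.
graph_distances <- function(adj, root, n) {
  d <- rep(NA_integer_, n)
  d[root] <- 0L
  queue <- root
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]$nbr) {
      if (is.na(d[u])) {
        d[u] <- d[v] + 1L
        queue <- c(queue, u)
      }
    }
  }
  d
}

is_connected <- function(mol, idx = heavy_atoms(mol)) {
  if (length(idx) <= 1) return(TRUE)
  adj <- adjacency(mol, keep = idx)
  d <- graph_distances(adj, idx[1], n_atoms(mol))
  all(!is.na(d[idx]))
}

# Induced subgraph on atom indices `idx` (original order retained).
induced_subgraph <- function(mol, idx, name = paste0(mol$name, "-sub")) {
  idx <- sort(idx)
  remap <- match(seq_len(n_atoms(mol)), idx)
  b <- mol$bonds
  keep <- b$i %in% idx & b$j %in% idx
  molecule(
    atoms = mol$atoms[idx, c("element", "charge", "aromatic")],
    bonds = tibble::tibble(i = remap[b$i[keep]], j = remap[b$j[keep]],
                           order = b$order[keep], aromatic = b$aromatic[keep]),
    name = name
  )
}

# TRUE when two molecules have identical graphs under identical atom order.
same_graph <- function(a, b) {
  identical(atom_type(a), atom_type(b)) &&
    nrow(a$bonds) == nrow(b$bonds) &&
    {
      oa <- order(a$bonds$i, a$bonds$j); ob <- order(b$bonds$i, b$bonds$j)
      identical(a$bonds$i[oa], b$bonds$i[ob]) &&
        identical(a$bonds$j[oa], b$bonds$j[ob]) &&
        identical(a$bonds$order[oa], b$bonds$order[ob]) &&
        identical(a$bonds$aromatic[oa], b$bonds$aromatic[ob])
    }
}

#' Standard atomic masses
#'
#' @return Named numeric vector of atomic masses (Da) for the elements the
#'   toolkit accepts.
#' @export
atomic_masses <- function() {
  c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
    Na = 22.990, Mg = 24.305, Si = 28.086, P = 30.974, S = 32.06,
    Cl = 35.45, K = 39.098, Ca = 40.078, Zn = 65.38, Se = 78.971,
    Br = 79.904, I = 126.904)
}

#' Van der Waals radii
#'
#' Bondi-style radii in Angstroms, used for contact filters and for the
#' Gaussian shape model of the 3D similarity.
#'
#' @return Named numeric vector of radii (Angstrom).
#' @export
vdw_radii <- function() {
  c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
    Na = 2.27, Mg = 1.73, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75,
    K = 2.75, Ca = 2.31, Zn = 1.39, Se = 1.90, Br = 1.85, I = 1.98)
}
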