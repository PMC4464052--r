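#' Construct a pose
#'
#' A pose is a molecule plus per-atom 3D coordinates in the shared binding
#' site frame, and optionally a docking score in pKd units (absent, `NA`,
#' for crystallographic reference poses). All poses compared by this
#' toolkit must already live in one common coordinate frame; no
#' superposition is ever performed.
#'
#' @param mol A [molecule()].
#' @param coords Numeric matrix, one row per atom, columns x, y, z
#'   (Angstrom).
#' @param score Docking score in pKd units, or `NA`.
#' @return An object of class `pose`.
#' @export
pose <- function(mol, coords, score = NA_real_) {
  stopifnot(inherits(mol, "molecule"))
  coords <- as.matrix(coords)
  if (ncol(coords) != 3 || nrow(coords) != n_atoms(mol)) {
    stop("coords must be an n_atoms x 3 matrix", call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite",
                                    call. = FALSE)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(mol = mol, coords = coords, score = as.numeric(score)[1]),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose> %s: %d atoms, score %s pKd\n", x$mol$name,
              n_atoms(x$mol),
              if (is.na(x$score)) "NA" else format(x$score)))
  invisible(x)
}

#' Centroid of a pose's heavy atoms
#' @param p A `pose`.
#' @return Numeric length-3 vector (Angstrom).
#' @export
pose_centroid <- function(p) {
  colMeans(p$coords[heavy_atoms(p$mol), , drop = FALSE])
}

#' Apply a rigid transform to a pose
#'
#' @param p A `pose`.
#' @param rotation 3x3 orthonormal rotation matrix.
#' @param translation Length-3 translation vector (Angstrom).
#' @return The transformed `pose` (score unchanged).
#' @export
transform_pose <- function(p, rotation = diag(3), translation = c(0, 0, 0)) {
  pose(p$mol,
       p$coords %*% t(rotation) + matrix(translation, nrow(p$coords), 3,
                                         byrow = TRUE),
       p$score)
}

# Rotation matrix for angle (radians) about unit axis, Rodrigues form.
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
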