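#' Similarity statistics of a candidate pose pool against known ligands
#'
#' Computes the full n x m table of in-frame 3D similarities between the
#' n candidate poses and the m known bound ligand poses, and summarizes
#' it by its mean `mu` and (population) standard deviation `sigma`. The
#' per-pose quantity rescored downstream is the *mean* similarity of a
#' pose to the m knowns; under the null that a pose is an unremarkable
#' member of the pool, that mean has standard deviation
#' `sigma_prime = sigma / sqrt(m)`.
#'
#' @param poses List of candidate [pose()]s (n >= 2; with a single pose
#'   the spread is undefined and the caller should skip the correction).
#' @param knowns List of m >= 1 known bound poses.
#' @param sim Similarity matrix function; default [sim3d_matrix()].
#' @param ... Passed to `sim`.
#' @return Object of class `similarity_stats`: list with `mu`, `sigma`,
#'   `sigma_prime`, `m`, `n`, `s` (per-pose mean similarity, length n)
#'   and the full `matrix`.
#' @export
similarity_stats <- function(poses, knowns, sim = sim3d_matrix, ...) {
  n <- length(poses)
  m <- length(knowns)
  if (m < 1) stop("need at least one known pose", call. = FALSE)
  if (n < 2) {
    stop(errorCondition(
      "need >= 2 candidate poses to estimate the similarity spread; skip the correction (w_i = 0) for smaller pools",
      class = "poseguide_too_few_poses"))
  }
  S <- sim(poses, knowns, ...)
  mu <- mean(S)
  sigma <- sqrt(mean((S - mu)^2))
  structure(list(mu = mu, sigma = sigma, sigma_prime = sigma / sqrt(m),
                 m = m, n = n, s = rowMeans(S), matrix = S),
            class = "similarity_stats")
}

#' @export
print.similarity_stats <- function(x, ...) {
  cat(sprintf(
    "<similarity_stats> n=%d poses x m=%d knowns: mu=%.4f sigma=%.4f sigma'=%.4f\n",
    x$n, x$m, x$mu, x$sigma, x$sigma_prime))
  invisible(x)
}

#' Upper-tail probability of a pose's mean similarity
#'
#' Probability that a pose drawn from the pool population would show a
#' mean similarity to the knowns at least as high as `s`: the area under
#' the right tail of a normal with mean `mu` and standard deviation
#' `sigma_prime`, i.e. `1 - (1 + erf((s - mu) / (sigma' sqrt(2)))) / 2`.
#' A pose that looks much more native-like than the pool gets a small
#' probability. Values are floored at `floor` (default 1e-6) to limit
#' the maximum score adjustment.
#'
#' @param s Mean similarity (scalar or vector).
#' @param stats A [similarity_stats()].
#' @param floor Lower bound for the probability (default 1e-6).
#' @return Probability in `[floor, 1]`. When `sigma_prime` is 0 the
#'   tail degenerates to a step: 0.5 at `s == mu`, `floor` above, 1
#'   below.
#' @export
pose_probability <- function(s, stats, floor = 1e-6) {
  if (stats$sigma_prime <= 0) {
    p <- ifelse(s == stats$mu, 0.5, ifelse(s > stats$mu, floor, 1))
    return(p)
  }
  p <- stats::pnorm(s, mean = stats$mu, sd = stats$sigma_prime,
                    lower.tail = FALSE)
  pmin(pmax(p, floor), 1)
}

#' Score adjustment from a pose probability
#'
#' Converts the tail probability into a score bonus in pKd units. The
#' thermodynamic correction is `-RT ln(1/p)` on the energy scale; with
#' the docking score in pKd (higher is better) and `RT ln 10` taken as
#' one pKd unit, the bonus is `w = log10(1/p)`, ranging from 0 (p = 1,
#' unremarkable pose) to 6 at the 1e-6 probability floor.
#'
#' @param p Probability (scalar or vector) in `[floor, 1]`; values below
#'   the floor are clamped with a warning.
#' @param floor Probability floor (default 1e-6).
#' @return Adjustment `w >= 0` in pKd units.
#' @export
score_adjustment <- function(p, floor = 1e-6) {
  if (any(p < floor)) {
    warning("probabilities below the floor were clamped",
            call. = FALSE)
    p <- pmax(p, floor)
  }
  if (any(p > 1)) stop("probabilities must be <= 1", call. = FALSE)
  log10(1 / p)
}

#' Knowledge-guided rescoring of docked poses
#'
#' The central operation: each candidate pose's docking score (pKd) is
#' augmented by a bonus reflecting how unusually similar the pose is to
#' the known bound ligands in the same site frame. Per pose, the mean 3D
#' similarity to the knowns is computed, recast as an upper-tail
#' probability against the pool's similarity distribution
#' ([pose_probability()]), and converted into a pKd bonus
#' ([score_adjustment()]). With no knowns (or a pool too small to
#' estimate the spread) scores pass through unchanged.
#'
#' @param poses List of scored candidate [pose()]s.
#' @param knowns List of known bound poses (may be empty).
#' @param floor Probability floor (default 1e-6).
#' @param sim Similarity matrix function; default [sim3d_matrix()].
#' @param ... Passed to `sim`.
#' @return A tibble of class `pose_rescoring`, one row per pose, in
#'   input order: `pose` (index), `score`, `s` (mean similarity), `p`
#'   (tail probability), `w` (pKd bonus), `adjusted_score`. The
#'   [similarity_stats()] ride along as attribute `stats` (see
#'   [glance.pose_rescoring()]).
#' @examples
#' fx <- guided_fixture(fixture_spec(seed = 7))
#' head(rescore(fx$poses, fx$knowns))
#' @export
rescore <- function(poses, knowns, floor = 1e-6, sim = sim3d_matrix, ...) {
  scores <- vapply(poses, function(p) p$score, numeric(1))
  unguided <- function() {
    tibble::tibble(pose = seq_along(poses), score = scores,
                   s = NA_real_, p = NA_real_, w = 0,
                   adjusted_score = scores)
  }
  out <- if (length(knowns) == 0) {
    unguided()
  } else {
    stats <- tryCatch(similarity_stats(poses, knowns, sim = sim, ...),
                      poseguide_too_few_poses = function(e) NULL)
    if (is.null(stats)) {
      unguided()
    } else {
      p <- pose_probability(stats$s, stats, floor = floor)
      w <- score_adjustment(p, floor = floor)
      res <- tibble::tibble(pose = seq_along(poses), score = scores,
                            s = stats$s, p = p, w = w,
                            adjusted_score = scores + w)
      attr(res, "stats") <- stats
      res
    }
  }
  class(out) <- c("pose_rescoring", class(out))
  out
}

#' Group poses into Boltzmann-ranked pose families
#'
#' Greedy leader clustering of a pose pool by symmetry-corrected RMSD:
#' poses are visited in order of decreasing adjusted score; each pose
#' joins the first existing family whose representative lies within
#' `rmsd_threshold`, otherwise it founds a new family (and becomes its
#' representative). Family weights follow the Boltzmann convention on
#' the pKd scale, `10^(representative score - best score)`, normalized
#' to probabilities that sum to one: the probability `x` of a family is
#' the model's expectation that the experimentally observed bound
#' configuration falls within that family.
#'
#' @param poses List of [pose()]s sharing one molecular graph.
#' @param adjusted_scores Numeric vector of adjusted scores (pKd), one
#'   per pose; defaults to the poses' own scores.
#' @param rmsd_threshold Family radius in Angstrom (default 2.0).
#' @param ops Optional [site_ops()] used by the RMSD.
#' @param weight `"representative"` (default) weights a family by its
#'   representative's score only; `"sum"` adds the members' weights
#'   (sensitive to sampling density; provided for sensitivity analysis).
#' @return Tibble of class `pose_families`, ordered by descending
#'   `probability`: `family`, `representative` (pose index),
#'   `rep_score`, `n_members`, `members` (list of pose indices),
#'   `probability`.
#' @examples
#' fx <- guided_fixture(fixture_spec(seed = 7))
#' fam <- build_pose_families(fx$poses)
#' sum(fam$probability)  # 1
#' @export
build_pose_families <- function(poses, adjusted_scores = NULL,
                                rmsd_threshold = 2.0, ops = NULL,
                                weight = c("representative", "sum")) {
  weight <- match.arg(weight)
  if (length(poses) == 0) {
    return(structure(tibble::tibble(
      family = integer(), representative = integer(),
      rep_score = numeric(), n_members = integer(), members = list(),
      probability = numeric()),
      class = c("pose_families", class(tibble::tibble()))))
  }
  if (is.null(adjusted_scores)) {
    adjusted_scores <- vapply(poses, function(p) p$score, numeric(1))
  }
  stopifnot(length(adjusted_scores) == length(poses))
  auto <- enumerate_automorphisms(poses[[1]]$mol)
  ord <- order(-adjusted_scores)
  reps <- integer()
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (f in seq_along(reps)) {
      r <- symmetry_rmsd(poses[[i]], poses[[reps[f]]], ops = ops,
                         automorphisms = auto)
      if (r <= rmsd_threshold) {
        members[[f]] <- c(members[[f]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      members[[length(reps)]] <- i
    }
  }
  rep_score <- adjusted_scores[reps]
  wgt <- if (weight == "representative") {
    10^(rep_score - max(adjusted_scores))
  } else {
    vapply(members, function(ix) {
      sum(10^(adjusted_scores[ix] - max(adjusted_scores)))
    }, numeric(1))
  }
  out <- tibble::tibble(
    family = seq_along(reps), representative = reps,
    rep_score = rep_score, n_members = lengths(members),
    members = members, probability = wgt / sum(wgt))
  out <- out[order(-out$probability), ]
  out$family <- seq_len(nrow(out))
  class(out) <- c("pose_families", class(out))
  out
}

#' @describeIn rescore Tidy method: returns the rescoring tibble itself.
#' @param x A `pose_rescoring` object.
#' @export
tidy.pose_rescoring <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a rescoring
#'
#' @param x A [rescore()] result.
#' @param ... Unused.
#' @return Tibble with `n`, `m`, `mu`, `sigma`, `sigma_prime`, `max_w`,
#'   and `guided` (whether a correction was applied).
#' @export
glance.pose_rescoring <- function(x, ...) {
  st <- attr(x, "stats")
  if (is.null(st)) {
    return(tibble::tibble(n = nrow(x), m = 0L, mu = NA_real_,
                          sigma = NA_real_, sigma_prime = NA_real_,
                          max_w = 0, guided = FALSE))
  }
  tibble::tibble(n = st$n, m = st$m, mu = st$mu, sigma = st$sigma,
                 sigma_prime = st$sigma_prime, max_w = max(x$w),
                 guided = TRUE)
}

#' Export pose families to JSON
#'
#' @param families A [build_pose_families()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_families_json <- function(families, path) {
  payload <- lapply(seq_len(nrow(families)), function(r) {
    list(family = families$family[r],
         representative = families$representative[r],
         rep_score = families$rep_score[r],
         probability = families$probability[r],
         members = families$members[[r]])
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
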