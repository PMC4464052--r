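# stub similarity returning a fixed matrix, for exact-statistics tests
stub_sim <- function(M) function(poses, knowns, ...) M

dummy_poses <- function(n, scores = rep(5, n)) {
  lapply(seq_len(n), function(i) {
    pose(chain_molecule("C"), matrix(0, 1, 3), score = scores[i])
  })
}

test_that("similarity statistics match direct summation", {
  M <- matrix(c(0.1, 0.4, 0.3, 0.9, 0.2, 0.6), 3, 2)
  st <- similarity_stats(dummy_poses(3), dummy_poses(2),
                         sim = stub_sim(M))
  expect_equal(st$mu, sum(M) / 6, tolerance = 1e-15)
  expect_equal(st$sigma, sqrt(sum((M - mean(M))^2) / 6),
               tolerance = 1e-15)
  expect_equal(st$sigma_prime, st$sigma / sqrt(2), tolerance = 1e-15)
  expect_equal(st$s, rowMeans(M), tolerance = 1e-15)
})

test_that("degenerate tables: constant similarity, single known", {
  M <- matrix(0.42, 4, 3)
  st <- similarity_stats(dummy_poses(4), dummy_poses(3),
                         sim = stub_sim(M))
  expect_equal(st$mu, 0.42)
  expect_equal(st$sigma, 0)
  M1 <- matrix(c(0.1, 0.5, 0.9), 3, 1)
  st1 <- similarity_stats(dummy_poses(3), dummy_poses(1),
                          sim = stub_sim(M1))
  expect_equal(st1$sigma_prime, st1$sigma)   # m = 1
  expect_error(similarity_stats(dummy_poses(1), dummy_poses(2),
                                sim = stub_sim(matrix(0, 1, 2))),
               class = "poseguide_too_few_poses")
})

test_that("tail probability: center, z = 2 case, floor, monotonicity", {
  st <- structure(list(mu = 0.5, sigma = 0.1, sigma_prime = 0.1 / 2,
                       m = 4, n = 10), class = "similarity_stats")
  expect_identical(pose_probability(0.5, st), 0.5)
  # z = (0.6 - 0.5) / 0.05 = 2: upper tail of the standard normal
  expect_equal(pose_probability(0.6, st), 0.02275013, tolerance = 1e-7)
  expect_equal(pose_probability(10, st), 1e-6)
  s_grid <- seq(0.2, 0.7, by = 0.01)    # below the floor region
  expect_true(all(diff(pose_probability(s_grid, st)) < 0))
})

test_that("zero spread degenerates to a step around the mean", {
  st <- structure(list(mu = 0.3, sigma = 0, sigma_prime = 0,
                       m = 2, n = 5), class = "similarity_stats")
  expect_identical(pose_probability(0.3, st), 0.5)
  expect_identical(pose_probability(0.4, st), 1e-6)
  expect_identical(pose_probability(0.2, st), 1)
})

test_that("score adjustment follows the pKd convention", {
  expect_identical(score_adjustment(1), 0)
  expect_equal(score_adjustment(1e-6), 6, tolerance = 1e-12)
  # the magnitude scale of a strong adjustment: p = 10^-3.1 gives +3.1
  expect_equal(score_adjustment(10^(-3.1)), 3.1, tolerance = 1e-12)
  expect_warning(w <- score_adjustment(1e-9), "clamped")
  expect_equal(w, 6)
  expect_error(score_adjustment(1.5), "<= 1")
})

test_that("rescore: unguided passthrough and constant-shift neutrality", {
  poses <- dummy_poses(5, scores = c(5, 4.5, 6, 5.5, 4))
  rs <- rescore(poses, list())
  expect_equal(rs$adjusted_score, rs$score)
  expect_true(all(rs$w == 0))
  expect_false(glance(rs)$guided)
  # equal similarity to knowns shifts all scores equally
  M <- matrix(0.4, 5, 2)
  rs2 <- rescore(poses, dummy_poses(2), sim = stub_sim(M))
  expect_equal(order(-rs2$adjusted_score), order(-rs2$score))
  expect_equal(stats::sd(rs2$w), 0)
})

test_that("a similarity-favored pose family overtakes a score-favored decoy", {
  # construct a pool: 10 native-like poses 2 sigma' above the mean
  # similarity but 0.5 pKd below 90 decoys
  n <- 100
  s <- c(rep(0.8, 10), rep(0.2, 90))
  M <- cbind(s, s, s, s)   # m = 4 knowns, sigma' = sigma / 2
  scores <- c(rep(5.0, 10), rep(5.5, 90))
  poses <- dummy_poses(n, scores)
  rs <- rescore(poses, dummy_poses(4), sim = stub_sim(M))
  expect_true(all(rs$w[1:10] > 0.5 + max(rs$w[11:100])))
  expect_true(which.max(rs$adjusted_score) <= 10)
  expect_equal(which.max(rs$score), 11)   # raw scores favored a decoy
})

test_that("pose families: leader clustering, Boltzmann probabilities", {
  sp <- fixture_spec(seed = 31, n_poses = 30)
  fx <- guided_fixture(sp)
  fam <- build_pose_families(fx$poses)
  # families partition the pool
  expect_setequal(unlist(fam$members), seq_along(fx$poses))
  expect_equal(sum(fam$probability), 1, tolerance = 1e-12)
  expect_true(all(diff(fam$probability) <= 1e-12))
  # single pose
  f1 <- build_pose_families(fx$poses[1])
  expect_identical(nrow(f1), 1L)
  expect_equal(f1$probability, 1)
})

test_that("family probabilities follow the 10^score convention", {
  m <- chain_molecule(c("C", "N", "O", "C"))
  co <- matrix(c(0, 0, 0, 1.5, 0, 0, 3, 0, 0, 4.5, 0, 0), 4, 3,
               byrow = TRUE)
  mk <- function(dz, score) {
    pose(m, co + matrix(c(0, 0, dz), 4, 3, byrow = TRUE), score)
  }
  # two well-separated families with equal representative scores
  fam <- build_pose_families(list(mk(0, 5), mk(10, 5)))
  expect_equal(fam$probability, c(0.5, 0.5))
  # representative scores 1.0 pKd apart: 10/11 vs 1/11
  fam2 <- build_pose_families(list(mk(0, 6), mk(10, 5)))
  expect_equal(fam2$probability, c(10 / 11, 1 / 11), tolerance = 1e-12)
  # members within the threshold join the leader's family
  fam3 <- build_pose_families(list(mk(0, 6), mk(0.5, 5), mk(10, 4)))
  expect_identical(fam3$n_members, c(2L, 1L))
})

test_that("tidy and glance expose the rescoring table and statistics", {
  sp <- fixture_spec(seed = 41, n_poses = 12)
  fx <- guided_fixture(sp)
  rs <- rescore(fx$poses, fx$knowns)
  td <- tidy(rs)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 12L)
  gl <- glance(rs)
  expect_identical(gl$n, 12L)
  expect_identical(gl$m, length(fx$knowns))
  expect_true(gl$guided)
})
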