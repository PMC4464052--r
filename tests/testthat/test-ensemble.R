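random_simmatrix <- function(n, seed) {
  withr::with_seed(seed, {
    v <- matrix(stats::runif(n * n), n, n)
    v <- (v + t(v)) / 2
    diag(v) <- 1
    pocket_sim_matrix(v, sprintf("P%02d", seq_len(n)))
  })
}

# exhaustive K-medoid optimum: best mean min-distance over all k-subsets
brute_force_objective <- function(mat, k) {
  d <- 1 - mat$values
  n <- nrow(d)
  combos <- utils::combn(n, k)
  min(apply(combos, 2, function(med) {
    mean(apply(d[, med, drop = FALSE], 1, min))
  }))
}

test_that("matrix validation enforces symmetry and unit diagonal", {
  v <- matrix(c(1, 0.4, 0.5, 1), 2, 2)
  expect_error(pocket_sim_matrix(v), "symmetric")
  v2 <- matrix(c(0.9, 0.4, 0.4, 1), 2, 2)
  expect_error(pocket_sim_matrix(v2), "diagonal")
})

test_that("matrix text round trip (TSV and CSV)", {
  m <- make_clustered_simmatrix(c(2, 3), 0.8, 0.2, noise = 0.05, seed = 4)
  for (ext in c(".tsv", ".csv")) {
    f <- withr::local_tempfile(fileext = ext)
    write_sim_matrix(m, f)
    back <- read_sim_matrix(f)
    expect_identical(back$ids, m$ids)
    expect_equal(back$values, m$values, tolerance = 1e-9)
  }
})

test_that("k = N and k = 1 selections behave as defined", {
  m <- random_simmatrix(5, seed = 2)
  sel <- choose_exemplars(m, 5, seed = 1)
  expect_setequal(sel$exemplar_ids, m$ids)
  expect_equal(sel$objective, 0)
  # k = 1: the item with maximal mean similarity to all others
  sel1 <- choose_exemplars(m, 1, seed = 1)
  mean_sim <- vapply(1:5, function(i) mean(m$values[i, -i]), numeric(1))
  expect_identical(sel1$exemplar_ids, m$ids[which.max(mean_sim)])
  expect_error(choose_exemplars(m, 6, seed = 1), "1..N")
})

test_that("planted two-block matrix yields one exemplar per block", {
  m <- make_clustered_simmatrix(c(3, 3), within = 0.9, between = 0.1)
  sel <- choose_exemplars(m, 2, seed = 7)
  blocks <- attr(m, "blocks")
  got <- sort(blocks[match(sel$exemplar_ids, m$ids)])
  expect_identical(got, 1:2)
  # assignment respects the planted partition
  td <- tidy(sel)
  expect_identical(blocks[match(td$exemplar, m$ids)], blocks)
})

test_that("multi-restart K-medoids attains the exhaustive optimum", {
  for (seed in 1:20) {
    n <- sample(4:8, 1)
    k <- sample(2:(n - 1), 1)
    m <- random_simmatrix(n, seed = seed + 300)
    sel <- choose_exemplars(m, k, seed = seed)
    expect_equal(sel$objective, brute_force_objective(m, k),
                 tolerance = 1e-12)
  }
})

test_that("diverse selection starts from the planted outlier", {
  # one outlier (low similarity to everyone), two tight blocks
  v <- matrix(0.85, 7, 7)
  v[7, ] <- 0.05
  v[, 7] <- 0.05
  diag(v) <- 1
  m <- pocket_sim_matrix(v, sprintf("Q%d", 1:7))
  for (k in 1:4) {
    expect_true("Q7" %in% choose_diverse(m, k)$exemplar_ids)
  }
  # uniform off-diagonal: lexicographic tie-break
  u <- matrix(0.5, 4, 4)
  diag(u) <- 1
  mu <- pocket_sim_matrix(u, c("A", "B", "C", "D"))
  expect_identical(choose_diverse(mu, 2)$exemplar_ids, c("A", "B"))
})

test_that("diverse picks one item per planted block at k = 2", {
  m <- make_clustered_simmatrix(c(3, 3), within = 0.9, between = 0.1)
  sel <- choose_diverse(m, 2)
  blocks <- attr(m, "blocks")
  expect_identical(sort(blocks[match(sel$exemplar_ids, m$ids)]), 1:2)
})

test_that("random selection is seeded and approximately uniform", {
  m <- random_simmatrix(6, seed = 9)
  s1 <- choose_random(m, 3, seed = 42)
  s2 <- choose_random(m, 3, seed = 42)
  expect_identical(s1$exemplar_ids, s2$exemplar_ids)
  expect_setequal(choose_random(m, 6, seed = 1)$exemplar_ids, m$ids)
  n_draws <- 3000
  counts <- integer(6)
  for (s in seq_len(n_draws)) {
    idx <- match(choose_random(m, 2, seed = s)$exemplar_ids, m$ids)
    counts[idx] <- counts[idx] + 1L
  }
  p <- 2 / 6
  sigma <- sqrt(n_draws * p * (1 - p))
  expect_true(all(abs(counts - n_draws * p) < 3.5 * sigma))
})

test_that("K-medoids beats random selection on planted clusters", {
  m <- make_clustered_simmatrix(c(4, 4, 4), within = 0.9, between = 0.2,
                                noise = 0.03, seed = 5)
  km <- choose_exemplars(m, 3, seed = 1)$objective
  rnd <- vapply(1:50, function(s) {
    choose_random(m, 3, seed = s)$objective
  }, numeric(1))
  expect_lt(km, mean(rnd))
})

test_that("single-linkage tree merges in similarity order", {
  v <- diag(3)
  v[1, 2] <- v[2, 1] <- 0.9
  v[2, 3] <- v[3, 2] <- 0.5
  v[1, 3] <- v[3, 1] <- 0.2
  diag(v) <- 1
  m <- pocket_sim_matrix(v, c("a", "b", "c"))
  tr <- single_linkage_tree(m)
  td <- tidy(tr)
  expect_equal(td$similarity, c(0.9, 0.5))
  expect_true(all(diff(td$height) >= -1e-12))   # non-increasing sim
  # first merge joins a and b
  expect_identical(sort(tr$hclust$labels[-tr$hclust$merge[1, ]]),
                   c("a", "b"))
  # single leaf
  tr1 <- single_linkage_tree(pocket_sim_matrix(matrix(1, 1, 1), "x"))
  expect_identical(tr1$ids, "x")
})

test_that("newick export is readable and preserves the leaves", {
  m <- make_clustered_simmatrix(c(3, 2), 0.8, 0.3, noise = 0.02, seed = 8)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(single_linkage_tree(m), f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, m$ids)
  expect_identical(ape::Ntip(phy), 5L)
})
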