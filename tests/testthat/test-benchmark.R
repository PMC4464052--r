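test_that("a well-buried whitelisted ligand passes every filter", {
  r <- ligand_passes_filters(make_record("ok", "2003-05-12"))
  expect_true(r$pass)
  expect_identical(r$reasons, "")
  expect_false(r$partial)
})

test_that("each curation rule is triggered individually", {
  se <- ligand_passes_filters(make_record("se", "2003-01-01",
                                          element4 = "Se"))
  expect_false(se$pass)
  expect_identical(se$reasons, "element")

  # a heavy-halogen chain pushes the weight over 1000 Da
  big <- molecule(data.frame(element = rep("I", 9)),
                  data.frame(i = 1:8, j = 2:9), name = "big")
  rec_big <- complex_record("big", "2003-01-01",
                            pose(big, matrix(seq(0, 16, 2), 9, 3)))
  w <- ligand_passes_filters(rec_big)
  expect_false(w$pass)
  expect_match(w$reasons, "weight")

  far <- ligand_passes_filters(make_record("far", "2003-01-01",
                                           offset = c(0, 40, 0)))
  expect_false(far$pass)
  expect_match(far$reasons, "contacts")
  expect_match(far$reasons, "buriedness")

  # sparse shell: contacts pass but buriedness ratio falls below 0.3
  sparse <- make_record("sparse", "2003-01-01", shell_atoms = 12L)
  sparse$protein_atoms <- sparse$protein_atoms[1:3, ]
  sparse$protein_atoms$y <- c(3.4, -3.4, 3.4)
  sparse$protein_atoms$z <- 0
  b <- ligand_passes_filters(sparse, buried_min = 0.9)
  expect_false(b$pass)
  expect_match(b$reasons, "buriedness")
})

test_that("missing protein shell evaluates only ligand-intrinsic rules", {
  r <- ligand_passes_filters(make_record("noshell", "2003-01-01",
                                         shell = FALSE))
  expect_true(r$partial)
  expect_true(is.na(r$contacts))
  expect_true(r$pass)   # both evaluated rules pass
})

test_that("temporal split: 25% ceiling rule and date-id ordering", {
  dates <- as.Date("2000-01-01") + seq(0, 390, by = 10)
  recs <- lapply(seq_len(40), function(i) {
    make_record(sprintf("r%02d", i), dates[i], shell = FALSE)
  })
  sp <- temporal_split(recs)
  expect_length(sp$early, 10)
  expect_length(sp$test, 30)
  expect_identical(sp$early[[1]]$id, "r01")
  expect_true(max(vapply(sp$early, function(r) r$deposition_date,
                         as.Date("2000-01-01"))) <= sp$cutoff_date)
  # 169 records: ceiling(0.25 * 169) = 43
  recs169 <- lapply(seq_len(169), function(i) {
    make_record(sprintf("s%03d", i), as.Date("2000-01-01") + i,
                shell = FALSE)
  })
  sp169 <- temporal_split(recs169)
  expect_length(sp169$early, 43)
  expect_length(sp169$test, 126)
  # equal dates: id is the tie-break
  ties <- lapply(c("b", "a", "d", "c"), function(id) {
    make_record(id, "2001-06-01", shell = FALSE)
  })
  spt <- temporal_split(ties)
  expect_identical(spt$early[[1]]$id, "a")
  expect_error(temporal_split(ties[1:3]), "at least 4")
})

test_that("centroid filter drops planted outliers, keeps the boundary", {
  base <- make_record("x", "2000-01-01", shell = FALSE)$ligand
  lig <- rep(list(base), 9)
  expect_length(centroid_filter(lig), 9)
  out <- transform_pose(base, translation = c(50, 0, 0))
  kept <- centroid_filter(c(lig, list(out)), max_dist = 10)
  expect_length(kept, 9)
  expect_identical(attr(kept, "dropped"), 10L)
  # exactly at the threshold: retained (closed boundary)
  two <- list(base, transform_pose(base, translation = c(20, 0, 0)))
  expect_length(centroid_filter(two, max_dist = 10), 2)
})

test_that("family evaluation: reference recovery and top-k curve", {
  sp <- fixture_spec(seed = 61, n_poses = 40)
  fx <- guided_fixture(sp)
  poses <- c(list(fx$reference), fx$poses)
  poses[[1]]$score <- 99     # the reference itself tops the ranking
  fam <- build_pose_families(poses)
  ev <- evaluate_families(list(lig = fam), list(lig = poses),
                          list(lig = fx$reference))
  expect_equal(ev$top1, 0)
  expect_true(all(diff(unlist(ev[1, c("top1", "top2", "top5", "top10",
                                      "top_all")])) <= 1e-12))
  # top-k equals brute force over the ranked families
  fr <- ev$family_rmsd[[1]]
  expect_equal(ev$top2, min(fr[seq_len(min(2, length(fr)))]))
  expect_equal(ev$top_all, min(fr))
})

test_that("success rates count ligands below the threshold", {
  ev <- tibble::tibble(ligand = letters[1:4],
                       family_rmsd = list(1, 1, 1, 1),
                       top1 = c(0.5, 1.9, 2.0, 8.0),
                       top2 = c(0.5, 1.9, 2.0, 3.0),
                       top5 = c(0.5, 1.9, 2.0, 3.0),
                       top10 = c(0.5, 1.9, 2.0, 3.0),
                       top_all = c(0.5, 1.9, 1.0, 2.0))
  expect_equal(success_rate(ev, 2.0, k = 1), 0.75)
  expect_equal(success_rate(ev, 2.0, k = Inf), 1.0)
  expect_lte(success_rate(ev, 1.0, k = 1), success_rate(ev, 2.0, k = 1))
})

test_that("cumulative histogram integrates the standard histogram", {
  vals <- c(0.4, 1.2, 1.2, 3.0, 7.5)
  ch <- cumulative_histogram(vals, edges = c(0, 1, 2, 4, 8))
  expect_equal(ch$proportion, c(0, 1 / 5, 3 / 5, 4 / 5, 1))
  expect_true(all(diff(ch$proportion) >= 0))
  expect_equal(cumulative_histogram(0.1, edges = c(1, 2))$proportion,
               c(1, 1))
  expect_error(cumulative_histogram(numeric()), "no values")
})

test_that("novelty fractions from maximal similarity", {
  sim_id <- function(a, b) as.numeric(a == b)
  expect_equal(as.numeric(novelty_fraction(as.list(1:4), as.list(1:4),
                                           sim_id, 0.5)), 0)
  expect_warning(nv <- novelty_fraction(as.list(1:4), list(), sim_id, 0.5),
                 "vacuously")
  expect_equal(as.numeric(nv), 1)
  # half the test items appear among the knowns
  nv2 <- novelty_fraction(as.list(1:4), as.list(3:4), sim_id, 0.5)
  expect_equal(as.numeric(nv2), 0.5)
})

test_that("KS comparison agrees with a direct ECDF-difference oracle", {
  a <- c(0.5, 1.1, 1.8, 2.2)
  b <- c(2.5, 3.1, 4.0)
  ks <- ks_compare(a, b)
  grid <- sort(unique(c(a, b)))
  D <- max(abs(vapply(grid, function(x) mean(a <= x) - mean(b <= x),
                      numeric(1))))
  expect_equal(ks$statistic, D, tolerance = 1e-12)
  expect_equal(ks$statistic, 1)   # disjoint supports
  expect_equal(ks_compare(a, a)$statistic, 0)
  expect_equal(ks_compare(a, a)$p_value, 1)
})

test_that("exact binomial tail matches the closed form", {
  bt <- exact_binomial(0, 10, 0.5)
  expect_equal(bt$p_value, 2 / 1024, tolerance = 1e-12)
  expect_equal(exact_binomial(5, 10, 0.5)$p_value, 1, tolerance = 1e-12)
  # p-value shrinks as the observation moves away from the null
  ps <- vapply(5:0, function(s) exact_binomial(s, 10, 0.5)$p_value,
               numeric(1))
  expect_true(all(diff(ps) < 0))
})
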