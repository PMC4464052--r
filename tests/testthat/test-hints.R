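big_budget <- function() search_budget(10000000L)

test_that("self-match covers the whole molecule", {
  m <- chain_molecule(c("C", "N", "C", "O", "C"))
  kp <- pose(m, matrix(seq(0, 14, length.out = 15), 5, 3))
  res <- common_substructures(m, kp, budget = big_budget())
  expect_gte(nrow(res), 1)
  expect_identical(max(res$size), 5L)
  expect_true(attr(res, "exhausted"))
})

test_that("fragments below four heavy atoms are rejected", {
  a <- chain_molecule(c("C", "C", "O"))          # shares only C-C-O
  b <- chain_molecule(c("C", "C", "O"))
  b$atoms$element[1] <- "N"                       # now shares C-O only
  b <- molecule(b$atoms[, c("element", "charge", "aromatic")], b$bonds,
                "NCO")
  kp <- pose(b, matrix(0, 3, 3) + 1:3)
  expect_identical(nrow(common_substructures(a, kp,
                                             budget = big_budget())), 0L)
  # the full 3-atom self match is also below the cutoff
  kp2 <- pose(a, matrix(0, 3, 3) + 1:3)
  expect_identical(nrow(common_substructures(a, kp2,
                                             budget = big_budget())), 0L)
})

test_that("toluene vs phenol maximal match equals the exhaustive oracle", {
  tol <- toluene_mol()
  ph <- phenol_pose()
  res <- common_substructures(tol, ph, budget = big_budget())
  # exocyclic C cannot map onto the O: only the aromatic 6-ring matches
  expect_identical(max(res$size), 6L)
  expect_identical(max(res$size), mcs_oracle_size(tol, ph$mol))
})

test_that("budgeted search equals exhaustive MCS on random pairs", {
  for (seed in 1:12) {
    a <- random_tree_molecule(sample(5:9, 1), seed = seed)
    b <- random_tree_molecule(sample(5:9, 1), seed = seed + 500)
    kp <- pose(b, withr::with_seed(seed, matrix(stats::rnorm(
      3 * n_atoms(b)), n_atoms(b), 3)))
    res <- common_substructures(a, kp, budget = big_budget())
    got <- if (nrow(res) == 0) 0L else max(res$size)
    expect_identical(got, mcs_oracle_size(a, b))
  }
})

test_that("budget exhaustion is flagged and non-fatal", {
  # identical 8-rings have many aromatic self-matches; a tiny budget
  # must truncate
  r <- ring_molecule(8)
  kp <- pose(r, ring_coords(8))
  res <- common_substructures(r, kp, budget = search_budget(10L))
  expect_false(attr(res, "exhausted"))
})

test_that("redundant and subset matches are pruned per known", {
  m <- chain_molecule(c("C", "C", "C", "C", "C"))
  kp <- pose(m, matrix(c(seq(0, 6, 1.5), rep(0, 10)), 5, 3))
  res <- common_substructures(m, kp, budget = big_budget())
  sets <- lapply(res$ligand_atoms, sort)
  expect_false(anyDuplicated(vapply(sets, paste, character(1),
                                    collapse = ",")) > 0)
  # no retained set is a strict subset of another
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i != j && length(sets[[i]]) < length(sets[[j]])) {
        expect_false(all(sets[[i]] %in% sets[[j]]))
      }
    }
  }
})

test_that("extract_hints: empty knowns, ranking, cap, coordinates", {
  expect_identical(nrow(extract_hints(ethanol_heavy(), list())), 0L)
  sp <- fixture_spec(seed = 5, n_knowns = 4)
  fx <- guided_fixture(sp)
  h <- extract_hints(fx$ligand, fx$knowns, budget = big_budget())
  expect_true(all(h$size >= 4))
  expect_true(all(diff(h$gsim) <= 1e-12))      # sorted descending
  # fragment coordinates are copied verbatim from the known pose
  for (r in seq_len(nrow(h))) {
    kp <- fx$knowns[[match(h$known_id[r],
                           vapply(fx$knowns, function(k) k$mol$name,
                                  character(1)))]]
    expect_identical(unname(h$fragment[[r]]$coords),
                     unname(kp$coords[sort(h$known_atoms[[r]]), ,
                                      drop = FALSE]))
  }
  # cap at max_hints
  h2 <- extract_hints(fx$ligand, fx$knowns, max_hints = 2,
                      budget = big_budget())
  expect_identical(nrow(h2), 2L)
})

test_that("hint ranking is invariant to the order of knowns", {
  sp <- fixture_spec(seed = 9, n_knowns = 4)
  fx <- guided_fixture(sp)
  h1 <- extract_hints(fx$ligand, fx$knowns, budget = big_budget())
  h2 <- extract_hints(fx$ligand, rev(fx$knowns), budget = big_budget())
  expect_identical(h1$known_id, h2$known_id)
  expect_identical(h1$size, h2$size)
  expect_equal(h1$gsim, h2$gsim, tolerance = 1e-12)
})
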