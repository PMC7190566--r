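test_that("fleiss_kappa is 1 under perfect agreement across classes", {
  ratings <- matrix(rep(c("TB", "NEITHER", "PDC", "TB"), each = 3),
                    4, 3, byrow = TRUE)
  expect_identical(fleiss_kappa(rating_panel(ratings)), 1)
})

test_that("fleiss_kappa matches the direct-formula oracle", {
  # fixed printed pattern: 4 objects x 3 raters
  fixed <- matrix(c("TB", "TB", "PDC",
                    "NEITHER", "NEITHER", "NEITHER",
                    "TB", "PDC", "NEITHER",
                    "PDC", "PDC", "TB"), 4, 3, byrow = TRUE)
  expect_equal(fleiss_kappa(rating_panel(fixed)), fleiss_oracle(fixed),
               tolerance = 1e-12)
  # random small panels
  for (s in 1:40) {
    r <- random_ratings(nrow <- 5 + s %% 20, 2 + s %% 6, seed = 1000 + s)
    expect_equal(fleiss_kappa(rating_panel(r)), fleiss_oracle(r),
                 tolerance = 1e-12)
  }
})

test_that("fleiss_kappa validates input and flags degenerate panels", {
  expect_error(fleiss_kappa(rating_panel(matrix("TB", 3, 1))), "2 raters")
  expect_warning(k <- fleiss_kappa(rating_panel(matrix("TB", 5, 3))),
                 "single class")
  expect_identical(k, 1)
  # duplicate rater added to a perfect panel leaves kappa at 1
  perfect <- matrix(rep(c("TB", "PDC", "NEITHER"), each = 3), 3, 3,
                    byrow = TRUE)
  expect_identical(fleiss_kappa(rating_panel(cbind(perfect, perfect[, 1]))),
                   1)
})

test_that("fleiss_kappa tends to zero for object-independent ratings", {
  u <- matrix(1 / 3, 3, 3)
  ks <- vapply(1:8, function(s) {
    fleiss_kappa(generate_rating_panel(panel_spec(10000, 4,
                                                  rater_confusions = u,
                                                  seed = 400 + s))$panel)
  }, numeric(1))
  expect_lt(max(abs(ks)), 0.05)
})

test_that("cohen_kappa matches hand values and the contingency oracle", {
  a <- c("TB", "PDC", "NEITHER", "TB")
  expect_identical(cohen_kappa(a, a), 1)
  # fully crossed disagreement with symmetric marginals
  expect_identical(cohen_kappa(c("TB", "PDC"), c("PDC", "TB")), -1)
  for (s in 1:30) {
    r <- random_ratings(1000, 2, seed = 2000 + s)
    expect_equal(cohen_kappa(r[, 1], r[, 2]), cohen_oracle(r[, 1], r[, 2]),
                 tolerance = 1e-12)
  }
  expect_error(cohen_kappa(c("TB"), c("TB", "PDC")), "equal length")
})

test_that("kappas are label- and order-permutation invariant and bounded", {
  relabel <- c(TB = "NEITHER", PDC = "TB", NEITHER = "PDC")
  for (s in 1:10) {
    r <- random_ratings(50, 5, seed = 3000 + s)
    k1 <- fleiss_kappa(rating_panel(r))
    expect_equal(fleiss_kappa(rating_panel(
      matrix(relabel[r], nrow(r), ncol(r)))), k1, tolerance = 1e-12)
    perm <- withr::with_seed(s, sample(nrow(r)))
    expect_equal(fleiss_kappa(rating_panel(r[perm, ])), k1,
                 tolerance = 1e-12)
    expect_true(k1 >= -1 && k1 <= 1)
    k2 <- cohen_kappa(r[, 1], r[, 2])
    expect_equal(cohen_kappa(relabel[r[, 1]], relabel[r[, 2]]), k2,
                 tolerance = 1e-12)
    expect_true(k2 >= -1 && k2 <= 1)
  }
})

test_that("two-rater fleiss equals its own formula, not forced to Cohen", {
  r <- random_ratings(200, 2, seed = 77)
  expect_equal(fleiss_kappa(rating_panel(r)), fleiss_oracle(r),
               tolerance = 1e-12)
})

test_that("pairwise matrix is symmetric and matches per-pair computation", {
  r <- random_ratings(120, 3, seed = 55)
  colnames(r) <- c("a", "b", "c")
  panel <- rating_panel(r)
  m <- pairwise_kappa_matrix(panel)
  expect_identical(m, t(m))
  expect_true(all(is.na(diag(m))))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(m[i, j], cohen_oracle(r[, i], r[, j]), tolerance = 1e-12)
  }
  # all-identical raters give 1 everywhere off-diagonal
  same <- rating_panel(matrix(rep(c("TB", "PDC"), 5), 10, 4))
  m1 <- pairwise_kappa_matrix(same)
  expect_true(all(m1[upper.tri(m1)] == 1))
})

test_that("raters with no shared objects get an undefined pairwise kappa", {
  r <- matrix(NA_character_, 4, 2)
  r[1:2, 1] <- "TB"
  r[3:4, 2] <- "PDC"
  m <- pairwise_kappa_matrix(rating_panel(r, allow_incomplete = TRUE))
  expect_true(is.na(m[1, 2]))
})

test_that("Landis-Koch bands follow upper-inclusive boundaries", {
  expect_identical(interpret_kappa(c(0.42, 0.51)),
                   c("moderate", "moderate"))
  expect_identical(
    interpret_kappa(c(-0.5, 0.20, 0.21, 0.40, 0.60, 0.80, 0.81, 1)),
    c("poor", "poor", "fair", "fair", "moderate", "good", "very good",
      "very good"))
  expect_error(interpret_kappa(1.2), "\\[-1, 1\\]")
})

test_that("identity-confusion panels give kappa exactly 1 end to end", {
  gp <- generate_rating_panel(panel_spec(300, 7, seed = 8))
  expect_identical(fleiss_kappa(gp$panel), 1)
  m <- pairwise_kappa_matrix(gp$panel)
  expect_true(all(m[upper.tri(m)] == 1))
  cons <- consensus_labels(gp$panel)
  expect_identical(cons$label, unname(gp$truth))
  expect_true(all(cons$tier == "uniform"))
})

test_that("agreement_report bundles per-group fleiss with banded pairs", {
  r <- random_ratings(100, 4, seed = 66)
  colnames(r) <- c("a", "b", "c", "d")
  panel <- rating_panel(r, rater_groups = c("g1", "g1", "g2", "g2"))
  rep <- agreement_report(panel)
  expect_identical(rep$fleiss$group, c("g1", "g2"))
  expect_equal(rep$fleiss$kappa[1],
               fleiss_oracle(r[, 1:2]), tolerance = 1e-12)
  expect_identical(rep$fleiss$band, interpret_kappa(rep$fleiss$kappa))
  expect_identical(dim(rep$cohen_matrix), c(4L, 4L))
})
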