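test_that("contingency cells sum stems by habitat and trait", {
  plots <- tibble::tibble(plot_id = "p1", habitat = "SW", taxon = "A",
                          stems = 10)
  traits <- tibble::tibble(taxon = "A", trait = "Fallback apes")
  ct <- build_contingency(plots, traits)
  expect_equal(dim(ct$table), c(1, 1))
  expect_equal(ct$table["SW", "Fallback apes"], 10)
  expect_equal(ct$n_excluded_plots, 0)
})

test_that("plots without consumed-taxon stems are excluded and counted", {
  plots <- tibble::tibble(
    plot_id = c("p1", "p2", "p3", "p4"),
    habitat = c("SW", "MF", "MF", "RF"),
    taxon = c("A", "A", "B", "B"),
    stems = c(10, 5, 3, 0))
  traits <- tibble::tibble(taxon = c("A", "B"),
                           trait = c("Preferred apes", "none"))
  ct <- build_contingency(plots, traits)
  # p3 holds only a "none" taxon and p4 only zero stems: both excluded
  expect_equal(ct$n_excluded_plots, 2)
  expect_equal(ct$n_plots_used, 2)
  expect_false("Fallback apes" %in% colnames(ct$table))
  expect_error(build_contingency(plots[4, ], traits), "no nonzero cells")
})

test_that("contingency cells match generator intensities within Poisson error", {
  gen <- generate_dataset(generator_config(n_taxa = 8, samples_per_month = 3,
                                           nests_per_season = 5), seed = 13)
  traits <- tibble::tibble(taxon = gen$truth$config$taxa, trait = "Preferred apes")
  ct <- build_contingency(gen$dataset$plots, traits, by = "taxon")
  lambda <- gen$truth$config$stem_lambda
  plot_counts <- table(gen$dataset$plots$habitat[
    !duplicated(gen$dataset$plots$plot_id)])
  for (h in rownames(ct$table)) {
    expected <- lambda[colnames(ct$table), h] * plot_counts[[h]]
    observed <- ct$table[h, ]
    expect_true(all(abs(observed - expected) <= 4 * sqrt(expected) + 4),
                info = h)
  }
})

test_that("CA total inertia equals Pearson chi-squared over n", {
  set.seed(7)
  for (i in 1:100) {
    m <- random_contingency()
    ca <- correspondence_analysis(m)
    chi2 <- suppressWarnings(chisq.test(m, correct = FALSE)$statistic)
    expect_equal(ca$total_inertia, unname(chi2) / sum(m), tolerance = 1e-10)
  }
})

test_that("CA recovers the structure of canonical tables", {
  # perfect diagonal association: inertia 1 on a single axis
  ca <- correspondence_analysis(matrix(c(10, 0, 0, 10), 2))
  expect_equal(ca$total_inertia, 1)
  expect_length(ca$inertia, 1)
  expect_equal(ca$percent_inertia, 100)
  # independence: zero inertia, no axes, no failure
  r <- c(2, 3, 5)
  cc <- c(1, 4)
  ca0 <- correspondence_analysis(outer(r, cc))
  expect_equal(ca0$total_inertia, 0, tolerance = 1e-12)
  expect_length(ca0$inertia, 0)
})

test_that("CA deviations have zero margins and axes respect rank bound", {
  set.seed(11)
  for (i in 1:20) {
    m <- random_contingency()
    ca <- correspondence_analysis(m)
    expect_true(all(abs(rowSums(ca$deviations)) < 1e-10))
    expect_true(all(abs(colSums(ca$deviations)) < 1e-10))
    expect_lte(length(ca$inertia), min(dim(m)) - 1)
    # weighted mean of principal coordinates is zero on every axis
    r <- rowSums(m) / sum(m)
    if (length(ca$inertia)) {
      expect_true(all(abs(colSums(ca$row_coords * r)) < 1e-10))
    }
  }
})

test_that("CA matches vegan's eigenvalues and InfoStat-style scaling", {
  set.seed(5)
  m <- random_contingency(4, 6, lambda = 8)
  ca <- correspondence_analysis(m)
  cca_fit <- vegan::cca(m)
  ev <- cca_fit$CA$eig
  expect_equal(unname(ca$inertia), unname(ev[seq_along(ca$inertia)]),
               tolerance = 1e-8)
})

test_that("Bray-Curtis follows the formula and its metric-like properties", {
  expect_equal(as.numeric(bray_curtis(rbind(c(1, 2), c(2, 1)))), 2 / 6)
  expect_equal(as.numeric(bray_curtis(rbind(c(1, 2), c(1, 2)))), 0)
  expect_equal(as.numeric(bray_curtis(rbind(c(1, 2), c(0, 0)))), 1)
  expect_warning(d0 <- bray_curtis(rbind(c(0, 0), c(0, 0))), "all-zero")
  expect_equal(as.numeric(d0), 0)
  expect_error(bray_curtis(rbind(c(-1, 2), c(0, 0))), "non-negative")
  set.seed(2)
  for (i in 1:50) {
    x <- matrix(rexp(40), 8, 5)
    d <- as.matrix(bray_curtis(x))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
  }
})

test_that("PERMANOVA pseudo-F agrees with a coordinate-based oracle", {
  set.seed(17)
  for (i in 1:10) {
    X <- matrix(rnorm(16), 8, 2)
    g <- rep(c("a", "b"), each = 4)
    d <- dist(X)
    pm <- permanova(d, g, n_perm = 99, seed = i)
    expect_equal(pm$pseudo_F, coord_pseudo_F(X, g), tolerance = 1e-10)
  }
})

test_that("PERMANOVA agrees with vegan::adonis2 on Bray-Curtis data", {
  set.seed(19)
  x <- matrix(rexp(60), 12, 5)
  g <- rep(c("a", "b", "c"), each = 4)
  d <- bray_curtis(x)
  pm <- permanova(d, g, n_perm = 999, seed = 1)
  ad <- vegan::adonis2(d ~ g, permutations = 999)
  expect_equal(pm$pseudo_F, ad$F[1], tolerance = 1e-10)
  expect_equal(pm$ss[["total"]], ad["Total", "SumOfSqs"], tolerance = 1e-10)
})

test_that("exact enumeration reproduces the brute-force permutation test", {
  set.seed(23)
  X <- matrix(rnorm(12), 6, 2)
  g <- rep(c("a", "b"), each = 3)
  d <- dist(X)
  pm <- permanova(d, g, exact = TRUE)
  expect_equal(pm$n_perm, choose(6, 3))
  # independent brute force from coordinates over all 20 assignments
  combos <- combn(6, 3)
  F_all <- apply(combos, 2, function(idx) {
    gg <- rep("b", 6)
    gg[idx] <- "a"
    coord_pseudo_F(X, gg)
  })
  F_obs <- coord_pseudo_F(X, g)
  expect_equal(pm$pseudo_F, F_obs, tolerance = 1e-10)
  expect_equal(pm$p_value, mean(F_all >= F_obs - 1e-12))
})

test_that("duplicated point clouds give F near zero and large p", {
  X <- matrix(rnorm(10), 5, 2)
  XX <- rbind(X, X)
  g <- rep(c("a", "b"), each = 5)
  pm <- permanova(dist(XX), g, n_perm = 199, seed = 3)
  expect_lt(pm$pseudo_F, 1e-10)
  expect_gt(pm$p_value, 0.9)
})

test_that("dispersion test matches vegan::betadisper distances and F", {
  set.seed(29)
  x <- matrix(rexp(60), 12, 5)
  g <- rep(c("a", "b", "c"), each = 4)
  d <- bray_curtis(x)
  dh <- dispersion_homogeneity(d, g, n_perm = 99, seed = 1)
  bd <- vegan::betadisper(d, g, type = "centroid")
  expect_equal(dh$distances, unname(bd$distances), tolerance = 1e-10)
  an <- anova(bd)
  expect_equal(dh$F, an$F[1], tolerance = 1e-10)
})

test_that("equal within-group spreads give F = 0 and p = 1", {
  # two groups forming congruent equilateral triangles: every distance to the
  # group centroid is identical, under any labelling F* >= F = 0
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  X <- rbind(tri, tri + 10)
  g <- rep(c("a", "b"), each = 3)
  dh <- dispersion_homogeneity(dist(X), g, n_perm = 99, seed = 1)
  expect_equal(dh$F, 0, tolerance = 1e-20)
  expect_equal(dh$p_value, 1)
})

test_that("a group with triple the spread is detected", {
  set.seed(31)
  base <- matrix(rnorm(20), 10, 2)
  X <- rbind(base, 3 * matrix(rnorm(20), 10, 2))
  g <- rep(c("tight", "wide"), each = 10)
  dh <- dispersion_homogeneity(dist(X), g, n_perm = 999, seed = 2)
  expect_lt(dh$p_value, 0.05)
})
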