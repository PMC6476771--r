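test_that("stem density counts all plots, including absences", {
  plots <- data.frame(plot_id = paste0("p", 1:4), habitat = "MF",
                      taxon = "A", stems = c(4, 3, 2, 1))
  d <- stem_density(plots)
  expect_equal(d$D, 10 / (4 * 625))
  expect_equal(d$S, 625)
  # taxon present in one plot only: K still 4
  plots2 <- rbind(plots, data.frame(plot_id = "p1", habitat = "MF",
                                    taxon = "B", stems = 5))
  d2 <- stem_density(plots2)
  expect_equal(d2$D[d2$taxon == "B"], 5 / (4 * 625))
  # absent taxon contributes zero rows; explicit zero rows give D = 0
  plots3 <- rbind(plots, data.frame(plot_id = paste0("p", 1:4), habitat = "MF",
                                    taxon = "C", stems = 0))
  d3 <- stem_density(plots3)
  expect_equal(d3$D[d3$taxon == "C"], 0)
  expect_error(stem_density(plots, plot_area = 0), "plot_area")
})

test_that("basal area follows the circular cross-section in metres", {
  expect_equal(basal_area(10), pi * 0.05^2)
  expect_equal(basal_area(10), 7.854e-3, tolerance = 1e-4)
  # doubling DBH quadruples area; B -> 0 as dbh -> 0+
  expect_equal(basal_area(20) / basal_area(10), 4)
  expect_lt(basal_area(1e-6), 1e-12)
  expect_error(basal_area(0), "positive")
})

test_that("FAP combines score-weighted basal area and density", {
  # two individuals with (SS, B) = (4, 0.10) and (2, 0.05), D = 0.004:
  # FAP = ((4*0.10 + 2*0.05)/2) * 0.004 = 0.001
  dbh1 <- 200 * sqrt(0.10 / pi) # basal area exactly 0.10 m^2
  dbh2 <- 200 * sqrt(0.05 / pi)
  phen <- data.frame(
    individual_id = c("i1", "i2"), taxon = "A", month = 1L,
    dbh_cm = c(dbh1, dbh2),
    score_unripe_tree = c(1, 1), score_ripe_tree = c(1, 1),
    score_unripe_ground = c(1, 0), score_ripe_ground = c(1, 0))
  density <- tibble::tibble(taxon = "A", D = 0.004)
  fap <- fap_table(phen, density, months = 1)
  expect_equal(fap$fap, 0.001)
  # all scores zero in a month -> FAP 0; unobserved months -> 0 too
  fap12 <- fap_table(phen, density, months = 1:12)
  expect_equal(fap12$fap[fap12$month == 2], 0)
  # ripe_only restricts SS to the two ripe scores: SS = (2, 1)
  fap_ripe <- fap_table(phen, density, months = 1, ripe_only = TRUE)
  expect_equal(fap_ripe$fap, ((2 * 0.10 + 1 * 0.05) / 2) * 0.004)
})

test_that("unobserved individuals still count in the FAP denominator", {
  phen <- data.frame(
    individual_id = c("i1", "i2"), taxon = "A", month = c(1L, 2L),
    dbh_cm = 200 / sqrt(pi), # basal area exactly 1
    score_unripe_tree = 2, score_ripe_tree = 2,
    score_unripe_ground = 2, score_ripe_ground = 2)
  density <- tibble::tibble(taxon = "A", D = 1)
  fap <- fap_table(phen, density, months = 1)
  # only i1 observed in month 1 (SS = 8, B = 1) but N = 2
  expect_equal(fap$fap, 8 / 2)
})

test_that("fruit quantity applies the count rule branch by branch", {
  expect_equal(fruit_quantity(12, 5, 20), 60) # ceil(2.4) = 3 fruits
  expect_equal(fruit_quantity(3, 5, 20), 20)  # below mean: one fruit
  expect_equal(fruit_quantity(5, 5, 20), 20)  # at the mean: exactly one
  expect_equal(fruit_quantity(0, 5, 20), 0)
  expect_equal(fruit_quantity(c(0, 3, 12), 5, 20), c(0, 20, 60))
  expect_error(fruit_quantity(3, NA, 20), "lacks")
  expect_error(fruit_quantity(-1, 5, 20), "non-negative")
})

test_that("MCS multiplies the mass share by the sample frequency", {
  # month with 4 samples; taxon A has 300 g of 400 g total, in 3 of 4 samples
  taxa <- tibble::tibble(taxon = c("A", "B"), family = "f",
                         mean_fruit_weight_g = c(100, 100),
                         mean_seeds_per_fruit = c(10, 10))
  fecal <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s4"),
    ape = "gorilla", month = 1L,
    taxon = c("A", "A", "A", "B"),
    seeds = c(10, 10, 10, 10))
  m <- mcs_table(fecal, taxa, "gorilla", months = 1)
  expect_equal(m$mcs[m$taxon == "A"], 0.75 * 0.75)
  expect_equal(m$mcs[m$taxon == "B"], 0.25 * 0.25)
  # only taxon consumed, present in every sample -> MCS = 1
  fecal2 <- fecal
  fecal2$taxon <- "A"
  m2 <- mcs_table(fecal2, taxa, "gorilla", months = 1)
  expect_equal(m2$mcs, 1)
})

test_that("MCS invariants hold on synthetic data", {
  gen <- generate_dataset(generator_config(n_taxa = 8, samples_per_month = 10,
                                           nests_per_season = 5), seed = 3)
  m <- mcs_table(gen$dataset$fecal, gen$dataset$taxa, "chimpanzee")
  expect_true(all(m$mcs >= 0 & m$mcs <= 1))
  expect_true(all(m$mcs <= m$pf / m$npf + 1e-12))
  shares <- m |>
    dplyr::summarise(total_qf = sum(.data$qf), .by = "month")
  by_month <- m |>
    dplyr::left_join(shares, by = "month") |>
    dplyr::filter(.data$total_qf > 0) |>
    dplyr::summarise(share = sum(.data$qf / .data$total_qf), .by = "month")
  expect_true(all(abs(by_month$share - 1) < 1e-12))
})

test_that("taxa without fruit traits are excluded from MCS with a warning", {
  taxa <- tibble::tibble(taxon = c("A", "B"), family = "f",
                         mean_fruit_weight_g = c(100, NA),
                         mean_seeds_per_fruit = c(10, NA))
  fecal <- tibble::tibble(sample_id = c("s1", "s2"), ape = "gorilla",
                          month = 1L, taxon = c("A", "B"), seeds = c(5, 5))
  expect_warning(m <- mcs_table(fecal, taxa, "gorilla", months = 1), "B")
  expect_false("B" %in% m$taxon)
  expect_equal(m$npf, 2L) # the sample still counts toward effort
})

test_that("GIS averages consumption/availability ratios over study months", {
  # ratios {10, 20} over J = 12; fruiting 4 months, consumed 2 -> GIS 1.25
  fap <- tibble::tibble(taxon = "A", month = 1:12,
                        fap = c(0.01, 0.01, 0.01, 0.01, rep(0, 8)))
  mcs <- tibble::tibble(taxon = "A", month = 1:12,
                        mcs = c(0.1, 0.2, rep(0, 10)),
                        qf = 0, pf = 0L, npf = 1L)
  g <- gis_table(mcs, fap, J = 12)
  expect_equal(g$gis, (10 + 20) / 12 * 0.5)
  expect_equal(g$pe, 0.5)
  expect_equal(g$status, "classified")
})

test_that("GIS handles never-consumed, UC and Pe > 1 cases", {
  fap <- tibble::tibble(taxon = rep(c("A", "B"), each = 4),
                        month = rep(1:4, 2),
                        fap = c(1, 1, 0, 0, 0, 0, 0, 0))
  mcs <- tibble::tibble(taxon = c("A", "A", "A", "C"), month = c(1, 2, 3, 1),
                        mcs = c(0.5, 0.5, 0.2, 0.1),
                        qf = 0, pf = 0L, npf = 1L)
  g <- gis_table(mcs, fap, J = 4)
  gA <- g[g$taxon == "A", ]
  # consumed in month 3 while not fruiting: ratio excluded, Pe = 3/2 > 1
  expect_equal(gA$pe, 1.5)
  expect_true(gA$pe_gt_1)
  expect_equal(gA$gis, (0.5 + 0.5) / 4 * 1.5)
  # B never fruits -> UC; C consumed but never monitored -> UC
  expect_equal(g$status[g$taxon == "B"], "UC")
  expect_equal(g$status[g$taxon == "C"], "UC")
  expect_true(all(is.na(g$rank[g$status == "UC"])))
})

test_that("ranking is descending with UC last and tiny values displayed as 0", {
  tbl <- tibble::tibble(taxon = c("x", "y", "z", "u"),
                        gis = c(5, 3, 0.0005, NA),
                        pe = c(1, 1, 1, NA),
                        status = c("classified", "classified", "classified",
                                   "UC"))
  r <- rank_preference(tbl)
  expect_equal(r$rank[match(c("x", "y", "z"), r$taxon)], 1:3)
  expect_true(is.na(r$rank[r$taxon == "u"]))
  expect_equal(r$gis_display[r$taxon == "z"], 0)
  expect_equal(r$gis[r$taxon == "z"], 0.0005) # ranked by underlying value
})

test_that("GIS is invariant to duplicating every fecal sample", {
  d <- toy$dataset
  fecal2 <- d$fecal |>
    dplyr::mutate(sample_id = paste0(.data$sample_id, "_dup"))
  fecal_dbl <- dplyr::bind_rows(d$fecal, fecal2)
  dens <- stem_density(d$plots)
  fap <- fap_table(d$phenology, dens, months = c(1, 4, 7, 9))
  g1 <- gis_table(mcs_table(d$fecal, d$taxa, "gorilla", months = c(1, 4, 7, 9)),
                  fap, J = 4)
  g2 <- gis_table(mcs_table(fecal_dbl, d$taxa, "gorilla", months = c(1, 4, 7, 9)),
                  fap, J = 4)
  expect_equal(g1$gis, g2$gis)
})

test_that("scaling FAP by c scales GIS by 1/c and preserves ranks", {
  d <- toy$dataset
  dens <- stem_density(d$plots)
  fap <- fap_table(d$phenology, dens, months = c(1, 4, 7, 9))
  mcs <- mcs_table(d$fecal, d$taxa, "gorilla", months = c(1, 4, 7, 9))
  g1 <- gis_table(mcs, fap, J = 4)
  fap_scaled <- dplyr::mutate(fap, fap = .data$fap * 7)
  g2 <- gis_table(mcs, fap_scaled, J = 4)
  expect_equal(g2$gis, g1$gis / 7)
  expect_equal(g2$rank, g1$rank)
})

test_that("GIS ranks recover true preference on a default synthetic study", {
  gen <- generate_dataset(generator_config(), seed = 101)
  sc <- diet_scores(gen$dataset)
  for (a in ape_codes()) {
    g <- sc$gis[[a]]
    j <- dplyr::inner_join(g[!is.na(g$rank), c("taxon", "rank")],
                           gen$truth$preference[[a]], by = "taxon")
    rho <- cor(j$rank, j$true_rank, method = "spearman")
    expect_gte(rho, 0.8)
  }
})
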