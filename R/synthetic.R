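#' Configuration for the synthetic survey generator
#'
#' Defines the generating conditions for a complete synthetic field study:
#' habitat availability, transect design, botanical plot intensities,
#' seasonal fruiting profiles, per-ape fruit preference weights and habitat
#' selection weights, and sampling effort. Defaults emulate the field design
#' the analysis assumes: 20 transects of 120 stations (50-m spacing), 184
#' botanical plots of 625 m^2 across the four inventoried habitats, 20 fruit
#' taxa with about 10 monitored phenology individuals each, 30 fecal samples
#' per month per ape over 12 months, and 200 nests per season per ape.
#'
#' Community fruit availability is high in the two rainy seasons (LRS, SRS)
#' and low in the two dry seasons (LDS, SDS). Three designed fallback taxa
#' fruit year-round but have their consumption intensity boosted fivefold in
#' the low-availability seasons, the signature the fallback classifier is
#' meant to recover. Habitat selection weights are expressed on the W' scale
#' and sum to the habitat count, so the configured value is exactly the
#' expected selectivity ratio: gorillas prefer swamps (W' = 2.4) and avoid
#' mature and riparian forest (0.4); chimpanzees prefer mature forest (2.4)
#' and avoid young secondary forest (0.4). Strong effects (W' at or beyond
#' 2 or 0.5) are placed on habitats common enough that the survey design has
#' power to detect them; the rare light-gap microhabitat gets weights near 1.
#'
#' @param n_taxa Number of fruit taxa (default 20).
#' @param months Study months (default 1:12).
#' @param calendar A [season_calendar()].
#' @param availability Named habitat availability weights summing to 1.
#' @param n_transects,points_per_transect Availability survey design.
#' @param n_plots Number of botanical plots (default 184).
#' @param plot_area Plot area in m^2 (default 625).
#' @param stem_lambda Matrix (n_taxa x 4) of Poisson stem intensities per
#'   plot for habitats MF, YSF, SW, RF. Default: each taxon concentrated in
#'   one habitat (lambda 4) with background 0.4 elsewhere.
#' @param fruiting Matrix (n_taxa x 4 seasons, columns LDS, LRS, SDS, SRS) of
#'   fruiting intensities in 0-1 driving the phenology score distribution.
#' @param n_phenology_individuals Monitored individuals per taxon (default 10).
#' @param preference Named list (`gorilla`, `chimpanzee`) of positive
#'   per-taxon preference weight vectors. Default: a geometric ladder from
#'   0.2 to 5, in opposite taxon order for the two apes.
#' @param fallback_taxa Indices of designed fallback taxa (default: taxa 2, 9
#'   and 16, truncated to the taxon count for small communities).
#' @param fallback_boost Low-season consumption multiplier for fallback taxa
#'   (default 5).
#' @param true_w_prime Named list (`gorilla`, `chimpanzee`) of habitat
#'   selection weights on the W' scale (must average 1 over the 5 habitats).
#' @param samples_per_month Fecal samples per month per ape (default 30).
#' @param nests_per_season Nests per season per ape (default 200).
#' @param mean_mass_per_sample Mean consumed fruit mass (g) per taxon per
#'   sample at preference weight 1 in an average fruiting month (default
#'   100 g). Consumption is mass-based: the expected number of fruits is this
#'   mass divided by the taxon's mean fruit weight, so preference governs
#'   mass intake regardless of fruit size.
#' @param dbh_meanlog,dbh_sdlog Lognormal DBH (cm) parameters (defaults
#'   log(30) and 0.35).
#' @param fruit_weight_range,seeds_per_fruit_range Uniform ranges for the
#'   fruit trait table (grams; seeds per fruit drawn as integers).
#' @return A `generator_config` list (validated).
#' @export
generator_config <- function(
    n_taxa = 20,
    months = 1:12,
    calendar = season_calendar(),
    availability = c(MF = 0.45, YSF = 0.20, LG = 0.08, SW = 0.15, RF = 0.12),
    n_transects = 20,
    points_per_transect = 120,
    n_plots = 184,
    plot_area = 625,
    stem_lambda = NULL,
    fruiting = NULL,
    n_phenology_individuals = 10,
    preference = NULL,
    fallback_taxa = NULL,
    fallback_boost = 5,
    true_w_prime = list(
      gorilla = c(MF = 0.4, YSF = 0.8, LG = 1.0, SW = 2.4, RF = 0.4),
      chimpanzee = c(MF = 2.4, YSF = 0.4, LG = 0.8, SW = 0.8, RF = 0.6)
    ),
    samples_per_month = 30,
    nests_per_season = 200,
    mean_mass_per_sample = 100,
    dbh_meanlog = log(30),
    dbh_sdlog = 0.35,
    fruit_weight_range = c(5, 80),
    seeds_per_fruit_range = c(2, 15)) {

  taxa <- sprintf("taxon_%02d", seq_len(n_taxa))
  if (is.null(stem_lambda)) {
    stem_lambda <- matrix(0.4, n_taxa, length(PLOT_HABITATS),
                          dimnames = list(taxa, PLOT_HABITATS))
    primary <- PLOT_HABITATS[(seq_len(n_taxa) - 1) %% length(PLOT_HABITATS) + 1]
    stem_lambda[cbind(seq_len(n_taxa), match(primary, PLOT_HABITATS))] <- 4
  }
  if (is.null(fruiting)) {
    # community availability high in the rainy seasons, low in the dry ones;
    # taxon-specific amplitude keeps taxa distinguishable
    base <- c(LDS = 0.30, LRS = 0.90, SDS = 0.40, SRS = 0.80)
    amp <- 0.8 + 0.4 * (seq_len(n_taxa) - 1) / max(n_taxa - 1, 1)
    fruiting <- pmin(outer(amp, base), 1)
    dimnames(fruiting) <- list(taxa, SEASON_CODES)
  }
  if (is.null(fallback_taxa)) {
    fallback_taxa <- unique(pmin(c(2L, 9L, 16L), n_taxa))
  }
  if (is.null(preference)) {
    ladder <- exp(seq(log(0.2), log(5), length.out = n_taxa))
    preference <- list(gorilla = stats::setNames(ladder, taxa),
                       chimpanzee = stats::setNames(rev(ladder), taxa))
  }
  stopifnot(
    abs(sum(availability) - 1) < 1e-8,
    setequal(names(availability), HABITAT_CODES),
    all(availability >= 0),
    nrow(stem_lambda) == n_taxa, all(stem_lambda >= 0),
    nrow(fruiting) == n_taxa, all(fruiting >= 0 & fruiting <= 1),
    all(fallback_taxa >= 1 & fallback_taxa <= n_taxa),
    fallback_boost > 0,
    all(vapply(preference, function(w) all(w > 0), logical(1))),
    samples_per_month >= 1, nests_per_season >= 1,
    n_plots >= 1, plot_area > 0, n_phenology_individuals >= 1
  )
  for (a in APE_CODES) {
    w <- true_w_prime[[a]]
    if (!setequal(names(w), HABITAT_CODES) ||
        abs(mean(w) - 1) > 1e-8 || any(w < 0)) {
      stop("true_w_prime[[", a, "]] must cover all habitats, be non-negative ",
           "and average 1 (the W' scale)", call. = FALSE)
    }
  }
  structure(list(
    n_taxa = n_taxa, taxa = taxa, months = months, calendar = calendar,
    availability = availability[HABITAT_CODES], n_transects = n_transects,
    points_per_transect = points_per_transect, n_plots = n_plots,
    plot_area = plot_area, stem_lambda = stem_lambda, fruiting = fruiting,
    n_phenology_individuals = n_phenology_individuals,
    preference = preference, fallback_taxa = as.integer(fallback_taxa),
    fallback_boost = fallback_boost, true_w_prime = true_w_prime,
    samples_per_month = samples_per_month, nests_per_season = nests_per_season,
    mean_mass_per_sample = mean_mass_per_sample,
    dbh_meanlog = dbh_meanlog, dbh_sdlog = dbh_sdlog,
    fruit_weight_range = fruit_weight_range,
    seeds_per_fruit_range = seeds_per_fruit_range
  ), class = "generator_config")
}

#' Generate a synthetic survey dataset with known ground truth
#'
#' Draws a complete six-table dataset from the generating model of
#' [generator_config()]: availability stations are multinomial in the habitat
#' weights; plot stem counts are Poisson in the per-taxon, per-habitat
#' intensities; phenology scores are drawn per individual and month from the
#' taxon's seasonal fruiting intensity (each of the four 0/1/2 scores is 0
#' with probability 1 - f, else 1 or 2 with equal probability); nests are
#' multinomial over habitats with probability proportional to availability
#' times the true selection weight; and fecal fruit counts per taxon and
#' sample are Poisson with intensity proportional to preference weight times
#' the month's realized population FAP (times the fallback boost in
#' low-availability seasons for designed fallback taxa), seeds being fruits
#' times the taxon's seeds-per-fruit. Fully reproducible from `seed`.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return A list with `dataset` (a [survey_dataset()]) and `truth` (a
#'   `ground_truth` list: per-ape preference table with effective weights and
#'   true ranks, the designed fallback taxa, per-ape true habitat selection
#'   classes, and the config).
#' @export
generate_dataset <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  cf <- config
  taxa <- cf$taxa

  # --- availability survey points ----------------------------------------
  n_pts <- cf$n_transects * cf$points_per_transect
  availability <- tibble::tibble(
    transect_id = rep(sprintf("t%02d", seq_len(cf$n_transects)),
                      each = cf$points_per_transect),
    position_m = rep((seq_len(cf$points_per_transect) - 1) * 50,
                     cf$n_transects),
    habitat = sample(HABITAT_CODES, n_pts, replace = TRUE,
                     prob = cf$availability)
  )

  # --- fruit trait table --------------------------------------------------
  taxa_tbl <- tibble::tibble(
    taxon = taxa,
    family = sprintf("family_%02d", (seq_along(taxa) - 1) %% 8 + 1),
    mean_fruit_weight_g = round(runif(length(taxa), cf$fruit_weight_range[1],
                                      cf$fruit_weight_range[2]), 1),
    mean_seeds_per_fruit = sample(cf$seeds_per_fruit_range[1]:
                                    cf$seeds_per_fruit_range[2],
                                  length(taxa), replace = TRUE)
  )

  # --- botanical plots (full grid; LG never inventoried) ------------------
  plot_habitat <- sample(PLOT_HABITATS, cf$n_plots, replace = TRUE,
                         prob = cf$availability[PLOT_HABITATS] /
                           sum(cf$availability[PLOT_HABITATS]))
  plots <- tidyr::expand_grid(
    plot_id = sprintf("plot_%03d", seq_len(cf$n_plots)),
    taxon = taxa
  ) |>
    dplyr::mutate(
      habitat = plot_habitat[match(.data$plot_id,
                                   sprintf("plot_%03d", seq_len(cf$n_plots)))],
      stems = rpois(dplyr::n(),
                    cf$stem_lambda[cbind(match(.data$taxon, taxa),
                                         match(.data$habitat, PLOT_HABITATS))])
    ) |>
    dplyr::select("plot_id", "habitat", "taxon", "stems")

  # --- phenology ----------------------------------------------------------
  ind <- tidyr::expand_grid(
    taxon = taxa,
    replicate = seq_len(cf$n_phenology_individuals)
  ) |>
    dplyr::mutate(individual_id = sprintf("%s_ind%02d", .data$taxon,
                                          .data$replicate),
                  dbh_cm = round(rlnorm(dplyr::n(), cf$dbh_meanlog,
                                        cf$dbh_sdlog), 1))
  draw_score <- function(f) {
    # each of the four component scores: 0 w.p. 1-f, else 1 or 2 equally
    u <- runif(length(f))
    ifelse(u > f, 0L, ifelse(runif(length(f)) < 0.5, 1L, 2L))
  }
  phenology <- tidyr::expand_grid(ind, month = as.integer(cf$months)) |>
    dplyr::mutate(
      f = cf$fruiting[cbind(match(.data$taxon, taxa),
                            match(season_of(.data$month, cf$calendar),
                                  SEASON_CODES))],
      score_unripe_tree = draw_score(.data$f),
      score_ripe_tree = draw_score(.data$f),
      score_unripe_ground = draw_score(.data$f),
      score_ripe_ground = draw_score(.data$f)
    ) |>
    dplyr::select("individual_id", "taxon", "month", "dbh_cm",
                  dplyr::starts_with("score_"))

  # --- nests --------------------------------------------------------------
  nests <- purrr::map_dfr(APE_CODES, function(a) {
    w <- cf$true_w_prime[[a]][HABITAT_CODES]
    prob <- cf$availability * w
    purrr::map_dfr(SEASON_CODES, function(s) {
      season_months <- which(unclass(cf$calendar) == s)
      season_months <- intersect(season_months, cf$months)
      if (!length(season_months)) return(NULL)
      n <- cf$nests_per_season
      tibble::tibble(
        ape = a,
        month = sample(rep(season_months, length.out = max(n, 1)))[seq_len(n)],
        habitat = sample(HABITAT_CODES, n, replace = TRUE, prob = prob),
        group_id = sprintf("%s_%s_g%03d", a, s, seq_len(n))
      )
    })
  })

  # --- fecal samples, coupled to realized availability --------------------
  dens <- stem_density(plots, plot_area = cf$plot_area)
  fap <- fap_table(phenology, dens, months = cf$months)
  fap_mat <- tidyr::pivot_wider(fap, names_from = "month",
                                values_from = "fap") |>
    tibble::column_to_rownames("taxon") |>
    as.matrix()
  fap_scale <- mean(fap_mat[fap_mat > 0])
  low_seasons <- c("LDS", "SDS")
  boost <- matrix(1, length(taxa), length(cf$months),
                  dimnames = list(taxa, cf$months))
  month_season <- season_of(cf$months, cf$calendar)
  boost[cf$fallback_taxa, month_season %in% low_seasons] <- cf$fallback_boost

  fecal <- purrr::map_dfr(APE_CODES, function(a) {
    pref <- cf$preference[[a]][taxa]
    purrr::map_dfr(seq_along(cf$months), function(mi) {
      m <- cf$months[mi]
      lambda <- cf$mean_mass_per_sample * pref * boost[, mi] *
        (fap_mat[taxa, as.character(m)] / fap_scale) /
        taxa_tbl$mean_fruit_weight_g
      n_s <- cf$samples_per_month
      fruits <- matrix(rpois(n_s * length(taxa), rep(lambda, each = n_s)),
                       nrow = n_s)
      idx <- which(fruits > 0, arr.ind = TRUE)
      if (!nrow(idx)) return(NULL)
      tibble::tibble(
        sample_id = sprintf("%s_m%02d_s%02d", a, m, idx[, 1]),
        ape = a,
        month = as.integer(m),
        taxon = taxa[idx[, 2]],
        seeds = fruits[idx] *
          taxa_tbl$mean_seeds_per_fruit[match(taxa[idx[, 2]], taxa_tbl$taxon)]
      )
    })
  })
  # keep every analysed sample on record, including all-zero ones, so NPf_j
  # counts true sampling effort
  all_samples <- tidyr::expand_grid(ape = APE_CODES,
                                    month = as.integer(cf$months),
                                    s = seq_len(cf$samples_per_month)) |>
    dplyr::mutate(sample_id = sprintf("%s_m%02d_s%02d", .data$ape,
                                      .data$month, .data$s))
  empty <- all_samples |>
    dplyr::filter(!.data$sample_id %in% fecal$sample_id) |>
    dplyr::mutate(taxon = taxa[1], seeds = 0L) |>
    dplyr::select("sample_id", "ape", "month", "taxon", "seeds")
  fecal <- dplyr::bind_rows(fecal, empty) |>
    dplyr::arrange(.data$sample_id, .data$taxon)

  dataset <- survey_dataset(availability, nests, fecal, phenology, plots,
                            taxa_tbl, calendar = cf$calendar,
                            plot_area = cf$plot_area)

  # --- ground truth -------------------------------------------------------
  months_fruiting <- rowSums(fap_mat > 0)
  mean_boost <- vapply(seq_along(taxa), function(i) {
    j <- fap_mat[i, ] > 0
    if (!any(j)) return(NA_real_)
    mean(boost[i, j])
  }, numeric(1))
  pref_truth <- lapply(cf$preference, function(w) {
    eff <- w[taxa] * mean_boost
    tibble::tibble(taxon = taxa, weight = as.numeric(w[taxa]),
                   effective_weight = as.numeric(eff),
                   true_rank = rank(-eff, ties.method = "first"))
  })
  sel_truth <- lapply(cf$true_w_prime, function(w) {
    tibble::tibble(
      habitat = HABITAT_CODES,
      true_w_prime = as.numeric(w[HABITAT_CODES]),
      true_class = dplyr::case_when(
        w[HABITAT_CODES] > 1 ~ "preferred",
        w[HABITAT_CODES] < 1 ~ "avoided",
        TRUE ~ "proportional"
      )
    )
  })
  truth <- structure(list(
    preference = pref_truth,
    fallback_taxa = taxa[cf$fallback_taxa],
    selection = sel_truth,
    config = cf,
    seed = seed
  ), class = "ground_truth")

  list(dataset = dataset, truth = truth)
}

#' Tiny hand-computable toy dataset
#'
#' A two-taxon, two-habitat, four-month dataset small enough that every score
#' in the pipeline (stem density, FAP, fruit quantity, MCS, GIS) can be
#' verified by hand arithmetic. The expected values — written out as explicit
#' arithmetic on the input numbers, independent of the package's code paths —
#' are returned alongside the dataset.
#'
#' Layout: taxa A (20 g fruits, 5 seeds each) and B (10 g, 2 seeds); four
#' 625-m^2 plots holding 10 stems of A and 2 of B; two phenology individuals
#' of A (DBH 30 and 40 cm) and one of B (DBH 20 cm) scored in months 1, 4, 7
#' and 9 (one month per season); gorilla and chimpanzee fecal samples with
#' seed counts chosen to exercise every branch of the fruit-count rule.
#'
#' @return A list with `dataset` (a [survey_dataset()]) and `expected` (named
#'   list of hand-computed D, FAP, QF, MCS and GIS values).
#' @export
make_toy_fixture <- function() {
  months <- c(1L, 4L, 7L, 9L)
  availability <- tibble::tibble(
    transect_id = "t1",
    position_m = (seq_len(120) - 1) * 50,
    habitat = rep(c("MF", "SW", "YSF", "RF"), c(60, 30, 18, 12))
  )
  taxa <- tibble::tibble(
    taxon = c("A", "B"),
    family = c("fam1", "fam2"),
    mean_fruit_weight_g = c(20, 10),
    mean_seeds_per_fruit = c(5, 2)
  )
  plots <- tibble::tibble(
    plot_id = rep(c("p1", "p2", "p3", "p4"), each = 2),
    habitat = rep(c("MF", "MF", "SW", "SW"), each = 2),
    taxon = rep(c("A", "B"), 4),
    stems = c(4, 0, 3, 1, 2, 1, 1, 0)
  )
  phen_scores <- tibble::tribble(
    ~individual_id, ~month, ~ss,
    "A_1", 1L, c(1, 1, 1, 1),
    "A_1", 4L, c(2, 2, 2, 2),
    "A_1", 7L, c(0, 0, 0, 0),
    "A_1", 9L, c(0, 0, 0, 0),
    "A_2", 1L, c(1, 1, 0, 0),
    "A_2", 4L, c(0, 0, 0, 0),
    "A_2", 7L, c(0, 0, 0, 0),
    "A_2", 9L, c(2, 2, 0, 0),
    "B_1", 1L, c(0, 0, 0, 0),
    "B_1", 4L, c(1, 1, 0, 0),
    "B_1", 7L, c(2, 2, 1, 1),
    "B_1", 9L, c(0, 0, 0, 0)
  )
  phenology <- phen_scores |>
    dplyr::mutate(
      taxon = substr(.data$individual_id, 1, 1),
      dbh_cm = c(A_1 = 30, A_2 = 40, B_1 = 20)[.data$individual_id],
      score_unripe_tree = purrr::map_dbl(.data$ss, 1),
      score_ripe_tree = purrr::map_dbl(.data$ss, 2),
      score_unripe_ground = purrr::map_dbl(.data$ss, 3),
      score_ripe_ground = purrr::map_dbl(.data$ss, 4)
    ) |>
    dplyr::select(-"ss")
  fecal <- tibble::tribble(
    ~sample_id, ~ape, ~month, ~taxon, ~seeds,
    "g1", "gorilla", 1L, "A", 12L,
    "g2", "gorilla", 1L, "A", 3L,
    "g2", "gorilla", 1L, "B", 1L,
    "g3", "gorilla", 1L, "A", 5L,
    "g4", "gorilla", 1L, "B", 4L,
    "g5", "gorilla", 4L, "A", 10L,
    "g6", "gorilla", 4L, "A", 0L,
    "g7", "gorilla", 7L, "B", 2L,
    "g8", "gorilla", 7L, "B", 6L,
    "g9", "gorilla", 9L, "A", 5L,
    "c1", "chimpanzee", 1L, "A", 5L,
    "c2", "chimpanzee", 1L, "A", 12L,
    "c3", "chimpanzee", 4L, "A", 7L,
    "c4", "chimpanzee", 7L, "B", 4L,
    "c5", "chimpanzee", 9L, "A", 2L
  )
  nests <- tibble::tribble(
    ~ape, ~month, ~habitat, ~group_id,
    "gorilla", 1L, "SW", "n1",
    "gorilla", 1L, "SW", "n2",
    "gorilla", 4L, "MF", "n3",
    "chimpanzee", 1L, "MF", "n4",
    "chimpanzee", 4L, "MF", "n5",
    "chimpanzee", 7L, "SW", "n6"
  )
  dataset <- survey_dataset(availability, nests, fecal, phenology, plots,
                            taxa, plot_area = 625)

  # hand arithmetic (independent of the package code paths) ---------------
  b_a1 <- pi * (30 / 200)^2
  b_a2 <- pi * (40 / 200)^2
  b_b1 <- pi * (20 / 200)^2
  d_a <- 10 / (4 * 625)
  d_b <- 2 / (4 * 625)
  fap_a <- c(`1` = (4 * b_a1 + 2 * b_a2) / 2 * d_a,
             `4` = (8 * b_a1 + 0) / 2 * d_a,
             `7` = 0,
             `9` = (0 + 4 * b_a2) / 2 * d_a)
  fap_b <- c(`1` = 0, `4` = 2 * b_b1 * d_b, `7` = 6 * b_b1 * d_b, `9` = 0)
  # gorilla QF per month (fruit-count rule applied by hand)
  qf_a <- c(`1` = (3 + 1 + 1) * 20, `4` = 2 * 20, `7` = 0, `9` = 1 * 20)
  qf_b <- c(`1` = (1 + 2) * 10, `4` = 0, `7` = (1 + 3) * 10, `9` = 0)
  mcs_a <- c(`1` = qf_a[["1"]] / (qf_a[["1"]] + qf_b[["1"]]) * 3 / 4,
             `4` = 1 * 1 / 2, `7` = 0, `9` = 1 * 1 / 1)
  mcs_b <- c(`1` = qf_b[["1"]] / (qf_a[["1"]] + qf_b[["1"]]) * 2 / 4,
             `4` = 0, `7` = 1 * 2 / 2, `9` = 0)
  gis_a <- (mcs_a[["1"]] / fap_a[["1"]] + mcs_a[["4"]] / fap_a[["4"]] +
              mcs_a[["9"]] / fap_a[["9"]]) / 4 * (3 / 3)
  # B consumed in months 1 and 7 but fruiting only in 4 and 7: the month-1
  # ratio is excluded while Pe counts both consumption months
  gis_b <- (mcs_b[["7"]] / fap_b[["7"]]) / 4 * (2 / 2)

  expected <- list(
    d = c(A = d_a, B = d_b),
    fap_a = fap_a, fap_b = fap_b,
    qf_gorilla_a = qf_a, qf_gorilla_b = qf_b,
    mcs_gorilla_a = mcs_a, mcs_gorilla_b = mcs_b,
    gis_gorilla = c(A = gis_a, B = gis_b),
    availability_p = c(MF = 0.50, SW = 0.25, YSF = 0.15, RF = 0.10, LG = 0)
  )
  list(dataset = dataset, expected = expected)
}
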