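#' Stem density of each taxon across botanical plots
#'
#' Density of a fruiting taxon over the inventoried area:
#' \deqn{D_i = \frac{\sum_k n_{ik}}{K \, S}}
#' where n_ik is the number of stems of taxon i in plot k, K the total number
#' of plots inventoried (including plots where the taxon is absent) and S the
#' area of each plot in square metres (default 625 m^2, a 25 x 25 m plot).
#'
#' @param plots Long-format plot table (`plot_id`, `habitat`, `taxon`,
#'   `stems`), e.g. the `plots` table of a [survey_dataset()].
#' @param plot_area Plot area S in m^2 (default 625).
#' @param n_plots Total number of plots K. Defaults to the number of distinct
#'   `plot_id` values; supply explicitly when plots with no recorded stems are
#'   omitted from the long table.
#' @return A tibble `taxon`, `stems`, `K`, `S`, `D` (stems per m^2).
#' @examples
#' plots <- data.frame(plot_id = c(1, 2, 3, 4), habitat = "MF",
#'                     taxon = "A", stems = c(4, 3, 2, 1))
#' stem_density(plots) # D = 10 / (4 * 625) = 0.004
#' @export
stem_density <- function(plots, plot_area = 625, n_plots = NULL) {
  plots <- check_schema(plots, "plots", c("plot_id", "habitat", "taxon", "stems"))
  if (plot_area <= 0) stop("plot_area must be > 0", call. = FALSE)
  K <- n_plots %||% dplyr::n_distinct(plots$plot_id)
  if (K < 1) stop("at least one plot is required", call. = FALSE)
  plots |>
    dplyr::summarise(stems = sum(.data$stems), .by = "taxon") |>
    dplyr::mutate(K = K, S = plot_area,
                  D = .data$stems / (K * plot_area)) |>
    dplyr::arrange(.data$taxon)
}

#' Basal area from diameter at breast height
#'
#' Cross-sectional area of a stem in square metres from its DBH in
#' centimetres: B = pi (dbh / 200)^2.
#'
#' @param dbh_cm Diameter(s) at breast height in cm; must be positive.
#' @return Basal area(s) in m^2.
#' @examples
#' basal_area(10) # 0.007854 m^2
#' @export
basal_area <- function(dbh_cm) {
  if (any(dbh_cm <= 0)) stop("DBH must be positive", call. = FALSE)
  pi * (dbh_cm / 200)^2
}

#' Monthly Fruit Availability Potential (FAP)
#'
#' Availability index per taxon and month, combining the phenology fruiting
#' score, the size of the monitored individuals, and stand density:
#' \deqn{FAP_{ij} = \frac{\sum_n SS_{nij} B_{nij}}{N_i} \, D_i}
#' where SS_nij is the summed fruiting score of monitored individual n of
#' taxon i in month j, B_nij its basal area (m^2), N_i the number of
#' monitored individuals of taxon i, and D_i the stem density from
#' [stem_density()]. By default SS pools all four 0-2 scores (unripe/ripe on
#' tree and on ground; range 0-8); `ripe_only = TRUE` restricts SS to the two
#' ripe-fruit scores. Individuals not observed in a month contribute a score
#' of zero but still count in N_i. Taxa monitored in phenology but absent
#' from the plots have D_i = 0 and hence FAP 0; taxa never monitored are not
#' in the output at all (they are unclassifiable for availability).
#'
#' @param phenology Phenology table (see [survey_dataset()]).
#' @param density Output of [stem_density()] (or any tibble `taxon`, `D`).
#' @param months Months to evaluate (default 1:12).
#' @param ripe_only Use only the two ripe-fruit scores in SS (default FALSE).
#' @return A tibble `taxon`, `month`, `fap` covering every monitored taxon
#'   and every requested month.
#' @export
fap_table <- function(phenology, density, months = 1:12, ripe_only = FALSE) {
  phenology <- check_schema(
    phenology, "phenology",
    c("individual_id", "taxon", "month", "dbh_cm", "score_unripe_tree",
      "score_ripe_tree", "score_unripe_ground", "score_ripe_ground"))
  score_cols <- if (ripe_only) {
    c("score_ripe_tree", "score_ripe_ground")
  } else {
    c("score_unripe_tree", "score_ripe_tree", "score_unripe_ground",
      "score_ripe_ground")
  }
  n_ind <- phenology |>
    dplyr::summarise(N = dplyr::n_distinct(.data$individual_id),
                     .by = "taxon")
  obs <- phenology |>
    dplyr::mutate(ss = rowSums(dplyr::pick(dplyr::all_of(score_cols))),
                  b = basal_area(.data$dbh_cm)) |>
    dplyr::summarise(sum_ssb = sum(.data$ss * .data$b),
                     .by = c("taxon", "month")) |>
    dplyr::filter(.data$month %in% .env$months)
  tidyr::expand_grid(taxon = sort(unique(phenology$taxon)),
                     month = as.integer(months)) |>
    dplyr::left_join(obs, by = c("taxon", "month")) |>
    dplyr::left_join(n_ind, by = "taxon") |>
    dplyr::left_join(density[, c("taxon", "D")], by = "taxon") |>
    dplyr::mutate(
      sum_ssb = tidyr::replace_na(.data$sum_ssb, 0),
      D = tidyr::replace_na(.data$D, 0),
      fap = .data$sum_ssb / .data$N * .data$D
    ) |>
    dplyr::select("taxon", "month", "fap")
}

#' Reconstruct fruit quantity from seed counts
#'
#' Converts the seed count of one taxon in one fecal sample into an estimated
#' fruit mass in grams. The number of fruits is 0 when no seeds are present;
#' 1 when the count is below the taxon's mean seeds per fruit; otherwise the
#' seed count divided by the mean seeds per fruit, rounded up to the next
#' whole fruit. The mass is fruits times the taxon's mean fruit weight. For
#' taxa whose seeds cannot be counted individually (figs), a calibrated
#' seeds-per-fruit value takes the place of the empirical mean.
#'
#' @param seeds Seed count(s) in a sample (non-negative integers).
#' @param mean_seeds Mean (or calibrated) seeds per fruit (>= 1).
#' @param mean_weight Mean fruit weight in grams (> 0).
#' @return Estimated fruit mass in grams (vectorised).
#' @examples
#' fruit_quantity(12, mean_seeds = 5, mean_weight = 20) # ceil(2.4)=3 -> 60 g
#' fruit_quantity(3, mean_seeds = 5, mean_weight = 20)  # 1 fruit -> 20 g
#' @export
fruit_quantity <- function(seeds, mean_seeds, mean_weight) {
  if (any(seeds < 0)) stop("seed counts must be non-negative", call. = FALSE)
  if (any(is.na(mean_seeds) | is.na(mean_weight))) {
    stop("taxon lacks mean seeds per fruit or mean fruit weight",
         call. = FALSE)
  }
  if (any(mean_seeds < 1) || any(mean_weight <= 0)) {
    stop("mean_seeds must be >= 1 and mean_weight > 0", call. = FALSE)
  }
  fruits <- ifelse(seeds == 0, 0,
                   ifelse(seeds < mean_seeds, 1, ceiling(seeds / mean_seeds)))
  fruits * mean_weight
}

#' Monthly Mean Consumption Score (MCS)
#'
#' Dietary importance of each taxon for one ape species, per month:
#' \deqn{MCS_{ij} = \frac{QF_{ij}}{\sum_i QF_{ij}} \times \frac{Pf_{ij}}{NPf_j}}
#' where QF_ij is the reconstructed fruit mass of taxon i across all fecal
#' samples of month j ([fruit_quantity()] summed over samples), Pf_ij the
#' number of that month's samples containing the taxon, and NPf_j the number
#' of samples analysed that month. MCS lies in \[0, 1\]; months with no
#' reconstructed fruit mass give MCS = 0 for all taxa. Taxa without fruit
#' trait values cannot enter the mass reconstruction: they are dropped from
#' the table with a warning (flagged, never silently).
#'
#' @param fecal Long fecal table (`sample_id`, `ape`, `month`, `taxon`,
#'   `seeds`).
#' @param taxa Fruit trait table (`taxon`, `mean_fruit_weight_g`,
#'   `mean_seeds_per_fruit`).
#' @param ape `"gorilla"` or `"chimpanzee"`.
#' @param months Months to evaluate (default 1:12).
#' @return A tibble `taxon`, `month`, `qf` (g), `pf`, `npf`, `mcs` covering
#'   every consumed (trait-complete) taxon and every requested month that has
#'   samples.
#' @export
mcs_table <- function(fecal, taxa, ape, months = 1:12) {
  fecal <- check_schema(fecal, "fecal",
                        c("sample_id", "ape", "month", "taxon", "seeds"))
  taxa <- check_schema(taxa, "taxa",
                       c("taxon", "family", "mean_fruit_weight_g",
                         "mean_seeds_per_fruit"))
  if (!ape %in% APE_CODES) stop("unknown ape label: ", ape, call. = FALSE)
  fec <- fecal |>
    dplyr::filter(.data$ape == .env$ape, .data$month %in% .env$months)
  if (nrow(fec) == 0L) {
    return(tibble::tibble(taxon = character(), month = integer(),
                          qf = numeric(), pf = integer(), npf = integer(),
                          mcs = numeric()))
  }
  traits <- taxa |>
    dplyr::filter(!is.na(.data$mean_fruit_weight_g),
                  !is.na(.data$mean_seeds_per_fruit))
  no_traits <- setdiff(unique(fec$taxon), traits$taxon)
  if (length(no_traits)) {
    warning("taxa without fruit trait values excluded from MCS: ",
            paste(sort(no_traits), collapse = ", "), call. = FALSE)
  }
  npf <- fec |>
    dplyr::summarise(npf = dplyr::n_distinct(.data$sample_id), .by = "month")
  per_sample <- fec |>
    dplyr::inner_join(traits, by = "taxon") |>
    dplyr::filter(.data$seeds > 0) |>
    dplyr::mutate(qf = fruit_quantity(.data$seeds, .data$mean_seeds_per_fruit,
                                      .data$mean_fruit_weight_g))
  monthly <- per_sample |>
    dplyr::summarise(qf = sum(.data$qf),
                     pf = dplyr::n_distinct(.data$sample_id),
                     .by = c("taxon", "month"))
  tidyr::expand_grid(taxon = sort(unique(per_sample$taxon)),
                     month = sort(unique(npf$month))) |>
    dplyr::left_join(monthly, by = c("taxon", "month")) |>
    dplyr::mutate(qf = tidyr::replace_na(.data$qf, 0),
                  pf = as.integer(tidyr::replace_na(.data$pf, 0L))) |>
    dplyr::left_join(npf, by = "month") |>
    dplyr::mutate(qf_month = sum(.data$qf), .by = "month") |>
    dplyr::mutate(mcs = dplyr::if_else(
      .data$qf_month > 0,
      .data$qf / .data$qf_month * .data$pf / .data$npf,
      0)) |>
    dplyr::select("taxon", "month", "qf", "pf", "npf", "mcs")
}

#' Global Importance Score (GIS) and preference ranking
#'
#' Consumption relative to availability for each taxon:
#' \deqn{GIS_i = \frac{\sum_j MCS_{ij} / FAP_{ij}}{J} \times Pe_i}
#' where the sum runs over the months in which the taxon bore fruit
#' (FAP_ij > 0), J is the number of study months, and Pe_i is the proportion
#' of months the taxon was consumed relative to the number of months it bore
#' fruit. Months with consumption but FAP = 0 are excluded from the sum while
#' the Pe denominator stays the number of fruiting months, so Pe can exceed 1
#' (such taxa are flagged in `pe_gt_1`). Taxa never monitored in phenology
#' (or never fruiting, so that no month has FAP > 0) cannot be scored and are
#' returned with status `"UC"` (unclassified); consumed-but-unmonitored taxa
#' present in `mcs` but absent from `fap` are appended as UC rows. Taxa never
#' consumed get GIS = 0 and rank below all consumed taxa.
#'
#' Ranking is by descending GIS among classified taxa (ties broken
#' alphabetically for determinism); UC taxa carry rank `NA`. `gis_display`
#' shows values below 0.001 as 0, as in field reporting, while ranking always
#' uses the underlying value.
#'
#' @param mcs Output of [mcs_table()] for one ape.
#' @param fap Output of [fap_table()].
#' @param J Number of study months (default 12).
#' @return A tibble `taxon`, `gis`, `gis_display`, `pe`, `months_fruiting`,
#'   `months_consumed`, `pe_gt_1`, `status`, `rank`, sorted by rank.
#' @export
gis_table <- function(mcs, fap, J = 12) {
  if (J < 1) stop("J must be >= 1", call. = FALSE)
  joined <- fap |>
    dplyr::left_join(mcs[, c("taxon", "month", "mcs")],
                     by = c("taxon", "month")) |>
    dplyr::mutate(mcs = tidyr::replace_na(.data$mcs, 0))
  per_taxon <- joined |>
    dplyr::summarise(
      months_fruiting = sum(.data$fap > 0),
      ratio_sum = sum(ifelse(.data$fap > 0, .data$mcs / .data$fap, 0)),
      months_consumed = sum(.data$mcs > 0),
      .by = "taxon"
    )
  # consumption months are counted over the whole study, including months the
  # taxon was consumed while not fruiting, so Pe is deliberately unclamped
  extra_consumed <- mcs |>
    dplyr::filter(.data$mcs > 0) |>
    dplyr::summarise(months_consumed_all = dplyr::n_distinct(.data$month),
                     .by = "taxon")
  scored <- per_taxon |>
    dplyr::left_join(extra_consumed, by = "taxon") |>
    dplyr::mutate(
      months_consumed = pmax(.data$months_consumed,
                             tidyr::replace_na(.data$months_consumed_all, 0L)),
      status = dplyr::if_else(.data$months_fruiting > 0, "classified", "UC"),
      pe = dplyr::if_else(.data$months_fruiting > 0,
                          .data$months_consumed / .data$months_fruiting,
                          NA_real_),
      gis = dplyr::if_else(.data$status == "classified",
                           .data$ratio_sum / J * .data$pe, NA_real_),
      pe_gt_1 = !is.na(.data$pe) & .data$pe > 1
    ) |>
    dplyr::select(-"months_consumed_all", -"ratio_sum")
  consumed_unmonitored <- setdiff(unique(mcs$taxon[mcs$mcs > 0]), fap$taxon)
  if (length(consumed_unmonitored)) {
    scored <- dplyr::bind_rows(
      scored,
      tibble::tibble(taxon = sort(consumed_unmonitored),
                     months_fruiting = 0L, months_consumed = NA_integer_,
                     status = "UC", pe = NA_real_, gis = NA_real_,
                     pe_gt_1 = FALSE))
  }
  rank_preference(scored)
}

#' Rank taxa by Global Importance Score
#'
#' Orders classified taxa by descending GIS (rank 1 = most preferred), with
#' alphabetical tie-breaking; unclassified (UC) taxa are listed last without
#' a rank.
#'
#' @param gis_tbl A tibble with at least `taxon`, `gis`, `status` columns.
#' @return The same tibble with `rank` and `gis_display` columns, sorted.
#' @export
rank_preference <- function(gis_tbl) {
  classified <- gis_tbl |>
    dplyr::filter(.data$status == "classified") |>
    dplyr::arrange(dplyr::desc(.data$gis), .data$taxon) |>
    dplyr::mutate(rank = dplyr::row_number())
  uc <- gis_tbl |>
    dplyr::filter(.data$status != "classified") |>
    dplyr::arrange(.data$taxon) |>
    dplyr::mutate(rank = NA_integer_)
  dplyr::bind_rows(classified, uc) |>
    dplyr::mutate(gis_display = dplyr::if_else(
      !is.na(.data$gis) & .data$gis < 0.001, 0, .data$gis)) |>
    dplyr::relocate("taxon", "gis", "gis_display", "rank", "pe", "status")
}

#' Full diet scoring stack for a survey dataset
#'
#' Runs the whole scoring pipeline on a [survey_dataset()]: stem density per
#' taxon, the monthly FAP table, and per ape the monthly MCS table and the
#' GIS ranking.
#'
#' @param dataset A [survey_dataset()].
#' @param J Number of study months (default 12).
#' @param months Months analysed (default 1:12).
#' @param ripe_only Restrict phenology scores to ripe fruit (default FALSE).
#' @return An object of class `diet_scores`: a list with `density`, `fap`,
#'   and per-ape `mcs` and `gis` tibbles.
#' @export
diet_scores <- function(dataset, J = 12, months = 1:12, ripe_only = FALSE) {
  stopifnot(inherits(dataset, "survey_dataset"))
  density <- stem_density(dataset$plots, plot_area = dataset$plot_area)
  fap <- fap_table(dataset$phenology, density, months = months,
                   ripe_only = ripe_only)
  mcs <- lapply(stats::setNames(APE_CODES, APE_CODES), function(a) {
    mcs_table(dataset$fecal, dataset$taxa, a, months = months)
  })
  gis <- lapply(mcs, gis_table, fap = fap, J = J)
  structure(list(density = density, fap = fap, mcs = mcs, gis = gis,
                 J = J, months = months, ripe_only = ripe_only),
            class = "diet_scores")
}

#' @export
print.diet_scores <- function(x, ...) {
  cat("<diet_scores>\n")
  cat(sprintf("  %d taxa in plots; FAP over %d taxa x %d months\n",
              nrow(x$density), dplyr::n_distinct(x$fap$taxon),
              dplyr::n_distinct(x$fap$month)))
  for (a in names(x$gis)) {
    top <- x$gis[[a]] |> dplyr::filter(!is.na(.data$rank)) |> head(3)
    cat(sprintf("  %s: top taxa %s\n", a,
                paste(top$taxon, collapse = ", ")))
  }
  invisible(x)
}
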