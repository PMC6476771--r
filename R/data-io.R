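#' Assemble a validated survey dataset
#'
#' Binds the six field tables of the study design — habitat availability
#' survey points, fresh nest records, fecal seed counts, monthly phenology,
#' botanical plot inventories and the fruit trait table — into one validated
#' bundle, together with the month-to-season calendar. All cross-references
#' are checked at construction: every taxon appearing in the fecal, phenology
#' or plot tables must have a row in `taxa`, otherwise it is flagged
#' unclassifiable (never silently dropped). An optional alias table collapses
#' raw field names onto aggregate taxa (e.g. congeners pooled to genus).
#'
#' @param availability Data frame: `transect_id`, `position_m`, `habitat`.
#'   One row per 50-m survey station.
#' @param nests Data frame: `ape`, `month`, `habitat`, `group_id`. One row per
#'   fresh nest.
#' @param fecal Data frame (long): `sample_id`, `ape`, `month`, `taxon`,
#'   `seeds`. One row per taxon per fecal sample.
#' @param phenology Data frame: `individual_id`, `taxon`, `month`, `dbh_cm`,
#'   `score_unripe_tree`, `score_ripe_tree`, `score_unripe_ground`,
#'   `score_ripe_ground`. Scores are 0 = none, 1 = few, 2 = many.
#' @param plots Data frame (long): `plot_id`, `habitat`, `taxon`, `stems`.
#'   Light gaps (`LG`) are never inventoried and may not appear here.
#' @param taxa Data frame: `taxon`, `family`, `mean_fruit_weight_g`,
#'   `mean_seeds_per_fruit`. The seeds-per-fruit value may be a calibrated
#'   figure for taxa whose seeds cannot be counted directly (figs). Either
#'   trait may be `NA`, in which case the taxon cannot enter the fruit
#'   quantity reconstruction.
#' @param calendar A [season_calendar()].
#' @param aliases Optional data frame `raw_name`, `taxon` applied to the
#'   taxon column of `fecal`, `phenology` and `plots` before validation.
#' @param plot_area Area of each botanical plot in square metres (default 625,
#'   a 25 x 25 m plot).
#'
#' @return A `survey_dataset`: a list with the six tables (as tibbles), the
#'   calendar, `plot_area`, and `unclassifiable` — the sorted character vector
#'   of taxa referenced by any table but absent from `taxa`.
#' @seealso [load_dataset()], [write_dataset()], [generate_dataset()]
#' @export
survey_dataset <- function(availability, nests, fecal, phenology, plots, taxa,
                           calendar = season_calendar(), aliases = NULL,
                           plot_area = 625) {
  availability <- check_schema(availability, "availability",
                               c("transect_id", "position_m", "habitat"))
  nests <- check_schema(nests, "nests", c("ape", "month", "habitat", "group_id"))
  fecal <- check_schema(fecal, "fecal",
                        c("sample_id", "ape", "month", "taxon", "seeds"))
  phenology <- check_schema(
    phenology, "phenology",
    c("individual_id", "taxon", "month", "dbh_cm", "score_unripe_tree",
      "score_ripe_tree", "score_unripe_ground", "score_ripe_ground"))
  plots <- check_schema(plots, "plots", c("plot_id", "habitat", "taxon", "stems"))
  taxa <- check_schema(taxa, "taxa",
                       c("taxon", "family", "mean_fruit_weight_g",
                         "mean_seeds_per_fruit"))

  if (!is.null(aliases)) {
    aliases <- check_schema(aliases, "aliases", c("raw_name", "taxon"))
    fecal$taxon <- apply_aliases(fecal$taxon, aliases)
    phenology$taxon <- apply_aliases(phenology$taxon, aliases)
    plots$taxon <- apply_aliases(plots$taxon, aliases)
    # aliasing can split one sample's taxon across rows; re-aggregate counts
    fecal <- fecal |>
      dplyr::summarise(seeds = sum(.data$seeds),
                       .by = c("sample_id", "ape", "month", "taxon"))
    plots <- plots |>
      dplyr::summarise(stems = sum(.data$stems),
                       .by = c("plot_id", "habitat", "taxon"))
  }

  check_habitat(availability$habitat, "availability")
  check_habitat(nests$habitat, "nests")
  check_habitat(plots$habitat, "plots")
  if (any(plots$habitat == "LG")) {
    stop("validation error: botanical plots may not be located in LG",
         call. = FALSE)
  }
  check_month(nests$month, "nests")
  check_month(fecal$month, "fecal")
  check_month(phenology$month, "phenology")
  check_ape(nests$ape, "nests")
  check_ape(fecal$ape, "fecal")
  check_nonneg(fecal$seeds, "fecal$seeds")
  check_nonneg(plots$stems, "plots$stems")
  check_nonneg(availability$position_m, "availability$position_m")
  if (any(phenology$dbh_cm <= 0)) {
    stop("validation error: phenology$dbh_cm must be > 0", call. = FALSE)
  }
  scores <- as.matrix(phenology[, c("score_unripe_tree", "score_ripe_tree",
                                    "score_unripe_ground", "score_ripe_ground")])
  if (any(!scores %in% 0:2)) {
    stop("validation error: phenology scores must be 0, 1 or 2", call. = FALSE)
  }
  if (!is.numeric(plot_area) || length(plot_area) != 1L || plot_area <= 0) {
    stop("validation error: plot_area must be a single positive number",
         call. = FALSE)
  }
  if (anyDuplicated(taxa$taxon)) {
    stop("validation error: duplicated taxon in taxa table", call. = FALSE)
  }
  with_traits <- !is.na(taxa$mean_fruit_weight_g) & !is.na(taxa$mean_seeds_per_fruit)
  if (any(taxa$mean_fruit_weight_g[with_traits] <= 0) ||
      any(taxa$mean_seeds_per_fruit[with_traits] < 1)) {
    stop("validation error: fruit weight must be > 0 and seeds per fruit >= 1",
         call. = FALSE)
  }

  referenced <- unique(c(fecal$taxon, phenology$taxon, plots$taxon))
  unclassifiable <- sort(setdiff(referenced, taxa$taxon))

  structure(
    list(
      availability = tibble::as_tibble(availability),
      nests = tibble::as_tibble(nests),
      fecal = tibble::as_tibble(fecal),
      phenology = tibble::as_tibble(phenology),
      plots = tibble::as_tibble(plots),
      taxa = tibble::as_tibble(taxa),
      calendar = calendar,
      plot_area = plot_area,
      unclassifiable = unclassifiable
    ),
    class = "survey_dataset"
  )
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset>\n")
  cat(sprintf("  availability: %d points; nests: %d; fecal rows: %d (%d samples)\n",
              nrow(x$availability), nrow(x$nests), nrow(x$fecal),
              dplyr::n_distinct(x$fecal$sample_id)))
  cat(sprintf("  phenology rows: %d; plots: %d (%d plot ids); taxa: %d\n",
              nrow(x$phenology), nrow(x$plots),
              dplyr::n_distinct(x$plots$plot_id), nrow(x$taxa)))
  if (length(x$unclassifiable)) {
    cat("  unclassifiable taxa:", paste(x$unclassifiable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a survey dataset from CSV files
#'
#' Reads the six study tables from disk and validates them with
#' [survey_dataset()]. `paths` is either a directory containing the canonical
#' file names (`availability.csv`, `nests.csv`, `fecal.csv`, `phenology.csv`,
#' `plots.csv`, `taxa.csv`, optional `aliases.csv`) or a named list of file
#' paths using those table names.
#'
#' @param paths Directory or named list of CSV paths.
#' @inheritParams survey_dataset
#' @return A `survey_dataset`.
#' @export
load_dataset <- function(paths, calendar = season_calendar(), plot_area = 625) {
  tables <- c("availability", "nests", "fecal", "phenology", "plots", "taxa")
  if (is.character(paths) && length(paths) == 1L) {
    dir <- paths
    paths <- stats::setNames(file.path(dir, paste0(tables, ".csv")), tables)
    alias_path <- file.path(dir, "aliases.csv")
    if (file.exists(alias_path)) paths <- c(paths, aliases = alias_path)
    paths <- as.list(paths)
  }
  missing <- setdiff(tables, names(paths))
  if (length(missing)) {
    stop("missing table path(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (p in unlist(paths)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  read1 <- function(p) readr::read_csv(p, show_col_types = FALSE,
                                       progress = FALSE)
  aliases <- if (!is.null(paths$aliases)) read1(paths$aliases) else NULL
  survey_dataset(
    availability = read1(paths$availability),
    nests = read1(paths$nests),
    fecal = read1(paths$fecal),
    phenology = read1(paths$phenology),
    plots = read1(paths$plots),
    taxa = read1(paths$taxa),
    calendar = calendar,
    aliases = aliases,
    plot_area = plot_area
  )
}

#' Write a survey dataset to CSV files
#'
#' Writes the six tables of a `survey_dataset` into a directory under the
#' canonical file names read by [load_dataset()]. Writing then reloading a
#' dataset reproduces it exactly.
#'
#' @param dataset A `survey_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in c("availability", "nests", "fecal", "phenology", "plots", "taxa")) {
    readr::write_csv(dataset[[tab]], file.path(dir, paste0(tab, ".csv")),
                     progress = FALSE)
  }
  invisible(dir)
}

# ---- internal validators -----------------------------------------------

check_schema <- function(df, table, cols) {
  if (!is.data.frame(df)) {
    stop(sprintf("schema error: `%s` must be a data frame", table),
         call. = FALSE)
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("schema error in `%s`: missing column(s) %s", table,
                 paste0("`", missing, "`", collapse = ", ")), call. = FALSE)
  }
  tibble::as_tibble(df[cols])
}

check_habitat <- function(x, table) {
  bad <- setdiff(unique(x), HABITAT_CODES)
  if (length(bad)) {
    stop(sprintf("validation error in `%s`: unknown habitat code(s) %s", table,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
}

check_month <- function(x, table) {
  if (any(is.na(x)) || any(x < 1 | x > 12) || any(x != as.integer(x))) {
    stop(sprintf("validation error in `%s`: month must be an integer in 1-12",
                 table), call. = FALSE)
  }
}

check_ape <- function(x, table) {
  bad <- setdiff(unique(x), APE_CODES)
  if (length(bad)) {
    stop(sprintf("validation error in `%s`: unknown ape label(s) %s", table,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
}

check_nonneg <- function(x, what) {
  if (any(is.na(x)) || any(x < 0)) {
    stop(sprintf("validation error: %s must be non-negative", what),
         call. = FALSE)
  }
}

apply_aliases <- function(x, aliases) {
  idx <- match(x, aliases$raw_name)
  ifelse(is.na(idx), x, aliases$taxon[idx])
}
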