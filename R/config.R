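#' Run the pipeline from a YAML configuration file
#'
#' A run configuration collects everything needed for a reproducible analysis
#' in one YAML file:
#'
#' ```yaml
#' input_dir: data/          # directory with the six CSV tables
#' output_dir: results/      # where report CSVs are written
#' alpha: 0.05
#' J: 12
#' months: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12]
#' mcs_floor: 0.001
#' permutations: 999
#' seed: 1
#' ripe_only: false
#' plot_area: 625
#' calendar:                 # optional; default used when absent
#'   LDS: [11, 12, 1, 2]
#'   LRS: [3, 4, 5, 6]
#'   SDS: [7, 8]
#'   SRS: [9, 10]
#' ```
#'
#' `run_from_config()` loads the dataset, executes [run_all()] and writes the
#' report tables to `output_dir`.
#'
#' @param path Path to the YAML configuration.
#' @return `read_run_config()` returns the validated configuration list;
#'   `run_from_config()` returns the [run_all()] result invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  defaults <- list(alpha = 0.05, J = 12, months = 1:12, mcs_floor = 0.001,
                   permutations = 999, seed = 1, ripe_only = FALSE,
                   plot_area = 625, output_dir = "results")
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  if (is.null(cfg$input_dir)) {
    stop("config must name `input_dir`", call. = FALSE)
  }
  cfg$calendar <- if (is.null(cfg$calendar)) {
    season_calendar()
  } else {
    season_calendar(lds = as.integer(cfg$calendar$LDS),
                    lrs = as.integer(cfg$calendar$LRS),
                    sds = as.integer(cfg$calendar$SDS),
                    srs = as.integer(cfg$calendar$SRS))
  }
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$J >= 1, cfg$permutations >= 1,
            cfg$mcs_floor >= 0, cfg$plot_area > 0)
  cfg
}

#' @rdname read_run_config
#' @export
run_from_config <- function(path) {
  cfg <- read_run_config(path)
  dataset <- load_dataset(cfg$input_dir, calendar = cfg$calendar,
                          plot_area = cfg$plot_area)
  run <- run_all(dataset, alpha = cfg$alpha, J = cfg$J,
                 months = as.integer(cfg$months), mcs_floor = cfg$mcs_floor,
                 n_perm = cfg$permutations, seed = cfg$seed,
                 ripe_only = cfg$ripe_only)
  write_results(run, cfg$output_dir)
  invisible(run)
}

#' Write generator ground truth as JSON
#'
#' Serialises the `truth` component of [generate_dataset()] (true preference
#' ranks, designed fallback taxa, true habitat selection classes, and the
#' generating configuration's scalar settings) next to a written dataset, so
#' a simulated study is fully self-describing on disk.
#'
#' @param truth A `ground_truth` object.
#' @param path Output file path (e.g. `"data/ground_truth.json"`).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  cf <- truth$config
  out <- list(
    seed = truth$seed,
    fallback_taxa = truth$fallback_taxa,
    preference = truth$preference,
    selection = truth$selection,
    config = list(
      n_taxa = cf$n_taxa, months = cf$months,
      availability = as.list(cf$availability),
      true_w_prime = lapply(cf$true_w_prime, as.list),
      samples_per_month = cf$samples_per_month,
      nests_per_season = cf$nests_per_season,
      fallback_boost = cf$fallback_boost,
      n_plots = cf$n_plots, plot_area = cf$plot_area
    )
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
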