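#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis on a validated dataset: seasonal
#' habitat selection per ape, the diet scoring stack (density, FAP, MCS,
#' GIS), fallback/preferred classification collapsed to consumption traits,
#' the habitat-by-trait and habitat-by-taxon correspondence analyses, and the
#' seasonal PERMANOVA plus dispersion-homogeneity tests on Bray-Curtis
#' dissimilarities of the monthly FAP and per-ape MCS profiles
#' (months as replicates, grouped by season). All exclusions (empty plots,
#' unclassifiable taxa, UC taxa) are collected in a structured log. The run
#' is deterministic for a fixed dataset and seed.
#'
#' @param dataset A [survey_dataset()], e.g. from [load_dataset()] or
#'   [generate_dataset()].
#' @param alpha Significance level for habitat selection (default 0.05).
#' @param J Number of study months for the GIS (default 12).
#' @param months Months analysed (default 1:12).
#' @param mcs_floor Minimum study-total MCS for fallback candidacy.
#' @param n_perm Permutations for PERMANOVA/dispersion tests (default 999).
#' @param seed Seed for the permutation tests (default 1).
#' @param ripe_only Restrict phenology scores to ripe fruit.
#' @return An object of class `fruitniche_run`: list with `selection` (per
#'   ape, per season), `scores` ([diet_scores()]), `traits`
#'   ([consumption_traits()]), `contingency`, `ca_traits`, `ca_taxa`,
#'   `permanova` and `dispersion` (per matrix: `fap`, `mcs_gorilla`,
#'   `mcs_chimpanzee`), and `log` (named list of exclusion counts and
#'   settings).
#' @export
run_all <- function(dataset, alpha = 0.05, J = 12, months = 1:12,
                    mcs_floor = 0.001, n_perm = 999, seed = 1,
                    ripe_only = FALSE) {
  stopifnot(inherits(dataset, "survey_dataset"))

  selection <- lapply(stats::setNames(APE_CODES, APE_CODES), function(a) {
    seasonal_selection(dataset, a, alpha = alpha)
  })
  scores <- diet_scores(dataset, J = J, months = months,
                        ripe_only = ripe_only)
  traits <- consumption_traits(scores, calendar = dataset$calendar,
                               mcs_floor = mcs_floor)

  notes <- character(0)
  try_ca <- function(ct, label) {
    tryCatch(correspondence_analysis(ct), error = function(e) {
      notes <<- c(notes, sprintf("CA (%s) skipped: %s", label,
                                 conditionMessage(e)))
      NULL
    })
  }
  contingency <- build_contingency(dataset$plots, traits, by = "trait")
  ca_traits <- try_ca(contingency, "traits")
  contingency_taxa <- build_contingency(dataset$plots, traits, by = "taxon")
  ca_taxa <- try_ca(contingency_taxa, "taxa")

  season_groups <- season_of(months, dataset$calendar)
  profile_matrix <- function(tbl, value) {
    wide <- tidyr::pivot_wider(tbl[, c("taxon", "month", value)],
                               names_from = "taxon",
                               values_from = dplyr::all_of(value),
                               values_fill = 0) |>
      dplyr::arrange(.data$month)
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$month
    m
  }
  matrices <- list(fap = profile_matrix(scores$fap, "fap"))
  for (a in APE_CODES) {
    matrices[[paste0("mcs_", a)]] <- profile_matrix(scores$mcs[[a]], "mcs")
  }
  perm <- list()
  disp <- list()
  for (nm in names(matrices)) {
    mat <- matrices[[nm]]
    grp <- season_of(as.integer(rownames(mat)), dataset$calendar)
    if (any(table(grp) < 2) || length(unique(grp)) < 2) {
      notes <- c(notes, sprintf(
        "distance tests (%s) skipped: every season needs >= 2 months", nm))
      next
    }
    d <- bray_curtis(mat)
    perm[[nm]] <- permanova(d, grp, n_perm = n_perm, seed = seed)
    disp[[nm]] <- dispersion_homogeneity(d, grp, n_perm = n_perm, seed = seed)
  }

  log <- list(
    alpha = alpha, J = J, mcs_floor = mcs_floor, n_perm = n_perm, seed = seed,
    ripe_only = ripe_only,
    unclassifiable_taxa = dataset$unclassifiable,
    n_excluded_plots = contingency$n_excluded_plots,
    n_plots_used = contingency$n_plots_used,
    uc_taxa = lapply(scores$gis, function(g) g$taxon[g$status == "UC"]),
    uc_conflicts = traits$uc_conflicts,
    season_split = traits$split,
    notes = notes
  )
  structure(list(selection = selection, scores = scores, traits = traits,
                 contingency = contingency, ca_traits = ca_traits,
                 ca_taxa = ca_taxa, permanova = perm, dispersion = disp,
                 log = log),
            class = "fruitniche_run")
}

#' @export
print.fruitniche_run <- function(x, ...) {
  cat("<fruitniche_run>\n")
  pct <- if (is.null(x$ca_traits)) NA_real_ else
    sum(x$ca_traits$percent_inertia[seq_len(min(2, length(x$ca_traits$percent_inertia)))])
  cat(sprintf("  %d empty plots excluded; trait CA axes 1-2: %.2f%%\n",
              x$log$n_excluded_plots, pct))
  for (nm in names(x$permanova)) {
    cat(sprintf("  PERMANOVA %s: F = %.3f, p = %.4g; dispersion p = %.4g\n",
                nm, x$permanova[[nm]]$pseudo_F, x$permanova[[nm]]$p_value,
                x$dispersion[[nm]]$p_value))
  }
  invisible(x)
}

#' Write pipeline results to CSV files
#'
#' Emits the report tables of a [run_all()] result into a directory:
#' `selection_<ape>.csv` (per season, per habitat selectivity with the global
#' chi-squared row values), `density.csv`, `fap.csv`, `mcs_<ape>.csv`,
#' `gis_<ape>.csv`, `traits.csv`, `ca_traits.csv`, `ca_taxa.csv`,
#' `ca_deviations.csv`, `permanova.csv` and `run_log.csv` (settings and
#' exclusion counts).
#'
#' @param run A `fruitniche_run` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_results <- function(run, dir) {
  stopifnot(inherits(run, "fruitniche_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, name) {
    readr::write_csv(x, file.path(dir, paste0(name, ".csv")), progress = FALSE)
  }
  for (a in names(run$selection)) {
    tab <- purrr::imap_dfr(run$selection[[a]], function(res, s) {
      dplyr::mutate(tidy(res), season = s, chi2 = res$chi2, df = res$df,
                    p_value = res$p_value, .before = 1)
    })
    w(tab, paste0("selection_", a))
  }
  w(run$scores$density, "density")
  w(run$scores$fap, "fap")
  for (a in names(run$scores$mcs)) {
    w(run$scores$mcs[[a]], paste0("mcs_", a))
    w(run$scores$gis[[a]], paste0("gis_", a))
  }
  w(run$traits$table, "traits")
  if (!is.null(run$ca_traits)) {
    w(tidy(run$ca_traits), "ca_traits")
    w(tibble::as_tibble(run$ca_traits$deviations, rownames = "habitat"),
      "ca_deviations")
  }
  if (!is.null(run$ca_taxa)) w(tidy(run$ca_taxa), "ca_taxa")
  if (length(run$permanova)) {
    perm_tab <- purrr::imap_dfr(run$permanova, function(p, nm) {
      dplyr::mutate(glance(p), matrix = nm,
                    dispersion_F = run$dispersion[[nm]]$F,
                    dispersion_p = run$dispersion[[nm]]$p_value, .before = 1)
    })
    w(perm_tab, "permanova")
  }
  log_tab <- tibble::tibble(
    setting = c("alpha", "J", "mcs_floor", "n_perm", "seed", "ripe_only",
                "n_excluded_plots", "n_plots_used", "unclassifiable_taxa",
                "uc_conflicts"),
    value = c(run$log$alpha, run$log$J, run$log$mcs_floor, run$log$n_perm,
              run$log$seed, run$log$ripe_only, run$log$n_excluded_plots,
              run$log$n_plots_used,
              paste(run$log$unclassifiable_taxa, collapse = ";"),
              paste(run$log$uc_conflicts, collapse = ";"))
  )
  w(log_tab, "run_log")
  invisible(dir)
}
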