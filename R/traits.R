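#' Split the four seasons into high and low fruit availability groups
#'
#' Sums FAP over all taxa and months within each season and labels the two
#' seasons with the largest totals "high" and the two smallest "low". Ties are
#' broken by the fixed season order LDS, LRS, SDS, SRS, with a warning.
#'
#' @param fap Monthly FAP table from [fap_table()].
#' @param calendar A [season_calendar()].
#' @return A tibble `season`, `total_fap`, `group` ("high"/"low"), in fixed
#'   season order.
#' @export
season_split <- function(fap, calendar = season_calendar()) {
  totals <- fap |>
    dplyr::mutate(season = season_of(.data$month, calendar)) |>
    dplyr::summarise(total_fap = sum(.data$fap), .by = "season")
  if (!setequal(totals$season, SEASON_CODES)) {
    stop("FAP table must cover months from all four seasons", call. = FALSE)
  }
  totals <- totals |>
    dplyr::mutate(season = factor(.data$season, levels = SEASON_CODES)) |>
    dplyr::arrange(.data$season)
  if (anyDuplicated(totals$total_fap)) {
    warning("tied seasonal FAP totals; high/low split tie-broken by fixed ",
            "season order (LDS, LRS, SDS, SRS)", call. = FALSE)
  }
  ord <- order(-totals$total_fap, as.integer(totals$season))
  group <- character(4)
  group[ord[1:2]] <- "high"
  group[ord[3:4]] <- "low"
  totals |>
    dplyr::mutate(season = as.character(.data$season), group = group)
}

#' Seasonal FAP and MCS profiles per taxon
#'
#' Collapses the monthly FAP and (per-ape) MCS tables to season level by
#' summing over the months of each season, and counts in how many seasons
#' each taxon bore fruit.
#'
#' @param fap Monthly FAP table from [fap_table()].
#' @param mcs Monthly MCS table from [mcs_table()] for one ape.
#' @param calendar A [season_calendar()].
#' @return A tibble `taxon`, `season`, `fap`, `mcs`, `fruiting_seasons`.
#' @export
seasonal_profile <- function(fap, mcs, calendar = season_calendar()) {
  f <- fap |>
    dplyr::mutate(season = season_of(.data$month, calendar)) |>
    dplyr::summarise(fap = sum(.data$fap), .by = c("taxon", "season"))
  m <- mcs |>
    dplyr::mutate(season = season_of(.data$month, calendar)) |>
    dplyr::summarise(mcs = sum(.data$mcs), .by = c("taxon", "season"))
  f |>
    dplyr::left_join(m, by = c("taxon", "season")) |>
    dplyr::mutate(mcs = tidyr::replace_na(.data$mcs, 0)) |>
    dplyr::mutate(fruiting_seasons = sum(.data$fap > 0), .by = "taxon")
}

#' Identify fallback-food candidates
#'
#' A taxon is a fallback candidate for an ape when it (a) fruited in at least
#' three of the four seasons, (b) was more available (mean seasonal FAP) in
#' the two high-availability seasons than in the two low ones, yet (c) was
#' consumed more (mean seasonal MCS) in the low seasons than in the high ones
#' — consumption running against the availability trend. Taxa whose
#' study-total MCS falls below `mcs_floor` are excluded as too rarely eaten
#' to classify.
#'
#' @param profile Output of [seasonal_profile()] for one ape.
#' @param split Output of [season_split()].
#' @param mcs_floor Minimum study-total MCS for candidacy (default 0.001).
#' @return A tibble `taxon`, `fruiting_seasons`, `fap_high`, `fap_low`,
#'   `mcs_high`, `mcs_low`, `mcs_total`, `candidate`.
#' @export
fallback_candidates <- function(profile, split, mcs_floor = 0.001) {
  high <- split$season[split$group == "high"]
  profile |>
    dplyr::mutate(is_high = .data$season %in% high) |>
    dplyr::summarise(
      fruiting_seasons = .data$fruiting_seasons[1],
      fap_high = mean(.data$fap[.data$is_high]),
      fap_low = mean(.data$fap[!.data$is_high]),
      mcs_high = mean(.data$mcs[.data$is_high]),
      mcs_low = mean(.data$mcs[!.data$is_high]),
      mcs_total = sum(.data$mcs),
      .by = "taxon"
    ) |>
    dplyr::mutate(candidate = .data$fruiting_seasons >= 3 &
                    .data$fap_high > .data$fap_low &
                    .data$mcs_low > .data$mcs_high &
                    .data$mcs_total >= mcs_floor) |>
    dplyr::arrange(.data$taxon)
}

#' Assign preferred and fallback lists for one ape
#'
#' The list size target is the number of classified (GIS-scored) taxa divided
#' by three, rounded half away from zero. Fallback species are selected
#' before preferred ones: the fallback list is the candidate set (truncated
#' to the target by descending low-season MCS when over-long), and the
#' preferred list is then the top-GIS taxa not already fallback, up to the
#' target. A taxon qualifying as both is therefore assigned fallback.
#'
#' @param gis GIS table for one ape from [gis_table()].
#' @param candidates Output of [fallback_candidates()] for the same ape.
#' @return A list with `preferred` and `fallback` character vectors, the
#'   `target` list size, and `both`: taxa that qualified as both preferred
#'   and fallback (assigned fallback).
#' @export
assign_lists <- function(gis, candidates) {
  classified <- gis |> dplyr::filter(.data$status == "classified")
  n_cl <- nrow(classified)
  target <- round_half_up(n_cl / 3)
  cand <- candidates |>
    dplyr::filter(.data$candidate) |>
    dplyr::arrange(dplyr::desc(.data$mcs_low), .data$taxon)
  fallback <- head(cand$taxon, target)
  ranked <- classified |> dplyr::arrange(.data$rank)
  preferred <- head(setdiff(ranked$taxon, fallback), target)
  both <- intersect(head(ranked$taxon, target), fallback)
  list(preferred = preferred, fallback = fallback, target = target,
       both = both)
}

#' Collapse per-ape statuses to a plant consumption trait
#'
#' Maps the pair (gorilla status, chimpanzee status) — each one of
#' `"preferred"`, `"fallback"`, `"neither"` or `"UC"` — onto one of the six
#' plant consumption traits or `"none"`: both preferred gives "Preferred
#' apes", both fallback "Fallback apes", exactly one ape preferred (the other
#' neither/UC) "Preferred gorilla"/"Preferred chimpanzee", exactly one
#' fallback the corresponding fallback trait. When one ape prefers a taxon
#' the other uses as fallback, the fallback-first rule extends: the taxon is
#' labelled fallback for that ape.
#'
#' @param status_gorilla,status_chimpanzee Character vectors of per-ape
#'   statuses (vectorised).
#' @return Character vector of traits.
#' @export
collapse_trait <- function(status_gorilla, status_chimpanzee) {
  valid <- c("preferred", "fallback", "neither", "UC")
  if (any(!status_gorilla %in% valid) || any(!status_chimpanzee %in% valid)) {
    stop("statuses must be one of: ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  mapply(function(g, c) {
    if (g == "fallback" && c == "fallback") return("Fallback apes")
    if (g == "preferred" && c == "preferred") return("Preferred apes")
    # conflict: fallback-first rule extended to the cross-ape case
    if (g == "fallback") return("Fallback gorilla")
    if (c == "fallback") return("Fallback chimpanzee")
    if (g == "preferred") return("Preferred gorilla")
    if (c == "preferred") return("Preferred chimpanzee")
    "none"
  }, status_gorilla, status_chimpanzee, USE.NAMES = FALSE)
}

#' Classify taxa into plant consumption traits
#'
#' End-to-end trait assignment for a scored dataset: splits seasons into
#' high/low fruit availability, finds fallback candidates per ape, assigns
#' the preferred and fallback lists (fallback first), and collapses the
#' per-ape statuses into the six plant consumption traits.
#'
#' @param scores A [diet_scores()] object.
#' @param calendar A [season_calendar()].
#' @param mcs_floor Minimum study-total MCS for fallback candidacy.
#' @return An object of class `trait_assignment`: a list with `table`
#'   (tibble: `taxon`, `status_gorilla`, `status_chimpanzee`, `trait`),
#'   `split` (the season split), per-ape `lists` from [assign_lists()], and
#'   `uc_conflicts` — taxa UC for one ape but status-bearing for the other.
#' @export
consumption_traits <- function(scores, calendar = season_calendar(),
                               mcs_floor = 0.001) {
  stopifnot(inherits(scores, "diet_scores"))
  split <- season_split(scores$fap, calendar)
  lists <- list()
  status <- list()
  for (a in APE_CODES) {
    prof <- seasonal_profile(scores$fap, scores$mcs[[a]], calendar)
    cand <- fallback_candidates(prof, split, mcs_floor = mcs_floor)
    lists[[a]] <- assign_lists(scores$gis[[a]], cand)
    gis <- scores$gis[[a]]
    st <- dplyr::case_when(
      gis$taxon %in% lists[[a]]$fallback ~ "fallback",
      gis$taxon %in% lists[[a]]$preferred ~ "preferred",
      gis$status == "UC" ~ "UC",
      TRUE ~ "neither"
    )
    status[[a]] <- tibble::tibble(taxon = gis$taxon, status = st)
  }
  tab <- dplyr::full_join(status$gorilla, status$chimpanzee, by = "taxon",
                          suffix = c("_gorilla", "_chimpanzee")) |>
    dplyr::mutate(
      status_gorilla = tidyr::replace_na(.data$status_gorilla, "UC"),
      status_chimpanzee = tidyr::replace_na(.data$status_chimpanzee, "UC"),
      trait = collapse_trait(.data$status_gorilla, .data$status_chimpanzee)
    ) |>
    dplyr::arrange(.data$taxon)
  uc_conflicts <- tab$taxon[
    (tab$status_gorilla == "UC") != (tab$status_chimpanzee == "UC")]
  structure(list(table = tab, split = split, lists = lists,
                 uc_conflicts = uc_conflicts),
            class = "trait_assignment")
}

#' @export
print.trait_assignment <- function(x, ...) {
  cat("<trait_assignment>\n")
  print(table(x$table$trait))
  invisible(x)
}

#' @rdname consumption_traits
#' @param x,object A `trait_assignment` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.trait_assignment <- function(x, ...) x$table

#' @rdname consumption_traits
#' @exportS3Method ggplot2::autoplot
autoplot.trait_assignment <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(y = .data$trait)) +
    ggplot2::geom_bar() +
    ggplot2::labs(y = "Consumption trait", x = "Number of taxa") +
    ggplot2::theme_minimal()
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)
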