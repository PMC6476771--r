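#' Season calendars
#'
#' A season calendar maps each calendar month (1-12) to one of the four
#' seasons of the study region: long dry (`LDS`), long rainy (`LRS`), short
#' dry (`SDS`) and short rainy (`SRS`). The default follows the regional
#' climate: the long dry season runs November-February, the long rainy season
#' March-June, the short dry season July-August and the short rainy season
#' September-October. Month-boundary assignment is configurable because
#' transition months straddle seasons.
#'
#' @param lds,lrs,sds,srs Integer vectors of months (1-12) assigned to each
#'   season. Together they must partition all twelve months.
#'
#' @return A `season_calendar`: a length-12 character vector of season codes
#'   indexed by month.
#' @examples
#' cal <- season_calendar()
#' season_of(12, cal) # "LDS"
#' season_of(7, cal)  # "SDS"
#' @export
season_calendar <- function(lds = c(11, 12, 1, 2),
                            lrs = 3:6,
                            sds = 7:8,
                            srs = 9:10) {
  months <- c(lds, lrs, sds, srs)
  if (!setequal(months, 1:12) || length(months) != 12L) {
    stop("season calendar must assign each month 1-12 to exactly one season",
         call. = FALSE)
  }
  cal <- character(12)
  cal[lds] <- "LDS"
  cal[lrs] <- "LRS"
  cal[sds] <- "SDS"
  cal[srs] <- "SRS"
  structure(cal, class = "season_calendar")
}

#' @rdname season_calendar
#' @param month Integer month(s) of year, 1-12 (vectorised).
#' @param calendar A `season_calendar`, default [season_calendar()].
#' @export
season_of <- function(month, calendar = season_calendar()) {
  if (any(is.na(month)) || any(month < 1 | month > 12) ||
      any(month != as.integer(month))) {
    stop("`month` must be an integer in 1-12", call. = FALSE)
  }
  unclass(calendar)[month]
}

#' @export
print.season_calendar <- function(x, ...) {
  cat("<season_calendar>\n")
  for (s in SEASON_CODES) {
    cat(sprintf("  %s: months %s\n", s,
                paste(which(unclass(x) == s), collapse = ", ")))
  }
  invisible(x)
}
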