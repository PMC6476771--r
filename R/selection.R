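#' Habitat availability proportions from survey points
#'
#' Converts the 50-m habitat survey stations into the availability
#' proportions p_i used as the denominator of the selectivity ratio. Habitats
#' never recorded along the transects get p_i = 0 and are flagged with a
#' warning, since any use of such a habitat would make the ratio undefined.
#'
#' @param points Data frame with a `habitat` column (one row per survey
#'   station), e.g. the `availability` table of a [survey_dataset()].
#' @return A tibble `habitat`, `n_points`, `p` covering all five habitat
#'   codes, with `sum(p) == 1`.
#' @examples
#' pts <- data.frame(habitat = rep(c("MF", "SW", "YSF", "RF"),
#'                                 c(60, 30, 18, 12)))
#' availability_proportions(pts)
#' @export
availability_proportions <- function(points) {
  points <- check_schema(points[, "habitat", drop = FALSE], "availability",
                         "habitat")
  if (nrow(points) == 0L) {
    stop("availability requires at least one survey point", call. = FALSE)
  }
  check_habitat(points$habitat, "availability")
  counts <- table(factor(points$habitat, levels = HABITAT_CODES))
  out <- tibble::tibble(
    habitat = HABITAT_CODES,
    n_points = as.integer(counts),
    p = as.numeric(counts) / sum(counts)
  )
  absent <- out$habitat[out$n_points == 0L]
  if (length(absent)) {
    warning("habitat(s) absent from availability survey: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  out
}

#' Manly design-1 habitat selectivity
#'
#' Computes the normalised selectivity ratio for each habitat from population
#' level use (nest counts) and availability:
#' \deqn{W_i = \frac{r_i / p_i}{\sum_k r_k / p_k}, \qquad W'_i = m \, W_i,}
#' where r_i is the proportion of nests in habitat i, p_i the proportion of
#' that habitat available, and m the number of habitat types. W_i sums to 1
#' across habitats; W'_i compares against 1 (proportional use), with values
#' above 1 indicating preference and below 1 avoidance. A chi-squared
#' goodness-of-fit test of the nest counts against availability
#' ([chi_square_gof()]) provides the global significance gate, and habitats
#' are classified preferred/avoided/proportional from Bonferroni-adjusted
#' confidence intervals on W' ([classify_selection()]).
#'
#' Standard errors treat availability as known (design 1): on the raw ratio
#' w_i = o_i/p_i, var(w_i) = o_i(1 - o_i) / (n p_i^2) with o_i the used
#' proportion and n the total count; the normalising sum is treated as fixed
#' when propagating to W'.
#'
#' @param nest_counts Named numeric vector or data frame
#'   (`habitat`, `n`) of nest counts per habitat.
#' @param availability Named numeric vector of availability proportions, or a
#'   data frame with `habitat` and `p` columns as returned by
#'   [availability_proportions()]. Must sum to 1.
#' @param alpha Family-wise significance level for the global test and the
#'   Bonferroni-adjusted intervals (default 0.05).
#' @return An object of class `manly_selection`: a list with `table` (tibble:
#'   `habitat`, `n`, `r`, `p`, `W`, `W_prime`, `se`, `ci_low`, `ci_high`,
#'   `class`), `m`, `n_total`, `chi2`, `df`, `p_value`, `alpha`. [tidy()]
#'   returns the per-habitat table, [glance()] the global test.
#' @examples
#' res <- manly_selection(c(A = 10, B = 5, C = 5), c(A = 0.5, B = 0.3, C = 0.2))
#' tidy(res)
#' glance(res)
#' @export
manly_selection <- function(nest_counts, availability, alpha = 0.05) {
  counts <- as_named_counts(nest_counts, "n")
  avail <- as_named_counts(availability, "p")
  if (!setequal(names(counts), names(avail))) {
    stop("nest counts and availability must cover the same habitats",
         call. = FALSE)
  }
  avail <- avail[names(counts)]
  if (abs(sum(avail) - 1) > 1e-8) {
    stop("availability proportions must sum to 1", call. = FALSE)
  }
  if (any(counts < 0)) stop("nest counts must be non-negative", call. = FALSE)
  n_total <- sum(counts)
  if (n_total <= 0) stop("at least one nest is required", call. = FALSE)
  if (any(avail == 0 & counts > 0)) {
    stop("habitat used but unavailable (p_i = 0 with count > 0)",
         call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)

  m <- length(counts)
  r <- counts / n_total
  ratio <- ifelse(avail > 0, r / avail, 0)
  denom <- sum(ratio)
  W <- ratio / denom
  W_prime <- m * W
  # design-1 variance of the raw ratio, delta-propagated through the
  # (treated-as-fixed) normalising sum
  se_w <- sqrt(ifelse(avail > 0, r * (1 - r) / (n_total * avail^2), NA_real_))
  se <- m * se_w / denom
  z <- qnorm(1 - alpha / (2 * m))
  ci_low <- W_prime - z * se
  ci_high <- W_prime + z * se

  gof <- chi_square_gof(counts, avail)

  tab <- tibble::tibble(
    habitat = names(counts),
    n = as.numeric(counts),
    r = as.numeric(r),
    p = as.numeric(avail),
    W = as.numeric(W),
    W_prime = as.numeric(W_prime),
    se = as.numeric(se),
    ci_low = as.numeric(ci_low),
    ci_high = as.numeric(ci_high)
  )
  out <- structure(
    list(table = tab, m = m, n_total = n_total, chi2 = gof$chi2, df = gof$df,
         p_value = gof$p_value, alpha = alpha),
    class = "manly_selection"
  )
  out$table$class <- classify_selection(out, alpha)
  out
}

#' Chi-squared goodness-of-fit of habitat use against availability
#'
#' Pearson goodness-of-fit of observed per-habitat counts against expected
#' counts n p_i, restricted to habitats with p_i > 0. Quantifies whether use
#' deviates from availability overall before any per-habitat call is made.
#'
#' @inheritParams manly_selection
#' @return A list with `chi2`, `df` (habitats with p > 0, minus one) and
#'   `p_value` (upper tail).
#' @examples
#' chi_square_gof(c(A = 10, B = 5, C = 5), c(A = 0.5, B = 0.3, C = 0.2))
#' @export
chi_square_gof <- function(nest_counts, availability) {
  o <- as_named_counts(nest_counts, "n")
  p <- as_named_counts(availability, "p")
  if (!setequal(names(o), names(p))) {
    stop("nest counts and availability must cover the same habitats",
         call. = FALSE)
  }
  p <- p[names(o)]
  if (any(p == 0 & o > 0)) {
    stop("expected count is 0 for a habitat with observed use", call. = FALSE)
  }
  keep <- p > 0
  o <- o[keep]
  p <- p[keep]
  n <- sum(o)
  expected <- n * p / sum(p)
  chi2 <- sum((o - expected)^2 / expected)
  df <- length(o) - 1L
  list(chi2 = as.numeric(chi2), df = df,
       p_value = pchisq(chi2, df, lower.tail = FALSE))
}

#' Classify habitats as preferred, avoided or proportional
#'
#' A habitat is called preferred when the lower bound of the
#' Bonferroni-adjusted confidence interval of W' exceeds 1, avoided when the
#' upper bound falls below 1, and proportional otherwise. No per-habitat call
#' is made unless the global chi-squared test is significant at `alpha`: when
#' it is not, every habitat is proportional regardless of W'.
#'
#' @param result A `manly_selection` object.
#' @param alpha Significance level (default: the one stored in `result`).
#' @return Character vector of classes, one per habitat, in the order of
#'   `result$table`.
#' @export
classify_selection <- function(result, alpha = result$alpha) {
  stopifnot(inherits(result, "manly_selection"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  tab <- result$table
  cls <- rep("proportional", nrow(tab))
  if (!is.na(result$p_value) && result$p_value < alpha) {
    cls[!is.na(tab$ci_low) & tab$ci_low > 1] <- "preferred"
    cls[!is.na(tab$ci_high) & tab$ci_high < 1] <- "avoided"
  }
  cls
}

#' Seasonal habitat selection for one ape species
#'
#' Stratifies the nest records of one ape by the season each nest was
#' recorded fresh, and runs [manly_selection()] per season against the
#' availability proportions of the whole survey. Seasons with no nests are
#' absent from the result rather than reported as zeros.
#'
#' @param dataset A [survey_dataset()].
#' @param ape `"gorilla"` or `"chimpanzee"`.
#' @param alpha Significance level passed to [manly_selection()].
#' @param unit Counting unit: `"nest"` (each nest record counts once, the
#'   default) or `"group"` (each nest group counts once per habitat, using
#'   `group_id`).
#' @return A named list of `manly_selection` objects, one per season with
#'   nests, in calendar order LDS, LRS, SDS, SRS.
#' @export
seasonal_selection <- function(dataset, ape, alpha = 0.05,
                               unit = c("nest", "group")) {
  stopifnot(inherits(dataset, "survey_dataset"))
  unit <- match.arg(unit)
  if (!ape %in% APE_CODES) {
    stop("unknown ape label: ", ape, call. = FALSE)
  }
  avail <- availability_proportions(dataset$availability)
  p <- stats::setNames(avail$p, avail$habitat)
  nests <- dataset$nests |>
    dplyr::filter(.data$ape == .env$ape) |>
    dplyr::mutate(season = season_of(.data$month, dataset$calendar))
  if (unit == "group") {
    nests <- dplyr::distinct(nests, .data$season, .data$habitat,
                             .data$group_id)
  }
  seasons <- intersect(SEASON_CODES, unique(nests$season))
  out <- lapply(seasons, function(s) {
    counts_tab <- table(factor(nests$habitat[nests$season == s],
                               levels = HABITAT_CODES))
    manly_selection(stats::setNames(as.numeric(counts_tab), HABITAT_CODES),
                    p, alpha = alpha)
  })
  stats::setNames(out, seasons)
}

#' @export
print.manly_selection <- function(x, ...) {
  cat(sprintf("<manly_selection>  n = %d nests over %d habitats\n",
              x$n_total, x$m))
  cat(sprintf("  chi-squared GOF: chi2 = %.3f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p_value))
  print(x$table)
  invisible(x)
}

#' @rdname manly_selection
#' @param x A `manly_selection` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.manly_selection <- function(x, ...) x$table

#' @rdname manly_selection
#' @exportS3Method generics::glance
glance.manly_selection <- function(x, ...) {
  tibble::tibble(n_nests = x$n_total, m = x$m, chi2 = x$chi2, df = x$df,
                 p_value = x$p_value, alpha = x$alpha)
}

#' @rdname manly_selection
#' @param object A `manly_selection` object.
#' @exportS3Method ggplot2::autoplot
autoplot.manly_selection <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$habitat, y = .data$W_prime,
                               colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = "Habitat", y = "Selectivity ratio W'",
                  colour = "Selection") +
    ggplot2::theme_minimal()
}

# coerce a named vector or (habitat, value) data frame to a named vector
as_named_counts <- function(x, col) {
  if (is.data.frame(x)) {
    if (!"habitat" %in% names(x) || !col %in% names(x)) {
      stop(sprintf("data frame input needs columns `habitat` and `%s`", col),
           call. = FALSE)
    }
    return(stats::setNames(as.numeric(x[[col]]), x$habitat))
  }
  if (is.null(names(x))) {
    stop("vector input must be named by habitat", call. = FALSE)
  }
  stats::setNames(as.numeric(x), names(x))
}
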