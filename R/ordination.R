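#' Habitat-by-trait (or habitat-by-taxon) contingency table
#'
#' Sums botanical-plot stem counts into a habitat x trait (or habitat x
#' taxon) contingency table for correspondence analysis. Taxa with trait
#' `"none"` are excluded; plots containing no stems of any included taxon are
#' dropped before the analysis and their number reported, mirroring the field
#' practice of excluding plots without any consumed fruiting species.
#'
#' @param plots Long plot table (`plot_id`, `habitat`, `taxon`, `stems`).
#' @param traits A `trait_assignment` (or its `table` tibble with `taxon`,
#'   `trait`). Ignored when `by = "taxon"` except for the none-exclusion.
#' @param by Column unit: `"trait"` (default) or `"taxon"`.
#' @return A list of class `fn_contingency` with `table` (numeric matrix,
#'   habitats x columns), `n_excluded_plots`, `n_plots_used`.
#' @export
build_contingency <- function(plots, traits, by = c("trait", "taxon")) {
  by <- match.arg(by)
  plots <- check_schema(plots, "plots", c("plot_id", "habitat", "taxon", "stems"))
  tab <- if (inherits(traits, "trait_assignment")) traits$table else traits
  tab <- check_schema(tab[, c("taxon", "trait")], "traits", c("taxon", "trait"))
  keep <- tab |> dplyr::filter(.data$trait != "none")
  joined <- plots |>
    dplyr::inner_join(keep, by = "taxon") |>
    dplyr::filter(.data$stems > 0)
  all_plots <- unique(plots$plot_id)
  used_plots <- unique(joined$plot_id)
  n_excluded <- length(setdiff(all_plots, used_plots))
  if (nrow(joined) == 0L) {
    stop("contingency table has no nonzero cells", call. = FALSE)
  }
  col_var <- if (by == "trait") "trait" else "taxon"
  cells <- joined |>
    dplyr::summarise(stems = sum(.data$stems),
                     .by = c("habitat", dplyr::all_of(col_var)))
  m <- tidyr::pivot_wider(cells, names_from = dplyr::all_of(col_var),
                          values_from = "stems", values_fill = 0)
  mat <- as.matrix(m[, -1, drop = FALSE])
  rownames(mat) <- m$habitat
  mat <- mat[order(rownames(mat)), order(colnames(mat)), drop = FALSE]
  structure(list(table = mat, n_excluded_plots = n_excluded,
                 n_plots_used = length(used_plots)),
            class = "fn_contingency")
}

#' @export
print.fn_contingency <- function(x, ...) {
  cat(sprintf("<fn_contingency>  %d plots used, %d empty plots excluded\n",
              x$n_plots_used, x$n_excluded_plots))
  print(x$table)
  invisible(x)
}

#' Correspondence analysis of a contingency table
#'
#' Classical (simple) correspondence analysis: the matrix of standardized
#' Pearson residuals of the table under row-column independence is decomposed
#' by singular value decomposition; each axis carries inertia equal to its
#' squared singular value, and total inertia equals the table's Pearson
#' chi-squared statistic divided by the grand total. Row and column scores
#' are reported in principal coordinates (both scaled by the singular values,
#' the symmetric biplot convention), so the weighted mean of the scores on
#' every axis is zero. The deviation table of observed minus expected
#' frequencies — whose rows and columns each sum to zero — shows which
#' habitat/trait combinations drive the inertia.
#'
#' @param x A matrix of non-negative counts (or an `fn_contingency`).
#' @param tol Singular values below `tol` times the largest are treated as
#'   null axes (default 1e-10).
#' @return An object of class `fruit_ca`: list with `row_coords`,
#'   `col_coords` (matrices, axes in columns), `singular_values`, `inertia`
#'   (per axis), `percent_inertia`, `total_inertia`, `deviations`
#'   (observed - expected counts), `n`. A perfectly independent table yields
#'   zero axes and zero total inertia.
#' @examples
#' ca <- correspondence_analysis(matrix(c(10, 0, 0, 10), 2))
#' ca$total_inertia # 1
#' @export
correspondence_analysis <- function(x, tol = 1e-10) {
  if (inherits(x, "fn_contingency")) x <- x$table
  x <- as.matrix(x)
  if (any(x < 0)) stop("contingency table must be non-negative", call. = FALSE)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("contingency table needs at least 2 rows and 2 columns", call. = FALSE)
  }
  n <- sum(x)
  if (n <= 0) stop("contingency table must have a positive total", call. = FALSE)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop("all-zero row or column in contingency table", call. = FALSE)
  }
  P <- x / n
  r <- rowSums(P)
  cc <- colSums(P)
  E <- outer(r, cc)
  S <- (P - E) / sqrt(E)
  sv <- svd(S)
  keep <- sv$d > tol * max(sv$d, 1)
  k <- sum(keep)
  d <- sv$d[keep]
  axes <- if (k > 0) paste0("axis", seq_len(k)) else character(0)
  row_coords <- sweep(sv$u[, keep, drop = FALSE], 1, sqrt(r), "/")
  row_coords <- sweep(row_coords, 2, d, "*")
  col_coords <- sweep(sv$v[, keep, drop = FALSE], 1, sqrt(cc), "/")
  col_coords <- sweep(col_coords, 2, d, "*")
  dimnames(row_coords) <- list(rownames(x), axes)
  dimnames(col_coords) <- list(colnames(x), axes)
  inertia <- d^2
  total <- sum(sv$d^2)
  deviations <- n * (P - E)
  structure(list(
    row_coords = row_coords, col_coords = col_coords,
    singular_values = d, inertia = inertia,
    percent_inertia = if (total > 0) 100 * inertia / total else numeric(0),
    total_inertia = total, deviations = deviations, n = n
  ), class = "fruit_ca")
}

#' @export
print.fruit_ca <- function(x, ...) {
  cat(sprintf("<fruit_ca>  total inertia %.6g over %d axis/axes\n",
              x$total_inertia, length(x$inertia)))
  if (length(x$inertia)) {
    cat("  percent inertia:",
        paste(sprintf("%.2f%%", x$percent_inertia), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname correspondence_analysis
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fruit_ca <- function(x, ...) {
  bind_coords <- function(m, type) {
    if (length(m) == 0 || nrow(m) == 0) return(tibble::tibble())
    tibble::as_tibble(m, rownames = "entity") |>
      dplyr::mutate(type = type, .before = 1)
  }
  dplyr::bind_rows(bind_coords(x$row_coords, "row"),
                   bind_coords(x$col_coords, "column"))
}

#' @rdname correspondence_analysis
#' @exportS3Method generics::glance
glance.fruit_ca <- function(x, ...) {
  tibble::tibble(
    total_inertia = x$total_inertia,
    n_axes = length(x$inertia),
    pct_axis1 = if (length(x$percent_inertia) >= 1) x$percent_inertia[1] else NA_real_,
    pct_axis2 = if (length(x$percent_inertia) >= 2) x$percent_inertia[2] else NA_real_,
    n = x$n
  )
}

#' @rdname correspondence_analysis
#' @param object A `fruit_ca` object.
#' @exportS3Method ggplot2::autoplot
autoplot.fruit_ca <- function(object, ...) {
  df <- tidy(object)
  if (!"axis2" %in% names(df)) df$axis2 <- 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2,
                                   colour = .data$type,
                                   label = .data$entity)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, show.legend = FALSE) +
    ggplot2::labs(x = sprintf("Axis 1 (%.1f%%)", object$percent_inertia[1]),
                  y = if (length(object$percent_inertia) >= 2) {
                    sprintf("Axis 2 (%.1f%%)", object$percent_inertia[2])
                  } else "Axis 2") +
    ggplot2::theme_minimal()
}

#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarities between the rows of a non-negative
#' matrix (e.g. months x taxa FAP or MCS profiles):
#' d(j, k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik). Pairs of all-zero
#' rows have an undefined ratio and are assigned distance 0 with a warning.
#'
#' @param x Non-negative numeric matrix or data frame, observations in rows.
#' @return A `dist` object with values in \[0, 1\].
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("Bray-Curtis requires non-negative input", call. = FALSE)
  d <- suppressWarnings(vegan::vegdist(x, method = "bray"))
  if (anyNA(d)) {
    warning("pair(s) of all-zero rows: Bray-Curtis undefined, set to 0",
            call. = FALSE)
    d[is.na(d)] <- 0
  }
  d
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-factor PERMANOVA on a dissimilarity matrix. The total sum of squares
#' is the sum of squared dissimilarities divided by the number of
#' observations; the within-group sum of squares is the analogous sum within
#' each group divided by its size. The pseudo-F statistic is
#' (SS_between / (k - 1)) / (SS_within / (N - k)). Significance is assessed
#' by permuting observation labels: p = (1 + #\{F* >= F\}) / (1 + n_perm).
#' With `exact = TRUE` and two groups, all distinct label assignments are
#' enumerated and p is the exact proportion of assignments with F* >= F
#' (the observed assignment included).
#'
#' @param dist A `dist` object or symmetric distance matrix.
#' @param groups Grouping vector (one label per observation; every group
#'   needs at least 2 members).
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @param exact Enumerate all distinct assignments instead of sampling
#'   (two-group case only).
#' @return An object of class `fn_permanova`: list with `pseudo_F`,
#'   `p_value`, `df` (between, within), `ss` (between, within, total),
#'   `n_perm`, `method`.
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = NULL, exact = FALSE) {
  d2 <- as.matrix(dist)^2
  groups <- as.character(groups)
  N <- length(groups)
  if (nrow(d2) != N) stop("groups length must match distance matrix", call. = FALSE)
  sizes <- table(groups)
  k <- length(sizes)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2)) stop("every group needs at least 2 members", call. = FALSE)

  ss_total <- sum(d2[upper.tri(d2)]) / N
  f_stat <- function(g) {
    ss_w <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      ss_w <- ss_w + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ss_b <- ss_total - ss_w
    (ss_b / (k - 1)) / (ss_w / (N - k))
  }
  F_obs <- f_stat(groups)

  ss_w_obs <- 0
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    ss_w_obs <- ss_w_obs + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }

  if (exact) {
    if (k != 2) stop("exact enumeration is implemented for two groups",
                     call. = FALSE)
    lev <- names(sizes)
    combos <- combn(N, sizes[[1]])
    F_all <- apply(combos, 2, function(idx) {
      g <- rep(lev[2], N)
      g[idx] <- lev[1]
      f_stat(g)
    })
    p <- mean(F_all >= F_obs - 1e-12)
    return(structure(list(pseudo_F = F_obs, p_value = p,
                          df = c(between = k - 1, within = N - k),
                          ss = c(between = ss_total - ss_w_obs,
                                 within = ss_w_obs, total = ss_total),
                          n_perm = ncol(combos), method = "exact enumeration"),
                     class = "fn_permanova"))
  }

  if (!is.null(seed)) set.seed(seed)
  # vectorised permutation evaluation via group membership indicators
  P <- t(replicate(n_perm, sample(groups)))
  ss_w_perm <- numeric(n_perm)
  for (lev in unique(groups)) {
    B <- (P == lev) * 1
    ss_w_perm <- ss_w_perm + rowSums((B %*% d2) * B) / (2 * sizes[[lev]])
  }
  F_perm <- ((ss_total - ss_w_perm) / (k - 1)) / (ss_w_perm / (N - k))
  p <- (1 + sum(F_perm >= F_obs - 1e-12)) / (1 + n_perm)

  structure(list(pseudo_F = F_obs, p_value = p,
                 df = c(between = k - 1, within = N - k),
                 ss = c(between = ss_total - ss_w_obs, within = ss_w_obs,
                        total = ss_total),
                 n_perm = n_perm, method = "label permutation"),
            class = "fn_permanova")
}

#' @export
print.fn_permanova <- function(x, ...) {
  cat(sprintf("<fn_permanova>  pseudo-F = %.4f, p = %.4g (%s, %d perms)\n",
              x$pseudo_F, x$p_value, x$method, x$n_perm))
  invisible(x)
}

#' @rdname permanova
#' @param x An `fn_permanova` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.fn_permanova <- function(x, ...) {
  tibble::tibble(pseudo_F = x$pseudo_F, p_value = x$p_value,
                 df_between = x$df[["between"]], df_within = x$df[["within"]],
                 n_perm = x$n_perm, method = x$method)
}

#' Homogeneity of multivariate dispersion
#'
#' Tests whether groups differ in multivariate spread rather than location,
#' the standard companion check to PERMANOVA. Observations are embedded by
#' principal coordinates analysis of the dissimilarity matrix (axes with
#' negative eigenvalues are retained and enter the squared distances with a
#' negative sign, the usual correction for semi-metric dissimilarities such
#' as Bray-Curtis); each observation's distance to its group centroid is
#' computed in that embedding, a one-way F statistic compares those distances
#' across groups, and p is obtained by permuting group labels and recomputing
#' the centroid distances and F.
#'
#' @inheritParams permanova
#' @return An object of class `fn_dispersion`: list with `F`, `p_value`,
#'   `distances` (to own-group centroid), `groups`, `n_perm`.
#' @export
dispersion_homogeneity <- function(dist, groups, n_perm = 999, seed = NULL) {
  dmat <- as.matrix(dist)
  groups <- as.character(groups)
  N <- length(groups)
  if (nrow(dmat) != N) stop("groups length must match distance matrix", call. = FALSE)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2)) stop("every group needs at least 2 members", call. = FALSE)

  # PCoA (Gower) embedding, keeping negative-eigenvalue axes separately
  A <- -0.5 * dmat^2
  J <- diag(N) - matrix(1 / N, N, N)
  G <- J %*% A %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  pos <- e$values > tol
  neg <- e$values < -tol
  Xpos <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  Xneg <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), sum(neg))

  centroid_dist <- function(g) {
    out <- numeric(N)
    for (lev in unique(g)) {
      idx <- which(g == lev)
      cp <- colMeans(Xpos[idx, , drop = FALSE])
      cn <- if (ncol(Xneg)) colMeans(Xneg[idx, , drop = FALSE]) else numeric(0)
      d2 <- rowSums(sweep(Xpos[idx, , drop = FALSE], 2, cp)^2)
      if (ncol(Xneg)) {
        d2 <- d2 - rowSums(sweep(Xneg[idx, , drop = FALSE], 2, cn)^2)
      }
      out[idx] <- sqrt(pmax(d2, 0))
    }
    out
  }
  f_of <- function(g) {
    z <- centroid_dist(g)
    # all centroid distances equal (to numerical precision): no dispersion
    # signal at all, define F = 0
    if (diff(range(z)) <= 1e-8 * (max(abs(z)) + 1e-300)) return(0)
    k <- length(unique(g))
    gm <- mean(z)
    means <- tapply(z, g, mean)
    ns <- tapply(z, g, length)
    ss_b <- sum(ns * (means - gm)^2)
    ss_w <- sum((z - means[g])^2)
    if (ss_w <= 0) return(0)
    (ss_b / (k - 1)) / (ss_w / (N - k))
  }
  F_obs <- f_of(groups)
  if (!is.null(seed)) set.seed(seed)
  F_perm <- replicate(n_perm, f_of(sample(groups)))
  p <- (1 + sum(F_perm >= F_obs - 1e-12)) / (1 + n_perm)
  structure(list(F = F_obs, p_value = p, distances = centroid_dist(groups),
                 groups = groups, n_perm = n_perm),
            class = "fn_dispersion")
}

#' @export
print.fn_dispersion <- function(x, ...) {
  cat(sprintf("<fn_dispersion>  F = %.4f, p = %.4g (%d perms)\n",
              x$F, x$p_value, x$n_perm))
  invisible(x)
}

#' @rdname dispersion_homogeneity
#' @param x An `fn_dispersion` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.fn_dispersion <- function(x, ...) {
  tibble::tibble(F = x$F, p_value = x$p_value, n_perm = x$n_perm)
}
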