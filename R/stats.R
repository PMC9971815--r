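#' D'Agostino-Pearson omnibus normality test
#'
#' The K2 statistic combines the transformed sample skewness
#' (D'Agostino 1970) and kurtosis (Anscombe & Glynn 1983) z scores;
#' under normality K2 is approximately chi-squared with 2 df. Requires
#' n >= 8.
#'
#' @param x Numeric sample.
#' @return List with `statistic` (K2), `p.value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance sample")
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2
  # skewness z (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis z (Anscombe-Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Distribution-routed two-sample (or paired) comparison
#'
#' Implements the decision tree used for group comparisons:
#' 1. Both samples pass the D'Agostino-Pearson normality test at `alpha` →
#'    parametric route on the raw values: paired t-test, or — unpaired — the
#'    F-test of equality of variances decides between the ordinary unpaired
#'    t-test (UT) and Welch's correction (UTWC).
#' 2. Otherwise, if both samples are strictly positive and their logs pass
#'    the normality test → the same parametric route on log-transformed
#'    values.
#' 3. Otherwise the nonparametric route: Mann-Whitney (unpaired) or Wilcoxon
#'    signed rank (paired; zero differences dropped, the standard
#'    convention).
#'
#' Samples smaller than 8 (the minimum for the normality test) take the
#' nonparametric route; below 3 a warning is also issued.
#'
#' @param a,b Numeric samples (paired samples must have equal length).
#' @param paired Paired comparison?
#' @param alpha Significance level used for the normality and
#'   variance-homogeneity decisions (and reported significance).
#' @return A `comparison_result`: `test` (PT, UT, UTWC, MW or WSRT),
#'   `p.value`, `route` (normal / lognormal / nonparametric), `paired`,
#'   effect summaries per group.
#' @export
choose_and_run_test <- function(a, b, paired = FALSE, alpha = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (paired && length(a) != length(b)) {
    stop("paired samples must have equal length")
  }
  if (min(length(a), length(b)) < 3) {
    warning("sample with n < 3: nonparametric route with low power")
  }
  normal_p <- function(x) {
    if (length(x) < 8) return(NA_real_)
    tryCatch(dagostino_pearson(x)$p.value, error = function(e) NA_real_)
  }
  passes <- function(p) !is.na(p) && p >= alpha
  route <- "nonparametric"
  ta <- a; tb <- b
  if (passes(normal_p(a)) && passes(normal_p(b))) {
    route <- "normal"
  } else if (all(a > 0) && all(b > 0) &&
             passes(normal_p(log(a))) && passes(normal_p(log(b)))) {
    route <- "lognormal"
    ta <- log(a); tb <- log(b)
  }
  # degenerate data (all-zero differences, constant samples) yields an
  # undefined p, not an error
  safe <- function(expr) {
    tryCatch(expr, error = function(e) {
      list(p.value = NA_real_, statistic = NA_real_,
           note = conditionMessage(e))
    })
  }
  if (route %in% c("normal", "lognormal")) {
    if (paired) {
      res <- safe(stats::t.test(ta, tb, paired = TRUE))
      test <- "PT"
    } else {
      vr <- safe(stats::var.test(ta, tb))
      welch <- !is.na(vr$p.value) && vr$p.value < alpha
      res <- safe(stats::t.test(ta, tb, var.equal = !welch))
      test <- if (welch) "UTWC" else "UT"
    }
  } else {
    if (paired) {
      res <- safe(suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                                      exact = FALSE)))
      test <- "WSRT"
    } else {
      res <- safe(suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)))
      test <- "MW"
    }
  }
  structure(list(
    test = test, p.value = unname(res$p.value), route = route,
    paired = paired, alpha = alpha,
    summary = data.frame(
      group = c("a", "b"), n = c(length(a), length(b)),
      mean = c(mean(a), mean(b)), sd = c(stats::sd(a), stats::sd(b)),
      median = c(stats::median(a), stats::median(b))),
    statistic = unname(res$statistic)),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s (%s route%s): p = %.4g %s\n",
              x$test, x$route, if (x$paired) ", paired" else "",
              x$p.value, significance_stars(x$p.value)))
  invisible(x)
}

#' Significance stars
#' @param p p value(s).
#' @return `"****"` below 0.0001, `"***"` below 0.001, `"**"` below 0.01,
#'   `"*"` below 0.05, `"ns"` otherwise.
#' @export
significance_stars <- function(p) {
  cut(p, c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}

#' Per-heart aggregation with a one-sample t-test
#'
#' Cell-level values (typically paired epitubular-minus-paratubular
#' differences) are averaged within each heart; hearts contributing fewer
#' than `min_cells` cells are excluded (an isolation represented by a single
#' cell carries no within-heart information); the heart means are tested
#' against zero with a one-sample t-test.
#'
#' @param values Numeric vector, one value per cell.
#' @param heart_ids Heart/isolation identifier per cell.
#' @param min_cells Minimum cells for a heart to qualify.
#' @return List with `heart_means` (named), `excluded_hearts`, `n_hearts`,
#'   `p.value` and `t` (both `NA`, with `underpowered = TRUE`, when fewer
#'   than 2 hearts qualify).
#' @export
per_heart_summary <- function(values, heart_ids, min_cells = 2) {
  stopifnot(length(values) == length(heart_ids))
  sizes <- table(heart_ids)
  qualify <- names(sizes)[sizes >= min_cells]
  excluded <- setdiff(names(sizes), qualify)
  keep <- heart_ids %in% qualify
  means <- tapply(values[keep], factor(heart_ids[keep], levels = qualify),
                  mean)
  if (length(means) < 2) {
    return(list(heart_means = means, excluded_hearts = excluded,
                n_hearts = length(means), t = NA_real_, p.value = NA_real_,
                underpowered = TRUE))
  }
  tt <- stats::t.test(as.numeric(means), mu = 0)
  list(heart_means = means, excluded_hearts = excluded,
       n_hearts = length(means), t = unname(tt$statistic),
       p.value = tt$p.value, underpowered = FALSE)
}

#' Restrict cells to a common imaging time window
#'
#' Scans candidate window start times (every observed imaging time) and
#' keeps the cells imaged within `[start, start + window_min]` for the start
#' that maximizes the number of retained cells while both groups remain
#' represented — reducing systematic bias from imaging time on group
#' comparisons. Ties go to the window retaining the most balanced groups,
#' then to the earliest start.
#'
#' @param cells data.frame of per-cell metadata.
#' @param window_min Window length in minutes (> 0).
#' @param time_col Column with minutes since start of dye loading.
#' @param group_col Column with the group label (e.g. ventricle).
#' @return The retained subset, with the chosen window in
#'   `attr(, "window_start")`.
#' @export
filter_by_time_window <- function(cells, window_min,
                                  time_col = "minutes_since_load",
                                  group_col = "ventricle") {
  if (!is.numeric(window_min) || window_min <= 0) {
    stop("window_min must be positive")
  }
  stopifnot(time_col %in% names(cells), group_col %in% names(cells))
  t <- cells[[time_col]]
  g <- cells[[group_col]]
  if (any(!is.finite(t))) stop("missing imaging times in metadata")
  best <- NULL
  for (start in sort(unique(t))) {
    inside <- t >= start & t <= start + window_min
    if (!any(inside)) next
    groups <- unique(g[inside])
    n <- sum(inside)
    balance <- min(table(factor(g[inside], levels = unique(g))))
    cand <- list(start = start, inside = inside, n = n,
                 both = length(groups) == length(unique(g)),
                 balance = balance)
    if (is.null(best) ||
        (cand$both > best$both) ||
        (cand$both == best$both && cand$n > best$n) ||
        (cand$both == best$both && cand$n == best$n &&
           cand$balance > best$balance)) {
      best <- cand
    }
  }
  if (is.null(best) || best$n == 0) stop("no cells fall in any time window")
  out <- cells[best$inside, , drop = FALSE]
  attr(out, "window_start") <- best$start
  out
}
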