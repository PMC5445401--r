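#' Blank-correct a growth curve
#'
#' Subtracts the blank absorbance and floors the result at a small positive
#' value so the log transform stays defined.
#'
#' @param curve Tibble with columns `time_h` and `absorbance` (a `well`
#'   column is carried through when present).
#' @param blank Blank absorbance to subtract.
#' @param floor Positive lower bound applied after subtraction.
#' @return The curve with corrected absorbance.
#' @export
blank_correct <- function(curve, blank = 0, floor = 1e-6) {
  stopifnot_scalar_number(blank, "blank")
  stopifnot_scalar_number(floor, "floor", positive = TRUE)
  corrected <- curve$absorbance - blank
  n_floored <- sum(corrected < floor)
  if (n_floored > 0) {
    warn(paste0(n_floored, " absorbance value(s) at or below the blank; ",
                "floored at ", floor))
  }
  curve$absorbance <- pmax(corrected, floor)
  curve
}

#' Doubling time from the exponential region of a growth curve
#'
#' Operationalises "the linear region of the exponential portion": among all
#' contiguous windows of at least `min_window` time points, selects the one
#' maximising the R-squared of the least-squares fit of log2(absorbance)
#' against time, subject to a positive slope. Windows whose R-squared is
#' within `tie_tol` of the maximum are treated as ties, resolved toward the
#' longer and then the earlier window, so a long genuinely-exponential
#' stretch is preferred over a short window that fits marginally better by
#' noise. The slope is in doublings per hour, so `T_d = 1/slope`.
#'
#' @param curve Tibble `time_h`, `absorbance` (replicate wells allowed; they
#'   are averaged per time point before the log transform).
#' @param min_window Minimum number of time points in the fitted window.
#' @param tie_tol R-squared margin within which windows count as tied.
#' @return An object of class `td_fit`: `td_hours`, `slope` (log2 units/h),
#'   `r_squared`, `se_td`, `window_start`, `window_end` (indices into the
#'   ordered unique time points), `window_times`, `curve`.
#' @export
doubling_time <- function(curve, min_window = 3L, tie_tol = 1e-3) {
  if (!all(c("time_h", "absorbance") %in% names(curve))) {
    abort("curve needs columns `time_h` and `absorbance`")
  }
  if (any(!is.finite(curve$absorbance))) abort("absorbance must be finite")
  avg <- curve %>%
    group_by(.data$time_h) %>%
    summarise(absorbance = mean(.data$absorbance), .groups = "drop") %>%
    arrange(.data$time_h)
  ok <- avg$absorbance > 0
  if (sum(ok) < min_window) {
    abort("fewer positive-absorbance points than `min_window`")
  }
  t <- avg$time_h; y <- log2(avg$absorbance)
  np <- length(t)
  if (min_window < 3L) abort("`min_window` must be >= 3")

  cand <- list()
  for (len in seq.int(min_window, np)) {
    for (start in seq_len(np - len + 1L)) {
      idx <- seq.int(start, start + len - 1L)
      if (!all(ok[idx])) next
      fit <- lm(y[idx] ~ t[idx])
      slope <- coef(fit)[[2]]
      if (!is.finite(slope) || slope <= 0) next
      ssr <- sum(fit$residuals^2)
      sst <- sum((y[idx] - mean(y[idx]))^2)
      r2 <- if (sst == 0) 1 else 1 - ssr / sst
      se_slope <- tryCatch(suppressWarnings(summary(fit)$coefficients[2, 2]),
                           error = function(e) NA_real_)
      cand[[length(cand) + 1L]] <- list(r2 = r2, len = len, start = start,
                                        slope = slope, se_slope = se_slope)
    }
  }
  if (length(cand) == 0L) {
    abort("no exponential region: no window with positive slope")
  }
  r2max <- max(purrr::map_dbl(cand, "r2"))
  tied <- purrr::keep(cand, function(w) w$r2 >= r2max - tie_tol)
  lens <- purrr::map_int(tied, "len")
  starts <- purrr::map_int(tied, "start")
  best <- tied[[order(-lens, starts)[1]]]
  idx <- seq.int(best$start, best$start + best$len - 1L)
  structure(list(
    td_hours = 1 / best$slope,
    slope = best$slope,
    r_squared = max(0, min(1, best$r2)),
    se_td = if (is.finite(best$se_slope)) best$se_slope / best$slope^2 else NA_real_,
    window_start = best$start, window_end = best$start + best$len - 1L,
    window_times = t[idx],
    curve = avg
  ), class = "td_fit")
}

#' @export
print.td_fit <- function(x, ...) {
  cat(sprintf("Doubling time: %.2f h (R^2 = %.4f, window %d..%d)\n",
              x$td_hours, x$r_squared, x$window_start, x$window_end))
  invisible(x)
}

#' Window fit of a doubling-time estimate
#' @param x A `td_fit`.
#' @param ... Unused.
#' @return One-row tibble with the fitted quantities.
#' @export
tidy.td_fit <- function(x, ...) {
  tibble(td_hours = x$td_hours, slope = x$slope, r_squared = x$r_squared,
         se_td = x$se_td, window_start = x$window_start,
         window_end = x$window_end)
}

#' @rdname tidy.td_fit
#' @export
glance.td_fit <- function(x, ...) tidy(x)

#' Growth-curve plot with the fitted exponential window
#' @param object A `td_fit`.
#' @param ... Unused.
#' @return A ggplot object: log2 absorbance vs time, window highlighted.
#' @export
autoplot.td_fit <- function(object, ...) {
  df <- mutate(object$curve,
               in_window = .data$time_h %in% object$window_times)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, log2(.data$absorbance))) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_window)) +
    ggplot2::labs(x = "time (h)", y = "log2 absorbance",
                  subtitle = sprintf("T_d = %.1f h", object$td_hours)) +
    ggplot2::theme_minimal()
}

#' Compare doubling times across cell lines
#'
#' One-way ANOVA on per-replicate doubling-time estimates with Tukey HSD
#' post-hoc pairwise comparisons.
#'
#' @param estimates Tibble with columns `cell_line` and `td_hours`, one row
#'   per replicate estimate; >= 2 lines with >= 2 estimates each.
#' @return An object of class `td_comparison`: `anova` (one-row tibble
#'   `f_statistic`, `p_value`, `df_between`, `df_within`) and `tukey`
#'   (tibble `comparison`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
compare_doubling_times <- function(estimates) {
  if (!all(c("cell_line", "td_hours") %in% names(estimates))) {
    abort("`estimates` needs columns `cell_line` and `td_hours`")
  }
  counts <- table(estimates$cell_line)
  if (length(counts) < 2L) abort("need >= 2 groups to compare")
  if (any(counts < 2L)) abort("every group needs >= 2 estimates")
  df <- tibble(cell_line = factor(estimates$cell_line),
               td_hours = estimates$td_hours)
  fit <- aov(td_hours ~ cell_line, data = df)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$cell_line
  structure(list(
    anova = tibble(f_statistic = s[["F value"]][1],
                   p_value = s[["Pr(>F)"]][1],
                   df_between = s[["Df"]][1], df_within = s[["Df"]][2]),
    tukey = tibble(comparison = rownames(tk), diff = tk[, "diff"],
                   lwr = tk[, "lwr"], upr = tk[, "upr"],
                   p_adj = tk[, "p adj"])
  ), class = "td_comparison")
}

#' @export
print.td_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.3g\n",
              x$anova$f_statistic, x$anova$p_value))
  print(x$tukey)
  invisible(x)
}

#' Pairwise Tukey comparisons of a doubling-time comparison
#' @param x A `td_comparison`.
#' @param ... Unused.
#' @return The Tukey pairwise tibble.
#' @export
tidy.td_comparison <- function(x, ...) x$tukey

#' ANOVA summary of a doubling-time comparison
#' @param x A `td_comparison`.
#' @param ... Unused.
#' @return The one-row ANOVA tibble.
#' @export
glance.td_comparison <- function(x, ...) x$anova
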