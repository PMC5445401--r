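# Two-class unpaired moderated statistic with a permutation null:
# d_i = (mean_A - mean_B) / (s_i + s0), s_i the pooled standard error and
# s0 a fudge factor chosen from the percentiles of the s_i distribution to
# stabilise the coefficient of variation of d across the range of s.

# Pooled two-sample standard error and mean difference, vectorised over the
# rows of X. Returns list(r = mean difference A-B, s = pooled SE).
two_class_stats <- function(X, a_cols, b_cols) {
  na <- length(a_cols); nb <- length(b_cols)
  A <- X[, a_cols, drop = FALSE]; B <- X[, b_cols, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  ssa <- rowSums((A - ma)^2); ssb <- rowSums((B - mb)^2)
  a <- (1 / na + 1 / nb) / (na + nb - 2)
  list(r = unname(ma - mb), s = unname(sqrt(a * (ssa + ssb))))
}

expr_to_matrix <- function(expression) {
  expression <- validate_expression_matrix(expression)
  X <- as.matrix(expression[, setdiff(names(expression), "probe_id")])
  rownames(X) <- expression$probe_id
  X
}

resolve_groups <- function(X, group_a, group_b) {
  miss <- setdiff(c(group_a, group_b), colnames(X))
  if (length(miss)) abort(paste0("array(s) not in matrix: ", paste(miss, collapse = ", ")))
  if (length(intersect(group_a, group_b))) abort("groups overlap")
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("each group needs >= 2 arrays")
  }
  list(a = match(group_a, colnames(X)), b = match(group_b, colnames(X)))
}

#' Moderated two-class statistic
#'
#' `d_i = (mean_A - mean_B) / (s_i + s0)` per probe, with `s_i` the pooled
#' two-sample standard error.
#'
#' @param expression Expression tibble (`probe_id` + array columns).
#' @param group_a,group_b Character vectors of array ids (>= 2 each).
#' @param s0 Fudge factor, >= 0.
#' @return Tibble `probe_id`, `mean_diff`, `s`, `d`.
#' @export
sam_statistic <- function(expression, group_a, group_b, s0 = 0) {
  if (s0 < 0) abort("`s0` must be >= 0")
  X <- expr_to_matrix(expression)
  g <- resolve_groups(X, group_a, group_b)
  st <- two_class_stats(X, g$a, g$b)
  tibble(probe_id = rownames(X), mean_diff = st$r, s = st$s,
         d = st$r / (st$s + s0))
}

#' Fudge-factor estimate from percentiles of the standard errors
#'
#' Percentile search: for each candidate `s0` = alpha-quantile of the `s_i`
#' distribution (alpha = 0, 0.05, ..., 1), the probes are split into bins by
#' quantiles of `s_i`; within each bin the median absolute deviation of
#' `d_i(s0)` is computed, and the candidate minimising the coefficient of
#' variation of these bin MADs is returned. Deterministic given the input.
#'
#' @inheritParams sam_statistic
#' @param n_bins Number of s-quantile bins (reduced when few probes).
#' @return The chosen `s0` (a single non-negative number).
#' @export
estimate_s0 <- function(expression, group_a, group_b, n_bins = 100L) {
  X <- expr_to_matrix(expression)
  g <- resolve_groups(X, group_a, group_b)
  st <- two_class_stats(X, g$a, g$b)
  s <- st$s; r <- st$r
  if (all(s == 0)) {
    warn("all pooled standard errors are zero; using a small positive s0 floor")
    return(max(abs(r)) * 1e-3 + 1e-8)
  }
  if (max(s) - min(s) < 1e-12) return(s[1])
  alphas <- seq(0, 1, by = 0.05)
  cand <- quantile(s, alphas, names = FALSE, type = 7)
  n_bins <- max(2L, min(n_bins, floor(length(s) / 5)))
  breaks <- unique(quantile(s, seq(0, 1, length.out = n_bins + 1L),
                            names = FALSE))
  bin <- cut(s, breaks = breaks, include.lowest = TRUE)
  cv <- purrr::map_dbl(cand, function(s0) {
    d <- r / (s + s0)
    mads <- tapply(d, bin, mad)
    mads <- mads[!is.na(mads)]
    m <- mean(mads)
    if (m == 0) Inf else sd(mads) / m
  })
  cand[which.min(cv)]
}

# Distinct two-group assignments: columns of indices forming "group A".
# Complementary assignments produce sign-flipped d, so |d| is shared; they
# are kept so that exhaustive counts match a full enumeration of labelings.
group_assignments <- function(n, na) {
  combn(n, na)
}

#' Permutation p-values for the moderated statistic
#'
#' Re-randomises the group labels and counts permuted `|d*|` at least as
#' large as observed `|d|`, per probe. When the number of distinct
#' assignments `choose(n, n_A)` does not exceed `n_perm`, all assignments
#' are enumerated and plain counting is used (so p-values are exact
#' multiples of `1/choose(n, n_A)`); otherwise `n_perm` random assignments
#' are sampled and the add-one convention
#' `p = (1 + count) / (1 + n_perm)` applies. `s0` is held fixed while the
#' pooled standard error is recomputed for every permutation.
#'
#' @inheritParams sam_statistic
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; required in sampled mode.
#' @return Tibble `probe_id`, `mean_diff`, `s`, `d`, `p`, plus attributes
#'   `mode` ("exhaustive"/"sampled"), `n_perm_used`, `s0`.
#' @export
permutation_pvalues <- function(expression, group_a, group_b, s0 = 0,
                                n_perm = 1000L, seed = NULL) {
  if (n_perm < 1L) abort("`n_perm` must be >= 1")
  X <- expr_to_matrix(expression)
  g <- resolve_groups(X, group_a, group_b)
  cols <- c(g$a, g$b)
  Xg <- X[, cols, drop = FALSE]
  na <- length(g$a); n <- length(cols)
  obs <- two_class_stats(Xg, seq_len(na), seq.int(na + 1L, n))
  d_obs <- obs$r / (obs$s + s0)
  abs_obs <- abs(d_obs)

  n_distinct <- choose(n, na)
  exhaustive <- n_distinct <= n_perm
  if (exhaustive) {
    assign_a <- group_assignments(n, na)
  } else {
    if (is.null(seed)) abort("`seed` is required in sampled permutation mode")
    set.seed(seed)
    assign_a <- replicate(n_perm, sample(n, na))
  }
  count <- numeric(nrow(Xg))
  for (k in seq_len(ncol(assign_a))) {
    ia <- assign_a[, k]
    st <- two_class_stats(Xg, ia, setdiff(seq_len(n), ia))
    d_perm <- st$r / (st$s + s0)
    count <- count + (abs(d_perm) >= abs_obs - 1e-12)
  }
  p <- if (exhaustive) count / n_distinct else (1 + count) / (1 + n_perm)

  out <- tibble(probe_id = rownames(Xg), mean_diff = obs$r, s = obs$s,
                d = d_obs, p = p)
  attr(out, "mode") <- if (exhaustive) "exhaustive" else "sampled"
  attr(out, "n_perm_used") <- if (exhaustive) n_distinct else n_perm
  attr(out, "s0") <- s0
  out
}

#' Benjamini--Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment of a p-value vector, capped at 1
#' and monotone in p-rank.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must be finite numbers in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Two-class permutation differential-expression test
#'
#' The full moderated-statistic pipeline: fudge factor from the percentile
#' search (unless supplied), per-probe statistic, permutation p-values and
#' Benjamini--Hochberg q-values.
#'
#' @inheritParams permutation_pvalues
#' @param s0 Fudge factor; `NULL` (default) estimates it via [estimate_s0()].
#' @return An object of class `sam_fit`: list with `table` (tibble
#'   `probe_id`, `mean_diff`, `s`, `d`, `p`, `q`), `s0`, `n_perm`, `mode`,
#'   `seed`, `groups`.
#' @export
sam_test <- function(expression, group_a, group_b, s0 = NULL,
                     n_perm = 1000L, seed = NULL) {
  s0 <- s0 %||% estimate_s0(expression, group_a, group_b)
  res <- permutation_pvalues(expression, group_a, group_b, s0 = s0,
                             n_perm = n_perm, seed = seed)
  tab <- mutate(res, q = bh_fdr(.data$p))
  structure(list(table = as_tibble(tab), s0 = s0,
                 n_perm = attr(res, "n_perm_used"),
                 mode = attr(res, "mode"), seed = seed,
                 groups = list(a = group_a, b = group_b)),
            class = "sam_fit")
}

#' @export
print.sam_fit <- function(x, ...) {
  cat("Two-class permutation DE fit\n")
  cat("  probes:", nrow(x$table), "  s0:", signif(x$s0, 4),
      "  permutations:", x$n_perm, paste0("(", x$mode, ")"), "\n")
  cat("  probes with q < 0.05:", sum(x$table$q < 0.05), "\n")
  invisible(x)
}

#' Per-probe results of a DE fit
#' @param x A `sam_fit`.
#' @param ... Unused.
#' @return The per-probe results tibble.
#' @export
tidy.sam_fit <- function(x, ...) x$table

#' One-row summary of a DE fit
#' @param x A `sam_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n_probes`, `s0`, `n_perm`, `mode`,
#'   `n_significant` (q < 0.05).
#' @export
glance.sam_fit <- function(x, ...) {
  tibble(n_probes = nrow(x$table), s0 = x$s0, n_perm = x$n_perm,
         mode = x$mode, n_significant = sum(x$table$q < 0.05))
}

#' Volcano-style plot of a DE fit
#' @param object A `sam_fit`.
#' @param q_cut Significance threshold to highlight.
#' @param ... Unused.
#' @return A ggplot object: moderated statistic vs -log10 q.
#' @export
autoplot.sam_fit <- function(object, q_cut = 0.05, ...) {
  df <- mutate(object$table, significant = .data$q < q_cut)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d,
                                   y = -log10(pmax(.data$q, 1e-16)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "moderated statistic d", y = "-log10 q") +
    ggplot2::theme_minimal()
}
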