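#' Summarise dome formation per cell line
#'
#' Each flask contributes 21 fields of view (100x magnification, T-25
#' flask); the summary is the mean dome count per field, the mean per 21
#' fields (exactly 21 times the per-field mean), and whether any dome was
#' observed.
#'
#' @param domes Tibble `flask`, `field_index`, `count` for one cell line, or
#'   with an additional `cell_line` column for several.
#' @param n_fields Required fields of view per flask.
#' @return A tibble (one row per line, or one row) with `domes_per_field`,
#'   `domes_per_21_fields`, `dome_positive`, `n_flasks`.
#' @export
dome_summary <- function(domes, n_fields = 21L) {
  if (!all(c("flask", "field_index", "count") %in% names(domes))) {
    abort("`domes` needs columns flask, field_index, count")
  }
  if (any(domes$count < 0) || any(domes$count != round(domes$count))) {
    abort("dome counts must be non-negative integers")
  }
  if (!"cell_line" %in% names(domes)) domes$cell_line <- "line"
  per_flask <- domes %>% count(.data$cell_line, .data$flask)
  if (any(per_flask$n != n_fields)) {
    bad <- per_flask$flask[per_flask$n != n_fields][1]
    abort(paste0("flask '", bad, "' has ", per_flask$n[per_flask$flask == bad][1],
                 " fields; expected ", n_fields))
  }
  out <- domes %>%
    group_by(.data$cell_line) %>%
    summarise(domes_per_field = sum(.data$count) /
                (n_fields * dplyr::n_distinct(.data$flask)),
              dome_positive = any(.data$count > 0),
              n_flasks = dplyr::n_distinct(.data$flask), .groups = "drop") %>%
    mutate(domes_per_21_fields = n_fields * .data$domes_per_field) %>%
    select("cell_line", "domes_per_field", "domes_per_21_fields",
           "dome_positive", "n_flasks")
  if (identical(unique(out$cell_line), "line")) out$cell_line <- NULL
  out
}

#' Combine daily TER means
#'
#' The combined day-5/6/7 value: arithmetic mean of the three daily means,
#' rounded to two decimals (round-half-to-even).
#'
#' @param daily_means Numeric vector of per-day mean TER values.
#' @return A single number, rounded to two decimals.
#' @export
ter_combine_days <- function(daily_means) {
  if (!is.numeric(daily_means) || any(!is.finite(daily_means))) {
    abort("`daily_means` must be finite numbers")
  }
  round(mean(daily_means), 2)
}

#' Summarise transepithelial resistance per cell line
#'
#' Per filter: the mean of the raw readings minus the bare-filter blank,
#' scaled by the membrane area. Per day: mean and SEM over replicate
#' filters. Combined: arithmetic mean of the daily means (two decimals).
#'
#' @param ter Tibble `filter`, `day`, `reading_index`, `resistance_ohm`,
#'   `blank_ohm`, `area_cm2`, optionally `cell_line`.
#' @param days Days that must all be present.
#' @return A list with `daily` (tibble `cell_line`, `day`, `mean_ter`,
#'   `sem_ter`, `n_filters`) and `combined` (tibble `cell_line`,
#'   `combined_ter`).
#' @export
ter_summary <- function(ter, days = c(5L, 6L, 7L)) {
  need <- c("filter", "day", "reading_index", "resistance_ohm",
            "blank_ohm", "area_cm2")
  miss <- setdiff(need, names(ter))
  if (length(miss)) abort(paste0("`ter` missing column(s): ",
                                 paste(miss, collapse = ", ")))
  if (any(ter$resistance_ohm <= 0) || any(ter$area_cm2 <= 0)) {
    abort("readings and membrane area must be > 0")
  }
  if (!"cell_line" %in% names(ter)) ter$cell_line <- "line"
  missing_days <- setdiff(days, unique(ter$day))
  if (length(missing_days)) {
    abort(paste0("missing TER day(s): ", paste(missing_days, collapse = ", ")))
  }
  per_filter <- ter %>%
    filter(.data$day %in% days) %>%
    group_by(.data$cell_line, .data$day, .data$filter) %>%
    summarise(ter = (mean(.data$resistance_ohm) - .data$blank_ohm[1]) *
                .data$area_cm2[1], .groups = "drop")
  daily <- per_filter %>%
    group_by(.data$cell_line, .data$day) %>%
    summarise(mean_ter = mean(.data$ter),
              sem_ter = sd(.data$ter) / sqrt(dplyr::n()),
              n_filters = dplyr::n(), .groups = "drop")
  combined <- daily %>%
    group_by(.data$cell_line) %>%
    summarise(combined_ter = ter_combine_days(.data$mean_ter), .groups = "drop")
  if (identical(unique(daily$cell_line), "line")) {
    daily$cell_line <- NULL; combined$cell_line <- NULL
  }
  list(daily = daily, combined = combined)
}

#' Associate the dome phenotype with gene-set expression
#'
#' Rank-sum statistic of per-line summary expression between dome-positive
#' and dome-negative lines, with a permutation p-value over line-label
#' reassignments: exhaustive when `choose(n, n_positive)` is small,
#' otherwise seeded sampling. The default alternative is one-sided
#' ("greater": dome-positive lines express the set more highly).
#'
#' @param phenotype Tibble with columns `cell_line`, `dome_positive`
#'   (logical) and `set_expression` (per-line mean expression of the probe
#'   set under test).
#' @param alternative `"greater"` or `"two.sided"`.
#' @param max_exhaustive Enumerate all assignments when their count does not
#'   exceed this; otherwise sample `n_perm` with `seed`.
#' @param n_perm,seed Sampling controls for the non-exhaustive mode.
#' @return One-row tibble: `rank_sum` (sum of ranks of the dome-positive
#'   lines), `p_value`, `mode`, `n_assignments`.
#' @export
dome_geneset_association <- function(phenotype,
                                     alternative = c("greater", "two.sided"),
                                     max_exhaustive = 20000L,
                                     n_perm = 10000L, seed = NULL) {
  alternative <- match.arg(alternative)
  need <- c("cell_line", "dome_positive", "set_expression")
  if (!all(need %in% names(phenotype))) {
    abort("`phenotype` needs columns cell_line, dome_positive, set_expression")
  }
  pos <- as.logical(phenotype$dome_positive)
  x <- phenotype$set_expression
  n <- length(x); k <- sum(pos)
  if (k == 0L || k == n) abort("both phenotype classes must be present")
  r <- rank(x)
  stat <- function(idx) sum(r[idx])
  w_obs <- stat(which(pos))
  mu <- k * (n + 1) / 2
  score <- function(w) if (alternative == "greater") w else abs(w - mu)
  obs <- score(w_obs)

  n_assign <- choose(n, k)
  if (n_assign <= max_exhaustive) {
    idx <- combn(n, k)
    ws <- apply(idx, 2, stat)
    p <- mean(score(ws) >= obs - 1e-12)
    mode <- "exhaustive"
  } else {
    if (is.null(seed)) abort("`seed` is required in sampled mode")
    set.seed(seed)
    ws <- replicate(n_perm, stat(sample(n, k)))
    p <- (1 + sum(score(ws) >= obs - 1e-12)) / (1 + n_perm)
    mode <- "sampled"
    n_assign <- n_perm
  }
  tibble(rank_sum = w_obs, p_value = p, mode = mode,
         n_assignments = n_assign)
}

#' Published phenotype summary tables for the MCF-7 construct panel
#'
#' Plain-text copies of the dome-formation and transepithelial-resistance
#' summary tables for the eight MCF-7 metallothionein construct lines,
#' bundled as worked-example inputs. `mcf7_ter_daily()` returns per-line
#' daily TER means and SEMs for days 5--7 together with the combined value
#' as originally printed; `mcf7_dome_table()` returns the per-field and
#' per-21-field dome averages.
#'
#' @return A tibble.
#' @export
mcf7_ter_daily <- function() {
  readr::read_tsv(system.file("extdata", "mcf7_ter_daily_means.tsv",
                              package = "ohclust"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname mcf7_ter_daily
#' @export
mcf7_dome_table <- function() {
  readr::read_tsv(system.file("extdata", "mcf7_dome_summary.tsv",
                              package = "ohclust"),
                  show_col_types = FALSE, progress = FALSE)
}
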