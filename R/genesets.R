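#' Reference (parental) expression profile
#'
#' Per-probe arithmetic mean intensity over all reference arrays, the
#' denominator of every fold change.
#'
#' @param expression Expression tibble (`probe_id` + array columns).
#' @param samples Sample sheet tibble; rows with `is_reference = TRUE`
#'   define the parental arrays.
#' @return A tibble `probe_id`, `reference_mean`.
#' @export
reference_profile <- function(expression, samples) {
  expression <- validate_expression_matrix(expression)
  samples <- validate_sample_sheet(samples)
  check_arrays_covered(expression, samples)
  ref_arrays <- samples$array_id[samples$is_reference]
  ref_arrays <- intersect(ref_arrays, names(expression))
  if (length(ref_arrays) == 0L) {
    abort("no reference (parental) array available for the reference profile")
  }
  vals <- as.matrix(expression[, ref_arrays, drop = FALSE])
  tibble(probe_id = expression$probe_id, reference_mean = rowMeans(vals))
}

#' Per-probe fold changes of one array over the reference profile
#'
#' `FC = intensity / max(reference_mean, floor)`. The floor keeps the ratio
#' finite when a probe has zero mean reference intensity.
#'
#' @param expression Expression tibble.
#' @param array_id Column name of the array to compare.
#' @param profile Output of [reference_profile()].
#' @param floor Positive intensity floor for the denominator. Default: the
#'   smallest positive value in the expression matrix.
#' @return A tibble `probe_id`, `fold_change`.
#' @export
fold_changes <- function(expression, array_id, profile, floor = NULL) {
  expression <- validate_expression_matrix(expression)
  if (!array_id %in% names(expression)) {
    abort(paste0("array '", array_id, "' not found in expression matrix"))
  }
  floor <- floor %||% min_positive(expression)
  stopifnot_scalar_number(floor, "floor", positive = TRUE)
  merged <- dplyr::left_join(expression[, c("probe_id", array_id)], profile,
                             by = "probe_id")
  if (anyNA(merged$reference_mean)) {
    abort("reference profile does not cover every probe")
  }
  tibble(probe_id = merged$probe_id,
         fold_change = merged[[array_id]] / pmax(merged$reference_mean, floor))
}

min_positive <- function(expression) {
  vals <- as.matrix(expression[, setdiff(names(expression), "probe_id")])
  pos <- vals[vals > 0]
  if (length(pos) == 0L) 1 else min(pos)
}

# Membership rule shared by build_gene_set*() — returns tagged probe ids.
select_members <- function(probe_id, fc, threshold, mode) {
  if (threshold <= 1) abort("`threshold` must be > 1")
  up <- fc > threshold
  dn <- fc < 1 / threshold
  switch(mode,
    "up" = probe_id[up],
    "two-sided" = probe_id[up | dn],
    "signed" = c(paste0(probe_id[up], "+"), paste0(probe_id[dn], "-"))
  )
}

#' Build fold-change gene sets
#'
#' For each non-reference array (or each line, from its mean profile, with
#' `per_line = TRUE`), collects the probes whose fold change over the
#' parental reference passes the threshold — the sets A, B between which
#' overlap distance is computed.
#'
#' Modes: `"up"` keeps probes with `FC > threshold` (strict, so FC exactly
#' equal to the threshold is excluded); `"two-sided"` adds probes with
#' `FC < 1/threshold`; `"signed"` is two-sided but tags members with the
#' direction (`"+"`/`"-"` suffix) so that induction and suppression of the
#' same probe count as different set elements.
#'
#' @inheritParams reference_profile
#' @param threshold Fold-change cutoff (> 1), default 2.
#' @param mode `"up"` (default), `"two-sided"` or `"signed"`.
#' @param per_line Build one set per cell line from the line's mean profile
#'   instead of one per array.
#' @param floor Denominator floor, see [fold_changes()].
#' @param include_reference Also build sets for reference arrays (default
#'   FALSE: fold change is defined for the transformed lines).
#' @return A tibble `array_id`, `probe_id` (long format; one row per set
#'   member) with attributes `threshold` and `mode`. Arrays whose set is
#'   empty still appear in attribute `set_ids`.
#' @export
build_gene_sets <- function(expression, samples, threshold = 2,
                            mode = c("up", "two-sided", "signed"),
                            per_line = FALSE, floor = NULL,
                            include_reference = FALSE) {
  mode <- match.arg(mode)
  if (threshold <= 1) abort("`threshold` must be > 1")
  expression <- validate_expression_matrix(expression)
  samples <- validate_sample_sheet(samples)
  check_arrays_covered(expression, samples)
  profile <- reference_profile(expression, samples)
  floor <- floor %||% min_positive(expression)

  keep <- if (include_reference) samples else filter(samples, !.data$is_reference)
  if (per_line) {
    units <- unique(keep$cell_line)
    get_values <- function(u) {
      cols <- keep$array_id[keep$cell_line == u]
      rowMeans(as.matrix(expression[, cols, drop = FALSE]))
    }
  } else {
    units <- keep$array_id
    get_values <- function(u) expression[[u]]
  }

  sets <- purrr::map(units, function(u) {
    fc <- get_values(u) / pmax(profile$reference_mean, floor)
    members <- select_members(expression$probe_id, fc, threshold, mode)
    if (length(members)) tibble(array_id = u, probe_id = members) else NULL
  })
  out <- bind_rows(sets)
  if (nrow(out) == 0L) out <- tibble(array_id = character(), probe_id = character())
  attr(out, "threshold") <- threshold
  attr(out, "mode") <- mode
  attr(out, "set_ids") <- units
  out
}

#' Build a single gene set from fold changes
#'
#' The elementary set rule applied to one array's fold-change table.
#'
#' @param fc Tibble `probe_id`, `fold_change` from [fold_changes()].
#' @param threshold Cutoff (> 1).
#' @param mode See [build_gene_sets()].
#' @return Character vector of member probe ids.
#' @export
build_gene_set <- function(fc, threshold = 2,
                           mode = c("up", "two-sided", "signed")) {
  mode <- match.arg(mode)
  select_members(fc$probe_id, fc$fold_change, threshold, mode)
}
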