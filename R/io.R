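#' Read a probes-by-arrays expression matrix
#'
#' Reads a tabular intensity matrix: first column probe identifiers, header
#' row array identifiers, numeric body. Intensities must be finite and
#' non-negative; the input row and column order is preserved, never sorted.
#'
#' @param path Path to a TSV (default) or CSV file.
#' @param delim Field delimiter, `"\t"` or `","`.
#' @return A tibble with a `probe_id` character column followed by one
#'   numeric column per array.
#' @export
read_expression_matrix <- function(path, delim = "\t") {
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, na = character())
  names(tbl)[1] <- "probe_id"
  tbl$probe_id <- as.character(tbl$probe_id)
  for (j in seq_along(tbl)[-1]) {
    v <- suppressWarnings(as.numeric(tbl[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      abort(paste0("non-numeric or non-finite intensity '", tbl[[j]][bad[1]],
                   "' at row ", bad[1], " (probe '", tbl$probe_id[bad[1]],
                   "'), column '", names(tbl)[j], "'"))
    }
    tbl[[j]] <- v
  }
  validate_expression_matrix(tbl)
}

#' Validate an expression matrix tibble
#'
#' Checks the invariants the pipeline relies on: unique probe and array
#' identifiers, and finite non-negative intensities.
#'
#' @param expression A tibble: `probe_id` column plus numeric array columns.
#' @return The validated tibble, invisibly usable downstream.
#' @export
validate_expression_matrix <- function(expression) {
  expression <- as_tibble(expression)
  if (!"probe_id" %in% names(expression) || ncol(expression) < 2L) {
    abort("expression matrix needs a `probe_id` column and >= 1 array column")
  }
  dup_p <- unique(expression$probe_id[duplicated(expression$probe_id)])
  if (length(dup_p)) {
    abort(paste0("duplicate probe identifier(s): ",
                 paste(head(dup_p, 5), collapse = ", ")))
  }
  arrays <- setdiff(names(expression), "probe_id")
  dup_a <- unique(arrays[duplicated(arrays)])
  if (length(dup_a)) {
    abort(paste0("duplicate array identifier(s): ", paste(dup_a, collapse = ", ")))
  }
  for (a in arrays) {
    v <- expression[[a]]
    if (!is.numeric(v)) abort(paste0("array column '", a, "' is not numeric"))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      abort(paste0("invalid intensity ", v[bad[1]], " at row ", bad[1],
                   " (probe '", expression$probe_id[bad[1]], "'), column '",
                   a, "': values must be finite and >= 0"))
    }
  }
  expression
}

#' Read a sample sheet
#'
#' One row per array: `array_id`, `cell_line`, `replicate`, and the logical
#' flags `is_reference` (parental line), `has_ct` (carries the C-terminal
#' domain) and `has_nt` (carries the N-terminal domain).
#'
#' @inheritParams read_expression_matrix
#' @return A validated tibble with the six columns above.
#' @export
read_sample_sheet <- function(path, delim = "\t") {
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  validate_sample_sheet(tbl)
}

#' Validate a sample sheet tibble
#' @param samples A data frame with columns `array_id`, `cell_line`,
#'   `replicate`, `is_reference`, `has_ct`, `has_nt`.
#' @return The validated tibble with flags parsed as logicals.
#' @export
validate_sample_sheet <- function(samples) {
  samples <- as_tibble(samples)
  need <- c("array_id", "cell_line", "replicate", "is_reference", "has_ct", "has_nt")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    abort(paste0("sample sheet missing column(s): ", paste(miss, collapse = ", ")))
  }
  samples$array_id <- as.character(samples$array_id)
  samples$cell_line <- as.character(samples$cell_line)
  samples$replicate <- as.character(samples$replicate)
  for (f in c("is_reference", "has_ct", "has_nt")) {
    v <- samples[[f]]
    if (is.character(v)) v <- toupper(trimws(v)) %in% c("TRUE", "T", "1", "YES")
    v <- as.logical(v)
    if (anyNA(v)) abort(paste0("flag column '", f, "' has unparseable values"))
    samples[[f]] <- v
  }
  dup <- unique(samples$array_id[duplicated(samples$array_id)])
  if (length(dup)) {
    abort(paste0("duplicate array_id in sample sheet: ", paste(dup, collapse = ", ")))
  }
  samples[need]
}

# Cross-check that every matrix array is described by the sheet.
check_arrays_covered <- function(expression, samples) {
  arrays <- setdiff(names(expression), "probe_id")
  miss <- setdiff(arrays, samples$array_id)
  if (length(miss)) {
    abort(paste0("array(s) in matrix missing from sample sheet: ",
                 paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Write / read a labelled distance matrix
#'
#' The matrix is stored as a square labelled TSV at full `%.17g` precision,
#' so a write/read round trip reproduces the values exactly.
#'
#' @param D A symmetric numeric matrix with zero diagonal and entries in
#'   \[0, 1\], with dimnames.
#' @param path Output (or input) file path.
#' @return `write_distance_matrix()` returns `path` invisibly;
#'   `read_distance_matrix()` returns the validated matrix.
#' @export
write_distance_matrix <- function(D, path) {
  D <- validate_distance_matrix(D)
  tbl <- tibble(label = rownames(D))
  for (j in seq_len(ncol(D))) {
    tbl[[colnames(D)[j]]] <- sprintf("%.17g", D[, j])
  }
  write_atomic(path, function(p) {
    readr::write_tsv(tbl, p, progress = FALSE)
  })
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  # base parser: correctly-rounded strtod, so %.17g round-trips bit-exactly
  tbl <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  labs <- as.character(tbl[[1]])
  D <- as.matrix(tbl[, -1, drop = FALSE])
  storage.mode(D) <- "double"
  rownames(D) <- labs
  validate_distance_matrix(D)
}

#' Validate a distance matrix
#' @param D Square numeric matrix; symmetric, zero diagonal, entries in \[0,1\].
#' @return The matrix, with dimnames guaranteed.
#' @export
validate_distance_matrix <- function(D) {
  if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D)) {
    abort("distance matrix must be a square numeric matrix")
  }
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) %||% paste0("item", seq_len(nrow(D)))
  }
  if (is.null(colnames(D))) colnames(D) <- rownames(D)
  if (!identical(rownames(D), colnames(D))) {
    abort("distance matrix row and column labels differ")
  }
  if (anyDuplicated(rownames(D))) abort("duplicate distance-matrix labels")
  if (any(!is.finite(D)) || any(D < 0) || any(D > 1)) {
    abort("distance entries must be finite and in [0, 1]")
  }
  if (any(abs(D - t(D)) > 1e-12)) abort("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-12)) abort("distance matrix diagonal is not zero")
  D
}

#' Write gene sets
#'
#' Serialises a long gene-set table either as two-column TSV
#' (`array_id`, `probe_id`) or as GMT lines (set name, description, members).
#'
#' @param gene_sets Tibble with columns `array_id` and `probe_id`.
#' @param path Output path.
#' @param format `"tsv"` or `"gmt"`.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gene_sets, path, format = c("tsv", "gmt")) {
  format <- match.arg(format)
  write_atomic(path, function(p) {
    if (format == "tsv") {
      readr::write_tsv(gene_sets[, c("array_id", "probe_id")], p, progress = FALSE)
    } else {
      lines <- gene_sets %>%
        group_by(.data$array_id) %>%
        summarise(line = paste(c(.data$array_id[1], "fold-change gene set",
                                 .data$probe_id), collapse = "\t"),
                  .groups = "drop")
      writeLines(lines$line, p)
    }
  })
}
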