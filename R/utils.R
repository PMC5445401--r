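#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects.
#' Used to score recovery of planted group structure by a dendrogram cut.
#'
#' @param x,y Vectors of cluster labels of equal length. Any atomic type;
#'   labels are compared within each vector only.
#' @return A single number, 1 for identical partitions (up to relabeling),
#'   around 0 for independent ones.
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must label the same objects (equal length).")
  }
  tab <- table(x, y)
  if (length(tab) == 1L) return(1)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- ch2(as.vector(tab))
  sum_i <- ch2(rowSums(tab))
  sum_j <- ch2(colSums(tab))
  n2 <- ch2(sum(tab))
  expected <- sum_i * sum_j / n2
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Atomic write: materialise via `writer(tmp)` then rename into place, so a
# failure mid-write never leaves a partial artifact at `path`.
write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    abort(paste0("failed to move temporary file into place at '", path, "'"))
  }
  invisible(path)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number."))
  }
  if (positive && x <= 0) abort(paste0("`", name, "` must be > 0."))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
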