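# Small in-code fixtures shared across test files.

tiny_matrix <- function() {
  tibble::tibble(
    probe_id = c("p1", "p2"),
    arr1 = c(10, 5),
    arr2 = c(20, 5)
  )
}

tiny_sheet <- function() {
  tibble::tibble(
    array_id = c("arr1", "arr2"),
    cell_line = c("parent", "lineA"),
    replicate = c("a", "a"),
    is_reference = c(TRUE, FALSE),
    has_ct = c(FALSE, TRUE),
    has_nt = c(FALSE, FALSE)
  )
}

# Expression tibble built from an explicit probes-by-arrays matrix.
expr_from_matrix <- function(M, probes = NULL, arrays = NULL) {
  probes <- probes %||% rownames(M) %||% paste0("p", seq_len(nrow(M)))
  arrays <- arrays %||% colnames(M) %||% paste0("a", seq_len(ncol(M)))
  out <- tibble::tibble(probe_id = probes)
  for (j in seq_len(ncol(M))) out[[arrays[j]]] <- M[, j]
  out
}

# Two-line, two-group study with chosen per-probe group means and sd.
two_group_expr <- function(n_probes = 50, n_per_group = 3, delta = 0,
                           sd = 1, seed = 42, base = 100) {
  set.seed(seed)
  M <- matrix(rnorm(n_probes * 2 * n_per_group, base, sd), n_probes)
  M[, seq_len(n_per_group)] <- M[, seq_len(n_per_group)] + delta
  M <- pmax(M, 0.01)
  arrays <- c(paste0("A", seq_len(n_per_group)), paste0("B", seq_len(n_per_group)))
  expr_from_matrix(M, arrays = arrays)
}

random_distance_matrix <- function(n) {
  M <- matrix(runif(n * n), n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  rownames(M) <- colnames(M) <- paste0("l", seq_len(n))
  M
}

random_gene_set <- function(universe_size = 30, max_size = 15) {
  k <- sample(0:max_size, 1)
  sample(paste0("g", seq_len(universe_size)), k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
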