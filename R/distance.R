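#' Overlap (Jaccard) distance between two gene sets
#'
#' `D(A, B) = 1 - |A intersect B| / |A union B|`: 0 for identical sets,
#' 1 for disjoint non-empty sets. Two empty sets are treated as identical
#' objects (distance 0, with a warning); exactly one empty set gives 1.
#'
#' @param a,b Character vectors of set members (duplicates ignored).
#' @return A single number in \[0, 1\].
#' @export
overlap_distance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) {
    warn("overlap_distance: both sets empty; returning 0 (identical objects)")
    return(0)
  }
  n_int <- length(intersect(a, b))
  n_uni <- length(a) + length(b) - n_int
  1 - n_int / n_uni
}

#' Pairwise overlap-distance matrix of gene sets
#'
#' @param gene_sets Long tibble `array_id`, `probe_id` as produced by
#'   [build_gene_sets()]. The attribute `set_ids`, when present, supplies
#'   the full roster of sets (so empty sets keep their place).
#' @param set_ids Optional explicit character vector of set labels.
#' @return A symmetric numeric matrix with zero diagonal, labelled by set id.
#' @export
gene_set_distance <- function(gene_sets, set_ids = NULL) {
  set_ids <- set_ids %||% attr(gene_sets, "set_ids") %||% unique(gene_sets$array_id)
  set_ids <- as.character(set_ids)
  if (length(set_ids) < 2L) abort("need >= 2 gene sets for a distance matrix")
  if (anyDuplicated(set_ids)) abort("duplicate gene-set labels")
  members <- purrr::map(setNames(set_ids, set_ids), function(id) {
    unique(gene_sets$probe_id[gene_sets$array_id == id])
  })
  n <- length(set_ids)
  D <- matrix(0, n, n, dimnames = list(set_ids, set_ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      D[i, j] <- D[j, i] <- overlap_distance(members[[i]], members[[j]])
    }
  }
  validate_distance_matrix(D)
}
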