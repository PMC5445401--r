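#' Ward-linkage agglomeration of a precomputed distance matrix
#'
#' Agglomerative clustering driven by the Lance--Williams recurrence for
#' Ward's criterion, applied directly to the supplied dissimilarities. Two
#' variants are offered: `"ward.D2"` (default) squares the dissimilarities
#' before updating and reports merge heights on the original scale (square
#' root), `"ward.D"` applies the recurrence to the dissimilarities as given.
#' Ties in the minimum inter-cluster distance are broken toward the lowest
#' (i, j) pair in current label order, so the merge sequence is
#' deterministic. No height-monotonicity repair is applied; with arbitrary
#' (non-Euclidean) dissimilarities Ward can produce inversions, which are
#' reported via a message.
#'
#' @param D Symmetric distance matrix with labels (see
#'   [validate_distance_matrix()]; any non-negative symmetric matrix with a
#'   zero diagonal is accepted here, entries need not be <= 1).
#' @param variant `"ward.D2"` or `"ward.D"`.
#' @return An object of class `c("ohc_tree", "hclust")`: `merge` (n-1 x 2,
#'   negative entries are leaves), `height`, `order`, `labels`, `method`.
#'   Compatible with [stats::cutree()] and `plot()`.
#' @export
ward_agglomerate <- function(D, variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  if (!is.matrix(D) || nrow(D) != ncol(D) || !is.numeric(D)) {
    abort("`D` must be a square numeric matrix")
  }
  if (any(!is.finite(D)) || any(D < 0)) abort("distances must be finite and >= 0")
  if (any(abs(D - t(D)) > 1e-12)) abort("`D` must be symmetric")
  n <- nrow(D)
  if (n < 2L) abort("need >= 2 objects to cluster")
  labels <- rownames(D) %||% paste0("item", seq_len(n))

  W <- if (variant == "ward.D2") D^2 else D
  size <- rep(1, n)
  id <- -seq_len(n)            # hclust coding: negative = singleton leaf
  active <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in seq.int(ii + 1L, length(active))) {
        i <- active[ii]; j <- active[jj]
        if (W[i, j] < best_d) { best_d <- W[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    height[step] <- if (variant == "ward.D2") sqrt(best_d) else best_d
    pair <- c(id[i], id[j])
    # hclust row convention: two leaves ascending by original index
    # (-1 before -2), leaf before cluster, two clusters ascending.
    merge[step, ] <- if (all(pair < 0)) sort(pair, decreasing = TRUE)
                     else if (all(pair > 0)) sort(pair)
                     else c(min(pair), max(pair))

    others <- setdiff(active, c(i, j))
    ni <- size[i]; nj <- size[j]
    for (k in others) {
      nk <- size[k]
      W[i, k] <- W[k, i] <-
        ((ni + nk) * W[i, k] + (nj + nk) * W[j, k] - nk * W[i, j]) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    id[i] <- step
    active <- setdiff(active, j)
  }

  if (any(diff(height) < -1e-10)) {
    inform(paste0("ward_agglomerate: ", sum(diff(height) < -1e-10),
                  " height inversion(s) present (non-Euclidean input)"))
  }

  tree <- structure(
    list(merge = merge, height = height, order = tree_order(merge, n),
         labels = labels, method = variant,
         call = match.call(), dist.method = "overlap"),
    class = c("ohc_tree", "hclust"))
  tree
}

# Leaf order for plotting: left-to-right traversal of the merge tree.
tree_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' Cut a linkage tree into k clusters
#'
#' @param tree An `ohc_tree` from [ward_agglomerate()].
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return A tibble `array_id`, `cluster` (integer labels, deterministic:
#'   clusters numbered by first appearance in leaf input order).
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n || k != round(k)) {
    abort(paste0("`k` must be an integer in [1, ", n, "]"))
  }
  cl <- cutree(tree, k = k)
  tibble(array_id = tree$labels, cluster = as.integer(cl))
}

#' Export a linkage tree as a Newick string
#'
#' Branch lengths follow the midpoint (ultrametric) convention: every leaf
#' sits at depth `height/2` below each ancestor node, so two leaves merged
#' at height h are rendered `(a:h/2,b:h/2)`.
#'
#' @param tree An `ohc_tree`.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string terminated by `";"`.
#' @export
to_newick <- function(tree, digits = 10) {
  fmt <- function(x) sprintf("%.*g", digits, x)
  node_str <- function(node, parent_h) {
    if (node < 0) {
      return(paste0(tree$labels[-node], ":", fmt(parent_h / 2)))
    }
    h <- tree$height[node]
    paste0("(", node_str(tree$merge[node, 1], h), ",",
           node_str(tree$merge[node, 2], h), "):",
           fmt((parent_h - h) / 2))
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  paste0("(", node_str(tree$merge[root, 1], h), ",",
         node_str(tree$merge[root, 2], h), ");")
}

#' Merge table of a linkage tree
#'
#' @param x An `ohc_tree`.
#' @param ... Unused.
#' @return A tibble with one row per merge: `cluster_i`, `cluster_j`
#'   (hclust coding: negative = leaf), `height`, `size` of the new cluster.
#' @export
tidy.ohc_tree <- function(x, ...) {
  sizes <- numeric(nrow(x$merge))
  leafcount <- function(v) if (v < 0) 1 else sizes[v]
  for (s in seq_len(nrow(x$merge))) {
    sizes[s] <- leafcount(x$merge[s, 1]) + leafcount(x$merge[s, 2])
  }
  tibble(cluster_i = x$merge[, 1], cluster_j = x$merge[, 2],
         height = x$height, size = as.integer(sizes))
}

#' Dendrogram plot of a linkage tree
#'
#' @param object An `ohc_tree`.
#' @param ... Unused.
#' @return A ggplot object drawing the dendrogram with leaf labels.
#' @export
autoplot.ohc_tree <- function(object, ...) {
  n <- length(object$labels)
  pos <- setNames(seq_len(n), object$order)  # leaf -> x position
  xcoord <- numeric(nrow(object$merge))
  hcoord <- object$height
  segs <- list()
  node_x <- function(v) if (v < 0) pos[[as.character(-v)]] else xcoord[v]
  node_h <- function(v) if (v < 0) 0 else hcoord[v]
  for (s in seq_len(nrow(object$merge))) {
    x1 <- node_x(object$merge[s, 1]); x2 <- node_x(object$merge[s, 2])
    h1 <- node_h(object$merge[s, 1]); h2 <- node_h(object$merge[s, 2])
    xcoord[s] <- (x1 + x2) / 2
    segs[[s]] <- tibble(
      x = c(x1, x1, x2), xend = c(x1, x2, x2),
      y = c(h1, hcoord[s], hcoord[s]), yend = c(hcoord[s], hcoord[s], h2))
  }
  seg <- bind_rows(segs)
  leaves <- tibble(x = seq_len(n), label = object$labels[object$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg, ggplot2::aes(x = .data$x, y = .data$y,
                          xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_text(data = leaves, ggplot2::aes(x = .data$x, y = 0,
                       label = .data$label), angle = 90, hjust = 1.05, size = 3) +
    ggplot2::scale_y_continuous("merge height") +
    ggplot2::scale_x_continuous(NULL, breaks = NULL) +
    ggplot2::coord_cartesian(clip = "off") +
    ggplot2::theme_minimal()
}
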