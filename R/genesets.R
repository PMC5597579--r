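#' Exact two-group (high/low) classification of 1-D scores
#'
#' The k = 2 k-means partition of one-dimensional data, computed exactly:
#' for 1-D data the optimal two-cluster solution is a threshold on the
#' sorted values, so scanning the n - 1 sorted-order cut points and taking
#' the minimum within-cluster sum of squares yields the global optimum with
#' no dependence on initialization. A \code{seed} argument is accepted for
#' interface compatibility but has no effect.
#'
#' @param scores named numeric vector (names become set members; unnamed
#'   input is labelled by index).
#' @param seed ignored (the exact algorithm is deterministic).
#' @return List with \code{high} and \code{low} (names of members, the
#'   "high" cluster having the larger mean), \code{threshold} (midpoint
#'   between the clusters' closest values), and \code{withinss}.
#' @export
kmeans_high_low <- function(scores, seed = NULL) {
  x <- as.numeric(scores)
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_along(x))
  if (length(x) < 2 || length(unique(x)) < 2)
    stop("degenerate clustering: need at least two distinct score values")
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  cs <- cumsum(xs); tot <- cs[n]
  k <- seq_len(n - 1)
  # within-cluster SS = total SS - between SS for each split after position k
  wss <- (sum(xs^2) - cs[k]^2 / k - (tot - cs[k])^2 / (n - k))
  kbest <- which.min(wss)
  low_idx <- o[seq_len(kbest)]
  high_idx <- o[(kbest + 1):n]
  list(high = ids[high_idx], low = ids[low_idx],
       threshold = (xs[kbest] + xs[kbest + 1]) / 2,
       withinss = wss[kbest])
}

#' Hypergeometric over-enrichment test for the overlap of two gene sets
#'
#' Upper-tail p-value for the observed overlap between two subsets of a
#' common gene universe: \eqn{P(X \ge k)} for X hypergeometric, i.e. the
#' probability of seeing at least the observed overlap if set B were drawn
#' at random from the universe independently of set A. An overlap of 0 gives
#' p = 1 exactly.
#'
#' @param universe character vector of all genes considered.
#' @param set_a,set_b character vectors; must be subsets of \code{universe}.
#' @return An object of class \code{gene_set_overlap} with
#'   \code{universe_size}, \code{set_a_size}, \code{set_b_size},
#'   \code{overlap}, \code{expected_overlap} and \code{p_value}.
#' @export
hypergeom_overlap <- function(universe, set_a, set_b) {
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe)) stop("set_a is not a subset of the universe")
  if (!all(set_b %in% universe)) stop("set_b is not a subset of the universe")
  U <- length(universe); a <- length(set_a); b <- length(set_b)
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, a, U - a, b, lower.tail = FALSE)
  structure(list(universe_size = U, set_a_size = a, set_b_size = b,
                 overlap = k, expected_overlap = a * b / U, p_value = p),
            class = "gene_set_overlap")
}

#' @export
print.gene_set_overlap <- function(x, ...) {
  cat(sprintf(
    "<gene_set_overlap> %d / %d vs %d in universe %d (expected %.2f), p = %.4g\n",
    x$overlap, x$set_a_size, x$set_b_size, x$universe_size,
    x$expected_overlap, x$p_value))
  invisible(x)
}
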