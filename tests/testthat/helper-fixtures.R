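# Small layouts/tracks built in code, and brute-force oracles kept
# deliberately naive and independent of the package internals.

toy_layout <- function(n_bins, bin_width = 50, name = "chr1") {
  genome_layout(data.frame(name = name, length = n_bins * bin_width))
}

toy_track <- function(values, bin_width = 50, type = "count", name = "chr1") {
  lay <- toy_layout(length(values), bin_width, name)
  binned_track(lay, bin_width, stats::setNames(list(as.numeric(values)), name),
               type = type)
}

# SES oracle: for every cut point k, recompute the cumulative-fraction gap
# with explicit sums over the head of the IP-ascending ordering, take the
# first maximal gap, and form the background ratio.
ses_oracle <- function(ip_vals, input_vals) {
  o <- order(ip_vals)
  ti <- sum(ip_vals); tn <- sum(input_vals)
  gaps <- vapply(seq_along(ip_vals), function(k) {
    head_idx <- o[seq_len(k)]
    sum(input_vals[head_idx]) / tn - sum(ip_vals[head_idx]) / ti
  }, 0)
  k <- match(max(gaps), gaps)
  bg_ip <- sum(ip_vals[o[seq_len(k)]])
  bg_in <- sum(input_vals[o[seq_len(k)]])
  if (bg_ip <= 0 || bg_in <= 0) return(NULL)   # degenerate
  (bg_ip / ti) / (bg_in / tn)
}

# Exact 1-D 2-means oracle: enumerate every nontrivial binary labeling.
kmeans2_oracle <- function(x) {
  n <- length(x)
  best <- Inf; best_high <- NULL
  for (mask in 1:(2^n - 2)) {
    lab <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    a <- x[lab]; b <- x[!lab]
    wss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (wss < best - 1e-12) {
      best <- wss
      best_high <- if (mean(a) >= mean(b)) which(lab) else which(!lab)
    }
  }
  list(high = sort(best_high), withinss = best)
}

# Hypergeometric upper-tail oracle: enumerate every possible draw of |B|
# elements from the universe and count those overlapping A at least k times.
hyper_oracle <- function(U, a, b, k) {
  draws <- utils::combn(U, b)
  hits <- colSums(draws <= a)        # A is taken as elements 1..a
  mean(hits >= k)
}
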