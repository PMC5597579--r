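#' Normalized per-bin fold-change track
#'
#' Forms the per-bin ratio \eqn{(N \cdot IP + p) / (input + p)} between two
#' count tracks, where N is a normalization factor (from spike-in
#' calibration, SES, or 1) and p an optional pseudocount. With
#' \code{log2 = TRUE} the ratio is log2-transformed. The result is a
#' ratio-type [binned_track()].
#'
#' @param ip,input [binned_track()]s on the same layout and bin width.
#' @param n_factor positive normalization factor applied to the numerator.
#' @param pseudocount non-negative pseudocount added to both numerator and
#'   denominator. With \code{pseudocount = 0}, any bin with zero denominator
#'   signal is an error (the offending bins are listed).
#' @param log2 logical: return log2 ratios.
#' @return A ratio-type [binned_track()].
#' @export
ratio_track <- function(ip, input, n_factor = 1, pseudocount = 0,
                        log2 = FALSE) {
  stopifnot(inherits(ip, "binned_track"), inherits(input, "binned_track"))
  if (!same_grid(ip, input))
    stop("ratio_track: tracks must share layout and bin width")
  stopifnot(n_factor > 0, pseudocount >= 0)
  num <- n_factor * track_concat(ip) + pseudocount
  den <- track_concat(input) + pseudocount
  if (any(den == 0)) {
    bad <- which(den == 0)
    stop("zero denominator in ", length(bad), " bin(s) with pseudocount 0 ",
         "(first offenders: ", paste(utils::head(bad, 5), collapse = ", "),
         "); use a positive pseudocount")
  }
  r <- num / den
  if (log2) r <- base::log2(r)
  track_from_concat(ip, r, type = "ratio", log2 = log2)
}

#' Normalized mutant vs wild-type IP fold-change track
#'
#' Per-bin ratio of two IP tracks from different conditions, scaled by the
#' mutant-vs-wild-type normalization factor (see [n_factor_mut_vs_wt()]) so
#' the track reads as the spike-in calibrated occupancy fold change of the
#' mutant relative to wild type.
#'
#' @param ip_mut,ip_wt IP count tracks for the two conditions.
#' @inheritParams ratio_track
#' @return A ratio-type [binned_track()].
#' @export
mutant_vs_wt_track <- function(ip_mut, ip_wt, n_factor = 1, pseudocount = 0,
                               log2 = FALSE) {
  ratio_track(ip_mut, ip_wt, n_factor = n_factor, pseudocount = pseudocount,
              log2 = log2)
}

#' Region-level fold enrichment (qPCR-style readout)
#'
#' Compares the target/control coverage ratio between the IP and input
#' libraries:
#' \deqn{FE = \frac{IP_{target} / IP_{control}}{input_{target} / input_{control}}}
#' Region sums use fractional-overlap weighting for bins straddling interval
#' edges. Equals 1 when IP and input cover the two regions proportionally,
#' and is invariant to uniform depth rescaling of either library.
#'
#' @param ip,input [binned_track()]s on the same layout and bin width.
#' @param target,control lists (or one-row data.frames) with \code{chrom},
#'   \code{start}, \code{end} — e.g. the centromeric central core vs a
#'   euchromatic control locus.
#' @return An object of class \code{region_enrichment} with the four region
#'   sums and \code{fold_enrichment}.
#' @export
region_fold_enrichment <- function(ip, input, target, control) {
  stopifnot(inherits(ip, "binned_track"), inherits(input, "binned_track"))
  if (!same_grid(ip, input))
    stop("region_fold_enrichment: tracks must share layout and bin width")
  s <- function(track, r) interval_sum(track, r$chrom, r$start, r$end)
  ip_t <- s(ip, target); ip_c <- s(ip, control)
  in_t <- s(input, target); in_c <- s(input, control)
  if (ip_c <= 0 || in_c <= 0)
    stop("zero control-region ", if (ip_c <= 0) "IP" else "input", " sum")
  if (ip_t <= 0 || in_t <= 0)
    stop("zero target-region ", if (ip_t <= 0) "IP" else "input", " sum")
  structure(list(target = target, control = control,
                 ip_target = ip_t, ip_control = ip_c,
                 input_target = in_t, input_control = in_c,
                 fold_enrichment = (ip_t / ip_c) / (in_t / in_c)),
            class = "region_enrichment")
}

#' @export
print.region_enrichment <- function(x, ...) {
  cat(sprintf("<region_enrichment> fold enrichment = %.4g\n",
              x$fold_enrichment))
  invisible(x)
}

#' Mean and sample s.d. over replicate values
#'
#' Replicate aggregation used for region enrichments and loss rates:
#' mean plus sample standard deviation (n - 1 denominator; \code{NA} for a
#' single replicate).
#'
#' @param x numeric vector of replicate values.
#' @return List with \code{mean}, \code{sd}, \code{n}, \code{values}.
#' @export
summarize_replicates <- function(x) {
  x <- as.numeric(x)
  if (!length(x)) stop("no replicate values")
  list(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_,
       n = length(x), values = x)
}
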