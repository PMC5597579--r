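#' Genome-split read totals for a spike-in calibrated ChIP experiment
#'
#' The four read totals that calibrate a ChIP-Rx experiment: reads mapped to
#' the experimental genome and to the exogenous spike-in genome, in the IP
#' and in the input library.
#'
#' @param ip_exp,input_exp reads mapped to the experimental genome in the IP
#'   and input libraries.
#' @param ip_spike,input_spike reads mapped to the spike-in genome.
#' @return An object of class \code{spike_in_counts}.
#' @export
spike_in_counts <- function(ip_exp, input_exp, ip_spike, input_spike) {
  x <- c(ip_exp = ip_exp, input_exp = input_exp,
         ip_spike = ip_spike, input_spike = input_spike)
  if (any(!is.finite(x)) || any(x < 0))
    stop("spike-in counts must be finite and >= 0")
  if (any(abs(x - round(x)) > 1e-6))
    stop("spike-in counts must be integer read totals")
  structure(as.list(round(x)), class = "spike_in_counts")
}

#' @export
print.spike_in_counts <- function(x, ...) {
  cat(sprintf("<spike_in_counts> IP %d/%d (exp/spike), input %d/%d\n",
              as.integer(x$ip_exp), as.integer(x$ip_spike),
              as.integer(x$input_exp), as.integer(x$input_spike)))
  invisible(x)
}

#' Spike-in normalized IP/input ratio (E^IP)
#'
#' The calibration constant of a ChIP-Rx experiment:
#' \deqn{E^{IP} = \frac{IP_{exp} / input_{exp}}{IP_{spike} / input_{spike}}}
#' Because a fixed ratio of spike-in cells is mixed into every sample before
#' lysis, E^IP is comparable across samples and invariant to sequencing
#' depth: rescaling the whole IP library (or the whole input library) leaves
#' it unchanged. It is computed here as a single quotient of two integer
#' cross-products, so that depth invariance holds exactly in floating point
#' for integer counts.
#'
#' @param counts a [spike_in_counts()].
#' @return A positive number.
#' @export
compute_eip <- function(counts) {
  stopifnot(inherits(counts, "spike_in_counts"))
  if (counts$input_exp <= 0 || counts$ip_spike <= 0 || counts$input_spike <= 0)
    stop("E^IP undefined: input_exp, ip_spike and input_spike must all be > 0")
  (counts$ip_exp * counts$input_spike) / (counts$input_exp * counts$ip_spike)
}

new_normalization_result <- function(e_ip, n_factor, mode) {
  structure(list(e_ip = e_ip, n_factor = n_factor, mode = mode),
            class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf("<normalization_result> mode = %s, E^IP = %.6g, N = %.6g\n",
              x$mode, x$e_ip, x$n_factor))
  invisible(x)
}

#' Scaling factor N for an IP vs input comparison
#'
#' Solves \eqn{N \times IP_{exp}/input_{exp} = E^{IP}} for N: multiplying the
#' raw IP/input read-count ratio by N makes it equal the spike-in calibrated
#' ratio.
#'
#' @param counts a [spike_in_counts()].
#' @return A \code{normalization_result} with \code{mode = "ip_vs_input"}.
#' @export
n_factor_ip_vs_input <- function(counts) {
  e <- compute_eip(counts)
  if (counts$ip_exp <= 0) stop("N undefined: ip_exp must be > 0")
  new_normalization_result(e, e * counts$input_exp / counts$ip_exp,
                           "ip_vs_input")
}

#' Scaling factor N for a mutant vs wild-type IP comparison
#'
#' Solves \eqn{N \times IP_{mut}/IP_{wt} = E^{IP}_{mut} / E^{IP}_{wt}}:
#' N rescales the raw mutant/wild-type IP read ratio so it reflects the
#' spike-in calibrated fold change between conditions.
#'
#' @param counts_mut,counts_wt [spike_in_counts()] for the two conditions.
#' @return A \code{normalization_result} with \code{mode = "mutant_vs_wt"};
#'   \code{e_ip} holds the E^IP ratio mutant/wt.
#' @export
n_factor_mut_vs_wt <- function(counts_mut, counts_wt) {
  e_mut <- compute_eip(counts_mut)
  e_wt <- compute_eip(counts_wt)
  if (counts_mut$ip_exp <= 0) stop("N undefined: mutant ip_exp must be > 0")
  if (counts_wt$ip_exp <= 0) stop("N undefined: wild-type ip_exp must be > 0")
  e_ratio <- e_mut / e_wt
  new_normalization_result(
    e_ratio, e_ratio * counts_wt$ip_exp / counts_mut$ip_exp, "mutant_vs_wt")
}

#' Signal extraction scaling (SES) factor for IP vs input
#'
#' Background-based scaling for ChIP samples without a spike-in. Bins are
#' sorted in ascending order of IP signal and the cut index maximizing the
#' gap between the cumulative input fraction and the cumulative IP fraction
#' is taken as the boundary of the background; ties in the maximal gap are
#' broken toward the smallest index (most conservative background). The
#' returned factor is
#' \deqn{s = \frac{IP_{bg} / IP_{tot}}{input_{bg} / input_{tot}}}
#' and is intended to be applied multiplicatively to the input track, after
#' both tracks are expressed as fractions of their totals, before forming the
#' IP/input ratio: in the background the rescaled ratio then averages to 1.
#' Equivalently, pass \code{n_factor = (input_total / ip_total) / s} to
#' [ratio_track()] on the raw count tracks.
#'
#' @param ip,input [binned_track()]s on the same layout and bin width.
#' @return A positive scalar, with attribute \code{cut_index} (number of
#'   background bins in IP-ascending order).
#' @export
ses_scale <- function(ip, input) {
  stopifnot(inherits(ip, "binned_track"), inherits(input, "binned_track"))
  if (!same_grid(ip, input))
    stop("ses_scale: tracks must share layout and bin width")
  vi <- track_concat(ip)
  vn <- track_concat(input)
  ti <- sum(vi); tn <- sum(vn)
  if (ti <= 0 || tn <= 0) stop("ses_scale: total counts must be > 0")
  o <- order(vi)                        # ascending by IP, stable
  gap <- cumsum(vn[o]) / tn - cumsum(vi[o]) / ti
  k <- which.max(gap)                   # first maximum
  bg_ip <- sum(vi[o][seq_len(k)])
  bg_in <- sum(vn[o][seq_len(k)])
  if (bg_ip <= 0 || bg_in <= 0)
    stop("ses_scale: degenerate enrichment, zero background ",
         if (bg_ip <= 0) "IP" else "input", " count at the cut point")
  structure((bg_ip / ti) / (bg_in / tn), cut_index = k)
}
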