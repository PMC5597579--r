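#' Per-division minichromosome loss rate
#'
#' Converts a colony's marker-retention measurements into a per-division
#' loss rate, assuming geometric retention decay over generations:
#' \deqn{\mathrm{loss\ rate\ per\ division\ (\%)} = 100 \times
#'   \left(1 - (F / I)^{1/N}\right)}
#' where I and F are the initial and final percentages of
#' minichromosome-containing cells and N the number of generations.
#'
#' Boundary handling: F = 0 (complete loss; the formula is undefined) is
#' reported as 100\% with flag \code{"complete_loss"}; F > I (retention
#' noisily estimated above its start) yields a negative rate with flag
#' \code{"gain"} and a warning.
#'
#' @param I initial percentage of minichromosome-containing cells (0 < I <=
#'   100). Vectorized over colonies together with \code{F} and \code{N}.
#' @param F final percentage (0 <= F <= 100).
#' @param N number of generations (>= 1).
#' @return Numeric vector of loss rates in percent per division, with a
#'   character attribute \code{flag} ("ok", "complete_loss" or "gain").
#' @export
loss_rate <- function(I, F, N) {
  n <- max(length(I), length(F), length(N))
  I <- rep_len(as.numeric(I), n)
  F <- rep_len(as.numeric(F), n)
  N <- rep_len(as.numeric(N), n)
  if (any(I <= 0)) stop("initial retention I must be > 0")
  if (any(F < 0)) stop("final retention F must be >= 0")
  if (any(N < 1)) stop("number of generations N must be >= 1")
  flag <- rep("ok", n)
  rate <- 100 * (1 - (F / I)^(1 / N))
  complete <- F == 0
  rate[complete] <- 100
  flag[complete] <- "complete_loss"
  gained <- !complete & F > I
  if (any(gained)) {
    flag[gained] <- "gain"
    warning(sum(gained), " colon(y/ies) with F > I: negative loss rate")
  }
  structure(rate, flag = flag)
}

#' Aggregate loss rates over independent colonies
#'
#' Applies [loss_rate()] per colony and reports the mean and sample
#' standard deviation (n - 1 denominator) across colonies, the standard
#' per-strain summary for assays scoring a few independent colonies.
#'
#' @param observations data.frame with columns \code{I}, \code{F}, \code{N}
#'   (and optionally \code{colony_id}), one row per colony, as produced by
#'   [simulate_loss_assay()] or read from a TSV.
#' @return An object of class \code{loss_rate_result}: list with
#'   \code{per_colony_rates}, \code{flags}, \code{mean_rate},
#'   \code{sd_rate} (NA for a single colony), \code{n_colonies}.
#' @export
aggregate_loss <- function(observations) {
  obs <- as.data.frame(observations)
  if (!nrow(obs)) stop("no loss-assay observations")
  stopifnot(all(c("I", "F", "N") %in% names(obs)))
  r <- loss_rate(obs$I, obs$F, obs$N)
  s <- summarize_replicates(as.numeric(r))
  structure(list(per_colony_rates = as.numeric(r), flags = attr(r, "flag"),
                 mean_rate = s$mean, sd_rate = s$sd, n_colonies = s$n),
            class = "loss_rate_result")
}

#' @export
print.loss_rate_result <- function(x, ...) {
  cat(sprintf("<loss_rate_result> %.4g%% +/- %s per division (n = %d colonies)\n",
              x$mean_rate,
              if (is.na(x$sd_rate)) "NA" else sprintf("%.4g%%", x$sd_rate),
              x$n_colonies))
  invisible(x)
}
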