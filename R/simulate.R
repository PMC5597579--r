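#' Dual-genome occupancy model for synthetic ChIP experiments
#'
#' Describes, per target protein (e.g. histone H3, CENP-A, a remodeler
#' subunit), the per-bin chromatin occupancy on an experimental genome and on
#' an exogenous spike-in genome, plus multiplicative condition effects
#' (e.g. an H3 increase on remodeler-bound bins in a deletion mutant).
#' The whole-chromatin input library samples a separate, condition-independent
#' per-bin density (\code{input_density}): sonicated input DNA tracks genome
#' content rather than the occupancy of any one target.
#'
#' @param layout experimental-genome [genome_layout()].
#' @param occupancy named list, one non-negative numeric vector per target,
#'   concatenated over the layout's bins at \code{bin_width}.
#' @param ip_efficiency named numeric in (0, 1]: capture efficiency per target.
#' @param spike_layout spike-in genome [genome_layout()] (default: one 40 kb
#'   chromosome).
#' @param spike_occupancy named list like \code{occupancy}, on the spike
#'   genome's bins (default: uniform 1 for every target).
#' @param condition_effects list of \code{list(condition, target, bins,
#'   factor)} entries; \code{bins} are indices into the concatenated
#'   experimental bin vector, \code{factor > 0} multiplies the target's
#'   occupancy there.
#' @param input_density,spike_input_density per-bin input sampling densities
#'   (default uniform 1).
#' @param bin_width bin width in bp shared by all vectors.
#' @return An object of class \code{occupancy_model}.
#' @export
occupancy_model <- function(layout, occupancy, ip_efficiency,
                            spike_layout = NULL, spike_occupancy = NULL,
                            condition_effects = list(),
                            input_density = NULL,
                            spike_input_density = NULL,
                            bin_width = 50) {
  stopifnot(inherits(layout, "genome_layout"))
  if (is.null(spike_layout))
    spike_layout <- genome_layout(data.frame(name = "spike_I", length = 40000))
  nb_exp <- sum(track_nbins(layout, bin_width))
  nb_spk <- sum(track_nbins(spike_layout, bin_width))

  check_occ <- function(x, n, what) {
    for (tg in names(x)) {
      v <- as.numeric(x[[tg]])
      if (length(v) != n)
        stop(what, " occupancy for ", tg, ": expected ", n, " bins, got ",
             length(v))
      if (any(!is.finite(v)) || any(v < 0))
        stop(what, " occupancy for ", tg, " must be finite and >= 0")
      if (sum(v) <= 0)
        stop(what, " occupancy for ", tg, " is zero everywhere")
      x[[tg]] <- v
    }
    x
  }
  occupancy <- check_occ(occupancy, nb_exp, "experimental")
  if (is.null(spike_occupancy))
    spike_occupancy <- lapply(occupancy, function(z) rep(1, nb_spk))
  spike_occupancy <- check_occ(spike_occupancy, nb_spk, "spike-in")
  if (!setequal(names(occupancy), names(spike_occupancy)))
    stop("occupancy and spike_occupancy must name the same targets")
  if (!all(names(occupancy) %in% names(ip_efficiency)))
    stop("ip_efficiency must be named for every target")
  if (any(ip_efficiency <= 0 | ip_efficiency > 1))
    stop("ip_efficiency values must lie in (0, 1]")
  if (is.null(input_density)) input_density <- rep(1, nb_exp)
  if (is.null(spike_input_density)) spike_input_density <- rep(1, nb_spk)
  stopifnot(length(input_density) == nb_exp,
            length(spike_input_density) == nb_spk,
            all(input_density >= 0), all(spike_input_density >= 0),
            sum(input_density) > 0, sum(spike_input_density) > 0)
  for (ce in condition_effects) {
    stopifnot(all(c("condition", "target", "bins", "factor") %in% names(ce)))
    if (!ce$target %in% names(occupancy))
      stop("condition effect on unknown target ", ce$target)
    if (ce$factor <= 0) stop("condition-effect factor must be > 0")
    if (any(ce$bins < 1 | ce$bins > nb_exp))
      stop("condition-effect bins out of range")
  }
  structure(list(layout = layout, spike_layout = spike_layout,
                 bin_width = bin_width, occupancy = occupancy,
                 spike_occupancy = spike_occupancy,
                 ip_efficiency = ip_efficiency,
                 condition_effects = condition_effects,
                 input_density = input_density,
                 spike_input_density = spike_input_density),
            class = "occupancy_model")
}

#' @export
print.occupancy_model <- function(x, ...) {
  cat(sprintf("<occupancy_model> targets: %s; %d + %d bins (exp + spike), %d condition effect(s)\n",
              paste(names(x$occupancy), collapse = ", "),
              length(x$input_density), length(x$spike_input_density),
              length(x$condition_effects)))
  invisible(x)
}

# Target occupancy on the experimental genome under a condition.
condition_occupancy <- function(model, condition, target) {
  v <- model$occupancy[[target]]
  if (is.null(v)) stop("unknown target: ", target)
  for (ce in model$condition_effects) {
    if (ce$condition == condition && ce$target == target)
      v[ce$bins] <- v[ce$bins] * ce$factor
  }
  v
}

#' Simulation configuration for the synthetic ChIP generator
#'
#' @param seed integer seed; mandatory for sampled runs (\code{expectation =
#'   FALSE}). Unseeded stochastic simulation is refused rather than silently
#'   using the global RNG state.
#' @param total_ip_reads,total_input_reads library sizes.
#' @param mix_ratio spike-in cells per experimental cell (the study design
#'   mixes fixed spike-in cells into the culture before lysis; 1:8 means
#'   \code{mix_ratio = 1/8}).
#' @param expectation logical: return exact expected per-bin read counts
#'   instead of multinomial draws. Expectation mode makes analytic identities
#'   testable to machine precision.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(seed = NULL, total_ip_reads = 1e6,
                       total_input_reads = 1e6, mix_ratio = 1 / 8,
                       expectation = FALSE) {
  stopifnot(total_ip_reads > 0, total_input_reads > 0, mix_ratio > 0)
  if (!expectation && is.null(seed))
    stop("a seed is required for sampled simulation; pass expectation = TRUE for the analytic mode")
  structure(list(seed = seed, total_ip_reads = total_ip_reads,
                 total_input_reads = total_input_reads,
                 mix_ratio = mix_ratio, expectation = expectation),
            class = "sim_config")
}

allocate_reads <- function(weights, total, expectation) {
  s <- sum(weights)
  if (s <= 0) stop("zero total sampling weight")
  p <- weights / s
  if (expectation) p * total
  else as.numeric(stats::rmultinom(1, total, p))
}

#' Simulate one dual-genome ChIP experiment
#'
#' Input reads are allocated across the experimental and spike-in genomes in
#' proportion to mix-weighted total chromatin (\code{input_density} sums,
#' the spike genome weighted by \code{mix_ratio}) and, within a genome, in
#' proportion to per-bin input density. IP reads are allocated in proportion
#' to the pulled-down target's occupancy times its capture efficiency, with
#' the same mix weighting. Sampling is multinomial; in expectation mode the
#' exact expected counts are returned instead.
#'
#' @param model an [occupancy_model()].
#' @param cfg a [sim_config()].
#' @param condition condition name (matched against the model's
#'   \code{condition_effects}; unknown names simply apply no effect).
#' @param target which target is immunoprecipitated.
#' @return A list with the four [binned_track()]s (\code{ip_exp},
#'   \code{input_exp}, \code{ip_spike}, \code{input_spike}) and
#'   \code{counts}, a [spike_in_counts()] equal to their sums (rounded in
#'   expectation mode).
#' @export
simulate_chip <- function(model, cfg, condition = "wt", target = "H3") {
  stopifnot(inherits(model, "occupancy_model"), inherits(cfg, "sim_config"))
  occ_exp <- condition_occupancy(model, condition, target)
  occ_spk <- model$spike_occupancy[[target]]
  eff <- model$ip_efficiency[[target]]
  if (sum(occ_exp) + sum(occ_spk) <= 0)
    stop("zero total occupancy for pulled-down target ", target)
  if (!cfg$expectation) set.seed(cfg$seed)

  m <- cfg$mix_ratio
  w_ip <- c(occ_exp * eff, m * occ_spk * eff)
  w_in <- c(model$input_density, m * model$spike_input_density)
  n_exp <- length(occ_exp)
  ip <- allocate_reads(w_ip, cfg$total_ip_reads, cfg$expectation)
  input <- allocate_reads(w_in, cfg$total_input_reads, cfg$expectation)

  tmpl_exp <- binned_track(model$layout, model$bin_width, 0)
  tmpl_spk <- binned_track(model$spike_layout, model$bin_width, 0)
  ip_exp <- track_from_concat(tmpl_exp, ip[seq_len(n_exp)])
  ip_spike <- track_from_concat(tmpl_spk, ip[-seq_len(n_exp)])
  input_exp <- track_from_concat(tmpl_exp, input[seq_len(n_exp)])
  input_spike <- track_from_concat(tmpl_spk, input[-seq_len(n_exp)])

  counts <- spike_in_counts(round(sum(ip[seq_len(n_exp)])),
                            round(sum(input[seq_len(n_exp)])),
                            round(sum(ip[-seq_len(n_exp)])),
                            round(sum(input[-seq_len(n_exp)])))
  list(counts = counts, ip_exp = ip_exp, input_exp = input_exp,
       ip_spike = ip_spike, input_spike = input_spike,
       condition = condition, target = target)
}

#' Analytic E^IP implied by an occupancy model
#'
#' The infinite-depth value of the spike-in normalized IP/input ratio for a
#' given condition and target:
#' \eqn{(T_{exp}/C_{exp}) / (T_{spike}/C_{spike})} where T are total target
#' occupancies and C total input densities. Capture efficiency and the mixing
#' ratio cancel. Deep sampled simulations converge to this value.
#'
#' @inheritParams simulate_chip
#' @return A positive number.
#' @export
analytic_eip <- function(model, condition = "wt", target = "H3") {
  occ_exp <- condition_occupancy(model, condition, target)
  (sum(occ_exp) / sum(model$input_density)) /
    (sum(model$spike_occupancy[[target]]) / sum(model$spike_input_density))
}

#' Simulate a minichromosome loss assay
#'
#' Each colony starts with \code{I}\% of cells carrying the marker; after
#' \code{N} divisions at per-division loss probability \code{p_loss} the true
#' retention is \eqn{I (1 - p)^N}. The scored final percentage is a binomial
#' draw over \code{n_cells} colonies scored (exact in expectation mode).
#'
#' @param p_loss per-division loss probability in [0, 1).
#' @param N number of generations (the assay lets cells divide 10 to 12
#'   times; default 11).
#' @param I initial percentage of minichromosome-containing cells.
#' @param colonies number of independent colonies.
#' @param n_cells cells scored per colony.
#' @param seed integer seed (required unless \code{expectation = TRUE}).
#' @param expectation logical: return exact expected retention.
#' @return data.frame with columns \code{colony_id}, \code{I}, \code{F},
#'   \code{N}, \code{n_cells_scored}.
#' @export
simulate_loss_assay <- function(p_loss, N = 11, I = 100, colonies = 3,
                                n_cells = 1000, seed = NULL,
                                expectation = FALSE) {
  stopifnot(p_loss >= 0, p_loss < 1, N >= 1, colonies >= 1, n_cells >= 1)
  if (I <= 0) stop("initial retention I must be > 0")
  if (!expectation && is.null(seed))
    stop("a seed is required for sampled simulation; pass expectation = TRUE for the analytic mode")
  frac <- (I / 100) * (1 - p_loss)^N
  F_pct <- if (expectation) {
    rep(100 * frac, colonies)
  } else {
    set.seed(seed)
    100 * stats::rbinom(colonies, n_cells, frac) / n_cells
  }
  data.frame(colony_id = paste0("colony_", seq_len(colonies)),
             I = I, F = F_pct, N = N, n_cells_scored = n_cells,
             stringsAsFactors = FALSE)
}
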