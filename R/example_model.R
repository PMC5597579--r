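#' A fission-yeast-like demonstration layout and occupancy model
#'
#' `example_layout()` builds a compact regional-centromere genome: one 660 kb
#' experimental chromosome carrying a centromere with the canonical
#' otr-imr-cnt-imr-otr domain structure at its centre, flanked by euchromatin
#' tiled with 200 equally sized genes (2 kb bodies, alternating strands,
#' 1 kb spacing).
#'
#' `example_model()` places three targets on that layout with the occupancy
#' structure the analysis is designed to resolve:
#' \itemize{
#'   \item \strong{H3}: near-uniform nucleosomal occupancy, depleted in the
#'     central core where the CENP-A variant replaces it;
#'   \item \strong{CENP-A}: enrichment confined to the central centromere
#'     domain (cnt), ten-fold over its residual euchromatic level;
#'   \item \strong{Ies6}: a remodeler subunit bound at a designated subset of
#'     genes (the first \code{n_bound} genes).
#' }
#' A \code{"mutant"} condition multiplies H3 occupancy on the bound genes'
#' body bins by \code{h3_fold}, emulating the histone H3 gain observed at
#' remodeler-bound genes when the remodeler is inactivated. The spike-in
#' genome is a single 40 kb chromosome with uniform occupancy.
#'
#' @param n_genes number of genes tiling the euchromatin.
#' @param n_bound number of remodeler-bound genes (taken from the start of
#'   the gene list).
#' @param h3_fold multiplicative H3 increase on bound gene bodies in the
#'   mutant condition.
#' @param bin_width bin width in bp.
#' @return A [genome_layout()] or [occupancy_model()].
#' @export
example_layout <- function(n_genes = 200) {
  stopifnot(n_genes >= 2, n_genes %% 2 == 0)
  chrom_len <- 660000
  cen <- data.frame(
    chrom = "chrI",
    start = c(310000, 320000, 325000, 335000, 340000),
    end   = c(320000, 325000, 335000, 340000, 350000),
    label = c("otr", "imr", "cnt", "imr", "otr"),
    stringsAsFactors = FALSE)
  # genes tile the two euchromatic arms: 2 kb bodies every 3 kb
  half <- n_genes / 2
  left_starts <- 2000 + (seq_len(half) - 1) * 3000
  right_starts <- 352000 + (seq_len(half) - 1) * 3000
  starts <- c(left_starts, right_starts)
  stopifnot(max(starts) + 2000 <= chrom_len)
  genes <- data.frame(
    gene_id = sprintf("gene_%03d", seq_len(n_genes)),
    chrom = "chrI",
    start = starts,
    end = starts + 2000,
    strand = rep(c("+", "-"), length.out = n_genes),
    stringsAsFactors = FALSE)
  genome_layout(data.frame(name = "chrI", length = chrom_len),
                domains = cen, genes = genes)
}

#' @rdname example_layout
#' @export
example_model <- function(n_genes = 200, n_bound = 60, h3_fold = 1.5,
                          bin_width = 50) {
  layout <- example_layout(n_genes)
  nb <- sum(track_nbins(layout, bin_width))
  bins_of <- function(start, end)
    (floor(start / bin_width) + 1):(ceiling(end / bin_width))
  d <- layout$domains
  cnt_bins <- bins_of(d$start[d$label == "cnt"], d$end[d$label == "cnt"])

  g <- layout$genes
  bound_ids <- g$gene_id[seq_len(n_bound)]
  bound_bins <- sort(unique(unlist(Map(bins_of,
                                       g$start[seq_len(n_bound)],
                                       g$end[seq_len(n_bound)]))))

  h3 <- rep(1, nb); h3[cnt_bins] <- 0.2
  cenpa <- rep(0.5, nb); cenpa[cnt_bins] <- 5
  ies6 <- rep(0.5, nb); ies6[bound_bins] <- 4

  model <- occupancy_model(
    layout,
    occupancy = list(H3 = h3, `CENP-A` = cenpa, Ies6 = ies6),
    ip_efficiency = c(H3 = 0.8, `CENP-A` = 0.5, Ies6 = 0.3),
    condition_effects = list(
      list(condition = "mutant", target = "H3", bins = bound_bins,
           factor = h3_fold)),
    bin_width = bin_width)
  model$bound_gene_ids <- bound_ids
  model$bound_bins <- bound_bins
  model$cnt_bins <- cnt_bins
  model
}
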