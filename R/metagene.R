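#' Scaled-region metagene matrix over all genes
#'
#' Builds the genes x positions matrix behind metagene plots and heatmaps:
#' each row is one gene's signal from \code{upstream} bp before its TSS to
#' \code{downstream} bp after its TES, with the gene body rescaled to a
#' common length. Flank columns have fixed width equal to the track's bin
#' width; the body is divided into \code{body_bins} equal-length
#' subintervals, each summarized by the length-weighted mean of the
#' overlapping track bins (so bodies shorter than one track bin are handled
#' by the same fractional-overlap interpolation, and are flagged). Rows of
#' minus-strand genes are computed along the direction of transcription, so
#' column 1 is always the 5' upstream edge. Columns reaching beyond a
#' chromosome end are set to \code{NA}.
#'
#' The per-gene \code{summary} score — the statistic fed to heatmap ordering
#' and high/low classification — is the mean over the body columns.
#'
#' @param track a [binned_track()] (typically a normalized ratio track).
#' @param layout layout providing the gene models; defaults to the track's.
#' @param upstream,downstream flank extents in bp (defaults 500, matching the
#'   -0.5 kb TSS .. +0.5 kb TES convention).
#' @param body_bins number of scaled body columns (default 100).
#' @return An object of class \code{gene_profile_matrix}: list with
#'   \code{matrix} (rownames = gene ids), \code{gene_ids}, \code{n_up},
#'   \code{body_bins}, \code{n_down}, \code{bin_width}, \code{summary},
#'   \code{short_genes}.
#' @export
metagene_matrix <- function(track, layout = track$layout, upstream = 500,
                            downstream = 500, body_bins = 100) {
  stopifnot(inherits(track, "binned_track"), upstream >= 0, downstream >= 0,
            body_bins >= 1)
  g <- layout$genes
  if (!nrow(g)) stop("layout has no genes")
  w <- track$bin_width
  n_up <- as.integer(round(upstream / w))
  n_down <- as.integer(round(downstream / w))
  ncol_total <- n_up + body_bins + n_down

  mat <- matrix(NA_real_, nrow = nrow(g), ncol = ncol_total,
                dimnames = list(g$gene_id, NULL))
  short <- logical(nrow(g))
  for (i in seq_len(nrow(g))) {
    len <- g$end[i] - g$start[i]
    short[i] <- len < w
    # column boundaries along the direction of transcription, in bp from
    # the upstream edge (5' flank start)
    bounds <- c(seq_len(n_up) * w - w,                      # upstream starts
                n_up * w + (0:body_bins) * (len / body_bins),
                n_up * w + len + seq_len(n_down) * w)
    # map transcription-direction offsets to genomic coordinates
    if (g$strand[i] == "+") {
      gx <- (g$start[i] - n_up * w) + bounds
    } else {
      gx <- (g$end[i] + n_up * w) - bounds
    }
    clen <- chrom_length(track$layout, g$chrom[i])
    for (j in seq_len(ncol_total)) {
      a <- min(gx[j], gx[j + 1]); b <- max(gx[j], gx[j + 1])
      if (a < 0 || b > clen) next                      # off-chromosome: NA
      mat[i, j] <- interval_mean(track, g$chrom[i], a, b)
    }
  }
  body_cols <- n_up + seq_len(body_bins)
  structure(list(matrix = mat, gene_ids = g$gene_id, n_up = n_up,
                 body_bins = as.integer(body_bins), n_down = n_down,
                 bin_width = w,
                 summary = rowMeans(mat[, body_cols, drop = FALSE],
                                    na.rm = TRUE),
                 short_genes = stats::setNames(short, g$gene_id)),
            class = "gene_profile_matrix")
}

#' @export
print.gene_profile_matrix <- function(x, ...) {
  cat(sprintf("<gene_profile_matrix> %d genes x (%d up + %d body + %d down) columns\n",
              length(x$gene_ids), x$n_up, x$body_bins, x$n_down))
  invisible(x)
}

#' Column-wise average metagene profile
#'
#' Mean signal per scaled position over all genes, ignoring missing entries;
#' a column that is missing in every gene yields \code{NA}.
#'
#' @param m a [metagene_matrix()] result.
#' @return Numeric vector of length \code{n_up + body_bins + n_down}.
#' @export
average_profile <- function(m) {
  stopifnot(inherits(m, "gene_profile_matrix"))
  v <- colMeans(m$matrix, na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  v
}

#' Heatmap row order: descending per-gene enrichment
#'
#' Stable sort of the gene ids by decreasing summary score (body mean), the
#' ordering used to display ranked single-gene heatmaps; ties are broken by
#' lexicographic gene id.
#'
#' @param m a [metagene_matrix()] result.
#' @return Character vector: gene ids in display order.
#' @export
heatmap_order <- function(m) {
  stopifnot(inherits(m, "gene_profile_matrix"))
  if (any(is.na(m$summary))) stop("summary undefined for some genes")
  m$gene_ids[order(-m$summary, m$gene_ids, method = "radix")]
}
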