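#' Genome layout: chromosomes, annotated domains, and gene models
#'
#' The coordinate frame shared by every track and matrix in the package.
#' All intervals are 0-based, half-open (BED convention). Gene models store
#' their genomic extent with \code{start < end}; strand is kept separately,
#' so the transcription start of a minus-strand gene is its \code{end}
#' coordinate (see [gene_tss()]).
#'
#' @param chromosomes data.frame with columns \code{name}, \code{length} (bp).
#' @param domains optional data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{label}. Labels are free-form but \code{cnt}, \code{imr},
#'   \code{otr}, \code{euchromatin} and \code{insert} are the conventional
#'   centromere-domain vocabulary. Domains carrying distinct labels on one
#'   chromosome must not overlap.
#' @param genes optional data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand} (\code{"+"} or \code{"-"}).
#' @return An object of class \code{genome_layout}.
#' @export
genome_layout <- function(chromosomes, domains = NULL, genes = NULL) {
  chromosomes <- as.data.frame(chromosomes, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (anyDuplicated(chromosomes$name))
    stop("duplicated chromosome names in layout")
  if (any(!is.finite(chromosomes$length)) || any(chromosomes$length <= 0))
    stop("chromosome lengths must be positive and finite")

  if (is.null(domains)) {
    domains <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), label = character(),
                          stringsAsFactors = FALSE)
  } else {
    domains <- as.data.frame(domains, stringsAsFactors = FALSE)
    stopifnot(all(c("chrom", "start", "end", "label") %in% names(domains)))
  }
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        strand = character(), stringsAsFactors = FALSE)
  } else {
    genes <- as.data.frame(genes, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                    names(genes)))
  }

  layout <- structure(
    list(chromosomes = chromosomes, domains = domains, genes = genes),
    class = "genome_layout")
  validate_layout(layout)
  layout
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout>\n")
  cat("  chromosomes:", nrow(x$chromosomes),
      sprintf("(%.0f bp total)", sum(x$chromosomes$length)), "\n")
  if (nrow(x$domains))
    cat("  domains:", nrow(x$domains), "[",
        paste(unique(x$domains$label), collapse = ", "), "]\n")
  cat("  genes:", nrow(x$genes), "\n")
  invisible(x)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chromosomes$name)
  if (anyNA(i)) stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  layout$chromosomes$length[i]
}

validate_layout <- function(layout) {
  chr <- layout$chromosomes
  check_intervals <- function(df, what) {
    if (!nrow(df)) return(invisible())
    i <- match(df$chrom, chr$name)
    if (anyNA(i))
      stop(what, " on unknown chromosome: ",
           paste(unique(df$chrom[is.na(i)]), collapse = ", "))
    bad <- df$start < 0 | df$end > chr$length[i] | df$start >= df$end
    if (any(bad))
      stop(what, " interval out of range or empty (rows ",
           paste(which(bad), collapse = ", "), ")")
  }
  check_intervals(layout$domains, "domain")
  check_intervals(layout$genes, "gene")

  # domains with distinct labels on one chromosome must not overlap
  d <- layout$domains
  if (nrow(d) > 1) {
    for (cn in unique(d$chrom)) {
      dc <- d[d$chrom == cn, , drop = FALSE]
      if (nrow(dc) < 2) next
      o <- order(dc$start)
      dc <- dc[o, , drop = FALSE]
      for (k in seq_len(nrow(dc) - 1)) {
        if (dc$end[k] > dc$start[k + 1] && dc$label[k] != dc$label[k + 1])
          stop("overlapping domains with distinct labels on ", cn, ": ",
               dc$label[k], " and ", dc$label[k + 1])
      }
    }
  }
  g <- layout$genes
  if (nrow(g)) {
    if (any(!g$strand %in% c("+", "-")))
      stop("gene strand must be '+' or '-'")
    if (anyDuplicated(g$gene_id))
      stop("duplicated gene ids")
  }
  invisible(layout)
}

#' Transcription start / end sites of the genes in a layout
#'
#' Strand-aware accessors: for a plus-strand gene the TSS is its left
#' (\code{start}) coordinate, for a minus-strand gene its right (\code{end})
#' coordinate; the TES is the opposite extremity.
#'
#' @param layout a [genome_layout()].
#' @return Named numeric vector of genomic positions, one per gene.
#' @export
gene_tss <- function(layout) {
  g <- layout$genes
  stats::setNames(ifelse(g$strand == "+", g$start, g$end), g$gene_id)
}

#' @rdname gene_tss
#' @export
gene_tes <- function(layout) {
  g <- layout$genes
  stats::setNames(ifelse(g$strand == "+", g$end, g$start), g$gene_id)
}

#' Read a genome layout from BED-like annotation files
#'
#' Domains are read from a 4-column BED (\code{chrom start end label});
#' genes from a 6-column BED (\code{chrom start end id score strand}).
#' Coordinates are taken verbatim as 0-based half-open.
#'
#' @param chromosomes data.frame of chromosome names and lengths (there is no
#'   standard BED encoding for these, so they are passed directly).
#' @param domains_path,genes_path paths to the BED files; either may be
#'   \code{NULL}.
#' @return A [genome_layout()].
#' @export
read_layout <- function(chromosomes, domains_path = NULL, genes_path = NULL) {
  domains <- if (!is.null(domains_path)) {
    b <- read_bed(domains_path, n_min = 4)
    data.frame(chrom = b[[1]], start = b[[2]], end = b[[3]], label = b[[4]],
               stringsAsFactors = FALSE)
  }
  genes <- if (!is.null(genes_path)) {
    b <- read_bed(genes_path, n_min = 6)
    data.frame(gene_id = b[[4]], chrom = b[[1]], start = b[[2]], end = b[[3]],
               strand = b[[6]], stringsAsFactors = FALSE)
  }
  genome_layout(chromosomes, domains = domains, genes = genes)
}

# Strict line-by-line BED reader: names the offending line on a parse error.
read_bed <- function(path, n_min) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$|^(track|browser|#)", lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  for (j in seq_along(fields)) {
    f <- fields[[j]]
    if (length(f) < n_min)
      stop("malformed BED line ", idx[j], " in ", path,
           ": expected >= ", n_min, " fields, got ", length(f))
    s <- suppressWarnings(as.numeric(f[2:3]))
    if (anyNA(s))
      stop("malformed BED line ", idx[j], " in ", path,
           ": non-numeric coordinates")
  }
  cols <- seq_len(n_min)
  out <- lapply(cols, function(k) vapply(fields, `[[`, "", k))
  out[[2]] <- as.numeric(out[[2]])
  out[[3]] <- as.numeric(out[[3]])
  out
}

#' Write layout annotation back to BED files
#'
#' @param layout a [genome_layout()].
#' @param domains_path,genes_path output paths; either may be \code{NULL} to
#'   skip that component.
#' @return Invisibly, the layout.
#' @export
write_layout <- function(layout, domains_path = NULL, genes_path = NULL) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  if (!is.null(domains_path)) {
    d <- layout$domains
    writeLines(paste(d$chrom, fmt(d$start), fmt(d$end), d$label, sep = "\t"),
               domains_path)
  }
  if (!is.null(genes_path)) {
    g <- layout$genes
    writeLines(paste(g$chrom, fmt(g$start), fmt(g$end), g$gene_id, 0,
                     g$strand, sep = "\t"),
               genes_path)
  }
  invisible(layout)
}
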