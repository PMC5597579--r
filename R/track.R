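#' Fixed-width binned signal track on a genome layout
#'
#' One numeric vector per chromosome, \code{ceiling(length / bin_width)} bins
#' each; the last bin may be partial and covers to the chromosome end.
#' Count-type tracks must be finite and non-negative; ratio-type tracks may
#' carry any finite real and record whether they are on the log2 scale.
#'
#' @param layout a [genome_layout()].
#' @param bin_width bin width in bp (default 50).
#' @param values named list (one numeric vector per chromosome) or a single
#'   value recycled into every bin.
#' @param type \code{"count"} or \code{"ratio"}.
#' @param log2 logical flag: values are log2-transformed (ratio tracks only).
#' @return An object of class \code{binned_track}.
#' @export
binned_track <- function(layout, bin_width = 50, values = 0,
                         type = c("count", "ratio"), log2 = FALSE) {
  type <- match.arg(type)
  stopifnot(inherits(layout, "genome_layout"), bin_width >= 1)
  nb <- track_nbins(layout, bin_width)
  if (!is.list(values))
    values <- lapply(nb, function(n) rep(as.numeric(values), n))
  if (!all(names(nb) %in% names(values)))
    stop("values must name every chromosome in the layout")
  values <- values[names(nb)]
  for (cn in names(nb)) {
    v <- as.numeric(values[[cn]])
    if (length(v) != nb[[cn]])
      stop("chromosome ", cn, ": expected ", nb[[cn]], " bins, got ", length(v))
    if (any(!is.finite(v)))
      stop("chromosome ", cn, ": non-finite track values")
    if (type == "count" && any(v < 0))
      stop("chromosome ", cn, ": negative values in a count track")
    values[[cn]] <- v
  }
  structure(list(layout = layout, bin_width = bin_width, values = values,
                 type = type, log2 = log2 && type == "ratio"),
            class = "binned_track")
}

track_nbins <- function(layout, bin_width) {
  stats::setNames(as.integer(ceiling(layout$chromosomes$length / bin_width)),
                  layout$chromosomes$name)
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("<binned_track> %s, %d bp bins, %d bins over %d chromosome(s)%s\n",
              x$type, as.integer(x$bin_width),
              sum(lengths(x$values)), length(x$values),
              if (isTRUE(x$log2)) ", log2 scale" else ""))
  invisible(x)
}

# All bin values as one vector, chromosome order of the layout.
track_concat <- function(track) unlist(track$values, use.names = FALSE)

# Rebuild a track from a concatenated vector (inverse of track_concat).
track_from_concat <- function(template, v, type = template$type,
                              log2 = template$log2) {
  nb <- lengths(template$values)
  stopifnot(length(v) == sum(nb))
  split_idx <- rep(seq_along(nb), nb)
  vals <- split(v, split_idx)
  names(vals) <- names(template$values)
  binned_track(template$layout, template$bin_width, vals,
               type = type, log2 = log2)
}

same_grid <- function(a, b) {
  identical(a$bin_width, b$bin_width) &&
    identical(lengths(a$values), lengths(b$values)) &&
    identical(a$layout$chromosomes, b$layout$chromosomes)
}

#' Length-weighted sum / mean of a track over a genomic interval
#'
#' Bins straddling the interval edges contribute with fractional-overlap
#' weights, so a sum over \code{[a, b)} is exactly the integral of the
#' piecewise-constant per-bp signal. For \code{interval_mean} the weights are
#' the overlap lengths. Intervals must lie within the chromosome.
#'
#' @param track a [binned_track()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return A single number.
#' @export
interval_sum <- function(track, chrom, start, end) {
  w <- track$bin_width
  v <- track$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  len <- chrom_length(track$layout, chrom)
  if (start < 0 || end > len || start >= end)
    stop("interval [", start, ", ", end, ") out of range on ", chrom)
  b0 <- floor(start / w)
  b1 <- ceiling(end / w) - 1
  bins <- b0:b1
  lo <- pmax(bins * w, start)
  hi <- pmin(pmin((bins + 1) * w, len), end)
  sum(v[bins + 1] * (hi - lo) / w)
}

#' @rdname interval_sum
#' @export
interval_mean <- function(track, chrom, start, end) {
  w <- track$bin_width
  interval_sum(track, chrom, start, end) * w / (end - start)
}

#' Write a binned track as a bedGraph file
#'
#' Adjacent bins with equal values are merged into one line (run-length
#' encoding); the final interval of each chromosome is clipped to the
#' chromosome end. Reading the file back with [read_track()] on the same
#' layout and bin width reproduces the per-bin values.
#'
#' @param track a [binned_track()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- track$bin_width
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  for (cn in names(track$values)) {
    v <- track$values[[cn]]
    if (!length(v)) next
    len <- chrom_length(track$layout, cn)
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts <- c(0, ends_bin[-length(ends_bin)]) * w
    ends <- pmin(ends_bin * w, len)
    writeLines(paste(cn, fmt(starts), fmt(ends),
                     format(r$values, digits = 17, scientific = FALSE,
                            trim = TRUE), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bedGraph file onto a layout's bin grid
#'
#' Each bin receives the length-weighted mean of the intervals covering it
#' (uncovered stretches count as 0), so files written by [write_track()]
#' round-trip exactly and arbitrary bedGraphs are resampled onto the grid.
#'
#' @param path bedGraph path.
#' @param layout a [genome_layout()].
#' @param bin_width bin width in bp.
#' @param type,log2 passed to [binned_track()].
#' @return A [binned_track()].
#' @export
read_track <- function(path, layout, bin_width = 50, type = "count",
                       log2 = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$|^(track|browser|#)", lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nb <- track_nbins(layout, bin_width)
  acc <- lapply(nb, function(n) numeric(n))  # weighted value sums
  for (j in seq_along(fields)) {
    f <- fields[[j]]
    if (length(f) < 4)
      stop("malformed bedGraph line ", idx[j], " in ", path)
    cn <- f[1]
    if (is.null(acc[[cn]]))
      stop("bedGraph line ", idx[j], ": unknown chromosome ", cn)
    s <- as.numeric(f[2]); e <- as.numeric(f[3]); val <- as.numeric(f[4])
    if (anyNA(c(s, e, val)) || s >= e)
      stop("malformed bedGraph line ", idx[j], " in ", path)
    len <- chrom_length(layout, cn)
    e <- min(e, len)
    b0 <- floor(s / bin_width); b1 <- ceiling(e / bin_width) - 1
    bins <- b0:b1
    lo <- pmax(bins * bin_width, s)
    hi <- pmin(pmin((bins + 1) * bin_width, len), e)
    acc[[cn]][bins + 1] <- acc[[cn]][bins + 1] + val * (hi - lo)
  }
  # normalize by the true width of each bin (last bin may be partial)
  for (cn in names(acc)) {
    n <- nb[[cn]]
    if (!n) next
    len <- chrom_length(layout, cn)
    widths <- pmin(seq_len(n) * bin_width, len) - (seq_len(n) - 1) * bin_width
    acc[[cn]] <- acc[[cn]] / widths
  }
  binned_track(layout, bin_width, acc, type = type, log2 = log2)
}
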