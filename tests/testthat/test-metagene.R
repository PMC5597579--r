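# A small layout for profile tests: one 20 kb chromosome, one gene per strand
profile_layout <- function() {
  genome_layout(
    data.frame(name = "chr1", length = 20000),
    genes = data.frame(gene_id = c("plus", "minus"), chrom = "chr1",
                       start = c(5000, 12000), end = c(10000, 17000),
                       strand = c("+", "-")))
}

test_that("a constant track yields a perfectly flat matrix and profile", {
  lay <- profile_layout()
  tr <- binned_track(lay, 50, 3.5)
  m <- metagene_matrix(tr, lay, upstream = 500, downstream = 500,
                       body_bins = 100)
  expect_equal(dim(m$matrix), c(2, 10 + 100 + 10))
  expect_true(all(m$matrix == 3.5))
  expect_equal(unname(average_profile(m)), rep(3.5, 120))
  expect_equal(unname(m$summary), c(3.5, 3.5))
})

test_that("a TSS impulse lands in the first body column on either strand", {
  lay <- profile_layout()
  vals <- rep(0, 400)
  vals[5000 / 50 + 1] <- 7        # bin [5000, 5050): plus-strand TSS
  vals[(17000 - 50) / 50 + 1] <- 7  # bin [16950, 17000): minus-strand TSS
  tr <- binned_track(lay, 50, list(chr1 = vals))
  m <- metagene_matrix(tr, lay, upstream = 500, downstream = 500,
                       body_bins = 100)
  # gene bodies are 5000 bp, so each body column is exactly one 50 bp bin
  expect_equal(which.max(m$matrix["plus", ]), m$n_up + 1)
  expect_equal(which.max(m$matrix["minus", ]), m$n_up + 1)
  expect_equal(unname(m$matrix["plus", m$n_up + 1]), 7)
  expect_equal(unname(m$matrix["minus", m$n_up + 1]), 7)
  # upstream flanks saw nothing
  expect_true(all(m$matrix[, seq_len(m$n_up)] == 0))
})

test_that("matrix mean conserves the genome mean when genes tile the genome", {
  set.seed(8)
  n_genes <- 10; gene_len <- 1000; w <- 50
  lay <- genome_layout(
    data.frame(name = "chr1", length = n_genes * gene_len),
    genes = data.frame(gene_id = sprintf("g%02d", 1:n_genes), chrom = "chr1",
                       start = (0:(n_genes - 1)) * gene_len,
                       end = (1:n_genes) * gene_len,
                       strand = rep(c("+", "-"), 5)))
  vals <- runif(n_genes * gene_len / w, 0, 10)
  tr <- binned_track(lay, w, list(chr1 = vals))
  m <- metagene_matrix(tr, lay, upstream = 0, downstream = 0, body_bins = 20)
  expect_equal(mean(m$matrix), mean(vals), tolerance = 1e-9)
})

test_that("columns beyond the chromosome edge are missing, not fabricated", {
  lay <- genome_layout(
    data.frame(name = "chr1", length = 2000),
    genes = data.frame(gene_id = "edge", chrom = "chr1", start = 0,
                       end = 1000, strand = "+"))
  tr <- binned_track(lay, 50, 2)
  m <- metagene_matrix(tr, lay, upstream = 500, downstream = 500,
                       body_bins = 10)
  expect_true(all(is.na(m$matrix[1, 1:10])))       # upstream of position 0
  expect_true(all(!is.na(m$matrix[1, 11:30])))
  prof <- average_profile(m)
  expect_true(all(is.na(prof[1:10])))              # all-missing columns
  expect_equal(unname(prof[11:30]), rep(2, 20))
  # summary ignores the missing flanks
  expect_equal(unname(m$summary), 2)
})

test_that("strand-flipping the layout with a mirrored track reproduces the matrix", {
  set.seed(17)
  L <- 20000; w <- 50
  lay <- profile_layout()
  vals <- runif(L / w, 0, 5)
  tr <- binned_track(lay, w, list(chr1 = vals))
  m <- metagene_matrix(tr, lay, upstream = 500, downstream = 500,
                       body_bins = 50)

  g <- lay$genes
  flipped <- genome_layout(
    lay$chromosomes,
    genes = data.frame(gene_id = g$gene_id, chrom = g$chrom,
                       start = L - g$end, end = L - g$start,
                       strand = ifelse(g$strand == "+", "-", "+")))
  tr_m <- binned_track(flipped, w, list(chr1 = rev(vals)))
  m2 <- metagene_matrix(tr_m, flipped, upstream = 500, downstream = 500,
                        body_bins = 50)
  expect_equal(m2$matrix, m$matrix, tolerance = 1e-12)
})

test_that("heatmap ordering is descending with lexicographic tie-breaks", {
  lay <- genome_layout(
    data.frame(name = "chr1", length = 3000),
    genes = data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                       start = c(0, 1000, 2000), end = c(1000, 2000, 3000),
                       strand = "+"))
  vals <- c(rep(3, 20), rep(1, 20), rep(2, 20))
  tr <- binned_track(lay, 50, list(chr1 = vals))
  m <- metagene_matrix(tr, lay, upstream = 0, downstream = 0, body_bins = 10)
  expect_equal(heatmap_order(m), c("a", "c", "b"))

  # exact ties fall back to id order
  tr_tie <- binned_track(lay, 50, 1)
  m_tie <- metagene_matrix(tr_tie, lay, upstream = 0, downstream = 0,
                           body_bins = 10)
  expect_equal(heatmap_order(m_tie), c("a", "b", "c"))

  # random summaries match an oracle sort
  set.seed(2)
  vals_r <- rep(runif(3, 0, 9), each = 20)
  m_r <- metagene_matrix(binned_track(lay, 50, list(chr1 = vals_r)), lay,
                         upstream = 0, downstream = 0, body_bins = 10)
  expect_equal(heatmap_order(m_r), c("a", "b", "c")[order(-vals_r[c(1, 21, 41)])])
})

test_that("short genes are interpolated and flagged", {
  lay <- genome_layout(
    data.frame(name = "chr1", length = 1000),
    genes = data.frame(gene_id = "tiny", chrom = "chr1", start = 500,
                       end = 520, strand = "+"))
  tr <- binned_track(lay, 50, list(chr1 = seq(1, 20, length.out = 20)))
  m <- metagene_matrix(tr, lay, upstream = 0, downstream = 0, body_bins = 10)
  expect_true(m$short_genes[["tiny"]])
  # the 20 bp body sits inside bin [500, 550): every column equals that bin
  expect_equal(unname(m$matrix[1, ]), rep(tr$values$chr1[11], 10))
})
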