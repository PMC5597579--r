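test_that("ratio tracks follow per-bin arithmetic and scaling laws", {
  ip <- toy_track(c(10, 20)); input <- toy_track(c(10, 10))
  r <- ratio_track(ip, input)
  expect_equal(unlist(r$values, use.names = FALSE), c(1, 2))
  expect_equal(r$type, "ratio")

  # identity and log2 form
  same <- ratio_track(ip, ip)
  expect_equal(unlist(same$values, use.names = FALSE), c(1, 1))
  expect_equal(unlist(ratio_track(ip, ip, log2 = TRUE)$values,
                      use.names = FALSE), c(0, 0))

  # N = 2 doubles linear ratios, adds exactly 1 in log2
  r2 <- ratio_track(ip, input, n_factor = 2)
  expect_equal(unlist(r2$values, use.names = FALSE),
               2 * unlist(r$values, use.names = FALSE))
  expect_equal(unlist(ratio_track(ip, input, n_factor = 2, log2 = TRUE)$values,
                      use.names = FALSE),
               unlist(ratio_track(ip, input, log2 = TRUE)$values,
                      use.names = FALSE) + 1)

  # swapping numerator and denominator inverts the ratio at pseudocount 0
  expect_equal(unlist(mutant_vs_wt_track(input, ip)$values, use.names = FALSE),
               1 / unlist(mutant_vs_wt_track(ip, input)$values,
                          use.names = FALSE))

  # zero denominator bins are an error that names offenders
  expect_error(ratio_track(ip, toy_track(c(10, 0))), "zero denominator")
  expect_silent(ratio_track(ip, toy_track(c(10, 0)), pseudocount = 1))
})

test_that("region fold enrichment matches direct arithmetic and its invariances", {
  # three 50 bp bins: target = bin 1, control = bin 3
  ip <- toy_track(c(90, 0, 30)); input <- toy_track(c(30, 0, 30))
  target <- list(chrom = "chr1", start = 0, end = 50)
  control <- list(chrom = "chr1", start = 100, end = 150)
  fe <- region_fold_enrichment(ip, input, target, control)
  expect_equal(fe$fold_enrichment, (90 / 30) / (30 / 30))

  # proportional coverage gives exactly 1
  fe1 <- region_fold_enrichment(ip, toy_track(c(45, 0, 15)), target, control)
  expect_equal(fe1$fold_enrichment, 1)

  # invariant to uniform depth rescaling of either library
  ip_deep <- toy_track(c(90, 0, 30) * 7)
  expect_equal(region_fold_enrichment(ip_deep, input, target,
                                      control)$fold_enrichment,
               fe$fold_enrichment)

  # strictly monotone in target-region IP signal
  fe_hi <- region_fold_enrichment(toy_track(c(120, 0, 30)), input, target,
                                  control)
  expect_gt(fe_hi$fold_enrichment, fe$fold_enrichment)

  expect_error(region_fold_enrichment(ip, input, target,
                                      list(chrom = "chr1", start = 50,
                                           end = 100)),
               "zero")
})

test_that("interval-averaged ratio track agrees with region enrichment under uniform input", {
  set.seed(21)
  ip <- toy_track(rpois(40, 50) + 1)
  input <- toy_track(rep(20, 40))
  target <- list(chrom = "chr1", start = 100, end = 400)
  control <- list(chrom = "chr1", start = 1500, end = 1800)
  fe <- region_fold_enrichment(ip, input, target, control)
  r <- ratio_track(ip, input)
  expect_equal(interval_mean(r, "chr1", 100, 400) /
                 interval_mean(r, "chr1", 1500, 1800),
               fe$fold_enrichment, tolerance = 1e-9)
})

test_that("simulated mutant vs wild-type tracks recover the programmed fold change", {
  f <- 1.5
  m <- example_model(n_genes = 40, n_bound = 12, h3_fold = f)
  wt <- simulate_chip(m, sim_config(seed = 31), "wt", "H3")
  mut <- simulate_chip(m, sim_config(seed = 32), "mutant", "H3")
  nf <- n_factor_mut_vs_wt(mut$counts, wt$counts)
  tr <- mutant_vs_wt_track(mut$ip_exp, wt$ip_exp, n_factor = nf$n_factor)
  v <- unlist(tr$values, use.names = FALSE)
  expect_lt(abs(mean(v[m$bound_bins]) - f), 0.1)
  unbound <- setdiff(seq_along(v), c(m$bound_bins, m$cnt_bins))
  expect_lt(abs(mean(v[unbound]) - 1), 0.05)
})

test_that("simulated CENP-A central-core enrichment matches the model", {
  m <- example_model(n_genes = 20, n_bound = 6)
  s <- simulate_chip(m, sim_config(seed = 44), "wt", "CENP-A")
  d <- m$layout$domains
  cnt <- list(chrom = "chrI", start = d$start[d$label == "cnt"],
              end = d$end[d$label == "cnt"])
  control <- list(chrom = "chrI", start = 2000, end = 4000)
  fe <- region_fold_enrichment(s$ip_exp, s$input_exp, cnt, control)
  expect_lt(abs(fe$fold_enrichment - 10) / 10, 0.1)  # cnt occupancy 5 vs 0.5
})
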