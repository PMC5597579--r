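test_that("sampled reads are conserved and runs are seed-deterministic", {
  m <- example_model(n_genes = 20, n_bound = 6)
  cfg <- sim_config(seed = 5, total_ip_reads = 2e4, total_input_reads = 3e4)
  s1 <- simulate_chip(m, cfg, "wt", "H3")
  s2 <- simulate_chip(m, cfg, "wt", "H3")
  # conservation over all bins and both genomes
  expect_equal(sum(track_sum <- sapply(
    s1[c("ip_exp", "ip_spike")], function(t) sum(unlist(t$values)))), 2e4)
  expect_equal(sum(sapply(s1[c("input_exp", "input_spike")],
                          function(t) sum(unlist(t$values)))), 3e4)
  # spike_in_counts equals the column sums of the returned tracks
  expect_equal(s1$counts$ip_exp, sum(unlist(s1$ip_exp$values)))
  expect_equal(s1$counts$input_spike, sum(unlist(s1$input_spike$values)))
  # bit-identical under the same seed
  expect_identical(s1$ip_exp$values, s2$ip_exp$values)
  expect_identical(s1$input_spike$values, s2$input_spike$values)
  # unseeded sampling refused
  expect_error(sim_config(), "seed")
})

test_that("expectation mode reproduces closed-form mixture fractions", {
  # equal per-cell chromatin content in both genomes, mix 1:8
  lay_e <- toy_layout(10); lay_s <- toy_layout(10, name = "spk")
  m <- occupancy_model(lay_e, occupancy = list(H3 = rep(1, 10)),
                       ip_efficiency = c(H3 = 1), spike_layout = lay_s,
                       spike_occupancy = list(H3 = rep(1, 10)))
  cfg <- sim_config(mix_ratio = 1 / 8, expectation = TRUE,
                    total_input_reads = 9e5)
  s <- simulate_chip(m, cfg, "wt", "H3")
  spike_frac <- sum(unlist(s$input_spike$values)) /
    (sum(unlist(s$input_spike$values)) + sum(unlist(s$input_exp$values)))
  expect_equal(spike_frac, (1 / 8) / (1 + 1 / 8), tolerance = 1e-12)
  # per-bin expectations are exactly uniform within each genome
  expect_equal(unlist(s$input_exp$values, use.names = FALSE),
               rep(9e5 * (8 / 9) / 10, 10), tolerance = 1e-12)
})

test_that("expectation mode recovers a condition fold change exactly", {
  lay <- toy_layout(20)
  occ <- rep(2, 20); bound <- 3:8; f <- 1.7
  m <- occupancy_model(lay, occupancy = list(H3 = occ),
                       ip_efficiency = c(H3 = 0.5),
                       condition_effects = list(
                         list(condition = "mut", target = "H3",
                              bins = bound, factor = f)))
  cfg <- sim_config(expectation = TRUE)
  wt <- simulate_chip(m, cfg, "wt", "H3")
  mut <- simulate_chip(m, cfg, "mut", "H3")
  # spike-normalized mutant/wt ratio on the bound bins is exactly f
  n <- analytic_eip(m, "mut", "H3") / analytic_eip(m, "wt", "H3") *
    sum(unlist(wt$ip_exp$values)) / sum(unlist(mut$ip_exp$values))
  ratio <- n * unlist(mut$ip_exp$values, use.names = FALSE) /
    unlist(wt$ip_exp$values, use.names = FALSE)
  expect_equal(ratio[bound], rep(f, length(bound)), tolerance = 1e-12)
  expect_equal(ratio[-bound], rep(1, 14), tolerance = 1e-12)
})

test_that("empirical E^IP from a deep simulation converges to the analytic value", {
  m <- example_model(n_genes = 20, n_bound = 6)
  cfg <- sim_config(seed = 99, total_ip_reads = 2e6, total_input_reads = 2e6)
  s <- simulate_chip(m, cfg, "wt", "H3")
  e_hat <- compute_eip(s$counts)
  e_true <- analytic_eip(m, "wt", "H3")
  # binomial split error on log E^IP
  se_log <- sqrt(1 / s$counts$ip_exp + 1 / s$counts$ip_spike +
                   1 / s$counts$input_exp + 1 / s$counts$input_spike)
  expect_lt(abs(log(e_hat / e_true)), 3 * se_log)
})

test_that("loss-assay simulation follows the geometric retention model", {
  # no loss: expected F equals I
  obs0 <- simulate_loss_assay(0, N = 5, I = 80, colonies = 4,
                              expectation = TRUE)
  expect_equal(obs0$F, rep(80, 4))
  # one halving division
  obs1 <- simulate_loss_assay(0.5, N = 1, I = 100, colonies = 1,
                              expectation = TRUE)
  expect_equal(obs1$F, 50)
  expect_error(simulate_loss_assay(0.1, I = 0, expectation = TRUE), "I must")
  expect_error(simulate_loss_assay(0.1, N = 5, I = 50), "seed")
  # sampled draws are reproducible and bounded
  obs <- simulate_loss_assay(0.05, N = 10, I = 100, colonies = 50,
                             n_cells = 500, seed = 3)
  obs_b <- simulate_loss_assay(0.05, N = 10, I = 100, colonies = 50,
                               n_cells = 500, seed = 3)
  expect_identical(obs, obs_b)
  expect_true(all(obs$F >= 0 & obs$F <= 100))
})
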