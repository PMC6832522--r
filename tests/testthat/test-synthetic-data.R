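test_that("every generator is bit-identical under a fixed seed", {
  expect_identical(generate_flow_events(500, 0.3, seed = 11),
                   generate_flow_events(500, 0.3, seed = 11))
  p <- treg_params(k_f = 0.2, k_r = 0.05)
  tm <- seq(0, 48, length.out = 12)
  expect_identical(generate_trajectories("III", p, 1000, 0, tm, 0.1, seed = 4),
                   generate_trajectories("III", p, 1000, 0, tm, 0.1, seed = 4))
  expect_identical(
    generate_spatial_image(64, "clustered", n_points = 400, seed = 8),
    generate_spatial_image(64, "clustered", n_points = 400, seed = 8))
  cfg <- scrna_config(n_genes = 30, n_cells_per_group = c(WT = 50, MT = 50,
                                                          TREG = 50),
                      isg_gene_ids = c("G1", "G2"))
  expect_identical(generate_scrna_counts(cfg, seed = 5),
                   generate_scrna_counts(cfg, seed = 5))
})

test_that("flow mixture respects degenerate converted fractions", {
  ev0 <- generate_flow_events(2000, 0, seed = 1)
  expect_false(any(ev0$converted))
  expect_lt(gate_fraction(ev0, default_treg_gate()), 0.01)
  ev1 <- generate_flow_events(2000, 1, seed = 1)
  expect_true(all(ev1$converted))
  expect_gt(gate_fraction(ev1, default_treg_gate()), 0.99)
})

test_that("gated fraction tracks the converted fraction", {
  # binomial CI oracle at n = 10000: 0.30 +/- 0.02 covers > 5 sigma
  ev <- generate_flow_events(10000, 0.30, seed = 1)
  expect_lt(abs(gate_fraction(ev, default_treg_gate()) - 0.30), 0.02)
})

test_that("flow generator rejects invalid parameters", {
  expect_error(generate_flow_events(100, 1.2), "\\[0, 1\\]")
  expect_error(generate_flow_events(0, 0.5), ">= 1")
  bad <- default_flow_channels()
  bad$CD4[["sdlog"]] <- 0
  expect_error(generate_flow_events(100, 0.5, channel_params = bad),
               "positive")
})

test_that("noise-free trajectories equal the exact solution", {
  p <- treg_params(k_f = 0.2, k_r = 0.05)
  tm <- seq(0, 48, length.out = 12)
  d <- generate_trajectories("III", p, 1000, 0, tm, noise_sd = 0, seed = 1)
  tr <- simulate_treg("III", p, 1000, 0, tm)
  expect_identical(d$x_obs, tr$x)
  expect_identical(d$y_obs, tr$y)
})

test_that("noisy trajectories are unbiased on the log scale", {
  p <- treg_params(k_f = 0.2, k_r = 0.05)
  tm <- seq(0, 48, length.out = 200)
  d <- generate_trajectories("III", p, 1000, 10, tm, noise_sd = 0.05,
                             seed = 2)
  tr <- simulate_treg("III", p, 1000, 10, tm)
  resid <- log(d$x_obs) - log(tr$x)
  expect_lt(abs(mean(resid)), 0.02)
  expect_lt(abs(sd(resid) - 0.05), 0.015)
})

test_that("spatial patterns have exact foreground counts", {
  expect_identical(sum(generate_spatial_image(81, "solid")$pixels), 6561L)
  expect_identical(sum(generate_spatial_image(32, "empty")$pixels), 0L)
  expect_identical(
    sum(generate_spatial_image(81, "sierpinski_carpet")$pixels), 4096L)
  expect_identical(
    sum(generate_spatial_image(64, "uniform_random", n_points = 500,
                               seed = 3)$pixels), 500L)
  expect_identical(
    sum(generate_spatial_image(64, "clustered", n_points = 500,
                               seed = 3)$pixels), 500L)
})

test_that("carpet padding anchors at the origin and reports its level", {
  img <- generate_spatial_image(c(100, 90), "sierpinski_carpet")
  expect_match(img$provenance, "side=81")
  expect_false(any(img$pixels[82:100, ]))
  expect_false(any(img$pixels[, 82:90]))
  expect_identical(sum(img$pixels), 4096L)
})

test_that("spatial generator enforces its preconditions", {
  expect_error(generate_spatial_image(20, "sierpinski_carpet"), "27x27")
  expect_error(generate_spatial_image(8, "uniform_random", n_points = 100),
               "pixel count")
  expect_error(generate_spatial_image(1, "solid"), "2x2")
})

test_that("scRNA groups are exchangeable when effects are off", {
  base <- scrna_config(n_genes = 40,
                       n_cells_per_group = c(WT = 400, MT = 400, TREG = 400),
                       isg_gene_ids = paste0("G", 1:4))
  # responder fraction 0: MT carries no elevated cells at all
  cfg0 <- base
  cfg0$mt_responder_fraction <- 0
  cm0 <- generate_scrna_counts(cfg0, seed = 6)
  expect_false(any(cm0$mt_responder))
  isg_means <- function(cm, grp)
    mean(cm$counts[paste0("G", 1:4), cm$group == grp])
  expect_lt(abs(isg_means(cm0, "MT") - isg_means(cm0, "WT")), 0.3)
  # multiplier 1: all three groups share the baseline distribution
  cfg1 <- base
  cfg1$effect_multiplier <- 1
  cm1 <- generate_scrna_counts(cfg1, seed = 6)
  expect_lt(abs(isg_means(cm1, "TREG") - isg_means(cm1, "WT")), 0.3)
})

test_that("ISG fraction agrees with the analytic plug-in oracle", {
  # Oracle: threshold ~ E[count | nonzero] of the elevated distribution;
  # expected fraction = sum over strata of (1 - dropout) P(NB > threshold).
  cfg <- scrna_config()
  mu_hi <- cfg$baseline_mean * cfg$effect_multiplier
  thr <- mu_hi / (1 - dnbinom(0, mu = mu_hi, size = cfg$dispersion))
  p_hi <- 1 - pnbinom(floor(thr), mu = mu_hi, size = cfg$dispersion)
  p_lo <- 1 - pnbinom(floor(thr), mu = cfg$baseline_mean,
                      size = cfg$dispersion)
  expected <- 100 * (1 - cfg$dropout_rate) *
    (cfg$mt_responder_fraction * p_hi +
       (1 - cfg$mt_responder_fraction) * p_lo)
  fr <- vapply(1:10, function(s)
    isg_upregulated_fraction(generate_scrna_counts(cfg, seed = s),
                             "G1")$fraction_above, numeric(1))
  expect_lt(abs(mean(fr) - expected), 1.5)
})

test_that("scrna_config rejects inconsistent settings", {
  expect_error(scrna_config(n_genes = 0), "positive")
  expect_error(scrna_config(isg_gene_ids = "G999"), "subset")
  expect_error(scrna_config(mt_responder_fraction = 1.5), "\\[0, 1\\]")
  expect_error(scrna_config(baseline_mean = 0), "> 0")
  expect_error(scrna_config(dropout_rate = 1), "\\[0, 1\\)")
  expect_error(scrna_config(n_cells_per_group = c(WT = 10, MT = 10)),
               "TREG")
})
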