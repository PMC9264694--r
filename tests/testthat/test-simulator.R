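test_that("config validation enforces the generative constraints", {
  expect_s3_class(sim_config(), "decaf_simconfig")
  expect_error(sim_config(sigma_effect = 0.5, sigma_nf = 0.6), "sum to < 1")
  expect_error(sim_config(maf = 0), "maf")
  expect_error(sim_config(rho = 1), "rho")
})

test_that("allelic simulation conserves reads and honors HWE het counts", {
  cfg <- sim_config(maf = 0.25, n_individuals = 200, pi_f = 0.7)
  sim <- simulate_allelic(cfg, seed = 51)
  obs <- sim$observations
  expect_equal(obs$ref_reads + obs$alt_reads, obs$depth)
  expect_equal(nrow(obs), 2 * 0.25 * 0.75 * 200)  # = 75 expected hets
  expect_equal(sim$truth$n_het, 75)
})

test_that("deterministic extremes and null symmetry of the allelic model", {
  # f = 1 and pi_f = 1 with no overdispersion: every read is ALT
  cfg1 <- sim_config(pi_f = 1, rho = 0, mean_depth = 10,
                     fraction_source = rep(1, 20), n_individuals = 100)
  sim1 <- suppressWarnings(simulate_allelic(cfg1, seed = 52))
  expect_true(all(sim1$observations$ref_reads == 0))
  # pi_f = 0.5 pools to an allelic fraction of ~0.5
  cfg2 <- sim_config(pi_f = 0.5, n_individuals = 2000, mean_depth = 50,
                     rho = 0)
  sim2 <- simulate_allelic(cfg2, seed = 53)
  tot <- sum(sim2$observations$depth)
  frac <- sum(sim2$observations$alt_reads) / tot
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / tot))
})

test_that("empirical allelic fraction converges to the mixture line", {
  # with rho = 0 and huge depth the per-individual fraction approaches
  # 0.5 (1 - f) + pi_f f
  cfg <- sim_config(pi_f = 0.8, rho = 0, mean_depth = 10000,
                    n_individuals = 500)
  sim <- simulate_allelic(cfg, seed = 54)
  obs <- sim$observations
  expected <- 0.5 * (1 - obs$f) + 0.8 * obs$f
  dev <- obs$alt_reads / obs$depth - expected
  expect_lt(mean(abs(dev)), 0.01)
  expect_lt(max(abs(dev)), 5 * sqrt(0.25 / 10000) + 0.01)
})

test_that("expression generator hits the configured variance shares", {
  cfg <- sim_config(sigma_effect = 0.04, n_individuals = 10000)
  set.seed(55)
  x <- rbinom(10000, 2, 0.25)
  f <- runif(10000)
  sim <- simulate_expression(cfg, x, f, nf = runif(10000))
  # empirical share of the x*f term
  xf <- scale(x * f)[, 1] * sqrt(0.04 / (1 - 0.04 - 0.0269))
  share <- var(xf) / var(sim$y)
  expect_gt(share, 0.03)
  expect_lt(share, 0.05)
  # all shares zero gives pure standard normal noise
  cfg0 <- sim_config(sigma_effect = 0, sigma_nf = 0, sigma_cnv = 0)
  sim0 <- simulate_expression(cfg0, x, f, nf = runif(10000), seed = 56)
  expect_equal(sd(sim0$y), 1, tolerance = 0.05)
  expect_equal(unname(sim0$truth$coefficients), rep(0, 3))
})

test_that("simulation is reproducible from its seed", {
  cfg <- sim_config(pi_f = 0.7)
  a <- simulate_cohort(cfg, seed = 57)
  b <- simulate_cohort(cfg, seed = 57)
  expect_identical(a, b)
  pw1 <- power_experiment(data.frame(pi_f = 0.6), n_reps = 20,
                          alpha = 0.05, seed = 58)
  pw2 <- power_experiment(data.frame(pi_f = 0.6), n_reps = 20,
                          alpha = 0.05, seed = 58)
  expect_identical(pw1, pw2)
})

test_that("cell-fraction sources behave as documented", {
  u <- sample_cell_fractions("uniform", 50, seed = 59)
  expect_true(all(u >= 0 & u <= 1))
  expect_identical(u, sample_cell_fractions("uniform", 50, seed = 59))
  real <- c(0.01, 0.05, 0.1, 0.12, 0.2, 0.22, 0.3, 0.4, 0.55, 0.9)
  bs <- sample_cell_fractions(real, 200, seed = 60)
  expect_true(all(bs %in% real))                 # bootstrap support
  expect_error(sample_cell_fractions(real[1:5], 10), "at least 10")
  expect_warning(sample_cell_fractions(rep(0.3, 12), 20),
                 "unidentifiable")
  # file source
  p <- tempfile()
  write.table(data.frame(fraction = real), p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  bf <- sample_cell_fractions(p, 30, seed = 61)
  expect_true(all(bf %in% real))
})

test_that("CNV carriers shift the allelic fraction as configured", {
  cfg <- sim_config(pi_f = 0.5, rho = 0, mean_depth = 5000,
                    cnv_model = "fixed", cnv_fraction = 0.5,
                    n_individuals = 1000)
  sim <- simulate_allelic(cfg, seed = 62)
  obs <- sim$observations
  frac <- obs$alt_reads / obs$depth
  base <- 0.5 * (1 - obs$f) + 0.5 * obs$f
  expect_equal(mean(frac[obs$cnv_carrier] - base[obs$cnv_carrier]), 0.1,
               tolerance = 0.01)
  expect_equal(mean(frac[!obs$cnv_carrier] - base[!obs$cnv_carrier]), 0,
               tolerance = 0.01)
  # random model shifts either direction with mean ~0
  cfgr <- sim_config(pi_f = 0.5, rho = 0, mean_depth = 5000,
                     cnv_model = "random", cnv_fraction = 0.5,
                     n_individuals = 1000)
  simr <- simulate_allelic(cfgr, seed = 63)
  obsr <- simr$observations
  fr <- obsr$alt_reads / obsr$depth - 0.5
  shifts <- fr[obsr$cnv_carrier]
  expect_gt(mean(abs(shifts)), 0.05)
  expect_lt(abs(mean(shifts)), 0.03)
})

test_that("power increases with cohort size and null cells sit near alpha", {
  pw <- power_experiment(data.frame(n_individuals = c(100, 400, 1000)),
                         base_config = sim_config(pi_f = 0.7),
                         n_reps = 150, alpha = 0.05 / 20000, seed = 64)
  dec <- pw[pw$test == "DeCAF", ]
  # non-decreasing in N with 2 MC-SE slack
  expect_true(all(diff(dec$power) >= -2 * max(dec$mc_se)))
  null_pw <- power_experiment(
    data.frame(pi_f = 0.5, sigma_effect = 0), n_reps = 300,
    alpha = 0.05, seed = 65)
  expect_true(all(abs(null_pw$power - 0.05) < 0.05))
})
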