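test_that("beta-binomial likelihood has the right closed forms and limits", {
  obs1 <- data.frame(alt_reads = 5, depth = 10, overdispersion = 0)
  expect_equal(betabin_loglik(obs1, 0, matrix(1)),
               lchoose(10, 5) + 10 * log(0.5))
  # saturated: all reads alt, eta -> +Inf gives loglik -> 0
  obs2 <- data.frame(alt_reads = 10, depth = 10, overdispersion = 0)
  expect_lt(abs(betabin_loglik(obs2, 30, matrix(1))), 1e-8)
  # overdispersed case agrees with numerical integration over the Beta mix
  obs3 <- data.frame(alt_reads = 6, depth = 10, overdispersion = 0.0263)
  expect_equal(betabin_loglik(obs3, 0, matrix(1)),
               bb_log_pmf_integrate(6, 10, 0.5, 0.0263), tolerance = 1e-7)
  # depth-0 observations rejected
  expect_error(betabin_loglik(data.frame(alt_reads = 0, depth = 0,
                                         overdispersion = 0), 0, matrix(1)),
               "depth")
})

test_that("likelihood is invariant under allele swap with sign-flipped coefficients", {
  set.seed(3)
  n <- 40
  obs <- data.frame(alt_reads = rbinom(n, 50, 0.4), depth = 50,
                    overdispersion = runif(n, 0, 0.1))
  obs$ref_reads <- obs$depth - obs$alt_reads
  X <- cbind(1, runif(n))
  b <- c(0.3, -0.8)
  swapped <- transform(obs, alt_reads = ref_reads, ref_reads = alt_reads)
  expect_equal(betabin_loglik(obs, b, X), betabin_loglik(swapped, -b, X))
})

test_that("beta-binomial tends to the binomial as rho tends to 0", {
  set.seed(4)
  n <- 30
  obs <- data.frame(alt_reads = rbinom(n, 40, 0.5), depth = 40)
  X <- cbind(1, rnorm(n))
  b <- c(0.1, 0.4)
  obs$overdispersion <- 1e-8
  ll_bb <- betabin_loglik(obs, b, X)
  obs$overdispersion <- 0
  ll_bin <- betabin_loglik(obs, b, X)
  expect_equal(ll_bb, ll_bin, tolerance = 1e-4)
})

test_that("overdispersion MLE hits the boundary cases", {
  # perfectly balanced deep sites: no overdispersion signal
  est0 <- estimate_overdispersion(rep(50, 20), rep(50, 20))
  expect_lt(est0$rho, 1e-3)
  # fully polarized sites: near the upper clamp
  est1 <- estimate_overdispersion(rep(c(100, 0), 10), rep(c(0, 100), 10))
  expect_gt(est1$rho, 0.9)
  expect_lte(est1$rho, 0.999)
  expect_error(estimate_overdispersion(integer(0), integer(0)), "site")
})

test_that("overdispersion is recovered within 3 SEs in >=90% of replicates", {
  rho_true <- 0.0263
  set.seed(101)
  covered <- vapply(1:200, function(i) {
    n <- rep(100, 200)
    s <- (1 - rho_true) / rho_true
    alt <- rbinom(200, n, rbeta(200, 0.5 * s, 0.5 * s))
    est <- estimate_overdispersion(n - alt, alt)
    is.finite(est$se) && abs(est$rho - rho_true) <= 3 * est$se
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("cohort overdispersion table falls back below min_sites", {
  counts <- data.frame(
    individual = c(rep("a", 5), "b"),
    refCount = c(rpois(5, 30), 10), altCount = c(rpois(5, 30), 12))
  tab <- estimate_overdispersion_table(counts, min_sites = 3,
                                       fallback_rho = 0.05)
  expect_equal(tab$rho[tab$individual == "b"], 0.05)
  expect_equal(tab$n_sites[tab$individual == "a"], 5L)
  # per-region estimation keys on (individual, region)
  counts$region <- rep(c("r1", "r2"), 3)
  tab2 <- estimate_overdispersion_table(counts, by_region = TRUE,
                                        min_sites = 1)
  expect_setequal(tab2$region[tab2$individual == "a"], c("r1", "r2"))
})

test_that("iAI fit is null on perfectly balanced data and flags bad designs", {
  set.seed(6)
  n <- 80
  obs <- data.frame(alt_reads = 25, ref_reads = 25, depth = 50,
                    overdispersion = 0, f = runif(n))
  fit <- fit_iai(obs)
  expect_true(fit$identifiable)
  expect_lt(abs(fit$coefficients["mu_a"]), 1e-6)
  expect_lt(abs(fit$coefficients["alpha_f"]), 1e-6)
  # constant fraction makes alpha_f inseparable from the intercept
  obs$f <- 0.4
  fit2 <- fit_iai(obs)
  expect_false(fit2$identifiable)
  expect_null(fit2$z)
  # below min_het no fit is attempted
  fit3 <- fit_iai(obs[1:3, ], min_het = 5)
  expect_false(fit3$identifiable)
})

test_that("iAI at rho = 0 matches an independent binomial GLM", {
  set.seed(8)
  n <- 150
  f <- runif(n)
  pi_i <- plogis(0.2 + 0.9 * f)
  depth <- rpois(n, 60) + 1
  alt <- rbinom(n, depth, pi_i)
  obs <- data.frame(alt_reads = alt, ref_reads = depth - alt, depth = depth,
                    overdispersion = 0, f = f)
  fit <- fit_iai(obs)
  glm_fit <- glm(cbind(alt, depth - alt) ~ f, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(glm_fit)),
               tolerance = 1e-4)
  expect_equal(unname(fit$z),
               unname(summary(glm_fit)$coefficients[, "z value"]),
               tolerance = 1e-3)
})

test_that("focal-cell allelic fraction is recovered within 3 SEs in >=90% of replicates", {
  pi_f <- 0.7
  set.seed(109)
  hits <- vapply(1:200, function(i) {
    n <- 500
    f <- runif(n)
    depth <- rpois(n, 100)
    alt <- rbinom(n, depth, 0.5 * (1 - f) + pi_f * f)
    obs <- data.frame(alt_reads = alt, ref_reads = depth - alt,
                      depth = depth, overdispersion = 0, f = f)
    obs <- obs[obs$depth > 0, ]
    fit <- fit_iai(obs)
    # allelic fraction at f = 1 via the delta method on mu_a + alpha_f
    eta <- sum(fit$coefficients)
    se_eta <- sqrt(sum(fit$vcov))
    abs(plogis(eta) - pi_f) <= 3 * dlogis(eta) * se_eta
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Wald z for alpha_f grows with depth and with sample size", {
  run_z <- function(n, depth_mean, seed = 21) {
    set.seed(seed)
    f <- runif(n)
    depth <- rpois(n, depth_mean) + 1
    alt <- rbinom(n, depth, 0.5 * (1 - f) + 0.65 * f)
    fit <- fit_iai(data.frame(alt_reads = alt, ref_reads = depth - alt,
                              depth = depth, overdispersion = 0, f = f))
    abs(fit$z["alpha_f"])
  }
  z_small <- mean(vapply(1:30, function(s) run_z(100, 20, s), numeric(1)))
  z_deep <- mean(vapply(1:30, function(s) run_z(100, 200, s), numeric(1)))
  z_big <- mean(vapply(1:30, function(s) run_z(800, 20, s), numeric(1)))
  expect_gt(z_deep, z_small)
  expect_gt(z_big, z_small)
})
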