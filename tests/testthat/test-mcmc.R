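test_that("latent occupancy full conditional matches direct enumeration", {
  # certainty and symmetry limits
  p1 <- sample_latent_z(y = 3, K = 12, site = 1, psi = 1,
                        theta11 = 0.9, theta10 = 0.1, p11 = 0.8, p10 = 0.02,
                        prob = TRUE)
  expect_equal(p1, 1)
  # theta11 = theta10, p11 = p10: the data carry no information
  p2 <- sample_latent_z(y = c(5, 7), K = 12, site = c(1, 2), psi = 0.37,
                        theta11 = 0.5, theta10 = 0.5, p11 = 0.3, p10 = 0.3,
                        prob = TRUE)
  expect_equal(p2, c(0.37, 0.37))

  # brute-force enumeration of both mixture terms with exact binomial pmfs
  psi <- 0.2; t11 <- 0.95; t10 <- 0.015; p11 <- 0.8; p10 <- 0.02
  K <- 12; y <- 12
  num <- psi * (t11 * dbinom(y, K, p11) + (1 - t11) * dbinom(y, K, p10))
  den <- num + (1 - psi) * (t10 * dbinom(y, K, p11) +
                              (1 - t10) * dbinom(y, K, p10))
  oracle <- num / den
  expect_equal(sample_latent_z(y, K, 1, psi, t11, t10, p11, p10, prob = TRUE),
               oracle, tolerance = 1e-12)
  set.seed(2)
  draws <- replicate(4000, sample_latent_z(y, K, 1, psi, t11, t10, p11, p10))
  expect_lt(abs(mean(draws) - oracle),
            4 * sqrt(oracle * (1 - oracle) / 4000))
})

test_that("latent sample-state full conditional matches direct arithmetic", {
  # p11 = p10: probability reduces to theta regardless of y
  pw <- sample_latent_w(y = c(0, 6, 12), K = 12, site = c(1, 1, 2),
                        z = c(1, 0), theta11 = 0.7, theta10 = 0.2,
                        p11 = 0.4, p10 = 0.4, prob = TRUE)
  expect_equal(pw, c(0.7, 0.7, 0.2))

  # theta = 0.9, y = 0: 0.9 * 0.2^12 / (0.9 * 0.2^12 + 0.1 * 0.98^12)
  pw0 <- sample_latent_w(0, 12, 1, z = 1, theta11 = 0.9, theta10 = 0.1,
                         p11 = 0.8, p10 = 0.02, prob = TRUE)
  expect_equal(pw0, 0.9 * 0.2^12 / (0.9 * 0.2^12 + 0.1 * 0.98^12),
               tolerance = 1e-10)
  expect_equal(pw0, 4.70e-8, tolerance = 1e-2)
  pw12 <- sample_latent_w(12, 12, 1, z = 1, theta11 = 0.9, theta10 = 0.1,
                          p11 = 0.8, p10 = 0.02, prob = TRUE)
  expect_gt(pw12, 1 - 1e-15)
})

test_that("error-probability updates are conjugate and respect the priors", {
  cfg <- model_config()
  # empty strata fall back to the prior: Beta(9, 1) has mean 0.9
  set.seed(3)
  th11 <- replicate(3000, {
    # all sites unoccupied, all samples DNA-free: theta11 and p11 unidentified
    update_error_probs(y = c(0, 0), K = 12, site = c(1, 2), z = c(0, 0),
                       w = c(0, 0), cfg)$theta11
  })
  expect_lt(abs(mean(th11) - 0.9), 0.02)

  # 100 all-positive samples with y = K = 12: p11 ~ Beta(9 + 1200, 1)
  set.seed(4)
  p11 <- replicate(2000, {
    update_error_probs(y = rep(12, 100), K = 12, site = 1:100,
                       z = rep(1, 100), w = rep(1, 100), cfg)$p11
  })
  expect_lt(abs(mean(p11) - 1209 / 1210), 4 * sd(p11) / sqrt(2000))

  # concentration: 1e4 Bernoulli trials at rate 0.02 pin p10 within 0.005
  set.seed(5)
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    y <- rbinom(1e4, 1, 0.02)
    m <- mean(replicate(200, update_error_probs(
      y, K = 1, site = seq_along(y), z = rep(0, 1e4), w = rep(0, 1e4),
      cfg)$p10))
    abs(m - 0.02) < 0.005
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("prior recovery: unidentified error rates reproduce their beta priors", {
  cfg <- model_config(enforce_ordering = FALSE)
  set.seed(6)
  d <- t(replicate(10000, {
    u <- update_error_probs(y = 12, K = 12, site = 1, z = 1, w = 1, cfg)
    c(u$theta10, u$p10)  # both strata empty here
  }))
  expect_gt(ks.test(d[, 1], pbeta, 1, 9)$p.value, 0.001)
  expect_gt(ks.test(d[, 2], pbeta, 1, 9)$p.value, 0.001)
})

test_that("ordering constraint holds in every retained draw", {
  sv <- simulate_survey(fitted_gen_params(S = 150, seed = 12))
  fit <- fit_occupancy(sv$detections, config = short_config(seed = 2))
  expect_true(all(fit$theta11 > fit$theta10))
  expect_true(all(fit$p11 > fit$p10))
  expect_length(fit$theta11, 100)
  # beta entries outside active groups are exactly zero (intercept-only: none)
  expect_equal(ncol(fit$beta), 1)
})

test_that("fits are reproducible under identical config and seed", {
  sv <- simulate_survey(fitted_gen_params(S = 80, K = 6, seed = 3))
  cfg <- model_config(n_burn = 100, n_iter = 100, n_thinned_draws = 20,
                      seed = 9)
  f1 <- fit_occupancy(sv$detections, config = cfg)
  f2 <- fit_occupancy(sv$detections, config = cfg)
  expect_identical(f1, f2)
})

test_that("degenerate all-zero data return draws near the prior", {
  det <- data.frame(site_id = 1:30, sample_id = 1, k_replicates = 12,
                    y_positive = 0)
  fit <- fit_occupancy(det, config = short_config(seed = 4))
  expect_true(all(is.finite(fit$theta11)))
  # p11 is informed only through its prior here (no DNA-positive samples)
  expect_lt(abs(mean(fit$p11) - 0.9), 0.15)
})

test_that("excluded groups carry exactly zero coefficients in stored draws", {
  tbl <- simulate_covariate_table(120, n_continuous = 3, seed = 5)
  des <- build_design_matrix(tbl, c("cont1", "cont2", "cont3"))
  sv <- simulate_survey(gen_params(S = 120, K = 12, design = des,
                                   beta = c(-1.4, 0, 0, 0), seed = 6))
  fit <- fit_occupancy(sv$detections, design = des,
                       config = short_config(seed = 7))
  for (g in fit$groups) {
    off <- !fit$gamma[, g]
    expect_true(all(fit$beta[off, des$groups[[g]]] == 0))
  }
})
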