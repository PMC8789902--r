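make_factor_draws <- function(n = 200, seed = 51) {
  # a 3-level factor design plus fake coefficient draws, for contrast tests
  set.seed(seed)
  tbl <- data.frame(site_id = 1:30,
                    f = factor(rep(c("a", "b", "c"), each = 10)))
  des <- build_design_matrix(tbl, "f")
  beta <- cbind(rnorm(n, 0, 0.3), rnorm(n, 1, 0.5), rnorm(n, -0.5, 0.5))
  colnames(beta) <- colnames(des$X)
  gamma <- matrix(TRUE, n, 1, dimnames = list(NULL, "f"))
  fake_draws(beta, gamma, design = des)
}

test_that("PIP is the inclusion frequency over retained draws", {
  tbl <- data.frame(site_id = 1:10, x = rnorm(10))
  des <- build_design_matrix(tbl, "x")
  beta <- cbind(rep(0, 4), c(1, 0, 1, 1))
  colnames(beta) <- colnames(des$X)
  gamma <- matrix(c(TRUE, FALSE, TRUE, TRUE), 4, 1,
                  dimnames = list(NULL, "x"))
  pr <- compute_pip(fake_draws(beta, gamma, design = des))
  expect_equal(pr$groups$pip, 0.75)
  expect_true(pr$groups$important)

  # a never-selected group reports all-zero marginal draws
  gamma0 <- matrix(FALSE, 4, 1, dimnames = list(NULL, "x"))
  beta0 <- beta; beta0[, 2] <- 0
  pr0 <- compute_pip(fake_draws(beta0, gamma0, design = des))
  expect_equal(pr0$groups$pip, 0)
  expect_false(pr0$groups$important)
  cf <- pr0$coefficients[pr0$coefficients$column == "x", ]
  expect_equal(cf$mean, 0)
  expect_equal(c(cf$lower95, cf$upper95), c(0, 0))
})

test_that("pairwise contrasts match brute-force recomputation from raw draws", {
  dr <- make_factor_draws()
  ct <- pairwise_contrasts(dr, "f")
  expect_equal(nrow(ct), 3)  # L(L-1)/2 with L = 3

  # brute force: per-draw level coefficients with baseline == 0
  B <- cbind(a = 0, b = dr$beta[, "f_b"], c = dr$beta[, "f_c"])
  for (i in seq_len(nrow(ct))) {
    d <- B[, ct$level_a[i]] - B[, ct$level_b[i]]
    expect_equal(ct$mean[i], mean(d))
    expect_equal(ct$lower95[i], unname(quantile(d, 0.025)))
    expect_equal(ct$upper95[i], unname(quantile(d, 0.975)))
  }

  # identical draws for two levels: difference 0 with degenerate interval
  dr2 <- dr; dr2$beta[, "f_c"] <- dr2$beta[, "f_b"]
  ct2 <- pairwise_contrasts(dr2, "f")
  bc <- ct2[ct2$level_a == "b" & ct2$level_b == "c", ]
  expect_equal(c(bc$mean, bc$lower95, bc$upper95), c(0, 0, 0))

  # a constant unit shift gives a degenerate unit contrast
  dr3 <- dr; dr3$beta[, "f_c"] <- dr3$beta[, "f_b"] + 1
  ct3 <- pairwise_contrasts(dr3, "f")
  bc3 <- ct3[ct3$level_a == "b" & ct3$level_b == "c", ]
  expect_equal(c(bc3$mean, bc3$lower95, bc3$upper95), c(-1, -1, -1))
  expect_true(bc3$excludes_zero)
})

test_that("conditional absence follows the exact posterior formula", {
  p <- fitted_values
  dr <- draws_from_values(p$psi, p$theta11, p$theta10, p$p11, p$p10,
                          K = 12, n = 1)
  # direct arithmetic oracle at x = 0
  b1 <- dbinom(0, 12, p$p11); b0 <- dbinom(0, 12, p$p10)
  num <- p$psi * (p$theta11 * b1 + (1 - p$theta11) * b0)
  den <- num + (1 - p$psi) * (p$theta10 * b1 + (1 - p$theta10) * b0)
  oracle <- 1 - num / den
  ca <- conditional_absence(dr, 0, 12)
  expect_equal(ca$mean, oracle, tolerance = 1e-12)

  # normalization: absence + presence = 1 per draw
  pres <- ednaocc:::psi_given_x(p$psi, p$theta11, p$theta10, p$p11, p$p10,
                                0, 12)
  expect_equal(ca$mean + pres, 1, tolerance = 1e-12)

  # structural zero: with theta10 = p10 = 0 a positive implies presence
  dr0 <- draws_from_values(0.3, 0.9, 0, 0.8, 0, K = 12, n = 5)
  ca0 <- conditional_absence(dr0, 1:12, 12)
  expect_true(all(ca0$mean == 0))

  # Fig-3 shape: non-increasing in x >= 1 at the fitted values
  drf <- draws_from_values(p$psi, p$theta11, p$theta10, p$p11, p$p10,
                           K = 12, n = 50)
  caf <- conditional_absence(drf, 0:12, 12)
  expect_true(all(diff(caf$mean[caf$x >= 1]) <= 1e-12))
  expect_gt(caf$mean[caf$x == 2], 0.9)   # 0-3 replicates: likely absent
  expect_lt(caf$mean[caf$x == 6], 0.15)  # 5-12 replicates: likely present
})

test_that("naive occupancy counts thresholded sites and is monotone", {
  det <- data.frame(site_id = 1:5, sample_id = 1, k_replicates = 12,
                    y_positive = c(0, 1, 2, 3, 12))
  expect_equal(naive_occupancy(det, 2)$count, 3)
  expect_equal(naive_occupancy(det, 2)$proportion, 0.6)
  z <- data.frame(site_id = 1:4, sample_id = 1, k_replicates = 12,
                  y_positive = 0)
  expect_equal(naive_occupancy(z, 1)$count, 0)
  expect_equal(naive_occupancy(z, 1)$proportion, 0)

  set.seed(61)
  for (i in 1:5) {
    sv <- simulate_survey(fitted_gen_params(S = 300, seed = 60 + i))
    counts <- naive_occupancy(sv$detections, 1:12)$count
    expect_true(all(diff(counts) <= 0))
  }

  # false positives inflate the naive estimate relative to the truth
  sv <- simulate_survey(fitted_gen_params(S = 5000, seed = 71))
  expect_gt(naive_occupancy(sv$detections, 1)$proportion, mean(sv$z))
})

test_that("false-positive magnification across replicates is exact", {
  expect_equal(fp_magnification(0, 12), 0)
  expect_equal(fp_magnification(0.3, 1), 0.3)
  expect_equal(round(fp_magnification(0.02, 12), 5), 0.21528)
  # Stage-1 path included, for an unoccupied site
  v <- fp_magnification(0.02, 12, theta_fp = 0.015, p_tp = 0.808)
  expect_equal(v, 0.015 * (1 - (1 - 0.808)^12) +
                 0.985 * (1 - 0.98^12), tolerance = 1e-12)
  expect_error(fp_magnification(0.02, 12, theta_fp = 0.5), "p_tp")
})
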