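test_that("degenerate parameter settings give deterministic detection counts", {
  sv <- simulate_survey(gen_params(S = 40, M = 2, K = 5, psi = 1,
                                   theta11 = 1, theta10 = 0, p11 = 1,
                                   p10 = 0, seed = 1))
  expect_true(all(sv$detections$y_positive == 5))
  expect_true(all(sv$z == 1) && all(sv$w == 1))

  sv0 <- simulate_survey(gen_params(S = 40, M = 2, K = 5, psi = 0,
                                    theta11 = 1, theta10 = 0, p11 = 1,
                                    p10 = 0, seed = 1))
  expect_true(all(sv0$w == 0))
  expect_true(all(sv0$detections$y_positive == 0))
})

test_that("unoccupied surveys with lab false positives are Binomial(K, p10)", {
  sv <- simulate_survey(gen_params(S = 20000, M = 1, K = 12, psi = 0,
                                   theta10 = 0, p10 = 0.1, seed = 3))
  expect_true(all(sv$w == 0))
  obs <- tabulate(sv$detections$y_positive + 1L, 13)
  ct <- suppressWarnings(
    chisq.test(obs, p = dbinom(0:12, 12, 0.1), rescale.p = TRUE))
  expect_gt(ct$p.value, 0.001)
})

test_that("marginal DNA-positive fraction matches the closed-form mixture", {
  # oracle: P(w = 1) = psi * theta11 + (1 - psi) * theta10
  p <- fitted_values
  expected <- p$psi * p$theta11 + (1 - p$psi) * p$theta10
  expect_equal(expected, 0.1997, tolerance = 1e-3)
  sv <- simulate_survey(fitted_gen_params(S = 4925, seed = 5))
  se <- sqrt(expected * (1 - expected) / 4925)
  expect_lt(abs(mean(sv$w) - expected), 4 * se)
})

test_that("occupancy and DNA-state frequencies converge to generating values", {
  sv <- simulate_survey(fitted_gen_params(S = 1e5, seed = 8))
  p <- fitted_values
  expect_lt(abs(mean(sv$z) - p$psi), 3 * sqrt(p$psi * (1 - p$psi) / 1e5))
  # replicate counts in DNA-positive samples are Binomial(K, p11)
  ypos <- sv$detections$y_positive[sv$w == 1]
  ct <- suppressWarnings(
    chisq.test(tabulate(ypos + 1L, 13), p = dbinom(0:12, 12, p$p11),
               rescale.p = TRUE))
  expect_gt(ct$p.value, 0.001)
})

test_that("identical seeds reproduce surveys byte-for-byte", {
  a <- simulate_survey(fitted_gen_params(S = 200, seed = 42))
  b <- simulate_survey(fitted_gen_params(S = 200, seed = 42))
  expect_identical(a, b)
  d1 <- tempfile(fileext = ".csv"); d2 <- tempfile(fileext = ".csv")
  write_detection_table(a$detections, d1)
  write_detection_table(b$detections, d2)
  expect_identical(unname(tools::md5sum(d1)), unname(tools::md5sum(d2)))
})

test_that("covariate-linked occupancy uses the shared design encoding", {
  tbl <- simulate_covariate_table(500, n_continuous = 2, seed = 2)
  des <- build_design_matrix(tbl, c("cont1", "cont2"))
  beta <- c(`(Intercept)` = -1, cont1 = 1.5, cont2 = 0)
  sv <- simulate_survey(gen_params(S = 500, K = 12, design = des, beta = beta,
                                   seed = 9))
  psi <- plogis(des$X %*% beta)
  expect_equal(sv$psi, as.numeric(psi))
  expect_lt(abs(mean(sv$z) - mean(psi)), 4 * sqrt(mean(psi) / 500))
})

test_that("covariate tables honour shape, frequencies and correlation", {
  tbl <- simulate_covariate_table(10, n_continuous = 2,
                                  categorical = list(hab = list(
                                    levels = c("a", "b", "c"),
                                    freqs = c(0.8, 0.1, 0.1))),
                                  seed = 1)
  expect_equal(dim(tbl), c(10, 4))
  expect_true(all(tbl$hab %in% c("a", "b", "c")))

  r1 <- simulate_covariate_table(1000, n_continuous = 2,
                                 corr = matrix(c(1, 1, 1, 1), 2), seed = 4)
  expect_gte(cor(r1$cont1, r1$cont2), 0.99)

  lc <- simulate_covariate_table(5000, n_continuous = 0,
                                 categorical = list(landcover = 17), seed = 6)
  expect_length(levels(lc$landcover), 17)

  expect_error(simulate_covariate_table(10, categorical = list(
    bad = list(levels = c("a", "b"), freqs = c(0.5, 0.4)))), "sum to 1")
})

test_that("invalid generator parameters are rejected", {
  expect_error(gen_params(S = 0), "S")
  expect_error(gen_params(S = 10, theta11 = 1.2), "theta11")
  expect_error(gen_params(S = 10, psi = -0.1), "psi")
  expect_error(gen_params(S = 10, psi = NULL), "together")
})
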