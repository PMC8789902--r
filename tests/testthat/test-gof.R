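test_that("degenerate parameter draws give point-mass count distributions", {
  dr0 <- draws_from_values(0, 0.9, 0, 0.8, 0, K = 12, n = 20)
  g0 <- gof_simulate(dr0, S = 100, M = 1, K = 12, seed = 1)
  expect_true(all(g0$counts[, "0"] == 100))
  expect_true(all(g0$counts[, -1] == 0))
  expect_true(all(g0$fp_replicates[, "0"] == 100))  # all samples DNA-free

  dr1 <- draws_from_values(1, 1, 0, 1, 0, K = 12, n = 20)
  g1 <- gof_simulate(dr1, S = 100, M = 1, K = 12, seed = 2)
  expect_true(all(g1$counts[, "12"] == 100))
})

test_that("stage tallies conserve the sample total in every repeat", {
  p <- fitted_values
  dr <- draws_from_values(p$psi, p$theta11, p$theta10, p$p11, p$p10,
                          K = 12, n = 100)
  g <- gof_simulate(dr, S = 500, M = 2, K = 12, seed = 3)
  expect_true(all(rowSums(g$counts) == 1000))
  expect_true(all(rowSums(g$fp_replicates) + rowSums(g$tp_replicates) == 1000))
  expect_true(all(rowSums(g$stage1) == 1000))
  # false-positive replicates in DNA-free samples are Binomial(K, p10)
  n_free <- rowSums(g$fp_replicates)
  fp_mean <- sum(g$fp_replicates %*% (0:12)) / sum(n_free)
  se <- sqrt(12 * p$p10 * (1 - p$p10) / sum(n_free))
  expect_lt(abs(fp_mean - 12 * p$p10), 3 * se)
})

test_that("repeats reuse retained draws one-for-one", {
  p <- fitted_values
  dr <- draws_from_values(p$psi, p$theta11, p$theta10, p$p11, p$p10,
                          K = 12, n = 30)
  expect_error(gof_simulate(dr, S = 50, n_repeats = 31), "retained draws")
  g <- gof_simulate(dr, S = 50, K = 12, n_repeats = 10, seed = 4)
  expect_equal(nrow(g$counts), 10)
})

test_that("covariate-driven draws require and use the design", {
  tbl <- simulate_covariate_table(200, n_continuous = 1, seed = 5)
  des <- build_design_matrix(tbl, "cont1")
  sv <- simulate_survey(gen_params(S = 200, K = 12, design = des,
                                   beta = c(-1, 1.5), seed = 6))
  fit <- fit_occupancy(sv$detections, design = des,
                       config = short_config(ads_moves = 2,
                                             expected_num_covariates = 1,
                                             seed = 7))
  if (any(fit$beta[, "cont1"] != 0)) {
    stripped <- fit; stripped$design <- NULL
    expect_error(gof_simulate(stripped, S = 200, K = 12,
                              n_repeats = nrow(fit$beta)), "design")
  }
  g <- gof_simulate(fit, S = 200, K = 12, design = des, seed = 8)
  expect_equal(rowSums(g$counts), rep(200, nrow(g$counts)))
})

test_that("observed data are placed against the simulated envelope", {
  p <- fitted_values
  dr <- draws_from_values(p$psi, p$theta11, p$theta10, p$p11, p$p10,
                          K = 12, n = 100)
  g <- gof_simulate(dr, S = 800, M = 1, K = 12, seed = 9)

  # data equal to one simulated repeat fall inside the envelope everywhere
  fake <- data.frame(site_id = 1:800, sample_id = 1, k_replicates = 12,
                     y_positive = rep(0:12, times = g$counts[1, ]))
  cmp <- gof_compare(g, fake)
  expect_equal(cmp$observed, unname(g$counts[1, ]))
  expect_gte(sum(cmp$inside), 11)

  # a gross excess at k = 0 is flagged as above the envelope
  excess <- data.frame(site_id = 1:800, sample_id = 1, k_replicates = 12,
                       y_positive = 0)
  cmp2 <- gof_compare(g, excess)
  expect_identical(cmp2$direction[cmp2$k == 0], "observed > simulated envelope")

  wrongK <- data.frame(site_id = 1, sample_id = 1, k_replicates = 6,
                       y_positive = 0)
  expect_error(gof_compare(g, wrongK), "different K")
})

test_that("data simulated from the model land inside their own envelope", {
  p <- fitted_values
  dr <- draws_from_values(p$psi, p$theta11, p$theta10, p$p11, p$p10,
                          K = 12, n = 100)
  ok <- vapply(1:10, function(s) {
    g <- gof_simulate(dr, S = 1000, M = 1, K = 12, seed = 100 + s)
    sv <- simulate_survey(fitted_gen_params(S = 1000, seed = 200 + s))
    cmp <- gof_compare(g, sv$detections)
    sum(cmp$inside) >= 11
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
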