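test_that("the recovery function has the stated shape and landmarks", {
  # zero at the absolute refractory period, saturating to A
  expect_equal(ecap_model(0.52, 104, 0.52, 1.0), 0)
  expect_equal(ecap_model(1e6, 104, 0.52, 1.0), 104)
  # clamped (not negative) below t0
  expect_equal(ecap_model(0.1, 104, 0.52, 1.0), 0)
  # one time constant past t0: 63.2% of A
  expect_equal(ecap_model(1.52, 104, 0.52, 1.0), 104 * (1 - exp(-1)))
  expect_equal(ecap_model(1.52, 104, 0.52, 1.0) / 104, 0.632, tolerance = 1e-3)

  # monotone non-decreasing and bounded in [0, A]
  mpi <- seq(0.1, 10, by = 0.05)
  v <- ecap_model(mpi, 104, 0.52, 1.0)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v >= 0 & v <= 104))

  expect_error(ecap_model(1, 104, 0.52, 0), "tau")
})

test_that("simulated curves are reproducible and carry the stated noise", {
  c0 <- simulate_recovery_curve(noise_sd = 0)
  expect_equal(c0$amplitude_uv, ecap_model(c0$mpi_ms, 104, 0.52, 1.0))

  c1 <- simulate_recovery_curve(noise_sd = 2, seed = 42)
  c2 <- simulate_recovery_curve(noise_sd = 2, seed = 42)
  expect_identical(c1$amplitude_uv, c2$amplitude_uv)

  # residual variance approaches noise_sd^2 (law of large numbers)
  big <- simulate_recovery_curve(mpi_ms = seq(0.3, 10, length.out = 1e4),
                                 noise_sd = 2, seed = 7)
  res <- big$amplitude_uv - ecap_model(big$mpi_ms, 104, 0.52, 1.0)
  expect_equal(stats::var(res), 4, tolerance = 0.1)

  expect_error(simulate_recovery_curve(mpi_ms = numeric(0)), "empty")
  expect_error(recovery_curve(c(1, 1, 2), c(0, 1, 2)), "strictly increasing")
})

test_that("the fitter recovers known parameters and reports uncertainty", {
  # noiseless generate-then-fit round trip: all three within 1e-4 relative
  cv <- simulate_recovery_curve(A = 104, t0 = 0.52, tau = 1.0, noise_sd = 0)
  ft <- fit_recovery(cv)
  expect_equal(unname(coef(ft)), c(104, 0.52, 1.0), tolerance = 1e-4)
  expect_equal(ft$t_recovery, 1.52, tolerance = 1e-3)
  expect_lt(ft$sigma, 1e-4)

  # model-object surface behaves like a fitted model
  expect_equal(predict(ft, 1.52), 104 * (1 - exp(-1)), tolerance = 1e-3)
  expect_equal(fitted(ft) + residuals(ft), cv$amplitude_uv)
  expect_output(print(ft), "absolute refractory")
  expect_output(print(summary(ft)), "t0 \\+ tau")
  sims <- simulate(ft, nsim = 2, seed = 1)
  expect_length(sims, 2L)
  expect_s3_class(sims[[1]], "recovery_curve")

  # degenerate all-zero curve is non-identifiable
  expect_error(fit_recovery(recovery_curve(1:5, numeric(5))),
               "non-identifiable")
  expect_error(fit_recovery(recovery_curve(c(1, 2, 3), c(0, 1, 2))),
               "at least 4")
})

test_that("t0 is estimated within its reported uncertainty under 2 uV noise", {
  # 100 seeded replicates; tolerance three times the representative
  # per-measurement standard error of 0.07 ms
  hits <- 0L
  for (s in 1:100) {
    cv <- simulate_recovery_curve(noise_sd = 2, seed = 1000L + s)
    ft <- fit_recovery(cv)
    if (abs(coef(ft)[["t0"]] - 0.52) <= 3 * 0.07) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("parameter bias vanishes as measurement noise goes to zero", {
  bias <- vapply(c(0, 0.5, 2), function(sd) {
    est <- vapply(1:100, function(s) {
      coef(fit_recovery(simulate_recovery_curve(noise_sd = sd,
                                                seed = 5000L + s)))
    }, numeric(3))
    mean(abs(rowMeans(est) - c(104, 0.52, 1.0)) / c(104, 0.52, 1.0))
  }, numeric(1))
  expect_lt(bias[1], 1e-6)
  expect_true(all(diff(bias) >= 0) || bias[3] < 0.02)
  expect_lt(bias[3], 0.05)
})

test_that("recovery curves round-trip through their text format", {
  cv <- simulate_recovery_curve(noise_sd = 1, seed = 3, electrode = 12)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_recovery_curve(cv, tmp)
  cv2 <- read_recovery_curve(tmp)
  expect_equal(cv2$mpi_ms, cv$mpi_ms, tolerance = 1e-5)
  expect_equal(cv2$amplitude_uv, cv$amplitude_uv, tolerance = 1e-4)
  expect_equal(attr(cv2, "electrode"), "12")
})

test_that("the block-design test behaves at the null, under effects, and on ties", {
  # identical conditions within every block: no effect by definition
  flat <- matrix(rep(c(60, 70, 80, 55, 65), 3), ncol = 3)
  qt <- quade_test(flat)
  expect_equal(qt$statistic, 0)
  expect_equal(qt$p_value, 1)

  # strong monotone condition effect across 10 blocks, cross-checked
  # against a within-block permutation null
  set.seed(8)
  eff <- matrix(stats::rnorm(30, sd = 2), 10, 3) +
         matrix(rep(c(0, 8, 16), each = 10), 10, 3) +
         stats::rnorm(10)                       # block offsets
  qe <- quade_test(eff)
  expect_lt(qe$p_value, 0.01)
  p_perm <- permutation_null_pvalue(eff, n_perm = 2000)
  expect_lt(p_perm, 0.01)
  # the two p-values agree in magnitude
  expect_equal(qe$p_value, p_perm, tolerance = 0.02)

  # invariance to order-preserving rescaling: a common positive gain plus
  # arbitrary per-block shifts leaves ranks and range ranks unchanged.
  # (Arbitrary per-block monotone maps can reorder the block ranges that
  # weight the statistic, so the invariance is stated in this form.)
  resc <- 3.7 * eff + matrix(stats::rnorm(10, 0, 50), 10, 3)
  expect_equal(quade_test(resc)$statistic, qe$statistic, tolerance = 1e-12)
  expect_equal(quade_test(resc)$p_value, qe$p_value, tolerance = 1e-12)

  expect_error(quade_test(eff[, 1, drop = FALSE]), "at least 2")
  expect_error(quade_test(eff[1, , drop = FALSE]), "at least 2")
  eff[2, 2] <- NA
  expect_error(quade_test(eff), "complete")
})

test_that("rank correlation matches the brute-force formula and flags degeneracy", {
  expect_equal(spearman_rank(1:6, (1:6)^2)$rho, 1)
  expect_equal(spearman_rank(1:6, -(1:6))$rho, -1)

  # tied data against the midrank Pearson oracle
  x <- c(1, 2, 2, 3, 5, 5, 5, 8)
  y <- c(0.4, 0.4, 1.2, 1.0, 2.5, 2.5, 3.0, 2.9)
  expect_equal(spearman_rank(x, y)$rho, spearman_oracle(x, y), tolerance = 1e-12)

  expect_warning(dg <- spearman_rank(rep(1, 5), 1:5), "constant")
  expect_true(dg$degenerate)
  expect_true(is.na(dg$rho))
  expect_error(spearman_rank(1:3, 1:4), "lengths")
})

test_that("per-subject best half-life uses argmax with ties toward smaller", {
  scores <- rbind(c(50, 60, 55, 40),     # best at 0.5
                  c(70, 70, 60, 50),     # tie 0 vs 0.5 -> 0, flagged
                  c(10, 20, 30, 40))     # best at 1.1
  th <- c(0, 0.5, 0.8, 1.1)
  bt <- best_t_half(scores, th)
  expect_equal(bt$best_t_half_ms, c(0.5, 0, 1.1))
  expect_equal(bt$tied, c(FALSE, TRUE, FALSE))
  # feeding the result into the rank correlation works end to end
  sr <- spearman_rank(bt$best_t_half_ms, c(1.0, 0.9, 1.4))
  expect_true(is.finite(sr$rho))
})
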