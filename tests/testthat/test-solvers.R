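test_that("TSVD with pseudo-inverse threshold exactly solves a well-posed noiseless system", {
  set.seed(51)
  B <- runif(8) + 0.2      # no leading zeros: full-rank system
  sys <- build_conv_matrix(B, 1)
  G_true <- matrix(abs(rnorm(10 * 8)), 10, 8)
  C <- conv_forward(sys, G_true)
  fit <- ctp_solve(C, sys, solver_config("tsvd", tsvd_threshold = 0))
  expect_lt(sqrt(sum((fit$G_hat - G_true)^2) / sum(G_true^2)), 1e-6)
  expect_true(fit$converged)
})

test_that("Tikhonov solves the ridge normal equations", {
  set.seed(52)
  sys <- build_conv_matrix(runif(6) + 0.1, 1)
  C <- matrix(rnorm(18), 3, 6)
  lam <- 0.7
  fit <- ctp_solve(C, sys, solver_config("tikhonov", lambda = lam,
                                         nonnegativity = FALSE))
  ref <- t(solve(crossprod(sys$A) + diag(lam, 6), t(sys$A) %*% t(C)))
  expect_equal(unname(fit$G_hat), unname(ref), tolerance = 1e-10)
})

test_that("ISTA with the regularizer off matches least squares on a well-conditioned system", {
  set.seed(53)
  sys <- build_conv_matrix(c(1, 0.2, 0.05, rep(0, 5)), 1)  # delta-like AIF
  G_true <- matrix(abs(rnorm(12 * 8)), 12, 8)
  C <- conv_forward(sys, G_true)
  fit <- ctp_solve(C, sys, solver_config("wa_tv", lambda = 0, max_iter = 500,
                                         tol = 1e-14))
  expect_lt(sqrt(sum((fit$G_hat - G_true)^2) / sum(G_true^2)), 1e-3)
})

test_that("objective trace is non-increasing on random problems, with and without projection", {
  set.seed(54)
  for (i in 1:6) {
    sys <- build_conv_matrix(runif(10), 1)
    C <- array(rnorm(5 * 5 * 1 * 10), c(5, 5, 1, 10))
    method <- if (i %% 2) "wa_tv" else "tv"
    fit <- ctp_solve(C, sys, solver_config(method, max_iter = 50,
                                           nonnegativity = i %% 3 == 0))
    d <- diff(fit$objective_trace$objective)
    if (length(d))
      expect_lte(max(d), 1e-10 * max(1, abs(fit$objective_trace$objective[-1])))
  }
})

test_that("wa_tv with a huge delta reduces to plain TV", {
  spec <- small_phantom_spec()
  ph <- build_phantom(spec)
  sys <- build_conv_matrix(ph$aif, spec$time$dt)
  noisy <- add_noise(ph$series, 2, 77)
  ftv <- ctp_solve(noisy, sys, solver_config("tv", max_iter = 60))
  fwa <- ctp_solve(noisy, sys, solver_config("wa_tv", delta = 1e9, max_iter = 60))
  expect_lt(sqrt(sum((ftv$G_hat - fwa$G_hat)^2) / max(sum(ftv$G_hat^2), 1e-300)),
            1e-6)
})

test_that("all-zero input returns an all-zero estimate immediately", {
  sys <- build_conv_matrix(runif(8), 1)
  C <- array(0, c(3, 3, 1, 8))
  fit <- ctp_solve(C, sys, solver_config("wa_tv"))
  expect_true(all(fit$G_hat == 0))
  expect_true(fit$converged)
  expect_equal(fit$n_iter, 0L)
})

test_that("nonnegativity flag controls the sign of the estimate", {
  set.seed(55)
  sys <- build_conv_matrix(runif(8) + 0.2, 1)
  C <- matrix(rnorm(40), 5, 8)   # incoherent data force negative pieces
  fit_on <- ctp_solve(C, sys, solver_config("tv", max_iter = 30))
  expect_true(all(fit_on$G_hat >= 0))
  fit_off <- ctp_solve(C, sys, solver_config("tsvd", tsvd_threshold = 0,
                                             nonnegativity = FALSE))
  expect_true(any(fit_off$G_hat < 0))
})

test_that("invalid solver inputs are rejected with structured conditions", {
  sys <- build_conv_matrix(runif(6), 1)
  expect_error(solver_config("tv", lambda = -1), "lambda")
  expect_error(solver_config("wa_tv", delta = 0), "delta")
  expect_error(ctp_solve(matrix(c(NA, rnorm(11)), 2, 6), sys, solver_config("tv")),
               class = "ctpdeconv_validation_error")
  expect_error(ctp_solve(matrix(0, 2, 5), sys, solver_config("tv")),
               class = "ctpdeconv_validation_error")
})

test_that("noise SD is estimated from the baseline frame and drives the default lambda", {
  spec <- small_phantom_spec()
  ph <- build_phantom(spec)
  sys <- build_conv_matrix(ph$aif, spec$time$dt)
  noisy <- add_noise(ph$series, 2, 13)
  fit <- ctp_solve(noisy, sys, solver_config("tv", max_iter = 2))
  expect_lt(abs(fit$sigma_hat - 2) / 2, 0.15)
  expect_equal(fit$lambda, 0.4 * fit$sigma_hat * sqrt(fit$L))
  # noiseless data: sigma_hat ~ 0, so the default prior weight vanishes
  fit0 <- ctp_solve(ph$series, sys, solver_config("tv", max_iter = 2))
  expect_equal(fit0$sigma_hat, 0)
})

test_that("wa_tv beats the unregularized pseudo-inverse on noisy data (sign test)", {
  spec <- small_phantom_spec()
  ph <- build_phantom(spec)
  sys <- build_conv_matrix(ph$aif, spec$time$dt)
  wins <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    noisy <- add_noise(ph$series, 2, 300 + s)
    mse_of <- function(cfg) mean((ctp_solve(noisy, sys, cfg)$G_hat - ph$truth$G_true)^2)
    wins <- wins + (mse_of(solver_config("wa_tv", max_iter = 60)) <
                      mse_of(solver_config("tsvd", tsvd_threshold = 0)))
  }
  # one-sided sign test at alpha = 0.05: >= 9/10 wins
  expect_gte(wins, 9)
})
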