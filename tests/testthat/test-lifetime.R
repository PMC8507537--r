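test_that("reconvolve matches convolution identities and a quadrature oracle", {
  dt <- 0.25; n <- 64
  # delta IRF: prediction is the sampled bi-exponential scaled by dt
  p <- list(alpha_fast = 0.7, tau_fast = 0.5, alpha_slow = 0.3,
            tau_slow = 3)
  u <- numeric(n); u[5] <- 1
  y <- reconvolve(p, u, dt, n)
  t_shift <- (seq_len(n) - 5) * dt
  h <- ifelse(t_shift < 0, 0,
              p$alpha_fast * exp(-t_shift / p$tau_fast) +
                p$alpha_slow * exp(-t_shift / p$tau_slow))
  expect_equal(y, dt * h, tolerance = 1e-12)

  # alpha_fast = 0 degenerates to the mono-exponential reconvolution
  irf <- make_irf(dt, n_time = n)
  mono <- list(alpha_fast = 0, tau_fast = 0.5, alpha_slow = 1,
               tau_slow = 3)
  y1 <- reconvolve(mono, irf, dt, n)
  y2 <- maflim:::conv_exp(irf$u$b452, dt, 3, n)
  expect_equal(y1, y2, tolerance = 1e-12)

  # the discrete convolution is exact against independent direct summation
  p2 <- list(alpha_fast = 0.7, tau_fast = 0.5, alpha_slow = 0.3,
             tau_slow = 3)
  yr <- reconvolve(p2, irf, dt, n)
  direct <- sapply(seq_len(n), function(k)
    dt * sum(irf$u$b452[1:k] *
               (p2$alpha_fast * exp(-((k - (1:k)) * dt) / p2$tau_fast) +
                  p2$alpha_slow * exp(-((k - (1:k)) * dt) / p2$tau_slow))))
  expect_equal(yr, direct, tolerance = 1e-12)
  # and it converges to the continuous (dense-quadrature) convolution as
  # the grid refines: first-order quadrature error, roughly halved by
  # halving dt
  err_at <- function(dtx) {
    nx <- round(n * dt / dtx)
    irfx <- make_irf(dtx, n_time = nx)
    yq <- quadrature_reconvolve(p2, irfx$u$b452, dtx, nx)
    yrx <- reconvolve(p2, irfx, dtx, nx)
    max(abs(yrx - yq)) / max(yq)
  }
  e1 <- err_at(0.25); e2 <- err_at(0.125)
  expect_lt(e1, 0.35)
  expect_lt(e2, 0.65 * e1)

  expect_error(reconvolve(list(alpha_fast = 0.5, tau_fast = -1,
                               alpha_slow = 0.5, tau_slow = 3),
                          irf, dt, n),
               class = "maflim_validation_error")
})

test_that("fit_biexp recovers noiseless ground truth to high accuracy", {
  dt <- 0.25; n <- 256
  irf <- make_irf(dt, n_time = n)
  truth <- list(alpha_fast = 0.7, tau_fast = 0.5, alpha_slow = 0.3,
                tau_slow = 3, amplitude = 1)
  y <- reconvolve(truth, irf, dt, n)
  fit <- fit_biexp(y, irf, dt)
  expect_true(fit$converged)
  expect_lt(abs(fit$tau_fast - 0.5) / 0.5, 0.01)
  expect_lt(abs(fit$tau_slow - 3.0) / 3.0, 0.01)
  expect_lt(abs(fit$alpha_fast - 0.7), 0.02)
  # invariants of the returned object
  expect_lte(fit$tau_fast, fit$tau_slow)
  expect_equal(fit$alpha_fast + fit$alpha_slow, 1)
  expect_true(fit$tau_fast <= fit$tau_avg && fit$tau_avg <= fit$tau_slow)
  expect_gte(fit$mse, 0)

  # mono-exponential truth: tau_avg pinned regardless of the split
  ym <- reconvolve(list(alpha_fast = 0.5, tau_fast = 2, alpha_slow = 0.5,
                        tau_slow = 2), irf, dt, n)
  fm <- fit_biexp(ym, irf, dt)
  expect_lt(abs(fm$tau_avg - 2) / 2, 0.01)

  # no signal at all is a validation error
  expect_error(fit_biexp(numeric(n), irf, dt),
               class = "maflim_validation_error")
})

test_that("fit_biexp is invariant to start reordering and decay scaling", {
  dt <- 0.25; n <- 128
  irf <- make_irf(dt, n_time = n)
  y <- reconvolve(list(alpha_fast = 0.6, tau_fast = 0.8, alpha_slow = 0.4,
                       tau_slow = 4), irf, dt, n)
  cfg1 <- biexp_config(starts = list(c(0.3, 2), c(0.5, 4), c(1, 6)))
  cfg2 <- biexp_config(starts = list(c(2, 0.3), c(4, 0.5), c(6, 1)))
  f1 <- fit_biexp(y, irf, dt, cfg1)
  f2 <- fit_biexp(y, irf, dt, cfg2)
  # swapped component labels in the starts give the identical sorted fit
  expect_equal(coef(f1)[c("tau_fast", "tau_slow", "alpha_fast")],
               coef(f2)[c("tau_fast", "tau_slow", "alpha_fast")],
               tolerance = 1e-6)

  # time-resolved parameters are invariant to intensity scaling
  f10 <- fit_biexp(10 * y, irf, dt, cfg1)
  expect_equal(f10$tau_fast, f1$tau_fast, tolerance = 1e-6)
  expect_equal(f10$alpha_fast, f1$alpha_fast, tolerance = 1e-6)
  expect_equal(f10$amplitude, 10 * f1$amplitude, tolerance = 1e-4)
})

test_that("average_lifetime has the closed form of the FIR time integrals", {
  # alpha 0.5/0.5, tau 1 and 5 -> 13/3 ns (analytic)
  expect_equal(average_lifetime(list(alpha_fast = 0.5, tau_fast = 1,
                                     alpha_slow = 0.5, tau_slow = 5)),
               13 / 3)
  # mono-exponential limit
  expect_equal(average_lifetime(list(alpha_fast = 1, tau_fast = 2,
                                     alpha_slow = 0, tau_slow = 7)), 2)
  # trapezoid-rule oracle on a densely sampled FIR
  p <- list(alpha_fast = 0.64, tau_fast = 0.47, alpha_slow = 0.36,
            tau_slow = 3.1)
  tt <- seq(0, 120, by = 0.001)
  h <- p$alpha_fast * exp(-tt / p$tau_fast) +
    p$alpha_slow * exp(-tt / p$tau_slow)
  trap <- function(f) sum((f[-1] + f[-length(f)]) / 2) * 0.001
  num <- trap(tt * h) / trap(h)
  expect_lt(abs(average_lifetime(p) - num) / num, 0.001)

  expect_error(average_lifetime(list(alpha_fast = 0, tau_fast = 1,
                                     alpha_slow = 0, tau_slow = 2)),
               class = "maflim_validation_error")
})

test_that("model-order selection finds the MSE plateau", {
  dt <- 0.25; n <- 256
  irf <- make_irf(dt, n_time = n)
  # mono-exponential truth -> order 1
  y1 <- reconvolve(list(alpha_fast = 0, tau_fast = 1, alpha_slow = 1,
                        tau_slow = 3), irf, dt, n)
  expect_equal(as.integer(select_model_order(y1, irf, dt)), 1L)
  # well-separated bi-exponential truth at high SNR -> order 2
  set.seed(21)
  y2 <- reconvolve(list(alpha_fast = 0.5, tau_fast = 0.5, alpha_slow = 0.5,
                        tau_slow = 5), irf, dt, n)
  y2n <- y2 + rnorm(n, 0, max(y2) / 10^(50 / 20))
  expect_equal(as.integer(select_model_order(y2n, irf, dt)), 2L)
})

test_that("fit MSE is bounded by an exhaustive grid-search oracle on toy decays", {
  dt <- 0.5; n <- 16
  irf <- make_irf(dt, fwhm_ns = 1.2, n_time = n, peak_ns = 1.5)
  grid_tf <- seq(0.2, 1.4, by = 0.01)
  grid_ts <- seq(1.6, 6, by = 0.01)
  set.seed(31)
  for (rep in 1:4) {
    tf <- runif(1, 0.3, 1.2); ts <- runif(1, 2, 5); af <- runif(1, 0.3, 0.7)
    y <- reconvolve(list(alpha_fast = af, tau_fast = tf,
                         alpha_slow = 1 - af, tau_slow = ts),
                    irf, dt, n)
    y <- y + rnorm(n, 0, max(y) / 10^(35 / 20))
    fit <- fit_biexp(y, irf, dt)
    best_grid <- Inf
    for (a in grid_tf) {
      sses <- vapply(grid_ts, function(b)
        maflim:::cpp_vp_fit(c(a, b), irf$u$b452, dt, y)$sse, 0)
      best_grid <- min(best_grid, min(sses))
    }
    # fitted MSE no worse than the grid oracle plus resolution slack
    expect_lte(fit$mse * n, best_grid * (1 + 1e-6) + 1e-9)
  }
})

test_that("parameter recovery holds across random ground truths", {
  # 60 draws spanning noiseless to 30 dB; median errors must stay small
  dt <- 0.25; n <- 256
  irf <- make_irf(dt, n_time = n)
  set.seed(7)
  snrs <- rep(c(Inf, 50, 45, 40, 35, 30), length.out = 60)
  errs <- matrix(NA_real_, 60, 3)
  mses <- matrix(NA_real_, 60, 2)
  for (i in 1:60) {
    tf <- runif(1, 0.2, 1.5); ts <- runif(1, 2, 8); af <- runif(1, 0.2, 0.8)
    p <- list(alpha_fast = af, tau_fast = tf, alpha_slow = 1 - af,
              tau_slow = ts)
    y <- reconvolve(p, irf, dt, n)
    noise <- max(y) * 10^(-snrs[i] / 20)
    yn <- y + rnorm(n, 0, noise)
    f <- fit_biexp(yn, irf, dt)
    errs[i, ] <- c(abs(f$tau_fast - tf) / tf, abs(f$tau_slow - ts) / ts,
                   abs(f$tau_avg - average_lifetime(p)) /
                     average_lifetime(p))
    # MSE never increases when the same truth is fitted with less noise
    f_clean <- fit_biexp(y, irf, dt)
    mses[i, ] <- c(f_clean$mse, f$mse)
  }
  expect_lt(median(errs[, 1:2]), 0.05)
  expect_lt(median(errs[, 3]), 0.03)
  expect_true(all(mses[, 1] <= mses[, 2] + 1e-12))
})

test_that("fit_image covers exactly the valid mask and flags bad pixels", {
  params <- default_class_params("null")$healthy
  sc <- generate_scene(params, rows = 6, cols = 6, n_time = 128, seed = 4)
  mask <- pixel_mask(dim = c(6, 6))
  mask$valid[1, 1] <- FALSE; mask$reason[1, 1] <- "manual"
  pp_img <- subtract_background(sc$image, preprocess_config())
  fits <- fit_image(pp_img, sc$irf, mask)
  for (b in maflim_bands()) {
    expect_true(all(is.na(fits$bands[[b]]$tau_fast[!mask$valid])))
    expect_true(all(is.finite(fits$bands[[b]]$tau_fast[mask$valid])))
  }
  # per-pixel fits track the generated truth (noiseless comparison is in
  # the synthetic-data tests; here a loose sanity band at 30 dB)
  tb <- sc$truth$bands$b452
  ok <- mask$valid
  err <- abs(fits$bands$b452$tau_slow[ok] - tb$tau_slow[ok]) /
    tb$tau_slow[ok]
  expect_lt(median(err), 0.25)

  # fully masked image -> empty maps
  none <- pixel_mask(matrix(FALSE, 6, 6),
                     matrix("manual", 6, 6))
  f0 <- fit_image(pp_img, sc$irf, none)
  expect_true(all(is.na(f0$bands$b452$tau_fast)))

  # pathological all-zero pixels are flagged, not fatal
  img2 <- pp_img
  for (b in maflim_bands()) img2$decay[[b]][2, 2, ] <- 0
  f2 <- fit_image(img2, sc$irf, mask)
  expect_false(f2$bands$b452$converged[2, 2])
  expect_true(f2$bands$b452$converged[3, 3])
})
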