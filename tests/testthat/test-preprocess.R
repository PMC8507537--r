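test_that("background subtraction removes a constant offset", {
  t <- toy_image(n_time = 64, offset = 7.0)
  cfg <- preprocess_config(baseline_window = 6)
  out <- subtract_background(t$image, cfg)
  # baseline mean ~ 0 after subtraction (signal is ~0 pre-pulse)
  base <- out$decay$b452[1, 1, 1:6]
  expect_lt(abs(mean(base)), 1e-9)
  # the known decay shape is recovered up to the tiny pre-pulse signal leak
  clean <- toy_image(n_time = 64, offset = 0)
  expect_lt(max(abs(out$decay$b452 - clean$image$decay$b452)),
            2e-3 * max(clean$image$decay$b452))

  # all-zero traces stay all-zero
  z <- array(0, c(2, 2, 16))
  zi <- maflim_image(list(b390 = z, b452 = z, b500 = z), 0.25)
  expect_equal(subtract_background(zi, preprocess_config(baseline_window = 4))$decay$b452, z)

  expect_error(subtract_background(t$image,
                                   preprocess_config(baseline_window = 64)),
               class = "maflim_config_error")
})

test_that("background subtraction leaves residual offset below noise floor", {
  set.seed(5)
  n_time <- 128; rows <- 6; cols <- 6
  noise_sd <- 0.01; offset <- 3.2
  t <- toy_image(rows, cols, n_time, offset = offset)
  for (b in maflim_bands())
    t$image$decay[[b]] <- t$image$decay[[b]] +
      array(rnorm(rows * cols * n_time, 0, noise_sd), c(rows, cols, n_time))
  w <- 8
  out <- subtract_background(t$image, preprocess_config(baseline_window = w))
  resid <- mean(out$decay$b452[, , 1:w])
  expect_lt(abs(resid), 10 * noise_sd / sqrt(w * rows * cols))
})

test_that("saturation masking flags exactly the clipped pixels", {
  t <- toy_image(rows = 5, cols = 5, n_time = 32)
  cfg <- preprocess_config(full_scale = 1)
  expect_true(all(mask_saturated(t$image, cfg)$valid))  # ~10% FS: none

  clip <- rbind(c(1, 1), c(2, 4), c(3, 3), c(5, 5), c(4, 2))
  img <- t$image
  for (i in seq_len(nrow(clip)))
    img$decay$b452[clip[i, 1], clip[i, 2], 10] <- 1.0
  m <- mask_saturated(img, cfg)
  expect_equal(sum(!m$valid), 5)
  expect_true(all(!m$valid[clip]))
  expect_true(all(m$reason[clip] == "saturated"))

  img2 <- t$image; img2$meta$full_scale <- NULL
  expect_error(mask_saturated(img2, preprocess_config()),
               class = "maflim_config_error")
})

test_that("spatial averaging is an exact neighbourhood mean", {
  # spatially constant image is unchanged
  t <- toy_image(rows = 7, cols = 7, n_time = 16)
  out <- spatial_average(t$image, preprocess_config(kernel_size = 5))
  expect_equal(out$decay$b390, t$image$decay$b390, tolerance = 1e-12)

  # kernel_size = 1 is the identity
  out1 <- spatial_average(t$image, preprocess_config(kernel_size = 1))
  expect_identical(out1$decay, t$image$decay)

  # single bright pixel spreads as 25-fold dilution at the centre
  z <- array(0, c(5, 5, 1)); z[3, 3, 1] <- 25
  img <- maflim_image(list(b390 = z, b452 = z, b500 = z), 0.25)
  avg <- spatial_average(img, preprocess_config(kernel_size = 5))
  expect_equal(avg$decay$b452[3, 3, 1], 1.0)
  # corner neighbourhood only has 9 in-bounds members
  expect_equal(avg$decay$b452[1, 1, 1], 25 / 9)

  expect_error(spatial_average(toy_image(rows = 3, cols = 3)$image,
                               preprocess_config(kernel_size = 5)),
               class = "maflim_config_error")
})

test_that("spatial averaging excludes masked pixels and preserves interior mean", {
  set.seed(3)
  arr <- array(abs(rnorm(8 * 8 * 4)) + 0.5, c(8, 8, 4))
  img <- maflim_image(list(b390 = arr, b452 = arr, b500 = arr), 0.25)
  mask <- pixel_mask(dim = c(8, 8))
  mask$valid[4, 4] <- FALSE; mask$reason[4, 4] <- "saturated"
  out <- spatial_average(img, preprocess_config(kernel_size = 3), mask)
  # manual mean over the 8 valid neighbours of (4,4), excluding (4,4) itself
  nb <- expand.grid(r = 3:5, c = 3:5)
  nb <- nb[!(nb$r == 4 & nb$c == 4), ]
  expect_equal(out$decay$b452[4, 4, 2],
               mean(arr[cbind(nb$r, nb$c, 2)]))
  # nonnegativity preserved
  expect_true(all(out$decay$b390 >= 0))
})

test_that("SNR masking uses the worst band and keeps zero-noise pixels", {
  n_time <- 64; dt <- 0.25
  irf <- make_irf(dt, n_time = n_time)
  mk <- function(peak_scale, noise_sd, seed = 1) {
    set.seed(seed)
    y <- reconvolve(list(alpha_fast = 0.6, tau_fast = 0.5,
                         alpha_slow = 0.4, tau_slow = 3,
                         amplitude = peak_scale), irf, dt, n_time)
    y + rnorm(n_time, 0, noise_sd)
  }
  # peak/noise = 100 -> 40 dB -> kept; peak/noise ~ 1 -> masked
  arr_hi <- array(rep(mk(1, 0), each = 1), c(1, 1, n_time))
  peak <- max(arr_hi)
  noisy <- function(sdv, seed) array(mk(1, sdv, seed), c(1, 1, n_time))
  img_hi <- maflim_image(list(b390 = noisy(peak / 100, 1),
                              b452 = noisy(peak / 100, 2),
                              b500 = noisy(peak / 100, 3)), dt)
  m_hi <- mask_low_snr(img_hi, preprocess_config(baseline_window = 8))
  expect_true(all(m_hi$valid))

  img_lo <- maflim_image(list(b390 = noisy(peak / 100, 1),
                              b452 = noisy(peak * 1.0, 2),  # ~0 dB band
                              b500 = noisy(peak / 100, 3)), dt)
  m_lo <- mask_low_snr(img_lo, preprocess_config(baseline_window = 8))
  expect_false(any(m_lo$valid))       # worst band decides
  expect_equal(unique(as.vector(m_lo$reason)), "low_snr")

  # exactly zero baseline noise -> +Inf sentinel, kept
  flat <- arr_hi; flat[, , 1:8] <- 0
  img0 <- maflim_image(list(b390 = flat, b452 = flat, b500 = flat), dt)
  m0 <- mask_low_snr(img0, preprocess_config(baseline_window = 8))
  expect_true(all(m0$valid))
  expect_true(all(is.infinite(attr(m0, "snr_db"))))
})

test_that("manual masking handles rectangles, polygons and idempotence", {
  m <- pixel_mask(dim = c(10, 10))
  expect_identical(apply_manual_mask(m, list()), m)

  regions <- list(list(type = "rect", r0 = 2, c0 = 2, r1 = 3, c1 = 4),
                  list(type = "rect", r0 = 8, c0 = 9, r1 = 9, c1 = 10))
  m2 <- apply_manual_mask(m, regions)
  expect_equal(sum(!m2$valid), 10)       # 6 + 4 disjoint pixels
  m3 <- apply_manual_mask(m2, regions)   # idempotent
  expect_identical(m3, m2)

  full <- apply_manual_mask(m, list(list(type = "rect", r0 = 1, c0 = 1,
                                         r1 = 10, c1 = 10)))
  expect_false(any(full$valid))

  tri <- list(list(type = "poly",
                   vertices = list(c(1, 1), c(1, 10), c(10, 1))))
  mp <- apply_manual_mask(m, tri)
  expect_gt(sum(!mp$valid), 25)          # about half the image
  expect_true(mp$valid[10, 10])          # opposite corner untouched

  expect_error(
    apply_manual_mask(m, list(list(type = "rect", r0 = 0, c0 = 1,
                                   r1 = 2, c1 = 2))),
    class = "maflim_validation_error")
})

test_that("sampling harmonization preserves identity, integrals and lifetimes", {
  dt_hi <- 0.16                      # 6.25 GS/s
  t <- toy_image(rows = 2, cols = 2, n_time = 200, dt = dt_hi)

  same <- harmonize_sampling(t$image, t$irf, dt_hi)
  expect_identical(same$image, t$image)

  out <- harmonize_sampling(t$image, t$irf, 0.25)   # onto 4 GS/s
  expect_equal(out$image$dt, 0.25)
  # integrals preserved within 1%
  i_old <- absolute_intensity(t$image, "b452")[1, 1]
  i_new <- absolute_intensity(out$image, "b452")[1, 1]
  expect_lt(abs(i_new - i_old) / i_old, 0.01)

  # mono-exponential lifetime survives resampling; the residual change is
  # the cross-grid discretization bias of the discrete convolution model
  # (rectangle rule at 0.16 vs 0.25 ns), about 3% for tau = 3 ns
  irf6 <- make_irf(dt_hi, n_time = 200)
  y6 <- reconvolve(list(alpha_fast = 0, tau_fast = 0.5, alpha_slow = 1,
                        tau_slow = 3), irf6, dt_hi, 200)
  arr <- array(rep(y6, each = 1), c(1, 1, 200))
  img6 <- maflim_image(list(b390 = arr, b452 = arr, b500 = arr), dt_hi)
  h <- harmonize_sampling(img6, irf6, 0.25)
  fit6 <- fit_biexp(y6, irf6, dt_hi)
  fit4 <- fit_biexp(h$image$decay$b452[1, 1, ], h$irf, 0.25)
  expect_lt(abs(fit4$tau_avg - fit6$tau_avg) / fit6$tau_avg, 0.04)

  # constant signal stays constant
  carr <- array(2, c(1, 1, 100))
  cimg <- maflim_image(list(b390 = carr, b452 = carr, b500 = carr), dt_hi)
  hc <- harmonize_sampling(cimg, NULL, 0.25)
  expect_true(all(abs(hc$image$decay$b452 - 2) < 1e-12))

  expect_error(harmonize_sampling(t$image, t$irf, 0.1),
               class = "maflim_config_error")
})

test_that("the preprocessing chain is ordered and masks only grow", {
  params <- default_class_params("null")$healthy
  sc <- generate_scene(params, rows = 12, cols = 12, n_time = 128, seed = 9)
  cfg <- preprocess_config()
  pp <- preprocess(sc$image, cfg,
                   regions = list(list(type = "rect", r0 = 1, c0 = 1,
                                       r1 = 2, c1 = 2)))
  # manual region masked
  expect_true(all(!pp$mask$valid[1:2, 1:2]))
  # injected saturated pixels are masked with the saturation reason
  if (any(sc$truth$saturated))
    expect_true(all(pp$mask$reason[sc$truth$saturated] == "saturated"))

  # masks only grow along the chain: every pixel masked by the saturation
  # step is still masked after the full chain
  sat <- mask_saturated(sc$image, cfg)
  expect_true(all(pp$mask$valid <= sat$valid))

  # re-running mask decisions on the chain output changes nothing
  pp2 <- preprocess(pp$image, cfg,
                    regions = list(list(type = "rect", r0 = 1, c0 = 1,
                                        r1 = 2, c1 = 2)))
  expect_true(all(pp2$mask$valid >= pp$mask$valid - 0L | !pp$mask$valid))
  # no previously-masked saturated pixel becomes valid
  expect_true(all(!(pp2$mask$valid & !sat$valid & !pp$mask$valid)))
})
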