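#' Gaussian instrument response function
#'
#' Builds a unit-area Gaussian IRF (discrete sum x dt = 1) emulating a
#' ~1 ns excitation pulse, with the peak at a configurable delay inside the
#' record.
#'
#' @param dt Time step in ns.
#' @param fwhm_ns Full width at half maximum in ns (default 1.0); must
#'   exceed `2 * dt` to be resolved.
#' @param n_time Number of samples.
#' @param peak_ns Peak position in ns (default 3.0, leaving a clean
#'   pre-pulse baseline window).
#' @return An [instrument_response()] (same IRF in all three bands).
#' @export
make_irf <- function(dt, fwhm_ns = 1.0, n_time = 256L, peak_ns = 3.0) {
  if (fwhm_ns <= 2 * dt)
    abort_config("IRF under-resolved: need fwhm_ns > 2 * dt")
  if (peak_ns <= 0 || peak_ns >= (n_time - 1) * dt)
    abort_config("IRF peak must lie inside the record")
  sigma <- fwhm_ns / (2 * sqrt(2 * log(2)))
  t <- (seq_len(n_time) - 1L) * dt
  u <- exp(-0.5 * ((t - peak_ns) / sigma)^2)
  u <- u / (sum(u) * dt)
  instrument_response(u, dt)
}

band_param_defaults <- function() {
  # Healthy oral tissue kinetics per band, chosen once as field-realistic:
  # collagen dominates b390 (long-lived), NADH b452 and FAD b500 (shorter,
  # strongly quenched fast components). Intensities in relative units.
  list(
    b390 = list(alpha_fast = c(0.55, 0.06), tau_fast = c(0.90, 0.10),
                tau_slow = c(5.0, 0.40), intensity = c(1.00, 0.15)),
    b452 = list(alpha_fast = c(0.60, 0.06), tau_fast = c(0.45, 0.06),
                tau_slow = c(3.2, 0.30), intensity = c(0.65, 0.10)),
    b500 = list(alpha_fast = c(0.55, 0.06), tau_fast = c(0.50, 0.06),
                tau_slow = c(3.0, 0.30), intensity = c(0.45, 0.08))
  )
}

#' Tissue-class generator parameters
#'
#' Distributional parameters of one tissue class for the synthetic maFLIM
#' generator: per band, mean and spread (standard deviation) of
#' `alpha_fast`, `tau_fast` (ns), `tau_slow` (ns) and mean absolute band
#' intensity; plus spatial correlation length, target SNR, saturation and
#' tooth-region probabilities, and the constant electronic offset.
#'
#' @param bands Per-band list like `band_param_defaults()`: each band a
#'   list of `c(mean, sd)` pairs for `alpha_fast`, `tau_fast`, `tau_slow`,
#'   `intensity`.
#' @param corr_len Spatial correlation length of the parameter fields, in
#'   pixels.
#' @param snr_db Target per-pixel SNR (peak over baseline-noise sd) in dB.
#' @param p_sat Probability that a pixel is injected as saturated.
#' @param p_tooth Probability that the scene contains a non-tissue
#'   ("tooth") region of near-zero fluorescence.
#' @param offset_frac Constant offset as a fraction of full scale.
#' @return Object of class `tissue_class_params`.
#' @export
tissue_class_params <- function(bands = band_param_defaults(),
                                corr_len = 2, snr_db = 30,
                                p_sat = 0.01, p_tooth = 0.15,
                                offset_frac = 0.05) {
  for (b in maflim_bands()) {
    bp <- bands[[b]]
    if (is.null(bp)) abort_validation(sprintf("missing band %s", b))
    if (bp$tau_fast[1] <= 0 || bp$tau_slow[1] <= bp$tau_fast[1])
      abort_validation("need 0 < tau_fast < tau_slow")
    if (bp$alpha_fast[1] <= 0 || bp$alpha_fast[1] >= 1)
      abort_validation("alpha_fast mean must lie in (0, 1)")
    if (bp$intensity[1] <= 0)
      abort_validation("band intensity must be positive")
  }
  structure(list(bands = bands, corr_len = corr_len, snr_db = snr_db,
                 p_sat = p_sat, p_tooth = p_tooth,
                 offset_frac = offset_frac),
            class = "tissue_class_params")
}

#' Healthy and lesion generator parameters at a chosen effect size
#'
#' Returns the paired (healthy, lesion) parameter sets. Under the null
#' effect the distributions are identical; for `moderate` (0.5 sigma) and
#' `strong` (1.5 sigma) effects the lesion parameters shift, in units of
#' the healthy spread, along the six biomarker directions reported for
#' dysplastic/cancerous oral tissue: lower collagen-band relative intensity
#' (down I390n and hence down I390/I500), higher NADH-band relative
#' intensity (up I452n), faster collagen-band decay (down tau_avg_390), and
#' a faster, larger fast NADH component (down tau_fast_452,
#' up alpha_fast_452).
#'
#' @param effect_size `"null"`, `"moderate"` or `"strong"`.
#' @param ... Passed to [tissue_class_params()] (both classes).
#' @return List with elements `healthy` and `lesion`.
#' @export
default_class_params <- function(effect_size = c("null", "moderate",
                                                 "strong"), ...) {
  effect_size <- match.arg(effect_size)
  k <- switch(effect_size, null = 0, moderate = 0.5, strong = 1.5)
  healthy <- tissue_class_params(...)
  shift <- function(pair, mult) c(pair[1] + mult * pair[2], pair[2])
  bands <- healthy$bands
  bands$b390$intensity <- shift(bands$b390$intensity, -k)  # down I390n
  bands$b452$intensity <- shift(bands$b452$intensity, +k)  # up I452n
  bands$b390$tau_fast  <- shift(bands$b390$tau_fast, -k)   # down tau_avg_390
  bands$b390$tau_slow  <- shift(bands$b390$tau_slow, -k)
  bands$b452$tau_fast  <- shift(bands$b452$tau_fast, -k)   # down tau_fast_452
  bands$b452$alpha_fast <- shift(bands$b452$alpha_fast, +k) # up alpha_fast_452
  bands$b452$alpha_fast[1] <- min(bands$b452$alpha_fast[1], 0.92)
  lesion <- healthy
  lesion$bands <- bands
  list(healthy = healthy, lesion = lesion)
}

# Unit-variance spatially correlated Gaussian random field: white noise
# smoothed with a separable Gaussian kernel, then re-standardized.
smooth_field <- function(rows, cols, corr_len) {
  z <- matrix(rnorm(rows * cols), rows, cols)
  if (corr_len <= 0) return(z)
  half <- max(1L, ceiling(2 * corr_len))
  k <- dnorm(seq(-half, half), sd = corr_len)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    idx <- pmin(pmax(seq(1 - half, n + half), 1L), n)  # replicate edges
    as.numeric(stats::filter(v[idx], k, sides = 2))[half + seq_len(n)]
  }
  z <- apply(z, 2L, pad_conv)
  z <- t(apply(z, 1L, pad_conv))
  s <- sd(as.vector(z))
  if (s > 0) z / s else z
}

#' Generate one synthetic maFLIM scene with ground truth
#'
#' Draws per-pixel bi-exponential kinetic parameters from spatially
#' correlated fields around the class means, synthesizes each decay as
#' amplitude x bi-exponential convolved with a Gaussian IRF plus a constant
#' offset and shot-like noise (Gaussian, variance increasing with signal)
#' scaled to the target SNR, injects saturated (clipped) pixels and an
#' optional near-zero-signal "tooth" region, and records every ground-truth
#' quantity. Fully deterministic given `(params, seed)`.
#'
#' @param params A [tissue_class_params()].
#' @param rows,cols Spatial dimensions (default 64 x 64).
#' @param dt Time step in ns (default 0.25, i.e. 4 GS/s).
#' @param n_time Samples per decay (default 256).
#' @param seed Integer seed.
#' @param label Image-level label stored in metadata.
#' @param irf Optional [instrument_response()]; default [make_irf()] on the
#'   same grid.
#' @return Object of class `maflim_scene`: `image` ([maflim_image()], full
#'   scale 1.0), `irf`, `label`, and `truth` (per-band per-pixel parameter
#'   matrices, amplitude and intensity maps, `saturated` and `tooth`
#'   logical maps, the per-pixel baseline noise sd `sigma0`, seed).
#' @export
generate_scene <- function(params, rows = 64L, cols = 64L, dt = 0.25,
                           n_time = 256L, seed = 1L,
                           label = "unknown", irf = NULL) {
  if (is.null(irf)) irf <- make_irf(dt, n_time = n_time)
  full_scale <- 1.0
  with_local_seed(seed, {
    truth <- list(bands = list(), seed = seed)
    npx <- rows * cols
    # per-band kinetic parameter fields
    for (b in maflim_bands()) {
      bp <- params$bands[[b]]
      draw <- function(pair, lo, hi)
        pmin(pmax(pair[1] + pair[2] * smooth_field(rows, cols,
                                                   params$corr_len),
                  lo), hi)
      af <- draw(bp$alpha_fast, 0.02, 0.98)
      tf <- draw(bp$tau_fast, 0.10, 15)
      ts <- draw(bp$tau_slow, 0.30, 19)
      ts <- pmax(ts, tf + 0.2)
      ii <- draw(bp$intensity, 0.02 * bp$intensity[1], Inf)
      truth$bands[[b]] <- list(alpha_fast = af, tau_fast = tf,
                               tau_slow = ts, intensity = ii)
    }
    sat <- matrix(runif(npx) < params$p_sat, rows, cols)
    tooth <- matrix(FALSE, rows, cols)
    if (runif(1) < params$p_tooth) {
      h <- max(2L, round(rows * runif(1, 0.15, 0.3)))
      w <- max(2L, round(cols * runif(1, 0.15, 0.3)))
      r0 <- sample.int(rows - h + 1L, 1L)
      c0 <- sample.int(cols - w + 1L, 1L)
      tooth[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- TRUE
    }
    offset <- params$offset_frac * full_scale
    sigma0_map <- matrix(0, rows, cols)
    decay <- setNames(vector("list", 3), maflim_bands())

    # global gain: map the configured intensity units onto the digitizer so
    # a typical pixel peaks near 45% of full scale in its brightest band
    peak_unit <- c(b390 = 0, b452 = 0, b500 = 0)
    for (b in maflim_bands()) {
      bp <- params$bands[[b]]
      h0 <- bp$alpha_fast[1] * conv_exp(irf$u[[b]], dt, bp$tau_fast[1], n_time) +
        (1 - bp$alpha_fast[1]) * conv_exp(irf$u[[b]], dt, bp$tau_slow[1], n_time)
      amp0 <- bp$intensity[1] /
        (bp$alpha_fast[1] * bp$tau_fast[1] +
           (1 - bp$alpha_fast[1]) * bp$tau_slow[1])
      peak_unit[b] <- amp0 * max(h0)
    }
    gain <- 0.45 * full_scale / max(peak_unit)

    # noise referenced to each band's typical (mean-parameter) peak, so the
    # per-band SNR tracks the target while genuinely weak pixels (tooth
    # regions) fall far below it
    noise_floor <- 10^(-params$snr_db / 20)
    band_sigma0 <- gain * peak_unit * noise_floor
    sigma0_map[] <- band_sigma0["b452"]
    for (b in maflim_bands()) {
      sigma0 <- band_sigma0[[b]]
      ref_peak <- gain * peak_unit[[b]]
      tb <- truth$bands[[b]]
      arr <- array(0, c(rows, cols, n_time))
      u <- irf$u[[b]]
      amp <- gain * tb$intensity /
        (tb$alpha_fast * tb$tau_fast + (1 - tb$alpha_fast) * tb$tau_slow)
      amp[tooth] <- amp[tooth] * 0.02
      amp[sat] <- amp[sat] * 3.5
      for (r in seq_len(rows)) for (cc in seq_len(cols)) {
        af <- tb$alpha_fast[r, cc]
        clean <- amp[r, cc] *
          (af * conv_exp(u, dt, tb$tau_fast[r, cc], n_time) +
             (1 - af) * conv_exp(u, dt, tb$tau_slow[r, cc], n_time))
        noise_sd <- sigma0 * sqrt(1 + 2 * pmax(clean, 0) / ref_peak)
        y <- clean + offset + rnorm(n_time, 0, noise_sd)
        arr[r, cc, ] <- pmin(y, full_scale)
      }
      truth$bands[[b]]$amplitude <- amp
      decay[[b]] <- arr
    }
    truth$saturated <- sat
    truth$tooth <- tooth
    truth$sigma0 <- sigma0_map
    truth$offset <- offset
    truth$gain <- gain
    image <- maflim_image(decay, dt,
                          meta = list(label = label, full_scale = full_scale))
    structure(list(image = image, irf = irf, label = label, truth = truth),
              class = "maflim_scene")
  })
}

#' @export
print.maflim_scene <- function(x, ...) {
  cat(sprintf("Synthetic maFLIM scene (%s), seed %d\n", x$label,
              x$truth$seed))
  print(x$image)
  invisible(x)
}

#' Generate a paired lesion/healthy synthetic cohort
#'
#' One lesion scene and one paired contralateral healthy scene per subject,
#' sharing a subject-level random offset (inter-subject variability applied
#' to intensity and lifetime means, at 0.5 of the population spread).
#' Lesion grades are drawn with SCC-dominated frequencies typical of a
#' biopsy-confirmed referral population. Deterministic given `seed`.
#'
#' @param n_subjects Number of subjects (pairs); at least 2.
#' @param effect_size Passed to [default_class_params()].
#' @param rows,cols Per-image spatial dimensions; cohort default 16 x 16
#'   keeps a full cross-validation study desk-scale.
#' @param dt,n_time Sampling grid (defaults 0.25 ns, 256 samples).
#' @param seed Integer seed.
#' @return A [maflim_dataset()] of `maflim_scene` pairs.
#' @export
generate_cohort <- function(n_subjects, effect_size = "strong",
                            rows = 16L, cols = 16L, dt = 0.25,
                            n_time = 256L, seed = 1L) {
  if (n_subjects < 2L) abort_config("need at least 2 subjects")
  base <- default_class_params(effect_size)
  grade_levels <- c("MiD", "MoD", "HiD", "SCC")
  grade_probs <- c(0.04, 0.04, 0.10, 0.82)
  subjects <- with_local_seed(seed, {
    out <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      # subject offset shared by the pair: 0.5 sigma on means
      zs <- rnorm(6, 0, 0.5)
      adj <- function(cls) {
        bands <- cls$bands
        bump <- function(pair, z) c(pair[1] + z * pair[2], pair[2])
        bands$b390$intensity <- bump(bands$b390$intensity, zs[1])
        bands$b452$intensity <- bump(bands$b452$intensity, zs[2])
        bands$b500$intensity <- bump(bands$b500$intensity, zs[3])
        bands$b390$tau_slow  <- bump(bands$b390$tau_slow, zs[4])
        bands$b452$tau_fast  <- bump(bands$b452$tau_fast, zs[5])
        bands$b500$tau_slow  <- bump(bands$b500$tau_slow, zs[6])
        bands$b452$tau_fast[1] <- max(bands$b452$tau_fast[1], 0.15)
        cls$bands <- bands
        cls
      }
      grade <- sample(grade_levels, 1L, prob = grade_probs)
      out[[i]] <- list(
        subject_id = sprintf("S%03d", i),
        grade = grade,
        params = list(healthy = adj(base$healthy),
                      lesion = adj(base$lesion)))
    }
    out
  })
  for (i in seq_len(n_subjects)) {
    s <- subjects[[i]]
    subjects[[i]]$lesion <- generate_scene(
      s$params$lesion, rows, cols, dt, n_time,
      seed = derive_seed(seed, 2L * i), label = "dysplasia/cancer")
    subjects[[i]]$healthy <- generate_scene(
      s$params$healthy, rows, cols, dt, n_time,
      seed = derive_seed(seed, 2L * i + 1L), label = "healthy")
    subjects[[i]]$params <- NULL
  }
  maflim_dataset(subjects)
}
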