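#' Preprocessing configuration
#'
#' Parameters of the five-step decay preprocessing chain.
#'
#' @param baseline_window Number of leading pre-pulse samples used to
#'   estimate the electronic offset and the baseline noise. Must precede the
#'   excitation pulse.
#' @param saturation_fraction Fraction of the digitizer full scale at or
#'   above which a sample counts as saturated (default 0.98, tolerant of
#'   quantization at the rail).
#' @param kernel_size Spatial averaging order; the field-standard value is a
#'   5 x 5 neighbourhood. Must be odd.
#' @param snr_threshold_db Pixels whose worst-band SNR (peak amplitude over
#'   baseline-noise standard deviation, in dB) falls below this are masked.
#'   Default 15 dB.
#' @param target_dt_ns Optional common time step for cross-instrument
#'   harmonization (see [harmonize_sampling()]).
#' @param full_scale Digitizer full scale in decay intensity units; may
#'   instead be carried in the image metadata.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(baseline_window = 8L,
                              saturation_fraction = 0.98,
                              kernel_size = 5L,
                              snr_threshold_db = 15,
                              target_dt_ns = NULL,
                              full_scale = NULL) {
  if (kernel_size < 1L || kernel_size %% 2L == 0L)
    abort_config("kernel_size must be odd and >= 1")
  if (!is.finite(snr_threshold_db))
    abort_config("snr_threshold_db must be finite")
  if (!(saturation_fraction > 0 && saturation_fraction <= 1))
    abort_config("saturation_fraction must be in (0, 1]")
  if (baseline_window < 1L)
    abort_config("baseline_window must be >= 1")
  structure(list(
    baseline_window = as.integer(baseline_window),
    saturation_fraction = saturation_fraction,
    kernel_size = as.integer(kernel_size),
    snr_threshold_db = snr_threshold_db,
    target_dt_ns = target_dt_ns,
    full_scale = full_scale
  ), class = "preprocess_config")
}

# Band array as (pixels x time) matrix and back.
band_matrix <- function(arr) {
  d <- dim(arr)
  list(m = matrix(arr, d[1] * d[2], d[3]), dim = d)
}

full_scale_of <- function(image, cfg) {
  fs <- cfg$full_scale
  if (is.null(fs)) fs <- image$meta$full_scale
  if (is.null(fs) || !is.finite(fs) || fs <= 0)
    abort_config("digitizer full scale unknown: set cfg$full_scale or image meta")
  fs
}

#' Subtract the electronic offset and background from every decay
#'
#' Estimates the offset per pixel and band as the mean of the leading
#' `baseline_window` pre-pulse samples and subtracts it from the whole
#' trace. Small negative excursions (noise) may remain.
#'
#' @param image A [maflim_image()].
#' @param cfg A [preprocess_config()].
#' @return A background-subtracted `maflim_image`.
#' @export
subtract_background <- function(image, cfg = preprocess_config()) {
  w <- cfg$baseline_window
  if (w >= image$n_time)
    abort_config("baseline_window must be smaller than n_time")
  decay <- lapply(image$decay, function(arr) {
    bm <- band_matrix(arr)
    base <- rowMeans(bm$m[, seq_len(w), drop = FALSE])
    array(bm$m - base, bm$dim)
  })
  maflim_image(decay, image$dt, image$meta)
}

#' Mask pixels with temporal signal saturation
#'
#' A pixel is saturated when its raw (pre-background-subtraction) amplitude
#' reaches `saturation_fraction` of the digitizer full scale in any band for
#' at least one time sample.
#'
#' @inheritParams subtract_background
#' @return A [pixel_mask()] with reason `"saturated"` where clipped.
#' @export
mask_saturated <- function(image, cfg = preprocess_config()) {
  fs <- full_scale_of(image, cfg)
  thr <- cfg$saturation_fraction * fs
  sat <- matrix(FALSE, image$rows, image$cols)
  for (b in maflim_bands()) {
    bm <- band_matrix(image$decay[[b]])
    mx <- do.call(pmax, c(as.data.frame(bm$m), list(na.rm = TRUE)))
    sat <- sat | matrix(mx >= thr, image$rows, image$cols)
  }
  reason <- matrix("ok", image$rows, image$cols)
  reason[sat] <- "saturated"
  pixel_mask(!sat, reason)
}

# Exact box sum over a (2*half+1)-neighbourhood via a summed-area table;
# edges shrink to the in-bounds part of the window.
box_sum <- function(M, half) {
  r <- nrow(M); c <- ncol(M)
  colcum <- matrix(apply(M, 2L, cumsum), r, c)
  sat <- matrix(0, r + 1L, c + 1L)
  sat[-1L, -1L] <- t(matrix(apply(colcum, 1L, cumsum), c, r))
  r0 <- pmax(seq_len(r) - half, 1L); r1 <- pmin(seq_len(r) + half, r)
  c0 <- pmax(seq_len(c) - half, 1L); c1 <- pmin(seq_len(c) + half, c)
  R0 <- matrix(r0, r, c);               R1 <- matrix(r1, r, c)
  C0 <- matrix(c0, r, c, byrow = TRUE); C1 <- matrix(c1, r, c, byrow = TRUE)
  res <- sat[cbind(as.vector(R1) + 1L, as.vector(C1) + 1L)] -
    sat[cbind(as.vector(R0),      as.vector(C1) + 1L)] -
    sat[cbind(as.vector(R1) + 1L, as.vector(C0))] +
    sat[cbind(as.vector(R0),      as.vector(C0))]
  matrix(res, r, c)
}

#' Spatially average decays to boost temporal SNR
#'
#' Replaces each temporal sample with the mean over the
#' `kernel_size x kernel_size` spatial neighbourhood, per band. Masked
#' pixels and out-of-bounds positions are excluded from the mean (the
#' neighbourhood shrinks; no padding is invented at the field-of-view rim).
#'
#' @inheritParams subtract_background
#' @param mask Optional [pixel_mask()]; masked pixels do not contribute to
#'   their neighbours' averages.
#' @return A spatially averaged `maflim_image`.
#' @export
spatial_average <- function(image, cfg = preprocess_config(), mask = NULL) {
  k <- cfg$kernel_size
  if (k == 1L) return(image)
  if (image$rows < k || image$cols < k)
    abort_config("image smaller than the averaging kernel")
  half <- (k - 1L) %/% 2L
  W <- if (is.null(mask)) matrix(1, image$rows, image$cols)
       else mask$valid + 0
  cnt <- box_sum(W, half)
  cnt[cnt == 0] <- NA_real_
  decay <- lapply(image$decay, function(arr) {
    out <- arr
    for (t in seq_len(dim(arr)[3])) {
      num <- box_sum(arr[, , t] * W, half)
      out[, , t] <- num / cnt
    }
    out[!is.finite(out)] <- 0
    out
  })
  maflim_image(decay, image$dt, image$meta)
}

# Per-pixel SNR in dB for one band: peak over baseline-noise sd.
band_snr_db <- function(arr, baseline_window) {
  bm <- band_matrix(arr)
  base <- bm$m[, seq_len(baseline_window), drop = FALSE]
  noise <- apply(base, 1L, sd)
  peak <- do.call(pmax, as.data.frame(bm$m))
  snr <- ifelse(noise <= 0, Inf, 20 * log10(pmax(peak, 0) / noise))
  snr[peak <= 0] <- -Inf
  matrix(snr, dim(arr)[1], dim(arr)[2])
}

#' Mask pixels with insufficient signal-to-noise ratio
#'
#' SNR per pixel and band is `20 log10(peak amplitude / baseline-noise
#' standard deviation)`; the worst band decides. Pixels are kept iff
#' SNR >= `snr_threshold_db` (inclusive). A zero noise estimate yields +Inf
#' and the pixel is kept. Apply after background subtraction and spatial
#' averaging.
#'
#' @inheritParams subtract_background
#' @return A [pixel_mask()] with reason `"low_snr"` where below threshold.
#' @export
mask_low_snr <- function(image, cfg = preprocess_config()) {
  snr <- Reduce(pmin, lapply(image$decay, band_snr_db,
                             baseline_window = cfg$baseline_window))
  keep <- snr >= cfg$snr_threshold_db
  reason <- matrix("ok", image$rows, image$cols)
  reason[!keep] <- "low_snr"
  m <- pixel_mask(keep, reason)
  attr(m, "snr_db") <- snr
  m
}

# Even-odd rule point-in-polygon for pixel centres.
points_in_polygon <- function(r, c, vr, vc) {
  n <- length(vr)
  inside <- rep(FALSE, length(r))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vr[i] > r) != (vr[j] > r)) &
      (c < (vc[j] - vc[i]) * (r - vr[i]) / (vr[j] - vr[i]) + vc[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Manually mask regions (e.g. visible tooth areas)
#'
#' Marks all pixels inside the given regions with reason `"manual"`.
#' Idempotent. Regions use 1-based inclusive (row, col) coordinates:
#' `list(type = "rect", r0, c0, r1, c1)` or
#' `list(type = "poly", vertices = list(c(r, c), ...))`.
#'
#' @param mask A [pixel_mask()].
#' @param regions List of region specifications (possibly empty).
#' @return The updated [pixel_mask()].
#' @export
apply_manual_mask <- function(mask, regions) {
  if (!length(regions)) return(mask)
  nr <- nrow(mask$valid); nc <- ncol(mask$valid)
  hit <- matrix(FALSE, nr, nc)
  for (reg in regions) {
    if (identical(reg$type, "rect")) {
      if (reg$r0 < 1 || reg$c0 < 1 || reg$r1 > nr || reg$c1 > nc ||
          reg$r0 > reg$r1 || reg$c0 > reg$c1)
        abort_validation("manual mask rectangle out of image bounds")
      hit[reg$r0:reg$r1, reg$c0:reg$c1] <- TRUE
    } else if (identical(reg$type, "poly")) {
      vr <- vapply(reg$vertices, `[`, 0, 1L)
      vc <- vapply(reg$vertices, `[`, 0, 2L)
      if (any(vr < 1 | vr > nr | vc < 1 | vc > nc))
        abort_validation("manual mask polygon vertex out of image bounds")
      idx <- expand.grid(r = seq_len(nr), c = seq_len(nc))
      hit[as.matrix(idx)] <- hit[as.matrix(idx)] |
        points_in_polygon(idx$r, idx$c, vr, vc)
    } else abort_validation("region type must be 'rect' or 'poly'")
  }
  reason <- matrix("ok", nr, nc)
  reason[hit] <- "manual"
  mask_union(mask, pixel_mask(!hit, reason))
}

#' Harmonize the sampling grid across instruments
#'
#' Linearly interpolates decays and the IRF onto a coarser common time grid
#' (e.g. from 6.25 GS/s testing data onto the 4 GS/s training grid). Only
#' downsampling is supported; discrete integrals are preserved to within
#' about 1% for band-limited inputs.
#'
#' @param image A [maflim_image()].
#' @param irf An [instrument_response()] on the same grid.
#' @param target_dt_ns Target time step in ns; must be >= the source step.
#' @return List with elements `image` and `irf` on the new grid.
#' @export
harmonize_sampling <- function(image, irf, target_dt_ns) {
  dt <- image$dt
  if (target_dt_ns < dt * (1 - 1e-9))
    abort_config("harmonize_sampling only downsamples (target_dt_ns >= dt)")
  if (abs(target_dt_ns - dt) <= 1e-12 * dt)
    return(list(image = image, irf = irf))
  t_old_max <- (image$n_time - 1L) * dt
  n_new <- floor(t_old_max / target_dt_ns) + 1L
  t_new <- (seq_len(n_new) - 1L) * target_dt_ns
  # fractional source indices for vectorized linear interpolation
  u <- t_new / dt + 1
  i0 <- pmin(floor(u), image$n_time - 1L)
  fr <- u - i0
  decay <- lapply(image$decay, function(arr) {
    bm <- band_matrix(arr)
    m_new <- bm$m[, i0, drop = FALSE] * rep(1 - fr, each = nrow(bm$m)) +
      bm$m[, i0 + 1L, drop = FALSE] * rep(fr, each = nrow(bm$m))
    array(m_new, c(bm$dim[1], bm$dim[2], n_new))
  })
  new_img <- maflim_image(decay, target_dt_ns, image$meta)
  new_irf <- NULL
  if (!is.null(irf)) {
    nu <- length(irf$u[[1]])
    t_irf_new <- seq(0, (nu - 1L) * irf$dt, by = target_dt_ns)
    u_list <- lapply(irf$u, function(v)
      approx((seq_along(v) - 1L) * irf$dt, v, xout = t_irf_new)$y)
    new_irf <- instrument_response(u_list, target_dt_ns)
  }
  list(image = new_img, irf = new_irf)
}

#' Run the full preprocessing chain
#'
#' Applies, in fixed order: background subtraction, saturation masking,
#' spatial averaging (excluding masked pixels), SNR masking, then manual
#' region masking. Masks only grow along the chain.
#'
#' @inheritParams subtract_background
#' @param regions Optional manual mask regions (see [apply_manual_mask()]).
#' @return List of class `maflim_preprocessed` with elements `image`
#'   (fit-ready decays), `mask`, and `snr_db` (worst-band SNR map).
#' @export
preprocess <- function(image, cfg = preprocess_config(), regions = list()) {
  sat <- mask_saturated(image, cfg)
  sub <- subtract_background(image, cfg)
  avg <- spatial_average(sub, cfg, mask = sat)
  snr <- mask_low_snr(avg, cfg)
  mask <- mask_union(sat, snr)
  mask <- apply_manual_mask(mask, regions)
  structure(list(image = avg, mask = mask, snr_db = attr(snr, "snr_db")),
            class = "maflim_preprocessed")
}
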