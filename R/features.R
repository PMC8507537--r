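#' The canonical 21-feature maFLIM inventory
#'
#' Per-pixel features, in canonical order: the three normalized band
#' intensities, six absolute-intensity ratios, then the four time-resolved
#' parameters (tau_fast, tau_slow, alpha_fast, tau_avg) for each of the
#' three bands. `alpha_slow` is not a feature (it is `1 - alpha_fast` under
#' normalization).
#'
#' @param pool `"all"` (21), `"spectral"` (the 9 intensity-derived
#'   features), or `"time"` (the 12 time-resolved features).
#' @return Character vector of feature names.
#' @export
maflim_feature_names <- function(pool = c("all", "spectral", "time")) {
  pool <- match.arg(pool)
  spectral <- c("I390n", "I452n", "I500n",
                "R390_452", "R390_500", "R452_500",
                "R452p500_390", "R390p500_452", "R390p452_500")
  timef <- as.vector(vapply(c("390", "452", "500"), function(s)
    paste0(c("tau_fast_", "tau_slow_", "alpha_fast_", "tau_avg_"), s),
    character(4)))
  switch(pool, all = c(spectral, timef), spectral = spectral, time = timef)
}

#' Absolute fluorescence intensity map
#'
#' Integrates the decay trace of one band over the full recorded transient
#' (trapezoid rule), per pixel, giving intensity x ns.
#'
#' @param image A preprocessed [maflim_image()].
#' @param band Band label.
#' @return Numeric `rows x cols` matrix.
#' @export
absolute_intensity <- function(image, band) {
  arr <- image$decay[[band]]
  if (is.null(arr)) abort_validation(sprintf("unknown band '%s'", band))
  bm <- band_matrix(arr)
  n <- ncol(bm$m)
  s <- rowSums(bm$m) - 0.5 * (bm$m[, 1L] + bm$m[, n])
  matrix(s * image$dt, bm$dim[1], bm$dim[2])
}

#' Normalized multispectral intensities
#'
#' Each band's absolute intensity divided by the across-band sum, so the
#' three maps sum to 1 at every pixel. Pixels where all three intensities
#' are zero are invalidated (`NA`).
#'
#' @param I390,I452,I500 Absolute intensity matrices (see
#'   [absolute_intensity()]).
#' @return Named list of three matrices `I390n`, `I452n`, `I500n`.
#' @export
normalized_intensity <- function(I390, I452, I500) {
  tot <- I390 + I452 + I500
  tot[tot == 0] <- NA_real_
  list(I390n = I390 / tot, I452n = I452 / tot, I500n = I500 / tot)
}

#' The six absolute-intensity ratios
#'
#' Three single-channel ratios (I390/I452, I390/I500, I452/I500) and three
#' two-vs-one ratios ((I452+I500)/I390, (I390+I500)/I452, (I390+I452)/I500).
#' A zero denominator invalidates that pixel for that feature (`NA`).
#'
#' @inheritParams normalized_intensity
#' @return Named list of six matrices in canonical order.
#' @export
intensity_ratios <- function(I390, I452, I500) {
  safe_div <- function(num, den) {
    den[den == 0] <- NA_real_
    num / den
  }
  list(R390_452     = safe_div(I390, I452),
       R390_500     = safe_div(I390, I500),
       R452_500     = safe_div(I452, I500),
       R452p500_390 = safe_div(I452 + I500, I390),
       R390p500_452 = safe_div(I390 + I500, I452),
       R390p452_500 = safe_div(I390 + I452, I500))
}

#' Assemble the 21-feature per-pixel stack
#'
#' Combines normalized intensities and intensity ratios (computed from the
#' preprocessed image) with the per-band time-resolved fit parameters into
#' the canonical 21-map feature stack. Absolute intensities are
#' intermediates only, not features. Pixels where any feature is
#' non-finite are removed from the valid mask.
#'
#' @param image Preprocessed [maflim_image()].
#' @param fits [fit_image()] output covering the mask.
#' @param mask [pixel_mask()] of valid pixels.
#' @return Object of class `feature_stack`: list with `features` (named
#'   list of 21 matrices in canonical order) and `valid` (logical matrix).
#' @export
build_feature_stack <- function(image, fits, mask = fits$mask) {
  I390 <- absolute_intensity(image, "b390")
  I452 <- absolute_intensity(image, "b452")
  I500 <- absolute_intensity(image, "b500")
  feats <- c(normalized_intensity(I390, I452, I500),
             intensity_ratios(I390, I452, I500))
  for (b in c(b390 = "390", b452 = "452", b500 = "500")) {
    key <- paste0("b", b)
    maps <- fits$bands[[key]]
    if (is.null(maps)) abort_validation(sprintf("fits missing band %s", key))
    miss <- mask$valid & !is.finite(maps$tau_fast)
    if (any(miss))
      abort_validation(sprintf(
        "missing fit at %d valid pixel(s) in band %s", sum(miss), key))
    feats[[paste0("tau_fast_", b)]]   <- maps$tau_fast
    feats[[paste0("tau_slow_", b)]]   <- maps$tau_slow
    feats[[paste0("alpha_fast_", b)]] <- maps$alpha_fast
    feats[[paste0("tau_avg_", b)]]    <- maps$tau_avg
  }
  feats <- feats[maflim_feature_names()]
  valid <- mask$valid
  for (f in feats) valid <- valid & is.finite(f)
  structure(list(features = feats, valid = valid), class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("maFLIM feature stack: %d features, %d x %d pixels (%d valid)\n",
              length(x$features), nrow(x$valid), ncol(x$valid),
              sum(x$valid)))
  cat(" ", paste(names(x$features), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy per-pixel feature table
#'
#' @param x A `feature_stack`.
#' @param row.names,optional Unused (S3 signature).
#' @param ... Unused.
#' @return `data.frame` with `row`, `col` and one column per feature; valid
#'   pixels only.
#' @export
as.data.frame.feature_stack <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  idx <- which(x$valid, arr.ind = TRUE)
  out <- data.frame(row = idx[, 1], col = idx[, 2])
  for (nm in names(x$features)) out[[nm]] <- x$features[[nm]][idx]
  out
}
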