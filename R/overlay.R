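#' Render a posterior probability overlay image
#'
#' Superposes the posterior probability map (red scale) on the total
#' fluorescence intensity map (grey scale) and writes an 8-bit RGB PNG.
#' Blend per pixel with grey level `g` (intensity normalized to \[0, 1\])
#' and posterior `p`: red channel `g + p (1 - g)`, green and blue
#' `g (1 - p)`, so redness is exactly `p` (strictly monotone in the
#' posterior) while anatomy stays visible. Masked pixels render as pure
#' grayscale.
#'
#' @param pmap A [posterior_map()] result.
#' @param intensity Total-intensity matrix (same dims), any nonnegative
#'   scale.
#' @param path Output PNG path.
#' @param gamma Display gamma applied to the normalized intensity
#'   (default 0.7 lifts dim tissue).
#' @return The normalized RGB array (rows x cols x 3), invisibly; the file
#'   is written to `path`.
#' @export
render_overlay <- function(pmap, intensity, path, gamma = 0.7) {
  if (!identical(dim(pmap$p), dim(intensity)))
    abort_validation("posterior map and intensity map dims differ")
  g <- intensity - min(intensity, na.rm = TRUE)
  mx <- max(g, na.rm = TRUE)
  if (mx > 0) g <- g / mx
  g[!is.finite(g)] <- 0
  g <- g^gamma
  p <- pmap$p
  p[!pmap$valid | !is.finite(p)] <- 0
  rgb <- array(0, c(nrow(g), ncol(g), 3L))
  rgb[, , 1] <- g + p * (1 - g)
  rgb[, , 2] <- g * (1 - p)
  rgb[, , 3] <- g * (1 - p)
  rgb <- pmin(pmax(rgb, 0), 1)
  png::writePNG(rgb, target = path)
  invisible(rgb)
}

#' Total fluorescence intensity map of an image
#'
#' Sum of the three absolute band intensities, the grayscale background
#' used for overlays.
#'
#' @param image A [maflim_image()].
#' @return Numeric matrix.
#' @export
total_intensity <- function(image) {
  absolute_intensity(image, "b390") + absolute_intensity(image, "b452") +
    absolute_intensity(image, "b500")
}
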