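#' maFLIM spectral band labels
#'
#' The three emission bands of the maFLIM endoscope, in fixed order:
#' 390 +/- 20 nm (collagen), 452 +/- 22.5 nm (NADH) and >500 nm (FAD).
#' The open-ended third band is labelled `"b500"` and its features carry the
#' 500 subscript.
#'
#' @return Character vector `c("b390", "b452", "b500")`.
#' @export
maflim_bands <- function() c("b390", "b452", "b500")

#' Construct a maFLIM image
#'
#' A maFLIM image holds, for each of the three emission spectral bands, a
#' 3-D array of fluorescence intensity decay signals `decay[row, col, time]`
#' sampled with a common time step `dt` (ns). All bands must share identical
#' dimensions and all values must be finite. Construction validates every
#' invariant; no partially valid object is ever returned.
#'
#' @param decay Named list of three numeric 3-D arrays, names
#'   `c("b390","b452","b500")` (order enforced), each `rows x cols x n_time`.
#' @param dt Time step in nanoseconds (`1 / sampling rate`); e.g. `0.25` for
#'   4 GS/s acquisition, `0.16` for 6.25 GS/s.
#' @param meta Optional list of metadata: `subject_id`, `site`, `label`
#'   (one of `"healthy"`, `"dysplasia/cancer"`, `"unknown"`),
#'   `instrument_id`, `full_scale` (digitizer full scale, same units as
#'   the decays).
#' @return An object of class `maflim_image` with elements `decay`, `dt`,
#'   `rows`, `cols`, `n_time`, `meta`.
#' @examples
#' arr <- array(rexp(4 * 4 * 16), c(4, 4, 16))
#' img <- maflim_image(list(b390 = arr, b452 = arr, b500 = arr), dt = 0.25)
#' img
#' @export
maflim_image <- function(decay, dt, meta = list()) {
  if (!is.list(decay) || !identical(names(decay), maflim_bands()))
    abort_validation(paste0(
      "`decay` must be a named list with bands ",
      paste(maflim_bands(), collapse = ", "), " in that order"))
  dims <- lapply(decay, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    abort_validation("each band decay must be a 3-D array (rows x cols x time)")
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    abort_validation("all bands must share identical rows x cols x n_time")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    abort_validation("`dt` must be a single positive finite number (ns)")
  for (b in maflim_bands())
    if (!all(is.finite(decay[[b]])))
      abort_validation(sprintf("band %s contains non-finite decay values", b))
  d <- dims[[1]]
  lab <- meta$label
  if (!is.null(lab) &&
      !lab %in% c("healthy", "dysplasia/cancer", "unknown"))
    abort_validation("meta$label must be healthy, dysplasia/cancer or unknown")
  structure(list(
    decay = decay, dt = dt,
    rows = d[1], cols = d[2], n_time = d[3],
    meta = meta
  ), class = "maflim_image")
}

#' @export
print.maflim_image <- function(x, ...) {
  cat(sprintf(
    "maFLIM image: %d x %d pixels, %d time samples, dt = %g ns (%.3g GS/s)\n",
    x$rows, x$cols, x$n_time, x$dt, 1 / x$dt))
  if (length(x$meta)) {
    keep <- intersect(c("subject_id", "site", "label", "instrument_id"),
                      names(x$meta))
    for (k in keep) cat(sprintf("  %s: %s\n", k, as.character(x$meta[[k]])))
  }
  invisible(x)
}

#' Construct an instrument response function
#'
#' The instrument response function (IRF) `u(t)` per spectral band, on the
#' same time grid as the images it will be used with. The IRF must be
#' non-negative (after baseline removal), have positive discrete integral,
#' and peak strictly inside the record.
#'
#' @param u Named list of three numeric vectors (one per band, names as
#'   [maflim_bands()]), or a single numeric vector reused for all bands.
#' @param dt Time step in ns.
#' @return Object of class `instrument_response` with elements `u` (list of
#'   three vectors) and `dt`.
#' @seealso [make_irf()] to build a Gaussian IRF.
#' @export
instrument_response <- function(u, dt) {
  if (is.numeric(u)) u <- setNames(rep(list(u), 3), maflim_bands())
  if (!is.list(u) || !identical(names(u), maflim_bands()))
    abort_validation("`u` must be a numeric vector or a named 3-band list")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    abort_validation("`dt` must be a single positive finite number (ns)")
  for (b in maflim_bands()) {
    v <- u[[b]]
    if (!is.numeric(v) || length(v) < 3L || !all(is.finite(v)))
      abort_validation(sprintf("IRF for band %s must be finite, length >= 3", b))
    if (min(v) < -1e-9 * max(abs(v)))
      abort_validation(sprintf("IRF for band %s must be nonnegative", b))
    if (sum(v) * dt <= 0)
      abort_validation(sprintf("IRF for band %s must have positive integral", b))
    pk <- which.max(v)
    if (pk == 1L || pk == length(v))
      abort_validation(sprintf("IRF peak for band %s must lie inside the record", b))
  }
  structure(list(u = u, dt = dt), class = "instrument_response")
}

#' @export
print.instrument_response <- function(x, ...) {
  n <- length(x$u[[1]])
  cat(sprintf("Instrument response: %d samples, dt = %g ns\n", n, x$dt))
  invisible(x)
}

# Resolve an IRF argument to the per-band vector.
irf_vector <- function(irf, band) {
  if (inherits(irf, "instrument_response")) irf$u[[band]]
  else if (is.numeric(irf)) irf
  else abort_validation("`irf` must be an instrument_response or numeric vector")
}

#' Construct a pixel validity mask
#'
#' Tracks which pixels survive preprocessing, and why the others were
#' dropped. The invariant `valid == (reason == "ok")` is enforced.
#'
#' @param valid Logical matrix (rows x cols), or `NULL` to build an all-valid
#'   mask of dimensions `dim`.
#' @param reason Character matrix of the same shape with entries among
#'   `"ok"`, `"saturated"`, `"low_snr"`, `"manual"`; defaults to `"ok"`
#'   where valid.
#' @param dim Integer vector `c(rows, cols)` when `valid` is `NULL`.
#' @return Object of class `pixel_mask` with elements `valid` and `reason`.
#' @export
pixel_mask <- function(valid = NULL, reason = NULL, dim = NULL) {
  if (is.null(valid)) {
    if (is.null(dim)) abort_validation("supply `valid` or `dim`")
    valid <- matrix(TRUE, dim[1], dim[2])
  }
  if (!is.logical(valid) || !is.matrix(valid))
    abort_validation("`valid` must be a logical matrix")
  if (is.null(reason)) {
    reason <- matrix("ok", nrow(valid), ncol(valid))
    reason[!valid] <- "manual"
  }
  if (!identical(base::dim(reason), base::dim(valid)))
    abort_validation("`reason` shape must match `valid`")
  ok <- reason %in% c("ok", "saturated", "low_snr", "manual")
  if (!all(ok)) abort_validation("unknown mask reason code")
  if (!identical(as.vector(valid), as.vector(reason == "ok")))
    abort_validation("mask invariant violated: valid must equal (reason == 'ok')")
  structure(list(valid = valid, reason = reason), class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  tab <- table(factor(x$reason,
                      levels = c("ok", "saturated", "low_snr", "manual")))
  cat(sprintf("Pixel mask %d x %d: %d valid\n",
              nrow(x$valid), ncol(x$valid), sum(x$valid)))
  print(tab)
  invisible(x)
}

# Union of masked-out pixels; earlier reasons win so masks only grow and a
# pixel keeps the first cause that removed it.
mask_union <- function(a, b) {
  if (!identical(dim(a$valid), dim(b$valid)))
    abort_validation("mask shapes differ")
  valid <- a$valid & b$valid
  reason <- a$reason
  take_b <- a$valid & !b$valid
  reason[take_b] <- b$reason[take_b]
  pixel_mask(valid, reason)
}

#' Assemble a paired lesion/healthy maFLIM dataset
#'
#' Each subject contributes one lesion image and one clinically healthy
#' contralateral image; the pairing is total. Lesion images carry a
#' histopathology grade (MiD, MoD, HiD, SCC), pooled as the positive class.
#'
#' @param subjects List of records, each a list with elements `subject_id`,
#'   `lesion`, `healthy` (each a `maflim_image` or `maflim_scene`) and
#'   `grade`.
#' @return Object of class `maflim_dataset`.
#' @export
maflim_dataset <- function(subjects) {
  if (!length(subjects)) abort_validation("empty dataset")
  for (s in subjects) {
    if (is.null(s$subject_id) || is.null(s$lesion) || is.null(s$healthy))
      abort_validation("each subject needs subject_id, lesion and healthy images")
    if (is.null(s$grade)) abort_validation("each lesion needs a histopathology grade")
  }
  ids <- vapply(subjects, function(s) as.character(s$subject_id), "")
  if (anyDuplicated(ids)) abort_validation("duplicated subject_id")
  structure(list(subjects = subjects), class = "maflim_dataset")
}

#' @export
print.maflim_dataset <- function(x, ...) {
  n <- length(x$subjects)
  grades <- vapply(x$subjects, function(s) as.character(s$grade), "")
  cat(sprintf("maFLIM paired dataset: %d subjects (%d images)\n", n, 2L * n))
  print(table(grades))
  invisible(x)
}

#' @export
length.maflim_dataset <- function(x) length(x$subjects)

# Image/IRF accessors for the shapes a dataset entry may take: a
# maflim_scene, a bare maflim_image, or a plain list(image=, irf=) as
# produced by read_maflim().
scene_image <- function(x) {
  if (inherits(x, "maflim_scene")) x$image
  else if (inherits(x, "maflim_image")) x
  else if (is.list(x) && inherits(x$image, "maflim_image")) x$image
  else abort_validation("expected a maflim_image or maflim_scene")
}

scene_irf <- function(x) {
  if (inherits(x, "instrument_response")) x
  else if (is.list(x) && inherits(x$irf, "instrument_response")) x$irf
  else abort_validation("no instrument response available for this image")
}
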