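#' Write a maFLIM image container
#'
#' Stores an image, its instrument response and pixel mask in a single
#' self-describing HDF5 file:
#' \preformatted{
#'   /bands/{b390,b452,b500}/decay   rows x cols x n_time
#'   /irf/{b390,b452,b500}           n_irf
#'   /mask/valid                     rows x cols (0/1)
#'   /mask/reason                    rows x cols (strings)
#'   root attributes: dt_ns, rows, cols, n_time, subject_id, site, label,
#'                    instrument_id, full_scale
#' }
#' The write is atomic: a temporary file in the target directory is renamed
#' over `path` only after a successful write. All invariants are validated
#' before anything is written.
#'
#' @param image A [maflim_image()].
#' @param irf An [instrument_response()] (optional but recommended).
#' @param mask A [pixel_mask()]; defaults to all-valid.
#' @param path Output file path (conventionally `.h5`).
#' @return `path`, invisibly.
#' @seealso [read_maflim()]
#' @export
write_maflim <- function(image, irf = NULL, mask = NULL, path) {
  if (!inherits(image, "maflim_image"))
    abort_validation("`image` must be a maflim_image")
  # re-validate (objects may have been mutated since construction)
  image <- maflim_image(image$decay, image$dt, image$meta)
  if (!is.null(irf)) {
    if (!inherits(irf, "instrument_response"))
      abort_validation("`irf` must be an instrument_response")
    irf <- instrument_response(irf$u, irf$dt)
  }
  if (is.null(mask)) mask <- pixel_mask(dim = c(image$rows, image$cols))
  mask <- pixel_mask(mask$valid, mask$reason)
  if (!identical(dim(mask$valid), c(image$rows, image$cols)))
    abort_validation("mask shape does not match image")

  tmp <- tempfile(pattern = basename(path), tmpdir = dirname(path),
                  fileext = ".tmp.h5")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  rhdf5::h5createFile(tmp)
  rhdf5::h5createGroup(tmp, "bands")
  for (b in maflim_bands()) {
    rhdf5::h5createGroup(tmp, file.path("bands", b))
    rhdf5::h5write(image$decay[[b]], tmp, file.path("bands", b, "decay"))
  }
  if (!is.null(irf)) {
    rhdf5::h5createGroup(tmp, "irf")
    for (b in maflim_bands())
      rhdf5::h5write(irf$u[[b]], tmp, file.path("irf", b))
  }
  rhdf5::h5createGroup(tmp, "mask")
  rhdf5::h5write(mask$valid + 0L, tmp, "mask/valid")
  rhdf5::h5write(mask$reason, tmp, "mask/reason")

  fid <- rhdf5::H5Fopen(tmp)
  wattr <- function(name, value)
    rhdf5::h5writeAttribute(value, fid, name)
  wattr("format", "maflim-container")
  wattr("format_version", 1L)
  wattr("dt_ns", image$dt)
  wattr("rows", as.integer(image$rows))
  wattr("cols", as.integer(image$cols))
  wattr("n_time", as.integer(image$n_time))
  if (!is.null(irf)) wattr("irf_dt_ns", irf$dt)
  for (k in c("subject_id", "site", "label", "instrument_id"))
    if (!is.null(image$meta[[k]])) wattr(k, as.character(image$meta[[k]]))
  if (!is.null(image$meta$full_scale))
    wattr("full_scale", as.numeric(image$meta$full_scale))
  rhdf5::H5Fclose(fid)

  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Read a maFLIM image container
#'
#' Reads a file written by [write_maflim()] and reconstructs the image,
#' instrument response and mask, re-running full validation. Arrays and the
#' time step round-trip losslessly.
#'
#' @param path Path to a maFLIM HDF5 container.
#' @return List with elements `image` ([maflim_image()]), `irf`
#'   ([instrument_response()] or `NULL`), `mask` ([pixel_mask()]).
#' @export
read_maflim <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  contents <- tryCatch(rhdf5::h5ls(path, recursive = TRUE),
                       error = function(e)
                         abort_format(sprintf("not an HDF5 container: %s", path)))
  have <- file.path(contents$group, contents$name)
  have <- sub("^/+", "/", have)
  attrs <- rhdf5::h5readAttributes(path, "/")
  if (!identical(as.character(attrs$format), "maflim-container"))
    abort_format("missing root attribute 'format' (= maflim-container)")
  for (a in c("dt_ns", "rows", "cols", "n_time"))
    if (is.null(attrs[[a]]))
      abort_format(sprintf("missing required root attribute '%s'", a))

  bands_present <- intersect(file.path("/bands", maflim_bands()),
                             sub("^/+", "/", contents$group))
  decay <- list()
  for (b in maflim_bands()) {
    ds <- sprintf("/bands/%s/decay", b)
    if (!ds %in% have)
      abort_format(sprintf("missing required dataset '%s'", ds))
    decay[[b]] <- rhdf5::h5read(path, ds)
  }
  dims <- lapply(decay, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    abort_validation("band decay shapes differ in container")

  meta <- list()
  for (k in c("subject_id", "site", "label", "instrument_id"))
    if (!is.null(attrs[[k]])) meta[[k]] <- as.character(attrs[[k]])
  if (!is.null(attrs$full_scale)) meta$full_scale <- as.numeric(attrs$full_scale)
  image <- maflim_image(decay, dt = as.numeric(attrs$dt_ns), meta = meta)

  irf <- NULL
  if ("/irf" %in% sub("^/+", "/", file.path(contents$group, contents$name))
      || any(grepl("^/irf/", have))) {
    u <- list()
    for (b in maflim_bands()) {
      ds <- sprintf("/irf/%s", b)
      if (!ds %in% have)
        abort_format(sprintf("missing required dataset '%s'", ds))
      u[[b]] <- as.numeric(rhdf5::h5read(path, ds))
    }
    irf_dt <- if (!is.null(attrs$irf_dt_ns)) as.numeric(attrs$irf_dt_ns)
              else image$dt
    irf <- instrument_response(u, irf_dt)
  }

  if (!"/mask/valid" %in% have)
    abort_format("missing required dataset '/mask/valid'")
  valid <- rhdf5::h5read(path, "/mask/valid") != 0
  reason <- if ("/mask/reason" %in% have)
    rhdf5::h5read(path, "/mask/reason") else NULL
  if (!is.null(reason)) {
    reason <- matrix(as.character(reason), nrow(valid), ncol(valid))
  }
  mask <- pixel_mask(valid, reason)
  if (!identical(dim(mask$valid), c(image$rows, image$cols)))
    abort_validation("mask shape does not match image in container")

  list(image = image, irf = irf, mask = mask)
}
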