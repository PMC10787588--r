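#' Construct a ScanSet
#'
#' A ScanSet carries one B-scan of paired PA and US raw RF frames (matrices of
#' axial samples x A-lines), the acquisition parameters, free-form provenance
#' metadata, and — for simulated scans — the flow ground truth.
#'
#' @param pa,us Numeric matrices `[n_samples x n_lines]` of identical shape,
#'   all values finite; `n_lines >= 2`.
#' @param params An [acquisition_params()] object.
#' @param meta Named list of scalar provenance values (seed, generator
#'   version, realized noise levels, ...).
#' @param ground_truth Optional ground truth list as produced by the
#'   simulator: matrices `true_axial_velocity` and `true_speed` (m/s, same
#'   shape as `pa`, zero outside flow regions), per-line `flow_angle`
#'   (degrees) and `surface_arrival` (1-based sample index).
#' @return An object of class `scan_set`.
#' @export
scan_set <- function(pa, us, params, meta = list(), ground_truth = NULL) {
  s <- list(pa = pa, us = us, params = params, meta = meta,
            ground_truth = ground_truth)
  class(s) <- "scan_set"
  validate_scan_set(s)
}

validate_scan_set <- function(s) {
  if (!is.matrix(s$pa) || !is.matrix(s$us))
    stop("scan_set: 'pa' and 'us' must be matrices [n_samples x n_lines]")
  if (!identical(dim(s$pa), dim(s$us)))
    stop("scan_set: 'pa' and 'us' shapes differ")
  if (ncol(s$pa) < 2L) stop("scan_set: need n_lines >= 2")
  if (!all(is.finite(s$pa)) || !all(is.finite(s$us)))
    stop("scan_set: non-finite values in 'pa' or 'us'")
  validate_acq_params(s$params)
  gt <- s$ground_truth
  if (!is.null(gt)) {
    for (f in c("true_axial_velocity", "true_speed"))
      if (!is.null(gt[[f]]) && !identical(dim(gt[[f]]), dim(s$pa)))
        stop("scan_set: ground_truth$", f, " shape differs from pa")
    for (f in c("flow_angle", "surface_arrival"))
      if (!is.null(gt[[f]]) && length(gt[[f]]) != ncol(s$pa))
        stop("scan_set: ground_truth$", f, " length differs from n_lines")
  }
  s
}

#' @export
print.scan_set <- function(x, ...) {
  cat(sprintf("<scan_set> %d samples x %d lines (%s, %s)\n",
              nrow(x$pa), ncol(x$pa), x$params$scan_mode,
              x$params$propagation_convention))
  if (!is.null(x$ground_truth)) cat("  with ground truth\n")
  invisible(x)
}

.h5_layout_version <- "corrdop-1"

#' Write a ScanSet to an HDF5 container
#'
#' Layout (all SI units): datasets `/pa` and `/us` (float64,
#' samples x lines), scalar datasets under `/params/*` and `/meta/*`,
#' optional ground truth under `/truth/*`, and a root attribute
#' `layout_version`.
#'
#' @param scan A valid [scan_set()].
#' @param path Output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_scanset <- function(scan, path) {
  validate_scan_set(scan)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("write_scanset: directory does not exist: ", dir)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(scan$pa, path, "pa")
  rhdf5::h5write(scan$us, path, "us")
  rhdf5::h5createGroup(path, "params")
  p <- scan$params
  for (f in names(p)) rhdf5::h5write(p[[f]], path, paste0("params/", f))
  if (length(scan$meta)) {
    rhdf5::h5createGroup(path, "meta")
    for (k in names(scan$meta))
      rhdf5::h5write(scan$meta[[k]], path, paste0("meta/", k))
  }
  gt <- scan$ground_truth
  if (!is.null(gt)) {
    rhdf5::h5createGroup(path, "truth")
    for (k in names(gt))
      if (!is.null(gt[[k]])) rhdf5::h5write(gt[[k]], path, paste0("truth/", k))
  }
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(.h5_layout_version, fid, "layout_version")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a ScanSet from an HDF5 container
#'
#' Inverse of [write_scanset()]; the round trip is bit-exact for float64
#' arrays. A container missing `/pa`, `/us` or `/params` fails with a format
#' error naming the dataset; a missing `/truth` group yields a `NULL`
#' `ground_truth`.
#'
#' @param path Path to an HDF5 file written by [write_scanset()].
#' @return A validated [scan_set()].
#' @export
read_scanset <- function(path) {
  if (!file.exists(path)) stop("read_scanset: file not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  present <- file.path(ls$group, ls$name)
  have <- function(nm) any(present == file.path("/", nm) | present == paste0("//", nm))
  for (nm in c("pa", "us", "params"))
    if (!have(nm)) stop("read_scanset: container missing dataset '", nm, "'")
  pa <- rhdf5::h5read(path, "pa")
  us <- rhdf5::h5read(path, "us")
  praw <- rhdf5::h5read(path, "params")
  praw <- lapply(praw, function(v) if (is.array(v)) as.vector(v) else v)
  params <- do.call(acquisition_params, praw[names(formals(acquisition_params))[
    names(formals(acquisition_params)) %in% names(praw)]])
  meta <- if (have("meta")) {
    m <- rhdf5::h5read(path, "meta")
    lapply(m, function(v) if (is.array(v)) as.vector(v) else v)
  } else list()
  gt <- if (have("truth")) rhdf5::h5read(path, "truth") else NULL
  if (!is.null(gt))
    gt <- lapply(gt, function(v) {
      if (is.array(v) && length(dim(v)) == 1L) as.vector(v) else v
    })
  scan_set(pa, us, params, meta = meta, ground_truth = gt)
}
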