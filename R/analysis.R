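# Region statistics, group comparison, and color-Doppler rendering.

#' Mean Doppler speed per B-scan sector
#'
#' Divides the B-scan uniformly into `n_regions` contiguous sectors of equal
#' line-pair count (1000 lines / 20 regions = 50 pairs each at the defaults)
#' and reports the mean absolute compensated velocity over valid windows per
#' sector. Sectors with no valid window report `NaN` speed and `n = 0`.
#'
#' @param vmap A `velocity_map` with compensated `v`.
#' @param n_regions Number of sectors (must not exceed the number of pairs).
#' @return `data.frame` with columns `region`, `mean_speed` (m/s), `n_valid`.
#' @export
sector_speeds <- function(vmap, n_regions = 20L) {
  stopifnot(inherits(vmap, "velocity_map"))
  if (is.null(vmap$v)) stop("sector_speeds: run compensate() first")
  np <- ncol(vmap$v)
  if (n_regions > np)
    stop("sector_speeds: n_regions exceeds the number of line pairs")
  sector <- ceiling(seq_len(np) / (np / n_regions))
  res <- lapply(seq_len(n_regions), function(s) {
    cols <- which(sector == s)
    vals <- abs(vmap$v[, cols, drop = FALSE])[vmap$valid[, cols, drop = FALSE]]
    vals <- vals[is.finite(vals)]
    data.frame(region = s,
               mean_speed = if (length(vals)) mean(vals) else NaN,
               n_valid = length(vals))
  })
  do.call(rbind, res)
}

#' Two-sample Student's t-test on region speeds
#'
#' Classical unpaired pooled-variance Student's t with
#' `df = na + nb - 2` and a two-sided p-value; used to compare mean Doppler
#' speeds between tissue groups. Degenerate zero-variance inputs are handled
#' explicitly: equal means give `t = 0, p = 1`; unequal means give `p = 0`
#' flagged degenerate.
#'
#' @param a,b Numeric vectors of speeds (each length >= 2).
#' @return List with `t`, `df`, `p`, and `degenerate` flag.
#' @export
ttest_groups <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("ttest_groups: each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1,
                  degenerate = FALSE))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L, p = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' Paint a velocity map onto the original sample grid
#'
#' Expands the per-window estimates back to an `[n_samples x n_lines-1]`
#' image on the original (pre-interpolation) axial grid, filling the support
#' of each window; invalid windows stay `NA`. Uses the back-shifted window
#' centers when present (see [backshift()]).
#'
#' @param vmap A `velocity_map`.
#' @param n_samples A-line length on the original grid.
#' @param field `"v"`, `"vc"`, `"pshift"` or `"rho"`.
#' @return Numeric matrix `[n_samples x n_pairs]` with `NA` where no valid
#'   window contributes.
#' @export
vmap_to_image <- function(vmap, n_samples, field = c("v", "vc", "pshift", "rho")) {
  stopifnot(inherits(vmap, "velocity_map"))
  field <- match.arg(field)
  M <- vmap[[field]]
  if (is.null(M)) stop("vmap_to_image: field '", field, "' not filled")
  np <- ncol(M)
  hop <- if (is.na(vmap$window_hop)) 12L else vmap$window_hop
  half_orig <- max(1L, round(hop / vmap$nres / 2))
  out <- matrix(NA_real_, n_samples, np)
  centers <- vmap$window_centers_orig %||%
    matrix(vmap$window_centers, nrow(M), np)
  for (i in seq_len(np)) {
    ok <- which(vmap$valid[, i] & is.finite(M[, i]))
    for (w in ok) {
      kc <- round((centers[w, i] - 1) / vmap$nres) + 1
      rows <- max(1L, kc - half_orig):min(n_samples, kc + half_orig)
      out[rows, i] <- M[w, i]
    }
  }
  out
}

# Diverging color-Doppler palette on [-1, 1]: black at 0, red->orange for
# positive (toward the transducer), blue->cyan for negative.
.doppler_rgb <- function(x) {
  x <- pmax(-1, pmin(1, x))
  r <- ifelse(x > 0, x, 0)
  g <- ifelse(x > 0, 0.5 * x^2, x^2)
  b <- ifelse(x < 0, -x, 0)
  cbind(r, g, b)
}

#' Render a color-Doppler overlay on the US image
#'
#' Grayscale log-compressed US underlay with valid velocity pixels colored by
#' the diverging Doppler map (black = stationary, red to orange = increasing
#' positive velocity, blue to cyan = increasing negative velocity), symmetric
#' over `[-v_display, v_display]`. Invalid pixels show the US underlay only.
#'
#' @param vmap A `velocity_map` with compensated `v`.
#' @param us_frame US RF matrix `[n_samples x n_lines]`.
#' @param params [acquisition_params()].
#' @param cfg [doppler_config()].
#' @param v_display Full-scale display speed, m/s.
#' @param dynamic_range_db US display dynamic range, dB.
#' @param polar Also produce the polar-warped raster (rotational scans).
#' @param out_px Polar raster side length.
#' @return List with `linear` (`[n_samples x n_pairs x 3]` RGB array in
#'   `[0,1]`) and, when `polar = TRUE`, `polar` (`[out_px x out_px x 3]`).
#' @export
render_color_doppler <- function(vmap, us_frame, params = acquisition_params(),
                                 cfg = doppler_config(), v_display = 5e-3,
                                 dynamic_range_db = 40, polar = FALSE,
                                 out_px = 512L) {
  stopifnot(inherits(vmap, "velocity_map"))
  if (is.null(vmap$v)) stop("render_color_doppler: run compensate() first")
  np <- ncol(vmap$v)
  env <- envelope(us_frame[, seq_len(np), drop = FALSE])
  env <- env / max(env, 1e-300)
  us_gray <- pmax(1 + 20 * log10(pmax(env, 1e-300)) / dynamic_range_db, 0)
  vimg <- vmap_to_image(vmap, nrow(us_frame), "v")
  lin <- array(rep(us_gray, 3L), dim = c(nrow(us_gray), np, 3L))
  sel <- which(is.finite(vimg))
  if (length(sel)) {
    cols <- .doppler_rgb(vimg[sel] / v_display)
    for (ch in 1:3) {
      plane <- lin[, , ch]
      plane[sel] <- cols[, ch]
      lin[, , ch] <- plane
    }
  }
  out <- list(linear = lin)
  if (polar) {
    pol <- array(NA_real_, dim = c(out_px, out_px, 3L))
    for (ch in 1:3) pol[, , ch] <- to_polar(lin[, , ch], params, out_px)
    out$polar <- pol
  }
  out
}

#' Write an RGB array to PNG
#'
#' @param img `[h x w x 3]` array in `[0,1]`; `NA` renders black.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(img, path) {
  img[is.na(img)] <- 0
  png::writePNG(img, path)
  invisible(path)
}
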