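#' Peak-detection parameters
#'
#' Defaults follow the screening protocol: a peakdet delta of 10 intensity
#' units, the 5 most intense peaks kept per pixel, and exclusion of any peak
#' below 10 times the background noise level.
#'
#' @param delta minimum fall from a running maximum for it to count as a peak
#'   (intensity units, > 0).
#' @param top_k number of peaks kept per pixel (>= 1).
#' @param noise_factor multiple of the background noise level a peak must
#'   reach (inclusive) to be retained (>= 1).
#' @param delta_mode `"classic"` for the standard peakdet drop-from-running-max
#'   rule; `"preceding_min"` applies delta to the height of the candidate
#'   maximum above the preceding minimum instead.
#' @return A `detection_params` list.
#' @export
detection_params <- function(delta = 10, top_k = 5, noise_factor = 10,
                             delta_mode = c("classic", "preceding_min")) {
  delta_mode <- match.arg(delta_mode)
  stopifnot(delta > 0, top_k >= 1, noise_factor >= 1)
  structure(list(delta = delta, top_k = as.integer(top_k),
                 noise_factor = noise_factor, delta_mode = delta_mode),
            class = "detection_params")
}

#' Alternating-extrema (peakdet) detection
#'
#' Scans the series left to right tracking a running maximum and minimum. A
#' maximum is emitted once the series has fallen at least `delta` below the
#' running maximum, then a minimum once it has risen at least `delta` above
#' the running minimum, and so on, so reported maxima and minima strictly
#' alternate. The trailing running extremum at the end of the series is not
#' emitted.
#'
#' @param values intensity series.
#' @param positions positions (m/z) aligned with `values`; defaults to
#'   indices.
#' @param delta detection threshold (> 0).
#' @param delta_mode see [detection_params()].
#' @return List with data frames `maxima` and `minima`, each with `index`
#'   (1-based), `position` and `value`.
#' @examples
#' detect_extrema(c(0, 12, 1, 15, 2), delta = 10)$maxima
#' @export
detect_extrema <- function(values, positions = seq_along(values), delta,
                           delta_mode = c("classic", "preceding_min")) {
  delta_mode <- match.arg(delta_mode)
  stopifnot(delta > 0, length(values) == length(positions))
  res <- .peakdet_cpp(as.numeric(values), delta,
                      if (delta_mode == "classic") 0L else 1L)
  as_df <- function(idx0) {
    idx <- idx0 + 1L
    data.frame(index = idx, position = positions[idx], value = values[idx])
  }
  list(maxima = as_df(res$max_idx), minima = as_df(res$min_idx))
}

#' Estimate background noise from clean-chip spectra
#'
#' Robust scale of the baseline: the median over spectra of each spectrum's
#' median absolute intensity, so occasional real peaks in a "clean" region
#' (e.g. ubiquitous background ions) do not inflate the estimate.
#'
#' @param clean_spectra list of `msi_spectrum`, or a numeric matrix with one
#'   spectrum per row.
#' @return Scalar noise level.
#' @export
estimate_noise <- function(clean_spectra) {
  if (is.matrix(clean_spectra)) {
    if (nrow(clean_spectra) == 0) stop("no clean spectra supplied")
    per <- apply(clean_spectra, 1, function(v) median(abs(v)))
  } else {
    if (length(clean_spectra) == 0) stop("no clean spectra supplied")
    per <- vapply(clean_spectra,
                  function(s) median(abs(s$intensity)), 0)
  }
  median(per)
}

#' Pick the retained peaks of one pixel
#'
#' peakdet maxima are thresholded at `noise_factor * noise` (inclusive: a
#' peak at exactly ten times background is kept) and the `top_k` most intense
#' survivors are retained, ties broken toward lower m/z. The reported m/z is
#' the apex sample position (no centroiding).
#'
#' @param spectrum a `msi_spectrum`.
#' @param params a [detection_params()].
#' @param noise background noise level (see [estimate_noise()]).
#' @return Data frame with `mz`, `intensity`, ordered by decreasing
#'   intensity.
#' @export
pick_pixel_peaks <- function(spectrum, params = detection_params(), noise) {
  ex <- detect_extrema(spectrum$intensity, spectrum$mz, params$delta,
                       params$delta_mode)
  pk <- ex$maxima
  pk <- pk[pk$value >= params$noise_factor * noise, , drop = FALSE]
  pk <- pk[order(-pk$value, pk$position), , drop = FALSE]
  pk <- head(pk, params$top_k)
  data.frame(mz = pk$position, intensity = pk$value)
}

#' Does a pixel carry usable signal?
#'
#' A pixel is kept only if at least one peak survived the
#' `noise_factor`-times-background threshold; pixels from the ragged fringe
#' of a dried droplet (or dropout pixels) fail and are excluded from spot
#' quantification entirely. Ubiquitous background ions (enzyme-preparation
#' ions present on every pixel of the chip) do not count as signal, so when
#' a background list is supplied a pixel must carry at least one
#' non-background peak.
#'
#' @param peaks result of [pick_pixel_peaks()].
#' @param background_mz optional background ion list; peaks within `tol` of
#'   a background ion are ignored.
#' @param tol background matching tolerance in Da (default 0.1).
#' @return Logical flag.
#' @export
pixel_passes_signal_filter <- function(peaks, background_mz = numeric(0),
                                       tol = 0.1) {
  if (nrow(peaks) == 0) return(FALSE)
  if (!length(background_mz)) return(TRUE)
  any(vapply(peaks$mz, function(m) all(abs(m - background_mz) > tol), TRUE))
}

#' Pixels carrying non-background signal
#'
#' Vectorized form of [pixel_passes_signal_filter()] over a raster peak
#' table: which pixels have at least one retained peak that is not a
#' background ion.
#'
#' @param peaks raster peak table from [raster_peaks()].
#' @param n_pixels number of raster pixels.
#' @param background_mz background ion list (possibly empty).
#' @param tol background matching tolerance in Da.
#' @return Logical vector of length `n_pixels`.
#' @export
pixels_with_signal <- function(peaks, n_pixels, background_mz = numeric(0),
                               tol = 0.1) {
  keep <- peaks
  if (length(background_mz)) {
    is_bg <- vapply(peaks$mz, function(m) any(abs(m - background_mz) <= tol),
                    TRUE)
    keep <- peaks[!is_bg, , drop = FALSE]
  }
  seq_len(n_pixels) %in% keep$pixel
}

#' Pick peaks for every pixel of a raster
#'
#' Fast path over the whole raster; continuous-mode rasters are processed in
#' compiled code.
#'
#' @param raster a `msi_raster`.
#' @param params a [detection_params()].
#' @param noise background noise level.
#' @return Data frame with `pixel` (row index into `raster$coords`), `x`,
#'   `y`, `mz`, `intensity`.
#' @export
raster_peaks <- function(raster, params = detection_params(), noise) {
  if (raster$mode == "continuous") {
    idx <- .pick_peaks_matrix_cpp(raster$intensity, params$delta,
                                  params$noise_factor * noise, params$top_k,
                                  if (params$delta_mode == "classic") 0L else 1L)
    npk <- lengths(idx)
    px <- rep.int(seq_along(idx), npk)
    j <- unlist(idx) + 1L
    data.frame(pixel = px,
               x = raster$coords$x[px], y = raster$coords$y[px],
               mz = raster$mz[j],
               intensity = raster$intensity[cbind(px, j)])
  } else {
    out <- lapply(seq_len(n_pixels(raster)), function(i) {
      pk <- pick_pixel_peaks(raster$spectra[[i]], params, noise)
      if (nrow(pk) == 0) return(NULL)
      cbind(pixel = i, x = raster$coords$x[i], y = raster$coords$y[i], pk)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
      out <- data.frame(pixel = integer(), x = integer(), y = integer(),
                        mz = numeric(), intensity = numeric())
    out
  }
}

#' Determine background ions from substrate-free controls
#'
#' Peaks pooled from no-substrate control spots and clean chip areas are
#' consolidated within `tol`, and consolidated ions present in at least
#' `min_fraction` of the contributing pixels are reported as background.
#'
#' @param control_peaks data frame of peaks from control pixels with columns
#'   `pixel`, `mz`, `intensity`, or a list of per-pixel peak data frames.
#' @param n_pixels total number of control pixels examined (defaults to the
#'   number of distinct `pixel` values / list elements, which undercounts if
#'   some control pixels yielded no peaks — pass the true count when known).
#' @param tol consolidation tolerance in Da (default 0.1).
#' @param min_fraction minimum fraction of control pixels an ion must appear
#'   in (default 0.25).
#' @return Sorted numeric vector of background ion m/z values.
#' @export
collect_background_ions <- function(control_peaks, n_pixels = NULL,
                                    tol = 0.1, min_fraction = 0.25) {
  if (is.list(control_peaks) && !is.data.frame(control_peaks)) {
    n_pixels <- n_pixels %||% length(control_peaks)
    keep <- lengths(lapply(control_peaks, `[[`, "mz")) > 0
    control_peaks <- do.call(rbind, Map(function(p, i) cbind(pixel = i, p),
                                        control_peaks[keep],
                                        which(keep)))
    if (is.null(control_peaks))
      control_peaks <- data.frame(pixel = integer(), mz = numeric(),
                                  intensity = numeric())
  }
  if (is.null(n_pixels)) n_pixels <- length(unique(control_peaks$pixel))
  if (n_pixels < 1) stop("no control pixels supplied")
  if (nrow(control_peaks) == 0) return(numeric(0))
  bins <- consolidate_bins(control_peaks, tol = tol)
  counts <- vapply(seq_len(nrow(bins)), function(b) {
    members <- abs(control_peaks$mz - bins$seed_mz[b]) <= tol
    length(unique(control_peaks$pixel[members]))
  }, 0L)
  sort(bins$mz[counts / n_pixels >= min_fraction])
}
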