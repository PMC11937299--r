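#' Run the full arrayed-screen analysis on a raster in memory
#'
#' Chains the analysis stages without intermediate files: TIC image, spot
#' localization and refinement, noise estimation from clean chip areas,
#' per-pixel peak picking, background-ion determination from no-substrate
#' control spots plus clean areas, the non-background signal filter, pixel
#' assignment and per-spot quantification.
#'
#' @param raster a `msi_raster`.
#' @param grid a [grid_spec()] describing the printed array.
#' @param design the plate design (used to locate no-substrate control
#'   spots; may be `NULL` when the plate has none).
#' @param substrate a `lig_substrate`.
#' @param params a [detection_params()].
#' @param windows a [category_windows()].
#' @param clean_exclusion_px distance from any spot center beyond which a
#'   pixel counts as clean chip (default: spot radius + 2).
#' @param bg_min_fraction minimum control-pixel fraction for a background
#'   ion (default 0.25).
#' @return List with `spots` (refined centers), `noise`, `peaks`,
#'   `background`, `assignment` and `quant` (per-spot table from
#'   [quantify_spots()]).
#' @export
screen_analysis <- function(raster, grid, design = NULL, substrate,
                            params = detection_params(),
                            windows = category_windows(),
                            clean_exclusion_px = NULL,
                            bg_min_fraction = 0.25) {
  tic <- tic_image(raster)
  centers <- nominal_centers(grid, extent = c(ncol(tic), nrow(tic)))
  spots <- refine_centers(tic, centers, grid$search_radius_px)
  excl <- clean_exclusion_px %||% (grid$spot_radius_px + 2)
  clean <- clean_pixel_indices(raster, spots, excl)
  if (!length(clean)) stop("no clean chip pixels available for noise estimation")
  noise <- if (raster$mode == "continuous")
    estimate_noise(raster$intensity[clean, , drop = FALSE])
  else estimate_noise(raster$spectra[clean])
  peaks <- raster_peaks(raster, params, noise)

  ctrl_px <- clean
  if (!is.null(design) && any(design$is_no_substrate_control)) {
    ns <- design[design$is_no_substrate_control, ]
    cc <- spots[match(paste(ns$row, ns$col),
                      paste(spots$spot_row, spots$spot_col)), ]
    d2 <- outer(raster$coords$x, cc$x, `-`)^2 +
      outer(raster$coords$y, cc$y, `-`)^2
    ctrl_px <- union(which(sqrt(apply(d2, 1, min)) <= grid$spot_radius_px),
                     clean)
  }
  bg <- collect_background_ions(peaks[peaks$pixel %in% ctrl_px, , drop = FALSE],
                                n_pixels = length(ctrl_px),
                                min_fraction = bg_min_fraction)
  pass <- pixels_with_signal(peaks, n_pixels(raster), bg)
  asg <- assign_pixels(raster, spots, grid$spot_radius_px, pass)
  quant <- quantify_spots(peaks, asg, substrate, bg, windows)
  list(spots = spots, noise = noise, peaks = peaks, background = bg,
       assignment = asg, quant = quant)
}

#' Tracked-ion relative abundances per spot
#'
#' Consolidates each spot's peaks into bins and reports the relative
#' abundance of the requested target ions (relative to the summed intensity
#' over the target set), one row per spot and target.
#'
#' @param peaks raster peak table from [raster_peaks()].
#' @param assignment an [assign_pixels()] result.
#' @param targets target m/z values.
#' @param background_mz background ions to remove first.
#' @param tol consolidation/matching tolerance in Da.
#' @return Data frame with `spot_row`, `spot_col`, `target_mz`, `intensity`,
#'   `rel_abundance`.
#' @export
track_spot_ions <- function(peaks, assignment, targets,
                            background_mz = numeric(0), tol = 0.1) {
  peak_spot <- assignment$pixel_spot[peaks$pixel]
  rows <- lapply(seq_len(nrow(assignment$spots)), function(i) {
    spk <- peaks[!is.na(peak_spot) & peak_spot == i, , drop = FALSE]
    bins <- remove_background(consolidate_bins(spk, tol), background_mz, tol)
    ti <- track_ions(bins, targets, tol)
    data.frame(spot_row = assignment$spots$spot_row[i],
               spot_col = assignment$spots$spot_col[i], ti)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
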