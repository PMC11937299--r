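#' Specification of the printed spot grid
#'
#' Dried droplets are printed in an 8 x 12 array with adjacent droplets
#' 1.4 mm apart; imaged at a 125 um raster step the nominal center spacing
#' is 1.4 mm / 125 um = 11.2 pixels.
#'
#' @param rows,cols grid dimensions (defaults 8 x 12).
#' @param pitch_mm center-to-center droplet spacing in mm (default 1.4).
#' @param pixel_um raster step in micrometers (default 125).
#' @param origin pixel coordinates `c(x, y)` of spot (0, 0).
#' @param search_radius_px half-width of the center-refinement window in
#'   pixels; must stay below half the pitch.
#' @param spot_radius_px pixel-inclusion radius around a refined center;
#'   defaults to 0.45 x pitch (just under half-pitch, since overlap between
#'   neighbouring spots is minimal).
#' @return A `grid_spec` list; `pitch_px` is the pitch in pixels.
#' @export
grid_spec <- function(rows = 8, cols = 12, pitch_mm = 1.4, pixel_um = 125,
                      origin = c(8, 8), search_radius_px = 4,
                      spot_radius_px = NULL) {
  pitch_px <- pitch_mm * 1000 / pixel_um
  if (pitch_px < 3)
    stop("pitch must be at least 3 raster steps for spots to be separable")
  spot_radius_px <- spot_radius_px %||% (0.45 * pitch_px)
  if (search_radius_px >= pitch_px / 2)
    stop("search radius must be below half the pitch")
  if (spot_radius_px > pitch_px / 2)
    stop("spot radius must not exceed half the pitch")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pitch_mm = pitch_mm, pixel_um = pixel_um,
                 pitch_px = pitch_px, origin = origin,
                 search_radius_px = search_radius_px,
                 spot_radius_px = spot_radius_px),
            class = "grid_spec")
}

#' Nominal spot centers of a grid
#'
#' @param grid a [grid_spec()].
#' @param extent optional raster extent `c(nx, ny)` in pixels; when given,
#'   centers falling outside it raise an error.
#' @return Data frame with `spot_row`, `spot_col`, `x`, `y` (fractional
#'   pixel coordinates), in row-major spot order.
#' @export
nominal_centers <- function(grid, extent = NULL) {
  g <- expand.grid(spot_col = seq_len(grid$cols) - 1L,
                   spot_row = seq_len(grid$rows) - 1L)
  out <- data.frame(spot_row = g$spot_row, spot_col = g$spot_col,
                    x = grid$origin[1] + g$spot_col * grid$pitch_px,
                    y = grid$origin[2] + g$spot_row * grid$pitch_px)
  if (!is.null(extent) &&
      (any(out$x < 0 | out$x > extent[1] - 1) ||
       any(out$y < 0 | out$y > extent[2] - 1)))
    stop("nominal centers fall outside the raster extent")
  out
}

#' Refine spot centers on the TIC image
#'
#' Each center is moved to the intensity-weighted centroid of the TIC within
#' `search_radius_px` of its current position, iterating until the move is
#' below `tol_px` or `max_iter` iterations. The window's median TIC (the
#' flat contribution of baseline noise and ubiquitous background ions) is
#' subtracted before weighting so the centroid follows the droplet, not the
#' chip. A window with zero total weight leaves the center at its nominal
#' position and flags the spot `empty`.
#'
#' @param tic TIC image from [tic_image()].
#' @param centers nominal centers from [nominal_centers()].
#' @param search_radius_px window radius in pixels.
#' @param max_iter,tol_px convergence controls.
#' @param bg_subtract subtract the window median before weighting (default
#'   `TRUE`).
#' @return `centers` with refined `x`, `y` and a logical `empty` column.
#' @export
refine_centers <- function(tic, centers, search_radius_px = 4,
                           max_iter = 5, tol_px = 0.25, bg_subtract = TRUE) {
  ny <- nrow(tic); nx <- ncol(tic)
  out <- centers
  out$empty <- FALSE
  for (i in seq_len(nrow(centers))) {
    cx <- centers$x[i]; cy <- centers$y[i]
    for (it in seq_len(max_iter)) {
      xs <- max(0, floor(cx - search_radius_px)):min(nx - 1, ceiling(cx + search_radius_px))
      ys <- max(0, floor(cy - search_radius_px)):min(ny - 1, ceiling(cy + search_radius_px))
      g <- expand.grid(x = xs, y = ys)
      g <- g[(g$x - cx)^2 + (g$y - cy)^2 <= search_radius_px^2, , drop = FALSE]
      w <- tic[cbind(g$y + 1L, g$x + 1L)]
      if (bg_subtract) w <- pmax(w - median(w), 0)
      if (sum(w) <= 0) { out$empty[i] <- TRUE; break }
      nxy <- c(sum(g$x * w), sum(g$y * w)) / sum(w)
      moved <- sqrt(sum((nxy - c(cx, cy))^2))
      cx <- nxy[1]; cy <- nxy[2]
      if (moved < tol_px) break
    }
    if (!out$empty[i]) { out$x[i] <- cx; out$y[i] <- cy }
  }
  out
}

#' Assign raster pixels to spots
#'
#' A pixel is assigned to a spot iff it passes the signal filter, lies
#' within `spot_radius_px` of that spot's refined center, and that center is
#' the nearest one (ties broken toward the lower spot index), so assigned
#' pixel sets are pairwise disjoint.
#'
#' @param raster a `msi_raster`.
#' @param centers refined centers from [refine_centers()].
#' @param spot_radius_px inclusion radius in pixels.
#' @param pixel_pass logical vector, one element per raster pixel, from the
#'   10-times-background signal filter (default: all pass).
#' @return List with `spots` (centers plus `n_pixels`) and `pixel_spot`
#'   (integer spot index per raster pixel, `NA` when unassigned).
#' @export
assign_pixels <- function(raster, centers, spot_radius_px,
                          pixel_pass = rep(TRUE, n_pixels(raster))) {
  stopifnot(length(pixel_pass) == n_pixels(raster))
  px <- raster$coords
  n <- nrow(px)
  pixel_spot <- rep(NA_integer_, n)
  cand <- which(pixel_pass)
  if (length(cand)) {
    dx <- outer(px$x[cand], centers$x, `-`)
    dy <- outer(px$y[cand], centers$y, `-`)
    d2 <- dx * dx + dy * dy
    nearest <- max.col(-d2, ties.method = "first")
    dmin2 <- d2[cbind(seq_along(cand), nearest)]
    ok <- dmin2 <= spot_radius_px^2
    pixel_spot[cand[ok]] <- nearest[ok]
  }
  spots <- centers
  names(spots)[names(spots) == "x"] <- "center_x"
  names(spots)[names(spots) == "y"] <- "center_y"
  spots$n_pixels <- tabulate(pixel_spot, nbins = nrow(centers))
  list(spots = spots, pixel_spot = pixel_spot)
}
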