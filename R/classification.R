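#' Category windows for mass-offset classification
#'
#' Detected ions are assigned to one of four categories by their mass offset
#' from the substrate ion S: *unreacted* when within `tol_substrate` of S,
#' *modified* for offsets of -70..-1 or +2..+68 (small gains/losses such as
#' oxygenation), *cleaved* for -502..-71 (loss of at least an aromatic unit)
#' and *polymerized* for +69..+1000 (gain of at least an aromatic unit). All
#' bounds are inclusive and offsets are rounded to the nearest integer
#' (half away from zero) before the window test, so the real-valued gaps
#' between the integer bounds cannot swallow observations. Offsets rounding
#' to 0 or +1 that are not within `tol_substrate` of S, and offsets outside
#' all windows, are *unclassified* and excluded from proportions.
#'
#' Registry ion masses are already the protonated ion \eqn{[M+H]^+}, so the
#' unreacted test is `|mz - S| <= tol_substrate` with no further +1.
#'
#' @param tol_substrate tolerance around the substrate ion (Da, default 0.1).
#' @param modified,cleaved,polymerized inclusive integer offset windows;
#'   `modified` is a 2-row matrix (two disjoint intervals), the others
#'   length-2 vectors.
#' @return A `category_windows` list.
#' @export
category_windows <- function(tol_substrate = 0.1,
                             modified = rbind(c(-70, -1), c(2, 68)),
                             cleaved = c(-502, -71),
                             polymerized = c(69, 1000)) {
  w <- structure(list(tol_substrate = tol_substrate,
                      modified = modified, cleaved = cleaved,
                      polymerized = polymerized),
                 class = "category_windows")
  ivs <- rbind(modified, cleaved, polymerized)
  ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
  if (any(ivs[-1, 1] <= ivs[-nrow(ivs), 2]))
    stop("category windows overlap")
  w
}

#' Classify an observed m/z by its offset from the substrate ion
#'
#' @param mz observed m/z (vectorized).
#' @param substrate_mz the substrate ion m/z S.
#' @param windows a [category_windows()].
#' @return Character vector in `{"unreacted", "modified", "cleaved",
#'   "polymerized", "unclassified"}`.
#' @examples
#' classify_offset(c(1104, 998, 1088, 2173), 1088)
#' @export
classify_offset <- function(mz, substrate_mz, windows = category_windows()) {
  stopifnot(substrate_mz > 0)
  out <- rep("unclassified", length(mz))
  d <- mz - substrate_mz
  out[abs(d) <= windows$tol_substrate] <- "unreacted"
  rest <- out == "unclassified"
  di <- round_half_away(d)
  inw <- function(x, iv) x >= iv[1] & x <= iv[2]
  out[rest & (inw(di, windows$modified[1, ]) | inw(di, windows$modified[2, ]))] <- "modified"
  out[rest & inw(di, windows$cleaved)] <- "cleaved"
  out[rest & inw(di, windows$polymerized)] <- "polymerized"
  out
}

#' Consolidate peaks into +/- tol m/z bins
#'
#' Greedy agglomeration: peaks are visited by decreasing intensity; each
#' peak either joins an existing bin whose *seed* m/z (the m/z of the most
#' intense founding peak) lies within `tol`, or founds a new bin. The
#' reported bin m/z is the intensity-weighted mean of its members and bin
#' intensity is the sum over all member peaks (i.e. across a spot's pixels).
#'
#' @param peaks data frame with columns `mz`, `intensity` (extra columns are
#'   ignored).
#' @param tol half-width of a bin in Da (default 0.1).
#' @return Data frame with `mz`, `seed_mz`, `intensity`, `n_peaks`, ordered
#'   by decreasing intensity, with a `members` attribute listing the peak
#'   row indices of each bin.
#' @export
consolidate_bins <- function(peaks, tol = 0.1) {
  stopifnot(tol > 0)
  empty <- data.frame(mz = numeric(), seed_mz = numeric(),
                      intensity = numeric(), n_peaks = integer())
  if (nrow(peaks) == 0) {
    attr(empty, "members") <- list()
    return(empty)
  }
  ord <- order(-peaks$intensity, peaks$mz)
  seeds <- numeric(0)
  assign_bin <- integer(nrow(peaks))
  for (i in ord) {
    hit <- which(abs(peaks$mz[i] - seeds) <= tol)
    if (length(hit)) {
      assign_bin[i] <- hit[which.min(abs(peaks$mz[i] - seeds[hit]))]
    } else {
      seeds <- c(seeds, peaks$mz[i])
      assign_bin[i] <- length(seeds)
    }
  }
  members <- split(seq_len(nrow(peaks)), assign_bin)
  bmz <- vapply(members, function(m)
    sum(peaks$mz[m] * peaks$intensity[m]) / sum(peaks$intensity[m]), 0)
  bint <- vapply(members, function(m) sum(peaks$intensity[m]), 0)
  out <- data.frame(mz = bmz, seed_mz = seeds[as.integer(names(members))],
                    intensity = bint, n_peaks = lengths(members))
  ord2 <- order(-out$intensity, out$mz)
  out <- out[ord2, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "members") <- unname(members[ord2])
  out
}

#' Remove background-ion bins
#'
#' @param bins output of [consolidate_bins()].
#' @param background_mz numeric vector of background ion m/z values.
#' @param tol removal tolerance in Da (default 0.1).
#' @return `bins` without rows within `tol` of any background ion.
#' @export
remove_background <- function(bins, background_mz, tol = 0.1) {
  if (length(background_mz) == 0 || nrow(bins) == 0) return(bins)
  drop <- vapply(bins$mz, function(m) any(abs(m - background_mz) <= tol), TRUE)
  out <- bins[!drop, , drop = FALSE]
  attr(out, "members") <- attr(bins, "members")[!drop]
  out
}

#' Relative category proportions for one spot
#'
#' Bin intensities are summed within each of the four categories and each
#' category's proportion is its summed intensity divided by the summed
#' intensity of all four categories. Unclassified intensity is reported but
#' excluded from the denominator. A spot with zero classified intensity gets
#' `NA` proportions and an `empty` flag.
#'
#' @param bins output of [consolidate_bins()] (after background removal).
#' @param substrate_mz substrate ion m/z.
#' @param windows a [category_windows()].
#' @return One-row data frame with intensity sums `I_*`, proportions `p_*`,
#'   `I_unclassified` and `empty`.
#' @export
spot_proportions <- function(bins, substrate_mz, windows = category_windows()) {
  cats <- c("unreacted", "modified", "cleaved", "polymerized")
  cl <- if (nrow(bins)) classify_offset(bins$mz, substrate_mz, windows) else character(0)
  I <- vapply(cats, function(k) sum(bins$intensity[cl == k]), 0)
  total <- sum(I)
  p <- if (total > 0) I / total else rep(NA_real_, 4)
  out <- data.frame(t(c(I, p)))
  names(out) <- c(paste0("I_", cats), paste0("p_", cats))
  out$I_unclassified <- sum(bins$intensity[cl == "unclassified"])
  out$empty <- total <= 0
  out
}

#' Relative abundances of tracked ions
#'
#' For time-course analysis: each target ion's matched-bin intensity divided
#' by the total intensity matched to any target.
#'
#' @param bins output of [consolidate_bins()].
#' @param targets distinct target m/z values (separated by more than
#'   `2 * tol`).
#' @param tol matching tolerance in Da (default 0.1).
#' @return Data frame with `target_mz`, `intensity`, `rel_abundance`.
#' @export
track_ions <- function(bins, targets, tol = 0.1) {
  stopifnot(length(targets) >= 1)
  if (length(targets) > 1 && min(diff(sort(targets))) <= 2 * tol)
    stop("tracked ions must be separated by more than 2 * tol")
  I <- vapply(targets, function(t)
    sum(bins$intensity[abs(bins$mz - t) <= tol]), 0)
  total <- sum(I)
  data.frame(target_mz = targets, intensity = I,
             rel_abundance = if (total > 0) I / total else rep(NA_real_, length(I)))
}

#' Quantify every spot of an assigned raster
#'
#' Runs bin consolidation, background removal and category classification
#' per spot and returns the per-spot quantification table. Spots with no
#' passing pixels are retained with `n_pixels = 0` and `NA` proportions so
#' the plate stays rectangular.
#'
#' @param peaks raster peak table from [raster_peaks()].
#' @param assignment a [assign_pixels()] result.
#' @param substrate a `lig_substrate` (or a bare substrate ion m/z).
#' @param background_mz background ion list (possibly empty).
#' @param windows a [category_windows()].
#' @param tol bin consolidation tolerance (default 0.1 Da).
#' @return Data frame with one row per spot: `spot_row`, `spot_col`,
#'   `center_x`, `center_y`, `n_pixels`, intensity sums, proportions,
#'   `I_unclassified`, `empty`.
#' @export
quantify_spots <- function(peaks, assignment, substrate, background_mz = numeric(0),
                           windows = category_windows(), tol = 0.1) {
  S <- if (inherits(substrate, "lig_substrate")) check_ion_mz(substrate) else substrate
  spots <- assignment$spots
  rows <- lapply(seq_len(nrow(spots)), function(i) {
    px <- assignment$pixel_spot == i
    spk <- peaks[peaks$pixel %in% which(px), , drop = FALSE]
    bins <- consolidate_bins(spk, tol = tol)
    bins <- remove_background(bins, background_mz, tol = tol)
    cbind(spots[i, c("spot_row", "spot_col", "center_x", "center_y", "n_pixels")],
          spot_proportions(bins, S, windows))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
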