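#' Simulation configuration for synthetic arrayed rasters
#'
#' Emulates the acquisition geometry of the screen: an arrayed dried-droplet
#' chip printed at 1.4 mm pitch and imaged at a 125 um raster step (11.2
#' pixels between spot centers, about 24 pixels per spot), profile-mode
#' spectra over m/z 200-3500 with Gaussian peaks at the substrate and
#' product masses, ubiquitous enzyme-preparation background ions, additive
#' baseline noise, per-pixel log-normal intensity scaling, dropout pixels
#' and a clean-chip margin band around the array.
#'
#' @param seed integer RNG seed.
#' @param pitch_mm droplet pitch (default 1.4 mm).
#' @param pixel_um raster step (default 125 um).
#' @param mz_range acquisition range in Da (default 200-3500).
#' @param mz_step profile sampling interval in Da (default 0.5; see the
#'   methods vignette for the choice of sampling density).
#' @param peak_sigma Gaussian peak width (SD, Da).
#' @param spot_radius_px_mean,spot_radius_px_jitter droplet radius in pixels:
#'   mean and half-width of its uniform jitter. The default radius of 2.8 px
#'   gives about 24 pixels per spot.
#' @param center_jitter_px half-width of the uniform per-axis jitter of true
#'   spot centers around the nominal grid.
#' @param edge_erosion probability that a boundary pixel of a spot is lost,
#'   mimicking irregular dried-droplet shapes.
#' @param snr ratio of the substrate-peak apex (at proportion 1) to the
#'   baseline noise SD.
#' @param baseline_sd SD of the additive baseline noise.
#' @param background_ions m/z values of enzyme-preparation background ions,
#'   present on every pixel (including no-substrate controls and the clean
#'   margin).
#' @param background_intensity apex intensity of each background ion.
#' @param dropout per-pixel probability of a low-signal (baseline-only)
#'   pixel.
#' @param lognormal_sdlog SD (log scale) of the per-pixel intensity factor
#'   applied to all emitted peaks of a pixel.
#' @param margin_px width of the clean-chip band around the printed array.
#' @param pixels_per_spot_target informational design target.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, pitch_mm = 1.4, pixel_um = 125,
                       mz_range = c(200, 3500), mz_step = 0.5,
                       peak_sigma = 0.35,
                       spot_radius_px_mean = 2.8, spot_radius_px_jitter = 0.3,
                       center_jitter_px = 0.6, edge_erosion = 0.3,
                       snr = 300, baseline_sd = 1,
                       background_ions = c(301.0, 413.5, 522.0),
                       background_intensity = 20,
                       dropout = 0.05, lognormal_sdlog = 0.25,
                       margin_px = 8, pixels_per_spot_target = 24) {
  stopifnot(pitch_mm * 1000 / pixel_um >= 3, snr > 0,
            dropout >= 0, dropout <= 1, edge_erosion >= 0, edge_erosion <= 1,
            mz_step > 0, peak_sigma > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Deterministic plate design for a screen
#'
#' Lays out enzyme x pH x replicate (x optional timepoint) wells on the
#' plate in row-major order, with no-enzyme and no-substrate controls placed
#' last. Reactions are prepared in 96-well plates, so the design errors when
#' the wells exceed the grid capacity.
#'
#' @param enzymes character vector of enzyme labels (may be empty for a
#'   controls-only design).
#' @param pHs pH levels (subset of 3..10).
#' @param substrate substrate name.
#' @param replicates replicates per enzyme x pH (x timepoint).
#' @param n_no_enzyme,n_no_substrate numbers of control wells, cycled over
#'   `pHs`.
#' @param timepoints optional vector of incubation times (minutes).
#' @param rows,cols plate dimensions (default 8 x 12).
#' @return Data frame (`plate_design`) with columns `well`, `row`, `col`,
#'   `enzyme`, `pH`, `substrate`, `replicate`, `timepoint`,
#'   `is_no_enzyme_control`, `is_no_substrate_control`.
#' @export
make_design <- function(enzymes, pHs = 3:10, substrate = "b-b",
                        replicates = 1, n_no_enzyme = 0, n_no_substrate = 0,
                        timepoints = NULL, rows = 8, cols = 12) {
  tps <- timepoints %||% NA_real_
  trt <- if (length(enzymes)) expand.grid(
    replicate = seq_len(replicates), pH = pHs, timepoint = tps,
    enzyme = enzymes, stringsAsFactors = FALSE) else
      data.frame(replicate = integer(), pH = numeric(), timepoint = numeric(),
                 enzyme = character())
  trt$is_no_enzyme_control <- logical(nrow(trt))
  trt$is_no_substrate_control <- logical(nrow(trt))
  ctrl <- function(n, label, ne, ns) {
    if (n == 0) return(NULL)
    data.frame(replicate = seq_len(n), pH = rep_len(pHs, n),
               timepoint = NA_real_, enzyme = label,
               is_no_enzyme_control = ne, is_no_substrate_control = ns)
  }
  wells <- rbind(trt,
                 ctrl(n_no_enzyme, "none", TRUE, FALSE),
                 ctrl(n_no_substrate, "none", FALSE, TRUE))
  n <- nrow(wells)
  if (n > rows * cols)
    stop("design needs ", n, " wells but the plate holds ", rows * cols)
  k <- seq_len(n) - 1L
  out <- data.frame(well = k + 1L, row = k %/% cols, col = k %% cols,
                    enzyme = wells$enzyme, pH = wells$pH,
                    substrate = substrate, replicate = wells$replicate,
                    timepoint = wells$timepoint,
                    is_no_enzyme_control = wells$is_no_enzyme_control,
                    is_no_substrate_control = wells$is_no_substrate_control)
  class(out) <- c("plate_design", "data.frame")
  out
}

#' Draw ground-truth category proportions for each well
#'
#' Each treatment well's true proportions theta = (unreacted, modified,
#' cleaved, polymerized) are drawn from a Dirichlet distribution centered on
#' the activity model's mean with concentration `concentration` (larger =
#' tighter; `Inf` gives the mean exactly). No-enzyme controls are forced to
#' `(1 - leak, leak, 0, 0)`; no-substrate controls have all-`NA` theta
#' (there is nothing to react).
#'
#' @param design a [make_design()] result.
#' @param activity_model function `(enzyme, pH, timepoint) -> length-4
#'   simplex vector`, or a single length-4 vector used for every treatment
#'   well.
#' @param concentration Dirichlet concentration (sum of the shape
#'   parameters).
#' @param seed RNG seed.
#' @param control_leak small "modified" leak proportion for no-enzyme
#'   controls (default 0).
#' @return `design` plus columns `theta_unreacted`, `theta_modified`,
#'   `theta_cleaved`, `theta_polymerized`.
#' @export
draw_proportions <- function(design, activity_model, concentration = 300,
                             seed = 1, control_leak = 0) {
  fmean <- if (is.function(activity_model)) activity_model else
    function(enzyme, pH, timepoint) activity_model
  th <- matrix(NA_real_, nrow(design), 4)
  with_seed(seed, {
    for (i in seq_len(nrow(design))) {
      if (design$is_no_substrate_control[i]) next
      if (design$is_no_enzyme_control[i]) {
        th[i, ] <- c(1 - control_leak, control_leak, 0, 0)
        next
      }
      m <- fmean(design$enzyme[i], design$pH[i], design$timepoint[i])
      if (length(m) != 4 || any(m < 0) || abs(sum(m) - 1) > 1e-8)
        stop("activity model must return a length-4 simplex vector")
      if (is.infinite(concentration)) {
        th[i, ] <- m
      } else {
        g <- rgamma(4, shape = m * concentration)
        if (sum(g) == 0) g <- m
        th[i, ] <- g / sum(g)
      }
    }
  })
  design$theta_unreacted <- th[, 1]
  design$theta_modified <- th[, 2]
  design$theta_cleaved <- th[, 3]
  design$theta_polymerized <- th[, 4]
  design
}

#' Default product-emission menu
#'
#' Which product ions a well actually emits, per category, as offsets from
#' the substrate ion with within-category weights. The default emits a
#' single oxidation (+16) for modified, the lactone cleavage product (-108)
#' for cleaved, and a +162 (one aryl-glycerol unit) coupling product for
#' polymerized.
#'
#' @param modified,cleaved,polymerized named numeric vectors
#'   `c(offset = weight, ...)` or two-column matrices; weights are
#'   normalized within category.
#' @return Function `(well) -> data.frame(category, offset, weight)` usable
#'   as the `product_menu` argument of [render_raster()].
#' @export
static_product_menu <- function(modified = c("16" = 1),
                                cleaved = c("-108" = 1),
                                polymerized = c("162" = 1)) {
  as_menu <- function(x, cat) data.frame(
    category = cat, offset = as.numeric(names(x)),
    weight = as.numeric(x) / sum(x))
  menu <- rbind(as_menu(modified, "modified"),
                as_menu(cleaved, "cleaved"),
                as_menu(polymerized, "polymerized"))
  function(well) menu
}

#' pH-dependent cleaved-product menu for the resinol (b-b') substrate
#'
#' Emulates the lactone/open-acid equilibrium of the cleavage products:
#' basic conditions favour hydrolysis of the lactone (-108, observed at 980
#' m/z) to the hydroxycarboxylic acid (-90, observed at 998 m/z), so the
#' acid's weight increases with pH and the lactone's decreases; the
#' further-oxidized -106 product (982 m/z) keeps a small constant weight.
#'
#' @return A `product_menu` function of the well (uses `well$pH`).
#' @export
ph_shift_product_menu <- function() {
  function(well) {
    w <- c("-90" = well$pH - 2.5, "-108" = 10.5 - well$pH, "-106" = 1.2)
    rbind(data.frame(category = "modified", offset = 16, weight = 1),
          data.frame(category = "cleaved", offset = as.numeric(names(w)),
                     weight = as.numeric(w) / sum(w)),
          data.frame(category = "polymerized", offset = 162, weight = 1))
  }
}

#' Mean proportions for a pH-plateau activity model
#'
#' Total reacted fraction follows a plateau over `active_ph` (and is
#' `baseline` elsewhere); the reacted fraction is split over the three
#' product categories by `split`.
#'
#' @param active_ph pH levels at which the enzyme is active.
#' @param total reacted fraction on the plateau.
#' @param baseline reacted fraction off the plateau.
#' @param split length-3 nonnegative weights for (modified, cleaved,
#'   polymerized).
#' @return An activity-model function for [draw_proportions()].
#' @export
plateau_activity <- function(active_ph, total = 0.75, baseline = 0.02,
                             split = c(2, 2, 1)) {
  split <- split / sum(split)
  function(enzyme, pH, timepoint) {
    r <- if (pH %in% active_ph) total else baseline
    c(1 - r, r * split)
  }
}

#' Sequential first-order time-course proportions
#'
#' Substrate decays at rate `k1` into an oxidized intermediate (modified)
#' which decays at rate `k2` into cleavage products, the qualitative shape
#' of a laccase incubation: substrate falls, the +16 intermediate rises then
#' falls, cleaved accumulates.
#'
#' @param k1,k2 first-order rates (1/min).
#' @return An activity-model function using the well timepoint (minutes).
#' @export
timecourse_activity <- function(k1 = 0.03, k2 = 0.02) {
  function(enzyme, pH, timepoint) {
    t <- if (is.na(timepoint)) 0 else timepoint
    u <- exp(-k1 * t)
    m <- k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
    c(u, m, 1 - u - m, 0)
  }
}

#' Render a synthetic raster for a plate
#'
#' Spots are disks with jittered radius and center and eroded boundaries.
#' Each non-dropout spot pixel emits a Gaussian peak at the substrate ion
#' with apex `snr * baseline_sd * theta_unreacted` and peaks at the menu
#' products with apexes proportional to their category proportion times the
#' within-category weight; all of a pixel's emitted peaks (including the
#' ubiquitous background ions) are scaled by the pixel's log-normal factor.
#' Additive baseline noise (absolute Gaussian) covers every pixel, including
#' the clean-chip margin band.
#'
#' @param truth output of [draw_proportions()].
#' @param substrate a `lig_substrate`.
#' @param config a [sim_config()].
#' @param product_menu a menu function (default [static_product_menu()]).
#' @param grid optional [grid_spec()]; defaults to the plate's dimensions at
#'   the config's geometry.
#' @return List with `raster` (a `msi_raster`), `truth` (with realized
#'   center/radius/pixel counts appended) and `grid`; the per-well emitted
#'   product tables are in `attr(truth, "emitted")` and per-well pixel index
#'   sets in `attr(truth, "pixel_sets")`.
#' @export
render_raster <- function(truth, substrate, config = sim_config(),
                          product_menu = static_product_menu(), grid = NULL) {
  S <- check_ion_mz(substrate)
  grid <- grid %||% grid_spec(rows = max(truth$row) + 1L,
                              cols = max(truth$col) + 1L,
                              pitch_mm = config$pitch_mm,
                              pixel_um = config$pixel_um,
                              origin = rep(config$margin_px +
                                             config$spot_radius_px_mean, 2))
  nx <- as.integer(ceiling(grid$origin[1] + (grid$cols - 1) * grid$pitch_px +
                             grid$origin[1])) + 1L
  ny <- as.integer(ceiling(grid$origin[2] + (grid$rows - 1) * grid$pitch_px +
                             grid$origin[2])) + 1L
  mz <- seq(config$mz_range[1], config$mz_range[2], by = config$mz_step)
  nmz <- length(mz)
  coords <- expand.grid(x = 0:(nx - 1), y = 0:(ny - 1))
  npx <- nrow(coords)
  pix_index <- function(x, y) y * nx + x + 1L  # matches expand.grid order

  centers <- nominal_centers(grid)
  key <- paste(truth$row, truth$col)
  ckey <- paste(centers$spot_row, centers$spot_col)
  centers <- centers[match(key, ckey), ]  # align to well order

  gauss_idx <- function(m0) {
    lo <- max(1L, ceiling((m0 - 5 * config$peak_sigma - mz[1]) / config$mz_step) + 1L)
    hi <- min(nmz, floor((m0 + 5 * config$peak_sigma - mz[1]) / config$mz_step) + 1L)
    if (lo > hi) integer(0) else lo:hi
  }

  out <- with_seed(config$seed, {
    intens <- matrix(abs(rnorm(npx * nmz, sd = config$baseline_sd)), npx, nmz)
    L <- exp(rnorm(npx, sd = config$lognormal_sdlog))
    drop_px <- runif(npx) < config$dropout

    # ubiquitous background ions on every non-dropout pixel
    for (b in config$background_ions) {
      j <- gauss_idx(b)
      if (!length(j)) next
      prof <- config$background_intensity *
        exp(-0.5 * ((mz[j] - b) / config$peak_sigma)^2)
      scale <- ifelse(drop_px, 0, L)
      intens[, j] <- intens[, j] + scale %o% prof
    }

    A <- config$snr * config$baseline_sd
    emitted <- vector("list", nrow(truth))
    pixel_sets <- vector("list", nrow(truth))
    truth$center_x <- truth$center_y <- truth$spot_radius_px <- NA_real_
    truth$n_pixels_emitted <- 0L
    for (i in seq_len(nrow(truth))) {
      cx <- centers$x[i] + runif(1, -config$center_jitter_px, config$center_jitter_px)
      cy <- centers$y[i] + runif(1, -config$center_jitter_px, config$center_jitter_px)
      r <- config$spot_radius_px_mean +
        runif(1, -config$spot_radius_px_jitter, config$spot_radius_px_jitter)
      xs <- floor(cx - r):ceiling(cx + r)
      ys <- floor(cy - r):ceiling(cy + r)
      g <- expand.grid(x = xs, y = ys)
      d <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
      g <- g[d <= r & !(d > r - 1 & runif(nrow(g)) < config$edge_erosion), ]
      g <- g[g$x >= 0 & g$x < nx & g$y >= 0 & g$y < ny, ]
      px <- pix_index(g$x, g$y)
      truth$center_x[i] <- cx; truth$center_y[i] <- cy
      truth$spot_radius_px[i] <- r
      truth$n_pixels_emitted[i] <- length(px)
      pixel_sets[[i]] <- px
      if (truth$is_no_substrate_control[i]) next

      menu <- product_menu(truth[i, ])
      th <- c(unreacted = truth$theta_unreacted[i],
              modified = truth$theta_modified[i],
              cleaved = truth$theta_cleaved[i],
              polymerized = truth$theta_polymerized[i])
      peaks <- rbind(data.frame(category = "unreacted", offset = 0, weight = 1),
                     menu)
      peaks$mz <- S + peaks$offset
      peaks$apex <- A * th[peaks$category] * peaks$weight
      peaks <- peaks[peaks$apex > 0, ]
      emitted[[i]] <- peaks
      live <- px[!drop_px[px]]
      if (!length(live) || !nrow(peaks)) next
      for (k in seq_len(nrow(peaks))) {
        j <- gauss_idx(peaks$mz[k])
        if (!length(j)) next
        prof <- peaks$apex[k] * exp(-0.5 * ((mz[j] - peaks$mz[k]) / config$peak_sigma)^2)
        intens[live, j] <- intens[live, j] + L[live] %o% prof
      }
    }
    list(intens = intens, truth = truth, emitted = emitted,
         pixel_sets = pixel_sets)
  })

  raster <- msi_raster(mz = mz, intensity = out$intens, coords = coords,
                       pixel_um = config$pixel_um,
                       metadata = list(generator = "lignims synthetic",
                                       seed = config$seed,
                                       substrate = substrate$name))
  truth <- out$truth
  attr(truth, "emitted") <- out$emitted
  attr(truth, "pixel_sets") <- out$pixel_sets
  list(raster = raster, truth = truth, grid = grid)
}

#' Indices of clean-chip margin pixels
#'
#' Pixels farther than `exclusion_radius_px` from every spot center, used to
#' estimate baseline noise from clean areas of the chip.
#'
#' @param raster a `msi_raster`.
#' @param centers data frame with spot centers `x`, `y` (nominal or
#'   refined).
#' @param exclusion_radius_px keep pixels at least this far from any center.
#' @return Integer vector of pixel indices.
#' @export
clean_pixel_indices <- function(raster, centers, exclusion_radius_px = 5) {
  d2 <- outer(raster$coords$x, centers$x, `-`)^2 +
    outer(raster$coords$y, centers$y, `-`)^2
  which(sqrt(apply(d2, 1, min)) > exclusion_radius_px)
}
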