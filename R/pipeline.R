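#' Default pipeline configuration
#'
#' A nested list mirroring the CLI config file (YAML). Sections: `paths`
#' (output directory), `design` (plate layout for simulation), `activity`
#' (mean proportions for simulated treatments), `sim` (overrides for
#' [sim_config()]), `grid` (overrides for [grid_spec()]), `detection`
#' (overrides for [detection_params()]), `substrate` (`name`, optional
#' `b_O_4_mz` or `registry_file`), `stats` (`f`, `alpha`) and `seed`.
#'
#' @return The default configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    paths = list(outdir = "lignims-run"),
    substrate = list(name = "b-b", b_O_4_mz = NULL, registry_file = NULL),
    design = list(enzymes = c("enzymeA", "enzymeB"), pHs = 3:10,
                  replicates = 5, n_no_enzyme = 8, n_no_substrate = 8),
    activity = list(type = "uniform",
                    mean = c(0.40, 0.25, 0.23, 0.12),
                    active_ph = 5:8, total = 0.75, split = c(2, 2, 1),
                    concentration = 300),
    sim = list(),
    grid = list(),
    detection = list(),
    stats = list(f = 0.5, alpha = 0.05))
}

#' Read a pipeline configuration file
#'
#' Values in the YAML file override the defaults of
#' [default_pipeline_config()].
#'
#' @param path YAML file path.
#' @return Configuration list with a `config_hash` attribute.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  utils::modifyList(default_pipeline_config(), user)
}

# Hash of the analysis-relevant configuration (paths excluded, so the same
# analysis written to two directories carries the same fingerprint).
config_hash <- function(config) {
  cfg <- config
  cfg$paths <- NULL
  attributes(cfg)[setdiff(names(attributes(cfg)), "names")] <- NULL
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(cfg, tf)
  unname(tools::md5sum(tf))
}

stage_header <- function(config) {
  sprintf("# lignims %s\tconfig=%s\tseed=%s",
          as.character(packageVersion("lignims")),
          config_hash(config), config$seed)
}

write_stage_table <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stage_header(config), con)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_stage_table <- function(path, stage) {
  if (!file.exists(path))
    stop("missing output of stage '", stage, "'; run it first")
  read.delim(path, comment.char = "#")
}

read_stage_raster <- function(path) {
  if (!dir.exists(path))
    stop("missing output of stage 'simulate'; run it first")
  read_raster(path)
}

cfg_substrate <- function(config) {
  reg <- if (!is.null(config$substrate$registry_file))
    read_substrate_registry(config$substrate$registry_file)
  else lig_substrates(b_O_4_mz = config$substrate$b_O_4_mz)
  s <- reg[[config$substrate$name]]
  if (is.null(s)) stop("unknown substrate: ", config$substrate$name)
  s
}

cfg_sim <- function(config) {
  do.call(sim_config, utils::modifyList(list(seed = config$seed), config$sim))
}

cfg_grid <- function(config, sim) {
  defaults <- list(origin = rep(sim$margin_px + sim$spot_radius_px_mean, 2),
                   pitch_mm = sim$pitch_mm, pixel_um = sim$pixel_um)
  do.call(grid_spec, utils::modifyList(defaults, config$grid))
}

cfg_detection <- function(config) {
  do.call(detection_params, config$detection)
}

cfg_activity <- function(config) {
  a <- config$activity
  if (a$type == "plateau")
    plateau_activity(a$active_ph, a$total, split = a$split)
  else function(enzyme, pH, timepoint) a$mean
}

#' Run one pipeline stage
#'
#' Stages in order: `simulate`, `detect-spots`, `pick-peaks`, `classify`,
#' `quantify`, `stats`, `report`. Each stage reads the previous stage's
#' tab-delimited tables from the output directory, writes its own and logs
#' pixel/peak/spot counts. Every output carries a header line with the
#' package version, config hash and seed, so a rerun with identical config
#' and seed is byte-identical.
#'
#' @param stage stage name.
#' @param config configuration list (see [default_pipeline_config()]).
#' @param quiet suppress log messages.
#' @return Invisibly, the path(s) written.
#' @export
run_stage <- function(stage, config = default_pipeline_config(),
                      quiet = FALSE) {
  stage <- match.arg(stage, c("simulate", "detect-spots", "pick-peaks",
                              "classify", "quantify", "stats", "report"))
  out <- config$paths$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (!quiet) message("[", stage, "] ", ...)
  p <- function(f) file.path(out, f)
  switch(stage,
    "simulate" = {
      d <- config$design
      sim0 <- cfg_sim(config)
      g0 <- cfg_grid(config, sim0)
      design <- make_design(d$enzymes, d$pHs, config$substrate$name,
                            d$replicates, d$n_no_enzyme, d$n_no_substrate,
                            rows = g0$rows, cols = g0$cols)
      truth <- draw_proportions(design, cfg_activity(config),
                                concentration = config$activity$concentration,
                                seed = config$seed)
      sim <- cfg_sim(config)
      r <- render_raster(truth, cfg_substrate(config), sim,
                         grid = cfg_grid(config, sim))
      write_raster(r$raster, p("raster"))
      write_stage_table(r$truth, p("truth.tsv"), config)
      write_stage_table(design, p("design.tsv"), config)
      log(nrow(design), " wells, ", n_pixels(r$raster), " pixels rendered")
      invisible(p("raster"))
    },
    "detect-spots" = {
      raster <- read_stage_raster(p("raster"))
      sim <- cfg_sim(config)
      grid <- cfg_grid(config, sim)
      tic <- tic_image(raster)
      centers <- nominal_centers(grid, extent = c(ncol(tic), nrow(tic)))
      refined <- refine_centers(tic, centers, grid$search_radius_px)
      log(nrow(refined), " centers refined, ", sum(refined$empty), " empty")
      write_stage_table(refined, p("spots.tsv"), config)
    },
    "pick-peaks" = {
      spots <- read_stage_table(p("spots.tsv"), "detect-spots")
      raster <- read_stage_raster(p("raster"))
      params <- cfg_detection(config)
      sim <- cfg_sim(config)
      clean <- clean_pixel_indices(raster, spots,
                                   exclusion_radius_px =
                                     cfg_grid(config, sim)$spot_radius_px + 2)
      noise <- estimate_noise(raster$intensity[clean, , drop = FALSE])
      peaks <- raster_peaks(raster, params, noise)
      log(length(clean), " clean pixels, noise = ", signif(noise, 4),
          "; ", nrow(peaks), " peaks on ", length(unique(peaks$pixel)),
          " of ", n_pixels(raster), " pixels")
      # background ions from no-substrate control spots and clean areas
      design <- read_stage_table(p("design.tsv"), "simulate")
      ns <- design[design$is_no_substrate_control, ]
      grid <- cfg_grid(config, sim)
      ctrl_centers <- spots[match(paste(ns$row, ns$col),
                                  paste(spots$spot_row, spots$spot_col)), ]
      ctrl_px <- integer(0)
      if (nrow(ctrl_centers)) {
        d2 <- outer(raster$coords$x, ctrl_centers$x, `-`)^2 +
          outer(raster$coords$y, ctrl_centers$y, `-`)^2
        ctrl_px <- which(sqrt(apply(d2, 1, min)) <= grid$spot_radius_px)
      }
      ctrl_px <- union(ctrl_px, clean)
      bg_src <- peaks[peaks$pixel %in% ctrl_px, , drop = FALSE]
      bg <- collect_background_ions(bg_src, n_pixels = length(ctrl_px))
      log(length(bg), " background ions")
      write_stage_table(peaks, p("peaks.tsv"), config)
      writeLines(c(stage_header(config), format(bg, digits = 10)),
                 p("background_ions.txt"))
      writeLines(c(stage_header(config), format(noise, digits = 10)),
                 p("noise.txt"))
      invisible(p("peaks.tsv"))
    },
    "classify" = {
      peaks <- read_stage_table(p("peaks.tsv"), "pick-peaks")
      spots <- read_stage_table(p("spots.tsv"), "detect-spots")
      raster <- read_stage_raster(p("raster"))
      bg <- as.numeric(readLines(p("background_ions.txt"))[-1])
      sim <- cfg_sim(config)
      grid <- cfg_grid(config, sim)
      pass <- pixels_with_signal(peaks, n_pixels(raster), bg)
      asg <- assign_pixels(raster, spots, grid$spot_radius_px, pass)
      S <- check_ion_mz(cfg_substrate(config))
      peak_spot <- asg$pixel_spot[peaks$pixel]
      rows <- lapply(seq_len(nrow(asg$spots)), function(i) {
        spk <- peaks[!is.na(peak_spot) & peak_spot == i, , drop = FALSE]
        bins <- remove_background(consolidate_bins(spk), bg)
        if (nrow(bins) == 0) return(NULL)
        data.frame(spot_row = asg$spots$spot_row[i],
                   spot_col = asg$spots$spot_col[i],
                   mz = bins$mz, intensity = bins$intensity,
                   n_peaks = bins$n_peaks,
                   category = classify_offset(bins$mz, S))
      })
      bins <- do.call(rbind, rows)
      log(nrow(bins), " bins across ", length(unique(paste(
        bins$spot_row, bins$spot_col))), " spots")
      write_stage_table(bins, p("bins.tsv"), config)
      write_stage_table(asg$spots, p("assignment.tsv"), config)
    },
    "quantify" = {
      bins <- read_stage_table(p("bins.tsv"), "classify")
      asg <- read_stage_table(p("assignment.tsv"), "classify")
      cats <- c("unreacted", "modified", "cleaved", "polymerized")
      rows <- lapply(seq_len(nrow(asg)), function(i) {
        b <- bins[bins$spot_row == asg$spot_row[i] &
                    bins$spot_col == asg$spot_col[i], ]
        I <- vapply(cats, function(k) sum(b$intensity[b$category == k]), 0)
        tot <- sum(I)
        q <- data.frame(spot_row = asg$spot_row[i], spot_col = asg$spot_col[i],
                        center_x = asg$center_x[i], center_y = asg$center_y[i],
                        n_pixels = asg$n_pixels[i])
        for (k in cats) q[[paste0("I_", k)]] <- I[[k]]
        for (k in cats) q[[paste0("p_", k)]] <-
          if (tot > 0) I[[k]] / tot else NA_real_
        q$I_unclassified <- sum(b$intensity[b$category == "unclassified"])
        q$empty <- tot <= 0
        q
      })
      quant <- do.call(rbind, rows)
      log(sum(!quant$empty), " quantified spots, ", sum(quant$empty), " empty")
      write_stage_table(quant, p("spotquant.tsv"), config)
    },
    "stats" = {
      quant <- read_stage_table(p("spotquant.tsv"), "quantify")
      design <- read_stage_table(p("design.tsv"), "simulate")
      summ <- aggregate_conditions(quant, design)
      write_stage_table(summ, p("condition_summary.tsv"), config)
      dn <- dunnett_by_category(quant, design)
      write_stage_table(dn, p("dunnett.tsv"), config)
      tr <- dn[dn$category == "total_reacted" & !dn$skipped, ]
      ranges <- lapply(split(tr, tr$enzyme), function(d) {
        s <- summ[summ$enzyme == d$enzyme[1] & !summ$is_no_enzyme_control, ]
        s <- s[match(d$pH, s$pH), ]
        rng <- ph_activity_range(d$pH, s$mean_total_reacted, d$p_adjusted,
                                 f = config$stats$f, alpha = config$stats$alpha)
        data.frame(enzyme = d$enzyme[1], range = rng$label,
                   ph_min = rng$ph_min, ph_max = rng$ph_max)
      })
      ranges <- do.call(rbind, ranges)
      rownames(ranges) <- NULL
      log(nrow(ranges), " pH ranges called")
      write_stage_table(ranges, p("ph_ranges.tsv"), config)
    },
    "report" = {
      summ <- read_stage_table(p("condition_summary.tsv"), "stats")
      quant <- read_stage_table(p("spotquant.tsv"), "quantify")
      write_stage_table(fig_matrix(summ), p("fig_matrix.tsv"), config)
      lines <- c(stage_header(config),
                 sprintf("spots: %d (%d quantified, %d empty)",
                         nrow(quant), sum(!quant$empty), sum(quant$empty)),
                 sprintf("mean pixels per spot: %.1f", mean(quant$n_pixels)),
                 sprintf("conditions: %d", nrow(summ)))
      writeLines(lines, p("summary.txt"))
      log("report written")
      invisible(p("summary.txt"))
    })
}

#' Run the full pipeline
#'
#' @param config configuration list.
#' @param stages stages to run, in order.
#' @param quiet suppress log messages.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         stages = c("simulate", "detect-spots", "pick-peaks",
                                    "classify", "quantify", "stats", "report"),
                         quiet = FALSE) {
  for (s in stages) run_stage(s, config, quiet = quiet)
  invisible(config$paths$outdir)
}
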