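test_that("make_design lays out wells deterministically with controls last", {
  d <- make_design("lacc", pHs = 3:10, replicates = 3, n_no_enzyme = 8)
  expect_equal(nrow(d), 32)
  expect_true(all(tail(d$is_no_enzyme_control, 8)))
  expect_false(any(head(d$is_no_enzyme_control, 24)))
  expect_equal(anyDuplicated(d[c("row", "col")]), 0)
  # capacity: 10 enzymes x 8 pH x 1 rep = 80 fits, plus 20 controls does not
  expect_equal(nrow(make_design(paste0("e", 1:10), 3:10)), 80)
  expect_error(make_design(paste0("e", 1:10), 3:10, n_no_enzyme = 10,
                           n_no_substrate = 10), "96")
  # controls-only design
  d0 <- make_design(character(0), n_no_enzyme = 4)
  expect_equal(nrow(d0), 4)
  expect_true(all(d0$is_no_enzyme_control))
})

test_that("draw_proportions respects controls, dispersion and the simplex", {
  d <- make_design("lacc", pHs = 5, replicates = 3, n_no_enzyme = 2,
                   n_no_substrate = 1, rows = 1, cols = 6)
  m <- c(0.4, 0.3, 0.2, 0.1)
  # infinite concentration collapses to the mean
  tr <- draw_proportions(d, m, concentration = Inf, seed = 1)
  expect_equal(unlist(tr[1, paste0("theta_", c("unreacted", "modified",
                                               "cleaved", "polymerized"))],
                      use.names = FALSE), m)
  # no-enzyme controls are pure substrate (leak 0)
  ne <- tr[tr$is_no_enzyme_control, ]
  expect_equal(ne$theta_unreacted, rep(1, 2))
  expect_equal(ne$theta_cleaved, rep(0, 2))
  # no-substrate controls have nothing to react
  expect_true(all(is.na(tr$theta_unreacted[tr$is_no_substrate_control])))
  # finite concentration: valid simplex, reproducible under the seed
  tr2 <- draw_proportions(d, m, concentration = 50, seed = 9)
  th <- as.matrix(tr2[1:3, grep("^theta_", names(tr2))])
  expect_true(all(th >= 0))
  expect_equal(unname(rowSums(th)), rep(1, 3))
  expect_equal(draw_proportions(d, m, concentration = 50, seed = 9), tr2)
  expect_error(draw_proportions(d, c(0.5, 0.5, 0.5, -0.5), seed = 1),
               "simplex")
})

test_that("Dirichlet draws are centred on the mean (law of large numbers)", {
  d <- make_design("e", pHs = rep(5, 1), replicates = 96, rows = 8, cols = 12)
  means <- colMeans(do.call(rbind, lapply(1:11, function(i) {
    tr <- draw_proportions(d, c(0.25, 0.25, 0.25, 0.25),
                           concentration = 20, seed = i)
    as.matrix(tr[, grep("^theta_", names(tr))])
  })))  # 1056 draws
  expect_true(all(abs(means - 0.25) <= 0.02))
})

test_that("rendering is reproducible and respects the geometry contract", {
  fx1 <- small_screen_inputs(seed = 13)
  fx2 <- small_screen_inputs(seed = 13)
  expect_identical(fx1$raster$intensity, fx2$raster$intensity)
  expect_identical(fx1$truth$center_x, fx2$truth$center_x)
  # realized centers within the configured jitter of the nominal grid
  cen <- nominal_centers(fx1$grid)
  key <- paste(fx1$truth$row, fx1$truth$col)
  cen <- cen[match(key, paste(cen$spot_row, cen$spot_col)), ]
  expect_true(all(abs(fx1$truth$center_x - cen$x) <=
                    fx1$config$center_jitter_px + 1e-9))
  expect_true(all(abs(fx1$truth$center_y - cen$y) <=
                    fx1$config$center_jitter_px + 1e-9))
  # every spot emits pixels
  expect_true(all(fx1$truth$n_pixels_emitted >= 10))
})

test_that("noise-free rendering conserves category intensity ratios", {
  reg <- lig_substrates()
  d <- make_design("e", pHs = 5, replicates = 4, rows = 1, cols = 4)
  theta <- c(0.4, 0.3, 0.2, 0.1)
  tr <- draw_proportions(d, theta, concentration = Inf, seed = 2)
  cfg <- sim_config(seed = 2, mz_range = c(900, 1300), snr = 1e8,
                    baseline_sd = 1, dropout = 0, edge_erosion = 0,
                    background_ions = numeric(0))
  r <- render_raster(tr, reg[["b-b"]], cfg)
  mzs <- c(1088, 1104, 980, 1250)  # substrate, +16, -108, +162
  idx <- vapply(mzs, function(m) which.min(abs(r$raster$mz - m)), 0L)
  sets <- attr(r$truth, "pixel_sets")
  for (w in 1:4) {
    apexes <- colSums(r$raster$intensity[sets[[w]], idx, drop = FALSE])
    expect_equal(apexes / sum(apexes), theta, tolerance = 1e-6)
  }
})

test_that("degenerate wells render as specified", {
  reg <- lig_substrates()
  d <- make_design("e", pHs = 5, replicates = 1, n_no_substrate = 1,
                   rows = 1, cols = 2)
  tr <- draw_proportions(d, c(1, 0, 0, 0), concentration = Inf, seed = 4)
  cfg <- sim_config(seed = 4, mz_range = c(900, 1300), snr = 1e6,
                    dropout = 0, background_ions = numeric(0))
  r <- render_raster(tr, reg[["b-b"]], cfg)
  sets <- attr(r$truth, "pixel_sets")
  # pure-substrate well: the global maximum of every spot pixel is the
  # substrate ion sample
  imax <- apply(r$raster$intensity[sets[[1]], ], 1, which.max)
  expect_true(all(abs(r$raster$mz[imax] - 1088) < 1e-9))
  # no-substrate control: only baseline noise (no background ions here)
  expect_lt(max(r$raster$intensity[sets[[2]], ]), 10)
})

test_that("no-substrate wells carry only background ions over the baseline", {
  fx <- small_screen_inputs(seed = 21)
  sets <- attr(fx$truth, "pixel_sets")
  ns <- which(fx$truth$is_no_substrate_control)
  px <- unlist(sets[ns])
  m <- fx$raster$intensity[px, , drop = FALSE]
  far_from_bg <- vapply(fx$raster$mz, function(z)
    all(abs(z - fx$config$background_ions) > 3 * fx$config$peak_sigma), TRUE)
  # away from the background ions nothing exceeds plausible baseline noise
  expect_lt(max(m[, far_from_bg]), 10 * fx$config$baseline_sd)
  # at the background ions the configured apex is visible on most pixels
  bgcol <- which.min(abs(fx$raster$mz - fx$config$background_ions[1]))
  expect_gt(median(m[, bgcol]), 5)
})
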