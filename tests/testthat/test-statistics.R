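mk_quant <- function(design, p) {
  # minimal quant table matching a design, given a matrix of proportions
  data.frame(spot_row = design$row, spot_col = design$col,
             center_x = 0, center_y = 0, n_pixels = 20,
             I_unreacted = p[, 1] * 100, I_modified = p[, 2] * 100,
             I_cleaved = p[, 3] * 100, I_polymerized = p[, 4] * 100,
             p_unreacted = p[, 1], p_modified = p[, 2],
             p_cleaved = p[, 3], p_polymerized = p[, 4],
             I_unclassified = 0, empty = FALSE)
}

test_that("condition aggregation computes replicate mean, SD and n", {
  d <- make_design("e", pHs = 5, replicates = 2, rows = 1, cols = 2)
  p <- rbind(c(0.8, 0.2, 0, 0), c(0.6, 0.4, 0, 0))
  s <- aggregate_conditions(mk_quant(d, p), d)
  expect_equal(s$mean_p_modified, 0.3)
  expect_equal(s$sd_p_modified, sd(c(0.2, 0.4)))
  expect_equal(s$sd_p_modified, 0.1414, tolerance = 1e-3)
  expect_equal(s$n, 2)
  expect_equal(s$mean_total_reacted, 1 - s$mean_p_unreacted)
  # single replicate: SD undefined
  d1 <- make_design("e", pHs = 5, replicates = 1, rows = 1, cols = 1)
  s1 <- aggregate_conditions(mk_quant(d1, p[1, , drop = FALSE]), d1)
  expect_true(is.na(s1$sd_p_modified))
  expect_equal(s1$n, 1)
  # empty spots drop out of n and flag the condition when none remain
  q <- mk_quant(d, p); q$empty <- TRUE
  q[paste0("p_", c("unreacted", "modified", "cleaved", "polymerized"))] <- NA
  s0 <- aggregate_conditions(q, d)
  expect_true(s0$flagged)
  expect_equal(s0$n, 0)
})

test_that("condition means recover the truth on the reference screen", {
  fx <- default_screen()
  s <- aggregate_conditions(fx$res$quant, fx$design)
  trt <- s[!s$is_no_enzyme_control & !s$is_no_substrate_control, ]
  expect_true(all(trt$n >= 4))
  # estimation error: condition means track the realized per-condition truth
  m <- merge(fx$truth, fx$res$quant, by.x = c("row", "col"),
             by.y = c("spot_row", "spot_col"))
  m <- m[!m$is_no_substrate_control & !m$is_no_enzyme_control, ]
  agg <- aggregate(cbind(theta_unreacted, theta_cleaved) ~ enzyme + pH,
                   m, mean)
  agg <- agg[match(paste(trt$enzyme, trt$pH),
                   paste(agg$enzyme, agg$pH)), ]
  expect_true(all(abs(trt$mean_p_unreacted - agg$theta_unreacted) <= 0.01))
  expect_true(all(abs(trt$mean_p_cleaved - agg$theta_cleaved) <= 0.01))
  # sampling noise: replicate means stay within 4 SE of the design means
  # (SE = sqrt(p (1 - p) / (conc + 1) / n) ~ 0.0126 for p = 0.4, n = 5)
  expect_true(all(abs(trt$mean_p_unreacted - 0.40) <= 0.05))
  expect_true(all(abs(trt$mean_p_cleaved - 0.23) <= 0.05))
})

test_that("dunnett statistics match the textbook pooled-t construction", {
  set.seed(31)
  ctrl <- rnorm(5)
  grp <- list(a = rnorm(4) + 1, b = rnorm(6) - 0.2)
  res <- dunnett_one_sided(ctrl, grp)
  sp2 <- (sum((ctrl - mean(ctrl))^2) + sum((grp$a - mean(grp$a))^2) +
            sum((grp$b - mean(grp$b))^2)) / (5 + 4 + 6 - 3)
  t_a <- (mean(grp$a) - mean(ctrl)) / sqrt(sp2 * (1 / 4 + 1 / 5))
  expect_equal(res$t[1], t_a)
  expect_equal(attr(res, "df"), 12)
  # adjusted p bounded by the unadjusted p and the Bonferroni bound
  expect_true(all(res$p_adjusted >= res$p_unadjusted))
  expect_true(all(res$p_adjusted <= pmin(1, 2 * res$p_unadjusted) + 1e-6))
})

test_that("k = 1 reduces exactly to the one-sided pooled t test", {
  set.seed(12)
  ctrl <- rnorm(4); g <- rnorm(4) + 0.8
  res <- dunnett_one_sided(ctrl, list(g))
  tt <- t.test(g, ctrl, alternative = "greater", var.equal = TRUE)
  expect_equal(res$p_adjusted, tt$p.value, tolerance = 1e-3)
  expect_equal(res$p_unadjusted, tt$p.value, tolerance = 1e-12)
})

test_that("quadrature and mvtnorm routes agree", {
  set.seed(77)
  ctrl <- rnorm(4)
  grp <- lapply(c(0, 0.5, 1, 1.5, 2, 3), function(s) rnorm(4) + s)
  a <- dunnett_one_sided(ctrl, grp, method = "quadrature")
  b <- dunnett_one_sided(ctrl, grp, method = "mvt", seed = 5)
  expect_equal(a$p_adjusted, b$p_adjusted, tolerance = 2e-3)
  # and against multcomp's independent implementation
  skip_if_not_installed("multcomp")
  dat <- data.frame(y = c(ctrl, unlist(grp)),
                    g = factor(rep(0:6, each = 4)))
  mc <- multcomp::glht(stats::aov(y ~ g, dat),
                       linfct = multcomp::mcp(g = "Dunnett"),
                       alternative = "greater")
  pmc <- summary(mc)$test$pvalues
  expect_equal(a$p_adjusted, as.numeric(pmc), tolerance = 5e-3)
})

test_that("degenerate and directional cases behave as documented", {
  # all observations identical: p = 1 everywhere
  res <- dunnett_one_sided(rep(2, 3), list(rep(2, 3), rep(2, 4)))
  expect_equal(res$p_adjusted, c(1, 1))
  # zero variance with unequal means is an error
  expect_error(dunnett_one_sided(rep(2, 3), list(rep(3, 3))), "variance")
  # adjusted p is monotone nonincreasing in the simulated shift
  set.seed(55)
  ctrl <- rnorm(6)
  base <- rnorm(6)
  shifts <- seq(0, 2, by = 0.5)
  ps <- vapply(shifts, function(s)
    dunnett_one_sided(ctrl, list(base + s))$p_adjusted, 0)
  expect_true(all(diff(ps) <= 1e-12))
  # Welch variant runs and stays in [0, 1]
  rw <- dunnett_one_sided(rnorm(5), list(rnorm(3, sd = 3), rnorm(8, sd = 0.3)),
                          variance = "welch")
  expect_true(all(rw$p_adjusted >= 0 & rw$p_adjusted <= 1))
})

test_that("pH activity ranges follow the max-activity rule", {
  ph <- 3:8
  tr <- c(0, 0, 0.8, 0.9, 0.7, 0)
  p <- c(1, 1, 0.001, 0.001, 0.001, 1)
  rng <- ph_activity_range(ph, tr, p)
  expect_equal(rng$label, "5-7")
  expect_equal(rng$levels, 5:7)
  # nothing significant -> N.D.
  expect_equal(ph_activity_range(ph, tr, rep(1, 6))$label, "N.D.")
  # the run must contain the argmax: a disjoint significant level is ignored
  tr2 <- c(0.5, 0, 0.9, 0.9, 0, 0)
  p2 <- c(0.001, 1, 0.001, 0.001, 1, 1)
  expect_equal(ph_activity_range(ph, tr2, p2)$label, "5-6")
  # single qualifying level prints as that level
  expect_equal(ph_activity_range(
    c(4, 5), c(0.1, 0.9), c(1, 0.01))$label, "5")
  # invariant to uniform rescaling of the activity values
  expect_equal(ph_activity_range(ph, tr * 7, p)$label, "5-7")
})

test_that("product-pH correlations detect direction and degeneracy", {
  ph <- rep(3:10, each = 2)
  a <- 10 - 0.5 * ph
  b <- 2 + 0.5 * ph
  res <- product_ph_correlation(ph, cbind(`980` = a, `998` = b))
  expect_equal(res$r[res$product == "980"], -1)
  expect_equal(res$r[res$product == "998"], 1)
  # constant shares: undefined, flagged
  res2 <- product_ph_correlation(ph, cbind(`980` = rep(1, 16),
                                           `998` = rep(1, 16)))
  expect_true(all(res2$flagged))
  expect_error(product_ph_correlation(c(3, 4), cbind(a = c(1, 2))), ">= 3")
})

test_that("time-course summaries average replicates per ion and timepoint", {
  tracked <- data.frame(target_mz = rep(c(1088, 1104), each = 4),
                        timepoint = rep(c(0, 30), 4),
                        replicate = rep(1:2, each = 2),
                        rel_abundance = c(1, 0.5, 1, 0.7, 0, 0.5, 0, 0.3))
  s <- timecourse_summary(tracked)
  expect_equal(s$mean[s$target_mz == 1088 & s$timepoint == 0], 1)
  expect_equal(s$mean[s$target_mz == 1088 & s$timepoint == 30], 0.6)
  expect_equal(s$n, rep(2, 4))
  one <- tracked[tracked$replicate == 1 & tracked$target_mz == 1088, ]
  expect_true(all(is.na(timecourse_summary(one)$sd)))
  expect_error(timecourse_summary(tracked[tracked$timepoint == 0, ]),
               "two timepoints")
})

test_that("tracked ions recover a configured kinetic crossing", {
  reg <- lig_substrates()
  tps <- c(0, 15, 30, 45, 60, 90)
  d <- make_design("lacc", pHs = 5, replicates = 2, timepoints = tps,
                   rows = 2, cols = 6)
  tr <- draw_proportions(d, timecourse_activity(k1 = 0.03, k2 = 0.02),
                         concentration = 2000, seed = 17)
  cfg <- sim_config(seed = 17, mz_range = c(900, 1300))
  r <- render_raster(tr, reg[["b-b"]], cfg)
  res <- screen_analysis(r$raster, r$grid, d, reg[["b-b"]])
  tracked <- track_spot_ions(res$peaks, res$assignment, c(1088, 1104, 980),
                             res$background)
  m <- merge(d, tracked, by.x = c("row", "col"),
             by.y = c("spot_row", "spot_col"))
  m$replicate <- m$replicate
  s <- timecourse_summary(m[, c("target_mz", "timepoint", "replicate",
                                "rel_abundance")])
  # substrate is everything at t = 0
  expect_gt(s$mean[s$target_mz == 1088 & s$timepoint == 0], 0.95)
  # the +16 intermediate peaks at ln(k1/k2)/(k1-k2) ~ 40.5 min:
  # its argmax lands within one timepoint
  inter <- s[s$target_mz == 1104, ]
  expect_true(inter$timepoint[which.max(inter$mean)] %in% c(30, 45, 60))
  # cleaved increases monotonically on average
  clv <- s[s$target_mz == 980, ]
  expect_gt(clv$mean[clv$timepoint == 90], clv$mean[clv$timepoint == 0])
})
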