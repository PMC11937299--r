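test_that("classify_offset agrees with brute-force window membership", {
  S <- 1088
  d <- -600:1200
  expect_equal(classify_offset(S + d, S),
               vapply(d, ref_category, ""))
})

test_that("reported pathway ions classify into their categories", {
  S <- lig_substrates()[["b-b"]]$ion_mz
  expect_equal(classify_offset(c(1104, 1120), S),
               c("modified", "modified"))
  expect_equal(classify_offset(c(998, 980, 982, 898), S),
               rep("cleaved", 4))
  expect_equal(classify_offset(S, S), "unreacted")
  # the 2173 substrate dimer falls beyond the +1000 polymerized bound
  expect_equal(classify_offset(2173, S), "unclassified")
  # a widened window (config option) captures it
  expect_equal(classify_offset(2173, S,
                               category_windows(polymerized = c(69, 1200))),
               "polymerized")
})

test_that("offset rounding is half-away-from-zero with inclusive bounds", {
  S <- 1000
  expect_equal(classify_offset(S - 70.5, S), "cleaved")      # -70.5 -> -71
  expect_equal(classify_offset(S - 70.4, S), "modified")     # -> -70
  expect_equal(classify_offset(S + 68.5, S), "polymerized")  # +68.5 -> +69
  expect_equal(classify_offset(S + 68.4, S), "modified")     # -> +68
  expect_equal(classify_offset(S + 1, S), "unclassified")    # substrate isotope
  expect_equal(classify_offset(S + 0.3, S), "unclassified")  # rounds to 0
  expect_equal(classify_offset(S + 0.05, S), "unreacted")    # within tol
  expect_error(category_windows(modified = rbind(c(-70, -1), c(2, 80))),
               "overlap")
})

test_that("bin consolidation follows the +/- 0.1 greedy agglomeration", {
  pk <- data.frame(mz = c(1088.00, 1088.05), intensity = c(100, 50))
  expect_equal(nrow(consolidate_bins(pk)), 1)
  pk2 <- data.frame(mz = c(1088.00, 1088.25), intensity = c(100, 50))
  expect_equal(nrow(consolidate_bins(pk2)), 2)
  # three pixels each contributing (998, 100) sum into one bin
  pk3 <- data.frame(mz = rep(998, 3), intensity = rep(100, 3))
  b3 <- consolidate_bins(pk3)
  expect_equal(b3$mz, 998)
  expect_equal(b3$intensity, 300)
  # bin m/z is the intensity-weighted mean of members
  pk4 <- data.frame(mz = c(1000.00, 1000.08), intensity = c(300, 100))
  expect_equal(consolidate_bins(pk4)$mz, (1000 * 300 + 1000.08 * 100) / 400)
  # membership is tested against the seed (most intense founder) m/z
  expect_equal(consolidate_bins(pk4)$seed_mz, 1000)
})

test_that("background bins are removed within tolerance", {
  bins <- consolidate_bins(data.frame(mz = c(301.02, 500, 1088),
                                      intensity = c(50, 20, 400)))
  out <- remove_background(bins, c(301, 500.15))
  expect_equal(sort(out$mz), c(500, 1088))  # 500 is 0.15 away: kept
  expect_equal(nrow(remove_background(bins, numeric(0))), 3)
})

test_that("spot proportions normalize over the four categories only", {
  S <- 1088
  mk <- function(mz, I) {
    b <- data.frame(mz = mz, seed_mz = mz, intensity = I,
                    n_peaks = rep(1L, length(mz)))
    attr(b, "members") <- as.list(seq_along(mz))
    b
  }
  bins <- mk(c(1088, 1104, 998, 1250), c(10, 10, 10, 10))
  q <- spot_proportions(bins, S)
  expect_equal(unlist(q[paste0("p_", c("unreacted", "modified", "cleaved",
                                       "polymerized"))], use.names = FALSE),
               rep(0.25, 4))
  # scale invariance
  q7 <- spot_proportions(mk(c(1088, 1104, 998, 1250), 7 * c(10, 10, 10, 10)), S)
  expect_equal(q7$p_cleaved, q$p_cleaved)
  # single category
  q1 <- spot_proportions(mk(998, 50), S)
  expect_equal(q1$p_cleaved, 1)
  # unclassified intensity excluded from the denominator but reported
  bins2 <- mk(c(1088, 2173), c(30, 10))
  q2 <- spot_proportions(bins2, S)
  expect_equal(q2$p_unreacted, 1)
  expect_equal(q2$I_unclassified, 10)
  # empty spot: proportions undefined, flagged
  q0 <- spot_proportions(mk(numeric(0), numeric(0)), S)
  expect_true(q0$empty)
  expect_true(is.na(q0$p_unreacted))
})

test_that("track_ions reports shares within the target set", {
  bins <- data.frame(mz = c(1088, 1104, 998), seed_mz = c(1088, 1104, 998),
                     intensity = c(30, 30, 30), n_peaks = 1L)
  tr <- track_ions(bins, c(1088, 1104, 998))
  expect_equal(tr$rel_abundance, rep(1 / 3, 3))
  tr1 <- track_ions(bins[1, ], 1088)
  expect_equal(tr1$rel_abundance, 1)
  expect_error(track_ions(bins, c(1088, 1088.15)), "separated")
})
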