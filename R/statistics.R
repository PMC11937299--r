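#' Aggregate spot quantifications to condition summaries
#'
#' Joins per-spot proportions to the plate design and summarizes each
#' (enzyme, pH, substrate[, timepoint]) condition over replicates: mean, SD
#' and n per category plus the total reacted fraction (modified + cleaved +
#' polymerized). Empty spots (no classified signal) are excluded from n;
#' conditions with no usable replicate are flagged.
#'
#' @param quant per-spot table from [quantify_spots()].
#' @param design the [make_design()] table (spots are matched by plate
#'   row/column).
#' @return Data frame with one row per condition: `enzyme`, `pH`,
#'   `substrate`, `timepoint`, `n`, `mean_p_*`, `sd_p_*`,
#'   `mean_total_reacted`, `flagged`.
#' @export
aggregate_conditions <- function(quant, design) {
  m <- merge(design, quant, by.x = c("row", "col"),
             by.y = c("spot_row", "spot_col"))
  if (nrow(m) < nrow(design))
    stop("some design wells have no quantified spot")
  m$total_reacted <- m$p_modified + m$p_cleaved + m$p_polymerized
  grp <- paste(m$enzyme, m$pH, m$substrate, m$timepoint,
               m$is_no_enzyme_control)
  cats <- c("unreacted", "modified", "cleaved", "polymerized")
  rows <- lapply(split(m, grp), function(d) {
    ok <- !d$empty
    out <- d[1, c("enzyme", "pH", "substrate", "timepoint",
                  "is_no_enzyme_control", "is_no_substrate_control")]
    out$n <- sum(ok)
    for (k in cats) {
      v <- d[[paste0("p_", k)]][ok]
      out[[paste0("mean_p_", k)]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0("sd_p_", k)]] <- if (length(v) > 1) sd(v) else NA_real_
    }
    tr <- d$total_reacted[ok]
    out$mean_total_reacted <- if (length(tr)) mean(tr) else NA_real_
    out$sd_total_reacted <- if (length(tr) > 1) sd(tr) else NA_real_
    out$flagged <- sum(ok) == 0
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$enzyme, out$pH, out$timepoint), ]
}

## Exact one-factor evaluation of the many-to-one multivariate-t CDF.
## For treatment-vs-control t statistics with pooled variance the
## correlation matrix is rank-one plus diagonal: corr(T_i, T_j) =
## lambda_i * lambda_j with lambda_i = sqrt(n_i / (n_i + n_0)). Writing
## T_i = (lambda_i Z0 + sqrt(1 - lambda_i^2) Z_i) / W with W^2 ~ chi^2_nu/nu,
## P(T_i <= u_i for all i) reduces to a 2-D integral over (Z0, W), evaluated
## here with Gauss-Hermite (Z0) x Gauss-Legendre on the chi quantile scale
## (W). Deterministic, accurate to ~1e-6 with the default node counts.
dunnett_pall <- function(u, lambda, nu, n_gh = 48, n_gl = 64) {
  gh <- pracma::gaussHermite(n_gh)
  gl <- pracma::gaussLegendre(n_gl, 0, 1)
  s <- sqrt(qchisq(gl$x, df = nu) / nu)
  k <- length(u)
  denom <- sqrt(1 - lambda^2)
  # grid over (gl, gh); accumulate the product over groups
  z0 <- sqrt(2) * gh$x
  prodphi <- matrix(1, n_gl, n_gh)
  for (i in seq_len(k)) {
    arg <- (outer(s, rep(1, n_gh)) * u[i] - outer(rep(1, n_gl), z0) * lambda[i]) / denom[i]
    prodphi <- prodphi * pnorm(arg)
  }
  w <- outer(gl$w, gh$w / sqrt(pi))
  sum(w * prodphi)
}

#' One-sided Dunnett many-to-one comparison against a shared control
#'
#' Computes pooled-variance t statistics for each treatment group against
#' the control and adjusts the one-sided p values for simultaneity over the
#' groups using the equicorrelated many-to-one multivariate-t distribution.
#' By default the distribution is evaluated with a deterministic 2-D Gauss
#' quadrature exploiting its one-factor structure; `method = "mvt"` uses
#' [mvtnorm::pmvt()] (randomized Genz-Bretz integration, seeded).
#'
#' @param control numeric vector of control observations (n >= 2).
#' @param groups named list of numeric vectors, one per treatment group
#'   (each n >= 2).
#' @param alternative `"greater"` tests whether treatments exceed the
#'   control; `"less"` the reverse.
#' @param method `"quadrature"` (deterministic, default) or `"mvt"`.
#' @param variance `"pooled"` (default) or `"welch"` for unpooled
#'   per-comparison variances with Welch-Satterthwaite degrees of freedom.
#' @param seed RNG seed used by `method = "mvt"` (recorded either way).
#' @return Data frame with one row per group: `group`, `n`, `mean`, `t`,
#'   `p_unadjusted`, `p_adjusted`; the control summary, degrees of freedom
#'   and method are attached as attributes.
#' @examples
#' set.seed(4)
#' dunnett_one_sided(rnorm(4), list(a = rnorm(4) + 2, b = rnorm(4)))
#' @export
dunnett_one_sided <- function(control, groups,
                              alternative = c("greater", "less"),
                              method = c("quadrature", "mvt"),
                              variance = c("pooled", "welch"), seed = 1) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  variance <- match.arg(variance)
  stopifnot(length(control) >= 2, length(groups) >= 1,
            all(vapply(groups, length, 0L) >= 2))
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  n0 <- length(control); m0 <- mean(control)
  ni <- vapply(groups, length, 0L)
  mi <- vapply(groups, mean, 0)
  sgn <- if (alternative == "greater") 1 else -1
  if (variance == "pooled") {
    ss <- sum((control - m0)^2) + sum(vapply(groups, function(g)
      sum((g - mean(g))^2), 0))
    nu <- n0 - 1 + sum(ni - 1)
    s2 <- ss / nu
    if (s2 <= 0) {
      if (all(mi == m0)) {
        out <- data.frame(group = names(groups), n = ni, mean = mi, t = 0,
                          p_unadjusted = 1, p_adjusted = 1)
        rownames(out) <- NULL
        return(out)
      }
      stop("zero pooled variance with unequal group means")
    }
    se <- sqrt(s2 * (1 / ni + 1 / n0))
    lambda <- sqrt(ni / (ni + n0))
    nu_i <- rep(nu, length(ni))
  } else {
    v0 <- stats::var(control) / n0
    vi <- vapply(groups, function(g) stats::var(g) / length(g), 0)
    if (any(vi + v0 <= 0)) stop("zero variance in a Welch comparison")
    se <- sqrt(vi + v0)
    lambda <- sqrt(v0 / (vi + v0))
    nu_i <- (vi + v0)^2 /
      (vi^2 / (ni - 1) + v0^2 / (n0 - 1))
    nu <- min(nu_i)
  }
  tstat <- sgn * (mi - m0) / se
  p_un <- pt(tstat, df = nu_i, lower.tail = FALSE)
  k <- length(groups)
  p_adj <- vapply(seq_len(k), function(i) {
    if (method == "quadrature") {
      1 - dunnett_pall(rep(tstat[i], k), lambda, nu)
    } else {
      R <- outer(lambda, lambda); diag(R) <- 1
      1 - with_seed(seed, as.numeric(mvtnorm::pmvt(
        upper = rep(tstat[i], k), corr = R, df = as.integer(round(nu)),
        algorithm = mvtnorm::GenzBretz(maxpts = 100000, abseps = 1e-4))))
    }
  }, 0)
  out <- data.frame(group = names(groups), n = ni, mean = mi, t = tstat,
                    p_unadjusted = p_un,
                    p_adjusted = pmin(pmax(p_adj, p_un), 1))
  rownames(out) <- NULL
  attr(out, "control") <- c(n = n0, mean = m0)
  attr(out, "df") <- nu
  attr(out, "method") <- method
  attr(out, "seed") <- seed
  out
}

#' Dunnett comparisons per category for a screen
#'
#' For each enzyme x pH treatment (within one substrate), tests whether the
#' category proportion exceeds the pooled no-enzyme controls. Product
#' categories in which every control observation is zero are skipped and
#' flagged (no signal above background in controls means no valid
#' many-to-one comparison for that category), mirroring the screen's
#' handling of such cases; `total_reacted` is always tested, since the
#' pooled variance across all groups keeps the statistic well defined even
#' when the controls show no activity at all.
#'
#' @param quant per-spot table from [quantify_spots()].
#' @param design the plate design.
#' @param categories which proportions to test (default the three product
#'   categories plus total reacted).
#' @param ... passed to [dunnett_one_sided()].
#' @return Data frame with `category`, `enzyme`, `pH`, `t`, `p_unadjusted`,
#'   `p_adjusted`, `skipped`.
#' @export
dunnett_by_category <- function(quant, design,
                                categories = c("modified", "cleaved",
                                               "polymerized", "total_reacted"),
                                ...) {
  m <- merge(design, quant, by.x = c("row", "col"),
             by.y = c("spot_row", "spot_col"))
  m$p_total_reacted <- m$p_modified + m$p_cleaved + m$p_polymerized
  m <- m[!m$is_no_substrate_control & !m$empty, ]
  ctrl <- m[m$is_no_enzyme_control, ]
  trt <- m[!m$is_no_enzyme_control, ]
  if (nrow(ctrl) < 2) stop("need at least two usable no-enzyme control spots")
  out <- list()
  for (cat in categories) {
    col <- paste0("p_", cat)
    cv <- ctrl[[col]]
    groups <- split(trt[[col]], paste(trt$enzyme, trt$pH, sep = "|"))
    keyinfo <- do.call(rbind, strsplit(names(groups), "|", fixed = TRUE))
    if (all(cv == 0) && cat != "total_reacted") {
      out[[cat]] <- data.frame(category = cat, enzyme = keyinfo[, 1],
                               pH = as.numeric(keyinfo[, 2]),
                               t = NA_real_, p_unadjusted = NA_real_,
                               p_adjusted = NA_real_, skipped = TRUE)
      next
    }
    res <- dunnett_one_sided(cv, groups, ...)
    out[[cat]] <- data.frame(category = cat, enzyme = keyinfo[, 1],
                             pH = as.numeric(keyinfo[, 2]),
                             t = res$t, p_unadjusted = res$p_unadjusted,
                             p_adjusted = res$p_adjusted, skipped = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Call the pH activity range of one enzyme on one substrate
#'
#' The range is determined by maximum total activity (cleaved + modified +
#' polymerized): pH levels whose mean total reacted fraction reaches at
#' least `f` of the enzyme's maximum *and* whose Dunnett-adjusted p value
#' against the no-enzyme controls is below `alpha` qualify, and the maximal
#' contiguous run of qualifying levels containing the maximum is reported.
#' When no level qualifies the result is `"N.D."` (not determined: activity
#' similar to the negative control or too variable).
#'
#' @param ph pH levels (will be sorted; contiguity means consecutive
#'   entries of the sorted grid).
#' @param total_reacted mean total reacted fraction per level.
#' @param p_adjusted Dunnett-adjusted p per level (`NA` disqualifies).
#' @param f fraction of the maximum required (default 0.5).
#' @param alpha significance level (default 0.05).
#' @return List with `label` (e.g. `"5-7"` or `"N.D."`), `ph_min`, `ph_max`
#'   and the qualifying `levels`.
#' @export
ph_activity_range <- function(ph, total_reacted, p_adjusted,
                              f = 0.5, alpha = 0.05) {
  stopifnot(length(ph) >= 2, length(total_reacted) == length(ph),
            length(p_adjusted) == length(ph))
  ord <- order(ph)
  ph <- ph[ord]; tr <- total_reacted[ord]; p <- p_adjusted[ord]
  pass <- !is.na(tr) & !is.na(p) & tr >= f * max(tr, na.rm = TRUE) & p < alpha
  if (!any(pass))
    return(list(label = "N.D.", ph_min = NA_real_, ph_max = NA_real_,
                levels = numeric(0)))
  imax <- which(pass)[which.max(tr[pass])]
  runs <- rle(pass)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  r <- which(runs$values & starts <= imax & ends >= imax)
  lv <- ph[starts[r]:ends[r]]
  list(label = if (length(lv) == 1) as.character(lv[1]) else
    paste0(min(lv), "-", max(lv)),
    ph_min = min(lv), ph_max = max(lv), levels = lv)
}

#' Correlation between pH and product shares
#'
#' Shares of the stated products are renormalized within each observation
#' (so they sum to one over the product set) and each product's share is
#' correlated with pH (Pearson by default, two-sided p).
#'
#' @param ph numeric vector of pH values, one per observation (replicate).
#' @param shares matrix or data frame of product intensities or shares, one
#'   column per product (named by product m/z), rows aligned with `ph`.
#' @param method correlation method passed to [stats::cor.test()].
#' @return Data frame with `product`, `r`, `p_value`, `sign`, `flagged`
#'   (`TRUE` when a variance was zero and the correlation is undefined).
#' @export
product_ph_correlation <- function(ph, shares, method = "pearson") {
  shares <- as.matrix(shares)
  stopifnot(length(ph) >= 3, nrow(shares) == length(ph))
  tot <- rowSums(shares)
  ok <- tot > 0
  norm <- shares[ok, , drop = FALSE] / tot[ok]
  phk <- ph[ok]
  rows <- lapply(colnames(norm) %||% as.character(seq_len(ncol(norm))),
                 function(nm) {
    v <- norm[, nm]
    if (sd(v) == 0 || sd(phk) == 0)
      return(data.frame(product = nm, r = NA_real_, p_value = NA_real_,
                        sign = NA_real_, flagged = TRUE))
    ct <- cor.test(phk, v, method = method)
    data.frame(product = nm, r = unname(ct$estimate), p_value = ct$p.value,
               sign = sign(unname(ct$estimate)), flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize tracked-ion time courses over replicates
#'
#' @param tracked data frame with columns `target_mz`, `timepoint`,
#'   `replicate`, `rel_abundance`.
#' @return Data frame with per (ion, timepoint) `mean`, `sd` (`NA` for a
#'   single replicate) and `n`.
#' @export
timecourse_summary <- function(tracked) {
  stopifnot(all(c("target_mz", "timepoint", "rel_abundance") %in% names(tracked)))
  if (length(unique(tracked$timepoint)) < 2)
    stop("need at least two timepoints")
  grp <- interaction(tracked$target_mz, tracked$timepoint, drop = TRUE)
  rows <- lapply(split(tracked, grp), function(d)
    data.frame(target_mz = d$target_mz[1], timepoint = d$timepoint[1],
               mean = mean(d$rel_abundance),
               sd = if (nrow(d) > 1) sd(d$rel_abundance) else NA_real_,
               n = nrow(d)))
  out <- do.call(rbind, rows)
  out <- out[order(out$target_mz, out$timepoint), ]
  rownames(out) <- NULL
  out
}

#' Enzyme-by-pH matrix of category proportions
#'
#' The data behind a screening bubble chart: one row per enzyme x pH with
#' the four mean proportions, in wide plate-report form.
#'
#' @param summary output of [aggregate_conditions()].
#' @return Data frame with `enzyme`, `pH` and the four `mean_p_*` columns,
#'   treatments only.
#' @export
fig_matrix <- function(summary) {
  s <- summary[!summary$is_no_enzyme_control & !summary$is_no_substrate_control, ]
  s <- s[order(s$enzyme, s$pH),
         c("enzyme", "pH", "mean_p_unreacted", "mean_p_modified",
           "mean_p_cleaved", "mean_p_polymerized")]
  rownames(s) <- NULL
  s
}
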