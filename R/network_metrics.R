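#' Component-level fMRI statistics
#'
#' Operations applied downstream of group ICA: selecting components of
#' neuronal origin, cleaning component timecourses, estimating condition
#' beta weights with a block-design GLM, functional network connectivity
#' (FNC), and robust brain-behavior correlations.
#'
#' @name network_metrics
#' @keywords internal
NULL

#' Select or reject an ICA component by tissue overlap
#'
#' Converts the component spatial map to a z-map (mean 0, SD 1 over all
#' voxels), thresholds it at `z_thresh` (sub-threshold voxels set to 0),
#' and computes the squared Pearson correlation of the thresholded map
#' with grey-matter, white-matter and CSF probability maps over all
#' voxels. A component is rejected if R^2 with CSF or WM exceeds
#' `r2_thresh`, or R^2 with GM falls below it. The decision is invariant
#' to affine rescaling of the input map, which the z-scoring absorbs.
#'
#' @param spatial_map 3-D numeric array (or path to a NIfTI file).
#' @param gm_mask,wm_mask,csf_mask tissue probability volumes on the same
#'   grid (arrays or NIfTI paths).
#' @param z_thresh z threshold applied to the map (default 1.96).
#' @param r2_thresh squared-correlation threshold (default .025).
#' @return List with `keep` (logical), `r2` (named vector gm/wm/csf), and
#'   `reason` (`NA` if kept).
#' @export
select_components <- function(spatial_map, gm_mask, wm_mask, csf_mask,
                              z_thresh = 1.96, r2_thresh = .025) {
  vol <- function(x) if (is.character(x)) as.array(RNifti::readNifti(x)) else as.array(x)
  map <- vol(spatial_map); gm <- vol(gm_mask); wm <- vol(wm_mask); csf <- vol(csf_mask)
  dims <- dim(map)
  for (m in list(gm, wm, csf))
    if (!identical(dim(m), dims)) stop("tissue mask grid does not match the map grid")
  z <- (map - mean(map)) / stats::sd(map)
  z[z < z_thresh] <- 0
  r2 <- c(gm = stats::cor(as.vector(z), as.vector(gm))^2,
          wm = stats::cor(as.vector(z), as.vector(wm))^2,
          csf = stats::cor(as.vector(z), as.vector(csf))^2)
  reason <- if (r2["csf"] > r2_thresh) "CSF overlap"
            else if (r2["wm"] > r2_thresh) "WM overlap"
            else if (r2["gm"] < r2_thresh) "low GM overlap"
            else NA_character_
  list(keep = is.na(reason), r2 = r2, reason = reason)
}

#' Clean a component timecourse
#'
#' Regresses out nuisance signals (typically six motion parameters plus
#' mean WM and CSF), then removes slow drift by linear detrending - in
#' that order. Both steps are ordinary least squares with an intercept.
#'
#' @param values numeric timecourse (one value per volume).
#' @param nuisance optional matrix of nuisance regressors (rows =
#'   volumes); must be full column rank.
#' @return Cleaned numeric vector of the same length.
#' @export
clean_timecourse <- function(values, nuisance = NULL) {
  v <- as.numeric(values)
  if (anyNA(v)) stop("timecourse contains missing values")
  if (!is.null(nuisance)) {
    X <- as.matrix(nuisance)
    if (nrow(X) != length(v))
      stop("nuisance matrix has ", nrow(X), " rows but timecourse has ",
           length(v), " volumes")
    if (qr(cbind(1, X))$rank < ncol(X) + 1)
      stop("nuisance matrix is rank deficient")
    v <- stats::lsfit(X, v)$residuals
  }
  stats::lsfit(seq_along(v), v)$residuals
}

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style canonical HRF: a gamma density peaking at `peak` seconds
#' minus `ratio` times a gamma density peaking at `undershoot` seconds,
#' sampled every `dt` seconds over `duration` seconds and normalized to
#' unit peak.
#'
#' @param dt sampling interval in seconds (> 0).
#' @param duration kernel length in seconds (default 32).
#' @param peak,undershoot gamma peak times in seconds (defaults 6 and 16).
#' @param ratio undershoot amplitude ratio (default 1/6).
#' @return Numeric kernel with attribute `times` (seconds).
#' @export
canonical_hrf <- function(dt, duration = 32, peak = 6, undershoot = 16,
                          ratio = 1 / 6) {
  if (dt <= 0) stop("`dt` must be > 0")
  t <- seq(0, duration, by = dt)
  # gamma with shape a, rate 1 peaks at a - 1
  h <- stats::dgamma(t, shape = peak + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot + 1, rate = 1)
  h <- h / max(h)
  attr(h, "times") <- t
  h
}

# HRF-convolved condition regressors sampled at volume acquisition times.
# Boxcars are built on a fine time grid (dt = 0.1 s), convolved with the
# canonical HRF, then sampled at t = (0, TR, 2 TR, ...).
build_design <- function(events, tr, n_volumes,
                         conditions = sort(unique(events$condition)),
                         hrf_args = list()) {
  stopifnot(all(c("condition", "onset", "duration") %in% names(events)))
  if (any(events$onset < 0)) stop("event onsets must be non-negative")
  if (any(events$duration <= 0)) stop("event durations must be positive")
  dt <- 0.1
  total <- n_volumes * tr
  fine_t <- seq(0, total, by = dt)
  hrf <- do.call(canonical_hrf, c(list(dt = dt), hrf_args))
  X <- matrix(0, n_volumes, length(conditions),
              dimnames = list(NULL, conditions))
  vol_t <- (seq_len(n_volumes) - 1) * tr
  for (j in seq_along(conditions)) {
    box <- numeric(length(fine_t))
    ev <- events[events$condition == conditions[j], , drop = FALSE]
    for (i in seq_len(nrow(ev)))
      box[fine_t >= ev$onset[i] & fine_t < ev$onset[i] + ev$duration[i]] <- 1
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(fine_t)] * dt
    X[, j] <- stats::approx(fine_t, conv, xout = vol_t, rule = 2)$y
  }
  X
}

#' Block-event table
#'
#' @param condition character condition labels (e.g. "structured",
#'   "random").
#' @param onset,duration event timing in seconds; onsets must be
#'   non-negative and events within a condition non-overlapping.
#' @return A data.frame of class `block_event_table`.
#' @export
block_event_table <- function(condition, onset, duration) {
  d <- data.frame(condition = as.character(condition),
                  onset = as.numeric(onset), duration = as.numeric(duration))
  if (any(d$onset < 0)) stop("onsets must be non-negative")
  if (any(d$duration <= 0)) stop("durations must be positive")
  for (cond in unique(d$condition)) {
    e <- d[d$condition == cond, ]
    e <- e[order(e$onset), ]
    if (nrow(e) > 1 && any(e$onset[-1] < (e$onset + e$duration)[-nrow(e)]))
      stop("overlapping events within condition '", cond, "'")
  }
  structure(d, class = c("block_event_table", "data.frame"))
}

#' Read a block-event table from 3-column delimited text
#'
#' Columns: condition, onset_s, duration_s (tab- or whitespace-separated,
#' no header required).
#'
#' @param path file path.
#' @return A `block_event_table`.
#' @export
read_events <- function(path) {
  d <- utils::read.table(path, header = FALSE,
                         col.names = c("condition", "onset", "duration"),
                         colClasses = c("character", "numeric", "numeric"))
  block_event_table(d$condition, d$onset, d$duration)
}

#' GLM condition betas for component timecourses
#'
#' Fits ordinary least squares of a cleaned component timecourse on
#' HRF-convolved condition boxcars plus an intercept, returning one beta
#' weight per condition. When `tc` is a list (one cleaned timecourse per
#' run), run-level betas are estimated per run and averaged, giving the
#' session-level estimate.
#'
#' @param tc numeric vector, or list of numeric vectors (runs).
#' @param events a `block_event_table` (recycled across runs).
#' @param tr repetition time in seconds.
#' @return Named numeric vector of betas (one per condition).
#' @export
glm_betas <- function(tc, events, tr) {
  if (!is.list(tc)) tc <- list(tc)
  design <- build_design(events, tr, length(tc[[1]]))
  B <- vapply(tc, function(y) fit_betas(y, design), numeric(ncol(design)))
  rowMeans(B)
}

# OLS betas for one run against a prebuilt design.
fit_betas <- function(y, X) {
  y <- as.numeric(y)
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("design matrix is rank deficient")
  fit <- stats::lsfit(X, y)
  stats::setNames(fit$coefficients[-1], colnames(X))
}

#' Post-minus-pre change scores
#'
#' Elementwise `post - pre` for named vectors or matrices with matching
#' identifiers (names / dimnames).
#'
#' @param post,pre numeric vectors or matrices with identical identifiers.
#' @return Object of the same shape.
#' @export
delta_scores <- function(post, pre) {
  if (is.matrix(post)) {
    if (!identical(dimnames(post), dimnames(pre)))
      stop("dimnames of `post` and `pre` do not match")
  } else if (!identical(names(post), names(pre))) {
    stop("names of `post` and `pre` do not match")
  }
  post - pre
}

#' Functional network connectivity matrix
#'
#' Pairwise Pearson correlation between component timecourses within each
#' run, Fisher z-transformed (`atanh`) and averaged across runs. A
#' correlation of exactly +-1 (degenerate duplicate timecourses) is
#' clipped to +-(1 - 1e-12) with a warning so the transform stays finite.
#'
#' @param runs a single matrix (volumes x components) or a list of such
#'   matrices, one per run; all runs must have the same components.
#' @return An `fnc_matrix`: symmetric components x components matrix of
#'   mean Fisher-z values with `NA` diagonal.
#' @export
fnc_matrix <- function(runs) {
  if (!is.list(runs)) runs <- list(runs)
  runs <- lapply(runs, as.matrix)
  k <- ncol(runs[[1]])
  if (k < 2) stop("need at least 2 components")
  zs <- lapply(seq_along(runs), function(ri) {
    m <- runs[[ri]]
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      bad <- colnames(m)[sds == 0]
      if (is.null(bad)) bad <- which(sds == 0)
      stop("zero-variance timecourse for component ", paste(bad, collapse = ", "),
           " in run ", ri)
    }
    r <- stats::cor(m)
    if (any(abs(r[upper.tri(r)]) >= 1)) {
      warning("correlation of |r| = 1 between components; clipping before Fisher z")
      r[r >= 1] <- 1 - 1e-12
      r[r <= -1] <- -(1 - 1e-12)
    }
    atanh(r)
  })
  z <- Reduce(`+`, zs) / length(zs)
  diag(z) <- NA_real_
  structure(z, class = c("fnc_matrix", "matrix"))
}

#' @export
print.fnc_matrix <- function(x, ...) {
  cat("FNC matrix (mean Fisher z), ", ncol(x), " components\n", sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Skipped correlation with percentile-bootstrap confidence interval
#'
#' Robust alternative to Pearson correlation. Each observation is
#' projected onto the direction running from the bivariate
#' (coordinatewise) median through that observation; the point is flagged
#' as an outlier when its projected distance is extreme relative to the
#' projections of the rest of the sample. Two detection rules are
#' provided: `"boxplot"` (the default) flags a point whose projection
#' lies outside the projection median plus or minus Carling's
#' sample-size-adjusted constant times the ideal-fourths interquartile
#' range; `"mad"` flags a point whose MAD-standardized projected distance
#' exceeds the chi-square-derived cutoff `sqrt(qchisq(.975, 2))`.
#' Pearson's r is then computed on the non-flagged points, and a
#' percentile bootstrap over the non-flagged pairs gives the 95% CI,
#' using the small-sample-adjusted quantile bounds of Wilcox's percentile
#' bootstrap for correlations (wider, asymmetric tails below n = 250).
#' The correlation is deemed significant when the CI excludes zero. With
#' no flagged outliers the estimate equals plain Pearson's r exactly.
#'
#' @param x,y paired numeric vectors (n >= 10 recommended).
#' @param n_boot bootstrap resamples (default 1000).
#' @param detector outlier rule, `"boxplot"` (Carling) or `"mad"`
#'   (chi-square cutoff).
#' @return A `robust_correlation`: list with `r`, `ci_low`, `ci_high`,
#'   `significant`, `outlier_flags`, `n_used`, `n_boot`.
#' @export
skipped_correlation <- function(x, y, n_boot = 1000,
                                detector = c("boxplot", "mad")) {
  detector <- match.arg(detector)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  flags <- detect_bivariate_outliers(x, y, detector)
  xc <- x[!flags]; yc <- y[!flags]
  if (length(xc) < 4) stop("fewer than 4 observations remain after outlier removal")
  r <- stats::cor(xc, yc)
  m <- length(xc)
  idx <- matrix(sample.int(m, m * n_boot, replace = TRUE), nrow = m)
  rb <- sort(boot_pearson(xc, yc, idx))
  nb <- length(rb)
  q <- boot_quantile_bounds(m)
  ci <- c(rb[max(1L, round(q[1] * nb))], rb[min(nb, round(q[2] * nb))])
  structure(list(r = r, ci_low = ci[1], ci_high = ci[2],
                 significant = ci[1] > 0 || ci[2] < 0,
                 outlier_flags = flags, n_used = m, n_boot = n_boot,
                 detector = detector),
            class = "robust_correlation")
}

# Wilcox's adjusted percentile bounds for bootstrapped correlations
# (quantile positions of the 599-resample table, expressed as fractions).
boot_quantile_bounds <- function(n) {
  if (n < 40) c(7, 593) / 599
  else if (n < 80) c(8, 592) / 599
  else if (n < 180) c(11, 588) / 599
  else if (n < 250) c(14, 585) / 599
  else c(15, 584) / 599
}

# Projection outlier detection: each point judged on the direction from
# the coordinatewise-median center through itself.
detect_bivariate_outliers <- function(x, y, detector = "boxplot") {
  n <- length(x)
  ctr <- c(stats::median(x), stats::median(y))
  X <- cbind(x - ctr[1], y - ctr[2])
  flags <- logical(n)
  for (i in seq_len(n)) {
    d <- X[i, ]
    nrm2 <- sum(d^2)
    if (nrm2 == 0) next
    proj <- as.vector(X %*% d) / sqrt(nrm2)
    med <- stats::median(proj)
    if (detector == "mad") {
      mad <- stats::mad(proj)         # includes the 1.4826 consistency factor
      if (mad == 0) next
      flags[i] <- abs(proj[i] - med) / mad > sqrt(stats::qchisq(.975, df = 2))
    } else {
      q <- ideal_fourths(proj)
      iqr <- q[2] - q[1]
      if (iqr == 0) next
      k <- (17.63 * n - 23.64) / (7.74 * n - 3.71)   # Carling's constant
      flags[i] <- proj[i] < med - k * iqr || proj[i] > med + k * iqr
    }
  }
  flags
}

# Ideal fourths (interpolated quartile estimator).
ideal_fourths <- function(v) {
  n <- length(v)
  j <- floor(n / 4 + 5 / 12)
  h <- n / 4 + 5 / 12 - j
  vs <- sort(v)
  k <- n - j + 1
  c((1 - h) * vs[j] + h * vs[j + 1],
    (1 - h) * vs[k] + h * vs[k - 1])
}

# Vectorized Pearson r over bootstrap index columns.
boot_pearson <- function(x, y, idx) {
  m <- nrow(idx)
  xb <- matrix(x[idx], nrow = m)
  yb <- matrix(y[idx], nrow = m)
  mx <- colMeans(xb); my <- colMeans(yb)
  sxy <- colMeans(xb * yb) - mx * my
  sx <- sqrt(colMeans(xb^2) - mx^2)
  sy <- sqrt(colMeans(yb^2) - my^2)
  sxy / (sx * sy)
}

#' @export
print.robust_correlation <- function(x, ...) {
  cat(sprintf("skipped r = %.3f, %d%% CI [%.3f, %.3f]%s (%d outliers removed, n = %d)\n",
              x$r, 95, x$ci_low, x$ci_high,
              if (x$significant) " *" else "",
              sum(x$outlier_flags), x$n_used))
  invisible(x)
}

#' Steiger's z test for two dependent correlations with a shared variable
#'
#' Compares `r_a = cor(s, x)` against `r_b = cor(s, y)` where both
#' correlations share the variable `s` and `r_xy = cor(x, y)`. Uses the
#' Z1-bar-star statistic with back-transformed averaged correlations
#' (Fisher z difference scaled by the pooled covariance of dependent
#' correlations); two-sided p from the standard normal.
#'
#' @param r_a,r_b the two dependent correlations (|r| < 1).
#' @param r_xy correlation between the two non-shared variables.
#' @param n sample size (> 3).
#' @return List with `z` and `p`.
#' @export
steiger_z <- function(r_a, r_b, r_xy, n) {
  if (any(abs(c(r_a, r_b, r_xy)) >= 1)) stop("correlations must satisfy |r| < 1")
  if (n <= 3) stop("`n` must exceed 3")
  z1 <- atanh(r_a); z2 <- atanh(r_b)
  rbar <- tanh((z1 + z2) / 2)
  psi <- r_xy * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_xy^2)
  s <- psi / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - s)))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Correlate brain change scores with strategy across subjects
#'
#' Skipped correlation of per-subject change scores (post minus
#' pre-training beta weights, or FNC Fisher-z change) against the
#' per-subject strategy index. A negative correlation means the increase
#' after training is linked to matching-like responders; a positive one
#' links it to maximization.
#'
#' @param delta_values per-subject change scores.
#' @param strategy_indices per-subject strategy indices (same subjects,
#'   same order).
#' @param n_boot bootstrap resamples.
#' @return A `robust_correlation`.
#' @export
strategy_brain_correlation <- function(delta_values, strategy_indices,
                                       n_boot = 1000) {
  if (length(delta_values) != length(strategy_indices))
    stop("subject mismatch between change scores and strategy indices")
  if (!is.null(names(delta_values)) && !is.null(names(strategy_indices)) &&
      !identical(names(delta_values), names(strategy_indices)))
    stop("subject identifiers of change scores and strategy indices differ")
  skipped_correlation(strategy_indices, delta_values, n_boot = n_boot)
}
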