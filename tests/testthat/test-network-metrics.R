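test_that("component selection applies the tissue-overlap rule", {
  set.seed(301)
  fix <- make_fixture_maps(c(10, 10, 10), overlaps = c(gm = 1, csf = 1, wm = 1))
  gm_like <- select_components(fix$maps[[1]], fix$gm, fix$wm, fix$csf)
  expect_true(gm_like$keep)
  csf_like <- select_components(fix$maps[[2]], fix$gm, fix$wm, fix$csf)
  expect_false(csf_like$keep)
  expect_match(csf_like$reason, "CSF")
  wm_like <- select_components(fix$maps[[3]], fix$gm, fix$wm, fix$csf)
  expect_false(wm_like$keep)

  # brute-force oracle: voxelwise correlation of the thresholded z-map
  m <- fix$maps[[1]]
  z <- (m - mean(m)) / sd(m); z[z < 1.96] <- 0
  expect_equal(unname(gm_like$r2["gm"]), cor(as.vector(z), as.vector(fix$gm))^2,
               tolerance = 1e-12)

  # affine rescaling of the map cannot change the decision
  rescaled <- select_components(3.7 * fix$maps[[1]] + 11, fix$gm, fix$wm, fix$csf)
  expect_equal(rescaled$r2, gm_like$r2, tolerance = 1e-10)

  expect_error(select_components(fix$maps[[1]], fix$gm[1:5, , ], fix$wm, fix$csf),
               "grid")
})

test_that("timecourse cleaning removes nuisance and drift", {
  set.seed(302)
  nuis <- matrix(rnorm(100 * 3), 100, 3)
  expect_equal(clean_timecourse(nuis[, 2], nuis), rep(0, 100),
               tolerance = 1e-10, ignore_attr = TRUE)
  ramp <- seq(0, 5, length.out = 80)
  expect_equal(clean_timecourse(ramp), rep(0, 80), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(clean_timecourse(rnorm(50), cbind(1:50, 2 * (1:50))),
               "rank deficient")

  # generative recovery: signal + planted nuisance mixture
  signal <- sin(seq(0, 12 * pi, length.out = 2000))
  W <- matrix(rnorm(2000 * 4), 2000, 4)
  contrib <- as.numeric(W %*% c(2, -1, .5, 3))
  cleaned <- clean_timecourse(signal + contrib, W)
  expect_gt(cor(cleaned, signal), .99)
})

test_that("the canonical HRF peaks at 6 s with a late undershoot", {
  h <- canonical_hrf(2)
  t <- attr(h, "times")
  expect_equal(t[which.max(h)], 6)
  expect_equal(max(h), 1)
  expect_gt(sum(h), 0)
  expect_lt(min(h), 0)
  expect_gt(t[which.min(h)], 10)

  # convolving a 16-s boxcar: brute-force discrete convolution oracle
  hf <- canonical_hrf(0.5)
  box <- rep(c(0, 1, 0), c(20, 32, 60))
  manual <- vapply(seq_along(box), function(t) {
    j <- seq_len(min(t, length(hf)))
    sum(hf[j] * box[t - j + 1])
  }, numeric(1))
  viaconv <- stats::convolve(box, rev(hf), type = "open")[seq_along(box)]
  expect_equal(viaconv, manual, tolerance = 1e-8)
  expect_gt(max(viaconv), 0)
  expect_lt(min(viaconv[60:112]), 0)   # undershoot after offset
})

test_that("GLM betas recover planted condition amplitudes", {
  ev <- demo_events(120, 2)
  X <- predstat:::build_design(as.data.frame(ev), 2, 120,
                               conditions = c("random", "structured"))
  tc <- as.numeric(X %*% c(0.5, 2.0))
  b <- glm_betas(tc, ev, 2)
  expect_equal(unname(b["structured"]), 2.0, tolerance = 1e-8)
  expect_equal(unname(b["random"]), 0.5, tolerance = 1e-8)

  set.seed(303)
  bn <- glm_betas(rnorm(120), ev, 2)
  expect_true(all(abs(bn) < 1))   # pure noise: betas near zero

  # identical onsets for both conditions: collinear design
  bad <- block_event_table(c("structured", "random"), c(10, 10), c(20, 20))
  expect_error(glm_betas(rnorm(60), bad, 2), "rank deficient")

  # run-averaging equals the scalar mean of run betas
  tcs <- list(tc + rnorm(120, sd = .1), tc + rnorm(120, sd = .1))
  expect_equal(glm_betas(tcs, ev, 2),
               (glm_betas(tcs[[1]], ev, 2) + glm_betas(tcs[[2]], ev, 2)) / 2,
               tolerance = 1e-12)
})

test_that("event tables validate and parse from delimited text", {
  expect_error(block_event_table("structured", -1, 10), "non-negative")
  expect_error(block_event_table("structured", 0, 0), "positive")
  expect_error(block_event_table(c("a", "a"), c(0, 5), c(10, 10)), "overlap")
  path <- tempfile(fileext = ".tsv")
  writeLines(c("structured\t10\t20", "random\t40\t20"), path)
  ev <- read_events(path)
  expect_equal(ev$onset, c(10, 40))
  expect_equal(ev$condition, c("structured", "random"))
})

test_that("FNC matrices are symmetric, run-averaged Fisher z", {
  set.seed(304)
  runs <- lapply(1:3, function(i) matrix(rnorm(180 * 4), 180, 4))
  z <- fnc_matrix(runs)
  expect_true(all(is.na(diag(z))))
  expect_equal(unclass(z), t(unclass(z)))
  expect_true(all(abs(z[upper.tri(z)]) < .25))   # independent noise

  # invariance under component permutation
  perm <- c(3, 1, 4, 2)
  zp <- fnc_matrix(lapply(runs, function(m) m[, perm]))
  expect_equal(unclass(zp), unclass(z)[perm, perm], tolerance = 1e-12)

  # run-averaged z equals the scalar average of per-run z
  z_each <- sapply(runs, function(m) atanh(cor(m[, 1], m[, 2])))
  expect_equal(z[1, 2], mean(z_each), tolerance = 1e-12)

  # planted correlation .6 via a shared latent
  set.seed(305)
  lat_sd <- sqrt(.6 / .4)
  runs2 <- lapply(1:3, function(i) {
    lat <- rnorm(180, sd = lat_sd)
    sapply(1:4, function(j) lat + rnorm(180))
  })
  z2 <- fnc_matrix(runs2)
  expect_lt(abs(mean(z2[upper.tri(z2)]) - atanh(.6)), .1)

  # degenerate duplicate pair is clipped, zero variance is an error
  dup <- cbind(a = rnorm(50), b = 0)
  dup[, "b"] <- dup[, "a"]
  expect_warning(zd <- fnc_matrix(dup), "clipping")
  expect_true(is.finite(zd[1, 2]))
  expect_error(fnc_matrix(cbind(a = rnorm(50), b = rep(1, 50))), "b")
})

test_that("change scores subtract elementwise with identifier checks", {
  expect_equal(delta_scores(c(a = 1), c(a = .4)), c(a = .6))
  x <- c(a = 2, b = 3)
  expect_equal(delta_scores(x, x), c(a = 0, b = 0))
  expect_error(delta_scores(c(a = 1), c(b = 1)), "match")
  post <- matrix(1:4, 2, dimnames = list(c("s1", "s2"), c("c1", "c2")))
  pre <- matrix(c(0, 1, 1, 0), 2, dimnames = dimnames(post))
  loop <- post
  for (i in 1:2) for (j in 1:2) loop[i, j] <- post[i, j] - pre[i, j]
  expect_equal(delta_scores(post, pre), loop)
})

test_that("skipped correlation reduces to Pearson and resists outliers", {
  # a configuration with no flagged outliers: exact reduction
  set.seed(6)
  x <- rnorm(19); y <- .5 * x + rnorm(19, sd = .8)
  expect_false(any(predstat:::detect_bivariate_outliers(x, y)))
  rc <- skipped_correlation(x, y, n_boot = 200)
  expect_identical(rc$r, cor(x, y))
  expect_equal(rc$n_used, 19)

  # one gross contaminant: flagged, r close to the clean-subset Pearson
  set.seed(5)
  xo <- rnorm(18); yo <- xo + rnorm(18, sd = .3)
  xo <- c(xo, 6); yo <- c(yo, -6)
  rco <- skipped_correlation(xo, yo, n_boot = 500)
  expect_true(rco$outlier_flags[19])
  expect_lt(abs(rco$r - cor(xo[1:18], yo[1:18])), .05)

  expect_error(skipped_correlation(rnorm(3), rnorm(3)), "4")
  expect_error(skipped_correlation(rnorm(5), rnorm(6)), "equal length")
})

test_that("Steiger's z compares dependent correlations", {
  same <- steiger_z(.4, .4, .3, 50)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  # frozen oracle from the direct back-transformed-average formula
  st <- steiger_z(.5, .3, .2, 100)
  expect_equal(st$z, 1.7783320, tolerance = 1e-6)
  expect_equal(st$p, 0.0753493, tolerance = 1e-6)
  # antisymmetry
  expect_equal(steiger_z(.3, .5, .2, 100)$z, -st$z, tolerance = 1e-12)
  expect_error(steiger_z(1, .3, .2, 100), "< 1")
  expect_error(steiger_z(.5, .3, .2, 3), "exceed 3")
})

test_that("brain-strategy correlations recover planted coupling", {
  set.seed(306)
  strat <- rnorm(19)
  db <- -.7 * scale(strat)[, 1] + rnorm(19, sd = sqrt(1 - .49))
  rc <- strategy_brain_correlation(db, strat, n_boot = 500)
  expect_lt(rc$r, 0)

  # perfectly coupled change scores: r = 1 guard path
  rc1 <- strategy_brain_correlation(strat, strat, n_boot = 100)
  expect_equal(rc1$r, 1)

  expect_error(strategy_brain_correlation(1:5, 1:4), "mismatch")
  expect_error(strategy_brain_correlation(c(a = 1, b = 2, c = 3, d = 4) ,
                                          c(a = 1, d = 2, c = 3, b = 4)),
               "identifiers")
})
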