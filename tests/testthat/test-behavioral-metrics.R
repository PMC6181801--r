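test_that("response distributions are conditional frequencies", {
  d <- response_dataset(rep(1, 56), rep(NA_character_, 56), rep("B", 56), 0)
  r <- response_distribution(d, src0)
  expect_equal(unname(r$q_table[1, ]), c(0, 1, 0, 0))

  exact <- exact_response_dataset(src0$stationary)
  r2 <- response_distribution(exact, src0)
  expect_equal(unname(r2$q_table[1, ]), c(.18, .72, .05, .05))

  # missing responses excluded from numerator and denominator
  d3 <- response_dataset(rep(1, 4), rep(NA_character_, 4),
                         c("A", NA, "A", NA), 0)
  r3 <- response_distribution(d3, src0)
  expect_equal(unname(r3$q_table[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(r3$n_obs), 2)

  d4 <- response_dataset(rep(1, 3), rep(NA_character_, 3),
                         rep(NA_character_, 3), 0)
  expect_error(response_distribution(d4, src0), "usable")

  set.seed(201)
  big <- simulate_responses(agent("matcher"), src1, 1, 1e4, 0)
  rb <- response_distribution(big, src1)
  expect_true(max(abs(rb$q_table - src1$prob_table)) < .02)
})

test_that("the minimum-overlap PI matches its closed forms", {
  # uniform responder baselines: .53 (level 0) and .45 (level 1)
  expect_equal(performance_index(uniform_table(src0), matcher_table(src0))$pi,
               .53, tolerance = 1e-12)
  expect_equal(performance_index(uniform_table(src1), matcher_table(src1))$pi,
               .45, tolerance = 1e-12)
  expect_equal(random_guess_baseline(src0), .53, tolerance = 1e-12)
  expect_equal(random_guess_baseline(src1), .45, tolerance = 1e-12)
  expect_equal(random_guess_baseline(build_level0_source(rep(.25, 4))), 1,
               tolerance = 1e-12)

  # identity: PI(p, p) = 1
  expect_equal(performance_index(matcher_table(src1), matcher_table(src1))$pi, 1)

  expect_error(
    performance_index(uniform_table(src0),
                      matcher_table(build_level0_source(c(.18, .72, .05, .05),
                                                        alphabet = c("W", "X", "Y", "Z")))),
    "alphabet")
})

test_that("PI is symmetric and bounded on random distribution pairs", {
  set.seed(202)
  for (i in 1:20) {
    p <- stats::runif(4) + .01; p <- p / sum(p)
    q <- stats::runif(4) + .01; q <- q / sum(q)
    tp <- distribution_table(0L, src0$alphabet, matrix(p, 1), stats::setNames(1, ""))
    tq <- distribution_table(0L, src0$alphabet, matrix(q, 1), stats::setNames(1, ""))
    a <- performance_index(tp, tq, weights = stats::setNames(1, ""))$pi
    b <- performance_index(tq, tp, weights = stats::setNames(1, ""))$pi
    expect_equal(a, b, tolerance = 1e-12)
    expect_gte(a, 0); expect_lte(a, 1)
  }
})

test_that("PI normalization is a plain baseline subtraction", {
  expect_equal(normalize_pi(.53, .53), 0)
  expect_equal(normalize_pi(1, .53), .47)
  expect_equal(normalize_pi(.72, .53), .19, tolerance = 1e-12)
})

test_that("the maximization model is one-hot on the most probable target", {
  m0 <- maximization_model(src0)
  expect_equal(unname(m0$q_table[1, ]), c(0, 1, 0, 0))
  m1 <- maximization_model(src1)
  expect_equal(unname(m1$q_table["A", ]), c(0, 1, 0, 0))  # A -> B
  expect_error(maximization_model(build_level0_source(rep(.25, 4))), "tied")
  tb <- maximization_model(build_level0_source(rep(.25, 4)),
                           tie_break = c("C", "A", "B", "D"))
  expect_equal(unname(tb$q_table[1, ]), c(0, 0, 1, 0))
})

test_that("model-to-response KL matches hand-computed oracles", {
  unif <- uniform_table(src0)
  match0 <- matcher_table(src0)
  # model == responses
  expect_equal(kl_model_to_responses(match0, match0, eps = 1e-9), 0,
               tolerance = 1e-6)
  # frozen oracle: sum p ln(p / .25) for p = (.18,.72,.05,.05) = 0.5415345
  expect_equal(kl_model_to_responses(match0, unif, eps = 1e-9), 0.5415345,
               tolerance = 1e-5)
  # maximization model vs uniform responder: ln 4
  expect_equal(kl_model_to_responses(maximization_model(src0), unif, eps = 1e-9),
               log(4), tolerance = 1e-6)
  expect_error(kl_model_to_responses(match0, unif, eps = 0), "eps")

  # decreasing in eps for a degenerate responder
  degen <- distribution_table(0L, src0$alphabet, matrix(c(0, 1, 0, 0), 1),
                              stats::setNames(1, ""))
  kls <- vapply(c(1e-4, 1e-3, 1e-2), function(e)
    kl_model_to_responses(match0, degen, eps = e), numeric(1))
  expect_true(all(diff(kls) < 0))
  expect_true(all(kls >= 0))
})

test_that("strategy choice has the documented sign convention", {
  # exact matcher: dKL = -KL(max || source) = -ln(1/p_high)
  expect_equal(strategy_choice(matcher_table(src0), src0, eps = 1e-10),
               log(.72), tolerance = 1e-6)
  expect_equal(strategy_choice(matcher_table(src1), src1, eps = 1e-10),
               log(.8), tolerance = 1e-6)
  # pure maximizer: large positive
  degen <- distribution_table(0L, src0$alphabet, matrix(c(0, 1, 0, 0), 1),
                              stats::setNames(1, ""))
  expect_gt(strategy_choice(degen, src0, eps = 1e-4), 1)
})

test_that("the strategy index separates matchers from maximizers", {
  set.seed(203)
  d_max <- simulate_responses(agent("maximizer"), src0, 5, 56, 0)
  expect_gt(strategy_index(d_max, src0, eps = 1e-4)$strategy_index, 0)

  set.seed(204)
  d_match <- simulate_responses(agent("matcher"), src0, 5, 1e4, 0)
  res <- strategy_index(d_match, src0)
  expect_lt(abs(res$strategy_index), .05)
  # invariant: ICD equals the sum of curve differences (rectangular rule)
  expect_equal(res$strategy_index,
               sum(res$delta_kl_curve) - sum(res$matcher_curve),
               tolerance = 1e-12)

  # trapezoid rule differs only in the endpoint weights
  res_t <- strategy_index(d_match, src0, rule = "trapezoid")
  dif <- res$delta_kl_curve - res$matcher_curve
  expect_equal(res_t$strategy_index,
               unname(res$strategy_index - (dif[1] + dif[length(dif)]) / 2),
               tolerance = 1e-12)
})

test_that("level-0 strategy indices rescale by the maximization ceilings", {
  expect_equal(scale_strategy_index(1), .8 / .72, tolerance = 1e-12)
  expect_equal(scale_strategy_index(0), 0)
  # the ceilings themselves
  expect_equal(performance_index(maximization_model(src0), matcher_table(src0))$pi,
               .72, tolerance = 1e-12)
  expect_equal(performance_index(maximization_model(src1), matcher_table(src1))$pi,
               .8, tolerance = 1e-12)
})

test_that("residualize computes OLS residuals", {
  x <- 1:10
  expect_equal(residualize(2 * x, x), rep(0, 10), tolerance = 1e-12,
               ignore_attr = TRUE)
  y <- c(1, -1, 1, -1, 1, -1)
  xc <- rep(c(1, 1, 2, 2, 3, 3))
  expect_equal(residualize(y, xc), y - mean(y), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(residualize(y, rep(1, 6)), "constant")
  # normal-equations oracle
  set.seed(205)
  yv <- stats::rnorm(30); xv <- stats::rnorm(30)
  X <- cbind(1, xv)
  beta <- solve(t(X) %*% X, t(X) %*% yv)
  expect_equal(residualize(yv, xv), as.numeric(yv - X %*% beta),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("response datasets round-trip through delimited text", {
  set.seed(206)
  d <- simulate_responses(agent("blend", lambda = .4), src1, 2, 30, .1)
  path <- tempfile(fileext = ".tsv")
  write_responses(d, path)
  back <- read_responses(path, level = 1)
  expect_equal(as.data.frame(back)[c("block", "context", "response")],
               as.data.frame(d)[c("block", "context", "response")])
})
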