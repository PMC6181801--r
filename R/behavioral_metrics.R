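#' Behavioral scoring: Performance Index and strategy index
#'
#' Functions that score trial-level prediction responses against the
#' generating Markov source. The Performance Index (PI) measures the
#' minimum overlap between the response distribution and the presented
#' distribution; the strategy index locates a responder on the continuum
#' between probability matching (reproducing the source's conditional
#' probabilities) and probability maximization (always choosing the most
#' probable target).
#'
#' @name behavioral_metrics
#' @keywords internal
NULL

#' Construct a response dataset
#'
#' @param block integer block index per trial (contiguous from 1).
#' @param context context symbol per trial (`NA` for a zero-order task,
#'   where there is a single null context).
#' @param response response symbol per trial; `NA` = missing (no response
#'   recorded before the deadline).
#' @param level statistical level (0 or 1).
#' @return A `response_dataset` (data.frame subclass).
#' @export
response_dataset <- function(block, context, response, level) {
  d <- data.frame(block = as.integer(block),
                  context = as.character(context),
                  response = as.character(response),
                  stringsAsFactors = FALSE)
  blocks <- sort(unique(d$block))
  if (!identical(blocks, seq_along(blocks)))
    stop("block indices must be contiguous from 1")
  structure(d, level = as.integer(level),
            class = c("response_dataset", "data.frame"))
}

#' Conditional response distribution
#'
#' Relative frequency of each response per context, `R(target | context)`.
#' Missing responses are excluded from both numerator and denominator.
#' Context weights are taken from the source's stationary distribution so
#' that downstream weighted statistics use the design probabilities, not
#' the realized context counts.
#'
#' @param data a `response_dataset`.
#' @param source the `markov_source` the trials were generated from.
#' @param block optional block index; if given only that block's trials
#'   are used.
#' @return A `distribution_table`.
#' @export
response_distribution <- function(data, source, block = NULL) {
  d <- as.data.frame(data)
  if (!is.null(block)) d <- d[d$block == block, , drop = FALSE]
  d <- d[!is.na(d$response), , drop = FALSE]
  if (!nrow(d)) stop("no usable (non-missing) trials",
                     if (!is.null(block)) paste0(" in block ", block) else "")
  alpha <- source$alphabet
  k <- length(alpha)
  if (source$order == 0L) {
    counts <- tabulate(match(d$response, alpha), nbins = k)
    q <- matrix(counts / sum(counts), nrow = 1, dimnames = list("", alpha))
    distribution_table(0L, alpha, q, stats::setNames(1, ""),
                       n_obs = stats::setNames(nrow(d), ""))
  } else {
    ci <- match(d$context, alpha)
    ri <- match(d$response, alpha)
    if (anyNA(ci)) stop("context symbol outside the source alphabet")
    if (anyNA(ri)) stop("response symbol outside the source alphabet")
    counts <- matrix(0, k, k, dimnames = list(alpha, alpha))
    for (t in seq_along(ci)) counts[ci[t], ri[t]] <- counts[ci[t], ri[t]] + 1
    n_ctx <- rowSums(counts)
    q <- counts / ifelse(n_ctx > 0, n_ctx, NA_real_)
    q[n_ctx == 0, ] <- NA_real_
    distribution_table(1L, alpha, q, source$stationary, n_obs = n_ctx)
  }
}

#' Minimum-overlap Performance Index
#'
#' Per context, `PI(context) = sum_target min(R(t|c), P(t|c))` where `R`
#' is the response distribution and `P` the presented distribution; the
#' overall PI averages over contexts with the supplied weights,
#' `PI = sum_context PI(context) P(context)`. PI = 1 means the response
#' distribution reproduces the presented one exactly; PI is symmetric in
#' its two distribution arguments.
#'
#' Contexts with zero weight are ignored. A context whose response row is
#' undefined (never observed) contributes 0 overlap.
#'
#' @param resp,presented `distribution_table`s of equal order over the
#'   same alphabet.
#' @param weights context weights (default: `presented$context_weights`).
#' @return List with `pi` (scalar) and `per_context` (named vector).
#' @export
performance_index <- function(resp, presented,
                              weights = presented$context_weights) {
  stopifnot(inherits(resp, "distribution_table"),
            inherits(presented, "distribution_table"))
  if (resp$order != presented$order)
    stop("order mismatch between response and presented tables")
  if (!identical(resp$alphabet, presented$alphabet))
    stop("alphabet mismatch between response and presented tables")
  n_ctx <- nrow(presented$q_table)
  per <- stats::setNames(numeric(n_ctx), rownames(presented$q_table))
  for (i in seq_len(n_ctx)) {
    r <- resp$q_table[i, ]
    p <- presented$q_table[i, ]
    per[i] <- if (anyNA(r) || anyNA(p)) 0 else sum(pmin(r, p))
  }
  use <- weights > 0
  list(pi = sum(per[use] * weights[use]), per_context = per)
}

#' Random-guess Performance Index baseline
#'
#' PI of a uniform responder (probability 1/4 for every target in every
#' context) against the source, weighted by the stationary context
#' distribution. For the default level-0 source this is .53 and for the
#' default level-1 source .45; subtracting it puts the two levels on a
#' common scale.
#'
#' @param source a `markov_source`.
#' @return Scalar PI in `[0, 1]`.
#' @export
random_guess_baseline <- function(source) {
  k <- length(source$alphabet)
  unif <- matrix(1 / k, nrow = nrow(source$prob_table), ncol = k,
                 dimnames = dimnames(source$prob_table))
  src <- source_distribution(source)
  resp <- distribution_table(source$order, source$alphabet, unif,
                             src$context_weights)
  performance_index(resp, src)$pi
}

#' Normalize a Performance Index by the random-guess baseline
#'
#' @param pi,pi_rand scalars in `[0, 1]`.
#' @return `pi - pi_rand` (may be negative).
#' @export
normalize_pi <- function(pi, pi_rand) {
  stopifnot(pi >= 0, pi <= 1, pi_rand >= 0, pi_rand <= 1)
  pi - pi_rand
}

#' Full performance record for a response dataset
#'
#' Convenience wrapper: response distribution, PI against the source,
#' random-guess baseline and normalized PI.
#'
#' @param data a `response_dataset`.
#' @param source the generating `markov_source`.
#' @param block optional block restriction.
#' @return A `performance_record`: list with `pi`, `pi_rand`,
#'   `pi_normalized`, `per_context_pi`.
#' @export
performance_record <- function(data, source, block = NULL) {
  resp <- response_distribution(data, source, block)
  src <- source_distribution(source)
  p <- performance_index(resp, src)
  pi_rand <- random_guess_baseline(source)
  structure(list(pi = p$pi, pi_rand = pi_rand,
                 pi_normalized = normalize_pi(p$pi, pi_rand),
                 per_context_pi = p$per_context),
            class = "performance_record")
}

#' @export
print.performance_record <- function(x, ...) {
  cat(sprintf("PI = %.4f  (random-guess baseline %.4f, normalized %+.4f)\n",
              x$pi, x$pi_rand, x$pi_normalized))
  invisible(x)
}

#' Probability-maximization model of a source
#'
#' The deterministic policy that always chooses the most probable target
#' in each context: probability 1 on the argmax, 0 elsewhere. A tie for
#' the maximum is an error (supply `tie_break` to resolve it explicitly,
#' as silent tie-breaking would make the strategy index irreproducible).
#'
#' @param source a `markov_source`.
#' @param tie_break optional preference order of symbols used only to
#'   resolve exact ties.
#' @return A `distribution_table` with one-hot rows.
#' @export
maximization_model <- function(source, tie_break = NULL) {
  P <- source$prob_table
  k <- ncol(P)
  M <- matrix(0, nrow(P), k, dimnames = dimnames(P))
  for (i in seq_len(nrow(P))) {
    m <- max(P[i, ])
    idx <- which(P[i, ] == m)
    if (length(idx) > 1) {
      if (is.null(tie_break))
        stop("tied maxima in context '", rownames(P)[i],
             "'; supply `tie_break` to resolve deterministically")
      idx <- idx[order(match(source$alphabet[idx], tie_break))][1]
    }
    M[i, idx] <- 1
  }
  w <- if (source$order == 0L) stats::setNames(1, "") else source$stationary
  distribution_table(source$order, source$alphabet, M, w)
}

# Matching model: the source's own conditional distribution.
matching_model <- function(source) source_distribution(source)

#' KL divergence from a model distribution to a response distribution
#'
#' `KL = sum_context M(context) sum_target M(t|c) log(M(t|c)/R(t|c))`
#' with `M` the model (matching or maximization) and `R` the responses.
#' Because deterministic responders put zero mass on model-positive
#' targets, `R` is epsilon-smoothed before the sum:
#' `R <- (R + eps) / (1 + k*eps)` per context row (k = alphabet size).
#' Context rows never observed are treated as uniform (with a warning).
#'
#' @param model,resp `distribution_table`s sharing order and alphabet.
#' @param weights context weights (default: the model's).
#' @param eps smoothing constant (> 0); a natural default is
#'   `1/(2 * trials per block)`.
#' @return Non-negative scalar.
#' @export
kl_model_to_responses <- function(model, resp, weights = model$context_weights,
                                  eps) {
  stopifnot(inherits(model, "distribution_table"),
            inherits(resp, "distribution_table"))
  if (model$order != resp$order) stop("order mismatch")
  if (!identical(model$alphabet, resp$alphabet)) stop("alphabet mismatch")
  if (eps <= 0) stop("`eps` must be > 0")
  k <- length(model$alphabet)
  total <- 0
  for (i in seq_len(nrow(model$q_table))) {
    w <- if (length(weights) == 1) weights else weights[i]
    if (w == 0) next
    m <- model$q_table[i, ]
    r <- resp$q_table[i, ]
    if (anyNA(r)) {
      warning("context '", rownames(model$q_table)[i],
              "' never observed in responses; treated as uniform")
      r <- rep(1 / k, k)
    }
    r <- (r + eps) / (1 + k * eps)
    pos <- m > 0
    total <- total + w * sum(m[pos] * log(m[pos] / r[pos]))
  }
  unname(total)
}

#' Strategy choice (delta-KL) of a response distribution
#'
#' `dKL = KL(matching model || R) - KL(maximization model || R)`.
#' Negative values mean the responses are closer to probability matching,
#' positive values closer to maximization. An exact matcher scores
#' `-KL(maximization || source)` (level 0: -ln(1/.72) = -.3285;
#' level 1: -ln(1/.8) = -.2231) in the small-eps limit.
#'
#' @param resp a response `distribution_table`.
#' @param source the generating `markov_source`.
#' @param eps smoothing constant passed to [kl_model_to_responses()].
#' @return Scalar delta-KL.
#' @export
strategy_choice <- function(resp, source, eps) {
  match_m <- matching_model(source)
  max_m <- maximization_model(source)
  kl_model_to_responses(match_m, resp, eps = eps) -
    kl_model_to_responses(max_m, resp, eps = eps)
}

#' Integral-curve-difference strategy index
#'
#' Computes the per-block strategy choice (delta-KL) curve and subtracts
#' the integral of the exact-matcher reference curve, giving the
#' integral curve difference (ICD): negative = matching-like, positive =
#' maximization-like. The matcher reference is the analytic constant
#' `-KL(maximization || source)` per block (the small-eps limit of an
#' exact matcher), so the index is deterministic given the responses.
#' Integration over blocks is rectangular (unit block width); set
#' `rule = "trapezoid"` for trapezoidal end-point weighting.
#'
#' @param data a `response_dataset` with one or more blocks.
#' @param source the generating `markov_source`.
#' @param eps smoothing constant; `NULL` (default) uses
#'   `1/(2 * median trials per block)`.
#' @param rule integration rule over blocks.
#' @return A `strategy_result`: list with `delta_kl_curve`,
#'   `matcher_curve`, `strategy_index`, `eps`.
#' @export
strategy_index <- function(data, source, eps = NULL,
                           rule = c("rectangular", "trapezoid")) {
  rule <- match.arg(rule)
  d <- as.data.frame(data)
  blocks <- sort(unique(d$block))
  if (!length(blocks)) stop("no blocks in response dataset")
  if (is.null(eps)) {
    n_per_block <- stats::median(table(d$block))
    eps <- 1 / (2 * n_per_block)
  }
  curve <- vapply(blocks, function(b) {
    strategy_choice(response_distribution(data, source, block = b), source, eps)
  }, numeric(1))
  # analytic matcher reference: dKL = 0 - KL(max || source)
  max_m <- maximization_model(source)
  src <- source_distribution(source)
  w <- src$context_weights
  kl_max_src <- 0
  for (i in seq_len(nrow(max_m$q_table))) {
    wi <- if (length(w) == 1) w else w[i]
    j <- which(max_m$q_table[i, ] == 1)
    kl_max_src <- kl_max_src + wi * log(1 / src$q_table[i, j])
  }
  matcher <- rep(-kl_max_src, length(blocks))
  integrate_blocks <- function(v) {
    if (rule == "rectangular" || length(v) < 2) sum(v)
    else sum(v) - (v[1] + v[length(v)]) / 2
  }
  icd <- unname(integrate_blocks(curve) - integrate_blocks(matcher))
  structure(list(delta_kl_curve = stats::setNames(curve, blocks),
                 matcher_curve = stats::setNames(matcher, blocks),
                 strategy_index = icd, eps = eps, rule = rule),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("Strategy index (ICD) = %+.4f  [%s]\n", x$strategy_index,
              if (x$strategy_index < 0) "matching-like" else "maximization-like"))
  cat("per-block dKL:", paste(sprintf("%+.3f", x$delta_kl_curve), collapse = " "), "\n")
  invisible(x)
}

#' Scale a level-0 strategy index to the level-1 maximization ceiling
#'
#' Multiplies a level-0 ICD by the ratio of the maximum PI attainable by
#' pure maximization under the level-1 source to that under the level-0
#' source (.8/.72 for the default sources), so that strategy indices can
#' be compared across levels without being confounded by the different
#' probability distributions.
#'
#' @param icd_level0 strategy index computed on level-0 data.
#' @param source0,source1 the two sources (defaults: the standard ones).
#' @return Scaled strategy index.
#' @export
scale_strategy_index <- function(icd_level0,
                                 source0 = default_source(0),
                                 source1 = default_source(1)) {
  stopifnot(is.finite(icd_level0))
  max_pi <- function(src) {
    performance_index(maximization_model(src), source_distribution(src))$pi
  }
  denom <- max_pi(source0)
  if (denom == 0) stop("maximization PI of the level-0 source is zero")
  icd_level0 * max_pi(source1) / denom
}

#' Residualize one variable on another
#'
#' Ordinary least-squares residuals of `y` regressed on `x` with an
#' intercept; used to control a strategy index for post-training
#' performance.
#'
#' @param y,x numeric vectors of equal length (>= 3).
#' @return Residual vector (mean zero).
#' @export
residualize <- function(y, x) {
  if (length(y) != length(x)) stop("`y` and `x` must have equal length")
  if (length(y) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("`x` is constant; cannot residualize")
  stats::lsfit(x, y)$residuals
}

#' Write / read trial-level response data as delimited text
#'
#' Tab-separated columns `block`, `trial`, `context`, `response`; an empty
#' response field marks a missing response.
#'
#' @param data a `response_dataset`.
#' @param path file path.
#' @return `path` (write) or a `response_dataset` (read).
#' @export
write_responses <- function(data, path) {
  d <- as.data.frame(data)
  d$trial <- stats::ave(seq_len(nrow(d)), d$block, FUN = seq_along)
  d$context[is.na(d$context)] <- ""
  d$response[is.na(d$response)] <- ""
  utils::write.table(d[, c("block", "trial", "context", "response")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @param level statistical level of the stored data.
#' @export
read_responses <- function(path, level) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("integer", "integer",
                                        "character", "character"))
  d$context[d$context == ""] <- NA_character_
  d$response[d$response == ""] <- NA_character_
  response_dataset(d$block, d$context, d$response, level)
}
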