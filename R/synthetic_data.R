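#' Synthetic agents, cohorts and timecourses
#'
#' Generators that emulate the study's inputs with known ground truth:
#' responder agents spanning the matching-maximization continuum, cohorts
#' of such agents, and HRF-convolved component timecourses with planted
#' condition betas, pairwise couplings and a planted correlation between
#' training-related beta change and strategy. Every downstream statistic
#' can therefore be checked by parameter recovery.
#'
#' @name synthetic_data
#' @keywords internal
NULL

#' Construct a responder agent
#'
#' Policies: `matcher` reproduces the source's conditional probabilities
#' (lambda = 0); `maximizer` always picks the most probable target
#' (lambda = 1); `uniform` guesses at random; `blend` mixes matcher and
#' maximizer with weight `lambda` toward maximization; `learner` starts
#' as a matcher and approaches maximization across blocks with
#' `lambda_b = 1 - exp(-rate * b)`.
#'
#' @param policy one of "matcher", "maximizer", "uniform", "blend",
#'   "learner".
#' @param lambda blend weight toward maximization (in `[0, 1]`).
#' @param learning_rate rate of the learner's approach to maximization
#'   (>= 0).
#' @return An `agent`.
#' @export
agent <- function(policy = c("matcher", "maximizer", "uniform", "blend",
                             "learner"),
                  lambda = 0, learning_rate = 0) {
  policy <- match.arg(policy)
  if (lambda < 0 || lambda > 1) stop("`lambda` must be in [0, 1]")
  if (learning_rate < 0) stop("`learning_rate` must be >= 0")
  lambda <- switch(policy, matcher = 0, maximizer = 1, blend = lambda,
                   uniform = NA_real_, learner = NA_real_)
  structure(list(policy = policy, lambda = lambda,
                 learning_rate = learning_rate),
            class = "agent")
}

# Response probability rows for an agent on a given block:
# (1 - lambda) * source row + lambda * one-hot(argmax).
agent_policy_rows <- function(ag, source, block) {
  P <- source$prob_table
  if (ag$policy == "uniform")
    return(matrix(1 / ncol(P), nrow(P), ncol(P), dimnames = dimnames(P)))
  lam <- switch(ag$policy,
                matcher = 0, maximizer = 1, blend = ag$lambda,
                learner = 1 - exp(-ag$learning_rate * block))
  M <- maximization_model(source)$q_table
  (1 - lam) * P + lam * M
}

#' Simulate trial-level prediction responses for an agent
#'
#' Per trial a context is drawn (from the stationary distribution for an
#' order-1 source; the null context for order 0) and a response sampled
#' from the agent's policy distribution for that context. With
#' probability `miss_rate` the response is recorded as missing, mimicking
#' trials where no response was given before the deadline.
#'
#' @param ag an [agent()].
#' @param source the `markov_source` defining the task statistics.
#' @param n_blocks,trials_per_block design size (defaults: 5 blocks of 56
#'   trials, one training session).
#' @param miss_rate probability of a missing response (default .02).
#' @return A `response_dataset`.
#' @export
simulate_responses <- function(ag, source, n_blocks = 5,
                               trials_per_block = 56, miss_rate = .02) {
  stopifnot(inherits(ag, "agent"), inherits(source, "markov_source"))
  if (miss_rate < 0 || miss_rate >= 1) stop("`miss_rate` must be in [0, 1)")
  k <- length(source$alphabet)
  blocks <- rep(seq_len(n_blocks), each = trials_per_block)
  n <- length(blocks)
  ctx_idx <- if (source$order == 0L) rep(1L, n)
             else sample.int(k, n, replace = TRUE, prob = source$stationary)
  resp <- character(n)
  for (b in seq_len(n_blocks)) {
    rows <- agent_policy_rows(ag, source, b)
    sel <- which(blocks == b)
    cum <- t(apply(rows, 1, cumsum))
    u <- stats::runif(length(sel))
    ri <- rowSums(u > cum[ctx_idx[sel], , drop = FALSE]) + 1L
    resp[sel] <- source$alphabet[ri]
  }
  resp[stats::runif(n) < miss_rate] <- NA_character_
  ctx <- if (source$order == 0L) rep(NA_character_, n)
         else source$alphabet[ctx_idx]
  response_dataset(blocks, ctx, resp, level = source$order)
}

#' Simulate a cohort of responders spanning the strategy continuum
#'
#' Each subject is a blend agent with weight `lambda` toward
#' maximization; by default the lambdas form an evenly spaced grid over
#' `[0, 1]` so the cohort spans matching to maximization. The true
#' lambdas are returned for recovery scoring.
#'
#' @param n_subjects cohort size (default 19).
#' @param source the `markov_source`.
#' @param lambdas per-subject blend weights (default: even grid on
#'   `[0, 1]`).
#' @param n_blocks,trials_per_block,miss_rate passed to
#'   [simulate_responses()].
#' @return List with `datasets` (list of `response_dataset`), `lambda`
#'   (true blend weights), `strategy` (estimated ICD per subject).
#' @export
simulate_cohort_behavior <- function(n_subjects = 19, source = default_source(0),
                                     lambdas = seq(0, 1, length.out = n_subjects),
                                     n_blocks = 5, trials_per_block = 56,
                                     miss_rate = .02) {
  if (n_subjects < 4) stop("`n_subjects` must be >= 4")
  stopifnot(length(lambdas) == n_subjects)
  datasets <- lapply(lambdas, function(l)
    simulate_responses(agent("blend", lambda = l), source,
                       n_blocks, trials_per_block, miss_rate))
  icd <- vapply(datasets, function(d)
    strategy_index(d, source)$strategy_index, numeric(1))
  list(datasets = datasets, lambda = lambdas, strategy = icd)
}

#' Simulate component timecourses with planted effects
#'
#' Generates, per subject x session x run x component, a timecourse
#'
#'   `beta_structured * X_s + beta_random * X_r + latent + nuisance + noise`
#'
#' where `X_s`, `X_r` are HRF-convolved condition boxcars, `latent` is a
#' shared component-pair signal that sets the planted pairwise
#' correlation, `nuisance` mixes the supplied-style motion/WM/CSF
#' regressors into the data, and `noise` is white. Post-training
#' structured betas are shifted by `coupling * strategy` (per subject, in
#' standardized units) so that the post-minus-pre beta change correlates
#' with the strategy score at the planted level.
#'
#' @param strategy per-subject strategy scores (any scale; standardized
#'   internally).
#' @param events a `block_event_table` describing one run.
#' @param n_components,n_runs,n_volumes,tr design geometry (defaults: 4
#'   components, 3 runs per session, 180 volumes, TR 2 s).
#' @param betas length-2 baseline betas (structured, random) shared by
#'   all components (default c(1, .5)).
#' @param coupling planted correlation (in `[-1, 1]`) between structured
#'   beta change and strategy (default -.7).
#' @param pairwise_r planted correlation between component pairs induced
#'   by the shared latent (default 0; set e.g. .6 to test FNC recovery).
#' @param noise_sd white-noise SD (default 1).
#' @param nuisance_sd SD of the nuisance contribution mixed into the data
#'   (default .5).
#' @param delta_scale SD of the beta change distribution (default .5).
#' @return List with `data` (nested subject -> session -> run: list of
#'   `tc` volumes x components matrix and `nuisance` matrix), `events`,
#'   `tr`, and ground truth `truth` (true betas per session, true beta
#'   change, strategy, coupling, pairwise_r).
#' @export
simulate_timecourses <- function(strategy, events,
                                 n_components = 4, n_runs = 3,
                                 n_volumes = 180, tr = 2,
                                 betas = c(structured = 1, random = .5),
                                 coupling = -.7, pairwise_r = 0,
                                 noise_sd = 1, nuisance_sd = .5,
                                 delta_scale = .5) {
  if (abs(coupling) > 1) stop("|coupling| must be <= 1")
  if (max(events$onset + events$duration) > n_volumes * tr)
    stop("event table extends beyond the acquisition (",
         n_volumes * tr, " s)")
  n_subj <- length(strategy)
  s_std <- if (n_subj >= 2 && stats::sd(strategy) > 0)
    as.numeric(scale(strategy)) else rep(0, n_subj)
  X <- build_design(as.data.frame(events), tr, n_volumes,
                    conditions = names(betas))
  # planted beta change for the structured condition: in-sample
  # correlation with strategy equals `coupling` exactly, via an
  # orthogonalized residual component
  eps <- stats::rnorm(n_subj)
  if (n_subj >= 3 && sum(s_std^2) > 0) {
    eps <- eps - s_std * sum(eps * s_std) / sum(s_std^2)
    eps <- as.numeric(scale(eps))
  } else if (n_subj < 2) {
    eps <- rep(0, n_subj)
  }
  d_beta <- delta_scale * (coupling * s_std + sqrt(1 - coupling^2) * eps)
  lat_sd <- if (pairwise_r > 0) sqrt(pairwise_r / (1 - pairwise_r)) else 0
  comp_names <- paste0("C", seq_len(n_components))
  subjects <- vector("list", n_subj)
  truth_beta <- array(NA_real_, c(n_subj, 2, length(betas)),
                      dimnames = list(NULL, c("pre", "post"), names(betas)))
  for (s in seq_len(n_subj)) {
    sess <- list()
    for (session in c("pre", "post")) {
      b <- betas
      if (session == "post") b["structured"] <- b["structured"] + d_beta[s]
      truth_beta[s, session, ] <- b
      runs <- vector("list", n_runs)
      for (r in seq_len(n_runs)) {
        latent <- stats::rnorm(n_volumes, sd = lat_sd * noise_sd)
        nuis <- matrix(stats::rnorm(n_volumes * 8), n_volumes, 8)
        tc <- sapply(seq_len(n_components), function(cc) {
          drop(X %*% b) + latent +
            nuis %*% stats::rnorm(8, sd = nuisance_sd / sqrt(8)) +
            stats::rnorm(n_volumes, sd = noise_sd)
        })
        colnames(tc) <- comp_names
        runs[[r]] <- list(tc = tc, nuisance = nuis)
      }
      sess[[session]] <- runs
    }
    subjects[[s]] <- sess
  }
  list(data = subjects, events = events, tr = tr,
       truth = list(beta = truth_beta, delta_beta = d_beta,
                    strategy = strategy, coupling = coupling,
                    pairwise_r = pairwise_r),
       n_components = n_components, n_runs = n_runs,
       n_volumes = n_volumes)
}

#' Session-level structured/random betas for every subject and component
#'
#' Runs [clean_timecourse()] and [glm_betas()] over the nested output of
#' [simulate_timecourses()] (or identically shaped real data), averaging
#' run betas per session.
#'
#' @param sim output of [simulate_timecourses()].
#' @return Array subjects x sessions x conditions x components.
#' @export
pipeline_betas <- function(sim) {
  conds <- sort(unique(sim$events$condition))
  n_subj <- length(sim$data)
  X <- build_design(as.data.frame(sim$events), sim$tr, sim$n_volumes,
                    conditions = conds)
  out <- array(NA_real_, c(n_subj, 2, length(conds), sim$n_components),
               dimnames = list(NULL, c("pre", "post"), conds,
                               paste0("C", seq_len(sim$n_components))))
  for (s in seq_len(n_subj)) {
    for (session in c("pre", "post")) {
      runs <- sim$data[[s]][[session]]
      for (cc in seq_len(sim$n_components)) {
        B <- vapply(runs, function(rn)
          fit_betas(clean_timecourse(rn$tc[, cc], rn$nuisance), X),
          numeric(length(conds)))
        out[s, session, , cc] <- rowMeans(B)[conds]
      }
    }
  }
  out
}

#' Synthetic spatial maps and tissue masks for component selection
#'
#' Builds smooth random grey-matter, white-matter and CSF probability
#' volumes on a small grid, plus component statistic maps whose overlap
#' with a chosen tissue is controlled, so the selection rule of
#' [select_components()] can be exercised with known intended decisions.
#'
#' @param grid_shape integer length-3 grid (each >= 8).
#' @param overlaps named numeric vector: for each fixture map, the
#'   fraction of its activation placed inside the named tissue; names
#'   are "gm", "wm" or "csf" (default one pure-GM and one pure-CSF map).
#' @return List with `maps` (list of 3-D arrays), `gm`, `wm`, `csf`
#'   volumes, and `intended_keep` logical vector.
#' @export
make_fixture_maps <- function(grid_shape = c(12, 12, 12),
                              overlaps = c(gm = 1, csf = 1)) {
  if (any(grid_shape < 8)) stop("grid must be at least 8 voxels per axis")
  smooth3 <- function(a) {
    # separable 3-point box smoothing along each axis
    for (ax in 1:3) {
      idx <- seq_len(dim(a)[ax])
      lo <- pmax(idx - 1, 1); hi <- pmin(idx + 1, dim(a)[ax])
      perm <- c(ax, setdiff(1:3, ax))
      m <- aperm(a, perm)
      m <- (m[lo, , , drop = FALSE] + m + m[hi, , , drop = FALSE]) / 3
      a <- aperm(m, order(perm))
    }
    a
  }
  rescale01 <- function(v) (v - min(v)) / (max(v) - min(v))
  rnd_vol <- function() smooth3(array(stats::runif(prod(grid_shape)), grid_shape))
  # three smooth probability fields, made exactly uncorrelated voxelwise;
  # unlike real tissue priors they carry no mutual (anti-)correlation,
  # which isolates the selection rule from incidental tissue overlap
  gm <- rnd_vol(); wm <- rnd_vol(); csf <- rnd_vol()
  v <- cbind(as.vector(gm), as.vector(wm), as.vector(csf))
  v <- scale(v, scale = FALSE)
  v[, 2] <- stats::lsfit(v[, 1], v[, 2])$residuals
  v[, 3] <- stats::lsfit(v[, 1:2], v[, 3])$residuals
  gm <- rescale01(array(v[, 1], grid_shape))
  wm <- rescale01(array(v[, 2], grid_shape))
  csf <- rescale01(array(v[, 3], grid_shape))
  tissues <- list(gm = gm, wm = wm, csf = csf)
  n_sites <- 200
  maps <- vector("list", length(overlaps))
  intended <- logical(length(overlaps))
  for (i in seq_along(overlaps)) {
    tissue <- names(overlaps)[i]
    frac <- overlaps[i]
    inside <- tissues[[tissue]] > stats::quantile(tissues[[tissue]], .8)
    act <- array(stats::rnorm(prod(grid_shape), sd = .2), grid_shape)
    n_in <- round(frac * n_sites)
    act[sample(which(inside), min(n_in, sum(inside)))] <- 5
    if (n_sites - n_in > 0)
      act[sample(which(!inside), min(n_sites - n_in, sum(!inside)))] <- 5
    maps[[i]] <- act
    intended[i] <- tissue == "gm" && frac >= .75
  }
  list(maps = maps, gm = gm, wm = wm, csf = csf, intended_keep = intended,
       overlaps = overlaps)
}
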