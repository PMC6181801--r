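#' Pipeline configuration and the umbrella runner
#'
#' A `PipelineConfig` gathers every tunable of the pipeline - source
#' definitions, design sizes, smoothing and bootstrap settings, seeds -
#' with the study's defaults filled in for absent keys. Configs are plain
#' YAML on disk and round-trip losslessly.
#'
#' @name cli_io
#' @keywords internal
NULL

#' Default pipeline configuration
#'
#' Defaults mirror the study design: level-0 symbol probabilities
#' (.18, .72, .05, .05); the canonical cyclic level-1 matrix with .8/.2
#' successors; 5 blocks of 56 trials per session; 10,000 candidate
#' sequences of 672 symbols with 50 selected; training sequence lengths
#' 8-14 and scanning length 10; 1000 bootstrap resamples; a cohort of 19
#' subjects; TR 2 s.
#'
#' @return A named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    level0_probs = c(.18, .72, .05, .05),
    level1_matrix = default_level1_matrix(),
    alphabet = DEFAULT_ALPHABET,
    trials_per_block = 56L,
    n_blocks = 5L,
    seq_length_train = c(8L, 14L),
    seq_length_scan = 10L,
    n_candidates = 10000L,
    n_select = 50L,
    candidate_length = 672L,
    eps = "auto",
    n_boot = 1000L,
    hrf = list(peak = 6, undershoot = 16, ratio = 1 / 6, duration = 32),
    tr = 2,
    n_subjects = 19L,
    n_components = 4L,
    n_runs = 3L,
    n_volumes = 180L,
    coupling = -.7,
    miss_rate = .02,
    noise_sd = 1,
    seed = 1L
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Absent keys are filled from [default_config()]; unknown keys are an
#' error (listing them), as are invalid probability vectors or transition
#' matrices. An empty file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  for (k in names(user)) cfg[[k]] <- user[[k]]
  if (is.list(cfg$level1_matrix))
    cfg$level1_matrix <- do.call(rbind, cfg$level1_matrix)
  # validation via the source constructors
  build_level0_source(cfg$level0_probs, cfg$alphabet)
  build_level1_source(cfg$level1_matrix, cfg$alphabet)
  counts <- c("trials_per_block", "n_blocks", "n_candidates", "n_select",
              "candidate_length", "n_boot", "n_subjects", "n_components",
              "n_runs", "n_volumes")
  for (k in counts)
    if (any(cfg[[k]] <= 0)) stop("config key `", k, "` must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Save a pipeline configuration to YAML
#'
#' @param cfg a `pipeline_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  c2 <- unclass(cfg)
  c2$level1_matrix <- apply(cfg$level1_matrix, 1, as.numeric, simplify = FALSE)
  yaml::write_yaml(c2, path, precision = 15)
  invisible(path)
}

# Stable hash of a config for provenance stamps.
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

# Deterministic per-stage child seeds below 2^31.
stage_seed <- function(root_seed, stage) {
  offsets <- c(generate = 101L, behavior = 211L, timecourses = 307L,
               fnc = 401L, correlate = 503L)
  as.integer((as.numeric(root_seed) * 1009 + offsets[[stage]]) %% 2147483647)
}

#' Run the full synthetic pipeline
#'
#' Executes the stages end to end on synthetic data: sequence generation
#' and KL selection (scaled down by default), cohort behavior simulation
#' and scoring (PI, strategy index), timecourse simulation, session
#' betas, FNC, and the strategy-brain correlation. Writes a JSON report
#' with per-stage seeds and the config hash when `out` is given;
#' identical config and seed reproduce identical reports.
#'
#' @param cfg a `pipeline_config`.
#' @param out optional path for the JSON report.
#' @param n_candidates override for the sequence-selection stage (the
#'   full 10,000 x 672 selection takes minutes; the demo default is 200).
#' @return The report as a list, invisibly if `out` is given.
#' @export
run_pipeline <- function(cfg = default_config(), out = NULL,
                         n_candidates = 200L) {
  stopifnot(inherits(cfg, "pipeline_config"))
  src0 <- build_level0_source(cfg$level0_probs, cfg$alphabet)
  src1 <- build_level1_source(cfg$level1_matrix, cfg$alphabet)

  set.seed(stage_seed(cfg$seed, "generate"))
  seqs <- select_sequences(src0, n_candidates, cfg$candidate_length,
                           min(cfg$n_select, n_candidates))

  set.seed(stage_seed(cfg$seed, "behavior"))
  cohort <- simulate_cohort_behavior(
    cfg$n_subjects, src0,
    n_blocks = cfg$n_blocks, trials_per_block = cfg$trials_per_block,
    miss_rate = cfg$miss_rate)
  pi_records <- lapply(cohort$datasets, performance_record, source = src0)

  events <- demo_events(cfg$n_volumes, cfg$tr)
  set.seed(stage_seed(cfg$seed, "timecourses"))
  sim <- simulate_timecourses(cohort$strategy, events,
                              n_components = cfg$n_components,
                              n_runs = cfg$n_runs,
                              n_volumes = cfg$n_volumes, tr = cfg$tr,
                              coupling = cfg$coupling,
                              noise_sd = cfg$noise_sd)
  betas <- pipeline_betas(sim)

  set.seed(stage_seed(cfg$seed, "fnc"))
  fnc_pre <- lapply(sim$data, function(subj)
    fnc_matrix(lapply(subj$pre, function(rn)
      apply(rn$tc, 2, clean_timecourse, nuisance = rn$nuisance))))

  set.seed(stage_seed(cfg$seed, "correlate"))
  d_beta <- betas[, "post", "structured", 1] - betas[, "pre", "structured", 1]
  corr <- strategy_brain_correlation(d_beta, cohort$strategy,
                                     n_boot = cfg$n_boot)

  report <- list(
    provenance = list(seed = cfg$seed, config_hash = config_hash(cfg),
                      package_version = as.character(utils::packageVersion("predstat"))),
    sequences = list(n_candidates = n_candidates,
                     n_selected = sum(seqs$selected),
                     kl_selected_max = max(seqs$kl_scores[seqs$selected])),
    behavior = list(
      pi = vapply(pi_records, `[[`, numeric(1), "pi"),
      pi_rand_level0 = random_guess_baseline(src0),
      pi_rand_level1 = random_guess_baseline(src1),
      strategy_index = cohort$strategy,
      lambda_true = cohort$lambda),
    brain = list(
      delta_beta_structured = unname(d_beta),
      mean_fnc_z = mean(vapply(fnc_pre, function(z)
        mean(z[upper.tri(z)]), numeric(1))),
      strategy_correlation = list(r = corr$r, ci = c(corr$ci_low, corr$ci_high),
                                  significant = corr$significant,
                                  n_outliers = sum(corr$outlier_flags)))
  )
  if (!is.null(out)) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}

#' Demonstration block-event table
#'
#' Alternating structured and random blocks of 20 s separated by 10 s
#' rest, filling the acquisition.
#'
#' @param n_volumes,tr acquisition geometry.
#' @param block_s,rest_s block and rest durations in seconds.
#' @return A `block_event_table`.
#' @export
demo_events <- function(n_volumes, tr, block_s = 20, rest_s = 10) {
  total <- n_volumes * tr
  onsets <- seq(rest_s, total - block_s, by = block_s + rest_s)
  cond <- rep(c("structured", "random"), length.out = length(onsets))
  block_event_table(cond, onsets, rep(block_s, length(onsets)))
}
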