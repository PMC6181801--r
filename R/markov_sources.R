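#' Markov stimulus sources
#'
#' A `markov_source` describes the stochastic source that emits stimulus
#' sequences in a serial prediction experiment: either a memory-less
#' (order k = 0) symbol distribution, or a first-order (k = 1) chain where
#' the previous symbol (the *context*) determines the distribution of the
#' next symbol (the *target*).
#'
#' @name markov_source
#' @keywords internal
NULL

DEFAULT_ALPHABET <- c("A", "B", "C", "D")

new_markov_source <- function(order, alphabet, prob_table, stationary) {
  structure(
    list(order = order, alphabet = alphabet,
         prob_table = prob_table, stationary = stationary),
    class = "markov_source"
  )
}

#' Build a zero-order (memory-less) Markov source
#'
#' @param probs numeric vector of length 4: occurrence probability of each
#'   symbol. Must be non-negative and sum to 1 (tolerance 1e-9).
#' @param alphabet character vector of 4 symbol names.
#' @return A `markov_source` with `order = 0`; the stationary distribution
#'   equals `probs`.
#' @examples
#' build_level0_source(c(.18, .72, .05, .05))
#' @export
build_level0_source <- function(probs, alphabet = DEFAULT_ALPHABET) {
  probs <- as.numeric(probs)
  if (length(probs) != length(alphabet))
    stop("`probs` must have one entry per symbol (", length(alphabet), ")")
  neg <- which(probs < 0)
  if (length(neg))
    stop("negative probability for symbol '", alphabet[neg[1]], "': ", probs[neg[1]])
  if (abs(sum(probs) - 1) > 1e-9)
    stop("`probs` must sum to 1 (got ", format(sum(probs), digits = 12), ")")
  names(probs) <- alphabet
  tab <- matrix(probs, nrow = 1, dimnames = list("", alphabet))
  new_markov_source(0L, alphabet, tab, probs)
}

#' Build a first-order Markov source
#'
#' Rows of `T` are contexts (the previous symbol), columns are targets.
#' The experimental design requires that each context allows exactly two
#' successors (a likely and an unlikely one) and that the chain's marginal
#' symbol frequencies are uniform; a warning is emitted if the stationary
#' distribution deviates from uniform by more than `1e-6`.
#'
#' @param T 4x4 row-stochastic matrix `P(target | context)` with exactly
#'   two nonzero entries per row.
#' @param alphabet character vector of 4 symbol names.
#' @return A `markov_source` with `order = 1`; `stationary` is the
#'   principal left eigenvector of `T`, normalized to sum to 1.
#' @examples
#' build_level1_source(default_level1_matrix())
#' @export
build_level1_source <- function(T, alphabet = DEFAULT_ALPHABET) {
  T <- as.matrix(T)
  k <- length(alphabet)
  if (!all(dim(T) == k))
    stop("`T` must be a ", k, "x", k, " matrix")
  dimnames(T) <- list(alphabet, alphabet)
  for (i in seq_len(k)) {
    row <- T[i, ]
    if (any(row < 0))
      stop("negative probability in row '", alphabet[i], "'")
    if (abs(sum(row) - 1) > 1e-9)
      stop("row '", alphabet[i], "' must sum to 1 (got ",
           format(sum(row), digits = 12), ")")
    nz <- sum(row > 0)
    if (nz != 2)
      stop("row '", alphabet[i], "' has ", nz,
           " nonzero entries; the design requires exactly 2 successors per context")
  }
  stat <- stationary_distribution(T)
  if (max(abs(stat - 1 / k)) > 1e-6)
    warning("stationary distribution deviates from uniform; ",
            "the design requires uniform marginal symbol frequencies")
  new_markov_source(1L, alphabet, T, stat)
}

# Principal left eigenvector of a row-stochastic matrix, normalized.
stationary_distribution <- function(T) {
  e <- eigen(t(T))
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10))
    stop("stationary distribution has negative entries; matrix is not a valid chain")
  v[v < 0] <- 0
  stats::setNames(v / sum(v), colnames(T))
}

#' Canonical first-order transition matrix
#'
#' The cyclic two-successor structure used for context-based sequences:
#' each symbol is followed by one of two successors, the likely one with
#' probability .8 and the unlikely one with .2
#' (A -> B/.8, C/.2; B -> C/.8, D/.2; C -> D/.8, A/.2; D -> A/.8, B/.2).
#' All column sums equal 1, so the stationary distribution is exactly
#' uniform and every symbol appears with marginal probability .25.
#'
#' @param alphabet character vector of 4 symbol names.
#' @return A 4x4 row-stochastic matrix.
#' @export
default_level1_matrix <- function(alphabet = DEFAULT_ALPHABET) {
  T <- matrix(0, 4, 4, dimnames = list(alphabet, alphabet))
  succ <- c(2L, 3L, 4L, 1L)          # likely successor: next symbol in the cycle
  alt  <- c(3L, 4L, 1L, 2L)          # unlikely successor: two ahead
  for (i in 1:4) {
    T[i, succ[i]] <- .8
    T[i, alt[i]]  <- .2
  }
  T
}

#' Default sources for the two statistical levels
#'
#' Level 0: symbol probabilities (.18, .72, .05, .05) - one frequent symbol,
#' one less frequent, two rare. Level 1: the canonical cyclic matrix of
#' [default_level1_matrix()].
#'
#' @param level 0 or 1.
#' @return A `markov_source`.
#' @export
default_source <- function(level) {
  if (level == 0) build_level0_source(c(.18, .72, .05, .05))
  else if (level == 1) build_level1_source(default_level1_matrix())
  else stop("`level` must be 0 or 1")
}

#' @export
print.markov_source <- function(x, ...) {
  cat("Markov source (order ", x$order, "), alphabet: ",
      paste(x$alphabet, collapse = " "), "\n", sep = "")
  print(round(x$prob_table, 4))
  cat("stationary:", paste(format(round(x$stationary, 4)), collapse = " "), "\n")
  invisible(x)
}

#' Generate a symbol sequence from a Markov source
#'
#' For a zero-order source symbols are drawn i.i.d. from the symbol
#' distribution; for a first-order source a chain is run from an initial
#' context (drawn from the stationary distribution if not supplied).
#' Results are reproducible under `set.seed()`.
#'
#' @param source a `markov_source`.
#' @param length number of symbols (>= 1).
#' @param initial_context optional starting context symbol (order-1 only).
#' @return Character vector of symbols with attribute `source_order`.
#' @export
generate_sequence <- function(source, length, initial_context = NULL) {
  stopifnot(inherits(source, "markov_source"))
  if (length < 1) stop("`length` must be >= 1")
  k <- base::length(source$alphabet)
  if (source$order == 0L) {
    idx <- sample.int(k, length, replace = TRUE, prob = source$prob_table[1, ])
  } else {
    if (is.null(initial_context)) {
      ctx <- sample.int(k, 1, prob = source$stationary)
    } else {
      ctx <- match(initial_context, source$alphabet)
      if (is.na(ctx)) stop("`initial_context` '", initial_context,
                           "' is not in the source alphabet")
    }
    cum <- t(apply(source$prob_table, 1, cumsum))
    u <- stats::runif(length)
    idx <- integer(length)
    for (i in seq_len(length)) {
      ctx <- sum(u[i] > cum[ctx, ]) + 1L
      idx[i] <- ctx
    }
  }
  out <- source$alphabet[idx]
  attr(out, "source_order") <- source$order
  out
}

#' Empirical symbol or transition distribution of a sequence
#'
#' For `order = 0`, relative symbol frequencies. For `order = 1`,
#' transition frequencies conditioned on each observed context;
#' `context_weights` are the observed context frequencies. Contexts never
#' observed are left undefined (`NA` row), not zero-filled.
#'
#' @param seq character vector of symbols.
#' @param order 0 or 1.
#' @param alphabet symbol names (default: the standard 4-symbol set).
#' @return A `distribution_table` (see [distribution_table()]).
#' @export
empirical_distribution <- function(seq, order, alphabet = DEFAULT_ALPHABET) {
  if (!length(seq)) stop("empty sequence")
  if (!order %in% c(0, 1)) stop("`order` must be 0 or 1")
  if (length(seq) <= order) stop("sequence too short for order ", order)
  idx <- match(seq, alphabet)
  if (anyNA(idx))
    stop("symbol '", seq[which(is.na(idx))[1]], "' not in alphabet")
  k <- length(alphabet)
  if (order == 0) {
    counts <- tabulate(idx, nbins = k)
    q <- matrix(counts / sum(counts), nrow = 1, dimnames = list("", alphabet))
    distribution_table(0L, alphabet, q, stats::setNames(1, ""),
                       n_obs = stats::setNames(length(seq), ""))
  } else {
    from <- idx[-length(idx)]
    to <- idx[-1]
    counts <- matrix(0, k, k, dimnames = list(alphabet, alphabet))
    for (t in seq_along(from)) counts[from[t], to[t]] <- counts[from[t], to[t]] + 1
    n_ctx <- rowSums(counts)
    q <- counts / ifelse(n_ctx > 0, n_ctx, NA_real_)
    q[n_ctx == 0, ] <- NA_real_
    distribution_table(1L, alphabet, q, n_ctx / sum(n_ctx), n_obs = n_ctx)
  }
}

#' Context-conditional probability table
#'
#' Shared container for source-, sequence- and response-derived
#' distributions: a contexts x targets matrix of conditional probabilities
#' plus a weight for each context. Zero-order tables use a single null
#' context (`""`) with weight 1. Undefined contexts (never observed) carry
#' `NA` rows.
#'
#' @param order Markov order (0 or 1).
#' @param alphabet target symbol names.
#' @param q_table contexts x targets matrix; each defined row sums to 1.
#' @param context_weights named non-negative weights summing to 1.
#' @param n_obs optional observation counts per context.
#' @return An object of class `distribution_table`.
#' @export
distribution_table <- function(order, alphabet, q_table, context_weights,
                               n_obs = NULL) {
  q_table <- as.matrix(q_table)
  colnames(q_table) <- alphabet
  for (i in seq_len(nrow(q_table))) {
    row <- q_table[i, ]
    if (!anyNA(row) && abs(sum(row) - 1) > 1e-12 * max(1, sum(abs(row))))
      if (abs(sum(row) - 1) > 1e-9)
        stop("row ", i, " of `q_table` does not sum to 1")
  }
  if (abs(sum(context_weights) - 1) > 1e-9)
    stop("`context_weights` must sum to 1")
  structure(
    list(order = as.integer(order), alphabet = alphabet, q_table = q_table,
         context_weights = context_weights, n_obs = n_obs),
    class = "distribution_table"
  )
}

#' @export
print.distribution_table <- function(x, ...) {
  cat("Distribution table (order ", x$order, ")\n", sep = "")
  print(round(x$q_table, 4))
  invisible(x)
}

# The source's own conditional table, as a distribution_table weighted by
# its stationary context distribution.
source_distribution <- function(source) {
  if (source$order == 0L) {
    distribution_table(0L, source$alphabet, source$prob_table,
                       stats::setNames(1, ""))
  } else {
    distribution_table(1L, source$alphabet, source$prob_table,
                       source$stationary)
  }
}

#' Kullback-Leibler divergence of a sequence's empirical distribution
#' from its generating source
#'
#' Measures how representative a sequence is of its source:
#' `KL = sum_target Q(target) log(Q(target)/P(target))` for order 0, and
#' the context-weighted analogue
#' `KL = sum_context Q(context) sum_target Q(t|c) log(Q(t|c)/P(t|c))`
#' for order 1, where `Q` is the source and `P` the empirical distribution.
#' Context weights `Q(context)` come from the source's stationary
#' distribution. Natural logarithm. Returns `+Inf` when the sequence
#' assigns zero (or undefined) probability to a source-positive target.
#'
#' @param source a `markov_source`.
#' @param emp a `distribution_table` of matching order (e.g. from
#'   [empirical_distribution()]).
#' @return Non-negative scalar (possibly `Inf`).
#' @export
kl_to_source <- function(source, emp) {
  stopifnot(inherits(source, "markov_source"),
            inherits(emp, "distribution_table"))
  if (source$order != emp$order)
    stop("order mismatch: source is order ", source$order,
         ", empirical table is order ", emp$order)
  Q <- source$prob_table
  P <- emp$q_table
  w <- if (source$order == 0L) 1 else source$stationary
  total <- 0
  for (i in seq_len(nrow(Q))) {
    if (w[i] == 0) next
    q <- Q[i, ]
    p <- P[i, ]
    pos <- q > 0
    if (anyNA(p[pos]) || any(p[pos] == 0)) return(Inf)
    total <- total + w[i] * sum(q[pos] * log(q[pos] / p[pos]))
  }
  total
}

#' Generate candidate sequences and keep those closest to the source
#'
#' Generates `n_candidates` sequences, scores each with [kl_to_source()],
#' and flags the `n_select` with the lowest KL divergence (ties broken by
#' generation index; infinite scores sort last). Deterministic under
#' `set.seed()`.
#'
#' @param source a `markov_source`.
#' @param n_candidates number of sequences to generate.
#' @param length symbols per sequence.
#' @param n_select number to keep (<= `n_candidates`).
#' @return A `sequence_set`: list with `sequences` (list of character
#'   vectors), `kl_scores`, and logical `selected`.
#' @export
select_sequences <- function(source, n_candidates, length, n_select) {
  if (n_select > n_candidates)
    stop("`n_select` (", n_select, ") exceeds `n_candidates` (", n_candidates, ")")
  sequences <- vector("list", n_candidates)
  kl <- numeric(n_candidates)
  for (i in seq_len(n_candidates)) {
    s <- generate_sequence(source, length)
    sequences[[i]] <- s
    kl[i] <- kl_to_source(source, empirical_distribution(s, source$order,
                                                         source$alphabet))
  }
  # order() with radix sort is stable: ties keep generation order; Inf last
  ord <- order(kl, method = "radix")
  selected <- logical(n_candidates)
  selected[ord[seq_len(n_select)]] <- TRUE
  structure(list(sequences = sequences, kl_scores = kl, selected = selected,
                 source_order = source$order),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("Sequence set: ", length(x$sequences), " candidates, ",
      sum(x$selected), " selected\n", sep = "")
  cat("KL of selected: [",
      format(min(x$kl_scores[x$selected]), digits = 4), ", ",
      format(max(x$kl_scores[x$selected]), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Write / read sequence sets as delimited text
#'
#' One sequence per row as a symbol string, with a JSON sidecar recording
#' KL scores and selection flags.
#'
#' @param x a `sequence_set`.
#' @param path output file for the sequences; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path) {
  lines <- vapply(x$sequences, paste, "", collapse = "")
  writeLines(lines, path)
  jsonlite::write_json(
    list(kl_scores = x$kl_scores, selected = x$selected,
         source_order = x$source_order),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sequences
#' @export
read_sequences <- function(path) {
  lines <- readLines(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(sequences = lapply(strsplit(lines, ""), identity),
                 kl_scores = meta$kl_scores,
                 selected = meta$selected,
                 source_order = meta$source_order),
            class = "sequence_set")
}
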