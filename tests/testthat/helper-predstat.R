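# Shared fixtures built in code.

src0 <- default_source(0)
src1 <- default_source(1)

# A response dataset whose per-context response frequencies equal a given
# probability table exactly (counts proportional to probabilities).
exact_response_dataset <- function(probs, n_per = 100, block = 1L) {
  counts <- round(probs * n_per)
  resp <- rep(names(probs), counts)
  response_dataset(rep(block, length(resp)), rep(NA_character_, length(resp)),
                   resp, level = 0L)
}

# Distribution table matching a source's own conditional probabilities
# (an idealized exact matcher).
matcher_table <- function(source) {
  w <- if (source$order == 0L) stats::setNames(1, "") else source$stationary
  distribution_table(source$order, source$alphabet, source$prob_table, w)
}

# Uniform responder table over the source's contexts.
uniform_table <- function(source) {
  k <- length(source$alphabet)
  q <- matrix(1 / k, nrow(source$prob_table), k,
              dimnames = dimnames(source$prob_table))
  w <- if (source$order == 0L) stats::setNames(1, "") else source$stationary
  distribution_table(source$order, source$alphabet, q, w)
}
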