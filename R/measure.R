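#' Born-rule measurement with collapse
#'
#' Measuring a mental state in its label basis yields outcome \eqn{i} with
#' probability \eqn{|a_i|^2}; the state then collapses (a non-unitary change)
#' to the basis state \eqn{|i\rangle}. Sampling is driven by one explicit
#' integer seed per call, with no hidden global state: the same seed always
#' reproduces the same outcome.
#'
#' @param state a normalized [qm_state].
#' @param seed integer seed for the draw, or `NULL` to use the current RNG
#'   stream.
#' @param observable_basis basis defining the measurement outcomes; must equal
#'   the state's basis (measurement is restricted to the label basis).
#' @return a list with `outcome` (the sampled label) and `state` (the
#'   post-measurement basis state).
#' @examples
#' b <- qm_basis(c("up", "down"))
#' collapse(qm_state(b, c(1, 0)), seed = 1)$outcome  # always "up"
#' @export
collapse <- function(state, seed = NULL, observable_basis = state$basis) {
  check_same_basis(observable_basis, state$basis, "observable basis and state")
  if (!is_normalized(state)) {
    qm_stop("measurement requires a normalized state", "qm_normalization_error")
  }
  outcome <- collapse_draws(state, n = 1L, seed = seed)
  list(outcome = outcome, state = basis_state(state$basis, outcome))
}

#' Repeated seeded Born draws
#'
#' Draws `n` independent measurement outcomes from the Born distribution of
#' `state`. Used for frequency checks against \eqn{|a_i|^2}.
#'
#' @param state a normalized [qm_state].
#' @param n number of draws.
#' @param seed integer seed, or `NULL` for the current RNG stream.
#' @return character vector of `n` outcome labels.
#' @export
collapse_draws <- function(state, n, seed = NULL) {
  if (!is_normalized(state)) {
    qm_stop("measurement requires a normalized state", "qm_normalization_error")
  }
  probs <- born_weights(state)
  probs <- probs / sum(probs)
  draw <- function() {
    sample(state$basis$labels, size = n, replace = TRUE, prob = probs)
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Goodness of fit of observed collapse frequencies to Born probabilities
#'
#' Chi-square test of observed outcome counts against the Born distribution
#' of the state. Outcomes with zero Born probability must not occur; if they
#' do, the fit fails with p = 0.
#'
#' @param state the measured [qm_state].
#' @param outcomes character vector of observed outcome labels.
#' @return the chi-square p-value.
#' @export
born_fit_pvalue <- function(state, outcomes) {
  probs <- born_weights(state)
  probs <- probs / sum(probs)
  counts <- table(factor(outcomes, levels = state$basis$labels))
  if (any(counts[probs == 0] > 0)) return(0)
  keep <- probs > 0
  stats::chisq.test(as.vector(counts[keep]), p = probs[keep])$p.value
}
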