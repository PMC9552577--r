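# Shared generators and independent oracles for the test suite.

# random normalized state over a basis; complex amplitudes unless real = TRUE
rand_state <- function(basis, seed, real = FALSE) {
  withr::with_seed(seed, {
    n <- basis$dimension
    amps <- stats::rnorm(n)
    if (!real) amps <- complex(real = amps, imaginary = stats::rnorm(n))
    qm_state(basis, amps, normalize = TRUE)
  })
}

rand_basis <- function(n, prefix = "x") {
  qm_basis(sprintf("%s%02d", prefix, seq_len(n)))
}

# brute-force variance of a diagonal observable: dense matrix arithmetic,
# independent of the divergence() code path
brute_force_variance <- function(state, op_matrix) {
  a <- state$amplitudes
  m1 <- Re(sum(Conj(a) * (op_matrix %*% a)))
  m2 <- Re(sum(Conj(a) * (op_matrix %*% op_matrix %*% a)))
  m2 - m1^2
}

# brute-force evaluation of the cross-concept projection double sum
# sum_{i,j} p_i e_j <j|i> |j>, as an explicit double loop
brute_force_projection <- function(source, target, overlap) {
  p <- source$state$amplitudes
  e <- target$state$amplitudes
  out <- rep(0+0i, length(e))
  for (j in seq_along(e)) {
    for (i in seq_along(p)) {
      out[j] <- out[j] + p[i] * e[j] * overlap[i, j]
    }
  }
  names(out) <- target$state$basis$labels
  out
}

# default literal-label-match overlap matrix for two concepts
default_overlap <- function(source, target) {
  src <- source$state$basis$labels
  tgt <- target$state$basis$labels
  m <- outer(src, tgt, function(i, j) as.complex(i == j))
  dimnames(m) <- list(src, tgt)
  m
}

# arrow glyphs used in conceptual-change tables
ARROW_UP <- "\u2191"
ARROW_DOWN <- "\u2193"
ARROW_FLAT <- "\u2212"

# four-label basis whose labels differ in exactly one membership each:
# "grounded" (observation only), "anchor" (observation + salient),
# "goal" (context only), "idle" (no memberships). Moving mass between a
# matched pair changes exactly one of the three measures.
orthogonality_family <- function() {
  b <- qm_basis(c("grounded", "anchor", "goal", "idle"))
  list(
    basis = b,
    obs = qm_observation_set(b, c("grounded", "anchor")),
    ctx = qm_context("goal", "goal"),
    obsv = qm_divergence_observable(b, mode = "projector",
                                    salient_labels = "anchor")
  )
}
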