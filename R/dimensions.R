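#' Observation sets
#'
#' The set of direct observations and experiences \eqn{\{|O_n\rangle\}}: the
#' purely concrete basis labels a person has experienced with their senses.
#' The abstractness of a thought is measured against this set.
#'
#' @param basis a [qm_basis].
#' @param labels non-empty subset of basis labels flagged as observations.
#' @return an object of class `qm_observation_set`.
#' @export
qm_observation_set <- function(basis, labels) {
  labels <- unique(as.character(labels))
  if (length(labels) == 0L) {
    qm_stop("an observation set needs at least one label",
            "qm_empty_subspace_error")
  }
  check_labels(basis, labels)
  structure(list(basis = basis, labels = labels),
            class = "qm_observation_set")
}

#' Divergence observables
#'
#' Divergence is measured as the spread of a thought over the salient
#' features \eqn{\{|u_i\rangle\}} of a person's internal and external
#' environment. Two operator modes are supported:
#'
#' * `"projector"` — \eqn{\hat B = \sum_{i \in S} |u_i\rangle\langle u_i|},
#'   the projector onto a proper subset of salient labels. (The projector
#'   onto a *complete* basis is the identity and has zero variance for every
#'   state, so a proper subset is required for a non-trivial measure.)
#' * `"weighted"` — \eqn{\hat B = \sum_i \lambda_i |u_i\rangle\langle u_i|}
#'   with one real eigenvalue per label, e.g. grading features by remoteness
#'   from the core of the concept; this gives a richer spread measure.
#'
#' @param basis a [qm_basis].
#' @param mode `"projector"` or `"weighted"`.
#' @param salient_labels projector mode: proper non-empty subset of labels.
#' @param eigenvalues weighted mode: finite real eigenvalues, one per label
#'   (optionally named by label; unnamed labels default to 0).
#' @return an object of class `qm_divergence_observable`.
#' @export
qm_divergence_observable <- function(basis,
                                     mode = c("projector", "weighted"),
                                     salient_labels = NULL,
                                     eigenvalues = NULL) {
  mode <- match.arg(mode)
  if (mode == "projector") {
    if (is.null(salient_labels) || length(salient_labels) == 0L) {
      qm_stop("projector mode needs salient_labels", "qm_empty_subspace_error")
    }
    salient_labels <- unique(as.character(salient_labels))
    check_labels(basis, salient_labels)
    if (length(salient_labels) >= basis$dimension) {
      qm_stop(
        "projector-mode salient labels must be a proper subset of the basis (the full-basis projector is the identity and measures nothing)",
        "qm_numerical_error"
      )
    }
    op <- projector(basis, salient_labels)
  } else {
    if (is.null(eigenvalues)) {
      qm_stop("weighted mode needs eigenvalues", "qm_numerical_error")
    }
    if (any(!is.finite(eigenvalues))) {
      qm_stop("eigenvalues must be finite reals", "qm_numerical_error")
    }
    op <- diagonal_op(basis, eigenvalues)
  }
  structure(
    list(basis = basis, mode = mode, salient_labels = salient_labels,
         op = op),
    class = "qm_divergence_observable"
  )
}

#' Abstractness of a mental state
#'
#' The expectation \eqn{\gamma_{obs} = \langle\psi|\hat\alpha|\psi\rangle} of
#' the observation projector \eqn{\hat\alpha = \sum_n |O_n\rangle\langle
#' O_n|} measures how grounded a thought is in direct observations. The
#' *reported* abstractness is `1 - gamma_obs`: a state fully supported on
#' observations has abstractness 0, and purely abstract knowledge — with no
#' direct observations in its superposition — has abstractness 1. Use
#' [observation_mass()] for the raw expectation.
#'
#' @param state a normalized [qm_state].
#' @param obs a [qm_observation_set] over the same basis.
#' @return abstractness in `[0, 1]`.
#' @export
abstractness <- function(state, obs) {
  min(max(1 - observation_mass(state, obs), 0), 1)
}

#' Raw observation mass of a state
#'
#' @inheritParams abstractness
#' @return \eqn{\langle\psi|\hat\alpha|\psi\rangle} in `[0, 1]`.
#' @export
observation_mass <- function(state, obs) {
  stopifnot(inherits(obs, "qm_observation_set"))
  expectation(state, projector(state$basis, obs$labels))
}

#' Context-specificity of a mental state
#'
#' The expectation \eqn{\gamma_C = \langle\psi|\hat C|\psi\rangle} of the
#' context projector: the Born mass the state places inside the context
#' subspace. Returned exactly in this overlap form; the complementary
#' quantity (how much the context *changes* the thought) is [context_shift()].
#'
#' @param state a normalized [qm_state].
#' @param ctx a [qm_context] with unit weights (a projector context).
#' @return \eqn{\gamma_C} in `[0, 1]`.
#' @export
context_specificity <- function(state, ctx) {
  stopifnot(inherits(ctx, "qm_context"))
  if (!is.null(ctx$weights) && any(abs(ctx$weights - 1) > 1e-12)) {
    qm_stop("context-specificity is defined for projector (unit-weight) contexts",
            "qm_hermitianity_error")
  }
  expectation(state, projector(state$basis, ctx$labels))
}

#' Complement of context-specificity
#'
#' `1 - context_specificity(state, ctx)`: the Born mass the context projector
#' removes, i.e. the degree to which applying the context changes the thought.
#'
#' @inheritParams context_specificity
#' @return numeric in `[0, 1]`.
#' @export
context_shift <- function(state, ctx) {
  1 - context_specificity(state, ctx)
}

#' Divergence of a mental state
#'
#' The spread of a thought over a salient-feature observable:
#' \eqn{\gamma_D = \sqrt{\langle\hat B^2\rangle - \langle\hat B\rangle^2}},
#' the standard deviation of \eqn{\hat B} in the state. In projector mode
#' \eqn{\hat B^2 = \hat B}, so \eqn{\gamma_D = \sqrt{p(1-p)}} where `p` is
#' the Born mass on the salient labels.
#'
#' @param state a normalized [qm_state].
#' @param obsv a [qm_divergence_observable] over the same basis.
#' @return \eqn{\gamma_D \ge 0}. A variance below `-1e-12` (a broken
#'   operator) signals `qm_numerical_error`.
#' @export
divergence <- function(state, obsv) {
  stopifnot(inherits(obsv, "qm_divergence_observable"))
  m1 <- expectation(state, obsv$op)
  op2 <- qm_operator(obsv$basis, obsv$op$matrix %*% obsv$op$matrix)
  m2 <- expectation(state, op2)
  v <- m2 - m1^2
  if (v < -1e-12) {
    qm_stop(sprintf("negative variance %.3g from divergence observable", v),
            "qm_numerical_error")
  }
  sqrt(max(v, 0))
}

#' Build an abstraction over observations
#'
#' A concept one step removed from direct experience is a superposition of a
#' subset of the observations, \eqn{|A_0\rangle = \sum_n a_n |O_n\rangle}
#' (e.g. the Flat-Earth model formed from observations of flat ground and a
#' flat horizon).
#'
#' @param obs a [qm_observation_set].
#' @param weights named numeric/complex vector of amplitudes over a subset of
#'   the observation labels.
#' @return a normalized [qm_state] over the observation set's basis.
#' @export
build_abstraction <- function(obs, weights) {
  stopifnot(inherits(obs, "qm_observation_set"), !is.null(names(weights)))
  bad <- setdiff(names(weights), obs$labels)
  if (length(bad) > 0L) {
    qm_stop(
      sprintf("weights refer to non-observation labels: %s",
              paste(bad, collapse = ", ")),
      "qm_unknown_label_error"
    )
  }
  normalize(qm_state(obs$basis, weights))
}

#' The three-dimensional mode-of-thought profile
#'
#' Computes abstractness, divergence, and context-specificity of one mental
#' state under a fixed environment (observation set, context, divergence
#' observable). For a two-factor composite the measures are taken on the
#' first factor — the operative mental representation — via
#' \eqn{\hat O \otimes \hat I}, so unintegrated knowledge in the second
#' factor does not alter the mode of thought.
#'
#' @param state a normalized [qm_state] or [qm_product_state].
#' @param obs a [qm_observation_set].
#' @param ctx a [qm_context].
#' @param obsv a [qm_divergence_observable].
#' @return an object of class `qm_profile`: named numeric vector
#'   `(gamma_A, gamma_D, gamma_C)`.
#' @export
dimension_profile <- function(state, obs, ctx, obsv) {
  if (inherits(state, "qm_product_state")) {
    basis <- state$basis_a
    exp_a <- function(op) product_expectation(state, op_a = op)
  } else {
    basis <- state$basis
    exp_a <- function(op) expectation(state, op)
  }
  check_labels(basis, obs$labels)
  # clamp away sub-epsilon excursions outside [0, 1]
  clamp01 <- function(x) min(max(x, 0), 1)
  gamma_a <- clamp01(1 - exp_a(projector(basis, obs$labels)))
  gamma_c <- clamp01(exp_a(projector(basis, ctx$labels)))
  m1 <- exp_a(obsv$op)
  m2 <- exp_a(qm_operator(obsv$basis, obsv$op$matrix %*% obsv$op$matrix))
  v <- m2 - m1^2
  if (v < -1e-12) {
    qm_stop("negative variance from divergence observable", "qm_numerical_error")
  }
  structure(
    c(gamma_A = gamma_a, gamma_D = sqrt(max(v, 0)), gamma_C = gamma_c),
    class = "qm_profile"
  )
}

#' @export
print.qm_profile <- function(x, digits = 4, ...) {
  cat(sprintf("<qm_profile> gamma_A = %.*g, gamma_D = %.*g, gamma_C = %.*g\n",
              digits, x[["gamma_A"]], digits, x[["gamma_D"]],
              digits, x[["gamma_C"]]))
  invisible(x)
}

#' Qualitative change between two profiles
#'
#' Quantizes the per-dimension differences `after - before` into the arrows
#' used in conceptual-change tables: up arrow (U+2191, increase), down arrow (U+2193,
#' decrease), or minus sign (U+2212, no change beyond `tol`).
#'
#' @param before,after [qm_profile]s.
#' @param tol positive tolerance below which a change counts as none.
#' @return named character vector of three arrows.
#' @export
delta_profile <- function(before, after, tol = 0.05) {
  stopifnot(tol > 0)
  d <- unclass(after) - unclass(before)
  arrows <- ifelse(abs(d) <= tol, "\u2212", ifelse(d > 0, "\u2191", "\u2193"))
  stats::setNames(arrows, names(d))
}
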