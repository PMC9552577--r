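#' Concepts as superposition states
#'
#' A basic-level concept (BIRD, ISLAND, DOG, ...) is represented as a
#' superposition over everything related to it: typical and atypical
#' instances, features, and remote associates. Amplitudes encode typicality;
#' a subset of labels may be flagged as direct observations (features the
#' person has experienced with their senses), which grounds the abstractness
#' measure.
#'
#' @param name concept name.
#' @param state a normalized [qm_state] over the concept's feature/instance
#'   basis (non-normalized input is normalized with a message-free rescale).
#' @param observations character vector of basis labels flagged as direct
#'   observations.
#' @return an object of class `qm_concept` with fields `name`, `state`,
#'   `observations`, and `salience_order` (labels ranked by decreasing
#'   squared amplitude, ties broken lexicographically).
#' @export
qm_concept <- function(name, state, observations = character()) {
  stopifnot(is.character(name), length(name) == 1L, inherits(state, "qm_state"))
  check_labels(state$basis, observations)
  if (!is_normalized(state)) state <- normalize(state)
  w <- born_weights(state)
  ord <- order(-w, state$basis$labels, method = "radix")
  structure(
    list(
      name = name,
      state = state,
      observations = unique(observations),
      salience_order = state$basis$labels[ord]
    ),
    class = "qm_concept"
  )
}

#' @export
print.qm_concept <- function(x, ...) {
  cat(sprintf("<qm_concept> %s (%d labels, %d observations)\n",
              x$name, x$state$basis$dimension, length(x$observations)))
  print(x$state)
  invisible(x)
}

#' Contexts as label subspaces
#'
#' A context (a goal, need, or question) is modeled as a projector onto the
#' subspace spanned by context-relevant labels, optionally with positive
#' per-label weights for the degree to which each feature relates to the
#' whole concept (weight 1 under the orthonormal-feature assumption).
#'
#' @param name context name.
#' @param labels non-empty character vector of context labels.
#' @param weights optional positive numeric vector, one per label.
#' @return an object of class `qm_context`.
#' @export
qm_context <- function(name, labels, weights = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  labels <- as.character(labels)
  if (length(labels) == 0L) {
    qm_stop("a context needs at least one label", "qm_empty_subspace_error")
  }
  if (anyDuplicated(labels)) labels <- unique(labels)
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(labels))
    if (any(!is.finite(weights)) || any(weights <= 0)) {
      qm_stop("context weights must be positive", "qm_numerical_error")
    }
    weights <- stats::setNames(as.numeric(weights), labels)
  }
  structure(list(name = name, labels = labels, weights = weights),
            class = "qm_context")
}

#' @export
print.qm_context <- function(x, ...) {
  cat(sprintf("<qm_context> %s: {%s}\n", x$name,
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Context projector as an operator
#'
#' @param ctx a [qm_context].
#' @param basis the [qm_basis] the context acts on.
#' @return a [qm_operator]: the (weighted) projector
#'   \eqn{\hat C = \sum_i w_i |i\rangle\langle i|}.
#' @export
context_op <- function(ctx, basis) {
  check_labels(basis, ctx$labels)
  if (is.null(ctx$weights)) {
    projector(basis, ctx$labels)
  } else {
    diagonal_op(basis, ctx$weights)
  }
}

#' Typicality of an instance with respect to a concept
#'
#' The typicality of instance \eqn{|a\rangle} with respect to concept
#' \eqn{|A\rangle} is the magnitude of the inner product
#' \eqn{\langle A | a \rangle}, i.e. of the amplitude on that label.
#'
#' @param concept a [qm_concept].
#' @param instance_label a basis label.
#' @return numeric in `[0, 1]`.
#' @export
typicality <- function(concept, instance_label) {
  check_labels(concept$state$basis, instance_label)
  Mod(inner(concept$state, basis_state(concept$state$basis, instance_label)))
}

#' Elaborate a mental state with new information
#'
#' Incorporating new, related information \eqn{|A\rangle} into a mental
#' representation is modeled by the operator \eqn{\hat U_A = \hat I +
#' |A\rangle\langle A|}, whose action is \eqn{\hat U_A |\Psi\rangle =
#' |\Psi\rangle + |A\rangle\langle A|\Psi\rangle}: the new information is
#' added on, weighted by how related it is to the current state. Orthogonal
#' information (\eqn{\langle A|\Psi\rangle = 0}) leaves the state unchanged —
#' use [combine_unintegrated()] for knowledge acquired but not integrated.
#'
#' @param state the current mental state ([qm_state]).
#' @param info the new information \eqn{|A\rangle}, a normalized [qm_state]
#'   over the same basis.
#' @param renormalize rescale the (generally non-unit) result to unit norm.
#' @return a [qm_state].
#' @examples
#' b <- qm_basis(c("x", "y"))
#' psi <- qm_state(b, c(1, 1), normalize = TRUE)
#' elaborate(psi, basis_state(b, "x"))  # amplitudes (2, 1)/sqrt(5)
#' @export
elaborate <- function(state, info, renormalize = TRUE) {
  check_same_basis(state$basis, info$basis, "state and information")
  if (!is_normalized(info)) {
    qm_stop("the information state must be normalized", "qm_normalization_error")
  }
  overlap <- inner(info, state)
  out <- qm_state(state$basis, state$amplitudes + info$amplitudes * overlap)
  if (renormalize) normalize(out) else out
}

#' Combine a state with unintegrated information
#'
#' When a learnt fact has negligible overlap with the current representation
#' (\eqn{\langle A|\Psi\rangle \ll 1}), adding it to the superposition has no
#' effect, yet the fact can still influence answers. The combined
#' representation is then the tensor product \eqn{|C\rangle = |\Psi\rangle
#' \otimes |A\rangle}, which keeps the two pieces of knowledge separate while
#' allowing them (once the joint amplitudes are edited) to become entangled.
#'
#' @param state the current mental state ([qm_state], normalized).
#' @param info the unintegrated information ([qm_state], normalized).
#' @param overlap_warn warn if \eqn{|\langle A|\Psi\rangle|} is at or above
#'   this cutoff, since elaboration would then be the natural operation.
#' @return a separable [qm_product_state]; callers may replace its `joint`
#'   amplitudes with a non-factorizing pattern to model entanglement.
#' @export
combine_unintegrated <- function(state, info, overlap_warn = 0.05) {
  ov <- Mod(inner(info, state))
  if (ov >= overlap_warn) {
    warning(sprintf(
      "overlap |<A|Psi>| = %.3g is not negligible (cutoff %.3g); elaborate() may be the intended operation",
      ov, overlap_warn
    ))
  }
  tensor_product(state, info)
}

#' Apply a context to a mental state
#'
#' Projects the state onto the context subspace: \eqn{\hat C|\Psi\rangle =
#' \sum_{i \in ctx} w_i \langle i|\Psi\rangle |i\rangle}. Under the
#' orthonormal-feature assumption (unit weights) the output amplitudes are
#' simply the original amplitudes restricted to the context labels. Features
#' irrelevant to the current goal are trimmed off.
#'
#' @param state a [qm_state].
#' @param ctx a [qm_context] whose labels lie within the state's basis.
#' @param renormalize rescale the projected state to unit norm.
#' @return a [qm_state] supported only on the context labels. A state
#'   orthogonal to the context subspace signals `qm_annihilation_error`.
#' @examples
#' b <- qm_basis(c("warm", "soft", "rectangular"))
#' blanket <- qm_state(b, c(0.7, 0.5, 0.51), normalize = TRUE)
#' sleep <- qm_context("going to bed", c("warm", "soft"))
#' apply_context(blanket, sleep, renormalize = FALSE)
#' @export
apply_context <- function(state, ctx, renormalize = TRUE) {
  op <- context_op(ctx, state$basis)
  out <- qm_state(state$basis, as.vector(op$matrix %*% state$amplitudes))
  if (state_norm(out) <= 1e-12) {
    qm_stop("state is orthogonal to the context subspace",
            "qm_annihilation_error")
  }
  if (renormalize) normalize(out) else out
}

#' Compact form of a concept
#'
#' Convergent thought uses a concept in its most compact form, limited to its
#' most typical features (an island is land surrounded by water; everything
#' else is trimmed). The compact form keeps the smallest salience-ordered
#' prefix of labels whose cumulative squared-amplitude mass reaches
#' `mass_threshold`, and renormalizes.
#'
#' @param concept a [qm_concept].
#' @param mass_threshold number in `(0, 1]`: minimum retained Born mass.
#' @return a normalized [qm_state] supported on the selected labels.
#' @export
compact_form <- function(concept, mass_threshold) {
  stopifnot(is.numeric(mass_threshold), length(mass_threshold) == 1L)
  if (mass_threshold <= 0 || mass_threshold > 1) {
    qm_stop("mass_threshold must lie in (0, 1]", "qm_numerical_error")
  }
  w <- born_weights(concept$state)[concept$salience_order]
  cum <- cumsum(w)
  k <- which(cum >= mass_threshold - 1e-12)[1L]
  if (is.na(k)) k <- length(w)  # threshold 1 with rounding slack
  keep <- concept$salience_order[seq_len(k)]
  amps <- concept$state$amplitudes
  amps[!(names(amps) %in% keep)] <- 0+0i
  normalize(qm_state(concept$state$basis, amps))
}

#' Expanded form of a concept
#'
#' Divergent thought uses the full superposition, including low-weight
#' features and remote associates. The expanded form is the concept's
#' complete state; its support contains the support of every compact form.
#'
#' @param concept a [qm_concept].
#' @return the concept's full normalized [qm_state].
#' @export
expanded_form <- function(concept) {
  concept$state
}

#' Project one concept's superposition onto another's
#'
#' Models reasoning by comparison: projecting what one knows about a source
#' concept (e.g. PLANET, \eqn{\sum_i p_i |i\rangle}) onto a target concept
#' (e.g. EARTH, \eqn{\sum_j e_j |j\rangle}) produces
#' \eqn{\sum_{i,j} p_i e_j \langle j|i\rangle\, |j\rangle}. The cross-basis
#' inner products \eqn{\langle j|i\rangle} default to 1 where labels
#' literally match and 0 otherwise; supply `basis_map` to override.
#'
#' @param source,target [qm_concept]s (bases may differ).
#' @param basis_map optional data.frame with columns `source`, `target`,
#'   `value` giving \eqn{\langle \mathrm{target} | \mathrm{source} \rangle}
#'   for label pairs; unlisted pairs use the literal-match default.
#' @param renormalize rescale the result to unit norm.
#' @return a [qm_state] over the target basis. If the concepts share no
#'   features under the map, a `qm_annihilation_error` is signalled.
#' @export
project_compare <- function(source, target, basis_map = NULL,
                            renormalize = TRUE) {
  src_lab <- source$state$basis$labels
  tgt_lab <- target$state$basis$labels
  overlap <- outer(src_lab, tgt_lab, function(i, j) as.numeric(i == j))
  dimnames(overlap) <- list(src_lab, tgt_lab)
  mode(overlap) <- "complex"
  if (!is.null(basis_map)) {
    stopifnot(all(c("source", "target", "value") %in% names(basis_map)))
    check_labels(source$state$basis, basis_map$source)
    check_labels(target$state$basis, basis_map$target)
    for (r in seq_len(nrow(basis_map))) {
      overlap[basis_map$source[r], basis_map$target[r]] <-
        as.complex(basis_map$value[r])
    }
  }
  p <- source$state$amplitudes
  e <- target$state$amplitudes
  # out_j = sum_i p_i e_j <j|i>
  out <- as.vector(crossprod(overlap, p)) * e
  result <- qm_state(target$state$basis, out)
  if (state_norm(result) <= 1e-12) {
    qm_stop("concepts share no features under the correspondence map",
            "qm_annihilation_error")
  }
  if (renormalize) normalize(result) else result
}

#' Ask a joint question of a composite state
#'
#' A question asked of a two-factor representation is the observable
#' \eqn{\hat O = \hat O_s \otimes \hat O_d}, where each factor operator is a
#' projector onto that factor's answer subspace (`NULL` means the identity: a
#' question touching only the other factor). Returns the joint Born
#' probabilities over the four (in/out of answer subspace) outcome pairs and
#' the marginal label distributions. When the marginals place at least
#' `incompatibility_threshold` of their product mass on caller-declared
#' contradictory label pairs, the question is flagged incompatible: the two
#' components force contradictory answers, so the person cannot answer.
#'
#' @param dual a normalized [qm_product_state].
#' @param op_s projector [qm_operator] on factor A, or `NULL` for identity.
#' @param op_d projector [qm_operator] on factor B, or `NULL` for identity.
#' @param contradictory_pairs optional data.frame with columns `a`, `b`:
#'   pairs of labels (one from each factor) that contradict each other.
#' @param incompatibility_threshold mass cutoff for flagging; default 0.5
#'   (majority mass on contradiction means the question has no usable answer).
#' @return a list with `outcomes` (2x2 matrix of joint probabilities, rows =
#'   factor A in/out, columns = factor B in/out), `marginal_a`, `marginal_b`,
#'   `contradictory_mass`, and `incompatible` (logical).
#' @export
joint_question <- function(dual, op_s = NULL, op_d = NULL,
                           contradictory_pairs = NULL,
                           incompatibility_threshold = 0.5) {
  for (op in list(op_s, op_d)) {
    if (!is.null(op) && !is_projector(op)) {
      qm_stop("question operators must be projectors",
              "qm_hermitianity_error")
    }
  }
  comp <- function(op, basis) {
    m <- if (is.null(op)) diag(basis$dimension) else op$matrix
    list(p = m, q = diag(basis$dimension) - m)
  }
  pa <- comp(op_s, dual$basis_a)
  pb <- comp(op_d, dual$basis_b)
  outcomes <- matrix(
    c(
      product_expectation(dual, qm_operator(dual$basis_a, pa$p),
                          qm_operator(dual$basis_b, pb$p)),
      product_expectation(dual, qm_operator(dual$basis_a, pa$p),
                          qm_operator(dual$basis_b, pb$q)),
      product_expectation(dual, qm_operator(dual$basis_a, pa$q),
                          qm_operator(dual$basis_b, pb$p)),
      product_expectation(dual, qm_operator(dual$basis_a, pa$q),
                          qm_operator(dual$basis_b, pb$q))
    ),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("a_in", "a_out"), c("b_in", "b_out"))
  )
  marg_a <- product_marginal(dual, "a")
  marg_b <- product_marginal(dual, "b")
  cmass <- 0
  if (!is.null(contradictory_pairs)) {
    stopifnot(all(c("a", "b") %in% names(contradictory_pairs)))
    check_labels(dual$basis_a, contradictory_pairs$a)
    check_labels(dual$basis_b, contradictory_pairs$b)
    cmass <- sum(marg_a[contradictory_pairs$a] * marg_b[contradictory_pairs$b])
  }
  list(
    outcomes = outcomes,
    marginal_a = marg_a,
    marginal_b = marg_b,
    contradictory_mass = cmass,
    incompatible = cmass >= incompatibility_threshold
  )
}
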