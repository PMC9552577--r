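#' Linear operators on a labeled Hilbert space
#'
#' Observables — the formal counterparts of questions asked of a mental
#' state — are Hermitian operators. Projectors onto label subsets model
#' contexts and multiple-choice questions; the elaboration operator
#' \eqn{\hat U_A = \hat I + |A\rangle\langle A|} models incorporating new
#' information.
#'
#' @param basis a [qm_basis].
#' @param matrix complex (or numeric) square matrix, `dimension x dimension`,
#'   acting on amplitude vectors in basis-label order.
#' @return an object of class `qm_operator`.
#' @export
qm_operator <- function(basis, matrix) {
  stopifnot(inherits(basis, "qm_basis"))
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != basis$dimension || ncol(matrix) != basis$dimension) {
    qm_stop(
      sprintf("operator matrix must be %d x %d", basis$dimension, basis$dimension),
      "qm_basis_mismatch_error"
    )
  }
  storage.mode(matrix) <- "complex"
  dimnames(matrix) <- list(basis$labels, basis$labels)
  structure(list(basis = basis, matrix = matrix), class = "qm_operator")
}

#' @export
print.qm_operator <- function(x, ...) {
  cat(sprintf("<qm_operator> %d x %d, hermitian: %s\n",
              x$basis$dimension, x$basis$dimension, is_hermitian(x)))
  invisible(x)
}

#' Is an operator Hermitian?
#'
#' @param op a [qm_operator].
#' @param tol elementwise tolerance against the conjugate transpose.
#' @return logical.
#' @export
is_hermitian <- function(op, tol = 1e-9) {
  max(Mod(op$matrix - Conj(t(op$matrix)))) <= tol
}

#' Is an operator an orthogonal projector?
#'
#' Checks hermiticity and idempotence (`P %*% P == P`) within tolerance.
#'
#' @param op a [qm_operator].
#' @param tol elementwise tolerance.
#' @return logical.
#' @export
is_projector <- function(op, tol = 1e-9) {
  is_hermitian(op, tol) &&
    max(Mod(op$matrix %*% op$matrix - op$matrix)) <= tol
}

#' Identity operator
#'
#' @param basis a [qm_basis].
#' @return the identity [qm_operator] on `basis`.
#' @export
identity_op <- function(basis) {
  qm_operator(basis, diag(basis$dimension))
}

#' Projector onto a label subspace
#'
#' Builds \eqn{\hat C = \sum_{i \in L} |i\rangle\langle i|}, the projector
#' onto the subspace spanned by the given labels. This is the operator form
#' of a context or a multiple-choice question: applied to a state it trims
#' off every component irrelevant to the labels in `L`.
#'
#' @param basis a [qm_basis].
#' @param labels non-empty subset of the basis labels.
#' @return a [qm_operator]; Hermitian, idempotent, rank `length(labels)`.
#' @examples
#' b <- qm_basis(c("warm", "soft", "rectangular"))
#' projector(b, c("warm", "soft"))
#' @export
projector <- function(basis, labels) {
  if (length(labels) == 0L) {
    qm_stop("projector needs a non-empty label subset", "qm_empty_subspace_error")
  }
  check_labels(basis, labels)
  d <- rep(0, basis$dimension)
  d[match(unique(labels), basis$labels)] <- 1
  qm_operator(basis, diag(d, nrow = basis$dimension))
}

#' Diagonal observable with one eigenvalue per label
#'
#' @param basis a [qm_basis].
#' @param eigenvalues real vector, one per label (optionally named by label).
#' @return a Hermitian diagonal [qm_operator].
#' @export
diagonal_op <- function(basis, eigenvalues) {
  if (!is.null(names(eigenvalues))) {
    check_labels(basis, names(eigenvalues))
    full <- stats::setNames(rep(0, basis$dimension), basis$labels)
    full[names(eigenvalues)] <- eigenvalues
    eigenvalues <- full
  }
  stopifnot(length(eigenvalues) == basis$dimension, is.numeric(eigenvalues))
  qm_operator(basis, diag(eigenvalues, nrow = basis$dimension))
}

#' Apply an operator to a state
#'
#' Computes the matrix–vector product \eqn{\hat O |\Psi\rangle}. Operators in
#' this formalism (elaboration, context projection) are generally
#' non-unitary; by default the result is rescaled to unit norm, matching the
#' convention that all amplitudes can be normalized. With
#' `renormalize = FALSE` the raw image is returned, which is how the
#' unnormalized right-hand sides of intermediate forms are displayed.
#'
#' @param op a [qm_operator].
#' @param state a [qm_state] over the same basis.
#' @param renormalize rescale the result to unit norm.
#' @param tol norm at or below which the image counts as annihilated.
#' @return a [qm_state]. If the image is numerically zero and
#'   `renormalize = TRUE`, a `qm_annihilation_error` is signalled: the state
#'   has no support in the operator's range.
#' @export
apply_op <- function(op, state, renormalize = TRUE, tol = 1e-12) {
  check_same_basis(op$basis, state$basis, "operator and state")
  out <- as.vector(op$matrix %*% state$amplitudes)
  result <- qm_state(state$basis, out)
  if (renormalize) {
    if (state_norm(result) <= tol) {
      qm_stop(
        "operator annihilates the state: no support in the operator's range",
        "qm_annihilation_error"
      )
    }
    result <- normalize(result)
  }
  result
}

#' Expectation value of a Hermitian operator
#'
#' Computes \eqn{\langle\psi|\hat O|\psi\rangle}, the mean measured value of
#' the observable in the given state. For a projector this is the
#' squared-amplitude mass the state places in the projector's subspace, a
#' number in `[0, 1]`.
#'
#' @param state a normalized [qm_state].
#' @param op a Hermitian [qm_operator] over the same basis.
#' @param tol hermiticity tolerance.
#' @return a real scalar.
#' @export
expectation <- function(state, op, tol = 1e-9) {
  check_same_basis(op$basis, state$basis, "operator and state")
  if (!is_hermitian(op, tol)) {
    qm_stop("expectation requires a Hermitian operator", "qm_hermitianity_error")
  }
  a <- state$amplitudes
  val <- sum(Conj(a) * as.vector(op$matrix %*% a))
  Re(val)
}
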