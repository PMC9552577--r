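#' State vectors over a labeled basis
#'
#' A mental representation is a superposition \eqn{|\Psi\rangle = \sum_i a_i
#' |\phi_i\rangle} with complex amplitudes \eqn{a_i} over a labeled
#' orthonormal basis. The squared magnitude \eqn{|a_i|^2} is the Born
#' probability that a measurement in the label basis yields outcome \eqn{i}.
#' Real amplitudes are accepted as a convenience and stored as complex.
#'
#' @param basis a [qm_basis].
#' @param amplitudes numeric or complex vector, one amplitude per basis label,
#'   optionally named by label (names are matched against the basis order).
#' @param normalize if `TRUE`, scale to unit norm on construction.
#' @return an object of class `qm_state` with fields `basis` and `amplitudes`
#'   (a complex vector named by label).
#' @examples
#' b <- qm_basis(c("sparrow", "penguin"))
#' bird <- qm_state(b, c(0.8, 0.6))
#' state_norm(bird)
#' @export
qm_state <- function(basis, amplitudes, normalize = FALSE) {
  stopifnot(inherits(basis, "qm_basis"))
  if (!is.null(names(amplitudes))) {
    check_labels(basis, names(amplitudes))
    full <- stats::setNames(rep(0+0i, basis$dimension), basis$labels)
    full[names(amplitudes)] <- as.complex(amplitudes)
    amplitudes <- full
  }
  if (length(amplitudes) != basis$dimension) {
    qm_stop(
      sprintf(
        "need %d amplitudes for a %d-dimensional basis, got %d",
        basis$dimension, basis$dimension, length(amplitudes)
      ),
      "qm_basis_mismatch_error"
    )
  }
  amplitudes <- as.complex(amplitudes)
  if (anyNA(amplitudes)) {
    qm_stop("amplitudes contain NA", "qm_numerical_error")
  }
  names(amplitudes) <- basis$labels
  state <- structure(list(basis = basis, amplitudes = amplitudes),
                     class = "qm_state")
  if (normalize) state <- normalize(state)
  state
}

#' @export
print.qm_state <- function(x, digits = 4, ...) {
  cat(sprintf("<qm_state> over %d labels (norm %.6g)\n",
              x$basis$dimension, state_norm(x)))
  amp <- x$amplitudes
  shown <- order(-Mod(amp)^2)
  for (i in utils::head(shown, 8L)) {
    a <- amp[i]
    txt <- if (all(Im(amp) == 0)) format(Re(a), digits = digits)
           else format(a, digits = digits)
    cat(sprintf("  %-20s %s\n", names(amp)[i], txt))
  }
  if (length(amp) > 8L) cat(sprintf("  ... %d more\n", length(amp) - 8L))
  invisible(x)
}

#' Norm of a state vector
#'
#' @param state a [qm_state].
#' @return the Euclidean norm \eqn{\sqrt{\sum_i |a_i|^2}}.
#' @export
state_norm <- function(state) {
  sqrt(sum(Mod(state$amplitudes)^2))
}

#' Is a state normalized?
#'
#' @param state a [qm_state].
#' @param tol numeric tolerance on `|norm - 1|`.
#' @return logical.
#' @export
is_normalized <- function(state, tol = 1e-9) {
  abs(state_norm(state) - 1) <= tol
}

#' Normalize a state to unit norm
#'
#' Scales the amplitude vector to unit norm, preserving its direction. The
#' formalism assumes all amplitudes can be normalized; a numerically zero
#' vector has no direction and signals a `qm_normalization_error`.
#'
#' @param state a [qm_state].
#' @param tol norms at or below `tol` count as zero.
#' @return a unit-norm [qm_state].
#' @examples
#' b <- qm_basis(c("x", "y"))
#' normalize(qm_state(b, c(3, 4)))  # (0.6, 0.8)
#' @export
normalize <- function(state, tol = 1e-12) {
  nrm <- state_norm(state)
  if (nrm <= tol) {
    qm_stop("cannot normalize a zero state vector", "qm_normalization_error")
  }
  qm_state(state$basis, state$amplitudes / nrm)
}

#' Inner product of two states
#'
#' Computes \eqn{\langle \mathrm{bra} | \mathrm{ket} \rangle = \sum_i
#' \overline{a_i} b_i}. The inner product of a concept with one of its
#' instances is that instance's (complex) typicality amplitude; a normalized
#' state is fully typical of itself, \eqn{\langle a|a\rangle = 1}.
#'
#' @param bra,ket [qm_state]s over the same basis.
#' @return a complex scalar; conjugate-symmetric in its arguments.
#' @examples
#' b <- qm_basis(c("x", "y"))
#' inner(qm_state(b, c(0.6, 0.8)), qm_state(b, c(1, 0)))  # 0.6
#' @export
inner <- function(bra, ket) {
  check_same_basis(bra$basis, ket$basis, "bra and ket")
  sum(Conj(bra$amplitudes) * ket$amplitudes)
}

#' Pure basis state
#'
#' Convenience constructor for the basis state `|label>`.
#'
#' @param basis a [qm_basis].
#' @param label one of the basis labels.
#' @return a [qm_state] with unit amplitude on `label`.
#' @export
basis_state <- function(basis, label) {
  check_labels(basis, label)
  stopifnot(length(label) == 1L)
  qm_state(basis, stats::setNames(1+0i, label))
}

#' Squared-amplitude (Born) weights of a state
#'
#' @param state a [qm_state].
#' @return named numeric vector of \eqn{|a_i|^2} per label.
#' @export
born_weights <- function(state) {
  stats::setNames(Mod(state$amplitudes)^2, state$basis$labels)
}
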