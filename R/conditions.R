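#' Structured error conditions
#'
#' All errors signalled by quantmind carry a subclass of `"qm_error"` so that
#' callers can distinguish, e.g., a basis mismatch from a failed
#' normalization. The subclasses are:
#'
#' * `qm_normalization_error` — zero vector where a normalizable state is required
#' * `qm_basis_mismatch_error` — two objects defined over different bases
#' * `qm_unknown_label_error` — a label not present in the basis
#' * `qm_empty_subspace_error` — an empty label subset where a subspace is required
#' * `qm_annihilation_error` — an operator maps the state to (numerically) zero
#' * `qm_hermitianity_error` — an operator that must be Hermitian (or a projector) is not
#' * `qm_numerical_error` — an internally inconsistent numerical result
#' * `qm_fixture_error` — a malformed packaged or user-supplied fixture file
#'
#' @param message character error message.
#' @param class condition subclass.
#' @param ... fields stored on the condition object.
#' @return never returns; throws a classed condition.
#' @keywords internal
qm_stop <- function(message, class, ...) {
  stop(structure(
    class = c(class, "qm_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}
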