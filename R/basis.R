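#' Labeled orthonormal basis
#'
#' A basis is an ordered set of unique string labels, each naming one basis
#' state of a finite-dimensional complex Hilbert space. Labels stand for
#' definite interpretations, features, or instances of a mental entity
#' (e.g. `"warm"`, `"soft"` for a blanket; `"land"`, `"water"` for an island).
#' Basis states are assumed mutually orthogonal and of unit length.
#'
#' @param labels character vector of unique, non-empty labels. Case-sensitive.
#' @return an object of class `qm_basis` with fields `labels` and `dimension`.
#' @examples
#' qm_basis(c("warm", "soft", "rectangular"))
#' @export
qm_basis <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L) {
    qm_stop("a basis needs at least one label", "qm_empty_subspace_error")
  }
  if (anyNA(labels) || any(!nzchar(labels))) {
    qm_stop("basis labels must be non-empty strings", "qm_unknown_label_error")
  }
  if (anyDuplicated(labels)) {
    qm_stop(
      sprintf("duplicated basis label: %s", labels[duplicated(labels)][1L]),
      "qm_unknown_label_error"
    )
  }
  structure(
    list(labels = labels, dimension = length(labels)),
    class = "qm_basis"
  )
}

#' @export
print.qm_basis <- function(x, ...) {
  cat(sprintf(
    "<qm_basis> dimension %d: %s\n", x$dimension,
    paste(x$labels, collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.qm_basis <- function(x) x$dimension

same_basis <- function(a, b) {
  identical(a$labels, b$labels)
}

check_same_basis <- function(a, b, what = "objects") {
  if (!same_basis(a, b)) {
    qm_stop(
      sprintf("%s are defined over different bases", what),
      "qm_basis_mismatch_error"
    )
  }
  invisible(TRUE)
}

check_labels <- function(basis, labels) {
  missing <- setdiff(labels, basis$labels)
  if (length(missing) > 0L) {
    qm_stop(
      sprintf("label(s) not in basis: %s", paste(missing, collapse = ", ")),
      "qm_unknown_label_error"
    )
  }
  invisible(TRUE)
}
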