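# JSON and CSV serialization. Complex numbers are stored as [re, im] pairs
# throughout; all files are UTF-8, labels are case-sensitive.

complex_to_pairs <- function(z) {
  lapply(as.complex(z), function(x) c(Re(x), Im(x)))
}

pairs_to_complex <- function(p) {
  if (is.matrix(p)) {  # jsonlite simplifies an array of equal pairs to a matrix
    return(complex(real = p[, 1L], imaginary = p[, 2L]))
  }
  vapply(p, function(x) {
    x <- unlist(x)
    if (length(x) != 2L || !is.numeric(x)) {
      qm_stop("amplitudes must be [re, im] pairs", "qm_fixture_error")
    }
    complex(real = x[1L], imaginary = x[2L])
  }, complex(1))
}

#' Read and write states as JSON
#'
#' A state is stored as `{"basis": {"labels": [...]}, "amplitudes":
#' [[re, im], ...]}`.
#'
#' @param state a [qm_state].
#' @param path file path.
#' @return `qm_read_state` returns a [qm_state]; `qm_write_state` returns
#'   `path` invisibly.
#' @export
qm_write_state <- function(state, path) {
  jsonlite::write_json(
    list(
      basis = list(labels = state$basis$labels),
      amplitudes = complex_to_pairs(state$amplitudes)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname qm_write_state
#' @export
qm_read_state <- function(path) {
  x <- read_json_fixture(path)
  if (is.null(x$basis$labels) || is.null(x$amplitudes)) {
    qm_stop("state JSON needs fields basis$labels and amplitudes",
            "qm_fixture_error")
  }
  qm_state(qm_basis(unlist(x$basis$labels)), pairs_to_complex(x$amplitudes))
}

#' Read and write concepts as JSON
#'
#' A concept is stored as `{"name": ..., "basis": {"labels": [...]},
#' "amplitudes": [[re, im], ...], "observations": [...]}`. A bundle file is
#' a JSON array of such objects.
#'
#' @param concept a [qm_concept].
#' @param path file path.
#' @return `qm_read_concept` returns a [qm_concept];
#'   `qm_read_concept_bundle` a named list of concepts.
#' @export
qm_write_concept <- function(concept, path) {
  jsonlite::write_json(concept_to_list(concept), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

concept_to_list <- function(concept) {
  list(
    name = concept$name,
    basis = list(labels = concept$state$basis$labels),
    amplitudes = complex_to_pairs(concept$state$amplitudes),
    observations = concept$observations
  )
}

concept_from_list <- function(x) {
  for (field in c("name", "basis", "amplitudes")) {
    if (is.null(x[[field]])) {
      qm_stop(sprintf("concept JSON is missing field '%s'", field),
              "qm_fixture_error")
    }
  }
  qm_concept(
    x$name,
    qm_state(qm_basis(unlist(x$basis$labels)), pairs_to_complex(x$amplitudes),
             normalize = TRUE),
    observations = as.character(unlist(x$observations))
  )
}

#' @rdname qm_write_concept
#' @export
qm_read_concept <- function(path) {
  concept_from_list(read_json_fixture(path))
}

#' @rdname qm_write_concept
#' @export
qm_read_concept_bundle <- function(path) {
  x <- read_json_fixture(path)
  concepts <- lapply(x, concept_from_list)
  stats::setNames(concepts, vapply(concepts, `[[`, "", "name"))
}

#' Bundled example concepts
#'
#' Loads the packaged concept fixtures: BLANKET, ISLAND, DOG, and BIRD with
#' their conventional features (a blanket is warm and soft; an island is
#' land surrounded by water, with a shoreline and remote associates; a dog
#' is furry, has a tail, is loyal, barks, rolls over, hunts, and smells
#' well; a bird spans typical and atypical instances and features).
#'
#' @return named list of [qm_concept]s.
#' @export
example_concepts <- function() {
  qm_read_concept_bundle(
    system.file("extdata", "concept_fixtures.json", package = "quantmind",
                mustWork = TRUE)
  )
}

#' Read and write contexts as JSON
#'
#' A context is stored as `{"name": ..., "labels": [...], "weights": ...}`
#' (weights optional).
#'
#' @param ctx a [qm_context].
#' @param path file path.
#' @return `qm_read_context` returns a [qm_context].
#' @export
qm_write_context <- function(ctx, path) {
  x <- list(name = ctx$name, labels = ctx$labels)
  if (!is.null(ctx$weights)) x$weights <- unname(ctx$weights)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname qm_write_context
#' @export
qm_read_context <- function(path) {
  x <- read_json_fixture(path)
  if (is.null(x$name) || is.null(x$labels)) {
    qm_stop("context JSON needs fields name and labels", "qm_fixture_error")
  }
  qm_context(x$name, unlist(x$labels),
             weights = if (!is.null(x$weights)) unlist(x$weights))
}

#' Read and write operators as JSON
#'
#' An operator is stored as a dense complex matrix in row-major order:
#' `{"basis": {"labels": [...]}, "matrix": [[[re, im], ...], ...]}`.
#'
#' @param op a [qm_operator].
#' @param path file path.
#' @return `qm_read_operator` returns a [qm_operator].
#' @export
qm_write_operator <- function(op, path) {
  rows <- lapply(seq_len(nrow(op$matrix)), function(i) {
    complex_to_pairs(op$matrix[i, ])
  })
  jsonlite::write_json(
    list(basis = list(labels = op$basis$labels), matrix = rows),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname qm_write_operator
#' @export
qm_read_operator <- function(path) {
  x <- read_json_fixture(path)
  basis <- qm_basis(unlist(x$basis$labels))
  rows <- lapply(x$matrix, pairs_to_complex)
  qm_operator(basis, do.call(rbind, rows))
}

read_json_fixture <- function(path) {
  tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      qm_stop(sprintf("cannot parse JSON fixture '%s': %s", path,
                      conditionMessage(e)),
              "qm_fixture_error")
    }
  )
}

#' Export and re-import an arrow table as CSV
#'
#' Writes the output of [arrow_table()] as UTF-8 CSV with a header row, and
#' reads it back. The round trip preserves arrows and numeric columns.
#'
#' @param table data.frame from [arrow_table()].
#' @param path CSV file path.
#' @return `read_arrow_csv` returns the data.frame.
#' @export
write_arrow_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_arrow_csv
#' @export
read_arrow_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
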