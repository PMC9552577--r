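#' A single conceptual-change step
#'
#' One transition in a conceptual-change trajectory: a named operation
#' (elaboration, context application, tensor combination, cross-concept
#' projection, ...) applied to the current mental state, together with its
#' source of change — individual learning (`"IL"`), social learning
#' (`"SL"`), or representational redescription (`"RR"`).
#'
#' @param description short label for the transition.
#' @param source one of `"IL"`, `"SL"`, `"RR"`.
#' @param operation name of the operation the transform applies (free text,
#'   e.g. `"elaborate"`, `"context projection"`).
#' @param transform function of one argument (the current [qm_state] or
#'   [qm_product_state]) returning the next state.
#' @param tag optional mental-model tag for the resulting state (one of
#'   `"Flat"`, `"Disk"`, `"Dual"`, `"Hollow"`, `"FlattenedSphere"`,
#'   `"Sphere"`, `"Mixed"`, or any user tag).
#' @param expected_arrows optional character triple of expected qualitative
#'   changes, for regression checks.
#' @return an object of class `qm_change_step`.
#' @export
qm_change_step <- function(description, source, operation, transform,
                           tag = NULL, expected_arrows = NULL) {
  source <- match.arg(source, c("IL", "SL", "RR"))
  stopifnot(is.function(transform))
  if (!is.null(expected_arrows)) stopifnot(length(expected_arrows) == 3L)
  structure(
    list(description = description, source = source, operation = operation,
         transform = transform, tag = tag, expected_arrows = expected_arrows),
    class = "qm_change_step"
  )
}

#' Run a conceptual-change trajectory
#'
#' Applies each step's transform in order, starting from `initial`, and
#' records the three-dimensional mode-of-thought profile of every state
#' (initial plus one per step) under a fixed environment. Deterministic:
#' no sampling is involved.
#'
#' @param initial the starting [qm_state].
#' @param steps list of [qm_change_step]s.
#' @param environment list with components `obs` ([qm_observation_set]),
#'   `ctx` ([qm_context]), and `obsv` ([qm_divergence_observable]), the fixed
#'   environment profiles are measured against.
#' @return an object of class `qm_trajectory`: list with `states` (length
#'   `n_steps + 1`), `profiles` (matrix, one row per state), `steps`,
#'   `tags`, and `environment`.
#' @export
run_trajectory <- function(initial, steps, environment) {
  stopifnot(
    inherits(environment$obs, "qm_observation_set"),
    inherits(environment$ctx, "qm_context"),
    inherits(environment$obsv, "qm_divergence_observable")
  )
  prof <- function(s) {
    dimension_profile(s, environment$obs, environment$ctx, environment$obsv)
  }
  states <- vector("list", length(steps) + 1L)
  tags <- character(length(steps) + 1L)
  states[[1L]] <- initial
  tags[1L] <- "None"
  profiles <- matrix(NA_real_, nrow = length(steps) + 1L, ncol = 3L,
                     dimnames = list(NULL, c("gamma_A", "gamma_D", "gamma_C")))
  profiles[1L, ] <- prof(initial)
  for (k in seq_along(steps)) {
    step <- steps[[k]]
    out <- tryCatch(
      step$transform(states[[k]]),
      error = function(e) {
        qm_stop(
          sprintf("step %d (%s) failed: %s", k, step$description,
                  conditionMessage(e)),
          "qm_numerical_error", step_index = k
        )
      }
    )
    states[[k + 1L]] <- out
    tags[k + 1L] <- if (is.null(step$tag)) tags[k] else step$tag
    profiles[k + 1L, ] <- prof(out)
  }
  structure(
    list(states = states, profiles = profiles, steps = steps, tags = tags,
         environment = environment),
    class = "qm_trajectory"
  )
}

#' @export
print.qm_trajectory <- function(x, ...) {
  cat(sprintf("<qm_trajectory> %d steps, %d recorded profiles\n",
              length(x$steps), nrow(x$profiles)))
  print(arrow_table(x))
  invisible(x)
}

#' Arrow table of a trajectory
#'
#' One row per step with the profile after the step, the raw per-dimension
#' differences, and their qualitative arrows. This is the tabular summary
#' format of conceptual-change case studies: step, source of change,
#' operation, and the direction each mode-of-thought dimension moved.
#'
#' @param traj a [qm_trajectory].
#' @param tol arrow tolerance passed to [delta_profile()].
#' @return a data.frame with columns `step`, `description`, `source`,
#'   `operation`, `gamma_A`, `gamma_D`, `gamma_C`, `d_gamma_A`, `d_gamma_D`,
#'   `d_gamma_C`, `arrow_A`, `arrow_D`, `arrow_C`.
#' @export
arrow_table <- function(traj, tol = 0.05) {
  stopifnot(inherits(traj, "qm_trajectory"))
  n <- length(traj$steps)
  p <- traj$profiles
  d <- p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  arrows <- t(vapply(seq_len(n), function(k) {
    delta_profile(
      structure(p[k, ], class = "qm_profile"),
      structure(p[k + 1L, ], class = "qm_profile"),
      tol = tol
    )
  }, character(3L)))
  data.frame(
    step = seq_len(n),
    description = vapply(traj$steps, `[[`, "", "description"),
    source = vapply(traj$steps, `[[`, "", "source"),
    operation = vapply(traj$steps, `[[`, "", "operation"),
    gamma_A = p[-1L, "gamma_A"],
    gamma_D = p[-1L, "gamma_D"],
    gamma_C = p[-1L, "gamma_C"],
    d_gamma_A = d[, "gamma_A"],
    d_gamma_D = d[, "gamma_D"],
    d_gamma_C = d[, "gamma_C"],
    arrow_A = arrows[, 1L],
    arrow_D = arrows[, 2L],
    arrow_C = arrows[, 3L],
    stringsAsFactors = FALSE
  )
}

#' Load the Earth-shape mental-model frequency table
#'
#' Reads the packaged frequency table of children's mental models of the
#' shape of the Earth by school grade (after Vosniadou and Brewer, 1992):
#' seven model rows (Flat earth, Disk earth, Dual earth, Hollow sphere,
#' Flattened sphere, Sphere, Mixed) by three grade columns (1, 3, 5), with
#' row, column, and grand totals. Marginal consistency is verified on load:
#' every stored total must equal the recomputed sum of its cells.
#'
#' @param path CSV file with columns `model`, `grade1`, `grade3`, `grade5`,
#'   `total` and a final `Total` row; defaults to the packaged fixture.
#' @return an object of class `qm_frequency_table`: list with `counts`
#'   (7 x 3 integer matrix), `row_totals`, `col_totals`, `grand_total`.
#' @export
load_frequency_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "earth_model_frequencies.csv",
                        package = "quantmind", mustWork = TRUE)
  }
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) {
      qm_stop(sprintf("cannot read frequency fixture: %s", conditionMessage(e)),
              "qm_fixture_error")
    }
  )
  need <- c("model", "grade1", "grade3", "grade5", "total")
  if (!all(need %in% names(raw))) {
    qm_stop(
      sprintf("frequency fixture must have columns %s",
              paste(need, collapse = ", ")),
      "qm_fixture_error"
    )
  }
  is_total <- raw$model == "Total"
  if (sum(is_total) != 1L) {
    qm_stop("frequency fixture needs exactly one 'Total' row", "qm_fixture_error")
  }
  cells <- raw[!is_total, , drop = FALSE]
  tot <- raw[is_total, , drop = FALSE]
  counts <- as.matrix(cells[, c("grade1", "grade3", "grade5")])
  rownames(counts) <- cells$model
  if (any(counts < 0) || any(counts != round(counts))) {
    qm_stop("frequency cells must be non-negative integers", "qm_fixture_error")
  }
  bad_row <- which(rowSums(counts) != cells$total)
  if (length(bad_row) > 0L) {
    qm_stop(
      sprintf("row total mismatch for model '%s': cells sum to %d, stored total %d",
              cells$model[bad_row[1L]], rowSums(counts)[bad_row[1L]],
              cells$total[bad_row[1L]]),
      "qm_fixture_error"
    )
  }
  col_stored <- unlist(tot[, c("grade1", "grade3", "grade5")])
  bad_col <- which(colSums(counts) != col_stored)
  if (length(bad_col) > 0L) {
    qm_stop(
      sprintf("column total mismatch for %s: cells sum to %d, stored total %d",
              names(col_stored)[bad_col[1L]], colSums(counts)[bad_col[1L]],
              col_stored[bad_col[1L]]),
      "qm_fixture_error"
    )
  }
  if (sum(counts) != tot$total) {
    qm_stop(
      sprintf("grand total mismatch: cells sum to %d, stored total %d",
              sum(counts), tot$total),
      "qm_fixture_error"
    )
  }
  structure(
    list(
      counts = counts,
      row_totals = rowSums(counts),
      col_totals = colSums(counts),
      grand_total = sum(counts)
    ),
    class = "qm_frequency_table"
  )
}

#' @export
print.qm_frequency_table <- function(x, ...) {
  cat("<qm_frequency_table> mental models of the shape of the Earth\n")
  m <- cbind(x$counts, total = x$row_totals)
  m <- rbind(m, Total = c(x$col_totals, x$grand_total))
  print(m)
  invisible(x)
}
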