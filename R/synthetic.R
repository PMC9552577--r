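#' Configuration for the synthetic concept-space generator
#'
#' Controls the random generation of concept spaces, contexts, and
#' trajectories with the structure the formalism assumes: a feature basis, a
#' subset of observation labels, and salience-weighted amplitudes. The
#' `concentration` parameter sets the spread of the squared amplitudes
#' (symmetric Dirichlet): low values give peaked, convergent-like states;
#' high values give near-uniform, divergent-like states.
#'
#' @param n_features number of basis labels (>= 2).
#' @param n_observations number of labels flagged as observations, in
#'   `[1, n_features]`.
#' @param concentration positive Dirichlet concentration for squared
#'   amplitudes.
#' @param context_size number of labels in a generated context (>= 1, at most
#'   `n_features`).
#' @param n_steps number of steps in a generated trajectory (>= 0).
#' @param seed integer seed; every generator call is a pure function of its
#'   config.
#' @param random_phases if `TRUE`, amplitudes get uniform random complex
#'   phases; by default phases are zero (real weights), which matches the
#'   usual real-weight reading of typicality while the complex path stays
#'   exercised elsewhere.
#' @return an object of class `qm_generator_config`.
#' @export
qm_generator_config <- function(n_features = 12, n_observations = 6,
                                concentration = 1, context_size = 3,
                                n_steps = 6, seed = 1,
                                random_phases = FALSE) {
  stopifnot(
    n_features >= 2,
    n_observations >= 1, n_observations <= n_features,
    is.finite(concentration), concentration > 0,
    context_size >= 1, context_size <= n_features,
    n_steps >= 0
  )
  structure(
    list(
      n_features = as.integer(n_features),
      n_observations = as.integer(n_observations),
      concentration = as.numeric(concentration),
      context_size = as.integer(context_size),
      n_steps = as.integer(n_steps),
      seed = as.integer(seed),
      random_phases = isTRUE(random_phases)
    ),
    class = "qm_generator_config"
  )
}

synthetic_basis <- function(config) {
  qm_basis(sprintf("f%02d", seq_len(config$n_features)))
}

#' Generate a random concept
#'
#' Squared amplitudes are drawn from a symmetric Dirichlet distribution with
#' the configured concentration (via normalized gamma draws); amplitudes are
#' their square roots, with optional uniform random phases. The first
#' `n_observations` labels are flagged as observations. Identical configs
#' (including seed) give identical concepts.
#'
#' @param config a [qm_generator_config].
#' @return a [qm_concept] with a normalized state.
#' @export
random_concept <- function(config) {
  stopifnot(inherits(config, "qm_generator_config"))
  basis <- synthetic_basis(config)
  withr::with_seed(config$seed, {
    w <- stats::rgamma(config$n_features, shape = config$concentration)
    if (all(w == 0)) w <- rep(1, config$n_features)  # extreme concentration underflow
    w <- w / sum(w)
    amps <- sqrt(w)
    if (config$random_phases) {
      amps <- amps * exp(2i * pi * stats::runif(config$n_features))
    }
    qm_concept(
      sprintf("synthetic-%d", config$seed),
      qm_state(basis, amps, normalize = TRUE),
      observations = basis$labels[seq_len(config$n_observations)]
    )
  })
}

#' Generate a random context
#'
#' A uniformly sampled label subset of the configured size.
#'
#' @param config a [qm_generator_config].
#' @return a [qm_context].
#' @export
random_context <- function(config) {
  stopifnot(inherits(config, "qm_generator_config"))
  basis <- synthetic_basis(config)
  withr::with_seed(config$seed + 1L, {
    labels <- sort(sample(basis$labels, config$context_size))
    qm_context(sprintf("synthetic-ctx-%d", config$seed), labels)
  })
}

#' Generate a random trajectory
#'
#' Fuzzes the trajectory engine: starting from a random concept state,
#' alternates elaboration with random information states, context
#' application (with a context guaranteed to overlap the current state), and
#' compact/expand moves, recording profiles throughout. All operations are
#' drawn through one seeded stream, so identical configs give identical
#' trajectories.
#'
#' @param config a [qm_generator_config].
#' @return a [qm_trajectory] with `n_steps + 1` profiles.
#' @export
random_trajectory <- function(config) {
  stopifnot(inherits(config, "qm_generator_config"))
  basis <- synthetic_basis(config)
  concept <- random_concept(config)
  n_sal <- max(1L, min(config$n_features - 1L, config$n_features %/% 2L))
  environment <- list(
    obs = qm_observation_set(basis, concept$observations),
    ctx = random_context(config),
    obsv = qm_divergence_observable(
      basis, mode = "projector",
      salient_labels = basis$labels[seq_len(n_sal)]
    )
  )
  steps <- withr::with_seed(config$seed + 2L, {
    lapply(seq_len(config$n_steps), function(k) {
      kind <- c("elaborate", "context", "compact")[(k - 1L) %% 3L + 1L]
      switch(kind,
        elaborate = {
          w <- stats::rgamma(config$n_features, shape = config$concentration)
          if (all(w == 0)) w <- rep(1, config$n_features)
          info <- qm_state(basis, sqrt(w / sum(w)), normalize = TRUE)
          qm_change_step(
            sprintf("fuzz %d: elaborate", k), "IL", "elaborate",
            function(state) elaborate(state, info)
          )
        },
        context = {
          size <- sample.int(config$n_features - 1L, 1L)
          qm_change_step(
            sprintf("fuzz %d: context", k), "RR", "context projection",
            function(state) {
              # include the state's top label so projection cannot annihilate
              top <- state$basis$labels[which.max(Mod(state$amplitudes)^2)]
              labels <- unique(c(top, sample(state$basis$labels, size)))
              apply_context(state, qm_context("fuzz", labels))
            }
          )
        },
        compact = {
          thr <- stats::runif(1, 0.5, 1)
          qm_change_step(
            sprintf("fuzz %d: compact", k), "RR", "compact form",
            function(state) compact_state(state, thr)
          )
        }
      )
    })
  })
  withr::with_seed(config$seed + 3L, {
    run_trajectory(concept$state, steps, environment)
  })
}
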