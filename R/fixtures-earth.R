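# Earth-shape conceptual-change case study: two children's trajectories from
# no model of the Earth to a spherical-Earth model, replayed as operator
# applications. The case study makes qualitative claims — the direction each
# mode-of-thought measure moves at each step. The numeric amplitudes below
# are package fixtures, chosen once so that every recorded arrow is
# reproduced with margin under the default 0.05 arrow tolerance, then
# frozen; regression tests pin all 42 arrow cells. The arrows, not the
# magnitudes, are the modeled content.

.earth <- local({
  labels <- c("ground", "horizon", "sky", "ball", "red", "balloon",
              "flat", "round", "sphere", "hollow", "planet", "mars")
  list(
    labels = labels,
    # features a child has experienced directly with their senses
    observations = c("ground", "horizon", "sky", "ball", "red", "balloon"),
    # the pretend-play context: a red balloon standing in for Mars
    context = c("red", "balloon", "mars"),
    # eigenvalues of the weighted divergence observable: remoteness of each
    # feature from the core of the earth concept. Remoteness is
    # concept-relative, not concreteness: flat ground and the flat horizon
    # are the core percepts (0) and the simple shape abstractions sit close
    # to them, while balls, red things, Mars, and above all balloons are
    # remote associates that only enter earth-related thought through
    # analogy. Spread over this grading is the divergence measure.
    remoteness = c(
      ground = 0, horizon = 0, sky = 0.1261, ball = 0.9374, red = 1.2869,
      balloon = 4.4713, flat = 0.4069, round = 0.2217, sphere = 0.4089,
      hollow = 0.1583, planet = 1.2668, mars = 2.0501
    )
  )
})

# compaction thresholds used by child i (full precision: the kept label set
# depends on where cumulative mass crosses the threshold)
.earth_thr_disk <- 0.9898415
.earth_thr_dual <- 0.8821368

#' Feature basis of the Earth-shape case study
#'
#' Twelve features spanning the children's mental models: six direct
#' observations (flat ground underfoot, the flat horizon, the sky, balls,
#' red things, balloons) and six abstractions (flatness, roundness,
#' sphericality, hollowness, the planet category, Mars).
#'
#' @return a [qm_basis].
#' @export
earth_basis <- function() {
  qm_basis(.earth$labels)
}

#' Fixed measurement environment of the Earth-shape case study
#'
#' The environment against which every trajectory profile is measured: the
#' observation set (the six concrete features), the pretend-play context
#' (red, balloon, Mars), and a weighted divergence observable whose
#' eigenvalues grade each feature by its remoteness from the core of the
#' earth concept — convergent, compact thought concentrates on near-core
#' features and has low spread; divergent thought activates remote
#' associates and has high spread.
#'
#' @return list with components `obs`, `ctx`, `obsv`, as used by
#'   [run_trajectory()].
#' @export
earth_environment <- function() {
  b <- earth_basis()
  list(
    obs = qm_observation_set(b, .earth$observations),
    ctx = qm_context("pretend play", .earth$context),
    obsv = qm_divergence_observable(b, mode = "weighted",
                                    eigenvalues = .earth$remoteness)
  )
}

# normalized state over the earth basis from named amplitude weights
earth_state <- function(weights) {
  normalize(qm_state(earth_basis(), weights))
}

# compact form of a bare state (wraps it as an anonymous concept)
compact_state <- function(state, mass_threshold) {
  compact_form(qm_concept("state", state), mass_threshold)
}

#' Starting state of both children
#'
#' Before any model of the Earth forms, the child's earth-related thought is
#' grounded entirely in direct observations (reported abstractness 0),
#' dominated by the flat ground underfoot.
#'
#' @return a normalized [qm_state] supported on observation labels only.
#' @export
earth_initial_state <- function() {
  earth_state(c(ground = 2.4503, horizon = 0.2447, sky = 0.1641,
                ball = 0.5740, red = 0.0348, balloon = 0.1094))
}

# step-1 information for both children: flatness, anchored on the
# flat-ground and flat-horizon observations it abstracts over
.info_flat <- function() {
  earth_state(c(flat = 2.4251, ground = 1.2160, horizon = 0.0204))
}

#' The shape question asked of the Dual-Earth state
#'
#' The cross-factor observable \eqn{\hat O_s \otimes \hat O_d}: the
#' flatness-answer projector on the operative (disk) factor and the
#' sphere-answer projector on the unintegrated (sphere) factor, with the
#' contradictory answer pairs declared (a flat/round-disk answer contradicts
#' a sphere answer).
#'
#' @return list with `op_s`, `op_d` ([qm_operator]s) and `pairs`
#'   (data.frame of contradictory label pairs) for [joint_question()].
#' @export
earth_shape_question <- function() {
  b <- earth_basis()
  flatness <- c("ground", "horizon", "flat", "round")
  list(
    op_s = projector(b, flatness),
    op_d = projector(b, "sphere"),
    pairs = data.frame(a = flatness, b = "sphere", stringsAsFactors = FALSE)
  )
}

#' Conceptual-change trajectory fixture for child i
#'
#' Five steps: (1) a Flat-Earth model forms as an abstraction over
#' observations of flat ground and horizon (IL); (2) socially transmitted
#' roundness is elaborated onto the compact form of the Flat model, giving a
#' Disk model (SL); (3) the socially transmitted sphere fact is orthogonal
#' to the Disk model (a thing cannot be both a flat disk and a sphere), so
#' it is combined unintegrated as a tensor product — the Dual-Earth model
#' (SL); (4) a cross-factor shape question exposes the contradiction between
#' the two components (it cannot be answered), and the sphere idea is
#' elaborated onto the *expanded* Disk model, yielding the Spherical-Earth
#' model (RR); (5) pretending a red balloon is Mars enters as a low-weight
#' elaboration that moves no measure beyond tolerance (SL).
#'
#' @return list with `initial` ([qm_state]), `steps` (list of
#'   [qm_change_step]), and `environment` (as for [run_trajectory()]).
#' @seealso [child_j_fixture()], [run_trajectory()], [arrow_table()]
#' @export
child_i_fixture <- function() {
  stash <- new.env(parent = emptyenv())
  info_round <- earth_state(c(round = 0.3790, ground = 0.4585,
                              horizon = 0.0633))
  sphere_fact <- basis_state(earth_basis(), "sphere")
  info_sphere <- earth_state(c(sphere = 2.4801, round = 1.8617,
                               ground = 1.8662, horizon = 0.1396))
  info_pretend <- earth_state(c(mars = 0.0203, balloon = 0.8765,
                                red = 0.0203, sphere = 0.0304))
  q <- earth_shape_question()
  up <- "\u2191"; dn <- "\u2193"; fl <- "\u2212"
  steps <- list(
    qm_change_step(
      "No earth model to flat earth", "IL", "abstraction over observations",
      function(state) elaborate(state, .info_flat()),
      tag = "Flat", expected_arrows = c(up, fl, fl)
    ),
    qm_change_step(
      "Flat earth to disk earth", "SL", "elaborate (compact form)",
      function(state) {
        elaborate(compact_state(state, .earth_thr_disk), info_round)
      },
      tag = "Disk", expected_arrows = c(fl, dn, fl)
    ),
    qm_change_step(
      "Disk earth to dual earth", "SL", "elaborate + tensor combination",
      function(state) {
        stash$disk_expanded <- state
        combine_unintegrated(compact_state(state, .earth_thr_dual),
                             sphere_fact)
      },
      tag = "Dual", expected_arrows = c(fl, dn, fl)
    ),
    qm_change_step(
      "Dual earth to spherical earth", "RR",
      "incompatible question, then elaborate on expanded form",
      function(state) {
        ans <- joint_question(state, q$op_s, q$op_d,
                              contradictory_pairs = q$pairs)
        out <- elaborate(stash$disk_expanded, info_sphere)
        attr(out, "question_incompatible") <- ans$incompatible
        out
      },
      tag = "Sphere", expected_arrows = c(up, up, fl)
    ),
    qm_change_step(
      "Pretend red balloon is mars", "SL", "elaborate (low weight)",
      function(state) elaborate(state, info_pretend),
      tag = "Sphere", expected_arrows = c(fl, fl, fl)
    )
  )
  list(initial = earth_initial_state(), steps = steps,
       environment = earth_environment())
}

#' Conceptual-change trajectory fixture for child j
#'
#' Nine steps: (1) a Flat-Earth model forms, as for child i (IL); (2) the
#' sphere idea is fitted against the *expanded* Flat model — the sky becomes
#' the top hemisphere and the ground the bottom — giving a Hollow-Earth
#' model anchored on core percepts (RR); (3) Mars and the planet category
#' are added as new mental objects (SL); (4) planets are grounded as solid
#' spheres, like balls (SL); (5) Earth is recognized as a planet (SL); (6)
#' the PLANET concept is projected onto the EARTH concept — Earth must be a
#' sphere (RR); (7) Mars is learnt to be red and spherical, like a ball
#' (SL); (8) a red spherical balloon is observed (IL); (9) pretend play
#' projects the current thought into the red-balloon-as-Mars context (RR) —
#' the only step in either trajectory that moves context-specificity, and
#' one that *lowers* abstractness because the context contains the concrete
#' balloon and red observations.
#'
#' @return list with `initial`, `steps`, `environment`, and
#'   `planet_concept` (the frozen PLANET [qm_concept] used by step 6).
#' @seealso [child_i_fixture()], [run_trajectory()], [arrow_table()]
#' @export
child_j_fixture <- function() {
  env <- earth_environment()
  info_hollow <- earth_state(c(hollow = 1.9162, ground = 2.0463,
                               horizon = 0.4518, sky = 0.0418))
  info_mars_planet <- earth_state(c(mars = 0.8291, planet = 2.3357,
                                    sky = 1.3603))
  info_sphere_ball <- earth_state(c(sphere = 0.1496, ball = 0.5565,
                                    ground = 2.3664))
  info_planet <- earth_state(c(planet = 0.1162, flat = 1.2444,
                               ground = 1.7287))
  planet_concept <- qm_concept(
    "planet",
    earth_state(c(planet = 0.9694, sphere = 1.0558, ball = 0.4437,
                  round = 0.0291)),
    observations = "ball"
  )
  info_mars_red <- earth_state(c(mars = 0.4117, red = 0.8746,
                                 sphere = 1.8816, ball = 2.4879))
  info_balloon <- earth_state(c(balloon = 0.0203, red = 0.0251,
                                sphere = 1.2289, ball = 2.4739))
  up <- "\u2191"; dn <- "\u2193"; fl <- "\u2212"
  steps <- list(
    qm_change_step(
      "No earth model to flat earth", "IL", "abstraction over observations",
      function(state) elaborate(state, .info_flat()),
      tag = "Flat", expected_arrows = c(up, fl, fl)
    ),
    qm_change_step(
      "Flat earth to hollow earth", "RR", "elaborate (expanded form)",
      function(state) elaborate(state, info_hollow),
      tag = "Hollow", expected_arrows = c(fl, dn, fl)
    ),
    qm_change_step(
      "Mars is a planet", "SL", "elaborate (new mental objects)",
      function(state) elaborate(state, info_mars_planet),
      tag = "Hollow", expected_arrows = c(fl, fl, fl)
    ),
    qm_change_step(
      "Planet is a solid sphere", "SL", "elaborate",
      function(state) elaborate(state, info_sphere_ball),
      tag = "Hollow", expected_arrows = c(dn, fl, fl)
    ),
    qm_change_step(
      "Earth is a planet", "SL", "elaborate",
      function(state) elaborate(state, info_planet),
      tag = "Hollow", expected_arrows = c(up, fl, fl)
    ),
    qm_change_step(
      "Earth is a sphere", "RR", "cross-concept projection",
      function(state) {
        project_compare(planet_concept, qm_concept("earth", state))
      },
      tag = "Sphere", expected_arrows = c(up, up, fl)
    ),
    qm_change_step(
      "Mars is red, spherical", "SL", "elaborate",
      function(state) elaborate(state, info_mars_red),
      tag = "Sphere", expected_arrows = c(dn, fl, fl)
    ),
    qm_change_step(
      "Balloon is red, spherical", "IL", "elaborate",
      function(state) elaborate(state, info_balloon),
      tag = "Sphere", expected_arrows = c(dn, fl, fl)
    ),
    qm_change_step(
      "Pretend red balloon is mars", "RR", "context projection",
      function(state) apply_context(state, env$ctx),
      tag = "Sphere", expected_arrows = c(dn, up, up)
    )
  )
  list(initial = earth_initial_state(), steps = steps, environment = env,
       planet_concept = planet_concept)
}
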