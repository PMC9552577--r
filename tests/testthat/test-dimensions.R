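test_that("abstractness complements the observation mass", {
  b <- qm_basis(c("o1", "o2", "a1", "a2"))
  obs <- qm_observation_set(b, c("o1", "o2"))
  grounded <- qm_state(b, c(0.6, 0.8, 0, 0))
  expect_equal(abstractness(grounded, obs), 0)
  abstract <- qm_state(b, c(0, 0, 0.6, 0.8))
  expect_equal(abstractness(abstract, obs), 1)
  half <- qm_state(b, c(1, 0, 1, 0) / sqrt(2))
  expect_equal(abstractness(half, obs), 0.5)
  # reported abstractness + raw observation mass is exactly 1
  for (seed in 1:10) {
    s <- rand_state(b, seed + 40)
    expect_equal(abstractness(s, obs) + observation_mass(s, obs), 1)
  }
})

test_that("context-specificity is the Born mass inside the context", {
  b <- qm_basis(c("hunt", "smell", "furry", "tail"))
  ctx <- qm_context("hunting", c("hunt", "smell"))
  expect_equal(context_specificity(basis_state(b, "hunt"), ctx), 1)
  expect_equal(context_specificity(basis_state(b, "furry"), ctx), 0)
  # dog fixture vs the hunting context: d_h^2 + d_s^2
  dog <- example_concepts()$dog
  w <- born_weights(dog$state)
  expect_equal(
    context_specificity(dog$state, qm_context("hunting", c("hunt", "smell"))),
    unname(w[["hunt"]] + w[["smell"]]),
    tolerance = 1e-12
  )
  s <- rand_state(b, 9)
  expect_equal(context_shift(s, ctx), 1 - context_specificity(s, ctx))
})

test_that("divergence is the standard deviation of the salience observable", {
  b <- qm_basis(c("u1", "u2", "u3"))
  wobs <- qm_divergence_observable(b, mode = "weighted",
                                   eigenvalues = c(1, 2, 3))
  # eigenstates have zero spread
  expect_equal(divergence(basis_state(b, "u2"), wobs), 0)
  # uniform over eigenvalues {1,2,3}: variance 2/3
  uni <- qm_state(b, rep(1, 3) / sqrt(3))
  expect_equal(divergence(uni, wobs), sqrt(2 / 3), tolerance = 1e-12)
  # projector mode: p = 1/2 gives sqrt(p(1-p)) = 1/2
  pobs <- qm_divergence_observable(b, salient_labels = "u1")
  s <- qm_state(b, c(1, 1, 0) / sqrt(2))
  expect_equal(divergence(s, pobs), 0.5, tolerance = 1e-12)
  # full-basis projector mode is rejected (identity measures nothing)
  expect_error(qm_divergence_observable(b, salient_labels = b$labels),
               class = "qm_numerical_error")
})

test_that("projector-mode divergence equals p(1-p) and brute-force variance", {
  withr::with_seed(13, {
    for (k in 1:60) {
      d <- sample(2:12, 1)
      b <- rand_basis(d)
      sal <- sample(b$labels, sample(seq_len(d - 1), 1))
      obsv <- qm_divergence_observable(b, salient_labels = sal)
      s <- rand_state(b, k + 7000)
      p <- expectation(s, projector(b, sal))
      gd <- divergence(s, obsv)
      expect_equal(gd^2, p * (1 - p), tolerance = 1e-9)
      expect_equal(gd^2, brute_force_variance(s, obsv$op$matrix),
                   tolerance = 1e-9)
    }
  })
})

test_that("abstractions over observations are normalized superpositions", {
  b <- qm_basis(c("o1", "o2", "o3", "a1"))
  obs <- qm_observation_set(b, c("o1", "o2", "o3"))
  expect_equal(build_abstraction(obs, c(o2 = 1))$amplitudes,
               basis_state(b, "o2")$amplitudes)
  eq <- build_abstraction(obs, c(o1 = 1, o2 = 1, o3 = 1))
  expect_equal(Mod(eq$amplitudes[1:3]), rep(1 / sqrt(3), 3),
               ignore_attr = TRUE)
  # a flat-earth model built purely from observations has abstractness 0
  flat0 <- build_abstraction(obs, c(o1 = 0.8, o2 = 0.6))
  expect_equal(abstractness(flat0, obs), 0)
  expect_error(build_abstraction(obs, c(o1 = 0)),
               class = "qm_normalization_error")
  expect_error(build_abstraction(obs, c(a1 = 1)),
               class = "qm_unknown_label_error")
})

test_that("profiles compose the three measures and ignore global phase", {
  fam <- orthogonality_family()
  # a pure observation state inside the context, eigenstate of the observable
  s1 <- basis_state(fam$basis, "anchor")
  expect_equal(
    unclass(dimension_profile(
      s1, fam$obs, qm_context("goal", "anchor"), fam$obsv
    )),
    c(gamma_A = 0, gamma_D = 0, gamma_C = 1),
    tolerance = 1e-12
  )
  # fully abstract, maximal projector spread, half inside the context
  b <- qm_basis(c("obs", "sal", "goal", "idle"))
  env <- list(obs = qm_observation_set(b, "obs"),
              ctx = qm_context("goal", "goal"),
              obsv = qm_divergence_observable(b, salient_labels = "sal"))
  s2 <- qm_state(b, c(0, 1, 1, 0) / sqrt(2))
  expect_equal(
    unclass(dimension_profile(s2, env$obs, env$ctx, env$obsv)),
    c(gamma_A = 1, gamma_D = 0.5, gamma_C = 0.5),
    tolerance = 1e-12
  )
  # global phase invariance
  s <- rand_state(fam$basis, 55)
  rotated <- qm_state(fam$basis, s$amplitudes * exp(0.7i))
  ctx <- qm_context("goal", "goal")
  expect_equal(dimension_profile(s, fam$obs, ctx, fam$obsv),
               dimension_profile(rotated, fam$obs, ctx, fam$obsv),
               tolerance = 1e-12)
  # basis-label permutation invariance
  perm <- c(3, 1, 4, 2)
  bp <- qm_basis(fam$basis$labels[perm])
  sp <- qm_state(bp, s$amplitudes[perm])
  envp <- list(obs = qm_observation_set(bp, fam$obs$labels),
               obsv = qm_divergence_observable(bp, salient_labels = "anchor"))
  expect_equal(dimension_profile(sp, envp$obs, ctx, envp$obsv),
               dimension_profile(s, fam$obs, ctx, fam$obsv),
               tolerance = 1e-12)
})

test_that("profile deltas quantize into arrows at the tolerance", {
  p1 <- structure(c(gamma_A = 0.2, gamma_D = 0.5, gamma_C = 0.1),
                  class = "qm_profile")
  expect_equal(unname(delta_profile(p1, p1)),
               rep(ARROW_FLAT, 3))
  p2 <- structure(c(gamma_A = 0.4, gamma_D = 0.3, gamma_C = 0.12),
                  class = "qm_profile")
  expect_equal(unname(delta_profile(p1, p2)),
               c(ARROW_UP, ARROW_DOWN, ARROW_FLAT))
  # a huge tolerance flattens every arrow
  expect_equal(unname(delta_profile(p1, p2, tol = 10)), rep(ARROW_FLAT, 3))
})

test_that("each measure can vary widely while the other two stay fixed", {
  fam <- orthogonality_family()
  prof <- function(amps) {
    dimension_profile(qm_state(fam$basis, amps, normalize = TRUE),
                      fam$obs, fam$ctx, fam$obsv)
  }
  base <- c(grounded = 0.1, anchor = 0.5, goal = 0.2, idle = 0.2)
  move <- function(from, to, t) {
    w <- base; w[to] <- w[to] + t * w[from]; w[from] <- (1 - t) * w[from]
    sqrt(w)
  }
  # abstractness: grounded <-> idle (both outside salient set and context)
  pa <- sapply(c(0, 1), function(t) prof(move("grounded", "idle", t)))
  expect_gte(abs(pa["gamma_A", 2] - pa["gamma_A", 1]), 0.05)
  expect_lt(abs(pa["gamma_D", 2] - pa["gamma_D", 1]), 1e-9)
  expect_lt(abs(pa["gamma_C", 2] - pa["gamma_C", 1]), 1e-9)
  # divergence: anchor <-> grounded (both observations, outside the context)
  pd <- sapply(c(0, 0.9), function(t) prof(move("anchor", "grounded", t)))
  expect_gte(abs(pd["gamma_D", 2] - pd["gamma_D", 1]), 0.05)
  expect_lt(abs(pd["gamma_A", 2] - pd["gamma_A", 1]), 1e-9)
  expect_lt(abs(pd["gamma_C", 2] - pd["gamma_C", 1]), 1e-9)
  # context-specificity: goal <-> idle (both abstract, outside salient set)
  pc <- sapply(c(0, 1), function(t) prof(move("idle", "goal", t)))
  expect_gte(abs(pc["gamma_C", 2] - pc["gamma_C", 1]), 0.05)
  expect_lt(abs(pc["gamma_A", 2] - pc["gamma_A", 1]), 1e-9)
  expect_lt(abs(pc["gamma_D", 2] - pc["gamma_D", 1]), 1e-9)
})
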