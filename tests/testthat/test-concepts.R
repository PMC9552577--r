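test_that("typicality reads off amplitude magnitudes", {
  b <- qm_basis(c("sparrow", "penguin"))
  bird <- qm_concept("bird", qm_state(b, c(0.6, 0.8)))
  expect_equal(typicality(bird, "sparrow"), 0.6)
  pure <- qm_concept("sparrow", basis_state(b, "sparrow"))
  expect_equal(typicality(pure, "sparrow"), 1)
  expect_equal(typicality(pure, "penguin"), 0)
  expect_error(typicality(bird, "ostrich"), class = "qm_unknown_label_error")
})

test_that("elaboration adds information weighted by relatedness", {
  b <- qm_basis(c("x", "y"))
  psi <- qm_state(b, c(1, 1) / sqrt(2))
  ex <- basis_state(b, "x")
  # |psi> + |x><x|psi> has amplitudes (2, 1)/sqrt(2); normalized (2, 1)/sqrt(5)
  raw <- elaborate(psi, ex, renormalize = FALSE)
  expect_equal(Re(raw$amplitudes), c(x = 2, y = 1) / sqrt(2))
  expect_equal(Re(elaborate(psi, ex)$amplitudes),
               c(x = 2, y = 1) / sqrt(5))
  # fixed direction: elaborating a state with itself doubles then renormalizes
  expect_equal(Re(elaborate(ex, ex, renormalize = FALSE)$amplitudes),
               c(x = 2, y = 0))
  expect_equal(elaborate(ex, ex)$amplitudes, ex$amplitudes)
  # orthogonal information acts as the identity (property over random pairs)
  b6 <- rand_basis(6)
  withr::with_seed(3, {
    for (k in 1:20) {
      half <- sample(b6$labels, 3)
      s <- normalize(qm_state(b6, stats::setNames(stats::rnorm(3), half)))
      info <- normalize(qm_state(
        b6, stats::setNames(stats::rnorm(3), setdiff(b6$labels, half))
      ))
      expect_equal(elaborate(s, info)$amplitudes, s$amplitudes,
                   tolerance = 1e-12)
    }
  })
  # mass along the information direction never decreases
  withr::with_seed(4, {
    for (k in 1:20) {
      s <- rand_state(b6, k); info <- rand_state(b6, k + 50)
      before <- Mod(inner(info, s))^2
      after <- Mod(inner(info, elaborate(s, info)))^2
      expect_gte(after, before - 1e-12)
    }
  })
  expect_error(elaborate(psi, qm_state(b, c(2, 0))),
               class = "qm_normalization_error")
})

test_that("unintegrated combination forms a separable product state", {
  b <- qm_basis(c("flatland", "disk", "sphere", "orbit"))
  disk <- qm_state(b, c(0.7, 0.71, 0, 0), normalize = TRUE)
  sphere <- basis_state(b, "sphere")
  expect_equal(Mod(inner(sphere, disk)), 0)  # mutually exclusive shapes
  dual <- combine_unintegrated(disk, sphere)
  expect_s3_class(dual, "qm_product_state")
  expect_identical(separability_test(dual)$verdict, "separable")
  expect_equal(product_norm(dual), 1, tolerance = 1e-12)
  # non-negligible overlap triggers a warning
  expect_warning(combine_unintegrated(disk, qm_state(b, c(1, 1, 1, 1) / 2)),
                 "elaborate")
})

test_that("context application trims to the context subspace", {
  b <- qm_basis(c("warm", "soft", "rectangular"))
  blanket <- qm_state(b, c(0.7, 0.5, 0.51), normalize = TRUE)
  sleep <- qm_context("going to bed", c("warm", "soft"))
  raw <- apply_context(blanket, sleep, renormalize = FALSE)
  # under orthonormal features the projected amplitudes are the originals
  expect_equal(raw$amplitudes[c("warm", "soft")],
               blanket$amplitudes[c("warm", "soft")])
  expect_equal(Mod(raw$amplitudes[["rectangular"]]), 0)
  # dog in a hunting context: support exactly {hunt, smell}
  dog <- example_concepts()$dog
  hunting <- qm_context("hunting", c("hunt", "smell"))
  focused <- apply_context(dog$state, hunting)
  expect_setequal(names(which(born_weights(focused) > 0)), c("hunt", "smell"))
  # projected state lies inside the context subspace
  expect_equal(
    expectation(focused, projector(focused$basis, hunting$labels)), 1,
    tolerance = 1e-12
  )
  # full-basis context is the identity
  full <- qm_context("everything", b$labels)
  expect_equal(apply_context(blanket, full)$amplitudes, blanket$amplitudes)
  expect_error(
    apply_context(basis_state(b, "rectangular"), sleep),
    class = "qm_annihilation_error"
  )
})

test_that("compact forms keep the smallest typicality-ordered mass prefix", {
  island <- example_concepts()$island
  compact <- compact_form(island, 0.95)
  expect_setequal(names(which(born_weights(compact) > 0)), c("land", "water"))
  # threshold 1 keeps the full expanded state
  expect_equal(compact_form(island, 1)$amplitudes,
               expanded_form(island)$amplitudes, tolerance = 1e-12)
  # uniform state over 10 labels at threshold 0.5 keeps exactly 5
  b10 <- rand_basis(10)
  uni <- qm_concept("uniform", qm_state(b10, rep(1, 10), normalize = TRUE))
  expect_length(which(born_weights(compact_form(uni, 0.5)) > 0), 5)
  # coverage and minimality over random concepts and thresholds
  withr::with_seed(8, {
    for (k in 1:15) {
      con <- qm_concept("c", rand_state(rand_basis(8), k + 300))
      thr <- stats::runif(1, 0.3, 0.99)
      keep <- names(which(born_weights(compact_form(con, thr)) > 0))
      w <- born_weights(con$state)
      expect_gte(sum(w[keep]), thr - 1e-9)
      last <- keep[length(keep)]  # salience order puts the smallest kept last
      ordered <- intersect(con$salience_order, keep)
      expect_lt(sum(w[setdiff(keep, ordered[length(ordered)])]), thr)
    }
  })
})

test_that("expanded forms contain every compact form and raise divergence", {
  island <- example_concepts()$island
  expanded <- expanded_form(island)
  expect_true(all(born_weights(expanded)[c("shoreline", "finland")] > 0))
  for (thr in c(0.5, 0.8, 0.95)) {
    sup_c <- names(which(born_weights(compact_form(island, thr)) > 0))
    sup_e <- names(which(born_weights(expanded) > 0))
    expect_true(all(sup_c %in% sup_e))
  }
  remoteness <- c(land = 0, water = 0, shoreline = 1, tropical = 2,
                  vacation = 2, finland = 3)
  obsv <- qm_divergence_observable(island$state$basis, mode = "weighted",
                                   eigenvalues = remoteness)
  expect_gte(divergence(expanded, obsv),
             divergence(compact_form(island, 0.95), obsv))
})

test_that("cross-concept projection matches the brute-force double sum", {
  # identical concepts with the identity map are unchanged
  b <- qm_basis(c("p", "q", "r"))
  con <- qm_concept("c", rand_state(b, 77, real = TRUE))
  expect_equal(project_compare(con, con)$amplitudes,
               normalize(qm_state(b, con$state$amplitudes^2))$amplitudes,
               tolerance = 1e-12)
  # disjoint label sets with the default map share nothing
  c1 <- qm_concept("a", rand_state(rand_basis(3, "a"), 1))
  c2 <- qm_concept("b", rand_state(rand_basis(3, "b"), 2))
  expect_error(project_compare(c1, c2), class = "qm_annihilation_error")
  # planet/earth sharing only "sphere": output concentrates there
  planet <- qm_concept("planet", qm_state(
    qm_basis(c("sphere", "orbits")), c(0.8, 0.6)
  ))
  earth <- qm_concept("earth", qm_state(
    qm_basis(c("sphere", "earthground")), c(0.3, 0.954), normalize = TRUE
  ))
  proj <- project_compare(planet, earth)
  expect_equal(Mod(proj$amplitudes[["sphere"]]), 1, tolerance = 1e-9)
  # oracle comparison with a custom correspondence map
  map <- data.frame(source = "orbits", target = "earthground", value = 0.4)
  got <- project_compare(planet, earth, basis_map = map)
  overlap <- default_overlap(planet, earth)
  overlap["orbits", "earthground"] <- 0.4
  want <- brute_force_projection(planet, earth, overlap)
  want <- want / sqrt(sum(Mod(want)^2))
  expect_equal(got$amplitudes, want, tolerance = 1e-12)
})

test_that("joint questions produce marginals, joint outcomes, and flags", {
  b <- qm_basis(c("flatland", "disk", "sphere", "orbit"))
  disk <- qm_state(b, c(0.8, 0.6, 0, 0))
  sphere <- basis_state(b, "sphere")
  dual <- tensor_product(disk, sphere)
  ps <- projector(b, c("flatland", "disk"))
  # a question touching only factor A returns factor A's distribution
  ans <- joint_question(dual, op_s = ps, op_d = NULL)
  expect_equal(unname(ans$marginal_a), unname(born_weights(disk)),
               tolerance = 1e-12)
  expect_equal(ans$outcomes["a_in", "b_in"] + ans$outcomes["a_in", "b_out"],
               expectation(disk, ps), tolerance = 1e-12)
  # contradictory flat-vs-sphere answers flag the question as unanswerable
  pairs <- data.frame(a = c("flatland", "disk"), b = "sphere")
  ans2 <- joint_question(dual, ps, projector(b, "sphere"),
                         contradictory_pairs = pairs)
  expect_true(ans2$incompatible)
  expect_equal(ans2$contradictory_mass, 1, tolerance = 1e-12)
  # both factors certain and compatible: single outcome with probability 1
  certain <- tensor_product(basis_state(b, "disk"), basis_state(b, "disk"))
  ans3 <- joint_question(certain, projector(b, "disk"), projector(b, "disk"))
  expect_equal(ans3$outcomes["a_in", "b_in"], 1, tolerance = 1e-12)
  expect_equal(sum(ans3$outcomes), 1, tolerance = 1e-12)
  # non-projector question operators are rejected
  notproj <- diagonal_op(b, c(2, 0, 0, 0))
  expect_error(joint_question(dual, notproj, NULL),
               class = "qm_hermitianity_error")
})
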