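test_that("the ABS rule reproduces its truth table with inclusive bounds", {
  p <- plasticity_parameters("nest")   # theta_minus 0.11, delta 2e-4
  # the four branches
  expect_equal(hebbian_delta(0.06, 0.16, p), 2e-4)    # LTP
  expect_equal(hebbian_delta(0.06, 0.13, p), -2e-4)   # homosynaptic LTD
  expect_equal(hebbian_delta(0.02, 0.16, p), -2e-4)   # heterosynaptic LTD
  expect_equal(hebbian_delta(0.02, 0.05, p), 0)       # otherwise
  # inclusive boundaries: omega_E = theta_pre and V = theta_minus
  expect_equal(hebbian_delta(0.05, 0.16, p), 2e-4)
  expect_equal(hebbian_delta(0.05, 0.11, p), -2e-4)
  # at V = theta_plus both LTP and homosynaptic conditions hold as
  # printed; LTP wins by branch order
  expect_equal(hebbian_delta(0.05, 0.15, p), 2e-4)
  expect_equal(hebbian_delta(0.02, 0.15, p), -2e-4)   # hetero at boundary
  # below both postsynaptic thresholds with active pre: no change only
  # under theta_minus
  expect_equal(hebbian_delta(0.06, 0.1099, p), 0)
  # felix preset uses its own column
  pf <- plasticity_parameters("felix")
  expect_equal(hebbian_delta(0.06, 0.13, pf), 0)      # 0.13 < 0.14
  expect_equal(hebbian_delta(0.06, 0.145, pf), -8e-4)
})

test_that("apply_plasticity clips weights and refuses static projections", {
  p <- plasticity_parameters("nest")
  proj <- wire_projection(projection_spec("A1", "A1", "EE_local"), seed = 1)
  # ceiling clip
  proj$edges$weight[] <- 0.2249
  up <- apply_plasticity(proj, rep(1, 625), rep(1, 625), p)
  expect_true(all(up$edges$weight == 0.225))
  # floor clip
  proj$edges$weight[] <- 1e-4
  down <- apply_plasticity(proj, rep(1, 625), rep(0.13, 625), p)
  expect_true(all(down$edges$weight == 0))
  # silence changes nothing
  same <- apply_plasticity(proj, rep(0, 625), rep(0, 625), p)
  expect_identical(same$edges$weight, proj$edges$weight)
  ei <- wire_projection(projection_spec("A1", "A1", "EI"))
  expect_error(apply_plasticity(ei, rep(1, 625), rep(1, 625), p),
               "not plastic")
})

test_that("weights stay in [0, w_max] under randomised update sequences", {
  p <- plasticity_parameters("felix")
  proj <- wire_projection(projection_spec("A1", "A1", "EE_local"), seed = 2)
  set.seed(42)
  for (i in 1:60) {
    rates <- runif(625, 0, 0.12)
    pots <- runif(625, -0.1, 0.3)
    proj <- apply_plasticity(proj, rates, pots, p)
    expect_true(all(proj$edges$weight >= 0 & proj$edges$weight <= 0.225))
  }
  # per-step change never exceeds delta
  before <- proj$edges$weight
  proj2 <- apply_plasticity(proj, runif(625, 0, 0.12),
                            runif(625, -0.1, 0.3), p)
  expect_lte(max(abs(proj2$edges$weight - before)), p$delta + 1e-15)
})

test_that("compiled edge-store update agrees with the reference rule", {
  # the C++ kernel that drives the simulator must agree edge-for-edge
  # with the R reference implementation on random states
  p <- plasticity_parameters("nest")
  proj <- wire_projection(projection_spec("A1", "A1", "EE_local"), seed = 3)
  n <- 625L
  csc <- hebbnet:::compile_csc(proj$edges$pre, proj$edges$post,
                               proj$edges$weight, n)
  set.seed(7)
  ref <- proj
  for (i in 1:25) {
    rates <- runif(n, 0, 0.12)
    pots <- runif(n, -0.05, 0.3)
    ref <- apply_plasticity(ref, rates, pots, p)
    hebbnet:::abs_plasticity_csc(csc$p, csc$i, csc$x, rates >= p$theta_pre,
                                 pots, p$theta_plus, p$theta_minus,
                                 p$delta, p$w_min, p$w_max)
  }
  ref_csc <- hebbnet:::compile_csc(ref$edges$pre, ref$edges$post,
                                   ref$edges$weight, n)
  expect_equal(csc$x, ref_csc$x, tolerance = 1e-15)
})

test_that("co-activated patterns gain weight relative to uncorrelated ones", {
  # Hebbian sanity in a two-area toy network: two disjoint cell groups are
  # repeatedly co-activated across areas; within-pattern weights must end
  # up stronger than across-pattern weights.
  toy_areas <- data.frame(area = c("X", "Y"),
                          system = c("auditory", "articulatory"),
                          role = c("primary", "primary"),
                          stringsAsFactors = FALSE)
  toy_links <- data.frame(a = "X", b = "Y", class = "within_system",
                          stringsAsFactors = FALSE)
  arch <- architecture(areas = toy_areas, links = toy_links)
  net <- build_network(model_parameters("felix"),
                       plasticity_parameters("felix"), arch = arch,
                       seed = 4)
  set.seed(9)
  # two disjoint groups 8 rows apart: inside the 19x19 kernel window, so
  # both within- and across-pattern between-area edges exist
  g1 <- 0:19; g2 <- 200:219
  d1 <- drive_vector(net, list(X = g1, Y = g1), 5000)
  d2 <- drive_vector(net, list(X = g2, Y = g2), 5000)
  w_before <- network_weights(net)
  for (trial in 1:30) {
    run_steps(net, 16, drive = d1)
    # relaxation long enough for the presynaptic rate estimates
    # (time constant 30) to fall back below theta_pre
    run_steps(net, 80)
    run_steps(net, 16, drive = d2)
    run_steps(net, 80)
  }
  w <- network_weights(net)
  # between-area edges among co-driven cells vs across the two patterns
  in1 <- w$pre %in% g1 & w$post %in% (625 + g1)
  in2 <- w$pre %in% g2 & w$post %in% (625 + g2)
  across <- (w$pre %in% g1 & w$post %in% (625 + g2)) |
    (w$pre %in% g2 & w$post %in% (625 + g1))
  expect_gt(mean(w$weight[in1 | in2]), mean(w$weight[across]))
  expect_gt(mean(w$weight[in1 | in2]), mean(w_before$weight[in1 | in2]))
})
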