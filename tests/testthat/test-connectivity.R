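test_that("kernel probability follows the bivariate Gaussian", {
  k <- kernel_spec(sigma_x = 3.2, k_c = 0.15, half_width = 9)
  # centre equals the amplitude
  expect_equal(kernel_probability(k, 0, 0), 0.15)
  # hand evaluation at offset (3, 0): 0.15 * exp(-9 / (2 * 3.2^2))
  expect_equal(kernel_probability(k, 3, 0), 0.15 * exp(-9 / 20.48),
               tolerance = 1e-12)
  # isotropy and symmetry with q = 0 and zero means
  expect_equal(kernel_probability(k, 2, 1), kernel_probability(k, -2, -1))
  expect_equal(kernel_probability(k, 2, 1), kernel_probability(k, 1, 2))
  # bounded by the amplitude over the whole window
  off <- expand.grid(dx = -9:9, dy = -9:9)
  expect_true(all(kernel_probability(k, off$dx, off$dy) <= 0.15))
  # outside the window the value is zero by convention
  expect_equal(kernel_probability(k, 10, 0), 0)
})

test_that("invalid kernels are rejected", {
  expect_error(kernel_spec(3.2, k_c = 0.15, half_width = 9, q = 1),
               "invalid kernel")
  expect_error(kernel_spec(-1, k_c = 0.15, half_width = 9), "positive")
  expect_error(kernel_spec(3.2, k_c = 1.5, half_width = 9), "k_c")
})

test_that("expected out-degree matches an independent window summation", {
  k_local <- kernel_spec(3.2, k_c = 0.15, half_width = 9)
  # independent brute-force oracle over the 19x19 window
  off <- expand.grid(dx = -9:9, dy = -9:9)
  oracle <- sum(0.15 * exp(-(off$dx^2 + off$dy^2) / (2 * 3.2^2)))
  expect_equal(expected_out_degree(k_local, exclude_self = FALSE), oracle,
               tolerance = 1e-12)
  expect_equal(expected_out_degree(k_local, exclude_self = TRUE),
               oracle - 0.15, tolerance = 1e-12)
  # frozen values bracketing the published 9.5 local connections
  expect_equal(expected_out_degree(k_local, exclude_self = FALSE),
               9.595568, tolerance = 1e-6)
  expect_equal(expected_out_degree(k_local, exclude_self = TRUE),
               9.445568, tolerance = 1e-6)
  # cross-system kernel: analytic 16.633 against the published 16.65
  k_cross <- kernel_spec(9, k_c = 0.065, half_width = 9)
  expect_equal(expected_out_degree(k_cross), 16.63279, tolerance = 1e-5)
  # amplitude zero wires nothing
  expect_equal(expected_out_degree(kernel_spec(3.2, k_c = 0,
                                               half_width = 9)), 0)
})

test_that("toroidal offsets are signed minimal differences", {
  expect_equal(toroidal_offset(0, 24), -1)
  expect_equal(toroidal_offset(24, 0), 1)
  expect_equal(toroidal_offset(0, 12), 12)
  expect_equal(toroidal_offset(0, 13), -12)
  expect_equal(grid_index(24 + 1, 0), 0)  # wrap-around
})

test_that("wiring is deterministic under a fixed seed", {
  spec <- projection_spec("A1", "A1", "EE_local")
  p1 <- wire_projection(spec, seed = 7)
  p2 <- wire_projection(spec, seed = 7)
  expect_identical(p1$edges, p2$edges)
  p3 <- wire_projection(spec, seed = 8)
  expect_false(identical(p1$edges, p3$edges))
})

test_that("empirical out-degree converges to the analytic expectation", {
  spec <- projection_spec("A1", "A1", "EE_local")
  mu <- expected_out_degree(spec$kernel, exclude_self = TRUE)
  degs <- vapply(1:10, function(s)
    mean_out_degree(wire_projection(spec, seed = s)), numeric(1))
  # 361 independent Bernoulli terms per neuron; SE of the grand mean
  se <- sqrt(mu / (625 * 10))  # Poisson-binomial variance bounded by mean
  expect_lt(abs(mean(degs) - mu), 3 * se)
})

test_that("wiring statistics are translation invariant on the torus", {
  spec <- projection_spec("A1", "A1", "EE_local")
  border <- which(grid_coords(0:624)[, "row"] %in% c(0L, 24L)) - 1L
  interior <- which(grid_coords(0:624)[, "row"] %in% 11:13) - 1L
  deg_border <- deg_interior <- numeric(20)
  for (s in 1:20) {
    pr <- wire_projection(spec, seed = 100 + s)
    d <- tabulate(pr$edges$pre + 1L, nbins = 625)
    deg_border[s] <- mean(d[border + 1L])
    deg_interior[s] <- mean(d[interior + 1L])
  }
  mu <- expected_out_degree(spec$kernel, exclude_self = TRUE)
  se <- sqrt(mu / (50 * 20))
  expect_lt(abs(mean(deg_border) - mu), 4 * se)
  expect_lt(abs(mean(deg_interior) - mu), 4 * se)
})

test_that("per-class wiring rules hold", {
  ee <- wire_projection(projection_spec("A1", "A1", "EE_local"), seed = 3)
  expect_true(all(ee$edges$weight >= 0 & ee$edges$weight <= 0.1))
  expect_false(any(ee$edges$pre == ee$edges$post))  # autapses excluded
  ee2 <- wire_projection(projection_spec("A1", "A1", "EE_local",
                                         exclude_self = FALSE), seed = 3)
  expect_true(any(ee2$edges$pre == ee2$edges$post))

  ei <- wire_projection(projection_spec("A1", "A1", "EI"))
  # every excitatory neuron contacts its full 5x5 inhibitory neighbourhood
  expect_equal(unname(tabulate(ei$edges$pre + 1L, 625)), rep(25L, 625))
  # weights equal the Gaussian kernel value at the offset
  kern <- kernel_spec(1.42, k_c = 0.295, half_width = 2)
  rc_pre <- grid_coords(ei$edges$pre)
  rc_post <- grid_coords(ei$edges$post)
  dx <- toroidal_offset(rc_pre[, "row"], rc_post[, "row"])
  dy <- toroidal_offset(rc_pre[, "col"], rc_post[, "col"])
  expect_equal(ei$edges$weight, kernel_probability(kern, dx, dy))

  ie <- wire_projection(projection_spec("A1", "A1", "IE"))
  expect_identical(ie$edges$pre, ie$edges$post)
  expect_true(all(ie$edges$weight == 1))

  egi <- wire_projection(projection_spec("A1", "A1", "E_GI"))
  expect_equal(nrow(egi$edges), 625L)
  expect_true(all(egi$edges$post == 0L))
  gie <- wire_projection(projection_spec("A1", "A1", "GI_E"))
  expect_equal(sort(gie$edges$post), 0:624)

  expect_error(projection_spec("A1", "A1", "nonsense"), "unknown")
})

test_that("edges never exceed the kernel window under toroidal distance", {
  for (cls in c("EE_local", "EE_between")) {
    spec <- projection_spec("A1", "AB", cls)
    pr <- wire_projection(spec, seed = 5)
    rc_pre <- grid_coords(pr$edges$pre)
    rc_post <- grid_coords(pr$edges$post)
    dx <- toroidal_offset(rc_pre[, "row"], rc_post[, "row"])
    dy <- toroidal_offset(rc_pre[, "col"], rc_post[, "col"])
    hw <- spec$kernel$half_width
    expect_true(all(abs(dx) <= hw & abs(dy) <= hw))
  }
})

test_that("the twelve-area architecture has the published composition", {
  arch <- architecture()
  expect_equal(nrow(arch$areas), 12L)
  built <- build_architecture(arch, seed = 2)
  # 12 x 625 = 7500 excitatory units
  expect_equal(length(arch$areas$area) * arch$n_exc, 7500L)
  # one global-inhibitory unit per area
  gi <- Filter(function(p) p$spec$synapse_class == "GI_E",
               built$projections)
  expect_equal(length(gi), 12L)
  # every between-area projection has a mirror with swapped endpoints
  between <- Filter(function(p) p$spec$synapse_class == "EE_between",
                    built$projections)
  keys <- unname(vapply(between, function(p)
    paste(p$spec$source_area, p$spec$target_area), character(1)))
  rev_keys <- unname(vapply(between, function(p)
    paste(p$spec$target_area, p$spec$source_area), character(1)))
  expect_setequal(keys, rev_keys)
  # within-system links use k_c 0.13, cross-system 0.065
  kc <- vapply(between, function(p) p$spec$kernel$k_c, numeric(1))
  expect_setequal(unique(kc), c(0.13, 0.065))
  expect_error(architecture(links = data.frame(a = "A1", b = "XX",
                                               class = "within_system")),
               "unknown areas")
})
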