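test_that("membrane conductance and area follow the frustum geometry", {
  p <- passive_params(RM = 1, CM = 0.01, RA = 1)
  # single cylinder L=100 um, d=2 um hanging off the soma
  m <- morphology(data.frame(id = 1:2, type = c(1, 3),
                             x = c(0, 100), y = 0, z = 0,
                             radius = c(5, 1), parent = c(-1, 1)))
  cm <- build_compartments(m, p)
  gm_cyl <- pi * 2e-6 * 100e-6 / 1          # pi d L / RM
  dend_comp <- unname(cm$node2comp[["2"]])
  expect_equal(cm$gm[dend_comp], gm_cyl, tolerance = 1e-12)
  # total membrane area equals the frustum sum on a tapered tree
  mt <- generate_morphology(synth_spec(seed = 121, max_depth = 8))
  cmt <- build_compartments(mt, p)
  nd <- normalize_soma(mt, "three_point")$nodes
  pid <- match(nd$parent, nd$id)
  manual <- 0
  for (i in which(nd$type != 1)) {
    L <- sqrt(sum((nd[i, c("x", "y", "z")] - nd[pid[i], c("x", "y", "z")])^2))
    r2 <- nd$radius[i]
    r1 <- if (nd$type[pid[i]] == 1) r2 else nd$radius[pid[i]]
    manual <- manual + pi * (r1 + r2) * sqrt((r2 - r1)^2 + L^2)
  }
  manual <- manual * 1e-12 + pi * (2 * nd$radius[1] * 1e-6)^2
  expect_equal(sum(cmt$area), manual, tolerance = 1e-3)
})

test_that("axial resistance is additive and matches frustum quadrature", {
  p <- passive_params(RA = 1.98)
  base <- data.frame(id = 1, type = 1, x = 0, y = 0, z = 0, radius = 5,
                     parent = -1)
  # one full cylinder vs two half-cylinders: same end-to-end resistance
  full <- build_compartments(morphology(rbind(base,
    data.frame(id = 2, type = 3, x = 100, y = 0, z = 0, radius = 1,
               parent = 1))), p)
  halves <- build_compartments(morphology(rbind(base,
    data.frame(id = 2:3, type = 3, x = c(50, 100), y = 0, z = 0,
               radius = 1, parent = c(1, 2)))), p)
  r_full <- 1 / full$ga[unname(full$node2comp[["2"]])]
  r_half <- sum(1 / halves$ga[unname(halves$node2comp[c("2", "3")])])
  expect_equal(r_half, r_full, tolerance = 1e-12)
  expect_equal(sum(full$area), sum(halves$area), tolerance = 1e-12)
  # tapered frustum r 1->3 um over 100 um vs 1000-slice integral
  tap <- build_compartments(morphology(rbind(base,
    data.frame(id = 2, type = 3, x = 100, y = 0, z = 0, radius = 3,
               parent = 1),
    data.frame(id = 3, type = 3, x = 200, y = 0, z = 0, radius = 1,
               parent = 2))), p)
  r_model <- 1 / tap$ga[unname(tap$node2comp[["3"]])]
  xs <- seq(0, 100e-6, length.out = 1001)
  rr <- seq(3e-6, 1e-6, length.out = 1001)
  rmid <- (rr[-1] + rr[-1001]) / 2
  r_quad <- sum(1.98 * diff(xs) / (pi * rmid^2))
  expect_lt(abs(r_model - r_quad) / r_quad, 1e-4)
})

test_that("an isopotential compartment relaxes with tau = RM*CM", {
  soma <- morphology(data.frame(id = 1, type = 1, x = 0, y = 0, z = 0,
                                radius = 10, parent = -1))
  p <- passive_params()                     # RM 1.6, CM 0.0186
  cm <- build_compartments(soma, p)
  tr <- simulate_passive(cm, current_step(1.5, 1, onset = 1), dt = 0.01,
                         t_end = 250)
  fit <- fit_double_exponential(tr$time, tr$v[, 1], window = c(2.2, 250))
  expect_lt(abs(fit$tau1 - 29.76) / 29.76, 0.001)
  expect_true(fit$degenerate)               # a sphere has one exponential
  # steady state: dV = I RM / area, exactly
  dv <- steady_state_voltage(cm, 0.03)[1] - p$Em
  area <- 4 * pi * (10e-6)^2
  expect_equal(dv, 0.03e-9 * 1.6 / area * 1e3, tolerance = 1e-9)
})

test_that("zero stimulus leaves the membrane exactly at rest", {
  m <- generate_morphology(synth_spec(seed = 122, max_depth = 6))
  cm <- build_compartments(m, passive_params())
  tr <- simulate_passive(cm, current_step(0, 10, onset = 1), dt = 0.1,
                         t_end = 50)
  expect_equal(max(abs(tr$v - (-65))), 0, tolerance = 1e-10)
  expect_equal(steady_state_deflection(tr$time, tr$v[, 1], c(0, 5),
                                       c(40, 50)), 0, tolerance = 1e-10)
})

test_that("a sealed-end cable reproduces the cosh attenuation profile", {
  n <- 400; L <- 500; d <- 2
  cab <- morphology(data.frame(
    id = 1:(n + 1), type = c(1, rep(3, n)),
    x = seq(0, L, length.out = n + 1), y = 0, z = 0,
    radius = d / 2, parent = c(-1, 1:n)))
  p <- passive_params()
  cm <- build_compartments(cab, p)
  v <- steady_state_voltage(cm, 0.1)
  lambda <- sqrt(p$RM * (d * 1e-6) / (4 * p$RA)) * 1e6   # um
  xs <- seq(0, L, length.out = n + 1)[-1]
  prof <- (v[unname(cm$node2comp[as.character(2:(n + 1))])] - p$Em)
  prof <- prof / prof[1]
  analytic <- cosh((L - xs) / lambda) / cosh((L - xs[1]) / lambda)
  expect_lt(max(abs(prof - analytic) / analytic), 0.005)
  # the time-stepped plateau converges to the same steady state
  tr <- simulate_passive(cm, current_step(0.1, 800, onset = 5), dt = 0.2,
                         t_end = 600)
  expect_equal(tr$v[nrow(tr$v), 1], v[1], tolerance = 1e-3)
})

test_that("double-exponential fits recover known time constants", {
  t <- seq(0, 120, by = 0.01)
  v <- -65 + 5 * exp(-t / 21.0) + 3 * exp(-t / 1.57)
  f <- fit_double_exponential(t, v)
  expect_lt(abs(f$tau1 - 21.0) / 21.0, 0.001)
  expect_lt(abs(f$tau2 - 1.57) / 1.57, 0.001)
  expect_gte(f$tau1, f$tau2)
  # with seeded gaussian noise (10 uV): slow constant within 2%
  set.seed(123)
  vn <- v + rnorm(length(v), 0, 0.01)
  fn <- fit_double_exponential(t, vn)
  expect_lt(abs(fn$tau1 - 21.0) / 21.0, 0.02)
  # single-exponential input is flagged degenerate, not an error
  fs <- fit_double_exponential(t, -65 + 4 * exp(-t / 10))
  expect_true(fs$degenerate)
  expect_lt(abs(fs$tau1 - 10) / 10, 0.01)
  # a flat noise window holds no transient and is rejected
  set.seed(127)
  expect_error(fit_double_exponential(t, -65 + rnorm(length(t), 0, 0.05)),
               "not a decaying")
})

test_that("synaptic responses attenuate toward the soma and scale linearly", {
  m <- generate_morphology(synth_spec(seed = 124, max_depth = 8))
  cm <- build_compartments(m, passive_params())
  tip <- m$nodes$id[nrow(m$nodes)]
  zero <- synaptic_response(cm, synaptic_input(gmax = 0, site = tip),
                            t_end = 30)
  expect_equal(zero$dendrite, 0, tolerance = 1e-10)
  r10 <- synaptic_response(cm, synaptic_input(gmax = 10, site = tip),
                           t_end = 40)
  expect_gt(r10$dendrite, r10$soma)         # passive attenuation
  expect_gt(r10$soma, 0)
  # small-conductance linear regime: doubling 2 -> 4 pS doubles the peak
  r2 <- synaptic_response(cm, synaptic_input(gmax = 2, site = tip),
                          t_end = 40)
  r4 <- synaptic_response(cm, synaptic_input(gmax = 4, site = tip),
                          t_end = 40)
  expect_lt(abs(r4$dendrite / r2$dendrite - 2), 0.01)
})

test_that("normalized differences behave as dimensionless ratios", {
  expect_equal(unname(normalized_difference(c(tau1 = 2.0, deltaV = 1.0),
                                            c(tau1 = 2.0, deltaV = 1.0))),
               c(0, 0))
  expect_equal(unname(normalized_difference(c(deltaV = 1.16),
                                            c(deltaV = 1.00))), 0.16)
  expect_error(normalized_difference(c(a = 1), c(a = 0)), "zero")
})

test_that("a self-predicted noise-free morphology is electrically identical", {
  set <- striatal_set()
  spec <- synth_spec(n_initial = 3, branch_prob = 0.2,
                     segment_length = c(12, 2), max_depth = 7,
                     soma_diameter = c(12, 0), diameter_rule = set,
                     noise_sd = 0, seed = 125)
  m <- generate_morphology(spec)
  pm <- predict_diameters(m, set)
  orig <- response_metrics(m, dt = 0.05)
  pred <- response_metrics(pm, dt = 0.05)
  ratios <- normalized_difference(pred, orig)
  expect_lt(max(ratios), 1e-5)
})

test_that("halving the step changes tau and deltaV by less than 0.1%", {
  m <- generate_morphology(synth_spec(seed = 126, max_depth = 6,
                                      n_initial = 2))
  coarse <- response_metrics(m, dt = 0.05)
  fine <- response_metrics(m, dt = 0.025)
  expect_lt(abs(fine$tau1 - coarse$tau1) / fine$tau1, 0.001)
  expect_lt(abs(fine$deltaV - coarse$deltaV) / abs(fine$deltaV), 0.001)
})
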