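test_that("isotropic kernel follows the Gaussian distance profile", {
  expect_equal(isotropic_probability(0, 0.2, p_max = 0.3), 0.3)
  expect_equal(isotropic_probability(0.2, 0.2, p_max = 1), exp(-0.5))
  # sigma far beyond the torus diameter: flat, completely random limit
  set.seed(3)
  d <- runif(500, 0, sqrt(2) / 2)
  p <- isotropic_probability(d, sigma_x = 10, p_max = 0.01)
  expect_lt((max(p) - min(p)) / mean(p), 0.003)
})

test_that("latency is torus distance over source speed", {
  expect_equal(latency(0.1, 0.5, 0.5, 0, 0.3, 0.5), 0.4)
  expect_equal(latency(0.2, 0.2, 1, 1, 0.2, 0.2), 0)
  set.seed(4)
  for (k in 1:50) {
    src <- runif(2); tgt <- runif(2); vel <- rnorm(2)
    sp <- sqrt(sum(vel^2))
    tau <- latency(src[1], src[2], vel[1], vel[2], tgt[1], tgt[2])
    expect_equal(tau * sp,
                 torus_distance(src[1], src[2], tgt[1], tgt[2]),
                 tolerance = 1e-12)
  }
  expect_error(latency(0, 0, 0, 0, 1, 1), "zero source speed")
})

test_that("predicted position advances the source along its motion", {
  p0 <- predicted_position(0.3, 0.8, 1.2, -0.4, 0)
  expect_equal(c(p0$x, p0$y), c(0.3, 0.8))
  p1 <- predicted_position(0.9, 0.5, 0.5, 0, 0.4)
  expect_equal(c(p1$x, p1$y), c(0.1, 0.5))
  # when the source's motion points at the target, the scan over tau is
  # minimized at the trajectory latency
  src <- c(0.2, 0.5); tgt <- c(0.6, 0.5); vel <- c(0.8, 0)
  tau_star <- latency(src[1], src[2], vel[1], vel[2], tgt[1], tgt[2])
  taus <- seq(0, 1.2, by = 0.01)
  d <- sapply(taus, function(tau) {
    p <- predicted_position(src[1], src[2], vel[1], vel[2], tau)
    torus_distance(p$x, p$y, tgt[1], tgt[2])
  })
  expect_equal(taus[which.min(d)], tau_star, tolerance = 0.011)
})

test_that("motion-based kernel peaks on the predicted trajectory", {
  # target at the predicted position with identical velocity
  p <- motion_based_probability(0.2, 0.5, 0.5, 0, 0.4, 0.5, 0.5, 0,
                                sigma_x = 0.1, sigma_v = 0.1)
  expect_equal(p, 1)
  # identical velocity, target displaced sigma_x off the predicted point:
  # a target 0.1 behind a rightward mover has its predicted point 0.1 ahead,
  # so the spatial offset is exactly 0.2 = sigma_x
  p2 <- motion_based_probability(0.5, 0.5, 1, 0, 0.4, 0.5, 1, 0,
                                 sigma_x = 0.2, sigma_v = 0.1)
  expect_equal(p2, exp(-0.5), tolerance = 1e-12)
  # the anisotropy: a rightward mover prefers the neuron ahead of it
  ahead <- motion_based_probability(0.5, 0.5, 1, 0, 0.7, 0.5, 1, 0,
                                    sigma_x = 0.1, sigma_v = 0.1)
  behind <- motion_based_probability(0.5, 0.5, 1, 0, 0.3, 0.5, 1, 0,
                                     sigma_x = 0.1, sigma_v = 0.1)
  expect_gt(ahead, behind)
})

test_that("direction-based kernel depends only on angles", {
  s <- 0.5
  # aligned displacement, identical direction: global maximum
  p <- direction_based_probability(0.5, 0.5, 1, 0, 0.55, 0.5, 1, 0,
                                   sigma_x = s, sigma_v = s)
  expect_equal(p, exp(1 / s^2) * exp(1 / s^2))
  # target directly behind: spatial term at its minimum
  pb <- direction_based_probability(0.5, 0.5, 1, 0, 0.45, 0.5, 1, 0,
                                    sigma_x = s, sigma_v = s)
  expect_equal(pb, exp(-1 / s^2) * exp(1 / s^2))
  # doubling both speeds leaves the probability unchanged
  set.seed(5)
  for (k in 1:20) {
    src <- runif(2); tgt <- runif(2); v1 <- rnorm(2); v2 <- rnorm(2)
    a <- direction_based_probability(src[1], src[2], v1[1], v1[2],
                                     tgt[1], tgt[2], v2[1], v2[2],
                                     s, s, r_conn = 1, tau_max = 1e6)
    b <- direction_based_probability(src[1], src[2], 2 * v1[1], 2 * v1[2],
                                     tgt[1], tgt[2], 2 * v2[1], 2 * v2[2],
                                     s, s, r_conn = 1, tau_max = 1e6)
    expect_equal(a, b, tolerance = 1e-12)
  }
  # exclusion: far pair with slow source exceeds both radius and latency cap
  pfar <- direction_based_probability(0.1, 0.1, 0.2, 0, 0.45, 0.1,
                                      0.2, 0, s, s,
                                      r_conn = 0.1, tau_max = 100)
  expect_equal(pfar, 0)
  # the same far pair with a fast source is admitted via the latency branch
  pfast <- direction_based_probability(0.1, 0.1, 4, 0, 0.45, 0.1, 4, 0,
                                       s, s, r_conn = 0.1, tau_max = 100)
  expect_gt(pfast, 0)
  # coincident positions are excluded
  expect_equal(direction_based_probability(0.2, 0.2, 1, 0, 0.2, 0.2, 1, 0,
                                           s, s), 0)
})

test_that("top-k selection matches a full-sort oracle with index tie-break", {
  expect_length(select_incoming(runif(13000), 0.005), 65)
  # ties broken by ascending source index
  expect_equal(select_incoming(rep(0.5, 200), 0.05), 1:10)
  set.seed(6)
  for (k in 1:20) {
    p <- runif(400)
    sel <- select_incoming(p, 0.03)
    oracle <- sort(order(-p)[1:12])
    expect_equal(sel, oracle)
  }
  expect_warning(sel <- select_incoming(c(0.2, 0.1, rep(0, 98)), 0.05),
                 "non-zero")
  expect_equal(sel, 1:2)
})

test_that("weight normalization is proportional and exact", {
  expect_equal(normalize_weights(c(0.2, 0.2), 0.2), c(0.1, 0.1))
  expect_equal(normalize_weights(c(0.3, 0.1), 0.2), c(0.15, 0.05))
  set.seed(9)
  for (k in 1:50) {
    p <- runif(sample(2:100, 1))
    w <- normalize_weights(p, 0.25)
    expect_lt(abs(sum(w) - 0.25), 1e-12)
  }
  expect_error(normalize_weights(c(0, 0), 0.2), "zero")
})

test_that("isotropic weight draws have the documented moments", {
  set.seed(10)
  w <- draw_isotropic_weights(1e5, w_sum = 0.3, n_expected = 65)
  mu <- 0.3 / 65
  expect_lt(abs(mean(w) - mu), 3 * 0.2 * mu / sqrt(1e5))
  expect_equal(sd(w) / mean(w), 0.2, tolerance = 0.02)
  expect_true(all(w >= 0))
})

test_that("delay assignment honours distributions, latencies and caps", {
  params <- connectivity_params(scheme = "motion_based")
  # trajectory latency in ms, before cap
  expect_equal(assign_delays("motion_based", params, tau_s = 0.2 / 0.5), 400)
  expect_equal(assign_delays("motion_based", params, tau_s = 1.0),
               params$tau_max_mb)
  expect_equal(assign_delays("direction_based", params, tau_s = 0.5),
               params$tau_max_db)
  set.seed(12)
  d <- assign_delays("isotropic", params, n = 1e5)
  expect_lt(abs(mean(d) - 3), 3 * 1 / sqrt(1e5) + 0.01)
  expect_equal(sd(d), 1, tolerance = 0.02)
  expect_true(all(d >= params$dt))
})

test_that("built networks satisfy the structural invariants", {
  set.seed(21)
  spec_e <- grid_spec(n_cells = 16, n_speeds = 4, n_angles = 8)
  spec_i <- grid_spec(n_cells = 4, n_speeds = 2, n_angles = 4)
  tuning_e <- assemble_population(spec_e, 600)
  set.seed(22)
  tuning_i <- assemble_population(spec_i, 120)

  params_mb <- connectivity_params(scheme = "motion_based")
  net_mb <- build_network(tuning_e, tuning_i, params_mb)
  # anisotropic EE: exact in-degree round(k_frac * N) for every target
  indeg <- table(factor(net_mb$EE$target_id, levels = 1:600))
  expect_true(all(indeg == round(0.005 * 600)))
  # per-target weight sums equal w_EE to 1e-9
  wsums <- tapply(net_mb$EE$weight, net_mb$EE$target_id, sum)
  expect_true(all(abs(wsums - params_mb$w[["EE"]]) < 1e-9))
  for (tab in net_mb) {
    expect_true(all(tab$weight >= 0))
    expect_true(all(tab$delay >= params_mb$dt))
  }
  expect_false(any(net_mb$EE$source_id == net_mb$EE$target_id))
  expect_false(any(net_mb$II$source_id == net_mb$II$target_id))

  # isotropic EE: empirical density close to p_EE
  set.seed(23)
  net_iso <- build_network(tuning_e, tuning_i,
                           connectivity_params(scheme = "isotropic"))
  n_pairs <- 600 * 600
  phat <- nrow(net_iso$EE) / n_pairs
  expect_lt(abs(phat - 0.005), 4 * sqrt(0.005 * 0.995 / n_pairs))

  # anisotropy statistic: near zero for isotropic, 10x larger for both
  # anisotropic schemes
  a_iso <- anisotropy_statistic(net_iso$EE, tuning_e)
  a_mb <- anisotropy_statistic(net_mb$EE, tuning_e)
  net_db <- build_network(tuning_e, tuning_i,
                          connectivity_params(scheme = "direction_based"))
  a_db <- anisotropy_statistic(net_db$EE, tuning_e)
  expect_lt(abs(a_iso), 0.005)
  expect_gt(a_mb, 10 * abs(a_iso))
  expect_gt(a_db, 10 * abs(a_iso))
})

test_that("anisotropic tables are deterministic; isotropic ones seeded", {
  tuning_e <- lattice_tuning(4, 2, 4, 32)
  params <- connectivity_params(scheme = "motion_based")
  ee1 <- mbpnet:::build_anisotropic_ee(tuning_e, params)
  ee2 <- mbpnet:::build_anisotropic_ee(tuning_e, params)
  expect_identical(ee1, ee2)
  set.seed(31)
  i1 <- mbpnet:::build_isotropic_pathway(tuning_e, tuning_e, "EE", 0.05, 0.3,
                                         0.2, params, same_pop = TRUE)
  set.seed(31)
  i2 <- mbpnet:::build_isotropic_pathway(tuning_e, tuning_e, "EE", 0.05, 0.3,
                                         0.2, params, same_pop = TRUE)
  expect_identical(i1, i2)
})

test_that("wide sigma_v collapses the motion-based rule onto the isotropic
          spatial profile around predicted positions", {
  set.seed(32)
  for (k in 1:50) {
    src <- runif(2); tgt <- runif(2); v1 <- rnorm(2); v2 <- rnorm(2)
    p_wide <- motion_based_probability(src[1], src[2], v1[1], v1[2],
                                       tgt[1], tgt[2], v2[1], v2[2],
                                       sigma_x = 0.15, sigma_v = 1e9)
    tau <- latency(src[1], src[2], v1[1], v1[2], tgt[1], tgt[2])
    pred <- predicted_position(src[1], src[2], v1[1], v1[2], tau)
    p_iso <- isotropic_probability(
      torus_distance(pred$x, pred$y, tgt[1], tgt[2]), sigma_x = 0.15)
    expect_equal(p_wide, p_iso, tolerance = 1e-9)
  }
})
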