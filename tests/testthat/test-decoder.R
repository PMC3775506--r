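spike_rec <- function(id, t) {
  rec <- data.frame(neuron_id = as.integer(id), time = t)
  class(rec) <- c("spike_record", "data.frame")
  rec
}

test_that("spike binning partitions counts and refines consistently", {
  rec <- spike_rec(c(1, 1, 2), c(10, 60, 61))
  counts <- bin_spikes(rec, 2, bin_width = 50, t_max = 100)
  expect_equal(rowSums(counts), c(1, 2))
  expect_equal(counts[2, ], c(1L, 1L))
  empty <- bin_spikes(spike_rec(integer(0), numeric(0)), 3,
                      bin_width = 50, t_max = 100)
  expect_true(all(empty == 0))
  # refinement: halving the width and summing pairs reproduces the counts
  set.seed(61)
  rec2 <- spike_rec(sample(1:20, 500, replace = TRUE), runif(500, 0, 400))
  c1 <- bin_spikes(rec2, 20, bin_width = 50, t_max = 400)
  c2 <- bin_spikes(rec2, 20, bin_width = 25, t_max = 400)
  merged <- c2[seq(1, 15, by = 2), ] + c2[seq(2, 16, by = 2), ]
  expect_equal(unname(merged), unname(c1), ignore_attr = TRUE)
  expect_equal(sum(c1), 500)
})

test_that("confidence weights normalize per bin and flag silent bins", {
  counts <- rbind(c(2, 1, 1), c(0, 0, 0))
  conf <- confidence_weights(counts)
  expect_equal(conf$p[1, ], c(0.5, 0.25, 0.25))
  expect_equal(conf$valid, c(TRUE, FALSE))
  set.seed(62)
  counts2 <- matrix(rpois(200, 2), nrow = 10)
  conf2 <- confidence_weights(counts2)
  expect_true(all(abs(rowSums(conf2$p)[conf2$valid] - 1) < 1e-12))
  # scale invariance: p is unchanged under uniform count scaling
  conf3 <- confidence_weights(counts2 * 7L)
  expect_equal(conf2$p, conf3$p)
})

test_that("position decoding is the circular mean with point-mass identity", {
  tun <- manual_tuning(x = c(0.25, 0.9, 0.1, 0.2, 0.4),
                       y = c(0.25, 0.5, 0.5, 0.5, 0.5),
                       u = rep(0.5, 5), v = rep(0, 5))
  # single active neuron decodes to its own center
  p <- matrix(c(1, 0, 0, 0, 0), nrow = 1)
  d <- decode_position(p, tun)
  expect_equal(d$x_pred, 0.25)
  expect_equal(d$y_pred, 0.25)
  # seam wrap: equal weight at 0.9 and 0.1 decodes to 0.0
  p2 <- matrix(c(0, 0.5, 0.5, 0, 0), nrow = 1)
  expect_equal(decode_position(p2, tun)$x_pred, 0)
  # arithmetic midpoint away from the seam
  p3 <- matrix(c(0, 0, 0, 0.5, 0.5), nrow = 1)
  expect_equal(decode_position(p3, tun)$x_pred, 0.3)
  # the literal mode differs from the centered one by the additive constant
  expect_equal(decode_position(p, tun, mode = "literal")$x_pred, 0.75)
})

test_that("direction decoding matches the printed circular formula", {
  tun <- manual_tuning(x = rep(0.5, 3), y = rep(0.5, 3),
                       u = c(0.5, 0.3, -0.3), v = c(0, 0.2, -0.2))
  p <- matrix(c(1, 0, 0), nrow = 1)
  expect_equal(decode_direction(p, tun)$u_pred, 0.5)
  p2 <- matrix(c(0, 0.5, 0.5), nrow = 1)
  expect_equal(decode_direction(p2, tun)$u_pred, 0, tolerance = 1e-12)
  expect_equal(decode_direction(p2, tun)$v_pred, 0, tolerance = 1e-12)
  # direct evaluation of the arctan2 formula at v_scale = 1
  set.seed(63)
  for (k in 1:20) {
    w <- runif(3); w <- w / sum(w)
    got <- decode_direction(matrix(w, nrow = 1), tun)$u_pred
    want <- atan2(sum(w * sin(pi * tun$u)), sum(w * cos(pi * tun$u))) / pi
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("decoding is equivariant under torus translation", {
  set.seed(64)
  tun <- lattice_tuning(16, 2, 4)
  p <- matrix(runif(3 * nrow(tun)), nrow = 3)
  p <- p / rowSums(p)
  delta <- 0.37
  tun2 <- tun
  tun2$x <- wrap_torus(tun$x + delta)
  d1 <- decode_position(p, tun)
  d2 <- decode_position(p, tun2)
  expect_equal(wrap_torus(d1$x_pred + delta), d2$x_pred, tolerance = 1e-9)
  # concentrated activity: circular mean agrees with the arithmetic mean
  conc <- which(tun$x > 0.3 & tun$x < 0.5)
  pc <- matrix(0, nrow = 1, ncol = nrow(tun))
  pc[1, conc] <- 1 / length(conc)
  d3 <- decode_position(pc, tun)
  expect_equal(d3$x_pred, sum(pc * tun$x), tolerance = 1e-6)
})

test_that("confidence maps conserve weight within time bins", {
  set.seed(65)
  tun <- lattice_tuning(16, 2, 4)
  p <- matrix(runif(4 * nrow(tun)), nrow = 4)
  p <- p / rowSums(p)
  m <- confidence_map(p, tun, "x", n_bins = 10)
  expect_equal(rowSums(m), rep(1, 4), tolerance = 1e-12)
  # point mass lands in a single histogram cell
  pp <- matrix(0, nrow = 1, ncol = nrow(tun)); pp[1, 5] <- 1
  mp <- confidence_map(pp, tun, "x", n_bins = 10)
  expect_equal(sum(mp > 0), 1)
  # uniform weights reproduce the tuning marginal
  pu <- matrix(1 / nrow(tun), nrow = 1, ncol = nrow(tun))
  mu_map <- confidence_map(pu, tun, "u", n_bins = 8)
  breaks <- attr(mu_map, "breaks")
  marginal <- as.vector(table(cut(tun$u, breaks, right = FALSE,
                                  include.lowest = TRUE)))
  expect_equal(as.vector(mu_map[1, ]) * nrow(tun), marginal,
               tolerance = 1e-9)
})

test_that("prediction error uses the torus metric per phase", {
  pr <- stimulus_protocol(x0 = c(0.1, 0.5), v_stim = c(0.5, 0))
  tun <- manual_tuning(x = 0.5, y = 0.5, u = 0.5, v = 0)
  # fabricate decoded output equal to truth
  bins <- seq(25, 975, by = 50)
  truth <- stimulus_position(pr, bins)
  dec <- data.frame(bin_start = bins - 25, bin_mid = bins,
                    x_pred = truth$x, y_pred = truth$y,
                    u_pred = 0.5, v_pred = 0, valid = TRUE)
  err <- prediction_error(dec, pr)
  expect_true(all(err$per_bin$sq_err < 1e-24))
  expect_true(all(err$intervals$mse < 1e-24))
  # constant offset of 0.1 gives MSE 0.01
  dec2 <- dec; dec2$x_pred <- wrap_torus(dec$x_pred + 0.1)
  err2 <- prediction_error(dec2, pr)
  expect_equal(err2$intervals$mse, rep(0.01, 4), tolerance = 1e-9)
  # seam: decoded 0.95 against truth 0.05 is 0.1 away, not 0.9
  dec3 <- dec[1, ]; dec3$x_pred <- 0.95; dec3$y_pred <- 0.5
  pr3 <- stimulus_protocol(x0 = c(0.05, 0.5), v_stim = c(0, 0),
                           phases = data.frame(kind = "stimulus",
                                               t_start = 0, t_end = 50))
  err3 <- prediction_error(dec3, pr3)
  expect_equal(err3$per_bin$sq_err, 0.01, tolerance = 1e-12)
})

test_that("invalid bins propagate as missing estimates", {
  rec <- spike_rec(c(1, 2), c(10, 20)) # spikes only in the first bin
  tun <- manual_tuning(x = c(0.2, 0.4), y = c(0.5, 0.5),
                       u = c(0.5, 0.5), v = c(0, 0))
  dec <- decode_trajectory(rec, tun, bin_width = 50, t_max = 150)
  expect_equal(dec$valid, c(TRUE, FALSE, FALSE))
  expect_equal(dec$x_pred[1], 0.3)
  expect_true(all(is.na(dec$x_pred[2:3])))
})
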