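#' Bin spikes into per-neuron counts
#'
#' Partitions spike times into consecutive bins of `bin_width` ms over
#' `[0, t_max)` and counts spikes per neuron and bin.
#'
#' @param spikes A `spike_record` (columns `neuron_id`, `time`).
#' @param n_neurons Number of neurons (columns of the result).
#' @param bin_width Bin width, ms.
#' @param t_max End of the binned interval, ms.
#' @return Integer matrix, bins x neurons; attribute `bin_edges` gives the
#'   bin boundaries in ms.
#' @export
bin_spikes <- function(spikes, n_neurons, bin_width = 50, t_max = NULL) {
  stopifnot(bin_width > 0)
  t_max <- t_max %||% (if (nrow(spikes)) max(spikes$time) + 1e-9 else bin_width)
  n_bins <- ceiling(t_max / bin_width)
  counts <- matrix(0L, nrow = n_bins, ncol = n_neurons)
  keep <- spikes$time >= 0 & spikes$time < n_bins * bin_width &
    spikes$neuron_id >= 1 & spikes$neuron_id <= n_neurons
  if (any(keep)) {
    b <- floor(spikes$time[keep] / bin_width) + 1
    idx <- cbind(b, spikes$neuron_id[keep])
    tab <- table(factor(b, levels = seq_len(n_bins)),
                 factor(spikes$neuron_id[keep], levels = seq_len(n_neurons)))
    counts <- matrix(as.integer(tab), nrow = n_bins)
  }
  attr(counts, "bin_edges") <- seq(0, n_bins * bin_width, by = bin_width)
  counts
}

#' Per-bin confidence weights
#'
#' Normalizes each bin's spike counts to sum to one:
#' `p_i = n_i / sum_i n_i`. A neuron's weight is its share of the
#' population's activity and is read as its share of the network's belief.
#' Bins without any spike carry no estimate and are flagged invalid.
#'
#' @param counts Matrix of spike counts, bins x neurons (from
#'   [bin_spikes()]).
#' @return List with `p` (matrix, rows of valid bins sum to 1; invalid rows
#'   are all zero) and `valid` (logical per bin).
#' @export
confidence_weights <- function(counts) {
  tot <- rowSums(counts)
  valid <- tot > 0
  p <- counts
  p[valid, ] <- counts[valid, , drop = FALSE] / tot[valid]
  p[!valid, ] <- 0
  list(p = p, valid = valid)
}

# Circular weighted mean of torus coordinates in [0,1).
# mode "centered" returns the true circular mean mod 1 (identity on point
# masses); "literal" adds a full unit instead, as sometimes printed.
circ_mean_unit <- function(p, coord, mode = c("centered", "literal")) {
  mode <- match.arg(mode)
  theta <- 2 * pi * coord - pi
  s <- as.vector(p %*% sin(theta))
  c_ <- as.vector(p %*% cos(theta))
  ang <- atan2(s, c_)
  if (mode == "centered") wrap_torus((ang + pi) / (2 * pi))
  else 1 + ang / (2 * pi)
}

#' Decode position from confidence weights
#'
#' Circular weighted mean of the receptive-field centers: each coordinate is
#' mapped to an angle on the unit circle, the activity-weighted mean vector
#' is computed, and its angle is mapped back to `[0, 1)`. With
#' `mode = "centered"` (default) a single active neuron decodes exactly to
#' its own center; `mode = "literal"` applies an additive full unit instead
#' of the half-unit recentering, for comparison.
#'
#' @param p Weight matrix (bins x neurons) from [confidence_weights()].
#' @param tuning Excitatory `tuning_table`.
#' @param mode `"centered"` or `"literal"`.
#' @return data.frame with `x_pred`, `y_pred`, one row per bin.
#' @export
decode_position <- function(p, tuning, mode = "centered") {
  data.frame(x_pred = circ_mean_unit(p, tuning$x, mode),
             y_pred = circ_mean_unit(p, tuning$y, mode))
}

#' Decode direction from confidence weights
#'
#' Componentwise circular weighted mean of the preferred velocities: each
#' component is mapped to the angle `pi * v / v_scale`, averaged on the unit
#' circle, and mapped back. `v_scale = 1` reproduces the printed readout,
#' which wraps at `|v| = 1`; set `v_scale = v_max` for unambiguous decoding
#' when preferred speeds exceed 1.
#'
#' @inheritParams decode_position
#' @param v_scale Velocity magnitude mapped to the half-circle.
#' @return data.frame with `u_pred`, `v_pred`, one row per bin.
#' @export
decode_direction <- function(p, tuning, v_scale = 1) {
  one <- function(comp) {
    theta <- pi * comp / v_scale
    s <- as.vector(p %*% sin(theta))
    c_ <- as.vector(p %*% cos(theta))
    v_scale * atan2(s, c_) / pi
  }
  data.frame(u_pred = one(tuning$u), v_pred = one(tuning$v))
}

#' Decode the full trajectory from a spike record
#'
#' Convenience wrapper: bins excitatory spikes, forms confidence weights,
#' and decodes position and direction per bin.
#'
#' @param spikes Excitatory `spike_record`.
#' @param tuning Excitatory `tuning_table`.
#' @param bin_width Bin width, ms.
#' @param t_max End of the decoded interval, ms.
#' @param v_scale See [decode_direction()].
#' @param mode See [decode_position()].
#' @return data.frame of class `decoded_trajectory` with `bin_start`,
#'   `bin_mid`, `x_pred`, `y_pred`, `u_pred`, `v_pred`, `valid`; invalid
#'   bins carry `NA` estimates. The confidence weights are attached as
#'   attribute `confidence` (list `p`, `valid`).
#' @export
decode_trajectory <- function(spikes, tuning, bin_width = 50, t_max = NULL,
                              v_scale = 1, mode = "centered") {
  counts <- bin_spikes(spikes, nrow(tuning), bin_width, t_max)
  conf <- confidence_weights(counts)
  pos <- decode_position(conf$p, tuning, mode)
  dir <- decode_direction(conf$p, tuning, v_scale)
  edges <- attr(counts, "bin_edges")
  out <- data.frame(bin_start = edges[-length(edges)],
                    bin_mid = edges[-length(edges)] + bin_width / 2,
                    x_pred = pos$x_pred, y_pred = pos$y_pred,
                    u_pred = dir$u_pred, v_pred = dir$v_pred,
                    valid = conf$valid)
  out$x_pred[!out$valid] <- NA_real_
  out$y_pred[!out$valid] <- NA_real_
  out$u_pred[!out$valid] <- NA_real_
  out$v_pred[!out$valid] <- NA_real_
  attr(out, "confidence") <- conf
  class(out) <- c("decoded_trajectory", "data.frame")
  out
}

#' Confidence map over a tuning dimension
#'
#' For each time bin, sums the confidence weights of neurons falling into
#' each bin of a tuning dimension (`x`, `y`, `u` or `v`), yielding the
#' marginal of the network's belief over that dimension through time.
#'
#' @param p Weight matrix (bins x neurons).
#' @param tuning Excitatory `tuning_table`.
#' @param dimension One of `"x"`, `"y"`, `"u"`, `"v"`.
#' @param n_bins Number of histogram bins along the tuning dimension.
#' @return Matrix, time bins x tuning bins, with attribute `breaks`; rows of
#'   valid time bins sum to the bin's total weight.
#' @export
confidence_map <- function(p, tuning, dimension = c("x", "y", "u", "v"),
                           n_bins = 20) {
  dimension <- match.arg(dimension)
  vals <- tuning[[dimension]]
  rng <- if (dimension %in% c("x", "y")) c(0, 1) else range(vals)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cut_idx <- pmin(pmax(findInterval(vals, breaks, rightmost.closed = TRUE),
                       1L), n_bins)
  agg <- matrix(0, nrow = nrow(p), ncol = n_bins)
  for (b in seq_len(n_bins)) {
    cols <- which(cut_idx == b)
    if (length(cols))
      agg[, b] <- rowSums(p[, cols, drop = FALSE])
  }
  attr(agg, "breaks") <- breaks
  agg
}

#' Prediction error against the true dot trajectory
#'
#' Squared minimal-image (torus) distance between the decoded position and
#' the true dot position at each bin center, plus mean squared error over
#' each protocol phase. Invalid bins are excluded from the averages and
#' counted.
#'
#' @param decoded A `decoded_trajectory`.
#' @param protocol The [stimulus_protocol()] that generated the input.
#' @return List with `per_bin` (data.frame `bin_mid`, `sq_err`, `valid`) and
#'   `intervals` (data.frame `kind`, `t_start`, `t_end`, `mse`, `n_valid`,
#'   `n_invalid`).
#' @export
prediction_error <- function(decoded, protocol) {
  truth <- stimulus_position(protocol, decoded$bin_mid)
  sq_err <- torus_distance(decoded$x_pred, decoded$y_pred,
                           truth$x, truth$y)^2
  per_bin <- data.frame(bin_mid = decoded$bin_mid, sq_err = sq_err,
                        valid = decoded$valid)
  ph <- protocol$phases
  ivs <- lapply(seq_len(nrow(ph)), function(k) {
    inb <- decoded$bin_mid >= ph$t_start[k] & decoded$bin_mid < ph$t_end[k]
    ok <- inb & decoded$valid
    data.frame(kind = ph$kind[k], t_start = ph$t_start[k],
               t_end = ph$t_end[k],
               mse = if (any(ok)) mean(sq_err[ok]) else NA_real_,
               n_valid = sum(ok), n_invalid = sum(inb & !decoded$valid))
  })
  list(per_bin = per_bin, intervals = do.call(rbind, ivs))
}
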