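#' Connectivity parameters for the four synaptic pathways
#'
#' Bundles everything needed to wire the network: the E-to-E wiring `scheme`,
#' the selectivity widths of the wiring kernels, per-pathway overall
#' connection probabilities and incoming-weight targets, the isotropic delay
#' distribution, and the caps applied to trajectory-derived delays.
#'
#' For the Gaussian rules (`isotropic`, `motion_based`) `sigma_x` is in space
#' units and `sigma_v` in space units per second; for the von Mises
#' `direction_based` rule both act approximately as tuning widths in radians.
#'
#' @param scheme One of `"random"`, `"isotropic"`, `"motion_based"`,
#'   `"direction_based"` (applied to the E-to-E pathway; the other pathways
#'   are always isotropic).
#' @param sigma_x,sigma_v Selectivity widths of the E-to-E wiring kernel. If
#'   `NULL`, scheme-specific defaults are used: 0.2 (isotropic), 10 (random,
#'   i.e. effectively flat), 1.0 (motion-based), 0.5 (direction-based).
#' @param sigma_x_iso Spatial width of the isotropic kernel used for the
#'   E-to-I, I-to-E and I-to-I pathways (and for isotropic E-to-E).
#' @param p_ee,p_ei,p_ie,p_ii Overall pairwise connection probabilities.
#' @param w_ee,w_ei,w_ie,w_ii Target sums of incoming weights per neuron, in
#'   microsiemens. If `w_ee` is `NULL` the scheme default is used: 0.3
#'   (isotropic/random), 0.20 (motion-based), 0.25 (direction-based).
#' @param k_frac Fraction of source neurons retained per target by the
#'   anisotropic rules (top-`k_frac` highest probabilities).
#' @param delay_mean,delay_sd Normal delay distribution of isotropic
#'   pathways, ms.
#' @param tau_max_mb Delay cap for motion-based latencies, ms.
#' @param tau_max_db Delay/latency cap for the direction-based rule, ms.
#' @param r_conn Connection radius of the direction-based rule, space units.
#' @param dt Simulation step, ms (delays are floored at one step).
#' @return Object of class `connectivity_params`.
#' @export
connectivity_params <- function(scheme = c("motion_based", "direction_based",
                                           "isotropic", "random"),
                                sigma_x = NULL, sigma_v = NULL,
                                sigma_x_iso = 0.2,
                                p_ee = 0.005, p_ei = 0.02, p_ie = 0.02, p_ii = 0.01,
                                w_ee = NULL, w_ei = 1.8, w_ie = 0.8, w_ii = 0.15,
                                k_frac = 0.005,
                                delay_mean = 3, delay_sd = 1,
                                tau_max_mb = 400, tau_max_db = 100,
                                r_conn = 0.10, dt = 0.1) {
  scheme <- match.arg(scheme)
  defaults <- list(
    random = list(sigma_x = 10, sigma_v = 10, w_ee = 0.3),
    isotropic = list(sigma_x = sigma_x_iso, sigma_v = sigma_x_iso, w_ee = 0.3),
    motion_based = list(sigma_x = 1.0, sigma_v = 1.0, w_ee = 0.20),
    direction_based = list(sigma_x = 0.5, sigma_v = 0.5, w_ee = 0.25))[[scheme]]
  sigma_x <- sigma_x %||% defaults$sigma_x
  sigma_v <- sigma_v %||% defaults$sigma_v
  w_ee <- w_ee %||% defaults$w_ee
  stopifnot(sigma_x > 0, sigma_v > 0, sigma_x_iso > 0,
            all(c(p_ee, p_ei, p_ie, p_ii) > 0), all(c(p_ee, p_ei, p_ie, p_ii) <= 1),
            all(c(w_ee, w_ei, w_ie, w_ii) >= 0),
            k_frac > 0, k_frac <= 1, r_conn > 0,
            tau_max_mb >= dt, tau_max_db >= dt, dt > 0)
  structure(list(scheme = scheme, sigma_x = sigma_x, sigma_v = sigma_v,
                 sigma_x_iso = sigma_x_iso,
                 p = c(EE = p_ee, EI = p_ei, IE = p_ie, II = p_ii),
                 w = c(EE = w_ee, EI = w_ei, IE = w_ie, II = w_ii),
                 k_frac = k_frac,
                 delay_mean = delay_mean, delay_sd = delay_sd,
                 tau_max_mb = tau_max_mb, tau_max_db = tau_max_db,
                 r_conn = r_conn, dt = dt),
            class = "connectivity_params")
}

#' Isotropic (distance-only) connection probability
#'
#' Gaussian fall-off of connection probability with torus distance,
#' `p_max * exp(-d^2 / (2 sigma_x^2))`. With `sigma_x` much larger than the
#' torus diameter the rule degenerates to a flat, completely random profile.
#'
#' @param d Torus distance(s) between source and target, space units.
#' @param sigma_x Spatial width, space units.
#' @param p_max Normalizing factor (probability at zero distance).
#' @return Probabilities, same length as `d`.
#' @export
isotropic_probability <- function(d, sigma_x, p_max = 1) {
  stopifnot(all(d >= 0))
  p_max * exp(-d^2 / (2 * sigma_x^2))
}

#' Trajectory latency between two neurons
#'
#' Travel time implied by the source neuron's preferred speed to cover the
#' torus distance to the target: `tau = d / |v_source|`, in seconds.
#'
#' @param src_x,src_y,src_u,src_v Source tuning rows (vectors recycle).
#' @param tgt_x,tgt_y Target position(s).
#' @return Latencies in seconds.
#' @export
latency <- function(src_x, src_y, src_u, src_v, tgt_x, tgt_y) {
  speed <- sqrt(src_u^2 + src_v^2)
  if (any(speed <= 0)) stop("latency undefined for zero source speed")
  torus_distance(src_x, src_y, tgt_x, tgt_y) / speed
}

#' Position predicted by a source neuron after a latency
#'
#' Advances the source receptive-field center along the source's preferred
#' velocity for `tau` seconds and wraps back onto the torus.
#'
#' @inheritParams latency
#' @param tau Latency in seconds (`>= 0`).
#' @return List with components `x`, `y`.
#' @export
predicted_position <- function(src_x, src_y, src_u, src_v, tau) {
  stopifnot(all(tau >= 0))
  list(x = wrap_torus(src_x + src_u * tau),
       y = wrap_torus(src_y + src_v * tau))
}

#' Motion-based (smooth-trajectory) connection probability
#'
#' A source neuron connects preferentially to targets that lie where its
#' preferred motion predicts the stimulus to be after the inter-neuron
#' latency, and that prefer a similar velocity: the product of a spatial
#' Gaussian on the torus distance between the predicted position and the
#' target's receptive field, and a velocity Gaussian on the (plain Euclidean)
#' difference of preferred velocities. Generally asymmetric in i and j.
#'
#' @inheritParams latency
#' @param tgt_u,tgt_v Target preferred velocity.
#' @param sigma_x,sigma_v Spatial / velocity selectivity widths.
#' @param p_max Normalizing factor.
#' @return Probabilities.
#' @export
motion_based_probability <- function(src_x, src_y, src_u, src_v,
                                     tgt_x, tgt_y, tgt_u, tgt_v,
                                     sigma_x, sigma_v, p_max = 1) {
  tau <- latency(src_x, src_y, src_u, src_v, tgt_x, tgt_y)
  pred <- predicted_position(src_x, src_y, src_u, src_v, tau)
  d_star <- torus_distance(pred$x, pred$y, tgt_x, tgt_y)
  dv2 <- (src_u - tgt_u)^2 + (src_v - tgt_v)^2
  p_max * exp(-d_star^2 / (2 * sigma_x^2)) * exp(-dv2 / (2 * sigma_v^2))
}

#' Direction-based (von Mises) connection probability
#'
#' Speed- and distance-free variant of the anisotropic rule: the product of a
#' von Mises kernel on the angle between the source-to-target displacement
#' and the source's preferred direction, and a von Mises kernel on the angle
#' between the two preferred directions. Pairs are admitted only within a
#' radius `r_conn` of the source or when the trajectory latency is at most
#' `tau_max` (otherwise the probability is 0); coincident positions leave the
#' displacement angle undefined and are likewise excluded.
#'
#' @inheritParams motion_based_probability
#' @param r_conn Maximum connection radius, space units.
#' @param tau_max Maximum admissible latency, ms.
#' @return Probabilities (0 for excluded pairs).
#' @export
direction_based_probability <- function(src_x, src_y, src_u, src_v,
                                        tgt_x, tgt_y, tgt_u, tgt_v,
                                        sigma_x, sigma_v, p_max = 1,
                                        r_conn = 0.10, tau_max = 100) {
  disp <- torus_displacement(src_x, src_y, tgt_x, tgt_y)
  d <- sqrt(disp$dx^2 + disp$dy^2)
  src_speed <- sqrt(src_u^2 + src_v^2)
  tgt_speed <- sqrt(tgt_u^2 + tgt_v^2)
  if (any(src_speed <= 0) || any(tgt_speed <= 0))
    stop("direction-based rule requires non-zero preferred speeds")
  cos_disp <- (disp$dx * src_u + disp$dy * src_v) / (d * src_speed)
  cos_dir <- (src_u * tgt_u + src_v * tgt_v) / (src_speed * tgt_speed)
  p <- p_max * exp(cos_disp / sigma_x^2) * exp(cos_dir / sigma_v^2)
  tau_ms <- 1000 * d / src_speed
  admissible <- (d <= r_conn | tau_ms <= tau_max) & d > 0
  p[!admissible] <- 0
  p
}

#' Select the strongest incoming connections for a target
#'
#' Keeps the `round(k_frac * n_source)` sources with the highest connection
#' probability. Ties are broken by ascending source index so the selection is
#' deterministic; `self` (if given) is excluded before ranking. If fewer
#' sources have non-zero probability than requested, all non-zero ones are
#' taken with a warning.
#'
#' @param p Vector of connection probabilities, one per source neuron.
#' @param k_frac Fraction of sources to keep.
#' @param self Optional index of the target within the source population.
#' @return Integer vector of selected source indices (ascending).
#' @export
select_incoming <- function(p, k_frac, self = NULL) {
  stopifnot(k_frac > 0, k_frac <= 1)
  n <- length(p)
  if (!is.null(self)) p[self] <- -Inf
  k <- max(1L, round_half_up(k_frac * n))
  ord <- order(-p, seq_along(p))
  sel <- ord[seq_len(min(k, n))]
  nz <- p[sel] > 0
  if (!all(nz)) {
    warning("fewer than ", k, " sources with non-zero probability; taking ",
            sum(nz))
    sel <- sel[nz]
  }
  sort(sel)
}

#' Convert selected probabilities to incoming weights
#'
#' Deterministic proportional mapping `w_s = w_sum * p_s / sum(p)`, so the
#' per-target sum of incoming weights equals `w_sum` exactly.
#'
#' @param p Probabilities of the selected sources (at least one `> 0`).
#' @param w_sum Target sum of incoming weights, microsiemens.
#' @return Weights, microsiemens.
#' @export
normalize_weights <- function(p, w_sum) {
  s <- sum(p)
  if (s <= 0) stop("cannot normalize: all selected probabilities are zero")
  w_sum * p / s
}

#' Draw isotropic synaptic weights
#'
#' Weights of isotropically wired synapses are normal with mean
#' `w_sum / n_expected` and coefficient of variation 0.2, truncated at zero;
#' `n_expected` is the expected in-degree of the pathway, so the expected sum
#' of incoming weights equals `w_sum`.
#'
#' @param n Number of weights to draw.
#' @param w_sum Target expected sum of incoming weights, microsiemens.
#' @param n_expected Expected in-degree of the pathway.
#' @return Non-negative weights, microsiemens.
#' @export
draw_isotropic_weights <- function(n, w_sum, n_expected) {
  stopifnot(n >= 0, n_expected > 0)
  mu <- w_sum / n_expected
  pmax(0, stats::rnorm(n, mu, 0.2 * mu))
}

#' Assign synaptic delays for a set of selected pairs
#'
#' Isotropic/random pathways draw delays from `Normal(delay_mean, delay_sd)`
#' ms; the anisotropic rules use the trajectory latency `1000 * d / |v_src|`
#' ms. All delays are clipped to `[dt, tau_max]` for the scheme's cap.
#'
#' @param scheme `"isotropic"`, `"random"`, `"motion_based"` or
#'   `"direction_based"`.
#' @param params A [connectivity_params()].
#' @param n Number of delays (isotropic schemes).
#' @param tau_s Trajectory latencies in seconds (anisotropic schemes).
#' @return Delays in ms, all `>= params$dt`.
#' @export
assign_delays <- function(scheme, params, n = NULL, tau_s = NULL) {
  if (scheme %in% c("isotropic", "random")) {
    stopifnot(!is.null(n))
    d <- stats::rnorm(n, params$delay_mean, params$delay_sd)
    pmin(pmax(d, params$dt), params$tau_max_mb)
  } else {
    stopifnot(!is.null(tau_s))
    cap <- if (scheme == "motion_based") params$tau_max_mb else params$tau_max_db
    pmin(pmax(1000 * tau_s, params$dt), cap)
  }
}

# Solve p_max for an isotropic pathway so the mean pairwise probability
# equals the pathway's overall probability p_kl. Exact (chunked) mean of the
# Gaussian kernel over all source-target pairs.
solve_p_max_iso <- function(src, tgt, sigma_x, p_kl, chunk = 500L) {
  n_t <- nrow(tgt)
  acc <- 0
  for (start in seq(1L, n_t, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_t)
    dx <- outer(src$x, tgt$x[idx], function(a, b) wrap_torus(b - a + 0.5) - 0.5)
    dy <- outer(src$y, tgt$y[idx], function(a, b) wrap_torus(b - a + 0.5) - 0.5)
    acc <- acc + sum(exp(-(dx^2 + dy^2) / (2 * sigma_x^2)))
  }
  p_max <- p_kl * nrow(src) * n_t / acc
  if (p_max > 1) {
    warning("isotropic p_max capped at 1 (sigma_x too narrow for p_kl)")
    p_max <- 1
  }
  p_max
}

# Build one isotropic pathway as a synapse table (Bernoulli draws pair by
# pair, chunked over targets). same_pop excludes self-connections.
build_isotropic_pathway <- function(src, tgt, pathway, p_kl, w_kl, sigma_x,
                                    params, same_pop = FALSE, chunk = 500L) {
  p_max <- solve_p_max_iso(src, tgt, sigma_x, p_kl, chunk = chunk)
  n_s <- nrow(src); n_t <- nrow(tgt)
  src_ids <- integer(0); tgt_ids <- integer(0)
  for (start in seq(1L, n_t, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_t)
    dx <- outer(src$x, tgt$x[idx], function(a, b) wrap_torus(b - a + 0.5) - 0.5)
    dy <- outer(src$y, tgt$y[idx], function(a, b) wrap_torus(b - a + 0.5) - 0.5)
    p <- p_max * exp(-(dx^2 + dy^2) / (2 * sigma_x^2))
    if (same_pop) {
      for (j in seq_along(idx)) if (idx[j] <= n_s) p[idx[j], j] <- 0
    }
    hit <- which(matrix(stats::runif(length(p)), nrow = n_s) < p, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      src_ids <- c(src_ids, hit[, 1L])
      tgt_ids <- c(tgt_ids, idx[hit[, 2L]])
    }
  }
  n_syn <- length(src_ids)
  w <- draw_isotropic_weights(n_syn, w_kl, n_expected = p_kl * n_s)
  d <- assign_delays("isotropic", params, n = n_syn)
  synapse_table(src_ids, tgt_ids, w, d, pathway)
}

# Build the anisotropic EE pathway (motion- or direction-based): per target,
# rank all sources, keep top k_frac, normalize weights, latency delays.
build_anisotropic_ee <- function(tuning, params) {
  n <- nrow(tuning)
  k <- max(1L, round_half_up(params$k_frac * n))
  src_ids <- vector("list", n); w_l <- vector("list", n); d_l <- vector("list", n)
  x <- tuning$x; y <- tuning$y; u <- tuning$u; v <- tuning$v
  mb <- params$scheme == "motion_based"
  for (j in seq_len(n)) {
    p <- if (mb) {
      motion_based_probability(x, y, u, v, x[j], y[j], u[j], v[j],
                               params$sigma_x, params$sigma_v)
    } else {
      direction_based_probability(x, y, u, v, x[j], y[j], u[j], v[j],
                                  params$sigma_x, params$sigma_v,
                                  r_conn = params$r_conn,
                                  tau_max = params$tau_max_db)
    }
    sel <- select_incoming(p, params$k_frac, self = j)
    w_l[[j]] <- normalize_weights(p[sel], params$w[["EE"]])
    tau <- latency(x[sel], y[sel], u[sel], v[sel], x[j], y[j])
    d_l[[j]] <- assign_delays(params$scheme, params, tau_s = tau)
    src_ids[[j]] <- sel
  }
  lens <- lengths(src_ids)
  synapse_table(unlist(src_ids), rep(seq_len(n), lens),
                unlist(w_l), unlist(d_l), "EE")
}

#' Construct a synapse table
#'
#' @param source_id,target_id Neuron indices within the source / target
#'   population.
#' @param weight Synaptic weights, microsiemens (`>= 0`).
#' @param delay Synaptic delays, ms.
#' @param pathway One of `"EE"`, `"EI"`, `"IE"`, `"II"` (source population
#'   first: `"EI"` is excitatory onto inhibitory).
#' @return data.frame of class `synapse_table`.
#' @export
synapse_table <- function(source_id, target_id, weight, delay, pathway) {
  stopifnot(pathway %in% c("EE", "EI", "IE", "II"),
            length(source_id) == length(target_id),
            length(weight) == length(source_id),
            length(delay) == length(source_id))
  tab <- data.frame(source_id = as.integer(source_id),
                    target_id = as.integer(target_id),
                    weight = weight, delay = delay,
                    pathway = rep_len(pathway, length(source_id)))
  class(tab) <- c("synapse_table", "data.frame")
  tab
}

#' Validate a synapse table
#'
#' Checks: no self-connections within a population, non-negative weights,
#' delays at least one integration step.
#'
#' @param tab A `synapse_table`.
#' @param dt Integration step, ms.
#' @return Invisibly `tab`; stops on violation.
#' @export
validate_synapses <- function(tab, dt = 0.1) {
  same_pop <- unique(tab$pathway) %in% c("EE", "II")
  if (any(same_pop) && any(tab$source_id == tab$target_id))
    stop("self-connections are not allowed")
  if (any(tab$weight < 0)) stop("negative synaptic weight")
  if (any(tab$delay < dt - 1e-12)) stop("delay below one integration step")
  invisible(tab)
}

#' Build the four pathway synapse tables
#'
#' Wires E-to-E with the scheme in `params` (isotropic/random draws or
#' anisotropic deterministic top-k selection with proportional weights and
#' latency delays) and the E-to-I, I-to-E, I-to-I pathways isotropically.
#'
#' @param tuning_e,tuning_i Tuning tables of the excitatory and inhibitory
#'   populations.
#' @param params A [connectivity_params()].
#' @return Named list of `synapse_table`s: `EE`, `EI`, `IE`, `II`.
#' @export
build_network <- function(tuning_e, tuning_i, params) {
  validate_tuning(tuning_e); validate_tuning(tuning_i)
  ee <- if (params$scheme %in% c("isotropic", "random")) {
    build_isotropic_pathway(tuning_e, tuning_e, "EE",
                            params$p[["EE"]], params$w[["EE"]],
                            params$sigma_x, params, same_pop = TRUE)
  } else {
    build_anisotropic_ee(tuning_e, params)
  }
  ei <- build_isotropic_pathway(tuning_e, tuning_i, "EI",
                                params$p[["EI"]], params$w[["EI"]],
                                params$sigma_x_iso, params)
  ie <- build_isotropic_pathway(tuning_i, tuning_e, "IE",
                                params$p[["IE"]], params$w[["IE"]],
                                params$sigma_x_iso, params)
  ii <- build_isotropic_pathway(tuning_i, tuning_i, "II",
                                params$p[["II"]], params$w[["II"]],
                                params$sigma_x_iso, params, same_pop = TRUE)
  tables <- list(EE = ee, EI = ei, IE = ie, II = ii)
  lapply(tables, validate_synapses, dt = params$dt)
  tables
}

#' Anisotropy statistic of a synapse table
#'
#' For each source neuron, the mean outgoing torus displacement vector is
#' projected onto the source's normalized preferred direction; the statistic
#' is the population mean of these projections. It is approximately zero for
#' isotropic wiring and positive when outgoing connections align with
#' preferred directions.
#'
#' @param tab A `synapse_table` (within one population).
#' @param tuning Tuning table of that population.
#' @return A single number (space units).
#' @export
anisotropy_statistic <- function(tab, tuning) {
  disp <- torus_displacement(tuning$x[tab$source_id], tuning$y[tab$source_id],
                             tuning$x[tab$target_id], tuning$y[tab$target_id])
  speed <- sqrt(tuning$u^2 + tuning$v^2)
  proj <- (disp$dx * tuning$u[tab$source_id] +
           disp$dy * tuning$v[tab$source_id]) / speed[tab$source_id]
  per_source <- tapply(proj, tab$source_id, mean)
  mean(per_source)
}
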