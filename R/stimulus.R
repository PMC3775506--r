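#' Stimulus protocol: dot trajectory and phase schedule
#'
#' Describes the moving-dot experiment timeline: the dot starts at `x0`,
#' moves with constant velocity `v_stim` (and keeps moving invisibly during
#' blanks), and the input alternates between `stimulus` phases, where each
#' excitatory neuron is driven through its tuning-curve envelope, and `blank`
#' phases, where the envelope vector is randomly permuted across the
#' population at every time step so that all selectivity is destroyed while
#' the summed input rate is preserved in expectation.
#'
#' @param x0 Initial dot position (length-2, torus coordinates).
#' @param v_stim Dot velocity, space units per second (length-2).
#' @param phases data.frame with columns `kind` (`"blank"`/`"stimulus"`),
#'   `t_start`, `t_end` in ms; must be contiguous, non-overlapping and cover
#'   `[0, T]`. The default is blank 0-200, stimulus 200-600, blank 600-800,
#'   stimulus 800-1000 ms.
#' @param f_max Peak envelope rate, Hz.
#' @param dt Envelope/integration time step, ms (`f_max * dt <= 1000` so the
#'   per-step spike probability stays at most 1).
#' @return Object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(x0 = c(0.1, 0.5), v_stim = c(0.5, 0),
                              phases = default_phases(), f_max = 5000,
                              dt = 0.1) {
  stopifnot(length(x0) == 2, length(v_stim) == 2, f_max > 0, dt > 0,
            f_max * dt <= 1000)
  stopifnot(all(phases$kind %in% c("blank", "stimulus")))
  o <- order(phases$t_start)
  phases <- phases[o, , drop = FALSE]
  if (nrow(phases) > 0) {
    if (phases$t_start[1] != 0) stop("phases must start at 0 ms")
    if (any(phases$t_end <= phases$t_start)) stop("empty or inverted phase")
    if (nrow(phases) > 1 &&
        any(abs(phases$t_start[-1] - phases$t_end[-nrow(phases)]) > 1e-9))
      stop("phases must be contiguous and non-overlapping")
  }
  structure(list(x0 = wrap_torus(x0), v_stim = v_stim, phases = phases,
                 f_max = f_max, dt = dt,
                 duration = if (nrow(phases)) max(phases$t_end) else 0),
            class = "stimulus_protocol")
}

#' Default blanking schedule
#'
#' Blank 0-200 ms, stimulus 200-600 ms, blank 600-800 ms, stimulus
#' 800-1000 ms.
#'
#' @return data.frame of phases.
#' @export
default_phases <- function() {
  data.frame(kind = c("blank", "stimulus", "blank", "stimulus"),
             t_start = c(0, 200, 600, 800),
             t_end = c(200, 600, 800, 1000))
}

#' Input synapse parameters
#'
#' @param w_input Weight of the stimulus synapse onto each excitatory neuron,
#'   nanosiemens.
#' @param f_noise Rate of the background Poisson noise per neuron and
#'   polarity, Hz.
#' @param w_noise Weight of the noise synapses, nanosiemens.
#' @return Object of class `input_params`.
#' @export
input_params <- function(w_input = 5, f_noise = 2000, w_noise = 4) {
  stopifnot(w_input >= 0, f_noise >= 0, w_noise >= 0)
  structure(list(w_input = w_input, f_noise = f_noise, w_noise = w_noise),
            class = "input_params")
}

#' Dot position at a given time
#'
#' Rectilinear constant-velocity motion wrapped onto the torus,
#' `x(t) = x0 + v_stim * t`, with `t` in ms and velocity per second.
#'
#' @param protocol A [stimulus_protocol()].
#' @param t Time(s) in ms.
#' @return List with components `x`, `y`.
#' @export
stimulus_position <- function(protocol, t) {
  stopifnot(all(t >= 0))
  list(x = wrap_torus(protocol$x0[1] + protocol$v_stim[1] * t / 1000),
       y = wrap_torus(protocol$x0[2] + protocol$v_stim[2] * t / 1000))
}

#' Tuning-curve envelope of the moving dot
#'
#' Per-neuron firing envelope in `(0, 1]`: a Gaussian in the torus distance
#' between the dot and the receptive-field center (width `beta_x`) times a
#' Gaussian in the plain Euclidean distance between the dot velocity and the
#' preferred velocity (width `beta_v`). Equals 1 only for a neuron matching
#' the dot in both position and velocity.
#'
#' @param tuning A `tuning_table` (its `beta_x`/`beta_v` attributes are the
#'   tuning widths).
#' @param t Time in ms (scalar).
#' @param protocol A [stimulus_protocol()].
#' @return Numeric vector, one envelope value per neuron.
#' @export
stimulus_envelope <- function(tuning, t, protocol) {
  beta_x <- attr(tuning, "beta_x"); beta_v <- attr(tuning, "beta_v")
  stopifnot(beta_x > 0, beta_v > 0)
  pos <- stimulus_position(protocol, t)
  d2 <- torus_distance(tuning$x, tuning$y, pos$x, pos$y)^2
  dv2 <- (protocol$v_stim[1] - tuning$u)^2 + (protocol$v_stim[2] - tuning$v)^2
  exp(-d2 / (2 * beta_x^2) - dv2 / (2 * beta_v^2))
}

#' Randomly permute an envelope vector (blank phase)
#'
#' During blanks the envelope is still computed from the (invisible) dot
#' state and then permuted uniformly across the excitatory population, so
#' the multiset of rates -- and hence the summed input rate -- is preserved
#' exactly while all selectivity is destroyed.
#'
#' @param env Envelope vector.
#' @return A uniform random permutation of `env`.
#' @export
blank_shuffle <- function(env) {
  env[sample.int(length(env))]
}

#' Generate the moving-dot input spike trains
#'
#' Inhomogeneous Poisson encoding by per-step Bernoulli thinning: at each
#' step of width `dt` neuron `i` fires an input spike with probability
#' `L_i(t) * f_max * dt / 1000`, where the envelope `L_i` follows the dot
#' during stimulus phases and is permuted across neurons at every step
#' during blanks. Spikes are delivered to excitatory neurons only.
#'
#' @param tuning Excitatory `tuning_table`.
#' @param protocol A [stimulus_protocol()].
#' @return data.frame of class `spike_record` with columns `neuron_id`,
#'   `time` (ms, multiples of `dt`); attribute `channel = "stimulus"`.
#' @export
generate_input_spiketrains <- function(tuning, protocol) {
  n <- nrow(tuning)
  n_steps <- round(protocol$duration / protocol$dt)
  scale <- protocol$f_max * protocol$dt / 1000
  # velocity tuning term is time-invariant; only the spatial term moves
  beta_x <- attr(tuning, "beta_x"); beta_v <- attr(tuning, "beta_v")
  dv2 <- (protocol$v_stim[1] - tuning$u)^2 + (protocol$v_stim[2] - tuning$v)^2
  vel_term <- exp(-dv2 / (2 * beta_v^2))
  blank_step <- phase_is_blank(protocol)
  ids <- vector("list", n_steps); times <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    t_ms <- (s - 1) * protocol$dt
    pos <- stimulus_position(protocol, t_ms)
    d2 <- torus_distance(tuning$x, tuning$y, pos$x, pos$y)^2
    env <- exp(-d2 / (2 * beta_x^2)) * vel_term
    if (blank_step[s]) env <- blank_shuffle(env)
    fired <- which(stats::runif(n) < env * scale)
    if (length(fired)) {
      ids[[s]] <- fired
      times[[s]] <- rep(t_ms, length(fired))
    }
  }
  rec <- data.frame(neuron_id = as.integer(unlist(ids) %||% integer(0)),
                    time = as.numeric(unlist(times) %||% numeric(0)))
  attr(rec, "channel") <- "stimulus"
  class(rec) <- c("spike_record", "data.frame")
  rec
}

# Logical vector over integration steps: TRUE where the step falls in a
# blank phase. Step s covers [ (s-1)*dt, s*dt ).
phase_is_blank <- function(protocol) {
  n_steps <- round(protocol$duration / protocol$dt)
  t_ms <- (seq_len(n_steps) - 1) * protocol$dt
  blank <- logical(n_steps)
  ph <- protocol$phases
  for (k in seq_len(nrow(ph))) {
    if (ph$kind[k] == "blank")
      blank[t_ms >= ph$t_start[k] - 1e-9 & t_ms < ph$t_end[k] - 1e-9] <- TRUE
  }
  blank
}

#' Generate background noise spike trains
#'
#' Every neuron receives two independent homogeneous Poisson trains at rate
#' `f_noise`, one delivered through an excitatory synapse and one through an
#' inhibitory synapse, both of weight `w_noise`. Event times are continuous;
#' the simulator discretizes them to its integration grid at delivery.
#'
#' @param n_neurons Number of neurons receiving noise.
#' @param duration Duration in ms.
#' @param params An [input_params()].
#' @return List of two `spike_record`s: `exc` and `inh`.
#' @export
generate_noise_spiketrains <- function(n_neurons, duration, params) {
  one <- function(channel) {
    if (duration <= 0 || params$f_noise <= 0 || n_neurons == 0) {
      rec <- data.frame(neuron_id = integer(0), time = numeric(0))
    } else {
      total <- stats::rpois(1, n_neurons * params$f_noise * duration / 1000)
      rec <- data.frame(neuron_id = sample.int(n_neurons, total, replace = TRUE),
                        time = sort(stats::runif(total, 0, duration)))
    }
    attr(rec, "channel") <- channel
    class(rec) <- c("spike_record", "data.frame")
    rec
  }
  list(exc = one("noise_exc"), inh = one("noise_inh"))
}
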