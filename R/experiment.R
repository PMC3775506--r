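#' Full experiment configuration
#'
#' Bundles every stage's parameters for one moving-dot blanking experiment.
#' Stage-level random draws use child seeds derived deterministically from
#' `seed`, so a run is reproducible end to end and schemes compared under
#' the same master seed see literally identical tuning tables, input spikes,
#' noise realizations and initial membrane potentials.
#'
#' @param grid_e,grid_i [grid_spec()]s for the excitatory and inhibitory
#'   lattices.
#' @param n_exc,n_inh Population sizes.
#' @param connectivity A [connectivity_params()].
#' @param protocol A [stimulus_protocol()].
#' @param inputs An [input_params()].
#' @param neurons A [neuron_params()].
#' @param sim A [simulator_config()] (its `duration` should cover the
#'   protocol).
#' @param bin_width Decoder bin width, ms.
#' @param scale_factor Book-keeping field recording the reduction applied by
#'   [make_fixture_config()] (1 = full scale).
#' @param seed Master seed.
#' @param out_dir Optional output directory; when set, [run_experiment()]
#'   persists every intermediate artifact there as CSV plus a JSON manifest.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(grid_e = grid_spec(), grid_i = grid_spec(n_cells = 36),
                              n_exc = 13000, n_inh = 2520,
                              connectivity = connectivity_params(),
                              protocol = stimulus_protocol(),
                              inputs = input_params(),
                              neurons = neuron_params(),
                              sim = simulator_config(),
                              bin_width = 50,
                              scale_factor = 1, seed = 1,
                              out_dir = NULL) {
  stopifnot(n_exc >= 1, n_inh >= 1, scale_factor > 0, scale_factor <= 1)
  structure(list(grid_e = grid_e, grid_i = grid_i,
                 n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
                 connectivity = connectivity, protocol = protocol,
                 inputs = inputs, neurons = neurons, sim = sim,
                 bin_width = bin_width, scale_factor = scale_factor,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

# Nearest grid-cell count to `target` that admits an offset rows x cols
# layout (hex_grid_dims does not reject it).
nearest_factorable <- function(target) {
  target <- max(1L, as.integer(round(target)))
  for (off in 0:target) {
    for (cand in unique(c(target + off, target - off))) {
      if (cand >= 1 && !inherits(try(hex_grid_dims(cand), silent = TRUE),
                                 "try-error"))
        return(cand)
    }
  }
  target
}

#' Scaled-down experiment configuration
#'
#' Produces a configuration whose neuron counts, grid-cell counts and
#' in-degrees are reduced by `scale_factor` while each neuron's operating
#' point is preserved: per-neuron incoming-weight targets `w_kl`, noise
#' rates and input weights are unchanged, and in-degrees scale with the
#' population (overall probabilities `p_kl` are untouched). At
#' `scale_factor = 1` this is the full-size model (13000 excitatory / 2520
#' inhibitory neurons, 100 grid cells with 10 speeds x 10 angles).
#'
#' @param scale_factor Uniform reduction factor in `(0, 1]`.
#' @param scheme E-to-E wiring scheme (see [connectivity_params()]).
#' @param seed Master seed.
#' @param ... Further arguments passed to [experiment_config()].
#' @return An `experiment_config`.
#' @export
make_fixture_config <- function(scale_factor = 1,
                                scheme = "motion_based", seed = 1, ...) {
  stopifnot(scale_factor > 0, scale_factor <= 1)
  experiment_config(
    grid_e = grid_spec(n_cells = nearest_factorable(100 * scale_factor)),
    grid_i = grid_spec(n_cells = nearest_factorable(36 * scale_factor)),
    n_exc = round(13000 * scale_factor),
    n_inh = round(2520 * scale_factor),
    connectivity = connectivity_params(scheme = scheme),
    scale_factor = scale_factor, seed = seed, ...)
}

# Child seeds per pipeline stage, derived from the master seed; kept well
# below 2^31.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 20000000L) * 100L +
    match(stage, c("tuning_e", "tuning_i", "wiring", "input", "noise", "vinit"))
}

# Build both tuning tables under the config's child seeds.
build_tuning <- function(config) {
  set.seed(stage_seed(config$seed, "tuning_e"))
  tuning_e <- assemble_population(config$grid_e, config$n_exc)
  set.seed(stage_seed(config$seed, "tuning_i"))
  tuning_i <- assemble_population(config$grid_i, config$n_inh)
  list(E = tuning_e, I = tuning_i)
}

# Generate the shared input and noise realizations for a config.
build_inputs <- function(config, tuning_e) {
  set.seed(stage_seed(config$seed, "input"))
  input_spikes <- generate_input_spiketrains(tuning_e, config$protocol)
  set.seed(stage_seed(config$seed, "noise"))
  noise <- generate_noise_spiketrains(config$n_exc + config$n_inh,
                                      config$sim$duration, config$inputs)
  list(input = input_spikes, noise = noise)
}

# Simulate one wired network under the config's V-init seed and decode.
run_wired <- function(config, tuning, synapses, drive) {
  set.seed(stage_seed(config$seed, "vinit"))
  sim_out <- simulate_network(tuning$E, tuning$I, synapses,
                              drive$input, drive$noise,
                              config$inputs, config$neurons, config$sim)
  spikes_e <- sim_out$spikes[sim_out$spikes$population == "E", , drop = FALSE]
  decoded <- decode_trajectory(spikes_e, tuning$E, config$bin_width,
                               t_max = config$sim$duration)
  errors <- prediction_error(decoded, config$protocol)
  list(spikes = sim_out$spikes, vtrace = sim_out$vtrace,
       decoded = decoded, errors = errors)
}

#' Run the moving-dot blanking experiment end to end
#'
#' Assembles the tuning tables, wires the network under the configured
#' scheme, generates stimulus and noise spike trains, integrates the
#' network, decodes the trajectory and scores it against the true dot path.
#' All stages are seeded from the master seed. When `config$out_dir` is set,
#' every intermediate table is written there as CSV along with a manifest.
#'
#' @param config An [experiment_config()].
#' @return List of class `experiment_result`: `config`, `tuning`,
#'   `synapses`, `input_spikes`, `noise_spikes`, `spikes`, `decoded`,
#'   `errors`, `rates` (per-phase population rates).
#' @export
run_experiment <- function(config) {
  tuning <- build_tuning(config)
  set.seed(stage_seed(config$seed, "wiring"))
  synapses <- build_network(tuning$E, tuning$I, config$connectivity)
  drive <- build_inputs(config, tuning$E)
  run <- run_wired(config, tuning, synapses, drive)
  res <- structure(
    list(config = config, tuning = tuning, synapses = synapses,
         input_spikes = drive$input, noise_spikes = drive$noise,
         spikes = run$spikes, vtrace = run$vtrace, decoded = run$decoded,
         errors = run$errors,
         rates = phase_rates(run$spikes, config)),
    class = "experiment_result")
  if (!is.null(config$out_dir)) persist_result(res)
  res
}

#' Population firing rates per protocol phase
#'
#' Mean rate over all neurons of each population within each phase of the
#' protocol, in Hz.
#'
#' @param spikes Network `spike_record` (with `population` column).
#' @param config The `experiment_config` of the run.
#' @return data.frame with `kind`, `t_start`, `t_end`, `rate_E`, `rate_I`.
#' @export
phase_rates <- function(spikes, config) {
  ph <- config$protocol$phases
  out <- ph
  out$rate_E <- rep(NA_real_, nrow(ph))
  out$rate_I <- rep(NA_real_, nrow(ph))
  for (k in seq_len(nrow(ph))) {
    dur_s <- (ph$t_end[k] - ph$t_start[k]) / 1000
    inw <- spikes$time >= ph$t_start[k] & spikes$time < ph$t_end[k]
    out$rate_E[k] <- sum(inw & spikes$population == "E") / (config$n_exc * dur_s)
    out$rate_I[k] <- sum(inw & spikes$population == "I") / (config$n_inh * dur_s)
  }
  out
}

persist_result <- function(res) {
  out_dir <- res$config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    write_tuning_csv(res$tuning$E, file.path(out_dir, "tuning_exc.csv"), "E"),
    write_tuning_csv(res$tuning$I, file.path(out_dir, "tuning_inh.csv"), "I"),
    write_synapses_csv(res$synapses, file.path(out_dir, "synapses.csv")),
    write_spikes_csv(res$input_spikes, file.path(out_dir, "input_spikes.csv")),
    write_spikes_csv(res$spikes, file.path(out_dir, "network_spikes.csv")),
    write_decoded_csv(res$decoded, file.path(out_dir, "decoded.csv"),
                      res$errors$per_bin))
  utils::write.csv(res$errors$intervals,
                   file.path(out_dir, "phase_errors.csv"), row.names = FALSE)
  files <- c(files, file.path(out_dir, "phase_errors.csv"))
  write_manifest(out_dir, res$config$seed, files,
                 extra = list(scheme = res$config$connectivity$scheme,
                              scale_factor = res$config$scale_factor))
  invisible(res)
}

#' Compare connectivity schemes on identical input
#'
#' Runs the experiment for several E-to-E wiring schemes while holding
#' everything else fixed: the same tuning tables, the same stimulus and
#' noise spike realizations, the same isotropic E-to-I / I-to-E / I-to-I
#' pathways and the same initial membrane potentials (all derived from the
#' master seed). Only the E-to-E table differs between runs.
#'
#' @param config An [experiment_config()] (its `connectivity$scheme` is
#'   overridden per run).
#' @param schemes Character vector of schemes to compare.
#' @return List of class `scheme_comparison`: `runs` (named list of per-
#'   scheme results with `spikes`, `decoded`, `errors`, `rates`, `synapses`)
#'   and `report` (one row per scheme: blank- and stimulus-phase position
#'   MSE, per-phase mean rates, fraction of valid bins). The blank MSE is
#'   measured over the second blank, after the network has locked on.
#' @export
compare_schemes <- function(config,
                            schemes = c("motion_based", "direction_based",
                                        "isotropic")) {
  tuning <- build_tuning(config)
  drive <- build_inputs(config, tuning$E)
  # isotropic non-EE pathways are shared across schemes
  set.seed(stage_seed(config$seed, "wiring"))
  base_params <- config$connectivity
  shared <- build_network(tuning$E, tuning$I,
                          modify_scheme(base_params, "isotropic"))[c("EI", "IE", "II")]
  runs <- list(); rows <- list()
  for (sc in schemes) {
    params <- modify_scheme(base_params, sc)
    set.seed(stage_seed(config$seed, "wiring") + 7L)
    ee <- if (sc %in% c("isotropic", "random")) {
      build_isotropic_pathway(tuning$E, tuning$E, "EE",
                              params$p[["EE"]], params$w[["EE"]],
                              params$sigma_x, params, same_pop = TRUE)
    } else {
      build_anisotropic_ee(tuning$E, params)
    }
    synapses <- c(list(EE = ee), shared)
    run <- run_wired(config, tuning, synapses, drive)
    run$rates <- phase_rates(run$spikes, config)
    run$synapses <- synapses
    runs[[sc]] <- run
    iv <- run$errors$intervals
    blanks <- which(iv$kind == "blank")
    blank_row <- blanks[length(blanks)]
    stim_row <- which(iv$kind == "stimulus")[1]
    rows[[sc]] <- data.frame(
      scheme = sc,
      mse_blank = iv$mse[blank_row],
      mse_stimulus = iv$mse[stim_row],
      rate_E_blank = run$rates$rate_E[blank_row],
      rate_E_stimulus = run$rates$rate_E[stim_row],
      rate_I_stimulus = run$rates$rate_I[stim_row],
      frac_valid = mean(run$decoded$valid))
  }
  structure(list(config = config, tuning = tuning, drive = drive,
                 runs = runs, report = do.call(rbind, rows)),
            class = "scheme_comparison")
}

modify_scheme <- function(params, scheme) {
  connectivity_params(scheme = scheme,
                      sigma_x_iso = params$sigma_x_iso,
                      p_ee = params$p[["EE"]], p_ei = params$p[["EI"]],
                      p_ie = params$p[["IE"]], p_ii = params$p[["II"]],
                      w_ei = params$w[["EI"]], w_ie = params$w[["IE"]],
                      w_ii = params$w[["II"]],
                      k_frac = params$k_frac,
                      delay_mean = params$delay_mean, delay_sd = params$delay_sd,
                      tau_max_mb = params$tau_max_mb,
                      tau_max_db = params$tau_max_db,
                      r_conn = params$r_conn, dt = params$dt)
}
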