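# Small deterministic fixtures shared across test files.

# Tuning table on an exact lattice (no dispersal); seed-independent.
lattice_tuning <- function(n_cells = 4, n_speeds = 2, n_angles = 4,
                           n_target = NULL, beta_x = 0.15, beta_v = 0.15) {
  spec <- grid_spec(n_cells = n_cells, n_speeds = n_speeds,
                    n_angles = n_angles, jitter_x = 0, jitter_v = 0)
  n_target <- n_target %||% (n_cells * n_speeds * n_angles)
  assemble_population(spec, n_target, beta_x = beta_x, beta_v = beta_v)
}

# Hand-built tuning table from explicit columns.
manual_tuning <- function(x, y, u, v, beta_x = 0.15, beta_v = 0.15,
                          v_max = 4) {
  tab <- data.frame(neuron_id = seq_along(x), x = x, y = y, u = u, v = v)
  attr(tab, "beta_x") <- beta_x
  attr(tab, "beta_v") <- beta_v
  attr(tab, "v_max") <- v_max
  class(tab) <- c("tuning_table", "data.frame")
  tab
}

# Empty synapse tables (all four pathways), for unconnected-network runs.
empty_synapses <- function() {
  lapply(list(EE = "EE", EI = "EI", IE = "IE", II = "II"), function(p)
    synapse_table(integer(0), integer(0), numeric(0), numeric(0), p))
}

# Silent drive: no stimulus, no noise.
no_input <- function() {
  rec <- data.frame(neuron_id = integer(0), time = numeric(0))
  class(rec) <- c("spike_record", "data.frame")
  list(input = rec,
       noise = list(exc = rec, inh = rec))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
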