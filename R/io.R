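#' Write / read a tuning table as CSV
#'
#' Columns: `neuron_id`, `population`, `x`, `y`, `u`, `v`. Tuning widths and
#' the speed cap travel in a `#`-comment header line and are restored on
#' read; the reader re-validates all invariants.
#'
#' @param tab A `tuning_table`.
#' @param path Output file.
#' @param population Population label stored with the rows (`"E"` or `"I"`).
#' @return `path`, invisibly.
#' @export
write_tuning_csv <- function(tab, path, population = "E") {
  hdr <- sprintf("# beta_x=%.17g beta_v=%.17g v_max=%.17g",
                 attr(tab, "beta_x"), attr(tab, "beta_v"), attr(tab, "v_max"))
  writeLines(hdr, path)
  out <- data.frame(neuron_id = tab$neuron_id, population = population,
                    x = tab$x, y = tab$y, u = tab$u, v = tab$v)
  data.table::fwrite(out, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tuning_csv
#' @export
read_tuning_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- as.numeric(sub(".*=", "", strsplit(sub("^# ", "", hdr), " ")[[1]]))
  tab <- as.data.frame(data.table::fread(path, skip = 1))
  tab <- tab[, c("neuron_id", "x", "y", "u", "v")]
  attr(tab, "beta_x") <- meta[1]; attr(tab, "beta_v") <- meta[2]
  attr(tab, "v_max") <- meta[3]
  class(tab) <- c("tuning_table", "data.frame")
  validate_tuning(tab)
}

#' Write / read synapse tables as CSV
#'
#' Columns: `source_id`, `target_id`, `pathway`, `weight_uS`, `delay_ms`.
#' The reader validates the table invariants (no self-connections,
#' non-negative weights, delays of at least one step).
#'
#' @param tables Named list of `synapse_table`s.
#' @param path Output file.
#' @param dt Integration step used for validation on read, ms.
#' @return `path` (write) or the list of tables (read).
#' @export
write_synapses_csv <- function(tables, path) {
  all_tab <- do.call(rbind, lapply(tables, function(s)
    data.frame(source_id = s$source_id, target_id = s$target_id,
               pathway = s$pathway, weight_uS = s$weight, delay_ms = s$delay)))
  data.table::fwrite(all_tab, path)
  invisible(path)
}

#' @rdname write_synapses_csv
#' @export
read_synapses_csv <- function(path, dt = 0.1) {
  raw <- as.data.frame(data.table::fread(path))
  tables <- lapply(split(raw, raw$pathway), function(s)
    synapse_table(s$source_id, s$target_id, s$weight_uS, s$delay_ms,
                  s$pathway[1]))
  lapply(tables, validate_synapses, dt = dt)
}

#' Write / read a spike record as CSV
#'
#' Columns: `neuron_id`, `time_ms`, and `channel` (input records) or
#' `population` (network records).
#'
#' @param rec A `spike_record`.
#' @param path Output file.
#' @return `path` (write) or the record (read).
#' @export
write_spikes_csv <- function(rec, path) {
  out <- data.frame(neuron_id = rec$neuron_id, time_ms = rec$time)
  if (!is.null(rec$population)) out$population <- rec$population
  else out$channel <- attr(rec, "channel") %||% "stimulus"
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) {
  raw <- as.data.frame(data.table::fread(path))
  rec <- data.frame(neuron_id = raw$neuron_id, time = raw$time_ms)
  if (!is.null(raw$population)) rec$population <- raw$population
  if (!is.null(raw$channel)) attr(rec, "channel") <- raw$channel[1]
  class(rec) <- c("spike_record", "data.frame")
  rec
}

#' Write a decoded trajectory as CSV
#'
#' Columns: `bin_start_ms`, `x_pred`, `y_pred`, `u_pred`, `v_pred`, `valid`,
#' and `sq_err` if error scoring is attached.
#'
#' @param decoded A `decoded_trajectory`.
#' @param path Output file.
#' @param errors Optional `per_bin` component of [prediction_error()].
#' @return `path`, invisibly.
#' @export
write_decoded_csv <- function(decoded, path, errors = NULL) {
  out <- data.frame(bin_start_ms = decoded$bin_start,
                    x_pred = decoded$x_pred, y_pred = decoded$y_pred,
                    u_pred = decoded$u_pred, v_pred = decoded$v_pred,
                    valid = decoded$valid)
  if (!is.null(errors)) out$sq_err <- errors$sq_err
  data.table::fwrite(out, path)
  invisible(path)
}

# Manifest of an experiment run: seeds and md5 hashes of written artifacts.
write_manifest <- function(out_dir, seed, files, extra = list()) {
  manifest <- c(list(package = "mbpnet",
                     version = as.character(utils::packageVersion("mbpnet")),
                     seed = seed,
                     files = lapply(files, function(f)
                       list(path = basename(f),
                            md5 = unname(tools::md5sum(f))))),
                extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
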