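# Short-schedule parameter builders and a per-session cache so that
# expensive simulations are run once and shared across test files.

short_cyto <- function(...) {
  cytoneme_params(total_steps = 20001, burn_in_steps = 5000,
                  snapshot_interval = 149, snapshot_count = 100, ...)
}

short_vertex <- function(...) {
  vertex_params(n_cells = 20L, box_size = 9, total_steps = 30000,
                burn_in = 15000, snapshot_count = 10, ...)
}

sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = sim_cache)) assign(key, force(expr), envir = sim_cache)
  get(key, envir = sim_cache)
}
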