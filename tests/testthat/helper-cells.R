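# Shared model cells and cached bias currents. Everything here is cheap to
# build; bias searches are memoised because many tests hold the same cells at
# the same potentials.

std_cell <- tspn_neuron()
fig5_cell <- tspn_neuron("fig5")

.bias_cache <- new.env(parent = emptyenv())
cached_bias <- function(cell, v, key) {
  k <- paste0(key, "@", v)
  if (is.null(.bias_cache[[k]]))
    .bias_cache[[k]] <- find_bias_current(cell, v)
  .bias_cache[[k]]
}

with_imp <- function(cell, g) {
  cell$channels$imp$g_max <- g
  cell
}

# a leak-only RC cell: 1 nS to -55 mV, 100 pF
rc_cell <- function(g_leak = 1, e_leak = -55, c_m = 100) {
  tspn_neuron(g = c(Na = 0, Kd = 0, M = 0, KCa = 0, A = 0, H = 0, CaL = 0,
                    leak = g_leak),
              e_rev = c(leak = e_leak), c_m = c_m)
}

# hand-built trace for feature-extraction unit tests
manual_trace <- function(v, dt = 0.1, window = NULL, step_pa = NULL) {
  structure(list(dt = dt, v = v, i_inj = rep(0, length(v)), g_syn = NULL,
                 meta = list(window = window, step_pa = step_pa,
                             bias_pa = 0)),
            class = "tspn_trace")
}
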