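# Shared fixtures, computed lazily and cached for the whole test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

ctrl300_traj <- function() fixture("ctrl300", {
  integrate_model("5D", condition_params("Ctrl", IApp = 300), t_end = 450)
})

cgs250_traj <- function() fixture("cgs250", {
  integrate_model("5D", condition_params("CGS", IApp = 250), t_end = 450)
})

cgs250_reduced <- function() fixture("cgs250_red", {
  reduce_model(condition_params("CGS", IApp = 250))
})

# Build a synthetic trajectory object from a voltage signal (other state
# columns flat), for detector unit tests.
synthetic_traj <- function(t, V, params = neuron_parameters()) {
  n <- length(t)
  st <- cbind(V = V, h = rep(0.5, n), s = rep(0.1, n),
              r = rep(0.1, n), w = rep(0.1, n))
  structure(list(t = t, state = st, params = params, model = "5D",
                 dt = if (n > 1) t[2] - t[1] else 1),
            class = "neuron_trajectory")
}

events_df <- function(kinds, dt = 10) {
  data.frame(t_peak = seq_along(kinds) * dt,
             V_peak = ifelse(kinds == "LAO", 10, -60),
             kind = kinds, stringsAsFactors = FALSE)
}
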