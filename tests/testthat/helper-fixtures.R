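# shared fixtures: parameter presets and small deterministic grids
informed <- cf_preset("informed")
neutral <- cf_preset("neutral")

# random valid states under a fixed seed, for property-style loops
random_states <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    x <- runif(3, 0, 0.3)
    cf_state(xL = x[1], xA = x[2], xO = x[3],
             cA = runif(1, 0, 2), cL = runif(1, 0, 2))
  })
}

# a hand-built trajectory object (for equilibration-detector tests)
fake_trajectory <- function(states) {
  structure(list(times = seq_len(nrow(states)) - 1, states = states,
                 params = informed, regime = cf_regime("none"),
                 events = numeric(0), t_end = nrow(states) - 1),
            class = "cf_trajectory")
}

state_mat <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("xL", "xA", "xO", "cA", "cL")
  m
}
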