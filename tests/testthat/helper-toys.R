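# Shared fixtures: a <=50-neuron toy hemisphere, the four-neuron AER worked
# example, naive per-synapse oracles, and a cached default hemisphere.

toy_specs <- function() {
  population_specs(counts = c(mf = 10L, gr = 20L, Go = 3L, ba = 5L, Pk = 2L))
}

toy_ratios <- function() {
  r <- connection_ratios()
  r$convergence <- c(2L, 1L, 3L, 5L, 2L, 4L, 1L, 6L, 2L)
  r
}

build_toy <- function(seed = 7L, side = "left") {
  build_hemisphere(seed, toy_specs(), toy_ratios(), side = side)
}

# cache of the full default hemisphere (built once per test run)
.net_cache <- new.env(parent = emptyenv())
default_net <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.net_cache[[key]]))
    .net_cache[[key]] <- build_hemisphere(seed, side = "left")
  .net_cache[[key]]
}

# independent per-synapse oracle for the staged hemisphere update
oracle_step <- function(net, rates, mf, relax = 1) {
  rg <- net$population_ranges
  rates[rg$mf[1]:rg$mf[2]] <- pmin(1, pmax(0, mf))
  post <- rep.int(net$ID, net$N_P)
  for (popn in intersect(c("gr", "Go", "ba", "Pk"), names(rg))) {
    for (id in rg[[popn]][1]:rg[[popn]][2]) {
      s <- 0
      for (k in seq_len(net$N_P[id])) {
        j <- net$ptr[id] + k
        s <- s + net$W[j] * (rates[net$P[j]] - 0.5)
      }
      target <- min(1, max(0, 0.5 + s))
      rates[id] <- rates[id] + relax * (target - rates[id])
    }
  }
  rates
}

# the published four-neuron, six-synapse AER example: neuron 3 is contacted
# by neurons 1 and 2 with weights 0.3 and -0.4
fig4_network <- function() {
  pos <- data.frame(neuron_id = 1:4, population = "mf",
                    x = c(0, 10, 20, 30), y = 0, z = 0,
                    stringsAsFactors = FALSE)
  tab <- data.frame(
    pre = c(4L, 3L, 4L, 1L, 2L, 3L),
    post = c(1L, 2L, 2L, 3L, 3L, 4L),
    class = "toy", nature = "excitatory",
    weight = c(0.5, 0.2, 0.1, 0.3, -0.4, 0.6),
    stringsAsFactors = FALSE)
  list(positions = pos, table = tab)
}

# minimal trial_log for metric tests
fake_log <- function(phi_fun, n_cycles = 4, freq = 0.25, amplitude = pi,
                     dt = 0.01, fall_step = NA_integer_) {
  t <- seq(0, n_cycles / freq - dt, by = dt)
  ref <- reference_trajectory(t, freq, amplitude)
  df <- data.frame(t = t, phi_ref = ref$phi_ref,
                   phi_dot_ref = ref$phi_dot_ref,
                   theta = 0, theta_dot = 0,
                   phi = phi_fun(t, ref$phi_ref), phi_dot = 0,
                   pd_out = 0, bicnn_out = 0, vn_out = 0,
                   cf_left = 0.05, cf_right = 0.05, fallen = 0)
  if (!is.na(fall_step)) df$fallen[fall_step:nrow(df)] <- 1
  structure(list(df = df, fall_step = fall_step,
                 cfg = list(freq = freq, amplitude = amplitude),
                 repeat_idx = 1L),
            class = "trial_log")
}
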