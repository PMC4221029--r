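#' Plasticity constants for the two learning sites
#'
#' `gamma_LTD` and `gamma_LTP` are the parallel fiber-Purkinje learning
#' rates (per 10 ms step); climbing-fiber activity above `cf_spont` drives
#' depression, activity below it drives potentiation. `gamma_PkVn` is the
#' Purkinje-vestibular nucleus learning rate. `w_max` clips the pf-Pk
#' weights (twice the largest possible initial weight, 2/1024 for the
#' default circuit).
#'
#' @param gamma_LTD,gamma_LTP,gamma_PkVn,cf_spont,w_max overrides.
#' @return named list of constants.
#' @export
plasticity_params <- function(gamma_LTD = -4e-6, gamma_LTP = 0.3e-6,
                              gamma_PkVn = 1e-4, cf_spont = 0.05,
                              w_max = 2 / 1024) {
  stopifnot(gamma_LTD < 0, gamma_LTP > 0, cf_spont > 0, cf_spont < 1)
  list(gamma_LTD = gamma_LTD, gamma_LTP = gamma_LTP, gamma_PkVn = gamma_PkVn,
       cf_spont = cf_spont, w_max = w_max)
}

#' Climbing-fiber construction parameters
#'
#' The kinematic error is mapped to a signed rate
#' `raw = error_gain * (w_p * error_pos + w_v * error_vel)`; the left
#' channel prefers forward error (`cf_spont_left + raw`), the right channel
#' backward error (`cf_spont_right - raw`), each clipped to \[0, 1\] so that
#' contradirectional error dips a channel below its spontaneous level.
#'
#' `error_gain` is deliberately small (0.02 rad^-1): the plasticity
#' equilibrium is healthy only while the climbing-fiber rates stay in the
#' informative band around the spontaneous level; mapping the full
#' reference amplitude onto \[0, 1\] saturates cf during early learning and
#' pins the parallel fiber-Purkinje weights at their bounds (see the
#' methods vignette for the closed-loop stability analysis).
#'
#' @param cf_spont_left,cf_spont_right spontaneous rates (default 0.05).
#' @param error_gain rad^-1, scales error into rate units.
#' @param w_p,w_v weights of position (rad) and velocity (rad/s) error.
#' @return named list.
#' @export
cf_params <- function(cf_spont_left = 0.05, cf_spont_right = 0.05,
                      error_gain = 0.02, w_p = 1, w_v = 0.1) {
  list(cf_spont_left = cf_spont_left, cf_spont_right = cf_spont_right,
       error_gain = error_gain, w_p = w_p, w_v = w_v)
}

#' Compute the directional climbing-fiber pair
#'
#' @param error_pos position error (rad), reference minus actual.
#' @param error_vel velocity error (rad/s).
#' @param params from [cf_params()].
#' @return list with `cf_left`, `cf_right` (rates in \[0, 1\]) and the
#'   spontaneous levels.
#' @examples
#' compute_cf(0, 0, cf_params()) # both channels at 0.05
#' @export
compute_cf <- function(error_pos, error_vel, params = cf_params()) {
  raw <- params$error_gain * (params$w_p * error_pos + params$w_v * error_vel)
  list(cf_left = min(1, max(0, params$cf_spont_left + raw)),
       cf_right = min(1, max(0, params$cf_spont_right - raw)),
       cf_spont_left = params$cf_spont_left,
       cf_spont_right = params$cf_spont_right)
}

#' Full-scale ranges of the seven mossy-fiber signals
#'
#' Order: desired wheel angle and velocity, body-tilt error and error
#' velocity, wheel-angle error and error velocity, efference copy. Ranges
#' map each signal's expected full amplitude onto the rate interval
#' \[0, 1\] around the resting rate 0.5.
#'
#' @return named numeric vector of full-scale values.
#' @export
mossy_ranges <- function() {
  # error and efference channels are encoded three times shallower than the
  # reference channels: deep error modulation turns the learned pf-Pk
  # pattern into a parasitic positive feedback around the plant, while the
  # reference channels carry the feedforward basis the circuit learns on
  c(phi_ref = pi, phi_dot_ref = 2 * pi * 0.25 * pi,
    theta_e = 1.5, theta_dot_e = 6,
    phi_e = 3 * pi, phi_dot_e = 3 * 2 * pi * 0.25 * pi,
    eff_copy = 3)
}

#' Encode the seven control signals as 562 mossy-fiber rates
#'
#' Each signal x is mapped affinely to `0.5 + 0.5 * x / fullscale` and
#' clipped to \[0, 1\]; the 7 resulting rates are assigned round-robin to
#' the 562 channels (channel k carries signal ((k - 1) mod 7) + 1), so the
#' assignment truncates mid-block rather than repeating a whole multiple.
#'
#' @param signals named numeric vector of length 7 (names as in
#'   [mossy_ranges()]).
#' @param ranges full-scale values; must be positive.
#' @param n_channels number of mf channels (default 562).
#' @return numeric vector of `n_channels` rates in \[0, 1\].
#' @export
encode_mossy <- function(signals, ranges = mossy_ranges(), n_channels = 562L) {
  stopifnot(length(signals) == 7L, all(ranges > 0))
  r7 <- pmin(1, pmax(0, 0.5 + 0.5 * as.numeric(signals) /
                          as.numeric(ranges[names(ranges)])))
  r7[((seq_len(n_channels) - 1L) %% 7L) + 1L]
}

#' Initialize the mutable state of one hemisphere
#'
#' Holds the per-neuron firing rates (all start at the resting rate 0.5),
#' a private copy of the AER weight vector (the pf-Pk entries of which are
#' plastic), and the Pk-Vn weight vector initialized uniformly at 1/n_Pk so
#' the untrained bi-hemispheric output is mean(right) - mean(left).
#'
#' @param net `aer_network` for this hemisphere.
#' @param side `"left"` or `"right"`.
#' @return object of class `hemisphere_state`.
#' @export
new_hemisphere_state <- function(net, side = net$side) {
  n <- length(net$ID)
  post <- rep.int(net$ID, net$N_P)
  rg <- net$population_ranges
  gr <- rg$gr; pk <- rg$Pk
  pfpk_idx <- which(post >= pk[1] & post <= pk[2] &
                    net$P >= gr[1] & net$P <= gr[2])
  n_pk <- pk[2] - pk[1] + 1L
  pf_indeg <- length(pfpk_idx) / n_pk
  structure(list(rates = rep(0.5, n),
                 W = net$W,
                 W_PkVn = rep(1 / n_pk, n_pk),
                 side = if (is.null(side)) "left" else side,
                 pfpk_idx = pfpk_idx,
                 pfpk_pre = net$P[pfpk_idx],
                 pfpk_post = post[pfpk_idx] - pk[1] + 1L,
                 w_max = 2 / pf_indeg,
                 n_pk = n_pk),
            class = "hemisphere_state")
}

#' One synchronous 10 ms update of a hemisphere
#'
#' Sets the mossy-fiber rates from `mf`, then updates the populations in
#' circuit order (gr, Go, ba, Pk — parallel-fiber rates are the fresh gr
#' rates and Pk rates are produced last). Each neuron's new rate is
#' `clip(0.5 + sum of signed weights times (presynaptic rate - 0.5), 0, 1)`.
#'
#' @param net `aer_network`.
#' @param state `hemisphere_state` (its `W` is used, not the network's).
#' @param mf mossy vector of rates, length of the mf population.
#' @param relax first-order rate-relaxation factor in (0, 1\]: each neuron
#'   moves this fraction of the way to its saturated-affine target per step
#'   (1 = memoryless unit; the closed-loop default 0.3 corresponds to a
#'   membrane time constant of roughly 23 ms at the 10 ms step).
#' @return the updated `hemisphere_state`.
#' @export
step_hemisphere <- function(net, state, mf, relax = 1) {
  rg <- net$population_ranges
  n_mf <- rg$mf[2] - rg$mf[1] + 1L
  if (length(mf) != n_mf) stop("mf vector length ", length(mf),
                               " does not match mf population size ", n_mf)
  if (length(state$rates) != length(net$ID)) stop("state/network shape mismatch")
  rates <- state$rates
  rates[rg$mf[1]:rg$mf[2]] <- pmin(1, pmax(0, mf))
  post <- rep.int(net$ID, net$N_P)
  for (popn in intersect(c("gr", "Go", "ba", "Pk"), names(rg))) {
    lo <- rg[[popn]][1]; hi <- rg[[popn]][2]
    sel <- (net$ptr[lo] + 1L):net$ptr[hi + 1L]
    if (net$ptr[hi + 1L] > net$ptr[lo]) {
      contrib <- state$W[sel] * (rates[net$P[sel]] - 0.5)
      g <- post[sel] - lo + 1L
      s <- numeric(hi - lo + 1L)
      agg <- rowsum(contrib, g)
      s[as.integer(rownames(agg))] <- agg
    } else s <- numeric(hi - lo + 1L)
    target <- pmin(1, pmax(0, 0.5 + s))
    rates[lo:hi] <- rates[lo:hi] + relax * (target - rates[lo:hi])
  }
  state$rates <- rates
  state
}

#' Combine the two hemispheres into the cerebellar output
#'
#' The left hemisphere's contribution is inverted and added to the right
#' one: `sum(W_PkVn_right * right_Pk) - sum(W_PkVn_left * left_Pk)`,
#' clipped to \[-1, 1\]. With the default uniform Pk-Vn weights this is
#' mean(right) - mean(left).
#'
#' @param left_Pk,right_Pk Purkinje rate vectors in \[0, 1\].
#' @param W_PkVn_left,W_PkVn_right Pk-Vn weight vectors.
#' @return scalar in \[-1, 1\].
#' @export
bicnn_output <- function(left_Pk, right_Pk, W_PkVn_left, W_PkVn_right) {
  min(1, max(-1, sum(W_PkVn_right * right_Pk) - sum(W_PkVn_left * left_Pk)))
}

#' Parallel fiber-Purkinje plasticity (LTD/LTP)
#'
#' Per synapse: depression `gamma_LTD * cf * pf_i` when the hemisphere's
#' climbing-fiber rate exceeds its spontaneous level, potentiation
#' `gamma_LTP * pf_i` when it is below it, and no change at exact equality.
#' Weights are clipped to \[0, w_max\].
#'
#' @param W_pfPk numeric vector of pf-Pk weights.
#' @param pf_rates parallel-fiber (granule) rates aligned per synapse.
#' @param cf this hemisphere's climbing-fiber rate in \[0, 1\].
#' @param params from [plasticity_params()].
#' @param cf_spont spontaneous level for this hemisphere (defaults to
#'   `params$cf_spont`).
#' @return updated weight vector.
#' @export
update_pf_pk <- function(W_pfPk, pf_rates, cf, params = plasticity_params(),
                         cf_spont = params$cf_spont) {
  dW <- if (cf > cf_spont) params$gamma_LTD * cf * pf_rates
        else if (cf < cf_spont) params$gamma_LTP * pf_rates
        else 0
  pmin(params$w_max, pmax(0, W_pfPk + dW))
}

#' Purkinje-vestibular nucleus plasticity
#'
#' Per Purkinje cell j: `dW = gamma_PkVn * vn * (Pk_j - 0.5)` — weights
#' potentiate when the Vn activity and the centered Pk rate share a sign and
#' depress otherwise. Clipped to \[0, 2/n_Pk\].
#'
#' @param W_PkVn Pk-Vn weight vector.
#' @param Pk_rates Purkinje rates in \[0, 1\].
#' @param vn vestibular-nucleus activity (signed, \[-1, 1\]).
#' @param params from [plasticity_params()].
#' @return updated weight vector.
#' @export
update_pk_vn <- function(W_PkVn, Pk_rates, vn, params = plasticity_params()) {
  n_pk <- length(W_PkVn)
  pmin(2 / n_pk, pmax(0, W_PkVn + params$gamma_PkVn * vn * (Pk_rates - 0.5)))
}

#' Rates of one population, by label
#'
#' @param net `aer_network`.
#' @param state `hemisphere_state`.
#' @param label population label (`"mf"`, `"gr"`, `"Go"`, `"ba"`, `"Pk"`).
#' @return numeric vector of rates.
#' @export
population_rates <- function(net, state, label) {
  r <- net$population_ranges[[label]]
  state$rates[r[1]:r[2]]
}
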