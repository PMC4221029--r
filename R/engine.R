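# Internal glue between the R-level objects and the C++ closed-loop engine.

# 0-based engine view of one hemisphere
hemi_engine_args <- function(net, state, cf_spont) {
  rg <- net$population_ranges
  pops <- intersect(c("gr", "Go", "ba", "Pk"), names(rg))
  list(ptr = net$ptr,
       P = net$P - 1L,
       W = state$W,
       pfpk_idx = state$pfpk_idx - 1L,
       W_PkVn = state$W_PkVn,
       mf_lo = rg$mf[1] - 1L, mf_hi = rg$mf[2] - 1L,
       pop_lo = vapply(pops, function(p) rg[[p]][1] - 1L, integer(1)),
       pop_hi = vapply(pops, function(p) rg[[p]][2] - 1L, integer(1)),
       w_max = state$w_max,
       cf_spont = cf_spont)
}

# Run one closed-loop trial through the C++ engine. Returns the raw engine
# output plus a tidy data.frame view of the per-step log.
run_trial_engine <- function(controller, n_steps, freq, amplitude, dt,
                             substep, onset_step, pd_gains, cf, plast,
                             plant, pert, net_left = NULL, net_right = NULL,
                             theta0 = 0, noise = NULL, encoder_quant = 0,
                             mf_fullscale = mossy_ranges(), rate_relax = 0.3) {
  ctrl <- list(controller = match(controller,
                                  c("pd_only", "uni_cnn", "bicnn")) - 1L,
               n_steps = as.integer(n_steps), dt = dt,
               n_substeps = as.integer(round(dt / substep)),
               freq = freq, amplitude = amplitude,
               onset_step = if (is.null(onset_step)) -1L
                            else as.integer(onset_step),
               theta0 = theta0, encoder_quant = encoder_quant,
               rate_relax = rate_relax)
  qb <- resolve_plant(plant, perturbation("none"))
  qp <- resolve_plant(plant, pert)
  qb$fall_threshold <- plant$fall_threshold
  qp$fall_threshold <- plant$fall_threshold
  left <- right <- NULL
  if (controller != "pd_only") {
    sl <- new_hemisphere_state(net_left, side = "left")
    left <- hemi_engine_args(net_left, sl, cf$cf_spont_left)
  }
  if (controller == "bicnn") {
    sr <- new_hemisphere_state(net_right, side = "right")
    right <- hemi_engine_args(net_right, sr, cf$cf_spont_right)
  }
  raw <- .run_trial_cpp(ctrl, qb, qp, pd_gains, cf, plast,
                        as.numeric(mf_fullscale), left, right, noise)
  df <- as.data.frame(raw$log)
  names(df) <- c("t", "phi_ref", "phi_dot_ref", "theta", "theta_dot",
                 "phi", "phi_dot", "pd_out", "bicnn_out", "vn_out",
                 "cf_left", "cf_right", "fallen")
  list(df = df,
       fall_step = if (raw$fall_step < 0) NA_integer_
                   else raw$fall_step + 1L,
       W_left = raw$W_left, W_right = raw$W_right,
       W_PkVn_left = raw$W_PkVn_left, W_PkVn_right = raw$W_PkVn_right)
}
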