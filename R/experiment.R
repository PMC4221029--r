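#' Configure a closed-loop experiment
#'
#' Resolves a named scenario into the full set of run parameters: the
#' tracking task (100 cycles of `amplitude * sin(2 pi freq t)` by default),
#' the perturbation and its onset cycle, the per-hemisphere spontaneous
#' climbing-fiber levels, the controller variant and all module parameter
#' blocks. Scenarios:
#' `baseline` (no perturbation), `load_center` / `load_front` / `load_back`
#' (300 g load at cycle `perturbation_onset_cycle`), `incline` / `decline`
#' (+/-10 deg platform), `cf_no_spont` (both spontaneous levels zero,
#' symmetric load by default), `cf_one_sided` (right hemisphere loses its
#' spontaneous level, no perturbation), `cf_asymmetric` (unequal levels,
#' default right 0.08 / left 0.01, no perturbation).
#'
#' @param scenario scenario name (see above).
#' @param controller `"bicnn"`, `"uni_cnn"` or `"pd_only"`.
#' @param n_cycles number of reference cycles (default 100).
#' @param freq reference frequency in Hz (default 0.25).
#' @param amplitude reference amplitude in rad (default pi).
#' @param perturbation_onset_cycle 0-based cycle at which the perturbation
#'   switches on (default 50); must be < `n_cycles`.
#' @param cf_spont_left,cf_spont_right override the scenario's spontaneous
#'   levels.
#' @param pert_kind override the scenario's perturbation kind.
#' @param seeds list with `builder` (hemisphere build seed base) and
#'   optional `noise`.
#' @param n_repeats experiment repetitions (distinct builder seeds).
#' @param dt,substep control period and integrator substep (s).
#' @param rate_relax neuronal rate-relaxation factor per step (see
#'   [step_hemisphere()]).
#' @param pd_gains,plant,plasticity,cf,specs,ratios parameter blocks.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(scenario = c("baseline", "load_center",
                                           "load_front", "load_back",
                                           "incline", "decline",
                                           "cf_no_spont", "cf_one_sided",
                                           "cf_asymmetric"),
                              controller = c("bicnn", "pd_only", "uni_cnn"),
                              n_cycles = 100L, freq = 0.25, amplitude = pi,
                              perturbation_onset_cycle = 50L,
                              cf_spont_left = NULL, cf_spont_right = NULL,
                              pert_kind = NULL,
                              seeds = list(builder = 1L, noise = NULL),
                              n_repeats = 6L, dt = 0.01, substep = 0.001,
                              rate_relax = 0.3,
                              pd_gains = default_pd_gains(),
                              plant = plant_params(),
                              plasticity = plasticity_params(),
                              cf = cf_params(),
                              specs = population_specs(),
                              ratios = connection_ratios()) {
  scenario <- match.arg(scenario)
  controller <- match.arg(controller)
  defaults <- switch(scenario,
    baseline      = list(pert = "none", sl = 0.05, sr = 0.05),
    load_center   = list(pert = "load_center", sl = 0.05, sr = 0.05),
    load_front    = list(pert = "load_front", sl = 0.05, sr = 0.05),
    load_back     = list(pert = "load_back", sl = 0.05, sr = 0.05),
    incline       = list(pert = "incline", sl = 0.05, sr = 0.05),
    decline       = list(pert = "decline", sl = 0.05, sr = 0.05),
    cf_no_spont   = list(pert = "load_center", sl = 0, sr = 0),
    cf_one_sided  = list(pert = "none", sl = 0.05, sr = 0),
    cf_asymmetric = list(pert = "none", sl = 0.01, sr = 0.08))
  if (!is.null(pert_kind)) defaults$pert <- pert_kind
  if (!is.null(cf_spont_left)) defaults$sl <- cf_spont_left
  if (!is.null(cf_spont_right)) defaults$sr <- cf_spont_right
  stopifnot(freq > 0, n_repeats >= 1)
  if (defaults$pert != "none" && perturbation_onset_cycle >= n_cycles)
    stop("perturbation_onset_cycle must be smaller than n_cycles")
  cf$cf_spont_left <- defaults$sl
  cf$cf_spont_right <- defaults$sr
  structure(list(scenario = scenario, controller = controller,
                 n_cycles = as.integer(n_cycles), freq = freq,
                 amplitude = amplitude,
                 perturbation_onset_cycle = as.integer(perturbation_onset_cycle),
                 pert_kind = defaults$pert, seeds = seeds,
                 n_repeats = as.integer(n_repeats), dt = dt,
                 substep = substep, rate_relax = rate_relax,
                 pd_gains = pd_gains, plant = plant,
                 plasticity = plasticity, cf = cf, specs = specs,
                 ratios = ratios),
            class = "experiment_config")
}

# builder seeds for one repeat: left and right hemispheres always differ
repeat_seeds <- function(cfg, repeat_idx) {
  base <- cfg$seeds$builder + 2L * (repeat_idx - 1L)
  c(left = base, right = base + 1L)
}

#' Run one closed-loop trial
#'
#' Executes the full loop (sensors, mossy encoding, climbing fibers,
#' hemisphere updates, cerebellar combination, vestibular command, plant,
#' plasticity) at the 10 ms control period for `n_cycles` reference cycles,
#' switching the perturbation on at its onset cycle. Deterministic given
#' the config seeds. A fall is recorded (latched, state frozen) without
#' aborting.
#'
#' @param cfg an [experiment_config()].
#' @param repeat_idx which repetition (selects the builder seeds).
#' @param engine `"cpp"` (fast path) or `"R"` (pure-R reference loop; use
#'   only for small networks/short runs).
#' @return object of class `trial_log`: list with `df` (per-step log),
#'   `fall_step` (1-based step index or `NA`), final plastic weights, the
#'   config and the repeat index.
#' @export
run_scenario <- function(cfg, repeat_idx = 1L, engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  stopifnot(inherits(cfg, "experiment_config"))
  sds <- repeat_seeds(cfg, repeat_idx)
  net_l <- net_r <- NULL
  if (cfg$controller != "pd_only")
    net_l <- build_hemisphere(sds["left"], cfg$specs, cfg$ratios,
                              side = "left")
  if (cfg$controller == "bicnn")
    net_r <- build_hemisphere(sds["right"], cfg$specs, cfg$ratios,
                              side = "right")
  n_steps <- as.integer(round(cfg$n_cycles / cfg$freq / cfg$dt))
  onset_step <- if (cfg$pert_kind == "none") NULL
                else as.integer(round(cfg$perturbation_onset_cycle /
                                      cfg$freq / cfg$dt))
  pert <- perturbation(cfg$pert_kind)
  runner <- if (engine == "cpp") run_trial_engine else run_trial_r
  res <- runner(cfg$controller, n_steps, cfg$freq, cfg$amplitude, cfg$dt,
                cfg$substep, onset_step, cfg$pd_gains, cfg$cf,
                cfg$plasticity, cfg$plant, pert,
                net_left = net_l, net_right = net_r,
                rate_relax = cfg$rate_relax)
  structure(c(res, list(cfg = cfg, repeat_idx = repeat_idx)),
            class = "trial_log")
}

#' Run all repeats of a scenario
#'
#' @param cfg an [experiment_config()].
#' @param engine see [run_scenario()].
#' @return list of `trial_log` objects (class `trial_set`).
#' @export
run_repeats <- function(cfg, engine = "cpp") {
  structure(lapply(seq_len(cfg$n_repeats), function(i)
    run_scenario(cfg, i, engine)), class = "trial_set")
}

# pure-R reference of the closed loop; arithmetic mirrors the C++ engine
run_trial_r <- function(controller, n_steps, freq, amplitude, dt, substep,
                        onset_step, pd_gains, cf, plast, plant, pert,
                        net_left = NULL, net_right = NULL, theta0 = 0,
                        noise = NULL, encoder_quant = 0,
                        mf_fullscale = mossy_ranges(), rate_relax = 0.3) {
  state <- list(theta = theta0, theta_dot = 0, phi = 0, phi_dot = 0,
                fallen = FALSE)
  sl <- sr <- NULL
  n_mf <- 0L
  if (controller != "pd_only") {
    sl <- new_hemisphere_state(net_left, "left")
    rgl <- net_left$population_ranges$mf
    n_mf <- rgl[2] - rgl[1] + 1L
  }
  if (controller == "bicnn") sr <- new_hemisphere_state(net_right, "right")
  plast_l <- plast; plast_l$cf_spont <- cf$cf_spont_left
  plast_r <- plast; plast_r$cf_spont <- cf$cf_spont_right
  eff <- 0
  no_pert <- perturbation("none")
  cols <- c("t", "phi_ref", "phi_dot_ref", "theta", "theta_dot", "phi",
            "phi_dot", "pd_out", "bicnn_out", "vn_out", "cf_left",
            "cf_right", "fallen")
  log <- matrix(0, n_steps, length(cols), dimnames = list(NULL, cols))
  fall_step <- NA_integer_
  for (i in seq_len(n_steps)) {
    t <- (i - 1) * dt
    ref <- reference_trajectory(t, freq, amplitude)
    meas <- read_sensors(state)
    theta_e <- -meas$theta; theta_dot_e <- -meas$theta_dot
    phi_e <- ref$phi_ref - meas$phi; phi_dot_e <- ref$phi_dot_ref - meas$phi_dot
    cfs <- compute_cf(phi_e, phi_dot_e, cf)
    if (controller == "uni_cnn") {
      raw <- cf$error_gain * (cf$w_p * phi_e + cf$w_v * phi_dot_e)
      cfs$cf_left <- min(1, max(0, cf$cf_spont_left + abs(raw)))
      cfs$cf_right <- 0
    } else if (controller == "pd_only") {
      cfs$cf_left <- 0; cfs$cf_right <- 0
    }
    bic <- 0
    if (controller != "pd_only" && !state$fallen) {
      sig <- c(ref$phi_ref, ref$phi_dot_ref, theta_e, theta_dot_e,
               phi_e, phi_dot_e, eff)
      mf <- encode_mossy(sig, mf_fullscale, n_mf)
      sl <- step_hemisphere(net_left, sl, mf, rate_relax)
      if (controller == "bicnn") {
        sr <- step_hemisphere(net_right, sr, mf, rate_relax)
        bic <- bicnn_output(population_rates(net_left, sl, "Pk"),
                            population_rates(net_right, sr, "Pk"),
                            sl$W_PkVn, sr$W_PkVn)
      } else {
        bic <- min(1, max(-1, sum(sl$W_PkVn *
                                  population_rates(net_left, sl, "Pk")) - 0.5))
      }
    }
    pd <- pd_control(theta_e, theta_dot_e, phi_e, phi_dot_e, pd_gains)
    vn <- if (state$fallen) 0 else vn_combine(pd, bic)$vn_out
    log[i, ] <- c(t, ref$phi_ref, ref$phi_dot_ref, state$theta,
                  state$theta_dot, state$phi, state$phi_dot, pd, bic, vn,
                  cfs$cf_left, cfs$cf_right, as.numeric(state$fallen))
    if (!state$fallen) {
      if (controller != "pd_only") {
        plast_l$w_max <- sl$w_max
        sl$W[sl$pfpk_idx] <- update_pf_pk(sl$W[sl$pfpk_idx],
                                          sl$rates[sl$pfpk_pre],
                                          cfs$cf_left, plast_l)
        sl$W_PkVn <- update_pk_vn(sl$W_PkVn,
                                  population_rates(net_left, sl, "Pk"),
                                  vn, plast)
      }
      if (controller == "bicnn") {
        plast_r$w_max <- sr$w_max
        sr$W[sr$pfpk_idx] <- update_pf_pk(sr$W[sr$pfpk_idx],
                                          sr$rates[sr$pfpk_pre],
                                          cfs$cf_right, plast_r)
        sr$W_PkVn <- update_pk_vn(sr$W_PkVn,
                                  population_rates(net_right, sr, "Pk"),
                                  vn, plast)
      }
      p <- if (!is.null(onset_step) && (i - 1) >= onset_step) pert else no_pert
      state <- plant_step(state, vn, plant, p, dt, substep)
      if (state$fallen && is.na(fall_step)) fall_step <- i
      eff <- vn
    }
  }
  list(df = as.data.frame(log), fall_step = fall_step,
       W_left = if (!is.null(sl)) sl$W else NULL,
       W_right = if (!is.null(sr)) sr$W else NULL,
       W_PkVn_left = if (!is.null(sl)) sl$W_PkVn else NULL,
       W_PkVn_right = if (!is.null(sr)) sr$W_PkVn else NULL)
}

#' Directional root-mean-square tracking error per cycle
#'
#' Splits every reference cycle into its forward and backward half (by the
#' sign of the reference velocity, or by the sign of a time-shifted
#' reference) and computes the RSE of the wheel angle and of the body tilt
#' over each half. Cycles at or after a fall are reported as `Inf`.
#'
#' @param log a `trial_log`.
#' @param split `"velocity"` (default; forward = rising reference) or
#'   `"shift"` (forward = positive half-wave of the reference shifted by
#'   `shift_s` seconds).
#' @param shift_s shift in seconds for `split = "shift"` (default 10).
#' @return data.frame of class `rse_series` with columns `cycle` (1-based),
#'   `rse_phi_fwd`, `rse_phi_bwd`, `rse_theta_fwd`, `rse_theta_bwd`.
#' @export
rse_by_direction <- function(log, split = c("velocity", "shift"),
                             shift_s = 10) {
  split <- match.arg(split)
  df <- log$df
  freq <- log$cfg$freq
  amplitude <- log$cfg$amplitude
  cyc <- floor(df$t * freq + 1e-9)
  fwd <- if (split == "velocity") df$phi_dot_ref > 0
         else amplitude * sin(2 * pi * freq * (df$t + shift_s)) > 0
  fall_cyc <- if (is.na(log$fall_step)) Inf else cyc[log$fall_step]
  cycles <- sort(unique(cyc))
  rse <- function(sel, ref, act) {
    if (!any(sel)) return(NA_real_)
    sqrt(mean((ref[sel] - act[sel])^2))
  }
  out <- do.call(rbind, lapply(cycles, function(cc) {
    if (cc >= fall_cyc)
      return(data.frame(cycle = cc + 1L, rse_phi_fwd = Inf,
                        rse_phi_bwd = Inf, rse_theta_fwd = Inf,
                        rse_theta_bwd = Inf))
    s <- cyc == cc & df$fallen == 0
    data.frame(cycle = cc + 1L,
               rse_phi_fwd = rse(s & fwd, df$phi_ref, df$phi),
               rse_phi_bwd = rse(s & !fwd, df$phi_ref, df$phi),
               rse_theta_fwd = rse(s & fwd, 0 * df$theta, df$theta),
               rse_theta_bwd = rse(s & !fwd, 0 * df$theta, df$theta))
  }))
  structure(out, class = c("rse_series", "data.frame"),
            repeat_idx = log$repeat_idx, split = split)
}

#' Mean and standard deviation of RSE across repeats
#'
#' @param series list of `rse_series` (e.g. from lapply over a
#'   `trial_set`).
#' @return data.frame with per-cycle mean and sd of each directional RSE
#'   column.
#' @export
summarize_repeats <- function(series) {
  stopifnot(length(series) >= 1)
  cycles <- series[[1]]$cycle
  cols <- c("rse_phi_fwd", "rse_phi_bwd", "rse_theta_fwd", "rse_theta_bwd")
  out <- data.frame(cycle = cycles)
  for (cl in cols) {
    m <- sapply(series, function(s) s[[cl]])
    if (is.null(dim(m))) m <- matrix(m, nrow = length(cycles))
    out[[paste0(cl, "_mean")]] <- rowMeans(m)
    out[[paste0(cl, "_sd")]] <- if (ncol(m) == 1L) rep(0, nrow(m))
                                else apply(m, 1, stats::sd)
  }
  out
}

#' Phase-aligned traces of selected cycles
#'
#' Re-indexes the controller traces of the requested cycles to reference
#' phase in \[0, 1) so repeated cycles can be superimposed.
#'
#' @param log a `trial_log`.
#' @param cycle_range integer vector of 1-based cycle indices.
#' @return data.frame with `cycle`, `phase`, `phi_ref`, `phi`, `pd_out`,
#'   `vn_out`, `bicnn_out`.
#' @export
overlay_cycles <- function(log, cycle_range) {
  df <- log$df
  freq <- log$cfg$freq
  cyc <- floor(df$t * freq + 1e-9) + 1L
  if (any(!(cycle_range %in% cyc)))
    stop("cycle_range outside the logged cycles")
  sel <- cyc %in% cycle_range
  data.frame(cycle = cyc[sel], phase = (df$t[sel] * freq) %% 1,
             phi_ref = df$phi_ref[sel], phi = df$phi[sel],
             pd_out = df$pd_out[sel], vn_out = df$vn_out[sel],
             bicnn_out = df$bicnn_out[sel])
}

#' @export
print.trial_log <- function(x, ...) {
  cat("trial_log:", x$cfg$scenario, "/", x$cfg$controller, "-",
      nrow(x$df), "steps")
  if (!is.na(x$fall_step))
    cat(" (fell at step", x$fall_step, ")")
  cat("\n")
  invisible(x)
}
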