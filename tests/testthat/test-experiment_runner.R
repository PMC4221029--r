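test_that("experiment_config resolves scenario presets and validates", {
  cfg <- experiment_config("baseline")
  expect_equal(cfg$pert_kind, "none")
  expect_equal(cfg$cf$cf_spont_left, 0.05)
  cfg2 <- experiment_config("cf_no_spont")
  expect_equal(cfg2$cf$cf_spont_left, 0)
  expect_equal(cfg2$cf$cf_spont_right, 0)
  expect_equal(cfg2$pert_kind, "load_center")
  cfg3 <- experiment_config("cf_asymmetric")
  expect_equal(cfg3$cf$cf_spont_right, 0.08)
  expect_equal(cfg3$cf$cf_spont_left, 0.01)
  cfg4 <- experiment_config("cf_one_sided")
  expect_equal(cfg4$cf$cf_spont_right, 0)
  expect_equal(cfg4$cf$cf_spont_left, 0.05)
  expect_error(experiment_config("load_center", n_cycles = 10,
                                 perturbation_onset_cycle = 50))
  # an unperturbed scenario does not need an onset inside the run
  expect_silent(experiment_config("baseline", n_cycles = 10))
})

test_that("directional RSE reproduces closed forms", {
  # perfect tracking
  lg <- fake_log(function(t, ref) ref)
  r <- rse_by_direction(lg)
  expect_true(all(r$rse_phi_fwd == 0) && all(r$rse_phi_bwd == 0))
  # immobile robot vs pi*sin reference: RMS of a half sinusoid = pi/sqrt(2)
  lg0 <- fake_log(function(t, ref) 0 * ref)
  r0 <- rse_by_direction(lg0)
  expect_equal(r0$rse_phi_fwd, rep(pi / sqrt(2), 4), tolerance = 5e-3)
  expect_equal(r0$rse_phi_bwd, rep(pi / sqrt(2), 4), tolerance = 5e-3)
  # constant offset
  lge <- fake_log(function(t, ref) ref + 0.25)
  re <- rse_by_direction(lge)
  expect_equal(re$rse_phi_fwd, rep(0.25, 4), tolerance = 1e-12)
  # fall: cycles at/after the fall are Inf
  lgf <- fake_log(function(t, ref) ref, fall_step = 900L)
  rf <- rse_by_direction(lgf)
  expect_true(all(is.infinite(unlist(rf[rf$cycle >= 3, -1]))))
  expect_true(all(rf$rse_phi_fwd[rf$cycle <= 2] == 0))
  # the time-shifted split is also available
  rs <- rse_by_direction(lg0, split = "shift", shift_s = 1)
  expect_equal(rs$rse_phi_fwd, rep(pi / sqrt(2), 4), tolerance = 5e-3)
})

test_that("repeat summaries have the stated mean/sd semantics", {
  lg <- fake_log(function(t, ref) ref + 0.2)
  r <- rse_by_direction(lg)
  s1 <- summarize_repeats(list(r))
  expect_equal(s1$rse_phi_fwd_mean, r$rse_phi_fwd)
  expect_true(all(s1$rse_phi_fwd_sd == 0))
  s2 <- summarize_repeats(list(r, r))
  expect_true(all(s2$rse_phi_fwd_sd == 0))
  lg2 <- fake_log(function(t, ref) ref + 0.4)
  s3 <- summarize_repeats(list(r, rse_by_direction(lg2)))
  expect_equal(s3$rse_phi_fwd_mean, rep(0.3, 4), tolerance = 1e-12)
  expect_equal(s3$rse_phi_fwd_sd, rep(stats::sd(c(0.2, 0.4)), 4),
               tolerance = 1e-12)
})

test_that("overlay re-indexes cycles to phase and validates the range", {
  lg <- fake_log(function(t, ref) ref)
  ov <- overlay_cycles(lg, 2:3)
  expect_setequal(unique(ov$cycle), 2:3)
  expect_true(all(ov$phase >= 0 & ov$phase < 1))
  # periodic log: traces at equal phase coincide across cycles
  sp <- split(ov$phi_ref, ov$cycle)
  expect_equal(sp[[1]], sp[[2]], tolerance = 1e-9)
  expect_error(overlay_cycles(lg, 99), "outside")
})

test_that("run_scenario is deterministic and logs the full protocol", {
  cfg <- experiment_config("baseline", controller = "bicnn", n_cycles = 2,
                          perturbation_onset_cycle = 1, pert_kind = "none",
                          specs = toy_specs(), ratios = toy_ratios(),
                          n_repeats = 2)
  a <- run_scenario(cfg, 1)
  b <- run_scenario(cfg, 1)
  expect_identical(a$df, b$df)
  expect_identical(a$W_left, b$W_left)
  expect_equal(nrow(a$df), 2 / 0.25 / 0.01)
  # different repeats use different builder seeds -> different trajectories
  c2 <- run_scenario(cfg, 2)
  expect_false(identical(a$df$bicnn_out, c2$df$bicnn_out))
  # pd_only reduces exactly to the PD pathway (zero cerebellar output)
  cfgp <- experiment_config("baseline", controller = "pd_only", n_cycles = 2,
                           perturbation_onset_cycle = 1, pert_kind = "none")
  tp <- run_scenario(cfgp)
  expect_true(all(tp$df$bicnn_out == 0))
  expect_equal(tp$df$vn_out, tp$df$pd_out)
})

test_that("the C++ engine matches the pure-R reference loop step for step", {
  cfg <- experiment_config("baseline", controller = "bicnn", n_cycles = 1,
                          perturbation_onset_cycle = 0, pert_kind = "none",
                          specs = toy_specs(), ratios = toy_ratios())
  a <- run_scenario(cfg, 1, engine = "cpp")
  b <- run_scenario(cfg, 1, engine = "R")
  expect_equal(a$df, b$df, tolerance = 1e-9)
  expect_equal(a$W_left, b$W_left, tolerance = 1e-12)
  expect_equal(a$W_PkVn_left, b$W_PkVn_left, tolerance = 1e-12)
  # and for the uni-hemispheric ablation
  cfgu <- experiment_config("baseline", controller = "uni_cnn", n_cycles = 1,
                           perturbation_onset_cycle = 0, pert_kind = "none",
                           specs = toy_specs(), ratios = toy_ratios())
  au <- run_scenario(cfgu, 1, engine = "cpp")
  bu <- run_scenario(cfgu, 1, engine = "R")
  expect_equal(au$df, bu$df, tolerance = 1e-9)
})
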