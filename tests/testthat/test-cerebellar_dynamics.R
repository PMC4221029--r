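test_that("mossy encoding is the stated affine map with round-robin replication", {
  expect_equal(encode_mossy(rep(0, 7)), rep(0.5, 562))
  fs <- mossy_ranges()
  sig <- rep(0, 7); sig[1] <- fs[["phi_ref"]]
  mf <- encode_mossy(sig, fs)
  expect_equal(mf[1], 1.0)   # channel 1 carries phi_ref
  expect_equal(mf[8], 1.0)   # replicated 7 channels later
  expect_equal(mf[2], 0.5)
  # clipping
  sig[1] <- 10 * fs[["phi_ref"]]
  expect_equal(encode_mossy(sig, fs)[1], 1.0)
  # replication property over random signals
  set.seed(42)
  for (i in 1:20) {
    mf <- encode_mossy(stats::runif(7, -5, 5), fs)
    expect_equal(mf[1:7], mf[8:14])
    expect_equal(mf[554:560], mf[1:7])  # last full block (562 = 80*7 + 2)
    expect_equal(mf[561:562], mf[1:2])  # truncated final block
    expect_true(all(mf >= 0 & mf <= 1))
  }
  expect_length(encode_mossy(rep(0, 7), fs, 562L), 562L)
})

test_that("climbing-fiber pair sits at the spontaneous level at zero error and clips directionally", {
  p <- cf_params(error_gain = 1, w_p = 1, w_v = 0.1)
  z <- compute_cf(0, 0, p)
  expect_equal(z$cf_left, 0.05)
  expect_equal(z$cf_right, 0.05)
  r1 <- compute_cf(0.30, 0, p)   # raw = +0.30
  expect_equal(r1$cf_left, 0.35)
  expect_equal(r1$cf_right, 0)   # floored
  r2 <- compute_cf(-0.02, 0, p)  # raw = -0.02
  expect_equal(r2$cf_left, 0.03)
  expect_equal(r2$cf_right, 0.07)
  # velocity error contributes through w_v
  r3 <- compute_cf(0, 1, p)
  expect_equal(r3$cf_left, 0.15)
})

test_that("pf-Pk plasticity follows the LTD/LTP branches exactly and clips", {
  p <- plasticity_params()
  w <- rep(1e-3, 4)
  pf <- c(0.5, 0.5, 0.5, 0.5)
  expect_equal(update_pf_pk(w, pf, cf = 0.1, p) - w, rep(-2e-7, 4))
  expect_equal(update_pf_pk(w, pf, cf = 0.05, p), w)      # quiescent at spont
  expect_equal(update_pf_pk(w, pf, cf = 0.02, p) - w, rep(1.5e-7, 4))
  # LTD at pf = cf = 1 is gamma_LTD itself
  expect_equal(update_pf_pk(1e-3, pf_rates = 1, cf = 1, p) - 1e-3, -4e-6)
  # clipping at both bounds
  expect_equal(update_pf_pk(1e-9, 1, 1, p), 0)
  expect_equal(update_pf_pk(p$w_max, 1, 0.01, p), p$w_max)
  # drift direction flips exactly at cf_spont (monotone branches)
  for (cf in seq(0, 1, by = 0.05)) {
    d <- update_pf_pk(1e-3, 0.7, cf, p) - 1e-3
    expect_equal(sign(d), if (cf > 0.05) -1 else if (cf < 0.05) 1 else 0)
  }
})

test_that("Pk-Vn plasticity matches the sign rule and bounds", {
  p <- plasticity_params()
  w <- rep(1 / 15, 15)
  expect_equal(update_pk_vn(w, rep(0.5, 15), vn = 0.9, p), w)
  d <- update_pk_vn(1 / 15, 0.7, vn = 0.5, p) - 1 / 15
  expect_equal(d, 1e-5)
  d2 <- update_pk_vn(1 / 15, 0.7, vn = -0.5, p) - 1 / 15
  expect_equal(d2, -1e-5)
})

test_that("Pk-Vn bounds clip at both ends", {
  p <- plasticity_params()
  up <- update_pk_vn(rep(2 / 5, 5), rep(1, 5), vn = 1, p)
  expect_equal(up, rep(2 / 5, 5))
  dn <- update_pk_vn(rep(0, 5), rep(1, 5), vn = -1, p)
  expect_equal(dn, rep(0, 5))
})

test_that("bi-hemispheric combination inverts the left side and clips", {
  wl <- rep(1 / 15, 15); wr <- wl
  expect_equal(bicnn_output(rep(0.5, 15), rep(0.5, 15), wl, wr), 0)
  expect_equal(bicnn_output(rep(0, 15), rep(1, 15), wl, wr), 1)
  expect_equal(bicnn_output(rep(0.4, 15), rep(0.6, 15), wl, wr), 0.2)
  expect_equal(bicnn_output(rep(1, 15), rep(0, 15), wl, wr), -1)
})

test_that("the hemisphere step is bounded, centered, and symmetric across identical builds", {
  net <- build_toy(3)
  st <- new_hemisphere_state(net)
  n_mf <- diff(net$population_ranges$mf) + 1
  # centered inputs leave every rate at 0.5
  st2 <- step_hemisphere(net, st, rep(0.5, n_mf))
  expect_equal(st2$rates, rep(0.5, length(net$ID)))
  # zeroed weights give 0.5 everywhere regardless of input
  stz <- st; stz$W[] <- 0
  stz <- step_hemisphere(net, stz, runif(n_mf))
  non_mf <- setdiff(seq_along(net$ID),
                    net$population_ranges$mf[1]:net$population_ranges$mf[2])
  expect_equal(stz$rates[non_mf], rep(0.5, length(non_mf)))
  # rates stay in [0, 1] under arbitrary drive
  set.seed(8)
  stx <- new_hemisphere_state(net)
  for (i in 1:20) {
    stx <- step_hemisphere(net, stx, runif(n_mf), relax = 0.5)
    expect_true(all(stx$rates >= 0 & stx$rates <= 1))
  }
  # identical seeds on both sides cancel exactly
  netL <- build_toy(3, side = "left"); netR <- build_toy(3, side = "right")
  sl <- new_hemisphere_state(netL); sr <- new_hemisphere_state(netR)
  mf <- runif(n_mf)
  sl <- step_hemisphere(netL, sl, mf); sr <- step_hemisphere(netR, sr, mf)
  expect_identical(population_rates(netL, sl, "Pk"),
                   population_rates(netR, sr, "Pk"))
  expect_equal(bicnn_output(population_rates(netL, sl, "Pk"),
                            population_rates(netR, sr, "Pk"),
                            sl$W_PkVn, sr$W_PkVn), 0)
})

test_that("the vectorized AER step equals the per-synapse oracle and the C++ kernel", {
  net <- build_toy(13)
  n_mf <- diff(net$population_ranges$mf) + 1
  set.seed(5)
  for (relax in c(1, 0.3)) {
    st <- new_hemisphere_state(net)
    st$rates <- runif(length(net$ID))
    mf <- runif(n_mf)
    r_vec <- step_hemisphere(net, st, mf, relax)$rates
    r_orc <- oracle_step(net, st$rates, mf, relax)
    expect_equal(r_vec, r_orc, tolerance = 1e-12)
    rg <- net$population_ranges
    pops <- c("gr", "Go", "ba", "Pk")
    r_cpp <- bicnn:::.aer_step_cpp(net$ptr, net$P - 1L, st$W,
      vapply(pops, function(p) rg[[p]][1] - 1L, integer(1)),
      vapply(pops, function(p) rg[[p]][2] - 1L, integer(1)),
      rg$mf[1] - 1L, rg$mf[2] - 1L, st$rates, mf, relax)
    expect_equal(r_cpp, r_orc, tolerance = 1e-12)
  }
})

test_that("plasticity is quiescent at the spontaneous level and mirrors under mirrored cf", {
  net <- build_toy(21)
  st <- new_hemisphere_state(net)
  # widen the clip to the toy network's own bound so the identity is exact
  p <- plasticity_params(w_max = st$w_max)
  w0 <- st$W[st$pfpk_idx]
  # cf pinned at spont, vn = 0: invariant weights
  for (i in 1:10) {
    w <- update_pf_pk(w0, runif(length(w0)), cf = p$cf_spont, p)
    expect_identical(w, w0)
    expect_identical(update_pk_vn(st$W_PkVn, runif(st$n_pk), 0, p),
                     st$W_PkVn)
  }
  # mirrored cf sequences produce mirrored weight trajectories on identical nets
  pf <- runif(length(w0))
  cfs <- c(0.10, 0.02, 0.30, 0.05)
  wa <- w0; wb <- w0
  for (cf in cfs) wa <- update_pf_pk(wa, pf, cf, p)
  for (cf in cfs) wb <- update_pf_pk(wb, pf, cf, p)
  expect_identical(wa, wb)
})
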