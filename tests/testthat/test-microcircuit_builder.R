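test_that("default placement yields the full hemisphere with layered, non-overlapping cells", {
  specs <- population_specs()
  pos <- allocate_positions(specs, 100, rng_seed = 11)
  expect_equal(nrow(pos), 4694L)
  counts <- table(pos$population)
  expect_equal(unname(counts[c("mf", "gr", "Go", "ba", "Pk")]),
               c(281L, 4096L, 28L, 274L, 15L), ignore_attr = TRUE)
  # layering
  gran <- pos$population %in% c("mf", "gr", "Go")
  expect_true(all(pos$z[gran] >= 0 & pos$z[gran] <= 100))
  expect_true(all(pos$z[!gran] >= 100 & pos$z[!gran] <= 120))
  # non-overlap on a sampled subset against all cells
  rad <- specs$exclusion_radius[match(pos$population, specs$label)]
  set.seed(1)
  for (i in sample(nrow(pos), 50)) {
    d <- sqrt((pos$x - pos$x[i])^2 + (pos$y - pos$y[i])^2 +
              (pos$z - pos$z[i])^2)
    ok <- d[-i] >= (rad[-i] + rad[i]) - 1e-9
    expect_true(all(ok))
  }
})

test_that("placement is deterministic in the seed and degenerate cases work", {
  specs <- toy_specs()
  a <- allocate_positions(specs, 100, rng_seed = 3)
  b <- allocate_positions(specs, 100, rng_seed = 3)
  expect_identical(a, b)
  c2 <- allocate_positions(specs, 100, rng_seed = 4)
  expect_false(isTRUE(all.equal(a$x, c2$x)))
  one <- population_specs(counts = c(mf = 1L, gr = 1L, Go = 1L, ba = 1L,
                                     Pk = 1L))
  p1 <- allocate_positions(one, 100, rng_seed = 1)
  expect_equal(nrow(p1), 5L)
  expect_true(all(p1$z[p1$population == "gr"] <= 100))
})

test_that("infeasible packing is reported as an error", {
  specs <- population_specs(counts = c(mf = 1L, gr = 200L, Go = 1L,
                                       ba = 1L, Pk = 1L))
  specs$exclusion_radius[specs$label == "gr"] <- 40
  expect_error(allocate_positions(specs, 100, rng_seed = 1,
                                  max_attempts = 50L),
               "packing infeasible")
})

test_that("nearest-neighbour wiring realizes the exact convergence of every class", {
  net <- default_net()
  rep_tab <- validate_network(net)
  expect_equal(rep_tab$deviations, character(0))
  expect_equal(rep_tab$per_class$conv_min, rep_tab$per_class$requested)
  expect_equal(rep_tab$per_class$conv_max, rep_tab$per_class$requested)
  # headline convergences
  pc <- rep_tab$per_class
  expect_equal(pc$requested[pc$class == "mf_gr"], 4L)
  expect_equal(pc$requested[pc$class == "gr_Pk"], 1024L)
  expect_equal(pc$requested[pc$class == "ba_Pk"], 110L)
  # total synapse count: Table-1 arithmetic, within 0.5% of the printed total
  expect_equal(rep_tab$total_synapses, 110358L)
  expect_lt(abs(rep_tab$total_synapses - 110300) / 110300, 0.005)
})

test_that("wiring selects nearest sources, breaks ties by id, refuses infeasible convergence", {
  pos <- data.frame(neuron_id = 1:4, population = c("mf", "mf", "gr", "gr"),
                    x = c(0, 1, 0.2, 3), y = 0, z = 0)
  r <- connection_ratios()[1, ]  # mf_gr, convergence 4
  r$convergence <- 1L
  tab <- wire_nearest_neighbor(pos, r)
  expect_equal(tab$pre[tab$post == 3], 1L)  # 0.2 from mf 1, 0.8 from mf 2
  expect_equal(tab$pre[tab$post == 4], 2L)
  r$convergence <- 3L
  expect_error(wire_nearest_neighbor(pos, r), "convergence 3 exceeds")
  # tie broken by lower id: both mf equidistant
  pos2 <- data.frame(neuron_id = 1:3, population = c("mf", "mf", "gr"),
                     x = c(-1, 1, 0), y = 0, z = 0)
  r$convergence <- 1L
  expect_equal(wire_nearest_neighbor(pos2, r)$pre, 1L)
})

test_that("initial weights are truncated-normal magnitudes normalized per class in-degree", {
  net <- default_net()
  tab <- decode_aer(net)
  key <- paste(tab$post, tab$class)
  indeg <- ave(rep(1, nrow(tab)), key, FUN = sum)
  pre_norm <- abs(tab$weight) * indeg
  expect_true(all(pre_norm >= 0.8 - 1e-9 & pre_norm <= 1 + 1e-9))
  # inhibitory classes carry negative sign
  expect_true(all(tab$weight[tab$nature == "inhibitory"] < 0))
  expect_true(all(tab$weight[tab$nature == "excitatory"] > 0))
  # d = 1/(class in-degree): spot-check the Go cell classes
  go_gr <- tab$class == "gr_Go"
  expect_true(all(abs(tab$weight[go_gr]) <= 1 / 1639 + 1e-12))
  expect_true(all(abs(tab$weight[go_gr]) >= 0.8 / 1639 - 1e-12))
})

test_that("AER encoding reproduces the published four-neuron example field-for-field", {
  f4 <- fig4_network()
  net <- encode_aer(f4$table, f4$positions)
  # R is 1-based; the published zero-based ID[2]=3 is ID[[3]] here, etc.
  expect_equal(net$ID[3], 3L)
  expect_equal(net$N_P[3], 2L)
  expect_equal(net$P[4], 1L)
  expect_equal(net$P[5], 2L)
  expect_equal(net$W[4], 0.3)
  expect_equal(net$W[5], -0.4)
  expect_equal(net$n_syn, 6L)
  expect_equal(sum(net$N_P), 6L)
})

test_that("AER encode/decode round-trips exactly, including the empty network", {
  net <- default_net()
  tab <- decode_aer(net)
  net2 <- encode_aer(tab, net$positions)
  expect_identical(net2$ID, net$ID)
  expect_identical(net2$N_P, net$N_P)
  expect_identical(net2$P, net$P)
  expect_identical(net2$W, net$W)
  expect_identical(sum(net$N_P), length(net$P))
  expect_identical(length(net$P), length(net$W))
  # unknown ids rejected
  bad <- fig4_network()
  bad$table$pre[1] <- 99L
  expect_error(encode_aer(bad$table, bad$positions), "unknown neuron ids")
  # empty synapse table
  f4 <- fig4_network()
  empty <- f4$table[0, ]
  net0 <- encode_aer(empty, f4$positions)
  expect_equal(net0$N_P, rep(0L, 4))
  expect_length(net0$P, 0)
  expect_length(net0$W, 0)
})

test_that("hemisphere builds are seed-deterministic and unique across seeds", {
  a <- build_toy(5)
  b <- build_toy(5)
  expect_identical(a$W, b$W)
  expect_identical(a$P, b$P)
  c2 <- build_toy(6)
  expect_false(identical(a$P, c2$P) && identical(a$W, c2$W))
})

test_that("network export/import round-trips through CSV + JSON", {
  net <- build_toy(9)
  path <- file.path(tempdir(), "toy_net")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$P, net$P)
  expect_equal(back$W, net$W, tolerance = 1e-12)
  expect_equal(back$population_ranges, net$population_ranges)
})
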