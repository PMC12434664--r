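cfg_neutral <- sim_config(n_mg = 0L, phosphate_charge = 0)

test_that("a 6-bead chain gets 5 bonds and 4 angles", {
  xyz <- cbind(seq(0, 25, by = 5), 0, 0)
  cg <- make_cg(xyz, residue_index = rep(1:2, each = 3))
  nc <- native_contacts(cg, cutoff = 4, min_sep = 1)   # none within 4 A
  top <- build_topology(cg, nc, cfg_neutral)
  expect_equal(nrow(top$bonds), 5L)
  expect_equal(nrow(top$angles), 4L)
})

test_that("contacts referencing nonexistent beads are rejected", {
  xyz <- cbind(seq(0, 25, by = 5), 0, 0)
  cg <- make_cg(xyz, residue_index = rep(1:2, each = 3))
  bad <- make_nc(i = 1L, j = 99L, r_native = 5, residue_index = rep(1:2, 50))
  expect_error(build_topology(cg, bad, cfg_neutral), "99")
})

test_that("native state is the potential minimum of the neutral model", {
  top <- build_topology(fx$cg_rb, fx$nc_rb, cfg_neutral)
  e <- potential_energy(top)
  expect_equal(e$total, -nrow(top$contacts), tolerance = 1e-10)
  expect_equal(e$bond, 0, tolerance = 1e-10)
  expect_equal(e$angle, 0, tolerance = 1e-10)
  expect_lt(max(abs(e$forces)), 1e-8)
})

test_that("analytic forces match a numerical gradient", {
  top <- build_topology(fx$cg_hp, fx$nc_hp, sim_config(n_mg = 0L))
  set.seed(9)
  xyz <- fx$cg_hp$xyz + matrix(rnorm(nrow(fx$cg_hp$xyz) * 3, sd = 0.3),
                               ncol = 3)
  ions <- matrix(c(4, 1, 6, -8, 3, 20), 2, 3, byrow = TRUE)
  e <- potential_energy(top, xyz, ions)
  h <- 1e-6
  # probe a spread of bead and ion coordinates
  probes <- rbind(c(1, 1), c(14, 2), c(36, 3), c(37, 1), c(38, 3))
  all_xyz <- rbind(xyz, ions)
  for (p in seq_len(nrow(probes))) {
    i <- probes[p, 1]; k <- probes[p, 2]
    up <- all_xyz; up[i, k] <- up[i, k] + h
    dn <- all_xyz; dn[i, k] <- dn[i, k] - h
    e_up <- potential_energy(top, up[1:36, ], up[-(1:36), , drop = FALSE])
    e_dn <- potential_energy(top, dn[1:36, ], dn[-(1:36), , drop = FALSE])
    num <- -(e_up$total - e_dn$total) / (2 * h)
    expect_equal(e$forces[i, k], num, tolerance = 1e-4)
  }
})

test_that("Debye-Hueckel pair energy matches the closed form", {
  # two +2 ions at exactly one Debye length, no other charges
  lambda <- 10
  cfg <- sim_config(n_mg = 2L, phosphate_charge = 0, debye_length = lambda,
                    coulomb_k = 1)
  top <- build_topology(fx$cg_hp, fx$nc_hp, cfg)
  ions <- rbind(c(60, 0, 0), c(60 + lambda, 0, 0))   # far from the RNA
  e <- potential_energy(top, ions = ions)
  expect_equal(e$electrostatic, 4 * exp(-1) / lambda, tolerance = 1e-12)
})

test_that("seeded runs are bit-identical and seeds matter", {
  top <- build_topology(fx$cg_hp, fx$nc_hp, sim_config())
  cfg <- sim_config(n_steps = 2000L, save_interval = 200L, n_mg = 4L,
                    temperature = temperature_folded(), seed = 11L)
  t1 <- run_langevin(top, cfg)
  t2 <- run_langevin(top, cfg)
  expect_identical(t1$rna, t2$rna)
  expect_identical(t1$ions, t2$ions)
  cfg2 <- cfg; cfg2$seed <- 12L
  t3 <- run_langevin(top, cfg2)
  expect_false(identical(t1$rna, t3$rna))
})

test_that("zero temperature, zero friction at the native state stays put", {
  top <- build_topology(fx$cg_hp, fx$nc_hp, cfg_neutral)
  cfg <- sim_config(n_steps = 1000L, save_interval = 100L, temperature = 0,
                    friction = 0, n_mg = 0L, phosphate_charge = 0)
  tr <- run_langevin(top, cfg)
  drift <- max(abs(frame_xyz(tr, n_frames(tr)) - fx$cg_hp$xyz))
  expect_lt(drift, 1e-6)
})

test_that("ions stay inside the periodic box and are conserved", {
  top <- build_topology(fx$cg_hp, fx$nc_hp, sim_config())
  cfg <- sim_config(n_steps = 3000L, save_interval = 300L, n_mg = 6L,
                    temperature = 1.5, seed = 2L)
  tr <- run_langevin(top, cfg)
  expect_equal(dim(tr$ions)[2], 6L)
  expect_true(all(abs(tr$ions) <= cfg$box_edge / 2 + 1e-9))
  expect_true(all(is.finite(tr$rna)))
})

test_that("an unbiased umbrella run equals the plain run frame by frame", {
  top <- build_topology(fx$cg_hp, fx$nc_hp, sim_config())
  cfg <- sim_config(n_steps = 2000L, save_interval = 200L, n_mg = 3L,
                    temperature = 1, seed = 5L)
  ions <- place_ions(top, 3L, seed = 5L)
  win <- umbrella_window(q0 = 0.5, k_q = 1)
  win$k_q <- 0   # null bias
  t_plain <- run_langevin(top, cfg, ions = ions)
  t_null <- umbrella_run(top, cfg, win, ions = ions)
  expect_identical(t_plain$rna, t_null$rna)
})

test_that("a stiff umbrella spring pins the smoothed Q near its target", {
  top <- build_topology(fx$cg_hp, fx$nc_hp, sim_config())
  cfg <- sim_config(n_steps = 20000L, save_interval = 200L, n_mg = 0L,
                    temperature = temperature_folded(), seed = 3L)
  win <- umbrella_window(q0 = 0.9, k_q = 5000)
  tr <- umbrella_run(top, cfg, win)
  qs <- tr$q_smooth[-(1:20)]    # discard the relaxation transient
  expect_lt(abs(mean(qs) - 0.9), 0.05)
})

test_that("adjacent umbrella windows overlap in Q", {
  top <- build_topology(fx$cg_hp, fx$nc_hp, sim_config())
  cfg <- sim_config(n_steps = 10000L, save_interval = 50L, n_mg = 0L,
                    temperature = temperature_folded(), seed = 4L)
  q0 <- seq(0.1, 0.9, by = 0.1)
  wins <- umbrella_series(top, cfg, q0 = q0, k_q = 30, equil_steps = 2000L)
  qs <- lapply(wins, function(tr) as.numeric(q_trajectory(tr, fx$nc_hp)))
  h <- make_q_histograms(qs, n_bins = 25L)
  for (w in seq_len(length(q0) - 1)) {
    expect_gt(sum(h$counts[w, ] > 0 & h$counts[w + 1, ] > 0), 0)
  }
})

test_that("the Q time series is stationary at fixed temperature", {
  top <- build_topology(fx$cg_hp, fx$nc_hp, sim_config())
  cfg <- sim_config(n_steps = 40000L, save_interval = 100L, n_mg = 0L,
                    temperature = temperature_folded(), seed = 6L)
  tr <- run_langevin(top, cfg)
  q <- as.numeric(q_trajectory(tr, fx$nc_hp))
  n <- length(q)
  q3 <- q[(n / 2 + 1):(3 * n / 4)]
  q4 <- q[(3 * n / 4 + 1):n]
  pooled_sd <- sd(q[(n / 2 + 1):n])
  expect_lt(abs(mean(q3) - mean(q4)), 3 * pooled_sd / sqrt(length(q3)) + 0.05)
})

test_that("morph ensembles hit their scripted endpoints", {
  tr0 <- morph_ensemble(fx$cg_hp, n_frames = 4, unfold_fraction = 0,
                        noise = 0)
  for (f in 1:4) expect_equal(frame_xyz(tr0, f), fx$cg_hp$xyz)
  expect_equal(fraction_native(frame_xyz(tr0, 1), fx$nc_hp), 1)
  tr1 <- morph_ensemble(fx$cg_hp, n_frames = 6, unfold_fraction = 1,
                        noise = 0)
  expect_equal(fraction_native(frame_xyz(tr1, 6), fx$nc_hp), 0)
})

test_that("sim_config enforces its invariants", {
  expect_error(sim_config(timestep = 0), "timestep")
  expect_error(sim_config(n_mg = -1), "n_mg")
})
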