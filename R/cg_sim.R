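# Desk-scale surrogate simulator: configuration, topology assembly, Langevin
# runs and umbrella-biased windows. Reduced units throughout: energies in
# units of the contact well depth (epsilon_0 = 1), k_B = 1, lengths in
# Angstrom, masses in mu_R, time in tau_R.

#' Simulation configuration
#'
#' Defaults follow the surrogate model's conventions: timestep 0.001 tau_R,
#' unit bead mass and drag coefficient 1 / tau_R, phosphate charge -1 and
#' divalent ion charge +2, and a 15 nm periodic box (a desk-scale default;
#' larger boxes are accepted via \code{box_edge_nm}). The Debye length
#' encodes the implicit monovalent salt; the Coulomb prefactor of
#' 7.1 energy.Angstrom corresponds to a Bjerrum length of ~7 Angstrom when
#' the reference thermal energy is one reduced unit. Temperatures are
#' multiples of the reduced reference; the calibrated defaults for the
#' folded and unfolded regimes of the bundled systems are
#' \code{temperature_folded()} and \code{temperature_unfolded()}.
#'
#' @param n_steps Number of integration steps.
#' @param timestep Integration timestep in tau_R.
#' @param save_interval Steps between saved frames.
#' @param temperature Reduced temperature (k_B = 1).
#' @param friction Drag coefficient per particle (1 / tau_R).
#' @param mass Bead/ion mass (mu_R).
#' @param box_edge_nm Cubic box edge in nm.
#' @param n_mg Number of divalent ions.
#' @param phosphate_charge,mg_charge Effective site charges.
#' @param debye_length Screening length in Angstrom (implicit monovalent
#'   salt).
#' @param coulomb_k Electrostatic prefactor (energy * Angstrom).
#' @param ion_radius Hydrated-ion excluded-volume radius in Angstrom.
#' @param bead_radius Excluded-volume radius per bead (Angstrom).
#' @param k_bond,k_angle Harmonic stiffnesses (energy/A^2, energy/rad^2).
#' @param contact_epsilon Native-contact well depth.
#' @param contact_width Gaussian well width (Angstrom).
#' @param ev_epsilon Excluded-volume energy scale.
#' @param seed RNG seed.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_steps = 100000L, timestep = 0.001,
                       save_interval = 500L, temperature = 1.0,
                       friction = 1.0, mass = 1.0, box_edge_nm = 15,
                       n_mg = 20L, phosphate_charge = -1, mg_charge = 2,
                       debye_length = 10, coulomb_k = 7.1,
                       ion_radius = 3.5, bead_radius = 1.6,
                       k_bond = 100, k_angle = 20, contact_epsilon = 1,
                       contact_width = 0.6, ev_epsilon = 1, seed = 1L) {
  stopifnot(timestep > 0, n_steps >= 1, save_interval >= 1, n_mg >= 0,
            temperature >= 0, friction >= 0, mass > 0, box_edge_nm > 0)
  structure(list(n_steps = as.integer(n_steps), timestep = timestep,
                 save_interval = as.integer(save_interval),
                 temperature = temperature, friction = friction, mass = mass,
                 box_edge = box_edge_nm * 10, n_mg = as.integer(n_mg),
                 phosphate_charge = phosphate_charge, mg_charge = mg_charge,
                 debye_length = debye_length, coulomb_k = coulomb_k,
                 ion_radius = ion_radius, bead_radius = bead_radius,
                 k_bond = k_bond, k_angle = k_angle,
                 contact_epsilon = contact_epsilon,
                 contact_width = contact_width, ev_epsilon = ev_epsilon,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Calibrated reduced temperature of the folded regime
#'
#' Fixed once from a temperature scan of the bundled reference systems: at
#' this temperature a run started from the native structure stays folded.
#' @export
temperature_folded <- function() 0.5

#' Calibrated reduced temperature of the unfolded regime
#'
#' From the same scan: well above the surrogate's folding temperature, so a
#' run started from the native structure unfolds.
#' @export
temperature_unfolded <- function() 2.5

#' Assemble the structure-based topology for a coarse-grained chain
#'
#' Potential terms: harmonic bonds between consecutive beads along the
#' chain, harmonic angles on consecutive bead triples (both at their native
#' geometry), Gaussian wells at the native distance for every native
#' contact (over a purely repulsive core), WCA-style excluded volume for all
#' remaining nonbonded pairs and for ions, and a Debye-Hueckel term over
#' charged sites (P beads and ions). Excluded-volume diameters are capped at
#' 95% of the pair's native distance so the native structure sits exactly at
#' the potential minimum of its bonded + contact terms.
#'
#' @param cg Native \code{cg_structure}.
#' @param nc \code{native_contacts} derived from the same structure.
#' @param cfg A \code{sim_config}.
#' @return Object of class \code{cg_topology} (parameter list consumed by
#'   the compiled engine).
#' @export
build_topology <- function(cg, nc, cfg = sim_config()) {
  nb <- nrow(cg$xyz)
  if (nrow(nc$pairs) > 0 && max(nc$pairs$j) > nb)
    stop("contact set references bead ", max(nc$pairs$j),
         " but structure has ", nb, " beads")
  xyz <- cg$xyz
  bonds <- cbind(seq_len(nb - 1L), seq_len(nb - 1L) + 1L)
  bond_r0 <- sqrt(rowSums((xyz[bonds[, 1], , drop = FALSE] -
                           xyz[bonds[, 2], , drop = FALSE])^2))
  angles <- if (nb >= 3L) cbind(seq_len(nb - 2L), seq_len(nb - 2L) + 1L,
                                seq_len(nb - 2L) + 2L)
            else matrix(integer(), 0, 3)
  angle_theta0 <- apply(angles, 1, function(a) {
    u <- xyz[a[1], ] - xyz[a[2], ]; v <- xyz[a[3], ] - xyz[a[2], ]
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  })
  cp <- nc$pairs[abs(nc$pairs$i - nc$pairs$j) > 2L, , drop = FALSE]
  contact_sigma <- pmin(2 * cfg$bead_radius, 0.95 * cp$r_native)
  # pair classification for excluded volume: skip bonded (|i-j| <= 2) and
  # contact pairs; cap sigma below the native separation
  ev <- matrix(0, nb, nb)
  sig0 <- 2 * cfg$bead_radius
  d_nat <- as.matrix(dist(xyz))
  idx <- abs(outer(seq_len(nb), seq_len(nb), "-")) > 2L
  ev[idx] <- pmin(sig0, 0.95 * d_nat[idx])
  if (nrow(cp) > 0) {
    ev[cbind(cp$i, cp$j)] <- 0
    ev[cbind(cp$j, cp$i)] <- 0
  }
  charge <- ifelse(cg$role == "P", cfg$phosphate_charge, 0)
  structure(list(
    bonds = bonds - 1L, bond_r0 = bond_r0, k_bond = cfg$k_bond,
    angles = angles - 1L, angle_theta0 = as.numeric(angle_theta0),
    k_angle = cfg$k_angle,
    contacts = as.matrix(cp[, c("i", "j")]) - 1L,
    contact_r0 = cp$r_native,
    contact_eps = rep(cfg$contact_epsilon, nrow(cp)),
    contact_sigma = contact_sigma,
    contact_width = rep(cfg$contact_width, nrow(cp)),
    ev_sigma = ev, charge = charge,
    bead_radius = rep(cfg$bead_radius, nb),
    ion_charge = cfg$mg_charge, ion_radius = cfg$ion_radius,
    ev_eps = cfg$ev_epsilon, coulomb_k = cfg$coulomb_k,
    debye_length = cfg$debye_length,
    dh_cutoff = 4 * cfg$debye_length, box_edge = cfg$box_edge,
    native_xyz = cg$xyz, n_beads = nb,
    residue_index = cg$residue_index, role = cg$role),
    class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("<cg_topology> ", x$n_beads, " beads, ", nrow(x$bonds), " bonds, ",
      nrow(x$angles), " angles, ", nrow(x$contacts), " contacts\n", sep = "")
  invisible(x)
}

#' Potential energy (and forces) of a configuration
#'
#' Evaluates the full surrogate potential; useful for verifying that the
#' native structure is a stationary point and as the oracle for numerical
#' gradient checks.
#' @param top A \code{cg_topology}.
#' @param xyz Bead coordinates; defaults to the native structure.
#' @param ions Ion coordinate matrix (may have zero rows).
#' @param bias Optional \code{list(k_q, q0, qbeta = 5, qlambda = 1.2)}.
#' @return List of energy terms, total, smoothed Q and the force matrix.
#' @export
potential_energy <- function(top, xyz = top$native_xyz,
                             ions = matrix(numeric(), 0, 3), bias = NULL) {
  par <- unclass(top)
  if (!is.null(bias)) {
    par$k_q <- bias$k_q; par$q0 <- bias$q0
    par$qbeta <- bias$qbeta %||% 5; par$qlambda <- bias$qlambda %||% 1.2
  }
  .fs_energy(xyz, ions, par)
}

#' Seeded uniform ion placement in the periodic box
#'
#' Ions are placed uniformly at random, rejecting positions within the
#' excluded-volume diameter of any bead so runs never start inside a core.
#' @param top A \code{cg_topology}.
#' @param n_ions Number of ions.
#' @param seed RNG seed.
#' @export
place_ions <- function(top, n_ions, seed = 1L) {
  if (n_ions == 0L) return(matrix(numeric(), 0, 3))
  set.seed(seed)
  box <- top$box_edge
  out <- matrix(NA_real_, n_ions, 3)
  min_d <- top$ion_radius + max(top$bead_radius)
  k <- 0L
  while (k < n_ions) {
    cand <- runif(3, -box / 2, box / 2)
    d <- sqrt(colSums((t(top$native_xyz) - cand)^2))
    if (min(d) > min_d) {
      k <- k + 1L
      out[k, ] <- cand
    }
  }
  out
}

.run_engine <- function(top, cfg, start_xyz, ions, bias = NULL,
                        velocities = NULL, window_id = NA_integer_) {
  par <- unclass(top)
  par$box_edge <- cfg$box_edge
  if (!is.null(bias)) {
    par$k_q <- bias$k_q; par$q0 <- bias$q0
    par$qbeta <- bias$qbeta %||% 5; par$qlambda <- bias$qlambda %||% 1.2
  }
  res <- .fs_run_langevin(start_xyz, ions, par,
                          list(timestep = cfg$timestep,
                               n_steps = cfg$n_steps,
                               save_interval = cfg$save_interval,
                               temperature = cfg$temperature,
                               friction = cfg$friction, mass = cfg$mass,
                               seed = cfg$seed, velocities = velocities))
  ni <- nrow(ions)
  tr <- new_trajectory(res$rna,
                       ions = if (ni > 0) res$ions else NULL,
                       box_edge = cfg$box_edge, steps = res$steps,
                       q_smooth = res$q_smooth,
                       bias_energy = res$bias_energy,
                       window_id = window_id, seed = cfg$seed,
                       meta = list(energy = res$energy,
                                   final_x = res$final_x,
                                   final_v = res$final_v,
                                   temperature = cfg$temperature))
  tr
}

#' Langevin dynamics run
#'
#' BAOAB Langevin integration of the coarse-grained chain plus explicit
#' ions. Identical (config, seed) pairs give bit-identical trajectories.
#' Ions are wrapped into the periodic box each step; the RNA is kept whole
#' and interacts with ions through the minimum-image convention.
#'
#' @param top A \code{cg_topology}.
#' @param cfg A \code{sim_config} (n_mg ions are placed with the same seed
#'   unless \code{ions} is given).
#' @param start_xyz Starting bead coordinates (default native).
#' @param ions Optional explicit ion start positions.
#' @param velocities Optional starting velocities ((beads+ions) x 3).
#' @return A \code{cg_trajectory}.
#' @export
run_langevin <- function(top, cfg, start_xyz = top$native_xyz, ions = NULL,
                         velocities = NULL) {
  if (is.null(ions)) ions <- place_ions(top, cfg$n_mg, seed = cfg$seed)
  .run_engine(top, cfg, start_xyz, ions, velocities = velocities)
}

#' Umbrella window definition
#' @param q0 Target Q in [0, 1]; \code{k_q} spring constant (energy per
#'   Q^2); \code{window_id} integer label; \code{n_steps} optional override.
#' @export
umbrella_window <- function(q0, k_q = 200, window_id = 1L, n_steps = NULL) {
  stopifnot(q0 >= 0, q0 <= 1, k_q > 0)
  structure(list(q0 = q0, k_q = k_q, window_id = as.integer(window_id),
                 n_steps = n_steps),
            class = "umbrella_window")
}

#' Umbrella-biased Langevin run
#'
#' Adds the harmonic bias 0.5 k_q (Q_smooth - q0)^2 where Q_smooth is the
#' differentiable contact fraction
#' (1/N_c) sum 1 / (1 + exp(beta (r_ij - lambda r_ij^nat))) with beta =
#' 5 / Angstrom and lambda = 1.2. Per-frame Q_smooth and bias energy are
#' recorded. Hard Q (see \code{\link{fraction_native}}) remains the
#' reporting coordinate.
#'
#' @param top,cfg,start_xyz,ions,velocities As \code{\link{run_langevin}}.
#' @param window An \code{umbrella_window}.
#' @return A \code{cg_trajectory} with bias metadata.
#' @export
umbrella_run <- function(top, cfg, window, start_xyz = top$native_xyz,
                         ions = NULL, velocities = NULL) {
  stopifnot(inherits(window, "umbrella_window"))
  if (!is.null(window$n_steps)) cfg$n_steps <- as.integer(window$n_steps)
  if (is.null(ions)) ions <- place_ions(top, cfg$n_mg, seed = cfg$seed)
  bias <- if (window$k_q > 0) list(k_q = window$k_q, q0 = window$q0) else NULL
  .run_engine(top, cfg, start_xyz, ions, bias = bias,
              window_id = window$window_id)
}

#' Sequential umbrella window series along Q
#'
#' Runs the windows from the highest to the lowest target Q, seeding each
#' window's start from the final frame of the previous one (a slow-pulling
#' style protocol that keeps adjacent windows overlapping).
#'
#' @param top A \code{cg_topology}.
#' @param cfg A \code{sim_config}; each window w runs with seed
#'   \code{cfg$seed + w}.
#' @param q0 Vector of window targets.
#' @param k_q Spring constant (energy per Q^2).
#' @param equil_steps Per-window equilibration discarded before sampling.
#' @return List of \code{cg_trajectory}, ordered as \code{q0}.
#' @export
umbrella_series <- function(top, cfg, q0 = seq(0.1, 0.9, by = 0.1),
                            k_q = 200, equil_steps = 5000L) {
  ord <- order(q0, decreasing = TRUE)
  out <- vector("list", length(q0))
  start <- top$native_xyz
  ions <- place_ions(top, cfg$n_mg, seed = cfg$seed)
  for (w in seq_along(ord)) {
    iw <- ord[w]
    wcfg <- cfg
    wcfg$seed <- cfg$seed + iw
    win <- umbrella_window(q0[iw], k_q, window_id = iw)
    if (equil_steps > 0) {
      ecfg <- wcfg
      ecfg$n_steps <- as.integer(equil_steps)
      ecfg$save_interval <- as.integer(equil_steps)
      eq <- umbrella_run(top, ecfg, win, start_xyz = start, ions = ions)
      start <- eq$meta$final_x[seq_len(top$n_beads), , drop = FALSE]
      ions <- eq$meta$final_x[-seq_len(top$n_beads), , drop = FALSE]
      wcfg$seed <- wcfg$seed + 100000L
    }
    tr <- umbrella_run(top, wcfg, win, start_xyz = start, ions = ions)
    out[[iw]] <- tr
    start <- tr$meta$final_x[seq_len(top$n_beads), , drop = FALSE]
    ions <- tr$meta$final_x[-seq_len(top$n_beads), , drop = FALSE]
  }
  out
}
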