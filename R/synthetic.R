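# Synthetic reference structures. These are clearly-labelled stand-ins built
# from idealized geometry: a 52-nt solenoid-like compact fold whose sequence
# matches the residue identities of the SAM-II riboswitch at the positions
# the analyses refer to (G3..C29 of P1, G28/U38, the L3 adenines, ...), and a
# 12-nt hairpin used as the fast demo system. Neither is a crystal structure;
# they provide self-avoiding compact folds with nonlocal native contacts so
# that every downstream analysis has a well-defined ground truth.

.seq_riboswitch_52 <- function() {
  s <- rep(c("A", "C", "G", "U"), length.out = 52)
  fixed <- c(`3` = "G", `4` = "C", `5` = "G", `6` = "G", `7` = "C", `8` = "G",
             `12` = "U", `13` = "A", `14` = "A", `16` = "C", `17` = "G",
             `18` = "U", `27` = "C", `28` = "G", `29` = "C", `33` = "A",
             `35` = "A", `36` = "A", `37` = "A", `38` = "U", `39` = "G",
             `40` = "U", `41` = "A", `46` = "A", `47` = "A", `48` = "A",
             `50` = "G")
  s[as.integer(names(fixed))] <- fixed
  s
}

# Local frames along a solenoid: residues one turn apart stack on top of each
# other, giving nonlocal contacts (|i-j| = turn length) as in a compactly
# wound chain.
.frames_solenoid <- function(n, turn = 10L, rise = 6.5, spacing = 6.0) {
  radius <- spacing / (2 * sin(pi / turn))
  th <- 2 * pi * (seq_len(n) - 1) / turn
  z <- rise * (seq_len(n) - 1) / turn
  center <- cbind(radius * cos(th), radius * sin(th), z)
  u_r <- cbind(cos(th), sin(th), 0)
  u_t <- cbind(-sin(th), cos(th), 0)
  u_z <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  list(center = center, u_r = u_r, u_t = u_t, u_z = u_z)
}

# Hairpin: two antiparallel strands 9 A apart. u_r is the outward normal
# (same convention as the solenoid): bases sit at -2.5 u_r, pointing inward.
.frames_hairpin <- function(n = 12L, stem = 5L, rise = 6.0, gap = 9.0) {
  center <- matrix(NA_real_, n, 3)
  u_r <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (i <= stem) {                       # 5' strand, going up
      center[i, ] <- c(0, 0, (i - 1) * rise)
      u_r[i, ] <- c(-1, 0, 0)
    } else if (i > n - stem) {             # 3' strand, coming down
      center[i, ] <- c(gap, 0, (n - i) * rise)
      u_r[i, ] <- c(1, 0, 0)
    } else {                               # loop
      k <- i - stem
      center[i, ] <- c(gap / 2 + 4 * sin(pi * k / 3), 4 * cos(pi * k / 3),
                       stem * rise + 3.5)
      u_r[i, ] <- c(0, -1, 0)
    }
  }
  u_t <- matrix(rep(c(0, 1, 0), each = n), n, 3)
  u_z <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  list(center = center, u_r = u_r, u_t = u_t, u_z = u_z)
}

# Reduced atom set per residue: enough atoms in each of the three groups for
# the coarse-graining table to resolve P, sugar and base centers.
.build_atoms <- function(fr, seqv, source_id) {
  n <- nrow(fr$center)
  rows <- vector("list", n * 16L)
  k <- 0L
  add <- function(name, element, res, xyz) {
    k <<- k + 1L
    rows[[k]] <<- data.frame(name = name, element = element,
                             residue_index = res, residue_name = seqv[res],
                             chain_id = "A", resno_orig = res,
                             x = xyz[1], y = xyz[2], z = xyz[3],
                             stringsAsFactors = FALSE)
  }
  for (r in seq_len(n)) {
    c0 <- fr$center[r, ]; ur <- fr$u_r[r, ]; ut <- fr$u_t[r, ]
    uz <- fr$u_z[r, ]
    p_c <- c0 + 2.0 * ur          # phosphate outside
    s_c <- c0                     # sugar at the path
    b_c <- c0 - 2.5 * ur          # base inward
    if (r == 1L) {                # 5' terminus: no phosphate group
      add("O5'", "O", r, p_c)
      add("HO5'", "H", r, p_c + 0.4 * uz)
    } else {
      add("P", "P", r, p_c)
      add("OP1", "O", r, p_c + 0.8 * ut)
      add("OP2", "O", r, p_c - 0.8 * ut)
      add("O5'", "O", r, p_c + 0.6 * uz)
    }
    ring5 <- 0.7 * cbind(cos(2 * pi * (0:4) / 5), sin(2 * pi * (0:4) / 5))
    sn <- c("C1'", "C2'", "C3'", "C4'", "O4'")
    se <- c("C", "C", "C", "C", "O")
    for (a in 1:5)
      add(sn[a], se[a], r, s_c + ring5[a, 1] * ut + ring5[a, 2] * uz)
    add("C5'", "C", r, s_c + 0.9 * ur)
    add("O2'", "O", r, s_c - 0.6 * ur + 0.3 * ut)
    add("O3'", "O", r, s_c - 0.6 * ur - 0.3 * ut)
    purine <- seqv[r] %in% c("A", "G")
    ring6 <- 0.7 * cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6))
    bn <- c("N1", "C2", "N3", "C4", "C5", "C6")
    be <- c("N", "C", "N", "C", "C", "C")
    for (a in 1:6)
      add(bn[a], be[a], r, b_c + ring6[a, 1] * ut + ring6[a, 2] * ur)
    if (purine) {
      add("N7", "N", r, b_c - 1.2 * ur + 0.5 * ut)
      add("C8", "C", r, b_c - 1.5 * ur)
      add("N9", "N", r, b_c - 1.2 * ur - 0.5 * ut)
    } else {
      add("O2", "O", r, b_c + 1.2 * ur + 0.5 * ut)
    }
  }
  atoms <- do.call(rbind, rows[seq_len(k)])
  structure(list(atoms = atoms, het = NULL, source_id = source_id),
            class = "rna_structure")
}

#' Synthetic 52-nt riboswitch-like reference structure
#'
#' A programmatically generated, compact, self-avoiding 52-residue fold
#' (solenoid layout: residues one helical turn apart are in contact) whose
#' sequence carries the riboswitch residue identities at the positions used
#' in the analyses (for example G28 and U38, the P1 pairs G3-C29, C4-G28,
#' G5-C27, and the L3 adenines). It is a synthetic stand-in, not a crystal
#' structure: it exists so that native contacts, ion bridges and pair
#' annotations have an exactly known ground truth.
#' @return An \code{rna_structure}.
#' @export
synthetic_riboswitch <- function() {
  .build_atoms(.frames_solenoid(52L), .seq_riboswitch_52(),
               "synthetic-riboswitch-52nt")
}

#' Synthetic 12-nt hairpin (fast demo system)
#'
#' Five-pair stem plus a two-residue loop with idealized geometry; the small
#' bead count makes it the default fixture for end-to-end runs.
#' @return An \code{rna_structure}.
#' @export
synthetic_hairpin <- function() {
  seqv <- c("G", "G", "C", "G", "C", "U", "U", "G", "C", "G", "C", "C")
  .build_atoms(.frames_hairpin(12L), seqv, "synthetic-hairpin-12nt")
}

#' Annotation list for the synthetic riboswitch-like structure
#'
#' Base pairs between turn-adjacent residues of the solenoid fold plus
#' nearest-neighbour stacks. Labels are free-text placeholders.
#' @export
synthetic_riboswitch_annotations <- function() {
  i <- c(3:8, 16:20, 28:32)
  annotations(base_pairs = cbind(i, i + 10L),
              stacks = cbind(1:51, 2:52),
              classes = rep("cWW", length(i)), n_residues = 52L)
}

#' Annotation list for the synthetic hairpin
#' @export
synthetic_hairpin_annotations <- function() {
  annotations(base_pairs = cbind(1:5, 12:8),
              stacks = cbind(1:11, 2:12),
              classes = rep("cWW", 5L), n_residues = 12L)
}

#' Serialize an atomistic structure as PDB text
#' @param s An \code{rna_structure}.
#' @return Character vector of PDB lines.
#' @export
as_pdb_text <- function(s) {
  at <- s$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(at)), at$name, at$residue_name, at$chain_id,
    at$residue_index, at$x, at$y, at$z, at$element)
  c(lines, "END")
}

#' Self-avoiding extended-chain coordinates for a coarse-grained structure
#'
#' Residues laid out along a straight line, 6.5 A apart, with P/S/B offsets
#' perpendicular to the chain axis; every nonlocal native contact is broken.
#' @param cg A \code{cg_structure}.
#' @return Bead coordinate matrix matching \code{cg$xyz} in shape.
#' @export
extended_chain <- function(cg) {
  n <- cg$n_residues
  xyz <- matrix(NA_real_, 3L * n, 3)
  for (r in seq_len(n)) {
    x <- 6.5 * (r - 1)
    xyz[bead_index(r, "P"), ] <- c(x, -2.0, 0)
    xyz[bead_index(r, "S"), ] <- c(x, 0, 0)
    xyz[bead_index(r, "B"), ] <- c(x, 2.5, 0)
  }
  xyz
}

# Deterministic bridging-ion position: near both target phosphates but, if
# geometrically possible, outside the cutoff of every other phosphate, so
# the designed bridge is the unique ground-truth signal. Starting from the
# pair midpoint, the point is pushed outward (away from the phosphate
# centroid) until only the target pair remains within the cutoff.
.bridge_position <- function(xyz, pair, cutoff = 8) {
  n_res <- nrow(xyz) / 3L
  p_idx <- bead_index(seq_len(n_res), "P")
  P <- xyz[p_idx, , drop = FALSE]
  mid <- (P[pair[1], ] + P[pair[2], ]) / 2
  outward <- mid - colMeans(P)
  nrm <- sqrt(sum(outward^2))
  if (nrm < 1e-9) return(mid)
  outward <- outward / nrm
  others <- setdiff(seq_len(n_res), pair)
  for (t in seq(0, 6, by = 0.25)) {
    cand <- mid + t * outward
    d <- sqrt(rowSums((P - matrix(cand, n_res, 3, byrow = TRUE))^2))
    if (all(d[pair] < cutoff) && all(d[others] >= cutoff)) return(cand)
  }
  mid
}

#' Morph ensemble: scripted unfolded-to-native fixture trajectories
#'
#' Interpolates linearly between the native structure and a self-avoiding
#' extended chain along the frame index, adding Gaussian coordinate noise.
#' Frame f uses unfolding parameter u_f = unfold_fraction * (f-1)/(n-1), so
#' the ensemble traces a morph path from the native state (u = 0) to the
#' requested unfolding level. Optional scripted ions provide designed ground
#' truth for the ion analytics: a persistent "bridging" ion placed at the
#' midpoint of two chosen phosphates in a chosen fraction of frames, and
#' "site" ions parked next to chosen phosphates only in frames whose
#' fraction of native contacts exceeds a threshold.
#'
#' @param cg Native \code{cg_structure}.
#' @param n_frames Number of frames.
#' @param unfold_fraction Final unfolding level in [0, 1].
#' @param noise Gaussian coordinate noise s.d. in Angstrom.
#' @param seed RNG seed (frame noise, ion placement, bridge occupancy).
#' @param n_ions Number of free ions placed uniformly in the box per frame.
#' @param box_edge Periodic box edge (Angstrom).
#' @param bridge Optional \code{list(pair = c(res_i, res_j), fraction = p)}:
#'   one extra ion bridges the two residues' P beads in a Bernoulli(p)
#'   subset of frames and wanders in the box otherwise.
#' @param sites Optional \code{list(residues =, q_min =, contacts =,
#'   lambda = 1.2)}: one extra ion per listed residue sits 1.5 A from that
#'   residue's P bead whenever the frame's hard Q exceeds \code{q_min}.
#' @return A \code{cg_trajectory}; per-frame hard Q is stored in
#'   \code{meta$q_hard} when \code{sites} supplies a contact set.
#' @export
morph_ensemble <- function(cg, n_frames, unfold_fraction = 1, noise = 0,
                           seed = 1L, n_ions = 0L, box_edge = 150,
                           bridge = NULL, sites = NULL) {
  stopifnot(n_frames >= 1, unfold_fraction >= 0, unfold_fraction <= 1)
  set.seed(seed)
  nat <- cg$xyz
  ext <- extended_chain(cg)
  nb <- nrow(nat)
  u <- if (n_frames == 1L) unfold_fraction else
    unfold_fraction * (seq_len(n_frames) - 1) / (n_frames - 1)
  rna <- array(NA_real_, c(n_frames, nb, 3))
  for (f in seq_len(n_frames)) {
    x <- (1 - u[f]) * nat + u[f] * ext
    if (noise > 0) x <- x + matrix(rnorm(nb * 3, sd = noise), nb, 3)
    rna[f, , ] <- x
  }
  n_extra <- (!is.null(bridge)) + if (is.null(sites)) 0L else
    length(sites$residues)
  n_tot <- n_ions + n_extra
  ions <- NULL
  q_hard <- NULL
  if (!is.null(sites) || !is.null(bridge)) {
    cset <- if (!is.null(sites)) sites$contacts else NULL
  }
  if (!is.null(sites)) {
    lam <- if (is.null(sites$lambda)) 1.2 else sites$lambda
    q_hard <- vapply(seq_len(n_frames), function(f)
      fraction_native(rna[f, , ], sites$contacts, lambda = lam), 1.0)
  }
  if (n_tot > 0L) {
    ions <- array(runif(n_frames * n_tot * 3, -box_edge / 2, box_edge / 2),
                  c(n_frames, n_tot, 3))
    idx <- n_ions
    if (!is.null(bridge)) {
      idx <- idx + 1L
      on <- runif(n_frames) < bridge$fraction
      cutoff <- bridge$cutoff %||% 8
      for (f in which(on))
        ions[f, idx, ] <- .bridge_position(rna[f, , ], bridge$pair, cutoff)
      attr(ions, "bridge_frames") <- which(on)
    }
    if (!is.null(sites)) {
      for (k in seq_along(sites$residues)) {
        idx <- idx + 1L
        pb <- bead_index(sites$residues[k], "P")
        for (f in which(q_hard > sites$q_min))
          ions[f, idx, ] <- rna[f, pb, ] + c(1.5, 0, 0)
      }
    }
  }
  new_trajectory(rna, ions, box_edge, steps = seq_len(n_frames),
                 seed = seed,
                 meta = list(u = u, q_hard = q_hard,
                             generator = "morph_ensemble"))
}
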