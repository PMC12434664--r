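# Ion-coordination analytics: Mg-phosphate RDF, per-phosphate occupancy
# along Q, ion-mediated bridging maps, and excess-ion counts.

# Minimum-image displacement distances between one set of points and ions.
.min_image_dist <- function(a, b, box) {
  # a: n x 3, b: m x 3 -> n x m distances
  out <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    d <- outer(a[, k], b[, k], "-")
    if (is.finite(box) && box > 0) d <- d - box * round(d / box)
    out <- out + d * d
  }
  sqrt(out)
}

p_bead_matrix <- function(traj, frame) {
  nb <- dim(traj$rna)[2]
  stopifnot(nb %% 3L == 0L)
  frame_xyz(traj, frame)[seq(1L, nb, by = 3L), , drop = FALSE]
}

#' Radial distribution function of ions around phosphate beads
#'
#' Shell-normalized g(r) of the ion density around P beads, against the
#' ideal-gas density of the same number of ions in the periodic box. The
#' first minimum after the first peak of the (running-mean smoothed) g(r) is
#' reported: it is the default coordination cutoff used downstream when none
#' is given, mirroring the practice of reading the coordination cutoff off
#' the radial distribution function.
#'
#' @param traj A \code{cg_trajectory} with ions.
#' @param bin_width Histogram bin width in Angstrom.
#' @param r_max Histogram range (default: min(box/2, 30)).
#' @return Object of class \code{ion_rdf}: data.frame \code{r}, \code{g};
#'   plus \code{bin_width}, \code{n_frames}, \code{first_minimum}.
#' @export
rdf_mg_phosphate <- function(traj, bin_width = 0.25, r_max = NULL) {
  if (is.null(traj$ions) || dim(traj$ions)[2] == 0L)
    stop("trajectory has no ions")
  box <- traj$box_edge
  if (is.null(r_max))
    r_max <- min(if (is.finite(box)) box / 2 else Inf, 30)
  edges <- seq(0, r_max, by = bin_width)
  counts <- numeric(length(edges) - 1L)
  nf <- n_frames(traj)
  ni <- dim(traj$ions)[2]
  np <- dim(traj$rna)[2] / 3L
  for (f in seq_len(nf)) {
    d <- .min_image_dist(p_bead_matrix(traj, f), ion_xyz(traj, f), box)
    dv <- d[d < r_max]
    if (length(dv))
      counts <- counts + tabulate(pmin(floor(dv / bin_width) + 1L,
                                       length(counts)), length(counts))
  }
  r_mid <- (edges[-1] + edges[-length(edges)]) / 2
  rho <- ni / box^3
  shell_v <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  g <- counts / (nf * np * shell_v * rho)
  # running-mean smoothing before locating the first peak / first minimum
  k <- 5L
  gs <- stats::filter(g, rep(1 / k, k), sides = 2)
  gs[is.na(gs)] <- g[is.na(gs)]
  pk <- which.max(gs)
  fm <- NA_real_
  if (pk < length(gs)) {
    after <- as.numeric(gs[(pk + 1):length(gs)])
    loc <- which(diff(after) >= 0)   # first upturn ends the descent
    fm_idx <- pk + (if (length(loc)) loc[1] else length(after))
    fm <- r_mid[fm_idx]
  }
  structure(list(rdf = data.frame(r = r_mid, g = g), bin_width = bin_width,
                 n_frames = nf, first_minimum = fm),
            class = "ion_rdf")
}

#' @export
print.ion_rdf <- function(x, ...) {
  cat("<ion_rdf> ", nrow(x$rdf), " bins of ", x$bin_width, " A over ",
      x$n_frames, " frames; first minimum ~", round(x$first_minimum, 2),
      " A\n", sep = "")
  invisible(x)
}

#' Per-frame, per-phosphate ion occupancy counts
#'
#' Number of ions strictly within \code{cutoff} of each residue's P bead
#' (minimum-image convention; ties at exactly the cutoff are excluded). An
#' ion within the cutoff of two phosphates counts once for each.
#'
#' @param traj A \code{cg_trajectory} with ions.
#' @param cutoff Distance cutoff in Angstrom (default 8, the coordination
#'   shell radius read off the radial distribution function).
#' @return Integer matrix (frames x residues).
#' @export
occupancy <- function(traj, cutoff = 8) {
  stopifnot(cutoff > 0)
  nf <- n_frames(traj)
  np <- dim(traj$rna)[2] / 3L
  out <- matrix(0L, nf, np)
  if (is.null(traj$ions) || dim(traj$ions)[2] == 0L) return(out)
  for (f in seq_len(nf)) {
    d <- .min_image_dist(p_bead_matrix(traj, f), ion_xyz(traj, f),
                         traj$box_edge)
    out[f, ] <- as.integer(rowSums(d < cutoff))
  }
  out
}

#' Mean ion occupancy per phosphate, binned along Q
#'
#' Frames are binned by Q (default bin width 0.05, bins [k w, (k+1) w) with
#' Q = 1 assigned to the top bin); each cell is the mean ion count for that
#' residue over the bin's frames. Bins without frames are NA, not zero.
#'
#' @param counts Occupancy matrix from \code{occupancy()}.
#' @param q Per-frame Q vector aligned with \code{counts} rows.
#' @param bin_width Q bin width.
#' @return Object of class \code{occupancy_heatmap}: \code{matrix}
#'   (Q-bin x residue), \code{q_breaks}, \code{frames_per_bin},
#'   \code{bin_width}.
#' @export
occupancy_vs_q <- function(counts, q, bin_width = 0.05) {
  if (nrow(counts) != length(q))
    stop("counts and q have mismatched lengths")
  stopifnot(bin_width > 0)
  nbin <- ceiling(1 / bin_width)
  bin <- pmin(floor(as.numeric(q) / bin_width) + 1L, nbin)
  m <- matrix(NA_real_, nbin, ncol(counts))
  npb <- integer(nbin)
  for (b in seq_len(nbin)) {
    sel <- bin == b
    npb[b] <- sum(sel)
    if (npb[b] > 0) m[b, ] <- colMeans(counts[sel, , drop = FALSE])
  }
  rownames(m) <- sprintf("Q[%.2f,%.2f)", (seq_len(nbin) - 1) * bin_width,
                         pmin(seq_len(nbin) * bin_width, 1))
  colnames(m) <- paste0("res", seq_len(ncol(counts)))
  structure(list(matrix = m, frames_per_bin = npb, bin_width = bin_width),
            class = "occupancy_heatmap")
}

#' Ion-mediated bridging probability map between nonlocal phosphates
#'
#' P(i, j) is the fraction of frames in which at least one ion is
#' simultaneously strictly within \code{cutoff} of phosphate i and phosphate
#' j, for residue pairs at least \code{min_sep} apart; the near-diagonal
#' band is zeroed.
#'
#' @param traj A \code{cg_trajectory} with ions.
#' @param cutoff Distance cutoff in Angstrom.
#' @param min_sep Minimum residue separation defining "nonlocal" (default 4).
#' @return Object of class \code{bridge_map}: symmetric probability
#'   \code{matrix}, \code{cutoff}, \code{min_sep}, \code{n_frames}.
#' @export
bridging_map <- function(traj, cutoff = 8, min_sep = 4L) {
  stopifnot(min_sep >= 1L)
  nf <- n_frames(traj)
  np <- dim(traj$rna)[2] / 3L
  acc <- matrix(0, np, np)
  if (!is.null(traj$ions) && dim(traj$ions)[2] > 0L) {
    for (f in seq_len(nf)) {
      within <- .min_image_dist(p_bead_matrix(traj, f), ion_xyz(traj, f),
                                traj$box_edge) < cutoff
      shared <- within %*% t(within)      # common-ion counts
      acc <- acc + (shared > 0)
    }
  }
  p <- acc / nf
  sep <- abs(outer(seq_len(np), seq_len(np), "-"))
  p[sep < min_sep] <- 0
  dimnames(p) <- list(paste0("res", seq_len(np)), paste0("res", seq_len(np)))
  structure(list(matrix = p, cutoff = cutoff, min_sep = min_sep,
                 n_frames = nf),
            class = "bridge_map")
}

#' Top-ranked cell of a bridging map
#' @param bm A \code{bridge_map}.
#' @return List: \code{res_i}, \code{res_j} (res_i < res_j), \code{p}.
#' @export
top_bridge <- function(bm) {
  m <- bm$matrix
  k <- which.max(m)
  ij <- arrayInd(k, dim(m))
  list(res_i = min(ij), res_j = max(ij), p = m[k])
}

#' Excess ions near the phosphate backbone, per conformational state
#'
#' Counts distinct ions strictly within \code{cutoff} of any phosphate and
#' subtracts the ideal-bulk expectation for the same interrogated volume
#' (the union of the phosphate-centered spheres, estimated by seeded Monte
#' Carlo on each analyzed frame). Reported separately for folded
#' (Q >= q_folded) and unfolded (Q < q_unfolded) frames.
#'
#' @param traj A \code{cg_trajectory} with ions.
#' @param q Per-frame Q vector.
#' @param cutoff Shell radius (Angstrom).
#' @param q_folded,q_unfolded State thresholds on Q (defaults 0.85, 0.4).
#' @param mc_samples Monte Carlo samples per frame for the union volume.
#' @param seed Seed for the volume estimate.
#' @return data.frame with one row per state: n_frames, mean_ions_shell,
#'   expected_bulk, excess.
#' @export
excess_ions <- function(traj, q, cutoff = 8, q_folded = 0.85,
                        q_unfolded = 0.4, mc_samples = 4000L, seed = 1L) {
  stopifnot(n_frames(traj) == length(q))
  set.seed(seed)
  rho <- dim(traj$ions)[2] / traj$box_edge^3
  states <- list(folded = which(q >= q_folded),
                 unfolded = which(q < q_unfolded))
  rows <- lapply(names(states), function(s) {
    fr <- states[[s]]
    if (length(fr) == 0L)
      return(data.frame(state = s, n_frames = 0L, mean_ions_shell = NA_real_,
                        expected_bulk = NA_real_, excess = NA_real_))
    nin <- vol <- numeric(length(fr))
    for (k in seq_along(fr)) {
      f <- fr[k]
      P <- p_bead_matrix(traj, f)
      d <- .min_image_dist(P, ion_xyz(traj, f), traj$box_edge)
      nin[k] <- sum(apply(d < cutoff, 2, any))
      # MC union volume inside the bounding box of the spheres
      lo <- apply(P, 2, min) - cutoff; hi <- apply(P, 2, max) + cutoff
      pts <- cbind(runif(mc_samples, lo[1], hi[1]),
                   runif(mc_samples, lo[2], hi[2]),
                   runif(mc_samples, lo[3], hi[3]))
      dd <- .min_image_dist(P, pts, Inf)
      vol[k] <- prod(hi - lo) * mean(apply(dd < cutoff, 2, any))
    }
    data.frame(state = s, n_frames = length(fr),
               mean_ions_shell = mean(nin),
               expected_bulk = rho * mean(vol),
               excess = mean(nin) - rho * mean(vol))
  })
  do.call(rbind, rows)
}

#' Write a labelled matrix (heatmap / bridge map) as TSV
#' @param x An \code{occupancy_heatmap}, \code{bridge_map} or plain matrix.
#' @param path Output file.
#' @export
write_matrix_tsv <- function(x, path) {
  m <- if (is.list(x) && !is.null(x$matrix)) x$matrix else x
  write.table(cbind(row = rownames(m) %||% seq_len(nrow(m)), as.data.frame(m)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an RDF as two-column TSV
#' @param rdf An \code{ion_rdf}; \code{path} output file.
#' @export
write_rdf_tsv <- function(rdf, path) {
  write.table(rdf$rdf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
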