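# Trajectory container shared by the simulator, the morph generator and all
# downstream analytics. RNA coordinates are kept whole (never wrapped); ion
# coordinates live inside the periodic box.

new_trajectory <- function(rna, ions = NULL, box_edge = NA_real_,
                           steps = NULL, q_smooth = NULL, bias_energy = NULL,
                           window_id = NA_integer_, seed = NA_integer_,
                           meta = list()) {
  stopifnot(length(dim(rna)) == 3L)
  if (!is.null(ions)) stopifnot(dim(ions)[1] == dim(rna)[1])
  if (is.null(steps)) steps <- seq_len(dim(rna)[1])
  structure(list(rna = rna, ions = ions, box_edge = box_edge, steps = steps,
                 q_smooth = q_smooth, bias_energy = bias_energy,
                 window_id = window_id, seed = seed, meta = meta),
            class = "cg_trajectory")
}

#' Number of frames in a trajectory
#' @param traj A \code{cg_trajectory}.
#' @export
n_frames <- function(traj) dim(traj$rna)[1]

#' Extract one frame's RNA bead coordinates
#' @param traj A \code{cg_trajectory}.
#' @param i Frame index.
#' @return Numeric matrix (beads x 3).
#' @export
frame_xyz <- function(traj, i) {
  x <- traj$rna[i, , , drop = FALSE]
  dim(x) <- dim(traj$rna)[2:3]
  x
}

#' Extract one frame's ion coordinates
#' @param traj A \code{cg_trajectory}.
#' @param i Frame index.
#' @export
ion_xyz <- function(traj, i) {
  if (is.null(traj$ions) || dim(traj$ions)[2] == 0L)
    return(matrix(numeric(), 0, 3))
  x <- traj$ions[i, , , drop = FALSE]
  dim(x) <- dim(traj$ions)[2:3]
  x
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory> ", n_frames(x), " frames, ", dim(x$rna)[2], " beads, ",
      if (is.null(x$ions)) 0L else dim(x$ions)[2], " ions, box ",
      x$box_edge, " A\n", sep = "")
  invisible(x)
}

#' Write trajectory coordinates in the package's fixed binary layout
#'
#' Layout (little-endian): header int64 c(n_frames, n_beads, n_ions), then a
#' float64 box edge, then per frame: int64 step, float32 RNA xyz
#' (bead-major), float32 ion xyz.
#' @param traj A \code{cg_trajectory}.
#' @param path Output file.
#' @export
write_traj_bin <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj); nb <- dim(traj$rna)[2]
  ni <- if (is.null(traj$ions)) 0L else dim(traj$ions)[2]
  writeBin(as.integer(c(nf, nb, ni)), con, size = 8, endian = "little")
  writeBin(as.double(traj$box_edge), con, size = 8, endian = "little")
  for (f in seq_len(nf)) {
    writeBin(as.integer(traj$steps[f]), con, size = 8, endian = "little")
    writeBin(as.vector(t(frame_xyz(traj, f))), con, size = 4,
             endian = "little")
    if (ni > 0)
      writeBin(as.vector(t(ion_xyz(traj, f))), con, size = 4,
               endian = "little")
  }
  invisible(path)
}

#' Read a trajectory written by \code{write_traj_bin}
#' @param path Binary coordinate file.
#' @export
read_traj_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", 3, size = 8, endian = "little")
  box <- readBin(con, "double", 1, size = 8, endian = "little")
  nf <- hdr[1]; nb <- hdr[2]; ni <- hdr[3]
  rna <- array(NA_real_, c(nf, nb, 3))
  ions <- if (ni > 0) array(NA_real_, c(nf, ni, 3)) else NULL
  steps <- integer(nf)
  for (f in seq_len(nf)) {
    steps[f] <- readBin(con, "integer", 1, size = 8, endian = "little")
    x <- readBin(con, "double", nb * 3, size = 4, endian = "little")
    rna[f, , ] <- matrix(x, nb, 3, byrow = TRUE)
    if (ni > 0) {
      x <- readBin(con, "double", ni * 3, size = 4, endian = "little")
      ions[f, , ] <- matrix(x, ni, 3, byrow = TRUE)
    }
  }
  new_trajectory(rna, ions, box, steps)
}

#' Write the per-frame Q / bias log as TSV
#' @param traj A \code{cg_trajectory} with \code{q_smooth}/\code{bias_energy}.
#' @param q_hard Optional vector of hard-Q values aligned with frames.
#' @param path Output file.
#' @export
write_q_log <- function(traj, path, q_hard = NULL) {
  d <- data.frame(step = traj$steps)
  d$Q_hard <- if (!is.null(q_hard)) q_hard else NA_real_
  d$Q_smooth <- if (!is.null(traj$q_smooth)) traj$q_smooth else NA_real_
  d$bias_energy <- if (!is.null(traj$bias_energy)) traj$bias_energy else NA_real_
  d$window_id <- traj$window_id
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Concatenate trajectories that share geometry
#'
#' Frames are stacked in order; bead and ion counts and the box edge must
#' match across inputs. Bias metadata is carried through per frame.
#' @param trajs List of \code{cg_trajectory} objects.
#' @return A single \code{cg_trajectory}.
#' @export
bind_trajectories <- function(trajs) {
  rna <- do.call(abind3, lapply(trajs, `[[`, "rna"))
  ions <- if (is.null(trajs[[1]]$ions)) NULL else
    do.call(abind3, lapply(trajs, `[[`, "ions"))
  new_trajectory(rna, ions, trajs[[1]]$box_edge,
                 steps = unlist(lapply(trajs, `[[`, "steps")),
                 q_smooth = unlist(lapply(trajs, `[[`, "q_smooth")),
                 bias_energy = unlist(lapply(trajs, `[[`, "bias_energy")))
}

abind3 <- function(...) {
  xs <- list(...)
  n <- sum(vapply(xs, function(x) dim(x)[1], 1L))
  out <- array(NA_real_, c(n, dim(xs[[1]])[2], 3))
  at <- 0L
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}
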