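# Reaction coordinates and structural metrics.

#' Fraction of native contacts Q
#'
#' A native contact (i, j) counts as formed in a frame when its distance is
#' strictly below \code{lambda} times the native distance; Q is the formed
#' fraction over the whole contact set. This hard-count Q is the reporting
#' coordinate throughout; the differentiable variant used for umbrella
#' biasing lives in the simulator.
#'
#' @param xyz Bead coordinate matrix (beads x 3).
#' @param nc A \code{native_contacts} set.
#' @param lambda Formation threshold as a multiple of the native distance
#'   (default 1.2, the standard structure-based-model convention).
#' @return Q in [0, 1].
#' @export
fraction_native <- function(xyz, nc, lambda = 1.2) {
  p <- nc$pairs
  if (nrow(p) == 0L) stop("empty native contact set")
  stopifnot(max(p$j) <= nrow(xyz))
  d <- sqrt(rowSums((xyz[p$i, , drop = FALSE] - xyz[p$j, , drop = FALSE])^2))
  mean(d < lambda * p$r_native)
}

#' Per-frame Q series over a trajectory
#' @param traj A \code{cg_trajectory}.
#' @param nc Native contact set.
#' @param lambda Formation threshold multiplier.
#' @return Object of class \code{q_series}: numeric vector with metadata
#'   attributes \code{lambda} and \code{contact_id}.
#' @export
q_trajectory <- function(traj, nc, lambda = 1.2) {
  q <- vapply(seq_len(n_frames(traj)),
              function(f) fraction_native(frame_xyz(traj, f), nc, lambda),
              1.0)
  structure(q, lambda = lambda,
            contact_id = paste0("cutoff", nc$cutoff_used, "_sep", nc$min_sep),
            class = c("q_series", "numeric"))
}

#' Write a Q series as TSV (frame_index, Q)
#' @param q Numeric Q vector.
#' @param path Output file.
#' @export
write_q_series <- function(q, path) {
  write.table(data.frame(frame_index = seq_along(q), Q = as.numeric(q)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Root-mean-square deviation after optimal superposition
#'
#' Kabsch algorithm: both frames are centered, the optimal rotation is taken
#' from the SVD of the covariance matrix (with the determinant correction
#' against improper rotations), and the RMSD of the superposed coordinates
#' is returned.
#' @param a,b Coordinate matrices (beads x 3) with equal bead counts.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  if (nrow(a) < 3L) stop("rmsd needs at least 3 beads")
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(ac, bc))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((ac %*% rot - bc)^2)))
}

#' Distance RMSD (superposition-free)
#'
#' Root mean square difference over all bead pairs i < j of the internal
#' distances of the two conformations; invariant under rigid-body motion of
#' either frame by construction.
#' @param a,b Coordinate matrices (beads x 3).
#' @return dRMSD in Angstrom.
#' @export
drmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  if (nrow(a) < 2L) stop("drmsd needs at least 2 beads")
  da <- dist(a); db <- dist(b)
  sqrt(mean((da - db)^2))
}

# Pairwise dRMSD matrix over a set of frames (frames: list of matrices or a
# trajectory); used by the local-signature machinery.
drmsd_matrix <- function(frames) {
  dv <- lapply(frames, function(x) as.vector(dist(x)))
  n <- length(dv)
  m <- matrix(0, n, n)
  for (k in seq_len(n - 1)) for (l in (k + 1):n) {
    v <- sqrt(mean((dv[[k]] - dv[[l]])^2))
    m[k, l] <- v; m[l, k] <- v
  }
  m
}

frames_as_list <- function(traj) {
  if (inherits(traj, "cg_trajectory"))
    lapply(seq_len(n_frames(traj)), function(f) frame_xyz(traj, f))
  else traj
}
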