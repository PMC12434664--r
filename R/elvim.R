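# Energy-landscape visualization: Q_w dissimilarity, force-scheme projection,
# Gaussian KDE density, region handling and local conformational signatures.

#' Bead-pair set and sequence-dependent widths for the Q_w dissimilarity
#'
#' The pair set is every bead pair on different residues (|delta n| >= 1);
#' intra-residue pairs are excluded because the width rule
#' sigma_ij = sigma0 * |delta n|^eps vanishes at delta n = 0.
#'
#' @param residue_index Residue index per bead.
#' @param sigma0 Similarity resolution in Angstrom (default 3).
#' @param eps Sequence-distance exponent (default 0.15).
#' @return List with integer pair indices \code{i}, \code{j} and the width
#'   vector \code{sigma}.
#' @export
qw_pair_set <- function(residue_index, sigma0 = 3, eps = 0.15) {
  stopifnot(sigma0 > 0)
  n <- length(residue_index)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dn <- abs(residue_index[ij[, 1]] - residue_index[ij[, 2]])
  keep <- dn >= 1L
  if (!any(keep)) stop("empty pair set: all beads share one residue")
  list(i = ij[keep, 1], j = ij[keep, 2],
       sigma = sigma0 * dn[keep]^eps)
}

#' Sequence-dependent Gaussian width sigma_ij
#' @param dn Absolute residue-index separation |delta n|.
#' @param sigma0,eps Width rule parameters.
#' @export
qw_sigma <- function(dn, sigma0 = 3, eps = 0.15) sigma0 * abs(dn)^eps

.pair_dists <- function(xyz, ps) {
  sqrt(rowSums((xyz[ps$i, , drop = FALSE] - xyz[ps$j, , drop = FALSE])^2))
}

#' Q_w structural dissimilarity between two conformations
#'
#' q_w is the mean over the included bead pairs of
#' exp(-(r_ij_k - r_ij_l)^2 / (2 sigma_ij^2)); the dissimilarity is
#' delta = 1 - q_w, zero for identical conformations and approaching one for
#' highly dissimilar ones. Depends only on internal distances, hence is
#' invariant under rigid-body motion of either frame.
#'
#' @param a,b Bead coordinate matrices (beads x 3).
#' @param residue_index Residue index per bead.
#' @param sigma0,eps Width rule parameters.
#' @param pair_set Optional precomputed \code{qw_pair_set}.
#' @return delta in [0, 1].
#' @export
qw_dissimilarity <- function(a, b, residue_index, sigma0 = 3, eps = 0.15,
                             pair_set = NULL) {
  stopifnot(nrow(a) == nrow(b))
  ps <- if (is.null(pair_set)) qw_pair_set(residue_index, sigma0, eps)
        else pair_set
  ra <- .pair_dists(a, ps); rb <- .pair_dists(b, ps)
  1 - mean(exp(-(ra - rb)^2 / (2 * ps$sigma^2)))
}

#' Pairwise Q_w dissimilarity matrix over an ensemble
#'
#' Computes internal pair distances once per frame, then fills the symmetric
#' matrix; the result is independent of evaluation order.
#'
#' @param frames A \code{cg_trajectory} or list of coordinate matrices.
#' @param residue_index Residue index per bead (taken from
#'   \code{attr(frames, "residue_index")} or given explicitly).
#' @param sigma0,eps Width rule parameters.
#' @return Object of class \code{dissimilarity_matrix}: the n x n matrix with
#'   attributes \code{sigma0}, \code{eps}, \code{frame_ids}.
#' @export
dissimilarity_matrix <- function(frames, residue_index, sigma0 = 3,
                                 eps = 0.15) {
  fl <- frames_as_list(frames)
  if (length(fl) < 2L) stop("need at least 2 frames")
  nb <- vapply(fl, nrow, 1L)
  if (length(unique(nb)) != 1L)
    stop("inconsistent bead counts across frames: ",
         paste(unique(nb), collapse = ", "))
  ps <- qw_pair_set(residue_index, sigma0, eps)
  n <- length(fl)
  D <- matrix(NA_real_, n, length(ps$i))
  for (f in seq_len(n)) D[f, ] <- .pair_dists(fl[[f]], ps)
  inv2s2 <- 1 / (2 * ps$sigma^2)
  out <- matrix(0, n, n)
  for (k in seq_len(n - 1)) {
    dk <- D[k, ]
    for (l in (k + 1):n) {
      v <- 1 - mean(exp(-(dk - D[l, ])^2 * inv2s2))
      out[k, l] <- v; out[l, k] <- v
    }
  }
  structure(out, sigma0 = sigma0, eps = eps,
            frame_ids = seq_len(n), class = c("dissimilarity_matrix",
                                              "matrix", "array"))
}

#' Force-scheme 2D projection of a dissimilarity matrix
#'
#' Points start at seeded random 2D positions. Each iteration visits every
#' point once as a pivot (pivot order reshuffled per iteration) and moves all
#' other points along the pivot-to-point direction by
#' \code{step_fraction * (delta_target - d_current)}. Dissimilarities are
#' scaled by their maximum before projection so targets live on the same
#' scale as the embedding. Normalized stress sum((delta - d)^2) / sum(delta^2)
#' is recorded each iteration.
#'
#' @param D Dissimilarity matrix (square, symmetric, zero diagonal).
#' @param n_iter Number of sweeps (default 100).
#' @param step_fraction Move fraction per update (default 1/8).
#' @param seed RNG seed for the initial layout and pivot shuffles.
#' @return Object of class \code{elvim_embedding}: \code{points} (n x 2),
#'   \code{stress} (per-iteration trace), \code{n_iter}, \code{seed}.
#' @export
force_scheme <- function(D, n_iter = 100L, step_fraction = 1 / 8,
                         seed = 1L) {
  if (n_iter < 1L) stop("n_iter must be >= 1")
  D <- unclass(D)
  n <- nrow(D)
  dmax <- max(D)
  Dt <- if (dmax > 0) D / dmax else D
  set.seed(seed)
  X <- matrix(runif(2L * n), n, 2)
  stress <- numeric(n_iter)
  eps0 <- 1e-9
  for (it in seq_len(n_iter)) {
    for (p in sample.int(n)) {
      v <- sweep(X, 2, X[p, ])           # pivot -> point vectors
      d <- sqrt(rowSums(v * v))
      d[p] <- 1                          # pivot skips itself
      mv <- step_fraction * (Dt[, p] - d) / pmax(d, eps0)
      mv[p] <- 0
      X <- X + v * mv
    }
    dcur <- as.matrix(dist(X))
    stress[it] <- sum((Dt - dcur)^2) / sum(Dt^2 + (sum(Dt) == 0))
  }
  structure(list(points = X, stress = stress, n_iter = n_iter, seed = seed,
                 scale = dmax),
            class = "elvim_embedding")
}

#' @export
print.elvim_embedding <- function(x, ...) {
  cat("<elvim_embedding> ", nrow(x$points), " points, ", x$n_iter,
      " iterations, final stress ", signif(tail(x$stress, 1), 4), "\n",
      sep = "")
  invisible(x)
}

#' Gaussian kernel density at the embedded points
#'
#' Product Gaussian kernel with per-axis Scott's-rule bandwidths
#' h_j = sd_j * n^(-1/6); the density is evaluated at every sample point
#' (self term included) and integrates to one over the plane.
#'
#' @param points n x 2 coordinate matrix (or an \code{elvim_embedding}).
#' @return Numeric density vector, one value per point.
#' @export
kde_density <- function(points) {
  if (inherits(points, "elvim_embedding")) points <- points$points
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points")
  h <- apply(points, 2, sd) * n^(-1 / 6)
  if (any(h <= 0) || any(!is.finite(h)))
    stop("degenerate point set: zero spread on an axis")
  kde_at(points, points, h)
}

# Evaluate the same KDE at arbitrary query points.
kde_at <- function(points, query, h) {
  n <- nrow(points)
  dx <- outer(query[, 1], points[, 1], "-") / h[1]
  dy <- outer(query[, 2], points[, 2], "-") / h[2]
  rowSums(exp(-0.5 * (dx^2 + dy^2))) / (n * 2 * pi * h[1] * h[2])
}

#' Select embedded points inside a polygon region
#'
#' Ray-casting point-in-polygon test; the programmatic replacement for
#' manual lasso selection on the projection.
#' @param points n x 2 matrix or \code{elvim_embedding}.
#' @param polygon m x 2 matrix of vertices (closed implicitly).
#' @param label Free-text region label.
#' @return Object of class \code{elvim_region}: \code{idx}, \code{label}.
#' @export
region_polygon <- function(points, polygon, label = "region") {
  if (inherits(points, "elvim_embedding")) points <- points$points
  px <- polygon[, 1]; py <- polygon[, 2]
  m <- length(px)
  inside <- rep(FALSE, nrow(points))
  j <- m
  for (i in seq_len(m)) {
    cross <- (py[i] > points[, 2]) != (py[j] > points[, 2])
    xi <- (px[j] - px[i]) * (points[, 2] - py[i]) / (py[j] - py[i]) + px[i]
    inside <- xor(inside, cross & points[, 1] < xi)
    j <- i
  }
  idx <- which(inside)
  if (length(idx) == 0L) stop("region is empty")
  structure(list(idx = idx, label = label), class = "elvim_region")
}

#' Select a region by density threshold
#' @param density Per-point density vector.
#' @param quantile_min Keep points at or above this density quantile.
#' @param label Region label.
#' @export
region_density <- function(density, quantile_min = 0.75, label = "basin") {
  thr <- quantile(density, quantile_min)
  idx <- which(density >= thr)
  structure(list(idx = idx, label = label), class = "elvim_region")
}

#' Local conformational signature of a landscape region
#'
#' Within the region, computes the pairwise dRMSD matrix, takes as centroid
#' the frame minimizing the mean dRMSD to all other member frames (ties
#' broken by lowest frame index), and returns its m nearest neighbours by
#' dRMSD.
#'
#' @param region An \code{elvim_region} (or integer frame indices).
#' @param frames A \code{cg_trajectory} or list of coordinate matrices.
#' @param n_neighbors Number of neighbour frames to return (default 5).
#' @return List: \code{centroid} (frame index), \code{neighbors},
#'   \code{mean_drmsd} (centroid's mean dRMSD to other members),
#'   \code{drmsd} (the region's dRMSD matrix).
#' @export
local_signature <- function(region, frames, n_neighbors = 5L) {
  idx <- if (inherits(region, "elvim_region")) region$idx else as.integer(region)
  if (length(idx) == 0L) stop("region is empty")
  fl <- frames_as_list(frames)[idx]
  if (length(idx) == 1L)
    return(list(centroid = idx, neighbors = integer(0), mean_drmsd = 0,
                drmsd = matrix(0, 1, 1)))
  dm <- drmsd_matrix(fl)
  avg <- rowSums(dm) / (length(idx) - 1)
  c_local <- which.min(avg)            # which.min takes the first tie
  nb_order <- order(dm[c_local, ], decreasing = FALSE)
  nb_local <- setdiff(nb_order, c_local)
  nb_local <- nb_local[seq_len(min(n_neighbors, length(nb_local)))]
  list(centroid = idx[c_local], neighbors = idx[nb_local],
       mean_drmsd = avg[c_local], drmsd = dm)
}

#' Write an embedding as TSV (frame_id, x, y, density, Q, rmsd)
#' @param emb An \code{elvim_embedding}.
#' @param path Output file.
#' @param density,q,rmsd_ref Optional per-point columns.
#' @export
write_embedding_tsv <- function(emb, path, density = NULL, q = NULL,
                                rmsd_ref = NULL) {
  n <- nrow(emb$points)
  d <- data.frame(frame_id = seq_len(n), x = emb$points[, 1],
                  y = emb$points[, 2],
                  density = if (is.null(density)) NA_real_ else density,
                  Q = if (is.null(q)) NA_real_ else as.numeric(q),
                  rmsd = if (is.null(rmsd_ref)) NA_real_ else rmsd_ref)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write/read a dissimilarity matrix as TSV
#' @param D Matrix; \code{path} file path.
#' @export
write_dissimilarity_tsv <- function(D, path) {
  write.table(unclass(D), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a dissimilarity matrix in the package's binary layout
#'
#' Layout (little-endian): int64 n, then the n x n float64 matrix
#' column-major.
#' @param D Square matrix; \code{path} output file.
#' @export
write_dissimilarity_bin <- function(D, path) {
  D <- unclass(D)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(nrow(D)), con, size = 8, endian = "little")
  writeBin(as.vector(D), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a dissimilarity matrix written by \code{write_dissimilarity_bin}
#' @param path Binary matrix file.
#' @export
read_dissimilarity_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  n <- readBin(con, "integer", 1, size = 8, endian = "little")
  matrix(readBin(con, "double", n * n, size = 8, endian = "little"), n, n)
}

#' Read/write region polygons as TSV of vertices (columns x, y)
#' @param path TSV file; \code{polygon} an m x 2 vertex matrix.
#' @export
write_polygon_tsv <- function(polygon, path) {
  write.table(data.frame(x = polygon[, 1], y = polygon[, 2]), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_polygon_tsv
#' @export
read_polygon_tsv <- function(path) {
  as.matrix(read.table(path, header = TRUE, sep = "\t"))
}
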