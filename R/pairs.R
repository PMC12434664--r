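# Native base-pair / stacking formation detection and frequency maps.

# Native B-bead distances for every annotated interaction.
.annotation_geometry <- function(cg_native, ann) {
  bd <- function(df) {
    if (nrow(df) == 0L) return(numeric(0))
    bi <- bead_index(df$res_i, "B"); bj <- bead_index(df$res_j, "B")
    sqrt(rowSums((cg_native$xyz[bi, , drop = FALSE] -
                  cg_native$xyz[bj, , drop = FALSE])^2))
  }
  list(pair_r0 = bd(ann$base_pairs), stack_r0 = bd(ann$stacks))
}

#' Detect formed native base pairs and stacks in one frame
#'
#' At coarse-grained resolution an annotated interaction (i, j) counts as
#' formed when the distance between the two residues' base beads is strictly
#' below \code{lambda} times its native B-bead distance; the same rule is
#' used for base pairs and stacks. Leontis-Westhof class labels are carried
#' through as annotation only.
#'
#' @param xyz Frame bead coordinates (beads x 3).
#' @param cg_native Native \code{cg_structure} (defines native distances).
#' @param ann An \code{annotation_list}.
#' @param lambda Formation threshold multiplier (default 1.2).
#' @return Object of class \code{interaction_state}: logical vectors
#'   \code{pairs} and \code{stacks} plus \code{lambda}.
#' @export
detect_interactions <- function(xyz, cg_native, ann, lambda = 1.2) {
  validate_annotations(ann, cg_native$n_residues)
  geo <- .annotation_geometry(cg_native, ann)
  fd <- function(df, r0) {
    if (nrow(df) == 0L) return(logical(0))
    bi <- bead_index(df$res_i, "B"); bj <- bead_index(df$res_j, "B")
    d <- sqrt(rowSums((xyz[bi, , drop = FALSE] - xyz[bj, , drop = FALSE])^2))
    d < lambda * r0
  }
  structure(list(pairs = fd(ann$base_pairs, geo$pair_r0),
                 stacks = fd(ann$stacks, geo$stack_r0),
                 lambda = lambda),
            class = "interaction_state")
}

#' Interaction states over all frames of a trajectory
#'
#' @param traj A \code{cg_trajectory} (or list of frames).
#' @param cg_native,ann,lambda See \code{\link{detect_interactions}}.
#' @return List of logical matrices \code{pairs} and \code{stacks}
#'   (frames x interactions), with annotation metadata attached.
#' @export
interaction_states <- function(traj, cg_native, ann, lambda = 1.2) {
  fl <- frames_as_list(traj)
  states <- lapply(fl, detect_interactions, cg_native = cg_native, ann = ann,
                   lambda = lambda)
  pairs <- do.call(rbind, lapply(states, `[[`, "pairs"))
  stacks <- do.call(rbind, lapply(states, `[[`, "stacks"))
  structure(list(pairs = pairs, stacks = stacks, lambda = lambda,
                 annotations = ann),
            class = "interaction_state_set")
}

.state_matrix <- function(states) {
  if (inherits(states, "interaction_state_set"))
    cbind(states$pairs, states$stacks)
  else states
}

.state_labels <- function(states) {
  if (!inherits(states, "interaction_state_set"))
    return(paste0("int", seq_len(ncol(states))))
  ann <- states$annotations
  c(if (nrow(ann$base_pairs)) paste0("pair_", ann$base_pairs$res_i, "_",
                                     ann$base_pairs$res_j),
    if (nrow(ann$stacks)) paste0("stack_", ann$stacks$res_i, "_",
                                 ann$stacks$res_j))
}

#' Interaction formation frequencies binned along Q
#'
#' Per Q bin, the fraction of frames in which each annotated interaction is
#' formed; the machinery behind frequency-vs-Q onset analyses (where, for
#' example, early helix pairs switch on at low Q and tertiary interactions
#' only near the folded state).
#'
#' @param states An \code{interaction_state_set} (or logical matrix).
#' @param q Per-frame Q vector.
#' @param bin_width Q bin width (default 0.05).
#' @return Matrix (Q-bin x interaction) of frequencies in [0, 1]; empty bins
#'   are NA.
#' @export
frequency_vs_q <- function(states, q, bin_width = 0.05) {
  m <- .state_matrix(states)
  if (nrow(m) != length(q)) stop("states and q have mismatched lengths")
  nbin <- ceiling(1 / bin_width)
  bin <- pmin(floor(as.numeric(q) / bin_width) + 1L, nbin)
  out <- matrix(NA_real_, nbin, ncol(m))
  for (b in seq_len(nbin)) {
    sel <- bin == b
    if (any(sel)) out[b, ] <- colMeans(m[sel, , drop = FALSE])
  }
  rownames(out) <- sprintf("Q[%.2f,%.2f)", (seq_len(nbin) - 1) * bin_width,
                           pmin(seq_len(nbin) * bin_width, 1))
  colnames(out) <- .state_labels(states)
  out
}

#' Residue-by-residue interaction frequency map over a frame region
#'
#' Symmetric matrix of formation frequencies of the annotated interactions
#' (base pairs and stacks pooled) over the selected frames.
#'
#' @param states An \code{interaction_state_set}.
#' @param region_frames Frame indices defining the ensemble (default: all).
#' @param n_residues Matrix dimension; defaults to the largest annotated
#'   residue index.
#' @return Symmetric numeric matrix (residue x residue).
#' @export
ensemble_map <- function(states, region_frames = NULL, n_residues = NULL) {
  stopifnot(inherits(states, "interaction_state_set"))
  ann <- states$annotations
  all_res <- c(ann$base_pairs$res_i, ann$base_pairs$res_j,
               ann$stacks$res_i, ann$stacks$res_j)
  if (is.null(n_residues)) n_residues <- max(all_res)
  m <- .state_matrix(states)
  if (is.null(region_frames)) region_frames <- seq_len(nrow(m))
  if (length(region_frames) == 0L) stop("region is empty")
  freq <- colMeans(m[region_frames, , drop = FALSE])
  out <- matrix(0, n_residues, n_residues)
  ij <- rbind(as.matrix(ann$base_pairs[, c("res_i", "res_j")]),
              as.matrix(ann$stacks[, c("res_i", "res_j")]))
  for (k in seq_len(nrow(ij))) {
    i <- ij[k, 1]; j <- ij[k, 2]
    out[i, j] <- max(out[i, j], freq[k])
    out[j, i] <- out[i, j]
  }
  dimnames(out) <- list(paste0("res", seq_len(n_residues)),
                        paste0("res", seq_len(n_residues)))
  out
}
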