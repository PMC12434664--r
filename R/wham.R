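# Weighted Histogram Analysis Method along Q, plus the Q-threshold state
# classifier.

#' Build per-window Q histograms on a shared grid
#'
#' @param q_by_window List of per-window Q sample vectors.
#' @param n_bins Number of bins on [0, 1] (default 50).
#' @return List: \code{counts} (windows x bins), \code{centers},
#'   \code{breaks}.
#' @export
make_q_histograms <- function(q_by_window, n_bins = 50L) {
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  counts <- t(vapply(q_by_window, function(q) {
    b <- pmin(pmax(findInterval(q, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
    tabulate(b, n_bins)
  }, numeric(n_bins)))
  list(counts = counts, centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
       breaks = breaks)
}

#' Harmonic umbrella bias energies on a bin grid
#' @param centers Bin centers.
#' @param q0 Window target values.
#' @param k_q Spring constant(s), energy per Q^2.
#' @return Matrix (windows x bins) of bias energies.
#' @export
umbrella_bias_matrix <- function(centers, q0, k_q) {
  k_q <- rep_len(k_q, length(q0))
  t(vapply(seq_along(q0),
           function(w) 0.5 * k_q[w] * (centers - q0[w])^2,
           numeric(length(centers))))
}

#' Reconstruct a free-energy profile from umbrella windows (WHAM)
#'
#' Standard self-consistent WHAM iteration on the per-window free-energy
#' offsets f_w:
#'   P(b) = sum_w n_w(b) / sum_w N_w exp((f_w - c_w(b)) / kT),
#'   f_w  = -kT log sum_b P(b) exp(-c_w(b) / kT),
#' converged when max |delta f_w| < tol. The unbiased profile is
#' F(b) = -kT log P(b), shifted so its minimum is zero. Bins with no samples
#' in any window are NA. Windows whose sampled supports do not overlap are
#' reported as disconnected components with a warning.
#'
#' @param counts Histogram count matrix (windows x bins).
#' @param bias Bias energy matrix (windows x bins), same units as kT.
#' @param centers Bin centers (Q grid).
#' @param temperature kT in reduced units (default 1).
#' @param tol Convergence tolerance on the offsets (default 1e-7).
#' @param max_iter Iteration cap (default 1e5).
#' @return Object of class \code{free_energy_profile}: data.frame
#'   \code{profile} (Q, F, counts), \code{f_w}, \code{residual},
#'   \code{iterations}, \code{components}.
#' @export
wham_solve <- function(counts, bias, centers, temperature = 1,
                       tol = 1e-7, max_iter = 1e5L) {
  counts <- rbind(counts); bias <- rbind(bias)
  stopifnot(nrow(counts) >= 1L, all(dim(counts) == dim(bias)),
            ncol(counts) == length(centers))
  kT <- temperature
  nw <- nrow(counts); nb <- ncol(counts)
  # connectivity of window supports
  support <- counts > 0
  comp <- seq_len(nw)
  repeat {
    changed <- FALSE
    for (w in seq_len(nw)) for (v in seq_len(nw)) {
      if (comp[w] != comp[v] &&
          any(support[w, ] & support[v, ])) {
        comp[comp == max(comp[c(w, v)])] <- min(comp[c(w, v)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  n_comp <- length(unique(comp))
  if (n_comp > 1L)
    warning("umbrella windows form ", n_comp,
            " disconnected components; profile offsets between components ",
            "are arbitrary")
  N_w <- rowSums(counts)
  sum_counts <- colSums(counts)
  expb <- exp(-bias / kT)                       # windows x bins
  f <- numeric(nw)
  it <- 0L
  residual <- Inf
  repeat {
    it <- it + 1L
    denom <- colSums(N_w * exp(f / kT) * expb)  # per bin
    p <- ifelse(denom > 0, sum_counts / denom, 0)
    f_new <- -kT * log(expb %*% p)
    f_new <- as.numeric(f_new - f_new[1])       # gauge: f_1 = 0
    residual <- max(abs(f_new - f))
    f <- f_new
    if (residual < tol) break
    if (it >= max_iter)
      stop("WHAM failed to converge after ", max_iter,
           " iterations (residual ", signif(residual, 3), ")")
  }
  p[sum_counts == 0] <- NA_real_
  Fq <- -kT * log(p)
  Fq <- Fq - min(Fq, na.rm = TRUE)
  structure(list(profile = data.frame(Q = centers, F_kBT = Fq,
                                      counts = sum_counts),
                 f_w = f, residual = residual, iterations = it,
                 components = comp, temperature = temperature),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat("<free_energy_profile> ", nrow(x$profile), " bins, converged in ",
      x$iterations, " iterations (residual ", signif(x$residual, 3), ")\n",
      sep = "")
  invisible(x)
}

#' Barrier height between the two lowest minima of a profile
#'
#' Utility for multi-basin profiles: finds the local minima of F(Q), takes
#' the two deepest, and returns the height of the highest point between
#' them, measured from the deeper basin (or from the shallower one with
#' \code{from = "higher"}).
#' @param fep A \code{free_energy_profile} (or data.frame Q/F_kBT).
#' @param from Measure the barrier from the "deeper" or "higher" minimum.
#' @return List: \code{barrier}, \code{q_min1}, \code{q_min2}, \code{q_top}.
#' @export
profile_barrier <- function(fep, from = c("deeper", "higher")) {
  from <- match.arg(from)
  pr <- if (inherits(fep, "free_energy_profile")) fep$profile else fep
  ok <- is.finite(pr$F_kBT)
  q <- pr$Q[ok]; Fv <- pr$F_kBT[ok]
  n <- length(Fv)
  is_min <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    Fv[i] <= Fv[lo] && Fv[i] <= Fv[hi]
  }, TRUE)
  mins <- which(is_min)
  if (length(mins) < 2L) stop("profile has fewer than two local minima")
  mins <- mins[order(Fv[mins])][1:2]
  mins <- sort(mins)
  seg <- seq(mins[1], mins[2])
  top <- seg[which.max(Fv[seg])]
  ref <- if (from == "deeper") min(Fv[mins]) else max(Fv[mins])
  list(barrier = Fv[top] - ref, q_min1 = q[mins[1]], q_min2 = q[mins[2]],
       q_top = q[top])
}

#' Classify conformational states by Q thresholds
#'
#' Unfolded (U) for Q < 0.4, partially open (PO) for 0.4 <= Q < 0.55,
#' partially folded (PF) for 0.55 <= Q < 0.85, folded (F) for Q >= 0.85.
#' Intervals are left-closed: a boundary value belongs to the higher state.
#'
#' @param q Q value(s) in [0, 1].
#' @param thresholds Ordered cut points (defaults 0.4, 0.55, 0.85).
#' @return Factor with levels U, PO, PF, F.
#' @export
classify_state <- function(q, thresholds = c(0.4, 0.55, 0.85)) {
  stopifnot(length(thresholds) == 3L, all(diff(thresholds) > 0),
            thresholds[1] > 0, thresholds[3] < 1)
  q <- as.numeric(q)
  if (any(q < 0 | q > 1)) stop("Q outside [0, 1]")
  lab <- c("U", "PO", "PF", "F")
  factor(lab[findInterval(q, thresholds) + 1L], levels = lab)
}

#' Write a free-energy profile as TSV with a JSON window sidecar
#' @param fep A \code{free_energy_profile}.
#' @param path TSV output path; sidecar written to \code{paste0(path,
#'   ".windows.json")}.
#' @param windows Optional window metadata list (q0, k_q, n_steps, seed).
#' @export
write_profile_tsv <- function(fep, path, windows = NULL) {
  write.table(fep$profile, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- list(f_w = fep$f_w, residual = fep$residual,
               iterations = fep$iterations, temperature = fep$temperature,
               windows = windows)
  jsonlite::write_json(meta, paste0(path, ".windows.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
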