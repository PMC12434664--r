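# Shared fixtures, built once per test run. Everything is generated in code;
# no binary data.

fx <- new.env()

fx$rb <- synthetic_riboswitch()
fx$cg_rb <- coarse_grain(fx$rb)
fx$nc_rb <- native_contacts(fx$cg_rb)
fx$ann_rb <- synthetic_riboswitch_annotations()

fx$hp <- synthetic_hairpin()
fx$cg_hp <- coarse_grain(fx$hp)
fx$nc_hp <- native_contacts(fx$cg_hp)
fx$ann_hp <- synthetic_hairpin_annotations()

# Hand-built coarse-grained object (bypasses the atomistic path) for small
# geometric fixtures.
make_cg <- function(xyz, residue_index,
                    role = rep(c("P", "S", "B"),
                               length.out = nrow(xyz))) {
  structure(list(xyz = xyz, role = role, residue_index = residue_index,
                 sequence = rep("A", max(residue_index)),
                 n_residues = max(residue_index), source_id = "fixture"),
            class = "cg_structure")
}

# Hand-built native contact set.
make_nc <- function(i, j, r_native, residue_index, cutoff = NA, min_sep = NA) {
  structure(list(pairs = data.frame(i = i, j = j,
                                    res_i = residue_index[i],
                                    res_j = residue_index[j],
                                    r_native = r_native),
                 residue_pairs = unique(data.frame(
                   res_i = residue_index[i], res_j = residue_index[j])),
                 cutoff_used = cutoff, min_sep = min_sep,
                 n_beads = if (length(j)) max(j) else 0L),
            class = "native_contacts")
}

# Trajectory assembled directly from coordinate arrays.
make_traj <- function(frames, ions = NULL, box_edge = 150) {
  rna <- array(NA_real_, c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) rna[f, , ] <- frames[[f]]
  ion_arr <- NULL
  if (!is.null(ions)) {
    ion_arr <- array(NA_real_, c(length(ions), nrow(ions[[1]]), 3))
    for (f in seq_along(ions)) ion_arr[f, , ] <- ions[[f]]
  }
  foldscape:::new_trajectory(rna, ion_arr, box_edge)
}

# Independent naive Q_w implementation (explicit loops) used as the Eq-2
# oracle; kept deliberately separate from the package's vectorized path.
qw_naive <- function(a, b, residue_index, sigma0 = 3, eps = 0.15) {
  n <- nrow(a)
  total <- 0
  np <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dn <- abs(residue_index[i] - residue_index[j])
    if (dn < 1L) next
    np <- np + 1L
    sig <- sigma0 * dn^eps
    ra <- sqrt(sum((a[i, ] - a[j, ])^2))
    rb <- sqrt(sum((b[i, ] - b[j, ])^2))
    total <- total + exp(-(ra - rb)^2 / (2 * sig^2))
  }
  1 - total / np
}

# Random rigid rotation matrix.
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
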