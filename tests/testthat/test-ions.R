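# Helper: one-frame trajectory around the riboswitch fold with ions placed
# by hand.
ion_frame <- function(ions, box = 150) {
  make_traj(list(fx$cg_rb$xyz), list(ions), box_edge = box)
}

p_xyz <- function(res) fx$cg_rb$xyz[bead_index(res, "P"), ]

test_that("occupancy counts ions within the strict cutoff", {
  tr <- ion_frame(rbind(p_xyz(7) + c(5, 0, 0) * 1.0,
                        c(70, 70, 70)))
  cnt <- occupancy(tr, cutoff = 8)
  expect_equal(cnt[1, 7], 1L)
  # an ion at 5 A of residue 7's phosphate may also sit near neighbours;
  # residues far in space must see nothing
  expect_equal(cnt[1, 45], 0L)
  # boundary: exactly outside
  tr2 <- ion_frame(matrix(p_xyz(7) + c(8.1, 0, 0), 1, 3))
  expect_equal(occupancy(tr2, cutoff = 8)[1, 7], 0L)
  tr3 <- ion_frame(matrix(p_xyz(7) + c(8, 0, 0), 1, 3))
  expect_equal(occupancy(tr3, cutoff = 8)[1, 7], 0L)   # tie excluded
})

test_that("occupancy equals a brute-force loop on random frames", {
  set.seed(12)
  tr <- morph_ensemble(fx$cg_rb, n_frames = 6, unfold_fraction = 0.7,
                       noise = 0.2, seed = 12, n_ions = 15, box_edge = 80)
  cnt <- occupancy(tr, cutoff = 8)
  box <- tr$box_edge
  for (f in seq_len(6)) {
    ions <- ion_xyz(tr, f)
    for (r in c(1L, 17L, 28L, 52L)) {
      p <- frame_xyz(tr, f)[bead_index(r, "P"), ]
      n <- 0L
      for (a in seq_len(nrow(ions))) {
        d <- p - ions[a, ]
        d <- d - box * round(d / box)
        if (sqrt(sum(d^2)) < 8) n <- n + 1L
      }
      expect_identical(cnt[f, r], n)
    }
  }
})

test_that("occupancy_vs_q bins frames and flags empty bins as NA", {
  counts <- matrix(1:12, 4, 3)
  q <- c(0.62, 0.64, 0.61, 0.63)       # all in one bin
  hm <- occupancy_vs_q(counts, q, bin_width = 0.05)
  expect_equal(nrow(hm$matrix), 20L)
  filled <- which(!is.na(hm$matrix[, 1]))
  expect_length(filled, 1L)
  expect_equal(hm$matrix[filled, ], colMeans(counts),
               ignore_attr = TRUE)
  expect_true(all(is.na(hm$matrix[-filled, ])))
  expect_error(occupancy_vs_q(counts, q[1:3]), "mismatch")
  expect_equal(nrow(occupancy_vs_q(counts, q, bin_width = 0.3)$matrix), 4L)
})

test_that("scripted site ions dominate the high-Q rows of the heatmap", {
  tr <- morph_ensemble(fx$cg_rb, n_frames = 300, unfold_fraction = 1,
                       noise = 0, seed = 5, n_ions = 0, box_edge = 150,
                       sites = list(residues = c(5L, 6L, 7L), q_min = 0.5,
                                    contacts = fx$nc_rb))
  q <- tr$meta$q_hard
  cnt <- occupancy(tr, cutoff = 8)
  hm <- occupancy_vs_q(cnt, q, bin_width = 0.05)
  m <- hm$matrix
  hi <- which(!is.na(m[, 1]) &
                (seq_len(nrow(m)) - 1) * 0.05 >= 0.55)
  lo <- which(!is.na(m[, 1]) & seq_len(nrow(m)) * 0.05 <= 0.45)
  site_cols <- 5:7
  other <- setdiff(seq_len(ncol(m)), c(site_cols, 4L, 8L))
  expect_gt(min(rowSums(m[hi, site_cols, drop = FALSE])), 2.5)
  # below the switching threshold the site ions wander: occupancies there
  # and away from the sites stay at stray-hit level
  expect_lt(mean(m[lo, site_cols]), 0.05)
  expect_lt(mean(m[, other], na.rm = TRUE), 0.05)
})

test_that("bridging probabilities are exact on scripted frames", {
  # bridge ion present in exactly 7 of 10 frames
  frames <- replicate(10, fx$cg_rb$xyz, simplify = FALSE)
  pos <- foldscape:::.bridge_position(fx$cg_rb$xyz, c(28L, 38L), cutoff = 8)
  ions <- lapply(1:10, function(f) {
    if (f <= 7) matrix(pos, 1, 3) else matrix(c(70, 70, 70), 1, 3)
  })
  tr <- make_traj(frames, ions)
  bm <- bridging_map(tr, cutoff = 8, min_sep = 4)
  expect_equal(bm$matrix["res28", "res38"], 0.7)
  expect_equal(bm$matrix, t(bm$matrix))
  expect_equal(top_bridge(bm)$res_i, 28L)
  expect_equal(top_bridge(bm)$res_j, 38L)
  # the near-diagonal band is zeroed
  sep <- abs(outer(1:52, 1:52, "-"))
  expect_true(all(bm$matrix[sep < 4] == 0))
})

test_that("a trajectory without ions gives a zero bridge map", {
  tr <- make_traj(replicate(3, fx$cg_rb$xyz, simplify = FALSE))
  bm <- bridging_map(tr, cutoff = 8, min_sep = 4)
  expect_equal(max(bm$matrix), 0)
})

test_that("the morph bridge generator recovers its designed probability", {
  tr <- morph_ensemble(fx$cg_rb, n_frames = 1000, unfold_fraction = 0,
                       noise = 0, seed = 9, n_ions = 0,
                       bridge = list(pair = c(28L, 38L), fraction = 0.7))
  bm <- bridging_map(tr, cutoff = 8, min_sep = 4)
  tb <- top_bridge(bm)
  expect_equal(c(tb$res_i, tb$res_j), c(28L, 38L))
  expect_lt(abs(tb$p - 0.7), 3 * sqrt(0.7 * 0.3 / 1000))
  expect_equal(tb$p, length(attr(tr$ions, "bridge_frames")) / 1000)
})

test_that("RDF is flat for ideal-gas ions and spikes for frozen ones", {
  set.seed(20)
  box <- 60
  frames <- replicate(60, fx$cg_hp$xyz, simplify = FALSE)
  ions <- lapply(1:60, function(f) matrix(runif(120, -box / 2, box / 2),
                                          40, 3))
  tr <- make_traj(frames, ions, box_edge = box)
  rdf <- rdf_mg_phosphate(tr, bin_width = 1)
  bulk <- rdf$rdf$g[rdf$rdf$r > 10 & rdf$rdf$r < 25]
  expect_true(all(abs(bulk - 1) < 0.25))
  expect_lt(abs(mean(bulk) - 1), 0.05)
  # frozen shell at exactly 5 A from one phosphate
  p <- fx$cg_hp$xyz[bead_index(3, "P"), ]
  tr2 <- make_traj(list(fx$cg_hp$xyz),
                   list(matrix(p + c(5, 0, 0), 1, 3)), box_edge = box)
  rdf2 <- rdf_mg_phosphate(tr2, bin_width = 0.5)
  spike_bin <- which(rdf2$rdf$g == max(rdf2$rdf$g))
  expect_equal(rdf2$rdf$r[spike_bin], 5.25)
  expect_error(rdf_mg_phosphate(make_traj(frames)), "no ions")
})

test_that("doubling the frame count leaves the RDF unchanged within noise", {
  box <- 60
  set.seed(30)
  mk <- function(n, seed) {
    set.seed(seed)
    make_traj(replicate(n, fx$cg_hp$xyz, simplify = FALSE),
              lapply(seq_len(n), function(f)
                matrix(runif(90, -box / 2, box / 2), 30, 3)),
              box_edge = box)
  }
  g1 <- rdf_mg_phosphate(mk(40, 1), bin_width = 2)$rdf
  g2 <- rdf_mg_phosphate(mk(80, 2), bin_width = 2)$rdf
  sel <- g1$r > 8 & g1$r < 25
  expect_lt(max(abs(g1$g[sel] - g2$g[sel])), 0.2)
})

test_that("excess-ion accounting splits folded and unfolded states", {
  tr <- morph_ensemble(fx$cg_rb, n_frames = 40, unfold_fraction = 1,
                       noise = 0, seed = 3, n_ions = 30, box_edge = 100,
                       sites = list(residues = c(5L, 6L, 7L), q_min = 0.85,
                                    contacts = fx$nc_rb))
  res <- excess_ions(tr, tr$meta$q_hard, cutoff = 8)
  expect_equal(res$state, c("folded", "unfolded"))
  expect_true(all(res$n_frames > 0))
  # scripted site ions make the folded state ion-enriched relative to bulk
  expect_gt(res$excess[res$state == "folded"],
            res$excess[res$state == "unfolded"])
})
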