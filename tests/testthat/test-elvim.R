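test_that("identical conformations have zero dissimilarity", {
  a <- fx$cg_hp$xyz
  expect_equal(qw_dissimilarity(a, a, fx$cg_hp$residue_index), 0)
})

test_that("a single included pair reproduces the hand-evaluated kernel", {
  # beads on residues 5 and 6 (|dn| = 1 so sigma = 3 A); r_k = 10, r_l = 13
  a <- rbind(c(0, 0, 0), c(10, 0, 0))
  b <- rbind(c(0, 0, 0), c(13, 0, 0))
  delta <- qw_dissimilarity(a, b, residue_index = c(5L, 6L))
  expect_equal(delta, 1 - exp(-9 / 18), tolerance = 1e-12)
})

test_that("the width rule follows sigma0 * |dn|^eps", {
  expect_equal(qw_sigma(1), 3, tolerance = 1e-9)
  expect_equal(qw_sigma(2), 3 * 2^0.15, tolerance = 1e-9)
  expect_equal(qw_sigma(32), 3 * 32^0.15, tolerance = 1e-9)
  expect_equal(qw_sigma(32), 5.0453782, tolerance = 1e-6)
})

test_that("intra-residue bead pairs are excluded from the pair set", {
  ps <- qw_pair_set(rep(1:2, each = 3))
  expect_equal(length(ps$i), 9L)    # 3 x 3 inter-residue pairs
  expect_true(all(ps$sigma > 0))
  expect_error(qw_pair_set(rep(1L, 3)), "empty pair set")
})

test_that("dissimilarity is invariant under rigid motion of either frame", {
  set.seed(21)
  tr <- morph_ensemble(fx$cg_hp, n_frames = 3, unfold_fraction = 0.8,
                       noise = 0.2, seed = 21)
  a <- frame_xyz(tr, 1); b <- frame_xyz(tr, 3)
  d0 <- qw_dissimilarity(a, b, fx$cg_hp$residue_index)
  b_mov <- b %*% t(random_rotation()) + 13
  expect_equal(qw_dissimilarity(a, b_mov, fx$cg_hp$residue_index), d0,
               tolerance = 1e-10)
})

test_that("the dissimilarity matrix matches per-pair evaluation exactly", {
  tr <- morph_ensemble(fx$cg_hp, n_frames = 12, unfold_fraction = 1,
                       noise = 0.3, seed = 8)
  D <- dissimilarity_matrix(tr, fx$cg_hp$residue_index)
  expect_equal(diag(unclass(D)), rep(0, 12))
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(unclass(D), t(unclass(D)))
  ps <- qw_pair_set(fx$cg_hp$residue_index)
  for (k in c(1, 5)) for (l in c(7, 12)) {
    expect_equal(D[k, l],
                 qw_dissimilarity(frame_xyz(tr, k), frame_xyz(tr, l),
                                  fx$cg_hp$residue_index, pair_set = ps),
                 tolerance = 1e-12)
    # independent naive double-loop oracle
    expect_equal(D[k, l],
                 qw_naive(frame_xyz(tr, k), frame_xyz(tr, l),
                          fx$cg_hp$residue_index),
                 tolerance = 1e-10)
  }
  expect_error(dissimilarity_matrix(list(frame_xyz(tr, 1),
                                         frame_xyz(tr, 2)[1:10, ]),
                                    fx$cg_hp$residue_index),
               "inconsistent bead counts")
})

test_that("three identical frames give a zero matrix", {
  fr <- list(fx$cg_hp$xyz, fx$cg_hp$xyz, fx$cg_hp$xyz)
  D <- dissimilarity_matrix(fr, fx$cg_hp$residue_index)
  expect_equal(max(abs(D)), 0)
})

test_that("force scheme recovers an equilateral triangle", {
  D <- matrix(0.5, 3, 3); diag(D) <- 0
  emb <- force_scheme(D, n_iter = 200, seed = 2)
  d <- as.vector(dist(emb$points))
  expect_lt(max(d) / min(d) - 1, 0.02)
})

test_that("an all-zero dissimilarity matrix collapses the embedding", {
  D <- matrix(0, 5, 5)
  emb <- force_scheme(D, n_iter = 50, seed = 3)
  expect_lt(max(dist(emb$points)), 1e-3)
})

test_that("normalized stress does not increase over iterations", {
  for (s in 1:20) {
    set.seed(s)
    M <- matrix(runif(50 * 50), 50, 50)
    D <- (M + t(M)) / 2; diag(D) <- 0
    emb <- force_scheme(D, n_iter = 100, seed = s)
    expect_lte(emb$stress[100], emb$stress[1])
  }
})

test_that("embedding distances track dissimilarities on a morph path", {
  tr <- morph_ensemble(fx$cg_hp, n_frames = 200, unfold_fraction = 1,
                       noise = 0.15, seed = 14)
  D <- dissimilarity_matrix(tr, fx$cg_hp$residue_index)
  emb <- force_scheme(D, n_iter = 100, seed = 14)
  d <- as.matrix(dist(emb$points))
  ut <- upper.tri(d)
  expect_gt(cor(d[ut], unclass(D)[ut]), 0.7)
  # the morph path projects as a connected filament: no consecutive step
  # jumps a noticeable fraction of the landscape, and consecutive frames sit
  # at nearest-neighbour scale
  consec <- d[cbind(1:199, 2:200)]
  nn <- apply(d + diag(Inf, 200), 1, min)
  expect_lt(max(consec), 0.05 * max(d))
  expect_lt(median(consec), 3 * median(nn))
})

test_that("KDE separates dense clusters from the gap between them", {
  set.seed(4)
  pts <- rbind(matrix(rnorm(200, 0, 0.05), 100, 2),
               matrix(rnorm(200, 5, 0.05), 100, 2))
  dens <- kde_density(pts)
  mid <- foldscape:::kde_at(pts, matrix(c(2.5, 2.5), 1, 2),
                            apply(pts, 2, sd) * 200^(-1 / 6))
  expect_true(all(dens > mid))
})

test_that("KDE is flat on a uniform grid and integrates to one", {
  g <- as.matrix(expand.grid(x = seq(0, 10, 0.5), y = seq(0, 10, 0.5)))
  dens <- kde_density(g)
  interior <- g[, 1] > 2 & g[, 1] < 8 & g[, 2] > 2 & g[, 2] < 8
  expect_lt(sd(dens[interior]) / mean(dens[interior]), 0.1)
  # integrate over a covering grid
  h <- apply(g, 2, sd) * nrow(g)^(-1 / 6)
  cover <- as.matrix(expand.grid(x = seq(-5, 15, 0.25),
                                 y = seq(-5, 15, 0.25)))
  total <- sum(foldscape:::kde_at(g, cover, h)) * 0.25^2
  expect_equal(total, 1, tolerance = 0.02)
  expect_error(kde_density(matrix(1, 5, 2)), "degenerate")
})

test_that("local signatures find the medoid of a region", {
  A <- fx$cg_hp$xyz
  B <- extended_chain(fx$cg_hp)
  ls0 <- local_signature(1:3, list(A, A, A))
  expect_equal(ls0$mean_drmsd, 0)
  lsb <- local_signature(1:3, list(A, A, B))
  expect_equal(lsb$centroid, 1L)     # tie between the two A frames -> first
  # brute-force oracle on 20 random frames
  set.seed(31)
  fr <- lapply(1:20, function(i) matrix(rnorm(30, sd = 3), 10, 3))
  ls <- local_signature(1:20, fr)
  means <- vapply(1:20, function(k) {
    mean(vapply(setdiff(1:20, k), function(l) drmsd(fr[[k]], fr[[l]]), 1.0))
  }, 1.0)
  expect_equal(ls$centroid, which.min(means))
  expect_equal(ls$mean_drmsd, min(means))
  one <- local_signature(7L, fr)
  expect_equal(one$centroid, 7L)
  expect_length(one$neighbors, 0)
})

test_that("polygon and density regions select the expected points", {
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(5, 5)) * 1.0
  poly <- rbind(c(-0.5, -0.5), c(1.5, -0.5), c(1.5, 1.5), c(-0.5, 1.5))
  reg <- region_polygon(pts, poly)
  expect_equal(reg$idx, 1:4)
  expect_error(region_polygon(pts, poly - 100), "empty")
  td <- withr::local_tempdir()
  p <- file.path(td, "poly.tsv")
  write_polygon_tsv(poly, p)
  expect_equal(read_polygon_tsv(p), poly, ignore_attr = TRUE)
})

test_that("dissimilarity matrices round-trip through the binary layout", {
  tr <- morph_ensemble(fx$cg_hp, n_frames = 8, unfold_fraction = 1,
                       noise = 0.2, seed = 17)
  D <- dissimilarity_matrix(tr, fx$cg_hp$residue_index)
  td <- withr::local_tempdir()
  p <- file.path(td, "diss.bin")
  write_dissimilarity_bin(D, p)
  expect_equal(read_dissimilarity_bin(p), unclass(D), ignore_attr = TRUE)
})
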