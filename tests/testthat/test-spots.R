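test_that("the radial symmetry response peaks at spot centers", {
  expect_true(all(radial_symmetry_transform(matrix(7, 40, 40)) == 0))
  fr <- matrix(100, 60, 60)
  fr <- trapline:::add_gaussian_spot(fr, 20, 30, 300, 1.3)
  resp <- radial_symmetry_transform(fr)
  am <- which(resp == max(resp), arr.ind = TRUE)[1, ] - 1
  expect_lte(sqrt(sum((am - c(20, 30))^2)), 1)
  # two equal spots give two near-equal local maxima
  fr2 <- matrix(100, 60, 60)
  fr2 <- trapline:::add_gaussian_spot(fr2, 20, 20, 300, 1.3)
  fr2 <- trapline:::add_gaussian_spot(fr2, 20, 30, 300, 1.3)
  sp <- detect_spots(radial_symmetry_transform(fr2))
  expect_equal(nrow(sp), 2L)
  expect_lt(abs(diff(sp$response)) / max(sp$response), 0.05)
})

test_that("the response is translation-equivariant in the interior", {
  set.seed(23)
  fr <- matrix(100, 50, 50)
  fr <- trapline:::add_gaussian_spot(fr, 22, 25, 250, 1.3)
  shifted <- matrix(100, 50, 50)
  shifted[4:50, 6:50] <- fr[1:47, 1:45]   # shift by (+3, +5)
  r1 <- radial_symmetry_transform(fr)
  r2 <- radial_symmetry_transform(shifted)
  inner <- 10:40
  expect_equal(r2[inner + 3, inner + 5], r1[inner, inner],
               tolerance = 1e-9)
})

test_that("detection is clean on noise and monotone in the threshold", {
  set.seed(29)
  fp <- 0L
  for (i in 1:20) {
    fr <- matrix(rpois(80 * 80, 100), 80) + matrix(rnorm(6400, 0, 2), 80)
    fp <- fp + nrow(detect_spots(radial_symmetry_transform(fr), k = 8))
  }
  expect_lte(fp / 20, 0.05)
  # planted spots at SNR ~ 10 are all found within 1 px
  fr <- matrix(100, 80, 80)
  pos <- cbind(c(15, 30, 50, 65, 40), c(20, 60, 30, 70, 45))
  for (i in 1:5)
    fr <- trapline:::add_gaussian_spot(fr, pos[i, 1], pos[i, 2], 300, 1.3)
  fr <- matrix(rpois(length(fr), fr), nrow(fr))
  resp <- radial_symmetry_transform(fr)
  sp <- detect_spots(resp, k = 8)
  expect_equal(nrow(sp), 5L)
  d <- vapply(seq_len(5), function(i)
    min(sqrt((sp$row - pos[i, 1])^2 + (sp$col - pos[i, 2])^2)),
    numeric(1))
  expect_true(all(d <= 1))
  # counts never increase with k
  ks <- c(2, 4, 8, 16, 64)
  n <- vapply(ks, function(k) nrow(detect_spots(resp, k = k)), integer(1))
  expect_true(all(diff(n) <= 0))
  # close maxima are suppressed to one detection
  fr3 <- matrix(100, 40, 40)
  fr3 <- trapline:::add_gaussian_spot(fr3, 20, 20, 300, 1.3)
  fr3 <- trapline:::add_gaussian_spot(fr3, 20, 21, 300, 1.3)
  expect_equal(nrow(detect_spots(radial_symmetry_transform(fr3),
                                 min_separation_px = 3)), 1L)
})

test_that("camera transform estimation is exact and errors as promised", {
  pts <- cbind(c(0, 10, 0, 7), c(0, 0, 10, 3))
  expect_error(estimate_camera_transform(pts[1:2, ], pts[1:2, ]),
               "at least 3")
  col_pts <- cbind(1:5, 2 * (1:5))
  expect_error(estimate_camera_transform(col_pts, col_pts), "collinear")
  est <- estimate_camera_transform(pts, pts)
  expect_equal(est$A, diag(2), tolerance = 1e-12)
  expect_equal(est$b, c(0, 0), tolerance = 1e-12)
  expect_equal(est$rms, 0, tolerance = 1e-9)
  shifted <- pts + matrix(rep(c(5, -3), each = 4), ncol = 2)
  est2 <- estimate_camera_transform(pts, shifted)
  expect_equal(est2$A, diag(2), tolerance = 1e-9)
  expect_equal(est2$b, c(5, -3), tolerance = 1e-9)
})

test_that("noisy landmark fits recover parameters within 3 SE", {
  tf <- affine_transform(matrix(c(1.002, -0.001, 0.003, 0.998), 2, 2),
                         c(2.5, -1.5))
  noise_sd <- 0.5
  pts <- simulate_landmark_pair(tf, 50, noise_sd = noise_sd, rng_seed = 31)
  est <- estimate_camera_transform(pts$cam1, pts$cam2)
  # closed-form least-squares covariance: sigma^2 (X^T X)^-1 per output
  X <- cbind(pts$cam1, 1)
  se <- sqrt(noise_sd^2 * diag(solve(crossprod(X))))
  for (d in 1:2) {
    est_beta <- c(est$A[d, ], est$b[d])
    true_beta <- c(tf$A[d, ], tf$b[d])
    expect_true(all(abs(est_beta - true_beta) <= 3 * se))
  }
})

test_that("transforms compose, invert and reject singular linear parts", {
  tf <- affine_transform(matrix(c(1.1, 0.1, -0.2, 0.9), 2, 2), c(4, -7))
  p <- cbind(c(1, 5, 9), c(2, 4, 8))
  back <- apply_transform(invert_transform(tf), apply_transform(tf, p))
  expect_equal(back, p, tolerance = 1e-12)
  expect_error(affine_transform(matrix(0, 2, 2), c(0, 0)), "singular")
})

test_that("spots map into the right cells with background rescue", {
  mask <- matrix(0L, 30, 30)
  mask[5:15, 5:12] <- 1L; mask[18:28, 5:12] <- 2L
  mask <- label_mask(mask)
  id <- affine_transform()
  sp <- data.frame(frame = 0L, row = c(9, 22, 2, 16), col = c(8, 8, 25, 8),
                   response = 1)
  asg <- assign_spots_to_cells(sp, id, mask, rescue_radius_px = 2)
  # centroid hit, second cell hit, far-background unassigned, rescued
  expect_equal(asg$spots$cell, c(1L, 2L, 0L, 2L))
  expect_equal(asg$counts$n_spots[asg$counts$cell == 2L], 2L)
  # a known camera offset carries spots into the phase frame
  tf <- affine_transform(diag(2), c(3, -2))
  sp2 <- data.frame(frame = 0L, row = 6, col = 10, response = 1)
  asg2 <- assign_spots_to_cells(sp2, tf, mask, rescue_radius_px = 0)
  expect_equal(asg2$spots$cell, 1L)
})

test_that("per-cell counts match ground truth for isolated molecules", {
  # one molecule per cell, far apart: counting is exact end-to-end
  p <- sim_params(n_traps = 4, total_duration_min = 20,
                  frame_interval_phase_s = 600,
                  frame_interval_fluo_s = 600,
                  mean_molecules_per_cell = c(a = 0.5, b = 0.5),
                  genotype_fractions = c(a = 0.5, b = 0.5), rng_seed = 37)
  sim <- simulate_trap_timelapse(p)
  lm_pts <- simulate_landmark_pair(p$camera_offset, 30, noise_sd = 0,
                                   rng_seed = 1)
  tf <- estimate_camera_transform(lm_pts$cam1, lm_pts$cam2)
  ok <- 0L; n <- 0L
  for (q in seq_along(sim$fluo$frames)) {
    sp <- detect_spots(radial_symmetry_transform(sim$fluo$frames[[q]]))
    asg <- assign_spots_to_cells(sp, tf, sim$truth$masks[[q]])
    tc <- sim$truth$counts[sim$truth$counts$fluo_frame == q - 1, ]
    for (i in seq_len(nrow(tc))) {
      if (tc$n_molecules[i] >= 2) next  # merging is expected when crowded
      got <- asg$counts$n_spots[asg$counts$cell == tc$cell_id[i]]
      n <- n + 1L
      ok <- ok + as.integer(length(got) == 1 &&
                              got == tc$n_molecules[i])
    }
  }
  expect_gte(ok / n, 0.9)
})
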