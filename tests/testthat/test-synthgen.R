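test_that("sim_params validates its invariants", {
  expect_s3_class(sim_params(), "sim_params")
  expect_error(sim_params(genotype_fractions = c(a = 0.6, b = 0.5)),
               "sum to 1")
  expect_error(sim_params(trap_length_px = -1), "positive")
  expect_error(sim_params(total_duration_min = 0.5), "duration")
  expect_error(sim_params(frame_interval_fluo_s = 90), "multiple")
  expect_error(sim_params(total_duration_min = 1.5), "divide")
})

test_that("timelapse growth and division follow the deterministic rule", {
  # one trap, long enough that no cell exits: after t minutes at rate
  # log(2)/30 a single ancestor yields at least 2^(t/30 - 1) cells
  p <- sim_params(n_traps = 1, total_duration_min = 100,
                  trap_length_px = 260, frame_interval_fluo_s = 1200,
                  mean_molecules_per_cell = c(g = 1),
                  genotype_fractions = c(g = 1), rng_seed = 21)
  sim <- simulate_trap_timelapse(p)
  final <- sim$truth$masks[[length(sim$truth$masks)]]
  n_final <- length(setdiff(unique(as.vector(final)), 0L))
  lower <- 2^(100 / 30 - 1)
  capacity <- floor(p$trap_length_px / p$division_length_px)
  expect_gte(n_final, min(floor(lower), capacity))
  # clonality: every cell carries the trap genotype
  expect_true(all(sim$truth$lineage$genotype_id == "g"))
  # division produces exactly two daughters
  par_tab <- table(sim$truth$lineage$parent_id)
  expect_true(all(par_tab == 2))
})

test_that("timelapse is bit-identical under the same seed", {
  p <- sim_params(n_traps = 2, total_duration_min = 30,
                  frame_interval_fluo_s = 600, rng_seed = 5)
  a <- simulate_trap_timelapse(p)
  b <- simulate_trap_timelapse(p)
  expect_identical(a$phase$frames, b$phase$frames)
  expect_identical(a$fluo$frames, b$fluo$frames)
  expect_identical(a$truth$lineage, b$truth$lineage)
  expect_identical(a$truth$spots, b$truth$spots)
})

test_that("molecule bookkeeping conserves mass and respects zero means", {
  p <- sim_params(n_traps = 2, total_duration_min = 30,
                  frame_interval_fluo_s = 600,
                  mean_molecules_per_cell = c(a = 4, b = 4),
                  genotype_fractions = c(a = 0.5, b = 0.5), rng_seed = 9)
  sim <- simulate_trap_timelapse(p)
  # every true molecule appears as one rendered spot center
  per_frame_counts <- tapply(sim$truth$counts$n_molecules,
                             sim$truth$counts$fluo_frame, sum)
  sp <- sim$truth$spots
  per_frame_spots <- table(factor(sp$fluo_frame,
                                  levels = names(per_frame_counts)))
  expect_equal(as.integer(per_frame_counts),
               as.integer(per_frame_spots))
  # zero expression leaves the fluorescence stack spot-free
  p0 <- sim_params(n_traps = 2, total_duration_min = 30,
                   frame_interval_fluo_s = 600,
                   mean_molecules_per_cell = c(a = 0, b = 0),
                   genotype_fractions = c(a = 0.5, b = 0.5), rng_seed = 9)
  sim0 <- simulate_trap_timelapse(p0)
  expect_null(sim0$truth$spots)
  for (fr in sim0$fluo$frames)
    expect_equal(nrow(detect_spots(radial_symmetry_transform(fr))), 0L)
})

test_that("duration shorter than one frame interval is rejected", {
  expect_error(sim_params(total_duration_min = 0.5,
                          frame_interval_phase_s = 60,
                          frame_interval_fluo_s = 60),
               "duration")
})

test_that("FISH rounds encode bits in the correct dye with crosstalk", {
  cb <- demo_codebook()
  p <- sim_params(n_traps = 3, noise_gain = 0, read_noise_sd = 0,
                  fish_background = 0, fish_crosstalk_fraction = 0)
  fish <- simulate_fish_rounds(c("lacI_kd", "lacY_kd", "no_kd"), cb, p,
                               n_rounds = 2)
  ivs <- fish$trap_intervals
  sum_in <- function(frame, k) sum(frame[, (ivs[k, 1] + 1):ivs[k, 2]])
  # lacI_kd = code 10: round 1 Cy3-dominant, round 2 Cy5-dominant
  expect_gt(sum_in(fish$rounds[[1]]$cy3$frames[[1]], 1), 0)
  expect_equal(sum_in(fish$rounds[[1]]$cy5$frames[[1]], 1), 0)
  expect_equal(sum_in(fish$rounds[[2]]$cy3$frames[[1]], 1), 0)
  expect_gt(sum_in(fish$rounds[[2]]$cy5$frames[[1]], 1), 0)
  # lacY_kd = code 01: the reverse
  expect_equal(sum_in(fish$rounds[[1]]$cy3$frames[[1]], 2), 0)
  expect_gt(sum_in(fish$rounds[[1]]$cy5$frames[[1]], 2), 0)
})

test_that("FISH round validation and miscall bookkeeping work", {
  cb <- demo_codebook()
  p <- sim_params(n_traps = 2)
  expect_error(simulate_fish_rounds(c("lacI_kd", "no_kd"), cb, p,
                                    n_rounds = 5), "does not divide")
  expect_error(simulate_fish_rounds(c("lacI_kd", "unknown"), cb, p),
               "absent from codebook")
  fish <- simulate_fish_rounds(c("lacI_kd", "no_kd"), cb, p, n_rounds = 6,
                               miscall = list(trap = 2, round = 3))
  flipped <- fish$bits[fish$bits$flipped, ]
  expect_equal(nrow(flipped), 1L)
  expect_equal(flipped$trap_id, 2L)
  expect_equal(flipped$round, 3L)
  expect_false(flipped$bit_true == flipped$bit_emitted)
})

test_that("landmark pairs follow the stated transform", {
  tf <- affine_transform(diag(2), c(0, 0))
  pts <- simulate_landmark_pair(tf, 10, noise_sd = 0, rng_seed = 3)
  expect_equal(pts$cam1, pts$cam2)
  tf2 <- affine_transform(diag(2), c(5, -3))
  pts2 <- simulate_landmark_pair(tf2, 10, noise_sd = 0, rng_seed = 3)
  expect_equal(pts2$cam2 - pts2$cam1,
               matrix(rep(c(5, -3), each = 10), ncol = 2))
  expect_error(simulate_landmark_pair(tf, 2), "at least 3")
})

test_that("growth-curve generator matches its closed form", {
  g <- simulate_growth_curves(doubling_time_min = 30, lag_min = 0,
                              plateau_od = Inf, n_timepoints = 60)
  expect_equal(max_growth_rate(g)$doubling_time_min, 30, tolerance = 1e-9)
  g2 <- simulate_growth_curves(fluo_per_od = 1000, blank_fluo = 50,
                               n_timepoints = 100)
  rr <- repression_ratio(list(a = g2, ref = g2), "ref")
  expect_equal(rr$fluo_per_od, c(1000, 1000), tolerance = 1e-9)
  expect_error(simulate_growth_curves(doubling_time_min = -2), "positive")
})
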