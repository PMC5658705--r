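make_mask <- function(nr, nc, rects) {
  m <- matrix(0L, nr, nc)
  for (i in seq_along(rects)) {
    r <- rects[[i]]
    m[r[1]:r[2], r[3]:r[4]] <- i
  }
  m
}

test_that("jaccard_index matches hand counts and is symmetric", {
  a <- matrix(FALSE, 4, 4); b <- matrix(FALSE, 4, 4)
  a[1, 1:4] <- TRUE           # |A| = 4
  b[1, 3:4] <- TRUE; b[2, 1:2] <- TRUE   # |B| = 4, |A n B| = 2
  expect_equal(jaccard_index(a, b), 1 / 3)
  expect_equal(jaccard_index(a, b), jaccard_index(b, a))
  expect_equal(jaccard_index(a, a), 1)
  expect_equal(jaccard_index(a, !a & FALSE), 0)
  expect_equal(jaccard_index(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 0)
  expect_error(jaccard_index(a, matrix(FALSE, 2, 2)), "same raster")
})

test_that("identical masks link as the identity migration", {
  m <- make_mask(30, 10, list(c(2, 8, 3, 8), c(12, 18, 3, 8),
                              c(22, 28, 3, 8)))
  link <- link_frames(m, m)
  expect_equal(nrow(link$migrations), 3L)
  expect_equal(link$migrations$parent, link$migrations$child)
  expect_equal(nrow(link$divisions), 0L)
  expect_equal(link$score, 3)
})

test_that("a clean split is scored as a division, not a migration", {
  parent <- make_mask(20, 10, list(c(2, 17, 3, 8)))
  kids <- matrix(0L, 20, 10)
  kids[2:9, 3:8] <- 1L; kids[10:17, 3:8] <- 2L  # union equals the parent
  link <- link_frames(parent, kids)
  expect_equal(nrow(link$divisions), 1L)
  expect_equal(link$divisions$child1 + link$divisions$child2, 3L)
  expect_equal(link$score, 1)   # J(p, c1 u c2) = 1 beats J = 0.5 migration
})

test_that("shifted cells keep their migration mapping", {
  m1 <- make_mask(40, 10, list(c(2, 10, 3, 8), c(14, 22, 3, 8),
                               c(26, 34, 3, 8)))
  m2 <- rbind(matrix(0L, 1, 10), m1[-40, ])   # 1 px down
  link <- link_frames(m1, m2)
  expect_equal(nrow(link$migrations), 3L)
  expect_equal(link$migrations$parent, link$migrations$child)
  expect_equal(nrow(link$divisions), 0L)
})

test_that("link_frames equals the brute-force oracle on small instances", {
  set.seed(11)
  for (case in 1:15) {
    nK <- sample(1:4, 1); nM <- sample(1:4, 1)
    mk <- function(n) {
      m <- matrix(0L, 20, 20)
      for (i in seq_len(n)) {
        r0 <- sample(1:14, 1); c0 <- sample(1:14, 1)
        patch <- m[r0:(r0 + 5), c0:(c0 + 5)]
        patch[patch == 0L] <- i
        m[r0:(r0 + 5), c0:(c0 + 5)] <- patch
      }
      # keep labels 4-connected and non-empty: drop missing ones
      labs <- setdiff(sort(unique(as.vector(m))), 0L)
      m2 <- matrix(0L, 20, 20)
      for (j in seq_along(labs)) m2[m == labs[j]] <- j
      m2
    }
    a <- mk(nK); b <- mk(nM)
    if (max(a) == 0 || max(b) == 0) next
    expect_equal(link_frames(a, b)$score, brute_force_link_score(a, b),
                 tolerance = 1e-9)
  }
})

test_that("build_lineages reconstructs simple histories", {
  # single non-dividing cell spanning all frames
  m <- make_mask(20, 10, list(c(5, 15, 3, 8)))
  fo <- build_lineages(list(m, m, m, m))
  expect_equal(nrow(fo$nodes), 1L)
  expect_equal(fo$nodes$frame_birth, 0L)
  expect_equal(fo$nodes$frame_death, 3L)
  # cell vanishing at frame 2: death frame is 1
  blank <- matrix(0L, 20, 10)
  fo2 <- build_lineages(list(m, m, blank))
  expect_equal(fo2$nodes$frame_death, 1L)
  # division produces two child nodes
  parent <- make_mask(20, 10, list(c(2, 17, 3, 8)))
  kids <- matrix(0L, 20, 10)
  kids[2:9, 3:8] <- 1L; kids[10:17, 3:8] <- 2L
  fo3 <- build_lineages(list(parent, kids, kids))
  expect_equal(nrow(fo3$nodes), 3L)
  expect_true(fo3$nodes$divided[1])
  expect_equal(sort(fo3$nodes$parent_id[-1]), c(1L, 1L))
})

test_that("a lineage tree is reconstructed isomorphic to ground truth", {
  p <- sim_params(n_traps = 1, total_duration_min = 120,
                  trap_length_px = 160, frame_interval_fluo_s = 1200,
                  mean_molecules_per_cell = c(g = 0),
                  genotype_fractions = c(g = 1),
                  noise_gain = 0, read_noise_sd = 0, rng_seed = 13)
  sim <- simulate_trap_timelapse(p)
  rl <- relabel_truth_masks(sim$truth$masks)
  fo <- build_lineages(rl$masks)
  chains <- truth_chains(sim$truth$lineage)
  rec_sets <- node_cell_sets(fo, rl$maps)
  expect_equal(length(rec_sets), length(chains))
  exp_sets <- lapply(chains, function(ch) sort(ch$members))
  key <- function(s) paste(s, collapse = ",")
  expect_setequal(vapply(rec_sets, key, character(1)),
                  vapply(exp_sets, key, character(1)))
  # division structure matches: reconstructed divided nodes correspond to
  # observably divided chains
  expect_equal(sum(fo$nodes$divided),
               sum(vapply(chains, `[[`, logical(1), "divided")))
})

test_that("the four lineage filters fire on their target defects", {
  mk_forest <- function(areas, centroids_row = NULL, parent = NA_integer_,
                        divided = FALSE) {
    n <- length(areas)
    if (is.null(centroids_row)) centroids_row <- seq_len(n)
    structure(list(
      nodes = data.frame(node_id = 1L, parent_id = parent,
                         frame_birth = 0L, frame_death = n - 1L,
                         divided = divided, trap_id = 1L),
      obs = data.frame(node_id = 1L, frame = 0:(n - 1), label = 1L,
                       area_px = areas, centroid_row = centroids_row,
                       centroid_col = 5)),
      class = "lineage_forest")
  }
  fp <- filter_params(min_lifespan_frames = 5)
  # clean node: no rejections
  clean <- mk_forest(100 * exp(0.02 * 0:9))
  res <- filter_lineages(clean, fp)
  expect_equal(res$forest$nodes$filter_flag, "pass")
  expect_equal(nrow(res$log), 0L)
  # rule i: one transient 3x area spike is dropped, node retained
  spiky <- mk_forest(c(100, 100, 300, 100, 100, 100))
  res <- filter_lineages(spiky, fp)
  expect_equal(res$forest$nodes$filter_flag, "pass")
  expect_equal(res$log$rule, "i")
  expect_equal(nrow(res$forest$obs), 5L)
  # rule ii: persistent halving rejects the node
  shift <- mk_forest(c(100, 100, 100, 50, 50, 50))
  res <- filter_lineages(shift, fp)
  expect_equal(res$forest$nodes$filter_flag, "rejected_ii")
  # rule iii: a large centroid jump rejects the node
  jump <- mk_forest(rep(100, 6), centroids_row = c(1, 2, 3, 30, 31, 32))
  res <- filter_lineages(jump, fp)
  expect_equal(res$forest$nodes$filter_flag, "rejected_iii")
  # rule iv: short lifespan rejected ...
  short <- mk_forest(c(100, 102))
  res <- filter_lineages(short, fp)
  expect_equal(res$forest$nodes$filter_flag, "rejected_iv")
  # ... unless the node has both a mother and two daughters
  ctx <- mk_forest(c(100, 102), parent = 7L, divided = TRUE)
  ctx$nodes <- rbind(ctx$nodes,
                     data.frame(node_id = 2:3, parent_id = 1L,
                                frame_birth = 2L, frame_death = 9L,
                                divided = FALSE, trap_id = 1L))
  ctx$obs <- rbind(ctx$obs, data.frame(
    node_id = rep(2:3, each = 8), frame = rep(2:9, 2), label = 1L,
    area_px = 60, centroid_row = 5, centroid_col = 5))
  res <- filter_lineages(ctx, fp)
  expect_equal(res$forest$nodes$filter_flag[1], "pass")
})

test_that("loosening filter thresholds never increases rejections", {
  p <- sim_params(n_traps = 1, total_duration_min = 100,
                  trap_length_px = 160, frame_interval_fluo_s = 1200,
                  mean_molecules_per_cell = c(g = 0),
                  genotype_fractions = c(g = 1), rng_seed = 17)
  sim <- simulate_trap_timelapse(p)
  rl <- relabel_truth_masks(sim$truth$masks)
  fo <- build_lineages(rl$masks)
  n_rej <- function(fp) {
    res <- filter_lineages(fo, fp)
    sum(res$forest$nodes$filter_flag != "pass")
  }
  base <- filter_params(transient_size_jump_frac = 0.2,
                        persistent_size_shift_frac = 0.2,
                        max_com_step_px = 4, min_lifespan_frames = 8)
  loose <- list(
    filter_params(0.5, 0.2, 4, 8), filter_params(0.2, 0.5, 4, 8),
    filter_params(0.2, 0.2, 12, 8), filter_params(0.2, 0.2, 4, 2))
  for (fp in loose) expect_lte(n_rej(fp), n_rej(base))
})

test_that("growth curves report per-node exponential rates and layout", {
  rate <- 0.0231
  areas <- 100 * exp(rate * 0:19)
  fo <- structure(list(
    nodes = data.frame(node_id = 1L, parent_id = NA_integer_,
                       frame_birth = 0L, frame_death = 19L,
                       divided = FALSE, trap_id = 1L),
    obs = data.frame(node_id = 1L, frame = 0:19, label = 1L,
                     area_px = areas, centroid_row = 1, centroid_col = 1)),
    class = "lineage_forest")
  gc <- growth_curves_from_lineage(fo, frame_interval_min = 1)
  expect_equal(gc$summary$rate_per_min, rate, tolerance = 1e-6)
  expect_equal(gc$summary$doubling_time_min, log(2) / rate,
               tolerance = 1e-4)
  expect_true(gc$summary$dashed_end == FALSE)
  # a node observed once has no rate
  fo$obs <- fo$obs[1, ]; fo$nodes$frame_death <- 0L
  gc1 <- growth_curves_from_lineage(fo)
  expect_true(is.na(gc1$summary$rate_per_min))
  expect_equal(nrow(gc1$series), 1L)
})

test_that("leaf count of a reconstructed tree matches ground truth", {
  p <- sim_params(n_traps = 1, total_duration_min = 100,
                  trap_length_px = 160, frame_interval_fluo_s = 1200,
                  mean_molecules_per_cell = c(g = 0),
                  genotype_fractions = c(g = 1), rng_seed = 19)
  sim <- simulate_trap_timelapse(p)
  rl <- relabel_truth_masks(sim$truth$masks)
  fo <- build_lineages(rl$masks)
  gc <- growth_curves_from_lineage(fo)
  chains <- truth_chains(sim$truth$lineage)
  expect_equal(sum(gc$summary$leaf),
               sum(!vapply(chains, `[[`, logical(1), "divided")))
})
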