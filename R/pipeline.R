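# End-to-end driver: simulate -> segment -> track -> spots -> genotype ->
# stats on one synthetic experiment, plus a small command-line front end.

#' Run the full pipeline on a synthetic experiment
#'
#' Simulates a trap time-lapse and sequential FISH rounds, then runs every
#' analysis stage: per-trap segmentation of the phase stack, lineage
#' tracking and filtering, camera-transform estimation from simulated
#' landmarks, spot detection and per-cell assignment on the fluorescence
#' stack, trap genotyping with redundancy-corrected consensus, and
#' genotype-level summary statistics against the simulation's ground
#' truth.
#'
#' @param params a [sim_params].
#' @param codebook a [codebook]; defaults to the three-strain
#'   demonstration codebook.
#' @param n_rounds FISH rounds probed (a multiple of the codeword length).
#' @param miscall optional injected dye flip, `list(trap =, round =)`.
#' @param use_true_masks if `TRUE`, skip segmentation and track on the
#'   ground-truth masks (faster; used by callers that only exercise the
#'   downstream stages).
#' @return A list with the simulation (`sim`, `fish`), per-trap forests
#'   (`forests`), spot assignment table (`spot_counts`), genotyping result
#'   (`genotypes`), confusion counts against truth (`confusion`) and the
#'   sensitivity/specificity intervals (`accuracy`) for the brightest
#'   genotype.
#' @export
run_pipeline <- function(params = sim_params_preset("mini"),
                         codebook = demo_codebook(),
                         n_rounds = 6L, miscall = NULL,
                         use_true_masks = FALSE) {
  sim <- simulate_trap_timelapse(params)
  ivs <- sim$truth$trap_intervals
  n_frames <- length(sim$phase)

  # segmentation + tracking per trap
  forests <- vector("list", params$n_traps)
  empty_ref <- matrix(params$phase_background, nrow(sim$phase$frames[[1]]),
                      ncol(sim$phase$frames[[1]]))
  for (k in seq_len(params$n_traps)) {
    cols <- (ivs[k, "from"] - 2):(ivs[k, "to"] + 2)
    cols <- cols[cols >= 0 & cols < ncol(sim$phase$frames[[1]])]
    masks <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      if (use_true_masks) {
        mk <- sim$truth$masks[[f]][, cols + 1, drop = FALSE]
        # relabel to per-frame ids
        labs <- setdiff(sort(unique(as.vector(mk))), 0L)
        mk2 <- matrix(0L, nrow(mk), ncol(mk))
        for (i in seq_along(labs)) mk2[mk == labs[i]] <- i
        masks[[f]] <- label_mask(mk2, f - 1L)
      } else {
        fr <- sim$phase$frames[[f]][, cols + 1, drop = FALSE]
        corr <- subtract_empty_trap(fr, empty_ref[, cols + 1, drop = FALSE],
                                    max_shift_px = 0L)
        masks[[f]] <- segment_cells(corr)
      }
    }
    forests[[k]] <- build_lineages(masks, trap_id = k)
  }

  # camera registration + spot counting on the fluorescence stack
  lm_pair <- simulate_landmark_pair(params$camera_offset, n_landmarks = 25,
                                    noise_sd = 0.2,
                                    rng_seed = params$rng_seed + 1L)
  tf <- estimate_camera_transform(lm_pair$cam1, lm_pair$cam2)
  phase_per_fluo <- params$frame_interval_fluo_s /
    params$frame_interval_phase_s
  spot_counts <- list()
  for (q in seq_along(sim$fluo$frames)) {
    resp <- radial_symmetry_transform(sim$fluo$frames[[q]])
    sp <- detect_spots(resp, frame_index = q - 1L)
    pf <- as.integer((q - 1L) * phase_per_fluo)
    mask <- sim$truth$masks[[pf + 1L]]
    asg <- assign_spots_to_cells(sp, tf, mask)
    cnt <- asg$counts
    if (nrow(cnt)) {
      cnt$fluo_frame <- q - 1L
      spot_counts[[length(spot_counts) + 1L]] <- cnt
    }
  }
  spot_counts <- if (length(spot_counts)) do.call(rbind, spot_counts) else
    data.frame(cell = integer(), n_spots = integer(),
               fluo_frame = integer())

  # genotyping
  fish <- simulate_fish_rounds(sim$truth$genotypes, codebook, params,
                               n_rounds = n_rounds, miscall = miscall,
                               rng_seed = params$rng_seed + 2L)
  gt <- genotype_traps(fish, codebook,
                       expected_n_traps = params$n_traps)

  # accuracy of the brightest genotype's identification
  bright <- names(which.max(
    params$mean_molecules_per_cell[names(params$genotype_fractions)]))
  conf <- acc <- NULL
  if (bright %in% sim$truth$genotypes) {
    dets <- determinations_table(gt)
    conf <- confusion_counts(dets, sim$truth$genotypes, bright)
    if (conf$n_pos >= 1 && conf$n_neg >= 1)
      acc <- sensitivity_specificity(conf)
  }
  list(sim = sim, fish = fish, forests = forests,
       spot_counts = spot_counts, genotypes = gt, transform = tf,
       confusion = conf, accuracy = acc)
}

#' Per-determination genotype table
#'
#' Expands a `genotype_result` into one row per trap and determination,
#' for determination-level confusion counting.
#'
#' @param result a `genotype_result`.
#' @return `data.frame(trap_id, determination, genotype)`.
#' @export
determinations_table <- function(result) {
  stopifnot(inherits(result, "genotype_result"))
  asg <- result$assignments
  rows <- lapply(seq_len(nrow(asg)), function(i) {
    dets <- strsplit(asg$determinations[i], ";", fixed = TRUE)[[1]]
    dets[dets == "-"] <- NA_character_
    data.frame(trap_id = asg$trap_id[i],
               determination = seq_along(dets), genotype = dets)
  })
  do.call(rbind, rows)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write synthetic TIFF stacks plus ground-truth
#' TSVs), `genotype` (simulate FISH rounds and write barcode calls and
#' assignments), `run-all` (full pipeline and a summary report). Invoked
#' from the `exec/trapline` script as e.g.
#' `trapline simulate --out dir --seed 1 --preset mini`.
#'
#' @param args character vector of command-line arguments.
#' @return 0 on success, invisibly.
#' @export
trapline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: trapline <simulate|genotype|run-all>",
    "[--out DIR] [--seed N] [--preset reference|mini] [--rounds N]")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(name, default) {
    i <- which(args == paste0("--", name))
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  out_dir <- opt("out", ".")
  seed <- as.integer(opt("seed", "1"))
  preset <- opt("preset", "mini")
  n_rounds <- as.integer(opt("rounds", "6"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- sim_params_preset(preset, rng_seed = seed)
  if (cmd == "simulate") {
    sim <- simulate_trap_timelapse(params)
    write_tiff(sim$phase, file.path(out_dir, "phase.tif"))
    write_tiff(sim$fluo, file.path(out_dir, "fluor.tif"))
    write_tiff(lapply(sim$truth$masks, unclass),
               file.path(out_dir, "true_masks.tif"))
    write.table(sim$truth$lineage, file.path(out_dir, "true_lineage.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(sim$truth$spots))
      write.table(sim$truth$spots, file.path(out_dir, "true_spots.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    message("wrote synthetic stacks and ground truth to ", out_dir)
  } else if (cmd == "genotype") {
    cb <- demo_codebook()
    with_seed(seed, {
      genos <- sample(unname(cb$map), params$n_traps, replace = TRUE)
    })
    fish <- simulate_fish_rounds(genos, cb, params, n_rounds = n_rounds)
    gt <- genotype_traps(fish, cb, expected_n_traps = params$n_traps)
    write_genotype_tsv(gt, file.path(out_dir, "genotype"))
    message("wrote barcode calls and assignments to ", out_dir)
  } else if (cmd == "run-all") {
    res <- run_pipeline(params, n_rounds = n_rounds)
    write_genotype_tsv(res$genotypes, file.path(out_dir, "genotype"))
    for (k in seq_along(res$forests))
      write_lineage_tsv(res$forests[[k]],
                        file.path(out_dir, sprintf("trap%03d", k)))
    write.table(res$spot_counts, file.path(out_dir, "spot_counts.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    correct <- sum(res$genotypes$assignments$genotype ==
                     res$sim$truth$genotypes, na.rm = TRUE)
    report <- c(
      sprintf("traps: %d", params$n_traps),
      sprintf("barcode reads: %d", nrow(res$genotypes$calls)),
      sprintf("genotype accuracy: %d/%d", correct, params$n_traps),
      if (!is.null(res$accuracy)) sprintf(
        "sensitivity: %.4f-%.4f  specificity: %.4f-%.4f",
        res$accuracy$sensitivity$lower, res$accuracy$sensitivity$upper,
        res$accuracy$specificity$lower, res$accuracy$specificity$upper))
    writeLines(report, file.path(out_dir, "report.txt"))
    message(paste(report, collapse = "\n"))
  } else {
    message(usage); return(invisible(1L))
  }
  invisible(0L)
}
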