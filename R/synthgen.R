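# Synthetic mother-machine data with full ground truth. Every raster the
# pipeline consumes (phase time-lapse, single-molecule fluorescence, FISH
# rounds, landmark pairs, plate-reader curves) can be generated here, so the
# whole analysis is testable without any raw microscopy download.

# Evaluate `code` with a private RNG stream seeded by `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulation parameters
#'
#' The stated world of the synthetic generator. Defaults follow the
#' reference experiment: 233 traps imaged every 60 s in phase contrast and
#' every 13 min in single-molecule fluorescence for 272 min, cells doubling
#' every 30 min. Geometry, intensities and noise are package choices
#' documented in the methods vignette.
#'
#' @param n_traps number of trap channels in the field of view.
#' @param trap_length_px,trap_width_px trap channel geometry in pixels;
#'   traps are vertical, closed end at the top.
#' @param trap_period_px center-to-center trap spacing in pixels.
#' @param margin_px empty rows above the closed trap end.
#' @param frame_interval_phase_s,frame_interval_fluo_s acquisition cadence
#'   in seconds; the fluorescence interval must be a multiple of the phase
#'   interval.
#' @param total_duration_min experiment duration in minutes.
#' @param growth_rate_per_min exponential cell elongation rate (1/min);
#'   `log(2)/30` is a 30-min doubling time.
#' @param division_length_px deterministic division threshold length.
#' @param division_asymmetry daughter size asymmetry in (0, 1); 0 gives
#'   exact halving.
#' @param cell_gap_px visual gap stacked between neighbouring cells; the
#'   default 0 conserves total column length across divisions (septation
#'   does not push the stack).
#' @param mean_molecules_per_cell named vector: mean true molecule count
#'   per cell per fluorescence frame, one entry per genotype.
#' @param genotype_fractions named simplex over genotype IDs (sums to 1).
#' @param psf_sigma_px Gaussian point-spread-function sigma for rendered
#'   spots.
#' @param spot_intensity peak spot amplitude in camera counts.
#' @param camera_offset true [affine_transform] mapping fluorescence-camera
#'   coordinates to phase-camera coordinates.
#' @param noise_gain camera gain for Poisson shot noise; 0 disables shot
#'   noise.
#' @param read_noise_sd Gaussian read noise standard deviation (counts).
#' @param phase_background,phase_cell_depth phase-contrast background level
#'   and cell darkening (cells are dark on a light background).
#' @param fluo_background fluorescence background level.
#' @param dapi_signal_mean,fish_signal_mean,fish_background per-pixel DAPI
#'   and FISH dye intensities inside the cell band, and FISH background.
#' @param fish_crosstalk_fraction fraction of a trap's FISH signal leaking
#'   into the other dye channel.
#' @param rng_seed integer seed; identical parameters and seed give
#'   bit-identical output.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_traps = 233L,
                       trap_length_px = 100,
                       trap_width_px = 9,
                       trap_period_px = 20,
                       margin_px = 8,
                       frame_interval_phase_s = 60,
                       frame_interval_fluo_s = 780,
                       total_duration_min = 272,
                       growth_rate_per_min = log(2) / 30,
                       division_length_px = 26,
                       division_asymmetry = 0,
                       cell_gap_px = 0,
                       mean_molecules_per_cell = c(lacI_kd = 12, lacY_kd = 0.4,
                                                   no_kd = 4),
                       genotype_fractions = c(lacI_kd = 74 / 233,
                                              lacY_kd = 80 / 233,
                                              no_kd = 79 / 233),
                       psf_sigma_px = 1.3,
                       spot_intensity = 300,
                       camera_offset = affine_transform(diag(2), c(2.5, -1.5)),
                       noise_gain = 1,
                       read_noise_sd = 2,
                       phase_background = 1000,
                       phase_cell_depth = 600,
                       fluo_background = 100,
                       dapi_signal_mean = 3000,
                       fish_signal_mean = 2000,
                       fish_background = 50,
                       fish_crosstalk_fraction = 0.02,
                       rng_seed = 1L) {
  p <- list(n_traps = as.integer(n_traps), trap_length_px = trap_length_px,
            trap_width_px = trap_width_px, trap_period_px = trap_period_px,
            margin_px = margin_px,
            frame_interval_phase_s = frame_interval_phase_s,
            frame_interval_fluo_s = frame_interval_fluo_s,
            total_duration_min = total_duration_min,
            growth_rate_per_min = growth_rate_per_min,
            division_length_px = division_length_px,
            division_asymmetry = division_asymmetry,
            cell_gap_px = cell_gap_px,
            mean_molecules_per_cell = mean_molecules_per_cell,
            genotype_fractions = genotype_fractions,
            psf_sigma_px = psf_sigma_px, spot_intensity = spot_intensity,
            camera_offset = camera_offset, noise_gain = noise_gain,
            read_noise_sd = read_noise_sd,
            phase_background = phase_background,
            phase_cell_depth = phase_cell_depth,
            fluo_background = fluo_background,
            dapi_signal_mean = dapi_signal_mean,
            fish_signal_mean = fish_signal_mean,
            fish_background = fish_background,
            fish_crosstalk_fraction = fish_crosstalk_fraction,
            rng_seed = as.integer(rng_seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  lens <- c(p$trap_length_px, p$trap_width_px, p$trap_period_px,
            p$division_length_px, p$growth_rate_per_min,
            p$frame_interval_phase_s, p$frame_interval_fluo_s,
            p$total_duration_min)
  if (any(lens <= 0)) stop("lengths, rates and intervals must be positive")
  if (p$n_traps < 1L) stop("n_traps must be >= 1")
  if (any(p$mean_molecules_per_cell < 0))
    stop("mean_molecules_per_cell must be non-negative")
  gf <- p$genotype_fractions
  if (is.null(names(gf)) || any(names(gf) == ""))
    stop("genotype_fractions must be named by genotype ID")
  if (abs(sum(gf) - 1) > 1e-9) stop("genotype_fractions must sum to 1")
  if (!all(names(gf) %in% names(p$mean_molecules_per_cell)))
    stop("every genotype needs an entry in mean_molecules_per_cell")
  if (p$total_duration_min * 60 < p$frame_interval_phase_s)
    stop("duration shorter than one phase frame interval")
  if ((p$total_duration_min * 60) %% p$frame_interval_phase_s != 0)
    stop("phase frame interval must divide the total duration")
  if (p$frame_interval_fluo_s %% p$frame_interval_phase_s != 0)
    stop("fluorescence interval must be a multiple of the phase interval")
  if (p$trap_width_px >= p$trap_period_px)
    stop("trap_period_px must exceed trap_width_px")
  if (p$division_asymmetry < 0 || p$division_asymmetry >= 1)
    stop("division_asymmetry must be in [0, 1)")
  invisible(p)
}

#' Preset simulation parameters
#'
#' `"reference"` reproduces the reference experiment's scale: 233 traps,
#' 3 genotypes with 2-bit codes read over 6 FISH rounds in 2 colors.
#' `"mini"` is a small fast configuration for examples and tests.
#'
#' @param preset preset name.
#' @param ... overrides passed on to [sim_params].
#' @return A `sim_params` object.
#' @export
sim_params_preset <- function(preset = c("reference", "mini"), ...) {
  preset <- match.arg(preset)
  switch(preset,
    reference = sim_params(...),
    mini = sim_params(n_traps = 4L, total_duration_min = 60,
                      frame_interval_fluo_s = 600,
                      frame_interval_phase_s = 60, ...))
}

# Half-open column interval [from, to) of each trap, 0-based.
trap_intervals <- function(p) {
  centers <- (seq_len(p$n_traps) - 1) * p$trap_period_px +
    p$trap_period_px / 2
  half <- p$trap_width_px / 2
  cbind(from = floor(centers - half), to = floor(centers - half) +
          p$trap_width_px)
}

frame_dim <- function(p) {
  c(rows = as.integer(p$margin_px + p$trap_length_px + p$margin_px),
    cols = as.integer(p$n_traps * p$trap_period_px))
}

# Fill a spherocylinder (rod) footprint into `frame`: vertical axis at
# column cx (0-based), spanning rows [top, top + len), radius rad.
# `set` receives (frame, idx) and returns the updated frame.
rod_pixels <- function(dim_rc, top, len, cx, rad) {
  r0 <- max(0L, floor(top)); r1 <- min(dim_rc[1] - 1L, ceiling(top + len))
  c0 <- max(0L, floor(cx - rad)); c1 <- min(dim_rc[2] - 1L, ceiling(cx + rad))
  if (r1 < r0 || c1 < c0) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  a1 <- top + rad; a2 <- top + len - rad
  if (a2 < a1) { a1 <- a2 <- top + len / 2 }
  dy <- pmax(pmax(a1 - rr, rr - a2), 0)
  dx <- cc - cx
  inside <- outer(dy^2, dx^2, "+") <= rad^2
  # 1-based linear indices into the frame matrix
  which(inside) -> loc
  if (length(loc) == 0L) return(integer(0))
  lr <- (loc - 1) %% length(rr) + r0
  lc <- (loc - 1) %/% length(rr) + c0
  as.integer(lc * dim_rc[1] + lr + 1)
}

apply_camera_noise <- function(frame, p) {
  v <- as.vector(frame)
  if (p$noise_gain > 0)
    v <- rpois(length(v), pmax(v, 0) * p$noise_gain) / p$noise_gain
  if (p$read_noise_sd > 0)
    v <- v + rnorm(length(v), 0, p$read_noise_sd)
  matrix(pmax(v, 0), nrow(frame), ncol(frame))
}

#' Simulate a mother-machine phase + fluorescence time-lapse
#'
#' Cells are rods (rectangles with semicircular caps) confined to vertical
#' traps. Each cell elongates exponentially at `growth_rate_per_min` and
#' splits into exactly two daughters on reaching `division_length_px`;
#' daughters stack from the closed (top) trap end and cells pushed past the
#' open end leave the trap. All cells in a trap carry the trap's genotype.
#' True molecule counts per cell and fluorescence frame are Poisson with
#' the genotype's mean; each molecule is rendered as a 2-D Gaussian spot on
#' the fluorescence camera after mapping phase coordinates through the
#' inverse of the true camera transform. Poisson shot noise and Gaussian
#' read noise are applied to both channels.
#'
#' @param params a [sim_params] object.
#' @param render_truth_masks if `TRUE` (default) return per-phase-frame
#'   ground-truth label masks (labels are global cell IDs).
#' @return A list of class `sim_timelapse` with elements `phase` and
#'   `fluo` ([image_stack]s) and `truth`: trap genotypes, trap column
#'   intervals, true label masks, lineage table (`cell_id`, `parent_id`,
#'   `frame_birth`, `frame_death`, `trap_id`, `genotype_id`), per-molecule
#'   spot table, per-cell-frame count table, the true camera transform and
#'   the parameters.
#' @export
simulate_trap_timelapse <- function(params, render_truth_masks = TRUE) {
  p <- validate_sim_params(params)
  with_seed(p$rng_seed, {
    dim_rc <- frame_dim(p)
    ivs <- trap_intervals(p)
    centers <- unname((ivs[, "from"] + ivs[, "to"]) / 2 - 0.5)
    rad <- (p$trap_width_px - 1) / 2
    gap <- p$cell_gap_px
    gt_names <- names(p$genotype_fractions)
    trap_geno <- sample(gt_names, p$n_traps, replace = TRUE,
                        prob = p$genotype_fractions)
    phase_times <- seq(0, p$total_duration_min * 60,
                       by = p$frame_interval_phase_s)
    fluo_times <- seq(0, p$total_duration_min * 60,
                      by = p$frame_interval_fluo_s)
    n_frames <- length(phase_times)
    r <- p$growth_rate_per_min

    # per-trap cell state: vectors over live cells, ordered top to bottom
    next_id <- 1L
    state <- vector("list", p$n_traps)
    lineage <- list()
    for (k in seq_len(p$n_traps)) {
      L0 <- p$division_length_px / 2 * 2^runif(1)
      state[[k]] <- list(id = next_id, Lb = L0, tb = 0)
      lineage[[next_id]] <- list(cell_id = next_id, parent_id = NA_integer_,
                                 frame_birth = 0L, frame_death = NA_integer_,
                                 trap_id = k, genotype_id = trap_geno[k])
      next_id <- next_id + 1L
    }

    phase_frames <- vector("list", n_frames)
    masks <- if (render_truth_masks) vector("list", n_frames) else NULL
    obs <- vector("list", n_frames)   # per-frame cell layout for fluo lookup

    for (fi in seq_len(n_frames)) {
      t_min <- phase_times[fi] / 60
      # grow and divide
      for (k in seq_len(p$n_traps)) {
        st <- state[[k]]
        if (length(st$id) == 0L) next
        len <- st$Lb * exp(r * (t_min - st$tb))
        # divisions (a cell can only cross the threshold once per minute)
        div <- which(len >= p$division_length_px)
        if (length(div) > 0L) {
          for (d in rev(div)) {
            f <- if (p$division_asymmetry > 0)
              0.5 + p$division_asymmetry * (runif(1) - 0.5) else 0.5
            parent <- st$id[d]
            lineage[[parent]]$frame_death <- fi - 2L  # last frame undivided
            ids <- c(next_id, next_id + 1L)
            for (j in 1:2) {
              lineage[[ids[j]]] <- list(cell_id = ids[j], parent_id = parent,
                                        frame_birth = fi - 1L,
                                        frame_death = NA_integer_,
                                        trap_id = k,
                                        genotype_id = trap_geno[k])
            }
            next_id <- next_id + 2L
            st$id <- append(st$id[-d], ids, after = d - 1L)
            st$Lb <- append(st$Lb[-d], len[d] * c(f, 1 - f), after = d - 1L)
            st$tb <- append(st$tb[-d], c(t_min, t_min), after = d - 1L)
            len <- st$Lb * exp(r * (t_min - st$tb))
          }
        }
        # stack from the closed end; drop cells fully past the open end
        top <- p$margin_px + c(0, cumsum(len + gap))[seq_along(len)]
        out <- which(top >= p$margin_px + p$trap_length_px)
        if (length(out) > 0L) {
          for (i in out) lineage[[st$id[i]]]$frame_death <- fi - 2L
          st$id <- st$id[-out]; st$Lb <- st$Lb[-out]; st$tb <- st$tb[-out]
          len <- len[-out]; top <- top[-out]
        }
        st$top <- top; st$len <- len
        state[[k]] <- st
      }
      # observations + truth mask + phase render
      frame <- matrix(p$phase_background, dim_rc[1], dim_rc[2])
      mk <- if (render_truth_masks) matrix(0L, dim_rc[1], dim_rc[2]) else NULL
      ob <- list()
      for (k in seq_len(p$n_traps)) {
        st <- state[[k]]
        if (length(st$id) == 0L) next
        for (i in seq_along(st$id)) {
          idx <- rod_pixels(dim_rc, st$top[i], st$len[i], centers[k], rad)
          frame[idx] <- p$phase_background - p$phase_cell_depth
          if (render_truth_masks) mk[idx] <- st$id[i]
          ob[[length(ob) + 1L]] <- c(cell = st$id[i], trap = k,
                                     top = st$top[i], len = st$len[i],
                                     cx = centers[k])
        }
      }
      obs[[fi]] <- if (length(ob)) do.call(rbind, ob) else
        matrix(numeric(0), 0, 5,
               dimnames = list(NULL, c("cell", "trap", "top", "len", "cx")))
      phase_frames[[fi]] <- apply_camera_noise(frame, p)
      if (render_truth_masks) masks[[fi]] <- label_mask(mk, fi - 1L)
    }
    for (i in seq_len(next_id - 1L))
      if (is.na(lineage[[i]]$frame_death))
        lineage[[i]]$frame_death <- n_frames - 1L

    # fluorescence frames at the fluo cadence
    inv_tf <- invert_transform(p$camera_offset)
    fluo_frames <- vector("list", length(fluo_times))
    spot_rows <- list()
    count_rows <- list()
    for (qi in seq_along(fluo_times)) {
      fi <- which(phase_times == fluo_times[qi])
      frame <- matrix(p$fluo_background, dim_rc[1], dim_rc[2])
      ob <- obs[[fi]]
      for (j in seq_len(nrow(ob))) {
        g <- trap_geno[ob[j, "trap"]]
        n_mol <- rpois(1, p$mean_molecules_per_cell[[g]])
        count_rows[[length(count_rows) + 1L]] <-
          data.frame(fluo_frame = qi - 1L, phase_frame = fi - 1L,
                     time_s = fluo_times[qi], trap_id = ob[j, "trap"],
                     cell_id = as.integer(ob[j, "cell"]), n_molecules = n_mol)
        if (n_mol == 0L) next
        # rejection-sample uniform positions inside the rod
        got <- 0L
        pos <- matrix(0, n_mol, 2)
        rad_i <- rad; topj <- ob[j, "top"]; lenj <- ob[j, "len"]
        cxj <- ob[j, "cx"]
        a1 <- topj + rad_i; a2 <- max(topj + lenj - rad_i, a1)
        while (got < n_mol) {
          y <- runif(1, topj, topj + lenj)
          x <- runif(1, -rad_i, rad_i)
          dy <- max(a1 - y, y - a2, 0)
          if (dy^2 + x^2 <= rad_i^2) {
            got <- got + 1L
            pos[got, ] <- c(y, cxj + x)
          }
        }
        fl <- apply_transform(inv_tf, pos)
        for (m in seq_len(n_mol)) {
          spot_rows[[length(spot_rows) + 1L]] <-
            data.frame(fluo_frame = qi - 1L, phase_frame = fi - 1L,
                       trap_id = ob[j, "trap"],
                       cell_id = as.integer(ob[j, "cell"]),
                       row_phase = pos[m, 1], col_phase = pos[m, 2],
                       row_fluo = fl[m, 1], col_fluo = fl[m, 2])
          frame <- add_gaussian_spot(frame, fl[m, 1], fl[m, 2],
                                     p$spot_intensity, p$psf_sigma_px)
        }
      }
      fluo_frames[[qi]] <- apply_camera_noise(frame, p)
    }

    truth <- list(
      genotypes = trap_geno,
      trap_intervals = ivs,
      masks = masks,
      lineage = do.call(rbind, lapply(lineage, as.data.frame)),
      spots = if (length(spot_rows)) do.call(rbind, spot_rows) else NULL,
      counts = if (length(count_rows)) do.call(rbind, count_rows) else NULL,
      transform = p$camera_offset,
      params = p)
    structure(
      list(phase = image_stack(phase_frames, "phase", phase_times, 0.1),
           fluo = image_stack(fluo_frames, "fluor", fluo_times, 0.1),
           truth = truth),
      class = "sim_timelapse")
  })
}

# Add a 2-D Gaussian of amplitude `amp`, sigma `sigma` centred at
# (r0, c0) (0-based) to `frame`, truncated at 4 sigma.
add_gaussian_spot <- function(frame, r0, c0, amp, sigma) {
  ext <- ceiling(4 * sigma)
  rr <- max(0, floor(r0 - ext)):min(nrow(frame) - 1, ceiling(r0 + ext))
  cc <- max(0, floor(c0 - ext)):min(ncol(frame) - 1, ceiling(c0 + ext))
  if (length(rr) == 0L || length(cc) == 0L) return(frame)
  g <- outer(exp(-(rr - r0)^2 / (2 * sigma^2)),
             exp(-(cc - c0)^2 / (2 * sigma^2)))
  frame[rr + 1, cc + 1] <- frame[rr + 1, cc + 1] + amp * g
  frame
}

#' Simulate sequential FISH rounds for fixed trapped cells
#'
#' For each probing round every trap emits signal in the dye channel
#' dictated by the corresponding symbol of its genotype's codeword (Cy3
#' encodes 1, Cy5 encodes 0), plus a crosstalk fraction in the other dye.
#' DAPI stains the fixed cell band of every occupied trap. An optional
#' injected miscall swaps the dyes of one trap in one round, emulating a
#' single barcode read error.
#'
#' @param trap_genotypes character vector of genotype IDs, one per trap;
#'   all must exist in `codebook`.
#' @param codebook a [codebook].
#' @param params a [sim_params]; `n_traps` is taken from
#'   `length(trap_genotypes)`.
#' @param n_rounds number of probing rounds; must be a multiple of the
#'   codeword length (codes are re-probed cyclically).
#' @param miscall `NULL` or `list(trap =, round =)` naming the single
#'   injected dye flip.
#' @param rng_seed seed for the camera noise.
#' @return A list of class `sim_fish` with `rounds` (per round: `dapi`,
#'   `cy3`, `cy5` single-frame [image_stack]s), `bits` (trap_id, round,
#'   bit_true, bit_emitted, flipped), `trap_intervals`, `genotypes`,
#'   `codebook`.
#' @export
simulate_fish_rounds <- function(trap_genotypes, codebook,
                                 params = sim_params(),
                                 n_rounds = NULL, miscall = NULL,
                                 rng_seed = params$rng_seed) {
  stopifnot(inherits(codebook, "codebook"))
  codes <- codebook_lookup_code(codebook, trap_genotypes)
  if (anyNA(codes)) stop("trap genotype absent from codebook: ",
                         paste(unique(trap_genotypes[is.na(codes)]),
                               collapse = ", "))
  p <- params
  p$n_traps <- length(trap_genotypes)
  validate_sim_params(p)
  len <- codebook$rounds
  if (is.null(n_rounds)) n_rounds <- len
  if (n_rounds %% len != 0)
    stop(sprintf("codeword length %d does not divide %d requested rounds",
                 len, n_rounds))
  bit_mat <- t(vapply(codes, function(cd)
    rep(strsplit(cd, "")[[1]], n_rounds / len), character(n_rounds)))
  emitted <- bit_mat
  if (!is.null(miscall)) {
    k <- miscall$trap; r <- miscall$round
    stopifnot(k >= 1, k <= p$n_traps, r >= 1, r <= n_rounds)
    emitted[k, r] <- if (bit_mat[k, r] == "1") "0" else "1"
  }
  with_seed(rng_seed, {
    dim_rc <- frame_dim(p)
    ivs <- trap_intervals(p)
    band_rows <- (p$margin_px + 1):(p$margin_px + round(0.8 * p$trap_length_px))
    paint <- function(values_per_trap, background) {
      f <- matrix(background, dim_rc[1], dim_rc[2])
      for (k in seq_len(p$n_traps)) {
        cols <- (ivs[k, "from"] + 1):ivs[k, "to"]
        f[band_rows, cols] <- f[band_rows, cols] + values_per_trap[k]
      }
      f
    }
    rounds <- vector("list", n_rounds)
    for (r in seq_len(n_rounds)) {
      is1 <- emitted[, r] == "1"
      cy3 <- p$fish_signal_mean *
        ifelse(is1, 1, p$fish_crosstalk_fraction)
      cy5 <- p$fish_signal_mean *
        ifelse(is1, p$fish_crosstalk_fraction, 1)
      rounds[[r]] <- list(
        dapi = image_stack(list(apply_camera_noise(
          paint(rep(p$dapi_signal_mean, p$n_traps), p$fish_background), p)),
          "DAPI", r - 1),
        cy3 = image_stack(list(apply_camera_noise(
          paint(cy3, p$fish_background), p)), "Cy3", r - 1),
        cy5 = image_stack(list(apply_camera_noise(
          paint(cy5, p$fish_background), p)), "Cy5", r - 1))
    }
    bits <- data.frame(
      trap_id = rep(seq_len(p$n_traps), n_rounds),
      round = rep(seq_len(n_rounds), each = p$n_traps),
      bit_true = as.vector(bit_mat),
      bit_emitted = as.vector(emitted))
    bits$flipped <- bits$bit_true != bits$bit_emitted
    structure(list(rounds = rounds, bits = bits, trap_intervals = ivs,
                   genotypes = trap_genotypes, codebook = codebook,
                   params = p),
              class = "sim_fish")
  })
}

#' Simulate matched landmark coordinates on two cameras
#'
#' @param true_transform an [affine_transform] mapping camera-1 to camera-2
#'   coordinates.
#' @param n_landmarks number of landmark pairs (>= 3, non-collinear by
#'   construction).
#' @param noise_sd Gaussian localization noise (pixels) on camera 2.
#' @param rng_seed seed.
#' @param extent field-of-view extent (rows, cols) the landmarks span.
#' @return `list(cam1 =, cam2 =)` of n x 2 coordinate matrices.
#' @export
simulate_landmark_pair <- function(true_transform, n_landmarks = 50,
                                   noise_sd = 0.5, rng_seed = 1L,
                                   extent = c(512, 512)) {
  if (n_landmarks < 3) stop("at least 3 landmarks are required")
  with_seed(rng_seed, {
    repeat {
      p1 <- cbind(runif(n_landmarks, 0, extent[1]),
                  runif(n_landmarks, 0, extent[2]))
      if (qr(cbind(p1, 1))$rank == 3) break
    }
    p2 <- apply_transform(true_transform, p1)
    if (noise_sd > 0)
      p2 <- p2 + matrix(rnorm(2 * n_landmarks, 0, noise_sd), ncol = 2)
    list(cam1 = p1, cam2 = p2)
  })
}

#' Simulate a plate-reader growth curve
#'
#' Logistic OD curve whose exponential-phase slope equals
#' `log(2)/doubling_time_min`, with fluorescence proportional to cell
#' density plus instrument background. `plateau_od = Inf` yields a pure
#' exponential.
#'
#' @param doubling_time_min exponential-phase doubling time (minutes).
#' @param lag_min lag phase duration before growth starts.
#' @param plateau_od carrying capacity of cell OD (above blank).
#' @param fluo_per_od steady-state fluorescence per unit cell OD.
#' @param n_timepoints number of 5-min-cadence measurements.
#' @param noise Gaussian measurement noise sd, applied to OD (scaled by
#'   1e-3) and fluorescence (absolute).
#' @param od0 inoculum cell OD.
#' @param blank_od,blank_fluo medium background absorption / fluorescence.
#' @param dt_min measurement cadence in minutes.
#' @param well well identifier.
#' @param rng_seed seed.
#' @return A `growth_curve` (see [growth_curve]).
#' @export
simulate_growth_curves <- function(doubling_time_min = 30, lag_min = 60,
                                   plateau_od = 1.0, fluo_per_od = 1000,
                                   n_timepoints = 241, noise = 0,
                                   od0 = 0.01, blank_od = 0.04,
                                   blank_fluo = 50, dt_min = 5,
                                   well = "A1", rng_seed = 1L) {
  if (doubling_time_min <= 0) stop("doubling_time_min must be positive")
  r <- log(2) / doubling_time_min
  times <- seq(0, by = dt_min, length.out = n_timepoints)
  te <- pmax(times - lag_min, 0)
  x <- if (is.finite(plateau_od)) {
    plateau_od * od0 * exp(r * te) / (plateau_od + od0 * (exp(r * te) - 1))
  } else od0 * exp(r * te)
  with_seed(rng_seed, {
    od <- blank_od + x
    fluo <- blank_fluo + fluo_per_od * x
    if (noise > 0) {
      od <- od + rnorm(n_timepoints, 0, noise * 1e-3)
      fluo <- fluo + rnorm(n_timepoints, 0, noise)
    }
    growth_curve(times, od, fluo, blank_od = blank_od,
                 blank_fluo = blank_fluo, well = well)
  })
}
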