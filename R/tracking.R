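# Lineage tracking: Jaccard-scored linking of per-frame label masks with
# migration and binary-fission division hypotheses solved exactly per frame
# pair, followed by four lineage-quality filters.

#' Jaccard index of two pixel sets
#'
#' `|A n B| / |A u B|`; defined as 0 when both sets are empty.
#'
#' @param maskA,maskB logical matrices on the same grid.
#' @return A real in `[0, 1]`.
#' @export
jaccard_index <- function(maskA, maskB) {
  if (!all(dim(maskA) == dim(maskB)))
    stop("masks must be on the same raster grid")
  u <- sum(maskA | maskB)
  if (u == 0) return(0)
  sum(maskA & maskB) / u
}

# Pairwise overlap bookkeeping between two label masks:
# areas of each label and the joint overlap table.
overlap_table <- function(mask_t, mask_t1) {
  labs_t <- setdiff(sort(unique(as.vector(mask_t))), 0L)
  labs_t1 <- setdiff(sort(unique(as.vector(mask_t1))), 0L)
  a <- tabulate(mask_t[mask_t > 0], max(c(labs_t, 1L)))
  b <- tabulate(mask_t1[mask_t1 > 0], max(c(labs_t1, 1L)))
  both <- mask_t > 0 & mask_t1 > 0
  ov <- matrix(0, length(labs_t), length(labs_t1),
               dimnames = list(labs_t, labs_t1))
  if (any(both)) {
    ia <- match(mask_t[both], labs_t)
    ib <- match(mask_t1[both], labs_t1)
    cnt <- tabulate((ib - 1L) * length(labs_t) + ia,
                    length(labs_t) * length(labs_t1))
    ov[] <- cnt
  }
  list(labs_t = labs_t, labs_t1 = labs_t1,
       area_t = a[labs_t], area_t1 = b[labs_t1], overlap = ov)
}

#' Link the cells of two consecutive frames
#'
#' Each cell at time t maps to 0 (death/exit), 1 (migration) or exactly 2
#' (binary-fission division) cells at t+1, and each t+1 cell has at most
#' one parent. The assignment maximizes the total Jaccard score, where a
#' migration (p -> c) scores `J(p, c)` and a division (p -> c1, c2) scores
#' `J(p, c1 u c2)` and requires positive overlap with both daughters. The
#' optimum is found exactly by dynamic programming over parents and used
#' child subsets (trap-scale instances are small).
#'
#' @param mask_t,mask_t1 [label_mask]s (or integer matrices) of two
#'   consecutive frames of the same trap.
#' @return A list: `migrations` (parent, child), `divisions` (parent,
#'   child1, child2), `deaths` (parents unmatched), `entrants` (children
#'   unmatched), `score`.
#' @export
link_frames <- function(mask_t, mask_t1) {
  ot <- overlap_table(mask_t, mask_t1)
  K <- length(ot$labs_t); M <- length(ot$labs_t1)
  if (M > 18) stop("too many cells in one frame for exact linking")
  empty <- list(
    migrations = data.frame(parent = integer(), child = integer()),
    divisions = data.frame(parent = integer(), child1 = integer(),
                           child2 = integer()),
    deaths = ot$labs_t, entrants = ot$labs_t1, score = 0)
  if (K == 0L || M == 0L) return(empty)
  jac <- ot$overlap /
    (outer(ot$area_t, ot$area_t1, "+") - ot$overlap)
  # candidate children per parent: positive overlap only
  cand <- lapply(seq_len(K), function(i) which(ot$overlap[i, ] > 0))
  div_score <- function(i, j, k) {
    o <- ot$overlap[i, j] + ot$overlap[i, k]
    o / (ot$area_t[i] + ot$area_t1[j] + ot$area_t1[k] - o)
  }
  # options per parent: action code 0 = unmatched, j = migration to j,
  # j + k*32 = division into (j, k). Enumerated in a fixed order so that
  # score ties resolve towards the earliest (topmost) children.
  options <- lapply(seq_len(K), function(i) {
    cc <- cand[[i]]
    opts <- list(list(act = c(0L, 0L), bits = 0L, sc = 0))
    for (j in cc)
      opts[[length(opts) + 1L]] <- list(act = c(j, 0L),
                                        bits = bitwShiftL(1L, j - 1L),
                                        sc = jac[i, j])
    if (length(cc) >= 2) {
      for (aj in seq_len(length(cc) - 1)) {
        for (bk in (aj + 1):length(cc)) {
          j <- cc[aj]; k <- cc[bk]
          opts[[length(opts) + 1L]] <- list(
            act = c(j, k),
            bits = bitwOr(bitwShiftL(1L, j - 1L), bitwShiftL(1L, k - 1L)),
            sc = div_score(i, j, k))
        }
      }
    }
    opts
  })
  # flatten options to parallel vectors for a tight inner loop
  opt_bits <- lapply(options, function(o) vapply(o, `[[`, integer(1), "bits"))
  opt_sc <- lapply(options, function(o) vapply(o, `[[`, numeric(1), "sc"))
  n_states <- bitwShiftL(1L, M)
  score_mat <- matrix(NA_real_, K + 1L, n_states)
  choice_mat <- matrix(0L, K, n_states)
  score_mat[K + 1L, ] <- 0
  dp <- function(i, used) {
    hit <- score_mat[i, used + 1L]
    if (!is.na(hit)) return(hit)
    best <- -Inf; best_o <- 1L
    bits <- opt_bits[[i]]; scs <- opt_sc[[i]]
    for (o in seq_along(bits)) {
      b <- bits[o]
      if (b != 0L && bitwAnd(used, b) != 0L) next
      nxt <- bitwOr(used, b)
      rest <- score_mat[i + 1L, nxt + 1L]
      if (is.na(rest)) rest <- dp(i + 1L, nxt)
      sc <- scs[o] + rest
      if (sc > best + 1e-12) { best <- sc; best_o <- o }
    }
    score_mat[i, used + 1L] <<- best
    choice_mat[i, used + 1L] <<- best_o
    best
  }
  total <- dp(1L, 0L)
  mig <- div <- list()
  used_children <- integer(0)
  matched_parents <- integer(0)
  used <- 0L
  for (i in seq_len(K)) {
    op <- options[[i]][[choice_mat[i, used + 1L]]]
    used <- bitwOr(used, op$bits)
    if (op$act[1] == 0L) next
    matched_parents <- c(matched_parents, i)
    if (op$act[2] == 0L) {
      mig[[length(mig) + 1L]] <- data.frame(
        parent = ot$labs_t[i], child = ot$labs_t1[op$act[1]])
      used_children <- c(used_children, op$act[1])
    } else {
      div[[length(div) + 1L]] <- data.frame(
        parent = ot$labs_t[i], child1 = ot$labs_t1[op$act[1]],
        child2 = ot$labs_t1[op$act[2]])
      used_children <- c(used_children, op$act)
    }
  }
  list(
    migrations = if (length(mig)) do.call(rbind, mig) else empty$migrations,
    divisions = if (length(div)) do.call(rbind, div) else empty$divisions,
    deaths = ot$labs_t[setdiff(seq_len(K), matched_parents)],
    entrants = ot$labs_t1[setdiff(seq_len(M), used_children)],
    score = total)
}

#' Build a lineage forest from a mask sequence
#'
#' Stitches the pairwise [link_frames] assignments of one trap into rooted
#' trees of cell generations. A node is one cell generation: its
#' observations run on consecutive frames from birth (first frame or
#' division) to death (division, exit or end of movie). Roots are
#' first-frame cells or later entrants; every internal node has exactly two
#' children.
#'
#' @param masks list of [label_mask]s, one per frame, same trap.
#' @param trap_id trap identifier stored on every node.
#' @return An object of class `lineage_forest`: `nodes` (node_id,
#'   parent_id, frame_birth, frame_death, divided, trap_id) and `obs`
#'   (node_id, frame, label, area_px, centroid_row, centroid_col).
#' @export
build_lineages <- function(masks, trap_id = 1L) {
  stopifnot(length(masks) >= 1L)
  nodes <- list()
  obs <- list()
  new_node <- function(parent_id, frame) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(node_id = id, parent_id = parent_id,
                         frame_birth = frame, frame_death = frame,
                         divided = FALSE, trap_id = trap_id)
    id
  }
  # active: label -> node id on the current frame
  props0 <- mask_properties(masks[[1]])
  active <- stats::setNames(integer(0), character(0))
  record <- function(node_id, frame, label, props) {
    i <- match(label, props$label)
    nodes[[node_id]]$frame_death <<- frame
    obs[[length(obs) + 1L]] <<- data.frame(
      node_id = node_id, frame = frame, label = label,
      area_px = props$area_px[i],
      centroid_row = props$centroid_row[i],
      centroid_col = props$centroid_col[i])
  }
  for (l in props0$label) {
    id <- new_node(NA_integer_, 0L)
    record(id, 0L, l, props0)
    active[as.character(l)] <- id
  }
  n_frames <- length(masks)
  if (n_frames >= 2) {
    for (f in 2:n_frames) {
      link <- link_frames(masks[[f - 1]], masks[[f]])
      props <- mask_properties(masks[[f]])
      nxt <- stats::setNames(integer(0), character(0))
      for (i in seq_len(nrow(link$migrations))) {
        p <- link$migrations$parent[i]; c1 <- link$migrations$child[i]
        id <- active[[as.character(p)]]
        record(id, f - 1L, c1, props)
        nxt[as.character(c1)] <- id
      }
      for (i in seq_len(nrow(link$divisions))) {
        p <- link$divisions$parent[i]
        pid <- active[[as.character(p)]]
        nodes[[pid]]$divided <- TRUE
        for (c1 in c(link$divisions$child1[i], link$divisions$child2[i])) {
          id <- new_node(pid, f - 1L)
          record(id, f - 1L, c1, props)
          nxt[as.character(c1)] <- id
        }
      }
      for (c1 in link$entrants) {
        id <- new_node(NA_integer_, f - 1L)
        record(id, f - 1L, c1, props)
        nxt[as.character(c1)] <- id
      }
      active <- nxt
    }
  }
  nodes_df <- do.call(rbind, lapply(nodes, as.data.frame))
  obs_df <- do.call(rbind, obs)
  obs_df <- obs_df[order(obs_df$node_id, obs_df$frame), ]
  rownames(obs_df) <- NULL
  structure(list(nodes = nodes_df, obs = obs_df),
            class = "lineage_forest")
}

#' @export
print.lineage_forest <- function(x, ...) {
  cat(sprintf("<lineage_forest> %d node(s), %d observation(s), frames %d..%d\n",
              nrow(x$nodes), nrow(x$obs), min(x$nodes$frame_birth),
              max(x$nodes$frame_death)))
  invisible(x)
}

#' Lineage filter thresholds
#'
#' Thresholds of the four lineage-quality rules. The rules come from the
#' tracking literature; the numerical defaults are package choices
#' calibrated on synthetic fixtures.
#'
#' @param transient_size_jump_frac rule i: drop single observations whose
#'   area deviates by more than this fraction from the median of a
#'   5-observation centered window.
#' @param persistent_size_shift_frac rule ii: reject generations whose area
#'   shifts persistently between consecutive observations by more than this
#'   fraction.
#' @param max_com_step_px rule iii: reject generations with any
#'   center-of-mass step larger than this (about one cell width).
#' @param min_lifespan_frames rule iv: reject generations observed for
#'   fewer frames, unless they have both a mother and two daughters.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(transient_size_jump_frac = 0.3,
                          persistent_size_shift_frac = 0.3,
                          max_com_step_px = 9,
                          min_lifespan_frames = 5) {
  stopifnot(transient_size_jump_frac > 0, persistent_size_shift_frac > 0,
            max_com_step_px > 0, min_lifespan_frames > 0)
  structure(list(transient_size_jump_frac = transient_size_jump_frac,
                 persistent_size_shift_frac = persistent_size_shift_frac,
                 max_com_step_px = max_com_step_px,
                 min_lifespan_frames = min_lifespan_frames),
            class = "filter_params")
}

running_median <- function(x, half = 2L) {
  n <- length(x)
  vapply(seq_len(n), function(i)
    median(x[max(1, i - half):min(n, i + half)]), numeric(1))
}

#' Apply the four lineage-quality filters
#'
#' Rule i drops individual observations with transient area excursions
#' (missegmentation); rule ii rejects generations with persistent area
#' shifts; rule iii rejects generations with large center-of-mass
#' movements; rule iv rejects very short-lived generations unless they
#' contain both a mother and two daughter cells.
#'
#' @param forest a [lineage_forest].
#' @param params a [filter_params].
#' @return `list(forest =, log =)`: the forest with dropped observations
#'   removed and a `filter_flag` column on its nodes (`pass`,
#'   `rejected_ii`, `rejected_iii`, `rejected_iv`), plus a rejection log
#'   (node_id, rule, detail).
#' @export
filter_lineages <- function(forest, params = filter_params()) {
  stopifnot(inherits(forest, "lineage_forest"))
  log_rows <- list()
  note <- function(node_id, rule, detail)
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      node_id = node_id, rule = rule, detail = detail)
  obs <- forest$obs
  drop_idx <- integer(0)
  for (id in forest$nodes$node_id) {
    sel <- which(obs$node_id == id)
    a <- obs$area_px[sel]
    if (length(a) >= 3) {
      med <- running_median(a)
      bad <- abs(a - med) / med > params$transient_size_jump_frac
      if (any(bad)) {
        drop_idx <- c(drop_idx, sel[bad])
        note(id, "i", sprintf("%d transient size excursion(s) dropped",
                              sum(bad)))
      }
    }
  }
  if (length(drop_idx)) obs <- obs[-drop_idx, ]
  nodes <- forest$nodes
  has_children <- nodes$node_id %in% nodes$parent_id[!is.na(nodes$parent_id)]
  flag <- rep("pass", nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    id <- nodes$node_id[i]
    sel <- which(obs$node_id == id)
    a <- obs$area_px[sel]
    # rule ii: persistent size shift between consecutive observations
    if (length(a) >= 2) {
      rel <- abs(diff(a)) / head(a, -1)
      persistent <- vapply(seq_along(rel), function(t) {
        if (rel[t] <= params$persistent_size_shift_frac) return(FALSE)
        pre <- median(a[max(1, t - 2):t])
        post_idx <- (t + 1):min(length(a), t + 3)
        post <- median(a[post_idx])
        # shift must hold over the following observations, not spike back
        abs(post - pre) / pre > params$persistent_size_shift_frac
      }, logical(1))
      if (any(persistent)) {
        flag[i] <- "rejected_ii"
        note(id, "ii", sprintf("persistent area shift at observation %d",
                               which(persistent)[1]))
        next
      }
    }
    # rule iii: center-of-mass steps
    if (length(sel) >= 2) {
      step <- sqrt(diff(obs$centroid_row[sel])^2 +
                     diff(obs$centroid_col[sel])^2)
      if (any(step > params$max_com_step_px)) {
        flag[i] <- "rejected_iii"
        note(id, "iii", sprintf("max centroid step %.1f px", max(step)))
        next
      }
    }
    # rule iv: short lifespan without mother-and-daughters context
    lifespan <- nodes$frame_death[i] - nodes$frame_birth[i] + 1L
    if (lifespan < params$min_lifespan_frames &&
        !(!is.na(nodes$parent_id[i]) && nodes$divided[i] &&
          has_children[i])) {
      flag[i] <- "rejected_iv"
      note(id, "iv", sprintf("lifespan %d frame(s)", lifespan))
    }
  }
  nodes$filter_flag <- flag
  out <- structure(list(nodes = nodes, obs = obs),
                   class = "lineage_forest")
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(node_id = integer(), rule = character(),
               detail = character())
  list(forest = out, log = log_df)
}

#' Per-generation growth curves and tree layout
#'
#' One (time, area) series per generation node of a filtered forest, with a
#' log-linear growth-rate fit where at least two observations exist, plus a
#' tree layout table for family-tree plotting. Branches that leave
#' detection before the end of the movie are flagged `dashed_end`.
#'
#' @param forest a [lineage_forest] (pass-flagged nodes only are fitted if
#'   a `filter_flag` column is present).
#' @param frame_interval_min minutes per frame for the time axis.
#' @return `list(series =, summary =)`: per-observation series (node_id,
#'   frame, time_min, area_px) and per-node summary (node_id, parent_id,
#'   n_obs, rate_per_min, doubling_time_min, depth, leaf, dashed_end).
#' @export
growth_curves_from_lineage <- function(forest, frame_interval_min = 1) {
  stopifnot(inherits(forest, "lineage_forest"))
  nodes <- forest$nodes
  keep <- if ("filter_flag" %in% names(nodes))
    nodes$node_id[nodes$filter_flag == "pass"] else nodes$node_id
  obs <- forest$obs[forest$obs$node_id %in% keep, ]
  series <- data.frame(node_id = obs$node_id, frame = obs$frame,
                       time_min = obs$frame * frame_interval_min,
                       area_px = obs$area_px)
  last_frame <- max(nodes$frame_death)
  depth_of <- function(id) {
    d <- 0L
    while (!is.na(nodes$parent_id[match(id, nodes$node_id)])) {
      id <- nodes$parent_id[match(id, nodes$node_id)]
      d <- d + 1L
    }
    d
  }
  summ <- lapply(keep, function(id) {
    s <- series[series$node_id == id, ]
    rate <- NA_real_
    if (nrow(s) >= 2 && all(s$area_px > 0)) {
      fit <- lm(log(s$area_px) ~ s$time_min)
      rate <- unname(coef(fit)[2])
    }
    i <- match(id, nodes$node_id)
    data.frame(node_id = id, parent_id = nodes$parent_id[i],
               n_obs = nrow(s), rate_per_min = rate,
               doubling_time_min = ifelse(is.na(rate) || rate <= 0,
                                          NA_real_, log(2) / rate),
               depth = depth_of(id),
               leaf = !nodes$divided[i],
               dashed_end = !nodes$divided[i] &&
                 nodes$frame_death[i] < last_frame)
  })
  list(series = series, summary = do.call(rbind, summ))
}
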