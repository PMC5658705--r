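# Shared fixtures and independent oracles, all built in code.

# Relabel ground-truth masks (global cell IDs) to per-frame labels 1..K,
# returning the masks plus per-frame label -> cell_id maps.
relabel_truth_masks <- function(truth_masks) {
  maps <- vector("list", length(truth_masks))
  masks <- vector("list", length(truth_masks))
  for (f in seq_along(truth_masks)) {
    mk <- truth_masks[[f]]
    labs <- setdiff(sort(unique(as.vector(mk))), 0L)
    m2 <- matrix(0L, nrow(mk), ncol(mk))
    for (i in seq_along(labs)) m2[mk == labs[i]] <- i
    masks[[f]] <- label_mask(m2, f - 1L)
    maps[[f]] <- labs   # position i holds the cell_id of label i
  }
  list(masks = masks, maps = maps)
}

# Render a frame with rods at given (top, length, center-col), dark cells
# on a light background (no noise).
render_rod_frame <- function(nrow_px, ncol_px, rods, bg = 1000, depth = 600,
                             radius = 4) {
  fr <- matrix(bg, nrow_px, ncol_px)
  for (i in seq_len(nrow(rods))) {
    idx <- trapline:::rod_pixels(c(nrow_px, ncol_px), rods[i, 1], rods[i, 2],
                                 rods[i, 3], radius)
    fr[idx] <- bg - depth
  }
  fr
}

# Brute-force oracle for link_frames: enumerate every legal assignment
# (parent -> none, one child, or an overlap-positive pair of children;
# children used at most once) and return the maximum total score.
brute_force_link_score <- function(mask_t, mask_t1) {
  labs_t <- setdiff(sort(unique(as.vector(mask_t))), 0L)
  labs_t1 <- setdiff(sort(unique(as.vector(mask_t1))), 0L)
  K <- length(labs_t); M <- length(labs_t1)
  if (K == 0 || M == 0) return(0)
  jac <- function(p, cs) {
    a <- mask_t == p
    b <- array(FALSE, dim(mask_t1))
    for (cc in cs) b <- b | mask_t1 == cc
    u <- sum(a | b)
    if (u == 0) 0 else sum(a & b) / u
  }
  best <- -Inf
  rec <- function(i, used, acc) {
    if (i > K) { best <<- max(best, acc); return(invisible()) }
    rec(i + 1, used, acc)                      # unmatched parent
    for (j in setdiff(seq_len(M), used)) {
      rec(i + 1, c(used, j), acc + jac(labs_t[i], labs_t1[j]))
      for (k in setdiff(seq_len(M), c(used, j))) {
        if (k <= j) next
        if (jac(labs_t[i], labs_t1[j]) > 0 &&
            jac(labs_t[i], labs_t1[k]) > 0)
          rec(i + 1, c(used, j, k),
              acc + jac(labs_t[i], labs_t1[c(j, k)]))
      }
    }
  }
  rec(1, integer(0), 0)
  best
}

# Observable-truth oracle for lineage reconstruction: collapse the true
# lineage to what the masks show. A cell is observable when it has at
# least one observed frame; a division is observable when both daughters
# are observable; a lone observable daughter continues its parent's chain.
# Returns, per chain, the set of member cell_ids plus parent chain links.
truth_chains <- function(lineage) {
  lin <- lineage
  obs_ok <- lin$frame_death >= lin$frame_birth
  observable <- lin$cell_id[obs_ok]
  kids_of <- function(cid) {
    k <- lin$cell_id[!is.na(lin$parent_id) & lin$parent_id == cid]
    k[k %in% observable]
  }
  chains <- list()
  # a cell continues its parent's chain iff it is the parent's only
  # observable daughter; otherwise it starts a chain
  continues <- function(cid) {
    p <- lin$parent_id[lin$cell_id == cid]
    !is.na(p) && p %in% observable && length(kids_of(p)) == 1
  }
  starts <- Filter(function(cid) !continues(cid), observable)
  for (s in starts) {
    members <- s
    cur <- s
    repeat {
      k <- kids_of(cur)
      if (length(k) == 1) { members <- c(members, k); cur <- k }
      else break
    }
    chains[[length(chains) + 1L]] <- list(
      members = members,
      divided = length(kids_of(cur)) == 2)
  }
  chains
}

# Map reconstructed forest nodes to sets of true cell IDs via the
# per-frame label maps; returns a list of sorted cell-id vectors.
node_cell_sets <- function(forest, maps) {
  lapply(forest$nodes$node_id, function(id) {
    o <- forest$obs[forest$obs$node_id == id, ]
    sort(unique(vapply(seq_len(nrow(o)), function(i)
      maps[[o$frame[i] + 1L]][o$label[i]], numeric(1))))
  })
}

# Independent Clopper-Pearson oracle by binomial tail root-finding.
cp_oracle <- function(x, n, conf = 0.95) {
  a <- 1 - conf
  lower <- if (x == 0) 0 else
    uniroot(function(p) stats::pbinom(x - 1, n, p, lower.tail = FALSE) -
              a / 2, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (x == n) 1 else
    uniroot(function(p) stats::pbinom(x, n, p) - a / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}
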