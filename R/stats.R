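# Genotype-calling accuracy statistics (exact binomial intervals over
# redundant barcode determinations), per-genotype expression aggregation,
# and bulk growth-curve / repression-ratio analysis.

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Lower bound `qbeta(alpha/2; x, n-x+1)` (0 when x = 0), upper bound
#' `qbeta(1-alpha/2; x+1, n-x)` (1 when x = n), point estimate `x/n`.
#'
#' @param x number of successes (0 <= x <= n).
#' @param n number of trials (>= 1).
#' @param confidence confidence level in (0, 1).
#' @return A list of class `interval_estimate`: `point`, `lower`, `upper`,
#'   `confidence`.
#' @export
clopper_pearson <- function(x, n, confidence = 0.95) {
  if (n < 1 || x < 0 || x > n || x != round(x) || n != round(n))
    stop("need integers 0 <= x <= n, n >= 1")
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must be in (0, 1)")
  a <- 1 - confidence
  lower <- if (x == 0) 0 else qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x)
  structure(list(point = x / n, lower = lower, upper = upper,
                 confidence = confidence),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%.4f  [%g%% CI %.4f-%.4f]\n", x$point,
              100 * x$confidence, x$lower, x$upper))
  invisible(x)
}

#' Confusion counts over redundant genotype determinations
#'
#' Tallies true/false positive/negative identifications of
#' `positive_label`, per determination. With `redundancy` r each trap's
#' call is treated as r independent determinations; a trap-level call
#' vector is expanded r times, or a determination-level table
#' (`trap_id`, `genotype`) is counted as given, so single erroneous
#' determinations stay attributed to their determination.
#'
#' A no-call (`NA`) counts as a negative identification of
#' `positive_label`.
#'
#' @param calls per-trap genotype vector (same length/order as `truth`),
#'   or a data.frame with columns `trap_id` and `genotype`, one row per
#'   determination.
#' @param truth per-trap reference genotype vector.
#' @param positive_label the genotype treated as positive; must occur in
#'   `truth`.
#' @param redundancy determinations per trap when `calls` is a vector.
#' @return A list of class `confusion_counts`: `tp`, `fp`, `tn`, `fn`,
#'   `n_pos`, `n_neg`.
#' @export
confusion_counts <- function(calls, truth, positive_label,
                             redundancy = 1L) {
  truth <- as.character(truth)
  if (!positive_label %in% truth)
    stop("positive_label absent from truth")
  if (is.data.frame(calls)) {
    stopifnot(all(c("trap_id", "genotype") %in% names(calls)))
    det_truth <- truth[calls$trap_id]
    det_call <- as.character(calls$genotype)
  } else {
    if (length(calls) != length(truth))
      stop("per-trap calls must match truth length")
    if (redundancy < 1 || redundancy != round(redundancy))
      stop("redundancy must be a positive integer")
    det_truth <- rep(truth, each = redundancy)
    det_call <- rep(as.character(calls), each = redundancy)
  }
  pos_t <- det_truth == positive_label
  pos_c <- !is.na(det_call) & det_call == positive_label
  out <- list(tp = sum(pos_t & pos_c), fp = sum(!pos_t & pos_c),
              tn = sum(!pos_t & !pos_c), fn = sum(pos_t & !pos_c))
  out$n_pos <- out$tp + out$fn
  out$n_neg <- out$tn + out$fp
  structure(out, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d  (n_pos %d, n_neg %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$n_pos, x$n_neg))
  invisible(x)
}

#' Sensitivity and specificity with exact intervals
#'
#' Sensitivity interval = Clopper-Pearson of `tp` out of `tp + fn`;
#' specificity interval = Clopper-Pearson of `tn` out of `tn + fp`.
#'
#' @param counts a [confusion_counts].
#' @param confidence confidence level.
#' @return `list(sensitivity =, specificity =)` of `interval_estimate`s.
#' @export
sensitivity_specificity <- function(counts, confidence = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$n_pos < 1 || counts$n_neg < 1)
    stop("need at least one positive and one negative determination")
  list(sensitivity = clopper_pearson(counts$tp, counts$n_pos, confidence),
       specificity = clopper_pearson(counts$tn, counts$n_neg, confidence))
}

#' Aggregate single-molecule expression by genotype
#'
#' Per-genotype histograms of per-cell spot counts (integer bins,
#' normalized to frequency), mean molecules per cell, and pairwise fold
#' differences of the means.
#'
#' @param table data.frame with one row per cell observation: columns
#'   `genotype` and `n_spots` (additional columns are ignored). Rows with
#'   `NA` genotype are dropped.
#' @return `list(histograms =, means =, fold =)`: named list of frequency
#'   tables, per-genotype `data.frame(genotype, n_cells, mean_count)`, and
#'   pairwise `data.frame(genotype_a, genotype_b, fold)` with
#'   `fold = mean_a / mean_b`.
#' @export
expression_by_genotype <- function(table) {
  stopifnot(all(c("genotype", "n_spots") %in% names(table)))
  tab <- table[!is.na(table$genotype), ]
  gts <- unique(tab$genotype)
  if (length(gts) < length(unique(table$genotype)))
    warning("cells with unknown genotype omitted")
  hists <- lapply(gts, function(g) {
    x <- tab$n_spots[tab$genotype == g]
    h <- table(factor(x, levels = 0:max(x, 0)))
    h / sum(h)
  })
  names(hists) <- gts
  means <- data.frame(
    genotype = gts,
    n_cells = vapply(gts, function(g) sum(tab$genotype == g), integer(1)),
    mean_count = vapply(gts, function(g)
      mean(tab$n_spots[tab$genotype == g]), numeric(1)))
  fold <- if (length(gts) >= 2) {
    pairs <- expand.grid(a = seq_along(gts), b = seq_along(gts))
    pairs <- pairs[pairs$a != pairs$b, ]
    data.frame(genotype_a = gts[pairs$a], genotype_b = gts[pairs$b],
               fold = means$mean_count[pairs$a] / means$mean_count[pairs$b])
  } else data.frame(genotype_a = character(), genotype_b = character(),
                    fold = numeric())
  list(histograms = hists, means = means, fold = fold)
}

#' Plate-reader growth curve
#'
#' @param times minutes, strictly increasing.
#' @param od OD_600 absorbance readings (including medium blank).
#' @param fluo fluorescence readings (including medium blank).
#' @param blank_od,blank_fluo medium background absorption / fluorescence.
#' @param well well identifier.
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(times, od, fluo = NULL, blank_od = 0,
                         blank_fluo = 0, well = "A1") {
  stopifnot(length(times) == length(od), all(diff(times) > 0))
  if (!is.null(fluo)) stopifnot(length(fluo) == length(od))
  structure(list(times = as.numeric(times), od = as.numeric(od),
                 fluo = if (is.null(fluo)) NULL else as.numeric(fluo),
                 blank_od = blank_od, blank_fluo = blank_fluo,
                 well = well),
            class = "growth_curve")
}

#' @export
as.data.frame.growth_curve <- function(x, ...) {
  data.frame(well = x$well, time_min = x$times, od = x$od,
             fluo = if (is.null(x$fluo)) NA_real_ else x$fluo)
}

#' Maximum growth rate and minimum doubling time
#'
#' Background-subtracts the OD, slides a log-linear fit of `window`
#' consecutive points along the curve, takes the maximum slope and
#' converts it to the minimum doubling time `log(2) / rate`. Invariant to
#' scaling the OD by a positive constant.
#'
#' @param curve a [growth_curve].
#' @param window fit width in points (default 7, i.e. 35 min at the 5-min
#'   plate-reader cadence).
#' @param min_od windows are restricted to background-subtracted OD above
#'   this floor, to keep instrument noise at low OD out of the log fit.
#' @return `list(doubling_time_min =, rate_per_min =, window_start_min =)`.
#' @export
max_growth_rate <- function(curve, window = 7L, min_od = 0) {
  stopifnot(inherits(curve, "growth_curve"), window >= 2)
  odc <- curve$od - curve$blank_od
  n <- length(odc)
  if (n < window) stop("fewer points than the fit window")
  best_rate <- -Inf; best_t <- NA_real_
  for (i in seq_len(n - window + 1L)) {
    idx <- i:(i + window - 1L)
    if (any(odc[idx] <= max(min_od, 0))) next
    sl <- unname(coef(lm(log(odc[idx]) ~ curve$times[idx]))[2])
    if (sl > best_rate) { best_rate <- sl; best_t <- curve$times[i] }
  }
  if (!is.finite(best_rate) || best_rate <= 0)
    stop("no window with positive exponential growth above background")
  list(doubling_time_min = log(2) / best_rate,
       rate_per_min = unname(best_rate), window_start_min = best_t)
}

#' Steady-state Fluo/OD and repression ratios
#'
#' For each curve, computes the background-subtracted fluorescence
#' normalized by background-subtracted OD, averaged over the steady-state
#' window (the last `steady_points` time points where the OD signal is
#' well above background), and reports each strain's ratio to the
#' reference strain. Used for CRISPRi repression ratios.
#'
#' @param curves named list of [growth_curve]s.
#' @param reference_id name of the reference curve.
#' @param steady_points number of late time points to average.
#' @param min_od_frac windows require the OD signal to exceed this
#'   fraction of its maximum.
#' @return `data.frame(id, fluo_per_od, ratio_vs_reference)`.
#' @export
repression_ratio <- function(curves, reference_id, steady_points = 12L,
                             min_od_frac = 0.1) {
  stopifnot(is.list(curves), reference_id %in% names(curves))
  val <- vapply(curves, function(cu) {
    odc <- cu$od - cu$blank_od
    flc <- cu$fluo - cu$blank_fluo
    ok <- which(odc > min_od_frac * max(odc))
    if (length(ok) == 0) stop("OD never rises above background")
    idx <- tail(ok, steady_points)
    mean(flc[idx] / odc[idx])
  }, numeric(1))
  data.frame(id = names(curves), fluo_per_od = unname(val),
             ratio_vs_reference = unname(val / val[[reference_id]]))
}
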