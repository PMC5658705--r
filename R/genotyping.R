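# Sequential-FISH genotyping: locate traps on the vertically summed DAPI
# profile, call one barcode symbol per trap per round from the log ratio of
# vertically summed Cy3/Cy5 signal, decode codewords to genotypes and take
# a redundancy-corrected consensus per trap.

#' Barcode codebook
#'
#' Maps length-N codewords over a C-symbol color alphabet to genotype
#' identifiers. With C colors and N rounds of probing, C^N genotypes can
#' be distinguished.
#'
#' @param codes character vector of codewords, all of equal length, unique.
#' @param genotypes character vector of genotype IDs, one per code.
#' @param colors size of the color alphabet C (default 2: Cy5 encodes
#'   symbol 0, Cy3 encodes symbol 1).
#' @return An object of class `codebook`.
#' @export
codebook <- function(codes, genotypes, colors = 2L) {
  codes <- as.character(codes); genotypes <- as.character(genotypes)
  if (length(codes) != length(genotypes))
    stop("codes and genotypes must have equal length")
  if (anyDuplicated(codes)) stop("codes must be unique")
  n <- unique(nchar(codes))
  if (length(n) != 1L) stop("all codes must have equal length")
  alphabet <- as.character(0:(colors - 1))
  if (!all(strsplit(paste(codes, collapse = ""), "")[[1]] %in% alphabet))
    stop("codes contain symbols outside the color alphabet")
  if (length(codes) > colors^n)
    stop("more codes than the C^N capacity allows")
  structure(list(colors = as.integer(colors), rounds = as.integer(n),
                 map = stats::setNames(genotypes, codes)),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook> C=%d colors, N=%d rounds, %d/%d codes used\n",
              x$colors, x$rounds, length(x$map), codebook_capacity(x$colors,
                                                                   x$rounds)))
  invisible(x)
}

# genotype -> code (inverse lookup), NA when absent
codebook_lookup_code <- function(cb, genotypes) {
  inv <- stats::setNames(names(cb$map), cb$map)
  unname(inv[genotypes])
}

#' The three-strain demonstration codebook
#'
#' Two-round, two-color codes: `10` = lacI knockdown, `01` = lacY
#' knockdown, `11` = no knockdown.
#'
#' @return A [codebook].
#' @export
demo_codebook <- function() {
  codebook(c("10", "01", "11"), c("lacI_kd", "lacY_kd", "no_kd"), colors = 2L)
}

#' Codebook capacity
#'
#' Number of genotypes distinguishable with `C` colors and `N` rounds of
#' probing: `C^N`.
#'
#' @param C number of colors (>= 1).
#' @param N number of probing rounds (>= 1).
#' @return `C^N` as a numeric count.
#' @export
codebook_capacity <- function(C, N) {
  if (C < 1 || N < 1) stop("C and N must be >= 1")
  as.numeric(C)^as.numeric(N)
}

#' Locate trap channels from the vertically summed DAPI signal
#'
#' Sums the fixed-cell DAPI image over rows, then finds profile peaks above
#' background with a minimum spacing; each peak becomes a half-open column
#' interval of the trap width.
#'
#' @param dapi_frame DAPI raster (matrix) of the fixed cells.
#' @param expected_n_traps if given, error (listing candidates) unless
#'   exactly this many traps are found.
#' @param min_spacing_px minimum center-to-center trap spacing.
#' @param width_px width of the reported interval around each center.
#' @param k background threshold: peaks must exceed
#'   `median(profile) + k * mad(profile)`.
#' @return Integer matrix with columns `from`, `to` (half-open, 0-based)
#'   and attribute `centers`.
#' @export
locate_traps <- function(dapi_frame, expected_n_traps = NULL,
                         min_spacing_px = 10, width_px = 9, k = 5) {
  prof <- colSums(dapi_frame)
  thr <- median(prof) + k * mad(prof)
  if (mad(prof) == 0) thr <- median(prof) + k * max(sd(prof), 1e-12)
  above <- prof > thr
  centers <- numeric(0)
  if (any(above)) {
    # contiguous above-threshold runs -> intensity-weighted centers
    rle_ <- rle(above)
    ends <- cumsum(rle_$lengths)
    starts <- ends - rle_$lengths + 1
    for (i in which(rle_$values)) {
      cols <- starts[i]:ends[i]
      centers <- c(centers, sum(cols * prof[cols]) / sum(prof[cols]))
    }
    # enforce minimum spacing, keeping the stronger peak
    if (length(centers) > 1) {
      keep <- rep(TRUE, length(centers))
      height <- vapply(centers, function(cc) prof[round(cc)], numeric(1))
      ord <- order(height, decreasing = TRUE)
      for (i in ord) {
        if (!keep[i]) next
        close_ <- which(keep & abs(centers - centers[i]) < min_spacing_px)
        keep[setdiff(close_, i)] <- FALSE
      }
      centers <- centers[keep]
    }
    centers <- sort(centers)
  }
  if (!is.null(expected_n_traps) && length(centers) != expected_n_traps)
    stop(sprintf(
      "expected %d traps but found %d (candidate centers: %s)",
      expected_n_traps, length(centers),
      paste(round(centers, 1), collapse = ", ")))
  from <- floor(centers - 0.5 - width_px / 2)   # 0-based half-open
  ivs <- cbind(from = from, to = from + width_px)
  attr(ivs, "centers") <- centers - 1          # 0-based
  ivs
}

#' Call one barcode symbol from Cy3/Cy5 trap sums
#'
#' The log ratio of the vertically summed, background-subtracted Cy3 and
#' Cy5 signals calls a 1 (Cy3-dominant) or 0 (Cy5-dominant). Sums are
#' floored at 1 count before the log. The call is scale-invariant.
#'
#' @param cy3_sum,cy5_sum background-subtracted summed intensities.
#' @param ambiguity_band non-negative half-width of the ambiguous zone
#'   around log-ratio 0; the default 0 is the strict sign rule.
#' @return `list(bit =, log_ratio =, ambiguous =)`; `bit` is `"1"`, `"0"`
#'   or `NA` when ambiguous.
#' @export
call_bit <- function(cy3_sum, cy5_sum, ambiguity_band = 0) {
  stopifnot(ambiguity_band >= 0)
  c3 <- max(cy3_sum, 1); c5 <- max(cy5_sum, 1)
  lr <- log(c3 / c5)
  ambiguous <- (c3 == 1 && c5 == 1) || abs(lr) <= ambiguity_band
  bit <- if (ambiguous) NA_character_ else if (lr > 0) "1" else "0"
  list(bit = bit, log_ratio = lr, ambiguous = ambiguous)
}

#' Decode a codeword into a genotype
#'
#' Exact codebook lookup. Ambiguous symbols or a codeword absent from the
#' codebook yield a no-call (`NA`) with the raw code attached.
#'
#' @param bits length-N character vector of symbols, or a single string.
#' @param codebook a [codebook].
#' @return Genotype ID, or `NA` with attribute `code` on no-call.
#' @export
decode_barcode <- function(bits, codebook) {
  code <- if (length(bits) == 1L && nchar(bits[1]) > 1L) bits else
    paste(bits, collapse = "")
  if (anyNA(bits)) {
    out <- NA_character_; attr(out, "code") <- NA_character_
    return(out)
  }
  if (nchar(code) != codebook$rounds)
    stop(sprintf("codeword length %d does not match codebook rounds %d",
                 nchar(code), codebook$rounds))
  g <- unname(codebook$map[code])
  if (is.na(g)) attr(g, "code") <- code
  g
}

#' Consensus genotype across redundant determinations
#'
#' Strict majority vote over the per-determination genotype calls of one
#' trap. When determinations disagree but a majority exists the call is
#' kept and flagged `corrected`; without a majority the trap is a no-call.
#'
#' @param determinations character vector of genotype IDs (`NA` = no-call
#'   determination).
#' @return `list(genotype =, corrected =, n_determinations =,
#'   determinations =)`; `genotype` is `NA` on no-call.
#' @export
consensus_genotype <- function(determinations) {
  if (length(determinations) == 0L) stop("at least one determination needed")
  det <- as.character(determinations)
  tab <- sort(table(det[!is.na(det)]), decreasing = TRUE)
  if (length(tab) == 0L)
    return(list(genotype = NA_character_, corrected = FALSE,
                n_determinations = length(det), determinations = det))
  majority <- tab[1] > length(det) / 2
  disagree <- length(tab) > 1L || any(is.na(det))
  if (!majority)
    return(list(genotype = NA_character_, corrected = FALSE,
                n_determinations = length(det), determinations = det))
  list(genotype = names(tab)[1], corrected = disagree,
       n_determinations = length(det), determinations = det)
}

# Background-subtracted vertical sums of one FISH frame over each trap's
# column interval. Background is the per-frame median of inter-trap
# columns, subtracted per pixel before summation and flooring at 0.
trap_channel_sums <- function(frame, intervals) {
  nc <- ncol(frame)
  in_trap <- rep(FALSE, nc)
  for (k in seq_len(nrow(intervals)))
    in_trap[(intervals[k, "from"] + 1):intervals[k, "to"]] <- TRUE
  bg <- if (any(!in_trap)) median(frame[, !in_trap]) else median(frame)
  vapply(seq_len(nrow(intervals)), function(k) {
    cols <- (intervals[k, "from"] + 1):intervals[k, "to"]
    sum(pmax(frame[, cols] - bg, 0))
  }, numeric(1))
}

#' Genotype traps from sequential FISH rounds
#'
#' Full genotyping driver: locates traps on the round-1 DAPI image (or uses
#' supplied intervals), computes background-subtracted vertical Cy3/Cy5
#' sums per trap and round, calls one symbol per trap per round from the
#' log ratio, decodes each block of `rounds_per_code` rounds into one
#' genotype determination, and reports the per-trap consensus with a
#' `corrected` flag where redundancy fixed a disagreement.
#'
#' @param fish a `sim_fish` object, or a list with `rounds` (per round:
#'   `dapi`, `cy3`, `cy5` [image_stack]s).
#' @param codebook a [codebook].
#' @param expected_n_traps optional hard check on the trap count.
#' @param intervals optional pre-computed trap column intervals.
#' @param ambiguity_band passed to [call_bit].
#' @return A list of class `genotype_result`: `calls` (one row per trap and
#'   round: sums, log ratio, symbol), `assignments` (one row per trap:
#'   consensus genotype, per-determination genotypes, n_determinations,
#'   corrected), `intervals`.
#' @export
genotype_traps <- function(fish, codebook, expected_n_traps = NULL,
                           intervals = NULL, ambiguity_band = 0) {
  rounds <- fish$rounds
  n_rounds <- length(rounds)
  if (n_rounds %% codebook$rounds != 0)
    stop("number of probed rounds is not a multiple of the codeword length")
  if (is.null(intervals)) {
    dapi <- rounds[[1]]$dapi$frames[[1]]
    intervals <- locate_traps(dapi, expected_n_traps = expected_n_traps)
  }
  n_traps <- nrow(intervals)
  calls <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    s3 <- trap_channel_sums(rounds[[r]]$cy3$frames[[1]], intervals)
    s5 <- trap_channel_sums(rounds[[r]]$cy5$frames[[1]], intervals)
    per <- lapply(seq_len(n_traps), function(k)
      call_bit(s3[k], s5[k], ambiguity_band))
    calls[[r]] <- data.frame(
      trap_id = seq_len(n_traps), round = r,
      cy3_sum = s3, cy5_sum = s5,
      log_ratio = vapply(per, `[[`, numeric(1), "log_ratio"),
      bit = vapply(per, `[[`, character(1), "bit"))
  }
  calls <- do.call(rbind, calls)
  n_det <- n_rounds %/% codebook$rounds
  assignments <- lapply(seq_len(n_traps), function(k) {
    bits <- calls$bit[calls$trap_id == k][order(calls$round[calls$trap_id == k])]
    dets <- vapply(seq_len(n_det), function(d) {
      block <- bits[((d - 1) * codebook$rounds + 1):(d * codebook$rounds)]
      as.character(decode_barcode(block, codebook))
    }, character(1))
    cons <- consensus_genotype(dets)
    data.frame(trap_id = k, genotype = cons$genotype,
               n_determinations = cons$n_determinations,
               corrected = cons$corrected,
               determinations = paste(ifelse(is.na(dets), "-", dets),
                                      collapse = ";"))
  })
  structure(list(calls = calls, assignments = do.call(rbind, assignments),
                 intervals = intervals),
            class = "genotype_result")
}

#' @export
print.genotype_result <- function(x, ...) {
  n <- nrow(x$assignments)
  cat(sprintf(
    "<genotype_result> %d traps, %d barcode reads, %d corrected, %d no-call\n",
    n, nrow(x$calls), sum(x$assignments$corrected),
    sum(is.na(x$assignments$genotype))))
  invisible(x)
}

#' Annotate a lineage forest with per-trap genotypes
#'
#' Every cell in a trap is the progeny of the cell at the back of the
#' channel and shares the trap's genotype, so the trap's consensus call is
#' attached to all of its cell nodes. Traps containing cells but lacking a
#' genotype call are flagged `genotype_unknown`.
#'
#' @param assignments the `assignments` table of a `genotype_result` (or
#'   the object itself), with the phenotyping trap in `trap_id`.
#' @param forest a [lineage_forest]; its nodes carry `trap_id`.
#' @return The forest with `genotype` and `genotype_unknown` columns added
#'   to its node table.
#' @export
map_genotype_to_cells <- function(assignments, forest) {
  if (inherits(assignments, "genotype_result"))
    assignments <- assignments$assignments
  stopifnot(inherits(forest, "lineage_forest"))
  traps_pheno <- sort(unique(forest$nodes$trap_id))
  missing_traps <- setdiff(traps_pheno, assignments$trap_id)
  if (length(missing_traps) > 0 &&
      max(traps_pheno) > nrow(assignments))
    stop("trap count mismatch between phenotyping and genotyping")
  g <- assignments$genotype[match(forest$nodes$trap_id,
                                  assignments$trap_id)]
  forest$nodes$genotype <- g
  forest$nodes$genotype_unknown <- is.na(g)
  forest
}
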