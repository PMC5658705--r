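# Plain-text external interfaces: TSV/CSV readers and writers for lineage
# forests, spot tables, barcode calls, codebooks and plate-reader data.

#' Write / read a codebook CSV
#'
#' Columns: `code`, `genotype_id`.
#'
#' @param cb a [codebook].
#' @param path file path.
#' @return `path` (writer) or a [codebook] (reader).
#' @export
write_codebook_csv <- function(cb, path) {
  stopifnot(inherits(cb, "codebook"))
  df <- data.frame(code = names(cb$map), genotype_id = unname(cb$map))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_codebook_csv
#' @param colors color alphabet size for the reader.
#' @export
read_codebook_csv <- function(path, colors = 2L) {
  df <- utils::read.csv(path, colClasses = "character")
  codebook(df$code, df$genotype_id, colors = colors)
}

#' Write a lineage forest as TSV
#'
#' Two files: `<stem>_nodes.tsv` (node_id, parent_id, trap_id,
#' frame_birth, frame_death, divided, and filter/genotype flags when
#' present) and `<stem>_obs.tsv` (node_id, frame, label, area_px,
#' centroids).
#'
#' @param forest a [lineage_forest].
#' @param stem output path stem.
#' @return The two paths, invisibly.
#' @export
write_lineage_tsv <- function(forest, stem) {
  stopifnot(inherits(forest, "lineage_forest"))
  p1 <- paste0(stem, "_nodes.tsv"); p2 <- paste0(stem, "_obs.tsv")
  write.table(forest$nodes, p1, sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(forest$obs, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}

#' Write barcode calls and genotype assignments as TSV
#'
#' @param result a `genotype_result` from [genotype_traps].
#' @param stem output path stem; writes `<stem>_calls.tsv` and
#'   `<stem>_assignments.tsv`.
#' @return The two paths, invisibly.
#' @export
write_genotype_tsv <- function(result, stem) {
  stopifnot(inherits(result, "genotype_result"))
  p1 <- paste0(stem, "_calls.tsv"); p2 <- paste0(stem, "_assignments.tsv")
  write.table(result$calls, p1, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(result$assignments, p2, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(c(p1, p2))
}

#' Read a long-format plate-reader CSV
#'
#' Expected columns: `well`, `time_min`, `od`, `fluo`.
#'
#' @param path CSV path.
#' @param blank_od,blank_fluo medium background values attached to every
#'   curve.
#' @return Named list of [growth_curve]s, one per well.
#' @export
read_plate_reader_csv <- function(path, blank_od = 0, blank_fluo = 0) {
  df <- utils::read.csv(path)
  stopifnot(all(c("well", "time_min", "od", "fluo") %in% names(df)))
  wells <- unique(df$well)
  out <- lapply(wells, function(w) {
    d <- df[df$well == w, ]
    d <- d[order(d$time_min), ]
    growth_curve(d$time_min, d$od, d$fluo, blank_od = blank_od,
                 blank_fluo = blank_fluo, well = w)
  })
  stats::setNames(out, wells)
}
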