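## Plain-text interchange formats.
##
## Scans are GenePix-like TSV: Block (print-tip group), Row, Column, ID,
## F635_Median/B635_Median (red foreground/background), F532_Median/
## B532_Median (green). One file per array, named <array_id>.gpr.tsv.
## The design table lists array_id, cy3_sample, cy5_sample, dye_swap_of.

GPR_COLUMNS <- c("Block", "Row", "Column", "ID",
                 "F635_Median", "B635_Median", "F532_Median", "B532_Median")

#' Write an array scan set to GPR-like TSV files
#'
#' @param scan_set an `array_scan_set`.
#' @param dir output directory (created if missing); one `<array_id>.gpr.tsv`
#'   file per array plus `design.tsv`.
#' @return Invisibly, the directory.
#' @export
write_array_scans <- function(scan_set, dir) {
  stopifnot(inherits(scan_set, "array_scan_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(scan_set$scans)) {
    s <- scan_set$scans[[id]]
    per_block <- table(s$print_tip_group)
    pos <- stats::ave(seq_len(nrow(s)), s$print_tip_group, FUN = seq_along)
    ncol_block <- ceiling(sqrt(max(per_block)))
    out <- data.frame(Block = s$print_tip_group,
                      Row = ((pos - 1L) %/% ncol_block) + 1L,
                      Column = ((pos - 1L) %% ncol_block) + 1L,
                      ID = s$probe_id,
                      F635_Median = s$fg_red, B635_Median = s$bg_red,
                      F532_Median = s$fg_green, B532_Median = s$bg_green)
    write_tsv(out, file.path(dir, paste0(id, ".gpr.tsv")))
  }
  write_tsv(scan_set$design, file.path(dir, "design.tsv"))
  invisible(dir)
}

#' Read array scans and join them to a hybridization design
#'
#' Replicate spots of a probe are collapsed to their per-channel median.
#' Negative intensities are rejected; arrays referenced by the design but
#' missing from disk raise an error naming the array.
#'
#' @param path directory holding `<array_id>.gpr.tsv` files.
#' @param design_path design TSV (array_id, cy3_sample, cy5_sample,
#'   dye_swap_of).
#' @return An `array_scan_set`.
#' @export
read_array_scans <- function(path, design_path) {
  design <- read_tsv(design_path)
  need <- c("array_id", "cy3_sample", "cy5_sample", "dye_swap_of")
  if (!all(need %in% names(design)))
    stop_arg("design table must have columns: ", paste(need, collapse = ", "))
  design$dye_swap_of[design$dye_swap_of %in% c("", "NA")] <- NA
  scans <- list()
  for (id in design$array_id) {
    f <- file.path(path, paste0(id, ".gpr.tsv"))
    if (!file.exists(f))
      stop_arg("scan file for array '", id, "' not found: ", f)
    g <- read_tsv(f)
    if (!all(GPR_COLUMNS %in% names(g)))
      stop_arg("array '", id, "': missing GPR columns")
    vals <- g[, c("F635_Median", "B635_Median", "F532_Median", "B532_Median")]
    if (any(vals < 0, na.rm = TRUE))
      stop_arg("array '", id, "': negative intensity values")
    scans[[id]] <- collapse_spots(data.frame(
      probe_id = as.character(g$ID), print_tip_group = g$Block,
      fg_red = g$F635_Median, bg_red = g$B635_Median,
      fg_green = g$F532_Median, bg_green = g$B532_Median,
      stringsAsFactors = FALSE))
  }
  new_scan_set(scans, design)
}

#' Collapse replicate spots of a probe to per-channel medians
#'
#' @param scan one scan data.frame (possibly several rows per probe).
#' @return A scan data.frame with one row per probe, in first-occurrence
#'   order.
#' @export
collapse_spots <- function(scan) {
  if (!anyDuplicated(scan$probe_id)) return(scan)
  keys <- unique(scan$probe_id)
  idx <- split(seq_len(nrow(scan)), factor(scan$probe_id, levels = keys))
  med <- function(col) vapply(idx, function(i) median(scan[[col]][i]),
                              numeric(1))
  data.frame(probe_id = keys,
             print_tip_group = vapply(idx, function(i)
               scan$print_tip_group[i][1], scan$print_tip_group[1]),
             fg_red = med("fg_red"), bg_red = med("bg_red"),
             fg_green = med("fg_green"), bg_green = med("bg_green"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a long-format qPCR table
#'
#' Columns: sample, assay, role (`standard`, `unknown`, `reference`,
#' `target`), log10_copies (standards only), replicate, cq, and optionally
#' time.
#'
#' @param qpcr data.frame in long format.
#' @param path output TSV path.
#' @return Invisibly, the path.
#' @export
write_qpcr_table <- function(qpcr, path) write_tsv(qpcr, path)

#' Read a long-format qPCR table
#' @param path TSV path.
#' @return data.frame.
#' @export
read_qpcr_table <- function(path) {
  q <- read_tsv(path)
  need <- c("sample", "assay", "role", "replicate", "cq")
  if (!all(need %in% names(q)))
    stop_arg("qPCR table must have columns: ", paste(need, collapse = ", "))
  q
}

#' Write / read a probe annotation table
#' @param annotation annotation data.frame.
#' @param path TSV path.
#' @return `write_annotation` the path, invisibly; `read_annotation` a
#'   data.frame.
#' @export
write_annotation <- function(annotation, path) write_tsv(annotation, path)

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  a <- read_tsv(path)
  if (!all(c("probe_id", "origin") %in% names(a)))
    stop_arg("annotation must have columns probe_id and origin")
  a
}
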