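#' @title Curated marker catalog
#' @name marker_catalog
#' @description Machine-readable transcription of the published candidate
#'   and known promoter SNP markers of familial and sporadic Alzheimer's
#'   disease (90 rows over six table groups), with printed K_D pairs,
#'   Z/alpha/rank columns, candidate flags, and count summaries feeding
#'   the selection-pressure tests.
NULL

FAMILIAL_AD_GENES <- c("MAPT", "APP", "APOE", "PSEN1", "PSEN2")

#' Load the packaged marker catalog fixture
#'
#' Verifies the content checksum recorded in the file header, parses all
#' rows, and attaches derived columns: `context_wt` / `context_mut`
#' (full flank5 + allele + flank3 concatenations for the first minor) and
#' `context_available` (FALSE for the one row whose deleted wt sequence is
#' not printed).
#'
#' @param path optional path; defaults to the packaged fixture.
#' @return data.frame of class `anchor_table`, 90 rows.
#' @export
load_fixture <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "marker_catalog.tsv", package = "tatasnp",
                        mustWork = TRUE)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  data_lines <- lines[!startsWith(lines, "#")]
  stored <- sub("^# checksum: *", "", hdr[grepl("^# checksum:", hdr)])
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(data_lines, tf)
  actual <- unname(tools::md5sum(tf))
  if (!length(stored) || !identical(stored, actual))
    stop("fixture-corruption error: checksum mismatch (expected ",
         if (length(stored)) stored else "<none>", ", got ", actual, ")")
  tab <- read.delim(tf, stringsAsFactors = FALSE,
                    colClasses = c(table_id = "integer", gene = "character",
                                   omim = "character", snp_id = "character",
                                   flank5 = "character", wt = "character",
                                   minors = "character", flank3 = "character",
                                   kd_wt_nM = "numeric", kd_mut_nM = "numeric",
                                   direction = "character",
                                   z_printed = "numeric",
                                   alpha_printed = "numeric",
                                   rank_printed = "character",
                                   is_proposed_candidate = "logical",
                                   is_known_marker = "logical",
                                   tbp_site_effect = "character",
                                   gene_group = "character",
                                   annotation = "character"))
  tab$context_available <- !startsWith(tab$wt, "?")
  wt_allele <- ifelse(tab$context_available, sub("^-$", "", tab$wt), NA)
  first_minor <- sub(",.*$", "", tab$minors)
  first_minor[first_minor == "-"] <- ""
  tab$context_wt <- ifelse(tab$context_available,
                           paste0(tab$flank5, wt_allele, tab$flank3), NA)
  tab$context_mut <- ifelse(tab$context_available,
                            paste0(tab$flank5, first_minor, tab$flank3), NA)
  stopifnot(identical(tab$gene_group == "familial_AD",
                      tab$gene %in% FAMILIAL_AD_GENES))
  class(tab) <- c("anchor_table", "data.frame")
  tab
}

#' Convert catalog rows to `snp_record` objects
#' @param rows an `anchor_table` (or subset of rows).
#' @return list of [snp_record()]s.
#' @export
fixture_snp_records <- function(rows) {
  lapply(seq_len(nrow(rows)), function(i)
    snp_record(rows$snp_id[i], rows$flank5[i],
               if (rows$wt[i] == "-") "" else rows$wt[i],
               strsplit(rows$minors[i], ",")[[1]], rows$flank3[i],
               gene = rows$gene[i]))
}

#' Build calibration anchors from the catalog
#'
#' Anchors are the full flank-allele-flank concatenations paired with the
#' printed K_D values (wt and first-minor contexts, deduplicated by
#' sequence); Z anchors pair the absolute printed ln K_D difference with
#' the printed Z of every row carrying both.
#'
#' @param rows an `anchor_table`.
#' @return list with `anchors` (sequence, kd_nM) and `z_anchors`
#'   (delta_ln_kd, z).
#' @export
calibration_anchors <- function(rows) {
  ok <- rows$context_available & !is.na(rows$kd_wt_nM) & !is.na(rows$kd_mut_nM)
  anchors <- rbind(
    data.frame(sequence = rows$context_wt[ok], kd_nM = rows$kd_wt_nM[ok],
               stringsAsFactors = FALSE),
    data.frame(sequence = rows$context_mut[ok], kd_nM = rows$kd_mut_nM[ok],
               stringsAsFactors = FALSE))
  anchors <- anchors[!duplicated(anchors$sequence), ]
  zok <- !is.na(rows$kd_wt_nM) & !is.na(rows$kd_mut_nM) & !is.na(rows$z_printed)
  z_anchors <- data.frame(
    delta_ln_kd = abs(log(rows$kd_mut_nM[zok] / rows$kd_wt_nM[zok])),
    z = rows$z_printed[zok])
  list(anchors = anchors, z_anchors = z_anchors)
}

#' Classify one catalog row into a marker call
#'
#' A row is a candidate when its TBP-site effect is significant, or via the
#' annotation-based override used for the handful of rows whose TBP effect
#' is insignificant or unprinted but which the analysis proposes anyway.
#'
#' @param row a single-row `anchor_table` slice.
#' @param result optional `comparison_result` to supply the expression
#'   call; otherwise the printed direction is used.
#' @return object of class `marker_call` with `snp_id`, `candidate`,
#'   `expression_call`, `risk_note`.
#' @export
classify_row <- function(row, result = NULL) {
  stopifnot(nrow(row) == 1L)
  candidate <- row$tbp_site_effect == "significant" || row$is_proposed_candidate
  call <- if (!is.null(result)) result$decision else
    switch(row$direction,
           down = "underexpression", up = "overexpression",
           equal = "insignificant", absent = "not_printed")
  structure(list(snp_id = row$snp_id, candidate = candidate,
                 expression_call = call, risk_note = row$annotation),
            class = "marker_call")
}

#' Count summary feeding the selection-pressure tests
#'
#' @param rows an `anchor_table` (possibly filtered).
#' @return object of class `counts_summary` with `n_candidates_total`,
#'   `n_significant_other`, `n_decrease_other`, `n_candidates_familial`,
#'   `n_decrease_familial`.
#' @export
summarize_markers <- function(rows) {
  cand <- rows$is_proposed_candidate
  fam <- rows$gene_group == "familial_AD"
  sig <- rows$tbp_site_effect == "significant"
  out <- list(
    n_candidates_total = sum(cand),
    n_significant_other = sum(cand & !fam & sig),
    n_decrease_other = sum(cand & !fam & sig & rows$direction == "down"),
    n_candidates_familial = sum(cand & fam),
    n_decrease_familial = sum(cand & fam & rows$direction == "down"))
  stopifnot(out$n_decrease_other <= out$n_significant_other,
            out$n_decrease_familial <= out$n_candidates_familial)
  structure(out, class = "counts_summary")
}

#' @export
print.counts_summary <- function(x, ...) {
  cat(sprintf(paste0("<counts_summary> candidates %d; other group %d/%d ",
                     "decreasing; familial-AD group %d/%d decreasing\n"),
              x$n_candidates_total, x$n_decrease_other,
              x$n_significant_other, x$n_decrease_familial,
              x$n_candidates_familial))
  invisible(x)
}

#' Export the catalog fixture for external audit
#' @param path destination file path.
#' @return the path, invisibly.
#' @export
export_fixture <- function(path) {
  src <- system.file("extdata", "marker_catalog.tsv", package = "tatasnp",
                     mustWork = TRUE)
  file.copy(src, path, overwrite = TRUE)
  invisible(path)
}
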