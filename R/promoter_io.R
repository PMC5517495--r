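#' @title Promoter and SNP input handling
#' @name promoter_io
#' @description Readers for promoter FASTA files and SNP description tables,
#'   plus allele editing: substituting a minor allele into a promoter
#'   sequence and building fixed-width allele contexts around the edit.
NULL

# internal: validate a DNA field; "-" (empty allele) and "?<n>" (unknown
# allele of known length) are permitted where allowed = TRUE for them
.check_dna <- function(x, field, line = NA, allow_empty = FALSE,
                       allow_unknown = FALSE) {
  if (allow_empty && (is.na(x) || x == "" || x == "-")) return("")
  if (allow_unknown && grepl("^\\?[0-9]+$", x)) return(x)
  up <- toupper(x)
  if (is.na(x) || nchar(x) == 0L || grepl("[^ACGT]", up)) {
    bad <- if (is.na(x) || nchar(x) == 0L) "<empty>" else
      substring(gsub("[ACGTacgt]", "", x), 1L, 1L)
    stop(sprintf("parse error in field '%s'%s: invalid character '%s'",
                 field,
                 if (is.na(line)) "" else sprintf(" (line %s)", line),
                 bad), call. = FALSE)
  }
  tolower(x)
}

#' Read promoter sequences from a FASTA file
#'
#' @param fasta_path path to a (multi-record) FASTA file.
#' @return a data.frame with columns `id`, `gene` (second whitespace token of
#'   the header, or `NA`), and `sequence` (lowercase ACGT), in file order.
#' @export
read_promoters <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  set <- Biostrings::readDNAStringSet(fasta_path)
  ids <- names(set)
  first <- vapply(strsplit(ids, "\\s+"), `[`, "", 1L)
  gene <- vapply(strsplit(ids, "\\s+"), function(t)
    if (length(t) >= 2L) t[2L] else NA_character_, "")
  seqs <- tolower(as.character(set))
  for (i in seq_along(seqs))
    .check_dna(seqs[i], field = paste0("sequence:", first[i]))
  data.frame(id = first, gene = gene, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Construct a single SNP record
#'
#' A SNP is described by its 5' flank, ancestral (wt) allele, one or more
#' minor alleles, and 3' flank, following the flank-anchored notation of
#' curated promoter-variant tables (no genomic coordinates required).
#'
#' @param snp_id identifier (rsID or free label).
#' @param flank5,flank3 flanking sequences (non-empty DNA).
#' @param wt ancestral allele; `""` or `"-"` denotes an insertion site,
#'   `"?<n>"` an allele of known length `<n>` but unknown sequence.
#' @param minors character vector of minor alleles; `""`/`"-"` = deletion.
#' @param gene optional gene symbol.
#' @return an object of class `snp_record`.
#' @export
snp_record <- function(snp_id, flank5, wt, minors, flank3, gene = NA_character_) {
  flank5 <- .check_dna(flank5, "flank5")
  flank3 <- .check_dna(flank3, "flank3")
  wt <- .check_dna(wt, "wt", allow_empty = TRUE, allow_unknown = TRUE)
  minors <- vapply(minors, .check_dna, "", field = "minors",
                   allow_empty = TRUE, USE.NAMES = FALSE)
  if (any(minors == wt))
    stop("wt and minor allele identical for ", snp_id)
  structure(list(snp_id = snp_id, gene = gene, flank5 = flank5, wt = wt,
                 minors = minors, flank3 = flank3),
            class = "snp_record")
}

#' @export
print.snp_record <- function(x, ...) {
  cat(sprintf("<snp_record %s> %s [%s -> %s] %s\n", x$snp_id, x$flank5,
              ifelse(x$wt == "", "-", x$wt),
              paste(ifelse(x$minors == "", "-", x$minors), collapse = ","),
              x$flank3))
  invisible(x)
}

#' Classify the edit type of a wt/minor allele pair
#'
#' @param wt,minor allele strings ("" for absent).
#' @return one of "substitution", "deletion", "insertion".
#' @export
edit_type <- function(wt, minor) {
  # "?<n>" declares an allele of length <n> with unknown sequence
  nw <- if (startsWith(wt, "?")) as.integer(sub("^\\?", "", wt)) else nchar(wt)
  nm <- nchar(minor)
  if (nw == 0L) return("insertion")
  if (nm < nw) return("deletion")
  if (nm > nw) return("insertion")
  "substitution"
}

#' Read a SNP description table (TSV)
#'
#' Expected columns: `snp_id`, `gene`, `flank5`, `wt`, `minors`
#' (comma-separated), `flank3`. Lines starting with `#` are ignored.
#'
#' @param snp_path path to the TSV file.
#' @return a data.frame (class `snp_table`) in file order; alphabet is
#'   validated, case preserved for echo (computation is case-insensitive).
#' @export
read_snps <- function(snp_path) {
  if (!file.exists(snp_path)) stop("SNP table not found: ", snp_path)
  tab <- read.delim(snp_path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("snp_id", "gene", "flank5", "wt", "minors", "flank3")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  for (i in seq_len(nrow(tab))) {
    .check_dna(tab$flank5[i], "flank5", line = i + 1L)
    .check_dna(tab$flank3[i], "flank3", line = i + 1L)
    .check_dna(tab$wt[i], "wt", line = i + 1L, allow_empty = TRUE,
               allow_unknown = TRUE)
    for (m in strsplit(tab$minors[i], ",")[[1]])
      .check_dna(m, "minors", line = i + 1L, allow_empty = TRUE)
  }
  class(tab) <- c("snp_table", "data.frame")
  tab
}

#' Convert a `snp_table` to a list of `snp_record` objects
#' @param tab a data.frame as returned by [read_snps()].
#' @return list of [snp_record()] objects, one per table row; multi-allele
#'   cells are kept in printed order inside `minors`.
#' @export
as_snp_records <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i)
    snp_record(tab$snp_id[i], tab$flank5[i], tab$wt[i],
               strsplit(tab$minors[i], ",")[[1]], tab$flank3[i],
               gene = tab$gene[i]))
}

#' Parse promoter FASTA and SNP TSV inputs together
#' @param fasta_path promoter FASTA path.
#' @param snp_path SNP TSV path.
#' @return list with elements `promoters` (data.frame) and `snps`
#'   (list of `snp_record`).
#' @export
parse_inputs <- function(fasta_path, snp_path) {
  list(promoters = read_promoters(fasta_path),
       snps = as_snp_records(read_snps(snp_path)))
}

#' Apply an allele of a SNP to a promoter sequence
#'
#' The edit locus is located by exact, case-insensitive matching of
#' `flank5 + wt + flank3`; it must occur exactly once.
#'
#' @param sequence promoter DNA string.
#' @param snp a [snp_record()].
#' @param allele `"wt"` or the index (or string value) of a minor allele.
#' @return the edited sequence (lowercase); selecting `"wt"` returns the
#'   input unchanged (case-normalized).
#' @export
apply_allele <- function(sequence, snp, allele = "wt") {
  stopifnot(inherits(snp, "snp_record"))
  if (startsWith(snp$wt, "?"))
    stop("wt allele sequence unknown for ", snp$snp_id,
         ": context not available")
  seq_lc <- tolower(sequence)
  locus <- paste0(snp$flank5, snp$wt, snp$flank3)
  hits <- gregexpr(locus, seq_lc, fixed = TRUE)[[1]]
  if (hits[1] == -1L) stop("context not found for ", snp$snp_id)
  if (length(hits) > 1L) stop("ambiguous context for ", snp$snp_id,
                              " (", length(hits), " matches)")
  new <- if (identical(allele, "wt")) snp$wt else {
    m <- if (is.numeric(allele)) snp$minors[allele] else {
      a <- tolower(allele); a[a == "-"] <- ""
      if (!a %in% snp$minors) stop("unknown allele '", allele, "' for ",
                                   snp$snp_id)
      a
    }
    if (is.na(m)) stop("minor allele index out of range for ", snp$snp_id)
    m
  }
  pre <- substr(seq_lc, 1L, hits[1] + nchar(snp$flank5) - 1L)
  post <- substring(seq_lc, hits[1] + nchar(snp$flank5) + nchar(snp$wt))
  paste0(pre, new, post)
}

#' Build the wt/minor allele-context pair of a SNP
#'
#' Targets a fixed-width wt context (default 26 nt, the synthetic duplex
#' design width) with the edited position(s) centred; on ties the edit sits
#' left of centre. When one flank is too short its deficit is borrowed from
#' the other; when both are, a shorter context is returned with a warning.
#' The minor context shares the (possibly trimmed) flanks.
#'
#' @param snp a [snp_record()].
#' @param width target wt-context width (nt).
#' @param minor index of the minor allele to pair with the wt.
#' @return list of two `allele_context` objects (`wt`, `minor`), each with
#'   fields `snp_id`, `allele_label`, `sequence`, `width_achieved`.
#' @export
build_context_pair <- function(snp, width = 26L, minor = 1L) {
  stopifnot(inherits(snp, "snp_record"))
  if (startsWith(snp$wt, "?"))
    stop("wt allele sequence unknown for ", snp$snp_id,
         ": context not available")
  lw <- nchar(snp$wt)
  l5 <- nchar(snp$flank5); l3 <- nchar(snp$flank3)
  room <- width - lw
  if (room < 0L) room <- 0L
  a5 <- room %/% 2L                      # edit left-of-centre on ties
  a3 <- room - a5
  if (a5 > l5) { a3 <- min(l3, a3 + (a5 - l5)); a5 <- l5 }
  if (a3 > l3) { a5 <- min(l5, a5 + (a3 - l3)); a3 <- l3 }
  if (a5 + lw + a3 < width)
    warning(sprintf("flanks of %s too short for width %d; context length %d",
                    snp$snp_id, width, a5 + lw + a3))
  f5 <- substring(snp$flank5, l5 - a5 + 1L)
  f3 <- substr(snp$flank3, 1L, a3)
  mk <- function(allele, label) {
    s <- paste0(f5, allele, f3)
    structure(list(snp_id = snp$snp_id, allele_label = label, sequence = s,
                   width_achieved = nchar(s)),
              class = "allele_context")
  }
  list(wt = mk(snp$wt, "wt"),
       minor = mk(snp$minors[minor], paste0("minor_", minor)))
}

#' Read a minimal VCF subset together with a promoter BED and FASTA
#'
#' Accepts an uncompressed VCF (columns CHROM, POS, ID, REF, ALT are used)
#' and a BED file of promoter intervals whose `name` field matches the
#' FASTA record ids. Variants falling inside an interval are converted to
#' [snp_record()]s by slicing flanks from the corresponding promoter
#' sequence (forward strand of the supplied promoter).
#'
#' @param vcf_path,bed_path,fasta_path input file paths.
#' @param flank number of flanking bases to slice on each side.
#' @return list of `snp_record` objects.
#' @export
read_vcf_snps <- function(vcf_path, bed_path, fasta_path, flank = 10L) {
  proms <- read_promoters(fasta_path)
  bed <- read.delim(bed_path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop("BED file must have at least 4 columns")
  names(bed)[1:4] <- c("chrom", "start", "end", "name")
  lines <- readLines(vcf_path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    chrom <- f[1]; pos <- as.integer(f[2]); id <- f[3]
    ref <- tolower(f[4]); alts <- tolower(strsplit(f[5], ",")[[1]])
    hit <- which(bed$chrom == chrom & pos > bed$start & pos <= bed$end)
    if (!length(hit)) next
    b <- bed[hit[1], ]
    prom <- proms[proms$id == b$name, ]
    if (!nrow(prom)) next
    off <- pos - b$start            # 1-based position within promoter
    s <- prom$sequence
    if (tolower(substr(s, off, off + nchar(ref) - 1L)) != ref)
      stop("REF allele mismatch for ", id, " at ", chrom, ":", pos)
    f5 <- substr(s, max(1L, off - flank), off - 1L)
    f3 <- substr(s, off + nchar(ref), min(nchar(s), off + nchar(ref) + flank - 1L))
    out[[length(out) + 1L]] <-
      snp_record(id, f5, ref, alts, f3, gene = prom$gene)
  }
  out
}
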