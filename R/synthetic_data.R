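#' @title Synthetic promoter benchmark generator
#' @name synthetic_data
#' @description Generates [-70; -20] core-promoter regions (51 nt) of
#'   i.i.d. background sequence with one planted consensus TATA element
#'   (TATAAAAG frame) near position -30, together with SNPs of controlled
#'   ground-truth effect: core transversions against the consensus
#'   (decrease affinity), consensus-restoring edits at degenerate element
#'   positions (increase affinity), and flank edits (neutral). The set is
#'   emitted through the same FASTA/TSV interfaces the real pipeline
#'   consumes, so every stage is testable without downloads.
NULL

REGION_LEN <- 51L           # [-70; -20] inclusive
TATA_FRAME <- "tataaaag"    # TATAWAWR consensus instance
TATA_HOME <- 41L            # 1-based element start mapping to position -30

.sample_background <- function(n, gc) {
  p <- c(a = (1 - gc) / 2, c = gc / 2, g = gc / 2, t = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic promoter set with known ground truth
#'
#' @param n number of promoters (>= 1); truth classes are assigned
#'   round-robin (decrease_affinity, increase_affinity, neutral).
#' @param seed integer seed; the output is fully reproducible from it.
#' @param gc background GC content in (0, 1); values >= 0.9 trigger a
#'   warning (the planted AT-rich element then dominates trivially).
#' @param tata_offset_jitter maximum absolute jitter (nt) of the element
#'   start around its home position.
#' @return list with `promoters` (data.frame id/gene/sequence), `snps`
#'   (list of [snp_record()]), and `truth` (data.frame snp_id,
#'   planted_effect, planted_offset, magnitude_class).
#' @export
generate_promoter_set <- function(n, seed = 20170720L, gc = 0.4,
                                  tata_offset_jitter = 2L) {
  stopifnot(n >= 1, gc > 0, gc < 1)
  j <- as.integer(tata_offset_jitter)
  if (TATA_HOME + j + nchar(TATA_FRAME) - 1L > REGION_LEN || TATA_HOME - j < 1L)
    stop("parameter error: jitter pushes the TATA element outside the region")
  if (gc >= 0.9)
    warning("gc >= 0.9: the planted TATA element dominates trivially")
  set.seed(seed)
  classes <- rep(c("decrease_affinity", "increase_affinity", "neutral"),
                 length.out = n)
  proms <- vector("list", n); snps <- vector("list", n)
  truth <- data.frame(snp_id = character(n), planted_effect = character(n),
                      planted_offset = integer(n),
                      magnitude_class = character(n),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    repeat {
      off <- TATA_HOME + sample.int(2L * j + 1L, 1L) - j - 1L
      elem <- TATA_FRAME
      cls <- classes[i]
      # increase class: the wt carries a weakened element (degenerate W
      # position 5 set to c); the SNP restores the consensus base
      if (cls == "increase_affinity")
        substr(elem, 5L, 5L) <- "c"
      s <- .sample_background(REGION_LEN, gc)
      substr(s, off, off + nchar(elem) - 1L) <- elem
      if (cls == "decrease_affinity") {
        pos <- off + sample(c(0L, 2L), 1L)        # T of TA..TA.. core
        wt <- substr(s, pos, pos); minor <- sample(c("g", "c"), 1L)
      } else if (cls == "increase_affinity") {
        pos <- off + 4L
        wt <- "c"; minor <- "a"
      } else {
        flankpos <- setdiff(seq_len(REGION_LEN),
                            (off - 3L):(off + nchar(elem) + 2L))
        pos <- sample(flankpos, 1L)
        wt <- substr(s, pos, pos)
        minor <- sample(setdiff(c("a", "c", "g", "t"), wt), 1L)
      }
      f5 <- substr(s, max(1L, pos - 10L), pos - 1L)
      f3 <- substr(s, pos + 1L, min(REGION_LEN, pos + 10L))
      if (nchar(f5) < 5L || nchar(f3) < 5L) next
      locus <- paste0(f5, wt, f3)
      if (length(gregexpr(locus, s, fixed = TRUE)[[1]]) != 1L) next
      id <- sprintf("synth%04d", i)
      proms[[i]] <- data.frame(id = id, gene = id, sequence = s,
                               stringsAsFactors = FALSE)
      snps[[i]] <- snp_record(paste0(id, "_snp"), f5, wt, minor, f3,
                              gene = id)
      truth$snp_id[i] <- paste0(id, "_snp")
      truth$planted_effect[i] <- cls
      truth$planted_offset[i] <- off
      truth$magnitude_class[i] <- if (cls == "neutral") "flank" else "core"
      break
    }
  }
  list(promoters = do.call(rbind, proms), snps = snps, truth = truth)
}

#' Write a synthetic set to FASTA + SNP TSV + truth TSV
#' @param set output of [generate_promoter_set()].
#' @param dir destination directory (created if needed).
#' @return named character vector of the three file paths.
#' @export
write_synthetic_set <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "promoters.fasta")
  dna <- Biostrings::DNAStringSet(toupper(set$promoters$sequence))
  names(dna) <- paste(set$promoters$id, set$promoters$gene)
  Biostrings::writeXStringSet(dna, fa)
  snp_tab <- do.call(rbind, lapply(set$snps, function(r)
    data.frame(snp_id = r$snp_id, gene = r$gene, flank5 = r$flank5,
               wt = ifelse(r$wt == "", "-", r$wt),
               minors = paste(ifelse(r$minors == "", "-", r$minors),
                              collapse = ","),
               flank3 = r$flank3, stringsAsFactors = FALSE)))
  snp_path <- file.path(dir, "snps.tsv")
  write.table(snp_tab, snp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  write.table(set$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  c(fasta = fa, snps = snp_path, truth = truth_path)
}

#' Recovery report of pipeline calls against planted truth
#'
#' @param calls data.frame with columns `snp_id`, `decision`, `rank`
#'   (e.g. the result table of [run_analyze()]).
#' @param truth truth data.frame from [generate_promoter_set()].
#' @return list with per-class recovery rates (`rate_decrease`: fraction of
#'   decrease_affinity SNPs called underexpression with rank better than E;
#'   `rate_increase`: the symmetric overexpression rate; `rate_neutral`:
#'   fraction of neutral SNPs called insignificant) and the confusion
#'   table. Empty inputs yield an empty report.
#' @export
recovery_report <- function(calls, truth) {
  if (nrow(truth) == 0L && (is.null(calls) || nrow(calls) == 0L))
    return(list(rate_decrease = NA_real_, rate_increase = NA_real_,
                rate_neutral = NA_real_, confusion = table(NULL)))
  unmatched <- union(setdiff(truth$snp_id, calls$snp_id),
                     setdiff(calls$snp_id, truth$snp_id))
  if (length(unmatched))
    stop("id mismatch between calls and truth: ",
         paste(unmatched, collapse = ", "))
  m <- merge(truth, calls, by = "snp_id")
  rate <- function(cls, dec) {
    sel <- m$planted_effect == cls
    if (!any(sel)) return(NA_real_)
    if (dec == "insignificant") mean(m$decision[sel] == "insignificant")
    else mean(m$decision[sel] == dec & m$rank[sel] != "E")
  }
  list(rate_decrease = rate("decrease_affinity", "underexpression"),
       rate_increase = rate("increase_affinity", "overexpression"),
       rate_neutral = rate("neutral", "insignificant"),
       confusion = table(truth = m$planted_effect, call = m$decision))
}
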