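test_that("FASTA promoters round-trip in file order", {
  fa <- tempfile(fileext = ".fa")
  dna <- Biostrings::DNAStringSet(c("ACGTACGTACGTACGTACGT",
                                    "TTTTAAAACCCCGGGGACGT"))
  names(dna) <- c("prom1 GENE1", "prom2 GENE2")
  Biostrings::writeXStringSet(dna, fa)
  p <- read_promoters(fa)
  expect_equal(p$id, c("prom1", "prom2"))
  expect_equal(p$gene, c("GENE1", "GENE2"))
  expect_equal(toupper(p$sequence), as.character(dna), ignore_attr = TRUE)
})

test_that("SNP table parsing validates schema and alphabet", {
  tf <- tempfile()
  writeLines(c("snp_id\tgene\tflank5\twt\tminors\tflank3",
               "rs750789679\tGSTM3\tcgggtataaa\tg\tc\tcccctcccgc"), tf)
  tab <- read_snps(tf)
  rec <- as_snp_records(tab)[[1]]
  expect_s3_class(rec, "snp_record")
  expect_equal(edit_type(rec$wt, rec$minors[1]), "substitution")

  writeLines(c("snp_id\tgene\tflank5\twt\tminors\tflank3",
               "bad\tG\tacgtacgtac\tx\tc\tacgtacgtac"), tf)
  expect_error(read_snps(tf), "invalid character 'x'")

  writeLines(c("snp_id\tflank5\twt\tminors\tflank3",
               "bad\tacgtacgtac\ta\tc\tacgtacgtac"), tf)
  expect_error(read_snps(tf), "missing mandatory column")
})

test_that("apply_allele reproduces the printed minor-allele duplex", {
  # stopped-flow duplex pair of the TPI1 promoter variant
  odn_wt <- "cgcggcgctctatataagtgggcagt"
  snp <- snp_record("rs1800202", "gcgctctata", "t", "g", "aagtgggcag")
  expect_equal(apply_allele(odn_wt, snp, 1L), "cgcggcgctctatagaagtgggcagt")
  expect_equal(apply_allele(odn_wt, snp, "wt"), odn_wt)
})

test_that("apply_allele handles deletions, errors, and round-trips", {
  del <- snp_record("rs63750953", "ctgggcataa", "aa", "", "gtcagggcag")
  s <- paste0("gggg", "ctgggcataa", "aa", "gtcagggcag", "cccc")
  edited <- apply_allele(s, del, 1L)
  expect_equal(nchar(edited), nchar(s) - 2L)

  expect_error(apply_allele("acgtacgtacgt", del), "context not found")
  twice <- paste0(s, s)
  expect_error(apply_allele(twice, del), "ambiguous context")

  # substitution round-trip and length arithmetic, randomized
  set.seed(11)
  for (i in 1:25) {
    s <- random_dna(60)
    pos <- sample(15:45, 1)
    wt <- substr(s, pos, pos)
    minor <- sample(setdiff(c("a", "c", "g", "t"), wt), 1)
    snp <- snp_record("r", substr(s, pos - 10, pos - 1), wt, minor,
                      substr(s, pos + 1, pos + 10))
    locus <- paste0(snp$flank5, wt, snp$flank3)
    if (length(gregexpr(locus, s, fixed = TRUE)[[1]]) != 1L) next
    mut <- apply_allele(s, snp, 1L)
    expect_equal(nchar(mut) - nchar(s), nchar(minor) - nchar(wt))
    back <- snp_record("r2", snp$flank5, minor, wt, snp$flank3)
    expect_equal(apply_allele(mut, back, 1L), s)
  }
})

test_that("build_context_pair reproduces the printed 26-mer duplex pair", {
  # flanks long enough to reach the design width of 26
  snp <- snp_record("rs1800202", "cgcggcgctctata", "t", "g", "aagtgggcagt")
  ctx <- build_context_pair(snp, width = 26)
  expect_equal(ctx$wt$sequence, "cgcggcgctctatataagtgggcagt")
  expect_equal(ctx$minor$sequence, "cgcggcgctctatagaagtgggcagt")
  expect_equal(ctx$wt$width_achieved, 26L)
})

test_that("build_context_pair trims, warns when short, and tracks lengths", {
  # catalog-style 10-nt flanks cannot reach 26: warn, return 21-mer
  snp <- snp_record("rs1800202", "gcgctctata", "t", "g", "aagtgggcag")
  expect_warning(ctx <- build_context_pair(snp), "too short")
  expect_equal(ctx$wt$width_achieved, 21L)
  d <- mapply(function(a, b) a != b,
              strsplit(ctx$wt$sequence, "")[[1]],
              strsplit(ctx$minor$sequence, "")[[1]])
  expect_equal(sum(d), 1L)  # substitution: Hamming distance exactly 1

  # 18-bp deletion: minor context is 18 nt shorter, flanks shared
  del <- snp_record("DEL-51", "cgtgggggct", "gggcggacatacatatac", "",
                    "gggctccagg")
  ctx <- build_context_pair(del, width = 26)
  expect_equal(ctx$wt$width_achieved - ctx$minor$width_achieved, 18L)
})

test_that("all catalog rows parse and rebuild their wt contexts", {
  rows <- the_fixture()
  recs <- fixture_snp_records(rows)
  expect_length(recs, 90L)
  for (i in which(rows$context_available)) {
    rec <- recs[[i]]
    expect_equal(paste0(rec$flank5, rec$wt, rec$flank3), rows$context_wt[i])
  }
})

test_that("minimal VCF subset converts to SNP records via BED + FASTA", {
  dir <- tempdir()
  fa <- file.path(dir, "v.fa")
  s <- "acgtacgtacgttataaaagacgtacgtacgtacgtacgtacgtacgtacg"
  dna <- Biostrings::DNAStringSet(toupper(s)); names(dna) <- "prom1 GENE1"
  Biostrings::writeXStringSet(dna, fa)
  bed <- file.path(dir, "v.bed")
  writeLines("chr1\t1000\t1051\tprom1", bed)
  vcf <- file.path(dir, "v.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t1013\trsTEST\tT\tG,C\t.\t.\t."), vcf)
  recs <- read_vcf_snps(vcf, bed, fa)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$wt, "t")          # 13th base of the promoter
  expect_equal(recs[[1]]$minors, c("g", "c"))
  expect_equal(recs[[1]]$flank5, substr(s, 3, 12))

  writeLines(c("#CHROM\tPOS\tID\tREF\tALT",
               "chr1\t1013\trsTEST\tA\tG"), vcf)
  expect_error(read_vcf_snps(vcf, bed, fa), "REF allele mismatch")
})
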