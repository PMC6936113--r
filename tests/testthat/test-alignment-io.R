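ref_fix <- make_reference(300, seed = 9)

test_that("fetch_reads matches a brute-force linear scan and filters flags", {
  dir <- withr::local_tempdir()
  bam <- write_fixture_sam_bam(dir, ref_fix$seq)
  got <- fetch_reads(bam, "chr_fix", 60L)
  # oracle: linear scan over the SAM text
  expect_equal(sort(got$qname),
               oracle_fetch_linear(file.path(dir, "fix.sam"), 60L))
  # 10 spanning reads minus 2 duplicates (secondary/unmapped also dropped)
  expect_equal(nrow(got), 8L)
  expect_false(any(c("r06", "r07", "r11", "r12") %in% got$qname))
  # duplicates kept when filtering is off
  cfg_all <- vartag_config(filter_reads = FALSE)
  expect_equal(nrow(fetch_reads(bam, "chr_fix", 60L, cfg = cfg_all)), 11L)
  # locus beyond all alignments: empty, not an error
  expect_equal(nrow(fetch_reads(bam, "chr_fix", 250L)), 0L)
  expect_equal(nrow(fetch_reads(bam, "chr_nope", 60L)), 0L)
})

test_that("support classification and distances follow the CIGAR", {
  dir <- withr::local_tempdir()
  bam <- write_fixture_sam_bam(dir, ref_fix$seq)
  refb <- substr(ref_fix$seq, 60, 60) # "C" for this seed, so G is a real alt
  v <- variant_call("chr_fix", 60L, refb, "G")
  reads <- fetch_reads(bam, "chr_fix", 60L)
  ev <- vartag:::build_read_evidence(reads, v, ref_fix$seq)
  sup <- ev$read_id[ev$supports]
  expect_setequal(sup, c("r01", "r02", "r04"))
  # read with a deletion spanning the locus covers but does not support
  r10 <- ev[ev$read_id == "r10", ]
  expect_true(r10$covers)
  expect_false(r10$supports)
  expect_equal(r10$allele, "*")
  # soft-clipped prefix is invisible to head distance
  r08 <- ev[ev$read_id == "r08", ]
  expect_equal(r08$dist_head, 60L - 50L)
  expect_equal(r08$aln_start, 50L)
  # classify_support agrees read by read
  for (i in seq_len(nrow(reads))) {
    expect_equal(classify_support(reads[i, ], v) == "supports",
                 ev$supports[ev$read_id == reads$qname[i]])
  }
})

test_that("insertion support requires the exact inserted sequence", {
  refseq <- make_reference(200, seed = 5)$seq
  v <- variant_call("c", 100L, substr(refseq, 100, 100),
                    paste0(substr(refseq, 100, 100), "TTC"))
  mk <- function(ins) tibble::tibble(
    qname = "q", flag = 0L, chrom = "c", pos = 51L, mapq = 60L,
    cigar = "50M3I47M",
    seq = paste0(substr(refseq, 51, 100), ins, substr(refseq, 101, 147)),
    mpos = NA_integer_, isize = NA_integer_)
  expect_equal(classify_support(mk("TTC"), v), "supports")
  expect_equal(classify_support(mk("TTA"), v), "covers_only")
  # malformed read: sequence/CIGAR length mismatch
  bad <- mk("TTC"); bad$seq <- substr(bad$seq, 1, 80)
  expect_error(classify_support(bad, v), "malformed")
})

test_that("deletion support requires the exact deleted span", {
  refseq <- make_reference(200, seed = 5)$seq
  v <- variant_call("c", 100L, substr(refseq, 100, 102), substr(refseq, 100, 100))
  rd <- tibble::tibble(
    qname = "q", flag = 0L, chrom = "c", pos = 61L, mapq = 60L,
    cigar = "40M2D60M",
    seq = paste0(substr(refseq, 61, 100), substr(refseq, 103, 162)),
    mpos = NA_integer_, isize = NA_integer_)
  expect_equal(classify_support(rd, v), "supports")
  rd$cigar <- "40M3D60M"
  rd$seq <- paste0(substr(refseq, 61, 100), substr(refseq, 104, 163))
  expect_equal(classify_support(rd, v), "covers_only")
})

test_that("classification is invariant under read order", {
  ctx1 <- sim_context("linked_mismatch", seed = 8)
  v <- fixture_snv()
  reads <- simulate_variant_pileup(
    fixture_ref()$seq, v, artifact_spec("linked_mismatch", seed = 8))
  set.seed(1)
  shuffled <- reads[sample(nrow(reads)), ]
  ctx2 <- pileup_context(v, shuffled, fixture_ref()$seq)
  expect_equal(compute_metric_vector(ctx1), compute_metric_vector(ctx2))
})

test_that("mismatch catalog counts depth and co-occurrence per allele", {
  # 8 of 10 supporting reads also carry C at pos+3 (hand-counted)
  ev <- vartag:::build_read_evidence_empty()
  mk_row <- function(id, supports, mm) tibble::tibble(
    read_id = id, flag = 0L, covers = TRUE, supports = supports,
    allele = ifelse(supports, "G", "A"), dist_head = 50L, dist_end = 49L,
    strand = "forward", mapq = 60L, aln_start = 1L, aln_end = 100L,
    has_adjacent_insertion = FALSE, has_adjacent_deletion = FALSE,
    paired = FALSE, mate_mapped = FALSE, mate_covers = FALSE,
    in_mate_overlap = FALSE, mismatches = list(mm))
  ev <- dplyr::bind_rows(
    lapply(1:8, function(i) mk_row(paste0("s", i), TRUE, "1003:C")),
    mk_row("s9", TRUE, character(0)), mk_row("s10", TRUE, character(0)),
    mk_row("n1", FALSE, "1005:T"), mk_row("n2", FALSE, "1005:T"))
  cat <- catalog_mismatches(ev)
  expect_equal(nrow(cat), 2L)
  linked <- cat[cat$pos == 1003, ]
  expect_equal(list(linked$depth, linked$cooccurrence), list(8L, 8L))
  unlinked <- cat[cat$pos == 1005, ]
  expect_equal(list(unlinked$depth, unlinked$cooccurrence), list(2L, 0L))
  # clean pileup: empty catalog
  expect_equal(nrow(catalog_mismatches(mk_row("x", TRUE, character(0)))), 0L)
})

test_that("scored output writes TSV and a round-tripping annotated VCF", {
  dir <- withr::local_tempdir()
  scored <- tibble::tibble(
    chrom = c("chr1", "chr1"), pos = c(100L, 150L), ref = c("A", "C"),
    alt = c("G", "T"), lcr = c(1 / 3, 0), vafr = c(0.2, 0),
    vscore = c(3.0, 0), tags = c("LC", "."))
  vcf_in <- file.path(dir, "in.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=500>",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"),
               "chr1\t100\t.\tA\tG\t.\t.\t.",
               "chr1\t150\t.\tC\tT\t.\t.\tDP=7"), vcf_in)
  paths <- write_scored_output(scored, file.path(dir, "out"), vcf_in = vcf_in)
  tsv <- readLines(paths$tsv)
  expect_true(endsWith(tsv[2], "3.00\tLC"))
  vcf_lines <- readLines(paths$vcf)
  expect_true(any(grepl("VS=3.00;VT=LC", vcf_lines, fixed = TRUE)))
  # tagless variant omits VT and keeps prior INFO
  expect_true(any(grepl("DP=7;VS=0.00$", vcf_lines)))
  # round-trip through a VCF parser
  reparsed <- vcfR::read.vcfR(paths$vcf, verbose = FALSE)
  vs <- vcfR::extract.info(reparsed, "VS")
  expect_equal(as.numeric(vs), c(3.00, 0.00))
  vt <- vcfR::extract.info(reparsed, "VT")
  expect_equal(vt[1], "LC")
  # empty input: header-only outputs
  p0 <- write_scored_output(scored[0, ], file.path(dir, "empty"))
  expect_equal(length(readLines(p0$tsv)), 1L)
})
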