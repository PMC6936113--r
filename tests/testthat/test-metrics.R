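counts_of <- function(...) {
  base <- tibble::tibble(d = 0L, d_m = 0L, d_h = 0L, d_e = 0L, d_insert = 0L,
                         d_del = 0L, d_s_max = 0L, d_d_max = 0L, d_l = 0L,
                         d_mv = 0L, d_mv_alleles = 0L, d_si = 0L, d_p = 0L)
  over <- list(...)
  base[names(over)] <- over
  base
}

test_that("coverage and allele-frequency risks follow their closed forms", {
  cfg <- vartag_config(thr = 15)
  expect_equal(coverage_metrics(counts_of(d = 100L, d_m = 50L), cfg)$lcr, 0)
  expect_equal(coverage_metrics(counts_of(d = 10L, d_m = 5L), cfg)$lcr, 1 / 3)
  expect_equal(coverage_metrics(counts_of(d = 50L, d_m = 5L), cfg)$vafr, 0.9)
  # no reads: maximal risk with a warning
  expect_warning(out <- coverage_metrics(counts_of(), cfg), "no covering")
  expect_equal(list(out$lcr, out$vafr), list(1, 1))
})

test_that("positional, indel, duplicate, strand and MAPQ rates divide by d_m", {
  expect_equal(positional_rates(counts_of(d_m = 10L, d_h = 9L))$nh, 0.9)
  expect_equal(positional_rates(counts_of(d_m = 10L))$ne, 0)
  expect_equal(positional_rates(counts_of(d_m = 1L, d_h = 1L, d_e = 1L)),
               list(nh = 1, ne = 1))
  expect_equal(adjacent_indel_rates(counts_of(d_m = 10L, d_insert = 9L))$ni, 0.9)
  expect_equal(adjacent_indel_rates(counts_of(d_m = 10L))$nd, 0)
  dup <- duplication_strand_rates(counts_of(d_m = 10L, d_s_max = 1L,
                                            d_d_max = 5L))
  expect_equal(list(dup$sse, dup$dir), list(0.1, 0.5))
  expect_equal(duplication_strand_rates(counts_of(d_m = 4L, d_s_max = 4L,
                                                  d_d_max = 4L)),
               list(sse = 1, dir = 1))
  expect_equal(mapping_quality_rate(counts_of(d_m = 8L, d_l = 2L)), 0.25)
  expect_warning(z <- positional_rates(counts_of()), "no supporting")
  expect_equal(z, list(nh = 0, ne = 0))
})

test_that("MAPQ exactly at the threshold is not counted low", {
  cfg <- vartag_config()
  ctx <- sim_context("none", depth = 10, vaf = 1, cfg = cfg)
  ctx$evidence$mapq <- 10L # boundary: strict <
  expect_equal(pileup_counts(ctx)$d_l, 0L)
  ctx$evidence$mapq <- 9L
  expect_equal(pileup_counts(ctx)$d_l, 10L)
})

test_that("head/end distance at the threshold counts as near", {
  ctx <- sim_context("none", depth = 10, vaf = 1)
  ctx$evidence$dist_head <- 5L
  expect_equal(pileup_counts(ctx)$d_h, 10L)
  ctx$evidence$dist_head <- 6L
  expect_equal(pileup_counts(ctx)$d_h, 0L)
})

test_that("mismatch score keeps only rare mismatches", {
  ctx <- random_evidence_context(1)
  # construct exactly: d = 100 impossible at <=30 reads, so scale the
  # arithmetic case directly: depths 1 and 3 at d = 20, n = 20
  ctx$evidence <- ctx$evidence[0, ]
  mk <- function(id, mm) tibble::tibble(
    read_id = id, flag = 0L, covers = TRUE, supports = FALSE, allele = "A",
    dist_head = 50L, dist_end = 49L, strand = "forward", mapq = 60L,
    aln_start = 900L, aln_end = 999L + 100L, has_adjacent_insertion = FALSE,
    has_adjacent_deletion = FALSE, paired = FALSE, mate_mapped = FALSE,
    mate_covers = FALSE, in_mate_overlap = FALSE, mismatches = list(mm))
  rows <- c(list(mk("a", "995:C")),
            lapply(1:3, function(i) mk(paste0("b", i), "1003:T")),
            lapply(4:99, function(i) mk(paste0("c", i), character(0))))
  ctx$evidence <- dplyr::bind_rows(rows)
  ctx$mismatch_catalog <- catalog_mismatches(ctx$evidence)
  # d = 100, freq 0.01 and 0.03 both < 0.05: mm = (1+3)*100/20 = 20
  expect_equal(multiple_mismatch_score(ctx), 20)
  # a mismatch at frequency 0.5 is excluded
  rows2 <- c(lapply(1:50, function(i) mk(paste0("d", i), "995:C")),
             lapply(51:100, function(i) mk(paste0("e", i), character(0))))
  ctx$evidence <- dplyr::bind_rows(rows2)
  ctx$mismatch_catalog <- catalog_mismatches(ctx$evidence)
  expect_equal(multiple_mismatch_score(ctx), 0)
})

test_that("high-discrepancy score follows the concordance-ratio branches", {
  # one fully linked mismatch: d_m = 10, d_i = 8, h = 8 -> HR = 16/18
  ctx <- sim_context("linked_mismatch", depth = 20, vaf = 0.5, seed = 4)
  hd <- high_discrepancy_score(ctx)
  cat <- ctx$mismatch_catalog
  expect_equal(hd$hr_max,
               2 * cat$cooccurrence[1] / (pileup_counts(ctx)$d_m + cat$depth[1]))
  expect_equal(hd$hdr, 1) # fully linked: HR = 2h/(d_m + d_i) = 1
  # two fully linked mismatches: the sum branch exceeds 1
  ctx2 <- sim_context("linked_mismatch", depth = 20, vaf = 0.5, seed = 4,
                      n_linked = 2)
  expect_equal(high_discrepancy_score(ctx2)$hdr, 2)
  # no linked mismatches
  ctx3 <- sim_context("none", seed = 4)
  expect_equal(high_discrepancy_score(ctx3)$hdr, 0)
})

test_that("direct Eq-12 arithmetic matches the published worked case", {
  # d_m = 10, d_i = 8, h = 9 -> HR = 18/18 = 1 -> hdr = 1
  ctx <- random_evidence_context(3)
  ev <- ctx$evidence[0, ]
  mk <- function(id, supports, mm) tibble::tibble(
    read_id = id, flag = 0L, covers = TRUE, supports = supports,
    allele = ifelse(supports, "G", "A"), dist_head = 50L, dist_end = 49L,
    strand = "forward", mapq = 60L, aln_start = 900L, aln_end = 999L,
    has_adjacent_insertion = FALSE, has_adjacent_deletion = FALSE,
    paired = FALSE, mate_mapped = FALSE, mate_covers = FALSE,
    in_mate_overlap = FALSE, mismatches = list(mm))
  # 9 supporters with the mismatch, 1 supporter without, but the mismatch
  # depth must be 8: impossible with h = 9 <= d_i, so use h = 8, d_i = 8
  # plus one extra co-occurrence carried by a non-supporter is not counted
  ev <- dplyr::bind_rows(
    lapply(1:8, function(i) mk(paste0("s", i), TRUE, "1004:T")),
    lapply(9:10, function(i) mk(paste0("s", i), TRUE, character(0))))
  ctx$evidence <- ev
  ctx$mismatch_catalog <- catalog_mismatches(ev)
  hd <- high_discrepancy_score(ctx)
  expect_equal(hd$hr_max, 2 * 8 / (10 + 8))
  expect_equal(hd$hdr, 2 * 8 / (10 + 8)) # below 0.9: max branch
})

test_that("short-insert rate and multiple-variant rate", {
  expect_equal(short_insert_rate(counts_of(d_p = 4L, d_si = 3L)), 0.75)
  expect_equal(short_insert_rate(counts_of()), 0) # single-end data
  ctx <- random_evidence_context(11)
  cand <- "G"
  ev <- ctx$evidence
  d_mv_hand <- sum(ev$covers & !ev$supports & !is.na(ev$allele) &
                   ev$allele != "*" & ev$allele != "A" & ev$allele != cand)
  out <- multiple_variant_rate(ctx)
  expect_equal(out$d_mv, d_mv_hand)
})

test_that("repeat flags detect tracts, unit insertions and duplications", {
  cfg <- vartag_config()
  #       123456789012345678901
  win <- "ACGTACGTTTTTTTGCAAGTC"
  v <- tibble::tibble(chrom = "c", pos = 11L, ref = "T", alt = "A",
                      vclass = "SNV")
  expect_equal(repeat_flags(v, win, cfg)$r, 1L)
  # insertion of T adjacent to the homopolymer: minimal unit match
  vi <- tibble::tibble(chrom = "c", pos = 8L, ref = "T", alt = "TT",
                       vclass = "INS")
  fi <- repeat_flags(vi, win, cfg)
  expect_equal(list(fi$r, fi$ri), list(1L, 1L))
  # SNV far from any tract
  clean <- strrep("ACGGT", 10) # no unit reaches 4 copies contiguously
  vc <- tibble::tibble(chrom = "c", pos = 25L, ref = "G", alt = "A",
                       vclass = "SNV")
  expect_equal(repeat_flags(vc, clean, cfg)$r, 1L) # ACGGT x4+ IS a tract
  cfg6 <- vartag_config(min_copies = 6, unit_len_max = 4)
  expect_equal(repeat_flags(vc, clean, cfg6)$r, 0L)
  # 25-bp insertion duplicating the following reference
  ref <- make_reference(200, seed = 13)$seq
  dup <- substr(ref, 101, 125)
  anchor <- substr(ref, 100, 100)
  vl <- tibble::tibble(chrom = "c", pos = 100L, ref = anchor,
                       alt = paste0(anchor, dup), vclass = "INS")
  expect_equal(repeat_flags(vl, ref, cfg)$li, 1L)
  # same length, different content
  vl2 <- vl
  vl2$alt <- paste0(anchor, strrep("A", 12), strrep("C", 13))
  fl2 <- repeat_flags(vl2, ref, cfg)
  expect_equal(fl2$li, 0L)
})

test_that("empty pileup yields maximal risks and zero rates", {
  v <- fixture_snv()
  ctx <- pileup_context(v, vartag:::empty_read_records(), fixture_ref()$seq)
  m <- compute_metric_vector(ctx)
  expect_equal(list(m$lcr, m$vafr), list(1, 1))
  expect_true(all(unlist(m[c("nh", "ne", "ni", "nd", "sse", "dir", "lm",
                             "mm", "mv", "hdr", "si")]) == 0))
})

test_that("adding a clean mid-read supporter never raises risk rates", {
  ctx <- sim_context("linked_mismatch", depth = 24, vaf = 0.5, seed = 6)
  before <- compute_metric_vector(ctx)
  extra <- tibble::tibble(
    read_id = "extra", flag = 0L, covers = TRUE, supports = TRUE,
    allele = ctx$variant$alt, dist_head = 50L, dist_end = 49L,
    strand = "forward", mapq = 60L, aln_start = ctx$variant$pos - 50L,
    aln_end = ctx$variant$pos + 49L, has_adjacent_insertion = FALSE,
    has_adjacent_deletion = FALSE, paired = FALSE, mate_mapped = FALSE,
    mate_covers = FALSE, in_mate_overlap = FALSE,
    mismatches = list(character(0)))
  ctx$evidence <- dplyr::bind_rows(ctx$evidence, extra)
  ctx$mismatch_catalog <- catalog_mismatches(ctx$evidence)
  after <- compute_metric_vector(ctx)
  for (f in c("vafr", "lm", "nh", "ne", "hdr")) {
    expect_lte(after[[f]], before[[f]])
  }
})
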