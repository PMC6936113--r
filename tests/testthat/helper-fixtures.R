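# Shared fixtures, built in code at test time.

# one memoized clean reference per session
fixture_ref <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_reference(2000, seed = 3)
    cache
  }
})

# a clean SNV candidate at position 1000 on the fixture reference
fixture_snv <- function(pos = 1000L) {
  ref <- fixture_ref()
  refb <- substr(ref$seq, pos, pos)
  variant_call("chr_sim", pos, refb, setdiff(c("A", "C", "G", "T"), refb)[1])
}

# simulate + build context in one call
sim_context <- function(signature, intensity = 1, depth = 50L, vaf = 0.5,
                        seed = 2L, cfg = vartag_config(), n_linked = 1L,
                        variant = NULL, ref = NULL) {
  ref <- ref %||% fixture_ref()
  variant <- variant %||% fixture_snv()
  reads <- simulate_variant_pileup(
    ref$seq, variant,
    artifact_spec(signature, intensity = intensity, depth = depth,
                  vaf = vaf, seed = seed, n_linked = n_linked))
  pileup_context(variant, reads, ref$seq, cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-written 12-record SAM over a small contig. Ten primary reads span
# position 60 but two are flagged duplicates; one secondary and one
# unmapped record are also present. Returns the BAM path.
write_fixture_sam_bam <- function(dir, ref_seq, contig = "chr_fix") {
  len <- nchar(ref_seq)
  sub_at <- function(s, p, b) { substr(s, p, p) <- b; s }
  piece <- function(s, e) substr(ref_seq, s, e)
  rd <- function(qname, flag, pos, mapq, cigar, seq) {
    paste(qname, flag, contig, pos, mapq, cigar, "*", 0, 0, seq,
          strrep("I", nchar(seq)), sep = "\t")
  }
  reads <- c(
    rd("r01", 0, 21, 60, "50M", sub_at(piece(21, 70), 40, "G")), # supports G@60
    rd("r02", 16, 31, 60, "50M", sub_at(piece(31, 80), 30, "G")),
    rd("r03", 0, 35, 60, "50M", piece(35, 84)),                  # reference
    rd("r04", 16, 40, 5, "50M", sub_at(piece(40, 89), 21, "G")), # low MAPQ
    rd("r05", 0, 41, 60, "50M", piece(41, 90)),
    rd("r06", 1024, 45, 60, "50M", piece(45, 94)),               # duplicate
    rd("r07", 1040, 46, 60, "50M", piece(46, 95)),               # duplicate
    rd("r08", 0, 50, 60, "5S45M", paste0("AAAAA", piece(50, 94))), # soft clip
    rd("r09", 16, 55, 60, "50M", piece(55, 104)),
    rd("r10", 0, 57, 60, "2M2D48M",
       paste0(piece(57, 58), piece(61, 108))),                   # del 59-60
    rd("r11", 256, 58, 60, "50M", piece(58, 107)),               # secondary
    rd("r12", 4, 61, 0, "*", "ACGT"))                            # unmapped
  sam <- file.path(dir, "fix.sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", contig, len),
               reads), sam)
  Rsamtools::asBam(sam, file.path(dir, "fix"), overwrite = TRUE,
                   indexDestination = TRUE)
}
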