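# CIGAR geometry: per-op reference/query coordinates for one aligned read.
# Reference coordinates are 1-based inclusive; insertions are anchored to the
# reference base they follow (ref_start == ref_end == anchor).

cigar_ops_table <- function(cigar, aln_start) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  n <- length(ops)
  ref_start <- ref_end <- q_start <- q_end <- integer(n)
  rpos <- aln_start
  qpos <- 1L
  for (i in seq_len(n)) {
    op <- ops[i]; len <- lens[i]
    consumes_ref <- op %in% c("M", "=", "X", "D", "N")
    consumes_q <- op %in% c("M", "=", "X", "I", "S")
    if (op == "I") {
      # anchor: reference base immediately before the inserted sequence
      ref_start[i] <- rpos - 1L
      ref_end[i] <- rpos - 1L
    } else if (consumes_ref) {
      ref_start[i] <- rpos
      ref_end[i] <- rpos + len - 1L
    } else {
      ref_start[i] <- rpos - 1L
      ref_end[i] <- rpos - 1L
    }
    if (consumes_q) {
      q_start[i] <- qpos
      q_end[i] <- qpos + len - 1L
    } else {
      q_start[i] <- qpos
      q_end[i] <- qpos - 1L
    }
    if (consumes_ref) rpos <- rpos + len
    if (consumes_q) qpos <- qpos + len
  }
  list(op = ops, len = lens, ref_start = ref_start, ref_end = ref_end,
       q_start = q_start, q_end = q_end)
}

# last reference base consumed by the alignment
cigar_ref_end <- function(cigar, aln_start) {
  aln_start + GenomicAlignments::cigarWidthAlongReferenceSpace(cigar) - 1L
}

# query index of the base aligned to reference position vpos, or
# NA_integer_ if vpos falls in a deletion/skip; NULL if not covered.
query_index_at <- function(tab, vpos) {
  for (i in seq_along(tab$op)) {
    op <- tab$op[i]
    if (op %in% c("M", "=", "X") && vpos >= tab$ref_start[i] && vpos <= tab$ref_end[i]) {
      return(tab$q_start[i] + (vpos - tab$ref_start[i]))
    }
    if (op %in% c("D", "N") && vpos >= tab$ref_start[i] && vpos <= tab$ref_end[i]) {
      return(NA_integer_)
    }
  }
  NULL
}

# The allele a read presents at vpos: a base, an insertion allele
# "ins:<seq>" (anchored at vpos), a deletion allele "del:<len>" (starting at
# vpos + 1), "*" inside a deletion, or NA when the read does not cover vpos.
read_allele_at <- function(tab, seq, vpos) {
  ins <- which(tab$op == "I" & tab$ref_start == vpos)
  if (length(ins)) {
    return(paste0("ins:", substr(seq, tab$q_start[ins[1]], tab$q_end[ins[1]])))
  }
  del <- which(tab$op == "D" & tab$ref_start == vpos + 1L)
  if (length(del)) {
    return(paste0("del:", tab$len[del[1]]))
  }
  qi <- query_index_at(tab, vpos)
  if (is.null(qi)) return(NA_character_)
  if (is.na(qi)) return("*")
  substr(seq, qi, qi)
}
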