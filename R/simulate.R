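.signatures <- c("none", "near_head", "near_end", "strand_bias",
                 "same_start_end", "low_mapq", "adjacent_insertion",
                 "adjacent_deletion", "linked_mismatch", "many_mismatches",
                 "multi_allele", "low_vaf", "low_coverage",
                 "short_insert_overlap", "repeat_context",
                 "repeat_unit_insertion", "large_duplicative_insertion",
                 "tumor_in_normal", "low_normal_coverage",
                 "no_normal_coverage")

#' Specify an artifact signature for the pileup simulator
#'
#' Each signature is engineered to trip exactly one review tag at
#' sufficient intensity: reads are otherwise clean (mid-read support, high
#' MAPQ, balanced strands, distinct coordinates, reference-matching
#' sequence), so the signature is the only artifact present.
#'
#' @param signature One of the supported signatures (see
#'   `vartag:::.signatures`); `"none"` emits a clean true-variant pileup.
#' @param intensity Fraction of supporting reads carrying the signature
#'   (for `multi_allele` / `many_mismatches`: fraction of covering reads).
#' @param depth Covering reads to simulate at the locus.
#' @param vaf Variant allele fraction among covering reads.
#' @param seed Integer seed; simulation is deterministic given the spec.
#' @param n_linked Number of distinct linked mismatches for
#'   `linked_mismatch` (2 drives `hdr` above 1).
#' @return A list of class `artifact_spec`.
#' @export
artifact_spec <- function(signature = "none", intensity = 1, depth = 50L,
                          vaf = 0.5, seed = 1L, n_linked = 1L) {
  signature <- match.arg(signature, .signatures)
  stopifnot(intensity >= 0, intensity <= 1, vaf >= 0, vaf <= 1, depth >= 0)
  structure(list(signature = signature, intensity = intensity,
                 depth = as.integer(depth), vaf = vaf,
                 seed = as.integer(seed), n_linked = as.integer(n_linked)),
            class = "artifact_spec")
}

#' Generate a synthetic reference contig
#'
#' Random sequence at the requested GC content, with homopolymer runs
#' capped at 3 bp so that repeat context arises only where a repeat tract
#' is explicitly requested.
#'
#' @param length Contig length (bp).
#' @param gc GC fraction.
#' @param repeat_inserts List of `list(pos, unit, copies)`: the tract
#'   `strrep(unit, copies)` overwrites the sequence starting at `pos`.
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @return List with `seq` (character) and `repeats` (tibble of the placed
#'   tracts: `start`, `end`, `unit`, `copies`).
#' @export
#' @examples
#' ref <- make_reference(1000, repeat_inserts = list(list(pos = 500,
#'   unit = "AT", copies = 8)), seed = 7)
#' substr(ref$seq, 500, 515)
make_reference <- function(length, gc = 0.5, repeat_inserts = list(),
                           seed = 1L) {
  stopifnot(length >= 1)
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(p), length, replace = TRUE, prob = p)
  # cap homopolymer runs at 3
  for (i in seq_len(length)) {
    if (i >= 4L && bases[i] == bases[i - 1L] && bases[i] == bases[i - 2L] &&
        bases[i] == bases[i - 3L]) {
      bases[i] <- sample(setdiff(names(p), bases[i]), 1L)
    }
  }
  seq <- paste(bases, collapse = "")
  placed <- purrr::map(repeat_inserts, function(ins) {
    tract <- strrep(ins$unit, ins$copies)
    stopifnot(ins$pos >= 1, ins$pos + nchar(tract) - 1L <= length)
    seq <<- paste0(substr(seq, 1L, ins$pos - 1L), tract,
                   substr(seq, ins$pos + nchar(tract), length))
    tibble::tibble(start = as.integer(ins$pos),
                   end = as.integer(ins$pos + nchar(tract) - 1L),
                   unit = ins$unit, copies = ins$copies)
  })
  list(seq = seq,
       repeats = if (length(placed)) dplyr::bind_rows(placed) else
         tibble::tibble(start = integer(), end = integer(),
                        unit = character(), copies = numeric()))
}

#' Simulate a paired-end read pileup over one candidate variant
#'
#' Emits aligned read records (the same tabular shape [fetch_reads()]
#' returns) realizing the requested depth, allele fraction and artifact
#' signature: `depth` covering reads plus their mates, 100 bp paired-end
#' reads with ~300 bp fragments (short-insert signatures use ~150 bp so
#' mates overlap the locus).
#'
#' @param ref Reference contig: a character string or the list returned by
#'   [make_reference()].
#' @param variant One-row variant tibble from [variant_call()].
#' @param spec An [artifact_spec()].
#' @param read_len Read length (bp).
#' @param fragment_mean,fragment_sd Fragment-size distribution.
#' @param chrom Contig name stamped on the records.
#' @param mapq Default mapping quality for clean reads.
#' @return Tibble of read records ordered by position; consumable by
#'   [pileup_context()] directly or writable with [write_alignment()].
#' @export
simulate_variant_pileup <- function(ref, variant, spec = artifact_spec(),
                                    read_len = 100L, fragment_mean = 300L,
                                    fragment_sd = 30L,
                                    chrom = variant$chrom, mapq = 60L) {
  seq <- if (is.list(ref)) ref$seq else ref
  clen <- nchar(seq)
  vpos <- variant$pos
  sig <- spec$signature
  set.seed(spec$seed)
  n_alt <- round(spec$depth * spec$vaf)
  n_ref <- spec$depth - n_alt
  ins_seq <- if (variant$vclass == "INS") {
    substr(variant$alt, nchar(variant$ref) + 1L, nchar(variant$alt))
  } else ""
  del_len <- if (variant$vclass == "DEL") {
    nchar(variant$ref) - nchar(variant$alt)
  } else 0L
  margin <- 6L
  # default start range keeps the locus clear of both read ends
  start_range <- function(extra = 0L) {
    lo <- max(1L, vpos - read_len + 1L + margin + extra)
    hi <- min(clen - read_len + 1L, vpos - margin)
    if (lo > hi) lo <- hi <- max(1L, min(vpos, clen - read_len + 1L))
    c(lo, hi)
  }
  n_aff <- function(n) round(spec$intensity * n)
  alt_aff <- rep(FALSE, n_alt)
  if (n_alt > 0L && sig %in% c("near_head", "near_end", "strand_bias",
                               "same_start_end", "low_mapq",
                               "adjacent_insertion", "adjacent_deletion",
                               "linked_mismatch", "short_insert_overlap")) {
    alt_aff[seq_len(min(n_alt, n_aff(n_alt)))] <- TRUE
  }
  rows <- vector("list", spec$depth)
  frag_id <- 0L
  emit_pair <- function(s, is_alt, affected) {
    frag_id <<- frag_id + 1L
    qname <- sprintf("sim_%s_%d_%05d", sig, vpos, frag_id)
    this_mapq <- mapq
    short_frag <- affected && sig == "short_insert_overlap"
    frag <- if (short_frag) {
      150L
    } else {
      max(2L * read_len + 10L, round(stats::rnorm(1, fragment_mean, fragment_sd)))
    }
    # strand of the covering read: balanced deterministically
    fwd <- frag_id %% 2L == 1L
    if (affected && sig == "strand_bias") fwd <- TRUE
    if (affected && sig == "low_mapq") this_mapq <- 2L
    if (affected && sig == "same_start_end") {
      s <- max(1L, vpos - floor(read_len / 2L))
    }
    if (affected && sig == "near_head") {
      s <- vpos - (frag_id %% (1L + min(5L, vpos - 1L)))
    }
    if (affected && sig == "near_end") {
      s <- vpos - read_len + 1L + (frag_id %% 6L)
      s <- max(1L, s)
    }
    if (short_frag) {
      # both mates must cover, neither end near the locus; the overlap
      # sits on the mate-facing side of the covering read
      off <- if (fwd) 56L + (frag_id %% 38L) else 6L + (frag_id %% 38L)
      s <- max(1L, vpos - off)
    }
    # mate placement
    if (fwd) {
      mate_s <- min(s + frag - read_len, clen - read_len + 1L)
      flag <- 99L; mflag <- 147L
      isize <- mate_s + read_len - s
    } else {
      mate_s <- max(1L, s - (frag - read_len))
      flag <- 83L; mflag <- 163L
      isize <- -(s + read_len - mate_s)
    }
    # build the covering read
    mism <- character(0)
    if (is_alt && affected && sig == "linked_mismatch") {
      offs <- c(3L, -4L)[seq_len(min(spec$n_linked, 2L))]
      mism <- vpos + offs
    }
    if (!is_alt && sig == "many_mismatches" && affected) {
      mism <- vpos + c(2L, -3L, 5L)
    }
    third <- !is_alt && affected && sig == "multi_allele"
    extra_ins_at <- if (is_alt && affected && sig == "adjacent_insertion") {
      vpos + 2L
    } else NA_integer_
    extra_del_at <- if (is_alt && affected && sig == "adjacent_deletion") {
      vpos + 2L
    } else NA_integer_
    cov <- build_sim_read(seq, s, read_len, vpos, variant, is_alt,
                          ins_seq, del_len, mism, third, extra_ins_at,
                          extra_del_at)
    covering <- tibble::tibble(
      qname = qname, flag = flag, chrom = chrom, pos = s, mapq = this_mapq,
      cigar = cov$cigar, seq = cov$seq, mpos = mate_s, isize = isize)
    # the mate: clean reference copy unless it also covers (short fragments)
    mate_alt <- is_alt && short_frag
    mt <- build_sim_read(seq, mate_s, read_len, vpos, variant, mate_alt,
                         ins_seq, del_len, character(0), FALSE,
                         NA_integer_, NA_integer_)
    mate <- tibble::tibble(
      qname = qname, flag = mflag, chrom = chrom, pos = mate_s,
      mapq = this_mapq, cigar = mt$cigar, seq = mt$seq, mpos = s,
      isize = -isize)
    dplyr::bind_rows(covering, mate)
  }
  k_alt <- 0L; k_ref <- 0L
  # affected non-supporting reads for multi_allele / many_mismatches
  ref_aff <- rep(FALSE, n_ref)
  if (sig %in% c("multi_allele", "many_mismatches") && n_ref > 0L) {
    ref_aff[seq_len(min(n_ref, round(spec$intensity * spec$depth)))] <- TRUE
  }
  for (i in seq_len(spec$depth)) {
    is_alt <- i <= n_alt
    aff <- if (is_alt) {
      k_alt <- k_alt + 1L
      alt_aff[k_alt]
    } else {
      k_ref <- k_ref + 1L
      ref_aff[k_ref]
    }
    extra <- if (is_alt && variant$vclass == "INS") nchar(ins_seq) + margin else 0L
    rng <- start_range(extra)
    s <- rng[1] + ((i * 37L) %% max(1L, rng[2] - rng[1] + 1L))
    rows[[i]] <- emit_pair(s, is_alt, aff)
  }
  out <- if (spec$depth > 0L) dplyr::bind_rows(rows) else empty_read_records()
  dplyr::arrange(out, .data$pos, .data$qname)
}

# one simulated read: sequence + CIGAR given its start and payload
build_sim_read <- function(refseq, s, read_len, vpos, variant, is_alt,
                           ins_seq, del_len, mism_pos, third_allele,
                           extra_ins_at, extra_del_at) {
  clen <- nchar(refseq)
  covers <- vpos >= s && vpos < s + read_len
  events <- list() # list of (ref_pos, type, payload) applied left to right
  if (is_alt && covers) {
    if (variant$vclass == "INS") {
      events <- c(events, list(list(pos = vpos, type = "ins", payload = ins_seq)))
    } else if (variant$vclass == "DEL") {
      events <- c(events, list(list(pos = vpos, type = "del", payload = del_len)))
    } else {
      events <- c(events, list(list(pos = vpos, type = "sub",
                                    payload = variant$alt)))
    }
  }
  if (third_allele && covers) {
    refb <- substr(refseq, vpos, vpos)
    other <- setdiff(c("A", "C", "G", "T"), c(refb, variant$alt))[1]
    events <- c(events, list(list(pos = vpos, type = "sub", payload = other)))
  }
  for (mp in mism_pos) {
    if (mp >= s && mp < s + read_len && mp >= 1L && mp <= clen) {
      refb <- substr(refseq, mp, mp)
      sub <- setdiff(c("A", "C", "G", "T"), refb)[1]
      events <- c(events, list(list(pos = mp, type = "sub", payload = sub)))
    }
  }
  if (!is.na(extra_ins_at) && extra_ins_at >= s && extra_ins_at < s + read_len - 3L) {
    events <- c(events, list(list(pos = extra_ins_at, type = "ins",
                                  payload = "CA")))
  }
  if (!is.na(extra_del_at) && extra_del_at >= s && extra_del_at < s + read_len - 3L) {
    events <- c(events, list(list(pos = extra_del_at, type = "del",
                                  payload = 2L)))
  }
  ord <- order(vapply(events, function(e) e$pos, numeric(1)))
  events <- events[ord]
  seq_out <- ""
  cigar <- character(0)
  push_m <- function(cig, n) {
    if (n > 0L) c(cig, paste0(n, "M")) else cig
  }
  rpos <- s          # next reference base to consume
  remaining <- read_len # query bases still to emit
  for (e in events) {
    if (remaining <= 0L) break
    if (e$pos < rpos) next
    lead <- min(e$pos - rpos + 1L, remaining) # through the event anchor
    chunk <- substr(refseq, rpos, rpos + lead - 1L)
    if (e$type == "sub" && lead == e$pos - rpos + 1L) {
      substr(chunk, nchar(chunk), nchar(chunk)) <- e$payload
    }
    seq_out <- paste0(seq_out, chunk)
    cigar <- push_m(cigar, lead)
    rpos <- rpos + lead
    remaining <- remaining - lead
    if (remaining <= 0L) break
    if (e$type == "ins") {
      take <- min(nchar(e$payload), remaining)
      seq_out <- paste0(seq_out, substr(e$payload, 1L, take))
      cigar <- c(cigar, paste0(take, "I"))
      remaining <- remaining - take
    } else if (e$type == "del") {
      cigar <- c(cigar, paste0(e$payload, "D"))
      rpos <- rpos + e$payload
    }
  }
  if (remaining > 0L) {
    tail_len <- min(remaining, clen - rpos + 1L)
    seq_out <- paste0(seq_out, substr(refseq, rpos, rpos + tail_len - 1L))
    cigar <- push_m(cigar, tail_len)
    remaining <- remaining - tail_len
  }
  # merge adjacent M runs
  cig <- merge_cigar(cigar)
  list(seq = seq_out, cigar = cig)
}

merge_cigar <- function(parts) {
  if (!length(parts)) return("")
  ops <- sub("^[0-9]+", "", parts)
  lens <- as.integer(sub("[MID]$", "", parts))
  out_ops <- character(0); out_lens <- integer(0)
  for (i in seq_along(ops)) {
    if (length(out_ops) && out_ops[length(out_ops)] == ops[i]) {
      out_lens[length(out_lens)] <- out_lens[length(out_lens)] + lens[i]
    } else {
      out_ops <- c(out_ops, ops[i])
      out_lens <- c(out_lens, lens[i])
    }
  }
  paste0(out_lens, out_ops, collapse = "")
}

#' Write simulated read records to a sorted, indexed BAM
#'
#' @param reads Read-record tibble (from [simulate_variant_pileup()] or
#'   concatenated pileups).
#' @param contig,contig_len Contig name and length for the header.
#' @param bam_prefix Output path without extension; `<prefix>.bam` and its
#'   index are created.
#' @return Path to the BAM file.
#' @export
write_alignment <- function(reads, contig, contig_len, bam_prefix) {
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len))
  reads <- dplyr::arrange(reads, .data$pos, .data$qname, .data$flag)
  body <- if (nrow(reads)) {
    paste(reads$qname, reads$flag, reads$chrom, reads$pos, reads$mapq,
          reads$cigar, "=", reads$mpos, reads$isize, reads$seq,
          strrep("I", nchar(reads$seq)), sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, bam_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

#' Generate a complete labeled synthetic dataset on disk
#'
#' Writes a reference FASTA (+ index), a coordinate-sorted indexed tumor
#' BAM (and a normal BAM in somatic mode), a VCF of candidate calls and a
#' truth TSV. Variants are spaced along one contig; each receives an
#' artifact signature drawn from `signature_mix`, with `"none"` labeled
#' true (1) and every artifact labeled false (0) — a simulation convention
#' for supervised evaluation.
#'
#' @param dir Output directory (created if needed).
#' @param n_variants Number of candidate variants.
#' @param signature_mix Named fractions over signatures, summing to 1.
#' @param somatic Also emit a matched normal track.
#' @param depth,vaf Baseline depth and allele fraction (signature-specific
#'   overrides apply, e.g. `low_coverage` uses depth 5, `low_vaf` uses
#'   VAF 0.08).
#' @param seed Integer seed; the whole dataset is reproducible.
#' @param cfg A [vartag_config()] (controls the repeat definition used to
#'   keep clean loci repeat-free).
#' @return List with paths (`ref_fasta`, `tumor_bam`, `normal_bam`, `vcf`,
#'   `truth_tsv`), the contig name/length, and the `truth` tibble
#'   (`chrom`, `pos`, `ref`, `alt`, `label`, `signature`).
#' @export
generate_dataset <- function(dir, n_variants,
                             signature_mix = c(none = 0.5, low_vaf = 0.1,
                                               near_head = 0.1,
                                               linked_mismatch = 0.1,
                                               strand_bias = 0.1,
                                               low_coverage = 0.1),
                             somatic = FALSE, depth = 50L, vaf = 0.5,
                             seed = 1L, cfg = vartag_config()) {
  if (abs(sum(signature_mix) - 1) > 1e-8) {
    stop("signature_mix must sum to 1 (got ", sum(signature_mix), ")")
  }
  bad <- setdiff(names(signature_mix), .signatures)
  if (length(bad)) stop("unknown signature(s): ", paste(bad, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contig <- "chr_sim"
  spacing <- 400L
  clen <- max(4000L, (n_variants + 2L) * spacing)
  # largest-remainder apportionment keeps the mix exact
  raw <- signature_mix * n_variants
  n_k <- floor(raw)
  rem <- n_variants - sum(n_k)
  if (rem > 0L) {
    extra <- order(raw - n_k, decreasing = TRUE)[seq_len(rem)]
    n_k[extra] <- n_k[extra] + 1L
  }
  sig_of <- rep(names(signature_mix), times = n_k)
  set.seed(seed)
  sig_of <- sample(sig_of)
  loci <- spacing * seq_len(n_variants) + 100L
  repeat_ins <- list()
  for (i in seq_len(n_variants)) {
    if (sig_of[i] == "repeat_context") {
      repeat_ins <- c(repeat_ins, list(list(pos = loci[i] - 3L, unit = "T",
                                            copies = 7L)))
    } else if (sig_of[i] == "repeat_unit_insertion") {
      repeat_ins <- c(repeat_ins, list(list(pos = loci[i] + 1L, unit = "AT",
                                            copies = 6L)))
    }
  }
  ref <- make_reference(clen, repeat_inserts = repeat_ins, seed = seed + 1L)
  # nudge clean loci off chance repeat tracts
  for (i in seq_len(n_variants)) {
    if (sig_of[i] %in% c("repeat_context", "repeat_unit_insertion")) next
    tries <- 0L
    while (tries < 12L) {
      refb <- substr(ref$seq, loci[i], loci[i])
      probe <- variant_call(contig, loci[i], refb,
                            setdiff(c("A", "C", "G", "T"), refb)[1])
      rf <- repeat_flags(probe, ref$seq, cfg)
      if (rf$r == 0L) break
      loci[i] <- loci[i] + 17L
      tries <- tries + 1L
    }
  }
  variants <- vector("list", n_variants)
  tumor_reads <- vector("list", n_variants)
  normal_reads <- if (somatic) vector("list", n_variants) else NULL
  labels <- integer(n_variants)
  for (i in seq_len(n_variants)) {
    sig <- sig_of[i]
    p <- loci[i]
    refb <- substr(ref$seq, p, p)
    v <- switch(sig,
      repeat_unit_insertion = variant_call(contig, p, refb, paste0(refb, "AT")),
      large_duplicative_insertion = variant_call(
        contig, p, refb, paste0(refb, substr(ref$seq, p + 1L, p + 22L))),
      variant_call(contig, p, refb, setdiff(c("A", "C", "G", "T"), refb)[1]))
    d_i <- if (sig == "low_coverage") 5L else depth
    v_i <- if (sig == "low_vaf") 0.08 else vaf
    tum_sig <- if (sig %in% c("tumor_in_normal", "low_normal_coverage",
                              "no_normal_coverage", "repeat_context",
                              "repeat_unit_insertion",
                              "large_duplicative_insertion")) "none" else sig
    spec <- artifact_spec(tum_sig, intensity = 1, depth = d_i, vaf = v_i,
                          seed = seed + 10L + i)
    tumor_reads[[i]] <- simulate_variant_pileup(ref$seq, v, spec,
                                                chrom = contig)
    if (somatic) {
      normal_reads[[i]] <- simulate_normal_pileup(ref$seq, v, sig,
                                                  depth = 40L,
                                                  seed = seed + 9000L + i,
                                                  chrom = contig)
    }
    labels[i] <- as.integer(sig == "none")
    variants[[i]] <- v
  }
  truth <- if (n_variants > 0L) {
    dplyr::bind_rows(variants) |>
      dplyr::mutate(label = labels, signature = sig_of) |>
      dplyr::select("chrom", "pos", "ref", "alt", "label", "signature")
  } else {
    tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), label = integer(),
                   signature = character())
  }
  # write files
  ref_fasta <- file.path(dir, "reference.fa")
  dna <- Biostrings::DNAStringSet(stats::setNames(ref$seq, contig))
  Biostrings::writeXStringSet(dna, ref_fasta)
  Rsamtools::indexFa(ref_fasta)
  bind_reads <- function(x) {
    if (length(x)) dplyr::bind_rows(x) else empty_read_records()
  }
  tumor_bam <- write_alignment(bind_reads(tumor_reads), contig, clen,
                               file.path(dir, "tumor"))
  normal_bam <- if (somatic) {
    write_alignment(bind_reads(normal_reads), contig, clen,
                    file.path(dir, "normal"))
  } else NULL
  vcf <- file.path(dir, "calls.vcf")
  write_minimal_vcf(truth, contig, clen, vcf)
  truth_tsv <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(ref_fasta = ref_fasta, tumor_bam = tumor_bam, normal_bam = normal_bam,
       vcf = vcf, truth_tsv = truth_tsv, contig = contig, contig_len = clen,
       truth = truth)
}

# normal-track pileup per signature: clean reference coverage unless the
# signature manipulates the normal track
simulate_normal_pileup <- function(refseq, variant, sig, depth = 40L, seed = 1L,
                                   chrom = variant$chrom) {
  if (sig == "no_normal_coverage") return(empty_read_records())
  nd <- if (sig == "low_normal_coverage") 3L else depth
  nv <- if (sig == "tumor_in_normal") 0.3 else 0
  simulate_variant_pileup(refseq, variant,
                          artifact_spec("none", depth = nd, vaf = nv,
                                        seed = seed),
                          chrom = chrom)
}

write_minimal_vcf <- function(truth, contig, contig_len, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", contig, contig_len),
           paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                               "FILTER", "INFO"), collapse = "\t")))
  body <- if (nrow(truth)) {
    paste(truth$chrom, truth$pos, ".", truth$ref, truth$alt, ".", ".", ".",
          sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  path
}
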