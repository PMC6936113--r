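#' Fetch aligned reads covering a locus from an indexed alignment file
#'
#' Retrieves the primary, non-duplicate, non-secondary/supplementary reads
#' whose aligned span intersects `[pos - pad, pos + pad]`, using the BAM
#' index so that retrieval cost is logarithmic in track size.
#'
#' @param bam_path Path to a coordinate-sorted, indexed BAM file.
#' @param chrom,pos Locus (1-based).
#' @param pad Padding in bp around the locus (default 0).
#' @param cfg A [vartag_config()]; `cfg$filter_reads = FALSE` keeps
#'   duplicates and secondary/supplementary records.
#' @return Tibble of raw read records (one row per read): `qname`, `flag`,
#'   `chrom`, `pos` (leftmost aligned base), `mapq`, `cigar`, `seq`,
#'   `mpos`, `isize`. Reads are ordered by alignment start. An empty tibble
#'   (not an error) is returned for a locus beyond all alignments.
#' @seealso [pileup_context()] which turns these records into per-read
#'   evidence.
#' @export
fetch_reads <- function(bam_path, chrom, pos, pad = 0L, cfg = vartag_config()) {
  if (!file.exists(bam_path)) stop("alignment file not found: ", bam_path)
  idx <- paste0(bam_path, ".bai")
  if (!file.exists(idx) && !file.exists(sub("\\.bam$", ".bai", bam_path))) {
    stop("no index found for ", bam_path,
         "; index it first (e.g. Rsamtools::indexBam or samtools index)")
  }
  flag <- if (cfg$filter_reads) {
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                           isSecondaryAlignment = FALSE,
                           isSupplementaryAlignment = FALSE,
                           isDuplicate = FALSE)
  } else {
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  if (!chrom %in% names(hdr)) {
    return(empty_read_records())
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(max(1L, pos - pad), pos + pad))
  par <- Rsamtools::ScanBamParam(
    flag = flag, which = gr,
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq",
             "mrnm", "mpos", "isize"))
  res <- Rsamtools::scanBam(bam_path, param = par)[[1]]
  if (length(res$qname) == 0L) return(empty_read_records())
  tibble::tibble(
    qname = res$qname,
    flag = as.integer(res$flag),
    chrom = as.character(res$rname),
    pos = as.integer(res$pos),
    mapq = as.integer(res$mapq),
    cigar = res$cigar,
    seq = as.character(res$seq),
    mpos = as.integer(res$mpos),
    isize = as.integer(res$isize)) |>
    dplyr::arrange(.data$pos, .data$qname)
}

empty_read_records <- function() {
  tibble::tibble(qname = character(), flag = integer(), chrom = character(),
                 pos = integer(), mapq = integer(), cigar = character(),
                 seq = character(), mpos = integer(), isize = integer())
}

#' Classify a read's support for a candidate variant
#'
#' A read supports an SNV when the base aligned to the variant position
#' equals the alternate allele; an insertion when an insertion of exactly
#' the inserted sequence is anchored at the variant position; a deletion
#' when a deletion of exactly the deleted length starts one base after the
#' variant position. A read that spans the position without carrying the
#' allele covers only.
#'
#' @param read One-row read record (as returned by [fetch_reads()]).
#' @param variant One-row variant tibble from [variant_call()].
#' @return One of `"supports"`, `"covers_only"`, `"no_cover"`.
#' @export
classify_support <- function(read, variant) {
  if (nchar(read$seq) != GenomicAlignments::cigarWidthAlongQuerySpace(read$cigar)) {
    stop("malformed read ", read$qname,
         ": sequence length does not match CIGAR query width")
  }
  tab <- cigar_ops_table(read$cigar, read$pos)
  aln_end <- cigar_ref_end(read$cigar, read$pos)
  vpos <- variant$pos
  if (vpos < read$pos || vpos > aln_end) return("no_cover")
  allele <- read_allele_at(tab, read$seq, vpos)
  if (identical(allele, candidate_allele_string(variant))) "supports" else "covers_only"
}

# Per-read evidence at a locus. `ref_seq` is the contig (or window)
# sequence starting at reference position `ref_offset`.
build_read_evidence <- function(reads, variant, ref_seq, cfg = vartag_config(),
                                ref_offset = 1L) {
  vpos <- variant$pos
  cand <- candidate_allele_string(variant)
  win <- cfg$window
  refbase <- function(p) {
    i <- p - ref_offset + 1L
    if (i < 1L || i > nchar(ref_seq)) NA_character_ else substr(ref_seq, i, i)
  }
  one <- function(k) {
    rd <- reads[k, ]
    tab <- cigar_ops_table(rd$cigar, rd$pos)
    aln_end <- cigar_ref_end(rd$cigar, rd$pos)
    covers <- vpos >= rd$pos && vpos <= aln_end
    allele <- if (covers) read_allele_at(tab, rd$seq, vpos) else NA_character_
    supports <- covers && identical(allele, cand)
    # indel ops near the locus, the candidate's own event excluded
    ii <- which(tab$op == "I")
    if (variant$vclass == "INS") ii <- ii[tab$ref_start[ii] != vpos]
    dd <- which(tab$op == "D")
    if (variant$vclass == "DEL") {
      dd <- dd[!(tab$ref_start[dd] == vpos + 1L &
                 tab$len[dd] == nchar(variant$ref) - nchar(variant$alt))]
    }
    ins_dist <- if (length(ii)) {
      min(pmin(abs(tab$ref_start[ii] - vpos), abs(tab$ref_start[ii] + 1L - vpos)))
    } else Inf
    del_dist <- if (length(dd)) {
      min(ifelse(vpos >= tab$ref_start[dd] & vpos <= tab$ref_end[dd], 0L,
                 pmin(abs(tab$ref_start[dd] - vpos), abs(tab$ref_end[dd] - vpos))))
    } else Inf
    paired <- bitwAnd(rd$flag, 1L) > 0L
    mate_mapped <- paired && bitwAnd(rd$flag, 8L) == 0L && !is.na(rd$mpos)
    # mate span approximated from mate start and this read's length
    mate_covers <- mate_mapped &&
      vpos >= rd$mpos && vpos <= rd$mpos + nchar(rd$seq) - 1L
    # substitution mismatches within the window, locus excluded
    mm <- character(0)
    for (j in which(tab$op %in% c("M", "=", "X"))) {
      lo <- max(tab$ref_start[j], vpos - win)
      hi <- min(tab$ref_end[j], vpos + win)
      if (lo > hi) next
      for (p in lo:hi) {
        if (p == vpos) next
        rb <- refbase(p)
        qb <- substr(rd$seq, tab$q_start[j] + (p - tab$ref_start[j]),
                     tab$q_start[j] + (p - tab$ref_start[j]))
        if (!is.na(rb) && qb != "N" && qb != rb) {
          mm <- c(mm, paste0(p, ":", qb))
        }
      }
    }
    tibble::tibble(
      read_id = rd$qname, flag = rd$flag,
      covers = covers, supports = supports, allele = allele,
      dist_head = if (covers) vpos - rd$pos else NA_integer_,
      dist_end = if (covers) aln_end - vpos else NA_integer_,
      strand = if (bitwAnd(rd$flag, 16L) > 0L) "reverse" else "forward",
      mapq = rd$mapq, aln_start = rd$pos, aln_end = aln_end,
      has_adjacent_insertion = is.finite(ins_dist) && ins_dist <= cfg$near_dist,
      has_adjacent_deletion = is.finite(del_dist) && del_dist <= cfg$near_dist,
      paired = paired, mate_mapped = mate_mapped, mate_covers = mate_covers,
      in_mate_overlap = covers && mate_covers,
      mismatches = list(mm))
  }
  if (nrow(reads) == 0L) {
    return(build_read_evidence_empty())
  }
  dplyr::bind_rows(purrr::map(seq_len(nrow(reads)), one)) |>
    dplyr::arrange(.data$aln_start, .data$read_id)
}

build_read_evidence_empty <- function() {
  tibble::tibble(read_id = character(), flag = integer(), covers = logical(),
                 supports = logical(), allele = character(),
                 dist_head = integer(), dist_end = integer(),
                 strand = character(), mapq = integer(), aln_start = integer(),
                 aln_end = integer(), has_adjacent_insertion = logical(),
                 has_adjacent_deletion = logical(), paired = logical(),
                 mate_mapped = logical(), mate_covers = logical(),
                 in_mate_overlap = logical(),
                 mismatches = list())
}

#' Catalog secondary mismatches around a candidate variant
#'
#' Collects every (position, base) substitution mismatch observed within
#' the reference window around the locus, excluding the candidate allele
#' itself, with its read depth and its co-occurrence with supporting reads.
#'
#' @param evidence Per-read evidence tibble (see [pileup_context()]).
#' @return Tibble with columns `pos`, `allele`, `depth` (reads carrying the
#'   mismatch) and `cooccurrence` (reads carrying it that also support the
#'   candidate). Empty catalog is valid.
#' @export
catalog_mismatches <- function(evidence) {
  keys <- unlist(evidence$mismatches, use.names = FALSE)
  if (length(keys) == 0L) {
    return(tibble::tibble(pos = integer(), allele = character(),
                          depth = integer(), cooccurrence = integer()))
  }
  per_read <- tibble::tibble(
    key = keys,
    supports = rep(evidence$supports, lengths(evidence$mismatches)))
  per_read |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(depth = dplyr::n(),
                     cooccurrence = sum(.data$supports), .groups = "drop") |>
    tidyr::separate(.data$key, into = c("pos", "allele"), sep = ":", convert = TRUE) |>
    dplyr::arrange(.data$pos, .data$allele)
}

#' Assemble the pileup context for one candidate variant
#'
#' Combines raw read records, the reference window and the mismatch catalog
#' into the single object all metric computations consume.
#'
#' @param variant One-row variant tibble ([variant_call()]).
#' @param reads Read-record tibble ([fetch_reads()] or the synthetic
#'   generator).
#' @param ref_seq Contig (or window) sequence as a character string.
#' @param cfg A [vartag_config()].
#' @param ref_offset 1-based reference position of the first `ref_seq` base.
#' @return A `pileup_context` list: `variant`, `evidence`, `mismatch_catalog`,
#'   `ref_window`, `window_n` (reference positions within the window,
#'   locus excluded), `cfg`.
#' @export
pileup_context <- function(variant, reads, ref_seq, cfg = vartag_config(),
                           ref_offset = 1L) {
  stopifnot(nrow(variant) == 1L)
  evidence <- build_read_evidence(reads, variant, ref_seq, cfg, ref_offset)
  contig_last <- ref_offset + nchar(ref_seq) - 1L
  lo <- max(ref_offset, variant$pos - cfg$window)
  hi <- min(contig_last, variant$pos + cfg$window)
  window_n <- (hi - lo + 1L) - 1L # exclude the locus itself
  ref_window <- substr(ref_seq, lo - ref_offset + 1L, hi - ref_offset + 1L)
  structure(
    list(variant = variant, evidence = evidence,
         mismatch_catalog = catalog_mismatches(evidence),
         ref_window = ref_window, window_start = lo, window_n = window_n,
         ref_seq = ref_seq, ref_offset = as.integer(ref_offset), cfg = cfg),
    class = "pileup_context")
}

#' @export
print.pileup_context <- function(x, ...) {
  cat(sprintf("<pileup_context> %s:%d %s>%s (%s)\n", x$variant$chrom,
              x$variant$pos, x$variant$ref, x$variant$alt, x$variant$vclass))
  cat(sprintf("  reads: %d covering, %d supporting; %d cataloged mismatches\n",
              sum(x$evidence$covers), sum(x$evidence$supports),
              nrow(x$mismatch_catalog)))
  invisible(x)
}
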