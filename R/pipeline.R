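#' Score every candidate variant in a VCF against an alignment
#'
#' The end-to-end scoring pipeline: load and normalize candidates, fetch
#' the covering reads per locus, compute the metric vector (plus the two
#' normal-track metrics in somatic mode), assign review tags and the
#' weighted v-score. Per-variant results are independent of worker count
#' and processing order.
#'
#' @param bam Path to the (tumor) alignment, coordinate-sorted and indexed.
#' @param vcf Path to the candidate VCF, or a variant tibble as returned by
#'   [load_variants()].
#' @param ref Path to an indexed FASTA, or a named character vector of
#'   contig sequences.
#' @param cfg A [vartag_config()].
#' @param weights Metric weights ([vartag_weights()]).
#' @param mode `"germline"` or `"somatic"`.
#' @param normal_bam Matched normal alignment; required in somatic mode.
#' @param workers Parallel workers for per-variant scoring (forked;
#'   results are deterministic regardless of the count).
#' @return Tibble with one row per candidate: identity columns, the metric
#'   vector, the underlying counts, `vscore` and `tags`
#'   (semicolon-joined, `"."` when none).
#' @export
score_variants <- function(bam, vcf, ref, cfg = vartag_config(),
                           weights = vartag_weights(),
                           mode = c("germline", "somatic"),
                           normal_bam = NULL, workers = 1L) {
  mode <- match.arg(mode)
  if (mode == "somatic" && is.null(normal_bam)) {
    stop("somatic mode requires a matched normal alignment (normal_bam)")
  }
  ref_get <- reference_accessor(ref)
  variants <- if (is.character(vcf)) load_variants(vcf) else vcf
  if (nrow(variants) == 0L) {
    return(empty_scored(mode))
  }
  score_one <- function(i) {
    v <- variants[i, ]
    span <- max(cfg$window, cfg$li_len + 2L, 150L)
    rw <- ref_get(v$chrom, v$pos - span, v$pos + span)
    reads <- fetch_reads(bam, v$chrom, v$pos, pad = 0L, cfg = cfg)
    ctx <- pileup_context(v, reads, rw$seq, cfg, ref_offset = rw$start)
    if (mode == "germline") {
      m <- compute_metric_vector(ctx)
    } else {
      nreads <- fetch_reads(normal_bam, v$chrom, v$pos, pad = 0L, cfg = cfg)
      nctx <- pileup_context(v, nreads, rw$seq, cfg, ref_offset = rw$start)
      m <- score_somatic_variant(ctx, nctx, weights)
    }
    vs <- vscore(m, weights)
    tags <- assign_tags(m, cfg, mode)
    dplyr::bind_cols(v, m,
                     tibble::tibble(vscore = vs,
                                    tags = if (length(tags)) {
                                      paste(tags, collapse = ";")
                                    } else "."))
  }
  idx <- seq_len(nrow(variants))
  rows <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, score_one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(idx, score_one)
  }
  dplyr::bind_rows(rows)
}

empty_scored <- function(mode) {
  base <- tibble::tibble(chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         vclass = character())
  feats <- if (mode == "germline") .metrics_germline else .metrics_somatic
  for (f in feats) base[[f]] <- numeric(0)
  base$vscore <- numeric(0)
  base$tags <- character(0)
  base
}

# uniform window access over a FASTA path or in-memory named sequences
reference_accessor <- function(ref) {
  if (is.character(ref) && length(ref) == 1L && file.exists(ref)) {
    fa <- Rsamtools::FaFile(ref)
    if (!file.exists(paste0(ref, ".fai"))) Rsamtools::indexFa(ref)
    lens <- Rsamtools::scanFaIndex(fa)
    len_of <- stats::setNames(GenomicRanges::width(lens),
                              as.character(GenomicRanges::seqnames(lens)))
    function(chrom, start, end) {
      if (!chrom %in% names(len_of)) stop("contig '", chrom,
                                          "' absent from reference")
      start <- max(1L, start); end <- min(len_of[[chrom]], end)
      gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
      list(seq = as.character(Rsamtools::getSeq(fa, gr)[[1]]), start = start)
    }
  } else {
    stopifnot(is.character(ref), !is.null(names(ref)))
    function(chrom, start, end) {
      if (!chrom %in% names(ref)) stop("contig '", chrom,
                                       "' absent from reference")
      start <- max(1L, start); end <- min(nchar(ref[[chrom]]), end)
      list(seq = substr(ref[[chrom]], start, end), start = start)
    }
  }
}

#' Write scored variants to TSV and an annotated VCF
#'
#' Writes `<out_prefix>.tsv` with one row per variant (identity, every
#' metric, v-score to two decimals, semicolon-joined tags) and, when the
#' input VCF is supplied, `<out_prefix>.vcf`: a copy of the input with INFO
#' keys `VS` (v-score, two decimals, one value per alt allele) and `VT`
#' (tags joined by `|` within an allele) declared in the header. Records
#' whose alleles were all untagged omit `VT`.
#'
#' @param scored Tibble from [score_variants()].
#' @param out_prefix Output path prefix.
#' @param vcf_in Optional path to the input VCF to annotate.
#' @return Named list of written paths (`tsv`, and `vcf` if produced).
#' @export
write_scored_output <- function(scored, out_prefix, vcf_in = NULL) {
  metric_cols <- intersect(.metrics_somatic, names(scored))
  tsv <- paste0(out_prefix, ".tsv")
  df <- scored
  out <- data.frame(chrom = df$chrom, pos = df$pos, ref = df$ref,
                    alt = df$alt, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (mc in metric_cols) out[[mc]] <- sprintf("%.4f", df[[mc]])
  out$vscore <- sprintf("%.2f", df$vscore)
  out$tags <- if (nrow(df)) df$tags else character(0)
  dir.create(dirname(tsv), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- list(tsv = tsv)
  if (!is.null(vcf_in)) {
    paths$vcf <- annotate_vcf(scored, vcf_in, paste0(out_prefix, ".vcf"))
  }
  paths
}

annotate_vcf <- function(scored, vcf_in, vcf_out) {
  lines <- readLines(vcf_in)
  is_hdr <- startsWith(lines, "#")
  chrom_line <- which(startsWith(lines, "#CHROM"))
  info_hdr <- c(
    paste0("##INFO=<ID=VS,Number=A,Type=Float,",
           "Description=\"Weighted variant score; low means likely true\">"),
    paste0("##INFO=<ID=VT,Number=A,Type=String,",
           "Description=\"Review tags per alt allele, joined by |\">"))
  header <- append(lines[is_hdr], info_hdr, after = chrom_line - 1L)
  key <- paste(scored$chrom, scored$pos, scored$ref, scored$alt, sep = "\r")
  body <- vapply(lines[!is_hdr], function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    hits <- match(paste(f[1], f[2], f[4], alts, sep = "\r"), key)
    if (all(is.na(hits))) return(ln)
    vs <- vapply(hits, function(h) {
      if (is.na(h)) "." else sprintf("%.2f", scored$vscore[h])
    }, character(1))
    vt <- vapply(hits, function(h) {
      if (is.na(h) || scored$tags[h] == ".") "." else
        gsub(";", "|", scored$tags[h], fixed = TRUE)
    }, character(1))
    add <- paste0("VS=", paste(vs, collapse = ","))
    if (any(vt != ".")) add <- paste0(add, ";VT=", paste(vt, collapse = ","))
    f[8] <- if (f[8] %in% c(".", "")) add else paste0(f[8], ";", add)
    paste(f, collapse = "\t")
  }, character(1), USE.NAMES = FALSE)
  writeLines(c(header, body), vcf_out)
  vcf_out
}

#' Evaluate scored variants against truth labels
#'
#' Joins a scored table to truth labels and delegates to
#' [sweep_thresholds()].
#'
#' @param scored Tibble from [score_variants()] (or a scored TSV path).
#' @param truth Truth tibble (`chrom`, `pos`, `ref`, `alt`, `label`) or a
#'   TSV path.
#' @param beta,step Passed to [sweep_thresholds()].
#' @return A `vartag_sweep`.
#' @export
evaluate_scored <- function(scored, truth, beta = 0.3, step = 0.1) {
  if (is.character(scored)) {
    scored <- tibble::as_tibble(utils::read.delim(scored,
                                                  stringsAsFactors = FALSE))
  }
  if (is.character(truth)) {
    truth <- tibble::as_tibble(utils::read.delim(truth,
                                                 stringsAsFactors = FALSE))
  }
  joined <- dplyr::inner_join(
    scored, dplyr::select(truth, "chrom", "pos", "ref", "alt", "label"),
    by = c("chrom", "pos", "ref", "alt"))
  if (nrow(joined) == 0L) stop("no scored variant matched a truth label")
  sweep_thresholds(joined, joined$label, beta = beta, step = step)
}
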