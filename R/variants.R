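#' Construct a candidate variant call
#'
#' Builds the one-row tibble used throughout the package to represent a
#' candidate variant. Alleles are reduced to their minimal representation
#' (shared suffix then prefix trimmed) and, when the reference sequence is
#' supplied, indels are left-aligned, so that identical variants written
#' differently compare equal.
#'
#' @param chrom Chromosome / contig name.
#' @param pos 1-based reference position of the first allele base.
#' @param ref,alt Reference and alternate alleles over A/C/G/T.
#' @param ref_seq Optional contig sequence (character) used to left-align
#'   indels; assumed to start at reference position `ref_offset`.
#' @param ref_offset 1-based reference position of `substr(ref_seq, 1, 1)`.
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `vclass`
#'   (one of `"SNV"`, `"INS"`, `"DEL"`).
#' @export
#' @examples
#' variant_call("chr1", 100, "A", "G")
#' variant_call("chr1", 100, "AT", "A") # a 1-bp deletion
variant_call <- function(chrom, pos, ref, alt, ref_seq = NULL, ref_offset = 1L) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!nzchar(ref) || !nzchar(alt) ||
      grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt)) {
    stop("ref/alt must be non-empty strings over A/C/G/T (got ",
         ref, ">", alt, ")")
  }
  if (ref == alt) stop("ref and alt alleles are identical at ", chrom, ":", pos)
  norm <- normalize_alleles(as.integer(pos), ref, alt, ref_seq, ref_offset)
  vclass <- if (nchar(norm$ref) == nchar(norm$alt)) "SNV"
            else if (nchar(norm$alt) > nchar(norm$ref)) "INS" else "DEL"
  if (vclass == "SNV" && nchar(norm$ref) != 1L) {
    stop("multi-nucleotide substitutions are not supported (", ref, ">", alt, ")")
  }
  tibble::tibble(chrom = as.character(chrom), pos = norm$pos,
                 ref = norm$ref, alt = norm$alt, vclass = vclass)
}

# minimal representation + left alignment (when ref_seq given)
normalize_alleles <- function(pos, ref, alt, ref_seq = NULL, ref_offset = 1L) {
  last <- function(x) substr(x, nchar(x), nchar(x))
  # trim shared suffix
  while (nchar(ref) > 1L && nchar(alt) > 1L && last(ref) == last(alt)) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # left-shift indels while the trailing bases still agree
  if (!is.null(ref_seq)) {
    while (nchar(ref) != nchar(alt) && last(ref) == last(alt) && pos > ref_offset) {
      prev <- substr(ref_seq, pos - 1L - ref_offset + 1L, pos - 1L - ref_offset + 1L)
      if (!nzchar(prev)) break
      ref <- paste0(prev, substr(ref, 1L, nchar(ref) - 1L))
      alt <- paste0(prev, substr(alt, 1L, nchar(alt) - 1L))
      pos <- pos - 1L
      while (nchar(ref) > 1L && nchar(alt) > 1L && last(ref) == last(alt)) {
        ref <- substr(ref, 1L, nchar(ref) - 1L)
        alt <- substr(alt, 1L, nchar(alt) - 1L)
      }
    }
  }
  # trim shared prefix (keep the anchor base of indels)
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

# the allele string a supporting read presents (see read_allele_at)
candidate_allele_string <- function(variant) {
  switch(variant$vclass,
    SNV = variant$alt,
    INS = paste0("ins:", substr(variant$alt, nchar(variant$ref) + 1L,
                                nchar(variant$alt))),
    DEL = paste0("del:", nchar(variant$ref) - nchar(variant$alt)))
}

#' Load candidate variants from a VCF file
#'
#' Reads a VCF, splits multi-allelic records into one candidate per
#' alternate allele, normalizes alleles (left-aligned, minimal
#' representation when `ref_seq` is given) and classifies each candidate as
#' SNV, insertion or deletion from the allele lengths.
#'
#' @param vcf_path Path to a VCF (v4.x) file.
#' @param ref_seq Optional named character vector of contig sequences used
#'   for left-alignment and contig validation.
#' @param region Optional list with `chrom`, `start`, `end` restricting the
#'   candidates returned.
#' @return Tibble of candidates ordered by `(chrom, pos)` with columns
#'   `chrom`, `pos`, `ref`, `alt`, `vclass`.
#' @export
load_variants <- function(vcf_path, ref_seq = NULL, region = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix_mat <- vcfR::getFIX(v)
  if (is.null(dim(fix_mat))) fix_mat <- t(fix_mat) # single-record VCF
  fix <- tibble::as_tibble(as.data.frame(fix_mat, stringsAsFactors = FALSE))
  if (nrow(fix) == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          vclass = character()))
  }
  if (!is.null(ref_seq)) {
    missing_contigs <- setdiff(unique(fix$CHROM), names(ref_seq))
    if (length(missing_contigs)) {
      stop("contig(s) in VCF absent from the reference: ",
           paste(missing_contigs, collapse = ", "))
    }
  }
  rows <- purrr::pmap(
    list(fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT),
    function(chrom, pos, ref, alts) {
      alts <- strsplit(alts, ",", fixed = TRUE)[[1]]
      alts <- alts[alts != "*" & !grepl("^<", alts)]
      purrr::map(alts, function(a) {
        variant_call(chrom, pos, ref, a,
                     ref_seq = if (is.null(ref_seq)) NULL else ref_seq[[chrom]])
      })
    })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (!is.null(region)) {
    out <- dplyr::filter(out, .data$chrom == region$chrom,
                         .data$pos >= region$start, .data$pos <= region$end)
  }
  dplyr::arrange(out, .data$chrom, .data$pos, .data$ref, .data$alt)
}
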