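#' Detect potential germline alleles in the normal track
#'
#' Every non-reference base allele at the locus with at least two
#' supporting normal reads is scored with the full germline metric vector
#' and v-score on the normal pileup; alleles scoring at or below
#' `cfg$vscore_cutoff` are declared germline and are later excluded from
#' the tumor-track other-allele count.
#'
#' @param normal_ctx A [pileup_context()] built on the normal track for the
#'   candidate variant's locus.
#' @param weights Metric weights ([vartag_weights()]).
#' @return A `normal_track_summary` list: `d_normal` (covering normal
#'   reads), `d_n` (normal reads supporting the candidate allele),
#'   `germline_alleles` (tibble of allele, support, vscore).
#' @export
detect_germline_in_normal <- function(normal_ctx, weights = vartag_weights()) {
  ev <- normal_ctx$evidence
  cfg <- normal_ctx$cfg
  variant <- normal_ctx$variant
  cov <- dplyr::filter(ev, .data$covers)
  refb <- substr(normal_ctx$ref_window,
                 variant$pos - normal_ctx$window_start + 1L,
                 variant$pos - normal_ctx$window_start + 1L)
  d_normal <- nrow(cov)
  d_n <- sum(ev$supports)
  if (d_normal == 0L) {
    return(structure(list(d_normal = 0L, d_n = 0L,
                          germline_alleles = empty_germline_tbl()),
                     class = "normal_track_summary"))
  }
  # candidate base alleles: observed at the locus, not reference
  tally <- cov |>
    dplyr::filter(!is.na(.data$allele), .data$allele %in% c("A", "C", "G", "T"),
                  .data$allele != refb) |>
    dplyr::count(.data$allele, name = "support") |>
    dplyr::filter(.data$support >= 2L)
  if (nrow(tally) == 0L) {
    return(structure(list(d_normal = d_normal, d_n = d_n,
                          germline_alleles = empty_germline_tbl()),
                     class = "normal_track_summary"))
  }
  # score each allele as a germline candidate on the normal pileup;
  # the normal track uses thr_n as its coverage requirement
  ncfg <- cfg
  ncfg$thr <- cfg$thr_n
  scores <- purrr::map_dbl(tally$allele, function(a) {
    av <- variant_call(variant$chrom, variant$pos, refb, a)
    actx <- normal_ctx
    actx$cfg <- ncfg
    actx$variant <- av
    actx$evidence <- build_read_evidence_for_allele(normal_ctx, av)
    actx$mismatch_catalog <- catalog_mismatches(actx$evidence)
    mv <- compute_metric_vector(actx)
    vscore(mv, weights)
  })
  tally$vscore <- scores
  germ <- dplyr::filter(tally, .data$vscore <= cfg$vscore_cutoff)
  structure(list(d_normal = d_normal, d_n = d_n,
                 germline_alleles = germ),
            class = "normal_track_summary")
}

empty_germline_tbl <- function() {
  tibble::tibble(allele = character(), support = integer(), vscore = numeric())
}

# re-derive support flags for a different candidate allele at the same
# locus without re-walking CIGARs: support = allele match
build_read_evidence_for_allele <- function(ctx, alt_variant) {
  cand <- candidate_allele_string(alt_variant)
  dplyr::mutate(ctx$evidence,
                supports = .data$covers & !is.na(.data$allele) &
                  .data$allele == cand,
                in_mate_overlap = .data$covers & .data$mate_covers)
}

#' @export
print.normal_track_summary <- function(x, ...) {
  cat(sprintf("<normal_track_summary> d_normal=%d d_n=%d germline alleles: %s\n",
              x$d_normal, x$d_n,
              if (nrow(x$germline_alleles)) {
                paste(x$germline_alleles$allele, collapse = ",")
              } else "none"))
  invisible(x)
}

#' Somatic-only metrics from the normal track
#'
#' `nvaf = d_n / d_normal` (0 when the normal track has no coverage; the
#' no-coverage condition is carried by `lncr` and the NCN tag instead) and
#' `lncr = 1 - min(thr_n, d_normal) / thr_n`.
#'
#' @param summary A `normal_track_summary` from
#'   [detect_germline_in_normal()].
#' @param cfg A [vartag_config()].
#' @return Named list with `nvaf` and `lncr`, both in `[0, 1]`.
#' @export
somatic_metrics <- function(summary, cfg = vartag_config()) {
  nvaf <- if (summary$d_normal == 0L) 0 else summary$d_n / summary$d_normal
  lncr <- 1 - min(cfg$thr_n, summary$d_normal) / cfg$thr_n
  list(nvaf = nvaf, lncr = lncr)
}

#' Score a somatic candidate from paired tumor and normal pileups
#'
#' Runs germline-allele detection on the normal track, computes the tumor
#' metric vector with detected germline alleles excluded from the
#' other-allele count, and appends the two normal-track metrics.
#'
#' @param tumor_ctx,normal_ctx [pileup_context()]s for the same variant on
#'   the tumor and normal tracks.
#' @param weights Metric weights ([vartag_weights()]).
#' @return One-row tibble: the 18-field somatic metric vector, the tumor
#'   counts, plus `d_normal` and `d_n`.
#' @export
score_somatic_variant <- function(tumor_ctx, normal_ctx,
                                  weights = vartag_weights()) {
  summary <- detect_germline_in_normal(normal_ctx, weights)
  mv <- compute_metric_vector(tumor_ctx,
                              germline_alleles = summary$germline_alleles$allele)
  sm <- somatic_metrics(summary, tumor_ctx$cfg)
  dplyr::bind_cols(mv,
                   tibble::tibble(nvaf = sm$nvaf, lncr = sm$lncr,
                                  d_normal = summary$d_normal,
                                  d_n = summary$d_n))
}
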