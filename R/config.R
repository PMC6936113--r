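#' Threshold configuration for metric computation and tagging
#'
#' Bundles every tunable cutoff used by the metric and tagging layers.
#' Defaults follow common review practice: a supporting read placed within
#' 5 bp of a read end is "near" the end, mapping quality below 10 is "low",
#' a secondary mismatch seen in under 5% of covering reads is "rare", and a
#' linked mismatch with concordance ratio at or above 0.9 is "recurrent".
#'
#' @param thr Minimal acceptable read coverage at a locus (reads). Sites with
#'   fewer covering reads accrue low-coverage risk `lcr`.
#' @param thr_n Minimal acceptable normal-track coverage (somatic mode).
#' @param thr_vaf Minimal acceptable variant allele frequency, in (0,1].
#'   Drives the LVF tag: `vafr >= 1 - thr_vaf`.
#' @param near_dist Distance (bp) within which a supporting read's head/end,
#'   or an adjacent indel, counts as "near" the locus (inclusive).
#' @param mapq_thr Mapping quality below which (strict `<`) a supporter
#'   counts as low-quality.
#' @param mm_freq_thr Frequency (relative to total coverage `d`) below which
#'   a windowed mismatch enters the multiple-mismatch sum.
#' @param hr_thr Concordance-ratio threshold for the high-discrepancy
#'   branch: when the maximal HR reaches it, `hdr` is the sum of all HR at
#'   or above it.
#' @param li_len Minimal insertion length (bp) for the large duplicative
#'   insertion flag `li`.
#' @param window Half-width (bp) of the reference window used for mismatch
#'   cataloging and repeat scanning.
#' @param unit_len_max Maximal tandem-repeat unit length considered.
#' @param min_copies Minimal copies for a repeat tract with unit length
#'   at least 2.
#' @param min_copies_homopolymer Minimal copies for a homopolymer tract.
#' @param vscore_cutoff Normal-track v-score at or below which a candidate
#'   normal allele is declared germline (somatic mode).
#' @param vn_rule Interpretation of the tumor-in-normal (VN) tag rule:
#'   `"scaled_vaf"` requires `nvaf >= 0.1 * thr_vaf` and at least two
#'   supporting normal reads; `"literal"` requires `nvaf >= 0.1 * thr` and
#'   normal coverage of at least two reads.
#' @param filter_reads Drop duplicate, secondary, supplementary and unmapped
#'   records before any counting (what a default review track shows).
#'
#' @return A list of class `vartag_config`.
#' @export
#' @examples
#' cfg <- vartag_config(thr = 15, thr_vaf = 0.15, thr_n = 5)
#' cfg$near_dist
vartag_config <- function(thr = 15L,
                          thr_n = 5L,
                          thr_vaf = 0.15,
                          near_dist = 5L,
                          mapq_thr = 10L,
                          mm_freq_thr = 0.05,
                          hr_thr = 0.9,
                          li_len = 20L,
                          window = 10L,
                          unit_len_max = 5L,
                          min_copies = 4L,
                          min_copies_homopolymer = 5L,
                          vscore_cutoff = 3.5,
                          vn_rule = c("scaled_vaf", "literal"),
                          filter_reads = TRUE) {
  vn_rule <- match.arg(vn_rule)
  stopifnot(thr >= 1, thr_n >= 1, thr_vaf > 0, thr_vaf <= 1,
            near_dist >= 0, mapq_thr >= 0,
            mm_freq_thr > 0, mm_freq_thr <= 1,
            hr_thr > 0, hr_thr <= 1, li_len >= 1, window >= 1,
            unit_len_max >= 1, min_copies >= 2, min_copies_homopolymer >= 2)
  structure(
    list(thr = as.integer(thr), thr_n = as.integer(thr_n),
         thr_vaf = thr_vaf, near_dist = as.integer(near_dist),
         mapq_thr = as.integer(mapq_thr), mm_freq_thr = mm_freq_thr,
         hr_thr = hr_thr, li_len = as.integer(li_len),
         window = as.integer(window),
         unit_len_max = as.integer(unit_len_max),
         min_copies = as.integer(min_copies),
         min_copies_homopolymer = as.integer(min_copies_homopolymer),
         vscore_cutoff = vscore_cutoff, vn_rule = vn_rule,
         filter_reads = isTRUE(filter_reads)),
    class = "vartag_config")
}

# canonical metric order; somatic vectors append nvaf, lncr
.metrics_germline <- c("lcr", "vafr", "nh", "ne", "ni", "nd", "sse", "dir",
                       "lm", "mm", "mv", "hdr", "si", "r", "ri", "li")
.metrics_somatic <- c(.metrics_germline, "nvaf", "lncr")

#' Metric weights for the v-score
#'
#' The v-score is the weighted sum `v = sum(w_i * x_i)` over the metric
#' vector. Metrics are grouped in three importance levels: coverage,
#' allele-frequency, mapping-quality and adjacent-indel risks carry weight 3;
#' normal-coverage risk, multiple-variant rate and the high-discrepancy
#' score carry weight 2; all remaining metrics carry weight 1. Any weight
#' can be overridden.
#'
#' @param ... Named overrides, e.g. `vartag_weights(hdr = 3)`.
#' @return Named numeric vector over all 18 metrics.
#' @export
#' @examples
#' w <- vartag_weights()
#' w[["lcr"]]
vartag_weights <- function(...) {
  w <- stats::setNames(rep(1, length(.metrics_somatic)), .metrics_somatic)
  w[c("lcr", "vafr", "lm", "ni", "nd")] <- 3
  w[c("lncr", "mv", "hdr")] <- 2
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(w))
    if (length(bad)) {
      stop("unknown metric(s) in weight override: ", paste(bad, collapse = ", "))
    }
    ov <- unlist(over)
    if (any(ov < 0)) stop("weights must be nonnegative")
    w[names(over)] <- ov
  }
  w
}

#' @export
print.vartag_config <- function(x, ...) {
  cat("<vartag_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
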