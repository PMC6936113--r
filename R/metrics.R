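#' Summarise a pileup context into the underlying counts
#'
#' Computes the count layer every rate metric is built from: total and
#' supporting coverage, near-head/end supporters, adjacent-indel events,
#' duplicate and strand groupings, low-MAPQ supporters, other-allele reads
#' and mate-overlap support.
#'
#' @param ctx A [pileup_context()].
#' @param germline_alleles Optional character vector of allele strings
#'   (same encoding as the evidence `allele` column) excluded from the
#'   other-allele count `d_mv` (somatic mode).
#' @return One-row tibble of counts: `d`, `d_m`, `d_h`, `d_e`, `d_insert`,
#'   `d_del`, `d_s_max`, `d_d_max`, `d_l`, `d_mv`, `d_mv_alleles`, `d_si`,
#'   `d_p`.
#' @export
pileup_counts <- function(ctx, germline_alleles = NULL) {
  ev <- ctx$evidence
  cfg <- ctx$cfg
  sup <- dplyr::filter(ev, .data$supports)
  cov <- dplyr::filter(ev, .data$covers)
  refb <- substr(ctx$ref_window, ctx$variant$pos - ctx$window_start + 1L,
                 ctx$variant$pos - ctx$window_start + 1L)
  cand <- candidate_allele_string(ctx$variant)
  other <- dplyr::filter(
    cov, !.data$supports, !is.na(.data$allele),
    .data$allele != "*", .data$allele != refb, .data$allele != cand,
    !(.data$allele %in% (germline_alleles %||% character(0))))
  d_s_max <- if (nrow(sup)) {
    max(dplyr::count(sup, .data$aln_start, .data$aln_end)$n)
  } else 0L
  d_d_max <- if (nrow(sup)) {
    max(sum(sup$strand == "forward"), sum(sup$strand == "reverse"))
  } else 0L
  tibble::tibble(
    d = nrow(cov),
    d_m = nrow(sup),
    d_h = sum(sup$dist_head <= cfg$near_dist),
    d_e = sum(sup$dist_end <= cfg$near_dist),
    d_insert = sum(sup$has_adjacent_insertion),
    d_del = sum(sup$has_adjacent_deletion),
    d_s_max = d_s_max,
    d_d_max = d_d_max,
    d_l = sum(sup$mapq < cfg$mapq_thr),
    d_mv = nrow(other),
    d_mv_alleles = dplyr::n_distinct(other$allele),
    d_si = sum(sup$in_mate_overlap),
    d_p = sum(sup$paired & sup$mate_mapped))
}

#' Coverage and allele-frequency risk
#'
#' `lcr = 1 - min(thr, d) / thr` is 0 when coverage meets the requirement
#' and rises to 1 as coverage vanishes. `vafr = 1 - d_m / d` is the
#' complement of the variant allele frequency.
#'
#' @param counts One-row counts tibble from [pileup_counts()].
#' @param cfg A [vartag_config()].
#' @return Named list with `lcr` and `vafr`, both in `[0, 1]`.
#' @export
coverage_metrics <- function(counts, cfg = vartag_config()) {
  lcr <- 1 - min(cfg$thr, counts$d) / cfg$thr
  if (counts$d == 0L) {
    warning("no covering reads: vafr set to 1")
    return(list(lcr = 1, vafr = 1))
  }
  list(lcr = lcr, vafr = 1 - counts$d_m / counts$d)
}

#' Positional clustering of supporting reads
#'
#' `nh = d_h / d_m` and `ne = d_e / d_m`: the fraction of supporting reads
#' whose aligned head (resp. end) lies within `near_dist` bp of the locus.
#' @inheritParams coverage_metrics
#' @return Named list with `nh`, `ne`.
#' @export
positional_rates <- function(counts) {
  if (counts$d_m == 0L) {
    warning("no supporting reads: nh and ne set to 0")
    return(list(nh = 0, ne = 0))
  }
  list(nh = counts$d_h / counts$d_m, ne = counts$d_e / counts$d_m)
}

#' Adjacent insertion / deletion rates
#'
#' `ni = d_insert / d_m`, `nd = d_del / d_m`: one event per supporting read
#' carrying an insertion (resp. deletion) within `near_dist` bp of the
#' locus, so both rates stay within `[0, 1]`.
#' @inheritParams coverage_metrics
#' @return Named list with `ni`, `nd`.
#' @export
adjacent_indel_rates <- function(counts) {
  if (counts$d_m == 0L) {
    warning("no supporting reads: ni and nd set to 0")
    return(list(ni = 0, nd = 0))
  }
  list(ni = counts$d_insert / counts$d_m, nd = counts$d_del / counts$d_m)
}

#' Duplicate-signature and strand-bias rates
#'
#' `sse = max(d_s) / d_m` where groups share an identical (start, end) pair;
#' `dir = max(d_d) / d_m` over the two strand directions, hence at least
#' 0.5 whenever supporters exist.
#' @inheritParams coverage_metrics
#' @return Named list with `sse`, `dir`.
#' @export
duplication_strand_rates <- function(counts) {
  if (counts$d_m == 0L) {
    warning("no supporting reads: sse and dir set to 0")
    return(list(sse = 0, dir = 0))
  }
  list(sse = counts$d_s_max / counts$d_m, dir = counts$d_d_max / counts$d_m)
}

#' Low mapping-quality rate
#'
#' `lm = d_l / d_m` where `d_l` counts supporters with MAPQ strictly below
#' `mapq_thr`.
#' @inheritParams coverage_metrics
#' @return `lm` in `[0, 1]`.
#' @export
mapping_quality_rate <- function(counts) {
  if (counts$d_m == 0L) {
    warning("no supporting reads: lm set to 0")
    return(0)
  }
  counts$d_l / counts$d_m
}

#' Multiple-mismatch score
#'
#' `mm = 100 * sum(v_i, i in T) / n` where `T` is the set of windowed
#' mismatches with frequency `v_i / d` strictly below `mm_freq_thr`, `v_i`
#' the mismatch depth and `n` the number of reference positions within the
#' window (locus excluded, 20 for a full window).
#'
#' @param ctx A [pileup_context()].
#' @return `mm >= 0` (can exceed 1).
#' @export
multiple_mismatch_score <- function(ctx) {
  counts <- pileup_counts(ctx)
  cat <- ctx$mismatch_catalog
  if (nrow(cat) == 0L || counts$d == 0L) return(0)
  in_T <- cat$depth / counts$d < ctx$cfg$mm_freq_thr
  sum(cat$depth[in_T]) * 100 / ctx$window_n
}

#' Multiple-variant rate
#'
#' `mv = d_mv / d_m` where `d_mv` counts covering reads presenting an
#' allele at the locus that is neither the reference base, the candidate
#' allele, nor (somatic mode) a detected germline allele.
#'
#' @inheritParams multiple_mismatch_score
#' @param germline_alleles Optional allele strings excluded from `d_mv`.
#' @return Named list with `mv` (may exceed 1) and the count `d_mv`.
#' @export
multiple_variant_rate <- function(ctx, germline_alleles = NULL) {
  counts <- pileup_counts(ctx, germline_alleles)
  if (counts$d_m == 0L) return(list(mv = 0, d_mv = counts$d_mv))
  list(mv = counts$d_mv / counts$d_m, d_mv = counts$d_mv)
}

#' High-discrepancy score from linked mismatches
#'
#' For every cataloged mismatch co-occurring with the candidate on at least
#' one supporting read, the concordance ratio is `HR = 2h / (d_m + d_i)`
#' with `h` the co-occurrence count and `d_i` the mismatch depth. When the
#' maximal HR reaches `hr_thr`, `hdr` is the sum of all HR at or above the
#' threshold (so two fully linked mismatches give 2.0); otherwise `hdr` is
#' the maximal HR.
#'
#' @inheritParams multiple_mismatch_score
#' @return Named list with `hdr` (may exceed 1) and `hr_max`.
#' @export
high_discrepancy_score <- function(ctx) {
  counts <- pileup_counts(ctx)
  cat <- dplyr::filter(ctx$mismatch_catalog, .data$cooccurrence > 0L)
  if (nrow(cat) == 0L || counts$d_m == 0L) return(list(hdr = 0, hr_max = 0))
  hr <- 2 * cat$cooccurrence / (counts$d_m + cat$depth)
  hr_max <- max(hr)
  hdr <- if (hr_max >= ctx$cfg$hr_thr) sum(hr[hr >= ctx$cfg$hr_thr]) else hr_max
  list(hdr = hdr, hr_max = hr_max)
}

#' Short-insert (mate-overlap) rate
#'
#' `si = d_si / d_p`: among paired supporting reads with a mapped mate
#' (`d_p`), the fraction whose support lies inside the mate overlap.
#' Fragments shorter than two read lengths — typical of archival material —
#' drive this toward 1.
#' @inheritParams coverage_metrics
#' @return `si` in `[0, 1]`; 0 when no supporting read is paired.
#' @export
short_insert_rate <- function(counts) {
  if (counts$d_p == 0L) return(0)
  counts$d_si / counts$d_p
}

#' Repeat-context flags
#'
#' Scans the reference window for tandem repeats (unit length 1 to
#' `unit_len_max`; homopolymers need `min_copies_homopolymer` copies, longer
#' units `min_copies`). `r = 1` when a qualifying tract contains or lies
#' within `near_dist` bp of the locus. `ri = 1` for an insertion in such a
#' context whose inserted sequence equals whole copies of the minimal
#' repeat unit (cyclic rotations allowed). `li = 1` for an insertion of at
#' least `li_len` bp identical to the adjacent reference sequence on either
#' side of the locus.
#'
#' @param variant One-row variant tibble.
#' @param ref_seq Contig or window sequence.
#' @param cfg A [vartag_config()].
#' @param ref_offset Reference position of the first `ref_seq` base.
#' @return Named list of 0/1 flags `r`, `ri`, `li`.
#' @export
repeat_flags <- function(variant, ref_seq, cfg = vartag_config(),
                         ref_offset = 1L) {
  vpos <- variant$pos
  lo <- max(ref_offset, vpos - cfg$window)
  hi <- min(ref_offset + nchar(ref_seq) - 1L, vpos + cfg$window)
  win <- substr(ref_seq, lo - ref_offset + 1L, hi - ref_offset + 1L)
  tracts <- scan_repeats(win, cfg)
  r <- 0L; ri <- 0L
  near_unit <- NULL
  if (nrow(tracts)) {
    tracts$start <- tracts$start + lo - 1L
    tracts$end <- tracts$end + lo - 1L
    dist <- ifelse(vpos >= tracts$start & vpos <= tracts$end, 0L,
                   pmin(abs(tracts$start - vpos), abs(tracts$end - vpos)))
    near <- which(dist <= cfg$near_dist)
    if (length(near)) {
      r <- 1L
      near_unit <- tracts$unit[near[which.min(dist[near])]]
    }
  }
  insert <- if (variant$vclass == "INS") {
    substr(variant$alt, nchar(variant$ref) + 1L, nchar(variant$alt))
  } else ""
  if (r == 1L && nzchar(insert)) {
    units <- unique(tracts$unit[dist <= cfg$near_dist])
    ri <- as.integer(any(vapply(units, insert_matches_unit, logical(1),
                                insert = insert)))
  }
  li <- 0L
  if (nzchar(insert) && nchar(insert) >= cfg$li_len) {
    k <- nchar(insert)
    right <- substr(ref_seq, vpos + 1L - ref_offset + 1L, vpos + k - ref_offset + 1L)
    left <- if (vpos - k >= ref_offset) {
      substr(ref_seq, vpos - k - ref_offset + 1L + 1L, vpos - ref_offset + 1L)
    } else ""
    li <- as.integer(identical(insert, right) || identical(insert, left))
  }
  list(r = r, ri = ri, li = li)
}

# inserted sequence equals whole copies of the unit, any cyclic rotation
insert_matches_unit <- function(unit, insert) {
  u <- nchar(unit)
  if (nchar(insert) %% u != 0L) return(FALSE)
  rotations <- vapply(seq_len(u), function(s) {
    paste0(substr(unit, s, u), substr(unit, 1L, s - 1L))
  }, character(1))
  any(vapply(rotations, function(rot) {
    identical(insert, strrep(rot, nchar(insert) / u))
  }, logical(1)))
}

# maximal tandem tracts in a window string; 1-based coords within `win`
scan_repeats <- function(win, cfg = vartag_config()) {
  n <- nchar(win)
  out <- list()
  for (u in seq_len(min(cfg$unit_len_max, n))) {
    min_cop <- if (u == 1L) cfg$min_copies_homopolymer else cfg$min_copies
    i <- 1L
    while (i + u - 1L <= n) {
      unit <- substr(win, i, i + u - 1L)
      if (grepl("[^ACGT]", unit)) { i <- i + 1L; next }
      j <- i + u
      while (j + u - 1L <= n && substr(win, j, j + u - 1L) == unit) j <- j + u
      copies <- (j - i) / u
      if (copies >= min_cop) {
        # skip tracts that are really homopolymers of a shorter unit
        if (u == 1L || nchar(unique_chars(unit)) > 1L) {
          out[[length(out) + 1L]] <-
            tibble::tibble(start = i, end = j - 1L, unit = unit,
                           copies = copies)
        }
        i <- j
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          unit = character(), copies = numeric()))
  }
  dplyr::bind_rows(out)
}

unique_chars <- function(x) paste(unique(strsplit(x, "")[[1]]), collapse = "")

#' Compute the full germline metric vector for one pileup
#'
#' Aggregates all read-level metrics into the 16-field germline metric
#' vector (plus the count layer needed downstream for tagging).
#'
#' @param ctx A [pileup_context()].
#' @param germline_alleles Optional allele strings excluded from `d_mv`
#'   (somatic mode).
#' @return One-row tibble: the 16 metrics in canonical order followed by
#'   the counts from [pileup_counts()].
#' @export
#' @examples
#' ref <- strrep("ACGT", 30)
#' v <- variant_call("chr_sim", 60, substr(ref, 60, 60), "T")
#' reads <- simulate_variant_pileup(ref, v, artifact_spec("none", depth = 30,
#'                                  vaf = 0.5, seed = 1))
#' ctx <- pileup_context(v, reads, ref)
#' compute_metric_vector(ctx)
compute_metric_vector <- function(ctx, germline_alleles = NULL) {
  counts <- pileup_counts(ctx, germline_alleles)
  cfg <- ctx$cfg
  suppress_empty <- function(expr) withCallingHandlers(expr,
    warning = function(w) invokeRestart("muffleWarning"))
  cv <- if (counts$d == 0L) {
    list(lcr = 1, vafr = 1)
  } else {
    coverage_metrics(counts, cfg)
  }
  pr <- suppress_empty(positional_rates(counts))
  ai <- suppress_empty(adjacent_indel_rates(counts))
  ds <- suppress_empty(duplication_strand_rates(counts))
  lm <- suppress_empty(mapping_quality_rate(counts))
  mvr <- multiple_variant_rate(ctx, germline_alleles)
  hd <- high_discrepancy_score(ctx)
  rf <- repeat_flags(ctx$variant, ctx$ref_seq, cfg,
                     ref_offset = ctx$ref_offset)
  dplyr::bind_cols(
    tibble::tibble(
      lcr = cv$lcr, vafr = cv$vafr, nh = pr$nh, ne = pr$ne,
      ni = ai$ni, nd = ai$nd, sse = ds$sse, dir = ds$dir, lm = lm,
      mm = multiple_mismatch_score(ctx), mv = mvr$mv, hdr = hd$hdr,
      si = short_insert_rate(counts),
      r = rf$r, ri = rf$ri, li = rf$li),
    counts)
}
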