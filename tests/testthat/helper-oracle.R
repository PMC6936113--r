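# Independent brute-force oracles. These deliberately avoid the package's
# counting code paths: plain loops and base R only.

# A randomized synthetic pileup context built directly at the evidence
# level (no CIGAR machinery involved), <= 30 reads.
random_evidence_context <- function(seed, cfg = vartag_config()) {
  set.seed(seed)
  n <- sample(0:30, 1)
  win <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
               collapse = "")
  substr(win, 11, 11) <- "A" # locus base
  variant <- tibble::tibble(chrom = "chr_r", pos = 1000L, ref = "A",
                            alt = "G", vclass = "SNV")
  mm_keys <- c("995:C", "997:T", "1003:A", "1006:G", "1009:C")
  rows <- lapply(seq_len(n), function(i) {
    covers <- stats::runif(1) < 0.9
    supports <- covers && stats::runif(1) < 0.6
    allele <- if (!covers) NA_character_
      else if (supports) "G"
      else sample(c("A", "A", "A", "T", "C", "*"), 1)
    paired <- stats::runif(1) < 0.8
    mate_mapped <- paired && stats::runif(1) < 0.9
    mate_covers <- mate_mapped && stats::runif(1) < 0.5
    k <- sample(0:3, 1)
    tibble::tibble(
      read_id = sprintf("r%02d", i), flag = 0L,
      covers = covers, supports = supports, allele = allele,
      dist_head = if (covers) sample(0:60, 1) else NA_integer_,
      dist_end = if (covers) sample(0:60, 1) else NA_integer_,
      strand = sample(c("forward", "reverse"), 1),
      mapq = sample(c(0L, 2L, 9L, 10L, 30L, 60L), 1),
      aln_start = sample(seq(900L, 990L, by = 10L), 1),
      aln_end = 0L,
      has_adjacent_insertion = stats::runif(1) < 0.15,
      has_adjacent_deletion = stats::runif(1) < 0.15,
      paired = paired, mate_mapped = mate_mapped, mate_covers = mate_covers,
      in_mate_overlap = covers && mate_covers,
      mismatches = list(if (covers && k > 0) sample(mm_keys, k) else character(0)))
  })
  ev <- if (n > 0) dplyr::bind_rows(rows) else vartag:::build_read_evidence_empty()
  ev$aln_end <- ev$aln_start + sample(c(99L, 100L), max(n, 1),
                                      replace = TRUE)[seq_len(n)]
  structure(
    list(variant = variant, evidence = ev,
         mismatch_catalog = catalog_mismatches(ev),
         ref_window = win, window_start = 990L, window_n = 20L,
         ref_seq = win, ref_offset = 990L, cfg = cfg),
    class = "pileup_context")
}

# Brute-force recount of every rate metric from the evidence rows.
oracle_metrics <- function(ctx) {
  ev <- ctx$evidence
  cfg <- ctx$cfg
  d <- 0; d_m <- 0; d_h <- 0; d_e <- 0; d_ins <- 0; d_del <- 0; d_l <- 0
  d_mv <- 0; d_si <- 0; d_p <- 0
  fwd <- 0; rev <- 0
  coords <- character(0)
  refb <- substr(ctx$ref_window, 11, 11)
  for (i in seq_len(nrow(ev))) {
    if (!ev$covers[i]) next
    d <- d + 1
    a <- ev$allele[i]
    if (ev$supports[i]) {
      d_m <- d_m + 1
      if (ev$dist_head[i] <= cfg$near_dist) d_h <- d_h + 1
      if (ev$dist_end[i] <= cfg$near_dist) d_e <- d_e + 1
      if (ev$has_adjacent_insertion[i]) d_ins <- d_ins + 1
      if (ev$has_adjacent_deletion[i]) d_del <- d_del + 1
      if (ev$mapq[i] < cfg$mapq_thr) d_l <- d_l + 1
      if (ev$strand[i] == "forward") fwd <- fwd + 1 else rev <- rev + 1
      coords <- c(coords, paste(ev$aln_start[i], ev$aln_end[i]))
      if (ev$paired[i] && ev$mate_mapped[i]) d_p <- d_p + 1
      if (ev$in_mate_overlap[i]) d_si <- d_si + 1
    } else if (!is.na(a) && a != "*" && a != refb) {
      d_mv <- d_mv + 1
    }
  }
  # windowed mismatch tallies
  all_mm <- character(0); sup_mm <- character(0)
  for (i in seq_len(nrow(ev))) {
    all_mm <- c(all_mm, ev$mismatches[[i]])
    if (ev$supports[i]) sup_mm <- c(sup_mm, ev$mismatches[[i]])
  }
  tab <- table(all_mm)
  mm <- 0
  if (d > 0) {
    for (k in names(tab)) {
      if (tab[[k]] / d < cfg$mm_freq_thr) mm <- mm + tab[[k]]
    }
  }
  mm <- mm * 100 / ctx$window_n
  hrs <- numeric(0)
  for (k in names(tab)) {
    h <- sum(sup_mm == k)
    if (h > 0) hrs <- c(hrs, 2 * h / (d_m + tab[[k]]))
  }
  hdr <- if (!length(hrs)) 0
    else if (max(hrs) >= cfg$hr_thr) sum(hrs[hrs >= cfg$hr_thr])
    else max(hrs)
  list(
    d = d, d_m = d_m,
    lcr = 1 - min(cfg$thr, d) / cfg$thr,
    vafr = if (d == 0) 1 else 1 - d_m / d,
    nh = if (d_m == 0) 0 else d_h / d_m,
    ne = if (d_m == 0) 0 else d_e / d_m,
    ni = if (d_m == 0) 0 else d_ins / d_m,
    nd = if (d_m == 0) 0 else d_del / d_m,
    sse = if (d_m == 0) 0 else max(table(coords)) / d_m,
    dir = if (d_m == 0) 0 else max(fwd, rev) / d_m,
    lm = if (d_m == 0) 0 else d_l / d_m,
    mm = mm,
    mv = if (d_m == 0) 0 else d_mv / d_m,
    hdr = hdr,
    si = if (d_p == 0) 0 else d_si / d_p)
}

# exhaustive threshold sweep used to check sweep_thresholds
oracle_sweep <- function(vscores, truth, beta, thresholds) {
  out <- data.frame()
  for (t in thresholds) {
    pred <- vscores < t
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    fb <- if (p == 0 && r == 0) 0 else (1 + beta^2) * p * r / (beta^2 * p + r)
    out <- rbind(out, data.frame(threshold = t, tp = tp, fp = fp, tn = tn,
                                 fn = fn, precision = p, recall = r,
                                 f_beta = fb))
  }
  out
}

# AUC by exhaustive pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# linear scan over a SAM text file: primary non-duplicate reads whose
# aligned span covers `pos` (reference width derived from the CIGAR)
oracle_fetch_linear <- function(sam_path, pos) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  hits <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0 || bitwAnd(flag, 256L) > 0 ||
        bitwAnd(flag, 1024L) > 0 || bitwAnd(flag, 2048L) > 0) next
    start <- as.integer(f[4])
    cig <- f[6]
    ops <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1]]
    width <- 0
    for (o in ops) {
      op <- substr(o, nchar(o), nchar(o))
      if (op %in% c("M", "D", "N", "=", "X")) {
        width <- width + as.integer(substr(o, 1, nchar(o) - 1))
      }
    }
    if (pos >= start && pos <= start + width - 1) hits <- c(hits, f[1])
  }
  sort(hits)
}
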