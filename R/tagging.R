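.tags_germline <- c("LC", "LVF", "LM", "MM", "HDR", "HE", "EN", "NI", "ND",
                    "D", "SSE", "MV", "RR", "RI", "AO", "SI")
.tags_somatic <- c(.tags_germline, "NCN", "LCN", "VN")

#' Assign manual-review tags from a metric vector
#'
#' Applies the review tag standard to a scored metric vector: each tag
#' flags one artifact mode (LC low coverage, LVF low allele frequency, LM
#' low mapping quality, MM many windowed mismatches, HDR linked recurrent
#' mismatches, HE/EN positional clustering at read heads/ends, NI/ND
#' adjacent indels, D strand bias, SSE shared start/end, MV other alleles,
#' RR repeat context, RI repeat-unit insertion, AO duplicative large
#' insertion, SI mate-overlap-only support; somatic-only NCN/LCN normal
#' coverage and VN tumor-in-normal). RI implies RR.
#'
#' @param metrics One-row tibble from [compute_metric_vector()] or
#'   [score_somatic_variant()] (must carry the count columns).
#' @param cfg A [vartag_config()].
#' @param mode `"germline"` or `"somatic"`; somatic-only tags are
#'   suppressed in germline mode.
#' @return Character vector of tags (possibly empty).
#' @export
assign_tags <- function(metrics, cfg = vartag_config(),
                        mode = c("germline", "somatic")) {
  mode <- match.arg(mode)
  m <- metrics
  tags <- character(0)
  add <- function(tags, tag, cond) if (isTRUE(cond)) c(tags, tag) else tags
  tags <- add(tags, "LC", m$lcr > 0)
  tags <- add(tags, "LVF", m$vafr >= 1 - cfg$thr_vaf)
  tags <- add(tags, "LM", m$lm >= 0.2 && m$d_l >= 2)
  tags <- add(tags, "MM", m$mm >= 1)
  tags <- add(tags, "HDR", m$hdr >= 1)
  tags <- add(tags, "HE", m$nh >= 0.9)
  tags <- add(tags, "EN", m$ne >= 0.9)
  tags <- add(tags, "NI", m$ni >= 0.9)
  tags <- add(tags, "ND", m$nd >= 0.9)
  tags <- add(tags, "D", m$dir >= 0.9)
  tags <- add(tags, "SSE", m$sse >= 0.9)
  tags <- add(tags, "MV", m$mv >= 0.2 && m$d_mv >= 2)
  tags <- add(tags, "RR", m$r == 1 || m$ri == 1) # RR is the prerequisite of RI
  tags <- add(tags, "RI", m$ri == 1)
  tags <- add(tags, "AO", m$li == 1)
  tags <- add(tags, "SI", m$si >= 0.9)
  if (mode == "somatic") {
    tags <- add(tags, "NCN", m$lncr == 1)
    tags <- add(tags, "LCN", m$lncr > 0 && m$lncr < 1)
    vn <- if (cfg$vn_rule == "scaled_vaf") {
      m$nvaf >= 0.1 * cfg$thr_vaf && m$d_n >= 2
    } else {
      m$nvaf >= 0.1 * cfg$thr && m$d_normal >= 2
    }
    tags <- add(tags, "VN", vn)
  }
  tags
}

#' Weighted variant score
#'
#' `v = sum(w_i * x_i)` over the metric vector; low scores indicate likely
#' true variants. Only the metrics present in `metrics` contribute, so the
#' same weights serve germline (16 metrics) and somatic (18) vectors.
#'
#' @param metrics One-row tibble carrying metric columns.
#' @param weights Named weights from [vartag_weights()].
#' @return Nonnegative numeric score.
#' @export
#' @examples
#' m <- tibble::tibble(lcr = 1, vafr = 0.9, hdr = 1)
#' vscore(m) # 3*1 + 3*0.9 + 2*1 = 7.7
vscore <- function(metrics, weights = vartag_weights()) {
  active <- intersect(names(weights), names(metrics))
  x <- unlist(metrics[1, active])
  sum(weights[active] * x)
}

#' F-beta score
#'
#' `F_beta = (1 + beta^2) * P * R / (beta^2 * P + R)`. Values of `beta`
#' below 1 weight precision more heavily, above 1 recall.
#'
#' @param precision,recall Fractions in `[0, 1]`.
#' @param beta Positive weight; default 0.3 (precision-leaning).
#' @return Value in `[0, 1]`; defined as 0 when both inputs are 0.
#' @export
#' @examples
#' f_beta(0.904, 0.825, beta = 0.3) # ~0.897
f_beta <- function(precision, recall, beta = 0.3) {
  stopifnot(beta > 0)
  ifelse(precision == 0 & recall == 0, 0,
         (1 + beta^2) * precision * recall / (beta^2 * precision + recall))
}

#' Matthews correlation coefficient
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @return MCC in `[-1, 1]`; 0 when any marginal total is 0.
#' @export
mcc <- function(tp, fp, tn, fn) {
  denom <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  if (denom == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
}

#' Sweep v-score thresholds against truth labels
#'
#' Evaluates every threshold from 0 to the maximal v-score (inclusive) in
#' steps of `step`. A variant is predicted positive (retained as true) when
#' its v-score is strictly below the threshold. The best threshold
#' maximises the F-beta score, with ties broken toward the smallest
#' threshold.
#'
#' @param scored Tibble with a `vscore` column (one row per variant).
#' @param truth Logical or 0/1 vector: `TRUE`/1 marks a true variant.
#' @param beta F-beta weight (default 0.3).
#' @param step Threshold step (default 0.1).
#' @return A `vartag_sweep` object: tibble of per-threshold rows
#'   (`threshold`, `tp`, `fp`, `tn`, `fn`, `precision`, `recall`, `f_beta`,
#'   `accuracy`, `mcc`) with the best threshold in attribute `best` (also
#'   via [glance.vartag_sweep()]).
#' @export
sweep_thresholds <- function(scored, truth, beta = 0.3, step = 0.1) {
  stopifnot(step > 0, nrow(scored) == length(truth))
  truth <- as.logical(truth)
  if (anyNA(truth)) stop("truth labels must be complete (no NA)")
  if (all(truth) || !any(truth)) {
    warning("all truth labels are one class; precision or recall may be 0")
  }
  v <- scored$vscore
  thresholds <- seq(0, max(v, 0), by = step)
  if (max(v, 0) > thresholds[length(thresholds)]) {
    thresholds <- c(thresholds, thresholds[length(thresholds)] + step)
  }
  rows <- purrr::map(thresholds, function(t) {
    pred <- v < t
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    tibble::tibble(threshold = t, tp = tp, fp = fp, tn = tn, fn = fn,
                   precision = precision, recall = recall,
                   f_beta = f_beta(precision, recall, beta),
                   accuracy = (tp + tn) / length(truth),
                   mcc = mcc(tp, fp, tn, fn))
  })
  out <- dplyr::bind_rows(rows)
  best_i <- which.max(out$f_beta) # which.max returns the first (smallest t)
  structure(out, best = out$threshold[best_i], beta = beta, step = step,
            class = c("vartag_sweep", class(out)))
}

#' @rdname sweep_thresholds
#' @param x A `vartag_sweep` object.
#' @param ... Unused.
#' @export
glance.vartag_sweep <- function(x, ...) {
  best <- attr(x, "best")
  dplyr::filter(tibble::as_tibble(x), .data$threshold == best) |>
    dplyr::mutate(beta = attr(x, "beta"), .before = 1)
}

#' @export
print.vartag_sweep <- function(x, ...) {
  cat(sprintf("<vartag_sweep> %d thresholds (step %.3g, beta %.3g)\n",
              nrow(x), attr(x, "step"), attr(x, "beta")))
  g <- glance.vartag_sweep(x)
  cat(sprintf("  best threshold %.2f: P=%.3f R=%.3f F_beta=%.3f MCC=%.3f\n",
              g$threshold, g$precision, g$recall, g$f_beta, g$mcc))
  invisible(x)
}

#' Plot a threshold sweep
#'
#' @param object A `vartag_sweep`.
#' @param ... Unused.
#' @return A ggplot: F-beta, precision and recall versus threshold, with
#'   the selected threshold marked.
#' @export
autoplot.vartag_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("precision", "recall", "f_beta"),
                        names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value,
                                   colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "best"), linetype = 2) +
    ggplot2::labs(x = "v-score threshold", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
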