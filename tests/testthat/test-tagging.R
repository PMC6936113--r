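metric_row <- function(...) {
  base <- tibble::as_tibble(as.list(stats::setNames(
    rep(0, length(vartag:::.metrics_somatic)), vartag:::.metrics_somatic)))
  base$dir <- 0.5
  base <- dplyr::bind_cols(base, tibble::tibble(
    d = 50L, d_m = 25L, d_l = 0L, d_mv = 0L, d_normal = 40L, d_n = 0L))
  over <- list(...)
  base[names(over)] <- over
  base
}

test_that("tag rules apply the published standard", {
  cfg <- vartag_config(thr_vaf = 0.15)
  expect_true("LM" %in% assign_tags(metric_row(lm = 0.25, d_l = 3L), cfg))
  # conjunction fails on the count arm
  expect_false("LM" %in% assign_tags(metric_row(lm = 0.25, d_l = 1L), cfg))
  expect_true("LC" %in% assign_tags(metric_row(lcr = 0.01), cfg))
  expect_true("LVF" %in% assign_tags(metric_row(vafr = 0.85), cfg))
  expect_false("LVF" %in% assign_tags(metric_row(vafr = 0.84), cfg))
  expect_true("MV" %in% assign_tags(metric_row(mv = 0.2, d_mv = 2L), cfg))
  expect_false("MV" %in% assign_tags(metric_row(mv = 0.2, d_mv = 1L), cfg))
  expect_setequal(assign_tags(metric_row(), cfg), character(0))
  # RI implies RR
  expect_setequal(assign_tags(metric_row(ri = 1), cfg), c("RR", "RI"))
  for (pair in list(c("mm", "MM"), c("hdr", "HDR"), c("nh", "HE"),
                    c("ne", "EN"), c("ni", "NI"), c("nd", "ND"),
                    c("dir", "D"), c("sse", "SSE"), c("si", "SI"))) {
    m <- do.call(metric_row, stats::setNames(list(1), pair[1]))
    expect_true(pair[2] %in% assign_tags(m, cfg))
  }
})

test_that("somatic-only tags are gated by mode and follow lncr/nvaf", {
  cfg <- vartag_config()
  expect_true("NCN" %in% assign_tags(metric_row(lncr = 1), cfg, "somatic"))
  expect_false("LCN" %in% assign_tags(metric_row(lncr = 1), cfg, "somatic"))
  expect_true("LCN" %in% assign_tags(metric_row(lncr = 0.4), cfg, "somatic"))
  expect_false("NCN" %in% assign_tags(metric_row(lncr = 0.4), cfg, "somatic"))
  # VN: nvaf >= 0.1 * thr_vaf and at least 2 supporting normal reads
  expect_true("VN" %in% assign_tags(metric_row(nvaf = 0.3, d_n = 5L), cfg,
                                    "somatic"))
  expect_false("VN" %in% assign_tags(metric_row(nvaf = 0.3, d_n = 1L), cfg,
                                     "somatic"))
  expect_false("VN" %in% assign_tags(metric_row(nvaf = 0.01, d_n = 5L), cfg,
                                     "somatic"))
  # literal reading selectable
  cfg_lit <- vartag_config(vn_rule = "literal")
  expect_false("VN" %in% assign_tags(metric_row(nvaf = 0.3, d_n = 5L),
                                     cfg_lit, "somatic"))
  expect_true("VN" %in% assign_tags(metric_row(nvaf = 2, d_n = 5L),
                                    cfg_lit, "somatic"))
  # germline mode never emits somatic tags
  expect_setequal(assign_tags(metric_row(lncr = 1, nvaf = 1, d_n = 9L), cfg,
                              "germline"), character(0))
})

test_that("tags are reproducible from the stored metrics (round trip)", {
  cfg <- vartag_config()
  set.seed(20)
  for (i in 1:50) {
    m <- metric_row(lcr = sample(c(0, 0.3), 1), vafr = runif(1),
                    nh = runif(1), ne = runif(1), ni = runif(1),
                    nd = runif(1), sse = runif(1), dir = runif(1, 0.5, 1),
                    lm = runif(1), mm = rexp(1), mv = rexp(1, 2),
                    hdr = rexp(1), si = runif(1),
                    r = sample(0:1, 1), ri = 0,
                    li = sample(0:1, 1), nvaf = runif(1),
                    lncr = sample(c(0, 0.5, 1), 1),
                    d_l = sample(0:4, 1), d_mv = sample(0:4, 1),
                    d_n = sample(0:4, 1))
    tags <- assign_tags(m, cfg, "somatic")
    expect_identical(tags, assign_tags(m, cfg, "somatic"))
    # spot-check predicates both ways
    expect_equal("LC" %in% tags, m$lcr > 0)
    expect_equal("HE" %in% tags, m$nh >= 0.9)
    expect_equal("LM" %in% tags, m$lm >= 0.2 && m$d_l >= 2)
    expect_equal("NCN" %in% tags, m$lncr == 1)
  }
})

test_that("vscore is the weighted metric sum and monotone in each metric", {
  w <- vartag_weights()
  expect_equal(vscore(metric_row()), 0.5) # only dir = 0.5 at weight 1
  expect_equal(vscore(metric_row(lcr = 1, dir = 0)), 3)
  expect_equal(vscore(metric_row(lcr = 1, vafr = 0.9, hdr = 1, dir = 0)), 7.7)
  # per-level weights
  expect_equal(unname(w[c("lcr", "vafr", "lm", "ni", "nd")]), rep(3, 5))
  expect_equal(unname(w[c("lncr", "mv", "hdr")]), rep(2, 3))
  expect_equal(unname(w[c("nh", "ne", "sse", "dir", "mm", "si", "r", "ri",
                          "li", "nvaf")]), rep(1, 10))
  # monotone: raising any metric cannot lower the score
  set.seed(4)
  base <- metric_row(vafr = 0.3, nh = 0.2, mm = 0.5)
  v0 <- vscore(base)
  for (f in vartag:::.metrics_somatic) {
    up <- base
    up[[f]] <- up[[f]] + 0.25
    expect_gte(vscore(up), v0)
  }
  # override changes the sum accordingly
  expect_equal(vscore(metric_row(hdr = 1, dir = 0), vartag_weights(hdr = 3)), 3)
})

test_that("f_beta matches its closed form and is bounded by min/max", {
  expect_equal(f_beta(0.5, 0.5, 1), 0.5)
  for (x in c(0.1, 0.7, 1)) expect_equal(f_beta(x, x, 0.3), x)
  expect_equal(f_beta(0, 0, 0.3), 0)
  set.seed(5)
  for (i in 1:100) {
    p <- runif(1); r <- runif(1); b <- runif(1, 0.1, 3)
    fb <- f_beta(p, r, b)
    expect_gte(fb, min(p, r) - 1e-12)
    expect_lte(fb, max(p, r) + 1e-12)
  }
  # beta < 1 weights precision: raising P moves F more than raising R
  expect_gt(f_beta(0.9, 0.5, 0.3) , f_beta(0.5, 0.9, 0.3))
})

test_that("mcc equals the closed form and hits its extremes", {
  expect_equal(mcc(10, 0, 10, 0), 1)
  expect_equal(mcc(0, 10, 0, 10), -1)
  expect_equal(mcc(0, 0, 5, 0), 0) # zero marginal
  tp <- 4; fp <- 1; tn <- 3; fn <- 2
  expect_equal(mcc(tp, fp, tn, fn),
               (tp * tn - fp * fn) /
                 sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
})

test_that("threshold sweep equals exhaustive enumeration on 6 variants", {
  scored <- tibble::tibble(vscore = c(0.5, 1.2, 2.8, 3.4, 5.0, 9.1))
  truth <- c(1, 1, 1, 0, 0, 0)
  sw <- sweep_thresholds(scored, truth, beta = 0.3, step = 0.1)
  oracle <- oracle_sweep(scored$vscore, truth == 1, 0.3, sw$threshold)
  expect_equal(sw$tp, oracle$tp)
  expect_equal(sw$fp, oracle$fp)
  expect_equal(sw$precision, oracle$precision)
  expect_equal(sw$f_beta, oracle$f_beta)
  expect_equal(attr(sw, "best"),
               oracle$threshold[which.max(oracle$f_beta)])
  # separable scores reach F_beta 1 between the classes
  g <- glance(sw)
  expect_equal(g$f_beta, 1)
  expect_gt(g$threshold, 2.8)
  expect_lte(g$threshold, 3.4)
})

test_that("sweep covers 0..max inclusive at the requested step", {
  scored <- tibble::tibble(vscore = c(0, 4.0))
  sw <- sweep_thresholds(scored, c(1, 0), step = 0.1)
  expect_equal(nrow(sw), 41L)
  expect_equal(sw$threshold[1], 0)
  expect_equal(sw$threshold[41], 4.0)
  # positivity is strict <: at t = 0 nothing is called positive
  expect_equal(sw$tp[1] + sw$fp[1], 0L)
  # ties break toward the smallest threshold
  tie <- sweep_thresholds(tibble::tibble(vscore = c(0.05, 9)), c(1, 0),
                          step = 0.1)
  expect_equal(attr(tie, "best"),
               min(tie$threshold[tie$f_beta == max(tie$f_beta)]))
  expect_warning(sweep_thresholds(tibble::tibble(vscore = c(1, 2)),
                                  c(1, 1)), "one class")
})
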