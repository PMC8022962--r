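# Shared toy setting: a dosage panel whose variants form known-LD groups,
# a truth study with planted significant variants, and test loci to label.

test_that("efdr implements V/(V+S) with the zero-rejection convention", {
  expect_equal(efdr(0, 0), 0)
  expect_equal(efdr(1, 16), 1 / 17)
  expect_equal(efdr(3, 0), 1)
  expect_error(efdr(-1, 2), "nonnegative")
})

test_that("build_truth collects significant variants into loci", {
  cfg <- tiny_config(seed = 31)
  ps <- make_paired_studies(cfg)
  ts <- build_truth(ps$truth_stats, ps$ld)
  expect_s3_class(ts, "truth_set")
  expect_equal(nrow(ts$sig), sum(ps$truth_stats$P < 5e-8))
  expect_equal(ts$n_truth_loci, ts$truth_loci$m_star)
  # well-powered truth study detects every causal block; LD leakage around
  # very strong signals can add satellite loci but not an unbounded number
  expect_gte(ts$n_truth_loci, cfg$n_causal)
  expect_lte(ts$n_truth_loci, 3 * cfg$n_causal)
  expect_true(all(tm_p <- ps$truth_stats$P[match(ps$truth_model$causal_ids,
                                                 ps$truth_stats$SNP)] < 5e-8))
  # no significant truth variants -> warning, zero loci
  null_truth <- ps$truth_stats
  null_truth$P <- pmin(1, null_truth$P + 0.5)
  expect_warning(ts0 <- build_truth(null_truth, ps$ld), "false positive")
  expect_equal(ts0$n_truth_loci, 0)
})

test_that("match criteria carry the documented defaults", {
  strict <- match_criterion("ld_strict")
  expect_equal(strict$r2_min, 0.80)
  expect_equal(strict$truth_p_max, 5e-8)
  relaxed <- match_criterion("ld_relaxed")
  expect_equal(relaxed$r2_min, 0.60)
  expect_equal(relaxed$truth_p_max, 5e-7)
  dist <- match_criterion("distance")
  expect_equal(dist$dist_bp, 50000)
  expect_equal(match_criterion("ld_strict", r2_min = 0.9)$r2_min, 0.9)
})

test_that("label_loci applies the matching rule exactly (oracle panel)", {
  # build a panel where pairwise r^2 is controlled by column duplication
  set.seed(32)
  n <- 3000
  mix <- function(g, w) ifelse(runif(n) < w, rbinom(n, 2, 0.3), g)
  t1 <- rbinom(n, 2, 0.3); t2 <- rbinom(n, 2, 0.4); t3 <- rbinom(n, 2, 0.25)
  # leads: l1 = t1 itself; l2 high LD with t2; l3 moderate LD with t3;
  # l4 low LD with everything; l5 near t1 in position only; l6 another chrom
  G <- cbind(t1, t2, t3, t1, mix(t2, 0.05), mix(t3, 0.15),
             rbinom(n, 2, 0.3), rbinom(n, 2, 0.35), rbinom(n, 2, 0.45))
  ids <- c("t1", "t2", "t3", "l1", "l2", "l3", "l4", "l5", "l6")
  chrom <- c("1", "1", "2", "1", "1", "2", "1", "1", "3")
  pos <- as.integer(c(1e6, 5e6, 1e6, 1e6, 5.02e6, 1.01e6, 9e6, 1.03e6, 1e6))
  ld <- ld_source(G, ids, chrom, pos)
  truth <- structure(list(
    sig = data.frame(SNP = c("t1", "t2", "t3"), CHR = c("1", "1", "2"),
                     BP = as.integer(c(1e6, 5e6, 1e6)),
                     P = c(1e-20, 1e-9, 4e-7), stringsAsFactors = FALSE),
    truth_loci = NULL, n_truth_loci = 3, p_cut = 5e-7), class = "truth_set")
  leads <- c("l1", "l2", "l3", "l4", "l5", "l6")
  test_loci <- new_locus_set(lapply(leads, function(id) {
    i <- match(id, ids)
    list(lead_id = id, member_ids = id, chrom = chrom[i], lead_pos = pos[i],
         lead_p = 1e-9)
  }), 0.1, 1e6L)

  r2_to <- function(a, b) cor(G[, match(a, ids)], G[, match(b, ids)])^2
  for (mode in c("ld_strict", "ld_relaxed")) {
    crit <- match_criterion(mode)
    ev <- label_loci(test_loci, truth, crit, ld)
    # brute-force re-application of the rule
    want <- vapply(leads, function(l) {
      cand <- truth$sig[truth$sig$P < crit$truth_p_max &
                          truth$sig$CHR == chrom[match(l, ids)], ]
      if (!nrow(cand)) return("FP")
      if (any(vapply(cand$SNP, function(tv) r2_to(l, tv), 1) > crit$r2_min))
        "TP" else "FP"
    }, "")
    expect_equal(setNames(ev$labels$LABEL, ev$labels$LEAD), want)
    expect_equal(ev$R, ev$V + ev$S)
  }
  # specific straddles: identical lead is TP under both; moderate-LD l3 only
  # matches t3, whose truth P (4e-7) passes only the relaxed criterion
  expect_gt(r2_to("l3", "t3"), 0.6)
  expect_lt(r2_to("l3", "t3"), 0.8)
  strict <- label_loci(test_loci, truth, match_criterion("ld_strict"), ld)
  relaxed <- label_loci(test_loci, truth, match_criterion("ld_relaxed"), ld)
  lab <- function(ev, id) ev$labels$LABEL[ev$labels$LEAD == id]
  expect_equal(lab(strict, "l1"), "TP")
  expect_equal(lab(strict, "l3"), "FP")
  expect_equal(lab(relaxed, "l3"), "TP")
  # relaxed never labels fewer TPs than strict
  expect_gte(relaxed$S, strict$S)

  # distance mode: l5 is 30 kb from t1 -> TP; l4 is 8 Mb away -> FP
  dev <- label_loci(test_loci, truth, match_criterion("distance"), ld)
  expect_equal(lab(dev, "l5"), "TP")
  expect_equal(lab(dev, "l4"), "FP")

  # a lead absent from the LD source is labeled FP with a warning
  odd <- new_locus_set(list(list(lead_id = "ghost", member_ids = "ghost",
                                 chrom = "1", lead_pos = 1e6L, lead_p = 1e-9)),
                       0.1, 1e6L)
  expect_warning(ev2 <- label_loci(odd, truth, match_criterion("ld_strict"), ld),
                 "ghost")
  expect_equal(ev2$V, 1)
})

test_that("labeling is independent of locus ordering", {
  cfg <- tiny_config(seed = 33)
  ps <- make_paired_studies(cfg)
  ts <- build_truth(ps$truth_stats, ps$ld)
  cs <- clump(ps$test, ps$ld, p_subset = 5e-6)
  ev1 <- label_loci(cs, ts, match_criterion("ld_strict"), ps$ld)
  rev_cs <- new_locus_set(rev(cs$loci), cs$r2_threshold, cs$window_bp)
  ev2 <- label_loci(rev_cs, ts, match_criterion("ld_strict"), ps$ld)
  expect_equal(ev1$V, ev2$V)
  expect_equal(ev1$S, ev2$S)
  expect_setequal(ev1$labels$LEAD[ev1$labels$LABEL == "TP"],
                  ev2$labels$LEAD[ev2$labels$LABEL == "TP"])
})

test_that("compare_thresholds reproduces the delta/%-true bookkeeping", {
  mk <- function(V, S) structure(list(R = V + S, V = V, S = S,
                                      efdr = efdr(V, S)), class = "eval_result")
  # identical results: +0, undefined percentage
  same <- compare_thresholds(mk(1, 10), mk(1, 10))
  expect_equal(same$delta_loci, 0)
  expect_true(is.na(same$pct_true_of_additional))
  expect_error(compare_thresholds(mk(0, 10), mk(0, 8)), "nested")
  got <- compare_thresholds(mk(0, 157), mk(1, 217))
  expect_equal(got$delta_loci, 61)
  expect_equal(got$additional_true, 60)
})

test_that("evaluation_table runs both clumping regimes and matches single runs", {
  cfg <- tiny_config(seed = 34)
  ps <- make_paired_studies(cfg)
  ts <- build_truth(ps$truth_stats, ps$ld)
  methods <- list(list(method = "p", level = 5e-8),
                  list(method = "p", level = 5e-7),
                  list(method = "bh", level = 0.05),
                  list(method = "by", level = 0.05),
                  list(method = "bfdp", level = 0.05))
  tab <- suppressWarnings(
    evaluation_table(ps$test, ts, ps$ld, methods, pi1 = 1e-4))
  expect_equal(nrow(tab), 5)
  expect_equal(tab$R, tab$V + tab$S)
  expect_true(all(tab$efdr >= 0 & tab$efdr <= 1))
  # fixed-P nesting between its two rows
  expect_lte(tab$R[1], tab$R[2])
  # consistency oracle: the fixed-P row equals an independent run
  cs <- clump(ps$test, ps$ld, p_subset = 5e-8)
  ev <- label_loci(cs, ts, match_criterion("ld_strict"), ps$ld)
  expect_equal(tab$R[1], ev$R)
  expect_equal(tab$V[1], ev$V)
  # BH row equals step-up on the lead P-values of the all-variant clump
  all_cs <- clump(ps$test, ps$ld)
  k <- fdr_bh(lead_pvalues(all_cs), 0.05)$k_reject
  expect_equal(tab$R[3], k)
  # BY never rejects more than BH at equal alpha
  expect_lte(tab$R[4], tab$R[3])
})
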