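#' Build a truth set from a large reference study
#'
#' The largest, most recent study of a trait is treated as approximate truth.
#' Its genome-wide-significant variants (`P < p_cut`) are recorded and
#' LD-clumped into truth loci; a test-set locus will later be labeled a true
#' positive if its lead variant is in high LD with (or near) any of these
#' truth-significant variants.
#'
#' @param truth_stats [sumstats] of the truth study (harmonized with the
#'   test study).
#' @param ld an [ld_source] covering the truth-significant variants.
#' @param p_cut significance cutoff in the truth study, default 5e-8.
#' @return object of class `truth_set`: list with `sig` (data frame of
#'   significant variants), `truth_loci` (a `locus_set`), `n_truth_loci`,
#'   `p_cut`.
#' @export
build_truth <- function(truth_stats, ld, p_cut = 5e-8) {
  sig <- as.data.frame(truth_stats)[truth_stats$P < p_cut,
                                    c("SNP", "CHR", "BP", "P"), drop = FALSE]
  if (!nrow(sig))
    warning("no significant truth variants; every test locus will be a false positive")
  loci <- if (nrow(sig)) clump(sig, ld) else new_locus_set(list(), 0.1, 1e6L)
  structure(list(sig = sig, truth_loci = loci, n_truth_loci = loci$m_star,
                 p_cut = p_cut), class = "truth_set")
}

#' Truth set from known causal variants (simulation ground truth)
#'
#' In simulated studies the causal variants are known, so the truth set is
#' the causal ids themselves rather than detections of a reference study.
#' Their truth "P-values" are set to 0 so every matching criterion's truth
#' significance condition is met.
#'
#' @param ids causal variant ids.
#' @param chrom,pos their chromosomes and positions.
#' @return a `truth_set`.
#' @export
causal_truth <- function(ids, chrom, pos) {
  sig <- data.frame(SNP = as.character(ids), CHR = as.character(chrom),
                    BP = as.integer(pos), P = rep(0, length(ids)),
                    stringsAsFactors = FALSE)
  structure(list(sig = sig, truth_loci = NULL, n_truth_loci = nrow(sig),
                 p_cut = 0), class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("Truth set: %d significant variants", nrow(x$sig)))
  if (!is.null(x$truth_loci))
    cat(sprintf(" in %d loci (P < %g)", x$n_truth_loci, x$p_cut))
  cat("\n")
  invisible(x)
}

#' True-positive matching criteria
#'
#' A test locus is judged against the truth set under one of three modes:
#' `ld_strict` — its lead has `r^2 > 0.80` with some truth variant of
#' `P < 5e-8`; `ld_relaxed` — `r^2 > 0.60` with some truth variant of
#' `P < 5e-7`; `distance` — its lead lies within 50 kb of some truth variant
#' of `P < 5e-8`.  Parameters can be overridden individually.
#'
#' @param mode one of `"ld_strict"`, `"ld_relaxed"`, `"distance"`.
#' @param r2_min LD threshold for the LD modes.
#' @param truth_p_max truth-set significance requirement.
#' @param dist_bp window for distance mode, in bp.
#' @return object of class `match_criterion`.
#' @export
match_criterion <- function(mode = c("ld_strict", "ld_relaxed", "distance"),
                            r2_min = NULL, truth_p_max = NULL, dist_bp = NULL) {
  mode <- match.arg(mode)
  def <- switch(mode,
                ld_strict = list(r2_min = 0.80, truth_p_max = 5e-8, dist_bp = NA),
                ld_relaxed = list(r2_min = 0.60, truth_p_max = 5e-7, dist_bp = NA),
                distance = list(r2_min = NA, truth_p_max = 5e-8, dist_bp = 50000L))
  structure(list(mode = mode,
                 r2_min = r2_min %||% def$r2_min,
                 truth_p_max = truth_p_max %||% def$truth_p_max,
                 dist_bp = dist_bp %||% def$dist_bp),
            class = "match_criterion")
}

#' Label test loci as true or false positives against a truth set
#'
#' Applies a [match_criterion()] to every locus of `test_loci`: the locus is
#' a true positive iff its lead variant matches any sufficiently significant
#' truth variant (by LD or by distance, depending on the criterion mode);
#' otherwise it is a false positive.  A lead that is itself a truth
#' significant variant always matches (self r^2 = 1, distance 0).  LD is only
#' evaluated against truth variants on the lead's chromosome.  A lead absent
#' from the LD source is labeled a false positive with a warning.
#'
#' @param test_loci a `locus_set` of the rejected test loci.
#' @param truth a `truth_set`.
#' @param crit a [match_criterion()].
#' @param ld an [ld_source] (needed for the LD modes).
#' @return object of class `eval_result`: counts `R`, `V`, `S`, the `efdr`,
#'   and a `labels` data frame (LEAD, CHR, BP, P, LABEL, MATCH_ID,
#'   MATCH_R2/MATCH_DIST).
#' @export
label_loci <- function(test_loci, truth, crit = match_criterion(), ld = NULL) {
  cand <- truth$sig[truth$sig$P < crit$truth_p_max, , drop = FALSE]
  n <- test_loci$m_star
  lab <- character(n); match_id <- rep(NA_character_, n); match_val <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    loc <- test_loci$loci[[i]]
    here <- cand[cand$CHR == loc$chrom, , drop = FALSE]
    if (!nrow(here)) { lab[i] <- "FP"; next }
    if (loc$lead_id %in% here$SNP) {
      lab[i] <- "TP"; match_id[i] <- loc$lead_id
      match_val[i] <- if (crit$mode == "distance") 0 else 1
      next
    }
    if (crit$mode == "distance") {
      d <- abs(here$BP - loc$lead_pos)
      j <- which.min(d)
      if (d[j] <= crit$dist_bp) {
        lab[i] <- "TP"; match_id[i] <- here$SNP[j]; match_val[i] <- d[j]
      } else lab[i] <- "FP"
    } else {
      r2 <- tryCatch(
        ld_r2_vec(ld, ld_index(ld, loc$lead_id), ld_index(ld, here$SNP)),
        error = function(e) {
          warning("lead ", loc$lead_id, " unusable in LD source; labeling FP: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(r2)) { lab[i] <- "FP"; next }
      j <- which.max(r2)
      if (r2[j] > crit$r2_min) {
        lab[i] <- "TP"; match_id[i] <- here$SNP[j]; match_val[i] <- r2[j]
      } else lab[i] <- "FP"
    }
  }
  V <- sum(lab == "FP"); S <- sum(lab == "TP")
  labels <- data.frame(
    LEAD = vapply(test_loci$loci, `[[`, "", "lead_id"),
    CHR = vapply(test_loci$loci, `[[`, "", "chrom"),
    BP = vapply(test_loci$loci, `[[`, 0L, "lead_pos"),
    P = vapply(test_loci$loci, `[[`, 0, "lead_p"),
    LABEL = lab, MATCH_ID = match_id, stringsAsFactors = FALSE)
  labels[[if (crit$mode == "distance") "MATCH_DIST" else "MATCH_R2"]] <- match_val
  structure(list(R = n, V = V, S = S, efdr = efdr(V, S), labels = labels,
                 criterion = crit), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("Evaluation: R = %d rejected loci, S = %d true, V = %d false, eFDR = %s\n",
              x$R, x$S, x$V, format_pct(x$efdr)))
  invisible(x)
}

#' Empirical false discovery rate
#'
#' The number of false-positive loci divided by all rejected loci,
#' `V / (V + S)`, set to 0 when nothing is rejected.
#'
#' @param V false-positive count.
#' @param S true-positive count.
#' @return eFDR as a fraction in [0, 1].
#' @export
efdr <- function(V, S) {
  if (V < 0 || S < 0) stop("counts must be nonnegative")
  if (V + S == 0) return(0)
  V / (V + S)
}

#' Gain from relaxing a significance cutoff
#'
#' Given evaluations of the same study under a cutoff and a looser cutoff,
#' reports the number of additional significant loci and the percentage of
#' those that are true positives ("Delta (% true)").
#'
#' @param eval_a `eval_result` at the stricter cutoff.
#' @param eval_b `eval_result` at the looser cutoff.
#' @return list with `delta_loci`, `additional_true`, and
#'   `pct_true_of_additional` (NA when no loci were gained).
#' @export
compare_thresholds <- function(eval_a, eval_b) {
  delta <- eval_b$R - eval_a$R
  if (delta < 0)
    stop("rejection counts must be nested: the looser cutoff rejected fewer loci")
  add_true <- eval_b$S - eval_a$S
  pct <- if (delta > 0) 100 * add_true / delta else NA_real_
  list(delta_loci = delta, additional_true = add_true,
       pct_true_of_additional = pct)
}

#' Evaluate a panel of procedures against a truth set
#'
#' Runs each requested procedure on the test study, clumps its rejections
#' into loci, labels them against the truth set, and tabulates false/true
#' positives and eFDR per procedure.  Two clumping regimes are used, matching
#' how the procedures are defined: fixed P-value thresholds clump the
#' significant variants only, while the step-up procedures (BH, BY, BFDP)
#' first clump *all* tested variants and then apply the step-up to the locus
#' lead variants.
#'
#' @param test_stats [sumstats] of the test study.
#' @param truth a `truth_set`.
#' @param ld an [ld_source].
#' @param methods list of `list(method =, level =)`; `method` one of `"p"`,
#'   `"bh"`, `"by"`, `"bfdp"`.
#' @param criterion a [match_criterion()].
#' @param r2_threshold,window_bp clumping parameters.
#' @param W,pi1 BFDP prior parameters (pi1 estimated from the full test
#'   study when NULL).
#' @return object of class `eval_table`: a data frame with columns
#'   `method`, `level`, `R`, `V` (false), `S` (true), `efdr`, plus the
#'   per-row `eval_result`s in `attr(, "evals")`.
#' @export
evaluation_table <- function(test_stats, truth, ld, methods,
                             criterion = match_criterion(),
                             r2_threshold = 0.1, window_bp = 1e6L,
                             W = 0.04, pi1 = NULL) {
  needs_all <- any(vapply(methods, function(m) m$method != "p", TRUE))
  all_loci <- if (needs_all)
    clump(test_stats, ld, r2_threshold, window_bp) else NULL
  lead_p <- if (needs_all) lead_pvalues(all_loci) else NULL
  evals <- vector("list", length(methods))
  rows <- vector("list", length(methods))
  for (i in seq_along(methods)) {
    m <- methods[[i]]
    if (m$method == "p") {
      rej_loci <- clump(test_stats, ld, r2_threshold, window_bp,
                        p_subset = m$level)
    } else {
      pr <- switch(m$method,
        bh = fdr_bh(lead_p, m$level),
        by = fdr_by(lead_p, m$level),
        bfdp = {
          leads <- test_stats[match(names(lead_p), test_stats$SNP), , drop = FALSE]
          class(leads) <- class(test_stats)
          pi1_use <- pi1 %||% estimate_pi1(test_stats)
          fdr_bayes(bfdp_scores(leads, W = W, pi1 = pi1_use), m$level)
        },
        stop("unknown method: ", m$method))
      keep <- lead_ids(all_loci) %in% pr$rejected_ids
      rej_loci <- new_locus_set(all_loci$loci[keep], r2_threshold, window_bp)
    }
    ev <- label_loci(rej_loci, truth, criterion, ld)
    evals[[i]] <- ev
    rows[[i]] <- data.frame(method = m$method, level = m$level,
                            R = ev$R, V = ev$V, S = ev$S, efdr = ev$efdr,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "evals") <- evals
  class(out) <- c("eval_table", "data.frame")
  out
}

#' @export
print.eval_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$eFDR <- format_pct(df$efdr)
  df$efdr <- NULL
  cat("Procedure evaluation against truth set\n")
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
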