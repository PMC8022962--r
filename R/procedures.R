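#' Result of a multiple-testing procedure
#'
#' Every procedure returns a `procedure_result` carrying the rejection set
#' and the procedure's internals: the target level `alpha`, the step-up cut
#' index `k_reject` (equal to the number of rejections for step-up
#' procedures), the dependency correction factor `correction_factor`
#' (`c(m)` for Benjamini-Yekutieli, 1 otherwise), and the per-id score the
#' decision was based on (P-value or BFDP).
#'
#' @name procedure_result
NULL

new_procedure_result <- function(procedure, alpha, rejected_ids, k_reject,
                                 correction_factor, per_id_score,
                                 extra = list()) {
  structure(c(list(procedure = procedure, alpha = alpha,
                   rejected_ids = rejected_ids, k_reject = k_reject,
                   correction_factor = correction_factor,
                   per_id_score = per_id_score), extra),
            class = "procedure_result")
}

#' @export
print.procedure_result <- function(x, ...) {
  cat(sprintf("Procedure '%s' at level %g: %d of %d hypotheses rejected",
              x$procedure, x$alpha, length(x$rejected_ids),
              length(x$per_id_score)))
  if (x$procedure %in% c("bh", "by", "bfdp"))
    cat(sprintf(" (step-up k = %d, c(m) = %g)", x$k_reject, x$correction_factor))
  cat("\n")
  invisible(x)
}

#' Fixed P-value threshold
#'
#' Rejects hypotheses with `p < alpha_p` (strict inequality, as in the
#' genome-wide "P < 5e-8" convention).
#'
#' @param pvals named numeric vector of P-values (id -> p) or a [sumstats]
#'   object.
#' @param alpha_p the P-value cutoff.
#' @return a [procedure_result].
#' @export
fixed_threshold <- function(pvals, alpha_p) {
  p <- as_pmap(pvals)
  rej <- names(p)[p < alpha_p]
  new_procedure_result("fixed_p", alpha_p, rej, length(rej), 1, p)
}

#' Bonferroni control of the family-wise error rate
#'
#' Rejects hypotheses with `p <= alpha / m`.  Supplying `m_eff < m` (an
#' effective number of independent tests under LD) loosens the cutoff to
#' `alpha / m_eff`; with m_eff = 1e6 and alpha = 0.05 this reproduces the
#' genome-wide 5e-8 convention.
#'
#' @inheritParams fixed_threshold
#' @param alpha target FWER level.
#' @param m_eff optional effective number of independent tests (<= m).
#' @return a [procedure_result].
#' @export
bonferroni <- function(pvals, alpha, m_eff = NULL) {
  p <- as_pmap(pvals)
  m <- length(p)
  m_use <- m_eff %||% m
  cut <- alpha / m_use
  rej <- names(p)[p <= cut]
  new_procedure_result("bonferroni", alpha, rej, length(rej), 1, p,
                       extra = list(m_eff = m_use, cutoff = cut))
}

# shared step-up engine: reject the k smallest scores where k is the largest
# index satisfying threshold_fn(k); deterministic tie-break on (score, id).
stepup <- function(score, threshold_ok) {
  ord <- order(score, names(score))
  s <- score[ord]
  ok <- threshold_ok(s)
  k <- if (any(ok)) max(which(ok)) else 0L
  list(k = k, rejected = if (k > 0) names(s)[seq_len(k)] else character(0))
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Sorts the m P-values ascending and rejects the k smallest, where k is the
#' largest index with `p(k) <= k * alpha / m`.  Valid under positive
#' regression dependence; in GWAS it is applied to the lead-variant P-values
#' of LD-clumped loci (see [clump()]) so the tested units are approximately
#' independent.
#'
#' @inheritParams fixed_threshold
#' @param alpha target FDR level.
#' @return a [procedure_result] with `correction_factor = 1`.
#' @export
fdr_bh <- function(pvals, alpha) {
  p <- as_pmap(pvals)
  m <- length(p)
  r <- stepup(p, function(s) s <= seq_len(m) * alpha / m)
  new_procedure_result("bh", alpha, r$rejected, r$k, 1, p)
}

#' Benjamini-Yekutieli step-up FDR control
#'
#' As [fdr_bh()] but with threshold `k * alpha / (m * c(m))`,
#' `c(m) = sum(1/i, i = 1..m)`, which guarantees FDR control under any
#' dependency structure at the price of conservativeness.
#'
#' @inheritParams fdr_bh
#' @return a [procedure_result] with `correction_factor = c(m)`.
#' @export
fdr_by <- function(pvals, alpha) {
  p <- as_pmap(pvals)
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  r <- stepup(p, function(s) s <= seq_len(m) * alpha / (m * cm))
  new_procedure_result("by", alpha, r$rejected, r$k, cm, p)
}

#' Bayesian FDR step-up on BFDPs
#'
#' Orders the Bayesian false discovery probabilities ascending and rejects
#' the k smallest, where k is the largest index at which the running mean
#' `mean(BFDP(1..k)) <= alpha`.  In GWAS it is applied to the lead-variant
#' BFDPs of LD-clumped loci.
#'
#' @param bfdps named numeric vector of BFDPs (id -> BFDP).
#' @param alpha target Bayesian FDR level.
#' @return a [procedure_result].
#' @export
fdr_bayes <- function(bfdps, alpha) {
  b <- as_pmap(bfdps)
  r <- stepup(b, function(s) cumsum(s) / seq_along(s) <= alpha)
  new_procedure_result("bfdp", alpha, r$rejected, r$k, 1, b)
}
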