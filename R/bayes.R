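#' Estimate the prior probability of association
#'
#' The exchangeable prior probability that a tested variant is associated,
#' estimated conservatively as the proportion of tested variants reaching
#' `P < p_cut` (default genome-wide 5e-8).  In underpowered studies this
#' proportion can be zero, which would make the prior odds infinite; the
#' estimate is therefore floored at `1 / (10 m)` (with a warning).  The
#' alternative estimator discussed for this setting — number of clumped loci
#' with a genome-wide-significant lead divided by one million, an estimate of
#' the number of independent common variants in the genome — is available as
#' `method = "loci_per_million"` (pass the locus count as `n_loci`).
#'
#' @param stats a [sumstats] object (or named P-value vector).
#' @param p_cut significance cutoff defining "associated", default 5e-8.
#' @param method `"proportion"` (default) or `"loci_per_million"`.
#' @param n_loci locus count for `method = "loci_per_million"`.
#' @return estimated pi1 in (0, 1).
#' @export
estimate_pi1 <- function(stats, p_cut = 5e-8,
                         method = c("proportion", "loci_per_million"),
                         n_loci = NULL) {
  method <- match.arg(method)
  p <- as_pmap(stats)
  m <- length(p)
  if (method == "loci_per_million") {
    if (is.null(n_loci)) stop("n_loci required for method 'loci_per_million'")
    pi1 <- n_loci / 1e6
  } else {
    pi1 <- sum(p < p_cut) / m
  }
  floor_val <- 1 / (10 * m)
  if (pi1 < floor_val) {
    warning(sprintf("pi1 estimate %.3g below floor; using 1/(10m) = %.3g",
                    pi1, floor_val))
    pi1 <- floor_val
  }
  min(pi1, 1 - .Machine$double.eps)
}

#' Wakefield approximate Bayes factor
#'
#' With effect estimate sampling variance `V` and prior effect variance `W`,
#' let `r = W / (V + W)`.  The approximate Bayes factor is
#' \deqn{ABF = \frac{1}{\sqrt{1-r}} \exp(-z^2 r / 2),}
#' the ratio of prior predictive densities of the effect estimate under the
#' null, N(0, V), and under the alternative, N(0, V + W).  Under this
#' convention ABF = P(data | H0) / P(data | H1): small values are evidence
#' against the null.
#'
#' @param z Z statistic(s).
#' @param V sampling variance of the effect estimate (se^2); positive.
#' @param W prior variance of the effect; positive.  The default 0.04
#'   corresponds to a prior effect standard deviation of 0.2 trait-SD per
#'   allele.
#' @return numeric ABF value(s).
#' @export
abf <- function(z, V, W = 0.04) {
  if (any(V <= 0)) stop("V must be positive")
  if (any(W <= 0)) stop("W must be positive")
  r <- W / (V + W)
  exp(-z^2 * r / 2) / sqrt(1 - r)
}

#' Bayesian false discovery probability
#'
#' The (approximate) posterior probability of no association:
#' \deqn{BFDP = \frac{ABF \times PO}{ABF \times PO + 1},}
#' with `PO = (1 - pi1) / pi1` the prior odds of no association.  With an
#' uninformative observation (ABF = 1) the BFDP returns the prior `1 - pi1`.
#'
#' @param abf_value ABF value(s) from [abf()].
#' @param prior_odds prior odds of no association.
#' @return BFDP in (0, 1).
#' @export
bfdp <- function(abf_value, prior_odds) {
  if (any(abf_value <= 0) || any(prior_odds <= 0))
    stop("abf_value and prior_odds must be positive")
  abf_value * prior_odds / (abf_value * prior_odds + 1)
}

#' Per-variant BFDPs for a study
#'
#' Convenience wrapper: computes `V = SE^2` (reconstructing effects from Z,
#' EAF, N where SE is missing), the ABF at prior variance `W`, and the BFDP
#' at prior odds derived from `pi1` (estimated from the study's full P-value
#' distribution when not supplied).
#'
#' @param stats a [sumstats] object.
#' @param W prior effect variance, default 0.04.
#' @param pi1 prior association probability; default estimated by
#'   [estimate_pi1()] on `stats`.
#' @return named numeric vector of BFDPs (id -> BFDP).
#' @export
bfdp_scores <- function(stats, W = 0.04, pi1 = NULL) {
  se <- stats$SE
  fix <- is.na(se) & !is.na(stats$Z) & !is.na(stats$EAF) & !is.na(stats$N)
  if (any(fix))
    se[fix] <- reconstruct_effects(stats$Z[fix], stats$EAF[fix], stats$N[fix])$se
  if (anyNA(se)) stop("SE unavailable and not reconstructible for some variants")
  pi1 <- pi1 %||% estimate_pi1(stats)
  po <- (1 - pi1) / pi1
  stats::setNames(bfdp(abf(stats$Z, se^2, W), po), stats$SNP)
}
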