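#' Estimate the between-trait correlation of association statistics
#'
#' The multivariate tests require the L x L correlation matrix Omega of the
#' trait Z statistics under the null.  It is estimated as the Pearson
#' correlation of the Z columns over approximately-null variants
#' (default mask: `max |Z| < 2` across traits), which for overlapping-sample
#' studies reflects the residual correlation of the traits.  The result is
#' forced symmetric with unit diagonal; if it is not positive definite a
#' ridge of 1e-6 is added (with a message).
#'
#' @param zmat numeric matrix, variants x L traits, of Z statistics.
#' @param null_mask optional logical vector selecting the variants used for
#'   estimation; default `rowMax(|Z|) < 2`.
#' @return object of class `trait_corr`: list with `omega`, `trait_names`,
#'   `L`, `n_used`.
#' @export
estimate_trait_correlation <- function(zmat, null_mask = NULL) {
  zmat <- as.matrix(zmat)
  L <- ncol(zmat)
  nm <- colnames(zmat) %||% paste0("trait", seq_len(L))
  if (L == 1) {
    omega <- matrix(1, 1, 1, dimnames = list(nm, nm))
    return(structure(list(omega = omega, trait_names = nm, L = 1L,
                          n_used = nrow(zmat)), class = "trait_corr"))
  }
  mask <- null_mask %||% (apply(abs(zmat), 1, max) < 2)
  if (sum(mask) < 100)
    stop("fewer than 100 variants available to estimate the trait correlation")
  omega <- stats::cor(zmat[mask, , drop = FALSE])
  omega <- (omega + t(omega)) / 2
  diag(omega) <- 1
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    message("trait correlation not positive definite; adding ridge 1e-6")
    omega <- omega + diag(1e-6, L)
    omega <- omega / sqrt(diag(omega) %o% diag(omega))
  }
  dimnames(omega) <- list(nm, nm)
  structure(list(omega = omega, trait_names = nm, L = L, n_used = sum(mask)),
            class = "trait_corr")
}

#' @export
print.trait_corr <- function(x, ...) {
  cat(sprintf("Trait Z-score correlation (L = %d, %d null variants used):\n",
              x$L, x$n_used))
  print(round(x$omega, 3))
  invisible(x)
}

as_omega <- function(omega) {
  if (inherits(omega, "trait_corr")) omega$omega else as.matrix(omega)
}

#' metaMANOVA multivariate association test
#'
#' For the length-L vector of per-trait Z statistics at a variant, the test
#' statistic is \eqn{t = z' \Omega^{-1} z}, referred to a chi-squared
#' distribution with L degrees of freedom.  A matrix of Z vectors (variants
#' in rows) is processed in one call.
#'
#' @param zvec length-L numeric vector, or a variants x L matrix.
#' @param omega a `trait_corr` object or L x L correlation matrix.
#' @return list with `statistic` and `p` (vectors when `zvec` is a matrix).
#' @export
meta_manova <- function(zvec, omega) {
  Om <- as_omega(omega)
  Z <- if (is.matrix(zvec)) zvec else matrix(zvec, nrow = 1)
  if (ncol(Z) != ncol(Om)) stop("dimension mismatch between z and omega")
  Oi <- solve(Om)
  stat <- rowSums((Z %*% Oi) * Z)
  p <- stats::pchisq(stat, df = ncol(Om), lower.tail = FALSE)
  if (!is.matrix(zvec)) { stat <- stat[[1]]; p <- p[[1]] }
  list(statistic = stat, p = p)
}

#' Multivariate approximate Bayes factor
#'
#' Extension of [abf()] to L traits with an independent standardized-effect
#' prior of common variance `W`: the ratio of multivariate normal densities
#' of the Z vector under the null, \eqn{N_L(0, \Omega)}, and under the
#' alternative, \eqn{N_L(0, \Omega + W I)}.  For L = 1 this reduces exactly
#' to the univariate ABF at `V = 1` (Z scale).  Small values are evidence
#' against the null of no association with any trait.
#'
#' @inheritParams meta_manova
#' @param W prior variance added to each trait's Z-scale diagonal.
#' @return numeric ABF value(s).
#' @export
multivariate_abf <- function(zvec, omega, W = 0.04) {
  Om <- as_omega(omega)
  L <- ncol(Om)
  Z <- if (is.matrix(zvec)) zvec else matrix(zvec, nrow = 1)
  if (ncol(Z) != L) stop("dimension mismatch between z and omega")
  Oa <- Om + diag(W, L)
  ev <- eigen(Oa, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("alternative covariance omega + W*I is not positive definite")
  q0 <- rowSums((Z %*% solve(Om)) * Z)
  q1 <- rowSums((Z %*% solve(Oa)) * Z)
  logabf <- 0.5 * (determinant(Oa, logarithm = TRUE)$modulus -
                     determinant(Om, logarithm = TRUE)$modulus) -
    0.5 * (q0 - q1)
  out <- exp(as.numeric(logabf))
  if (!is.matrix(zvec)) out <- out[[1]]
  out
}

#' Parallel univariate testing of L traits with a shared threshold
#'
#' Applies a fixed P-value threshold of `alpha_p / L` to each trait
#' separately (Bonferroni adjustment for testing L traits; with L = 3 and
#' alpha_p = 5e-8 the per-trait cutoff is 1.67e-8) and reports the union of
#' rejections with trait provenance.
#'
#' @param pvals_by_trait named list of per-trait P-value maps (named numeric
#'   vectors or [sumstats] objects).
#' @param alpha_p the unadjusted P-value threshold.
#' @param L number of traits; defaults to `length(pvals_by_trait)`.
#' @return list with `per_trait` ([procedure_result] per trait), `union_ids`,
#'   and `provenance` (data frame id x trait of rejections).
#' @export
univariate_multi_trait <- function(pvals_by_trait, alpha_p,
                                   L = length(pvals_by_trait)) {
  if (L < 1) stop("L must be >= 1")
  cutoff <- alpha_p / L
  per_trait <- lapply(pvals_by_trait, fixed_threshold, alpha_p = cutoff)
  prov <- do.call(rbind, lapply(names(per_trait) %||% seq_along(per_trait),
    function(tr) {
      ids <- per_trait[[tr]]$rejected_ids
      if (!length(ids)) return(NULL)
      data.frame(id = ids, trait = tr, stringsAsFactors = FALSE)
    }))
  prov <- prov %||% data.frame(id = character(0), trait = character(0))
  list(per_trait = per_trait, union_ids = unique(prov$id),
       provenance = prov, cutoff = cutoff)
}
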