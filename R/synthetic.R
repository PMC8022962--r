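#' Simulation study configuration
#'
#' Describes the genotype panel, causal architecture and study design for the
#' simulator.  Defaults are a desk-scale analogue of a lipid-like GWAS:
#' 20,000 common variants in 200 independent LD blocks of 100 (latent AR(1)
#' correlation 0.95), MAF uniform on (0.05, 0.5), 30 causal blocks jointly
#' explaining 5% of trait variance, a test study of n = 20,000 paired with a
#' truth study of n = 100,000, and 200 phenotype replicates on fixed
#' genotypes.
#'
#' @param n_test,n_truth test- and truth-study sample sizes.
#' @param M total variant count (must be divisible by `n_blocks`).
#' @param n_blocks number of independent LD blocks.
#' @param rho latent AR(1) correlation within a block.
#' @param maf_range range of target minor allele frequencies.
#' @param n_causal number of causal blocks (one causal variant per block).
#' @param hsq total trait variance explained by the causal variants.
#' @param effect_law `"truth_sig"` (default), `"half_normal"`, or an
#'   explicit numeric vector of per-allele effects (length `n_causal`; used
#'   as given, mirroring effect sizes estimated from a reference study).
#'   Both named laws draw half-normal magnitudes with random signs,
#'   normalized so the explained variance totals `hsq`; `"truth_sig"`
#'   additionally floors each causal's explained variance at the truth
#'   study's genome-wide detection threshold
#'   (`qnorm(1 - 2.5e-8)^2 / n_truth`), mirroring designs that seed causal
#'   effects from a truth study's significant variants — every causal is
#'   then detectable at the truth sample size by construction.
#' @param L number of traits.
#' @param sigma L x L residual trait correlation matrix (default identity).
#' @param reps number of phenotype replicates.
#' @param inverse_normal inverse-normalize simulated traits before scanning.
#' @param truth_mode `"analytic"` simulates the truth study's summary
#'   statistics directly from the block LD structure at `n_truth`
#'   (a 100,000-row dosage matrix is never materialized); `"genotype"` draws
#'   a genotype pool of `n_truth` rows and scans it.
#' @param seed master seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_test = 20000, n_truth = 100000, M = 20000,
                       n_blocks = 200, rho = 0.95, maf_range = c(0.05, 0.5),
                       n_causal = 30, hsq = 0.05, effect_law = "truth_sig",
                       L = 1, sigma = NULL, reps = 200,
                       inverse_normal = FALSE,
                       truth_mode = c("analytic", "genotype"), seed = 1L) {
  if (M %% n_blocks != 0) stop("M must be divisible by n_blocks")
  if (n_causal > n_blocks) stop("n_causal must not exceed n_blocks")
  if (hsq < 0 || hsq >= 1) stop("hsq must lie in [0, 1)")
  if (is.numeric(effect_law)) {
    if (length(effect_law) != n_causal)
      stop("explicit effect list must have length n_causal")
  } else if (!effect_law %in% c("truth_sig", "half_normal")) {
    stop("unknown effect_law: ", effect_law)
  }
  if (identical(effect_law, "truth_sig") && n_causal > 0) {
    v_min <- stats::qnorm(1 - 2.5e-8)^2 / n_truth
    if (n_causal * v_min >= hsq && hsq > 0)
      stop("hsq too small for n_causal truth-detectable causal variants")
  }
  sigma <- sigma %||% diag(L)
  if (!isTRUE(all.equal(unname(diag(sigma)), rep(1, L))))
    stop("sigma must be a correlation matrix (unit diagonal)")
  if (L > 1 && min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("sigma must be positive definite")
  structure(list(n_test = n_test, n_truth = n_truth, M = M,
                 n_blocks = n_blocks, block_size = M %/% n_blocks, rho = rho,
                 maf_range = maf_range, n_causal = n_causal, hsq = hsq,
                 effect_law = effect_law, L = L, sigma = sigma, reps = reps,
                 inverse_normal = inverse_normal,
                 truth_mode = match.arg(truth_mode),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("Simulation config: M = %d variants in %d blocks ",
                     "(rho = %g), %d causal, hsq = %g, n_test = %d, ",
                     "n_truth = %d, reps = %d, seed = %d\n"),
              x$M, x$n_blocks, x$rho, x$n_causal, x$hsq, x$n_test,
              x$n_truth, x$reps, x$seed))
  invisible(x)
}

#' Simulate a block-LD genotype dosage matrix
#'
#' Per block, `2n` haplotypes are drawn from a latent AR(1) Gaussian with
#' parameter `rho` and each column thresholded at the quantile of its target
#' MAF; the dosage is the sum of an individual's two haplotypes, giving
#' values in {0, 1, 2} with within-block r-squared decaying with lag.
#' Blocks are mutually independent.  Positions place blocks > 1 Mb apart
#' (2 Mb start spacing on a chromosome, blocks cycled over 22 chromosomes)
#' with a within-block span under 200 kb, so clumping windows never bridge
#' blocks.
#'
#' @param config a [sim_config()].
#' @param seed seed (defaults to the config's master seed).
#' @param n number of individuals (defaults to `config$n_test`).
#' @return object of class `c("genotypes", "ld_source")` with the dosage
#'   matrix `G`, variant `ids`/`chrom`/`pos`, target `mafs`, and a `blocks`
#'   data frame.
#' @export
simulate_genotypes <- function(config, seed = config$seed, n = config$n_test) {
  set.seed(seed)
  M <- config$M; bs <- config$block_size; nb <- config$n_blocks
  rho <- config$rho
  mafs <- stats::runif(M, config$maf_range[1], config$maf_range[2])
  chrom <- as.character(rep_len(1:22, nb)[rep(seq_len(nb), each = bs)])
  block_on_chrom <- (seq_len(nb) - 1L) %/% 22L
  start <- 1e6L + block_on_chrom * 2e6L
  pos <- rep(start, each = bs) + rep(seq_len(bs) - 1L, nb) * 2000L
  ids <- sprintf("v%05d", seq_len(M))
  G <- matrix(0, nrow = n, ncol = M)
  a <- sqrt(1 - rho^2)
  for (b in seq_len(nb)) {
    cols <- ((b - 1L) * bs + 1L):(b * bs)
    Z <- matrix(0, 2L * n, bs)
    Z[, 1] <- stats::rnorm(2L * n)
    for (j in seq_len(bs)[-1]) Z[, j] <- rho * Z[, j - 1] + a * stats::rnorm(2L * n)
    H <- Z < rep(stats::qnorm(mafs[cols]), each = 2L * n)
    G[, cols] <- H[1:n, , drop = FALSE] + H[(n + 1L):(2L * n), , drop = FALSE]
    # large temporaries churn the heap; keep the collector from growing it
    if (b %% 4L == 0L) gc(FALSE)
  }
  gc(FALSE)
  obj <- ld_source(G, ids, chrom, pos)
  obj$mafs <- mafs
  obj$blocks <- data.frame(block = seq_len(nb),
                           start_col = (seq_len(nb) - 1L) * bs + 1L,
                           end_col = seq_len(nb) * bs,
                           chrom = as.character(rep_len(1:22, nb)),
                           rho = rho)
  class(obj) <- c("genotypes", "ld_source")
  obj
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("Simulated genotypes: %d individuals x %d variants in %d AR(1) blocks (rho = %g)\n",
              nrow(x$G), ncol(x$G), nrow(x$blocks), x$blocks$rho[1]))
  invisible(x)
}

#' Assign a causal architecture to a genotype panel
#'
#' Samples `n_causal` blocks without replacement, picks one causal variant
#' uniformly within each (so truth loci are well separated), and draws
#' per-allele effects from the configured law.  For the default half-normal
#' law, magnitudes `|N(0,1)|` with random signs are rescaled so the explained
#' variance \eqn{\sum_j 2 p_j (1 - p_j) \theta_j^2} equals `hsq` (the trait
#' is variance-standardized, so the residual variance is `1 - hsq`).  For
#' `L > 1` traits the causal variants are shared and each trait receives an
#' independent effect draw; the residual covariance is
#' `(1 - hsq) * sigma`.
#'
#' @param G a `genotypes` object.
#' @param config the [sim_config()].
#' @param seed seed (defaults to `config$seed + 1`).
#' @return object of class `truth_model`: `causal_ids`, `theta` (named
#'   vector, or ids x L matrix for multiple traits), `hsq`, `sigma_resid`,
#'   `causal_chrom`, `causal_pos`.
#' @export
assign_effects <- function(G, config, seed = config$seed + 1L) {
  set.seed(seed)
  nb <- nrow(G$blocks)
  if (config$n_causal == 0) {
    return(structure(list(causal_ids = character(0),
                          theta = stats::setNames(numeric(0), character(0)),
                          hsq = 0, sigma_resid = (1 - 0) * config$sigma,
                          causal_chrom = character(0),
                          causal_pos = integer(0)),
                     class = "truth_model"))
  }
  blocks <- sort(sample.int(nb, config$n_causal))
  within <- sample.int(config$block_size, config$n_causal, replace = TRUE)
  idx <- G$blocks$start_col[blocks] + within - 1L
  eaf <- colMeans(G$G[, idx, drop = FALSE]) / 2
  wt <- 2 * eaf * (1 - eaf)
  draw_theta <- function() {
    if (is.numeric(config$effect_law)) return(config$effect_law)
    sgn <- sample(c(-1, 1), config$n_causal, replace = TRUE)
    x2 <- stats::rnorm(config$n_causal)^2
    if (config$hsq == 0) return(x2 * 0)
    if (identical(config$effect_law, "truth_sig")) {
      # explained variance floored at the truth study's 5e-8 detection
      # threshold; the remainder follows the half-normal-squared law
      v_min <- stats::qnorm(1 - 2.5e-8)^2 / config$n_truth
      v <- v_min + (config$hsq - config$n_causal * v_min) * x2 / sum(x2)
      return(sgn * sqrt(v / wt))
    }
    # per-allele effects proportional to |N(0,1)|, rescaled to total hsq
    sgn * sqrt(x2) * sqrt(config$hsq / sum(wt * x2))
  }
  if (config$L == 1) {
    theta <- stats::setNames(draw_theta(), G$ids[idx])
  } else {
    theta <- vapply(seq_len(config$L), function(l) draw_theta(),
                    numeric(config$n_causal))
    rownames(theta) <- G$ids[idx]
  }
  hsq_real <- if (config$L == 1) sum(wt * theta^2) else
    max(apply(theta, 2, function(th) sum(wt * th^2)))
  if (hsq_real >= 1) stop("requested explained variance >= 1")
  structure(list(causal_ids = G$ids[idx], theta = theta, hsq = hsq_real,
                 sigma_resid = (1 - config$hsq) * config$sigma,
                 causal_chrom = G$chrom[idx], causal_pos = G$pos[idx]),
            class = "truth_model")
}

#' @export
print.truth_model <- function(x, ...) {
  cat(sprintf("Truth model: %d causal variants, explained variance %.4f\n",
              length(x$causal_ids), x$hsq))
  invisible(x)
}

#' Simulate a quantitative trait from a causal architecture
#'
#' `y = sum_j G_j theta_j + e`, `e ~ N(0, 1 - hsq)`, with no covariates.
#' Optionally the trait is inverse-normal transformed afterwards.
#'
#' @param G a `genotypes` object.
#' @param truth a `truth_model` on the same panel.
#' @param seed seed for the residual draw.
#' @param rows optional row subset (individuals) to simulate for.
#' @param inverse_normal apply a rank-based inverse-normal transform.
#' @return numeric trait vector.
#' @export
simulate_phenotype <- function(G, truth, seed, rows = NULL,
                               inverse_normal = FALSE) {
  set.seed(seed)
  rows <- rows %||% seq_len(nrow(G$G))
  n <- length(rows)
  g <- if (length(truth$causal_ids))
    G$G[rows, ld_index(G, truth$causal_ids), drop = FALSE] %*%
      as.numeric(truth$theta)
  else 0
  y <- as.numeric(g) + stats::rnorm(n, 0, sqrt(1 - truth$hsq))
  if (inverse_normal) y <- stats::qnorm((rank(y) - 0.5) / n)
  y
}

#' Simulate L correlated traits
#'
#' `Y = G Theta + E` with rows of `E` iid `N(0, sigma_resid)`.  With `L = 1`
#' this reduces to [simulate_phenotype()].
#'
#' @inheritParams simulate_phenotype
#' @return n x L trait matrix.
#' @export
simulate_phenotypes_multi <- function(G, truth, seed, rows = NULL,
                                      inverse_normal = FALSE) {
  set.seed(seed)
  rows <- rows %||% seq_len(nrow(G$G))
  n <- length(rows)
  Theta <- if (is.matrix(truth$theta)) truth$theta else
    matrix(truth$theta, ncol = 1, dimnames = list(names(truth$theta), NULL))
  L <- ncol(truth$sigma_resid)
  Gen <- if (length(truth$causal_ids))
    G$G[rows, ld_index(G, truth$causal_ids), drop = FALSE] %*% Theta
  else matrix(0, n, L)
  E <- matrix(stats::rnorm(n * L), n, L) %*% chol(truth$sigma_resid)
  Y <- Gen + E
  if (inverse_normal)
    Y <- apply(Y, 2, function(col) stats::qnorm((rank(col) - 0.5) / n))
  Y
}

# dosage sufficient statistics for a (possibly row-subset) panel; computed
# once and reused across scan chunks
dosage_moments <- function(G, rows = NULL) {
  Gm <- G$G
  if (!is.null(rows)) Gm <- Gm[rows, , drop = FALSE]
  n <- nrow(Gm)
  sg <- colSums(Gm)
  sgg <- colsums_sq(Gm)
  list(n = n, sg = sg, sxx = sgg - sg^2 / n)
}

# Per-variant simple linear regression of a phenotype matrix on each dosage
# column (shared sufficient statistics; the workhorse behind
# association_scan and run_replicates).  Returns M x r matrices.
scan_stats <- function(G, Y, rows = NULL, moments = NULL) {
  Gm <- G$G
  if (!is.null(rows)) Gm <- Gm[rows, , drop = FALSE]
  n <- nrow(Gm)
  Y <- as.matrix(Y)
  mo <- moments %||% dosage_moments(G, rows)
  sg <- mo$sg
  sxx <- mo$sxx
  ybar <- colMeans(Y)
  syy <- colSums(Y^2) - n * ybar^2
  sxy <- crossprod(Gm, Y) - outer(sg, ybar)
  ok <- sxx > 0
  beta <- sxy / sxx
  sigma2 <- pmax(sweep(-beta^2 * sxx, 2, syy, `+`), 0) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  z <- beta / se
  p <- 2 * stats::pt(-abs(z), df = n - 2)
  list(beta = beta, se = se, z = z, p = p, eaf = sg / (2 * n), n = n, ok = ok)
}

#' Per-variant association scan
#'
#' Ordinary least-squares regression of the trait on each dosage column with
#' an intercept and no further covariates: effect `beta`, standard error,
#' `z = beta / se`, and a two-sided P-value from the t distribution with
#' n - 2 degrees of freedom.  Constant dosage columns are skipped with a
#' message.
#'
#' @param G a `genotypes` object (or any [ld_source]).
#' @param y trait vector (length = rows used).
#' @param rows optional row subset of individuals.
#' @param trait trait name for the result.
#' @return a [sumstats] object (EAF from the dosage mean; N = sample size).
#' @export
association_scan <- function(G, y, rows = NULL, trait = "simulated") {
  st <- scan_stats(G, y, rows)
  if (!all(st$ok))
    message(sum(!st$ok), " constant dosage column(s) skipped")
  keep <- st$ok
  se <- st$se[keep, 1]
  beta <- st$beta[keep, 1]
  # a noiseless trait gives a zero residual; keep the row representable
  se <- pmax(se, 1e-150)
  z <- beta / se
  p <- pmax(st$p[keep, 1], .Machine$double.xmin)
  sumstats(data.frame(
    SNP = G$ids[keep], CHR = G$chrom[keep], BP = G$pos[keep],
    EA = "A", OA = "C",
    EAF = st$eaf[keep], BETA = beta, SE = se,
    Z = z, P = p, N = st$n,
    stringsAsFactors = FALSE), trait = trait)
}

#' Simulate a study's summary statistics analytically from block LD
#'
#' Generates the association scan a study of size `n` on this panel would
#' produce, without materializing its dosage matrix: per LD block with
#' in-sample dosage correlation R, the Z vector has mean
#' \eqn{\sqrt{n}\, R\, \theta^{(std)}} (standardized causal effects) and
#' correlated noise `N(0, R)`.  This is how [make_paired_studies()] builds
#' a truth study far larger than the genotype pool (e.g. n = 100,000 on a
#' 20,000-row pool).  Effect sizes and standard errors are back-filled via
#' [reconstruct_effects()]; underflowed P-values are floored at the
#' smallest positive double (the Z column carries the signal).
#'
#' @param G a `genotypes` object (the LD panel).
#' @param truth a `truth_model` on the same panel.
#' @param n sample size of the simulated study.
#' @param seed seed for the Z noise.
#' @param trait trait name of the result.
#' @return a [sumstats] object.
#' @export
simulate_sumstats_analytic <- function(G, truth, n, seed, trait = "truth") {
  set.seed(seed)
  M <- ncol(G$G)
  sdG <- sqrt(apply_sd2(G$G))
  theta_std <- numeric(M)
  if (length(truth$causal_ids)) {
    ci <- ld_index(G, truth$causal_ids)
    theta_std[ci] <- as.numeric(truth$theta) * sdG[ci]
  }
  z <- numeric(M)
  for (b in seq_len(nrow(G$blocks))) {
    cols <- G$blocks$start_col[b]:G$blocks$end_col[b]
    R <- stats::cor(G$G[, cols, drop = FALSE])
    mu <- sqrt(n) * drop(R %*% theta_std[cols])
    Lch <- chol(R + diag(1e-8, length(cols)))
    z[cols] <- mu + drop(crossprod(Lch, stats::rnorm(length(cols))))
  }
  eaf <- colMeans(G$G) / 2
  rec <- reconstruct_effects(z, eaf, n)
  p <- 2 * stats::pnorm(-abs(z))
  p[p == 0] <- .Machine$double.xmin  # keep P in (0,1]; Z carries the signal
  sumstats(data.frame(
    SNP = G$ids, CHR = G$chrom, BP = G$pos, EA = "A", OA = "C",
    EAF = eaf, BETA = rec$beta, SE = rec$se, Z = z, P = p, N = n,
    stringsAsFactors = FALSE), trait = trait)
}

# column sums of squares, chunked so no matrix-sized temporary is allocated;
# slabs are kept small and the collector is nudged so transient subset and
# square copies never pile up
colsums_sq <- function(X, chunk = 250L) {
  out <- numeric(ncol(X))
  it <- 0L
  for (lo in seq(1L, ncol(X), by = chunk)) {
    hi <- min(lo + chunk - 1L, ncol(X))
    out[lo:hi] <- colSums(X[, lo:hi, drop = FALSE]^2)
    it <- it + 1L
    if (it %% 10L == 0L) gc(FALSE)
  }
  out
}

# column variances without forming a centered copy
apply_sd2 <- function(X) {
  n <- nrow(X)
  (colsums_sq(X) - colSums(X)^2 / n) / (n - 1)
}

#' Generate a paired test / truth study on one genotype pool
#'
#' Draws one genotype pool and one causal architecture, then simulates an
#' independent phenotype realization for the test study (scanned at
#' `n_test`) and for the truth study at `n_truth`.  With the default
#' `truth_mode = "analytic"` the truth study's summary statistics are
#' simulated directly from the block LD structure at the truth sample size;
#' with `"genotype"` the pool is drawn at `n_truth` rows and the test study
#' scans its first `n_test` rows.
#'
#' @param config a [sim_config()].
#' @param seed master seed (defaults to the config's).
#' @return list with `test` and `truth_stats` ([sumstats]), `truth_model`,
#'   and `ld` (the genotype pool as an [ld_source]).
#' @export
make_paired_studies <- function(config, seed = config$seed) {
  if (config$n_truth <= config$n_test)
    stop("n_truth must exceed n_test")
  pool_n <- if (config$truth_mode == "genotype") config$n_truth else config$n_test
  G <- simulate_genotypes(config, seed = seed, n = pool_n)
  truth_model <- assign_effects(G, config, seed = child_seed(seed, 1L))
  test_rows <- seq_len(config$n_test)
  y_test <- simulate_phenotype(G, truth_model, seed = child_seed(seed, 2L),
                               rows = test_rows,
                               inverse_normal = config$inverse_normal)
  test <- association_scan(G, y_test, rows = test_rows, trait = "test")
  if (config$truth_mode == "genotype") {
    y_truth <- simulate_phenotype(G, truth_model, seed = child_seed(seed, 3L),
                                  inverse_normal = config$inverse_normal)
    truth_stats <- association_scan(G, y_truth, trait = "truth")
  } else {
    truth_stats <- simulate_sumstats_analytic(G, truth_model, config$n_truth,
                                              seed = child_seed(seed, 3L))
  }
  list(test = test, truth_stats = truth_stats, truth_model = truth_model,
       ld = G)
}
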