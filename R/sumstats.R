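#' GWAS summary statistics
#'
#' A `sumstats` object is a data frame of per-variant association results for
#' one trait in one study, with canonical columns `SNP` (variant id), `CHR`
#' (chromosome, character), `BP` (1-based position), `EA`/`OA` (effect/other
#' allele), `EAF` (effect-allele frequency), `BETA` (per-allele effect on the
#' standardized trait scale), `SE` (its standard error), `Z` (Wald statistic),
#' `P` (two-sided P-value) and `N` (sample size).  Rows are sorted by
#' `(CHR, BP)` and variant ids are unique; rows violating the invariants
#' (P outside (0,1], non-positive SE, allele frequency outside (0,1),
#' inconsistent Z vs BETA/SE) are dropped at construction and counted in the
#' load report (`attr(x, "load_report")`).
#'
#' Missing fields are back-filled where algebra permits: `Z = BETA/SE`, and
#' `BETA`/`SE` from `Z`, `EAF`, `N` via [reconstruct_effects()] (which assumes
#' a variance-standardized, e.g. inverse-normalized, trait).
#'
#' @param x data frame with at least `SNP`, `CHR`, `BP`, `P` and either
#'   (`BETA`, `SE`) or (`Z`, `EAF`, `N`).
#' @param trait trait name, stored as `attr(x, "trait")`.
#' @return object of class `c("sumstats", "data.frame")`.
#' @export
sumstats <- function(x, trait = "trait") {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("SNP", "CHR", "BP", "P")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  has <- function(v) v %in% names(x)
  if (!((has("BETA") && has("SE")) || (has("Z") && has("EAF") && has("N"))))
    stop("need either (BETA, SE) or (Z, EAF, N) columns")
  for (col in c("EAF", "BETA", "SE", "Z", "N"))
    if (!has(col)) x[[col]] <- NA_real_
  x$SNP <- as.character(x$SNP)
  x$CHR <- as.character(x$CHR)
  x$BP <- as.integer(x$BP)
  for (col in c("EAF", "BETA", "SE", "Z", "P", "N"))
    x[[col]] <- as.numeric(x[[col]])
  if (!has("EA")) x$EA <- NA_character_
  if (!has("OA")) x$OA <- NA_character_

  n_in <- nrow(x)
  drop_reason <- character(0)
  bad <- function(cond, reason) {
    cond[is.na(cond)] <- FALSE
    if (any(cond)) drop_reason <<- c(drop_reason, rep(reason, sum(cond)))
    cond
  }
  rej <- bad(is.na(x$P) | x$P <= 0 | x$P > 1, "p_out_of_range")
  rej <- rej | bad(!rej & !is.na(x$SE) & x$SE <= 0, "nonpositive_se")
  rej <- rej | bad(!rej & !is.na(x$EAF) & (x$EAF <= 0 | x$EAF >= 1), "eaf_out_of_range")
  zchk <- !rej & !is.na(x$BETA) & !is.na(x$SE) & !is.na(x$Z)
  rej <- rej | bad(zchk & abs(x$Z - x$BETA / x$SE) > 1e-6 * pmax(1, abs(x$Z)),
                   "z_beta_se_mismatch")
  rej <- rej | bad(!rej & (is.na(x$SNP) | is.na(x$CHR) | is.na(x$BP)), "missing_key")
  x <- x[!rej, , drop = FALSE]

  # back-fill: Z from BETA/SE, then BETA/SE from (Z, EAF, N)
  n_filled_z <- 0L
  fz <- is.na(x$Z) & !is.na(x$BETA) & !is.na(x$SE)
  if (any(fz)) {
    x$Z[fz] <- x$BETA[fz] / x$SE[fz]
    n_filled_z <- sum(fz)
  }
  n_filled_beta <- 0L
  fb <- (is.na(x$BETA) | is.na(x$SE)) & !is.na(x$Z) & !is.na(x$EAF) & !is.na(x$N)
  if (any(fb)) {
    rec <- reconstruct_effects(x$Z[fb], x$EAF[fb], x$N[fb])
    x$BETA[fb] <- rec$beta
    x$SE[fb] <- rec$se
    n_filled_beta <- sum(fb)
  }

  dup <- duplicated(x$SNP)
  if (any(dup)) {
    drop_reason <- c(drop_reason, rep("duplicate_id", sum(dup)))
    x <- x[!dup, , drop = FALSE]
  }
  x <- x[order(x$CHR, x$BP, x$SNP), , drop = FALSE]
  x <- x[, c("SNP", "CHR", "BP", "EA", "OA", "EAF", "BETA", "SE", "Z", "P", "N")]
  rownames(x) <- NULL
  structure(x,
            trait = trait,
            load_report = list(n_input = n_in, n_kept = nrow(x),
                               n_dropped = n_in - nrow(x) + sum(dup),
                               reasons = table(drop_reason),
                               n_filled_z = n_filled_z,
                               n_filled_beta_se = n_filled_beta),
            class = c("sumstats", "data.frame"))
}

#' Number of tested variants
#' @param x a `sumstats` object.
#' @return integer count m.
#' @export
n_variants <- function(x) nrow(x)

#' @export
print.sumstats <- function(x, ...) {
  rep <- attr(x, "load_report")
  cat(sprintf("GWAS summary statistics: trait '%s', m = %d variants\n",
              attr(x, "trait"), nrow(x)))
  if (!is.null(rep) && rep$n_dropped > 0)
    cat(sprintf("  (%d of %d input rows dropped at load)\n", rep$n_dropped, rep$n_input))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Column dialects for summary-statistics files
#'
#' A dialect maps the canonical column names to the headers found in a file.
#' `sumstats_dialect()` is the identity (canonical headers);
#' `glgc_dialect()` covers the public lipid/anthropometric consortium format
#' (`MarkerName`, `Allele1`, `Allele2`, `Freq.Allele1.HapMapCEU`, `b`, `SE`,
#' `p`, `N`).
#'
#' @param ... canonical = file-header overrides, e.g. `P = "pval"`.
#' @return named character vector, names are canonical columns.
#' @export
sumstats_dialect <- function(...) {
  d <- c(SNP = "SNP", CHR = "CHR", BP = "BP", EA = "EA", OA = "OA",
         EAF = "EAF", BETA = "BETA", SE = "SE", Z = "Z", P = "P", N = "N")
  ov <- c(...)
  if (length(ov)) d[names(ov)] <- ov
  d
}

#' @rdname sumstats_dialect
#' @export
glgc_dialect <- function() {
  c(SNP = "MarkerName", EA = "Allele1", OA = "Allele2",
    EAF = "Freq.Allele1.HapMapCEU", BETA = "b", SE = "SE", P = "p", N = "N",
    CHR = "CHR", BP = "BP")
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a (possibly gzip-compressed) delimited file with a header, renames
#' columns through `dialect`, and validates through [sumstats()].  Rows that
#' fail the invariants are dropped and counted in the attached load report.
#'
#' @param path file path; `.gz` is read transparently.
#' @param dialect canonical -> file column-name map, see [sumstats_dialect()].
#' @param trait trait name for the resulting object.
#' @return a [sumstats] object.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(), trait = "trait") {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  present <- dialect[dialect %in% names(dt)]
  if (!length(present)) stop("no dialect columns found in ", path)
  dt <- dt[, unname(present), drop = FALSE]
  names(dt) <- names(present)
  need <- c("SNP", "CHR", "BP", "P")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("file ", path, " is missing mandatory column(s): ",
         paste(dialect[miss], collapse = ", "))
  sumstats(dt, trait = trait)
}

#' Write summary statistics as tab-delimited text
#'
#' Numeric fields are written with 12 significant digits so a
#' read -> write -> read round trip is lossless to that precision.
#' A `.gz` suffix writes gzip output.
#'
#' @param x a [sumstats] object.
#' @param path output path.
#' @export
write_sumstats <- function(x, path) {
  out <- as.data.frame(x)
  for (col in c("EAF", "BETA", "SE", "Z", "P", "N"))
    out[[col]] <- ifelse(is.na(out[[col]]), NA,
                         formatC(out[[col]], digits = 12, format = "g"))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA",
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Reconstruct effect size and standard error from Z, EAF and N
#'
#' For a variance-standardized quantitative trait, the standard error of the
#' per-allele effect is approximately
#' \deqn{se = 1 / \sqrt{2 p (1-p) (n + z^2)}}
#' with `p` the effect-allele frequency, and the effect itself is
#' `beta = z * se`.  This is the usual route to effect estimates when a
#' public result file carries only Z statistics, allele frequencies and
#' sample sizes.
#'
#' @param z Z statistic(s).
#' @param eaf effect-allele frequency in (0,1).
#' @param n sample size.
#' @return list with numeric vectors `beta` and `se`.
#' @export
reconstruct_effects <- function(z, eaf, n) {
  if (any(eaf <= 0 | eaf >= 1)) stop("eaf must lie strictly in (0, 1)")
  if (any(n <= 0)) stop("n must be positive")
  se <- 1 / sqrt(2 * eaf * (1 - eaf) * (n + z^2))
  list(beta = z * se, se = se)
}

#' Filter variants by minor allele frequency
#'
#' Keeps variants with `min(EAF, 1-EAF) > threshold` (strict inequality:
#' a "MAF > 5%" filter excludes MAF exactly 0.05).
#'
#' @param stats a [sumstats] object with `EAF` present.
#' @param threshold MAF cutoff, default 0.05.
#' @return filtered [sumstats] object with updated m.
#' @export
maf_filter <- function(stats, threshold = 0.05) {
  maf <- pmin(stats$EAF, 1 - stats$EAF)
  keep <- !is.na(maf) & maf > threshold
  out <- stats[keep, , drop = FALSE]
  attr(out, "trait") <- attr(stats, "trait")
  attr(out, "load_report") <- attr(stats, "load_report")
  class(out) <- class(stats)
  rownames(out) <- NULL
  out
}

#' Harmonize a test and a truth study onto shared, allele-aligned variants
#'
#' Intersects the two studies on variant id.  Where the truth study codes the
#' opposite allele as the effect allele (effect/other swapped), its `BETA` and
#' `Z` are negated and `EAF` reflected.  Variants whose alleles cannot be
#' reconciled by a swap are dropped and reported.  Variants without allele
#' labels on either side are matched verbatim.
#'
#' @param test,truth [sumstats] objects.
#' @return object of class `harmonized_pair`: list with elements `test` and
#'   `truth` (row-aligned on `shared_ids`), `shared_ids`, `n_flipped`, and
#'   `dropped_ids` (irreconcilable alleles).
#' @export
harmonize <- function(test, truth) {
  ids <- intersect(test$SNP, truth$SNP)
  if (!length(ids)) stop("no shared variant ids between test and truth")
  a <- test[match(ids, test$SNP), , drop = FALSE]
  b <- truth[match(ids, truth$SNP), , drop = FALSE]
  has_alleles <- !is.na(a$EA) & !is.na(a$OA) & !is.na(b$EA) & !is.na(b$OA)
  same <- !has_alleles | (a$EA == b$EA & a$OA == b$OA)
  swap <- has_alleles & !same & a$EA == b$OA & a$OA == b$EA
  drop <- !(same | swap)
  if (any(swap)) {
    b$BETA[swap] <- -b$BETA[swap]
    b$Z[swap] <- -b$Z[swap]
    b$EAF[swap] <- 1 - b$EAF[swap]
    b$EA[swap] <- a$EA[swap]
    b$OA[swap] <- a$OA[swap]
  }
  dropped <- ids[drop]
  keep <- !drop
  a <- a[keep, , drop = FALSE]
  b <- b[keep, , drop = FALSE]
  ord <- order(a$CHR, a$BP, a$SNP)
  a <- a[ord, , drop = FALSE]; b <- b[ord, , drop = FALSE]
  rownames(a) <- rownames(b) <- NULL
  class(a) <- class(b) <- c("sumstats", "data.frame")
  structure(list(test = a, truth = b, shared_ids = a$SNP,
                 n_flipped = sum(swap), dropped_ids = dropped),
            class = "harmonized_pair")
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat(sprintf("Harmonized pair: %d shared variants (%d allele-flipped, %d irreconcilable dropped)\n",
              length(x$shared_ids), x$n_flipped, length(x$dropped_ids)))
  invisible(x)
}

#' Genomic-control inflation factor
#'
#' \eqn{\lambda_{GC}} is the median association \eqn{\chi^2 = Z^2} divided by
#' the null median `qchisq(0.5, 1)` (0.4549364).  When Z is absent the
#' \eqn{\chi^2} values are quantile-transformed from the P-values, which gives
#' the identical result for two-sided tests.
#'
#' @param stats a [sumstats] object with `Z` or `P`.
#' @return scalar inflation factor.
#' @export
lambda_gc <- function(stats) {
  if (nrow(stats) < 10)
    warning("lambda_gc computed on fewer than 10 variants")
  z <- stats$Z
  if (all(is.na(z))) {
    chisq <- stats::qchisq(stats$P, df = 1, lower.tail = FALSE)
  } else {
    chisq <- z^2
  }
  stats::median(chisq, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
}
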