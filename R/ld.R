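#' LD source backed by a dosage matrix
#'
#' Wraps an `n x M` genotype dosage matrix (values in [0, 2]) together with
#' the variant ids, chromosomes and positions aligned to its columns.
#' Pairwise LD is the squared Pearson correlation of dosage columns,
#' computed in-sample.
#'
#' @param dosage numeric matrix, individuals in rows, variants in columns.
#' @param ids character vector of variant ids (unique), one per column.
#' @param chrom chromosome per column.
#' @param pos 1-based position per column.
#' @return object of class `ld_source`.
#' @export
ld_source <- function(dosage, ids, chrom, pos) {
  if (ncol(dosage) != length(ids)) stop("one id per dosage column required")
  if (anyDuplicated(ids)) stop("variant ids must be unique")
  structure(list(G = dosage, ids = as.character(ids),
                 chrom = as.character(chrom), pos = as.integer(pos),
                 index = stats::setNames(seq_along(ids), ids)),
            class = "ld_source")
}

#' @export
print.ld_source <- function(x, ...) {
  cat(sprintf("LD source: %d individuals x %d variants\n", nrow(x$G), ncol(x$G)))
  invisible(x)
}

ld_index <- function(ld, ids) {
  i <- ld$index[ids]
  if (anyNA(i)) stop("variant(s) absent from LD source: ",
                     paste(utils::head(ids[is.na(i)], 5), collapse = ", "))
  unname(i)
}

#' Pairwise LD (r-squared) between two variants
#'
#' Squared Pearson correlation of the two dosage columns.  An allele flip
#' (dosage `2 - g`) leaves r-squared unchanged.
#'
#' @param ld an [ld_source].
#' @param id_a,id_b variant ids.
#' @return r-squared in [0, 1].
#' @export
ld_r2 <- function(ld, id_a, id_b) {
  i <- ld_index(ld, c(id_a, id_b))
  a <- ld$G[, i[1]]; b <- ld$G[, i[2]]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("LD undefined: constant dosage column")
  stats::cor(a, b)^2
}

# r^2 between one lead column and several candidate columns, via sufficient
# statistics (no centered copies; vectorized over candidates).
ld_r2_vec <- function(ld, lead_idx, cand_idx) {
  x <- ld$G[, lead_idx]
  Y <- ld$G[, cand_idx, drop = FALSE]
  n <- length(x)
  sx <- sum(x); sxx <- sum(x^2) - sx^2 / n
  sy <- colSums(Y); syy <- colSums(Y^2) - sy^2 / n
  if (sxx == 0 || any(syy == 0)) stop("LD undefined: constant dosage column")
  sxy <- drop(crossprod(Y, x)) - sx * sy / n
  pmin(sxy^2 / (sxx * syy), 1)
}

new_locus_set <- function(loci, r2_threshold, window_bp) {
  structure(list(loci = loci, m_star = length(loci),
                 r2_threshold = r2_threshold, window_bp = window_bp),
            class = "locus_set")
}

#' Greedy P-value-ordered LD clumping of variants into loci
#'
#' Repeatedly takes the unassigned variant with the smallest P-value as a
#' lead, assigns to its locus every unassigned variant on the same chromosome
#' within `window_bp` of the lead with dosage `r^2 > r2_threshold` against the
#' lead, and iterates until all variants are assigned.  The result is a
#' partition of the (subset of) variants into loci, ordered by lead P-value.
#' P-value ties are broken by `(CHR, BP, SNP)` so the partition is
#' deterministic.
#'
#' Distances are measured lead-to-member and the window is inclusive
#' (`|pos - lead_pos| <= window_bp`); loci never span chromosomes.
#'
#' @param stats a [sumstats] object (or data frame with `SNP`, `CHR`, `BP`,
#'   `P`) for the variants to clump.
#' @param ld an [ld_source] covering those variants.
#' @param r2_threshold LD membership threshold (strict `>`), default 0.1.
#' @param window_bp maximal lead-to-member distance in bp, default 1 Mb.
#' @param p_subset optional P cutoff: only variants with `P < p_subset` are
#'   clumped (used to clump "significant" variants only).
#' @return object of class `locus_set`; element `loci` is a list of loci,
#'   each with `lead_id`, `member_ids`, `chrom`, `lead_pos`, `lead_p`.
#' @export
clump <- function(stats, ld, r2_threshold = 0.1, window_bp = 1e6L,
                  p_subset = NULL) {
  clump_engine(stats, ld = ld, r2_threshold = r2_threshold,
               window_bp = window_bp, p_subset = p_subset, use_ld = TRUE)
}

#' Distance-only clumping
#'
#' Same greedy loop as [clump()] with the LD condition removed: every
#' unassigned variant within `window_bp` of the lead (same chromosome) joins
#' the lead's locus.
#'
#' @inheritParams clump
#' @export
distance_clump <- function(stats, window_bp = 1e6L, p_subset = NULL) {
  clump_engine(stats, ld = NULL, r2_threshold = NA_real_,
               window_bp = window_bp, p_subset = p_subset, use_ld = FALSE)
}

clump_engine <- function(stats, ld, r2_threshold, window_bp, p_subset, use_ld) {
  df <- as.data.frame(stats)[, c("SNP", "CHR", "BP", "P")]
  if (!is.null(p_subset)) df <- df[df$P < p_subset, , drop = FALSE]
  if (!nrow(df)) return(new_locus_set(list(), r2_threshold, window_bp))
  ord <- order(df$P, df$CHR, df$BP, df$SNP)
  df <- df[ord, , drop = FALSE]
  if (use_ld) gidx <- ld_index(ld, df$SNP)
  n <- nrow(df)
  unassigned <- rep(TRUE, n)
  loci <- vector("list", n)
  nl <- 0L
  # variants are scanned in P order; 'next_free' skips the assigned prefix
  next_free <- 1L
  while (next_free <= n) {
    if (!unassigned[next_free]) { next_free <- next_free + 1L; next }
    i <- next_free
    cand <- which(unassigned & df$CHR == df$CHR[i] &
                    abs(df$BP - df$BP[i]) <= window_bp)
    cand <- setdiff(cand, i)
    if (use_ld && length(cand)) {
      r2 <- ld_r2_vec(ld, gidx[i], gidx[cand])
      cand <- cand[r2 > r2_threshold]
    }
    members <- c(i, cand)
    unassigned[members] <- FALSE
    nl <- nl + 1L
    loci[[nl]] <- list(lead_id = df$SNP[i],
                       member_ids = df$SNP[members],
                       chrom = df$CHR[i],
                       lead_pos = df$BP[i],
                       lead_p = df$P[i])
    next_free <- next_free + 1L
  }
  new_locus_set(loci[seq_len(nl)], r2_threshold, window_bp)
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("Locus set: m* = %d loci (r2 > %s, window %s bp)\n",
              x$m_star,
              if (is.na(x$r2_threshold)) "-" else format(x$r2_threshold),
              format(x$window_bp, big.mark = ",")))
  if (x$m_star) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' @export
as.data.frame.locus_set <- function(x, ...) {
  if (!x$m_star)
    return(data.frame(LEAD = character(0), CHR = character(0),
                      BP = integer(0), P = numeric(0),
                      N_MEMBERS = integer(0), MEMBER_IDS = character(0)))
  data.frame(
    LEAD = vapply(x$loci, `[[`, "", "lead_id"),
    CHR = vapply(x$loci, `[[`, "", "chrom"),
    BP = vapply(x$loci, `[[`, 0L, "lead_pos"),
    P = vapply(x$loci, `[[`, 0, "lead_p"),
    N_MEMBERS = vapply(x$loci, function(l) length(l$member_ids), 0L),
    MEMBER_IDS = vapply(x$loci, function(l) paste(l$member_ids, collapse = ","), ""),
    stringsAsFactors = FALSE)
}

#' Lead variant ids / P-values of a locus set
#' @param x a `locus_set`.
#' @return character vector of lead ids, or named numeric of lead P-values.
#' @export
lead_ids <- function(x) vapply(x$loci, `[[`, "", "lead_id")

#' @rdname lead_ids
#' @export
lead_pvalues <- function(x) {
  stats::setNames(vapply(x$loci, `[[`, 0, "lead_p"), lead_ids(x))
}

#' Write a locus set as a PLINK-clump-style table
#' @param x a `locus_set`.
#' @param path output path (tab-delimited text).
#' @export
write_clumps <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", quote = FALSE)
  invisible(path)
}
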