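# Internal helpers shared across modules.

# Round half away from zero (printed tables round 5.85 -> 5.9, not to even).
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# Format a proportion as a percent string at the precision used in reports:
# integer percent at >= 10%, one decimal in [1%, 10%), two decimals below 1%.
format_pct <- function(q) {
  vapply(q, function(qi) {
    p <- 100 * qi
    if (p >= 10) sprintf("%d%%", as.integer(round_half_up(p)))
    else if (p >= 1) sprintf("%.1f%%", round_half_up(p, 1))
    else sprintf("%.2f%%", round_half_up(p, 2))
  }, character(1))
}

# Extract a named id -> p map from either a named numeric vector or a
# sumstats object; procedures accept both.
as_pmap <- function(pvals) {
  if (inherits(pvals, "sumstats")) {
    p <- pvals$P
    names(p) <- pvals$SNP
    return(p)
  }
  if (!is.numeric(pvals)) stop("'pvals' must be a named numeric vector or a sumstats object")
  if (is.null(names(pvals)) || anyNA(names(pvals)) || any(names(pvals) == ""))
    stop("'pvals' must be named by variant id")
  pvals
}

# Derive a child seed from a master seed and a counter, kept within the
# 32-bit signed integer range so set.seed() never overflows.
child_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807) %% 2147483399) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
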