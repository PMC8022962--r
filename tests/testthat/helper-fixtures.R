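# Fixtures and independent oracles shared across test files.
# Everything is generated in code under fixed seeds; no data files.

# random summary-statistics table with self-consistent fields
rand_sumstats_df <- function(m, seed = 1) {
  set.seed(seed)
  beta <- rnorm(m, 0, 0.05)
  se <- runif(m, 0.01, 0.05)
  z <- beta / se
  data.frame(
    SNP = sprintf("rs%05d", seq_len(m)),
    CHR = as.character(sample(1:22, m, replace = TRUE)),
    BP = sample.int(5e7, m),
    EA = sample(c("A", "C", "G", "T"), m, replace = TRUE),
    OA = sample(c("A", "C", "G", "T"), m, replace = TRUE),
    EAF = runif(m, 0.01, 0.99),
    BETA = beta, SE = se, Z = z,
    P = 2 * pnorm(-abs(z)),
    N = 10000,
    stringsAsFactors = FALSE)
}

# small dosage panel with blocky correlation, plus matching sumstats
toy_panel <- function(seed = 1, n_var = 20, n_ind = 400, rho = 0.9,
                      block = 5) {
  set.seed(seed)
  nb <- ceiling(n_var / block)
  G <- matrix(0, n_ind, n_var)
  for (b in seq_len(nb)) {
    cols <- ((b - 1) * block + 1):min(b * block, n_var)
    z <- rnorm(2 * n_ind)
    for (j in cols) {
      maf <- runif(1, 0.1, 0.5)
      hap <- as.numeric(z < qnorm(maf))
      G[, j] <- hap[1:n_ind] + hap[(n_ind + 1):(2 * n_ind)]
      z <- rho * z + sqrt(1 - rho^2) * rnorm(2 * n_ind)
    }
  }
  ids <- sprintf("s%03d", seq_len(n_var))
  chrom <- as.character(rep(1:2, length.out = nb)[rep(seq_len(nb), each = block)][seq_len(n_var)])
  pos <- as.integer(seq_len(n_var) * 5e4)
  list(ld = ld_source(G, ids, chrom, pos),
       df = data.frame(SNP = ids, CHR = chrom, BP = pos,
                       P = runif(n_var), stringsAsFactors = FALSE))
}

# independent straight-line reimplementation of greedy P-ordered clumping,
# working from an explicit r^2 matrix (the oracle for clump())
clump_oracle <- function(df, r2mat, r2_thr, window, use_ld = TRUE) {
  ord <- order(df$P, df$CHR, df$BP, df$SNP)
  df <- df[ord, ]
  r2mat <- r2mat[df$SNP, df$SNP, drop = FALSE]
  assigned <- rep(FALSE, nrow(df))
  out <- list()
  repeat {
    lead <- which(!assigned)[1]
    if (is.na(lead)) break
    members <- lead
    for (j in which(!assigned)) {
      if (j == lead) next
      if (df$CHR[j] != df$CHR[lead]) next
      if (abs(df$BP[j] - df$BP[lead]) > window) next
      if (use_ld && !(r2mat[lead, j] > r2_thr)) next
      members <- c(members, j)
    }
    assigned[members] <- TRUE
    out[[length(out) + 1]] <- list(lead = df$SNP[lead],
                                   members = sort(df$SNP[members]))
  }
  out
}

# exhaustive max-k search oracles for the step-up procedures
bh_oracle_k <- function(p, alpha, cm = 1) {
  p <- sort(p); m <- length(p)
  ks <- which(p <= seq_len(m) * alpha / (m * cm))
  if (length(ks)) max(ks) else 0L
}
bayes_oracle_k <- function(b, alpha) {
  b <- sort(b); m <- length(b)
  ks <- which(vapply(seq_len(m), function(k) mean(b[seq_len(k)]) <= alpha, TRUE))
  if (length(ks)) max(ks) else 0L
}

# tiny default simulation config used across module tests
tiny_config <- function(..., seed = 99) {
  sim_config(n_test = 1500, n_truth = 15000, M = 600, n_blocks = 12,
             n_causal = 4, hsq = 0.15, reps = 3, seed = seed, ...)
}
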