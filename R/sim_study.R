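#' Specify a procedure panel for a replicate study
#'
#' Helper building the `procedures` argument of [run_replicates()]: a named
#' list of `list(method, level)` entries, e.g.
#' `procedure_panel(p = c(5e-8, 5e-7), bh = 0.05)`.
#'
#' @param p,bh,by,bfdp numeric vectors of levels for each procedure family
#'   (P-value cutoffs for `p`, target FDR levels otherwise).
#' @return named list of procedure specifications.
#' @export
procedure_panel <- function(p = NULL, bh = NULL, by = NULL, bfdp = NULL) {
  out <- list()
  for (method in c("p", "bh", "by", "bfdp")) {
    for (level in get(method) %||% numeric(0)) {
      out[[sprintf("%s:%g", method, level)]] <-
        list(method = method, level = level)
    }
  }
  if (!length(out)) stop("no procedures specified")
  out
}

#' Run a replicate simulation study
#'
#' Generates one genotype pool and causal architecture from `config`, then
#' for each replicate draws a fresh phenotype, scans it, applies every
#' procedure in the panel (fixed-P cutoffs clump significant variants only;
#' BH/BY/BFDP clump all tested variants and step up on locus leads), and
#' labels the rejected loci against the known causal variants under
#' `criterion` (default: strict LD matching, lead r^2 > 0.8 with a causal
#' variant).  Genotypes are fixed across replicates; child seeds are derived
#' from the master seed so each replicate is individually reproducible.
#'
#' @param config a [sim_config()].
#' @param procedures a [procedure_panel()].
#' @param seed master seed (defaults to the config's).
#' @param criterion a [match_criterion()] for truth labeling.
#' @param W BFDP prior effect variance.
#' @param n_override optional test sample size (row subset of the pool) so
#'   sample-size contrasts can reuse one pool.
#' @param G,truth_model optional pre-built genotype pool and causal
#'   architecture (as produced with the same config and seed), so several
#'   panels or sample sizes can share one pool without regenerating it.
#' @param truth optional `truth_set` to label against instead of the causal
#'   variants — e.g. `build_truth()` on a generated truth study, mirroring
#'   the empirical sequential-meta-analysis evaluation.
#' @return object of class `replicate_set`: list of per-replicate outcomes
#'   (`rep`, `seed`, `evals` = named list of `eval_result`), with the config
#'   and panel attached as attributes.
#' @export
run_replicates <- function(config, procedures, seed = config$seed,
                           criterion = match_criterion("ld_strict"),
                           W = 0.04, n_override = NULL,
                           G = NULL, truth_model = NULL, truth = NULL) {
  G <- G %||% simulate_genotypes(config, seed = seed, n = config$n_test)
  truth_model <- truth_model %||%
    assign_effects(G, config, seed = child_seed(seed, 1L))
  truth <- truth %||% causal_truth(truth_model$causal_ids,
                                   truth_model$causal_chrom,
                                   truth_model$causal_pos)
  rows <- if (!is.null(n_override)) seq_len(n_override) else NULL
  needs_all <- any(vapply(procedures, function(m) m$method != "p", TRUE))
  needs_bfdp <- any(vapply(procedures, function(m) m$method == "bfdp", TRUE))
  base_df <- data.frame(SNP = G$ids, CHR = G$chrom, BP = G$pos,
                        stringsAsFactors = FALSE)
  outcomes <- vector("list", config$reps)
  moments <- dosage_moments(G, rows)
  chunk <- 50L
  for (lo in seq(1L, config$reps, by = chunk)) {
    hi <- min(lo + chunk - 1L, config$reps)
    idx <- lo:hi
    seeds <- vapply(idx, function(i) child_seed(seed, 100L + i), 1L)
    n_eff <- if (is.null(rows)) nrow(G$G) else length(rows)
    Y <- vapply(seeds, function(s)
      simulate_phenotype(G, truth_model, seed = s, rows = rows,
                         inverse_normal = config$inverse_normal),
      numeric(n_eff))
    st <- scan_stats(G, Y, rows = rows, moments = moments)
    gc(FALSE)
    for (k in seq_along(idx)) {
      i <- idx[k]
      outcomes[[i]] <- tryCatch(
        replicate_outcome(i, seeds[k], base_df, st, k, G, truth,
                          procedures, criterion, W, needs_all, needs_bfdp),
        error = function(e)
          stop(sprintf("replicate %d (seed %d) failed: %s", i, seeds[k],
                       conditionMessage(e)), call. = FALSE))
    }
  }
  structure(outcomes, config = config, procedures = procedures,
            criterion = criterion, class = "replicate_set")
}

replicate_outcome <- function(i, seed_i, base_df, st, k, G, truth,
                              procedures, criterion, W, needs_all,
                              needs_bfdp) {
  df <- base_df
  df$P <- st$p[, k]
  all_loci <- if (needs_all) clump(df, G) else NULL
  lead_p <- if (needs_all) lead_pvalues(all_loci) else NULL
  lead_bfdp <- NULL
  if (needs_bfdp) {
    pmap <- stats::setNames(df$P, df$SNP)
    pi1 <- suppressWarnings(estimate_pi1(pmap))
    li <- match(names(lead_p), df$SNP)
    lead_bfdp <- stats::setNames(
      bfdp(abf(st$z[li, k], st$se[li, k]^2, W), (1 - pi1) / pi1),
      names(lead_p))
  }
  evals <- lapply(procedures, function(m) {
    if (m$method == "p") {
      rej_loci <- clump(df, G, p_subset = m$level)
    } else {
      pr <- switch(m$method,
                   bh = fdr_bh(lead_p, m$level),
                   by = fdr_by(lead_p, m$level),
                   bfdp = fdr_bayes(lead_bfdp, m$level))
      keep <- lead_ids(all_loci) %in% pr$rejected_ids
      rej_loci <- new_locus_set(all_loci$loci[keep],
                                all_loci$r2_threshold, all_loci$window_bp)
    }
    label_loci(rej_loci, truth, criterion, G)
  })
  list(rep = i, seed = seed_i, evals = evals)
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("Replicate study: %d replicates x %d procedures\n",
              length(x), length(attr(x, "procedures"))))
  print(aggregate(x))
  invisible(x)
}

#' Aggregate replicate outcomes
#'
#' Per procedure: the mean false- and true-positive locus counts, the mean
#' of the per-replicate eFDRs (a replicate with no rejections contributes
#' eFDR 0, matching FDR = E\[Q\]) with its Monte Carlo standard error
#' `sd / sqrt(reps)`, and for transparency the pooled ratio-of-means eFDR
#' `sum(V) / sum(R)`.
#'
#' @param x a `replicate_set` from [run_replicates()].
#' @param ... unused.
#' @return data frame of class `sim_aggregate` with one row per procedure:
#'   `procedure`, `mean_V`, `mean_S`, `mean_efdr`, `se_efdr`, `efdr_pooled`,
#'   `reps`.
#' @export
aggregate.replicate_set <- function(x, ...) {
  procs <- names(attr(x, "procedures"))
  rows <- lapply(procs, function(pn) {
    V <- vapply(x, function(o) o$evals[[pn]]$V, 0)
    S <- vapply(x, function(o) o$evals[[pn]]$S, 0)
    q <- vapply(x, function(o) o$evals[[pn]]$efdr, 0)
    data.frame(procedure = pn, mean_V = mean(V), mean_S = mean(S),
               mean_efdr = mean(q),
               se_efdr = stats::sd(q) / sqrt(length(q)),
               efdr_pooled = if (sum(V + S) > 0) sum(V) / sum(V + S) else 0,
               reps = length(q), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sim_aggregate", "data.frame")
  out
}

#' @export
print.sim_aggregate <- function(x, ...) {
  df <- as.data.frame(x)
  df$`eFDR (SE)` <- sprintf("%s (%s)", format_pct(df$mean_efdr),
                            format_pct(df$se_efdr))
  df$mean_efdr <- df$se_efdr <- df$efdr_pooled <- NULL
  print.data.frame(df, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Study report: procedure table and threshold ladder
#'
#' From an aggregate, emits (1) a per-procedure table of mean false/true
#' positives with "eFDR (SE)", and (2) for an ordered ladder of fixed
#' P-value thresholds, the gain in mean significant loci from each threshold
#' to the next and the percentage of the additional loci that are true
#' positives, computed on the mean counts.
#'
#' @param agg a `sim_aggregate` from [aggregate.replicate_set()].
#' @param ladder character vector of procedure names (as in
#'   `agg$procedure`), ordered strict to loose, e.g.
#'   `c("p:5e-08", "p:5e-07", "p:5e-06")`.
#' @return object of class `study_report`: list with data frames
#'   `procedures` and `ladder`.
#' @export
study_report <- function(agg, ladder = NULL) {
  proc_tab <- data.frame(procedure = agg$procedure,
                         false_positives = agg$mean_V,
                         true_positives = agg$mean_S,
                         efdr = agg$mean_efdr, se = agg$se_efdr,
                         stringsAsFactors = FALSE)
  lad <- NULL
  if (!is.null(ladder)) {
    miss <- setdiff(ladder, agg$procedure)
    if (length(miss)) stop("ladder method(s) missing from aggregate: ",
                           paste(miss, collapse = ", "))
    a <- agg[match(ladder, agg$procedure), ]
    R <- a$mean_V + a$mean_S
    delta <- c(NA, diff(R))
    add_true <- c(NA, diff(a$mean_S))
    lad <- data.frame(procedure = ladder,
                      false_positives = a$mean_V, true_positives = a$mean_S,
                      efdr = a$mean_efdr,
                      delta_loci = delta,
                      pct_true_of_additional =
                        ifelse(!is.na(delta) & delta > 0,
                               100 * add_true / delta, NA),
                      stringsAsFactors = FALSE)
  }
  structure(list(procedures = proc_tab, ladder = lad),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Per-procedure outcomes (means over replicates)\n")
  df <- x$procedures
  df$`eFDR (SE)` <- sprintf("%s (%s)", format_pct(df$efdr), format_pct(df$se))
  df$efdr <- df$se <- NULL
  print.data.frame(df, row.names = FALSE, digits = 3)
  if (!is.null(x$ladder)) {
    cat("\nThreshold ladder (means; Delta sig. loci and % true of additional)\n")
    df <- x$ladder
    df$efdr <- format_pct(df$efdr)
    df$delta <- ifelse(is.na(df$delta_loci), "-",
                       sprintf("+%.3g (%d%%)", df$delta_loci,
                               as.integer(round_half_up(df$pct_true_of_additional))))
    df$delta_loci <- df$pct_true_of_additional <- NULL
    print.data.frame(df, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write a study report as tab-delimited text
#' @param x a `study_report`.
#' @param dir output directory (created if needed); writes
#'   `procedures.tsv` and, when present, `ladder.tsv`.
#' @export
write_study_report <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data.table::fwrite(x$procedures, file.path(dir, "procedures.tsv"), sep = "\t")
  if (!is.null(x$ladder))
    data.table::fwrite(x$ladder, file.path(dir, "ladder.tsv"), sep = "\t")
  invisible(dir)
}
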