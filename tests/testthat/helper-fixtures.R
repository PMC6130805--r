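# Small deterministic fixtures used across test files.

# genotype matrix straight from a dosage matrix (rows = samples)
toy_genotypes <- function(dosages, chrom = "1",
                          allele_a = NULL, allele_b = NULL) {
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (is.null(allele_a)) allele_a <- rep("A", m)
  if (is.null(allele_b)) allele_b <- rep("G", m)
  genotype_matrix(
    sample_ids = sprintf("s%03d", seq_len(n)),
    variants = data.frame(variant_id = paste0("rs", seq_len(m)),
                          chrom = chrom, pos = seq_len(m) * 100L,
                          allele_a = allele_a, allele_b = allele_b,
                          stringsAsFactors = FALSE),
    dosages = dosages)
}

toy_phenotypes <- function(n_case, n_control, n_relative = 0,
                           centres = "centre_1",
                           diagnosis = "schizophrenia") {
  n <- n_case + n_control + n_relative
  grp <- c(rep("case", n_case), rep("control", n_control),
           rep("relative", n_relative))
  phenotype_table(data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    group = grp,
    diagnosis = ifelse(grp == "case", diagnosis, NA_character_),
    centre = rep_len(centres, n),
    stringsAsFactors = FALSE))
}

# summary-stats table built by hand
toy_sumstats <- function(variant_id, effect_allele, other_allele,
                         odds_ratio, p_value) {
  ss <- data.frame(variant_id = variant_id, chrom = "1",
                   pos = seq_along(variant_id) * 100L,
                   effect_allele = effect_allele,
                   other_allele = other_allele,
                   odds_ratio = odds_ratio, p_value = p_value,
                   stringsAsFactors = FALSE)
  class(ss) <- c("summary_stats", "data.frame")
  ss
}

# fast, small simulation settings for unit tests
quick_params <- function(...) {
  args <- utils::modifyList(
    list(m_variants = 300L, n_discovery = 20000L, n_cases = 100L,
         n_controls = 100L, n_relatives = 50L, n_centres = 2L,
         prevalence = 0.1, fst_drift = 0.02),
    list(...))
  do.call(sim_params, args)
}

# exhaustive case-control pair-counting AUC (ties count one half)
auc_pair_oracle <- function(scores, outcome) {
  y <- as.logical(outcome)
  cs <- scores[y]
  ct <- scores[!y]
  total <- 0
  for (a in cs) total <- total + sum(a > ct) + 0.5 * sum(a == ct)
  total / (length(cs) * length(ct))
}

# loop-based multiply-accumulate PRS oracle with mean imputation
prs_loop_oracle <- function(g, w, selection) {
  idx <- w$variant_index[selection]
  wt <- w$signed_weight[selection]
  n <- length(g$sample_ids)
  fills <- vapply(idx, function(j) {
    d <- g$dosages[, j]
    2 * sum(d, na.rm = TRUE) / (2 * sum(!is.na(d)))
  }, numeric(1))
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (k in seq_along(idx)) {
      d <- g$dosages[i, idx[k]]
      if (is.na(d)) d <- fills[k]
      s <- s + d * wt[k]
    }
    out[i] <- s
  }
  out
}
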