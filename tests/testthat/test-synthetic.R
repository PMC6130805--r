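test_that("parameter validation names the offending field", {
  expect_error(sim_params(prevalence = 0), "prevalence")
  expect_error(sim_params(maf_range = c(0.4, 0.1)), "maf_range")
  expect_error(sim_params(h2_liability = 1.2), "h2_liability")
  expect_error(sim_params(causal_fraction = 0), "causal_fraction")
  expect_error(sim_params(n_cases = -1), "n_cases")
})

test_that("discovery simulation is reproducible and calibrated", {
  p <- quick_params(seed = 131)
  d1 <- simulate_discovery(p)
  d2 <- simulate_discovery(p)
  expect_identical(d1, d2)
  # null heritability: betas zero, P-values uniform
  p0 <- sim_params(m_variants = 10000L, h2_liability = 0, seed = 131)
  d0 <- simulate_discovery(p0)
  expect_true(all(d0$truth$effects$beta == 0))
  frac <- mean(d0$sumstats$p_value < 0.05)
  band <- 2.58 * sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(frac - 0.05), band)
  # noise-free limit: estimated effects converge on the truth
  pbig <- quick_params(seed = 131, n_discovery = 1e9)
  dbig <- simulate_discovery(pbig)
  causal <- dbig$truth$effects$causal
  expect_gt(cor(dbig$truth$effects$beta_hat[causal],
                dbig$truth$effects$beta[causal]), 0.99)
})

test_that("planted genetic variance and prevalence are recovered", {
  p <- sim_params(m_variants = 2000L, seed = 137)
  disc <- simulate_discovery(p)
  pop <- simulate_population(p, disc$truth, n = 4000)
  # realised genetic variance within 10% of the planted heritability
  expect_lt(abs(var(pop$genetic_value) - p$h2_liability),
            0.1 * p$h2_liability)
  # case fraction within binomial noise of the prevalence
  expect_lt(abs(mean(pop$affected) - p$prevalence),
            3.5 * sqrt(p$prevalence * (1 - p$prevalence) / 4000))
  # noise-free PRS explains ~h2 of the liability
  r2 <- summary(lm(pop$liability ~ pop$genetic_value))$r.squared
  expect_lt(abs(r2 - p$h2_liability), 0.05)
})

test_that("cohort generation is deterministic and correctly shaped", {
  p <- quick_params(seed = 139)
  truth <- simulate_discovery(p)$truth
  c1 <- simulate_cohort(p, truth)
  c2 <- simulate_cohort(p, truth)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_equal(table(c1$phenotypes$group),
               table(factor(c(rep("case", p$n_cases),
                              rep("control", p$n_controls),
                              rep("relative", p$n_relatives)))))
  expect_equal(dim(c1$genotypes), c(250L, 300L))
  # cases are affected, controls and relatives unaffected
  thr <- qnorm(1 - p$prevalence)
  s <- c1$truth$samples
  expect_true(all(s$liability[s$group == "case"] > thr))
  expect_true(all(s$liability[s$group != "case"] <= thr))
})

test_that("null heritability removes the case-control score gap", {
  set.seed(149)
  diffs <- replicate(8, {
    p <- quick_params(seed = sample.int(1e6, 1), h2_liability = 0,
                      n_relatives = 0L, screen_controls = FALSE)
    disc <- simulate_discovery(p)
    coh <- simulate_cohort(p, disc$truth)
    w <- harmonise(disc$sumstats, coh$genotypes)
    sm <- score_all_thresholds(coh$genotypes, w, seq_len(p$m_variants),
                               thresholds = 1)
    sm <- z_standardise(sm, coh$phenotypes)
    grp <- coh$phenotypes$group[match(sm$sample_ids,
                                      coh$phenotypes$sample_id)]
    mean(sm$z[grp == "case", 1]) - mean(sm$z[grp == "control", 1])
  })
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 0.05)
})

test_that("noise-free weights order cases above relatives above controls", {
  p <- sim_params(m_variants = 500L, h2_liability = 0.5, prevalence = 0.05,
                  n_cases = 250L, n_controls = 250L, n_relatives = 250L,
                  n_centres = 1L, fst_drift = 0, seed = 151)
  disc <- simulate_discovery(p)
  coh <- simulate_cohort(p, disc$truth)
  # noise-free weights: use the true liability-scale effects
  ss <- disc$sumstats
  ss$odds_ratio <- exp(disc$truth$effects$beta)
  ss$p_value <- ifelse(disc$truth$effects$causal, 1e-10, 1)
  w <- harmonise(ss, coh$genotypes)
  sm <- score_all_thresholds(coh$genotypes, w, seq_len(p$m_variants),
                             thresholds = 1)
  sm <- z_standardise(sm, coh$phenotypes)
  grp <- coh$phenotypes$group[match(sm$sample_ids, coh$phenotypes$sample_id)]
  m_case <- mean(sm$z[grp == "case", 1])
  m_rel <- mean(sm$z[grp == "relative", 1])
  m_ctrl <- mean(sm$z[grp == "control", 1])
  expect_gt(m_case, m_rel)
  expect_gt(m_rel, m_ctrl)
  expect_gt(m_rel, 0)
  expect_equal(m_ctrl, 0, tolerance = 1e-10)
})

test_that("centre drift creates PCA structure; none without drift", {
  p_drift <- quick_params(seed = 157, fst_drift = 0.05, n_centres = 2L)
  coh <- simulate_cohort(p_drift, simulate_discovery(p_drift)$truth)
  pca <- pca_genotypes(coh$genotypes, seq_len(300), k = 2)
  centre <- as.integer(factor(coh$phenotypes$centre))
  expect_gt(abs(cor(pca$components[, 1], centre)), 0.8)

  p_flat <- quick_params(seed = 157, fst_drift = 0, n_centres = 2L)
  coh0 <- simulate_cohort(p_flat, simulate_discovery(p_flat)$truth)
  pca0 <- pca_genotypes(coh0$genotypes, seq_len(300), k = 2)
  centre0 <- as.integer(factor(coh0$phenotypes$centre))
  expect_lt(abs(cor(pca0$components[, 1], centre0)), 0.4)
})

test_that("block-correlation mode plants prunable LD", {
  p <- quick_params(seed = 163, ld_block_size = 5L, ld_block_flip = 0.05,
                    h2_liability = 0.2)
  coh <- simulate_cohort(p, simulate_discovery(p)$truth)
  kept <- ld_prune(coh$genotypes,
                   qc_thresholds(ld_window = 300, ld_step = 30))
  expect_lt(length(kept), 300)
})

test_that("missingness rate is honoured", {
  p <- quick_params(seed = 167, missing_rate = 0.05)
  coh <- simulate_cohort(p, simulate_discovery(p)$truth)
  frac <- mean(is.na(coh$genotypes$dosages))
  expect_lt(abs(frac - 0.05), 0.01)
})

test_that("sibling-proband correlation at causal variants is about half", {
  # fast check at reduced scale; the acceptance suite runs the full 2000
  p <- sim_params(m_variants = 200L, h2_liability = 0.5, prevalence = 0.1,
                  n_cases = 0L, n_controls = 0L, n_relatives = 500L,
                  n_centres = 1L, fst_drift = 0, seed = 173)
  coh <- simulate_cohort(p, simulate_discovery(p)$truth)
  sib <- coh$genotypes$dosages[coh$phenotypes$group == "relative",
                               coh$truth$causal]
  pro <- coh$truth$proband_causal
  cors <- vapply(seq_len(ncol(sib)), function(j) {
    suppressWarnings(cor(sib[, j], pro[, j]))
  }, numeric(1))
  expect_lt(abs(mean(cors, na.rm = TRUE) - 0.5), 0.08)
})
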