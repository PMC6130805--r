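test_that("2x2-table logistic fit recovers the closed-form log odds ratio", {
  y <- c(rep(1, 100), rep(0, 100))
  x <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  fit <- fit_logistic(y, data.frame(exposed = x))
  slope <- fit$coefficients$estimate[fit$coefficients$term == "exposed"]
  expect_equal(slope, log((30 * 90) / (70 * 10)), tolerance = 1e-8)
  expect_true(fit$converged)
  # swapping outcome classes negates all slopes
  fit2 <- fit_logistic(1 - y, data.frame(exposed = x))
  slope2 <- fit2$coefficients$estimate[fit2$coefficients$term == "exposed"]
  expect_equal(slope2, -slope, tolerance = 1e-8)
})

test_that("null predictors give near-null coefficients", {
  set.seed(73)
  y <- rep(c(0, 1), 100)
  ps <- replicate(50, {
    x <- rnorm(200)
    fit <- fit_logistic(y, data.frame(x = x))
    fit$coefficients$p[fit$coefficients$term == "x"]
  })
  # under the null, Wald P-values are close to uniform
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("separation is flagged", {
  y <- c(rep(0, 20), rep(1, 20))
  x <- c(rnorm(20, -5), rnorm(20, 5))
  fit <- fit_logistic(y, data.frame(x = x))
  expect_false(fit$converged)
})

test_that("Nagelkerke R2 matches the two-line formula oracle", {
  # construct two nested fits and evaluate the formula independently
  set.seed(79)
  n <- 100
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.8 * x))
  full <- fit_logistic(y, data.frame(x = x))
  ref <- fit_logistic(y, NULL)
  lf <- full$log_likelihood
  lr <- ref$log_likelihood
  oracle <- (1 - exp(-2 * (lf - lr) / n)) / (1 - exp(2 * lr / n))
  expect_equal(nagelkerke_r2(full, ref), oracle, tolerance = 1e-10)
  # identical models: exactly zero improvement
  expect_equal(nagelkerke_r2(ref, ref), 0)
  # mismatched n refuses
  ref_small <- fit_logistic(y[1:50], NULL)
  expect_error(nagelkerke_r2(full, ref_small), "sample sizes")
})

test_that("near-perfect separation pushes Nagelkerke R2 towards 1", {
  set.seed(83)
  n <- 200
  x <- c(rnorm(100, -3), rnorm(100, 3))
  y <- rep(c(0, 1), each = 100)
  full <- fit_logistic(y, data.frame(x = x))
  ref <- fit_logistic(y, NULL)
  r2 <- nagelkerke_r2(full, ref)
  expect_gt(r2, 0.9)
  expect_lt(r2, 1)
})

test_that("AUC equals exhaustive pair counting, including ties", {
  # fixed toy set with ties
  s <- c(1, 2, 2, 3, 3, 3, 4, 5)
  y <- c(0, 0, 1, 0, 1, 1, 0, 1)
  expect_equal(auc(s, y), auc_pair_oracle(s, y))
  # degenerate inputs
  expect_equal(auc(rep(7, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_error(auc(1:5, rep(1, 5)), "both classes")
  # randomised instances
  set.seed(89)
  for (rep in 1:20) {
    n <- sample(4:60, 1)
    s <- sample(1:8, n, replace = TRUE)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc(s, y), auc_pair_oracle(s, y))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(97)
  s <- rnorm(80)
  y <- rbinom(80, 1, plogis(s))
  if (length(unique(y)) < 2) skip("degenerate draw")
  expect_equal(auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("Z-standardisation anchors controls of each centre at 0/1", {
  set.seed(101)
  p <- quick_params(seed = 101)
  coh <- simulate_cohort(p, simulate_discovery(p)$truth)
  w <- harmonise(simulate_discovery(p)$sumstats, coh$genotypes)
  sm <- score_all_thresholds(coh$genotypes, w, seq_len(300),
                             thresholds = c(0.05, 1))
  sm <- z_standardise(sm, coh$phenotypes)
  phen <- coh$phenotypes
  for (cen in unique(phen$centre)) {
    ctrl <- phen$sample_id[phen$group == "control" & phen$centre == cen]
    zc <- sm$z[match(ctrl, sm$sample_ids), ]
    expect_lt(max(abs(colMeans(zc))), 1e-10)
    expect_equal(unname(apply(zc, 2, sd)), c(1, 1), tolerance = 1e-10)
  }
})

test_that("two-centre Z-standardisation matches hand arithmetic", {
  raw <- matrix(c(10, 12, 14, 20, 26, 32), ncol = 1)
  sm <- structure(list(sample_ids = sprintf("s%03d", 1:6),
                       thresholds = 1, raw = raw,
                       n_snps_used = 5L, z = NULL), class = "score_matrix")
  phen <- phenotype_table(data.frame(
    sample_id = sprintf("s%03d", 1:6),
    group = c("case", "control", "control", "case", "control", "control"),
    diagnosis = c("schizophrenia", NA, NA, "schizophrenia", NA, NA),
    centre = rep(c("c1", "c2"), each = 3)))
  sm <- z_standardise(sm, phen)
  # c1 controls: mean 13, sd sqrt(2); c2 controls: mean 29, sd sqrt(18)
  expect_equal(unname(sm$z[, 1]),
               c((10 - 13) / sqrt(2), -1 / sqrt(2), 1 / sqrt(2),
                 (20 - 29) / sqrt(18), -3 / sqrt(18), 3 / sqrt(18)))
  # single-centre cohort equals global control-anchored standardisation
  phen1 <- phenotype_table(data.frame(
    sample_id = sprintf("s%03d", 1:6),
    group = c("case", "control", "control", "case", "control", "control"),
    diagnosis = c("schizophrenia", NA, NA, "schizophrenia", NA, NA),
    centre = "c1"))
  sm0 <- structure(list(sample_ids = sprintf("s%03d", 1:6),
                        thresholds = 1, raw = raw,
                        n_snps_used = 5L, z = NULL), class = "score_matrix")
  sm1 <- z_standardise(sm0, phen1)
  ctrl <- c(2, 3, 5, 6)
  expect_equal(unname(sm1$z[, 1]),
               (raw[, 1] - mean(raw[ctrl, 1])) / sd(raw[ctrl, 1]))
  # a centre without controls refuses by name
  phen_bad <- phenotype_table(data.frame(
    sample_id = sprintf("s%03d", 1:6),
    group = c("case", "case", "case", "case", "control", "control"),
    diagnosis = c(rep("schizophrenia", 4), NA, NA),
    centre = rep(c("c1", "c2"), each = 3)))
  expect_error(z_standardise(sm0, phen_bad), "c1")
})

test_that("covariate-free decile ORs equal crude 2x2 odds ratios", {
  set.seed(103)
  n <- 400
  z <- rnorm(n)
  grp <- rbinom(n, 1, plogis(z))
  ids <- sprintf("s%03d", seq_len(n))
  phen <- phenotype_table(data.frame(
    sample_id = ids, group = ifelse(grp == 1, "case", "control"),
    diagnosis = ifelse(grp == 1, "schizophrenia", NA), centre = "c1"))
  sm <- structure(list(sample_ids = ids, thresholds = 0.05,
                       raw = matrix(z, ncol = 1), n_snps_used = 10L,
                       z = matrix(z, ncol = 1)), class = "score_matrix")
  dt <- decile_analysis(sm, phen, covariates = NULL, threshold = 0.05)
  ref_case <- sum(dt$n_case[5:6])
  ref_ctrl <- sum(dt$n_comparison[5:6])
  for (d in c(1:4, 7:10)) {
    crude <- (dt$n_case[d] * ref_ctrl) / (dt$n_comparison[d] * ref_case)
    expect_equal(dt$odds_ratio[d], crude, tolerance = 1e-6)
  }
  expect_equal(dt$odds_ratio[5:6], c(1, 1))
  expect_true(all(dt$ci_low <= dt$odds_ratio + 1e-12))
  expect_true(all(dt$odds_ratio <= dt$ci_high + 1e-12))
  expect_equal(sum(dt$n_case) + sum(dt$n_comparison), n)
})

test_that("deciles are near-equal sized under combined boundaries", {
  set.seed(107)
  n <- 205
  z <- rnorm(n)
  grp <- rbinom(n, 1, 0.5)
  ids <- sprintf("s%03d", seq_len(n))
  phen <- phenotype_table(data.frame(
    sample_id = ids, group = ifelse(grp == 1, "case", "control"),
    diagnosis = ifelse(grp == 1, "schizophrenia", NA), centre = "c1"))
  sm <- structure(list(sample_ids = ids, thresholds = 0.05,
                       raw = matrix(z, ncol = 1), n_snps_used = 10L,
                       z = matrix(z, ncol = 1)), class = "score_matrix")
  dt <- decile_analysis(sm, phen, covariates = NULL, threshold = 0.05)
  sizes <- dt$n_case + dt$n_comparison
  expect_true(all(sizes %in% c(floor(n / 10), ceiling(n / 10))))
})

test_that("a zero score column is reported as uninformative", {
  set.seed(109)
  n <- 80
  ids <- sprintf("s%03d", seq_len(n))
  grp <- rep(c("case", "control"), each = n / 2)
  phen <- phenotype_table(data.frame(
    sample_id = ids, group = grp,
    diagnosis = ifelse(grp == "case", "schizophrenia", NA), centre = "c1"))
  sm <- structure(list(sample_ids = ids, thresholds = c(0.05, 1),
                       raw = cbind(rep(0, n), rnorm(n)),
                       n_snps_used = c(0L, 5L), z = NULL),
                  class = "score_matrix")
  colnames(sm$raw) <- c("pt_0.05", "pt_1")
  ev <- evaluate_contrast(sm, phen, pcs = NULL)
  expect_equal(ev$assoc_p[1], 1)
  expect_equal(ev$nagelkerke_r2[1], 0)
  expect_equal(ev$auc_full[1], ev$auc_reference[1])
})

test_that("exchangeable centres barely change the variance explained", {
  set.seed(127)
  p <- quick_params(seed = 129, fst_drift = 0, n_cases = 150L,
                    n_controls = 150L, n_relatives = 0L)
  disc <- simulate_discovery(p)
  coh <- simulate_cohort(p, disc$truth)
  w <- harmonise(disc$sumstats, coh$genotypes)
  sm <- score_all_thresholds(coh$genotypes, w, seq_len(300),
                             thresholds = c(0.05, 1))
  sm <- z_standardise(sm, coh$phenotypes)
  with_centre <- evaluate_contrast(sm, coh$phenotypes, pcs = NULL)
  # collapsing the (exchangeable, drift-free) centres drops the covariate
  phen_one <- coh$phenotypes
  phen_one$centre <- "all"
  sm_one <- z_standardise(
    score_all_thresholds(coh$genotypes, w, seq_len(300),
                         thresholds = c(0.05, 1)), phen_one)
  without_centre <- evaluate_contrast(sm_one, phen_one, pcs = NULL)
  expect_lt(max(abs(with_centre$nagelkerke_r2 -
                      without_centre$nagelkerke_r2)), 0.01)
})

test_that("Nagelkerke R2 is invariant to centre relabelling and PRS scaling", {
  set.seed(113)
  p <- quick_params(seed = 113)
  disc <- simulate_discovery(p)
  coh <- simulate_cohort(p, disc$truth)
  w <- harmonise(disc$sumstats, coh$genotypes)
  sm <- score_all_thresholds(coh$genotypes, w, seq_len(300),
                             thresholds = c(0.05, 1))
  sm <- z_standardise(sm, coh$phenotypes)
  ev1 <- evaluate_contrast(sm, coh$phenotypes, pcs = NULL)
  # affine rescaling of the score column
  sm2 <- sm
  sm2$z <- sm$z * 3.7 + 2
  ev2 <- evaluate_contrast(sm2, coh$phenotypes, pcs = NULL)
  expect_equal(ev2$nagelkerke_r2, ev1$nagelkerke_r2, tolerance = 1e-6)
  # permuting centre labels
  phen3 <- coh$phenotypes
  phen3$centre <- chartr("12", "21", phen3$centre)
  ev3 <- evaluate_contrast(sm, phen3, pcs = NULL)
  expect_equal(ev3$nagelkerke_r2, ev1$nagelkerke_r2, tolerance = 1e-6)
})
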