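#' Maximum-likelihood logistic regression fit
#'
#' Fits a binomial GLM (logit link, intercept always included) by iteratively
#' reweighted least squares, relative tolerance 1e-8, at most 100 iterations.
#' Fits that fail to converge, or show complete/quasi-complete separation
#' (fitted probabilities at the 0/1 boundary), are flagged; downstream
#' metrics refuse flagged fits.
#'
#' @param outcome binary vector (0/1 or logical); both classes required.
#' @param predictors numeric matrix or data.frame of predictors, or `NULL`
#'   for an intercept-only model. Factors are expanded to indicators.
#' @return List of class `logistic_fit`: `coefficients` (data.frame with
#'   `term`, `estimate`, `se`, `z`, `p`), `log_likelihood`, `n`, `converged`,
#'   `fitted` (probabilities).
#' @export
fit_logistic <- function(outcome, predictors = NULL) {
  y <- as.integer(outcome)
  if (any(is.na(y)) || !all(y %in% c(0L, 1L)))
    stop("outcome must be binary with no missing values")
  if (length(unique(y)) < 2) stop("outcome must contain both classes")
  if (is.null(predictors)) {
    dat <- data.frame(.y = y)
  } else {
    dat <- as.data.frame(predictors)
    if (nrow(dat) != length(y)) stop("predictor rows must match outcome length")
    dat$.y <- y
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      z = sm[, 3], p = sm[, 4], row.names = NULL)
  structure(list(coefficients = coefs,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 n = length(y),
                 converged = fit$converged && !separated,
                 fitted = as.numeric(stats::fitted(fit))),
            class = "logistic_fit")
}

#' Nagelkerke pseudo-R-squared of a nested model comparison
#'
#' Cox-Snell R^2 from the likelihood-ratio of the full over the reference
#' model, rescaled by its maximum attainable value:
#' `R2_CS = 1 - exp(-2 (l_full - l_ref) / n)` divided by
#' `1 - exp(2 l_ref / n)`.
#'
#' @param full,reference [fit_logistic()] results on identical samples; the
#'   reference model must be nested in the full model.
#' @return Value in [0, 1].
#' @export
nagelkerke_r2 <- function(full, reference) {
  if (full$n != reference$n)
    stop("full and reference fits are on different sample sizes")
  lf <- full$log_likelihood
  lr <- reference$log_likelihood
  if (lf < lr - 1e-8)
    stop("full-model likelihood below reference: broken fit")
  n <- full$n
  r2_cs <- 1 - exp(-2 * (lf - lr) / n)
  r2_cs / (1 - exp(2 * lr / n))
}

#' Rank-based AUC
#'
#' Mann-Whitney area under the ROC curve: the probability that a random
#' case outranks a random control, with ties counted one half. Exact via
#' midranks; applicable to raw scores or fitted probabilities.
#'
#' @param scores numeric vector.
#' @param outcome binary vector; 1/TRUE = case.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, outcome) {
  y <- as.logical(outcome)
  if (any(is.na(y)) || any(is.na(scores))) stop("missing values in AUC input")
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Z-standardise scores against the controls of each centre
#'
#' Within each centre, all individuals' raw scores are transformed to
#' `(raw - mean_controls) / sd_controls`, using the sample (n-1) standard
#' deviation of that centre's controls, separately per threshold. By
#' construction each centre's controls then have mean 0 and s.d. 1.
#'
#' A score column that is constant across the whole cohort (e.g. no variant
#' passed its threshold) carries no information and is set to zero with a
#' warning; a variable column whose control scores are degenerate within a
#' centre is refused.
#'
#' @param scores a `score_matrix` (see [score_all_thresholds()]).
#' @param phen a `phenotype_table` covering all scored samples.
#' @return The `score_matrix` with the `z` field filled.
#' @export
z_standardise <- function(scores, phen) {
  idx <- match(scores$sample_ids, phen$sample_id)
  if (anyNA(idx)) stop("scored samples missing from phenotype table")
  centre <- phen$centre[idx]
  group <- phen$group[idx]
  z <- scores$raw
  constant <- apply(scores$raw, 2, stats::sd) == 0
  if (any(constant)) {
    warning("constant score column(s) left at zero: ",
            paste(colnames(scores$raw)[constant], collapse = ", "))
    z[, constant] <- 0
  }
  live <- which(!constant)
  for (cen in unique(centre)) {
    in_cen <- centre == cen
    ctrl <- in_cen & group == "control"
    if (sum(ctrl) < 2)
      stop("centre '", cen, "' has fewer than 2 controls")
    mu <- colMeans(scores$raw[ctrl, live, drop = FALSE])
    sdv <- apply(scores$raw[ctrl, live, drop = FALSE], 2, stats::sd)
    if (any(sdv == 0))
      stop("degenerate control score variance in centre '", cen, "'")
    z[in_cen, live] <-
      sweep(sweep(scores$raw[in_cen, live, drop = FALSE], 2, mu, "-"),
            2, sdv, "/")
  }
  scores$z <- z
  scores
}

# deciles 1..10 by score rank, ties broken by stable sample order; or by
# control-anchored quantile boundaries
assign_deciles <- function(z, is_ref_pool = NULL,
                           boundaries = c("combined", "controls")) {
  boundaries <- match.arg(boundaries)
  n <- length(z)
  if (boundaries == "combined") {
    r <- rank(z, ties.method = "first")
    as.integer(ceiling(10 * r / n))
  } else {
    q <- stats::quantile(z[is_ref_pool], probs = seq(0.1, 0.9, by = 0.1),
                         names = FALSE)
    findInterval(z, q, left.open = TRUE) + 1L
  }
}

#' Decile odds-ratio stratification
#'
#' Allocates the combined two-group sample to deciles of the Z-standardised
#' score (decile 1 lowest, 10 highest), merges the central deciles 5 and 6
#' as reference, and estimates per-decile odds ratios for affected status by
#' logistic regression on decile indicator variables (plus any covariates),
#' with Wald 95% confidence intervals. Per-decile case and comparison counts
#' are included. Without covariates the estimates equal the crude 2x2 odds
#' ratios against the merged reference.
#'
#' @param scores a `score_matrix` with `z` filled (see [z_standardise()]).
#' @param phen a `phenotype_table`.
#' @param covariates optional data.frame/matrix of covariates with rownames
#'   (or a `sample_id` column) identifying samples; `NULL` for crude ORs.
#' @param contrast contrast label understood by [build_contrast()]
#'   (default `"all-cases-vs-controls"`).
#' @param threshold which score threshold to use (default 0.05).
#' @param boundaries `"combined"` (default): decile boundaries from the
#'   pooled two-group sample; `"controls"`: anchored on the comparison group.
#' @return Data.frame of class `decile_table` with columns `decile`,
#'   `n_case`, `n_comparison`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `reference`. The merged reference deciles (5, 6) carry OR = 1. Empty
#'   deciles report `NA` odds ratios.
#' @export
decile_analysis <- function(scores, phen, covariates = NULL,
                            contrast = "all-cases-vs-controls",
                            threshold = 0.05,
                            boundaries = c("combined", "controls")) {
  boundaries <- match.arg(boundaries)
  if (is.null(scores$z)) stop("scores must be Z-standardised first")
  grp <- build_contrast(phen, contrast)
  ids <- c(grp$group1, grp$group2)
  if (length(ids) < 20) stop("need >= 20 samples for decile analysis")
  col <- match_threshold_col(scores, threshold)
  z <- scores$z[match(ids, scores$sample_ids), col]
  if (anyNA(z)) stop("contrast samples missing from score matrix")
  y <- as.integer(ids %in% grp$group1)
  dec <- assign_deciles(z, is_ref_pool = y == 0, boundaries = boundaries)
  dec_f <- factor(ifelse(dec %in% c(5L, 6L), "ref", paste0("d", dec)),
                  levels = c("ref", paste0("d", c(1:4, 7:10))))
  counts <- t(vapply(1:10, function(d)
    c(sum(y == 1 & dec == d), sum(y == 0 & dec == d)), numeric(2)))
  preds <- data.frame(decile = dec_f)
  if (!is.null(covariates)) {
    cov_df <- as.data.frame(covariates)
    if ("sample_id" %in% names(cov_df)) {
      rownames(cov_df) <- cov_df$sample_id
      cov_df$sample_id <- NULL
    }
    cov_idx <- match(ids, rownames(cov_df))
    if (anyNA(cov_idx)) stop("contrast samples missing from covariates")
    preds <- cbind(preds, cov_df[cov_idx, , drop = FALSE])
  }
  present <- levels(dec_f)[levels(dec_f) %in% unique(as.character(dec_f))]
  preds$decile <- factor(as.character(dec_f), levels = present)
  fit <- fit_logistic(y, preds)
  est <- fit$coefficients
  out <- data.frame(decile = 1:10, n_case = counts[, 1],
                    n_comparison = counts[, 2],
                    odds_ratio = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, reference = FALSE)
  out$reference[c(5, 6)] <- TRUE
  out$odds_ratio[c(5, 6)] <- 1
  out$ci_low[c(5, 6)] <- 1
  out$ci_high[c(5, 6)] <- 1
  for (d in c(1:4, 7:10)) {
    # a zero case or comparison cell leaves the decile OR undefined
    if (counts[d, 1] == 0 || counts[d, 2] == 0) next
    term <- paste0("deciled", d)
    row <- est[est$term == term, ]
    if (nrow(row) == 1 && is.finite(row$estimate)) {
      out$odds_ratio[d] <- exp(row$estimate)
      out$ci_low[d] <- exp(row$estimate - 1.96 * row$se)
      out$ci_high[d] <- exp(row$estimate + 1.96 * row$se)
    }
  }
  attr(out, "fit") <- fit
  class(out) <- c("decile_table", "data.frame")
  out
}

match_threshold_col <- function(scores, threshold) {
  col <- which(abs(scores$thresholds - threshold) < 1e-12)
  if (length(col) != 1)
    stop("threshold ", threshold, " not present in score matrix")
  col
}

#' Evaluate a score against a two-group contrast
#'
#' Per P-value threshold, fits the full logistic model (score plus the first
#' k ancestry principal components plus centre-of-ascertainment indicators)
#' and the reference model (covariates only) for the requested contrast, and
#' reports the score coefficient's Wald P, the Nagelkerke pseudo-R-squared of
#' full over reference, and the in-sample AUC of both models' fitted
#' probabilities. A degenerate (constant) score column is dropped from the
#' model and reported with P = 1, R^2 = 0.
#'
#' @param scores a `score_matrix` (Z-standardised scores are used when
#'   present, raw scores otherwise).
#' @param phen a `phenotype_table`.
#' @param pcs optional `prs_pca` object or numeric matrix of per-sample
#'   components (rownames = sample ids) used as covariates.
#' @param contrast contrast label understood by [build_contrast()].
#' @return Data.frame of class `prs_eval`: one row per threshold with
#'   `threshold`, `n_snps_used`, `assoc_p`, `nagelkerke_r2`, `auc_full`,
#'   `auc_reference`, `n_group1`, `n_group2`.
#' @export
evaluate_contrast <- function(scores, phen, pcs = NULL,
                              contrast = "all-cases-vs-controls") {
  grp <- build_contrast(phen, contrast)
  ids <- c(grp$group1, grp$group2)
  y <- as.integer(ids %in% grp$group1)
  sidx <- match(ids, scores$sample_ids)
  if (anyNA(sidx)) stop("contrast samples missing from score matrix")
  S <- if (!is.null(scores$z)) scores$z else scores$raw
  pidx <- match(ids, phen$sample_id)
  covs <- data.frame(row.names = seq_along(ids))
  if (!is.null(pcs)) {
    pc_mat <- if (inherits(pcs, "prs_pca")) pcs$components else as.matrix(pcs)
    cidx <- match(ids, rownames(pc_mat))
    if (anyNA(cidx)) stop("contrast samples missing from principal components")
    covs <- cbind(covs, as.data.frame(pc_mat[cidx, , drop = FALSE]))
  }
  centre <- phen$centre[pidx]
  if (length(unique(centre)) > 1)
    covs$centre <- factor(centre)  # first centre = reference level
  have_covs <- ncol(covs) > 0
  ref_fit <- fit_logistic(y, if (have_covs) covs else NULL)
  out <- data.frame(threshold = scores$thresholds,
                    n_snps_used = scores$n_snps_used,
                    assoc_p = NA_real_, nagelkerke_r2 = NA_real_,
                    auc_full = NA_real_, auc_reference = NA_real_,
                    n_group1 = sum(y), n_group2 = sum(1 - y))
  for (t in seq_along(scores$thresholds)) {
    prs <- S[sidx, t]
    if (stats::sd(prs) == 0) {
      out$assoc_p[t] <- 1
      out$nagelkerke_r2[t] <- 0
      out$auc_full[t] <- out$auc_reference[t] <- auc(ref_fit$fitted, y)
      next
    }
    full_fit <- fit_logistic(y, cbind(prs = prs, covs))
    if (!full_fit$converged || !ref_fit$converged)
      warning("flagged (non-converged or separated) fit at threshold ",
              scores$thresholds[t])
    prs_row <- full_fit$coefficients[full_fit$coefficients$term == "prs", ]
    out$assoc_p[t] <- prs_row$p
    out$nagelkerke_r2[t] <- nagelkerke_r2(full_fit, ref_fit)
    out$auc_full[t] <- auc(full_fit$fitted, y)
    out$auc_reference[t] <- auc(ref_fit$fitted, y)
  }
  class(out) <- c("prs_eval", "data.frame")
  out
}

#' Write an evaluation table as TSV
#' @param eval_result a `prs_eval` data.frame.
#' @param path output path.
#' @export
write_eval <- function(eval_result, path) {
  utils::write.table(as.data.frame(eval_result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a decile table as TSV
#' @param decile_table a `decile_table` data.frame.
#' @param path output path.
#' @export
write_deciles <- function(decile_table, path) {
  utils::write.table(as.data.frame(decile_table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
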