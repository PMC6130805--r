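#' Default P-value thresholds for score construction
#'
#' The ten discovery-significance thresholds at which variants are selected
#' into the score.
#'
#' @return Increasing numeric vector of length ten.
#' @export
default_thresholds <- function() {
  c(5e-08, 1e-06, 1e-04, 1e-03, 0.01, 0.05, 0.1, 0.2, 0.5, 1)
}

threshold_labels <- function(thresholds) paste0("pt_", as.character(thresholds))

#' Select score variants at one P-value threshold
#'
#' A variant enters the score when it survived LD pruning and its discovery
#' P-value passes the threshold (inclusive by default: p <= p_t).
#'
#' @param w a `harmonised_weights` table (see [harmonise()]).
#' @param pruned_indices variant indices retained by [ld_prune()].
#' @param p_t threshold in (0, 1].
#' @param inclusive use `p <= p_t` (default) rather than `p < p_t`.
#' @return Integer vector of selected rows of `w` (possibly empty).
#' @export
select_at_threshold <- function(w, pruned_indices, p_t, inclusive = TRUE) {
  stopifnot(p_t > 0, p_t <= 1)
  pass <- if (inclusive) w$p_value <= p_t else w$p_value < p_t
  which(pass & w$variant_index %in% pruned_indices)
}

#' Compute polygenic risk scores for one variant selection
#'
#' Per individual, the dosage at each selected variant is multiplied by its
#' signed log-odds-ratio weight and the products summed. Missing calls are
#' mean-imputed as twice the target allele frequency (configurable to
#' averaging over observed calls only).
#'
#' @param g a [genotype_matrix()].
#' @param w a `harmonised_weights` table.
#' @param selection rows of `w` to use, from [select_at_threshold()].
#' @param missing_policy `"mean_impute"` (default) or `"observed"`
#'   (average over the observed calls: each individual's sum over observed
#'   terms is rescaled by the number selected over the number observed).
#' @return Numeric score vector aligned with `g$sample_ids`.
#' @export
compute_prs <- function(g, w, selection,
                        missing_policy = c("mean_impute", "observed")) {
  missing_policy <- match.arg(missing_policy)
  n <- length(g$sample_ids)
  if (length(selection) == 0) {
    warning("empty variant selection: scores are all zero")
    return(stats::setNames(rep(0, n), g$sample_ids))
  }
  D <- g$dosages[, w$variant_index[selection], drop = FALSE]
  storage.mode(D) <- "double"
  rescale <- rep(1, n)
  if (anyNA(D)) {
    if (missing_policy == "mean_impute") {
      f <- col_freqs(D)
      mu <- rep(2 * f, each = n)
      D[is.na(D)] <- mu[is.na(D)]
    } else {
      n_obs <- rowSums(!is.na(D))
      rescale <- ifelse(n_obs > 0, ncol(D) / n_obs, 0)
      D[is.na(D)] <- 0
    }
  }
  scores <- drop(D %*% w$signed_weight[selection]) * rescale
  stats::setNames(scores, g$sample_ids)
}

#' Score all thresholds
#'
#' Builds the full score matrix: one raw-score column per P-value threshold,
#' each over the LD-pruned variants passing that threshold, plus the number
#' of variants used per threshold.
#'
#' @param g a [genotype_matrix()].
#' @param w a `harmonised_weights` table.
#' @param pruned_indices variant indices retained by [ld_prune()].
#' @param thresholds increasing numeric vector in (0, 1]
#'   (default [default_thresholds()]).
#' @param inclusive threshold comparison, see [select_at_threshold()].
#' @return List of class `score_matrix`: `sample_ids`, `thresholds`,
#'   `raw` (n x n_thresholds matrix, columns `pt_<threshold>`),
#'   `n_snps_used`, and `z` (`NULL` until [z_standardise()] fills it).
#' @export
score_all_thresholds <- function(g, w, pruned_indices,
                                 thresholds = default_thresholds(),
                                 inclusive = TRUE) {
  stopifnot(all(diff(thresholds) > 0), all(thresholds > 0),
            all(thresholds <= 1))
  n <- length(g$sample_ids)
  raw <- matrix(0, n, length(thresholds),
                dimnames = list(g$sample_ids, threshold_labels(thresholds)))
  n_used <- integer(length(thresholds))
  for (t in seq_along(thresholds)) {
    sel <- select_at_threshold(w, pruned_indices, thresholds[t], inclusive)
    n_used[t] <- length(sel)
    if (length(sel))
      raw[, t] <- compute_prs(g, w, sel)
    else
      warning("no variants pass p_t = ", thresholds[t])
  }
  structure(list(sample_ids = g$sample_ids, thresholds = thresholds,
                 raw = raw, n_snps_used = n_used, z = NULL),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d samples x %d thresholds (z %s)\n",
              length(x$sample_ids), length(x$thresholds),
              if (is.null(x$z)) "unset" else "set"))
  print(stats::setNames(x$n_snps_used, threshold_labels(x$thresholds)))
  invisible(x)
}

#' Write scores as TSV
#'
#' One row per sample; raw (and, when present, Z-standardised) score columns
#' per threshold. The per-threshold variant counts are written as `#`-prefixed
#' header metadata.
#'
#' @param scores a `score_matrix`.
#' @param path output path.
#' @export
write_scores <- function(scores, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# n_snps_used\t",
                    paste(threshold_labels(scores$thresholds),
                          scores$n_snps_used, sep = "=", collapse = "\t")),
             con)
  out <- data.frame(sample_id = scores$sample_ids, scores$raw,
                    check.names = FALSE)
  if (!is.null(scores$z)) {
    z <- scores$z
    colnames(z) <- paste0("z_", colnames(z))
    out <- cbind(out, z)
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
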