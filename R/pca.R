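#' Ancestry principal components from genotypes
#'
#' Classic ancestry PCA: each variant column is mean-imputed for missing
#' calls, centred by twice its allele frequency and scaled by
#' `sqrt(2 f (1 - f))` (the binomial standard deviation), then the top-k left
#' singular vectors of the standardised matrix are returned as per-sample
#' components. Monomorphic variants carry no information and are dropped.
#' The sign of each component is fixed so that its largest-magnitude entry
#' is positive.
#'
#' @param g a [genotype_matrix()].
#' @param pruned_indices variant indices to use (typically the output of
#'   [apply_qc()] followed by [ld_prune()]).
#' @param k number of components (default 3, the usual number of ancestry
#'   covariate vectors).
#' @return List of class `prs_pca` with `components` (n_samples x k matrix,
#'   columns `PC1..PCk`) and `eigenvalues` (eigenvalues of the sample-by-
#'   sample covariance of the standardised genotypes, non-increasing).
#' @export
pca_genotypes <- function(g, pruned_indices = seq_len(ncol(g$dosages)),
                          k = 3L) {
  if (length(pruned_indices) == 0) stop("pruned_indices is empty")
  n <- length(g$sample_ids)
  if (k > min(n - 1L, length(pruned_indices)))
    stop("k exceeds the available rank")
  X <- g$dosages[, pruned_indices, drop = FALSE]
  storage.mode(X) <- "double"
  f <- col_freqs(X)
  poly <- !is.na(f) & f > 0 & f < 1
  X <- X[, poly, drop = FALSE]
  f <- f[poly]
  if (ncol(X) < k) stop("k exceeds the available rank")
  if (anyNA(X)) {
    mu <- rep(2 * f, each = n)
    X[is.na(X)] <- mu[is.na(X)]
  }
  X <- sweep(X, 2, 2 * f, "-")
  X <- sweep(X, 2, sqrt(2 * f * (1 - f)), "/")
  sv <- svd(X, nu = k, nv = 0)
  comp <- sv$u
  for (j in seq_len(k)) {
    if (comp[which.max(abs(comp[, j])), j] < 0) comp[, j] <- -comp[, j]
  }
  dimnames(comp) <- list(g$sample_ids, paste0("PC", seq_len(k)))
  structure(list(components = comp,
                 eigenvalues = (sv$d[seq_len(k)]^2) / ncol(X)),
            class = "prs_pca")
}

#' Write principal components as TSV
#' @param pca a `prs_pca` object.
#' @param path output path.
#' @export
write_pca <- function(pca, path) {
  out <- data.frame(sample_id = rownames(pca$components),
                    pca$components, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
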