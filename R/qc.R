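#' Variant QC thresholds
#'
#' Defaults follow the population-structure SNP selection commonly used for
#' ancestry PCA on chip data: minor allele frequency >= 10%, Hardy-Weinberg
#' equilibrium P >= 1e-3, and windowed LD pruning so that no pair of SNPs
#' within a 1500-SNP window has r^2 >= 0.2 (window shifted by 150 SNPs).
#'
#' @param maf_min minimum minor allele frequency, in [0, 0.5].
#' @param hwe_p_min minimum HWE goodness-of-fit P-value, in (0, 1).
#' @param ld_r2_max maximum tolerated squared dosage correlation, in (0, 1].
#' @param ld_window window size in variants.
#' @param ld_step window shift in variants; must not exceed `ld_window`.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.10, hwe_p_min = 1e-3,
                          ld_r2_max = 0.2, ld_window = 1500L,
                          ld_step = 150L) {
  stopifnot(maf_min >= 0, maf_min <= 0.5,
            hwe_p_min > 0, hwe_p_min < 1,
            ld_r2_max > 0, ld_r2_max <= 1,
            ld_window >= 1, ld_step >= 1)
  if (ld_step > ld_window) stop("ld_step must be <= ld_window")
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 ld_r2_max = ld_r2_max, ld_window = as.integer(ld_window),
                 ld_step = as.integer(ld_step)),
            class = "qc_thresholds")
}

#' Allele-a frequency of one variant
#'
#' Frequency of `allele_a` among non-missing calls; the minor allele
#' frequency is `min(f, 1 - f)`.
#'
#' @param g a [genotype_matrix()].
#' @param variant variant index (column of `g`).
#' @return Frequency in [0, 1].
#' @export
allele_frequency <- function(g, variant) {
  d <- g$dosages[, variant]
  d <- d[!is.na(d)]
  if (length(d) == 0) stop("variant ", variant, " has no non-missing calls")
  sum(d) / (2 * length(d))
}

# column-wise allele_a frequencies (NA-aware, vectorised)
col_freqs <- function(dosages) {
  nn <- colSums(!is.na(dosages))
  s <- colSums(dosages, na.rm = TRUE)
  ifelse(nn > 0, s / (2 * nn), NA_real_)
}

#' Hardy-Weinberg equilibrium chi-square test for one variant
#'
#' 1-df goodness-of-fit chi-square comparing observed genotype counts to the
#' p^2, 2pq, q^2 expectations at the sample allele frequency. Monomorphic
#' variants have no testable deviation and return P = 1.
#'
#' @param g a [genotype_matrix()].
#' @param variant variant index.
#' @return P-value.
#' @export
hwe_test <- function(g, variant) {
  d <- g$dosages[, variant]
  d <- d[!is.na(d)]
  if (length(d) < 2) stop("need >= 2 non-missing calls for HWE test")
  n <- length(d)
  obs <- c(sum(d == 0), sum(d == 1), sum(d == 2))
  p <- sum(d) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi <- sum((obs - expd)^2 / expd)
  stats::pchisq(chi, df = 1, lower.tail = FALSE)
}

#' MAF and HWE variant filters
#'
#' @param g a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return Integer vector of surviving variant indices, with attribute
#'   `counts` giving per-filter removal counts
#'   (`n_removed_maf`, `n_removed_hwe`).
#' @export
apply_qc <- function(g, thresholds = qc_thresholds()) {
  f <- col_freqs(g$dosages)
  maf <- pmin(f, 1 - f)
  pass_maf <- !is.na(maf) & maf >= thresholds$maf_min
  hwe_p <- vapply(seq_len(ncol(g$dosages)), function(j) {
    d <- g$dosages[, j]
    if (sum(!is.na(d)) < 2) return(NA_real_)
    hwe_test(g, j)
  }, numeric(1))
  pass_hwe <- !is.na(hwe_p) & hwe_p >= thresholds$hwe_p_min
  keep <- which(pass_maf & pass_hwe)
  attr(keep, "counts") <- c(n_input = ncol(g$dosages),
                            n_removed_maf = sum(!pass_maf),
                            n_removed_hwe = sum(pass_maf & !pass_hwe),
                            n_retained = length(keep))
  keep
}

# squared Pearson correlation matrix of dosage columns; pairwise-complete
# when missing calls are present; zero-variance overlaps give r2 = 0
r2_matrix <- function(dosages) {
  if (anyNA(dosages)) {
    r <- suppressWarnings(stats::cor(dosages, use = "pairwise.complete.obs"))
  } else {
    sds <- apply(dosages, 2, stats::sd)
    if (any(sds == 0)) {
      r <- suppressWarnings(stats::cor(dosages))
    } else {
      x <- scale(dosages)
      r <- crossprod(x) / (nrow(dosages) - 1)
    }
  }
  r[is.na(r)] <- 0
  r * r
}

#' Windowed greedy LD pruning
#'
#' Slides a window of `ld_window` variants along the (chrom, pos)-sorted
#' variant list, advancing by `ld_step`. Within each window every pair of
#' still-retained variants with squared dosage correlation at or above
#' `ld_r2_max` loses one member: the variant with the lower minor allele
#' frequency (ties: the later one in file order). Deterministic given the
#' input order; the retained set contains no within-window pair at or above
#' the threshold.
#'
#' @param g a [genotype_matrix()] with variants sorted by chrom then pos.
#' @param thresholds a [qc_thresholds()].
#' @param variant_indices optional subset of variant indices to prune
#'   (default: all variants).
#' @return Integer vector of retained variant indices (subset of
#'   `variant_indices`, in input order).
#' @export
ld_prune <- function(g, thresholds = qc_thresholds(),
                     variant_indices = NULL) {
  if (is.null(variant_indices)) variant_indices <- seq_len(ncol(g$dosages))
  m <- length(variant_indices)
  if (m == 0) return(integer(0))
  f <- col_freqs(g$dosages[, variant_indices, drop = FALSE])
  maf <- pmin(f, 1 - f)
  maf[is.na(maf)] <- 0
  retained <- rep(TRUE, m)
  w <- min(thresholds$ld_window, m)
  starts <- seq(1L, m, by = thresholds$ld_step)
  for (start in starts) {
    end <- min(start + w - 1L, m)
    loc <- seq(start, end)
    loc <- loc[retained[loc]]
    if (length(loc) < 2) {
      if (end == m) break else next
    }
    r2 <- r2_matrix(g$dosages[, variant_indices[loc], drop = FALSE])
    k <- length(loc)
    alive <- rep(TRUE, k)
    viol <- which(r2 >= thresholds$ld_r2_max & upper.tri(r2), arr.ind = TRUE)
    if (nrow(viol)) {
      viol <- viol[order(viol[, 1], viol[, 2]), , drop = FALSE]
      for (p in seq_len(nrow(viol))) {
        a <- viol[p, 1]; b <- viol[p, 2]
        if (!alive[a] || !alive[b]) next
        ia <- loc[a]; ib <- loc[b]
        # drop the lower-MAF member; tie -> the later one in file order
        alive[if (maf[ia] < maf[ib]) a else b] <- FALSE
      }
    }
    retained[loc[!alive]] <- FALSE
    if (end == m) break  # later windows are subsets of this one
  }
  variant_indices[retained]
}
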