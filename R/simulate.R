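#' Simulation parameters for the synthetic study
#'
#' Defaults describe the emulated study design: a discovery GWAS of 50 000
#' individuals providing noisy log-OR weights for 2000 variants (half of
#' them causal, a highly polygenic architecture at reduced scale),
#' and a three-centre target cohort of 600 cases ascertained as affected
#' under an additive liability-threshold model with 40% liability-scale
#' heritability and 1% population prevalence, 300 screened controls (no
#' personal or family history) and 300 unaffected full siblings of affected
#' probands. Mild allele-frequency drift between centres (Balding-Nichols,
#' Fst 0.01) gives the cohort PCA-detectable structure.
#'
#' @param m_variants number of variants.
#' @param maf_range allele-frequency range (low, high) for the base
#'   population, within (0, 0.5).
#' @param h2_liability liability-scale heritability in [0, 1].
#' @param prevalence population prevalence in (0, 1).
#' @param causal_fraction fraction of variants with non-zero effect, (0, 1].
#' @param n_discovery discovery GWAS sample size.
#' @param n_cases,n_controls,n_relatives target cohort group sizes.
#' @param n_centres number of centres of ascertainment.
#' @param fst_drift between-centre drift variance multiplier (Fst-like),
#'   >= 0; 0 disables structure.
#' @param screen_controls require controls and their simulated first-degree
#'   family (two parents, one sibling) to be unaffected.
#' @param missing_rate fraction of genotype calls set missing, [0, 1).
#' @param ld_block_size when > 1, consecutive non-causal variants are
#'   generated in correlated blocks of this size (to exercise LD pruning);
#'   1 keeps all variants in linkage equilibrium.
#' @param ld_block_flip per-call probability that a block member's call is
#'   re-drawn rather than copied (controls within-block r^2).
#' @param retry_cap rejection-sampling cap per family / per needed sample.
#' @param seed integer seed; every draw derives from it.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(m_variants = 2000L, maf_range = c(0.05, 0.5),
                       h2_liability = 0.4, prevalence = 0.01,
                       causal_fraction = 0.5, n_discovery = 50000L,
                       n_cases = 600L, n_controls = 300L,
                       n_relatives = 300L, n_centres = 3L,
                       fst_drift = 0.01, screen_controls = TRUE,
                       missing_rate = 0, ld_block_size = 1L,
                       ld_block_flip = 0.1, retry_cap = 1000L,
                       seed = 1L) {
  p <- list(m_variants = as.integer(m_variants), maf_range = maf_range,
            h2_liability = h2_liability, prevalence = prevalence,
            causal_fraction = causal_fraction,
            n_discovery = as.integer(n_discovery),
            n_cases = as.integer(n_cases),
            n_controls = as.integer(n_controls),
            n_relatives = as.integer(n_relatives),
            n_centres = as.integer(n_centres), fst_drift = fst_drift,
            screen_controls = isTRUE(screen_controls),
            missing_rate = missing_rate,
            ld_block_size = as.integer(ld_block_size),
            ld_block_flip = ld_block_flip,
            retry_cap = as.integer(retry_cap), seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  fail <- function(field) stop("invalid sim_params field: ", field)
  if (p$m_variants < 1) fail("m_variants")
  if (length(p$maf_range) != 2 || p$maf_range[1] <= 0 ||
      p$maf_range[2] > 0.5 || p$maf_range[1] > p$maf_range[2])
    fail("maf_range")
  if (p$h2_liability < 0 || p$h2_liability > 1) fail("h2_liability")
  if (p$prevalence <= 0 || p$prevalence >= 1) fail("prevalence")
  if (p$causal_fraction <= 0 || p$causal_fraction > 1) fail("causal_fraction")
  if (p$n_discovery < 1) fail("n_discovery")
  if (p$n_cases < 0) fail("n_cases")
  if (p$n_controls < 0) fail("n_controls")
  if (p$n_relatives < 0) fail("n_relatives")
  if (p$n_centres < 1) fail("n_centres")
  if (p$fst_drift < 0) fail("fst_drift")
  if (p$missing_rate < 0 || p$missing_rate >= 1) fail("missing_rate")
  if (p$ld_block_size < 1) fail("ld_block_size")
  if (p$ld_block_flip < 0 || p$ld_block_flip > 1) fail("ld_block_flip")
  if (p$retry_cap < 1) fail("retry_cap")
  invisible(p)
}

# non-palindromic, non-identical ordered allele pairs
ALLELE_PAIRS <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                      c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))

#' Simulate a discovery GWAS
#'
#' Draws per-variant allele frequencies uniformly over `maf_range`; causal
#' liability-scale effects are normal with variance
#' `h2 / (m_causal * 2 f (1 - f))` so the planted genetic variance equals
#' `h2_liability`; the estimated effect adds GWAS sampling noise with
#' variance `1 / (2 f (1 - f) n_discovery)`. Reported odds ratios are
#' `exp(beta_hat)` (a small-effect approximation to a logistic GWAS) with
#' two-sided normal-test P-values. Fully reproducible from the seed.
#'
#' @param params a [sim_params()] object.
#' @return List with `sumstats` (a `summary_stats` table) and `truth`
#'   (class `sim_truth`: per-variant frequencies, true and estimated
#'   effects, causal indicator).
#' @export
simulate_discovery <- function(params) {
  validate_sim_params(params)
  set.seed(params$seed)
  m <- params$m_variants
  f <- stats::runif(m, params$maf_range[1], params$maf_range[2])
  m_causal <- max(1L, round(params$causal_fraction * m))
  causal <- sort(sample.int(m, m_causal))
  beta <- numeric(m)
  if (params$h2_liability > 0)
    beta[causal] <- stats::rnorm(
      m_causal, 0, sqrt(params$h2_liability /
                          (m_causal * 2 * f[causal] * (1 - f[causal]))))
  se <- sqrt(1 / (2 * f * (1 - f) * params$n_discovery))
  beta_hat <- beta + stats::rnorm(m, 0, se)
  p <- pmax(2 * stats::pnorm(-abs(beta_hat / se)), 1e-300)
  pair <- ALLELE_PAIRS[sample.int(nrow(ALLELE_PAIRS), m, replace = TRUE), ,
                       drop = FALSE]
  ss <- data.frame(variant_id = paste0("rs", seq_len(m)),
                   chrom = "1", pos = seq_len(m) * 1000L,
                   effect_allele = pair[, 1], other_allele = pair[, 2],
                   odds_ratio = exp(beta_hat), p_value = p,
                   stringsAsFactors = FALSE)
  class(ss) <- c("summary_stats", "data.frame")
  truth <- structure(
    list(effects = data.frame(variant_id = ss$variant_id, f = f,
                              beta = beta, beta_hat = beta_hat, se = se,
                              p_value = p, causal = seq_len(m) %in% causal),
         causal = causal, alleles = pair, params = params),
    class = "sim_truth")
  list(sumstats = ss, truth = truth)
}

split_evenly <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + as.integer(seq_len(k) <= extra)
}

# B x m genotype draws at per-variant frequencies f
draw_geno <- function(nb, f) {
  matrix(stats::rbinom(nb * length(f), 2L, rep(f, each = nb)), nrow = nb)
}

# Mendelian transmission: one allele from each parent dosage matrix
transmit <- function(gm, gf) {
  matrix(stats::rbinom(length(gm), 1L, gm / 2) +
           stats::rbinom(length(gf), 1L, gf / 2), nrow = nrow(gm))
}

# printed-style diagnosis mix for simulated cases
DIAGNOSIS_PROBS <- c(schizophrenia = 0.628, schizoaffective = 0.051,
                     psychotic_nos = 0.089, schizophreniform = 0.080,
                     brief_psychotic = 0.037, delusional = 0.016,
                     substance_induced = 0.006, bipolar_psychotic = 0.093)

#' Simulate the multi-centre target cohort
#'
#' Centre-specific allele frequencies are drawn around the base frequencies
#' with Balding-Nichols drift variance `fst_drift * f (1 - f)`. Individual
#' liability is the centred genotype-weighted sum of true effects plus
#' normal environment of variance `1 - h2_liability`; an individual is
#' affected when liability exceeds the threshold set by the prevalence.
#' Cases are rejection-sampled affected individuals. Relatives are
#' unaffected full siblings of affected probands: for each family two
#' parents are simulated, the proband is re-drawn by Mendelian transmission
#' (with fresh environment) until affected, and one sibling is drawn by
#' transmission and re-drawn until unaffected, each under the family retry
#' cap. Controls are unaffected individuals; with `screen_controls`, two
#' parents and one sibling are additionally simulated and all must be
#' unaffected.
#'
#' @param params a [sim_params()] object.
#' @param truth the `sim_truth` from [simulate_discovery()] run with the
#'   same params.
#' @return List with `genotypes` (a [genotype_matrix()]), `phenotypes`
#'   (a `phenotype_table`) and `truth` (the input truth extended with
#'   per-sample genetic values and liabilities, centre frequencies, and the
#'   proband causal dosages of each relative's family).
#' @export
simulate_cohort <- function(params, truth) {
  validate_sim_params(params)
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(params$seed + 1L)
  m <- params$m_variants
  eff <- truth$effects
  causal <- truth$causal
  mc <- length(causal)
  beta_c <- eff$beta[causal]
  thr <- stats::qnorm(1 - params$prevalence)
  sd_e <- sqrt(1 - params$h2_liability)
  k <- params$n_centres

  # centre-specific frequencies (Balding-Nichols around the base f)
  fst <- params$fst_drift
  centre_freqs <- vapply(seq_len(k), function(cc) {
    if (fst > 0) {
      a <- eff$f * (1 - fst) / fst
      b <- (1 - eff$f) * (1 - fst) / fst
      pmin(pmax(stats::rbeta(m, a, b), 0.01), 0.99)
    } else eff$f
  }, numeric(m))

  gval_of <- function(G, fc) drop((G - matrix(2 * fc, nrow(G), mc,
                                              byrow = TRUE)) %*% beta_c)
  liab_of <- function(gval) gval + stats::rnorm(length(gval), 0, sd_e)

  n_case_c <- split_evenly(params$n_cases, k)
  n_ctrl_c <- split_evenly(params$n_controls, k)
  n_rel_c <- split_evenly(params$n_relatives, k)

  rows <- list()   # per accepted individual: causal dosages
  meta <- list()   # per accepted individual: group, centre, gval, liability
  fam_proband <- list()

  for (cc in seq_len(k)) {
    fc <- centre_freqs[causal, cc]

    # --- cases: rejection sampling of affected individuals ---
    need <- n_case_c[cc]
    got <- 0L
    tries <- 0L
    max_draws <- params$retry_cap * max(need, 1L)
    block <- min(20000L, max(200L, ceiling(need / params$prevalence * 0.25)))
    while (got < need) {
      if (tries >= max_draws)
        stop("case rejection sampling exceeded the retry cap; ",
             "increase retry_cap or the prevalence")
      nb <- min(block, max_draws - tries)
      G <- draw_geno(nb, fc)
      gv <- gval_of(G, fc)
      li <- liab_of(gv)
      aff <- which(li > thr)
      if (length(aff)) {
        take <- aff[seq_len(min(length(aff), need - got))]
        rows[[length(rows) + 1L]] <- G[take, , drop = FALSE]
        meta[[length(meta) + 1L]] <-
          data.frame(group = "case", centre = cc, gval = gv[take],
                     liability = li[take])
        got <- got + length(take)
      }
      tries <- tries + nb
    }

    # --- relatives: unaffected siblings of affected probands ---
    # families are ascertained through an affected proband, so family-level
    # rejection (fresh family per attempt) gives the correct risk-weighted
    # family distribution
    nrel <- n_rel_c[cc]
    if (nrel > 0) {
      Gm <- matrix(0L, nrel, mc)
      Gf <- matrix(0L, nrel, mc)
      prob_G <- matrix(0L, nrel, mc)
      prob_li <- numeric(nrel)
      got <- 0L
      tries <- 0L
      max_draws <- params$retry_cap * nrel
      block <- min(20000L, max(200L, ceiling(nrel / params$prevalence * 0.25)))
      while (got < nrel) {
        if (tries >= max_draws)
          stop("affected-proband sampling exceeded the retry cap; ",
               "increase retry_cap or the prevalence")
        nb <- min(block, max_draws - tries)
        Bm <- draw_geno(nb, fc)
        Bf <- draw_geno(nb, fc)
        Gp <- transmit(Bm, Bf)
        li <- liab_of(gval_of(Gp, fc))
        hit <- which(li > thr)
        if (length(hit)) {
          take <- hit[seq_len(min(length(hit), nrel - got))]
          sl <- got + seq_along(take)
          Gm[sl, ] <- Bm[take, , drop = FALSE]
          Gf[sl, ] <- Bf[take, , drop = FALSE]
          prob_G[sl, ] <- Gp[take, , drop = FALSE]
          prob_li[sl] <- li[take]
          got <- got + length(take)
        }
        tries <- tries + nb
      }
      sib_G <- matrix(0L, nrel, mc)
      sib_gv <- numeric(nrel)
      sib_li <- numeric(nrel)
      pending <- seq_len(nrel)
      for (it in seq_len(params$retry_cap)) {
        if (!length(pending)) break
        Gs <- transmit(Gm[pending, , drop = FALSE],
                       Gf[pending, , drop = FALSE])
        gv <- gval_of(Gs, fc)
        li <- liab_of(gv)
        ok <- li <= thr
        if (any(ok)) {
          sib_G[pending[ok], ] <- Gs[ok, , drop = FALSE]
          sib_gv[pending[ok]] <- gv[ok]
          sib_li[pending[ok]] <- li[ok]
          pending <- pending[!ok]
        }
      }
      if (length(pending))
        stop("unaffected-sibling sampling exceeded the retry cap (",
             params$retry_cap, " per family); increase retry_cap")
      rows[[length(rows) + 1L]] <- sib_G
      meta[[length(meta) + 1L]] <-
        data.frame(group = "relative", centre = cc, gval = sib_gv,
                   liability = sib_li)
      fam_proband[[length(fam_proband) + 1L]] <- prob_G
    }

    # --- controls: unaffected, optionally family-screened ---
    need <- n_ctrl_c[cc]
    got <- 0L
    tries <- 0L
    max_draws <- params$retry_cap * max(need, 1L)
    while (got < need) {
      if (tries >= max_draws)
        stop("control screening exceeded the retry cap; increase retry_cap")
      nb <- min(max(100L, need - got + 20L), max_draws - tries)
      if (params$screen_controls) {
        Gm <- draw_geno(nb, fc)
        Gf <- draw_geno(nb, fc)
        G <- transmit(Gm, Gf)
        Gs <- transmit(Gm, Gf)
        gv <- gval_of(G, fc)
        li <- liab_of(gv)
        ok <- li <= thr &
          liab_of(gval_of(Gm, fc)) <= thr &
          liab_of(gval_of(Gf, fc)) <= thr &
          liab_of(gval_of(Gs, fc)) <= thr
      } else {
        G <- draw_geno(nb, fc)
        gv <- gval_of(G, fc)
        li <- liab_of(gv)
        ok <- li <= thr
      }
      sel <- which(ok)
      if (length(sel)) {
        take <- sel[seq_len(min(length(sel), need - got))]
        rows[[length(rows) + 1L]] <- G[take, , drop = FALSE]
        meta[[length(meta) + 1L]] <-
          data.frame(group = "control", centre = cc, gval = gv[take],
                     liability = li[take])
        got <- got + length(take)
      }
      tries <- tries + nb
    }
  }

  meta <- do.call(rbind, meta)
  causal_G <- do.call(rbind, rows)
  n <- nrow(meta)
  ord <- order(factor(meta$group, levels = c("case", "relative", "control")),
               meta$centre)
  meta <- meta[ord, , drop = FALSE]
  causal_G <- causal_G[ord, , drop = FALSE]

  # non-causal genotypes are independent of ascertainment: direct draws
  G_full <- matrix(0L, n, m)
  G_full[, causal] <- causal_G
  noncausal <- setdiff(seq_len(m), causal)
  if (length(noncausal)) {
    for (cc in seq_len(k)) {
      r <- which(meta$centre == cc)
      if (length(r))
        G_full[r, noncausal] <- draw_geno(length(r),
                                          centre_freqs[noncausal, cc])
    }
    if (params$ld_block_size > 1L)
      G_full <- add_ld_blocks(G_full, noncausal, centre_freqs, meta$centre,
                              params)
  }
  if (params$missing_rate > 0) {
    drop_idx <- which(stats::runif(length(G_full)) < params$missing_rate)
    G_full[drop_idx] <- NA_integer_
  }

  sample_ids <- sprintf("%s_%04d", meta$group, seq_len(n))
  phen <- phenotype_table(data.frame(
    sample_id = sample_ids, group = meta$group,
    diagnosis = ifelse(meta$group == "case",
                       sample(names(DIAGNOSIS_PROBS), n, replace = TRUE,
                              prob = DIAGNOSIS_PROBS), NA_character_),
    centre = paste0("centre_", meta$centre), stringsAsFactors = FALSE))
  g <- genotype_matrix(
    sample_ids = sample_ids,
    variants = data.frame(variant_id = truth$effects$variant_id, chrom = "1",
                          pos = seq_len(m) * 1000L,
                          allele_a = truth$alleles[, 1],
                          allele_b = truth$alleles[, 2],
                          stringsAsFactors = FALSE),
    dosages = G_full)
  truth$centre_freqs <- centre_freqs
  truth$samples <- data.frame(sample_id = sample_ids, group = meta$group,
                              centre = paste0("centre_", meta$centre),
                              genetic_value = meta$gval,
                              liability = meta$liability)
  if (length(fam_proband)) {
    truth$proband_causal <- do.call(rbind, fam_proband)
    rownames(truth$proband_causal) <- sample_ids[meta$group == "relative"]
  }
  list(genotypes = g, phenotypes = phen, truth = truth)
}

# correlate consecutive non-causal variants in blocks by copy-with-flip
add_ld_blocks <- function(G_full, noncausal, centre_freqs, centre, params) {
  s <- params$ld_block_size
  n <- nrow(G_full)
  blocks <- split(noncausal, ceiling(seq_along(noncausal) / s))
  for (blk in blocks) {
    if (length(blk) < 2) next
    base <- G_full[, blk[1]]
    for (j in blk[-1]) {
      flip <- stats::runif(n) < params$ld_block_flip
      col <- base
      if (any(flip)) {
        fj <- centre_freqs[j, centre[flip]]
        col[flip] <- stats::rbinom(sum(flip), 2L, fj)
      }
      G_full[, j] <- col
    }
  }
  G_full
}

#' Draw an unascertained population sample
#'
#' Random individuals at the base allele frequencies (no centre drift, no
#' ascertainment), used to validate the generator against its own model:
#' the case fraction should match the prevalence and the regression of
#' liability on the noise-free genetic value should recover the planted
#' heritability.
#'
#' @param params a [sim_params()] object.
#' @param truth the `sim_truth` from [simulate_discovery()].
#' @param n number of individuals.
#' @param seed seed for this draw (default derives from `params$seed`).
#' @return List with `causal_dosages`, `genetic_value`, `liability`,
#'   `affected`.
#' @export
simulate_population <- function(params, truth, n,
                                seed = params$seed + 2L) {
  validate_sim_params(params)
  set.seed(seed)
  causal <- truth$causal
  f <- truth$effects$f[causal]
  beta_c <- truth$effects$beta[causal]
  G <- draw_geno(n, f)
  gv <- drop((G - matrix(2 * f, n, length(f), byrow = TRUE)) %*% beta_c)
  li <- gv + stats::rnorm(n, 0, sqrt(1 - params$h2_liability))
  list(causal_dosages = G, genetic_value = gv, liability = li,
       affected = li > stats::qnorm(1 - params$prevalence))
}

#' Write a complete synthetic study to disk
#'
#' Runs [simulate_discovery()] and [simulate_cohort()] and writes every file
#' the pipeline readers consume: discovery summary statistics (TSV),
#' genotypes as both a PLINK bed/bim/fam triple and a VCF, the phenotype
#' table (TSV), and per-variant / per-sample truth tables (TSV).
#'
#' @param params a [sim_params()] object.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
end_to_end_fixture <- function(params = sim_params(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  disc <- simulate_discovery(params)
  coh <- simulate_cohort(params, disc$truth)
  paths <- list(
    sumstats = file.path(dir, "sumstats.tsv"),
    plink = file.path(dir, "genotypes"),
    vcf = file.path(dir, "genotypes.vcf"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    variant_truth = file.path(dir, "variant_truth.tsv"),
    sample_truth = file.path(dir, "sample_truth.tsv"))
  write_summary_stats(disc$sumstats, paths$sumstats)
  write_plink(coh$genotypes, paths$plink)
  write_vcf(coh$genotypes, paths$vcf)
  write_phenotypes(coh$phenotypes, paths$phenotypes)
  utils::write.table(coh$truth$effects, paths$variant_truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(coh$truth$samples, paths$sample_truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
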