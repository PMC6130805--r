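#' Pipeline run configuration
#'
#' Collects every input path and analysis option for [run_pipeline()].
#' The configuration round-trips losslessly through its JSON file form
#' ([read_run_config()] / [write_run_config()]).
#'
#' @param genotypes path to genotypes (PLINK triple prefix/.bed or VCF).
#' @param sumstats path to discovery summary statistics.
#' @param phenotypes path to the phenotype table.
#' @param out_dir output directory.
#' @param qc a [qc_thresholds()] list for the PCA variant set.
#' @param score_ld a [qc_thresholds()] list whose LD settings are used for
#'   score pruning (no MAF/HWE floor is applied to the scoring pool).
#' @param thresholds score P-value thresholds.
#' @param k_pcs number of ancestry principal components (default 3).
#' @param contrasts character vector of contrast labels
#'   (see [build_contrast()]).
#' @param decile_threshold threshold at which the decile analysis is run.
#' @param decile_boundaries `"combined"` or `"controls"`.
#' @param drop_palindromic harmonisation flag (see [harmonise()]).
#' @param seed integer seed recorded in the manifest.
#' @return List of class `run_config`.
#' @export
run_config <- function(genotypes, sumstats, phenotypes, out_dir,
                       qc = qc_thresholds(),
                       score_ld = qc_thresholds(),
                       thresholds = default_thresholds(), k_pcs = 3L,
                       contrasts = c("all-cases-vs-controls",
                                     "relatives-vs-controls"),
                       decile_threshold = 0.05,
                       decile_boundaries = "combined",
                       drop_palindromic = TRUE, seed = 1L) {
  cfg <- list(genotypes = genotypes, sumstats = sumstats,
              phenotypes = phenotypes, out_dir = out_dir,
              qc = unclass(qc), score_ld = unclass(score_ld),
              thresholds = thresholds, k_pcs = as.integer(k_pcs),
              contrasts = contrasts, decile_threshold = decile_threshold,
              decile_boundaries = decile_boundaries,
              drop_palindromic = isTRUE(drop_palindromic),
              seed = as.integer(seed))
  for (p in c("genotypes", "sumstats", "phenotypes")) {
    path <- cfg[[p]]
    if (!file.exists(path) && !file.exists(paste0(path, ".bed")))
      stop("config path does not exist: ", p, " = ", path)
  }
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$qc <- do.call(qc_thresholds, cfg$qc)
  cfg$score_ld <- do.call(qc_thresholds, cfg$score_ld)
  do.call(run_config, cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full PRS analysis pipeline
#'
#' QC -> LD pruning -> ancestry PCA -> allele harmonisation -> scoring at
#' all thresholds -> per-centre control-anchored Z-standardisation ->
#' per-contrast evaluation and decile analysis. All outputs are TSV plus a
#' JSON run manifest (config, config hash, seed, package version, per-stage
#' counts). Identical config and seed give identical numerical outputs.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(cfg) {
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)

  g <- stage("read_genotypes", read_genotypes(cfg$genotypes))
  ss <- stage("read_summary_stats", read_summary_stats(cfg$sumstats))
  phen <- stage("read_phenotypes", read_phenotypes(cfg$phenotypes))
  log_count("genotypes", length(g$sample_ids), "samples x",
            nrow(g$variants), "variants")

  qc_thr <- do.call(qc_thresholds, cfg$qc)
  ld_thr <- do.call(qc_thresholds, cfg$score_ld)
  qc_keep <- stage("qc", apply_qc(g, qc_thr))
  qc_counts <- attr(qc_keep, "counts")
  log_count("qc", qc_counts[["n_retained"]], "of", qc_counts[["n_input"]],
            "variants pass MAF/HWE")
  pca_set <- stage("ld_prune_pca", ld_prune(g, qc_thr, qc_keep))
  log_count("ld_prune_pca", length(pca_set), "variants for PCA")
  pca <- stage("pca", pca_genotypes(g, pca_set, k = cfg$k_pcs))

  w <- stage("harmonise",
             harmonise(ss, g, drop_palindromic = cfg$drop_palindromic))
  harm_counts <- attr(w, "counts")
  log_count("harmonise", harm_counts[["retained"]], "of",
            harm_counts[["input"]], "discovery variants harmonised")
  score_set <- stage("ld_prune_score", ld_prune(g, ld_thr))
  scores <- stage("scoring",
                  score_all_thresholds(g, w, score_set,
                                       thresholds = cfg$thresholds))
  scores <- stage("z_standardise", z_standardise(scores, phen))

  utils::write.table(
    data.frame(stage = c("input", "maf_hwe", "ld_prune_pca", "harmonised",
                         "ld_prune_score"),
               n_variants = c(qc_counts[["n_input"]],
                              qc_counts[["n_retained"]], length(pca_set),
                              harm_counts[["retained"]], length(score_set))),
    out("qc_report.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_pca(pca, out("pcs.tsv"))
  write_scores(scores, out("scores.tsv"))

  evals <- list()
  deciles <- list()
  for (ct in cfg$contrasts) {
    ev <- stage(paste0("evaluate:", ct),
                evaluate_contrast(scores, phen, pca, contrast = ct))
    write_eval(ev, out(paste0("eval_", gsub("[^a-z0-9]+", "_", ct), ".tsv")))
    evals[[ct]] <- ev
    dc <- stage(paste0("deciles:", ct),
                decile_analysis(scores, phen,
                                covariates = decile_covariates(pca, phen),
                                contrast = ct,
                                threshold = cfg$decile_threshold,
                                boundaries = cfg$decile_boundaries))
    write_deciles(dc, out(paste0("deciles_", gsub("[^a-z0-9]+", "_", ct),
                                 ".tsv")))
    deciles[[ct]] <- dc
  }

  cfg_file <- out("config.json")
  write_run_config(cfg, cfg_file)
  manifest <- list(config = unclass(cfg),
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   seed = cfg$seed,
                   package_version = as.character(
                     utils::packageVersion("psyprs")),
                   r_version = R.version.string,
                   n_samples = length(g$sample_ids),
                   n_variants = nrow(g$variants))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(genotypes = g, pca = pca, scores = scores, evals = evals,
                 deciles = deciles, out_dir = cfg$out_dir))
}

decile_covariates <- function(pca, phen) {
  cov <- as.data.frame(pca$components)
  centre <- phen$centre[match(rownames(pca$components), phen$sample_id)]
  if (length(unique(centre)) > 1) cov$centre <- factor(centre)
  cov
}

log_count <- function(stage, ...) {
  message("[", stage, "] ", paste(..., collapse = " "))
}

#' Simulate a study and write it to a fixture directory
#'
#' Thin wrapper over [end_to_end_fixture()] matching the `simulate` CLI
#' subcommand.
#'
#' @param params a [sim_params()].
#' @param dir output directory.
#' @return Invisibly, the list of file paths written.
#' @export
simulate_command <- function(params = sim_params(), dir) {
  end_to_end_fixture(params, dir)
}
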