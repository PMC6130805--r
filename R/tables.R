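#' Read discovery GWAS summary statistics
#'
#' Delimited text (tab or comma, autodetected from the header line) with one
#' row per variant. Odds ratios are stored as given, never logged here. Rows
#' whose odds ratio or P-value cannot be parsed (or fall outside OR > 0,
#' 0 < P <= 1) are dropped and counted in the `n_dropped` attribute.
#'
#' @param path path to the file.
#' @param column_map named character vector mapping the required fields
#'   `variant_id`, `effect_allele`, `other_allele`, `odds_ratio`, `p_value`
#'   (and optionally `chrom`, `pos`) to column names in the file.
#' @return A data.frame of class `summary_stats` with the canonical columns.
#' @export
read_summary_stats <- function(path,
                               column_map = c(variant_id = "variant_id",
                                              effect_allele = "effect_allele",
                                              other_allele = "other_allele",
                                              odds_ratio = "odds_ratio",
                                              p_value = "p_value")) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  req <- c("variant_id", "effect_allele", "other_allele",
           "odds_ratio", "p_value")
  missing_map <- setdiff(req, names(column_map))
  if (length(missing_map))
    stop("column_map lacks mappings for: ", paste(missing_map, collapse = ", "))
  missing_col <- setdiff(column_map[req], names(df))
  if (length(missing_col))
    stop("mapped column(s) not in file: ", paste(missing_col, collapse = ", "))
  out <- data.frame(
    variant_id = df[[column_map[["variant_id"]]]],
    chrom = if ("chrom" %in% names(column_map))
      df[[column_map[["chrom"]]]] else rep(NA_character_, nrow(df)),
    pos = if ("pos" %in% names(column_map))
      suppressWarnings(as.integer(df[[column_map[["pos"]]]]))
    else rep(NA_integer_, nrow(df)),
    effect_allele = toupper(df[[column_map[["effect_allele"]]]]),
    other_allele = toupper(df[[column_map[["other_allele"]]]]),
    odds_ratio = suppressWarnings(as.numeric(df[[column_map[["odds_ratio"]]]])),
    p_value = suppressWarnings(as.numeric(df[[column_map[["p_value"]]]])),
    stringsAsFactors = FALSE)
  ok <- !is.na(out$odds_ratio) & !is.na(out$p_value) &
    out$odds_ratio > 0 & out$p_value > 0 & out$p_value <= 1
  n_dropped <- sum(!ok)
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("summary statistics table is empty")
  if (anyDuplicated(out$variant_id)) stop("duplicate variant_id in ", path)
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Write summary statistics as TSV
#' @param ss a `summary_stats` data.frame.
#' @param path output path.
#' @export
write_summary_stats <- function(ss, path) {
  utils::write.table(as.data.frame(ss), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' TSV with header columns `sample_id`, `group` (case / relative / control),
#' `diagnosis` (required for cases, empty otherwise) and `centre`.
#'
#' @param path path to the file.
#' @return A data.frame of class `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = c("NA", ""))
  phenotype_table(df)
}

#' Construct a validated phenotype table
#'
#' @param df data.frame with columns `sample_id`, `group`, `diagnosis`,
#'   `centre`. `diagnosis` must be present for every case and absent (`NA`
#'   or `"none"`) for relatives and controls.
#' @return The validated data.frame with class `phenotype_table`.
#' @export
phenotype_table <- function(df) {
  req <- c("sample_id", "group", "diagnosis", "centre")
  if (!all(req %in% names(df)))
    stop("phenotype table needs columns: ", paste(req, collapse = ", "))
  df <- as.data.frame(df)[, req]
  for (cc in req) df[[cc]] <- as.character(df[[cc]])
  df$diagnosis[!is.na(df$diagnosis) & df$diagnosis == "none"] <- NA_character_
  if (anyDuplicated(df$sample_id)) stop("sample_id must be unique")
  bad_group <- setdiff(unique(df$group), c("case", "relative", "control"))
  if (length(bad_group))
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "))
  if (any(df$group == "case" & is.na(df$diagnosis)))
    stop("every case must have a diagnosis")
  if (any(df$group != "case" & !is.na(df$diagnosis)))
    stop("diagnosis must be absent for relatives and controls")
  rownames(df) <- NULL
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Write a phenotype table as TSV
#' @param phen a `phenotype_table`.
#' @param path output path.
#' @export
write_phenotypes <- function(phen, path) {
  out <- as.data.frame(phen)
  out$diagnosis[is.na(out$diagnosis)] <- "none"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonise discovery effects onto target genotypes
#'
#' Matches discovery variants to the target genotype matrix and resolves the
#' effect-allele orientation, producing a signed per-variant weight
#' log(odds ratio) to be applied to `allele_a` dosage counts:
#' the sign is flipped when the target `allele_a` corresponds to the
#' discovery other allele. Strand-complement matches are aligned after
#' complementing both target alleles. Palindromic variants (A/T, C/G) are
#' ambiguous under strand flips and are dropped by default. Variants that
#' cannot be matched or aligned are dropped; counts per drop reason are
#' attached as attribute `counts`.
#'
#' @param ss a `summary_stats` table.
#' @param g a [genotype_matrix()].
#' @param drop_palindromic drop A/T and C/G variants (default `TRUE`).
#' @param match_by `"id"` (default) matches on `variant_id`; `"pos"` matches
#'   on `chrom:pos`.
#' @return Data.frame of class `harmonised_weights` with columns
#'   `variant_index` (into `g`), `signed_weight`, `p_value`.
#' @export
harmonise <- function(ss, g, drop_palindromic = TRUE,
                      match_by = c("id", "pos")) {
  match_by <- match.arg(match_by)
  if (nrow(ss) == 0 || nrow(g$variants) == 0)
    stop("harmonise needs non-empty summary statistics and genotypes")
  if (match_by == "id") {
    idx <- match(ss$variant_id, g$variants$variant_id)
  } else {
    idx <- match(paste(ss$chrom, ss$pos), paste(g$variants$chrom, g$variants$pos))
  }
  matched <- !is.na(idx)
  counts <- c(input = nrow(ss), unmatched = sum(!matched),
              palindromic = 0L, allele_mismatch = 0L, retained = 0L)
  ssm <- ss[matched, , drop = FALSE]
  gi <- idx[matched]
  ta <- g$variants$allele_a[gi]
  tb <- g$variants$allele_b[gi]
  ea <- ssm$effect_allele
  oa <- ssm$other_allele
  pal <- !is.na(COMPLEMENT[ta]) & COMPLEMENT[ta] == tb
  sign <- rep(NA_real_, length(gi))
  direct_pos <- ea == ta & oa == tb
  direct_neg <- ea == tb & oa == ta
  cta <- unname(COMPLEMENT[ta])
  ctb <- unname(COMPLEMENT[tb])
  flip_pos <- !direct_pos & !direct_neg & ea == cta & oa == ctb
  flip_neg <- !direct_pos & !direct_neg & ea == ctb & oa == cta
  sign[direct_pos | flip_pos] <- 1
  sign[direct_neg | flip_neg] <- -1
  drop_pal <- drop_palindromic & pal
  counts["palindromic"] <- sum(drop_pal & !is.na(sign))
  counts["allele_mismatch"] <- sum(is.na(sign))
  keep <- !is.na(sign) & !drop_pal
  counts["retained"] <- sum(keep)
  if (!any(keep)) stop("no variants could be harmonised")
  out <- data.frame(variant_index = gi[keep],
                    signed_weight = sign[keep] * log(ssm$odds_ratio[keep]),
                    p_value = ssm$p_value[keep])
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  class(out) <- c("harmonised_weights", "data.frame")
  out
}
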