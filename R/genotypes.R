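#' Genotype matrix container
#'
#' Hard-call genotypes for a target cohort: an individuals x variants dosage
#' matrix counting copies of `allele_a` (0, 1, 2 or `NA` for missing), plus
#' per-variant metadata. Positions are 1-based throughout, as in VCF.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`. `allele_a` is the allele the dosages count;
#'   effect-allele orientation is resolved later by [harmonise()], never by
#'   the reader.
#' @param dosages integer matrix, `length(sample_ids)` rows and
#'   `nrow(variants)` columns; entries in {0,1,2} or `NA`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sample_ids, variants, dosages) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  req <- c("variant_id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(req %in% names(variants)))
    stop("variants must have columns: ", paste(req, collapse = ", "))
  variants <- as.data.frame(variants)[, req]
  variants$variant_id <- as.character(variants$variant_id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (nrow(dosages) != length(sample_ids) || ncol(dosages) != nrow(variants))
    stop("dosage dimensions do not match sample_ids / variants")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("non-missing dosages must be in {0,1,2}")
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$variant_id
  structure(list(sample_ids = sample_ids, variants = variants,
                 dosages = dosages),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d missing calls)\n",
              length(x$sample_ids), nrow(x$variants), sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read hard-call genotypes
#'
#' Reads a PLINK bed/bim/fam triple or a VCF (GT field only) into a
#' [genotype_matrix()]. Sample and variant order follow file order.
#'
#' For PLINK input, `allele_a` is the bim A1 allele. For VCF input,
#' `allele_a` is the ALT allele (dosage = ALT allele count), `allele_b` the
#' REF. Non-biallelic VCF records are skipped; the skip count is attached as
#' attribute `n_skipped` and reported via a message.
#'
#' @param path path to the `.bed` file (or bare prefix) of a PLINK triple,
#'   or to a VCF file.
#' @param format_hint `"auto"` (by extension), `"plink"` or `"vcf"`.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, format_hint = c("auto", "plink", "vcf")) {
  format_hint <- match.arg(format_hint)
  if (format_hint == "auto") {
    format_hint <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "plink"
  }
  if (format_hint == "vcf") read_vcf_genotypes(path) else read_plink(path)
}

# ---- PLINK bed/bim/fam ------------------------------------------------------

plink_prefix <- function(path) sub("\\.(bed|bim|fam)$", "", path)

read_plink <- function(path) {
  prefix <- plink_prefix(path)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing PLINK file: ", f)
  bim_df <- utils::read.table(bim, header = FALSE, colClasses = "character")
  if (ncol(bim_df) != 6) stop("malformed .bim: expected 6 columns in ", bim)
  names(bim_df) <- c("chrom", "variant_id", "cm", "pos", "a1", "a2")
  fam_df <- utils::read.table(fam, header = FALSE, colClasses = "character")
  if (ncol(fam_df) < 2) stop("malformed .fam: expected >= 2 columns in ", fam)
  n <- nrow(fam_df)
  m <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("malformed .bed: bad magic bytes in ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported: ", bed)
  bpv <- ceiling(n / 4)
  body <- as.integer(raw[-(1:3)])
  if (length(body) != bpv * m)
    stop(sprintf("malformed .bed: expected %d data bytes, found %d",
                 bpv * m, length(body)))
  bytes <- matrix(body, nrow = bpv, ncol = m)
  codes <- matrix(0L, nrow = 4L * bpv, ncol = m)
  for (s in 0:3) {
    codes[seq(s + 1L, 4L * bpv, by = 4L), ] <-
      bitwAnd(bitwShiftR(bytes, 2L * s), 3L)
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # 2-bit code -> copies of A1: 00 hom A1, 01 missing, 10 het, 11 hom A2
  lut <- c(2L, NA_integer_, 1L, 0L)
  dos <- matrix(lut[codes + 1L], nrow = n, ncol = m)
  genotype_matrix(
    sample_ids = fam_df[[2]],
    variants = data.frame(variant_id = bim_df$variant_id,
                          chrom = bim_df$chrom,
                          pos = as.integer(bim_df$pos),
                          allele_a = bim_df$a1, allele_b = bim_df$a2,
                          stringsAsFactors = FALSE),
    dosages = dos)
}

#' Write a genotype matrix as a PLINK bed/bim/fam triple
#'
#' SNP-major bed with the standard magic bytes; `allele_a` is written as A1.
#'
#' @param g a [genotype_matrix()].
#' @param prefix output path prefix (writes `prefix.bed/.bim/.fam`).
#' @return Invisibly, the three file paths.
#' @export
write_plink <- function(g, prefix) {
  n <- length(g$sample_ids)
  m <- nrow(g$variants)
  bim <- data.frame(chrom = g$variants$chrom, id = g$variants$variant_id,
                    cm = 0L, pos = g$variants$pos,
                    a1 = g$variants$allele_a, a2 = g$variants$allele_b)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = g$sample_ids, iid = g$sample_ids,
                    pid = 0L, mid = 0L, sex = 0L, pheno = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  # dosage (copies of A1) -> 2-bit code
  code_of <- function(d) ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])
  bpv <- ceiling(n / 4)
  pad <- 4L * bpv - n
  codes <- apply(g$dosages, 2, function(col) c(code_of(col), rep(0L, pad)))
  codes <- matrix(codes, nrow = 4L * bpv, ncol = m)
  i1 <- seq(1L, 4L * bpv, by = 4L)
  bytes <- codes[i1, , drop = FALSE] +
    4L * codes[i1 + 1L, , drop = FALSE] +
    16L * codes[i1 + 2L, , drop = FALSE] +
    64L * codes[i1 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

# ---- VCF --------------------------------------------------------------------

read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !is.na(alt) & !grepl(",", alt) &
    nchar(ref) == 1 & nchar(alt) == 1
  n_skipped <- sum(!biallelic)
  if (n_skipped > 0)
    message(n_skipped, " non-biallelic VCF record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  # dosage = ALT allele count; map each distinct GT string once
  u <- unique(as.vector(gt))
  dose_of <- vapply(u, function(s) {
    if (is.na(s) || grepl("\\.", s)) return(NA_integer_)
    sum(as.integer(strsplit(s, "[/|]")[[1]]))
  }, integer(1))
  dos <- matrix(dose_of[match(as.vector(gt), u)],
                nrow = nrow(gt), ncol = ncol(gt))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[is.na(ids) | ids == ".", "CHROM"], ":",
           fix[is.na(ids) | ids == ".", "POS"])
  g <- genotype_matrix(
    sample_ids = colnames(gt),
    variants = data.frame(variant_id = ids, chrom = fix[, "CHROM"],
                          pos = as.integer(fix[, "POS"]),
                          allele_a = fix[, "ALT"], allele_b = fix[, "REF"],
                          stringsAsFactors = FALSE),
    dosages = t(dos))
  attr(g, "n_skipped") <- n_skipped
  g
}

#' Write a genotype matrix as VCF
#'
#' Plain-text VCF 4.2 with a single GT FORMAT field. `allele_a` is written as
#' ALT (so dosages are ALT allele counts) and `allele_b` as REF.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(g, path) {
  gt_of <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_of[g$dosages + 1L], nrow = nrow(g$dosages))
  gt[is.na(g$dosages)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", g$sample_ids), collapse = "\t"))
  body <- paste(g$variants$chrom, g$variants$pos, g$variants$variant_id,
                g$variants$allele_b, g$variants$allele_a, ".", "PASS", ".",
                "GT", apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
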