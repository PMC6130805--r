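# round half-up to one decimal, matching printed-table style
round1_half_up <- function(x) floor(x * 10 + 0.5) / 10

#' Diagnosis subgroup summary among cases
#'
#' Counts and one-decimal percentages (rounded half-up) of each diagnosis
#' label among the cases of a phenotype table.
#'
#' @param phen a `phenotype_table` with at least one case.
#' @return Data.frame with `label`, `count`, `percent`, ordered by
#'   decreasing count.
#' @export
summarise_diagnoses <- function(phen) {
  dx <- phen$diagnosis[phen$group == "case"]
  if (length(dx) == 0) stop("phenotype table contains no cases")
  tab <- sort(table(dx), decreasing = TRUE)
  out <- data.frame(label = names(tab), count = as.integer(tab),
                    percent = round1_half_up(100 * as.integer(tab) / length(dx)))
  rownames(out) <- NULL
  out
}

# diagnosis labels pooled as schizophrenia/schizoaffective; bipolar with
# psychotic features stands alone; everything else is "other psychoses"
SZ_POOL <- c("schizophrenia", "schizoaffective")
BIPOLAR_LABEL <- "bipolar_psychotic"
KNOWN_DIAGNOSES <- c(SZ_POOL, BIPOLAR_LABEL, "psychotic_nos",
                     "schizophreniform", "brief_psychotic", "delusional",
                     "substance_induced")

case_subcategory <- function(diagnosis) {
  unknown <- setdiff(unique(diagnosis[!is.na(diagnosis)]), KNOWN_DIAGNOSES)
  if (length(unknown))
    message("diagnosis label(s) pooled into 'other psychoses': ",
            paste(unknown, collapse = ", "))
  ifelse(diagnosis %in% SZ_POOL, "sz",
         ifelse(diagnosis == BIPOLAR_LABEL, "bipolar", "other"))
}

#' Build a two-group contrast from a phenotype table
#'
#' Returns the two disjoint sample-ID sets named by the contrast label.
#' Cases partition into three subcategories: schizophrenia and
#' schizoaffective disorder pooled; bipolar disorder with psychotic features
#' alone; all remaining case diagnoses pooled as other psychotic disorders.
#' New (unrecognised) diagnosis labels default into the "other" pool with a
#' logged notice. The comparison group is always the controls, except that
#' relatives are contrasted with controls and never pooled with cases.
#'
#' @param phen a `phenotype_table`.
#' @param spec one of `"all-cases-vs-controls"`,
#'   `"schizophrenia-vs-controls"` (schizophrenia + schizoaffective),
#'   `"bipolar-vs-controls"`, `"other-psychoses-vs-controls"`,
#'   `"relatives-vs-controls"`.
#' @return List with `group1` and `group2` character vectors of sample IDs.
#' @export
build_contrast <- function(phen, spec) {
  controls <- phen$sample_id[phen$group == "control"]
  cases <- phen$group == "case"
  group1 <- switch(spec,
    "all-cases-vs-controls" = phen$sample_id[cases],
    "schizophrenia-vs-controls" =
      phen$sample_id[cases & case_subcategory(phen$diagnosis) == "sz"],
    "bipolar-vs-controls" =
      phen$sample_id[cases & case_subcategory(phen$diagnosis) == "bipolar"],
    "other-psychoses-vs-controls" =
      phen$sample_id[cases & case_subcategory(phen$diagnosis) == "other"],
    "relatives-vs-controls" = phen$sample_id[phen$group == "relative"],
    stop("unknown contrast spec: ", spec))
  if (length(group1) == 0)
    stop("contrast '", spec, "' selects no group-1 samples")
  if (length(controls) == 0)
    stop("contrast '", spec, "' selects no controls")
  list(group1 = group1, group2 = controls)
}
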