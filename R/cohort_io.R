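#' Default variant-class mapping
#'
#' Maps MAF `Variant_Classification` labels onto the three functional classes
#' used throughout the package: `nonsilent` (protein-changing point
#' substitutions), `silent` (synonymous substitutions) and `other`
#' (everything else -- indels, splice, UTR, intron -- which point-substitution
#' dN/dS theory does not cover and which is therefore excluded from
#' estimation).
#'
#' @param include_nonsense logical; count nonsense (stop-gain) and related
#'   protein-truncating point substitutions as `nonsilent` (default `TRUE`).
#'   Source cohorts differ on this point, so it is exposed as a switch.
#' @return named list with character vectors `nonsilent` and `silent`.
#' @export
default_class_map <- function(include_nonsense = TRUE) {
  nonsilent <- "Missense_Mutation"
  if (include_nonsense) {
    nonsilent <- c(nonsilent, "Nonsense_Mutation", "Nonstop_Mutation",
                   "Translation_Start_Site")
  }
  list(nonsilent = nonsilent, silent = c("Silent", "Synonymous"))
}

#' Read a variant-class mapping from a YAML file
#'
#' The file must define `nonsilent:` and `silent:` lists of raw
#' `Variant_Classification` labels; labels in neither list map to `other`.
#'
#' @param path path to a YAML file.
#' @return named list as [default_class_map()].
#' @export
read_class_map <- function(path) {
  m <- yaml::read_yaml(path)
  if (!all(c("nonsilent", "silent") %in% names(m)))
    stop("class map must define 'nonsilent' and 'silent'")
  list(nonsilent = as.character(unlist(m$nonsilent)),
       silent = as.character(unlist(m$silent)))
}

#' Map raw variant-classification labels to functional classes
#'
#' @param raw_class character vector of raw annotation labels.
#' @param class_map mapping as returned by [default_class_map()].
#' @return factor with levels `nonsilent`, `silent`, `other`.
#' @export
map_variant_class <- function(raw_class, class_map = default_class_map()) {
  out <- rep("other", length(raw_class))
  out[raw_class %in% class_map$nonsilent] <- "nonsilent"
  out[raw_class %in% class_map$silent] <- "silent"
  factor(out, levels = c("nonsilent", "silent", "other"))
}

maf_required_cols <- c("Hugo_Symbol", "Variant_Classification",
                       "Tumor_Sample_Barcode")

#' Read a MAF-like somatic mutation table
#'
#' Reads a tab-separated, `#`-commented MAF-style file and normalizes it into
#' the internal mutation-record table. Allele frequency is taken from an `AF`
#' column when present, otherwise computed as `t_alt_count /
#' (t_alt_count + t_ref_count)`; if neither is available it is `NA`. A
#' `Patient_ID` column is used when present, otherwise the sample barcode
#' doubles as the patient identifier.
#'
#' @param path path to the TSV file.
#' @param class_map variant-class mapping (see [default_class_map()]).
#' @return data.frame with columns `patient_id`, `sample_id`, `gene`,
#'   `variant_class`, `allele_frequency`, `raw_class`, plus `position` when a
#'   `Start_Position` column is present (used for mutation identity in
#'   trunk/branch partitioning).
#' @export
read_maf <- function(path, class_map = default_class_map()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(maf_required_cols, names(df))
  if (length(missing))
    stop("MAF is missing required column(s): ", paste(missing, collapse = ", "))
  af <- rep(NA_real_, nrow(df))
  if ("AF" %in% names(df)) {
    af <- suppressWarnings(as.numeric(df$AF))
  } else if (all(c("t_alt_count", "t_ref_count") %in% names(df))) {
    alt <- suppressWarnings(as.numeric(df$t_alt_count))
    ref <- suppressWarnings(as.numeric(df$t_ref_count))
    bad <- which(is.na(alt) != is.na(df$t_alt_count == "") |
                   (is.na(alt) & nzchar(as.character(df$t_alt_count))) |
                   (is.na(ref) & nzchar(as.character(df$t_ref_count))))
    if (length(bad))
      stop("non-numeric read counts at data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    af <- ifelse(!is.na(alt) & !is.na(ref) & (alt + ref) > 0,
                 alt / (alt + ref), NA_real_)
  }
  if (any(af < 0 | af > 1, na.rm = TRUE))
    stop("allele frequencies outside [0, 1]")
  out <- data.frame(
    patient_id = as.character(
      if ("Patient_ID" %in% names(df)) df$Patient_ID else df$Tumor_Sample_Barcode),
    sample_id = as.character(df$Tumor_Sample_Barcode),
    gene = as.character(df$Hugo_Symbol),
    variant_class = map_variant_class(df$Variant_Classification, class_map),
    allele_frequency = af,
    raw_class = as.character(df$Variant_Classification),
    stringsAsFactors = FALSE)
  if ("Start_Position" %in% names(df)) out$position <- df$Start_Position
  out
}

#' Write a mutation-record table back to MAF-like TSV
#'
#' Inverse of [read_maf()] for the columns the pipeline uses; round-trips
#' gene, class, sample, patient and allele frequency.
#'
#' @param mutations mutation-record data.frame.
#' @param path output path.
#' @export
write_maf <- function(mutations, path) {
  out <- data.frame(Hugo_Symbol = mutations$gene,
                    Variant_Classification = mutations$raw_class,
                    Tumor_Sample_Barcode = mutations$sample_id,
                    Patient_ID = mutations$patient_id,
                    AF = mutations$allele_frequency,
                    stringsAsFactors = FALSE)
  if (!is.null(mutations$position)) out$Start_Position <- mutations$position
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table with survival and drug-exposure indicators
#'
#' Expects tab-separated columns `patient_id` (or `Patient_ID`),
#' `survival_time` (months, positive) and `event` (1 = death/progression,
#' 0 = censored). Any column whose name starts with `drug` is treated as a
#' 0/1 exposure indicator; exposed drug labels are collected into a `drugs`
#' list-column. Other columns are preserved untouched.
#'
#' @param path path to the TSV file.
#' @return data.frame with `patient_id`, `survival_time`, `event`, the raw
#'   drug indicator columns, a `drugs` list-column, and attribute
#'   `drug_labels`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  names(df)[names(df) == "Patient_ID"] <- "patient_id"
  for (col in c("patient_id", "survival_time", "event"))
    if (!col %in% names(df)) stop("clinical table missing column: ", col)
  if (!all(df$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (event)")
  if (any(df$survival_time <= 0))
    stop("survival_time must be positive")
  drug_cols <- grep("^drug", names(df), ignore.case = TRUE, value = TRUE)
  for (d in drug_cols)
    if (!all(df[[d]] %in% c(0, 1)))
      stop("drug indicator column must be 0/1: ", d)
  df$drugs <- lapply(seq_len(nrow(df)), function(i)
    drug_cols[vapply(drug_cols, function(d) df[[d]][i] == 1, logical(1))])
  attr(df, "drug_labels") <- drug_cols
  df
}

#' Read a per-sample metadata table
#'
#' Tab-separated with at least `patient_id` and `sample_id`; recognised
#' optional columns are `status`, `timepoint`, `tumor_purity`, `msi_score`
#' and `cna_fraction`. `(patient_id, sample_id)` must be unique.
#'
#' @param path path to the TSV file.
#' @return data.frame of sample metadata.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("patient_id", "sample_id"))
    if (!col %in% names(df)) stop("sample meta missing column: ", col)
  if (anyDuplicated(df[c("patient_id", "sample_id")]))
    stop("(patient_id, sample_id) pairs must be unique")
  df
}

#' Order the samples of one patient along the inferred time axis
#'
#' Samples are ordered by `timepoint` when available. When timepoints are
#' missing or tied the total mutation count decides (ascending): an earlier
#' sample is assumed to carry fewer mutations than a more evolved one.
#' Residual ties break lexicographically on `sample_id`, making the order
#' total and deterministic.
#'
#' @param samples data.frame with `sample_id` and optionally `timepoint` and
#'   `n_mutations` columns.
#' @return the same data.frame, reordered.
#' @export
order_samples <- function(samples) {
  tp <- if ("timepoint" %in% names(samples))
    as.numeric(samples$timepoint) else rep(NA_real_, nrow(samples))
  tp[is.na(tp)] <- Inf
  nm <- if ("n_mutations" %in% names(samples))
    as.numeric(samples$n_mutations) else rep(0, nrow(samples))
  samples[order(tp, nm, samples$sample_id), , drop = FALSE]
}

#' Classify microsatellite status from an instability score
#'
#' Genomes with a score strictly above 3.5 are classified unstable (`MSI`);
#' the boundary value itself is stable (`MSS`). The score is consumed, not
#' computed, here.
#'
#' @param msi_score non-negative numeric vector.
#' @return character vector of `"MSI"` / `"MSS"` (`NA` propagated).
#' @export
msi_classify <- function(msi_score) {
  if (any(msi_score < 0, na.rm = TRUE)) stop("msi_score must be >= 0")
  ifelse(is.na(msi_score), NA_character_,
         ifelse(msi_score > 3.5, "MSI", "MSS"))
}
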