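# Domain vocabulary and tabular I/O for variant, gene-length and
# patient-case tables. All tables are plain data.frames; missing numeric
# features are NA (never 0 -- a ddG of exactly 0 means "neutral").

#' Five-tier variant classification labels
#'
#' The classification vocabulary used throughout the package: benign (B),
#' likely benign (LB), variant of uncertain significance (VUS), likely
#' pathogenic (LP) and pathogenic (P). Any other token in an input table is
#' a parse error.
#'
#' @return Character vector of the five valid labels.
#' @export
classification_labels <- function() {
  c("B", "LB", "VUS", "LP", "P")
}

# Column order of the on-disk variant table; also the canonical column
# order of the in-memory data.frame.
variant_table_columns <- function() {
  c("gene", "protein_change", "classification", "ddg_fold", "cadd",
    "confidence", "sasa_percent", "maf", "in_characterized_domain")
}

#' Construct a variant table
#'
#' Builds and validates a variant table from per-field vectors. One row per
#' missense variant; identity is the (gene, protein_change) pair. Numeric
#' features may be NA meaning "not measured".
#'
#' @param gene Character vector of gene symbols.
#' @param protein_change Character vector of protein-level HGVS changes
#'   (e.g. `"NP_076927.1:p.Met384Lys"` or `"p.Met384Lys"`); only
#'   non-emptiness is enforced.
#' @param classification Character vector of labels from
#'   [classification_labels()].
#' @param ddg_fold Folding free energy difference in kcal/mol, positive =
#'   destabilizing (variant minus wild type).
#' @param cadd PHRED-scaled CADD score, non-negative.
#' @param confidence Per-residue model confidence (pLDDT) in \[0, 100\].
#' @param sasa_percent Relative solvent accessible surface area, percent
#'   of the residue's theoretical maximum; may exceed 100.
#' @param maf Minor allele frequency in \[0, 1\].
#' @param in_characterized_domain Logical; whether the residue lies in a
#'   characterized functional domain.
#' @return A validated data.frame with the canonical column order.
#' @export
variant_table <- function(gene, protein_change, classification,
                          ddg_fold = NA_real_, cadd = NA_real_,
                          confidence = NA_real_, sasa_percent = NA_real_,
                          maf = NA_real_, in_characterized_domain = NA) {
  df <- data.frame(
    gene = as.character(gene),
    protein_change = as.character(protein_change),
    classification = as.character(classification),
    ddg_fold = as.numeric(ddg_fold),
    cadd = as.numeric(cadd),
    confidence = as.numeric(confidence),
    sasa_percent = as.numeric(sasa_percent),
    maf = as.numeric(maf),
    in_characterized_domain = as.logical(in_characterized_domain),
    stringsAsFactors = FALSE
  )
  validate_variant_table(df)
}

#' Validate a variant table
#'
#' Enforces the range and uniqueness invariants of the variant table:
#' valid classification labels, confidence within \[0, 100\], MAF within
#' \[0, 1\], non-negative CADD and SASA, and unique
#' (gene, protein_change) pairs. Violations stop with an informative
#' error; values are never silently clamped.
#'
#' @param df A data.frame with the variant-table columns.
#' @return `df`, invisibly unchanged, with canonical column order.
#' @export
validate_variant_table <- function(df) {
  cols <- variant_table_columns()
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    stop("variant table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- !(df$classification %in% classification_labels())
  if (any(bad)) {
    stop("unknown classification token(s) '",
         paste(unique(df$classification[bad]), collapse = "', '"),
         "' at row(s) ", paste(utils::head(which(bad), 5), collapse = ", "))
  }
  key <- paste(df$gene, df$protein_change, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (gene, protein_change) pair: ",
         gsub("\r", " ", dup, fixed = TRUE))
  }
  chk_range <- function(x, lo, hi, what) {
    out <- !is.na(x) & (x < lo | x > hi)
    if (any(out)) {
      stop(what, " out of [", lo, ", ", hi, "] at row(s) ",
           paste(utils::head(which(out), 5), collapse = ", "))
    }
  }
  chk_range(df$confidence, 0, 100, "confidence")
  chk_range(df$maf, 0, 1, "maf")
  chk_range(df$cadd, 0, Inf, "cadd")
  chk_range(df$sasa_percent, 0, Inf, "sasa_percent")
  if (any(df$gene == "" | is.na(df$gene)) ||
      any(df$protein_change == "" | is.na(df$protein_change))) {
    stop("gene and protein_change must be non-empty")
  }
  df[, cols]
}

# Format a numeric column for TSV output: NA -> empty cell, otherwise full
# double precision so read-write roundtrips are lossless.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.15g", v)
  }, character(1))
  out
}

fmt_lgl <- function(x) {
  ifelse(is.na(x), "", ifelse(x, "TRUE", "FALSE"))
}

write_tsv_raw <- function(df_chr, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(df_chr), collapse = "\t"), con)
  if (nrow(df_chr) > 0) {
    rows <- do.call(paste, c(unname(as.list(df_chr)), sep = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Write a variant table to TSV
#'
#' Columns are written in the canonical order, rows in input order;
#' absent (NA) features become empty cells.
#'
#' @param records A validated variant table (data.frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_variant_table()]
#' @export
write_variant_table <- function(records, path) {
  records <- validate_variant_table(records)
  out <- data.frame(
    gene = records$gene,
    protein_change = records$protein_change,
    classification = records$classification,
    ddg_fold = fmt_num(records$ddg_fold),
    cadd = fmt_num(records$cadd),
    confidence = fmt_num(records$confidence),
    sasa_percent = fmt_num(records$sasa_percent),
    maf = fmt_num(records$maf),
    in_characterized_domain = fmt_lgl(records$in_characterized_domain),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  write_tsv_raw(out, path)
}

read_tsv_chr <- function(path, required_cols) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          na.strings = NULL, check.names = FALSE,
                          quote = "", stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

parse_num_col <- function(x, col) {
  blank <- x == "" | x == "NA"
  out <- rep(NA_real_, length(x))
  if (any(!blank)) {
    v <- suppressWarnings(as.numeric(x[!blank]))
    if (anyNA(v)) {
      stop("non-numeric value in column '", col, "': ",
           x[!blank][which(is.na(v))[1]])
    }
    out[!blank] <- v
  }
  out
}

parse_lgl_col <- function(x, col) {
  blank <- x == "" | x == "NA"
  out <- rep(NA, length(x))
  tok <- toupper(x[!blank])
  if (!all(tok %in% c("TRUE", "FALSE"))) {
    stop("non-logical value in column '", col, "'")
  }
  out[!blank] <- tok == "TRUE"
  out
}

#' Read a variant table from TSV
#'
#' Reads a tab-separated variant table with the canonical header. Empty
#' and `"NA"` cells in numeric columns become NA ("feature absent").
#' Unknown classification tokens and duplicate (gene, protein_change)
#' pairs are parse errors.
#'
#' @param path Path to a TSV file.
#' @return A validated variant table data.frame.
#' @seealso [write_variant_table()]
#' @export
read_variant_table <- function(path) {
  df <- read_tsv_chr(path, variant_table_columns())
  out <- data.frame(
    gene = df$gene,
    protein_change = df$protein_change,
    classification = df$classification,
    ddg_fold = parse_num_col(df$ddg_fold, "ddg_fold"),
    cadd = parse_num_col(df$cadd, "cadd"),
    confidence = parse_num_col(df$confidence, "confidence"),
    sasa_percent = parse_num_col(df$sasa_percent, "sasa_percent"),
    maf = parse_num_col(df$maf, "maf"),
    in_characterized_domain =
      parse_lgl_col(df$in_characterized_domain, "in_characterized_domain"),
    stringsAsFactors = FALSE
  )
  validate_variant_table(out)
}

#' Read a gene-length table
#'
#' Two-column TSV `gene`/`length` giving each protein's length in amino
#' acids. Lengths must be positive integers.
#'
#' @param path Path to a TSV file.
#' @return data.frame with columns `gene` (character) and `length`
#'   (integer).
#' @export
read_gene_lengths <- function(path) {
  df <- read_tsv_chr(path, c("gene", "length"))
  len <- parse_num_col(df$length, "length")
  if (any(is.na(len)) || any(len < 1) || any(len != round(len))) {
    stop("gene lengths must be positive integers")
  }
  data.frame(gene = df$gene, length = as.integer(len),
             stringsAsFactors = FALSE)
}

#' Write a gene-length table to TSV
#'
#' @param lengths data.frame with columns `gene` and `length`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_lengths <- function(lengths, path) {
  out <- data.frame(gene = as.character(lengths$gene),
                    length = as.character(as.integer(lengths$length)),
                    stringsAsFactors = FALSE)
  write_tsv_raw(out, path)
}

patient_case_columns <- function() {
  c("patient_id", "gene", "inheritance", "priority_variant",
    "second_variant", "second_classification", "segregation")
}

#' Read a patient-case table
#'
#' One row per proband: the gene and inheritance mode (`AR` or `AD`), the
#' candidate priority variant, an optional second variant with its
#' classification, and the segregation-analysis status. In the
#' `segregation` column, `"Yes"` maps to `confirmed`, `"No"` to
#' `refuted`, and `"NA"` or an empty cell to `unavailable` (segregation
#' testing not performed). A second variant of `"None"` or an empty cell
#' means no second variant; its classification must then be absent too.
#'
#' @param path Path to a TSV file with columns `patient_id`, `gene`,
#'   `inheritance`, `priority_variant`, `second_variant`,
#'   `second_classification`, `segregation`.
#' @return data.frame of validated patient cases; `segregation` is one of
#'   `"confirmed"`, `"unavailable"`, `"refuted"`.
#' @export
read_patient_cases <- function(path) {
  df <- read_tsv_chr(path, patient_case_columns())
  n <- nrow(df)
  inh <- df$inheritance
  if (n > 0 && !all(inh %in% c("AR", "AD"))) {
    stop("unknown inheritance token(s): ",
         paste(unique(inh[!inh %in% c("AR", "AD")]), collapse = ", "))
  }
  seg_map <- c("Yes" = "confirmed", "confirmed" = "confirmed",
               "No" = "refuted", "refuted" = "refuted",
               "NA" = "unavailable", "unavailable" = "unavailable")
  seg_tok <- df$segregation
  seg_tok[seg_tok == ""] <- "NA"
  if (n > 0 && !all(seg_tok %in% names(seg_map))) {
    stop("unknown segregation token(s): ",
         paste(unique(seg_tok[!seg_tok %in% names(seg_map)]),
               collapse = ", "))
  }
  second <- df$second_variant
  second[second %in% c("", "NA", "None")] <- NA_character_
  second_cls <- df$second_classification
  second_cls[second_cls %in% c("", "NA", "None")] <- NA_character_
  if (any(!is.na(second_cls) &
          !second_cls %in% classification_labels())) {
    stop("unknown second_classification token(s)")
  }
  if (any(is.na(second) != is.na(second_cls))) {
    stop("second_classification must be present exactly when ",
         "second_variant is present")
  }
  data.frame(
    patient_id = df$patient_id,
    gene = df$gene,
    inheritance = inh,
    priority_variant = df$priority_variant,
    second_variant = second,
    second_classification = second_cls,
    segregation = if (n > 0) unname(seg_map[seg_tok]) else character(0),
    stringsAsFactors = FALSE
  )
}
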