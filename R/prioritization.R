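# Applying calibrated thresholds to VUSs: selection, per-gene density
# summaries, class-conditional descriptive statistics, cross-tabulations
# of categorical features, and the hidden-pathogenic extrapolation.

#' Select priority VUSs at a threshold pair
#'
#' The subset of VUS-labeled, score-complete records called positive by
#' [classify_call()]; input order is preserved.
#'
#' @param records A variant table.
#' @param thresholds A [threshold_pair()].
#' @return Variant table of the selected records.
#' @export
select_priority_vus <- function(records, thresholds) {
  stopifnot(inherits(thresholds, "threshold_pair"))
  use <- records$classification == "VUS" &
    score_complete(records, thresholds)
  vus <- records[use, , drop = FALSE]
  if (nrow(vus) == 0) return(vus)
  vus[classify_call(vus, thresholds), , drop = FALSE]
}

#' Prioritized-variant density per 1000 amino acids
#'
#' @param n_prioritized Number of prioritized variants in the gene.
#' @param protein_length Protein length in amino acids.
#' @param digits Decimals to round the density to (default 1).
#' @return `1000 * n_prioritized / protein_length`, rounded.
#' @export
variant_density <- function(n_prioritized, protein_length, digits = 1) {
  stopifnot(all(protein_length >= 1))
  round(1000 * n_prioritized / protein_length, digits)
}

#' Per-gene summary of prioritized VUSs
#'
#' Aggregates prioritized variants by gene, computes the density of
#' prioritized VUSs per 1000 amino acids of protein length, and keeps
#' genes whose (unrounded) density reaches `min_density`. Densities and
#' mean scores are rounded to one decimal for reporting; means are taken
#' over unrounded per-variant values.
#'
#' @param prioritized A variant table of prioritized records (e.g. from
#'   [select_priority_vus()]).
#' @param lengths Gene-length data.frame (`gene`, `length`), as from
#'   [read_gene_lengths()]. Every prioritized gene must be present.
#' @param min_density Minimum density to report (default 30).
#' @return data.frame sorted by gene symbol with columns `gene`,
#'   `n_prioritized`, `protein_length`, `variant_density`, `mean_ddg`,
#'   `mean_cadd`.
#' @export
summarize_genes <- function(prioritized, lengths, min_density = 30) {
  genes <- sort(unique(prioritized$gene))
  missing <- setdiff(genes, lengths$gene)
  if (length(missing) > 0) {
    stop("gene(s) missing from the length table: ",
         paste(missing, collapse = ", "))
  }
  len <- lengths$length[match(genes, lengths$gene)]
  n <- as.integer(table(factor(prioritized$gene, levels = genes)))
  density_raw <- 1000 * n / len
  mean_ddg <- vapply(genes, function(g) {
    mean(prioritized$ddg_fold[prioritized$gene == g], na.rm = TRUE)
  }, numeric(1))
  mean_cadd <- vapply(genes, function(g) {
    mean(prioritized$cadd[prioritized$gene == g], na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(
    gene = genes,
    n_prioritized = n,
    protein_length = as.integer(len),
    variant_density = round(density_raw, 1),
    mean_ddg = round(mean_ddg, 1),
    mean_cadd = round(mean_cadd, 1),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[density_raw >= min_density, , drop = FALSE]
}

#' Class-conditional ddG statistics
#'
#' Per classification label (optionally split into high/low model
#' confidence at the [low_confidence_cutoff()]): number of records with a
#' ddG value, mean ddG, and the fractions of destabilizing (ddG > 0),
#' stabilizing (ddG < 0) and neutral (ddG exactly 0) variants. When both
#' a benign (B) and pathogenic (P) class are present, a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) comparison of their ddG locations is
#' attached as the `"b_vs_p_test"` attribute.
#'
#' @param records A variant table; rows without `ddg_fold` are dropped.
#' @param group_by NULL (no grouping) or `"confidence"` to split each
#'   class at confidence 70 into `"high"`/`"low"`.
#' @return data.frame with columns `class`, `group`, `n`, `mean_ddg`,
#'   `fraction_destabilizing`, `fraction_stabilizing`,
#'   `fraction_neutral`.
#' @export
class_statistics <- function(records, group_by = NULL) {
  stopifnot(is.null(group_by) || identical(group_by, "confidence"))
  use <- records[!is.na(records$ddg_fold), , drop = FALSE]
  if (!is.null(group_by)) {
    use <- use[!is.na(use$confidence), , drop = FALSE]
    grp <- ifelse(use$confidence >= low_confidence_cutoff(),
                  "high", "low")
  } else {
    grp <- rep("all", nrow(use))
  }
  lev <- classification_labels()
  rows <- list()
  for (cl in lev) {
    for (g in unique(grp)) {
      sel <- use$classification == cl & grp == g
      if (!any(sel)) next
      ddg <- use$ddg_fold[sel]
      rows[[length(rows) + 1]] <- data.frame(
        class = cl, group = g, n = length(ddg),
        mean_ddg = mean(ddg),
        fraction_destabilizing = mean(ddg > 0),
        fraction_stabilizing = mean(ddg < 0),
        fraction_neutral = mean(ddg == 0),
        stringsAsFactors = FALSE
      )
    }
  }
  present <- unique(use$classification)
  empty <- setdiff(lev, present)
  if (length(empty) > 0) {
    warning("class(es) with no ddG values omitted: ",
            paste(empty, collapse = ", "))
  }
  out <- do.call(rbind, rows)
  if (all(c("B", "P") %in% present)) {
    attr(out, "b_vs_p_test") <- stats::wilcox.test(
      use$ddg_fold[use$classification == "B"],
      use$ddg_fold[use$classification == "P"],
      alternative = "two.sided", exact = FALSE)
  }
  out
}

#' Cross-tabulate two categorical variant features
#'
#' Tabulates counts and percent-of-grand-total (one decimal) over two
#' categorical features: `"classification"`, `"confidence_bin"` (derived
#' from the `confidence` column via [confidence_bin()]) or
#' `"in_characterized_domain"`. Records missing either feature are
#' excluded and counted. Row/column margins are included via `Total`.
#'
#' @param records A variant table.
#' @param row_feature,column_feature Feature names.
#' @return List with `counts` (integer matrix with margins), `percent`
#'   (same shape, percent of grand total at one decimal) and
#'   `n_excluded_missing`.
#' @export
cross_tabulate <- function(records, row_feature, column_feature) {
  get_feature <- function(name) {
    switch(name,
      classification = factor(records$classification,
                              levels = classification_labels()),
      confidence_bin = {
        f <- factor(rep(NA_character_, nrow(records)),
                    levels = levels(confidence_bin(0)))
        ok <- !is.na(records$confidence)
        f[ok] <- confidence_bin(records$confidence[ok])
        f
      },
      in_characterized_domain = factor(records$in_characterized_domain,
                                       levels = c(FALSE, TRUE)),
      stop("unknown feature: ", name)
    )
  }
  rf <- get_feature(row_feature)
  cf <- get_feature(column_feature)
  keep <- !is.na(rf) & !is.na(cf)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(n_excluded, " record(s) missing a feature were excluded")
  }
  tab <- table(rf[keep], cf[keep], dnn = c(row_feature, column_feature))
  counts <- stats::addmargins(tab, FUN = list(Total = sum), quiet = TRUE)
  percent <- round(100 * counts / sum(tab), 1)
  list(counts = counts, percent = percent,
       n_excluded_missing = n_excluded)
}

#' Extrapolate pathogenic variants hidden among VUSs
#'
#' If a fraction f of known pathogenic variants destabilize folding
#' enough to exceed the thresholds, and the prioritized VUSs are assumed
#' to be that same fraction of all pathogenic variants still hidden among
#' the VUSs, then the hidden total is `n_prioritized_vus / f` and the
#' hidden pathogenic variants whose mechanism is *not* misfolding number
#' `n_prioritized_vus / f - n_prioritized_vus`. The fraction is rounded
#' (as a percentage, to `fraction_digits` decimals) before the division;
#' the unrounded variant is reported alongside.
#'
#' @param n_p_total Number of known pathogenic variants.
#' @param n_p_above Pathogenic variants exceeding the thresholds.
#' @param n_prioritized_vus Number of prioritized VUSs.
#' @param fraction_digits Decimals of the percentage to round to
#'   (default 1, e.g. 12.5).
#' @return List of class `"extrapolation_result"`: `misfolding_fraction`
#'   (rounded), `misfolding_fraction_unrounded`, `n_prioritized_vus`,
#'   `estimated_total_hidden_pathogenic`,
#'   `estimated_non_misfolding_pathogenic`, and `_unrounded` variants of
#'   the two estimates.
#' @export
estimate_hidden_pathogenic <- function(n_p_total, n_p_above,
                                       n_prioritized_vus,
                                       fraction_digits = 1) {
  stopifnot(n_p_total > 0, n_p_above <= n_p_total, n_prioritized_vus >= 0)
  if (n_p_above <= 0) {
    stop("no pathogenic variants above threshold; extrapolation undefined")
  }
  frac_raw <- n_p_above / n_p_total
  frac <- round(100 * frac_raw, fraction_digits) / 100
  total <- n_prioritized_vus / frac
  total_raw <- n_prioritized_vus / frac_raw
  structure(list(
    misfolding_fraction = frac,
    misfolding_fraction_unrounded = frac_raw,
    n_prioritized_vus = n_prioritized_vus,
    estimated_total_hidden_pathogenic = total,
    estimated_non_misfolding_pathogenic = total - n_prioritized_vus,
    estimated_total_hidden_pathogenic_unrounded = total_raw,
    estimated_non_misfolding_pathogenic_unrounded =
      total_raw - n_prioritized_vus
  ), class = "extrapolation_result")
}
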