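# Synthetic data emulating the statistical structure of an expert-curated
# deafness variant catalogue: five-tier class proportions and per-class
# confidence strata taken from the published class-by-confidence counts,
# class-conditional ddG marginals (Gaussian with a point mass at exactly
# zero for "neutral" substitutions) coupled to CADD scores through a
# Gaussian copula, burial bias for pathogenic classes, plus toy helix
# structures and patient cohorts. Everything is reproducible from the
# config seed.

# Published class-by-confidence-bin counts (columns <50, 50-70, 70-90,
# >90); their row sums give the class proportions.
dvd_confidence_counts <- function() {
  m <- rbind(
    B   = c(719, 231, 506, 269),
    LB  = c(15395, 3153, 5973, 3386),
    VUS = c(25707, 10306, 30106, 23647),
    LP  = c(579, 203, 827, 832),
    P   = c(1201, 470, 2084, 2573)
  )
  colnames(m) <- c("<50", "50-70", "70-90", ">90")
  m[classification_labels(), ]
}

default_gene_list <- function() {
  c("GJB2", "SLC26A4", "MYO7A", "CDH23", "OTOF", "TMC1", "MYO6",
    "TECTA", "TMPRSS3", "WFS1", "PCDH15", "OTOGL", "MYO3A", "HARS2",
    "GRXCR1", "PDZD7", "ATP6V1B1", "COCH", "ACTG1", "STRC")
}

#' Configuration of the synthetic variant generator
#'
#' Defaults emulate the catalogue the analysis is designed for: class
#' proportions and per-class confidence strata from the published
#' class-by-confidence counts; class-conditional ddG means of 0.13 (B)
#' and 0.80 (P) kcal/mol with a point mass at exactly zero for neutral
#' substitutions; a positive ddG-CADD correlation; burial bias for P/LP.
#' Standard deviations, the LB/VUS/LP ddG means and all CADD marginals
#' are the generator's own choices (see the package vignette), picked so
#' the overall destabilizing/stabilizing/neutral split approximates
#' 59/27/14 percent and roughly 17 percent of P variants exceed
#' 1.8 kcal/mol.
#'
#' @param n_variants Number of variants to draw.
#' @param class_proportions Named probability vector over the five
#'   labels; must sum to 1 (default: normalized published class counts).
#' @param confidence_bin_probs 5 x 4 matrix (rows = labels, columns =
#'   bins `<50`, `50-70`, `70-90`, `>90`) of per-class bin
#'   probabilities; rows must sum to 1.
#' @param ddg_class_params data.frame with columns `class`, `mean`,
#'   `sd`, `p_zero`: per-class ddG Gaussian parameters (kcal/mol) and
#'   the probability of an exact zero.
#' @param cadd_class_params data.frame with columns `class`, `mean`,
#'   `sd`.
#' @param ddg_cadd_correlation Gaussian-copula correlation between ddG
#'   and CADD within a class, in \[-1, 1\] (default 0.5).
#' @param genes Character vector of gene symbols assigned round-robin.
#' @param seed Integer seed making the draw reproducible.
#' @return List of class `"generator_config"`.
#' @export
generator_config <- function(n_variants = 50000,
                             class_proportions = NULL,
                             confidence_bin_probs = NULL,
                             ddg_class_params = NULL,
                             cadd_class_params = NULL,
                             ddg_cadd_correlation = 0.5,
                             genes = default_gene_list(),
                             seed = 1) {
  lev <- classification_labels()
  counts <- dvd_confidence_counts()
  if (is.null(class_proportions)) {
    class_proportions <- rowSums(counts) / sum(counts)
  }
  if (is.null(confidence_bin_probs)) {
    confidence_bin_probs <- counts / rowSums(counts)
  }
  if (is.null(ddg_class_params)) {
    ddg_class_params <- data.frame(
      class = lev,
      mean = c(0.13, 0.13, 0.45, 0.70, 0.80),
      sd = c(0.8, 0.8, 0.9, 1.1, 1.2),
      p_zero = rep(0.14, 5),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(cadd_class_params)) {
    cadd_class_params <- data.frame(
      class = lev,
      mean = c(15, 15, 20, 26, 27),
      sd = c(4, 4, 5, 4, 4),
      stringsAsFactors = FALSE
    )
  }
  cfg <- structure(list(
    n_variants = n_variants,
    class_proportions = class_proportions[lev],
    confidence_bin_probs = confidence_bin_probs[lev, , drop = FALSE],
    ddg_class_params = ddg_class_params,
    cadd_class_params = cadd_class_params,
    ddg_cadd_correlation = ddg_cadd_correlation,
    genes = genes,
    seed = as.integer(seed)
  ), class = "generator_config")
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  lev <- classification_labels()
  stopifnot(cfg$n_variants >= 1)
  p <- cfg$class_proportions
  if (length(p) != 5 || any(is.na(p)) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-9) {
    stop("class_proportions must be 5 non-negative values summing to 1")
  }
  bp <- cfg$confidence_bin_probs
  if (!all(dim(bp) == c(5, 4)) || any(bp < 0) ||
      any(abs(rowSums(bp) - 1) > 1e-9)) {
    stop("confidence_bin_probs rows must be 4 probabilities summing to 1")
  }
  dp <- cfg$ddg_class_params
  stopifnot(setequal(dp$class, lev), all(dp$sd > 0),
            all(dp$p_zero >= 0 & dp$p_zero <= 1))
  cp <- cfg$cadd_class_params
  stopifnot(setequal(cp$class, lev), all(cp$sd > 0))
  rho <- cfg$ddg_cadd_correlation
  if (!is.finite(rho) || rho < -1 || rho > 1) {
    stop("ddg_cadd_correlation must lie in [-1, 1]")
  }
  if (length(cfg$genes) < 1) stop("need at least one gene symbol")
  cfg
}

#' Generate a synthetic variant table
#'
#' Draws `n_variants` records per the [generator_config()]: class from
#' the class proportions; confidence uniform within a bin drawn from the
#' class's bin probabilities; (ddG, CADD) from a Gaussian copula with
#' the class marginals and the configured correlation, with ddG replaced
#' by exactly 0 at the class's point-mass probability; relative SASA
#' from a burial-biased Beta for P/LP and a broader Beta otherwise; MAF
#' log-uniform; domain membership more likely for P/LP. Gene symbols are
#' assigned round-robin with per-gene sequential residue numbers so
#' (gene, protein_change) is unique.
#'
#' @param config A [generator_config()].
#' @return A validated variant table of `n_variants` rows.
#' @export
generate_variant_table <- function(config = generator_config()) {
  config <- validate_generator_config(config)
  n <- config$n_variants
  lev <- classification_labels()
  set.seed(config$seed)

  cls <- sample(lev, n, replace = TRUE, prob = config$class_proportions)

  # confidence: bin per class, then uniform within the bin
  bin_lo <- c(0, 50, 70, 90)
  bin_hi <- c(50, 70, 90, 100)
  conf <- numeric(n)
  bin_idx <- integer(n)
  for (cl in lev) {
    sel <- which(cls == cl)
    if (length(sel) == 0) next
    b <- sample.int(4, length(sel), replace = TRUE,
                    prob = config$confidence_bin_probs[cl, ])
    bin_idx[sel] <- b
    conf[sel] <- stats::runif(length(sel), bin_lo[b], bin_hi[b])
  }

  # (ddg, cadd) via a Gaussian copula within each class
  rho <- config$ddg_cadd_correlation
  ddg <- numeric(n)
  cadd <- numeric(n)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  u_zero <- stats::runif(n)
  dp <- config$ddg_class_params
  cp <- config$cadd_class_params
  for (cl in lev) {
    sel <- which(cls == cl)
    if (length(sel) == 0) next
    d <- dp[dp$class == cl, ]
    cc <- cp[cp$class == cl, ]
    ddg[sel] <- d$mean + d$sd * z1[sel]
    ddg[sel][u_zero[sel] < d$p_zero] <- 0
    cadd[sel] <- pmax(0, cc$mean + cc$sd * z2[sel])
  }

  # burial bias: pathogenic classes sit in buried (low relative SASA),
  # benign classes in more exposed positions
  sasa <- numeric(n)
  path_cls <- cls %in% c("P", "LP")
  sasa[path_cls] <- 100 * stats::rbeta(sum(path_cls), 1.0, 4.0)
  sasa[!path_cls] <- 100 * stats::rbeta(sum(!path_cls), 1.4, 1.8)

  maf <- 10^stats::runif(n, -6, -2)
  in_domain <- stats::runif(n) < ifelse(path_cls, 0.75, 0.40)

  gene <- config$genes[((seq_len(n) - 1) %% length(config$genes)) + 1]
  pos <- stats::ave(seq_len(n), gene, FUN = seq_along)
  protein_change <- sprintf("p.Ala%dVal", pos)

  variant_table(
    gene = gene, protein_change = protein_change, classification = cls,
    ddg_fold = ddg, cadd = cadd, confidence = conf,
    sasa_percent = sasa, maf = maf, in_characterized_domain = in_domain
  )
}

#' Generate a toy poly-alanine helix as PDB text
#'
#' Writes an idealized alpha-helical poly-alanine backbone (rise 1.5
#' Angstrom and 100 degree twist per residue, so consecutive CA atoms sit
#' ~3.8 Angstrom apart) with N, CA, C, O and CB atoms per residue, and
#' plants the given per-residue pLDDT values in the temperature-factor
#' column, the AlphaFold convention. Several chains may be generated at
#' fixed offsets (e.g. two far-apart copies for additivity checks). The
#' geometry is deterministic; `seed` is accepted for interface symmetry
#' with the other generators.
#'
#' @param n_residues Residues per chain (>= 1).
#' @param plddt_profile Numeric vector of length `n_residues`, values in
#'   \[0, 100\]; recycled across chains.
#' @param seed Unused by the deterministic geometry; kept for a uniform
#'   generator interface.
#' @param chain_ids Character vector of chain identifiers.
#' @param offsets Numeric matrix (`length(chain_ids)` x 3) of per-chain
#'   translations in Angstrom.
#' @return A single string of PDB text (parseable by
#'   [parse_structure()]).
#' @export
generate_toy_structure <- function(n_residues, plddt_profile, seed = 0,
                                   chain_ids = "A",
                                   offsets = matrix(0, length(chain_ids),
                                                    3)) {
  if (n_residues < 1) stop("n_residues must be >= 1")
  stopifnot(length(plddt_profile) == n_residues,
            all(plddt_profile >= 0 & plddt_profile <= 100),
            nrow(offsets) == length(chain_ids))
  lines <- character(0)
  serial <- 0
  for (ci in seq_along(chain_ids)) {
    off <- offsets[ci, ]
    for (i in seq_len(n_residues)) {
      theta <- (i - 1) * 100 * pi / 180
      z <- (i - 1) * 1.5
      # backbone atoms placed on concentric helical tracks; bond-accurate
      # geometry is not needed for confidence or SASA behaviour
      coords <- rbind(
        N  = c(1.45 * cos(theta - 0.50), 1.45 * sin(theta - 0.50),
               z - 0.90),
        CA = c(2.30 * cos(theta), 2.30 * sin(theta), z),
        C  = c(1.95 * cos(theta + 0.45), 1.95 * sin(theta + 0.45),
               z + 0.95),
        O  = c(2.40 * cos(theta + 0.60), 2.40 * sin(theta + 0.60),
               z + 2.05),
        CB = c(3.65 * cos(theta + 0.12), 3.65 * sin(theta + 0.12),
               z - 0.35)
      )
      elements <- c("N", "C", "C", "O", "C")
      for (a in seq_len(nrow(coords))) {
        serial <- serial + 1
        xyz <- coords[a, ] + off
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, rownames(coords)[a], "ALA", chain_ids[ci], i,
          xyz[1], xyz[2], xyz[3], 1.00, plddt_profile[i], elements[a]))
      }
    }
    lines <- c(lines, "TER")
  }
  paste(c(lines, "END", ""), collapse = "\n")
}

#' Generate a synthetic patient cohort
#'
#' Reproducible cohort mixing autosomal recessive and dominant cases and
#' second-variant configurations across the branches of the diagnostic
#' rule. AR cases carry a second P/LP variant with probability
#' `fraction_with_second_pathogenic` (segregation then confirmed or
#' unavailable), otherwise a second VUS/LB variant or none, occasionally
#' with refuted segregation.
#'
#' @param n Number of cases.
#' @param fraction_ar Fraction of autosomal recessive cases.
#' @param fraction_with_second_pathogenic Among AR cases, fraction with a
#'   second P/LP variant.
#' @param seed Integer seed.
#' @return Patient-case data.frame in the [read_patient_cases()] layout.
#' @export
generate_patient_cohort <- function(n, fraction_ar = 0.8,
                                    fraction_with_second_pathogenic = 0.8,
                                    seed = 1) {
  stopifnot(n >= 0, fraction_ar >= 0, fraction_ar <= 1,
            fraction_with_second_pathogenic >= 0,
            fraction_with_second_pathogenic <= 1)
  set.seed(as.integer(seed))
  if (n == 0) {
    return(read_patient_cases(empty_patient_file()))
  }
  genes <- default_gene_list()
  gene <- genes[((seq_len(n) - 1) %% length(genes)) + 1]
  inh <- ifelse(stats::runif(n) < fraction_ar, "AR", "AD")
  priority <- sprintf("p.Met%dLys", 100 + seq_len(n))
  second <- rep(NA_character_, n)
  second_cls <- rep(NA_character_, n)
  seg <- rep("unavailable", n)
  for (i in seq_len(n)) {
    if (inh[i] == "AR") {
      if (stats::runif(1) < fraction_with_second_pathogenic) {
        second[i] <- sprintf("p.Arg%dTer", 50 + i)
        second_cls[i] <- sample(c("P", "LP"), 1)
        seg[i] <- sample(c("confirmed", "unavailable"), 1)
      } else if (stats::runif(1) < 0.5) {
        second[i] <- sprintf("p.Gly%dAsp", 50 + i)
        second_cls[i] <- sample(c("VUS", "LB"), 1)
        seg[i] <- sample(c("confirmed", "unavailable", "refuted"), 1)
      }
    }
  }
  data.frame(
    patient_id = sprintf("PT%04d", seq_len(n)),
    gene = gene, inheritance = inh, priority_variant = priority,
    second_variant = second, second_classification = second_cls,
    segregation = seg, stringsAsFactors = FALSE
  )
}

empty_patient_file <- function() {
  path <- tempfile(fileext = ".tsv")
  writeLines(paste(patient_case_columns(), collapse = "\t"), path)
  path
}
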