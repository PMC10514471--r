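#' Derived metabolic quantities
#'
#' Energy charges summarize the phosphorylation state of a nucleotide
#' pool: charge = (NTP + 0.5 NDP) / (NTP + NDP + NMP), a number in
#' \[0, 1\] (1 = fully charged pool). Metabolite ratios such as
#' lactate/pyruvate and malate/aspartate serve as indirect readouts of the
#' cytoplasmic NADH/NAD+ redox state. Inputs are per-sample concentration
#' profiles (already normalized, e.g. pmol/mg tissue); group comparisons
#' beyond mean +/- SEM are left to standard statistical tooling.
#'
#' @name derived-metrics
NULL

.lookup_metabolite <- function(concentrations, name, required = TRUE) {
  nm <- tolower(names(concentrations))
  key <- tolower(name)
  hit <- which(nm == key)
  if (length(hit) >= 1L) return(unname(concentrations[hit[1]]))
  # UDP-HexNAc is the sum of its two interconvertible components
  if (key == "udp-hexnac") {
    g1 <- which(nm == "udp-glcnac"); g2 <- which(nm == "udp-galnac")
    if (length(g1) == 1L && length(g2) == 1L) {
      return(unname(concentrations[g1] + concentrations[g2]))
    }
  }
  if (required) stop("metabolite '", name, "' missing from profile")
  NA_real_
}

#' Construct a metabolite profile
#'
#' @param sample_id Sample label.
#' @param group Group label (e.g. `"WT"`, `"KO"`).
#' @param concentrations Named non-negative numeric vector; names are
#'   matched case-insensitively, must be unique.
#' @return A `metabolite_profile`.
#' @export
metabolite_profile <- function(sample_id, group, concentrations) {
  if (is.null(names(concentrations)) || any(!nzchar(names(concentrations)))) {
    stop("concentrations must be a fully named vector")
  }
  if (anyDuplicated(tolower(names(concentrations)))) {
    stop("duplicate metabolite names in profile")
  }
  if (any(concentrations < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative")
  }
  structure(list(sample_id = as.character(sample_id),
                 group = as.character(group),
                 concentrations = concentrations),
            class = "metabolite_profile")
}

.conc_of <- function(x) {
  if (inherits(x, "metabolite_profile")) x$concentrations
  else if (is.numeric(x) && !is.null(names(x))) x
  else stop("expected a metabolite_profile or a named numeric vector")
}

.energy_charge <- function(conc, tp, dp, mp) {
  vals <- c(.lookup_metabolite(conc, tp), .lookup_metabolite(conc, dp),
            .lookup_metabolite(conc, mp))
  denom <- sum(vals)
  if (denom == 0) return(NA_real_)
  (vals[1] + 0.5 * vals[2]) / denom
}

#' Adenylate energy charge
#'
#' `(ATP + 0.5 ADP) / (ATP + ADP + AMP)`; `NA` when the pool is empty.
#'
#' @param profile A [metabolite_profile()] or named concentration vector
#'   containing ATP, ADP and AMP.
#' @return Fraction in \[0, 1\] or `NA`.
#' @examples
#' adenylate_energy_charge(c(ATP = 1, ADP = 1, AMP = 1)) # 0.5
#' @export
adenylate_energy_charge <- function(profile) {
  .energy_charge(.conc_of(profile), "ATP", "ADP", "AMP")
}

#' Guanylate energy charge
#'
#' `(GTP + 0.5 GDP) / (GTP + GDP + GMP)`; `NA` when the pool is empty.
#'
#' @inheritParams adenylate_energy_charge
#' @export
guanylate_energy_charge <- function(profile) {
  .energy_charge(.conc_of(profile), "GTP", "GDP", "GMP")
}

#' Metabolite concentration ratio
#'
#' @param profile A [metabolite_profile()] or named concentration vector.
#' @param numerator,denominator Metabolite names (case-insensitive;
#'   `"UDP-HexNAc"` resolves to UDP-GlcNAc + UDP-GalNAc when only the
#'   components are present).
#' @return Plain ratio; `NA` with a warning when the denominator is 0.
#' @examples
#' metabolite_ratio(c(lactate = 10, pyruvate = 5), "lactate", "pyruvate") # 2
#' @export
metabolite_ratio <- function(profile, numerator, denominator) {
  conc <- .conc_of(profile)
  num <- .lookup_metabolite(conc, numerator)
  den <- .lookup_metabolite(conc, denominator)
  if (den == 0) {
    warning("denominator metabolite '", denominator, "' is 0; ratio undefined")
    return(NA_real_)
  }
  num / den
}

#' Read a metabolite table with group assignments
#'
#' Input TSV: rows = metabolites (first column `metabolite`), remaining
#' columns = samples. `groups` maps sample name to group label.
#'
#' @param path TSV path.
#' @param groups Named character vector, `sample -> group`.
#' @return List of [metabolite_profile()]s, one per sample column.
#' @export
read_metabolite_table <- function(path, groups) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  if (!identical(tolower(names(tb)[1]), "metabolite")) {
    stop("first column of the metabolite table must be 'metabolite'")
  }
  samples <- names(tb)[-1]
  missing <- setdiff(samples, names(groups))
  if (length(missing) > 0) {
    stop("no group assigned to sample(s): ", paste(missing, collapse = ", "))
  }
  lapply(samples, function(s) {
    conc <- stats::setNames(as.numeric(tb[[s]]), tb$metabolite)
    metabolite_profile(s, groups[[s]], conc)
  })
}

#' Per-sample derived metrics with group mean +/- SEM
#'
#' Computes the adenylate and guanylate energy charges and any requested
#' metabolite ratios for each sample, then summarizes each metric per
#' group as mean and standard error of the mean.
#'
#' @param profiles List of [metabolite_profile()]s.
#' @param ratios Named list of `c(numerator, denominator)` pairs; default
#'   the two redox surrogate ratios.
#' @return List with `per_sample` (sample x metric data frame) and
#'   `group_summary` (group x metric mean/SEM, long format).
#' @export
derived_metrics_table <- function(profiles, ratios = list(
  lactate_pyruvate = c("lactate", "pyruvate"),
  malate_aspartate = c("malate", "aspartate"))) {
  stopifnot(length(profiles) >= 1L)
  per <- do.call(rbind, lapply(profiles, function(p) {
    row <- data.frame(sample_id = p$sample_id, group = p$group,
                      adenylate_energy_charge = adenylate_energy_charge(p),
                      guanylate_energy_charge = guanylate_energy_charge(p),
                      stringsAsFactors = FALSE)
    for (rn in names(ratios)) {
      row[[rn]] <- metabolite_ratio(p, ratios[[rn]][1], ratios[[rn]][2])
    }
    row
  }))
  rownames(per) <- NULL
  metrics <- setdiff(names(per), c("sample_id", "group"))
  sum_rows <- list()
  for (g in unique(per$group)) {
    sub <- per[per$group == g, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]][!is.na(sub[[m]])]
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        group = g, metric = m, n = length(v),
        mean = if (length(v) > 0) mean(v) else NA_real_,
        sem = if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  list(per_sample = per, group_summary = do.call(rbind, sum_rows))
}
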