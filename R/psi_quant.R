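#' Percent spliced-in from junction reads
#'
#' An included cassette exon contributes two junction reads (upstream and
#' downstream flanking introns); a skipped exon contributes one (the
#' exon-bridging skip junction). The estimator therefore half-weights
#' inclusion-supporting reads:
#'
#' \deqn{PSI = \frac{0.5 I}{E + 0.5 I}}
#'
#' with I = inclusion-supporting reads (both flanking junctions pooled) and
#' E = exclusion-supporting reads. PSI is undefined (NA) when I = E = 0;
#' "no inclusion evidence" is only a zero when exclusion reads exist.
#'
#' @name psi-quantification
NULL

#' Classify junction records against a cassette model
#'
#' A record supports inclusion iff its intron matches one of the model's
#' flanking introns at both boundaries exactly; it supports exclusion iff
#' it matches the skip intron (upstream exon end to downstream exon start)
#' exactly. Everything else — other sequences, shifted boundaries,
#' overlapping but non-identical introns — is ignored. No tolerance window
#' is applied.
#'
#' @param model A [cassette_exon_model()].
#' @param junctions Junction data frame (see [junction-io]).
#' @param count_mode `"unique"` (default) counts unique-mapping reads only;
#'   `"all"` adds multi-mapping reads.
#' @return Named numeric vector `c(inclusion_up, inclusion_down, exclusion)`.
#' @export
classify_junctions <- function(model, junctions,
                               count_mode = c("unique", "all")) {
  count_mode <- match.arg(count_mode)
  stopifnot(inherits(model, "cassette_exon_model"))
  ii <- model_introns(model)
  reads <- junctions$unique_reads +
    if (count_mode == "all") junctions$multi_reads else 0
  on_seq <- junctions$seq_name == model$seq_name
  match_iv <- function(iv) {
    on_seq & junctions$intron_start == iv$start & junctions$intron_end == iv$end
  }
  c(inclusion_up = sum(reads[match_iv(ii$upstream_intron)]),
    inclusion_down = sum(reads[match_iv(ii$downstream_intron)]),
    exclusion = sum(reads[match_iv(ii$skip_intron)]))
}

#' Compute PSI from classified counts
#'
#' @param inclusion_up,inclusion_down Reads on the upstream / downstream
#'   flanking junction.
#' @param exclusion Reads on the skip junction.
#' @return PSI in \[0, 1\], or `NA` when there is no evidence at all.
#' @examples
#' compute_psi(10, 10, 10) # 0.5
#' compute_psi(0, 0, 5)    # 0
#' compute_psi(0, 0, 0)    # NA
#' @export
compute_psi <- function(inclusion_up, inclusion_down, exclusion) {
  if (any(c(inclusion_up, inclusion_down, exclusion) < 0)) {
    stop("read counts must be non-negative")
  }
  i_half <- 0.5 * (inclusion_up + inclusion_down)
  denom <- exclusion + i_half
  if (denom == 0) return(NA_real_)
  i_half / denom
}

#' One dataset's PSI estimate
#'
#' @param dataset_id,species,tissue Grouping labels.
#' @param inclusion_up,inclusion_down,exclusion Classified read counts.
#' @return One-row data frame with the counts and the PSI.
#' @export
psi_estimate <- function(dataset_id, species, tissue,
                         inclusion_up, inclusion_down, exclusion) {
  data.frame(
    dataset_id = as.character(dataset_id), species = as.character(species),
    tissue = as.character(tissue),
    inclusion_up = inclusion_up, inclusion_down = inclusion_down,
    exclusion = exclusion,
    psi = compute_psi(inclusion_up, inclusion_down, exclusion),
    stringsAsFactors = FALSE
  )
}

#' PSI for one junction table against a model
#'
#' Convenience wrapper: classify, then estimate. With `min_reads > 0`,
#' estimates whose total informative reads (I + E) fall below the cutoff
#' have their PSI suppressed to `NA` (counts are kept).
#'
#' @inheritParams classify_junctions
#' @param dataset_id,species,tissue Labels for the estimate.
#' @param min_reads Minimum informative reads for a defined PSI (default 0:
#'   no filter, low-evidence estimates are reported and their support shown
#'   in the counts).
#' @return One-row estimate data frame.
#' @export
psi_from_junctions <- function(model, junctions, dataset_id,
                               species = "NA", tissue = "NA",
                               min_reads = 0,
                               count_mode = c("unique", "all")) {
  k <- classify_junctions(model, junctions, count_mode)
  est <- psi_estimate(dataset_id, species, tissue,
                      k[["inclusion_up"]], k[["inclusion_down"]],
                      k[["exclusion"]])
  if (sum(k) < min_reads) est$psi <- NA_real_
  est
}

#' Aggregate PSI estimates by species and tissue
#'
#' Unweighted mean and sample (n-1) standard deviation of the defined PSIs
#' per group, plus the group's total informative reads (for display
#' weighting, e.g. circle sizes). Undefined PSIs are excluded from the
#' mean/SD and tallied in the `skipped` attribute; a group with no defined
#' PSI is omitted with a warning.
#'
#' @param estimates Data frame of PSI estimates.
#' @param group_by Grouping columns (default species, tissue).
#' @param sd_mode `"sample"` (n-1, default) or `"population"`.
#' @return Data frame with columns `species`, `tissue` (the grouping
#'   columns), `n_datasets`, `mean_psi`, `sd_psi` (`NA` when a single
#'   dataset), `total_reads`; attribute `skipped` = number of undefined
#'   estimates excluded.
#' @export
aggregate_psi <- function(estimates, group_by = c("species", "tissue"),
                          sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(all(group_by %in% names(estimates)))
  defined <- !is.na(estimates$psi)
  skipped <- sum(!defined)
  groups_all <- unique(estimates[group_by])
  e <- estimates[defined, , drop = FALSE]
  key <- interaction(e[group_by], drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(e, key), function(g) {
    n <- nrow(g)
    s <- if (n >= 2) {
      v <- stats::sd(g$psi)
      if (sd_mode == "population") v * sqrt((n - 1) / n) else v
    } else NA_real_
    cbind(
      g[1, group_by, drop = FALSE],
      data.frame(n_datasets = n, mean_psi = mean(g$psi), sd_psi = s,
                 total_reads = sum(g$inclusion_up + g$inclusion_down +
                                     g$exclusion))
    )
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- cbind(groups_all[0, , drop = FALSE],
                 data.frame(n_datasets = integer(), mean_psi = numeric(),
                            sd_psi = numeric(), total_reads = numeric()))
  }
  rownames(out) <- NULL
  ord <- do.call(order, c(unname(as.list(out[group_by])),
                          list(method = "radix")))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) < nrow(groups_all)) {
    warning(nrow(groups_all) - nrow(out),
            " group(s) had no defined PSI and were omitted")
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write an aggregated PSI summary table
#'
#' @param summary Output of [aggregate_psi()].
#' @param path Output TSV path.
#' @param provenance Optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_psi_summary <- function(summary, path, provenance = NULL) {
  s <- summary
  s$mean_psi <- sprintf("%.6f", s$mean_psi)
  s$sd_psi <- ifelse(is.na(summary$sd_psi), "",
                     sprintf("%.6f", summary$sd_psi))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  writeLines(paste(names(s), collapse = "\t"), con)
  if (nrow(s) > 0L) {
    writeLines(do.call(paste, c(unname(as.list(s)), sep = "\t")), con)
  }
  invisible(path)
}
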