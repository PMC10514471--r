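#' Cis-regulatory element scanning
#'
#' The cassette exon's inclusion is governed by position-dependent trans
#' factors: SR proteins (e.g. SRSF1) bound in the exon enhance and bound in
#' an intron repress splicing at the 5' splice site; hnRNP H/F G-runs do
#' the opposite (exonic = silencer, intronic = enhancer); Rbfox (U)GCAUG
#' elements enhance from the downstream intron and repress from the exon or
#' upstream intron. The scanners below report motif occurrences together
#' with these position-rule effect annotations — annotations of binding
#' potential, not predictions of measured splicing outcomes.
#'
#' Hit coordinates use the package-wide 0-based half-open convention,
#' relative to the start of the annotated sequence.
#'
#' @name cis-elements
NULL

.region_levels <- c("upstream_intron", "exon", "downstream_intron")

#' Annotate a sequence with intron/exon/intron regions
#'
#' @param sequence Nucleotide text (RNA accepted, stored as uppercase DNA).
#' @param up_len,exon_len,down_len Lengths of the upstream intron segment,
#'   the exon, and the downstream intron segment. Must sum to the sequence
#'   length (the three spans partition the sequence).
#' @return A `region_sequence`: list with `sequence` and a `regions` data
#'   frame (`region`, `start`, `end`, 0-based half-open).
#' @export
region_sequence <- function(sequence, up_len, exon_len, down_len) {
  seqc <- normalize_dna(as.character(sequence))
  lens <- c(up_len, exon_len, down_len)
  if (any(lens < 0)) stop("region lengths must be non-negative")
  if (sum(lens) != nchar(seqc)) {
    stop("region lengths (", sum(lens), ") do not cover the sequence (",
         nchar(seqc), " nt)")
  }
  ends <- cumsum(lens)
  structure(
    list(sequence = seqc,
         regions = data.frame(region = .region_levels,
                              start = c(0, ends[1], ends[2]),
                              end = ends, stringsAsFactors = FALSE)),
    class = "region_sequence"
  )
}

#' @export
print.region_sequence <- function(x, ...) {
  lens <- x$regions$end - x$regions$start
  cat("<region_sequence> ", nchar(x$sequence), " nt (",
      paste(x$regions$region, lens, sep = "=", collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

# region label for [start, end); NA when the span crosses a boundary
.region_of <- function(rs, start, end) {
  r <- rs$regions
  hit <- r$region[r$start <= start & end <= r$end]
  if (length(hit) == 1L) hit else NA_character_
}

.motif_hits <- function(motif_id = character(), start = numeric(),
                        end = numeric(), region = character(),
                        score = numeric(), predicted_effect = character(),
                        note = character()) {
  data.frame(motif_id = motif_id, start = start, end = end, region = region,
             score = score, predicted_effect = predicted_effect, note = note,
             stringsAsFactors = FALSE)
}

.effect_for <- function(region, enhance_in, repress_in) {
  as.character(ifelse(is.na(region), "not_applicable",
         ifelse(region %in% enhance_in, "enhance",
                ifelse(region %in% repress_in, "repress",
                       "not_applicable"))))
}

#' Read / construct an additive position weight matrix
#'
#' The PWM file is a TSV whose first column is the position (1..width) and
#' whose `A`, `C`, `G`, `T` columns hold per-letter additive scores; a
#' leading comment line `# motif_id=<id> threshold=<t>` carries metadata.
#' The packaged SRSF1 (SF2/ASF) matrix is at
#' `system.file("extdata", "srsf1_sf2asf_pwm.tsv", package = "cassPSI")`.
#'
#' @param path PWM file path.
#' @return A `pwm` object: list with `motif_id`, `width`, `weights`
#'   (width x 4 matrix, columns A,C,G,T) and `threshold`.
#' @export
read_pwm <- function(path) {
  ln <- readLines(path, warn = FALSE)
  meta <- ln[startsWith(ln, "#")]
  motif_id <- "PWM"; threshold <- 0
  if (length(meta) > 0L) {
    m1 <- regmatches(meta[1], regexec("motif_id=(\\S+)", meta[1]))[[1]]
    if (length(m1) == 2L) motif_id <- m1[2]
    m2 <- regmatches(meta[1], regexec("threshold=([-0-9.eE+]+)", meta[1]))[[1]]
    if (length(m2) == 2L) threshold <- as.numeric(m2[2])
  }
  tb <- utils::read.delim(textConnection(ln[!startsWith(ln, "#")]),
                          stringsAsFactors = FALSE)
  if (!all(c("A", "C", "G", "T") %in% names(tb))) {
    stop("PWM file must have columns A, C, G, T")
  }
  w <- as.matrix(tb[, c("A", "C", "G", "T")])
  pwm(w, motif_id = motif_id, threshold = threshold)
}

#' @rdname read_pwm
#' @param weights Numeric width x 4 matrix (columns A, C, G, T).
#' @param motif_id Motif label.
#' @param threshold Default reporting threshold for [scan_pwm()].
#' @export
pwm <- function(weights, motif_id = "PWM", threshold = 0) {
  weights <- as.matrix(weights)
  if (ncol(weights) != 4L) stop("PWM weights need 4 columns (A, C, G, T)")
  colnames(weights) <- c("A", "C", "G", "T")
  if (any(!is.finite(weights))) stop("PWM weights must be finite")
  rownames(weights) <- NULL
  structure(list(motif_id = motif_id, width = nrow(weights),
                 weights = weights, threshold = threshold),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$motif_id, ", width ", x$width, ", threshold ",
      x$threshold, "\n", sep = "")
  invisible(x)
}

#' Score one k-mer with an additive PWM
#'
#' Additive convention: the score of a window is the sum over positions of
#' the weight of the observed letter (this is the ESEfinder-style score for
#' which the packaged SRSF1 matrix gives CACACGG = 5.86).
#'
#' @param pwm A [pwm()].
#' @param kmer Text of length `pwm$width` (RNA accepted).
#' @return Numeric score.
#' @export
score_pwm_window <- function(pwm, kmer) {
  stopifnot(inherits(pwm, "pwm"))
  kmer <- normalize_dna(kmer)
  if (nchar(kmer) != pwm$width) {
    stop("k-mer length ", nchar(kmer), " != PWM width ", pwm$width)
  }
  letters <- strsplit(kmer, "", fixed = TRUE)[[1]]
  idx <- match(letters, c("A", "C", "G", "T"))
  if (anyNA(idx)) stop("invalid letter in k-mer '", kmer, "'")
  sum(pwm$weights[cbind(seq_len(pwm$width), idx)])
}

#' Scan an annotated sequence with a PWM
#'
#' Every window of width `pwm$width` fully inside the sequence is scored;
#' windows scoring at or above the threshold are reported (all windows when
#' `report_below_threshold`). The SR-protein position rule annotates exonic
#' hits as `enhance` and intronic hits as `repress`; windows straddling a
#' region boundary get region `NA` and effect `not_applicable`.
#'
#' @param rs A [region_sequence()].
#' @param pwm A [pwm()].
#' @param threshold Score cutoff; default the matrix's own threshold.
#' @param report_below_threshold Report every window regardless of score.
#' @return Motif-hit data frame (`motif_id`, `start`, `end`, `region`,
#'   `score`, `predicted_effect`, `note`), in increasing `start` order.
#' @export
scan_pwm <- function(rs, pwm, threshold = pwm$threshold,
                     report_below_threshold = FALSE) {
  stopifnot(inherits(rs, "region_sequence"), inherits(pwm, "pwm"))
  n <- nchar(rs$sequence)
  w <- pwm$width
  if (n < w) return(.motif_hits())
  letters <- strsplit(rs$sequence, "", fixed = TRUE)[[1]]
  idx <- match(letters, c("A", "C", "G", "T"))
  idx[is.na(idx)] <- NA  # N scores as NA -> window dropped
  starts <- 0:(n - w)
  scores <- vapply(starts, function(s) {
    ii <- idx[(s + 1):(s + w)]
    if (anyNA(ii)) return(NA_real_)
    sum(pwm$weights[cbind(seq_len(w), ii)])
  }, numeric(1))
  keep <- if (report_below_threshold) !is.na(scores)
          else !is.na(scores) & scores >= threshold
  starts <- starts[keep]; scores <- scores[keep]
  region <- vapply(starts, function(s) .region_of(rs, s, s + w), character(1))
  .motif_hits(
    motif_id = rep(pwm$motif_id, length(starts)),
    start = starts, end = starts + w, region = region, score = scores,
    predicted_effect = .effect_for(region, "exon",
                                   c("upstream_intron", "downstream_intron")),
    note = rep("", length(starts))
  )
}

#' Find Rbfox (U)GCAUG elements
#'
#' Reports every GCAUG (DNA: GCATG) occurrence; the `note` column records
#' whether the core is preceded by U/T (the canonical (U)GCAUG element).
#' Position rule: downstream-intron hits enhance, exonic and
#' upstream-intron hits repress inclusion.
#'
#' @param rs A [region_sequence()].
#' @return Motif-hit data frame; hit span covers the 5-nt GCATG core.
#' @export
find_rbfox_motifs <- function(rs) {
  stopifnot(inherits(rs, "region_sequence"))
  m <- gregexpr("(?=GCATG)", rs$sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) return(.motif_hits())
  starts <- as.numeric(m) - 1  # to 0-based
  region <- vapply(starts, function(s) .region_of(rs, s, s + 5), character(1))
  u_prev <- starts > 0 &
    substring(rs$sequence, starts, starts) == "T"
  .motif_hits(
    motif_id = rep("RBFOX", length(starts)),
    start = starts, end = starts + 5, region = region,
    score = rep(NA_real_, length(starts)),
    predicted_effect = .effect_for(region, "downstream_intron",
                                   c("exon", "upstream_intron")),
    note = ifelse(u_prev, "U_preceded", "")
  )
}

#' Find hnRNP H/F G-runs
#'
#' Maximal runs of at least `min_run` consecutive G (not extendable on
#' either side). Position rule: exonic runs are silencers (`repress`),
#' intronic runs are enhancers (`enhance`).
#'
#' @param rs A [region_sequence()].
#' @param min_run Minimum run length (default 3, the shortest G-run the
#'   hnRNP H/F literature treats as a binding element).
#' @return Motif-hit data frame; `score` holds the run length.
#' @export
find_g_runs <- function(rs, min_run = 3) {
  stopifnot(inherits(rs, "region_sequence"))
  if (min_run < 1) stop("min_run must be >= 1")
  m <- gregexpr("G+", rs$sequence)[[1]]
  if (m[1] == -1L) return(.motif_hits())
  starts <- as.numeric(m) - 1
  lens <- attr(m, "match.length")
  keep <- lens >= min_run
  starts <- starts[keep]; lens <- lens[keep]
  region <- mapply(function(s, l) .region_of(rs, s, s + l), starts, lens)
  region <- as.character(region)
  .motif_hits(
    motif_id = rep("G_RUN", length(starts)),
    start = starts, end = starts + lens, region = region, score = lens,
    predicted_effect = .effect_for(region,
                                   c("upstream_intron", "downstream_intron"),
                                   "exon"),
    note = rep("", length(starts))
  )
}

#' Motif presence/absence across species
#'
#' For each species' annotated sequence and each motif specification,
#' records whether the motif occurs (optionally restricted to one region)
#' and at which first position. With a designated clade, each motif is
#' flagged clade-specific when present in every clade member and absent
#' outside it — the pattern expected of a regulatory element conserved in
#' mammals but not in other vertebrates.
#'
#' @param per_species Named list of [region_sequence()] objects.
#' @param motifs Named list of motif specs; each spec is a list with
#'   `type` (`"pattern"`, `"g_run"`, `"rbfox"`, or `"pwm"`), plus
#'   `pattern =` (for `"pattern"`), `min_run =` (for `"g_run"`),
#'   `pwm =`/`threshold =` (for `"pwm"`), and optional `region =` to
#'   restrict where the motif must lie.
#' @param clade Character vector of species names forming the focal clade
#'   (empty: no clade summary).
#' @return Data frame species x motif of logicals, with attributes
#'   `positions` (list of first-hit 0-based positions, NA when absent) and
#'   `clade_specific` (named logical per motif, when a clade was given).
#' @export
motif_conservation <- function(per_species, motifs, clade = character()) {
  stopifnot(is.list(per_species), length(per_species) >= 1L,
            !is.null(names(per_species)))
  if (length(clade) > 0 && !all(clade %in% names(per_species))) {
    stop("clade names must be a subset of the species names")
  }
  hits_for <- function(rs, spec) {
    h <- switch(spec$type,
      pattern = {
        pat <- normalize_dna(spec$pattern)
        m <- gregexpr(paste0("(?=", pat, ")"), rs$sequence, perl = TRUE)[[1]]
        if (m[1] == -1L) .motif_hits() else {
          st <- as.numeric(m) - 1
          w <- nchar(pat)
          .motif_hits(motif_id = rep("pattern", length(st)), start = st,
                      end = st + w,
                      region = vapply(st, function(s) .region_of(rs, s, s + w),
                                      character(1)),
                      score = rep(NA_real_, length(st)),
                      predicted_effect = rep("not_applicable", length(st)),
                      note = rep("", length(st)))
        }
      },
      g_run = find_g_runs(rs, min_run = if (is.null(spec$min_run)) 3
                                        else spec$min_run),
      rbfox = find_rbfox_motifs(rs),
      pwm = scan_pwm(rs, spec$pwm,
                     threshold = if (is.null(spec$threshold))
                       spec$pwm$threshold else spec$threshold),
      stop("unknown motif spec type '", spec$type, "'")
    )
    if (!is.null(spec$region)) h <- h[!is.na(h$region) &
                                        h$region == spec$region, , drop = FALSE]
    h
  }
  sp <- names(per_species)
  present <- matrix(FALSE, nrow = length(sp), ncol = length(motifs),
                    dimnames = list(sp, names(motifs)))
  positions <- present
  positions[] <- NA_real_
  for (s in sp) {
    for (m in names(motifs)) {
      h <- hits_for(per_species[[s]], motifs[[m]])
      present[s, m] <- nrow(h) > 0
      positions[s, m] <- if (nrow(h) > 0) min(h$start) else NA_real_
    }
  }
  out <- as.data.frame(present)
  attr(out, "positions") <- as.data.frame(positions)
  if (length(clade) > 0 && length(clade) < length(sp)) {
    outgroup <- setdiff(sp, clade)
    attr(out, "clade_specific") <- apply(present, 2, function(p) {
      all(p[clade]) && !any(p[outgroup])
    })
  }
  out
}
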