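#' 5' splice-site strength evaluation
#'
#' The donor (5' splice) site is the 9-mer spanning the last three exonic
#' bases (-3..-1) and the first six intronic bases (+1..+6), recognized by
#' base-pairing with U1 snRNA. Three evaluations are provided:
#' consensus-mismatch reporting against the vertebrate donor consensus
#' (C/A)AG|gt(a/g)ag(t/g); a maximum-entropy 9-mer scorer driven by
#' externally supplied reference model tables; and a frequency-trained
#' position-weight-matrix scorer usable when no external tables are
#' available.
#'
#' @name splice-site-scoring
NULL

.ss_positions <- c(-3, -2, -1, 1, 2, 3, 4, 5, 6)

#' Donor-site consensus specification
#'
#' Per-position allowed-letter sets for positions -3..+6. The default is
#' the vertebrate consensus (C/A)AG|gt(a/g)ag(t/g): position -3 admits C or
#' A, +3 admits A or G, +6 admits T or G, and the remaining positions are
#' single-letter.
#'
#' @param allowed Named list of character vectors, names
#'   `"-3","-2","-1","+1",...,"+6"`; letters in A/C/G/T.
#' @return A `consensus_spec`.
#' @export
donor_consensus <- function(allowed = list(
  `-3` = c("C", "A"), `-2` = "A", `-1` = "G",
  `+1` = "G", `+2` = "T", `+3` = c("A", "G"),
  `+4` = "A", `+5` = "G", `+6` = c("T", "G"))) {
  need <- c("-3", "-2", "-1", "+1", "+2", "+3", "+4", "+5", "+6")
  if (!identical(sort(names(allowed)), sort(need))) {
    stop("consensus must specify positions -3..-1 and +1..+6")
  }
  ok <- vapply(allowed, function(s) {
    length(s) >= 1 && all(s %in% c("A", "C", "G", "T"))
  }, logical(1))
  if (!all(ok)) stop("each position needs a non-empty subset of A/C/G/T")
  structure(allowed[need], class = "consensus_spec")
}

#' Positions of a donor site deviating from consensus
#'
#' @param context A [splice_site_context()] or a 9-letter string.
#' @param spec A [donor_consensus()].
#' @return Sorted numeric vector of mismatching positions
#'   (negative = exonic, positive = intronic). Empty for a full-consensus
#'   site.
#' @examples
#' consensus_mismatches("GAGGTGGGA") # -3, 4, 6
#' @export
consensus_mismatches <- function(context, spec = donor_consensus()) {
  if (is.character(context)) context <- splice_site_context(context)
  stopifnot(inherits(context, "splice_site_context"),
            inherits(spec, "consensus_spec"))
  letters <- strsplit(context$nine_mer, "", fixed = TRUE)[[1]]
  bad <- vapply(seq_along(.ss_positions), function(i) {
    !letters[i] %in% spec[[i]]
  }, logical(1))
  .ss_positions[bad]
}

#' Enumerate every site matching a consensus spec
#'
#' @param spec A [donor_consensus()].
#' @return Character vector of all 9-mers constructible from the spec.
#' @export
consensus_sites <- function(spec = donor_consensus()) {
  grid <- expand.grid(unclass(spec), stringsAsFactors = FALSE)
  apply(grid, 1, paste0, collapse = "")
}

# -- maximum-entropy scorer ---------------------------------------------------

# Reference model constants: near-obligate +1/+2 dinucleotide frequencies
# and the background composition used by the reference donor-site scorer.
.me_cons1 <- c(A = 0.004, C = 0.0032, G = 0.9896, T = 0.0032)   # position +1
.me_cons2 <- c(A = 0.0034, C = 0.0039, G = 0.0042, T = 0.9884)  # position +2
.me_bgd <- c(A = 0.27, C = 0.23, G = 0.23, T = 0.27)

#' Load reference maximum-entropy donor-site tables
#'
#' The maximum-entropy donor model factorizes the 9-mer into the
#' near-obligate GT dinucleotide at +1/+2 (scored by marginal frequencies
#' against background) and the remaining 7 positions, whose joint
#' distribution is given by a table of 4^7 = 16384 probabilities (one per
#' 7-mer, lexicographic in A<C<G<T, most significant letter first;
#' customarily distributed as the file `me2x5`, one value per line). These
#' tables are third-party model files and are not bundled; point `dir` (or
#' `options(cassPSI.maxent_dir = ...)`) at a directory containing `me2x5`.
#'
#' @param dir Directory holding the `me2x5` table.
#' @return A `maxent_5ss_model`.
#' @export
load_maxent_5ss <- function(dir = getOption("cassPSI.maxent_dir")) {
  if (is.null(dir) || !nzchar(dir)) {
    stop("maximum-entropy 5'ss scorer unavailable: no table directory ",
         "configured (set options(cassPSI.maxent_dir = ...))")
  }
  path <- file.path(dir, "me2x5")
  if (!file.exists(path)) {
    stop("maximum-entropy 5'ss scorer unavailable: '", path, "' not found")
  }
  vals <- as.numeric(readLines(path, warn = FALSE))
  if (length(vals) != 16384L || anyNA(vals)) {
    stop("me2x5 must contain 16384 numeric lines (one per 7-mer), got ",
         length(vals))
  }
  structure(list(me2x5 = vals, dir = dir), class = "maxent_5ss_model")
}

#' Maximum-entropy donor-site score
#'
#' Log2-odds of the 9-mer under the maximum-entropy donor model relative
#' to its null model. Deterministic; matches the reference implementation
#' to 2 decimals when driven by the reference tables.
#'
#' @param nine_mer 9-letter donor site (string or
#'   [splice_site_context()]).
#' @param model A [load_maxent_5ss()] model; default loads from the
#'   configured directory and errors when tables are absent (no silent
#'   fallback to another scorer).
#' @return One-row data frame `nine_mer`, `scorer_id`, `score`.
#' @export
maxent_5ss_score <- function(nine_mer, model = load_maxent_5ss()) {
  if (inherits(nine_mer, "splice_site_context")) nine_mer <- nine_mer$nine_mer
  ctx <- splice_site_context(nine_mer)
  stopifnot(inherits(model, "maxent_5ss_model"))
  letters <- strsplit(ctx$nine_mer, "", fixed = TRUE)[[1]]
  cons_ratio <- (.me_cons1[letters[4]] * .me_cons2[letters[5]]) /
    (.me_bgd[letters[4]] * .me_bgd[letters[5]])
  rest <- letters[c(1:3, 6:9)]
  digits <- match(rest, c("A", "C", "G", "T")) - 1L
  idx <- sum(digits * 4^(6:0)) + 1L
  score <- log2(cons_ratio * model$me2x5[idx])
  data.frame(nine_mer = ctx$nine_mer, scorer_id = "maxent_5ss",
             score = unname(score), stringsAsFactors = FALSE)
}

# -- frequency-trained PWM scorer --------------------------------------------

#' Train a donor-site PWM from example sites
#'
#' Position-wise log2(frequency / 0.25) with a pseudocount added to every
#' letter count. A pseudocount of 0 with an unobserved letter would give
#' -Inf weights and is rejected.
#'
#' @param training_sites Character vector of 9-letter donor sites.
#' @param pseudocount Added to each letter count per position
#'   (default 0.25).
#' @return A width-9 [pwm()] (`motif_id` `"pwm_5ss"`) scorable with
#'   [score_pwm_window()] or [pwm_5ss_score()].
#' @export
build_pwm_5ss <- function(training_sites, pseudocount = 0.25) {
  if (length(training_sites) < 1L) stop("need at least one training site")
  sites <- vapply(training_sites, function(s) splice_site_context(s)$nine_mer,
                  character(1))
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  mat <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  counts <- vapply(c("A", "C", "G", "T"), function(l) {
    colSums(mat == l) + pseudocount
  }, numeric(9))
  freq <- counts / rowSums(counts)
  if (any(freq == 0)) {
    stop("letter never observed with pseudocount 0: ",
         "weights would be -Inf; use a positive pseudocount")
  }
  pwm(log2(freq / 0.25), motif_id = "pwm_5ss", threshold = 0)
}

#' @rdname build_pwm_5ss
#' @param nine_mer 9-letter donor site.
#' @param pwm Trained donor PWM.
#' @return For `pwm_5ss_score()`: one-row data frame `nine_mer`,
#'   `scorer_id`, `score`.
#' @export
pwm_5ss_score <- function(nine_mer, pwm) {
  if (inherits(nine_mer, "splice_site_context")) nine_mer <- nine_mer$nine_mer
  ctx <- splice_site_context(nine_mer)
  data.frame(nine_mer = ctx$nine_mer, scorer_id = "pwm_5ss",
             score = score_pwm_window(pwm, ctx$nine_mer),
             stringsAsFactors = FALSE)
}

#' Donor-site report
#'
#' Scores a site with every available scorer and lists its consensus
#' mismatches. Third-party score columns (e.g. an externally computed SD
#' score) can be passed through for side-by-side display; they are never
#' recomputed here.
#'
#' @param nine_mer 9-letter donor site.
#' @param maxent_model Optional [load_maxent_5ss()] model.
#' @param pwm Optional trained donor PWM ([build_pwm_5ss()]).
#' @param external Optional named numeric vector of pass-through scores.
#' @return Data frame with one row per scorer plus a `mismatches`
#'   attribute (positions off consensus).
#' @export
score_donor_site <- function(nine_mer, maxent_model = NULL, pwm = NULL,
                             external = NULL) {
  ctx <- splice_site_context(
    if (inherits(nine_mer, "splice_site_context")) nine_mer$nine_mer
    else nine_mer)
  rows <- list()
  if (!is.null(maxent_model)) rows <- c(rows, list(maxent_5ss_score(ctx, maxent_model)))
  if (!is.null(pwm)) rows <- c(rows, list(pwm_5ss_score(ctx, pwm)))
  if (!is.null(external)) {
    rows <- c(rows, list(data.frame(
      nine_mer = ctx$nine_mer, scorer_id = names(external),
      score = unname(external), stringsAsFactors = FALSE)))
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(nine_mer = character(), scorer_id = character(),
               score = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "mismatches") <- consensus_mismatches(ctx)
  out
}
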