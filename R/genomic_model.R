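#' Genome intervals and cassette-exon gene models
#'
#' All coordinates in this package are 0-based, half-open internally:
#' an interval covers bases `start .. end - 1` and its length is
#' `end - start`. Printed "start-end" loci (1-based genome-browser style)
#' are converted at the parser boundary ([parse_printed_interval()]); STAR
#' junction coordinates are converted in [read_star_sj()]. No other code
#' performs coordinate arithmetic across conventions.
#'
#' @name genomic-coordinates
NULL

#' Construct a genome interval
#'
#' @param seq_name Sequence (chromosome) name. `NA` is allowed for
#'   coordinate-only intervals parsed from bare "start-end" text.
#' @param start,end 0-based half-open boundaries, `end >= start >= 0`.
#' @param strand `"+"`, `"-"`, or `"*"` (unknown).
#' @return A `genome_interval` object (list with the four fields).
#' @examples
#' iv <- genome_interval("chr6", 100, 172)
#' interval_length(iv) # 72
#' @export
genome_interval <- function(seq_name, start, end, strand = "*") {
  if (is.na(start) || is.na(end)) stop("interval boundaries must be numbers")
  start <- as.numeric(start); end <- as.numeric(end)
  if (start < 0) stop("interval start must be non-negative")
  if (end < start) stop("interval end (", end, ") < start (", start, ")")
  if (!strand %in% c("+", "-", "*")) stop("strand must be '+', '-' or '*'")
  structure(
    list(seq_name = as.character(seq_name), start = start, end = end,
         strand = strand),
    class = "genome_interval"
  )
}

#' @rdname genome_interval
#' @param x A `genome_interval`.
#' @export
interval_length <- function(x) {
  stopifnot(inherits(x, "genome_interval"))
  x$end - x$start
}

#' @export
format.genome_interval <- function(x, ...) {
  sn <- if (is.na(x$seq_name)) "" else paste0(x$seq_name, ":")
  sprintf("%s%s-%s", sn,
          format(x$start, scientific = FALSE, big.mark = ""),
          format(x$end, scientific = FALSE, big.mark = ""))
}

#' @export
print.genome_interval <- function(x, ...) {
  cat("<genome_interval> ", format(x), " (", x$strand, "), length ",
      interval_length(x), "\n", sep = "")
  invisible(x)
}

#' Parse a printed locus string into an interval
#'
#' Accepts genome-browser style loci such as `"chr 6: 87,060,757-87,060,829"`
#' or bare ranges like `"69,581,290 to 69,581,564"`. Commas and internal
#' spaces in the sequence name are stripped; `"-"`, en-dash and `" to "` all
#' separate the endpoints. The printed endpoints are kept verbatim, so the
#' interval length is the difference of the printed endpoints — the
#' convention under which a 72-nt deletion prints as a span whose endpoints
#' differ by 72.
#'
#' @param text Locus string.
#' @return A [genome_interval()] with no strand. `seq_name` is `NA` when the
#'   text carries no sequence name.
#' @examples
#' interval_length(parse_printed_interval("chr 6: 87,060,757-87,060,829")) # 72
#' @export
parse_printed_interval <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  m <- regexec(
    "^(?:([^:]+):)?\\s*([0-9][0-9,]*)\\s*(?:-|–|\\bto\\b)\\s*([0-9][0-9,]*)$",
    txt, perl = TRUE
  )
  parts <- regmatches(txt, m)[[1]]
  if (length(parts) == 0L) {
    # locate the first token that breaks the expected shape, for the error
    bad <- sub("^(?:[^:]+:)?\\s*[0-9,]*", "", txt, perl = TRUE)
    stop("cannot parse locus '", text, "': unexpected token '",
         substr(trimws(bad), 1, 20), "'")
  }
  seq_name <- gsub("\\s+", "", parts[2])
  if (identical(seq_name, "")) seq_name <- NA_character_
  a <- as.numeric(gsub(",", "", parts[3], fixed = TRUE))
  b <- as.numeric(gsub(",", "", parts[4], fixed = TRUE))
  if (b < a) stop("cannot parse locus '", text, "': end before start")
  genome_interval(seq_name, a, b)
}

#' Amino acids encoded by an exon
#'
#' A cassette exon whose length is a multiple of 3 preserves the reading
#' frame of the downstream exons; otherwise its inclusion shifts the frame.
#'
#' @param exon_length_nt Exon length in nucleotides, `>= 0`.
#' @return List with `aa` (codon count, floor for frame-shifting exons) and
#'   `frame_preserving` (logical).
#' @examples
#' exon_peptide_length(54) # 18 aa, frame-preserving
#' @export
exon_peptide_length <- function(exon_length_nt) {
  if (length(exon_length_nt) != 1L || is.na(exon_length_nt) ||
      exon_length_nt < 0) {
    stop("exon length must be a single non-negative number")
  }
  list(aa = floor(exon_length_nt / 3),
       frame_preserving = exon_length_nt %% 3 == 0)
}

#' Build a cassette-exon gene model
#'
#' Three exons on one sequence: upstream (constitutive), cassette
#' (alternative), downstream (constitutive). "Upstream"/"downstream" are in
#' transcript (sense) orientation, so on the minus strand the upstream exon
#' has the larger genomic coordinates.
#'
#' @param seq_name Sequence name shared by all three exons.
#' @param strand `"+"` or `"-"`; `"*"` is accepted but rejected by
#'   strand-dependent operations.
#' @param upstream_exon,cassette_exon,downstream_exon [genome_interval()]s
#'   (strand fields ignored; numeric `c(start, end)` also accepted).
#' @return A `cassette_exon_model`.
#' @export
cassette_exon_model <- function(seq_name, strand, upstream_exon,
                                cassette_exon, downstream_exon) {
  as_iv <- function(x) {
    if (inherits(x, "genome_interval")) return(x)
    if (is.numeric(x) && length(x) == 2L)
      return(genome_interval(seq_name, x[1], x[2]))
    stop("exons must be genome_interval objects or c(start, end) pairs")
  }
  up <- as_iv(upstream_exon); ce <- as_iv(cassette_exon)
  dn <- as_iv(downstream_exon)
  if (!strand %in% c("+", "-", "*")) stop("strand must be '+', '-' or '*'")
  ord <- if (identical(strand, "-")) {
    dn$end <= ce$start && ce$start <= ce$end && ce$end <= up$start
  } else {
    up$end <= ce$start && ce$start <= ce$end && ce$end <= dn$start
  }
  if (!ord) stop("exons out of order for strand '", strand, "'")
  m <- structure(
    list(seq_name = as.character(seq_name), strand = strand,
         upstream_exon = up, cassette_exon = ce, downstream_exon = dn),
    class = "cassette_exon_model"
  )
  ii <- model_introns(m)
  if (interval_length(ii$upstream_intron) < 1 ||
      interval_length(ii$downstream_intron) < 1) {
    stop("both flanking introns must have length >= 1")
  }
  m
}

#' Flanking introns of a cassette model
#'
#' @param model A [cassette_exon_model()].
#' @return List with `upstream_intron` (between upstream and cassette exon)
#'   and `downstream_intron` (between cassette and downstream exon), plus
#'   `skip_intron` (the exclusion junction's intron, bridging the two
#'   constitutive exons).
#' @export
model_introns <- function(model) {
  stopifnot(inherits(model, "cassette_exon_model"))
  s <- model$seq_name
  if (identical(model$strand, "-")) {
    list(
      upstream_intron = genome_interval(s, model$cassette_exon$end,
                                        model$upstream_exon$start, "-"),
      downstream_intron = genome_interval(s, model$downstream_exon$end,
                                          model$cassette_exon$start, "-"),
      skip_intron = genome_interval(s, model$downstream_exon$end,
                                    model$upstream_exon$start, "-")
    )
  } else {
    list(
      upstream_intron = genome_interval(s, model$upstream_exon$end,
                                        model$cassette_exon$start, model$strand),
      downstream_intron = genome_interval(s, model$cassette_exon$end,
                                          model$downstream_exon$start, model$strand),
      skip_intron = genome_interval(s, model$upstream_exon$end,
                                    model$downstream_exon$start, model$strand)
    )
  }
}

#' @export
print.cassette_exon_model <- function(x, ...) {
  cat("<cassette_exon_model> on ", x$seq_name, " (", x$strand, ")\n",
      "  upstream exon:   ", format(x$upstream_exon), "\n",
      "  cassette exon:   ", format(x$cassette_exon), " (",
      interval_length(x$cassette_exon), " nt)\n",
      "  downstream exon: ", format(x$downstream_exon), "\n", sep = "")
  invisible(x)
}

#' Read a cassette model from a BED12 line or a three-exon TSV
#'
#' Two dialects: (a) BED12 with exactly three blocks (block coordinates are
#' relative to `chromStart`, standard BED semantics, already 0-based
#' half-open); (b) a TSV with columns `role` (upstream/cassette/downstream),
#' `seq_name`, `start`, `end`, `strand`, coordinates already in the internal
#' 0-based half-open convention.
#'
#' @param path File path.
#' @param format `"bed12"` or `"tsv"`; default guesses from the extension.
#' @return A [cassette_exon_model()].
#' @export
read_cassette_model <- function(path, format = c("auto", "bed12", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "tsv"
  }
  if (format == "bed12") {
    ln <- readLines(path, warn = FALSE)
    ln <- ln[nzchar(ln) & !startsWith(ln, "#") & !startsWith(ln, "track")]
    if (length(ln) != 1L) stop("expected exactly one BED12 record in ", path)
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) stop("BED12 record needs 12 fields, got ", length(f))
    chrom <- f[1]; chrom_start <- as.numeric(f[2]); strand <- f[6]
    n_blocks <- as.integer(f[10])
    if (n_blocks != 3L) stop("cassette model requires exactly 3 exon blocks")
    sizes <- as.numeric(strsplit(sub(",$", "", f[11]), ",")[[1]])
    starts <- as.numeric(strsplit(sub(",$", "", f[12]), ",")[[1]])
    exon <- lapply(seq_len(3), function(i) {
      genome_interval(chrom, chrom_start + starts[i],
                      chrom_start + starts[i] + sizes[i])
    })
    # BED blocks are in genomic order; transcript order flips on '-'
    if (identical(strand, "-")) exon <- rev(exon)
    cassette_exon_model(chrom, strand, exon[[1]], exon[[2]], exon[[3]])
  } else {
    tb <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("role", "seq_name", "start", "end", "strand")
    if (!all(need %in% names(tb))) {
      stop("model TSV must have columns: ", paste(need, collapse = ", "))
    }
    row_iv <- function(role) {
      r <- tb[tb$role == role, , drop = FALSE]
      if (nrow(r) != 1L) stop("model TSV needs exactly one '", role, "' row")
      genome_interval(r$seq_name, r$start, r$end)
    }
    cassette_exon_model(tb$seq_name[1], tb$strand[1],
                        row_iv("upstream"), row_iv("cassette"),
                        row_iv("downstream"))
  }
}

# -- sequence helpers ---------------------------------------------------------

.as_dna_string <- function(sequence, seq_name = NULL) {
  if (inherits(sequence, "DNAStringSet")) {
    if (!is.null(seq_name) && seq_name %in% names(sequence)) {
      return(sequence[[seq_name]])
    }
    if (length(sequence) == 1L) return(sequence[[1L]])
    stop("sequence set does not contain '", seq_name, "'")
  }
  if (inherits(sequence, "DNAString")) return(sequence)
  if (is.character(sequence) && length(sequence) == 1L) {
    return(Biostrings::DNAString(normalize_dna(sequence)))
  }
  stop("sequence must be a character string, DNAString or DNAStringSet")
}

#' Normalize nucleotide text to uppercase DNA
#'
#' RNA input (U) is converted to T; case is folded to upper. Letters outside
#' `A/C/G/T/N` raise an error.
#'
#' @param x Character vector of sequences.
#' @return Uppercase DNA character vector.
#' @export
normalize_dna <- function(x) {
  out <- chartr("u", "T", toupper(x))
  out <- chartr("U", "T", out)
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    ch <- regmatches(out[bad][1], regexpr("[^ACGTN]", out[bad][1]))
    stop("invalid nucleotide letter '", ch, "' in sequence")
  }
  out
}

#' Extract the 5' splice-site context of the cassette exon
#'
#' Returns the 9-mer around the cassette exon's donor site: the last three
#' exonic bases (positions -3..-1) followed by the first six bases of the
#' downstream intron (positions +1..+6), always read 5'->3' on the sense
#' strand (minus-strand models are reverse-complemented).
#'
#' @param model A [cassette_exon_model()] with known strand.
#' @param sequence Character string, `DNAString`, or named `DNAStringSet`
#'   covering the model's coordinates on its `seq_name`.
#' @return A `splice_site_context`: list with `nine_mer`, `exon_part`
#'   (3 nt) and `intron_part` (6 nt), uppercase DNA.
#' @examples
#' m <- cassette_exon_model("s", "+", c(0, 10), c(20, 30), c(40, 50))
#' sq <- paste(rep("A", 50), collapse = "")
#' substr(sq, 28, 36) <- "TTTGTAAGT"
#' five_prime_ss_context(m, sq)$nine_mer # "TTTGTAAGT"
#' @export
five_prime_ss_context <- function(model, sequence) {
  stopifnot(inherits(model, "cassette_exon_model"))
  if (model$strand == "*") {
    stop("5' splice-site extraction requires a stranded model")
  }
  if (interval_length(model$cassette_exon) < 3) {
    stop("cassette exon shorter than 3 nt")
  }
  ii <- model_introns(model)
  if (interval_length(ii$downstream_intron) < 6) {
    stop("downstream intron shorter than 6 nt")
  }
  dna <- .as_dna_string(sequence, model$seq_name)
  if (model$strand == "+") {
    from0 <- model$cassette_exon$end - 3   # 0-based window start
    to0 <- model$cassette_exon$end + 6     # exclusive
    if (from0 < 0 || to0 > length(dna)) {
      stop("donor window extends past the supplied sequence")
    }
    nine <- as.character(Biostrings::subseq(dna, from0 + 1, to0))
  } else {
    from0 <- model$cassette_exon$start - 6
    to0 <- model$cassette_exon$start + 3
    if (from0 < 0 || to0 > length(dna)) {
      stop("donor window extends past the supplied sequence")
    }
    win <- Biostrings::subseq(dna, from0 + 1, to0)
    nine <- as.character(Biostrings::reverseComplement(win))
  }
  nine <- normalize_dna(nine)
  splice_site_context(nine)
}

#' @rdname five_prime_ss_context
#' @param nine_mer A 9-letter donor-site sequence (-3..-1 exonic,
#'   +1..+6 intronic); RNA letters accepted.
#' @export
splice_site_context <- function(nine_mer) {
  nine <- normalize_dna(nine_mer)
  if (nchar(nine) != 9L) stop("donor context must be exactly 9 nt")
  structure(
    list(nine_mer = nine,
         exon_part = substr(nine, 1, 3),
         intron_part = substr(nine, 4, 9)),
    class = "splice_site_context"
  )
}

#' @export
print.splice_site_context <- function(x, ...) {
  cat("<5'ss context> ", x$exon_part, "|",
      tolower(x$intron_part), "\n", sep = "")
  invisible(x)
}
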