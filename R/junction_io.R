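#' Splice-junction count table I/O
#'
#' Junction records are plain data frames with one row per intron and
#' columns `seq_name`, `intron_start`, `intron_end` (internal 0-based
#' half-open: first and one-past-last intronic base), `strand`,
#' `unique_reads`, `multi_reads`, `dataset_id`. STAR's 1-based inclusive
#' coordinates are converted here, at the parser boundary, and nowhere else.
#'
#' @name junction-io
NULL

.junction_df <- function(seq_name = character(), intron_start = numeric(),
                         intron_end = numeric(), strand = character(),
                         unique_reads = numeric(), multi_reads = numeric(),
                         dataset_id = character()) {
  data.frame(seq_name = seq_name, intron_start = intron_start,
             intron_end = intron_end, strand = strand,
             unique_reads = unique_reads, multi_reads = multi_reads,
             dataset_id = dataset_id, stringsAsFactors = FALSE)
}

.read_table_lines <- function(path) {
  con <- gzfile(path, open = "rt")  # transparent for plain text too
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

.int_field <- function(x, what, line_no) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v) || v != floor(v)) {
    stop("line ", line_no, ": ", what, " is not an integer ('", x, "')")
  }
  v
}

#' Read a STAR SJ.out.tab junction table
#'
#' Layout: seq name, intron first base (1-based), intron last base (1-based,
#' inclusive), strand code (0 unknown / 1 `+` / 2 `-`), intron motif code,
#' annotation flag, unique-mapping read count, multi-mapping read count,
#' maximum spliced overhang. Gzip-compressed files are read transparently.
#'
#' @param path Path to an SJ.out.tab (optionally .gz).
#' @param dataset_id Label attached to every record.
#' @return Junction data frame (see [junction-io]); attribute
#'   `skipped_rows` counts rows dropped (always 0: malformed rows are
#'   errors, never silent skips). An empty file yields an empty frame with
#'   a warning.
#' @export
read_star_sj <- function(path, dataset_id = basename(path)) {
  ln <- .read_table_lines(path)
  ln <- ln[nzchar(ln)]
  if (length(ln) == 0L) {
    warning("no junction records in ", path)
    out <- .junction_df()
    attr(out, "skipped_rows") <- 0L
    return(out)
  }
  rows <- strsplit(ln, "\t", fixed = TRUE)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) < 8L) {
      stop("line ", i, ": expected >= 8 tab-separated fields, got ", length(f))
    }
    first1 <- .int_field(f[2], "intron start", i)
    last1 <- .int_field(f[3], "intron end", i)
    code <- .int_field(f[4], "strand code", i)
    if (!code %in% c(0, 1, 2)) stop("line ", i, ": bad strand code ", code)
    uniq <- .int_field(f[7], "unique read count", i)
    mult <- .int_field(f[8], "multi read count", i)
    if (uniq < 0 || mult < 0) stop("line ", i, ": negative read count")
    out[[i]] <- .junction_df(
      seq_name = f[1],
      intron_start = first1 - 1,     # 1-based first base -> 0-based
      intron_end = last1,            # 1-based last base -> half-open end
      strand = c("*", "+", "-")[code + 1L],
      unique_reads = uniq, multi_reads = mult, dataset_id = dataset_id
    )
  }
  res <- do.call(rbind, out)
  attr(res, "skipped_rows") <- 0L
  res
}

#' Read a 6-column junction BED
#'
#' `chrom start end name score strand`, with the BED interval giving the
#' intron (already 0-based half-open) and the score column holding the
#' junction read count (mapped to `unique_reads`; `multi_reads` is 0).
#'
#' @inheritParams read_star_sj
#' @return Junction data frame; zero-score junctions are retained.
#' @export
read_junction_bed <- function(path, dataset_id = basename(path)) {
  ln <- .read_table_lines(path)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#") & !startsWith(ln, "track")]
  if (length(ln) == 0L) {
    warning("no junction records in ", path)
    out <- .junction_df()
    attr(out, "skipped_rows") <- 0L
    return(out)
  }
  rows <- strsplit(ln, "\t", fixed = TRUE)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) < 6L) {
      stop("line ", i, ": junction BED needs 6 columns (strand missing?)")
    }
    start <- .int_field(f[2], "start", i)
    end <- .int_field(f[3], "end", i)
    score <- .int_field(f[5], "score", i)
    if (score < 0) stop("line ", i, ": negative read count")
    if (!f[6] %in% c("+", "-", ".")) stop("line ", i, ": bad strand '", f[6], "'")
    out[[i]] <- .junction_df(
      seq_name = f[1], intron_start = start, intron_end = end,
      strand = if (f[6] == ".") "*" else f[6],
      unique_reads = score, multi_reads = 0, dataset_id = dataset_id
    )
  }
  res <- do.call(rbind, out)
  attr(res, "skipped_rows") <- 0L
  res
}

#' Write / read a PSI estimate table
#'
#' TSV with columns `dataset_id`, `species`, `tissue`,
#' `inclusion_reads_up`, `inclusion_reads_down`, `exclusion_reads`,
#' `total_reads`, `psi` (6 decimal places; empty cell when PSI is
#' undefined). Rows are ordered lexicographically by (species, tissue,
#' dataset_id) so repeated runs are byte-identical.
#'
#' @param estimates Data frame of PSI estimates ([psi_estimate()] rows).
#' @param path Output path.
#' @param provenance Optional character vector written as leading `#`
#'   comment lines (ignored by [read_psi_table()]).
#' @return `path`, invisibly.
#' @export
write_psi_table <- function(estimates, path, provenance = NULL) {
  need <- c("dataset_id", "species", "tissue", "inclusion_up",
            "inclusion_down", "exclusion", "psi")
  if (!all(need %in% names(estimates))) {
    stop("estimates must have columns: ", paste(need, collapse = ", "))
  }
  e <- estimates[order(estimates$species, estimates$tissue,
                       estimates$dataset_id, method = "radix"), , drop = FALSE]
  psi_txt <- ifelse(is.na(e$psi), "", sprintf("%.6f", e$psi))
  body <- data.frame(
    dataset_id = e$dataset_id, species = e$species, tissue = e$tissue,
    inclusion_reads_up = e$inclusion_up,
    inclusion_reads_down = e$inclusion_down,
    exclusion_reads = e$exclusion,
    total_reads = e$inclusion_up + e$inclusion_down + e$exclusion,
    psi = psi_txt, stringsAsFactors = FALSE
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), con)
  }
  writeLines(paste(names(body), collapse = "\t"), con)
  if (nrow(body) > 0L) {
    writeLines(do.call(paste, c(unname(as.list(body)), sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_psi_table
#' @export
read_psi_table <- function(path) {
  tb <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c(psi = "character"))
  tb$psi <- suppressWarnings(as.numeric(tb$psi))
  data.frame(
    dataset_id = as.character(tb$dataset_id), species = tb$species,
    tissue = tb$tissue,
    inclusion_up = tb$inclusion_reads_up,
    inclusion_down = tb$inclusion_reads_down,
    exclusion = tb$exclusion_reads, psi = tb$psi,
    stringsAsFactors = FALSE
  )
}
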