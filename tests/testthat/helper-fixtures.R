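# Shared fixtures and independent brute-force oracles. The oracles walk
# every candidate explicitly and never call the functions they check.

random_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# a random plus-strand cassette model on its own sequence
random_cassette_model <- function(seq_name = "chrR") {
  up_s <- sample(0:50, 1)
  up_e <- up_s + sample(20:80, 1)
  ce_s <- up_e + sample(30:120, 1)
  ce_e <- ce_s + sample(20:90, 1)
  dn_s <- ce_e + sample(30:120, 1)
  dn_e <- dn_s + sample(20:80, 1)
  cassette_exon_model(seq_name, "+", c(up_s, up_e), c(ce_s, ce_e),
                      c(dn_s, dn_e))
}

# random junction table: mixture of model junctions, near-miss decoys
# (boundaries jittered by -2..2) and far decoys
random_junctions <- function(model, n = 20, dataset_id = "fx") {
  ii <- model_introns(model)
  real <- list(
    c(ii$upstream_intron$start, ii$upstream_intron$end),
    c(ii$downstream_intron$start, ii$downstream_intron$end),
    c(ii$skip_intron$start, ii$skip_intron$end)
  )
  rows <- lapply(seq_len(n), function(i) {
    base <- real[[sample(3, 1)]]
    jit <- sample(c(0, 0, -2, -1, 1, 2), 2, replace = TRUE)
    st <- base[1] + jit[1]; en <- max(base[2] + jit[2], st + 1)
    data.frame(seq_name = sample(c(model$seq_name, "chrOther"), 1,
                                 prob = c(0.85, 0.15)),
               intron_start = st, intron_end = en,
               strand = sample(c("+", "-", "*"), 1),
               unique_reads = sample(0:30, 1), multi_reads = sample(0:5, 1),
               dataset_id = dataset_id, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# oracle: exhaustive per-record boundary comparison
oracle_classify <- function(model, junctions, count_mode = "unique") {
  ii <- model_introns(model)
  out <- c(inclusion_up = 0, inclusion_down = 0, exclusion = 0)
  for (i in seq_len(nrow(junctions))) {
    r <- junctions[i, ]
    if (r$seq_name != model$seq_name) next
    reads <- r$unique_reads + if (count_mode == "all") r$multi_reads else 0
    if (r$intron_start == ii$upstream_intron$start &&
        r$intron_end == ii$upstream_intron$end) {
      out["inclusion_up"] <- out["inclusion_up"] + reads
    } else if (r$intron_start == ii$downstream_intron$start &&
               r$intron_end == ii$downstream_intron$end) {
      out["inclusion_down"] <- out["inclusion_down"] + reads
    } else if (r$intron_start == ii$skip_intron$start &&
               r$intron_end == ii$skip_intron$end) {
      out["exclusion"] <- out["exclusion"] + reads
    }
  }
  out
}

# oracle: score every window of a plain character sequence independently
oracle_pwm_scan <- function(sequence, weights, threshold) {
  w <- nrow(weights)
  lets <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hits <- data.frame(start = numeric(), score = numeric())
  for (s in 0:(nchar(sequence) - w)) {
    sc <- 0
    for (j in seq_len(w)) {
      sc <- sc + weights[j, match(lets[s + j], c("A", "C", "G", "T"))]
    }
    if (!is.na(sc) && sc >= threshold) {
      hits <- rbind(hits, data.frame(start = s, score = sc))
    }
  }
  hits
}

# oracle: all GCATG occurrences by direct substring comparison
oracle_rbfox <- function(sequence) {
  n <- nchar(sequence)
  starts <- numeric(0)
  for (s in 0:(n - 5)) {
    if (substr(sequence, s + 1, s + 5) == "GCATG") starts <- c(starts, s)
  }
  starts
}

# oracle: maximal G-runs by left-to-right walk
oracle_g_runs <- function(sequence, min_run) {
  lets <- strsplit(sequence, "", fixed = TRUE)[[1]]
  runs <- data.frame(start = numeric(), len = numeric())
  i <- 1
  while (i <= length(lets)) {
    if (lets[i] == "G") {
      j <- i
      while (j < length(lets) && lets[j + 1] == "G") j <- j + 1
      if (j - i + 1 >= min_run) {
        runs <- rbind(runs, data.frame(start = i - 1, len = j - i + 1))
      }
      i <- j + 1
    } else i <- i + 1
  }
  runs
}

# donor-context fixture: synthetic sequence whose cassette donor reads
# GAG|gtggga (the weak wild-type-like site)
donor_fixture <- function() {
  model <- cassette_exon_model("fix", "+", c(0, 20), c(40, 94), c(150, 180))
  set.seed(42)
  seqc <- random_dna(180)
  # exon [40,94) ends with GAG; intron starts GTGGGA
  substr(seqc, 92, 100) <- "GAGGTGGGA"
  list(model = model, sequence = seqc)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
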