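#' Synthetic inputs with known ground truth
#'
#' Generators for every input the pipeline consumes: junction-count tables
#' emulating multi-tissue, multi-species public RNA-seq (muscle/heart-high
#' cassette-exon inclusion, near-zero elsewhere), sequences with planted
#' regulatory motifs, and metabolite concentration tables. All generators
#' are seed-deterministic: the same seed gives byte-identical outputs.
#'
#' The junction-count model: with true inclusion level pi and expected
#' informative fragment depth lambda, a dataset's inclusion-supporting
#' reads are I ~ Poisson(2 lambda pi) — an included exon spans two
#' junctions — split Binomial(I, 1/2) between the upstream and downstream
#' junctions, and its exclusion-supporting reads are E ~ Poisson(lambda
#' (1 - pi)). Then E\[0.5 I\] = lambda pi and E\[E\] = lambda (1 - pi), so
#' the half-weighted PSI estimator is consistent for pi. Poisson is the
#' minimal noise model; a negative-binomial option (`dispersion`) is
#' exposed for robustness checks.
#'
#' @name synthetic-data
NULL

#' Toy cassette-exon model used by the simulators
#'
#' A 54-nt cassette exon (the human cassette length) between two
#' constitutive exons on a small synthetic sequence.
#'
#' @return A [cassette_exon_model()] on sequence `"chrT"`, `+` strand.
#' @export
toy_cassette_model <- function() {
  cassette_exon_model("chrT", "+", c(100, 200), c(300, 354), c(500, 600))
}

.rcounts <- function(n, mean, dispersion = NULL) {
  if (is.null(dispersion) || dispersion <= 0) {
    stats::rpois(n, mean)
  } else {
    # NB with variance mean + mean^2/size
    stats::rnbinom(n, size = 1 / dispersion, mu = mean)
  }
}

.sj_line <- function(seq_name, start0, end0, strand, uniq, multi = 0) {
  code <- c("+" = 1L, "-" = 2L, "*" = 0L)[strand]
  paste(seq_name, start0 + 1, end0, code, 1L, 1L, uniq, multi, 38L,
        sep = "\t")
}

#' Simulate junction counts for one condition
#'
#' Draws `n_datasets` independent datasets at true inclusion `pi` and
#' depth `lambda`. With `dir` set, each dataset is written as a valid
#' STAR-dialect SJ.out.tab containing the model's three informative
#' junctions plus decoy junctions whose boundaries are kept at least 2 nt
#' away from every model boundary, so exact-match classification has
#' unambiguous truth.
#'
#' @param pi True inclusion fraction in \[0, 1\].
#' @param lambda Expected informative fragments per dataset (> 0).
#' @param n_datasets Number of datasets.
#' @param seed Integer seed (local RNG; the caller's RNG state is
#'   untouched).
#' @param model Cassette model (default [toy_cassette_model()]).
#' @param dir Output directory for SJ.out.tab files (`NULL`: counts only).
#' @param dataset_prefix Prefix for dataset ids / filenames.
#' @param dispersion Optional negative-binomial overdispersion
#'   (`NULL` = Poisson).
#' @return Truth data frame: `dataset_id`, `true_psi`, `inclusion_up`,
#'   `inclusion_down`, `exclusion`, and `path` when files were written.
#' @export
simulate_junction_counts <- function(pi, lambda, n_datasets, seed,
                                     model = toy_cassette_model(),
                                     dir = NULL, dataset_prefix = "sim",
                                     dispersion = NULL) {
  stopifnot(pi >= 0, pi <= 1, lambda > 0, n_datasets >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  i_tot <- .rcounts(n_datasets, 2 * lambda * pi, dispersion)
  i_up <- stats::rbinom(n_datasets, i_tot, 0.5)
  i_dn <- i_tot - i_up
  excl <- .rcounts(n_datasets, lambda * (1 - pi), dispersion)
  ids <- sprintf("%s_%03d", dataset_prefix, seq_len(n_datasets))
  truth <- data.frame(dataset_id = ids, true_psi = pi,
                      inclusion_up = i_up, inclusion_down = i_dn,
                      exclusion = excl, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ii <- model_introns(model)
    # decoys: boundaries offset >= 2 nt from all model boundaries
    decoys <- list(
      c(ii$upstream_intron$start + 3, ii$upstream_intron$end - 3),
      c(ii$downstream_intron$start + 4, ii$downstream_intron$end + 7),
      c(ii$skip_intron$start - 5, ii$skip_intron$end + 6)
    )
    truth$path <- file.path(dir, paste0(ids, ".SJ.out.tab"))
    for (k in seq_len(n_datasets)) {
      decoy_reads <- .rcounts(length(decoys), lambda / 10, dispersion)
      lines <- c(
        .sj_line(model$seq_name, ii$upstream_intron$start,
                 ii$upstream_intron$end, model$strand, i_up[k]),
        .sj_line(model$seq_name, ii$downstream_intron$start,
                 ii$downstream_intron$end, model$strand, i_dn[k]),
        .sj_line(model$seq_name, ii$skip_intron$start, ii$skip_intron$end,
                 model$strand, excl[k]),
        vapply(seq_along(decoys), function(d) {
          .sj_line(model$seq_name, decoys[[d]][1], decoys[[d]][2], "*",
                   decoy_reads[d])
        }, character(1))
      )
      writeLines(lines, truth$path[k])
    }
  }
  truth
}

#' Default multi-species tissue profile
#'
#' The generator's study conditions: striated-muscle-restricted inclusion
#' across four mammals — skeletal muscle pi = 0.83 and heart pi = 0.35
#' (the measured long-isoform mRNA fractions in triceps brachii and
#' heart), all other tissues pi = 0.
#'
#' @param species Species labels.
#' @param tissues Tissue labels (must include `skeletal_muscle` and
#'   `heart` for the default pi map).
#' @return Data frame `species`, `tissue`, `true_psi`.
#' @export
fig_profile_muscle <- function(species = c("human", "macaque", "mouse", "rat"),
                               tissues = c("skeletal_muscle", "heart",
                                           "brain", "liver", "kidney",
                                           "lung")) {
  grid <- expand.grid(species = species, tissue = tissues,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, c("species", "tissue")]
  grid$true_psi <- ifelse(grid$tissue == "skeletal_muscle", 0.83,
                          ifelse(grid$tissue == "heart", 0.35, 0))
  grid[order(grid$species, grid$tissue, method = "radix"), , drop = FALSE]
}

#' Simulate a multi-tissue junction panel
#'
#' One SJ.out.tab per dataset under `out_dir/datasets/`, plus
#' `labels.tsv` (dataset -> species, tissue) and `truth.tsv` (simulated
#' counts and true PSI). Deterministic per seed.
#'
#' @param out_dir Output directory (created; must be empty or absent).
#' @param seed Integer seed.
#' @param profile Data frame `species`, `tissue`, `true_psi`
#'   (default [fig_profile_muscle()]).
#' @param lambda Expected informative fragments per dataset.
#' @param n_datasets Datasets per (species, tissue) group.
#' @param model Cassette model.
#' @param dispersion Optional negative-binomial overdispersion.
#' @return Invisibly, the truth data frame with labels.
#' @export
simulate_tissue_panel <- function(out_dir, seed,
                                  profile = fig_profile_muscle(),
                                  lambda = 200, n_datasets = 3,
                                  model = toy_cassette_model(),
                                  dispersion = NULL) {
  stopifnot(all(c("species", "tissue", "true_psi") %in% names(profile)))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0) {
    stop("output directory '", out_dir, "' is not empty")
  }
  ds_dir <- file.path(out_dir, "datasets")
  dir.create(ds_dir, recursive = TRUE, showWarnings = FALSE)
  profile <- profile[order(profile$species, profile$tissue,
                           method = "radix"), , drop = FALSE]
  pieces <- vector("list", nrow(profile))
  for (g in seq_len(nrow(profile))) {
    prefix <- paste(profile$species[g], profile$tissue[g], sep = "_")
    tr <- simulate_junction_counts(
      pi = profile$true_psi[g], lambda = lambda, n_datasets = n_datasets,
      seed = (seed + g * 1009L) %% .Machine$integer.max,
      model = model, dir = ds_dir, dataset_prefix = prefix,
      dispersion = dispersion
    )
    tr$species <- profile$species[g]
    tr$tissue <- profile$tissue[g]
    pieces[[g]] <- tr
  }
  truth <- do.call(rbind, pieces)
  labels <- truth[, c("dataset_id", "species", "tissue")]
  utils::write.table(labels, file.path(out_dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    truth[, c("dataset_id", "species", "tissue", "true_psi",
              "inclusion_up", "inclusion_down", "exclusion")],
    file.path(out_dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(truth)
}

#' Generate a sequence with planted motifs
#'
#' Background letters are i.i.d. over `background` (default uniform
#' A/C/G/T); each planted motif overwrites the background at a stated
#' 0-based offset within its region. Planting records truth positions
#' only; chance background occurrences are possible unless the background
#' alphabet excludes them, so exactness checks should either use a
#' collision-free background or compare against the scanners.
#'
#' @param up_len,exon_len,down_len Region lengths.
#' @param plants List of `list(motif =, region =, offset =)` entries;
#'   `offset` is 0-based within the region.
#' @param seed Integer seed.
#' @param background Letters to draw background from.
#' @param fasta Optional path: write the sequence as FASTA
#'   (record name `synthetic_region`) and the truth as
#'   `<fasta>.truth.tsv`.
#' @return List with `rs` (a [region_sequence()]) and `truth` (data frame
#'   `motif`, `region`, `offset`, `start` — sequence-level 0-based).
#' @export
generate_motif_sequence <- function(up_len, exon_len, down_len,
                                    plants = list(), seed = 1,
                                    background = c("A", "C", "G", "T"),
                                    fasta = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  total <- up_len + exon_len + down_len
  letters <- sample(background, total, replace = TRUE)
  region_start <- c(upstream_intron = 0, exon = up_len,
                    downstream_intron = up_len + exon_len)
  region_len <- c(upstream_intron = up_len, exon = exon_len,
                  downstream_intron = down_len)
  truth <- list()
  for (p in plants) {
    motif <- strsplit(normalize_dna(p$motif), "", fixed = TRUE)[[1]]
    if (!p$region %in% names(region_start)) {
      stop("unknown region '", p$region, "'")
    }
    if (p$offset < 0 || p$offset + length(motif) > region_len[[p$region]]) {
      stop("motif '", p$motif, "' does not fit in region '", p$region, "'")
    }
    s0 <- region_start[[p$region]] + p$offset
    letters[(s0 + 1):(s0 + length(motif))] <- motif
    truth[[length(truth) + 1L]] <- data.frame(
      motif = paste(motif, collapse = ""), region = p$region,
      offset = p$offset, start = s0, stringsAsFactors = FALSE
    )
  }
  rs <- region_sequence(paste(letters, collapse = ""),
                        up_len, exon_len, down_len)
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(motif = character(), region = character(),
               offset = numeric(), start = numeric(),
               stringsAsFactors = FALSE)
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(rs$sequence,
                                               "synthetic_region")),
      fasta
    )
    utils::write.table(truth, paste0(fasta, ".truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(rs = rs, truth = truth)
}

#' Generate a synthetic metabolite table
#'
#' Per-sample concentrations are the group means under multiplicative
#' lognormal noise: `value = mean * exp(rnorm(0, sdlog))`; `sdlog = 0`
#' reproduces the configured truth exactly.
#'
#' @param group_means Named list: group -> named numeric vector of
#'   metabolite means.
#' @param n_per_group Samples per group.
#' @param sdlog Lognormal noise scale (default 0.1, a ~10% coefficient of
#'   variation).
#' @param seed Integer seed.
#' @return List of [metabolite_profile()]s (samples named
#'   `<group>_<k>`).
#' @export
generate_metabolite_profiles <- function(group_means, n_per_group = 3,
                                         sdlog = 0.1, seed = 1) {
  stopifnot(length(group_means) >= 1L, !is.null(names(group_means)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- list()
  for (g in names(group_means)) {
    mu <- group_means[[g]]
    for (k in seq_len(n_per_group)) {
      noise <- if (sdlog > 0) exp(stats::rnorm(length(mu), 0, sdlog)) else 1
      out[[length(out) + 1L]] <- metabolite_profile(
        sprintf("%s_%d", g, k), g, mu * noise
      )
    }
  }
  out
}
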