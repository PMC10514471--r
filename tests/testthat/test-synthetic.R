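test_that("junction simulation honours the boundary inclusion levels", {
  tr0 <- simulate_junction_counts(0, lambda = 100, n_datasets = 50, seed = 2)
  expect_true(all(tr0$inclusion_up + tr0$inclusion_down == 0))
  psis0 <- mapply(compute_psi, tr0$inclusion_up, tr0$inclusion_down,
                  tr0$exclusion)
  expect_true(all(psis0[tr0$exclusion > 0] == 0))

  tr1 <- simulate_junction_counts(1, lambda = 100, n_datasets = 50, seed = 3)
  expect_true(all(tr1$exclusion == 0))
  psis1 <- mapply(compute_psi, tr1$inclusion_up, tr1$inclusion_down,
                  tr1$exclusion)
  expect_true(all(psis1[tr1$inclusion_up + tr1$inclusion_down > 0] == 1))
})

test_that("estimator recovery across an inclusion-depth grid", {
  for (lam in c(50, 500)) {
    for (pi0 in seq(0.1, 0.9, by = 0.2)) {
      tr <- simulate_junction_counts(pi0, lambda = lam, n_datasets = 500,
                                     seed = round(1e4 * pi0) + lam)
      psis <- mapply(compute_psi, tr$inclusion_up, tr$inclusion_down,
                     tr$exclusion)
      expect_lt(abs(mean(psis, na.rm = TRUE) - pi0), 0.02)
    }
  }
})

test_that("written junction files are valid STAR dialect with decoys", {
  d <- tempfile()
  tr <- simulate_junction_counts(0.5, lambda = 80, n_datasets = 4, seed = 9,
                                 dir = d)
  expect_true(all(file.exists(tr$path)))
  m <- toy_cassette_model()
  for (k in seq_len(nrow(tr))) {
    jx <- read_star_sj(tr$path[k], tr$dataset_id[k])
    expect_equal(attr(jx, "skipped_rows"), 0L)
    expect_gt(nrow(jx), 3)  # three informative junctions + decoys
    counts <- classify_junctions(m, jx)
    expect_equal(unname(counts["inclusion_up"]), tr$inclusion_up[k])
    expect_equal(unname(counts["inclusion_down"]), tr$inclusion_down[k])
    expect_equal(unname(counts["exclusion"]), tr$exclusion[k])
  }
})

test_that("generators are seed-deterministic (byte-identical files)", {
  d1 <- tempfile(); d2 <- tempfile()
  simulate_tissue_panel(d1, seed = 42, lambda = 60, n_datasets = 2)
  simulate_tissue_panel(d2, seed = 42, lambda = 60, n_datasets = 2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  d3 <- tempfile()
  simulate_tissue_panel(d3, seed = 43, lambda = 60, n_datasets = 2)
  truth42 <- read.delim(file.path(d1, "truth.tsv"))
  truth43 <- read.delim(file.path(d3, "truth.tsv"))
  expect_false(identical(truth42$inclusion_up, truth43$inclusion_up))
})

test_that("tissue panel encodes muscle-high, heart-mid inclusion", {
  labels <- NULL
  d <- tempfile()
  truth <- simulate_tissue_panel(d, seed = 4, lambda = 150, n_datasets = 2)
  expect_true(all(truth$true_psi[truth$tissue == "skeletal_muscle"] == 0.83))
  expect_true(all(truth$true_psi[truth$tissue == "heart"] == 0.35))
  expect_true(all(truth$true_psi[!truth$tissue %in%
                                   c("skeletal_muscle", "heart")] == 0))
  # single-dataset groups summarize without SD
  d1 <- tempfile()
  t1 <- simulate_tissue_panel(d1, seed = 4, lambda = 150, n_datasets = 1,
                              profile = fig_profile_muscle("mouse",
                                                           c("heart")))
  est <- quantify_panel(file.path(d1, "datasets"), toy_cassette_model(),
                        labels = t1[, c("dataset_id", "species", "tissue")])
  s <- aggregate_psi(est)
  expect_equal(s$n_datasets, 1)
  expect_true(is.na(s$sd_psi))
})

test_that("motif sequence generator plants what it records", {
  g <- generate_motif_sequence(
    30, 54, 30,
    plants = list(list(motif = "CACACGG", region = "exon", offset = 5),
                  list(motif = "GGGG", region = "exon", offset = 30),
                  list(motif = "TGCATG", region = "downstream_intron",
                       offset = 10)),
    seed = 12
  )
  sq <- g$rs$sequence
  for (k in seq_len(nrow(g$truth))) {
    s <- g$truth$start[k]; mlen <- nchar(g$truth$motif[k])
    expect_equal(substr(sq, s + 1, s + mlen), g$truth$motif[k])
  }
  # determinism
  g2 <- generate_motif_sequence(
    30, 54, 30,
    plants = list(list(motif = "CACACGG", region = "exon", offset = 5),
                  list(motif = "GGGG", region = "exon", offset = 30),
                  list(motif = "TGCATG", region = "downstream_intron",
                       offset = 10)),
    seed = 12
  )
  expect_identical(g$rs$sequence, g2$rs$sequence)
  # G-free background with planted runs: exactly the planted runs found
  gfree <- generate_motif_sequence(
    20, 40, 20, seed = 6, background = c("A", "C", "T"),
    plants = list(list(motif = "GGG", region = "exon", offset = 2),
                  list(motif = "GGGG", region = "downstream_intron",
                       offset = 8))
  )
  runs <- find_g_runs(gfree$rs)
  expect_equal(nrow(runs), 2)
  expect_setequal(runs$start, gfree$truth$start)
  # FASTA output round-trips
  fa <- tempfile(fileext = ".fa")
  generate_motif_sequence(10, 10, 10, seed = 2, fasta = fa)
  ss <- Biostrings::readDNAStringSet(fa)
  expect_equal(unname(as.character(ss)),
               generate_motif_sequence(10, 10, 10, seed = 2)$rs$sequence)
  expect_error(
    generate_motif_sequence(10, 10, 10,
                            plants = list(list(motif = "AAAA", region = "exon",
                                               offset = 8))),
    "does not fit"
  )
})

test_that("metabolite generator is deterministic and centres on the truth", {
  means <- list(WT = c(ATP = 9, ADP = 1, AMP = 0.2))
  p1 <- generate_metabolite_profiles(means, n_per_group = 5, sdlog = 0.1,
                                     seed = 77)
  p2 <- generate_metabolite_profiles(means, n_per_group = 5, sdlog = 0.1,
                                     seed = 77)
  expect_identical(p1, p2)
  # configured charge recovered under noise
  truth_aec <- adenylate_energy_charge(means$WT)
  many <- generate_metabolite_profiles(means, n_per_group = 200,
                                       sdlog = 0.1, seed = 13)
  aecs <- vapply(many, adenylate_energy_charge, numeric(1))
  expect_lt(abs(mean(aecs) - truth_aec), 3 * sd(aecs) / sqrt(length(aecs)) +
              0.01)
})
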