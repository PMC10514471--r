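srsf1 <- read_pwm(system.file("extdata", "srsf1_sf2asf_pwm.tsv",
                              package = "cassPSI"))

test_that("SRSF1 matrix scores the two exonic enhancer motifs as published", {
  expect_equal(score_pwm_window(srsf1, "CACACGG"), 5.86, tolerance = 1e-9)
  expect_equal(score_pwm_window(srsf1, "CACAGGG"), 5.25, tolerance = 1e-9)
  expect_equal(srsf1$threshold, 1.956)
  expect_error(score_pwm_window(srsf1, "CACACG"), "width")
  zero <- pwm(matrix(0, nrow = 4, ncol = 4))
  expect_equal(score_pwm_window(zero, "ACGT"), 0)
})

test_that("PWM scan reports exonic SRSF1 hits as enhancers", {
  g <- generate_motif_sequence(
    up_len = 40, exon_len = 54, down_len = 40,
    plants = list(list(motif = "CACACGG", region = "exon", offset = 10)),
    seed = 3, background = c("A", "T")  # no C/G background: collision-free
  )
  hits <- scan_pwm(g$rs, srsf1)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 50)
  expect_equal(hits$region, "exon")
  expect_equal(hits$predicted_effect, "enhance")
  expect_equal(hits$score, 5.86, tolerance = 1e-9)

  none <- scan_pwm(region_sequence(strrep("A", 60), 20, 20, 20), srsf1)
  expect_equal(nrow(none), 0)
})

test_that("PWM scan equals brute-force all-window scoring", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(50:300, 1)
    sq <- random_dna(n)
    u <- sample(5:(n - 10), 1); e <- sample(1:(n - u - 1), 1)
    rs <- region_sequence(sq, u, e, n - u - e)
    hits <- scan_pwm(rs, srsf1)
    oracle <- oracle_pwm_scan(sq, srsf1$weights, srsf1$threshold)
    expect_equal(hits$start, oracle$start)
    expect_equal(hits$score, oracle$score, tolerance = 1e-12)
    expect_true(!is.unsorted(hits$start, strictly = TRUE))
    # report-all mode scores every window
    all_hits <- scan_pwm(rs, srsf1, report_below_threshold = TRUE)
    expect_equal(nrow(all_hits), n - srsf1$width + 1)
  }
})

test_that("Rbfox finder reports (U)GCAUG with position-dependent effects", {
  g <- generate_motif_sequence(
    up_len = 30, exon_len = 30, down_len = 30,
    plants = list(list(motif = "TGCATG", region = "downstream_intron",
                       offset = 5)),
    seed = 8, background = c("A", "C")
  )
  hits <- find_rbfox_motifs(g$rs)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 66)  # GCATG core starts after the planted T
  expect_equal(hits$region, "downstream_intron")
  expect_equal(hits$predicted_effect, "enhance")
  expect_equal(hits$note, "U_preceded")

  expect_equal(nrow(find_rbfox_motifs(
    region_sequence(strrep("A", 30), 10, 10, 10))), 0)
})

test_that("planted Rbfox motifs across regions recover position and effect", {
  plants <- list(
    list(motif = "GCATG", region = "upstream_intron", offset = 2),
    list(motif = "TGCATG", region = "upstream_intron", offset = 20),
    list(motif = "GCATG", region = "exon", offset = 4),
    list(motif = "TGCATG", region = "exon", offset = 30),
    list(motif = "GCATG", region = "downstream_intron", offset = 0),
    list(motif = "TGCATG", region = "downstream_intron", offset = 12)
  )
  g <- generate_motif_sequence(50, 50, 50, plants = plants, seed = 21,
                               background = c("A", "C"))
  hits <- find_rbfox_motifs(g$rs)
  expect_equal(nrow(hits), 6)
  expected_effect <- c(upstream_intron = "repress", exon = "repress",
                       downstream_intron = "enhance")
  expect_equal(hits$predicted_effect, unname(expected_effect[hits$region]))
  # each planted core position is recovered
  core_starts <- g$truth$start + ifelse(nchar(g$truth$motif) == 6, 1, 0)
  expect_setequal(hits$start, core_starts)
  expect_identical(find_rbfox_motifs(g$rs), find_rbfox_motifs(g$rs))
})

test_that("G-run finder reports maximal runs with hnRNP position effects", {
  rs <- region_sequence("AAGGGGTTGGGAA", 0, 13, 0)
  runs <- find_g_runs(rs, min_run = 3)
  expect_equal(nrow(runs), 2)
  expect_equal(runs$score, c(4, 3))
  expect_equal(runs$start, c(2, 8))
  expect_equal(runs$predicted_effect, c("repress", "repress"))

  expect_equal(nrow(find_g_runs(region_sequence("GG", 0, 2, 0), 3)), 0)

  intronic <- region_sequence("AAAAAGGGAAAA", 0, 4, 8)
  expect_equal(find_g_runs(intronic)$predicted_effect, "enhance")
})

test_that("G-run finder equals the brute-force walk; min_run 1 partitions Gs", {
  set.seed(13)
  for (i in 1:60) {
    n <- sample(30:300, 1)
    sq <- random_dna(n, letters = c("A", "G", "G", "T"))  # G-rich
    u <- sample(1:(n - 5), 1); e <- sample(1:(n - u - 1), 1)
    rs <- region_sequence(sq, u, e, n - u - e)
    for (mr in c(1, 3, 5)) {
      runs <- find_g_runs(rs, min_run = mr)
      oracle <- oracle_g_runs(sq, mr)
      expect_equal(runs$start, oracle$start)
      expect_equal(runs$end - runs$start, oracle$len)
    }
    all_g <- find_g_runs(rs, min_run = 1)
    expect_equal(sum(all_g$score),
                 sum(strsplit(sq, "")[[1]] == "G"))
  }
})

test_that("Rbfox finder equals brute-force substring comparison", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(50:400, 1)
    sq <- random_dna(n)
    rs <- region_sequence(sq, 10, 10, n - 20)
    expect_equal(find_rbfox_motifs(rs)$start, oracle_rbfox(sq))
  }
})

test_that("hits lie inside their assigned regions", {
  set.seed(23)
  for (i in 1:40) {
    n <- 120
    sq <- random_dna(n, letters = c("A", "C", "G", "T", "G"))
    rs <- region_sequence(sq, 40, 40, 40)
    hits <- rbind(find_g_runs(rs, 2)[, c("start", "end", "region")],
                  find_rbfox_motifs(rs)[, c("start", "end", "region")],
                  scan_pwm(rs, srsf1, threshold = -100)[,
                    c("start", "end", "region")])
    for (k in seq_len(nrow(hits))) {
      if (is.na(hits$region[k])) next
      r <- rs$regions[rs$regions$region == hits$region[k], ]
      expect_true(r$start <= hits$start[k] && hits$end[k] <= r$end)
    }
  }
})

test_that("conservation matrix flags clade-restricted motifs", {
  plant_all <- list(
    list(motif = "CACACGG", region = "exon", offset = 2),
    list(motif = "GGG", region = "exon", offset = 20),
    list(motif = "TGCATG", region = "downstream_intron", offset = 4)
  )
  mams <- lapply(1:4, function(k) {
    generate_motif_sequence(30, 40, 30, plants = plant_all, seed = 100 + k,
                            background = c("A", "T"))$rs
  })
  outs <- lapply(1:2, function(k) {
    generate_motif_sequence(30, 40, 30, seed = 200 + k,
                            background = c("A", "T"))$rs
  })
  per_species <- c(setNames(mams, paste0("mammal", 1:4)),
                   setNames(outs, paste0("fish", 1:2)))
  motifs <- list(
    SRSF1_site1 = list(type = "pattern", pattern = "CACACGG",
                       region = "exon"),
    exonic_g_run = list(type = "g_run", region = "exon"),
    rbfox_down = list(type = "rbfox", region = "downstream_intron")
  )
  cons <- motif_conservation(per_species, motifs,
                             clade = paste0("mammal", 1:4))
  expect_true(all(as.matrix(cons[paste0("mammal", 1:4), ])))
  expect_false(any(as.matrix(cons[paste0("fish", 1:2), ])))
  expect_equal(attr(cons, "clade_specific"),
               c(SRSF1_site1 = TRUE, exonic_g_run = TRUE,
                 rbfox_down = TRUE))

  single <- motif_conservation(per_species["mammal1"], motifs)
  expect_equal(nrow(single), 1)
  expect_null(attr(single, "clade_specific"))

  absent <- motif_conservation(per_species,
                               list(gone = list(type = "pattern",
                                                pattern = "CGCGCGCG")))
  expect_false(any(absent$gone))
})
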