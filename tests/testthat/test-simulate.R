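small_cfg <- function(seed = 1, ...) {
  sim_config(clades = list(cA = c("A1", "A2"), cB = c("B1", "B2"),
                           cC = c("C1", "C2"), cD = c("D1", "D2")),
             gene_lengths = c(ND2 = 480, COI = 600, COII = 450, ND3 = 351),
             seed = seed, ...)
}

test_that("a fixed seed gives identical genomes and truth", {
  s1 <- simulate_mitogenomes(small_cfg(seed = 5))
  s2 <- simulate_mitogenomes(small_cfg(seed = 5))
  expect_identical(lapply(s1$genomes, `[[`, "sequence"),
                   lapply(s2$genomes, `[[`, "sequence"))
  expect_identical(s1$truth$agg_sites, s2$truth$agg_sites)
  expect_identical(s1$truth$cr_repeats, s2$truth$cr_repeats)
  s3 <- simulate_mitogenomes(small_cfg(seed = 6))
  expect_false(identical(s1$genomes[["A1"]]$sequence,
                         s3$genomes[["A1"]]$sequence))
})

test_that("genome-wide A+T tracks the configured content", {
  sim <- simulate_mitogenomes(sim_config(seed = 26))
  for (g in sim$genomes[c(1, 7)]) {
    expect_gte(nchar(g$sequence), 15000L)
    at <- mean(strsplit(g$sequence, "")[[1]] %in% c("A", "T"))
    expect_lt(abs(at - 0.7), 0.03)
  }
})

test_that("conserved columns are invariant in the emitted translations", {
  sim <- simulate_mitogenomes(small_cfg(seed = 27))
  cfg <- small_cfg(seed = 27)
  aas <- lapply(names(sim$genomes), function(t) {
    code <- if (sim$truth$code_map[[t]] == "K") mito_code_agg_lys() else mito_code()
    cds <- paste(unlist(concatenated_pcgs(sim$genomes[[t]])), collapse = "")
    strsplit(translate_cds(cds, code, warn_internal_stops = FALSE), "")[[1]]
  })
  aa_mat <- do.call(rbind, aas)
  cons <- sim$truth$conserved_sites
  expect_true(all(apply(aa_mat[, cons, drop = FALSE], 2,
                        function(col) length(unique(col)) == 1L)))
  expect_false(any(aa_mat == "*"))
})

test_that("AGG codons are planted only at code-consistent conserved columns", {
  sim <- simulate_mitogenomes(small_cfg(seed = 28))
  root_aa <- ifelse(sim$truth$code_map == "K", "K", "S")
  for (t in names(sim$genomes)) {
    sites <- sim$truth$agg_sites[[t]]
    expect_length(sites, 5L)
    expect_true(all(sites %in% sim$truth$conserved_sites))
    cds <- paste(unlist(concatenated_pcgs(sim$genomes[[t]])), collapse = "")
    codons <- substring(cds, 3 * sites - 2, 3 * sites)
    expect_true(all(codons == "AGG"))
  }
})

test_that("impossible planting demands fail loudly", {
  expect_error(simulate_mitogenomes(small_cfg(seed = 1,
                                              agg_occurrences = 10000L)),
               "exceeds available")
})

test_that("fixture files round-trip through the parsers", {
  sim <- simulate_mitogenomes(small_cfg(seed = 29))
  dir <- tempfile("fixtures")
  write_fixture_set(sim$genomes, sim$truth, dir)
  g <- sim$genomes[["B1"]]
  g2 <- parse_feature_table(file.path(dir, "B1.fasta"),
                            file.path(dir, "B1.features.tsv"))
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$features, g$features)
  truth_tab <- read.delim(file.path(dir, "truth_code.tsv"))
  expect_equal(nrow(truth_tab), length(sim$genomes))
  expect_equal(stats::setNames(truth_tab$agg_meaning, truth_tab$taxon),
               sim$truth$code_map[truth_tab$taxon])
  reps <- read.delim(file.path(dir, "truth_repeats.tsv"))
  expect_equal(nrow(reps),
               sum(vapply(sim$truth$cr_repeats, nrow, integer(1))))
})

test_that("planted repeats match the detector on emitted control regions", {
  sim <- simulate_mitogenomes(sim_config(seed = 30))
  for (t in c("A1", "B2", "D3")) {
    found <- cr_architecture(sim$genomes[[t]])$repeats
    truth <- sim$truth$cr_repeats[[t]]
    expect_equal(found$start, truth$start)
    expect_equal(found$unit_length, truth$unit_length)
    expect_equal(found$full_copies, truth$full_copies)
    expect_equal(found$partial_length, truth$partial_length)
    expect_equal(found$unit_seq, truth$unit_seq)
  }
})
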