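# hand-built alignments: one gene block from a character matrix
block_aln <- function(m) codon_alignment(list(g = m))

test_that("column filter honors occupancy, conservation and the target carve-out", {
  taxa <- paste0("t", 1:10)
  m <- matrix("AAA", 10, 4, dimnames = list(taxa, NULL))
  m[1:3, 2] <- "---"                      # 3/10 gaps
  m[1:3, 3] <- "TTT"; m[4:5, 3] <- "CCC"  # highly variable column
  m[6:7, 3] <- "GGA"; m[8:10, 3] <- "ATT"
  m[1:6, 4] <- "AGG"                      # target-rich but otherwise conserved
  m[7:10, 4] <- "AAA"
  aln <- block_aln(m)

  ident <- filter_columns(aln, 0, 0)
  expect_equal(ncol(ident$blocks$g), 4L)

  f <- filter_columns(aln, min_occupancy = 0.8, min_conservation = 0.5)
  kept <- attr(f, "kept")$g
  expect_false(2L %in% kept)  # occupancy 0.7 < 0.8
  expect_false(3L %in% kept)  # top amino-acid fraction 0.3 < 0.5
  expect_true(4L %in% kept)   # conservation among non-AGG cells = 4/4
  expect_true(1L %in% kept)

  all_target <- block_aln(matrix("AGG", 10, 1, dimnames = list(taxa, NULL)))
  expect_equal(ncol(filter_columns(all_target, 0.8, 0.9)$blocks$g), 1L)

  expect_warning(filter_columns(block_aln(m[, 2, drop = FALSE]), 0.9, 0.5),
                 "all alignment columns removed")
})

test_that("majority rule, ties, and UNUSED follow the stated semantics", {
  taxa <- paste0("t", 1:10)
  # focal t1 has one AGG; 8 others have Lys codons, 1 has a Ser codon
  m <- matrix("ATG", 10, 2, dimnames = list(taxa, NULL))
  m[1, 1] <- "AGG"; m[2:9, 1] <- "AAA"; m[10, 1] <- "TCA"
  a <- predict_codon_meaning(block_aln(m), "t1")
  expect_equal(a$predicted, "K")
  expect_equal(a$support, 8 / 9)
  expect_equal(a$n_occurrences, 1L)

  # aggregated tie K:2 vs S:2 -> UNPREDICTED
  m2 <- matrix("ATG", 5, 1, dimnames = list(paste0("t", 1:5), NULL))
  m2[1, 1] <- "AGG"; m2[2:3, 1] <- "AAA"; m2[4:5, 1] <- "TCA"
  a2 <- predict_codon_meaning(block_aln(m2), "t1", min_informative = 3)
  expect_equal(a2$predicted, "UNPREDICTED")

  # zero occurrences -> UNUSED
  a3 <- predict_codon_meaning(block_aln(m2), "t2")
  expect_equal(a3$predicted, "UNUSED")
  expect_equal(a3$n_occurrences, 0L)

  # too few informative taxa -> UNPREDICTED (not a guess)
  m3 <- matrix("---", 4, 1, dimnames = list(paste0("t", 1:4), NULL))
  m3[1, 1] <- "AGG"; m3[2, 1] <- "AAA"
  a4 <- predict_codon_meaning(block_aln(m3), "t1", min_informative = 3)
  expect_equal(a4$predicted, "UNPREDICTED")

  # other taxa's target cells are excluded from the tally (no circularity)
  m4 <- matrix("AAA", 6, 1, dimnames = list(paste0("t", 1:6), NULL))
  m4[1:3, 1] <- "AGG"
  a5 <- predict_codon_meaning(block_aln(m4), "t1")
  expect_equal(a5$predicted, "K")
  expect_equal(sum(a5$tally), 3L)

  expect_error(predict_codon_meaning(block_aln(m4), "t1", target = "AGZ"),
               "not a valid codon")
  expect_error(predict_codon_meaning(block_aln(m4), "nope"), "not in alignment")
})

test_that("prediction is invariant to taxon and gene-block order", {
  sim <- simulate_mitogenomes(sim_config(
    clades = list(cA = c("A1", "A2"), cB = c("B1", "B2"),
                  cC = c("C1", "C2"), cD = c("D1", "D2")),
    gene_lengths = c(ND2 = 300, COI = 450, COII = 300),
    seed = 31))
  pcgs <- lapply(sim$genomes, concatenated_pcgs)
  aln <- filter_columns(build_codon_alignment(pcgs))
  base <- predict_all(aln)

  perm <- rev(aln$taxa)
  aln2 <- codon_alignment(lapply(aln$blocks, function(b) b[perm, , drop = FALSE]))
  p2 <- predict_all(aln2)
  expect_equal(p2$predicted[match(base$taxon, p2$taxon)], base$predicted)

  aln3 <- codon_alignment(rev(aln$blocks))
  p3 <- predict_all(aln3)
  expect_equal(p3$predicted, base$predicted)
})

test_that("raising the majority threshold only moves calls toward UNPREDICTED", {
  sim <- simulate_mitogenomes(sim_config(
    clades = list(cA = c("A1", "A2"), cB = c("B1", "B2"),
                  cC = c("C1", "C2"), cD = c("D1", "D2")),
    gene_lengths = c(ND2 = 300, COI = 450, COII = 300),
    seed = 32))
  pcgs <- lapply(sim$genomes, concatenated_pcgs)
  aln <- filter_columns(build_codon_alignment(pcgs))
  prev <- predict_all(aln, majority_threshold = 0.5)
  for (thr in c(0.7, 0.9, 1.0)) {
    cur <- predict_all(aln, majority_threshold = thr)
    flip <- prev$predicted %in% c("K", "S") & cur$predicted %in% c("K", "S") &
      prev$predicted != cur$predicted
    expect_false(any(flip))
    prev <- cur
  }
})

test_that("planted code maps are recovered on reduced synthetic sets", {
  for (seed in 1:5) {
    sim <- simulate_mitogenomes(sim_config(
      clades = list(cA = c("A1", "A2"), cB = c("B1", "B2"),
                    cC = c("C1", "C2"), cD = c("D1", "D2")),
      gene_lengths = c(ND2 = 480, COI = 600, COII = 450, ND3 = 351),
      seed = 100 + seed))
    pcgs <- lapply(sim$genomes, concatenated_pcgs)
    pa <- predict_all(filter_columns(build_codon_alignment(pcgs)))
    got <- stats::setNames(pa$predicted, pa$taxon)
    expect_equal(got[names(sim$truth$code_map)], sim$truth$code_map)
  }
})
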