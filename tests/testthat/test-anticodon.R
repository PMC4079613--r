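test_that("wobble decoding reproduces the reassignment-relevant anticodons", {
  expect_equal(decoded_codons("CUU"), "AAG")
  expect_equal(decoded_codons("UUU"), c("AAA", "AAG"))
  expect_equal(decoded_codons("GCU"), c("AGC", "AGU"))
  expect_equal(decoded_codons("UCU"), c("AGA", "AGG"))
  # custom rules are honored
  expect_equal(decoded_codons("CUU", wobble_rules(C = c("G", "A"))),
               c("AAA", "AAG"))
})

test_that("the standard 22 anticodons cover all 62 sense codons consistently", {
  cov <- decoding_coverage()
  expect_length(cov$uncovered, 0L)
  expect_length(cov$conflicts, 0L)
  sense <- sum(mito_code() != "*")
  expect_equal(sense, 62L)
  expect_setequal(unique(cov$claims$codon),
                  mitocode:::dna_to_rna(names(mito_code())[mito_code() != "*"]))
  # every claim translates to the claiming tRNA's amino acid
  code <- mito_code()
  expect_true(all(code[mitocode:::rna_to_dna(cov$claims$codon)] ==
                  cov$claims$aa))
})

test_that("annotated anticodon offsets are sliced and transcribed", {
  g <- toy_genome()
  rec <- extract_anticodon(g, "tRNA-Met")
  expect_equal(rec$anticodon, "CAU")
  expect_equal(rec$source, "annotation")
  expect_error(extract_anticodon(g, "tRNA-Lys"), "no tRNA feature")
})

test_that("the structural heuristic recovers planted anticodons", {
  acs <- c(standard_anticodons()$anticodon, "UUU", "UCU", "CUU", "GCU")
  for (ac in unique(acs)) {
    s <- mitocode:::trna_scaffold(ac)
    feats <- data.frame(name = "tRNA-Lys", kind = "tRNA", start = 0L,
                        end = nchar(s), strand = "+",
                        anticodon_offset = NA_integer_)
    g <- mitogenome("h1", s, feats)
    rec <- extract_anticodon(g, "tRNA-Lys")
    expect_equal(rec$anticodon, ac)
    expect_equal(rec$source, "heuristic")
    expect_true(rec$has_dhu_stem)
  }
  # unfoldable sequence: no stem with >= 3 pairs
  g2 <- mitogenome("h2", strrep("AC", 33),
                   data.frame(name = "tRNA-Lys", kind = "tRNA", start = 0L,
                              end = 66L, strand = "+",
                              anticodon_offset = NA_integer_))
  expect_error(extract_anticodon(g2, "tRNA-Lys"), "not localizable")
})

test_that("Fisher association matches exhaustive enumeration", {
  # perfect association, 4 Ser/UCU vs 2 Lys/GCU
  antic <- data.frame(taxon = paste0("t", 1:6),
                      anticodon = c(rep("UCU", 4), rep("GCU", 2)))
  asg <- data.frame(taxon = paste0("t", 1:6),
                    codon = "AGG",
                    predicted = c(rep("S", 4), rep("K", 2)),
                    n_occurrences = 5L, support = 1)
  res <- anticodon_code_association(antic, asg)
  expect_equal(res$fisher_p, 1 / 15)
  expect_equal(res$fisher_p, fisher_enum_p(res$table))

  # degenerate margin: everyone shares the anticodon
  antic2 <- transform(antic, anticodon = "GCU")
  expect_equal(anticodon_code_association(antic2, asg)$fisher_p, 1)

  # UNUSED/UNPREDICTED taxa are excluded; too few informative -> error
  asg3 <- transform(asg, predicted = c("S", rep("UNUSED", 5)))
  expect_error(anticodon_code_association(antic, asg3), "fewer than 2")

  # random 2x2 tables with n <= 12 agree with the enumeration oracle
  set.seed(14)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    states <- sample(c("UCU", "GCU"), n, replace = TRUE)
    preds <- sample(c("S", "K"), n, replace = TRUE)
    if (length(unique(states)) < 2 && length(unique(preds)) < 2) next
    a <- data.frame(taxon = paste0("x", 1:n), anticodon = states)
    b <- data.frame(taxon = paste0("x", 1:n), codon = "AGG",
                    predicted = preds, n_occurrences = 1L, support = 1)
    res <- anticodon_code_association(a, b)
    expect_equal(res$fisher_p, fisher_enum_p(res$table), tolerance = 1e-12)
  }
})

test_that("association type-I error is controlled under label shuffling", {
  set.seed(15)
  n <- 12
  states <- c(rep("UCU", 6), rep("GCU", 6))
  hits <- 0L
  n_perm <- 500L
  for (i in seq_len(n_perm)) {
    preds <- sample(c(rep("S", 6), rep("K", 6)))
    a <- data.frame(taxon = paste0("x", 1:n), anticodon = states)
    b <- data.frame(taxon = paste0("x", 1:n), codon = "AGG",
                    predicted = preds, n_occurrences = 1L, support = 1)
    p <- anticodon_code_association(a, b)$fisher_p
    if (p <= 0.05) hits <- hits + 1L
  }
  expect_lte(hits / n_perm, 0.07)
})

test_that("anticodon tables track the planted correlated states", {
  sim <- simulate_mitogenomes(sim_config(seed = 8))
  tab <- anticodon_table(sim$genomes)
  lys <- tab[tab$trna == "tRNA-Lys", ]
  ser <- tab[tab$trna == "tRNA-Ser(S1)", ]
  for (t in names(sim$truth$code_map)) {
    expect_equal(lys$anticodon[lys$taxon == t],
                 sim$truth$anticodon_plan[[t]][["tRNA-Lys"]])
    expect_equal(ser$anticodon[ser$taxon == t],
                 sim$truth$anticodon_plan[[t]][["tRNA-Ser(S1)"]])
  }
})
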