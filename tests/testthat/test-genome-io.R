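test_that("gene names normalize onto the canonical vocabulary", {
  expect_equal(normalize_gene_name("COX1"),
               list(name = "COI", kind = "PCG"))
  expect_equal(normalize_gene_name("cob"),
               list(name = "CYTB", kind = "PCG"))
  expect_equal(normalize_gene_name("trnL-UUR"),
               list(name = "tRNA-Leu(L2)", kind = "tRNA"))
  expect_equal(normalize_gene_name("tRNA-Ser(AGN)"),
               list(name = "tRNA-Ser(S1)", kind = "tRNA"))
  expect_equal(normalize_gene_name("12S rRNA"),
               list(name = "srRNA", kind = "rRNA"))
  expect_warning(res <- normalize_gene_name("ORF-X"), "unmappable")
  expect_equal(res$kind, "misc_noncoding")
})

test_that("GenBank parsing converts coordinates, strands and names", {
  gb <- write_toy_genbank(tempfile(fileext = ".gb"))
  g <- parse_genbank(gb$path)
  expect_s3_class(g, "mitogenome")
  expect_identical(g$sequence, gb$seq)
  expect_true(g$circular)
  f <- g$features
  coi <- f[f$name == "COI", ]
  expect_equal(c(coi$start, coi$end), c(98L, 149L))
  expect_equal(coi$strand, "+")
  expect_equal(coi$kind, "PCG")
  leu <- f[f$name == "tRNA-Leu(L2)", ]
  expect_equal(leu$strand, "-")
  expect_equal(f[f$name == "srRNA", "kind"], "rRNA")
  met <- f[f$name == "tRNA-Met", ]                 # origin-spanning join
  expect_equal(c(met$start, met$end), c(289L, 355L))
  expect_equal(nchar(gene_sequence(g, "tRNA-Met")), 66L)
})

test_that("malformed GenBank records fail with a located error", {
  p <- tempfile()
  writeLines(c("LOCUS       X 10 bp",
               "FEATURES             Location/Qualifiers",
               "     CDS             5..x9",
               "ORIGIN", "        1 acgtacgtac", "//"), p)
  expect_error(parse_genbank(p), "line")
})

test_that("feature tables round-trip exactly and honor conventions", {
  g <- toy_genome()
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_genome_fasta(g, fa)
  write_feature_table(g, tsv)
  g2 <- parse_feature_table(fa, tsv, genus = g$genus, family = g$family)
  expect_identical(g2$features, g$features)
  expect_identical(g2$sequence, g$sequence)

  # 1-based inclusive at the file boundary: row "srRNA 1 700 -" on 1000 bp
  fa2 <- tempfile(fileext = ".fasta")
  writeLines(c(">mini", random_seq(1000)), fa2)
  tsv2 <- tempfile()
  writeLines(c("name\tkind\tstart\tend\tstrand",
               "srRNA\trRNA\t1\t700\t-",
               "control_region\tcontrol_region\t701\t1100\t+"), tsv2)
  g3 <- parse_feature_table(fa2, tsv2)
  expect_equal(g3$features$start, c(0L, 700L))
  expect_equal(g3$features$end[1], 700L)
  expect_equal(g3$features$end[2], 1100L)  # origin-spanning on circular
  expect_error(parse_feature_table(fa2, tsv2, circular = FALSE), "beyond")

  # empty table: zero features, later census reports one full-length NCR
  tsv3 <- tempfile()
  writeLines("name\tkind\tstart\tend\tstrand", tsv3)
  g4 <- parse_feature_table(fa2, tsv3)
  expect_equal(nrow(g4$features), 0L)
})

test_that("gene_sequence is strand-aware and handles the origin", {
  fa <- tempfile(fileext = ".fasta")
  s <- random_seq(1000)
  writeLines(c(">g", s), fa)
  tsv <- tempfile()
  writeLines(c("name\tkind\tstart\tend\tstrand",
               "ND2\tPCG\t101\t104\t+",
               "COI\tPCG\t201\t204\t-",
               "control_region\tcontrol_region\t991\t1010\t+"), tsv)
  g <- parse_feature_table(fa, tsv)
  expect_equal(gene_sequence(g, "ND2"), substr(s, 101, 104))
  expect_equal(gene_sequence(g, "COI"), revcomp(substr(s, 201, 204)))
  # origin-spanning slice equals the rotation oracle
  rotated <- paste0(substr(s, 501, 1000), substr(s, 1, 500))
  expect_equal(gene_sequence(g, "control_region"),
               substr(rotated, 991 - 500, 1010 - 500))
  expect_equal(nchar(gene_sequence(g, "control_region")), 20L)
  expect_error(gene_sequence(g, "ND5"), "no feature")
})

test_that("feature lengths and reverse-complement invariants hold", {
  set.seed(11)
  for (i in 1:20) {
    s <- random_seq(sample(1:80, 1))
    expect_identical(revcomp(revcomp(s)), s)
  }
  g <- toy_genome()
  for (i in seq_len(nrow(g$features))) {
    f <- g$features[i, ]
    expect_equal(nchar(gene_sequence(g, f$name)), f$end - f$start)
  }
})

test_that("concatenated_pcgs returns canonical order and warns on absences", {
  sim <- simulate_mitogenomes(sim_config(seed = 42))
  g <- sim$genomes[[1]]
  pcgs <- concatenated_pcgs(g)
  expect_equal(names(pcgs), mitocode:::PCG_ORDER)
  expect_equal(sum(nchar(unlist(pcgs))), sum(sim$truth$gene_lengths))

  g$features <- g$features[g$features$name != "ND2", ]
  expect_warning(p2 <- concatenated_pcgs(g), "ND2")
  expect_equal(length(p2), 12L)
})
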