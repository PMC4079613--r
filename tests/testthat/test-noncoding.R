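mini_genome <- function(feats, len = 1000L, seq = NULL) {
  mitogenome("m1", seq %||% random_seq(len), feats)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the census reports gaps, not junctions or overlaps", {
  f <- data.frame(name = c("ND2", "COI"), kind = "PCG",
                  start = c(0L, 100L), end = c(100L, 200L), strand = "+",
                  anticodon_offset = NA_integer_)
  g <- mini_genome(f, 200L)
  cen <- noncoding_census(g)
  expect_equal(nrow(cen), 0L)

  f2 <- transform(f, start = c(0L, 103L), end = c(100L, 200L))
  cen2 <- noncoding_census(mini_genome(f2, 200L))
  expect_equal(cen2$length, 3L)
  expect_equal(c(cen2$left, cen2$right), c("ND2", "COI"))

  f3 <- transform(f, start = c(0L, 90L), end = c(100L, 200L))
  cen3 <- noncoding_census(mini_genome(f3, 200L))
  expect_equal(nrow(cen3), 0L)
  expect_equal(attr(cen3, "overlaps")$overlap, 10L)
})

test_that("census conserves total length on synthetic genomes", {
  sim <- simulate_mitogenomes(sim_config(seed = 17))
  g <- sim$genomes[[3]]
  cen <- noncoding_census(g)
  feat_len <- sum(g$features$end - g$features$start)
  over <- attr(cen, "overlaps")
  expect_equal(feat_len + sum(cen$length) - sum(over$overlap %||% 0),
               nchar(g$sequence))
})

test_that("control region location follows annotation, then flanks", {
  sim <- simulate_mitogenomes(sim_config(seed = 18))
  g <- sim$genomes[[1]]
  cr <- locate_control_region(g)                 # explicit annotation
  f <- g$features[g$features$kind == "control_region", ]
  expect_equal(c(cr$start, cr$end), c(f$start, f$end))

  g2 <- g
  g2$features <- g2$features[g2$features$kind != "control_region", ]
  cr2 <- locate_control_region(g2)               # srRNA..tRNA-Ile gap
  expect_equal(c(cr2$start, cr2$end - cr2$start), c(f$start, f$end - f$start))
  expect_setequal(c(cr2$left, cr2$right), c("srRNA", "tRNA-Ile"))

  g3 <- g2
  g3$features <- g3$features[g3$features$name != "srRNA", ]
  expect_error(locate_control_region(g3), "flanks missing")
})

test_that("termination-site search finds exact and degraded copies", {
  ref <- "TACTAAAGGTTCAATG"
  region <- paste0(random_seq(20), ref, random_seq(14))
  set.seed(19)
  hit <- dmttf_search(region, ref)
  expect_equal(hit$identity, 100)
  expect_equal(hit$window_length, nchar(ref))
  expect_equal(substr(region, hit$offset + 1, hit$offset + hit$window_length),
               ref)

  # exhaustive ungapped window scan lower-bounds the local alignment
  set.seed(20)
  rand <- random_seq(50)
  best_window <- max(vapply(1:(50 - 15), function(i) {
    w <- substr(rand, i, i + 15)
    mean(strsplit(w, "")[[1]] == strsplit(ref, "")[[1]])
  }, numeric(1)))
  hit2 <- dmttf_search(rand, ref)
  expect_gte(hit2$identity, 100 * best_window * 0.999)

  expect_true(is.na(dmttf_search("ACG", ref)$identity))
})

test_that("pairwise identity matches hand-checked alignments", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT")$identity, 100)
  expect_equal(pairwise_identity("AAAA", "AAAT")$identity, 75)
  # single deletion: 7 matches over 8 columns
  expect_equal(pairwise_identity("ACGTACGT", "ACGTCGT")$identity, 100 * 7 / 8)
  # two substitutions, no gaps: 6/8
  expect_equal(pairwise_identity("ACGTACGT", "ACGAACGA")$identity, 75)
  # gap-excluded convention drops the gap column
  expect_equal(pairwise_identity("ACGTACGT", "ACGTCGT",
                                 gap_columns = "exclude")$identity, 100)
})

test_that("identity is symmetric and invariant under joint reverse complement", {
  set.seed(21)
  for (i in 1:10) {
    a <- random_seq(sample(20:60, 1)); b <- random_seq(sample(20:60, 1))
    ab <- pairwise_identity(a, b)
    expect_equal(pairwise_identity(b, a)$identity, ab$identity)
    expect_equal(pairwise_identity(revcomp(a), revcomp(b))$identity,
                 ab$identity)
    expect_equal(pairwise_identity(a, a)$identity, 100)
  }
})

test_that("repeat masking removes arrays and keeps the background", {
  seq <- paste0("GATTACA", strrep("ACGTT", 4), "TTGACAG")
  reps <- find_tandem_repeats(seq, min_unit = 5, max_unit = 6)
  expect_equal(nrow(reps), 1L)
  expect_equal(mask_repeats(seq, reps), "GATTACATTGACAG")
  expect_equal(mask_repeats(seq, reps, retain_one = TRUE),
               "GATTACAACGTTTTGACAG")
  expect_equal(mask_repeats(seq, reps[0, ]), seq)
  arr <- strrep("ACGTT", 4)
  reps2 <- find_tandem_repeats(arr, min_unit = 5, max_unit = 6)
  expect_warning(out <- mask_repeats(arr, reps2), "empty remainder")
  expect_equal(out, "")
})

test_that("masked synthetic control regions recover the planted background", {
  sim <- simulate_mitogenomes(sim_config(seed = 22))
  g <- sim$genomes[["A1"]]
  arch <- cr_architecture(g)
  truth <- sim$truth$cr_repeats[["A1"]]
  expect_equal(arch$repeats$start, truth$start)
  expect_equal(nchar(arch$remainder),
               arch$cr$length - sum(truth$span))
  # intra-clade masked identity is high, inter-clade low
  archB <- cr_architecture(sim$genomes[["A2"]])
  archC <- cr_architecture(sim$genomes[["C1"]])
  intra <- pairwise_identity(arch$remainder, archB$remainder)$identity
  inter <- pairwise_identity(arch$remainder, archC$remainder)$identity
  expect_gt(intra, 85)
  expect_lt(inter, intra)
})
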