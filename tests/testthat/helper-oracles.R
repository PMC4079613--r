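# Independent oracles and small fixture builders shared across tests.

# Brute-force maximal exact tandem arrays: naive per-period, per-position
# character scan (no seeding, no vectorization), same candidate resolution
# (span desc, unit asc, start asc; greedy non-overlap).
brute_force_repeats <- function(seq, min_unit = 2L, max_unit = 30L,
                                min_copies = 2L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  cands <- list()
  for (p in min_unit:min(max_unit, n %/% 2L)) {
    i <- 1L
    while (i <= n - p) {
      if (ch[i] == ch[i + p]) {
        j <- i
        while (j < n - p && ch[j + 1L] == ch[j + 1L + p]) j <- j + 1L
        span <- (j - i + 1L) + p
        full <- span %/% p
        if (full >= min_copies) {
          cands[[length(cands) + 1L]] <- data.frame(
            start = i - 1L, unit_length = p,
            unit_seq = substr(seq, i, i + p - 1L),
            full_copies = full, partial_length = span %% p, span = span,
            mismatch_rate = 0)
        }
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  empty <- data.frame(start = integer(0), unit_length = integer(0),
                      unit_seq = character(0), full_copies = integer(0),
                      partial_length = integer(0), span = integer(0),
                      mismatch_rate = numeric(0))
  if (!length(cands)) return(empty)
  cands <- do.call(rbind, cands)
  cands <- cands[order(-cands$span, cands$unit_length, cands$start), ,
                 drop = FALSE]
  kept <- empty
  for (i in seq_len(nrow(cands))) {
    ci <- cands[i, ]
    if (!nrow(kept) ||
        all(ci$start >= kept$start + kept$span |
            ci$start + ci$span <= kept$start)) {
      kept <- rbind(kept, ci)
    }
  }
  kept <- kept[order(kept$start), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

# Exhaustive two-sided Fisher probability for a 2x2 table with fixed margins:
# sum of hypergeometric probabilities of all tables at most as probable as
# the observed one (with the same relative tolerance R's fisher.test uses).
fisher_enum_p <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hand OLS: slope/intercept/r2 by the closed-form sums
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  yhat <- mean(y) + slope * (x - mean(x))
  sst <- sum((y - mean(y))^2)
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r2 = if (sst == 0) NA_real_ else 1 - sum((y - yhat)^2) / sst)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small annotated genome built in code: two PCGs, one tRNA, one rRNA pair
# around a control-region-like gap
toy_genome <- function() {
  nd2 <- "ATAATTAATAAAATA"                     # 15 bp, +
  coi <- "ATGCCTAAACGAATT"                     # 15 bp, -
  trna_met <- mitocode:::trna_scaffold("CAU")  # 66 bp
  srr <- strrep("AT", 30)                      # 60 bp, -
  ile <- mitocode:::trna_scaffold("GAU")
  cr <- "TTATTATTAAACCCTTAAAT"                 # 20 bp gap before tRNA-Ile
  seqs <- c(nd2, revcomp(coi), trna_met, revcomp(srr), cr, ile)
  ends <- cumsum(nchar(seqs))
  starts <- c(0L, ends[-length(ends)])
  feats <- data.frame(
    name = c("ND2", "COI", "tRNA-Met", "srRNA", "tRNA-Ile"),
    kind = c("PCG", "PCG", "tRNA", "rRNA", "tRNA"),
    start = starts[c(1, 2, 3, 4, 6)], end = ends[c(1, 2, 3, 4, 6)],
    strand = c("+", "-", "+", "-", "+"),
    anticodon_offset = c(NA, NA, 38L, NA, 38L))
  mitogenome("toy1", paste(seqs, collapse = ""), feats,
             circular = TRUE, genus = "Toyus", family = "Toyidae")
}

# minimal GenBank flat file written in code
write_toy_genbank <- function(path) {
  seq <- substr(paste0(strrep("A", 98),
                       "ATGCCTAAACGAATTTTAACCGGGGATTTACAAATTGATCTAGAAATTCAA",
                       strrep("T", 60), strrep("ACGT", 25)), 1, 300)
  rows <- vapply(seq(1, 300, 60), function(i) {
    chunk <- substr(seq, i, min(i + 59, 300))
    grp <- gsub("(.{10})", "\\1 ", chunk)
    sprintf("%9d %s", i, trimws(grp))
  }, character(1))
  writeLines(c(
    "LOCUS       TOYGB1                 300 bp    DNA     circular INV 01-JAN-2020",
    "DEFINITION  Toyus gbius mitochondrion, complete genome.",
    "ACCESSION   TOYGB1",
    "  ORGANISM  Toyus gbius",
    "FEATURES             Location/Qualifiers",
    "     CDS             99..149",
    "                     /gene=\"COX1\"",
    "     tRNA            complement(150..215)",
    "                     /product=\"trnL-UUR\"",
    "     rRNA            216..275",
    "                     /gene=\"12S rRNA\"",
    "     tRNA            join(290..300,1..55)",
    "                     /gene=\"trnM\"",
    "ORIGIN",
    rows,
    "//"), path)
  list(path = path, seq = seq)
}
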