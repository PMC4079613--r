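# tRNA anticodon extraction, wobble decoding and anticodon-vs-code
# association. Anticodons are always stored in standard 5'->3' notation
# (e.g. CUU for the lysine tRNA reading AAG), in RNA letters.

#' Default wobble pairing rules
#'
#' Maps the anticodon wobble base (position 34) to the set of codon
#' third-position bases it reads: G reads C and U, U reads A and G, C reads
#' G, A reads U. The defaults reproduce the textbook decodings of the
#' anticodons relevant to AGG reassignment (CUU -> AAG; UUU -> AAA, AAG;
#' GCU -> AGC, AGU; UCU -> AGA, AGG) and are overridable.
#'
#' @param G,U,C,A character vectors of codon third-position bases (RNA).
#' @return named list of class \code{wobble_rules}.
#' @export
wobble_rules <- function(G = c("C", "U"), U = c("A", "G"), C = "G", A = "U") {
  structure(list(G = G, U = U, C = C, A = A), class = "wobble_rules")
}

#' Extract a tRNA's anticodon from an annotated genome
#'
#' Uses the feature's \code{anticodon_offset} when annotated; otherwise a
#' structural heuristic: among all windows forming a 5-bp stem closing a 7-nt
#' loop, the best-pairing stem (Watson-Crick plus G-U wobble pairs, at least
#' 3 pairs required) nearest the sequence midpoint is taken as the anticodon
#' arm, and loop positions 3-5 are returned as the anticodon.
#'
#' @param genome a \code{\link{mitogenome}}.
#' @param trna canonical tRNA name, e.g. \code{"tRNA-Lys"}.
#' @return list of class \code{anticodon_record}: \code{taxon}, \code{trna},
#'   \code{anticodon} (RNA, standard 5'->3'), \code{source}
#'   (\code{"annotation"} or \code{"heuristic"}), \code{has_dhu_stem}
#'   (heuristic only: a second stem-loop found 5' of the anticodon arm).
#' @export
extract_anticodon <- function(genome, trna) {
  i <- which(genome$features$name == trna & genome$features$kind == "tRNA")
  if (!length(i)) stop("no tRNA feature named '", trna, "' in ", genome$id)
  f <- genome$features[i[1L], ]
  s <- gene_sequence(genome, trna)
  if (!is.na(f$anticodon_offset)) {
    ac <- substr(s, f$anticodon_offset + 1L, f$anticodon_offset + 3L)
    return(structure(list(taxon = genome$id, trna = trna,
                          anticodon = dna_to_rna(toupper(ac)),
                          source = "annotation", has_dhu_stem = NA),
                     class = "anticodon_record"))
  }
  loc <- locate_anticodon_loop(s)
  if (is.null(loc)) stop("anticodon not localizable in ", trna, " of ", genome$id)
  ac <- substr(s, loc$loop_start + 2L, loc$loop_start + 4L)
  structure(list(taxon = genome$id, trna = trna,
                 anticodon = dna_to_rna(toupper(ac)), source = "heuristic",
                 has_dhu_stem = loc$has_dhu_stem),
            class = "anticodon_record")
}

# Watson-Crick + GU pairing indicator
base_pairs <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
  (a == "G" & b == "C") | (a == "C" & b == "G") |
  (a == "G" & b == "T") | (a == "T" & b == "G")
}

stem_score <- function(ch, loop_start, stem = 5L, loop = 7L) {
  left <- ch[(loop_start - stem):(loop_start - 1L)]
  right <- ch[(loop_start + loop):(loop_start + loop + stem - 1L)]
  sum(base_pairs(left, rev(right)))
}

# find the best 5-bp stem / 7-nt loop; returns 1-based loop start
locate_anticodon_loop <- function(s, stem = 5L, loop = 7L, min_pairs = 3L) {
  ch <- strsplit(toupper(s), "")[[1]]
  n <- length(ch)
  starts <- seq.int(stem + 1L, n - loop - stem + 1L)
  if (!length(starts) || starts[1] > starts[length(starts)]) return(NULL)
  scores <- vapply(starts, function(i) stem_score(ch, i, stem, loop), numeric(1))
  ok <- scores >= min_pairs
  if (!any(ok)) return(NULL)
  best <- max(scores[ok])
  cand <- starts[ok & scores == best]
  centers <- cand + (loop - 1) / 2
  loop_start <- cand[which.min(abs(centers - (n + 1) / 2))]
  # DHU arm presence: any >=3-pair stem-loop strictly 5' of the anticodon arm
  dhu <- FALSE
  dhu_starts <- starts[starts + loop + stem - 1L < loop_start - stem]
  if (length(dhu_starts)) {
    dhu <- any(vapply(dhu_starts, function(i) stem_score(ch, i, stem, loop),
                      numeric(1)) >= min_pairs)
  }
  list(loop_start = loop_start, score = best, has_dhu_stem = dhu)
}

#' Codons decoded by an anticodon under wobble rules
#'
#' Codon positions 1-2 are the reverse complement of anticodon positions
#' 35-36; the third position expands according to the rule for the wobble
#' base (position 34).
#'
#' @param ac an \code{anticodon_record} from \code{\link{extract_anticodon}},
#'   or a 3-letter anticodon string in standard notation.
#' @param rules a \code{\link{wobble_rules}} object.
#' @return character vector of RNA codons.
#' @export
#' @examples
#' decoded_codons("CUU")  # "AAG"
#' decoded_codons("UCU")  # "AGA" "AGG"
decoded_codons <- function(ac, rules = wobble_rules()) {
  anticodon <- if (inherits(ac, "anticodon_record")) ac$anticodon else ac
  anticodon <- toupper(dna_to_rna(anticodon))
  stopifnot(nchar(anticodon) == 3L,
            all(strsplit(anticodon, "")[[1]] %in% c("A", "C", "G", "U")))
  wob <- substr(anticodon, 1L, 1L)
  prefix <- dna_to_rna(revcomp(substr(anticodon, 2L, 3L)))
  third <- rules[[wob]]
  sort(paste0(prefix, third))
}

#' Standard anticodons of the 22 insect mitochondrial tRNAs
#'
#' The typical (ancestral) anticodon of each tRNA in standard 5'->3'
#' notation, as used across most insects; the lysine tRNA carries CUU and the
#' AGN-serine tRNA GCU.
#'
#' @return data.frame with columns \code{trna}, \code{anticodon}.
#' @export
standard_anticodons <- function() {
  data.frame(
    trna = c("tRNA-Ala", "tRNA-Arg", "tRNA-Asn", "tRNA-Asp", "tRNA-Cys",
             "tRNA-Gln", "tRNA-Glu", "tRNA-Gly", "tRNA-His", "tRNA-Ile",
             "tRNA-Leu(L1)", "tRNA-Leu(L2)", "tRNA-Lys", "tRNA-Met",
             "tRNA-Phe", "tRNA-Pro", "tRNA-Ser(S1)", "tRNA-Ser(S2)",
             "tRNA-Thr", "tRNA-Trp", "tRNA-Tyr", "tRNA-Val"),
    anticodon = c("UGC", "UCG", "GUU", "GUC", "GCA",
                  "UUG", "UUC", "UCC", "GUG", "GAU",
                  "UAG", "UAA", "CUU", "CAU",
                  "GAA", "UGG", "GCU", "UGA",
                  "UGU", "UCA", "GUA", "UAC"))
}

#' Codon coverage of a tRNA set under a genetic code
#'
#' Assigns every sense codon of \code{code} to a decoding tRNA, box by box:
#' each anticodon first claims the codons given by the wobble rules; codons
#' of a box left unclaimed are then assigned to a claiming tRNA of the same
#' box whose amino acid matches (the modified-wobble extensions seen in
#' mitochondria, e.g. a U34 tRNA reading a whole fourfold-degenerate family
#' box, or the modified C34 of the lysine tRNA also reading AAA).
#'
#' @param anticodons data.frame as from \code{\link{standard_anticodons}}.
#' @param code a \code{\link{genetic_code}}.
#' @param rules a \code{\link{wobble_rules}}.
#' @return list with \code{claims} (data.frame codon/trna), \code{uncovered}
#'   (sense codons no tRNA reads) and \code{conflicts} (codons claimed by
#'   tRNAs of different amino acids).
#' @export
decoding_coverage <- function(anticodons = standard_anticodons(),
                              code = mito_code(), rules = wobble_rules()) {
  trna_aa <- vapply(anticodons$trna, function(nm) {
    full <- sub("^tRNA-([A-Za-z]+).*$", "\\1", nm)
    AA3_TO_1[[full]]
  }, character(1))
  claims <- data.frame(codon = character(0), trna = character(0),
                       aa = character(0))
  for (k in seq_len(nrow(anticodons))) {
    cods <- decoded_codons(anticodons$anticodon[k], rules)
    claims <- rbind(claims, data.frame(codon = cods,
                                       trna = anticodons$trna[k],
                                       aa = trna_aa[k]))
  }
  sense_rna <- dna_to_rna(names(code)[code != "*"])
  aa_of <- stats::setNames(as.character(code), dna_to_rna(names(code)))
  # same-box, same-amino-acid extension for unclaimed codons
  for (cod in setdiff(sense_rna, claims$codon)) {
    box <- paste0(substr(cod, 1, 2), c("A", "C", "G", "U"))
    cand <- claims[claims$codon %in% box & claims$aa == aa_of[[cod]], , drop = FALSE]
    if (nrow(cand)) {
      claims <- rbind(claims, data.frame(codon = cod, trna = cand$trna[1L],
                                         aa = cand$aa[1L]))
    }
  }
  multi <- tapply(claims$aa, claims$codon, function(a) length(unique(a)) > 1L)
  conflicts <- names(multi)[multi]
  list(claims = claims,
       uncovered = setdiff(sense_rna, claims$codon),
       conflicts = conflicts)
}

#' Association between anticodon state and inferred codon meaning
#'
#' Builds the 2x2 table of anticodon state by predicted target-codon meaning
#' over taxa with an informative prediction (UNUSED and UNPREDICTED taxa are
#' excluded) and reports the two-sided Fisher exact probability. The formal
#' test is an addition of this package; the underlying observation is the
#' co-occurrence of anticodon point mutations with the reassignment.
#'
#' @param anticodons list of \code{anticodon_record}s or a data.frame with
#'   columns \code{taxon}, \code{anticodon}.
#' @param assignments data.frame from \code{\link{predict_all}}.
#' @param meanings the two amino-acid states compared (default Ser/Lys as
#'   one-letter codes).
#' @return list of class \code{association_result}: \code{table} (2x2 counts),
#'   \code{fisher_p}.
#' @export
anticodon_code_association <- function(anticodons, assignments,
                                       meanings = c("S", "K")) {
  if (!is.data.frame(anticodons)) {
    anticodons <- data.frame(
      taxon = vapply(anticodons, `[[`, character(1), "taxon"),
      anticodon = vapply(anticodons, `[[`, character(1), "anticodon"))
  }
  merged <- merge(anticodons, assignments, by = "taxon")
  merged <- merged[merged$predicted %in% meanings, , drop = FALSE]
  if (nrow(merged) < 2L) stop("fewer than 2 informative taxa for association")
  tab <- table(anticodon = merged$anticodon,
               predicted = factor(merged$predicted, levels = meanings))
  # a degenerate margin (all taxa share a state) carries no information
  p <- if (nrow(tab) < 2L || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    1 else stats::fisher.test(tab)$p.value
  structure(list(table = tab, fisher_p = p), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("two-sided Fisher exact p = %.4g\n", x$fisher_p))
  invisible(x)
}

#' Anticodon table for a set of genomes
#'
#' @param genomes list of \code{\link{mitogenome}}s.
#' @param trnas tRNA names to extract (default the two reassignment-relevant
#'   tRNAs, lysine and AGN-serine).
#' @param rules wobble rules used to report decoded codons.
#' @return data.frame: taxon, trna, anticodon, source, decoded codons.
#' @export
anticodon_table <- function(genomes,
                            trnas = c("tRNA-Lys", "tRNA-Ser(S1)"),
                            rules = wobble_rules()) {
  rows <- list()
  for (g in genomes) for (tr in trnas) {
    rec <- tryCatch(extract_anticodon(g, tr), error = function(e) NULL)
    if (is.null(rec)) next
    rows[[length(rows) + 1L]] <- data.frame(
      taxon = rec$taxon, trna = rec$trna, anticodon = rec$anticodon,
      source = rec$source,
      decodes = paste(decoded_codons(rec, rules), collapse = ","))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
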