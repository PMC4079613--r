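# Compositional statistics: AT/GC strand skews (Perna & Kocher convention),
# G+C% by codon position, GARP amino-acid fraction, and the GC-vs-GARP
# ordinary-least-squares fit. All skews are computed on the stored "+"
# (J-)strand; N bases count toward length but are excluded from denominators.

#' Base counts and strand skews of a DNA sequence
#'
#' AT-skew = (A - T)/(A + T), GC-skew = (G - C)/(G + C), both on the strand as
#' given. An undefined denominator (A+T = 0 or G+C = 0) yields \code{NA} with
#' a warning, never a silent 0.
#'
#' @param seq non-empty DNA string.
#' @return list of class \code{base_composition}: \code{counts} (A, C, G, T),
#'   \code{at_skew}, \code{gc_skew}.
#' @export
#' @examples
#' skews("AAAT")$at_skew  # 0.5
skews <- function(seq) {
  stopifnot(is_dna_string(seq), nchar(seq) > 0L)
  ch <- strsplit(toupper(seq), "")[[1]]
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(ch == b), integer(1))
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  at_skew <- if (at > 0) (counts[["A"]] - counts[["T"]]) / at else {
    warning("A+T = 0: AT-skew undefined"); NA_real_
  }
  gc_skew <- if (gc > 0) (counts[["G"]] - counts[["C"]]) / gc else {
    warning("G+C = 0: GC-skew undefined"); NA_real_
  }
  structure(list(counts = counts, at_skew = at_skew, gc_skew = gc_skew),
            class = "base_composition")
}

#' G+C percentage by codon position
#'
#' Computes G+C% at each of the three codon positions of a CDS and the pooled
#' (count-weighted) overall G+C%; a trailing incomplete codon is dropped and N
#' bases are excluded from denominators.
#'
#' @param cds DNA string, length >= 3.
#' @return list with \code{gc1}, \code{gc2}, \code{gc3}, \code{gc_all}
#'   (percentages in [0, 100]).
#' @export
gc_by_position <- function(cds) {
  if (nchar(cds) < 3L) stop("CDS shorter than one codon")
  codons <- split_codons(cds)
  mat <- do.call(rbind, strsplit(codons, ""))
  pos_gc <- integer(3); pos_n <- integer(3)
  for (p in 1:3) {
    b <- mat[, p]
    pos_gc[p] <- sum(b %in% c("G", "C"))
    pos_n[p] <- sum(b %in% c("A", "C", "G", "T"))
  }
  pct <- ifelse(pos_n > 0, 100 * pos_gc / pos_n, NA_real_)
  list(gc1 = pct[1], gc2 = pct[2], gc3 = pct[3],
       gc_all = 100 * sum(pos_gc) / sum(pos_n))
}

#' Fraction of GARP amino acids in a protein
#'
#' Gly, Ala, Arg and Pro are encoded by G+C-rich codons; their combined
#' frequency tracks genomic G+C content. Stops (\code{*}) and ambiguous
#' residues (\code{X}) are excluded from the denominator.
#'
#' @param protein amino-acid string (one-letter codes).
#' @return percentage in [0, 100].
#' @export
garp_fraction <- function(protein) {
  ch <- strsplit(toupper(protein), "")[[1]]
  ch <- ch[ch %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]]
  if (!length(ch)) stop("empty protein after removing stops/ambiguity")
  100 * sum(ch %in% c("G", "A", "R", "P")) / length(ch)
}

#' Ordinary least squares fit of GARP% on G+C%
#'
#' @param points data.frame with columns \code{taxon}, \code{x} (overall G+C%
#'   of the concatenated PCGs) and \code{y} (GARP% of the same concatenation's
#'   conceptual translation).
#' @return list with \code{slope}, \code{intercept}, \code{r2}.
#' @export
fit_gc_garp <- function(points) {
  stopifnot(nrow(points) >= 3L, all(c("x", "y") %in% names(points)))
  if (stats::var(points$x) == 0) stop("zero variance in x: fit undefined")
  fit <- stats::lm(y ~ x, data = points)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = summary(fit)$r.squared)
}

#' Per-genome composition table
#'
#' One row per genome: whole-genome base percentages and skews on the
#' J-strand, codon-position G+C of the concatenated PCGs, and GARP% of their
#' translation. Terminal stop codons are excluded from each CDS before
#' pooling. The analog of the package's TSV composition report.
#'
#' @param genomes list of \code{\link{mitogenome}} objects.
#' @param code genetic code used for the conceptual translation.
#' @return data.frame.
#' @export
composition_table <- function(genomes, code = mito_code()) {
  rows <- lapply(genomes, function(g) {
    sk <- skews(g$sequence)
    tot <- sum(sk$counts)
    pcgs <- tryCatch(concatenated_pcgs(g), error = function(e) NULL)
    gc <- list(gc1 = NA_real_, gc2 = NA_real_, gc3 = NA_real_, gc_all = NA_real_)
    garp <- NA_real_
    if (!is.null(pcgs)) {
      trimmed <- vapply(pcgs, drop_terminal_stop, character(1), code = code)
      cat_cds <- paste(trimmed, collapse = "")
      gc <- gc_by_position(cat_cds)
      garp <- garp_fraction(translate_cds(cat_cds, code, warn_internal_stops = FALSE))
    }
    data.frame(id = g$id, genus = g$genus, family = g$family,
               length = nchar(g$sequence),
               A_pct = 100 * sk$counts[["A"]] / tot,
               T_pct = 100 * sk$counts[["T"]] / tot,
               G_pct = 100 * sk$counts[["G"]] / tot,
               C_pct = 100 * sk$counts[["C"]] / tot,
               at_skew = sk$at_skew, gc_skew = sk$gc_skew,
               gc1 = gc$gc1, gc2 = gc$gc2, gc3 = gc$gc3, gc_all = gc$gc_all,
               garp_pct = garp)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# strip one terminal stop codon (complete or the common truncated T/TA stop)
drop_terminal_stop <- function(cds, code = mito_code()) {
  n <- nchar(cds)
  r <- n %% 3L
  if (r > 0L) return(substr(cds, 1L, n - r))
  last <- substr(cds, n - 2L, n)
  if (!is.na(code[last]) && code[last] == "*") substr(cds, 1L, n - 3L) else cds
}
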