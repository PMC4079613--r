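# Genetic-code tables and translation. The built-in baseline is the
# invertebrate mitochondrial code (AGA/AGG = Ser, AUA = Met, UGA = Trp); the
# AGG = Lys variant found in several heteropteran lineages is derived from it
# by a single declared override.

#' Build a genetic-code table
#'
#' A genetic code is a total map from the 64 DNA codons to one-letter amino
#' acids, with \code{"*"} for stops. Variants are declared as per-codon
#' overrides of a base table, so a variant differs from its base only at the
#' declared codons (asserted at construction).
#'
#' @param id \code{"invertebrate_mito"} or \code{"standard"}.
#' @param variants named character vector of overrides, e.g.
#'   \code{c(AGG = "K")}; names are DNA codons.
#' @return named character vector of length 64 with class
#'   \code{genetic_code} and attributes \code{id} and \code{variants}.
#' @export
#' @examples
#' mito_code()["AGG"]          # "S"
#' mito_code_agg_lys()["AGG"]  # "K"
genetic_code <- function(id = c("invertebrate_mito", "standard"),
                         variants = NULL) {
  id <- match.arg(id)
  tbl <- Biostrings::getGeneticCode(switch(id, invertebrate_mito = "5",
                                           standard = "1"))
  tbl <- stats::setNames(as.character(tbl), names(tbl))
  label <- id
  if (!is.null(variants)) {
    stopifnot(!is.null(names(variants)),
              all(names(variants) %in% names(tbl)),
              all(variants %in% c(Biostrings::AA_STANDARD, "*")))
    base <- tbl
    tbl[names(variants)] <- variants
    changed <- names(tbl)[tbl != base]
    stopifnot(setequal(changed, names(variants)[variants != base[names(variants)]]))
    label <- paste0(id, "+", paste0(names(variants), "=", variants, collapse = ","))
  }
  stopifnot(length(tbl) == 64L)
  structure(tbl, id = label, variants = variants, class = "genetic_code")
}

#' Invertebrate mitochondrial genetic code
#' @return a \code{\link{genetic_code}}.
#' @export
mito_code <- function() genetic_code("invertebrate_mito")

#' Invertebrate mitochondrial code with AGG reassigned to lysine
#' @return a \code{\link{genetic_code}}.
#' @export
mito_code_agg_lys <- function() {
  genetic_code("invertebrate_mito", variants = c(AGG = "K"))
}

#' Translate a CDS under a given genetic code
#'
#' One residue per complete codon; a trailing 1-2 bases are treated as an
#' incomplete stop and dropped. Codons containing non-ACGT characters
#' translate to \code{"X"}; internal stops translate to \code{"*"} and are
#' reported via a warning.
#'
#' @param cds DNA string, length >= 3.
#' @param code a \code{\link{genetic_code}} (default invertebrate mito).
#' @param warn_internal_stops warn when stops occur before the final codon.
#' @return amino-acid string.
#' @export
translate_cds <- function(cds, code = mito_code(), warn_internal_stops = TRUE) {
  if (nchar(cds) < 3L) stop("CDS shorter than one codon")
  codons <- split_codons(cds)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  if (warn_internal_stops && any(aa[-length(aa)] == "*")) {
    warning(sum(aa[-length(aa)] == "*"), " internal stop codon(s) translated as '*'")
  }
  paste(aa, collapse = "")
}

#' Tabulate codon usage across a set of protein-coding genes
#'
#' @param pcgs named list of CDS strings (e.g. from
#'   \code{\link{concatenated_pcgs}}); each CDS is trimmed to complete codons.
#' @param taxon optional taxon label stored as an attribute.
#' @return named integer vector of 64 codon counts (class
#'   \code{codon_usage}); counts sum to the number of complete codons.
#' @export
codon_usage <- function(pcgs, taxon = NULL) {
  if (is.character(pcgs)) pcgs <- as.list(pcgs)
  codons <- unlist(lapply(pcgs, split_codons), use.names = FALSE)
  all64 <- names(mito_code())
  counts <- table(factor(codons[codons %in% all64], levels = all64))
  structure(stats::setNames(as.integer(counts), all64),
            taxon = taxon, class = "codon_usage")
}
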