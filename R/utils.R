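#' Reverse complement of DNA strings
#'
#' Plain character-vector reverse complement over the {A,C,G,T,U,N} alphabet
#' (case preserved for upper case input; everything is uppercased first).
#'
#' @param x character vector of DNA (or RNA) sequences.
#' @return character vector of the same length with each sequence
#'   reverse-complemented (U treated as T).
#' @export
#' @examples
#' revcomp("ATGC")  # "GCAT"
revcomp <- function(x) {
  x <- toupper(gsub("U", "T", x))
  vapply(x, function(s) {
    chars <- strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]
    paste(rev(chars), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

dna_to_rna <- function(x) chartr("Tt", "Uu", x)
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

# Split a CDS into complete codons; trailing 1-2 bases dropped.
split_codons <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds) %/% 3L
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, by = 3L, length.out = n), seq(3L, by = 3L, length.out = n))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_dna_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl("^[ACGTNacgtn]*$", x)
}
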