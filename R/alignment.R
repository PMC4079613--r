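# Codon-aware multiple alignment. Each gene is aligned at the amino-acid
# level by progressive profile alignment (guide order from k-mer distances,
# pairwise global alignment with BLOSUM62 and affine gaps), then
# back-translated to codons. Pre-computed codon-aware MSAs (aligned FASTA)
# are accepted as a drop-in replacement for the internal aligner.

#' Construct a codon alignment object
#'
#' @param blocks named list (per gene) of character matrices, rows = taxa,
#'   cells = codons or \code{"---"}; all matrices share the same rownames.
#' @return object of class \code{codon_alignment} with fields \code{taxa},
#'   \code{genes}, \code{blocks}.
#' @export
codon_alignment <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  taxa <- rownames(blocks[[1L]])
  for (b in blocks) {
    stopifnot(is.matrix(b), identical(rownames(b), taxa),
              all(nchar(b) == 3L | b == "---"))
  }
  structure(list(taxa = taxa, genes = names(blocks), blocks = blocks),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d taxa, %d gene blocks, %d codon columns\n",
              length(x$taxa), length(x$blocks),
              sum(vapply(x$blocks, ncol, integer(1)))))
  invisible(x)
}

# single codon matrix over all gene blocks, columns in gene order
concat_blocks <- function(aln) do.call(cbind, unname(aln$blocks))

# translate a codon matrix cell-wise; gaps stay "-"
aa_matrix <- function(m, code = mito_code()) {
  aa <- unname(code[m])
  aa[is.na(aa)] <- "X"
  aa[m == "---"] <- "-"
  matrix(aa, nrow = nrow(m), dimnames = dimnames(m))
}

# ---- internal progressive amino-acid aligner --------------------------------

aa_kmer_dist <- function(seqs, k = 3L) {
  kmers <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    u <- length(union(kmers[[i]], kmers[[j]]))
    d[i, j] <- d[j, i] <- if (u == 0) 0 else
      1 - length(intersect(kmers[[i]], kmers[[j]])) / u
  }
  d
}

profile_consensus <- function(prof) {
  letters_used <- setdiff(sort(unique(as.vector(prof))), "-")
  if (!length(letters_used)) return(rep("X", ncol(prof)))
  counts <- vapply(letters_used, function(l) colSums(prof == l),
                   numeric(ncol(prof)))
  counts <- matrix(counts, ncol = length(letters_used),
                   dimnames = list(NULL, letters_used))
  cons <- letters_used[max.col(counts, ties.method = "first")]
  cons[rowSums(counts) == 0] <- "X"
  cons
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# insert all-gap columns into a profile at the gap positions of an aligned
# consensus string
project_gaps <- function(prof, aligned_consensus) {
  ch <- strsplit(aligned_consensus, "")[[1]]
  out <- matrix("-", nrow = nrow(prof), ncol = length(ch),
                dimnames = list(rownames(prof), NULL))
  out[, ch != "-"] <- prof
  out
}

align_two_profiles <- function(a, b) {
  ca <- paste(profile_consensus(a), collapse = "")
  cb <- paste(profile_consensus(b), collapse = "")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ca), Biostrings::AAString(cb),
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5,
    type = "global")
  a2 <- project_gaps(a, as.character(Biostrings::alignedPattern(pa)))
  b2 <- project_gaps(b, as.character(Biostrings::alignedSubject(pa)))
  rbind(a2, b2)
}

align_aa_set <- function(aa) {
  stopifnot(length(aa) >= 1L)
  mats <- lapply(names(aa), function(nm) {
    matrix(strsplit(aa[[nm]], "")[[1]], nrow = 1, dimnames = list(nm, NULL))
  })
  if (length(mats) == 1L) return(mats[[1L]])
  d <- aa_kmer_dist(unname(aa))
  # guide order: start from the closest pair, then add nearest remaining taxon
  pair <- which(d == min(d[upper.tri(d)]), arr.ind = TRUE)
  pair <- pair[pair[, 1] < pair[, 2], , drop = FALSE][1, ]
  order_idx <- as.integer(pair)
  while (length(order_idx) < length(mats)) {
    rest <- setdiff(seq_along(mats), order_idx)
    nearest <- rest[which.min(vapply(rest, function(r) min(d[r, order_idx]),
                                     numeric(1)))]
    order_idx <- c(order_idx, nearest)
  }
  prof <- mats[[order_idx[1L]]]
  for (i in order_idx[-1L]) prof <- align_two_profiles(prof, mats[[i]])
  prof[match(names(aa), rownames(prof)), , drop = FALSE]
}

back_translate <- function(aa_row, cds) {
  codons <- split_codons(cds)
  out <- rep("---", length(aa_row))
  out[aa_row != "-"] <- codons[seq_len(sum(aa_row != "-"))]
  out
}

#' Build a codon-aware multiple alignment from per-taxon CDS sets
#'
#' For each gene the CDSs are translated under \code{code}, aligned at the
#' amino-acid level by progressive profile alignment, and back-translated to
#' codons. A taxon missing a gene receives an all-gap row for that gene.
#'
#' @param cds_by_taxon named list (taxon) of named lists (gene) of CDS strings.
#' @param code genetic code used for the translation step.
#' @return a \code{\link{codon_alignment}}.
#' @export
build_codon_alignment <- function(cds_by_taxon, code = mito_code()) {
  stopifnot(length(cds_by_taxon) >= 3L)
  taxa <- names(cds_by_taxon)
  genes <- unique(unlist(lapply(cds_by_taxon, names)))
  blocks <- list()
  for (g in genes) {
    have <- taxa[vapply(cds_by_taxon, function(x) !is.null(x[[g]]), logical(1))]
    cds <- lapply(cds_by_taxon[have], function(x) {
      s <- x[[g]]
      substr(s, 1L, (nchar(s) %/% 3L) * 3L)
    })
    aa <- stats::setNames(vapply(cds, translate_cds, character(1),
                                 code = code, warn_internal_stops = FALSE), have)
    prof <- align_aa_set(aa)
    block <- matrix("---", nrow = length(taxa), ncol = ncol(prof),
                    dimnames = list(taxa, NULL))
    for (t in have) block[t, ] <- back_translate(prof[t, ], cds[[t]])
    blocks[[g]] <- block
  }
  codon_alignment(blocks)
}

# ---- aligned FASTA I/O ------------------------------------------------------

#' Read a pre-computed codon-aware alignment from aligned FASTA
#'
#' All records must have equal width, a multiple of 3; gaps are \code{-}.
#' The alignment is loaded as a single gene block and bypasses the internal
#' aligner, with identical downstream behavior.
#'
#' @param path aligned FASTA file.
#' @param gene block label (default \code{"MSA"}).
#' @return a \code{\link{codon_alignment}}.
#' @export
read_aligned_fasta <- function(path, gene = "MSA") {
  ss <- Biostrings::readBStringSet(path)
  w <- unique(Biostrings::width(ss))
  if (length(w) != 1L) stop("aligned FASTA rows have unequal widths")
  if (w %% 3L != 0L) stop("aligned FASTA width is not a multiple of 3")
  rows <- toupper(as.character(ss))
  n <- w / 3L
  block <- t(vapply(rows, function(s) {
    cod <- substring(s, seq(1L, w, 3L), seq(3L, w, 3L))
    cod[grepl("-", cod)] <- "---"
    cod
  }, character(n)))
  rownames(block) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  codon_alignment(stats::setNames(list(block), gene))
}

#' Write a codon alignment as aligned FASTA (concatenated gene blocks)
#' @param aln a \code{\link{codon_alignment}}.
#' @param path output path.
#' @export
write_aligned_fasta <- function(aln, path) {
  m <- concat_blocks(aln)
  rows <- apply(m, 1, paste, collapse = "")
  writeLines(paste0(">", rownames(m), "\n", rows), path)
  invisible(path)
}
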