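# Non-coding region census, control-region location, transcription-
# termination-factor (DmTTF-like) site search, and alignment identities.

#' Census of non-coding regions
#'
#' Reports every inter-feature gap of at least 1 bp on the (circular) genome,
#' with its flanking genes. Overlapping features (negative gaps) are never
#' reported as non-coding regions; they are returned in the \code{"overlaps"}
#' attribute.
#'
#' @param genome a \code{\link{mitogenome}} with at least 2 features.
#' @return data.frame: \code{id}, \code{left}, \code{right}, \code{start},
#'   \code{end}, \code{length}, \code{seq}; coordinates 0-based half-open,
#'   \code{end} may exceed the genome length for the origin-wrapping gap.
#' @export
noncoding_census <- function(genome) {
  f <- genome$features
  stopifnot(nrow(f) >= 2L)
  len <- genome_length(genome)
  f <- f[order(f$start), , drop = FALSE]
  n <- nrow(f)
  rows <- list(); overlaps <- list()
  # effective end of the last feature may wrap the origin
  for (i in seq_len(n)) {
    j <- if (i < n) i + 1L else 1L
    gap_start <- f$end[i]
    gap_end <- if (i < n) f$start[j] else f$start[j] + (if (genome$circular) len else 0L)
    width <- gap_end - gap_start
    if (i == n && !genome$circular) next
    if (width >= 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = genome$id, left = f$name[i], right = f$name[j],
        start = gap_start %% len, end = gap_start %% len + width,
        length = width,
        seq = slice_circular(genome$sequence, gap_start %% len,
                             gap_start %% len + width))
    } else if (width < 0L) {
      overlaps[[length(overlaps) + 1L]] <- data.frame(
        left = f$name[i], right = f$name[j], overlap = -width)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), left = character(0), right = character(0),
               start = integer(0), end = integer(0), length = integer(0),
               seq = character(0))
  rownames(out) <- NULL
  attr(out, "overlaps") <- if (length(overlaps)) do.call(rbind, overlaps) else NULL
  out
}

#' Locate the control region
#'
#' Returns the explicitly annotated control region when present; otherwise
#' the non-coding gap between \code{srRNA} and \code{tRNA-Ile} in circular
#' order, which in the ancestral insect arrangement is the major non-coding
#' region containing the replication origin.
#'
#' @param genome a \code{\link{mitogenome}}.
#' @return one-row data.frame as in \code{\link{noncoding_census}}.
#' @export
locate_control_region <- function(genome) {
  f <- genome$features
  cr <- which(f$kind == "control_region")
  if (length(cr)) {
    i <- cr[1L]
    return(data.frame(id = genome$id, left = NA_character_,
                      right = NA_character_, start = f$start[i], end = f$end[i],
                      length = f$end[i] - f$start[i],
                      seq = slice_circular(genome$sequence, f$start[i], f$end[i])))
  }
  if (!all(c("srRNA", "tRNA-Ile") %in% f$name)) {
    stop("control region not annotated and srRNA/tRNA-Ile flanks missing in ",
         genome$id)
  }
  census <- noncoding_census(genome)
  hit <- which((census$left == "srRNA" & census$right == "tRNA-Ile") |
               (census$left == "tRNA-Ile" & census$right == "srRNA"))
  if (!length(hit)) stop("no gap between srRNA and tRNA-Ile in ", genome$id)
  census[hit[1L], , drop = FALSE]
}

#' Search a non-coding region for a termination-factor binding site
#'
#' Best local alignment of a reference site (e.g. the Drosophila
#' melanogaster mitochondrial transcription termination factor binding
#' sequence) against a non-coding region; identity is computed over the
#' aligned window.
#'
#' @param region DNA string of the region (or a one-row census data.frame).
#' @param reference DNA string of the reference site, length >= 5.
#' @return list of class \code{dmttf_hit}: \code{offset} (0-based window
#'   start in the region), \code{identity} (percent), \code{window_length};
#'   a region shorter than 5 bp yields a no-hit result (NA identity).
#' @export
dmttf_search <- function(region, reference) {
  if (is.data.frame(region)) region <- region$seq[1L]
  stopifnot(nchar(reference) >= 5L)
  if (nchar(region) < 5L) {
    return(structure(list(offset = NA_integer_, identity = NA_real_,
                          window_length = 0L), class = "dmttf_hit"))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(region)),
    Biostrings::DNAString(toupper(reference)),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
    gapOpening = 2, gapExtension = 1)
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  cols <- nchar(p)
  matches <- sum(strsplit(p, "")[[1]] == strsplit(s, "")[[1]] &
                 strsplit(p, "")[[1]] != "-")
  structure(list(offset = Biostrings::start(Biostrings::pattern(aln)) - 1L,
                 identity = 100 * matches / cols,
                 window_length = cols),
            class = "dmttf_hit")
}

#' Global-alignment identity between two sequences
#'
#' Needleman-Wunsch alignment (defaults: match +1, mismatch -1, gap open -2,
#' gap extend -1); identity = 100 x matches / aligned columns, with gap
#' columns included in the denominator by default (set
#' \code{gap_columns = "exclude"} for the gap-free convention). Inputs are
#' ordered canonically before aligning so the result is symmetric.
#'
#' @param a,b non-empty DNA strings.
#' @param gap_columns \code{"include"} (default) or \code{"exclude"}.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return list of class \code{identity_result}: \code{identity} (percent),
#'   \code{aligned_columns}, \code{matches}, \code{params}.
#' @export
pairwise_identity <- function(a, b, gap_columns = c("include", "exclude"),
                              match = 1, mismatch = -1,
                              gap_open = 2, gap_extend = 1) {
  gap_columns <- match.arg(gap_columns)
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  # canonical orientation and order: co-optimal alignments can differ in
  # realized match counts, so the aligned pair is chosen deterministically
  fwd <- sort(c(toupper(a), toupper(b)))
  rcp <- sort(revcomp(c(a, b)))
  pair <- if (paste(rcp, collapse = "\1") < paste(fwd, collapse = "\1"))
    rcp else fwd
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pair[1]), Biostrings::DNAString(pair[2]),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  matches <- sum(p == s & p != "-")
  cols <- if (gap_columns == "include") length(p) else sum(p != "-" & s != "-")
  structure(list(identity = 100 * matches / cols, aligned_columns = cols,
                 matches = matches,
                 params = list(match = match, mismatch = mismatch,
                               gap_open = gap_open, gap_extend = gap_extend,
                               gap_columns = gap_columns)),
            class = "identity_result")
}

#' Average pairwise identity over a set of sequences
#'
#' Summary used for multi-taxon comparisons (e.g. inter-genus control-region
#' identity after repeat masking): the mean of all pairwise global-alignment
#' identities.
#'
#' @param seqs named character vector of DNA strings (>= 2).
#' @param ... passed to \code{\link{pairwise_identity}}.
#' @return list with \code{mean_identity} and the pairwise \code{matrix}.
#' @export
mean_pairwise_identity <- function(seqs, ...) {
  n <- length(seqs)
  stopifnot(n >= 2L)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  vals <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    id <- pairwise_identity(seqs[[i]], seqs[[j]], ...)$identity
    m[i, j] <- m[j, i] <- id
    vals <- c(vals, id)
  }
  list(mean_identity = mean(vals), matrix = m)
}
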