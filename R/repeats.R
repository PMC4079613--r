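# Tandem-repeat annotation of control regions: a seed-and-extend detector
# over candidate periods. An array at period p is a union of exact
# self-match runs at lag p, grown from seed runs by absorbing an adjacent
# mismatch gap together with the exact run beyond it whenever the pair
# locally satisfies the tolerance: gap/(gap + run) <= max_mismatch and
# gap <= max_mismatch * p. The local criterion lets the detector bridge
# occasional mismatches inside degraded copies without spending the mismatch
# budget of a long exact core on unrelated flanking sequence, and every
# array ends on an exact run, so planted exact arrays are recovered with
# their exact boundaries.

#' Find maximal tandem-repeat arrays
#'
#' Detects non-overlapping tandem arrays by self-comparison at every
#' candidate period: runs of exact matches at lag \code{p} seed candidate
#' arrays, which are extended left and right one base at a time while the
#' per-array mismatch rate stays at or below \code{max_mismatch}. Overlaps
#' between candidates are resolved greedily by descending span, then
#' ascending unit length, then position.
#'
#' @param seq DNA string.
#' @param min_unit,max_unit repeat-unit length bounds in bp (defaults 10 and
#'   300, bracketing the unit sizes seen in insect control regions).
#' @param min_copies minimum number of full copies (default 2).
#' @param max_mismatch maximum per-array mismatch rate (default 0.1).
#' @return data.frame with columns \code{start} (0-based), \code{unit_length},
#'   \code{unit_seq}, \code{full_copies}, \code{partial_length}, \code{span},
#'   \code{mismatch_rate}; zero rows when nothing is found.
#' @export
#' @examples
#' find_tandem_repeats("ACGACGACGAC", min_unit = 2, max_unit = 5)
find_tandem_repeats <- function(seq, min_unit = 10L, max_unit = 300L,
                                min_copies = 2L, max_mismatch = 0.1) {
  stopifnot(min_unit >= 2L, min_copies >= 2L,
            max_mismatch >= 0, max_mismatch < 1)
  seq <- toupper(seq)
  n <- nchar(seq)
  x <- strsplit(seq, "")[[1]]
  cands <- list()
  for (p in seq.int(min_unit, min(max_unit, n %/% 2L))) {
    m <- x[seq_len(n - p)] == x[(p + 1L):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seedlen <- if (max_mismatch == 0) 1L else min(p, 8L)
    seeds <- which(r$values & r$lengths >= seedlen)
    seen <- character(0)
    absorb_ok <- function(gap, run) {
      gap / (gap + run) <= max_mismatch && gap <= max_mismatch * p
    }
    for (sd in seeds) {
      lo <- sd; hi <- sd  # run indices covered by the array
      while (hi + 2L <= length(r$lengths) &&
             absorb_ok(r$lengths[hi + 1L], r$lengths[hi + 2L])) hi <- hi + 2L
      while (lo - 2L >= 1L &&
             absorb_ok(r$lengths[lo - 1L], r$lengths[lo - 2L])) lo <- lo - 2L
      a <- starts[lo]; b <- ends[hi]
      mis <- sum(!m[a:b])
      span <- (b - a + 1L) + p
      full <- span %/% p
      if (full < min_copies) next
      key <- paste(a, b, p)
      if (key %in% seen) next
      seen <- c(seen, key)
      cands[[length(cands) + 1L]] <- data.frame(
        start = a - 1L, unit_length = p,
        unit_seq = substr(seq, a, a + p - 1L),
        full_copies = full, partial_length = span %% p, span = span,
        mismatch_rate = mis / (span - p))
    }
  }
  empty <- data.frame(start = integer(0), unit_length = integer(0),
                      unit_seq = character(0), full_copies = integer(0),
                      partial_length = integer(0), span = integer(0),
                      mismatch_rate = numeric(0))
  if (!length(cands)) return(empty)
  cands <- do.call(rbind, cands)
  cands <- cands[order(-cands$span, cands$unit_length, cands$start), , drop = FALSE]
  kept <- empty
  for (i in seq_len(nrow(cands))) {
    ci <- cands[i, ]
    if (!nrow(kept) ||
        all(ci$start >= kept$start + kept$span | ci$start + ci$span <= kept$start)) {
      kept <- rbind(kept, ci)
    }
  }
  kept <- kept[order(kept$start), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Control-region repeat architecture of a genome
#'
#' Locates the control region and annotates its tandem-repeat arrays.
#'
#' @param genome a \code{\link{mitogenome}}.
#' @param ... passed to \code{\link{find_tandem_repeats}}.
#' @return list of class \code{cr_architecture}: \code{id}, \code{cr}
#'   (one-row census data.frame), \code{repeats} (repeat table, coordinates
#'   relative to the CR), \code{remainder} (repeat-masked sequence).
#' @export
cr_architecture <- function(genome, ...) {
  cr <- locate_control_region(genome)
  reps <- find_tandem_repeats(cr$seq[1L], ...)
  arch <- structure(list(id = genome$id, cr = cr, repeats = reps,
                         remainder = NULL),
                    class = "cr_architecture")
  arch$remainder <- mask_repeats(arch)
  arch
}

#' Remove tandem-repeat arrays from a control region
#'
#' Concatenates the non-repeat remainder in coordinate order; repeat arrays
#' contribute zero copies (they are removed outright). Set
#' \code{retain_one = TRUE} to keep a single unit copy per array instead.
#'
#' @param arch a \code{cr_architecture}, or a DNA string together with a
#'   repeat table in \code{repeats}.
#' @param repeats repeat data.frame when \code{arch} is a plain sequence.
#' @param retain_one keep one unit copy per array (default FALSE).
#' @return DNA string of the masked sequence (possibly empty, with a warning).
#' @export
mask_repeats <- function(arch, repeats = NULL, retain_one = FALSE) {
  if (inherits(arch, "cr_architecture")) {
    seq <- arch$cr$seq[1L]; reps <- arch$repeats
  } else {
    seq <- arch; reps <- repeats
  }
  if (is.null(reps) || !nrow(reps)) return(seq)
  reps <- reps[order(reps$start), , drop = FALSE]
  keep <- character(0)
  cursor <- 0L
  for (i in seq_len(nrow(reps))) {
    if (reps$start[i] > cursor) {
      keep <- c(keep, substr(seq, cursor + 1L, reps$start[i]))
    }
    if (retain_one) keep <- c(keep, reps$unit_seq[i])
    cursor <- reps$start[i] + reps$span[i]
  }
  if (cursor < nchar(seq)) keep <- c(keep, substr(seq, cursor + 1L, nchar(seq)))
  out <- paste(keep, collapse = "")
  if (!nchar(out)) warning("repeat arrays span the whole region: empty remainder")
  out
}
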