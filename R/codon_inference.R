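# Alignment-based inference of a codon's amino-acid meaning per taxon.
# For each occurrence of the target codon in a focal taxon, the amino acids
# of the other taxa at the same conserved alignment column are tallied
# (each translated under the baseline code, with cells that themselves carry
# the target codon excluded to avoid circularity); the majority amino acid,
# if frequent enough and supported by enough informative taxa, is the call
# for that occurrence, and the taxon-level prediction is the majority over
# occurrence calls. Taxa that never use the codon are UNUSED; ties and
# all-ambiguous cases are UNPREDICTED.

#' Filter alignment columns by occupancy and conservation
#'
#' Retains codon columns whose non-gap fraction is at least
#' \code{min_occupancy} and whose top amino-acid fraction among non-gap,
#' non-target cells is at least \code{min_conservation}. Cells equal to the
#' target codon are excluded from the conservation calculation so that
#' candidate columns (where the target's meaning is in question) are not
#' filtered out by their own target content; a column whose informative cells
#' are all target codons has undefined conservation and is retained on
#' occupancy alone.
#'
#' @param aln a \code{\link{codon_alignment}}.
#' @param min_occupancy,min_conservation fractions in [0, 1]
#'   (defaults 0.8 and 0.5).
#' @param target codon whose meaning is under study (default \code{"AGG"}).
#' @param code baseline genetic code for the conservation translation.
#' @return a filtered \code{\link{codon_alignment}}; the retained column
#'   indices per gene are stored in attribute \code{"kept"}.
#' @export
filter_columns <- function(aln, min_occupancy = 0.8, min_conservation = 0.5,
                           target = "AGG", code = mito_code()) {
  stopifnot(min_occupancy >= 0, min_occupancy <= 1,
            min_conservation >= 0, min_conservation <= 1)
  kept <- list()
  blocks <- list()
  for (g in aln$genes) {
    m <- aln$blocks[[g]]
    am <- aa_matrix(m, code)
    keep <- vapply(seq_len(ncol(m)), function(j) {
      nongap <- m[, j] != "---"
      occ <- mean(nongap)
      if (occ < min_occupancy) return(FALSE)
      inf <- nongap & m[, j] != target
      if (!any(inf)) return(TRUE)  # all-target column: candidate, keep
      cons <- max(table(am[inf, j])) / sum(inf)
      cons >= min_conservation
    }, logical(1))
    kept[[g]] <- which(keep)
    blocks[[g]] <- m[, keep, drop = FALSE]
  }
  if (sum(vapply(blocks, ncol, integer(1))) == 0L) {
    warning("all alignment columns removed by the filter")
  }
  out <- codon_alignment(blocks)
  attr(out, "kept") <- kept
  out
}

#' Predict the amino-acid meaning of a codon for one taxon
#'
#' Implements the conserved-column majority rule: at every (filtered) column
#' where the focal taxon carries \code{target}, the other taxa's amino acids
#' are tallied under the baseline \code{code}, excluding cells that are
#' themselves the target codon. An occurrence is called as the majority amino
#' acid when its fraction is at least \code{majority_threshold} and at least
#' \code{min_informative} taxa are informative, otherwise \code{"?"}. The
#' taxon-level prediction is the majority over occurrence calls;
#' \code{UNPREDICTED} when all occurrences are ambiguous or the majority
#' ties; \code{UNUSED} when the taxon has no occurrence of the target.
#'
#' @param aln a \code{\link{codon_alignment}}, normally already passed through
#'   \code{\link{filter_columns}}.
#' @param focal taxon label.
#' @param target codon (default \code{"AGG"}).
#' @param majority_threshold minimum majority fraction per occurrence
#'   (default 0.5).
#' @param min_informative minimum informative taxa per occurrence (default 3).
#' @param code baseline genetic code for the non-focal taxa.
#' @return list of class \code{codon_assignment}: \code{taxon}, \code{codon},
#'   \code{n_occurrences}, \code{tally} (aggregated amino-acid counts),
#'   \code{occurrence_calls}, \code{predicted} (one-letter amino acid,
#'   \code{"UNPREDICTED"} or \code{"UNUSED"}) and \code{support} (top
#'   amino-acid fraction of the aggregated tally).
#' @export
predict_codon_meaning <- function(aln, focal, target = "AGG",
                                  majority_threshold = 0.5,
                                  min_informative = 3, code = mito_code()) {
  if (!target %in% names(code)) stop("'", target, "' is not a valid codon")
  if (!focal %in% aln$taxa) stop("focal taxon '", focal, "' not in alignment")
  m <- concat_blocks(aln)
  am <- aa_matrix(m, code)
  hits <- which(m[focal, ] == target)
  if (!length(hits)) {
    return(structure(list(taxon = focal, codon = target, n_occurrences = 0L,
                          tally = integer(0), occurrence_calls = character(0),
                          predicted = "UNUSED", support = NA_real_),
                     class = "codon_assignment"))
  }
  others <- setdiff(aln$taxa, focal)
  calls <- character(length(hits))
  agg <- integer(0)
  for (k in seq_along(hits)) {
    j <- hits[k]
    inf <- others[m[others, j] != "---" & m[others, j] != target]
    tly <- table(am[inf, j])
    tly <- tly[!names(tly) %in% c("X", "-")]
    for (a in names(tly)) agg[a] <- (if (a %in% names(agg)) agg[a] else 0L) + tly[[a]]
    if (sum(tly) < min_informative || !length(tly)) { calls[k] <- "?"; next }
    top <- max(tly)
    winners <- names(tly)[tly == top]
    frac <- top / sum(tly)
    calls[k] <- if (length(winners) == 1L && frac >= majority_threshold)
      winners else "?"
  }
  informative_calls <- calls[calls != "?"]
  predicted <- if (!length(informative_calls)) "UNPREDICTED" else {
    tc <- table(informative_calls)
    winners <- names(tc)[tc == max(tc)]
    if (length(winners) == 1L) winners else "UNPREDICTED"
  }
  support <- if (sum(agg) > 0) max(agg) / sum(agg) else NA_real_
  structure(list(taxon = focal, codon = target,
                 n_occurrences = length(hits), tally = agg,
                 occurrence_calls = calls, predicted = predicted,
                 support = support),
            class = "codon_assignment")
}

#' @export
print.codon_assignment <- function(x, ...) {
  cat(sprintf("<codon_assignment> %s: %s -> %s (n = %d, support = %s)\n",
              x$taxon, x$codon, x$predicted, x$n_occurrences,
              ifelse(is.na(x$support), "NA", sprintf("%.2f", x$support))))
  invisible(x)
}

#' Predict a codon's meaning for every taxon in an alignment
#'
#' @inheritParams predict_codon_meaning
#' @return data.frame with one row per taxon: \code{taxon}, \code{codon},
#'   \code{n_occurrences}, \code{predicted}, \code{support}; the full
#'   \code{codon_assignment} objects are attached as attribute
#'   \code{"assignments"}. Deterministic given its inputs and invariant to
#'   taxon order.
#' @export
predict_all <- function(aln, target = "AGG", majority_threshold = 0.5,
                        min_informative = 3, code = mito_code()) {
  asg <- lapply(aln$taxa, function(t) {
    predict_codon_meaning(aln, t, target, majority_threshold,
                          min_informative, code)
  })
  out <- data.frame(
    taxon = vapply(asg, `[[`, character(1), "taxon"),
    codon = target,
    n_occurrences = vapply(asg, `[[`, integer(1), "n_occurrences"),
    predicted = vapply(asg, `[[`, character(1), "predicted"),
    support = vapply(asg, `[[`, numeric(1), "support"))
  attr(out, "assignments") <- asg
  out
}
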