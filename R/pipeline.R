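# Pipeline orchestration: run all analysis stages over a genome set and
# collect the report tables. A genome failing one stage is excluded from that
# stage only, with the reason recorded in the provenance block.

#' Pipeline run configuration
#'
#' @param inputs list of \code{\link{mitogenome}} objects, or a character
#'   vector of GenBank file paths.
#' @param target codon under study (default \code{"AGG"}).
#' @param min_occupancy,min_conservation column-filter thresholds.
#' @param majority_threshold,min_informative predictor thresholds.
#' @param repeat_params list passed to \code{\link{find_tandem_repeats}}.
#' @param identity_gap_columns \code{"include"} or \code{"exclude"} (identity
#'   denominator convention).
#' @param external_msa optional aligned FASTA path; when given, the internal
#'   aligner is bypassed.
#' @param dmttf_reference optional DNA string of a termination-factor binding
#'   site to search in non-coding regions.
#' @param newick optional tree file for tip annotation.
#' @param seed integer; recorded in provenance (all stages are deterministic).
#' @return list of class \code{run_config}.
#' @export
run_config <- function(inputs, target = "AGG",
                       min_occupancy = 0.8, min_conservation = 0.5,
                       majority_threshold = 0.5, min_informative = 3,
                       repeat_params = list(),
                       identity_gap_columns = "include",
                       external_msa = NULL, dmttf_reference = NULL,
                       newick = NULL, seed = 1L) {
  structure(list(inputs = inputs, target = target,
                 min_occupancy = min_occupancy,
                 min_conservation = min_conservation,
                 majority_threshold = majority_threshold,
                 min_informative = min_informative,
                 repeat_params = repeat_params,
                 identity_gap_columns = identity_gap_columns,
                 external_msa = external_msa,
                 dmttf_reference = dmttf_reference,
                 newick = newick, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full comparative-mitogenomics pipeline
#'
#' Stages, in order: genome loading and normalization; composition
#' statistics; codon usage; codon-aware alignment (internal progressive
#' aligner, or an external MSA when configured), column filtering, and
#' per-taxon prediction of the target codon's meaning; anticodon extraction,
#' decoding and anticodon-vs-meaning association; non-coding census,
#' control-region repeat architecture and repeat-masked identities.
#'
#' @param config a \code{\link{run_config}}.
#' @return list of class \code{run_report} with fields \code{composition},
#'   \code{codon_usage}, \code{assignments}, \code{anticodons},
#'   \code{association}, \code{ncr_census}, \code{cr_architecture},
#'   \code{identity} and \code{provenance}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))

  genomes <- config$inputs
  if (is.character(genomes)) {
    genomes <- lapply(genomes, function(p) {
      tryCatch(parse_genbank(p), error = function(e) {
        note("parse failure for ", p, ": ", conditionMessage(e)); NULL
      })
    })
    genomes <- Filter(Negate(is.null), genomes)
  }
  if (!length(genomes)) stop("zero parseable genomes")
  names(genomes) <- vapply(genomes, `[[`, character(1), "id")

  composition <- withCallingHandlers(
    composition_table(genomes),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })

  pcgs <- lapply(genomes, function(g) {
    tryCatch(suppressWarnings(concatenated_pcgs(g)), error = function(e) {
      note(g$id, " excluded from coding stages: ", conditionMessage(e)); NULL
    })
  })
  pcgs <- Filter(Negate(is.null), pcgs)

  usage <- do.call(rbind, lapply(names(pcgs), function(t) {
    u <- codon_usage(pcgs[[t]], taxon = t)
    cbind(data.frame(taxon = t), as.data.frame(t(unclass(u))))
  }))

  assignments <- NULL; association <- NULL; anticodons <- NULL
  if (length(pcgs) >= 3L) {
    aln <- if (!is.null(config$external_msa)) {
      read_aligned_fasta(config$external_msa)
    } else {
      build_codon_alignment(pcgs)
    }
    filtered <- suppressWarnings(filter_columns(
      aln, config$min_occupancy, config$min_conservation, config$target))
    assignments <- predict_all(filtered, config$target,
                               config$majority_threshold,
                               config$min_informative)
    anticodons <- anticodon_table(genomes)
    if (!is.null(anticodons)) {
      for (tr in unique(anticodons$trna)) {
        sub <- anticodons[anticodons$trna == tr, c("taxon", "anticodon")]
        res <- tryCatch(anticodon_code_association(sub, assignments),
                        error = function(e) { note("association (", tr, "): ",
                                                   conditionMessage(e)); NULL })
        association[[tr]] <- res
      }
    }
  } else {
    note("fewer than 3 genomes with PCGs: code-inference stage skipped")
  }

  census <- do.call(rbind, lapply(genomes, function(g) {
    tryCatch(noncoding_census(g), error = function(e) {
      note(g$id, " excluded from non-coding census: ", conditionMessage(e)); NULL
    })
  }))
  if (!is.null(census)) rownames(census) <- NULL

  archs <- lapply(genomes, function(g) {
    tryCatch(suppressWarnings(
      do.call(cr_architecture, c(list(g), config$repeat_params))),
      error = function(e) {
        note(g$id, " excluded from CR stage: ", conditionMessage(e)); NULL
      })
  })
  archs <- Filter(Negate(is.null), archs)

  identity <- NULL
  if (length(archs) >= 2L) {
    masked <- vapply(archs, `[[`, character(1), "remainder")
    masked <- masked[nchar(masked) > 0]
    if (length(masked) >= 2L) {
      identity <- mean_pairwise_identity(masked,
                                         gap_columns = config$identity_gap_columns)
    }
  }

  dmttf <- NULL
  if (!is.null(config$dmttf_reference) && !is.null(census) && nrow(census)) {
    dmttf <- do.call(rbind, lapply(seq_len(nrow(census)), function(i) {
      hit <- dmttf_search(census$seq[i], config$dmttf_reference)
      data.frame(id = census$id[i], left = census$left[i],
                 right = census$right[i], offset = hit$offset,
                 identity = hit$identity, window_length = hit$window_length)
    }))
  }

  structure(list(
    composition = composition, codon_usage = usage,
    assignments = assignments, anticodons = anticodons,
    association = association, ncr_census = census,
    cr_architecture = archs, identity = identity, dmttf = dmttf,
    provenance = list(
      package_version = as.character(utils::packageVersion("mitocode")),
      parameters = config[setdiff(names(config), "inputs")],
      n_genomes = length(genomes), seed = config$seed,
      warnings = warnings_log)),
    class = "run_report")
}

#' Write a run report as TSV tables
#'
#' Emits \code{composition.tsv}, \code{codon_usage.tsv},
#' \code{agg_assignments.tsv}, \code{anticodons.tsv}, \code{ncr_census.tsv},
#' \code{cr_architecture.tsv}, \code{identity.tsv} and a \code{provenance.txt}
#' block; tables absent from the report are skipped. Percentages are written
#' with 2 decimals; full precision is retained in the report object.
#'
#' @param report a \code{run_report}.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, name) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) round(x, 2))
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(report$composition)) wt(report$composition, "composition.tsv")
  if (!is.null(report$codon_usage)) wt(report$codon_usage, "codon_usage.tsv")
  if (!is.null(report$assignments)) wt(report$assignments, "agg_assignments.tsv")
  if (!is.null(report$anticodons)) wt(report$anticodons, "anticodons.tsv")
  if (!is.null(report$ncr_census)) {
    wt(report$ncr_census[, setdiff(names(report$ncr_census), "seq")],
       "ncr_census.tsv")
  }
  if (length(report$cr_architecture)) {
    cr <- do.call(rbind, lapply(report$cr_architecture, function(a) {
      if (!nrow(a$repeats)) return(NULL)
      cbind(id = a$id, a$repeats[, c("start", "unit_length", "full_copies",
                                     "partial_length", "span")])
    }))
    if (!is.null(cr)) wt(cr, "cr_architecture.tsv")
  }
  if (!is.null(report$identity)) {
    m <- as.data.frame(report$identity$matrix)
    wt(cbind(id = rownames(report$identity$matrix), m), "identity.tsv")
  }
  prov <- report$provenance
  writeLines(c(paste0("mitocode ", prov$package_version),
               paste0("n_genomes: ", prov$n_genomes),
               paste0("seed: ", prov$seed),
               paste0("parameters: ",
                      paste(names(prov$parameters),
                            vapply(prov$parameters, function(x)
                              paste(deparse(x), collapse = ""), character(1)),
                            sep = "=", collapse = "; ")),
               "warnings:", paste0("  ", prov$warnings)),
             file.path(dir, "provenance.txt"))
  invisible(c(paths, file.path(dir, "provenance.txt")))
}

#' Annotate tree tips with predicted codon meanings
#'
#' Appends the predicted meaning of the target codon to each matching tip
#' label (e.g. \code{"taxon|AGG=K"}); topology and branch lengths are
#' untouched. Tips without an assignment are left unannotated with a warning.
#'
#' @param assignments data.frame from \code{\link{predict_all}}.
#' @param tree an \code{ape} \code{phylo} object or a newick file path.
#' @return the annotated \code{phylo} object.
#' @export
annotate_tree <- function(assignments, tree) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(assignments) || !nrow(assignments)) return(tree)
  idx <- match(tree$tip.label, assignments$taxon)
  unmatched <- tree$tip.label[is.na(idx)]
  if (length(unmatched)) {
    warning("tips without assignment left unannotated: ",
            paste(unmatched, collapse = ", "))
  }
  hit <- !is.na(idx)
  tree$tip.label[hit] <- paste0(tree$tip.label[hit], "|",
                                assignments$codon[idx[hit]], "=",
                                assignments$predicted[idx[hit]])
  tree
}
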