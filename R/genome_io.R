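#' Construct an annotated mitochondrial genome object
#'
#' The central container of the package: a (typically circular) DNA sequence
#' plus an ordered table of typed gene features. Coordinates are 0-based
#' half-open internally; a feature with \code{end > nchar(sequence)} on a
#' circular genome spans the origin and is interpreted modulo the genome
#' length.
#'
#' @param id accession or label.
#' @param sequence DNA string over \code{{A,C,G,T,N}}.
#' @param features data.frame with columns \code{name}, \code{kind}
#'   (\code{PCG}, \code{tRNA}, \code{rRNA}, \code{control_region},
#'   \code{misc_noncoding}), \code{start} (0-based inclusive), \code{end}
#'   (0-based exclusive), \code{strand} (\code{"+"} = J-strand, \code{"-"}),
#'   and optionally \code{anticodon_offset} (0-based within the tRNA, NA
#'   otherwise).
#' @param circular,complete logical genome flags.
#' @param organism,genus,family taxon metadata strings.
#' @return an object of class \code{mitogenome}.
#' @export
mitogenome <- function(id, sequence, features,
                       circular = TRUE, complete = TRUE,
                       organism = "", genus = "", family = "") {
  stopifnot(is_dna_string(sequence), nchar(sequence) > 0L)
  sequence <- toupper(sequence)
  if (is.null(features) || nrow(features) == 0L) {
    features <- data.frame(name = character(0), kind = character(0),
                           start = integer(0), end = integer(0),
                           strand = character(0),
                           anticodon_offset = integer(0))
  }
  if (!"anticodon_offset" %in% names(features)) features$anticodon_offset <- NA_integer_
  features <- features[, c("name", "kind", "start", "end", "strand", "anticodon_offset")]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$anticodon_offset <- as.integer(features$anticodon_offset)
  len <- nchar(sequence)
  bad <- features$start < 0L | features$start >= len | features$end <= features$start
  if (any(bad)) stop("invalid feature coordinates for: ",
                     paste(features$name[bad], collapse = ", "))
  if (!circular && any(features$end > len)) {
    stop("feature beyond sequence end on a non-circular genome")
  }
  if (any(!is.na(features$anticodon_offset) & features$kind != "tRNA")) {
    stop("anticodon_offset present on a non-tRNA feature")
  }
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(id = id, organism = organism, genus = genus, family = family,
                 sequence = sequence, circular = circular, complete = complete,
                 features = features),
            class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s (%s%s, %d bp, %d features)\n",
              x$id, if (x$circular) "circular" else "linear",
              if (x$complete) "" else ", partial",
              nchar(x$sequence), nrow(x$features)))
  invisible(x)
}

genome_length <- function(genome) nchar(genome$sequence)

feature_length <- function(genome, i) {
  f <- genome$features[i, ]
  f$end - f$start
}

# slice [start, end) honoring origin-spanning coordinates (end may exceed L)
slice_circular <- function(sequence, start, end) {
  len <- nchar(sequence)
  if (end <= len) return(substr(sequence, start + 1L, end))
  paste0(substr(sequence, start + 1L, len), substr(sequence, 1L, end - len))
}

#' Extract the coding-strand sequence of a named gene
#'
#' Returns the feature sequence on its coding strand: minus-strand features
#' are reverse-complemented, origin-spanning features are concatenated across
#' the origin.
#'
#' @param genome a \code{\link{mitogenome}}.
#' @param name canonical gene name (see \code{\link{normalize_gene_name}}).
#' @return DNA string.
#' @export
gene_sequence <- function(genome, name) {
  i <- which(genome$features$name == name)
  if (length(i) == 0L) stop("no feature named '", name, "' in ", genome$id)
  f <- genome$features[i[1L], ]
  s <- slice_circular(genome$sequence, f$start, f$end)
  if (f$strand == "-") s <- revcomp(s)
  s
}

#' Collect the protein-coding genes of a genome
#'
#' Returns the annotated PCGs as coding-strand CDS strings, in the fixed
#' canonical order of the ancestral insect gene arrangement. Missing genes
#' are omitted with a warning.
#'
#' @param genome a \code{\link{mitogenome}}.
#' @return named list of CDS strings (up to 13 entries).
#' @export
concatenated_pcgs <- function(genome) {
  present <- intersect(PCG_ORDER, genome$features$name[genome$features$kind == "PCG"])
  if (length(present) == 0L) stop("no annotated PCGs in ", genome$id)
  missing <- setdiff(PCG_ORDER, present)
  if (length(missing)) {
    warning(genome$id, ": missing PCGs omitted: ", paste(missing, collapse = ", "))
  }
  stats::setNames(lapply(present, gene_sequence, genome = genome), present)
}

# ---- GenBank flat file ------------------------------------------------------

parse_gb_location <- function(loc, lineno) {
  loc0 <- loc
  strand <- "+"
  loc <- gsub(" ", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  spans <- if (grepl("^join\\(", loc)) {
    strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",")[[1]]
  } else loc
  m <- regmatches(spans, regexec("^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$", spans))
  single <- regmatches(spans, regexec("^(\\d+)$", spans))
  starts <- ends <- integer(length(spans))
  for (k in seq_along(spans)) {
    if (length(m[[k]]) == 3L) {
      starts[k] <- as.integer(m[[k]][2]); ends[k] <- as.integer(m[[k]][3])
    } else if (length(single[[k]]) == 2L) {
      starts[k] <- ends[k] <- as.integer(single[[k]][2])
    } else {
      stop("malformed GenBank location '", loc0, "' at line ", lineno)
    }
  }
  list(spans = cbind(start = starts - 1L, end = ends), strand = strand)
}

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Minimal parser for GenBank flat files carrying \code{CDS}, \code{tRNA},
#' \code{rRNA} and \code{D-loop}/\code{misc_feature} features. Gene names are
#' normalized to the canonical vocabulary; 1-based inclusive coordinates are
#' converted to 0-based half-open; \code{join(...)} locations wrapping the
#' origin become origin-spanning features.
#'
#' @param path path to a GenBank flat file.
#' @return a \code{\link{mitogenome}}.
#' @export
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1])) {
    stop("malformed GenBank record: missing LOCUS at line 1 in ", path)
  }
  circular <- grepl("circular", lines[1], ignore.case = TRUE)
  id <- {
    acc <- grep("^ACCESSION", lines, value = TRUE)
    if (length(acc)) strsplit(trimws(sub("^ACCESSION", "", acc[1])), "\\s+")[[1]][1]
    else strsplit(trimws(sub("^LOCUS", "", lines[1])), "\\s+")[[1]][1]
  }
  organism <- {
    org <- grep("^\\s{2}ORGANISM", lines, value = TRUE)
    if (length(org)) trimws(sub("^\\s+ORGANISM", "", org[1])) else ""
  }
  complete <- any(grepl("complete genome", lines[seq_len(min(10, length(lines)))],
                        ignore.case = TRUE))

  feat_start <- grep("^FEATURES", lines)
  origin_at <- grep("^ORIGIN", lines)
  if (!length(feat_start) || !length(origin_at)) {
    stop("malformed GenBank record: missing FEATURES or ORIGIN block in ", path)
  }
  seq_lines <- lines[(origin_at[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  len <- nchar(sequence)

  block <- lines[(feat_start[1] + 1L):(origin_at[1] - 1L)]
  is_key <- grepl("^\\s{5}\\S", block)
  idx <- which(is_key)
  feats <- list()
  for (j in seq_along(idx)) {
    from <- idx[j]
    to <- if (j < length(idx)) idx[j + 1L] - 1L else length(block)
    key <- sub("^\\s+(\\S+).*$", "\\1", block[from])
    if (!key %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")) next
    loc <- trimws(sub("^\\s+\\S+\\s+", "", block[from]))
    quals <- paste(trimws(block[(from + 1L):to]), collapse = " ")
    if (from == to) quals <- ""
    get_qual <- function(q) {
      m <- regmatches(quals, regexec(paste0("/", q, "=\"([^\"]*)\""), quals))[[1]]
      if (length(m) == 2L) m[2] else NA_character_
    }
    lx <- parse_gb_location(loc, feat_start[1] + from)
    start <- lx$spans[1, "start"]
    end <- lx$spans[nrow(lx$spans), "end"]
    if (nrow(lx$spans) > 1L && end <= start) end <- end + len  # origin-spanning
    kind_hint <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                        `D-loop` = "control_region", NULL)
    label <- get_qual("gene")
    if (is.na(label)) label <- get_qual("product")
    if (is.na(label) && key == "D-loop") label <- "control_region"
    if (is.na(label)) label <- get_qual("note")
    if (is.na(label)) label <- key
    nm <- normalize_gene_name(label, kind_hint = kind_hint)
    kind <- if (nm$kind == "misc_noncoding") "misc_noncoding"
            else if (key == "CDS") "PCG" else nm$kind

    ac_off <- NA_integer_
    ac <- regmatches(quals, regexec("/anticodon=\\(pos:([^,]+),", quals))[[1]]
    if (length(ac) == 2L) {
      pos <- gsub("complement\\(|\\)", "", ac[2])
      p1 <- suppressWarnings(as.integer(sub("\\.\\..*$", "", pos)))
      if (!is.na(p1)) {
        ac_off <- if (lx$strand == "+") p1 - 1L - start else end - p1 - 2L
      }
    }
    feats[[length(feats) + 1L]] <- data.frame(
      name = nm$name, kind = kind, start = start, end = end,
      strand = lx$strand, anticodon_offset = ac_off)
  }
  features <- do.call(rbind, feats)
  mitogenome(id = id, sequence = sequence, features = features,
             circular = circular, complete = complete, organism = organism,
             genus = strsplit(organism, "\\s+")[[1]][1] %||% "")
}

# ---- FASTA + feature table --------------------------------------------------

#' Read a mitogenome from FASTA plus a tab-separated feature table
#'
#' The table carries 1-based inclusive coordinates with header
#' \code{name kind start end strand anticodon_offset} (the last column
#' optional). On a circular genome, \code{end > length} denotes an
#' origin-spanning feature.
#'
#' @param fasta path to a single-record FASTA file.
#' @param table path to the feature table TSV.
#' @param circular,complete genome flags (defaults TRUE).
#' @param genus,family optional taxon metadata.
#' @return a \code{\link{mitogenome}}.
#' @export
parse_feature_table <- function(fasta, table, circular = TRUE, complete = TRUE,
                                genus = "", family = "") {
  ss <- Biostrings::readDNAStringSet(fasta)
  if (length(ss) != 1L) stop("expected exactly one FASTA record in ", fasta)
  sequence <- as.character(ss[[1]])
  id <- strsplit(names(ss)[1], "\\s+")[[1]][1]
  tab <- utils::read.delim(table, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    return(mitogenome(id, sequence, NULL, circular = circular,
                      complete = complete, genus = genus, family = family))
  }
  req <- c("name", "kind", "start", "end", "strand")
  if (!all(req %in% names(tab))) {
    stop("feature table must have columns: ", paste(req, collapse = ", "))
  }
  dup <- duplicated(tab$name)
  if (any(dup)) {
    over <- vapply(which(dup), function(i) {
      j <- which(tab$name == tab$name[i])[1]
      tab$start[i] <= tab$end[j] && tab$start[j] <= tab$end[i]
    }, logical(1))
    if (any(over)) stop("overlapping identical feature names: ",
                        paste(unique(tab$name[which(dup)[over]]), collapse = ", "))
  }
  len <- nchar(sequence)
  if (any(tab$end > len) && !circular) {
    stop("feature coordinates beyond sequence end on a non-circular genome")
  }
  if (!"anticodon_offset" %in% names(tab)) tab$anticodon_offset <- NA_integer_
  features <- data.frame(name = tab$name, kind = tab$kind,
                         start = as.integer(tab$start) - 1L,
                         end = as.integer(tab$end),
                         strand = tab$strand,
                         anticodon_offset = as.integer(tab$anticodon_offset))
  mitogenome(id, sequence, features, circular = circular, complete = complete,
             genus = genus, family = family)
}

#' Write a mitogenome's feature table (1-based inclusive coordinates)
#'
#' Inverse of \code{\link{parse_feature_table}}: round-tripping reproduces
#' names, kinds, coordinates and strands exactly.
#'
#' @param genome a \code{\link{mitogenome}}.
#' @param path output TSV path.
#' @export
write_feature_table <- function(genome, path) {
  f <- genome$features
  out <- data.frame(name = f$name, kind = f$kind, start = f$start + 1L,
                    end = f$end, strand = f$strand,
                    anticodon_offset = f$anticodon_offset)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a mitogenome's sequence as FASTA
#' @param genome a \code{\link{mitogenome}}.
#' @param path output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- genome$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
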