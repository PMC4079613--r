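# Synthetic annotated mitogenomes with planted ground truth. The generator
# emulates the data regime the inference modules are built for: AT-rich
# circular genomes in the ancestral insect gene order (13 PCGs, 22 tRNAs,
# 2 rRNAs, control region), clade-structured coding sequences with conserved
# amino-acid columns, a per-taxon genetic-code state for AGG (Ser vs Lys)
# with AGG codons planted only at code-consistent conserved columns,
# correlated anticodon states for the lysine and AGN-serine tRNAs, and
# control regions carrying planted tandem-repeat arrays.

# ancestral insect mitochondrial gene order with strands (+ = J-strand)
ANCESTRAL_ORDER <- data.frame(
  name = c("tRNA-Ile", "tRNA-Gln", "tRNA-Met", "ND2", "tRNA-Trp", "tRNA-Cys",
           "tRNA-Tyr", "COI", "tRNA-Leu(L2)", "COII", "tRNA-Lys", "tRNA-Asp",
           "ATP8", "ATP6", "COIII", "tRNA-Gly", "ND3", "tRNA-Ala", "tRNA-Arg",
           "tRNA-Asn", "tRNA-Ser(S1)", "tRNA-Glu", "tRNA-Phe", "ND5",
           "tRNA-His", "ND4", "ND4L", "tRNA-Thr", "tRNA-Pro", "ND6", "CYTB",
           "tRNA-Ser(S2)", "ND1", "tRNA-Leu(L1)", "lrRNA", "tRNA-Val",
           "srRNA", "control_region"),
  strand = c("+", "-", "+", "+", "+", "-", "-", "+", "+", "+", "+", "+",
             "+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "-", "-",
             "-", "-", "-", "+", "-", "+", "+", "+", "-", "-", "-", "-",
             "-", "+"))

DEFAULT_GENE_LENGTHS <- c(ND2 = 978, COI = 1536, COII = 684, ATP8 = 156,
                          ATP6 = 672, COIII = 786, ND3 = 351, ND5 = 1713,
                          ND4 = 1332, ND4L = 291, ND6 = 522, CYTB = 1137,
                          ND1 = 942)

DMTTF_MOTIF <- "TACTAAA"  # planted 7-bp site between tRNA-Ser(S2) and ND1

#' Configuration for the synthetic mitogenome generator
#'
#' Defaults describe the study conditions the package targets: 12 taxa in
#' four clades of three; 13 protein-coding genes at realistic insect
#' mitochondrial lengths (11.1 kb of coding sequence); 60 percent of
#' amino-acid columns conserved; A+T content 0.7; per-branch substitution
#' probability 0.05 per codon site; one clade translating AGG as Ser with the
#' mutated anticodons (lysine tRNA UUU, AGN-serine tRNA UCU), the others as
#' Lys with the typical anticodons (CUU, GCU); 5 planted AGG occurrences per
#' taxon; and control regions carrying a 60 bp x 11 + 58 bp partial array and
#' a 24 bp x 6 + 20 bp partial array.
#'
#' @param clades named list of taxon labels per clade.
#' @param gene_lengths named numeric vector of CDS lengths (bp, multiples
#'   of 3).
#' @param conserved_fraction fraction of amino-acid columns held fixed.
#' @param at_content target A+T fraction.
#' @param subst_rate per-branch, per-codon-site substitution probability.
#' @param code_map named character vector taxon -> \code{"S"} or \code{"K"}
#'   (meaning of AGG); default: first clade \code{"S"}, others \code{"K"}.
#' @param agg_occurrences scalar or named vector of planted AGG counts per
#'   taxon.
#' @param anticodon_plan named list taxon -> list(\code{"tRNA-Lys"},
#'   \code{"tRNA-Ser(S1)"}) anticodons; default correlated with
#'   \code{code_map}.
#' @param cr_spec list of repeat-array specs:
#'   \code{list(unit_length, full_copies, partial_length)}.
#' @param cr_background_length bp of background on each side/between arrays.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(clades = list(cladeA = c("A1", "A2", "A3"),
                                     cladeB = c("B1", "B2", "B3"),
                                     cladeC = c("C1", "C2", "C3"),
                                     cladeD = c("D1", "D2", "D3")),
                       gene_lengths = DEFAULT_GENE_LENGTHS,
                       conserved_fraction = 0.6,
                       at_content = 0.7,
                       subst_rate = 0.05,
                       code_map = NULL,
                       agg_occurrences = 5L,
                       anticodon_plan = NULL,
                       cr_spec = list(
                         list(unit_length = 60L, full_copies = 11L,
                              partial_length = 58L),
                         list(unit_length = 24L, full_copies = 6L,
                              partial_length = 20L)),
                       cr_background_length = 80L,
                       seed = 1L) {
  taxa <- unlist(clades, use.names = FALSE)
  stopifnot(length(taxa) >= 4L, !anyDuplicated(taxa),
            all(gene_lengths %% 3 == 0),
            conserved_fraction >= 0, conserved_fraction <= 1,
            at_content > 0, at_content < 1,
            subst_rate >= 0, subst_rate <= 1)
  if (is.null(code_map)) {
    code_map <- stats::setNames(rep("K", length(taxa)), taxa)
    code_map[clades[[1L]]] <- "S"
  }
  stopifnot(setequal(names(code_map), taxa), all(code_map %in% c("S", "K")))
  if (length(agg_occurrences) == 1L && is.null(names(agg_occurrences))) {
    agg_occurrences <- stats::setNames(rep(as.integer(agg_occurrences),
                                           length(taxa)), taxa)
  }
  stopifnot(setequal(names(agg_occurrences), taxa))
  if (is.null(anticodon_plan)) {
    anticodon_plan <- lapply(stats::setNames(taxa, taxa), function(t) {
      if (code_map[[t]] == "S") list(`tRNA-Lys` = "UUU", `tRNA-Ser(S1)` = "UCU")
      else list(`tRNA-Lys` = "CUU", `tRNA-Ser(S1)` = "GCU")
    })
  }
  structure(list(clades = clades, taxa = taxa, gene_lengths = gene_lengths,
                 conserved_fraction = conserved_fraction,
                 at_content = at_content, subst_rate = subst_rate,
                 code_map = code_map,
                 agg_occurrences = agg_occurrences[taxa],
                 anticodon_plan = anticodon_plan, cr_spec = cr_spec,
                 cr_background_length = as.integer(cr_background_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# AT-biased random DNA
random_dna <- function(n, at) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

codon_weights <- function(codons, at) {
  vapply(strsplit(codons, ""), function(b) {
    prod(ifelse(b %in% c("A", "T"), at / 2, (1 - at) / 2))
  }, numeric(1))
}

# canonical cloverleaf-like tRNA scaffold (66 nt) with the anticodon at a
# fixed offset; A/C filler regions cannot pair, so the two planted stems are
# the only 5-bp stem / 7-nt loop structures
TRNA_AC_OFFSET <- 38L

trna_scaffold <- function(anticodon) {
  ac <- rna_to_dna(toupper(anticodon))
  stopifnot(nchar(ac) == 3L)
  paste0("AAACAAACAA",              # 1-10   acceptor-side filler
         "GGCAG", "AAAAAAA", "CTGCC",  # 11-27  DHU-like stem-loop
         "ACAA",                    # 28-31  spacer
         "CAGCG", paste0("CT", ac, "AA"), "CGCTG",  # 32-48 anticodon arm
         "ACAA",                    # 49-52  spacer
         "AAACAAACAAACAA")          # 53-66  T-arm-side filler
}

mutate_codons <- function(codons, conserved, rate, code, sense, weights, at) {
  n <- length(codons)
  hit <- which(stats::runif(n) < rate)
  for (i in hit) {
    if (conserved[i]) {
      aa <- code[[codons[i]]]
      syn <- sense[code[sense] == aa & sense != "AGG"]
      if (length(syn) > 1L) syn <- setdiff(syn, codons[i])
      codons[i] <- if (length(syn) == 1L) syn else
        sample(syn, 1L, prob = codon_weights(syn, at))
    } else {
      pool <- setdiff(sense, "AGG")
      codons[i] <- sample(pool, 1L, prob = codon_weights(pool, at))
    }
  }
  codons
}

#' Simulate annotated mitogenomes with planted ground truth
#'
#' See \code{\link{sim_config}} for the generative model. Protein-coding
#' genes descend from a shared AT-biased root by per-codon substitution
#' (synonymous-only at conserved columns); AGG codons are planted only at
#' conserved lysine columns for AGG=Lys taxa and conserved serine columns for
#' AGG=Ser taxa; tRNA scaffolds carry the planted anticodons; control regions
#' are clade-shared background plus planted exact tandem arrays with
#' mismatching flanks (so each array is maximal as planted).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{genomes} (list of \code{\link{mitogenome}}) and
#'   \code{truth} (class \code{sim_truth}): \code{code_map},
#'   \code{anticodon_plan}, \code{conserved_sites} (global codon-site
#'   indices), \code{agg_sites} (per taxon), \code{cr_repeats} (per taxon
#'   data.frame, CR-relative coordinates), \code{dmttf} (motif and flanks),
#'   \code{gene_lengths}.
#' @export
simulate_mitogenomes <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_impl(config))
}

simulate_impl <- function(cfg) {
  code <- mito_code()
  sense <- names(code)[code != "*"]
  at <- cfg$at_content
  glens <- cfg$gene_lengths
  n_sites_per_gene <- glens %/% 3L
  n_sites <- sum(n_sites_per_gene)
  gene_of_site <- rep(names(glens), n_sites_per_gene)

  # root coding sequence and conserved-column set
  pool <- setdiff(sense, "AGG")
  root <- sample(pool, n_sites, replace = TRUE, prob = codon_weights(pool, at))
  conserved <- rep(FALSE, n_sites)
  conserved[sample.int(n_sites, round(cfg$conserved_fraction * n_sites))] <- TRUE

  # guarantee a supply of conserved Lys and Ser columns for AGG planting
  max_occ <- max(cfg$agg_occurrences)
  supply <- max(2L * max_occ, 12L)
  for (aa in c("K", "S")) {
    have <- which(conserved & code[root] == aa)
    need <- supply - length(have)
    if (need > 0L) {
      cand <- which(conserved & !(code[root] %in% c("K", "S")))
      take <- sample(cand, min(need, length(cand)))
      fam <- sense[code[sense] == aa & sense != "AGG"]
      root[take] <- sample(fam, length(take), replace = TRUE,
                           prob = codon_weights(fam, at))
    }
  }
  k_pool <- which(conserved & code[root] == "K")
  s_pool <- which(conserved & code[root] == "S")
  for (t in cfg$taxa) {
    avail <- if (cfg$code_map[[t]] == "K") length(k_pool) else length(s_pool)
    if (cfg$agg_occurrences[[t]] > avail) {
      stop("agg_occurrences for ", t, " (", cfg$agg_occurrences[[t]],
           ") exceeds available code-consistent conserved sites (", avail, ")")
    }
  }

  # evolve: root -> clade ancestor -> taxon; then plant AGG
  taxon_codons <- list()
  agg_sites <- list()
  for (cl in names(cfg$clades)) {
    anc <- mutate_codons(root, conserved, cfg$subst_rate, code, sense,
                         NULL, at)
    for (t in cfg$clades[[cl]]) {
      cods <- mutate_codons(anc, conserved, cfg$subst_rate, code, sense,
                            NULL, at)
      sites <- if (cfg$agg_occurrences[[t]] > 0L) {
        src <- if (cfg$code_map[[t]] == "K") k_pool else s_pool
        sort(sample(src, cfg$agg_occurrences[[t]]))
      } else integer(0)
      cods[sites] <- "AGG"
      taxon_codons[[t]] <- cods
      agg_sites[[t]] <- sites
    }
  }

  # clade-shared control-region background and units; arrays stay exact,
  # background diverges slightly per taxon
  bg_len <- cfg$cr_background_length
  cr_parts_by_clade <- lapply(cfg$clades, function(tx) {
    units <- lapply(cfg$cr_spec, function(sp) random_dna(sp$unit_length, at))
    bgs <- as.list(replicate(length(cfg$cr_spec) + 1L, random_dna(bg_len, at)))
    list(units = units, bgs = bgs)
  })

  mutate_dna <- function(s, rate = 0.02) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(c("A", "T", "G", "C"), ch[i]), 1L)
    paste(ch, collapse = "")
  }

  fix_base <- function(s, i, avoid) {
    if (substr(s, i, i) == avoid) {
      substr(s, i, i) <- setdiff(c("A", "T", "G", "C"), avoid)[1L]
    }
    s
  }

  assemble_cr <- function(parts, spec) {
    # per-taxon divergent copies of the clade background
    bgs <- lapply(parts$bgs, mutate_dna)
    # mismatching flanks keep every planted array maximal: the base before an
    # array must differ from the unit's last base (left extension), the base
    # after it from the base following the partial copy (right extension)
    for (k in seq_along(spec)) {
      unit <- parts$units[[k]]
      bgs[[k]] <- fix_base(bgs[[k]], nchar(bgs[[k]]),
                           substr(unit, nchar(unit), nchar(unit)))
      after <- substr(unit, spec[[k]]$partial_length + 1L,
                      spec[[k]]$partial_length + 1L)
      bgs[[k + 1L]] <- fix_base(bgs[[k + 1L]], 1L, after)
    }
    pieces <- character(0)
    repeats <- list()
    pos <- 0L
    for (k in seq_along(spec)) {
      sp <- spec[[k]]
      unit <- parts$units[[k]]
      arr <- paste0(strrep(unit, sp$full_copies),
                    substr(unit, 1L, sp$partial_length))
      pieces <- c(pieces, bgs[[k]])
      pos <- pos + nchar(bgs[[k]])
      repeats[[k]] <- data.frame(start = pos, unit_length = sp$unit_length,
                                 unit_seq = unit,
                                 full_copies = sp$full_copies,
                                 partial_length = sp$partial_length,
                                 span = nchar(arr))
      pieces <- c(pieces, arr)
      pos <- pos + nchar(arr)
    }
    pieces <- c(pieces, bgs[[length(spec) + 1L]])
    list(seq = paste(pieces, collapse = ""),
         repeats = do.call(rbind, repeats))
  }

  std_ac <- stats::setNames(standard_anticodons()$anticodon,
                            standard_anticodons()$trna)
  rrna_seq <- list(srRNA = random_dna(750L, at), lrRNA = random_dna(1250L, at))

  genomes <- list()
  cr_repeats <- list()
  for (t in cfg$taxa) {
    cl <- names(cfg$clades)[vapply(cfg$clades, function(x) t %in% x, logical(1))]
    cods <- taxon_codons[[t]]
    gene_cds <- lapply(stats::setNames(names(glens), names(glens)), function(g) {
      paste(cods[gene_of_site == g], collapse = "")
    })
    cr <- assemble_cr(cr_parts_by_clade[[cl]], cfg$cr_spec)
    cr_repeats[[t]] <- cr$repeats

    seq_parts <- character(0)
    feats <- list()
    pos <- 0L
    add <- function(name, kind, coding_seq, strand, ac_off = NA_integer_) {
      segment <- if (strand == "+") coding_seq else revcomp(coding_seq)
      seq_parts <<- c(seq_parts, segment)
      feats[[length(feats) + 1L]] <<- data.frame(
        name = name, kind = kind, start = pos, end = pos + nchar(segment),
        strand = strand, anticodon_offset = ac_off)
      pos <<- pos + nchar(segment)
    }
    for (i in seq_len(nrow(ANCESTRAL_ORDER))) {
      nm <- ANCESTRAL_ORDER$name[i]
      st <- ANCESTRAL_ORDER$strand[i]
      if (nm %in% names(glens)) {
        add(nm, "PCG", gene_cds[[nm]], st)
      } else if (startsWith(nm, "tRNA")) {
        ac <- cfg$anticodon_plan[[t]][[nm]] %||% std_ac[[nm]]
        add(nm, "tRNA", trna_scaffold(ac), st, TRNA_AC_OFFSET)
        # planted non-coding gaps mirroring real architectures
        if (nm == "tRNA-Pro") { seq_parts <- c(seq_parts, "TA"); pos <- pos + 2L }
        if (nm == "tRNA-Ser(S2)") {
          seq_parts <- c(seq_parts, DMTTF_MOTIF)
          pos <- pos + nchar(DMTTF_MOTIF)
        }
      } else if (nm %in% c("srRNA", "lrRNA")) {
        add(nm, "rRNA", rrna_seq[[nm]], st)
      } else if (nm == "control_region") {
        add("control_region", "control_region", cr$seq, "+")
      }
    }
    genomes[[t]] <- mitogenome(
      id = t, sequence = paste(seq_parts, collapse = ""),
      features = do.call(rbind, feats), circular = TRUE, complete = TRUE,
      organism = paste(cl, t), genus = cl)
  }

  truth <- structure(list(code_map = cfg$code_map,
                          anticodon_plan = cfg$anticodon_plan,
                          conserved_sites = which(conserved),
                          agg_sites = agg_sites,
                          cr_repeats = cr_repeats,
                          dmttf = list(motif = DMTTF_MOTIF,
                                       left = "tRNA-Ser(S2)", right = "ND1"),
                          gene_lengths = glens),
                     class = "sim_truth")
  list(genomes = genomes, truth = truth)
}

#' Write a simulated genome set as plain-text fixtures
#'
#' One FASTA and one feature-table TSV per genome, plus truth tables
#' (\code{truth_code.tsv}: taxon, AGG meaning, planted anticodons;
#' \code{truth_repeats.tsv}: planted repeat coordinates). The files
#' round-trip through \code{\link{parse_feature_table}}.
#'
#' @param genomes,truth output of \code{\link{simulate_mitogenomes}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_fixture_set <- function(genomes, truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (g in genomes) {
    fa <- file.path(dir, paste0(g$id, ".fasta"))
    tsv <- file.path(dir, paste0(g$id, ".features.tsv"))
    write_genome_fasta(g, fa)
    write_feature_table(g, tsv)
    paths <- c(paths, fa, tsv)
  }
  code_tab <- data.frame(
    taxon = names(truth$code_map),
    agg_meaning = unname(truth$code_map),
    trna_lys = vapply(truth$anticodon_plan[names(truth$code_map)],
                      `[[`, character(1), "tRNA-Lys"),
    trna_ser_agn = vapply(truth$anticodon_plan[names(truth$code_map)],
                          `[[`, character(1), "tRNA-Ser(S1)"),
    n_agg = vapply(truth$agg_sites[names(truth$code_map)], length, integer(1)))
  p1 <- file.path(dir, "truth_code.tsv")
  utils::write.table(code_tab, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  reps <- do.call(rbind, lapply(names(truth$cr_repeats), function(t) {
    cbind(taxon = t, truth$cr_repeats[[t]])
  }))
  p2 <- file.path(dir, "truth_repeats.tsv")
  utils::write.table(reps, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, p1, p2))
}
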