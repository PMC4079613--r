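# Canonical 37-gene vocabulary of the insect mitogenome and normalization of
# the many GenBank spellings onto it. Duplicated Leu/Ser tRNAs carry the
# L1/L2/S1/S2 suffixes (L1: CUN; L2: UUR; S1: AGN; S2: UCN).

PCG_ORDER <- c("ND2", "COI", "COII", "ATP8", "ATP6", "COIII", "ND3",
               "ND5", "ND4", "ND4L", "ND6", "CYTB", "ND1")

AA3_TO_1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
              Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
              Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
              Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

TRNA_NAMES <- c("tRNA-Ala", "tRNA-Arg", "tRNA-Asn", "tRNA-Asp", "tRNA-Cys",
                "tRNA-Gln", "tRNA-Glu", "tRNA-Gly", "tRNA-His", "tRNA-Ile",
                "tRNA-Leu(L1)", "tRNA-Leu(L2)", "tRNA-Lys", "tRNA-Met",
                "tRNA-Phe", "tRNA-Pro", "tRNA-Ser(S1)", "tRNA-Ser(S2)",
                "tRNA-Thr", "tRNA-Trp", "tRNA-Tyr", "tRNA-Val")

RRNA_NAMES <- c("srRNA", "lrRNA")

CANONICAL_GENES <- c(PCG_ORDER, TRNA_NAMES, RRNA_NAMES)

# fixed synonym table for PCGs and rRNAs (keys uppercased, punctuation stripped)
GENE_SYNONYMS <- c(
  COX1 = "COI", CO1 = "COI", COI = "COI", COXI = "COI",
  COX2 = "COII", CO2 = "COII", COII = "COII", COXII = "COII",
  COX3 = "COIII", CO3 = "COIII", COIII = "COIII", COXIII = "COIII",
  COB = "CYTB", CYTB = "CYTB", CYB = "CYTB", CTYB = "CYTB",
  ATP6 = "ATP6", ATPASE6 = "ATP6", ATP8 = "ATP8", ATPASE8 = "ATP8",
  NAD1 = "ND1", ND1 = "ND1", NADH1 = "ND1",
  NAD2 = "ND2", ND2 = "ND2", NADH2 = "ND2",
  NAD3 = "ND3", ND3 = "ND3", NADH3 = "ND3",
  NAD4 = "ND4", ND4 = "ND4", NADH4 = "ND4",
  NAD4L = "ND4L", ND4L = "ND4L", NADH4L = "ND4L",
  NAD5 = "ND5", ND5 = "ND5", NADH5 = "ND5",
  NAD6 = "ND6", ND6 = "ND6", NADH6 = "ND6",
  `12S` = "srRNA", SRRNA = "srRNA", RRNS = "srRNA", `12SRRNA` = "srRNA",
  SSURRNA = "srRNA", `S-RRNA` = "srRNA",
  `16S` = "lrRNA", LRRNA = "lrRNA", RRNL = "lrRNA", `16SRRNA` = "lrRNA",
  LSURRNA = "lrRNA", `L-RRNA` = "lrRNA"
)

# anticodon-class discriminators for the duplicated Leu and Ser tRNAs
LEU_SER_CLASS <- c(
  CUN = "tRNA-Leu(L1)", UUR = "tRNA-Leu(L2)",
  AGN = "tRNA-Ser(S1)", UCN = "tRNA-Ser(S2)",
  L1 = "tRNA-Leu(L1)", L2 = "tRNA-Leu(L2)",
  S1 = "tRNA-Ser(S1)", S2 = "tRNA-Ser(S2)",
  TAG = "tRNA-Leu(L1)", UAG = "tRNA-Leu(L1)",
  TAA = "tRNA-Leu(L2)", UAA = "tRNA-Leu(L2)",
  GCT = "tRNA-Ser(S1)", GCU = "tRNA-Ser(S1)",
  TGA = "tRNA-Ser(S2)", UGA = "tRNA-Ser(S2)"
)

#' Normalize a gene label to the canonical 37-gene vocabulary
#'
#' Maps the common GenBank spellings (COX1, cob, nad4L, trnL-UUR, 12S rRNA,
#' ...) onto the fixed vocabulary used throughout the package. Unrecognized
#' names are returned unchanged with kind \code{"misc_noncoding"} so they are
#' retained but excluded from coding-gene analyses.
#'
#' @param name raw gene label.
#' @param kind_hint optional feature kind ("PCG", "tRNA", "rRNA",
#'   "control_region") when known from the record context.
#' @return list with elements \code{name} (canonical) and \code{kind}.
#' @export
normalize_gene_name <- function(name, kind_hint = NULL) {
  raw <- name
  up <- toupper(trimws(name))
  key <- gsub("[ _.]", "", up)

  if (grepl("^(D-?LOOP|CONTROL.?REGION|A\\+T.?RICH|CR)$", key) ||
      identical(kind_hint, "control_region")) {
    return(list(name = "control_region", kind = "control_region"))
  }

  # tRNAs: trnK, trn L-UUR, tRNA-Lys, tRNA-Ser(AGN), trnS1 ...
  if (grepl("^T?RNA", key) || grepl("^TRN", key) || identical(kind_hint, "tRNA")) {
    body <- sub("^(TRNA-?|TRN)", "", key)
    # class discriminator for Leu/Ser, e.g. L(UUR), S1, SER(AGN), L-TAA
    disc <- regmatches(up, regexpr("(CUN|UUR|AGN|UCN|L1|L2|S1|S2)", up))
    aa3 <- names(AA3_TO_1)[match(toupper(substr(body, 1, 3)),
                                 toupper(names(AA3_TO_1)))]
    one <- if (!is.na(aa3) && length(aa3)) AA3_TO_1[[aa3]] else substr(body, 1, 1)
    if (one %in% c("L", "S")) {
      if (length(disc) && disc %in% names(LEU_SER_CLASS)) {
        return(list(name = unname(LEU_SER_CLASS[[disc]]), kind = "tRNA"))
      }
      # try an embedded anticodon triplet, e.g. trnL-taa
      tri <- regmatches(key, regexpr("(TAG|TAA|GCT|TGA|UAG|UAA|GCU|UGA)$", key))
      if (length(tri) && tri %in% names(LEU_SER_CLASS)) {
        return(list(name = unname(LEU_SER_CLASS[[tri]]), kind = "tRNA"))
      }
      warning("ambiguous duplicated tRNA name: ", raw,
              " (no L1/L2/S1/S2 or anticodon-class qualifier)")
      return(list(name = raw, kind = "misc_noncoding"))
    }
    full <- names(AA3_TO_1)[AA3_TO_1 == one]
    if (length(full) == 1L) {
      cand <- paste0("tRNA-", full)
      if (cand %in% TRNA_NAMES) return(list(name = cand, kind = "tRNA"))
    }
    warning("unmappable tRNA name: ", raw)
    return(list(name = raw, kind = "misc_noncoding"))
  }

  if (key %in% names(GENE_SYNONYMS)) {
    canon <- unname(GENE_SYNONYMS[[key]])
    kind <- if (canon %in% RRNA_NAMES) "rRNA" else "PCG"
    return(list(name = canon, kind = kind))
  }
  # rRNA spellings with decorations, e.g. "small subunit ribosomal RNA"
  if (grepl("RRNA|RIBOSOMAL", key) || identical(kind_hint, "rRNA")) {
    if (grepl("12S|SMALL|SSU|^S", key)) return(list(name = "srRNA", kind = "rRNA"))
    if (grepl("16S|LARGE|LSU|^L", key)) return(list(name = "lrRNA", kind = "rRNA"))
  }
  warning("unmappable gene name: ", raw, " (kept as misc_noncoding)")
  list(name = raw, kind = "misc_noncoding")
}
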