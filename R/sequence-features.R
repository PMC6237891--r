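# Sequence-derived features: codon/amino-acid composition, GC3,
# physicochemical indices, structure-stratified composition, and the tiered
# feature matrix consumed by the prediction harness.

#' Build a set of coding records from CDS strings
#'
#' Validates each CDS as a complete ORF (length divisible by 3, start codon,
#' exactly one stop at the terminal position) and derives the protein
#' sequence. The initiator Met is retained in the protein.
#'
#' @param ids Character vector of unique identifiers.
#' @param cds Character vector of coding sequences, same length as \code{ids}.
#' @param require_start Require the first codon to be ATG (default TRUE).
#' @return A data frame of class \code{coding_records} with columns
#'   \code{id}, \code{cds}, \code{protein}.
#' @export
coding_records <- function(ids, cds, require_start = TRUE) {
  if (length(ids) != length(cds)) stop("ids and cds lengths differ")
  if (anyDuplicated(ids)) {
    stop("duplicate ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cds <- vapply(cds, normalize_dna, character(1), USE.NAMES = FALSE)
  if (require_start && any(substr(cds, 1, 3) != "ATG")) {
    bad <- ids[substr(cds, 1, 3) != "ATG"][1L]
    stop("CDS does not begin with ATG: ", bad)
  }
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  if (any(!last %in% c("TAA", "TAG", "TGA"))) {
    bad <- ids[!last %in% c("TAA", "TAG", "TGA")][1L]
    stop("CDS lacks a terminal stop codon: ", bad)
  }
  protein <- vapply(cds, translate_cds, character(1), USE.NAMES = FALSE)
  out <- data.frame(id = as.character(ids), cds = cds, protein = protein,
                    stringsAsFactors = FALSE)
  class(out) <- c("coding_records", "data.frame")
  out
}

#' Codon and amino-acid composition of one coding sequence
#'
#' Computes the 81 composition features of a CDS: the percentage of each of
#' the 20 amino acids in the protein and of each of the 61 sense codons in
#' the CDS. The terminal stop codon is excluded from all counts; the
#' initiator Met codon is included. Both blocks sum to 100.
#'
#' @param cds A coding sequence (complete ORF with terminal stop, or a
#'   stop-free codon string).
#' @return Named numeric vector of length 81 (names as in
#'   \code{\link{composition_feature_names}}), percentages on the 0-100 scale.
#' @examples
#' v <- composition_vector("ATGGCTGCCTAA")
#' v[c("aa_M", "aa_A", "codon_GCT")]
#' @export
composition_vector <- function(cds) {
  cds <- normalize_dna(cds)
  codons <- codon_split(cds)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) stop("invalid codon in CDS")
  if (aa[length(aa)] == "*") {
    codons <- codons[-length(codons)]
    aa <- aa[-length(aa)]
  }
  if (any(aa == "*")) stop("internal stop codon in CDS")
  if (length(aa) == 0L) stop("empty protein")
  ct <- codon_table()
  aa_pct <- 100 * tabulate(factor(aa, levels = AA_LETTERS),
                           nbins = 20L) / length(aa)
  codon_pct <- 100 * tabulate(factor(codons, levels = ct$codon),
                              nbins = 61L) / length(codons)
  stats::setNames(c(aa_pct, codon_pct), composition_feature_names())
}

#' GC3: percentage of G-/C-ending codons
#'
#' The wobble (third) nucleotide content of a CDS: the percentage of codons
#' whose third base is G or C. The terminal stop codon is always excluded.
#' With \code{scope = "tunable_only"} the Met (ATG) and Trp (TGG) codons,
#' whose third base cannot be changed synonymously, are excluded from both
#' numerator and denominator; this is the scope the codon designer targets.
#'
#' @param cds Coding sequence.
#' @param scope \code{"all_codons"} (descriptive reporting, default) or
#'   \code{"tunable_only"}.
#' @return Percentage in [0, 100], or \code{NA} (with attribute
#'   \code{undefined = TRUE}) when no codon is in scope.
#' @export
gc3_fraction <- function(cds, scope = c("all_codons", "tunable_only")) {
  scope <- match.arg(scope)
  cds <- normalize_dna(cds)
  codons <- codon_split(cds)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) stop("invalid codon in CDS")
  if (length(aa) && aa[length(aa)] == "*") codons <- codons[-length(codons)]
  if (scope == "tunable_only") {
    codons <- codons[!codons %in% c("ATG", "TGG")]
  }
  if (length(codons) == 0L) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  100 * mean(substr(codons, 3, 3) %in% c("G", "C"))
}

# Kyte-Doolittle hydropathy scale
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                   L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# average residue masses (Da); water added once per chain
AA_RESIDUE_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                     C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
                     H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                     M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                     T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

# EMBOSS pKa set used for the isoelectric point
PKA_SET <- list(
  name = "EMBOSS",
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

# net charge of a protein at a given pH under PKA_SET
protein_net_charge <- function(counts, pH) {
  pos <- 1 / (1 + 10^(pH - PKA_SET$nterm)) +
    sum(counts[names(PKA_SET$positive)] /
          (1 + 10^(pH - PKA_SET$positive)))
  neg <- 1 / (1 + 10^(PKA_SET$cterm - pH)) +
    sum(counts[names(PKA_SET$negative)] /
          (1 + 10^(PKA_SET$negative - pH)))
  pos - neg
}

#' Physicochemical summary of a protein
#'
#' Computes the whole-protein scalars used as sequence-tier features:
#' average molecular weight (Da), theoretical isoelectric point (bisection
#' on the net charge under the EMBOSS pKa set), GRAVY (mean Kyte-Doolittle
#' hydropathy), the aliphatic index of Ikai
#' (\eqn{\%A + 2.9\,\%V + 3.9\,(\%I + \%L)}), chain length, and the
#' N-terminal residue, defined as the residue at position 2 of the protein
#' (the residue following the initiator Met, which is not cleaved).
#'
#' @param protein One-letter amino-acid string (initiator Met included).
#' @return List with elements \code{molecular_weight},
#'   \code{isoelectric_point}, \code{gravy}, \code{aliphatic_index},
#'   \code{length}, \code{nterm_residue}.
#' @export
physchem <- function(protein) {
  res <- strsplit(protein, "")[[1L]]
  if (length(res) == 0L) stop("empty protein")
  if (!all(res %in% AA_LETTERS)) {
    stop("invalid residue: ", paste(setdiff(res, AA_LETTERS), collapse = ", "))
  }
  counts <- tabulate(factor(res, levels = AA_LETTERS), nbins = 20L)
  names(counts) <- AA_LETTERS
  n <- length(res)
  mw <- sum(counts * AA_RESIDUE_MASS[AA_LETTERS]) + WATER_MASS
  gravy <- sum(counts * KD_HYDROPATHY[AA_LETTERS]) / n
  molepct <- 100 * counts / n
  ai <- molepct[["A"]] + 2.9 * molepct[["V"]] +
    3.9 * (molepct[["I"]] + molepct[["L"]])
  lo <- 0; hi <- 14
  for (i in seq_len(100)) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(counts, mid) > 0) lo <- mid else hi <- mid
  }
  list(
    molecular_weight = mw,
    isoelectric_point = (lo + hi) / 2,
    gravy = gravy,
    aliphatic_index = ai,
    length = n,
    nterm_residue = if (n >= 2L) res[2L] else res[1L]
  )
}

#' Structure-stratified composition
#'
#' Splits a coding sequence into its alpha-helix (H), beta-sheet (E) and
#' random-coil (C) regions according to a per-residue secondary-structure
#' string, and computes the 81 composition features within each class:
#' the percentage of class-c residues (or their codons) that are each amino
#' acid (codon). Classes with no residues yield all-zero blocks, flagged in
#' the \code{empty_classes} attribute.
#'
#' @param cds Coding sequence (terminal stop allowed and ignored).
#' @param structure H/E/C string, one character per protein residue.
#' @return Named numeric vector of length 243 with names
#'   \code{H_aa_A}, ..., \code{C_codon_TTT}.
#' @export
stratified_composition <- function(cds, structure) {
  cds <- normalize_dna(cds)
  codons <- codon_split(cds)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (length(aa) && aa[length(aa)] == "*") {
    codons <- codons[-length(codons)]
    aa <- aa[-length(aa)]
  }
  cls <- strsplit(structure, "")[[1L]]
  if (length(cls) != length(aa)) {
    stop(sprintf("structure length %d does not match protein length %d",
                 length(cls), length(aa)))
  }
  if (!all(cls %in% c("H", "E", "C"))) {
    stop("structure characters must be H, E or C")
  }
  ct <- codon_table()
  feat_names <- composition_feature_names()
  out <- numeric(0)
  empty <- character(0)
  for (k in c("H", "E", "C")) {
    sel <- cls == k
    if (!any(sel)) {
      block <- stats::setNames(numeric(81L), feat_names)
      empty <- c(empty, k)
    } else {
      aa_pct <- 100 * tabulate(factor(aa[sel], levels = AA_LETTERS),
                               nbins = 20L) / sum(sel)
      cd_pct <- 100 * tabulate(factor(codons[sel], levels = ct$codon),
                               nbins = 61L) / sum(sel)
      block <- stats::setNames(c(aa_pct, cd_pct), feat_names)
    }
    names(block) <- paste0(k, "_", names(block))
    out <- c(out, block)
  }
  if (length(empty)) attr(out, "empty_classes") <- empty
  out
}

#' Assemble a tiered feature matrix
#'
#' Builds the proteins-by-features matrix for one of the three feature
#' tiers. The \code{composition} tier holds exactly the 81 amino-acid and
#' codon percentages. The \code{sequence} tier adds the structure-stratified
#' composition (243 columns), the physicochemical scalars (molecular weight,
#' isoelectric point, GRAVY, aliphatic index), protein length, and a one-hot
#' encoding of the N-terminal (position-2) residue. The \code{all} tier
#' further appends binary annotation columns, retaining only terms present
#' in at least \code{min_prevalence} proteins. Any feature trivially derived
#' from the response (protein length when \code{response_kind = "length"})
#' is dropped and recorded in the \code{dropped} attribute.
#'
#' @param records A \code{\link{coding_records}} data frame.
#' @param tier \code{"composition"}, \code{"sequence"} or \code{"all"}.
#' @param structures Named character vector of H/E/C strings (required for
#'   tiers above composition).
#' @param annotations Binary term-by-nothing matrix: proteins in rows,
#'   terms in columns (required for tier \code{"all"}).
#' @param response_kind Name of the response being predicted; used only for
#'   the response-leak exclusion rule.
#' @param min_prevalence Minimum number of annotated proteins for an
#'   annotation column to be retained (default 10).
#' @return Numeric matrix with protein ids as row names and a
#'   \code{"tiers"} attribute naming each column's tier
#'   (composition/sequence/annotation).
#' @export
assemble_feature_matrix <- function(records,
                                    tier = c("composition", "sequence", "all"),
                                    structures = NULL, annotations = NULL,
                                    response_kind = "lifetime",
                                    min_prevalence = 10L) {
  tier <- match.arg(tier)
  comp <- t(vapply(records$cds, composition_vector,
                   numeric(81L), USE.NAMES = FALSE))
  dimnames(comp) <- list(records$id, composition_feature_names())
  tiers <- stats::setNames(rep("composition", ncol(comp)), colnames(comp))
  mat <- comp
  if (tier %in% c("sequence", "all")) {
    if (is.null(structures)) {
      stop("tier '", tier, "' requires secondary-structure strings")
    }
    missing <- setdiff(records$id, names(structures))
    if (length(missing)) {
      stop("no structure for: ", paste(utils::head(missing, 3), collapse = ", "))
    }
    strat <- t(vapply(seq_len(nrow(records)), function(i) {
      as.numeric(stratified_composition(records$cds[i],
                                        structures[[records$id[i]]]))
    }, numeric(243L)))
    colnames(strat) <- names(stratified_composition(records$cds[1L],
                                                    structures[[records$id[1L]]]))
    pc <- lapply(records$protein, physchem)
    scalars <- cbind(
      molecular_weight = vapply(pc, `[[`, numeric(1), "molecular_weight"),
      isoelectric_point = vapply(pc, `[[`, numeric(1), "isoelectric_point"),
      gravy = vapply(pc, `[[`, numeric(1), "gravy"),
      aliphatic_index = vapply(pc, `[[`, numeric(1), "aliphatic_index"),
      length = vapply(pc, `[[`, numeric(1), "length")
    )
    nterm <- vapply(pc, `[[`, character(1), "nterm_residue")
    onehot <- 1 * outer(nterm, AA_LETTERS, `==`)
    colnames(onehot) <- paste0("nterm_", AA_LETTERS)
    seq_block <- cbind(strat, scalars, onehot)
    rownames(seq_block) <- records$id
    mat <- cbind(mat, seq_block)
    tiers <- c(tiers, stats::setNames(rep("sequence", ncol(seq_block)),
                                      colnames(seq_block)))
  }
  if (tier == "all" && !is.null(annotations)) {
    ann <- as.matrix(annotations)
    missing <- setdiff(records$id, rownames(ann))
    if (length(missing)) {
      stop("no annotations for: ", paste(utils::head(missing, 3), collapse = ", "))
    }
    ann <- ann[records$id, , drop = FALSE]
    keep <- colSums(ann != 0) >= min_prevalence
    ann <- ann[, keep, drop = FALSE]
    if (ncol(ann)) {
      colnames(ann) <- paste0("ann_", colnames(ann))
      mat <- cbind(mat, ann)
      tiers <- c(tiers, stats::setNames(rep("annotation", ncol(ann)),
                                        colnames(ann)))
    }
  }
  dropped <- character(0)
  if (identical(response_kind, "length") && "length" %in% colnames(mat)) {
    dropped <- "length"
    tiers <- tiers[colnames(mat) != "length"]
    mat <- mat[, colnames(mat) != "length", drop = FALSE]
  }
  if (anyDuplicated(colnames(mat))) stop("duplicate feature names")
  if (anyNA(mat)) stop("missing values in assembled feature matrix")
  attr(mat, "tiers") <- tiers
  attr(mat, "dropped") <- dropped
  mat
}
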