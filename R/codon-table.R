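# Standard genetic code bookkeeping: sense codons, wobble classes and the
# 21 synonymous subgroups used throughout the wobble analyses.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Standard codon table with wobble classes and synonymous subgroups
#'
#' Returns a data frame describing the 61 sense codons of the standard
#' genetic code. Each codon is annotated with the amino acid it encodes, its
#' wobble class (\code{"GC_ending"} if the third nucleotide is G or C,
#' \code{"AU_ending"} otherwise), whether it is wobble-tunable (all codons
#' except ATG and TGG, whose amino acids Met and Trp are encoded by a single
#' codon), and its synonymous subgroup.
#'
#' A synonymous subgroup is the set of codons sharing both their amino acid
#' and their first two nucleotides. The three six-fold amino acids (Leu, Arg,
#' Ser) therefore split into a pair and a quadruplet each, giving 21 subgroups
#' in total. Every subgroup contains codons of both wobble classes. ATG and
#' TGG belong to no subgroup (\code{NA}): as single-codon families ending in
#' G they admit no within-group wobble comparison.
#'
#' @return A data frame with one row per sense codon and columns
#'   \code{codon}, \code{aa}, \code{wobble_class}, \code{tunable},
#'   \code{subgroup}.
#' @examples
#' ct <- codon_table()
#' nrow(ct)                        # 61 sense codons
#' length(unique(stats::na.omit(ct$subgroup)))  # 21 subgroups
#' @export
codon_table <- function() {
  if (!is.null(.codonlife_env$codon_table)) {
    return(.codonlife_env$codon_table)
  }
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  aa <- unname(gc[codons])
  third <- substr(codons, 3, 3)
  wobble <- ifelse(third %in% c("G", "C"), "GC_ending", "AU_ending")
  tunable <- !(codons %in% c("ATG", "TGG"))
  subgroup <- ifelse(tunable, paste0(aa, "_", substr(codons, 1, 2)), NA)
  tab <- data.frame(
    codon = codons, aa = aa, wobble_class = wobble,
    tunable = tunable, subgroup = subgroup,
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$codon), ]
  rownames(tab) <- tab$codon
  stopifnot(nrow(tab) == 61L,
            length(unique(stats::na.omit(tab$subgroup))) == 21L)
  .codonlife_env$codon_table <- tab
  tab
}

.codonlife_env <- new.env(parent = emptyenv())

#' Names of the 81 composition features
#'
#' The composition feature tier comprises the 20 amino-acid percentages
#' (\code{aa_A} ... \code{aa_Y}) and the 61 sense-codon percentages
#' (\code{codon_AAA} ...), in that order.
#'
#' @return Character vector of length 81.
#' @export
composition_feature_names <- function() {
  c(paste0("aa_", AA_LETTERS), paste0("codon_", codon_table()$codon))
}

#' Translate a coding sequence
#'
#' Translates a CDS under the standard genetic code. The sequence is
#' normalised on input (uppercased, U converted to T). A terminal stop codon
#' is removed from the translation; an internal stop is an error.
#'
#' @param cds A single DNA string (A/C/G/T, case-insensitive, U accepted).
#' @return One-letter protein string, without the terminal stop.
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
#' @export
translate_cds <- function(cds) {
  cds <- normalize_dna(cds)
  n <- nchar(cds)
  if (n == 0L) stop("empty coding sequence", call. = FALSE)
  if (n %% 3L != 0L) {
    stop(sprintf("CDS length %d is not divisible by 3", n), call. = FALSE)
  }
  bad <- regexpr("[^ACGT]", cds)
  if (bad > 0L) {
    stop(sprintf("ambiguous or invalid base '%s' at position %d",
                 substr(cds, bad, bad), bad), call. = FALSE)
  }
  codons <- codon_split(cds)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stops <- which(aa == "*")
  n_codon <- length(codons)
  internal <- stops[stops < n_codon]
  if (length(internal) > 0L) {
    stop(sprintf("internal stop codon at codon %d", internal[1L]),
         call. = FALSE)
  }
  if (length(stops) > 0L) aa <- aa[-n_codon]
  paste(aa, collapse = "")
}

# split a CDS into its codon triplets
codon_split <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

# uppercase, RNA -> DNA
normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}
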