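# Translation-preserving synonymous gene design at target G-/C-ending codon
# percentages, and the independent audit of designed variants.

#' Design a synonymous variant at a target GC3
#'
#' Recodes a protein (or the translation of a CDS) so that a chosen
#' percentage of its wobble-tunable codons end in G or C, leaving the
#' amino-acid sequence untouched. Met and Trp are fixed to ATG/TGG and
#' excluded from the target accounting. The number of G/C-ending codons is
#' \code{round(target/100 * n_tunable)} (half away from zero); their
#' positions are drawn uniformly at random under \code{seed}, or spaced
#' evenly with \code{even = TRUE}. Within the required wobble class the
#' codon for each residue is the alphabetically first by default, or the
#' highest-weight codon of that class under \code{usage_table}.
#'
#' @param x Protein string, or a CDS (auto-detected by alphabet and
#'   translated first).
#' @param target_gc3 Target percentage in [0, 100] of G/C-ending codons
#'   among tunable codons.
#' @param seed Integer seed for position selection.
#' @param even Place G/C-ending codons evenly along the sequence instead of
#'   randomly.
#' @param usage_table Optional named codon-weight vector used to pick the
#'   codon within a wobble class.
#' @param stop_codon Stop codon appended to the CDS (excluded from GC3).
#' @return List of class \code{designed_variant}: \code{cds},
#'   \code{protein}, \code{target_gc3}, \code{achieved_gc3_tunable},
#'   \code{achieved_gc3_all}, \code{overall_gc}, \code{gc_positions}
#'   (indices of tunable codons set to the G/C class), \code{seed},
#'   \code{placement}.
#' @examples
#' v <- design_variant("MKFW", 100)
#' v$cds                      # "ATGAAGTTCTGGTAA"
#' v$achieved_gc3_tunable     # 100
#' @export
design_variant <- function(x, target_gc3, seed = 1L, even = FALSE,
                           usage_table = NULL, stop_codon = "TAA") {
  if (target_gc3 < 0 || target_gc3 > 100) stop("target_gc3 must be in [0, 100]")
  if (!stop_codon %in% c("TAA", "TAG", "TGA")) stop("invalid stop codon")
  x <- toupper(x)
  protein <- if (grepl("^[ACGTU]+$", x) && nchar(x) %% 3 == 0 &&
                 nchar(x) >= 6) translate_cds(x) else x
  res <- strsplit(protein, "")[[1L]]
  if (length(res) == 0L) stop("empty protein")
  if (!all(res %in% AA_LETTERS)) {
    stop("invalid residue: ", paste(setdiff(res, AA_LETTERS), collapse = ", "))
  }
  ct <- codon_table()
  tunable_idx <- which(!(res %in% c("M", "W")))
  n_tun <- length(tunable_idx)
  n_gc <- if (n_tun == 0L) 0L else {
    as.integer(round_half_away(target_gc3 / 100 * n_tun))
  }
  gc_pos <- integer(0)
  if (n_gc > 0L) {
    gc_pos <- if (even) {
      tunable_idx[unique(as.integer(round(seq(1L, n_tun, length.out = n_gc))))]
    } else {
      with_seed(seed, sort(sample(tunable_idx, n_gc)))
    }
  }
  pick <- function(aa, class) {
    cands <- ct$codon[ct$aa == aa & ct$wobble_class == class]
    if (!is.null(usage_table)) {
      w <- usage_table[cands]
      if (!all(is.na(w))) return(cands[which.max(ifelse(is.na(w), -Inf, w))])
    }
    cands[1L]  # codons are sorted alphabetically in the table
  }
  codons <- vapply(seq_along(res), function(i) {
    aa <- res[i]
    if (aa == "M") return("ATG")
    if (aa == "W") return("TGG")
    pick(aa, if (i %in% gc_pos) "GC_ending" else "AU_ending")
  }, character(1))
  cds <- paste0(paste(codons, collapse = ""), stop_codon)
  structure(list(
    cds = cds,
    protein = protein,
    target_gc3 = target_gc3,
    achieved_gc3_tunable = as.numeric(gc3_fraction(cds, "tunable_only")),
    achieved_gc3_all = as.numeric(gc3_fraction(cds, "all_codons")),
    overall_gc = 100 * mean(strsplit(sub("...$", "", cds), "")[[1L]] %in%
                              c("G", "C")),
    gc_positions = gc_pos,
    n_tunable = n_tun,
    seed = seed,
    placement = if (even) "even" else "random"
  ), class = "designed_variant")
}

#' @export
print.designed_variant <- function(x, ...) {
  cat(sprintf(
    "Designed variant: %d aa | target GC3 %g%% | achieved %.1f%% (tunable), %.1f%% (all)\n",
    nchar(x$protein), x$target_gc3, x$achieved_gc3_tunable,
    x$achieved_gc3_all))
  invisible(x)
}

#' Design a family of variants across GC3 targets
#'
#' Convenience wrapper producing one \code{\link{design_variant}} per target
#' (default the five construct levels 0/25/50/75/100\%), all encoding the
#' same protein.
#'
#' @inheritParams design_variant
#' @param targets Vector of GC3 targets.
#' @return Named list of \code{designed_variant} objects.
#' @export
design_variant_family <- function(x, targets = c(0, 25, 50, 75, 100),
                                  seed = 1L, even = FALSE,
                                  usage_table = NULL, stop_codon = "TAA") {
  out <- lapply(targets, function(t) {
    design_variant(x, t, seed = seed, even = even,
                   usage_table = usage_table, stop_codon = stop_codon)
  })
  stats::setNames(out, paste0("gc3_", targets))
}

#' Audit a designed variant
#'
#' Independently verifies a designer output: re-translates the CDS codon by
#' codon and compares with the requested protein, and recomputes both GC3
#' scopes and overall GC content by a direct per-codon scan (separate from
#' \code{\link{gc3_fraction}}). A translation mismatch is a hard failure.
#'
#' @param variant A \code{designed_variant} (or a list with \code{cds} and
#'   \code{target_gc3}).
#' @param protein The protein the variant must encode.
#' @return List with \code{identity} (TRUE), \code{gc3_tunable},
#'   \code{gc3_all}, \code{overall_gc}, \code{delta_vs_target},
#'   \code{quantum} (the one-codon granularity 100 / n_tunable).
#' @export
audit_variant <- function(variant, protein) {
  cds <- normalize_dna(variant$cds)
  codons <- codon_split(cds)
  gcode <- Biostrings::GENETIC_CODE
  aa <- character(0)
  n_all <- 0L; gc_all <- 0L; n_tun <- 0L; gc_tun <- 0L; gc_nt <- 0L; nt <- 0L
  for (i in seq_along(codons)) {
    cd <- codons[i]
    a <- gcode[[cd]]
    if (a == "*") {
      if (i != length(codons)) stop("audit: internal stop at codon ", i)
      break
    }
    aa <- c(aa, a)
    third <- substr(cd, 3, 3)
    n_all <- n_all + 1L
    if (third == "G" || third == "C") gc_all <- gc_all + 1L
    if (!(cd %in% c("ATG", "TGG"))) {
      n_tun <- n_tun + 1L
      if (third == "G" || third == "C") gc_tun <- gc_tun + 1L
    }
    for (b in strsplit(cd, "")[[1L]]) {
      nt <- nt + 1L
      if (b == "G" || b == "C") gc_nt <- gc_nt + 1L
    }
  }
  translated <- paste(aa, collapse = "")
  if (!identical(translated, toupper(protein))) {
    stop("audit: translation mismatch (designer bug): got '",
         substr(translated, 1, 30), "...', expected '",
         substr(toupper(protein), 1, 30), "...'")
  }
  gc3_tun <- if (n_tun == 0L) NA_real_ else 100 * gc_tun / n_tun
  quantum <- if (n_tun == 0L) NA_real_ else 100 / n_tun
  list(identity = TRUE,
       gc3_tunable = gc3_tun,
       gc3_all = 100 * gc_all / n_all,
       overall_gc = 100 * gc_nt / nt,
       delta_vs_target = gc3_tun - variant$target_gc3,
       quantum = quantum)
}
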