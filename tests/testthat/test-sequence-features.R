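test_that("composition percentages match hand counts and sum to 100", {
  v <- composition_vector("ATGAAATAA")
  expect_equal(unname(v["aa_M"]), 50)
  expect_equal(unname(v["aa_K"]), 50)
  expect_equal(unname(v["codon_ATG"]), 50)
  expect_equal(unname(v["codon_AAA"]), 50)
  expect_equal(sum(v[startsWith(names(v), "aa_")]), 100)
  expect_equal(sum(v[startsWith(names(v), "codon_")]), 100)

  # 2/3 alanine by hand count
  v2 <- composition_vector("ATGGCTGCCTAA")
  expect_equal(unname(v2["aa_A"]), 200 / 3)
  expect_equal(unname(v2["aa_M"]), 100 / 3)
  expect_equal(unname(v2[c("codon_ATG", "codon_GCT", "codon_GCC")]),
               rep(100 / 3, 3))

  # stop-free poly-Lys string
  v3 <- composition_vector(strrep("AAA", 10))
  expect_equal(unname(v3["aa_K"]), 100)
  expect_equal(unname(v3["codon_AAA"]), 100)

  # block sums hold across a generated cohort, values within [0, 100]
  fm <- assemble_feature_matrix(small_cohort()$records)
  expect_true(all(fm >= 0 & fm <= 100))
  aa_cols <- startsWith(colnames(fm), "aa_")
  expect_equal(unname(rowSums(fm[, aa_cols])), rep(100, nrow(fm)))
  expect_equal(unname(rowSums(fm[, !aa_cols])), rep(100, nrow(fm)))
})

test_that("amino-acid composition is invariant under synonymous recoding", {
  prot <- random_protein(60, seed = 2)
  fam <- design_variant_family(prot, c(0, 50, 100), seed = 9)
  comps <- lapply(fam, function(v) composition_vector(v$cds))
  aa_cols <- startsWith(names(comps[[1]]), "aa_")
  expect_equal(comps[[1]][aa_cols], comps[[2]][aa_cols])
  expect_equal(comps[[1]][aa_cols], comps[[3]][aa_cols])
  expect_false(isTRUE(all.equal(comps[[1]][!aa_cols], comps[[3]][!aa_cols])))
})

test_that("GC3 matches an independent per-codon scan in both scopes", {
  expect_equal(as.numeric(gc3_fraction("AAGAAGAAG")), 100)
  expect_equal(as.numeric(gc3_fraction("AAGAAGAAG", "tunable_only")), 100)
  expect_equal(as.numeric(gc3_fraction("ATGTGGTAA")), 100)
  expect_true(is.na(gc3_fraction("ATGTGGTAA", "tunable_only")))
  expect_true(attr(gc3_fraction("ATGTGGTAA", "tunable_only"), "undefined"))
  expect_equal(as.numeric(gc3_fraction("AAATTT")), 0)
  expect_equal(as.numeric(gc3_fraction("AAATTT", "tunable_only")), 0)

  scan_gc3 <- function(cds, tunable_only) {
    cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    if (Biostrings::GENETIC_CODE[cods[length(cods)]] == "*") {
      cods <- cods[-length(cods)]
    }
    if (tunable_only) cods <- cods[!cods %in% c("ATG", "TGG")]
    100 * mean(substr(cods, 3, 3) %in% c("G", "C"))
  }
  for (cds in small_cohort(50, seed = 8)$records$cds[1:20]) {
    expect_equal(as.numeric(gc3_fraction(cds)), scan_gc3(cds, FALSE))
    expect_equal(as.numeric(gc3_fraction(cds, "tunable_only")),
                 scan_gc3(cds, TRUE))
  }
})

test_that("physicochemical indices obey their defining identities", {
  pa <- physchem(strrep("A", 25))
  expect_equal(pa$aliphatic_index, 100)          # pure Ala: mole% A = 100
  expect_equal(pa$gravy, 1.8)                    # hydropathy of Ala
  expect_equal(pa$length, 25)
  expect_equal(physchem("MKLV")$nterm_residue, "K")  # position-2 rule
  # acidic proteins sit below pH 7, basic above
  expect_lt(physchem(strrep("D", 20))$isoelectric_point, 7)
  expect_gt(physchem(strrep("K", 20))$isoelectric_point, 7)
  # the reported pI is the charge root of the titration model itself
  expect_error(physchem("MKX"), "invalid residue")
  # average molecular weight agrees with seqinr's residue tables
  skip_if_not_installed("seqinr")
  for (p in small_cohort(20, seed = 5)$records$protein[1:5]) {
    expect_equal(physchem(p)$molecular_weight,
                 seqinr::pmw(strsplit(p, "")[[1]]), tolerance = 1e-3)
  }
})

test_that("stratified composition respects structure classes", {
  v <- stratified_composition("ATGAAATAA", "HC")
  expect_equal(unname(v["H_aa_M"]), 100)
  expect_equal(unname(v["C_aa_K"]), 100)
  expect_equal(unname(v["H_aa_K"]), 0)

  # all-H structure reproduces the plain composition in the H block
  cds <- small_cohort(20, seed = 5)$records$cds[1]
  n <- nchar(cds) / 3 - 1
  v2 <- stratified_composition(cds, strrep("H", n))
  comp <- composition_vector(cds)
  expect_equal(unname(v2[paste0("H_", names(comp))]), unname(comp))
  expect_true(all(v2[startsWith(names(v2), "E_")] == 0))
  expect_setequal(attr(v2, "empty_classes"), c("E", "C"))

  # weighted re-aggregation over classes reproduces the composition
  set.seed(31)
  struct <- paste(sample(c("H", "E", "C"), n, replace = TRUE), collapse = "")
  v3 <- stratified_composition(cds, struct)
  w <- table(factor(strsplit(struct, "")[[1]], c("H", "E", "C"))) / n
  agg <- w[["H"]] * v3[paste0("H_", names(comp))] +
    w[["E"]] * v3[paste0("E_", names(comp))] +
    w[["C"]] * v3[paste0("C_", names(comp))]
  expect_equal(unname(agg), unname(comp))

  expect_error(stratified_composition("ATGAAATAA", "HCE"), "length")
  expect_error(stratified_composition("ATGAAATAA", "HX"), "H, E or C")
})

test_that("feature matrix tiers have the expected shape and filters", {
  coh <- small_cohort(60, seed = 12)
  coh <- generate_structures(coh)
  coh <- generate_annotations(coh, prevalences = 1:20, seed = 4)
  fm_comp <- assemble_feature_matrix(coh$records)
  expect_equal(ncol(fm_comp), 81L)
  expect_true(all(attr(fm_comp, "tiers") == "composition"))

  fm_seq <- assemble_feature_matrix(coh$records, tier = "sequence",
                                    structures = coh$structures)
  expect_equal(ncol(fm_seq), 81L + 243L + 5L + 20L)
  expect_true("length" %in% colnames(fm_seq))

  fm_all <- assemble_feature_matrix(coh$records, tier = "all",
                                    structures = coh$structures,
                                    annotations = coh$annotations)
  ann <- colnames(fm_all)[attr(fm_all, "tiers") == "annotation"]
  prev <- colSums(coh$annotations[, sub("^ann_", "", ann), drop = FALSE])
  expect_true(all(prev >= 10))
  expect_equal(length(ann), 11L)  # prevalences 10..20 survive

  # response-leak rule: no length column when predicting length
  fm_len <- assemble_feature_matrix(coh$records, tier = "sequence",
                                    structures = coh$structures,
                                    response_kind = "length")
  expect_false("length" %in% colnames(fm_len))
  expect_equal(attr(fm_len, "dropped"), "length")

  expect_error(assemble_feature_matrix(coh$records, tier = "sequence"),
               "requires secondary-structure")
})
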