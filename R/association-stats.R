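# Feature-response correlation screens across datasets, synonymous-subgroup
# wobble summaries, and the N-end-rule / degron-motif association checks.

#' Pearson correlation with degenerate-input handling
#'
#' Product-moment correlation of two equal-length vectors. Returns \code{NA}
#' with attribute \code{undefined = TRUE} when either vector is constant
#' (zero variance), rather than erroring.
#'
#' @param x,y Numeric vectors of equal length >= 3 with finite values.
#' @return Correlation in [-1, 1], or flagged \code{NA}.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  stats::cor(x, y)
}

#' Correlate every feature with a response across datasets
#'
#' For each response dataset and each feature column, computes Pearson's r
#' over the proteins shared by the feature matrix and that dataset, then
#' aggregates across datasets with an unweighted mean and the s.e.m. over
#' datasets. Datasets sharing fewer than 3 proteins with the feature matrix
#' are skipped with a warning. Optionally the response is log-transformed
#' first.
#'
#' @param features Numeric matrix (proteins x features) with row names.
#' @param responses A named numeric vector (one dataset) or a named list of
#'   such vectors; names of each vector are protein ids.
#' @param log_response Apply \code{log()} to responses before correlating
#'   (requires positive values). Default FALSE: values are used as provided.
#' @return Object of class \code{correlation_profile}: list with \code{r}
#'   (features x datasets matrix), \code{mean_r}, \code{sem_r},
#'   \code{n_datasets}.
#' @export
correlation_profile <- function(features, responses, log_response = FALSE) {
  if (!is.list(responses)) responses <- list(dataset1 = responses)
  if (is.null(names(responses))) {
    names(responses) <- paste0("dataset", seq_along(responses))
  }
  rmat <- matrix(NA_real_, nrow = ncol(features), ncol = length(responses),
                 dimnames = list(colnames(features), names(responses)))
  used <- logical(length(responses))
  for (j in seq_along(responses)) {
    y <- responses[[j]]
    shared <- intersect(rownames(features), names(y))
    if (length(shared) < 3L) {
      warning("dataset '", names(responses)[j],
              "' shares fewer than 3 proteins; skipped")
      next
    }
    yv <- y[shared]
    if (log_response) {
      if (any(yv <= 0)) stop("log transform requires positive responses")
      yv <- log(yv)
    }
    X <- features[shared, , drop = FALSE]
    sds <- apply(X, 2L, stats::sd)
    ok <- sds > 0 & stats::sd(yv) > 0
    rmat[ok, j] <- suppressWarnings(as.numeric(stats::cor(X[, ok, drop = FALSE], yv)))
    used[j] <- TRUE
  }
  rmat <- rmat[, used, drop = FALSE]
  if (ncol(rmat) == 0L) stop("no usable dataset")
  mean_r <- rowMeans(rmat, na.rm = TRUE)
  nd <- ncol(rmat)
  sem_r <- apply(rmat, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) 0 else stats::sd(v) / sqrt(length(v))
  })
  structure(list(r = rmat, mean_r = mean_r, sem_r = sem_r,
                 n_datasets = nd,
                 single_dataset = nd == 1L),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat("Correlation profile:", nrow(x$r), "features x",
      x$n_datasets, "dataset(s)\n")
  top <- utils::head(order(-abs(x$mean_r)), 5L)
  cat("Strongest mean r:\n")
  print(round(x$mean_r[top], 3))
  invisible(x)
}

#' Wobble-class summary over the 21 synonymous subgroups
#'
#' For each synonymous subgroup (codons sharing amino acid and first two
#' nucleotides; the six-fold Leu/Arg/Ser each contribute a pair and a
#' quadruplet), averages the per-dataset correlation values of its
#' G/C-ending and of its A/U-ending members and tests the two classes
#' against each other with a two-sample Student's t-test across datasets.
#'
#' @param profile A \code{\link{correlation_profile}} whose features include
#'   all 61 \code{codon_*} columns.
#' @param var_equal Use the equal-variance Student's t-test (default TRUE).
#' @return Object of class \code{wobble_summary}: a data frame with one row
#'   per subgroup (columns \code{subgroup}, \code{aa}, \code{gc_mean_r},
#'   \code{au_mean_r}, \code{difference}, \code{statistic}, \code{p_value})
#'   plus attribute \code{n_gc_gt_au}, the number of subgroups where the
#'   G/C-ending mean exceeds the A/U-ending mean.
#' @export
wobble_group_summary <- function(profile, var_equal = TRUE) {
  stopifnot(inherits(profile, "correlation_profile"))
  ct <- codon_table()
  need <- paste0("codon_", ct$codon)
  if (!all(need %in% rownames(profile$r))) {
    stop("profile must contain all 61 sense-codon features")
  }
  groups <- unique(stats::na.omit(ct$subgroup))
  rows <- lapply(groups, function(g) {
    members <- ct[!is.na(ct$subgroup) & ct$subgroup == g, ]
    gc_cod <- paste0("codon_", members$codon[members$wobble_class == "GC_ending"])
    au_cod <- paste0("codon_", members$codon[members$wobble_class == "AU_ending"])
    if (length(gc_cod) == 0L || length(au_cod) == 0L) {
      stop("subgroup '", g, "' has a single wobble class")
    }
    # per-dataset class means, then test across datasets
    gc_by_ds <- colMeans(profile$r[gc_cod, , drop = FALSE], na.rm = TRUE)
    au_by_ds <- colMeans(profile$r[au_cod, , drop = FALSE], na.rm = TRUE)
    if (profile$n_datasets >= 2L &&
        (stats::sd(gc_by_ds) > 0 || stats::sd(au_by_ds) > 0)) {
      tt <- stats::t.test(gc_by_ds, au_by_ds, var.equal = var_equal)
      stat <- unname(tt$statistic); p <- tt$p.value
    } else {
      stat <- NA_real_; p <- NA_real_
    }
    data.frame(subgroup = g, aa = members$aa[1L],
               gc_mean_r = mean(gc_by_ds), au_mean_r = mean(au_by_ds),
               difference = mean(gc_by_ds) - mean(au_by_ds),
               statistic = stat, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aa, out$subgroup), ]
  rownames(out) <- NULL
  stopifnot(nrow(out) == 21L)
  attr(out, "n_gc_gt_au") <- sum(out$difference > 0)
  class(out) <- c("wobble_summary", "data.frame")
  out
}

#' @export
print.wobble_summary <- function(x, ...) {
  cat("Wobble summary: ", attr(x, "n_gc_gt_au"),
      "/21 subgroups with GC-ending mean r > AU-ending mean r\n", sep = "")
  NextMethod()
}

#' N-end-rule association
#'
#' Maps each protein's N-terminal residue (position 2, following the
#' initiator Met) to a stability value from a user-supplied rule table and
#' reports the squared Pearson correlation with the response. The rule table
#' is input data: published N-end-rule stability scales vary.
#'
#' @param records A \code{\link{coding_records}} data frame.
#' @param response Named numeric vector of responses (names = ids).
#' @param rule_map Named numeric vector: residue -> stability value, covering
#'   every observed position-2 residue.
#' @return List with \code{r2}, \code{r}, \code{n}.
#' @export
nend_rule_association <- function(records, response, rule_map) {
  nterm <- vapply(records$protein, function(p) {
    if (nchar(p) >= 2L) substr(p, 2L, 2L) else substr(p, 1L, 1L)
  }, character(1), USE.NAMES = FALSE)
  missing <- setdiff(unique(nterm), names(rule_map))
  if (length(missing)) {
    stop("rule_map lacks residues: ", paste(missing, collapse = ", "))
  }
  shared <- intersect(records$id, names(response))
  idx <- match(shared, records$id)
  x <- unname(rule_map[nterm[idx]])
  y <- response[shared]
  r <- pearson_r(x, y)
  list(r2 = unname(r^2), r = unname(r), n = length(shared))
}

#' Degron-motif association screen
#'
#' For each motif (a plain residue string or simple regular expression over
#' the one-letter alphabet), scores presence/absence in every protein and
#' reports the point-biserial correlation with the response, the raw p-value
#' and Benjamini-Hochberg adjusted p-value. Motifs present in every protein
#' or in none are flagged undefined (constant regressor).
#'
#' @param records A \code{\link{coding_records}} data frame.
#' @param response Named numeric vector (names = ids).
#' @param motifs Character vector of motifs.
#' @return Data frame with columns \code{motif}, \code{n_carriers},
#'   \code{r}, \code{p_value}, \code{p_adjusted}, \code{undefined}.
#' @export
motif_association <- function(records, response, motifs) {
  if (any(!nzchar(motifs))) stop("empty motif")
  shared <- intersect(records$id, names(response))
  prot <- records$protein[match(shared, records$id)]
  y <- response[shared]
  rows <- lapply(motifs, function(m) {
    present <- as.integer(grepl(m, prot))
    nc <- sum(present)
    if (nc == 0L || nc == length(present)) {
      return(data.frame(motif = m, n_carriers = nc, r = NA_real_,
                        p_value = NA_real_, undefined = TRUE,
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(present, y)
    data.frame(motif = m, n_carriers = nc, r = unname(ct$estimate),
               p_value = ct$p.value, undefined = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("motif", "n_carriers", "r", "p_value", "p_adjusted", "undefined")]
}

#' Pairwise r-squared between response datasets
#'
#' Squared Pearson correlation for every pair of datasets over their shared
#' protein ids, quantifying how strongly different homeostasis parameters
#' (or replicate measurements) agree. Pairs sharing fewer than 3 ids get
#' \code{NA}.
#'
#' @param responses Named list of named numeric vectors.
#' @return Symmetric matrix of r^2 values with unit diagonal.
#' @export
cross_parameter_matrix <- function(responses) {
  if (length(responses) < 2L) stop("need at least 2 datasets")
  k <- length(responses)
  nm <- names(responses)
  out <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(out) <- 1
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      shared <- intersect(names(responses[[i]]), names(responses[[j]]))
      if (length(shared) >= 3L) {
        r <- pearson_r(responses[[i]][shared], responses[[j]][shared])
        out[i, j] <- out[j, i] <- unname(r^2)
      }
    }
  }
  out
}
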