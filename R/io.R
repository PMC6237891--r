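# Format-faithful readers and writers: FASTA for sequences, TSV for tabular
# artifacts (features, responses, structures, annotations, decay curves),
# JSON for nested reports.

#' Read coding sequences (or proteins) from FASTA
#'
#' Ids are taken up to the first whitespace; sequences are uppercased and
#' U is converted to T for DNA. The sequence type is auto-detected from the
#' alphabet unless forced.
#'
#' @param path FASTA file.
#' @param type \code{"auto"}, \code{"dna"} or \code{"protein"}.
#' @param as_records For DNA: validate as ORFs and return
#'   \code{\link{coding_records}} (default TRUE).
#' @return \code{coding_records}, or a named character vector for proteins /
#'   \code{as_records = FALSE}.
#' @export
read_fasta <- function(path, type = c("auto", "dna", "protein"),
                       as_records = TRUE) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(set))
  if (type == "auto") {
    type <- if (all(grepl("^[ACGTUN]+$", seqs))) "dna" else "protein"
  }
  if (type == "dna") {
    seqs <- vapply(seqs, normalize_dna, character(1), USE.NAMES = FALSE)
    if (as_records) return(coding_records(ids, seqs))
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param x \code{coding_records}, or a named character vector of sequences.
#' @param path Output file.
#' @param what For records: \code{"cds"} or \code{"protein"}.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(x, path, what = c("cds", "protein")) {
  what <- match.arg(what)
  seqs <- if (inherits(x, "coding_records")) {
    stats::setNames(x[[what]], x$id)
  } else x
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write and read response tables
#'
#' Long TSV with columns \code{id}, \code{dataset}, \code{value}.
#'
#' @param responses Named list of named numeric vectors.
#' @param path TSV file.
#' @return \code{write_responses}: the path, invisibly;
#'   \code{read_responses}: a named list of named numeric vectors.
#' @export
write_responses <- function(responses, path) {
  rows <- do.call(rbind, lapply(names(responses), function(d) {
    y <- responses[[d]]
    data.frame(id = names(y), dataset = d, value = unname(y),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(format_num_df(rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "dataset", "value") %in% names(df)))
  lapply(split(df, df$dataset), function(d) {
    stats::setNames(d$value, d$id)
  })
}

# fixed float precision for lossless-at-precision TSV round trips
format_num_df <- function(df, digits = 10) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- formatC(df[[j]], digits = digits, format = "g")
    }
  }
  df
}

#' Write and read a tiered feature matrix as TSV
#'
#' Columns are written as \code{name[tier]} headers; the id column comes
#' first. Values round-trip losslessly at 10 significant digits.
#'
#' @param mat Feature matrix from \code{\link{assemble_feature_matrix}}.
#' @param path TSV file.
#' @return \code{write_feature_matrix}: the path; \code{read_feature_matrix}:
#'   the matrix with its \code{"tiers"} attribute restored.
#' @export
write_feature_matrix <- function(mat, path) {
  tiers <- attr(mat, "tiers")
  hdr <- if (is.null(tiers)) colnames(mat) else {
    paste0(colnames(mat), "[", tiers[colnames(mat)], "]")
  }
  df <- data.frame(id = rownames(mat), stringsAsFactors = FALSE)
  if (ncol(mat) > 0L) {
    df <- cbind(df, as.data.frame(formatC(mat, digits = 10, format = "g"),
                                  stringsAsFactors = FALSE),
                stringsAsFactors = FALSE)
  }
  names(df) <- c("id", hdr)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  ids <- df$id
  df$id <- NULL
  hdr <- names(df)
  has_tier <- grepl("\\[[a-z]+\\]$", hdr)
  tiers <- ifelse(has_tier, sub("^.*\\[([a-z]+)\\]$", "\\1", hdr), "unknown")
  nm <- sub("\\[[a-z]+\\]$", "", hdr)
  mat <- as.matrix(df)
  dimnames(mat) <- list(ids, nm)
  storage.mode(mat) <- "double"
  attr(mat, "tiers") <- stats::setNames(tiers, nm)
  mat
}

#' Write and read secondary-structure strings
#'
#' TSV with columns \code{id}, \code{structure} (H/E/C strings).
#'
#' @param structures Named character vector.
#' @param path TSV file.
#' @return Path (write) or named character vector (read).
#' @export
write_structures <- function(structures, path) {
  utils::write.table(
    data.frame(id = names(structures), structure = unname(structures)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_structures
#' @export
read_structures <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$structure, df$id)
}

#' Write and read an annotation matrix
#'
#' TSV with an \code{id} column followed by one 0/1 column per term.
#'
#' @param annotations Binary matrix (proteins x terms).
#' @param path TSV file.
#' @return Path (write) or matrix (read).
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(id = rownames(annotations), annotations,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  ids <- df$id
  df$id <- NULL
  mat <- as.matrix(df)
  rownames(mat) <- ids
  mat
}

#' Write and read decay curves
#'
#' TSV with columns \code{construct}, \code{time_h}, \code{intensity} and
#' optionally \code{sem}, \code{n}.
#'
#' @param curves A \code{decay_curve} or list of them.
#' @param path TSV file.
#' @return Path (write) or named list of \code{decay_curve}s (read).
#' @export
write_decay_curves <- function(curves, path) {
  if (inherits(curves, "decay_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(construct = attr(cv, "construct") %||% "construct1",
               time_h = cv$time_h, intensity = cv$intensity,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(format_num_df(rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_decay_curves
#' @export
read_decay_curves <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("construct", "time_h", "intensity") %in% names(df)))
  lapply(split(df, df$construct), function(d) {
    d <- d[order(d$time_h), ]
    decay_curve(d$time_h, d$intensity, construct = d$construct[1L])
  })
}

#' Write a model report as JSON
#'
#' Serialises the test metrics, chosen hyperparameters and scaled
#' importances of a fitted \code{\link{homeostasis_model}}.
#'
#' @param model A \code{homeostasis_model}.
#' @param path JSON file.
#' @return Invisibly, the path.
#' @export
write_model_report <- function(model, path) {
  rep <- list(
    learner = model$learner,
    tier = model$tier,
    seed = model$spec$seed,
    rmse_cv = model$report$rmse_cv,
    rmse_test = model$report$rmse_test,
    r_test = model$report$r_test,
    r2_test = model$report$r2_test,
    percent_of_max = model$report$percent_of_max,
    hyperparameters = model$tuned$hyper[
      setdiff(names(model$tuned$hyper), "lambda_seq")],
    importances_scaled = if (!is.null(model$importances)) {
      as.list(model$importances$scaled)
    }
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
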