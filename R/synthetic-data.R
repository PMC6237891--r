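# Seeded synthetic cohorts: coding sequences with heterogeneous codon usage,
# planted linear responses at a target explainable r^2, replicate datasets at
# a target inter-study correlation, secondary-structure strings, annotation
# terms at fixed prevalence, and pulse-chase decay curves.

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  }
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = env))
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration of a synthetic cohort
#'
#' Collects the generator knobs: cohort size, protein length range, the
#' concentration parameter controlling between-protein codon-usage
#' heterogeneity (smaller values give more extreme per-protein usage, hence
#' larger GC3 variance), the planted linear effect map over composition
#' features, the explainable variance of the planted response, the target
#' correlation between replicate response datasets, and the master seed.
#'
#' Defaults describe the study conditions exercised throughout the package:
#' cohorts of 2000 proteins of 100-500 residues, a wobble-class effect
#' (G/C-ending codon percentages weighted positively, A/U-ending negatively),
#' half of the response variance explainable, and replicate datasets
#' correlated at r = 0.69, the typical agreement between independent
#' protein-lifetime studies of the same tissue.
#'
#' @param n_proteins Number of proteins (>= 2).
#' @param length_range Protein length range in residues, min >= 10.
#' @param codon_usage_concentration Positive Dirichlet concentration for
#'   per-protein within-family codon usage.
#' @param effect_map Named numeric vector of weights over composition
#'   feature names (see \code{\link{composition_feature_names}}).
#' @param target_r2 Fraction in [0,1]: population r^2 between the noiseless
#'   planted signal and the response.
#' @param replicate_r Fraction in [0,1]: target Pearson r between a response
#'   dataset and its replicate.
#' @param seed Integer master seed.
#' @return A list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_proteins = 2000L,
                             length_range = c(100L, 500L),
                             codon_usage_concentration = 5,
                             effect_map = wobble_effect_map(),
                             target_r2 = 0.5,
                             replicate_r = 0.69,
                             seed = 1L) {
  if (n_proteins < 2L) stop("n_proteins must be >= 2")
  if (length(length_range) != 2L || length_range[1L] < 10L ||
      length_range[2L] < length_range[1L]) {
    stop("length_range must be (min, max) with min >= 10")
  }
  if (codon_usage_concentration <= 0) {
    stop("codon_usage_concentration must be positive")
  }
  if (target_r2 < 0 || target_r2 > 1) stop("target_r2 must be in [0, 1]")
  if (replicate_r < 0 || replicate_r > 1) stop("replicate_r must be in [0, 1]")
  unknown <- setdiff(names(effect_map), composition_feature_names())
  if (length(unknown)) {
    stop("unknown feature names in effect_map: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(
    n_proteins = as.integer(n_proteins),
    length_range = as.integer(length_range),
    codon_usage_concentration = codon_usage_concentration,
    effect_map = effect_map,
    target_r2 = target_r2,
    replicate_r = replicate_r,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Wobble-class effect map
#'
#' A planted effect over the 59 wobble-tunable codon percentage features:
#' G/C-ending codons receive weight \code{+delta/2}, A/U-ending codons
#' \code{-delta/2}, emulating the positive association of G/C wobble
#' nucleotides with protein lifetime.
#'
#' @param delta Total contrast between the two wobble classes.
#' @return Named numeric vector over \code{codon_*} feature names.
#' @export
wobble_effect_map <- function(delta = 1) {
  ct <- codon_table()
  tun <- ct[ct$tunable, ]
  w <- ifelse(tun$wobble_class == "GC_ending", delta / 2, -delta / 2)
  stats::setNames(w, paste0("codon_", tun$codon))
}

# Dirichlet draw via gamma variates
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x <- rep(1, length(alpha))
  x / sum(x)
}

#' Generate a synthetic CDS cohort
#'
#' Draws \code{n_proteins} coding sequences. Each protein has a length
#' sampled uniformly from \code{length_range} and its own amino-acid
#' frequency vector (Dirichlet around the uniform composition), producing
#' the between-protein composition spread real proteomes show. Within each
#' synonymous family, per-protein codon usage is drawn from a Dirichlet
#' distribution with concentration \code{codon_usage_concentration} around
#' uniform usage (or around \code{usage_table} weights if supplied), so that
#' wobble-position content varies across proteins. Every CDS is a complete
#' ORF: ATG start, no internal stop, terminal TAA.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param usage_table Optional named numeric vector of global codon weights
#'   (names are codons); defaults to uniform usage within each family.
#' @return A list of class \code{synthetic_cohort} with elements
#'   \code{records} (\code{\link{coding_records}}), \code{responses} (empty
#'   named list), \code{structures}, \code{annotations}, \code{truth},
#'   \code{config}.
#' @export
generate_cds_cohort <- function(config, usage_table = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  ct <- codon_table()
  fam <- split(ct$codon, ct$aa)
  base_usage <- lapply(fam, function(cs) {
    if (is.null(usage_table)) {
      stats::setNames(rep(1 / length(cs), length(cs)), cs)
    } else {
      w <- usage_table[cs]
      w[is.na(w)] <- 0
      if (sum(w) == 0) w[] <- 1
      stats::setNames(w / sum(w), cs)
    }
  })
  conc <- config$codon_usage_concentration
  cds <- with_seed(config$seed, {
    lens <- sample(seq(config$length_range[1L], config$length_range[2L]),
                   config$n_proteins, replace = TRUE)
    vapply(seq_len(config$n_proteins), function(i) {
      aa_freq <- rdirichlet1(rep(1.5, 20L))
      residues <- c("M", sample(AA_LETTERS, lens[i] - 1L,
                                replace = TRUE, prob = aa_freq))
      usage <- lapply(base_usage, function(u) {
        stats::setNames(rdirichlet1(conc * length(u) * u), names(u))
      })
      codons <- vapply(residues, function(a) {
        u <- usage[[a]]
        if (length(u) == 1L) names(u) else sample(names(u), 1L, prob = u)
      }, character(1))
      paste0(paste(codons, collapse = ""), "TAA")
    }, character(1))
  })
  ids <- sprintf("prot%04d", seq_len(config$n_proteins))
  structure(list(
    records = coding_records(ids, cds),
    responses = list(),
    structures = NULL,
    annotations = NULL,
    truth = list(),
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$records), "coding records\n")
  if (length(x$responses)) {
    cat("  responses:", paste(names(x$responses), collapse = ", "), "\n")
  }
  if (!is.null(x$structures)) cat("  secondary-structure strings present\n")
  if (!is.null(x$annotations)) {
    cat("  annotations:", ncol(x$annotations), "terms\n")
  }
  invisible(x)
}

# composition features of a cohort, cached on the object's environment
cohort_composition <- function(cohort) {
  m <- t(vapply(cohort$records$cds, composition_vector,
                numeric(81L), USE.NAMES = FALSE))
  dimnames(m) <- list(cohort$records$id, composition_feature_names())
  m
}

#' Plant a linear response on a cohort
#'
#' Adds a response dataset \code{y = X w + e}: a linear combination of
#' composition features (weights from \code{config$effect_map}) plus
#' Gaussian noise calibrated so the population r^2 between the noiseless
#' signal and the response equals \code{config$target_r2}. At
#' \code{target_r2 = 1} the response is exactly the linear combination; at
#' \code{target_r2 = 0} it is pure noise with the signal's spread.
#'
#' When \code{replicate_of} names an existing dataset, the new dataset is
#' instead a replicate: a mixture \eqn{\rho z + \sqrt{1-\rho^2}\,\eta} of the
#' standardised original and fresh noise, whose expected Pearson correlation
#' with the original is \code{config$replicate_r}, rescaled to the
#' original's mean and spread. This emulates independent studies measuring
#' the same quantity with finite reproducibility.
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param config The cohort's \code{\link{synthetic_config}} (or a variant).
#' @param dataset_name Name under which the response is stored.
#' @param replicate_of Optional name of an existing dataset to replicate.
#' @return The cohort with \code{responses[[dataset_name]]} added and the
#'   generating truth recorded in \code{truth[[dataset_name]]}.
#' @export
plant_response <- function(cohort, config = cohort$config,
                           dataset_name = "lifetime",
                           replicate_of = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ids <- cohort$records$id
  seed <- config$seed + 7919L * (length(cohort$responses) + 1L)
  if (!is.null(replicate_of)) {
    y1 <- cohort$responses[[replicate_of]]
    if (is.null(y1)) stop("no dataset named '", replicate_of, "'")
    rho <- config$replicate_r
    y2 <- with_seed(seed, {
      z <- as.numeric(scale(y1))
      mix <- rho * z + sqrt(1 - rho^2) * stats::rnorm(length(z))
      mean(y1) + stats::sd(y1) * mix
    })
    cohort$responses[[dataset_name]] <- stats::setNames(y2, ids)
    cohort$truth[[dataset_name]] <- list(replicate_of = replicate_of,
                                         replicate_r = rho, seed = seed)
    return(cohort)
  }
  w <- config$effect_map
  unknown <- setdiff(names(w), composition_feature_names())
  if (length(unknown)) {
    stop("unknown feature names in effect_map: ",
         paste(unknown, collapse = ", "))
  }
  X <- cohort_composition(cohort)
  s <- as.numeric(X[, names(w), drop = FALSE] %*% w)
  vs <- stats::var(s)
  r2 <- config$target_r2
  y <- with_seed(seed, {
    if (r2 >= 1) {
      s
    } else if (r2 <= 0) {
      sd0 <- if (vs > 0) sqrt(vs) else 1
      mean(s) + stats::rnorm(length(s), sd = sd0)
    } else {
      noise_sd <- sqrt(vs * (1 - r2) / r2)
      s + stats::rnorm(length(s), sd = noise_sd)
    }
  })
  cohort$responses[[dataset_name]] <- stats::setNames(y, ids)
  cohort$truth[[dataset_name]] <- list(
    effect_map = w, signal = stats::setNames(s, ids),
    target_r2 = r2,
    noise_sd = if (r2 >= 1) 0 else if (r2 <= 0) ifelse(vs > 0, sqrt(vs), 1)
               else sqrt(vs * (1 - r2) / r2),
    seed = seed
  )
  cohort
}

#' Generate secondary-structure strings
#'
#' Draws an i.i.d. per-residue H/E/C string for each protein, emulating
#' predicted secondary structure used to stratify composition features.
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param proportions Named class probabilities for H, E, C.
#' @param seed Integer seed (default derived from the cohort's config).
#' @return The cohort with \code{structures} set (named character vector).
#' @export
generate_structures <- function(cohort,
                                proportions = c(H = 0.35, E = 0.15, C = 0.5),
                                seed = cohort$config$seed + 101L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  stopifnot(all(c("H", "E", "C") %in% names(proportions)))
  p <- proportions[c("H", "E", "C")] / sum(proportions)
  strs <- with_seed(seed, {
    vapply(nchar(cohort$records$protein), function(n) {
      paste(sample(c("H", "E", "C"), n, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
  })
  cohort$structures <- stats::setNames(strs, cohort$records$id)
  cohort
}

#' Generate annotation terms at fixed prevalence
#'
#' Builds a binary protein-by-term matrix with one term per requested
#' prevalence: term \code{k} marks exactly \code{prevalences[k]} proteins,
#' chosen at random. Zero-prevalence terms are retained as all-zero columns.
#'
#' @param ids Protein identifiers (character vector), or a
#'   \code{synthetic_cohort}.
#' @param prevalences Integer vector of per-term protein counts.
#' @param seed Integer seed.
#' @return If given a cohort, the cohort with \code{annotations} set;
#'   otherwise the binary matrix (rows = proteins, columns = terms).
#' @export
generate_annotations <- function(ids, prevalences, seed = 1L) {
  cohort <- NULL
  if (inherits(ids, "synthetic_cohort")) {
    cohort <- ids
    ids <- cohort$records$id
    if (missing(seed)) seed <- cohort$config$seed + 211L
  }
  n <- length(ids)
  if (any(prevalences > n)) {
    stop("prevalence exceeds number of proteins: ",
         paste(prevalences[prevalences > n], collapse = ", "))
  }
  if (any(prevalences < 0)) stop("prevalences must be non-negative")
  mat <- with_seed(seed, {
    m <- vapply(prevalences, function(p) {
      col <- integer(n)
      if (p > 0) col[sample.int(n, p)] <- 1L
      col
    }, integer(n))
    m
  })
  rownames(mat) <- ids
  colnames(mat) <- sprintf("term_p%03d", prevalences)
  if (anyDuplicated(colnames(mat))) {
    colnames(mat) <- make.unique(colnames(mat), sep = "_")
  }
  if (!is.null(cohort)) {
    cohort$annotations <- mat
    return(cohort)
  }
  mat
}

#' Simulate a pulse-chase decay curve
#'
#' Intensities follow \eqn{I(t) = b + f_0 e^{-(k_{deg}+k_{div}) t}} plus
#' Gaussian noise: a labelled protein pool decaying by degradation and by
#' dilution through cell division over a constant background. Negative
#' intensities caused by noise are kept and flagged, not clipped.
#'
#' @param k_deg Degradation rate, per hour.
#' @param k_div Division (dilution) rate, per hour.
#' @param f0 Initial labelled intensity.
#' @param background Background intensity.
#' @param times Time points in hours (non-negative).
#' @param noise_sd Gaussian noise s.d. on the intensity scale.
#' @param seed Integer seed.
#' @param construct Construct identifier.
#' @return Data frame of class \code{decay_curve} with columns
#'   \code{time_h}, \code{intensity}; attributes \code{construct},
#'   \code{truth} and (if any) \code{negative_intensities}.
#' @export
simulate_decay_curves <- function(k_deg, k_div = 0, f0 = 100,
                                  background = 0, times = seq(0, 24, by = 2),
                                  noise_sd = 0, seed = 1L,
                                  construct = "construct1") {
  if (k_deg < 0 || k_div < 0) stop("rates must be non-negative")
  if (length(times) == 0L || any(times < 0)) {
    stop("times must be non-empty and non-negative")
  }
  mu <- background + f0 * exp(-(k_deg + k_div) * times)
  y <- with_seed(seed, mu + stats::rnorm(length(times), sd = noise_sd))
  out <- data.frame(time_h = times, intensity = y)
  attr(out, "construct") <- construct
  attr(out, "truth") <- list(k_deg = k_deg, k_div = k_div, f0 = f0,
                             background = background, noise_sd = noise_sd,
                             seed = seed)
  if (any(y < 0)) attr(out, "negative_intensities") <- which(y < 0)
  class(out) <- c("decay_curve", "data.frame")
  out
}
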