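# Cross-validated prediction harness: 72/8/20 split, preprocessing filters,
# three learner families tuned by repeated 10-fold CV RMSE, test-set metrics,
# percent-of-maximum normalisation, and scaled/grouped feature importances.

#' Data-splitting specification
#'
#' Defaults follow the classical train / cross-validation / test layout:
#' 20\% of proteins held out for testing, the remaining 80\% split into
#' 10 balanced folds (each fold a 72\%/8\% train/validation division of the
#' whole dataset), repeated with 10 different fold initialisations.
#'
#' @param train_fraction,cv_fraction,test_fraction Fractions summing to 1.
#' @param folds Number of CV folds (>= 2).
#' @param repeats Number of fold initialisations (>= 1).
#' @param seed Integer seed governing the split.
#' @return List of class \code{split_spec}.
#' @export
split_spec <- function(train_fraction = 0.72, cv_fraction = 0.08,
                       test_fraction = 0.20, folds = 10L, repeats = 10L,
                       seed = 1L) {
  if (abs(train_fraction + cv_fraction + test_fraction - 1) > 1e-8) {
    stop("fractions must sum to 1")
  }
  if (folds < 2L) stop("folds must be >= 2")
  if (repeats < 1L) stop("repeats must be >= 1")
  structure(list(train_fraction = train_fraction,
                 cv_fraction = cv_fraction,
                 test_fraction = test_fraction,
                 folds = as.integer(folds),
                 repeats = as.integer(repeats),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Partition ids into test set and repeated CV folds
#'
#' Draws the held-out test partition (\code{test_fraction}, rounded) and
#' assigns the remaining ids to balanced folds, independently for each
#' repeat. Deterministic for a fixed seed.
#'
#' @param ids Character vector of unique ids.
#' @param spec A \code{\link{split_spec}}.
#' @return List with \code{test_ids}, \code{traincv_ids}, and \code{folds},
#'   an \code{n_traincv x repeats} integer matrix of fold labels.
#' @export
make_split <- function(ids, spec = split_spec()) {
  n <- length(ids)
  if (n < spec$folds + 1L) stop("too few ids for the requested folds")
  if (anyDuplicated(ids)) stop("duplicate ids")
  n_test <- round(spec$test_fraction * n)
  with_seed(spec$seed, {
    test_ids <- sample(ids, n_test)
    traincv_ids <- setdiff(ids, test_ids)
    m <- length(traincv_ids)
    folds <- vapply(seq_len(spec$repeats), function(r) {
      sample(rep(seq_len(spec$folds), length.out = m))
    }, integer(m))
    rownames(folds) <- traincv_ids
    list(test_ids = test_ids, traincv_ids = traincv_ids, folds = folds)
  })
}

#' Centre, scale and filter a feature matrix
#'
#' Fits a preprocessing transform on a training matrix: optional removal of
#' near-zero-variance columns, exact linear combinations and one member of
#' each highly collinear pair (|r| above \code{cor_cutoff}), followed by
#' centring and scaling to unit variance. The fitted transform is applied to
#' held-out data with the training statistics, so held-out columns need not
#' have zero mean.
#'
#' @param x Numeric training matrix.
#' @param filter Apply the redundancy filters (default TRUE).
#' @param cor_cutoff Absolute-correlation threshold for the collinearity
#'   filter.
#' @return Object of class \code{feature_transform}; apply it with
#'   \code{predict(transform, newdata)}.
#' @export
preprocess <- function(x, filter = TRUE, cor_cutoff = 0.95) {
  x <- as.matrix(x)
  sds0 <- apply(x, 2L, stats::sd)
  if (all(sds0 == 0)) stop("all feature columns are constant")
  removed <- list(near_zero_variance = character(0),
                  linear_combination = character(0),
                  collinear = character(0))
  keep <- colnames(x)
  if (filter) {
    nzv <- caret::nearZeroVar(x)
    if (length(nzv)) {
      removed$near_zero_variance <- colnames(x)[nzv]
      x <- x[, -nzv, drop = FALSE]
    }
    lc <- caret::findLinearCombos(x)$remove
    if (length(lc)) {
      removed$linear_combination <- colnames(x)[lc]
      x <- x[, -lc, drop = FALSE]
    }
    hc <- caret::findCorrelation(stats::cor(x), cutoff = cor_cutoff)
    if (length(hc)) {
      removed$collinear <- colnames(x)[hc]
      x <- x[, -hc, drop = FALSE]
    }
    keep <- colnames(x)
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2L, stats::sd)
  scale_[scale_ == 0] <- 1
  structure(list(keep = keep, center = center, scale = scale_,
                 removed = removed, filter = filter,
                 cor_cutoff = cor_cutoff),
            class = "feature_transform")
}

#' @export
predict.feature_transform <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, object$keep, drop = FALSE]
  scale(newdata, center = object$center, scale = object$scale)[, , drop = FALSE]
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

LEARNERS <- c("ensemble_trees", "elastic_linear", "greedy_forward_backward")

# ---- greedy forward-backward least squares -------------------------------

# Forward steps add the feature most correlated with the current residual;
# a backward step removes the weakest active feature whenever doing so costs
# less than `nu` times the last forward gain. Returns the nested active sets.
foba_path <- function(x, y, kmax, nu = 0.5) {
  p <- ncol(x)
  kmax <- min(kmax, p)
  active <- integer(0)
  path <- vector("list", 0L)
  rss_prev <- sum((y - mean(y))^2)
  resid <- y - mean(y)
  repeat {
    if (length(active) >= kmax || length(path) >= kmax) break
    cand <- setdiff(seq_len(p), active)
    if (!length(cand)) break
    sc <- abs(crossprod(x[, cand, drop = FALSE], resid))
    j <- cand[which.max(sc)]
    active <- c(active, j)
    fit <- stats::lm.fit(cbind(1, x[, active, drop = FALSE]), y)
    rss <- sum(fit$residuals^2)
    gain <- rss_prev - rss
    if (gain <= 1e-12) { active <- active[-length(active)]; break }
    rss_prev <- rss
    resid <- fit$residuals
    # backward pass
    while (length(active) > 1L) {
      inc <- vapply(seq_along(active), function(i) {
        a2 <- active[-i]
        f2 <- stats::lm.fit(cbind(1, x[, a2, drop = FALSE]), y)
        sum(f2$residuals^2) - rss_prev
      }, numeric(1))
      i_min <- which.min(inc)
      if (inc[i_min] < nu * gain) {
        active <- active[-i_min]
        fit <- stats::lm.fit(cbind(1, x[, active, drop = FALSE]), y)
        rss_prev <- sum(fit$residuals^2)
        resid <- fit$residuals
      } else break
    }
    path[[length(path) + 1L]] <- active
  }
  path
}

foba_fit_active <- function(x, y, active) {
  fit <- stats::lm.fit(cbind(1, x[, active, drop = FALSE]), y)
  list(active = active, coef = fit$coefficients)
}

foba_predict <- function(fit, x) {
  as.numeric(cbind(1, x[, fit$active, drop = FALSE]) %*% fit$coef)
}

# ---- learner-generic fit/predict -----------------------------------------

fit_learner <- function(learner, x, y, hyper, seed = 1L) {
  switch(learner,
    elastic_linear = glmnet::glmnet(x, y, alpha = hyper$alpha,
                                    lambda = hyper$lambda_seq),
    ensemble_trees = with_seed(seed,
      ranger::ranger(x = x, y = y, num.trees = hyper$num_trees,
                     mtry = min(hyper$mtry, ncol(x)),
                     min.node.size = hyper$min_node_size,
                     importance = "impurity",
                     num.threads = 1L)),
    greedy_forward_backward = {
      path <- foba_path(x, y, kmax = hyper$kmax, nu = hyper$nu)
      k <- min(hyper$k, length(path))
      foba_fit_active(x, y, path[[max(k, 1L)]])
    })
}

predict_learner <- function(learner, fit, x, hyper = NULL) {
  switch(learner,
    elastic_linear = as.numeric(
      stats::predict(fit, newx = x, s = hyper$lambda)),
    ensemble_trees = stats::predict(fit, data = x,
                                    num.threads = 1L)$predictions,
    greedy_forward_backward = foba_predict(fit, x))
}

default_grid <- function(learner, p) {
  switch(learner,
    elastic_linear = list(alpha = c(0, 0.5, 1)),
    ensemble_trees = list(
      mtry = unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3)))),
      num_trees = 300L, min_node_size = 5L),
    greedy_forward_backward = list(kmax = min(p, 30L), nu = 0.5))
}

#' Tune and fit a learner by repeated cross-validation
#'
#' Selects hyperparameters minimising the mean root-mean-square error over
#' \code{folds x repeats} cross-validation splits of the training set, then
#' refits the chosen configuration on the full training set. The three
#' learner families are \code{"ensemble_trees"} (random forest, able to
#' capture non-linear structure), \code{"elastic_linear"} (elastic net over
#' a penalty path and mixing grid) and \code{"greedy_forward_backward"}
#' (stepwise least squares with backward pruning; model size chosen by CV).
#' CV RMSE ties are broken toward the simpler configuration (larger penalty
#' / fewer features / smaller mtry).
#'
#' @param x Preprocessed numeric training matrix.
#' @param y Numeric response aligned to \code{x} rows.
#' @param spec A \code{\link{split_spec}} (folds/repeats/seed are used).
#' @param learner One of the three learner names.
#' @param folds Optional precomputed fold matrix (rows aligned to \code{x});
#'   generated from \code{spec} otherwise.
#' @param grid Optional hyperparameter grid overriding the defaults.
#' @return List with \code{fit}, \code{hyper}, \code{rmse_cv},
#'   \code{cv_table}.
#' @export
tune_and_fit <- function(x, y, spec = split_spec(), learner = LEARNERS,
                         folds = NULL, grid = NULL) {
  learner <- match.arg(learner, LEARNERS)
  if (stats::sd(y) == 0) stop("degenerate (constant) response")
  n <- nrow(x)
  if (is.null(folds)) {
    folds <- with_seed(spec$seed + 17L, {
      vapply(seq_len(spec$repeats), function(r) {
        sample(rep(seq_len(spec$folds), length.out = n))
      }, integer(n))
    })
  }
  grid <- utils::modifyList(default_grid(learner, ncol(x)),
                            if (is.null(grid)) list() else grid)
  fold_sets <- list()
  for (r in seq_len(ncol(folds))) {
    for (f in seq_len(spec$folds)) {
      val <- which(folds[, r] == f)
      if (length(val)) fold_sets[[length(fold_sets) + 1L]] <- val
    }
  }

  if (learner == "elastic_linear") {
    best <- NULL
    cv_table <- NULL
    for (alpha in grid$alpha) {
      lambda_seq <- glmnet::glmnet(x, y, alpha = alpha, nlambda = 60,
                                   lambda.min.ratio = 1e-5)$lambda
      errs <- vapply(fold_sets, function(val) {
        f <- glmnet::glmnet(x[-val, , drop = FALSE], y[-val], alpha = alpha,
                            lambda = lambda_seq)
        pred <- stats::predict(f, newx = x[val, , drop = FALSE],
                               s = lambda_seq)
        apply(pred, 2L, function(p) rmse(y[val], p))
      }, numeric(length(lambda_seq)))
      mean_err <- unname(rowMeans(errs))
      # ties toward the simpler (more penalised) model
      i <- which(mean_err <= min(mean_err) + 1e-12)[1L]
      cv_table <- rbind(cv_table,
                        data.frame(alpha = alpha, lambda = lambda_seq[i],
                                   rmse_cv = mean_err[i]))
      if (is.null(best) || mean_err[i] < best$rmse_cv - 1e-12) {
        best <- list(alpha = alpha, lambda = lambda_seq[i],
                     lambda_seq = lambda_seq, rmse_cv = mean_err[i])
      }
    }
    fit <- fit_learner(learner, x, y, best)
    return(list(fit = fit, hyper = best, rmse_cv = best$rmse_cv,
                cv_table = cv_table, learner = learner))
  }

  if (learner == "ensemble_trees") {
    cv_table <- NULL
    best <- NULL
    for (mtry in sort(grid$mtry)) {
      hyper <- list(mtry = mtry, num_trees = grid$num_trees,
                    min_node_size = grid$min_node_size)
      errs <- vapply(seq_along(fold_sets), function(k) {
        val <- fold_sets[[k]]
        f <- fit_learner(learner, x[-val, , drop = FALSE], y[-val], hyper,
                         seed = spec$seed + k)
        rmse(y[val], predict_learner(learner, f, x[val, , drop = FALSE]))
      }, numeric(1))
      m <- mean(errs)
      cv_table <- rbind(cv_table, data.frame(mtry = mtry, rmse_cv = m))
      if (is.null(best) || m < best$rmse_cv - 1e-12) {
        best <- c(hyper, list(rmse_cv = m))
      }
    }
    fit <- fit_learner(learner, x, y, best, seed = spec$seed)
    return(list(fit = fit, hyper = best, rmse_cv = best$rmse_cv,
                cv_table = cv_table, learner = learner))
  }

  # greedy forward-backward: choose the path length k by CV
  kmax <- grid$kmax
  err_by_k <- matrix(NA_real_, nrow = kmax, ncol = length(fold_sets))
  for (kf in seq_along(fold_sets)) {
    val <- fold_sets[[kf]]
    path <- foba_path(x[-val, , drop = FALSE], y[-val], kmax, grid$nu)
    for (k in seq_along(path)) {
      f <- foba_fit_active(x[-val, , drop = FALSE], y[-val], path[[k]])
      err_by_k[k, kf] <- rmse(y[val],
                              foba_predict(f, x[val, , drop = FALSE]))
    }
  }
  mean_err <- rowMeans(err_by_k, na.rm = TRUE)
  ok <- which(is.finite(mean_err))
  if (!length(ok)) stop("forward-backward selection found no usable model")
  k_best <- ok[which(mean_err[ok] <= min(mean_err[ok]) + 1e-12)][1L]
  hyper <- list(kmax = kmax, nu = grid$nu, k = k_best,
                rmse_cv = mean_err[k_best])
  fit <- fit_learner("greedy_forward_backward", x, y, hyper)
  list(fit = fit, hyper = hyper, rmse_cv = mean_err[k_best],
       cv_table = data.frame(k = ok, rmse_cv = mean_err[ok]),
       learner = learner)
}

#' Percent of the maximum expected prediction quality
#'
#' Expresses a model's r-squared relative to the inter-study r-squared (the
#' agreement between independent measurements of the same quantity): values
#' that do not reproduce between studies cannot be predicted, so the
#' inter-study r-squared bounds what any model can reach.
#'
#' @param r2_model Model test r-squared.
#' @param r2_interstudy Inter-study r-squared, in (0, 1].
#' @return List with \code{raw} (exact percentage) and \code{percent}
#'   (integer, rounded half away from zero).
#' @examples
#' percent_of_max(0.17, 0.48)$percent  # 35
#' percent_of_max(0.21, 0.48)$percent  # 44
#' @export
percent_of_max <- function(r2_model, r2_interstudy) {
  if (r2_interstudy <= 0) stop("r2_interstudy must be positive")
  raw <- 100 * r2_model / r2_interstudy
  list(raw = raw, percent = round_half_away(raw))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Fig.-style amino-acid grouping for importances
AA_GROUPS <- list(
  small_hydrophobic = c("A", "I", "L", "V"),
  negative_polar = c("D", "E", "N", "Q"),
  positive = c("K", "R"),
  phospho = c("S", "T"),
  unusual = c("P", "W", "C")
)

#' Scaled and grouped feature importances
#'
#' Raw importances are learner-specific: mean decrease in node impurity for
#' the random forest; for the two linear learners, the absolute mean
#' coefficient divided by its standard deviation (a t-statistic) over
#' \code{refits} leave-fold-out refits of the chosen configuration on the
#' training set. Raw values are scaled so the largest equals 100, and summed
#' over amino-acid classes (small hydrophobic A/I/L/V, negatively
#' charged/polar D/E/N/Q, positively charged K/R, potentially phosphorylated
#' S/T, unusually shaped/bonded P/W/C), separately for amino-acid and for
#' codon features.
#'
#' @param model A fitted \code{\link{homeostasis_model}}, or the list
#'   returned by \code{\link{tune_and_fit}} together with \code{x},
#'   \code{y}.
#' @param x,y Training data (required when \code{model} is a
#'   \code{tune_and_fit} result).
#' @param refits Number of leave-fold-out refits for linear importances.
#' @param seed Seed for the refit folds.
#' @return Object of class \code{importance_table}: list with \code{raw},
#'   \code{scaled} (max exactly 100), \code{groups} (data frame), and
#'   \code{undefined} flag when all raw importances are zero.
#' @export
importance_table <- function(model, x = NULL, y = NULL, refits = 30L,
                             seed = 1L) {
  if (inherits(model, "homeostasis_model")) {
    x <- model$train_x; y <- model$train_y
    tuned <- model$tuned
  } else {
    tuned <- model
    if (is.null(x) || is.null(y)) stop("x and y required")
  }
  learner <- tuned$learner
  feat <- colnames(x)
  if (learner == "ensemble_trees") {
    raw <- tuned$fit$variable.importance[feat]
    raw[is.na(raw)] <- 0
  } else {
    refits <- min(refits, nrow(x) - 2L)
    fold <- with_seed(seed, sample(rep(seq_len(refits),
                                       length.out = nrow(x))))
    coefs <- vapply(seq_len(refits), function(f) {
      xi <- x[fold != f, , drop = FALSE]; yi <- y[fold != f]
      if (learner == "elastic_linear") {
        fit <- glmnet::glmnet(xi, yi, alpha = tuned$hyper$alpha,
                              lambda = tuned$hyper$lambda_seq)
        as.numeric(stats::coef(fit, s = tuned$hyper$lambda))[-1L]
      } else {
        fit <- foba_fit_active(xi, yi, tuned$fit$active)
        b <- numeric(ncol(x))
        b[tuned$fit$active] <- fit$coef[-1L]
        b
      }
    }, numeric(ncol(x)))
    m <- rowMeans(coefs)
    s <- apply(coefs, 1L, stats::sd)
    raw <- abs(m) / pmax(s, 1e-8)
    raw[abs(m) < 1e-12] <- 0
    names(raw) <- feat
  }
  undefined <- max(raw) <= 0
  scaled <- if (undefined) raw else 100 * raw / max(raw)
  groups <- group_importances(scaled)
  structure(list(raw = raw, scaled = scaled, groups = groups,
                 learner = learner, undefined = undefined),
            class = "importance_table")
}

# sum scaled importances over the amino-acid classes, separately for
# amino-acid and codon features
group_importances <- function(scaled) {
  ct <- codon_table()
  rows <- lapply(names(AA_GROUPS), function(g) {
    aas <- AA_GROUPS[[g]]
    aa_feats <- intersect(paste0("aa_", aas), names(scaled))
    codons <- ct$codon[ct$aa %in% aas]
    cd_feats <- intersect(paste0("codon_", codons), names(scaled))
    data.frame(group = g,
               block = c("amino_acid", "codon"),
               importance = c(sum(scaled[aa_feats]), sum(scaled[cd_feats])),
               n_features = c(length(aa_feats), length(cd_feats)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.importance_table <- function(x, ...) {
  cat("Feature importances (", x$learner, "), scaled 0-100\n", sep = "")
  top <- utils::head(sort(x$scaled, decreasing = TRUE), 10L)
  print(round(top, 1))
  invisible(x)
}

#' Fit a homeostasis prediction model
#'
#' The central fitting function: given a tiered feature matrix and a
#' response (protein lifetime, abundance, mRNA abundance, ribosome density,
#' ...), holds out a test partition, preprocesses the training features,
#' tunes the requested learner by repeated cross-validated RMSE, refits on
#' the full training set and evaluates on the untouched test set. Test ids
#' take no part in preprocessing or tuning.
#'
#' @param features Numeric matrix (proteins x features), e.g. from
#'   \code{\link{assemble_feature_matrix}}.
#' @param response Named numeric vector (names = protein ids).
#' @param learner \code{"ensemble_trees"}, \code{"elastic_linear"} or
#'   \code{"greedy_forward_backward"}.
#' @param spec A \code{\link{split_spec}}.
#' @param filter Apply the redundancy filters in preprocessing.
#' @param log_response Model \code{log(response)} instead of the raw values.
#' @param max_expected_r2 Optional inter-study r-squared; when given, the
#'   report includes the percent-of-maximum normalisation.
#' @param importance Compute the importance table (default TRUE).
#' @param grid Optional hyperparameter grid override.
#' @return Object of class \code{homeostasis_model} with components
#'   \code{report} (RMSE/r/r-squared on CV and test), \code{importances},
#'   \code{split}, \code{transform}, \code{tuned}.
#' @examples
#' \donttest{
#' cfg <- synthetic_config(n_proteins = 300, seed = 1)
#' coh <- plant_response(generate_cds_cohort(cfg))
#' fm <- assemble_feature_matrix(coh$records)
#' m <- homeostasis_model(fm, coh$responses$lifetime,
#'                        learner = "elastic_linear",
#'                        spec = split_spec(folds = 5, repeats = 2))
#' summary(m)
#' }
#' @export
homeostasis_model <- function(features, response,
                              learner = LEARNERS,
                              spec = split_spec(), filter = TRUE,
                              log_response = FALSE,
                              max_expected_r2 = NULL,
                              importance = TRUE, grid = NULL) {
  learner <- match.arg(learner, LEARNERS)
  ids <- intersect(rownames(features), names(response))
  if (length(ids) < spec$folds + 5L) stop("too few proteins with responses")
  y_all <- response[ids]
  if (log_response) {
    if (any(y_all <= 0)) stop("log transform requires positive responses")
    y_all <- log(y_all)
  }
  split <- make_split(ids, spec)
  stopifnot(length(intersect(split$test_ids, split$traincv_ids)) == 0L)
  x_tr_raw <- features[split$traincv_ids, , drop = FALSE]
  tf <- preprocess(x_tr_raw, filter = filter)
  x_tr <- predict(tf, x_tr_raw)
  y_tr <- y_all[split$traincv_ids]
  tuned <- tune_and_fit(x_tr, y_tr, spec, learner,
                        folds = split$folds, grid = grid)
  x_te <- predict(tf, features[split$test_ids, , drop = FALSE])
  y_te <- y_all[split$test_ids]
  pred <- predict_learner(learner, tuned$fit, x_te, tuned$hyper)
  report <- evaluate_predictions(y_te, pred, tuned$rmse_cv,
                                 max_expected_r2)
  imp <- if (importance) {
    importance_table(list(learner = learner, fit = tuned$fit,
                          hyper = tuned$hyper),
                     x = x_tr, y = y_tr, seed = spec$seed)
  }
  structure(list(
    learner = learner,
    tier = if (!is.null(attr(features, "tiers"))) {
      paste(unique(attr(features, "tiers")), collapse = "+")
    } else "unknown",
    report = report,
    importances = imp,
    tuned = tuned,
    transform = tf,
    split = split,
    spec = spec,
    log_response = log_response,
    train_x = x_tr, train_y = y_tr,
    test_predictions = stats::setNames(pred, split$test_ids),
    test_observed = y_te
  ), class = "homeostasis_model")
}

# test-set metrics shared by homeostasis_model and the standalone evaluate
evaluate_predictions <- function(obs, pred, rmse_cv = NA_real_,
                                 max_expected_r2 = NULL) {
  r <- if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    NA_real_
  } else {
    stats::cor(obs, pred)
  }
  out <- list(rmse_cv = rmse_cv,
              rmse_test = rmse(obs, pred),
              r_test = r,
              r2_test = unname(r^2),
              n_test = length(obs))
  if (!is.null(max_expected_r2) && !is.na(r)) {
    out$percent_of_max <- percent_of_max(out$r2_test, max_expected_r2)
  }
  out
}

#' Evaluate a tuned model on held-out data
#'
#' Computes test RMSE, Pearson r and its square for predictions of a tuned
#' learner on data never used in tuning. Constant predictions yield an
#' undefined (NA) correlation but the RMSE is still reported.
#'
#' @param tuned Result of \code{\link{tune_and_fit}}.
#' @param x_test Preprocessed test matrix.
#' @param y_test Test responses.
#' @param max_expected_r2 Optional inter-study r-squared.
#' @return List of test metrics (see \code{\link{homeostasis_model}}).
#' @export
evaluate <- function(tuned, x_test, y_test, max_expected_r2 = NULL) {
  pred <- predict_learner(tuned$learner, tuned$fit, x_test, tuned$hyper)
  out <- evaluate_predictions(y_test, pred, tuned$rmse_cv, max_expected_r2)
  out$predictions <- pred
  out
}

#' Learning curve of a learner
#'
#' Refits the learner on nested subsets of the training data and reports
#' training and cross-validation RMSE per subset size, the standard
#' bias/variance diagnostic.
#'
#' @param features,response As for \code{\link{homeostasis_model}}.
#' @param spec A \code{\link{split_spec}}.
#' @param learner Learner name.
#' @param sizes Increasing subset sizes (each >= folds).
#' @param filter Preprocessing filter flag.
#' @return Data frame with columns \code{n}, \code{rmse_train},
#'   \code{rmse_cv}.
#' @export
learning_curve <- function(features, response, spec = split_spec(),
                           learner = LEARNERS, sizes, filter = TRUE) {
  learner <- match.arg(learner, LEARNERS)
  if (is.unsorted(sizes, strictly = TRUE)) stop("sizes must be increasing")
  if (any(sizes < spec$folds)) stop("every size must be >= folds")
  ids <- intersect(rownames(features), names(response))
  if (max(sizes) > length(ids)) stop("size exceeds available proteins")
  ids <- with_seed(spec$seed + 29L, sample(ids))
  rows <- lapply(sizes, function(s) {
    sub <- ids[seq_len(s)]
    x_raw <- features[sub, , drop = FALSE]
    tf <- preprocess(x_raw, filter = filter)
    x <- predict(tf, x_raw)
    y <- response[sub]
    tuned <- tune_and_fit(x, y, spec, learner)
    pred_tr <- predict_learner(learner, tuned$fit, x, tuned$hyper)
    data.frame(n = s, rmse_train = rmse(y, pred_tr),
               rmse_cv = tuned$rmse_cv)
  })
  do.call(rbind, rows)
}

# ---- S3 methods ----------------------------------------------------------

#' @export
print.homeostasis_model <- function(x, ...) {
  cat("Homeostasis prediction model (", x$learner, ", tier: ", x$tier,
      ")\n", sep = "")
  cat(sprintf("  CV RMSE %.4g | test RMSE %.4g | test r %.3f | test r2 %.3f\n",
              x$report$rmse_cv, x$report$rmse_test,
              x$report$r_test, x$report$r2_test))
  if (!is.null(x$report$percent_of_max)) {
    cat(sprintf("  %d%% of the maximum expected r2\n",
                x$report$percent_of_max$percent))
  }
  invisible(x)
}

#' @export
summary.homeostasis_model <- function(object, ...) {
  print(object)
  cat("  train/cv proteins:", length(object$split$traincv_ids),
      "| test proteins:", length(object$split$test_ids), "\n")
  if (!is.null(object$importances) && !object$importances$undefined) {
    cat("  top features:\n")
    print(round(utils::head(sort(object$importances$scaled,
                                 decreasing = TRUE), 5L), 1))
  }
  invisible(object)
}

#' @export
coef.homeostasis_model <- function(object, ...) {
  t <- object$tuned
  switch(object$learner,
    elastic_linear = {
      b <- as.numeric(stats::coef(t$fit, s = t$hyper$lambda))
      stats::setNames(b, c("(Intercept)", colnames(object$train_x)))
    },
    greedy_forward_backward = {
      stats::setNames(t$fit$coef,
                      c("(Intercept)",
                        colnames(object$train_x)[t$fit$active]))
    },
    ensemble_trees = stop("tree ensembles have no coefficients; see importance_table()"))
}

#' @export
predict.homeostasis_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$test_predictions)
  x <- predict(object$transform, newdata)
  predict_learner(object$learner, object$tuned$fit, x, object$tuned$hyper)
}

#' @export
residuals.homeostasis_model <- function(object, ...) {
  object$test_observed - object$test_predictions
}

#' @export
plot.homeostasis_model <- function(x, ...) {
  graphics::plot(x$test_observed, x$test_predictions,
                 xlab = "observed (test set)", ylab = "predicted",
                 main = sprintf("%s: test r2 = %.2f", x$learner,
                                x$report$r2_test), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
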