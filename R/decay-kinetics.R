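# Pulse-chase decay fitting with cell-division dilution correction.

#' Build a decay curve from time/intensity data
#'
#' @param time_h Time points in hours, strictly increasing, >= 3 points.
#' @param intensity Mean fluorescence intensities.
#' @param sem Optional per-time s.e.m.
#' @param construct Construct identifier.
#' @param n_replicates Number of replicate experiments averaged.
#' @return Data frame of class \code{decay_curve}.
#' @export
decay_curve <- function(time_h, intensity, sem = NULL,
                        construct = "construct1", n_replicates = NA_integer_) {
  if (length(time_h) < 3L) stop("need at least 3 time points")
  if (is.unsorted(time_h, strictly = TRUE)) {
    stop("time points must be strictly increasing")
  }
  if (length(intensity) != length(time_h)) stop("length mismatch")
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  out <- data.frame(time_h = time_h, intensity = intensity)
  if (!is.null(sem)) out$sem <- sem
  attr(out, "construct") <- construct
  attr(out, "n_replicates") <- n_replicates
  class(out) <- c("decay_curve", "data.frame")
  out
}

#' Fit a pulse-chase decay curve
#'
#' Nonlinear least squares on the model
#' \deqn{I(t) = b + f_0 \exp(-(k_{deg} + k_{div})\, t)}
#' where \eqn{k_{div}} is the label loss caused by cell-division dilution.
#' By default \eqn{k_{div}} is a supplied constant (measured externally, as
#' from the dilution line of a proliferation control); with
#' \code{k_div = "fit"} it is estimated jointly (>= 5 time points
#' required). All parameters are constrained non-negative. Reported
#' half-lives: \code{t_half = ln 2 / k_deg}, the division-corrected protein
#' half-life (infinite when the degradation-rate estimate hits zero, which
#' is flagged), and \code{t_half_composite = ln 2 / (k_deg + k_div)}, the
#' half-life of the observed composite decay. \code{fit_r2} is
#' \eqn{1 - SS_{res}/SS_{tot}} over the intensities. An alternative
#' log-linear fit (ordinary least squares on
#' \eqn{\log(I - b)} with \code{b} fixed at the supplied background) is
#' available with \code{method = "loglinear"}.
#'
#' @param curve A \code{\link{decay_curve}} (or data frame with
#'   \code{time_h} and \code{intensity}).
#' @param k_div Known division rate per hour, or \code{"fit"}.
#' @param method \code{"nls"} (default) or \code{"loglinear"}.
#' @param background For \code{method = "loglinear"}: fixed background
#'   (default 0).
#' @return Object of class \code{decay_fit}: \code{k_deg}, \code{k_div},
#'   \code{f0}, \code{background}, \code{t_half}, \code{t_half_composite},
#'   \code{fit_r2}, \code{converged}, \code{t_half_infinite} flag,
#'   \code{curve}.
#' @examples
#' cv <- simulate_decay_curves(k_deg = log(2) / 10, times = seq(0, 24, 2))
#' fit_decay(cv)
#' @export
fit_decay <- function(curve, k_div = 0, method = c("nls", "loglinear"),
                      background = 0) {
  method <- match.arg(method)
  t <- curve$time_h
  y <- curve$intensity
  if (length(t) < 3L) stop("need at least 3 time points")
  fit_kdiv <- identical(k_div, "fit")
  if (fit_kdiv && length(t) < 5L) {
    stop("fitting k_div requires at least 5 time points")
  }
  if (!fit_kdiv && k_div < 0) stop("k_div must be non-negative")

  # crude starting values from the data
  b0 <- max(min(y), 0)
  f0_0 <- max(max(y) - b0, max(y) * 0.5, 1e-6)
  pos <- y - b0 > f0_0 * 1e-3
  k0 <- if (sum(pos) >= 2L) {
    sl <- stats::coef(stats::lm(log(y[pos] - b0 + f0_0 * 1e-3) ~ t[pos]))[2L]
    max(-sl, 1e-4)
  } else 0.05

  if (method == "loglinear") {
    yy <- y - background
    ok <- yy > 0
    if (sum(ok) < 3L) stop("too few positive intensities for log-linear fit")
    lmfit <- stats::lm(log(yy[ok]) ~ t[ok])
    k_tot <- max(-unname(stats::coef(lmfit)[2L]), 0)
    kd <- if (fit_kdiv) 0 else k_div
    k_deg <- max(k_tot - kd, 0)
    f0 <- exp(unname(stats::coef(lmfit)[1L]))
    pred <- background + f0 * exp(-k_tot * t)
    converged <- TRUE
    bg <- background
  } else {
    form <- if (fit_kdiv) {
      stats::as.formula(
        "intensity ~ bg + f0 * exp(-(k_deg + k_div_est) * time_h)")
    } else {
      stats::as.formula("intensity ~ bg + f0 * exp(-(k_deg + KDIV) * time_h)")
    }
    dat <- data.frame(time_h = t, intensity = y, KDIV = if (fit_kdiv) 0 else k_div)
    # multi-start: the background/rate starting values interact badly when
    # the true background is near zero, so try a small cascade
    k_cands <- unique(pmax(c(k0, k0 / 2, 2 * k0, 0.03), 1e-4))
    b_cands <- unique(c(b0 / 2, 0, b0))
    starts <- list()
    for (kc in k_cands) for (bc in b_cands) {
      starts[[length(starts) + 1L]] <- if (fit_kdiv) {
        list(bg = bc, f0 = max(max(y) - bc, 1e-6), k_deg = kc / 2,
             k_div_est = kc / 2)
      } else {
        list(bg = bc, f0 = max(max(y) - bc, 1e-6),
             k_deg = max(kc - k_div, 1e-4))
      }
    }
    fit <- NULL
    for (start in starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(form, data = dat, start = start,
                          lower = rep(0, length(start)),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) e)
      if (!inherits(fit, "error")) break
    }
    if (inherits(fit, "error")) {
      out <- structure(list(k_deg = NA_real_, k_div = if (fit_kdiv) NA_real_ else k_div,
                            f0 = NA_real_, background = NA_real_,
                            t_half = NA_real_, t_half_composite = NA_real_,
                            fit_r2 = NA_real_, converged = FALSE,
                            t_half_infinite = FALSE,
                            diagnostics = conditionMessage(fit),
                            curve = curve),
                       class = "decay_fit")
      return(out)
    }
    cf <- stats::coef(fit)
    k_deg <- unname(cf["k_deg"])
    kd <- if (fit_kdiv) unname(cf["k_div_est"]) else k_div
    f0 <- unname(cf["f0"])
    bg <- unname(cf["bg"])
    pred <- stats::predict(fit)
    converged <- TRUE
  }
  sstot <- sum((y - mean(y))^2)
  fit_r2 <- if (sstot > 0) 1 - sum((y - pred)^2) / sstot else NA_real_
  # degradation indistinguishable from zero over the observation window
  infinite <- k_deg * max(t) < 1e-6
  structure(list(
    k_deg = k_deg, k_div = kd, f0 = f0, background = bg,
    t_half = if (infinite) Inf else log(2) / k_deg,
    t_half_composite = if (k_deg + kd <= 1e-9) Inf else log(2) / (k_deg + kd),
    fit_r2 = fit_r2, converged = converged,
    t_half_infinite = infinite,
    method = method,
    curve = curve
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Decay fit: did NOT converge (", x$diagnostics, ")\n", sep = "")
    return(invisible(x))
  }
  th <- if (x$t_half_infinite) "Inf (no detectable degradation)" else
    sprintf("%.2f h", x$t_half)
  cat(sprintf(
    "Decay fit: k_deg %.4g/h, k_div %.4g/h | t1/2 %s | fit r2 %.3f\n",
    x$k_deg, x$k_div, th, x$fit_r2))
  invisible(x)
}

#' @export
predict.decay_fit <- function(object, times = object$curve$time_h, ...) {
  object$background +
    object$f0 * exp(-(object$k_deg + object$k_div) * times)
}

#' @export
residuals.decay_fit <- function(object, ...) {
  object$curve$intensity - predict(object)
}

#' @export
plot.decay_fit <- function(x, ...) {
  graphics::plot(x$curve$time_h, x$curve$intensity,
                 xlab = "chase time (h)", ylab = "intensity",
                 main = sprintf("t1/2 = %.1f h (r2 = %.2f)",
                                x$t_half, x$fit_r2), ...)
  tt <- seq(min(x$curve$time_h), max(x$curve$time_h), length.out = 100)
  graphics::lines(tt, predict(x, tt))
  graphics::lines(tt, x$curve$intensity[1L] * dilution_line(x$k_div, tt) / 100,
                  lty = 2)
  invisible(x)
}

#' Cell-division dilution line
#'
#' Fraction of label remaining under division dilution alone:
#' \eqn{100\, e^{-k_{div} t}}, as a percentage of time zero. Plotted as the
#' segmented reference line in pulse-chase figures.
#'
#' @param k_div Division rate per hour, >= 0.
#' @param times Time points in hours.
#' @return Percentages of the time-0 label.
#' @export
dilution_line <- function(k_div, times) {
  if (k_div < 0) stop("k_div must be non-negative")
  100 * exp(-k_div * times)
}

#' Protein abundance at the start of the chase
#'
#' Returns the measured intensity at t = 0 when present; otherwise falls
#' back to the fitted \code{background + f0}. The basis used is recorded in
#' the \code{"basis"} attribute.
#'
#' @param curve A \code{\link{decay_curve}}.
#' @param fit Optional \code{\link{fit_decay}} result for the fallback.
#' @return Intensity with attribute \code{basis} (\code{"measured"} or
#'   \code{"fitted"}).
#' @export
time0_abundance <- function(curve, fit = NULL) {
  i0 <- which(curve$time_h == 0)
  if (length(i0)) {
    out <- curve$intensity[i0[1L]]
    attr(out, "basis") <- "measured"
    return(out)
  }
  if (is.null(fit) || !fit$converged) {
    stop("no t = 0 measurement and no converged fit available")
  }
  out <- fit$background + fit$f0
  attr(out, "basis") <- "fitted"
  out
}
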