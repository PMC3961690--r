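#' A pH-titration series for one NMR resonance
#'
#' Chemical shift of one resonance measured across a pH ladder. Points are
#' sorted by pH on construction; duplicate pH values (repeated measurements)
#' are allowed and retained.
#'
#' @param ph pH values (finite numeric).
#' @param shift Chemical shifts in ppm (finite numeric, same length).
#' @param residue_label,nucleus_label,state_label Free-text labels, e.g.
#'   `"C461"`, `"13Cb"`, `"reduced"`.
#' @return An object of class `titration_series` with a `points` data frame.
#' @export
titration_series <- function(ph, shift, residue_label = "",
                             nucleus_label = "", state_label = "") {
  stopifnot(is.numeric(ph), is.numeric(shift), length(ph) == length(shift),
            length(ph) >= 1L, all(is.finite(ph)), all(is.finite(shift)))
  ord <- order(ph)
  structure(
    list(
      residue_label = as.character(residue_label),
      nucleus_label = as.character(nucleus_label),
      state_label = as.character(state_label),
      points = data.frame(ph = ph[ord], shift = shift[ord])
    ),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "Titration series %s %s %s: %d points, pH %.2f-%.2f, shift range %.3f ppm\n",
    x$residue_label, x$nucleus_label, x$state_label, nrow(x$points),
    min(x$points$ph), max(x$points$ph),
    diff(range(x$points$shift))
  ))
  invisible(x)
}

# Condition helpers -----------------------------------------------------------

stop_trxpka <- function(class, msg) {
  stop(structure(
    class = c(class, "trxpka_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Shared least-squares machinery ----------------------------------------------

# Run nls.lm from several starts, return the converged fit with smallest
# deviance, or NULL when no start converges.
multistart_nls <- function(resid_fn, starts, lower = NULL) {
  best <- NULL
  for (start in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, fn = resid_fn, lower = lower,
        control = minpack.lm::nls.lm.control(maxiter = 400)
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || !(fit$info %in% 1:4)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  best
}

# Asymptotic standard errors from the (approximate) Gauss-Newton Hessian.
asymptotic_stderr <- function(fit, n_points) {
  dof <- n_points - length(fit$par)
  sigma2 <- fit$deviance / max(dof, 1L)
  vcov <- tryCatch(solve(fit$hessian) * sigma2, error = function(e) NULL)
  if (is.null(vcov)) return(rep(NA_real_, length(fit$par)))
  d <- diag(vcov)
  d[d < 0] <- NA_real_
  sqrt(d)
}

check_fittable <- function(series, n_min, min_amplitude) {
  stopifnot(inherits(series, "titration_series"))
  pts <- series$points
  if (nrow(pts) < n_min) {
    stop_trxpka("trxpka_too_few_points",
                sprintf("need at least %d points, got %d", n_min, nrow(pts)))
  }
  if (diff(range(pts$shift)) < min_amplitude) {
    stop_trxpka("trxpka_no_titration",
                sprintf(paste0(
                  "no titration detected: observed shift range %.4f ppm is ",
                  "below the amplitude floor %.4f ppm"),
                  diff(range(pts$shift)), min_amplitude))
  }
  pts
}

new_titration_fit <- function(model_kind, params, fit, pts, stderr_pka,
                              extrapolated, nonidentifiable = FALSE,
                              series = NULL) {
  structure(
    list(
      model_kind = model_kind,
      params = params,
      rss = fit$deviance,
      dof = nrow(pts) - length(fit$par),
      stderr_pka = stderr_pka,
      converged = TRUE,
      extrapolated = extrapolated,
      nonidentifiable = nonidentifiable,
      n_points = nrow(pts),
      residue_label = if (is.null(series)) "" else series$residue_label,
      nucleus_label = if (is.null(series)) "" else series$nucleus_label
    ),
    class = "titration_fit"
  )
}

#' Fit a one-pKa titration curve
#'
#' Unweighted least squares of [shift_one_pka()] over the three parameters
#' (two limiting shifts and the pKa), by Levenberg-Marquardt with
#' multi-start initialization: pKa starts on an integer grid 4-12 and the
#' limiting shifts start from the first and last observed points. A fitted
#' pKa outside the observed pH window (plus one unit either side) is flagged
#' `extrapolated` rather than suppressed.
#'
#' @param series A [titration_series()] with at least 6 points.
#' @param min_amplitude Amplitude floor in ppm; a series whose total
#'   observed shift range falls below it raises a "no titration detected"
#'   error (condition class `trxpka_no_titration`).
#' @param pka_starts pKa values used as multi-start initial guesses.
#' @return An object of class `titration_fit` with elements `model_kind`
#'   (`"one_pka"`), `params` ([one_pka_params()]), `rss`, `dof`,
#'   `stderr_pka`, `converged`, `extrapolated`.
#' @export
fit_one_pka <- function(series, min_amplitude = 0.1, pka_starts = 4:12) {
  pts <- check_fittable(series, 6L, min_amplitude)
  ph <- pts$ph
  obs <- pts$shift
  resid_fn <- function(p) {
    f <- 1 / (1 + 10^(p[3] - ph))
    p[1] * (1 - f) + p[2] * f - obs
  }
  d_lo <- obs[1L]
  d_hi <- obs[length(obs)]
  starts <- lapply(pka_starts, function(k) c(d_lo, d_hi, k))
  best <- multistart_nls(resid_fn, starts)
  if (is.null(best)) {
    stop_trxpka("trxpka_fit_failed",
                "one-pKa fit did not converge from any start")
  }
  params <- one_pka_params(best$par[1], best$par[2], best$par[3])
  stderr <- asymptotic_stderr(best, nrow(pts))
  extrapolated <- params$pka < min(ph) - 1 || params$pka > max(ph) + 1
  new_titration_fit("one_pka", params, best, pts,
                    stderr_pka = stderr[3], extrapolated = extrapolated,
                    series = series)
}

#' Fit a two-pKa titration curve
#'
#' Unweighted least squares of [shift_two_pka()] over five parameters. The
#' ordering `pka1 <= pka2` is enforced structurally by fitting `pka1` and
#' the separation `delta = pka2 - pka1 >= 0`. Multi-start initialization
#' uses all ordered pKa pairs from a grid (default 4, 6, 8, 10, 12), the
#' first/last observed shifts for the outer limits, and the mid-range shift
#' for the intermediate plateau.
#'
#' Practical non-identifiability is flagged when the fitted transitions
#' collapse (separation or a step amplitude near zero) or when fixing either
#' pKa 0.5 units away from its optimum and refitting the remaining
#' parameters barely changes the residual sum of squares.
#'
#' @inheritParams fit_one_pka
#' @param series A [titration_series()] with at least 8 points.
#' @param pka_start_grid Grid from which ordered pKa start pairs are formed.
#' @param profile_rtol Relative flatness tolerance for the profile check.
#' @return A `titration_fit` with `model_kind = "two_pka"`, `params` a
#'   [two_pka_params()], `stderr_pka` a length-2 vector, and a
#'   `nonidentifiable` flag.
#' @export
fit_two_pka <- function(series, min_amplitude = 0.1,
                        pka_start_grid = c(4, 6, 8, 10, 12),
                        profile_rtol = 0.01) {
  pts <- check_fittable(series, 8L, min_amplitude)
  ph <- pts$ph
  obs <- pts$shift

  eval_two <- function(d0, d1, d2, pka1, pka2) {
    e1 <- ph - pka1
    e2 <- 2 * ph - pka1 - pka2
    m <- pmax(0, e1, e2)
    w0 <- 10^(-m); w1 <- 10^(e1 - m); w2 <- 10^(e2 - m)
    (d0 * w0 + d1 * w1 + d2 * w2) / (w0 + w1 + w2)
  }
  # parameters: d0, d1, d2, pka1, delta (= pka2 - pka1, bounded below by 0)
  resid_fn <- function(p) {
    eval_two(p[1], p[2], p[3], p[4], p[4] + p[5]) - obs
  }
  d_lo <- obs[1L]
  d_hi <- obs[length(obs)]
  d_mid <- (min(obs) + max(obs)) / 2
  grid <- pka_start_grid
  starts <- list()
  for (i in seq_along(grid)) {
    for (j in seq_along(grid)) {
      if (grid[j] - grid[i] >= 0.5) {
        starts[[length(starts) + 1L]] <-
          c(d_lo, d_mid, d_hi, grid[i], grid[j] - grid[i])
      }
    }
  }
  lower <- c(-Inf, -Inf, -Inf, -Inf, 0)
  best <- multistart_nls(resid_fn, starts, lower = lower)
  if (is.null(best)) {
    stop_trxpka("trxpka_fit_failed",
                "two-pKa fit did not converge from any start")
  }
  p <- best$par
  params <- two_pka_params(p[1], p[2], p[3], p[4], p[4] + p[5])
  stderr <- asymptotic_stderr(best, nrow(pts))
  # pka2 = pka1 + delta, so var(pka2) = var(pka1) + var(delta) + 2 cov
  sigma2 <- best$deviance / max(nrow(pts) - 5L, 1L)
  vcov <- tryCatch(solve(best$hessian) * sigma2, error = function(e) NULL)
  se_pka2 <- if (is.null(vcov)) NA_real_ else {
    v <- vcov[4, 4] + vcov[5, 5] + 2 * vcov[4, 5]
    if (is.na(v) || v < 0) NA_real_ else sqrt(v)
  }
  extrapolated <-
    params$pka1 < min(ph) - 1 || params$pka1 > max(ph) + 1 ||
    params$pka2 < min(ph) - 1 || params$pka2 > max(ph) + 1

  # a transition is collapsed when the separation vanishes or when a step
  # amplitude is not clearly larger than the residual noise level
  sigma_hat <- sqrt(best$deviance / max(nrow(pts) - 5L, 1L))
  step_floor <- max(min_amplitude / 2, 3 * sigma_hat)
  collapse <- p[5] < 0.25 ||
    min(abs(p[2] - p[1]), abs(p[3] - p[2])) < step_floor
  flat <- FALSE
  if (!collapse) {
    flat <- profile_is_flat(eval_two, obs, p, best$deviance, profile_rtol)
  }
  new_titration_fit("two_pka", params, best, pts,
                    stderr_pka = c(stderr[4], se_pka2),
                    extrapolated = extrapolated,
                    nonidentifiable = collapse || flat,
                    series = series)
}

# Profile flatness check: fix each pKa at its optimum +/- 0.5 units, refit
# the remaining parameters, and compare the achieved RSS with the optimum.
profile_is_flat <- function(eval_two, obs, par_opt, rss_opt, rtol) {
  tol <- max(1e-7, rtol * rss_opt)
  pka1 <- par_opt[4]
  pka2 <- par_opt[4] + par_opt[5]
  for (which in 1:2) {
    for (sgn in c(-1, 1)) {
      if (which == 1L) {
        p1 <- pka1 + sgn * 0.5
        p2 <- pka2
      } else {
        p1 <- pka1
        p2 <- pka2 + sgn * 0.5
      }
      if (p1 > p2) next
      resid_fixed <- function(q) eval_two(q[1], q[2], q[3], p1, p2) - obs
      refit <- tryCatch(
        minpack.lm::nls.lm(par = par_opt[1:3], fn = resid_fixed,
                           control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL
      )
      if (is.null(refit)) next
      if (refit$deviance - rss_opt < tol) return(TRUE)
    }
  }
  FALSE
}

#' Choose between the one- and two-pKa models for a series
#'
#' Fits both nested models and compares them with an extra-sum-of-squares
#' F-test: the two-pKa model is preferred when its reduction in residual sum
#' of squares is significant at level `alpha`. Both fits are returned so the
#' decision can be audited.
#'
#' @inheritParams fit_one_pka
#' @param alpha Significance level of the F-test (default 0.05). `alpha = 1`
#'   always prefers the richer model, `alpha = 0` never does.
#' @return A list with `model_kind` (the preferred model), `fit_one`,
#'   `fit_two`, `f_statistic`, and `p_value`.
#' @export
select_model <- function(series, alpha = 0.05, min_amplitude = 0.1) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  fit1 <- fit_one_pka(series, min_amplitude = min_amplitude)
  fit2 <- fit_two_pka(series, min_amplitude = min_amplitude)
  df_extra <- fit1$dof - fit2$dof
  if (fit2$rss <= 0) {
    # both fits are exact to machine precision or the richer model is;
    # an exact richer fit with a worse simpler one is decisive
    f_stat <- if (fit1$rss > 0) Inf else 0
  } else {
    f_stat <- ((fit1$rss - fit2$rss) / df_extra) / (fit2$rss / fit2$dof)
  }
  f_stat <- max(f_stat, 0)
  p_value <- stats::pf(f_stat, df_extra, fit2$dof, lower.tail = FALSE)
  kind <- if (p_value <= alpha) "two_pka" else "one_pka"
  list(
    model_kind = kind,
    fit_one = fit1,
    fit_two = fit2,
    f_statistic = f_stat,
    p_value = p_value
  )
}

#' Aggregate per-resonance pKa fits into a single estimate
#'
#' Cross-resonance average of fitted pKa values: unweighted mean, sample
#' standard deviation (n - 1 denominator), and the number of resonances.
#' This is the headline reporting convention for titration studies in which
#' each residue's pKa is determined from the fits of several chemical-shift
#' curves and quoted as "mean +/- SD (n)".
#'
#' @param fits A list of `titration_fit` objects (or a single fit).
#' @param transition Which transition to aggregate: `"only"` for one-pKa
#'   fits, `"lower"` or `"upper"` for two-pKa fits. Mixing model kinds under
#'   one call is an error, since the transitions would not be comparable.
#' @return An object of class `pka_estimate` with `mean_pka`, `sd_pka`
#'   (`NA` with `sd_defined = FALSE` when only one fit is supplied), and
#'   `n_resonances`.
#' @export
aggregate_pka <- function(fits, transition = c("only", "lower", "upper")) {
  transition <- match.arg(transition)
  if (inherits(fits, "titration_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "titration_fit")))
  kinds <- vapply(fits, function(f) f$model_kind, character(1))
  if (transition == "only") {
    if (any(kinds != "one_pka")) {
      stop(paste("transition = \"only\" requires one-pKa fits;",
                 "use \"lower\"/\"upper\" for two-pKa fits"), call. = FALSE)
    }
    values <- vapply(fits, function(f) f$params$pka, numeric(1))
  } else {
    if (any(kinds != "two_pka")) {
      stop(sprintf(
        "transition = \"%s\" requires two-pKa fits; mixed or one-pKa fits cannot be aggregated under it",
        transition), call. = FALSE)
    }
    values <- vapply(fits, function(f) {
      if (transition == "lower") f$params$pka1 else f$params$pka2
    }, numeric(1))
  }
  n <- length(values)
  structure(
    list(
      mean_pka = mean(values),
      sd_pka = if (n > 1L) stats::sd(values) else NA_real_,
      sd_defined = n > 1L,
      n_resonances = n,
      transition = transition,
      values = values
    ),
    class = "pka_estimate"
  )
}

#' @export
print.titration_fit <- function(x, ...) {
  if (x$model_kind == "one_pka") {
    cat(sprintf("One-pKa fit: pKa = %.3f (se %.3f), rss = %.4g, dof = %d\n",
                x$params$pka, x$stderr_pka, x$rss, x$dof))
  } else {
    cat(sprintf(
      "Two-pKa fit: pKa1 = %.3f, pKa2 = %.3f, rss = %.4g, dof = %d\n",
      x$params$pka1, x$params$pka2, x$rss, x$dof))
  }
  if (x$extrapolated) cat("  [pKa outside observed pH window: extrapolated]\n")
  if (isTRUE(x$nonidentifiable)) cat("  [flagged practically non-identifiable]\n")
  invisible(x)
}

#' @export
print.pka_estimate <- function(x, ...) {
  cat(format_pka_estimate(x), "\n")
  invisible(x)
}
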