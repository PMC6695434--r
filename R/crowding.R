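# Concentration dependence of self-diffusion: short-time (Tokuyama-Oppenheim
# form) and long-time (caged) ratios, reaction-rate optimization over volume
# fraction and shape, and nonlinear fitting of the critical volume fraction.

#' Short-time self-diffusion ratio of a crowded suspension
#'
#' \deqn{D_S^S(\varphi)/D^0 = \frac{1}{1 + L(\varphi)}, \quad
#'   L(\varphi) = \frac{2B^2}{1-B} - \frac{C}{1+2C}
#'     - \frac{BC(2+C)}{(1+C)(1-B+C)}}
#' with \eqn{B = (9\varphi/8)^{1/2}} and \eqn{C = 11\varphi/16}.
#'
#' @param phi volume fraction(s) in \[0, 8/9) (B < 1 required).
#' @return ratio(s) in (0, 1\].
#' @export
short_time_ratio <- function(phi) {
  stopifnot(all(phi >= 0))
  B <- sqrt(9 * phi / 8)
  C <- 11 * phi / 16
  if (any(B >= 1) || any(1 - B + C <= 0))
    stop("short_time_ratio: volume fraction outside the model domain")
  L <- 2 * B^2 / (1 - B) - C / (1 + 2 * C) -
    B * C * (2 + C) / ((1 + C) * (1 - B + C))
  1 / (1 + L)
}

#' Long-time self-diffusion ratio with a cage-escape singularity
#'
#' \deqn{\frac{D_S^L(\varphi,\varphi_c)}{D^0} =
#'   \frac{D_S^S/D^0}{1 + \kappa\,(D_S^S/D^0)\,(\varphi/\varphi_c)
#'   (1-\varphi/\varphi_c)^{-2}}}
#' which vanishes at the critical volume fraction \eqn{\varphi_c} (the
#' glass/gel point). \eqn{\kappa = 2} describes protein data well.
#'
#' @param phi volume fraction(s).
#' @param phi_c critical volume fraction.
#' @param kappa cage-strength scaling parameter (default 2).
#' @return ratio(s); 0 (with attribute `singular = TRUE`) where
#'   `phi >= phi_c`.
#' @export
long_time_ratio <- function(phi, phi_c, kappa = 2) {
  stopifnot(phi_c > 0, kappa >= 0, all(phi >= 0))
  out <- numeric(length(phi))
  ok <- phi < phi_c
  if (any(ok)) {
    ss <- short_time_ratio(phi[ok])
    x <- phi[ok] / phi_c
    out[ok] <- ss / (1 + kappa * ss * x * (1 - x)^(-2))
  }
  if (any(!ok)) attr(out, "singular") <- TRUE
  out
}

#' Optimal volume fraction (and shape) for diffusion-limited reactions
#'
#' Maximizes the reaction-rate proxy \eqn{\varphi \cdot D(\varphi)/D^0}
#' over \eqn{\varphi \in (0, \varphi_c)}. Two diffusion models are
#' available: `"quadratic"` (\eqn{D = D^0 (1-\varphi/\varphi_c)^2}, hard
#' spheres; argmax \eqn{\varphi_c/3} in closed form) and `"tokuyama"`
#' (chained short/long-time ratios). When `phi_c` is a function of
#' (alpha, beta), a joint maximization over shape is performed including
#' the dilute shape factor of [dt_mean_shape()].
#'
#' @param model `"quadratic"` or `"tokuyama"`.
#' @param phi_c critical volume fraction: a scalar, or a
#'   `function(alpha, beta)` surface.
#' @param kappa cage parameter for the tokuyama model.
#' @param alpha_grid,beta_grid shape grids for the joint maximization
#'   (used only when `phi_c` is a function).
#' @param phi_tol grid resolution in phi for the numeric maximization.
#' @return list: `phi_opt`, `value`; plus `alpha_opt`, `beta_opt` for
#'   surface input. `phi_percent` is the integer-percent report.
#' @export
rate_optimum <- function(model = c("quadratic", "tokuyama"), phi_c,
                         kappa = 2,
                         alpha_grid = seq(1, 3, by = 0.01),
                         beta_grid = c(0),
                         phi_tol = 1e-5) {
  model <- match.arg(model)
  objective <- function(phi, pc) {
    if (model == "quadratic") phi * (1 - phi / pc)^2
    else phi * long_time_ratio(phi, pc, kappa)
  }
  best_phi <- function(pc) {
    phi <- seq(phi_tol, pc - phi_tol, by = phi_tol)
    v <- objective(phi, pc)
    i <- which.max(v)
    c(phi[i], v[i])
  }
  if (is.function(phi_c)) {
    best <- NULL
    for (b in beta_grid) for (a in alpha_grid) {
      pc <- phi_c(a, b)
      if (!is.finite(pc) || pc <= 0) next
      bp <- best_phi(pc)
      # dilute shape factor: Dt at fixed r' relative to the sphere
      shape_fac <- dt_mean_shape(a, if (a > 1) b else 0, 1) /
        dt_mean_shape(1, 0, 1)
      val <- bp[2] * shape_fac
      if (is.null(best) || val > best$value)
        best <- list(phi_opt = bp[1], value = val,
                     alpha_opt = a, beta_opt = b)
    }
    best$phi_percent <- round(100 * best$phi_opt)
    return(best)
  }
  bp <- best_phi(phi_c)
  list(phi_opt = bp[1], value = bp[2],
       phi_percent = round(100 * bp[1]))
}

#' Fit the critical volume fraction to diffusion-versus-concentration data
#'
#' Nonlinear least squares of the long-time model (chained with the
#' short-time form) to observed \eqn{(\varphi, D/D^0)} points, with
#' \eqn{\varphi_c} and optionally \eqn{\kappa} free. Initialization:
#' \eqn{\varphi_{c,0} = 1.05 \max\varphi_{obs}}, \eqn{\kappa_0 = 2};
#' bounds \eqn{\varphi_c \in (\max\varphi_{obs}, 1.2]},
#' \eqn{\kappa \in (0, 10]}. The fit is invariant to rescaling D by a
#' constant only if the ratios are supplied normalised; pass `normalise =
#' TRUE` to divide by the fitted dilute intercept instead.
#'
#' @param phi observed volume fractions (>= 4 points, spanning
#'   phi >= 0.2 for a well-conditioned fit).
#' @param ratio observed \eqn{D/D^0} values.
#' @param kappa `"free"` or a fixed numeric value.
#' @param weights fit weights; the default `"relative"` uses
#'   `1/ratio^2` (floored at 1e-3), appropriate for diffusion ratios with
#'   multiplicative error spanning decades. Pass a numeric vector or
#'   `"none"` for ordinary least squares.
#' @return a `crowding_fit` object: coefficients `phi_c` (and `kappa`),
#'   fitted values, residual summary and a `wide_ci` diagnostic flag set
#'   when the data do not constrain phi_c (relative SE > 25%).
#' @export
fit_phi_c <- function(phi, ratio, kappa = "free", weights = "relative") {
  stopifnot(length(phi) == length(ratio), length(phi) >= 4)
  if (max(phi) < 0.2)
    warning("no points with phi >= 0.2: phi_c will be poorly constrained")
  if (identical(weights, "relative")) weights <- pmax(ratio, 1e-3)^-2
  else if (identical(weights, "none")) weights <- NULL
  df <- data.frame(phi = phi, ratio = ratio)
  start <- list(phi_c = 1.05 * max(phi))
  lower <- c(phi_c = max(phi) + 1e-6)
  upper <- c(phi_c = 1.2)
  if (identical(kappa, "free")) {
    form <- ratio ~ long_time_ratio(phi, phi_c, kappa)
    start$kappa <- 2
    lower <- c(lower, kappa = 1e-3)
    upper <- c(upper, kappa = 10)
  } else {
    stopifnot(is.numeric(kappa), kappa >= 0)
    form <- substitute(ratio ~ long_time_ratio(phi, phi_c, k),
                       list(k = kappa))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start,
                      lower = lower, upper = upper,
                      weights = if (is.null(weights)) rep(1, nrow(df))
                                else weights,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop(sprintf(
      "fit_phi_c failed to converge: %s", conditionMessage(e))))
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  out <- list(phi_c = unname(est["phi_c"]),
              kappa = if (identical(kappa, "free")) unname(est["kappa"])
                      else kappa,
              se = se,
              wide_ci = is.na(se[1]) ||
                se[1] / est["phi_c"] > 0.25,
              fit = fit, phi = phi, ratio = ratio)
  class(out) <- "crowding_fit"
  out
}

#' @export
print.crowding_fit <- function(x, ...) {
  cat(sprintf("<crowding_fit> phi_c = %.4f (se %.4f)%s, kappa = %.3f\n",
              x$phi_c, x$se[1],
              if (isTRUE(x$wide_ci)) " [poorly constrained]" else "",
              x$kappa))
  invisible(x)
}

#' @export
coef.crowding_fit <- function(object, ...) {
  c(phi_c = object$phi_c, kappa = object$kappa)
}

#' @export
predict.crowding_fit <- function(object, newdata = NULL, ...) {
  phi <- if (is.null(newdata)) object$phi else newdata$phi
  long_time_ratio(phi, object$phi_c, object$kappa)
}

#' Crowding curve over a volume-fraction grid
#'
#' @param phi_c critical volume fraction.
#' @param kappa cage parameter.
#' @param n grid size over \[0, phi_c).
#' @return data frame `phi`, `short_ratio`, `long_ratio`.
#' @export
crowding_curve <- function(phi_c = 0.58, kappa = 2, n = 200) {
  phi <- seq(0, phi_c - phi_c / n, length.out = n)
  data.frame(phi = phi,
             short_ratio = short_time_ratio(phi),
             long_ratio = long_time_ratio(phi, phi_c, kappa))
}
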