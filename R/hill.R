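#' Fit a cooperative (Hill) binding isotherm
#'
#' Least-squares fit of the Hill model
#' \deqn{y(c) = B_{max} \, c^{n} / (K^{n} + c^{n})}
#' to an equilibrium binding isotherm, by Levenberg-Marquardt nonlinear
#' regression. Starting values are data-driven: `b_max` from the maximum
#' response, `k_half` from the interpolated half-maximum concentration, and
#' `n_hill = 1`. Parameter standard errors come from the asymptotic
#' (Jacobian-based) covariance at the optimum, and the coefficient of
#' determination is `R^2 = 1 - SS_res / SS_tot`. A Hill coefficient above 1
#' indicates positive cooperativity (sigmoidal isotherm). When per-point
#' standard deviations are supplied the fit is weighted by `1/sd^2`;
#' otherwise unweighted.
#'
#' @param concentrations strictly positive, strictly increasing ligand
#'   concentrations (any fixed unit; `k_half` is reported in the same unit).
#' @param responses equilibrium binding responses (arbitrary units, same
#'   length).
#' @param sd optional per-point standard deviations enabling weighted fitting.
#' @param n_fixed optionally fix the Hill coefficient (e.g. `n_fixed = 1`
#'   fits the Langmuir model).
#' @param max_iter iteration cap for the optimizer.
#' @return an object of class `hillfit` with components `coefficients`
#'   (`n_hill`, `k_half`, `b_max`), `se`, `vcov`, `r_squared`, `converged`,
#'   `fitted.values`, `residuals`, `data`, and a text `cooperativity` verdict.
#'   Non-convergence is reported via `converged = FALSE` (with the optimizer
#'   message in `diagnostics`), not as an error.
#' @examples
#' conc <- 10^seq(-2, 2, length.out = 9)
#' resp <- conc^2 / (1 + conc^2)
#' fit <- fit_hill(conc, resp)
#' summary(fit)
#' predict(fit, newdata = c(0.5, 1, 2))
#' @export
fit_hill <- function(concentrations, responses, sd = NULL, n_fixed = NULL,
                     max_iter = 200) {
  c0 <- as.numeric(concentrations); y <- as.numeric(responses)
  if (length(c0) != length(y))
    stop("concentrations and responses differ in length", call. = FALSE)
  if (any(c0 <= 0)) stop("concentrations must be strictly positive",
                         call. = FALSE)
  if (any(diff(c0) <= 0)) stop("concentrations must be strictly increasing",
                               call. = FALSE)
  npar <- if (is.null(n_fixed)) 3L else 2L
  if (length(c0) < npar + 1)
    stop("need at least ", npar + 1, " points for a ", npar,
         "-parameter fit", call. = FALSE)
  if (!is.null(sd) && (length(sd) != length(y) || any(sd <= 0)))
    stop("per-point sd must be positive and match the data length",
         call. = FALSE)
  if (any(diff(y) < 0) && (max(y) - min(y)) > 0 &&
      sum(diff(y) < 0) > length(y) / 2)
    warning("responses are grossly non-monotone in concentration; ",
            "the Hill model may be inappropriate")

  b0 <- max(y)
  k0 <- tryCatch(stats::approx(y, c0, xout = b0 / 2, ties = "ordered")$y,
                 error = function(e) NA_real_)
  if (!is.finite(k0) || k0 <= 0) k0 <- exp(mean(log(c0)))
  dat <- data.frame(c = c0, y = y)
  w <- if (is.null(sd)) rep(1, length(y)) else 1 / sd^2
  ctrl <- minpack.lm::nls.lm.control(maxiter = max_iter, ftol = 1e-14,
                                     ptol = 1e-14)

  fit <- tryCatch({
    if (is.null(n_fixed))
      minpack.lm::nlsLM(y ~ bmax * c^n / (k^n + c^n), data = dat,
                        start = list(bmax = b0, k = k0, n = 1),
                        lower = c(1e-12, 1e-12, 1e-6), weights = w,
                        control = ctrl)
    else
      minpack.lm::nlsLM(y ~ bmax * c^n_fixed / (k^n_fixed + c^n_fixed),
                        data = dat, start = list(bmax = b0, k = k0),
                        lower = c(1e-12, 1e-12), weights = w, control = ctrl)
  }, error = function(e) e)

  if (inherits(fit, "error")) {
    out <- list(coefficients = c(n_hill = NA_real_, k_half = NA_real_,
                                 b_max = NA_real_),
                se = c(n_hill = NA_real_, k_half = NA_real_,
                       b_max = NA_real_),
                vcov = NULL, r_squared = NA_real_, converged = FALSE,
                diagnostics = conditionMessage(fit),
                fitted.values = rep(NA_real_, length(y)),
                residuals = rep(NA_real_, length(y)),
                data = dat, weights = w, n_fixed = n_fixed,
                cooperativity = "fit did not converge",
                call = match.call())
    class(out) <- "hillfit"
    return(out)
  }

  cf <- stats::coef(fit)
  if (is.null(n_fixed)) {
    est <- c(n_hill = unname(cf["n"]), k_half = unname(cf["k"]),
             b_max = unname(cf["bmax"]))
    V <- stats::vcov(fit)[c("n", "k", "bmax"), c("n", "k", "bmax")]
  } else {
    est <- c(n_hill = n_fixed, k_half = unname(cf["k"]),
             b_max = unname(cf["bmax"]))
    V0 <- stats::vcov(fit)[c("k", "bmax"), c("k", "bmax")]
    V <- matrix(0, 3, 3); V[2:3, 2:3] <- V0
  }
  dimnames(V) <- list(names(est), names(est))
  fitted <- as.numeric(stats::fitted(fit))
  resid <- y - fitted
  ss_res <- sum(w * resid^2)
  ss_tot <- sum(w * (y - stats::weighted.mean(y, w))^2)
  r2 <- 1 - ss_res / ss_tot
  se <- sqrt(pmax(diag(V), 0))
  out <- list(coefficients = est, se = se, vcov = V, r_squared = r2,
              converged = fit$convInfo$isConv %||% TRUE,
              diagnostics = fit$convInfo$stopMessage %||% "",
              fitted.values = fitted, residuals = resid, data = dat,
              weights = w, n_fixed = n_fixed, ss_res = ss_res,
              cooperativity = if (est[["n_hill"]] > 1)
                "positive cooperativity (n_hill > 1)"
              else if (est[["n_hill"]] < 1)
                "negative cooperativity (n_hill < 1)"
              else "non-cooperative (n_hill = 1)",
              call = match.call())
  class(out) <- "hillfit"
  out
}

#' Evaluate a fitted Hill curve
#'
#' @param fit a converged [fit_hill()] object.
#' @param concentrations non-negative concentrations to evaluate at.
#' @return predicted responses (monotone non-decreasing in concentration).
#' @export
hill_predict <- function(fit, concentrations) {
  stopifnot(inherits(fit, "hillfit"))
  if (!isTRUE(fit$converged))
    stop("cannot predict from a non-converged fit", call. = FALSE)
  cc <- as.numeric(concentrations)
  if (any(cc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  p <- fit$coefficients
  ifelse(cc == 0, 0,
         p[["b_max"]] * cc^p[["n_hill"]] /
           (p[["k_half"]]^p[["n_hill"]] + cc^p[["n_hill"]]))
}

#' @export
predict.hillfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  cc <- if (is.data.frame(newdata)) newdata$c else newdata
  hill_predict(object, cc)
}

#' @export
coef.hillfit <- function(object, ...) object$coefficients

#' @export
vcov.hillfit <- function(object, ...) object$vcov

#' @export
fitted.hillfit <- function(object, ...) object$fitted.values

#' @export
residuals.hillfit <- function(object, ...) object$residuals

#' @export
print.hillfit <- function(x, ...) {
  cat("Hill binding-isotherm fit\n")
  if (!isTRUE(x$converged)) {
    cat("  NOT converged:", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat(sprintf("  n_hill = %.4g +/- %.2g, K = %.4g +/- %.2g, Bmax = %.4g +/- %.2g\n",
              x$coefficients[["n_hill"]], x$se[["n_hill"]],
              x$coefficients[["k_half"]], x$se[["k_half"]],
              x$coefficients[["b_max"]], x$se[["b_max"]]))
  cat(sprintf("  R^2 = %.4f; %s\n", x$r_squared, x$cooperativity))
  invisible(x)
}

#' @export
summary.hillfit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  structure(list(coefficients = tab, r_squared = object$r_squared,
                 converged = object$converged,
                 cooperativity = object$cooperativity,
                 n_points = nrow(object$data)),
            class = "summary.hillfit")
}

#' @export
print.summary.hillfit <- function(x, ...) {
  cat("Hill fit summary (", x$n_points, " points)\n", sep = "")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("R-squared: %.4f\nConverged: %s\n%s\n", x$r_squared,
              x$converged, x$cooperativity))
  invisible(x)
}

#' @export
plot.hillfit <- function(x, ...) {
  cc <- x$data$c
  grid <- exp(seq(log(min(cc)) - 1, log(max(cc)) + 1, length.out = 200))
  graphics::plot(cc, x$data$y, log = "x", pch = 16,
                 xlab = "concentration", ylab = "response", ...)
  graphics::lines(grid, hill_predict(x, grid), col = 2)
  graphics::abline(v = x$coefficients[["k_half"]], lty = 2, col = "grey50")
  invisible(x)
}

#' @export
simulate.hillfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- stats::sd(object$residuals)
  n <- nrow(object$data)
  out <- as.data.frame(replicate(nsim, object$fitted.values +
                                   stats::rnorm(n, 0, sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "concentrations") <- object$data$c
  out
}

#' Read a binding isotherm from a CSV/TSV table
#'
#' Expects columns `concentration`, `response` and optionally `sd`.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.tsv` = tab, otherwise comma).
#' @return a data.frame with validated columns.
#' @export
read_isotherm <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (!all(c("concentration", "response") %in% names(d)))
    stop("isotherm table needs 'concentration' and 'response' columns",
         call. = FALSE)
  d
}
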