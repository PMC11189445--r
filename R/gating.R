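#' Fit a single Boltzmann activation curve
#'
#' Nonlinear least squares fit of normalized tail-current conductances to
#' the single Boltzmann function
#'
#'   `G/Gmax = 1 / (1 + exp((V - V_half) / k))`,
#'
#' the standard description of hyperpolarization-activated gating (k > 0
#' gives G -> 1 at hyperpolarized V).  Gmax is fixed to 1 after
#' normalization; set `free_gmax = TRUE` to fit an amplitude for raw
#' tails.  Starting values default to the voltage nearest G = 0.5 and
#' k = 8 mV.
#'
#' @param curve A `gv_curve` (see [generate_gv_data()]) or data frame with
#'   columns `voltage` (mV) and `g_norm`.
#' @param init Optional list with `v_half` and `k` starting values.
#' @param free_gmax Fit a free maximal amplitude (default `FALSE`).
#' @return A `boltzmann_fit` object with `coef`, `vcov`, `residual_sse`,
#'   `fitted`, `data`; supports `print`, `summary`, `coef`, `vcov`,
#'   `predict`, `residuals` and `plot`.
#' @examples
#' gv <- generate_gv_data(v_half = -70, slope_k = 8)
#' fit <- fit_boltzmann(gv)
#' coef(fit)
#' @export
fit_boltzmann <- function(curve, init = NULL, free_gmax = FALSE) {
  v <- curve$voltage
  g <- curve$g_norm
  if (length(unique(v)) < 4)
    stop("need at least 4 distinct voltages to fit a Boltzmann")
  if (diff(range(g)) < 0.05)
    stop("degenerate fit: activation data are flat")
  if (max(g) < 0.5 || min(g) > 0.5)
    warning("data do not bracket G = 0.5; midpoint is extrapolated")
  if (is.null(init)) {
    init <- list(v_half = v[which.min(abs(g - 0.5))], k = 8)
  }
  fit <- tryCatch({
    if (free_gmax) {
      minpack.lm::nlsLM(g ~ gmax / (1 + exp((v - v_half) / k)),
                        start = c(init, list(gmax = max(g))),
                        lower = c(-Inf, 1e-3, 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(g ~ 1 / (1 + exp((v - v_half) / k)),
                        start = init, lower = c(-Inf, 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) {
    stop("Boltzmann fit did not converge (start: v_half = ", init$v_half,
         ", k = ", init$k, "): ", conditionMessage(e))
  })
  cf <- coef(fit)
  structure(list(coef = cf,
                 vcov = tryCatch(vcov(fit), error = function(e) matrix(NA, 2, 2)),
                 residual_sse = sum(stats::resid(fit)^2),
                 fitted = stats::fitted(fit),
                 data = data.frame(voltage = v, g_norm = g),
                 free_gmax = free_gmax, nls = fit),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit: V1/2 = %.2f mV, k = %.2f mV (SSE %.3g)\n",
              x$coef[["v_half"]], x$coef[["k"]], x$residual_sse))
  if (x$free_gmax) cat(sprintf(" Gmax = %.3f\n", x$coef[["gmax"]]))
  invisible(x)
}

#' @export
summary.boltzmann_fit <- function(object, ...) {
  print(object)
  se <- sqrt(diag(object$vcov))
  cat(sprintf(" standard errors: V1/2 %.3f, k %.3f\n", se[1], se[2]))
  invisible(object)
}

#' @export
coef.boltzmann_fit <- function(object, ...) object$coef

#' @export
vcov.boltzmann_fit <- function(object, ...) object$vcov

#' @export
residuals.boltzmann_fit <- function(object, ...) {
  object$data$g_norm - object$fitted
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$data$voltage else newdata$voltage
  gmax <- if (object$free_gmax) object$coef[["gmax"]] else 1
  gmax / (1 + exp((v - object$coef[["v_half"]]) / object$coef[["k"]]))
}

#' @export
plot.boltzmann_fit <- function(x, ...) {
  graphics::plot(x$data$voltage, x$data$g_norm, xlab = "V (mV)",
                 ylab = "G/Gmax", ...)
  vv <- seq(min(x$data$voltage), max(x$data$voltage), length.out = 200)
  graphics::lines(vv, predict(x, data.frame(voltage = vv)))
  invisible(x)
}
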