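#' Power-law gate response
#'
#' The quantitative model of one repressible promoter: with input (repressor
#' transcription) activity `x`, the output promoter activity is
#' `min(y_max, k * x^(-b))`, clamped at the unrepressed maximum `y_max`.
#' Unlike repressors that saturate as a Langmuir isotherm, the sgRNA gates
#' are log-linear over their working range, so the response is a straight
#' line of slope `-b` in log-log space.
#'
#' @param y_max Unrepressed output activity (au).
#' @param k Power-law scale (au).
#' @param b Power-law exponent (dimensionless, >= 0).
#' @param x_floor Input activity below which the output is taken as `y_max`;
#'   defaults to the clamp point `(k / y_max)^(1 / b)`.
#' @return A `gate_response` object.
#' @export
#' @examples
#' g <- gate_response(y_max = 1000, k = 100, b = 1)
#' gate_output(g, 10)
gate_response <- function(y_max, k, b, x_floor = NULL) {
  stopifnot(y_max > 0, k > 0, b >= 0)
  if (is.null(x_floor)) {
    x_floor <- if (b > 0) (k / y_max)^(1 / b) else 0
  }
  structure(list(y_max = y_max, k = k, b = b, x_floor = x_floor),
            class = "gate_response")
}

#' @export
print.gate_response <- function(x, ...) {
  cat(sprintf("<gate_response> y = min(%.4g, %.4g * x^-%.4g)\n", x$y_max, x$k, x$b))
  invisible(x)
}

#' Evaluate a gate response
#'
#' @param gate A `gate_response`.
#' @param x Input promoter activity (au), >= 0; vectorized.
#' @return Output activity in `(0, y_max]`; `x = 0` (no repressor) returns
#'   `y_max`.
#' @export
gate_output <- function(gate, x) {
  stopifnot(inherits(gate, "gate_response"), all(x >= 0))
  out <- ifelse(x <= gate$x_floor | x == 0, gate$y_max,
                pmin(gate$y_max, gate$k * x^(-gate$b)))
  pmax(out, 0)
}

#' Fold repression of a gate at a given input level
#'
#' The unrepressed output divided by the output at input activity `x_on`;
#' dimensionless and >= 1.
#'
#' @inheritParams gate_output
#' @param x_on Input activity of the fully induced state.
#' @export
#' @examples
#' fold_repression(gate_response(1000, 100, 1), 10) # 100
fold_repression <- function(gate, x_on) {
  gate$y_max / gate_output(gate, x_on)
}

#' Fit a power-law response to characterization data
#'
#' Least squares in (log input, log output) space. Points at or above
#' `saturation_frac * y_max` sit on the clamp rather than the power law and
#' are excluded from the regression; at least 3 points must remain.
#'
#' @param data Data frame with columns `input` and `output` (both positive,
#'   activity au).
#' @param y_max Unrepressed output activity used as the clamp (au).
#' @param saturation_frac Exclusion threshold as a fraction of `y_max`
#'   (default 0.9).
#' @return A `powerlaw_fit`: contains the fitted `gate` ([gate_response]),
#'   coefficient table, `r.squared`, residuals and point counts. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
fit_power_law <- function(data, y_max, saturation_frac = 0.9) {
  stopifnot(is.data.frame(data), all(c("input", "output") %in% names(data)))
  if (any(data$input <= 0) || any(data$output <= 0)) {
    rlang::abort("inputs and outputs must be positive for a log-log fit",
                 class = "crisprgates_invalid_data")
  }
  usable <- data$output < saturation_frac * y_max
  d <- data[usable, , drop = FALSE]
  if (nrow(d) < 3) {
    rlang::abort(sprintf("need >= 3 points below %.2g * y_max; have %d",
                         saturation_frac, nrow(d)),
                 class = "crisprgates_insufficient_data")
  }
  fit <- stats::lm(log(output) ~ log(input), data = d)
  cf <- summary(fit)$coefficients
  b_hat <- -cf[2, 1]
  k_hat <- exp(cf[1, 1])
  structure(
    list(
      gate = gate_response(y_max, k_hat, max(b_hat, 0)),
      coefficients = tibble::tibble(
        term = c("k", "b"),
        estimate = c(k_hat, b_hat),
        std.error = c(k_hat * cf[1, 2], cf[2, 2]),
        statistic = cf[, 3],
        p.value = cf[, 4]
      ),
      r.squared = summary(fit)$r.squared,
      sigma = summary(fit)$sigma,
      residuals = stats::residuals(fit),
      n_used = nrow(d),
      n_excluded = sum(!usable),
      data = tibble::as_tibble(data),
      lm = fit
    ),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> k = %.6g, b = %.4f (R^2 = %.4f, %d points, %d saturated excluded)\n",
              x$gate$k, x$coefficients$estimate[2], x$r.squared, x$n_used, x$n_excluded))
  invisible(x)
}

#' Tidiers for fitted gate and inducer models
#'
#' @param x A `powerlaw_fit`, `hill_fit` or `screen_report`.
#' @param ... Unused.
#' @name generics-tidiers
NULL

#' @rdname generics-tidiers
#' @exportS3Method generics::tidy
tidy.powerlaw_fit <- function(x, ...) x$coefficients

#' @rdname generics-tidiers
#' @exportS3Method generics::glance
glance.powerlaw_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r.squared, sigma = x$sigma,
                 nobs = x$n_used, n_excluded = x$n_excluded,
                 y_max = x$gate$y_max)
}

#' Hill model of an inducible input promoter
#'
#' Monotone dose-response surrogate used to rescale inducer concentration to
#' promoter activity: `y(c) = y_min + (y_max - y_min) * c^n / (K^n + c^n)`.
#'
#' @param y_min,y_max Promoter activity bounds (au).
#' @param K Half-maximal concentration (inducer units).
#' @param n Hill coefficient (> 0).
#' @return An `inducer_model`.
#' @export
inducer_model <- function(y_min, y_max, K, n) {
  stopifnot(y_min >= 0, y_max > y_min, K > 0, n > 0)
  structure(list(y_min = y_min, y_max = y_max, K = K, n = n),
            class = "inducer_model")
}

#' @export
print.inducer_model <- function(x, ...) {
  cat(sprintf("<inducer_model> y in [%.4g, %.4g], K = %.4g, n = %.3g\n",
              x$y_min, x$y_max, x$K, x$n))
  invisible(x)
}

#' Convert inducer concentration to promoter activity
#'
#' @param model An `inducer_model` or `hill_fit`.
#' @param concentration Inducer concentration(s), >= 0.
#' @return Promoter activity (au); 0 maps to `y_min`, the high-dose limit to
#'   `y_max`.
#' @export
inducer_to_activity <- function(model, concentration) {
  if (inherits(model, "hill_fit")) model <- model$model
  stopifnot(inherits(model, "inducer_model"), all(concentration >= 0))
  c_n <- concentration^model$n
  ifelse(concentration == 0, model$y_min,
         model$y_min + (model$y_max - model$y_min) * c_n / (model$K^model$n + c_n))
}

#' Fit a Hill curve to inducer characterization data
#'
#' Nonlinear least squares (Levenberg-Marquardt) for the four parameters
#' `(y_min, y_max, K, n)`. The fit is flagged `ill_conditioned` when `K` is
#' effectively unidentifiable - typically because the doses only sample the
#' saturated plateau.
#'
#' @param data Data frame with columns `concentration` and `output`.
#' @return A `hill_fit` with the fitted `model` ([inducer_model]), coefficient
#'   table, diagnostics and the `ill_conditioned` flag.
#' @export
fit_hill <- function(data) {
  stopifnot(is.data.frame(data), all(c("concentration", "output") %in% names(data)))
  if (nrow(data) < 4) {
    rlang::abort("need >= 4 points spanning low and high concentrations",
                 class = "crisprgates_insufficient_data")
  }
  y_lo <- min(data$output); y_hi <- max(data$output)
  pos <- data$concentration[data$concentration > 0]
  k_starts <- if (length(pos)) unique(stats::quantile(pos, c(0.1, 0.5, 0.9))) else 1
  # deterministic multi-start grid; first converging start wins
  fit <- NULL
  starts <- expand.grid(K0 = k_starts, n0 = c(1, 0.5, 2))
  for (s in seq_len(nrow(starts))) {
    if (!is.null(fit)) break
    K0 <- starts$K0[s]; n0 <- starts$n0[s]
    cand <- tryCatch(
      minpack.lm::nlsLM(
        output ~ y_min + (y_max - y_min) * concentration^n / (K^n + concentration^n),
        data = data,
        start = list(y_min = 0.9 * y_lo, y_max = y_hi, K = K0, n = n0),
        lower = c(y_min = 0, y_max = 0, K = 1e-12, n = 0.05),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) e
    )
    if (!inherits(cand, "error")) fit <- cand
  }
  if (is.null(fit)) {
    rlang::abort(paste0("Hill fit did not converge from any start; ",
                        "last error: ", conditionMessage(cand),
                        " (residual range of a constant fit: ",
                        paste(signif(range(data$output - mean(data$output)), 3),
                              collapse = " to "), ")"),
                 class = "crisprgates_fit_failure")
  }
  cf <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  est <- stats::coef(fit)
  se_K <- if (!is.null(cf)) cf["K", 2] else Inf
  rng <- range(data$concentration)
  ill <- !is.finite(se_K) || se_K / est[["K"]] > 1 ||
    est[["K"]] < rng[1] / 10 && rng[1] > 0 || est[["K"]] > max(rng[2], 0) * 10
  structure(
    list(
      model = inducer_model(max(est[["y_min"]], 0), est[["y_max"]],
                            est[["K"]], est[["n"]]),
      coefficients = if (!is.null(cf)) tibble::tibble(
        term = rownames(cf), estimate = cf[, 1], std.error = cf[, 2],
        statistic = cf[, 3], p.value = cf[, 4]
      ) else tibble::tibble(term = names(est), estimate = unname(est),
                            std.error = NA_real_, statistic = NA_real_,
                            p.value = NA_real_),
      residuals = stats::residuals(fit),
      ill_conditioned = isTRUE(ill),
      data = tibble::as_tibble(data),
      nls = fit
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  m <- x$model
  cat(sprintf("<hill_fit> y_min = %.4g, y_max = %.4g, K = %.4g, n = %.3g%s\n",
              m$y_min, m$y_max, m$K, m$n,
              if (x$ill_conditioned) " [ill-conditioned]" else ""))
  invisible(x)
}

#' @rdname generics-tidiers
#' @exportS3Method generics::tidy
tidy.hill_fit <- function(x, ...) x$coefficients

#' @rdname generics-tidiers
#' @exportS3Method generics::glance
glance.hill_fit <- function(x, ...) {
  tibble::tibble(sigma = sqrt(mean(x$residuals^2)), nobs = nrow(x$data),
                 ill_conditioned = x$ill_conditioned)
}
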