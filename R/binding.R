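#' Fit a one-site specific binding isotherm
#'
#' Nonlinear least squares on Y = Bmax X / (Kd + X) (a rectangular hyperbola),
#' the standard model for saturable 1:1 binding.  Replicates are pooled into a
#' single residual vector (joint fit) unless `per_replicate = TRUE`.
#' Initialization: Bmax0 = max(Y), Kd0 = median(X).
#'
#' @param data `binding_data` or data.frame with columns X (concentration, nM,
#'   positive) and Y (bound signal); an optional `replicate` column groups
#'   replicates.
#' @param init optional named list/vector with `Bmax` and `Kd` start values.
#' @param per_replicate fit each replicate separately and return a list.
#' @return `binding_fit`: list with `bmax`, `kd`, `r2`, `residuals`,
#'   `covariance` (2 x 2), `n`, and the underlying `nls` fit.
#' @export
fit_one_site <- function(data, init = NULL, per_replicate = FALSE) {
  stopifnot(all(c("X", "Y") %in% names(data)))
  if (per_replicate && "replicate" %in% names(data)) {
    return(lapply(split(as.data.frame(data), data$replicate),
                  fit_one_site, init = init))
  }
  X <- data$X; Y <- data$Y
  if (any(X <= 0)) stop("concentrations must be positive")
  if (length(unique(X)) < 3L) stop("at least 3 distinct concentrations are required")
  start <- if (is.null(init)) list(Bmax = max(Y), Kd = median(X)) else as.list(init)
  df <- data.frame(X = X, Y = Y)
  # the default relative-offset criterion is scale-invariant (preserving the
  # fit's exact equivariance under Y-scaling) but undefined at zero residuals;
  # retry with scaleOffset for noiseless data
  fit <- tryCatch(
    nls(Y ~ Bmax * X / (Kd + X), data = df, start = start,
        control = stats::nls.control(maxiter = 200, minFactor = 1e-10)),
    error = function(e1) tryCatch(
      nls(Y ~ Bmax * X / (Kd + X), data = df, start = start,
          control = stats::nls.control(maxiter = 200, minFactor = 1e-10,
                                       scaleOffset = 1)),
      error = function(e2) stop("one-site fit failed to converge: ",
                                conditionMessage(e2), call. = FALSE)))
  est <- coef(fit)
  if (any(est <= 0))
    stop(sprintf("fit returned non-positive parameters (Bmax = %.4g, Kd = %.4g)",
                 est[["Bmax"]], est[["Kd"]]))
  res <- resid(fit)
  ss_tot <- sum((Y - mean(Y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  structure(list(bmax = unname(est[["Bmax"]]), kd = unname(est[["Kd"]]),
                 r2 = r2, residuals = as.numeric(res),
                 covariance = tryCatch(vcov(fit), error = function(e) matrix(NA, 2, 2)),
                 n = length(Y), fit = fit),
            class = "binding_fit")
}

#' Evaluate a fitted one-site isotherm
#'
#' @param fit a `binding_fit`.
#' @param X concentrations (nM).
#' @return predicted bound signal Bmax X / (Kd + X).
#' @export
predict_one_site <- function(fit, X) {
  stopifnot(inherits(fit, "binding_fit"))
  fit$bmax * X / (fit$kd + X)
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("One-site binding fit: Bmax = %.4g au, Kd = %.4g nM (R^2 = %.4f, n = %d)\n",
              x$bmax, x$kd, x$r2, x$n))
  invisible(x)
}
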