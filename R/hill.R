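#' Hill dose-response model
#'
#' `hill_response()` evaluates `emax * C^n / (ec50^n + C^n)`;
#' `simulate_dose_response()` draws noisy replicate responses from it, the
#' standard synthetic pharmacology experiment being six doses spanning
#' 0.3-100 nM with six replicates and Gaussian noise of 20 ms standard
#' deviation (mirroring the between-slice scatter of refractory-period
#' assays).
#'
#' @param concentration Dose(s), any consistent unit.
#' @param ec50 Half-maximal concentration.
#' @param emax Effect ceiling.
#' @param hill_n Hill coefficient.
#' @return `hill_response()`: numeric responses.
#' @export
hill_response <- function(concentration, ec50, emax, hill_n = 1) {
  if (any(concentration < 0)) abort_domain("concentrations must be non-negative")
  emax * concentration^hill_n / (ec50^hill_n + concentration^hill_n)
}

#' @rdname hill_response
#' @param doses Dose grid.
#' @param n_rep Replicates per dose.
#' @param noise_sd Gaussian noise SD (response units).
#' @param seed RNG seed.
#' @return `simulate_dose_response()`: a tibble with `concentration` and
#'   `response`.
#' @export
simulate_dose_response <- function(doses = c(0.3, 1, 3, 10, 30, 100),
                                   n_rep = 6, noise_sd = 20, seed = 1,
                                   ec50 = 3, emax = 160, hill_n = 1) {
  mu <- hill_response(rep(doses, each = n_rep), ec50, emax, hill_n)
  resp <- mu + with_seed(seed, rnorm(length(mu), 0, noise_sd))
  tibble(concentration = rep(doses, each = n_rep), response = resp)
}

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of `R(C) = emax * C^n / (ec50^n + C^n)` to
#' concentration/response data. The fit is parameterised in `log(ec50)` and
#' run from multiple log-spaced `ec50` starts spanning the dose range
#' (Levenberg-Marquardt), keeping the best solution. The Hill coefficient
#' is fixed to 1 by default - appropriate for a single-site channel blocker
#' where only the midpoint and ceiling are identified - and can be freed
#' with `fix_hill_n = NULL`.
#'
#' @param data A data frame with columns `concentration` and `response`
#'   (replicates as repeated rows; per-dose means are equally acceptable).
#' @param fix_hill_n Fixed Hill coefficient, or `NULL` to estimate it.
#' @param n_starts Number of log-spaced `ec50` starting values.
#' @return An object of class `hill_fit` with elements `ec50`, `emax`,
#'   `hill_n`, `residual_norm`, `fitted`, `data`, `flags`. Methods:
#'   [tidy()], [glance()], `predict()`, `autoplot()`.
#' @export
#' @examples
#' d <- simulate_dose_response(seed = 7)
#' fit <- hill_fit(d)
#' tidy(fit)
hill_fit <- function(data, fix_hill_n = 1, n_starts = 8) {
  stopifnot(all(c("concentration", "response") %in% names(data)))
  conc <- data$concentration
  resp <- data$response
  if (length(unique(conc)) < 3) {
    abort_domain("need at least 3 distinct concentrations")
  }
  if (any(conc < 0)) abort_domain("concentrations must be non-negative")

  # degenerate data: no dose-dependent signal to fit
  if (max(abs(resp)) < 1e-12 ||
      sd(tapply(resp, conc, mean)) < 1e-12) {
    out <- structure(
      list(ec50 = NA_real_, emax = mean(resp), hill_n = fix_hill_n %||% NA_real_,
           residual_norm = sqrt(sum((resp - mean(resp))^2)),
           fitted = rep(mean(resp), length(resp)), data = as_tibble(data),
           flags = "ec50_unidentifiable"),
      class = "hill_fit")
    return(out)
  }

  pos <- conc[conc > 0]
  starts <- exp(seq(log(min(pos) / 10), log(max(pos) * 10),
                    length.out = n_starts))
  emax0 <- resp[which.max(abs(resp))]

  best <- NULL
  for (s in starts) {
    fit <- tryCatch({
      if (is.null(fix_hill_n)) {
        minpack.lm::nlsLM(
          response ~ emax * concentration^exp(log_n) /
            (exp(log_ec50)^exp(log_n) + concentration^exp(log_n)),
          data = data.frame(concentration = conc, response = resp),
          start = list(emax = emax0, log_ec50 = log(s), log_n = 0),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        n <- fix_hill_n
        minpack.lm::nlsLM(
          response ~ emax * concentration^n /
            (exp(log_ec50)^n + concentration^n),
          data = data.frame(concentration = conc, response = resp),
          start = list(emax = emax0, log_ec50 = log(s)),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    abort_convergence("Hill fit failed to converge from any start; the data may be non-monotone or degenerate")
  }
  cf <- coef(best$fit)
  structure(
    list(ec50 = unname(exp(cf[["log_ec50"]])),
         emax = unname(cf[["emax"]]),
         hill_n = if (is.null(fix_hill_n)) unname(exp(cf[["log_n"]])) else fix_hill_n,
         residual_norm = sqrt(best$rss),
         fitted = as.numeric(stats::fitted(best$fit)),
         data = as_tibble(data),
         flags = character()),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> EC50 = %.4g, Emax = %.4g, n = %.3g (residual norm %.3g)\n",
              x$ec50, x$emax, x$hill_n, x$residual_norm))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentration else
    newdata$concentration
  if (length(object$flags) && "ec50_unidentifiable" %in% object$flags) {
    return(rep(object$emax, length(conc)))
  }
  hill_response(conc, object$ec50, object$emax, object$hill_n)
}

#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("ec50", "emax", "hill_n"),
         estimate = c(x$ec50, x$emax, x$hill_n))
}

#' @export
glance.hill_fit <- function(x, ...) {
  tibble(residual_norm = x$residual_norm, nobs = nrow(x$data),
         n_doses = length(unique(x$data$concentration)),
         flags = paste(x$flags, collapse = ";"))
}

#' @export
autoplot.hill_fit <- function(object, ...) {
  d <- object$data
  pos <- d$concentration[d$concentration > 0]
  grid <- tibble(concentration = exp(seq(log(min(pos) / 3),
                                         log(max(pos) * 3),
                                         length.out = 200)))
  grid$response <- predict(object, grid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration,
                                  y = .data$response)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration", y = "response",
                  title = sprintf("Hill fit: EC50 = %.3g, Emax = %.3g",
                                  object$ec50, object$emax)) +
    ggplot2::theme_minimal()
}
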