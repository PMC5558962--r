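#' Normalise a feature series to its 37 degC reference
#'
#' Divides each replicate's values by that replicate's value at the
#' reference temperature, so that X(37) = 1 per replicate (the relative
#' reference point of the Q10 law). Idempotent.
#'
#' @param series Data frame with columns `temperature`, `value` and
#'   optionally `replicate`.
#' @param t_ref Reference temperature, degC.
#' @return The series with `value` normalised.
#' @export
#' @examples
#' relative_changes(data.frame(temperature = c(37, 27), value = c(200, 250)))
relative_changes <- function(series, t_ref = 37) {
  if (!all(c("temperature", "value") %in% names(series))) {
    stop("series needs columns 'temperature' and 'value'", call. = FALSE)
  }
  if (is.null(series$replicate)) series$replicate <- 1L
  out <- lapply(split(series, series$replicate), function(d) {
    ref <- d$value[d$temperature == t_ref]
    if (length(ref) != 1 || !is.finite(ref) || ref <= 0) {
      stop("each replicate needs one positive value at the reference ",
           "temperature (", t_ref, " degC)", call. = FALSE)
    }
    d$value <- d$value / ref
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Median relative change across replicates
#'
#' Per-temperature median of the normalised values over all replicates
#' (electrodes), the robust aggregation step preceding the Q10 fit.
#'
#' @param series Normalised series from [relative_changes()].
#' @return Data frame with columns `temperature`, `value` (the median).
#' @export
aggregate_median <- function(series) {
  if (!all(c("temperature", "value") %in% names(series))) {
    stop("series needs columns 'temperature' and 'value'", call. = FALSE)
  }
  agg <- vapply(split(series$value, series$temperature), median, numeric(1))
  out <- data.frame(temperature = as.numeric(names(agg)), value = unname(agg))
  out[order(-out$temperature), , drop = FALSE]
}

#' Fit the Q10 relative-change law to a normalised series
#'
#' Nonlinear least squares of `X(T) = Q10^((T - 37)/10)` on the per-layer
#' normalised series. The estimate is initialised by linear regression of
#' `log X` on `(T - 37)/10` (exact for noise-free data) and refined on the
#' stated objective; deterministic given the data.
#'
#' @param series Data frame with columns `temperature`, `value`
#'   (normalised; see [relative_changes()] / [aggregate_median()]).
#' @param t_ref Reference temperature, degC.
#' @return List of class `"q10_estimate"` with `q10` and `rmse`.
#' @export
#' @examples
#' fit_q10(data.frame(temperature = c(37, 27), value = c(1, 2)))$q10  # 0.5
fit_q10 <- function(series, t_ref = 37) {
  if (length(unique(series$temperature)) < 2) {
    stop("need at least two temperatures", call. = FALSE)
  }
  if (any(series$value <= 0)) {
    stop("normalised values must be positive", call. = FALSE)
  }
  d <- data.frame(dtemp = (series$temperature - t_ref) / 10,
                  value = series$value)
  sse <- function(q) sum((d$value - q^d$dtemp)^2)
  init <- exp(unname(coef(lm(log(value) ~ 0 + dtemp, data = d))))
  cand <- init                       # exact for noise-free series
  fit <- try(suppressWarnings(
    nls(value ~ q10^dtemp, data = d, start = list(q10 = init),
        control = list(maxiter = 200, tol = 1e-10, warnOnly = TRUE))),
    silent = TRUE)
  if (!inherits(fit, "try-error")) cand <- c(cand, coef(fit)[["q10"]])
  opt <- optimize(function(lq) sse(exp(lq)), interval = log(init) + c(-2, 2),
                  tol = 1e-10)
  cand <- c(cand, exp(opt$minimum))
  q10 <- cand[which.min(vapply(cand, sse, numeric(1)))]
  rmse <- sqrt(sse(q10) / nrow(d))
  if (!is.finite(q10) || q10 <= 0) {
    stop("Q10 fit did not converge", call. = FALSE)
  }
  structure(list(q10 = unname(q10), rmse = rmse), class = "q10_estimate")
}

#' @export
print.q10_estimate <- function(x, ...) {
  cat(sprintf("Q10 = %.4g (RMSE %.3g)\n", x$q10, x$rmse))
  invisible(x)
}

#' Synthesise a noisy feature-vs-temperature series
#'
#' Generates replicate feature series from a known Q10 with multiplicative
#' lognormal noise (median 1, `sdlog = noise_cv`), emulating per-electrode
#' temperature-series tables for parameter-recovery testing.
#'
#' @param true_q10 Generating Q10 (> 0).
#' @param temperatures Temperatures in degC.
#' @param n_replicates Number of replicates (electrodes).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0); 0 gives the deterministic Q10 curve.
#' @param seed Integer seed; the output is reproducible per seed.
#' @param t_ref Reference temperature, degC.
#' @return Data frame with columns `replicate`, `temperature`, `value`.
#' @export
#' @examples
#' s <- synthesize_feature_series(1.5, seq(37, 27, -2), 3, 0.05, seed = 1)
#' fit_q10(aggregate_median(relative_changes(s)))
synthesize_feature_series <- function(true_q10, temperatures = seq(37, 27, -2),
                                      n_replicates = 18, noise_cv = 0.05,
                                      seed = 1, t_ref = 37) {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (true_q10 <= 0) stop("true_q10 must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  grid <- expand.grid(temperature = temperatures,
                      replicate = seq_len(n_replicates))
  mu <- true_q10^((grid$temperature - t_ref) / 10)
  noise <- if (noise_cv == 0) 1 else rlnorm(nrow(grid), 0, noise_cv)
  data.frame(replicate = grid$replicate, temperature = grid$temperature,
             value = mu * noise)
}
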