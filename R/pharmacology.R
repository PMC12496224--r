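#' Percent inhibition relative to vehicle
#'
#' Converts raw viability readouts to percent inhibition,
#' `100 * (1 - v / vehicle_mean)`. Values below 0 (growth stimulation)
#' are retained with a warning, not clipped.
#'
#' @param viability Numeric vector of raw well readouts.
#' @param vehicle_mean Mean readout of the vehicle (0-dose) wells; must be
#'   positive.
#' @return Percent-inhibition values (percentage points).
#' @export
percent_inhibition <- function(viability, vehicle_mean) {
  assert_scalar_number(vehicle_mean, "vehicle_mean")
  if (vehicle_mean <= 0) stop_ds("'vehicle_mean' must be > 0")
  out <- 100 * (1 - viability / vehicle_mean)
  if (any(out < 0, na.rm = TRUE))
    warn_ds("negative inhibition (growth stimulation) retained for %d well(s)",
            sum(out < 0, na.rm = TRUE))
  out
}

# Four-parameter logistic in log10-dose space. Positive hill means
# response decreases with dose (viability curves); the midpoint is
# f(log_ic50) = (top + bottom) / 2.
fourpl <- function(x_log10, top, bottom, log_ic50, hill) {
  bottom + (top - bottom) / (1 + 10^((x_log10 - log_ic50) * hill))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the "log(inhibitor) vs response -- variable
#' slope" model
#' \deqn{Y = Bottom + (Top - Bottom) / (1 + 10^{(X - LogIC50) \cdot Hill})}
#' with \eqn{X = \log_{10}(dose)}. Positive Hill means the response
#' decreases with dose. Zero-dose wells are excluded from the fit
#' (log10(0) is undefined; the vehicle anchors normalization, not the
#' curve). Optimization is multi-start Levenberg-Marquardt
#' ([minpack.lm::nlsLM]): a deterministic heuristic grid (Top = max
#' response, Bottom = min response, LogIC50 = log-dose nearest the
#' half-range crossing, Hill in 0.5/1/2) plus `n_restarts` seeded jitters
#' inside the parameter box; the lowest-RSS solution wins.
#'
#' @param doses Concentrations (nM), may include 0; at least 5 distinct
#'   nonzero doses required.
#' @param responses Percent viability (or any response), same length as
#'   `doses`.
#' @param bounds Optional named list of `c(lower, upper)` boxes for
#'   `top`, `bottom`, `log_ic50`, `hill`; defaults span the data range
#'   generously with Hill in [0.05, 10].
#' @param n_restarts Number of additional randomized starts (default 5).
#' @param seed Integer seed for the jittered starts.
#' @return Object of class `dose_response_fit`: list with `top`,
#'   `bottom`, `log_ic50`, `hill`, `rss`, `converged`, `n_points`.
#' @examples
#' d <- c(1, 10, 100, 250, 500)
#' y <- 0 + (100 - 0) / (1 + 10^((log10(d) - 2) * 1))
#' fit <- fit_4pl(d, y)
#' ic50(fit)  # 100 nM
#' @export
fit_4pl <- function(doses, responses, bounds = NULL, n_restarts = 5,
                    seed = 1) {
  if (length(doses) != length(responses))
    stop_ds("'doses' and 'responses' must have equal length")
  if (!all(is.finite(responses))) stop_ds("responses must be finite")
  if (any(doses < 0)) stop_ds("doses must be >= 0")
  keep <- doses > 0
  if (length(unique(doses[keep])) < 5L)
    stop_ds("need at least 5 distinct nonzero doses, got %d",
            length(unique(doses[keep])))
  x <- log10(doses[keep])
  y <- responses[keep]

  rng_y <- range(y); rng_x <- range(x)
  default_bounds <- list(
    top = c(rng_y[1], rng_y[2] + 0.5 * max(diff(rng_y), 1)),
    bottom = c(rng_y[1] - 0.5 * max(diff(rng_y), 1), rng_y[2]),
    log_ic50 = c(rng_x[1] - 3, rng_x[2] + 3),
    hill = c(0.05, 10))
  if (!is.null(bounds)) default_bounds[names(bounds)] <- bounds
  b <- default_bounds
  lower <- c(top = b$top[1], bottom = b$bottom[1],
             log_ic50 = b$log_ic50[1], hill = b$hill[1])
  upper <- c(top = b$top[2], bottom = b$bottom[2],
             log_ic50 = b$log_ic50[2], hill = b$hill[2])

  # heuristic starts: half-range crossing locates LogIC50
  half <- (max(y) + min(y)) / 2
  lx_mid <- x[which.min(abs(y - half))]
  starts <- lapply(c(0.5, 1, 2), function(h)
    c(top = max(y), bottom = min(y), log_ic50 = lx_mid, hill = h))
  if (n_restarts > 0) {
    jit <- withr::with_seed(seed, lapply(seq_len(n_restarts), function(i)
      vapply(c("top", "bottom", "log_ic50", "hill"), function(p)
        stats::runif(1, b[[p]][1], b[[p]][2]), numeric(1))))
    starts <- c(starts, jit)
  }
  clamp <- function(st) pmin(pmax(st, lower + 1e-9), upper - 1e-9)

  best <- NULL
  dat <- data.frame(x = x, y = y)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^((x - log_ic50) * hill)),
        data = dat, start = as.list(clamp(st)),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    conv <- isTRUE(fit$convInfo$isConv)
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (conv && !best$converged && rss <= best$rss + 1e-12)) {
      cf <- stats::coef(fit)
      best <- list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                   log_ic50 = unname(cf["log_ic50"]),
                   hill = unname(cf["hill"]), rss = rss, converged = conv)
    }
  }
  if (is.null(best))
    best <- list(top = max(y), bottom = min(y), log_ic50 = lx_mid,
                 hill = 1, rss = Inf, converged = FALSE)
  best$n_points <- length(y)
  class(best) <- "dose_response_fit"
  best
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(paste0("dose_response_fit: Top = %.2f, Bottom = %.2f, ",
                     "LogIC50 = %.4f, Hill = %.3f (RSS %.3g, %s)\n"),
              x$top, x$bottom, x$log_ic50, x$hill, x$rss,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Predicted response from a 4PL fit
#'
#' @param fit A `dose_response_fit`.
#' @param doses Concentrations (nM), > 0.
#' @return Predicted responses.
#' @export
predict_4pl <- function(fit, doses) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (any(doses <= 0)) stop_ds("doses must be > 0 for curve prediction")
  fourpl(log10(doses), fit$top, fit$bottom, fit$log_ic50, fit$hill)
}

#' Half-maximal inhibitory concentration from a 4PL fit
#'
#' @param fit A converged `dose_response_fit`.
#' @return IC50 in the fit's dose units (nM), `10^log_ic50`.
#' @export
ic50 <- function(fit) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (!fit$converged)
    stop_ds("fit did not converge; IC50 is not reliable")
  10^fit$log_ic50
}

#' Expected combination inhibition under the HSA reference model
#'
#' The highest-single-agent model takes the expected effect of a dose
#' pair to be the maximum of the two monotherapy responses at the
#' corresponding concentrations:
#' `E(a, b) = max(I(a, 0), I(0, b))` for every combination cell
#' (both doses > 0).
#'
#' @param combo A [combination_matrix] with monotherapy margins.
#' @return Matrix of expected inhibition over the combination cells,
#'   dimension `(length(doses_a) - 1) x (length(doses_b) - 1)`.
#' @export
hsa_expected <- function(combo) {
  stopifnot(inherits(combo, "combination_matrix"))
  inh <- combo$inhibition
  if (nrow(inh) < 2L || ncol(inh) < 2L)
    stop_ds("combination matrix needs at least one nonzero dose per drug")
  margin_a <- inh[-1L, 1L]   # drug A alone
  margin_b <- inh[1L, -1L]   # drug B alone
  outer(margin_a, margin_b, pmax)
}

#' HSA synergy score and classification for a dose grid
#'
#' Scores a combination as the mean excess of observed percent inhibition
#' over the HSA expectation across all combination cells (both doses
#' > 0); monotherapy margins are not averaged in. The score is
#' classified with the standard bands: below -10 antagonistic, -10 to 10
#' (inclusive) additive, above 10 synergistic.
#'
#' @param combo A [combination_matrix].
#' @return Object of class `synergy_result`: list with `score`, `excess`
#'   (matrix over combination cells), `reference = "HSA"` and
#'   `classification`.
#' @export
synergy_score <- function(combo) {
  expected <- hsa_expected(combo)
  observed <- combo$inhibition[-1L, -1L, drop = FALSE]
  excess <- observed - expected
  score <- mean(excess)
  structure(list(score = score, excess = excess, reference = "HSA",
                 classification = classify_synergy(score),
                 drug_a = combo$drug_a, drug_b = combo$drug_b),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("synergy_result (%s + %s, %s reference): score = %.3f -> %s\n",
              x$drug_a, x$drug_b, x$reference, x$score, x$classification))
  invisible(x)
}

#' Classify a synergy score into interaction bands
#'
#' Bands: score < -10 antagonistic; -10 <= score <= 10 additive;
#' score > 10 synergistic. The endpoints are additive (the band is the
#' closed interval).
#'
#' @param score A finite synergy score (percentage points).
#' @return `"antagonistic"`, `"additive"` or `"synergistic"`.
#' @examples
#' classify_synergy(4.484)   # "additive"
#' classify_synergy(10.376)  # "synergistic"
#' @export
classify_synergy <- function(score) {
  if (!is.numeric(score) || length(score) != 1L || !is.finite(score))
    stop_ds("'score' must be a single finite number")
  if (score < -10) "antagonistic"
  else if (score > 10) "synergistic"
  else "additive"
}
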