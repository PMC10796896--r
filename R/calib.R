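# Linear calibration: OLS fit of channel grayscale on concentration,
# dispersion estimation, 3-sigma/10-sigma detection limits, inverse
# prediction, and best source/channel selection.

#' Fit a linear calibration curve
#'
#' Ordinary least squares of a channel's average grayscale on analyte
#' concentration (mg/dL), the classic straight-line calibration
#' \eqn{y = m\,c + b}. The coefficient of determination is
#' \eqn{R^2 = 1 - SSE/SST} (defined as 1 when both are zero). When a
#' dispersion estimate is available -- the standard deviation of blank
#' replicate means (`sigma_method = "blank_sd"`, requires `blanks`) or the
#' residual standard error (`"residual_se"`, requires at least 3 points) --
#' the detection and quantification limits \eqn{LOD = 3\sigma/|m|},
#' \eqn{LOQ = 10\sigma/|m|} are attached.
#'
#' @param formula Model formula, response grayscale on concentration, e.g.
#'   `mean_g ~ concentration`.
#' @param data Data frame with the formula's variables; one row per
#'   calibration standard.
#' @param blanks Optional numeric vector (>= 2) of blank replicate channel
#'   means for `sigma_method = "blank_sd"`.
#' @param sigma_method How to estimate the blank dispersion `sigma`;
#'   `"none"` leaves the limits unset.
#' @param source,channel Optional labels (light source, colour channel)
#'   carried into reports.
#' @return An object of class `"calib"`: list with elements `m` (slope,
#'   grayscale per mg/dL), `b` (intercept, grayscale), `r_squared`, `n`,
#'   `sigma`, `sigma_method`, `lod`, `loq` (mg/dL), the underlying `lm` fit,
#'   and the data used.
#' @seealso [detection_limits()], [predict.calib()], [select_best()]
#' @examples
#' d <- data.frame(concentration = seq(0.1, 2, length.out = 12))
#' d$mean_g <- -15.669 * d$concentration + 240.34
#' calib(mean_g ~ concentration, d, blanks = c(238, 240, 242))
#' @export
calib <- function(formula, data, blanks = NULL,
                  sigma_method = c("blank_sd", "residual_se", "none"),
                  source = NULL, channel = NULL) {
  sigma_method <- match.arg(sigma_method)
  if (sigma_method == "blank_sd" && is.null(blanks)) sigma_method <- "none"
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (ncol(mf) != 2L) stop("expected a single predictor (concentration)")
  x <- mf[[2L]]
  n <- length(y)
  if (n < 2L) stop("at least 2 calibration points are required")
  if (length(unique(x)) < 2L)
    stop("degenerate design: all concentrations identical")
  fit <- stats::lm(formula, data = data)
  m <- unname(stats::coef(fit)[2L])
  b <- unname(stats::coef(fit)[1L])
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sse / sst
  obj <- structure(list(m = m, b = b, r_squared = r2, n = n,
                        sigma = NA_real_, sigma_method = sigma_method,
                        lod = NA_real_, loq = NA_real_,
                        fit = fit, data = data.frame(concentration = x,
                                                     grayscale = y),
                        source = source, channel = channel,
                        call = match.call()),
                   class = "calib")
  if (sigma_method != "none") {
    obj$sigma <- switch(sigma_method,
                        blank_sd = estimate_sigma(blanks, "blank_sd"),
                        residual_se = estimate_sigma(obj, "residual_se"))
    lim <- detection_limits(obj$sigma, m)
    obj$lod <- lim[["lod"]]; obj$loq <- lim[["loq"]]
  }
  obj
}

#' Fit one channel of a calibration series
#'
#' Convenience wrapper around [calib()] for the standard stats table
#' produced by the imaging stage (columns `concentration`, `mean_r`,
#' `mean_g`, `mean_b`, `mean_y`).
#'
#' @param points Data frame of calibration points.
#' @param channel One of `"R"`, `"G"`, `"B"`, `"Y"`.
#' @param ... Passed to [calib()].
#' @return A `"calib"` object.
#' @export
fit_line <- function(points, channel = c("G", "R", "B", "Y"), ...) {
  channel <- match.arg(channel)
  col <- c(R = "mean_r", G = "mean_g", B = "mean_b", Y = "mean_y")[[channel]]
  if (!col %in% names(points)) stop("points lack a '", col, "' column")
  calib(stats::reformulate("concentration", response = col), points,
        channel = channel, ...)
}

#' Estimate the blank dispersion sigma
#'
#' Two conventions: `blank_sd`, the sample standard deviation (n-1
#' denominator) of blank replicate channel means; `residual_se`, the
#' residual standard error \eqn{\sqrt{SSE/(n-2)}} of a fitted calibration.
#'
#' @param x Numeric vector of blank means (`blank_sd`) or a `"calib"`
#'   object (`residual_se`).
#' @param method `"blank_sd"` or `"residual_se"`.
#' @return Non-negative scalar, grayscale units.
#' @export
estimate_sigma <- function(x, method = c("blank_sd", "residual_se")) {
  method <- match.arg(method)
  if (method == "blank_sd") {
    x <- as.numeric(x)
    if (length(x) < 2L) stop("blank_sd requires at least 2 blank replicates")
    return(stats::sd(x))
  }
  if (!inherits(x, "calib")) stop("residual_se requires a fitted calibration")
  if (x$n < 3L) stop("residual_se requires at least 3 calibration points")
  sqrt(sum(stats::residuals(x$fit)^2) / (x$n - 2))
}

#' Detection and quantification limits
#'
#' The 3-sigma / 10-sigma convention: \eqn{LOD = 3\sigma/|m|},
#' \eqn{LOQ = 10\sigma/|m|}, so LOQ/LOD = 10/3 exactly.
#'
#' @param sigma Blank dispersion, grayscale units, >= 0.
#' @param slope Calibration slope, grayscale per mg/dL, nonzero.
#' @return Named numeric vector `c(lod, loq)` in mg/dL.
#' @examples
#' detection_limits(2.3974, -15.669)  # ~ c(0.459, 1.530)
#' @export
detection_limits <- function(sigma, slope) {
  if (slope == 0) stop("detection limit undefined for zero slope")
  if (sigma < 0) stop("sigma must be non-negative")
  c(lod = 3 * sigma / abs(slope), loq = 10 * sigma / abs(slope))
}

#' Rank calibration curves and pick the best source/channel pair
#'
#' Curves are sorted by descending \eqn{R^2}. Ties are broken by preferring
#' the channel that matches the light source's colour name (G under the
#' green LED, etc.), then by channel order G, R, B, Y, then by source name
#' for full determinism.
#'
#' @param curves List of `"calib"` objects (or a `"calib_set"`).
#' @return List of class `"calib_ranking"`: `ranking` (data frame),
#'   `best` (the top `"calib"` object).
#' @export
select_best <- function(curves) {
  if (inherits(curves, "calib_set")) curves <- curves$curves
  if (inherits(curves, "calib")) curves <- list(curves)
  if (!length(curves)) stop("no calibration curves to rank")
  chan_order <- c(G = 1L, R = 2L, B = 3L, Y = 4L)
  tab <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(source = cv$source %||% "?", channel = cv$channel %||% "?",
               slope = cv$m, intercept = cv$b, r_squared = cv$r_squared,
               sigma = cv$sigma, lod = cv$lod, loq = cv$loq, n = cv$n,
               stringsAsFactors = FALSE)
  }))
  matches <- mapply(function(s, ch) {
    identical(toupper(substr(s, 1L, 1L)), ch)
  }, tab$source, tab$channel)
  ord <- order(-tab$r_squared, !matches,
               chan_order[tab$channel], tab$source)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(ranking = tab, best = curves[[ord[1L]]]),
            class = "calib_ranking")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.calib_ranking <- function(x, ...) {
  cat("Calibration ranking (best first):\n")
  print(x$ranking, digits = 4)
  cat(sprintf("Best combination: %s / %s channel\n",
              x$best$source %||% "?", x$best$channel %||% "?"))
  invisible(x)
}

#' Inverse prediction from a calibration curve
#'
#' Converts a measured average grayscale back to a concentration estimate
#' \eqn{\hat c = (y - b)/m} and classifies it against the detection limits:
#' `below_lod` (< LOD; negative estimates are clamped to 0),
#' `detected_not_quantifiable` (LOD <= c < LOQ), or `quantifiable`
#' (>= LOQ).
#'
#' @param curve A `"calib"` object with computed limits.
#' @param grayscale Measured average grayscale value(s).
#' @return Data frame of class `"quant_result"` with columns
#'   `concentration_estimate` and `status`.
#' @export
invert_concentration <- function(curve, grayscale) {
  if (!inherits(curve, "calib")) stop("curve must be a 'calib' object")
  if (curve$m == 0) stop("inverse prediction undefined for zero slope")
  if (is.na(curve$lod) || is.na(curve$loq))
    stop("calibration has no detection limits; fit with a sigma method")
  est <- (grayscale - curve$b) / curve$m
  status <- ifelse(est >= curve$loq, "quantifiable",
                   ifelse(est >= curve$lod, "detected_not_quantifiable",
                          "below_lod"))
  est <- pmax(est, 0)
  structure(data.frame(concentration_estimate = est, status = status,
                       stringsAsFactors = FALSE),
            class = c("quant_result", "data.frame"), curve = curve)
}

# --- methods for the "calib" class ------------------------------------------

#' @export
print.calib <- function(x, digits = 4, ...) {
  lab <- paste(c(x$source, if (!is.null(x$channel)) paste0(x$channel, " channel")),
               collapse = " / ")
  if (nzchar(lab)) cat(lab, "calibration\n") else cat("Calibration curve\n")
  cat(sprintf("  y = %s x + %s   (grayscale vs mg/dL, n = %d)\n",
              format(x$m, digits = digits), format(x$b, digits = digits), x$n))
  cat(sprintf("  R-squared = %s\n", format(x$r_squared, digits = digits)))
  if (!is.na(x$sigma))
    cat(sprintf("  sigma = %s (%s); LOD = %s, LOQ = %s mg/dL\n",
                format(x$sigma, digits = digits), x$sigma_method,
                format(x$lod, digits = digits),
                format(x$loq, digits = digits)))
  invisible(x)
}

#' @export
summary.calib <- function(object, ...) {
  s <- summary(object$fit)
  structure(list(calib = object, lm_summary = s,
                 slope_se = s$coefficients[2L, 2L],
                 intercept_se = s$coefficients[1L, 2L]),
            class = "summary.calib")
}

#' @export
print.summary.calib <- function(x, digits = 4, ...) {
  print(x$calib, digits = digits)
  cat(sprintf("  slope SE = %s, intercept SE = %s\n",
              format(x$slope_se, digits = digits),
              format(x$intercept_se, digits = digits)))
  invisible(x)
}

#' @export
coef.calib <- function(object, ...) {
  c(intercept = object$b, slope = object$m)
}

#' @export
residuals.calib <- function(object, ...) stats::residuals(object$fit)

#' Predict from a calibration curve
#'
#' By default performs inverse prediction (grayscale to concentration, with
#' limit-of-detection status, see [invert_concentration()]); with
#' `type = "response"` evaluates the forward line \eqn{m\,c + b}.
#'
#' @param object A `"calib"` object.
#' @param newdata Numeric vector: grayscale values (inverse) or
#'   concentrations (forward). Defaults to the training concentrations for
#'   `type = "response"`.
#' @param type `"concentration"` (inverse, default) or `"response"`.
#' @param ... Unused.
#' @return See [invert_concentration()] for the inverse direction; a
#'   numeric vector for the forward direction.
#' @export
predict.calib <- function(object, newdata = NULL,
                          type = c("concentration", "response"), ...) {
  type <- match.arg(type)
  if (type == "response") {
    conc <- if (is.null(newdata)) object$data$concentration else as.numeric(newdata)
    return(object$m * conc + object$b)
  }
  if (is.null(newdata)) stop("inverse prediction needs grayscale values")
  invert_concentration(object, as.numeric(newdata))
}

#' Simulate calibration responses
#'
#' Draws new grayscale responses at the fitted concentrations from
#' \eqn{m\,c + b + N(0, \sigma)}, using the curve's dispersion estimate.
#'
#' @param object A `"calib"` object with a sigma estimate.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated responses.
#' @export
simulate.calib <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.na(object$sigma)) stop("simulate requires a sigma estimate")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  conc <- object$data$concentration
  out <- as.data.frame(replicate(nsim, object$m * conc + object$b +
                                   stats::rnorm(length(conc), 0, object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a calibration curve
#'
#' Scatter of average grayscale against concentration with the fitted line
#' and an annotation of the equation, R-squared and LOD.
#'
#' @param x A `"calib"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.calib <- function(x, ...) {
  d <- x$data
  graphics::plot(d$concentration, d$grayscale,
                 xlab = "concentration (mg/dL)",
                 ylab = paste0("average grayscale",
                               if (!is.null(x$channel)) paste0(" (", x$channel, ")")),
                 pch = 19, ...)
  graphics::abline(a = x$b, b = x$m, col = "firebrick", lwd = 2)
  lab <- sprintf("y = %.3f x + %.2f\nR² = %.4f%s", x$m, x$b, x$r_squared,
                 if (!is.na(x$lod)) sprintf("\nLOD = %.3f mg/dL", x$lod) else "")
  graphics::legend("topright", legend = lab, bty = "n")
  invisible(x)
}

# save/restore the global RNG state so seeded helpers do not disturb the
# caller's stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
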