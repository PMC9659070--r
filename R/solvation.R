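# SASA - Log10(PF) calibration. Log(PF) of residues exposed to bulk
# solvent scales linearly with sidechain SASA; the regression is fitted on
# a designated calibration set (typically non-polar M/F/W/Y oxidations)
# and residues whose Log(PF) falls below the lower 95% confidence limit of
# that relation are flagged as anomalously low-PF (ALPF) — the diagnostic
# signature of structured-water proximity.

#' Fit the SASA - log(PF) calibration regression
#'
#' Ordinary least squares of log(PF) on SASA with a pointwise confidence
#' band for the mean response (band for a new observation available via
#' `interval = "prediction"` in [predict.sasa_pf_fit()]).
#'
#' @param sasa Numeric vector of residue SASA values (A^2).
#' @param logPF Numeric vector of log10 protection factors, same length.
#' @param level Confidence level for the band (default 0.95).
#' @return Object of class `sasa_pf_fit`: list with `slope`, `intercept`,
#'   `pearson_r`, `n`, `level`, and the underlying `lm` fit.
#' @export
fit_sasa_logpf <- function(sasa, logPF, level = 0.95) {
  ok <- is.finite(sasa) & is.finite(logPF)
  sasa <- sasa[ok]; logPF <- logPF[ok]
  n <- length(sasa)
  if (n < 3) stop("need at least 3 points to fit the calibration",
                  call. = FALSE)
  if (stats::sd(sasa) == 0) stop("degenerate predictor: all SASA equal",
                                 call. = FALSE)
  fit <- stats::lm(logPF ~ sasa, data = data.frame(sasa = sasa, logPF = logPF))
  out <- list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
              pearson_r = stats::cor(sasa, logPF), n = n, level = level,
              lm = fit)
  class(out) <- "sasa_pf_fit"
  out
}

#' @export
print.sasa_pf_fit <- function(x, ...) {
  cat("SASA - log(PF) calibration\n")
  cat(sprintf("  logPF = %.4g + %.4g * SASA   (n = %d, Pearson r = %.3f)\n",
              x$intercept, x$slope, x$n, x$pearson_r))
  cat(sprintf("  %.0f%% confidence band for the mean response\n",
              100 * x$level))
  invisible(x)
}

#' @export
coef.sasa_pf_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predicted log(PF) and confidence band at given SASA values
#'
#' @param object A `sasa_pf_fit`.
#' @param sasa SASA values at which to evaluate.
#' @param interval `"confidence"` (band for the mean response, default) or
#'   `"prediction"` (band for a new observation).
#' @param level Confidence level; defaults to the level the model was
#'   fitted with.
#' @param ... Unused.
#' @return Data frame with columns `sasa`, `fit`, `lwr`, `upr`.
#' @export
predict.sasa_pf_fit <- function(object, sasa,
                                interval = c("confidence", "prediction"),
                                level = object$level, ...) {
  interval <- match.arg(interval)
  p <- stats::predict(object$lm, newdata = data.frame(sasa = sasa),
                      interval = interval, level = level)
  data.frame(sasa = sasa, fit = p[, "fit"], lwr = p[, "lwr"],
             upr = p[, "upr"])
}

#' @export
plot.sasa_pf_fit <- function(x, ...) {
  d <- x$lm$model
  grid <- seq(min(d$sasa), max(d$sasa), length.out = 100)
  band <- predict(x, grid)
  plot(d$sasa, d$logPF, xlab = expression(SASA ~ (ring(A)^2)),
       ylab = expression(log[10](PF)), ...)
  lines(grid, band$fit, lty = 2, lwd = 2)
  lines(grid, band$lwr, lty = 3)
  lines(grid, band$upr, lty = 3)
  invisible(x)
}

#' Classify residues against the calibration band
#'
#' A residue is `anomalous_low` when its log(PF) lies strictly below the
#' lower confidence limit of the calibration regression evaluated at the
#' residue's SASA; residues on or above the limit are `normal`. Records
#' with missing SASA or log(PF) are returned as `not_classified`.
#'
#' @param records Data frame with columns `residue` (index), `sasa`,
#'   `logPF` (extra columns are carried through).
#' @param model A `sasa_pf_fit`.
#' @param level Band level (defaults to the model's).
#' @return `records` with added columns `band_lwr` and
#'   `status` in {`normal`, `anomalous_low`, `not_classified`}.
#' @export
classify_alpf <- function(records, model, level = model$level) {
  stopifnot(inherits(model, "sasa_pf_fit"))
  out <- as.data.frame(records)
  ok <- is.finite(out$sasa) & is.finite(out$logPF)
  out$band_lwr <- NA_real_
  out$status <- "not_classified"
  if (any(!ok)) {
    message(sum(!ok), " record(s) missing SASA or logPF: not classified")
  }
  if (any(ok)) {
    band <- predict(model, out$sasa[ok], level = level)
    out$band_lwr[ok] <- band$lwr
    out$status[ok] <- ifelse(out$logPF[ok] < band$lwr, "anomalous_low",
                             "normal")
  }
  out
}

#' Per-residue activation deltas and group summaries
#'
#' Differences value(A) - value(B) of log(PF) and SASA for residues shared
#' between two states (matched by residue index, so substituted positions
#' such as 13D/K compare by position; a type mismatch is flagged in the
#' `substituted` column).
#'
#' @param stateA,stateB Data frames with columns `residue`, `residue_type`,
#'   and any of `logPF`, `sasa`.
#' @param groups Optional named list of residue-index vectors defining
#'   groups to summarize (mean +/- SD per group).
#' @return List with `per_residue` (residue, substituted, delta_logPF,
#'   delta_sasa) and `group_summary` (group, metric, mean, sd, n).
#' @export
delta_metrics <- function(stateA, stateB, groups = NULL) {
  shared <- intersect(stateA$residue, stateB$residue)
  if (length(shared) == 0) stop("no shared residues between states",
                                call. = FALSE)
  ia <- match(shared, stateA$residue)
  ib <- match(shared, stateB$residue)
  per <- data.frame(residue = shared,
                    substituted = stateA$residue_type[ia] !=
                      stateB$residue_type[ib])
  for (m in c("logPF", "sasa")) {
    if (m %in% names(stateA) && m %in% names(stateB)) {
      per[[paste0("delta_", tolower(m))]] <- stateA[[m]][ia] - stateB[[m]][ib]
    }
  }
  group_summary <- NULL
  if (!is.null(groups)) {
    rows <- list()
    metrics <- grep("^delta_", names(per), value = TRUE)
    for (g in names(groups)) {
      sel <- per$residue %in% groups[[g]]
      for (m in metrics) {
        v <- per[[m]][sel]
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, metric = m,
          mean = if (length(v)) mean(v) else NA_real_,
          sd = if (length(v) > 1) stats::sd(v) else 0,
          n = length(v))
      }
    }
    group_summary <- do.call(rbind, rows)
  }
  list(per_residue = per, group_summary = group_summary)
}
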