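# Dose-response analysis: oxidized fraction F per dose, weighted
# single-exponential decay of the unoxidized fraction, and protection
# factors PF = S / IR.

#' Default intrinsic-reactivity table
#'
#' Intrinsic reactivity (IR) is the residue-type-specific susceptibility of a
#' sidechain to hydroxy-radical oxidation; dividing the fitted oxidation rate
#' by IR removes the chemistry so that the protection factor reflects solvent
#' accessibility alone. The default table carries the two anchored values
#' (lysine 2.2, aspartate 0.42); values for other residue types are
#' scale-dependent and must be supplied by the user (or by the synthetic-data
#' generator), e.g. via [read_ir_table()].
#'
#' @param extra Named numeric vector of additional `type = IR` entries to
#'   merge (all must be > 0). Entries for K and D override the defaults.
#' @return Named numeric vector, one-letter residue types as names.
#' @export
ir_table <- function(extra = NULL) {
  tab <- c(K = 2.2, D = 0.42)
  if (!is.null(extra)) {
    if (any(extra <= 0)) stop("IR values must be > 0", call. = FALSE)
    tab[names(extra)] <- extra
  }
  tab
}

#' Read an intrinsic-reactivity table from CSV
#'
#' @param path CSV with columns `residue_type` (one-letter) and `ir`.
#' @return Named numeric vector as in [ir_table()].
#' @export
read_ir_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("residue_type", "ir") %in% names(df))) {
    stop("format error: missing column(s): ",
         paste(setdiff(c("residue_type", "ir"), names(df)), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$ir <= 0)) stop("IR values must be > 0", call. = FALSE)
  ir_table(extra = setNames(df$ir, df$residue_type))
}

#' Oxidized fraction per dose for one residue
#'
#' Converts compiled oxidized/unoxidized areas into the oxidized fraction
#' F = area_ox / (area_ox + area_unox) at each dose point. Technical
#' replicates (a `replicate` column) are averaged per dose and the standard
#' error of F across replicates is propagated.
#'
#' @param table A `residue_area_table` (or any data frame with columns
#'   `dose_id`, `area_ox`, `area_unox`) restricted to a single residue, with
#'   an optional `replicate` column. `dose_id` must be numeric or coercible
#'   to the numeric dose.
#' @param residue Optional residue index to subset `table` by its `residue`
#'   column.
#' @return Data frame of class `dose_response_series` with columns `dose`
#'   (numeric, strictly increasing), `F`, and `se` (NA when replicates are
#'   unavailable). Dose points with zero total area are dropped with a
#'   warning.
#' @export
oxidized_fraction <- function(table, residue = NULL) {
  df <- as.data.frame(table)
  if (!is.null(residue)) df <- df[df$residue == residue, , drop = FALSE]
  if (nrow(df) == 0) stop("no rows for the requested residue", call. = FALSE)
  tot <- df$area_ox + df$area_unox
  if (any(tot <= 0)) {
    warning(sprintf("%d dose point(s) with zero total area dropped",
                    sum(tot <= 0)))
    df <- df[tot > 0, , drop = FALSE]
  }
  dose <- suppressWarnings(as.numeric(as.character(df$dose_id)))
  if (anyNA(dose)) stop("dose_id must be numeric exposure values", call. = FALSE)
  f <- df$area_ox / (df$area_ox + df$area_unox)
  if ("replicate" %in% names(df)) {
    sp <- split(seq_along(f), dose)
    dose_u <- as.numeric(names(sp))
    fm <- vapply(sp, function(i) mean(f[i]), 0)
    se <- vapply(sp, function(i)
      if (length(i) > 1) stats::sd(f[i]) / sqrt(length(i)) else NA_real_, 0)
    ord <- order(dose_u)
    out <- data.frame(dose = dose_u[ord], F = unname(fm)[ord],
                      se = unname(se)[ord])
  } else {
    ord <- order(dose)
    out <- data.frame(dose = dose[ord], F = f[ord], se = NA_real_)
  }
  if (anyDuplicated(out$dose)) stop("duplicate dose values", call. = FALSE)
  rt <- unique(df$residue_type)
  attr(out, "residue") <- if (!is.null(residue)) residue else unique(df$residue)
  attr(out, "residue_type") <- if (length(rt) == 1) rt else NA_character_
  class(out) <- c("dose_response_series", class(out))
  out
}

#' Fit a single-exponential decay to the unoxidized fraction
#'
#' Fits (1 - F) = exp(-S * dose) by weighted least squares. When every F < 1
#' the fit runs as a weighted linear regression of log(1 - F) on dose through
#' the origin (the model has no amplitude: F(0) = 0); otherwise it falls back
#' to a bound-constrained nonlinear fit. Weights are the reciprocal of the
#' per-point standard error of F when available, uniform otherwise.
#'
#' When the fit runs in log space the reciprocal-SE weights are applied on
#' the transformed scale: var(log(1 - F)) = var(F) / (1 - F)^2 by the delta
#' method, so the regression weights are ((1 - F) / se)^2; without per-point
#' SEs the (1 - F)^2 factor alone is used (homoscedastic noise on F). This
#' keeps nearly saturated dose points (F -> 1), whose log-residuals blow up,
#' from dominating the slope.
#'
#' @param series A `dose_response_series` (or data frame with `dose`, `F`
#'   and optionally `se`).
#' @param weights `"reciprocal-se"` (default) or `"uniform"` (unit weights
#'   in the fitting space).
#' @return Object of class `decay_fit`: list with elements `S` (constrained
#'   >= 0), `S_se`, `fitted`, `residuals`, `method`, `data`.
#' @export
fit_decay <- function(series, weights = c("reciprocal-se", "uniform")) {
  weights <- match.arg(weights)
  df <- as.data.frame(series)
  stopifnot(all(c("dose", "F") %in% names(df)))
  if (nrow(df) < 3) stop("fit error: fewer than 3 dose points", call. = FALSE)
  if (any(df$F < 0 | df$F > 1)) {
    stop("oxidized fractions must lie in [0, 1]", call. = FALSE)
  }
  n <- nrow(df)
  se <- if ("se" %in% names(df)) df$se else rep(NA_real_, n)
  have_se <- any(is.finite(se) & se > 0)
  if (have_se) {
    pos <- is.finite(se) & se > 0
    se[!pos] <- min(se[pos])   # unknown/zero SEs get the best observed SE
  }
  if (all(df$F < 1)) {
    y <- log(1 - df$F)
    dat <- data.frame(dose = df$dose, y = y)
    if (weights == "uniform") {
      fit <- stats::lm(y ~ 0 + dose, data = dat)
    } else {
      # two-pass reweighting: a first fit with observation-based weights,
      # then weights recomputed from the fitted curve so they are not
      # correlated with the per-point noise
      w <- if (have_se) ((1 - df$F) / se)^2 else (1 - df$F)^2
      fit <- stats::lm(y ~ 0 + dose, data = dat, weights = w)
      u_hat <- exp(pmin(stats::fitted(fit), 0))
      w2 <- if (have_se) (u_hat / se)^2 else u_hat^2
      fit <- stats::lm(y ~ 0 + dose, data = dat, weights = w2)
    }
    s <- -unname(coef(fit)[1])
    s_se <- sqrt(stats::vcov(fit)[1, 1])
    method <- "weighted log-linear"
  } else {
    w <- if (weights == "reciprocal-se" && have_se) 1 / se^2 else rep(1, n)
    fit <- tryCatch(
      minpack.lm::nlsLM((1 - F) ~ exp(-S * dose),
                        data = df, start = list(S = 0.1), lower = c(S = 0),
                        weights = w),
      error = function(e) stop("fit error: nonlinear fit failed: ",
                               conditionMessage(e), call. = FALSE))
    s <- unname(coef(fit)["S"])
    s_se <- sqrt(stats::vcov(fit)["S", "S"])
    method <- "nonlinear (bound-constrained)"
  }
  s_fit <- max(s, 0)
  fitted <- exp(-s_fit * df$dose)
  out <- list(S = s_fit, S_se = s_se, method = method,
              fitted = fitted, residuals = (1 - df$F) - fitted,
              data = df, weights = w)
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Single-exponential decay fit (1 - F) = exp(-S * dose)\n")
  cat(sprintf("  S = %.6g  (SE %.3g), %d dose points, %s\n",
              x$S, x$S_se, nrow(x$data), x$method))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) c(S = object$S)

#' @export
residuals.decay_fit <- function(object, ...) object$residuals

#' @export
predict.decay_fit <- function(object, newdose = NULL, ...) {
  d <- if (is.null(newdose)) object$data$dose else newdose
  1 - exp(-object$S * d)   # predicted oxidized fraction
}

#' Protection factor from a fitted oxidation rate
#'
#' PF = S / IR: the fitted oxidation rate normalized by the residue type's
#' intrinsic reactivity, so that log10(PF) tracks solvent accessibility.
#'
#' @param S Fitted decay slope (per dose unit), >= 0. May also be a
#'   `decay_fit`, in which case its slope and SE are used.
#' @param residue_type One-letter residue type.
#' @param ir Named IR vector (see [ir_table()]).
#' @param S_se Optional standard error of S (propagated to `PF_se`).
#' @param log_base Base for the log-PF column (default 10).
#' @return One-row data frame of class `protection_record`: `residue_type`,
#'   `S`, `S_se`, `IR`, `PF`, `logPF` (NA when PF = 0).
#' @export
protection_factor <- function(S, residue_type, ir = ir_table(),
                              S_se = NA_real_, log_base = 10) {
  if (inherits(S, "decay_fit")) {
    S_se <- S$S_se
    S <- S$S
  }
  stopifnot(length(S) == 1, S >= 0)
  if (!residue_type %in% names(ir)) {
    stop("configuration error: no intrinsic reactivity for residue type '",
         residue_type, "'", call. = FALSE)
  }
  irv <- unname(ir[[residue_type]])
  pf <- S / irv
  out <- data.frame(residue_type = residue_type, S = S, S_se = S_se,
                    IR = irv, PF = pf,
                    logPF = if (pf > 0) log(pf, base = log_base) else NA_real_,
                    PF_se = if (is.na(S_se)) NA_real_ else S_se / irv,
                    stringsAsFactors = FALSE)
  class(out) <- c("protection_record", class(out))
  out
}

#' Per-residue protection factors for a whole area table
#'
#' Convenience pipeline: for every residue in a compiled area table, compute
#' oxidized fractions, fit the decay and derive the protection factor.
#' Residues whose series cannot be fitted (fewer than 3 usable dose points)
#' are reported with NA and flagged in the `note` column.
#'
#' @param areas A `residue_area_table` from [match_and_aggregate()].
#' @param ir Named IR vector.
#' @param weights Passed to [fit_decay()].
#' @return Data frame with one row per residue: `residue`, `residue_type`,
#'   `S`, `S_se`, `IR`, `PF`, `logPF`, `note`.
#' @export
protection_factors <- function(areas, ir = ir_table(),
                               weights = "reciprocal-se") {
  res <- sort(unique(areas$residue))
  rows <- lapply(res, function(r) {
    sub <- areas[areas$residue == r, , drop = FALSE]
    type <- sub$residue_type[1]
    rec <- tryCatch({
      ser <- oxidized_fraction(sub)
      fit <- fit_decay(ser, weights = weights)
      pr <- protection_factor(fit, type, ir = ir)
      data.frame(residue = r, residue_type = type, S = pr$S, S_se = pr$S_se,
                 IR = pr$IR, PF = pr$PF, logPF = pr$logPF, note = "",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(residue = r, residue_type = type, S = NA_real_,
                 S_se = NA_real_, IR = NA_real_, PF = NA_real_,
                 logPF = NA_real_, note = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    rec
  })
  do.call(rbind, rows)
}
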