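# Concentration-response analysis: normalization of enzymatic rates to the
# negative control and four-parameter logistic (4PL) fitting
#   Y = Min + (Max - Min) / (1 + (IC50 / X)^Hill)
# with IC50 (half-maximal concentration), maximal inhibition
# (100 - fitted lower asymptote), R^2 on replicate means, and an
# R^2-gated activity call.

#' Normalize raw enzymatic rates to the negative control
#'
#' Treated activity is expressed as a percentage of the mean negative-
#' control rate within the same batch, so the negative control maps to
#' 100% by construction.
#'
#' @param table assay data.frame with columns `concentration_uM`,
#'   `replicate`, `rate`, `control_flag` (values `negative`, `positive`,
#'   `treated`) and optionally `batch` (defaults to one batch) plus
#'   `compound`/`form` carried through.
#' @return the treated rows with an added `activity_pct` column.
#' @export
normalize_activity <- function(table) {
  need <- c("concentration_uM", "rate", "control_flag")
  stopifnot(all(need %in% names(table)))
  if (is.null(table$batch)) table$batch <- "batch1"
  out <- list()
  for (b in unique(table$batch)) {
    tb <- table[table$batch == b, , drop = FALSE]
    neg <- tb$rate[tb$control_flag == "negative"]
    if (length(neg) == 0)
      stop("no negative control in batch '", b, "'")
    tb$activity_pct <- 100 * tb$rate / mean(neg)
    out[[b]] <- tb
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[out$control_flag == "treated", , drop = FALSE]
}

# default optimizer bounds (response in % of control, concentration in uM)
.fourpl_bounds <- function() {
  list(lower = c(min_resp = -20, max_resp = 50, log10_ic50 = -3, hill = 0.2),
       upper = c(min_resp = 120, max_resp = 150, log10_ic50 = 4, hill = 5))
}

#' Fit the 4PL concentration-response model
#'
#' Bounded Levenberg-Marquardt least squares on replicate-level responses,
#' with the IC50 fitted on the log10 scale and a multi-start over
#' log-spaced IC50 initializations to avoid local minima. R-squared is
#' computed on the replicate means (matching plots of mean +/- SD);
#' `r2_on_replicates = TRUE` computes it on raw replicates instead. A fit
#' is flagged unreliable (and its IC50 reported as NA) when the optimizer
#' fails or the IC50 lands on a box bound.
#'
#' @param norm_table data.frame with `concentration_uM` (> 0) and
#'   `activity_pct` (from [normalize_activity()]).
#' @param r2_on_replicates compute R^2 on raw replicates (default FALSE).
#' @param n_starts number of log-spaced IC50 starts (default 5).
#' @return object of class `dose_response_fit`: `params`
#'   ([fourpl_params()]), `ic50` (NA when unreliable), `max_inhibition`
#'   (= 100 - fitted Min), `r_squared`, `se` (per-parameter standard
#'   errors), `reliable`, `n_concentrations`.
#' @export
fit_4pl <- function(norm_table, r2_on_replicates = FALSE, n_starts = 5L) {
  stopifnot(all(c("concentration_uM", "activity_pct") %in%
                  names(norm_table)))
  x <- norm_table$concentration_uM
  y <- norm_table$activity_pct
  keep <- x > 0 & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 4)
    stop("4PL fit needs at least 4 distinct concentrations")
  bounds <- .fourpl_bounds()
  # inhibitor convention: hill > 0 falls from Max to Min (see
  # fourpl_response for the sign relation to the IC50/X form)
  model <- function(p, xx)
    p[1] + (p[2] - p[1]) / (1 + (xx / 10^p[3])^p[4])
  starts_ic50 <- 10^seq(log10(min(x)), log10(max(x)),
                        length.out = n_starts)
  p0_min <- max(min(y), bounds$lower["min_resp"])
  p0_max <- min(max(y), bounds$upper["max_resp"])
  best <- NULL
  for (s in starts_ic50) {
    start <- c(min_resp = unname(p0_min), max_resp = unname(p0_max),
               log10_ic50 = log10(s), hill = 1)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start,
                         fn = function(p) y - model(p, x),
                         lower = bounds$lower, upper = bounds$upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, ic50 = NA_real_,
                          max_inhibition = NA_real_, r_squared = NA_real_,
                          se = NULL, reliable = FALSE,
                          n_concentrations = length(unique(x))),
                     class = "dose_response_fit"))
  }
  p <- best$par
  # R^2 on replicate means (or raw replicates)
  if (r2_on_replicates) {
    ym <- y; xm <- x
  } else {
    ym <- tapply(y, x, mean)
    xm <- as.numeric(names(ym))
    ym <- as.numeric(ym)
  }
  resid <- ym - model(p, xm)
  sst <- sum((ym - mean(ym))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(resid^2) / sst
  at_bound <- p["log10_ic50"] <= bounds$lower["log10_ic50"] + 1e-6 ||
    p["log10_ic50"] >= bounds$upper["log10_ic50"] - 1e-6
  reliable <- best$info %in% 1:4 && !at_bound
  se <- tryCatch({
    covm <- solve(best$hessian) * best$deviance /
      max(1, length(y) - length(p))
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, 4))
  names(se) <- names(p)
  params <- fourpl_params(min_resp = unname(p["min_resp"]),
                          max_resp = unname(p["max_resp"]),
                          ic50 = unname(10^p["log10_ic50"]),
                          hill = unname(p["hill"]))
  structure(list(params = params,
                 ic50 = if (reliable) params$ic50 else NA_real_,
                 max_inhibition = 100 - params$min_resp,
                 r_squared = r2, se = se, reliable = reliable,
                 n_concentrations = length(unique(x))),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("dose_response_fit: optimizer failed (unreliable)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "dose_response_fit: IC50 %s uM | max inhibition %.1f%% | Hill %.2f | R2 %.3f%s\n",
    ifelse(is.na(x$ic50), "NA", sprintf("%.3g", x$ic50)),
    x$max_inhibition, x$params$hill, x$r_squared,
    if (x$reliable) "" else " [unreliable]"))
  invisible(x)
}

#' Activity call from a dose-response fit
#'
#' A compound is called an inhibitor iff the fit is reliable, the
#' R-squared meets the threshold (inclusive), and the maximal inhibition
#' is significantly above zero (its 95% lower confidence bound, when the
#' fitted Min has a standard error; otherwise the point estimate must
#' exceed `min_inhibition`).
#'
#' @param fit a [fit_4pl()] result.
#' @param r2_min minimum R-squared (default 0.18, the rejection threshold
#'   below which a flat concentration-response curve is called inactive).
#' @param min_inhibition fallback minimal inhibition in percentage points
#'   (default 10).
#' @return `"inhibitor"` or `"inactive"`.
#' @export
classify_activity <- function(fit, r2_min = 0.18, min_inhibition = 10) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (is.null(fit$params) || !fit$reliable) return("inactive")
  if (is.na(fit$r_squared) || fit$r_squared < r2_min) return("inactive")
  se_min <- if (!is.null(fit$se)) fit$se[["min_resp"]] else NA_real_
  signif_pos <- if (!is.na(se_min)) {
    fit$max_inhibition - 1.96 * se_min > 0
  } else {
    fit$max_inhibition > min_inhibition
  }
  if (isTRUE(signif_pos)) "inhibitor" else "inactive"
}
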