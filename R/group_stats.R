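# Downstream statistics for core scores and assay data: heteroscedastic
# group contrasts, blocked linear models with estimated marginal means,
# loading-control normalisation, fold changes, and the two correlation
# utilities used for validation.

#' Heteroscedastic group model with Welch-Satterthwaite contrasts
#'
#' Fits a one-factor model in which every group has its own mean *and* its
#' own variance -- the appropriate model when measurement spread differs
#' between groups, as it does for immunoreactive scores across histological
#' grades. For a single factor this model's estimands are the per-group
#' sample means and unbiased variances, and every pairwise contrast is a
#' Welch two-sample comparison with Satterthwaite degrees of freedom.
#' P values are adjusted for multiplicity across all pairwise contrasts
#' (Holm step-down by default).
#'
#' Contrasts involving the reference group (e.g. normal tissue) are flagged
#' `vs_reference`; the rest are `between_groups`, matching the two kinds of
#' annotation used on group-comparison figures.
#'
#' @param data Data frame of scores.
#' @param group,value Names of the grouping and response columns.
#' @param reference Label of the reference group (default `"normal"`); may be
#'   absent from the data, in which case all contrasts are `between_groups`.
#' @param p_adjust Multiplicity adjustment: `"holm"` (default),
#'   `"bonferroni"` or `"none"`.
#' @return An object of class `group_fit`: a list with `groups` (per-group
#'   `n`, `mean`, `variance`) and `contrasts` (pairwise `estimate`, `se`,
#'   Welch `df`, `t`, `p_raw`, `p_adj`, `type`).
#' @export
fit_hetero_groups <- function(data, group = "gleason_group", value = "irs",
                              reference = "normal",
                              p_adjust = c("holm", "bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  if (!all(c(group, value) %in% names(data))) {
    stop("`data` must contain columns '", group, "' and '", value, "'",
      call. = FALSE
    )
  }
  g <- data[[group]]
  y <- data[[value]]
  if (!is.factor(g)) g <- factor(g, levels = unique(g))
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(!is.finite(y))) stop("scores must be finite", call. = FALSE)

  lev <- levels(g)
  n <- tapply(y, g, length)
  small <- lev[n < 2L]
  if (length(small) > 0L) {
    stop(
      "insufficient data (n < 2) in group(s): ",
      paste(small, collapse = ", "),
      call. = FALSE
    )
  }
  means <- tapply(y, g, mean)
  vars <- tapply(y, g, stats::var)

  pairs <- utils::combn(lev, 2L)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]
    b <- pairs[2L, k]
    va <- vars[[a]] / n[[a]]
    vb <- vars[[b]] / n[[b]]
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n[[a]] - 1L) + vb^2 / (n[[b]] - 1L))
    est <- means[[a]] - means[[b]]
    tt <- if (se > 0) est / se else if (est == 0) 0 else sign(est) * Inf
    p <- if (is.infinite(tt)) 0 else 2 * stats::pt(-abs(tt), df)
    data.frame(
      group_i = a, group_j = b, estimate = est, se = se, df = df,
      t = tt, p_raw = p,
      type = if (reference %in% c(a, b)) "vs_reference" else "between_groups",
      stringsAsFactors = FALSE
    )
  }))
  contrasts$p_adj <- if (p_adjust == "none") {
    contrasts$p_raw
  } else if (p_adjust == "holm") {
    holm_adjust(contrasts$p_raw)
  } else {
    pmin(contrasts$p_raw * nrow(contrasts), 1)
  }

  structure(
    list(
      groups = data.frame(
        group = lev, n = as.integer(n), mean = as.numeric(means),
        variance = as.numeric(vars), stringsAsFactors = FALSE
      ),
      contrasts = contrasts,
      reference = reference,
      p_adjust = p_adjust
    ),
    class = "group_fit"
  )
}

#' @export
print.group_fit <- function(x, ...) {
  cat("Heteroscedastic group fit (", nrow(x$groups), " groups, ",
    x$p_adjust, "-adjusted contrasts)\n\n",
    sep = ""
  )
  print(x$groups, row.names = FALSE)
  cat("\nPairwise Welch contrasts:\n")
  ct <- x$contrasts
  ct$sig <- significance_stars(ct$p_adj)
  print(ct, row.names = FALSE, digits = 4)
  invisible(x)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Holm step-down multiplicity adjustment
#'
#' @param p Numeric vector of raw p values in `[0, 1]`.
#' @return Adjusted p values in the original order; never smaller than the
#'   input and capped at 1.
#' @export
holm_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("`p` must be numeric values in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "holm")
}

#' Date-blocked linear model with estimated marginal means
#'
#' Fits `value ~ treatment + date` by ordinary least squares, treating the
#' testing date as a blocking factor that absorbs day-to-day drift in assay
#' conditions (no interaction is fitted). Treatment means are reported as
#' estimated marginal means -- model predictions averaged over the date
#' levels -- with 95% confidence limits, and all pairwise treatment
#' contrasts are tested with multiplicity adjustment. With a single date
#' level the blocking term is dropped and the marginal means are the raw
#' treatment means.
#'
#' @param data Data frame with the response and factor columns.
#' @param value,treatment,date Column names.
#' @param p_adjust Adjustment for the pairwise contrasts (`"holm"` default).
#' @return An object of class `linear_fit`: list with `model` (the `lm`
#'   fit), `coefficients`, `sigma`, `df_residual`, `emmeans` (one row per
#'   treatment: `estimate`, `se`, `ci_low`, `ci_high`) and `contrasts`.
#' @export
fit_blocked_ols <- function(data, value = "value", treatment = "treatment",
                            date = "date",
                            p_adjust = c("holm", "bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  needed <- c(value, treatment, date)
  if (!all(needed %in% names(data))) {
    stop("`data` must contain columns: ", paste(needed, collapse = ", "),
      call. = FALSE
    )
  }
  d <- data.frame(
    value = data[[value]],
    treatment = factor(data[[treatment]]),
    date = factor(data[[date]])
  )
  use_date <- nlevels(d$date) >= 2L
  fml <- if (use_date) value ~ treatment + date else value ~ treatment
  fit <- stats::lm(fml, data = d)
  if (anyNA(stats::coef(fit))) {
    stop(
      "collinear design; aliased column(s): ",
      paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  emm <- emmeans::emmeans(fit, "treatment")
  emm_df <- as.data.frame(summary(emm, level = 0.95))
  emmeans_tab <- data.frame(
    treatment = as.character(emm_df$treatment),
    estimate = emm_df$emmean, se = emm_df$SE,
    ci_low = emm_df$lower.CL, ci_high = emm_df$upper.CL,
    stringsAsFactors = FALSE
  )
  ct <- as.data.frame(summary(
    emmeans::contrast(emm, method = "pairwise", adjust = "none")
  ))
  contrasts <- data.frame(
    contrast = as.character(ct$contrast),
    estimate = ct$estimate, se = ct$SE, df = ct$df, t = ct$t.ratio,
    p_raw = ct$p.value, stringsAsFactors = FALSE
  )
  contrasts$p_adj <- switch(p_adjust,
    none = contrasts$p_raw,
    holm = holm_adjust(contrasts$p_raw),
    bonferroni = pmin(contrasts$p_raw * nrow(contrasts), 1)
  )
  structure(
    list(
      model = fit,
      coefficients = stats::coef(fit),
      sigma = stats::sigma(fit),
      df_residual = fit$df.residual,
      emmeans = emmeans_tab,
      contrasts = contrasts,
      p_adjust = p_adjust
    ),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("Blocked linear model (residual sd ", format(x$sigma, digits = 4),
    ", df ", x$df_residual, ")\n\nEstimated marginal means:\n",
    sep = ""
  )
  print(x$emmeans, row.names = FALSE, digits = 4)
  cat("\nPairwise contrasts (", x$p_adjust, "-adjusted):\n", sep = "")
  print(x$contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Normalise intensities to a loading control
#'
#' Elementwise division of target-band intensities by the matching
#' loading-control (e.g. GAPDH) intensities from the same lanes.
#'
#' @param target,control Equal-length numeric vectors; `control` must be
#'   strictly positive.
#' @return `target / control`.
#' @export
normalize_to_loading_control <- function(target, control) {
  if (length(target) != length(control)) {
    stop("`target` and `control` must have equal length", call. = FALSE)
  }
  bad <- which(control <= 0)
  if (length(bad) > 0L) {
    stop("non-positive loading control in lane(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  target / control
}

#' Per-date fold changes against a control, with a test against 1
#'
#' Divides treated-line intensities by the paired control (e.g. empty-vector)
#' intensities date by date, then tests whether the mean fold change differs
#' from 1 with a one-sample t test (equivalently, an intercept-only least
#' squares fit to `fc - 1`). A degenerate set of identical fold changes gets
#' p = 1 when they equal 1 and p = 0 otherwise.
#'
#' @param treated,control Numeric vectors named by date (or aligned by
#'   position when unnamed); `control` must be strictly positive.
#' @return List with `fold_changes` (per date), `mean_fc`, `t`, `df`, `p`.
#' @export
fold_changes <- function(treated, control) {
  if (!is.null(names(treated)) || !is.null(names(control))) {
    if (is.null(names(treated)) || is.null(names(control)) ||
      !setequal(names(treated), names(control))) {
      stop("pairing error: `treated` and `control` date keys do not match",
        call. = FALSE
      )
    }
    control <- control[names(treated)]
  } else if (length(treated) != length(control)) {
    stop("pairing error: `treated` and `control` lengths differ",
      call. = FALSE
    )
  }
  if (any(control <= 0)) {
    stop("`control` values must be strictly positive", call. = FALSE)
  }
  fc <- treated / control
  n <- length(fc)
  s <- stats::sd(fc)
  if (n < 2L || s == 0) {
    p <- if (all(fc == 1)) 1 else 0
    tt <- if (all(fc == 1)) 0 else sign(mean(fc) - 1) * Inf
    return(list(
      fold_changes = fc, mean_fc = mean(fc), t = tt,
      df = max(n - 1L, 0L), p = p
    ))
  }
  tt <- (mean(fc) - 1) / (s / sqrt(n))
  list(
    fold_changes = fc, mean_fc = mean(fc), t = tt, df = n - 1L,
    p = 2 * stats::pt(-abs(tt), n - 1L)
  )
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, neither constant.
#' @return List with `r`, `r_squared` and the two-sided `p` from the
#'   t transform with `n - 2` degrees of freedom.
#' @export
pearson_corr <- function(x, y) {
  check_corr_input(x, y)
  n <- length(x)
  r <- stats::cor(x, y)
  p <- corr_t_pvalue(r, n)
  list(r = r, r_squared = r^2, p = p)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with the
#' two-sided p value from the t approximation.
#'
#' @inheritParams pearson_corr
#' @return List with `rho` and `p`.
#' @export
spearman_corr <- function(x, y) {
  check_corr_input(x, y)
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  list(rho = rho, p = corr_t_pvalue(rho, n))
}

check_corr_input <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input vector", call. = FALSE)
  }
  invisible(NULL)
}

corr_t_pvalue <- function(r, n) {
  if (abs(r) >= 1) {
    return(0)
  }
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), n - 2)
}
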