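#' ROUT outlier detection (one-sample adaptation)
#'
#' Robust outlier screening controlled by a false-discovery-rate parameter
#' Q, as applied to per-movie SE counts before group statistics. The
#' one-sample form used here: robust center = median; robust SD of the
#' residuals (RSDR) = 68.27th percentile of the absolute residuals with the
#' small-sample correction n/(n-1); each point gets a two-sided t ratio
#' |residual|/RSDR with n-1 degrees of freedom; the most extreme points
#' (at most 30% of the sample) are flagged by a Benjamini-Hochberg-style
#' step-down at level Q. This rule is the normative definition tested in
#' the package.
#'
#' Flagging is invariant to affine transformations of the values.
#'
#' @param values numeric vector, n >= 3.
#' @param Q FDR level in (0, 0.5); default 0.01 (the "Q = 1%" setting).
#' @return list of class `rout_result`: `mask` (TRUE = outlier), `Q`,
#'   `center`, `rsdr`, `t`, `p`.
#' @export
rout_outliers <- function(values, Q = 0.01) {
  n <- length(values)
  if (n < 3) stop("ROUT requires n >= 3")
  stopifnot(Q > 0, Q < 0.5)
  center <- median(values)
  res <- values - center
  rsdr <- quantile(abs(res), 0.6827, names = FALSE) * n / (n - 1)
  mask <- rep(FALSE, n)
  if (rsdr <= 0) {
    t <- rep(0, n); p <- rep(1, n)
  } else {
    t <- abs(res) / rsdr
    p <- 2 * pt(t, df = n - 1, lower.tail = FALSE)
    kmax <- floor(0.3 * n)
    if (kmax >= 1) {
      ord <- order(p)
      thr <- Q * seq_len(n) / n
      ok <- p[ord][seq_len(kmax)] <= thr[seq_len(kmax)]
      kstar <- if (any(ok)) max(which(ok)) else 0L
      if (kstar > 0) mask[ord[seq_len(kstar)]] <- TRUE
    }
  }
  structure(list(mask = mask, Q = Q, center = center, rsdr = rsdr,
                 t = if (rsdr > 0) t else rep(0, n), p = p),
            class = "rout_result")
}

#' @export
print.rout_result <- function(x, ...) {
  cat(sprintf("<rout_result> Q = %g%%: %d of %d flagged (center %.3g, RSDR %.3g)\n",
              100 * x$Q, sum(x$mask), length(x$mask), x$center, x$rsdr))
  invisible(x)
}

#' Mixed-model group comparison with Dunnett-adjusted contrasts
#'
#' Fits `value ~ group + (1 | animal)` by REML (lmerTest, Satterthwaite
#' degrees of freedom) -- the observation unit is typically a movie, nested
#' in animals -- and compares every group against the control with
#' Dunnett-type contrasts via emmeans using the multivariate-t adjustment
#' (mvtnorm quasi-Monte-Carlo, seeded for reproducibility). Adjusted
#' p-values are never below the unadjusted ones (enforced against QMC
#' jitter). Singular fits (e.g. one observation per animal, zero animal
#' variance) are reported, not hidden; the estimates then reduce to
#' fixed-effects group means.
#'
#' @param data data.frame of observations.
#' @param control control group label (reference of every contrast).
#' @param value,group,animal column names.
#' @param seed seed for the multivariate-t adjustment.
#' @return list of class `group_comparison`: `means` (per-group emmeans:
#'   estimate, SE, df, CIs), `contrasts` (estimate, SE, df, `p_raw`,
#'   `p_adj`, CIs), `varcomp` (`animal`, `residual` variances), `singular`.
#' @export
fit_group_lmm <- function(data, control, value = "value", group = "group",
                          animal = "animal", seed = 1L) {
  stopifnot(all(c(value, group, animal) %in% names(data)))
  d <- data.frame(value = data[[value]],
                  group = factor(data[[group]]),
                  animal = factor(data[[animal]]))
  if (anyNA(d)) stop("observations must have a value, group and animal")
  if (nlevels(d$group) < 2) stop("need >= 2 groups")
  if (!control %in% levels(d$group)) stop("control group not found")
  d$group <- stats::relevel(d$group, ref = control)
  per_gp_animals <- tapply(d$animal, d$group, function(a) length(unique(a)))
  if (any(per_gp_animals < 2))
    warning("some group has a single animal; random effect may be degenerate")

  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore")
  fit <- lmerTest::lmer(value ~ group + (1 | animal), data = d,
                        control = ctrl)
  singular <- lme4::isSingular(fit)
  if (singular)
    message("singular fit: animal variance estimated at zero")
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- c(animal = vc$vcov[vc$grp == "animal"],
               residual = vc$vcov[vc$grp == "Residual"])

  em <- emmeans::emmeans(fit, "group")
  set.seed(seed)
  con_adj <- summary(emmeans::contrast(em, "trt.vs.ctrl", ref = 1,
                                       adjust = "mvt"), infer = TRUE)
  con_raw <- summary(emmeans::contrast(em, "trt.vs.ctrl", ref = 1,
                                       adjust = "none"))
  contrasts <- data.frame(contrast = con_adj$contrast,
                          estimate = con_adj$estimate,
                          SE = con_adj$SE, df = con_adj$df,
                          lower.CL = con_adj$lower.CL,
                          upper.CL = con_adj$upper.CL,
                          p_raw = con_raw$p.value,
                          p_adj = pmax(con_adj$p.value, con_raw$p.value))
  structure(list(means = as.data.frame(summary(em, infer = TRUE)),
                 contrasts = contrasts, varcomp = varcomp,
                 singular = singular, model = fit),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> mixed model value ~ group + (1|animal)\n")
  cat(sprintf("  variance components: animal %.4g, residual %.4g%s\n",
              x$varcomp["animal"], x$varcomp["residual"],
              if (x$singular) " (singular)" else ""))
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}
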