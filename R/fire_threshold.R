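#' Fit a VPD threshold model for fire occurrence
#'
#' Fits a binomial-logit generalised linear model of daily fire occurrence
#' against daily maximum vapour pressure deficit,
#' `logit P(fire) = beta0 + beta1 * vpd`, by maximum likelihood (IRLS,
#' log-likelihood tolerance 1e-8, at most 100 iterations), and extracts
#' the critical fire-activity threshold `VPD_P=50 = -beta0/beta1` — the
#' daily VPD above which the fitted probability of fire exceeds 50% —
#' together with its delta-method standard error and a confidence interval
#' of plus/minus `level_se` standard errors.
#'
#' Skill diagnostics are computed on the fitting data: the area under the
#' ROC curve (trapezoidal integration over unique scores), the true
#' positive rate at the 0.5 probability cutoff (predicted probability of
#' exactly 0.5 counts as a positive prediction), and percent deviance
#' explained relative to the intercept-only model.
#'
#' Perfectly separated data (every burned row drier than every unburned
#' row) cannot identify a finite slope; the model is then returned with an
#' infinite slope flag and the threshold set to the midpoint of the
#' separating gap, rather than failing.
#'
#' @param formula model formula, `burned ~ vpd` by default; exactly one
#'   predictor is allowed, since the 50% threshold is defined on a single
#'   axis.
#' @param data a `data.frame` (e.g. an `occurrence_sample`) containing the
#'   response (0/1) and the predictor (kPa).
#' @param level_se half-width of the reported confidence interval in
#'   standard errors (default 2).
#' @param stratum optional stratum label stored on the fit.
#' @return an object of class `"fire_threshold"`: a list with elements
#'   `coefficients`, `vcov`, `vpd_p50`, `se_p50`, `ci_p50`, `auc`, `tpr`,
#'   `deviance_explained`, `n`, `converged`, `separated`, `stratum`,
#'   `data`, `call`.
#' @seealso [summary.fire_threshold()], [fit_strata()], [vpd_p50()],
#'   [threshold_uncertainty()], [model_skill()]
#' @examples
#' set.seed(1)
#' v <- runif(2000, 0, 5)
#' y <- rbinom(2000, 1, plogis(-5 + 2 * v))
#' fit <- fire_threshold(burned ~ vpd, data.frame(vpd = v, burned = y))
#' fit$vpd_p50  # close to 2.5 kPa
#' @export
fire_threshold <- function(formula = burned ~ vpd, data, level_se = 2,
                           stratum = NA_character_) {
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 2L)
    stop("the threshold model takes exactly one predictor")
  y <- stats::model.response(mf)
  x <- mf[[2L]]
  if (!all(y %in% c(0, 1))) stop("response must be 0/1 fire occurrence")
  if (any(!is.finite(x))) stop("non-finite predictor values")
  if (length(unique(y)) < 2L)
    stop("unfittable: all rows share one label; both burned and unburned rows are required")
  if (sum(y == 0) < 2L || sum(y == 1) < 2L)
    stop("at least 2 rows of each label are required")

  out <- list(call = match.call(), n = length(y), stratum = stratum,
              data = data.frame(vpd = x, burned = as.integer(y)),
              level_se = level_se)

  if (max(x[y == 1]) < min(x[y == 0]))
    stop("non-increasing fire response: burned rows are uniformly wetter than unburned rows")

  if (min(x[y == 1]) > max(x[y == 0])) {
    # perfect separation: slope unbounded, threshold = midpoint of the gap
    thr <- (max(x[y == 0]) + min(x[y == 1])) / 2
    out$separated <- TRUE
    out$converged <- TRUE
    out$coefficients <- c(beta0 = -Inf, beta1 = Inf)
    out$vcov <- matrix(NA_real_, 2L, 2L,
                       dimnames = list(c("beta0", "beta1"), c("beta0", "beta1")))
    out$vpd_p50 <- thr
    out$se_p50 <- NA_real_
    out$ci_p50 <- c(NA_real_, NA_real_)
    out$auc <- 1
    out$tpr <- 1
    out$deviance_explained <- 100
    class(out) <- "fire_threshold"
    return(out)
  }

  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100L)),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  b <- unname(stats::coef(fit))
  V <- stats::vcov(fit)
  dimnames(V) <- list(c("beta0", "beta1"), c("beta0", "beta1"))
  out$separated <- FALSE
  out$converged <- fit$converged && !warned
  out$coefficients <- c(beta0 = b[1L], beta1 = b[2L])
  out$vcov <- V
  if (b[2L] > 0) {
    out$vpd_p50 <- vpd_p50(b[1L], b[2L])
    unc <- threshold_uncertainty(b[1L], b[2L], V, level_se = level_se)
    out$se_p50 <- unc$se
    out$ci_p50 <- unc$ci
  } else {
    warning("fitted slope is not positive: threshold undefined for this stratum")
    out$vpd_p50 <- NA_real_
    out$se_p50 <- NA_real_
    out$ci_p50 <- c(NA_real_, NA_real_)
  }
  p_hat <- stats::fitted(fit)
  out$auc <- auc_roc(p_hat, y)
  out$tpr <- mean(p_hat[y == 1] >= 0.5)
  out$deviance_explained <- 100 * (1 - fit$deviance / fit$null.deviance)
  out$residual_deviance <- fit$deviance
  out$null_deviance <- fit$null.deviance
  class(out) <- "fire_threshold"
  out
}

#' The VPD value at which fire probability reaches 50%
#'
#' The unique root of `plogis(beta0 + beta1 * v) = 0.5`, i.e.
#' `-beta0 / beta1`, defined only for an increasing fire response
#' (`beta1 > 0`).
#'
#' @param beta0,beta1 logit intercept and slope (per kPa).
#' @return threshold in kPa.
#' @export
vpd_p50 <- function(beta0, beta1) {
  if (!is.finite(beta1) || beta1 <= 0)
    stop("non-increasing fire response: threshold undefined (beta1 must be > 0)")
  -beta0 / beta1
}

#' Delta-method uncertainty of the fitted threshold
#'
#' First-order error propagation of the coefficient covariance through the
#' ratio `-beta0/beta1`: with gradient `g = (-1/beta1, beta0/beta1^2)`,
#' `SE = sqrt(g' V g)`, and the interval is the point estimate plus/minus
#' `level_se` standard errors.
#'
#' @param beta0,beta1 fitted coefficients.
#' @param vcov 2x2 coefficient covariance matrix.
#' @param level_se interval half-width in SEs (default 2).
#' @return list with `se` (kPa) and `ci` (length-2 vector, kPa). A
#'   non-finite covariance yields `se = NA` and an omitted (NA) interval.
#' @export
threshold_uncertainty <- function(beta0, beta1, vcov, level_se = 2) {
  if (any(!is.finite(vcov)))
    return(list(se = NA_real_, ci = c(NA_real_, NA_real_)))
  g <- c(-1 / beta1, beta0 / beta1^2)
  se <- sqrt(drop(t(g) %*% vcov %*% g))
  p50 <- -beta0 / beta1
  list(se = se, ci = c(p50 - level_se * se, p50 + level_se * se))
}

#' Area under the ROC curve by trapezoidal integration
#'
#' ROC points are taken at every unique score value (descending cutoffs)
#' and the curve integrated by trapezoids, which credits ties with half
#' weight — numerically identical to the Mann-Whitney two-sample rank
#' statistic.
#'
#' @param scores numeric classifier scores (any monotone transform of the
#'   fitted probability gives the same AUC).
#' @param labels 0/1 true labels.
#' @return AUC in [0, 1]; `NA` with a warning if only one class is present.
#' @export
auc_roc <- function(scores, labels) {
  if (length(unique(labels)) < 2L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  last <- c(s[-1L] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- c(0, tp[last]); fp <- c(0, fp[last])
  sum(diff(fp) * (tp[-1L] + tp[-length(tp)]) / 2) /
    (as.numeric(sum(labels == 1)) * sum(labels == 0))
}

#' Skill diagnostics of a threshold model on labelled data
#'
#' @param object a [fire_threshold()] fit.
#' @param data optional `data.frame` with `vpd` and `burned`; defaults to
#'   the fitting data.
#' @return list with `auc`, `tpr` (at the 0.5 probability cutoff, ties
#'   counted positive) and `deviance_explained` (percent, vs the
#'   intercept-only model on the same data).
#' @export
model_skill <- function(object, data = object$data) {
  y <- data$burned
  p <- predict(object, newdata = data, type = "response")
  eps <- 1e-15
  pc <- pmin(pmax(p, eps), 1 - eps)
  dev <- -2 * sum(y * log(pc) + (1 - y) * log(1 - pc))
  p0 <- mean(y)
  null_dev <- -2 * sum(y * log(p0) + (1 - y) * log(1 - p0))
  list(auc = auc_roc(p, y),
       tpr = mean(p[y == 1] >= 0.5),
       deviance_explained = 100 * (1 - dev / null_dev))
}

# --- methods -----------------------------------------------------------------

#' @export
print.fire_threshold <- function(x, digits = 3, ...) {
  cat("VPD threshold model (binomial-logit)\n")
  if (!is.na(x$stratum)) cat("  stratum:", x$stratum, "\n")
  if (x$separated) {
    cat("  perfectly separated data: slope unbounded\n")
    cat(sprintf("  VPD_P=50: %.*f kPa (midpoint of separating gap)\n",
                digits, x$vpd_p50))
  } else {
    cat(sprintf("  coefficients: beta0 = %.*f, beta1 = %.*f per kPa\n",
                digits, x$coefficients[1L], digits, x$coefficients[2L]))
    cat(sprintf("  VPD_P=50: %.*f kPa (+/- %g SE: %.*f to %.*f)\n",
                digits, x$vpd_p50, x$level_se,
                digits, x$ci_p50[1L], digits, x$ci_p50[2L]))
  }
  cat(sprintf("  AUC %.*f | TPR %.*f | deviance explained %.1f%% | n = %d\n",
              digits, x$auc, digits, x$tpr, x$deviance_explained, x$n))
  invisible(x)
}

#' @export
summary.fire_threshold <- function(object, ...) {
  coefs <- NULL
  if (!object$separated) {
    se <- sqrt(diag(object$vcov))
    z <- object$coefficients / se
    coefs <- cbind(Estimate = object$coefficients, `Std. Error` = se,
                   `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  }
  structure(list(fit = object, coefficients = coefs),
            class = "summary.fire_threshold")
}

#' @export
print.summary.fire_threshold <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  if (!is.null(x$coefficients)) {
    cat("\nCoefficients:\n")
    stats::printCoefmat(x$coefficients, digits = digits)
  }
  if (!x$fit$converged) cat("\nWarning: IRLS did not cleanly converge\n")
  invisible(x)
}

#' @export
coef.fire_threshold <- function(object, ...) object$coefficients

#' @export
vcov.fire_threshold <- function(object, ...) object$vcov

#' Predicted fire probability (or linear predictor) at given VPD
#'
#' @param object a [fire_threshold()] fit.
#' @param newdata `data.frame` with a `vpd` column, or a numeric vector of
#'   VPD values; defaults to the fitting data.
#' @param type `"response"` (probability) or `"link"` (logit).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.fire_threshold <- function(object, newdata = NULL,
                                   type = c("response", "link"), ...) {
  type <- match.arg(type)
  v <- if (is.null(newdata)) object$data$vpd
       else if (is.numeric(newdata)) newdata
       else newdata$vpd
  if (object$separated) {
    eta <- ifelse(v > object$vpd_p50, Inf,
                  ifelse(v < object$vpd_p50, -Inf, 0))
  } else {
    eta <- object$coefficients[1L] + object$coefficients[2L] * v
  }
  if (type == "link") unname(eta) else unname(stats::plogis(eta))
}

#' @export
residuals.fire_threshold <- function(object,
                                     type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  y <- object$data$burned
  p <- predict(object, type = "response")
  if (type == "response") return(y - p)
  eps <- 1e-15
  pc <- pmin(pmax(p, eps), 1 - eps)
  d2 <- -2 * (y * log(pc) + (1 - y) * log(1 - pc))
  sign(y - p) * sqrt(d2)
}

#' Simulate fire occurrence labels under the fitted law
#'
#' Draws Bernoulli labels at the model's VPD values (or supplied ones)
#' using the fitted occurrence probabilities — a parametric-bootstrap
#' building block.
#'
#' @param object a [fire_threshold()] fit.
#' @param nsim number of simulated label vectors.
#' @param seed optional integer seed.
#' @param vpd optional numeric vector of VPD values (defaults to the
#'   fitting data).
#' @param ... unused.
#' @return `data.frame` with `nsim` columns of 0/1 labels.
#' @export
simulate.fire_threshold <- function(object, nsim = 1, seed = NULL,
                                    vpd = NULL, ...) {
  if (is.null(vpd)) vpd <- object$data$vpd
  p <- predict(object, newdata = vpd, type = "response")
  draw <- function() stats::rbinom(length(p), 1L, p)
  sims <- if (is.null(seed)) replicate(nsim, draw())
          else with_seed(seed, replicate(nsim, draw()))
  as.data.frame(matrix(sims, ncol = nsim,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}

#' Plot a fitted VPD threshold model
#'
#' The fitted occurrence-probability curve over the observed VPD range,
#' the 50% threshold (with its interval when available), and rugs of the
#' burned (top) and unburned (bottom) observations.
#'
#' @param x a [fire_threshold()] fit.
#' @param n_curve points along the fitted curve.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fire_threshold <- function(x, n_curve = 200L, ...) {
  rng <- range(x$data$vpd)
  v <- seq(rng[1L], rng[2L], length.out = n_curve)
  graphics::plot(v, predict(x, newdata = v, type = "response"),
                 type = "l", col = "red", lwd = 2, ylim = c(0, 1),
                 xlab = "daily maximum VPD (kPa)",
                 ylab = "probability of fire", ...)
  graphics::abline(h = 0.5, lty = 3)
  if (is.finite(x$vpd_p50)) {
    graphics::abline(v = x$vpd_p50, col = "blue", lwd = 2)
    if (all(is.finite(x$ci_p50)))
      graphics::abline(v = x$ci_p50, col = "blue", lty = 2)
  }
  graphics::rug(x$data$vpd[x$data$burned == 1], side = 3, col = "red")
  graphics::rug(x$data$vpd[x$data$burned == 0], side = 1, col = "grey40")
  invisible(x)
}

# --- strata ------------------------------------------------------------------

#' Fit threshold models for every stratum
#'
#' One [fire_threshold()] per non-empty stratum (biome x window
#' combination), plus group-level summaries: medians of the fitted
#' thresholds and true positive rates per biome group and overall.
#' Unfittable strata (single-label or empty) are listed, not dropped
#' silently.
#'
#' @param data an `occurrence_sample` (or any `data.frame` with `vpd`,
#'   `burned`, `stratum`).
#' @param groups optional named character vector mapping stratum id to
#'   biome group (e.g. `c(S1 = "tropical")`); default: each stratum is its
#'   own group.
#' @param ... passed to [fire_threshold()].
#' @return an object of class `"fire_threshold_set"`: list of fits, the
#'   group map, and a character vector of unfittable strata.
#' @export
fit_strata <- function(data, groups = NULL, ...) {
  strata <- sort(unique(data$stratum))
  fits <- list()
  unfittable <- character(0L)
  for (st in strata) {
    rows <- data[data$stratum == st, , drop = FALSE]
    f <- tryCatch(fire_threshold(burned ~ vpd, rows, stratum = st, ...),
                  error = function(e) conditionMessage(e))
    if (is.character(f)) unfittable <- c(unfittable, stats::setNames(f, st))
    else fits[[st]] <- f
  }
  if (is.null(groups))
    groups <- stats::setNames(names(fits), names(fits))
  structure(list(fits = fits, groups = groups, unfittable = unfittable),
            class = "fire_threshold_set")
}

#' One-row-per-stratum results table
#'
#' @param x a [fit_strata()] result.
#' @param ... unused.
#' @return `data.frame` with columns `stratum, group, beta0, beta1,
#'   vpd_p50, se, ci_lo, ci_hi, auc, tpr, dev_expl, n`.
#' @export
as.data.frame.fire_threshold_set <- function(x, ...) {
  rows <- lapply(x$fits, function(f) data.frame(
    stratum = f$stratum,
    group = unname(x$groups[f$stratum]),
    beta0 = f$coefficients[1L], beta1 = f$coefficients[2L],
    vpd_p50 = f$vpd_p50, se = f$se_p50,
    ci_lo = f$ci_p50[1L], ci_hi = f$ci_p50[2L],
    auc = f$auc, tpr = f$tpr, dev_expl = f$deviance_explained, n = f$n))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.fire_threshold_set <- function(x, digits = 3, ...) {
  cat(sprintf("VPD threshold models for %d strata\n", length(x$fits)))
  print(format(as.data.frame(x), digits = digits), row.names = FALSE)
  if (length(x$unfittable))
    cat("unfittable strata:", paste(names(x$unfittable), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.fire_threshold_set <- function(object, ...) {
  tab <- as.data.frame(object)
  med <- function(v) stats::median(v, na.rm = TRUE)
  by_group <- do.call(rbind, lapply(split(tab, tab$group), function(g)
    data.frame(group = g$group[1L], n_strata = nrow(g),
               median_vpd_p50 = med(g$vpd_p50), median_tpr = med(g$tpr),
               median_auc = med(g$auc))))
  rownames(by_group) <- NULL
  structure(list(table = tab, by_group = by_group,
                 overall = data.frame(n_strata = nrow(tab),
                                      median_vpd_p50 = med(tab$vpd_p50),
                                      median_tpr = med(tab$tpr),
                                      median_auc = med(tab$auc)),
                 unfittable = object$unfittable),
            class = "summary.fire_threshold_set")
}

#' @export
print.summary.fire_threshold_set <- function(x, digits = 3, ...) {
  cat("Per-group medians:\n")
  print(format(x$by_group, digits = digits), row.names = FALSE)
  cat("Overall:\n")
  print(format(x$overall, digits = digits), row.names = FALSE)
  if (length(x$unfittable))
    cat("unfittable strata:", paste(names(x$unfittable), collapse = ", "), "\n")
  invisible(x)
}

#' Write the per-stratum model table to CSV
#' @param fits a [fit_strata()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_table <- function(fits, path) {
  utils::write.csv(as.data.frame(fits), path, row.names = FALSE)
  invisible(path)
}
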