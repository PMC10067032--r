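# Random-intercept linear mixed model, fitted by profiled REML:
# y = X beta + u + e, u ~ N(0, sigma_u^2) per participant, e ~ N(0, sigma_e^2).
# The variance ratio lambda = sigma_u^2 / sigma_e^2 is profiled with a bounded
# 1-D search; beta is then the closed-form GLS solution. This keeps the fit
# deterministic and exactly testable against closed forms.

# Canonical reference levels (treatment contrasts): algorithm arm, doctor,
# lowest experience strata, advice strength 50.
canonical_factors <- function(data) {
  lv <- list(arm = ARM_LEVELS,
             profession = PROFESSION_LEVELS,
             total_experience = TOTAL_EXPERIENCE_LEVELS,
             palliative_experience = PALLIATIVE_EXPERIENCE_LEVELS,
             strength = c("50", "75", "90"))
  for (nm in intersect(names(lv), names(data))) {
    data[[nm]] <- factor(as.character(data[[nm]]), levels = lv[[nm]])
    if (anyNA(data[[nm]])) {
      stop(sprintf("column `%s` contains values outside its category set", nm),
           call. = FALSE)
    }
    # levels absent from the data would give all-zero design columns
    data[[nm]] <- droplevels(data[[nm]])
  }
  data
}

# Cluster-structured REML/ML machinery. All quantities use the Woodbury
# identity for V_j = sigma_e^2 (I + lambda J), so nothing larger than p x p is
# ever decomposed.
lmm_parts <- function(y, X, id) {
  id <- factor(id)
  nj <- as.numeric(table(id))
  list(y = y, X = X, id = id, nj = nj, N = length(y), p = ncol(X),
       XtX = crossprod(X), Xty = crossprod(X, y),
       Tg = rowsum(X, id), Sg = as.numeric(rowsum(y, id)))
}

# GLS beta and unit-scale (W = I + lambda J) quadratic forms for one lambda.
lmm_gls <- function(parts, lambda) {
  cg <- lambda / (1 + parts$nj * lambda)
  XtWX <- parts$XtX - crossprod(parts$Tg * cg, parts$Tg)
  XtWy <- parts$Xty - crossprod(parts$Tg, cg * parts$Sg)
  ch <- chol(XtWX)
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- parts$y - parts$X %*% beta
  Sr <- as.numeric(rowsum(as.numeric(r), parts$id))
  rss_w <- sum(r^2) - sum(cg * Sr^2)
  list(beta = as.numeric(beta), XtWX = XtWX, chol = ch, rss_w = rss_w,
       logdet_XtWX = 2 * sum(log(diag(ch))),
       logdet_W = sum(log(1 + parts$nj * lambda)))
}

# Profiled -2 * criterion (REML or ML) as a function of lambda.
lmm_profile <- function(parts, lambda, reml = TRUE) {
  g <- lmm_gls(parts, lambda)
  if (reml) {
    df <- parts$N - parts$p
    s2 <- g$rss_w / df
    df * log(s2) + g$logdet_W + g$logdet_XtWX + df + df * log(2 * pi)
  } else {
    s2 <- g$rss_w / parts$N
    parts$N * log(s2) + g$logdet_W + parts$N + parts$N * log(2 * pi)
  }
}

#' Log-likelihood of the random-intercept model at given variance components
#'
#' Evaluates the Gaussian likelihood (ML) or the restricted likelihood (REML)
#' of `y = X beta + u + e` with per-cluster compound-symmetric covariance
#' `V_j = sigma_e^2 I + sigma_u^2 J`, using the cluster-structured closed
#' form. If `beta` is `NULL` the GLS estimate at these variance components is
#' profiled in.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix.
#' @param id cluster (participant) identifier, one per row.
#' @param sigma_u2 random-intercept variance (>= 0).
#' @param sigma_e2 residual variance (> 0).
#' @param beta optional fixed-effect vector; default GLS.
#' @param reml evaluate the restricted likelihood (default FALSE).
#' @return Scalar log-likelihood.
#' @export
lmm_loglik <- function(y, X, id, sigma_u2, sigma_e2, beta = NULL,
                       reml = FALSE) {
  check_scalar_number(sigma_u2, "sigma_u2", lower = 0)
  check_scalar_number(sigma_e2, "sigma_e2", lower = 0, strict_lower = TRUE)
  parts <- lmm_parts(y, as.matrix(X), id)
  lambda <- sigma_u2 / sigma_e2
  g <- lmm_gls(parts, lambda)
  if (!is.null(beta)) {
    r <- y - as.matrix(X) %*% beta
    Sr <- as.numeric(rowsum(as.numeric(r), parts$id))
    cg <- lambda / (1 + parts$nj * lambda)
    rss_w <- sum(r^2) - sum(cg * Sr^2)
  } else {
    rss_w <- g$rss_w
  }
  quad <- rss_w / sigma_e2
  logdet_V <- parts$N * log(sigma_e2) + g$logdet_W
  ll <- -0.5 * (logdet_V + quad + parts$N * log(2 * pi))
  if (reml) {
    # Harville's restricted likelihood: integrate beta out
    logdet_XtVX <- g$logdet_XtWX - parts$p * log(sigma_e2)
    ll <- ll + 0.5 * (parts$p * log(2 * pi) - logdet_XtVX)
  }
  ll
}

#' Fit a participant random-intercept linear model by profiled REML
#'
#' The workhorse of the primary analysis: a linear mixed model for (capped)
#' weight-of-advice with fixed effects given by `fixed` and one random
#' intercept per participant, accounting for the repeated vignettes within
#' each participant. The variance ratio is profiled by a bounded
#' golden-section-free 1-D search (`optimize`) over `log(lambda)`, the
#' boundary `sigma_u^2 = 0` is checked explicitly, and `beta` follows in
#' closed form by GLS; Wald statistics use the GLS covariance of `beta`.
#'
#' @param data data frame holding the response, fixed-effect columns and the
#'   participant identifier. Known trial covariates are coerced to factors
#'   with canonical reference levels (algorithm arm, doctor, lowest experience
#'   band, strength 50).
#' @param fixed model formula for the fixed effects, e.g. `woa ~ arm` or
#'   `woa ~ arm * strength`.
#' @param id name of the participant-identifier column
#'   (default `"participant_id"`).
#' @param method `"REML"` (default) or `"ML"`.
#' @return Object of class `"woa_lmm"`: coefficients with standard errors,
#'   Wald z/p and 95% CIs, `sigma_u2`, `sigma_e2`, `loglik` (value of the
#'   chosen criterion), `vcov`, convergence and boundary flags, and the term
#'   assignment used by [wald_test()].
#' @export
#' @examples
#' trial <- simulate_trial(sim_config(n_participants = 60, seed = 2))
#' rec <- per_protocol_filter(woa_records(trial))
#' fit <- fit_random_intercept(rec[!rec$excluded, ], woa ~ arm)
#' fit
fit_random_intercept <- function(data, fixed, id = "participant_id",
                                 method = c("REML", "ML")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data), inherits(fixed, "formula"))
  if (!id %in% names(data)) {
    stop(sprintf("id column `%s` not found in data", id), call. = FALSE)
  }
  data <- canonical_factors(as.data.frame(data))
  mf <- stats::model.frame(fixed, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (length(unique(data[[id]])) < 2) {
    stop("need at least 2 participants to fit a random intercept",
         call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  parts <- lmm_parts(y, X, data[[id]])
  reml <- method == "REML"

  history <- new.env(parent = emptyenv())
  history$log <- list()
  obj <- function(loglam) {
    val <- lmm_profile(parts, exp(loglam), reml)
    history$log[[length(history$log) + 1L]] <- c(loglam = loglam, m2l = val)
    val
  }
  opt <- stats::optimize(obj, interval = c(-14, 14), tol = 1e-9)
  at_zero <- lmm_profile(parts, 0, reml)
  boundary <- at_zero <= opt$objective
  lambda <- if (boundary) 0 else exp(opt$minimum)
  m2l <- if (boundary) at_zero else opt$objective

  # Interior optimum: Newton-polish log(lambda) until the profile gradient is
  # flat to relative tolerance 1e-8; the sigma_u^2 = 0 boundary is an
  # admissible constrained optimum and needs no gradient condition.
  converged <- TRUE
  if (!boundary) {
    ll <- opt$minimum
    eps <- 1e-5
    tol <- 1e-8 * max(1, abs(m2l))
    for (iter in 1:25) {
      f0 <- lmm_profile(parts, exp(ll), reml)
      fp <- lmm_profile(parts, exp(ll + eps), reml)
      fm <- lmm_profile(parts, exp(ll - eps), reml)
      gr <- (fp - fm) / (2 * eps)
      if (abs(gr) < tol) break
      hess <- (fp - 2 * f0 + fm) / eps^2
      step <- if (is.finite(hess) && hess > 0) -gr / hess else -sign(gr) * 0.1
      ll <- ll + max(-1, min(1, step))
    }
    converged <- abs(gr) < tol
    lambda <- exp(ll)
    m2l <- lmm_profile(parts, lambda, reml)
    if (m2l > at_zero) { # polish must never lose to the boundary
      boundary <- TRUE; lambda <- 0; m2l <- at_zero
    }
  }

  g <- lmm_gls(parts, lambda)
  df <- if (reml) parts$N - parts$p else parts$N
  sigma_e2 <- g$rss_w / df
  sigma_u2 <- lambda * sigma_e2
  vcov_beta <- sigma_e2 * chol2inv(g$chol)
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  beta <- stats::setNames(g$beta, colnames(X))
  se <- sqrt(diag(vcov_beta))
  z <- beta / se
  coef_table <- data.frame(
    term = names(beta), estimate = beta, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    ci_lo = beta - stats::qnorm(0.975) * se,
    ci_hi = beta + stats::qnorm(0.975) * se,
    row.names = NULL)

  structure(
    list(beta = beta, se = se, vcov = vcov_beta, coef_table = coef_table,
         sigma_u2 = sigma_u2, sigma_e2 = sigma_e2, lambda = lambda,
         loglik = -m2l / 2, method = method, converged = converged,
         boundary = boundary, n_obs = parts$N,
         n_groups = nlevels(parts$id),
         assign = attr(X, "assign"),
         term_labels = attr(stats::terms(mf), "term.labels"),
         formula = fixed, history = do.call(rbind, history$log)),
    class = "woa_lmm")
}

#' @export
print.woa_lmm <- function(x, digits = 4, ...) {
  cat(sprintf("Random-intercept linear model (%s), %d obs in %d participants\n",
              x$method, x$n_obs, x$n_groups))
  cat(sprintf("  sigma_u^2 = %.*g%s, sigma_e^2 = %.*g, %s = %.*g\n",
              digits, x$sigma_u2, if (x$boundary) " (boundary)" else "",
              digits, x$sigma_e2,
              if (x$method == "REML") "restricted loglik" else "loglik",
              digits + 2, x$loglik))
  if (!x$converged) cat("  WARNING: profile optimiser did not converge\n")
  print(x$coef_table, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Joint Wald test on fitted coefficients
#'
#' Chi-square Wald test of the null that the named coefficients (or all
#' coefficients belonging to a model term, e.g. an interaction) are zero,
#' using the fitted GLS covariance of `beta`.
#'
#' @param fit a `"woa_lmm"` object.
#' @param terms coefficient names, a term label (e.g. `"arm:strength"`), or
#'   integer coefficient indices.
#' @return List with `statistic`, `df`, `p`.
#' @export
wald_test <- function(fit, terms) {
  stopifnot(inherits(fit, "woa_lmm"))
  if (length(terms) == 0) stop("`terms` must be non-empty", call. = FALSE)
  if (is.numeric(terms)) {
    idx <- as.integer(terms)
  } else if (all(terms %in% names(fit$beta))) {
    idx <- match(terms, names(fit$beta))
  } else if (all(terms %in% fit$term_labels)) {
    idx <- which(fit$assign %in% match(terms, fit$term_labels))
  } else {
    stop("`terms` must name coefficients or model terms of the fit",
         call. = FALSE)
  }
  if (length(idx) == 0 || anyNA(idx)) {
    stop("`terms` not found in the fit", call. = FALSE)
  }
  b <- fit$beta[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  stat <- as.numeric(t(b) %*% solve(V, b))
  df <- length(idx)
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Arm difference in mean weight of advice
#'
#' Convenience wrapper for the primary comparison: fits
#' `woa ~ arm` with a participant random intercept on the non-excluded
#' records and returns the clinician-minus-algorithm coefficient with its
#' 95% CI and Wald p-value.
#'
#' @param records a `"woa_records"` data frame (exclusions are honoured).
#' @param value response column (default `"woa"`).
#' @return List with `estimate`, `ci95` (length-2 vector), `p`, and the full
#'   `fit`.
#' @export
arm_difference <- function(records, value = "woa") {
  stopifnot(is.data.frame(records))
  d <- records[!records$excluded & !is.na(records[[value]]), , drop = FALSE]
  if (length(unique(d$arm)) < 2) {
    stop("both study arms must be present to estimate an arm difference",
         call. = FALSE)
  }
  d$.y <- d[[value]]
  fit <- fit_random_intercept(d, .y ~ arm)
  ct <- fit$coef_table[fit$coef_table$term == "armclinician", ]
  list(estimate = ct$estimate, ci95 = c(ct$ci_lo, ct$ci_hi), p = ct$p,
       fit = fit)
}
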