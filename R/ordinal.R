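# Multilevel proportional-odds model for binned weight-of-advice:
# cumulative logits P(Y_ij <= k | u_j) = logistic(zeta_k - x_ij'beta - u_j)
# with participant random intercept u_j ~ N(0, sigma_u^2), integrated by
# adaptive Gauss-Hermite quadrature (per-participant mode + curvature).

# Unconstrained parameterisation: (zeta_1, log diffs of zeta, beta, log sigma).
ord_unpack <- function(par, k, p, estimate_sigma) {
  zeta <- if (k == 2) par[1] else cumsum(c(par[1], exp(par[2:(k - 1)])))
  beta <- if (p > 0) par[(k - 1) + seq_len(p)] else numeric(0)
  sigma <- if (estimate_sigma) exp(par[length(par)]) else 0
  list(zeta = zeta, beta = beta, sigma = sigma)
}

# Row-wise category log-probabilities and their first two derivatives with
# respect to the random intercept, at linear predictor lp (= x'beta + u).
# zeta is padded with -Inf / Inf.
ord_cellprob <- function(y, lp, zeta) {
  zpad <- c(-Inf, zeta, Inf)
  up <- zpad[y + 1L] - lp
  lo <- zpad[y] - lp
  # F(up) - F(lo) computed stably for logistic tails
  p <- stats::plogis(up) - stats::plogis(lo)
  p <- pmax(p, 1e-300)
  f_up <- stats::dlogis(up)
  f_lo <- stats::dlogis(lo)
  # dF/du carries a factor d(up)/du = -1
  g <- (f_lo - f_up) / p
  fp_up <- f_up * (1 - 2 * stats::plogis(up))
  fp_lo <- f_lo * (1 - 2 * stats::plogis(lo))
  h <- (fp_up - fp_lo) / p - g^2
  list(logp = log(p), g = g, h = h)
}

# Vectorised Newton search for the per-participant posterior mode of u.
ord_modes <- function(y, eta, g_idx, J, zeta, sigma2, u0) {
  u <- u0
  for (iter in 1:50) {
    cp <- ord_cellprob(y, eta + u[g_idx], zeta)
    grad <- as.numeric(rowsum(cp$g, g_idx)) - u / sigma2
    hess <- as.numeric(rowsum(cp$h, g_idx)) - 1 / sigma2
    hess <- pmin(hess, -1e-8)
    step <- grad / hess
    step <- pmax(pmin(step, 2), -2)
    u <- u - step
    u[!is.finite(u)] <- 0
    if (max(abs(grad)) < 1e-9) break
  }
  cp <- ord_cellprob(y, eta + u[g_idx], zeta)
  hess <- as.numeric(rowsum(cp$h, g_idx)) - 1 / sigma2
  list(u = u, hess = pmin(hess, -1e-8))
}

# Negative marginal log-likelihood by adaptive Gauss-Hermite quadrature.
ord_nll <- function(par, y, X, g_idx, J, k, nodes, estimate_sigma, warm) {
  p <- ncol(X)
  # line searches can probe wild parameter values (overflowing thresholds,
  # enormous sigma); a large finite penalty keeps the optimiser on track
  if (any(!is.finite(par)) || any(par > 50)) return(1e10)
  th <- ord_unpack(par, k, p, estimate_sigma)
  if (any(!is.finite(th$zeta)) || !is.finite(th$sigma)) return(1e10)
  eta <- if (p > 0) as.numeric(X %*% th$beta) else numeric(length(y))
  if (!estimate_sigma || th$sigma < 1e-8) {
    cp <- ord_cellprob(y, eta, th$zeta)
    return(-sum(cp$logp))
  }
  sigma2 <- th$sigma^2
  md <- ord_modes(y, eta, g_idx, J, th$zeta, sigma2, warm$u)
  warm$u <- md$u
  s <- 1 / sqrt(-md$hess)
  # integrate exp(h(u)) du, h(u) = sum log p + log dnorm(u; 0, sigma)
  U <- outer(md$u, rep(1, length(nodes$x))) +
    sqrt(2) * s %o% nodes$x                    # J x Q abscissae
  LP <- matrix(eta, nrow = length(y), ncol = length(nodes$x)) +
    U[g_idx, , drop = FALSE]
  zpad <- c(-Inf, th$zeta, Inf)
  PU <- stats::plogis(zpad[y + 1L] - LP)
  PL <- stats::plogis(zpad[y] - LP)
  logp_rows <- log(pmax(PU - PL, 1e-300))
  H <- rowsum(logp_rows, g_idx) +
    stats::dnorm(U, 0, th$sigma, log = TRUE)   # J x Q
  A <- H + outer(rep(1, J), log(nodes$w) + nodes$x^2)
  amax <- apply(A, 1, max)
  logL <- log(sqrt(2) * s) + amax + log(rowSums(exp(A - amax)))
  out <- -sum(logL)
  if (!is.finite(out)) 1e10 else out
}

#' Fit a proportional-odds model with a participant random intercept
#'
#' Maximises the cumulative-logit likelihood
#' `P(Y <= k | u) = plogis(zeta_k - x'beta - u)` with `u ~ N(0, sigma_u^2)`
#' per participant, the marginal likelihood being evaluated by adaptive
#' Gauss-Hermite quadrature centred on each participant's posterior mode.
#' Used as the non-parametric sensitivity analysis on the five ordinal
#' weight-of-advice categories. Positive coefficients shift mass towards
#' higher categories (same convention as `MASS::polr`).
#'
#' @param data data frame with the ordinal response, covariates and the
#'   participant identifier.
#' @param fixed formula, e.g. `bin ~ arm`; the response must be integer
#'   categories `1..n_categories`.
#' @param id participant-identifier column name.
#' @param n_categories number of ordinal categories (default 5).
#' @param nodes number of quadrature nodes (default 15).
#' @param estimate_sigma estimate the random-intercept SD (default TRUE); if
#'   FALSE the model collapses to a plain proportional-odds fit.
#' @param control passed to [stats::optim()] (`BFGS`); defaults to
#'   `reltol = 1e-12, maxit = 500`.
#' @return Object of class `"woa_clmm"`: `zeta` (thresholds, strictly
#'   increasing), `beta`, `se` (from the numerical Hessian), `sigma_u2`,
#'   `loglik`, `nodes`, convergence info, and `merged_categories` when empty
#'   categories had to be collapsed.
#' @export
#' @examples
#' trial <- simulate_trial(sim_config(n_participants = 40, seed = 5))
#' rec <- per_protocol_filter(woa_records(trial))
#' fit <- fit_multilevel_ordinal(rec[!rec$excluded, ], bin ~ arm)
#' fit$beta
fit_multilevel_ordinal <- function(data, fixed, id = "participant_id",
                                   n_categories = 5L, nodes = 15L,
                                   estimate_sigma = TRUE, control = list()) {
  stopifnot(is.data.frame(data), inherits(fixed, "formula"))
  if (!id %in% names(data)) {
    stop(sprintf("id column `%s` not found in data", id), call. = FALSE)
  }
  data <- canonical_factors(as.data.frame(data))
  mf <- stats::model.frame(fixed, data, na.action = stats::na.fail)
  y <- as.integer(stats::model.response(mf))
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (any(y < 1 | y > n_categories)) {
    stop(sprintf("response categories must lie in 1..%d", n_categories),
         call. = FALSE)
  }
  gid <- factor(data[[id]])
  if (nlevels(gid) < 2) {
    stop("need at least 2 participants", call. = FALSE)
  }

  # collapse categories absent from the data (their thresholds are not
  # identifiable); record the merge so callers can interpret the cutpoints
  observed <- sort(unique(y))
  merged <- NULL
  if (length(observed) < n_categories) {
    warning("ordinal categories absent from data were merged with ",
            "neighbours: ", paste(setdiff(seq_len(n_categories), observed),
                                  collapse = ", "))
    merged <- list(original = seq_len(n_categories), observed = observed)
    y <- match(y, observed)
  }
  k <- length(unique(y))
  if (k < 2) stop("response has a single category; nothing to fit",
                  call. = FALSE)

  g_idx <- as.integer(gid)
  J <- nlevels(gid)
  p <- ncol(X)
  gh <- pracma::gaussHermite(nodes)
  nd <- list(x = gh$x, w = gh$w)
  warm <- new.env(parent = emptyenv())
  warm$u <- numeric(J)

  # empirical cumulative logits as threshold starts
  cum <- cumsum(tabulate(y, k))[1:(k - 1)] / length(y)
  zeta0 <- stats::qlogis(pmin(pmax(cum, 1e-3), 1 - 1e-3))
  zeta0 <- cummax(zeta0 + seq_len(k - 1) * 1e-6)
  par0 <- c(zeta0[1], log(pmax(diff(zeta0), 1e-3)), rep(0, p))

  ctrl <- utils::modifyList(list(reltol = 1e-12, maxit = 500), control)

  # stage 1: plain proportional-odds fit (also the sigma = 0 collapse)
  fit0 <- stats::optim(par0, ord_nll, y = y, X = X, g_idx = g_idx, J = J,
                       k = k, nodes = nd, estimate_sigma = FALSE, warm = warm,
                       method = "BFGS", control = ctrl)
  if (!estimate_sigma) {
    opt <- fit0
  } else {
    par1 <- c(fit0$par, log(0.5))
    opt <- stats::optim(par1, ord_nll, y = y, X = X, g_idx = g_idx, J = J,
                        k = k, nodes = nd, estimate_sigma = TRUE, warm = warm,
                        method = "BFGS", control = ctrl, hessian = TRUE)
  }
  th <- ord_unpack(opt$par, k, p, estimate_sigma)
  se_beta <- rep(NA_real_, p)
  if (estimate_sigma && p > 0) {
    vc <- try(solve(opt$hessian), silent = TRUE)
    if (!inherits(vc, "try-error")) {
      se_beta <- sqrt(pmax(diag(vc)[(k - 1) + seq_len(p)], 0))
    }
  }
  structure(
    list(zeta = th$zeta, beta = stats::setNames(th$beta, colnames(X)),
         se = stats::setNames(se_beta, colnames(X)),
         sigma_u2 = th$sigma^2, loglik = -opt$value,
         nodes = nodes, n_obs = length(y), n_groups = J,
         n_categories = k, merged_categories = merged,
         converged = opt$convergence == 0,
         formula = fixed),
    class = "woa_clmm")
}

#' @export
print.woa_clmm <- function(x, digits = 4, ...) {
  cat(sprintf(paste0("Multilevel proportional-odds model: %d obs, %d ",
                     "participants, %d categories\n"),
              x$n_obs, x$n_groups, x$n_categories))
  cat(sprintf("  adaptive Gauss-Hermite, %d nodes; sigma_u^2 = %.*g; loglik = %.*g\n",
              x$nodes, digits, x$sigma_u2, digits + 2, x$loglik))
  if (!x$converged) cat("  WARNING: optimiser did not converge\n")
  cat("  thresholds:", paste(signif(x$zeta, digits), collapse = " "), "\n")
  if (length(x$beta)) {
    print(data.frame(term = names(x$beta), estimate = x$beta, se = x$se,
                     row.names = NULL), digits = digits, row.names = FALSE)
  }
  if (!is.null(x$merged_categories)) {
    cat("  note: unobserved categories merged; thresholds refer to observed",
        "levels", paste(x$merged_categories$observed, collapse = " "), "\n")
  }
  invisible(x)
}
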