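# Independent oracles used to check the package's own implementations.
# Each oracle is deliberately naive (dense matrices, ANOVA closed forms,
# numeric integration) and shares no code with the implementation paths.

# Dense per-cluster multivariate-normal log-likelihood of the
# random-intercept model, ML form (no structure exploited).
oracle_mvn_loglik <- function(y, X, id, sigma_u2, sigma_e2, beta) {
  sum(vapply(split(seq_along(y), id), function(ix) {
    V <- sigma_e2 * diag(length(ix)) +
      sigma_u2 * matrix(1, length(ix), length(ix))
    r <- y[ix] - X[ix, , drop = FALSE] %*% beta
    as.numeric(-0.5 * (determinant(V)$modulus + t(r) %*% solve(V, r) +
                         length(ix) * log(2 * pi)))
  }, numeric(1)))
}

# Dense restricted log-likelihood (Harville form): ML loglik at the GLS beta
# plus the beta-integration term, all computed with dense solves.
oracle_reml_loglik <- function(y, X, id, sigma_u2, sigma_e2) {
  blocks <- split(seq_along(y), id)
  XtViX <- matrix(0, ncol(X), ncol(X))
  XtViy <- numeric(ncol(X))
  for (ix in blocks) {
    V <- sigma_e2 * diag(length(ix)) +
      sigma_u2 * matrix(1, length(ix), length(ix))
    Xi <- X[ix, , drop = FALSE]
    XtViX <- XtViX + t(Xi) %*% solve(V, Xi)
    XtViy <- XtViy + t(Xi) %*% solve(V, y[ix])
  }
  beta <- solve(XtViX, XtViy)
  oracle_mvn_loglik(y, X, id, sigma_u2, sigma_e2, beta) +
    0.5 * (ncol(X) * log(2 * pi) - as.numeric(determinant(XtViX)$modulus))
}

# Closed-form estimates for the balanced nested design: J participants with m
# records each, one cluster-level two-arm factor, no other covariates.
# ANOVA mean squares solve the REML equations exactly in this design.
oracle_balanced_fit <- function(y, id, arm) {
  id <- factor(id)
  m <- length(y) / nlevels(id)
  ybar_j <- tapply(y, id, mean)
  arm_j <- tapply(as.character(arm), id, unique)
  ybar_arm <- tapply(ybar_j, arm_j, mean)
  mse <- sum((y - ybar_j[id])^2) / (length(y) - nlevels(id))
  msb <- m * sum((ybar_j - ybar_arm[arm_j])^2) / (nlevels(id) - 2)
  list(beta = c(intercept = unname(ybar_arm["algorithm"]),
                armclinician = unname(ybar_arm["clinician"] -
                                        ybar_arm["algorithm"])),
       sigma_e2 = mse,
       sigma_u2 = max(0, (msb - mse) / m))
}

# Truncated-normal moments by numeric integration on [lo, hi].
oracle_truncnorm_moments <- function(mean, sd, lo = 0, hi = 100) {
  z <- stats::integrate(function(x) stats::dnorm(x, mean, sd), lo, hi)$value
  m1 <- stats::integrate(function(x) x * stats::dnorm(x, mean, sd),
                         lo, hi)$value / z
  m2 <- stats::integrate(function(x) x^2 * stats::dnorm(x, mean, sd),
                         lo, hi)$value / z
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

# Closed-form two-sample normal-approximation sample size (per arm).
oracle_per_arm_n <- function(sd, diff, alpha = 0.05, power = 0.8) {
  ceiling(2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 * (sd / diff)^2)
}

# Simulate clustered ordinal responses directly from the cumulative-logit
# random-intercept model (independent of the fitting code).
r_ordinal_df <- function(J, m, zeta, beta_arm, sigma_u, seed) {
  set.seed(seed)
  arm <- rep(c("algorithm", "clinician"), length.out = J)
  u <- rnorm(J, 0, sigma_u)
  do.call(rbind, lapply(seq_len(J), function(j) {
    eta <- (arm[j] == "clinician") * beta_arm + u[j]
    pr <- diff(c(0, plogis(c(zeta, Inf) - eta)))
    data.frame(participant_id = sprintf("p%03d", j), arm = arm[j],
               bin = sample.int(length(pr), m, replace = TRUE, prob = pr),
               stringsAsFactors = FALSE)
  }))
}

# Minimal hand-built records data frame for WOA-level tests.
make_records <- function(woa, arm, id = seq_along(woa), completed = TRUE) {
  data.frame(participant_id = sprintf("p%03d", id), vignette_id = "v1",
             arm = arm, strength = 90, profession = "doctor",
             total_experience = "<=14", palliative_experience = "<=5",
             initial = 60, final = 60, completed = completed,
             raw_woa = woa, woa = woa, bin = woasim::bin_woa(pmin(1, pmax(0, woa))),
             excluded = FALSE, reason = NA_character_,
             stringsAsFactors = FALSE)
}
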