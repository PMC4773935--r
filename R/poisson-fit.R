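# Shared Poisson likelihood fitter for the projection engines.
#
# Model: y_i ~ Poisson(mu_i),  mu_i = E_i * max(eta_i, 0)^k,  eta = X beta,
# where E_i is person-years / 100,000 so that eta^k is a rate per 100,000.
# k = 5 gives the power-5 link used for long-term age-period-cohort
# projection; k = 1 gives the identity-in-rate link of the age-specific
# linear-trend engine. Fitting is Fisher scoring (IRLS) with step halving
# and a floor on the linear predictor, which the power link requires to
# keep rates non-negative. Deterministic: no random initialisation, the
# caller supplies the null-model start.

poisson_power_fit <- function(X, y, exposure, power = 5, start,
                              tol = 1e-8, maxit = 100L) {
  k <- power
  eps <- 1e-10
  dev_fun <- function(mu) {
    mu <- pmax(mu, 1e-300)
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  }
  mu_of <- function(eta) exposure * pmax(eta, 0)^k

  beta <- start
  eta <- as.vector(X %*% beta)
  dev <- dev_fun(mu_of(eta))
  converged <- FALSE
  floored <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    if (any(eta < 0)) floored <- TRUE
    etaf <- pmax(eta, eps)
    mu <- exposure * etaf^k
    mu_prime <- exposure * k * etaf^(k - 1)
    w <- exposure * k^2 * etaf^(k - 2)        # (mu')^2 / mu
    z <- etaf + (y - mu) / mu_prime
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit)) break
    beta_new <- fit$coefficients
    beta_new[is.na(beta_new)] <- 0
    step <- 1
    repeat {
      beta_try <- beta + step * (beta_new - beta)
      eta_try <- as.vector(X %*% beta_try)
      dev_try <- dev_fun(mu_of(eta_try))
      if (is.finite(dev_try) && dev_try <= dev + 1e-12) break
      step <- step / 2
      if (step < 1e-8) {
        beta_try <- beta
        eta_try <- eta
        dev_try <- dev
        break
      }
    }
    rel_change <- abs(dev_try - dev) / (abs(dev_try) + 0.1)
    beta <- beta_try
    eta <- eta_try
    dev <- dev_try
    if (rel_change < tol) {
      converged <- TRUE
      break
    }
  }

  etaf <- pmax(eta, eps)
  w <- exposure * k^2 * etaf^(k - 2)
  xtwx <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(xtwx), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  list(coefficients = beta, eta = eta, fitted = mu_of(eta),
       deviance = dev, converged = converged, iterations = it,
       floored = floored, cov = cov)
}
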