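## Bayesian phylogenetic threshold (liability) model for a binary trait.
##
## Model:  y_i = 1  iff  l_i > 0,   l = mu + u + e,
##         u ~ N(0, sigma_p^2 * Vs),   e ~ N(0, I)
## where Vs is the Brownian-motion covariance of the species tree scaled to
## unit mean diagonal.  The residual variance is fixed at 1 (a binary
## threshold model is otherwise unidentifiable), so the phylogenetic
## heritability of the liability is h2 = sigma_p^2 / (sigma_p^2 + 1).
##
## Sampling: Gibbs with data augmentation on the liabilities (one-sided
## truncated normals), conjugate updates for u (in the eigenbasis of Vs) and
## mu (flat prior), and a slice-sampling update for sigma_p^2 under a
## half-Cauchy prior on sigma_p.

## vectorized sampler for N(mean, 1) truncated to sgn * l > 0, with
## sgn = +1 (y = 1, liability above the threshold) or -1 (y = 0).
## Inversion in the well-conditioned range, Robert (1995) exponential
## rejection in the far tail.
rtruncnorm01 <- function(mean, sgn) {
  a <- -sgn * mean  # standardized truncation point, X > a
  n <- length(a)
  if (all(a < 5)) {
    pa <- pnorm(a)
    x <- qnorm(pmin(pa + runif(n) * (1 - pa), 1 - 1e-16))
    return(mean + sgn * x)
  }
  x <- numeric(n)
  easy <- a < 5
  pa <- pnorm(a[easy])
  x[easy] <- qnorm(pmin(pa + runif(sum(easy)) * (1 - pa), 1 - 1e-16))
  ah <- a[!easy]
  lam <- (ah + sqrt(ah^2 + 4)) / 2
  m <- length(ah)
  z <- numeric(m)
  todo <- rep(TRUE, m)
  while (any(todo)) {
    k <- sum(todo)
    prop <- ah[todo] - log(runif(k)) / lam[todo]
    acc <- runif(k) <= exp(-(prop - lam[todo])^2 / 2)
    z[todo][acc] <- prop[acc]
    todo[todo] <- !acc
  }
  x[!easy] <- z
  mean + sgn * x
}

## slice sampler step for t = log(sigma_p^2) given
## S = sum(w_i^2 / lambda_i) over the k positive eigenvalues, with a
## half-Cauchy(scale) prior on sigma_p.
slice_log_sigma2 <- function(t0, k, S, scale, width = 2, max_step = 20) {
  logpost <- function(t) {
    s2 <- exp(t)
    -(k / 2) * t - S / (2 * s2) +               # likelihood of w
      0.5 * t - log1p(s2 / scale^2) +           # half-Cauchy prior on sigma
      0                                         # (jacobians folded in)
  }
  y <- logpost(t0) - stats::rexp(1)
  lo <- t0 - runif(1) * width
  hi <- lo + width
  for (i in seq_len(max_step)) {
    if (logpost(lo) < y) break
    lo <- lo - width
  }
  for (i in seq_len(max_step)) {
    if (logpost(hi) < y) break
    hi <- hi + width
  }
  repeat {
    t1 <- runif(1, lo, hi)
    if (logpost(t1) >= y) return(t1)
    if (t1 < t0) lo <- t1 else hi <- t1
  }
}

## simple effective sample size from the autocorrelation function
ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
  pos <- which(rho < 0.05)
  keep <- if (length(pos) > 0) seq_len(pos[1] - 1) else seq_along(rho)
  max(1, n / (1 + 2 * sum(rho[keep])))
}

#' Fit the phylogenetic threshold model to a binary trait
#'
#' Estimates the proportion of variance in the latent liability of a binary
#' trait (e.g., use or nonuse of one host taxon) attributable to the
#' phylogeny, `h2 = sigma_p^2 / (sigma_p^2 + 1)`, by MCMC.  The
#' phylogenetic covariance `V` is scaled to unit mean diagonal before
#' fitting, so estimates are invariant to rescaling all branch lengths; the
#' residual liability variance is fixed at 1.
#'
#' @param y binary 0/1 vector over species (both classes must occur).  If
#'   named, names must match the rows of `V`.
#' @param V phylogenetic variance-covariance matrix ([phylo_vcv()]).
#' @param mcmc list of chain settings: `nitt` (total iterations, default
#'   13000), `burnin` (default 3000), `thin` (default 10).
#' @param prior_scale scale of the half-Cauchy prior on `sigma_p`
#'   (default 1).
#' @param seed optional integer seed; fits with the same seed and settings
#'   are identical.
#' @return object of class `phylo_threshold` with posterior mean `h2`, 95%
#'   credible interval `h2_ci`, posterior draws `h2_samples` and
#'   `sigma2_samples`, posterior mean intercept `mu`, effective sample size
#'   `ess_h2`, and the chain settings.
#' @export
fit_signal <- function(y, V, mcmc = list(nitt = 13000, burnin = 3000, thin = 10),
                       prior_scale = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2) stop("signal undefined: y is constant")
  n <- length(y)
  if (!is.matrix(V) || nrow(V) != n || ncol(V) != n) {
    stop("V must be a square matrix conformable with y")
  }
  nitt <- mcmc$nitt %||% 13000
  burnin <- mcmc$burnin %||% 3000
  thin <- mcmc$thin %||% 10

  Vs <- V / mean(diag(V))
  ee <- eigen(Vs, symmetric = TRUE)
  lam <- ee$values
  if (min(lam) < -1e-6 * max(lam)) stop("V is not positive semidefinite")
  lam <- pmax(lam, 0)
  pos <- lam > 1e-10 * max(lam)
  k_pos <- sum(pos)
  Q <- ee$vectors

  ## state
  mu <- 0
  sig2 <- 0.5
  w <- numeric(n)       # coordinates of u in the eigenbasis
  u <- numeric(n)
  sgn <- 2 * y - 1
  lam_pos <- lam[pos]
  inv_lam_pos <- 1 / lam_pos

  n_keep <- floor((nitt - burnin) / thin)
  h2_draws <- numeric(n_keep)
  sig2_draws <- numeric(n_keep)
  mu_draws <- numeric(n_keep)
  kept <- 0L

  for (it in seq_len(nitt)) {
    ## liabilities
    l <- rtruncnorm01(mu + u, sgn)
    ## random effect in eigenbasis
    r <- l - mu
    z <- crossprod(Q, r)
    v_post <- sig2 * lam / (sig2 * lam + 1)
    v_post[!pos] <- 0
    w <- rnorm(n) * sqrt(v_post) + v_post * z
    u <- Q %*% w
    ## intercept, flat prior
    mu <- rnorm(1, mean = mean(l - u), sd = sqrt(1 / n))
    ## phylogenetic variance, half-Cauchy prior via slice sampling
    S <- sum(w[pos]^2 * inv_lam_pos)
    t_new <- slice_log_sigma2(log(sig2), k_pos, S, prior_scale)
    sig2 <- exp(min(max(t_new, -30), 10))

    if (it > burnin && (it - burnin) %% thin == 0) {
      kept <- kept + 1L
      sig2_draws[kept] <- sig2
      h2_draws[kept] <- sig2 / (sig2 + 1)
      mu_draws[kept] <- mu
    }
  }

  structure(list(
    h2 = mean(h2_draws),
    h2_ci = unname(quantile(h2_draws, c(0.025, 0.975))),
    h2_samples = h2_draws,
    sigma2_samples = sig2_draws,
    mu = mean(mu_draws),
    ess_h2 = ess(h2_draws),
    mcmc = list(nitt = nitt, burnin = burnin, thin = thin),
    prior_scale = prior_scale,
    n = n
  ), class = "phylo_threshold")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.phylo_threshold <- function(x, digits = 3, ...) {
  cat("Phylogenetic threshold (liability) model\n")
  cat(sprintf("  species: %d   chain: %d iterations, %d burn-in, thin %d\n",
              x$n, x$mcmc$nitt, x$mcmc$burnin, x$mcmc$thin))
  cat(sprintf("  h2 (phylogenetic heritability of liability): %.*f  [%.*f, %.*f]\n",
              digits, x$h2, digits, x$h2_ci[1], digits, x$h2_ci[2]))
  cat(sprintf("  effective sample size (h2): %.0f\n", x$ess_h2))
  invisible(x)
}

#' @export
summary.phylo_threshold <- function(object, ...) {
  print(object)
  cat(sprintf("  posterior mean sigma_p^2: %.3f   intercept mu: %.3f\n",
              mean(object$sigma2_samples), object$mu))
  invisible(object)
}

#' @export
coef.phylo_threshold <- function(object, ...) {
  c(h2 = object$h2, sigma2_p = mean(object$sigma2_samples), mu = object$mu)
}
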