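# Bayesian univariate Gaussian mixtures for length-based age-class (cohort)
# inference, with two procedures for choosing the number of components K:
# the overfitted-mixture weight-truncation rule and birth-death MCMC.

mix_priors <- function(x, priors = NULL) {
  # weakly informative, range-anchored defaults; the within-component
  # variance prior is an inverse-gamma with mean equal to the sample variance
  defaults <- list(
    m0 = mean(x), tau2 = max(diff(range(x)), 1e-6)^2,
    a0 = 2.5, b0 = 1.5 * max(stats::var(x), 1e-6),
    dirichlet = 1
  )
  utils::modifyList(defaults, if (is.null(priors)) list() else priors)
}

mix_mcmc_defaults <- function(mcmc = NULL) {
  utils::modifyList(list(iter = 10000L, burn = 2000L, thin = 5L),
                    if (is.null(mcmc)) list() else mcmc)
}

# one categorical draw per row of a probability matrix, vectorized
sample_rows <- function(P) {
  cp <- P %*% upper.tri(diag(ncol(P)), diag = TRUE)
  rowSums(stats::runif(nrow(P)) > cp) + 1L
}

#' Fit a Gaussian mixture with fixed K by Gibbs sampling
#'
#' Conjugate Gibbs sampler for a univariate normal mixture: component
#' assignments, Dirichlet weights, normal means and inverse-gamma variances.
#' Label switching is resolved by relabeling each retained draw so component
#' means are ascending; reported parameters are posterior means over
#' relabeled draws, and responsibilities are posterior-mean membership
#' probabilities.
#'
#' @param lengths positive numeric vector (larval total lengths, mm).
#' @param K number of components.
#' @param priors optional list overriding `m0`, `tau2`, `a0`, `b0`,
#'   `dirichlet`.
#' @param mcmc list with `iter` (default 10000), `burn` (2000), `thin` (5).
#' @param seed integer seed.
#' @return An object of class `mixture_fit`: `K`, `weights`, `means`, `sds`
#'   (ascending mean order), `responsibilities` (n x K, rows sum to 1),
#'   `weight_draws` (retained relabeled weight draws), `mcmc` settings.
#' @export
fit_mixture_fixed_k <- function(lengths, K, priors = NULL, mcmc = NULL,
                                seed = 1L) {
  x <- as.numeric(lengths)
  if (any(!is.finite(x))) stop("lengths must be finite")
  n <- length(x)
  if (K > n) stop("K exceeds the number of observations")
  if (K < 1) stop("K must be >= 1")
  pr <- mix_priors(x, priors)
  mc <- mix_mcmc_defaults(mcmc)
  set.seed(seed)

  # init from quantile bins
  z <- if (K == 1) rep(1L, n) else
    as.integer(cut(rank(x, ties.method = "first"), K, labels = FALSE))
  mu <- as.numeric(tapply(x, z, mean))
  s2 <- rep(max(stats::var(x) / K, 1e-6), K)
  w <- rep(1 / K, K)

  keep <- seq(mc$burn + 1L, mc$iter, by = mc$thin)
  n_keep <- length(keep)
  W <- matrix(NA_real_, n_keep, K)
  MU <- matrix(NA_real_, n_keep, K)
  S2 <- matrix(NA_real_, n_keep, K)
  R <- matrix(0, n, K)
  ki <- 0L
  for (it in seq_len(mc$iter)) {
    # responsibilities and assignments
    lp <- vapply(seq_len(K), function(k)
      log(w[k]) + stats::dnorm(x, mu[k], sqrt(s2[k]), log = TRUE),
      numeric(n))
    lp <- lp - apply(lp, 1, max)
    P <- exp(lp); P <- P / rowSums(P)
    z <- sample_rows(P)

    nk <- tabulate(z, K)
    w <- stats::rgamma(K, pr$dirichlet + nk, 1)
    w <- w / sum(w)
    for (k in seq_len(K)) {
      xk <- x[z == k]
      prec <- nk[k] / s2[k] + 1 / pr$tau2
      mean_k <- (sum(xk) / s2[k] + pr$m0 / pr$tau2) / prec
      mu[k] <- stats::rnorm(1, mean_k, sqrt(1 / prec))
      ss <- sum((xk - mu[k])^2)
      s2[k] <- 1 / stats::rgamma(1, pr$a0 + nk[k] / 2, pr$b0 + ss / 2)
    }

    if (it %in% keep) {
      ki <- ki + 1L
      ord <- order(mu)
      W[ki, ] <- w[ord]; MU[ki, ] <- mu[ord]; S2[ki, ] <- s2[ord]
      R <- R + P[, ord, drop = FALSE]
    }
  }
  R <- R / n_keep
  structure(
    list(K = K, weights = colMeans(W), means = colMeans(MU),
         sds = sqrt(colMeans(S2)), responsibilities = R,
         weight_draws = W, mean_draws = MU,
         mcmc = c(mc, n_saved = n_keep), priors = pr, n = n),
    class = c("mixture_fit", "list")
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: K = %d, n = %d\n", x$K, x$n))
  print(data.frame(weight = round(x$weights, 3), mean = round(x$means, 2),
                   sd = round(x$sds, 2)), row.names = FALSE)
  invisible(x)
}

#' Posterior over K from an overfitted mixture
#'
#' Fits a deliberately overfitted mixture with `k_max` components and, in
#' every retained draw, counts the components whose weight is at least
#' `cutoff`; the posterior probability of K = k is the fraction of draws
#' with exactly k surviving components (the weight-truncation rule for
#' overfitted mixtures, applied per draw).
#'
#' @param lengths numeric vector.
#' @param k_max overfitted component count (default 10).
#' @param cutoff membership-proportion cutoff (default 0.035); values
#'   outside the conventional 0.01-0.05 band trigger a warning.
#' @param priors,mcmc,seed passed to [fit_mixture_fixed_k()].
#' @return Object of class `k_posterior`: `method = "overfitted_cutoff"`,
#'   `prob` named vector over 1..k_max summing to 1, and the `fit`.
#' @export
posterior_k_overfitted <- function(lengths, k_max = 10, cutoff = 0.035,
                                   priors = NULL, mcmc = NULL, seed = 1L) {
  if (k_max < 2) stop("k_max must be >= 2")
  if (cutoff < 0.01 || cutoff > 0.05) {
    warning("cutoff ", cutoff, " is outside the conventional band [0.01, 0.05]")
  }
  # sparse Dirichlet concentration: an overfitted mixture only empties its
  # surplus components when the weight prior is sparse (asymptotically,
  # concentration below d/2); with a flat Dirichlet the truncation rule
  # overcounts badly on unimodal data
  if (is.null(priors)) priors <- list()
  if (is.null(priors$dirichlet)) priors$dirichlet <- 1 / k_max
  fit <- fit_mixture_fixed_k(lengths, K = k_max, priors = priors,
                             mcmc = mcmc, seed = seed)
  surv <- rowSums(fit$weight_draws >= cutoff)
  surv <- pmax(pmin(surv, k_max), 1)
  prob <- tabulate(surv, k_max) / length(surv)
  structure(list(method = "overfitted_cutoff",
                 prob = setNames(prob, seq_len(k_max)), fit = fit),
            class = c("k_posterior", "list"))
}

#' @export
print.k_posterior <- function(x, ...) {
  cat("k_posterior (", x$method, ")\n", sep = "")
  print(round(x$prob[x$prob > 0.001], 3))
  invisible(x)
}

# log-likelihood of data under a weighted normal mixture, plus the n x k
# matrix of weighted component densities (reused for death rates)
mix_loglik <- function(x, w, mu, s2) {
  D <- vapply(seq_along(w), function(k)
    w[k] * stats::dnorm(x, mu[k], sqrt(s2[k])), numeric(length(x)))
  D <- matrix(D, nrow = length(x))
  list(ll = sum(log(rowSums(D))), D = D)
}

#' Posterior over K from birth-death MCMC
#'
#' Treats K as a model parameter: between conjugate Gibbs sweeps, a
#' continuous-time birth-death process runs for one unit of virtual time.
#' Births occur at rate `birth_rate` with the new component drawn from the
#' prior and a Beta(1, k) weight; each component dies at a rate equal to
#' `birth_rate` times the likelihood ratio of the model without it (weights
#' renormalized), so stationary preference follows the data. The posterior
#' over K is the sojourn-time average of the component count after burn-in.
#'
#' @param lengths numeric vector.
#' @param k_max maximum K (default 10; uniform prior on 1..k_max).
#' @param birth_rate birth intensity (default 1).
#' @param priors,mcmc,seed as in [fit_mixture_fixed_k()].
#' @return Object of class `k_posterior` with `method = "bd_mcmc"`,
#'   `prob` over 1..k_max, and `diagnostics` (`n_births`, `n_deaths`,
#'   `stuck` flag set when the chain never changes dimension).
#' @export
posterior_k_bdmcmc <- function(lengths, k_max = 10, birth_rate = 1,
                               priors = NULL, mcmc = NULL, seed = 1L) {
  if (k_max < 2) stop("k_max must be >= 2")
  x <- as.numeric(lengths)
  if (any(!is.finite(x))) stop("lengths must be finite")
  n <- length(x)
  pr <- mix_priors(x, priors)
  mc <- mix_mcmc_defaults(mcmc)
  set.seed(seed)

  k <- 1L
  mu <- mean(x); s2 <- stats::var(x); w <- 1
  sojourn <- numeric(k_max)
  n_births <- 0L; n_deaths <- 0L
  max_events <- 100L

  for (it in seq_len(mc$iter)) {
    # birth-death process for one unit of virtual time
    t <- 0
    ev <- 0L
    repeat {
      ml <- mix_loglik(x, w, mu, s2)
      if (k > 1) {
        # log-likelihood with component j removed, weights renormalized
        ll_wo <- vapply(seq_len(k), function(j) {
          sum(log(pmax(rowSums(ml$D[, -j, drop = FALSE]), 1e-300))) -
            n * log(1 - w[j])
        }, numeric(1))
        death <- birth_rate * exp(pmin(ll_wo - ml$ll, 50))
      } else {
        death <- numeric(0)
      }
      lam_b <- if (k < k_max) birth_rate else 0
      total <- lam_b + sum(death)
      dt <- if (total > 0) stats::rexp(1, total) else Inf
      if (it > mc$burn) sojourn[k] <- sojourn[k] + min(dt, 1 - t)
      t <- t + dt
      ev <- ev + 1L
      if (t >= 1 || ev > max_events || !is.finite(dt)) break
      if (stats::runif(1) < lam_b / total) {
        wb <- stats::rbeta(1, 1, k)
        w <- c(w * (1 - wb), wb)
        mu <- c(mu, stats::rnorm(1, pr$m0, sqrt(pr$tau2)))
        s2 <- c(s2, 1 / stats::rgamma(1, pr$a0, pr$b0))
        k <- k + 1L
        n_births <- n_births + 1L
      } else {
        j <- sample.int(k, 1, prob = death)
        w <- w[-j] / (1 - w[j])
        mu <- mu[-j]; s2 <- s2[-j]
        k <- k - 1L
        n_deaths <- n_deaths + 1L
      }
    }

    # conjugate Gibbs sweep at the current dimension
    lp <- vapply(seq_len(k), function(kk)
      log(w[kk]) + stats::dnorm(x, mu[kk], sqrt(s2[kk]), log = TRUE),
      numeric(n))
    lp <- matrix(lp, nrow = n)
    lp <- lp - apply(lp, 1, max)
    P <- exp(lp); P <- P / rowSums(P)
    z <- sample_rows(P)
    nk <- tabulate(z, k)
    w <- stats::rgamma(k, 1 + nk, 1); w <- w / sum(w)
    for (kk in seq_len(k)) {
      xk <- x[z == kk]
      prec <- nk[kk] / s2[kk] + 1 / pr$tau2
      mean_k <- (sum(xk) / s2[kk] + pr$m0 / pr$tau2) / prec
      mu[kk] <- stats::rnorm(1, mean_k, sqrt(1 / prec))
      s2[kk] <- 1 / stats::rgamma(1, pr$a0 + nk[kk] / 2,
                                  pr$b0 + sum((xk - mu[kk])^2) / 2)
    }
  }

  if (sum(sojourn) == 0) sojourn[k] <- 1  # degenerate short runs
  prob <- sojourn / sum(sojourn)
  stuck <- (n_births + n_deaths) == 0L
  if (stuck) {
    warning("birth-death chain never changed dimension; treat the K ",
            "posterior as unreliable")
  }
  structure(
    list(method = "bd_mcmc", prob = setNames(prob, seq_len(k_max)),
         diagnostics = list(n_births = n_births, n_deaths = n_deaths,
                            stuck = stuck)),
    class = c("k_posterior", "list")
  )
}

#' Consensus K selection and final cohort assignment
#'
#' Applies the consensus rule between two K posteriors: if their modes
#' agree, that K is used; otherwise the mode with the higher posterior
#' probability wins; an exact probability tie resolves to the smaller K
#' (parsimony) with a message. A final fixed-K mixture is then fitted and
#' individuals are labeled by maximum responsibility.
#'
#' @param lengths numeric vector.
#' @param kp1,kp2 two [posterior_k_overfitted()]/[posterior_k_bdmcmc()]
#'   results over the same K range.
#' @param priors,mcmc,seed passed to the final [fit_mixture_fixed_k()].
#' @return List: `K`, `fit` (the final `mixture_fit`), `labels` (integer
#'   component per individual, components in ascending mean order),
#'   `selection` (modes, probabilities, rule used).
#' @export
select_k_and_assign <- function(lengths, kp1, kp2, priors = NULL,
                                mcmc = NULL, seed = 1L) {
  stopifnot(length(kp1$prob) == length(kp2$prob))
  mode1 <- as.integer(names(which.max(kp1$prob)))
  mode2 <- as.integer(names(which.max(kp2$prob)))
  p1 <- max(kp1$prob); p2 <- max(kp2$prob)
  if (mode1 == mode2) {
    K <- mode1; rule <- "consensus"
  } else if (p1 > p2) {
    K <- mode1; rule <- "higher_probability"
  } else if (p2 > p1) {
    K <- mode2; rule <- "higher_probability"
  } else {
    K <- min(mode1, mode2); rule <- "tie_smaller_k"
    message("K posterior tie (p = ", p1, "); choosing the smaller K = ", K)
  }
  fit <- fit_mixture_fixed_k(lengths, K = K, priors = priors, mcmc = mcmc,
                             seed = seed)
  labels <- max.col(fit$responsibilities, ties.method = "first")
  list(K = K, fit = fit, labels = labels,
       selection = list(mode1 = mode1, p1 = p1, mode2 = mode2, p2 = p2,
                        rule = rule))
}
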