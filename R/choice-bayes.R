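# Univariate slice sampler (stepping out + shrinkage, Neal 2003).  Used for
# the two scale parameters, whose half-normal priors are not conditionally
# conjugate; the procedure is tuning-free and leaves the target invariant.
.slice1 <- function(x0, logf, w = 0.5, lower = 1e-8, upper = Inf,
                    max_steps = 50L) {
  logy <- logf(x0) - stats::rexp(1)
  u <- runif(1, 0, w)
  L <- max(lower, x0 - u)
  R <- min(upper, L + w)
  j <- floor(runif(1) * max_steps)
  k <- max_steps - 1 - j
  while (j > 0 && L > lower && logf(L) > logy) { L <- max(lower, L - w); j <- j - 1 }
  while (k > 0 && R < upper && logf(R) > logy) { R <- min(upper, R + w); k <- k - 1 }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

#' Bayesian posterior for the per-cluster choice probability
#'
#' Oviposition decisions are coded 1 when the cluster lies on the tested
#' side (active speaker, or the hydrated plant in the baseline experiment)
#' and 0 otherwise.  A Gaussian likelihood is placed directly on the binary
#' codes, with a normal prior N(0.5, 0.1^2) on the mean choice probability
#' \code{mu} (centred on indifference), an optional normal random intercept
#' grouped by the experiment's female count, and half-normal(0, 1) priors on
#' the residual and random-intercept SDs.  \code{mu} and the intercepts are
#' updated by their exact conjugate normal conditionals; the two SDs by
#' slice sampling.  With no random effect and a fixed residual SD the draws
#' are exact iid samples from the closed-form conjugate posterior.
#'
#' An empty choice set returns the prior (draws from N(0.5, 0.1^2)); this is
#' documented behaviour, not an error.
#'
#' @param choices data frame with column \code{choice01} (0/1) and, when the
#'   random effect is used, the grouping column.
#' @param n_draws number of retained posterior draws.
#' @param seed integer seed; draws are reproducible.
#' @param prior_mean,prior_sd normal prior on \code{mu}.
#' @param group name of the grouping column for the random intercept, or
#'   \code{NULL} to disable the random effect.
#' @param sigma_fixed fix the residual SD at this value instead of sampling
#'   it (\code{NULL} to sample).
#' @param burnin discarded initial Gibbs sweeps.
#' @return object of class \code{choice_posterior}: \code{draws} (mu),
#'   \code{sigma_draws}, \code{group_effect_sd} (tau draws or NULL),
#'   \code{summary} (posterior mean and 95\% credible interval),
#'   \code{prior_mean}, \code{prior_sd}, \code{n_obs}.
#' @examples
#' ch <- data.frame(choice01 = rep(c(1, 0), c(15, 5)), n_females = 11)
#' post <- bayes_choice_posterior(ch, n_draws = 2000, seed = 1)
#' post$summary
#' @export
bayes_choice_posterior <- function(choices, n_draws = 16000, seed = NULL,
                                   prior_mean = 0.5, prior_sd = 0.1,
                                   group = "n_females", sigma_fixed = NULL,
                                   burnin = 1000) {
  stopifnot(n_draws >= 1, prior_sd > 0, is.null(sigma_fixed) || sigma_fixed > 0)
  y <- if (is.data.frame(choices)) choices$choice01 else as.numeric(choices)
  if (!is.null(y) && length(y) && !all(y %in% c(0, 1)))
    stop("choice01 must be coded 0/1", call. = FALSE)
  n <- length(y)

  with_seed(seed, {
    if (n == 0) {
      mu <- rnorm(n_draws, prior_mean, prior_sd)
      return(.choice_posterior(mu, NULL, NULL, prior_mean, prior_sd, 0L))
    }
    gidx <- NULL
    if (!is.null(group) && is.data.frame(choices) && group %in% names(choices)) {
      gf <- factor(choices[[group]])
      if (nlevels(gf) > 1L) gidx <- as.integer(gf)
    }
    G <- if (is.null(gidx)) 0L else max(gidx)
    ng <- if (G) tabulate(gidx, G) else integer(0)

    mu <- prior_mean
    b <- numeric(G)
    sigma <- if (is.null(sigma_fixed)) 0.5 else sigma_fixed
    tau <- 0.1
    total <- burnin + n_draws
    mu_d <- sig_d <- numeric(n_draws)
    tau_d <- if (G) numeric(n_draws) else NULL
    for (it in seq_len(total)) {
      off <- if (G) b[gidx] else 0
      prec <- 1 / prior_sd^2 + n / sigma^2
      m <- (prior_mean / prior_sd^2 + sum(y - off) / sigma^2) / prec
      mu <- rnorm(1, m, sqrt(1 / prec))
      if (G) {
        r <- y - mu
        sg <- vapply(seq_len(G), function(g) sum(r[gidx == g]), numeric(1))
        precb <- 1 / tau^2 + ng / sigma^2
        b <- rnorm(G, (sg / sigma^2) / precb, sqrt(1 / precb))
        ssb <- sum(b^2)
        tau <- .slice1(tau, function(t)
          -G * log(t) - ssb / (2 * t^2) - t^2 / 2)
      }
      if (is.null(sigma_fixed)) {
        sse <- sum((y - mu - (if (G) b[gidx] else 0))^2)
        sigma <- .slice1(sigma, function(s)
          -n * log(s) - sse / (2 * s^2) - s^2 / 2)
      }
      if (it > burnin) {
        mu_d[it - burnin] <- mu
        sig_d[it - burnin] <- sigma
        if (G) tau_d[it - burnin] <- tau
      }
    }
    .choice_posterior(mu_d, sig_d, tau_d, prior_mean, prior_sd, n)
  })
}

.choice_posterior <- function(mu, sigma, tau, prior_mean, prior_sd, n_obs) {
  structure(list(draws = mu, sigma_draws = sigma, group_effect_sd = tau,
                 summary = c(mean = mean(mu),
                             lower95 = unname(quantile(mu, 0.025)),
                             upper95 = unname(quantile(mu, 0.975))),
                 prior_mean = prior_mean, prior_sd = prior_sd, n_obs = n_obs),
            class = "choice_posterior")
}

#' @export
print.choice_posterior <- function(x, ...) {
  cat("Choice-probability posterior (", length(x$draws), " draws, ",
      x$n_obs, " clusters)\n", sep = "")
  cat(sprintf("  mean %.3f, 95%% CI [%.3f, %.3f]; prior N(%.2f, %.2f^2)\n",
              x$summary["mean"], x$summary["lower95"], x$summary["upper95"],
              x$prior_mean, x$prior_sd))
  invisible(x)
}
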