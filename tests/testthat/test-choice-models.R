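mk_nights <- function(ct, cc, n_females = 10) {
  k <- length(ct)
  data.frame(experiment_id = "e", arena_id = paste0("a", rep_len(1:2, k)),
             repetition_id = paste0("r", seq_len(k)), night_index = 1L,
             session_id = "s1", n_females = n_females,
             clusters_treatment = ct, clusters_control = cc,
             stringsAsFactors = FALSE)
}

test_that("perfectly balanced counts give a treatment estimate of zero", {
  n <- mk_nights(c(2, 3, 1, 4, 2, 5), c(2, 3, 1, 4, 2, 5))
  fit <- suppressWarnings(suppressMessages(fit_poisson_glmm(n)))
  expect_lt(abs(fit$beta[["treatment"]]), 1e-4)
  glm_fit <- suppressMessages(fit_poisson_glmm(n, glmm_spec(character(0))))
  expect_lt(abs(glm_fit$beta[["treatment"]]), 1e-8)
})

test_that("with no random effects the fit equals the closed-form two-group Poisson MLE", {
  n <- mk_nights(c(1, 1, 1, 1), c(1, 0, 0, 0))
  fit <- suppressMessages(
    fit_poisson_glmm(n, glmm_spec(character(0), include_females = FALSE)))
  expect_equal(fit$beta[["treatment"]], log(4 / 1), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_length(fit$sigma_u, 0)
})

test_that("zero-random-effect path matches a hand-coded Poisson IRLS with covariates", {
  set.seed(31)
  n <- mk_nights(rpois(12, 2), rpois(12, 1), n_females = sample(8:14, 12, TRUE))
  fit <- suppressMessages(fit_poisson_glmm(n, glmm_spec(character(0))))
  # same model, independent optimizer (covariate centred as in the fit)
  long_trt <- rep(c(1, 0), each = 12)
  y <- c(n$clusters_treatment, n$clusters_control)
  nf <- rep(n$n_females, 2); nf <- nf - mean(nf)
  X <- cbind(1, long_trt, nf)
  beta_o <- oracle_poisson_irls(X, y)
  expect_equal(unname(fit$beta), unname(beta_o), tolerance = 1e-6)
})

test_that("treatment estimate is antisymmetric under label swap", {
  set.seed(5)
  n <- mk_nights(rpois(20, 2) + 1, rpois(20, 1))
  swapped <- n
  swapped$clusters_treatment <- n$clusters_control
  swapped$clusters_control <- n$clusters_treatment
  f1 <- suppressMessages(fit_poisson_glmm(n, glmm_spec(character(0))))
  f2 <- suppressMessages(fit_poisson_glmm(swapped, glmm_spec(character(0))))
  expect_equal(f1$beta[["treatment"]], -f2$beta[["treatment"]], tolerance = 1e-8)
  g1 <- suppressWarnings(suppressMessages(fit_poisson_glmm(n)))
  g2 <- suppressWarnings(suppressMessages(fit_poisson_glmm(swapped)))
  expect_equal(g1$beta[["treatment"]], -g2$beta[["treatment"]], tolerance = 1e-4)
})

test_that("zero-laying nights are excluded exactly once with a message; single-level groupings drop with a warning", {
  n <- mk_nights(c(2, 0, 1), c(1, 0, 2))
  expect_message(
    fit <- suppressWarnings(fit_poisson_glmm(n, glmm_spec("session_id"))),
    "excluding 1 arena-night")
  expect_equal(fit$n_obs, 4)  # 2 remaining nights x 2 sides
  expect_warning(
    suppressMessages(fit_poisson_glmm(n, glmm_spec("session_id"))),
    "single-level")
})

test_that("the fit recovers the generative treatment effect at study scale", {
  n <- simulate_two_choice(two_choice_config(n_repetitions = 60, seed = 17))
  fit <- suppressWarnings(suppressMessages(fit_poisson_glmm(n)))
  expect_true(abs(fit$beta[["treatment"]] - 1.0) < 2 * fit$se[["treatment"]])
  expect_lt(fit$p[["treatment"]], 0.05)
})

test_that("posterior equals the prior on an empty choice set", {
  p <- bayes_choice_posterior(data.frame(choice01 = numeric(0)),
                              n_draws = 8000, seed = 1)
  expect_equal(mean(p$draws), 0.5, tolerance = 0.01)
  expect_equal(sd(p$draws), 0.1, tolerance = 0.03)
  expect_length(p$draws, 8000)
})

test_that("posterior draws are reproducible and the CI lies inside the draw range", {
  ch <- data.frame(choice01 = rep(c(1, 0), c(30, 15)),
                   n_females = rep(c(10, 11, 12), 15))
  p1 <- bayes_choice_posterior(ch, n_draws = 2000, seed = 4)
  p2 <- bayes_choice_posterior(ch, n_draws = 2000, seed = 4)
  expect_identical(p1$draws, p2$draws)
  expect_gte(p1$summary[["lower95"]], min(p1$draws))
  expect_lte(p1$summary[["upper95"]], max(p1$draws))
})

test_that("fixed-sigma no-random-effect posterior matches the conjugate closed form", {
  ch <- data.frame(choice01 = rep(c(1, 0), c(14, 6)))
  p <- bayes_choice_posterior(ch, n_draws = 16000, seed = 2, group = NULL,
                              sigma_fixed = 0.5)
  o <- oracle_conjugate_posterior(ch$choice01, 0.5, 0.1, 0.5)
  mc <- o$sd / sqrt(16000)
  expect_equal(mean(p$draws), o$mean, tolerance = 4 * mc)
  expect_equal(sd(p$draws), o$sd, tolerance = 0.02)
})

test_that("posterior mean shrinks strictly between prior mean and sample mean", {
  for (s in 1:5) {
    y <- rbinom(25, 1, 0.8)
    ch <- data.frame(choice01 = y)
    p <- bayes_choice_posterior(ch, n_draws = 4000, seed = s, group = NULL,
                                sigma_fixed = 0.5)
    lo <- min(0.5, mean(y)); hi <- max(0.5, mean(y))
    expect_gt(mean(p$draws), lo)
    expect_lt(mean(p$draws), hi)
  }
})

test_that("balanced choices in large n give a symmetric posterior at 0.5", {
  # groups balanced within each female-count level
  ch <- data.frame(choice01 = rep(c(1, 0), 300),
                   n_females = rep(c(9, 9, 10, 10, 11, 11), 100))
  p <- bayes_choice_posterior(ch, n_draws = 8000, seed = 3)
  expect_equal(mean(p$draws), 0.5, tolerance = 0.03)
  expect_lt(abs(mean(p$draws) - median(p$draws)), 0.01)
})

test_that("Pearson chi-square reproduces the deafening Q and the direct formula", {
  deaf <- matrix(c(5, 20, 0, 20), 2, byrow = TRUE)
  res <- pearson_chi2(deaf)
  expect_equal(res$q, 4.5, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$p, 1 - pchisq(4.5, 1))
  expect_equal(pearson_chi2(matrix(c(10, 10, 10, 10), 2))$q, 0)
  t2 <- matrix(c(3, 7, 6, 4), 2, byrow = TRUE)
  expect_equal(pearson_chi2(t2)$q, oracle_chi2_q(t2), tolerance = 1e-12)
})

test_that("chi-square is invariant to transposing and to swapping both labels", {
  tab <- matrix(c(3, 7, 6, 4), 2, byrow = TRUE)
  q <- pearson_chi2(tab)$q
  expect_equal(pearson_chi2(t(tab))$q, q)
  expect_equal(pearson_chi2(tab[2:1, 2:1])$q, q)
})

test_that("chi-square rejects invalid tables", {
  expect_error(pearson_chi2(matrix(c(5, 0, 3, 0), 2)), "margin")
  expect_error(pearson_chi2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
  expect_error(pearson_chi2(matrix(c(-1, 2, 3, 4), 2)), "integer|nonnegative")
})

test_that("chi-square type-I error of the simulate-then-test loop is near nominal", {
  # equal response probabilities; moderate p so expected counts are healthy
  pv <- vapply(1:600, function(s) {
    tab <- simulate_deafening(60, 60, 0.5, 0.5, seed = s)
    if (any(colSums(tab) == 0)) return(1)
    pearson_chi2(tab)$p
  }, numeric(1))
  rate <- mean(pv < 0.05)
  expect_gt(rate, 0.05 - 2.5 * sqrt(0.05 * 0.95 / 600))
  expect_lt(rate, 0.05 + 2.5 * sqrt(0.05 * 0.95 / 600))
})

test_that("laying comparison returns the group proportions and an enumeration-exact p", {
  a <- rep(c(TRUE, FALSE), c(68, 32))
  b <- rep(c(TRUE, FALSE), c(54, 46))
  res <- laying_probability_comparison(a, b)
  expect_equal(res$prop_a, 0.68)
  expect_equal(res$prop_b, 0.54)
  expect_lt(res$p, 0.06)

  same <- laying_probability_comparison(a, a)
  expect_equal(same$prop_a, same$prop_b)
  expect_equal(same$p, 1)

  ta <- rep(c(TRUE, FALSE), c(8, 2)); tb <- rep(c(TRUE, FALSE), c(3, 7))
  res2 <- laying_probability_comparison(ta, tb)
  expect_equal(res2$p,
               oracle_fisher_p(rbind(c(8, 2), c(3, 7))), tolerance = 1e-10)
  expect_error(laying_probability_comparison(logical(0), a), "non-empty")
})
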