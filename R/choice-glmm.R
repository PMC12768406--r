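#' Specification of the Poisson cluster-count mixed model
#'
#' The response is the number of egg clusters per arena side-night; the
#' treatment indicator (playback or tested side = 1) and optionally the
#' number of females in the arena are fixed effects; arena, repetition and
#' night-within-repetition (and session, when several sessions are present)
#' contribute independent normal random intercepts.  Family is Poisson with
#' log link, so the treatment coefficient is a log rate ratio.
#'
#' @param random_intercepts character vector of grouping columns; the night
#'   grouping is coded nested within repetition.  Use \code{character(0)}
#'   for a pure fixed-effects Poisson GLM.
#' @param include_females logical; add \code{n_females} as a fixed covariate.
#' @return a list of class \code{glmm_spec}.
#' @export
glmm_spec <- function(random_intercepts = c("arena_id", "repetition_id",
                                            "night_id"),
                      include_females = TRUE) {
  stopifnot(is.character(random_intercepts), is.logical(include_females))
  structure(list(random_intercepts = random_intercepts,
                 include_females = include_females),
            class = "glmm_spec")
}

# One row per side per night, treatment indicator 0/1, nested night coding,
# zero-laying nights excluded (exactly once, with a message of the count).
.nights_to_long <- function(nights) {
  need <- c("clusters_treatment", "clusters_control")
  if (!all(need %in% names(nights)))
    stop("night records need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  zero <- nights$clusters_treatment == 0 & nights$clusters_control == 0
  if (any(zero))
    message("excluding ", sum(zero), " arena-night(s) with zero clusters on both sides")
  nights <- nights[!zero, , drop = FALSE]
  if (!nrow(nights)) stop("no arena-nights with egg-laying remain", call. = FALSE)
  n <- nrow(nights)
  long <- rbind(nights, nights)
  long$clusters <- c(nights$clusters_treatment, nights$clusters_control)
  long$treatment <- rep(c(1L, 0L), each = n)
  if (all(c("repetition_id", "night_index") %in% names(long)))
    long$night_id <- interaction(long$repetition_id, long$night_index, drop = TRUE)
  long
}

#' Fit the Poisson mixed model of cluster counts
#'
#' Fits clusters ~ treatment (+ n_females) with independent normal random
#' intercepts by Laplace-approximate maximum likelihood (via
#' \code{lme4::glmer}); with no random intercepts the model reduces to a
#' Poisson GLM.  Groupings with a single level are dropped with a warning.
#' Zero-laying arena-nights are excluded before reshaping, mirroring the
#' exclusion applied to the observed data.
#'
#' @param nights data frame of night records (wide, one row per arena-night)
#'   as produced by \code{\link{simulate_two_choice}} or
#'   \code{\link{read_nights}}.
#' @param spec a \code{\link{glmm_spec}}.
#' @return object of class \code{glmm_fit}: fixed-effect estimates
#'   (\code{beta}), standard errors, Wald p-values, random-intercept SDs
#'   (\code{sigma_u}), log-likelihood, convergence flag and the underlying
#'   fit.
#' @examples
#' nights <- simulate_two_choice(two_choice_config(seed = 1))
#' fit <- fit_poisson_glmm(nights, glmm_spec())
#' fit$beta["treatment"]
#' @export
fit_poisson_glmm <- function(nights, spec = glmm_spec()) {
  stopifnot(inherits(spec, "glmm_spec"))
  long <- .nights_to_long(nights)
  fixed <- "treatment"
  if (spec$include_females && "n_females" %in% names(long) &&
      length(unique(long$n_females)) > 1L) {
    # centred for conditioning; leaves the treatment coefficient untouched
    long$n_females <- long$n_females - mean(long$n_females)
    fixed <- c(fixed, "n_females")
  }
  groups <- spec$random_intercepts
  groups <- groups[groups %in% names(long)]
  keep <- vapply(groups, function(g) length(unique(long[[g]])) > 1L, logical(1))
  if (any(!keep))
    warning("dropping single-level grouping(s): ",
            paste(groups[!keep], collapse = ", "), call. = FALSE)
  groups <- groups[keep]

  if (length(groups)) {
    form <- as.formula(paste("clusters ~", paste(fixed, collapse = " + "), "+",
                             paste(sprintf("(1 | %s)", groups), collapse = " + ")))
    fit <- suppressMessages(lme4::glmer(form, data = long, family = poisson))
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    vc <- lme4::VarCorr(fit)
    sigma_u <- vapply(groups, function(g) sqrt(vc[[g]][1, 1]), numeric(1))
    msgs <- unlist(fit@optinfo$conv$lme4)
    # a boundary (singular) fit is converged, at sigma_u = 0
    conv <- fit@optinfo$conv$opt == 0 &&
      !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  } else {
    form <- as.formula(paste("clusters ~", paste(fixed, collapse = " + ")))
    fit <- glm(form, data = long, family = poisson())
    beta <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    sigma_u <- setNames(numeric(0), character(0))
    conv <- fit$converged
  }
  p <- 2 * pnorm(-abs(beta / se))
  structure(list(beta = beta, se = se, p = p, sigma_u = sigma_u,
                 loglik = as.numeric(logLik(fit)), converged = conv,
                 n_obs = nrow(long), fixed = fixed, groups = groups,
                 model = fit),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Poisson cluster-count mixed model (", x$n_obs, " side-nights)\n", sep = "")
  est <- data.frame(estimate = x$beta, se = x$se, p = x$p)
  print(round(est, 4))
  if (length(x$sigma_u)) {
    cat("random-intercept SDs:\n")
    print(round(x$sigma_u, 4))
  }
  if (!x$converged) cat("WARNING: fit did not converge cleanly\n")
  invisible(x)
}
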