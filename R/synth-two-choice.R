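#' Configuration for the two-choice arena-night simulator
#'
#' Defaults mirror the combined playback-vs-silence condition of the study
#' design this package supports: a control-side baseline of 0.40 clusters per
#' night, a treatment log rate ratio of 1.0 (so the playback side averages
#' about 1.08 clusters per night), 15 repetitions of 3 nights each (45
#' arena-nights), up to 4 arenas running simultaneously, and 10.9 fertile
#' females per arena on average.
#'
#' @param n_repetitions number of repetitions (new sets of moths).
#' @param nights_per_repetition consecutive nights each repetition is observed.
#' @param n_arenas number of arenas run simultaneously (at most 4).
#' @param females_per_arena mean number of fertile females per arena.
#' @param beta0 log baseline cluster rate per side-night (control side).
#' @param beta1 treatment log rate ratio; exp(beta1) is the playback-side
#'   fold change in expected clusters.
#' @param sigma_arena,sigma_rep,sigma_night SDs of the normal random
#'   intercepts for arena, repetition and night-within-repetition.
#' @param n_sessions number of experimental sessions the repetitions are
#'   split into (sessions are months-apart replicates of the same treatment).
#' @param experiment_id label stored on every record.
#' @param seed integer seed; identical seed and config give bit-identical
#'   output.
#' @return a list of class \code{two_choice_config}.
#' @export
two_choice_config <- function(n_repetitions = 15,
                              nights_per_repetition = 3,
                              n_arenas = 4,
                              females_per_arena = 10.9,
                              beta0 = log(0.40),
                              beta1 = 1.0,
                              sigma_arena = 0.3,
                              sigma_rep = 0.2,
                              sigma_night = 0.2,
                              n_sessions = 1,
                              experiment_id = "sim",
                              seed = NULL) {
  cfg <- list(n_repetitions = n_repetitions,
              nights_per_repetition = nights_per_repetition,
              n_arenas = n_arenas,
              females_per_arena = females_per_arena,
              beta0 = beta0, beta1 = beta1,
              sigma_arena = sigma_arena, sigma_rep = sigma_rep,
              sigma_night = sigma_night,
              n_sessions = n_sessions,
              experiment_id = experiment_id,
              seed = seed)
  for (p in c("beta0", "beta1")) {
    if (!is.numeric(cfg[[p]]) || length(cfg[[p]]) != 1L || !is.finite(cfg[[p]]))
      stop("parameter '", p, "' must be a finite numeric scalar", call. = FALSE)
  }
  for (p in c("sigma_arena", "sigma_rep", "sigma_night")) {
    if (!is.finite(cfg[[p]]) || cfg[[p]] < 0)
      stop("parameter '", p, "' must be finite and >= 0", call. = FALSE)
  }
  for (p in c("n_repetitions", "nights_per_repetition", "n_arenas", "n_sessions")) {
    if (!is.finite(cfg[[p]]) || cfg[[p]] < 1 || cfg[[p]] != round(cfg[[p]]))
      stop("parameter '", p, "' must be a positive integer", call. = FALSE)
  }
  if (cfg$n_arenas > 4) stop("n_arenas must be at most 4", call. = FALSE)
  if (!is.finite(cfg$females_per_arena) || cfg$females_per_arena <= 0)
    stop("parameter 'females_per_arena' must be > 0", call. = FALSE)
  class(cfg) <- "two_choice_config"
  cfg
}

#' Simulate two-choice arena-night cluster counts
#'
#' Generative mirror of the Poisson mixed model used for inference: with
#' nested normal random intercepts u_arena, u_rep and u_night, the control
#' side of an arena-night draws Poisson(exp(beta0 + u)) clusters and the
#' treatment side Poisson(exp(beta0 + beta1 + u)) clusters, sharing the same
#' intercepts.  Nights on which neither side receives a cluster are kept and
#' flagged (\code{zero_laying}); excluding them is the analysis stage's job.
#'
#' @param config a \code{\link{two_choice_config}}.
#' @return data frame with one row per arena-night: \code{experiment_id},
#'   \code{arena_id}, \code{repetition_id}, \code{night_index},
#'   \code{session_id}, \code{n_females}, \code{clusters_treatment},
#'   \code{clusters_control}, \code{zero_laying}.
#' @examples
#' nights <- simulate_two_choice(two_choice_config(seed = 1))
#' colMeans(nights[!nights$zero_laying, c("clusters_treatment", "clusters_control")])
#' @export
simulate_two_choice <- function(config) {
  stopifnot(inherits(config, "two_choice_config"))
  with_seed(config$seed, {
    nrep <- config$n_repetitions
    nn <- config$nights_per_repetition
    arena_of_rep <- rep_len(seq_len(config$n_arenas), nrep)
    session_of_rep <- rep_len(seq_len(config$n_sessions), nrep)
    u_arena <- rnorm(config$n_arenas, 0, config$sigma_arena)
    u_rep <- rnorm(nrep, 0, config$sigma_rep)
    rows <- vector("list", nrep * nn)
    k <- 0L
    for (r in seq_len(nrep)) {
      # females are counted once per repetition; the observed spread of the
      # per-arena female count is small, so a tight jitter around the mean
      nf <- max(1L, as.integer(round(config$females_per_arena + rnorm(1, 0, 0.5))))
      for (night in seq_len(nn)) {
        u_n <- rnorm(1, 0, config$sigma_night)
        eta <- config$beta0 + u_arena[arena_of_rep[r]] + u_rep[r] + u_n
        lam_c <- exp(eta)
        lam_t <- exp(eta + config$beta1)
        if (!is.finite(lam_c) || !is.finite(lam_t))
          stop("non-finite Poisson rate from beta0/beta1/random intercepts (eta = ",
               format(eta), ")", call. = FALSE)
        ct <- rpois(1, lam_t)
        cc <- rpois(1, lam_c)
        k <- k + 1L
        rows[[k]] <- data.frame(
          experiment_id = config$experiment_id,
          arena_id = paste0("arena", arena_of_rep[r]),
          repetition_id = paste0("rep", r),
          night_index = night,
          session_id = paste0("s", session_of_rep[r]),
          n_females = nf,
          clusters_treatment = ct,
          clusters_control = cc,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out$zero_laying <- out$clusters_treatment == 0L & out$clusters_control == 0L
    out
  })
}

#' Expand night records into per-cluster choice codes
#'
#' Each laid cluster is one oviposition decision: clusters on the treatment
#' (tested) side are coded 1 and clusters on the control side 0, carrying the
#' night's covariates.  This is the input format of
#' \code{\link{bayes_choice_posterior}}.
#'
#' @param nights data frame of night records (see
#'   \code{\link{simulate_two_choice}}).
#' @return data frame with columns \code{cluster_id}, \code{experiment_id},
#'   \code{n_females}, \code{choice01}.
#' @export
nights_to_choices <- function(nights) {
  stopifnot(is.data.frame(nights),
            all(c("clusters_treatment", "clusters_control") %in% names(nights)))
  ch <- rep.int(rep(c(1L, 0L), nrow(nights)),
                as.vector(rbind(nights$clusters_treatment, nights$clusters_control)))
  idx <- rep.int(rep(seq_len(nrow(nights)), each = 2),
                 as.vector(rbind(nights$clusters_treatment, nights$clusters_control)))
  data.frame(cluster_id = paste0("c", seq_along(ch)),
             experiment_id = if ("experiment_id" %in% names(nights))
               nights$experiment_id[idx] else "sim",
             n_females = if ("n_females" %in% names(nights))
               nights$n_females[idx] else NA_integer_,
             choice01 = ch,
             stringsAsFactors = FALSE)
}
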