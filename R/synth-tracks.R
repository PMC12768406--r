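#' Configuration for the trajectory simulator
#'
#' Moth positions are sampled every 12 s over a 6 h night.  Side occupancy
#' follows a two-state Markov chain whose stationary log-odds of the playback
#' side grow linearly with time at \code{bias_slope}; the per-step switching
#' propensity varies between moths on a lognormal scale (\code{switch_sd}),
#' reflecting that some moths cross many times while others never leave a
#' side.  The defaults put the per-night crossing count at mean 4.2 with SD
#' near 5.7.
#'
#' @param n_moths number of moths (grouped 4 per trial).
#' @param duration observation length in seconds.
#' @param dt sampling interval in seconds.
#' @param switch_prob0 population-mean per-step side-switch probability at
#'   even occupancy; must lie in (0, 1).
#' @param bias_slope per-second increase in the stationary log-odds of being
#'   on the playback side.
#' @param switch_sd lognormal SD (log scale) of the per-moth switching
#'   propensity; 0 makes all moths identical.
#' @param arena_halfwidth half-length of the choice axis in cm (box arena
#'   100 cm long, midline at 0).
#' @param arena_depth extent of the transverse y axis in cm.
#' @param seed integer seed.
#' @return a list of class \code{trajectory_config}.
#' @export
trajectory_config <- function(n_moths = 13,
                              duration = 6 * 3600,
                              dt = 12,
                              switch_prob0 = 0.00256,
                              bias_slope = 5e-5,
                              switch_sd = 1.0,
                              arena_halfwidth = 50,
                              arena_depth = 50,
                              seed = NULL) {
  cfg <- list(n_moths = n_moths, duration = duration, dt = dt,
              switch_prob0 = switch_prob0, bias_slope = bias_slope,
              switch_sd = switch_sd, arena_halfwidth = arena_halfwidth,
              arena_depth = arena_depth, seed = seed)
  if (!is.finite(cfg$dt) || cfg$dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (cfg$duration < cfg$dt) stop("duration must be >= dt", call. = FALSE)
  if (!is.finite(cfg$switch_prob0) || cfg$switch_prob0 <= 0 || cfg$switch_prob0 >= 1)
    stop("switch_prob0 must lie in (0, 1)", call. = FALSE)
  if (cfg$switch_sd < 0) stop("switch_sd must be >= 0", call. = FALSE)
  if (cfg$n_moths < 1) stop("n_moths must be >= 1", call. = FALSE)
  class(cfg) <- "trajectory_config"
  cfg
}

#' Simulate side-switching moth trajectories
#'
#' A two-state Markov chain per moth: at step time t the stationary playback
#' occupancy is p(t) = plogis(bias_slope * t), and transition probabilities
#' towards/away from the playback side are 2 * s_i * p(t) and
#' 2 * s_i * (1 - p(t)) with per-moth propensity s_i, so the chain tracks
#' the drifting stationary law while switching at rate 2 * s_i on average.
#' The x coordinate is uniform within the occupied side; the playback side
#' alternates between trials.
#'
#' @param config a \code{\link{trajectory_config}}.
#' @return data frame with columns \code{moth_id}, \code{trial_id},
#'   \code{playback_side} ("left"/"right"), \code{t_s}, \code{x_cm},
#'   \code{y_cm}; time stamps per moth form an arithmetic sequence with
#'   step \code{dt}.
#' @examples
#' tr <- simulate_tracks(trajectory_config(n_moths = 2, duration = 600, seed = 1))
#' head(tr)
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "trajectory_config"))
  with_seed(config$seed, {
    nstep <- floor(config$duration / config$dt)
    tt <- (seq_len(nstep) - 1L) * config$dt
    p_t <- plogis(config$bias_slope * tt)
    rows <- vector("list", config$n_moths)
    for (i in seq_len(config$n_moths)) {
      trial <- (i - 1L) %/% 4L + 1L
      pb_side <- if (trial %% 2L == 1L) "left" else "right"
      # mean-preserving lognormal propensity: E[s_i] = switch_prob0
      s_i <- config$switch_prob0 *
        exp(rnorm(1, -config$switch_sd^2 / 2, config$switch_sd))
      on_pb <- integer(nstep)
      on_pb[1] <- rbinom(1, 1, p_t[1])
      if (nstep > 1) for (k in 2:nstep) {
        if (on_pb[k - 1] == 1L) {
          q <- min(1, 2 * s_i * (1 - p_t[k]))
          on_pb[k] <- if (runif(1) < q) 0L else 1L
        } else {
          q <- min(1, 2 * s_i * p_t[k])
          on_pb[k] <- if (runif(1) < q) 1L else 0L
        }
      }
      # map occupancy to a signed x: playback side left => x < 0
      side_sign <- ifelse(on_pb == 1L, if (pb_side == "left") -1 else 1,
                          if (pb_side == "left") 1 else -1)
      x <- side_sign * runif(nstep, 0, config$arena_halfwidth)
      y <- runif(nstep, 0, config$arena_depth)
      rows[[i]] <- data.frame(moth_id = paste0("m", i),
                              trial_id = paste0("trial", trial),
                              playback_side = pb_side,
                              t_s = tt, x_cm = x, y_cm = y,
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate the deafening-validation response table
#'
#' Bernoulli startle responses per moth in an intact control group and a
#' deafened group, tabulated as a 2x2 responder table for
#' \code{\link{pearson_chi2}}.
#'
#' @param n_control,n_deaf group sizes.
#' @param p_control,p_deaf response probabilities in [0, 1].
#' @param seed integer seed.
#' @return 2x2 integer matrix, rows control/deafened, columns
#'   responder/non_responder.
#' @examples
#' simulate_deafening(25, 20, p_control = 0.2, p_deaf = 0, seed = 1)
#' @export
simulate_deafening <- function(n_control, n_deaf, p_control, p_deaf,
                               seed = NULL) {
  stopifnot(n_control >= 1, n_deaf >= 1,
            p_control >= 0, p_control <= 1, p_deaf >= 0, p_deaf <= 1)
  with_seed(seed, {
    rc <- as.integer(rbinom(1, n_control, p_control))
    rd <- as.integer(rbinom(1, n_deaf, p_deaf))
    matrix(c(rc, as.integer(n_control) - rc, rd, as.integer(n_deaf) - rd),
           nrow = 2, byrow = TRUE,
           dimnames = list(group = c("control", "deafened"),
                           response = c("responder", "non_responder")))
  })
}
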