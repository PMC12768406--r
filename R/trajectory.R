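#' Assign arena sides and occupancy bins to one moth's track
#'
#' Each 12-s sample is labelled by the sign of (x - midline) mapped onto the
#' playback side (1 = on the playback side).  Samples exactly on the midline
#' inherit the previous label; leading midline samples are neutral (NA) and
#' excluded from bins.  Occupancy is summarised in fixed-duration bins
#' (default 30 min); a partial final bin keeps its true sample count.
#'
#' @param track data frame for a single moth with columns \code{t_s},
#'   \code{x_cm}, \code{playback_side} ("left"/"right") and optionally
#'   \code{moth_id}, \code{trial_id}.
#' @param midline x position of the arena midline, cm.
#' @param bin_minutes occupancy bin width in minutes.
#' @return object of class \code{occupancy_series}: per-sample times and
#'   playback indicator, plus a bin table (\code{bin_index},
#'   \code{bin_start_s}, \code{prop_playback}, \code{n_samples}).
#' @examples
#' tr <- simulate_tracks(trajectory_config(n_moths = 1, duration = 3600, seed = 1))
#' s <- assign_sides(tr)
#' s$bins
#' @export
assign_sides <- function(track, midline = 0, bin_minutes = 30) {
  stopifnot(is.data.frame(track))
  if (!nrow(track)) stop("empty track", call. = FALSE)
  need <- c("t_s", "x_cm", "playback_side")
  if (!all(need %in% names(track)))
    stop("track needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if ("moth_id" %in% names(track) && length(unique(track$moth_id)) > 1L)
    stop("assign_sides() takes one moth's track; split by moth_id first",
         call. = FALSE)
  track <- track[order(track$t_s), , drop = FALSE]
  dt <- diff(track$t_s)
  if (length(dt) && (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9))
    stop("time stamps must be strictly increasing with constant spacing",
         call. = FALSE)
  pb <- match.arg(track$playback_side[1], c("left", "right"))
  pb_sign <- if (pb == "left") -1 else 1

  side_sign <- sign(track$x_cm - midline)
  # midline samples inherit the previous label; leading ones stay neutral
  for (i in seq_along(side_sign)) {
    if (side_sign[i] == 0) side_sign[i] <- if (i > 1) side_sign[i - 1] else NA_real_
  }
  on_playback <- ifelse(is.na(side_sign), NA_integer_,
                        as.integer(side_sign == pb_sign))

  ok <- !is.na(on_playback)
  bin_w <- bin_minutes * 60
  bin_index <- floor((track$t_s - track$t_s[1]) / bin_w) + 1L
  bins <- do.call(rbind, lapply(sort(unique(bin_index)), function(bi) {
    sel <- ok & bin_index == bi
    data.frame(bin_index = bi,
               bin_start_s = track$t_s[1] + (bi - 1L) * bin_w,
               prop_playback = if (any(sel)) mean(on_playback[sel]) else NA_real_,
               n_samples = sum(sel))
  }))
  structure(list(moth_id = if ("moth_id" %in% names(track)) track$moth_id[1] else "m1",
                 trial_id = if ("trial_id" %in% names(track)) track$trial_id[1] else "trial1",
                 playback_side = pb, midline = midline,
                 bin_minutes = bin_minutes,
                 t_s = track$t_s, on_playback = on_playback, bins = bins),
            class = "occupancy_series")
}

#' Count side crossings in an occupancy series
#'
#' Number of adjacent label changes in the per-sample side sequence,
#' ignoring neutral (midline) samples.
#'
#' @param series an \code{occupancy_series}.
#' @return integer crossing count.
#' @export
count_crossings <- function(series) {
  stopifnot(inherits(series, "occupancy_series"))
  v <- series$on_playback[!is.na(series$on_playback)]
  if (length(v) < 2) return(0L)
  sum(diff(v) != 0L)
}

#' Logistic mixed-model trend of playback-side occupancy over time
#'
#' Fits the per-sample binary playback-side indicator on elapsed time
#' (hours) with random intercepts for trial and moth, by Laplace-approximate
#' maximum likelihood (\code{lme4::glmer}, binomial).  The per-sample binary
#' response is the well-defined logistic analogue of modelling accumulated
#' time on the playback side, which is also reported as a secondary linear
#' trend on the per-bin occupancy proportions.
#'
#' @param series_list list of \code{occupancy_series} (at least 2 moths and
#'   2 time bins).
#' @param bin_minutes bin width for the secondary per-bin linear trend.
#' @return object of class \code{trend_fit}: \code{slope} (log-odds per
#'   hour), \code{se}, \code{p}, random-effect SDs, convergence flag, the
#'   pooled bin table, and \code{bin_linear} (slope, se, p of the linear
#'   per-bin proportion trend, proportion per hour).
#' @export
fit_occupancy_trend <- function(series_list, bin_minutes = 30) {
  stopifnot(is.list(series_list), length(series_list) >= 2,
            all(vapply(series_list, inherits, logical(1), "occupancy_series")))
  dat <- do.call(rbind, lapply(series_list, function(s) {
    ok <- !is.na(s$on_playback)
    data.frame(moth_id = s$moth_id, trial_id = s$trial_id,
               t_h = (s$t_s[ok] - s$t_s[1]) / 3600,
               on = s$on_playback[ok], stringsAsFactors = FALSE)
  }))
  if (max(dat$t_h) * 60 < bin_minutes)  # second bin never reached
    stop("at least two occupancy bins are required", call. = FALSE)
  re <- c("trial_id", "moth_id")
  re <- re[vapply(re, function(g) length(unique(dat[[g]])) > 1L, logical(1))]
  form <- as.formula(paste("on ~ t_h",
                           if (length(re)) paste("+", paste(sprintf("(1 | %s)", re),
                                                            collapse = " + ")) else ""))
  separation <- with(dat, all(on == 1) || all(on == 0))
  if (length(re)) {
    fit <- suppressMessages(lme4::glmer(form, data = dat, family = binomial))
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    vc <- lme4::VarCorr(fit)
    sig <- vapply(re, function(g) sqrt(vc[[g]][1, 1]), numeric(1))
    msgs <- unlist(fit@optinfo$conv$lme4)
    conv <- fit@optinfo$conv$opt == 0 &&
      !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  } else {
    fit <- glm(form, data = dat, family = binomial())
    beta <- coef(fit); se <- sqrt(diag(vcov(fit)))
    sig <- setNames(numeric(0), character(0)); conv <- fit$converged
  }
  slope <- unname(beta["t_h"]); slope_se <- unname(se["t_h"])
  p <- 2 * pnorm(-abs(slope / slope_se))

  # secondary: linear trend of per-bin proportions (accumulated-time view)
  bins <- do.call(rbind, lapply(series_list, function(s) {
    b <- s$bins; b$moth_id <- s$moth_id; b
  }))
  bu <- bins[!is.na(bins$prop_playback) & bins$n_samples > 0, , drop = FALSE]
  lin <- stats::lm(prop_playback ~ I(bin_start_s / 3600), data = bu,
                   weights = bu$n_samples)
  lco <- summary(lin)$coefficients
  structure(list(slope = slope, se = slope_se, p = p, sigma_u = sig,
                 converged = conv && !separation, separation = separation,
                 n_samples = nrow(dat), bins = bins,
                 bin_linear = list(slope = lco[2, 1], se = lco[2, 2],
                                   p = lco[2, 4]),
                 model = fit),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Occupancy trend: slope %.4g log-odds/h (se %.3g, p = %.3g) on %d samples\n",
              x$slope, x$se, x$p, x$n_samples))
  if (x$separation) cat("NOTE: complete separation; estimates unreliable\n")
  invisible(x)
}
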