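#' Default end-to-end pipeline configuration
#'
#' All four stages run on synthetic data generated under child seeds derived
#' from one master seed (see \code{\link{derive_stream_seed}}).  Any stage
#' can instead point at a CSV file (\code{list(file = path)}); a stage entry
#' must name exactly one input source.
#'
#' @param seed master seed.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(seed = seed,
       schema_version = "1",
       two_choice = list(sim = list()),
       gradient = list(sim = list()),
       tracks = list(sim = list()),
       deafening = list(sim = list(n_control = 25, n_deaf = 20,
                                   p_control = 0.2, p_deaf = 0)))
}

.stage_input <- function(entry, stage) {
  has <- c(sim = !is.null(entry$sim), file = !is.null(entry$file))
  if (sum(has) != 1L)
    stop("stage '", stage, "' must name exactly one input source (sim or file)",
         call. = FALSE)
  names(has)[has]
}

#' Run the full analysis pipeline
#'
#' Executes, per enabled stage: simulation (or CSV input), the zero-laying
#' exclusion, the Poisson cluster-count mixed model and the Bayesian choice
#' posterior; the gradient permutation K-S test (pooled and replicate-wise);
#' trajectory crossing counts, occupancy bins and the logistic time trend;
#' and the deafening chi-square.  A stage failure is recorded with its
#' message and the remaining stages still run.  The report embeds the
#' configuration, master seed and schema version needed to rerun it, and is
#' fully reproducible from the master seed.
#'
#' @param config configuration list, see
#'   \code{\link{default_pipeline_config}}.  Stages are skipped when their
#'   entry is \code{NULL}.
#' @param out optional directory; when given, the report is written to
#'   \code{report.json} there.
#' @return the report as a nested list (invisibly written to JSON when
#'   \code{out} is set).
#' @examples
#' rep <- run_pipeline(default_pipeline_config(seed = 1))
#' rep$two_choice$glmm$beta[["treatment"]]
#' @export
run_pipeline <- function(config = default_pipeline_config(), out = NULL) {
  stopifnot(is.list(config), !is.null(config$seed))
  seed <- config$seed
  report <- list(schema_version = config$schema_version %||% "1",
                 seed = seed, config = config, errors = list())
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  if (!is.null(config$two_choice)) {
    report$two_choice <- run_stage("two_choice", function() {
      src <- .stage_input(config$two_choice, "two_choice")
      nights <- if (src == "sim") {
        args <- config$two_choice$sim
        args$seed <- args$seed %||% derive_stream_seed(seed, "two_choice")
        simulate_two_choice(do.call(two_choice_config, args))
      } else read_nights(config$two_choice$file)
      n_zero <- sum(nights$zero_laying)
      fit <- suppressWarnings(suppressMessages(fit_poisson_glmm(nights)))
      choices <- nights_to_choices(nights[!nights$zero_laying, , drop = FALSE])
      post <- bayes_choice_posterior(
        choices, seed = derive_stream_seed(seed, "bayes_choice"))
      list(n_nights = nrow(nights), n_excluded_zero_laying = n_zero,
           mean_clusters_treatment = mean(nights$clusters_treatment[!nights$zero_laying]),
           mean_clusters_control = mean(nights$clusters_control[!nights$zero_laying]),
           glmm = list(beta = as.list(fit$beta), se = as.list(fit$se),
                       p = as.list(fit$p), sigma_u = as.list(fit$sigma_u),
                       converged = fit$converged),
           posterior = as.list(post$summary))
    })
  }

  if (!is.null(config$gradient)) {
    report$gradient <- run_stage("gradient", function() {
      src <- .stage_input(config$gradient, "gradient")
      eggs <- if (src == "sim") {
        args <- config$gradient$sim
        args$seed <- args$seed %||% derive_stream_seed(seed, "gradient")
        simulate_gradient(do.call(gradient_config, args))
      } else read_eggs(config$gradient$file)
      pc <- permutation_null_config(
        n_shuffles = config$gradient$n_shuffles %||% 1000,
        seed = derive_stream_seed(seed, "gradient_null"), unit = "egg")
      pooled <- gradient_test(eggs, pc, method = "pooled")
      perm <- gradient_test(eggs, pc, method = "permutation")
      list(n_clusters = nrow(eggs), n_eggs = sum(eggs$n_eggs),
           ks_pooled = list(d = pooled$d, p = pooled$p),
           ks_permutation = list(d = perm$d, p = perm$p))
    })
  }

  if (!is.null(config$tracks)) {
    report$tracks <- run_stage("tracks", function() {
      src <- .stage_input(config$tracks, "tracks")
      tracks <- if (src == "sim") {
        args <- config$tracks$sim
        args$seed <- args$seed %||% derive_stream_seed(seed, "tracks")
        simulate_tracks(do.call(trajectory_config, args))
      } else read_tracks(config$tracks$file)
      series <- lapply(split(tracks, tracks$moth_id), assign_sides)
      cross <- vapply(series, count_crossings, integer(1))
      trend <- suppressWarnings(suppressMessages(fit_occupancy_trend(series)))
      list(n_moths = length(series),
           crossings_mean = mean(cross), crossings_sd = sd(cross),
           trend = list(slope = trend$slope, se = trend$se, p = trend$p,
                        converged = trend$converged))
    })
  }

  if (!is.null(config$deafening)) {
    report$deafening <- run_stage("deafening", function() {
      entry <- config$deafening
      tab <- if (!is.null(entry$table)) {
        matrix(unlist(entry$table), nrow = 2, byrow = TRUE)
      } else {
        args <- entry$sim
        args$seed <- args$seed %||% derive_stream_seed(seed, "deafening")
        do.call(simulate_deafening, args)
      }
      chi <- pearson_chi2(tab)
      list(table = as.list(as.vector(t(tab))), q = chi$q, df = chi$df,
           p = chi$p)
    })
  }

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
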