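#' Configuration for an end-to-end pipeline run
#'
#' @param output_dir directory for all artifacts.
#' @param cohort a [cohort_config()] describing the synthetic cohort to
#'   generate, or `NULL` to read traces from `input_dir`.
#' @param input_dir directory with `traces.csv` (+ optional `covariates.csv`)
#'   when not generating.
#' @param stages character vector of stages to run, in dependency order, from
#'   `c("generate", "extract", "stats", "survival", "distfit", "fit")`.
#' @param seed global seed; per-stage seeds are derived deterministically.
#' @param fit a [fit_config()] for the model-fitting stage.
#' @param resume skip stages whose outputs already exist under the same
#'   config hash.
#' @param log write progress to stderr.
#' @return A list of class `run_config`.
#' @export
run_config <- function(output_dir,
                       cohort = cohort_config(),
                       input_dir = NULL,
                       stages = c("generate", "extract", "stats", "survival",
                                  "distfit"),
                       seed = 1,
                       fit = fit_config(),
                       resume = FALSE,
                       log = TRUE) {
  all_stages <- c("generate", "extract", "stats", "survival", "distfit",
                  "fit")
  stopifnot(all(stages %in% all_stages))
  stages <- all_stages[all_stages %in% stages]  # enforce dependency order
  if (is.null(cohort) && is.null(input_dir))
    stop("either a cohort config or an input directory is required",
         call. = FALSE)
  structure(list(output_dir = output_dir, cohort = cohort,
                 input_dir = input_dir, stages = stages, seed = seed,
                 fit = fit, resume = resume, log = log),
            class = "run_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes the configured stages in order — generate (synthetic cohort),
#' extract (uptake/damage/lifespans from traces), stats (cross-sectional,
#' initial-condition, twilight tables), survival (curves and Gompertz slope),
#' distfit (per-age marginal fits and the GB2 age trend), fit (MP-SR maximum
#' likelihood) — writing CSV/JSON artifacts plus a manifest with per-file
#' checksums, the seed, and wall times. Re-running with the same config and
#' seed reproduces identical outputs; with `resume = TRUE` stages whose
#' outputs are present and whose config hash matches are skipped.
#'
#' @param config a [run_config()].
#' @return The manifest (list), invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- config_hash(config)
  manifest_path <- file.path(config$output_dir, "manifest.json")
  old_manifest <- if (config$resume && file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else NULL
  manifest <- list(seed = config$seed, config_hash = cfg_hash,
                   stages = list())
  note <- function(...) if (config$log) message(sprintf(...))
  state <- new.env(parent = emptyenv())

  outputs_of <- list(
    generate = c("traces.csv", "covariates.csv", "truth.json"),
    extract = c("windows.csv", "lifespans.csv"),
    stats = c("cross_sections.csv", "autocorrelation.csv",
              "initial_conditions.json", "twilight.csv"),
    survival = c("survival.csv", "survival_summary.json"),
    distfit = c("marginal_fits.csv", "gb2_trend.json"),
    fit = "mpsr_fit.json")

  run_stage <- function(stage, fun) {
    outs <- file.path(config$output_dir, outputs_of[[stage]])
    skip <- config$resume && !is.null(old_manifest) &&
      identical(old_manifest$config_hash, cfg_hash) &&
      all(file.exists(outs)) && stage %in% names(old_manifest$stages)
    t0 <- Sys.time()
    if (skip) {
      note("[%s] outputs present, skipped (resume)", stage)
    } else {
      note("[%s] running ...", stage)
      fun()
    }
    manifest$stages[[stage]] <<- list(
      outputs = as.list(stats::setNames(
        unname(tools::md5sum(outs)), basename(outs))),
      skipped = skip,
      wall_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  load_traces <- function() {
    if (!is.null(state$traces)) return()
    src_dir <- if ("generate" %in% config$stages) config$output_dir
      else config$input_dir %||% config$output_dir
    f <- file.path(src_dir, "traces.csv")
    if (!file.exists(f))
      stop("missing upstream artifact for extract: ", f, call. = FALSE)
    state$traces <- utils::read.csv(f, stringsAsFactors = FALSE)
  }
  load_extracted <- function(stage) {
    for (f in c("windows.csv", "lifespans.csv")) {
      path <- file.path(config$output_dir, f)
      if (!file.exists(path))
        stop("missing upstream artifact for ", stage, ": ", path,
             call. = FALSE)
    }
    if (is.null(state$windows)) {
      state$windows <- utils::read.csv(
        file.path(config$output_dir, "windows.csv"))
      state$lifespans <- utils::read.csv(
        file.path(config$output_dir, "lifespans.csv"))
    }
  }

  for (stage in config$stages) {
    switch(stage,
      generate = run_stage("generate", function() {
        cc <- config$cohort
        cc$seed <- derive_seed(config$seed, 1L)
        cohort <- generate_cohort(cc)
        write_truth(cohort, config$output_dir, overwrite = TRUE)
        state$cohort <- cohort
      }),
      extract = run_stage("extract", function() {
        load_traces()
        rule <- if (!is.null(config$cohort)) config$cohort$rule
          else death_rule(3.5)
        ex <- extract_cohort(state$traces, rule)
        utils::write.csv(ex$windows,
                         file.path(config$output_dir, "windows.csv"),
                         row.names = FALSE)
        utils::write.csv(ex$lifespans,
                         file.path(config$output_dir, "lifespans.csv"),
                         row.names = FALSE)
        state$windows <- ex$windows
        state$lifespans <- ex$lifespans
        state$trajectories <- ex$trajectories
      }),
      stats = run_stage("stats", function() {
        load_extracted("stats")
        # restrict to ages where at least 10 cells are alive with valid
        # windows; very late windows are sparsely populated
        life <- state$lifespans$lifespan_h[
          match(state$windows$cell_id, state$lifespans$cell_id)]
        alive <- is.na(life) | life > state$windows$window_center_h
        n_by_age <- tapply(alive & state$windows$valid,
                           state$windows$window_center_h, sum)
        ages_ok <- as.numeric(names(n_by_age))[n_by_age >= 10]
        cs <- cross_sectional_stats(state$windows, state$lifespans,
                                    ages = ages_ok, n_boot = 300,
                                    seed = derive_seed(config$seed, 2L))
        utils::write.csv(cs, file.path(config$output_dir,
                                       "cross_sections.csv"),
                         row.names = FALSE)
        ac <- do.call(rbind, lapply(utils::head(ages_ok, -1), function(a) {
          r <- tryCatch(damage_autocorrelation(
            state$windows, state$lifespans, a, n_boot = 300,
            seed = derive_seed(config$seed, 3L)), error = function(e) NULL)
          if (is.null(r)) NULL else
            data.frame(age_h = a, r = r$r, se = r$se, n_pairs = r$n_pairs)
        }))
        utils::write.csv(ac, file.path(config$output_dir,
                                       "autocorrelation.csv"),
                         row.names = FALSE)
        u0 <- initial_uptake_from(state, config)
        if (!is.null(u0)) {
          icr <- initial_condition_analysis(state$lifespans, u0,
                                            covariates_from(state, config))
          jsonlite::write_json(
            list(spearman = icr$spearman, split = icr$split,
                 r_high = icr$r_high, r_low = icr$r_low,
                 regression_r2_all = icr$regression_r2_all,
                 regression_r2_low = icr$regression_r2_low),
            file.path(config$output_dir, "initial_conditions.json"),
            auto_unbox = TRUE, digits = NA)
        } else {
          jsonlite::write_json(list(note = "no covariates available"),
                               file.path(config$output_dir,
                                         "initial_conditions.json"),
                               auto_unbox = TRUE)
        }
        tw <- tryCatch(twilight(state$windows, state$lifespans,
                                threshold_x = 2, x_c = 3.5,
                                seed = derive_seed(config$seed, 4L)),
                       error = function(e) NULL)
        if (!is.null(tw)) {
          utils::write.csv(cbind(tw$table,
                                 slope = tw$slope,
                                 ci_low = tw$ci[1], ci_high = tw$ci[2]),
                           file.path(config$output_dir, "twilight.csv"),
                           row.names = FALSE)
        } else {
          utils::write.csv(data.frame(), file.path(config$output_dir,
                                                   "twilight.csv"),
                           row.names = FALSE)
        }
      }),
      survival = run_stage("survival", function() {
        load_extracted("survival")
        sc <- survival_curves(state$lifespans$lifespan_h,
                              state$lifespans$censored,
                              n_boot = 300,
                              seed = derive_seed(config$seed, 5L))
        utils::write.csv(sc$curve, file.path(config$output_dir,
                                             "survival.csv"),
                         row.names = FALSE)
        gs <- gompertz_slope(sc, n_boot = 300,
                             seed = derive_seed(config$seed, 6L))
        jsonlite::write_json(
          list(lifespan_mean = sc$lifespan_mean,
               lifespan_cv = sc$lifespan_cv,
               quantiles = as.list(sc$quantiles),
               gompertz_slope = gs$slope, gompertz_ci = gs$ci,
               fit_window = gs$fit_window),
          file.path(config$output_dir, "survival_summary.json"),
          auto_unbox = TRUE, digits = NA)
      }),
      distfit = run_stage("distfit", function() {
        load_extracted("distfit")
        ages <- sort(unique(state$windows$window_center_h))
        fits <- list(); gb2_rows <- list()
        for (a in ages) {
          z <- state$windows$uptake[state$windows$window_center_h == a &
                                      state$windows$valid]
          z <- z[is.finite(z) & z > 0]
          if (length(z) < 30) next
          fm <- fit_marginal(z, age_h = a,
                             seed = derive_seed(config$seed, 7L))
          fits[[length(fits) + 1L]] <- data.frame(
            age_h = a, family = fm$family, loglik = fm$loglik,
            ks_stat = fm$ks_stat, ks_p = fm$ks_p, rank = fm$rank,
            n = fm$n)
          g <- fm$params[[which(fm$family == "gb2")]]
          if (!is.null(g))
            gb2_rows[[length(gb2_rows) + 1L]] <- data.frame(
              age_h = a, a = g[["a"]], b = g[["b"]], p = g[["p"]],
              q = g[["q"]])
        }
        utils::write.csv(do.call(rbind, fits),
                         file.path(config$output_dir, "marginal_fits.csv"),
                         row.names = FALSE)
        gb2_tab <- do.call(rbind, gb2_rows)
        trend <- if (!is.null(gb2_tab) && nrow(gb2_tab) >= 3)
          gb2_to_mpsr(gb2_tab, sigma = wildtype_params()$sigma)
        else list(per_age = NULL, trend = NULL)
        jsonlite::write_json(trend,
                             file.path(config$output_dir, "gb2_trend.json"),
                             auto_unbox = TRUE, digits = NA)
      }),
      fit = run_stage("fit", function() {
        load_extracted("fit")
        fc <- config$fit
        fc$seed <- derive_seed(config$seed, 8L)
        fit <- fit_mpsr(transition_table(state$windows), fc)
        write_fit(fit, file.path(config$output_dir, "mpsr_fit.json"))
      }))
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

initial_uptake_from <- function(state, config) {
  cov_path <- file.path(
    if ("generate" %in% config$stages) config$output_dir
    else config$input_dir %||% config$output_dir, "covariates.csv")
  if (!file.exists(cov_path)) return(NULL)
  cov <- utils::read.csv(cov_path, stringsAsFactors = FALSE)
  if (!"initial_uptake" %in% names(cov)) return(NULL)
  stats::setNames(cov$initial_uptake, cov$cell_id)
}

covariates_from <- function(state, config) {
  cov_path <- file.path(
    if ("generate" %in% config$stages) config$output_dir
    else config$input_dir %||% config$output_dir, "covariates.csv")
  utils::read.csv(cov_path, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic child seed for stage k of a run seeded with `seed`
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 2654435761 + k * 40503) %% 2147483647)
}

config_hash <- function(config) {
  s <- utils::capture.output(utils::str(
    config[setdiff(names(config), c("resume", "log"))], digits.d = 12))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(s, tmp)
  unname(tools::md5sum(tmp))
}
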