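#' Parse a flat key = value run-configuration file
#'
#' Lines of the form `key = value`; blank lines and lines starting with `#`
#' or `[` (section markers) are ignored. Values that parse as numbers are
#' returned numeric.
#'
#' @param file Path to the configuration file.
#' @return A named list.
#' @export
parse_run_config <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "[")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) {
      stop_phybite(sprintf("Malformed config line: %s", ln))
    }
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

config_fingerprint <- function(config) {
  # fingerprint only the analysis-relevant entries, so identical analyses
  # written to different output directories hash identically
  keep <- setdiff(sort(names(config)), "out_dir")
  sprintf("%08x",
          string_hash32(paste(deparse(config[keep]), collapse = "")))
}

write_csv_with_header <- function(df, file, seed, fingerprint) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d config=%s", seed, fingerprint), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Run the full prediction workflow
#'
#' Orchestrates, per muscle group: model fit on the response-bearing taxa,
#' leave-one-out cross-validation, posterior prediction for every taxon with
#' a missing response, and (when lever geometry is supplied) a bite-force
#' table at anterior and posterior bite points. Writes one CSV per stage
#' plus a run manifest; every output starts with a comment line carrying
#' the master seed and a configuration fingerprint.
#'
#' @param config A named list (or path to a `key = value` file, see
#'   [parse_run_config()]) with entries: `tree` (newick path), `data`
#'   (trait CSV: `taxon,muscle_group,x,y[,status]`), optionally `geometry`
#'   (lever CSV), `out_dir`, `groups` (comma-separated, default all three),
#'   `iterations`, `burnin`, `thin`, `chains`, `seed`, `threshold`,
#'   `lambda` (`fixed` or `estimate`), `run_loocv` (default 1).
#' @return Invisibly, a named list of per-group results
#'   (`fit`, `loocv`, `predictions`) plus `bite` and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- parse_run_config(config)
  }
  stopifnot(is.list(config))
  for (key in c("tree", "data")) {
    if (is.null(config[[key]])) {
      stop_phybite(sprintf("Config entry `%s` is required.", key))
    }
    if (!file.exists(config[[key]])) {
      stop_phybite(sprintf("File not found for `%s`: %s", key,
                           config[[key]]))
    }
  }
  out_dir <- config$out_dir %||% "phybite_run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1)
  threshold <- config$threshold %||% 0.05
  lambda <- config$lambda %||% "fixed"
  run_loocv <- as.logical(config$run_loocv %||% 1)
  mcfg <- ppm_config(
    iterations = config$iterations %||% 1000,
    burnin = config$burnin %||% 500,
    thin = config$thin %||% 1,
    chains = config$chains %||% 2,
    seed = seed
  )
  fingerprint <- config_fingerprint(config)
  t0 <- Sys.time()

  tree <- parse_newick(paste(readLines(config$tree, warn = FALSE),
                             collapse = ""))
  traits <- utils::read.csv(config$data, stringsAsFactors = FALSE,
                            comment.char = "#")
  require_columns(traits, c("taxon", "muscle_group", "x", "y"),
                  "trait CSV")
  groups <- if (!is.null(config$groups)) {
    trimws(strsplit(as.character(config$groups), ",")[[1]])
  } else {
    intersect(muscle_groups()$muscle_group, unique(traits$muscle_group))
  }

  results <- list()
  predictions <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage=%s error=%s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop_phybite(sprintf("Pipeline stage `%s` failed: %s", name,
                           conditionMessage(e)))
    })
  }
  for (g in groups) {
    dg <- traits[traits$muscle_group == g,
                 intersect(c("taxon", "x", "y", "status"), names(traits))]
    gcfg <- mcfg
    gcfg$seed <- derive_seed(seed, paste0("fit-", g))
    fit <- stage(paste0("fit-", g),
                 fit_ppm(dg, tree, gcfg, lambda = lambda))
    write_csv_with_header(fit$draws,
                          file.path(out_dir, sprintf("posterior_%s.csv", g)),
                          seed, fingerprint)
    cv <- NULL
    if (run_loocv) {
      cvcfg <- mcfg
      cvcfg$seed <- derive_seed(seed, paste0("loocv-", g))
      cv <- stage(paste0("loocv-", g),
                  loocv(dg, tree, cvcfg, lambda = lambda,
                        threshold = threshold))
      write_csv_with_header(cv$folds,
                            file.path(out_dir, sprintf("loocv_%s.csv", g)),
                            seed, fingerprint)
      message(sprintf("[%s] LOOCV accuracy: %.3f", g, cv$accuracy))
    }
    pred <- NULL
    if (any(!is.finite(dg$y))) {
      pred <- stage(paste0("predict-", g),
                    predict_batch(fit,
                                  seed = derive_seed(seed,
                                                     paste0("pred-", g))))
      write_csv_with_header(
        pred$summary,
        file.path(out_dir, sprintf("predictions_%s.csv", g)),
        seed, fingerprint)
      predictions[[g]] <- pred
    }
    results[[g]] <- list(fit = fit, loocv = cv, predictions = pred)
  }

  bite <- NULL
  if (!is.null(config$geometry) && length(predictions) == 3) {
    geometry <- stage("geometry", read_lever_geometry(config$geometry))
    bite <- stage("biteforce",
                  bite_force_from_predictions(predictions, geometry))
    write_csv_with_header(bite, file.path(out_dir, "bite_force.csv"),
                          seed, fingerprint)
  }

  manifest <- c(
    sprintf("seed = %d", seed),
    sprintf("config = %s", fingerprint),
    sprintf("groups = %s", paste(groups, collapse = ",")),
    sprintf("phybite_version = %s",
            as.character(utils::packageVersion("phybite"))),
    sprintf("r_version = %s", R.version.string),
    sprintf("wall_time_s = %.2f",
            as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    sprintf("timestamp = %s", format(t0, "%Y-%m-%dT%H:%M:%S"))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(c(results, list(bite = bite, out_dir = out_dir)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
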