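## ------------------------------------------------------------------
## Config-driven experiment runner and fixture generation
## ------------------------------------------------------------------

#' Run a configured simulation study
#'
#' Executes a relative-efficiency or bias study described by a config --
#' either a YAML file path or an equivalent named list -- and writes the
#' report, a manifest echoing the config, and returns the report
#' invisibly.  Config fields:
#' \preformatted{
#' study:      "re" or "bias"
#' scenario:   {name: ..., and scenario parameters}
#' missingness:{mechanism: MCAR|MAR, targets: [...], rate: ...,
#'              predictor: ..., slope: ...}
#' analyses:   list of {analysis: ..., outcome: ..., covariates: [...]}
#' n, M, reps: design sizes
#' seed:       master seed (mandatory)
#' out_dir:    output directory (optional; no files written when absent)
#' }
#'
#' @param config path to a YAML file or a named list.
#' @return the `"re_report"` or `"bias_report"`, invisibly.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("study", "scenario", "missingness", "analyses", "n", "M",
                "reps", "seed")
  missing_fields <- setdiff(required, names(config))
  if (length(missing_fields))
    stop("config is missing fields: ", paste(missing_fields, collapse = ", "))
  if (config$reps < 1) stop("config field 'reps' must be positive")

  sc <- do.call(scenario, config$scenario)
  ms <- do.call(missingness_spec, config$missingness)
  analyses <- lapply(config$analyses, function(a) {
    list(analysis = a$analysis, outcome = a$outcome,
         covariates = unlist(a$covariates))
  })
  report <- if (config$study == "re") {
    mi_re_simulation(sc, ms, analyses, n = config$n, M = config$M,
                     reps = config$reps, seed = config$seed)
  } else if (config$study == "bias") {
    bias_study(sc, ms, analyses, n = config$n, M = config$M,
               reps = config$reps, seed = config$seed,
               exclude_imputed_outcome = isTRUE(config$exclude_imputed_outcome))
  } else stop("config field 'study' must be 're' or 'bias'")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(report),
                     file.path(config$out_dir, paste0(config$study, "_report.csv")),
                     row.names = FALSE)
    manifest <- list(config = config,
                     package_version = as.character(utils::packageVersion("rglmi")),
                     timestamp = format(Sys.time(), tz = "UTC"))
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  }
  invisible(report)
}

#' Generate a scenario fixture on disk
#'
#' Writes a complete dataset, a masked copy, and a JSON sidecar of the
#' scenario's true analysis parameters -- handy for external checks and
#' test fixtures.
#'
#' @param name scenario name (see [scenario()]).
#' @param n rows.
#' @param seed integer seed.
#' @param dir output directory.
#' @param miss_spec optional [missingness_spec()]; default 50% MCAR on the
#'   scenario's first categorical column.
#' @param ... scenario parameters passed to [scenario()].
#' @return paths of the written files, invisibly.
#' @export
generate_fixture <- function(name, n, seed, dir = ".", miss_spec = NULL, ...) {
  set.seed(seed)
  sc <- scenario(name, ...)
  dat <- sc$sample(n)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f_complete <- file.path(dir, paste0(name, "_complete.csv"))
  f_masked <- file.path(dir, paste0(name, "_incomplete.csv"))
  f_truth <- file.path(dir, paste0(name, "_truth.json"))
  write_incomplete_csv(dat, f_complete)
  if (n > 0) {
    if (is.null(miss_spec))
      miss_spec <- missingness_spec("MCAR", targets = sc$roles$categorical[1])
    write_incomplete_csv(apply_missingness(dat, miss_spec, roles = sc$roles),
                         f_masked)
  } else {
    write_incomplete_csv(dat, f_masked)
  }
  jsonlite::write_json(lapply(sc$truth, function(v) as.list(v)), f_truth,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(complete = f_complete, incomplete = f_masked, truth = f_truth))
}

## ------------------------------------------------------------------
## Model spec YAML round trip
## ------------------------------------------------------------------

#' Write/read an RGL model specification as YAML
#'
#' Serialises the named parameter blocks (`theta_y`, `theta_yy`,
#' `theta_yz`, `theta_w0`, `theta_wy`, `theta_wz`, `theta_v`) so a model
#' can be stored alongside generated data.
#'
#' @param model an [rgl_model()].
#' @param file path.
#' @export
write_model_yaml <- function(model, file) {
  ll <- model$loglin
  g <- model$gaussian
  doc <- list(
    binary = as.list(ll$names),
    theta_y = as.list(unname(ll$theta_main)),
    theta_yy = lapply(seq_len(ll$L), function(i) as.list(ll$theta_pair[i, ])),
    theta_yz = if (!is.null(ll$theta_cov))
      lapply(seq_len(ll$L), function(i) as.list(ll$theta_cov[i, ])),
    extra_terms = lapply(ll$extra_terms, function(tm)
      list(idx = as.list(tm$idx), coef = tm$coef)),
    conditioned = as.list(model$conditioned_names),
    baseline_logit = if (!is.null(model$baseline_logit))
      list(intercept = model$baseline_logit$intercept,
           slopes = as.list(model$baseline_logit$slopes)))
  if (!is.null(g)) {
    doc$continuous <- as.list(g$names)
    doc$theta_w0 <- as.list(unname(g$intercept))
    doc$theta_wy <- lapply(seq_len(g$q), function(i) as.list(g$cat_loadings[i, ]))
    doc$theta_wz <- if (!is.null(g$cov_loadings))
      lapply(seq_len(g$q), function(i) as.list(g$cov_loadings[i, ]))
    doc$theta_v <- lapply(seq_len(g$q), function(i) as.list(g$resid_cov[i, ]))
  }
  yaml::write_yaml(doc, file, precision = 15)
  invisible(file)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(file) {
  doc <- yaml::read_yaml(file)
  L <- length(doc$theta_y)
  to_mat <- function(rows) do.call(rbind, lapply(rows, unlist))
  ll <- loglinear_spec(unlist(doc$theta_y),
                       theta_pair = to_mat(doc$theta_yy),
                       theta_cov = if (!is.null(doc$theta_yz)) to_mat(doc$theta_yz),
                       extra_terms = lapply(doc$extra_terms, function(tm)
                         list(idx = unlist(tm$idx), coef = tm$coef)),
                       names = unlist(doc$binary))
  g <- NULL
  if (!is.null(doc$theta_w0)) {
    g <- gaussian_layer(unlist(doc$theta_w0),
                        cat_loadings = to_mat(doc$theta_wy),
                        resid_cov = to_mat(doc$theta_v),
                        cov_loadings = if (!is.null(doc$theta_wz)) to_mat(doc$theta_wz),
                        names = unlist(doc$continuous))
  }
  bl <- if (!is.null(doc$baseline_logit))
    list(intercept = doc$baseline_logit$intercept,
         slopes = unlist(doc$baseline_logit$slopes))
  rgl_model(ll, g, conditioned_names = unlist(doc$conditioned) %||% character(),
            baseline_logit = bl)
}
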