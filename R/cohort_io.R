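# Dataset dialect and serialisation.
#
# A dataset on disk is a directory: `meta.json` (schema
# `evoked.dataset.v1`: subjects, condition labels, sampling metadata,
# provenance) plus `waveforms.csv` (long format: subject, condition, t,
# value).  The CSV is written by readr with shortest-round-trip doubles,
# so write-then-read reproduces the arrays exactly.  Model specifications
# round-trip through a YAML schema (`model.spec.v1`) and fitted posteriors
# through a JSON container (`fit.result.v1`).

.schema_fail <- function(path, msg) {
  stop("dataset schema violation at ", path, ": ", msg, call. = FALSE)
}

#' Write a dataset (or cohort) to disk
#'
#' @param ds a `tc_dataset` or `tc_cohort`; a cohort additionally writes
#'   its ground truth to `truth.json`
#' @param path directory to create/populate
#' @return `path`, invisibly
#' @export
write_dataset <- function(ds, path) {
  truth <- NULL
  if (inherits(ds, "tc_cohort")) {
    truth <- ds$truth
    ds <- ds$dataset
  }
  stopifnot(inherits(ds, "tc_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(schema = "evoked.dataset.v1",
               subjects = ds$subjects,
               condition_labels = ds$condition_labels,
               sampling_rate = ds$sampling_rate,
               t_origin = ds$t[1],
               n_samples = length(ds$t),
               provenance = ds$provenance)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  long <- do.call(rbind, lapply(seq_along(ds$waves), function(i) {
    W <- ds$waves[[i]]
    data.frame(subject = ds$subjects[i],
               condition = rep(ds$condition_labels, each = nrow(W)),
               t = rep(ds$t, times = ncol(W)),
               # 17 significant digits: doubles survive the text round-trip
               value = sprintf("%.17g", as.numeric(W)))
  }))
  readr::write_csv(long, file.path(path, "waveforms.csv"),
                   progress = FALSE)
  if (!is.null(truth)) {
    tr <- truth
    tr$theta <- apply(truth$theta, 1, as.list)
    jsonlite::write_json(
      list(schema = "cohort.truth.v1",
           theta = truth$theta, beta = truth$beta,
           quantities = colnames(truth$theta),
           design = truth$design, snr = truth$snr, seed = truth$seed,
           theta_sd = truth$theta_sd),
      file.path(path, "truth.json"), auto_unbox = TRUE, digits = NA,
      matrix = "rowmajor")
  }
  invisible(path)
}

#' Read a dataset from disk
#'
#' Validates the `evoked.dataset.v1` schema; violations are reported with
#' a JSON-pointer-style path to the offending field.
#'
#' @param path directory written by [write_dataset()]
#' @return a `tc_dataset` (a `tc_cohort` if `truth.json` is present)
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) .schema_fail("/", "meta.json not found")
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (f in c("schema", "subjects", "condition_labels", "sampling_rate",
              "t_origin", "n_samples"))
    if (is.null(meta[[f]])) .schema_fail(paste0("/", f), "missing field")
  if (!identical(meta$schema, "evoked.dataset.v1"))
    .schema_fail("/schema", paste0("unsupported schema '", meta$schema, "'"))

  # the value column is parsed as text and converted by base R's strtod,
  # which is correctly rounded, so the write/read cycle is lossless
  long <- as.data.frame(readr::read_csv(
    file.path(path, "waveforms.csv"), show_col_types = FALSE,
    progress = FALSE,
    col_types = readr::cols(value = readr::col_character())))
  long$value <- as.numeric(long$value)
  nt <- meta$n_samples
  dt <- 1000 / meta$sampling_rate
  t_grid <- meta$t_origin + (seq_len(nt) - 1) * dt
  labs <- meta$condition_labels
  waves <- vector("list", length(meta$subjects))
  for (i in seq_along(meta$subjects)) {
    si <- long[long$subject == meta$subjects[i], ]
    if (nrow(si) != nt * length(labs))
      .schema_fail(paste0("/subjects/", i),
                   paste0("subject '", meta$subjects[i], "' has ",
                          nrow(si), " samples; expected ",
                          nt * length(labs),
                          " (time grids must match across subjects)"))
    W <- matrix(NA_real_, nt, length(labs), dimnames = list(NULL, labs))
    for (cc in seq_along(labs)) {
      sc <- si[si$condition == labs[cc], ]
      if (nrow(sc) != nt)
        .schema_fail(paste0("/subjects/", i, "/", labs[cc]),
                     paste0("has ", nrow(sc), " samples, expected ", nt))
      W[, cc] <- sc$value[order(sc$t)]
    }
    waves[[i]] <- W
  }
  ds <- structure(list(subjects = meta$subjects, t = t_grid,
                       sampling_rate = meta$sampling_rate,
                       condition_labels = labs, waves = waves,
                       provenance = meta$provenance),
                  class = "tc_dataset")
  tf <- file.path(path, "truth.json")
  if (file.exists(tf)) {
    tr <- jsonlite::read_json(tf, simplifyVector = TRUE)
    theta <- matrix(tr$theta, ncol = length(tr$quantities), byrow = FALSE)
    colnames(theta) <- tr$quantities
    beta <- tr$beta
    if (!is.null(beta)) colnames(beta) <- tr$quantities
    return(structure(list(dataset = ds,
                          truth = list(theta = theta, beta = beta,
                                       design = tr$design, snr = tr$snr,
                                       seed = tr$seed,
                                       theta_sd = tr$theta_sd)),
                     class = "tc_cohort"))
  }
  ds
}

#' Import one subject from a per-condition CSV table
#'
#' Reads a plain CSV with one column per condition (pre, early_post,
#' late_post), one row per sample.
#'
#' @param path CSV file
#' @param sampling_rate samples per second
#' @param t_origin time of the first sample (ms)
#' @param subject subject identifier
#' @return a `tc_dataset` with one subject
#' @export
read_subject_csv <- function(path, sampling_rate = 1000, t_origin = 0,
                             subject = "sub-01") {
  d <- as.data.frame(readr::read_csv(path, show_col_types = FALSE,
                                     progress = FALSE))
  missing_cols <- setdiff(.cond_labels, names(d))
  if (length(missing_cols))
    .schema_fail("/columns", paste0("missing condition column(s): ",
                                    paste(missing_cols, collapse = ", ")))
  W <- as.matrix(d[, .cond_labels])
  dt <- 1000 / sampling_rate
  structure(list(subjects = subject,
                 t = t_origin + (seq_len(nrow(W)) - 1) * dt,
                 sampling_rate = sampling_rate,
                 condition_labels = .cond_labels,
                 waves = list(W),
                 provenance = list(source = path)),
            class = "tc_dataset")
}

# ---- model spec YAML --------------------------------------------------------

#' Serialise a model specification to YAML
#'
#' Schema `model.spec.v1`; includes every field (gains, kinetics, free
#' mask, delays, defaults) so a fitted model is fully reproducible from
#' the file.
#'
#' @param spec a `tc_model`
#' @param path output file; if `NULL`, the YAML text is returned
#' @return `path` (or the YAML string), invisibly
#' @export
write_model_yaml <- function(spec, path = NULL) {
  x <- list(schema = "model.spec.v1",
            populations = spec$populations,
            inhibitory = spec$inhibitory,
            kinetics = list(kappa = as.list(spec$kinetics$kappa),
                            V_rev = as.list(spec$kinetics$V_rev),
                            alpha_NMDA = spec$kinetics$alpha_NMDA),
            gains = lapply(spec$gains, function(m)
              apply(m, 1, as.list, simplify = FALSE)),
            gM = as.list(spec$gM), gH = as.list(spec$gH),
            free_mask = list(source = spec$free_mask$source,
                             target = spec$free_mask$target),
            C = spec$C, V_R = spec$V_R, Sigma = as.list(spec$Sigma),
            V_L = spec$V_L, g_L = spec$g_L,
            delay_tc = spec$delay_tc, delay_ct = spec$delay_ct,
            free_decay = spec$free_decay,
            input_target = spec$input_target)
  txt <- yaml::as.yaml(x, precision = 15)
  if (is.null(path)) return(invisible(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Read a model specification from YAML
#'
#' @param path file written by [write_model_yaml()] (or a YAML string)
#' @return a validated `tc_model`
#' @export
read_model_yaml <- function(path) {
  x <- yaml::yaml.load(if (file.exists(path)) paste(readLines(path),
                                                    collapse = "\n") else path)
  if (!identical(x$schema, "model.spec.v1"))
    stop("unsupported model schema: ", x$schema)
  pops <- unlist(x$populations)
  np <- length(pops)
  gains <- lapply(x$gains, function(g) {
    m <- do.call(rbind, lapply(g, function(r) unlist(r)))
    dimnames(m) <- list(pops, pops)
    m
  })
  spec <- list(populations = pops,
               inhibitory = unlist(x$inhibitory),
               kinetics = list(kappa = unlist(x$kinetics$kappa)[.kinds],
                               V_rev = unlist(x$kinetics$V_rev)[.kinds],
                               alpha_NMDA = x$kinetics$alpha_NMDA),
               gains = gains[.syn_kinds],
               gM = unlist(x$gM)[pops], gH = unlist(x$gH)[pops],
               free_mask = data.frame(source = unlist(x$free_mask$source),
                                      target = unlist(x$free_mask$target),
                                      stringsAsFactors = FALSE),
               C = x$C, V_R = x$V_R, Sigma = unlist(x$Sigma)[pops],
               V_L = x$V_L, g_L = x$g_L,
               delay_tc = x$delay_tc, delay_ct = x$delay_ct,
               free_decay = unlist(x$free_decay),
               input_target = x$input_target)
  class(spec) <- "tc_model"
  validate_model(spec)
  spec
}

# ---- fit results ------------------------------------------------------------

#' Write a fitted posterior to JSON (`fit.result.v1`)
#'
#' @param posterior a `tc_posterior`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fit <- function(posterior, path) {
  x <- list(schema = "fit.result.v1",
            design = posterior$design,
            parameter_names = posterior$layout$names,
            mean = as.numeric(posterior$mean),
            cov = posterior$cov,
            lambda = posterior$lambda,
            F = posterior$F, F_trace = posterior$F_trace,
            accuracy = posterior$accuracy,
            complexity = posterior$complexity,
            explained_variance = posterior$explained_variance,
            fitted = posterior$fitted,
            t_grid = posterior$t_grid,
            iterations = posterior$iterations)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a fitted posterior written by [write_fit()]
#'
#' @param path JSON file
#' @param spec,design the model and design the fit was made under (used to
#'   rebuild the parameter layout)
#' @return a `tc_posterior`
#' @export
read_fit <- function(path, spec = tc_model(), design = NULL) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "fit.result.v1"))
    stop("unsupported fit schema: ", x$schema)
  if (is.null(design)) design <- condition_design(x$design)
  lay <- .par_layout(spec, design,
                     estimate_gain = "obs:log_gain" %in% x$parameter_names)
  if (!identical(lay$names, x$parameter_names))
    stop("parameter layout in file does not match the given spec/design")
  fitted <- as.matrix(x$fitted)
  structure(list(mean = setNames(x$mean, x$parameter_names),
                 cov = as.matrix(x$cov), lambda = x$lambda,
                 F = x$F, F_trace = x$F_trace,
                 accuracy = x$accuracy, complexity = x$complexity,
                 fitted = fitted,
                 explained_variance = x$explained_variance,
                 design = x$design, layout = lay, t_grid = x$t_grid,
                 iterations = x$iterations),
            class = "tc_posterior")
}
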