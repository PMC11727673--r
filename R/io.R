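# All artifacts are plain delimited text with headers; designs carry a
# key-value metadata header in comment lines. Files reference items by
# their stable ids, never by position.

#' Write / read a block design
#'
#' The design file holds a metadata header (`# key: value` lines with
#' v, b, k, r, lambda and the package version) followed by one line per
#' block of comma-separated item ids.
#'
#' @param design a `"bibd"` object.
#' @param path file path.
#' @param items item ids (defaults to `item01 ...` tokens).
#' @return `write_design` returns `path` invisibly; `read_design`
#'   returns a list with the `"bibd"` design and the `items` vector.
#' @export
write_design <- function(design, path, items = NULL) {
  stopifnot(inherits(design, "bibd"))
  if (is.null(items)) items <- sprintf("item%02d", seq_len(design$v))
  if (length(items) != design$v) stop("need ", design$v, " item ids")
  ver <- as.character(utils::packageVersion("bwspref"))
  hdr <- c(sprintf("# v: %d", design$v), sprintf("# b: %d", design$b),
           sprintf("# k: %d", design$k), sprintf("# r: %d", design$r),
           sprintf("# lambda: %d", design$lambda),
           sprintf("# generator: bwspref %s", ver),
           sprintf("# items: %s", paste(items, collapse = ",")))
  lines <- apply(design$blocks, 1L, function(blk)
    paste(items[blk], collapse = ","))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("design file lacks header field '", key, "'")
    sub(paste0("^# ", key, ":\\s*"), "", ln[1L])
  }
  items <- strsplit(get("items"), ",")[[1L]]
  blocks <- t(vapply(strsplit(body, ","),
                     function(b) match(b, items),
                     integer(length(strsplit(body[1L], ",")[[1L]]))))
  if (anyNA(blocks)) stop("design file references unknown item ids")
  design <- .new_bibd(as.integer(get("v")), as.integer(get("b")),
                      as.integer(get("k")), as.integer(get("r")),
                      as.integer(get("lambda")), blocks)
  list(design = design, items = items)
}

#' Write / read long-format best-worst responses
#'
#' Tab-separated long format: one row per respondent-block with columns
#' `respondent_id`, `phase`, `block`, `best`, `worst`. Missing picks are
#' written as empty fields and read back as `NA`.
#'
#' @param x a `"bws_study"` or long response data frame.
#' @param path file path.
#' @return `write_responses` returns `path` invisibly; `read_responses`
#'   returns the long data frame.
#' @export
write_responses <- function(x, path) {
  resp <- if (inherits(x, "bws_study")) x$responses else x
  utils::write.table(resp, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           na.strings = "", colClasses = c(
                             respondent_id = "character",
                             phase = "character", block = "integer",
                             best = "character", worst = "character"),
                           stringsAsFactors = FALSE)
  out
}

#' Write counting scores or estimation results as delimited text
#'
#' @param x a `"bws_scores"` data frame, a `"maxdiff_fit"`, or a
#'   `"maxdiff_fit_list"` (subgroup results are stacked).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  tab <- if (inherits(x, "maxdiff_fit")) {
    cbind(x$coefficients,
          loglik = x$loglik, converged = x$converged)
  } else if (inherits(x, "maxdiff_fit_list")) {
    do.call(rbind, lapply(unclass(x), function(f)
      cbind(f$coefficients, loglik = f$loglik, converged = f$converged)))
  } else as.data.frame(x)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full best-worst scaling pipeline
#'
#' Executes design construction, respondent simulation, completeness
#' filtering, counting scores, overall and per-subgroup conditional-logit
#' fits, and the subgroup comparison, writing every artifact into an
#' output directory together with a log that records the seeds, the
#' configuration hash and stage-by-stage counts. A second run with an
#' identical configuration produces byte-identical artifacts.
#'
#' Recognised configuration fields (unknown fields are rejected):
#' \describe{
#'   \item{out_dir}{output directory (created if needed); required}
#'   \item{seed}{master seed, default 1}
#'   \item{preset}{`"study-emulation"` (default) for the packaged TJA
#'     emulation}
#'   \item{v, k}{design parameters when not using the preset}
#'   \item{strata}{named vector of complete respondents per phase}
#'   \item{n_submitted_extra}{incomplete extras, default 0}
#'   \item{heterogeneity_sd}{respondent perturbation sd, default 0.3}
#'   \item{estimator}{`"maxdiff"` (default) or `"sequential"`}
#'   \item{top}{top items per subgroup in the comparison, default 4}
#' }
#'
#' @param config a named list, or the path to a YAML file holding one.
#' @return Invisibly, a list with the in-memory artifacts (`design`,
#'   `study`, `included`, `excluded`, `scores`, `fit`, `subgroup_fits`,
#'   `comparison`) and the `files` written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  known <- c("out_dir", "seed", "preset", "v", "k", "strata",
             "n_submitted_extra", "heterogeneity_sd", "estimator", "top")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  estimator <- config$estimator %||% "maxdiff"
  top <- config$top %||% 4L
  cfg_hash <- .config_hash(config)
  log_lines <- c(sprintf("bwspref %s",
                         as.character(utils::packageVersion("bwspref"))),
                 sprintf("config_hash: %s", cfg_hash),
                 sprintf("seed: %d", seed))
  stage <- function(msg) log_lines <<- c(log_lines, msg)

  tryCatch({
    if (is.null(config$preset) || config$preset == "study-emulation") {
      study <- study_emulation(
        master_seed = seed,
        heterogeneity_sd = config$heterogeneity_sd %||% 0.3)
      items <- study$items
      design <- study$design
    } else stop("unknown preset '", config$preset, "'")
    if (!is.null(config$strata)) {
      strata <- unlist(config$strata)
      profiles <- stats::setNames(
        lapply(names(strata), default_profile,
               heterogeneity_sd = config$heterogeneity_sd %||% 0.3),
        names(strata))
      design <- bibd(as.integer(config$v %||% 13L),
                     as.integer(config$k %||% 4L))
      items <- if ((config$v %||% 13L) == 13L) tja_outcomes()$item_id
      else sprintf("item%02d", seq_len(design$v))
      study <- simulate_study(
        design, strata, profiles = profiles,
        n_submitted_extra = as.integer(config$n_submitted_extra %||% 0L),
        master_seed = seed, items = items)
    }
    stage(sprintf("design: v=%d b=%d k=%d r=%d lambda=%d",
                  design$v, design$b, design$k, design$r, design$lambda))
    stage(sprintf("simulate: %d submitted", study$n_submitted))

    flt <- filter_complete(study)
    stage(sprintf("filter: %d included, %d excluded",
                  length(unique(flt$included$responses$respondent_id)),
                  length(unique(flt$excluded$respondent_id))))

    scores <- count_scores(flt$included)
    fit <- fit_maxdiff(flt$included, method = estimator)
    sub_fits <- fit_by_subgroup(flt$included, method = estimator)
    comparison <- compare_subgroups(sub_fits, top = top)
    stage(sprintf("fit: logLik %.4f, converged %s", fit$loglik,
                  fit$converged))

    files <- c(design = file.path(out_dir, "design.txt"),
               responses = file.path(out_dir, "responses.tsv"),
               scores = file.path(out_dir, "scores.tsv"),
               results = file.path(out_dir, "results_overall.tsv"),
               results_by_phase = file.path(out_dir, "results_by_phase.tsv"),
               comparison = file.path(out_dir, "comparison.tsv"),
               plot_data = file.path(out_dir, "plot_data.tsv"),
               log = file.path(out_dir, "log.txt"))
    write_design(design, files[["design"]], items = items)
    write_responses(study, files[["responses"]])
    write_results(scores, files[["scores"]])
    write_results(fit, files[["results"]])
    write_results(sub_fits, files[["results_by_phase"]])
    write_results(comparison$top, files[["comparison"]])
    # forest-plot data: utilities with error bars, sorted
    write_results(fit$coefficients[, c("item_id", "beta", "se",
                                       "ci_low", "ci_high")],
                  files[["plot_data"]])
    writeLines(log_lines, files[["log"]])
    invisible(list(design = design, study = study,
                   included = flt$included, excluded = flt$excluded,
                   scores = scores, fit = fit, subgroup_fits = sub_fits,
                   comparison = comparison, files = files))
  }, error = function(e) {
    stop("pipeline failed after stages [",
         paste(log_lines[-(1:3)], collapse = " | "), "]: ",
         conditionMessage(e), call. = FALSE)
  })
}

# md5 of the canonicalised configuration (stable field order)
.config_hash <- function(config) {
  config$out_dir <- NULL
  config <- config[order(names(config))]
  txt <- paste(names(config),
               vapply(config, function(x) paste(format(x), collapse = ","),
                      character(1)),
               sep = "=", collapse = ";")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}
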