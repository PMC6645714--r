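# polynomial rolling hash of a character representation; used to stamp
# output files with a short, stable configuration fingerprint
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

.file_header <- function(seed = NULL, config = NULL) {
  c(sprintf("# saccRace %s",
            as.character(utils::packageVersion("saccRace"))),
    sprintf("# seed=%s", if (is.null(seed)) "NA" else seed),
    sprintf("# config_hash=%s", .config_hash(config)))
}

.trial_cols <- c("participant", "luminance", "gap_ms", "cue_side",
                 "choice_side", "correct", "rt_ms", "rpt_ms",
                 "deadline_exceeded", "outcome_class")

#' Write / read trial tables as CSV
#'
#' Trial tables are plain CSV with a short comment header (package version,
#' seed, configuration hash).  The canonical columns are `participant`,
#' `luminance`, `gap_ms`, `cue_side`, `choice_side`, `correct`, `rt_ms`,
#' `rpt_ms`, `deadline_exceeded`, `outcome_class`; latent simulator
#' diagnostics travel in optional `sim_`-prefixed columns.
#'
#' @param trials Trial-record data frame.
#' @param path Output file.
#' @param seed,config Provenance recorded in the header.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` returns
#'   the trial data frame.
#' @export
write_trials <- function(trials, path, seed = NULL, config = NULL) {
  if (!"participant" %in% names(trials)) trials$participant <- "pooled"
  if (!"luminance" %in% names(trials)) trials$luminance <- "all"
  extra <- grep("^sim_", names(trials), value = TRUE)
  trials <- trials[, c(.trial_cols, extra)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.file_header(seed, config), con)
  utils::write.csv(trials, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(.trial_cols, names(df))
  if (length(miss))
    stop("trial table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "),
         " (expected schema: ", paste(.trial_cols, collapse = ", "), ")")
  if (!is.logical(df$correct)) df$correct <- as.logical(df$correct)
  if (!is.logical(df$deadline_exceeded))
    df$deadline_exceeded <- as.logical(df$deadline_exceeded)
  bad <- which(!is.na(df$rt_ms) & !is.na(df$gap_ms) &
                 abs(df$rpt_ms - (df$rt_ms - df$gap_ms)) > 1e-6)
  if (length(bad))
    stop("rpt_ms != rt_ms - gap_ms at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  df
}

#' Write a tachometric curve or feature table as CSV
#'
#' @param x A `"tach_curve"` or `"feature_ci"` object (or feature vector).
#' @param path Output file.
#' @param seed,config Provenance recorded in the header.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(x, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.file_header(seed, config), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
write_features_csv <- function(x, path, seed = NULL, config = NULL) {
  df <- if (inherits(x, "feature_ci")) as.data.frame(x)
        else data.frame(feature = names(x), point = as.numeric(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.file_header(seed, config), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / deserialize model parameters as key-value config files
#'
#' One `[condition]` section per luminance, one `name = value` line per
#' parameter, mirroring the model's parameter names.
#'
#' @param params A [luminance_params()] object or a named list of them.
#' @param path File path.
#' @return `write_params_config()` returns `path` invisibly;
#'   `read_params_config()` returns a named list of [luminance_params()].
#' @export
write_params_config <- function(params, path) {
  if (inherits(params, "luminance_params")) params <- list(all = params)
  lines <- character()
  for (l in names(params)) {
    lines <- c(lines, sprintf("[%s]", l),
               sprintf("%s = %.15g", names(params[[l]]),
                       unlist(params[[l]])), "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  cur <- NULL
  vals <- list()
  flush <- function(out, cur, vals) {
    if (is.null(cur)) return(out)
    out[[cur]] <- do.call(luminance_params, vals)
    out
  }
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      out <- flush(out, cur, vals)
      cur <- sub("^\\[(.*)\\]$", "\\1", ln)
      vals <- list()
    } else {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) stop("malformed config line: ", ln)
      vals[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
    }
  }
  flush(out, cur, vals)
}
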