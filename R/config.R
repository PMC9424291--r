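# Configuration: flat `key = value` text files with dotted section keys,
# e.g. `model.n = 3`. Values: numbers, comma-separated numeric lists, or
# bare strings. `#` starts a comment.

config_defaults <- function() {
  list(
    model = list(n = 3L, delta_mu = 1, sigma = 1),
    boundary = list(family = "curve", theta = NA_real_, alpha = 0, beta = 0,
                    theta_axis = NULL, alpha_axis = NULL, beta_axis = NULL),
    costs = list(W = 1, cost_ratios = c(0.001, 0.04, 0.1)),
    mc = list(n_trials = 5000L, max_steps = 10000L, master_seed = 1L),
    analysis = list(delta = 0.02, sigma_mode = "per_trial",
                    min_count = 5L, classifier_z = 2, drift_tol = 0.08,
                    smoother_bs = "tp", smoother_k = -1,
                    hicks_n = c(2L, 3L, 4L)))
}

parse_config_value <- function(x) {
  x <- trimws(x)
  if (grepl(",", x, fixed = TRUE)) {
    parts <- trimws(strsplit(x, ",", fixed = TRUE)[[1L]])
    nums <- suppressWarnings(as.numeric(parts))
    if (!anyNA(nums)) return(nums)
    return(parts)
  }
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) return(num)
  if (tolower(x) %in% c("true", "false")) return(tolower(x) == "true")
  x
}

#' Load and validate a run configuration
#'
#' Reads a plain-text `key = value` config (dotted keys select blocks:
#' `model.n`, `boundary.family`, `costs.cost_ratios`, `mc.n_trials`,
#' `analysis.delta`, ...), fills unset keys with package defaults, and
#' validates the result. Comma-separated values become numeric vectors
#' (e.g. `costs.cost_ratios = 0.001, 0.04, 0.1`).
#'
#' @param path Path to the config file.
#' @return Validated nested list of class `run_config`, with attribute
#'   `"source"` recording the file path.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- config_defaults()
  bad <- character()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) { bad <- c(bad, ln); next }
    key <- trimws(sub("=.*$", "", ln))
    val <- sub("^[^=]*=", "", ln)
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || is.null(cfg[[parts[1L]]])) {
      bad <- c(bad, key); next
    }
    cfg[[parts[1L]]][[parts[2L]]] <- parse_config_value(val)
  }
  if (length(bad))
    stop("invalid config entries: ", paste(bad, collapse = "; "),
         call. = FALSE)
  cfg <- validate_config(cfg)
  attr(cfg, "source") <- normalizePath(path)
  cfg
}

validate_config <- function(cfg) {
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  m <- cfg$model
  chk(is.numeric(m$n) && length(m$n) == 1 && m$n >= 2 && m$n == round(m$n),
      "model.n must be an integer >= 2")
  chk(is.numeric(m$delta_mu) && m$delta_mu > 0, "model.delta_mu must be > 0")
  chk(is.numeric(m$sigma) && m$sigma > 0, "model.sigma must be > 0")
  b <- cfg$boundary
  chk(b$family %in% c("flat", "curve", "power", "oscil"),
      "boundary.family must be one of flat/curve/power/oscil")
  if (!is.na(b$theta))
    chk(is.numeric(b$theta) && b$theta > 0 && b$theta < 1,
        "boundary.theta must be in (0, 1)")
  co <- cfg$costs
  chk(is.numeric(co$W) && co$W > 0, "costs.W must be > 0")
  chk(is.numeric(co$cost_ratios) && all(co$cost_ratios >= 0),
      "costs.cost_ratios must be nonnegative")
  mc <- cfg$mc
  chk(is.numeric(mc$n_trials) && mc$n_trials >= 1,
      "mc.n_trials must be >= 1")
  chk(is.numeric(mc$max_steps) && mc$max_steps >= 1,
      "mc.max_steps must be >= 1")
  an <- cfg$analysis
  chk(is.numeric(an$delta) && an$delta >= 0, "analysis.delta must be >= 0")
  chk(an$sigma_mode %in% c("per_trial", "sem"),
      "analysis.sigma_mode must be per_trial or sem")
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  cfg$model$n <- as.integer(cfg$model$n)
  cfg$mc$n_trials <- as.integer(cfg$mc$n_trials)
  cfg$mc$max_steps <- as.integer(cfg$mc$max_steps)
  cfg$mc$master_seed <- as.integer(cfg$mc$master_seed)
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' Writes the flat `key = value` representation; `load_config()` of the
#' result is semantically identical to the input.
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config") || is.list(cfg))
  lines <- character()
  for (blk in names(config_defaults())) {
    for (key in names(cfg[[blk]])) {
      v <- cfg[[blk]][[key]]
      if (is.null(v) || (length(v) == 1L && is.na(v) && !is.character(v)))
        next
      lines <- c(lines, sprintf("%s.%s = %s", blk, key,
                                paste(format(v, digits = 15), collapse = ", ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
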