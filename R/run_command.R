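#' Run a pipeline subcommand
#'
#' Programmatic entry point behind the `nafc` command-line script. Each
#' subcommand reads everything it needs from the validated config, writes
#' CSV outputs plus a JSON manifest (config, master seed, package version,
#' config hash) into `out_dir`, and returns its results invisibly. Identical
#' config and seed give bitwise-identical tables.
#'
#' Subcommands:
#' \describe{
#'   \item{simulate}{trial batch at the fixed boundary -> `outcomes.csv`}
#'   \item{landscape}{reward landscape per cost ratio -> `landscape.csv`}
#'   \item{accept}{landscape + delta-acceptance sets -> `landscape.csv`,
#'     `acceptance.csv`}
#'   \item{sat}{SAT points and mean SAT curve over cost ratios ->
#'     `sat_points.csv`, `mean_sat_curve.csv`}
#'   \item{implicit}{implicit threshold series + category ->
#'     `implicit.csv`, `implicit_summary.json`}
#'   \item{hicks}{mean decision time vs number of choices + log-linear fit
#'     -> `hicks.csv`, `hicks_fit.json`}
#'   \item{analytics}{closed-form normalization identities for the
#'     configured boundary/model -> `analytics.json`}
#' }
#'
#' @param subcommand One of `simulate`, `landscape`, `accept`, `sat`,
#'   `implicit`, `hicks`, `analytics`.
#' @param config A `run_config` from [load_config()], or a path to one.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional master-seed override.
#' @param trials Optional trials-per-batch/cell override.
#' @return The subcommand's main result, invisibly.
#' @export
run_command <- function(subcommand, config, out_dir, seed = NULL,
                        trials = NULL) {
  subs <- c("simulate", "landscape", "accept", "sat", "implicit", "hicks",
            "analytics")
  if (!is.character(subcommand) || length(subcommand) != 1L ||
      !subcommand %in% subs)
    stop("unknown subcommand; use one of: ", paste(subs, collapse = ", "),
         call. = FALSE)
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) config$mc$master_seed <- as.integer(seed)
  if (!is.null(trials)) config$mc$n_trials <- as.integer(trials)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  model <- hypothesis_model(config$model$n, config$model$delta_mu,
                            config$model$sigma)
  ms <- config$mc$master_seed

  write_tab <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }

  boundary_or_stop <- function() {
    b <- config$boundary
    if (is.na(b$theta))
      stop("subcommand `", subcommand, "` needs boundary.theta in the config",
           call. = FALSE)
    boundary_spec(b$family, theta = b$theta, alpha = b$alpha, beta = b$beta)
  }
  axes_from_config <- function() {
    b <- config$boundary
    ax <- default_axes(model$n, b$family)
    if (!is.null(b$theta_axis)) ax$theta <- b$theta_axis
    if (!is.null(b$alpha_axis)) ax$alpha <- b$alpha_axis
    if (!is.null(b$beta_axis)) ax$beta <- b$beta_axis
    ax
  }
  sweep_all <- function() {
    crs <- config$costs$cost_ratios
    ax <- axes_from_config()
    n_cells <- length(ax$theta) * length(ax$alpha) * length(ax$beta)
    grids <- vector("list", length(crs))
    for (i in seq_along(crs)) {
      message(sprintf("landscape: c/W = %g (%d cells x %d trials)",
                      crs[i], n_cells, config$mc$n_trials))
      grids[[i]] <- sweep_landscape(
        model, config$boundary$family, cost_ratio = crs[i], axes = ax,
        n_trials = config$mc$n_trials, seed = ms, W = config$costs$W,
        max_steps = config$mc$max_steps,
        stream_offset = (i - 1L) * (n_cells + 1L))
    }
    grids
  }

  result <- switch(subcommand,
    simulate = {
      spec <- boundary_or_stop()
      costs <- cost_spec(c = config$costs$cost_ratios[1L] * config$costs$W,
                         W = config$costs$W)
      out <- run_trials(model, spec, costs, n_trials = config$mc$n_trials,
                        seed = ms, max_steps = config$mc$max_steps)
      message(sprintf("simulate: %d trials, %d unterminated",
                      nrow(out), sum(!out$terminated)))
      write_tab(out, "outcomes.csv")
      out
    },
    landscape = {
      grids <- sweep_all()
      tab <- do.call(rbind, lapply(grids, as.data.frame))
      write_tab(tab, "landscape.csv")
      grids
    },
    accept = {
      grids <- sweep_all()
      tab <- do.call(rbind, lapply(grids, as.data.frame))
      write_tab(tab, "landscape.csv")
      accs <- lapply(grids, acceptance_region, delta = config$analysis$delta,
                     sigma_mode = config$analysis$sigma_mode)
      for (a in accs)
        message(sprintf("accept: c/W = %g -> %d of %d cells",
                        a$cost_ratio[1L], nrow(a),
                        nrow(grids[[1L]])))
      write_tab(do.call(rbind, lapply(accs, as.data.frame)),
                "acceptance.csv")
      accs
    },
    sat = {
      grids <- sweep_all()
      accs <- lapply(grids, acceptance_region, delta = config$analysis$delta,
                     sigma_mode = config$analysis$sigma_mode)
      pts <- sat_points(accs)
      write_tab(pts, "sat_points.csv")
      curve <- mean_sat_curve(pts)
      write_tab(curve, "mean_sat_curve.csv")
      list(points = pts, curve = curve)
    },
    implicit = {
      spec <- boundary_or_stop()
      costs <- cost_spec(c = config$costs$cost_ratios[1L] * config$costs$W,
                         W = config$costs$W)
      out <- run_trials(model, spec, costs, n_trials = config$mc$n_trials,
                        seed = ms, max_steps = config$mc$max_steps)
      its <- implicit_threshold(out, min_count = config$analysis$min_count,
                                classifier_z = config$analysis$classifier_z,
                                drift_tol = config$analysis$drift_tol)
      message(sprintf("implicit: %d time points, category %s",
                      nrow(its$series), its$category))
      write_tab(its$series, "implicit.csv")
      jsonlite::write_json(
        list(category = its$category, n_time_points = nrow(its$series),
             boundary = as.data.frame(spec)),
        file.path(out_dir, "implicit_summary.json"),
        auto_unbox = TRUE, digits = NA)
      its
    },
    hicks = {
      spec <- boundary_or_stop()
      costs <- cost_spec(c = config$costs$cost_ratios[1L] * config$costs$W,
                         W = config$costs$W)
      ns <- as.integer(config$analysis$hicks_n)
      rows <- lapply(seq_along(ns), function(i) {
        mi <- hypothesis_model(ns[i], config$model$delta_mu,
                               config$model$sigma)
        est <- estimate_reward(mi, spec, costs,
                               n_trials = config$mc$n_trials, seed = ms,
                               max_steps = config$mc$max_steps,
                               stream = i * 1000L)
        data.frame(n = ns[i], mean_T = est$mean_T,
                   mean_error = est$mean_error)
      })
      tab <- do.call(rbind, rows)
      write_tab(tab, "hicks.csv")
      fit <- hicks_law_fit(tab)
      message(sprintf("hicks: a = %.3f, b = %.3f, R^2 = %.4f",
                      fit$a, fit$b, fit$r_squared))
      jsonlite::write_json(unclass(fit), file.path(out_dir, "hicks_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      fit
    },
    analytics = {
      n <- model$n
      res <- list(
        offset_decrease = offset_decrease(n),
        triplet_count = if (n >= 3) nrow(triplet_subspaces(n)) else 0L,
        example = {
          rn <- renormalize_added_option(0.6, 0.4, 0.5)
          list(renormalized = rn,
               belief_gap = belief_gap(0.6, 0.4, 0.5),
               iia = iia_distances(0.6, 0.5,
                                   if (is.na(config$boundary$theta)) 0.8
                                   else config$boundary$theta))
        })
      jsonlite::write_json(res, file.path(out_dir, "analytics.json"),
                           auto_unbox = TRUE, digits = NA)
      res
    })

  write_manifest(config, out_dir, subcommand)
  invisible(result)
}

write_manifest <- function(config, out_dir, subcommand) {
  tmp <- tempfile()
  save_config(config, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(
    subcommand = subcommand,
    master_seed = config$mc$master_seed,
    config = unclass(config),
    config_md5 = hash,
    package_version = as.character(utils::packageVersion("nafc")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
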