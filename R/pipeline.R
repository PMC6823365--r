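#' Run configuration
#'
#' Validates a configuration list against the known keys of the three
#' pipelines, fills defaults and echoes every defaulted parameter into the
#' run manifest. Unknown keys are rejected.
#'
#' @param config named list (or path to a JSON file).
#' @param pipeline one of `"groove"`, `"structure"`, `"assay"`.
#' @return validated config list of class `run_config` with attribute
#'   `defaulted` (names of parameters not supplied by the user).
#' @export
run_config <- function(config, pipeline = c("groove", "structure", "assay")) {
  pipeline <- match.arg(pipeline)
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- switch(pipeline,
    groove = list(trajectory = NULL, chain = "A", tau = 50, k = 8,
                  seed = 1, bins = 80, hydration = TRUE, lipids = TRUE,
                  out_dir = "."),
    structure = list(structure = NULL, pqr = NULL, chain = "A",
                     step = 0.25, seed = 1, z_range = NULL,
                     grid_spacing = 0.8, padding = 15,
                     membrane = TRUE, membrane_center_z = 0,
                     ionic_strength_mM = 150, out_dir = "."),
    assay = list(traces = NULL, L_i_PF = 0.5, gamma = NULL,
                 bounds = list(f0 = c(0, 1), alpha = c(1e-6, 10),
                               beta = c(1e-6, 10)),
                 n_starts = 8, seed = 1, reference_condition = NULL,
                 out_dir = "."))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  defaulted <- setdiff(names(defaults), names(config))
  out <- utils::modifyList(defaults, config)
  attr(out, "defaulted") <- defaulted
  attr(out, "pipeline") <- pipeline
  class(out) <- "run_config"
  out
}

# in-memory inputs (trajectories, structures, traces) are summarized, not
# serialized, in the manifest snapshot
.manifest_safe <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.atomic(x) && length(x) <= 32) return(x)
  if (is.list(x) && !is.object(x)) return(lapply(x, .manifest_safe))
  sprintf("<in-memory: %s>", paste(class(x), collapse = "/"))
}

.run_manifest <- function(config, inputs = character(0)) {
  list(config = lapply(unclass(config), .manifest_safe),
       defaulted = attr(config, "defaulted"),
       input_checksums = if (length(inputs)) as.list(tools::md5sum(inputs))
                         else list(),
       package_version = as.character(utils::packageVersion("grooveflow")),
       seed = config$seed, timestamp = format(Sys.time(), tz = "UTC"))
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

#' Trajectory-to-landscape pipeline
#'
#' Feature extraction, tICA, microstate clustering and the density
#' landscape, end to end, writing all intermediate artifacts to
#' `config$out_dir`. Per-protomer feature series are kept as separate
#' trajectories for the covariance estimates.
#'
#' @param config a [run_config()] for `pipeline = "groove"`, or a list; the
#'   `trajectory` entry may be a `gf_trajectory`, a list of feature
#'   matrices, or a path.
#' @return list with `features`, `tica`, `projection`, `microstates`,
#'   `landscape`, `manifest` (invisibly written as files too).
#' @export
run_groove_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config, "groove")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  traj <- config$trajectory
  stage <- "features"
  result <- tryCatch({
    series <- if (inherits(traj, "gf_trajectory")) {
      feats <- trajectory_features(traj, chain = config$chain,
                                   hydration = config$hydration,
                                   lipids = config$lipids)
      utils::write.csv(feats, file.path(config$out_dir, "features.csv"),
                       row.names = FALSE)
      list(as.matrix(feats[, c("d_T333_Y439", "d_Y439_R432", "d_E313_R432",
                               "d_E318_R432", "d_V337_V447_CA")]))
    } else if (is.character(traj)) {
      tr <- read_trajectory(traj)
      feats <- trajectory_features(tr, chain = config$chain,
                                   hydration = config$hydration,
                                   lipids = config$lipids)
      utils::write.csv(feats, file.path(config$out_dir, "features.csv"),
                       row.names = FALSE)
      list(as.matrix(feats[, 2:6]))
    } else if (is.list(traj) || is.matrix(traj)) {
      if (is.matrix(traj)) list(traj) else traj
    } else {
      stop("config$trajectory must be a trajectory, matrix list, or path")
    }
    stage <- "tica"
    n_min <- min(vapply(series, nrow, 1L))
    if (n_min <= config$tau) {
      stop(sprintf("trajectory too short for tICA: %d frames <= tau = %d",
                   n_min, config$tau))
    }
    model <- fit_tica(series, tau = config$tau)
    jsonlite::write_json(
      list(mean = model$mean, tau = model$tau,
           eigenvalues = model$eigenvalues,
           eigenvectors = as.numeric(t(model$eigenvectors)),  # row-major
           d = length(model$mean), n_samples = model$n_samples),
      file.path(config$out_dir, "tica_model.json"), auto_unbox = TRUE,
      digits = NA)
    stage <- "projection"
    proj <- project_tica(model, series)
    utils::write.csv(as.data.frame(proj),
                     file.path(config$out_dir, "tica_projection.csv"),
                     row.names = FALSE)
    stage <- "microstates"
    ms <- cluster_microstates(proj, k = config$k, seed = config$seed)
    utils::write.csv(data.frame(frame = seq_len(nrow(proj)),
                                microstate = ms$assignments),
                     file.path(config$out_dir, "microstates.csv"),
                     row.names = FALSE)
    stage <- "landscape"
    land <- density_landscape(proj, bins = config$bins)
    utils::write.csv(
      data.frame(x = rep(land$x, length(land$y)),
                 y = rep(land$y, each = length(land$x)),
                 p = as.numeric(land$p),
                 neglogp = as.numeric(land$neglogp)),
      file.path(config$out_dir, "landscape.csv"), row.names = FALSE)
    list(features = if (exists("feats", inherits = FALSE)) feats else NULL,
         series = series, tica = model, projection = proj,
         microstates = ms, landscape = land)
  }, error = function(e) {
    stop(sprintf("groove pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  manifest <- .run_manifest(config,
                            if (is.character(traj)) traj else character(0))
  .write_manifest(manifest, config$out_dir)
  result$manifest <- manifest
  invisible(result)
}

#' Structure-to-electrostatics pipeline
#'
#' Pore-radius profile, constriction minimum, and (when a charge-annotated
#' PQR is supplied) the membrane-slab LPBE potential and its profile along
#' the pore axis, with CSV/OpenDX exports.
#'
#' @param config a [run_config()] for `pipeline = "structure"`; `structure`
#'   (and `pqr`) may be `gf_structure` objects or paths.
#' @return list with `profile`, `minimum`, and optionally `grid`,
#'   `ep_profile`; plus `manifest`.
#' @export
run_structure_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config, "structure")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- config$structure
  if (is.character(st)) st <- read_structure(st)
  stage <- "pore"
  result <- tryCatch({
    prof <- profile_pore(st, step = config$step, seed = config$seed,
                         z_range = config$z_range, chain = config$chain)
    utils::write.csv(prof$samples,
                     file.path(config$out_dir, "pore_profile.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(prof$landmarks),
                         file.path(config$out_dir, "landmarks.json"),
                         auto_unbox = TRUE, digits = NA)
    mn <- min_pore(prof)
    out <- list(profile = prof, minimum = mn)
    pq <- config$pqr
    if (!is.null(pq)) {
      stage <- "electrostatics"
      if (is.character(pq)) pq <- read_structure(pq, format = "pqr")
      spec <- membrane_dielectric_spec(
        membrane = config$membrane,
        membrane_center_z = config$membrane_center_z,
        ionic_strength_mM = config$ionic_strength_mM)
      grid <- build_maps(pq, spec, spacing = config$grid_spacing,
                         padding = config$padding)
      grid <- solve_lpbe(grid)
      write_opendx(grid, file.path(config$out_dir, "potential.dx"))
      epp <- ep_profile(grid, prof)
      utils::write.csv(epp, file.path(config$out_dir, "ep_profile.csv"),
                       row.names = FALSE)
      out$grid <- grid
      out$ep_profile <- epp
    }
    out
  }, error = function(e) {
    stop(sprintf("structure pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  inputs <- c(if (is.character(config$structure)) config$structure,
              if (is.character(config$pqr)) config$pqr)
  manifest <- .run_manifest(config, inputs)
  .write_manifest(manifest, config$out_dir)
  result$manifest <- manifest
  invisible(result)
}

#' Assay-fitting pipeline
#'
#' Fits every trace, writes a per-trace JSON and a summary CSV, computes
#' fold changes against a named reference condition when present, and a QC
#' report flagging batches whose control falls outside 3 SD of the
#' reference mean (reported, never silently removed).
#'
#' @param config a [run_config()] for `pipeline = "assay"`; `traces` is a
#'   named list of `gf_trace` objects or CSV paths, `gamma` is required.
#' @return list with `fits` (data.frame), `fold_changes`, `qc`, `manifest`.
#' @export
run_assay_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config, "assay")
  if (is.null(config$gamma)) stop("config$gamma is required (fixed by experiment)")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  traces <- config$traces
  nm <- names(traces)
  if (is.null(nm)) nm <- sprintf("trace%02d", seq_along(traces))
  rows <- list()
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    if (is.character(tr)) tr <- read_trace(tr)
    fit <- withCallingHandlers(
      fit_scrambling(tr, L_i_PF = config$L_i_PF, gamma = config$gamma,
                     bounds = config$bounds, n_starts = config$n_starts,
                     seed = config$seed + i),
      warning = function(w) invokeRestart("muffleWarning"))
    slow <- max(tr$times) < 5 / config$gamma
    jsonlite::write_json(
      list(trace = nm[i], estimates = as.list(fit$estimates),
           fixed = as.list(fit$fixed), sse = fit$sse,
           converged = fit$converged,
           identifiability_warning = fit$identifiability_warning,
           slow_fit_warning = slow),
      file.path(config$out_dir, sprintf("fit_%s.json", nm[i])),
      auto_unbox = TRUE, digits = NA)
    rows[[i]] <- data.frame(trace = nm[i], f0 = fit$estimates[["f0"]],
                            alpha = fit$estimates[["alpha"]],
                            beta = fit$estimates[["beta"]], sse = fit$sse,
                            converged = fit$converged,
                            identifiability_warning = fit$identifiability_warning,
                            slow_fit_warning = slow,
                            stringsAsFactors = FALSE)
  }
  fits <- do.call(rbind, rows)
  utils::write.csv(fits, file.path(config$out_dir, "fit_summary.csv"),
                   row.names = FALSE)
  fold <- NULL
  ref <- config$reference_condition
  if (!is.null(ref)) {
    if (!ref %in% fits$trace) {
      .gf_log("reference condition '%s' missing: fold-change table omitted", ref)
    } else {
      aw <- fits$alpha[fits$trace == ref]
      bw <- fits$beta[fits$trace == ref]
      fold <- do.call(rbind, lapply(seq_len(nrow(fits)), function(i) {
        data.frame(trace = fits$trace[i],
                   fold_alpha = fold_change(fits$alpha[i], aw)$fold,
                   band_alpha = fold_change(fits$alpha[i], aw)$band,
                   fold_beta = fold_change(fits$beta[i], bw)$fold,
                   stringsAsFactors = FALSE)
      }))
      utils::write.csv(fold, file.path(config$out_dir, "fold_changes.csv"),
                       row.names = FALSE)
    }
  }
  # QC: controls outside 3 SD of the mean of reference-condition fits
  qc <- NULL
  if (!is.null(ref) && sum(fits$trace == ref) >= 2) {
    rf <- fits[fits$trace == ref, ]
    mu <- mean(rf$alpha); sdv <- stats::sd(rf$alpha)
    qc <- data.frame(trace = rf$trace,
                     outlier = abs(rf$alpha - mu) > 3 * sdv)
  }
  manifest <- .run_manifest(config,
                            unlist(Filter(is.character, traces)))
  .write_manifest(manifest, config$out_dir)
  invisible(list(fits = fits, fold_changes = fold, qc = qc,
                 manifest = manifest))
}
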