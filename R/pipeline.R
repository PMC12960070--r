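# End-to-end pipeline: scan -> populations -> pca, with a reproducible run
# manifest. JSON is the inter-stage format: volumes are small and diffable
# outputs beat opaque binaries for auditability.

#' Build a pipeline configuration
#'
#' @param traj Path to the trajectory (GRO/PDB/extended-XYZ).
#' @param roles Path to the role map (optional for extended XYZ).
#' @param out_dir Output directory (created if missing).
#' @param delta,contact_threshold,semiaxis_floor,n_max Shell parameters,
#'   see [shell_spec()].
#' @param stride Analyse every `stride`-th frame.
#' @param s_max Largest reported cluster class (default 4).
#' @param n_blocks Blocks for the maximum-error estimate (default 5).
#' @param order,seed Reference-ion ordering, see [partition_frame()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(traj, roles = NULL, out_dir = "ionclust-out",
                       delta = 0.4, contact_threshold = 0.3,
                       semiaxis_floor = 0.1, n_max = NULL, stride = 1L,
                       s_max = 4L, n_blocks = 5L, order = "index",
                       seed = NULL) {
  structure(list(
    traj = traj, roles = roles, out_dir = out_dir,
    spec = shell_spec(delta = delta, contact_threshold = contact_threshold,
                      semiaxis_floor = semiaxis_floor, n_max = n_max),
    stride = as.integer(stride), s_max = as.integer(s_max),
    n_blocks = as.integer(n_blocks), order = order, seed = seed),
    class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the [run_config()] arguments (`traj`, `roles`, `out_dir`,
#' `delta_nm`, `contact_threshold_nm`, `semiaxis_floor_nm`, `n_max`,
#' `stride`, `s_max`, `n_blocks`, `order`, `seed`).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  run_config(
    traj = cfg$traj, roles = cfg$roles,
    out_dir = cfg$out_dir %||% "ionclust-out",
    delta = cfg$delta_nm %||% 0.4,
    contact_threshold = cfg$contact_threshold_nm %||% 0.3,
    semiaxis_floor = cfg$semiaxis_floor_nm %||% 0.1,
    n_max = cfg$n_max, stride = cfg$stride %||% 1L,
    s_max = cfg$s_max %||% 4L, n_blocks = cfg$n_blocks %||% 5L,
    order = cfg$order %||% "index", seed = cfg$seed)
}

write_stage_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full cluster-analysis pipeline
#'
#' Stages: read frames; partition every analysed frame into clusters; build
#' the state-vector series; time-average it with maximum-error bars; PCA of
#' the population fluctuations. Each stage's result is written as JSON (and
#' the summary additionally as CSV) under `config$out_dir`, together with a
#' `manifest.json` recording the configuration, seeds and package versions.
#' Outputs are deterministic under a fixed seed; no timestamps are written.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results
#'   (`partitions`, `series`, `summary`, `pca`) and the `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  if (!file.exists(config$traj)) {
    stop("stage read_frames: trajectory not found: ", config$traj,
         call. = FALSE)
  }
  if (!is.null(config$roles) && !file.exists(config$roles)) {
    stop("stage read_frames: role map not found: ", config$roles,
         call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  say("reading frames from ", config$traj)
  frames <- read_frames(config$traj, roles = config$roles)
  say("  ", length(frames), " frame(s), ",
      length(ion_molecules(frames[[1]])), " ions")

  say("partitioning frames (stride ", config$stride, ")")
  partitions <- tryCatch(
    partition_trajectory(frames, spec = config$spec, order = config$order,
                         seed = config$seed, stride = config$stride),
    error = function(e) stop("stage partition: ", conditionMessage(e),
                             call. = FALSE))

  series <- state_vector_series(partitions, s_max = config$s_max)
  summary <- summarize_populations(series, n_blocks = config$n_blocks)
  pca <- pop_pca(series, s_max = config$s_max)
  report <- mode_report(pca, k = min(2L, config$s_max))

  sizes <- cluster_sizes(partitions)
  part_json <- lapply(split(sizes, sizes$frame), function(fr) {
    members <- split(partitions$molecule_id[partitions$frame == fr$frame[1]],
                     partitions$cluster[partitions$frame == fr$frame[1]])
    list(frame = fr$frame[1],
         clusters = unname(Map(function(s, nc, na, m) {
           list(size = s, n_cations = nc, n_anions = na, members = m)
         }, fr$size, fr$n_cations, fr$n_anions, members[as.character(fr$cluster)])))
  })

  files <- c(
    partitions = write_stage_json(unname(part_json),
                                  file.path(config$out_dir, "partitions.json")),
    populations = write_stage_json(tibble::as_tibble(series),
                                   file.path(config$out_dir, "populations.json")),
    summary = write_stage_json(tibble::as_tibble(summary),
                               file.path(config$out_dir, "summary.json")),
    pca = write_stage_json(list(
      covariance = unclass(pca$covariance),
      eigenvalues = pca$eigenvalues,
      eigenvectors = unclass(pca$eigenvectors),
      variance_fractions = pca$variance_fractions,
      cumulative_variance_2 = report$cumulative_variance,
      modes = tibble::as_tibble(report$loadings)),
      file.path(config$out_dir, "pca.json")))
  readr::write_csv(tibble::as_tibble(summary),
                   file.path(config$out_dir, "summary.csv"), progress = FALSE)

  manifest <- list(
    config = list(
      traj = config$traj, roles = config$roles, out_dir = config$out_dir,
      delta_nm = config$spec$delta,
      contact_threshold_nm = config$spec$contact_threshold,
      semiaxis_floor_nm = config$spec$semiaxis_floor,
      n_max = config$spec$n_max, stride = config$stride,
      s_max = config$s_max, n_blocks = config$n_blocks,
      order = config$order, seed = config$seed),
    n_frames_analysed = length(unique(partitions$frame)),
    n_ions = attr(partitions, "n_ions"),
    outputs = as.list(files),
    versions = list(
      ionclust = as.character(utils::packageVersion("ionclust")),
      R = paste(R.version$major, R.version$minor, sep = ".")))
  write_stage_json(manifest, file.path(config$out_dir, "manifest.json"))
  say("wrote ", length(files) + 2, " file(s) to ", config$out_dir)

  invisible(list(partitions = partitions, series = series, summary = summary,
                 pca = pca, manifest = manifest))
}
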