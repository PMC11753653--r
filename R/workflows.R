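#' Config-driven workflow runners
#'
#' The four runners tie the package's stages into the two end-to-end
#' workflows — PLS modeling/validation of a PEF sample table, and
#' membrane-frame analytics — with file inputs and outputs. Each accepts a
#' config as a named list or a YAML/JSON file path, rejects unknown keys,
#' and writes the resolved config (seed included) beside its outputs so
#' every run is reproducible from its output directory alone.
#'
#' @name workflows
NULL

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a named list or a file path",
                             call. = FALSE)
  config
}

.check_config <- function(config, allowed, required) {
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys)) {
    stop("missing config key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  config
}

.write_resolved <- function(config, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(c(list(package_version =
                                as.character(utils::packageVersion("pefpore"))),
                         config),
                       file.path(output_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' @describeIn workflows Fit the autoscaled PLS model on a sample CSV and
#'   write the model JSON, per-sample predictions CSV and fit-statistics
#'   JSON. Config keys: `samples` (CSV path), `output_dir`,
#'   `n_components` (default 1).
#' @param config Named list or YAML/JSON path (see each runner for keys).
#' @return Invisibly, the output directory.
#' @export
run_pls <- function(config) {
  config <- .check_config(.load_config(config),
                          allowed = c("samples", "output_dir", "n_components"),
                          required = c("samples", "output_dir"))
  n_components <- config$n_components %||% 1L
  table <- read_sample_table(config$samples)
  model <- pls_fit(table, n_components = n_components)
  stats_out <- fit_stats(model, table)
  out <- config$output_dir
  config$n_components <- n_components
  .write_resolved(config, out)
  pls_to_json(model, file.path(out, "pls_model.json"))
  pred <- table
  pred$predicted_fusion_rate <- predict(model, table)
  utils::write.csv(pred, file.path(out, "predictions.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(stats_out, file.path(out, "fit_stats.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn workflows Run repeated-split and Y-permutation validation on
#'   a sample CSV; writes per-repeat and per-permutation CSVs and a summary
#'   JSON. Config keys: `samples`, `output_dir`, `seed`, `n_repeats`
#'   (default 500), `n_perm` (default 500), `train_fraction` (default 2/3),
#'   `n_components` (default 1).
#' @export
run_validate <- function(config) {
  config <- .check_config(.load_config(config),
                          allowed = c("samples", "output_dir", "seed",
                                      "n_repeats", "n_perm", "train_fraction",
                                      "n_components"),
                          required = c("samples", "output_dir", "seed"))
  n_repeats <- config$n_repeats %||% 500L
  n_perm <- config$n_perm %||% 500L
  train_fraction <- config$train_fraction %||% (2 / 3)
  n_components <- config$n_components %||% 1L
  if (n_repeats < 1L) stop("n_repeats must be >= 1", call. = FALSE)
  table <- read_sample_table(config$samples)
  rs <- repeated_split_validation(table, n_repeats = n_repeats,
                                  train_fraction = train_fraction,
                                  seed = config$seed,
                                  n_components = n_components)
  train <- if (any(table$role == "train"))
    table[table$role == "train", , drop = FALSE] else table
  yp <- y_permutation_test(train, n_perm = n_perm, seed = config$seed,
                           n_components = n_components)
  out <- config$output_dir
  config[c("n_repeats", "n_perm", "train_fraction", "n_components")] <-
    list(n_repeats, n_perm, train_fraction, n_components)
  .write_resolved(config, out)
  utils::write.csv(rs$results, file.path(out, "repeated_splits.csv"),
                   row.names = FALSE)
  utils::write.csv(yp$records, file.path(out, "permutations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(repeated_splits = rs$summary,
                            n_failed_splits = rs$n_failed,
                            permutation_trend_spearman = yp$trend_spearman,
                            n_failed_permutations = yp$n_failed),
                       file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' @describeIn workflows Membrane analytics on one or more frame files:
#'   charge-density and potential profiles, transmembrane potential and a
#'   pore report per frame. Config keys: `frames` (vector of native-format
#'   frame paths), `output_dir`, `bin_width` (default 0.1), `normal_axis`
#'   (default "z"), `cell_size` (default 0.4), `min_cells` (default 2),
#'   `water_volume_per_particle` (default 0.030), `slab_fraction` (default
#'   0.5), `water_margin` (bulk-region offset from the leaflets, default 1).
#' @export
run_membrane <- function(config) {
  config <- .check_config(.load_config(config),
                          allowed = c("frames", "output_dir", "bin_width",
                                      "normal_axis", "cell_size", "min_cells",
                                      "water_volume_per_particle",
                                      "slab_fraction", "water_margin"),
                          required = c("frames", "output_dir"))
  bin_width <- config$bin_width %||% 0.1
  axis <- config$normal_axis %||% "z"
  cell_size <- config$cell_size %||% 0.4
  min_cells <- config$min_cells %||% 2L
  wvol <- config$water_volume_per_particle %||% 0.030
  slab_fraction <- config$slab_fraction %||% 0.5
  margin <- config$water_margin %||% 1
  out <- config$output_dir
  config[c("bin_width", "normal_axis", "cell_size", "min_cells",
           "water_volume_per_particle", "slab_fraction", "water_margin")] <-
    list(bin_width, axis, cell_size, min_cells, wvol, slab_fraction, margin)
  .write_resolved(config, out)
  reports <- list()
  dphi <- numeric(0)
  for (i in seq_along(config$frames)) {
    frame <- read_particle_frame(config$frames[[i]])
    tag <- sprintf("frame%03d", i)
    rho <- charge_density_profile(frame, bin_width = bin_width, axis = axis)
    phi <- potential_profile(rho)
    write_profile_csv(rho, file.path(out, paste0(tag, "_charge_density.csv")))
    write_profile_csv(phi, file.path(out, paste0(tag, "_potential.csv")))
    bounds <- leaflet_bounds(frame)
    L <- frame$box[.axis_index(axis)]
    dphi[i] <- transmembrane_potential(
      phi, c(0, max(1e-3, bounds[1] - margin)),
      c(min(L - 1e-3, bounds[2] + margin), L), leaflet_bounds = bounds)
    reports[[i]] <- count_pores(frame, bounds, cell_size = cell_size,
                                min_cells = min_cells,
                                water_volume_per_particle = wvol,
                                slab_fraction = slab_fraction)
  }
  write_pore_report_csv(reports, file.path(out, "pore_report.csv"))
  jsonlite::write_json(list(transmembrane_potential = dphi),
                       file.path(out, "transmembrane_potential.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(out)
}

#' @describeIn workflows Generate synthetic inputs: a PEF response table
#'   and/or bilayer frames. Config keys: `output_dir`, `seed`,
#'   `response` (logical, default TRUE), `n_frames` (default 0), `pores`
#'   (list of `list(center, radius)` planted in every frame).
#' @export
run_synth <- function(config) {
  config <- .check_config(.load_config(config),
                          allowed = c("output_dir", "seed", "response",
                                      "n_frames", "pores"),
                          required = c("output_dir", "seed"))
  response <- config$response %||% TRUE
  n_frames <- config$n_frames %||% 0L
  out <- config$output_dir
  config[c("response", "n_frames")] <- list(response, n_frames)
  .write_resolved(config, out)
  if (isTRUE(response)) {
    ds <- make_pef_response_dataset(pef_response_spec(seed = config$seed))
    write_sample_table(ds$table, file.path(out, "synthetic_samples.csv"))
    jsonlite::write_json(ds$ground_truth[c("pore_number",
                                           "large_pore_fraction",
                                           "yp_noiseless", "pi_noiseless",
                                           "coefficients")],
                         file.path(out, "synthetic_samples_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (n_frames > 0L) {
    pores <- lapply(config$pores %||% list(),
                    function(p) list(center = as.numeric(p$center),
                                     radius = as.numeric(p$radius)))
    for (i in seq_len(n_frames)) {
      bf <- make_bilayer_frame(bilayer_spec(pores = pores,
                                            seed = config$seed + i - 1L),
                               time = i - 1)
      write_particle_frame(bf$frame,
                           file.path(out, sprintf("frame%03d.dat", i)))
      jsonlite::write_json(bf$ground_truth,
                           file.path(out, sprintf("frame%03d_truth.json", i)),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(out)
}
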