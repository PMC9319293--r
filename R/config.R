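#' Default run configuration
#'
#' A fully serializable description of one pipeline run. A run is
#' reconstructible from this config plus its `seed`: every stage derives its
#' own seed from the global one by a fixed offset (cohort +0, forest +101,
#' single-image +201, patch CNN +301), so modules stay reproducible in
#' isolation.
#'
#' @param seed global seed.
#' @return A named list of stage parameters.
#' @export
default_run_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       cohort = list(n_malignant = 124L, n_benign = 76L,
                     image_size_px = 388L, mm_per_px = 0.09),
       contrast = list(percentiles = c(0.01, 0.99), gamma = 1),
       ring = list(r_inner = 2, r_outer = 5, patch_side = 32L),
       quantization = list(n_levels = 32L),
       forest = list(n_trees = 1000L),
       single_image = list(backbone = "small", learning_rate = 1e-4,
                           momentum = 0.9, batch_size = 32L, epochs = 40L,
                           input_size = 64L),
       patch_cnn = list(learning_rate = 0.001, batch_size = 128L,
                        epochs = 8L, dropout = 0.25, threshold = 0.63),
       ensemble = list(weights = c(0.41, 0.08, 0.51), cutoff = 0.53,
                       calibration = "train"))
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config a config list as from [default_run_config()].
#' @return `read_run_config` returns the config list (defaults filled in for
#'   missing sections); `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = if (!is.null(user$seed)) user$seed else 1L)
  for (sec in intersect(names(user), names(cfg))) {
    if (is.list(cfg[[sec]])) cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    else cfg[[sec]] <- user[[sec]]
  }
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

log_line <- function(level, module, msg, ...) {
  message(sprintf("%s %s %s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  level, module, sprintf(msg, ...)))
}
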