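# Structured pipeline configuration. Every study constant (250 Hz, 0.5-70
# Hz, 2 s windows, k = 5, 500 trees, linear kernel, band edges, block/rest
# durations) appears as an explicit default so that deviations are visible
# diffs against the resolved config echoed into each run's provenance.

#' Default pipeline configuration
#'
#' @return nested named list with sections `synthetic`, `montage`,
#'   `preprocess`, `features`, `classify`, `io`.
#' @export
default_config <- function() {
  list(
    synthetic = list(
      n_subjects = 20L, base_seed = 1L, rate_hz = 500, gain_jitter = 0.1,
      schedule = list(block_s = 40, rest_s = 60, lead_s = 5,
                      n_classes = 7L, n_repeats = 2L),
      signatures = list(effect_size = 1, gamma_gain_max = 4,
                        beta_gain_max = 2.5, asym_max = 0.1),
      noise = list(alpha = 1, background_rms_uv = 10,
                   osc_rms_uv = list(delta = 4, theta = 3, alpha = 4,
                                     beta = 2.5, gamma = 3),
                   line_hz = 50, line_amp_uv = 2, blink_rate_per_min = 12,
                   blink_amp_uv = 80, blink_duration_s = 0.4)),
    montage = "default",
    preprocess = list(target_hz = 250, lo_hz = 0.5, hi_hz = 70,
                      artifact_method = "ica", window_s = 2,
                      reject_uv = 100),
    features = list(log_base = "natural", de_pad = 250L),
    classify = list(protocol = "cv10", n_folds = 10L, seed = 1L,
                    classifiers = list(
                      bp = list(size = 64L, maxit = 500L),
                      knn = list(k = 5L),
                      rf = list(num_trees = 500L),
                      svm = list(kernel = "linear", cost = 1))),
    io = list(format = "edf"))
}

.merge_config <- function(defaults, user, path = character()) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste(paste(c(path, unknown[1]), collapse = "$"), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load and resolve a pipeline config
#'
#' Reads a YAML file, overlays it on [default_config()], and rejects
#' unknown keys. With `path = NULL` returns the fully materialized
#' defaults.
#'
#' @param path YAML file path, or NULL.
#' @return resolved config list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- .merge_config(cfg, user)
  }
  cfg
}

# construct the generator ingredients from a resolved config
.config_objects <- function(config) {
  montage <- montage_from_config(config$montage)
  nz <- config$synthetic$noise
  noise <- noise_model(
    montage, alpha = nz$alpha, background_rms_uv = nz$background_rms_uv,
    osc_rms_uv = unlist(nz$osc_rms_uv), line_hz = nz$line_hz,
    line_amp_uv = nz$line_amp_uv,
    blink_rate_per_min = nz$blink_rate_per_min,
    blink_amp_uv = nz$blink_amp_uv, blink_duration_s = nz$blink_duration_s)
  sg <- config$synthetic$signatures
  signatures <- class_signatures(
    montage, effect_size = sg$effect_size,
    gamma_gain_max = sg$gamma_gain_max, beta_gain_max = sg$beta_gain_max,
    asym_max = sg$asym_max, n_classes = config$synthetic$schedule$n_classes)
  specs <- lapply(names(config$classify$classifiers), function(k)
    do.call(classifier_spec, c(list(kind = k),
                               config$classify$classifiers[[k]])))
  names(specs) <- names(config$classify$classifiers)
  list(montage = montage, noise = noise, signatures = signatures,
       specs = specs)
}
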