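#' Default analysis configuration
#'
#' One nested list holding every module's tunable parameters. Values chosen
#' here are the package-wide defaults: FRC threshold 1/7 with 128-px blocks,
#' gap detection at 2 SD below the path mean with a 60 nm minimum gap (the
#' effective image resolution), SACD defaults (10 pre-iterations, 2x Fourier
#' upsampling, 10 post-iterations, order 2), and seed 0 for all randomized
#' operations.
#'
#' @return Nested named list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 0L,
    frc = list(
      threshold = 1 / 7,
      block_size_px = 128L,
      min_block_content = 0.2,
      window = TRUE
    ),
    gaps = list(
      k_sd = 2,
      min_gap_len_nm = 60,
      sampling_step_nm = NA_real_  # NA: use bio pixel / 2 of the image at hand
    ),
    registration = list(
      rotation_range_deg = 10,
      rotation_step_deg = 0.25,
      grid_spacing_px = 16L,
      block_half_px = 12L,
      search_px = 5L
    ),
    rms_curve = list(
      n_bins = 10L,
      n_pairs_per_bin = 1000L,
      min_length_um = 1
    ),
    sacd = list(
      n1 = 10L,
      fourier_scale = 2L,
      n2 = 10L,
      order = 2L
    )
  )
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys (at any nesting level) are rejected; missing keys fall back to
#' [default_config()] values, so a config file round-trips losslessly.
#'
#' @param path YAML file.
#' @return Full configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("I/O error: cannot read '%s'", path)
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user %||% list(), "config")
}

merge_config <- function(defaults, user, where) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stopf("unknown configuration key(s) under %s: %s", where,
          paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], paste0(where, "$", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Write an analysis configuration to YAML
#'
#' @param config Configuration list (as from [default_config()] or
#'   [read_config()]).
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 17)
  invisible(path)
}
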