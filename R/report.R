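#' Write a machine-readable report for an analysis result
#'
#' Every analysis result type is serialized as a JSON summary plus, where the
#' result carries tabular data (FRC curves, gap tables, RMS curves, depth
#' profiles), a CSV table with deterministic column ordering. Files are named
#' `<prefix>.json` / `<prefix>_<table>.csv` inside `dir`.
#'
#' @param result A result object from any memquant analysis (e.g.
#'   [detect_gaps()], [blockwise_frc()], [rms_error_curve()],
#'   [sbr_depth_profile()], [rand_score()], [estimate_expansion_factor()]), or
#'   a plain named list.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; defaults to the result's class.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(result, dir, prefix = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) stopf("I/O error: cannot create directory '%s'", dir)
  }
  prefix <- prefix %||% (class(result)[1] %||% "result")
  if (prefix == "list") prefix <- "result"
  tables <- report_tables(result)
  summary <- report_summary(result)
  files <- character(0)
  jf <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(summary, jf, auto_unbox = TRUE, digits = NA, na = "null")
  files <- c(files, jf)
  for (nm in names(tables)) {
    cf <- file.path(dir, paste0(prefix, "_", nm, ".csv"))
    utils::write.csv(tables[[nm]], cf, row.names = FALSE)
    files <- c(files, cf)
  }
  invisible(files)
}

# Tabular components per result class (named list of data.frames).
report_tables <- function(result) {
  cls <- class(result)[1]
  switch(cls,
    frc_curve = list(curve = data.frame(
      frequency_per_nm = result$frequencies,
      correlation = result$correlations,
      n_pixels = result$n_pixels_per_ring)),
    frc_result = {
      tabs <- list()
      if (!is.null(result$per_block)) {
        g <- result$per_block
        tabs$blocks <- data.frame(
          block_row = g$row, block_col = g$col,
          resolution_nm = g$resolution_nm, scored = g$scored)
      }
      tabs
    },
    gap_set = list(gaps = as.data.frame(result$gaps)),
    continuity_result = list(gaps = as.data.frame(result$gaps)),
    rms_curve = list(curve = data.frame(
      length_um = result$length_um, rms_um = result$rms_um,
      sd_um = result$sd_um, n_pairs = result$n_pairs)),
    sbr_profile = list(profile = data.frame(
      z_um = result$z_um, mean_signal = result$mean_signal, sbr = result$sbr)),
    expansion_estimate = list(ratios = data.frame(ratio = result$per_pair_ratios)),
    transverse_profile = list(profile = data.frame(
      offset_nm = result$offset_nm, intensity = result$intensity,
      normalized = result$normalized)),
    intensity_profile = list(profile = data.frame(
      arclength_nm = result$arclength_nm, intensity = result$intensity)),
    list()
  )
}

# JSON-serializable summary: drop heavy components, keep scalars/vectors.
report_summary <- function(result) {
  drop <- c("per_block_grid")
  x <- unclass(result)
  if (!is.list(x)) return(list(value = x))
  x <- x[setdiff(names(x), drop)]
  x <- lapply(x, function(v) {
    if (is.matrix(v)) return(apply(v, 1, as.numeric, simplify = FALSE))
    if (is.data.frame(v)) return(v)
    v
  })
  c(list(result_type = class(result)[1]), x)
}
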