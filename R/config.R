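#' Run configuration
#'
#' Bundles every tunable of the estimation pipeline with documented
#' defaults. A configuration can be built in code, or loaded from a plain
#' `key = value` text file with [load_config()].
#'
#' @param domain `c(lon_min, lon_max, lat_min, lat_max)` in degrees. The
#'   default is a 10 x 10 degree window straddling the 97.5 E time-zone
#'   band edge, so collocation exercises more than one clock offset.
#' @param kernel spatial kernel: `"bisquare"` (compact support, default),
#'   `"gaussian"`, or `"uniform"` (every observation weighted equally; the
#'   global-regression limit).
#' @param bandwidth_mode `"adaptive"` (bandwidth = distance to the k-th
#'   nearest calibration point) or `"fixed"` (constant `fixed_k`).
#' @param k_range integer `c(min, max)` search range for the adaptive
#'   neighbour count; the lower bound must exceed the regressor count + 1
#'   so every local fit is overdetermined.
#' @param fixed_k neighbour count used when `bandwidth_mode = "fixed"`.
#' @param folds cross-validation fold count.
#' @param seed master random seed.
#' @param rh_cap maximum admissible relative humidity, percent. The
#'   hygroscopic correction `(1 - RH/100)^-1` diverges as RH approaches
#'   100, so wetter rows are excluded rather than corrected.
#' @param fusion_precedence which algorithm wins where both retrievals are
#'   valid; only `"DT"` (finer, stricter QA) is supported.
#' @param tz_band_edges longitudes (degrees E) bounding the UTC offset
#'   bands; defaults to nominal 15-degree solar bands covering UTC+5..+9.
#' @param min_rows minimum rows for a daily GWR fit.
#' @param max_leverage prediction guard: a target point whose local
#'   design-space leverage `x' (X'WX)^-1 x` exceeds this value is
#'   predicted as missing. The default 1 marks predictions whose
#'   variance would exceed that of a single raw observation (pure
#'   extrapolation, e.g. a regressor value far outside its local
#'   range).
#' @param min_valid_days minimum valid days for a cell to enter a seasonal
#'   mean surface.
#' @param bw_sample_days number of days sampled (evenly across the period)
#'   when choosing one adaptive bandwidth per season; the median selected
#'   k is applied to every day.
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(domain = c(95, 105, 27.5, 37.5),
                       kernel = "bisquare",
                       bandwidth_mode = "adaptive",
                       k_range = c(8L, 60L),
                       fixed_k = 30L,
                       folds = 10L,
                       seed = 42L,
                       rh_cap = 95,
                       fusion_precedence = "DT",
                       tz_band_edges = seq(67.5, 142.5, by = 15),
                       min_rows = 20L,
                       max_leverage = 1,
                       min_valid_days = 5L,
                       bw_sample_days = 5L) {
  kernel <- match.arg(kernel, c("bisquare", "gaussian", "uniform"))
  bandwidth_mode <- match.arg(bandwidth_mode, c("adaptive", "fixed"))
  if (fusion_precedence != "DT") {
    stop("unsupported fusion precedence: ", fusion_precedence,
         call. = FALSE)
  }
  if (rh_cap <= 0 || rh_cap >= 100) {
    stop("rh_cap must lie in (0, 100)", call. = FALSE)
  }
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  k_range <- as.integer(k_range)
  if (k_range[1] < 8L) {
    stop("k_range minimum must be >= 8 (regressors + 2) so local fits ",
         "are overdetermined under compact-support kernels", call. = FALSE)
  }
  structure(
    list(domain = as.numeric(domain), kernel = kernel,
         bandwidth_mode = bandwidth_mode, k_range = k_range,
         fixed_k = as.integer(fixed_k), folds = as.integer(folds),
         seed = as.integer(seed), rh_cap = as.numeric(rh_cap),
         fusion_precedence = fusion_precedence,
         tz_band_edges = as.numeric(tz_band_edges),
         min_rows = as.integer(min_rows),
         max_leverage = as.numeric(max_leverage),
         min_valid_days = as.integer(min_valid_days),
         bw_sample_days = as.integer(bw_sample_days)),
    class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-18s %s\n", k, paste(format(x[[k]]), collapse = " ")))
  }
  invisible(x)
}

## keys whose values are numeric vectors in key = value files
.vector_keys <- c("domain", "k_range", "tz_band_edges")

#' Load a run configuration from a key = value file
#'
#' The file format is one `key = value` pair per line; blank lines and
#' `#` comments are ignored. Vector values are whitespace-separated.
#' Absent keys take their [run_config()] defaults; `overrides` (a named
#' list) wins over both. Unknown keys and out-of-range values are errors.
#' The effective configuration is echoed via `message()` so runs are
#' self-documenting.
#'
#' @param path config file path, or `NULL` for defaults only.
#' @param overrides named list applied after the file.
#' @param quiet suppress the configuration echo.
#' @return a [run_config()].
#' @export
load_config <- function(path = NULL, overrides = list(), quiet = FALSE) {
  kv <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(parts) != 2) {
        stop("malformed config line: '", ln, "'", call. = FALSE)
      }
      kv[[trimws(parts[1])]] <- trimws(parts[2])
    }
  }
  defaults <- formals(run_config)
  known <- names(defaults)
  unknown <- setdiff(names(kv), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; known keys: ", paste(known, collapse = ", "), call. = FALSE)
  }
  args <- list()
  for (k in names(kv)) {
    v <- kv[[k]]
    args[[k]] <- if (k %in% c("kernel", "bandwidth_mode",
                              "fusion_precedence")) {
      v
    } else {
      as.numeric(strsplit(v, "\\s+")[[1]])
    }
  }
  unknown_ov <- setdiff(names(overrides), known)
  if (length(unknown_ov)) {
    stop("unknown override key(s): ", paste(unknown_ov, collapse = ", "),
         call. = FALSE)
  }
  args[names(overrides)] <- overrides
  cfg <- do.call(run_config, args)
  if (!quiet) {
    message("effective run configuration:")
    for (k in names(cfg)) {
      message(sprintf("  %-18s %s", k,
                      paste(format(cfg[[k]]), collapse = " ")))
    }
  }
  cfg
}
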