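#' Construct a current sweep
#'
#' A `sweep_trace` is a uniformly sampled whole-cell current recording:
#' time in ms, current in pA with inward current negative, plus named
#' event markers (stimulus time, sucrose application start/stop, light
#' on/off, all in ms).
#'
#' @param time_ms numeric vector, uniform time grid in ms.
#' @param current_pA numeric vector of currents (pA, inward negative),
#'   same length as `time_ms`.
#' @param fs_khz sampling rate in kHz; must match the time grid.
#' @param markers named list of event times in ms (e.g. `t0_ms`,
#'   `app_start_ms`, `light_on_ms`). All must lie within the record.
#' @param ground_truth optional list of generator parameters carried
#'   alongside simulated sweeps.
#'
#' @return An object of class `sweep_trace`: a list with elements
#'   `time_ms`, `current_pA`, `fs_khz`, `markers`, `ground_truth`.
#' @examples
#' tr <- sweep_trace(seq(0, 10, by = 0.1), rnorm(101), fs_khz = 10)
#' print(tr)
#' @export
sweep_trace <- function(time_ms, current_pA, fs_khz,
                        markers = list(), ground_truth = NULL) {
  .assert(length(time_ms) == length(current_pA),
          "time and current must have equal length")
  .assert(.is_number(fs_khz) && fs_khz > 0, "fs_khz must be a positive number")
  if (length(time_ms) > 1) {
    dt <- diff(time_ms)
    .assert(max(abs(dt - 1 / fs_khz)) < 1e-6 / fs_khz,
            "time grid is not uniform at fs = %g kHz", fs_khz)
  }
  for (nm in names(markers)) {
    m <- markers[[nm]]
    .assert(all(m >= time_ms[1] & m <= time_ms[length(time_ms)]),
            "marker '%s' lies outside the record", nm)
  }
  structure(list(time_ms = as.numeric(time_ms),
                 current_pA = as.numeric(current_pA),
                 fs_khz = fs_khz,
                 markers = markers,
                 ground_truth = ground_truth),
            class = "sweep_trace")
}

#' @export
print.sweep_trace <- function(x, ...) {
  cat(sprintf("sweep_trace: %d samples, %.3g s at %g kHz\n",
              length(x$time_ms), diff(range(x$time_ms)) / 1000, x$fs_khz))
  if (length(x$markers))
    cat("  markers:", paste(sprintf("%s=%g", names(x$markers),
                                    vapply(x$markers, `[`, 0, 1)),
                            collapse = ", "), "\n")
  if (!is.null(x$ground_truth)) cat("  carries generator ground truth\n")
  invisible(x)
}

#' @export
plot.sweep_trace <- function(x, ...) {
  plot(x$time_ms, x$current_pA, type = "l",
       xlab = "time (ms)", ylab = "current (pA)", ...)
  for (m in x$markers) abline(v = m, lty = 3, col = "grey40")
  invisible(x)
}

#' Read / write sweep traces as CSV
#'
#' CSV schema: columns `time_ms`, `current_pA`; markers and ground truth
#' travel in a sidecar JSON file (`<path>.json`) written automatically.
#'
#' @param trace a [sweep_trace()].
#' @param path CSV file path.
#' @return `read_sweep_csv` returns a [sweep_trace()];
#'   `write_sweep_csv` returns `path` invisibly.
#' @export
write_sweep_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sweep_trace"))
  utils::write.csv(data.frame(time_ms = trace$time_ms,
                              current_pA = trace$current_pA),
                   path, row.names = FALSE)
  side <- list(fs_khz = trace$fs_khz, markers = trace$markers,
               ground_truth = trace$ground_truth)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  df <- utils::read.csv(path)
  .assert(all(c("time_ms", "current_pA") %in% names(df)),
          "CSV must have columns time_ms, current_pA")
  side_path <- paste0(path, ".json")
  fs <- NULL; markers <- list(); gt <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    fs <- side$fs_khz
    if (!is.null(side$markers)) markers <- as.list(side$markers)
    gt <- side$ground_truth
  }
  if (is.null(fs)) fs <- 1 / stats::median(diff(df$time_ms))
  sweep_trace(df$time_ms, df$current_pA, fs_khz = fs,
              markers = markers, ground_truth = gt)
}
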