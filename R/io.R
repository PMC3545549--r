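# Plain-text file formats: IMU CSV, reference CSV, velocity CSV, and the
# JSON/text agreement report. CSVs carry a `# key=value` metadata preamble so
# a file is self-describing (rate, units, pulley height).

read_preamble <- function(path) {
  meta <- list()
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || !startsWith(line, "#")) break
    kv <- strsplit(sub("^#\\s*", "", line), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  meta
}

#' Read an IMU recording from CSV
#'
#' Expected layout: an optional `# key=value` preamble (`f_hz`,
#' `accel_units` = `ms2` or `g`, `gyro_units` = `rads` or `dps`) followed by a
#' header row `time_s,ax,ay,az,gx,gy,gz`. Units are converted to m s^-2 and
#' rad s^-1 at ingest.
#'
#' @param path CSV file path.
#' @param f Sampling rate (Hz); overrides the preamble if given.
#' @return An [imu_recording()].
#' @export
read_imu_csv <- function(path, f = NULL) {
  meta <- read_preamble(path)
  d <- utils::read.csv(path, comment.char = "#")
  need <- c("time_s", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(d))) {
    stop("IMU CSV must have columns ", paste(need, collapse = ","))
  }
  f <- f %||% as.numeric(meta$f_hz %||% (1 / stats::median(diff(d$time_s))))
  accel <- as.matrix(d[, c("ax", "ay", "az")])
  gyro <- as.matrix(d[, c("gx", "gy", "gz")])
  if (identical(meta$accel_units %||% "ms2", "g")) accel <- accel * GRAVITY_DEFAULT
  if (identical(meta$gyro_units %||% "rads", "dps")) gyro <- gyro * pi / 180
  imu_recording(accel, gyro, f = f, t = d$time_s)
}

#' Write an IMU recording to CSV
#' @param recording An [imu_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(recording, path) {
  con <- file(path, "w")
  writeLines(c(sprintf("# f_hz=%g", recording$f),
               "# accel_units=ms2", "# gyro_units=rads"), con)
  d <- data.frame(time_s = recording$t,
                  ax = recording$accel[, 1], ay = recording$accel[, 2],
                  az = recording$accel[, 3],
                  gx = recording$gyro[, 1], gy = recording$gyro[, 2],
                  gz = recording$gyro[, 3])
  utils::write.table(format(d, digits = 10, trim = TRUE), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' Read a tethered-reference recording from CSV
#'
#' Expected layout: optional preamble (`f_ref_hz`, `pulley_height_m`, and for
#' `displacement_m` input a `tare_m` cord length at zero displacement)
#' followed by `time_s,cord_length_m` or `time_s,displacement_m`.
#'
#' @param path CSV file path.
#' @param f_ref,pulley_height Override the preamble values.
#' @return A [reference_recording()].
#' @export
read_reference_csv <- function(path, f_ref = NULL, pulley_height = NULL) {
  meta <- read_preamble(path)
  d <- utils::read.csv(path, comment.char = "#")
  f_ref <- f_ref %||% as.numeric(meta$f_ref_hz %||% 100)
  pulley_height <- pulley_height %||% as.numeric(meta$pulley_height_m %||% 0.72)
  cord <- if ("cord_length_m" %in% names(d)) {
    d$cord_length_m
  } else if ("displacement_m" %in% names(d)) {
    tare <- as.numeric(meta$tare_m %||% stop(
      "displacement_m input needs a '# tare_m=' preamble entry"))
    tare + d$displacement_m
  } else stop("reference CSV must have cord_length_m or displacement_m")
  reference_recording(cord, f_ref = f_ref, pulley_height = pulley_height,
                      t = d$time_s)
}

#' Write a reference recording to CSV
#' @param ref A [reference_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_csv <- function(ref, path) {
  con <- file(path, "w")
  writeLines(c(sprintf("# f_ref_hz=%g", ref$f_ref),
               sprintf("# pulley_height_m=%g", ref$pulley_height)), con)
  d <- data.frame(time_s = ref$t, cord_length_m = ref$cord_length)
  utils::write.table(format(d, digits = 10, trim = TRUE), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' Write a velocity profile to CSV
#' @param profile A [velocity_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_velocity_csv <- function(profile, path) {
  utils::write.csv(data.frame(time_s = profile$t, velocity_ms = profile$v),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an agreement report to JSON (and optionally plain text)
#'
#' @param report An [agreement_report()].
#' @param json_path Output JSON path.
#' @param txt_path Optional plain-text path (the `print()` rendering).
#' @param config Optional [run_config()] embedded for provenance.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, txt_path = NULL, config = NULL) {
  x <- unclass(report)
  if (!is.null(config)) x$config <- unclass(config)
  jsonlite::write_json(x, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    sink(con); print(report); sink()
    close(con)
  }
  invisible(json_path)
}
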