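# FicTrac-format treadmill data: 25 comma-separated numeric columns per
# camera frame. Only a handful of columns are interpreted (heading, movement
# speed, timestamps); the rest are carried opaquely so files round-trip
# unchanged. Column indices live in a format descriptor because FicTrac
# dialects drift.

#' FicTrac column-layout descriptor
#'
#' Maps the variables this package interprets onto 1-based column indices of
#' the 25-column FicTrac data file. Defaults follow the published layout:
#' frame counter in column 1, integrated lab-frame heading (rad, `[0, 2*pi)`)
#' in column 17, animal movement speed (radians of sphere rotation per camera
#' frame) in column 19, absolute timestamp (ms) in column 22, and delta
#' timestamp (s) in column 24.
#'
#' @param frame,heading,speed,timestamp,delta_timestamp Column indices.
#' @param n_cols Total column count (25 for standard FicTrac output).
#' @return An object of class `fictrac_format`.
#' @export
fictrac_format <- function(frame = 1L, heading = 17L, speed = 19L,
                           timestamp = 22L, delta_timestamp = 24L,
                           n_cols = 25L) {
  idx <- c(frame = frame, heading = heading, speed = speed,
           timestamp = timestamp, delta_timestamp = delta_timestamp)
  stopifnot(all(idx >= 1), all(idx <= n_cols), !anyDuplicated(idx))
  structure(as.list(c(idx, n_cols = n_cols)), class = "fictrac_format")
}

#' Sphere on which the fly walks
#'
#' Physical description of the air-supported foam sphere; its radius converts
#' FicTrac's angular movement speed into a translational walking speed.
#' Defaults: 9 mm diameter, density 320 kg/m^3 (a sphere of about 0.12 g).
#'
#' @param diameter Diameter in mm.
#' @param density Density in kg/m^3.
#' @return An object of class `sphere_spec`.
#' @export
sphere_spec <- function(diameter = 9, density = 320) {
  stopifnot(diameter > 0, density > 0)
  structure(list(diameter = diameter, density = density), class = "sphere_spec")
}

#' Mass of the treadmill sphere
#'
#' `density * (4/3) * pi * (diameter / 2)^3`, reported in grams.
#'
#' @param sphere A [sphere_spec()].
#' @return Mass in g.
#' @examples
#' sphere_mass(sphere_spec())  # ~0.12 g
#' @export
sphere_mass <- function(sphere = sphere_spec()) {
  r_m <- sphere$diameter / 2 / 1000
  sphere$density * 4 / 3 * pi * r_m^3 * 1000
}

#' Read a FicTrac data file
#'
#' Reads comma-separated (optionally whitespace-padded) numeric rows,
#' skipping `#` comment lines, and validates the layout: every row must have
#' exactly `n_cols` fields, the frame counter must increase strictly, delta
#' timestamps must be positive and headings must lie in `[0, 2*pi)`.
#'
#' @param path File path.
#' @param format A [fictrac_format()].
#' @return A tibble with columns `v1` ... `v25` (one row per camera frame)
#'   and the format attached as attribute `fictrac_format`.
#' @export
read_fictrac <- function(path, format = fictrac_format()) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  if (!length(lines)) stop("read_fictrac(): no data rows in ", path)
  fields <- strsplit(lines, ",")
  nf <- lengths(fields)
  bad <- which(nf != format$n_cols)
  if (length(bad)) {
    stop(sprintf(
      "read_fictrac(): row %d has %d fields, expected %d",
      which(keep)[bad[1]], nf[bad[1]], format$n_cols))
  }
  m <- matrix(as.numeric(trimws(unlist(fields))), ncol = format$n_cols,
              byrow = TRUE)
  if (anyNA(m)) stop("read_fictrac(): non-numeric field encountered")
  frames <- tibble::as_tibble(m, .name_repair = ~ paste0("v", seq_len(format$n_cols)))
  attr(frames, "fictrac_format") <- format
  validate_fictrac(frames, format)
  frames
}

#' Write FicTrac frames to a data file
#'
#' @param frames Tibble/data frame of `n_cols` numeric columns as produced by
#'   [read_fictrac()] or [simulate_fly()].
#' @param path Output path.
#' @param format A [fictrac_format()].
#' @return `path`, invisibly. `read_fictrac(write_fictrac(x))` reproduces `x`.
#' @export
write_fictrac <- function(frames, path, format = fictrac_format()) {
  stopifnot(ncol(frames) == format$n_cols)
  m <- as.matrix(frames)
  rows <- apply(m, 1, function(r) paste(format(r, digits = 15, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = ", "))
  writeLines(rows, path)
  invisible(path)
}

#' Validate FicTrac frames
#'
#' @param frames FicTrac frame tibble.
#' @param format A [fictrac_format()].
#' @return `frames`, invisibly; stops on violation.
#' @export
validate_fictrac <- function(frames, format = fictrac_format()) {
  fc <- frames[[format$frame]]
  if (length(fc) > 1 && any(diff(fc) <= 0))
    stop("validate_fictrac(): frame counter must be strictly increasing")
  dt <- frames[[format$delta_timestamp]]
  if (any(dt <= 0))
    stop("validate_fictrac(): delta timestamps must be positive")
  h <- frames[[format$heading]]
  if (any(h < 0 | h >= 2 * pi + 1e-9))
    stop("validate_fictrac(): heading must lie in [0, 2*pi)")
  invisible(frames)
}

#' Yaw (turning) velocity from FicTrac heading
#'
#' Unwraps the lab-frame heading (removing the 2*pi discontinuities), takes
#' first differences, and divides by the delta timestamp, giving the turning
#' velocity in deg/s. The velocity between frames `i-1` and `i` is assigned
#' to frame `i`; the first frame has no velocity and is returned as `NA`.
#'
#' @param frames FicTrac frame tibble.
#' @param format A [fictrac_format()].
#' @return Numeric vector of length `nrow(frames)`: deg/s, `NA` first.
#' @export
yaw_velocity <- function(frames, format = fictrac_format()) {
  if (nrow(frames) < 2) stop("yaw_velocity(): need at least 2 frames")
  validate_fictrac(frames, format)
  h <- signal::unwrap(frames[[format$heading]])
  dt <- frames[[format$delta_timestamp]][-1]
  c(NA_real_, diff(h) / dt * 180 / pi)
}

#' Translational (walking) speed from FicTrac movement speed
#'
#' FicTrac's animal movement speed is radians of sphere rotation per camera
#' frame; multiplying by the sphere radius and dividing by the frame interval
#' gives the walking speed in mm/s.
#'
#' @param frames FicTrac frame tibble.
#' @param sphere A [sphere_spec()].
#' @param format A [fictrac_format()].
#' @return Numeric vector of length `nrow(frames)`: mm/s.
#' @export
translational_speed <- function(frames, sphere = sphere_spec(),
                                format = fictrac_format()) {
  stopifnot(nrow(frames) >= 1)
  dt <- frames[[format$delta_timestamp]]
  if (any(dt <= 0)) stop("translational_speed(): delta timestamps must be positive")
  frames[[format$speed]] * (sphere$diameter / 2) / dt
}
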