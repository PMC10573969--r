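#' Nano-indentation load protocol
#'
#' Trapezoidal load history of the creep indentation test: constant-rate ramp
#' to the peak load, constant-load hold, then unload. The experimental
#' protocol this package emulates uses a flat cylindrical punch (radius
#' 100 um), a 0.5 mN/s ramp to 3 mN and a 200 s hold, giving a 6 s loading
#' stage.
#'
#' @param loading_rate mN/s, positive.
#' @param peak_load mN, positive.
#' @param hold_time s, positive.
#' @param indenter_radius um, positive.
#' @param indenter_shape Only `"cylindrical"` is supported.
#' @return An object of class `"load_protocol"`, with derived element
#'   `loading_duration = peak_load / loading_rate`.
#' @export
load_protocol <- function(loading_rate = 0.5, peak_load = 3, hold_time = 200,
                          indenter_radius = 100,
                          indenter_shape = "cylindrical") {
  for (nm in c("loading_rate", "peak_load", "hold_time", "indenter_radius")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
  }
  indenter_shape <- match.arg(indenter_shape)
  structure(list(loading_rate = loading_rate, peak_load = peak_load,
                 hold_time = hold_time, indenter_radius = indenter_radius,
                 indenter_shape = indenter_shape,
                 loading_duration = peak_load / loading_rate),
            class = "load_protocol")
}

#' Raw nano-indentation record
#'
#' Time, load and depth triplets for one experiment point, plus the local
#' PDL thickness used to convert depth to strain.
#'
#' @param time_s Strictly increasing time, s.
#' @param load_mN Load, mN, non-negative.
#' @param depth_um Indentation depth, um, non-negative after zero-correction.
#' @param thickness_um Local PDL thickness, um, positive.
#' @param region,plane,point_id Optional metadata.
#' @return An object of class `"indentation_record"` (a data.frame with
#'   metadata attributes).
#' @export
indentation_record <- function(time_s, load_mN, depth_um, thickness_um,
                               region = NA_character_, plane = NA_character_,
                               point_id = NA_character_) {
  n <- length(time_s)
  if (length(load_mN) != n || length(depth_um) != n)
    stop("time, load and depth must have equal length", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("'time_s' must be strictly increasing", call. = FALSE)
  if (any(load_mN < 0)) stop("'load_mN' must be non-negative", call. = FALSE)
  if (any(depth_um < 0)) stop("'depth_um' must be non-negative", call. = FALSE)
  if (!is.numeric(thickness_um) || thickness_um <= 0)
    stop("'thickness_um' must be positive", call. = FALSE)
  structure(data.frame(time_s = time_s, load_mN = load_mN, depth_um = depth_um),
            thickness_um = thickness_um, region = region, plane = plane,
            point_id = point_id,
            class = c("indentation_record", "data.frame"))
}

#' Segment a record into loading, hold and unload stages
#'
#' The loading stage ends at the first sample where the load reaches
#' `peak_load * (1 - tol)`; the hold stage spans `hold_time` from there; any
#' remaining samples are the unload stage (possibly empty).
#'
#' @param rec An [indentation_record()].
#' @param proto A [load_protocol()].
#' @param tol Peak-detection tolerance as a fraction of peak load
#'   (default 0.01).
#' @return An object of class `"segmented_record"`: list of integer index
#'   vectors `loading`, `hold`, `unload` (contiguous, ordered,
#'   non-overlapping).
#' @export
segment_record <- function(rec, proto, tol = 0.01) {
  stopifnot(inherits(rec, "indentation_record"),
            inherits(proto, "load_protocol"))
  thr <- proto$peak_load * (1 - tol)
  i_peak <- which(rec$load_mN >= thr)[1L]
  if (is.na(i_peak))
    stop(sprintf(
      "peak load %.3g mN never reached (max load seen: %.3g mN)",
      proto$peak_load, max(rec$load_mN)), call. = FALSE)
  t_hold_end <- rec$time_s[i_peak] + proto$hold_time
  # last sample still inside the hold window
  i_hold_end <- max(which(rec$time_s <= t_hold_end + 1e-9))
  n <- nrow(rec)
  structure(list(
    loading = seq_len(i_peak),
    hold = seq.int(i_peak, i_hold_end),
    unload = if (i_hold_end < n) seq.int(i_hold_end + 1L, n) else integer(0)
  ), class = "segmented_record")
}

#' Convert hold-stage displacement to a strain-time creep curve
#'
#' Divides the indentation depth by the local PDL thickness and re-zeroes
#' the clock at hold onset. By default strain is measured from total depth
#' (including loading-stage penetration); `reference = "hold_onset"`
#' subtracts the depth at hold onset instead.
#'
#' @param rec An [indentation_record()].
#' @param seg A [segment_record()] result for `rec`.
#' @param reference `"total"` (default) or `"hold_onset"`.
#' @return A [creep_curve()] for the hold stage.
#' @export
strain_from_displacement <- function(rec, seg, reference = c("total", "hold_onset")) {
  stopifnot(inherits(rec, "indentation_record"),
            inherits(seg, "segmented_record"))
  reference <- match.arg(reference)
  th <- attr(rec, "thickness_um")
  if (is.null(th) || th <= 0) stop("record thickness must be positive", call. = FALSE)
  idx <- seg$hold
  h <- rec$depth_um[idx]
  if (reference == "hold_onset") h <- h - h[1L]
  creep_curve(rec$time_s[idx] - rec$time_s[idx[1L]], h / th,
              sample_id = attr(rec, "point_id"), region = attr(rec, "region"),
              plane = attr(rec, "plane"))
}

#' Pointwise average of replicate curves
#'
#' Averages replicate series (load-depth or strain-time) after linear
#' interpolation onto the first series' abscissa; no extrapolation is
#' performed, so the common grid is restricted to the overlap of all series.
#'
#' @param series A list of data.frames, each with columns `x` and `y` (or
#'   two columns taken as x and y).
#' @return A data.frame with columns `x`, `mean`, `n` (number of series
#'   contributing at each point; constant here since the grid is the
#'   overlap).
#' @export
average_curves <- function(series) {
  if (!is.list(series) || length(series) == 0L)
    stop("'series' must be a non-empty list", call. = FALSE)
  series <- lapply(series, function(s) {
    s <- as.data.frame(s)
    if (!all(c("x", "y") %in% names(s))) names(s)[1:2] <- c("x", "y")
    s
  })
  lo <- max(vapply(series, function(s) min(s$x), 0))
  hi <- min(vapply(series, function(s) max(s$x), 0))
  if (lo >= hi) stop("series have disjoint abscissa ranges", call. = FALSE)
  grid <- series[[1L]]$x
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) == 0L) stop("no grid points in common abscissa range", call. = FALSE)
  ys <- vapply(series, function(s) stats::approx(s$x, s$y, xout = grid)$y,
               numeric(length(grid)))
  ys <- matrix(ys, nrow = length(grid))
  data.frame(x = grid, mean = rowMeans(ys), n = ncol(ys))
}

#' Reduced elastic modulus from a flat-punch unloading curve
#'
#' For a rigid flat cylindrical punch the contact area is constant, so the
#' Oliver-Pharr contact-stiffness relation `S = 2 E* a` applies with the
#' contact radius `a` equal to the punch radius `R`, giving `E* = S / (2R)`.
#' The unloading stiffness `S` is the slope of a linear fit to the upper
#' portion of the unloading curve (by load; fraction configurable).
#'
#' @param load_mN Unloading-stage loads, mN (>= 2 points).
#' @param depth_um Matching depths, um.
#' @param R_um Punch radius, um.
#' @param top_fraction Fraction of the unloading curve (by load, from the
#'   top) used in the linear fit. Default 0.5.
#' @return An object of class `"reduced_modulus"`: list with `E_star_MPa`,
#'   `stiffness_mN_per_um`, `method`, `n_points`.
#' @examples
#' # slope 1.016 mN/um on a 100 um punch gives E* = 5.08 MPa
#' h <- seq(20, 15, length.out = 20)
#' P <- 3 - 1.016 * (20 - h)
#' reduced_modulus_flat_punch(P, h, R_um = 100)
#' @export
reduced_modulus_flat_punch <- function(load_mN, depth_um, R_um,
                                       top_fraction = 0.5) {
  if (length(load_mN) != length(depth_um) || length(load_mN) < 2L)
    stop("need >= 2 matching unload points", call. = FALSE)
  if (!is.numeric(R_um) || R_um <= 0) stop("'R_um' must be positive", call. = FALSE)
  if (top_fraction <= 0 || top_fraction > 1)
    stop("'top_fraction' must be in (0, 1]", call. = FALSE)
  p_max <- max(load_mN); p_min <- min(load_mN)
  keep <- load_mN >= p_max - top_fraction * (p_max - p_min)
  P <- load_mN[keep]; h <- depth_um[keep]
  if (length(unique(h)) < 2L)
    stop("degenerate unload: depth is constant over the fitted portion",
         call. = FALSE)
  S <- unname(stats::coef(stats::lm(P ~ h))[2L])  # mN/um
  # mN/um over um: 1 mN/um^2 = 1000 MPa
  structure(list(E_star_MPa = 1000 * S / (2 * R_um),
                 stiffness_mN_per_um = S,
                 method = "flat_punch_oliver_pharr",
                 n_points = length(P)),
            class = "reduced_modulus")
}

#' @export
print.reduced_modulus <- function(x, ...) {
  cat(sprintf("Flat-punch reduced modulus: E* = %.4g MPa (S = %.4g mN/um, %d pts)\n",
              x$E_star_MPa, x$stiffness_mN_per_um, x$n_points))
  invisible(x)
}

#' Read an indentation record from CSV
#'
#' Expects columns `time_s`, `load_mN`, `depth_um`; metadata
#' (`thickness_um`, `region`, `plane`, `point_id`) is taken from a sidecar
#' JSON file `<path>.json` if present, or from arguments.
#'
#' @param path CSV path.
#' @param thickness_um,region,plane,point_id Metadata overrides.
#' @return An [indentation_record()].
#' @export
read_indentation_csv <- function(path, thickness_um = NULL,
                                 region = NA_character_,
                                 plane = NA_character_,
                                 point_id = NA_character_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "load_mN", "depth_um")
  if (!all(need %in% names(df)))
    stop("CSV must have columns time_s, load_mN, depth_um", call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(thickness_um)) thickness_um <- meta$thickness_um
    if (is.na(region) && !is.null(meta$region)) region <- meta$region
    if (is.na(plane) && !is.null(meta$plane)) plane <- meta$plane
    if (is.na(point_id) && !is.null(meta$point_id)) point_id <- meta$point_id
  }
  if (is.null(thickness_um))
    stop("thickness_um not given and no sidecar JSON found", call. = FALSE)
  indentation_record(df$time_s, df$load_mN, df$depth_um, thickness_um,
                     region = region, plane = plane, point_id = point_id)
}
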