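#' Specification for synthetic experiment generation
#'
#' Bundles the load protocol, material parameters, geometry and noise model
#' used by the generators. Identical specs (including seed) produce
#' identical output.
#'
#' @param protocol A [load_protocol()]; default is the creep protocol
#'   (0.5 mN/s ramp to 3 mN, 200 s hold, 100 um cylindrical punch).
#' @param sls An [sls_parameters()] object.
#' @param schapery A [schapery_parameters()] object.
#' @param load A [step_load()]; default unit step stress (normalized
#'   context).
#' @param thickness_um PDL thickness, um; default 200 (the protocol's
#'   minimum usable thickness).
#' @param noise_sd Gaussian noise standard deviation in strain units
#'   (applied to depth as `noise_sd * thickness_um`); default 0.
#' @param n_points_per_region Experiment points per region; default 5.
#' @param seed Integer seed.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(protocol = load_protocol(),
                           sls = sls_parameters(1, 1, 260.8893),
                           schapery = schapery_parameters(0.0049, -0.0096),
                           load = step_load(sigma0 = 1),
                           thickness_um = 200, noise_sd = 0,
                           n_points_per_region = 5L, seed = 1L) {
  stopifnot(inherits(protocol, "load_protocol"),
            inherits(sls, "sls_parameters"),
            inherits(schapery, "schapery_parameters"),
            inherits(load, "step_load"))
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  if (thickness_um <= 0) stop("'thickness_um' must be positive", call. = FALSE)
  structure(list(protocol = protocol, sls = sls, schapery = schapery,
                 load = load, thickness_um = thickness_um,
                 noise_sd = noise_sd,
                 n_points_per_region = as.integer(n_points_per_region),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic nano-indentation record
#'
#' Builds a record following the trapezoidal protocol: constant-rate ramp to
#' the peak load, constant-load hold with depth following
#' `thickness * eps(t)` from the nonlinear strain response (hold clock),
#' then an optional linear elastic unload. During the ramp the depth is
#' modeled quasi-statically through the instantaneous term only
#' (`eps = g0 D0' sigma(t)`); the hold stage, which is what gets fitted,
#' follows the full response. Gaussian noise of sd `noise_sd * thickness` is
#' added to depth with the spec's seed; a zero-noise spec is deterministic.
#'
#' @param spec A [synthetic_spec()].
#' @param include_unload Append a linear unload stage? Default `TRUE`.
#' @param unload_stiffness_mN_per_um Elastic unloading slope; the default
#'   `peak_load / depth_at_hold_end` makes the tissue rebound fully (depth
#'   returns to zero at zero load), consistent with the full-rebound
#'   assumption behind `g1 = 1`. The implied flat-punch reduced modulus is
#'   recorded in the ground truth.
#' @param dt_load,dt_hold,dt_unload Sampling intervals, s.
#' @return A list with `record` (an [indentation_record()]) and
#'   `ground_truth` (generating parameters, segment boundaries and the
#'   noiseless hold-stage strain).
#' @export
generate_indentation_record <- function(spec, include_unload = TRUE,
                                        unload_stiffness_mN_per_um = NULL,
                                        dt_load = 0.1, dt_hold = 1,
                                        dt_unload = 0.1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pr <- spec$protocol
  kv <- kelvin_voigt_from_sls(spec$sls)
  if (kv$tau1 >= 5 * pr$hold_time)
    warning(sprintf(
      "retardation time tau1 = %.3g s is >= 5x the hold time (%.3g s); ",
      kv$tau1, pr$hold_time),
      "parameters will not be resolvable by fitting", call. = FALSE)
  t_ramp_end <- pr$loading_duration
  t_load <- seq(0, t_ramp_end, by = dt_load)
  if (t_load[length(t_load)] < t_ramp_end) t_load <- c(t_load, t_ramp_end)
  P_load <- pr$loading_rate * t_load
  s0 <- spec$load$sigma0
  eps_load <- spec$schapery$g0 * kv$D0p * s0 * (P_load / pr$peak_load)

  t_hold <- t_ramp_end + seq(dt_hold, pr$hold_time, by = dt_hold)
  eps_hold <- strain_response(spec$schapery, spec$sls, spec$load,
                              t_hold - t_ramp_end)
  # the ramp's final sample is the hold onset (t = 0 on the hold clock)
  eps_truth_hold <- c(eps_load[length(eps_load)], eps_hold)

  tt <- c(t_load, t_hold)
  PP <- c(P_load, rep(pr$peak_load, length(t_hold)))
  eps <- c(eps_load, eps_hold)
  hh <- spec$thickness_um * eps

  i_unload_start <- NA_integer_
  if (include_unload) {
    h_end <- hh[length(hh)]
    if (is.null(unload_stiffness_mN_per_um))
      unload_stiffness_mN_per_um <- pr$peak_load / h_end  # full rebound
    n_un <- max(2L, ceiling(pr$peak_load / (0.5 * dt_unload)))
    P_un <- seq(pr$peak_load, 0, length.out = n_un + 1L)[-1L]
    h_un <- h_end - (pr$peak_load - P_un) / unload_stiffness_mN_per_um
    t_un <- tt[length(tt)] + dt_unload * seq_along(P_un)
    i_unload_start <- length(tt) + 1L
    tt <- c(tt, t_un); PP <- c(PP, P_un); hh <- c(hh, pmax(h_un, 0))
  }

  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    hh <- hh + stats::rnorm(length(hh), 0, spec$noise_sd * spec$thickness_um)
  }
  hh <- pmax(hh, 0)

  rec <- indentation_record(tt, PP, hh, spec$thickness_um)
  list(record = rec,
       ground_truth = list(
         schapery = spec$schapery, sls = spec$sls, load = spec$load,
         thickness_um = spec$thickness_um,
         kelvin_voigt = kv,
         hold_start_index = length(t_load),
         hold_end_index = length(t_load) + length(t_hold),
         unload_start_index = i_unload_start,
         hold_strain = eps_truth_hold,
         unload_stiffness_mN_per_um =
           if (include_unload) unload_stiffness_mN_per_um else NA_real_,
         E_star_MPa = if (include_unload)
           1000 * unload_stiffness_mN_per_um / (2 * pr$indenter_radius)
         else NA_real_))
}

#' Generate a synthetic elastic unloading curve
#'
#' Linear unload with the flat-punch stiffness implied by a known reduced
#' modulus: `S = 2 R E* / 1000` mN/um. Used to validate the Oliver-Pharr
#' flat-punch analysis against known ground truth.
#'
#' @param E_star_MPa True reduced modulus, MPa.
#' @param R_um Punch radius, um.
#' @param peak_load_mN Load at unload onset, mN.
#' @param h_peak_um Depth at unload onset, um.
#' @param n Number of unload samples.
#' @param noise_sd_um Gaussian depth noise, um (default 0).
#' @param seed Optional seed for the noise.
#' @return A data.frame with columns `load_mN`, `depth_um`, attribute
#'   `E_star_true`.
#' @export
generate_elastic_unload <- function(E_star_MPa, R_um = 100, peak_load_mN = 3,
                                    h_peak_um = 20, n = 50,
                                    noise_sd_um = 0, seed = NULL) {
  stopifnot(E_star_MPa > 0, R_um > 0, n >= 2)
  S <- 2 * R_um * E_star_MPa / 1000  # mN/um
  P <- seq(peak_load_mN, 0, length.out = n)
  h <- h_peak_um - (peak_load_mN - P) / S
  if (noise_sd_um > 0) {
    if (!is.null(seed)) set.seed(seed)
    h <- h + stats::rnorm(n, 0, noise_sd_um)
  }
  structure(data.frame(load_mN = P, depth_um = h), E_star_true = E_star_MPa)
}

# vectorized HSV -> RGB on numeric vectors in [0, 1]
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

# stamp a quadratic Bezier stroke of half-width w onto a logical mask
stamp_fiber <- function(mask, size, w) {
  p0 <- stats::runif(2, -0.1, 1.1) * size
  p2 <- stats::runif(2, -0.1, 1.1) * size
  mid <- (p0 + p2) / 2 + stats::rnorm(2, 0, 0.2 * size)
  u <- seq(0, 1, length.out = 2L * size)
  bx <- (1 - u)^2 * p0[1] + 2 * u * (1 - u) * mid[1] + u^2 * p2[1]
  by <- (1 - u)^2 * p0[2] + 2 * u * (1 - u) * mid[2] + u^2 * p2[2]
  off <- expand.grid(dx = -w:w, dy = -w:w)
  off <- off[off$dx^2 + off$dy^2 <= w^2 + 0.5, ]
  x <- round(rep(bx, each = nrow(off)) + off$dx)
  y <- round(rep(by, each = nrow(off)) + off$dy)
  keep <- x >= 1 & x <= size & y >= 1 & y <= size
  mask[cbind(y[keep], x[keep])] <- TRUE
  mask
}

# shift a logical matrix by (dy, dx), padding with FALSE
shift_mask <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  ys <- max(1, 1 + dy):min(H, H + dy)
  xs <- max(1, 1 + dx):min(W, W + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Generate a synthetic Masson-stained image with known collagen fraction
#'
#' Draws curvilinear fiber bundles (quadratic Bezier strokes) onto the frame
#' until the collagen area reaches the requested fraction, then adjusts the
#' mask boundary pixelwise so the ground-truth fraction matches the target
#' to quantization. Collagen pixels are rendered in Masson-blue hues,
#' background in red hues, with mild seeded color jitter.
#'
#' @param target_vf Target collagen fraction, percent in `[0, 100]`.
#' @param size Image side, px (square frame).
#' @param seed Integer seed.
#' @param fiber_halfwidth Fiber stroke half-width, px; default scales with
#'   image size.
#' @return A list with `image` (RGB array `size x size x 3`), `mask`
#'   (ground-truth logical collagen mask) and `target_vf`.
#' @examples
#' g <- generate_masson_image(52, size = 128, seed = 7)
#' measure_vf(g$mask)$vf  # ~52
#' @export
generate_masson_image <- function(target_vf, size = 1024, seed = 1,
                                  fiber_halfwidth = NULL) {
  if (!is.numeric(target_vf) || target_vf < 0 || target_vf > 100)
    stop("'target_vf' must be a percentage in [0, 100]", call. = FALSE)
  if (size < 8) stop("'size' must be at least 8 px", call. = FALSE)
  set.seed(seed)
  N <- size * size
  target_px <- round(target_vf / 100 * N)
  mask <- matrix(FALSE, size, size)
  if (is.null(fiber_halfwidth)) fiber_halfwidth <- max(1L, round(size / 300))

  if (target_px >= N) {
    mask[] <- TRUE
  } else if (target_px > 0) {
    w <- fiber_halfwidth
    # a full-frame stroke covers roughly 2*size*(2w+1) px before overlap
    guard <- 2 * size * (2 * w + 1)
    it <- 0L
    while (sum(mask) < target_px - guard && it < 50L * size) {
      mask <- stamp_fiber(mask, size, w)
      it <- it + 1L
    }
    while (sum(mask) < target_px - 6 * size && it < 100L * size) {
      mask <- stamp_fiber(mask, size, 1L)  # thin strokes near the target
      it <- it + 1L
    }
    # exact pixel-count adjustment along the mask boundary
    d <- target_px - sum(mask)
    while (d != 0) {
      if (d > 0) {
        dil <- mask
        for (sh in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0)))
          dil <- dil | shift_mask(mask, sh[1], sh[2])
        cand <- which(dil & !mask)
        if (length(cand) == 0L) cand <- which(!mask)
        add <- if (length(cand) <= d) cand else sample(cand, d)
        mask[add] <- TRUE
      } else {
        ero <- mask
        for (sh in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0)))
          ero <- ero & shift_mask(mask, sh[1], sh[2])
        cand <- which(mask & !ero)
        if (length(cand) == 0L) cand <- which(mask)
        drop <- if (length(cand) <= -d) cand else sample(cand, -d)
        mask[drop] <- FALSE
      }
      d <- target_px - sum(mask)
    }
  }

  # render: collagen blue (hue ~0.60), background red (hue ~0.99)
  h <- ifelse(mask, 0.60, 0.99) + stats::rnorm(N, 0, 0.015)
  h <- ifelse(mask, pmin(pmax(h, 0.47), 0.73), h %% 1)
  s <- ifelse(mask, 0.65, 0.50) + stats::rnorm(N, 0, 0.05)
  s <- pmin(pmax(s, 0.2), 1)
  v <- ifelse(mask, 0.75, 0.88) + stats::rnorm(N, 0, 0.05)
  v <- pmin(pmax(v, 0.3), 1)
  rgb <- hsv_to_rgb(h, s, v)
  img <- array(c(rgb$r, rgb$g, rgb$b), c(size, size, 3L))

  list(image = img, mask = mask, target_vf = target_vf)
}

#' Generate a complete synthetic study
#'
#' Emulates the experimental design end to end: indentation records for
#' 3 regions x 2 planes x `n_points_per_region` points, and Masson-style
#' images for 5 slices x 3 regions with region-specific collagen fractions.
#' Per region-plane material parameters default to a built-in table of
#' fitted PDL creep parameters ([pdl_creep_parameters]); slice collagen
#' fractions default to the built-in per-slice table
#' ([pdl_fiber_content]). When `out_dir` is given, records are written as
#' CSV + sidecar JSON, images as PNG, and a `manifest.json` ties artifacts
#' to their ground truth.
#'
#' @param spec A [synthetic_spec()] providing protocol, thickness, noise and
#'   seed.
#' @param materials Optional data.frame with columns `region`, `plane`,
#'   `g0`, `g2`, `eta` overriding the built-in parameter table.
#' @param image_size Side of generated images, px. Default 256 (keeps a full
#'   study fast; use 1024 for full-resolution checks).
#' @param out_dir Optional output directory.
#' @return A list with `records` (named list of
#'   [generate_indentation_record()] results), `images` (named list of
#'   [generate_masson_image()] results), `materials`, and `manifest`.
#' @export
generate_study <- function(spec = synthetic_spec(), materials = NULL,
                           image_size = 256, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(materials)) {
    tb <- pdl_creep_parameters
    # assign the two columns per region to the two planes (synthesis choice)
    materials <- data.frame(
      region = rep(c("neck", "middle", "apex"), each = 2L),
      plane = rep(c("transverse", "longitudinal"), times = 3L),
      g0 = tb$g0, g2 = tb$g2, eta = tb$eta, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("region", "plane", "g0", "g2", "eta") %in% names(materials)))

  records <- list()
  for (i in seq_len(nrow(materials))) {
    m <- materials[i, ]
    for (p in seq_len(spec$n_points_per_region)) {
      id <- sprintf("%s_%s_p%d", m$region, m$plane, p)
      sub <- synthetic_spec(
        protocol = spec$protocol,
        sls = sls_parameters(spec$sls$Etf, spec$sls$Em, m$eta),
        schapery = schapery_parameters(m$g0, m$g2),
        load = spec$load, thickness_um = spec$thickness_um,
        noise_sd = spec$noise_sd,
        seed = spec$seed + 1000L * i + p)
      g <- generate_indentation_record(sub)
      attr(g$record, "region") <- m$region
      attr(g$record, "plane") <- m$plane
      attr(g$record, "point_id") <- id
      records[[id]] <- g
    }
  }

  fc <- pdl_fiber_content
  images <- list()
  for (r in unique(fc$region)) {
    vfs <- fc$vf[fc$region == r]
    for (sl in seq_along(vfs)) {
      id <- sprintf("%s_slice%d", r, sl)
      images[[id]] <- generate_masson_image(
        vfs[sl], size = image_size,
        seed = spec$seed + 37L * match(r, unique(fc$region)) + 7L * sl)
      images[[id]]$region <- r
    }
  }

  manifest <- list(
    seed = spec$seed, noise_sd = spec$noise_sd,
    thickness_um = spec$thickness_um,
    n_records = length(records), n_images = length(images),
    protocol = unclass(spec$protocol),
    materials = materials)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "records"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
    for (id in names(records)) {
      rec <- records[[id]]$record
      pth <- file.path(out_dir, "records", paste0(id, ".csv"))
      utils::write.csv(as.data.frame(rec), pth, row.names = FALSE)
      jsonlite::write_json(list(thickness_um = attr(rec, "thickness_um"),
                                region = attr(rec, "region"),
                                plane = attr(rec, "plane"),
                                point_id = attr(rec, "point_id")),
                           paste0(pth, ".json"), auto_unbox = TRUE)
    }
    for (id in names(images))
      write_stained_image(images[[id]]$image,
                          file.path(out_dir, "images", paste0(id, ".png")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(records = records, images = images, materials = materials,
       manifest = manifest)
}
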