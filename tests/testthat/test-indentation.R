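test_that("records are segmented at peak load and hold duration", {
  spec <- synthetic_spec()
  g <- generate_indentation_record(spec)
  proto <- load_protocol()
  seg <- segment_record(g$record, proto)
  # 0.5 mN/s to 3 mN: loading takes 6 s
  expect_equal(g$record$time_s[max(seg$loading)], 6)
  expect_equal(max(seg$loading), g$ground_truth$hold_start_index)
  expect_equal(max(seg$hold), g$ground_truth$hold_end_index)
  expect_equal(min(seg$unload), g$ground_truth$unload_start_index)
  # hold clock spans the protocol hold time
  expect_equal(diff(range(g$record$time_s[seg$hold])), proto$hold_time)
  # no unload samples: empty unload range, no error
  g2 <- generate_indentation_record(spec, include_unload = FALSE)
  seg2 <- segment_record(g2$record, proto)
  expect_length(seg2$unload, 0L)
  # peak never reached
  rec <- indentation_record(0:10, seq(0, 2, length.out = 11),
                            rep(1, 11), 200)
  expect_error(segment_record(rec, proto), "max load seen: 2")
})

test_that("hold-stage strain is depth over thickness on the hold clock", {
  rec <- indentation_record(
    time_s = c(0, 3, 6, 50, 100, 150, 206),
    load_mN = c(0, 1.5, 3, 3, 3, 3, 3),
    depth_um = c(0, 10, 20, 20, 20, 20, 20),
    thickness_um = 200)
  seg <- segment_record(rec, load_protocol())
  cv <- strain_from_displacement(rec, seg)
  expect_equal(cv$strain, rep(0.1, 5))   # 20 um / 200 um
  expect_equal(cv$time_s[1L], 0)         # re-zeroed clock
  # hold-onset reference subtracts the loading-phase depth
  cv2 <- strain_from_displacement(rec, seg, reference = "hold_onset")
  expect_equal(cv2$strain, rep(0, 5))
  # zero depth everywhere gives zero strain
  rec0 <- indentation_record(rec$time_s, rec$load_mN, rep(0, 7), 200)
  expect_equal(strain_from_displacement(rec0, seg)$strain, rep(0, 5))
})

test_that("synthetic hold strain matches the constitutive response", {
  spec <- synthetic_spec()
  g <- generate_indentation_record(spec)
  seg <- segment_record(g$record, load_protocol())
  cv <- strain_from_displacement(g$record, seg)
  truth <- strain_response(spec$schapery, spec$sls, spec$load, cv$time_s)
  expect_lt(max(abs(cv$strain - truth)), 1e-9)
  # strain is invariant under a simultaneous unit change of depth/thickness
  rec_mm <- indentation_record(g$record$time_s, g$record$load_mN,
                               g$record$depth_um * 1000,
                               attr(g$record, "thickness_um") * 1000)
  cv_mm <- strain_from_displacement(rec_mm, seg)
  expect_equal(cv_mm$strain, cv$strain)
})

test_that("curve averaging interpolates onto the first grid", {
  s <- data.frame(x = 0:10, y = sin(0:10))
  expect_equal(average_curves(list(s, s, s, s, s))$mean, s$y)
  s_neg <- data.frame(x = 0:10, y = -sin(0:10))
  expect_equal(average_curves(list(s, s_neg))$mean, rep(0, 11))
  # five noisy replicates: mean is closer to truth in RMS than any replicate
  set.seed(21)
  truth <- data.frame(x = seq(0, 10, by = 0.5), y = sqrt(seq(0, 10, by = 0.5)))
  reps <- lapply(1:5, function(i)
    data.frame(x = truth$x, y = truth$y + rnorm(nrow(truth), 0, 0.2)))
  avg <- average_curves(reps)
  rms <- function(v) sqrt(mean(v^2))
  rms_mean <- rms(avg$mean - truth$y)
  rms_reps <- vapply(reps, function(r) rms(r$y - truth$y), 0)
  expect_true(all(rms_mean < rms_reps))
  expect_error(average_curves(list(data.frame(x = 0:5, y = 0:5),
                                   data.frame(x = 10:15, y = 0:5))),
               "disjoint")
})

test_that("flat-punch reduced modulus follows E* = S/(2R)", {
  # slope 1.016 mN/um on a 100 um punch: E* = 5.08 MPa
  h <- seq(20, 15, length.out = 30)
  P <- 3 - 1.016 * (20 - h)
  em <- reduced_modulus_flat_punch(P, h, R_um = 100)
  expect_equal(em$E_star_MPa, 5.08, tolerance = 1e-9)
  expect_equal(em$stiffness_mN_per_um, 1.016, tolerance = 1e-9)
  # zero slope (constant load while depth recedes) gives zero modulus
  em0 <- reduced_modulus_flat_punch(rep(2, 5), seq(5, 1, by = -1), 100)
  expect_equal(em0$E_star_MPa, 0)
  expect_error(reduced_modulus_flat_punch(c(3, 2, 1), c(5, 5, 5), 100),
               "degenerate")
  # known-modulus synthetic unloads recovered within 1%
  set.seed(33)
  for (i in 1:10) {
    E_true <- runif(1, 0.3, 6)
    u <- generate_elastic_unload(E_true)
    em <- reduced_modulus_flat_punch(u$load_mN, u$depth_um, 100)
    expect_lt(rel_err(em$E_star_MPa, E_true), 0.01)
    # invariant under 2x decimation for noiseless unloads
    idx <- seq(1, nrow(u), by = 2)
    em2 <- reduced_modulus_flat_punch(u$load_mN[idx], u$depth_um[idx], 100)
    expect_lt(rel_err(em2$E_star_MPa, em$E_star_MPa), 0.02)
  }
})

test_that("indentation CSV + sidecar JSON round-trips", {
  spec <- synthetic_spec(noise_sd = 0.001, seed = 9)
  g <- generate_indentation_record(spec)
  tmp <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(g$record), tmp, row.names = FALSE)
  jsonlite::write_json(list(thickness_um = 200, region = "apex",
                            plane = "transverse", point_id = "p1"),
                       paste0(tmp, ".json"), auto_unbox = TRUE)
  rec <- read_indentation_csv(tmp)
  expect_equal(rec$depth_um, g$record$depth_um)
  expect_equal(attr(rec, "region"), "apex")
  expect_equal(attr(rec, "thickness_um"), 200)
  suppressWarnings(
    expect_error(read_indentation_csv(tempfile(), thickness_um = 200)))
})
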