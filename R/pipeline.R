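#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected.
#' May be built directly or loaded from a YAML/JSON file with
#' [read_pipeline_config()].
#'
#' @param out_dir Output directory for the report bundle.
#' @param input_dir Optional directory of existing records/images (a
#'   [generate_study()] layout); when `NULL`, a synthetic study is generated.
#' @param seed Integer seed for synthesis.
#' @param noise_sd Strain-units noise for synthesis.
#' @param thickness_um PDL thickness for synthesis, um.
#' @param image_size Synthetic image side, px.
#' @param Etf,Em,sigma0,g1 Fixed fitting context (see [creep_context()]).
#' @param hue_window,sat_min Collagen segmentation parameters
#'   (see [segment_collagen()]).
#' @param top_fraction Unload fraction for stiffness fitting
#'   (see [reduced_modulus_flat_punch()]).
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, input_dir = NULL, seed = 1L,
                            noise_sd = 0, thickness_um = 200,
                            image_size = 256, Etf = 1, Em = 1, sigma0 = 1,
                            g1 = 1, hue_window = c(0.45, 0.75),
                            sat_min = 0.15, top_fraction = 0.5) {
  cfg <- list(out_dir = out_dir, input_dir = input_dir, seed = as.integer(seed),
              noise_sd = noise_sd, thickness_um = thickness_um,
              image_size = image_size, Etf = Etf, Em = Em, sigma0 = sigma0,
              g1 = g1, hue_window = hue_window, sat_min = sat_min,
              top_fraction = top_fraction)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys must match the arguments of [pipeline_config()]; unknown keys raise
#' an error.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("config must be YAML or JSON", call. = FALSE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate (or load) -> segment -> strain -> creep fit ->
#' reduced modulus -> fiber content -> report. Writes a report bundle to
#' `config$out_dir`:
#' \itemize{
#'   \item `creep_parameters.csv` — fitted (g0, g2, eta, R^2) per record;
#'   \item `reduced_modulus.csv` — flat-punch E* per region x plane;
#'   \item `fiber_content.csv` — per-slice Vf and region means;
#'   \item `manifest.json` — seed, config hash, stage log.
#' }
#' All stages are deterministic for a fixed config, so reruns are
#' bit-reproducible.
#'
#' @param config A [pipeline_config()] (or path to a YAML/JSON config).
#' @return Invisibly, a list with the three report data.frames and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message("[pdlcreep] ", msg)
  }

  # --- stage 1: obtain study data -----------------------------------------
  if (is.null(config$input_dir)) {
    say("generate: synthesizing study (seed %d, noise_sd %g)",
        config$seed, config$noise_sd)
    spec <- synthetic_spec(seed = config$seed, noise_sd = config$noise_sd,
                           thickness_um = config$thickness_um)
    study <- generate_study(spec, image_size = config$image_size)
    records <- lapply(study$records, `[[`, "record")
    images <- study$images
  } else {
    if (!dir.exists(config$input_dir))
      stop("input directory does not exist: ", config$input_dir, call. = FALSE)
    say("load: reading study from %s", config$input_dir)
    rec_files <- list.files(file.path(config$input_dir, "records"),
                            pattern = "\\.csv$", full.names = TRUE)
    if (length(rec_files) == 0L)
      stop("no record CSVs under ", config$input_dir, call. = FALSE)
    records <- lapply(rec_files, read_indentation_csv)
    names(records) <- vapply(records, function(r) attr(r, "point_id"), "")
    img_files <- list.files(file.path(config$input_dir, "images"),
                            pattern = "\\.png$", full.names = TRUE)
    images <- lapply(img_files, function(p)
      list(image = read_stained_image(p),
           region = sub("_slice.*$", "", basename(p))))
    names(images) <- sub("\\.png$", "", basename(img_files))
  }

  proto <- load_protocol()
  ctx <- creep_context(Etf = config$Etf, Em = config$Em,
                       sigma0 = config$sigma0, g1 = config$g1)

  # --- stage 2: segment, strain, fit --------------------------------------
  say("fit: segmenting and fitting %d records", length(records))
  curves <- lapply(names(records), function(id) {
    rec <- records[[id]]
    seg <- tryCatch(segment_record(rec, proto),
                    error = function(e) stop("stage fit, sample ", id, ": ",
                                             conditionMessage(e), call. = FALSE))
    strain_from_displacement(rec, seg)
  })
  fit_table <- fit_all(curves, ctx)

  # --- stage 3: reduced modulus from unload segments ----------------------
  say("modulus: flat-punch analysis of unload segments")
  mod_rows <- lapply(names(records), function(id) {
    rec <- records[[id]]
    seg <- segment_record(rec, proto)
    if (length(seg$unload) < 2L)
      return(data.frame(point_id = id, region = attr(rec, "region"),
                        plane = attr(rec, "plane"), E_star_MPa = NA_real_))
    em <- reduced_modulus_flat_punch(rec$load_mN[seg$unload],
                                     rec$depth_um[seg$unload],
                                     R_um = proto$indenter_radius,
                                     top_fraction = config$top_fraction)
    data.frame(point_id = id, region = attr(rec, "region"),
               plane = attr(rec, "plane"), E_star_MPa = em$E_star_MPa)
  })
  mod_table <- do.call(rbind, mod_rows)
  mod_summary <- stats::aggregate(E_star_MPa ~ region + plane, mod_table, mean)

  # --- stage 4: fiber content ---------------------------------------------
  say("fiber: segmenting %d stained images", length(images))
  vf_rows <- lapply(names(images), function(id) {
    im <- images[[id]]
    mask <- segment_collagen(im$image, hue_window = config$hue_window,
                             sat_min = config$sat_min)
    data.frame(slice_id = id, region = im$region,
               vf = measure_vf(mask)$vf)
  })
  vf_table <- do.call(rbind, vf_rows)
  vf_summary <- do.call(rbind, lapply(split(vf_table, vf_table$region),
    function(d) data.frame(region = d$region[1L],
                           mean_vf = summarize_region(d$vf, d$region[1L])$mean_vf)))
  rownames(vf_summary) <- NULL

  # --- stage 5: report bundle ---------------------------------------------
  f_fit <- file.path(config$out_dir, "creep_parameters.csv")
  f_mod <- file.path(config$out_dir, "reduced_modulus.csv")
  f_vf <- file.path(config$out_dir, "fiber_content.csv")
  utils::write.csv(fit_table, f_fit, row.names = FALSE)
  utils::write.csv(merge(mod_table, mod_summary, by = c("region", "plane"),
                         suffixes = c("", "_region_mean")),
                   f_mod, row.names = FALSE)
  utils::write.csv(merge(vf_table, vf_summary, by = "region"),
                   f_vf, row.names = FALSE)

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pdlcreep")),
    seed = config$seed,
    config = unclass(config),
    config_hash = substr(
      tools::md5sum(files = {
        tf <- tempfile(); writeLines(cfg_json, tf); tf
      })[[1L]], 1, 32),
    log = log_lines,
    outputs = basename(c(f_fit, f_mod, f_vf)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: report bundle in %s", config$out_dir)

  invisible(list(creep_parameters = fit_table, reduced_modulus = mod_table,
                 reduced_modulus_summary = mod_summary,
                 fiber_content = vf_table, fiber_content_summary = vf_summary,
                 manifest = manifest))
}
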