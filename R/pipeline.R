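#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end run, with the frozen study
#' defaults. See the methods vignette for the rationale behind each value.
#'
#' @param seed Master seed; every random draw in the run descends from it.
#' @param ... Named overrides of any default field.
#' @return A named list (`run_config`).
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # geometry
    subdivisions = 3L, radius = 40, center_target = 25,
    face_sigma = 6, house_sigma = 18, peak = 2,
    # normalization
    sigma = 1, pool_radius = 12,
    g_face_low = 1, g_face_high = 1, g_house_low = 0.5, g_house_high = 1,
    # noise
    beta_sd = 0.4, ts_sd = 1, ar1_rho = 0.3,
    # design
    n_subjects = 12L, n_runs = 9L, n_localizer_runs = 2L,
    emit = "betas", tr = 2,
    # ROI line
    mask_radius = 15, n_between = 19L, n_extend = 15L, k = 5L,
    # statistics
    slope_window = c(21L, 30L),
    # MVPA
    mvpa_rois = NULL, n_folds = 5L,
    searchlight = FALSE, searchlight_radius = 5, searchlight_alpha = 10,
    out_dir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  validate_config(cfg)
}

required_config_fields <- function() {
  c("seed", "subdivisions", "radius", "face_sigma", "house_sigma", "peak",
    "sigma", "pool_radius", "g_face_low", "g_face_high", "g_house_low",
    "g_house_high", "beta_sd", "n_subjects", "n_runs", "emit",
    "n_between", "n_extend", "k", "slope_window")
}

#' Validate a pipeline configuration
#'
#' @param cfg Named list.
#' @return The config, invisibly classed `run_config`; errors name the
#'   first missing or invalid field.
#' @export
validate_config <- function(cfg) {
  missing <- setdiff(required_config_fields(), names(cfg))
  if (length(missing)) {
    stop("config is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!cfg$emit %in% c("betas", "timeseries")) {
    stop("config field `emit` must be \"betas\" or \"timeseries\"",
         call. = FALSE)
  }
  if (cfg$n_subjects < 1) stop("config field `n_subjects` must be >= 1", call. = FALSE)
  structure(cfg, class = c("run_config", "list"))
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trips exactly: reading a written config reproduces the run.
#'
#' @param cfg A config list.
#' @param path YAML path.
#' @return `path` invisibly / the validated config.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  int_fields <- c("seed", "subdivisions", "n_subjects", "n_runs",
                  "n_localizer_runs", "n_between", "n_extend", "k", "n_folds")
  for (f in intersect(int_fields, names(cfg))) cfg[[f]] <- as.integer(cfg[[f]])
  if (!is.null(cfg$slope_window)) cfg$slope_window <- as.integer(cfg$slope_window)
  validate_config(cfg)
}

#' Run the full analysis pipeline on a simulated cortex
#'
#' Orchestrates: synthetic cortex construction, localizer and
#' main-experiment simulation, (optionally) GLM beta estimation from time
#' series, per-subject peak localization and virtual-line ROI construction,
#' ROI profiles, selectivity, boundary-window slopes with the asymmetry
#' ANOVA, the two 2 x 3 repeated-measures ANOVAs at the anchor ROIs, per-ROI
#' cross-condition classification at the anchors, and (optionally) a
#' surface searchlight with group test.
#'
#' @param cfg A config from [default_config()] / [read_config()].
#' @return A `report_bundle` list: `profile`, `localizer_profile`,
#'   `selectivity_face`, `selectivity_house`, `slopes`, `asymmetry`,
#'   `anova_face`, `anova_house`, `accuracy`, `searchlight` (or `NULL`),
#'   `lines`, `manifest`. When `cfg$out_dir` is set, CSVs and a JSON
#'   manifest are written there as a side effect.
#' @export
run_pipeline <- function(cfg = default_config()) {
  cfg <- validate_config(cfg)
  t0 <- Sys.time()
  log_stage <- function(name) message(sprintf("[cortexline] %s (%.1fs)", name,
                                              as.numeric(Sys.time() - t0, units = "secs")))

  # --- synthetic cortex -----------------------------------------------
  mesh <- build_sphere_patch_mesh(cfg$subdivisions, cfg$radius)
  centers <- pick_centers(mesh, cfg$center_target %||% 25)
  tuning <- plant_tuning(mesh, centers[1], centers[2],
                         cfg$face_sigma, cfg$house_sigma, cfg$peak)
  norm <- norm_params(cfg$sigma, cfg$pool_radius, cfg$g_face_low,
                      cfg$g_face_high, cfg$g_house_low, cfg$g_house_high)
  tuning <- precompute_pools(tuning, norm)
  noise <- noise_params(cfg$beta_sd, cfg$ts_sd, cfg$ar1_rho, cfg$seed)
  log_stage("synthetic cortex built")

  # --- simulate -------------------------------------------------------
  loc <- simulate_dataset(mesh, tuning, norm,
                          noise_params(cfg$beta_sd, cfg$ts_sd, cfg$ar1_rho,
                                       cfg$seed + 1L),
                          n_subjects = cfg$n_subjects,
                          n_runs = cfg$n_localizer_runs %||% 2L,
                          schedule = localizer_run_schedule(),
                          emit = cfg$emit, tr = cfg$tr %||% 2)
  main <- simulate_dataset(mesh, tuning, norm, noise,
                           n_subjects = cfg$n_subjects, n_runs = cfg$n_runs,
                           emit = cfg$emit, tr = cfg$tr %||% 2)
  loc_betas <- if (cfg$emit == "timeseries") fit_dataset_glm(loc, cfg$tr %||% 2) else loc$betas
  main_betas <- if (cfg$emit == "timeseries") fit_dataset_glm(main, cfg$tr %||% 2) else main$betas
  log_stage("datasets simulated")

  # --- peaks and lines ------------------------------------------------
  # Anatomical-parcel stand-ins: geodesic balls around the planted centers.
  d_face <- geodesic_distances_from(mesh, centers[1])
  d_house <- geodesic_distances_from(mesh, centers[2])
  mask_face <- which(d_face <= cfg$mask_radius %||% 15)
  mask_house <- which(d_house <= cfg$mask_radius %||% 15)

  loc_means <- condition_mean_betas(loc_betas, loc$meta)
  subjects <- unique(loc$meta$subject)
  lines <- lapply(subjects, function(s) {
    maps <- dplyr::filter(loc_means, .data$subject == s)
    contrast <- maps$map[[match("F", maps$condition)]] -
      maps$map[[match("H", maps$condition)]]
    pk_face <- find_peak(contrast, mask_face)$vertex
    pk_house <- find_peak(-contrast, mask_house)$vertex
    build_line_rois(mesh, pk_face, pk_house, cfg$n_between, cfg$n_extend,
                    cfg$k)
  })
  names(lines) <- as.character(subjects)
  log_stage("virtual lines localized")

  # --- profiles -------------------------------------------------------
  main_means <- condition_mean_betas(main_betas, main$meta)
  per_subject_profile <- function(means) {
    purrr::map_dfr(subjects, function(s) {
      roi_profile(dplyr::filter(means, .data$subject == s),
                  lines[[as.character(s)]])
    })
  }
  profile <- per_subject_profile(main_means)
  loc_profile <- per_subject_profile(loc_means)

  sel_face <- selectivity(profile, face_selectivity_pairs())
  sel_house <- selectivity(profile, house_selectivity_pairs())
  slopes <- fit_slopes(profile, cfg$slope_window)
  asym <- slope_asymmetry_anova(profile)
  anchor_a <- lines[[1]]$anchor_a
  anchor_b <- lines[[1]]$anchor_b
  anova_face <- roi_anova(profile, anchor_a, "face", posthoc = TRUE)
  anova_house <- roi_anova(profile, anchor_b, "house", posthoc = TRUE)
  log_stage("profiles and statistics")

  # --- MVPA -----------------------------------------------------------
  mvpa_rois <- cfg$mvpa_rois %||% c(anchor_a, anchor_b)
  accuracy <- purrr::map_dfr(subjects, function(s) {
    rows <- main$meta$subject == s
    ln <- lines[[as.character(s)]]
    purrr::map_dfr(mvpa_rois, function(ri) {
      roi_classify_main(main_betas[rows, ln$rois[[ri]], drop = FALSE],
                        main$meta$condition[rows], main$meta$run[rows],
                        cfg$n_folds %||% 5L, seed = cfg$seed + s) |>
        dplyr::mutate(subject = s, roi = ri, .before = 1)
    })
  })
  log_stage("ROI classification")

  searchlight <- NULL
  if (isTRUE(cfg$searchlight)) {
    sl_cfg <- searchlight_config(radius = cfg$searchlight_radius %||% 5,
                                 alpha = cfg$searchlight_alpha %||% 10,
                                 n_folds = cfg$n_folds %||% 5L)
    keep <- main$meta$condition %in% c("lF", "hF", "lH", "hH")
    acc_maps <- t(vapply(subjects, function(s) {
      rows <- keep & main$meta$subject == s
      surface_searchlight(mesh, main_betas[rows, , drop = FALSE],
                          condition_category(main$meta$condition[rows]),
                          main$meta$run[rows], sl_cfg, seed = cfg$seed + s)
    }, numeric(n_vertices(mesh))))
    searchlight <- list(accuracy_maps = acc_maps,
                        group = group_accuracy_test(acc_maps))
    log_stage("searchlight")
  }

  manifest <- list(
    config = unclass(cfg),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("cortexline")),
    n_vertices = n_vertices(mesh),
    peak_pairs = purrr::map(lines, ~ c(.x$anchor_a, .x$anchor_b)),
    elapsed_s = as.numeric(Sys.time() - t0, units = "secs")
  )

  bundle <- structure(
    list(profile = profile, localizer_profile = loc_profile,
         selectivity_face = sel_face, selectivity_house = sel_house,
         slopes = slopes, asymmetry = asym,
         anova_face = anova_face, anova_house = anova_house,
         accuracy = accuracy, searchlight = searchlight,
         lines = lines, mesh = mesh, tuning = tuning,
         manifest = manifest),
    class = "report_bundle"
  )
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a report bundle to disk
#'
#' Tidy CSVs for every table, JSON for the manifest and ANOVA fits. The
#' manifest (config + seed + version) suffices to reproduce the bundle.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) readr::write_csv(x, file.path(dir, paste0(name, ".csv")))
  wr(bundle$profile, "profile")
  wr(bundle$localizer_profile, "localizer_profile")
  wr(bundle$selectivity_face, "selectivity_face")
  wr(bundle$selectivity_house, "selectivity_house")
  wr(bundle$slopes, "slopes")
  wr(bundle$accuracy, "accuracy")
  wr(tidy(bundle$anova_face), "anova_face")
  wr(tidy(bundle$anova_house), "anova_house")
  wr(tidy(bundle$asymmetry$anova), "asymmetry_anova")
  wr(bundle$asymmetry$contrasts, "asymmetry_contrasts")
  if (!is.null(bundle$searchlight)) wr(bundle$searchlight$group, "searchlight_group")
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> ", length(x$lines), " subjects, ",
      length(x$lines[[1]]$rois), " ROIs/line, seed ", x$manifest$seed,
      "\n", sep = "")
  invisible(x)
}

#' Write / read a per-vertex scalar map as plain text
#'
#' One value per line, ordered by vertex index: the flat-array interchange
#' format for surface maps.
#'
#' @param map Numeric per-vertex vector.
#' @param path File path.
#' @return `path` invisibly / numeric vector.
#' @export
write_vertex_map <- function(map, path) {
  writeLines(format(map, digits = 17, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' @rdname write_vertex_map
#' @export
read_vertex_map <- function(path) as.numeric(readLines(path))
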