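#' Plant two category-tuned patches on a mesh
#'
#' Defines per-vertex face and house tuning weights as geodesic Gaussians
#' around two planted centers. The face patch is narrow and the house patch
#' wide, emulating the narrow spatial distribution of face selectivity
#' against the broad distribution of house selectivity in ventral temporal
#' cortex.
#'
#' @param mesh A `surface_mesh`.
#' @param face_center,house_center 1-based vertex indices of the patch
#'   centers; must be distinct and farther apart (geodesically) than the
#'   larger of the two sigmas.
#' @param face_sigma,house_sigma Gaussian spatial spreads in mm (geodesic).
#' @param peak Tuning weight at each patch center (response units).
#' @return A `tuning_field`: list with `w_face`, `w_house` (numeric vectors,
#'   one value per vertex), the centers, sigmas, `peak`, and the mesh.
#' @export
plant_tuning <- function(mesh, face_center, house_center,
                         face_sigma, house_sigma, peak = 2) {
  nv <- n_vertices(mesh)
  if (face_center == house_center) {
    stop("patch centers must be distinct vertices", call. = FALSE)
  }
  if (any(c(face_center, house_center) < 1) ||
      any(c(face_center, house_center) > nv)) {
    stop("center index out of range", call. = FALSE)
  }
  if (face_sigma <= 0 || house_sigma <= 0) {
    stop("sigmas must be positive", call. = FALSE)
  }
  d_face <- geodesic_distances_from(mesh, face_center)
  d_house <- geodesic_distances_from(mesh, house_center)
  if (d_face[house_center] <= max(face_sigma, house_sigma)) {
    stop("centers are closer than max(face_sigma, house_sigma)", call. = FALSE)
  }
  structure(
    list(
      w_face = peak * exp(-d_face^2 / (2 * face_sigma^2)),
      w_house = peak * exp(-d_house^2 / (2 * house_sigma^2)),
      face_center = face_center, house_center = house_center,
      face_sigma = face_sigma, house_sigma = house_sigma,
      peak = peak, mesh = mesh
    ),
    class = "tuning_field"
  )
}

#' Divisive-normalization parameters
#'
#' The response of a vertex is its stimulus drive divided by a semisaturation
#' constant plus the mean drive of a geodesic neighborhood pool. Face gain is
#' contrast-saturated (equal at low and high contrast) while house gain grows
#' with contrast, which is the minimal asymmetry producing contrast-invariant
#' face responses alongside contrast-dependent, clutter-suppressible house
#' responses.
#'
#' @param sigma Semisaturation constant, response units (> 0).
#' @param pool_radius Normalization pool radius in mm (> 0).
#' @param g_face_low,g_face_high,g_house_low,g_house_high Dimensionless
#'   contrast gains (>= 0); gain is 0 when a category is absent.
#' @return A `norm_params` list.
#' @export
norm_params <- function(sigma = 1, pool_radius = 12,
                        g_face_low = 1, g_face_high = 1,
                        g_house_low = 0.5, g_house_high = 1) {
  stopifnot(sigma > 0, pool_radius > 0,
            g_face_low >= 0, g_face_high >= 0,
            g_house_low >= 0, g_house_high >= 0)
  structure(list(sigma = sigma, pool_radius = pool_radius,
                 g_face_low = g_face_low, g_face_high = g_face_high,
                 g_house_low = g_house_low, g_house_high = g_house_high),
            class = "norm_params")
}

#' Noise parameters for the simulator
#'
#' @param beta_sd Additive Gaussian noise SD on block betas.
#' @param ts_sd Marginal SD of AR(1) time-series noise.
#' @param ar1_rho Lag-1 autocorrelation, in \[0, 1).
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#' @return A `noise_params` list.
#' @export
noise_params <- function(beta_sd = 0.4, ts_sd = 1, ar1_rho = 0.3, seed = 1L) {
  stopifnot(beta_sd >= 0, ts_sd >= 0, ar1_rho >= 0, ar1_rho < 1)
  structure(list(beta_sd = beta_sd, ts_sd = ts_sd, ar1_rho = ar1_rho,
                 seed = as.integer(seed)),
            class = "noise_params")
}

# Localizer blocks present one category at full contrast; map them onto
# the corresponding single-image main-experiment conditions for simulation.
normalize_condition <- function(label) {
  ifelse(label == "F", "hF", ifelse(label == "H", "hH", label))
}

condition_gains <- function(label, norm) {
  fl <- condition_factors(normalize_condition(label))
  g_face <- switch(fl[["face_level"]], none = 0,
                   low = norm$g_face_low, high = norm$g_face_high)
  g_house <- switch(fl[["house_level"]], none = 0,
                    low = norm$g_house_low, high = norm$g_house_high)
  c(g_face = g_face, g_house = g_house)
}

# Sparse row-normalized pool-averaging operator: row v averages over
# vertices within pool_radius geodesic distance of v (v included).
# Cached on the tuning field between calls.
pool_operator <- function(tuning, pool_radius) {
  cache <- attr(tuning, "pool_cache")
  if (!is.null(cache) && isTRUE(all.equal(cache$radius, pool_radius))) {
    return(cache$members)
  }
  D <- geodesic_distance_matrix(tuning$mesh)
  members <- apply(D <= pool_radius, 1, which, simplify = FALSE)
  members
}

#' Precompute pool membership on a tuning field
#'
#' Computing the full geodesic distance matrix dominates simulation start-up;
#' this caches the pool memberships so repeated simulations reuse them.
#'
#' @param tuning A `tuning_field`.
#' @param norm A `norm_params`.
#' @return The tuning field with the pool cache attached.
#' @export
precompute_pools <- function(tuning, norm = norm_params()) {
  members <- pool_operator(tuning, norm$pool_radius)
  attr(tuning, "pool_cache") <- list(radius = norm$pool_radius,
                                     members = members)
  tuning
}

#' Noiseless divisive-normalization response to one condition
#'
#' Drive `D(v) = w_face(v) g_face + w_house(v) g_house`; response
#' `R(v) = D(v) / (sigma + mean of D over the pool of v)`.
#'
#' @param tuning A `tuning_field`.
#' @param condition One of the eight condition labels, or the localizer
#'   labels `"F"` / `"H"` (treated as hF / hH).
#' @param norm A `norm_params`.
#' @return Numeric vector of responses, one per vertex.
#' @export
noiseless_response <- function(tuning, condition, norm = norm_params()) {
  g <- condition_gains(condition, norm)
  drive <- tuning$w_face * g[["g_face"]] + tuning$w_house * g[["g_house"]]
  members <- pool_operator(tuning, norm$pool_radius)
  pool_mean <- vapply(members, function(m) mean(drive[m]), numeric(1))
  drive / (norm$sigma + pool_mean)
}

#' Simulate one block's beta map
#'
#' Noiseless normalization response plus i.i.d. Gaussian beta noise drawn
#' under the stated seed. Reusing one seed across conditions reproduces the
#' identical noise draw, so condition differences are noise-free when wanted.
#'
#' @param tuning A `tuning_field`.
#' @param condition Condition label.
#' @param norm A `norm_params`.
#' @param noise A `noise_params`, or `NULL` for the noiseless response.
#' @return Numeric vertex map of block betas.
#' @export
simulate_block_betas <- function(tuning, condition, norm = norm_params(),
                                 noise = NULL) {
  r <- noiseless_response(tuning, condition, norm)
  if (is.null(noise) || noise$beta_sd == 0) return(r)
  r + rng_local(noise$seed)(stats::rnorm(length(r), sd = noise$beta_sd))
}

# Deterministic per-(subject, run) seed derivation, kept below 2^31.
derive_seed <- function(master, subject, run) {
  as.integer((as.numeric(master) * 7919 + subject * 1009 + run * 97) %% 2147483629)
}

ar1_noise <- function(n, sd, rho, nv) {
  if (sd == 0) return(matrix(0, nv, n))
  innov_sd <- sd * sqrt(1 - rho^2)
  z <- matrix(stats::rnorm(nv * n, sd = innov_sd), nv, n)
  z[, 1] <- z[, 1] / sqrt(1 - rho^2)
  if (rho == 0) return(z)
  # filter every vertex series at once (series along columns)
  t(stats::filter(t(z), rho, method = "recursive"))
}

#' Simulate a multi-subject block-design dataset
#'
#' Per subject and run, draws a randomized main-experiment block order (or
#' uses `schedule` verbatim when supplied), simulates per-block beta maps,
#' and optionally renders voxel time series by convolving the block schedule
#' with the canonical HRF, scaling by the block betas, and adding AR(1)
#' noise. All randomness descends deterministically from
#' `noise$seed -> (subject, run)`.
#'
#' @param mesh A `surface_mesh` (must match the tuning field's mesh).
#' @param tuning A `tuning_field`.
#' @param norm A `norm_params`.
#' @param noise A `noise_params`.
#' @param n_subjects,n_runs Positive counts.
#' @param schedule Optional fixed `block_schedule` used for every run;
#'   `NULL` (default) randomizes the main-experiment block order per run.
#' @param emit `"betas"` or `"timeseries"`.
#' @param tr Repetition time in seconds for time-series output.
#' @return A `synthetic_dataset`: list with `emit`, `meta` (tibble: subject,
#'   run, block, condition), `betas` (rows aligned with `meta`; planted
#'   betas when `emit = "timeseries"`), and for time series a `runs` list of
#'   per-run `timeseries` matrices (vertex x volume) with their schedules.
#' @export
simulate_dataset <- function(mesh, tuning, norm = norm_params(),
                             noise = noise_params(), n_subjects = 12,
                             n_runs = 9, schedule = NULL,
                             emit = c("betas", "timeseries"), tr = 2) {
  emit <- match.arg(emit)
  if (n_subjects < 1 || n_runs < 1) {
    stop("`n_subjects` and `n_runs` must be >= 1", call. = FALSE)
  }
  if (n_vertices(mesh) != length(tuning$w_face)) {
    stop("mesh does not match the tuning field", call. = FALSE)
  }
  tuning <- precompute_pools(tuning, norm)
  labels <- c(condition_table()$label, "F", "H")
  r0 <- vapply(labels, function(l) noiseless_response(tuning, l, norm),
               numeric(n_vertices(mesh)))  # nv x 10 (8 conditions + localizer)

  meta <- list(); beta_rows <- list(); runs <- list()
  hrf <- canonical_hrf(0.1)
  for (s in seq_len(n_subjects)) {
    for (r in seq_len(n_runs)) {
      run_seed <- derive_seed(noise$seed, s, r)
      sched <- if (is.null(schedule)) main_run_schedule(run_seed) else schedule
      blocks <- schedule_blocks(sched)
      nb <- nrow(blocks)
      noise_draw <- rng_local(run_seed)(
        matrix(stats::rnorm(nb * n_vertices(mesh), sd = noise$beta_sd),
               nb, n_vertices(mesh))
      )
      B <- unname(t(r0[, blocks$condition, drop = FALSE])) + noise_draw  # nb x nv
      meta[[length(meta) + 1L]] <- tibble::tibble(
        subject = s, run = r, block = seq_len(nb),
        condition = blocks$condition
      )
      beta_rows[[length(beta_rows) + 1L]] <- B
      if (emit == "timeseries") {
        design <- design_for_schedule(sched, hrf, tr)
        Xb <- design$matrix[, design$block_cols, drop = FALSE]
        Y <- t(Xb %*% B)                                  # nv x n_volumes
        e <- rng_local(run_seed + 1L)(
          ar1_noise(ncol(Y), noise$ts_sd, noise$ar1_rho, nrow(Y))
        )
        runs[[length(runs) + 1L]] <- list(subject = s, run = r,
                                          schedule = sched,
                                          timeseries = Y + e)
      }
    }
  }
  structure(
    list(emit = emit,
         meta = dplyr::bind_rows(meta),
         betas = do.call(rbind, beta_rows),
         runs = if (emit == "timeseries") runs,
         n_vertices = n_vertices(mesh)),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> emit=", x$emit, ", ",
      length(unique(x$meta$subject)), " subjects, ",
      nrow(x$meta), " blocks x ", x$n_vertices, " vertices\n", sep = "")
  invisible(x)
}

#' Estimate block betas from a simulated time-series dataset
#'
#' Runs the block-wise GLM of [fit_glm()] on every run of a
#' `emit = "timeseries"` dataset and returns them in the same row order as
#' the dataset's `meta` table.
#'
#' @param dataset A `synthetic_dataset` with time series.
#' @param tr Repetition time in seconds.
#' @return Matrix of estimated betas, rows aligned with `dataset$meta`.
#' @export
fit_dataset_glm <- function(dataset, tr = 2) {
  if (dataset$emit != "timeseries") {
    stop("dataset was not emitted as time series", call. = FALSE)
  }
  hrf <- canonical_hrf(0.1)
  out <- lapply(dataset$runs, function(rn) {
    design <- design_for_schedule(rn$schedule, hrf, tr)
    fit_glm(rn$timeseries, design)$betas
  })
  do.call(rbind, out)
}

#' Default synthetic-cortex study configuration
#'
#' The frozen study conditions used throughout the package: an icosphere
#' stand-in cortex of radius 40 mm, a narrow face patch and a wide house
#' patch whose centers are roughly 25 mm apart geodesically, asymmetric
#' normalization gains (face contrast-saturated, house contrast-dependent),
#' and moderate beta noise. See the methods vignette for how these were
#' chosen.
#'
#' @param subdivisions Icosphere subdivision level (default 3).
#' @param seed Master RNG seed for the noise model.
#' @return List with `mesh`, `tuning`, `norm`, `noise`.
#' @export
default_simulation <- function(subdivisions = 3, seed = 1L) {
  mesh <- build_sphere_patch_mesh(subdivisions, radius = 40)
  centers <- pick_centers(mesh, target_mm = 25)
  tuning <- plant_tuning(mesh, centers[1], centers[2],
                         face_sigma = 6, house_sigma = 18, peak = 2)
  list(mesh = mesh,
       tuning = precompute_pools(tuning, norm_params()),
       norm = norm_params(),
       noise = noise_params(seed = seed))
}

# Deterministic pair of vertices approximately `target_mm` apart
# geodesically: start from vertex 1, take the vertex whose distance is
# closest to the target.
pick_centers <- function(mesh, target_mm) {
  d <- geodesic_distances_from(mesh, 1)
  c(1L, which.min(abs(d - target_mm)))
}
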