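#' Canonical double-gamma haemodynamic response function
#'
#' The standard two-gamma BOLD impulse response: a positive gamma peaking at
#' 5 s minus an undershoot gamma centred near 15 s scaled by 1/6, normalized
#' to unit peak. Value at t = 0 is exactly 0.
#'
#' @param dt Sampling resolution in seconds, 0 < dt <= 2.
#' @param length_s Kernel support in seconds (default 32).
#' @return An `hrf_kernel`: list with `samples` (values at `t = 0, dt, ...`)
#'   and `dt`.
#' @export
canonical_hrf <- function(dt, length_s = 32) {
  if (length(dt) != 1L || !is.finite(dt) || dt <= 0 || dt > 2) {
    stop("`dt` must be in (0, 2]", call. = FALSE)
  }
  t <- seq(0, length_s, by = dt)
  # shape/rate chosen so modes sit at 5 s and 15 s
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h <- h / max(h)
  structure(list(samples = h, dt = dt), class = "hrf_kernel")
}

# Convolve a boxcar (onset/duration in s) with the HRF on a dt grid and
# sample at volume acquisition times.
regressor_from_block <- function(onset, duration, hrf, tr, n_volumes) {
  dt <- hrf$dt
  total_s <- n_volumes * tr
  n_fine <- ceiling(total_s / dt) + length(hrf$samples)
  box <- numeric(n_fine)
  i0 <- floor(onset / dt) + 1L
  i1 <- min(n_fine, ceiling((onset + duration) / dt))
  box[i0:i1] <- 1
  conv <- stats::convolve(box, rev(hrf$samples), type = "open")[seq_len(n_fine)]
  vol_t <- (seq_len(n_volumes) - 1L) * tr
  conv[floor(vol_t / dt) + 1L]
}

#' Build an HRF-convolved block design matrix
#'
#' One regressor per stimulation block (boxcar convolved with the HRF,
#' sampled at the TR), plus an intercept and a linear drift column.
#'
#' @param schedule A `block_schedule`.
#' @param hrf An `hrf_kernel` from [canonical_hrf()].
#' @param tr Repetition time in seconds (default 2).
#' @param n_volumes Number of volumes; defaults to `run_duration / tr`.
#' @return A `design_matrix`: list with `matrix` (n_volumes x n_regressors),
#'   `block_cols` (indices of block regressors), and `blocks` (tibble of
#'   block, condition, onset for each block regressor).
#' @export
build_design <- function(schedule, hrf = canonical_hrf(0.1), tr = 2,
                         n_volumes = NULL) {
  blocks <- schedule_blocks(schedule)
  run_dur <- attr(schedule, "run_duration")
  if (is.null(n_volumes)) n_volumes <- as.integer(round(run_dur / tr))
  if (nrow(blocks) > 0 && max(blocks$onset + blocks$duration) > n_volumes * tr + 1e-9) {
    stop("schedule does not fit within n_volumes * tr", call. = FALSE)
  }
  X_blocks <- if (nrow(blocks) == 0) {
    matrix(0, n_volumes, 0)
  } else {
    vapply(seq_len(nrow(blocks)), function(i) {
      regressor_from_block(blocks$onset[i], blocks$duration[i], hrf, tr, n_volumes)
    }, numeric(n_volumes))
  }
  drift <- seq_len(n_volumes) - (n_volumes + 1) / 2
  X <- cbind(X_blocks, intercept = 1, drift = drift / max(abs(drift)))
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  colnames(X) <- c(if (nrow(blocks)) paste0("block", seq_len(nrow(blocks))),
                   "intercept", "drift")
  structure(
    list(
      matrix = X,
      qr = qr(X),
      block_cols = seq_len(nrow(blocks)),
      blocks = tibble::tibble(block = seq_len(nrow(blocks)),
                              condition = blocks$condition,
                              onset = blocks$onset)
    ),
    class = "design_matrix"
  )
}

# Designs depend on the block onsets/durations, not the condition labels,
# so runs sharing a timing grid share one matrix; memoize on the timing.
.design_cache <- new.env(parent = emptyenv())

design_for_schedule <- function(schedule, hrf, tr) {
  blocks <- schedule_blocks(schedule)
  key <- paste(c(blocks$onset, blocks$duration, tr, hrf$dt,
                 attr(schedule, "run_duration")), collapse = "_")
  cached <- .design_cache[[key]]
  if (is.null(cached)) {
    cached <- build_design(schedule, hrf = hrf, tr = tr)
    .design_cache[[key]] <- cached
  }
  # re-label the cached matrix with this run's conditions
  cached$blocks$condition <- blocks$condition
  cached
}

#' Fit a block-wise GLM by ordinary least squares
#'
#' Estimates one beta per stimulation block per vertex. Nuisance columns
#' (intercept, drift) are estimated jointly but not returned.
#'
#' @param timeseries Numeric matrix, vertices x time points.
#' @param design A `design_matrix` from [build_design()].
#' @return A `beta_series`: list with `betas` (block x vertex matrix) and
#'   `blocks` (the design's block tibble).
#' @export
fit_glm <- function(timeseries, design) {
  Y <- as.matrix(timeseries)
  X <- design$matrix
  if (ncol(Y) != nrow(X)) {
    stop("time dimension of `timeseries` does not match the design",
         call. = FALSE)
  }
  if (any(!is.finite(Y))) stop("non-finite values in `timeseries`", call. = FALSE)
  coef <- qr.coef(design$qr %||% qr(X), t(Y))   # regressors x vertices
  betas <- coef[design$block_cols, , drop = FALSE]
  structure(list(betas = unname(betas), blocks = design$blocks),
            class = "beta_series")
}

#' @export
print.beta_series <- function(x, ...) {
  cat("<beta_series> ", nrow(x$betas), " blocks x ", ncol(x$betas),
      " vertices\n", sep = "")
  invisible(x)
}
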