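#' The eight-condition factorial stimulus space
#'
#' The main experiment crosses face contrast (none / low / high) with house
#' contrast (none / low / high), omitting the empty (none, none) cell and the
#' single-category cells being the four single-image conditions. Low contrast
#' is 0.025 RMS and high contrast 0.25 RMS in normalized units.
#'
#' @return A tibble with columns `label`, `face_level`, `house_level`,
#'   `face_rms`, `house_rms`; one row per condition in canonical order
#'   (lF, hF, lH, hH, lFlH, lFhH, hFlH, hFhH).
#' @examples
#' condition_table()
#' @export
condition_table <- function() {
  tibble::tibble(
    label = c("lF", "hF", "lH", "hH", "lFlH", "lFhH", "hFlH", "hFhH"),
    face_level = c("low", "high", "none", "none", "low", "low", "high", "high"),
    house_level = c("none", "none", "low", "high", "low", "high", "low", "high")
  ) |>
    dplyr::mutate(
      face_rms = contrast_rms(.data$face_level),
      house_rms = contrast_rms(.data$house_level)
    )
}

#' RMS value of a named contrast level
#'
#' @param level Character vector of levels in `none`, `low`, `high`.
#' @return Numeric vector: `NA` for none, 0.025 for low, 0.25 for high.
#' @export
contrast_rms <- function(level) {
  unname(c(none = NA_real_, low = 0.025, high = 0.25)[level])
}

#' Map a condition label to its factorial levels
#'
#' @param label One of the eight condition labels.
#' @return Named character vector with elements `face_level` and
#'   `house_level`.
#' @examples
#' condition_factors("lFhH") # face low, house high
#' @export
condition_factors <- function(label) {
  tab <- condition_table()
  i <- match(label, tab$label)
  if (any(is.na(i))) {
    stop("unknown condition label: ", paste(label[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  if (length(label) == 1L) {
    c(face_level = tab$face_level[i], house_level = tab$house_level[i])
  } else {
    tab[i, c("label", "face_level", "house_level")]
  }
}

#' Transform an image to a target RMS contrast
#'
#' RMS contrast is the population standard deviation of normalized pixel
#' intensities. The transform rescales deviations about the (preserved) mean
#' so the output hits `target_rms` exactly; if that pushes pixels outside
#' \[0, 1\], they are clipped and the scale re-estimated iteratively until
#' the post-clip RMS is within `tol` of the target.
#'
#' @param image Numeric matrix with values in \[0, 1\] and at least two
#'   distinct values.
#' @param target_rms Positive target RMS contrast in normalized units
#'   (0.025 for the low-contrast stimuli, 0.25 for the high-contrast ones).
#' @param tol Acceptable absolute deviation of the achieved RMS after
#'   clipping (default 1e-3).
#' @param max_iter Maximum clip-and-rescale iterations (default 50).
#' @return The transformed image matrix.
#' @examples
#' img <- matrix(c(0.4, 0.6), 1)
#' rms_transform(img, 0.025) # 0.475, 0.525
#' @export
rms_transform <- function(image, target_rms, tol = 1e-3, max_iter = 50L) {
  image <- as.matrix(image)
  if (any(!is.finite(image))) stop("image has non-finite values", call. = FALSE)
  if (target_rms <= 0) stop("`target_rms` must be positive", call. = FALSE)
  mu <- mean(image)
  dev <- image - mu
  s <- pop_sd(image)
  if (s == 0) stop("constant image: RMS contrast undefined", call. = FALSE)

  out <- mu + dev * (target_rms / s)
  if (min(out) >= 0 && max(out) <= 1) return(out)

  # clipping removes contrast; inflate the pre-clip scale until the
  # post-clip RMS converges onto the target
  scale <- target_rms / s
  for (i in seq_len(max_iter)) {
    clipped <- pmin(pmax(mu + dev * scale, 0), 1)
    achieved <- pop_sd(clipped)
    if (abs(achieved - target_rms) <= tol) return(clipped)
    if (achieved == 0) break
    scale <- scale * target_rms / achieved
  }
  stop("RMS target unreachable after clipping iterations", call. = FALSE)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Superimpose two stimulus images
#'
#' Pixelwise mean of the two images, with no re-normalization afterwards:
#' the contrast of an overlapping-image condition is emergent from its
#' components.
#'
#' @param face_img,house_img Equal-size numeric matrices in \[0, 1\].
#' @return The blended image matrix.
#' @export
overlay <- function(face_img, house_img) {
  if (!identical(dim(face_img), dim(house_img))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  (face_img + house_img) / 2
}

#' Procedurally generated face and house stimulus images
#'
#' Schematic grayscale stimuli for tests and demonstrations: the face is an
#' oval with internal features, the house a rectilinear grid pattern. These
#' are stand-ins with the right statistics (non-constant, mid-gray mean),
#' not photographs.
#'
#' @param size Image side length in pixels.
#' @param which `"face"` or `"house"`.
#' @param seed Optional integer; adds seeded pixel jitter so repeated calls
#'   can produce distinct exemplars.
#' @return Numeric `size` x `size` matrix in \[0, 1\].
#' @export
synth_stimulus <- function(size = 64L, which = c("face", "house"), seed = NULL) {
  which <- match.arg(which)
  xy <- expand.grid(x = seq(-1, 1, length.out = size),
                    y = seq(-1, 1, length.out = size))
  x <- matrix(xy$x, size, size)
  y <- matrix(xy$y, size, size)
  img <- matrix(0.5, size, size)
  if (which == "face") {
    oval <- (x / 0.7)^2 + (y / 0.9)^2 <= 1
    img[oval] <- 0.7
    eye_l <- (x + 0.25)^2 + (y - 0.25)^2 <= 0.01
    eye_r <- (x - 0.25)^2 + (y - 0.25)^2 <= 0.01
    mouth <- abs(y + 0.35) <= 0.05 & abs(x) <= 0.3
    nose <- abs(x) <= 0.04 & y > -0.2 & y < 0.15
    img[eye_l | eye_r | mouth | nose] <- 0.25
  } else {
    body <- abs(x) <= 0.8 & y <= 0.4 & y >= -0.9
    img[body] <- 0.65
    roof <- y > 0.4 & y <= 0.9 & abs(x) <= 0.8 * (1 - (y - 0.4) / 0.5)
    img[roof] <- 0.35
    wx <- (x + 1) %% 0.4 < 0.2
    wy <- (y + 1) %% 0.35 < 0.17
    img[body & wx & wy] <- 0.3
  }
  if (!is.null(seed)) {
    r <- rng_local(seed)
    img <- img + r(stats::rnorm(length(img), sd = 0.02))
    img <- pmin(pmax(img, 0), 1)
  }
  img
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. Returns a function applied to its argument so the
# call site reads r(rnorm(...)).
rng_local <- function(seed) {
  function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
  }
}

block_entries <- function(labels, block_dur, fix_dur, start_fix,
                          n_items, item_dur, isi) {
  onsets <- start_fix + (seq_along(labels) - 1) * (block_dur + fix_dur)
  stim <- tibble::tibble(
    onset = onsets, duration = block_dur, condition = labels,
    n_items = n_items, item_duration = item_dur, isi = isi
  )
  fix <- tibble::tibble(
    onset = c(0, onsets + block_dur), duration = c(start_fix, rep(fix_dur, length(onsets))),
    condition = "FIX", n_items = 0L, item_duration = 0, isi = 0
  )
  dplyr::arrange(dplyr::bind_rows(stim, fix), .data$onset)
}

#' Main-experiment block schedule
#'
#' One run presents each of the eight conditions once in 16 s blocks
#' (8 images, 1700 ms presentation + 300 ms ISI each), starting with 16 s of
#' fixation and interleaving 16 s fixation after every block: 272 s total.
#'
#' @param block_order Either a character permutation of the eight condition
#'   labels, or a single integer seed from which a random order is drawn.
#' @return A `block_schedule`: a tibble of (onset, duration, condition)
#'   entries, sorted and gap-free, with attributes `run_duration` (s) and
#'   `schedule_type`.
#' @examples
#' sched <- main_run_schedule(seed_order(1))
#' attr(sched, "run_duration") # 272
#' @export
main_run_schedule <- function(block_order) {
  labels <- condition_table()$label
  if (is.numeric(block_order) && length(block_order) == 1L) {
    block_order <- seed_order(block_order)
  }
  if (!setequal(block_order, labels) || length(block_order) != 8L) {
    stop("`block_order` must contain each of the 8 condition labels exactly once",
         call. = FALSE)
  }
  entries <- block_entries(block_order, block_dur = 16, fix_dur = 16,
                           start_fix = 16, n_items = 8L,
                           item_dur = 1.7, isi = 0.3)
  new_block_schedule(entries, type = "main")
}

#' Draw a random block order for the main experiment
#' @param seed Integer seed.
#' @return Character vector: a permutation of the eight condition labels.
#' @export
seed_order <- function(seed) {
  labels <- condition_table()$label
  rng_local(seed)(sample(labels))
}

#' Localizer block schedule
#'
#' Five face and five house blocks in strict alternation (F, H, F, ...),
#' each 16 s (16 images, 500 ms presentation + 500 ms ISI) followed by 16 s
#' fixation, after an initial 16 s fixation: 336 s total.
#'
#' @return A `block_schedule` tibble (see [main_run_schedule()]).
#' @export
localizer_run_schedule <- function() {
  labels <- rep(c("F", "H"), 5)
  entries <- block_entries(labels, block_dur = 16, fix_dur = 16,
                           start_fix = 16, n_items = 16L,
                           item_dur = 0.5, isi = 0.5)
  new_block_schedule(entries, type = "localizer")
}

new_block_schedule <- function(entries, type) {
  entries <- dplyr::arrange(entries, .data$onset)
  offs <- entries$onset + entries$duration
  if (any(abs(entries$onset[-1] - offs[-length(offs)]) > 1e-9)) {
    stop("schedule has gaps or overlaps", call. = FALSE)
  }
  structure(entries,
            run_duration = max(offs),
            schedule_type = type,
            class = c("block_schedule", class(entries)))
}

#' Stimulation blocks of a schedule
#' @param schedule A `block_schedule`.
#' @return The non-fixation rows as a tibble.
#' @export
schedule_blocks <- function(schedule) {
  dplyr::filter(tibble::as_tibble(schedule), .data$condition != "FIX")
}

#' Export a schedule as a BIDS-style events table
#'
#' @param schedule A `block_schedule`.
#' @param path Output TSV path.
#' @return `path`, invisibly. Columns: onset, duration, trial_type.
#' @export
write_events_tsv <- function(schedule, path) {
  ev <- tibble::as_tibble(schedule)[, c("onset", "duration", "condition")]
  names(ev)[3] <- "trial_type"
  readr::write_tsv(ev, path)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE)
  names(ev)[names(ev) == "trial_type"] <- "condition"
  ev$n_items <- 0L; ev$item_duration <- 0; ev$isi <- 0
  new_block_schedule(ev, type = "imported")
}
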