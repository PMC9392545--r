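#' Condition-mean beta maps per subject
#'
#' Averages block betas within condition per run, then across runs, giving
#' one vertex map per subject and condition. These condition means feed the
#' univariate profile analyses; block-level betas feed pattern
#' classification.
#'
#' @param betas Matrix of block betas, rows aligned with `meta`.
#' @param meta Tibble with columns `subject`, `run`, `condition` (one row
#'   per block, matching `betas`).
#' @return Tibble with columns `subject`, `condition`, and a list-column
#'   `map` holding the per-vertex mean beta vector.
#' @export
condition_mean_betas <- function(betas, meta) {
  stopifnot(nrow(betas) == nrow(meta))
  idx <- tibble::tibble(row = seq_len(nrow(meta)),
                        subject = meta$subject, run = meta$run,
                        condition = meta$condition)
  idx |>
    dplyr::group_by(.data$subject, .data$run, .data$condition) |>
    dplyr::summarise(map = list(colMeans(betas[.data$row, , drop = FALSE])),
                     .groups = "drop") |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::summarise(map = list(Reduce(`+`, .data$map) / length(.data$map)),
                     .groups = "drop")
}

#' Reduce condition-mean betas to an ROI x condition profile
#'
#' Each cell is the mean over the ROI's vertices of the subject's
#' condition-mean beta map.
#'
#' @param cond_means Output of [condition_mean_betas()] (or any tibble with
#'   `subject`, `condition`, list-column `map`).
#' @param line A `roi_line`.
#' @return Tibble: `subject`, `roi` (1-based ROI index), `condition`,
#'   `beta`.
#' @export
roi_profile <- function(cond_means, line) {
  nv <- length(cond_means$map[[1]])
  if (max(unlist(line$rois)) > nv) {
    stop("ROI references a vertex beyond the map length", call. = FALSE)
  }
  roi_means <- function(map) {
    vapply(line$rois, function(v) mean(map[v]), numeric(1))
  }
  cond_means |>
    dplyr::mutate(cell = purrr::map(.data$map, ~ tibble::tibble(
      roi = seq_along(line$rois), beta = roi_means(.x)
    ))) |>
    dplyr::select("subject", "condition", "cell") |>
    tidyr::unnest("cell") |>
    dplyr::select("subject", "roi", "condition", "beta") |>
    dplyr::arrange(.data$subject, .data$roi, .data$condition)
}

#' Default selectivity contrast pairs
#'
#' Face selectivity contrasts each face-containing condition against the
#' house-only condition of matching contrast; house selectivity contrasts
#' each house-containing condition against the face-only condition of
#' matching contrast.
#'
#' @return A list of (preferred, nonpreferred) label pairs.
#' @export
face_selectivity_pairs <- function() {
  list(c("lF", "lH"), c("hF", "hH"), c("lFlH", "lH"),
       c("lFhH", "hH"), c("hFlH", "lH"), c("hFhH", "hH"))
}

#' @rdname face_selectivity_pairs
#' @export
house_selectivity_pairs <- function() {
  list(c("lH", "lF"), c("hH", "hF"), c("lFlH", "lF"),
       c("lFhH", "lF"), c("hFlH", "hF"), c("hFhH", "hF"))
}

#' Selectivity: preferred minus nonpreferred beta
#'
#' @param profile A profile tibble from [roi_profile()].
#' @param pairs List of (preferred, nonpreferred) condition label pairs;
#'   defaults to the face pairs.
#' @return Tibble: `subject`, `roi`, `preferred`, `nonpreferred`,
#'   `selectivity`.
#' @export
selectivity <- function(profile, pairs = face_selectivity_pairs()) {
  labs <- unique(profile$condition)
  for (p in pairs) {
    if (!all(p %in% labs)) {
      stop("conditions not present in profile: ", paste(p, collapse = ", "),
           call. = FALSE)
    }
  }
  wide <- tidyr::pivot_wider(profile, names_from = "condition",
                             values_from = "beta")
  purrr::map_dfr(pairs, function(p) {
    tibble::tibble(subject = wide$subject, roi = wide$roi,
                   preferred = p[1], nonpreferred = p[2],
                   selectivity = wide[[p[1]]] - wide[[p[2]]])
  }) |>
    dplyr::arrange(.data$subject, .data$roi)
}

#' Per-ROI paired t-test between two conditions
#'
#' Paired across subjects at every ROI, two-sided, Bonferroni-corrected
#' across the ROIs on the line. ROIs with zero variance of the paired
#' differences are flagged degenerate and assigned p = 1.
#'
#' @param profile A profile tibble ([roi_profile()]).
#' @param cond_a,cond_b Condition labels to compare (a minus b).
#' @param correction Multiplicity correction; only `"bonferroni"`.
#' @return Tibble: `roi`, `mean_diff`, `t`, `df`, `p`, `p_corrected`,
#'   `degenerate`.
#' @export
paired_t_profile <- function(profile, cond_a, cond_b,
                             correction = "bonferroni") {
  correction <- match.arg(correction)
  wide <- profile |>
    dplyr::filter(.data$condition %in% c(cond_a, cond_b)) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "beta")
  if (length(unique(wide$subject)) < 3) {
    stop("need at least 3 subjects", call. = FALSE)
  }
  res <- wide |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(
      mean_diff = mean(.data[[cond_a]] - .data[[cond_b]]),
      sd_diff = stats::sd(.data[[cond_a]] - .data[[cond_b]]),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(
      degenerate = .data$sd_diff == 0,
      t = ifelse(.data$degenerate, 0,
                 .data$mean_diff / (.data$sd_diff / sqrt(.data$n))),
      df = .data$n - 1L,
      p = ifelse(.data$degenerate, 1,
                 2 * stats::pt(abs(.data$t), .data$df, lower.tail = FALSE)),
      p_corrected = pmin(1, .data$p * dplyr::n())
    )
  dplyr::select(res, "roi", "mean_diff", "t", "df", "p", "p_corrected",
                "degenerate")
}

#' Factorial cell assignments for the two 2 x 3 designs
#'
#' The face design crosses face contrast (low, high) with house contrast
#' (none, low, high) over the six face-containing conditions; the house
#' design crosses house contrast (low, high) with face contrast (none, low,
#' high) over the six house-containing conditions.
#'
#' @return Tibble: `label`, `a` (2-level factor), `b` (3-level factor).
#' @export
face_design_cells <- function() {
  tibble::tibble(
    label = c("lF", "lFlH", "lFhH", "hF", "hFlH", "hFhH"),
    a = rep(c("low", "high"), each = 3),
    b = rep(c("none", "low", "high"), 2)
  )
}

#' @rdname face_design_cells
#' @export
house_design_cells <- function() {
  tibble::tibble(
    label = c("lH", "lFlH", "hFlH", "hH", "lFhH", "hFhH"),
    a = rep(c("low", "high"), each = 3),
    b = rep(c("none", "low", "high"), 2)
  )
}

#' Two-way repeated-measures ANOVA on a 2 x 3 within-subject design
#'
#' Classical univariate within-subject partition: each effect is tested
#' against its own subject-interaction error term (A against A x S, B
#' against B x S, A x B against A x B x S). No sphericity correction is
#' applied by default; Greenhouse-Geisser is available for the 3-level
#' factor.
#'
#' @param data Tibble with columns `subject`, `a`, `b`, `value`; one row
#'   per subject x cell (complete, balanced).
#' @param posthoc If `TRUE`, adds Bonferroni-corrected pairwise paired
#'   t-tests among the six cells.
#' @param gg Apply Greenhouse-Geisser correction to effects involving the
#'   3-level factor.
#' @return A `cortex_anova` object; see [tidy.cortex_anova()].
#' @export
rm_anova_2x3 <- function(data, posthoc = FALSE, gg = FALSE) {
  data <- dplyr::mutate(data,
                        subject = factor(.data$subject),
                        a = factor(.data$a), b = factor(.data$b))
  counts <- dplyr::count(data, .data$subject, .data$a, .data$b)
  if (any(counts$n != 1) ||
      nrow(counts) != length(levels(data$subject)) *
        length(levels(data$a)) * length(levels(data$b))) {
    stop("design must be complete and balanced (one value per subject x cell)",
         call. = FALSE)
  }
  if (length(levels(data$subject)) < 3) {
    stop("need at least 3 subjects", call. = FALSE)
  }
  fit <- stats::aov(value ~ a * b + Error(subject / (a * b)), data = data)
  sm <- summary(fit)
  pull_effect <- function(stratum, term) {
    tab <- sm[[paste0("Error: ", stratum)]][[1]]
    i <- match(term, trimws(rownames(tab)))
    r <- match("Residuals", trimws(rownames(tab)))
    ss <- tab[["Sum Sq"]][i]
    # an exactly-zero effect sum of squares is a zero effect even when the
    # error stratum is also degenerate (0/0)
    degen <- isTRUE(all.equal(ss, 0))
    tibble::tibble(
      effect = term,
      df1 = tab$Df[i], df2 = tab$Df[r],
      ss = ss, ss_error = tab[["Sum Sq"]][r],
      F = if (degen) 0 else tab[["F value"]][i],
      p = if (degen) 1 else tab[["Pr(>F)"]][i]
    )
  }
  effects <- dplyr::bind_rows(
    pull_effect("subject:a", "a"),
    pull_effect("subject:b", "b"),
    pull_effect("subject:a:b", "a:b")
  )
  if (gg) {
    eps <- gg_epsilon(data)
    effects <- effects |>
      dplyr::mutate(
        epsilon = ifelse(.data$effect == "a", 1, eps[.data$effect]),
        p = ifelse(.data$effect == "a", .data$p,
                   stats::pf(.data$F, .data$df1 * .data$epsilon,
                             .data$df2 * .data$epsilon, lower.tail = FALSE))
      )
  }
  contrasts <- NULL
  if (posthoc) {
    wide <- data |>
      dplyr::mutate(cell = interaction(.data$a, .data$b, sep = ":")) |>
      dplyr::select("subject", "cell", "value") |>
      tidyr::pivot_wider(names_from = "cell", values_from = "value")
    cells <- setdiff(names(wide), "subject")
    cmb <- utils::combn(cells, 2)
    contrasts <- purrr::map_dfr(seq_len(ncol(cmb)), function(i) {
      d <- wide[[cmb[1, i]]] - wide[[cmb[2, i]]]
      tt <- stats::t.test(d)
      tibble::tibble(cell_1 = cmb[1, i], cell_2 = cmb[2, i],
                     mean_diff = mean(d), t = unname(tt$statistic),
                     p = tt$p.value)
    }) |>
      dplyr::mutate(p_corrected = pmin(1, .data$p * dplyr::n()))
  }
  structure(list(effects = effects, contrasts = contrasts,
                 correction = if (gg) "greenhouse-geisser" else "none",
                 n_subjects = length(levels(data$subject))),
            class = "cortex_anova")
}

# Greenhouse-Geisser epsilon for the b and a:b effects of a 2x3 design.
gg_epsilon <- function(data) {
  eps_from <- function(mat) {
    S <- stats::cov(mat)
    k <- ncol(S)
    C <- diag(k) - 1 / k
    Sc <- C %*% S %*% C
    sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  }
  wide_b <- data |>
    dplyr::group_by(.data$subject, .data$b) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "b", values_from = "value")
  wide_ab <- data |>
    dplyr::mutate(cell = interaction(.data$a, .data$b)) |>
    tidyr::pivot_wider(id_cols = "subject", names_from = "cell",
                       values_from = "value")
  c(b = eps_from(as.matrix(wide_b[, -1])),
    `a:b` = eps_from(as.matrix(wide_ab[, -1])))
}

#' @export
print.cortex_anova <- function(x, ...) {
  cat("<cortex_anova> two-way repeated measures,", x$n_subjects,
      "subjects, correction:", x$correction, "\n")
  print(as.data.frame(x$effects), digits = 4)
  if (!is.null(x$contrasts)) {
    cat("posthoc contrasts (Bonferroni):\n")
    print(as.data.frame(x$contrasts), digits = 4)
  }
  invisible(x)
}

#' Tidy a repeated-measures ANOVA fit
#'
#' @param x A `cortex_anova`.
#' @param ... Unused.
#' @return Tibble of effects: `effect`, `df1`, `df2`, `F`, `p`.
#' @export
tidy.cortex_anova <- function(x, ...) {
  dplyr::select(x$effects, "effect", "df1", "df2", "F", "p")
}

#' @rdname tidy.cortex_anova
#' @export
glance.cortex_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects,
                 correction = x$correction,
                 n_significant_05 = sum(x$effects$p < 0.05))
}

#' Run the 2 x 3 ANOVA on one ROI of a profile
#'
#' Maps conditions onto the requested factorial design and fits
#' [rm_anova_2x3()].
#'
#' @param profile Profile tibble.
#' @param roi ROI index to test.
#' @param design `"face"` or `"house"`.
#' @param ... Passed to [rm_anova_2x3()].
#' @return A `cortex_anova`.
#' @export
roi_anova <- function(profile, roi, design = c("face", "house"), ...) {
  design <- match.arg(design)
  cells <- if (design == "face") face_design_cells() else house_design_cells()
  data <- profile |>
    dplyr::filter(.data$roi == !!roi, .data$condition %in% cells$label) |>
    dplyr::inner_join(cells, by = c(condition = "label")) |>
    dplyr::select("subject", "a", "b", value = "beta")
  rm_anova_2x3(data, ...)
}

#' Per-subject regression slopes of beta on ROI index
#'
#' OLS slope of the profile against the ROI index over a contiguous window,
#' per subject and condition; the boundary window between the two anchors
#' is indices 21-30 on the default 51-ROI line.
#'
#' @param profile Profile tibble.
#' @param window Length-2 inclusive ROI-index range (default `c(21, 30)`).
#' @param conditions Conditions to fit (default: all present).
#' @return Tibble: `subject`, `condition`, `window`, `slope` (response
#'   units per ROI step).
#' @export
fit_slopes <- function(profile, window = c(21, 30), conditions = NULL) {
  if (diff(window) < 1) stop("window must span at least 2 ROIs", call. = FALSE)
  if (is.null(conditions)) conditions <- unique(profile$condition)
  if (!all(window %in% profile$roi)) {
    stop("window outside the profile's ROI range", call. = FALSE)
  }
  profile |>
    dplyr::filter(.data$condition %in% conditions,
                  .data$roi >= window[1], .data$roi <= window[2]) |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::summarise(
      slope = stats::cov(.data$roi, .data$beta) / stats::var(.data$roi),
      .groups = "drop"
    ) |>
    dplyr::mutate(window = paste0("[", window[1], ",", window[2], "]"))
}

#' Slope-asymmetry ANOVA across boundary and non-boundary windows
#'
#' Compares how steeply face-only versus house-only responses change on the
#' boundary side against their non-boundary sides: slopes are fitted per
#' subject for face-only (lF, hF) and house-only (lH, hH) conditions in the
#' windows \[1,10\] (face non-boundary), \[21,30\] (boundary) and \[41,50\]
#' (house non-boundary); a category x side repeated-measures ANOVA is run on
#' the per-subject category means, followed by the three planned paired
#' contrasts with Bonferroni correction.
#'
#' @param profile Profile tibble covering ROIs 1-51.
#' @param windows Named list of the three windows.
#' @return List with `anova` (a `cortex_anova`), `contrasts` (tibble) and
#'   `slopes` (per-subject slopes by category and side).
#' @export
slope_asymmetry_anova <- function(profile,
                                  windows = list(face_nonboundary = c(1, 10),
                                                 boundary = c(21, 30),
                                                 house_nonboundary = c(41, 50))) {
  need <- unlist(windows)
  if (!all(need %in% profile$roi)) stop("missing window ROIs", call. = FALSE)
  cat_conds <- list(face = c("lF", "hF"), house = c("lH", "hH"))
  grab <- function(win, conds) {
    fit_slopes(profile, windows[[win]], conds) |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(slope = mean(.data$slope), .groups = "drop")
  }
  slopes <- dplyr::bind_rows(
    dplyr::mutate(grab("boundary", cat_conds$face),
                  category = "face", side = "boundary"),
    dplyr::mutate(grab("face_nonboundary", cat_conds$face),
                  category = "face", side = "nonboundary"),
    dplyr::mutate(grab("boundary", cat_conds$house),
                  category = "house", side = "boundary"),
    dplyr::mutate(grab("house_nonboundary", cat_conds$house),
                  category = "house", side = "nonboundary")
  )
  fit <- rm_anova_2x2(slopes)
  wide <- tidyr::pivot_wider(slopes, id_cols = "subject",
                             names_from = c("category", "side"),
                             values_from = "slope")
  contrast <- function(x, y, name) {
    d <- wide[[x]] - wide[[y]]
    if (stats::sd(d) == 0) {
      return(tibble::tibble(contrast = name, mean_diff = mean(d),
                            t = 0, p = 1))
    }
    tt <- stats::t.test(d)
    tibble::tibble(contrast = name, mean_diff = mean(d),
                   t = unname(tt$statistic), p = tt$p.value)
  }
  contrasts <- dplyr::bind_rows(
    contrast("face_boundary", "face_nonboundary",
             "face boundary vs face non-boundary"),
    contrast("face_boundary", "house_nonboundary",
             "face boundary vs house non-boundary"),
    contrast("face_nonboundary", "house_boundary",
             "face non-boundary vs house boundary")
  ) |>
    dplyr::mutate(p_corrected = pmin(1, .data$p * 3))
  list(anova = fit, contrasts = contrasts, slopes = slopes)
}

# 2x2 within-subject ANOVA (category x side), same error-term scheme as
# the 2x3.
rm_anova_2x2 <- function(slopes) {
  data <- slopes |>
    dplyr::transmute(subject = factor(.data$subject),
                     a = factor(.data$category), b = factor(.data$side),
                     value = .data$slope)
  fit <- stats::aov(value ~ a * b + Error(subject / (a * b)), data = data)
  sm <- summary(fit)
  pull <- function(stratum, term, label) {
    tab <- sm[[paste0("Error: ", stratum)]][[1]]
    i <- match(term, trimws(rownames(tab)))
    r <- match("Residuals", trimws(rownames(tab)))
    ss <- tab[["Sum Sq"]][i]
    degen <- isTRUE(all.equal(ss, 0))
    tibble::tibble(effect = label, df1 = tab$Df[i], df2 = tab$Df[r],
                   ss = ss, ss_error = tab[["Sum Sq"]][r],
                   F = if (degen) 0 else tab[["F value"]][i],
                   p = if (degen) 1 else tab[["Pr(>F)"]][i])
  }
  effects <- dplyr::bind_rows(
    pull("subject:a", "a", "category"),
    pull("subject:b", "b", "side"),
    pull("subject:a:b", "a:b", "category:side")
  )
  structure(list(effects = effects, contrasts = NULL, correction = "none",
                 n_subjects = length(unique(slopes$subject))),
            class = "cortex_anova")
}

#' Centered moving average
#'
#' @param values Ordered numeric sequence.
#' @param window Odd window length (default 5).
#' @return Smoothed sequence, shorter by `window - 1` ( `(window-1)/2`
#'   entries dropped at each end).
#' @export
moving_average <- function(values, window = 5L) {
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (window > length(values)) stop("window longer than sequence", call. = FALSE)
  out <- stats::filter(values, rep(1 / window, window), sides = 2)
  as.numeric(out[!is.na(out)])
}
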