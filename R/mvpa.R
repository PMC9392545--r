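#' Assign runs to cross-validation folds
#'
#' Folds are grouped by run (all blocks of a run share a fold) so that
#' training and test samples never come from the same run, and the
#' assignment is seeded for reproducibility.
#'
#' @param runs Integer vector of run ids, one per sample.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer fold id per sample.
#' @export
make_run_folds <- function(runs, n_folds = 5L, seed = 1L) {
  ids <- sort(unique(runs))
  if (length(ids) < n_folds) {
    stop("need at least `n_folds` distinct runs", call. = FALSE)
  }
  shuffled <- rng_local(seed)(sample(ids))
  fold_of <- rep(seq_len(n_folds), length.out = length(ids))
  fold_of[order(match(ids, shuffled))][match(runs, ids)]
}

svm_train <- function(X, y) {
  e1071::svm(x = X, y = factor(y, levels = c("face", "house")),
             kernel = "linear", cost = 1, scale = FALSE)
}

#' Classify face vs house patterns in one ROI (localizer scheme)
#'
#' Linear maximum-margin classification with fivefold run-grouped
#' cross-validation; the reported accuracy is the mean over folds.
#'
#' @param features Numeric matrix, samples x vertices.
#' @param labels Character vector, `"face"` / `"house"` per sample.
#' @param runs Run id per sample (folds group runs).
#' @param n_folds,seed Fold construction (see [make_run_folds()]).
#' @return Mean cross-validated accuracy in \[0, 1\].
#' @export
roi_classify_localizer <- function(features, labels, runs, n_folds = 5L,
                                   seed = 1L) {
  features <- as.matrix(features)
  if (length(unique(labels)) < 2) {
    stop("need samples from both classes", call. = FALSE)
  }
  folds <- make_run_folds(runs, n_folds, seed)
  accs <- vapply(seq_len(n_folds), function(f) {
    tr <- folds != f
    fit <- svm_train(features[tr, , drop = FALSE], labels[tr])
    pred <- stats::predict(fit, features[!tr, , drop = FALSE])
    mean(as.character(pred) == labels[!tr])
  }, numeric(1))
  mean(accs)
}

single_image_conditions <- function() c("lF", "hF", "lH", "hH")
overlap_conditions <- function() c("lFlH", "lFhH", "hFlH", "hFhH")

condition_category <- function(condition) {
  ifelse(condition %in% c("lF", "hF"), "face",
         ifelse(condition %in% c("lH", "hH"), "house", NA_character_))
}

#' Cross-condition classification in one ROI (main-experiment scheme)
#'
#' Trains the face/house classifier on single-image conditions under a
#' fivefold run-grouped scheme, labels the held-out single-image samples per
#' fold, and additionally labels every overlapping-image sample with each
#' fold's classifier; overlap predictions are merged by majority vote over
#' the five fold classifiers (ties called "face"). Face accuracy for a
#' condition is the fraction of its samples labeled "face"; house accuracy
#' the fraction labeled "house".
#'
#' @param features Samples x vertices matrix (block betas of the ROI).
#' @param conditions Condition label per sample.
#' @param runs Run id per sample.
#' @param n_folds,seed Fold construction.
#' @return Tibble: `condition`, `category` ("face" over lF, hF and the four
#'   overlaps; "house" over lH, hH and the four overlaps), `accuracy`,
#'   `n_samples`.
#' @export
roi_classify_main <- function(features, conditions, runs, n_folds = 5L,
                              seed = 1L) {
  features <- as.matrix(features)
  single <- conditions %in% single_image_conditions()
  if (!any(single)) stop("no single-image training samples", call. = FALSE)
  folds <- make_run_folds(runs, n_folds, seed)

  pred_single <- character(nrow(features))
  overlap_votes <- matrix(NA_character_, nrow(features), n_folds)
  for (f in seq_len(n_folds)) {
    tr <- single & folds != f
    fit <- svm_train(features[tr, , drop = FALSE],
                     condition_category(conditions[tr]))
    te <- single & folds == f
    if (any(te)) {
      pred_single[te] <- as.character(stats::predict(fit, features[te, , drop = FALSE]))
    }
    ov <- !single
    if (any(ov)) {
      overlap_votes[ov, f] <- as.character(stats::predict(fit, features[ov, , drop = FALSE]))
    }
  }
  pred <- pred_single
  ov <- !single
  if (any(ov)) {
    face_votes <- rowSums(overlap_votes[ov, , drop = FALSE] == "face")
    pred[ov] <- ifelse(face_votes >= n_folds / 2, "face", "house")
  }

  face_conds <- c("lF", "hF", overlap_conditions())
  house_conds <- c("lH", "hH", overlap_conditions())
  acc_for <- function(conds, category) {
    purrr::map_dfr(conds, function(cc) {
      i <- conditions == cc
      tibble::tibble(condition = cc, category = category,
                     accuracy = mean(pred[i] == category),
                     n_samples = sum(i))
    })
  }
  dplyr::bind_rows(acc_for(face_conds, "face"), acc_for(house_conds, "house"))
}

#' Per-subject, per-ROI accuracy table along a line
#'
#' Applies [roi_classify_main()] at each requested ROI of a line for every
#' subject in a block-beta dataset.
#'
#' @param betas Block-beta matrix, rows aligned with `meta`.
#' @param meta Tibble: `subject`, `run`, `condition` per row.
#' @param line A `roi_line`.
#' @param rois ROI indices to classify (default: all).
#' @param n_folds,seed Fold construction.
#' @return Tibble: `subject`, `roi`, `condition`, `category`, `accuracy`.
#' @export
accuracy_table <- function(betas, meta, line, rois = NULL, n_folds = 5L,
                           seed = 1L) {
  if (is.null(rois)) rois <- seq_along(line$rois)
  subjects <- unique(meta$subject)
  purrr::map_dfr(subjects, function(s) {
    rows <- meta$subject == s
    purrr::map_dfr(rois, function(ri) {
      X <- betas[rows, line$rois[[ri]], drop = FALSE]
      roi_classify_main(X, meta$condition[rows], meta$run[rows],
                        n_folds, seed) |>
        dplyr::mutate(subject = s, roi = ri, .before = 1)
    })
  })
}

#' Searchlight configuration
#'
#' @param radius Disk radius in mm (geodesic, default 5).
#' @param alpha Ridge regularization strength (default 10).
#' @param n_folds Cross-validation folds (default 5).
#' @param chance Chance accuracy (default 0.5).
#' @param alpha_threshold Group-test significance threshold, uncorrected
#'   (default 0.001).
#' @param euclidean Use Euclidean instead of geodesic disks.
#' @return A `searchlight_config` list.
#' @export
searchlight_config <- function(radius = 5, alpha = 10, n_folds = 5L,
                               chance = 0.5, alpha_threshold = 0.001,
                               euclidean = FALSE) {
  stopifnot(radius > 0, n_folds >= 2)
  structure(list(radius = radius, alpha = alpha, n_folds = n_folds,
                 chance = chance, alpha_threshold = alpha_threshold,
                 euclidean = euclidean),
            class = "searchlight_config")
}

# Ridge regression classifier with intercept; class codes face = +1,
# house = -1; decision by sign with ties called face.
ridge_fit <- function(X, y_pm1, alpha) {
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  ym <- mean(y_pm1)
  A <- crossprod(Xc) + diag(alpha, ncol(X))
  w <- solve(A, crossprod(Xc, y_pm1 - ym))
  list(w = w, b = ym - sum(xm * w))
}

ridge_cv_accuracy <- function(X, labels, folds, alpha) {
  y <- ifelse(labels == "face", 1, -1)
  accs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- ridge_fit(X[tr, , drop = FALSE], y[tr], alpha)
    score <- X[!tr, , drop = FALSE] %*% fit$w + fit$b
    mean(ifelse(score >= 0, 1, -1) == y[!tr])
  }, numeric(1))
  mean(accs)
}

#' Surface searchlight decoding of face vs house
#'
#' For every mesh vertex, collects the block betas of all vertices within
#' the configured disk radius (geodesic by default), runs a ridge-regression
#' classifier (regularization `alpha`) with run-grouped fivefold
#' cross-validation on face-only vs house-only samples, and stores the mean
#' accuracy at the center vertex.
#'
#' @param mesh A `surface_mesh`.
#' @param betas Samples x vertices block-beta matrix (face-only and
#'   house-only conditions).
#' @param labels `"face"` / `"house"` per sample.
#' @param runs Run id per sample.
#' @param cfg A [searchlight_config()].
#' @param seed Fold seed.
#' @param dist Optional precomputed vertex distance matrix (saves the
#'   dominant cost when decoding several subjects on one mesh).
#' @return Numeric per-vertex accuracy map.
#' @export
surface_searchlight <- function(mesh, betas, labels, runs,
                                cfg = searchlight_config(), seed = 1L,
                                dist = NULL) {
  betas <- as.matrix(betas)
  stopifnot(ncol(betas) == n_vertices(mesh))
  D <- dist %||% if (cfg$euclidean) {
    as.matrix(stats::dist(mesh$vertices))
  } else {
    geodesic_distance_matrix(mesh)
  }
  folds <- make_run_folds(runs, cfg$n_folds, seed)
  vapply(seq_len(n_vertices(mesh)), function(v) {
    disk <- which(D[v, ] <= cfg$radius)
    ridge_cv_accuracy(betas[, disk, drop = FALSE], labels, folds, cfg$alpha)
  }, numeric(1))
}

#' Group-level test of accuracy maps against chance
#'
#' Per-vertex one-sample t-test of subject accuracies against chance,
#' two-sided, thresholded uncorrected. Vertices with zero variance across
#' subjects are flagged degenerate (t undefined) and never marked
#' significant.
#'
#' @param acc Subjects x vertices accuracy matrix.
#' @param chance Chance level (default 0.5).
#' @param alpha_threshold Uncorrected p threshold (default 0.001).
#' @return Tibble: `vertex`, `mean_accuracy`, `t`, `p`, `significant`,
#'   `degenerate`.
#' @export
group_accuracy_test <- function(acc, chance = 0.5, alpha_threshold = 0.001) {
  acc <- as.matrix(acc)
  if (nrow(acc) < 3) stop("need at least 3 subjects", call. = FALSE)
  n <- nrow(acc)
  m <- colMeans(acc)
  s <- apply(acc, 2, stats::sd)
  degenerate <- s == 0
  t <- ifelse(degenerate, NA_real_, (m - chance) / (s / sqrt(n)))
  p <- ifelse(degenerate, NA_real_,
              2 * stats::pt(abs(t), n - 1, lower.tail = FALSE))
  tibble::tibble(
    vertex = seq_len(ncol(acc)),
    mean_accuracy = m, t = t, p = p,
    significant = !degenerate & p < alpha_threshold,
    degenerate = degenerate
  )
}

#' Dice overlap between a significance mask and planted patch support
#'
#' @param significant Logical per-vertex vector.
#' @param support Logical per-vertex vector (e.g. tuning weight above 10%
#'   of peak).
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_overlap <- function(significant, support) {
  2 * sum(significant & support) / (sum(significant) + sum(support))
}
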