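# Simple two-class Gaussian pattern generator over run-structured samples.
make_patterns <- function(n_runs = 10, mu_face, mu_house, sd = 0.1,
                          per_run = 2) {
  p <- length(mu_face)
  n <- n_runs * per_run * 2
  labels <- rep(rep(c("face", "house"), each = per_run), n_runs)
  runs <- rep(seq_len(n_runs), each = per_run * 2)
  mu <- t(vapply(labels, function(l) if (l == "face") mu_face else mu_house,
                 numeric(p)))
  X <- mu + matrix(stats::rnorm(n * p, sd = sd), n, p)
  list(X = X, labels = labels, runs = runs)
}

test_that("run-grouped folds are deterministic and never split a run", {
  runs <- rep(1:10, each = 4)
  f1 <- make_run_folds(runs, 5, seed = 3)
  f2 <- make_run_folds(runs, 5, seed = 3)
  expect_identical(f1, f2)
  expect_false(identical(f1, make_run_folds(runs, 5, seed = 4)))
  per_run <- tapply(f1, runs, function(x) length(unique(x)))
  expect_true(all(per_run == 1))
  expect_setequal(unique(f1), 1:5)
  expect_error(make_run_folds(1:3, 5), "distinct runs")
})

test_that("separable patterns decode perfectly; uninformative ones at chance", {
  set.seed(10)
  pats <- make_patterns(10, mu_face = rep(2, 5), mu_house = rep(-2, 5),
                        sd = 0.1)
  expect_equal(roi_classify_localizer(pats$X, pats$labels, pats$runs), 1.0)

  # identical class means: accuracy within a generous binomial band of 0.5
  pats0 <- make_patterns(10, mu_face = rep(0, 5), mu_house = rep(0, 5),
                         sd = 1)
  acc0 <- roi_classify_localizer(pats0$X, pats0$labels, pats0$runs)
  expect_gt(acc0, 0.2); expect_lt(acc0, 0.8)
  expect_error(roi_classify_localizer(pats$X, rep("face", 40), pats$runs),
               "both classes")
})

test_that("label-shuffled classification is centred on chance", {
  set.seed(77)
  accs <- vapply(1:100, function(i) {
    pats <- make_patterns(5, mu_face = rep(2, 4), mu_house = rep(-2, 4),
                          sd = 0.5)
    # permute labels within run, keeping folds class-balanced
    shuffled <- unlist(tapply(pats$labels, pats$runs, sample,
                              simplify = FALSE), use.names = FALSE)
    roi_classify_localizer(pats$X, shuffled, pats$runs, seed = i)
  }, numeric(1))
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.01)
})

make_main_samples <- function(n_runs, response, sd, seed) {
  # response: named list condition -> mean pattern
  set.seed(seed)
  conds <- rep(names(response), n_runs)
  runs <- rep(seq_len(n_runs), each = length(response))
  mu <- t(vapply(conds, function(cc) response[[cc]], numeric(length(response[[1]]))))
  list(X = mu + matrix(stats::rnorm(length(conds) * ncol(mu), sd = sd),
                       nrow = length(conds)),
       conditions = conds, runs = runs)
}

test_that("cross-condition generalization labels overlaps by proximity", {
  p <- 5
  resp <- list(lF = rep(2, p), hF = rep(2, p),
               lH = rep(-2, p), hH = rep(-2, p),
               lFlH = rep(2, p),      # sits on the face class mean
               lFhH = rep(0.001, p),  # midway
               hFlH = rep(2, p), hFhH = rep(-2, p))
  s <- make_main_samples(10, resp, sd = 0.05, seed = 2)
  acc <- roi_classify_main(s$X, s$conditions, s$runs)
  face_acc <- function(cc) acc$accuracy[acc$condition == cc &
                                          acc$category == "face"]
  expect_equal(face_acc("lFlH"), 1.0)
  expect_equal(face_acc("hFlH"), 1.0)
  expect_equal(face_acc("hFhH"), 0.0)
  expect_equal(face_acc("lF"), 1.0)
  # house view of the same predictions
  house_acc <- function(cc) acc$accuracy[acc$condition == cc &
                                           acc$category == "house"]
  expect_equal(house_acc("hFhH"), 1.0)
  expect_equal(house_acc("lH"), 1.0)
  # face accuracy is reported for 6 conditions, house for 6
  expect_equal(sum(acc$category == "face"), 6)
  expect_equal(sum(acc$category == "house"), 6)
})

test_that("samples midway between class means split near-evenly", {
  set.seed(55)
  p <- 4
  accs <- vapply(1:50, function(i) {
    resp <- list(lF = rep(1, p), hF = rep(1, p),
                 lH = rep(-1, p), hH = rep(-1, p),
                 lFlH = rep(0, p), lFhH = rep(0, p),
                 hFlH = rep(0, p), hFhH = rep(0, p))
    s <- make_main_samples(10, resp, sd = 0.7, seed = i)
    acc <- roi_classify_main(s$X, s$conditions, s$runs, seed = i)
    mean(acc$accuracy[acc$condition == "lFlH" & acc$category == "face"])
  }, numeric(1))
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.05)
})

test_that("ridge classification equals whole-mesh decoding for huge disks", {
  mesh <- build_sphere_patch_mesh(0, 10)
  set.seed(9)
  pats <- make_patterns(5, mu_face = stats::rnorm(12),
                        mu_house = stats::rnorm(12), sd = 0.5)
  cfg <- searchlight_config(radius = 1e6)
  sl <- surface_searchlight(mesh, pats$X, pats$labels, pats$runs, cfg,
                            seed = 1)
  whole <- cortexline:::ridge_cv_accuracy(
    pats$X, pats$labels, make_run_folds(pats$runs, 5, 1), alpha = 10)
  expect_true(all(sl == whole))
})

test_that("searchlight finds planted signal and stays at chance elsewhere", {
  sim <- default_sim_cache(2)
  mesh <- sim$mesh
  nz <- noise_params(beta_sd = 0.2, seed = 33)
  ds <- simulate_dataset(mesh, sim$tuning, sim$norm, nz, n_subjects = 1,
                         n_runs = 10)
  keep <- ds$meta$condition %in% c("lF", "hF", "lH", "hH")
  labels <- cortexline:::condition_category(ds$meta$condition[keep])
  # coarse desk-scale mesh: use a radius spanning the nearest neighbours
  cfg <- searchlight_config(radius = 12)
  sl <- surface_searchlight(mesh, ds$betas[keep, ], labels,
                            ds$meta$run[keep], cfg, seed = 2)
  expect_gt(sl[sim$tuning$face_center], 0.9)
  expect_gt(sl[sim$tuning$house_center], 0.9)
  d_face <- geodesic_distances_from(mesh, sim$tuning$face_center)
  d_house <- geodesic_distances_from(mesh, sim$tuning$house_center)
  far <- d_face > 3 * sim$tuning$face_sigma + cfg$radius &
    d_house > 3 * sim$tuning$house_sigma + cfg$radius
  if (any(far)) expect_lt(mean(sl[far]), 0.75)
})

test_that("group_accuracy_test matches the one-sample t formula", {
  # brute-force oracle on a 4-subject toy map
  acc <- rbind(c(0.5, 0.9, 0.55), c(0.5, 0.85, 0.45),
               c(0.5, 0.95, 0.6), c(0.5, 0.88, 0.5))
  res <- group_accuracy_test(acc, chance = 0.5, alpha_threshold = 0.001)
  expect_true(res$degenerate[1])
  expect_false(res$significant[1])
  x <- acc[, 2]
  t_manual <- (mean(x) - 0.5) / (stats::sd(x) / sqrt(4))
  expect_equal(res$t[2], t_manual)
  expect_equal(res$p[2], 2 * stats::pt(abs(t_manual), 3, lower.tail = FALSE))

  # strong accuracy with n = 12 is significant
  set.seed(3)
  acc12 <- matrix(stats::rnorm(12, 0.9, 0.02), ncol = 1)
  expect_true(group_accuracy_test(acc12)$significant)
  expect_error(group_accuracy_test(acc[1:2, ]), "3 subjects")
})

test_that("dice_overlap follows the set formula", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  b <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(dice_overlap(a, b), 2 * 1 / (2 + 2))
  expect_equal(dice_overlap(a, a), 1)
})
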