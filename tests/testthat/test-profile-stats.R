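make_profile <- function(values) {
  # values: named function(subject, roi, condition) -> beta, or a constant
  grid <- expand.grid(subject = 1:4, roi = 1:6,
                      condition = c("lF", "lH"), stringsAsFactors = FALSE)
  grid$beta <- if (is.function(values)) {
    mapply(values, grid$subject, grid$roi, grid$condition)
  } else {
    values
  }
  tibble::as_tibble(grid)
}

test_that("roi_profile averages condition means over ROI vertices", {
  mesh <- build_sphere_patch_mesh(1, 40)
  line <- build_line_rois(mesh, 1, 30, n_between = 3, n_extend = 1, k = 5)
  nv <- 42
  # constant map -> every cell equals the constant
  cm <- tibble::tibble(subject = 1L, condition = "lF",
                       map = list(rep(3.5, nv)))
  prof <- roi_profile(cm, line)
  expect_true(all(prof$beta == 3.5))
  expect_equal(nrow(prof), length(line$rois))
  # known vertex values -> arithmetic mean
  m <- numeric(nv); m[line$rois[[2]]] <- 1:5
  prof2 <- roi_profile(tibble::tibble(subject = 1L, condition = "lF",
                                      map = list(m)), line)
  expect_equal(prof2$beta[prof2$roi == 2], 3)
  # random inputs match a brute-force loop
  set.seed(4)
  mm <- stats::rnorm(nv)
  prof3 <- roi_profile(tibble::tibble(subject = 1L, condition = "lF",
                                      map = list(mm)), line)
  brute <- vapply(line$rois, function(v) sum(mm[v]) / length(v), numeric(1))
  expect_equal(prof3$beta, brute)
})

test_that("condition_mean_betas averages within run then across runs", {
  betas <- rbind(c(1, 2), c(3, 4),   # subj 1 run 1: lF, lF
                 c(10, 20))          # subj 1 run 2: lF
  meta <- tibble::tibble(subject = 1, run = c(1, 1, 2),
                         condition = "lF")
  cm <- condition_mean_betas(betas, meta)
  # run means (2,3) and (10,20), then across runs: (6, 11.5)
  expect_equal(cm$map[[1]], c(6, 11.5))
})

test_that("selectivity is the cellwise preferred minus nonpreferred difference", {
  prof <- make_profile(function(s, r, c) if (c == "lF") 1.2 else 0.4)
  sel <- selectivity(prof, list(c("lF", "lH")))
  expect_equal(sel$selectivity, rep(0.8, nrow(sel)))
  # a condition against itself is exactly zero
  sel0 <- selectivity(prof, list(c("lF", "lF")))
  expect_true(all(sel0$selectivity == 0))
  expect_length(face_selectivity_pairs(), 6)
  expect_length(house_selectivity_pairs(), 6)
  expect_error(selectivity(prof, list(c("lF", "zz"))), "not present")
})

test_that("paired_t_profile matches the textbook formula and flags degeneracy", {
  # identical conditions -> t = 0, p = 1 everywhere
  prof_eq <- make_profile(function(s, r, c) s + r)
  res_eq <- paired_t_profile(prof_eq, "lF", "lH")
  expect_true(all(res_eq$t == 0))
  expect_true(all(res_eq$p == 1))
  expect_true(all(res_eq$degenerate))

  # hand-computed 4-subject oracle at one ROI
  dvals <- c(0.8, 1.1, 0.7, 1.0)   # planted paired differences
  prof <- make_profile(function(s, r, c) {
    if (c == "lF") dvals[s] else 0
  })
  res <- paired_t_profile(prof, "lF", "lH")
  t_manual <- mean(dvals) / (stats::sd(dvals) / sqrt(4))
  p_manual <- 2 * stats::pt(abs(t_manual), 3, lower.tail = FALSE)
  expect_equal(res$t[1], t_manual)
  expect_equal(res$p[1], p_manual)
  expect_equal(res$p_corrected[1], min(1, p_manual * 6))
  expect_equal(res$df[1], 3)
})

test_that("paired_t_profile power matches the noncentral-t closed form", {
  # planted difference 1.0, difference SD 0.5, n = 12, Bonferroni over the
  # 5 ROIs: closed-form power at corrected p < .001
  tcrit <- stats::qt(1 - (0.001 / 5) / 2, df = 11)
  power <- stats::pt(tcrit, df = 11, ncp = sqrt(12) / 0.5,
                     lower.tail = FALSE)   # 0.852
  set.seed(31)
  hits <- vapply(1:100, function(i) {
    prof <- purrr::map_dfr(1:12, function(s) {
      tibble::tibble(subject = s, roi = rep(1:5, 2),
                     condition = rep(c("lF", "lH"), each = 5),
                     beta = c(stats::rnorm(5, c(1, 0, 0, 0, 0), 0.5),
                              rep(0, 5)))
    })
    res <- paired_t_profile(prof, "lF", "lH")
    res$p_corrected[res$roi == 1] < 0.001
  }, logical(1))
  margin <- 3 * sqrt(power * (1 - power) / length(hits))
  expect_gt(mean(hits), power - margin)
  expect_lt(mean(hits), power + margin)
})


test_that("rm_anova_2x3 matches an independent sum-of-squares oracle", {
  set.seed(17)
  df <- expand.grid(subject = as.character(1:3),
                    a = c("low", "high"), b = c("none", "low", "high"),
                    stringsAsFactors = FALSE)
  df$value <- round(stats::rnorm(nrow(df), mean = 1), 2)
  fit <- rm_anova_2x3(tibble::as_tibble(df))
  orc <- oracle_rm_anova(df)
  td <- tidy(fit)
  expect_equal(td$F[td$effect == "a"], orc$F_a)
  expect_equal(td$F[td$effect == "b"], orc$F_b)
  expect_equal(td$F[td$effect == "a:b"], orc$F_ab)
  expect_equal(td$df1, c(1, 2, 2))
  expect_equal(td$df2, c(2, 4, 4))
  expect_true(all(td$p >= 0 & td$p <= 1))
})

test_that("rm_anova_2x3 degenerate and planted-effect behaviour", {
  df <- expand.grid(subject = 1:4, a = c("l", "h"),
                    b = c("n", "lo", "hi"), stringsAsFactors = FALSE)
  df$value <- 1
  fit <- rm_anova_2x3(tibble::as_tibble(df))
  expect_true(all(tidy(fit)$F == 0))
  expect_true(all(tidy(fit)$p == 1))

  # additive effect on factor b only
  set.seed(23)
  sig_b <- 0; sig_a <- 0
  for (i in 1:10) {
    df$value <- stats::rnorm(nrow(df), 0, 0.3) +
      c(n = 0, lo = 1, hi = 2)[df$b]
    td <- tidy(rm_anova_2x3(tibble::as_tibble(df)))
    sig_b <- sig_b + (td$p[td$effect == "b"] < 0.01)
    sig_a <- sig_a + (td$p[td$effect == "a"] < 0.01)
  }
  expect_gte(sig_b, 9)
  expect_lte(sig_a, 2)

  # unbalanced input is rejected
  expect_error(rm_anova_2x3(tibble::as_tibble(df[-1, ])), "balanced")
})

test_that("posthoc contrasts are Bonferroni-corrected paired t-tests", {
  set.seed(5)
  df <- expand.grid(subject = 1:5, a = c("l", "h"),
                    b = c("n", "lo", "hi"), stringsAsFactors = FALSE)
  df$value <- stats::rnorm(nrow(df))
  fit <- rm_anova_2x3(tibble::as_tibble(df), posthoc = TRUE)
  expect_equal(nrow(fit$contrasts), choose(6, 2))
  i <- 1
  cells <- strsplit(c(fit$contrasts$cell_1[i], fit$contrasts$cell_2[i]), ":")
  d <- df$value[df$a == cells[[1]][1] & df$b == cells[[1]][2]] -
    df$value[df$a == cells[[2]][1] & df$b == cells[[2]][2]]
  expect_equal(fit$contrasts$p_corrected[i],
               min(1, stats::t.test(d)$p.value * choose(6, 2)))
})

test_that("fit_slopes recovers trivial and planted slopes", {
  prof <- make_profile(3)   # flat
  prof$roi <- rep(rep(21:26, each = 4), 2)
  expect_true(all(fit_slopes(prof, c(21, 26))$slope == 0))
  prof$beta <- prof$roi     # identity
  expect_true(all(fit_slopes(prof, c(21, 26))$slope == 1))
  expect_error(fit_slopes(prof, c(21, 21)), "at least 2")
  expect_error(fit_slopes(prof, c(50, 60)), "outside")

  # noisy planted slope: mean recovered within 2 SE
  set.seed(41)
  est <- vapply(1:12, function(s) {
    p <- tibble::tibble(subject = s, roi = 21:30, condition = "lF",
                        beta = -0.3 * (21:30) + stats::rnorm(10, 0, 0.2))
    fit_slopes(p, c(21, 30))$slope
  }, numeric(1))
  se <- stats::sd(est) / sqrt(12)
  expect_lt(abs(mean(est) + 0.3), 2 * se + 0.02)
})

test_that("slope_asymmetry_anova is null on identical slopes and detects asymmetry", {
  mkprof <- function(f) {
    purrr::map_dfr(1:8, function(s) {
      g <- tidyr::expand_grid(roi = 1:51,
                              condition = c("lF", "hF", "lH", "hH"))
      g$subject <- s
      g$beta <- purrr::map2_dbl(g$roi, g$condition, function(r, c) f(s, r, c))
      g
    })
  }
  # identical linear trend for every condition -> no effects, p = 1
  flat <- mkprof(function(s, r, c) 0.1 * r)
  res <- slope_asymmetry_anova(flat)
  expect_true(all(tidy(res$anova)$F == 0))
  expect_true(all(res$contrasts$p == 1))

  # planted asymmetry: face boundary slope -0.3, all else flat
  set.seed(13)
  asym <- mkprof(function(s, r, c) {
    base <- if (c %in% c("lF", "hF") && r >= 21 && r <= 30) -0.3 * r else 0
    base + stats::rnorm(1, 0, 0.05)
  })
  res2 <- slope_asymmetry_anova(asym)
  key <- res2$contrasts[res2$contrasts$contrast ==
                          "face boundary vs face non-boundary", ]
  expect_lt(key$p_corrected, 0.05)
  td <- tidy(res2$anova)
  expect_lt(td$p[td$effect == "category:side"], 0.05)

  # symmetric x-shaped change -> interaction detected
  xshape <- mkprof(function(s, r, c) {
    slope <- if (c %in% c("lF", "hF")) -0.3 else 0.3
    if (r >= 21 && r <= 30) slope * r + stats::rnorm(1, 0, 0.05) else
      stats::rnorm(1, 0, 0.05)
  })
  res3 <- slope_asymmetry_anova(xshape)
  td3 <- tidy(res3$anova)
  expect_lt(td3$p[td3$effect == "category:side"], 0.05)
})

test_that("moving_average equals a brute-force windowed mean", {
  expect_equal(moving_average(rep(2, 10), 5), rep(2, 6))
  expect_equal(moving_average(1:5, 5), 3)
  set.seed(2)
  x <- stats::rnorm(20)
  got <- moving_average(x, 5)
  brute <- vapply(3:18, function(i) mean(x[(i - 2):(i + 2)]), numeric(1))
  expect_equal(got, brute)
  expect_error(moving_average(1:10, 4), "odd")
  expect_error(moving_average(1:3, 5), "longer")
})

test_that("gp_smooth tracks noiseless structure and shrinks noise", {
  # noiseless linear input: posterior mean stays on the line at interior points
  y <- seq(0, 2, length.out = 15)
  sm <- gp_smooth(y)
  expect_lt(max(abs(sm[3:13] - y[3:13])), 1e-2)
  # constant input is returned unchanged
  expect_equal(as.numeric(gp_smooth(rep(1.3, 8))), rep(1.3, 8))
  expect_error(gp_smooth(1:3), "at least 5")
  # variance reduction on white noise
  set.seed(19)
  shrunk <- vapply(1:50, function(i) {
    x <- stats::rnorm(20)
    stats::var(as.numeric(gp_smooth(x))) <= stats::var(x)
  }, logical(1))
  expect_true(all(shrunk))
})

test_that("gp_smooth_profile smooths per subject and condition", {
  set.seed(6)
  prof <- tidyr::expand_grid(subject = 1:2, condition = c("lF", "lH"),
                             roi = 1:20) |>
    dplyr::mutate(beta = sin(roi / 3) + stats::rnorm(dplyr::n(), 0, 0.3))
  sm <- gp_smooth_profile(prof)
  expect_equal(dim(sm), dim(prof))
  rough <- function(x) sum(diff(x)^2)
  raw1 <- dplyr::filter(prof, subject == 1, condition == "lF") |>
    dplyr::arrange(roi) |> dplyr::pull(beta)
  sm1 <- dplyr::filter(sm, subject == 1, condition == "lF") |>
    dplyr::arrange(roi) |> dplyr::pull(beta)
  expect_lt(rough(sm1), rough(raw1))
})
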