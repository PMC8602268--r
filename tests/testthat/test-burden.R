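make_meta <- function(ages, group = "healthy", clones_per_patient = 1) {
  n <- length(ages) * clones_per_patient
  tibble::tibble(
    clone_id = paste0("c", seq_len(n)),
    patient_id = rep(paste0("p", seq_along(ages)), each = clones_per_patient),
    age = rep(ages, each = clones_per_patient),
    group = group
  )
}

test_that("noiseless data recover the generating slope exactly through the origin", {
  meta <- make_meta(c(20, 35, 50, 65), clones_per_patient = 2)
  counts <- tibble::tibble(clone_id = meta$clone_id, count = 46 * meta$age)
  fit <- fit_burden_regression(counts, meta)
  expect_equal(fit$m, 46, tolerance = 1e-6)
  # zero-intercept contract: prediction at age 0 is the origin by model form
  expect_equal(fit$m * 0, 0)
})

test_that("all-zero counts yield a flagged zero-slope fit", {
  meta <- make_meta(c(30, 40))
  counts <- tibble::tibble(clone_id = meta$clone_id, count = c(0, 0))
  fit <- fit_burden_regression(counts, meta)
  expect_equal(fit$m, 0)
  expect_true(fit$degenerate)
})

test_that("single-patient groups fall back to zero-intercept OLS", {
  meta <- make_meta(50, clones_per_patient = 3)
  counts <- tibble::tibble(clone_id = meta$clone_id,
                           count = c(2280, 2310, 2350))
  expect_message(fit <- fit_burden_regression(counts, meta), "OLS")
  expect_equal(fit$method, "ols")
  expect_equal(fit$m, mean(counts$count / 50), tolerance = 1e-6)
  expect_gt(fit$se, 0)
})

test_that("slope Z-test matches its closed form and is antisymmetric", {
  fa <- mutaccum:::new_burden_fit("a", m = 50, se = 3, ci95 = 6, var = 100,
                                  10, 5, "lme", FALSE)
  fb <- mutaccum:::new_burden_fit("b", m = 46, se = 4, ci95 = 8, var = 100,
                                  10, 5, "lme", FALSE)
  zt <- slope_z_test(fa, fb)
  expect_equal(zt$Z, (50 - 46) / sqrt(3^2 + 4^2))
  expect_equal(zt$p_z, 2 * pnorm(-abs(zt$Z)))
  # identical fits -> Z = 0, p = 1
  z0 <- slope_z_test(fa, fa)
  expect_equal(z0$Z, 0)
  expect_equal(z0$p_z, 1)
  # unit difference -> p = 2 * pnorm(-1)
  fc <- mutaccum:::new_burden_fit("c", m = 46 + 5, se = 3, ci95 = 6,
                                  var = 100, 10, 5, "lme", FALSE)
  z1 <- slope_z_test(fc, fb)
  expect_equal(z1$Z, 1)
  expect_equal(z1$p_z, 2 * pnorm(-1), tolerance = 1e-12)
  expect_equal(z1$p_z, 0.3173105, tolerance = 1e-6)
  # antisymmetry
  swap <- slope_z_test(fb, fa)
  expect_equal(swap$Z, -zt$Z)
  expect_equal(swap$p_z, zt$p_z)
  # strict printed form warns and can be undefined
  expect_warning(expect_error(slope_z_test(fa, fb, strict_printed = TRUE),
                              "undefined"))
})

test_that("variance F-test follows the one-sided F distribution", {
  mk <- function(v, n) mutaccum:::new_burden_fit("g", 46, 2, 4, v, n, 5,
                                                 "lme", FALSE)
  eq <- variance_f_test(mk(100, 13), mk(100, 13))
  expect_equal(eq$F, 1)
  ft <- variance_f_test(mk(400, 13), mk(100, 13))
  expect_equal(ft$F, 4)
  expect_equal(ft$df1, 12)
  expect_equal(ft$p_f, 1 - pf(4, 12, 12))
  expect_equal(ft$p_f, 0.01165421, tolerance = 1e-6)
  lower <- variance_f_test(mk(50, 13), mk(100, 13))
  expect_lt(lower$F, 1)
  expect_gt(lower$p_f, 0.5)
  expect_error(variance_f_test(mk(0, 13), mk(100, 13)), "positive")
  expect_error(variance_f_test(mk(100, 1), mk(100, 13)), "degrees of freedom")
})

test_that("normality check reports W and p per group and flags degenerate input", {
  set.seed(9)
  data <- tibble::tibble(
    group = rep(c("healthy", "ALC"), each = 14),
    count = c(rnorm(14, 2000, 100), rnorm(14, 2100, 120))
  )
  nc <- normality_check(data)
  expect_equal(nrow(nc), 2)
  expect_true(all(nc$testable))
  expect_true(all(nc$p > 0 & nc$p <= 1))
  const <- normality_check(tibble::tibble(group = "g", count = rep(5, 10)))
  expect_false(const$testable)
  tiny <- normality_check(tibble::tibble(group = "g", count = c(1, 2)))
  expect_false(tiny$testable)
})

test_that("Shapiro check is calibrated under normal data and powered on exponential data", {
  p_norm <- vapply(1:100, function(s) {
    set.seed(s)
    normality_check(tibble::tibble(group = "g",
                                   count = rnorm(14, 2000, 100)))$p
  }, numeric(1))
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_exp <- vapply(1:100, function(s) {
    set.seed(s)
    normality_check(tibble::tibble(group = "g",
                                   count = rexp(50, 1 / 50)))$p
  }, numeric(1))
  expect_gte(mean(p_exp < 0.05), 0.90)
})

test_that("per-context Wilcoxon tests apply Bonferroni over tested categories", {
  mat <- matrix(0L, nrow = 96, ncol = 8,
                dimnames = list(sbs96_catalog(), paste0("c", 1:8)))
  groups <- setNames(rep(c("healthy", "ALC"), each = 4), colnames(mat))
  set.seed(3)
  mat[1, ] <- c(5L, 6L, 4L, 5L, 50L, 52L, 49L, 51L)  # strongly shifted
  mat[2, ] <- rep(3L, 8)                              # identical, tied
  mat[3, ] <- c(2L, 3L, 4L, 5L, 3L, 4L, 2L, 5L)      # exchangeable
  suppressMessages(res <- context_load_tests(mat, groups))
  tested <- res[res$tested, ]
  expect_equal(nrow(tested), 3)
  expect_equal(tested$p_bonferroni,
               pmin(1, tested$p_raw * 3))
  expect_true(all(is.na(res$p_raw[!res$tested])))
  expect_equal(res$p_bonferroni[res$context == rownames(mat)[2]], 1)
  expect_lt(res$p_raw[1], 0.05)
  # family of one: adjusted equals raw
  one <- context_load_tests(mat[1, , drop = FALSE], groups)
  expect_equal(one$p_bonferroni, one$p_raw)
  expect_error(context_load_tests(mat[, 1:4], groups[1:4]), "two nonempty")
})

test_that("power simulation returns {0,1} at one rep and respects its contract", {
  base <- sim_config(n_patients = c(healthy = 3, ALC = 3),
                     clones_per_patient = 2, seed = 5)
  pw <- power_simulation(base, effect_grid = c(1, 3), reps = 1)
  expect_true(all(pw$power %in% c(0, 1)))
  expect_equal(pw$multiplier, c(1, 3))
  expect_error(power_simulation(sim_config(n_patients = c(ALC = 3)),
                                reps = 1),
               "healthy")
})

test_that("study-scale Poisson cohorts cover the generating slope in >= 90/100 seeds", {
  cover <- c(SBS = 0L, INDEL = 0L)
  for (s in 1:100) {
    cfg <- sim_config(n_patients = c(healthy = 7), clones_per_patient = 2,
                      seed = s)
    co <- simulate_cohort(cfg)
    for (vc in c("SBS", "INDEL")) {
      cnt <- dplyr::filter(co$truth$clone_counts, var_class == vc)
      fit <- fit_burden_regression(cnt, co$meta, group = "healthy")
      hit <- abs(fit$m - cfg$slopes$healthy[[vc]]) <= fit$ci95
      cover[vc] <- cover[vc] + hit
    }
  }
  expect_gte(cover[["SBS"]], 90)
  expect_gte(cover[["INDEL"]], 90)
})
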