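#' Fit a zero-intercept mixed-effects burden regression
#'
#' Regresses per-clone mutation counts on donor age with no intercept (a
#' genome is assumed to carry zero somatic mutations at birth) and patient
#' as a random effect: `count = m * age + b_patient * age + error`, with a
#' per-patient random slope estimated by REML via [nlme::lme()]. The fitted
#' slope `m` is the group's accumulation rate in mutations/year; its 95%
#' confidence interval comes from [nlme::intervals()] (Wald). When the
#' mixed model is not estimable (a single patient, a single clone, or a
#' degenerate fit) the function falls back to zero-intercept ordinary least
#' squares with a message.
#'
#' @param counts Tibble with columns `clone_id` and `count` (one total per
#'   clone), or a named numeric vector of counts.
#' @param meta Clone metadata tibble (`clone_id`, `patient_id`, `age`,
#'   `group`), see [read_clone_metadata()].
#' @param group Optional group label to subset `meta` to; recorded in the
#'   fit either way.
#' @return A `burden_fit` object: `group`, `m` (mutations/year), `se`,
#'   `ci95` (half-width), `var` (residual variance), `n_clones`,
#'   `n_patients`, `method` (`"lme"` or `"ols"`), `degenerate`.
#' @examples
#' co <- simulate_cohort(sim_config(n_patients = c(healthy = 5), seed = 3))
#' cnt <- dplyr::filter(co$truth$clone_counts, var_class == "SBS")
#' fit_burden_regression(cnt, co$meta, group = "healthy")
#' @export
fit_burden_regression <- function(counts, meta, group = NULL) {
  if (!is.data.frame(counts)) {
    counts <- tibble(clone_id = names(counts), count = as.numeric(counts))
  }
  if (!is.null(group)) meta <- filter(meta, .data$group == !!group)
  df <- dplyr::inner_join(select(counts, "clone_id", "count"), meta,
                          by = "clone_id")
  if (nrow(df) < 2) abort("burden regression needs at least 2 clones")
  if (any(df$age <= 0)) abort("ages must be positive")
  grp <- group %||% (if (length(unique(df$group)) == 1) df$group[1] else NA)
  n_clones <- nrow(df)
  n_patients <- length(unique(df$patient_id))

  if (all(df$count == 0)) {
    return(new_burden_fit(grp, m = 0, se = 0, ci95 = 0, var = 0,
                          n_clones, n_patients, method = "degenerate",
                          degenerate = TRUE))
  }

  fit <- NULL
  if (n_patients >= 2) {
    fit <- tryCatch(
      nlme::lme(count ~ 0 + age, random = ~ 0 + age | patient_id,
                data = df, method = "REML",
                control = nlme::lmeControl(returnObject = TRUE)),
      error = function(e) NULL
    )
  }
  if (!is.null(fit)) {
    m <- unname(nlme::fixef(fit)[1])
    se <- unname(sqrt(vcov(fit)[1, 1]))
    ci <- tryCatch({
      iv <- nlme::intervals(fit, which = "fixed")$fixed
      (iv[1, "upper"] - iv[1, "lower"]) / 2
    }, error = function(e) 1.96 * se)
    sig2 <- fit$sigma^2
    method <- "lme"
  } else {
    inform("mixed model not estimable; falling back to zero-intercept OLS")
    ols <- lm(count ~ 0 + age, data = df)
    m <- unname(coef(ols)[1])
    se <- unname(sqrt(diag(vcov(ols)))[1])
    ci <- if (n_clones >= 2) {
      unname(diff(confint(ols)[1, ]) / 2)
    } else NA_real_
    sig2 <- summary(ols)$sigma^2
    method <- "ols"
  }
  new_burden_fit(grp, m, se, ci, sig2, n_clones, n_patients, method,
                 degenerate = FALSE)
}

new_burden_fit <- function(group, m, se, ci95, var, n_clones, n_patients,
                           method, degenerate) {
  structure(
    list(group = group, m = m, se = se, ci95 = ci95, var = var,
         n_clones = n_clones, n_patients = n_patients, method = method,
         degenerate = degenerate),
    class = "burden_fit"
  )
}

#' @export
print.burden_fit <- function(x, ...) {
  cat("<burden_fit> group:", x$group, "(", x$method, ")\n")
  cat(sprintf("  rate: %.2f +/- %.2f mutations/year (95%% CI half-width)\n",
              x$m, x$ci95))
  cat(sprintf("  SE %.3f, residual var %.2f, %d clones / %d patients\n",
              x$se, x$var, x$n_clones, x$n_patients))
  invisible(x)
}

#' Per-group Shapiro-Wilk normality check of mutation load
#'
#' Advisory check (does not gate any downstream analysis) that per-group
#' mutation counts are compatible with normality, run per group and, when a
#' `var_class` column is present, per variant class.
#'
#' @param data Tibble with columns `group`, `count` and optionally
#'   `var_class`.
#' @return Tibble with `group` (, `var_class`), `n`, `W`, `p`, `testable`;
#'   groups with fewer than 3 values or constant values are flagged
#'   untestable.
#' @export
normality_check <- function(data) {
  keys <- intersect(c("group", "var_class"), names(data))
  data |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(
      n = dplyr::n(),
      W = if (dplyr::n() >= 3 && length(unique(.data$count)) > 1) {
        shapiro.test(.data$count)$statistic
      } else NA_real_,
      p = if (dplyr::n() >= 3 && length(unique(.data$count)) > 1) {
        shapiro.test(.data$count)$p.value
      } else NA_real_,
      .groups = "drop"
    ) |>
    mutate(testable = !is.na(.data$W))
}

#' Z-test for a difference between two accumulation rates
#'
#' Compares the slopes of two burden regressions:
#' `Z = (m1 - m2) / sqrt(SE1^2 + SE2^2)`, with a two-sided p-value
#' `2 * pnorm(-|Z|)`. The `strict_printed` flag switches the denominator to
#' `sqrt(SE1^2 - SE2^2)` — a historically printed variant that is not a
#' valid standard error of a difference and can be imaginary; it exists for
#' auditing only and warns when used.
#'
#' @param fit_a,fit_b `burden_fit` objects.
#' @param strict_printed Use the difference-of-squares denominator (audit
#'   mode).
#' @return One-row tibble: `group_a`, `group_b`, `Z`, `p_z`.
#' @export
slope_z_test <- function(fit_a, fit_b, strict_printed = FALSE) {
  stopifnot(inherits(fit_a, "burden_fit"), inherits(fit_b, "burden_fit"))
  denom2 <- if (strict_printed) {
    warn("strict_printed mode: SE1^2 - SE2^2 is not a valid variance of a difference")
    fit_a$se^2 - fit_b$se^2
  } else {
    fit_a$se^2 + fit_b$se^2
  }
  if (is.na(denom2) || denom2 <= 0) {
    abort("undefined comparison: nonpositive variance of the slope difference")
  }
  z <- (fit_a$m - fit_b$m) / sqrt(denom2)
  tibble(group_a = fit_a$group, group_b = fit_b$group,
         Z = z, p_z = 2 * pnorm(-abs(z)))
}

#' One-sided F-test for increased regression variance in a disease group
#'
#' Tests whether the residual variance of the disease-group regression
#' exceeds that of the healthy (reference) group:
#' `F = var_disease / var_healthy`, `p = 1 - pf(F, df1, df2)`.
#' Degrees of freedom default to `n_clones - 1` per group.
#'
#' @param fit_disease,fit_healthy `burden_fit` objects.
#' @param df1,df2 Optional degrees of freedom overrides.
#' @return One-row tibble: `group_a`, `group_b`, `F`, `p_f`, `df1`, `df2`.
#' @export
variance_f_test <- function(fit_disease, fit_healthy, df1 = NULL,
                            df2 = NULL) {
  stopifnot(inherits(fit_disease, "burden_fit"),
            inherits(fit_healthy, "burden_fit"))
  if (fit_disease$var <= 0 || fit_healthy$var <= 0) {
    abort("undefined comparison: residual variances must be positive")
  }
  df1 <- df1 %||% (fit_disease$n_clones - 1)
  df2 <- df2 %||% (fit_healthy$n_clones - 1)
  if (df1 < 1 || df2 < 1) abort("undefined comparison: degrees of freedom < 1")
  f <- fit_disease$var / fit_healthy$var
  tibble(group_a = fit_disease$group, group_b = fit_healthy$group,
         F = f, p_f = 1 - pf(f, df1, df2), df1 = df1, df2 = df2)
}

#' Compare two groups on slope and variance
#'
#' Convenience wrapper running [slope_z_test()] and [variance_f_test()]
#' (disease first, healthy/reference second).
#'
#' @inheritParams variance_f_test
#' @return One-row tibble joining both test results.
#' @export
compare_groups <- function(fit_disease, fit_healthy) {
  zt <- slope_z_test(fit_disease, fit_healthy)
  ft <- variance_f_test(fit_disease, fit_healthy)
  dplyr::bind_cols(zt, select(ft, "F", "p_f", "df1", "df2"))
}

#' Per-context Wilcoxon rank-sum tests with Bonferroni correction
#'
#' Runs a two-sample Wilcoxon rank-sum test per context category comparing
#' clone counts between two groups. Categories that are zero in both groups
#' are excluded (and reported as untested); the Bonferroni family size is
#' the number of categories actually tested. The exact test is used when
#' the combined sample size is at most 20 and there are no ties, otherwise
#' the normal approximation with tie correction.
#'
#' @param mat Spectrum matrix, contexts x clones.
#' @param groups Named character vector or factor mapping each column of
#'   `mat` to a group; exactly two groups, each nonempty.
#' @return Tibble with `context`, `W`, `p_raw`, `p_bonferroni`, `tested`.
#' @export
context_load_tests <- function(mat, groups) {
  if (is.null(names(groups))) names(groups) <- colnames(mat)
  groups <- groups[colnames(mat)]
  lv <- unique(as.character(groups))
  if (length(lv) != 2 || any(table(groups) == 0)) {
    abort("context_load_tests needs exactly two nonempty groups")
  }
  a_cols <- which(groups == lv[1])
  b_cols <- which(groups == lv[2])
  res <- purrr::map(rownames(mat), function(ctx) {
    x <- mat[ctx, a_cols]; y <- mat[ctx, b_cols]
    if (all(x == 0) && all(y == 0)) {
      return(tibble(context = ctx, W = NA_real_, p_raw = NA_real_,
                    tested = FALSE))
    }
    n <- length(x) + length(y)
    wt <- suppressWarnings(
      wilcox.test(x, y, exact = n <= 20, correct = TRUE)
    )
    p <- wt$p.value
    if (is.nan(p)) p <- 1  # fully tied data carry no evidence of a shift
    tibble(context = ctx, W = unname(wt$statistic), p_raw = p,
           tested = TRUE)
  }) |> bind_rows()
  n_tested <- sum(res$tested)
  if (n_tested < nrow(res)) {
    inform(paste0(nrow(res) - n_tested,
                  " context(s) zero in both groups excluded from testing"))
  }
  res$p_bonferroni <- ifelse(res$tested, pmin(1, res$p_raw * n_tested),
                             NA_real_)
  res
}

#' Simulation-based power analysis for the slope Z-test
#'
#' For each slope multiplier, simulates paired disease/healthy cohorts from
#' the base configuration (the disease group's generating slope for the
#' chosen variant class is multiplied by the effect size), fits both burden
#' regressions, runs the slope Z-test, and reports the rejection fraction at
#' `alpha`. Multiplier 1 estimates the type-I error. Replicate seeds are a
#' fixed sequence derived from the base config's seed.
#'
#' @param base A [sim_config()] containing a `healthy` group and at least
#'   one other group (the first other group is used as the disease arm; if
#'   only `healthy` is present a `disease` arm with the same design is
#'   added).
#' @param effect_grid Numeric slope multipliers.
#' @param reps Replicates per effect size.
#' @param alpha Significance level.
#' @param var_class Variant class whose slope is scaled and tested.
#' @return Tibble with `multiplier`, `power`, `reps`, `alpha`.
#' @export
power_simulation <- function(base, effect_grid = c(1, 1.5, 2, 3),
                             reps = 200, alpha = 0.05, var_class = "SBS") {
  stopifnot(inherits(base, "sim_config"), reps >= 1, alpha > 0, alpha < 1)
  if (!"healthy" %in% names(base$n_patients)) {
    abort("base config must contain a 'healthy' group")
  }
  disease <- setdiff(names(base$n_patients), "healthy")[1]
  if (is.na(disease)) {
    disease <- "disease"
    base$n_patients <- c(base$n_patients,
                         setNames(base$n_patients["healthy"], disease))
    base$slopes[[disease]] <- base$slopes[["healthy"]]
  }
  out <- purrr::map(seq_along(effect_grid), function(ei) {
    eff <- effect_grid[ei]
    rejections <- vapply(seq_len(reps), function(r) {
      cfg_r <- base
      cfg_r$n_patients <- base$n_patients[c("healthy", disease)]
      cfg_r$slopes <- base$slopes[c("healthy", disease)]
      cfg_r$slopes[[disease]][var_class] <-
        cfg_r$slopes[[disease]][var_class] * eff
      cfg_r$seed <- (base$seed + 7919L * ei + r) %% .Machine$integer.max
      co <- simulate_cohort(cfg_r)
      cnt <- filter(co$truth$clone_counts, .data$var_class == !!var_class)
      fit_h <- fit_burden_regression(cnt, co$meta, group = "healthy")
      fit_d <- fit_burden_regression(cnt, co$meta, group = disease)
      slope_z_test(fit_d, fit_h)$p_z < alpha
    }, logical(1))
    tibble(multiplier = eff, power = mean(rejections), reps = reps,
           alpha = alpha)
  })
  bind_rows(out)
}
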