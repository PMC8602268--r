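#' Tidy a burden regression fit
#'
#' @param x A `burden_fit`.
#' @param ... Unused.
#' @return One-row tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high` (95%), `group`.
#' @method tidy burden_fit
#' @export
tidy.burden_fit <- function(x, ...) {
  tibble(term = "age", estimate = x$m, std.error = x$se,
         conf.low = x$m - x$ci95, conf.high = x$m + x$ci95,
         group = x$group)
}

#' Glance at a burden regression fit
#'
#' @param x A `burden_fit`.
#' @param ... Unused.
#' @return One-row tibble with residual variance, counts and fit method.
#' @method glance burden_fit
#' @export
glance.burden_fit <- function(x, ...) {
  tibble(group = x$group, sigma2 = x$var, n_clones = x$n_clones,
         n_patients = x$n_patients, method = x$method,
         degenerate = x$degenerate)
}

#' Tidy a signature fit
#'
#' @param x A `signature_fit` from [fit_nnls()].
#' @param ... Unused.
#' @return Tibble with one row per signature.
#' @method tidy signature_fit
#' @export
tidy.signature_fit <- function(x, ...) {
  tibble(clone_id = x$clone_id %||% NA_character_, signature = x$signatures,
         absolute = unname(x$absolute), relative = unname(x$relative))
}

#' Glance at a signature fit
#'
#' @param x A `signature_fit`.
#' @param ... Unused.
#' @return One-row tibble with the reconstruction residual and flags.
#' @method glance signature_fit
#' @export
glance.signature_fit <- function(x, ...) {
  tibble(clone_id = x$clone_id %||% NA_character_, residual = x$residual,
         total = sum(x$absolute), n_signatures = length(x$signatures),
         all_zero = x$all_zero)
}
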