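#' Select signatures by prevalence in a cancer-type exposure table
#'
#' A signature is selected when, in at least one of the requested cancer
#' types, the fraction of samples in which it is present exceeds the
#' threshold; selections are unioned over types. "Present" means exposure
#' strictly greater than `presence_floor` (PCAWG exposure tables zero-fill
#' absent signatures, so the default floor of 0 reads presence directly).
#'
#' @param exposures Tibble from [read_exposure_table()].
#' @param types Cancer-type labels to consider (e.g.
#'   `c("Liver-HCC", "Biliary-AdenoCA")`).
#' @param threshold Minimum fraction of samples, in `(0, 1]`; default 0.10.
#' @param presence_floor Exposure above which a signature counts as present.
#' @return Character vector of selected signature names, in table order.
#' @export
select_signatures <- function(exposures, types, threshold = 0.10,
                              presence_floor = 0) {
  stopifnot(threshold > 0, threshold <= 1)
  missing_t <- setdiff(types, unique(exposures$cancer_type))
  if (length(missing_t) > 0) {
    abort(paste0("cancer type(s) not in exposure table: ",
                 paste(missing_t, collapse = ", "), "; available: ",
                 paste(sort(unique(exposures$cancer_type)), collapse = ", ")))
  }
  sig_cols <- setdiff(names(exposures), c("sample", "cancer_type"))
  selected <- character(0)
  for (ty in types) {
    sub <- exposures[exposures$cancer_type == ty, sig_cols, drop = FALSE]
    frac <- colMeans(as.matrix(sub) > presence_floor)
    selected <- union(selected, sig_cols[frac >= threshold])
  }
  sig_cols[sig_cols %in% selected]
}

# Lawson-Hanson active-set non-negative least squares:
# argmin_{x >= 0} || A x - b ||_2. Deterministic; no scaling of inputs.
nnls_lawson_hanson <- function(A, b, max_iter = 10 * ncol(A)) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- as.vector(crossprod(A, b - A %*% x))
  tol <- 10 * .Machine$double.eps * max(abs(crossprod(A, b)), 1) * n
  iter <- 0L
  while (any(!passive) && max(w[!passive]) > tol && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- qr.coef(qr(Ap), b)
      s[passive][is.na(s[passive])] <- 0
      if (all(s[passive] > tol)) { x <- s; break }
      viol <- passive & s <= tol
      alpha <- min(x[viol] / (x[viol] - s[viol]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- as.vector(crossprod(A, b - A %*% x))
  }
  pmax(x, 0)
}

#' Fit a context spectrum to signature definitions by NNLS
#'
#' Finds the nonnegative signature contributions minimising the Euclidean
#' distance between the observed spectrum and its reconstruction
#' `definitions %*% x` (Lawson-Hanson active set; deterministic). Relative
#' contributions are absolute contributions divided by their total; an
#' all-zero spectrum yields all-zero contributions with `all_zero = TRUE`.
#'
#' @param spectrum Named numeric vector of context counts (names must match
#'   the model contexts in order), or an unnamed vector of the right length.
#' @param model A [signature_model()] (optionally a subset of signatures).
#' @param clone_id Optional label carried into the result.
#' @return A `signature_fit` list: `clone_id`, `signatures`, `absolute`,
#'   `relative`, `residual` (Euclidean), `all_zero`.
#' @examples
#' m <- synthetic_signature_model(2, "SBS", seed = 1)
#' sp <- round(500 * m$definitions[, 1])
#' fit_nnls(sp, m)$relative
#' @export
fit_nnls <- function(spectrum, model, clone_id = NULL) {
  stopifnot(inherits(model, "signature_model"))
  if (length(spectrum) != length(model$contexts)) {
    abort(paste0("spectrum length ", length(spectrum),
                 " does not match model catalog length ",
                 length(model$contexts)))
  }
  if (!is.null(names(spectrum)) &&
      !identical(names(spectrum), model$contexts)) {
    abort("spectrum context labels do not match the model catalog order")
  }
  b <- as.numeric(spectrum)
  if (any(b < 0)) abort("spectrum counts must be nonnegative")
  A <- model$definitions
  if (all(b == 0)) {
    absolute <- setNames(numeric(ncol(A)), model$signatures)
    return(structure(
      list(clone_id = clone_id, signatures = model$signatures,
           absolute = absolute, relative = absolute, residual = 0,
           all_zero = TRUE),
      class = "signature_fit"
    ))
  }
  x <- nnls_lawson_hanson(A, b)
  absolute <- setNames(x, model$signatures)
  relative <- if (sum(x) > 0) absolute / sum(absolute) else absolute
  structure(
    list(clone_id = clone_id, signatures = model$signatures,
         absolute = absolute, relative = relative,
         residual = sqrt(sum((A %*% x - b)^2)), all_zero = FALSE),
    class = "signature_fit"
  )
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("<signature_fit>", if (!is.null(x$clone_id)) x$clone_id else "",
      " residual =", format(x$residual, digits = 4), "\n")
  print(round(rbind(absolute = x$absolute, relative = x$relative), 4))
  invisible(x)
}

#' Fit every clone of a spectrum matrix to signatures
#'
#' @param spectra Matrix, contexts x clones (e.g. from
#'   [build_spectrum_matrix()]).
#' @param model A [signature_model()].
#' @return Tibble with one row per clone x signature: `clone_id`,
#'   `signature`, `absolute`, `relative`, `residual`, `all_zero`.
#' @export
fit_signatures <- function(spectra, model) {
  fits <- purrr::map(colnames(spectra), function(ci) {
    fit_nnls(spectra[, ci], model, clone_id = ci)
  })
  purrr::map(fits, function(f) {
    tibble(clone_id = f$clone_id, signature = f$signatures,
           absolute = unname(f$absolute), relative = unname(f$relative),
           residual = f$residual, all_zero = f$all_zero)
  }) |> bind_rows()
}

#' Relative contribution matrix from a set of signature fits
#'
#' @param fits Tibble from [fit_signatures()], or a list of `signature_fit`
#'   objects sharing one signature list.
#' @return Numeric matrix, signatures x clones, each column summing to 1
#'   (columns of all-zero fits are zero and flagged in the
#'   `"all_zero"` attribute).
#' @export
relative_contributions <- function(fits) {
  if (!is.data.frame(fits)) {
    fits <- purrr::map(fits, function(f) {
      tibble(clone_id = f$clone_id %||% NA_character_,
             signature = f$signatures,
             relative = unname(f$relative), all_zero = f$all_zero)
    }) |> bind_rows()
  }
  wide <- fits |>
    select("clone_id", "signature", "relative") |>
    tidyr::pivot_wider(names_from = "clone_id", values_from = "relative")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$signature
  zero_cols <- colSums(mat) == 0
  attr(mat, "all_zero") <- names(zero_cols)[zero_cols]
  mat
}
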