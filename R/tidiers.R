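#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DFA result
#'
#' @param x a `dfa_result`.
#' @param ... unused.
#' @return tibble of `n`, `F` (one row per box size).
#' @export
tidy.dfa_result <- function(x, ...) x$fluctuations

#' @rdname tidy.dfa_result
#' @export
glance.dfa_result <- function(x, ...) {
  tibble::tibble(alpha1 = x$alpha1, alpha2 = x$alpha2,
                 r_squared_1 = x$r_squared[["range1"]],
                 r_squared_2 = x$r_squared[["range2"]],
                 degenerate = x$degenerate)
}

#' Tidy a fitted risk model
#'
#' @param x an `ivh_model`.
#' @param ... unused.
#' @return `tidy()`: coefficient tibble (original predictor scale);
#'   `glance()`: one-row model summary with AUC, DeLong CI, LR+ and
#'   (when present) LOOCV AUC.
#' @export
tidy.ivh_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.ivh_model
#' @export
glance.ivh_model <- function(x, ...) {
  tibble::tibble(
    predictors = paste(x$predictors, collapse = "+"),
    method = x$method,
    auc = x$auc, ci_low = x$ci[1], ci_high = x$ci[2],
    delong_se = x$se,
    lr_plus = x$lr$lr_plus, lr_threshold = x$lr$threshold,
    loocv_auc = if (is.null(x$loocv)) NA_real_ else x$loocv$auc,
    loocv_ci_low = if (is.null(x$loocv)) NA_real_ else x$loocv$ci[1],
    loocv_ci_high = if (is.null(x$loocv)) NA_real_ else x$loocv$ci[2],
    n = length(x$labels)
  )
}

#' @rdname tidy.dfa_result
#' @param x a `roc_delong`.
#' @export
tidy.roc_delong <- function(x, ...) x$curve

#' @rdname tidy.dfa_result
#' @export
glance.roc_delong <- function(x, ...) {
  tibble::tibble(auc = x$auc, se = x$se,
                 ci_low = x$ci[1], ci_high = x$ci[2],
                 n_cases = x$n_cases, n_controls = x$n_controls)
}
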