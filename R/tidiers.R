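# broom-style tidiers for fitted objects.

#' Tidy a univariate animal-model fit
#'
#' @param x A `gs_fit`.
#' @param ... Unused.
#' @return Tibble of variance components with standard errors.
#' @method tidy gs_fit
#' @export
tidy.gs_fit <- function(x, ...) {
  x$varcomp
}

#' One-row summary of a univariate animal-model fit
#'
#' @param x A `gs_fit`.
#' @param ... Unused.
#' @method glance gs_fit
#' @export
glance.gs_fit <- function(x, ...) {
  tibble(
    trait = x$trait, h2 = x$h2, h2_se = x$h2_se,
    sigma2_a = x$varcomp$estimate[1], sigma2_e = x$varcomp$estimate[2],
    loglik = x$loglik, p_additive = x$p_additive,
    n = x$n, iterations = x$iterations, converged = x$converged,
    K_kind = x$K_kind
  )
}

#' Breeding values from a fit
#'
#' @param x A `gs_fit` with BLUP solutions.
#' @param ... Unused.
#' @return Tibble `id`, `ebv` (the BLUP), `se`.
#' @method augment gs_fit
#' @export
augment.gs_fit <- function(x, ...) {
  if (is.null(x$ebv)) stop_input("fit carries no breeding values")
  x$ebv
}

#' Tidy a bivariate fit
#'
#' @param x A `gs_bifit`.
#' @param ... Unused.
#' @method tidy gs_bifit
#' @export
tidy.gs_bifit <- function(x, ...) {
  x$varcomp
}

#' One-row summary of a bivariate fit
#'
#' @param x A `gs_bifit`.
#' @param ... Unused.
#' @method glance gs_bifit
#' @export
glance.gs_bifit <- function(x, ...) {
  tibble(
    trait_1 = x$traits[1], trait_2 = x$traits[2],
    r_a = x$r_a, r_a_se = x$r_a_se,
    r_e = x$r_e, r_e_se = x$r_e_se,
    r_p = x$r_p, r_p_se = x$r_p_se,
    loglik = x$loglik, p_genetic = x$p_genetic,
    p_phenotypic = x$p_phenotypic,
    n = x$n, converged = x$converged, K_kind = x$K_kind
  )
}

#' Per-fold cross-validation results
#'
#' @param x A `gs_cv`.
#' @param ... Unused.
#' @method tidy gs_cv
#' @export
tidy.gs_cv <- function(x, ...) {
  x$folds
}

#' One-row cross-validation summary
#'
#' @param x A `gs_cv`.
#' @param ... Unused.
#' @method glance gs_cv
#' @export
glance.gs_cv <- function(x, ...) {
  tibble(
    trait = x$trait, mean_pa = x$mean_pa, sd_pa = x$sd_pa,
    pacc = x$pacc, h2_ref = x$h2_ref,
    k = x$k, repeats = x$repeats, n_fits = nrow(x$folds),
    n_failed = x$n_failed, K_kind = x$K_kind
  )
}
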