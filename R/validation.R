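# Family-stratified k-fold cross-validation of (G)EBV prediction: predictive
# ability (PA) and predictive accuracy (PACC).

#' Family-stratified fold assignment
#'
#' Within each family, individuals are shuffled and dealt round-robin over a
#' shuffled fold order, so every fold receives approximately the same share
#' of each family (within-family fold sizes differ by at most one).
#'
#' @param data Phenotype tibble with an id and a family column.
#' @param k Number of folds.
#' @param stratify_by Family column name.
#' @param id_col Id column name.
#' @param seed Seed.
#' @return Tibble with columns `id`, `family`, `fold`.
#' @export
make_folds <- function(data, k = 10L, stratify_by = "family",
                       id_col = "id", seed = 1L) {
  check_columns(data, c(id_col, stratify_by), "phenotype data")
  if (!is_count(k, min = 2L)) stop_input("k must be an integer >= 2")
  with_seed(seed, {
    out <- lapply(split(data[[id_col]], data[[stratify_by]]), function(ids) {
      ids <- sample(ids)
      folds <- rep_len(sample.int(k), length(ids))
      tibble(id = ids, fold = folds)
    })
    fam <- rep(names(out), vapply(out, nrow, integer(1)))
    res <- dplyr::bind_rows(out)
    res$family <- fam
    res[, c("id", "family", "fold")]
  })
}

#' Cross-validated predictive ability of ABLUP/GBLUP
#'
#' Repeated family-stratified k-fold cross-validation: in every repeat x fold
#' the model is refitted on the training trees only (test phenotypes removed;
#' test individuals remain in `K` so their breeding values are predicted
#' through relationships), and the predictive ability (PA) is the Pearson
#' correlation between the held-out phenotypes and their predicted breeding
#' values. PACC = mean PA / sqrt(h2_ref), with `h2_ref` conventionally taken
#' from the genomic (GBLUP) fit of the full data.
#'
#' @inheritParams fit_univariate
#' @param k Folds per repeat.
#' @param repeats Number of repeats (k x repeats model fits in total).
#' @param seed Seed; fold assignments derive sub-streams per repeat.
#' @param h2_ref Reference heritability for PACC; default is the h2 of a full
#'   fit with this `K`.
#' @param reestimate Re-estimate variance components in every training fold
#'   (default); `FALSE` fixes them at the full-data estimates and only the
#'   BLUP solve is repeated.
#' @param family_col Family column used for stratification.
#' @return Object of class `gs_cv`: per-fold results, summary (mean/SD PA,
#'   PACC), the full-data fit and settings.
#' @export
cross_validate <- function(data, K, trait, fixed = ~block, id_col = "id",
                           family_col = "family", k = 10L, repeats = 10L,
                           seed = 1L, h2_ref = NULL, reestimate = TRUE) {
  check_columns(data, c(id_col, family_col, trait, all.vars(fixed)),
                "phenotype data")
  data <- data[is.finite(data[[trait]]), , drop = FALSE]
  ch <- try(chol(K), silent = TRUE)
  if (!inherits(ch, "matrix")) {
    stop_input("K is not positive definite; blend it first (see blend_K)")
  }
  K_inv <- chol2inv(ch)
  dimnames(K_inv) <- dimnames(K)
  full_fit <- fit_univariate(data, K, trait, fixed = fixed, id_col = id_col,
                             K_inv = K_inv)
  if (is.null(h2_ref)) h2_ref <- full_fit$h2
  sa_full <- full_fit$varcomp$estimate[1]
  se_full <- full_fit$varcomp$estimate[2]

  rows <- list()
  failures <- 0L
  for (r in seq_len(repeats)) {
    folds <- make_folds(data, k = k, stratify_by = family_col,
                        id_col = id_col, seed = substream(seed, 100L + r))
    for (f in sort(unique(folds$fold))) {
      test_ids <- folds$id[folds$fold == f]
      train <- data[!(data[[id_col]] %in% test_ids), , drop = FALSE]
      res <- tryCatch({
        if (reestimate) {
          fit <- fit_univariate(train, K, trait, fixed = fixed,
                                id_col = id_col, K_inv = K_inv,
                                compute_blup = "point")
          ebv <- fit$ebv
        } else {
          mf <- train
          for (v in all.vars(fixed)) mf[[v]] <- factor(mf[[v]])
          X <- model.matrix(fixed, data = mf)
          ebv <- solve_mme(train[[trait]], X, as.character(train[[id_col]]),
                           K, sa_full, se_full, K_inv = K_inv)$ebv
        }
        obs <- data[data[[id_col]] %in% test_ids, c(id_col, trait)]
        pred <- ebv$ebv[match(obs[[id_col]], ebv$id)]
        tibble(repeat_ = r, fold = f, n_test = nrow(obs),
               pa = cor(obs[[trait]], pred))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- failures + 1L
      } else {
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  folds_tbl <- dplyr::bind_rows(rows)
  mean_pa <- mean(folds_tbl$pa)
  structure(
    list(
      trait = trait,
      folds = folds_tbl,
      mean_pa = mean_pa, sd_pa = sd(folds_tbl$pa),
      pacc = mean_pa / sqrt(h2_ref), h2_ref = h2_ref,
      full_fit = full_fit,
      k = k, repeats = repeats, n_failed = failures,
      K_kind = attr(K, "kind") %||% "K"
    ),
    class = "gs_cv"
  )
}

#' @export
print.gs_cv <- function(x, ...) {
  cat(sprintf("<gs_cv> %s on %s: %dx%d folds (%d fits, %d failed)\n",
              x$trait, x$K_kind, x$repeats, x$k, nrow(x$folds), x$n_failed))
  cat(sprintf("  PA = %.3f (SD %.3f), PACC = %.3f (h2_ref = %.3f)\n",
              x$mean_pa, x$sd_pa, x$pacc, x$h2_ref))
  invisible(x)
}
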