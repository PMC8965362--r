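# Individual-tree ("animal") mixed model y = Xb + Za + e with
# a ~ N(0, sigma2_a K) and e ~ N(0, sigma2_e I), fitted by restricted
# maximum likelihood. Variance components are updated by average-information
# (AI) steps with expectation-maximization fallback whenever an AI step would
# leave the parameter space or decrease the restricted likelihood; the
# within-iteration algebra runs in the eigenspace of the phenotyped-subset
# relationship matrix, so each iteration is O(n p^2).

reml_workspace <- function(y, X, Ks) {
  eg <- eigen(Ks, symmetric = TRUE)
  d <- eg$values
  if (min(d) < -1e-6 * max(abs(d))) {
    stop_input("relationship matrix is not positive semi-definite; blend it first (see blend_K)")
  }
  d <- pmax(d, 0)
  list(
    d = d, U = eg$vectors,
    yt = drop(crossprod(eg$vectors, y)),
    Xt = crossprod(eg$vectors, X),
    n = length(y), p = ncol(X)
  )
}

# Restricted log-likelihood and, optionally, the score and AI matrix, for
# variance components th = (sigma2_a, sigma2_e) in the rotated basis.
reml_eval <- function(ws, th, derivs = FALSE) {
  v <- th[1] * ws$d + th[2]
  if (any(v <= 0)) return(list(ll = -Inf))
  w <- 1 / v
  Xw <- ws$Xt * w
  xtwx <- crossprod(ws$Xt, Xw)
  ch <- chol(xtwx)
  xtwy <- crossprod(Xw, ws$yt)
  beta <- backsolve(ch, forwardsolve(t(ch), xtwy))
  py <- w * ws$yt - Xw %*% beta
  ypy <- sum(ws$yt * py)
  ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(ch))) + ypy +
                  (ws$n - ws$p) * log(2 * pi))
  out <- list(ll = ll, beta = drop(beta), xtwx = xtwx, py = drop(py))
  if (!derivs) return(out)

  project <- function(f) {
    wf <- w * f
    drop(wf - Xw %*% backsolve(ch, forwardsolve(t(ch), crossprod(Xw, f))))
  }
  # tr(P V_k) = tr(V^-1 V_k) - tr((X'V^-1X)^-1 X'V^-1 V_k V^-1 X)
  tr_pv <- function(dk) {
    m <- crossprod(ws$Xt, ws$Xt * (w^2 * dk))
    sum(w * dk) - sum(diag(backsolve(ch, forwardsolve(t(ch), m))))
  }
  py <- out$py
  f1 <- ws$d * py
  f2 <- py
  ypv1py <- sum(py * ws$d * py)
  ypv2py <- sum(py * py)
  score <- c(-0.5 * (tr_pv(ws$d) - ypv1py),
             -0.5 * (tr_pv(rep(1, ws$n)) - ypv2py))
  pf1 <- project(f1)
  pf2 <- project(f2)
  ai <- 0.5 * matrix(c(sum(f1 * pf1), sum(f1 * pf2),
                       sum(f2 * pf1), sum(f2 * pf2)), 2, 2)
  c(out, list(score = score, ai = ai))
}

#' Fit the univariate animal model by AI-REML
#'
#' Estimates additive and residual variance components for one trait under
#' the individual-tree mixed model with covariance `sigma2_a K` (K the
#' pedigree A or a blended genomic G matrix), returning heritability with a
#' delta-method standard error, REML log-likelihood, a boundary-corrected
#' likelihood-ratio test of `sigma2_a = 0`, fixed-effect solutions, and BLUP
#' breeding values with standard errors for every individual in `K`
#' (including unphenotyped ones, predicted through relationships).
#'
#' @param data Phenotype tibble; must contain `id_col`, the trait column and
#'   the fixed-effect variables.
#' @param K Relationship matrix whose rownames cover all phenotyped ids.
#' @param trait Name of the trait column.
#' @param fixed One-sided formula of fixed effects (default `~ block`; an
#'   intercept is always included). Numeric `block` columns are treated as
#'   categorical.
#' @param id_col Name of the id column.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum REML iterations.
#' @param compute_blup `TRUE` (default) solves the mixed-model equations for
#'   BLUPs with prediction SEs; `"point"` computes point EBVs only (fast,
#'   used in cross-validation); `FALSE` skips breeding values entirely.
#' @param K_inv Optional precomputed inverse of `K` (reused across repeated
#'   fits, e.g. in cross-validation).
#' @return Object of class `gs_fit`; see [tidy.gs_fit()] and
#'   [glance.gs_fit()].
#' @export
fit_univariate <- function(data, K, trait, fixed = ~block, id_col = "id",
                           tol = 1e-7, max_iter = 200L,
                           compute_blup = TRUE, K_inv = NULL) {
  check_columns(data, c(id_col, trait, all.vars(fixed)), "phenotype data")
  data <- data[is.finite(data[[trait]]), , drop = FALSE]
  ids <- as.character(data[[id_col]])
  missing_ids <- setdiff(ids, rownames(K))
  if (length(missing_ids) > 0L) {
    stop_input(sprintf("phenotyped individual(s) absent from K: %s",
                       paste(head(missing_ids, 5L), collapse = ", ")))
  }
  n <- nrow(data)
  if (n < 30L) stop_input("animal model needs at least 30 records")
  mf <- data
  for (v in all.vars(fixed)) mf[[v]] <- factor(mf[[v]])
  X <- model.matrix(fixed, data = mf)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  y <- data[[trait]]
  ws <- reml_workspace(y, X, K[ids, ids])

  vy <- var(y)
  lb <- 1e-8 * vy
  rss <- sum(qr.resid(qr(ws$Xt), ws$yt)^2)
  se0 <- rss / (n - ws$p)
  th <- c(0.5 * se0, 0.5 * se0)
  cur <- reml_eval(ws, th, derivs = TRUE)
  trajectory <- cur$ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step_em <- function(th, ev) {
      py <- ev$py
      sc <- ev$score
      pmax(th + th^2 * (2 * sc) / ws$n, lb)
    }
    th_ai <- try(th + solve(cur$ai, cur$score), silent = TRUE)
    cand <- NULL
    if (!inherits(th_ai, "try-error") && all(is.finite(th_ai))) {
      # plain AI step, then the same step projected onto the boundary
      for (th_try in list(th_ai, pmax(th_ai, lb))) {
        if (any(th_try < lb)) next
        ev_try <- reml_eval(ws, th_try, derivs = TRUE)
        if (is.finite(ev_try$ll) && ev_try$ll >= cur$ll - 1e-10) {
          cand <- list(th = th_try, ev = ev_try)
          break
        }
      }
    }
    if (is.null(cand)) { # EM fallback: stays in the parameter space
      th_em <- step_em(th, cur)
      cand <- list(th = th_em, ev = reml_eval(ws, th_em, derivs = TRUE))
    }
    delta_ll <- cand$ev$ll - cur$ll
    th <- cand$th
    cur <- cand$ev
    trajectory <- c(trajectory, cur$ll)
    if (abs(delta_ll) < tol * (1 + abs(cur$ll))) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("REML did not converge in %d iterations (last change %.3g)",
                 max_iter, diff(tail(trajectory, 2L))))
  }

  ai_cov <- try(solve(cur$ai), silent = TRUE)
  if (inherits(ai_cov, "try-error")) ai_cov <- matrix(NA_real_, 2, 2)
  sa <- th[1]
  se <- th[2]
  h2 <- sa / (sa + se)
  grad <- c(se, -sa) / (sa + se)^2
  h2_se <- sqrt(max(drop(t(grad) %*% ai_cov %*% grad), 0))
  comp_se <- sqrt(pmax(diag(ai_cov), 0))

  # boundary-corrected LRT of sigma2_a = 0 (50:50 chi2_0 : chi2_1 mixture)
  ll_null <- reml_eval(ws, c(0, se0))$ll
  lrt <- 2 * (cur$ll - ll_null)
  p_additive <- if (lrt <= 0) 1 else 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)

  ebv <- NULL
  if (isTRUE(compute_blup)) {
    # full mixed-model-equation solve: BLUPs with prediction SEs
    ebv <- solve_mme(y, X, ids, K, sa, se, K_inv = K_inv)$ebv
  } else if (identical(compute_blup, "point")) {
    # BLUP identity a_hat = sigma2_a K Z' P y: point EBVs without SEs,
    # much cheaper than inverting the coefficient matrix
    py_orig <- drop(ws$U %*% cur$py)
    ebv <- tibble(id = rownames(K),
                  ebv = unname(drop(sa * K[, ids, drop = FALSE] %*% py_orig)),
                  se = NA_real_)
  }
  structure(
    list(
      trait = trait,
      varcomp = tibble(
        component = c("additive", "residual"),
        estimate = c(sa, se), std_error = comp_se
      ),
      h2 = h2, h2_se = h2_se,
      loglik = cur$ll, loglik_null = ll_null,
      lrt_additive = lrt, p_additive = p_additive,
      beta = tibble(term = colnames(X), estimate = cur$beta),
      ebv = ebv,
      n = n, n_k = nrow(K),
      converged = converged, iterations = length(trajectory) - 1L,
      trajectory = trajectory,
      K_kind = attr(K, "kind") %||% "K"
    ),
    class = "gs_fit"
  )
}

# Henderson's mixed-model equations for BLUE/BLUP at fixed variance
# components; returns breeding values with prediction standard errors for
# every individual carried in K.
solve_mme <- function(y, X, ids, K, sa, se, K_inv = NULL) {
  all_ids <- rownames(K)
  m <- length(all_ids)
  p <- ncol(X)
  if (is.null(K_inv)) {
    ch <- try(chol(K), silent = TRUE)
    if (!inherits(ch, "matrix")) {
      stop_input("K is not positive definite; blend it first (see blend_K)")
    }
    K_inv <- chol2inv(ch)
  }
  zi <- match(ids, all_ids)
  XtX <- crossprod(X)
  XtZ <- matrix(0, p, m)
  agg <- rowsum(X, zi)
  XtZ[, as.integer(rownames(agg))] <- t(agg)
  ZtZ_diag <- tabulate(zi, nbins = m)
  lambda <- se / sa
  Cmat <- matrix(0, p + m, p + m)
  Cmat[seq_len(p), seq_len(p)] <- XtX
  Cmat[seq_len(p), p + seq_len(m)] <- XtZ
  Cmat[p + seq_len(m), seq_len(p)] <- t(XtZ)
  Cmat[p + seq_len(m), p + seq_len(m)] <- lambda * K_inv
  diag(Cmat)[p + seq_len(m)] <- diag(Cmat)[p + seq_len(m)] + ZtZ_diag
  rhs <- c(crossprod(X, y), rowsum_vec(y, zi, m))
  Cinv <- solve(Cmat)
  sol <- drop(Cinv %*% rhs)
  pev <- pmax(diag(Cinv)[p + seq_len(m)] * se, 0)
  list(
    beta = sol[seq_len(p)],
    ebv = tibble(id = all_ids, ebv = sol[p + seq_len(m)], se = sqrt(pev))
  )
}

rowsum_vec <- function(y, zi, m) {
  out <- numeric(m)
  agg <- rowsum(y, zi)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Theoretical accuracy of breeding values
#'
#' Per individual, `r_i = sqrt(1 - SE_i^2 / ((1 + F_i) sigma2_a))`, clamped
#' to `[0, 1]` (values whose prediction-error variance exceeds the additive
#' variance are reported as 0 and counted).
#'
#' @param fit A `gs_fit` with breeding values.
#' @param inbreeding Named per-individual inbreeding coefficients `F`;
#'   defaults to the `"inbreeding"` attribute of the K used for fitting, or 0.
#' @return Tibble with columns `id`, `accuracy`; the number of clamped
#'   individuals is in attribute `"n_clamped"` and the mean accuracy in
#'   attribute `"mean_accuracy"`.
#' @export
theoretical_accuracy <- function(fit, inbreeding = NULL) {
  if (is.null(fit$ebv)) stop_input("fit carries no breeding values")
  sa <- fit$varcomp$estimate[fit$varcomp$component == "additive"]
  if (sa <= 0) stop_input("additive variance is zero; accuracy undefined")
  f <- inbreeding %||% setNames(rep(0, nrow(fit$ebv)), fit$ebv$id)
  f <- f[fit$ebv$id]
  f[is.na(f)] <- 0
  rel <- unname(1 - fit$ebv$se^2 / ((1 + f) * sa))
  n_clamped <- sum(rel < 0)
  rel <- pmin(pmax(rel, 0), 1)
  out <- tibble(id = fit$ebv$id, accuracy = sqrt(rel))
  attr(out, "n_clamped") <- n_clamped
  attr(out, "mean_accuracy") <- mean(out$accuracy)
  out
}

#' Spearman rank correlation of family means between two sites
#'
#' @param site1,site2 Tibbles with columns `family` and `value` (family mean
#'   phenotypes or breeding values at each site).
#' @return One-row tibble with `rho`, `p_value`, `n_families`.
#' @export
family_rank_correlation <- function(site1, site2) {
  check_columns(site1, c("family", "value"), "site 1 family means")
  check_columns(site2, c("family", "value"), "site 2 family means")
  joined <- dplyr::inner_join(site1, site2, by = "family",
                              suffix = c("_1", "_2"))
  if (nrow(joined) < 5L) {
    stop_input(sprintf("only %d common families; need >= 5", nrow(joined)))
  }
  ct <- suppressWarnings(
    cor.test(joined$value_1, joined$value_2, method = "spearman")
  )
  tibble(rho = unname(ct$estimate), p_value = ct$p.value,
         n_families = nrow(joined))
}

#' @export
print.gs_fit <- function(x, ...) {
  cat(sprintf("<gs_fit> %s on %s (n = %d, %s)\n", x$trait,
              x$K_kind, x$n, if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  sigma2_a = %.4g, sigma2_e = %.4g, h2 = %.3f (SE %.3f)\n",
              x$varcomp$estimate[1], x$varcomp$estimate[2], x$h2, x$h2_se))
  cat(sprintf("  logLik = %.3f, P(sigma2_a = 0) = %.3g\n",
              x$loglik, x$p_additive))
  invisible(x)
}
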