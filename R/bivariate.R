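# Bivariate animal model: two traits share the additive relationship matrix,
# with 2x2 additive and residual covariance structures parameterized as
# per-trait variances plus a correlation (unconstrained optimization on log
# variances and atanh correlations). Used for genetic and phenotypic
# correlations between traits with likelihood-ratio tests.

bivar_nll_factory <- function(ws1, y2t) {
  d <- ws1$d
  Xt <- ws1$Xt
  y1t <- ws1$yt
  n <- ws1$n
  p <- ws1$p
  function(par) {
    # par = (sa1, sa2, ra, se1, se2, re) on the natural scale
    sa1 <- par[1]; sa2 <- par[2]; ra <- par[3]
    se1 <- par[4]; se2 <- par[5]; re <- par[6]
    if (any(!is.finite(par)) || sa1 <= 0 || sa2 <= 0 || se1 <= 0 ||
        se2 <= 0 || abs(ra) >= 1 || abs(re) >= 1) {
      return(1e10)
    }
    ca <- ra * sqrt(sa1 * sa2)
    ce <- re * sqrt(se1 * se2)
    a <- sa1 * d + se1
    b <- ca * d + ce
    cc <- sa2 * d + se2
    det <- a * cc - b^2
    if (any(det <= 0) || any(a <= 0)) return(1e10)
    w11 <- cc / det
    w22 <- a / det
    w12 <- -b / det
    A11 <- crossprod(Xt, Xt * w11)
    A12 <- crossprod(Xt, Xt * w12)
    A22 <- crossprod(Xt, Xt * w22)
    xtvx <- rbind(cbind(A11, A12), cbind(A12, A22))
    ch <- try(chol(xtvx), silent = TRUE)
    if (!inherits(ch, "matrix")) return(1e10)
    u <- c(crossprod(Xt, w11 * y1t + w12 * y2t),
           crossprod(Xt, w12 * y1t + w22 * y2t))
    beta <- backsolve(ch, forwardsolve(t(ch), u))
    yvy <- sum(y1t * (w11 * y1t + w12 * y2t) +
                 y2t * (w12 * y1t + w22 * y2t))
    ypy <- yvy - sum(u * beta)
    0.5 * (sum(log(det)) + 2 * sum(log(diag(ch))) + ypy +
             (2 * n - 2 * p) * log(2 * pi))
  }
}

to_natural <- function(th) {
  c(exp(th[1]), exp(th[2]), tanh(th[3]), exp(th[4]), exp(th[5]), tanh(th[6]))
}

#' Phenotypic correlation from bivariate variance components
#'
#' `r_p = (r_a sqrt(sa_i sa_j) + r_e sqrt(se_i se_j)) /
#'  sqrt((sa_i + se_i)(sa_j + se_j))`.
#'
#' @param sa1,sa2 Additive variances of the two traits.
#' @param ra Additive (genetic) correlation.
#' @param se1,se2 Residual variances.
#' @param re Residual correlation.
#' @return Phenotypic correlation.
#' @export
#' @examples
#' rp_from_components(1, 1, 0.5, 1, 1, 0.1) # 0.3
rp_from_components <- function(sa1, sa2, ra, se1, se2, re) {
  (ra * sqrt(sa1 * sa2) + re * sqrt(se1 * se2)) /
    sqrt((sa1 + se1) * (sa2 + se2))
}

#' Fit the bivariate animal model and estimate trait correlations
#'
#' REML over six parameters (two additive variances, the genetic correlation
#' `r_a`, two residual variances, the residual correlation `r_e`) for a pair
#' of traits observed on overlapping trees, sharing the relationship matrix
#' `K`. The phenotypic correlation is assembled from the components (see
#' [rp_from_components()]). Significance: `r_a = 0` is tested by a 1-df
#' likelihood-ratio test, `r_a = r_e = 0` by a 2-df test.
#'
#' @inheritParams fit_univariate
#' @param traits Character vector of the two trait columns.
#' @param lrt Set `FALSE` to skip the reduced-model refits (faster in
#'   simulation loops).
#' @return Object of class `gs_bifit` with variance components, `r_a`, `r_e`,
#'   `r_p` (each with SE), log-likelihood, LRT p-values and a convergence
#'   flag.
#' @export
fit_bivariate <- function(data, K, traits, fixed = ~block, id_col = "id",
                          lrt = TRUE) {
  stopifnot(length(traits) == 2L)
  check_columns(data, c(id_col, traits, all.vars(fixed)), "phenotype data")
  keep <- is.finite(data[[traits[1]]]) & is.finite(data[[traits[2]]])
  data <- data[keep, , drop = FALSE]
  ids <- as.character(data[[id_col]])
  if (!all(ids %in% rownames(K))) {
    stop_input("all phenotyped individuals must appear in K")
  }
  if (nrow(data) < 30L) stop_input("bivariate model needs at least 30 records")
  mf <- data
  for (v in all.vars(fixed)) mf[[v]] <- factor(mf[[v]])
  X <- model.matrix(fixed, data = mf)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]

  ws1 <- reml_workspace(data[[traits[1]]], X, K[ids, ids])
  # reuse the rotation computed for trait 1 to rotate trait 2
  y2t <- drop(crossprod(ws1$U, data[[traits[2]]]))
  nll_raw <- bivar_nll_factory(ws1, y2t)
  nll <- function(th) nll_raw(to_natural(th))

  # starts from univariate component estimates
  uni <- lapply(traits, function(tr) {
    fit_univariate(data, K, tr, fixed = fixed, id_col = id_col,
                   compute_blup = FALSE)
  })
  sa0 <- vapply(uni, function(f) max(f$varcomp$estimate[1], 1e-6), numeric(1))
  se0 <- vapply(uni, function(f) max(f$varcomp$estimate[2], 1e-6), numeric(1))
  start <- c(log(sa0[1]), log(sa0[2]), 0, log(se0[1]), log(se0[2]), 0)
  lo <- c(rep(log(1e-10), 2), -6, rep(log(1e-10), 2), -6)
  hi <- c(rep(log(1e10), 2), 6, rep(log(1e10), 2), 6)
  opt <- nlminb(start, nll, lower = lo, upper = hi,
                control = list(iter.max = 500L, eval.max = 1000L))
  par <- to_natural(opt$par)
  names(par) <- c("sigma2_a_1", "sigma2_a_2", "r_a",
                  "sigma2_e_1", "sigma2_e_2", "r_e")
  ll <- -opt$objective
  boundary <- abs(par["r_a"]) > 0.999 || abs(par["r_e"]) > 0.999
  converged <- opt$convergence == 0 && is.finite(ll)

  # asymptotic SEs from the numerical Hessian on the natural scale
  vcov_par <- bivar_vcov(nll_raw, par)
  se_par <- sqrt(pmax(diag(vcov_par), 0))
  rp <- rp_from_components(par[1], par[2], par[3], par[4], par[5], par[6])
  grad_rp <- numeric_grad(function(p) {
    rp_from_components(p[1], p[2], p[3], p[4], p[5], p[6])
  }, par)
  rp_se <- sqrt(max(drop(t(grad_rp) %*% vcov_par %*% grad_rp), 0))

  p_genetic <- p_phenotypic <- NA_real_
  if (lrt) {
    fixed_fit <- function(free_idx, fixed_vals) {
      obj <- function(th_free) {
        th <- numeric(6L)
        th[free_idx] <- th_free
        th[-free_idx] <- fixed_vals
        nll(th)
      }
      o <- nlminb(start[free_idx], obj, lower = lo[free_idx],
                  upper = hi[free_idx],
                  control = list(iter.max = 500L, eval.max = 1000L))
      -o$objective
    }
    ll_ra0 <- fixed_fit(c(1, 2, 4, 5, 6), 0)        # r_a = 0
    ll_r00 <- fixed_fit(c(1, 2, 4, 5), c(0, 0))     # r_a = r_e = 0
    p_genetic <- pchisq(max(2 * (ll - ll_ra0), 0), df = 1, lower.tail = FALSE)
    p_phenotypic <- pchisq(max(2 * (ll - ll_r00), 0), df = 2,
                           lower.tail = FALSE)
  }

  structure(
    list(
      traits = traits,
      varcomp = tibble(
        parameter = names(par), estimate = unname(par), std_error = se_par
      ),
      r_a = unname(par["r_a"]), r_a_se = se_par[3],
      r_e = unname(par["r_e"]), r_e_se = se_par[6],
      r_p = unname(rp), r_p_se = rp_se,
      loglik = ll, p_genetic = p_genetic, p_phenotypic = p_phenotypic,
      n = nrow(data), converged = converged, boundary = boundary,
      K_kind = attr(K, "kind") %||% "K"
    ),
    class = "gs_bifit"
  )
}

numeric_grad <- function(fn, x, rel = 1e-5) {
  h <- pmax(abs(x) * rel, 1e-8)
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h[i]
    xm[i] <- xm[i] - h[i]
    (fn(xp) - fn(xm)) / (2 * h[i])
  }, numeric(1))
}

bivar_vcov <- function(nll_raw, par, rel = 1e-4) {
  k <- length(par)
  h <- pmax(abs(par) * rel, 1e-6)
  # keep correlations strictly inside (-1, 1) during differencing
  for (i in c(3L, 6L)) h[i] <- min(h[i], (0.999 - abs(par[i])) / 2 + 1e-8)
  hess <- matrix(NA_real_, k, k)
  f0 <- nll_raw(par)
  for (i in seq_len(k)) {
    for (j in i:k) {
      pp <- par; pp[i] <- pp[i] + h[i]; pp[j] <- pp[j] + h[j]
      pm <- par; pm[i] <- pm[i] + h[i]; pm[j] <- pm[j] - h[j]
      mp <- par; mp[i] <- mp[i] - h[i]; mp[j] <- mp[j] + h[j]
      mm <- par; mm[i] <- mm[i] - h[i]; mm[j] <- mm[j] - h[j]
      hess[i, j] <- hess[j, i] <-
        (nll_raw(pp) - nll_raw(pm) - nll_raw(mp) + nll_raw(mm)) /
        (4 * h[i] * h[j])
    }
  }
  out <- try(solve(hess), silent = TRUE)
  if (inherits(out, "try-error") || any(!is.finite(out))) {
    matrix(NA_real_, k, k)
  } else {
    out
  }
}

#' @export
print.gs_bifit <- function(x, ...) {
  cat(sprintf("<gs_bifit> %s ~ %s on %s (n = %d%s)\n",
              x$traits[1], x$traits[2], x$K_kind, x$n,
              if (x$converged) "" else ", NOT converged"))
  cat(sprintf("  r_a = %.3f (SE %.3f), r_e = %.3f (SE %.3f), r_p = %.3f (SE %.3f)\n",
              x$r_a, x$r_a_se, x$r_e, x$r_e_se, x$r_p, x$r_p_se))
  if (is.finite(x$p_genetic %||% NA)) {
    cat(sprintf("  LRT: genetic p = %.3g (1 df), phenotypic p = %.3g (2 df)\n",
                x$p_genetic, x$p_phenotypic))
  }
  invisible(x)
}
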