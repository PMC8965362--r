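# AI-REML animal model: likelihood identities, oracle equivalence, BLUP
# consistency, accuracy and rank correlations.

test_that("the restricted likelihood matches a dense-matrix evaluation", {
  trial <- tiny_trial()
  ph <- trial$phenotypes[1:60, ]
  K <- blend_K(suppressMessages(build_G(trial$genotypes)))
  ids <- ph$id
  X <- model.matrix(~ factor(block), data = ph)
  ws <- droughtgs:::reml_workspace(ph$height, X, K[ids, ids])
  for (th in list(c(5000, 8000), c(100, 20000), c(12000, 1500))) {
    expect_equal(droughtgs:::reml_eval(ws, th)$ll,
                 oracle_reml_ll(ph$height, X, K[ids, ids], th[1], th[2]),
                 tolerance = 1e-8)
  }
})

test_that("AI-REML agrees with the grid-search oracle on small instances", {
  trial <- tiny_trial()
  K <- blend_K(suppressMessages(build_G(trial$genotypes)))
  set.seed(8)
  for (r in 1:5) {
    n <- sample(40:60, 1)
    ph <- trial$phenotypes[sample(nrow(trial$phenotypes), n), ]
    fit <- fit_univariate(ph, K, "height", compute_blup = FALSE)
    grid <- oracle_reml_grid(
      ph$height, model.matrix(~ factor(block), data = ph),
      K[ph$id, ph$id]
    )
    expect_lt(abs(fit$h2 - grid["h2"]), 0.01)
  }
})

test_that("the REML log-likelihood never decreases along the trajectory", {
  trial <- big_trial()
  K <- blend_K(build_G(trial$genotypes))
  fit <- fit_univariate(trial$phenotypes, K, "wood_density")
  expect_true(fit$converged)
  expect_true(all(diff(fit$trajectory) > -1e-8))
  expect_true(all(fit$varcomp$estimate >= 0))
  expect_true(fit$h2 >= 0 && fit$h2 <= 1)
})

test_that("BLUP solutions satisfy the mixed-model equations", {
  trial <- tiny_trial()
  ph <- trial$phenotypes
  K <- blend_K(suppressMessages(build_G(trial$genotypes)))
  fit <- fit_univariate(ph, K, "height")
  sa <- fit$varcomp$estimate[1]
  se <- fit$varcomp$estimate[2]
  X <- model.matrix(~ factor(block), data = ph)
  all_ids <- rownames(K)
  Z <- matrix(0, nrow(ph), length(all_ids))
  Z[cbind(seq_len(nrow(ph)), match(ph$id, all_ids))] <- 1
  Kinv <- solve(K)
  C <- rbind(
    cbind(crossprod(X), crossprod(X, Z)),
    cbind(crossprod(Z, X), crossprod(Z) + (se / sa) * Kinv)
  )
  rhs <- c(crossprod(X, ph$height), crossprod(Z, ph$height))
  sol <- c(fit$beta$estimate, fit$ebv$ebv)
  expect_lt(sqrt(sum((C %*% sol - rhs)^2)) / sqrt(sum(rhs^2)), 1e-8)
  # the cheap point-EBV route agrees with the full MME solve
  fit_pt <- fit_univariate(ph, K, "height", compute_blup = "point")
  expect_equal(fit_pt$ebv$ebv, fit$ebv$ebv, tolerance = 1e-6)
})

test_that("repeated records on an identity K reduce to intraclass correlation", {
  set.seed(15)
  n_id <- 100
  reps <- 3
  u <- rnorm(n_id, sd = 1)
  ids <- sprintf("i%03d", seq_len(n_id))
  dat <- tibble::tibble(
    id = rep(ids, each = reps),
    block = 1L,
    y = rep(u, each = reps) + rnorm(n_id * reps, sd = 1)
  )
  K <- diag(n_id)
  dimnames(K) <- list(ids, ids)
  fit <- fit_univariate(dat, K, "y", fixed = ~1, compute_blup = FALSE)
  # balanced one-way ANOVA estimator (equals REML when interior)
  ybar <- tapply(dat$y, dat$id, mean)
  msb <- reps * var(ybar)
  msw <- sum((dat$y - ybar[dat$id])^2) / (n_id * (reps - 1))
  sa_aov <- (msb - msw) / reps
  h2_aov <- sa_aov / (sa_aov + msw)
  expect_equal(fit$h2, h2_aov, tolerance = 1e-3)
})

test_that("shuffling phenotypes against K collapses heritability", {
  trial <- big_trial()
  ph <- trial$phenotypes
  K <- blend_K(build_G(trial$genotypes))
  Kinv <- solve(K)
  set.seed(33)
  h2s <- vapply(1:20, function(r) {
    shuffled <- ph
    shuffled$height <- sample(shuffled$height)
    suppressWarnings(
      fit_univariate(shuffled, K, "height", compute_blup = FALSE)$h2
    )
  }, numeric(1))
  expect_lt(median(h2s), 0.05)
})

test_that("ABLUP and GBLUP heritabilities agree within their joint error", {
  trial <- big_trial()
  A <- build_A(trial$pedigree)
  G <- blend_K(build_G(trial$genotypes))
  fa <- fit_univariate(trial$phenotypes, A, "dbh", compute_blup = FALSE)
  fg <- fit_univariate(trial$phenotypes, G, "dbh", compute_blup = FALSE)
  expect_lt(abs(fa$h2 - fg$h2), 2 * (fa$h2_se + fg$h2_se))
})

test_that("theoretical accuracy follows its closed form", {
  fake <- structure(
    list(
      trait = "y",
      varcomp = tibble::tibble(component = c("additive", "residual"),
                               estimate = c(4, 1), std_error = c(NA, NA)),
      ebv = tibble::tibble(id = c("a", "b", "c", "d"),
                           ebv = 0,
                           se = c(0, 2, sqrt(0.75 * 4), 3))
    ),
    class = "gs_fit"
  )
  acc <- theoretical_accuracy(fake)
  expect_equal(acc$accuracy[acc$id == "a"], 1)            # SE = 0
  expect_equal(acc$accuracy[acc$id == "b"], 0)            # SE^2 = sigma2_a
  expect_equal(acc$accuracy[acc$id == "c"], 0.5)          # SE^2 = 0.75 sigma2_a
  expect_equal(acc$accuracy[acc$id == "d"], 0)            # clamped
  expect_equal(attr(acc, "n_clamped"), 1L)
  # inbreeding raises the denominator
  acc_f <- theoretical_accuracy(fake, inbreeding = c(a = 0, b = 1, c = 0,
                                                     d = 0))
  expect_equal(acc_f$accuracy[acc_f$id == "b"], sqrt(1 - 4 / 8))
})

test_that("family rank correlation handles the canonical cases", {
  fams <- sprintf("M%02d", 1:10)
  s1 <- tibble::tibble(family = fams, value = 1:10)
  expect_equal(family_rank_correlation(s1, s1)$rho, 1)
  s2 <- tibble::tibble(family = fams, value = 10:1)
  expect_equal(family_rank_correlation(s1, s2)$rho, -1)
  expect_error(
    family_rank_correlation(s1[1:4, ], s1[1:4, ]),
    "common families"
  )
  # independent site effects give small rank correlations on average
  set.seed(10)
  rhos <- vapply(1:30, function(r) {
    a <- tibble::tibble(family = fams, value = rnorm(10))
    b <- tibble::tibble(family = fams, value = rnorm(10))
    family_rank_correlation(a, b)$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.2)
})
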