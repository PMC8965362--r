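# Independent oracles kept deliberately naive: recursive coancestry for the
# pedigree relationship matrix, a dense-matrix REML log-likelihood with grid
# maximization, and a small random-pedigree generator.

# Malecot coancestry by direct recursion (memoized); A = 2f.
oracle_A <- function(pedigree) {
  ids <- pedigree$id
  pos <- setNames(seq_along(ids), ids)
  mo <- pos[pedigree$mother]
  fa <- pos[pedigree$father]
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i < j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      0.5 * (1 + f(mo[i], fa[i]))
    } else {
      # i is the later-born of the pair; descend through i's parents
      0.5 * (f(mo[i], j) + f(fa[i], j))
    }
    memo[[key]] <- val
    val
  }
  n <- length(ids)
  a <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    a[i, j] <- a[j, i] <- 2 * f(i, j)
  }
  a
}

# Random polycross-style pedigree, founders first (so the recursion in
# oracle_A can descend through the later individual of a pair).
random_pedigree <- function(n_founders, n_off, seed) {
  withr::with_seed(seed, {
    fnd <- sprintf("F%02d", seq_len(n_founders))
    off <- sprintf("O%02d", seq_len(n_off))
    parents_of <- function(k) sample(c(fnd, head(off, k - 1L)), 2L,
                                     replace = TRUE)
    mo <- character(n_off)
    fa <- character(n_off)
    for (k in seq_len(n_off)) {
      p <- parents_of(k)
      mo[k] <- p[1]
      fa[k] <- p[2]
    }
    tibble::tibble(
      id = c(fnd, off),
      mother = c(rep(NA_character_, n_founders), mo),
      father = c(rep(NA_character_, n_founders), fa)
    )
  })
}

# Dense REML log-likelihood, straight from the definition (no rotation).
oracle_reml_ll <- function(y, X, K, sa, se) {
  v <- sa * K + se * diag(length(y))
  cv <- chol(v)
  vi <- chol2inv(cv)
  xtvx <- t(X) %*% vi %*% X
  beta <- solve(xtvx, t(X) %*% vi %*% y)
  r <- y - X %*% beta
  as.numeric(
    -0.5 * (2 * sum(log(diag(cv))) + determinant(xtvx)$modulus +
              t(r) %*% vi %*% r + (length(y) - ncol(X)) * log(2 * pi))
  )
}

# Grid-search REML: outer grid on h2, inner 1-D optimization of the total
# variance at each h2.
oracle_reml_grid <- function(y, X, K, h2_grid = seq(0.005, 0.995, by = 0.005)) {
  vy <- var(y)
  best <- c(h2 = NA_real_, ll = -Inf)
  for (h2 in h2_grid) {
    opt <- optimize(function(vt) {
      oracle_reml_ll(y, X, K, h2 * vt, (1 - h2) * vt)
    }, interval = c(vy / 50, vy * 50), maximum = TRUE, tol = 1e-6)
    if (opt$objective > best["ll"]) best <- c(h2 = h2, ll = opt$objective)
  }
  best
}

# Small trial used across tests; memoized per session.
tiny_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_trial(sim_config(
        n_snps = 120, n_sites = 1, offspring_per_family_per_site = 4,
        seed = 123
      ))
    }
    cache
  }
})

# Larger single-site trial (n = 608) shared by the heavier tests.
big_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_trial(sim_config(
        n_sites = 1, offspring_per_family_per_site = 16, seed = 2024
      ))
    }
    cache
  }
})

# Strip all attributes except dim/dimnames (e.g. simulator bookkeeping).
unname_attrs <- function(m) {
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}
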