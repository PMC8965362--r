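# Pedigree A, its inverse, and the VanRaden G matrix.

test_that("A reproduces textbook relationships", {
  ped <- tibble::tibble(
    id = c("m", "f", "kid1", "kid2", "half"),
    mother = c(NA, NA, "m", "m", "m"),
    father = c(NA, NA, "f", "f", "f2")
  )
  a <- build_A(ped)
  expect_equal(a["m", "kid1"], 0.5)   # parent-offspring
  expect_equal(a["kid1", "kid2"], 0.5) # full sibs
  expect_equal(a["kid1", "half"], 0.25) # half sibs (shared mother)
  expect_equal(unname(diag(a)[c("kid1", "kid2")]), c(1, 1))

  selfed <- tibble::tibble(id = c("p", "s"), mother = c(NA, "p"),
                           father = c(NA, "p"))
  a_s <- build_A(selfed)
  expect_equal(a_s["s", "s"], 1.5)
  expect_equal(attr(a_s, "inbreeding")[["s"]], 0.5)
})

test_that("A equals the recursive coancestry oracle on random pedigrees", {
  for (r in 1:5) {
    ped <- random_pedigree(n_founders = 8, n_off = 40, seed = 400 + r)
    expect_equal(build_A(ped), oracle_A(ped), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("A is PSD and invariant under input permutation", {
  ped <- random_pedigree(10, 40, seed = 9)
  a <- build_A(ped)
  expect_gte(min(eigen(a, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  perm <- ped[sample(nrow(ped)), ]
  a2 <- build_A(perm)
  expect_equal(a2[rownames(a), colnames(a)], a, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("pedigree cycles and duplicates are rejected", {
  cyc <- tibble::tibble(id = c("a", "b"), mother = c("b", "a"),
                        father = c(NA, NA))
  expect_error(build_A(cyc), "cycle")
  dup <- tibble::tibble(id = c("a", "a"), mother = c(NA, NA),
                        father = c(NA, NA))
  expect_error(build_A(dup), "duplicate")
})

test_that("the A inverse passes the product test", {
  trial <- tiny_trial()
  ped <- trial$pedigree
  keep <- c(which(is.na(ped$mother)), which(!is.na(ped$mother))[1:143])
  ped <- ped[keep, ] # 200 individuals
  a <- build_A(ped)
  ainv <- build_A_inverse(ped)
  expect_equal(unname_attrs(a %*% ainv), diag(nrow(a)), tolerance = 1e-8,
               ignore_attr = TRUE)

  founders <- tibble::tibble(id = letters[1:6], mother = NA_character_,
                             father = NA_character_)
  expect_equal(build_A_inverse(founders), diag(6), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("G matches the VanRaden hand example and HWE expectations", {
  m <- matrix(c(0L, 2L, 2L, 0L), nrow = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  g <- build_G(m, maf_min = 0)
  expect_equal(g, matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12,
               ignore_attr = TRUE)

  # all-heterozygous individual at p = 0.5 SNPs has G_ii = 0, i.e. F = -1
  m2 <- rbind(a = c(0L, 2L), b = c(2L, 0L), c = c(1L, 1L), d = c(1L, 1L))
  colnames(m2) <- c("s1", "s2")
  g2 <- build_G(m2, maf_min = 0)
  expect_equal(g2["c", "c"], 0, tolerance = 1e-12)
  expect_equal(attr(g2, "inbreeding")[["c"]], -1, tolerance = 1e-12)

  # HWE founders: mean diagonal near 1
  cfg <- sim_config(n_mothers = 120, n_fathers = 80, n_snps = 1000, seed = 14)
  gh <- build_G(simulate_founders(cfg))
  expect_gt(mean(diag(gh)), 0.95)
  expect_lt(mean(diag(gh)), 1.05)
})

test_that("missing dosages are mean-imputed and filters can empty the panel", {
  m <- rbind(a = c(0L, 1L, 0L), b = c(2L, 1L, 0L), c = c(NA, 1L, 0L))
  colnames(m) <- c("s1", "s2", "s3")
  expect_message(g <- build_G(m, maf_min = 0), "excluded 1")
  expect_equal(dim(g), c(3L, 3L))
  mono <- rbind(a = c(0L, 2L), b = c(0L, 2L))
  expect_error(suppressMessages(build_G(mono)), "monomorphic")
})

test_that("G recovers full-sib and half-sib relatedness on a polycross", {
  trial <- big_trial() # 500 SNPs
  g <- build_G(trial$genotypes)
  ped <- trial$pedigree[!is.na(trial$pedigree$mother), ]
  key <- paste(ped$mother, ped$father)
  fs <- c()
  for (fam in unique(key)) {
    ids <- ped$id[key == fam]
    if (length(ids) < 2) next
    sub <- g[ids, ids]
    fs <- c(fs, sub[upper.tri(sub)])
  }
  hs <- c()
  set.seed(3)
  idx <- sample(nrow(ped), 250)
  for (k in idx) {
    for (j in idx) {
      if (j < k && key[k] != key[j] &&
          (ped$mother[k] == ped$mother[j] ||
           ped$father[k] == ped$father[j])) {
        hs <- c(hs, g[ped$id[k], ped$id[j]])
      }
    }
  }
  expect_lt(abs(mean(fs) - 0.5), 0.05)
  expect_lt(abs(mean(hs) - 0.25), 0.05)
})

test_that("blending restores positive definiteness", {
  # rank-deficient G: more individuals than informative dimensions
  cfg <- sim_config(n_mothers = 30, n_fathers = 10, n_snps = 12,
                    maf_range = c(0.3, 0.5), seed = 31)
  g <- suppressMessages(build_G(simulate_founders(cfg), maf_min = 0))
  expect_lt(min(eigen(g, symmetric = TRUE, only.values = TRUE)$values), 1e-10)
  gb <- blend_K(g, weight = 0.01)
  expect_gt(min(eigen(gb, symmetric = TRUE, only.values = TRUE)$values), 0)

  expect_equal(blend_K(g, weight = 1), diag(nrow(g)), ignore_attr = TRUE)
  pd <- diag(4) + 0.2
  expect_equal(blend_K(pd, weight = 0), pd, tolerance = 1e-15,
               ignore_attr = TRUE)
})
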