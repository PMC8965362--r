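#' Configuration for a synthetic polycross trial
#'
#' Builds the configuration object consumed by [simulate_trial()] and the
#' individual generators. Defaults emulate a replicated white spruce polycross
#' progeny test: 38 maternal families sired by a 19-father polymix, planted on
#' two sites in four randomized complete blocks (about 300 offspring per
#' site), genotyped at biallelic Mendelian SNPs, with an additive multi-trait
#' architecture, juvenile-trend basal area increment (BAI) series carrying one
#' drought-year growth multiplier per site, and daily climate containing a dry
#' summer in each site's drought year.
#'
#' Trait means and standard deviations default to realistic values for height
#' (cm), diameter at breast height (mm), wood density (kg/m3) and acoustic
#' velocity (km/s) on a boreal and a more southern, more productive site.
#' Heritabilities default to the 0.4-0.5 range typical for these traits;
#' the drought-year multiplier is itself heritable so that drought-response
#' components computed downstream carry recoverable genetic signal.
#'
#' @param n_mothers,n_fathers Number of maternal parents and polymix fathers.
#' @param offspring_per_family_per_site Offspring per maternal family on each
#'   site (balanced design unless `family_size_range` is given).
#' @param family_size_range Optional length-2 integer range; when given, each
#'   family x site cell draws its size uniformly from this range.
#' @param n_sites,n_blocks Number of sites and of complete blocks per site.
#' @param n_snps Number of biallelic SNPs to simulate (the emulated assay had
#'   4091; the default keeps desk-scale runs fast).
#' @param maf_range Range (0, 0.5] from which each SNP's minor allele
#'   frequency is drawn uniformly.
#' @param trait_names Character vector of trait names.
#' @param h2_true Named per-trait narrow-sense heritabilities in (0, 1).
#' @param genetic_corr_true Symmetric positive-definite genetic correlation
#'   matrix among traits (unit diagonal).
#' @param residual_corr_true Optional residual correlation matrix (defaults to
#'   identity).
#' @param pheno_means,pheno_sds Site x trait matrices of phenotypic means and
#'   standard deviations on the measurement scale (rows recycled over sites).
#' @param block_sd_frac Block effect standard deviation as a fraction of the
#'   within-site phenotypic SD.
#' @param years Calendar years spanned by the ring series.
#' @param drought_year_per_site One drought year per site.
#' @param drought_multiplier_mean Per-site mean of the drought-year growth
#'   multiplier (defaults 0.94 and 0.88, i.e. 6% and 12% mean growth loss).
#' @param drought_multiplier_sd Total SD of the multiplier across trees.
#' @param drought_multiplier_h2 Heritability of the multiplier in (0, 1).
#' @param drought_multiplier_cor_height Genetic correlation between the
#'   multiplier and height.
#' @param father_weights Optional unnormalized polymix contribution weights
#'   (defaults to equal pollen contribution).
#' @param seed Master seed; every generator derives fixed sub-streams from it.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_snps = 50, offspring_per_family_per_site = 2)
#' cfg$n_mothers
sim_config <- function(n_mothers = 38L,
                       n_fathers = 19L,
                       offspring_per_family_per_site = 8L,
                       family_size_range = NULL,
                       n_sites = 2L,
                       n_blocks = 4L,
                       n_snps = 500L,
                       maf_range = c(0.05, 0.5),
                       trait_names = c("height", "dbh", "wood_density",
                                       "acoustic_velocity"),
                       h2_true = c(height = 0.46, dbh = 0.45,
                                   wood_density = 0.42,
                                   acoustic_velocity = 0.41),
                       genetic_corr_true = NULL,
                       residual_corr_true = NULL,
                       pheno_means = rbind(c(784.0, 126.3, 382.6, 3.0),
                                           c(1099.8, 160.0, 368.9, 3.2)),
                       pheno_sds = rbind(c(158.4, 24.7, 28.9, 0.4),
                                         c(120.1, 21.4, 28.8, 0.3)),
                       block_sd_frac = 0.1,
                       years = 1997:2015,
                       drought_year_per_site = c(2010L, 2012L),
                       drought_multiplier_mean = c(0.94, 0.88),
                       drought_multiplier_sd = 0.18,
                       drought_multiplier_h2 = 0.25,
                       drought_multiplier_cor_height = 0.25,
                       father_weights = NULL,
                       seed = 42L) {
  n_traits <- length(trait_names)
  if (is.null(genetic_corr_true)) {
    genetic_corr_true <- default_genetic_corr(trait_names)
  }
  if (!is.matrix(pheno_means)) pheno_means <- matrix(pheno_means, nrow = 1L)
  if (!is.matrix(pheno_sds)) pheno_sds <- matrix(pheno_sds, nrow = 1L)
  cfg <- list(
    n_mothers = as.integer(n_mothers),
    n_fathers = as.integer(n_fathers),
    offspring_per_family_per_site = as.integer(offspring_per_family_per_site),
    family_size_range = family_size_range,
    n_sites = as.integer(n_sites),
    n_blocks = as.integer(n_blocks),
    n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    trait_names = trait_names,
    h2_true = h2_true[trait_names],
    genetic_corr_true = genetic_corr_true,
    residual_corr_true = residual_corr_true,
    pheno_means = pheno_means,
    pheno_sds = pheno_sds,
    block_sd_frac = block_sd_frac,
    years = as.integer(years),
    drought_year_per_site = as.integer(drought_year_per_site),
    drought_multiplier_mean = drought_multiplier_mean,
    drought_multiplier_sd = drought_multiplier_sd,
    drought_multiplier_h2 = drought_multiplier_h2,
    drought_multiplier_cor_height = drought_multiplier_cor_height,
    father_weights = father_weights,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

# Mild default genetic correlation structure: strong height-diameter
# correlation, weak negative growth vs wood density, weak positive
# density vs acoustic velocity; zero elsewhere.
default_genetic_corr <- function(trait_names) {
  n <- length(trait_names)
  r <- diag(n)
  dimnames(r) <- list(trait_names, trait_names)
  set_r <- function(r, a, b, v) {
    if (a %in% trait_names && b %in% trait_names) {
      r[a, b] <- v
      r[b, a] <- v
    }
    r
  }
  r <- set_r(r, "height", "dbh", 0.7)
  r <- set_r(r, "height", "wood_density", -0.2)
  r <- set_r(r, "dbh", "wood_density", -0.2)
  r <- set_r(r, "height", "acoustic_velocity", -0.1)
  r <- set_r(r, "dbh", "acoustic_velocity", -0.1)
  r <- set_r(r, "wood_density", "acoustic_velocity", 0.3)
  r
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_mothers)) stop_config("n_mothers must be a positive integer")
  if (!is_count(cfg$n_fathers, min = 2L)) {
    stop_config("n_fathers must be an integer >= 2")
  }
  if (!is_count(cfg$offspring_per_family_per_site)) {
    stop_config("offspring_per_family_per_site must be >= 1")
  }
  if (length(cfg$maf_range) != 2L || any(!is.finite(cfg$maf_range)) ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop_config("maf_range must lie within (0, 0.5] with min <= max")
  }
  if (any(cfg$h2_true <= 0 | cfg$h2_true >= 1) || anyNA(cfg$h2_true)) {
    stop_config("h2_true must provide a value in (0, 1) for every trait")
  }
  r <- cfg$genetic_corr_true
  if (!isTRUE(all.equal(unname(diag(r)), rep(1, nrow(r)), tolerance = 1e-10)) ||
      max(abs(r - t(r))) > 1e-10) {
    stop_config("genetic_corr_true must be symmetric with unit diagonal")
  }
  if (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
    stop_config("genetic_corr_true must be positive definite")
  }
  if (cfg$drought_multiplier_h2 <= 0 || cfg$drought_multiplier_h2 >= 1) {
    stop_config("drought_multiplier_h2 must lie in (0, 1)")
  }
  if (length(cfg$drought_year_per_site) < cfg$n_sites) {
    stop_config("drought_year_per_site must supply one year per site")
  }
  if (!all(cfg$drought_year_per_site[seq_len(cfg$n_sites)] %in% cfg$years)) {
    stop_config("every drought year must fall inside `years`")
  }
  invisible(cfg)
}

founder_ids <- function(cfg) {
  list(
    mothers = sprintf("M%02d", seq_len(cfg$n_mothers)),
    fathers = sprintf("F%02d", seq_len(cfg$n_fathers))
  )
}

#' Simulate founder genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP draws a minor allele frequency uniformly from `maf_range`, then
#' founder dosages are sampled as Binomial(2, p). Mothers and fathers are
#' returned together; no missing values are generated.
#'
#' @param config A [sim_config()] object.
#' @param seed Seed (defaults to a fixed sub-stream of `config$seed`).
#' @return Integer matrix of 0/1/2 dosages, individuals in rows (founder ids)
#'   and SNPs in columns, with the drawn allele frequencies in attribute
#'   `"maf"`.
#' @export
simulate_founders <- function(config, seed = substream(config$seed, 1L)) {
  validate_sim_config(config)
  ids <- founder_ids(config)
  all_ids <- c(ids$mothers, ids$fathers)
  n <- length(all_ids)
  with_seed(seed, {
    maf <- runif(config$n_snps, config$maf_range[1], config$maf_range[2])
    geno <- matrix(
      rbinom(n * config$n_snps, size = 2L, prob = rep(maf, each = n)),
      nrow = n, ncol = config$n_snps,
      dimnames = list(all_ids, sprintf("snp_%04d", seq_len(config$n_snps)))
    )
    attr(geno, "maf") <- maf
    geno
  })
}

#' Simulate a polycross pedigree and field design
#'
#' Every offspring receives its family's mother; the father is drawn from the
#' polymix (uniformly by default, emulating equal pollen volumes, or with
#' `father_weights`). Offspring are allocated to complete blocks within each
#' site so that families are spread evenly across blocks.
#'
#' @inheritParams simulate_founders
#' @return A tibble pedigree with founders first (`mother`/`father` `NA`) and
#'   one row per offspring with columns `id`, `mother`, `father`, `family`,
#'   `site`, `block`.
#' @export
simulate_polycross <- function(config, seed = substream(config$seed, 2L)) {
  validate_sim_config(config)
  ids <- founder_ids(config)
  w <- config$father_weights
  if (!is.null(w)) {
    if (length(w) != config$n_fathers || any(w < 0) || sum(w) <= 0) {
      stop_config("father_weights must be non-negative with a positive sum")
    }
    w <- w / sum(w)
  }
  founders <- tibble(
    id = c(ids$mothers, ids$fathers),
    mother = NA_character_, father = NA_character_,
    family = NA_character_, site = NA_integer_, block = NA_integer_
  )
  with_seed(seed, {
    rows <- list()
    for (s in seq_len(config$n_sites)) {
      for (m in ids$mothers) {
        n_off <- if (is.null(config$family_size_range)) {
          config$offspring_per_family_per_site
        } else {
          sample(config$family_size_range[1]:config$family_size_range[2], 1L)
        }
        fathers <- if (is.null(w)) {
          sample(ids$fathers, n_off, replace = TRUE)
        } else {
          sample(ids$fathers, n_off, replace = TRUE, prob = w)
        }
        blocks <- rep_len(sample(seq_len(config$n_blocks)), n_off)
        rows[[length(rows) + 1L]] <- tibble(
          id = sprintf("S%d_%s_%02d", s, m, seq_len(n_off)),
          mother = m, father = fathers, family = m,
          site = s, block = blocks
        )
      }
    }
    dplyr::bind_rows(founders, rows)
  })
}

#' Drop offspring genotypes through the pedigree by Mendelian gamete sampling
#'
#' For every offspring and locus, one allele is sampled from each parent's
#' genotype independently (probability dosage/2 of transmitting the counted
#' allele), so parent pairs (2, 0) always transmit a heterozygote.
#'
#' @param pedigree Pedigree tibble from [simulate_polycross()].
#' @param founder_genotypes Dosage matrix from [simulate_founders()].
#' @param seed Seed.
#' @return Integer dosage matrix for founders and offspring combined.
#' @export
drop_genotypes <- function(pedigree, founder_genotypes,
                           seed = 1L) {
  check_columns(pedigree, c("id", "mother", "father"), "pedigree")
  off <- pedigree[!is.na(pedigree$mother) | !is.na(pedigree$father), ]
  parents <- unique(c(off$mother, off$father))
  missing <- setdiff(parents[!is.na(parents)], rownames(founder_genotypes))
  if (length(missing) > 0L) {
    stop_input(sprintf(
      "ungenotyped parent(s): %s", paste(missing, collapse = ", ")
    ))
  }
  if (anyNA(off$mother) || anyNA(off$father)) {
    stop_input("offspring with a single known parent are not supported")
  }
  n_snp <- ncol(founder_genotypes)
  with_seed(seed, {
    dm <- founder_genotypes[off$mother, , drop = FALSE]
    dp <- founder_genotypes[off$father, , drop = FALSE]
    allele_m <- matrix(rbinom(length(dm), 1L, dm / 2), nrow = nrow(dm))
    allele_p <- matrix(rbinom(length(dp), 1L, dp / 2), nrow = nrow(dp))
    geno_off <- allele_m + allele_p
    dimnames(geno_off) <- list(off$id, colnames(founder_genotypes))
    out <- rbind(founder_genotypes, geno_off)
    attr(out, "maf") <- attr(founder_genotypes, "maf")
    out
  })
}

#' Simulate multi-trait phenotypes with a marker-effect architecture
#'
#' Marker effects are drawn multivariate normal across traits (and the
#' drought-year growth multiplier) with the configured genetic correlation
#' structure, then rescaled so the realized additive variance among offspring
#' matches `h2_true` exactly on a standardized within-site scale. Phenotype =
#' site mean + block effect + true breeding value + residual, mapped to the
#' measurement scale through the per-site means and SDs.
#'
#' @inheritParams drop_genotypes
#' @param config A [sim_config()].
#' @param genotypes Combined dosage matrix from [drop_genotypes()].
#' @return A list with `truth` (marker effects, true breeding values on the
#'   standardized scale, per-tree drought multiplier, realized heritabilities)
#'   and `phenotypes` (a per-tree tibble with design columns and one column
#'   per trait on the measurement scale).
#' @export
simulate_traits <- function(config, genotypes, pedigree,
                            seed = substream(config$seed, 3L)) {
  validate_sim_config(config)
  traits <- config$trait_names
  n_traits <- length(traits)
  off <- pedigree[!is.na(pedigree$site), ]
  if (!all(off$id %in% rownames(genotypes))) {
    stop_input("all offspring must be genotyped before trait simulation")
  }

  ext <- c(traits, "drought_multiplier")
  r_ext <- diag(length(ext))
  dimnames(r_ext) <- list(ext, ext)
  r_ext[traits, traits] <- config$genetic_corr_true
  if ("height" %in% traits) {
    r_ext["height", "drought_multiplier"] <- config$drought_multiplier_cor_height
    r_ext["drought_multiplier", "height"] <- config$drought_multiplier_cor_height
  }
  ch <- try(chol(r_ext), silent = TRUE)
  if (!inherits(ch, "matrix")) {
    stop_config("genetic correlation structure (traits + drought multiplier) is not positive definite")
  }

  h2_ext <- c(config$h2_true, drought_multiplier = config$drought_multiplier_h2)
  zc <- sweep(genotypes, 2L, colMeans(genotypes))
  with_seed(seed, {
    b_raw <- matrix(rnorm(ncol(genotypes) * length(ext)), ncol = length(ext)) %*% ch
    raw_bv <- zc %*% b_raw
    scale_fac <- vapply(seq_along(ext), function(j) {
      s <- sd(raw_bv[off$id, j])
      if (s == 0) stop_input("degenerate additive variance; increase n_snps")
      sqrt(h2_ext[j]) / s
    }, numeric(1))
    marker_effects <- sweep(b_raw, 2L, scale_fac, `*`)
    dimnames(marker_effects) <- list(colnames(genotypes), ext)
    true_bv <- zc %*% marker_effects

    # residuals (standardized scale), correlated across traits if requested
    r_e <- config$residual_corr_true %||% diag(n_traits)
    resid_sd <- sqrt(1 - config$h2_true)
    e <- matrix(rnorm(nrow(off) * n_traits), ncol = n_traits) %*% chol(r_e)
    e <- sweep(e, 2L, resid_sd, `*`)

    # block effects per site x block x trait
    blk <- array(
      rnorm(config$n_sites * config$n_blocks * n_traits,
            sd = config$block_sd_frac),
      dim = c(config$n_sites, config$n_blocks, n_traits)
    )
    blk_eff <- sapply(seq_len(n_traits), function(t) {
      blk[cbind(off$site, off$block, t)]
    })

    bv_off <- true_bv[off$id, traits, drop = FALSE]
    std <- blk_eff + bv_off + e
    means <- config$pheno_means[rep_len(seq_len(nrow(config$pheno_means)),
                                        config$n_sites), , drop = FALSE]
    sds <- config$pheno_sds[rep_len(seq_len(nrow(config$pheno_sds)),
                                    config$n_sites), , drop = FALSE]
    pheno <- means[off$site, , drop = FALSE] + sds[off$site, , drop = FALSE] * std
    colnames(pheno) <- traits

    # heritable drought multiplier, clamped to a biologically sane range
    mult_g <- true_bv[off$id, "drought_multiplier"]
    mult_e <- rnorm(nrow(off), sd = sqrt(1 - config$drought_multiplier_h2))
    mu_m <- rep_len(config$drought_multiplier_mean, config$n_sites)
    mult <- mu_m[off$site] +
      config$drought_multiplier_sd * (mult_g + mult_e)
    mult <- pmin(pmax(mult, 0.05), 1.5)
    names(mult) <- off$id

    realized <- dplyr::bind_rows(lapply(seq_len(config$n_sites), function(s) {
      i <- off$site == s
      tibble(
        site = s, trait = traits,
        h2_target = unname(config$h2_true),
        h2_realized = vapply(seq_len(n_traits), function(t) {
          var(bv_off[i, t]) / (var(bv_off[i, t]) + var(e[i, t]))
        }, numeric(1))
      )
    }))

    phenotypes <- dplyr::bind_cols(
      off[, c("id", "site", "block", "family", "mother", "father")],
      as_tibble(pheno)
    )
    list(
      truth = list(
        marker_effects = marker_effects,
        true_bv = true_bv,
        true_drought_multiplier = mult,
        realized_h2 = realized
      ),
      phenotypes = phenotypes
    )
  })
}

#' Simulate ring-width series with a drought-year growth multiplier
#'
#' Expected BAI follows a juvenile saturating trend scaled by a per-tree
#' vigor term tied to the height breeding value, multiplied by a common
#' lognormal year effect per site, a per-tree drought-year multiplier (in the
#' site's drought year only) and lognormal tree-year noise. BAI is inverted to
#' strictly positive ring widths assuming growth from the pith.
#'
#' @inheritParams simulate_traits
#' @param truth Truth list from [simulate_traits()].
#' @param bai_base Per-site asymptotic expected BAI (mm2/yr).
#' @param year_sd,tree_sd Lognormal SDs of the site-year effect and the
#'   tree-year noise.
#' @return Tibble with columns `id`, `site`, `year`, `width` (mm) and `bai`
#'   (mm2).
#' @export
simulate_ring_series <- function(config, truth, pedigree,
                                 seed = substream(config$seed, 4L),
                                 bai_base = c(600, 900),
                                 year_sd = 0.15, tree_sd = 0.1) {
  validate_sim_config(config)
  off <- pedigree[!is.na(pedigree$site), ]
  years <- config$years
  n_yr <- length(years)
  age <- seq_len(n_yr)
  trend <- 1 - exp(-age / 6)
  base <- rep_len(bai_base, config$n_sites)
  has_height <- "height" %in% colnames(truth$true_bv)
  with_seed(seed, {
    year_eff <- matrix(
      exp(rnorm(config$n_sites * n_yr, sd = year_sd) - year_sd^2 / 2),
      nrow = config$n_sites
    )
    out <- vector("list", nrow(off))
    for (i in seq_len(nrow(off))) {
      id <- off$id[i]
      s <- off$site[i]
      vig <- if (has_height) exp(0.2 * truth$true_bv[id, "height"]) else 1
      mult <- rep(1, n_yr)
      mult[years == config$drought_year_per_site[s]] <-
        truth$true_drought_multiplier[id]
      noise <- exp(rnorm(n_yr, sd = tree_sd) - tree_sd^2 / 2)
      bai <- base[s] * trend * vig * year_eff[s, ] * mult * noise
      r <- sqrt(cumsum(bai) / pi)
      out[[i]] <- tibble(
        id = id, site = s, year = years,
        width = diff(c(0, r)), bai = bai
      )
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate daily climate with optional drought summers
#'
#' Sinusoidal seasonal temperature with Gaussian noise; precipitation as
#' Bernoulli wet days with Gamma amounts. In drought years, summer
#' (June-August by default) precipitation amounts are scaled by
#' `drought_precip_factor`, giving a dry mid-summer with at least 40% less
#' July-August rain in expectation (60% less at the default 0.4).
#'
#' @param years Integer vector of calendar years (contiguous or not).
#' @param drought_years Years whose July-August rainfall is reduced.
#' @param seed Seed.
#' @param t_mean,t_amplitude,t_noise_sd Annual mean temperature (degC), seasonal
#'   half-amplitude and daily noise SD.
#' @param wet_prob Daily probability of rain.
#' @param precip_shape,precip_mean Gamma shape and mean (mm) of wet-day rain.
#' @param drought_months Months whose rain is reduced in drought years
#'   (default June-August: deep-layer drought indices respond with a lag, so
#'   a dry mid-summer on the ground starts earlier in the season).
#' @param drought_precip_factor Multiplier on drought-month rain in drought
#'   years.
#' @return Tibble with columns `date`, `tmean`, `precip`.
#' @export
simulate_climate <- function(years, drought_years = integer(), seed = 1L,
                             t_mean = 2.5, t_amplitude = 16, t_noise_sd = 2.5,
                             wet_prob = 0.45, precip_shape = 0.7,
                             precip_mean = 6, drought_months = 6:8,
                             drought_precip_factor = 0.4) {
  if (length(years) == 0L) stop_input("empty year range")
  years <- sort(unique(as.integer(years)))
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  dates <- dates[as.integer(format(dates, "%Y")) %in% years]
  doy <- as.integer(format(dates, "%j"))
  yr <- as.integer(format(dates, "%Y"))
  mo <- as.integer(format(dates, "%m"))
  with_seed(seed, {
    tmean <- t_mean - t_amplitude * cos(2 * pi * (doy - 15) / 365.25) +
      rnorm(length(dates), sd = t_noise_sd)
    wet <- rbinom(length(dates), 1L, wet_prob)
    amount <- rgamma(length(dates), shape = precip_shape,
                     scale = precip_mean / precip_shape)
    precip <- wet * amount
    dry <- yr %in% drought_years & mo %in% drought_months
    precip[dry] <- precip[dry] * drought_precip_factor
    tibble(date = dates, tmean = round(tmean, 2), precip = round(precip, 2))
  })
}

#' Simulate a complete polycross trial dataset
#'
#' Runs the whole generator chain (founders, polycross pedigree, Mendelian
#' genotype dropping, multi-trait phenotypes, ring series, per-site climate)
#' from one master seed, so every downstream analysis stage can be exercised
#' against known ground truth.
#'
#' @param config A [sim_config()].
#' @param climate_years Years of daily climate to generate (defaults to a
#'   31-year span ending at the last ring year, wide enough for a 1985-2015
#'   style anomaly baseline).
#' @return A list of class `gs_trial`: `config`, `pedigree`, `genotypes`,
#'   `truth`, `phenotypes`, `rings`, `climate` (list of per-site tibbles).
#' @export
#' @examples
#' trial <- simulate_trial(sim_config(n_snps = 100, n_sites = 1,
#'                                    offspring_per_family_per_site = 2))
#' names(trial)
simulate_trial <- function(config = sim_config(),
                           climate_years = (max(config$years) - 30):max(config$years)) {
  validate_sim_config(config)
  founders <- simulate_founders(config)
  pedigree <- simulate_polycross(config)
  genotypes <- drop_genotypes(pedigree, founders,
                              seed = substream(config$seed, 5L))
  sim <- simulate_traits(config, genotypes, pedigree)
  rings <- simulate_ring_series(config, sim$truth, pedigree)
  climate <- lapply(seq_len(config$n_sites), function(s) {
    simulate_climate(climate_years,
                     drought_years = config$drought_year_per_site[s],
                     seed = substream(config$seed, 10L + s))
  })
  structure(
    list(config = config, pedigree = pedigree, genotypes = genotypes,
         truth = sim$truth, phenotypes = sim$phenotypes, rings = rings,
         climate = climate),
    class = "gs_trial"
  )
}

#' @export
print.gs_trial <- function(x, ...) {
  off <- x$pedigree[!is.na(x$pedigree$site), ]
  cat("<gs_trial>\n")
  cat(sprintf("  %d offspring (%d sites), %d founders, %d SNPs\n",
              nrow(off), x$config$n_sites,
              x$config$n_mothers + x$config$n_fathers, x$config$n_snps))
  cat(sprintf("  traits: %s\n", paste(x$config$trait_names, collapse = ", ")))
  cat(sprintf("  drought year(s): %s\n",
              paste(x$config$drought_year_per_site[seq_len(x$config$n_sites)],
                    collapse = ", ")))
  invisible(x)
}
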