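# Configuration-driven orchestration of the full analysis: simulate (or
# load) -> climate indices -> dendro -> drought components -> relatedness ->
# genetic evaluation -> cross-validation -> selection gains, with one
# reproducible report bundle per configuration hash.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] describing the trial to simulate.
#' @param seed Master seed (overrides `sim$seed`).
#' @param methods Evaluation methods, subset of `"ABLUP"`, `"GBLUP"`.
#' @param post_valid_per_site Logical per site: is the post-drought window
#'   usable? (`FALSE` emulates a stand thinning right after the drought, so
#'   only resistance is computed for that site.)
#' @param pre_years,post_years Lloret window lengths.
#' @param dc_baseline Baseline year range for Drought Code anomalies.
#' @param chronology_min_frac Minimum fraction of trees present for a
#'   chronology year to be reported.
#' @param cv List: `enabled`, `traits`, `k`, `repeats`.
#' @param correlations List: `enabled`, `conventional` (traits paired with
#'   each drought component), `method`.
#' @param scenarios Named list of [selection_scenario()] objects.
#' @param proportion Selection fraction for gains.
#' @param blend_weight Identity blending weight applied to G before use.
#' @param quiet Suppress progress messages.
#' @return List of class `gs_pipeline_config`.
#' @export
gs_pipeline_config <- function(sim = sim_config(),
                               seed = sim$seed,
                               methods = c("ABLUP", "GBLUP"),
                               post_valid_per_site = c(TRUE, FALSE),
                               pre_years = 2L, post_years = 3L,
                               dc_baseline = NULL,
                               chronology_min_frac = 0.5,
                               cv = list(enabled = TRUE,
                                         traits = c("height", "resistance"),
                                         k = 10L, repeats = 10L),
                               correlations = list(
                                 enabled = TRUE,
                                 conventional = c("height", "wood_density"),
                                 method = "GBLUP"
                               ),
                               scenarios = default_scenarios(),
                               proportion = 0.05,
                               blend_weight = 0.01,
                               quiet = FALSE) {
  methods <- match.arg(methods, c("ABLUP", "GBLUP"), several.ok = TRUE)
  sim$seed <- as.integer(seed)
  cfg <- list(
    sim = sim, seed = as.integer(seed), methods = methods,
    post_valid_per_site = rep_len(post_valid_per_site, sim$n_sites),
    pre_years = pre_years, post_years = post_years,
    dc_baseline = dc_baseline,
    chronology_min_frac = chronology_min_frac,
    cv = utils::modifyList(list(enabled = TRUE,
                                traits = c("height", "resistance"),
                                k = 10L, repeats = 10L), cv),
    correlations = utils::modifyList(list(
      enabled = TRUE, conventional = c("height", "wood_density"),
      method = "GBLUP"
    ), correlations),
    scenarios = scenarios, proportion = proportion,
    blend_weight = blend_weight, quiet = quiet
  )
  class(cfg) <- "gs_pipeline_config"
  cfg
}

pipeline_hash <- function(config) {
  keep <- config[setdiff(names(config), "quiet")]
  substr(rlang::hash(keep), 1, 8)
}

#' Run the full drought genomic-selection analysis
#'
#' Executes every stage on a synthetic trial generated from the
#' configuration: trial simulation, Drought Code anomalies, BAI conversion
#' and spline detrending, robust chronologies, Lloret components, A/G
#' matrices, per-site per-trait REML fits (both methods), bivariate
#' correlations, family-stratified cross-validation and selection-index
#' gains. All report tables are written as CSV under
#' `out_dir/run_<confighash>/` together with a provenance manifest; reruns
#' with the same configuration and seed are byte-identical.
#'
#' @param config A [gs_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`trial`,
#'   `climate_monthly`, `chronologies`, `components`, `fits`,
#'   `heritability`, `correlations`, `cv`, `gains`, `paths`).
#' @export
run_pipeline <- function(config = gs_pipeline_config(), out_dir = tempdir()) {
  stopifnot(inherits(config, "gs_pipeline_config"))
  say <- function(...) if (!config$quiet) inform(sprintf(...))
  hash <- pipeline_hash(config)
  run_dir <- file.path(out_dir, paste0("run_", hash))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(run_dir, name)
    readr::write_csv(df, p, na = "")
    paths[[name]] <<- p
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "droughtgs_pipeline_error")
    })
  }

  say("simulating trial (seed %d, hash %s)", config$seed, hash)
  trial <- stage("simulate", simulate_trial(config$sim))
  n_sites <- config$sim$n_sites
  sites <- seq_len(n_sites)
  stage("write_inputs", {
    emit(trial$pedigree, "pedigree.csv")
    emit(trial$phenotypes, "phenotypes.csv")
    p <- file.path(run_dir, "dosages.tsv")
    write_dosages(trial$genotypes, p)
    paths[["dosages.tsv"]] <- p
    for (s in sites) {
      rw <- file.path(run_dir, sprintf("rings_site%d.rwl", s))
      write_rwl(trial$rings[trial$rings$site == s, ], rw)
      paths[[basename(rw)]] <- rw
      emit(trial$climate[[s]], sprintf("climate_site%d.csv", s))
    }
  })

  say("computing Drought Code anomalies")
  climate_monthly <- stage("climate", lapply(sites, function(s) {
    raw <- monthly_dc(trial$climate[[s]])
    base <- config$dc_baseline %||% range(raw$year)
    scaled <- scale_monthly(raw, baseline = base)
    emit(scaled, sprintf("monthly_dc_site%d.csv", s))
    scaled
  }))

  say("building chronologies and drought components")
  dendro <- stage("dendro", lapply(sites, function(s) {
    rings <- trial$rings[trial$rings$site == s, c("id", "year", "width")]
    bai <- width_to_bai(rings)
    idx <- detrend_spline(bai)
    chron <- build_chronology(idx, min_frac = config$chronology_min_frac)
    emit(chron, sprintf("chronology_site%d.csv", s))
    dy <- config$sim$drought_year_per_site[s]
    dip <- 1 - chron$index[chron$year == dy] /
      mean(chron$index[chron$year != dy])
    comp <- batch_components(bai, dy,
                             pre = config$pre_years, post = config$post_years,
                             post_valid = config$post_valid_per_site[s])
    emit(comp, sprintf("components_site%d.csv", s))
    list(bai = bai, chronology = chron, components = comp,
         drought_dip = dip)
  }))

  # phenotypes + drought components, per site
  pheno_site <- lapply(sites, function(s) {
    ph <- trial$phenotypes[trial$phenotypes$site == s, ]
    comp <- dendro[[s]]$components
    dplyr::left_join(
      ph,
      comp[, c("id", "resistance", "recovery", "resilience",
               "relative_resilience")],
      by = "id"
    )
  })
  comp_traits <- c("recovery", "relative_resilience", "resilience",
                   "resistance")
  trait_summary <- dplyr::bind_rows(lapply(sites, function(s) {
    ph <- pheno_site[[s]]
    all_tr <- c(comp_traits, config$sim$trait_names)
    dplyr::bind_rows(lapply(all_tr, function(tr) {
      v <- ph[[tr]]
      v <- v[is.finite(v)]
      if (length(v) == 0L) return(NULL)
      tibble(site = s, trait = tr, n = length(v), mean = mean(v),
             sd = sd(v), cv_pct = 100 * sd(v) / mean(v))
    }))
  }))
  emit(trait_summary, "trait_summary.csv")

  say("building relationship matrices")
  K_list <- stage("relatedness", {
    out <- list()
    if ("ABLUP" %in% config$methods) out$ABLUP <- build_A(trial$pedigree)
    if ("GBLUP" %in% config$methods) {
      out$GBLUP <- blend_K(build_G(trial$genotypes),
                           weight = config$blend_weight)
    }
    out
  })

  say("fitting animal models")
  eval_traits <- lapply(sites, function(s) {
    tr <- c(config$sim$trait_names, comp_traits)
    tr[vapply(tr, function(t) sum(is.finite(pheno_site[[s]][[t]])) >= 30L,
              logical(1))]
  })
  fits <- stage("evaluate", lapply(sites, function(s) {
    site_fits <- list()
    for (method in config$methods) {
      for (tr in eval_traits[[s]]) {
        site_fits[[paste(method, tr, sep = ".")]] <-
          fit_univariate(pheno_site[[s]], K_list[[method]], tr)
      }
    }
    site_fits
  }))
  heritability <- dplyr::bind_rows(lapply(sites, function(s) {
    dplyr::bind_rows(lapply(names(fits[[s]]), function(nm) {
      f <- fits[[s]][[nm]]
      acc <- theoretical_accuracy(
        f, inbreeding = attr(K_list[[sub("\\..*", "", nm)]], "inbreeding")
      )
      dplyr::bind_cols(tibble(site = s, method = sub("\\..*", "", nm)),
                       glance(f)[, c("trait", "h2", "h2_se", "p_additive",
                                     "converged")],
                       tibble(mean_theoretical_accuracy =
                                attr(acc, "mean_accuracy")))
    }))
  }))
  emit(heritability, "heritability.csv")

  rank_corr <- NULL
  if (n_sites >= 2L) {
    fam_means <- lapply(sites[1:2], function(s) {
      ph <- pheno_site[[s]]
      ph <- ph[is.finite(ph$resistance), ]
      dplyr::summarise(dplyr::group_by(ph, .data$family),
                       value = mean(.data$resistance), .groups = "drop")
    })
    rank_corr <- stage("rank_correlation",
                       family_rank_correlation(fam_means[[1]], fam_means[[2]]))
    emit(rank_corr, "family_rank_correlation.csv")
  }

  correlations <- NULL
  if (isTRUE(config$correlations$enabled)) {
    say("estimating bivariate correlations")
    method <- config$correlations$method
    correlations <- stage("correlations", dplyr::bind_rows(
      lapply(sites, function(s) {
        comps <- intersect(comp_traits, eval_traits[[s]])
        dplyr::bind_rows(lapply(comps, function(ct) {
          dplyr::bind_rows(lapply(config$correlations$conventional,
                                  function(cv_tr) {
            fit <- fit_bivariate(pheno_site[[s]], K_list[[method]],
                                 traits = c(ct, cv_tr))
            dplyr::bind_cols(tibble(site = s, method = method), glance(fit))
          }))
        }))
      })
    ))
    emit(correlations, "correlations.csv")
  }

  cv_results <- NULL
  if (isTRUE(config$cv$enabled)) {
    say("running %dx%d cross-validation", config$cv$repeats, config$cv$k)
    cv_results <- stage("validate", dplyr::bind_rows(
      lapply(sites, function(s) {
        dplyr::bind_rows(lapply(
          intersect(config$cv$traits, eval_traits[[s]]), function(tr) {
          # PACC uses the genomic h2 as the best "true" h2 for both methods
          h2_ref <- if ("GBLUP" %in% config$methods) {
            heritability$h2[heritability$site == s &
                              heritability$method == "GBLUP" &
                              heritability$trait == tr]
          } else {
            NULL
          }
          dplyr::bind_rows(lapply(config$methods, function(method) {
            cv <- cross_validate(
              pheno_site[[s]], K_list[[method]], tr,
              k = config$cv$k, repeats = config$cv$repeats,
              seed = substream(config$seed, 500L + s),
              h2_ref = if (length(h2_ref) == 1L) h2_ref else NULL
            )
            dplyr::bind_cols(tibble(site = s, method = method), glance(cv))
          }))
        }))
      })
    ))
    emit(cv_results, "cv_summary.csv")
  }

  say("computing selection gains")
  gains <- stage("select", dplyr::bind_rows(lapply(sites, function(s) {
    means <- setNames(trait_summary$mean[trait_summary$site == s],
                      trait_summary$trait[trait_summary$site == s])
    site_ids <- pheno_site[[s]]$id
    dplyr::bind_rows(lapply(config$methods, function(method) {
      ebv_tbl <- tibble(id = site_ids)
      for (tr in eval_traits[[s]]) {
        f <- fits[[s]][[paste(method, tr, sep = ".")]]
        ebv_tbl[[tr]] <- f$ebv$ebv[match(site_ids, f$ebv$id)]
      }
      usable <- vapply(config$scenarios, function(sc) {
        all(names(sc$weights) %in% names(ebv_tbl))
      }, logical(1))
      g <- compare_scenarios(ebv_tbl, config$scenarios[usable], means,
                             proportion = config$proportion)
      dplyr::bind_cols(tibble(site = s, method = method), g)
    }))
  })))
  emit(gains, "gains.csv")

  manifest <- list(
    config_hash = hash, seed = config$seed,
    package = "droughtgs",
    package_version = as.character(utils::packageVersion("droughtgs")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    files = sort(names(paths))
  )
  manifest_path <- file.path(run_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  paths[["manifest.json"]] <- manifest_path

  say("done: %s", run_dir)
  invisible(list(
    trial = trial, climate_monthly = climate_monthly,
    chronologies = lapply(dendro, `[[`, "chronology"),
    drought_dip = vapply(dendro, `[[`, numeric(1), "drought_dip"),
    components = lapply(dendro, `[[`, "components"),
    phenotypes = pheno_site,
    fits = fits, heritability = heritability,
    rank_correlation = rank_corr,
    correlations = correlations, cv = cv_results, gains = gains,
    trait_summary = trait_summary,
    run_dir = run_dir, paths = paths, config_hash = hash
  ))
}
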