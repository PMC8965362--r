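# Lloret components of drought response computed from BAI series around a
# stated drought year.

#' Lloret components of drought response for one tree
#'
#' Around a drought year d, with a pre-drought window of `pre` years and a
#' post-drought window of `post` years:
#' resistance = BAI(d) / mean BAI(d-pre .. d-1);
#' recovery = mean BAI(d+1 .. d+post) / BAI(d);
#' resilience = mean BAI(d+1 .. d+post) / mean BAI(d-pre .. d-1);
#' relative resilience = resilience - resistance.
#' When the post window is unavailable (truncated series, or `post_valid =
#' FALSE`, e.g. a stand thinning right after the drought), only resistance is
#' returned and the post-drought components are `NA`.
#'
#' @param series Tibble with columns `year`, `bai` for a single tree (a
#'   column `id` is carried through if present).
#' @param drought_year Calendar year of the drought episode.
#' @param pre,post Length (years) of the pre- and post-drought windows.
#' @param post_valid Set `FALSE` to suppress the post-drought components even
#'   when the years are available.
#' @return One-row tibble with columns `id`, `drought_year`, `resistance`,
#'   `recovery`, `resilience`, `relative_resilience`, `post_available`.
#' @export
#' @examples
#' s <- tibble::tibble(year = 2000:2006, bai = c(9, 8, 12, 5, 10, 10, 10))
#' lloret_components(s, drought_year = 2003)
lloret_components <- function(series, drought_year, pre = 2L, post = 3L,
                              post_valid = TRUE) {
  check_columns(series, c("year", "bai"), "BAI series")
  id <- if ("id" %in% names(series)) as.character(series$id[1]) else NA_character_
  pre_years <- (drought_year - pre):(drought_year - 1L)
  post_years <- (drought_year + 1L):(drought_year + post)
  get_bai <- function(years) series$bai[match(years, series$year)]
  pre_bai <- get_bai(pre_years)
  d_bai <- get_bai(drought_year)
  if (anyNA(pre_bai) || is.na(d_bai)) {
    stop_input(sprintf(
      "series%s does not cover the pre-drought window %d-%d",
      if (is.na(id)) "" else paste0(" ", id), min(pre_years), drought_year
    ))
  }
  if (any(pre_bai <= 0) || d_bai < 0) stop_input("BAI must be positive in the window")
  if (d_bai == 0) stop_input("drought-year BAI is zero; resistance undefined")
  post_bai <- get_bai(post_years)
  have_post <- post_valid && !anyNA(post_bai)
  resistance <- d_bai / mean(pre_bai)
  if (have_post) {
    if (any(post_bai <= 0)) stop_input("BAI must be positive in the post window")
    recovery <- mean(post_bai) / d_bai
    resilience <- mean(post_bai) / mean(pre_bai)
    rel_res <- resilience - resistance
  } else {
    recovery <- resilience <- rel_res <- NA_real_
  }
  tibble(
    id = id, drought_year = as.integer(drought_year),
    resistance = resistance, recovery = recovery, resilience = resilience,
    relative_resilience = rel_res, post_available = have_post
  )
}

#' Lloret components for a set of trees
#'
#' Applies [lloret_components()] per tree; per-tree failures (e.g. series not
#' covering the pre-drought window) are collected into a rejects table
#' attached as attribute `"rejects"` rather than aborting the batch.
#'
#' @param rings Tibble with columns `id`, `year`, `bai` for many trees.
#' @inheritParams lloret_components
#' @return Tibble with one row per successfully processed tree; attribute
#'   `"rejects"` holds a tibble (`id`, `reason`) for skipped trees.
#' @export
batch_components <- function(rings, drought_year, pre = 2L, post = 3L,
                             post_valid = TRUE) {
  check_columns(rings, c("id", "year", "bai"), "BAI series")
  pieces <- split(rings, rings$id)
  ok <- list()
  rejects <- list()
  for (id in names(pieces)) {
    res <- tryCatch(
      lloret_components(pieces[[id]], drought_year, pre, post, post_valid),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      rejects[[id]] <- tibble(id = id, reason = conditionMessage(res))
    } else {
      ok[[id]] <- res
    }
  }
  out <- dplyr::bind_rows(ok)
  attr(out, "rejects") <- dplyr::bind_rows(rejects)
  out
}

#' Summarize drought-response components
#'
#' Mean, SD and phenotypic coefficient of variation (CV% = 100 SD/mean) per
#' component, as reported in trial trait summaries.
#'
#' @param components Output of [batch_components()].
#' @return Tibble with columns `trait`, `n`, `mean`, `sd`, `cv_pct`.
#' @export
component_summary <- function(components) {
  comps <- c("resistance", "recovery", "resilience", "relative_resilience")
  long <- tidyr::pivot_longer(components[, c("id", comps)], -"id",
                              names_to = "trait", values_to = "value")
  long <- long[!is.na(long$value), ]
  dplyr::summarise(
    dplyr::group_by(long, .data$trait),
    n = dplyr::n(), mean = mean(.data$value), sd = sd(.data$value),
    cv_pct = 100 * sd(.data$value) / mean(.data$value),
    .groups = "drop"
  )
}
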