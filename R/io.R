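# Plain-text interchange: pedigree/phenotype/climate CSV, dosage TSV,
# minimal VCF, Tucson RWL ring-width files, relationship-matrix formats.

#' @rdname trial_io
#' @param path File path.
#' @param pedigree,phenotypes,climate Tibbles as produced by the simulators.
#' @export
write_pedigree <- function(pedigree, path) {
  readr::write_csv(pedigree, path, na = "")
}

#' @rdname trial_io
#' @export
read_pedigree <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    id = "c", mother = "c", father = "c",
                    .default = readr::col_guess()
                  ))
}

#' Read and write trial tables
#'
#' CSV/TSV readers and writers for the pipeline's tabular interchange
#' formats: pedigree (`id,mother,father,...`), phenotypes, daily climate
#' (`date,tmean,precip`), and SNP dosage matrices (rows = trees, first column
#' `id`, one column per SNP).
#'
#' @param genotypes Integer dosage matrix with individual rownames.
#' @name trial_io
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_csv(phenotypes, path, na = "")
}

#' @rdname trial_io
#' @export
read_phenotypes <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname trial_io
#' @export
write_climate <- function(climate, path) {
  readr::write_csv(climate, path)
}

#' @rdname trial_io
#' @export
read_climate <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(date = readr::col_date()))
}

#' @rdname trial_io
#' @export
write_dosages <- function(genotypes, path) {
  df <- dplyr::bind_cols(tibble(id = rownames(genotypes)),
                         as_tibble(genotypes))
  readr::write_tsv(df, path)
}

#' @rdname trial_io
#' @export
read_dosages <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  storage.mode(m) <- "integer"
  m
}

#' Minimal VCF writer and reader for dosage matrices
#'
#' Diploid unphased genotypes (GT field only) on one placeholder contig;
#' enough to round-trip 0/1/2 dosage matrices with standard tooling.
#'
#' @param genotypes Dosage matrix (individuals x SNPs).
#' @param path File path (uncompressed `.vcf`).
#' @export
write_vcf_minimal <- function(genotypes, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  ), con)
  snps <- colnames(genotypes) %||% sprintf("snp_%04d", seq_len(ncol(genotypes)))
  for (j in seq_len(ncol(genotypes))) {
    gt <- gt_code[as.character(genotypes[, j])]
    gt[is.na(gt)] <- "./."
    writeLines(paste(c("1", j, snps[j], "A", "G", ".", ".", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_vcf_minimal
#' @export
read_vcf_minimal <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-(1:9)]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  snps <- vapply(body, `[[`, character(1), 3L)
  dosage <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
              "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  m <- vapply(body, function(row) {
    unname(dosage[row[-(1:9)]])
  }, integer(length(samples)))
  m <- matrix(m, nrow = length(samples),
              dimnames = list(samples, snps))
  m
}

#' Write ring-width series in Tucson (RWL) format
#'
#' Decadal layout with 0.01 mm precision and the 999 series terminator.
#'
#' @param rings Tibble with columns `id`, `year`, `width` (mm).
#' @param path File path.
#' @export
write_rwl <- function(rings, path) {
  check_columns(rings, c("id", "year", "width"), "ring series")
  con <- file(path, "w")
  on.exit(close(con))
  for (s in split(rings, rings$id)) {
    s <- s[order(s$year), ]
    sid <- formatC(substr(as.character(s$id[1]), 1, 8), width = 8,
                   flag = "-")
    vals <- setNames(as.integer(round(s$width * 100)), s$year)
    yrs <- c(s$year, max(s$year) + 1L) # trailing slot for the terminator
    vals <- c(vals, setNames(999L, max(s$year) + 1L))
    decade_start <- yrs - (yrs %% 10L)
    for (dec in unique(decade_start)) {
      in_dec <- decade_start == dec
      row_years <- yrs[in_dec]
      line <- paste0(sid, formatC(row_years[1], width = 4),
                     paste0(formatC(vals[as.character(row_years)], width = 6),
                            collapse = ""))
      writeLines(line, con)
    }
  }
  invisible(path)
}

#' Read ring-width series from Tucson (RWL) format
#'
#' Auto-detects the 0.01 mm dialect (999 terminator) and the 0.001 mm
#' dialect (-9999 terminator).
#'
#' @param path File path.
#' @return Tibble with columns `id`, `year`, `width` (mm).
#' @export
read_rwl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parse_line <- function(line) {
    sid <- trimws(substr(line, 1, 8))
    rest <- substr(line, 9, nchar(line))
    toks <- strsplit(trimws(rest), "\\s+")[[1]]
    list(id = sid, year = as.integer(toks[1]),
         vals = as.integer(toks[-1]))
  }
  parsed <- lapply(lines, parse_line)
  all_vals <- unlist(lapply(parsed, `[[`, "vals"))
  divisor <- if (any(all_vals == -9999L, na.rm = TRUE)) 1000 else 100
  stop_val <- if (divisor == 1000) -9999L else 999L
  out <- lapply(parsed, function(p) {
    vals <- p$vals
    keep <- vals != stop_val
    if (!any(keep)) return(NULL)
    tibble(id = p$id, year = p$year + seq_along(vals)[keep] - 1L,
           width = vals[keep] / divisor)
  })
  dplyr::bind_rows(out)
}

#' Relationship-matrix interchange
#'
#' Dense CSV (id header) or sparse triplet (`id_i,id_j,value`) formats.
#'
#' @param K Relationship matrix.
#' @param path File path.
#' @param format `"dense"` or `"triplet"`.
#' @export
write_relationship <- function(K, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  if (format == "dense") {
    df <- dplyr::bind_cols(tibble(id = rownames(K)), as_tibble(K))
    readr::write_csv(df, path)
  } else {
    idx <- which(upper.tri(K, diag = TRUE), arr.ind = TRUE)
    df <- tibble(id_i = rownames(K)[idx[, 1]],
                 id_j = colnames(K)[idx[, 2]],
                 value = K[idx])
    df <- df[df$value != 0, ]
    readr::write_csv(df, path)
  }
  invisible(path)
}

#' @rdname write_relationship
#' @export
read_relationship <- function(path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (format == "dense") {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$id
    return(m)
  }
  ids <- sort(unique(c(df$id_i, df$id_j)))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(df$id_i, df$id_j)] <- df$value
  m[cbind(df$id_j, df$id_i)] <- df$value
  m
}
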