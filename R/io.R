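# readers for the plain-text input dialects (TSV/CSV, header required,
# decimal point). readr infers the delimiter-specific reader from the file
# extension; both read_tsv and read_csv are covered.

read_table_auto <- function(path, col_types) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, col_types = col_types, progress = FALSE)
  } else {
    readr::read_tsv(path, col_types = col_types, progress = FALSE)
  }
}

#' Read a dose-response table
#'
#' Expects columns `chemical`, `concentration`, `response` and optionally
#' `replicate`.
#'
#' @param path TSV or CSV file path.
#' @return A tibble.
#' @export
read_dose_response <- function(path) {
  out <- read_table_auto(path, readr::cols(
    chemical = readr::col_character(),
    concentration = readr::col_double(),
    response = readr::col_double(),
    .default = readr::col_guess()
  ))
  check_columns(out, c("chemical", "concentration", "response"), path)
  out
}

#' Read a mixture response table
#'
#' Expects columns `c1`, `c2`, `response`; axis data are rows with one
#' concentration equal to 0.
#'
#' @param path TSV or CSV file path.
#' @return A tibble.
#' @export
read_mixture_points <- function(path) {
  out <- read_table_auto(path, readr::cols(
    c1 = readr::col_double(), c2 = readr::col_double(),
    response = readr::col_double(), .default = readr::col_guess()
  ))
  check_columns(out, c("c1", "c2", "response"), path)
  out
}

#' Read a depuration time-course table
#'
#' Expects columns `chemical`, `time`, `concentration` (time in days).
#'
#' @param path TSV or CSV file path.
#' @return A tibble.
#' @export
read_elimination_series <- function(path) {
  out <- read_table_auto(path, readr::cols(
    chemical = readr::col_character(), time = readr::col_double(),
    concentration = readr::col_double(), .default = readr::col_guess()
  ))
  check_columns(out, c("chemical", "time", "concentration"), path)
  out
}

#' Read a long-format biomarker panel
#'
#' Expects columns `biomarker`, `group` (`control`/`exposed`), `value`.
#'
#' @param path TSV or CSV file path.
#' @return A tibble.
#' @export
read_biomarker_panel <- function(path) {
  out <- read_table_auto(path, readr::cols(
    biomarker = readr::col_character(), group = readr::col_character(),
    value = readr::col_double(), .default = readr::col_guess()
  ))
  check_columns(out, c("biomarker", "group", "value"), path)
  out
}

#' Read a differential-expression table
#'
#' Expects columns `gene_id`, `M`, `B` (and optionally `condition`); the
#' literal `N.A.` is recognised as missing.
#'
#' @param path TSV or CSV file path.
#' @return A tibble.
#' @export
read_deg_table <- function(path) {
  out <- read_table_auto(path, readr::cols(
    gene_id = readr::col_character(),
    M = readr::col_double(), B = readr::col_double(),
    .default = readr::col_guess()
  ))
  check_columns(out, c("gene_id", "M", "B"), path)
  out
}

#' Read a two-column annotation export
#'
#' Blast2GO-style export: `seq_id<TAB>GO:ID`, no header.
#'
#' @param path TSV file path.
#' @return Tibble with columns `seq_id`, `term`.
#' @export
read_annotation <- function(path) {
  out <- readr::read_tsv(path, col_names = c("seq_id", "term"),
                         col_types = "cc", progress = FALSE)
  bad <- !grepl("^GO:\\d{7}$", out$term)
  if (any(bad)) {
    stop_mixtox(sprintf("%d malformed GO id(s), e.g. '%s'.", sum(bad),
                        out$term[bad][1]), "mixtoxsys_validation_error")
  }
  out
}

#' The bundled microarray/qPCR comparison table
#'
#' Twelve genes assayed by both microarray (log2 ratio M and log-odds B)
#' and TaqMan qPCR (signed relative expression with a significance flag)
#' under nickel, chlorpyrifos and mixture exposure of mussel digestive
#' gland; one gene lacks array data under every condition. Used by the
#' worked examples and the concordance acceptance checks.
#'
#' @return Tibble with columns `condition`, `gene_id`, `description`,
#'   `qpcr_value`, `qpcr_significant`, `M`, `B`.
#' @export
qpcr_array_comparison <- function() {
  path <- system.file("extdata", "qpcr_array_comparison.tsv",
                      package = "mixtoxsys", mustWork = TRUE)
  out <- read_table_auto(path, readr::cols(
    condition = readr::col_character(),
    gene_id = readr::col_character(),
    description = readr::col_character(),
    qpcr_value = readr::col_double(),
    qpcr_significant = readr::col_logical(),
    M = readr::col_double(), B = readr::col_double()
  ))
  out
}
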