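# Preferred term (PT) -> system organ class (SOC) mapping. MedDRA itself is
# licensed and not redistributed; the dictionary is pluggable and a small toy
# dictionary covering common haematology/oncology terms ships with the package.

#' Normalize an adverse-event preferred term
#'
#' Trims, collapses internal whitespace and upper-cases, so verbatim reaction
#' text and dictionary keys compare exactly.
#'
#' @param x Character vector of terms.
#' @return Normalized character vector.
#' @export
#' @examples
#' normalize_term("  Febrile  Neutropenia ")
normalize_term <- function(x) {
  out <- toupper(stringr::str_squish(x))
  if (any(is.na(out) | out == "")) {
    abort("term is empty after normalization")
  }
  out
}

#' Read a PT-to-SOC term dictionary
#'
#' Expects a comma- or tab-separated file with a header row and four columns:
#' PT name, PT code, SOC name, SOC code. PT names are normalized on read and
#' must each map to a single SOC (the primary-SOC convention); duplicate rows
#' that agree are collapsed, conflicting duplicates are an error.
#'
#' @param file Path to the dictionary file.
#' @param version Optional version label stored on the result.
#' @return A `pv_dictionary`: a tibble with columns `pt`, `pt_code`, `soc`,
#'   `soc_code` and a `version` attribute.
#' @export
read_term_dictionary <- function(file, version = NULL) {
  first <- readLines(file, n = 1L, warn = FALSE)
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(file, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (ncol(raw) < 4) abort("dictionary must have 4 columns: pt, pt_code, soc, soc_code")
  names(raw)[1:4] <- c("pt", "pt_code", "soc", "soc_code")
  term_dictionary(raw$pt, raw$pt_code, raw$soc, raw$soc_code, version = version)
}

#' Build a term dictionary from vectors
#'
#' @param pt,pt_code,soc,soc_code Parallel character vectors.
#' @param version Optional version label.
#' @return A `pv_dictionary` tibble.
#' @export
term_dictionary <- function(pt, pt_code, soc, soc_code, version = NULL) {
  d <- tibble(pt = normalize_term(pt),
              pt_code = as.character(pt_code),
              soc = as.character(soc),
              soc_code = as.character(soc_code)) %>%
    distinct()
  dup <- d %>% count(.data$pt) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("preferred term maps to multiple SOCs: ",
                 paste(dup$pt, collapse = ", ")))
  }
  structure(d, class = c("pv_dictionary", class(d)),
            version = version %||% "unversioned")
}

#' Look up the system organ class of preferred terms
#'
#' Unknown terms get the sentinel SOC `"UNMAPPED"` (they still count toward
#' event totals downstream); the number of unmapped terms is reported.
#'
#' @param dict A `pv_dictionary`.
#' @param pt Character vector of normalized preferred terms.
#' @param quiet Suppress the unmapped-count message.
#' @return A tibble with columns `pt`, `soc`, `soc_code`.
#' @export
soc_of <- function(dict, pt, quiet = FALSE) {
  stopifnot(inherits(dict, "pv_dictionary"))
  out <- tibble(pt = pt) %>%
    left_join(as_tibble(dict)[, c("pt", "soc", "soc_code")], by = "pt") %>%
    mutate(soc = if_else(is.na(.data$soc), "UNMAPPED", .data$soc),
           soc_code = if_else(is.na(.data$soc_code), "UNMAPPED", .data$soc_code))
  n_un <- sum(out$soc == "UNMAPPED")
  if (n_un > 0 && !quiet) {
    inform(sprintf("%d term(s) not in dictionary (SOC = UNMAPPED)", n_un))
  }
  out
}

#' Toy PT-to-SOC dictionary shipped with the package
#'
#' Roughly fifty haematology/oncology-flavoured preferred terms with
#' plausible SOC assignments, for examples and tests. It is synthetic in the
#' sense that codes are illustrative; it is not MedDRA.
#'
#' @return A `pv_dictionary`.
#' @export
toy_dictionary <- function() {
  read_term_dictionary(
    system.file("extdata", "toy_meddra.csv", package = "pvsignal"),
    version = "toy-0.1"
  )
}
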