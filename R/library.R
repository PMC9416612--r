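#' Multiplet patterns understood by the renderer
#' @keywords internal
MULTIPLET_PATTERNS <- c("s", "d", "t", "q", "dd", "m")

#' Construct a metabolite multiplet library
#'
#' A library is a table of renderable multiplets — one row per resonance
#' group with its chemical shift, splitting pattern, scalar couplings and
#' proton count — plus the spectrometer frequency used to convert couplings
#' from Hz to ppm. It drives both the cohort simulator and the annotation
#' of selected spectral regions.
#'
#' @param entries data frame with columns `metabolite`, `group`,
#'   `shift_ppm`, `pattern` (one of `r paste(MULTIPLET_PATTERNS, collapse = ", ")`),
#'   `couplings_hz` (list column or semicolon-separated text), `protons`.
#' @param frequency spectrometer frequency in MHz.
#' @return an object of class `metabolite_library`.
#' @export
metabolite_library <- function(entries, frequency = 500.26) {
  if (frequency <= 0) stop("spectrometer frequency must be positive")
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("metabolite", "group", "shift_ppm", "pattern", "couplings_hz",
            "protons")
  if (!all(need %in% names(entries)))
    stop("library entries need columns: ", paste(need, collapse = ", "))
  if (!is.list(entries$couplings_hz))
    entries$couplings_hz <- lapply(as.character(entries$couplings_hz),
                                   parse_couplings)
  bad <- !entries$pattern %in% MULTIPLET_PATTERNS
  if (any(bad))
    stop("unknown multiplet pattern(s): ",
         paste(unique(entries$pattern[bad]), collapse = ", "))
  if (any(entries$shift_ppm < -1 | entries$shift_ppm > 12))
    stop("chemical shifts must lie within [-1, 12] ppm")
  if (any(entries$protons < 1)) stop("proton counts must be >= 1")
  nj <- lengths(entries$couplings_hz)
  needs_j <- !entries$pattern %in% c("s", "m")
  if (any(needs_j & nj == 0L))
    stop("patterns other than s and m require at least one coupling")
  if (any(!needs_j & nj > 0L))
    stop("s and m patterns must not carry couplings")
  structure(list(entries = entries, frequency = frequency),
            class = "metabolite_library")
}

parse_couplings <- function(txt) {
  if (is.na(txt) || !nzchar(trimws(txt))) return(numeric(0))
  as.numeric(strsplit(trimws(txt), ";")[[1L]])
}

#' @export
print.metabolite_library <- function(x, ...) {
  cat("<metabolite_library> ", length(unique(x$entries$metabolite)),
      " metabolites, ", nrow(x$entries), " multiplets, ",
      x$frequency, " MHz\n", sep = "")
  invisible(x)
}

#' Metabolite names in a library
#' @param library a [metabolite_library()].
#' @return character vector, in first-appearance order.
#' @export
library_metabolites <- function(library) unique(library$entries$metabolite)

#' Read a multiplet library from a delimited file
#'
#' One row per multiplet: metabolite, group, shift (ppm), pattern,
#' semicolon-separated couplings (Hz), proton count, optional note.
#'
#' @param path file path.
#' @param frequency spectrometer frequency in MHz.
#' @return a [metabolite_library()].
#' @export
read_library <- function(path, frequency = 500.26) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE)
  metabolite_library(tab, frequency = frequency)
}

#' The default serum metabolite library
#'
#' Twenty-six serum metabolites with their resonance groups, chemical
#' shifts, multiplet patterns and couplings, shipped as a delimited text
#' file under `extdata` so users can extend it. Spectrometer frequency is
#' 500.26 MHz.
#'
#' @return a [metabolite_library()] with 26 metabolites.
#' @examples
#' lib <- load_default_library()
#' library_metabolites(lib)
#' @export
load_default_library <- function() {
  path <- system.file("extdata", "metabolite_library.tsv",
                      package = "serumNMR", mustWork = TRUE)
  read_library(path, frequency = 500.26)
}
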