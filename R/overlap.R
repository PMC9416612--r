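#' Load a cross-cohort metabolite presence table
#'
#' Reads a delimited table with a metabolite column followed by one
#' presence column per cohort (`+` present, `-`/`−` absent) and optional
#' `refs` / `comment` columns. Row order is preserved.
#'
#' @param path file path; defaults to the shipped table of serum
#'   schizophrenia biomarkers reported for Serbian, Brazilian and Chinese
#'   cohorts.
#' @return a `presence_matrix`: metabolite names, cohort names, a logical
#'   matrix and per-row reference tags.
#' @export
load_presence_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "presence_table.tsv",
                        package = "serumNMR", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                           na.strings = NULL)
  if (nrow(tab) == 0L) stop("empty presence table")
  cohorts <- setdiff(names(tab), c("metabolite", "refs", "comment"))
  if (length(cohorts) == 0L) stop("no cohort columns found")
  if (anyDuplicated(tab$metabolite))
    stop("duplicate metabolite: ",
         tab$metabolite[duplicated(tab$metabolite)][1L])
  m <- matrix(NA, nrow = nrow(tab), ncol = length(cohorts),
              dimnames = list(tab$metabolite, cohorts))
  for (j in cohorts) {
    v <- trimws(as.character(tab[[j]]))
    ok <- v %in% c("+", "-", "−")
    if (!all(ok))
      stop("unknown presence symbol '", v[!ok][1L], "' in cohort ", j)
    m[, j] <- v == "+"
  }
  structure(list(metabolites = tab$metabolite, cohorts = cohorts,
                 presence = m,
                 refs = if ("refs" %in% names(tab)) tab$refs else NULL,
                 comment = if ("comment" %in% names(tab)) tab$comment
                           else NULL),
            class = "presence_matrix")
}

#' Count metabolites present in every named cohort
#'
#' @param pm a `presence_matrix`.
#' @param cohorts non-empty subset of `pm$cohorts`.
#' @return integer count of rows marked present in all named cohorts.
#' @examples
#' \dontrun{
#' pm <- load_presence_table()
#' overlap_counts(pm, c("Serbian", "Brazilian", "Chinese"))
#' }
#' @export
overlap_counts <- function(pm, cohorts) {
  if (length(cohorts) == 0L) stop("cohort subset must be non-empty")
  unknown <- setdiff(cohorts, pm$cohorts)
  if (length(unknown))
    stop("unknown cohort(s): ", paste(unknown, collapse = ", "))
  sum(rowSums(pm$presence[, cohorts, drop = FALSE]) == length(cohorts))
}

#' Metabolites present in all cohorts
#'
#' @param pm a `presence_matrix`.
#' @return character vector of consensus metabolites, in original row
#'   order.
#' @export
consensus_set <- function(pm) {
  pm$metabolites[rowSums(pm$presence) == length(pm$cohorts)]
}
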