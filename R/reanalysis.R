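#' Re-analyze published per-cell value tables
#'
#' Published figure source data for escape angles (and similar per-cell
#' quantities) ship as spreadsheets with one column per cell group and one
#' value per cell, with unequal column lengths. Export such a sheet to
#' CSV/TSV and this function recomputes per-group summaries: n, median,
#' mean, SD. Escape-angle columns can additionally be tested against the
#' 3D isotropic null with [sphere_uniformity_test()].
#'
#' @param path delimited text file; first row = group names, one numeric
#'   value per cell below, blank cells allowed.
#' @param sep field separator (`","` default; use `"\t"` for TSV).
#' @return data.frame with one row per group: `group`, `n`, `median`,
#'   `mean`, `sd`.
#' @export
reanalyze_value_table <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, fill = TRUE)
  if (!ncol(raw)) stopf("no columns in '%s'", path)
  out <- lapply(names(raw), function(nm) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    data.frame(group = nm, n = length(v), median = stats::median(v),
               mean = mean(v), sd = stats::sd(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) stopf("no numeric values in '%s'", path)
  out
}
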