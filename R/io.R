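#' Read a sample-by-taxon count table from TSV
#'
#' Expects a header row whose first column is `sample_id`, remaining columns
#' taxon (or family) labels, and nonnegative numeric values.  Duplicate
#' labels, non-numeric cells and negative values are rejected with the
#' offending row/column named.
#'
#' @param path path to a tab-separated file.
#' @return a [count_table] with `unit = "reads"`.
#' @export
read_count_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", sep = "\t")
  if (!ncol(raw) || names(raw)[1L] != "sample_id")
    stop2("first column of ", path, " must be 'sample_id'")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop2("duplicate sample_id: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  taxa <- names(raw)[-1L]
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L,
                                      dimnames = list(NULL, taxa))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop2("non-numeric value at sample '", ids[bad[1L]], "', taxon '",
          taxa[bad[2L]], "'")
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1L, ]
    stop2("negative value at sample '", ids[bad[1L]], "', taxon '",
          taxa[bad[2L]], "'")
  }
  rownames(vals) <- ids
  count_table(vals, "reads")
}

#' Read per-sample metadata from TSV
#'
#' Requires columns `sample_id, immigration_level, instar, plant_id,
#' lineage_id, copy_number`; extra columns pass through.
#'
#' @param path path to a tab-separated file.
#' @return a data.frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "immigration_level", "instar", "plant_id",
            "lineage_id", "copy_number")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop2("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop2("duplicate sample_id in metadata: ",
          paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  if (any(md$copy_number < 0, na.rm = TRUE) ||
      any(md$immigration_level < 0, na.rm = TRUE))
    stop2("copy_number and immigration_level must be nonnegative")
  md
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]; useful for exporting simulated studies.
#'
#' @param x a [count_table].
#' @param path output path.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Percent change between two percentages
#'
#' `100 * (b - a) / a`, the relative change from a baseline mean `a` to a
#' later mean `b` (both on the percent scale); reports, for example, how much
#' a taxon's mean relative abundance grew between developmental stages.
#'
#' @param a baseline value (must be > 0).
#' @param b later value.
#' @return the percent change (not rounded; round at report time).
#' @examples
#' relative_change(48.6, 81.6)  # ~68: the dominant family's increase
#' @export
relative_change <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b)) stop2("'a' and 'b' must be numeric")
  if (any(a <= 0)) stop2("baseline 'a' must be positive")
  100 * (b - a) / a
}
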