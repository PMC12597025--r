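#' Construct a validated sample-by-taxon count table
#'
#' The basic data container of the package: a numeric matrix with samples as
#' rows and taxa (or families) as columns, tagged with the unit of its values.
#' `unit` tracks where a table sits in the analysis chain: raw sequence
#' `"reads"`, per-sample `"relative"` abundances (rows sum to 1), or
#' `"copy_scaled"` abundances (relative abundances multiplied by the qPCR 16S
#' copy number, i.e. absolute-abundance estimates).
#'
#' @param x numeric matrix or data.frame; rows = samples, columns = taxa.
#'   Row and column names are required and must be unique.
#' @param unit one of `"reads"`, `"relative"`, `"copy_scaled"`.
#' @return a numeric matrix of class `"count_table"` with a `unit` attribute.
#' @examples
#' m <- matrix(c(2, 3, 5, 1, 0, 4), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("A", "B", "C")))
#' ct <- count_table(m)
#' relativize(ct)
#' @export
count_table <- function(x, unit = c("reads", "relative", "copy_scaled")) {
  unit <- match.arg(unit)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop2("'x' must be a numeric matrix or data.frame")
  if ((nrow(x) > 0L && is.null(rownames(x))) ||
      (ncol(x) > 0L && is.null(colnames(x))))
    stop2("count table needs sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(x)))
    stop2("duplicate sample ids: ",
          paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop2("duplicate taxon ids: ",
          paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (anyNA(x)) stop2("count table contains missing values")
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1L, ]
    stop2("negative abundance at sample '", rownames(x)[bad[1L]],
          "', taxon '", colnames(x)[bad[2L]], "'")
  }
  if (unit == "relative") {
    rs <- rowSums(x)
    if (any(abs(rs - 1) > 1e-9))
      stop2("unit = 'relative' but row sums deviate from 1 (max |sum - 1| = ",
            format(max(abs(rs - 1))), ")")
  }
  structure(x, unit = unit, class = c("count_table", class(x)))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa (unit: %s)\n",
              nrow(x), ncol(x), table_unit(x)))
  y <- x
  attr(y, "unit") <- NULL
  attr(y, "excluded") <- NULL
  class(y) <- NULL
  print(utils::head(y, 10L), ...)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more samples)\n", sep = "")
  invisible(x)
}

#' @rdname count_table
#' @export
table_unit <- function(x) attr(x, "unit") %||% "reads"

`%||%` <- function(a, b) if (is.null(a)) b else a

# rebuild class/attrs after matrix surgery
as_count_table <- function(x, unit, excluded = NULL) {
  ct <- count_table(x, unit)
  if (!is.null(excluded)) attr(ct, "excluded") <- excluded
  ct
}

#' Aggregate taxa into higher-level groups (e.g. families)
#'
#' Sums counts of member taxa within each group, sample by sample; per-sample
#' totals are conserved exactly.  Taxa missing from `mapping` are pooled into
#' an `"unassigned"` group by default, or rejected with `policy = "strict"`.
#'
#' @param x a [count_table].
#' @param mapping named character vector: `names(mapping)` are taxon ids in
#'   `x`, values are group labels.
#' @param policy `"bucket"` (default; unmapped taxa go to `"unassigned"`) or
#'   `"strict"` (unmapped taxa are an error).
#' @return a [count_table] whose columns are the group labels.
#' @export
aggregate_taxa <- function(x, mapping, policy = c("bucket", "strict")) {
  policy <- match.arg(policy)
  x <- count_table(x, table_unit(x))
  taxa <- colnames(x)
  grp <- unname(mapping[taxa])
  unmapped <- taxa[is.na(grp)]
  if (length(unmapped)) {
    if (policy == "strict")
      stop2("unmapped taxa under strict policy: ",
            paste(unmapped, collapse = ", "))
    grp[is.na(grp)] <- "unassigned"
  }
  grp <- factor(grp, levels = unique(grp))
  out <- sapply(levels(grp), function(g)
    rowSums(x[, grp == g, drop = FALSE]))
  if (nrow(x) == 1L)
    out <- matrix(out, nrow = 1L, dimnames = list(rownames(x), levels(grp)))
  as_count_table(out, table_unit(x))
}

#' Subset a count table to the focal taxa
#'
#' Restricts the analysis universe to a stated set of focal taxa (in the
#' motivating design, the five inoculated bacterial families).  Samples left
#' with zero focal reads carry no compositional information and are excluded;
#' their ids are recorded in the `"excluded"` attribute and reported with a
#' warning so the exclusion is auditable.
#'
#' @param x a [count_table].
#' @param focal character vector of taxon ids; must all be present in `x`.
#' @return a [count_table] with only the focal columns; excluded sample ids
#'   (possibly none) in `attr(, "excluded")`.
#' @export
subset_focal <- function(x, focal) {
  x <- count_table(x, table_unit(x))
  if (!length(focal)) stop2("'focal' must be non-empty")
  missing_taxa <- setdiff(focal, colnames(x))
  if (length(missing_taxa))
    stop2("focal taxa absent from table: ", paste(missing_taxa, collapse = ", "))
  out <- x[, focal, drop = FALSE]
  zero <- rowSums(out) == 0
  excluded <- rownames(out)[zero]
  if (length(excluded))
    warn2(length(excluded), " sample(s) with zero focal reads excluded: ",
          paste(excluded, collapse = ", "))
  as_count_table(out[!zero, , drop = FALSE], table_unit(x),
                 excluded = excluded)
}

#' Convert a count table to per-sample relative abundances
#'
#' Divides each row by its total so rows sum to 1.  All-zero rows are an
#' error: exclude them first with [subset_focal()], whose exclusion log keeps
#' the removal auditable.
#'
#' @param x a [count_table] with positive row sums.
#' @return a [count_table] with `unit = "relative"`.
#' @export
relativize <- function(x) {
  x <- count_table(x, table_unit(x))
  rs <- rowSums(x)
  if (any(rs == 0))
    stop2("all-zero row(s): ", paste(rownames(x)[rs == 0], collapse = ", "),
          "; exclude them first with subset_focal()")
  as_count_table(sweep(unclass(x), 1L, rs, "/"), "relative",
                 excluded = attr(x, "excluded"))
}

#' Scale relative abundances by per-sample total abundance
#'
#' Multiplies each sample's relative-abundance row by its total bacterial
#' abundance (16S rRNA copy number from qPCR), yielding absolute-abundance
#' estimates; the per-sample total then equals the copy number.
#'
#' @param x a [count_table] with `unit = "relative"`.
#' @param copy_number named numeric vector of per-sample copy numbers, or a
#'   metadata data.frame with columns `sample_id` and `copy_number`.
#' @return a [count_table] with `unit = "copy_scaled"`.
#' @export
copy_scale <- function(x, copy_number) {
  x <- count_table(x, table_unit(x))
  if (table_unit(x) != "relative")
    stop2("copy_scale() expects a relative-abundance table; call relativize() first")
  if (is.data.frame(copy_number)) {
    cn <- copy_number$copy_number
    names(cn) <- copy_number$sample_id
    copy_number <- cn
  }
  miss <- setdiff(rownames(x), names(copy_number))
  if (length(miss))
    stop2("missing copy_number for sample(s): ", paste(miss, collapse = ", "))
  cn <- copy_number[rownames(x)]
  if (anyNA(cn) || any(cn < 0))
    stop2("copy_number must be nonnegative and non-missing for every sample")
  if (any(cn == 0))
    warn2("copy_number is 0 for sample(s): ",
          paste(rownames(x)[cn == 0], collapse = ", "),
          " (rows become all-zero)")
  as_count_table(sweep(unclass(x), 1L, cn, "*"), "copy_scaled",
                 excluded = attr(x, "excluded"))
}

#' Round a scaled abundance table to integer counts
#'
#' The null model operates on whole individuals.  Values are rounded to the
#' nearest integer, but any taxon with positive real abundance keeps at least
#' one individual so that observed richness (presence/absence) survives the
#' rounding and the null model's richness constraint is well defined.
#'
#' @param x a [count_table] (typically `unit = "copy_scaled"`) or a numeric
#'   vector.
#' @return integer counts in the same shape as the input.
#' @export
integerize <- function(x) {
  f <- function(v) {
    out <- round(v)
    out[v > 0 & out < 1] <- 1
    out
  }
  if (is.matrix(x)) {
    out <- f(unclass(x))
    storage.mode(out) <- "double"
    as_count_table(out, "reads", excluded = attr(x, "excluded"))
  } else f(x)
}
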