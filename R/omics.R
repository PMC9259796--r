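#' Omics layer container
#'
#' A single omics layer: a samples x features numeric matrix plus an
#' omics-kind tag. Row names are sample ids, column names feature ids; both
#' must be unique. This is the unit of data every preprocessing and
#' signature operation consumes.
#'
#' @param values numeric matrix (samples x features) with unique row and
#'   column names.
#' @param kind one of `"mRNA"`, `"miRNA"`, `"lncRNA"`, `"methylation"`,
#'   `"cnv"`.
#' @return An object of class `omics_matrix`: a list with elements `values`
#'   and `kind`.
#' @export
omics_matrix <- function(values, kind) {
  kind <- match.arg(kind, omics_kinds())
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("`values` must carry sample ids (rownames) and feature ids (colnames)")
  if (anyDuplicated(rownames(values))) stopf("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stopf("duplicate feature ids")
  structure(list(values = values, kind = kind), class = "omics_matrix")
}

omics_kinds <- function() c("mRNA", "miRNA", "lncRNA", "methylation", "cnv")

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> kind=%s: %d samples x %d features\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

sample_ids <- function(x) {
  if (inherits(x, "omics_matrix")) rownames(x$values)
  else if (is.data.frame(x)) x$sample_id
  else rownames(x)
}

#' Clinical follow-up table
#'
#' Validates a per-sample table of follow-up time and binary relapse event
#' indicator (1 = relapse observed, 0 = censored).
#'
#' @param sample_id character vector of unique sample ids.
#' @param time strictly positive follow-up times (units are opaque but must
#'   be consistent within a run).
#' @param event 0/1 event indicators.
#' @return A `data.frame` with class `clinical_table` prepended.
#' @export
clinical_table <- function(sample_id, time, event) {
  if (anyDuplicated(sample_id)) stopf("duplicate sample ids in clinical table")
  if (any(!is.finite(time)) || any(time <= 0))
    stopf("follow-up times must be strictly positive")
  if (!all(event %in% c(0, 1))) stopf("event indicators must be 0 or 1")
  structure(data.frame(sample_id = as.character(sample_id),
                       time = as.numeric(time),
                       event = as.integer(event),
                       stringsAsFactors = FALSE),
            class = c("clinical_table", "data.frame"))
}

# Align a clinical table to a given ordered id vector; error on missing ids.
align_clinical <- function(clinical, ids) {
  idx <- match(ids, clinical$sample_id)
  if (anyNA(idx)) stopf("clinical table is missing %d sample ids", sum(is.na(idx)))
  clinical[idx, , drop = FALSE]
}
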