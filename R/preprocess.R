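# Cleaning, scaling and stacking of per-omics matrices into the single
# [0,1]-valued input matrix the autoencoder consumes. The logloss objective
# is only defined on [0,1], hence per-feature min-max scaling (not
# z-scoring).

#' Median-impute missing values per feature
#'
#' @param m an [omics_matrix()].
#' @return The matrix with each `NA` replaced by its column median; columns
#'   that are entirely missing raise an error.
#' @export
impute_median <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  v <- m$values
  if (!anyNA(v)) return(m)
  for (j in which(colSums(is.na(v)) > 0)) {
    med <- median(v[, j], na.rm = TRUE)
    if (is.na(med)) stopf("feature '%s' is entirely missing", colnames(v)[j])
    v[is.na(v[, j]), j] <- med
  }
  omics_matrix(v, m$kind)
}

#' Drop near-constant features
#'
#' Removes columns whose variance is `<= min_variance`, preserving the order
#' of the survivors.
#'
#' @param m an [omics_matrix()].
#' @param min_variance non-negative variance threshold (default 0: drop only
#'   exactly constant columns).
#' @return The filtered [omics_matrix()].
#' @export
drop_degenerate_features <- function(m, min_variance = 0) {
  stopifnot(inherits(m, "omics_matrix"), min_variance >= 0)
  v <- m$values
  keep <- apply(v, 2, var) > min_variance
  if (!any(keep)) stopf("all features are degenerate at min_variance=%g",
                        min_variance)
  omics_matrix(v[, keep, drop = FALSE], m$kind)
}

#' Min-max scale each feature to [0, 1]
#'
#' Affinely maps every column so its minimum is 0 and maximum 1. Constant
#' columns are an error; run [drop_degenerate_features()] first.
#'
#' @param m an [omics_matrix()].
#' @return The scaled [omics_matrix()].
#' @export
minmax_scale <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  v <- m$values
  lo <- apply(v, 2, min)
  hi <- apply(v, 2, max)
  if (any(hi - lo == 0))
    stopf("constant column(s) present; drop degenerate features before scaling")
  v <- sweep(sweep(v, 2, lo, "-"), 2, hi - lo, "/")
  omics_matrix(v, m$kind)
}

#' Align samples and stack omics blocks column-wise
#'
#' Restricts all blocks to the intersection of their sample ids (ordered as
#' in the first block; dropped ids are reported with a warning), then
#' concatenates the blocks' columns, recording for every stacked column its
#' omics kind and original feature id.
#'
#' @param blocks non-empty list of [omics_matrix()] objects with pairwise
#'   disjoint (kind, feature id) pairs.
#' @return An `omics_stack`: list with `values` (samples x total features
#'   matrix) and `provenance` (data.frame `column`, `kind`, `feature_id`).
#' @export
align_and_stack <- function(blocks) {
  if (length(blocks) < 1) stopf("need at least one omics block")
  stopifnot(all(vapply(blocks, inherits, TRUE, "omics_matrix")))
  keys <- unlist(lapply(blocks, function(b)
    paste(b$kind, colnames(b$values), sep = "\r")))
  if (anyDuplicated(keys)) stopf("duplicate (kind, feature id) pairs across blocks")
  common <- Reduce(intersect, lapply(blocks, function(b) rownames(b$values)))
  if (length(common) == 0) stopf("no common sample ids across blocks")
  common <- rownames(blocks[[1]]$values)[rownames(blocks[[1]]$values) %in% common]
  n_drop <- sum(vapply(blocks, function(b)
    sum(!rownames(b$values) %in% common), integer(1)))
  if (n_drop > 0)
    warnf("dropping %d sample rows absent from the id intersection", n_drop)
  mats <- lapply(blocks, function(b) b$values[common, , drop = FALSE])
  values <- do.call(cbind, mats)
  provenance <- data.frame(
    column = seq_len(ncol(values)),
    kind = rep(vapply(blocks, `[[`, "", "kind"),
               vapply(blocks, function(b) ncol(b$values), integer(1))),
    feature_id = unlist(lapply(blocks, function(b) colnames(b$values)),
                        use.names = FALSE),
    stringsAsFactors = FALSE, row.names = NULL)
  colnames(values) <- paste(provenance$kind, provenance$feature_id, sep = ":")
  structure(list(values = values, provenance = provenance),
            class = "omics_stack")
}

#' @export
print.omics_stack <- function(x, ...) {
  cat(sprintf("<omics_stack> %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$provenance$kind), collapse = ", ")))
  invisible(x)
}

#' Preprocess raw omics blocks into an autoencoder-ready stack
#'
#' Convenience wrapper: per block, median-impute, drop degenerate features,
#' min-max scale; then align and stack.
#'
#' @param blocks list of [omics_matrix()] objects.
#' @param min_variance variance threshold for [drop_degenerate_features()].
#' @param max_features_per_block optional cap per block: keep the
#'   `max_features_per_block` highest-variance features (default `Inf`, no
#'   limit).
#' @return An `omics_stack` with all values in `[0, 1]`.
#' @export
preprocess_blocks <- function(blocks, min_variance = 0,
                              max_features_per_block = Inf) {
  prepped <- lapply(blocks, function(b) {
    b <- drop_degenerate_features(impute_median(b), min_variance)
    if (is.finite(max_features_per_block) &&
        ncol(b$values) > max_features_per_block) {
      vs <- apply(b$values, 2, var)
      keep <- sort(order(vs, decreasing = TRUE)[seq_len(max_features_per_block)])
      b <- omics_matrix(b$values[, keep, drop = FALSE], b$kind)
    }
    minmax_scale(b)
  })
  align_and_stack(prepped)
}
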