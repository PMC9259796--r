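# The central loop: screen deep features for relapse association with
# univariate Cox-PH Wald tests, split patients into two subgroups by
# k-means, orient the labels so S2 is the higher-risk group, score each
# candidate model by 10-fold cross-validated concordance, and pick the final
# model by Kaplan-Meier log-rank separation among the top concordance pair.

#' Screen deep features for relapse association
#'
#' Fits a univariate Cox-PH model per deep feature and keeps those with Wald
#' p < `alpha` (raw, unadjusted — the screening is deliberately liberal).
#' Constant features are skipped with a message.
#'
#' @param F deep-feature matrix (samples x features) from [encode()].
#' @param clinical a [clinical_table()] aligned with `F` rows.
#' @param alpha significance level (default 0.05).
#' @param model_id label used in error messages.
#' @return The column-subset of `F` with attribute `"cox_results"` (a
#'   data.frame of per-feature beta, se, z, p over all tested features).
#' @export
select_relapse_features <- function(F, clinical, alpha = 0.05,
                                    model_id = "model") {
  clinical <- align_clinical(clinical, rownames(F))
  res <- vector("list", ncol(F))
  for (j in seq_len(ncol(F))) {
    fid <- colnames(F)[j]
    if (sd(F[, j]) == 0) {
      message(sprintf("skipping constant deep feature %s", fid))
      next
    }
    r <- fit_univariate_cox(F[, j], clinical, feature_id = fid)
    res[[j]] <- data.frame(feature_id = fid, beta = r$beta, se = r$se,
                           wald_z = r$wald_z, p = r$p,
                           stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, res)
  keep <- tab$feature_id[tab$p < alpha]
  if (length(keep) == 0)
    stopf("no deep features significant at alpha=%g for %s", alpha, model_id)
  out <- F[, keep, drop = FALSE]
  attr(out, "cox_results") <- tab
  out
}

#' Cluster samples into subgroups by k-means
#'
#' Best-of-`n_restarts` k-means (squared Euclidean) in deep-feature space.
#' With `k = 2` the clusters are provisionally labelled S1/S2 by cluster
#' index; use [orient_subgroups()] to fix the risk orientation.
#'
#' @param F_selected deep-feature matrix (samples x features).
#' @param k number of clusters (default 2, the canonical choice).
#' @param seed integer seed.
#' @param n_restarts random restarts (default 20).
#' @return A list of class `subgroup_assignment`: `sample_ids`, `label`,
#'   `centroids` (k x features), `withinss` (total within-cluster sum of
#'   squares).
#' @export
cluster_subgroups <- function(F_selected, k = 2, seed = 1, n_restarts = 20) {
  n <- nrow(F_selected)
  if (k > n) stopf("k=%d exceeds the number of samples (%d)", k, n)
  if (ncol(F_selected) < 1) stopf("no features to cluster on")
  km <- with_seed(seed,
    kmeans(F_selected, centers = k, nstart = n_restarts, iter.max = 100))
  lev <- if (k == 2) c("S1", "S2") else sprintf("C%d", seq_len(k))
  cent <- km$centers
  rownames(cent) <- lev
  structure(list(sample_ids = rownames(F_selected), label = lev[km$cluster],
                 centroids = cent, withinss = km$tot.withinss),
            class = "subgroup_assignment")
}

#' @export
print.subgroup_assignment <- function(x, ...) {
  cat(sprintf("<subgroup_assignment> %s\n",
              paste(sprintf("%s: %d", names(table(x$label)), table(x$label)),
                    collapse = ", ")))
  invisible(x)
}

#' Orient subgroup labels so S2 is the higher-risk group
#'
#' Relabels a two-cluster assignment so that S2 is the cluster with the
#' lower Kaplan-Meier survival at the median follow-up time; ties are broken
#' by the higher observed event fraction (and, failing that, the labels are
#' left as-is). The orientation is canonical: swapping the input labels
#' leaves the output unchanged.
#'
#' @param assignment a two-cluster `subgroup_assignment`.
#' @param clinical a [clinical_table()] covering the assigned samples.
#' @return The oriented `subgroup_assignment`.
#' @export
orient_subgroups <- function(assignment, clinical) {
  labs <- unique(assignment$label)
  if (length(labs) != 2) stopf("orientation requires exactly two clusters")
  clinical <- align_clinical(clinical, assignment$sample_ids)
  t_med <- median(clinical$time)
  surv <- vapply(sort(labs), function(l) {
    km <- km_estimate(clinical, assignment$label == l)
    km_surv_at(km, t_med)
  }, numeric(1))
  evfrac <- vapply(sort(labs), function(l)
    mean(clinical$event[assignment$label == l]), numeric(1))
  lab_sorted <- sort(labs)
  high_risk <- if (surv[1] != surv[2]) lab_sorted[which.min(surv)]
               else if (evfrac[1] != evfrac[2]) lab_sorted[which.max(evfrac)]
               else lab_sorted[2]
  new_label <- ifelse(assignment$label == high_risk, "S2", "S1")
  cent <- assignment$centroids
  if (!is.null(cent) && nrow(cent) == 2) {
    rownames(cent) <- ifelse(rownames(cent) == high_risk, "S2", "S1")
    cent <- cent[order(rownames(cent)), , drop = FALSE]
  }
  structure(list(sample_ids = assignment$sample_ids, label = new_label,
                 centroids = cent, withinss = assignment$withinss),
            class = "subgroup_assignment")
}

#' 10-fold cross-validated concordance of the clustered subgroups
#'
#' Folds are stratified on event status and seeded (fold membership is a
#' function of the sorted sample ids and the seed, so it is invariant to row
#' order). Per fold: the training samples are clustered and oriented, each
#' held-out sample is assigned to the nearest training centroid, and the
#' oriented label (S2 = risk 1, S1 = risk 0) is scored against the held-out
#' outcomes with Harrell's concordance. Folds without comparable pairs are
#' skipped with a warning; more than `max_skipped` skipped folds aborts.
#'
#' @param F_selected screened deep-feature matrix.
#' @param clinical a [clinical_table()].
#' @param folds number of folds (default 10).
#' @param seed integer seed.
#' @param k,n_restarts passed to [cluster_subgroups()].
#' @param model_id label carried into the report.
#' @param max_skipped maximum tolerated skipped folds (default 3).
#' @return A list of class `cv_report`: `model_id`,
#'   `n_deep_features_selected`, `fold_cindices`, `mean_cindex`,
#'   `sd_cindex`, `n_skipped`.
#' @export
cv_cindex <- function(F_selected, clinical, folds = 10, seed = 1, k = 2,
                      n_restarts = 10, model_id = "model", max_skipped = 3) {
  clinical <- align_clinical(clinical, rownames(F_selected))
  n <- nrow(F_selected)
  if (n < folds) stopf("need at least %d samples for %d-fold CV", folds, folds)
  fold_of <- stratified_folds(rownames(F_selected), clinical$event, folds,
                              seed)
  cis <- numeric(0); skipped <- 0
  for (f in seq_len(folds)) {
    te <- fold_of == f
    ci <- tryCatch({
      asg <- cluster_subgroups(F_selected[!te, , drop = FALSE], k = k,
                               seed = sub_seed(seed, paste0("fold", f)),
                               n_restarts = n_restarts)
      asg <- orient_subgroups(asg, clinical[!te, , drop = FALSE])
      nearest <- nearest_centroid(F_selected[te, , drop = FALSE],
                                  asg$centroids)
      risk <- as.numeric(rownames(asg$centroids)[nearest] == "S2")
      concordance_index(risk, clinical[te, , drop = FALSE])
    }, error = function(e) NA_real_)
    if (is.na(ci)) {
      skipped <- skipped + 1
      warnf("fold %d skipped (no comparable pairs or degenerate clustering)", f)
    } else cis <- c(cis, ci)
  }
  if (skipped > max_skipped)
    stopf("unreliable CV: %d of %d folds skipped", skipped, folds)
  structure(list(model_id = model_id,
                 n_deep_features_selected = ncol(F_selected),
                 fold_cindices = cis,
                 mean_cindex = mean(cis),
                 sd_cindex = sd(cis),
                 n_skipped = skipped),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report %s> %d deep features; C-index %.3f/%.3f over %d folds\n",
              x$model_id, x$n_deep_features_selected, x$mean_cindex,
              x$sd_cindex, length(x$fold_cindices)))
  invisible(x)
}

# Index of the squared-Euclidean-nearest centroid for every row of F.
nearest_centroid <- function(F, centroids) {
  d2 <- vapply(seq_len(nrow(centroids)), function(i)
    rowSums(sweep(F, 2, centroids[i, ], "-")^2), numeric(nrow(F)))
  if (nrow(F) == 1) d2 <- matrix(d2, nrow = 1)
  max.col(-d2, ties.method = "first")
}

# Event-stratified fold labels, a pure function of (sorted ids, event, seed).
stratified_folds <- function(ids, event, folds, seed) {
  ord <- order(ids)
  fold_of <- integer(length(ids))
  with_seed(sub_seed(seed, "folds"), {
    for (ev in c(1, 0)) {
      idx <- ord[event[ord] == ev]
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_of
}

#' Select the final model by KM separation among the top concordance pair
#'
#' Takes the two models with the highest mean cross-validated concordance,
#' runs a full-cohort log-rank test on each model's oriented subgroups, and
#' returns the id of the model with the smaller log-rank p (ties to machine
#' precision go to the earlier model in `reports`). A single candidate is
#' returned directly.
#'
#' @param reports list of `cv_report`s.
#' @param assignments named list of oriented `subgroup_assignment`s (one per
#'   model id).
#' @param clinical a [clinical_table()].
#' @return The selected `model_id` (character), with attribute `"selection"`
#'   holding the candidate table.
#' @export
select_best_model <- function(reports, assignments, clinical) {
  if (length(reports) == 0) stopf("no models to select from")
  ids <- vapply(reports, `[[`, "", "model_id")
  if (length(reports) == 1) return(ids[1])
  mc <- vapply(reports, `[[`, numeric(1), "mean_cindex")
  top <- order(-mc, seq_along(mc))[1:2]
  ps <- vapply(top, function(i) {
    a <- assignments[[ids[i]]]
    cl <- align_clinical(clinical, a$sample_ids)
    logrank_test(cl, a$label)$p
  }, numeric(1))
  pick <- top[order(ps, top)][1]
  sel <- data.frame(model_id = ids[top], mean_cindex = mc[top],
                    logrank_p = ps, stringsAsFactors = FALSE)
  structure(ids[pick], selection = sel)
}
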