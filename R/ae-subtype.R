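#' Fit the autoencoder multi-omics relapse subtyping model
#'
#' End-to-end fit: preprocess and stack the omics blocks, train one
#' penalized autoencoder per grid configuration, screen each model's
#' bottleneck deep features by univariate Cox-PH Wald tests, cluster the
#' cohort into low-risk (S1) / high-risk (S2) subgroups with k-means, score
#' every model by 10-fold cross-validated Harrell concordance, select the
#' final model by full-cohort Kaplan-Meier log-rank separation among the two
#' highest-concordance candidates, and (optionally) fit one per-omics lasso
#' signature of the final subgroups for external label transfer.
#'
#' @param omics list of [omics_matrix()] blocks (pairwise-disjoint kind /
#'   feature-id pairs).
#' @param clinical a [clinical_table()] covering the blocks' common samples.
#' @param grid list of [ae_config()]s; `NULL` (default) uses
#'   [default_ae_grid()] seeded from `seed`.
#' @param alpha Wald screening level (default 0.05, unadjusted).
#' @param k number of subgroups (default 2, the canonical choice).
#' @param folds cross-validation folds (default 10).
#' @param n_restarts k-means restarts (default 20).
#' @param fit_signatures fit per-omics lasso signatures of the final
#'   subgroups (default `TRUE`).
#' @param min_variance,max_features_per_block passed to
#'   [preprocess_blocks()].
#' @param seed global seed; every stochastic stage derives its own sub-seed
#'   from it.
#' @return An object of class `ae_subtype`; see [summary.ae_subtype()],
#'   [predict.ae_subtype()], [plot.ae_subtype()].
#' @examples
#' \donttest{
#' ds <- generate_dataset(synth_config(n_samples = 120,
#'   omics_blocks = default_omics_blocks(n_features = 40), seed = 7))
#' fit <- ae_subtype(ds$omics, ds$clinical,
#'                   grid = list(ae_config(bottleneck = 20, seed = 7)),
#'                   seed = 7)
#' summary(fit)
#' }
#' @export
ae_subtype <- function(omics, clinical, grid = NULL, alpha = 0.05, k = 2,
                       folds = 10, n_restarts = 20, fit_signatures = TRUE,
                       min_variance = 0, max_features_per_block = Inf,
                       seed = 1) {
  cl <- match.call()
  if (inherits(omics, "omics_matrix")) omics <- list(omics)
  stack <- preprocess_blocks(omics, min_variance = min_variance,
                             max_features_per_block = max_features_per_block)
  clinical <- align_clinical(clinical, rownames(stack$values))
  if (is.null(grid)) grid <- default_ae_grid(seed = seed)

  gr <- run_model_grid(stack, grid)
  ids <- names(gr$models)
  deep_sel <- assignments <- cv_reports <- vector("list", length(ids))
  names(deep_sel) <- names(assignments) <- names(cv_reports) <- ids
  for (i in seq_along(ids)) {
    id <- ids[i]
    sel <- tryCatch(
      select_relapse_features(gr$features[[i]], clinical, alpha = alpha,
                              model_id = id),
      error = function(e) { warnf("%s: %s", id, conditionMessage(e)); NULL })
    if (is.null(sel)) next
    deep_sel[[i]] <- sel
    asg <- cluster_subgroups(sel, k = k,
                             seed = sub_seed(seed, paste0("cluster_", id)),
                             n_restarts = n_restarts)
    if (k == 2) asg <- orient_subgroups(asg, clinical)
    assignments[[i]] <- asg
    cv_reports[[i]] <- cv_cindex(sel, clinical, folds = folds,
                                 seed = sub_seed(seed, paste0("cv_", id)),
                                 k = k, n_restarts = max(5, n_restarts %/% 2),
                                 model_id = id)
    gr$report$deep_features[i] <- ncol(sel)
    gr$report[["mean c-index/SD"]][i] <-
      sprintf("%.3f/%.3f", cv_reports[[i]]$mean_cindex,
              cv_reports[[i]]$sd_cindex)
  }
  ok <- !vapply(cv_reports, is.null, logical(1))
  if (!any(ok))
    stopf("no model retained any relapse-associated deep features at alpha=%g",
          alpha)
  best <- select_best_model(cv_reports[ok], assignments[ok], clinical)
  assignment <- assignments[[best]]
  lr <- logrank_test(align_clinical(clinical, assignment$sample_ids),
                     assignment$label)

  signatures <- NULL
  if (fit_signatures && k == 2) {
    signatures <- lapply(seq_along(omics), function(j) {
      b <- omics[[j]]
      keep <- rownames(b$values) %in% assignment$sample_ids
      b <- omics_matrix(b$values[keep, , drop = FALSE], b$kind)
      fit_lasso_signature(b, assignment,
                          seed = sub_seed(seed, paste0("lasso_", j, b$kind)))
    })
    names(signatures) <- vapply(omics, `[[`, "", "kind")
  }

  structure(list(stack = stack, grid_report = gr$report, models = gr$models,
                 deep_features = deep_sel, assignments = assignments,
                 cv_reports = cv_reports, best_model_id = as.character(best),
                 selection = attr(best, "selection"),
                 assignment = assignment, logrank = lr,
                 signatures = signatures, clinical = clinical,
                 alpha = alpha, k = k, folds = folds, seed = seed,
                 call = cl),
            class = "ae_subtype")
}

#' @export
print.ae_subtype <- function(x, ...) {
  cat("Autoencoder multi-omics relapse subtyping\n")
  cat(sprintf("  %d samples, %d stacked features, %d candidate models\n",
              nrow(x$stack$values), ncol(x$stack$values), length(x$models)))
  cv <- x$cv_reports[[x$best_model_id]]
  cat(sprintf("  selected %s: %d relapse-associated deep features; CV C-index %.3f/%.3f\n",
              x$best_model_id, cv$n_deep_features_selected, cv$mean_cindex,
              cv$sd_cindex))
  cat(sprintf("  subgroups S1=%d, S2=%d; log-rank p = %.3g\n",
              sum(x$assignment$label == "S1"), sum(x$assignment$label == "S2"),
              x$logrank$p))
  invisible(x)
}

#' Summarize a fitted subtyping model
#'
#' @param object an [ae_subtype()] fit.
#' @param ... unused.
#' @return The object, invisibly; prints the model-grid table, the selection
#'   contest and signature sizes.
#' @export
summary.ae_subtype <- function(object, ...) {
  print(object)
  cat("\nModel grid:\n")
  print(object$grid_report, row.names = FALSE, digits = 6)
  if (!is.null(object$selection)) {
    cat("\nSelection among top-concordance pair (smaller log-rank p wins):\n")
    print(object$selection, row.names = FALSE)
  }
  if (!is.null(object$signatures)) {
    cat("\nPer-omics signature sizes:\n")
    for (k in names(object$signatures))
      cat(sprintf("  %s: %d features\n", k,
                  length(object$signatures[[k]]$feature_ids)))
  }
  invisible(object)
}

#' Signature coefficients of a fitted subtyping model
#'
#' @param object an [ae_subtype()] fit with signatures.
#' @param ... unused.
#' @return Named list (per omics kind) of data.frames `feature_id`,
#'   `coefficient`, with the intercept as attribute `"intercept"`.
#' @export
coef.ae_subtype <- function(object, ...) {
  if (is.null(object$signatures)) stopf("fit has no signatures")
  lapply(object$signatures, function(s) {
    out <- data.frame(feature_id = s$feature_ids, coefficient = s$coefficients,
                      stringsAsFactors = FALSE)
    attr(out, "intercept") <- s$intercept
    out
  })
}

#' Transfer subgroup labels to an external single-omics cohort
#'
#' @param object an [ae_subtype()] fit with signatures.
#' @param newdata an [omics_matrix()] (its `kind` selects the signature) or
#'   a plain samples x features matrix (then give `kind`).
#' @param kind omics kind when `newdata` is a bare matrix.
#' @param type `"label"` (default) for transferred S1/S2 labels,
#'   `"probability"` for the logistic S2 score.
#' @param threshold optional override of the signature's decision threshold
#'   (a probability, or `"median"`).
#' @param ... unused.
#' @return Named character vector of labels or numeric vector of
#'   probabilities.
#' @export
predict.ae_subtype <- function(object, newdata, kind = NULL,
                               type = c("label", "probability"),
                               threshold = NULL, ...) {
  type <- match.arg(type)
  if (is.null(object$signatures)) stopf("fit has no signatures")
  if (!inherits(newdata, "omics_matrix")) {
    if (is.null(kind)) stopf("give `kind` for a bare matrix")
    newdata <- omics_matrix(as.matrix(newdata), kind)
  }
  sig <- object$signatures[[newdata$kind]]
  if (is.null(sig)) stopf("no signature for omics kind '%s'", newdata$kind)
  sc <- score_external(sig, newdata, threshold = threshold)
  if (type == "probability") sc$probability
  else stats::setNames(sc$assignment$label, sc$assignment$sample_ids)
}

#' Kaplan-Meier plot of the fitted subgroups
#'
#' Step-function KM curves for S1 and S2 with the full-cohort log-rank p in
#' the legend.
#'
#' @param x an [ae_subtype()] fit.
#' @param ... passed to [graphics::plot()].
#' @return The two `km_curve`s, invisibly.
#' @export
plot.ae_subtype <- function(x, ...) {
  cl <- align_clinical(x$clinical, x$assignment$sample_ids)
  km1 <- km_estimate(cl, x$assignment$label == "S1")
  km2 <- km_estimate(cl, x$assignment$label == "S2")
  graphics::plot(c(0, max(cl$time)), c(0, 1), type = "n",
                 xlab = "Time", ylab = "Relapse-free survival", ...)
  graphics::lines(stats::stepfun(km1$time, c(1, km1$survival)), do.points = FALSE,
                  col = "#2166AC", lwd = 2)
  graphics::lines(stats::stepfun(km2$time, c(1, km2$survival)), do.points = FALSE,
                  col = "#B2182B", lwd = 2)
  graphics::legend("bottomleft", bty = "n", lwd = 2,
                   col = c("#2166AC", "#B2182B"),
                   legend = c(sprintf("S1 (n=%d)", sum(x$assignment$label == "S1")),
                              sprintf("S2 (n=%d), log-rank p=%.2g",
                                      sum(x$assignment$label == "S2"),
                                      x$logrank$p)))
  invisible(list(S1 = km1, S2 = km2))
}
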