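# Per-omics sparse signatures: an L1-penalized logistic regression of the
# S2-vs-S1 subgroup label on one omics block (fit with glmnet coordinate
# descent), used to transfer the subgroup labels to external single-omics
# cohorts and validate the transfer by log-rank and concordance.

#' Fit a per-omics lasso subgroup signature
#'
#' L1-penalized logistic regression (S2 = 1) on the min-max scaled block,
#' with the penalty chosen by seeded cross-validated binomial deviance under
#' the one-standard-error rule. The signature is the set of features with
#' nonzero coefficients at the chosen lambda.
#'
#' @param block an [omics_matrix()].
#' @param labels a `subgroup_assignment` or named `"S1"`/`"S2"` vector
#'   covering the block's samples.
#' @param lambda_path optional decreasing lambda sequence (default: glmnet's
#'   own path).
#' @param cv_folds folds for the penalty cross-validation (default 10).
#' @param seed integer seed.
#' @param lambda_rule `"1se"` (default) or `"min"`.
#' @param lambda optional fixed penalty; skips the cross-validation
#'   (`lambda = 0` is the unpenalized logistic fit).
#' @return A list of class `lasso_signature`: `omics_kind`, `feature_ids`,
#'   `coefficients`, `intercept`, `lambda`, `decision_threshold`,
#'   `training_scaling` (per-selected-feature min/max on the raw scale).
#'   An empty signature (with a warning) if the path never selects a
#'   feature.
#' @export
fit_lasso_signature <- function(block, labels, lambda_path = NULL,
                                cv_folds = 10, seed = 1,
                                lambda_rule = c("1se", "min"),
                                lambda = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  lab <- if (inherits(labels, "subgroup_assignment")) {
    stats::setNames(labels$label, labels$sample_ids)
  } else labels
  ids <- rownames(block$values)
  lab <- lab[ids]
  if (anyNA(lab)) stopf("labels missing for %d block samples", sum(is.na(lab)))
  if (length(unique(lab)) < 2)
    stopf("degenerate labels: both subgroups must be present")
  lo <- apply(block$values, 2, min)
  hi <- apply(block$values, 2, max)
  rng <- pmax(hi - lo, 1e-12)
  Xs <- sweep(sweep(block$values, 2, lo, "-"), 2, rng, "/")
  y <- as.numeric(lab == "S2")
  if (is.null(lambda)) {
    cvfit <- with_seed(sub_seed(seed, "lasso_cv"),
      glmnet::cv.glmnet(Xs, y, family = "binomial", alpha = 1,
                        nfolds = cv_folds, lambda = lambda_path,
                        standardize = FALSE))
    lam <- if (lambda_rule == "1se") cvfit$lambda.1se else cvfit$lambda.min
    cf <- as.matrix(coef(cvfit, s = lam))[, 1]
  } else {
    # fixed penalty: refit on a short path ending at `lambda` so the
    # coordinate-descent warm starts stay on the regularization path
    lam <- lambda
    path <- sort(unique(c(exp(seq(log(1), log(max(lam, 1e-4)), length.out = 20)),
                          lam)), decreasing = TRUE)
    fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 1,
                          lambda = path, standardize = FALSE,
                          thresh = 1e-12, maxit = 1e6)
    cf <- as.matrix(coef(fit, s = lam, exact = TRUE, x = Xs, y = y))[, 1]
  }
  nz <- cf[-1][cf[-1] != 0]
  if (length(nz) == 0)
    warnf("lasso selected no features for kind '%s' (empty signature)",
          block$kind)
  sel <- names(nz)
  structure(list(omics_kind = block$kind,
                 feature_ids = sel,
                 coefficients = unname(nz),
                 intercept = unname(cf[1]),
                 lambda = lam,
                 decision_threshold = 0.5,
                 training_scaling = data.frame(
                   feature_id = sel, min = unname(lo[sel]),
                   max = unname(hi[sel]), stringsAsFactors = FALSE)),
            class = "lasso_signature")
}

#' @export
print.lasso_signature <- function(x, ...) {
  cat(sprintf("<lasso_signature %s> %d features, lambda=%.4g, threshold=%s\n",
              x$omics_kind, length(x$feature_ids), x$lambda,
              format(x$decision_threshold)))
  invisible(x)
}

#' Score an external single-omics cohort with a signature
#'
#' The external block is min-max scaled within the cohort (making the score
#' invariant to affine rescaling of the raw platform values); signature
#' features missing from the block are imputed at the scaled midpoint 0.5
#' with a message (more than half missing triggers an
#' untrustworthy-transfer warning). The logistic score
#' `sigmoid(intercept + sum(coef * x))` labels a sample S2 when it reaches
#' the decision threshold.
#'
#' @param sig a [fit_lasso_signature()] signature.
#' @param block an [omics_matrix()] of the same omics kind.
#' @param threshold probability cut; the default uses
#'   `sig$decision_threshold`; `"median"` labels by the cohort-median score
#'   (useful for heavily imbalanced transfers).
#' @return List with `probability` (named numeric) and `assignment`
#'   (`subgroup_assignment`).
#' @export
score_external <- function(sig, block, threshold = NULL) {
  if (block$kind != sig$omics_kind)
    stopf("block kind '%s' does not match signature kind '%s'",
          block$kind, sig$omics_kind)
  if (length(sig$feature_ids) == 0)
    stopf("untransferable signature: no features")
  present <- sig$feature_ids %in% colnames(block$values)
  if (!any(present))
    stopf("untransferable signature: none of its %d features are in the block",
          length(sig$feature_ids))
  n_missing <- sum(!present)
  if (n_missing > 0)
    message(sprintf("%d of %d signature features missing; imputing at 0.5",
                    n_missing, length(sig$feature_ids)))
  if (n_missing > length(sig$feature_ids) / 2)
    warnf("untrustworthy transfer: more than half of the signature features are missing")
  n <- nrow(block$values)
  Xsig <- matrix(0.5, n, length(sig$feature_ids),
                 dimnames = list(rownames(block$values), sig$feature_ids))
  for (j in which(present)) {
    v <- block$values[, sig$feature_ids[j]]
    rng <- max(v) - min(v)
    Xsig[, j] <- if (rng == 0) 0.5 else (v - min(v)) / rng
  }
  eta <- drop(Xsig %*% sig$coefficients) + sig$intercept
  prob <- plogis(eta)
  cut <- if (is.null(threshold)) sig$decision_threshold else threshold
  lab <- if (identical(cut, "median")) {
    ifelse(prob >= median(prob), "S2", "S1")
  } else ifelse(prob >= cut, "S2", "S1")
  asg <- structure(list(sample_ids = rownames(block$values), label = lab,
                        centroids = NULL, withinss = NULL),
                   class = "subgroup_assignment")
  list(probability = stats::setNames(prob, rownames(block$values)),
       assignment = asg)
}

#' Validate transferred subgroup labels against survival
#'
#' Log-rank test between transferred S1/S2 plus Harrell's concordance of the
#' binary label used as a risk score (S2 = 1). If only one group was
#' transferred, a flagged single-group report is returned (log-rank
#' undefined).
#'
#' @param assignment a `subgroup_assignment` of transferred labels.
#' @param clinical the external cohort's [clinical_table()].
#' @param cohort_id label carried into the report.
#' @return A list of class `validation_report`: `cohort_id`, `n_samples`,
#'   `group_sizes`, `logrank_chi_square`, `logrank_p`, `cindex`,
#'   `single_group`.
#' @export
validate_external <- function(assignment, clinical, cohort_id = "external") {
  clinical <- align_clinical(clinical, assignment$sample_ids)
  sizes <- c(n_S1 = sum(assignment$label == "S1"),
             n_S2 = sum(assignment$label == "S2"))
  if (any(sizes == 0)) {
    warnf("single transferred group in cohort '%s'; log-rank undefined",
          cohort_id)
    return(structure(list(cohort_id = cohort_id, n_samples = sum(sizes),
                          group_sizes = sizes,
                          logrank_chi_square = NA_real_, logrank_p = NA_real_,
                          cindex = NA_real_, single_group = TRUE),
                     class = "validation_report"))
  }
  lr <- logrank_test(clinical, assignment$label)
  ci <- concordance_index(as.numeric(assignment$label == "S2"), clinical)
  structure(list(cohort_id = cohort_id, n_samples = sum(sizes),
                 group_sizes = sizes,
                 logrank_chi_square = lr$chi_square,
                 logrank_p = max(lr$p, 1e-300),
                 cindex = ci, single_group = FALSE),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$single_group) {
    cat(sprintf("<validation_report %s> single group (n=%d); log-rank undefined\n",
                x$cohort_id, x$n_samples))
  } else {
    cat(sprintf("<validation_report %s> n=%d (S1=%d, S2=%d); log-rank p=%.3g; C-index=%.3f\n",
                x$cohort_id, x$n_samples, x$group_sizes[1], x$group_sizes[2],
                x$logrank_p, x$cindex))
  }
  invisible(x)
}
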