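risky_features <- function(n = 120, seed = 1, hr = 3) {
  lab <- make_subgroup_labels(n, 0.5, seed = seed)
  names(lab) <- sprintf("S%04d", seq_len(n))
  cl <- simulate_survival(lab, 0.2, hr, censoring_rate = 0.2,
                          admin_censor_time = 15, seed = seed + 99)
  F <- withr::with_seed(seed, cbind(
    DF1 = as.numeric(lab == "S2") + rnorm(n, 0, 0.3),   # strong risk score
    DF2 = rnorm(n), DF3 = rnorm(n)))                    # noise
  rownames(F) <- names(lab)
  list(F = F, clinical = cl, lab = lab)
}

test_that("Wald screening keeps planted risk features and drops pure noise", {
  rf <- risky_features(seed = 2)
  sel <- select_relapse_features(rf$F, rf$clinical)
  expect_true("DF1" %in% colnames(sel))
  tab <- attr(sel, "cox_results")
  expect_equal(nrow(tab), 3)
  expect_lt(tab$p[tab$feature_id == "DF1"], 0.001)

  Fc <- cbind(rf$F, DF4 = rep(1, nrow(rf$F)))
  expect_message(sel2 <- select_relapse_features(Fc, rf$clinical),
                 "constant deep feature")
  expect_false("DF4" %in% colnames(sel2))

  Fnoise <- rf$F[, 2:3]
  colnames(Fnoise) <- c("DF1", "DF2")
  expect_error(select_relapse_features(Fnoise, rf$clinical, alpha = 1e-6,
                                       model_id = "m_null"),
               "no deep features significant.*m_null")
})

test_that("k-means recovers separated blobs and attains the exhaustive optimum", {
  set.seed(3)
  X <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
             matrix(rnorm(40, 5, 0.2), 20, 2))
  rownames(X) <- sprintf("S%02d", 1:40)
  asg <- cluster_subgroups(X, k = 2, seed = 3)
  expect_length(unique(asg$label[1:20]), 1)
  expect_length(unique(asg$label[21:40]), 1)
  expect_false(asg$label[1] == asg$label[40])

  set.seed(4)
  P <- matrix(rnorm(16), 8, 2, dimnames = list(sprintf("P%d", 1:8), NULL))
  asg8 <- cluster_subgroups(P, k = 2, seed = 4, n_restarts = 50)
  expect_equal(asg8$withinss, oracle_best_wss_k2(P), tolerance = 1e-9)

  asg1 <- cluster_subgroups(P, k = 1, seed = 4)
  tss <- sum(sweep(P, 2, colMeans(P), "-")^2)
  expect_equal(asg1$withinss, tss, tolerance = 1e-9)
  expect_length(unique(asg1$label), 1)
  expect_error(cluster_subgroups(P, k = 9), "exceeds the number of samples")
})

test_that("orientation makes S2 the higher-risk cluster, canonically", {
  cl <- clinical_table(sprintf("P%d", 1:8),
                       c(1, 1.5, 2, 2.5, 9, 10, 11, 12),
                       c(1, 1, 1, 1, 0, 0, 0, 1))
  asg <- structure(list(sample_ids = cl$sample_id,
                        label = rep(c("S1", "S2"), each = 4),
                        centroids = matrix(c(0, 1), 2, 1,
                                           dimnames = list(c("S1", "S2"), NULL)),
                        withinss = 0),
                   class = "subgroup_assignment")
  # cluster with the early events must end up S2
  out <- orient_subgroups(asg, cl)
  expect_true(all(out$label[1:4] == "S2"))
  expect_true(all(out$label[5:8] == "S1"))

  flipped <- asg
  flipped$label <- rep(c("S2", "S1"), each = 4)
  out2 <- orient_subgroups(flipped, cl)
  expect_identical(out2$label, out$label)

  # equal KM at the median follow-up, unequal event fractions
  cl_tie <- clinical_table(sprintf("Q%d", 1:4), c(1, 10, 1, 10), c(1, 0, 1, 1))
  asg_tie <- structure(list(sample_ids = cl_tie$sample_id,
                            label = c("S1", "S1", "S2", "S2"),
                            centroids = NULL, withinss = 0),
                       class = "subgroup_assignment")
  out3 <- orient_subgroups(asg_tie, cl_tie)
  expect_identical(out3$label, c("S1", "S1", "S2", "S2"))
})

test_that("cross-validated concordance tracks the planted signal and the null", {
  rf <- risky_features(n = 150, seed = 5)
  cv <- cv_cindex(rf$F[, "DF1", drop = FALSE], rf$clinical, seed = 5,
                  model_id = "planted")
  expect_equal(cv$n_deep_features_selected, 1)
  expect_length(cv$fold_cindices, 10)
  expect_equal(cv$mean_cindex, mean(cv$fold_cindices))
  expect_equal(cv$sd_cindex, sd(cv$fold_cindices))
  # a perfect binary risk at HR=3 has concordance ~0.62 (simulation ceiling)
  expect_gte(cv$mean_cindex, 0.55)

  null_cis <- vapply(1:5, function(s) {
    rfn <- risky_features(n = 100, seed = s + 50, hr = 1)
    Fn <- rfn$F[, 2:3]
    cv_cindex(Fn, rfn$clinical, seed = s, model_id = "null")$mean_cindex
  }, numeric(1))
  expect_gt(mean(null_cis), 0.4)
  expect_lt(mean(null_cis), 0.6)
})

test_that("cross-validation folds are a function of ids, not row order", {
  rf <- risky_features(n = 120, seed = 6)
  cv1 <- cv_cindex(rf$F, rf$clinical, seed = 6)
  perm <- withr::with_seed(1, sample.int(120))
  cv2 <- cv_cindex(rf$F[perm, ], rf$clinical[perm, ], seed = 6)
  expect_equal(cv1$fold_cindices, cv2$fold_cindices)
  expect_equal(cv1$mean_cindex, cv2$mean_cindex)
})

test_that("model selection takes the top-concordance pair to a KM contest", {
  rf <- risky_features(n = 150, seed = 7)
  asg_good <- orient_subgroups(
    cluster_subgroups(rf$F[, "DF1", drop = FALSE], seed = 7), rf$clinical)
  asg_bad <- structure(list(sample_ids = rf$clinical$sample_id,
                            label = rep(c("S1", "S2"), 75),
                            centroids = NULL, withinss = 0),
                       class = "subgroup_assignment")
  mk_rep <- function(id, mc) structure(
    list(model_id = id, n_deep_features_selected = 1,
         fold_cindices = rep(mc, 10), mean_cindex = mc, sd_cindex = 0),
    class = "cv_report")
  reports <- list(mk_rep("model_1", 0.70), mk_rep("model_2", 0.69),
                  mk_rep("model_3", 0.40))
  assignments <- list(model_1 = asg_bad, model_2 = asg_good,
                      model_3 = asg_bad)
  best <- select_best_model(reports, assignments, rf$clinical)
  expect_equal(as.character(best), "model_2")
  sel <- attr(best, "selection")
  expect_equal(sort(sel$model_id), c("model_1", "model_2"))

  expect_equal(as.character(select_best_model(reports[1], assignments[1],
                                              rf$clinical)), "model_1")
  # exact tie in p: earlier model wins
  tie <- select_best_model(list(mk_rep("model_1", 0.7), mk_rep("model_2", 0.7)),
                           list(model_1 = asg_good, model_2 = asg_good),
                           rf$clinical)
  expect_equal(as.character(tie), "model_1")
  expect_error(select_best_model(list(), list(), rf$clinical), "no models")
})
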