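# Synthetic multi-omics survival generator.
#
# Emulates the statistical structure the subtyping pipeline assumes: K omics
# blocks with block-appropriate marginals, a latent two-subgroup structure
# expressed in a sparse set of informative features per block, a
# proportional-hazards relapse outcome driven by subgroup, and independent
# (uniform + administrative) censoring. Every generator is a pure function
# of its seed and parameters.

#' Synthetic dataset configuration
#'
#' Bundles all generator parameters. The defaults are the package's demo
#' conditions: 400 patients, five omics blocks of 200 features with 20
#' informative features each at effect size 1.0 (within-group SD units),
#' subgroup hazard ratio 3, and 30% expected censoring.
#'
#' @param n_samples number of patients.
#' @param subgroup_proportion fraction of samples assigned to the high-risk
#'   subgroup S2 (default 0.365, a roughly one-third minority subgroup).
#' @param omics_blocks list of block descriptors; each is a list with
#'   elements `kind`, `n_features`, `n_informative`, `effect_size`.
#' @param hazard_ratio relapse hazard ratio of S2 vs S1 (> 0).
#' @param baseline_hazard exponential event rate for S1, per unit time.
#' @param censoring_rate target expected censored fraction in `[0, 1)`.
#' @param admin_censor_time administrative end of follow-up (may be `Inf`).
#' @param methylation_values `"beta"` (values in (0,1)) or `"mvalue"`
#'   (logit scale) for methylation blocks.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 400,
                         subgroup_proportion = 0.365,
                         omics_blocks = default_omics_blocks(),
                         hazard_ratio = 3,
                         baseline_hazard = 0.2,
                         censoring_rate = 0.3,
                         admin_censor_time = 15,
                         methylation_values = c("beta", "mvalue"),
                         seed = 1) {
  methylation_values <- match.arg(methylation_values)
  if (!is_count(n_samples) || n_samples < 2) stopf("`n_samples` must be >= 2")
  if (subgroup_proportion <= 0 || subgroup_proportion >= 1)
    stopf("`subgroup_proportion` must lie in (0, 1)")
  if (hazard_ratio <= 0) stopf("`hazard_ratio` must be positive")
  if (baseline_hazard <= 0) stopf("`baseline_hazard` must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stopf("`censoring_rate` must lie in [0, 1)")
  if (admin_censor_time <= 0) stopf("`admin_censor_time` must be positive")
  for (b in omics_blocks) {
    stopifnot(is.list(b), all(c("kind", "n_features", "n_informative",
                                "effect_size") %in% names(b)))
    if (!b$kind %in% omics_kinds()) stopf("unsupported omics kind '%s'", b$kind)
    if (b$n_informative > b$n_features)
      stopf("block '%s': n_informative exceeds n_features", b$kind)
  }
  structure(list(n_samples = n_samples,
                 subgroup_proportion = subgroup_proportion,
                 omics_blocks = omics_blocks,
                 hazard_ratio = hazard_ratio,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 admin_censor_time = admin_censor_time,
                 methylation_values = methylation_values,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @rdname synth_config
#' @param n_features,n_informative,effect_size shared per-block settings for
#'   the default five-block design (one block per omics kind).
#' @export
default_omics_blocks <- function(n_features = 200, n_informative = 20,
                                 effect_size = 1.0) {
  lapply(omics_kinds(), function(k)
    list(kind = k, n_features = n_features, n_informative = n_informative,
         effect_size = effect_size))
}

#' Draw S1/S2 subgroup labels
#'
#' Assigns exactly `round(n * proportion)` samples to the high-risk label S2
#' at seeded-random positions; the rest are S1.
#'
#' @param n number of samples (>= 2).
#' @param proportion target S2 fraction in (0, 1).
#' @param seed integer seed.
#' @return Character vector of `"S1"`/`"S2"` of length `n`.
#' @export
make_subgroup_labels <- function(n, proportion, seed = 1) {
  if (!is_count(n) || n < 2) stopf("`n` must be an integer >= 2")
  if (proportion <= 0 || proportion >= 1) stopf("`proportion` must lie in (0, 1)")
  n_s2 <- round(n * proportion)
  labels <- rep("S1", n)
  labels[with_seed(seed, sample.int(n, n_s2))] <- "S2"
  labels
}

#' Simulate one omics block with planted subgroup signal
#'
#' Marginals depend on the omics kind: mRNA/miRNA/lncRNA are `log1p` of
#' negative-binomial counts; methylation is simulated on the logit (M-value)
#' scale and reported as beta values in (0, 1) by default; CNV scores are
#' Gaussian clipped to `[-2, 2]` (GISTIC-like). A seeded-random subset of
#' `n_informative` columns has its S2 mean shifted by `effect_size` pooled
#' within-group standard deviations (measured on the block's transformed
#' scale, i.e. after `log1p` / on the M-value scale); all other columns are
#' label-independent noise.
#'
#' @param labels character vector of `"S1"`/`"S2"` labels, optionally named
#'   by sample id.
#' @param kind omics kind tag.
#' @param n_features,n_informative block dimensions.
#' @param effect_size mean shift in within-group SD units (may be 0).
#' @param seed integer seed.
#' @param methylation_values `"beta"` or `"mvalue"` (methylation blocks only).
#' @return An [omics_matrix()] with attribute `"informative"` holding the
#'   planted informative feature ids.
#' @export
simulate_omics_block <- function(labels, kind, n_features,
                                 n_informative = 0, effect_size = 0,
                                 seed = 1,
                                 methylation_values = c("beta", "mvalue")) {
  methylation_values <- match.arg(methylation_values)
  if (length(labels) < 1) stopf("`labels` must be non-empty")
  if (!kind %in% omics_kinds())
    stopf("unsupported omics kind '%s'", kind)
  if (n_informative > n_features) stopf("n_informative exceeds n_features")
  n <- length(labels)
  ids <- names(labels)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(n))
  fids <- sprintf("%s_f%03d", kind, seq_len(n_features))
  is_s2 <- labels == "S2"

  out <- with_seed(seed, {
    base <- switch(
      kind,
      mRNA = ,
      lncRNA = ,
      miRNA = {
        mu <- exp(rnorm(n_features, mean = log(50), sd = 1))
        matrix(log1p(rnbinom(n * n_features, size = 5,
                             mu = rep(mu, each = n))), nrow = n)
      },
      methylation = {
        mu <- rnorm(n_features, 0, 1.5)
        matrix(rnorm(n * n_features, mean = rep(mu, each = n), sd = 1),
               nrow = n)
      },
      cnv = matrix(rnorm(n * n_features, 0, 0.4), nrow = n)
    )
    inf_idx <- if (n_informative > 0) sort(sample.int(n_features, n_informative))
               else integer(0)
    if (length(inf_idx) > 0 && effect_size != 0 && any(is_s2) && any(!is_s2)) {
      for (j in inf_idx) {
        s_pool <- pooled_sd(base[, j], is_s2)
        base[is_s2, j] <- base[is_s2, j] + effect_size * max(s_pool, 1e-8)
      }
    }
    list(base = base, inf_idx = inf_idx)
  })

  m <- out$base
  if (kind == "methylation" && methylation_values == "beta")
    m <- pmin(pmax(plogis(m), 1e-6), 1 - 1e-6)
  if (kind == "cnv") m <- pmin(pmax(m, -2), 2)
  dimnames(m) <- list(ids, fids)
  om <- omics_matrix(m, kind)
  attr(om, "informative") <- fids[out$inf_idx]
  om
}

pooled_sd <- function(x, grp) {
  n1 <- sum(grp); n2 <- sum(!grp)
  if (n1 < 2 || n2 < 2) return(sd(x))
  sqrt(((n1 - 1) * var(x[grp]) + (n2 - 1) * var(x[!grp])) / (n1 + n2 - 2))
}

#' Simulate a proportional-hazards relapse outcome
#'
#' Event times are exponential with rate `baseline_hazard` for S1 and
#' `baseline_hazard * hazard_ratio` for S2. Censoring is the minimum of an
#' administrative cutoff and an independent uniform censoring time whose
#' upper bound is calibrated so that the expected censored fraction equals
#' `censoring_rate`; observed time is the minimum of event and censoring
#' times and `event = 1` iff the event time wins.
#'
#' @inheritParams synth_config
#' @param labels `"S1"`/`"S2"` vector, optionally named by sample id.
#' @param seed integer seed.
#' @return A [clinical_table()].
#' @export
simulate_survival <- function(labels, baseline_hazard, hazard_ratio,
                              censoring_rate = 0, admin_censor_time = Inf,
                              seed = 1) {
  if (baseline_hazard <= 0 || hazard_ratio <= 0)
    stopf("hazard parameters must be strictly positive")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stopf("`censoring_rate` must lie in [0, 1)")
  n <- length(labels)
  ids <- names(labels)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(n))
  rate <- baseline_hazard * ifelse(labels == "S2", hazard_ratio, 1)
  pi2 <- mean(labels == "S2")

  with_seed(seed, {
    t_event <- rexp(n, rate)
    c_time <- rep(admin_censor_time, n)
    if (censoring_rate > 0) {
      b <- calibrate_censor_bound(
        rates = baseline_hazard * c(1, hazard_ratio),
        weights = c(1 - pi2, pi2),
        target_event = 1 - censoring_rate,
        admin = admin_censor_time)
      if (is.finite(b)) c_time <- pmin(runif(n, 0, b), admin_censor_time)
    }
    time <- pmin(t_event, c_time)
    event <- as.integer(t_event <= c_time)
    clinical_table(ids, time, event)
  })
}

# P(T < min(U(0,b), admin)) for T ~ Exp(rate), in closed form.
event_prob_uniform_censor <- function(b, rate, admin) {
  if (!is.finite(b)) return(1 - exp(-rate * admin))
  if (b <= admin) {
    1 - (1 - exp(-rate * b)) / (rate * b)
  } else {
    1 - ((1 - exp(-rate * admin)) / rate + (b - admin) * exp(-rate * admin)) / b
  }
}

# Uniform-censoring upper bound b such that the mixture event probability
# equals target_event; Inf when the administrative cutoff alone already
# censors at least the requested fraction.
calibrate_censor_bound <- function(rates, weights, target_event, admin) {
  pev <- function(b) sum(weights * vapply(rates, function(r)
    event_prob_uniform_censor(b, r, admin), numeric(1)))
  max_ev <- pev(Inf)
  if (max_ev <= target_event) {
    if (max_ev < target_event)
      warnf("administrative cutoff alone censors more than the requested rate; skipping uniform censoring")
    return(Inf)
  }
  uniroot(function(b) pev(b) - target_event,
          lower = 1e-9, upper = 1e9, tol = 1e-10)$root
}

#' Generate a complete synthetic multi-omics survival dataset
#'
#' Composes [make_subgroup_labels()], [simulate_omics_block()] and
#' [simulate_survival()] under stage-specific sub-seeds derived from
#' `config$seed`, recording the planted truth.
#'
#' @param config a [synth_config()].
#' @return A list of class `synthetic_dataset` with elements `omics` (list of
#'   [omics_matrix()]), `clinical` ([clinical_table()]), `true_labels` (named
#'   `"S1"`/`"S2"` vector), `truth` (per-block informative feature ids) and
#'   `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_samples
  labels <- make_subgroup_labels(n, config$subgroup_proportion,
                                 seed = sub_seed(config$seed, "labels"))
  names(labels) <- sprintf("S%04d", seq_len(n))
  omics <- vector("list", length(config$omics_blocks))
  truth <- vector("list", length(config$omics_blocks))
  for (i in seq_along(config$omics_blocks)) {
    b <- config$omics_blocks[[i]]
    om <- simulate_omics_block(labels, b$kind, b$n_features, b$n_informative,
                               b$effect_size,
                               seed = sub_seed(config$seed,
                                               paste0("block_", i, "_", b$kind)),
                               methylation_values = config$methylation_values)
    omics[[i]] <- om
    truth[[i]] <- attr(om, "informative")
  }
  names(omics) <- names(truth) <-
    make.unique(vapply(config$omics_blocks, `[[`, "", "kind"))
  clinical <- simulate_survival(labels, config$baseline_hazard,
                                config$hazard_ratio, config$censoring_rate,
                                config$admin_censor_time,
                                seed = sub_seed(config$seed, "survival"))
  structure(list(omics = omics, clinical = clinical, true_labels = labels,
                 truth = truth, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d samples, %d omics blocks (%s); %d events\n",
              length(x$true_labels), length(x$omics),
              paste(names(x$omics), collapse = ", "),
              sum(x$clinical$event)))
  invisible(x)
}

#' Generate an external single-omics validation cohort
#'
#' Draws a fresh cohort from the same generator family, planting the signal
#' in the *given* informative feature ids so that a signature fitted on a
#' training dataset is applicable (same feature universe, freshly drawn
#' samples). Mirrors the role of the external single-platform validation
#' sets in the study design.
#'
#' @param signature_truth non-empty character vector of informative feature
#'   ids (must belong to the cohort's feature universe).
#' @param kind omics kind of the cohort.
#' @param n_samples cohort size.
#' @param effect_size planted effect in within-group SD units.
#' @param hazard_ratio S2 vs S1 hazard ratio.
#' @param seed integer seed.
#' @param n_features size of the feature universe (canonical ids
#'   `<kind>_f001` ... unless `feature_ids` is given).
#' @param feature_ids optional explicit feature universe.
#' @param proportion,baseline_hazard,censoring_rate,admin_censor_time
#'   cohort-level simulation settings.
#' @param methylation_values `"beta"` or `"mvalue"`.
#' @return A list with elements `block` ([omics_matrix()]), `clinical`
#'   ([clinical_table()]) and `labels` (true subgroup labels).
#' @export
generate_external_cohort <- function(signature_truth, kind, n_samples,
                                     effect_size, hazard_ratio, seed = 1,
                                     n_features = 200, feature_ids = NULL,
                                     proportion = 0.365,
                                     baseline_hazard = 0.2,
                                     censoring_rate = 0.2,
                                     admin_censor_time = 15,
                                     methylation_values = c("beta", "mvalue")) {
  methylation_values <- match.arg(methylation_values)
  if (length(signature_truth) == 0)
    stopf("`signature_truth` must name at least one informative feature")
  if (!kind %in% omics_kinds()) stopf("unsupported omics kind '%s'", kind)
  if (is.null(feature_ids)) feature_ids <- sprintf("%s_f%03d", kind,
                                                   seq_len(n_features))
  inf_idx <- match(signature_truth, feature_ids)
  if (anyNA(inf_idx))
    stopf("%d signature truth ids are outside the cohort's feature universe",
          sum(is.na(inf_idx)))

  labels <- make_subgroup_labels(n_samples, proportion,
                                 seed = sub_seed(seed, "ext_labels"))
  names(labels) <- sprintf("E%04d", seq_len(n_samples))
  # Draw a block with no random informative subset, then plant the shift in
  # exactly the requested columns.
  om <- simulate_omics_block(labels, kind, length(feature_ids),
                             n_informative = 0, effect_size = 0,
                             seed = sub_seed(seed, "ext_block"),
                             methylation_values = "mvalue")
  vals <- om$values
  is_s2 <- labels == "S2"
  if (effect_size != 0) {
    shift <- with_seed(sub_seed(seed, "ext_shift"), {
      for (j in inf_idx) {
        s_pool <- pooled_sd(vals[, j], is_s2)
        vals[is_s2, j] <- vals[is_s2, j] + effect_size * max(s_pool, 1e-8)
      }
      vals
    })
    vals <- shift
  }
  if (kind == "methylation" && methylation_values == "beta")
    vals <- pmin(pmax(plogis(vals), 1e-6), 1 - 1e-6)
  if (kind == "cnv") vals <- pmin(pmax(vals, -2), 2)
  colnames(vals) <- feature_ids
  block <- omics_matrix(vals, kind)
  attr(block, "informative") <- feature_ids[sort(inf_idx)]
  clinical <- simulate_survival(labels, baseline_hazard, hazard_ratio,
                                censoring_rate, admin_censor_time,
                                seed = sub_seed(seed, "ext_survival"))
  list(block = block, clinical = clinical, labels = labels)
}
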