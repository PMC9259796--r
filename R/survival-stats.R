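# Survival statistics implemented from first principles: univariate Cox
# proportional-hazards with Efron tie handling and Wald test, Harrell's
# concordance index, the Kaplan-Meier product-limit estimator, and the
# two-group log-rank test. These are the screening, model-selection and
# validation primitives of the pipeline.

# Precompute the ordering, risk-set boundaries and tied-death groups for a
# covariate/outcome pair so that the Efron partial likelihood can be
# re-evaluated cheaply across Newton iterations.
make_cox_data <- function(x, time, event) {
  ord <- order(time)
  xs <- x[ord]; ts <- time[ord]; es <- event[ord]
  death <- which(es == 1)
  ut <- unique(ts[death])                      # increasing
  s <- match(ut, ts)                           # first index of each risk set
  grp <- match(ts[death], ut)                  # tied-death group per death
  d <- tabulate(grp, nbins = length(ut))
  # expansion over the Efron correction index l = 0 .. d-1 per group
  rep_g <- rep(seq_along(ut), d)
  f <- unlist(lapply(d, function(k) (seq_len(k) - 1) / k))
  list(xs = xs, death = death, s = s, grp = grp, rep_g = rep_g, f = f,
       x_death_sum = sum(xs[death]), n_events = length(death))
}

# Efron-corrected partial log-likelihood, score and observed information.
cox_eval <- function(beta, cd) {
  w <- exp(beta * cd$xs)
  wx <- w * cd$xs
  wxx <- wx * cd$xs
  R0 <- rev(cumsum(rev(w)))[cd$s]
  R1 <- rev(cumsum(rev(wx)))[cd$s]
  R2 <- rev(cumsum(rev(wxx)))[cd$s]
  T0 <- as.numeric(rowsum(w[cd$death], cd$grp))
  T1 <- as.numeric(rowsum(wx[cd$death], cd$grp))
  T2 <- as.numeric(rowsum(wxx[cd$death], cd$grp))
  D0 <- R0[cd$rep_g] - cd$f * T0[cd$rep_g]
  D1 <- R1[cd$rep_g] - cd$f * T1[cd$rep_g]
  D2 <- R2[cd$rep_g] - cd$f * T2[cd$rep_g]
  r <- D1 / D0
  list(loglik = beta * cd$x_death_sum - sum(log(D0)),
       score = cd$x_death_sum - sum(r),
       info = sum(D2 / D0 - r * r))
}

#' Univariate Cox proportional-hazards fit with Wald test
#'
#' Maximizes the Efron-tie-corrected partial likelihood for a single
#' covariate by safeguarded Newton iterations (step-halving; tolerance 1e-8,
#' at most 50 iterations). The standard error comes from the observed
#' information at the optimum and the p-value from the two-sided normal tail
#' of `beta / se` (Wald test).
#'
#' @param x numeric covariate vector aligned with `clinical` rows; must be
#'   non-constant.
#' @param clinical a [clinical_table()] (or data.frame with `time`,
#'   `event`); at least 2 events required.
#' @param feature_id optional label carried into the result.
#' @return A list of class `cox_feature_result`: `feature_id`, `beta`, `se`,
#'   `wald_z`, `p`, `converged`, `loglik`, `n`, `n_events`. With a monotone
#'   partial likelihood (perfect separation) `beta` is capped at +-20 and
#'   `converged` is `FALSE`.
#' @export
fit_univariate_cox <- function(x, clinical, feature_id = "x") {
  time <- clinical$time; event <- clinical$event
  if (length(x) != length(time)) stopf("covariate and clinical table differ in length")
  if (sd(x) == 0) stopf("degenerate covariate: '%s' is constant", feature_id)
  if (sum(event) < 2) stopf("need at least 2 events to fit")
  cd <- make_cox_data(x, time, event)
  beta <- 0; cap <- 20
  q <- cox_eval(beta, cd)
  converged <- FALSE
  for (iter in seq_len(50)) {
    if (q$info <= 0) break
    step <- q$score / q$info
    # step-halving safeguard
    new_beta <- beta + step
    for (h in seq_len(30)) {
      if (abs(new_beta) <= cap) {
        qn <- cox_eval(new_beta, cd)
        if (is.finite(qn$loglik) && qn$loglik >= q$loglik - 1e-12) break
      }
      step <- step / 2
      new_beta <- beta + step
    }
    if (abs(new_beta) > cap) new_beta <- sign(new_beta) * cap
    qn <- cox_eval(new_beta, cd)
    done <- abs(new_beta - beta) < 1e-8 || abs(qn$score) < 1e-8
    beta <- new_beta; q <- qn
    if (done) { converged <- TRUE; break }
  }
  # a maximizer this far out means a monotone partial likelihood (perfect
  # separation): cap the estimate and flag non-convergence
  if (abs(beta) >= cap - 5) {
    beta <- sign(beta) * cap
    q <- cox_eval(beta, cd)
    converged <- FALSE
  }
  se <- if (q$info > 0) 1 / sqrt(q$info) else NA_real_
  z <- beta / se
  p <- max(2 * pnorm(-abs(z)), 1e-300)
  structure(list(feature_id = feature_id, beta = beta, se = se, wald_z = z,
                 p = p, converged = converged, loglik = q$loglik,
                 n = length(x), n_events = sum(event)),
            class = "cox_feature_result")
}

#' @export
print.cox_feature_result <- function(x, ...) {
  cat(sprintf("Cox-PH [%s]: beta=%.4f se=%.4f z=%.3f p=%.3g%s\n",
              x$feature_id, x$beta, x$se, x$wald_z, x$p,
              if (x$converged) "" else " (non-converged)"))
  invisible(x)
}

#' Harrell's concordance index
#'
#' Fraction of comparable pairs in which the sample with the higher
#' predicted risk fails first. A pair is comparable when the strictly
#' shorter observed time ends in an event; tied risks score 0.5; pairs with
#' tied observed times are not comparable (including two tied events).
#'
#' @param risk numeric risk scores (higher = expected earlier failure).
#' @param clinical a [clinical_table()] aligned with `risk`.
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(risk, clinical) {
  time <- clinical$time; event <- clinical$event
  n <- length(risk)
  if (length(time) != n) stopf("risk and clinical table differ in length")
  earlier <- outer(time, time, "<") & (event == 1)   # [i,j]: i fails first
  n_comp <- sum(earlier)
  if (n_comp == 0) stopf("no comparable pairs; concordance undefined")
  hi <- outer(risk, risk, ">")
  tie <- outer(risk, risk, "==")
  (sum(hi & earlier) + 0.5 * sum(tie & earlier)) / n_comp
}

#' Kaplan-Meier product-limit estimator
#'
#' @param clinical a [clinical_table()].
#' @param mask optional logical/integer subset of rows.
#' @return A data.frame of class `km_curve` with one row per distinct
#'   observed time: `time`, `n_risk`, `n_event`, `survival` (the running
#'   product-limit estimate).
#' @export
km_estimate <- function(clinical, mask = NULL) {
  if (!is.null(mask)) clinical <- clinical[mask, , drop = FALSE]
  if (nrow(clinical) == 0) stopf("empty group: no samples to estimate")
  tt <- sort(unique(clinical$time))
  n_risk <- vapply(tt, function(t) sum(clinical$time >= t), numeric(1))
  n_event <- vapply(tt, function(t)
    sum(clinical$time == t & clinical$event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                       survival = surv),
            class = c("km_curve", "data.frame"))
}

# Step-function evaluation of a KM curve: S(t), right-continuous.
km_surv_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, 1, curve$survival[pmax(idx, 1)])
}

#' Two-group log-rank test
#'
#' Accumulates observed minus expected events for the first group at every
#' distinct event time together with the hypergeometric variance;
#' `chi_square = (sum(O - E))^2 / sum(V)` is referred to a chi-square
#' distribution with 1 df. P-values are floored at 1e-300.
#'
#' @param clinical a [clinical_table()].
#' @param groups two-level label vector aligned with `clinical`.
#' @return List with `chi_square`, `p`, `observed`, `expected` (group-1
#'   totals).
#' @export
logrank_test <- function(clinical, groups) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2) stopf("log-rank requires exactly two non-empty groups")
  if (sum(clinical$event) < 1) stopf("log-rank requires at least one event")
  g1 <- groups == lev[1]
  tt <- sort(unique(clinical$time[clinical$event == 1]))
  O <- E <- V <- 0
  for (t in tt) {
    at <- clinical$time >= t
    n_t <- sum(at); n1 <- sum(at & g1)
    d_t <- sum(clinical$time == t & clinical$event == 1)
    d1 <- sum(clinical$time == t & clinical$event == 1 & g1)
    O <- O + d1
    E <- E + d_t * n1 / n_t
    if (n_t > 1)
      V <- V + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
  }
  chi <- if (V > 0) (O - E)^2 / V else 0
  p <- max(pchisq(chi, df = 1, lower.tail = FALSE), 1e-300)
  list(chi_square = chi, p = p, observed = O, expected = E)
}
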