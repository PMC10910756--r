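#' Cohort summary table by response group
#'
#' Counts and percentages of each categorical covariate level within each
#' response group, with percentages rounded to the nearest whole percent
#' (one decimal place below 10%, e.g. "1 (7.1%)").
#'
#' @param clinical clinical table with `response` plus categorical columns.
#' @param covariates columns to summarize; defaults to every non-reserved
#'   character column plus a derived vital `status` when `event` is present.
#' @return data.frame: covariate, level, group, n, pct (numeric), label.
#' @export
cohort_summary <- function(clinical, covariates = NULL) {
  if (!"response" %in% names(clinical)) stop("response column required")
  if (any(table(clinical$response) == 0) || !nrow(clinical)) {
    stop("empty response group")
  }
  cl <- clinical
  if ("event" %in% names(cl) && !"status" %in% names(cl)) {
    cl$status <- ifelse(cl$event == 1, "Deceased", "Alive")
  }
  reserved <- c("sample_id", "response", "os_days", "event")
  covariates <- covariates %||% setdiff(
    names(cl)[vapply(cl, function(x) is.character(x) || is.factor(x),
                     logical(1))], reserved)
  fmt_pct <- function(p) ifelse(p < 10 & p > 0, sprintf("%.1f", round(p, 1)),
                                sprintf("%d", round(p)))
  res <- list()
  for (cv in covariates) {
    for (g in unique(cl$response)) {
      sub <- cl[cl$response == g, ]
      tab <- table(sub[[cv]])
      for (lv in names(tab)) {
        p <- 100 * tab[[lv]] / nrow(sub)
        res[[length(res) + 1]] <- data.frame(
          covariate = cv, level = lv, group = g, n = tab[[lv]],
          pct = if (p < 10 && p > 0) round(p, 1) else round(p),
          label = sprintf("%d (%s%%)", tab[[lv]], fmt_pct(p)),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, res)
}

#' Response-group t-tests over a feature matrix
#'
#' Shared harness with [differential_abundance()]: Welch t-tests of every
#' feature between responders and non-responders, unadjusted p-values
#' primary, BH q-values alongside. Features missing in more than half the
#' samples are skipped with a log attribute.
#'
#' @param features feature matrix data.frame with `sample_id`.
#' @param clinical clinical table with `sample_id`, `response`.
#' @param eps pseudofrequency for fold changes.
#' @return data.frame as [differential_abundance()], with a `skipped`
#'   attribute naming dropped features.
#' @export
feature_response_tests <- function(features, clinical, eps = 1e-3) {
  keep <- vapply(features, function(v) mean(is.na(v)) <= 0.5, logical(1))
  skipped <- names(features)[!keep]
  out <- differential_abundance(features[, keep, drop = FALSE], clinical,
                                eps = eps)
  attr(out, "skipped") <- skipped
  out
}

#' Logistic classification of response with in-sample AUC
#'
#' Fits univariate logistic models for each feature and one multivariate
#' model on `subset`, reporting in-sample AUC (the models are deliberately
#' in-sample, hence optimistic; an optional leave-one-out AUC is available).
#' Perfect separation yields AUC 1.0 with a flag rather than a failure.
#'
#' @param features feature matrix data.frame with `sample_id`.
#' @param clinical clinical table (`response` coded R/NR; R is the positive
#'   class).
#' @param subset feature names for the multivariate model; default all.
#' @param loo also compute leave-one-out AUCs.
#' @return data.frame: model, auc, separation flag, (loo_auc).
#' @export
logistic_auc <- function(features, clinical, subset = NULL, loo = FALSE) {
  y <- setNames(clinical$response == "R", clinical$sample_id)[features$sample_id]
  if (sum(y) < 2 || sum(!y) < 2) stop("at least 2 samples per class required")
  feats <- setdiff(names(features), "sample_id")
  subset <- subset %||% feats
  x <- features[, feats, drop = FALSE]
  fit_auc <- function(cols) {
    dat <- data.frame(y = y, x[, cols, drop = FALSE], check.names = TRUE)
    ok <- complete.cases(dat)
    fit <- suppressWarnings(glm(y ~ ., data = dat[ok, ], family = binomial()))
    pred <- predict(fit, type = "response")
    yy <- dat$y[ok]
    sep <- max(pred[!yy]) < min(pred[yy])  # complete separation
    auc <- rank_auc(pred, yy)
    lauc <- NA_real_
    if (loo) {
      d <- dat[ok, ]
      pl <- vapply(seq_len(nrow(d)), function(i) {
        f <- suppressWarnings(glm(y ~ ., data = d[-i, ], family = binomial()))
        predict(f, newdata = d[i, , drop = FALSE], type = "response")
      }, numeric(1))
      lauc <- rank_auc(pl, d$y)
    }
    list(auc = auc, separation = sep, loo_auc = lauc)
  }
  rows <- lapply(feats, function(f) {
    r <- fit_auc(f)
    data.frame(model = f, auc = r$auc, separation = r$separation,
               loo_auc = r$loo_auc, stringsAsFactors = FALSE)
  })
  mv <- fit_auc(subset)
  rows[[length(rows) + 1]] <- data.frame(
    model = "multivariate", auc = mv$auc, separation = mv$separation,
    loo_auc = mv$loo_auc, stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Cox proportional-hazards association of one feature with survival
#'
#' The feature is z-scored so the hazard ratio is per standard deviation;
#' ties are handled by the Efron method.
#'
#' @param feature numeric vector, one value per clinical row.
#' @param clinical clinical table with `os_days`, `event`.
#' @return list: hr, ci (length 2), p (Wald), n, n_events.
#' @export
cox_continuous <- function(feature, clinical) {
  ok <- !is.na(feature) & !is.na(clinical$os_days)
  if (sum(clinical$event[ok]) < 1) stop("no events; survival model undefined")
  # population SD so the per-SD scale is invariant to sample duplication
  x <- feature[ok]
  s <- sqrt(mean((x - mean(x))^2))
  z <- if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  fit <- survival::coxph(
    survival::Surv(clinical$os_days[ok], clinical$event[ok]) ~ z,
    ties = "efron")
  s <- summary(fit)
  list(hr = unname(exp(coef(fit))),
       ci = unname(exp(stats::confint(fit))[1, ]),
       p = unname(s$coefficients[1, "Pr(>|z|)"]),
       n = sum(ok), n_events = sum(clinical$event[ok]))
}

#' Median-cut Kaplan-Meier comparison
#'
#' Splits the cohort at the feature's median (ties assigned to "low"),
#' estimates Kaplan-Meier curves per side and compares them with a log-rank
#' test.
#'
#' @param feature numeric vector, one value per clinical row.
#' @param clinical clinical table with `os_days`, `event`.
#' @return list: group ("low"/"high" per sample), km (a `survfit`),
#'   logrank_p, median (threshold used).
#' @export
km_median_split <- function(feature, clinical) {
  ok <- !is.na(feature)
  med <- median(feature[ok])
  grp <- ifelse(feature[ok] <= med, "low", "high")
  if (length(unique(grp)) < 2 || min(table(grp)) < 2) {
    stop("degenerate median split: ", sum(grp == "low"), " low vs ",
         sum(grp == "high"), " high")
  }
  if (sum(clinical$event[ok]) < 1) stop("no events; survival model undefined")
  surv <- survival::Surv(clinical$os_days[ok], clinical$event[ok])
  km <- survival::survfit(surv ~ grp)
  sd <- survival::survdiff(surv ~ grp)
  list(group = grp, km = km,
       logrank_p = 1 - pchisq(sd$chisq, length(sd$n) - 1),
       median = med)
}

#' Survival screen over a feature matrix
#'
#' Runs [cox_continuous()] and [km_median_split()] for every feature,
#' collecting hazard ratios per SD, Wald and log-rank p-values.
#'
#' @param features feature matrix data.frame with `sample_id`.
#' @param clinical clinical table.
#' @return data.frame: feature, hr, ci_low, ci_high, wald_p, logrank_p.
#' @export
survival_screen <- function(features, clinical) {
  idx <- match(features$sample_id, clinical$sample_id)
  cl <- clinical[idx, , drop = FALSE]
  feats <- setdiff(names(features), "sample_id")
  rows <- lapply(feats, function(f) {
    v <- features[[f]]
    res <- tryCatch(suppressWarnings({
      cx <- cox_continuous(v, cl)
      kp <- tryCatch(km_median_split(v, cl)$logrank_p, error = function(e) NA_real_)
      data.frame(feature = f, hr = cx$hr, ci_low = cx$ci[1],
                 ci_high = cx$ci[2], wald_p = cx$p, logrank_p = kp,
                 stringsAsFactors = FALSE)
    }), error = function(e) NULL)
    res
  })
  do.call(rbind, rows)
}
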