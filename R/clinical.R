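#' Fit a Cox risk model on signature genes
#'
#' Fits a multivariable Cox proportional-hazards model with the signature
#' genes' expression as covariates. The coefficients (and, once chosen, the
#' risk-score threshold) are frozen at training time and applied to test
#' cohorts without re-estimation.
#'
#' @param expr Expression matrix (genes x samples) restricted to, or
#'   containing, the signature genes.
#' @param signature Character vector of signature gene ids.
#' @param surv_months,event Survival outcome aligned with samples.
#' @param training_id Free-text identifier of the training cohort.
#' @return An object of class `risk_model`: `genes`, `beta`, `threshold`
#'   (NA until set), `training_id`, and the underlying `fit`.
#' @export
fit_cox_risk_model <- function(expr, signature, surv_months, event,
                               training_id = "training") {
  missing <- setdiff(signature, rownames(expr))
  if (length(missing)) stop("signature gene(s) absent: ",
                            paste(missing, collapse = ", "))
  if (sum(event) < 1) stop("no events: cannot fit a Cox model")
  x <- t(expr[signature, , drop = FALSE])
  df <- as.data.frame(x)
  names(df) <- make.names(signature)
  df$.time <- surv_months; df$.event <- event
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(df)[seq_along(signature)],
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = df)
  if (any(!is.finite(stats::coef(fit)))) {
    stop("Cox fit failed to converge (non-finite coefficients); ",
         "check collinear or degenerate genes")
  }
  structure(
    list(genes = signature,
         beta = stats::setNames(unname(stats::coef(fit)), signature),
         threshold = NA_real_, training_id = training_id, fit = fit),
    class = "risk_model"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Cox risk model (", length(x$genes), "genes, trained on",
      x$training_id, ")\n")
  print(round(x$beta, 4))
  cat("risk-score threshold:",
      if (is.na(x$threshold)) "not set" else format(x$threshold, digits = 4), "\n")
  invisible(x)
}

#' @export
tidy.risk_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    gene = x$genes,
    beta = unname(x$beta),
    hr = exp(unname(x$beta)),
    se = unname(s[, "se(coef)"]),
    p_value = unname(s[, "Pr(>|z|)"])
  )
}

#' @export
glance.risk_model <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    n = s$n, n_events = s$nevent,
    concordance = unname(s$concordance["C"]),
    threshold = x$threshold, training_id = x$training_id
  )
}

#' Risk scores under a frozen Cox model
#'
#' The risk score is the Cox linear predictor `sum(beta_i * x_i)` over the
#' signature genes, computed with the frozen training coefficients.
#'
#' @param model A [fit_cox_risk_model()] result.
#' @param expr Expression matrix containing the model's genes.
#' @return Named numeric vector of per-sample scores.
#' @export
risk_score <- function(model, expr) {
  stopifnot(inherits(model, "risk_model"))
  missing <- setdiff(model$genes, rownames(expr))
  if (length(missing)) stop("expression lacks model gene(s): ",
                            paste(missing, collapse = ", "))
  as.numeric(model$beta %*% expr[model$genes, , drop = FALSE]) |>
    stats::setNames(colnames(expr))
}

#' Choose a risk-score cutoff on the 3-year ROC curve
#'
#' Dichotomizes the risk score at the threshold giving the best prediction
#' of death within 36 months. Samples censored before 36 months carry no
#' 3-year outcome and are excluded from the ROC construction. The best
#' threshold maximizes the Youden index (sensitivity + specificity - 1)
#' over the observed scores, classifying `score >= threshold` as high risk;
#' ties are resolved toward the lower threshold.
#'
#' @param scores Numeric risk scores.
#' @param surv_months,event Survival outcome.
#' @param horizon_months Outcome horizon (default 36).
#' @return A list of class `roc_cutoff`: `threshold`, `youden`, `auc`,
#'   `n_used`, `stable` (FALSE when the score is uninformative).
#' @export
select_cutoff_3yr_roc <- function(scores, surv_months, event,
                                  horizon_months = 36) {
  usable <- !(event == 0 & surv_months < horizon_months)
  outcome <- as.integer(surv_months <= horizon_months & event == 1)[usable]
  sc <- scores[usable]
  if (length(unique(outcome)) < 2) {
    stop("one 3-year outcome class only: cutoff undefined")
  }
  if (length(unique(sc)) < 2) stop("all risk scores equal: cutoff undefined")
  thr <- sort(unique(sc))
  stats_at <- vapply(thr, function(t) {
    pred <- sc >= t
    sens <- sum(pred & outcome == 1) / sum(outcome == 1)
    spec <- sum(!pred & outcome == 0) / sum(outcome == 0)
    sens + spec - 1
  }, numeric(1))
  best <- which(stats_at >= max(stats_at) - 1e-12)[1]  # ties -> lower threshold
  # Mann-Whitney AUC
  auc <- (mean(rank(sc)[outcome == 1]) - (sum(outcome == 1) + 1) / 2) /
    sum(outcome == 0)
  structure(list(threshold = thr[best], youden = stats_at[best], auc = auc,
                 n_used = sum(usable), stable = stats_at[best] > 0.1),
            class = "roc_cutoff")
}

#' Kaplan-Meier stratification with log-rank test
#'
#' Splits samples into high-risk (`score >= threshold`) and low-risk groups
#' and compares their Kaplan-Meier survival curves with the standard
#' log-rank test.
#'
#' @param scores Numeric risk scores.
#' @param threshold Frozen risk-score cutoff.
#' @param surv_months,event Survival outcome.
#' @return A list of class `km_logrank`: `curves` (tibble of step-function
#'   points per group), `chisq`, `p_value`, `n_high`, `n_low`.
#' @export
km_logrank <- function(scores, threshold, surv_months, event) {
  group <- factor(ifelse(scores >= threshold, "high", "low"),
                  levels = c("low", "high"))
  if (any(table(group) == 0)) stop("empty risk group at this threshold")
  df <- data.frame(time = surv_months, event = event, group = group)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- tibble::tibble(
    group = sub("group=", "", strata),
    time = sf$time, surv = sf$surv,
    n_risk = sf$n.risk, n_event = sf$n.event
  )
  structure(list(curves = curves, chisq = unname(sd$chisq), p_value = p,
                 n_high = sum(group == "high"), n_low = sum(group == "low")),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat("Kaplan-Meier stratification:", x$n_high, "high-risk vs", x$n_low,
      "low-risk; log-rank chisq =", format(x$chisq, digits = 4),
      ", p =", format(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' @export
autoplot.km_logrank <- function(object, ...) {
  # prepend the (0, 1) start so the step curves begin at full survival
  starts <- tibble::tibble(group = unique(object$curves$group),
                           time = 0, surv = 1, n_risk = NA, n_event = NA)
  df <- dplyr::bind_rows(starts, object$curves)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "survival probability",
                  colour = "risk group",
                  subtitle = sprintf("log-rank p = %.2g", object$p_value)) +
    ggplot2::theme_minimal()
}

#' Multivariate Cox analysis with clinical covariates
#'
#' Reports hazard ratios for the dichotomized risk group alongside standard
#' clinicopathological covariates, fitted both without and with the risk
#' group. Covariate coding: gender binary (1 = male), age dichotomized at
#' 60 years, tumor differentiation 3-level (well differentiated as
#' reference), stage 3-level (stage I as reference).
#'
#' @param clinical Data frame with `surv_months`, `event` and the covariate
#'   columns used in `covariates`.
#' @param risk_group Binary vector (1 = high risk), aligned with rows.
#' @param covariates Character vector of clinical column names to adjust
#'   for; factors are used as-is (set reference levels beforehand).
#' @return A list of class `hazard_table` with tibbles `without_risk` and
#'   `with_risk` (`term`, `hr`, `ci_low`, `ci_high`, `p_value`) and a
#'   `flags` field noting collinearity/separation problems.
#' @export
multivariate_cox <- function(clinical, risk_group,
                             covariates = c("gender", "age_gt60", "stage")) {
  stopifnot(nrow(clinical) == length(risk_group))
  df <- as.data.frame(clinical)
  df$.risk_group <- as.integer(risk_group)
  fit_tab <- function(terms) {
    fml <- stats::as.formula(paste("survival::Surv(surv_months, event) ~",
                                   paste(terms, collapse = " + ")))
    fit <- survival::coxph(fml, data = df)
    s <- summary(fit)
    flags <- character(0)
    if (any(!is.finite(stats::coef(fit))) ||
        any(sqrt(diag(fit$var)) > 100)) {
      flags <- "possible separation or collinearity"
    }
    alias <- is.na(stats::coef(fit))
    if (any(alias)) flags <- c(flags, paste("aliased (collinear) term:",
                                            paste(names(stats::coef(fit))[alias],
                                                  collapse = ", ")))
    co <- s$coefficients; ci <- s$conf.int
    list(tab = tibble::tibble(
      term = rownames(co),
      hr = unname(co[, "exp(coef)"]),
      ci_low = unname(ci[, "lower .95"]),
      ci_high = unname(ci[, "upper .95"]),
      p_value = unname(co[, "Pr(>|z|)"])
    ), flags = flags)
  }
  without <- fit_tab(covariates)
  with_rs <- fit_tab(c(covariates, ".risk_group"))
  structure(list(without_risk = without$tab, with_risk = with_rs$tab,
                 flags = unique(c(without$flags, with_rs$flags))),
            class = "hazard_table")
}

#' @export
print.hazard_table <- function(x, ...) {
  cat("Multivariate Cox, without risk score:\n"); print(x$without_risk)
  cat("with risk score:\n"); print(x$with_risk)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Association between risk group and a categorical factor
#'
#' Pearson chi-squared test (without continuity correction) of the
#' contingency between the dichotomized risk group and a categorical
#' variable such as smoking status or smoking cessation.
#'
#' @param risk_group Binary vector (1 = high risk).
#' @param category Categorical vector of equal length.
#' @return Tibble with `chisq`, `df`, `p_value`, `min_expected` (a warning
#'   is raised when an expected count falls below 5).
#' @export
group_association_test <- function(risk_group, category) {
  tab <- table(risk_group, category)
  if (any(dim(tab) < 2) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate contingency margins")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ht$expected < 5)) {
    warning("expected count below 5; chi-squared approximation is doubtful")
  }
  tibble::tibble(chisq = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value,
                 min_expected = min(ht$expected))
}

#' Nearest-neighbour diagnosis from signature expression
#'
#' k-nearest-neighbour classification (Euclidean distance, default k = 1)
#' on per-gene standardized signature expression. Standardization uses the
#' training means and standard deviations, frozen and applied to the test
#' set.
#'
#' @param train_expr,test_expr Expression matrices (genes x samples)
#'   containing the signature genes.
#' @param signature Feature gene ids.
#' @param train_labels Class labels (e.g. cancer 0/1) for training samples.
#' @param k Number of neighbours.
#' @param test_labels Optional true test labels; enables accuracy and the
#'   confusion table.
#' @param standardize Standardize features by training mean/sd (default).
#' @return A list of class `knn_result`: `predictions`, `accuracy` (NA
#'   without test labels), `confusion` (2x2 counts for binary labels).
#' @export
knn_train_predict <- function(train_expr, test_expr, signature, train_labels,
                              k = 1, test_labels = NULL, standardize = TRUE) {
  if (k > ncol(train_expr)) stop("k exceeds the number of training samples")
  missing <- setdiff(signature, intersect(rownames(train_expr),
                                          rownames(test_expr)))
  if (length(missing)) stop("signature gene(s) absent: ",
                            paste(missing, collapse = ", "))
  xtr <- t(train_expr[signature, , drop = FALSE])
  xte <- t(test_expr[signature, , drop = FALSE])
  if (standardize) {
    mu <- colMeans(xtr); sdv <- apply(xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    xtr <- scale(xtr, mu, sdv); xte <- scale(xte, mu, sdv)
  }
  pred <- class::knn(xtr, xte, cl = factor(train_labels), k = k)
  accuracy <- NA_real_; confusion <- NULL
  if (!is.null(test_labels)) {
    accuracy <- mean(as.character(pred) == as.character(test_labels))
    lv <- sort(unique(c(as.character(train_labels), as.character(test_labels))),
               decreasing = TRUE)
    if (length(lv) == 2) {
      confusion <- table(factor(as.character(pred), lv),
                         factor(as.character(test_labels), lv))
    }
  }
  structure(list(predictions = as.character(pred), accuracy = accuracy,
                 confusion = confusion, k = k),
            class = "knn_result")
}

#' Diagnostic odds ratio from a confusion table
#'
#' `OR = a*d / (b*c)` for a 2x2 table `(a, b; c, d)` with a = predicted
#' positive & truly positive. The 95% confidence interval is the Woolf
#' logit interval `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`;
#' the p-value is the two-sided Wald test of log(OR). When any cell is
#' zero the Haldane-Anscombe correction (+0.5 to every cell) is applied
#' and flagged.
#'
#' @param a,b,c,d Cell counts: a = (pred+, true+), b = (pred+, true-),
#'   c = (pred-, true+), d = (pred-, true-). Alternatively pass a 2x2
#'   matrix/table as `a`.
#' @return Tibble with `or`, `ci_low`, `ci_high`, `p_value`, `corrected`.
#' @export
diagnosis_odds_ratio <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a) || is.table(a)) {
    m <- as.matrix(a); b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]; a <- m[1, 1]
  }
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0))
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  lor <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  z <- lor / se
  tibble::tibble(
    or = exp(lor),
    ci_low = exp(lor - 1.96 * se),
    ci_high = exp(lor + 1.96 * se),
    p_value = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
    corrected = corrected
  )
}

#' Serialize a risk model to a plain-text file
#'
#' @param model A `risk_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  lines <- c(
    paste0("# smokenet risk model"),
    paste0("training_id\t", model$training_id),
    paste0("threshold\t", format(model$threshold, digits = 17)),
    paste0(model$genes, "\t", format(unname(model$beta), digits = 17))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a serialized risk model
#'
#' @param path Path written by [write_risk_model()].
#' @return A `risk_model` (without the original `fit` object).
#' @export
read_risk_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  kv <- strsplit(lines, "\t")
  training_id <- kv[[1]][2]
  threshold <- as.numeric(kv[[2]][2])
  genes <- vapply(kv[-(1:2)], `[`, character(1), 1)
  beta <- as.numeric(vapply(kv[-(1:2)], `[`, character(1), 2))
  structure(list(genes = genes, beta = stats::setNames(beta, genes),
                 threshold = threshold, training_id = training_id,
                 fit = NULL),
            class = "risk_model")
}
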