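test_that("the Cox risk model recovers a planted coefficient and freezes it", {
  set.seed(1)
  n <- 300
  x <- rnorm(n)
  haz <- 0.03 * exp(1 * x)
  t_ev <- rexp(n, haz)
  time <- pmin(t_ev, 60); event <- as.integer(t_ev <= 60)
  expr <- rbind(gene1 = x)
  colnames(expr) <- paste0("s", 1:n)
  m <- fit_cox_risk_model(expr, "gene1", time, event)
  expect_gt(m$beta[["gene1"]], 0.7); expect_lt(m$beta[["gene1"]], 1.3)

  # frozen-model contract: serialization round-trips coefficients and
  # threshold unchanged
  m$threshold <- 1.234567
  p <- withr::local_tempfile(fileext = ".txt")
  write_risk_model(m, p)
  m2 <- read_risk_model(p)
  expect_identical(m2$genes, m$genes)
  expect_equal(m2$beta, m$beta)
  expect_equal(m2$threshold, m$threshold)

  # scores are the linear predictor with frozen coefficients
  sc <- risk_score(m2, expr)
  expect_equal(unname(sc), as.numeric(m$beta %*% expr))

  expect_error(fit_cox_risk_model(expr, "gene1", time, rep(0L, n)), "events")
  expect_error(fit_cox_risk_model(expr, "nope", time, event), "absent")
  expect_s3_class(tidy(m), "tbl_df")
  expect_equal(glance(m)$n_events, sum(event))
})

test_that("3-year ROC cutoff maximizes Youden and handles degeneracies", {
  # perfectly separated scores
  time <- c(rep(10, 20), rep(50, 20))
  event <- c(rep(1L, 20), rep(0L, 20))
  scores <- c(rnorm(20, 5, 0.1), rnorm(20, 0, 0.1))
  cut <- select_cutoff_3yr_roc(scores, time, event)
  expect_equal(cut$youden, 1)
  expect_gt(cut$threshold, max(scores[21:40]))
  expect_lte(cut$threshold, min(scores[1:20]))
  expect_equal(cut$auc, 1)

  # censored before 36 months are excluded from the ROC
  time2 <- c(rep(10, 20), rep(50, 20), rep(5, 10))
  event2 <- c(rep(1L, 20), rep(0L, 20), rep(0L, 10))
  scores2 <- c(scores, rnorm(10, 10))   # would wreck the cutoff if counted
  cut2 <- select_cutoff_3yr_roc(scores2, time2, event2)
  expect_equal(cut2$n_used, 40)
  expect_equal(cut2$threshold, cut$threshold)

  # uninformative scores: AUC near one half and flagged unstable
  set.seed(2)
  sc_null <- rnorm(200)
  t_null <- c(rep(10, 100), rep(50, 100))
  e_null <- c(rep(1L, 100), rep(0L, 100))
  cut3 <- select_cutoff_3yr_roc(sc_null, t_null, e_null)
  expect_gt(cut3$auc, 0.35); expect_lt(cut3$auc, 0.65)

  expect_error(select_cutoff_3yr_roc(rep(1, 40), time, event), "equal")
  expect_error(select_cutoff_3yr_roc(scores, rep(50, 40), rep(0L, 40)),
               "class")
})

test_that("the ROC computation agrees with pROC on the same outcome", {
  skip_if_not_installed("pROC")
  set.seed(3)
  outcome_time <- c(rexp(60, 0.05), rexp(60, 0.01))
  event <- rep(1L, 120)
  scores <- c(rnorm(60, 1), rnorm(60, 0))
  cut <- select_cutoff_3yr_roc(scores, outcome_time, event)
  y <- as.integer(outcome_time <= 36)
  r <- pROC::roc(y, scores, quiet = TRUE, direction = "<")
  expect_equal(cut$auc, as.numeric(pROC::auc(r)), tolerance = 1e-9)
  best <- pROC::coords(r, "best", best.method = "youden", transpose = FALSE)
  expect_equal(cut$youden,
               max(best$sensitivity + best$specificity - 1),
               tolerance = 1e-9)
})

test_that("Kaplan-Meier stratification has valid curves and detects effects", {
  set.seed(4)
  n <- 200
  grp_score <- c(rnorm(100, 2), rnorm(100, 0))   # high vs low risk
  haz <- ifelse(grp_score >= 1, 0.03 * 3, 0.03)  # planted HR 3
  t_ev <- rexp(n, haz)
  time <- pmin(t_ev, 60); event <- as.integer(t_ev <= 60)
  km <- km_logrank(grp_score, 1, time, event)
  expect_lt(km$p_value, 0.001)

  # KM curves: start at most 1, non-increasing within group
  for (g in unique(km$curves$group)) {
    sv <- km$curves$surv[km$curves$group == g]
    expect_true(all(diff(sv) <= 1e-12))
    expect_lte(max(sv), 1)
  }
  # label swap leaves the log-rank p unchanged
  km_sw <- km_logrank(-grp_score, -1 + 1e-9, time, event)
  expect_equal(km_sw$p_value, km$p_value, tolerance = 1e-9)
  expect_s3_class(autoplot(km), "ggplot")
  expect_error(km_logrank(grp_score, 100, time, event), "empty")
})

test_that("multivariate Cox covers a planted covariate and flags collinearity", {
  set.seed(5)
  n <- 400
  cl <- tibble::tibble(
    gender = rbinom(n, 1, 0.5),
    age_gt60 = rbinom(n, 1, 0.5),
    stage = factor(sample(c("I", "II", "III"), n, TRUE), c("I", "II", "III")),
    planted = rbinom(n, 1, 0.5)
  )
  haz <- 0.02 * exp(log(2) * cl$planted)
  t_ev <- rexp(n, haz)
  cl$surv_months <- pmin(t_ev, 60); cl$event <- as.integer(t_ev <= 60)
  ht <- multivariate_cox(cl, risk_group = cl$planted,
                         covariates = c("gender", "age_gt60", "stage"))
  row <- ht$with_risk[ht$with_risk$term == ".risk_group", ]
  expect_gt(row$ci_high, 2 * 0.8)
  expect_lt(row$ci_low, 2 * 1.3)
  expect_lt(row$p_value, 0.05)
  expect_equal(nrow(ht$without_risk) + 1, nrow(ht$with_risk))

  cl$dup <- cl$gender   # duplicated covariate
  ht2 <- multivariate_cox(cl, cl$planted,
                          covariates = c("gender", "dup", "stage"))
  expect_true(length(ht2$flags) > 0)
})

test_that("risk-group association uses an uncorrected chi-squared test", {
  rg <- rep(c(1, 0), c(40, 40))
  cat_ <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  res <- group_association_test(rg, cat_)
  expect_equal(res$chisq, 20)                      # N(ad-bc)^2/(r1 r2 c1 c2)
  expect_equal(res$p_value, 7.7e-6, tolerance = 0.01)
  expect_error(group_association_test(rep(1, 10), rbinom(10, 1, 0.5)),
               "degenerate")
  expect_warning(group_association_test(c(1, 1, 0, 0, 1, 0),
                                        c(1, 0, 1, 0, 1, 0)),
                 "expected count")
})

test_that("nearest-neighbour prediction behaves on exact and separated data", {
  tr <- matrix(c(0, 0, 5, 5), 2, 2,
               dimnames = list(c("g1", "g2"), c("a", "b")))
  te <- matrix(c(5, 5), 2, 1, dimnames = list(c("g1", "g2"), "q"))
  res <- knn_train_predict(tr, te, c("g1", "g2"),
                           train_labels = c("neg", "pos"))
  expect_equal(res$predictions, "pos")
  expect_error(knn_train_predict(tr, te, c("g1", "g2"),
                                 train_labels = c("neg", "pos"), k = 5),
               "exceeds")

  set.seed(6)
  n <- 60
  sig <- paste0("g", 1:5)
  mk <- function(shift) {
    m <- matrix(rnorm(5 * n, 0, 0.5), 5, n, dimnames = list(sig, NULL))
    m[, seq_len(n / 2)] <- m[, seq_len(n / 2)] + shift
    m
  }
  lab <- rep(c(1, 0), each = n / 2)
  expr_tr <- mk(3); expr_te <- mk(3)
  res2 <- knn_train_predict(expr_tr, expr_te, sig, lab, test_labels = lab)
  expect_gte(res2$accuracy, 0.95)
  expect_equal(sum(res2$confusion), n)
})

test_that("diagnostic odds ratios match the Woolf construction", {
  flat <- diagnosis_odds_ratio(25, 25, 25, 25)
  expect_equal(flat$or, 1)

  or9 <- diagnosis_odds_ratio(30, 10, 10, 30)
  expect_equal(or9$or, 9)
  expect_equal(or9$ci_low, 3.27, tolerance = 0.01)
  expect_equal(or9$ci_high, 24.76, tolerance = 0.01)
  expect_false(or9$corrected)

  zero <- diagnosis_odds_ratio(10, 0, 5, 20)
  expect_true(zero$corrected)
  expect_true(is.finite(zero$or))

  # reciprocal symmetry: OR(a,b,c,d) * OR(b,a,d,c) = 1
  set.seed(7)
  for (i in 1:10) {
    cells <- rpois(4, 20) + 1
    o1 <- diagnosis_odds_ratio(cells[1], cells[2], cells[3], cells[4])$or
    o2 <- diagnosis_odds_ratio(cells[2], cells[1], cells[4], cells[3])$or
    expect_equal(o1 * o2, 1, tolerance = 1e-12)
  }

  # matrix input takes the standard confusion layout
  m <- matrix(c(30, 10, 10, 30), 2, byrow = TRUE)
  expect_equal(diagnosis_odds_ratio(m)$or, 9)
})
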