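test_that("planted rule states honor the rule exactly at zero violation", {
  for (r in rule_types()) {
    st <- plant_rule_states(r, 1000, violation_rate = 0, seed = 1)
    t <- pair_contingency(st$a, st$b)
    err <- switch(r,
      IMP = t$n10, IMPNOT = t$n11, NOTIMP = t$n00, NOTIMPNOT = t$n01,
      EQV = t$n10 + t$n01, NEQV = t$n11 + t$n00)
    expect_equal(err, 0)
  }
  # the biconditional example: zero violation forces agreement everywhere
  st <- plant_rule_states("EQV", 1000, 0, seed = 1)
  expect_true(all(st$a == st$b))
})

test_that("violations land in the error cells at the configured rate", {
  st <- plant_rule_states("NEQV", 2000, violation_rate = 0.02, seed = 7)
  agree <- mean(st$a == st$b)       # agreement is the error for A<=>!B
  expect_gt(agree, 0.01); expect_lt(agree, 0.03)
})

test_that("antecedent marginals are calibrated near one half", {
  set.seed(31)
  for (r in c("IMP", "EQV", "NOTIMPNOT")) {
    st <- plant_rule_states(r, 500, 0.02, seed = 17)
    expect_gt(mean(st$a), 0.45); expect_lt(mean(st$a), 0.55)
  }
  expect_error(plant_rule_states("XYZ", 10), "arg")
})

test_that("cohort generation is deterministic and validates its config", {
  cfg <- small_config(seed = 3)
  c1 <- generate_expression_cohort(cfg, "train")
  c2 <- generate_expression_cohort(cfg, "train")
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$states, c2$states)

  expect_error(generate_expression_cohort(
    cohort_config(n_smokers = 0, n_nonsmokers = 0), "train"), "degenerate")
  expect_error(cohort_config(violation_rate = 0.7))
  expect_error(cohort_config(noise_sd = 0))
})

test_that("train and test cohorts share gene-level structure", {
  cfg <- small_config(seed = 5)
  tr <- generate_expression_cohort(cfg, "train")
  te <- generate_expression_cohort(cfg, "test")
  expect_identical(rownames(tr$expression), rownames(te$expression))
  expect_identical(tr$truth$rules, te$truth$rules)
  expect_false(identical(tr$expression, te$expression))
  # baseline means agree across cohorts (same population stream)
  bg <- grep("^BG", rownames(tr$expression), value = TRUE)
  expect_lt(max(abs(rowMeans(tr$expression[bg, ]) -
                      rowMeans(te$expression[bg, ]))), 0.5)
})

test_that("noiseless planting is exactly recoverable by rule induction", {
  cfg <- cohort_config(n_smokers = 120, n_nonsmokers = 120,
                       n_background_genes = 5, violation_rate = 0,
                       noise_sd = 0.01, off_noise_sd = 0.01, seed = 11)
  co <- generate_expression_cohort(cfg, "train")
  means <- rowMeans(co$expression)
  states <- dichotomize(co$expression, means)
  sm <- co$clinical$smoker == 1
  for (g in co$truth$smoker_signature) {
    planted <- co$truth$rules$rule[co$truth$rules$gene == g]
    for (h in co$truth$hub_genes) {
      sel <- induce_relation(states[g, sm], states[h, sm])
      expect_equal(sel$rule, planted, info = paste(g, h))
      expect_equal(sel$precision, 1)
    }
  }
})

test_that("background gene pairs respect per-rule type-I control", {
  set.seed(41)
  n <- 300; n_pairs <- 400
  hits <- stats::setNames(numeric(6), rule_types())
  for (i in seq_len(n_pairs)) {
    tab <- pair_contingency(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
    for (r in rule_types()) {
      s <- rule_statistics(tab, r)
      if (s$testable && !is.na(s$p_precision) && s$p_precision < 0.05 &&
          s$precision > 0) hits[r] <- hits[r] + 1
    }
  }
  expect_true(all(hits / n_pairs <= 0.09))   # looser small-sample bound
})

test_that("survival generation links hazard to the planted risk", {
  cfg <- small_config(seed = 13)
  co <- generate_expression_cohort(cfg, "train")
  # HR recovery at the planted effect size (single fit, asymptotic check)
  surv <- generate_survival(co$states, co$truth,
                            survival_params(log_hr_per_risk_unit = log(3)),
                            groups = co$clinical$smoker, seed = 21)
  fit <- survival::coxph(survival::Surv(surv$surv_months, surv$event) ~ surv$risk)
  expect_gt(exp(coef(fit)), 2.0); expect_lt(exp(coef(fit)), 4.5)

  # null effect: stratifying by risk shows no survival difference
  surv0 <- generate_survival(co$states, co$truth,
                             survival_params(log_hr_per_risk_unit = 0),
                             groups = co$clinical$smoker, seed = 22)
  grp <- as.integer(surv0$risk > 0.5)
  sd0 <- survival::survdiff(
    survival::Surv(surv0$surv_months, surv0$event) ~ grp)
  expect_gt(stats::pchisq(sd0$chisq, 1, lower.tail = FALSE), 0.001)

  # full dropout: everything censored, downstream Cox screen refuses
  surv1 <- generate_survival(co$states, co$truth,
                             survival_params(censoring_rate = 1), seed = 23)
  expect_true(all(surv1$event == 0L))
  expect_error(cox_screen(co$expression, surv1$surv_months, surv1$event),
               "events")
  expect_error(survival_params(baseline_hazard = -1))
})

test_that("diagnosis cohorts separate classes according to the shift", {
  cfg0 <- cohort_config(n_smokers = 50, n_nonsmokers = 50,
                        n_background_genes = 30, effect_size_delta = 0,
                        seed = 7)
  d0 <- generate_diagnosis_cohort(cfg0)
  sig <- paste0("SMK", 1:6)
  half <- c(1:25, 51:75)   # stratified split: cases and controls in both
  knn0 <- knn_train_predict(d0$expression[, half], d0$expression[, -half],
                            sig, d0$labels$cancer[half],
                            test_labels = d0$labels$cancer[-half])
  expect_gt(knn0$accuracy, 0.3); expect_lt(knn0$accuracy, 0.7)

  cfg3 <- cohort_config(n_smokers = 50, n_nonsmokers = 50,
                        n_background_genes = 30, effect_size_delta = 3,
                        seed = 7)
  d3 <- generate_diagnosis_cohort(cfg3)
  knn3 <- knn_train_predict(d3$expression[, half], d3$expression[, -half],
                            sig, d3$labels$cancer[half],
                            test_labels = d3$labels$cancer[-half])
  expect_gte(knn3$accuracy, 0.95)

  # determinism of labels and expression
  d3b <- generate_diagnosis_cohort(cfg3)
  expect_identical(d3$labels, d3b$labels)
  expect_identical(d3$expression, d3b$expression)
})

test_that("truth annotations cover planted pairs and calibrate decoys", {
  cfg <- small_config(seed = 9)
  co <- generate_expression_cohort(cfg, "train")
  bg <- grep("^BG", rownames(co$expression), value = TRUE)
  ann <- generate_truth_annotations(co$truth, bg, n_decoy_sets = 40,
                                    decoy_sharing_rate = 0.1, seed = 2)
  # every planted (signature, hub) pair shares the planted pathway
  pairs <- expand.grid(gene_a = co$truth$smoker_signature,
                       gene_b = co$truth$hub_genes,
                       stringsAsFactors = FALSE)
  labs <- label_edges(pairs, ann)
  expect_true(all(labs$label == "TP"))

  # decoy sharing: FP rate of random annotated background pairs ~ 1 - rho
  annotated_bg <- intersect(bg, ann$universe)
  set.seed(77)
  rp <- t(replicate(400, sample(annotated_bg, 2)))
  labs_bg <- label_edges(tibble::tibble(gene_a = rp[, 1], gene_b = rp[, 2]), ann)
  fp_rate <- mean(labs_bg$label == "FP")
  expect_gt(fp_rate, 0.82); expect_lt(fp_rate, 0.97)

  # fully unannotated universe: everything is non-discriminatory
  ann_nd <- generate_truth_annotations(co$truth, bg, n_decoy_sets = 5,
                                       unannotated_fraction = 1, seed = 3)
  labs_nd <- label_edges(pairs, ann_nd)
  expect_true(all(labs_nd$label == "ND"))
})
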