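#' Pipeline configuration
#'
#' Collects every input and tuning knob of the end-to-end analysis. Cohorts
#' are given either as `synthetic_cohort` objects (see
#' [generate_expression_cohort()]), as lists with `expression` and
#' `clinical`, or as file paths (`expression` TSV/GCT plus `clinical` TSV).
#' Training and test cohorts must not share samples.
#'
#' @param train,test Training and test cohorts.
#' @param hubs Character vector of hub (signaling pathway) gene ids.
#' @param annotations Optional [annotation_collection()] (or GMT path) for
#'   network evaluation.
#' @param diagnosis Optional diagnosis cohort: list with `expression` and
#'   `labels` (`sample_id`, `cancer`), plus optional `split` fractions.
#' @param alpha Significance level used for screens and networks.
#' @param n_perm Permutations for the FDR stage.
#' @param n_stability Iterations for the stability stage.
#' @param subset_fraction Training fraction for the stability stage.
#' @param normalize Quantile-normalize expression before analysis.
#' @param seed Master seed for all randomized stages.
#' @param out_dir Optional output directory; when set, every stage result
#'   is serialized there together with a run manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(train, test, hubs, annotations = NULL,
                            diagnosis = NULL, alpha = 0.05, n_perm = 200,
                            n_stability = 20, subset_fraction = 0.8,
                            normalize = FALSE, seed = 1L, out_dir = NULL) {
  structure(
    list(train = train, test = test, hubs = hubs, annotations = annotations,
         diagnosis = diagnosis, alpha = alpha, n_perm = n_perm,
         n_stability = n_stability, subset_fraction = subset_fraction,
         normalize = normalize, seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

.load_cohort <- function(x, role) {
  if (inherits(x, "synthetic_cohort")) {
    return(list(expression = x$expression, clinical = x$clinical))
  }
  if (is.list(x) && !is.null(x$expression) && !is.null(x$clinical)) {
    expr <- x$expression; clin <- x$clinical
    if (is.character(expr)) expr <- read_expression_matrix(expr)
    if (is.character(clin)) clin <- read_clinical_table(clin)
    return(list(expression = expr, clinical = clin))
  }
  stop("cannot interpret the ", role, " cohort input")
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes the whole flow on a training and a test cohort: survival and
#' smoking screens, per-group implication networks over the candidate
#' genes, differential components, cross-cohort validation with frozen
#' training means, all-hub signature selection, optional network
#' evaluation (precision/FDR/stability against annotations), prognostic
#' modelling (Cox risk score, 3-year ROC cutoff, Kaplan-Meier/log-rank,
#' multivariate Cox, smoking association) and optional nearest-neighbour
#' diagnosis. Samples with missing smoking status are excluded from the
#' screens and networks (their count is logged in the manifest).
#'
#' @param config A [pipeline_config()].
#' @return A list of class `smokenet_run` with per-stage results and a
#'   `manifest` (stage log, counts, package version, configuration echo).
#'   When `config$out_dir` is set all stage outputs are also written there.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log_ <- list()
  note <- function(stage, ...) {
    log_[[stage]] <<- paste(..., collapse = " ")
  }

  train <- .load_cohort(config$train, "train")
  test <- .load_cohort(config$test, "test")
  overlap <- intersect(train$clinical$sample_id, test$clinical$sample_id)
  if (length(overlap)) stop("training and test cohorts share sample(s): ",
                            paste(utils::head(overlap, 5), collapse = ", "))
  absent <- setdiff(config$hubs, rownames(train$expression))
  if (length(absent)) stop("hub gene(s) absent from expression matrix: ",
                           paste(absent, collapse = ", "))

  keep_tr <- !is.na(train$clinical$smoker)
  keep_te <- !is.na(test$clinical$smoker)
  note("smoking_status", sum(!keep_tr), "train and", sum(!keep_te),
       "test samples dropped for missing smoking status")
  tr_expr <- train$expression[, keep_tr, drop = FALSE]
  tr_clin <- train$clinical[keep_tr, , drop = FALSE]
  te_expr <- test$expression[, keep_te, drop = FALSE]
  te_clin <- test$clinical[keep_te, , drop = FALSE]
  if (config$normalize) {
    tr_expr <- quantile_normalize(tr_expr)
    te_expr <- quantile_normalize(te_expr)
  }

  # --- screening (fixed order: survival screen, then smoking screen) ---
  surv_screen <- cox_screen(tr_expr, tr_clin$surv_months, tr_clin$event,
                            alpha = config$alpha)
  survivors <- surv_screen$gene_id[surv_screen$pass]
  smoke_screen <- ttest_screen(tr_expr[survivors, , drop = FALSE],
                               tr_clin$smoker, alpha = config$alpha)
  candidates <- assemble_candidates(surv_screen, smoke_screen, config$hubs,
                                    universe = rownames(tr_expr))
  note("screening", length(survivors), "survival-associated genes;",
       sum(smoke_screen$pass), "also smoking-associated;",
       length(candidates$candidates), "candidates incl.",
       length(config$hubs), "hubs")

  # --- per-group networks on frozen training means ---
  cand <- candidates$candidates
  training_means <- rowMeans(tr_expr[cand, , drop = FALSE])
  st_train <- dichotomize(tr_expr[cand, , drop = FALSE], training_means)
  net_smoker <- build_network(t(st_train[, tr_clin$smoker == 1, drop = FALSE]),
                              config$alpha, group = "smoker")
  net_nonsmoker <- build_network(t(st_train[, tr_clin$smoker == 0, drop = FALSE]),
                                 config$alpha, group = "nonsmoker")
  diff <- differential_edges(net_smoker, net_nonsmoker)
  validated <- validate_edges(diff, te_expr, te_clin$smoker, training_means,
                              alpha = config$alpha)
  note("networks", nrow(net_smoker$edges), "smoker edges;",
       nrow(net_nonsmoker$edges), "non-smoker edges;",
       sum(diff$edges$status == "smoker_specific"), "+",
       sum(diff$edges$status == "nonsmoker_specific"),
       "group-specific differential;", nrow(validated$edges), "validated")

  signature <- select_signature(validated, config$hubs)
  sig_genes <- c(signature$smoker_genes, signature$nonsmoker_genes)
  note("signature", length(signature$smoker_genes), "smoker-derived +",
       length(signature$nonsmoker_genes), "non-smoker-derived genes")

  # --- network evaluation ---
  evaluation <- NULL
  if (!is.null(config$annotations)) {
    ann <- config$annotations
    if (is.character(ann)) ann <- annotation_collection(sets = read_gmt(ann))
    labels <- label_edges(validated, ann)
    edge_summary <- summarize_labels(labels)
    fdr <- permutation_fdr(tr_expr[cand, , drop = FALSE], tr_clin$smoker,
                           te_expr[cand, , drop = FALSE], te_clin$smoker,
                           ann, n_perm = config$n_perm, alpha = config$alpha,
                           seed = .substream_seed(config$seed, "fdr"))
    stab <- network_stability(tr_expr[cand, , drop = FALSE], tr_clin$smoker,
                              te_expr[cand, , drop = FALSE], te_clin$smoker,
                              subset_fraction = config$subset_fraction,
                              n_iter = config$n_stability,
                              alpha = config$alpha,
                              seed = .substream_seed(config$seed, "stability"))
    evaluation <- list(labels = labels, summary = edge_summary,
                       fdr = fdr, stability = stab)
    note("evaluation", "precision =",
         format(edge_summary$network_precision, digits = 3),
         "; FDR =", format(fdr$fdr, digits = 3),
         "; stability =", format(stab$stability, digits = 3))
  }

  # --- prognosis ---
  prognosis <- NULL
  if (length(sig_genes) > 0 && sum(tr_clin$event) >= 1) {
    model <- fit_cox_risk_model(tr_expr, sig_genes, tr_clin$surv_months,
                                tr_clin$event)
    sc_train <- risk_score(model, tr_expr)
    cutoff <- select_cutoff_3yr_roc(sc_train, tr_clin$surv_months, tr_clin$event)
    model$threshold <- cutoff$threshold
    sc_test <- risk_score(model, te_expr)
    km_train <- km_logrank(sc_train, model$threshold,
                           tr_clin$surv_months, tr_clin$event)
    km_test <- km_logrank(sc_test, model$threshold,
                          te_clin$surv_months, te_clin$event)
    te_cov <- dplyr::mutate(te_clin, age_gt60 = as.integer(.data$age > 60),
                            stage = stats::relevel(factor(.data$stage), "I"))
    mv <- multivariate_cox(te_cov, as.integer(sc_test >= model$threshold))
    assoc <- group_association_test(as.integer(sc_test >= model$threshold),
                                    te_clin$smoker)
    prognosis <- list(model = model, cutoff = cutoff,
                      km_train = km_train, km_test = km_test,
                      multivariate = mv, smoking_association = assoc)
    note("prognosis", "log-rank p:", format(km_train$p_value, digits = 3),
         "(train),", format(km_test$p_value, digits = 3), "(test)")
  } else {
    note("prognosis", "skipped (empty signature or no events)")
  }

  # --- diagnosis ---
  diagnosis <- NULL
  if (!is.null(config$diagnosis) && length(sig_genes) > 0) {
    d <- config$diagnosis
    n <- ncol(d$expression)
    split <- if (!is.null(d$split)) d$split else
      .with_substream(config$seed, "diag_split", function() {
        i <- sample(n)
        list(train = i[seq_len(round(0.47 * n))],
             test = i[(round(0.47 * n) + 1):n])
      })
    knn <- knn_train_predict(d$expression[, split$train, drop = FALSE],
                             d$expression[, split$test, drop = FALSE],
                             sig_genes, d$labels$cancer[split$train],
                             test_labels = d$labels$cancer[split$test])
    or <- if (!is.null(knn$confusion)) diagnosis_odds_ratio(knn$confusion)
    diagnosis <- list(knn = knn, odds_ratio = or, split = split)
    note("diagnosis", "1-NN accuracy =", format(knn$accuracy, digits = 3))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("smokenet")),
    seed = config$seed, alpha = config$alpha,
    hubs = config$hubs, stages = log_,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  run <- structure(
    list(screens = list(survival = surv_screen, smoking = smoke_screen),
         candidates = candidates,
         networks = list(smoker = net_smoker, nonsmoker = net_nonsmoker),
         differential = diff, validated = validated, signature = signature,
         evaluation = evaluation, prognosis = prognosis,
         diagnosis = diagnosis, training_means = training_means,
         manifest = manifest),
    class = "smokenet_run"
  )
  if (!is.null(config$out_dir)) .write_run(run, config$out_dir)
  run
}

#' @export
print.smokenet_run <- function(x, ...) {
  cat("smokenet pipeline run\n")
  for (s in names(x$manifest$stages)) {
    cat(sprintf("  %-14s %s\n", s, x$manifest$stages[[s]]))
  }
  invisible(x)
}

# Serialize every stage output as plain text; the manifest gets md5
# checksums of the stage files so a rerun can be verified byte-identically.
.write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  readr::write_tsv(run$screens$survival, p("screen_survival.tsv"))
  readr::write_tsv(run$screens$smoking, p("screen_smoking.tsv"))
  readr::write_tsv(run$candidates$provenance, p("candidates.tsv"))
  write_network_sif(run$networks$smoker, p("network_smoker.sif"))
  write_network_sif(run$networks$nonsmoker, p("network_nonsmoker.sif"))
  readr::write_tsv(run$differential$edges, p("differential_edges.tsv"))
  readr::write_tsv(run$validated$edges, p("validated_edges.tsv"))
  readr::write_tsv(run$signature$justification, p("signature_justification.tsv"))
  sig <- tibble::tibble(
    gene = c(run$signature$smoker_genes, run$signature$nonsmoker_genes),
    group = c(rep("smoker", length(run$signature$smoker_genes)),
              rep("nonsmoker", length(run$signature$nonsmoker_genes))))
  readr::write_tsv(sig, p("signature.tsv"))
  if (!is.null(run$evaluation)) {
    readr::write_tsv(run$evaluation$labels, p("edge_labels.tsv"))
    readr::write_tsv(run$evaluation$summary, p("edge_summary.tsv"))
    readr::write_tsv(tibble::tibble(q_value = run$evaluation$fdr$q_values),
                     p("fdr_qvalues.tsv"))
    readr::write_tsv(tibble::tibble(
      fraction = run$evaluation$stability$per_iteration),
      p("stability_iterations.tsv"))
  }
  if (!is.null(run$prognosis)) {
    write_risk_model(run$prognosis$model, p("risk_model.txt"))
    readr::write_tsv(run$prognosis$km_train$curves, p("km_train.tsv"))
    readr::write_tsv(run$prognosis$km_test$curves, p("km_test.tsv"))
    readr::write_tsv(run$prognosis$multivariate$with_risk,
                     p("multivariate_cox.tsv"))
  }
  if (!is.null(run$diagnosis)) {
    readr::write_tsv(tibble::tibble(prediction = run$diagnosis$knn$predictions),
                     p("diagnosis_predictions.tsv"))
  }
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   p("manifest.json"))
  manifest <- run$manifest
  manifest$files <- lapply(stats::setNames(files, basename(files)),
                           function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}
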