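# Deterministic substreams: every randomized operation draws its seed from
# the master seed plus a named key, so one master seed reproduces the whole
# study while the sub-generators stay independent.
.substream_seed <- function(master, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 1014283
  as.integer((as.numeric(master) %% 1014283) * 2039 + h) %% 2147483647L
}

.with_substream <- function(master, key, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.substream_seed(master, key))
  fn()
}

#' Survival-generator parameters
#'
#' @param baseline_hazard Baseline event rate per month for a patient with
#'   risk 0. The default 0.02 gives a median survival of roughly 35 months
#'   at baseline, in line with resected NSCLC cohorts.
#' @param log_hr_per_risk_unit Log hazard ratio per unit of the planted risk
#'   covariate (the oriented mean planted-gene state, in \[0,1\]). The
#'   default log(4.5) makes full pathway activation comparable to the
#'   hazard contrast of a two-stage difference in NSCLC.
#' @param censoring_horizon Administrative follow-up limit in months.
#' @param censoring_rate Probability that a patient drops out and is
#'   recorded censored at a uniform fraction of their follow-up.
#' @return A list of class `survival_params`.
#' @export
survival_params <- function(baseline_hazard = 0.02,
                            log_hr_per_risk_unit = log(4.5),
                            censoring_horizon = 60,
                            censoring_rate = 0.1) {
  stopifnot(baseline_hazard > 0, censoring_horizon > 0,
            censoring_rate >= 0, censoring_rate <= 1)
  structure(list(baseline_hazard = baseline_hazard,
                 log_hr_per_risk_unit = log_hr_per_risk_unit,
                 censoring_horizon = censoring_horizon,
                 censoring_rate = censoring_rate),
            class = "survival_params")
}

#' Synthetic cohort configuration
#'
#' Defines the statistical structure of a generated smoking cohort: a panel
#' of hub (signaling pathway) genes whose dichotomized states follow a
#' shared latent driver within each smoking group, planted signature genes
#' tied to the hubs by implication rules in one group and silent in the
#' other, and independent background genes. Group sizes default to a
#' balanced 150/150 design for statistical power; `emulate_paper = TRUE`
#' switches to the 149/20 smoker/non-smoker imbalance of the motivating
#' training cohort.
#'
#' @param n_smokers,n_nonsmokers Samples per smoking group.
#' @param n_background_genes Independent decoy genes.
#' @param n_hubs Hub genes (default 6).
#' @param planted_smoker_genes,planted_nonsmoker_genes Signature genes
#'   planted in the smoker / non-smoker group (defaults 6 and 1).
#' @param violation_rate Fraction of samples violating a planted rule.
#' @param effect_size_delta Log2 expression shift of the "up" state.
#' @param noise_sd Log2 noise sd in a gene's active group.
#' @param off_noise_sd Log2 noise sd of a planted gene in the group where it
#'   is silent (smaller: a silenced gene varies less).
#' @param baseline_mean_range Range of per-gene baseline log2 means.
#' @param planted_rules Rule types for the planted smoker genes, recycled;
#'   defaults alternate the two equivalence forms.
#' @param survival A [survival_params()] object.
#' @param seed Master seed; all sub-streams derive from it.
#' @param emulate_paper Use the 149/20 group sizes.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_smokers = 150, n_nonsmokers = 150,
                          n_background_genes = 200, n_hubs = 6,
                          planted_smoker_genes = 6,
                          planted_nonsmoker_genes = 1,
                          violation_rate = 0.02,
                          effect_size_delta = 1.5,
                          noise_sd = 0.5,
                          off_noise_sd = 0.15,
                          baseline_mean_range = c(5, 9),
                          planted_rules = c("EQV", "NEQV"),
                          survival = survival_params(),
                          seed = 1L,
                          emulate_paper = FALSE) {
  if (emulate_paper) { n_smokers <- 149; n_nonsmokers <- 20 }
  stopifnot(
    n_smokers >= 0, n_nonsmokers >= 0, n_background_genes >= 0, n_hubs >= 0,
    planted_smoker_genes >= 0, planted_nonsmoker_genes >= 0,
    violation_rate >= 0, violation_rate < 0.5, noise_sd > 0, off_noise_sd > 0,
    length(baseline_mean_range) == 2
  )
  planted_rules <- match.arg(planted_rules, RULE_TYPES, several.ok = TRUE)
  structure(
    list(n_smokers = n_smokers, n_nonsmokers = n_nonsmokers,
         n_background_genes = n_background_genes, n_hubs = n_hubs,
         planted_smoker_genes = planted_smoker_genes,
         planted_nonsmoker_genes = planted_nonsmoker_genes,
         violation_rate = violation_rate,
         effect_size_delta = effect_size_delta,
         noise_sd = noise_sd, off_noise_sd = off_noise_sd,
         baseline_mean_range = baseline_mean_range,
         planted_rules = planted_rules,
         survival = survival, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Plant a pair of binary state vectors following one implication rule
#'
#' Generates antecedent states as fair coin flips and consequent states so
#' that the rule's error cell(s) receive an expected fraction
#' `violation_rate` of the samples. With `violation_rate = 0` the error
#' cells are exactly empty.
#'
#' @param rule_type One of [rule_types()].
#' @param n Number of samples.
#' @param violation_rate Expected total error-cell mass, in \[0, 0.5).
#' @param seed Integer seed.
#' @return A list with binary vectors `a` and `b` of length `n`.
#' @export
plant_rule_states <- function(rule_type, n, violation_rate = 0, seed = 1L) {
  rule_type <- match.arg(rule_type, RULE_TYPES)
  stopifnot(n >= 1, violation_rate >= 0, violation_rate < 0.5)
  .with_substream(seed, paste0("plant_", rule_type), function() {
    a <- stats::rbinom(n, 1L, 0.5)
    v <- violation_rate
    b <- switch(rule_type,
      EQV  = ifelse(stats::rbinom(n, 1L, v) == 1L, 1L - a, a),
      NEQV = ifelse(stats::rbinom(n, 1L, v) == 1L, a, 1L - a),
      # directional rules: the premise half is forced (up to 2v violations,
      # giving total error mass ~ v); the non-premise half is a fair coin.
      IMP       = ifelse(a == 1L, ifelse(stats::rbinom(n, 1L, 2 * v) == 1L, 0L, 1L),
                         stats::rbinom(n, 1L, 0.5)),
      IMPNOT    = ifelse(a == 1L, ifelse(stats::rbinom(n, 1L, 2 * v) == 1L, 1L, 0L),
                         stats::rbinom(n, 1L, 0.5)),
      NOTIMP    = ifelse(a == 0L, ifelse(stats::rbinom(n, 1L, 2 * v) == 1L, 0L, 1L),
                         stats::rbinom(n, 1L, 0.5)),
      NOTIMPNOT = ifelse(a == 0L, ifelse(stats::rbinom(n, 1L, 2 * v) == 1L, 1L, 0L),
                         stats::rbinom(n, 1L, 0.5))
    )
    list(a = as.integer(a), b = as.integer(b))
  })
}

# Consequent-gene state given the latent group driver, for a planted rule,
# before violations. Z is an independent fair coin that decouples the
# non-premise half of the directional rules.
.state_from_driver <- function(rule_type, d, z) {
  switch(rule_type,
    EQV       = d,
    NEQV      = 1L - d,
    IMP       = d * z,              # gene up forces hub up
    IMPNOT    = (1L - d) * z,       # gene up forces hub down
    NOTIMP    = pmax(1L - d, z),    # gene down forces hub up
    NOTIMPNOT = pmax(d, z)          # gene down forces hub down
  )
}

#' Generate a synthetic smoking cohort
#'
#' Produces a log2-scale expression matrix, a clinical table and the truth
#' record for one cohort under a [cohort_config()]. Gene-level structure
#' (baseline means, planted rule assignments, survival weights) is drawn
#' from a population sub-stream keyed only by the config seed, so cohorts
#' generated with different `cohort` labels (e.g. `"train"`, `"test"`)
#' share genes and differ only in samples — the setting required for
#' frozen-mean dichotomization of a test cohort.
#'
#' Within each smoking group the hub genes follow a shared latent driver
#' state; a signature gene planted in that group follows its assigned rule
#' against the driver (with `violation_rate` flips) and is silent (baseline
#' expression, reduced noise) in the other group. Background genes are
#' mutually independent.
#'
#' @param config A [cohort_config()].
#' @param cohort Cohort label; part of the sample-level random stream.
#' @return A list of class `synthetic_cohort` with `expression` (genes x
#'   samples), `clinical` (tibble: sample_id, smoker, surv_months, event,
#'   stage, age, gender), `states` (true dichotomous states, genes x
#'   samples) and `truth` (see Details).
#' @export
generate_expression_cohort <- function(config, cohort = "train") {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_smokers + config$n_nonsmokers
  n_sig <- config$planted_smoker_genes + config$planted_nonsmoker_genes
  n_genes <- config$n_hubs + n_sig + config$n_background_genes
  if (n < 2 || n_genes < 1) stop("degenerate config: need samples and genes")

  hubs <- if (config$n_hubs > 0) paste0("HUB", seq_len(config$n_hubs)) else character()
  sm_genes <- if (config$planted_smoker_genes > 0)
    paste0("SMK", seq_len(config$planted_smoker_genes)) else character()
  ns_genes <- if (config$planted_nonsmoker_genes > 0)
    paste0("NSM", seq_len(config$planted_nonsmoker_genes)) else character()
  bg <- if (config$n_background_genes > 0)
    paste0("BG", seq_len(config$n_background_genes)) else character()
  genes <- c(hubs, sm_genes, ns_genes, bg)

  # population-level structure: shared across cohorts of the same config
  pop <- .with_substream(config$seed, "population", function() {
    list(
      mu = stats::setNames(stats::runif(n_genes, config$baseline_mean_range[1],
                                        config$baseline_mean_range[2]), genes),
      rules_sm = stats::setNames(
        rep(config$planted_rules, length.out = max(length(sm_genes), 1))[seq_along(sm_genes)],
        sm_genes),
      rules_ns = stats::setNames(
        rep(config$planted_rules, length.out = max(length(ns_genes), 1))[seq_along(ns_genes)],
        ns_genes)
    )
  })

  smoker <- c(rep(1L, config$n_smokers), rep(0L, config$n_nonsmokers))
  sample_id <- sprintf("%s_s%03d", cohort, seq_len(n))

  states <- matrix(0L, nrow = n_genes, ncol = n,
                   dimnames = list(genes, sample_id))
  expr <- matrix(NA_real_, nrow = n_genes, ncol = n,
                 dimnames = list(genes, sample_id))

  .with_substream(config$seed, paste0("samples_", cohort), function() {
    driver <- stats::rbinom(n, 1L, 0.5)   # latent pathway activity per sample
    for (h in hubs) states[h, ] <<- driver
    flip <- function(s) {
      f <- stats::rbinom(n, 1L, config$violation_rate)
      ifelse(f == 1L, 1L - s, s)
    }
    for (g in sm_genes) {
      z <- stats::rbinom(n, 1L, 0.5)
      s <- flip(.state_from_driver(pop$rules_sm[[g]], driver, z))
      s[smoker == 0L] <- 0L             # silent in non-smokers
      states[g, ] <<- s
    }
    for (g in ns_genes) {
      z <- stats::rbinom(n, 1L, 0.5)
      s <- flip(.state_from_driver(pop$rules_ns[[g]], driver, z))
      s[smoker == 1L] <- 0L             # silent in smokers
      states[g, ] <<- s
    }
    for (g in bg) states[g, ] <<- stats::rbinom(n, 1L, 0.5)

    active <- matrix(TRUE, n_genes, n, dimnames = dimnames(expr))
    if (length(sm_genes)) active[sm_genes, smoker == 0L] <- FALSE
    if (length(ns_genes)) active[ns_genes, smoker == 1L] <- FALSE
    sds <- ifelse(active, config$noise_sd, config$off_noise_sd)
    noise <- matrix(stats::rnorm(n_genes * n, 0, 1), n_genes, n) * sds
    expr <<- pop$mu[genes] + config$effect_size_delta * states + noise
    dimnames(expr) <<- dimnames(states)

    NULL
  })

  sig_genes <- c(sm_genes, ns_genes)
  all_rules <- c(unname(pop$rules_sm[sm_genes]), unname(pop$rules_ns[ns_genes]))
  # survival effect follows each gene's orientation to the latent driver, so
  # that oppositely-planted genes do not cancel in the risk covariate
  rule_sign <- c(EQV = 1, IMP = 1, NOTIMPNOT = 1,
                 NEQV = -1, IMPNOT = -1, NOTIMP = -1)
  truth <- list(
    hub_genes = hubs,
    smoker_signature = sm_genes,
    nonsmoker_signature = ns_genes,
    rules = tibble::tibble(
      gene = c(sm_genes, ns_genes),
      group = c(rep("smoker", length(sm_genes)), rep("nonsmoker", length(ns_genes))),
      rule = all_rules
    ),
    survival_weight = stats::setNames(unname(rule_sign[all_rules]), sig_genes),
    gene_group = stats::setNames(
      c(rep("smoker", length(sm_genes)), rep("nonsmoker", length(ns_genes))),
      sig_genes)
  )

  surv <- generate_survival(states, truth, config$survival, groups = smoker,
                            seed = .substream_seed(config$seed, paste0("surv_", cohort)))

  clinical <- .with_substream(config$seed, paste0("clinical_", cohort), function() {
    tibble::tibble(
      sample_id = sample_id,
      smoker = smoker,
      surv_months = surv$surv_months,
      event = surv$event,
      stage = sample(c("I", "II", "III"), n, replace = TRUE,
                     prob = c(0.6, 0.22, 0.18)),
      age = round(stats::rnorm(n, 65, 10)),
      gender = stats::rbinom(n, 1L, 0.5)
    )
  })

  structure(list(expression = expr, clinical = clinical, states = states,
                 truth = truth, config = config, cohort = cohort),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic smoking cohort '", x$cohort, "': ",
      nrow(x$expression), " genes x ", ncol(x$expression), " samples (",
      sum(x$clinical$smoker), " smokers / ",
      sum(1 - x$clinical$smoker), " non-smokers)\n", sep = "")
  invisible(x)
}

#' Generate survival outcomes from planted gene states
#'
#' Event times are exponential with per-sample hazard
#' `baseline_hazard * exp(log_hr_per_risk_unit * risk)`. The risk covariate
#' is the mean oriented state of the planted survival genes: a gene with
#' positive survival weight contributes its state, a negatively weighted
#' gene (planted in opposition to the pathway driver) contributes
#' `1 - state`. When smoking groups are supplied, only the genes planted in
#' a sample's own group contribute (the pathway is inactive elsewhere); a
#' sample with no active planted gene sits at the neutral risk 0.5.
#' Follow-up is cut at the administrative horizon; a fraction
#' `censoring_rate` of samples is additionally withdrawn early and recorded
#' censored at a uniform fraction of their follow-up.
#'
#' @param states True 0/1 state matrix (genes x samples); must contain every
#'   gene named in `truth$survival_weight`.
#' @param truth Truth record, as produced by [generate_expression_cohort()]
#'   (at minimum `survival_weight`; optionally `gene_group`).
#' @param params A [survival_params()].
#' @param groups Optional binary smoking labels (1 = smoker) per sample.
#' @param seed Integer seed.
#' @return Tibble with `surv_months`, `event` and the latent `risk`.
#' @export
generate_survival <- function(states, truth, params, groups = NULL,
                              seed = 1L) {
  stopifnot(inherits(params, "survival_params"))
  if (params$baseline_hazard <= 0) stop("nonpositive baseline hazard")
  w <- truth$survival_weight
  n <- ncol(states)
  risk <- if (length(w) == 0) rep(0, n) else {
    missing <- setdiff(names(w), rownames(states))
    if (length(missing)) stop("states lack survival genes: ",
                              paste(missing, collapse = ", "))
    oriented <- states[names(w), , drop = FALSE]
    neg <- w < 0
    oriented[neg, ] <- 1L - oriented[neg, , drop = FALSE]
    if (is.null(groups) || is.null(truth$gene_group)) {
      colMeans(oriented)
    } else {
      grp <- ifelse(groups == 1L, "smoker", "nonsmoker")
      active <- outer(truth$gene_group[names(w)], grp, "==")
      n_active <- colSums(active)
      r <- colSums(oriented * active) / pmax(n_active, 1)
      r[n_active == 0] <- 0.5
      r
    }
  }
  .with_substream(seed, "survival", function() {
    hz <- params$baseline_hazard * exp(params$log_hr_per_risk_unit * risk)
    t_event <- stats::rexp(n, rate = hz)
    time <- pmin(t_event, params$censoring_horizon)
    event <- as.integer(t_event <= params$censoring_horizon)
    drop <- stats::rbinom(n, 1L, params$censoring_rate) == 1L
    time[drop] <- stats::runif(sum(drop)) * time[drop]
    event[drop] <- 0L
    tibble::tibble(surv_months = time, event = event, risk = risk)
  })
}

#' Generate a cancer/normal diagnosis cohort
#'
#' Emulates an airway-epithelium screening cohort: the planted signature
#' genes are mean-shifted by `effect_size_delta` in cancer samples; all
#' other genes are unshifted. Sample counts reuse the config's group sizes
#' (`n_smokers` cancer cases, `n_nonsmokers` normals).
#'
#' @param config A [cohort_config()].
#' @param cohort Cohort label (sample-level random stream key).
#' @return A list with `expression` (genes x samples) and `labels` (tibble:
#'   `sample_id`, `cancer` 0/1).
#' @export
generate_diagnosis_cohort <- function(config, cohort = "diagnosis") {
  stopifnot(inherits(config, "cohort_config"))
  n_cancer <- config$n_smokers; n_normal <- config$n_nonsmokers
  n <- n_cancer + n_normal
  if (n < 1) stop("degenerate config: no samples")
  base <- generate_expression_cohort(config, cohort = "train")
  genes <- rownames(base$expression)
  sig <- c(base$truth$smoker_signature, base$truth$nonsmoker_signature)
  mu <- .with_substream(config$seed, "population", function() {
    stats::runif(length(genes), config$baseline_mean_range[1],
                 config$baseline_mean_range[2])
  })
  names(mu) <- genes
  cancer <- c(rep(1L, n_cancer), rep(0L, n_normal))
  sample_id <- sprintf("%s_s%03d", cohort, seq_len(n))
  expr <- .with_substream(config$seed, paste0("diag_", cohort), function() {
    e <- matrix(stats::rnorm(length(genes) * n, 0, config$noise_sd),
                length(genes), n, dimnames = list(genes, sample_id))
    e <- e + mu[genes]
    e[sig, cancer == 1L] <- e[sig, cancer == 1L] + config$effect_size_delta
    e
  })
  list(expression = expr,
       labels = tibble::tibble(sample_id = sample_id, cancer = cancer))
}

#' Generate truth annotations for network evaluation
#'
#' Builds a gene-set collection in which every planted (signature, hub) pair
#' shares a set (a "planted pathway" containing the hubs and signature
#' genes), plus decoy sets of random background genes calibrated so that two
#' annotated background genes share at least one set with probability
#' `decoy_sharing_rate`. A fraction of the gene universe can be left
#' unannotated to exercise non-discriminatory (ND) edge labels.
#'
#' @param truth Truth record from [generate_expression_cohort()].
#' @param background_genes Character vector of background gene ids.
#' @param n_decoy_sets Number of decoy sets.
#' @param decoy_sharing_rate Target probability that two annotated
#'   background genes share a set.
#' @param unannotated_fraction Fraction of all genes removed from every set.
#' @param seed Integer seed.
#' @return An [annotation_collection()].
#' @export
generate_truth_annotations <- function(truth, background_genes,
                                       n_decoy_sets = 50,
                                       decoy_sharing_rate = 0.1,
                                       unannotated_fraction = 0,
                                       seed = 1L) {
  planted <- c(truth$hub_genes, truth$smoker_signature, truth$nonsmoker_signature)
  if (length(planted) == 0) stop("empty truth record")
  stopifnot(decoy_sharing_rate >= 0, decoy_sharing_rate < 1,
            unannotated_fraction >= 0, unannotated_fraction <= 1)
  .with_substream(seed, "annotations", function() {
    sets <- list(PLANTED_PATHWAY = planted)
    if (n_decoy_sets > 0 && length(background_genes) > 0) {
      # membership prob p per set s.t. P(share >= 1 set) = rate
      p <- sqrt(1 - (1 - decoy_sharing_rate)^(1 / n_decoy_sets))
      for (i in seq_len(n_decoy_sets)) {
        members <- background_genes[stats::rbinom(length(background_genes), 1, p) == 1L]
        sets[[sprintf("DECOY_%03d", i)]] <- members
      }
    }
    if (unannotated_fraction > 0) {
      universe <- unique(unlist(sets))
      drop <- universe[stats::runif(length(universe)) < unannotated_fraction]
      sets <- lapply(sets, function(s) setdiff(s, drop))
    }
    sets <- sets[vapply(sets, length, 1L) > 0]
    annotation_collection(sets = sets)
  })
}
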