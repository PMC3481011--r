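#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the identical distribution: the mean of
#' the per-sample order statistics. Ranks within each column are preserved;
#' ties receive the mean of their tied order statistics. Thin wrapper around
#' `limma::normalizeQuantiles()`. Idempotent.
#'
#' @param expr Numeric matrix, genes x samples, no missing values (drop or
#'   impute by gene median beforehand).
#' @return Normalized matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(expr) {
  stopifnot(is.matrix(expr))
  if (anyNA(expr)) stop("missing values: drop or impute before normalizing")
  if (ncol(expr) < 2) {
    warning("single-column input returned unchanged")
    return(expr)
  }
  out <- limma::normalizeQuantiles(expr, ties = TRUE)
  dimnames(out) <- dimnames(expr)
  out
}

#' Univariate Cox survival screen
#'
#' Fits one univariate Cox proportional-hazards model per gene, with the
#' gene's continuous expression as the only covariate, and flags genes with
#' a Wald p-value below `alpha`. No multiple-testing correction is applied
#' (optional Benjamini-Hochberg adjustment via `adjust`). Genes with
#' constant expression are non-testable and excluded from the significant
#' set.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param surv_months,event Survival time (months) and event indicator,
#'   aligned with the columns of `expr`.
#' @param alpha Significance level.
#' @param adjust If `TRUE`, flag on BH-adjusted p-values instead (off by
#'   default, matching a raw P<0.05 screen).
#' @return Tibble with `gene_id`, `statistic` (Wald z), `p_value`,
#'   `direction`, `pass`, `testable`.
#' @export
cox_screen <- function(expr, surv_months, event, alpha = 0.05,
                       adjust = FALSE) {
  stopifnot(is.matrix(expr), ncol(expr) == length(surv_months),
            length(surv_months) == length(event))
  if (sum(event) < 2) stop("need at least two events for the Cox screen")
  y <- survival::Surv(surv_months, event)
  res <- purrr::map_dfr(seq_len(nrow(expr)), function(i) {
    x <- expr[i, ]
    if (stats::sd(x) == 0) {
      return(tibble::tibble(gene_id = rownames(expr)[i],
                            statistic = NA_real_, p_value = NA_real_,
                            direction = 0L, testable = FALSE))
    }
    fit <- tryCatch(survival::coxph(y ~ x), error = function(e) NULL,
                    warning = function(w) suppressWarnings(survival::coxph(y ~ x)))
    if (is.null(fit)) {
      return(tibble::tibble(gene_id = rownames(expr)[i],
                            statistic = NA_real_, p_value = NA_real_,
                            direction = 0L, testable = FALSE))
    }
    s <- summary(fit)$coefficients
    tibble::tibble(gene_id = rownames(expr)[i],
                   statistic = unname(s[1, "z"]),
                   p_value = unname(s[1, "Pr(>|z|)"]),
                   direction = as.integer(sign(s[1, "coef"])),
                   testable = TRUE)
  })
  p_use <- if (adjust) stats::p.adjust(res$p_value, "BH") else res$p_value
  res$pass <- res$testable & !is.na(p_use) & p_use < alpha
  res
}

#' Differential-expression screen between smoking groups
#'
#' Two-sided Welch (unequal-variance) t-test per gene between the two
#' levels of a binary group vector. Genes with p below `alpha` are flagged;
#' no multiple-testing correction by default. A gene with zero variance in
#' both groups and equal means is reported with p = 1.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param group Binary vector (1 = smoker), aligned with columns.
#' @inheritParams cox_screen
#' @return Tibble with `gene_id`, `statistic` (Welch t), `p_value`,
#'   `direction`, `pass`.
#' @export
ttest_screen <- function(expr, group, alpha = 0.05, adjust = FALSE) {
  stopifnot(is.matrix(expr), ncol(expr) == length(group))
  g1 <- group == 1; g0 <- group == 0
  if (sum(g1) < 2 || sum(g0) < 2) stop("each group needs at least 2 samples")
  n1 <- sum(g1); n0 <- sum(g0)
  m1 <- rowMeans(expr[, g1, drop = FALSE])
  m0 <- rowMeans(expr[, g0, drop = FALSE])
  v1 <- apply(expr[, g1, drop = FALSE], 1, stats::var)
  v0 <- apply(expr[, g0, drop = FALSE], 1, stats::var)
  se2 <- v1 / n1 + v0 / n0
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v0^2 / (n0^2 * (n0 - 1)))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # zero variance in both groups: identical means convey no evidence
  degenerate <- se2 == 0
  tstat[degenerate] <- 0
  p[degenerate] <- 1
  p_use <- if (adjust) stats::p.adjust(p, "BH") else p
  tibble::tibble(
    gene_id = rownames(expr),
    statistic = unname(tstat), p_value = unname(p),
    direction = as.integer(unname(sign(m1 - m0))),
    pass = unname(!is.na(p_use) & p_use < alpha)
  )
}

#' Assemble the candidate gene set for network analysis
#'
#' Candidates are the genes passing both the survival screen and the
#' smoking screen, plus the hub (signaling pathway) genes, which are
#' included regardless of screen outcome. The screens are applied in a
#' fixed order: survival first on the whole gene set, then the smoking
#' screen on its survivors; provenance flags record the path.
#'
#' @param survival_screen Result of [cox_screen()].
#' @param smoking_screen Result of [ttest_screen()] run on the survival
#'   screen's significant genes.
#' @param hubs Character vector of hub gene ids.
#' @param universe All gene ids available in the expression matrix (used to
#'   verify the hubs exist).
#' @return A list of class `candidate_set`: `candidates`, `hubs`, and a
#'   `provenance` tibble with per-gene flags `survival_pass`,
#'   `smoking_pass`, `is_hub`.
#' @export
assemble_candidates <- function(survival_screen, smoking_screen, hubs,
                                universe = NULL) {
  if (!is.null(universe)) {
    absent <- setdiff(hubs, universe)
    if (length(absent)) stop("hub gene(s) absent from expression matrix: ",
                             paste(absent, collapse = ", "))
  }
  surv_pass <- survival_screen$gene_id[survival_screen$pass]
  smoke_pass <- smoking_screen$gene_id[smoking_screen$pass]
  screened <- intersect(surv_pass, smoke_pass)
  if (length(screened) == 0) {
    warning("no gene passed both screens; candidate set is the hubs only")
  }
  candidates <- union(screened, hubs)
  prov <- tibble::tibble(
    gene_id = candidates,
    survival_pass = candidates %in% surv_pass,
    smoking_pass = candidates %in% smoke_pass,
    is_hub = candidates %in% hubs
  )
  structure(list(candidates = candidates, hubs = hubs, provenance = prov),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate set:", length(x$candidates), "genes (",
      sum(!x$provenance$is_hub), "screened +", length(x$hubs), "hubs )\n")
  invisible(x)
}
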