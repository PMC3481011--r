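#' @importFrom rlang .data
NULL

# The six implication rule types, in tie-break priority order: equivalence
# rules first, then the directional rules in their conventional listing.
# Tokens follow the serialization used in SIF output.
RULE_TYPES <- c("EQV", "NEQV", "IMP", "IMPNOT", "NOTIMP", "NOTIMPNOT")

# Error cells of each rule on a 2x2 table of dichotomized states
# (first index = state of A, second = state of B; 1 = upregulated).
# A rule is violated exactly when a sample falls in one of its error cells.
.rule_error_cells <- list(
  IMP       = rbind(c(1L, 0L)),               # A=>B  : up-A with down-B
  IMPNOT    = rbind(c(1L, 1L)),               # A=>!B : up-A with up-B
  NOTIMP    = rbind(c(0L, 0L)),               # !A=>B : down-A with down-B
  NOTIMPNOT = rbind(c(0L, 1L)),               # !A=>!B: down-A with up-B
  EQV       = rbind(c(1L, 0L), c(0L, 1L)),    # A<=>B : disagreement
  NEQV      = rbind(c(1L, 1L), c(0L, 0L))     # A<=>!B: agreement
)

# Antecedent state for the directional rules (premise A = a or A = !a);
# equivalence rules make a prediction for every sample (scope 1).
.rule_premise_state <- c(
  IMP = 1L, IMPNOT = 1L, NOTIMP = 0L, NOTIMPNOT = 0L, EQV = NA, NEQV = NA
)

#' Implication rule types
#'
#' Returns the six prediction-logic rule tokens understood throughout the
#' package, in the order used for tie-breaking during rule selection
#' (equivalence rules preferred, then the directional rules).
#'
#' @return Character vector of rule tokens: `EQV` (A<=>B), `NEQV` (A<=>!B),
#'   `IMP` (A=>B), `IMPNOT` (A=>!B), `NOTIMP` (!A=>B), `NOTIMPNOT` (!A=>!B).
#' @export
rule_types <- function() RULE_TYPES

#' Dichotomize expression against frozen reference means
#'
#' Converts a genes-by-samples expression matrix into up/down states by
#' comparing each value with that gene's mean in the designated training
#' samples. The reference means are computed once on the training cohort and
#' reused unchanged for any test cohort, so train and test states live on the
#' same scale. A value strictly above the reference mean is "up" (1); a value
#' equal to or below it is "down" (0).
#'
#' @param expr Numeric matrix, genes x samples, log2 scale.
#' @param reference_means Named numeric vector of per-gene training means.
#'   Every gene of `expr` must be present.
#' @return Integer 0/1 matrix of the same shape as `expr`.
#' @export
dichotomize <- function(expr, reference_means) {
  stopifnot(is.matrix(expr))
  missing <- setdiff(rownames(expr), names(reference_means))
  if (length(missing) > 0) {
    stop("no reference mean for gene(s): ", paste(missing, collapse = ", "))
  }
  m <- reference_means[rownames(expr)]
  states <- (expr > m) * 1L
  storage.mode(states) <- "integer"
  states
}

#' Contingency table of an ordered gene pair
#'
#' Tallies the 2x2 joint distribution of two binary state vectors.
#'
#' @param a,b Binary (0/1) vectors of equal length.
#' @return A list of class `contingency_table` with counts `n11`, `n10`,
#'   `n01`, `n00` (first index = state of `a`) and total `n`.
#' @export
pair_contingency <- function(a, b) {
  if (length(a) != length(b)) stop("state vectors differ in length")
  if (length(a) < 1) stop("empty state vectors")
  a <- as.integer(a); b <- as.integer(b)
  out <- list(
    n11 = sum(a == 1L & b == 1L),
    n10 = sum(a == 1L & b == 0L),
    n01 = sum(a == 0L & b == 1L),
    n00 = sum(a == 0L & b == 0L)
  )
  out$n <- out$n11 + out$n10 + out$n01 + out$n00
  structure(out, class = "contingency_table")
}

.as_contingency <- function(t) {
  if (inherits(t, "contingency_table")) return(t)
  if (is.numeric(t) && length(t) == 4) {
    out <- list(n11 = t[[1]], n10 = t[[2]], n01 = t[[3]], n00 = t[[4]])
    out$n <- sum(unlist(out[1:4]))
    return(structure(out, class = "contingency_table"))
  }
  stop("not a contingency table")
}

#' Prediction-logic statistics of one rule on a 2x2 table
#'
#' Computes scope, precision ("del") and the one-sided z-tests for a single
#' implication rule. The observed error rate `V` is the fraction of samples
#' in the rule's error cells; the expected error rate `K` is what the same
#' cells would receive under independence of the two margins; precision is
#' `del = 1 - V/K`, the proportionate reduction in rule error relative to
#' chance. Scope `U` is the fraction of samples the rule's premise covers
#' (1 for the equivalence rules). The precision z-statistic treats the error
#' count as Binomial(N, K) under the independence null:
#' `z = (N*K - N*V) / sqrt(N*K*(1-K))`, with a one-sided upper-tail p-value.
#'
#' The normal approximation is unreliable when the expected error count is
#' tiny, so the test is only applied when `N*K >= min_expected_errors`;
#' otherwise the rule is flagged non-testable (`testable = FALSE`, p = NA).
#'
#' @param t A `contingency_table` (or numeric vector `c(n11,n10,n01,n00)`).
#' @param rule_type One of [rule_types()].
#' @param min_scope Minimum premise coverage tested by the scope z-test.
#'   With the default 0 the scope test is structural: it passes whenever the
#'   premise covers at least one sample.
#' @param min_expected_errors Validity threshold for the precision z-test.
#' @return A one-row tibble with `rule`, `scope`, `precision`, `error_rate`
#'   (V), `expected_error` (K), `z_precision`, `p_precision`, `z_scope`,
#'   `p_scope` and `testable`.
#' @export
rule_statistics <- function(t, rule_type, min_scope = 0,
                            min_expected_errors = 5) {
  t <- .as_contingency(t)
  rule_type <- match.arg(rule_type, RULE_TYPES)
  N <- t$n
  if (N <= 0) stop("empty table")
  counts <- matrix(c(t$n11, t$n10, t$n01, t$n00), 2, 2, byrow = TRUE,
                   dimnames = list(c("1", "0"), c("1", "0")))
  row_marg <- c("1" = t$n11 + t$n10, "0" = t$n01 + t$n00)
  col_marg <- c("1" = t$n11 + t$n01, "0" = t$n10 + t$n00)
  cells <- .rule_error_cells[[rule_type]]
  err <- 0; kexp <- 0
  for (i in seq_len(nrow(cells))) {
    ai <- as.character(cells[i, 1]); bi <- as.character(cells[i, 2])
    err <- err + counts[ai, bi]
    kexp <- kexp + row_marg[[ai]] * col_marg[[bi]] / N^2
  }
  V <- err / N
  K <- kexp

  prem <- .rule_premise_state[[rule_type]]
  U <- if (is.na(prem)) 1 else unname(row_marg[[as.character(prem)]]) / N
  n_prem <- round(U * N)
  if (min_scope <= 0) {
    z_scope <- Inf
    p_scope <- if (n_prem > 0) 0 else 1
  } else {
    z_scope <- (n_prem - N * min_scope) / sqrt(N * min_scope * (1 - min_scope))
    p_scope <- stats::pnorm(z_scope, lower.tail = FALSE)
  }

  testable <- K > 0 && K < 1 && (N * K) >= min_expected_errors
  if (K > 0) {
    precision <- 1 - V / K
  } else {
    precision <- NA_real_
  }
  if (testable) {
    z <- (N * K - N * V) / sqrt(N * K * (1 - K))
    p <- stats::pnorm(z, lower.tail = FALSE)
  } else {
    z <- NA_real_
    p <- NA_real_
  }
  tibble::tibble(
    rule = rule_type, scope = U, precision = precision,
    error_rate = V, expected_error = K,
    z_precision = z, p_precision = p,
    z_scope = z_scope, p_scope = p_scope,
    testable = testable
  )
}

#' Induce the implication relation of one gene pair
#'
#' Evaluates all six rules on the pair's contingency table and keeps those
#' that are significant: precision p-value and scope p-value both below
#' `alpha` and precision strictly positive. Among the keepers the rule with
#' maximal precision is selected; ties are broken in favour of equivalence
#' rules, then by the fixed rule order of [rule_types()].
#'
#' Degenerate vectors (all samples in one state) admit no rule and return
#' `NULL`, as screened expression data can contain near-constant genes.
#'
#' @param a,b Binary state vectors from the same sample set.
#' @inheritParams rule_statistics
#' @param alpha Significance level for both z-tests.
#' @return A one-row tibble (as [rule_statistics()]) for the selected rule,
#'   or `NULL` when no rule qualifies.
#' @export
induce_relation <- function(a, b, alpha = 0.05, min_scope = 0,
                            min_expected_errors = 5) {
  if (length(unique(a)) < 2 || length(unique(b)) < 2) return(NULL)
  t <- pair_contingency(a, b)
  best <- NULL
  for (r in RULE_TYPES) {
    s <- rule_statistics(t, r, min_scope = min_scope,
                         min_expected_errors = min_expected_errors)
    ok <- s$testable && !is.na(s$p_precision) && s$p_precision < alpha &&
      s$p_scope < alpha && s$precision > 0
    if (ok && (is.null(best) || s$precision > best$precision + 1e-12)) {
      best <- s
    }
  }
  best
}

# Vectorized all-pairs rule statistics for one group of samples.
# states: samples x genes 0/1 matrix. Returns a list of per-rule matrices
# (genes x genes): precision, p-value, significance, plus the per-pair
# selected rule index (0 = none) under the max-precision / tie-order policy.
# Degenerate genes (constant state) yield no edges.
.network_engine <- function(states, alpha = 0.05, min_scope = 0,
                            min_expected_errors = 5) {
  n <- nrow(states); g <- ncol(states)
  S <- states
  storage.mode(S) <- "double"
  ones <- colSums(S)
  N11 <- crossprod(S)                 # pairwise co-up counts
  N10 <- outer(ones, rep(1, g)) - N11 # a up, b down
  N01 <- t(N10)
  N00 <- n - N11 - N10 - N01
  R1 <- outer(ones, rep(1, g)); R0 <- n - R1   # row margins of a
  C1 <- t(R1); C0 <- n - C1                    # column margins of b
  degen <- ones == 0 | ones == n

  cell_count <- list("1_1" = N11, "1_0" = N10, "0_1" = N01, "0_0" = N00)
  rmarg <- list("1" = R1, "0" = R0)
  cmarg <- list("1" = C1, "0" = C0)

  best_prec <- matrix(-Inf, g, g)
  best_rule <- matrix(0L, g, g)
  per_rule <- vector("list", length(RULE_TYPES))
  names(per_rule) <- RULE_TYPES
  for (ri in seq_along(RULE_TYPES)) {
    r <- RULE_TYPES[[ri]]
    cells <- .rule_error_cells[[r]]
    E <- matrix(0, g, g); K <- matrix(0, g, g)
    for (i in seq_len(nrow(cells))) {
      key <- paste(cells[i, 1], cells[i, 2], sep = "_")
      E <- E + cell_count[[key]]
      K <- K + rmarg[[as.character(cells[i, 1])]] *
        cmarg[[as.character(cells[i, 2])]] / n^2
    }
    V <- E / n
    testable <- K > 0 & K < 1 & (n * K) >= min_expected_errors
    Kf <- K; Kf[Kf < .Machine$double.eps] <- .Machine$double.eps
    varf <- n * K * (1 - K)
    varf[varf < .Machine$double.eps] <- .Machine$double.eps
    prec <- 1 - V / Kf
    z <- (n * K - n * V) / sqrt(varf)
    p <- stats::pnorm(z, lower.tail = FALSE)
    dimnames(prec) <- dimnames(z) <- dimnames(p) <- NULL
    dimnames(V) <- dimnames(K) <- NULL

    prem <- .rule_premise_state[[r]]
    if (is.na(prem)) {
      scope <- matrix(1, g, g)
      p_scope_ok <- matrix(TRUE, g, g)
    } else {
      nprem <- if (prem == 1L) R1 else R0
      scope <- nprem / n
      if (min_scope <= 0) {
        p_scope_ok <- nprem > 0
      } else {
        zs <- (nprem - n * min_scope) / sqrt(n * min_scope * (1 - min_scope))
        p_scope_ok <- stats::pnorm(zs, lower.tail = FALSE) < alpha
      }
    }
    sig <- testable & !is.na(p) & p < alpha & p_scope_ok & prec > 0
    sig[degen, ] <- FALSE; sig[, degen] <- FALSE
    per_rule[[r]] <- list(precision = prec, p = p, z = z, V = V, K = K,
                          scope = scope, significant = sig)
    upd <- sig & (prec > best_prec + 1e-12)
    best_prec[upd] <- prec[upd]
    best_rule[upd] <- ri
  }
  list(per_rule = per_rule, best_rule = best_rule, best_prec = best_prec,
       n = n, genes = colnames(states))
}

#' Build a per-group implication coexpression network
#'
#' Runs [induce_relation()] over every unordered gene pair of a binary state
#' matrix and stores the selected significant rule per pair. The computation
#' is vectorized over pairs; for `k` genes exactly `k*(k-1)/2` pairs are
#' evaluated.
#'
#' @param states Binary matrix, samples x genes (dichotomized expression,
#'   see [dichotomize()]; note the transpose relative to expression input).
#' @param alpha Significance level for the rule z-tests.
#' @param group Optional label stored on the network (e.g. "smoker").
#' @inheritParams rule_statistics
#' @return An object of class `implication_network`: a list with `edges`
#'   (tibble: `gene_a`, `gene_b`, `rule`, `scope`, `precision`, `error_rate`,
#'   `expected_error`, `z_precision`, `p_precision`), `genes`, `group`,
#'   `alpha`, `n_samples`.
#' @export
build_network <- function(states, alpha = 0.05, group = NA_character_,
                          min_scope = 0, min_expected_errors = 5) {
  stopifnot(is.matrix(states), ncol(states) >= 2)
  if (is.null(colnames(states))) {
    colnames(states) <- paste0("g", seq_len(ncol(states)))
  }
  eng <- .network_engine(states, alpha, min_scope, min_expected_errors)
  g <- ncol(states)
  idx <- which(upper.tri(matrix(0, g, g)) & eng$best_rule > 0, arr.ind = TRUE)
  dimnames(idx) <- NULL
  edges <- if (nrow(idx) == 0) {
    tibble::tibble(
      gene_a = character(), gene_b = character(), rule = character(),
      scope = numeric(), precision = numeric(), error_rate = numeric(),
      expected_error = numeric(), z_precision = numeric(),
      p_precision = numeric()
    )
  } else {
    ri <- eng$best_rule[idx]
    purrr::map_dfr(seq_len(nrow(idx)), function(k) {
      i <- idx[k, 1]; j <- idx[k, 2]; r <- eng$per_rule[[ri[k]]]
      tibble::tibble(
        gene_a = eng$genes[i], gene_b = eng$genes[j],
        rule = RULE_TYPES[ri[k]],
        scope = r$scope[i, j], precision = r$precision[i, j],
        error_rate = r$V[i, j], expected_error = r$K[i, j],
        z_precision = r$z[i, j], p_precision = r$p[i, j]
      )
    })
  }
  structure(
    list(edges = edges, genes = colnames(states), group = group,
         alpha = alpha, n_samples = nrow(states)),
    class = "implication_network"
  )
}

#' @export
print.implication_network <- function(x, ...) {
  cat("Implication coexpression network",
      if (!is.na(x$group)) paste0("(group: ", x$group, ")"), "\n")
  cat(" ", length(x$genes), "genes,", nrow(x$edges), "edges,",
      x$n_samples, "samples, alpha =", x$alpha, "\n")
  invisible(x)
}

#' @export
tidy.implication_network <- function(x, ...) x$edges

#' Pearson-correlation comparator network
#'
#' Builds a gene association network in which an (undirected) edge is a
#' significant Pearson correlation between two genes' expression profiles.
#' Provided for side-by-side comparison with the implication networks; it
#' carries no rule type, only the correlation sign.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param alpha Significance level of the correlation test.
#' @return Tibble with `gene_a`, `gene_b`, `r`, `p`, `sign`. Pairs involving
#'   a zero-variance gene are skipped (reported via the `skipped` attribute).
#' @export
pearson_network <- function(expr, alpha = 0.05) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3)
  if (is.null(rownames(expr))) rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  sds <- apply(expr, 1, stats::sd)
  keep <- sds > 0
  skipped <- rownames(expr)[!keep]
  x <- expr[keep, , drop = FALSE]
  n <- ncol(x)
  cm <- stats::cor(t(x))
  tt <- cm * sqrt((n - 2) / pmax(1 - cm^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  idx <- which(upper.tri(cm) & p < alpha, arr.ind = TRUE)
  out <- tibble::tibble(
    gene_a = rownames(x)[idx[, 1]],
    gene_b = rownames(x)[idx[, 2]],
    r = cm[idx], p = p[idx],
    sign = ifelse(cm[idx] > 0, "+", "-")
  )
  attr(out, "skipped") <- skipped
  out
}
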