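#' Annotation collection for edge labeling
#'
#' Bundles named gene sets (pathways, positional bands, motif and GO-style
#' sets — all ingested uniformly, e.g. from GMT files) and optional binary
#' interaction pairs. The annotated universe is the union of all genes
#' appearing in any source; membership and interaction lookups are
#' symmetric in the pair.
#'
#' @param sets Named list of character vectors (gene sets).
#' @param interactions Optional two-column data frame of interacting gene
#'   pairs.
#' @return An object of class `annotation_collection`.
#' @export
annotation_collection <- function(sets = list(), interactions = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) > 0 && is.null(names(sets))) stop("gene sets must be named")
  inter <- if (is.null(interactions) || nrow(interactions) == 0) {
    tibble::tibble(gene_a = character(), gene_b = character())
  } else {
    tibble::tibble(gene_a = as.character(interactions[[1]]),
                   gene_b = as.character(interactions[[2]]))
  }
  universe <- unique(c(unlist(sets, use.names = FALSE),
                       inter$gene_a, inter$gene_b))
  structure(list(sets = sets, interactions = inter, universe = universe),
            class = "annotation_collection")
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat("Annotation collection:", length(x$sets), "gene sets,",
      nrow(x$interactions), "interaction pairs,",
      length(x$universe), "annotated genes\n")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-separated GMT file (set name, description,
#'   then member genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-set description column (defaults to the
#'   set name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column interaction pair file
#'
#' @param path Tab-separated file whose first two columns are interacting
#'   gene ids (header optional, detected by a `gene` prefix).
#' @return Tibble with `gene_a`, `gene_b`.
#' @export
read_interaction_pairs <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("^gene", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)[, 1:2]
  tibble::tibble(gene_a = as.character(df[[1]]), gene_b = as.character(df[[2]]))
}

#' Label coexpression edges against annotations
#'
#' An edge is non-discriminatory (`ND`) when either gene is outside the
#' annotated universe; a true positive (`TP`) when the pair shares at least
#' one gene set or has a recorded interaction; otherwise a false positive
#' (`FP`).
#'
#' @param pairs Data frame with `gene_a`, `gene_b` columns (or a
#'   `differential_edges` / `implication_network` object).
#' @param annotations An [annotation_collection()].
#' @return Tibble `gene_a`, `gene_b`, `label`.
#' @export
label_edges <- function(pairs, annotations) {
  stopifnot(inherits(annotations, "annotation_collection"))
  if (inherits(pairs, "differential_edges")) pairs <- pairs$edges
  if (inherits(pairs, "implication_network")) pairs <- pairs$edges
  if (nrow(pairs) == 0) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          label = character()))
  }
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  m <- matrix(FALSE, length(genes), length(annotations$sets),
              dimnames = list(genes, names(annotations$sets)))
  for (j in seq_along(annotations$sets)) {
    m[intersect(genes, annotations$sets[[j]]), j] <- TRUE
  }
  ikey <- c(.pair_key(annotations$interactions$gene_a,
                      annotations$interactions$gene_b))
  in_univ <- genes %in% annotations$universe
  names(in_univ) <- genes
  ia <- match(pairs$gene_a, genes); ib <- match(pairs$gene_b, genes)
  share <- rowSums(m[ia, , drop = FALSE] & m[ib, , drop = FALSE]) > 0
  interact <- .pair_key(pairs$gene_a, pairs$gene_b) %in% ikey
  label <- ifelse(!in_univ[pairs$gene_a] | !in_univ[pairs$gene_b], "ND",
                  ifelse(share | interact, "TP", "FP"))
  tibble::tibble(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                 label = unname(label))
}

#' Summarize edge labels into network precision and q-value
#'
#' Network precision is `TP / (TP + FP)` and the q-value is
#' `FP / (TP + FP)`; non-discriminatory edges are excluded from both
#' ratios. With no labeled (TP or FP) edges the precision is undefined and
#' flagged.
#'
#' @param labels Character vector of labels (or the tibble from
#'   [label_edges()]).
#' @return A one-row tibble: `tp`, `fp`, `nd`, `network_precision`,
#'   `q_value`, `defined`.
#' @export
summarize_labels <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  tp <- sum(labels == "TP"); fp <- sum(labels == "FP"); nd <- sum(labels == "ND")
  defined <- (tp + fp) > 0
  tibble::tibble(
    tp = tp, fp = fp, nd = nd,
    network_precision = if (defined) tp / (tp + fp) else NA_real_,
    q_value = if (defined) fp / (tp + fp) else NA_real_,
    defined = defined
  )
}

# Vectorized differential + cross-cohort validation on state matrices.
# states_*: genes x samples (already dichotomized on frozen training means);
# groups_*: binary, 1 = smoker. Returns tibble(gene_a, gene_b, status, rule)
# of the validated, group-specific edges.
.diff_validated_states <- function(states_train, groups_train,
                                   states_test, groups_test,
                                   alpha = 0.05, min_scope = 0,
                                   min_expected_errors = 5) {
  genes <- rownames(states_train)
  eng <- function(states, grp, val) {
    .network_engine(t(states[, grp == val, drop = FALSE]), alpha,
                    min_scope, min_expected_errors)
  }
  tr_s <- eng(states_train, groups_train, 1L)
  tr_n <- eng(states_train, groups_train, 0L)
  te_s <- eng(states_test, groups_test, 1L)
  te_n <- eng(states_test, groups_test, 0L)

  up <- upper.tri(tr_s$best_rule)
  res <- list()
  for (side in c("smoker", "nonsmoker")) {
    own_tr <- if (side == "smoker") tr_s else tr_n
    oth_tr <- if (side == "smoker") tr_n else tr_s
    own_te <- if (side == "smoker") te_s else te_n
    oth_te <- if (side == "smoker") te_n else te_s
    spec <- up & own_tr$best_rule > 0 & oth_tr$best_rule == 0
    idx <- which(spec, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    ri <- own_tr$best_rule[idx]
    keep <- logical(nrow(idx))
    for (k in seq_len(nrow(idx))) {
      sig_own <- own_te$per_rule[[ri[k]]]$significant[idx[k, 1], idx[k, 2]]
      keep[k] <- sig_own && oth_te$best_rule[idx[k, 1], idx[k, 2]] == 0
    }
    if (any(keep)) {
      res[[side]] <- tibble::tibble(
        gene_a = genes[idx[keep, 1]], gene_b = genes[idx[keep, 2]],
        status = paste0(side, "_specific"),
        rule = RULE_TYPES[ri[keep]]
      )
    }
  }
  if (length(res) == 0) {
    tibble::tibble(gene_a = character(), gene_b = character(),
                   status = character(), rule = character())
  } else {
    dplyr::bind_rows(res)
  }
}

#' Permutation false discovery rate of the differential network
#'
#' Estimates how biologically relevant the validated smoking-specific
#' network is by chance: for each permutation the smoking labels of the
#' test cohort are shuffled, the cross-cohort validated differential edge
#' set is recomputed against the unchanged training networks, the surviving
#' edges are labeled against the annotations and their q-value recorded.
#' The FDR is the mean q-value over permutations; permutations yielding no
#' labeled edge contribute nothing and are counted separately.
#'
#' @param train_expr,test_expr Expression matrices (genes x samples) over
#'   the same gene universe.
#' @param train_groups,test_groups Binary smoking labels (1 = smoker).
#' @param annotations An [annotation_collection()].
#' @param n_perm Number of label permutations.
#' @param alpha Edge significance level.
#' @param seed Integer seed.
#' @inheritParams rule_statistics
#' @return A list of class `permutation_fdr`: `fdr`, `q_values` (per
#'   non-empty permutation), `n_empty`, `n_perm`, and `observed` (the
#'   real-label validated edge summary).
#' @export
permutation_fdr <- function(train_expr, train_groups, test_expr, test_groups,
                            annotations, n_perm = 1000, alpha = 0.05,
                            seed = 1L, min_scope = 0, min_expected_errors = 5) {
  stopifnot(n_perm >= 1)
  genes <- rownames(train_expr)
  means <- rowMeans(train_expr)
  st_train <- dichotomize(train_expr, means)
  st_test <- dichotomize(test_expr[genes, , drop = FALSE], means)

  observed_edges <- .diff_validated_states(st_train, train_groups,
                                           st_test, test_groups,
                                           alpha, min_scope, min_expected_errors)
  observed <- summarize_labels(label_edges(observed_edges, annotations))

  qs <- numeric(0); n_empty <- 0L
  .with_substream(seed, "permutation_fdr", function() {
    for (b in seq_len(n_perm)) {
      perm <- sample(test_groups)
      edges <- .diff_validated_states(st_train, train_groups,
                                      st_test, perm,
                                      alpha, min_scope, min_expected_errors)
      if (nrow(edges) == 0) { n_empty <<- n_empty + 1L; next }
      s <- summarize_labels(label_edges(edges, annotations))
      if (!s$defined) { n_empty <<- n_empty + 1L; next }
      qs <<- c(qs, s$q_value)
    }
    NULL
  })
  fdr <- if (length(qs) > 0) mean(qs) else NA_real_
  structure(list(fdr = fdr, q_values = qs, n_empty = n_empty,
                 n_perm = n_perm, observed = observed),
            class = "permutation_fdr")
}

#' @export
print.permutation_fdr <- function(x, ...) {
  cat("Permutation FDR:", format(x$fdr, digits = 3), "over", x$n_perm,
      "permutations (", x$n_empty, "without labeled edges )\n")
  invisible(x)
}

#' Subsampling stability of the differential network
#'
#' Measures how much of the validated smoking-specific network survives
#' when only part of the training cohort is used: the reference edge set is
#' computed on the full data; in each iteration the training samples are
#' subsampled without replacement within each smoking group (preserving the
#' group ratio), the whole dichotomize/network/differential/validation
#' chain is re-run against the full test cohort, and the retrieved fraction
#' of reference edges recorded.
#'
#' @inheritParams permutation_fdr
#' @param subset_fraction Fraction of each training group retained.
#' @param n_iter Number of subsampling iterations.
#' @return A list of class `network_stability`: `stability` (mean retrieved
#'   fraction), `per_iteration`, `n_reference_edges`. With an empty
#'   reference set the stability is undefined (`NA`).
#' @export
network_stability <- function(train_expr, train_groups, test_expr,
                              test_groups, subset_fraction = 0.8,
                              n_iter = 100, alpha = 0.05, seed = 1L,
                              min_scope = 0, min_expected_errors = 5) {
  stopifnot(subset_fraction > 0, subset_fraction <= 1, n_iter >= 1)
  genes <- rownames(train_expr)
  means_full <- rowMeans(train_expr)
  st_test_full <- function(m) dichotomize(test_expr[genes, , drop = FALSE], m)
  ref <- .diff_validated_states(dichotomize(train_expr, means_full),
                                train_groups, st_test_full(means_full),
                                test_groups, alpha, min_scope,
                                min_expected_errors)
  if (nrow(ref) == 0) {
    return(structure(list(stability = NA_real_, per_iteration = numeric(0),
                          n_reference_edges = 0L),
                     class = "network_stability"))
  }
  ref_key <- paste(.pair_key(ref$gene_a, ref$gene_b), ref$status)

  idx_s <- which(train_groups == 1); idx_n <- which(train_groups == 0)
  k_s <- round(subset_fraction * length(idx_s))
  k_n <- round(subset_fraction * length(idx_n))
  if (k_s < 2 || k_n < 2) stop("subset keeps fewer than 2 samples in a group")

  fractions <- .with_substream(seed, "stability", function() {
    vapply(seq_len(n_iter), function(b) {
      sub <- c(sample(idx_s, k_s), sample(idx_n, k_n))
      expr_sub <- train_expr[, sub, drop = FALSE]
      means_sub <- rowMeans(expr_sub)
      edges <- .diff_validated_states(
        dichotomize(expr_sub, means_sub), train_groups[sub],
        st_test_full(means_sub), test_groups,
        alpha, min_scope, min_expected_errors)
      key <- paste(.pair_key(edges$gene_a, edges$gene_b), edges$status)
      mean(ref_key %in% key)
    }, numeric(1))
  })
  structure(list(stability = mean(fractions), per_iteration = fractions,
                 n_reference_edges = nrow(ref)),
            class = "network_stability")
}

#' @export
print.network_stability <- function(x, ...) {
  cat("Network stability:", format(x$stability, digits = 3),
      "(reference edges:", x$n_reference_edges, ")\n")
  invisible(x)
}

#' @export
autoplot.network_stability <- function(object, ...) {
  df <- tibble::tibble(fraction = object$per_iteration)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "fraction of reference edges retrieved",
                  y = "iterations",
                  title = "Differential-network subsampling stability") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.implication_network <- function(object, ...) {
  df <- object$edges
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scope, y = .data$precision,
                                   colour = .data$rule)) +
    ggplot2::geom_jitter(width = 0.01, height = 0, alpha = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "scope (premise coverage)",
                  y = "precision (del)", colour = "rule",
                  title = paste("Implication network",
                                if (!is.na(object$group))
                                  paste0("(", object$group, ")") else "")) +
    ggplot2::theme_minimal()
}
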