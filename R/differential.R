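.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Differential network components between smoking groups
#'
#' Compares the two per-group implication networks pair by pair. A pair
#' with an edge in the smoker network and no edge of any type in the
#' non-smoker network is smoker-specific (and mirrored); a pair carrying
#' edges of different rule types in both networks is reported as
#' type-changed but excluded from signature selection.
#'
#' @param net_smoker,net_nonsmoker `implication_network` objects built over
#'   the same gene universe and alpha.
#' @return An object of class `differential_edges`: a tibble with `gene_a`,
#'   `gene_b`, `status` (`smoker_specific`, `nonsmoker_specific`,
#'   `type_changed`), `rule` and the rule statistics from the group where
#'   the edge is present (for type-changed pairs, the smoker edge, with the
#'   non-smoker type in `rule_other`).
#' @export
differential_edges <- function(net_smoker, net_nonsmoker) {
  stopifnot(inherits(net_smoker, "implication_network"),
            inherits(net_nonsmoker, "implication_network"))
  if (!setequal(net_smoker$genes, net_nonsmoker$genes)) {
    stop("networks were built over different gene universes")
  }
  if (!isTRUE(all.equal(net_smoker$alpha, net_nonsmoker$alpha))) {
    stop("networks were built at different alpha levels")
  }
  es <- net_smoker$edges; en <- net_nonsmoker$edges
  ks <- .pair_key(es$gene_a, es$gene_b)
  kn <- .pair_key(en$gene_a, en$gene_b)

  smoker_only <- es[!(ks %in% kn), , drop = FALSE]
  nonsmoker_only <- en[!(kn %in% ks), , drop = FALSE]
  both_s <- es[ks %in% kn, , drop = FALSE]
  both_n <- en[match(.pair_key(both_s$gene_a, both_s$gene_b), kn), , drop = FALSE]
  changed <- both_s[both_s$rule != both_n$rule, , drop = FALSE]
  changed$rule_other <- both_n$rule[both_s$rule != both_n$rule]

  add_status <- function(df, status) {
    if (nrow(df) == 0 && !"rule_other" %in% names(df)) df$rule_other <- character(0)
    if (!"rule_other" %in% names(df)) df$rule_other <- NA_character_
    df$status <- rep(status, nrow(df))
    df
  }
  out <- dplyr::bind_rows(
    add_status(smoker_only, "smoker_specific"),
    add_status(nonsmoker_only, "nonsmoker_specific"),
    add_status(changed, "type_changed")
  )
  structure(
    list(edges = out, genes = net_smoker$genes, alpha = net_smoker$alpha),
    class = "differential_edges"
  )
}

#' @export
print.differential_edges <- function(x, ...) {
  tab <- table(factor(x$edges$status,
                      c("smoker_specific", "nonsmoker_specific", "type_changed")))
  cat("Differential network components:",
      tab[["smoker_specific"]], "smoker-specific,",
      tab[["nonsmoker_specific"]], "non-smoker-specific,",
      tab[["type_changed"]], "type-changed\n")
  invisible(x)
}

#' @export
tidy.differential_edges <- function(x, ...) x$edges

#' Validate differential edges in an independent cohort
#'
#' Re-examines every differential edge in a test cohort dichotomized with
#' the frozen training reference means. An edge is kept when the same rule
#' type is significant in the corresponding test-cohort smoking group and
#' the pair remains group-specific there (no edge of any type in the other
#' group's test network). Never adds edges. Type-changed pairs are not
#' validated (they are excluded from selection).
#'
#' @param diff A [differential_edges()] result.
#' @param test_expr Test-cohort expression matrix (genes x samples),
#'   covering the differential gene universe.
#' @param test_groups Binary vector (1 = smoker) over test samples.
#' @param training_means Named per-gene reference means from the training
#'   cohort (frozen; see [dichotomize()]).
#' @param alpha Significance level (defaults to the training alpha).
#' @inheritParams rule_statistics
#' @return A `differential_edges` object containing the surviving edges; the
#'   full per-edge bookkeeping, including the drop `reason`, is kept in the
#'   `validation` attribute.
#' @export
validate_edges <- function(diff, test_expr, test_groups, training_means,
                           alpha = NULL, min_scope = 0,
                           min_expected_errors = 5) {
  stopifnot(inherits(diff, "differential_edges"))
  if (is.null(alpha)) alpha <- diff$alpha
  if (sum(test_groups == 1) == 0 || sum(test_groups == 0) == 0) {
    stop("empty test smoking group")
  }
  genes <- diff$genes
  missing <- setdiff(genes, rownames(test_expr))
  if (length(missing)) stop("test expression lacks gene(s): ",
                            paste(missing, collapse = ", "))
  states <- dichotomize(test_expr[genes, , drop = FALSE], training_means)
  st_s <- t(states[, test_groups == 1, drop = FALSE])
  st_n <- t(states[, test_groups == 0, drop = FALSE])
  net_s <- build_network(st_s, alpha, "smoker", min_scope, min_expected_errors)
  net_n <- build_network(st_n, alpha, "nonsmoker", min_scope, min_expected_errors)
  keys_s <- .pair_key(net_s$edges$gene_a, net_s$edges$gene_b)
  keys_n <- .pair_key(net_n$edges$gene_a, net_n$edges$gene_b)

  edges <- diff$edges
  check_one <- function(i) {
    e <- edges[i, ]
    if (e$status == "type_changed") return("type_changed_not_validated")
    own <- if (e$status == "smoker_specific") st_s else st_n
    other_keys <- if (e$status == "smoker_specific") keys_n else keys_s
    key <- .pair_key(e$gene_a, e$gene_b)
    if (key %in% other_keys) return("edge_in_other_test_group")
    s <- rule_statistics(pair_contingency(own[, e$gene_a], own[, e$gene_b]),
                         e$rule, min_scope, min_expected_errors)
    if (!s$testable) return("not_testable_in_test_group")
    if (!(s$p_precision < alpha && s$p_scope < alpha && s$precision > 0)) {
      return("not_significant_in_test_group")
    }
    "validated"
  }
  reasons <- vapply(seq_len(nrow(edges)), check_one, character(1))
  kept <- edges[reasons == "validated", , drop = FALSE]
  out <- structure(
    list(edges = kept, genes = genes, alpha = diff$alpha),
    class = "differential_edges"
  )
  attr(out, "validation") <- dplyr::mutate(
    edges[, c("gene_a", "gene_b", "status", "rule")], reason = reasons)
  out
}

#' Select signature genes by all-hub adjacency
#'
#' A gene is selected from a smoking group's specific differential edges
#' when it has a group-specific edge to every hub gene. Hubs themselves are
#' never signature genes. When no gene reaches full adjacency the result is
#' empty and the per-gene maximum adjacency counts are reported for
#' diagnosis.
#'
#' @param diff A (typically validated) [differential_edges()] result.
#' @param hubs Character vector of hub gene ids.
#' @return A list of class `signature_result`: `smoker_genes`,
#'   `nonsmoker_genes`, `justification` (tibble of the hub edges behind
#'   each selection) and `adjacency` (per gene/group hub-adjacency counts).
#' @export
select_signature <- function(diff, hubs) {
  stopifnot(inherits(diff, "differential_edges"), length(hubs) >= 1)
  absent <- setdiff(hubs, diff$genes)
  if (length(absent)) stop("hub(s) outside gene universe: ",
                           paste(absent, collapse = ", "))
  edges <- diff$edges[diff$edges$status %in%
                        c("smoker_specific", "nonsmoker_specific"), , drop = FALSE]
  # orient each edge as (gene, hub) in either slot
  hub_edges <- dplyr::bind_rows(
    dplyr::filter(edges, .data$gene_b %in% hubs, !(.data$gene_a %in% hubs)) |>
      dplyr::rename(gene = "gene_a", hub = "gene_b"),
    dplyr::filter(edges, .data$gene_a %in% hubs, !(.data$gene_b %in% hubs)) |>
      dplyr::rename(gene = "gene_b", hub = "gene_a")
  )
  adjacency <- hub_edges |>
    dplyr::distinct(.data$gene, .data$hub, .data$status) |>
    dplyr::count(.data$gene, .data$status, name = "n_hubs")
  full <- adjacency[adjacency$n_hubs == length(hubs), , drop = FALSE]
  smoker_genes <- sort(full$gene[full$status == "smoker_specific"])
  nonsmoker_genes <- sort(full$gene[full$status == "nonsmoker_specific"])
  justification <- hub_edges[hub_edges$gene %in% c(smoker_genes, nonsmoker_genes), ,
                             drop = FALSE]
  structure(
    list(smoker_genes = smoker_genes, nonsmoker_genes = nonsmoker_genes,
         hubs = hubs, justification = justification, adjacency = adjacency),
    class = "signature_result"
  )
}

#' @export
print.signature_result <- function(x, ...) {
  cat("Signature genes:", length(x$smoker_genes), "smoker-derived (",
      paste(x$smoker_genes, collapse = ", "), "),",
      length(x$nonsmoker_genes), "non-smoker-derived (",
      paste(x$nonsmoker_genes, collapse = ", "), ")\n")
  if (length(x$smoker_genes) + length(x$nonsmoker_genes) == 0 &&
      nrow(x$adjacency) > 0) {
    cat("  no gene adjacent to all", length(x$hubs), "hubs; max adjacency:",
        max(x$adjacency$n_hubs), "\n")
  }
  invisible(x)
}

# Observed-change confirmation table: which (change_a, change_b) pairs are
# consistent with each rule. Any "none" leaves a rule unconfirmed.
.consistency_table <- list(
  EQV       = list(c("up", "up"), c("down", "down")),
  NEQV      = list(c("up", "down"), c("down", "up")),
  IMP       = list(c("up", "up")),
  IMPNOT    = list(c("up", "down")),
  NOTIMP    = list(c("down", "up")),
  NOTIMPNOT = list(c("down", "down"))
)

#' Check a rule against observed expression changes
#'
#' Confirms or rejects an induced implication rule using the observed
#' direction of expression change of the two genes in an independent
#' experiment (e.g. a carcinogen-exposure assay): a positive equivalence is
#' confirmed by concordant changes, a negative equivalence by discordant
#' ones, and each directional rule by its single consistent combination.
#' A gene with no observed change never confirms a rule.
#'
#' @param rule_type One of [rule_types()].
#' @param change_a,change_b Observed change of each gene: `"up"`, `"down"`
#'   or `"none"`.
#' @return `TRUE` if the observation is consistent with the rule.
#' @export
check_rule_consistency <- function(rule_type, change_a, change_b) {
  rule_type <- match.arg(rule_type, RULE_TYPES)
  change_a <- match.arg(change_a, c("up", "down", "none"))
  change_b <- match.arg(change_b, c("up", "down", "none"))
  if (change_a == "none" || change_b == "none") return(FALSE)
  any(vapply(.consistency_table[[rule_type]],
             function(cc) cc[1] == change_a && cc[2] == change_b,
             logical(1)))
}
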