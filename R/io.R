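#' Read an expression matrix from TSV or GCT
#'
#' TSV layout: a header row of sample ids, first column gene ids. GCT 1.2
#' layout: `#1.2`, a dimensions row, then `Name`/`Description` columns
#' before the samples; declared dimensions must match the body.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"gct"` (default guessed from the extension).
#' @return Numeric matrix, genes x samples.
#' @export
read_expression_matrix <- function(path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  }
  if (format == "gct") {
    header <- readLines(path, n = 2)
    if (!grepl("^#1\\.2", header[1])) stop("not a GCT 1.2 file: ", path)
    dims <- as.integer(strsplit(header[2], "\t")[[1]][1:2])
    df <- utils::read.delim(path, skip = 2, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (nrow(df) != dims[1] || (ncol(df) - 2) != dims[2]) {
      stop(sprintf("GCT declares %d x %d but body is %d x %d",
                   dims[1], dims[2], nrow(df), ncol(df) - 2))
    }
    ids <- as.character(df[[1]])
    body <- df[, -(1:2), drop = FALSE]
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    body <- df[, -1, drop = FALSE]
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicated gene id(s): ", paste(dup, collapse = ", "))
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))) &
                     !is.na(body[[j]]))[1]
      stop(sprintf("non-numeric value in column '%s' (data line %d)",
                   names(body)[j], if (is.na(bad)) NA_integer_ else bad))
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  m
}

#' Write an expression matrix as TSV or GCT 1.2
#'
#' @param expr Numeric matrix, genes x samples.
#' @param path Output file.
#' @param format `"tsv"` or `"gct"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  df <- tibble::as_tibble(expr, rownames = "gene_id")
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(expr), ncol(expr), sep = "\t")), con)
    gdf <- dplyr::mutate(df, Description = "na", .after = "gene_id")
    names(gdf)[1] <- "Name"
    utils::write.table(gdf, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    readr::write_tsv(df, path)
  }
  invisible(path)
}

.clinical_required <- c("sample_id", "smoker", "surv_months", "event")

#' Read a clinical table
#'
#' Requires columns `sample_id`, `smoker` (0/1, NA allowed for unknown
#' status), `surv_months`, `event`; optional `stage` (I/II/III/Unknown),
#' `age`, `gender`, `cancer`. Unknown smoking status is preserved as
#' missing and excluded downstream with a logged count.
#'
#' @param path TSV file.
#' @return Tibble with typed columns.
#' @export
read_clinical_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(.clinical_required, names(df))
  if (length(missing)) stop("clinical table lacks column(s): ",
                            paste(missing, collapse = ", "))
  if ("stage" %in% names(df)) {
    bad <- setdiff(unique(stats::na.omit(df$stage)), c("I", "II", "III", "Unknown"))
    if (length(bad)) stop("unrecognized stage token(s): ",
                          paste(bad, collapse = ", "))
  }
  df$smoker <- as.integer(df$smoker)
  df$event <- as.integer(df$event)
  df
}

#' Write a clinical table as TSV
#'
#' @param clinical Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  readr::write_tsv(tibble::as_tibble(clinical), path)
  invisible(path)
}

#' Write a network as SIF with a companion statistics TSV
#'
#' SIF lines are `gene_a  RULE  gene_b`; the companion file (same path with
#' `.edges.tsv`) carries scope, precision and test statistics per edge.
#'
#' @param network An `implication_network` or `differential_edges` object.
#' @param path Output `.sif` path.
#' @return `path`, invisibly.
#' @export
write_network_sif <- function(network, path) {
  edges <- if (inherits(network, "implication_network")) network$edges
  else if (inherits(network, "differential_edges")) network$edges
  else stop("not a network object")
  writeLines(paste(edges$gene_a, edges$rule, edges$gene_b, sep = "\t"), path)
  readr::write_tsv(edges, sub("\\.sif$", ".edges.tsv", path))
  invisible(path)
}
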