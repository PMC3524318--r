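#' Expression tables
#'
#' A `dton_expr` is a tibble holding one time-course expression experiment:
#' the first column, `gene`, carries unique gene (or probe) identifiers and
#' every remaining column is named by its sampling time in hours and holds
#' the measurements at that time. The object carries a `stage` attribute
#' recording how far along the preprocessing pipeline it is:
#' `"raw"` (intensities), `"lcr"` (log concentration ratios
#' \eqn{\log(C_t/C_0)}) or `"standardized_lcr"` (LCRs z-scored within each
#' time point across genes).
#'
#' @param x A data frame whose first column is a character gene id and whose
#'   remaining columns are numeric, named by sampling times in hours.
#' @param stage One of `"raw"`, `"lcr"`, `"standardized_lcr"`.
#' @return A `dton_expr` tibble.
#' @examples
#' tab <- as_expr_table(
#'   tibble::tibble(gene = c("A", "B"), `0` = c(1, 2), `4` = c(2, 1)),
#'   stage = "raw"
#' )
#' expr_times(tab)
#' @export
as_expr_table <- function(x, stage = c("raw", "lcr", "standardized_lcr")) {
  stage <- match.arg(stage)
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2) {
    rlang::abort("an expression table needs a gene column plus >= 1 time column")
  }
  names(x)[1] <- "gene"
  x$gene <- as.character(x$gene)
  times <- suppressWarnings(as.numeric(names(x)[-1]))
  if (anyNA(times)) {
    bad <- names(x)[-1][is.na(times)]
    rlang::abort(paste0(
      "time column headers must be numeric hours; cannot parse: ",
      paste(bad, collapse = ", ")
    ))
  }
  if (anyDuplicated(times)) {
    rlang::abort("duplicated time columns in expression table")
  }
  ord <- order(times)
  x <- x[, c(1L, 1L + ord)]
  vals <- as.matrix(x[, -1])
  if (nrow(x) > 0 && !is.numeric(vals)) {
    rlang::abort("expression values must be numeric")
  }
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf(
      "missing value for gene '%s' at time %s",
      x$gene[idx[1]], names(x)[-1][idx[2]]
    ))
  }
  if (anyDuplicated(x$gene)) {
    rlang::abort("gene ids must be unique; collapse duplicate probes first")
  }
  structure(x, stage = stage, class = c("dton_expr", class(tibble::tibble())))
}

#' @rdname as_expr_table
#' @export
expr_stage <- function(x) attr(x, "stage", exact = TRUE)

#' @rdname as_expr_table
#' @export
expr_times <- function(x) as.numeric(names(x)[-1])

#' Extract the gene-by-time value matrix
#'
#' @param x A `dton_expr` table.
#' @return A numeric matrix with genes as row names and times as column names.
#' @export
expr_matrix <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$gene
  m
}

assert_expr <- function(x, stage = NULL, arg = "table") {
  if (!inherits(x, "dton_expr")) {
    rlang::abort(sprintf("`%s` must be a dton_expr (see as_expr_table())", arg))
  }
  if (!is.null(stage) && !(expr_stage(x) %in% stage)) {
    rlang::abort(sprintf(
      "`%s` has stage '%s'; expected %s", arg, expr_stage(x),
      paste(sprintf("'%s'", stage), collapse = " or ")
    ))
  }
  invisible(x)
}

#' Read a delimited expression table
#'
#' Reads a genes-by-times text table: first column gene (or probe) ids, the
#' remaining column headers the sampling times in hours. Columns are
#' reordered so times increase left to right.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field delimiter (default tab).
#' @param stage Stage tag to attach; files usually hold raw intensities.
#' @return A `dton_expr` tibble.
#' @export
read_expression_table <- function(path, delimiter = "\t",
                                  stage = c("raw", "lcr", "standardized_lcr")) {
  stage <- match.arg(stage)
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  header <- strsplit(readLines(path, n = 1), delimiter, fixed = TRUE)[[1]]
  if (length(header) < 2) rlang::abort("expected an id column plus time columns")
  if (anyDuplicated(header[-1])) rlang::abort("duplicated time columns in header")
  types <- stats::setNames(
    c(list(readr::col_character()),
      rep(list(readr::col_double()), length(header) - 1)),
    header
  )
  df <- readr::read_delim(
    path, delim = delimiter, col_types = do.call(readr::cols, types),
    progress = FALSE, show_col_types = FALSE
  )
  as_expr_table(df, stage = stage)
}

#' Write an expression table
#'
#' Values are written with 12 significant digits so that a write/read cycle
#' reproduces the table to that precision.
#'
#' @param x A `dton_expr` table.
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, delimiter = "\t") {
  assert_expr(x)
  out <- x
  for (j in 2:ncol(out)) out[[j]] <- signif(out[[j]], 12)
  readr::write_delim(out, path, delim = delimiter)
  invisible(path)
}

#' Average duplicated probes into genes
#'
#' Microarray designs often carry several probes per gene; their intensities
#' are collapsed by the arithmetic mean at each time point. Gene order
#' follows the first occurrence of each gene among the probes.
#'
#' @param table A raw-stage `dton_expr` with probe ids in the `gene` column.
#' @param probe_to_gene A two-column data frame (`probe`, `gene`) or a named
#'   character vector `c(probe = gene)` mapping every probe to its gene.
#' @return A raw-stage `dton_expr` with one row per gene.
#' @export
average_duplicate_probes <- function(table, probe_to_gene) {
  assert_expr(table, "raw")
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(
      as.character(probe_to_gene[[2]]),
      as.character(probe_to_gene[[1]])
    )
  } else {
    map <- probe_to_gene
  }
  missing <- setdiff(table$gene, names(map))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "probes missing from the probe-to-gene map: ",
      paste(utils::head(missing, 5), collapse = ", "),
      if (length(missing) > 5) ", ..." else ""
    ))
  }
  genes <- unname(map[table$gene])
  out <- table |>
    dplyr::mutate(gene = genes) |>
    dplyr::mutate(.order = match(gene, unique(genes))) |>
    dplyr::group_by(.data$.order, .data$gene) |>
    dplyr::summarise(
      dplyr::across(dplyr::everything(), mean),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$.order) |>
    dplyr::select(-".order")
  as_expr_table(out, stage = "raw")
}

#' Filter genes by coefficient of variation
#'
#' Keeps genes whose coefficient of variation across time (sample standard
#' deviation divided by mean, on the raw intensity scale) exceeds
#' `cv_threshold`; flat, non-responsive genes are dropped. Genes at exactly
#' the threshold are dropped.
#'
#' @param table A raw-stage `dton_expr` with strictly positive intensities.
#' @param cv_threshold Keep genes with CV strictly above this value.
#' @return The filtered `dton_expr`, original gene order preserved.
#' @export
filter_variable_genes <- function(table, cv_threshold = 0.15) {
  assert_expr(table, "raw")
  m <- expr_matrix(table)
  if (any(m <= 0)) {
    rlang::abort("coefficient of variation requires strictly positive intensities")
  }
  cv <- apply(m, 1, stats::sd) / rowMeans(m)
  as_expr_table(table[cv > cv_threshold, , drop = FALSE], stage = "raw")
}

#' Log concentration ratios
#'
#' Converts raw intensities \eqn{C_t} to LCRs \eqn{\log(C_t/C_0)} against the
#' first (baseline) time point, using natural logarithms; the downstream
#' per-time-point standardization makes the log base immaterial.
#'
#' @param table A raw-stage `dton_expr` with strictly positive values.
#' @param base Log base (default `exp(1)`).
#' @return An lcr-stage `dton_expr`; the baseline column is identically zero.
#' @export
compute_lcr <- function(table, base = exp(1)) {
  assert_expr(table, "raw")
  m <- expr_matrix(table)
  if (any(m <= 0)) {
    rlang::abort("LCR requires strictly positive concentrations")
  }
  lcr <- log(m / m[, 1], base = base)
  lcr[, 1] <- 0 # exact zero at baseline, not just up to rounding
  out <- dplyr::bind_cols(tibble::tibble(gene = table$gene), tibble::as_tibble(lcr))
  as_expr_table(out, stage = "lcr")
}

#' Standardize LCRs within each time point
#'
#' Each time column with nonzero spread is z-scored across genes (mean 0,
#' sample standard deviation 1), putting all genes on a comparable scale at
#' every time. Zero-spread columns — in particular the all-zero baseline —
#' are left untouched, since a z-score is undefined there and zero is the
#' correct LCR at baseline.
#'
#' @param table An lcr-stage `dton_expr` with at least two genes.
#' @return A standardized_lcr-stage `dton_expr`.
#' @export
standardize_per_timepoint <- function(table) {
  assert_expr(table, "lcr")
  if (nrow(table) < 2) {
    rlang::abort("standardization needs at least 2 genes")
  }
  m <- expr_matrix(table)
  for (j in seq_len(ncol(m))) {
    s <- stats::sd(m[, j])
    if (s > 0) m[, j] <- (m[, j] - mean(m[, j])) / s
  }
  out <- dplyr::bind_cols(tibble::tibble(gene = table$gene), tibble::as_tibble(m))
  as_expr_table(out, stage = "standardized_lcr")
}

#' @export
print.dton_expr <- function(x, ...) {
  cat(sprintf(
    "# Expression table: %d genes x %d time points (stage: %s)\n",
    nrow(x), ncol(x) - 1, expr_stage(x)
  ))
  NextMethod()
}
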