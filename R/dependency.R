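#' Read a gene-dependency score matrix
#'
#' CSV with the first column holding cell-line labels and the remaining
#' columns per-gene normalized knockout scores (non-essential around 0,
#' median essential effect at -1; depmap-style). Missing entries are
#' kept as `NA`.
#'
#' @param path input CSV.
#' @return numeric matrix, rows = cell lines, columns = genes.
#' @export
read_dependency_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("dependency matrix needs cell lines plus >= 1 gene")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Binarize a dependency matrix
#'
#' A cell line is "dependent" on a gene when its score is strictly
#' below the threshold (default -1, the median essential knockout
#' effect); a score exactly at the threshold is not dependent. Missing
#' scores stay missing.
#'
#' @param matrix numeric score matrix (cell lines x genes).
#' @param threshold dependence cutoff (default -1).
#' @return logical matrix of the same shape with `NA` preserved.
#' @export
binarize_dependency <- function(matrix, threshold = -1) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  matrix < threshold
}

#' Two-way dependency contingency table for a gene pair
#'
#' Counts cell lines by joint dependence on two genes, over the cell
#' lines with non-missing scores for both (pairwise-complete policy).
#'
#' @param binary logical dependency matrix from [binarize_dependency()].
#' @param gene_x,gene_y gene column names.
#' @return named integer vector `c(n_both, n_x_only, n_y_only,
#'   n_neither)`.
#' @export
pair_contingency <- function(binary, gene_x, gene_y) {
  for (g in c(gene_x, gene_y))
    if (!g %in% colnames(binary)) stop("unknown gene: ", g)
  x <- binary[, gene_x]; y <- binary[, gene_y]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  c(n_both = sum(x & y), n_x_only = sum(x & !y),
    n_y_only = sum(!x & y), n_neither = sum(!x & !y))
}

counts_to_table <- function(counts) {
  matrix(as.integer(counts[c("n_both", "n_x_only", "n_y_only", "n_neither")]),
         nrow = 2, byrow = TRUE,
         dimnames = list(x = c("dep", "not"), y = c("dep", "not")))
}

#' Fisher's exact test on a 2x2 dependency table
#'
#' Exact hypergeometric tail probability via `stats::fisher.test`.
#' `side = "greater"` tests for co-occurrence (positive association of
#' the two dependence profiles), `side = "less"` for mutual exclusivity
#' (negative association), `"two-sided"` for any association.
#'
#' @param counts 2x2 matrix, or a named vector as returned by
#'   [pair_contingency()].
#' @param side `"two-sided"`, `"greater"` or `"less"`.
#' @return p-value.
#' @export
fisher_exact <- function(counts, side = c("two-sided", "greater", "less")) {
  side <- match.arg(side)
  tab <- if (is.matrix(counts)) counts else counts_to_table(counts)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  alt <- switch(side, `two-sided` = "two.sided", greater = "greater",
                less = "less")
  stats::fisher.test(tab, alternative = alt)$p.value
}

#' Classify a gene pair from its dependency contingency table
#'
#' Count-driven classification (p-values are reported for ranking but
#' do not drive the class):
#' \itemize{
#'   \item \emph{mutually exclusive}: no cell line depends on both
#'     genes (at most `max_overlap`, default 0), each gene has at least
#'     `min_lines` exclusively dependent lines, and each gene's total
#'     dependent count stays strictly below
#'     `max_dependent_fraction * n_lines` (eliminating near-universal,
#'     essential genes);
#'   \item \emph{co-occurring}: at least `min_lines` co-dependent
#'     lines, same essentiality cap;
#'   \item otherwise \emph{neither}.
#' }
#'
#' @param counts named vector from [pair_contingency()] (or 2x2 matrix,
#'   rows = gene X dep/not, cols = gene Y dep/not).
#' @param n_lines number of evaluable cell lines; defaults to
#'   `sum(counts)`.
#' @param max_dependent_fraction essentiality cap (strict; default 0.5).
#' @param min_lines minimum per-arm (ME) or joint (CO) line count,
#'   i.e. "more than one" = 2 (default).
#' @param max_overlap maximum co-dependent lines still compatible with
#'   mutual exclusivity (default 0, the strictest reading).
#' @return object of class `dependency_call`: list with the four
#'   counts, `p_me`, `p_co` (one-sided Fisher p-values), and `klass`.
#' @export
classify_pair <- function(counts, n_lines = NULL,
                          max_dependent_fraction = 0.5, min_lines = 2,
                          max_overlap = 0) {
  if (is.matrix(counts))
    counts <- c(n_both = counts[1, 1], n_x_only = counts[1, 2],
                n_y_only = counts[2, 1], n_neither = counts[2, 2])
  n_both <- counts[["n_both"]]; n_x_only <- counts[["n_x_only"]]
  n_y_only <- counts[["n_y_only"]]; n_neither <- counts[["n_neither"]]
  if (is.null(n_lines)) n_lines <- n_both + n_x_only + n_y_only + n_neither
  x_tot <- n_both + n_x_only
  y_tot <- n_both + n_y_only
  cap_ok <- x_tot < max_dependent_fraction * n_lines &&
            y_tot < max_dependent_fraction * n_lines
  klass <- if (cap_ok && n_both <= max_overlap &&
               n_x_only >= min_lines && n_y_only >= min_lines) {
    "mutual_exclusive"
  } else if (cap_ok && n_both >= min_lines) {
    "co_occurring"
  } else "neither"
  structure(list(n_both = n_both, n_x_only = n_x_only,
                 n_y_only = n_y_only, n_neither = n_neither,
                 n_lines = n_lines,
                 p_me = fisher_exact(counts, "less"),
                 p_co = fisher_exact(counts, "greater"),
                 klass = klass),
            class = "dependency_call")
}

#' @export
print.dependency_call <- function(x, ...) {
  cat(sprintf("dependency call: %s  [both %d | x-only %d | y-only %d | neither %d]  p_me=%.3g p_co=%.3g\n",
              x$klass, x$n_both, x$n_x_only, x$n_y_only, x$n_neither,
              x$p_me, x$p_co))
  invisible(x)
}

#' Screen protein pairs against a dependency matrix
#'
#' Classifies each pair as mutually exclusive / co-occurring / neither
#' (see [classify_pair()]); pairs with a gene absent from the matrix
#' are skipped with a message, degenerate pairs (x = y) raise an error.
#'
#' @param binary logical dependency matrix from [binarize_dependency()].
#' @param pairs two-column matrix/data.frame of gene pairs (a
#'   `commonality_pairs` data.frame works directly).
#' @param ... thresholds passed to [classify_pair()].
#' @return data.frame of class `dependency_calls` with one row per
#'   evaluable pair (`gene_x`, `gene_y`, the four counts, `p_me`,
#'   `p_co`, `klass`); per-class tallies in attribute `summary`.
#' @export
screen_pairs <- function(binary, pairs, ...) {
  if (is.data.frame(pairs)) {
    cols <- if (all(c("x", "y") %in% names(pairs))) c("x", "y") else 1:2
    pm <- as.matrix(pairs[, cols, drop = FALSE])
  } else pm <- as.matrix(pairs)[, 1:2, drop = FALSE]
  storage.mode(pm) <- "character"
  if (nrow(pm) && any(pm[, 1] == pm[, 2]))
    stop("degenerate pair: a gene cannot be paired with itself")
  present <- pm[, 1] %in% colnames(binary) & pm[, 2] %in% colnames(binary)
  if (any(!present))
    message(sum(!present), " pair(s) skipped: gene absent from matrix")
  pm <- pm[present, , drop = FALSE]
  rows <- lapply(seq_len(nrow(pm)), function(i) {
    cl <- classify_pair(pair_contingency(binary, pm[i, 1], pm[i, 2]), ...)
    data.frame(gene_x = pm[i, 1], gene_y = pm[i, 2],
               n_both = cl$n_both, n_x_only = cl$n_x_only,
               n_y_only = cl$n_y_only, n_neither = cl$n_neither,
               p_me = cl$p_me, p_co = cl$p_co, klass = cl$klass,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_x = character(), gene_y = character(),
               n_both = integer(), n_x_only = integer(),
               n_y_only = integer(), n_neither = integer(),
               p_me = numeric(), p_co = numeric(), klass = character(),
               stringsAsFactors = FALSE)
  attr(out, "summary") <- c(
    mutual_exclusive = sum(out$klass == "mutual_exclusive"),
    co_occurring = sum(out$klass == "co_occurring"),
    neither = sum(out$klass == "neither"))
  class(out) <- c("dependency_calls", "data.frame")
  out
}

#' @export
print.dependency_calls <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("dependency screen: %d pair(s) - %d mutually exclusive, %d co-occurring, %d neither\n",
              nrow(x), s[["mutual_exclusive"]], s[["co_occurring"]],
              s[["neither"]]))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
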