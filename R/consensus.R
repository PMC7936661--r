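#' Read a protein-to-term annotation table
#'
#' Two formats are supported: a plain two-column TSV (`protein<TAB>term`,
#' one pair per row, `#` comments skipped) and a GAF 2.x subset, from
#' which column 2 (accession) and column 5 (term id) are taken (`!`
#' header lines skipped).
#'
#' @param path input file.
#' @param format `"tsv"` or `"gaf"`.
#' @return an annotation map: named list, protein -> character vector of
#'   unique term identifiers. Look up unknown proteins with
#'   [annotation_terms()], which returns an empty set.
#' @export
read_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  comment <- if (format == "gaf") "^!" else "^\\s*#"
  lines <- lines[nzchar(trimws(lines)) & !grepl(comment, lines)]
  if (!length(lines)) return(stats::setNames(list(), character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  pcol <- if (format == "gaf") 2L else 1L
  tcol <- if (format == "gaf") 5L else 2L
  if (any(lengths(f) < tcol))
    stop("malformed annotation row at line ", which(lengths(f) < tcol)[1])
  prot <- trimws(vapply(f, `[[`, character(1), pcol))
  term <- trimws(vapply(f, `[[`, character(1), tcol))
  lapply(split(term, prot), function(x) sort(unique(x), method = "radix"))
}

#' Term set of a protein under an annotation map
#' @param annotations annotation map (named list).
#' @param protein accession.
#' @return character vector of terms; empty for unknown proteins.
#' @export
annotation_terms <- function(annotations, protein) {
  t <- annotations[[protein]]
  if (is.null(t)) character() else t
}

#' Functional consensus of one short loop
#'
#' A loop has functional consensus when its member proteins share at
#' least one annotation term (the intersection of their term sets is
#' non-empty). The graded percentage is the Jaccard-style
#' 100 * |intersection| / |union| of the member term sets (0 when the
#' union is empty).
#'
#' @param loop character vector of loop members (one row of a loop
#'   matrix).
#' @param annotations annotation map.
#' @return list with `has_consensus` (logical) and `graded_pct`.
#' @export
loop_consensus <- function(loop, annotations) {
  sets <- lapply(as.character(loop), annotation_terms,
                 annotations = annotations)
  inter <- Reduce(intersect, sets)
  uni <- Reduce(union, sets)
  pct <- if (length(uni) == 0L) 0 else 100 * length(inter) / length(uni)
  list(has_consensus = length(inter) > 0L, graded_pct = pct)
}

#' Functional-consensus ratio of a loop set
#'
#' Percentage of short loops whose members share at least one term:
#' 100 * (loops with consensus) / (total loops). Under
#' `unannotated_policy = "exclude"`, loops containing any protein with
#' an empty term set are removed from numerator and denominator; the
#' default counts such loops as non-consensual (an unannotated member
#' cannot share a term).
#'
#' @param loops loop matrix from [enumerate_short_loops()].
#' @param annotations annotation map.
#' @param unannotated_policy `"count"` or `"exclude"`.
#' @return percentage in [0, 100] at full precision, or `NA` (with a
#'   warning) when no loop remains in the denominator.
#' @export
consensus_ratio <- function(loops, annotations,
                            unannotated_policy = c("count", "exclude")) {
  unannotated_policy <- match.arg(unannotated_policy)
  if (is.null(dim(loops))) loops <- matrix(loops, nrow = 1)
  n <- nrow(loops)
  if (n == 0L) {
    warning("consensus ratio undefined: no loops")
    return(NA_real_)
  }
  has_ann <- function(p) !is.null(annotations[[p]]) &&
    length(annotations[[p]]) > 0L
  keep <- rep(TRUE, n)
  if (unannotated_policy == "exclude") {
    keep <- apply(loops, 1, function(r) all(vapply(r, has_ann, logical(1))))
    if (!any(keep)) {
      warning("consensus ratio undefined: no fully annotated loops")
      return(NA_real_)
    }
  }
  cons <- apply(loops[keep, , drop = FALSE], 1, function(r)
    loop_consensus(r, annotations)$has_consensus)
  100 * sum(cons) / sum(keep)
}
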