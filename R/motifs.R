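#' Enumerate short loops (triangles and 4-cycles)
#'
#' A short loop of length 3 is a triangle: three mutually interacting
#' proteins. A short loop of length 4 is a simple 4-cycle, counted once
#' per node cycle; by default chords are allowed (a 4-cycle inside a
#' 4-clique counts), set `chordless = TRUE` to restrict to induced
#' cycles.
#'
#' Triangles are found by sorted-adjacency neighbour intersection: nodes
#' are indexed, and for every edge (u, v) the common neighbours with
#' index above both endpoints each close one triangle, so every triangle
#' is emitted exactly once.
#'
#' @param network a [ppi_network()].
#' @param k loop length, 3 or 4.
#' @param chordless for `k = 4`, require the two diagonals to be
#'   non-edges.
#' @return a character matrix with `k` columns, one canonical loop per
#'   row, rows in lexicographic order. For `k = 3` rows are sorted
#'   triples; for `k = 4` rows list the cycle starting at its smallest
#'   member, walking towards its smaller neighbour.
#' @export
enumerate_short_loops <- function(network, k = 3, chordless = FALSE) {
  stopifnot(inherits(network, "ppi_network"))
  if (!k %in% c(3, 4)) stop("loop length k must be 3 or 4")
  nd <- network$nodes
  n <- length(nd)
  empty <- matrix(character(), ncol = k,
                  dimnames = list(NULL, paste0("p", seq_len(k))))
  if (n_edges(network) == 0L) return(empty)
  ia <- match(network$edges$a, nd)
  ib <- match(network$edges$b, nd)
  adj <- vector("list", n)
  for (i in seq_along(ia)) {
    adj[[ia[i]]] <- c(adj[[ia[i]]], ib[i])
    adj[[ib[i]]] <- c(adj[[ib[i]]], ia[i])
  }
  adj <- lapply(adj, sort)
  if (k == 3) {
    res <- vector("list", length(ia))
    for (i in seq_along(ia)) {
      u <- min(ia[i], ib[i]); v <- max(ia[i], ib[i])
      w <- intersect_sorted(adj[[u]], adj[[v]])
      w <- w[w > v]
      if (length(w)) res[[i]] <- cbind(u, v, w)
    }
    tri <- do.call(rbind, res)
    if (is.null(tri)) return(empty)
    out <- matrix(nd[tri], ncol = 3)
  } else {
    ekey <- paste(pmin(ia, ib), pmax(ia, ib))
    has_edge <- function(x, y) paste(pmin(x, y), pmax(x, y)) %in% ekey
    seen <- new.env(hash = TRUE, parent = emptyenv())
    rows <- list(); nr <- 0L
    for (u in seq_len(n)) {
      for (w in seq_len(n)) {
        if (w <= u) next
        cn <- intersect_sorted(adj[[u]], adj[[w]])
        cn <- setdiff(cn, c(u, w))
        if (length(cn) < 2L) next
        cmb <- utils::combn(cn, 2L)
        for (j in seq_len(ncol(cmb))) {
          x <- cmb[1, j]; y <- cmb[2, j]
          if (chordless && (has_edge(u, w) || has_edge(x, y))) next
          cyc <- canonical_cycle4(u, x, w, y)
          key <- paste(cyc, collapse = " ")
          if (!is.null(seen[[key]])) next
          seen[[key]] <- TRUE
          nr <- nr + 1L
          rows[[nr]] <- cyc
        }
      }
    }
    if (nr == 0L) return(empty)
    out <- matrix(nd[do.call(rbind, rows)], ncol = 4)
  }
  colnames(out) <- paste0("p", seq_len(k))
  out[order_rows(out), , drop = FALSE]
}

# intersection of two sorted integer vectors
intersect_sorted <- function(x, y) x[x %in% y]

# canonical form of the 4-cycle a-b-c-d-a: start at the smallest node,
# walk towards its smaller cycle neighbour
canonical_cycle4 <- function(a, b, c, d) {
  cyc <- c(a, b, c, d)
  i <- which.min(cyc)
  v1 <- cyc[i]
  nb <- cyc[c((i %% 4) + 1, ((i + 2) %% 4) + 1)]   # the two cycle neighbours
  opp <- cyc[(i %% 4 + 1) %% 4 + 1]                # the opposite node
  c(v1, min(nb), opp, max(nb))
}

order_rows <- function(m) do.call(order, c(lapply(seq_len(ncol(m)),
                                                  function(j) m[, j]),
                                           list(method = "radix")))

#' Normalized short-loop ratio
#'
#' The number of short loops divided by the number of interactions; loop
#' counts scale with network size, so this is the size-normalized
#' loop-density statistic. Reported to 2 decimals in profiles.
#'
#' @param n_loops number of short loops.
#' @param n_edges number of interactions (must be positive).
#' @return `n_loops / n_edges` at full precision.
#' @export
loop_ratio <- function(n_loops, n_edges) {
  if (length(n_edges) != 1L || is.na(n_edges) || n_edges <= 0)
    stop("loop ratio undefined: network has no interactions")
  n_loops / n_edges
}

#' Partner-pair sets from triangles
#'
#' Each triangle \{X, A, B\} contributes the unordered pair \{A, B\} to
#' X's partner-pair set (and symmetrically for A and B). Proteins in no
#' triangle are absent from the result.
#'
#' @param loops a loop matrix from [enumerate_short_loops()] with
#'   `k = 3` (3 columns).
#' @return named list: protein -> two-column character matrix of its
#'   partner pairs (each row sorted, rows unique).
#' @export
partner_pairs <- function(loops) {
  if (is.null(dim(loops)) || ncol(loops) != 3L)
    stop("partner pairs are defined for length-3 loops only")
  if (nrow(loops) == 0L) return(stats::setNames(list(), character()))
  # rows are sorted triples, so each owner's opposite pair is already sorted
  owner <- c(loops[, 1], loops[, 2], loops[, 3])
  p1 <- c(loops[, 2], loops[, 1], loops[, 1])
  p2 <- c(loops[, 3], loops[, 3], loops[, 2])
  res <- lapply(split(seq_along(owner), owner), function(i) {
    m <- unique(cbind(p1[i], p2[i]))
    colnames(m) <- c("p1", "p2")
    m[order_rows(m), , drop = FALSE]
  })
  res[sort(names(res), method = "radix")]
}

# internal: partner pairs as "A\rB" key sets
partner_pair_keys <- function(loops) {
  pp <- partner_pairs(loops)
  lapply(pp, function(m) paste(m[, 1], m[, 2], sep = "\r"))
}

#' Short-loop profile of a network
#'
#' The row-level summary used to compare mutation subnetworks: protein
#' and interaction counts, the short-loop count, the normalized
#' loop/interaction ratio and (when annotations are given) the
#' functional-consensus percentage.
#'
#' @param network a [ppi_network()].
#' @param annotations optional annotation map (named list protein ->
#'   character vector of term ids); when given, the functional-consensus
#'   percentage is computed.
#' @param k loop length (3 or 4); consensus is only defined for 3.
#' @param label a name for the network, echoed in printing.
#' @param ... passed to [consensus_ratio()] (e.g. `unannotated_policy`).
#' @return object of class `loop_profile`: list with `network_label`,
#'   `n_proteins`, `n_edges`, `n_loops`, `ratio`, `consensus_pct` (NA
#'   without annotations) and the loop matrix as attribute `loops`.
#' @export
loop_profile <- function(network, annotations = NULL, k = 3, label = "", ...) {
  loops <- enumerate_short_loops(network, k = k)
  ratio <- if (n_edges(network) > 0) loop_ratio(nrow(loops), n_edges(network))
           else NA_real_
  cons <- NA_real_
  if (!is.null(annotations)) {
    if (k != 3) stop("functional consensus is computed for k = 3 loops")
    cons <- consensus_ratio(loops, annotations, ...)
  }
  out <- structure(list(network_label = label,
                        n_proteins = n_nodes(network),
                        n_edges = n_edges(network),
                        n_loops = nrow(loops),
                        ratio = ratio,
                        consensus_pct = cons),
                   class = "loop_profile")
  attr(out, "loops") <- loops
  out
}

#' @export
print.loop_profile <- function(x, ...) {
  cat("Short loop profile", if (nzchar(x$network_label))
    paste0("[", x$network_label, "]"), "\n")
  cat("  proteins:     ", x$n_proteins, "\n")
  cat("  interactions: ", x$n_edges, "\n")
  cat("  short loops:  ", x$n_loops, "\n")
  cat("  loop/PPI ratio:", formatC(x$ratio, format = "f", digits = 2), "\n")
  if (!is.na(x$consensus_pct))
    cat("  functional consensus:",
        formatC(x$consensus_pct, format = "f", digits = 2), "%\n")
  invisible(x)
}

#' Write loops to TSV (one canonical loop per row)
#' @param loops loop matrix from [enumerate_short_loops()].
#' @param path output file.
#' @export
write_loops <- function(loops, path) {
  utils::write.table(loops, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
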