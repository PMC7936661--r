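#' Detect short-loop commonality pairs
#'
#' Two proteins X and Y are in short-loop commonality when they do not
#' interact directly but participate in the same short loops, i.e. they
#' share the same triangle partner pairs. A pair qualifies when (i) at
#' least `min_shared` partner pairs are shared and (ii) at least
#' `min_frac` of each protein's partner pairs are among the shared ones
#' (the symmetric reading; `frac_mode` selects a one-sided variant).
#'
#' @param network a [ppi_network()].
#' @param loops its length-3 loop matrix; computed if `NULL`.
#' @param min_shared minimum number of shared partner pairs (default 3).
#' @param min_frac minimum shared fraction of each protein's partner
#'   pairs, in (0, 1] (default 0.95).
#' @param frac_mode `"both"`/`"min"`: both fractions must reach
#'   `min_frac` (default); `"either"`/`"max"`: one suffices.
#' @return data.frame of class `commonality_pairs` with columns `x`,
#'   `y` (x < y), `shared`, `frac_x`, `frac_y`, rows in lexicographic
#'   order.
#' @export
find_commonality_pairs <- function(network, loops = NULL, min_shared = 3,
                                   min_frac = 0.95,
                                   frac_mode = c("both", "either",
                                                 "min", "max")) {
  stopifnot(inherits(network, "ppi_network"))
  frac_mode <- match.arg(frac_mode)
  if (!is.numeric(min_frac) || min_frac <= 0 || min_frac > 1)
    stop("min_frac must be in (0, 1]")
  if (is.null(loops)) loops <- enumerate_short_loops(network, k = 3)
  empty <- structure(
    data.frame(x = character(), y = character(), shared = integer(),
               frac_x = numeric(), frac_y = numeric(),
               stringsAsFactors = FALSE),
    class = c("commonality_pairs", "data.frame"))
  if (nrow(loops) == 0L) return(empty)
  pk <- partner_pair_keys(loops)
  owners <- names(pk)
  sizes <- lengths(pk)
  # invert: pair key -> owners, then count co-ownership per owner pair
  key <- unlist(pk, use.names = FALSE)
  own <- rep(owners, sizes)
  shared_count <- new.env(hash = TRUE, parent = emptyenv())
  for (grp in split(own, key)) {
    if (length(grp) < 2L) next
    grp <- sort(grp, method = "radix")
    cmb <- utils::combn(grp, 2L)
    for (j in seq_len(ncol(cmb))) {
      k2 <- paste(cmb[1, j], cmb[2, j], sep = "\r")
      shared_count[[k2]] <- (shared_count[[k2]] %||% 0L) + 1L
    }
  }
  cand <- ls(shared_count, sorted = TRUE)
  if (!length(cand)) return(empty)
  shared <- vapply(cand, function(k2) shared_count[[k2]], integer(1))
  parts <- matrix(unlist(strsplit(cand, "\r", fixed = TRUE)),
                  ncol = 2, byrow = TRUE)
  x <- parts[, 1]; y <- parts[, 2]
  adjacent <- paste(x, y, sep = "\r") %in% edge_keys(network)
  fx <- shared / sizes[x]
  fy <- shared / sizes[y]
  frac_ok <- switch(frac_mode,
    both = , min = pmin(fx, fy) >= min_frac,
    either = , max = pmax(fx, fy) >= min_frac)
  keep <- !adjacent & shared >= min_shared & frac_ok
  out <- data.frame(x = x[keep], y = y[keep],
                    shared = unname(shared[keep]),
                    frac_x = unname(fx[keep]), frac_y = unname(fy[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$x, out$y, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("commonality_pairs", "data.frame")
  out
}

#' Assemble the commonality network and its summary statistics
#'
#' Commonality pairs become edges of a new graph; the summary reports
#' node and pair counts, the mean number of neighbours
#' (2 * n_pairs / n_nodes) and connected-component sizes.
#'
#' @param pairs a `commonality_pairs` data.frame, or any two-column
#'   matrix/data.frame of protein pairs.
#' @return object of class `commonality_summary`: list with `network`
#'   (a [ppi_network()]), `n_nodes`, `n_pairs`, `mean_neighbours` and
#'   `components` (sorted decreasing sizes).
#' @export
commonality_network <- function(pairs) {
  if (is.data.frame(pairs)) {
    cols <- if (all(c("x", "y") %in% names(pairs))) c("x", "y") else 1:2
    m <- as.matrix(pairs[, cols, drop = FALSE])
  } else m <- as.matrix(pairs)[, 1:2, drop = FALSE]
  net <- ppi_network(m, sources = "commonality")
  nn <- n_nodes(net); ne <- n_edges(net)
  comp <- if (nn > 0) {
    sizes <- igraph::components(as_igraph(net))$csize
    sort(as.integer(sizes), decreasing = TRUE)
  } else integer()
  structure(list(network = net,
                 n_nodes = nn,
                 n_pairs = ne,
                 mean_neighbours = if (nn > 0) 2 * ne / nn else NA_real_,
                 components = comp),
            class = "commonality_summary")
}

#' @export
print.commonality_summary <- function(x, ...) {
  cat("Short loop commonality network\n")
  cat("  proteins:        ", x$n_nodes, "\n")
  cat("  commonality pairs:", x$n_pairs, "\n")
  cat("  mean neighbours: ",
      formatC(x$mean_neighbours, format = "f", digits = 2), "\n")
  cat("  components:      ", length(x$components),
      if (length(x$components))
        paste0("(sizes ", paste(utils::head(x$components, 8), collapse = ", "),
               if (length(x$components) > 8) ", ..." else "", ")"), "\n")
  invisible(x)
}

#' Build the control pair set for dependency comparison
#'
#' For disease commonality pairs found in a mutation subnetwork, the
#' control set consists of commonality pairs (A, B) of the general
#' network, under the same thresholds, where A occurs in some disease
#' pair, B carries no disease mutation, and (A, B) is not itself a
#' disease pair.
#'
#' @param disease_pairs `commonality_pairs` from the disease subnetwork.
#' @param general_network the full [ppi_network()].
#' @param general_loops its loop matrix; computed if `NULL`.
#' @param disease_proteins accessions mutated in the disease.
#' @param min_shared,min_frac thresholds, as in
#'   [find_commonality_pairs()].
#' @return a `commonality_pairs` data.frame (x = disease-linked protein
#'   A may appear in either column; rows lexicographic).
#' @export
control_set <- function(disease_pairs, general_network, general_loops = NULL,
                        disease_proteins, min_shared = 3, min_frac = 0.95) {
  gp <- find_commonality_pairs(general_network, loops = general_loops,
                               min_shared = min_shared, min_frac = min_frac)
  dprot <- unique(c(disease_pairs$x, disease_pairs$y))
  dkey <- paste(disease_pairs$x, disease_pairs$y, sep = "\r")
  a_in <- gp$x %in% dprot
  b_in <- gp$y %in% dprot
  # exactly one endpoint from the disease pairs; the other unmutated
  one_side <- (a_in & !(gp$y %in% disease_proteins) & !b_in) |
              (b_in & !(gp$x %in% disease_proteins) & !a_in)
  keep <- one_side & !(paste(gp$x, gp$y, sep = "\r") %in% dkey)
  out <- gp[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write commonality pairs to TSV
#' @param pairs `commonality_pairs` data.frame.
#' @param path output file.
#' @export
write_commonality_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
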