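#' Protein-protein interaction network
#'
#' A `ppi_network` is a simple undirected graph over protein accessions:
#' no self-loops, no duplicate edges, and every edge endpoint present in
#' the node set. Each edge carries a set of source labels recording which
#' input dataset(s) contributed it.
#'
#' @param edges two-column character matrix or data.frame of interacting
#'   protein pairs. Self-loops are dropped and duplicates collapsed.
#' @param nodes optional character vector of node accessions; endpoints of
#'   `edges` are always included. Use this to keep isolated proteins.
#' @param sources character vector of source labels, one per edge row (or a
#'   single label recycled). Labels of collapsed duplicate edges are unioned.
#'
#' @return An object of class `ppi_network`: a list with elements `nodes`
#'   (sorted character vector) and `edges` (data.frame with columns `a`,
#'   `b`, `sources`; `a < b`, rows sorted).
#' @export
ppi_network <- function(edges = NULL, nodes = NULL, sources = "") {
  if (is.null(edges) || NROW(edges) == 0L) {
    ed <- data.frame(a = character(), b = character(),
                     sources = character(), stringsAsFactors = FALSE)
    nd <- sort(unique(as.character(nodes %||% character())), method = "radix")
    return(new_ppi_network(nd, ed))
  }
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  storage.mode(edges) <- "character"
  a <- trimws(edges[, 1]); b <- trimws(edges[, 2])
  if (any(a == "") || any(b == ""))
    stop("empty protein accession in edge list")
  sources <- rep_len(as.character(sources), length(a))
  keep <- a != b                       # self-loops removed
  a <- a[keep]; b <- b[keep]; sources <- sources[keep]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\r")
  src <- vapply(split(sources, key), function(s) {
    s <- sort(unique(s[nzchar(s)]), method = "radix")
    paste(s, collapse = ";")
  }, character(1))
  uk <- sort(unique(key), method = "radix")
  parts <- matrix(unlist(strsplit(uk, "\r", fixed = TRUE)),
                  ncol = 2, byrow = TRUE)
  ed <- data.frame(a = parts[, 1], b = parts[, 2],
                   sources = unname(src[uk]), stringsAsFactors = FALSE)
  nd <- sort(unique(c(as.character(nodes %||% character()), ed$a, ed$b)),
             method = "radix")
  new_ppi_network(nd, ed)
}

new_ppi_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", n_nodes(x), "proteins,", n_edges(x), "interactions\n")
  if (n_edges(x) > 0) {
    show <- utils::head(x$edges, 5L)
    cat(paste0("  ", show$a, " -- ", show$b,
               ifelse(nzchar(show$sources), paste0("  [", show$sources, "]"), ""),
               collapse = "\n"), "\n")
    if (n_edges(x) > 5L) cat("  ...\n")
  }
  invisible(x)
}

#' Number of nodes / edges of a network
#' @param network a `ppi_network`
#' @return integer count
#' @export
n_nodes <- function(network) length(network$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(network) nrow(network$edges)

# canonical "a\rb" edge keys, a < b
edge_keys <- function(network) {
  if (n_edges(network) == 0L) return(character())
  paste(network$edges$a, network$edges$b, sep = "\r")
}

#' Convert a ppi_network to an igraph graph
#'
#' @param network a `ppi_network`
#' @return an undirected simple \pkg{igraph} graph with a `sources` edge
#'   attribute
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("a", "b", "sources")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE))
  g
}
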