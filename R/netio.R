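#' Read an edge-list TSV into a network
#'
#' Edge lists have one interaction per line: two protein accessions
#' separated by tabs (an optional third column naming the source is
#' ignored in favour of `source_label`). Lines starting with `#` are
#' skipped. A header line `protein_a<TAB>protein_b[...]` is detected and
#' skipped automatically. Self-loop rows are dropped and duplicate rows
#' collapsed; identifiers are case-sensitive and only surrounding
#' whitespace is trimmed.
#'
#' @param path path to the TSV file.
#' @param source_label label attached to every retained edge.
#' @param keep_isolated keep proteins that appear only in dropped
#'   self-loop rows as isolated nodes? Default drops them, so that the
#'   node set is exactly the proteins participating in interactions.
#' @param mapping optional two-column data.frame (from, to) applied to
#'   both endpoint columns before the network is built; rows with an
#'   unmapped endpoint are dropped with a message.
#' @param sep field separator, tab by default.
#' @return a [ppi_network()].
#' @export
read_edge_list <- function(path, source_label = "", keep_isolated = FALSE,
                           mapping = NULL, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("empty edge list: ", path)
    return(ppi_network())
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop("malformed edge-list row at line ", lineno[bad[1]], " of ", path,
         " (need at least 2 columns)")
  a <- trimws(vapply(fields, `[[`, character(1), 1L))
  b <- trimws(vapply(fields, `[[`, character(1), 2L))
  if (identical(tolower(a[1]), "protein_a") &&
      identical(tolower(b[1]), "protein_b")) {
    a <- a[-1]; b <- b[-1]
    if (length(a) == 0L) {
      warning("empty edge list: ", path)
      return(ppi_network())
    }
  }
  if (!is.null(mapping)) {
    mp <- stats::setNames(as.character(mapping[[2]]), as.character(mapping[[1]]))
    ma <- unname(mp[a]); mb <- unname(mp[b])
    drop <- is.na(ma) | is.na(mb)
    if (any(drop))
      message(sum(drop), " row(s) dropped: endpoint absent from ID mapping")
    a <- ma[!drop]; b <- mb[!drop]
  }
  nodes <- if (keep_isolated) unique(c(a, b)) else NULL
  ppi_network(cbind(a, b), nodes = nodes, sources = source_label)
}

#' Merge networks by union
#'
#' Node and edge sets are unioned; source labels of coincident edges are
#' unioned per edge. Duplicates and self-loops cannot survive the merge
#' by construction.
#'
#' @param ... `ppi_network` objects, or a single list of them.
#' @return a [ppi_network()].
#' @export
merge_networks <- function(...) {
  nets <- list(...)
  if (length(nets) == 1L && !inherits(nets[[1]], "ppi_network"))
    nets <- nets[[1]]
  if (length(nets) == 0L) stop("merge_networks() needs at least one network")
  ok <- vapply(nets, inherits, logical(1), "ppi_network")
  if (!all(ok)) stop("all arguments must be ppi_network objects")
  ed <- do.call(rbind, lapply(nets, function(n) n$edges))
  nodes <- unique(unlist(lapply(nets, function(n) n$nodes)))
  if (is.null(ed) || nrow(ed) == 0L) return(ppi_network(nodes = nodes))
  # split multi-source strings so labels re-union cleanly across networks
  src <- strsplit(ed$sources, ";", fixed = TRUE)
  reps <- pmax(lengths(src), 1L)
  idx <- rep(seq_len(nrow(ed)), reps)
  flat_src <- unlist(lapply(src, function(s) if (length(s)) s else ""))
  ppi_network(cbind(ed$a[idx], ed$b[idx]), nodes = nodes, sources = flat_src)
}

#' Extract the subnetwork induced by a protein set
#'
#' Keeps the proteins of `proteins` that map into the network, and every
#' edge with both endpoints among them. The mapping coverage
#' (percentage of the input accessions found in the network, rounded to
#' the nearest integer) is attached as attributes `coverage`, `n_input`
#' and `n_mapped`.
#'
#' @param network a `ppi_network`.
#' @param proteins character vector of accessions; entries absent from the
#'   network are counted against coverage but otherwise ignored.
#' @return a [ppi_network()] with coverage attributes.
#' @export
induce_subnetwork <- function(network, proteins) {
  stopifnot(inherits(network, "ppi_network"))
  proteins <- unique(trimws(as.character(proteins)))
  proteins <- proteins[nzchar(proteins)]
  mapped <- proteins[proteins %in% network$nodes]
  if (length(mapped) == 0L)
    warning("no input protein maps into the network")
  keep <- network$edges$a %in% mapped & network$edges$b %in% mapped
  ed <- network$edges[keep, , drop = FALSE]
  out <- new_ppi_network(sort(mapped, method = "radix"),
                         `rownames<-`(ed, NULL))
  attr(out, "n_input") <- length(proteins)
  attr(out, "n_mapped") <- length(mapped)
  attr(out, "coverage") <- if (length(proteins))
    as.integer(round(100 * length(mapped) / length(proteins))) else NA_integer_
  out
}

#' Read a protein set (one accession per line)
#'
#' @param path text file, one accession per line; `#` comments skipped.
#' @return character vector of unique accessions.
#' @export
read_protein_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path, warn = FALSE)
  x <- trimws(x[!grepl("^\\s*#", x)])
  unique(x[nzchar(x)])
}

#' Write a protein set
#' @param proteins character vector.
#' @param path output file.
#' @export
write_protein_set <- function(proteins, path) {
  writeLines(as.character(proteins), path)
  invisible(path)
}

#' Write / read a network
#'
#' Supported formats: `"tsv"` (columns protein_a, protein_b, source),
#' `"sif"` (`A pp B`) and `"graphml"` (via \pkg{igraph}). Round trips are
#' lossless for nodes and edges; SIF does not carry source labels.
#'
#' @param network a `ppi_network`.
#' @param path output (input) file path.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @return `write_network` returns `path` invisibly; `read_network`
#'   returns a [ppi_network()].
#' @export
write_network <- function(network, path, format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(network, "ppi_network"))
  format <- match.arg(format)
  ed <- network$edges
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("protein_a\tprotein_b\tsource", con)
    if (nrow(ed))
      writeLines(paste(ed$a, ed$b, ed$sources, sep = "\t"), con)
  } else if (format == "sif") {
    iso <- setdiff(network$nodes, c(ed$a, ed$b))
    writeLines(c(if (nrow(ed)) paste(ed$a, "pp", ed$b), iso), path)
  } else {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    if (length(lines) && grepl("^protein_a\t", lines[1])) lines <- lines[-1]
    if (!length(lines)) return(ppi_network())
    f <- strsplit(lines, "\t", fixed = TRUE)
    a <- vapply(f, `[[`, character(1), 1L)
    b <- vapply(f, `[[`, character(1), 2L)
    src <- vapply(f, function(x) if (length(x) >= 3) x[[3]] else "", character(1))
    ppi_network(cbind(a, b), sources = src)
  } else if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    f <- strsplit(lines, "[ \t]+")
    iso <- vapply(f, length, integer(1)) < 3L
    a <- vapply(f[!iso], `[[`, character(1), 1L)
    b <- vapply(f[!iso], `[[`, character(1), 3L)
    ppi_network(if (length(a)) cbind(a, b),
                nodes = unlist(f[iso]))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    ed <- igraph::as_edgelist(g, names = TRUE)
    src <- igraph::edge_attr(g, "sources") %||% ""
    ppi_network(ed, nodes = igraph::V(g)$name, sources = src)
  }
}
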