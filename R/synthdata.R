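#' Erdos-Renyi random network generator
#'
#' Each unordered pair of proteins is an edge independently with
#' probability `p`; seed-reproducible.
#'
#' @param n number of proteins.
#' @param p edge probability.
#' @param seed RNG seed.
#' @param prefix accession prefix; proteins are named
#'   `prefix` + zero-padded index.
#' @return a [ppi_network()] (isolated nodes kept, so the node count is
#'   exactly `n`).
#' @export
gen_er_network <- function(n, p, seed = NULL, prefix = "P") {
  nodes <- sprintf("%s%04d", prefix, seq_len(n))
  if (n < 2 || p <= 0) return(ppi_network(nodes = nodes))
  idx <- utils::combn(n, 2)
  keep <- with_seed(seed, stats::runif(ncol(idx)) < p)
  ppi_network(cbind(nodes[idx[1, keep]], nodes[idx[2, keep]]),
              nodes = nodes, sources = "er")
}

#' Planted short-loop commonality generator
#'
#' Plants `n_motifs` commonality motifs on an Erdos-Renyi background:
#' each motif is a hub pair (X, Y) with no X-Y edge plus a chain of
#' `fan_size + 1` partner proteins C1-C2-...-C(fan_size+1) (adjacent
#' partner pairs share members, so the fan contributes the chained
#' pairs C1C2, C2C3, ... as in the canonical commonality picture), with
#' every chain protein connected to both X and Y. At zero background
#' density the detector recovers exactly the planted (X, Y) pairs for
#' `fan_size >= min_shared`.
#'
#' @param n_background background proteins.
#' @param p_background background edge probability.
#' @param n_motifs number of planted motifs.
#' @param fan_size partner pairs per motif (>= 1; detection at the
#'   default thresholds needs >= 3).
#' @param seed RNG seed.
#' @return list with `network` (a [ppi_network()]) and `truth` (list
#'   with `planted_commonality_pairs` data.frame `x`, `y`, the
#'   generator parameters and the seed).
#' @export
gen_planted_commonality <- function(n_background, p_background, n_motifs,
                                    fan_size = 3, seed = NULL) {
  if (fan_size < 1) stop("fan_size must be >= 1")
  bg <- gen_er_network(n_background, p_background, seed = seed, prefix = "B")
  edges <- NULL
  pairs <- data.frame(x = character(), y = character(),
                      stringsAsFactors = FALSE)
  for (m in seq_len(n_motifs)) {
    x <- sprintf("X%03d", m); y <- sprintf("Y%03d", m)
    chain <- sprintf("C%03d_%02d", m, seq_len(fan_size + 1))
    ce <- cbind(chain[-length(chain)], chain[-1])
    hub <- rbind(cbind(x, chain), cbind(y, chain))
    edges <- rbind(edges, ce, hub)
    xy <- sort(c(x, y), method = "radix")
    pairs <- rbind(pairs, data.frame(x = xy[1], y = xy[2],
                                     stringsAsFactors = FALSE))
  }
  planted <- ppi_network(edges, sources = "planted")
  net <- merge_networks(bg, planted)
  pairs <- pairs[order(pairs$x, pairs$y, method = "radix"), , drop = FALSE]
  rownames(pairs) <- NULL
  list(network = net,
       truth = list(planted_commonality_pairs = pairs,
                    n_background = n_background,
                    p_background = p_background,
                    n_motifs = n_motifs, fan_size = fan_size, seed = seed))
}

#' Synthetic annotation generator with planted per-loop consensus
#'
#' Every protein receives a private term unique to it; each triangle of
#' the network, independently with probability `p_consensus`, receives
#' a fresh term shared by exactly its three members. Decoy terms
#' (`n_terms` of them, each a unique identifier attached to one random
#' protein) add annotation bulk without ever creating consensus, so a
#' loop has consensus if and only if it was selected - the per-loop
#' consensus events are exact independent Bernoulli(p_consensus)
#' draws.
#'
#' @param network a [ppi_network()].
#' @param n_terms number of decoy term assignments.
#' @param p_consensus per-loop consensus probability.
#' @param seed RNG seed.
#' @return list with `annotations` (named list protein -> terms) and
#'   `truth` (logical vector: which loops, in the canonical order of
#'   [enumerate_short_loops()], were planted consensual).
#' @export
gen_annotations <- function(network, n_terms = 0, p_consensus = 0.5,
                            seed = NULL) {
  loops <- enumerate_short_loops(network, k = 3)
  nodes <- network$nodes
  ann <- stats::setNames(lapply(nodes, function(p) paste0("PRIV:", p)),
                         nodes)
  planted <- logical(nrow(loops))
  with_seed(seed, {
    if (nrow(loops)) {
      planted <- stats::runif(nrow(loops)) < p_consensus
      for (i in which(planted)) {
        term <- sprintf("CONS:%06d", i)
        for (p in loops[i, ]) ann[[p]] <- c(ann[[p]], term)
      }
    }
    if (n_terms > 0) {
      tgt <- sample(nodes, n_terms, replace = TRUE)
      for (j in seq_len(n_terms))
        ann[[tgt[j]]] <- c(ann[[tgt[j]]], sprintf("DECOY:%06d", j))
    }
  })
  list(annotations = ann,
       truth = list(planted_consensus = planted,
                    p_consensus = p_consensus, n_terms = n_terms,
                    seed = seed))
}

#' Synthetic mutation-record generator with planted hotspots
#'
#' Allocates `round(hotspot_mass * n_records)` records to the planted
#' hotspot positions (cycled deterministically, so the achieved MHRD is
#' exact by construction) and the remaining records uniformly over the
#' non-hotspot positions. Sample ids `S001..` are cycled over
#' `n_samples`.
#'
#' @param protein_length protein length in residues.
#' @param n_records number of mutation records.
#' @param hotspot_positions planted hotspot positions (may be empty).
#' @param hotspot_mass fraction of records placed on hotspots.
#' @param n_samples number of distinct sample ids.
#' @param seed RNG seed.
#' @param protein accession used for the `protein` column.
#' @return a `mutation_records` data.frame.
#' @export
gen_mutations <- function(protein_length, n_records, hotspot_positions,
                          hotspot_mass, n_samples, seed = NULL,
                          protein = "PROT1") {
  hot <- unique(as.integer(hotspot_positions))
  cold <- setdiff(seq_len(protein_length), hot)
  n_hot <- if (length(hot)) round(hotspot_mass * n_records) else 0L
  if (n_hot > 0 && length(hot) == 0L)
    stop("hotspot mass requested but no hotspot positions")
  if (n_records - n_hot > 0 && length(cold) == 0L)
    stop("no non-hotspot positions available")
  pos <- with_seed(seed, {
    c(if (n_hot) rep_len(hot, n_hot),
      if (n_records - n_hot) cold[sample.int(length(cold),
                                             n_records - n_hot,
                                             replace = TRUE)])
  })
  df <- data.frame(protein = protein,
                   sample_id = sprintf("S%03d",
                                       rep_len(seq_len(n_samples), n_records)),
                   position = as.integer(pos),
                   mutation_type = "substitution_missense",
                   aa_change = NA_character_,
                   stringsAsFactors = FALSE)
  df <- df[order(df$protein, df$position, df$sample_id, method = "radix"), ]
  rownames(df) <- NULL
  class(df) <- c("mutation_records", "data.frame")
  df
}

#' Synthetic dependency-matrix generator with planted classes
#'
#' Builds a depmap-style score matrix in which planted mutually
#' exclusive pairs receive disjoint dependent-line blocks (`block_size`
#' lines each), planted co-occurring pairs a shared block, and every
#' other gene sparse dependence in at most one line (so decoy pairs
#' classify as "neither"). Dependent entries score in (-2, -1.2),
#' others in (-0.3, 0.3); `noise_rate` flips each entry's dependence
#' state independently.
#'
#' @param n_lines number of cell lines.
#' @param genes character vector of gene labels.
#' @param planted data.frame with columns `x`, `y`, `class`
#'   (`"mutual_exclusive"` or `"co_occurring"`); genes must appear in
#'   `genes` and in at most one planted pair.
#' @param noise_rate per-entry flip probability (default 0).
#' @param block_size dependent lines per planted arm/block (default 2).
#' @param seed RNG seed.
#' @return list with `scores` (numeric matrix, lines x genes) and
#'   `truth` (the planted data.frame plus parameters).
#' @export
gen_dependency <- function(n_lines, genes, planted = NULL, noise_rate = 0,
                           block_size = 2, seed = NULL) {
  genes <- as.character(genes)
  dep <- matrix(FALSE, n_lines, length(genes),
                dimnames = list(sprintf("CL%03d", seq_len(n_lines)), genes))
  nxt <- 1L
  take <- function(k) {
    if (nxt + k - 1L > n_lines)
      stop("not enough cell lines for the planted blocks")
    out <- nxt:(nxt + k - 1L); nxt <<- nxt + k; out
  }
  if (!is.null(planted) && nrow(planted)) {
    pg <- c(planted$x, planted$y)
    if (anyDuplicated(pg)) stop("a gene may appear in one planted pair only")
    if (!all(pg %in% genes)) stop("planted genes must be listed in `genes`")
    for (i in seq_len(nrow(planted))) {
      x <- planted$x[i]; y <- planted$y[i]
      if (planted$class[i] == "mutual_exclusive") {
        dep[take(block_size), x] <- TRUE
        dep[take(block_size), y] <- TRUE
      } else if (planted$class[i] == "co_occurring") {
        rows <- take(block_size)
        dep[rows, x] <- TRUE
        dep[rows, y] <- TRUE
      } else stop("unknown planted class: ", planted$class[i])
    }
  }
  scores <- with_seed(seed, {
    decoys <- setdiff(genes, if (is.null(planted)) character()
                      else c(planted$x, planted$y))
    for (g in decoys) {
      if (stats::runif(1) < 0.5)
        dep[sample.int(n_lines, 1L), g] <- TRUE
    }
    if (noise_rate > 0) {
      flip <- matrix(stats::runif(length(dep)) < noise_rate,
                     nrow(dep), ncol(dep))
      dep <- xor(dep, flip)
    }
    s <- matrix(stats::runif(length(dep), -0.3, 0.3),
                nrow(dep), ncol(dep), dimnames = dimnames(dep))
    s[dep] <- stats::runif(sum(dep), -2, -1.2)
    s
  })
  list(scores = scores,
       truth = list(planted = planted, n_lines = n_lines,
                    noise_rate = noise_rate, block_size = block_size,
                    seed = seed))
}

#' Write synthetic inputs in the package's file formats
#'
#' Writes a mutation table, a protein length table, an annotation table
#' or a dependency matrix in exactly the format the corresponding
#' reader consumes, so round trips exercise the public I/O surface.
#'
#' @param records `mutation_records` data.frame.
#' @param path output file.
#' @name write_inputs
#' @export
write_mutation_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_inputs
#' @param lengths named vector protein -> length.
#' @export
write_protein_lengths <- function(lengths, path) {
  utils::write.table(data.frame(protein = names(lengths),
                                length = as.integer(lengths)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_inputs
#' @param annotations named list protein -> terms.
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(protein = rep(names(annotations), lengths(annotations)),
                   term = unlist(annotations, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_inputs
#' @param scores numeric matrix, cell lines x genes.
#' @export
write_dependency_matrix <- function(scores, path) {
  df <- data.frame(cell_line = rownames(scores), scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
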