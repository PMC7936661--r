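#' Non-synonymous mutation types admitted by default
#'
#' The amino-acid-changing mutation classes retained when reading a
#' mutation table: nonsense and missense substitutions, in-frame and
#' frameshift insertions and deletions, complex/compound mutations, and
#' the rare whole-gene deletion and nonstop-extension classes.
#'
#' @return character vector of normalized type labels (lower case,
#'   underscores).
#' @export
mutation_types <- function() {
  c("substitution_nonsense", "substitution_missense",
    "insertion_inframe", "insertion_frameshift",
    "deletion_inframe", "deletion_frameshift",
    "complex", "compound",
    "whole_gene_deletion", "nonstop_extension")
}

normalize_type <- function(x) gsub("[ -]+", "_", tolower(trimws(x)))

#' Read a per-sample mutation table
#'
#' TSV with columns `protein`, `sample_id`, `position` (1-based
#' amino-acid index), `mutation_type` and optional `aa_change`. Rows
#' with a type outside `allowed_types` are skipped (count reported via
#' `message`); proteins observed in fewer than `min_patients` distinct
#' samples are removed entirely, so that single-case observations never
#' enter downstream statistics.
#'
#' @param path input TSV (header required).
#' @param allowed_types admitted mutation-type labels; compared after
#'   normalization to lower case/underscores.
#' @param min_patients minimum number of distinct sample ids per
#'   protein (default 2).
#' @return data.frame of class `mutation_records` with columns
#'   `protein`, `sample_id`, `position`, `mutation_type`, `aa_change`,
#'   sorted by protein then position.
#' @export
read_mutation_table <- function(path, allowed_types = mutation_types(),
                                min_patients = 2) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("protein", "sample_id", "position", "mutation_type")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("mutation table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"aa_change" %in% names(df)) df$aa_change <- NA_character_
  df$mutation_type <- normalize_type(df$mutation_type)
  known <- df$mutation_type %in% normalize_type(allowed_types)
  if (any(!known))
    message(sum(!known), " row(s) skipped: mutation type outside allowed set")
  df <- df[known, , drop = FALSE]
  df$position <- as.integer(df$position)
  if (any(is.na(df$position) | df$position < 1))
    stop("positions must be 1-based positive integers")
  npat <- vapply(split(df$sample_id, df$protein),
                 function(s) length(unique(s)), integer(1))
  keep_prot <- names(npat)[npat >= min_patients]
  df <- df[df$protein %in% keep_prot, , drop = FALSE]
  df <- df[order(df$protein, df$position, df$sample_id, method = "radix"),
           c("protein", "sample_id", "position", "mutation_type", "aa_change")]
  rownames(df) <- NULL
  class(df) <- c("mutation_records", "data.frame")
  df
}

#' Length-normalized nsSNV frequency
#'
#' Number of non-synonymous variants divided by the protein's length in
#' residues, under the assumption that mutability scales with protein
#' size.
#'
#' @param n_variants variant count.
#' @param protein_length length in amino acids (> 0).
#' @return per-residue frequency.
#' @export
nsnv_frequency <- function(n_variants, protein_length) {
  if (any(protein_length <= 0)) stop("protein length must be positive")
  n_variants / protein_length
}

#' Detect mutation hotspot positions of one protein
#'
#' A hotspot is an amino-acid position carrying a disproportionate
#' share of the protein's mutations: at least `min_fraction` of all its
#' records, observed in at least `min_samples` distinct samples.
#'
#' @param records mutation records of a single protein (data.frame with
#'   `position` and `sample_id`).
#' @param min_fraction minimum share of the protein's mutations at the
#'   position (default 0.05).
#' @param min_samples minimum distinct samples at the position
#'   (default 2).
#' @return sorted integer vector of hotspot positions.
#' @export
detect_hotspots <- function(records, min_fraction = 0.05, min_samples = 2) {
  if (nrow(records) == 0L) stop("no mutation records")
  if ("protein" %in% names(records) &&
      length(unique(records$protein)) > 1L)
    stop("detect_hotspots() expects records of a single protein")
  total <- nrow(records)
  cnt <- table(records$position)
  nsamp <- vapply(split(records$sample_id, records$position),
                  function(s) length(unique(s)), integer(1))
  pos <- names(cnt)[as.integer(cnt) >= min_fraction * total &
                    nsamp[names(cnt)] >= min_samples]
  sort(as.integer(pos))
}

#' Mutation hotspot ratio density (MHRD)
#'
#' Fraction of a protein's mutation records that fall on its hotspot
#' positions: mutations at hotspots / all mutations of the protein.
#'
#' @param records mutation records of one protein.
#' @param hotspot_positions integer vector of hotspot positions.
#' @return fraction in [0, 1].
#' @export
mhrd <- function(records, hotspot_positions) {
  if (nrow(records) == 0L) stop("no mutation records")
  sum(records$position %in% hotspot_positions) / nrow(records)
}

#' Significance of the observed MHRD under a uniform null
#'
#' Simulates `n_sims` placements of the protein's N mutation records,
#' each record landing uniformly and independently on positions
#' 1..`protein_length`, and measures the mass falling on the FIXED
#' observed hotspot positions (the hotspot set is not re-detected per
#' simulation). Returns the z-score of the observed MHRD against the
#' simulated null and an add-one-smoothed empirical p-value,
#' (r + 1) / (n_sims + 1) with r the number of simulations reaching the
#' observed MHRD.
#'
#' @param records mutation records of one protein.
#' @param hotspot_positions fixed hotspot positions.
#' @param protein_length protein length in residues (>= 1).
#' @param n_sims number of simulations (>= 100; default 10000).
#' @param seed RNG seed.
#' @return object of class `hotspot_significance`: list with
#'   `observed` (MHRD), `z`, `p_empirical`, `null_mean`, `null_sd`,
#'   `n_sims`, `seed`, and `degenerate` (TRUE when the null sd is 0, in
#'   which case `z` is a signed infinity or 0).
#' @export
hotspot_significance <- function(records, hotspot_positions, protein_length,
                                 n_sims = 10000, seed = NULL) {
  if (protein_length < 1) stop("protein length must be >= 1")
  if (n_sims < 100) stop("use at least 100 simulations")
  n <- nrow(records)
  if (n == 0L) stop("no mutation records")
  observed <- mhrd(records, hotspot_positions)
  hot <- unique(as.integer(hotspot_positions))
  null_stat <- with_seed(seed, {
    out <- numeric(n_sims)
    block <- max(1L, min(n_sims, as.integer(5e6 / n)))
    done <- 0L
    while (done < n_sims) {
      b <- min(block, n_sims - done)
      pos <- matrix(sample.int(protein_length, n * b, replace = TRUE),
                    nrow = n)
      out[done + seq_len(b)] <- colSums(matrix(pos %in% hot, nrow = n)) / n
      done <- done + b
    }
    out
  })
  nm <- mean(null_stat)
  ns <- stats::sd(null_stat)
  degenerate <- is.na(ns) || ns == 0
  z <- if (degenerate) {
    if (observed == nm) 0 else sign(observed - nm) * Inf
  } else (observed - nm) / ns
  p <- (sum(null_stat >= observed) + 1) / (n_sims + 1)
  structure(list(observed = observed, z = z, p_empirical = p,
                 null_mean = nm, null_sd = ns, n_sims = n_sims,
                 seed = seed, degenerate = degenerate),
            class = "hotspot_significance")
}

#' @export
print.hotspot_significance <- function(x, ...) {
  cat(sprintf("MHRD %.4f vs uniform null (mean %.4f, sd %.4g): z = %.2f, p = %.4g [%d sims]\n",
              x$observed, x$null_mean, x$null_sd, x$z, x$p_empirical,
              x$n_sims))
  if (x$degenerate) cat("  (degenerate null: sd = 0)\n")
  invisible(x)
}

#' Read a protein length table
#' @param path TSV with columns `protein`, `length`.
#' @return named integer vector, protein -> length in residues.
#' @export
read_protein_lengths <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("protein", "length") %in% names(df)))
    stop("length table needs columns protein, length")
  stats::setNames(as.integer(df$length), df$protein)
}

#' Hotspot report across proteins
#'
#' Runs [detect_hotspots()], [mhrd()] and [hotspot_significance()] per
#' protein of a mutation table.
#'
#' @param records a `mutation_records` data.frame (several proteins).
#' @param lengths named vector protein -> length (see
#'   [read_protein_lengths()]); proteins without a length are skipped
#'   with a message.
#' @param min_fraction,min_samples hotspot rule, see [detect_hotspots()].
#' @param n_sims,seed null simulation, see [hotspot_significance()].
#' @return data.frame with one row per protein: `protein`, `n_records`,
#'   `hotspots` (comma-separated), `mhrd`, `z`, `p_empirical`,
#'   `n_sims`, `seed`.
#' @export
hotspot_report <- function(records, lengths, min_fraction = 0.05,
                           min_samples = 2, n_sims = 10000, seed = NULL) {
  prots <- unique(records$protein)
  skip <- prots[!prots %in% names(lengths)]
  if (length(skip))
    message(length(skip), " protein(s) skipped: no length available")
  prots <- setdiff(prots, skip)
  rows <- lapply(seq_along(prots), function(i) {
    p <- prots[i]
    rec <- records[records$protein == p, , drop = FALSE]
    hs <- detect_hotspots(rec, min_fraction, min_samples)
    sig <- hotspot_significance(rec, hs, lengths[[p]], n_sims = n_sims,
                                seed = if (is.null(seed)) NULL else seed + i)
    data.frame(protein = p, n_records = nrow(rec),
               hotspots = paste(hs, collapse = ","),
               mhrd = sig$observed, z = sig$z,
               p_empirical = sig$p_empirical, n_sims = n_sims,
               seed = if (is.null(seed)) NA_integer_ else seed + i,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
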