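# evaluate code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Null distribution of a statistic over random subnetworks
#'
#' Draws `n_samples` uniform random node subsets of size `n_proteins`
#' (without replacement within a sample, independently across samples),
#' induces the subnetwork of each, and evaluates the statistic:
#' `"loop3_ratio"` (triangles / interactions) or
#' `"mean_neighbours_commonality"` (mean degree of the commonality
#' network of the sample, under `min_shared`/`min_frac`). Samples on
#' which the statistic is undefined (no interactions, or no commonality
#' nodes) score 0 and are counted in `n_degenerate`.
#'
#' @param network a [ppi_network()].
#' @param n_proteins nodes per sample (at most `n_nodes(network)`).
#' @param n_samples number of samples (>= 2).
#' @param statistic `"loop3_ratio"` or `"mean_neighbours_commonality"`.
#' @param seed RNG seed for reproducibility.
#' @param min_shared,min_frac commonality thresholds (used by the
#'   commonality statistic only).
#' @return object of class `null_distribution`: list with
#'   `statistic_name`, `samples`, `n_samples`, `mean`, `sd` (n-1
#'   denominator), `se`, `seed`, `n_degenerate`.
#' @export
sample_random_subnetworks <- function(network, n_proteins, n_samples,
                                      statistic = c("loop3_ratio",
                                                    "mean_neighbours_commonality"),
                                      seed = NULL, min_shared = 3,
                                      min_frac = 0.95) {
  stopifnot(inherits(network, "ppi_network"))
  statistic <- match.arg(statistic)
  if (n_proteins > n_nodes(network))
    stop("n_proteins exceeds the number of proteins in the network")
  if (n_samples < 2) stop("need at least 2 samples")
  degenerate <- 0L
  eval_one <- function(sub) {
    if (statistic == "loop3_ratio") {
      if (n_edges(sub) == 0L) {
        degenerate <<- degenerate + 1L
        return(0)
      }
      loop_ratio(nrow(enumerate_short_loops(sub, 3)), n_edges(sub))
    } else {
      pr <- find_commonality_pairs(sub, min_shared = min_shared,
                                   min_frac = min_frac)
      if (nrow(pr) == 0L) {
        degenerate <<- degenerate + 1L
        return(0)
      }
      commonality_network(pr)$mean_neighbours
    }
  }
  samples <- with_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      sub <- induce_subnetwork(network,
                               sample(network$nodes, n_proteins))
      eval_one(sub)
    }, numeric(1))
  })
  m <- mean(samples)
  s <- stats::sd(samples)
  structure(list(statistic_name = statistic,
                 samples = samples,
                 n_samples = n_samples,
                 mean = m, sd = s, se = s / sqrt(n_samples),
                 seed = seed, n_degenerate = degenerate),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Null distribution of", x$statistic_name, "\n")
  cat(sprintf("  n = %d samples: mean %.4f, sd %.4f, se %.4g\n",
              x$n_samples, x$mean, x$sd, x$se))
  if (x$n_degenerate > 0)
    cat("  ", x$n_degenerate, "degenerate sample(s) scored 0\n")
  invisible(x)
}

#' z-score of an observed statistic against a null distribution
#'
#' @param observed observed value.
#' @param null a `null_distribution` (or any list with `mean` and `sd`).
#' @return `(observed - mean) / sd`. When `sd` is zero, a signed
#'   infinity is returned with a warning (0 when observed equals the
#'   mean).
#' @export
z_score <- function(observed, null) {
  if (is.na(null$sd) || null$sd == 0) {
    warning("null distribution has zero standard deviation; ",
            "z-score is a signed infinity")
    d <- observed - null$mean
    return(if (d == 0) 0 else sign(d) * Inf)
  }
  (observed - null$mean) / null$sd
}
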