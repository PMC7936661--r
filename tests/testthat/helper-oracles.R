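# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# all triangles by exhaustive scan over node triples (vectorized via a
# dense adjacency matrix; shares nothing with the package internals)
oracle_triangles <- function(net) {
  nd <- sort(net$nodes, method = "radix")
  n <- length(nd)
  if (n < 3) return(matrix(character(), ncol = 3))
  M <- matrix(FALSE, n, n, dimnames = list(nd, nd))
  if (nrow(net$edges)) {
    M[cbind(net$edges$a, net$edges$b)] <- TRUE
    M[cbind(net$edges$b, net$edges$a)] <- TRUE
  }
  tri <- combn(n, 3)
  keep <- M[t(tri[c(1, 2), ])] & M[t(tri[c(1, 3), ])] & M[t(tri[c(2, 3), ])]
  out <- matrix(nd[t(tri[, keep, drop = FALSE])], ncol = 3)
  out[do.call(order, c(split(out, col(out)), list(method = "radix"))), ,
      drop = FALSE]
}

# one-sided / two-sided Fisher p by full enumeration of tables with the
# observed margins, using hypergeometric point probabilities from choose()
oracle_fisher <- function(n_both, n_x_only, n_y_only, n_neither, side) {
  m1 <- n_both + n_x_only            # margin: X dependent
  m2 <- n_y_only + n_neither         # margin: X not dependent
  k <- n_both + n_y_only             # margin: Y dependent
  N <- m1 + m2
  lo <- max(0, k - m2); hi <- min(k, m1)
  support <- lo:hi
  pr <- choose(m1, support) * choose(m2, k - support) / choose(N, k)
  obs <- which(support == n_both)
  switch(side,
         greater = sum(pr[support >= n_both]),
         less = sum(pr[support <= n_both]),
         `two-sided` = sum(pr[pr <= pr[obs] * (1 + 1e-7)]))
}

# commonality pairs by exhaustive pair scan built on the triangle oracle
oracle_commonality <- function(net, min_shared = 3, min_frac = 0.95) {
  tri <- oracle_triangles(net)
  sets <- list()
  if (nrow(tri)) {
    for (i in seq_len(nrow(tri))) {
      t <- tri[i, ]
      for (j in 1:3) {
        o <- t[j]; rest <- sort(t[-j], method = "radix")
        sets[[o]] <- union(sets[[o]], paste(rest[1], rest[2], sep = "|"))
      }
    }
  }
  ek <- paste(net$edges$a, net$edges$b, sep = "\r")
  prots <- if (length(sets)) sort(names(sets), method = "radix")
           else character()
  out <- NULL
  if (length(prots) >= 2) {
    for (i in seq_along(prots)) for (j in seq_along(prots)) {
      if (j <= i) next
      x <- prots[i]; y <- prots[j]
      if (paste(x, y, sep = "\r") %in% ek) next
      sh <- length(intersect(sets[[x]], sets[[y]]))
      if (sh >= min_shared && sh >= min_frac * length(sets[[x]]) &&
          sh >= min_frac * length(sets[[y]]))
        out <- rbind(out, data.frame(x = x, y = y, shared = sh,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) data.frame(x = character(), y = character(),
                               shared = integer()) else out
}

# random graph helper on letter-ish node names (exercises non-trivial
# label ordering)
random_net <- function(n, p) {
  nodes <- sprintf("N%02d", sample(seq_len(3 * n), n))
  if (n < 2) return(ppi_network(nodes = nodes))
  idx <- combn(n, 2)
  keep <- runif(ncol(idx)) < p
  ppi_network(cbind(nodes[idx[1, keep]], nodes[idx[2, keep]]),
              nodes = nodes)
}

# complete graph
complete_net <- function(labels) ppi_network(t(combn(labels, 2)))

fig3a_network <- function(extra_xy_edge = FALSE) {
  ch <- c("A", "B", "C", "D")
  ed <- rbind(cbind(ch[-4], ch[-1]), cbind("X", ch), cbind("Y", ch))
  if (extra_xy_edge) ed <- rbind(ed, c("X", "Y"))
  ppi_network(ed)
}
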