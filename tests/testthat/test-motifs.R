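test_that("triangle counts on canonical small graphs", {
  expect_equal(nrow(enumerate_short_loops(complete_net(c("A", "B", "C")))), 1L)
  k4 <- complete_net(c("A", "B", "C", "D"))
  expect_equal(nrow(enumerate_short_loops(k4, 3)), 4L)   # C(4,3)
  expect_equal(nrow(enumerate_short_loops(k4, 4)), 3L)   # 3 Hamiltonian 4-cycles
  expect_equal(nrow(enumerate_short_loops(ppi_network(), 3)), 0L)
  expect_error(enumerate_short_loops(k4, 5), "3 or 4")
})

test_that("triangle enumeration equals the exhaustive-triple oracle", {
  set.seed(101)
  for (i in 1:60) {
    net <- random_net(sample(4:25, 1), runif(1, 0.05, 0.5))
    got <- enumerate_short_loops(net, 3)
    want <- oracle_triangles(net)
    expect_equal(unname(got), unname(want))
    # counting cross-check against igraph
    expect_equal(nrow(got),
                 length(igraph::triangles(as_igraph(net))) / 3L)
  }
})

test_that("4-cycle enumeration is correct with and without chords", {
  # C4 (square): one 4-cycle, chordless or not
  sq <- ppi_network(rbind(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "A")))
  expect_equal(nrow(enumerate_short_loops(sq, 4)), 1L)
  expect_equal(nrow(enumerate_short_loops(sq, 4, chordless = TRUE)), 1L)
  # K4: 3 with chords allowed, 0 chordless
  k4 <- complete_net(c("A", "B", "C", "D"))
  expect_equal(nrow(enumerate_short_loops(k4, 4)), 3L)
  expect_equal(nrow(enumerate_short_loops(k4, 4, chordless = TRUE)), 0L)
  # K5 has 3 * C(5,4) = 15 4-cycles
  k5 <- complete_net(LETTERS[1:5])
  expect_equal(nrow(enumerate_short_loops(k5, 4)), 15L)
  # oracle by brute force over 4-permutations on random graphs
  set.seed(55)
  for (i in 1:10) {
    net <- random_net(9, 0.4)
    got <- enumerate_short_loops(net, 4)
    nd <- net$nodes
    ek <- paste(net$edges$a, net$edges$b, sep = "\r")
    has <- function(x, y) paste(min(x, y), max(x, y), sep = "\r") %in% ek
    cnt <- 0L
    if (length(nd) >= 4) {
      qs <- combn(nd, 4)
      for (j in seq_len(ncol(qs))) {
        q <- qs[, j]
        # 3 distinct cycle structures on 4 labelled nodes
        for (ord in list(q, q[c(1, 2, 4, 3)], q[c(1, 3, 2, 4)])) {
          if (has(ord[1], ord[2]) && has(ord[2], ord[3]) &&
              has(ord[3], ord[4]) && has(ord[4], ord[1]))
            cnt <- cnt + 1L
        }
      }
    }
    expect_equal(nrow(got), cnt)
  }
})

test_that("canonicalization survives relabelling round trips", {
  set.seed(21)
  net <- random_net(15, 0.3)
  loops1 <- enumerate_short_loops(net, 3)
  # relabel, enumerate, map back: same canonical set
  perm <- setNames(sprintf("Q%02d", sample(n_nodes(net))), net$nodes)
  rel <- ppi_network(cbind(perm[net$edges$a], perm[net$edges$b]))
  loops2 <- enumerate_short_loops(rel, 3)
  inv <- setNames(names(perm), perm)
  back <- t(apply(matrix(inv[loops2], ncol = 3), 1, sort))
  back <- back[do.call(order, split(back, col(back))), , drop = FALSE]
  expect_equal(unname(loops1), unname(back))
  # repeat enumeration is bit-identical
  expect_identical(loops1, enumerate_short_loops(net, 3))
})

test_that("triangle count is edge-monotone", {
  set.seed(31)
  net <- random_net(14, 0.35)
  n0 <- nrow(enumerate_short_loops(net, 3))
  # deleting any edge never increases the count
  for (i in seq_len(min(10, n_edges(net)))) {
    smaller <- ppi_network(as.matrix(net$edges[-i, c("a", "b")]),
                           nodes = net$nodes)
    expect_lte(nrow(enumerate_short_loops(smaller, 3)), n0)
  }
  # adding an absent edge never decreases it
  all_pairs <- t(combn(net$nodes, 2))
  present <- paste(all_pairs[, 1], all_pairs[, 2], sep = "\r") %in%
    paste(net$edges$a, net$edges$b, sep = "\r")
  missing <- all_pairs[!present, , drop = FALSE]
  for (i in seq_len(min(10, nrow(missing)))) {
    bigger <- ppi_network(rbind(as.matrix(net$edges[, c("a", "b")]),
                                missing[i, ]))
    expect_gte(nrow(enumerate_short_loops(bigger, 3)), n0)
  }
})

test_that("loop ratio follows its definition and guards zero edges", {
  expect_equal(round(loop_ratio(17443, 14119), 2), 1.24)
  expect_equal(round(loop_ratio(228, 367), 2), 0.62)
  expect_equal(loop_ratio(0, 10), 0)
  expect_error(loop_ratio(5, 0), "undefined")
})

test_that("partner pairs decompose triangles symmetrically", {
  # chained fan: X forms loops with AB, BC, CD
  net <- fig3a_network()
  pp <- partner_pairs(enumerate_short_loops(net, 3))
  expect_equal(unname(pp[["X"]]),
               cbind(c("A", "B", "C"), c("B", "C", "D")))
  # K3: each node maps to the single opposite pair
  ppk <- partner_pairs(enumerate_short_loops(complete_net(c("A", "B", "C"))))
  expect_equal(unname(ppk[["A"]]), cbind("B", "C"))
  expect_equal(unname(ppk[["C"]]), cbind("A", "B"))
  # counting identity on a random graph: sum |pairs| = 3 * n_triangles
  set.seed(61)
  rnet <- random_net(20, 0.3)
  loops <- enumerate_short_loops(rnet, 3)
  expect_equal(sum(vapply(partner_pairs(loops), nrow, integer(1))),
               3L * nrow(loops))
  expect_error(partner_pairs(enumerate_short_loops(rnet, 4)), "length-3")
})

test_that("loop profile fills counts, ratio and closed forms", {
  k5 <- complete_net(LETTERS[1:5])
  prof <- loop_profile(k5, label = "K5")
  expect_equal(prof$n_loops, 10L)
  expect_equal(prof$n_edges, 10L)
  expect_equal(prof$ratio, 1)
  # K_n ratio = (n - 2) / 3
  for (n in c(4, 6, 9)) {
    kn <- complete_net(sprintf("P%02d", 1:n))
    expect_equal(loop_profile(kn)$ratio, (n - 2) / 3)
  }
  # consensus slot filled only with annotations
  expect_true(is.na(prof$consensus_pct))
  ann <- setNames(rep(list("T1"), 5), LETTERS[1:5])
  expect_equal(loop_profile(k5, annotations = ann)$consensus_pct, 100)
  expect_output(print(prof), "loop/PPI ratio")
})

test_that("profile of a planted network matches generator ground truth", {
  sim <- gen_planted_commonality(40, 0, n_motifs = 2, fan_size = 3, seed = 3)
  prof <- loop_profile(sim$network)
  # each motif: chain of 4 nodes, every chain edge closes one triangle
  # with X and one with Y -> 2 * fan_size triangles per motif
  expect_equal(prof$n_loops, 2L * 3L * 2L)
  expect_equal(prof$n_edges, n_edges(sim$network))
})
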