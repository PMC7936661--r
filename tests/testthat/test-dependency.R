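test_that("binarization is strict at the threshold and keeps NA", {
  m <- matrix(c(-1.2, -1.0, 0, NA), 2, 2,
              dimnames = list(c("L1", "L2"), c("g1", "g2")))
  b <- binarize_dependency(m)
  expect_true(b["L1", "g1"])       # -1.2 dependent
  expect_false(b["L2", "g1"])      # exactly -1: NOT dependent
  expect_false(b["L1", "g2"])      # 0 not dependent
  expect_true(is.na(b["L2", "g2"]))
  # moving the threshold flips only boundary cells
  b2 <- binarize_dependency(m, threshold = -0.999999)
  expect_true(b2["L2", "g1"])
  expect_error(binarize_dependency(m, Inf), "finite")
})

test_that("contingency tables count pairwise-complete lines", {
  sc <- rbind(c(-2, -2), c(-2, 0), c(0, -2), c(0, 0), c(NA, -2))
  dimnames(sc) <- list(sprintf("L%d", 1:5), c("gx", "gy"))
  b <- binarize_dependency(sc)
  ct <- pair_contingency(b, "gx", "gy")
  expect_equal(ct, c(n_both = 1L, n_x_only = 1L, n_y_only = 1L,
                     n_neither = 1L))
  # hand-built corner cases
  sc2 <- rbind(c(-2, -2), c(-2, -2), c(0, 0))
  dimnames(sc2) <- list(sprintf("L%d", 1:3), c("gx", "gy"))
  expect_equal(pair_contingency(binarize_dependency(sc2), "gx", "gy"),
               c(n_both = 2L, n_x_only = 0L, n_y_only = 0L,
                 n_neither = 1L))
  sc3 <- rbind(c(-2, 0), c(-2, 0), c(0, -2))
  dimnames(sc3) <- list(sprintf("L%d", 1:3), c("gx", "gy"))
  expect_equal(pair_contingency(binarize_dependency(sc3), "gx", "gy"),
               c(n_both = 0L, n_x_only = 2L, n_y_only = 1L,
                 n_neither = 0L))
  expect_error(pair_contingency(b, "gx", "nope"), "unknown gene")
})

test_that("Fisher p-values match the frozen enumeration values", {
  expect_equal(fisher_exact(c(n_both = 3, n_x_only = 1, n_y_only = 1,
                              n_neither = 3), "greater"), 17 / 70)
  expect_equal(fisher_exact(c(n_both = 0, n_x_only = 5, n_y_only = 5,
                              n_neither = 0), "less"), 1 / 252)
  # zero margin -> p = 1 (all sides)
  for (s in c("two-sided", "greater", "less"))
    expect_equal(fisher_exact(c(n_both = 0, n_x_only = 0, n_y_only = 3,
                                n_neither = 7), s), 1)
  expect_error(fisher_exact(c(n_both = -1, n_x_only = 0, n_y_only = 0,
                              n_neither = 1)), "non-negative")
})

test_that("Fisher test equals full hypergeometric enumeration (N <= 30)", {
  # systematic sweep over small tables plus a random sample of larger ones
  tabs <- expand.grid(a = 0:4, b = 0:4, c = 0:4, d = 0:4)
  set.seed(17)
  big <- data.frame(a = sample(0:12, 150, TRUE), b = sample(0:12, 150, TRUE),
                    c = sample(0:12, 150, TRUE), d = sample(0:12, 150, TRUE))
  tabs <- rbind(tabs, big[rowSums(big) <= 30, ])
  for (i in seq_len(nrow(tabs))) {
    ct <- c(n_both = tabs$a[i], n_x_only = tabs$b[i],
            n_y_only = tabs$c[i], n_neither = tabs$d[i])
    for (s in c("greater", "less", "two-sided")) {
      expect_equal(fisher_exact(ct, s),
                   oracle_fisher(ct[1], ct[2], ct[3], ct[4], s),
                   tolerance = 1e-9)
    }
  }
})

test_that("pair classification follows the count criteria", {
  # mutual exclusivity: disjoint dependence, both arms > 1 line, caps ok
  me <- classify_pair(c(n_both = 0, n_x_only = 3, n_y_only = 4,
                        n_neither = 60), n_lines = 67)
  expect_equal(me$klass, "mutual_exclusive")
  # co-occurrence: > 1 co-dependent line below the essentiality cap
  co <- classify_pair(c(n_both = 2, n_x_only = 1, n_y_only = 0,
                        n_neither = 64), n_lines = 67)
  expect_equal(co$klass, "co_occurring")
  # essentiality cap: a gene dependent in 40 of 67 lines is "neither"
  ess <- classify_pair(c(n_both = 0, n_x_only = 40, n_y_only = 4,
                         n_neither = 23), n_lines = 67)
  expect_equal(ess$klass, "neither")
  # exactly half the lines violates the strict < 50% cap
  half <- classify_pair(c(n_both = 0, n_x_only = 5, n_y_only = 2,
                          n_neither = 3), n_lines = 10)
  expect_equal(half$klass, "neither")
  # one arm with a single line: not mutual exclusivity
  arm <- classify_pair(c(n_both = 0, n_x_only = 3, n_y_only = 1,
                         n_neither = 63), n_lines = 67)
  expect_equal(arm$klass, "neither")
  # one co-dependent line is not co-occurrence
  co1 <- classify_pair(c(n_both = 1, n_x_only = 0, n_y_only = 0,
                         n_neither = 66), n_lines = 67)
  expect_equal(co1$klass, "neither")
  # overlap tolerance is configurable
  tol <- classify_pair(c(n_both = 1, n_x_only = 3, n_y_only = 3,
                         n_neither = 60), n_lines = 67, max_overlap = 1)
  expect_equal(tol$klass, "mutual_exclusive")
  expect_output(print(me), "mutual_exclusive")
})

test_that("classification is symmetric in gene order", {
  set.seed(23)
  for (i in 1:25) {
    ct <- c(n_both = sample(0:3, 1), n_x_only = sample(0:6, 1),
            n_y_only = sample(0:6, 1), n_neither = sample(10:40, 1))
    sw <- ct[c("n_both", "n_y_only", "n_x_only", "n_neither")]
    names(sw) <- names(ct)
    expect_equal(classify_pair(ct)$klass, classify_pair(sw)$klass)
  }
})

test_that("screening recovers planted dependency classes exactly", {
  planted <- data.frame(x = c("gA", "gC", "gE"), y = c("gB", "gD", "gF"),
                        class = c("mutual_exclusive", "mutual_exclusive",
                                  "co_occurring"),
                        stringsAsFactors = FALSE)
  genes <- c(planted$x, planted$y, sprintf("decoy%02d", 1:8))
  sim <- gen_dependency(67, genes, planted, noise_rate = 0, seed = 19)
  b <- binarize_dependency(sim$scores)
  pairs <- rbind(planted[, c("x", "y")],
                 data.frame(x = sprintf("decoy%02d", c(1, 3, 5)),
                            y = sprintf("decoy%02d", c(2, 4, 6))))
  calls <- screen_pairs(b, pairs)
  expect_equal(calls$klass[1:3], planted$class)
  expect_true(all(calls$klass[4:6] == "neither"))
  s <- attr(calls, "summary")
  expect_equal(unname(s["mutual_exclusive"]), 2L)
  expect_equal(unname(s["co_occurring"]), 1L)
  expect_output(print(calls), "2 mutually exclusive")
})

test_that("screening guards degenerate input and missing genes", {
  sim <- gen_dependency(10, c("g1", "g2"), seed = 2)
  b <- binarize_dependency(sim$scores)
  expect_error(screen_pairs(b, cbind("g1", "g1")), "degenerate")
  expect_message(out <- screen_pairs(b, rbind(c("g1", "g2"),
                                              c("g1", "gX"))),
                 "skipped")
  expect_equal(nrow(out), 1L)
  empty <- screen_pairs(b, matrix(character(), ncol = 2))
  expect_equal(nrow(empty), 0L)
})

test_that("dependency matrices round trip through CSV", {
  planted <- data.frame(x = "gA", y = "gB", class = "co_occurring",
                        stringsAsFactors = FALSE)
  sim <- gen_dependency(12, c("gA", "gB", "gC"), planted, seed = 31)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dependency_matrix(sim$scores, f)
  back <- read_dependency_matrix(f)
  expect_equal(back, sim$scores, tolerance = 1e-8)
  calls <- screen_pairs(binarize_dependency(back), cbind("gA", "gB"))
  expect_equal(calls$klass, "co_occurring")
})
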