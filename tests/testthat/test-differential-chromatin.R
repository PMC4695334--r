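mk_ct <- function(a, b, lib = NULL) {
  if (!is.matrix(a)) a <- matrix(a, ncol = 1)
  if (!is.matrix(b)) b <- matrix(b, ncol = 1)
  m <- cbind(a, b)
  colnames(m) <- c(sprintf("a.r%d", seq_len(ncol(a))),
                   sprintf("b.r%d", seq_len(ncol(b))))
  rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(lib)) lib <- rep(1e6, ncol(m))
  count_table(m, lib)
}

test_that("window count validation passes through and flags gaps", {
  ct <- mk_ct(matrix(1:4, 2), matrix(5:8, 2))
  out <- quantify_window_counts(c("g002", "g001"), ct)
  expect_equal(rownames(out$counts), c("g002", "g001"))
  expect_equal(out$counts["g001", ], ct$counts["g001", ])
  expect_error(quantify_window_counts(c("g001", "gX"), ct),
               "missing from count table")
})

test_that("replicate-free binomial test matches the exact tail oracle", {
  ct <- mk_ct(matrix(c(100, 30), 2), matrix(c(20, 30), 2))
  d <- differential_test(ct, c("a", "b"), a = "a", method = "binomial")
  # oracle: exact two-sided binomial tail by enumeration at p = 0.5
  tail_p <- function(k, n) {
    probs <- stats::dbinom(0:n, n, 0.5)
    sum(probs[probs <= probs[k + 1] + 1e-12])
  }
  expect_equal(d$p[1], tail_p(100, 120), tolerance = 1e-9)
  expect_equal(d$log2fc[1], log2(100.5 / 20.5), tolerance = 1e-9)
  expect_gt(d$log2fc[1], 2.2)
  # equal counts, equal libraries: symmetric null
  expect_equal(d$log2fc[2], 0)
  expect_equal(d$direction[2], "ns")
  # unequal library sizes shift the null success probability
  ct2 <- mk_ct(matrix(60, 1), matrix(30, 1), lib = c(2e6, 1e6))
  d2 <- differential_test(ct2, c("a", "b"), a = "a", method = "binomial")
  expect_equal(d2$p[1], stats::binom.test(60, 90, 2 / 3)$p.value)
  expect_equal(d2$log2fc[1], log2(30.5 / 30.5))
})

test_that("direction calls respect both the FDR and the effect floor", {
  set.seed(61)
  n <- 300
  mu_a <- rep(50, n); mu_a[1:30] <- 200
  a <- matrix(stats::rnbinom(3 * n, mu = mu_a, size = 20), n)
  b <- matrix(stats::rnbinom(3 * n, mu = 50, size = 20), n)
  ct <- mk_ct(a, b, lib = rep(1e6, 6))
  d <- differential_test(ct, rep(c("a", "b"), each = 3), a = "a")
  expect_true(mean(d$direction[1:30] == "higher_a") >= 0.9)
  expect_true(mean(d$direction[31:n] == "ns") >= 0.95)
  # direction requires the log2FC floor even when significant
  d_hi <- differential_test(ct, rep(c("a", "b"), each = 3), a = "a",
                            min_lfc = 3)
  expect_true(all(d_hi$direction[1:30] == "ns"))
})

test_that("swapping conditions flips directions and negates log2FC", {
  set.seed(62)
  a <- matrix(stats::rnbinom(60, mu = c(rep(200, 10), rep(50, 10)),
                             size = 20), 20)
  b <- matrix(stats::rnbinom(60, mu = 50, size = 20), 20)
  ct <- mk_ct(a, b, lib = rep(1e6, 6))
  side <- rep(c("a", "b"), each = 3)
  d1 <- differential_test(ct, side, a = "a")
  d2 <- differential_test(ct, side, a = "b")
  expect_equal(d1$log2fc, -d2$log2fc, tolerance = 1e-12)
  flip <- c(higher_a = "higher_b", higher_b = "higher_a", ns = "ns")
  expect_equal(d2$direction, unname(flip[d1$direction]))
})

test_that("epigenome sets apply the union and inversion rules", {
  mk_calls <- function(higher_a, higher_b, universe) {
    data.frame(window_id = universe, factor = NA,
               log2fc = 0, p = 1, fdr = 1,
               direction = ifelse(universe %in% higher_a, "higher_a",
                                  ifelse(universe %in% higher_b,
                                         "higher_b", "ns")),
               stringsAsFactors = FALSE)
  }
  u <- sprintf("g%02d", 1:10)
  calls <- list(
    SMAD3 = mk_calls("g01", "g02", u),
    H3K4me3 = mk_calls("g03", character(0), u),
    H3K27ac = mk_calls(c("g03", "g04"), "g05", u),
    POL2 = mk_calls(character(0), "g06", u),
    H3K27me3 = mk_calls(character(0), character(0), u),
    METH = mk_calls("g07", "g08", u))
  es <- build_epigenome_sets(calls)
  expect_equal(es$a$smad3_high, "g01")
  expect_equal(es$b$smad3_high, "g02")
  # open chromatin is the union over the three open factors
  expect_setequal(es$a$open_chromatin_high, c("g03", "g04"))
  expect_setequal(es$b$open_chromatin_high, c("g05", "g06"))
  # hypo-methylation inverts the methylation direction
  expect_equal(es$a$hypo_methylation, "g08")
  expect_equal(es$b$hypo_methylation, "g07")
  # a gene higher for one open mark only joins open, not smad3
  expect_false("g04" %in% es$a$smad3_high)
  expect_error(build_epigenome_sets(calls[-2]), "missing differential")
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # enumeration oracle over all draws
  enum_p <- function(N, m, s, k) {
    ks <- max(0, s - (N - m)):min(m, s)
    probs <- choose(m, ks) * choose(N - m, s - ks) / choose(N, s)
    sum(probs[ks >= k])
  }
  u <- sprintf("g%02d", 1:20)
  res <- gene_set_enrichment(u[1:5], u[c(1:4, 10)], u)
  expect_equal(res$p, enum_p(20, 5, 5, 4), tolerance = 1e-12)
  expect_equal(res$overlap, 4)
  # all universes <= 25, randomized sets
  set.seed(9)
  for (k in 1:50) {
    N <- sample(5:25, 1)
    u <- sprintf("g%02d", seq_len(N))
    m <- sample.int(N, 1); s <- sample.int(N, 1)
    ds <- sample(u, m); cs <- sample(u, s)
    ov <- length(intersect(ds, cs))
    expect_equal(gene_set_enrichment(ds, cs, u)$p, enum_p(N, m, s, ov),
                 tolerance = 1e-12)
  }
  # differential set == universe carries no information
  u <- sprintf("g%02d", 1:20)
  expect_equal(gene_set_enrichment(u, u[1:5], u)$p, 1)
  expect_error(gene_set_enrichment("gX", u[1:2], u), "subsets")
  expect_error(gene_set_enrichment(character(0), character(0),
                                   character(0)), "empty universe")
})

test_that("overlap at expectation is unremarkable", {
  set.seed(17)
  u <- sprintf("g%03d", 1:200)
  ds <- u[1:50]
  ps <- replicate(50, gene_set_enrichment(ds, sample(u, 40), u)$p)
  expect_gt(median(ps), 0.2)
})
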