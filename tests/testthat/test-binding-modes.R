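mk_windows <- function(gene_id, start, end, chrom = "chr1") {
  data.frame(gene_id = gene_id, kind = "gene_proximal", chrom = chrom,
             start = start, end = end, stringsAsFactors = FALSE)
}

mk_matches <- function(start, end, status, chrom = "chr1") {
  data.frame(match_id = sprintf("m%03d", seq_along(start)),
             peak_a = NA, peak_b = NA, status = status, chrom = chrom,
             start = start, end = end,
             summit = floor((start + end) / 2), stringsAsFactors = FALSE)
}

test_that("proximal assignment uses >= 1 bp overlap on half-open windows", {
  w <- mk_windows("g1", 3500, 8000)
  # 1 bp overlap at the left edge
  asg <- assign_proximal_peaks(w, mk_matches(3400, 3600, "shared"))
  expect_equal(nrow(asg), 1)
  # half-open: match starting exactly at window end is not assigned
  expect_equal(nrow(assign_proximal_peaks(
    w, mk_matches(8000, 8100, "unique_a"))), 0)
  # a match spanning two windows is assigned to both genes
  w2 <- mk_windows(c("g1", "g2"), c(1000, 2100), c(2000, 3000))
  both <- assign_proximal_peaks(w2, mk_matches(1900, 2200, "shared"))
  expect_setequal(both$gene_id, c("g1", "g2"))
  # containment rule excludes boundary-crossing matches
  cont <- assign_proximal_peaks(w, mk_matches(3400, 3600, "shared"),
                                rule = "containment")
  expect_equal(nrow(cont), 0)
})

test_that("assignment agrees with a brute-force overlap scan", {
  set.seed(77)
  for (k in 1:100) {
    n_g <- sample(2:50, 1)
    starts <- sort(sample.int(1e5, n_g))
    w <- mk_windows(sprintf("g%02d", seq_len(n_g)), starts,
                    starts + sample(500:3000, n_g, replace = TRUE))
    n_m <- sample(2:200, 1)
    ms <- sample.int(1e5, n_m)
    m <- mk_matches(ms, ms + sample(50:500, n_m, replace = TRUE),
                    sample(c("shared", "unique_a", "unique_b"), n_m,
                           replace = TRUE))
    asg <- assign_proximal_peaks(w, m)
    brute <- do.call(rbind, lapply(seq_len(n_g), function(i) {
      hit <- m$start < w$end[i] & w$start[i] < m$end
      if (!any(hit)) return(NULL)
      data.frame(gene_id = w$gene_id[i], match_id = m$match_id[hit])
    }))
    got <- paste(asg$gene_id, asg$match_id)
    want <- if (is.null(brute)) character(0)
    else paste(brute$gene_id, brute$match_id)
    expect_setequal(got, want)
  }
})

test_that("mode and category follow the presence rules", {
  cases <- list(
    list(c(2, 0, 0), 1, "a_only"),
    list(c(0, 1, 0), 2, "b_only"),
    list(c(0, 0, 3), 3, "identical"),
    list(c(1, 2, 0), 3, "mutually_exclusive"),
    list(c(1, 0, 2), 3, "mixed"),
    list(c(0, 1, 1), 3, "mixed"),
    list(c(0, 0, 0), 4, "unbound"))
  for (cs in cases) {
    counts <- cs[[1]]
    k <- sum(counts)
    asg <- data.frame(
      gene_id = rep("g1", k),
      match_id = sprintf("m%d", seq_len(k)),
      status = rep(c("unique_a", "unique_b", "shared"), counts),
      stringsAsFactors = FALSE)
    prof <- gene_binding_profiles("g1", asg)
    expect_equal(prof$mode, cs[[2]])
    expect_equal(prof$category, cs[[3]])
  }
})

test_that("category refines mode and A/B swap acts as expected", {
  set.seed(99)
  genes <- sprintf("g%03d", 1:200)
  status_pool <- c("unique_a", "unique_b", "shared")
  asg <- data.frame(
    gene_id = sample(genes[1:150], 400, replace = TRUE),
    match_id = sprintf("m%03d", 1:400),
    status = sample(status_pool, 400, replace = TRUE),
    stringsAsFactors = FALSE)
  prof <- gene_binding_profiles(genes, asg)
  # every gene gets exactly one mode; refinement rules
  expect_true(all(prof$mode %in% 1:4))
  expect_true(all(prof$category[prof$mode == 1] == "a_only"))
  expect_true(all(prof$category[prof$mode == 2] == "b_only"))
  expect_true(all(prof$category[prof$mode == 3] %in%
                    c("identical", "mixed", "mutually_exclusive")))
  expect_true(all(prof$category[prof$mode == 4] == "unbound"))
  # swapping conditions maps 1<->2, a_only<->b_only, fixes 3/4
  swapped <- asg
  swapped$status <- c(unique_a = "unique_b", unique_b = "unique_a",
                      shared = "shared")[asg$status]
  prof_s <- gene_binding_profiles(genes, swapped)
  expect_equal(prof_s$mode, c(2L, 1L, 3L, 4L)[prof$mode])
  map <- c(identical = "identical", mixed = "mixed",
           mutually_exclusive = "mutually_exclusive", a_only = "b_only",
           b_only = "a_only", unbound = "unbound")
  expect_equal(prof_s$category, unname(map[prof$category]))
  expect_equal(prof_s$n_unique_a, prof$n_unique_b)
})

test_that("bound-fraction chi-square matches the closed-form oracle", {
  # table [[50, 50], [200, 800]]: oracle value from the standard
  # N(ad-bc)^2 / (r1 r2 c1 c2) formula, computed independently
  oracle_chi2 <- 1100 * (50 * 800 - 50 * 200)^2 /
    (100 * 1000 * 250 * 850)
  oracle_p <- stats::pchisq(oracle_chi2, df = 1, lower.tail = FALSE)
  genes <- sprintf("g%04d", 1:1100)
  resp <- genes[1:100]
  bg <- genes[101:1100]
  bound <- c(resp[1:50], bg[1:200])
  prof <- data.frame(gene_id = genes,
                     mode = ifelse(genes %in% bound, 1L, 4L),
                     stringsAsFactors = FALSE)
  res <- bound_fraction_enrichment(resp, bg, prof)
  expect_equal(res$chisq, oracle_chi2, tolerance = 1e-9)
  expect_equal(res$p, oracle_p, tolerance = 1e-9)
  expect_equal(res$fold, (50 / 100) / (200 / 1000))
  expect_false(res$low_expected)
  expect_error(bound_fraction_enrichment(resp, c(resp[1], bg), prof),
               "disjoint")
})

test_that("extreme separation gives maximal fold and vanishing p", {
  genes <- sprintf("g%03d", 1:300)
  resp <- genes[1:100]
  bg <- genes[101:300]
  prof <- data.frame(gene_id = genes,
                     mode = ifelse(genes %in% resp, 3L, 4L))
  res <- bound_fraction_enrichment(resp, bg, prof)
  expect_equal(res$fold, Inf)
  expect_lt(res$p, 1e-50)
})

test_that("mode enrichment computes folds over the background", {
  genes <- sprintf("g%04d", 1:1100)
  set_ids <- genes[1:100]
  bg <- genes[101:1100]
  mode <- integer(1100)
  mode[1:100] <- rep(c(3L, 1L), c(50, 50))
  mode[101:1100] <- rep(c(3L, 1L, 4L), c(200, 50, 750))
  prof <- data.frame(gene_id = genes, mode = mode)
  enr <- mode_enrichment(set_ids, bg, prof, "set")
  expect_equal(enr$fold[enr$mode == 3], (50 / 100) / (200 / 1000))
  expect_equal(nrow(enr), 4)
  expect_true(all(enr$fdr >= enr$p - 1e-12))
  expect_error(mode_enrichment(character(0), bg, prof), "empty")
  # a set drawn from the background distribution has folds near 1
  set.seed(4)
  null_set <- sample(bg, 300)
  enr0 <- mode_enrichment(null_set, setdiff(bg, null_set), prof)
  expect_true(all(abs(enr0$fold - 1) < 0.35, na.rm = TRUE))
})

test_that("composite profile table groups and counts by category", {
  genes <- sprintf("g%02d", 1:9)
  prof <- data.frame(
    gene_id = genes,
    n_unique_a = 0, n_unique_b = 0, n_shared = 0,
    mode = c(3, 3, 3, 1, 2, 4, 3, 1, 4),
    category = c("identical", "mixed", "mutually_exclusive", "a_only",
                 "b_only", "unbound", "identical", "a_only", "unbound"),
    stringsAsFactors = FALSE)
  ct <- composite_profile_table(prof, genes)
  expect_equal(sum(ct$counts), 9)
  expect_equal(unname(ct$counts["identical"]), 2L)
  expect_equal(ct$table$category[1:2], c("identical", "identical"))
  # single-gene set maps to its own category
  one <- composite_profile_table(prof, "g05")
  expect_equal(unname(one$counts["b_only"]), 1L)
  expect_equal(sum(one$counts), 1)
  # random instance vs brute-force recount
  set.seed(15)
  pick <- sample(genes, 5)
  cp <- composite_profile_table(prof, pick)
  for (cat in names(cp$counts)) {
    expect_equal(unname(cp$counts[cat]),
                 sum(prof$category[prof$gene_id %in% pick] == cat))
  }
})
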