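small_cfg <- function(...) {
  simulation_config(n_genes = 150, seed = 7, ...)
}

noise_free_cfg <- function(...) {
  simulation_config(n_genes = 150, seed = 7, expr_sigma = 0, jitter = 0,
                    count_noise = FALSE, peak_fp_rate = 0,
                    peak_fn_rate = 0, ...)
}

test_that("the generator is deterministic under a fixed seed", {
  e1 <- simulate_experiment(small_cfg())
  e2 <- simulate_experiment(small_cfg())
  expect_identical(e1$truth, e2$truth)
  expect_identical(e1$peaks, e2$peaks)
  expect_identical(e1$expression$values, e2$expression$values)
  expect_identical(lapply(e1$counts, function(x) x$ct$counts),
                   lapply(e2$counts, function(x) x$ct$counts))
  # and the written files are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_experiment(e1, d1)
  write_experiment(e2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("config validation rejects inconsistent fractions", {
  expect_error(simulation_config(class_fractions = c(
    a_unique = 0.5, b_unique = 0.5, shared = 0.5, independent = 0)),
    "sum to 1")
  expect_error(simulation_config(seed = NA), "seed is mandatory")
})

test_that("simulated NB counts match the configured moments", {
  cfg <- simulation_config(n_genes = 2000, seed = 11)
  exp <- simulate_experiment(cfg)
  tr <- exp$truth
  # >= 10,000 low-state draws for SMAD3 across replicates
  low_a <- tr$smad3_a == "low"
  draws <- as.vector(exp$counts$SMAD3$ct$counts[low_a, 1:3])
  expect_gt(length(draws), 1000)
  expect_equal(mean(draws), cfg$nb_mean_low, tolerance = 0.05)
  expect_equal(var(draws),
               cfg$nb_mean_low + cfg$nb_mean_low^2 / cfg$nb_size,
               tolerance = 0.15)
  hi_a <- tr$smad3_a == "high"
  draws_hi <- as.vector(exp$counts$SMAD3$ct$counts[hi_a, 1:3])
  expect_equal(mean(draws_hi), cfg$nb_mean_high, tolerance = 0.05)
  # moment check covers > 10,000 window draws across both conditions
  pooled <- c(draws, draws_hi,
              as.vector(exp$counts$SMAD3$ct$counts[, 4:6]))
  expect_gt(length(pooled), 10000)
})

test_that("planted truth is internally consistent", {
  exp <- simulate_experiment(small_cfg())
  tr <- exp$truth
  ctx <- tr$class %in% c("a_unique", "b_unique")
  # directed genes: identical shared binding, no differential SMAD3 state
  dir_g <- ctx & !is.na(tr$context_label) & tr$context_label == "directed"
  expect_true(all(tr$mode[dir_g] == 3))
  expect_true(all(tr$category[dir_g] == "identical"))
  expect_true(all(tr$smad3_a[dir_g] == tr$smad3_b[dir_g]))
  # directed genes carry at least one epigenetic difference
  has_epi <- function(i) {
    own <- ifelse(tr$class[i] == "a_unique", "a", "b")
    oth <- ifelse(own == "a", "b", "a")
    open_diff <- any(vapply(c("h3k4me3", "h3k27ac", "pol2"), function(f) {
      tr[[paste0(f, "_", own)]][i] == "high" &&
        tr[[paste0(f, "_", oth)]][i] == "low"
    }, logical(1)))
    meth_diff <- tr$meth_a[i] != tr$meth_b[i] &&
      tr[[paste0("meth_", oth)]][i] == "high"
    open_diff || meth_diff
  }
  expect_true(all(vapply(which(dir_g), has_epi, logical(1))))
  # assisted genes are uniquely bound in their own condition
  asst <- ctx & !is.na(tr$context_label) & tr$context_label == "assisted"
  expect_true(all(tr$mode[asst & tr$class == "a_unique"] == 1))
  expect_true(all(tr$mode[asst & tr$class == "b_unique"] == 2))
  # responsive classes per time point respect the onset
  expect_true(all(tr$class_t1 == "independent"))
  late <- !is.na(tr$onset) & tr$onset == 24
  expect_true(all(tr$class_t6[late] == "independent"))
  resp_g <- tr$class != "independent"
  expect_true(all(tr$class_t24[resp_g] == tr$class[resp_g]))
})

test_that("zero-jitter planted shared peaks sit at identical coordinates", {
  exp <- simulate_experiment(noise_free_cfg())
  tr <- exp$truth
  m <- match_peaks(exp$peaks$a, exp$peaks$b)
  asg <- assign_proximal_peaks(
    derive_gene_proximal(exp$genes, exp$layout), m)
  prof <- gene_binding_profiles(exp$genes$gene_id, asg)
  ident <- tr$gene_id[tr$category == "identical"]
  expect_gt(length(ident), 0)
  got <- prof[match(ident, prof$gene_id), ]
  expect_true(all(got$category == "identical"))
  expect_true(all(got$n_unique_a == 0 & got$n_unique_b == 0))
  # the matched shared peaks have equal start/end in both conditions
  sh <- m[m$status == "shared", ]
  pa <- exp$peaks$a[match(sh$peak_a, exp$peaks$a$peak_id), ]
  pb <- exp$peaks$b[match(sh$peak_b, exp$peaks$b$peak_id), ]
  expect_equal(pa$start, pb$start)
  expect_equal(pa$end, pb$end)
})

test_that("infeasible peak placement names the offending gene", {
  cfg <- simulation_config(n_genes = 50, seed = 3,
                           gene_length_range = c(300, 400),
                           peak_width_min = 2000)
  expect_error(simulate_experiment(cfg), "gene_[0-9]+.*too small")
})

test_that("noise-free synthesis is recovered exactly end-to-end", {
  exp <- simulate_experiment(noise_free_cfg())
  res <- analyze_experiment(exp)
  rep <- truth_vs_result_report(exp$truth, res)
  expect_equal(rep$responsive_class$accuracy, 1)
  expect_equal(rep$mode$accuracy, 1)
  expect_equal(rep$category$accuracy, 1)
  expect_equal(rep$context_label$accuracy, 1)
  expect_true(all(rep$epigenome_sets$sensitivity == 1))
  expect_true(all(rep$epigenome_sets$precision == 1))
  # identity confusion matrices: off-diagonal mass is zero
  cm <- rep$mode$confusion
  expect_equal(sum(cm) - sum(diag(cm[, 1:4])), 0)
})

test_that("corrupted predictions degrade the report as expected", {
  exp <- simulate_experiment(noise_free_cfg())
  res <- analyze_experiment(exp)
  # controlled corruption at rate r: accuracy ~ 1 - r
  set.seed(19)
  r <- 0.2
  n <- nrow(res$profiles)
  flip <- sample(n, round(r * n))
  res_bad <- res
  res_bad$profiles$mode[flip] <-
    (res_bad$profiles$mode[flip] %% 4) + 1L
  rep_bad <- truth_vs_result_report(exp$truth, res_bad)
  expect_equal(rep_bad$mode$accuracy, 1 - r, tolerance = 0.02)
  # full permutation: accuracy near chance for a shuffled assignment
  res_perm <- res
  res_perm$profiles$mode <- sample(res_perm$profiles$mode)
  rep_perm <- truth_vs_result_report(exp$truth, res_perm)
  chance <- sum(table(exp$truth$mode)^2) / nrow(exp$truth)^2
  expect_lt(abs(rep_perm$mode$accuracy - chance), 0.12)
})
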