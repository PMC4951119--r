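test_that("IFS produces one full curve per test dataset", {
  cohort <- generate_cohort(small_cohort_config(seed = 71L))
  flist <- mrmr_ranking(discretize_expression(cohort$datasets$A), 12L)
  curves <- run_ifs(cohort$datasets$A, cohort$datasets[c("B", "C")],
                    flist, n_max = 10L)
  expect_named(curves, c("B", "C"))
  for (cur in curves) {
    expect_equal(cur$k, 1:10)
    expect_equal(attr(cur, "train"), "A")
    expect_true(all(cur$total_acc >= 0 & cur$total_acc <= 1))
    # total accuracy is the class-size weighted mean of per-class accuracy
    sizes <- table(factor(cohort$datasets[[attr(cur, "test")]]$regions,
                          levels = region_labels()))
    weighted <- (cur$acc_BS * sizes[["BS"]] + cur$acc_CB * sizes[["CB"]] +
                   cur$acc_CC * sizes[["CC"]]) / sum(sizes)
    expect_equal(weighted, cur$total_acc, tolerance = 1e-12)
    expect_equal(cur$correct / cur$n, cur$total_acc)
  }
  expect_equal(run_ifs(cohort$datasets$A, list(), flist, 5L), list())
})

test_that("IFS errors when a ranked gene is missing from a dataset", {
  cohort <- generate_cohort(small_cohort_config(seed = 72L))
  flist <- feature_list(c("g00001", "nope"), c(1, 0.5), flavor = "mRMR")
  expect_error(run_ifs(cohort$datasets$A, cohort$datasets["B"], flist, 2L),
               "nope.*absent")
})

test_that("one overwhelming planted gene saturates accuracy at k = 1", {
  cfg <- cohort_config(
    n_genes = 30L, n_planted_per_region = 1L, effect_size = 100,
    noise_sd = 0.1, batch_sd = 0.05,
    per_individual_counts = list(A = c(10L, 10L, 10L), B = c(8L, 12L, 10L),
                                 C = c(10L, 8L, 12L)),
    seed = 73L)
  # scale effect relative to noise: delta = 100 * 0.1 = 10 units
  cohort <- generate_cohort(cfg)
  # rank features on the training donor; the three planted genes lead
  flist <- mrmr_ranking(discretize_expression(cohort$datasets$A), 5L)
  curves <- run_ifs(cohort$datasets$A, cohort$datasets[c("B", "C")],
                    flist, n_max = 3L)
  for (cur in curves) expect_gte(cur$total_acc[3L], 0.99)
})

test_that("the inflection detector follows the verbal rule on fixtures", {
  cur <- make_curve_fixture(c(0.5, 0.7, 0.6, 0.8, 0.7))
  p <- find_inflection(cur, k_min = 2L, k_max = 4L)
  expect_equal(p$k, 2L)
  expect_false(p$fallback_used)
  expect_equal(p$total_acc, 0.7)

  # strictly increasing: no drop anywhere -> argmax fallback at k_max
  mono <- make_curve_fixture(seq(0.1, 0.9, length.out = 9L))
  pm <- find_inflection(mono, k_min = 2L, k_max = 8L)
  expect_true(pm$fallback_used)
  expect_equal(pm$k, 8L)

  # plateau then drop: the >= arm admits the plateau's second point
  pl <- find_inflection(make_curve_fixture(c(0.5, 0.5, 0.4)),
                        k_min = 2L, k_max = 2L)
  expect_equal(pl$k, 2L)
  expect_false(pl$fallback_used)

  expect_error(find_inflection(make_curve_fixture(c(0.5, 0.6))), "3 points")
  expect_error(find_inflection(cur, k_min = 1L, k_max = 4L), "k_min")
  expect_error(find_inflection(cur, k_min = 2L, k_max = 5L), "k_min")
})

test_that("inflection detection equals a brute-force scan on random curves", {
  set.seed(501)
  for (rep in 1:1000) {
    N <- sample(5:40, 1L)
    acc <- switch(1L + rep %% 4L,
      runif(N),                                   # rough random curve
      round(runif(N), 1L),                        # many exact ties/plateaus
      sort(runif(N)),                             # monotone -> fallback
      cummax(round(runif(N), 2L)))                # plateaus + monotone mix
    k_min <- sample(2:(N - 1L), 1L)
    k_max <- if (k_min == N - 1L) k_min else sample(k_min:(N - 1L), 1L)
    got <- find_inflection(make_curve_fixture(acc), k_min, k_max)
    want <- oracle_inflection(acc, k_min, k_max)
    expect_equal(got$k, want$k)
    expect_equal(got$fallback_used, want$fallback)
  }
})

test_that("max-accuracy point takes the smallest maximizing k", {
  expect_equal(max_accuracy_point(make_curve_fixture(c(0.2, 0.9, 0.9)))$k, 2L)
  mono <- make_curve_fixture(seq(0.05, 0.95, length.out = 10L))
  expect_equal(max_accuracy_point(mono)$k, 10L)
  set.seed(511)
  for (rep in 1:50) {
    acc <- round(runif(12L), 1L)
    got <- max_accuracy_point(make_curve_fixture(acc))
    expect_equal(got$k, which(acc == max(acc))[1L])
    expect_equal(got$total_acc, max(acc))
  }
})

test_that("important features equal the minimum-k prefix by nestedness", {
  fl <- feature_list(sprintf("g%02d", 1:40), seq(4, 0.1, length.out = 40L),
                     flavor = "mRMR")
  mk <- function(k) structure(list(k = k, total_acc = 0.5,
                                   fallback_used = FALSE,
                                   train = "A", test = "B"),
                              class = "ifs_inflection")
  got <- important_features(fl, lapply(c(7L, 12L, 9L, 30L, 7L), mk))
  expect_equal(got, sprintf("g%02d", 1:7))
  expect_equal(important_features(fl, list(mk(5L))), sprintf("g%02d", 1:5))
  expect_equal(important_features(fl, lapply(c(4L, 4L, 4L), mk)),
               sprintf("g%02d", 1:4))
  expect_error(important_features(fl, list()), "non-empty")
})

test_that("literal intersection equals the min-k prefix on random tuples", {
  set.seed(521)
  genes <- sprintf("g%03d", 1:100)
  for (rep in 1:1000) {
    ks <- sample(1:100, sample(1:6, 1L), replace = TRUE)
    literal <- Reduce(intersect, lapply(ks, function(k) genes[seq_len(k)]))
    expect_equal(sort(literal), sort(genes[seq_len(min(ks))]))
  }
  # and through the package path on a permuted list
  fl <- feature_list(sample(genes), runif(100L), flavor = "mRMR")
  mk <- function(k) list(k = k, fallback_used = FALSE)
  for (rep in 1:20) {
    ks <- sample(1:100, 4L, replace = TRUE)
    expect_equal(important_features(fl, lapply(ks, mk)),
                 fl$gene_id[seq_len(min(ks))])
  }
})

test_that("consensus frequencies count contributing training sets", {
  sets <- list(A = c("g1", "g2"), B = c("g1", "g3"), C = c("g1", "g2"),
               D = c("g1"), E = c("g1", "g4"), F = c("g1", "g2"))
  tab <- consensus_frequency(sets)
  expect_s3_class(tab, "consensus_table")
  expect_equal(tab$frequency[tab$gene_id == "g1"], 6L)
  expect_equal(tab$frequency[tab$gene_id == "g2"], 3L)
  expect_equal(tab$training_ids[tab$gene_id == "g2"], "A,C,F")
  # sorted by frequency descending then gene id
  expect_equal(tab$gene_id, c("g1", "g2", "g3", "g4"))
  expect_true(all(diff(tab$frequency) <= 0))

  # disjoint sets -> all frequency 1; identical sets -> all = n sets
  expect_true(all(consensus_frequency(list(A = "g1", B = "g2"))$frequency == 1L))
  same <- consensus_frequency(list(A = c("g1", "g2"), B = c("g1", "g2"),
                                   C = c("g1", "g2")))
  expect_true(all(same$frequency == 3L))
  expect_error(consensus_frequency(list(c("g1"), c("g2"))), "named")
})

test_that("a gene in five of six sets surfaces with frequency five", {
  sets <- list(d1 = c("gTOP", "gX"), d2 = c("gTOP"), d3 = c("gTOP", "gY"),
               d4 = c("gTOP"), d5 = c("gTOP"), d6 = c("gZ"))
  tab <- consensus_frequency(sets)
  expect_equal(tab$gene_id[1L], "gTOP")
  expect_equal(tab$frequency[1L], 5L)
  expect_false("d6" %in% strsplit(tab$training_ids[1L], ",")[[1L]])
})

test_that("IFS curves round-trip through their TSV form", {
  cohort <- generate_cohort(small_cohort_config(seed = 74L))
  flist <- mrmr_ranking(discretize_expression(cohort$datasets$B), 6L)
  cur <- run_ifs(cohort$datasets$B, cohort$datasets["C"], flist, 5L)[[1L]]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ifs_curve(cur, path)
  back <- read_ifs_curve(path)
  expect_equal(attr(back, "train"), "B")
  expect_equal(attr(back, "test"), "C")
  expect_equal(back$total_acc, cur$total_acc, tolerance = 1e-10)
  expect_equal(back$correct, cur$correct)
  # the inflection decision is preserved across the round trip
  expect_equal(find_inflection(back, 2L, 4L)$k,
               find_inflection(cur, 2L, 4L)$k)
})
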