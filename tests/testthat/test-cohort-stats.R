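test_that("prevalence and organism filters apply the boundary rules", {
  hit <- matrix(FALSE, 8, 5,
                dimnames = list(sprintf("p%d", 1:8), sprintf("s%d", 1:5)))
  hit["p1", 1:3] <- TRUE          # exactly 3 samples -> kept
  hit["p2", 1:2] <- TRUE          # 2 samples -> dropped
  hit[3:8, 1:4] <- TRUE
  hits <- make_hits(hit)
  kept <- prevalence_filter(hits, 3)
  expect_true("p1" %in% kept)
  expect_false("p2" %in% kept)
  # empty at an unreachable threshold
  expect_equal(length(prevalence_filter(hits, 6)), 0)
  ann <- tibble::tibble(clone_id = sprintf("p%d", 1:8),
                        organism = c(rep("wheat", 6), rep("dust", 2)))
  # wheat contributes 5 recognised peptides (kept), dust only 1 (removed)
  kept2 <- organism_filter(setdiff(kept, "p8"), ann, 5)
  expect_setequal(kept2, c("p1", sprintf("p%d", 3:6)))
  expect_equal(organism_filter(character(0), ann), character(0))
  # filters are idempotent
  expect_equal(organism_filter(kept2, ann, 5), kept2)
})

test_that("sample clustering recovers planted structure deterministically", {
  hit <- cbind(s1 = c(TRUE, TRUE, FALSE, FALSE),
               s2 = c(TRUE, TRUE, FALSE, FALSE),
               s3 = c(FALSE, FALSE, TRUE, TRUE))
  rownames(hit) <- sprintf("p%d", 1:4)
  hits <- make_hits(hit)
  cl <- cluster_samples(hits, "binary", k = 2)
  expect_equal(cl$clusters[["s1"]], cl$clusters[["s2"]])
  expect_false(cl$clusters[["s1"]] == cl$clusters[["s3"]])
  cl2 <- cluster_samples(hits, "binary", k = 2)
  expect_identical(cl$hclust$merge, cl2$hclust$merge)
  expect_error(cluster_samples(hits, "binary", k = 5), "k exceeds")
  # planted 3-group cohort with disjoint reactive sets: perfect recovery
  set.seed(80)
  truth <- rep(1:3, each = 6)
  hit3 <- sapply(truth, function(g) {
    v <- rep(FALSE, 30)
    v[(g - 1) * 10 + sample(10, 7)] <- TRUE
    v
  })
  dimnames(hit3) <- list(sprintf("p%02d", 1:30), sprintf("s%02d", 1:18))
  cl3 <- cluster_samples(make_hits(hit3), "binary", k = 3)
  expect_equal(mclust::adjustedRandIndex(cl3$clusters, truth), 1)
  # euclidean/Ward mode runs on the fold-change values
  cl4 <- cluster_samples(make_hits(hit3), "euclidean", k = 3)
  expect_equal(mclust::adjustedRandIndex(cl4$clusters, truth), 1)
})

test_that("rank-sum p-values match exhaustive enumeration", {
  df <- tibble::tibble(value = c(1, 2, 3, 10, 11, 12),
                       group = rep(c("a", "b"), each = 3))
  res <- compare_groups(df, value, group)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, brute_ranksum_p(c(1, 2, 3), c(10, 11, 12)))
  # random no-ties cases across small group sizes
  set.seed(90)
  for (m in c(2, 4, 6)) for (n in c(3, 5, 8)) {
    x <- sample(seq_len(100), m)
    y <- sample(setdiff(seq_len(100), x), n)
    df2 <- tibble::tibble(value = c(x, y),
                          group = rep(c("g1", "g2"), c(m, n)))
    expect_equal(compare_groups(df2, value, group)$p_value,
                 brute_ranksum_p(x, y), info = paste(m, n))
  }
  # identical groups show no separation
  df3 <- tibble::tibble(value = rep(c(5, 6, 7, 8), 2),
                        group = rep(c("a", "b"), each = 4))
  expect_gte(compare_groups(df3, value, group)$p_value, 0.9)
  # multi-group input yields all pairwise rows, optional BH column
  df4 <- tibble::tibble(value = rnorm(12), group = rep(c("a", "b", "c"), 4))
  res4 <- compare_groups(df4, value, group, adjust = TRUE)
  expect_equal(nrow(res4), 3)
  expect_true("p_adj" %in% names(res4))
  expect_error(compare_groups(df4[1:4, ], value, group), ">= 2")
})

test_that("signed-rank p-values match sign enumeration", {
  b <- c(3, 1, 4, 1, 5, 9)
  a <- b + c(1, 2, 3, 4, 5, 6)
  res <- paired_change(b, a)
  expect_equal(res$p_value, 2 / 64)
  expect_equal(res$p_value, brute_signedrank_p(b, a))
  set.seed(91)
  for (n in c(4, 6, 8)) {
    before <- sample(seq(1, 200, by = 2), n)
    after <- before + sample(c(-1, 1), n, TRUE) * sample(seq(2, 40, 2), n)
    expect_equal(paired_change(before, after)$p_value,
                 brute_signedrank_p(before, after), info = n)
  }
  # unchanged pairs: degenerate with p = 1
  res0 <- paired_change(1:5, 1:5)
  expect_equal(res0$p_value, 1)
  expect_true(res0$degenerate)
  # zero differences are dropped before ranking
  resz <- paired_change(c(1, 2, 3, 4, 10), c(1, 2, 3, 4, 30))
  expect_equal(resz$n_nonzero, 1)
})

test_that("group tests are calibrated under the null", {
  set.seed(92)
  rejections <- replicate(300, {
    df <- tibble::tibble(value = rnorm(20), group = rep(c("a", "b"), 10))
    compare_groups(df, value, group)$p_value < 0.05
  })
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 300)
  expect_gte(mean(rejections), ci[1])
  expect_lte(mean(rejections), ci[2])
})

test_that("isotype concordance fractions partition the reactive set", {
  h <- matrix(FALSE, 10, 2, dimnames = list(sprintf("p%d", 1:10), c("a", "b")))
  h1 <- h; h2 <- h
  h1[1:7, 1] <- TRUE              # 10 IgE-only: p1..p7 a, p1..p3 b
  h1[1:3, 2] <- TRUE
  h2[8:10, 1] <- TRUE             # 6 IgG-only
  h2[8:10, 2] <- TRUE
  h1[4:5, 2] <- TRUE; h2[4:5, 2] <- TRUE   # adjust: 4 both
  h1[6:7, 2] <- TRUE; h2[6:7, 2] <- TRUE
  conc <- isotype_concordance(h1, h2)
  expect_equal(conc$both + conc$ige_only + conc$igg_only, 1)
  # identical hit sets
  expect_equal(isotype_concordance(h1, h1)$both, 1)
  # disjoint hit sets
  hd <- h; hd[1:2, 1] <- TRUE
  he <- h; he[3:4, 1] <- TRUE
  expect_equal(isotype_concordance(hd, he)$both, 0)
  # the worked fixture: 10 IgE-only, 6 IgG-only, 4 both
  f1 <- h; f2 <- h
  f1[1:10, 1] <- TRUE; f1[1:4, 2] <- TRUE
  f2[1:4, 2] <- TRUE; f2[5:10, 2] <- TRUE
  conc2 <- isotype_concordance(f1, f2)
  expect_equal(unlist(conc2[, c("both", "ige_only", "igg_only")]),
               c(both = 0.2, ige_only = 0.5, igg_only = 0.3))
  expect_warning(c0 <- isotype_concordance(h, h), "no reactive")
  expect_true(is.na(c0$both))
})

test_that("epitope summaries aggregate members by max and count prevalence", {
  hit <- matrix(FALSE, 4, 4,
                dimnames = list(c("e1", "e2", "e3", "x"),
                                sprintf("s%d", 1:4)))
  vals <- matrix(1, 4, 4, dimnames = dimnames(hit))
  hit["e1", 1] <- TRUE; vals["e1", 1] <- 12
  hit["e2", 1] <- TRUE; vals["e2", 1] <- 30
  hit["e3", 2] <- TRUE; vals["e3", 2] <- 8
  hits <- make_hits(hit, vals)
  meta <- tibble::tibble(sample_id = sprintf("s%d", 1:4),
                         group = c("g1", "g1", "g2", "g2"))
  es <- epitope_summary(hits, c("e1", "e2", "e3"), meta)
  expect_equal(es$samples$value[1], 30)           # max over members
  expect_equal(es$samples$reactive, c(TRUE, TRUE, FALSE, FALSE))
  prev <- es$prevalence
  expect_equal(prev$prevalence[prev$group == "g1"], 1)
  expect_equal(prev$prevalence[prev$group == "g2"], 0)
  expect_error(epitope_summary(hits, "nope"), "unknown")
})

test_that("longitudinal pair tables flag the target organism", {
  ann <- tibble::tibble(clone_id = c("w1", "w2", "o1"),
                        organism = c("wheat", "wheat", "dust"))
  pd <- longitudinal_pairplot_data(c(10L, 20L, 30L), c(10L, 20L, 30L), ann)
  expect_equal(pd$table$log_t0, pd$table$log_t1)
  expect_equal(pd$summary$frac_above, 0)
  expect_equal(pd$summary$frac_below, 0)
  expect_equal(pd$table$is_target, c(TRUE, TRUE, FALSE))
  pd2 <- longitudinal_pairplot_data(c(10L, 20L, 30L), c(100L, 200L, 30L), ann)
  expect_equal(pd2$summary$frac_above, 1)
  expect_error(longitudinal_pairplot_data(c(0L, 0L, 0L), c(1L, 1L, 1L), ann),
               "depth")
})

test_that("treatment response classification uses the dose-gain threshold", {
  expect_true(classify_woit_response(443, 7443))
  expect_false(classify_woit_response(1000, 1999))   # gain 999 <= 1000
  expect_true(classify_woit_response(0, 1001))
  expect_false(classify_woit_response(0, 1000))      # boundary: strict
  expect_true(is.na(classify_woit_response(NA, 5000)))
  expect_equal(classify_woit_response(c(0, 1000, NA), c(2000, 1500, 1)),
               c(TRUE, FALSE, NA))
  expect_error(classify_woit_response(-1, 100), ">= 0")
})
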