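test_that("the NB upper tail matches direct pmf summation", {
  set.seed(10)
  for (i in 1:50) {
    mu <- runif(1, 0.5, 1000)
    phi <- runif(1, 0, 0.5)
    count <- rpois(1, mu * runif(1, 0.5, 5))
    p <- nb_tail(count, mu, phi)
    b <- brute_nb_tail(count, mu, phi)
    expect_lt(abs(p - b) / b, 1e-8)
  }
  # frozen Poisson reference: P(X >= 150 | mu = 100)
  expect_equal(nb_tail(150, 100, 0), 1.8842105e-06, tolerance = 1e-6)
  expect_lt(abs(nb_tail(150, 100, 0) - brute_nb_tail(150, 100, 0)) /
              brute_nb_tail(150, 100, 0), 1e-8)
  # zero count is never significant
  expect_equal(nb_tail(0, 100, 0.2), 1)
})

test_that("the tail probability is non-increasing in the observed count", {
  p <- nb_tail(0:400, mu = 120, phi = 0.15)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p > 0 & p <= 1))
})

test_that("mock model estimates proportions and recovers the dispersion", {
  set.seed(20)
  n <- 400
  props <- as.numeric(prop.table(exp(rnorm(n, 0, 0.5))))
  depth <- 1e5
  mocks <- as.data.frame(replicate(200, simulate_ip(props, depth = depth,
                                                    dispersion = 0.1)))
  names(mocks) <- sprintf("mock_%03d", 1:200)
  counts <- dplyr::bind_cols(
    tibble::tibble(clone_id = sprintf("c%03d", 1:n)), mocks)
  mm <- fit_mock_model(counts, names(mocks))
  expect_equal(sum(mm$clones$p_hat), 1)
  expect_equal(mm$clones$p_hat, props, tolerance = 0.1)
  big <- mm$clones$mean_norm >= 50
  # pooled dispersion recovered within 30% of the generative truth
  expect_equal(median(mm$clones$phi[big]), 0.1, tolerance = 0.3)
  # Poisson-like mocks collapse to near-zero dispersion
  mocks0 <- as.data.frame(replicate(100, simulate_ip(props, depth = depth,
                                                     dispersion = 0)))
  names(mocks0) <- sprintf("m%03d", 1:100)
  counts0 <- dplyr::bind_cols(
    tibble::tibble(clone_id = sprintf("c%03d", 1:n)), mocks0)
  mm0 <- fit_mock_model(counts0, names(mocks0))
  expect_lt(mm0$global_phi, 0.02)
})

test_that("degenerate mock inputs are handled explicitly", {
  counts <- tibble::tibble(clone_id = c("a", "b", "c"),
                           m1 = c(10L, 0L, 5L))
  expect_error(fit_mock_model(counts, character(0)), "no mock")
  expect_warning(mm1 <- fit_mock_model(counts, "m1"), "one mock")
  expect_equal(unique(mm1$clones$phi), 0.2)
  # alpha = 0 leaves unseen clones at zero proportion; they are floored
  counts2 <- tibble::tibble(clone_id = c("a", "b", "c"),
                            m1 = c(100L, 50L, 0L), m2 = c(90L, 60L, 0L))
  expect_warning(mm2 <- fit_mock_model(counts2, c("m1", "m2"), alpha = 0),
                 "floor")
  res <- test_sample(c(95L, 55L, 4000L), mm2)
  expect_true(res$floored[3])
  expect_false(any(res$floored[1:2]))
  expect_lt(res$p_value[3], 1)
})

test_that("per-sample testing returns calibrated fold changes and p-values", {
  set.seed(30)
  n <- 300
  props <- rep(1 / n, n)
  mocks <- as.data.frame(replicate(8, simulate_ip(props, depth = 3e5,
                                                  dispersion = 0.05)))
  names(mocks) <- sprintf("mock_%d", 1:8)
  counts <- dplyr::bind_cols(tibble::tibble(clone_id = sprintf("c%03d", 1:n)),
                             mocks)
  mm <- fit_mock_model(counts, names(mocks))
  # a pure mock tested as a sample: no tiny p-values, fold changes near 1
  s <- simulate_ip(props, depth = 3e5, dispersion = 0.05)
  res <- test_sample(s, mm)
  expect_true(all(res$p_value > 1e-6))
  expect_equal(median(res$fold_change), 1, tolerance = 0.1)
  expect_equal(res$p_value[res$count == 0], rep(1, sum(res$count == 0)))
  expect_true(all(res$fold_change[res$count == 0] <= 1))
  expect_error(test_sample(rep(0L, n), mm), "depth")
})

test_that("hit calling applies all three thresholds jointly", {
  enr <- structure(list(
    clone_ids = c("c1", "c2", "c3", "c4"),
    sample_ids = "s1",
    counts = matrix(c(500, 99, 500, 0), 4, 1,
                    dimnames = list(c("c1", "c2", "c3", "c4"), "s1")),
    expected = matrix(25, 4, 1),
    fold_change = matrix(c(20, 50, 20, 0.5), 4, 1),
    p_value = matrix(c(1e-5, 1e-10, 0.01, 1), 4, 1)
  ), class = "allerscan_enrichment")
  hits <- call_hits(enr)
  # passes all three thresholds -> hit carrying its fold change
  expect_equal(hits$values["c1", "s1"], 20)
  # count below 100 binds despite extreme p and fc
  expect_false(hits$hit["c2", "s1"])
  # p above 0.001 binds
  expect_false(hits$hit["c3", "s1"])
  expect_equal(unname(hits$values[!hits$hit]), rep(1, 3))
  expect_error(call_hits(enr, min_count = 0), "min_count")
})

test_that("spiked clones are detected with high probability", {
  set.seed(40)
  n <- 1000
  props <- as.numeric(prop.table(exp(rnorm(n, 0, 0.5))))
  depth <- 1e6
  eligible <- which(depth * props >= 50)
  spiked <- sample(eligible, 10)
  fc <- rep(1, n); fc[spiked] <- 10
  calls <- replicate(10, {
    mocks <- as.data.frame(replicate(8, simulate_ip(props, depth = depth,
                                                    dispersion = 0.1)))
    names(mocks) <- sprintf("mock_%d", 1:8)
    counts <- dplyr::bind_cols(
      tibble::tibble(clone_id = sprintf("c%04d", 1:n)), mocks,
      tibble::tibble(s = simulate_ip(props, fc, depth, 0.1)))
    mm <- fit_mock_model(counts, names(mocks))
    hits <- call_hits(test_enrichment(counts, mm, "s"))
    mean(hits$hit[spiked, 1])
  })
  expect_gte(mean(calls), 0.9)
})
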