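# Percentile sweep and multicriteria model evaluation.

test_that("linear-interpolation percentile matches the closed form", {
  vals <- seq(0, 1, length.out = 101)
  expect_equal(ccl_percentile(vals, 50), 0.5)
  expect_equal(ccl_percentile(vals, 25), 0.25)
  expect_equal(ccl_percentile(rep(0.7, 10), 83), 0.7)
  # monotone in p
  set.seed(2)
  v <- runif(50)
  tp <- vapply(1:99, function(p) ccl_percentile(v, p), numeric(1))
  expect_true(all(diff(tp) >= 0))
  expect_error(ccl_percentile(numeric(0), 50), "empty")
})

test_that("sweep agrees exactly with the brute-force oracle", {
  set.seed(11)
  for (case in 1:100) {
    N <- 200
    ccl_values <- runif(N)
    correct <- runif(N) < (0.3 + 0.6 * ccl_values)  # CCL-dependent rate
    got <- ccl_sweep(ccl_values, correct)
    ref <- sweep_oracle(ccl_values, correct)
    expect_identical(got$p, ref$p)
    expect_identical(got$t_p, ref$t_p)
    expect_identical(got$n_p, ref$n_p)
    expect_identical(got$a_p, ref$a_p)
    expect_identical(got$m_p, ref$m_p)
    # raising the cutoff shrinks the kept subset: n_p non-increasing,
    # t_p non-decreasing
    expect_true(all(diff(got$n_p) <= 0))
    expect_true(all(diff(got$t_p) >= 0))
  }
})

test_that("degenerate sweeps behave as specified", {
  # all incorrect -> every a_p = 0 -> m = 0
  ev <- evaluate_model(runif(50), rep(FALSE, 50))
  expect_equal(ev$m, 0)
  # single sample: every percentile equals its CCL, strict > empties the set
  ev1 <- evaluate_model(0.8, TRUE)
  expect_equal(ev1$m, 0)
  expect_true(all(ev1$sweep$n_p == 0))
})

test_that("the maximum is attained and ties break to the smallest p", {
  set.seed(4)
  v <- runif(300)
  corr <- runif(300) < 0.9
  ev <- evaluate_model(v, corr)
  expect_equal(ev$m, max(ev$sweep$m_p))
  expect_equal(ev$p_opt, ev$sweep$p[which.max(ev$sweep$m_p)])
  expect_true(all(ev$sweep$m_p[ev$sweep$p < ev$p_opt] < ev$m))
})

test_that("a strictly better model never lowers m", {
  set.seed(21)
  for (case in 1:100) {
    N <- 120
    v <- runif(N)
    corr <- runif(N) < (0.2 + 0.7 * v)
    better <- corr
    wrong <- which(!corr)
    if (length(wrong)) better[sample(wrong, 1)] <- TRUE
    m1 <- evaluate_model(v, corr)$m
    m2 <- evaluate_model(v, better)$m
    expect_gte(m2, m1)
  }
})

test_that("evaluation is invariant to sample order", {
  set.seed(33)
  v <- runif(80); corr <- runif(80) < 0.7
  perm <- sample(80)
  e1 <- evaluate_model(v, corr)
  e2 <- evaluate_model(v[perm], corr[perm])
  expect_equal(e1$m, e2$m)
  expect_equal(e1$p_opt, e2$p_opt)
  expect_equal(e1$sweep, e2$sweep)
})

test_that("a positive CCL-correctness association makes a_p non-decreasing", {
  # in aggregate over simulations, mean accuracy over retained samples rises
  # with the cutoff percentile when correct samples carry higher CCL
  set.seed(55)
  acc_by_p <- matrix(0, 200, 3)
  for (s in 1:200) {
    N <- 150
    corr <- runif(N) < 0.75
    v <- ifelse(corr, rbeta(N, 4, 2), rbeta(N, 2, 4))
    sw <- ccl_sweep(v, corr, percentiles = c(10, 50, 90))
    acc_by_p[s, ] <- sw$a_p
  }
  means <- colMeans(acc_by_p)
  expect_true(all(diff(means) > 0))
})

test_that("tidy/glance/autoplot expose the evaluation", {
  set.seed(6)
  ev <- evaluate_model(runif(60), runif(60) < 0.8)
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("p", "t_p", "n_p", "a_p", "m_p"))
  gl <- glance(ev)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$m, ev$m)
  expect_s3_class(autoplot(ev), "ggplot")
})
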