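test_that("Bland-Altman statistics match hand calculations", {
  pc <- paired_comparison(c(1.0, 2.0), c(1.2, 2.4))
  ba <- bland_altman(pc)
  expect_equal(ba$mean_diff, -0.3, tolerance = 1e-12)
  expect_equal(ba$sd_diff, stats::sd(c(-0.2, -0.4)), tolerance = 1e-12)
  expect_equal(ba$sd_diff, 0.1414, tolerance = 1e-3)
  expect_equal(ba$loa95, c(-0.3 - 1.96 * ba$sd_diff, -0.3 + 1.96 * ba$sd_diff))
  expect_equal(unname(ba$loa95), c(-0.5772, -0.0228), tolerance = 1e-3)
  ## identical series degenerate to zero width
  ba0 <- bland_altman(paired_comparison(1:3, 1:3))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(unname(ba0$ci95_mean_diff), c(0, 0))
  ## shift invariance of a difference statistic
  ba_shift <- bland_altman(paired_comparison(c(1, 2) + 7, c(1.2, 2.4) + 7))
  expect_equal(ba_shift$mean_diff, ba$mean_diff)
  expect_equal(ba_shift$sd_diff, ba$sd_diff)
  expect_equal(ba_shift$loa95, ba$loa95)
  expect_error(paired_comparison(1, 1), "2 pairs")
})

test_that("limits of agreement bracket the bias and the CI narrows with n", {
  set.seed(3)
  for (n in c(10, 40, 160)) {
    a <- stats::rnorm(n); b <- a + stats::rnorm(n, 0.2, 0.3)
    ba <- bland_altman(paired_comparison(a, b))
    expect_gte(ba$mean_diff, ba$loa95[1])
    expect_lte(ba$mean_diff, ba$loa95[2])
    expect_gte(ba$mean_diff, ba$ci95_mean_diff[1])
    expect_lte(ba$mean_diff, ba$ci95_mean_diff[2])
  }
  widths <- vapply(c(20, 80, 320), function(n) {
    set.seed(11)
    a <- stats::rnorm(n); b <- a + stats::rnorm(n, 0.2, 0.3)
    diff(bland_altman(paired_comparison(a, b))$ci95_mean_diff)
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("agreement analysis recovers configured bias and noise", {
  n <- 200; bias <- 0.23; sdn <- 0.4
  model <- stats::runif(n, 0.2, 2)
  mcl <- synth_mcl_measurements(model, bias = bias, noise_sd = sdn, seed = 5)
  ba <- bland_altman(paired_comparison(mcl$dP_model_mmHg, mcl$dP_mmHg))
  expect_lt(abs(ba$mean_diff - (-bias)), 3 * sdn / sqrt(n))
  expect_lt(abs(ba$sd_diff - sdn) / sdn, 0.15)
})

test_that("Pearson correlation matches closed forms and affine invariance", {
  a <- c(1, 2, 3)
  expect_equal(pearson_r(paired_comparison(a, 2 * a + 1)), 1)
  expect_equal(pearson_r(paired_comparison(a, -a)), -1)
  expect_equal(pearson_r(paired_comparison(a, c(1, 2, 4))), 0.981981,
               tolerance = 1e-5)
  set.seed(9)
  x <- stats::rnorm(20); y <- stats::rnorm(20)
  r0 <- pearson_r(paired_comparison(x, y))
  expect_equal(pearson_r(paired_comparison(3 * x + 2, 0.5 * y - 1)), r0,
               tolerance = 1e-12)
  expect_error(pearson_r(paired_comparison(c(1, 1, 1), c(1, 2, 3))),
               "variance")
})

test_that("comparison tables join on (CO, model) and report unmatched keys", {
  cfd <- expand.grid(CO_L_min = c(3, 5, 7, 9, 11),
                     model = c("blank", "vip109", "vip162"),
                     stringsAsFactors = FALSE)
  cfd$dP_max_mmHg <- seq_len(nrow(cfd)) / 10
  mcl <- synth_mcl_measurements(cfd$dP_max_mmHg, bias = 0.1, noise_sd = 0,
                                CO = cfd$CO_L_min, model = cfd$model)
  tab <- comparison_table(cfd, mcl)
  expect_equal(nrow(tab), 15)
  expect_equal(tab$difference, rep(-0.1, 15), tolerance = 1e-12)
  ## one missing bench case
  tab14 <- comparison_table(cfd, mcl[-1, ])
  expect_equal(nrow(tab14), 14)
  expect_length(attr(tab14, "unmatched"), 1)
  ## duplicates rejected
  expect_error(comparison_table(rbind(cfd, cfd[1, ]), mcl), "duplicate")
})
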