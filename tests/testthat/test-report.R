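fake_fit <- function(y, fitted, family = "binomial") {
  structure(list(family = family,
                 fitted_conditional = fitted,
                 features = if (family == "binomial")
                   data.frame(y_binary = y) else data.frame(y_vas = y)),
            class = "pain_glme")
}

test_that("binary error percentage is the 0.5-threshold misclassification rate", {
  expect_equal(binary_error_percent(fake_fit(c(0, 0, 1, 1),
                                             c(0.1, 0.4, 0.6, 0.9))), 0)
  y <- c(rep(0, 10), rep(1, 10))
  f <- c(rep(0.2, 10), rep(0.8, 9), 0.2)          # one miss out of twenty
  expect_equal(binary_error_percent(fake_fit(y, f)), 5)
  # random predictions against random labels converge to 50%
  set.seed(14)
  yr <- rbinom(10000, 1, 0.5)
  fr <- runif(10000)
  expect_lt(abs(binary_error_percent(fake_fit(yr, fr)) - 50), 2)
  # invariant to trial order
  o <- sample(20)
  expect_equal(binary_error_percent(fake_fit(y[o], f[o])),
               binary_error_percent(fake_fit(y, f)))
  expect_error(binary_error_percent(fake_fit(numeric(0), numeric(0))),
               "empty")
})

test_that("binomial coefficients read linearly as percent change", {
  expect_equal(coefficient_to_percent(0.12), 12)
  expect_equal(coefficient_to_percent(0.02), 2)
  expect_equal(coefficient_to_percent(0), 0)
  expect_equal(coefficient_to_percent(-0.05), -5)
})

test_that("heatmap matrices reshape, mark significance, and round-trip TSV", {
  wg <- window_grid("hand_on")
  regions <- region_table()$region
  sc <- expand.grid(region = regions, w = seq_len(nrow(wg)),
                    stringsAsFactors = FALSE)
  sc$event <- "hand_on"; sc$family <- "binomial"
  sc$win_start <- wg[sc$w, 1]; sc$win_end <- wg[sc$w, 2]
  set.seed(15)
  sc$t_real <- rnorm(nrow(sc))
  sc$significant <- abs(sc$t_real) > 2
  hm <- tstat_heatmap(sc, "binomial", "hand_on")
  expect_equal(dim(hm$t), c(16, 4))
  expect_equal(unname(hm$significant[cbind(sc$region, paste0(sc$win_start,
                                                             ":", sc$win_end))]),
               sc$significant)
  path <- tempfile(fileext = ".tsv")
  tstat_heatmap(sc, "binomial", "hand_on", file = path)
  back <- read_heatmap_tsv(path)
  expect_equal(back, hm$t, tolerance = 1e-12)
})

test_that("fitted-versus-real scatter reports pairs and rank correlation", {
  y <- c(0, 1, 2, 3, 5, 8)
  perfect <- fake_fit(y, y, family = "gaussian")
  sc <- fitted_vs_real_scatter(perfect)
  expect_equal(sc$rank_cor, 1)
  expect_equal(nrow(sc$pairs), 6)
  # null fits carry no rank correlation on average
  set.seed(16)
  cors <- replicate(40, {
    f <- fake_fit(rnorm(60), rnorm(60), family = "gaussian")
    fitted_vs_real_scatter(f)$rank_cor
  })
  expect_lt(abs(mean(cors)), 0.1)
  expect_error(fitted_vs_real_scatter(fake_fit(1, 1)), "VAS")
})

test_that("VAS accuracy is the mean absolute conditional error", {
  f <- fake_fit(c(0, 2, 4), c(1, 2, 6), family = "gaussian")
  expect_equal(vas_mae(f), mean(c(1, 0, 2)))
})

test_that("accuracy report covers exactly the significant scan rows", {
  fx <- small_proc()
  sc <- scan_windows(fx$proc, regions = "Amyg", events = "hand_on",
                     families = "binomial", n_perm = 60, seed = 17)
  acc <- accuracy_report(sc, fx$proc)
  expect_equal(nrow(acc), sum(sc$significant %in% TRUE))
  if (nrow(acc)) {
    expect_true(all(acc$error_percent >= 0 & acc$error_percent <= 100))
  }
})
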