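test_that("the sliding-window grid tiles 500 ms windows every 250 ms", {
  on <- window_grid("hand_on")
  expect_equal(nrow(on), 4)
  expect_equal(on[, "start"], c(-250, 0, 250, 500))
  expect_equal(on[, "end"], c(250, 500, 750, 1000))
  off <- window_grid("hand_off")
  expect_true(any(off[, "start"] == -750 & off[, "end"] == -250))
  expect_equal(nrow(off), 7)
  expect_equal(unname(window_grid("hand_on", span = c(0, 500))),
               cbind(0, 500), ignore_attr = TRUE)
  expect_error(window_grid("hand_on", span = c(0, 400)), "span")
})

test_that("feature building averages window samples then channels", {
  fx <- small_proc()
  proc <- fx$proc
  # constant-envelope oracle via a hand-built processed object
  ep <- make_epochs(array(NA_real_, c(2, 2, 2000)), 500)
  ep$data[, 1, ] <- 1.0
  ep$data[, 2, ] <- 2.0
  ep$channels$region <- "Amyg"
  ep$trials <- data.frame(trial_id = 1:2)
  ep$zscored <- TRUE; ep$envelope <- TRUE
  toy <- structure(list(patients = list(P1 = list(hand_on = ep)),
                        channels = ep$channels,
                        inclusion = list(regions = "Amyg",
                                         mask = c(TRUE, TRUE)),
                        trials = data.frame(patient_id = "P1", trial_id = 1:2,
                                            temperature = 45,
                                            binary_response = c(0, 1),
                                            vas = c(0, 2))),
                   class = "pain_hfa_study")
  toy$patients$P1$hand_on$trials <- data.frame(trial_id = 1:2,
                                               temperature = 45,
                                               binary_response = c(0, 1),
                                               vas = c(0, 2))
  f <- build_features(toy, "Amyg", "hand_on", c(0, 500))
  expect_equal(f$A, c(1.5, 1.5))           # per-channel means, then averaged
  # rejected channel epochs are excluded from the average
  toy$patients$P1$hand_on$reject[1, 2] <- TRUE
  f2 <- build_features(toy, "Amyg", "hand_on", c(0, 500))
  expect_equal(f2$A, c(1.0, 1.5))
  # brute-force oracle on the real fixture
  f3 <- build_features(proc, "Amyg", "hand_on", c(0, 500))
  ep3 <- proc$patients$P01$hand_on
  sel <- ep3$t_axis >= 0 & ep3$t_axis < 500
  ch <- which(ep3$channels$region == "Amyg")
  i <- 1
  keep <- ch[!ep3$reject[i, ch]]
  oracle <- mean(vapply(keep, function(j) mean(ep3$data[i, j, sel]), 0))
  expect_equal(f3$A[f3$patient_id == "P01"][1], oracle)
})

test_that("with random effects forced to zero the fit reduces to OLS", {
  df <- synth_features(n_pat = 6, n_tr = 15, beta = 0.8, seed = 3)
  dff <- painhfa:::glme_frame(df)
  pf <- lme4::lFormula(y_vas ~ A + (A | temp_f) + (A | patient_f), data = dff,
                       REML = FALSE)
  devf <- do.call(lme4::mkLmerDevfun, pf)
  devf(rep(0, 6))                           # theta = 0: no random variance
  beta_mixed <- environment(devf)$pp$beta(1)
  ols <- coef(lm(y_vas ~ A, dff))
  expect_lt(max(abs(beta_mixed - ols)), 1e-6)
})

test_that("null features give |t| < 2 in at least 90% of seeded runs", {
  hits <- 0
  for (s in 1:100) {
    df <- synth_features(n_pat = 8, n_tr = 15, beta = 0, seed = 1000 + s)
    fit <- fit_glme(df, "binomial")
    if (abs(fit$t_stat) < 2) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("fit_glme enforces its preconditions and returns sane objects", {
  df <- synth_features(n_pat = 2, n_tr = 10, seed = 4)
  expect_error(fit_glme(df, "binomial"), "3 patients")
  one_class <- synth_features(n_pat = 5, n_tr = 10, seed = 5)
  one_class$y_binary <- 1
  expect_error(fit_glme(one_class, "binomial"), "both response classes")

  df2 <- synth_features(n_pat = 6, n_tr = 15, beta = 1, seed = 6)
  fit <- fit_glme(df2, "binomial")
  expect_s3_class(fit, "pain_glme")
  expect_true(is.finite(fit$t_stat))
  expect_true(all(fit$fitted_conditional >= 0 & fit$fitted_conditional <= 1))
  expect_equal(fit$t_stat, fit$beta / fit$se)
  expect_equal(length(coef(fit)), 2)
  expect_equal(length(predict(fit)), nrow(df2))
  g <- fit_glme(df2, "gaussian")
  expect_equal(length(residuals(g)), nrow(df2))
})

test_that("beta and t are invariant to trial-row permutation", {
  df <- synth_features(n_pat = 6, n_tr = 15, beta = 0.5, seed = 7)
  fit1 <- fit_glme(df, "binomial")
  set.seed(8)
  df2 <- df[sample(nrow(df)), ]
  fit2 <- fit_glme(df2, "binomial")
  expect_lt(abs(fit1$beta - fit2$beta), 1e-5)
  expect_lt(abs(fit1$t_stat - fit2$t_stat), 1e-4)
})

test_that("permutation engine matches refitting the model from scratch", {
  df <- synth_features(n_pat = 6, n_tr = 15, beta = 0.4, seed = 9)
  for (fam in c("gaussian", "binomial")) {
    fit <- fit_glme(df, fam)
    resp <- if (fam == "binomial") "y_binary" else "y_vas"
    set.seed(101)
    pseudo <- painhfa:::perm_pseudo_t(fit, n_perm = 3)
    # replicate the within-patient feature shuffles with the same RNG stream
    set.seed(101)
    A <- fit$features$A
    cell_idx <- split(seq_along(A), fit$features$patient_f)
    cell_idx <- cell_idx[lengths(cell_idx) > 1L]
    for (b in 1:3) {
      Ap <- A
      for (sel in cell_idx) Ap[sel] <- A[sel][sample.int(length(sel))]
      df_b <- df
      df_b$A <- Ap
      ref <- fit_glme(df_b, fam)
      expect_lt(abs(pseudo[b] - ref$t_stat), 1e-6)
    }
  }
})

test_that("permutation test keeps bounds/significance/p-value consistent", {
  df <- synth_features(n_pat = 6, n_tr = 15, beta = 1.2, seed = 11)
  fit <- fit_glme(df, "binomial")
  pt <- permutation_test(fit, n_perm = 60, seed = 12)
  expect_equal(pt$significant,
               pt$t_real < pt$bounds[1] || pt$t_real > pt$bounds[2])
  expect_gte(pt$p_value, 2 / pt$n_eff)
  expect_lte(pt$p_value, 1)
  expect_error(permutation_test(fit, n_perm = 4), "minimum")
})

test_that("the permutation p-value formula matches the printed convention", {
  expect_equal(pvalue_from_counts(1, 1000), 0.002)
  expect_equal(pvalue_from_counts(3, 1000), 0.006)
  expect_equal(pvalue_from_counts(0, 1000), 0.002)   # floored at one count
  expect_equal(pvalue_from_counts(1000, 1000), 1)    # capped
  expect_error(pvalue_from_counts(1001, 1000), "between")
})

test_that("window scan assembles a complete results table", {
  fx <- small_proc()
  sc <- scan_windows(fx$proc, regions = "Amyg", events = "hand_on",
                     families = "gaussian", n_perm = 60, seed = 13)
  expect_equal(nrow(sc), 4)                      # 4 onset windows
  expect_true(all(c("beta", "t_real", "p_value", "significant",
                    "n_eff_perm") %in% names(sc)))
  expect_true(all(is.finite(sc$t_real)))
})
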