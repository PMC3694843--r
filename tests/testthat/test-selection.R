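test_that("log_ratio_series forms pseudocounted log ratios", {
  tbl <- exact_count_table(w = c(same = 1), times = 0:3)
  lr <- log_ratio_series(tbl, pseudocount = 0)
  expect_true(all(lr$log_ratio == 0))  # identical counts -> zero series
  # pseudocount arithmetic on a zero count
  tbl2 <- exact_count_table(w = c(v = 1), times = 0:2, n0 = 100)
  tbl2[tbl2$variant_id == "v", c("t1", "t2")] <- list(0, 0)
  lr2 <- log_ratio_series(tbl2, pseudocount = 0.5)
  expect_equal(lr2$log_ratio[lr2$time_hr == 1],
               log(0.5 / 200.5))
  expect_error(
    log_ratio_series(dplyr::mutate(tbl, t0 = ifelse(wt == 1, 0, t0))),
    "positive"
  )
})

test_that("estimate_selection anchors s at 0 (tracks WT) and -1 (no growth)", {
  # WT doubles hourly; 'a' tracks it, 'b' is frozen, 'c' grows at half rate
  tbl <- exact_count_table(w = c(a = 1, b = 0, c = 0.5), times = 0:4)
  est <- estimate_selection(tbl, G_wt = log(2), pseudocount = 0)
  est <- est[order(est$variant_id), ]
  expect_equal(est$s, c(0, -1, -0.5), tolerance = 1e-12)
  expect_equal(est$slope, c(0, -log(2), -log(2) / 2), tolerance = 1e-12)
  expect_true(all(est$klass == "NUMERIC"))
  expect_true(all(est$residual_per_timepoint < 1e-12))
  expect_equal(est$initial_ratio, rep(1, 3))
  expect_error(estimate_selection(tbl, G_wt = 0), "positive growth rate")
})

test_that("vectorized slopes equal per-variant lm fits", {
  set.seed(42)
  times <- c(12, 16, 20, 24, 32, 40, 48)
  Y <- matrix(rnorm(20 * 7), nrow = 20)
  fit <- elastidms:::row_ls_fit(Y, times)
  for (i in c(1, 7, 20)) {
    ref <- lm(Y[i, ] ~ times)
    expect_equal(fit$slope[i], unname(coef(ref)[2]), tolerance = 1e-10)
    expect_equal(fit$mean_abs_resid[i], mean(abs(resid(ref))),
                 tolerance = 1e-10)
  }
})

test_that("null_like_cutoff is mean plus two stop-codon SDs", {
  expect_equal(null_like_cutoff(c(-0.30, -0.30)), -0.30)
  s <- c(-0.34, -0.26)  # mean -0.30, sd ~0.0566
  expect_equal(null_like_cutoff(s), mean(s) + 2 * sd(s))
  expect_error(null_like_cutoff(-0.3), "at least 2")
})

test_that("null refit uses the first three timepoints and gates correctly", {
  tbl <- exact_count_table(w = c(a = 1, b = 0, c = 0.5), times = 0:4)
  est <- estimate_selection(tbl, G_wt = log(2), pseudocount = 0)
  out <- refit_null_like(est, tbl, cutoff = -0.8, G_wt = log(2),
                         pseudocount = 0)
  b <- out[out$variant_id == "b", ]
  expect_equal(b$klass, "NULL_LIKE")
  expect_equal(b$n_timepoints_used, 3)
  expect_equal(b$s, -1, tolerance = 1e-12)  # exact data: same slope on 3 pts
  # variants above the cutoff untouched
  expect_equal(out[out$variant_id == "a", ]$klass, "NUMERIC")
  expect_equal(out[out$variant_id == "c", ]$klass, "NUMERIC")
  expect_equal(out[out$variant_id == "c", ]$n_timepoints_used, 5)
})

test_that("filters fire strictly and commute with null refitting", {
  est <- tibble::tibble(
    variant_id = c("a", "b", "c", "d"),
    s = c(-0.1, -0.1, -0.1, -0.1),
    residual_per_timepoint = c(0.25, 0.26, 0.01, 0.01),
    initial_ratio = c(0.01, 0.01, 0.004, 0.003),
    klass = "NUMERIC"
  )
  out <- apply_filters(est)
  expect_equal(out$klass, c("NUMERIC", "FILTERED", "NUMERIC", "FILTERED"))

  # order independence on simulated data: filter(refit(x)) == filter(refit(filter(x)))
  tr <- truth_std("bimodal", seed = 5)
  con <- constructs_std[1, ]
  tbl <- simulate_bulk_competition(tr, con, params_std, depth = 1e5, seed = 5)
  est0 <- estimate_selection(tbl, G_wt = con$G_wt)
  cut <- null_like_cutoff(est0)
  a <- apply_filters(refit_null_like(est0, tbl, cut, con$G_wt))
  b <- apply_filters(refit_null_like(apply_filters(est0), tbl, cut, con$G_wt))
  expect_identical(a$klass, b$klass)
  expect_equal(a$s, b$s)
})

test_that("noise-free synthetic data returns exact selection coefficients", {
  tr <- truth_std("intermediate", seed = 2)
  con <- constructs_std[1, ]
  tbl <- simulate_bulk_competition(tr, con, params_std, depth = Inf)
  est <- estimate_selection(tbl, G_wt = con$G_wt, pseudocount = 0)
  s_true <- selection_from_function(con$E, tr$F_true, params_std)
  expect_equal(est$s[match(tr$variant_id, est$variant_id)], s_true,
               tolerance = 1e-6)
})

test_that("stop codons read near s = -1 before binning at finite depth", {
  tr <- truth_std("bimodal", seed = 5)
  con <- constructs_std[1, ]
  tbl <- simulate_bulk_competition(tr, con, params_std, depth = 5e5, seed = 9)
  sel <- fit_selection(tbl, G_wt = con$G_wt)
  cut <- attr(sel, "null_cutoff")
  expect_gt(cut, -1)
  expect_lt(cut, -0.05)
  # after the three-timepoint refit the stops sit near true null
  stops <- sel[sel$is_stop, ]
  expect_true(all(stops$klass == "NULL_LIKE"))
  expect_lt(abs(median(stops$s) + 1), 0.15)
  # null variants deplete below the initial-abundance scale within three
  # timepoints under the strongest promoter
  t3 <- paste0("t", con$timepoints[[1]][3])
  wt_c <- tbl[[t3]][tbl$wt == 1]
  stop_c <- tbl[[t3]][!is.na(tbl$is_stop) & tbl$is_stop & tbl$wt != 1]
  expect_lt(median(stop_c) / wt_c, 0.004)
})

test_that("synonym averaging and deviations behave as means", {
  est <- tibble::tibble(
    position = 582L,
    aa = c("K", "K", "M"),
    variant_id = c("582.AAA", "582.AAG", "582.ATG"),
    is_stop = FALSE,
    s = c(-0.10, -0.20, -0.05),
    klass = "NUMERIC"
  )
  agg <- aggregate_synonyms(est, cutoff = -0.4)
  expect_equal(agg$s[agg$aa == "K"], -0.15)        # mean of synonyms
  expect_equal(agg$s[agg$aa == "M"], -0.05)        # single-codon aa
  expect_equal(agg$n_codons[agg$aa == "K"], 2)
  # filtered codons are excluded from the mean
  est$klass[2] <- "FILTERED"
  agg2 <- aggregate_synonyms(est, cutoff = -0.4)
  expect_equal(agg2$s[agg2$aa == "K"], -0.10)
  # deviations of persisting synonyms are centred on zero; the persistence
  # gate is strict (s = -0.1 itself does not persist)
  per <- dplyr::mutate(est, klass = "NUMERIC",
                       s = c(-0.04, 0.06, -0.10))
  dev <- synonym_deviations(per)
  expect_equal(dev$deviation[dev$aa == "K"], c(-0.05, 0.05))
  expect_false("M" %in% dev$aa)
})

test_that("synonyms sharing true function give zero-centred deviations", {
  tr <- truth_std("intermediate", seed = 2)
  con <- constructs_std[3, ]  # TEFdter: intermediate range is informative
  tbl <- simulate_bulk_competition(tr, con, params_std, depth = 5e5, seed = 21)
  sel <- fit_selection(tbl, G_wt = con$G_wt)
  dev <- synonym_deviations(sel)
  expect_gt(nrow(dev), 50)
  expect_lt(abs(median(dev$deviation)), 0.01)
  expect_lt(sd(dev$deviation), 0.05)
})

test_that("epistasis follows the reduced-minus-endogenous convention", {
  endog <- tibble::tibble(position = 582L, aa = c("K", "M", "R"),
                          s = c(0, -0.1, 0), klass = "NUMERIC")
  reduced <- tibble::tibble(position = 582L, aa = c("K", "M", "R"),
                            s = c(-0.6, -0.3, NA),
                            klass = c("NULL_LIKE", "NUMERIC", "MISSING"))
  e <- epistasis(endog, reduced)
  # WT-like at endogenous, null-like at reduced -> epistasis of -1 exactly
  expect_equal(e$epistasis[e$aa == "K"], -1)
  expect_equal(e$epistasis[e$aa == "M"], -0.2)
  expect_true(is.na(e$epistasis[e$aa == "R"]))
  # identical fitness in both conditions -> no epistasis
  same <- epistasis(endog, endog)
  expect_true(all(same$epistasis == 0))
})
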