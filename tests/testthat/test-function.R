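test_that("per_construct_function assigns exactly one of numeric/above/below", {
  tef <- get_construct("TEF")
  tefd <- get_construct("TEFdter")
  aa <- tibble::tibble(
    position = 582L, aa = c("A", "C", "D", "E"),
    s = c(-0.5, -0.2, -0.01, NA),
    klass = c("NULL_LIKE", "NUMERIC", "NUMERIC", "MISSING")
  )
  fn_tef <- per_construct_function(aa, tef, params_std)
  # null-like under TEF -> below the TEF lower edge, 0.067
  expect_equal(fn_tef$kind[fn_tef$aa == "A"], "below")
  expect_equal(round(fn_tef$F[fn_tef$aa == "A"], 3), 0.067)
  # numeric inversion agrees with bisection on the forward model
  f_num <- fn_tef$F[fn_tef$aa == "C"]
  oracle <- uniroot(function(f)
    selection_from_function(tef$E, f, params_std) + 0.2,
    c(1e-9, 10), tol = 1e-12)$root
  expect_equal(f_num, oracle, tolerance = 1e-8)
  # nearly wild-type under TEFdter -> above the 0.71 upper edge
  fn_tefd <- per_construct_function(aa, tefd, params_std)
  expect_equal(fn_tefd$kind[fn_tefd$aa == "D"], "above")
  expect_equal(round(fn_tefd$F[fn_tefd$aa == "D"], 2), 0.71)
  # missing stays missing; every non-missing row has exactly one kind
  expect_true(is.na(fn_tef$kind[fn_tef$aa == "E"]))
  expect_true(all(fn_tef$kind[fn_tef$aa != "E"] %in%
                    c("numeric", "above", "below")))
})

test_that("combine_across_constructs averages numerics and intersects bounds", {
  pc <- tibble::tibble(
    position = 582L, aa = "A",
    construct = c("GPD", "TEF", "TEFdter"),
    kind = c("numeric", "numeric", "above"),
    F = c(0.4, 0.6, 0.2), s = NA_real_
  )
  cmb <- combine_across_constructs(pc)
  expect_equal(cmb$combined_F, 0.5)                 # unweighted mean
  expect_equal(cmb$sd_across_constructs, sd(c(0.4, 0.6)))
  expect_equal(cmb$n_numeric, 2)
  expect_false(cmb$inconsistent)
  # only "above" bounds -> reported as above the largest edge, no numeric
  pc2 <- dplyr::mutate(pc, kind = "above", F = c(0.21, 0.45, 0.71))
  cmb2 <- combine_across_constructs(pc2)
  expect_true(is.na(cmb2$combined_F))
  expect_equal(cmb2$bound_above, 0.71)
  # contradictory bounds flag, not an error
  pc3 <- dplyr::mutate(pc, kind = c("above", "below", "above"),
                       F = c(0.7, 0.1, 0.2))
  expect_true(combine_across_constructs(pc3)$inconsistent)
  # permutation invariance in construct order
  cmb_perm <- combine_across_constructs(pc[c(3, 1, 2), ])
  expect_equal(cmb_perm, cmb)
})

test_that("cross-construct consistency is 1 for identical and ~0 for random F", {
  base <- tidyr::expand_grid(position = 582:584, aa = LETTERS[1:10])
  f <- runif(nrow(base), 0.1, 0.9)
  pc <- dplyr::bind_rows(
    dplyr::mutate(base, construct = "GPD", kind = "numeric", F = f),
    dplyr::mutate(base, construct = "TEF", kind = "numeric", F = f)
  )
  cc <- cross_construct_consistency(pc)
  expect_equal(cc$pairs$r_squared, 1, tolerance = 1e-12)
  expect_equal(cc$pooled_r_squared, 1, tolerance = 1e-12)
  set.seed(1)
  big <- tidyr::expand_grid(position = 582:590, aa = LETTERS[1:20])
  pc2 <- dplyr::bind_rows(
    dplyr::mutate(big, construct = "GPD", kind = "numeric",
                  F = runif(nrow(big))),
    dplyr::mutate(big, construct = "TEF", kind = "numeric",
                  F = runif(nrow(big)))
  )
  expect_lt(cross_construct_consistency(pc2)$pooled_r_squared, 0.1)
  # too few shared numerics -> NA for that pair
  pc3 <- dplyr::bind_rows(pc[pc$construct == "GPD", ],
                          head(pc[pc$construct == "TEF", ], 2))
  expect_true(is.na(cross_construct_consistency(pc3)$pairs$r_squared[1]))
})

test_that("surface/core partition splits positions correctly", {
  cmb <- tibble::tibble(
    position = c(582, 583, 585, 584, 586, 590),
    aa = "A",
    combined_F = c(0.2, 0.3, 0.4, 0.5, 0.6, NA),
    bound_above = c(NA, NA, NA, NA, NA, 0.38),
    bound_below = NA_real_
  )
  part <- partition_surface_core(cmb)
  expect_setequal(part$partition[part$position %in% c(582, 583, 585)],
                  "surface")
  expect_setequal(part$partition[part$position %in% c(584, 586, 590)],
                  "core")
  # bounded estimate carried at its edge and flagged
  expect_true(part$is_bound[part$position == 590])
  expect_equal(part$F_plot[part$position == 590], 0.38)
})

test_that("partition recovers a planted surface-core difference", {
  set.seed(8)
  cmb <- tidyr::expand_grid(position = 582:590, aa = LETTERS[1:15]) |>
    dplyr::mutate(
      combined_F = ifelse(position %in% c(582, 583, 585),
                          runif(dplyr::n(), 0.1, 0.5),
                          runif(dplyr::n(), 0.5, 0.9)),
      bound_above = NA_real_, bound_below = NA_real_
    )
  part <- partition_surface_core(cmb)
  med <- tapply(part$F_plot, part$partition, median)
  expect_lt(med[["surface"]], med[["core"]])
  # and under uniform truth the two partitions are indistinguishable
  cmb$combined_F <- runif(nrow(cmb))
  part2 <- partition_surface_core(cmb)
  p <- wilcox.test(F_plot ~ partition, data = part2)$p.value
  expect_gt(p, 0.01)
})

test_that("BLOSUM similarity correlates with planted similarity-driven function", {
  res <- cached_pipeline("planted", seed = 13)
  bl <- blosum_similarity_table(res$combined_F)
  expect_gt(bl$spearman_rho, 0.3)
  # self-substitutions carry the diagonal score but are excluded
  self <- bl$table[bl$table$is_self, ]
  expect_true(all(self$blosum_score ==
                    diag(elastidms:::blosum62_matrix)[self$aa]))
})

test_that("ddg join handles degenerate and exact-inverse inputs", {
  cmb <- tibble::tibble(position = rep(582:584, each = 3),
                        aa = rep(c("A", "C", "D"), 3),
                        combined_F = runif(9))
  # identical ddG everywhere -> correlation undefined
  flat <- dplyr::mutate(cmb[, c("position", "aa")], ddg_kcal_mol = 2)
  out <- ddg_function_join(flat, cmb)
  expect_true(is.na(out$pearson_r))
  # ddG = -F exactly -> r = -1
  inv <- dplyr::mutate(cmb[, c("position", "aa")],
                       ddg_kcal_mol = -cmb$combined_F)
  expect_equal(ddg_function_join(inv, cmb)$pearson_r, -1, tolerance = 1e-12)
  # unmatched keys are counted, not fatal
  out2 <- ddg_function_join(flat[1:5, ], cmb)
  expect_equal(out2$n_dropped, 4)
  # independent ddG at library scale -> weak correlation
  set.seed(2)
  big <- tidyr::expand_grid(position = 582:590, aa = LETTERS[1:20]) |>
    dplyr::mutate(combined_F = runif(dplyr::n()))
  rand <- dplyr::mutate(big[, c("position", "aa")],
                        ddg_kcal_mol = rnorm(nrow(big)))
  expect_lt(abs(ddg_function_join(rand, big)$pearson_r), 0.2)
})

test_that("dfe_histogram bins and classifies shares", {
  z <- dfe_histogram(rep(0, 10), type = "selection")
  expect_equal(sum(z$histogram$count > 0), 1)        # single occupied bin
  expect_equal(z$shares$wt_like, 1)
  # constructed bimodal F at endogenous expression gives a bimodal s DFE
  f <- c(rep(1, 50), rep(0, 50))
  s <- selection_from_function(1, f, params_std)
  d <- dfe_histogram(s, type = "selection")
  expect_equal(d$shares$wt_like, 0.5)
  expect_equal(d$shares$null_like, 0.5)
  expect_equal(d$shares$intermediate, 0)
})

test_that("intermediate functional defects hide at endogenous expression", {
  # F_true uniform on (0.25, 0.95): nearly all WT-like at E = 1, and the
  # WT-like share falls monotonically down the expression ladder
  set.seed(3)
  f_true <- runif(400, 0.25, 0.95)
  share_wt <- vapply(constructs_std$E, function(E) {
    s <- selection_from_function(E, f_true, params_std)
    mean(s > -0.05)
  }, numeric(1))
  expect_gte(share_wt[1], 0.9)
  expect_true(all(diff(share_wt) < 0))
})
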