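test_that("baseline subtraction is correct and idempotent", {
  tr <- bret_truth("a", "p1", 6, 1, basal = 0.2)
  d <- generate_bret_dataset(tr, n_rep = 1)

  # constant curve maps to all zeros
  dc <- d
  dc$response <- 0.7
  expect_true(all(subtract_baseline(dc)$response == 0))

  # synthetic basal is removed: refitting finds basal ~ 0
  ds <- subtract_baseline(d)
  f <- fit_hill(ds)
  expect_equal(f$basal, 0, tolerance = 1e-4)

  # idempotent after first application (basal already ~ 0)
  expect_equal(subtract_baseline(ds)$response, ds$response,
               tolerance = 1e-6)

  # explicit zero baseline column is the identity
  d0 <- d
  d0$baseline <- 0
  expect_equal(subtract_baseline(d0)$response, d$response)
})

test_that("reference normalization scales as expected", {
  trs <- list(bret_truth("dopamine", "p1", 7, 1.0),
              bret_truth("test", "p1", 6, 0.5))
  d <- generate_bret_dataset(trs, n_rep = 2)
  dn <- normalize_to_reference(d, "dopamine")
  ref_top <- max(d$conc_M[d$agonist == "dopamine"])
  m <- mean(d$response[d$agonist == "dopamine" & d$conc_M == ref_top])
  sel <- dn$agonist == "dopamine" & dn$conc_M == ref_top
  expect_equal(mean(dn$response[sel]), 1.0)

  # scale invariance: multiplying all raw responses by k changes nothing
  dk <- d
  dk$response <- d$response * 3.7
  expect_equal(normalize_to_reference(dk, "dopamine")$response,
               dn$response, tolerance = 1e-12)

  expect_error(normalize_to_reference(d, "absent"), "not in data")
})

test_that("Hill fit recovers printed GIRK parameter sets exactly", {
  for (tr in girk_legend_truths()) {
    d <- generate_bret_dataset(tr, n_rep = 1)
    f <- fit_hill(d)
    expect_true(f$converged)
    expect_equal(f$pec50, tr$pec50, tolerance = 0.01 / tr$pec50)
    expect_equal(f$top, tr$emax, tolerance = 0.01 / tr$emax)
  }
})

test_that("flat and undersampled curves are handled without crashing", {
  d <- data.frame(conc_M = default_conc_grid(), response = 0)
  f <- fit_hill(d)
  expect_false(f$converged)

  expect_error(fit_hill(data.frame(conc_M = c(1e-8, 1e-7, 1e-6),
                                   response = c(0, 0.5, 1))),
               "4 distinct")
})

test_that("optimizer matches the brute-force grid-search oracle", {
  set.seed(101)
  grid <- default_conc_grid()
  for (i in 1:20) {
    # truths on the oracle's own grid so its best point is exact
    p <- sample(seq(4.5, 8.5, by = 0.01), 1)
    n <- sample(seq(0.5, 2, by = 0.05), 1)
    top <- runif(1, 0.5, 2)
    d <- generate_bret_dataset(bret_truth("a", "p", p, top, n), grid,
                               n_rep = 1)
    f <- fit_hill(d)
    o <- grid_search_hill(d$conc_M, d$response,
                          pec50_grid = seq(4, 9, by = 0.01),
                          n_grid = seq(0.4, 2.2, by = 0.05))
    expect_lt(abs(f$pec50 - o$pec50), 0.01 + 1e-9)
    expect_lt(abs(f$hill_n - o$hill_n), 0.05 + 1e-9)
  }
})

test_that("predicted curves satisfy the sigmoid identities", {
  d <- generate_bret_dataset(bret_truth("a", "p", 6, 1, hill_n = 1,
                                        basal = 0.1), n_rep = 1)
  f <- fit_hill(d)
  ec50 <- 10^-f$pec50
  expect_equal(predict_curve(f, ec50), f$basal + f$top / 2,
               tolerance = 1e-9)
  expect_equal(predict_curve(f, 1e3), f$basal + f$top, tolerance = 1e-6)
  # one log unit below EC50 at unit slope: basal + top/11
  expect_equal(predict_curve(f, ec50 / 10), f$basal + f$top / 11,
               tolerance = 1e-6)
  # round trip: noise-free data are reproduced
  expect_equal(predict_curve(f, d$conc_M), d$response, tolerance = 1e-6)
})

test_that("fit is invariant to row order and row duplication", {
  d <- generate_bret_dataset(bret_truth("a", "p", 6.4, 1.2, 1.3,
                                        noise_sd = 0.05),
                             n_rep = 3, seed = 5)
  f1 <- fit_hill(d)
  f2 <- fit_hill(d[rev(seq_len(nrow(d))), ])
  f3 <- fit_hill(rbind(d, d))
  expect_equal(f1$pec50, f2$pec50, tolerance = 1e-8)
  expect_equal(f1$pec50, f3$pec50, tolerance = 1e-8)
  expect_equal(f1$top, f3$top, tolerance = 1e-8)
})

test_that("pEC50 recovery stays accurate under 5 percent noise", {
  # each curve is assayed on a series bracketing its own EC50, as a
  # dilution series is designed in practice
  set.seed(202)
  errs <- replicate(200, {
    p <- runif(1, 4, 9)
    n <- runif(1, 0.5, 2)
    grid <- 10^seq(-p - 4, -p + 4, length.out = 9)
    tr <- bret_truth("a", "p", p, 1, n, noise_sd = 0.05)
    d <- generate_bret_dataset(tr, grid, n_rep = 3,
                               seed = sample.int(1e6, 1))
    abs(fit_hill(d)$pec50 - p)
  })
  expect_lt(median(errs), 0.05)
})
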