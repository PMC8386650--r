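test_that("a single hill reconstructs to an inverted Gaussian", {
  h <- hills_record(time = 4, center = 3, sigma = 0.2, height = 0.1,
                    bias_factor = 10)
  grid <- seq(0, 6, by = 0.01)
  fes <- reconstruct_fes(h, grid)
  # depth gamma/(gamma-1) * h, minimum exactly at the hill center
  expect_equal(fes$cv[which.min(fes$free_energy)], 3)
  expect_equal(min(fes$free_energy), 0)
  expect_equal(max(fes$free_energy), 10 / 9 * 0.1, tolerance = 1e-6)
  # shape: F(s) = depth * (1 - exp(-(s-c)^2 / 2 sigma^2))
  expect_equal(fes$free_energy,
               10 / 9 * 0.1 * (1 - exp(-(grid - 3)^2 / (2 * 0.2^2))),
               tolerance = 1e-9)
  expect_error(reconstruct_fes(h[0, ], grid), "no hills")
})

test_that("reconstruction is invariant to hill order", {
  set.seed(4)
  n <- 500
  h <- hills_record(time = seq_len(n), center = runif(n, 1, 7),
                    sigma = 0.1, height = runif(n, 0.01, 0.1),
                    bias_factor = 10)
  grid <- seq(0, 8, by = 0.05)
  perm <- sample(n)
  hp <- hills_record(time = seq_len(n), center = h$center[perm],
                     sigma = 0.1, height = h$height[perm],
                     bias_factor = 10)
  expect_equal(reconstruct_fes(h, grid)$free_energy,
               reconstruct_fes(hp, grid)$free_energy, tolerance = 1e-12)
})

test_that("convergence series counts blocks and ends at the full FES", {
  n <- 2500
  h <- hills_record(time = seq_len(n), center = runif(n, 1, 7),
                    sigma = 0.1, height = 0.05, bias_factor = 10)
  grid <- seq(0, 8, by = 0.05)
  ser <- convergence_series(h, grid, block = 1000)
  # 2 full blocks plus the remainder profile
  expect_length(ser, 3)
  expect_equal(ser[[3]]$free_energy, reconstruct_fes(h, grid)$free_energy)
  # block larger than the record: a single profile equal to the full FES
  ser1 <- convergence_series(h, grid, block = 10000)
  expect_length(ser1, 1)
  expect_equal(ser1[[1]]$free_energy,
               reconstruct_fes(h, grid)$free_energy)
})

test_that("successive profiles stabilize on a converged toy run", {
  pot <- toy_potential("double_well", wells = c(2.8, 5.5), barrier = 1.3)
  r <- run_langevin_metadynamics(
    pot, metad_params(wall_position = 8, wall_lower = 1),
    n_steps = 2e6, seed = 42)
  grid <- seq(1, 8, by = 0.02)
  ser <- convergence_series(r$hills, grid, block = 1500)
  d <- vapply(seq_len(length(ser) - 1), function(i) {
    fes_rms_difference(ser[[i]], ser[[i + 1]], region = c(2, 6.5))
  }, numeric(1))
  # late increments move the profile far less than early ones
  expect_lt(mean(tail(d, 2)), mean(head(d, 2)))
  expect_lt(tail(d, 1), 0.15)
})

test_that("well and barrier detection matches analytic profiles", {
  grid <- seq(-3, 3, by = 0.01)
  b <- 1.3
  u <- b * ((grid^2 - 1)^2)  # symmetric double well at +-1, barrier b
  fes <- structure(data.frame(cv = grid, free_energy = u - min(u)),
                   class = c("free_energy_profile", "data.frame"))
  wb <- find_wells_and_barriers(fes)
  expect_equal(nrow(wb$wells), 2)
  expect_equal(wb$wells$cv, c(-1, 1), tolerance = 0.011)
  expect_equal(wb$barriers$barrier_kcal_mol, c(b, b), tolerance = 1e-3)

  # monotone profile: a single well at the boundary, no barriers
  mono <- structure(data.frame(cv = grid, free_energy = grid - min(grid)),
                    class = c("free_energy_profile", "data.frame"))
  wbm <- find_wells_and_barriers(mono)
  expect_equal(nrow(wbm$wells), 1)
  expect_equal(wbm$wells$cv, min(grid))
  expect_equal(nrow(wbm$barriers), 0)

  # shallow ripples below the prominence threshold are not wells
  ripple <- structure(
    data.frame(cv = grid,
               free_energy = 0.1 * (1 + sin(5 * grid))),
    class = c("free_energy_profile", "data.frame"))
  expect_equal(nrow(find_wells_and_barriers(ripple, 0.5)$wells), 0)
})

test_that("hills records round-trip through the text format", {
  h <- hills_record(time = c(4, 8, 4, 8), center = c(2.1, 2.3, 5.0, 5.2),
                    sigma = 0.1, height = c(0.1, 0.09, 0.1, 0.08),
                    walker = c(1, 1, 2, 2), bias_factor = 10,
                    cv_label = "d_OG")
  path <- withr::local_tempfile(fileext = ".hills")
  write_hills(h, path)
  expect_true(startsWith(readLines(path, n = 1), "#! FIELDS"))
  h2 <- read_hills(path)
  expect_equal(h2$center, h$center, tolerance = 1e-7)
  expect_equal(h2$height, h$height, tolerance = 1e-7)
  expect_equal(attr(h2, "bias_factor"), 10)
  expect_equal(attr(h2, "cv_label"), "d_OG")

  expect_error(hills_record(time = c(2, 1), center = c(1, 2), sigma = 0.1,
                            height = 0.1), "non-decreasing")
})

test_that("FES profiles round-trip through CSV", {
  h <- hills_record(time = 1:3, center = c(2, 3, 4), sigma = 0.2,
                    height = 0.1, bias_factor = 10)
  fes <- reconstruct_fes(h, seq(0, 6, by = 0.1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fes_csv(fes, path)
  fes2 <- read_fes_csv(path)
  expect_equal(fes2$free_energy, fes$free_energy, tolerance = 1e-9)
})
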