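test_that("size inclusion is a guarded product with the log identity", {
  expect_equal(size_include(161.75, 2.0), 323.5)
  expect_equal(size_include(5, 1.0), 5)
  expect_error(size_include(-1, 2), "positive")
  expect_error(size_include(1, 0), "positive")
  withr::with_seed(14, {
    t <- exp(rnorm(50)); s <- exp(rnorm(50))
    expect_equal(log(size_include(t, s)), log(t) + log(s), tolerance = 1e-12)
  })
})

test_that("ln transform renames columns and rejects non-positive entries", {
  df <- data.frame(a = c(exp(1), 1, 10), b = 1:3)
  out <- ln_transform(df, "a")
  expect_named(out, c("ln_a", "b"))
  expect_equal(out$ln_a[1:2], c(1, 0))
  expect_equal(exp(out$ln_a), df$a, tolerance = 1e-12)
  df$a[2] <- -5
  expect_error(ln_transform(df, "a"), "row")
  expect_error(ln_transform(df, "zz"), "not in table")
})

test_that("phylogenetic size correction returns proper PGLS residuals", {
  tr <- generate_pure_birth_tree(15, seed = 3)
  C <- bm_covariance(tr)
  withr::with_seed(4, {
    size_ln <- as.numeric(crossprod(chol(C), rnorm(15)))
    # exactly proportional trait -> zero residuals
    expect_equal(size_correct(2 * size_ln + 1, size_ln, C), rep(0, 15),
                 tolerance = 1e-10, ignore_attr = TRUE)
    trait_ln <- 0.5 * size_ln + rnorm(15)
    # identity covariance reduces to OLS residuals
    r_ols <- size_correct(trait_ln, size_ln, diag(15))
    expect_equal(unname(r_ols), unname(resid(lm(trait_ln ~ size_ln))),
                 tolerance = 1e-8)
    # PGLS normal equations: residuals orthogonal to design under C^-1
    r <- size_correct(trait_ln, size_ln, C)
    Ci <- solve(C)
    expect_equal(as.numeric(size_ln %*% Ci %*% r), 0, tolerance = 1e-8)
    expect_equal(as.numeric(rep(1, 15) %*% Ci %*% r), 0, tolerance = 1e-8)
    expect_error(size_correct(trait_ln[-1], size_ln, C), "dimension")
  })
})

test_that("expected isometric slopes follow dimensional arguments", {
  expect_equal(expected_isometry_slope("volume"), 1)
  expect_equal(expected_isometry_slope("area"), 2 / 3)
  expect_equal(expected_isometry_slope("modulus"), 0)
  expect_equal(expected_isometry_slope("strength"), 1)
  expect_error(expected_isometry_slope("density"))
})

test_that("allometry fit matches hand OLS on identity covariance", {
  x <- c(0, 1, 2, 3)
  y <- c(0.1, 1.1, 1.9, 3.1)
  fa <- fit_allometry(y, x, diag(4))
  b_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fa$slope, b_hand, tolerance = 1e-10)
  expect_named(fa$ci, c("95", "99"))
  expect_error(fit_allometry(y[1:3], x[1:3], diag(3)), "at least 4")
})

test_that("noiseless allometric data give exact slope and degenerate CI", {
  tr <- generate_pure_birth_tree(20, seed = 5)
  cfg <- bm_trait_config(slope = 1, sigma_size = 0.4, sigma_resid = 0,
                         seed = 6)
  tt <- simulate_allometric_traits(tr, cfg)
  C <- bm_covariance(tr, tt$species)
  fa <- fit_allometry(tt$ln_trait, tt$ln_size, C, trait_kind = "volume")
  expect_equal(fa$slope, 1, tolerance = 1e-8)
  expect_lt(diff(fa$ci[["95"]]), 1e-6)
  expect_equal(unname(fa$classification["95"]), "isometric")
})

test_that("classification follows the CI rule", {
  expect_equal(classify_allometry(
    fake_allometry(1.42, c(1.25, 1.60)), 0.95, expected_slope = 0.67),
    "positive")
  expect_equal(classify_allometry(
    fake_allometry(1.00, c(0.88, 1.12)), 0.95, expected_slope = 1.00),
    "isometric")
  expect_equal(classify_allometry(
    fake_allometry(0.50, c(0.40, 0.60)), 0.95, expected_slope = 1.00),
    "negative")
  expect_error(classify_allometry(
    fake_allometry(1, c(0, 2)), 0.90, expected_slope = 1), "level")
})

test_that("the 99% classification is never stricter than the 95% one", {
  tr <- generate_pure_birth_tree(25, seed = 7)
  C <- bm_covariance(tr)
  for (s in 1:25) {
    cfg <- bm_trait_config(slope = 1, sigma_size = 0.3, sigma_resid = 0.15,
                           seed = s)
    tt <- simulate_allometric_traits(tr, cfg)
    fa <- fit_allometry(tt$ln_trait, tt$ln_size, C, trait_kind = "volume")
    if (fa$classification[["95"]] == "isometric")
      expect_equal(unname(fa$classification[["99"]]), "isometric")
    expect_gte(fa$ci[["95"]]["lower"], fa$ci[["99"]]["lower"])
    expect_lte(fa$ci[["95"]]["upper"], fa$ci[["99"]]["upper"])
  }
})

test_that("false-allometry rate under true isometry is about 1 - level", {
  tr <- generate_pure_birth_tree(40, seed = 8)
  C <- bm_covariance(tr)
  flagged <- vapply(1:200, function(s) {
    cfg <- bm_trait_config(slope = 1, sigma_size = 0.3, sigma_resid = 0.1,
                           seed = 1000 + s)
    tt <- simulate_allometric_traits(tr, cfg)
    fa <- fit_allometry(tt$ln_trait, tt$ln_size, C, trait_kind = "volume")
    fa$classification[["95"]] != "isometric"
  }, logical(1))
  expect_gt(mean(flagged), 0.005)
  expect_lt(mean(flagged), 0.12)
})

test_that("the allometry battery covers 4 traits x 2 size measures", {
  tr <- generate_pure_birth_tree(20, seed = 9)
  C <- bm_covariance(tr)
  withr::with_seed(10, {
    ln_cs <- as.numeric(crossprod(chol(C), rnorm(20))) * 0.2
    traits <- list(volume = 1 * ln_cs + rnorm(20, sd = 0.05),
                   complexity = 1.42 * ln_cs + rnorm(20, sd = 0.05),
                   modulus = rnorm(20, sd = 0.05),
                   strength = 1 * ln_cs + rnorm(20, sd = 0.05))
    tab <- run_allometry_battery(
      traits,
      c(volume = "volume", complexity = "area", modulus = "modulus",
        strength = "strength"),
      sizes = list(centroid_size = ln_cs, body_mass = ln_cs + 8),
      C = C)
    expect_equal(nrow(tab), 8L)
    expect_equal(tab$expected_RC,
                 rep(c(1, 1, 2 / 3, 2 / 3, 0, 0, 1, 1)))
    expect_true(all(tab$classification %in%
                      c("isometric", "positive", "negative")))
  })
})
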