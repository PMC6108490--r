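test_that("Newick parsing validates and round-trips", {
  tr <- parse_newick("(A:1,B:1);")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  C <- bm_covariance(tr, c("A", "B"))
  expect_equal(unname(diag(C)), c(1, 1))

  tr2 <- parse_newick("((A:1,B:1):1,C:2);")
  C2 <- bm_covariance(tr2, c("A", "B", "C"))
  expect_equal(unname(diag(C2)), c(2, 2, 2))
  # canonical round trip
  expect_equal(parse_newick(ape::write.tree(tr2))$tip.label, tr2$tip.label)

  expect_error(parse_newick("(A:1,A:1);"), "duplicate")
  expect_error(parse_newick("(A:1,B:1;"), "parse|malformed")
  expect_error(parse_newick("(A,B);"), "branch lengths")
})

test_that("Brownian covariance equals shared path lengths", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  C <- bm_covariance(tr, c("A", "B", "C"))
  expect_equal(unname(C),
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3))
  # unknown tip request
  expect_error(bm_covariance(tr, c("A", "Z")), "absent")
})

test_that("covariance matches the independent vcv computation on random trees", {
  withr::with_seed(21, {
    for (i in 1:10) {
      tr <- ape::rtree(sample(4:15, 1))
      C <- bm_covariance(tr)
      ref <- ape::vcv(tr)[rownames(C), colnames(C)]
      expect_equal(C, ref, tolerance = 1e-12)
      # invariants: symmetry, PSD, diagonal = tip depths, C_ij <= min(C_ii, C_jj)
      expect_equal(C, t(C))
      expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-10)
      expect_true(all(C <= pmin(outer(diag(C), rep(1, nrow(C))),
                                outer(rep(1, nrow(C)), diag(C))) + 1e-12))
    }
  })
})

test_that("uniform branch lengths reset every edge to one, idempotently", {
  tr <- parse_newick("((A:1,B:0.5):2,C:0.25);")
  u <- set_uniform_branch_lengths(tr)
  expect_true(all(u$edge.length == 1))
  expect_identical(set_uniform_branch_lengths(u)$edge.length, u$edge.length)
  # tip depths become node counts from the root
  Cu <- bm_covariance(u, c("A", "B", "C"))
  expect_equal(unname(diag(Cu)), c(2, 2, 1))
  expect_equal(Cu, round(Cu))
})

test_that("PGLS reduces to OLS on a star phylogeny (identity covariance)", {
  withr::with_seed(5, {
    n <- 20
    y <- rnorm(n)
    x <- rnorm(n)
    f <- pgls_fit(y, cbind(`(Intercept)` = 1, x = x), diag(n))
    ref <- lm(y ~ x)
    expect_equal(f$coefficients$estimate, unname(coef(ref)), tolerance = 1e-8)
    expect_equal(f$coefficients$se,
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-8)
    expect_equal(f$coefficients$p,
                 unname(summary(ref)$coefficients[, 4]), tolerance = 1e-8)
  })
})

test_that("three-taxon worked case equals the dense-algebra oracle", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  C <- bm_covariance(tr, c("A", "B", "C"))
  y <- c(2, 1, 0)
  X <- cbind(`(Intercept)` = 1, x = c(1, 0, 0))
  f <- pgls_fit(y, X, C)
  o <- gls_oracle(y, X, C)
  expect_equal(f$coefficients$estimate, o$beta, tolerance = 1e-10)
  expect_equal(f$coefficients$se, o$se, tolerance = 1e-10)
  # frozen values from the oracle
  expect_equal(f$coefficients$estimate, c(0.50, 1.25), tolerance = 1e-10)
})

test_that("rank deficiency and singular covariance are reported", {
  n <- 8
  y <- rnorm(n)
  X <- cbind(`(Intercept)` = 1, a = 1:n, b = 2 * (1:n))
  expect_error(pgls_fit(y, X, diag(n)), "b")
  # zero-length resolved polytomy makes C singular -> documented jitter path
  trs <- parse_newick("((A:0,B:0):1,C:1);")
  Cs <- bm_covariance(trs, c("A", "B", "C"))
  expect_message(
    pgls_fit(c(1, 2, 3), cbind(1, x = c(0, 1, 0)), Cs), "jitter")
})

test_that("log-likelihood and sigma2 match direct formulas", {
  withr::with_seed(9, {
    tr <- ape::rtree(6)
    C <- bm_covariance(tr)
    y <- rnorm(6)
    X <- cbind(`(Intercept)` = 1, x = rnorm(6))
    f <- pgls_fit(y, X, C)
    o <- gls_oracle(y, X, C)
    expect_equal(f$sigma2, o$sigma2, tolerance = 1e-10)
    Ci <- solve(C)
    r <- y - X %*% o$beta
    s2ml <- as.numeric(t(r) %*% Ci %*% r) / 6
    ll <- -0.5 * (6 * log(2 * pi * s2ml) + determinant(C)$modulus[1] + 6)
    expect_equal(f$logLik, ll, tolerance = 1e-8)
  })
})
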