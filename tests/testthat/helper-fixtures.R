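# shared builders for small test objects

# stress-strain curve from raw vectors (bypasses record plumbing)
make_curve <- function(strain, stress) {
  structure(list(stress = stress, strain = strain,
                 area = cylinder_contact_area(), gauge_height = 10),
            class = "stress_strain_curve")
}

# analytic solid-cylinder core in canonical coordinates
solid_cylinder_core <- function(height = 10, n_seg = 256) {
  core_sample(mesh_cylinder(height, height / 2, n_seg = n_seg),
              height = height)
}

# a fake allometry result with given slope and CIs, for classifier tests
fake_allometry <- function(slope, ci95, ci99 = ci95, expected = NA_real_) {
  structure(list(trait = "t", size_measure = "s", slope = slope, se = NA,
                 p = NA, df = NA,
                 ci = list("95" = c(lower = ci95[1], upper = ci95[2]),
                           "99" = c(lower = ci99[1], upper = ci99[2])),
                 expected_slope = expected, classification = NULL),
            class = "allometry_result")
}

# dense-algebra GLS oracle: direct matrix arithmetic, independent of pgls_fit
gls_oracle <- function(y, X, C) {
  Ci <- solve(C)
  beta <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y)
  r <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- as.numeric(t(r) %*% Ci %*% r) / df
  se <- sqrt(sigma2 * diag(solve(t(X) %*% Ci %*% X)))
  list(beta = as.numeric(beta), se = as.numeric(se), sigma2 = sigma2)
}
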