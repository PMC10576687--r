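test_that("band power matches analytic sinusoid power and Parseval", {
  fs <- 250
  tt <- (0:(20 * fs - 1)) / fs
  rec <- recording(rbind(2 * sin(2 * pi * 9 * tt),
                         0.5 * sin(2 * pi * 20 * tt),
                         0 * tt), fs = fs)
  la <- band_power(rec, c(8, 10))
  expect_equal(unname(la[1]), 2^2 / 2, tolerance = 0.05)
  beta <- band_power(rec, c(12, 30))
  expect_lt(unname(beta[1]), 0.01 * la[1])
  expect_equal(unname(beta[2]), 0.5^2 / 2, tolerance = 0.05)
  # all-zero channel has zero power in every band
  for (b in default_bands()) expect_equal(unname(band_power(rec, b)[3]), 0)

  # white noise: six-band sum below total variance; tiling bands recover it
  set.seed(2)
  wn <- recording(matrix(rnorm(2 * 6000), 2), fs = fs)
  six <- sum(vapply(default_bands(), function(b) band_power(wn, b)[1], numeric(1)))
  expect_lt(six, var(wn$data[1, ]))
  tiling <- list(c(0.5, 40), c(40, 80), c(80, 124.5))
  tot <- sum(vapply(tiling, function(b) band_power(wn, b)[1], numeric(1)))
  expect_equal(tot / var(wn$data[1, ]), 1, tolerance = 0.05)
  expect_error(band_power(rec, c(100, 130)), "Nyquist")
})

test_that("theta/beta ratio is element-wise, scale invariant, and guards zeros", {
  expect_equal(theta_beta_ratio(6, 3), 2)
  th <- c(a = 1, b = 2.5); be <- c(a = 1, b = 2.5)
  expect_equal(unname(theta_beta_ratio(th, be)), c(1, 1))
  fs <- 250; tt <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 6 * tt) + 0.5 * sin(2 * pi * 20 * tt)
  r1 <- recording(rbind(x, -x), fs = fs)
  r2 <- recording(rbind(2 * x, -2 * x), fs = fs)
  tbr1 <- theta_beta_ratio(band_power(r1, c(4, 8)), band_power(r1, c(12, 30)))
  tbr2 <- theta_beta_ratio(band_power(r2, c(4, 8)), band_power(r2, c(12, 30)))
  expect_equal(tbr1, tbr2, tolerance = 1e-9)
  expect_error(theta_beta_ratio(c(Cz = 1), c(Cz = 0)), "Cz")
})

test_that("power matrices have cohort shape, aligned rows, and six bands plus TBR", {
  sub <- make_subject(n_channels = 16, duration_s = 6, seed = 61)
  recs <- list(sub$rec, sub$rec, synthesize_recording(sub$labels, sub$templates,
                                                      noise_sd = 2, seed = 99))
  pms <- build_power_matrices(recs, subject_ids = c("a", "b", "c"))
  expect_length(pms, 7)
  expect_named(pms, c("delta", "theta", "low_alpha", "high_alpha", "beta",
                      "gamma", "tbr"))
  for (pm in pms) expect_equal(dim(pm), c(3, 16))
  # identical recordings give identical rows
  expect_equal(pms$delta["a", ], pms$delta["b", ])
  expect_false(isTRUE(all.equal(pms$delta["a", ], pms$delta["c", ])))
  # scale equivariance: c*V -> c^2 * power, TBR unchanged
  recs2 <- lapply(recs, function(r) { r$data <- 3 * r$data; r })
  pms2 <- build_power_matrices(recs2, subject_ids = c("a", "b", "c"))
  expect_equal(pms2$delta, 9 * pms$delta, tolerance = 1e-9)
  expect_equal(pms2$tbr, pms$tbr, tolerance = 1e-9)
})

test_that("ICA recovers planted non-Gaussian sources and reconstructs the rank-M fit", {
  worst <- 1
  for (s in 1:10) {
    set.seed(s)
    N <- 60; C <- 91
    s1 <- rep(0, C); s1[1:12] <- 3
    s2 <- rep(0, C); s2[(C - 11):C] <- 3
    S <- rbind(s1, s2)
    A <- cbind(rexp(N) - 1, sample(c(-1, 1), N, TRUE) * rexp(N))
    X <- A %*% S + matrix(rnorm(N * C, sd = 0.3), N, C)
    ica <- ica_decompose(X, 2, seed = s)
    cc <- abs(cor(t(ica$spatial_maps), t(S)))
    worst <- min(worst, min(apply(cc, 2, max)))
  }
  expect_gt(worst, 0.95)

  set.seed(3)
  X <- matrix(rexp(40 * 30), 40, 30)
  ica <- ica_decompose(X, 5, seed = 7)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 5, nv = 5)
  rank5 <- sv$u %*% diag(sv$d[1:5]) %*% t(sv$v)
  expect_lt(max(abs(ica$loadings %*% ica$spatial_maps - rank5)) /
              max(abs(rank5)), 1e-6)
  # determinism under a fixed seed
  ica2 <- ica_decompose(X, 5, seed = 7)
  expect_equal(ica$loadings, ica2$loadings, tolerance = 1e-12)
  expect_error(ica_decompose(X, 50, seed = 1), "exceeds")
})

test_that("component orientation follows the reference group and is idempotent", {
  set.seed(4)
  X <- matrix(rexp(30 * 20), 30, 20)
  g <- rep(c("HC", "ADHD"), each = 15)
  ica <- ica_decompose(X, 4, seed = 2)
  o1 <- orient_and_zscore(ica, g, reference_group = "HC")
  for (m in 1:4) {
    expect_gte(mean(o1$loadings[g == "HC", m]),
               mean(o1$loadings[g == "ADHD", m]))
  }
  o2 <- orient_and_zscore(o1, g, reference_group = "HC")
  expect_equal(o1$loadings, o2$loadings)
  # z-maps are channel-standardized
  expect_lt(max(abs(rowMeans(o1$zmaps))), 1e-9)
  expect_lt(max(abs(apply(o1$zmaps, 1, sd) - 1)), 1e-9)
  expect_error(orient_and_zscore(ica, rep("HC", 30)), "two groups")
})

test_that("loading tests apply the Bonferroni threshold and |Z|>2 selection", {
  set.seed(6)
  N <- 60
  X <- matrix(rexp(N * 24), N, 24)
  g <- rep(c("HC", "ADHD"), each = N / 2)
  ica <- ica_decompose(X, 5, seed = 3)
  # plant a strong group shift on component 2's loadings
  ica$loadings[g == "ADHD", 2] <- ica$loadings[g == "ADHD", 2] +
    3 * sd(ica$loadings[, 2])
  tc <- test_components(ica, g)
  expect_true(tc$tests$significant[2])
  expect_equal(tc$n_comparisons, 5)
  # threshold rule: p must beat alpha/M, not alpha
  borderline <- tc$tests$p < 0.05 & tc$tests$p >= 0.05 / 5
  expect_true(all(!tc$tests$significant[borderline]))
  # channel selection matches the z threshold exactly
  for (nm in names(tc$selected_channels)) {
    m <- match(nm, tc$tests$component)
    expect_identical(tc$selected_channels[[nm]],
                     colnames(ica$zmaps)[abs(ica$zmaps[m, ]) > 2])
  }
  # permutation invariance of subjects
  perm <- sample(N)
  ica_p <- ica
  ica_p$loadings <- ica$loadings[perm, ]
  tc_p <- test_components(ica_p, g[perm])
  expect_equal(tc_p$tests$t, tc$tests$t, tolerance = 1e-12)
})
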