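test_that("GFP matches the defining formula on hand-computed cases", {
  rec2 <- recording(matrix(c(1, -1), 2, 1), fs = 250)
  expect_equal(compute_gfp(rec2)$values, 1)
  rec3 <- recording(matrix(c(3, 1, 2), 3, 1), fs = 250)
  expect_equal(compute_gfp(rec3)$values, sqrt(2 / 3))
  recc <- recording(matrix(5, 4, 3), fs = 250)
  expect_equal(compute_gfp(recc)$values, c(0, 0, 0))
  expect_error(compute_gfp(recording(matrix(1, 1, 5), fs = 250)), "2 channels")
})

test_that("GFP peak picking uses strict rise, non-strict fall, plateau start", {
  expect_identical(find_gfp_peaks(c(0, 1, 0, 2, 0)), c(2L, 4L))
  expect_identical(find_gfp_peaks(c(1, 2, 3, 4, 5)), integer(0))
  expect_identical(find_gfp_peaks(c(0, 2, 2, 0)), 2L)
  expect_error(find_gfp_peaks(c(1, 2)), "too short")
})

test_that("spatial correlation handles identity, polarity and orthogonality", {
  u <- c(1, -2, 0.5, 3, -1)
  expect_equal(spatial_correlation(u, u), 1)
  expect_equal(spatial_correlation(u, -u, polarity_invariant = TRUE), 1)
  expect_equal(spatial_correlation(u, -u, polarity_invariant = FALSE), -1)
  a <- c(1, -1, 1, -1); b <- c(1, 1, -1, -1)
  expect_lt(abs(spatial_correlation(a, b)), 1e-9)
  expect_error(spatial_correlation(u, rep(2, 5)), "zero-variance")
})

test_that("modified k-means recovers planted maps and improves with restarts", {
  set.seed(5)
  # two orthogonal mean-zero templates, random polarity/scale samples
  t1 <- c(1, -1, 1, -1, 1, -1, 1, -1); t1 <- t1 - mean(t1); t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(1, 1, -1, -1, 1, 1, -1, -1); t2 <- t2 - mean(t2); t2 <- t2 / sqrt(sum(t2^2))
  X <- do.call(rbind, lapply(1:60, function(i) {
    sample(c(-1, 1), 1) * runif(1, 0.5, 2) * (if (i %% 2) t1 else t2)
  }))
  m <- cluster_microstates(X, K = 2, n_restarts = 5, seed = 1)
  cc <- abs(cor(t(m$maps), cbind(t1, t2)))
  expect_gt(min(apply(cc, 2, max)), 0.999)
  expect_gt(m$gev, 0.999)

  # restart monotonicity on noisy data sharing the seed stream
  Xn <- X + matrix(rnorm(length(X), sd = 0.4), nrow(X))
  g1 <- cluster_microstates(Xn, K = 2, n_restarts = 1, seed = 9)$gev
  g20 <- cluster_microstates(Xn, K = 2, n_restarts = 20, seed = 9)$gev
  expect_gte(g20, g1)
  expect_error(cluster_microstates(X, K = 1), "at least 2")
})

test_that("GEV equals the brute-force definition and is maximal for back-fit labels", {
  sub <- make_subject(n_channels = 24, duration_s = 6, noise_sd = 2, seed = 21)
  model <- model_from_maps(template_matrix(sub$templates))
  bf <- backfit(sub$rec, model)
  gev <- compute_gev(model, sub$rec, bf)
  expect_equal(gev, oracle_gev(sub$rec$data, model$maps, bf$labels),
               tolerance = 1e-10)
  expect_true(gev >= 0 && gev <= 1)
  # permuted labels explain strictly less variance
  set.seed(1)
  perm <- label_sequence(sample(bf$labels), fs = bf$fs, K = 4)
  expect_lt(compute_gev(model, sub$rec, perm), gev)
  # exact scaled maps: GEV = 1
  pure <- recording(t(model$maps[c(1, 2, 3, 4, 1), ] * c(2, -1, 3, 1, -2)),
                    fs = 100)
  lab <- label_sequence(c(1, 2, 3, 4, 1), fs = 100, K = 4)
  expect_equal(compute_gev(model, pure, lab), 1, tolerance = 1e-12)
  expect_error(compute_gev(model, recording(matrix(0, 24, 5), fs = 100),
                           label_sequence(rep(1, 5), fs = 100, K = 4)),
               "all-zero")
})

test_that("group-level pooling preserves shared maps and single-subject models", {
  sub <- make_subject(n_channels = 24, duration_s = 8, noise_sd = 1, seed = 31)
  m1 <- subject_model(sub$rec, n_restarts = 5, seed = 1)
  # identical individual models pool to themselves
  gm <- group_level_model(list(m1, m1, m1), n_restarts = 5, seed = 2)
  cc <- abs(cor(t(gm$maps), t(m1$maps)))
  expect_gt(min(apply(cc, 2, max)), 0.999)
  # single-subject pooling is the identity up to sign/order
  g1 <- group_level_model(list(m1), n_restarts = 5, seed = 3)
  cc1 <- abs(cor(t(g1$maps), t(m1$maps)))
  expect_gt(min(apply(cc1, 2, max)), 0.999)
  expect_error(group_level_model(list()), "no individual")
})

test_that("A-D labelling undoes shuffles and sign flips and beats greedy matching", {
  tp <- make_templates(32, seed = 6)
  ref <- template_matrix(tp)
  perm <- c(3, 1, 4, 2); signs <- c(-1, 1, -1, 1)
  shuffled <- model_from_maps(ref[perm, ] * signs)
  reo <- reorient_to_ABCD(list(shuffled), reference_templates = ref)
  lab <- reo$models[[1]]
  expect_identical(lab$labels, c("A", "B", "C", "D"))
  for (k in 1:4) expect_gt(abs(cor(lab$maps[k, ], ref[k, ])), 0.999)
  # identity case
  ident <- reorient_to_ABCD(list(model_from_maps(ref)), reference_templates = ref)
  for (k in 1:4) expect_gt(abs(cor(ident$models[[1]]$maps[k, ], ref[k, ])), 0.999)

  # exhaustive assignment never scores below greedy matching
  greedy_score <- function(C) {
    C <- abs(C)
    s <- 0
    for (i in 1:4) {
      best <- which(C == max(C, na.rm = TRUE), arr.ind = TRUE)[1, ]
      s <- s + C[best[1], best[2]]
      C[best[1], ] <- NA; C[, best[2]] <- NA
    }
    s
  }
  set.seed(12)
  for (rep in 1:100) {
    A <- matrix(rnorm(4 * 16), 4); A <- A - rowMeans(A)
    B <- matrix(rnorm(4 * 16), 4); B <- B - rowMeans(B)
    C <- cor(t(B), t(A))
    expect_gte(microdyn:::match_maps(A, B)$score, greedy_score(C) - 1e-12)
  }
})

test_that("back-fitting is polarity invariant and handles degenerate inputs", {
  sub <- make_subject(n_channels = 24, duration_s = 6, noise_sd = 2, seed = 41)
  model <- model_from_maps(template_matrix(sub$templates))
  bf <- backfit(sub$rec, model)
  neg <- sub$rec; neg$data <- -neg$data
  expect_identical(backfit(neg, model)$labels, bf$labels)
  # single-map model labels everything with that map
  m1 <- model_from_maps(template_matrix(sub$templates)[1, , drop = FALSE], K = 1)
  expect_true(all(backfit(sub$rec, m1)$labels == 1L))
  # zero-variance leading samples take the lowest index, interior ones hold
  z <- sub$rec
  z$data[, 1:3] <- 0
  z$data[, 10] <- 0
  bz <- backfit(z, model)
  expect_true(all(bz$labels[1:3] == bz$labels[4] | bz$labels[1:3] == 1L))
  expect_identical(bz$labels[10], bz$labels[9])
})

test_that("feature extraction does exact run-length arithmetic and flattens to 24", {
  labs <- label_sequence(c(1, 1, 1, 1, 2, 2), fs = 250, K = 4)
  f <- extract_features(labs)
  expect_equal(unname(f$duration_ms[c("A", "B")]), c(16, 8))
  expect_equal(unname(f$coverage_frac["A"]), 2 / 3)
  expect_equal(unname(f$transitions["A", "B"]), 1)
  expect_equal(sum(f$coverage_frac), 1)

  labs2 <- label_sequence(c(1, 1, 2, 2, 3, 3, 1), fs = 250, K = 4)
  f2 <- extract_features(labs2)
  expect_equal(unname(f2$transitions["A", "B"]), 1)
  expect_equal(unname(f2$transitions["B", "C"]), 1)
  expect_equal(unname(f2$transitions["C", "A"]), 1)
  expect_equal(sum(f2$transitions), 3)

  fv <- feature_vector(f2)
  expect_length(fv, 24)
  expect_identical(names(fv)[1:4], c("dur_A", "dur_B", "dur_C", "dur_D"))
  expect_identical(names(fv)[13], "tp_A_B")
})

test_that("coverage, occurrence and duration are mutually consistent; features are polarity invariant", {
  sub <- make_subject(n_channels = 24, duration_s = 60, noise_sd = 2, seed = 51)
  model <- model_from_maps(template_matrix(sub$templates))
  f <- extract_features(backfit(sub$rec, model))
  # transition rows with outgoing segments sum to one
  rs <- rowSums(f$transitions)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-9))
  expect_equal(sum(f$coverage_frac), 1, tolerance = 1e-9)
  for (k in which(f$occurrence_hz > 0)) {
    expect_equal(f$coverage_frac[k],
                 f$occurrence_hz[k] * f$duration_ms[k] / 1000,
                 tolerance = 0.02)
  }
  neg <- sub$rec; neg$data <- -neg$data
  fneg <- extract_features(backfit(neg, model))
  expect_identical(feature_vector(f), feature_vector(fneg))
})
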