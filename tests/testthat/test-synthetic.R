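test_that("templates are mean-zero unit-norm, spatially distinct, deterministic", {
  tp <- make_templates(91, seed = 1)
  expect_length(tp, 4)
  expect_identical(vapply(tp, `[[`, character(1), "label"), c(A = "A", B = "B", C = "C", D = "D"))
  for (t in tp) {
    expect_lt(abs(mean(t$values)), 1e-9)
    expect_lt(abs(sum(t$values^2) - 1), 1e-9)
  }
  cors <- template_cor_matrix(tp)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.7)
  # polarity symmetry of the correlation measure
  expect_equal(spatial_correlation(tp$A$values, -tp$A$values), 1)
  # determinism
  tp2 <- make_templates(91, seed = 1)
  expect_identical(template_matrix(tp), template_matrix(tp2))
  expect_error(make_templates(4), "n_channels")
})

test_that("markov_spec validates stochasticity and positivity", {
  tm <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  expect_s3_class(markov_spec(c(80, 80), tm), "microdyn_markov")
  expect_error(markov_spec(c(80, -1), tm), "positive")
  expect_error(markov_spec(c(80, 80), tm * 0.9), "sum to 1")
  expect_error(markov_spec(c(80, 80), diag(2)), "diagonal")
})

test_that("simulated dwell times match the geometric mean and the chain is honored", {
  tm4 <- matrix(1 / 3, 4, 4); diag(tm4) <- 0
  # empirical mean dwell over many seeds vs the geometric-distribution mean
  dwells <- vapply(1:50, function(s) {
    labs <- simulate_label_sequence(markov_spec(rep(80, 4), tm4, seed = s),
                                    fs = 250, n_samples = 30000)
    mean(rle(labs$labels)$lengths) * 1000 / 250
  }, numeric(1))
  expect_lt(abs(mean(dwells) - 80), 5)

  # degenerate two-state chain alternates
  tm2 <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  labs <- simulate_label_sequence(markov_spec(c(40, 40), tm2, seed = 3),
                                  fs = 250, n_samples = 5000)
  r <- rle(labs$labels)
  expect_true(all(abs(diff(r$values)) == 1))

  # empirical transition frequencies approach the spec matrix
  spec_tm <- group_dynamics("ADHD-C")$transition_matrix
  emp <- matrix(0, 4, 4)
  for (s in 1:20) {
    ms <- group_dynamics("ADHD-C", seed = 100 + s)
    labs <- simulate_label_sequence(ms, fs = 250, n_samples = 30000)
    r <- rle(labs$labels)
    from <- r$values[-length(r$values)]; to <- r$values[-1]
    for (k in 1:4) emp[k, ] <- emp[k, ] + tabulate(to[from == k], 4)
  }
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(emp - spec_tm)), 0.05)
})

test_that("long-run state coverage matches the stationary distribution", {
  ms <- group_dynamics("ADHD-I")
  # stationary over segments, weighted by mean dwell, gives sample coverage
  ev <- eigen(t(ms$transition_matrix))
  pi_seg <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_seg <- pi_seg / sum(pi_seg)
  expected <- pi_seg * ms$mean_durations_ms
  expected <- expected / sum(expected)
  cov_emp <- rowMeans(vapply(1:10, function(s) {
    ms$seed <- 400 + s
    labs <- simulate_label_sequence(ms, fs = 250, n_samples = 40000)
    tabulate(labs$labels, 4) / 40000
  }, numeric(4)))
  expect_lt(max(abs(cov_emp - expected)), 0.03)
})

test_that("synthesized recordings are deterministic and identifiable without noise", {
  sub <- make_subject(n_channels = 32, duration_s = 8, noise_sd = 0, seed = 7)
  rec2 <- synthesize_recording(sub$labels, sub$templates, noise_sd = 0, seed = 8)
  expect_identical(sub$rec$data, rec2$data)
  # noiseless back-fit against the true templates reproduces the labels
  bf <- backfit(sub$rec, model_from_maps(template_matrix(sub$templates)))
  expect_identical(bf$labels, sub$labels$labels)
  expect_error(synthesize_recording(sub$labels, sub$templates,
                                    band_effects = list(list(channels = 99,
                                                             freq = 10,
                                                             amplitude = 1))),
               "out of range")
})

test_that("planted occipital gamma oscillation dominates gamma band power", {
  tp <- make_templates(91, seed = 4)
  labs <- simulate_label_sequence(group_dynamics("HC", seed = 8),
                                  fs = 250, n_samples = 250 * 20)
  occ <- 1:10
  rec <- synthesize_recording(labs, tp, noise_sd = 1, amplitude = 10,
                              band_effects = list(list(channels = occ,
                                                       freq = 40,
                                                       amplitude = 2)),
                              seed = 9)
  gp <- band_power(rec, c(30, 45))
  expect_gt(median(gp[occ]), 3 * median(gp[-occ]))
})

test_that("cohort defaults reproduce the study group sizes and margins", {
  spec <- cohort_spec(duration_s = 0.5)  # signal length only; counts are default
  cohort <- simulate_cohort(spec)
  expect_length(cohort$recordings, 161)
  expect_equal(sum(cohort$meta$group == "HC"), 54)
  expect_equal(sum(cohort$meta$subtype == "ADHD-C", na.rm = TRUE), 53)
  expect_equal(sum(cohort$meta$subtype == "ADHD-I", na.rm = TRUE), 54)
  expect_named(cohort$meta,
               c("subject_id", "group", "subtype", "sex", "age", "hand",
                 "inatt_score", "hyper_score", "total_score"))
  # determinism of the full cohort
  cohort2 <- simulate_cohort(cohort_spec(duration_s = 0.5))
  expect_identical(cohort$meta, cohort2$meta)
  expect_identical(cohort$recordings[[10]]$data, cohort2$recordings[[10]]$data)
})

test_that("null cohorts give calibrated two-sample tests; planted effects have the right sign", {
  # identical dynamics in both groups: type-I error near alpha
  tm4 <- matrix(1 / 3, 4, 4); diag(tm4) <- 0
  reject <- vapply(1:200, function(rep) {
    f <- vapply(1:12, function(i) {
      labs <- simulate_label_sequence(
        markov_spec(rep(80, 4), tm4, seed = rep * 37 + i),
        fs = 250, n_samples = 4000)
      extract_features(labs)$coverage_frac["C"]
    }, numeric(1))
    t.test(f[1:6], f[7:12], var.equal = TRUE)$p.value < 0.05
  }, logical(1))
  rate <- mean(reject)
  expect_gt(rate, 0.05 - 2.58 * sqrt(0.05 * 0.95 / 200))
  expect_lt(rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / 200))

  # planted lower state-C occurrence recovers with the planted sign
  sign_ok <- vapply(1:50, function(rep) {
    occ <- function(grp, base) vapply(1:6, function(i) {
      ms <- group_dynamics(grp, seed = base + i)
      labs <- simulate_label_sequence(ms, fs = 250, n_samples = 7500)
      extract_features(labs)$occurrence_hz["C"]
    }, numeric(1))
    mean(occ("HC", rep * 101)) > mean(occ("ADHD-I", rep * 101 + 50))
  }, logical(1))
  expect_gte(mean(sign_ok), 0.95)
})
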