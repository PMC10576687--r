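#' Canonical frequency-band definitions
#'
#' delta 1-4, theta 4-8, low alpha 8-10, high alpha 10-12, beta 12-30,
#' gamma 30-45 Hz.
#'
#' @return named list of `c(low, high)` pairs in Hz.
#' @export
default_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), low_alpha = c(8, 10),
       high_alpha = c(10, 12), beta = c(12, 30), gamma = c(30, 45))
}

#' Welch power spectral density per channel
#'
#' Hamming-tapered segments with 50% overlap, per-segment mean removal,
#' one-sided density in uV^2/Hz.
#'
#' @param rec a `microdyn_recording`.
#' @param window_s segment length in seconds (default 2, matching the
#'   preprocessing epoch length).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list with `freq` (Hz) and `psd` (channels x frequencies).
#' @export
welch_psd <- function(rec, window_s = 2, overlap = 0.5) {
  assert_recording(rec)
  fs <- rec$fs
  nwin <- round(window_s * fs)
  n <- n_samples(rec)
  if (n < nwin) stop("recording shorter than one Welch window")
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, n - nwin + 1L, by = step)
  w <- signal::hamming(nwin)
  scale <- fs * sum(w^2)
  nfreq <- nwin %/% 2 + 1
  acc <- matrix(0, n_channels(rec), nfreq)
  for (s0 in starts) {
    seg <- rec$data[, s0:(s0 + nwin - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- seg * rep(w, each = nrow(seg))
    X <- t(apply(seg, 1, stats::fft))
    P <- (Mod(X[, seq_len(nfreq), drop = FALSE])^2) / scale
    P[, 2:(nfreq - 1)] <- 2 * P[, 2:(nfreq - 1)]   # one-sided
    acc <- acc + P
  }
  list(freq = (seq_len(nfreq) - 1) * fs / nwin, psd = acc / length(starts))
}

#' Absolute band power per channel
#'
#' Sums PSD bin mass (density times bin width) over the FFT bins in
#' `[low, high)`. Riemann summation keeps a spectral line's full mass in
#' the band containing it and makes band powers Parseval-consistent;
#' trapezoid weighting would halve the mass of a line falling on an edge
#' bin.
#'
#' @param rec a `microdyn_recording`.
#' @param band `c(low, high)` in Hz, `high < fs/2`.
#' @param psd optional precomputed [welch_psd()] result (reused across
#'   bands).
#' @param window_s,overlap passed to [welch_psd()].
#' @return named numeric vector of band power (uV^2), one per channel.
#' @export
band_power <- function(rec, band, psd = NULL, window_s = 2, overlap = 0.5) {
  if (band[1] <= 0 || band[1] >= band[2]) stop("invalid band definition")
  if (band[2] >= rec$fs / 2) stop("band edge above Nyquist")
  if (is.null(psd)) psd <- welch_psd(rec, window_s = window_s, overlap = overlap)
  idx <- psd$freq >= band[1] & psd$freq < band[2]
  if (sum(idx) < 2) stop("band narrower than the frequency resolution")
  df <- psd$freq[2] - psd$freq[1]
  out <- rowSums(psd$psd[, idx, drop = FALSE]) * df
  stats::setNames(out, rec$channel_names)
}

#' Channel-wise theta/beta ratio
#'
#' @param theta,beta per-channel absolute power vectors.
#' @return per-channel ratio theta/beta.
#' @export
theta_beta_ratio <- function(theta, beta) {
  if (length(theta) != length(beta)) stop("theta/beta channel counts differ")
  bad <- which(beta <= 0)
  if (length(bad)) {
    nm <- if (!is.null(names(beta))) names(beta)[bad] else as.character(bad)
    stop("zero beta power in channel(s): ", paste(nm, collapse = ", "))
  }
  theta / beta
}

#' Subject-by-channel power matrices for all bands plus TBR
#'
#' @param recordings list of `microdyn_recording` sharing channels and fs.
#' @param subject_ids row names (default S001...).
#' @param bands named list of band edges (default [default_bands()]).
#' @param include_tbr append the theta/beta ratio matrix (default TRUE).
#' @param window_s,overlap Welch parameters.
#' @return named list of subjects x channels matrices (6 bands + `tbr`).
#' @export
build_power_matrices <- function(recordings, subject_ids = NULL,
                                 bands = default_bands(), include_tbr = TRUE,
                                 window_s = 2, overlap = 0.5) {
  n <- length(recordings)
  if (n == 0) stop("no recordings supplied")
  ch <- recordings[[1]]$channel_names
  fs <- recordings[[1]]$fs
  for (r in recordings) {
    if (!identical(r$channel_names, ch) || r$fs != fs) {
      stop("recordings differ in channels or sampling rate")
    }
  }
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(n))
  mats <- lapply(bands, function(b) matrix(NA_real_, n, length(ch),
                                           dimnames = list(subject_ids, ch)))
  for (i in seq_len(n)) {
    psd <- welch_psd(recordings[[i]], window_s = window_s, overlap = overlap)
    for (bn in names(bands)) {
      mats[[bn]][i, ] <- band_power(recordings[[i]], bands[[bn]], psd = psd)
    }
  }
  if (include_tbr) {
    tbr <- mats$theta
    for (i in seq_len(n)) tbr[i, ] <- theta_beta_ratio(mats$theta[i, ], mats$beta[i, ])
    mats$tbr <- tbr
  }
  mats
}

# Extended Infomax natural-gradient ICA on an M x n whitened matrix.
# Returns the M x M unmixing matrix. The sign of the kurtosis of each
# output switches the nonlinearity between super- and sub-Gaussian
# updates; signs are re-estimated in blocks so a near-Gaussian component
# cannot flap the update into a limit cycle. The learning rate anneals
# when the update direction swings by more than 60 degrees and the run
# stops when the realized (lrate-scaled) relative weight change falls
# below `tol` -- the classic runica schedule, plus a slow unconditional
# decay (0.9997/iteration) so flat directions spanned by near-Gaussian
# trailing components cannot sustain an endless drift.
.infomax <- function(Z, max_iter = 20000, tol = 1e-5, lrate = NULL,
                     sign_interval = 5L) {
  M <- nrow(Z)
  n <- ncol(Z)
  if (is.null(lrate)) lrate <- 0.01 / log(M + 2)
  W <- diag(M)
  k <- rep(1, M)
  old_dW <- NULL
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    U <- W %*% Z
    if (it == 1L || it %% sign_interval == 0L) {
      k <- sign(rowMeans(U^4) - 3 * rowMeans(U^2)^2)
      k[k == 0] <- 1
    }
    G <- diag(M) - (k * tanh(U)) %*% t(U) / n - U %*% t(U) / n
    dW <- G %*% W
    W_new <- W + lrate * dW
    if (!all(is.finite(W_new)) || max(abs(W_new)) > 1e8) {
      # blow-up: restart colder
      W <- diag(M)
      lrate <- lrate / 2
      old_dW <- NULL
      next
    }
    change <- sqrt(sum((lrate * dW)^2) / sum(W^2))
    if (!is.null(old_dW)) {
      ang <- sum(dW * old_dW) / sqrt(sum(dW^2) * sum(old_dW^2) + 1e-300)
      if (ang < cos(60 * pi / 180)) lrate <- lrate * 0.95
    }
    old_dW <- dW
    W <- W_new
    lrate <- lrate * 0.9997
    if (change < tol && it > sign_interval) {
      return(list(W = W, iterations = it, converged = TRUE))
    }
  }
  list(W = W, iterations = max_iter, converged = FALSE)
}

#' ICA decomposition of a power matrix
#'
#' Column-centers the subjects x channels matrix, PCA-whitens it to
#' `n_components`, and unmixes with extended Infomax (entropy
#' maximisation with a kurtosis-sign switch for sub-Gaussian sources).
#' `loadings %*% spatial_maps` reconstructs the rank-M approximation of
#' the centered matrix.
#'
#' @param pm subjects x channels power matrix.
#' @param n_components number of components M (<= min(subjects, channels)).
#' @param seed integer seed (random rotation of the whitened basis).
#' @param max_iter,tol Infomax convergence controls; non-convergence is
#'   an error reporting the iteration count.
#' @return a `microdyn_ica`: `loadings` (subjects x M), `spatial_maps`
#'   (M x channels), `zmaps` (M x channels, channel-standardized),
#'   `n_components`, `orientation` (per-component sign record), `seed`.
#' @export
ica_decompose <- function(pm, n_components, seed = 1, max_iter = 20000,
                          tol = 1e-5) {
  pm <- as.matrix(pm)
  N <- nrow(pm); C <- ncol(pm)
  if (n_components > min(N, C)) stop("n_components exceeds min(subjects, channels)")
  Xc <- sweep(pm, 2, colMeans(pm))
  sv <- svd(Xc, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  if (any(d < 1e-12 * d[1])) stop("power matrix is rank-deficient for this M")
  Z <- sqrt(C) * t(sv$v)                         # M x C, ~unit-variance rows
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  Q <- qr.Q(qr(matrix(stats::rnorm(n_components^2), n_components)))
  Z <- Q %*% Z                                   # seeded random rotation
  fit <- .infomax(Z, max_iter = max_iter, tol = tol)
  if (!fit$converged) {
    stop("Infomax did not converge within ", fit$iterations, " iterations")
  }
  S <- fit$W %*% Z                               # M x channels
  # loadings solve Xc = A S for the rank-M subspace
  A <- (sv$u %*% diag(d, n_components) %*% t(Q) %*% solve(fit$W)) / sqrt(C)
  # fix component scale: unit-variance maps, variance carried by loadings
  sds <- apply(S, 1, stats::sd)
  S <- S / sds
  A <- A * rep(sds, each = N)
  dimnames(S) <- list(sprintf("IC%d", seq_len(n_components)), colnames(pm))
  dimnames(A) <- list(rownames(pm), rownames(S))
  structure(list(loadings = A, spatial_maps = S,
                 zmaps = .zscore_maps(S),
                 n_components = n_components,
                 orientation = rep(1, n_components),
                 iterations = fit$iterations, seed = seed),
            class = "microdyn_ica")
}

.zscore_maps <- function(S) {
  t(apply(S, 1, function(x) (x - mean(x)) / stats::sd(x)))
}

#' ICA sweep over component counts
#'
#' @param pm subjects x channels power matrix.
#' @param components integer vector of M values (default 5:10).
#' @inheritParams ica_decompose
#' @return named list of `microdyn_ica`, one per M.
#' @export
ica_sweep <- function(pm, components = 5:10, seed = 1) {
  out <- lapply(components, function(m) ica_decompose(pm, m, seed = seed))
  names(out) <- sprintf("M%d", components)
  out
}

#' Orient components by group mean and standardize maps
#'
#' Flips each component's sign (loadings and spatial map jointly) so the
#' mean loading of the reference group is at least that of the other
#' group; recomputes the channel-standardized z-maps. Idempotent.
#'
#' @param result a `microdyn_ica`.
#' @param group_labels factor/character of length subjects with exactly
#'   two levels.
#' @param reference_group the group whose mean loading is oriented high
#'   (default the first level).
#' @return the reoriented `microdyn_ica`.
#' @export
orient_and_zscore <- function(result, group_labels, reference_group = NULL) {
  g <- as.factor(group_labels)
  if (nlevels(g) != 2) stop("exactly two groups are required for orientation")
  if (is.null(reference_group)) reference_group <- levels(g)[1]
  ref <- g == reference_group
  if (!any(ref) || all(ref)) stop("reference group is empty or covers everyone")
  for (m in seq_len(result$n_components)) {
    d <- mean(result$loadings[ref, m]) - mean(result$loadings[!ref, m])
    if (d < 0) {
      result$loadings[, m] <- -result$loadings[, m]
      result$spatial_maps[m, ] <- -result$spatial_maps[m, ]
      result$orientation[m] <- -result$orientation[m]
    }
  }
  result$zmaps <- .zscore_maps(result$spatial_maps)
  result
}

#' Group tests on component loadings with Bonferroni selection
#'
#' Two-sample t-test (pooled variance) per component on its loadings;
#' a component is significant if `p < alpha / M`. For significant
#' components the top contributing channels are those with `|Z| > 2` on
#' the standardized spatial map.
#'
#' @param result a `microdyn_ica`.
#' @param group_labels two-group factor over subjects.
#' @param alpha family-wise level before the Bonferroni division
#'   (default 0.05).
#' @param z_threshold channel-selection threshold on `|Z|` (default 2).
#' @return list with `tests` (data.frame: component, t, df, p,
#'   significant) and `selected_channels` (named list for significant
#'   components).
#' @export
test_components <- function(result, group_labels, alpha = 0.05,
                            z_threshold = 2) {
  g <- as.factor(group_labels)
  if (nlevels(g) != 2) stop("exactly two groups are required")
  if (any(table(g) < 2)) stop("need at least 2 subjects per group")
  M <- result$n_components
  rows <- lapply(seq_len(M), function(m) {
    x <- result$loadings[g == levels(g)[1], m]
    y <- result$loadings[g == levels(g)[2], m]
    if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
      stop("degenerate (zero-variance) loadings for component ", m)
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    data.frame(component = colnames(result$loadings)[m],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, significant = tt$p.value < alpha / M)
  })
  tests <- do.call(rbind, rows)
  sel <- list()
  for (m in which(tests$significant)) {
    z <- result$zmaps[m, ]
    sel[[tests$component[m]]] <- colnames(result$zmaps)[abs(z) > z_threshold]
  }
  list(tests = tests, selected_channels = sel, alpha = alpha,
       n_comparisons = M)
}
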