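#' Global field power
#'
#' GFP(t) is the spatial standard deviation of the average-referenced
#' scalp potential at each sample:
#' `sqrt(mean((V_i(t) - mean_i V_i(t))^2))` over electrodes `i`, with the
#' population divisor `n`.
#'
#' @param rec a `microdyn_recording` with at least 2 channels.
#' @return a `microdyn_gfp` object: `values` (uV, one per sample), `fs`.
#' @export
compute_gfp <- function(rec) {
  assert_recording(rec)
  if (n_channels(rec) < 2) stop("GFP needs at least 2 channels")
  centered <- sweep(rec$data, 2, colMeans(rec$data))
  structure(list(values = sqrt(colMeans(centered^2)), fs = rec$fs),
            class = "microdyn_gfp")
}

#' Local maxima of a GFP series
#'
#' A peak is an interior sample with a strict rise and a non-strict fall
#' (`gfp[t-1] < gfp[t] >= gfp[t+1]`), so a flat plateau contributes its
#' first sample. Endpoints are never peaks.
#'
#' @param gfp a `microdyn_gfp` (or numeric vector) of length >= 3.
#' @return integer sample indices (1-based).
#' @export
find_gfp_peaks <- function(gfp) {
  v <- if (inherits(gfp, "microdyn_gfp")) gfp$values else as.numeric(gfp)
  if (length(v) < 3) stop("series too short for peak picking")
  t <- 2:(length(v) - 1)
  t[v[t - 1] < v[t] & v[t] >= v[t + 1]]
}

#' Spatial correlation between two topographies
#'
#' Pearson correlation across channels; with `polarity_invariant = TRUE`
#' (the resting-state convention, since map polarity is arbitrary) the
#' absolute value is returned.
#'
#' @param u,v numeric vectors of equal length (one value per channel).
#' @param polarity_invariant return `|r|` instead of `r`.
#' @return a single correlation value.
#' @export
spatial_correlation <- function(u, v, polarity_invariant = TRUE) {
  if (length(u) != length(v)) stop("topographies have different channel counts")
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    stop("zero-variance topography has no defined spatial correlation")
  }
  r <- stats::cor(u, v)
  if (polarity_invariant) abs(r) else r
}

# Center rows (average reference) and scale to unit norm. Zero rows stay
# zero and are reported by the attribute "zero".
.center_norm_rows <- function(X) {
  X <- X - rowMeans(X)
  nrm <- sqrt(rowSums(X^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  out <- X / nrm
  attr(out, "zero") <- zero
  out
}

#' Modified (polarity-invariant) k-means over GFP-peak maps
#'
#' Samples are assigned to the map with maximal squared spatial
#' correlation; each centroid is updated as the dominant eigenvector of
#' its assigned maps' channel covariance, so a map and its negation are
#' equivalent. Iterates to an assignment fixpoint (or `max_iter`);
#' restarted `n_restarts` times from random map initialisations and the
#' solution with the highest GEV over the input maps is kept.
#'
#' @param peak_maps numeric matrix, samples x channels (topographies at
#'   GFP peaks).
#' @param K number of microstate classes (default 4).
#' @param n_restarts number of random restarts (default 100).
#' @param seed integer seed for the restarts.
#' @param max_iter iteration cap per restart.
#' @return a `microdyn_model`: `maps` (K x channels, mean-zero,
#'   unit-norm), `labels` (NULL until reoriented), `gev`, `K`,
#'   `n_restarts`, `seed`.
#' @export
cluster_microstates <- function(peak_maps, K = 4, n_restarts = 100, seed = 1,
                                max_iter = 100) {
  peak_maps <- as.matrix(peak_maps)
  if (K < 2) stop("K must be at least 2")
  U <- .center_norm_rows(peak_maps)
  keep <- !attr(U, "zero")
  U <- U[keep, , drop = FALSE]
  if (nrow(unique(round(U, 12))) < K) stop("fewer than K distinct peak maps")
  # GFP of each input map weights the GEV objective
  gfp2 <- rowMeans((peak_maps[keep, , drop = FALSE] -
                      rowMeans(peak_maps[keep, , drop = FALSE]))^2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    A <- U[sample.int(nrow(U), K), , drop = FALSE]
    assign_old <- rep(-1L, nrow(U))
    for (it in seq_len(max_iter)) {
      P <- (U %*% t(A))^2                 # squared spatial correlation
      assign_new <- max.col(P, ties.method = "first")
      if (all(assign_new == assign_old)) break
      assign_old <- assign_new
      for (k in seq_len(K)) {
        idx <- assign_new == k
        if (!any(idx)) {
          # dead cluster: reseed from the currently worst-fit map
          fit <- P[cbind(seq_len(nrow(U)), assign_new)]
          A[k, ] <- U[which.min(fit), ]
          next
        }
        S <- crossprod(U[idx, , drop = FALSE])
        v <- eigen(S, symmetric = TRUE)$vectors[, 1]
        v <- v - mean(v)
        A[k, ] <- v / sqrt(sum(v^2))
      }
    }
    fit <- (U %*% t(A))^2
    gev <- sum(gfp2 * fit[cbind(seq_len(nrow(U)), max.col(fit, ties.method = "first"))]) /
      sum(gfp2)
    if (is.null(best) || gev > best$gev) {
      best <- list(maps = A, gev = gev)
    }
  }
  maps <- best$maps
  rownames(maps) <- NULL
  structure(list(maps = maps, labels = NULL, gev = best$gev, K = K,
                 n_restarts = n_restarts, seed = seed),
            class = "microdyn_model")
}

#' @export
print.microdyn_model <- function(x, ...) {
  cat(sprintf("<microdyn_model> K=%d over %d channels, GEV=%.4f%s\n",
              x$K, ncol(x$maps), x$gev,
              if (is.null(x$labels)) "" else paste0(" [", paste(x$labels, collapse = ""), "]")))
  invisible(x)
}

#' Global explained variance of a labeled recording
#'
#' `GEV = sum_t GFP(t)^2 * r^2(V(t), map_{L(t)}) / sum_t GFP(t)^2`, with
#' `r` the polarity-invariant spatial correlation. Zero-GFP samples
#' contribute nothing to either sum.
#'
#' @param model a `microdyn_model`.
#' @param rec the recording the labels refer to.
#' @param labels a [label_sequence()] over the same samples.
#' @return a fraction in [0, 1].
#' @export
compute_gev <- function(model, rec, labels) {
  assert_recording(rec)
  if (length(labels$labels) != n_samples(rec)) stop("labels/recording length mismatch")
  V <- t(rec$data)                      # samples x channels
  Vc <- V - rowMeans(V)
  gfp2 <- rowMeans(Vc^2)
  if (all(gfp2 == 0)) stop("all-zero recording has no explained variance")
  nrm <- sqrt(rowSums(Vc^2))
  nz <- nrm > 0
  Un <- Vc[nz, , drop = FALSE] / nrm[nz]
  corr2 <- rowSums(Un * model$maps[labels$labels[nz], , drop = FALSE])^2
  sum(gfp2[nz] * corr2) / sum(gfp2)
}

#' Individual-level microstate model for one recording
#'
#' GFP, GFP-peak extraction and modified k-means in one call.
#'
#' @inheritParams cluster_microstates
#' @param rec a `microdyn_recording`.
#' @return a `microdyn_model`.
#' @export
subject_model <- function(rec, K = 4, n_restarts = 100, seed = 1) {
  gfp <- compute_gfp(rec)
  pk <- find_gfp_peaks(gfp)
  cluster_microstates(t(rec$data[, pk, drop = FALSE]), K = K,
                      n_restarts = n_restarts, seed = seed)
}

#' Group-level model from pooled individual maps
#'
#' Pools every subject's K individual maps and re-clusters them with the
#' same modified k-means; the individual maps are the "samples" of the
#' second clustering level.
#'
#' @param individual_models list of `microdyn_model` with equal channel
#'   counts.
#' @inheritParams cluster_microstates
#' @return a `microdyn_model`.
#' @export
group_level_model <- function(individual_models, K = 4, n_restarts = 100,
                              seed = 1) {
  if (length(individual_models) == 0) stop("no individual models supplied")
  nch <- vapply(individual_models, function(m) ncol(m$maps), integer(1))
  if (length(unique(nch)) != 1) stop("individual models differ in channel count")
  pooled <- do.call(rbind, lapply(individual_models, `[[`, "maps"))
  cluster_microstates(pooled, K = K, n_restarts = n_restarts, seed = seed)
}

# Exhaustive best permutation + signs matching `maps` rows to `ref` rows,
# maximizing the sum of absolute spatial correlations. K! is small (24).
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

match_maps <- function(maps, ref) {
  K <- nrow(ref)
  C <- stats::cor(t(ref), t(maps))      # K_ref x K_maps correlations
  perms <- .permutations(K)
  scores <- apply(perms, 1, function(p) sum(abs(C[cbind(seq_len(K), p)])))
  best <- perms[which.max(scores), ]
  signs <- sign(C[cbind(seq_len(K), best)])
  signs[signs == 0] <- 1
  list(order = best, signs = signs, score = max(scores))
}

#' Canonical A-D labelling of group models
#'
#' Aligns all group models, averages them into a group-mean model, labels
#' the mean maps A-D by the permutation (exhaustive over all 4! = 24)
#' maximizing the summed absolute spatial correlation with the four
#' reference templates, and then labels each group model against those
#' labeled group-mean maps the same way. Returned models have their maps
#' reordered to A, B, C, D and sign-aligned with the group mean.
#'
#' @param models list of `microdyn_model` with K = 4.
#' @param reference_templates 4 x channels matrix of reference maps, or a
#'   template list from [make_templates()]. Defaults to the package's
#'   canonical synthesized gradients for the matching channel count.
#' @return list with `models` (labeled, reordered), `mean_model`.
#' @export
reorient_to_ABCD <- function(models, reference_templates = NULL) {
  if (length(models) == 0) stop("no models supplied")
  K <- models[[1]]$K
  if (K != 4) stop("A-D labelling requires K = 4")
  nch <- ncol(models[[1]]$maps)
  if (is.null(reference_templates)) {
    reference_templates <- make_templates(nch, seed = 1, jitter_sd = 0)
  }
  ref <- if (is.list(reference_templates) && !is.matrix(reference_templates)) {
    template_matrix(reference_templates)
  } else as.matrix(reference_templates)
  if (ncol(ref) != nch || nrow(ref) != 4) {
    stop("reference templates must be 4 maps over ", nch, " channels")
  }
  # align every model to the first, then average into the group mean
  base <- models[[1]]$maps
  aligned <- lapply(models, function(m) {
    mm <- match_maps(m$maps, base)
    m$maps[mm$order, , drop = FALSE] * mm$signs
  })
  mean_maps <- Reduce(`+`, aligned) / length(aligned)
  mean_maps <- .center_norm_rows(mean_maps)
  attr(mean_maps, "zero") <- NULL
  mm <- match_maps(mean_maps, ref)
  mean_maps <- mean_maps[mm$order, , drop = FALSE] * mm$signs
  labels <- c("A", "B", "C", "D")
  relabel <- function(m) {
    a <- match_maps(m$maps, mean_maps)
    m$maps <- m$maps[a$order, , drop = FALSE] * a$signs
    m$labels <- labels
    m
  }
  mean_model <- structure(list(maps = mean_maps, labels = labels, gev = NA_real_,
                               K = 4, n_restarts = NA_integer_, seed = NA_integer_),
                          class = "microdyn_model")
  list(models = lapply(models, relabel), mean_model = mean_model)
}

#' Back-fit a model onto every sample of a recording
#'
#' Each sample is labeled with the map of maximal absolute spatial
#' correlation. Ties keep the previous sample's label; a zero-variance
#' sample inherits the previous label; leading unlabeled samples take the
#' lowest map index. No temporal smoothing is applied by default.
#'
#' @param rec a `microdyn_recording`.
#' @param model a `microdyn_model` with matching channel count.
#' @return a [label_sequence()].
#' @export
backfit <- function(rec, model) {
  assert_recording(rec)
  if (ncol(model$maps) != n_channels(rec)) stop("model/recording channel mismatch")
  V <- t(rec$data)
  Vc <- V - rowMeans(V)
  P <- abs(Vc %*% t(model$maps))        # |corr| up to the per-sample norm
  nrm <- sqrt(rowSums(Vc^2))
  lab <- max.col(P, ties.method = "first")
  top <- P[cbind(seq_along(lab), lab)]
  n_ties <- rowSums(P == top)           # >1 means an exact tie
  needs_fix <- nrm == 0 | n_ties > 1
  if (any(needs_fix)) {
    prev <- 1L
    for (t in seq_along(lab)) {
      if (needs_fix[t]) {
        if (nrm[t] == 0) lab[t] <- prev
        else if (t > 1 && P[t, prev] == top[t]) lab[t] <- prev
      }
      prev <- lab[t]
    }
  }
  label_sequence(lab, fs = rec$fs, K = model$K)
}

#' Microstate dynamics features from a label sequence
#'
#' Run-length encodes the sequence into segments and derives, per state:
#' mean duration (ms), occurrence (segments per second) and coverage
#' (fraction of samples); plus the K x K segment-transition probability
#' matrix (row-normalized over segments with a successor, zero diagonal).
#' Boundary (first/last, possibly truncated) segments are included in the
#' duration statistics. States that never occur get zeros.
#'
#' @param labels a [label_sequence()].
#' @return a `microdyn_features` object: `duration_ms`, `occurrence_hz`,
#'   `coverage_frac` (named per state), `transitions` (K x K), `K`, `fs`.
#' @export
extract_features <- function(labels) {
  if (!inherits(labels, "microdyn_labels")) stop("`labels` must be a label_sequence")
  K <- labels$K
  fs <- labels$fs
  n <- length(labels$labels)
  r <- rle(labels$labels)
  states <- LETTERS[seq_len(K)]
  duration <- occurrence <- coverage <- stats::setNames(numeric(K), states)
  for (k in seq_len(K)) {
    seg <- r$values == k
    if (any(seg)) {
      duration[k] <- mean(r$lengths[seg]) * 1000 / fs
      occurrence[k] <- sum(seg) / (n / fs)
      coverage[k] <- sum(r$lengths[seg]) / n
    }
  }
  trans <- matrix(0, K, K, dimnames = list(states, states))
  if (length(r$values) > 1) {
    from <- r$values[-length(r$values)]
    to <- r$values[-1]
    for (k in seq_len(K)) {
      idx <- from == k
      if (any(idx)) trans[k, ] <- tabulate(to[idx], nbins = K) / sum(idx)
    }
  }
  structure(list(duration_ms = duration, occurrence_hz = occurrence,
                 coverage_frac = coverage, transitions = trans,
                 K = K, fs = fs),
            class = "microdyn_features")
}

#' Flatten microstate features to the canonical named vector
#'
#' At K = 4 this is the 24-feature vector: `dur_A..dur_D`,
#' `occ_A..occ_D`, `cov_A..cov_D`, then the 12 off-diagonal transition
#' probabilities `tp_A_B, tp_A_C, ..., tp_D_C` (row-major).
#'
#' @param feats a `microdyn_features` object.
#' @return named numeric vector of length `3K + K(K-1)`.
#' @export
feature_vector <- function(feats) {
  K <- feats$K
  states <- LETTERS[seq_len(K)]
  tp <- c()
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i != j) {
      tp <- c(tp, stats::setNames(feats$transitions[i, j],
                                  sprintf("tp_%s_%s", states[i], states[j])))
    }
  }
  c(stats::setNames(feats$duration_ms, paste0("dur_", states)),
    stats::setNames(feats$occurrence_hz, paste0("occ_", states)),
    stats::setNames(feats$coverage_frac, paste0("cov_", states)),
    tp)
}

#' Per-subject microstate feature table
#'
#' Back-fits one model per subject (its group's labeled model) and
#' assembles the per-subject feature vectors into a data.frame keyed by
#' subject id.
#'
#' @param recordings list of `microdyn_recording`.
#' @param models either one `microdyn_model` used for everyone or a list
#'   parallel to `recordings`.
#' @param subject_ids character vector of ids (default S001...).
#' @return data.frame: `subject_id` plus one column per feature.
#' @export
microstate_feature_table <- function(recordings, models,
                                     subject_ids = NULL) {
  n <- length(recordings)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(n))
  one_model <- inherits(models, "microdyn_model")
  rows <- lapply(seq_len(n), function(i) {
    m <- if (one_model) models else models[[i]]
    fv <- feature_vector(extract_features(backfit(recordings[[i]], m)))
    as.data.frame(as.list(fv))
  })
  cbind(data.frame(subject_id = subject_ids, stringsAsFactors = FALSE),
        do.call(rbind, rows))
}
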