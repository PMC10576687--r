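#' Canonical four-state topography templates
#'
#' Builds four average-referenced, unit-norm scalp topographies on a
#' synthetic disc montage, following the canonical resting-state
#' microstate geometry: A and B are mirror-image diagonal gradients
#' (left-posterior to right-anterior, and right-posterior to
#' left-anterior), C is an anterior-posterior gradient, and D is a radial
#' fronto-central focus. A small seeded perturbation keeps the maps in
#' general position; the pairwise absolute spatial correlation is
#' required to stay below 0.7.
#'
#' @param n_channels number of electrodes (>= 8).
#' @param seed integer seed for the perturbation.
#' @param jitter_sd standard deviation of the perturbation before
#'   re-normalisation (relative to a unit-norm map spread over channels).
#' @return list of 4 templates; each has `values` (numeric vector,
#'   mean zero, unit norm), `label` (one of A-D) and the montage.
#' @export
make_templates <- function(n_channels, seed = 1, jitter_sd = 0.02) {
  if (n_channels < 8) {
    stop("`n_channels` must be >= 8 to resolve four distinct gradients")
  }
  montage <- disc_montage(n_channels)
  x <- montage$x
  y <- montage$y
  alpha <- 50 * pi / 180  # diagonal axes tilted 50 degrees off anterior
  raw <- list(
    A = sin(alpha) * x + cos(alpha) * y,
    B = -sin(alpha) * x + cos(alpha) * y,
    C = y,
    D = exp(-((x - 0)^2 + (y - 0.45)^2) / (2 * 0.30^2))
  )
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- lapply(names(raw), function(lab) {
    v <- raw[[lab]] + stats::rnorm(n_channels, sd = jitter_sd)
    v <- v - mean(v)
    v <- v / sqrt(sum(v^2))
    list(values = v, label = lab, montage = montage)
  })
  names(out) <- names(raw)
  cors <- template_cor_matrix(out)
  if (any(abs(cors[upper.tri(cors)]) >= 0.7)) {
    stop("montage too small: templates are not spatially distinct (|corr| >= 0.7)")
  }
  out
}

#' Pairwise spatial correlations between templates
#'
#' @param templates list of templates from [make_templates()].
#' @return K x K correlation matrix.
#' @export
template_cor_matrix <- function(templates) {
  m <- sapply(templates, `[[`, "values")
  stats::cor(m)
}

#' Stack templates into a K x channels map matrix
#'
#' @param templates list of templates from [make_templates()].
#' @return numeric matrix, one row per template.
#' @export
template_matrix <- function(templates) {
  t(sapply(templates, `[[`, "values"))  # K x channels
}

# Save/restore the global RNG state so seeded generators do not disturb
# the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Markov specification of microstate dynamics
#'
#' @param mean_durations_ms positive mean dwell time per state, in ms.
#' @param transition_matrix K x K row-stochastic matrix with zero
#'   diagonal: probability of the next segment's state given the current.
#' @param seed integer seed.
#' @return a `microdyn_markov` specification.
#' @export
markov_spec <- function(mean_durations_ms, transition_matrix, seed = 1) {
  K <- length(mean_durations_ms)
  transition_matrix <- as.matrix(transition_matrix)
  if (any(mean_durations_ms <= 0)) stop("mean durations must be positive")
  if (!all(dim(transition_matrix) == c(K, K))) {
    stop("`transition_matrix` must be K x K with K = length(mean_durations_ms)")
  }
  if (any(abs(diag(transition_matrix)) > 0)) {
    stop("`transition_matrix` diagonal must be exactly zero")
  }
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-9)) {
    stop("`transition_matrix` rows must be nonnegative and sum to 1")
  }
  structure(list(mean_durations_ms = mean_durations_ms,
                 transition_matrix = transition_matrix, seed = seed),
            class = "microdyn_markov")
}

#' Per-sample label sequence container
#'
#' @param labels integer vector of state indices in 1..K.
#' @param fs sampling rate in Hz.
#' @param K number of states (defaults to `max(labels)`).
#' @return a `microdyn_labels` object.
#' @export
label_sequence <- function(labels, fs, K = max(labels)) {
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > K)) stop("labels out of range 1..K")
  structure(list(labels = labels, fs = fs, K = as.integer(K)),
            class = "microdyn_labels")
}

#' Simulate a quasi-stable microstate label sequence
#'
#' Segment dwell times are geometric in samples (memoryless, support
#' >= 1 sample) with the specified per-state mean; successive segment
#' states follow the transition matrix; the first state is uniform.
#'
#' @param spec a [markov_spec()].
#' @param fs sampling rate in Hz.
#' @param n_samples length of the sequence to generate.
#' @return a [label_sequence()].
#' @export
simulate_label_sequence <- function(spec, fs, n_samples) {
  if (!inherits(spec, "microdyn_markov")) stop("`spec` must be a markov_spec")
  if (n_samples <= 0) stop("`n_samples` must be positive")
  K <- length(spec$mean_durations_ms)
  mean_samp <- spec$mean_durations_ms * fs / 1000
  if (any(mean_samp < 1)) stop("mean durations must be at least one sample")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  labels <- integer(0)
  state <- sample.int(K, 1L)
  while (length(labels) < n_samples) {
    dwell <- 1L + stats::rgeom(1L, prob = 1 / mean_samp[state])
    labels <- c(labels, rep.int(state, dwell))
    state <- sample.int(K, 1L, prob = spec$transition_matrix[state, ])
  }
  label_sequence(labels[seq_len(n_samples)], fs = fs, K = K)
}

#' Synthesize a multichannel recording from a label sequence
#'
#' Signal model: `V(t) = s_seg * a(t) * amplitude * T[L(t)] + band
#' oscillations + white sensor noise`, where `a(t)` is a rectified
#' alpha-rhythm envelope with a positive floor, rescaled to mean one, and
#' `s_seg` is a random per-segment polarity in {-1, +1} so that
#' downstream analysis must be polarity-invariant.
#'
#' @param labels a [label_sequence()].
#' @param templates list of topography templates from [make_templates()]
#'   (or any list with unit-norm `values`).
#' @param noise_sd white sensor-noise standard deviation per channel (uV).
#' @param band_effects list of oscillatory effects; each element is a
#'   list with `channels` (integer or logical index), `freq` (Hz) and
#'   `amplitude` (uV) of a coherent sinusoid added to those channels.
#' @param seed integer seed for polarity, phases and noise.
#' @param amplitude scale of the microstate source on the unit-norm map
#'   (uV; about `amplitude/sqrt(n_channels)` per channel RMS).
#' @param envelope_hz envelope rhythm frequency (Hz).
#' @param envelope_floor positive floor added to the rectified envelope so
#'   the source never vanishes; keeps every sample identifiable.
#' @return a `microdyn_recording` (original reference).
#' @export
synthesize_recording <- function(labels, templates, noise_sd = 2,
                                 band_effects = list(), seed = 1,
                                 amplitude = 100, envelope_hz = 10,
                                 envelope_floor = 0.3) {
  if (!inherits(labels, "microdyn_labels")) stop("`labels` must be a label_sequence")
  tm <- template_matrix(templates)  # K x channels
  if (labels$K > nrow(tm)) stop("more states in `labels` than templates")
  nch <- ncol(tm)
  n <- length(labels$labels)
  fs <- labels$fs
  tt <- (seq_len(n) - 1) / fs
  env <- (envelope_floor + abs(sin(2 * pi * envelope_hz * tt))) /
    (envelope_floor + 2 / pi)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  seg_id <- cumsum(c(1L, diff(labels$labels) != 0L))
  polarity <- sample(c(-1, 1), max(seg_id), replace = TRUE)[seg_id]
  # channels x samples microstate source
  V <- t(tm[labels$labels, , drop = FALSE]) *
    rep(amplitude * env * polarity, each = nch)
  for (eff in band_effects) {
    ch <- eff$channels
    if (is.logical(ch)) ch <- which(ch)
    if (length(ch) == 0) next
    if (any(ch < 1 | ch > nch)) stop("band effect channels out of range")
    phase <- stats::runif(1, 0, 2 * pi)
    wave <- eff$amplitude * sin(2 * pi * eff$freq * tt + phase)
    V[ch, ] <- V[ch, ] + rep(wave, each = length(ch))
  }
  if (noise_sd > 0) {
    V <- V + matrix(stats::rnorm(nch * n, sd = noise_sd), nch, n)
  }
  recording(V, fs = fs, history = "synthesize")
}

#' Default group-specific microstate dynamics
#'
#' Returns the planted [markov_spec()] for one of the cohort groups.
#' Relative to healthy controls (uniform transitions, 80 ms dwell
#' everywhere), the patient groups have fewer A-C transitions and state-C
#' visits, more B-D transitions, and a longer state-D dwell; the combined
#' subtype additionally shortens state A and routes more transitions into
#' state B than the inattentive subtype.
#'
#' @param group `"HC"`, `"ADHD-I"` or `"ADHD-C"`.
#' @param seed integer seed stored in the spec.
#' @return a [markov_spec()].
#' @export
group_dynamics <- function(group = c("HC", "ADHD-I", "ADHD-C"), seed = 1) {
  group <- match.arg(group)
  tm <- switch(group,
    "HC" = matrix(c(0, 1, 1, 1,
                    1, 0, 1, 1,
                    1, 1, 0, 1,
                    1, 1, 1, 0) / 3, 4, 4, byrow = TRUE),
    "ADHD-I" = matrix(c(0.00, 0.40, 0.18, 0.42,
                        0.28, 0.00, 0.24, 0.48,
                        0.18, 0.41, 0.00, 0.41,
                        0.26, 0.48, 0.26, 0.00), 4, 4, byrow = TRUE),
    "ADHD-C" = matrix(c(0.00, 0.48, 0.14, 0.38,
                        0.28, 0.00, 0.24, 0.48,
                        0.14, 0.48, 0.00, 0.38,
                        0.22, 0.54, 0.24, 0.00), 4, 4, byrow = TRUE)
  )
  dur <- switch(group,
    "HC" = c(80, 80, 80, 80),
    "ADHD-I" = c(80, 80, 70, 95),
    "ADHD-C" = c(65, 90, 70, 100)
  )
  names(dur) <- c("A", "B", "C", "D")
  markov_spec(dur, tm, seed = seed)
}

#' Default group-specific band-power effects
#'
#' All groups carry baseline fronto-central delta, fronto-temporal theta
#' and posterior-occipital gamma oscillations; patients get stronger
#' delta and theta (raising the theta/beta ratio fronto-temporally), and
#' the combined subtype gets stronger posterior-occipital gamma.
#'
#' @param montage montage data.frame from [disc_montage()].
#' @param group `"HC"`, `"ADHD-I"` or `"ADHD-C"`.
#' @return list of band-effect descriptors for [synthesize_recording()].
#' @export
group_band_effects <- function(montage, group = c("HC", "ADHD-I", "ADHD-C")) {
  group <- match.arg(group)
  fc <- region_mask(montage, "fronto-central")
  ft <- region_mask(montage, "fronto-temporal")
  po <- region_mask(montage, "posterior-occipital")
  delta_amp <- if (group == "HC") 3 else 6
  theta_amp <- if (group == "HC") 2 else 4
  gamma_amp <- if (group == "ADHD-C") 2.5 else 1
  list(
    list(channels = fc, freq = 2.5, amplitude = delta_amp, band = "delta"),
    list(channels = ft, freq = 6.0, amplitude = theta_amp, band = "theta"),
    list(channels = po, freq = 40.0, amplitude = gamma_amp, band = "gamma")
  )
}

#' Cohort specification for the synthetic generator
#'
#' Defaults reproduce the study conditions: 54 controls, 53 combined-type
#' and 54 inattentive-type patients; 91 channels at 250 Hz for 120 s.
#'
#' @param n_hc,n_adhd_c,n_adhd_i per-group subject counts.
#' @param n_channels,fs,duration_s recording geometry.
#' @param noise_sd sensor noise (uV per channel).
#' @param amplitude microstate source scale (uV on the unit-norm map).
#' @param seed integer master seed; all subject-level seeds derive from it.
#' @return a `microdyn_cohort_spec`.
#' @export
cohort_spec <- function(n_hc = 54, n_adhd_c = 53, n_adhd_i = 54,
                        n_channels = 91, fs = 250, duration_s = 120,
                        noise_sd = 2, amplitude = 100, seed = 1) {
  if (n_channels < 8) stop("`n_channels` must be >= 8")
  if (fs <= 90) stop("`fs` must exceed twice the 45 Hz band edge")
  structure(list(n_hc = n_hc, n_adhd_c = n_adhd_c, n_adhd_i = n_adhd_i,
                 n_channels = n_channels, fs = fs, duration_s = duration_s,
                 noise_sd = noise_sd, amplitude = amplitude, seed = seed),
            class = "microdyn_cohort_spec")
}

# Table-margin generators for the demographic metadata. Proportions and
# score distributions follow the study's cohort description.
.meta_margins <- list(
  "HC" = list(p_male = 40 / 54, p_left = 0.5 / 54, age = c(11.6, 1.81),
              inatt = c(15.14, 3.70), hyper = c(11.79, 2.48), total = c(26.93, 5.03)),
  "ADHD-C" = list(p_male = 42 / 51, p_left = 4 / 53, age = c(11.6, 1.57),
                  inatt = c(27.58, 3.12), hyper = c(24.60, 5.70), total = c(52.18, 7.02)),
  "ADHD-I" = list(p_male = 42 / 54, p_left = 4 / 54, age = c(11.6, 2.02),
                  inatt = c(27.16, 2.99), hyper = c(17.52, 5.10), total = c(44.69, 6.48))
)

#' Simulate a labeled synthetic EEG cohort
#'
#' Generates one recording per subject with group-dependent microstate
#' dynamics and band-power effects, plus a metadata table whose margins
#' (sex, age, handedness, rating-scale scores) match the emulated study
#' cohort. The planted ground truth (templates, per-group Markov specs
#' and band effects) is returned for recovery testing.
#'
#' @param spec a [cohort_spec()].
#' @return list with `recordings` (list of `microdyn_recording`), `meta`
#'   (data.frame: subject_id, group, subtype, sex, age, hand,
#'   inatt_score, hyper_score, total_score), and `truth`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "microdyn_cohort_spec")) stop("`spec` must be a cohort_spec")
  templates <- make_templates(spec$n_channels, seed = spec$seed)
  montage <- templates[[1]]$montage
  groups <- c(rep("HC", spec$n_hc), rep("ADHD-C", spec$n_adhd_c),
              rep("ADHD-I", spec$n_adhd_i))
  n <- length(groups)
  n_samples <- round(spec$duration_s * spec$fs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  subject_seeds <- sample.int(2^31 - 2, 2 * n)
  dyn <- lapply(c("HC", "ADHD-C", "ADHD-I"), group_dynamics)
  names(dyn) <- c("HC", "ADHD-C", "ADHD-I")
  eff <- lapply(c("HC", "ADHD-C", "ADHD-I"), group_band_effects, montage = montage)
  names(eff) <- names(dyn)
  recordings <- vector("list", n)
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    mspec <- dyn[[g]]
    mspec$seed <- subject_seeds[2 * i - 1]
    labs <- simulate_label_sequence(mspec, fs = spec$fs, n_samples = n_samples)
    recordings[[i]] <- synthesize_recording(
      labs, templates, noise_sd = spec$noise_sd, band_effects = eff[[g]],
      seed = subject_seeds[2 * i], amplitude = spec$amplitude
    )
    mg <- .meta_margins[[g]]
    meta[[i]] <- data.frame(
      subject_id = sprintf("S%03d", i),
      group = if (g == "HC") "HC" else "ADHD",
      subtype = if (g == "HC") NA_character_ else g,
      sex = if (stats::runif(1) < mg$p_male) "M" else "F",
      age = round(stats::rnorm(1, mg$age[1], mg$age[2]), 1),
      hand = if (stats::runif(1) < mg$p_left) "L" else "R",
      inatt_score = round(stats::rnorm(1, mg$inatt[1], mg$inatt[2]), 1),
      hyper_score = round(stats::rnorm(1, mg$hyper[1], mg$hyper[2]), 1),
      total_score = round(stats::rnorm(1, mg$total[1], mg$total[2]), 1),
      stringsAsFactors = FALSE
    )
  }
  list(recordings = recordings, meta = do.call(rbind, meta),
       truth = list(templates = templates, dynamics = dyn,
                    band_effects = eff, montage = montage, spec = spec))
}
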