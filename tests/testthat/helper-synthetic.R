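# Shared fixture builders. Everything is generated in code with fixed
# seeds; no data files.

# A microdyn_model wrapping known maps (e.g. the planted templates), for
# back-fitting against ground truth.
model_from_maps <- function(maps, K = nrow(maps)) {
  structure(list(maps = maps, labels = NULL, gev = NA_real_, K = K,
                 n_restarts = NA_integer_, seed = NA_integer_),
            class = "microdyn_model")
}

# Small synthetic subject: planted templates + Markov labels + recording.
make_subject <- function(n_channels = 91, fs = 250, duration_s = 10,
                         group = "HC", noise_sd = 2, seed = 1,
                         template_seed = 2, ...) {
  tp <- make_templates(n_channels, seed = template_seed)
  ms <- group_dynamics(group, seed = seed)
  labs <- simulate_label_sequence(ms, fs = fs,
                                  n_samples = round(duration_s * fs))
  rec <- synthesize_recording(labs, tp, noise_sd = noise_sd,
                              seed = seed + 1, ...)
  list(templates = tp, spec = ms, labels = labs, rec = rec,
       montage = tp[[1]]$montage)
}

# Pooled-variance two-sample t, coded independently from the package
# (textbook formula), used as the oracle for t-based tests.
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, df = n1 + n2 - 2, p = 2 * pt(-abs(tt), n1 + n2 - 2))
}

# Tie-corrected Kruskal-Wallis H from first principles (rank formula).
oracle_kruskal_h <- function(x, g) {
  g <- as.factor(g)
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Pearson chi-square for a 2x2 table from first principles.
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# GEV by direct per-sample evaluation of the defining sum (independent
# of the package's vectorized path).
oracle_gev <- function(data, maps, labels) {
  num <- 0; den <- 0
  for (t in seq_len(ncol(data))) {
    v <- data[, t]
    gfp2 <- mean((v - mean(v))^2)
    if (gfp2 == 0) next
    r <- cor(v, maps[labels[t], ])
    num <- num + gfp2 * r^2
    den <- den + gfp2
  }
  num / den
}
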