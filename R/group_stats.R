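#' Statistical test result container
#'
#' @param test test name.
#' @param statistic test statistic value.
#' @param df degrees of freedom (length 1 or 2).
#' @param p p value.
#' @param alpha family-wise level (default 0.05).
#' @param correction `"none"` or `"bonferroni"`.
#' @param n_comparisons number of comparisons the correction divides by.
#' @return a `microdyn_stat` object; `significant` is `p < alpha`
#'   (uncorrected) or `p < alpha / n_comparisons` (Bonferroni).
#' @export
stat_result <- function(test, statistic, df, p, alpha = 0.05,
                        correction = c("none", "bonferroni"),
                        n_comparisons = 1) {
  correction <- match.arg(correction)
  if (!is.finite(p) || p < 0 || p > 1) stop("p value outside [0, 1]")
  threshold <- if (correction == "bonferroni") alpha / n_comparisons else alpha
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), p = unname(p), alpha = alpha,
                 correction = correction, n_comparisons = n_comparisons,
                 significant = p < threshold),
            class = "microdyn_stat")
}

#' @export
print.microdyn_stat <- function(x, ...) {
  cat(sprintf("<%s> statistic=%.4g, df=%s, p=%.3g%s%s\n", x$test, x$statistic,
              paste(signif(x$df, 6), collapse = ","), x$p,
              if (x$correction == "bonferroni")
                sprintf(" (Bonferroni /%d)", x$n_comparisons) else "",
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Two-way ANOVA group-by-state interaction
#'
#' Fixed-effects two-way ANOVA on the long format (one observation per
#' subject and state) with group and state as factors; returns the
#' group-by-state interaction F test. Note that state is a within-subject
#' factor in the underlying design; the fixed-effects layout treats the
#' observations as independent.
#'
#' @param features subjects x levels matrix for one feature family
#'   (4 columns for duration/occurrence/coverage, 12 for transitions).
#' @param group_labels two-group factor over subjects.
#' @param alpha significance level.
#' @return a [stat_result()] for the interaction.
#' @export
anova_interaction <- function(features, group_labels, alpha = 0.05) {
  features <- as.matrix(features)
  g <- as.factor(group_labels)
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) == 0)) stop("empty group cell")
  long <- data.frame(
    value = as.vector(features),
    state = factor(rep(colnames(features) %||% seq_len(ncol(features)),
                       each = nrow(features))),
    group = rep(g, ncol(features))
  )
  if (stats::var(long$value) <= 1e-18 * (mean(long$value)^2 + 1)) {
    stop("interaction F undefined (zero residual variance)")
  }
  fit <- stats::aov(value ~ group * state, data = long)
  tab <- summary(fit)[[1]]
  row <- grep("group:state", rownames(tab))
  Fv <- tab[row, "F value"]
  if (!is.finite(Fv)) stop("interaction F undefined (zero residual variance)")
  stat_result("two-way ANOVA interaction", Fv,
              c(tab[row, "Df"], tab[nrow(tab), "Df"]),
              tab[row, "Pr(>F)"], alpha = alpha)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bonferroni-corrected post-hoc two-sample t tests per feature
#'
#' Pooled-variance (Student) two-sample t test for every feature column,
#' flagged significant at `alpha / n_comparisons`.
#'
#' @param feature_table data.frame or matrix of features (e.g. the 24
#'   microstate features); a `subject_id` column is ignored.
#' @param group_labels two-group factor over subjects.
#' @param alpha family-wise level (default 0.05).
#' @param n_comparisons Bonferroni divisor (default: number of features).
#' @return data.frame: feature, t, df, p, significant.
#' @export
posthoc_t_tests <- function(feature_table, group_labels, alpha = 0.05,
                            n_comparisons = NULL) {
  ft <- as.data.frame(feature_table)
  ft$subject_id <- NULL
  g <- as.factor(group_labels)
  if (nlevels(g) != 2) stop("exactly two groups are required")
  if (any(table(g) < 2)) stop("need at least 2 subjects per group")
  if (is.null(n_comparisons)) n_comparisons <- ncol(ft)
  rows <- lapply(names(ft), function(f) {
    x <- ft[[f]][g == levels(g)[1]]
    y <- ft[[f]][g == levels(g)[2]]
    if (stats::var(x) + stats::var(y) == 0) {
      stop("zero pooled variance for feature ", f)
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    data.frame(feature = f, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               significant = tt$p.value < alpha / n_comparisons,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "n_comparisons") <- n_comparisons
  out
}

#' Pearson chi-square on a 2x2 table, no continuity correction
#'
#' The no-correction convention is fixed by the demographic worked
#' examples it reproduces.
#'
#' @param table 2x2 matrix of nonnegative integer counts with all
#'   marginals positive.
#' @param alpha significance level.
#' @return a [stat_result()] with df = 1.
#' @export
chi_square_2x2 <- function(table, alpha = 0.05) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("a 2x2 count table is required")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal in the 2x2 table")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  stat_result("Pearson chi-square", ct$statistic, ct$parameter, ct$p.value,
              alpha = alpha)
}

#' Pooled-variance two-sample t test (raw data or summaries)
#'
#' Student t with `df = n1 + n2 - 2`. Supply either raw vectors `x` and
#' `y`, or group summaries (`mean1, sd1, n1, mean2, sd2, n2`).
#'
#' @param x,y raw data vectors (optional).
#' @param mean1,sd1,n1,mean2,sd2,n2 group summary statistics (optional).
#' @param alpha significance level.
#' @return a [stat_result()].
#' @export
two_sample_t <- function(x = NULL, y = NULL, mean1 = NULL, sd1 = NULL,
                         n1 = NULL, mean2 = NULL, sd2 = NULL, n2 = NULL,
                         alpha = 0.05) {
  if (!is.null(x) && !is.null(y)) {
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (is.null(mean1) || is.null(sd1) || is.null(n1) ||
      is.null(mean2) || is.null(sd2) || is.null(n2)) {
    stop("supply raw vectors x,y or full group summaries")
  }
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if (sd1 == 0 && sd2 == 0) stop("zero variance in both groups")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  t <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  stat_result("two-sample t (pooled)", t, df,
              2 * stats::pt(-abs(t), df), alpha = alpha)
}

#' Per-subject topography similarity to the grand-mean maps
#'
#' For each subject and state, the absolute spatial correlation between
#' the subject's individual map (optimally permuted/signed against the
#' grand-mean model) and the grand-mean map of that state. This is the
#' scalar ranked by the topography comparison.
#'
#' @param individual_models list of `microdyn_model` (one per subject).
#' @param mean_model the labeled grand-mean `microdyn_model`.
#' @return subjects x K matrix of similarities in [0, 1], columns named
#'   by state.
#' @export
topography_similarity <- function(individual_models, mean_model) {
  K <- mean_model$K
  sim <- t(vapply(individual_models, function(m) {
    mm <- match_maps(m$maps, mean_model$maps)
    aligned <- m$maps[mm$order, , drop = FALSE] * mm$signs
    vapply(seq_len(K), function(k) {
      abs(stats::cor(aligned[k, ], mean_model$maps[k, ]))
    }, numeric(1))
  }, numeric(K)))
  colnames(sim) <- mean_model$labels %||% LETTERS[seq_len(K)]
  sim
}

#' Kruskal-Wallis topography comparison per state
#'
#' Tie-corrected Kruskal-Wallis H across groups, one test per state, on
#' the per-subject topography-similarity scalars.
#'
#' @param similarities subjects x K matrix from [topography_similarity()].
#' @param group_labels factor over subjects.
#' @param alpha significance level.
#' @return named list of [stat_result()], one per state.
#' @export
kruskal_wallis_topography <- function(similarities, group_labels,
                                      alpha = 0.05) {
  similarities <- as.matrix(similarities)
  g <- as.factor(group_labels)
  out <- lapply(seq_len(ncol(similarities)), function(k) {
    x <- similarities[, k]
    if (length(unique(x)) == 1) stop("all-tied similarities for state ", k)
    kt <- stats::kruskal.test(x, g)
    stat_result("Kruskal-Wallis", kt$statistic, kt$parameter, kt$p.value,
                alpha = alpha)
  })
  names(out) <- colnames(similarities) %||% LETTERS[seq_len(ncol(similarities))]
  out
}
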