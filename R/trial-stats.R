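#' Geometric mean and geometric coefficient of variation
#'
#' @param values Positive numeric vector.
#' @return List with `gm` (geometric mean) and `cv_percent`
#'   (`100 * sqrt(exp(var(log x)) - 1)`).
#' @export
geometric_mean_cv <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values) || any(values <= 0)) {
    stop("geometric_mean_cv requires positive values")
  }
  lv <- log(values)
  list(gm = exp(mean(lv)),
       cv_percent = 100 * sqrt(exp(var(lv)) - 1))
}

#' Paired log-scale comparison of two crossover arms at one time
#'
#' Within-participant paired t test of log concentration at a single
#' nominal sampling time, reported as a geometric mean ratio (GMR) with a
#' one-sided lower confidence bound.  Pairs in which either member is
#' below the limit of quantification (or missing) are excluded.
#'
#' @param data Validated trial table ([read_trial_table()]).
#' @param arm_a,arm_b Arm labels; the ratio is arm_a / arm_b.
#' @param time Nominal time (min), one of [protocol_times()].
#' @param conf One-sided confidence level for the lower bound (default
#'   0.978, matching a 0.022 nominal significance level).
#'
#' @return List with `gmr`, `lower_bound`, `p_one_sided`, `n_pairs`,
#'   `df`, `gm_a`, `gm_b`.
#' @export
paired_log_comparison <- function(data, arm_a, arm_b, time, conf = 0.978) {
  pick <- function(arm) {
    sub <- data[data$arm == arm & data$nominal_time == time &
                  !data$blq & is.finite(data$concentration) &
                  data$concentration > 0, ]
    setNames(sub$concentration, sub$participant)
  }
  xa <- pick(arm_a); xb <- pick(arm_b)
  ids <- intersect(names(xa), names(xb))
  if (length(ids) < 3) {
    stop("fewer than 3 complete pairs for ", arm_a, " vs ", arm_b,
         " at t = ", time)
  }
  d <- log(xa[ids]) - log(xb[ids])
  n <- length(d)
  se <- sd(d) / sqrt(n)
  # zero-variance differences: the t statistic degenerates
  tstat <- if (se == 0) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else mean(d) / se
  df <- n - 1
  list(gmr = exp(mean(d)),
       lower_bound = exp(mean(d) - qt(conf, df) * se),
       p_one_sided = pt(tstat, df, lower.tail = FALSE),
       n_pairs = n, df = df,
       gm_a = exp(mean(log(xa[ids]))), gm_b = exp(mean(log(xb[ids]))))
}

#' Pocock nominal significance level for K equally spaced looks
#'
#' Constant per-look significance level such that the familywise error of
#' a group-sequential test with K equal information increments equals
#' `alpha`.  The joint distribution of the K standardized statistics is
#' multivariate normal with correlation `sqrt(i/j)` (i <= j); the
#' boundary is found by numerically integrating that distribution
#' (deterministic Miwa algorithm) and solving for the critical value.
#'
#' The default `sided = 2` reproduces the standard published Pocock
#' boundaries (K = 3, alpha = 0.05 gives 0.022); `sided = 1` solves the
#' one-sided crossing problem instead.
#'
#' @param K Number of looks (>= 1).
#' @param alpha Overall familywise level in (0, 1).
#' @param sided 1 or 2.
#' @return The nominal per-look significance level.
#' @export
pocock_nominal_level <- function(K, alpha = 0.05, sided = 2) {
  stopifnot(K >= 1, K == round(K), alpha > 0, alpha < 1, sided %in% 1:2)
  if (K == 1) return(alpha)
  key <- sprintf("%d_%.10g_%d", K, alpha, sided)
  hit <- .pocock_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- seq_len(K)
  corr <- outer(idx, idx, function(i, j) sqrt(pmin(i, j) / pmax(i, j)))
  joint <- function(cv) {
    lower <- if (sided == 2) rep(-cv, K) else rep(-Inf, K)
    as.numeric(mvtnorm::pmvnorm(lower = lower, upper = rep(cv, K),
                                corr = corr,
                                algorithm = mvtnorm::Miwa(steps = 4097)))
  }
  f <- function(cv) (1 - joint(cv)) - alpha
  cv <- uniroot(f, interval = c(0.5, 6), tol = 1e-9)$root
  out <- if (sided == 2) 2 * pnorm(-cv) else pnorm(-cv)
  assign(key, out, envir = .pocock_cache)
  out
}

# memoised boundary computations (deterministic, so caching is safe)
.pocock_cache <- new.env(parent = emptyenv())

#' Sequential paired comparison at prespecified times
#'
#' Evaluates [paired_log_comparison()] at each prespecified time in
#' order, stopping at the first look whose one-sided p-value falls below
#' the nominal level (Pocock-adjusted by default).  All evaluated looks
#' are retained.
#'
#' @param data Validated trial table.
#' @param arm_a,arm_b Arm labels (ratio arm_a / arm_b).
#' @param times Ordered prespecified nominal times (min).
#' @param nominal Per-look one-sided significance level; default
#'   `pocock_nominal_level(length(times), alpha)`.
#' @param alpha Overall familywise level used when `nominal` is `NULL`.
#'
#' @return Object of class `"sequential_comparison"`: list with `looks`
#'   (data frame: time, gmr, lower_bound, p_one_sided, n_pairs,
#'   significant), `earliest_significant_time` (or `NA`), `nominal`,
#'   `comparison`.
#' @export
sequential_test <- function(data, arm_a, arm_b, times, nominal = NULL,
                            alpha = 0.05) {
  stopifnot(length(times) >= 1, !is.unsorted(times))
  if (is.null(nominal)) nominal <- pocock_nominal_level(length(times), alpha)
  looks <- list()
  earliest <- NA_real_
  for (tm in times) {
    cmp <- paired_log_comparison(data, arm_a, arm_b, tm, conf = 1 - nominal)
    sig <- cmp$p_one_sided < nominal
    looks[[length(looks) + 1L]] <- data.frame(
      time = tm, gmr = cmp$gmr, lower_bound = cmp$lower_bound,
      p_one_sided = cmp$p_one_sided, n_pairs = cmp$n_pairs,
      significant = sig)
    if (sig) { earliest <- tm; break }
  }
  structure(list(looks = do.call(rbind, looks),
                 earliest_significant_time = earliest,
                 nominal = nominal,
                 comparison = paste(arm_a, "vs", arm_b)),
            class = "sequential_comparison")
}

#' @export
print.sequential_comparison <- function(x, ...) {
  cat("Sequential paired comparison:", x$comparison, "\n")
  cat(sprintf("  nominal one-sided level per look: %.4f\n", x$nominal))
  print(format(x$looks, digits = 4), row.names = FALSE)
  if (is.na(x$earliest_significant_time)) {
    cat("  no look reached significance\n")
  } else {
    cat(sprintf("  earliest significant time: %.3g min\n",
                x$earliest_significant_time))
  }
  invisible(x)
}

#' Dose-proportionality assessment between two arms
#'
#' Paired log-scale geometric mean ratio of a dose-normalized NCA
#' exposure parameter (AUC or Cmax), with a two-sided confidence
#' interval.  A ratio of 1 indicates dose-proportional exposure.
#'
#' @param nca_table Output of [nca_by_participant()].
#' @param arm_x,arm_ref Arm labels; ratio is (x / dose_x) / (ref / dose_ref).
#' @param dose_x,dose_ref Total administered dose (mg) in each arm.
#' @param parameter `"auc"` (AUC_inf, falling back to AUC_last where not
#'   estimable) or `"cmax"`.
#' @param conf Two-sided confidence level (default 0.90).
#'
#' @return List with `gmr_dose_normalized`, `ci_lower`, `ci_upper`,
#'   `conf`, `n_pairs`, `n_excluded`.
#' @export
dose_proportionality <- function(nca_table, arm_x, arm_ref, dose_x, dose_ref,
                                 parameter = c("auc", "cmax"), conf = 0.90) {
  parameter <- match.arg(parameter)
  val <- function(arm) {
    sub <- nca_table[nca_table$arm == arm, ]
    v <- if (parameter == "cmax") sub$cmax else
      ifelse(is.finite(sub$auc_inf), sub$auc_inf, sub$auc_last)
    setNames(v, sub$participant)
  }
  vx <- val(arm_x) / dose_x
  vr <- val(arm_ref) / dose_ref
  ids <- intersect(names(vx)[is.finite(vx) & vx > 0],
                   names(vr)[is.finite(vr) & vr > 0])
  n_excluded <- max(length(vx), length(vr)) - length(ids)
  if (length(ids) < 3) stop("fewer than 3 complete dose-normalized pairs")
  d <- log(vx[ids]) - log(vr[ids])
  n <- length(d)
  se <- sd(d) / sqrt(n)
  half <- qt(1 - (1 - conf) / 2, n - 1) * se
  list(gmr_dose_normalized = exp(mean(d)),
       ci_lower = exp(mean(d) - half), ci_upper = exp(mean(d) + half),
       conf = conf, n_pairs = n, n_excluded = n_excluded)
}
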