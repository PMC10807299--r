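#' Noncompartmental analysis of a single concentration-time profile
#'
#' Computes the standard model-free exposure summaries for one
#' participant-period profile: `Cmax`, `Tmax`, `AUC_last`, the terminal
#' log-linear slope `lambda_z`, and the extrapolated `AUC_inf`.
#'
#' AUC uses the lin-up/log-down rule by default: linear trapezoids while
#' concentration rises, logarithmic trapezoids while it falls (both
#' endpoints positive); `method = "linear"` selects plain trapezoids
#' throughout.  `lambda_z` is fitted by log-linear regression on the
#' terminal points, starting from the last 3 quantifiable points after
#' `Tmax` and extending earlier while the adjusted R-squared improves.
#' `AUC_inf = AUC_last + C_last / lambda_z`; when no negative terminal
#' slope is estimable, `lambda_z` and `AUC_inf` are `NA` and flagged.
#'
#' Below-quantification samples are excluded, except a predose (t = 0)
#' BLQ which contributes a zero concentration to the AUC only.
#'
#' @param time Sampling times (min).
#' @param conc Concentrations (ng/mL), same length.
#' @param blq Logical below-limit-of-quantification flags (default all
#'   `FALSE`).
#' @param method `"lin-up-log-down"` (default) or `"linear"`.
#'
#' @return An object of class `"nca_result"`: a list with `cmax`, `tmax`,
#'   `auc_last`, `auc_inf`, `lambda_z`, `n_points_lambda_z`,
#'   `lambda_z_estimable`, `n_quantifiable`.
#' @export
nca <- function(time, conc, blq = NULL, method = c("lin-up-log-down", "linear")) {
  method <- match.arg(method)
  if (length(time) != length(conc)) stop("time and conc lengths differ")
  if (is.null(blq)) blq <- rep(FALSE, length(conc))
  ord <- order(time)
  time <- time[ord]; conc <- conc[ord]; blq <- blq[ord]

  quant <- !blq & is.finite(conc)
  if (!any(quant)) stop("all-BLQ profile: no quantifiable concentrations")
  # predose BLQ enters the AUC as zero; other BLQ samples are dropped
  use <- quant | (blq & time == 0)
  t_u <- time[use]
  c_u <- ifelse(quant[use], conc[use], 0)
  post <- quant & time > 0
  if (sum(post) < 3) stop("fewer than 3 quantifiable post-dose points")

  cmax <- max(conc[quant])
  tmax <- time[quant][which.max(conc[quant])]
  auc_last <- auc_trapezoid(t_u, c_u, method = method)

  lz <- lambda_z_fit(time[quant], conc[quant], tmax)
  c_last <- c_u[length(c_u)]
  auc_inf <- if (lz$estimable) auc_last + c_last / lz$lambda_z else NA_real_

  structure(list(cmax = cmax, tmax = tmax, auc_last = auc_last,
                 auc_inf = auc_inf, lambda_z = lz$lambda_z,
                 n_points_lambda_z = lz$n_points,
                 lambda_z_estimable = lz$estimable,
                 n_quantifiable = sum(quant)),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat("Noncompartmental analysis\n")
  cat(sprintf("  Cmax     %8.3g ng/mL at Tmax %.3g min\n", x$cmax, x$tmax))
  cat(sprintf("  AUC_last %8.4g ng*min/mL\n", x$auc_last))
  if (x$lambda_z_estimable) {
    cat(sprintf("  AUC_inf  %8.4g ng*min/mL  (lambda_z %.4g /min, %d points)\n",
                x$auc_inf, x$lambda_z, x$n_points_lambda_z))
  } else {
    cat("  AUC_inf  not estimable (no negative terminal slope)\n")
  }
  invisible(x)
}

# Trapezoidal AUC; log trapezoid on strictly decreasing positive segments
# when method = "lin-up-log-down".
auc_trapezoid <- function(time, conc, method = "lin-up-log-down") {
  if (length(time) < 2) return(0)
  dt <- diff(time)
  c1 <- conc[-length(conc)]
  c2 <- conc[-1]
  seg <- (c1 + c2) / 2 * dt
  if (method == "lin-up-log-down") {
    logdown <- c2 < c1 & c2 > 0 & c1 > 0
    seg[logdown] <- (c1[logdown] - c2[logdown]) /
      log(c1[logdown] / c2[logdown]) * dt[logdown]
  }
  sum(seg)
}

# Terminal slope: last k points strictly after Tmax, k from 3 upward,
# keeping the fit with the best adjusted R^2 among negative slopes.
lambda_z_fit <- function(time, conc, tmax) {
  cand <- which(time > tmax & conc > 0)
  out <- list(lambda_z = NA_real_, n_points = 0L, estimable = FALSE)
  if (length(cand) < 3) return(out)
  best_r2 <- -Inf
  for (k in 3:length(cand)) {
    idx <- tail(cand, k)
    fit <- lm(log(conc[idx]) ~ time[idx])
    slope <- coef(fit)[[2]]
    r2 <- suppressWarnings(summary(fit)$adj.r.squared)
    if (!is.finite(r2)) next
    if (slope < -1e-10 && r2 > best_r2 + 1e-12) {
      best_r2 <- r2
      out <- list(lambda_z = -slope, n_points = length(idx), estimable = TRUE)
    }
  }
  out
}

#' Per-participant NCA over a trial table
#'
#' Applies [nca()] to every participant-arm profile of a validated trial
#' table and returns one row per profile.
#'
#' @param data Trial table (see [read_trial_table()]).
#' @param method AUC method passed to [nca()].
#' @return Data frame with columns `participant`, `arm`, `period`,
#'   `cmax`, `tmax`, `auc_last`, `auc_inf`, `lambda_z`.
#' @export
nca_by_participant <- function(data, method = "lin-up-log-down") {
  keys <- unique(data[c("participant", "arm", "period")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- data[data$participant == keys$participant[i] &
                  data$arm == keys$arm[i] & data$period == keys$period[i], ]
    res <- tryCatch(nca(sub$nominal_time, sub$concentration, sub$blq,
                        method = method),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(participant = keys$participant[i], arm = keys$arm[i],
               period = keys$period[i], cmax = res$cmax, tmax = res$tmax,
               auc_last = res$auc_last, auc_inf = res$auc_inf,
               lambda_z = res$lambda_z)
  })
  do.call(rbind, rows)
}
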