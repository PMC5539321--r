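#' One-step growth-curve analysis
#'
#' Burst size is the ratio of the mean titer after the exponential
#' (rise) phase to the mean titer before the infected cells start
#' releasing virions; the latent period is read off as the time at
#' which the rise crosses the midpoint between the two log-scale
#' plateaus ("median of the exponential curve"). Segmentation into
#' pre-plateau / rise / post-plateau is exhaustive over changepoint
#' pairs, minimizing the summed within-segment squared error of the
#' log-titer (plateaus about their means, rise about an OLS line).
#'
#' @name growth_kinetics
NULL

#' Construct a growth curve
#'
#' @param time_min strictly increasing sampling times (minutes).
#' @param pfu_ml positive titers (PFU/ml).
#' @param phage_id optional label.
#' @return object of class `growth_curve`.
#' @export
growth_curve <- function(time_min, pfu_ml, phage_id = NA_character_) {
  pv_assert(length(time_min) == length(pfu_ml) && length(time_min) >= 2,
            "growth_curve: need matching time/titer vectors")
  pv_assert(all(diff(time_min) > 0), "times must be strictly increasing")
  pv_assert(all(pfu_ml > 0), "titers must be positive")
  structure(list(time_min = time_min, pfu_ml = pfu_ml,
                 phage_id = phage_id),
            class = "growth_curve")
}

#' Estimate burst size and latent period
#'
#' @param curve a [growth_curve()] with at least 5 points spanning both
#'   plateaus.
#' @param min_rise minimum post/pre plateau ratio below which the burst
#'   is reported undefined (default 1.2).
#' @return list (burst, latent_min, pre_idx, rise_idx, post_idx,
#'   flagged). `flagged = TRUE` (with NA burst/latent) when no rise is
#'   detectable.
#' @export
estimate_burst <- function(curve, min_rise = 1.2) {
  t <- curve$time_min
  y <- log10(curve$pfu_ml)
  n <- length(t)
  pv_assert(n >= 5, "estimate_burst needs >= 5 time points",
            "panvirome_validation_error")
  sse <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  sse_line <- function(tt, vv) {
    if (length(vv) < 3) return(0)
    f <- lm(vv ~ tt)
    sum(f$residuals^2)
  }
  best <- NULL
  # pre = 1..i, rise = (i+1)..(j-1), post = j..n; i descends so that ties
  # resolve to the longest pre-plateau
  for (i in (n - 2):2) {
    for (j in (i + 1):(n - 1)) {
      if (j - i - 1 < 0) next
      obj <- sse(y[1:i]) + sse(y[j:n]) +
        sse_line(t[(i + 1):(j - 1)], y[(i + 1):(j - 1)])
      if (is.null(best) || obj < best$obj - 1e-12) {
        best <- list(obj = obj, i = i, j = j)
      }
    }
  }
  i <- best$i; j <- best$j
  pre <- curve$pfu_ml[1:i]; post <- curve$pfu_ml[j:n]
  burst <- mean(post) / mean(pre)
  if (burst < min_rise) {
    return(list(burst = NA_real_, latent_min = NA_real_,
                pre_idx = 1:i, rise_idx = if (j - i > 1) (i + 1):(j - 1)
                else integer(0),
                post_idx = j:n, flagged = TRUE))
  }
  lo <- mean(y[1:i]); hi <- mean(y[j:n])
  mid <- (lo + hi) / 2
  rise_idx <- if (j - i > 1) (i + 1):(j - 1) else integer(0)
  if (length(rise_idx) >= 2) {
    fit <- lm(y[rise_idx] ~ t[rise_idx])
    latent <- (mid - coef(fit)[1]) / coef(fit)[2]
  } else {
    # too few rise points for a line: interpolate through flanks
    tt <- c(t[i], t[rise_idx], t[j])
    vv <- c(y[i], y[rise_idx], y[j])
    fit <- lm(vv ~ tt)
    latent <- (mid - coef(fit)[1]) / coef(fit)[2]
  }
  list(burst = burst, latent_min = unname(latent), pre_idx = 1:i,
       rise_idx = rise_idx, post_idx = j:n, flagged = FALSE)
}

#' Read / write growth-curve TSVs
#'
#' TSV columns: phage_id, time_min, pfu_ml.
#'
#' @param path TSV path.
#' @return named list of `growth_curve` objects.
#' @export
read_growth_curves <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  pv_assert(all(c("phage_id", "time_min", "pfu_ml") %in% names(df)),
            "growth TSV needs phage_id, time_min, pfu_ml")
  lapply(split(df, df$phage_id), function(d) {
    d <- d[order(d$time_min), ]
    growth_curve(d$time_min, d$pfu_ml, d$phage_id[1])
  })
}
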