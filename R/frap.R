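# FRAP recovery analysis: single-exponential fits, immobile fractions, and
# the group-level geometric-mean summary used for skewed half-times.

#' A bleach-recovery intensity trace
#'
#' @param trace_id identifier.
#' @param times_s strictly increasing sample times, seconds.
#' @param intensities non-negative intensities, same length.
#' @param phase character vector of `"pre"`/`"post"` labels per sample;
#'   alternatively pass `bleach_time_s`.
#' @param bleach_time_s bleach instant; samples at or after it are
#'   post-bleach. Ignored when `phase` is given.
#' @return a `frap_trace` list with fields `trace_id`, `times_s`,
#'   `intensities`, `bleach_index` (first post-bleach position) and
#'   `pre_bleach_intensity` (mean over all pre-bleach samples).
#' @export
frap_trace <- function(trace_id, times_s, intensities, phase = NULL,
                       bleach_time_s = NULL) {
  stopifnot(length(times_s) == length(intensities),
            all(diff(times_s) > 0), all(is.finite(intensities)),
            all(intensities >= 0))
  if (is.null(phase)) {
    if (is.null(bleach_time_s)) {
      stop("either `phase` labels or `bleach_time_s` must be given")
    }
    phase <- ifelse(times_s >= bleach_time_s, "post", "pre")
  }
  stopifnot(all(phase %in% c("pre", "post")))
  post <- phase == "post"
  if (!any(!post)) stop("trace has no pre-bleach samples")
  if (sum(post) < 4L) {
    stop("trace needs at least 4 post-bleach samples, has ", sum(post))
  }
  if (any(diff(post) < 0)) {
    stop("post-bleach samples must follow all pre-bleach samples")
  }
  pre_mean <- mean(intensities[!post])
  if (pre_mean <= 0) stop("pre-bleach intensity must be positive")
  structure(
    list(trace_id = as.character(trace_id), times_s = times_s,
         intensities = intensities,
         bleach_index = which(post)[1],
         pre_bleach_intensity = pre_mean),
    class = "frap_trace"
  )
}

#' Fit the single-exponential FRAP recovery model
#'
#' Nonlinear least squares of `Intensity(t) = A + B exp(-C t)` on the
#' post-bleach samples, with `t` re-zeroed at the first post-bleach frame so
#' parameters are comparable across traces. Starting values: `A0` the mean
#' of the final three samples, `B0` the first post-bleach intensity minus
#' `A0`, and `C0 = ln 2 / t_half0` with `t_half0` the time at which the
#' trace first crosses halfway between the first post-bleach intensity and
#' `A0` (falling back to a third of the post-bleach span). `C` is bounded
#' positive. Traces with no resolvable recovery amplitude are returned with
#' `converged = FALSE` (the rate is unidentifiable) rather than an error.
#'
#' @param trace a [frap_trace()].
#' @return a `frap_fit` list: `A`, `B`, `C`, `half_time_s = ln(2)/C`,
#'   `rss`, `converged`, and the re-zeroed fit inputs.
#' @export
fit_recovery <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  i0 <- trace$bleach_index
  t <- trace$times_s[i0:length(trace$times_s)]
  y <- trace$intensities[i0:length(trace$times_s)]
  t <- t - t[1]
  n <- length(y)
  A0 <- mean(y[(n - 2):n])
  B0 <- y[1] - A0
  span <- t[n]
  degenerate <- abs(B0) < 1e-8 * max(abs(y), 1e-12) ||
    stats::sd(y) < 1e-12 * max(abs(y), 1e-12)
  if (degenerate) {
    fit <- list(A = mean(y), B = 0, C = NA_real_, half_time_s = NA_real_,
                rss = sum((y - mean(y))^2), converged = FALSE)
    return(structure(c(fit, list(trace_id = trace$trace_id,
                                 times_post_s = t, intensities_post = y)),
                     class = "frap_fit"))
  }
  halfway <- A0 + B0 / 2
  crossed <- if (B0 < 0) which(y >= halfway) else which(y <= halfway)
  t_half0 <- if (length(crossed) && t[crossed[1]] > 0) t[crossed[1]] else span / 3
  C0 <- log(2) / t_half0
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A + B * exp(-C * t),
      start = list(A = A0, B = B0, C = C0),
      lower = c(-Inf, -Inf, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out <- list(A = A0, B = B0, C = C0, half_time_s = log(2) / C0,
                rss = sum((y - (A0 + B0 * exp(-C0 * t)))^2),
                converged = FALSE)
  } else {
    cf <- stats::coef(fit)
    out <- list(A = unname(cf["A"]), B = unname(cf["B"]),
                C = unname(cf["C"]),
                half_time_s = log(2) / unname(cf["C"]),
                rss = sum(stats::residuals(fit)^2),
                converged = fit$convInfo$isConv %||% TRUE)
  }
  structure(c(out, list(trace_id = trace$trace_id,
                        times_post_s = t, intensities_post = y)),
            class = "frap_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Immobile fraction of a FRAP recovery
#'
#' The proportion of the bleached signal that never recovers:
#' `IF = 1 - (A - I_bleach) / (I_pre - I_bleach)`, where `A` is the fitted
#' recovery plateau, `I_bleach` the first post-bleach intensity and `I_pre`
#' the mean pre-bleach intensity. Full recovery to the pre-bleach level
#' gives 0; no recovery gives 1. The raw value is reported alongside a
#' `[0, 1]`-clipped value (noise can push the raw estimate slightly
#' outside). The ratio form makes the fraction invariant to affine
#' rescaling of the whole trace.
#'
#' @param fit a [fit_recovery()] result.
#' @param trace the matching [frap_trace()].
#' @return list with `raw` and `clipped` immobile fractions.
#' @export
immobile_fraction <- function(fit, trace) {
  stopifnot(inherits(fit, "frap_fit"), inherits(trace, "frap_trace"))
  i_pre <- trace$pre_bleach_intensity
  i_bleach <- trace$intensities[trace$bleach_index]
  if (i_pre <= i_bleach) {
    stop("bleach failure: pre-bleach intensity (", signif(i_pre, 4),
         ") does not exceed the first post-bleach intensity (",
         signif(i_bleach, 4), ")")
  }
  raw <- 1 - (fit$A - i_bleach) / (i_pre - i_bleach)
  list(raw = raw, clipped = min(max(raw, 0), 1))
}

#' Group summary of FRAP half-times
#'
#' Recovery half-times are typically right-skewed, so the group statistic
#' is the geometric mean with a 95% confidence interval computed on the
#' natural-log scale: `exp(mean(log x) +/- t(0.975, n-1) sd(log x) /
#' sqrt(n))`. Shapiro-Wilk normality p-values are reported for both the raw
#' and the log-transformed values so the transform can be justified per
#' dataset.
#'
#' @param half_times positive half-times, length >= 3.
#' @return a `frap_group_summary` list: `n`, `geometric_mean_half_time_s`,
#'   `ci95_low`, `ci95_high`, `shapiro_p_raw`, `shapiro_p_log`.
#' @export
summarize_half_times <- function(half_times) {
  if (any(!is.finite(half_times)) || any(half_times <= 0)) {
    stop("all half-times must be positive and finite")
  }
  n <- length(half_times)
  if (n < 3L) stop("at least 3 half-times are required, got ", n)
  lx <- log(half_times)
  m <- mean(lx); s <- stats::sd(lx)
  if (s == 0) {
    ci <- c(exp(m), exp(m))
    sp_raw <- NA_real_; sp_log <- NA_real_
  } else {
    half_width <- stats::qt(0.975, n - 1) * s / sqrt(n)
    ci <- exp(c(m - half_width, m + half_width))
    sp_raw <- stats::shapiro.test(half_times)$p.value
    sp_log <- stats::shapiro.test(lx)$p.value
  }
  structure(
    list(n = n, geometric_mean_half_time_s = exp(m),
         ci95_low = ci[1], ci95_high = ci[2],
         shapiro_p_raw = sp_raw, shapiro_p_log = sp_log),
    class = "frap_group_summary"
  )
}

#' Summarize immobile fractions of a group
#'
#' Immobile fractions are bounded and usually close to normal, so the raw
#' (untransformed) mean and standard deviation are reported.
#'
#' @param fractions immobile fractions in `[0, 1]` (clipped values).
#' @return list with `n`, `immobile_mean`, `immobile_sd`.
#' @export
summarize_immobile <- function(fractions) {
  stopifnot(all(is.finite(fractions)))
  list(n = length(fractions), immobile_mean = mean(fractions),
       immobile_sd = stats::sd(fractions))
}

#' Two-group comparison by t-test
#'
#' Two-sided comparison of two samples, either with Welch's unequal
#' variance correction (Welch-Satterthwaite degrees of freedom) or the
#' classical pooled-variance Student form. Two degenerate constant groups
#' with equal means return `p = 1`, statistic 0.
#'
#' @param values_a,values_b numeric samples, each of length >= 2.
#' @param mode `"welch"` or `"student"`.
#' @return list with `statistic`, `p_value`, `df`, `mode`.
#' @export
compare_groups <- function(values_a, values_b,
                           mode = c("welch", "student")) {
  mode <- match.arg(mode)
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  res <- tryCatch(
    stats::t.test(values_a, values_b, var.equal = (mode == "student")),
    error = function(e) {
      if (isTRUE(all.equal(mean(values_a), mean(values_b)))) {
        list(statistic = c(t = 0), p.value = 1,
             parameter = c(df = length(values_a) + length(values_b) - 2))
      } else {
        stop(e)
      }
    }
  )
  list(statistic = unname(res$statistic), p_value = res$p.value,
       df = unname(res$parameter), mode = mode)
}
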