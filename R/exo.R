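# Exocytosis retention kinetics: normalization of tracer-retention curves,
# half-retention time, per-replicate AUC, and ANOVA + Tukey HSD across
# strains.

#' Normalize a raw retention measurement to a retention curve
#'
#' Divides raw fluorescence by the initial (t = 0) measurement so every
#' curve starts at 1, and re-zeros the time axis at the first sample.
#' Normalizing an already-normalized curve is a no-op.
#'
#' @param raw_times increasing measurement times, minutes.
#' @param raw_fluorescence raw fluorescence values; the first must be > 0.
#' @param replicate_id,strain identifiers carried on the curve.
#' @return a `retention_curve` list with `times_min` (starting at 0) and
#'   `fraction_remaining` (first value 1).
#' @export
normalize_retention <- function(raw_times, raw_fluorescence,
                                replicate_id = NA, strain = NA) {
  stopifnot(length(raw_times) == length(raw_fluorescence),
            all(diff(raw_times) > 0))
  if (!is.finite(raw_fluorescence[1]) || raw_fluorescence[1] <= 0) {
    stop("cannot normalize: initial fluorescence must be positive")
  }
  if (any(raw_fluorescence < 0)) {
    stop("fluorescence values must be non-negative")
  }
  structure(
    list(replicate_id = replicate_id, strain_label = strain,
         times_min = raw_times - raw_times[1],
         fraction_remaining = raw_fluorescence / raw_fluorescence[1]),
    class = "retention_curve"
  )
}

#' Time to 50% of initial fluorescence
#'
#' Locates the first downward crossing of 0.5 in a normalized retention
#' curve and linearly interpolates between the bracketing samples. A curve
#' that never reaches 0.5 is censored: the flag is set and the last
#' observed time returned in its place.
#'
#' @param curve a [normalize_retention()] curve.
#' @return list with `t50_min`, `censored` (logical), and `last_time_min`.
#' @export
half_retention_time <- function(curve) {
  stopifnot(inherits(curve, "retention_curve"))
  t <- curve$times_min; f <- curve$fraction_remaining
  below <- which(f <= 0.5)
  if (length(below) == 0L) {
    return(list(t50_min = NA_real_, censored = TRUE,
                last_time_min = t[length(t)]))
  }
  i <- below[1]
  t50 <- if (f[i] == 0.5 || i == 1L) {
    t[i]
  } else {
    t[i - 1] + (0.5 - f[i - 1]) * (t[i] - t[i - 1]) / (f[i] - f[i - 1])
  }
  list(t50_min = t50, censored = FALSE, last_time_min = t[length(t)])
}

#' Area under a retention curve
#'
#' Trapezoidal integral of the normalized fraction over the observed time
#' span (no extrapolation), in units of minutes x fraction.
#'
#' @param curve a [normalize_retention()] curve with >= 2 time points.
#' @return the area.
#' @export
retention_auc <- function(curve) {
  stopifnot(inherits(curve, "retention_curve"))
  t <- curve$times_min; f <- curve$fraction_remaining
  if (length(t) < 2L) stop("AUC needs at least 2 time points")
  sum(diff(t) * (f[-1] + f[-length(f)]) / 2)
}

#' Compare retention kinetics across strains
#'
#' One-way ANOVA on per-replicate AUC values followed by Tukey's HSD test
#' for every strain pair (Tukey-Kramer adjustment handles unequal group
#' sizes). Per-strain t50 means and standard deviations are reported
#' alongside when curves are given.
#'
#' @param auc_by_strain named list mapping strain label to a numeric vector
#'   of per-replicate AUCs; strains with fewer than 2 replicates are
#'   excluded with a warning.
#' @param t50_by_strain optional named list of per-replicate t50 values.
#' @return a `kinetics_summary` list: `anova_F`, `anova_p`, `tukey`
#'   (data.frame with columns `pair`, `diff`, `p_adj`), `strain_stats`
#'   (data.frame with per-strain n, AUC mean/sd and t50 mean/sd).
#' @export
compare_strains <- function(auc_by_strain, t50_by_strain = NULL) {
  stopifnot(is.list(auc_by_strain), !is.null(names(auc_by_strain)))
  sizes <- lengths(auc_by_strain)
  if (any(sizes < 2L)) {
    warning("excluding strains with fewer than 2 replicates: ",
            paste(names(auc_by_strain)[sizes < 2L], collapse = ", "))
    auc_by_strain <- auc_by_strain[sizes >= 2L]
  }
  if (length(auc_by_strain) < 2L) {
    stop("at least 2 strains with n >= 2 are required")
  }
  df <- data.frame(
    auc = unlist(auc_by_strain, use.names = FALSE),
    strain = factor(rep(names(auc_by_strain), lengths(auc_by_strain)))
  )
  fit <- stats::aov(auc ~ strain, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$strain
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  stats_df <- data.frame(
    strain = names(auc_by_strain),
    n = unname(lengths(auc_by_strain)),
    auc_mean = vapply(auc_by_strain, mean, numeric(1)),
    auc_sd = vapply(auc_by_strain, stats::sd, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(t50_by_strain)) {
    stats_df$t50_mean <- vapply(stats_df$strain, function(s) {
      mean(t50_by_strain[[s]], na.rm = TRUE)
    }, numeric(1))
    stats_df$t50_sd <- vapply(stats_df$strain, function(s) {
      stats::sd(t50_by_strain[[s]], na.rm = TRUE)
    }, numeric(1))
  }
  structure(
    list(anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
         tukey = tukey, strain_stats = stats_df),
    class = "kinetics_summary"
  )
}
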