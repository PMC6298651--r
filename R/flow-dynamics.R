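# From flow-cytometry event tables to copy-class proportions and CNV
# dynamics statistics: doublet/debris filtering, control-derived conservative
# gates, the detection threshold from evolving one-copy controls, T_up (first
# generation above threshold) and S_up (log-odds slope during the initial
# expansion), plus competitive-fitness regression.

#' Filter doublets and debris, add size-normalised fluorescence
#'
#' Doublets are removed where FSC-H/FSC-A falls outside `doublet_band`
#' (a single cell has FSC-H ~ FSC-A; two cells measured as one double FSC-A
#' but not FSC-H). Debris is removed below the `debris_quantile` of FSC-A or
#' SSC-A. Adds a `norm_fl` column (`FL1-A` / `FSC-A`) to the retained events.
#'
#' @param sample a `flow_sample`.
#' @param doublet_band allowed FSC-H/FSC-A ratio range for singlets.
#' @param debris_quantile lower quantile of FSC-A and SSC-A below which
#'   events are discarded as debris.
#' @return the filtered `flow_sample` with a `norm_fl` column; the original
#'   event count is kept in attribute `n_input`.
#' @export
preprocess_events <- function(sample, doublet_band = c(0.6, 1.4),
                              debris_quantile = 0.01) {
  ev <- sample$events
  if (is.null(ev) || nrow(ev) == 0) stop("event table is empty")
  n0 <- nrow(ev)
  keep_debris <- ev[["FSC-A"]] >= stats::quantile(ev[["FSC-A"]], debris_quantile) &
    ev[["SSC-A"]] >= stats::quantile(ev[["SSC-A"]], debris_quantile)
  ratio <- ev[["FSC-H"]] / ev[["FSC-A"]]
  keep_singlet <- ratio >= doublet_band[1] & ratio <= doublet_band[2]
  keep <- keep_debris & keep_singlet & is.finite(ratio) &
    ev[["FSC-A"]] > 0 & ev[["FL1-A"]] > 0
  if (!any(keep)) stop("all events removed by doublet/debris filtering")
  ev <- ev[keep, , drop = FALSE]
  tr <- attr(sample$events, "truth")
  if (!is.null(tr)) attr(ev, "truth") <- tr[keep, , drop = FALSE]
  ev$norm_fl <- ev[["FL1-A"]] / ev[["FSC-A"]]
  attr(ev, "n_input") <- n0
  sample$events <- ev
  sample
}

#' Derive conservative copy-class gates from control strains
#'
#' A liberal upper gate for the one-copy control is drawn at its
#' `liberal_quantile` of normalised fluorescence; the two-copy gate starts at
#' `max` of that boundary and the lower tail of the two-copy control, which
#' guarantees the gates do not overlap (events in between are conservatively
#' assigned to one copy). The zero-copy boundary is a configurable fraction
#' of the one-copy lower tail; the 3+ boundary is the upper quantile of the
#' two-copy control.
#'
#' @param one_copy_control,two_copy_control preprocessed `flow_sample`s.
#' @param liberal_quantile upper quantile of the 1-copy control bounding its
#'   gate (default 0.995).
#' @param zero_floor_frac zero/one boundary as a fraction of the 1-copy
#'   control's lower-tail quantile.
#' @return object of class `gate_set`: list with `breaks` `(b0,b1,b2,b3)`.
#' @export
derive_gates <- function(one_copy_control, two_copy_control,
                         liberal_quantile = 0.995, zero_floor_frac = 0.5) {
  f1 <- one_copy_control$events$norm_fl
  f2 <- two_copy_control$events$norm_fl
  if (is.null(f1) || is.null(f2))
    stop("controls must be preprocessed (norm_fl missing)")
  b1 <- stats::quantile(f1, liberal_quantile, names = FALSE)
  b2 <- max(b1, stats::quantile(f2, 1 - liberal_quantile, names = FALSE))
  b0 <- zero_floor_frac * stats::quantile(f1, 1 - liberal_quantile,
                                          names = FALSE)
  b3 <- stats::quantile(f2, liberal_quantile, names = FALSE)
  if (stats::median(f2) <= b1)
    stop(sprintf(paste0("control distributions overlap too much for a ",
                        "non-empty two-copy gate (1-copy %.3g quantile %.3g ",
                        ">= 2-copy median %.3g)"),
                 liberal_quantile, b1, stats::median(f2)))
  if (!(b0 < b1 && b1 <= b2 && b2 < b3))
    stop("derived gate boundaries are not increasing")
  structure(list(breaks = c(b0 = b0, b1 = b1, b2 = b2, b3 = b3),
                 liberal_quantile = liberal_quantile),
            class = "gate_set")
}

#' @export
print.gate_set <- function(x, ...) {
  cat("gate_set boundaries (normalised fluorescence):\n")
  print(signif(x$breaks, 4))
  invisible(x)
}

#' Copy-class proportions of a sample under a gate set
#'
#' Classes: `0` below `b0`; `1` from `b0` to `b2` (the conservative one-copy
#' gate, absorbing the inter-control margin); `2` from `b2` to `b3`; `3+`
#' above `b3`. `cnv_fraction` is the 2 plus 3+ share; `deletion_fraction` the
#' zero-copy share.
#'
#' @param sample a preprocessed `flow_sample`.
#' @param gates a `gate_set`.
#' @return list with `proportions` (named, sums to 1), `cnv_fraction`,
#'   `deletion_fraction`, `n_events`.
#' @export
classify_proportions <- function(sample, gates) {
  f <- sample$events$norm_fl
  if (is.null(f)) stop("sample must be preprocessed first")
  b <- gates$breaks
  cls <- cut(f, breaks = c(-Inf, b["b0"], b["b2"], b["b3"], Inf),
             labels = c("0", "1", "2", "3+"), right = TRUE)
  pr <- as.numeric(table(cls)) / length(f)
  names(pr) <- c("0", "1", "2", "3+")
  list(proportions = pr,
       cnv_fraction = pr[["2"]] + pr[["3+"]],
       deletion_fraction = pr[["0"]],
       n_events = length(f))
}

#' Detection threshold from evolving one-copy control trajectories
#'
#' Mean plus one sample SD of the control populations' apparent CNV fraction
#' over a generation window: the false-positive level above which a real CNV
#' subpopulation is considered detected.
#'
#' @param control_fractions numeric vector of control `cnv_fraction` values,
#'   or a data.frame with `generation` and `cnv_fraction`.
#' @param generation_window optional `c(first, last)` window applied when a
#'   data.frame is supplied.
#' @return the threshold (proportion).
#' @export
compute_fp_threshold <- function(control_fractions, generation_window = NULL) {
  x <- control_fractions
  if (is.data.frame(x)) {
    if (!is.null(generation_window))
      x <- x[x$generation >= generation_window[1] &
               x$generation <= generation_window[2], ]
    x <- x$cnv_fraction
  }
  if (length(x) < 2) stop("need at least 2 control measurements in the window")
  mean(x) + stats::sd(x)
}

#' First generation at which the CNV fraction surpasses the threshold
#'
#' Strictly greater than the threshold ("surpasses"); ties do not trigger
#' detection. `NA` if the trajectory never exceeds it.
#'
#' @param trajectory data.frame with `generation` (strictly increasing) and
#'   `cnv_fraction`.
#' @param fp_threshold detection threshold from [compute_fp_threshold()].
#' @return generation (numeric) or `NA`.
#' @export
compute_Tup <- function(trajectory, fp_threshold) {
  if (is.unsorted(trajectory$generation, strictly = TRUE))
    stop("generations must be strictly increasing")
  i <- which(trajectory$cnv_fraction > fp_threshold)
  if (!length(i)) NA_real_ else trajectory$generation[i[1]]
}

#' Rate of increase of the CNV subpopulation (log-odds slope)
#'
#' Ordinary least squares of `ln(p/(1-p))` on generations over the earliest
#' window of at least `min_points` consecutive usable timepoints that
#' maximises R-squared. Usable points have CNV fraction strictly inside
#' (0, `saturation_cap`]; the cap keeps the fit inside the initial expansion
#' phase. S_up approximates the mean relative fitness advantage of the CNV
#' subpopulation per generation.
#'
#' @param trajectory data.frame with `generation`, `cnv_fraction`.
#' @param min_points minimum points per candidate window (default 3).
#' @param saturation_cap exclude points at or above this fraction.
#' @return list with `S_up`, `SE`, `window` `(first, last)` generation,
#'   `R2`, and `flagged` (TRUE when the fit was degenerate).
#' @export
compute_Sup <- function(trajectory, min_points = 3, saturation_cap = 0.90) {
  ok <- trajectory$cnv_fraction > 0 & trajectory$cnv_fraction < 1 &
    trajectory$cnv_fraction < saturation_cap
  tr <- trajectory[ok, , drop = FALSE]
  if (nrow(tr) < min_points)
    stop("fewer than min_points usable timepoints (fractions in (0,1) below the cap)")
  y <- log(tr$cnv_fraction / (1 - tr$cnv_fraction))
  g <- tr$generation
  n <- length(y)
  best <- NULL
  for (i in seq_len(n - min_points + 1L)) {
    for (j in seq(i + min_points - 1L, n)) {
      yy <- y[i:j]; gg <- g[i:j]
      if (stats::var(yy) == 0) {       # flat segment: slope 0, R2 undefined
        cand <- list(slope = 0, se = 0, r2 = NA_real_, i = i, j = j,
                     flagged = TRUE)
      } else {
        fit <- stats::lm(yy ~ gg)
        sm <- suppressWarnings(summary(fit))  # noiseless data fits perfectly
        cand <- list(slope = unname(stats::coef(fit)[2]),
                     se = sm$coefficients[2, 2],
                     r2 = sm$r.squared, i = i, j = j, flagged = FALSE)
      }
      r2k <- if (is.na(cand$r2)) -Inf else round(cand$r2, 10)
      bk <- if (is.null(best)) -Inf else
        if (is.na(best$r2)) -Inf else round(best$r2, 10)
      take <- is.null(best) || r2k > bk ||
        (r2k == bk && (cand$i < best$i ||
                         (cand$i == best$i && cand$j > best$j)))
      if (take) best <- cand
    }
  }
  list(S_up = best$slope, SE = best$se,
       window = c(g[best$i], g[best$j]), R2 = best$r2,
       flagged = isTRUE(best$flagged))
}

#' Competitive-fitness estimate from pairwise competition counts
#'
#' Linear regression of `ln(fluorescent/reference)` against generations; the
#' slope is the per-generation selection coefficient, with a normal-theory
#' 95 percent confidence interval.
#'
#' @param counts data.frame with `generation`, `fluorescent`, `reference`
#'   (cell or event counts, all > 0).
#' @return list with `s`, `se`, `ci` (length-2).
#' @export
estimate_relative_fitness <- function(counts) {
  if (nrow(counts) < 3) stop("need at least 3 timepoints")
  if (any(counts$fluorescent <= 0 | counts$reference <= 0))
    stop("counts must be positive at every timepoint")
  y <- log(counts$fluorescent / counts$reference)
  g <- counts$generation
  if (stats::var(y) == 0)
    return(list(s = 0, se = 0, ci = c(0, 0)))
  fit <- stats::lm(y ~ g)
  ci <- suppressWarnings(stats::confint(fit))["g", ]  # exact data fit cleanly
  list(s = unname(stats::coef(fit)["g"]),
       se = suppressWarnings(summary(fit))$coefficients["g", 2],
       ci = unname(ci))
}

#' Summarise CNV dynamics for one population
#'
#' Convenience wrapper producing the per-population dynamics summary:
#' detection generation `T_up`, expansion rate `S_up` (and `1 + S_up`), the
#' fitted window and R-squared, and the CNV fraction at requested
#' generations.
#'
#' @param trajectory data.frame with `generation`, `cnv_fraction`.
#' @param fp_threshold detection threshold.
#' @param report_at generations at which to report the CNV fraction.
#' @return object of class `dynamics_summary`.
#' @export
summarize_cnv_dynamics <- function(trajectory, fp_threshold,
                                   report_at = numeric(0)) {
  su <- compute_Sup(trajectory)
  at <- vapply(report_at, function(g) {
    i <- which.min(abs(trajectory$generation - g))
    trajectory$cnv_fraction[i]
  }, numeric(1))
  structure(list(T_up = compute_Tup(trajectory, fp_threshold),
                 S_up = su$S_up, SE = su$SE, window = su$window, R2 = su$R2,
                 fp_threshold = fp_threshold,
                 fraction_at = stats::setNames(at, report_at)),
            class = "dynamics_summary")
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat(sprintf("dynamics_summary: T_up=%s  1+S_up=%.3f +/- %.4f  R2=%.3f\n",
              format(x$T_up), 1 + x$S_up, x$SE,
              if (is.na(x$R2)) NA else x$R2))
  if (length(x$fraction_at)) {
    cat("CNV fraction at generations:\n"); print(round(x$fraction_at, 3))
  }
  invisible(x)
}
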