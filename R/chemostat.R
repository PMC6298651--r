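# Chemostat selection dynamics for CNV lineages: per generation, new CNV
# lineages are seeded from ancestral cells at rate mu, frequencies are
# updated deterministically by relative fitness, then resampled
# multinomially (one resampling per generation as a discretised stand-in for
# continuous-culture drift).

#' Simulate CNV lineage trajectories in a chemostat
#'
#' Per generation: new CNV lineages arise from ancestral cells at rate `mu`
#' per cell per generation (Poisson), each seeded at frequency `1/N`; then
#' the deterministic selection update `p_i <- p_i (1 + s_i) / w_bar` is
#' applied, followed by multinomial resampling of size `N` (skipped when
#' `N = Inf`, giving fully deterministic dynamics).
#'
#' @param N effective population size (>= 1000, or `Inf` for deterministic
#'   dynamics). Desk-scale stand-in for the ~1e8 cells of a real chemostat.
#' @param mu CNV formation rate per ancestral cell per generation.
#' @param fitness_distribution function(n) returning n per-generation
#'   selection coefficients for newly arising CNV lineages. Default: normal
#'   around 0.08 (SD 0.02), the scale typical of strongly selected
#'   nutrient-transporter amplifications.
#' @param n_generations number of generations to simulate.
#' @param dilution_rate chemostat dilution rate per hour; reported as
#'   `doubling_time = ln(2) / dilution_rate`.
#' @param seed integer RNG seed.
#' @param initial_lineages optional data.frame with columns `p0`, `s`,
#'   `is_cnv` describing lineages present at generation 0 besides the
#'   ancestor.
#' @return object of class `chemostat_trajectory`: list with `generations`
#'   (0..n), `freq` (generations x lineages matrix; column 1 is the
#'   ancestor), `fitness`, `is_cnv`, `mu`, `N`, `doubling_time`.
#' @export
simulate_chemostat <- function(N = 1e5, mu = 1e-4,
                               fitness_distribution = function(n)
                                 stats::rnorm(n, 0.08, 0.02),
                               n_generations = 100, dilution_rate = 0.12,
                               seed, initial_lineages = NULL) {
  if (missing(seed)) stop("seed must be supplied")
  if (is.finite(N) && N < 1000) stop("N must be >= 1000 (or Inf)")
  if (n_generations < 1) stop("n_generations must be >= 1")
  if (mu < 0 || mu > 1) stop("mu must be in [0,1]")
  set.seed(seed)

  s <- 0          # lineage 1 = ancestor
  is_cnv <- FALSE
  p <- 1
  if (!is.null(initial_lineages)) {
    p <- c(1 - sum(initial_lineages$p0), initial_lineages$p0)
    s <- c(0, initial_lineages$s)
    is_cnv <- c(FALSE, initial_lineages$is_cnv)
    if (p[1] < 0) stop("initial lineage frequencies exceed 1")
  }

  traj <- list(p)
  for (g in seq_len(n_generations)) {
    # mutation: new CNV lineages from ancestral cells
    if (mu > 0 && is.finite(N) && p[1] > 0) {
      n_new <- stats::rpois(1, mu * N * p[1])
      n_new <- min(n_new, floor(p[1] * N))
      if (n_new > 0) {
        p <- c(p, rep(1 / N, n_new))
        p[1] <- p[1] - n_new / N
        s <- c(s, fitness_distribution(n_new))
        is_cnv <- c(is_cnv, rep(TRUE, n_new))
      }
    }
    w <- 1 + s
    if (any(w <= 0)) stop("selection coefficients give non-positive fitness")
    wbar <- sum(p * w)
    if (wbar <= 0) stop("mean fitness is non-positive")
    p <- p * w / wbar
    if (is.finite(N)) p <- as.numeric(stats::rmultinom(1, N, p)) / N
    traj[[g + 1L]] <- p
  }

  nl <- length(p)
  freq <- matrix(0, nrow = n_generations + 1L, ncol = nl)
  for (g in seq_along(traj)) freq[g, seq_along(traj[[g]])] <- traj[[g]]
  structure(list(generations = 0:n_generations, freq = freq,
                 fitness = s, is_cnv = is_cnv, mu = mu, N = N,
                 doubling_time = log(2) / dilution_rate),
            class = "chemostat_trajectory")
}

#' @export
print.chemostat_trajectory <- function(x, ...) {
  cat(sprintf(paste0("chemostat_trajectory: %d generations, %d lineage(s), ",
                     "doubling time %.1f h\n"),
              max(x$generations), ncol(x$freq), x$doubling_time))
  invisible(x)
}

#' CNV subpopulation fraction per generation
#'
#' @param trajectory a `chemostat_trajectory`.
#' @return data.frame with `generation` and `cnv_fraction`.
#' @export
cnv_fraction <- function(trajectory) {
  cols <- which(trajectory$is_cnv)
  frac <- if (length(cols)) rowSums(trajectory$freq[, cols, drop = FALSE]) else
    rep(0, nrow(trajectory$freq))
  data.frame(generation = trajectory$generations, cnv_fraction = frac)
}

#' Number of surviving CNV lineages at the final generation
#' @param trajectory a `chemostat_trajectory`.
#' @export
surviving_cnv_lineages <- function(trajectory) {
  last <- trajectory$freq[nrow(trajectory$freq), ]
  sum(last > 0 & trajectory$is_cnv)
}
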