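# Flow-cytometry event simulation for a fluorescent copy-number reporter:
# fluorescence scales with reporter copies times cell size, with lognormal
# expression noise; forward scatter tracks size; a configurable fraction of
# doublets breaks the FSC-H ~ FSC-A relationship; debris sits in the low
# FSC-A x SSC-A corner.

#' Default fluorescence/scatter model for [simulate_flow_sample()]
#'
#' @param gain fluorescence units contributed per reporter copy per unit of
#'   cell size.
#' @param cv lognormal coefficient of variation of per-cell expression noise.
#' @param size_meanlog,size_sdlog lognormal cell-size distribution (arbitrary
#'   scatter units).
#' @param fsc_cv,fsch_cv relative noise on FSC-A and on the FSC-H/FSC-A
#'   relationship for singlets.
#' @param doublet_fraction fraction of events that are two cells measured as
#'   one (FSC-A, SSC-A and FL1-A doubled; FSC-H unchanged).
#' @param debris_fraction fraction of events that are debris (near-zero
#'   scatter and fluorescence).
#' @param background fluorescence of a zero-copy cell as a fraction of the
#'   one-copy signal (autofluorescence).
#' @export
flow_model <- function(gain = 100, cv = 0.2, size_meanlog = log(5e4),
                       size_sdlog = 0.25, fsc_cv = 0.05, fsch_cv = 0.03,
                       doublet_fraction = 0.03, debris_fraction = 0.02,
                       background = 0.05) {
  list(gain = gain, cv = cv, size_meanlog = size_meanlog,
       size_sdlog = size_sdlog, fsc_cv = fsc_cv, fsch_cv = fsch_cv,
       doublet_fraction = doublet_fraction, debris_fraction = debris_fraction,
       background = background)
}

.lnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + cv^2)))
}

#' Simulate a flow-cytometry sample of a mixed copy-number population
#'
#' Per event, FL1-A = copies x size x lognormal noise (median of the
#' size-normalised signal at `copies * gain`), FSC-A tracks size, and FSC-H
#' tracks FSC-A except for doublets. Class medians of FL1-A/FSC-A stand in
#' ratio 1:2:3... across copy classes.
#'
#' @param copy_class_proportions named numeric vector of class proportions;
#'   names are copy numbers (`"0"`, `"1"`, `"2"`, `"3"`, ...). Must sum to 1.
#' @param n_events number of events (default 1e5, a typical per-sample event
#'   count).
#' @param model list from [flow_model()].
#' @param seed integer RNG seed.
#' @param population,generation identifiers carried on the sample.
#' @return object of class `flow_sample`: list with `population`,
#'   `generation`, `events` (data.frame with columns `FSC-A`, `FSC-H`,
#'   `SSC-A`, `FL1-A`) and a `truth` attribute on `events` (data.frame
#'   `copies`, `is_doublet`, `is_debris`).
#' @export
simulate_flow_sample <- function(copy_class_proportions, n_events = 1e5,
                                 model = flow_model(), seed,
                                 population = NA, generation = NA) {
  if (missing(seed)) stop("seed must be supplied")
  pr <- copy_class_proportions
  if (any(pr < 0)) stop("class proportions must be non-negative")
  if (abs(sum(pr) - 1) > 1e-8) stop("class proportions must sum to 1")
  if (n_events < 1) stop("n_events must be >= 1")
  set.seed(seed)

  copies <- as.numeric(sample(names(pr), n_events, replace = TRUE, prob = pr))
  size <- stats::rlnorm(n_events, model$size_meanlog, model$size_sdlog)
  eff <- pmax(copies, model$background)
  fl1 <- eff * model$gain * size * .lnoise(n_events, model$cv)
  fsc_a <- size * .lnoise(n_events, model$fsc_cv)
  fsc_h <- fsc_a * .lnoise(n_events, model$fsch_cv)
  ssc_a <- 0.5 * size * .lnoise(n_events, 0.2)

  is_doublet <- stats::runif(n_events) < model$doublet_fraction
  fl1[is_doublet] <- 2 * fl1[is_doublet]
  fsc_a[is_doublet] <- 2 * fsc_a[is_doublet]
  ssc_a[is_doublet] <- 2 * ssc_a[is_doublet]

  is_debris <- !is_doublet & stats::runif(n_events) < model$debris_fraction
  shrink <- 0.005 * .lnoise(sum(is_debris), 0.5)
  fsc_a[is_debris] <- fsc_a[is_debris] * shrink
  fsc_h[is_debris] <- fsc_h[is_debris] * shrink
  ssc_a[is_debris] <- ssc_a[is_debris] * shrink
  fl1[is_debris] <- fl1[is_debris] * shrink

  events <- data.frame(fsc_a, fsc_h, ssc_a, fl1)
  names(events) <- c("FSC-A", "FSC-H", "SSC-A", "FL1-A")
  attr(events, "truth") <- data.frame(copies = copies,
                                      is_doublet = is_doublet,
                                      is_debris = is_debris)
  structure(list(population = population, generation = generation,
                 events = events),
            class = "flow_sample")
}

#' @export
print.flow_sample <- function(x, ...) {
  cat(sprintf("flow_sample: population=%s generation=%s, %d events\n",
              x$population, x$generation, nrow(x$events)))
  invisible(x)
}

#' Write/read flow events as CSV
#'
#' Columns `FSC-A`, `FSC-H`, `SSC-A`, `FL1-A`, one row per event.
#' @param sample a `flow_sample`.
#' @param path CSV file path.
#' @export
write_flow_csv <- function(sample, path) {
  utils::write.csv(sample$events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_csv
#' @param population,generation identifiers for the sample being read.
#' @export
read_flow_csv <- function(path, population = NA, generation = NA) {
  ev <- utils::read.csv(path, check.names = FALSE)
  need <- c("FSC-A", "FSC-H", "SSC-A", "FL1-A")
  if (!all(need %in% names(ev)))
    stop("flow CSV must have columns ", paste(need, collapse = ", "))
  structure(list(population = population, generation = generation,
                 events = ev[need]),
            class = "flow_sample")
}
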