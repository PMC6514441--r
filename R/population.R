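# Synthetic-population generator and correlation statistics. The generator
# emulates the heterogeneity of the recorded sample: log-normal maximal
# conductances (positive, right-skewed) and truncated-normal capacitance, with
# defaults chosen so the resulting input resistances span roughly 250-2300
# MOhm around a ~1 GOhm centre, the time constants tens to hundreds of ms, and
# the capacitances ~50-160 pF.

#' Specification of a synthetic tSPN population
#'
#' @param n number of cells.
#' @param seed integer seed governing all sampling.
#' @param leak log-normal parameters (meanlog, sdlog) for the leak conductance
#'   (nS); the dominant axis of input-resistance heterogeneity.
#' @param scales named list of log-normal (meanlog, sdlog) parameters for the
#'   other maximal conductances (nS).
#' @param c_m normal parameters (mean, sd) for the capacitance (pF), truncated
#'   to \code{c_m_range}.
#' @param c_m_range allowed capacitance range (pF).
#' @return a \code{tspn_population_spec}.
#' @export
population_spec <- function(n = 30, seed = 1,
                            leak = c(meanlog = log(0.32), sdlog = 0.85),
                            scales = list(
                              Na  = c(meanlog = log(300),  sdlog = 0.3),
                              Kd  = c(meanlog = log(2000), sdlog = 0.3),
                              M   = c(meanlog = log(30),   sdlog = 0.5),
                              KCa = c(meanlog = log(50),   sdlog = 0.5),
                              A   = c(meanlog = log(50),   sdlog = 0.5),
                              H   = c(meanlog = log(0.7),  sdlog = 0.7),
                              CaL = c(meanlog = log(1.2),  sdlog = 0.3)),
                            c_m = c(mean = 89, sd = 27),
                            c_m_range = c(51, 157)) {
  structure(list(n = n, seed = seed, leak = leak, scales = scales,
                 c_m = c_m, c_m_range = c_m_range),
            class = "tspn_population_spec")
}

#' Sample a synthetic population of model cells
#'
#' Draws \code{spec$n} parameter sets, rejecting cells that are not quiescent
#' and stable at rest (non-finite integration or spontaneous spiking with zero
#' input); sampling is reproducible given the seed.
#'
#' @param spec a \code{tspn_population_spec}.
#' @param max_tries rejection-resampling cap per cell.
#' @return list of \code{tspn_neuron} objects.
#' @export
sample_population <- function(spec = population_spec(), max_tries = 10) {
  set.seed(spec$seed)
  out <- vector("list", spec$n)
  if (spec$n == 0) return(out)
  rtrunc_norm <- function(mean, sd, range) {
    for (i in 1:100) {
      x <- rnorm(1, mean, sd)
      if (x >= range[1] && x <= range[2]) return(x)
    }
    mean
  }
  for (i in seq_len(spec$n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      g <- c(leak = rlnorm(1, spec$leak[["meanlog"]], spec$leak[["sdlog"]]),
             vapply(spec$scales, function(s)
               rlnorm(1, s[["meanlog"]], s[["sdlog"]]), numeric(1)))
      cm <- rtrunc_norm(spec$c_m[["mean"]], spec$c_m[["sd"]], spec$c_m_range)
      cell <- tspn_neuron(g = g, c_m = cm)
      tr <- tryCatch(tspn_integrate(cell, rep(0, 10000),
                                    init = steady_state_init(cell, -60)),
                     error = function(e) NULL)
      if (!is.null(tr) && all(is.finite(tr$v)) &&
          length(detect_spikes(tr)) == 0) { ok <- TRUE; break }
    }
    if (!ok) stop("could not sample a viable cell within max_tries")
    out[[i]] <- cell
  }
  out
}

#' Sidak-corrected per-comparison significance level
#'
#' \eqn{\alpha' = 1 - (1 - \alpha)^{1/m}}; for \eqn{\alpha = 0.05} and 30
#' comparisons this gives 0.0017.
#'
#' @param alpha experiment-wise error rate.
#' @param m number of comparisons.
#' @export
sidak_alpha <- function(alpha = 0.05, m = 30) 1 - (1 - alpha)^(1 / m)

#' Pairwise Pearson correlations with Sidak-corrected significance
#'
#' For each requested pair of columns: Pearson's r on pairwise-complete
#' observations, the two-tailed p value from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom, and a
#' significance flag at the Sidak-corrected level
#' \code{sidak_alpha(alpha, m)}. Pairs with fewer than 3 complete
#' observations or zero variance yield NA with a
#' \code{tspn_undefined_correlation} warning.
#'
#' @param data data.frame of per-cell features.
#' @param pairs list of length-2 character vectors naming column pairs.
#' @param alpha experiment-wise error rate.
#' @param m number of comparisons used for the correction (default:
#'   \code{length(pairs)}).
#' @return a \code{tspn_correlations} data.frame with columns \code{x},
#'   \code{y}, \code{r}, \code{r2}, \code{n}, \code{p}, \code{significant};
#'   the corrected alpha is attached as attribute \code{alpha_corrected}.
#' @export
correlate <- function(data, pairs, alpha = 0.05, m = length(pairs)) {
  a_corr <- sidak_alpha(alpha, m)
  rows <- lapply(pairs, function(pr) {
    x <- data[[pr[1]]]; y <- data[[pr[2]]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3 || var(x[ok]) == 0 || var(y[ok]) == 0) {
      warning(warningCondition(
        sprintf("correlation undefined for (%s, %s)", pr[1], pr[2]),
        class = "tspn_undefined_correlation"))
      return(data.frame(x = pr[1], y = pr[2], r = NA_real_, r2 = NA_real_,
                        n = n, p = NA_real_, significant = NA))
    }
    r <- stats::cor(x[ok], y[ok])
    p <- if (abs(r) >= 1) 0 else {
      t <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(-abs(t), df = n - 2)
    }
    data.frame(x = pr[1], y = pr[2], r = r, r2 = r^2, n = n, p = p,
               significant = p < a_corr)
  })
  structure(do.call(rbind, rows), alpha_corrected = a_corr,
            class = c("tspn_correlations", "data.frame"))
}

#' @export
print.tspn_correlations <- function(x, ...) {
  cat(sprintf("Pearson correlations (Sidak-corrected alpha = %.2g)\n",
              attr(x, "alpha_corrected")))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
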