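#' Genetic-algorithm hyperparameters for sub-ensemble selection
#'
#' @param population_size Chromosomes per generation (default 100).
#' @param generations Maximum generations (default 1000; runs stop earlier on
#'   convergence).
#' @param elite_fraction Fraction of best chromosomes copied unchanged
#'   (default 0.1), which makes the best chi-square non-increasing.
#' @param mutation_rate Per-gene probability of mutating to a uniformly
#'   random pool index (default 0.1).
#' @param tournament_size Parents are the best of this many random picks
#'   (default 2).
#' @param n_repeats Independent GA runs; the best result is kept (default 10).
#' @param convergence_tol Stop a run when the best chi-square improves by
#'   less than this over `convergence_window` generations (default 1e-4).
#' @param convergence_window Generations over which improvement is measured
#'   (default 50).
#' @param seed Integer seed; each repeat uses a derived substream.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 100L, generations = 1000L,
                      elite_fraction = 0.1, mutation_rate = 0.1,
                      tournament_size = 2L, n_repeats = 10L,
                      convergence_tol = 1e-4, convergence_window = 50L,
                      seed = 1L) {
  if (elite_fraction <= 0 || elite_fraction >= 1)
    stop("elite_fraction must be in (0, 1)")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must be in [0, 1]")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 elite_fraction = elite_fraction,
                 mutation_rate = mutation_rate,
                 tournament_size = as.integer(tournament_size),
                 n_repeats = as.integer(n_repeats),
                 convergence_tol = convergence_tol,
                 convergence_window = as.integer(convergence_window),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Average theoretical curve of a sub-ensemble
#'
#' Unweighted mean of the member curves; repeated indices count multiply,
#' which is how member weighting is realized.
#'
#' @param pool A `conformer_pool` with cached curves (see
#'   [precompute_curves()]).
#' @param members Integer vector of pool indices (repetition allowed) or an
#'   `ensemble` object.
#' @return A `scattering_curve` on the pool's cached grid.
#' @export
ensemble_average_curve <- function(pool, members) {
  if (is.null(pool$curves))
    stop("pool has no cached curves; run precompute_curves() first")
  idx <- if (inherits(members, "ensemble")) members$member_indices else
    as.integer(members)
  if (!length(idx) || any(idx < 1L | idx > ncol(pool$curves)))
    stop("member indices out of range for the pool")
  scattering_curve(pool$q, rowMeans(pool$curves[, idx, drop = FALSE]),
                   label = sprintf("ensemble mean (M=%d)", length(idx)))
}

# Vectorized fitness: reduced chi2 for each column of a count matrix
# (n_pool x P). Returns a numeric vector of length P.
ensemble_chi2_batch <- function(curves, counts, M, Ie, s2, denom) {
  avg <- (curves %*% counts) / M
  num <- colSums(avg * Ie / s2)
  den <- colSums(avg^2 / s2)
  mu <- num / den
  # chi2 = sum(((mu*avg - Ie)/sigma)^2) / denom
  chi <- sum(Ie^2 / s2) - mu^2 * den
  pmax(chi, 0) / denom
}

pop_counts <- function(pop, n_pool) {
  vapply(seq_len(ncol(pop)), function(j) tabulate(pop[, j], n_pool),
         integer(n_pool))
}

#' Select the best-fitting sub-ensemble by a genetic algorithm
#'
#' Chromosomes are multisets of `M` pool indices (repetition allowed);
#' fitness is the reduced chi-square of the ensemble-average curve against
#' the data. Each generation keeps the elite fraction unchanged, fills the
#' rest by tournament selection, single-point crossover and per-gene
#' mutation to a random pool index. The best chromosome across
#' `n_repeats` independent runs is returned; ties are broken towards the
#' lexicographically smallest sorted index multiset.
#'
#' @param pool A `conformer_pool` with curves cached on the data grid.
#' @param data_curve Data `scattering_curve` with `sigma`.
#' @param M Ensemble size (default 50, the canonical selected-ensemble size).
#' @param config A [ga_config()].
#' @param dof Degrees-of-freedom convention for chi-square.
#' @return An object of class `ensemble` with sorted `member_indices`, the
#'   `fit` (a `fit_result`), `generation_found`, and the per-generation best
#'   chi-square `trace` of the winning run.
#' @export
ga_select <- function(pool, data_curve, M = 50L, config = ga_config(),
                      dof = c("K-1", "K")) {
  dof <- match.arg(dof)
  if (is.null(pool$curves))
    stop("pool has no cached curves; run precompute_curves() first")
  if (!length(pool$conformers)) stop("empty pool")
  if (!same_grid(list(q = pool$q), data_curve))
    stop("pool curves are cached on a different grid than the data")
  if (is.null(data_curve$sigma)) stop("data curve needs sigma")
  n_pool <- ncol(pool$curves)
  M <- as.integer(M)
  Ie <- data_curve$intensity; s2 <- data_curve$sigma^2
  K <- length(Ie)
  denom <- if (dof == "K-1") K - 1L else K
  P <- config$population_size
  n_elite <- max(1L, ceiling(config$elite_fraction * P))

  run_once <- function() {
    pop <- matrix(sample.int(n_pool, M * P, replace = TRUE), M, P)
    best_chi <- Inf; best_idx <- NULL; best_gen <- 0L
    trace <- numeric(0)
    for (gen in seq_len(config$generations)) {
      fit <- ensemble_chi2_batch(pool$curves, pop_counts(pop, n_pool),
                                 M, Ie, s2, denom)
      ord <- order(fit)
      if (fit[ord[1L]] < best_chi - 1e-15) {
        best_chi <- fit[ord[1L]]
        best_idx <- sort(pop[, ord[1L]])
        best_gen <- gen
      }
      trace <- c(trace, best_chi)
      w <- config$convergence_window
      if (gen > w && trace[gen - w] - best_chi < config$convergence_tol)
        break
      elite <- pop[, ord[seq_len(n_elite)], drop = FALSE]
      n_new <- P - n_elite
      # tournament parent picks (ranked: lower chi2 wins)
      pick_parent <- function(k) {
        cand <- sample.int(P, config$tournament_size * k, replace = TRUE)
        cand <- matrix(cand, nrow = config$tournament_size)
        cand[apply(matrix(fit[cand], nrow = config$tournament_size), 2L,
                   which.min) + (seq_len(k) - 1L) * config$tournament_size]
      }
      p1 <- pick_parent(n_new); p2 <- pick_parent(n_new)
      cut <- sample.int(M - 1L, n_new, replace = TRUE)
      children <- vapply(seq_len(n_new), function(i)
        c(pop[seq_len(cut[i]), p1[i]], pop[(cut[i] + 1L):M, p2[i]]),
        integer(M))
      mut <- matrix(stats::runif(M * n_new) < config$mutation_rate, M, n_new)
      children[mut] <- sample.int(n_pool, sum(mut), replace = TRUE)
      pop <- cbind(elite, children)
    }
    list(chi = best_chi, idx = best_idx, gen = best_gen, trace = trace)
  }

  best <- NULL
  for (r in seq_len(config$n_repeats)) {
    res <- with_seed(derive_seed(config$seed, r, salt = 7L), run_once())
    if (is.null(best) || res$chi < best$chi ||
        (res$chi == best$chi && lex_less(res$idx, best$idx)))
      best <- res
  }
  fit <- chi_squared(ensemble_average_curve(pool, best$idx),
                     data_curve, dof = dof,
                     model_label = sprintf("selected ensemble (M=%d)", M))
  structure(list(member_indices = best$idx, fit = fit,
                 generation_found = best$gen, trace = best$trace),
            class = "ensemble")
}

lex_less <- function(a, b) {
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf(
    "<ensemble> M = %d (from %d distinct conformers), chi2 = %.3f, found at generation %d\n",
    length(x$member_indices), length(unique(x$member_indices)),
    x$fit$chi2, x$generation_found))
  invisible(x)
}

#' Root-mean-square average of radii of gyration
#'
#' The ensemble-averaged Rg convention for pools and selected ensembles:
#' sqrt(mean(Rg^2)). By Jensen's inequality it is never below the arithmetic
#' mean.
#'
#' @param rg_values Non-negative Rg values in Angstrom.
#' @export
ensemble_rg_rms <- function(rg_values) {
  if (!length(rg_values)) stop("empty Rg list")
  if (any(rg_values < 0)) stop("Rg values must be non-negative")
  sqrt(mean(rg_values^2))
}

# Gaussian-kernel smoothing of binned masses (sd in bins).
smooth_hist <- function(mass, bandwidth = 2) {
  if (bandwidth <= 0) return(mass)
  k <- stats::dnorm(seq(-ceiling(4 * bandwidth), ceiling(4 * bandwidth)),
                    sd = bandwidth)
  k <- k / sum(k)
  n <- length(mass)
  pad <- length(k) %/% 2L
  padded <- c(rep(0, pad), mass, rep(0, pad))
  out <- stats::filter(padded, k, sides = 2L)[(pad + 1L):(pad + n)]
  as.numeric(out)
}

# Local maxima of a smoothed mass vector above `floor_frac` of the global
# max; returns peak positions and basin masses (split at interior minima).
# Adjacent maxima whose intervening valley is shallower than `floor_frac` of
# the global maximum are merged into one peak (topographic prominence), so a
# flat-topped histogram does not split on floating-point jitter.
find_peaks <- function(mass, floor_frac = 0.05) {
  n <- length(mass)
  if (n < 3L) return(list(peaks = which.max(mass), masses = sum(mass)))
  is_peak <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) mass[i - 1L] else -Inf
    right <- if (i < n) mass[i + 1L] else -Inf
    mass[i] > left && mass[i] >= right
  }, TRUE)
  peaks <- which(is_peak & mass >= floor_frac * max(mass))
  if (!length(peaks)) peaks <- which.max(mass)
  prom <- floor_frac * max(mass)
  while (length(peaks) > 1L) {
    valleys <- vapply(seq_len(length(peaks) - 1L), function(j)
      min(mass[peaks[j]:peaks[j + 1L]]), 0)
    depth <- pmin(mass[peaks[-length(peaks)]], mass[peaks[-1L]]) - valleys
    j <- which.min(depth)
    if (depth[j] >= prom) break
    drop <- if (mass[peaks[j]] <= mass[peaks[j + 1L]]) j else j + 1L
    peaks <- peaks[-drop]
  }
  if (length(peaks) == 1L) return(list(peaks = peaks, masses = sum(mass)))
  # basin boundaries at the minimum between consecutive peaks
  bounds <- vapply(seq_len(length(peaks) - 1L), function(j) {
    seg <- peaks[j]:peaks[j + 1L]
    seg[which.min(mass[seg])]
  }, 0L)
  lo <- c(1L, bounds + 1L); hi <- c(bounds, n)
  masses <- vapply(seq_along(peaks), function(j) sum(mass[lo[j]:hi[j]]), 0)
  list(peaks = peaks, masses = masses)
}

#' Pool-versus-selected descriptor distributions
#'
#' Normalized histograms of Rg, Dmax and end-to-end distance for the random
#' pool and the selected ensemble on shared binning, plus RMS-averaged Rg for
#' both, and peak detection on the kernel-smoothed selected-Rg histogram
#' (local maxima above 5% of the global maximum). When at least two peaks
#' are found, `peak_ratio` is the mass of the largest peak basin over the
#' second largest — the compact-versus-extended population read-out.
#'
#' @param pool A `conformer_pool`.
#' @param ensemble An `ensemble` (or integer member indices).
#' @param n_bins Number of shared bins (default 40).
#' @param smooth_bandwidth Gaussian smoothing bandwidth in bins (default 2).
#' @return An object of class `distribution_summary`.
#' @export
summarize_distributions <- function(pool, ensemble, n_bins = 40L,
                                    smooth_bandwidth = 2) {
  idx <- if (inherits(ensemble, "ensemble")) ensemble$member_indices else
    as.integer(ensemble)
  d <- pool_descriptors(pool)
  sel <- d[idx, ]
  hist_pair <- function(vp, vs) {
    rng <- range(c(vp, vs))
    if (diff(rng) < 1e-9) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
    hp <- hist(vp, breaks = breaks, plot = FALSE)$counts
    hs <- hist(vs, breaks = breaks, plot = FALSE)$counts
    list(breaks = breaks, pool = hp / sum(hp), selected = hs / sum(hs))
  }
  rg_h <- hist_pair(d$rg, sel$rg)
  dmax_h <- hist_pair(d$dmax, sel$dmax)
  e2e_h <- hist_pair(d$end_to_end, sel$end_to_end)
  sm <- smooth_hist(rg_h$selected, smooth_bandwidth)
  pk <- find_peaks(sm)
  peak_ratio <- NA_real_
  if (length(pk$peaks) >= 2L) {
    m <- sort(pk$masses, decreasing = TRUE)
    peak_ratio <- m[1L] / m[2L]
  }
  structure(list(
    rg_hist = rg_h, dmax_hist = dmax_h, end_to_end_hist = e2e_h,
    rg_rms_pool = ensemble_rg_rms(d$rg),
    rg_rms_selected = ensemble_rg_rms(sel$rg),
    peak_count_selected = length(pk$peaks),
    peak_positions = (rg_h$breaks[pk$peaks] + rg_h$breaks[pk$peaks + 1L]) / 2,
    peak_masses = pk$masses,
    peak_ratio = peak_ratio,
    selected_indices = idx),
    class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf(
    "<distribution_summary> Rg RMS pool %.1f A, selected %.1f A; %d selected-Rg peak(s)%s\n",
    x$rg_rms_pool, x$rg_rms_selected, x$peak_count_selected,
    if (is.na(x$peak_ratio)) "" else sprintf(", peak mass ratio %.1f",
                                             x$peak_ratio)))
  invisible(x)
}

#' Shape-class fractions of a pool or sub-ensemble
#'
#' Fractions of L (bent), U (folded back) and I (extended) conformers, from
#' the hinge arm angle (I above 120 degrees, L 60--120, U below 60).
#'
#' @param pool A `conformer_pool` whose conformers carry arm angles.
#' @param indices Optional member indices (repetition counts multiply);
#'   default all pool members.
#' @return Named numeric vector over `c("L", "U", "I")` summing to 1.
#' @export
classify_shapes <- function(pool, indices = NULL) {
  d <- pool_descriptors(pool)
  if (!is.null(indices)) {
    if (inherits(indices, "ensemble")) indices <- indices$member_indices
    d <- d[indices, ]
  }
  if (anyNA(d$shape_class))
    stop("shape class undefined (topology has fewer than two rigid arms)")
  tab <- table(factor(d$shape_class, levels = c("L", "U", "I")))
  fr <- as.numeric(tab) / sum(tab)
  names(fr) <- c("L", "U", "I")
  fr
}
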