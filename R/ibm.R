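#' Configuration of the individual-based model
#'
#' The individual-based model (IBM) implements the same density dependence
#' as the deterministic maps, but with per-individual strategies \eqn{b_i}
#' and stochastic reproduction: in every generation each individual is
#' replaced by a Poisson-distributed number of offspring with mean
#' \eqn{f(N_t; b_i)}, where \eqn{N_t} is the current total population size.
#' Generations do not overlap. Before reproduction, each individual mutates
#' with probability \eqn{m/K} (so \eqn{m} is the expected number of
#' mutations per generation at carrying capacity): a Gaussian step with
#' standard deviation \code{sigma} is added to its strategy, clipped from
#' below at \code{b_min}, a technical floor that keeps density dependence
#' meaningful.
#'
#' @param model,r,K,d the growth law, as in [growth_params()].
#' @param m mutation intensity; per-individual mutation probability is
#'   \code{m / K}.
#' @param sigma mutation step standard deviation (default 0.1).
#' @param b_min strategy floor (default 0.17).
#' @param mod optional [tradeoff_mod()].
#' @param seed optional integer; when set, stochastic routines seed the RNG
#'   with it before running, making results fully reproducible.
#' @return An object of class \code{"ibm_config"}.
#' @examples
#' cfg <- ibm_config("mss", r = 5, K = 200, d = 0.05)
#' @export
ibm_config <- function(model = "mss", r = 5, K = 1000, d = 0.05,
                       m = 0, sigma = 0.1, b_min = 0.17, mod = NULL,
                       seed = NULL) {
  base <- growth_params(model, r = r, K = K, b = 1, d = d)
  stopifnot(m >= 0, m / K <= 1, sigma > 0, b_min > 0,
            is.null(mod) || inherits(mod, "tradeoff_mod"),
            is.null(seed) || (is.numeric(seed) && length(seed) == 1L))
  structure(list(base = base, mod = mod, m = m, sigma = sigma,
                 b_min = b_min, seed = seed),
            class = "ibm_config")
}

#' @export
print.ibm_config <- function(x, ...) {
  cat(sprintf(
    "<ibm_config> %s: r = %g, K = %g, d = %g, m = %g, sigma = %g, b_min = %g%s\n",
    x$base$model, x$base$r, x$base$K, x$base$d, x$m, x$sigma, x$b_min,
    if (is.null(x$mod) || !x$mod$enabled) "" else " [modified trade-off]"))
  invisible(x)
}

#' Named parameter presets for the simulation experiments
#'
#' \code{"invasion"} uses a small population (K = 200) where demographic
#' stochasticity is strong; \code{"evolution_fast"} uses K = 1000 with a
#' high mutation supply (m = 0.3); \code{"evolution"} uses K = 1000 with
#' m = 0.1; \code{"branching"} is \code{"evolution"} with the trade-off
#' modification enabled.
#'
#' @param name preset name.
#' @return an [ibm_config()].
#' @export
ibm_preset <- function(name = c("invasion", "evolution_fast", "evolution",
                                "branching")) {
  name <- match.arg(name)
  switch(name,
    invasion       = ibm_config("mss", r = 5, K = 200, d = 0.05, m = 0),
    evolution_fast = ibm_config("mss", r = 5, K = 1000, d = 0.05, m = 0.3),
    evolution      = ibm_config("mss", r = 5, K = 1000, d = 0.05, m = 0.1),
    branching      = ibm_config("mss", r = 5, K = 1000, d = 0.05, m = 0.1,
                                mod = tradeoff_mod()))
}

ibm_cpp_args <- function(cfg) {
  b <- cfg$base
  model_code <- match(b$model, c("mss", "ricker", "hassell")) - 1L
  mod <- cfg$mod
  enabled <- !is.null(mod) && mod$enabled
  if (enabled && !is.null(mod$map))
    stop("the individual-based simulator supports only the default ",
         "power-law trade-off mapping")
  list(model = model_code, r = b$r, K = b$K, d = b$d,
       mod_enabled = enabled,
       b_low = if (enabled) mod$b_low else 0,
       b_up = if (enabled) mod$b_up else 0,
       lambda = if (enabled) mod$scaling else 1)
}

maybe_seed <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  invisible(NULL)
}

#' One generation of the individual-based model (reference implementation)
#'
#' Pure-R single step: mutation first (probability \eqn{m/K} per
#' individual, Gaussian step, clipped at \code{b_min}), then every
#' individual is replaced by \eqn{Poisson(f(N_t; b_i))} offspring carrying
#' its post-mutation strategy, with \eqn{N_t} the pre-reproduction
#' population size. Draws random numbers in the same order as the compiled
#' simulator, so a single step from the same seed is bit-identical to
#' [run_ibm()]. Mainly useful for inspection and testing; long runs should
#' use [run_ibm()].
#'
#' @param strategies numeric vector of per-individual strategies \eqn{b_i};
#'   an empty vector is the (absorbing) extinct state.
#' @param cfg an [ibm_config()] (its \code{seed} is ignored here).
#' @return the next generation's strategy vector.
#' @export
ibm_step <- function(strategies, cfg) {
  n <- length(strategies)
  if (n == 0L) return(numeric(0))
  if (cfg$m > 0) {
    mut <- stats::runif(n) < cfg$m / cfg$base$K
    if (any(mut)) {
      step <- stats::rnorm(sum(mut), 0, cfg$sigma)
      strategies[mut] <- pmax(cfg$b_min, strategies[mut] + step)
    }
  }
  b <- cfg$base
  ratios <- vapply(strategies, function(bi) {
    p <- b; p$b <- bi
    reproduction_ratio(p, n, cfg$mod)
  }, numeric(1))
  n_off <- stats::rpois(n, ratios)
  rep(strategies, n_off)
}

#' Run the individual-based model
#'
#' Evolves a population of individually varying strategies for a number of
#' generations, recording population size and strategy summaries at
#' checkpoints and full strategy snapshots (histograms) where requested.
#' Identical seeds reproduce identical runs bit for bit.
#'
#' @param init initial strategies: a numeric vector (one entry per
#'   individual), or \code{NULL} for the default initialization of
#'   \code{K} individuals with strategies drawn uniformly from
#'   \code{[b_min, 15]}.
#' @param cfg an [ibm_config()].
#' @param generations number of generations to simulate.
#' @param record_every spacing of summary checkpoints (generation 0 and the
#'   final generation are always recorded).
#' @param hist_at generations at which to keep the full strategy vector
#'   (default: the final generation).
#' @param evolution_start generation from which mutation acts (default 0);
#'   lets a run begin with fixed strategies and switch evolution on later.
#' @return An object of class \code{"evolution_record"}: list with
#'   \code{record} (data.frame of checkpointed summaries),
#'   \code{histograms} (named list of strategy vectors), \code{final_b},
#'   \code{cfg}, \code{generations}.
#' @examples
#' cfg <- ibm_config("mss", r = 5, K = 100, d = 0.05, m = 0.3, seed = 1)
#' rec <- run_ibm(NULL, cfg, generations = 200, record_every = 50)
#' rec$record
#' @export
run_ibm <- function(init = NULL, cfg, generations, record_every = 100,
                    hist_at = generations, evolution_start = 0) {
  stopifnot(inherits(cfg, "ibm_config"), generations >= 1)
  maybe_seed(cfg)
  if (is.null(init))
    init <- stats::runif(cfg$base$K, cfg$b_min, 15)
  record_at <- unique(c(seq(0, generations, by = record_every), generations))
  a <- ibm_cpp_args(cfg)
  res <- cpp_ibm_run(init, a$model, a$r, a$K, a$d, a$mod_enabled,
                     a$b_low, a$b_up, a$lambda, cfg$m, cfg$sigma,
                     cfg$b_min, as.integer(generations),
                     as.integer(evolution_start),
                     as.integer(record_at), as.integer(hist_at))
  structure(list(record = res$record, histograms = res$histograms,
                 final_b = res$final_b, cfg = cfg,
                 generations = generations),
            class = "evolution_record")
}

#' @export
print.evolution_record <- function(x, ...) {
  last <- x$record[nrow(x$record), ]
  cat(sprintf(
    "<evolution_record> %d generations, %d checkpoints; final N = %d%s\n",
    x$generations, nrow(x$record), as.integer(last$N),
    if (last$N > 0) sprintf(", mean b = %.3f", last$mean_b) else " (extinct)"))
  invisible(x)
}

two_type_run <- function(b1, b2, n1, n2, cfg, max_gen) {
  a <- ibm_cpp_args(cfg)
  cpp_two_type_sim(b1, b2, n1, n2, a$model, a$r, a$K, a$d,
                   a$mod_enabled, a$b_low, a$b_up, a$lambda, max_gen)
}

#' Invasion probability in the individual-based model
#'
#' Estimates the probability \eqn{p} that a strategy invading a resident
#' population with a single individual survives for at least
#' \code{horizon} generations. Because single-propagule survival is rare,
#' the default estimator simulates invasions with three individuals,
#' giving the three-propagule extinction probability \eqn{q^{(3)}}; under
#' approximate independence of the propagules' fates (most extinctions
#' happen quickly after introduction), the one-propagule extinction
#' probability is \eqn{q = (q^{(3)})^{1/3}} and \eqn{p = 1 - q}. Setting
#' \code{propagules = 1} estimates \eqn{p} directly, which is the
#' independent check on the cube-root shortcut.
#'
#' Each replicate burns in the resident alone from its deterministic
#' equilibrium (mutation off), adds a uniformly random 0-49 extra
#' generations so invaders arrive at a random phase of the resident's
#' stochastic attractor, then introduces the invaders.
#'
#' @param b_res,b_inv resident and invader strategies.
#' @param cfg an [ibm_config()]; its mutation intensity is forced to zero
#'   for this experiment.
#' @param n_reps number of replicate invasions.
#' @param horizon survival horizon in generations (default 500).
#' @param burn_in resident-only generations before the invasion.
#' @param propagules number of invading individuals (3 = cube-root
#'   estimator, 1 = direct estimation).
#' @return An object of class \code{"invasion_estimate"}: list with
#'   \code{p}, \code{q}, \code{q_ext} (observed extinction fraction),
#'   \code{se_p}, \code{n_reps}, \code{horizon}, \code{propagules},
#'   \code{flagged} (TRUE when the resident itself died during burn-in in
#'   some replicates; those replicates are discarded).
#' @export
invasion_probability <- function(b_res, b_inv, cfg, n_reps = 100,
                                 horizon = 500, burn_in = 200,
                                 propagules = 3) {
  stopifnot(inherits(cfg, "ibm_config"), n_reps >= 1,
            propagules %in% c(1, 3))
  cfg$m <- 0
  maybe_seed(cfg)
  a <- ibm_cpp_args(cfg)
  p_res <- cfg$base; p_res$b <- b_res
  n_eq <- tryCatch(round(equilibrium_density(p_res, cfg$mod)),
                   error = function(e) NA_real_)
  if (is.na(n_eq) || n_eq < 1)
    stop("resident strategy is not viable at these parameters")
  extinct <- 0L; ok <- 0L; failed_burnin <- 0L
  for (i in seq_len(n_reps)) {
    phase <- sample.int(50, 1) - 1L
    nres <- cpp_single_sim(b_res, n_eq, a$model, a$r, a$K, a$d,
                           a$mod_enabled, a$b_low, a$b_up,
                           a$lambda, burn_in + phase)
    if (nres <= 0) { failed_burnin <- failed_burnin + 1L; next }
    run <- two_type_run(b_res, b_inv, nres, propagules, cfg, horizon)
    ok <- ok + 1L
    if (run$n2 <= 0) extinct <- extinct + 1L
  }
  if (ok == 0)
    stop("resident went extinct during burn-in in every replicate")
  q_ext <- extinct / ok
  se_ext <- sqrt(q_ext * (1 - q_ext) / ok)
  if (propagules == 3) {
    q <- q_ext^(1 / 3)
    se_p <- if (q_ext > 0) se_ext / (3 * q_ext^(2 / 3)) else se_ext / 3
  } else {
    q <- q_ext
    se_p <- se_ext
  }
  structure(list(p = 1 - q, q = q, q_ext = q_ext, se_p = se_p,
                 n_reps = ok, horizon = horizon, propagules = propagules,
                 flagged = failed_burnin > 0L,
                 failed_burnin = failed_burnin,
                 b_res = b_res, b_inv = b_inv),
            class = "invasion_estimate")
}

#' @export
print.invasion_estimate <- function(x, ...) {
  cat(sprintf(
    "<invasion_estimate> b_res = %g <- b_inv = %g: p = %.4f (se %.4f, %d reps, %d propagules)%s\n",
    x$b_res, x$b_inv, x$p, x$se_p, x$n_reps, x$propagules,
    if (x$flagged) sprintf(" [%d burn-in failures]", x$failed_burnin) else ""))
  invisible(x)
}

#' Time to competitive exclusion of two fixed strategies
#'
#' Starts two strategies at equal population sizes (\code{floor(K/2)} each,
#' mutation off) and simulates until one of them has no individuals left,
#' or until \code{max_gen} (censored). Along the diagonal
#' \eqn{b_1 = b_2} the two labels are exchangeable and exclusion happens by
#' neutral drift, which provides the reference timescale; strategy pairs
#' stabilized by relative nonlinearity persist orders of magnitude longer.
#'
#' @param b1,b2 the two strategies.
#' @param cfg an [ibm_config()]; mutation is forced off.
#' @param max_gen censoring cap in generations.
#' @param n_reps replicates.
#' @return An object of class \code{"exclusion_summary"}: list with the
#'   per-replicate \code{times}, \code{winners} (1, 2 or 0 for
#'   none/censored), \code{censored} flags, and summary fields
#'   \code{mean_time}, \code{mean_log10_time}, \code{median_time},
#'   \code{censored_fraction}, \code{typical_winner}. Censored replicates
#'   enter the summaries at the cap, so with censoring the reported times
#'   are lower bounds.
#' @export
coexistence_time <- function(b1, b2, cfg, max_gen = 1e7, n_reps = 20) {
  stopifnot(inherits(cfg, "ibm_config"), n_reps >= 1)
  cfg$m <- 0
  maybe_seed(cfg)
  n0 <- floor(cfg$base$K / 2)
  times <- numeric(n_reps); winners <- integer(n_reps)
  censored <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    run <- two_type_run(b1, b2, n0, n0, cfg, max_gen)
    times[i] <- run$time
    winners[i] <- run$winner
    censored[i] <- run$censored
  }
  wins <- table(factor(winners, levels = 0:2))
  typical <- c("none", "b1", "b2")[which.max(wins)]
  structure(list(b1 = b1, b2 = b2, times = times, winners = winners,
                 censored = censored,
                 mean_time = mean(times),
                 mean_log10_time = mean(log10(pmax(times, 1))),
                 median_time = stats::median(times),
                 censored_fraction = mean(censored),
                 typical_winner = typical,
                 n_reps = n_reps, max_gen = max_gen),
            class = "exclusion_summary")
}

#' @export
print.exclusion_summary <- function(x, ...) {
  cat(sprintf(
    "<exclusion_summary> b1 = %g vs b2 = %g: mean log10 time = %.2f (%d reps, %.0f%% censored at %g), typical winner: %s\n",
    x$b1, x$b2, x$mean_log10_time, x$n_reps, 100 * x$censored_fraction,
    x$max_gen, x$typical_winner))
  invisible(x)
}

#' Long-run evolutionary dynamics to the strategy attractor
#'
#' Runs the IBM with mutation switched on, starting (by default) from
#' \code{K} individuals with strategies drawn uniformly from
#' \code{[b_min, 15]}, and summarizes the post-transient strategy
#' distribution. Convergence is diagnosed by comparing windowed means of
#' the population mean strategy: the run is flagged converged when the
#' last two windows differ by less than \code{tol}.
#'
#' @inheritParams run_ibm
#' @param generations total generations (the published experiments use
#'   1e6; scaled-down runs are supported and used by the test-suite).
#' @param window width (in generations) of the convergence window.
#' @param tol tolerance on the drift of the windowed mean strategy.
#' @return an \code{"evolution_record"} (see [run_ibm()]) with extra
#'   fields \code{converged}, \code{evolved_mean_b} (mean strategy over
#'   the last window; \code{NA} if extinct) and \code{extinct}.
#' @export
evolve_to_equilibrium <- function(cfg, generations = 1e6, init = NULL,
                                  record_every = max(1, generations %/% 1000),
                                  window = max(record_every,
                                               generations %/% 10),
                                  tol = 0.25, hist_at = generations) {
  stopifnot(inherits(cfg, "ibm_config"), cfg$m > 0)
  rec <- run_ibm(init, cfg, generations, record_every = record_every,
                 hist_at = hist_at)
  r <- rec$record
  extinct <- r$N[nrow(r)] == 0
  last <- r[r$generation > generations - window & r$N > 0, ]
  prev <- r[r$generation > generations - 2 * window &
              r$generation <= generations - window & r$N > 0, ]
  evolved <- if (nrow(last)) mean(last$mean_b) else NA_real_
  converged <- !extinct && nrow(prev) > 0 &&
    is.finite(evolved) && abs(evolved - mean(prev$mean_b)) < tol
  rec$converged <- converged
  rec$evolved_mean_b <- if (extinct) NA_real_ else evolved
  rec$extinct <- extinct
  rec
}

#' Detect strategy branches in an evolved population
#'
#' One-dimensional gap-based clustering of the strategy values at a
#' checkpoint: sorted strategies are split wherever consecutive values are
#' separated by at least \code{min_sep} (default three mutation standard
#' deviations), and clusters holding less than \code{min_mass} of the
#' population are discarded as mutational fringe. Under the unmodified
#' growth laws the evolved population forms a single cluster; under the
#' modified trade-off, disruptive selection splits it into two.
#'
#' @param record an \code{"evolution_record"}, or a bare numeric vector of
#'   strategies.
#' @param checkpoint name or index of the stored histogram to use
#'   (default: the last).
#' @param sigma mutation standard deviation used for the separation scale;
#'   defaults to the record's configuration.
#' @param min_sep minimum gap separating clusters (default \code{3 * sigma}).
#' @param min_mass minimum fraction of individuals for a reported cluster.
#' @return list with \code{n_branches}, \code{means}, \code{masses}
#'   (fractions), and \code{n_individuals}.
#' @export
detect_branches <- function(record, checkpoint = NULL, sigma = NULL,
                            min_sep = NULL, min_mass = 0.1) {
  if (inherits(record, "evolution_record")) {
    if (is.null(sigma)) sigma <- record$cfg$sigma
    hists <- record$histograms
    b <- if (is.null(checkpoint)) hists[[length(hists)]]
         else hists[[format(checkpoint, scientific = FALSE, trim = TRUE)]]
    if (is.null(b))
      stop("no histogram stored at checkpoint ", checkpoint)
  } else {
    b <- as.numeric(record)
    if (is.null(sigma)) sigma <- 0.1
  }
  if (is.null(min_sep)) min_sep <- 3 * sigma
  n <- length(b)
  if (n == 0L)
    return(list(n_branches = 0L, means = numeric(0), masses = numeric(0),
                n_individuals = 0L))
  b <- sort(b)
  cut <- which(diff(b) >= min_sep)
  starts <- c(1L, cut + 1L)
  ends <- c(cut, n)
  means <- mapply(function(s, e) mean(b[s:e]), starts, ends)
  masses <- (ends - starts + 1L) / n
  keep <- masses >= min_mass
  list(n_branches = sum(keep), means = unname(means[keep]),
       masses = unname(masses[keep]), n_individuals = n)
}
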