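#' One generation of a multi-species community sharing a resource
#'
#' Advances a community of populations that reproduce under the same
#' density-dependence law but differ in their density-compensation
#' strategies. The shared resource enters through the total population
#' size: every species' reproduction ratio is evaluated at
#' \eqn{N = \sum_i N_i}, so \eqn{N_i \leftarrow N_i\, f(N; b_i)}.
#' With a single species this is one step of [iterate_map()].
#'
#' @param state a data.frame (or list) with numeric fields \code{b} and
#'   \code{N}, one row per species.
#' @param base a [growth_params()] supplying model, \code{r}, \code{K} and
#'   \code{d}; its own \code{b} is ignored.
#' @param mod optional [tradeoff_mod()].
#' @return The updated state, same shape.
#' @export
community_step <- function(state, base, mod = NULL) {
  b <- state$b; N <- state$N
  stopifnot(length(b) == length(N), all(N >= 0))
  Ntot <- sum(N)
  ratio <- vapply(b, function(bi) {
    p <- base; p$b <- bi
    reproduction_ratio(p, Ntot, mod)
  }, numeric(1))
  state$N <- N * ratio
  state
}

#' Iterate a community of strategies sharing a resource
#'
#' @inheritParams community_step
#' @param generations number of steps.
#' @return matrix of sizes, \code{generations + 1} rows, one column per
#'   species.
#' @export
community_trajectory <- function(state, base, generations, mod = NULL) {
  out <- matrix(NA_real_, nrow = generations + 1, ncol = length(state$N))
  out[1, ] <- state$N
  for (t in seq_len(generations)) {
    state <- community_step(state, base, mod)
    out[t + 1, ] <- state$N
  }
  colnames(out) <- paste0("b=", signif(state$b, 4))
  out
}

#' Attractor sample of a single resident strategy
#'
#' Iterates the resident map for \code{burn_in} transient generations and
#' returns the \code{T} subsequent population sizes. On a stable
#' equilibrium all values coincide with \eqn{\hat N}; for cyclic or chaotic
#' residents the sample traces the attractor, which is why invasion fitness
#' is averaged over it.
#'
#' @param base a [growth_params()]; its \code{b} is ignored.
#' @param b_res resident strategy.
#' @param burn_in transient generations discarded (default 1000).
#' @param T_avg number of attractor samples returned (default 500).
#' @param mod optional [tradeoff_mod()].
#' @return numeric vector of length \code{T_avg}.
#' @export
resident_attractor <- function(base, b_res, burn_in = 1000, T_avg = 500,
                               mod = NULL) {
  p <- base; p$b <- b_res
  tr <- iterate_map(p, N0 = 0.5 * p$K, generations = burn_in + T_avg,
                    mod = mod)
  att <- tr$sizes[(burn_in + 2):(burn_in + T_avg + 1)]
  if (any(att < .Machine$double.xmin * p$K))
    stop("resident population collapsed below the machine floor")
  att
}

#' Invasion fitness of a rare mutant strategy
#'
#' Time-averaged logarithmic growth rate of an infinitesimally rare
#' invader with strategy \code{b_inv} on the attractor of a resident with
#' strategy \code{b_res}:
#' \deqn{s(b_{res}, b_{inv}) = \frac{1}{T}\sum_{t=1}^{T}
#'   \log f(N_t;\, b_{inv}),}
#' where \eqn{N_t} runs over the resident's attractor. The invader is
#' assumed too rare to perturb the resident dynamics. The averaging horizon
#' \eqn{T} (default 500) makes the measure well defined for cyclic and
#' chaotic residents. A positive value means the mutant can invade.
#'
#' @inheritParams resident_attractor
#' @param b_inv invader strategy (vectorized).
#' @param attractor optionally, a precomputed [resident_attractor()] sample
#'   (then \code{b_res}, \code{burn_in}, \code{T_avg} are ignored).
#' @return invasion fitness, one value per \code{b_inv}.
#' @export
invasion_fitness <- function(base, b_res, b_inv, burn_in = 1000,
                             T_avg = 500, mod = NULL, attractor = NULL) {
  if (is.null(attractor))
    attractor <- resident_attractor(base, b_res, burn_in, T_avg, mod)
  vapply(b_inv, function(bi) {
    p <- base; p$b <- bi
    mean(log(reproduction_ratio(p, attractor, mod)))
  }, numeric(1))
}

#' Pairwise invasibility plot grid
#'
#' Evaluates invasion fitness on the full (resident, invader) strategy
#' grid. Each resident attractor is computed once and reused for the whole
#' column. The default grid is 101 points logarithmically spaced on
#' [0.17, 15]. A resident that cannot sustain a positive population is
#' flagged (its column is \code{NA}) rather than failing the scan.
#'
#' @inheritParams resident_attractor
#' @param b_grid strategy grid, used for both axes.
#' @return An object of class \code{"pip_grid"}: list with \code{resident_b},
#'   \code{invader_b}, \code{fitness} (rows = invader, columns = resident),
#'   \code{T_avg}, \code{base}, \code{mod}.
#' @examples
#' base <- growth_params("mss", r = 5, K = 100, b = 1, d = 0.05)
#' pip <- pairwise_invasibility(base, b_grid = pip_grid_default(21))
#' @export
pairwise_invasibility <- function(base, b_grid = pip_grid_default(),
                                  burn_in = 1000, T_avg = 500, mod = NULL) {
  stopifnot(!is.unsorted(b_grid), all(b_grid > 0))
  n <- length(b_grid)
  fit <- matrix(NA_real_, nrow = n, ncol = n)
  for (j in seq_len(n)) {
    att <- tryCatch(
      resident_attractor(base, b_grid[j], burn_in, T_avg, mod),
      error = function(e) NULL)
    if (is.null(att)) next
    fit[, j] <- invasion_fitness(base, b_inv = b_grid, mod = mod,
                                 attractor = att)
  }
  structure(list(resident_b = b_grid, invader_b = b_grid, fitness = fit,
                 T_avg = T_avg, base = base, mod = mod),
            class = "pip_grid")
}

#' @rdname pairwise_invasibility
#' @param n grid size.
#' @param from,to grid range (defaults matching the individual-based
#'   simulator's strategy range).
#' @export
pip_grid_default <- function(n = 101, from = 0.17, to = 15)
  exp(seq(log(from), log(to), length.out = n))

#' @export
print.pip_grid <- function(x, ...) {
  cat(sprintf(
    "<pip_grid> %d x %d strategies on [%.3g, %.3g], T = %d (%s model)\n",
    length(x$invader_b), length(x$resident_b),
    min(x$resident_b), max(x$resident_b), x$T_avg, x$base$model))
  invisible(x)
}

#' @export
as.data.frame.pip_grid <- function(x, ...) {
  data.frame(resident_b = rep(x$resident_b, each = length(x$invader_b)),
             invader_b = rep(x$invader_b, times = length(x$resident_b)),
             fitness = as.vector(x$fitness))
}

#' Plot a pairwise invasibility grid
#'
#' Shades regions of negative invasion fitness and draws a dashed vertical
#' line at the resident's critical strategy.
#'
#' @param x a [pairwise_invasibility()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot.pip_grid <- function(x, ...) {
  graphics::image(x$resident_b, x$invader_b, t(x$fitness > 0),
                  col = c("grey70", "white"),
                  xlab = "resident strategy b", ylab = "invader strategy b",
                  ...)
  bc <- tryCatch(critical_b(x$base$model, x$base$r, x$base$d),
                 error = function(e) NA_real_)
  if (is.finite(bc)) graphics::abline(v = bc, lty = 2)
  graphics::abline(0, 1, col = "grey40")
  invisible(x)
}

#' Mutual-invasibility region of a pairwise invasibility grid
#'
#' Entry \eqn{(i, j)} is \code{TRUE} when strategies \eqn{b_i} and
#' \eqn{b_j} can each invade the other — the signature of dynamically
#' stabilized coexistence by relative nonlinearity. The matrix is symmetric
#' by construction and \code{FALSE} on the diagonal (invasion fitness of a
#' strategy against itself is zero).
#'
#' @param pip a [pairwise_invasibility()] result on a square grid.
#' @param tol fitness values within \code{tol} of zero are treated as
#'   non-positive (guards the neutral diagonal at finite \eqn{T}).
#' @return logical matrix, \code{NA} where a resident was inviable.
#' @export
mutual_invasibility_region <- function(pip, tol = 1e-6) {
  stopifnot(inherits(pip, "pip_grid"))
  f <- pip$fitness
  if (nrow(f) != ncol(f) || !isTRUE(all.equal(pip$resident_b, pip$invader_b)))
    stop("mutual invasibility requires a square grid with equal axes")
  pos <- f > tol
  region <- pos & t(pos)
  # a strategy cannot mutually invade itself: the diagonal's finite-T
  # averaging residual on chaotic attractors must not count as invasion
  diag(region) <- FALSE
  region
}

# numeric selection gradient g(b) = d s(b, b_inv)/d b_inv at b_inv = b
selection_gradient <- function(base, b, burn_in = 1000, T_avg = 500,
                               mod = NULL, rel_step = 1e-3) {
  vapply(b, function(bb) {
    h <- rel_step * bb
    att <- resident_attractor(base, bb, burn_in, T_avg, mod)
    s <- invasion_fitness(base, b_inv = c(bb - h, bb + h), mod = mod,
                          attractor = att)
    (s[2] - s[1]) / (2 * h)
  }, numeric(1))
}

#' Locate and classify evolutionarily singular strategies
#'
#' Scans the numeric selection gradient
#' \eqn{g(b) = \partial s(b, b')/\partial b'|_{b'=b}} for sign changes on
#' \code{b_range}, refines each root by bisection, and classifies it by the
#' standard second-order criteria of adaptive dynamics, evaluated by finite
#' differences: the strategy is locally uninvadable when the fitness
#' curvature in the invader direction is negative, and convergence stable
#' when the gradient decreases through zero. Because a locally uninvadable
#' strategy can still sit in a fitness valley (distant mutants invade even
#' though close ones cannot — exactly what the modified growth trade-off
#' produces), the reported \code{ess} flag additionally requires global
#' uninvadability: no strategy on the scanned grid may have positive
#' invasion fitness against \eqn{b^*}. The flag combinations map to
#' \code{"CSS"} (continuously stable strategy: convergence stable and
#' uninvadable), \code{"branching_point"} (convergence stable, invadable),
#' \code{"garden_of_eden"} (uninvadable, unattainable) and
#' \code{"repellor"} (neither). Curvatures within \code{degenerate_tol} of
#' zero yield classification \code{"degenerate"}.
#'
#' @inheritParams resident_attractor
#' @param b_range interval scanned for singular strategies.
#' @param n_scan number of gradient evaluations across \code{b_range}.
#' @param curv_step finite-difference step (relative to \eqn{b^*}) for the
#'   second-order classification.
#' @param degenerate_tol curvature magnitudes below this are not classified.
#' @return data.frame with columns \code{b_star}, \code{gradient},
#'   \code{ess} (globally uninvadable), \code{locally_uninvadable},
#'   \code{convergence_stable}, \code{classification}; zero rows when the
#'   gradient does not change sign.
#' @export
find_singular_strategies <- function(base, b_range = c(0.3, 12),
                                     burn_in = 1000, T_avg = 500,
                                     mod = NULL, n_scan = 41,
                                     curv_step = 1e-2,
                                     degenerate_tol = 1e-7) {
  grid <- exp(seq(log(b_range[1]), log(b_range[2]), length.out = n_scan))
  g <- selection_gradient(base, grid, burn_in, T_avg, mod)
  sign_change <- which(g[-length(g)] * g[-1] < 0)
  rows <- lapply(sign_change, function(i) {
    root <- stats::uniroot(
      function(b) selection_gradient(base, b, burn_in, T_avg, mod),
      lower = grid[i], upper = grid[i + 1], tol = 1e-6)$root
    h <- curv_step * root
    att <- resident_attractor(base, root, burn_in, T_avg, mod)
    s_inv <- invasion_fitness(base, b_inv = c(root - h, root, root + h),
                              mod = mod, attractor = att)
    curv_inv <- (s_inv[1] - 2 * s_inv[2] + s_inv[3]) / h^2
    g_side <- selection_gradient(base, c(root - h, root + h),
                                 burn_in, T_avg, mod)
    dg <- (g_side[2] - g_side[1]) / (2 * h)
    local_ess <- curv_inv < 0
    # global uninvadability on the scan grid, excluding the immediate
    # neighbourhood of the root (one grid step)
    step_here <- root * (grid[2] / grid[1] - 1)
    far <- grid[abs(grid - root) > step_here]
    s_far <- invasion_fitness(base, b_inv = far, mod = mod,
                              attractor = att)
    ess <- local_ess && all(s_far < 1e-6)
    conv <- dg < 0
    cls <- if (abs(curv_inv) < degenerate_tol) "degenerate"
      else if (conv && ess) "CSS"
      else if (conv && !ess) "branching_point"
      else if (!conv && ess) "garden_of_eden"
      else "repellor"
    data.frame(b_star = root, gradient = selection_gradient(
                 base, root, burn_in, T_avg, mod),
               ess = ess, locally_uninvadable = local_ess,
               convergence_stable = conv,
               classification = cls, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(b_star = numeric(0), gradient = numeric(0),
                      ess = logical(0), locally_uninvadable = logical(0),
                      convergence_stable = logical(0),
                      classification = character(0)))
  do.call(rbind, rows)
}
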