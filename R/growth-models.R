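#' Parameter set for a discrete-time density-dependence model
#'
#' Bundles the parameters of one single-species map with non-overlapping
#' generations: the reproduction ratio \eqn{f(N_t) = N_{t+1}/N_t} depends on
#' the population size \eqn{N}, the intrinsic growth rate \eqn{r}, the
#' carrying capacity \eqn{K}, a density-compensation strategy \eqn{b}
#' controlling the shape (under- vs overcompensation) of the density
#' response, and a density-independent mortality risk \eqn{d} applied as a
#' survival factor \eqn{1-d}.
#'
#' The three supported laws are
#' \describe{
#'   \item{\code{"mss"}}{Maynard Smith-Slatkin:
#'     \eqn{f = (1-d)\,r / (1 + (r-1)(N/K)^b)}}
#'   \item{\code{"ricker"}}{generalized Ricker:
#'     \eqn{f = (1-d)\,\exp(r(1-(N/K)^b))}}
#'   \item{\code{"hassell"}}{Hassell, reparameterized so the
#'     \eqn{(r^{1/b}-1)} term in the denominator turns the original shape
#'     parameter into a carrying capacity:
#'     \eqn{f = (1-d)\,r / (1 + (r^{1/b}-1)N/K)^b}}
#' }
#' All three satisfy \eqn{f(K) = 1-d} for every \eqn{b}, which is the pivot
#' of the growth trade-off: increasing \eqn{b} raises growth below \eqn{K}
#' and lowers it above \eqn{K}.
#'
#' @param model one of \code{"mss"}, \code{"ricker"}, \code{"hassell"}.
#' @param r intrinsic growth rate (> 1 for MSS and Hassell; > 0 for Ricker).
#' @param K carrying capacity (> 0).
#' @param b density-compensation strategy (> 0).
#' @param d density-independent mortality in [0, 1).
#' @return An object of class \code{"growth_params"}.
#' @examples
#' p <- growth_params("mss", r = 5, K = 100, b = 2, d = 0.05)
#' reproduction_ratio(p, c(0, 50, 100, 150))
#' @export
growth_params <- function(model = c("mss", "ricker", "hassell"),
                          r, K, b, d = 0) {
  model <- match.arg(model)
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r), r > 0,
            is.numeric(K), length(K) == 1L, is.finite(K), K > 0,
            is.numeric(b), length(b) == 1L, is.finite(b), b > 0,
            is.numeric(d), length(d) == 1L, is.finite(d))
  if (d < 0 || d >= 1)
    stop("mortality 'd' must lie in [0, 1)")
  if (model %in% c("mss", "hassell") && r <= 1)
    stop("'r' must exceed 1 for the ", model, " model")
  structure(list(model = model, r = r, K = K, b = b, d = d),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("<growth_params> %s: r = %g, K = %g, b = %g, d = %g\n",
              x$model, x$r, x$K, x$b, x$d))
  invisible(x)
}

#' Trade-off modification of the density-compensation strategy
#'
#' Describes a density-dependent remapping of the strategy \eqn{b}: for
#' \eqn{b_{low} < b < b_{up}} the value used in the growth law is replaced
#' by \eqn{b_m(N)}, which depends on whether the population is below or at/
#' above the carrying capacity. With \eqn{u = (b-b_{low})/(b_{up}-b_{low})},
#' the default mapping is \eqn{b_m = b_{low} + (b_{up}-b_{low})u^\lambda}
#' for \eqn{N < K} and \eqn{b_m = b_{low} + (b_{up}-b_{low})u^{1/\lambda}}
#' for \eqn{N \ge K}. This depresses the effective growth of intermediate
#' strategies on both sides of \eqn{K} and thereby removes the uninvadable
#' intermediate strategy of the unmodified models. Outside
#' \eqn{(b_{low}, b_{up})} the mapping is the identity. An alternative
#' mapping can be plugged in via \code{map}.
#'
#' @param b_low,b_up pivot strategies delimiting the modified interval
#'   (defaults 0.8 and 5).
#' @param scaling nonlinearity strength \eqn{\lambda > 0} (default 3;
#'   \eqn{\lambda = 1} is the identity).
#' @param enabled logical; a disabled modification is the identity.
#' @param map optional replacement mapping, a
#'   \code{function(b, N, K, b_low, b_up, scaling)} returning \eqn{b_m};
#'   only consulted for \eqn{b} strictly inside \eqn{(b_{low}, b_{up})}.
#' @return An object of class \code{"tradeoff_mod"}.
#' @export
tradeoff_mod <- function(b_low = 0.8, b_up = 5, scaling = 3,
                         enabled = TRUE, map = NULL) {
  stopifnot(b_low > 0, b_up > b_low, scaling > 0,
            is.null(map) || is.function(map))
  structure(list(b_low = b_low, b_up = b_up, scaling = scaling,
                 enabled = isTRUE(enabled), map = map),
            class = "tradeoff_mod")
}

#' @export
print.tradeoff_mod <- function(x, ...) {
  cat(sprintf("<tradeoff_mod> %s: b_low = %g, b_up = %g, scaling = %g%s\n",
              if (x$enabled) "enabled" else "disabled",
              x$b_low, x$b_up, x$scaling,
              if (is.null(x$map)) "" else " (custom map)"))
  invisible(x)
}

#' Density-dependent effective strategy under the trade-off modification
#'
#' Returns the effective strategy \eqn{b_m} used in place of \eqn{b} when a
#' trade-off modification is active. Identity when \code{mod} is
#' \code{NULL}, disabled, or \eqn{b} lies outside \eqn{(b_{low}, b_{up})}.
#' Vectorized over \code{N} (and over \code{b} of matching length).
#'
#' @param b strategy value(s).
#' @param N population size(s), compared against \code{K}.
#' @param K carrying capacity.
#' @param mod a [tradeoff_mod()] or \code{NULL}.
#' @return \eqn{b_m}, same length as \code{max(length(b), length(N))}.
#' @export
modified_b <- function(b, N, K, mod = NULL) {
  n <- max(length(b), length(N))
  b <- rep_len(b, n)
  if (is.null(mod) || !mod$enabled)
    return(b)
  N <- rep_len(N, n)
  inside <- b > mod$b_low & b < mod$b_up
  if (!any(inside))
    return(b)
  if (!is.null(mod$map)) {
    b[inside] <- mod$map(b[inside], N[inside], K,
                         mod$b_low, mod$b_up, mod$scaling)
    return(b)
  }
  u <- (b[inside] - mod$b_low) / (mod$b_up - mod$b_low)
  ex <- ifelse(N[inside] < K, mod$scaling, 1 / mod$scaling)
  b[inside] <- mod$b_low + (mod$b_up - mod$b_low) * u^ex
  b
}

#' Reproduction ratio f(N)
#'
#' Evaluates the per-generation reproduction ratio
#' \eqn{f(N_t) = N_{t+1}/N_t} of the configured model at population size(s)
#' \code{N}, optionally with the strategy first remapped by a trade-off
#' modification. Note that even under the modification \eqn{f} remains
#' continuous in \eqn{N} at \eqn{N = K}, because \eqn{f(K) = 1-d}
#' independently of \eqn{b}.
#'
#' @param params a [growth_params()].
#' @param N nonnegative population size(s); vectorized.
#' @param mod optional [tradeoff_mod()].
#' @return \eqn{f(N)}, positive, same length as \code{N}.
#' @examples
#' p <- growth_params("mss", r = 5, K = 100, b = 2, d = 0)
#' reproduction_ratio(p, 100)  # exactly 1 at carrying capacity
#' @export
reproduction_ratio <- function(params, N, mod = NULL) {
  stopifnot(inherits(params, "growth_params"), is.numeric(N))
  if (any(N < 0 | !is.finite(N)))
    stop("'N' must be finite and nonnegative")
  b <- modified_b(params$b, N, params$K, mod)
  x <- N / params$K
  r <- params$r
  s <- 1 - params$d
  switch(params$model,
    mss     = s * r / (1 + (r - 1) * x^b),
    ricker  = s * exp(r * (1 - x^b)),
    hassell = s * r / (1 + (r^(1 / b) - 1) * x)^b)
}

#' Positive equilibrium population size
#'
#' Finds \eqn{\hat N} solving \eqn{f(\hat N) = 1} by a bracketed root search
#' on \eqn{(0, K]}. With \eqn{d = 0} the equilibrium is exactly \eqn{K};
#' with \eqn{d > 0} it lies slightly below \eqn{K}. Requires a viable
#' population, i.e. \eqn{f(0) > 1}.
#'
#' @inheritParams reproduction_ratio
#' @return \eqn{\hat N} with \eqn{|f(\hat N) - 1| < 10^{-10}}.
#' @export
equilibrium_density <- function(params, mod = NULL) {
  stopifnot(inherits(params, "growth_params"))
  K <- params$K
  f0 <- reproduction_ratio(params, 0, mod)
  if (f0 <= 1)
    stop("no positive equilibrium: f(0) = ", format(f0), " <= 1")
  if (params$d == 0)
    return(K)
  g <- function(N) reproduction_ratio(params, N, mod) - 1
  # f is strictly decreasing in N, f(0) > 1 and f(K) = 1 - d < 1
  root <- stats::uniroot(g, lower = K * 1e-12, upper = K,
                         tol = .Machine$double.eps * K)$root
  # one Newton polish via finite difference to push below 1e-10 residual
  h <- root * 1e-7
  slope <- (g(root + h) - g(root - h)) / (2 * h)
  polished <- root - g(root) / slope
  if (is.finite(polished) && polished > 0 && abs(g(polished)) < abs(g(root)))
    root <- polished
  root
}

#' Complexity: slope of population-level reproduction at equilibrium
#'
#' Computes \eqn{c = d[N f(N)]/dN} evaluated at the equilibrium
#' \eqn{\hat N}. Stability of the fixed point requires \eqn{c > -1};
#' at \eqn{c = -1} a deviation from equilibrium is compensated by an equal
#' deviation of opposite sign, and below it the map overcompensates and
#' population cycles (eventually chaos) appear.
#'
#' For the unmodified models the derivative is evaluated from closed forms
#' (with \eqn{\rho = (1-d)r}):
#' MSS \eqn{c = 1 - b(\rho-1)/\rho}; Ricker \eqn{c = 1 - b(r + \log(1-d))};
#' Hassell \eqn{c = 1 - b(1 - \rho^{-1/b})}. Under an active trade-off
#' modification the derivative is taken by central finite difference
#' (relative step 1e-6).
#'
#' @inheritParams reproduction_ratio
#' @param method \code{"auto"} (analytic when available), \code{"analytic"},
#'   or \code{"numeric"} (central difference; used for cross-checking).
#' @return the complexity \eqn{c}.
#' @export
complexity <- function(params, mod = NULL,
                       method = c("auto", "analytic", "numeric")) {
  method <- match.arg(method)
  modified <- !is.null(mod) && mod$enabled
  if (method == "auto")
    method <- if (modified) "numeric" else "analytic"
  if (method == "analytic") {
    if (modified)
      stop("no analytic complexity under an active trade-off modification")
    b <- params$b; r <- params$r; d <- params$d
    rho <- (1 - d) * r
    if (rho <= 1 && params$model != "ricker")
      stop("no positive equilibrium: (1-d) r <= 1")
    return(switch(params$model,
      mss     = 1 - b * (rho - 1) / rho,
      ricker  = 1 - b * (r + log1p(-d)),
      hassell = 1 - b * (1 - rho^(-1 / b))))
  }
  Nhat <- equilibrium_density(params, mod)
  h <- Nhat * 1e-6
  g <- function(N) N * reproduction_ratio(params, N, mod)
  (g(Nhat + h) - g(Nhat - h)) / (2 * h)
}

#' Critical density-compensation strategy
#'
#' The strategy \eqn{b_{cri}} at which the complexity reaches \eqn{-1},
#' i.e. the boundary between stable equilibrium dynamics
#' (\eqn{b < b_{cri}}) and cyclic/chaotic dynamics (\eqn{b > b_{cri}}),
#' found by bracketed root search in \eqn{b}. For MSS with \eqn{d = 0}
#' this matches the closed form \eqn{2r/(r-1)} (and, with mortality,
#' \eqn{2\rho/(\rho-1)} for \eqn{\rho = (1-d)r}).
#'
#' @param model model name, as in [growth_params()].
#' @param r intrinsic growth rate.
#' @param d density-independent mortality in [0, 1).
#' @param bracket search interval for \eqn{b}.
#' @param tol absolute tolerance on the root.
#' @return \eqn{b_{cri}} with \eqn{|c(b_{cri}) + 1| < } tolerance.
#' @examples
#' critical_b("mss", r = 5, d = 0)     # exactly 2r/(r-1) = 2.5
#' critical_b("mss", r = 5, d = 0.05)  # about 2.53
#' @export
critical_b <- function(model, r, d = 0, bracket = c(0.05, 50), tol = 1e-8) {
  cfun <- function(b)
    complexity(growth_params(model, r = r, K = 1, b = b, d = d)) + 1
  lo <- cfun(bracket[1]); hi <- cfun(bracket[2])
  if (is.na(lo) || is.na(hi) || lo * hi > 0)
    stop(sprintf(
      "no sign change of c + 1 in bracket [%g, %g]: c+1 = %g and %g",
      bracket[1], bracket[2], lo, hi))
  stats::uniroot(cfun, interval = bracket, tol = tol)$root
}

#' Iterate a single-population map
#'
#' Deterministic trajectory \eqn{N_{t+1} = N_t f(N_t)} from \code{N0} for
#' \code{generations} steps.
#'
#' @inheritParams reproduction_ratio
#' @param N0 positive initial size.
#' @param generations number of steps (>= 1).
#' @return An object of class \code{"trajectory"}: a list with \code{sizes}
#'   (length \code{generations + 1}) and \code{params}.
#' @export
iterate_map <- function(params, N0, generations, mod = NULL) {
  stopifnot(N0 > 0, generations >= 1)
  sizes <- numeric(generations + 1)
  sizes[1] <- N0
  for (t in seq_len(generations)) {
    sizes[t + 1] <- sizes[t] * reproduction_ratio(params, sizes[t], mod)
    if (!is.finite(sizes[t + 1]))
      stop("non-finite population size at generation ", t)
  }
  structure(list(sizes = sizes, params = params, mod = mod),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- length(x$sizes)
  cat(sprintf("<trajectory> %d generations, %s model; final N = %g\n",
              n - 1L, x$params$model, x$sizes[n]))
  invisible(x)
}

#' Bifurcation scan over the density-compensation strategy
#'
#' For each \eqn{b} on a grid, iterates the map from \eqn{N_0 = K/2},
#' discards a burn-in, and records subsequent attractor samples — the
#' numerical bifurcation diagram of population size against \eqn{b}. The
#' attractor has a single value (cardinality 1) below the critical
#' strategy, and period-doubles above it.
#'
#' @inheritParams critical_b
#' @param b_grid increasing vector of strategies to scan.
#' @param K carrying capacity (default 1; only sets the scale).
#' @param burn_in discarded transient generations (>= 500 recommended).
#' @param sample number of attractor samples kept per \eqn{b}.
#' @param mod optional [tradeoff_mod()].
#' @return A data.frame with columns \code{b}, \code{sample_index},
#'   \code{N}, of class \code{c("bifurcation_scan", "data.frame")}, with
#'   attributes \code{K} and \code{tol} used by [attractor_cardinality()].
#' @export
bifurcation_scan <- function(model, r, d, b_grid, K = 1,
                             burn_in = 1000, sample = 100, mod = NULL) {
  stopifnot(length(b_grid) >= 1, !is.unsorted(b_grid))
  out <- vector("list", length(b_grid))
  for (i in seq_along(b_grid)) {
    p <- growth_params(model, r = r, K = K, b = b_grid[i], d = d)
    tr <- iterate_map(p, N0 = 0.5 * K, generations = burn_in + sample,
                      mod = mod)
    out[[i]] <- data.frame(b = b_grid[i], sample_index = seq_len(sample),
                           N = tr$sizes[(burn_in + 2):(burn_in + sample + 1)])
  }
  res <- do.call(rbind, out)
  attr(res, "K") <- K
  attr(res, "tol") <- 1e-6 * K
  class(res) <- c("bifurcation_scan", "data.frame")
  res
}

#' Number of distinct attractor values per strategy
#'
#' Clusters the sampled attractor of a [bifurcation_scan()] with an
#' absolute tolerance (default \eqn{10^{-6} K}) and returns the cluster
#' count per \eqn{b}: 1 for a fixed point, 2 for a two-cycle, and so on.
#'
#' @param scan result of [bifurcation_scan()].
#' @param tol absolute clustering tolerance; defaults to the scan's.
#' @return data.frame with columns \code{b} and \code{n_attractor}.
#' @export
attractor_cardinality <- function(scan, tol = attr(scan, "tol")) {
  stopifnot(inherits(scan, "bifurcation_scan"))
  card <- vapply(split(scan$N, scan$b), function(v) {
    v <- sort(v)
    sum(diff(v) > tol) + 1L
  }, integer(1))
  data.frame(b = as.numeric(names(card)), n_attractor = unname(card))
}

#' @export
plot.bifurcation_scan <- function(x, ..., pch = ".", cex = 1.5,
                                  xlab = "density-compensation strategy b",
                                  ylab = "attractor population size N") {
  graphics::plot(x$b, x$N, pch = pch, cex = cex, xlab = xlab, ylab = ylab,
                 ...)
  invisible(x)
}

# flat serialization of a parameter set (+ optional modification), used by
# the experiment manifests and the CLI config files
#' Serialize / deserialize parameters as a flat mapping
#'
#' @param params a [growth_params()].
#' @param mod optional [tradeoff_mod()].
#' @return \code{params_to_config}: a named list with keys \code{model, r,
#'   K, b, d} and, when \code{mod} is given, \code{b_low, b_up, scaling,
#'   enabled}. \code{config_to_params}: a list with elements
#'   \code{params} and \code{mod} (possibly \code{NULL}).
#' @export
params_to_config <- function(params, mod = NULL) {
  cfg <- list(model = params$model, r = params$r, K = params$K,
              b = params$b, d = params$d)
  if (!is.null(mod))
    cfg <- c(cfg, list(b_low = mod$b_low, b_up = mod$b_up,
                       scaling = mod$scaling, enabled = mod$enabled))
  cfg
}

#' @rdname params_to_config
#' @param config a named list as produced by \code{params_to_config}.
#' @export
config_to_params <- function(config) {
  params <- growth_params(config$model, r = config$r, K = config$K,
                          b = config$b, d = config$d)
  mod <- NULL
  if (!is.null(config$b_low))
    mod <- tradeoff_mod(b_low = config$b_low, b_up = config$b_up,
                        scaling = config$scaling,
                        enabled = isTRUE(config$enabled))
  list(params = params, mod = mod)
}
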