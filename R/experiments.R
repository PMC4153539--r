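#' Specification of a canned simulation experiment
#'
#' The package ships seven figure-level experiments covering the full
#' analysis pipeline:
#' \describe{
#'   \item{fig1}{reproduction-ratio curves and the bifurcation diagram of
#'     the MSS map, with the critical strategy marked.}
#'   \item{fig2}{pairwise invasibility plots for the three growth laws at
#'     their standard presets (MSS r = 5, Hassell r = 40, Ricker r = 0.5,
#'     d = 0.05).}
#'   \item{fig3}{individual-based invasion-probability and
#'     log10 exclusion-time heatmaps at K = 200.}
#'   \item{fig4}{two evolution traces (a coexisting pair, and two isolated
#'     strategies) with evolution switched on partway through the run.}
#'   \item{fig5}{evolved strategy over an (r, d) grid, with the difference
#'     to the critical strategy.}
#'   \item{fig6}{reproduction-ratio curves of the original and modified
#'     MSS model plus the modified model's pairwise invasibility plot.}
#'   \item{fig7}{evolutionary branching trace under the modified trade-off
#'     and exclusion times around the branched pair.}
#' }
#' The defaults reproduce the full-scale analyses; \code{scale} shrinks
#' grids, generations and replicate counts proportionally so every code
#' path can be exercised quickly (the test-suite runs only scaled
#' presets).
#'
#' @param name experiment name, \code{"fig1"} ... \code{"fig7"}.
#' @param seed integer seed; every stochastic experiment is reproducible
#'   from (spec, seed).
#' @param scale scale factor in (0, 1]: 1 is the full published size.
#' @param overrides named list of preset overrides (grids, replicate
#'   counts, generation counts).
#' @return An object of class \code{"experiment_spec"}.
#' @export
experiment_spec <- function(name, seed = 1, scale = 1, overrides = list()) {
  known <- paste0("fig", 1:7)
  if (!name %in% known)
    stop("unknown experiment '", name, "'; expected one of ",
         paste(known, collapse = ", "))
  stopifnot(scale > 0, scale <= 1, is.list(overrides))
  structure(list(name = name, seed = as.integer(seed), scale = scale,
                 overrides = overrides),
            class = "experiment_spec")
}

exp_par <- function(spec, key, default) {
  if (!is.null(spec$overrides[[key]])) spec$overrides[[key]] else default
}

write_experiment_csv <- function(df, path, manifest_note = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run a canned experiment
#'
#' Executes the experiment described by an [experiment_spec()], writes its
#' tables as CSV (and, optionally, quick-look PNG figures) into
#' \code{out_dir}, and records a JSON run manifest (spec, package version,
#' seed, wall time, and md5 checksums of every produced file). The
#' manifest is written atomically after the run completes; failed
#' sub-steps are logged in the manifest's \code{errors} field and mark the
#' run as partial.
#'
#' @param spec an [experiment_spec()] (or a name, passed to
#'   [experiment_spec()] with defaults).
#' @param out_dir output directory, created if needed.
#' @param seed,scale used only when \code{spec} is given as a name.
#' @param plots logical: also render quick-look PNG figures.
#' @return the manifest, invisibly (class \code{"run_manifest"}).
#' @export
run_experiment <- function(spec, out_dir = ".", seed = 1, scale = 1,
                           plots = FALSE) {
  if (is.character(spec))
    spec <- experiment_spec(spec, seed = seed, scale = scale)
  stopifnot(inherits(spec, "experiment_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  t0 <- Sys.time()
  files <- character(0)
  errors <- character(0)
  runner <- get(paste0("experiment_", spec$name),
                envir = asNamespace("rncoex"))
  files <- tryCatch(runner(spec, out_dir, plots),
                    error = function(e) {
                      errors <<- conditionMessage(e)
                      character(0)
                    })
  manifest <- list(
    spec = list(name = spec$name, seed = spec$seed, scale = spec$scale,
                overrides = spec$overrides),
    package_version = as.character(utils::packageVersion("rncoex")),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = as.list(tools::md5sum(files)),
    partial = length(errors) > 0,
    errors = errors)
  mpath <- file.path(out_dir, paste0(spec$name, "_manifest.json"))
  tmp <- paste0(mpath, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, mpath)
  invisible(structure(manifest, class = "run_manifest"))
}

experiment_fig1 <- function(spec, out_dir, plots) {
  r <- exp_par(spec, "r", 5); d <- exp_par(spec, "d", 0.05)
  n_b <- max(20, round(exp_par(spec, "n_b", 200) * spec$scale))
  b_grid <- seq(0.5, 8, length.out = n_b)
  scan <- bifurcation_scan("mss", r = r, d = d, b_grid = b_grid, K = 1,
                           burn_in = 1000, sample = 100)
  f1 <- write_experiment_csv(scan, file.path(out_dir, "fig1_bifurcation.csv"))
  x <- seq(0, 2, length.out = 201)
  curves <- do.call(rbind, lapply(c(0.5, 1, 2.5, 6), function(b) {
    p <- growth_params("mss", r = r, K = 1, b = b, d = d)
    data.frame(b = b, N_over_K = x, f = reproduction_ratio(p, x))
  }))
  f2 <- write_experiment_csv(curves, file.path(out_dir, "fig1_ratio_curves.csv"))
  fs <- c(f1, f2)
  if (plots) {
    png_path <- file.path(out_dir, "fig1_bifurcation.png")
    grDevices::png(png_path, 800, 600)
    plot(scan)
    graphics::abline(v = critical_b("mss", r, d), lty = 2)
    grDevices::dev.off()
    fs <- c(fs, png_path)
  }
  fs
}

fig2_presets <- list(mss = 5, hassell = 40, ricker = 0.5)

experiment_fig2 <- function(spec, out_dir, plots) {
  d <- exp_par(spec, "d", 0.05)
  n_grid <- max(15, round(exp_par(spec, "n_grid", 101) * spec$scale))
  fs <- character(0)
  for (model in names(fig2_presets)) {
    base <- growth_params(model, r = fig2_presets[[model]], K = 1, b = 1,
                          d = d)
    pip <- pairwise_invasibility(base, b_grid = pip_grid_default(n_grid))
    fs <- c(fs, write_experiment_csv(
      as.data.frame(pip), file.path(out_dir, paste0("fig2_pip_", model, ".csv"))))
    if (plots) {
      png_path <- file.path(out_dir, paste0("fig2_pip_", model, ".png"))
      grDevices::png(png_path, 700, 700)
      plot(pip, main = model)
      grDevices::dev.off()
      fs <- c(fs, png_path)
    }
  }
  fs
}

experiment_fig3 <- function(spec, out_dir, plots) {
  cfg <- ibm_preset("invasion")
  n_grid <- max(6, round(exp_par(spec, "n_grid", 40) * spec$scale))
  n_reps <- max(5, round(exp_par(spec, "n_reps", 50) * spec$scale))
  max_gen <- exp_par(spec, "max_gen", round(1e6 * spec$scale))
  b_grid <- exp(seq(log(0.3), log(8), length.out = n_grid))
  inv <- expand.grid(b_res = b_grid, b_inv = b_grid)
  inv$p <- NA_real_
  for (i in seq_len(nrow(inv))) {
    est <- tryCatch(
      invasion_probability(inv$b_res[i], inv$b_inv[i], cfg,
                           n_reps = n_reps),
      error = function(e) NULL)
    inv$p[i] <- if (is.null(est)) NA_real_ else est$p
  }
  f1 <- write_experiment_csv(inv, file.path(out_dir, "fig3_invasion.csv"))
  coex <- expand.grid(b1 = b_grid, b2 = b_grid)
  coex$log10_time <- NA_real_
  coex$censored <- NA_real_
  for (i in seq_len(nrow(coex))) {
    cs <- coexistence_time(coex$b1[i], coex$b2[i], cfg, max_gen = max_gen,
                           n_reps = 1)
    coex$log10_time[i] <- cs$mean_log10_time
    coex$censored[i] <- cs$censored_fraction
  }
  f2 <- write_experiment_csv(coex, file.path(out_dir, "fig3_exclusion.csv"))
  c(f1, f2)
}

experiment_fig4 <- function(spec, out_dir, plots) {
  cfg <- ibm_preset("evolution_fast")
  gens <- max(1000, round(exp_par(spec, "generations", 1e6) * spec$scale))
  switch_at <- round(exp_par(spec, "evolution_start", 3e5) * spec$scale)
  K <- cfg$base$K
  # (a) a dynamically coexisting pair; (b) two isolated strategies
  init_a <- c(rep(0.9, K %/% 2), rep(5.4, K %/% 2))
  rec_a <- run_ibm(init_a, cfg, gens, record_every = max(1, gens %/% 500),
                   evolution_start = switch_at)
  fs <- write_experiment_csv(rec_a$record,
                             file.path(out_dir, "fig4a_trace.csv"))
  for (b0 in c(0.5, 6)) {
    rec <- run_ibm(rep(b0, K), cfg, gens,
                   record_every = max(1, gens %/% 500),
                   evolution_start = switch_at)
    fs <- c(fs, write_experiment_csv(
      rec$record, file.path(out_dir, sprintf("fig4b_trace_b%g.csv", b0))))
  }
  fs
}

experiment_fig5 <- function(spec, out_dir, plots) {
  n_r <- max(3, round(exp_par(spec, "n_r", 12) * spec$scale))
  n_d <- max(3, round(exp_par(spec, "n_d", 12) * spec$scale))
  gens <- max(2000, round(exp_par(spec, "generations", 1e6) * spec$scale))
  r_grid <- seq(2, 30, length.out = n_r)
  d_grid <- seq(0.01, 0.3, length.out = n_d)
  out <- expand.grid(r = r_grid, d = d_grid)
  out$evolved_b <- NA_real_; out$b_cri <- NA_real_; out$extinct <- NA
  for (i in seq_len(nrow(out))) {
    cfg <- ibm_config("mss", r = out$r[i], K = 1000, d = out$d[i], m = 0.1)
    rec <- tryCatch(evolve_to_equilibrium(cfg, generations = gens),
                    error = function(e) NULL)
    if (is.null(rec)) next
    out$evolved_b[i] <- rec$evolved_mean_b
    out$extinct[i] <- rec$extinct
    out$b_cri[i] <- tryCatch(critical_b("mss", out$r[i], out$d[i]),
                             error = function(e) NA_real_)
  }
  out$diff_to_bcri <- out$evolved_b - out$b_cri
  write_experiment_csv(out, file.path(out_dir, "fig5_ess_scan.csv"))
}

experiment_fig6 <- function(spec, out_dir, plots) {
  d <- exp_par(spec, "d", 0.05)
  mod <- tradeoff_mod()
  n_grid <- max(15, round(exp_par(spec, "n_grid", 101) * spec$scale))
  x <- seq(0, 2, length.out = 201)
  bs <- exp(seq(log(0.3), log(10), length.out = 12))
  curves <- do.call(rbind, lapply(bs, function(b) {
    p <- growth_params("mss", r = 5, K = 1, b = b, d = d)
    data.frame(b = b, N_over_K = x,
               f_original = reproduction_ratio(p, x),
               f_modified = reproduction_ratio(p, x, mod))
  }))
  f1 <- write_experiment_csv(curves, file.path(out_dir, "fig6_curves.csv"))
  base <- growth_params("mss", r = 5, K = 1, b = 1, d = d)
  pip <- pairwise_invasibility(base, b_grid = pip_grid_default(n_grid),
                               mod = mod)
  f2 <- write_experiment_csv(as.data.frame(pip),
                             file.path(out_dir, "fig6_pip_modified.csv"))
  c(f1, f2)
}

experiment_fig7 <- function(spec, out_dir, plots) {
  cfg <- ibm_preset("branching")
  gens <- max(5000, round(exp_par(spec, "generations", 1e6) * spec$scale))
  switch_at <- round(exp_par(spec, "evolution_start", gens %/% 3))
  K <- cfg$base$K
  rec <- run_ibm(rep(2.5, K), cfg, gens,
                 record_every = max(1, gens %/% 500),
                 evolution_start = switch_at)
  f1 <- write_experiment_csv(rec$record,
                             file.path(out_dir, "fig7_branching_trace.csv"))
  br <- detect_branches(rec)
  f2 <- write_experiment_csv(
    data.frame(branch = seq_along(br$means), mean_b = br$means,
               mass = br$masses),
    file.path(out_dir, "fig7_branches.csv"))
  fs <- c(f1, f2)
  if (br$n_branches >= 2) {
    pair <- range(br$means)
    n_reps <- max(3, round(exp_par(spec, "n_reps", 20) * spec$scale))
    cs <- coexistence_time(pair[1], pair[2], cfg,
                           max_gen = round(1e6 * spec$scale),
                           n_reps = n_reps)
    fs <- c(fs, write_experiment_csv(
      data.frame(b1 = pair[1], b2 = pair[2],
                 mean_log10_time = cs$mean_log10_time,
                 censored_fraction = cs$censored_fraction),
      file.path(out_dir, "fig7_exclusion.csv")))
  }
  fs
}
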