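#' Calibration configuration
#'
#' Controls the bounded simulated-annealing fit of the kinetic bloom model.
#' An "iteration" is one outer annealing step, within which a move is
#' proposed for each free parameter in turn. The run stops at `maxit`
#' iterations or after `patience` consecutive iterations without improvement
#' of the best objective. Parameter vectors for which no bloom is predicted
#' are scored by replacing the missing prediction with the observed date plus
#' `penalty` days, which keeps the objective finite everywhere while strongly
#' disfavouring such regions.
#'
#' @param start a [phenoflex_params()] object of starting values.
#' @param lower,upper named bound vectors (defaults: [phenoflex_bounds()]).
#' @param free names of the parameters to optimize; the rest stay fixed at
#'   `start`.
#' @param maxit maximum annealing iterations.
#' @param patience no-improvement iterations before stopping.
#' @param refine_patience consecutive non-improving refinement reruns before
#'   [refine_fit()] stops.
#' @param penalty no-bloom penalty, days.
#' @param season_start passed to the engine (default: 1 August preceding the
#'   bloom year).
#' @param seed integer seed; fits are reproducible given it.
#' @return list of class `"fit_config"`.
#' @export
fit_config <- function(start = phenoflex_params(),
                       lower = phenoflex_bounds()$lower,
                       upper = phenoflex_bounds()$upper,
                       free = .pf_par_names,
                       maxit = 1000, patience = 250, refine_patience = 2,
                       penalty = 60, season_start = NULL, seed = 1) {
  start <- as_phenoflex_params(start)
  stopifnot(all(free %in% .pf_par_names),
            all(.pf_par_names %in% names(lower)),
            all(.pf_par_names %in% names(upper)))
  if (any(start < lower[.pf_par_names] | start > upper[.pf_par_names]))
    stop("starting values must lie within the bounds")
  if (patience >= maxit) stop("patience must be smaller than maxit")
  structure(list(start = start, lower = lower[.pf_par_names],
                 upper = upper[.pf_par_names], free = free, maxit = maxit,
                 patience = patience, refine_patience = refine_patience,
                 penalty = penalty, season_start = season_start,
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Root mean square error and mean absolute error of bloom predictions
#'
#' No-bloom predictions (`NA`) are replaced by the observed date plus the
#' penalty before scoring, so the objective stays defined everywhere.
#'
#' @param predicted,observed day-of-year vectors of equal length.
#' @param penalty days added to the observed date for a no-bloom prediction.
#' @return named vector `c(rmse, mae)`.
#' @export
score <- function(predicted, observed, penalty = 60) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  stopifnot(length(observed) >= 1)
  predicted[is.na(predicted)] <- observed[is.na(predicted)] + penalty
  r <- predicted - observed
  c(rmse = sqrt(mean(r^2)), mae = mean(abs(r)))
}

# Internal: prepare per-cell season data and a bloom-prediction closure.
# When all chill-kinetics parameters (E0, E1, A0, A1, Tf, slope) are fixed,
# the chill trajectories are computed once and cached, leaving only the
# heat loop per objective evaluation.
make_predictor <- function(cell_ids, temps, cfg) {
  missing <- setdiff(cell_ids, names(temps))
  if (length(missing) > 0)
    stop("missing hourly temperatures for cell(s): ",
         paste(head(missing, 5), collapse = ", "))
  prep <- lapply(cell_ids, function(cid)
    prep_season(temps[[cid]], cfg$season_start, check_coverage = TRUE))
  chill_pars <- c("E0", "E1", "A0", "A1", "Tf", "slope")
  chill_fixed <- !any(chill_pars %in% cfg$free)
  ytrajs <- NULL
  if (chill_fixed) {
    s <- cfg$start
    ytrajs <- lapply(prep, function(p)
      pf_chill_traj_cpp(p$temp, s[["E0"]], s[["E1"]], s[["A0"]], s[["A1"]],
                        s[["Tf"]], s[["slope"]]))
  }
  # Predictions are continuous day-of-year values: the threshold crossing is
  # interpolated within the bloom hour, which keeps the RMSE objective smooth
  # in the parameters (integer-day predictions make it piecewise constant and
  # stall any local search on plateaus). The +0.5 aligns the continuous scale
  # with integer observed dates: a crossing at midday of day d maps to d.
  function(par) {
    vapply(seq_along(prep), function(i) {
      h <- if (chill_fixed)
        pf_bloom_from_traj_cpp(prep[[i]]$temp, ytrajs[[i]], par[["yc"]],
                               par[["zc"]], par[["s1"]], par[["Tu"]],
                               par[["Tc"]], par[["Tb"]])
      else
        pf_run_cpp(prep[[i]]$temp, as.numeric(par))$bloom_hour_frac
      if (h < 0) NA_real_ else prep[[i]]$day_doy[1] - 1 + h / 24 + 0.5
    }, numeric(1))
  }
}

# Reflect a proposal back into [lo, hi].
reflect <- function(x, lo, hi) {
  if (hi <= lo) return(lo)
  w <- hi - lo
  x <- (x - lo) %% (2 * w)
  lo + ifelse(x > w, 2 * w - x, x)
}

# Bounded simulated annealing over a box, followed by a deterministic
# pattern-search polish of the best point (the local-search phase of
# generalized simulated-annealing schemes). Each outer iteration proposes one
# move per free parameter, mixing single-coordinate and joint heavy-tailed
# (t3) moves so correlated parameter ridges can be followed; halfway through
# the patience window the walker re-anneals from the incumbent best. fn must
# return a scalar to be minimized. Returns the best point, its value, the
# best-objective trajectory and the iteration count.
anneal_box <- function(fn, par0, lower, upper, maxit, patience, seed,
                       temp0 = 0.5) {
  with_seed(seed, {
    d <- length(par0)
    cur <- par0
    fcur <- fn(cur)
    best <- cur
    fbest <- fcur
    trace <- numeric(maxit)
    rng <- upper - lower
    no_improve <- 0L
    iters <- 0L
    for (k in seq_len(maxit)) {
      iters <- k
      tk <- temp0 * exp(-6 * (k - 1) / maxit)
      sck <- pmax(0.03, 0.35 * exp(-4 * (k - 1) / maxit))
      improved <- FALSE
      for (j in seq_len(d)) {
        prop <- cur
        if (d > 1 && runif(1) < 0.5) { # joint move along a random direction
          step <- sck * rng * rt(d, df = 3) / sqrt(d)
          for (jj in seq_len(d))
            prop[jj] <- reflect(cur[jj] + step[jj], lower[jj], upper[jj])
        } else {
          prop[j] <- reflect(cur[j] + sck * rng[j] * rt(1, df = 3),
                             lower[j], upper[j])
        }
        fp <- fn(prop)
        if (fp < fcur || runif(1) < exp(-(fp - fcur) / tk)) {
          cur <- prop
          fcur <- fp
        }
        if (fp < fbest - 1e-12) {
          best <- prop
          fbest <- fp
          improved <- TRUE
        }
      }
      trace[k] <- fbest
      no_improve <- if (improved) 0L else no_improve + 1L
      if (no_improve == max(1L, patience %/% 2L)) { # re-anneal from the best
        cur <- best
        fcur <- fbest
      }
      if (no_improve >= patience) break
    }
    # local-search phase: restarted Nelder-Mead from the annealing best.
    # The objective's minimum lies in a long curved valley (the heat
    # requirement trades off against the GDH response shape), which simplex
    # search tracks far better than coordinate-wise moves. Bounds are kept by
    # clamping with a quadratic penalty on the excursion.
    if (d > 1) {
      pen_fn <- function(x) {
        xc <- pmin(upper, pmax(lower, x))
        fn(xc) + 100 * sum(((x - xc) / rng)^2)
      }
      for (r in 1:8) {
        nm <- stats::optim(best, pen_fn, method = "Nelder-Mead",
                           control = list(maxit = 600, parscale = rng,
                                          reltol = 1e-12))
        cand <- pmin(upper, pmax(lower, nm$par))
        fc <- fn(cand)
        if (fc < fbest - 1e-8) {
          best <- cand
          fbest <- fc
        } else break
      }
      # a final small compass sweep dislodges degenerate-simplex stalls
      for (frac in c(0.003, 0.001)) {
        repeat {
          moved <- FALSE
          for (j in seq_len(d)) for (dir in c(-1, 1)) {
            prop <- best
            prop[j] <- min(upper[j], max(lower[j], best[j] + dir * frac * rng[j]))
            fp <- fn(prop)
            if (fp < fbest - 1e-9) {
              best <- prop
              fbest <- fp
              moved <- TRUE
            }
          }
          if (!moved) break
        }
      }
    } else {
      for (frac in c(0.05, 0.02, 0.008, 0.003, 0.001)) {
        repeat {
          moved <- FALSE
          for (dir in c(-1, 1)) {
            prop <- pmin(upper, pmax(lower, best + dir * frac * rng))
            fp <- fn(prop)
            if (fp < fbest - 1e-12) {
              best <- prop
              fbest <- fp
              moved <- TRUE
            }
          }
          if (!moved) break
        }
      }
    }
    list(par = best, value = fbest, trace = trace[seq_len(iters)],
         iterations = iters)
  })
}

#' Fit the kinetic bloom model to onset observations
#'
#' Minimizes the calibration RMSE over the free parameters by bounded
#' simulated annealing (see [fit_config()]). Every proposal respects the
#' parameter box; the best-ever parameter vector is returned, so the result
#' is never worse than the starting point.
#'
#' @param observations data frame with `cell_id` and `onset_doy` (calibration
#'   set).
#' @param temps named list (by `cell_id`) of hourly series from
#'   [daily_to_hourly()].
#' @param cfg a [fit_config()].
#' @return list of class `"phenoflex_fit"`: `par` (full parameter set),
#'   `rmse`, `mae`, `trace` (best objective per iteration), `predictions`
#'   (per-observation table with residuals), `cfg`.
#' @export
fit_phenoflex <- function(observations, temps, cfg = fit_config()) {
  stopifnot(inherits(cfg, "fit_config"))
  if (nrow(observations) < 8)
    warning("fewer than 8 calibration observations; the fit is likely ",
            "under-determined")
  predictor <- make_predictor(observations$cell_id, temps, cfg)
  obs <- observations$onset_doy
  full <- unclass(cfg$start)
  objective <- function(theta) {
    par <- full
    par[cfg$free] <- theta
    # enforce the GDH temperature ordering; invalid orderings are rejected
    if (!(par[["Tb"]] < par[["Tu"]] && par[["Tu"]] < par[["Tc"]]))
      return(Inf)
    score(predictor(par), obs, cfg$penalty)[["rmse"]]
  }
  res <- anneal_box(objective, full[cfg$free], cfg$lower[cfg$free],
                    cfg$upper[cfg$free], cfg$maxit, cfg$patience, cfg$seed)
  par <- full
  par[cfg$free] <- res$par
  pred <- predictor(par)
  sc <- score(pred, obs, cfg$penalty)
  structure(list(
    par = as_phenoflex_params(par),
    rmse = sc[["rmse"]], mae = sc[["mae"]],
    trace = res$trace, iterations = res$iterations,
    predictions = data.frame(cell_id = observations$cell_id, observed = obs,
                             predicted = pred, residual = pred - obs),
    cfg = cfg
  ), class = "phenoflex_fit")
}

#' @export
print.phenoflex_fit <- function(x, ...) {
  cat(sprintf("kinetic bloom model fit: %d observations, RMSE %.3f d, MAE %.3f d\n",
              nrow(x$predictions), x$rmse, x$mae))
  cat("free parameters:", paste(x$cfg$free, collapse = ", "), "\n")
  print(round(unclass(x$par), 3))
  invisible(x)
}

#' Iterative refinement of a fit
#'
#' Re-runs the annealing fit with starting values set to the previous best
#' parameters, stopping after `refine_patience` (default 2) consecutive runs
#' that improve neither RMSE nor MAE. The last improving run's parameters are
#' returned, so the reported RMSE sequence is non-increasing.
#'
#' @param fit a completed [fit_phenoflex()] result.
#' @param observations,temps as in [fit_phenoflex()].
#' @param max_runs safety cap on refinement reruns.
#' @return the refined `"phenoflex_fit"`, with a `refinement` data frame
#'   (`run`, `rmse`, `mae`, `improved`) attached.
#' @export
refine_fit <- function(fit, observations, temps, max_runs = 10) {
  stopifnot(inherits(fit, "phenoflex_fit"))
  cfg <- fit$cfg
  best <- fit
  history <- data.frame(run = 0, rmse = fit$rmse, mae = fit$mae,
                        improved = TRUE)
  fails <- 0L
  run <- 0L
  while (fails < cfg$refine_patience && run < max_runs) {
    run <- run + 1L
    cfg_r <- cfg
    cfg_r$start <- best$par
    cfg_r$seed <- cfg$seed + 7919L * run
    cand <- fit_phenoflex(observations, temps, cfg_r)
    improved <- (cand$rmse < best$rmse - 1e-9) || (cand$mae < best$mae - 1e-9)
    history <- rbind(history, data.frame(run = run, rmse = cand$rmse,
                                         mae = cand$mae, improved = improved))
    if (improved) {
      # keep the run only if it does not worsen the objective
      if (cand$rmse <= best$rmse + 1e-9) best <- cand
      fails <- 0L
    } else {
      fails <- fails + 1L
    }
  }
  best$refinement <- history
  best
}

#' Residual-bootstrap uncertainty for a fit
#'
#' For each of `B` replicates the calibration residuals are resampled with
#' replacement, added to the original observed onset dates (rounded to whole
#' days, matching the daily resolution of the records) and the annealing fit
#' is re-run from the best parameters. The spread of the replicate parameter
#' sets -- standard deviation and 16th/84th percentiles -- quantifies
#' parameter uncertainty; the spread of replicate predictions quantifies
#' prediction uncertainty.
#'
#' @param fit a [fit_phenoflex()] (or refined) result.
#' @param observations,temps as in [fit_phenoflex()].
#' @param B number of replicates. The conventional choice for comparison
#'   across studies is 10; other values trigger a warning.
#' @return list of class `"bootstrap_ensemble"`: `params` (B x 12 matrix),
#'   `sd`, `p16`, `p84` (per parameter), `predictions` (B x n matrix of
#'   calibration predictions), `prediction_sd`, `B`.
#' @export
bootstrap_fit <- function(fit, observations, temps, B = 10) {
  stopifnot(inherits(fit, "phenoflex_fit"))
  if (B != 10)
    warning("B = 10 is the conventional replicate count; using B = ", B)
  cfg <- fit$cfg
  res <- fit$predictions$residual
  res[is.na(res)] <- 0
  mats <- with_seed(cfg$seed + 104729L, {
    lapply(seq_len(B), function(b) {
      obs_b <- observations
      obs_b$onset_doy <- observations$onset_doy +
        round(sample(res, length(res), replace = TRUE))
      cfg_b <- cfg
      cfg_b$start <- fit$par
      cfg_b$seed <- cfg$seed + 31L * b
      fit_phenoflex(obs_b, temps, cfg_b)
    })
  })
  params <- do.call(rbind, lapply(mats, function(f) as.numeric(f$par)))
  colnames(params) <- .pf_par_names
  preds <- do.call(rbind, lapply(mats, function(f) f$predictions$predicted))
  colnames(preds) <- observations$cell_id
  structure(list(
    params = params,
    sd = apply(params, 2, sd),
    p16 = apply(params, 2, function(v) bw_quantile(v, 0.16)),
    p84 = apply(params, 2, function(v) bw_quantile(v, 0.84)),
    predictions = preds,
    prediction_sd = apply(preds, 2, sd),
    B = B
  ), class = "bootstrap_ensemble")
}

#' Evaluate a fit on held-out observations
#'
#' Predictions use the best-fit parameters; if a bootstrap ensemble is
#' supplied, per-observation error bars are the 16th/84th percentiles and
#' standard deviation of the replicate predictions.
#'
#' @param fit a `"phenoflex_fit"`.
#' @param observations validation observations (`cell_id`, `onset_doy`).
#' @param temps named list of hourly series covering the validation cells.
#' @param ensemble optional `"bootstrap_ensemble"`.
#' @return list with `rmse`, `mae` and a per-observation `table` (`cell_id`,
#'   `observed`, `predicted`, `residual` and, with an ensemble, `sd`, `p16`,
#'   `p84`).
#' @export
evaluate_fit <- function(fit, observations, temps, ensemble = NULL) {
  stopifnot(inherits(fit, "phenoflex_fit"))
  if (nrow(observations) == 0) stop("empty validation set")
  cfg <- fit$cfg
  predictor <- make_predictor(observations$cell_id, temps, cfg)
  pred <- predictor(unclass(fit$par))
  sc <- score(pred, observations$onset_doy, cfg$penalty)
  tab <- data.frame(cell_id = observations$cell_id,
                    observed = observations$onset_doy, predicted = pred,
                    residual = pred - observations$onset_doy)
  if (!is.null(ensemble)) {
    reps <- apply(ensemble$params, 1,
                  function(p) predictor(stats::setNames(p, .pf_par_names)))
    reps <- matrix(reps, ncol = nrow(ensemble$params))
    tab$sd <- apply(reps, 1, function(v) sd(v, na.rm = TRUE))
    tab$p16 <- apply(reps, 1, function(v) bw_quantile(v, 0.16))
    tab$p84 <- apply(reps, 1, function(v) bw_quantile(v, 0.84))
  }
  list(rmse = sc[["rmse"]], mae = sc[["mae"]], table = tab)
}
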