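# Model fitting: PSO parameter estimation per (surface, model), AIC model
# selection, restart-dispersion confidence intervals and dependence calls.

# Batch surface prediction: P is an S x d matrix with columns named as in
# param_names(spec); returns S x 30 matrix of predicted PD. Exploits R's
# column-major recycling so per-particle exponents/constants broadcast down
# the dose dimension.
.predict_pd_batch <- function(spec, P, grid) {
  akt <- rep(grid$akt_doses, times = length(grid$mek_doses))
  mek <- rep(grid$mek_doses, each = length(grid$akt_doses))
  n <- nrow(P); m <- length(akt)
  A <- matrix(akt, n, m, byrow = TRUE)
  M <- matrix(mek, n, m, byrow = TRUE)

  hill_b <- function(Conc, tau, k) {
    CK <- Conc^k  # k length-n, recycled column-major = per particle
    CK / (tau + CK)
  }
  gate_b <- function(gate, pre) {
    cg <- function(f) P[, paste0(pre, f)]
    switch(gate,
      K  = matrix(1, n, m),
      OR = {
        S <- cg("w_akt") * A + cg("w_erk") * M
        SK <- S^cg("k")
        SK / (cg("tau") + SK)
      },
      AND = hill_b(A, cg("tau_akt"), cg("k_akt")) *
            hill_b(M, cg("tau_erk"), cg("k_erk")),
      stop("unknown gate", call. = FALSE))
  }
  if (spec$id == "M10") {
    f1 <- 1 - hill_b(M, P[, "f1_tau"], P[, "f1_k"])
    f2 <- hill_b(A, P[, "f2_tau"], P[, "f2_k"])
  } else {
    f1 <- gate_b(spec$f1_gate, "f1_")
    f2 <- gate_b(spec$f2_gate, "f2_")
  }
  P[, "mu_max"] * f1 - P[, "delta_max"] * f2
}

#' Mean-squared-error objective for a candidate parameter set
#'
#' @param p named parameter vector (see [param_names()]).
#' @param spec a `growth_model_spec`.
#' @param surface a [response_surface()].
#' @param scale `"pd"` compares population doublings directly; `"fold"`
#'   compares fold expansion `2^PD`.
#' @return mean over the 30 grid points of squared residuals.
#' @export
mse_objective <- function(p, spec, surface, scale = c("pd", "fold")) {
  scale <- match.arg(scale)
  pred <- predict_pd(spec, p, surface$grid)
  if (!all(dim(pred) == dim(surface$pd))) {
    stop("mse_objective: dimension mismatch", call. = FALSE)
  }
  obs <- surface$pd
  if (scale == "fold") { pred <- 2^pred; obs <- 2^obs }
  mean((obs - pred)^2)
}

#' PSO fitting configuration
#'
#' Defaults follow standard constriction-coefficient PSO (inertia 0.729,
#' cognitive = social = 1.494) with a swarm of 40 over 300 iterations, and
#' the 100-restart protocol used for confidence intervals. Half-effect
#' constants and pathway weights are searched in log10 space.
#'
#' @param swarm_size,iterations swarm size and PSO iterations per restart.
#' @param inertia,cognitive,social PSO coefficients.
#' @param n_restarts independent restarts (`>= 2`; the point estimate is the
#'   best-MSE restart, the CI comes from the restart distribution).
#' @param seed integer seed; restart seeds are derived from it.
#' @param objective_scale `"pd"` or `"fold"`.
#' @param bounds optional named list of `c(lo, hi)` overriding the default
#'   search box.
#' @return a `fit_config` list.
#' @export
fit_config <- function(swarm_size = 40L, iterations = 300L,
                       inertia = 0.729, cognitive = 1.494, social = 1.494,
                       n_restarts = 100L, seed = 1L,
                       objective_scale = c("pd", "fold"), bounds = NULL) {
  if (n_restarts < 2) stop("fit_config: n_restarts must be >= 2 (CI needs a SD)",
                           call. = FALSE)
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 inertia = inertia, cognitive = cognitive, social = social,
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 objective_scale = match.arg(objective_scale),
                 bounds = bounds),
            class = "fit_config")
}

# Default search box per parameter role. Weights and taus are log-spaced;
# mu/delta span the observed PD range (~0-5 doublings/96 h) with margin.
.param_bounds <- function(pname) {
  base <- sub("^f[12]_", "", pname)
  if (base == "mu_max")            c(1e-6, 8)
  else if (base == "delta_max")    c(1e-6, 12)
  else if (base %in% c("w_akt", "w_erk")) c(1e-2, 1e2)
  else if (grepl("^tau", base))    c(1e-3, 1e3)
  else if (grepl("^k", base))      c(0.3, 4)
  else stop("no default bounds for ", pname, call. = FALSE)
}

.param_log <- function(pname) {
  base <- sub("^f[12]_", "", pname)
  grepl("^tau", base) || base %in% c("w_akt", "w_erk")
}

#' Fit a growth model to a response surface by particle swarm optimisation
#'
#' Runs `n_restarts` independently seeded PSO searches; the reported
#' parameter set is the best restart by MSE and the full restart set is kept
#' for restart-dispersion confidence intervals. AIC uses the MSE floored at
#' `1e-6` so perfect synthetic fits stay finite.
#'
#' @inheritParams mse_objective
#' @param cfg a [fit_config()].
#' @return a `growth_model_fit` list: `spec`, `best_params`, `mse`, `aic`,
#'   `restart_params` (matrix, one row per restart), `restart_mse`, `bias`,
#'   `bias_ci` (NULL for variants without an OR gate), `cell_id`, `hrg`.
#' @export
fit_pso <- function(spec, surface, cfg = fit_config()) {
  pn <- param_names(spec)
  lo <- vapply(pn, function(p) .param_bounds(p)[1], 0)
  hi <- vapply(pn, function(p) .param_bounds(p)[2], 0)
  if (!is.null(cfg$bounds)) {
    for (p in names(cfg$bounds)) { lo[p] <- cfg$bounds[[p]][1]; hi[p] <- cfg$bounds[[p]][2] }
  }
  logs <- vapply(pn, .param_log, FALSE)
  obs <- surface$pd
  if (cfg$objective_scale == "fold") obs <- 2^obs
  obs_vec <- as.vector(obs)
  fn <- function(P) {
    pred <- .predict_pd_batch(spec, P, surface$grid)
    if (cfg$objective_scale == "fold") pred <- 2^pred
    rowMeans(sweep(pred, 2, obs_vec)^2)
  }
  restart_seeds <- .derive_seeds(cfg$seed, cfg$n_restarts)
  pars <- matrix(NA_real_, cfg$n_restarts, length(pn),
                 dimnames = list(NULL, pn))
  mses <- numeric(cfg$n_restarts)
  for (r in seq_len(cfg$n_restarts)) {
    res <- withr::with_seed(restart_seeds[r],
      pso_minimize(fn, lo, hi, logs,
                   swarm = cfg$swarm_size, iterations = cfg$iterations,
                   inertia = cfg$inertia, cognitive = cfg$cognitive,
                   social = cfg$social))
    pars[r, ] <- res$par
    mses[r] <- res$value
  }
  best <- which.min(mses)
  best_p <- pars[best, ]
  wk <- .weight_cols(spec)
  bias <- if (!is.null(wk)) pathway_bias(best_p[wk[1]], best_p[wk[2]]) else NA_real_
  ci <- if (!is.null(wk)) bias_ci(pars) else NULL
  structure(list(spec = spec, best_params = best_p,
                 mse = mses[best],
                 aic = aic(spec$param_count, length(obs_vec),
                           max(mses[best], 1e-6)),
                 restart_params = pars, restart_mse = mses,
                 bias = bias, bias_ci = ci,
                 cell_id = surface$cell_id, hrg = surface$hrg),
            class = "growth_model_fit")
}

# OR-gate weight columns used for Pathway Bias (survival gate preferred).
.weight_cols <- function(spec) {
  if (spec$f2_gate == "OR") c("f2_w_akt", "f2_w_erk")
  else if (spec$f1_gate == "OR") c("f1_w_akt", "f1_w_erk")
  else NULL
}

.derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Akaike Information Criterion (log10 form)
#'
#' `AIC = 2 * P + N * log10(MSE)`, with `P` the number of free parameters
#' (2-10 across the model catalog) and `N` the number of measurements (30
#' per surface).
#'
#' @param P parameter count.
#' @param N measurement count.
#' @param mse mean squared error, `> 0`.
#' @export
aic <- function(P, N, mse) {
  if (any(mse <= 0)) {
    stop("aic: mse must be > 0 (floor perfect fits before calling)",
         call. = FALSE)
  }
  2 * P + N * log10(mse)
}

#' Select the best model variant by AIC
#'
#' @param fits list of `growth_model_fit` objects for one surface.
#' @return list with `best` (winning model id) and `table` (data.frame
#'   ranked by AIC; ties broken by smaller parameter count, then id).
#' @export
select_model <- function(fits) {
  if (length(fits) < 2) stop("select_model: need >= 2 fits", call. = FALSE)
  tab <- data.frame(
    model_id = vapply(fits, function(f) f$spec$id, ""),
    P = vapply(fits, function(f) as.integer(f$spec$param_count), 0L),
    mse = vapply(fits, function(f) f$mse, 0),
    aic = vapply(fits, function(f) f$aic, 0),
    stringsAsFactors = FALSE)
  ord <- order(tab$aic, tab$P, tab$model_id)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  list(best = tab$model_id[1], table = tab)
}

#' Restart-dispersion confidence interval for Pathway Bias
#'
#' Computes the bias for every restart's parameter set and returns the mean
#' with a 2-standard-deviation interval. The interval is clipped to
#' `[-1, 1]` for reporting (bias is bounded); the unclipped bounds are kept
#' since the zero-crossing test is defined pre-clipping.
#'
#' @param restart_params matrix of restart parameter sets (from
#'   [fit_pso()]) or a numeric vector of per-restart biases.
#' @return list `(bias, lo, hi, raw_lo, raw_hi, sd, biases)`.
#' @export
bias_ci <- function(restart_params) {
  if (is.matrix(restart_params)) {
    wk <- grep("w_akt$", colnames(restart_params), value = TRUE)
    if (!length(wk)) stop("bias_ci: no pathway weights in parameter set",
                          call. = FALSE)
    pre <- sub("w_akt$", "", wk[length(wk)])  # prefer f2_
    b <- pathway_bias(restart_params[, paste0(pre, "w_akt")],
                      restart_params[, paste0(pre, "w_erk")])
  } else b <- restart_params
  if (length(b) < 2) stop("bias_ci: need >= 2 restarts", call. = FALSE)
  m <- mean(b); s <- stats::sd(b)
  list(bias = m, lo = max(m - 2 * s, -1), hi = min(m + 2 * s, 1),
       raw_lo = m - 2 * s, raw_hi = m + 2 * s, sd = s, biases = b)
}

#' Coefficient of variation of restart estimates, in percent
#'
#' @param values numeric vector with non-zero mean.
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (m == 0) stop("coefficient_of_variation: zero mean", call. = FALSE)
  100 * stats::sd(values) / abs(m)
}

#' Classify a cell line's pathway dependence from its two bias estimates
#'
#' A line is UNDETERMINED when either condition's 95% CI (mean +/- 2 SD over
#' restarts, pre-clipping) crosses zero; otherwise PI3K when both biases are
#' positive, MAPK when both negative, and SWITCH when the sign flips between
#' the unstimulated and heregulin-stimulated conditions (the observed
#' direction is PI3K without HRG to MAPK with HRG; the reverse is also
#' labelled SWITCH with `direction = "MAPK_to_PI3K"`).
#'
#' @param bias_fbs,bias_hrg point biases for the -HRG and +HRG conditions.
#' @param ci_fbs,ci_hrg length-2 `(lo, hi)` intervals (or [bias_ci()] lists).
#' @param cell_id optional identifier carried through.
#' @return a `dependence_call` list with fields `cell_id`, `call`,
#'   `direction`, `bias_fbs`, `bias_hrg`, `ci_fbs`, `ci_hrg`.
#' @export
classify_dependence <- function(bias_fbs, ci_fbs, bias_hrg, ci_hrg,
                                cell_id = NA_character_) {
  as_iv <- function(ci) {
    if (is.list(ci)) c(if (!is.null(ci$raw_lo)) ci$raw_lo else ci$lo,
                       if (!is.null(ci$raw_hi)) ci$raw_hi else ci$hi)
    else ci
  }
  iv_f <- as_iv(ci_fbs); iv_h <- as_iv(ci_hrg)
  crosses <- function(iv) iv[1] <= 0 && iv[2] >= 0
  direction <- NA_character_
  call <- if (crosses(iv_f) || crosses(iv_h)) "UNDETERMINED"
  else if (bias_fbs > 0 && bias_hrg > 0) "PI3K"
  else if (bias_fbs < 0 && bias_hrg < 0) "MAPK"
  else {
    direction <- if (bias_fbs > 0) "PI3K_to_MAPK" else "MAPK_to_PI3K"
    "SWITCH"
  }
  structure(list(cell_id = cell_id, call = call, direction = direction,
                 bias_fbs = bias_fbs, bias_hrg = bias_hrg,
                 ci_fbs = iv_f, ci_hrg = iv_h),
            class = "dependence_call")
}

#' Serialise fit results
#'
#' One CSV row per (surface, model): identifiers, every parameter, MSE, AIC,
#' bias and its clipped CI. `write_fits_json` additionally stores the full
#' restart distributions.
#'
#' @param fits list of `growth_model_fit` objects.
#' @param file output path.
#' @export
write_fits <- function(fits, file) {
  rows <- lapply(fits, function(f) {
    p <- as.list(f$best_params)
    names(p) <- paste0("par_", names(p))
    c(list(cell_id = f$cell_id, hrg = as.integer(f$hrg),
           model_id = f$spec$id), p,
      list(mse = f$mse, aic = f$aic, bias = f$bias,
           bias_lo = if (is.null(f$bias_ci)) NA else f$bias_ci$lo,
           bias_hi = if (is.null(f$bias_ci)) NA else f$bias_ci$hi))
  })
  cols <- unique(unlist(lapply(rows, names)))
  df <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(cols, names(r))] <- NA
    as.data.frame(r[cols], stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_fits
#' @export
write_fits_json <- function(fits, file) {
  out <- lapply(fits, function(f) {
    list(cell_id = f$cell_id, hrg = f$hrg, model_id = f$spec$id,
         best_params = as.list(f$best_params), mse = f$mse, aic = f$aic,
         bias = f$bias,
         bias_ci = if (is.null(f$bias_ci)) NULL else
           f$bias_ci[c("bias", "lo", "hi", "raw_lo", "raw_hi")],
         restart_params = apply(f$restart_params, 1, as.list),
         restart_mse = f$restart_mse)
  })
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
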