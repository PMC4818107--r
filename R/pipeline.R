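# Full pipeline: simulate/load -> fit growth models -> select -> bias ->
# dependence calls -> classifier evaluation -> screen + enrichment, with
# reproducible configuration and provenance.

#' Pipeline run configuration
#'
#' A run is reproducible from this object plus the inputs alone: every
#' source of randomness derives from `seed`.
#'
#' @param seed master integer seed.
#' @param recipe a [panel_recipe()]; its seed is overridden by `seed`.
#' @param fit a [fit_config()]; its seed is likewise derived.
#' @param models model ids to fit (fitting all ten is expensive; the
#'   default fits the selection-relevant OR-gate model plus the null).
#' @param feature_sets feature sets to evaluate by LOOCV + permutation.
#' @param B permutations per feature set.
#' @param alpha screen hit threshold.
#' @param effect_filter optional screen effect-size filter.
#' @param screen_spec arguments for [simulate_screen()].
#' @param use_fitted_bias label panel samples with fitted (rather than
#'   generating) biases before classification.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, recipe = panel_recipe(),
                       fit = fit_config(n_restarts = 20L),
                       models = c("M1", "M4"),
                       feature_sets = c("3BM", "PAKT_PERK"),
                       B = 1000L, alpha = 0.05, effect_filter = NULL,
                       screen_spec = list(), use_fitted_bias = TRUE) {
  structure(list(seed = as.integer(seed), recipe = recipe, fit = fit,
                 models = models, feature_sets = feature_sets,
                 B = as.integer(B), alpha = alpha,
                 effect_filter = effect_filter, screen_spec = screen_spec,
                 use_fitted_bias = use_fitted_bias),
            class = "run_config")
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(.config_echo(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.config_echo <- function(cfg) {
  rapply(unclass(cfg), function(x) x, how = "list")
}

#' Run the full synthetic-data pipeline
#'
#' Simulates (or loads) the panel, fits the configured growth-model
#' variants to every surface, selects per surface by AIC, derives Pathway
#' Bias with restart CIs and a dependence call per line, evaluates each
#' feature set by LOOCV with permutation significance, and runs the
#' stratified screen with canonical enrichment (using the first five
#' planted columns as the stand-in canonical set). When `out_dir` is given,
#' writes CSV/JSON outputs plus a structured log carrying the seed and a
#' config hash.
#'
#' @param cfg a [run_config()].
#' @param surfaces,panel optional pre-loaded inputs (from
#'   [read_surfaces()] / [read_panel()]); when `NULL`, synthesised.
#' @param out_dir optional output directory.
#' @return a report bundle: `fits`, `selection`, `calls`, `classifier`,
#'   `screen`, `enrichment`, `panel`, `config_hash`.
#' @export
run_pipeline <- function(cfg = run_config(), surfaces = NULL, panel = NULL,
                         out_dir = NULL) {
  seeds <- .derive_seeds(cfg$seed, 4L)
  if (is.null(surfaces) || is.null(panel)) {
    cfg$recipe$seed <- seeds[1]
    sim <- simulate_panel(cfg$recipe)
    surfaces <- sim$surfaces
    panel <- sim$panel
  }

  # -- fit stage -----------------------------------------------------------
  fit_seeds <- .derive_seeds(seeds[2], length(surfaces) * length(cfg$models))
  fits <- list()
  selection <- list()
  k <- 0L
  for (s in surfaces) {
    per_model <- list()
    for (mid in cfg$models) {
      k <- k + 1L
      fc <- cfg$fit
      fc$seed <- fit_seeds[k]
      f <- tryCatch(fit_pso(model_spec(mid), s, fc), error = function(e)
        stop("fit stage failed for ", surface_key(s), " ", mid, ": ",
             conditionMessage(e), call. = FALSE))
      per_model[[mid]] <- f
      fits[[paste(surface_key(s), mid, sep = "|")]] <- f
    }
    if (length(per_model) >= 2) {
      selection[[surface_key(s)]] <- select_model(per_model)
    }
  }

  # -- bias + dependence calls --------------------------------------------
  bias_model <- if ("M4" %in% cfg$models) "M4" else cfg$models[1]
  cells <- unique(vapply(surfaces, function(s) s$cell_id, ""))
  calls <- lapply(cells, function(cid) {
    f0 <- fits[[paste0(cid, ":0|", bias_model)]]
    f1 <- fits[[paste0(cid, ":1|", bias_model)]]
    if (is.null(f0) || is.null(f1)) return(NULL)
    classify_dependence(f0$bias, f0$bias_ci, f1$bias, f1$bias_ci, cid)
  })
  names(calls) <- cells
  calls <- calls[!vapply(calls, is.null, TRUE)]

  # -- classifier stage ----------------------------------------------------
  if (cfg$use_fitted_bias && length(fits)) {
    fitted_bias <- vapply(panel$sample_id, function(sid) {
      f <- fits[[paste(sid, bias_model, sep = "|")]]
      if (is.null(f)) NA_real_ else f$bias
    }, 0)
    ok <- !is.na(fitted_bias) & fitted_bias != 0
    panel$bias[ok] <- fitted_bias[ok]
    panel$class_label[ok] <- sign(fitted_bias[ok])
  }
  cls_seeds <- .derive_seeds(seeds[3], length(cfg$feature_sets))
  classifier <- lapply(seq_along(cfg$feature_sets), function(i) {
    permutation_test(panel, cfg$feature_sets[i], B = cfg$B,
                     seed = cls_seeds[i])
  })
  names(classifier) <- cfg$feature_sets

  # -- screen stage --------------------------------------------------------
  scr_args <- cfg$screen_spec
  scr_args$seed <- seeds[4]
  scr <- do.call(simulate_screen, scr_args)
  screen <- differential_sensitivity_screen(scr$matrix, scr$strat,
                                            alpha = cfg$alpha,
                                            effect_filter = cfg$effect_filter)
  enrichment <- canonical_enrichment(screen,
                                     canonical_ids = utils::head(scr$planted, 5))

  bundle <- list(fits = fits, selection = selection, calls = calls,
                 classifier = classifier, screen = screen,
                 enrichment = enrichment, panel = panel,
                 config_hash = .config_hash(cfg), seed = cfg$seed)

  if (!is.null(out_dir)) .write_bundle(bundle, cfg, out_dir)
  bundle
}

.write_bundle <- function(bundle, cfg, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_fits(bundle$fits, file.path(out_dir, "fits.csv"))
  write_panel(bundle$panel, file.path(out_dir, "panel.csv"))
  calls_df <- do.call(rbind, lapply(bundle$calls, function(d) {
    data.frame(cell_id = d$cell_id, call = d$call,
               direction = ifelse(is.na(d$direction), "", d$direction),
               bias_fbs = d$bias_fbs, bias_hrg = d$bias_hrg,
               fbs_lo = d$ci_fbs[1], fbs_hi = d$ci_fbs[2],
               hrg_lo = d$ci_hrg[1], hrg_hi = d$ci_hrg[2])
  }))
  utils::write.csv(calls_df, file.path(out_dir, "dependence_calls.csv"),
                   row.names = FALSE)
  cls <- lapply(bundle$classifier, function(r) {
    list(feature_set = r$feature_set, accuracy = r$accuracy,
         pearson = r$pearson, mse = r$mse,
         p_values = as.list(r$p_values))
  })
  log <- list(seed = bundle$seed, config_hash = bundle$config_hash,
              config = .config_echo(cfg),
              r_version = as.character(getRversion()),
              classifier = cls,
              screen = list(n_total = bundle$screen$n_total,
                            n_hits = bundle$screen$n_hits,
                            alpha = bundle$screen$alpha),
              enrichment = unclass(bundle$enrichment))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(bundle$screen$stats, file.path(out_dir, "screen.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
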