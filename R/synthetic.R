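# Synthetic data generation: dose-response surfaces from known gate models,
# biomarker panels with the qualitative class structure of the HER2+ cell
# line panel, and sensitivity matrices with planted differential columns.

#' Default 5 x 6 dose-combination grid
#'
#' 3-fold dilution series down from 1 uM on the AKT-inhibitor axis and
#' 10 uM on the MEK-inhibitor axis, each including the untreated control.
#'
#' @return a [dose_grid()].
#' @export
make_dose_grid <- function() dose_grid()

#' Simulate a noisy response surface from a known model
#'
#' @param spec a `growth_model_spec`.
#' @param params named parameter vector for `spec`.
#' @param grid a [dose_grid()].
#' @param noise_sd iid Gaussian observation noise, in population doublings
#'   per 96 h (0 gives the exact model surface).
#' @param seed integer seed.
#' @param cell_id,hrg identifiers for the resulting surface.
#' @return list with `surface` ([response_surface()]) and `truth`
#'   (generating spec id, parameters, true bias where defined).
#' @export
simulate_surface <- function(spec, params, grid = dose_grid(),
                             noise_sd = 0.25, seed = 1L,
                             cell_id = "SIM", hrg = FALSE) {
  mu_pd <- predict_pd(spec, params, grid)
  pd <- if (noise_sd > 0) {
    withr::with_seed(seed,
      mu_pd + matrix(stats::rnorm(length(mu_pd), 0, noise_sd),
                     nrow(mu_pd), ncol(mu_pd)))
  } else mu_pd
  wk <- .weight_cols(spec)
  list(surface = response_surface(cell_id, hrg, pd, grid),
       truth = list(model_id = spec$id, params = params,
                    bias = if (!is.null(wk))
                      pathway_bias(params[[wk[1]]], params[[wk[2]]])
                    else NA_real_))
}

#' Recipe for a synthetic cell-line panel
#'
#' Defaults encode the stated world of the emulated panel: 18 HER2+ lines
#' split 5 PI3K-dependent : 9 MAPK-dependent : 4 SWITCH, each assayed with
#' and without heregulin (36 samples); observation noise 0.25 PD; protein
#' signals log-normal (base-10 location 3.0, scale 0.3, arbitrary
#' Luminex-like units) with class-conditional shifts of +1 log10 for EGFR in
#' MAPK-dependent lines and +0.7 / +0.5 log10 for ERBB3 / CDKN1B in
#' PI3K-dependent (and SWITCH) lines; pAKT, pERK and total proteins drawn
#' independently of class; PI3K-pathway mutation probability 0.8 in the
#' PI3K class vs 0.3 otherwise; breast tissue for PI3K and SWITCH lines.
#'
#' @param n_lines number of cell lines.
#' @param class_mix proportions over (PI3K, MAPK, SWITCH).
#' @param noise_sd PD observation noise (doublings / 96 h).
#' @param feature_effects named list of log10 mean shifts.
#' @param mut_prob `c(pi3k_class, other)` PI3K-pathway mutation rates.
#' @param signal_loc,signal_scale log10 location/scale of baseline signals.
#' @param seed integer seed.
#' @return a `panel_recipe` list.
#' @export
panel_recipe <- function(n_lines = 18L,
                         class_mix = c(PI3K = 5, MAPK = 9, SWITCH = 4) / 18,
                         noise_sd = 0.25,
                         feature_effects = list(EGFR_mapk = 1,
                                                ERBB3_pi3k = 0.7,
                                                CDKN1B_pi3k = 0.5),
                         mut_prob = c(0.8, 0.3),
                         signal_loc = 3.0, signal_scale = 0.3,
                         seed = 1L) {
  if (abs(sum(class_mix) - 1) > 1e-8) {
    stop("panel_recipe: class_mix must sum to 1", call. = FALSE)
  }
  if (noise_sd < 0 || signal_scale <= 0) {
    stop("panel_recipe: noise_sd >= 0 and signal_scale > 0 required",
         call. = FALSE)
  }
  structure(list(n_lines = as.integer(n_lines), class_mix = class_mix,
                 noise_sd = noise_sd, feature_effects = feature_effects,
                 mut_prob = mut_prob, signal_loc = signal_loc,
                 signal_scale = signal_scale, seed = as.integer(seed)),
            class = "panel_recipe")
}

# Largest-remainder apportionment of n_lines over the class mix, so the
# default recipe yields exactly 5/9/4.
.class_counts <- function(n, mix) {
  raw <- n * mix
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(cnt), names(mix))
}

# One M4 parameter draw with the dominant pathway's weight in [3, 10] and
# the other in [0.1, 0.5]; proliferative (MAPK-like) lines grow faster.
.draw_m4 <- function(intrinsic, dominant) {
  runif1 <- function(lo, hi) stats::runif(1, lo, hi)
  w_hi <- 10^runif1(log10(3), 1)
  w_lo <- runif1(0.1, 0.5)
  mu <- if (intrinsic == "MAPK") runif1(3, 5) else runif1(1.5, 3.5)
  m4_params(mu_max = mu, delta_max = runif1(3, 8),
            w_akt = if (dominant == "PI3K") w_hi else w_lo,
            w_erk = if (dominant == "PI3K") w_lo else w_hi,
            k = runif1(1, 2.5), tau = 10^runif1(-0.5, 0.5))
}

#' Simulate a full cell-line panel: surfaces, biomarkers and ground truth
#'
#' Each line draws a dependence class, then per-condition M4 parameter sets:
#' PI3K lines have `w_akt >> w_erk` in both conditions, MAPK lines the
#' reverse, and SWITCH lines are PI3K-like without heregulin with the
#' weights swapped under stimulation. Biomarker shifts follow the line's
#' intrinsic (unstimulated) class, so the heregulin-induced switch is by
#' construction invisible to the protein features.
#'
#' @param recipe a [panel_recipe()].
#' @return list with `surfaces` (named list of [response_surface()]),
#'   `panel` (data.frame, one row per sample), `truth` (data.frame with
#'   generating parameters, true bias and class per sample), `screen`
#'   components being generated separately.
#' @export
simulate_panel <- function(recipe = panel_recipe()) {
  counts <- .class_counts(recipe$n_lines, recipe$class_mix)
  classes <- rep(names(counts), counts)
  fx <- recipe$feature_effects
  withr::with_seed(recipe$seed, {
    classes <- sample(classes)
    surfaces <- list()
    rows <- list()
    truth <- list()
    grid <- dose_grid()
    for (i in seq_len(recipe$n_lines)) {
      cl <- classes[i]
      cell <- sprintf("LINE%02d", i)
      intrinsic <- if (cl == "MAPK") "MAPK" else "PI3K"
      breast <- as.integer(cl %in% c("PI3K", "SWITCH"))
      mut <- stats::rbinom(1, 1, recipe$mut_prob[
        if (cl == "PI3K") 1 else 2]) == 1
      mut_gene <- if (mut) sample(c("pik3ca", "pten", "pik3r1"), 1,
                                  prob = c(0.6, 0.3, 0.1)) else NA
      for (hrg in c(FALSE, TRUE)) {
        dominant <- switch(cl,
          PI3K = "PI3K", MAPK = "MAPK",
          SWITCH = if (hrg) "MAPK" else "PI3K")
        p <- .draw_m4(intrinsic, dominant)
        true_bias <- pathway_bias(p[["f2_w_akt"]], p[["f2_w_erk"]])
        mu_pd <- predict_pd(model_spec("M4"), p, grid)
        pd <- mu_pd + matrix(stats::rnorm(length(mu_pd), 0, recipe$noise_sd),
                             nrow(mu_pd), ncol(mu_pd))
        s <- response_surface(cell, hrg, pd, grid)
        surfaces[[surface_key(s)]] <- s
        sig <- function(shift = 0) {
          10^stats::rnorm(1, recipe$signal_loc + shift, recipe$signal_scale)
        }
        rows[[surface_key(s)]] <- data.frame(
          sample_id = surface_key(s), cell_id = cell, hrg = as.integer(hrg),
          EGFR   = sig(if (intrinsic == "MAPK") fx$EGFR_mapk else 0),
          ERBB3  = sig(if (intrinsic == "PI3K") fx$ERBB3_pi3k else 0),
          CDKN1B = sig(if (intrinsic == "PI3K") fx$CDKN1B_pi3k else 0),
          pAKT = sig(), pERK = sig(), AKT_total = sig(), ERK_total = sig(),
          ERBB2 = sig(),
          proliferation_pd = p[["mu_max"]],
          tissue_breast = breast,
          pik3ca_mut = as.integer(identical(mut_gene, "pik3ca")),
          pten_mut = as.integer(identical(mut_gene, "pten")),
          pik3r1_mut = as.integer(identical(mut_gene, "pik3r1")),
          bias = true_bias, class_label = as.numeric(sign(true_bias)),
          stringsAsFactors = FALSE)
        truth[[surface_key(s)]] <- data.frame(
          sample_id = surface_key(s), cell_id = cell, hrg = as.integer(hrg),
          line_class = cl, model_id = "M4",
          t(p), true_bias = true_bias, stringsAsFactors = FALSE)
      }
    }
    panel <- do.call(rbind, rows)
    rownames(panel) <- NULL
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(surfaces = surfaces, panel = panel, truth = truth, recipe = recipe)
  })
}

#' Simulate a sensitivity matrix with planted differential columns
#'
#' Null columns are iid standard normal over all rows; in planted columns
#' the high-stratum rows are shifted by `effect_size` standard deviations.
#'
#' @param n_rows cell lines (default the two group sizes combined).
#' @param n_cols total agents/genes.
#' @param n_planted truly differential columns.
#' @param effect_size mean shift in SD units.
#' @param group_sizes `c(hi, lo)` stratum sizes (first rows are hi).
#' @param seed integer seed.
#' @return list `(matrix, strat, planted)`; `strat` has row-id vectors
#'   `hi`/`lo` and a provenance `rule`.
#' @export
simulate_screen <- function(n_rows = sum(group_sizes), n_cols = 500L,
                            n_planted = 50L, effect_size = 2,
                            group_sizes = c(10L, 10L), seed = 1L) {
  if (n_planted > n_cols) stop("simulate_screen: n_planted > n_cols",
                               call. = FALSE)
  if (n_rows < sum(group_sizes)) {
    stop("simulate_screen: n_rows smaller than the strata", call. = FALSE)
  }
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols,
                dimnames = list(sprintf("CELL%03d", seq_len(n_rows)),
                                sprintf("GENE%04d", seq_len(n_cols))))
    planted <- sort(sample(colnames(m), n_planted))
    hi_rows <- rownames(m)[seq_len(group_sizes[1])]
    lo_rows <- rownames(m)[group_sizes[1] + seq_len(group_sizes[2])]
    m[hi_rows, planted] <- m[hi_rows, planted] + effect_size
    list(matrix = m,
         strat = list(hi = hi_rows, lo = lo_rows,
                      rule = sprintf("synthetic %dv%d, %d planted at %g SD",
                                     group_sizes[1], group_sizes[2],
                                     n_planted, effect_size)),
         planted = planted)
  })
}

#' Export a complete synthetic fixture to plain-text files
#'
#' Writes `surfaces.csv`, `panel.csv`, `screen.csv` and `truth.json` so the
#' whole pipeline can be exercised from files; re-importing round-trips the
#' stored values.
#'
#' @param dir output directory (created if needed).
#' @param sim a [simulate_panel()] result.
#' @param screen optional [simulate_screen()] result.
#' @return invisible named vector of file paths.
#' @export
export_fixture <- function(dir, sim = simulate_panel(),
                           screen = simulate_screen()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(surfaces = file.path(dir, "surfaces.csv"),
             panel = file.path(dir, "panel.csv"),
             screen = file.path(dir, "screen.csv"),
             truth = file.path(dir, "truth.json"))
  write_surfaces(sim$surfaces, paths["surfaces"])
  write_panel(sim$panel, paths["panel"])
  write_matrix(screen$matrix, paths["screen"])
  jsonlite::write_json(list(truth = sim$truth, strat = screen$strat,
                            planted = screen$planted),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
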