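#' Logic gates for growth-model regulatory functions
#'
#' The growth models describe net population doublings over a 96 h assay as
#' `PD = mu_max * f1(A, M) - delta_max * f2(A, M)`, where `A` and `M` are AKT
#' and MEK inhibitor concentrations (uM) used as surrogates for PI3K/AKT and
#' MAPK/ERK pathway activity. Each regulatory function `f1` (proliferation)
#' and `f2` (death) is one of three gates: the null gate `K = 1`, an OR gate
#' (saturating Hill function of the weighted dose sum), or an AND gate
#' (product of two single-input Hill terms).
#'
#' @param akt_conc,mek_conc inhibitor concentrations in uM, `>= 0`.
#' @param p named numeric parameter vector; see [param_names()] for the
#'   fields each gate requires.
#' @return gate activation in `[0, 1)` (`k_gate` returns exactly 1).
#' @name gates
NULL

#' @rdname gates
#' @export
k_gate <- function() 1

#' @rdname gates
#' @export
or_gate <- function(akt_conc, mek_conc, p) {
  .check_conc(akt_conc, mek_conc)
  .check_pos(p, c("tau", "k"))
  .check_nonneg(p, c("w_akt", "w_erk"))
  s <- p[["w_akt"]] * akt_conc + p[["w_erk"]] * mek_conc
  sk <- s^p[["k"]]
  sk / (p[["tau"]] + sk)
}

#' @rdname gates
#' @export
and_gate <- function(akt_conc, mek_conc, p) {
  .check_conc(akt_conc, mek_conc)
  .check_pos(p, c("tau_akt", "tau_erk", "k_akt", "k_erk"))
  hill1(akt_conc, p[["tau_akt"]], p[["k_akt"]]) *
    hill1(mek_conc, p[["tau_erk"]], p[["k_erk"]])
}

#' Single-input Hill activation
#'
#' `conc^k / (tau + conc^k)`. Note the denominator is `tau + conc^k`
#' (not `tau^k + conc^k`): `tau` absorbs the concentration scale and has
#' units of uM^k.
#'
#' @param conc concentration (uM), `>= 0`.
#' @param tau half-effect constant, `> 0`.
#' @param k Hill coefficient, `> 0`.
#' @return activation in `[0, 1)`.
#' @export
hill1 <- function(conc, tau, k) {
  if (any(conc < 0)) stop("hill1: concentration must be >= 0", call. = FALSE)
  if (any(tau <= 0) || any(k <= 0)) {
    stop("hill1: tau and k must be > 0", call. = FALSE)
  }
  ck <- conc^k
  ck / (tau + ck)
}

.check_conc <- function(a, m) {
  if (any(a < 0) || any(m < 0)) {
    stop("gate: concentrations must be >= 0", call. = FALSE)
  }
}

.check_pos <- function(p, fields) {
  miss <- setdiff(fields, names(p))
  if (length(miss)) {
    stop("gate: missing parameters: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- fields[unlist(p[fields]) <= 0]
  if (length(bad)) {
    stop("gate: parameters must be > 0: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
}

.check_nonneg <- function(p, fields) {
  miss <- setdiff(fields, names(p))
  if (length(miss)) {
    stop("gate: missing parameters: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- fields[unlist(p[fields]) < 0]
  if (length(bad)) {
    stop("gate: parameters must be >= 0: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
}

# ---------------------------------------------------------------------------
# Model catalog

.GATE_PARAMS <- list(
  K     = character(0),
  OR    = c("w_akt", "w_erk", "k", "tau"),
  AND   = c("tau_akt", "tau_erk", "k_akt", "k_erk"),
  HILL1 = c("tau", "k")
)

#' The ten growth-model variants
#'
#' M1--M9 enumerate all pairs of proliferation gate `f1` and death gate `f2`
#' over \{K, OR, AND\} (f1 varies fastest), so M1 = (K, K) is the dose-blind
#' null with 2 parameters and M4 = (K, OR) is the OR-gate-on-survival model
#' used for Pathway Bias. M10 splits regulation by pathway: proliferation is
#' shut off by MEK inhibitor through a single-input Hill term and death is
#' driven by AKT inhibitor through another,
#' `PD = mu_max * (1 - hill1(M)) - delta_max * hill1(A)`.
#'
#' @param id model id, `"M1"` .. `"M10"`.
#' @return for `model_spec`, a list with fields `id`, `f1_gate`, `f2_gate`,
#'   `param_count` and `param_names`; `model_catalog()` returns the list of
#'   all ten specs.
#' @export
model_spec <- function(id) {
  catalog <- model_catalog()
  m <- catalog[[id]]
  if (is.null(m)) stop("unknown model id: ", id, call. = FALSE)
  m
}

#' @rdname model_spec
#' @export
model_catalog <- function() {
  gates <- c("K", "OR", "AND")
  specs <- list()
  i <- 0L
  for (f2 in gates) {
    for (f1 in gates) {
      i <- i + 1L
      specs[[paste0("M", i)]] <- .make_spec(paste0("M", i), f1, f2)
    }
  }
  specs[["M10"]] <- .make_spec("M10", "HILL1", "HILL1")
  specs
}

.make_spec <- function(id, f1, f2) {
  pn <- c("mu_max", "delta_max",
          if (length(.GATE_PARAMS[[f1]])) paste0("f1_", .GATE_PARAMS[[f1]]),
          if (length(.GATE_PARAMS[[f2]])) paste0("f2_", .GATE_PARAMS[[f2]]))
  structure(list(id = id, f1_gate = f1, f2_gate = f2,
                 param_count = length(pn), param_names = pn),
            class = "growth_model_spec")
}

#' @rdname model_spec
#' @param spec a `growth_model_spec`.
#' @export
param_names <- function(spec) spec$param_names

#' Build an M4 parameter vector from the conventional names
#'
#' Convenience constructor for the OR-gate-on-survival model: the survival
#' gate's parameters are given with their unprefixed field names.
#'
#' @param mu_max,delta_max maximal proliferation and death rates
#'   (doublings / 96 h, `>= 0`).
#' @param w_akt,w_erk dimensionless pathway weights (`>= 0`, not both 0).
#' @param k OR-gate Hill coefficient (`> 0`).
#' @param tau OR-gate half-effect constant (`> 0`).
#' @return named numeric vector in M4's canonical parameter order.
#' @export
m4_params <- function(mu_max, delta_max, w_akt, w_erk, k, tau) {
  c(mu_max = mu_max, delta_max = delta_max,
    f2_w_akt = w_akt, f2_w_erk = w_erk, f2_k = k, f2_tau = tau)
}

.gate_eval <- function(gate, prefix, p, akt, mek, which_conc) {
  sub <- function(f) p[[paste0(prefix, f)]]
  switch(gate,
    K   = rep(1, length(akt)),
    OR  = or_gate(akt, mek, list(w_akt = sub("w_akt"), w_erk = sub("w_erk"),
                                 k = sub("k"), tau = sub("tau"))),
    AND = and_gate(akt, mek, list(tau_akt = sub("tau_akt"),
                                  tau_erk = sub("tau_erk"),
                                  k_akt = sub("k_akt"),
                                  k_erk = sub("k_erk"))),
    HILL1 = hill1(if (which_conc == "akt") akt else mek, sub("tau"), sub("k")),
    stop("unknown gate: ", gate, call. = FALSE)
  )
}

#' Predict a population-doubling response surface
#'
#' Evaluates `mu_max * f1 - delta_max * f2` at every grid point. Under
#' constant inhibitor concentration the exponential growth solution makes
#' population doublings over the fixed 96 h assay linear in the net rate, so
#' the assay duration is absorbed into `mu_max` and `delta_max` and no ODE
#' integration is needed. For M10, `f1 = 1 - hill1(MEKi)` applies to
#' proliferation and `f2 = hill1(AKTi)` to death.
#'
#' @param spec a `growth_model_spec`.
#' @param p named numeric vector covering `param_names(spec)`.
#' @param grid a [dose_grid()].
#' @return 5 x 6 matrix of predicted population doublings per 96 h
#'   (rows = AKT doses, columns = MEK doses).
#' @export
predict_pd <- function(spec, p, grid) {
  miss <- setdiff(spec$param_names, names(p))
  if (length(miss)) {
    stop("predict_pd: incomplete parameter set for ", spec$id, ": missing ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  p <- as.list(p)
  if (p$mu_max < 0 || p$delta_max < 0) {
    stop("predict_pd: mu_max and delta_max must be >= 0", call. = FALSE)
  }
  akt <- rep(grid$akt_doses, times = length(grid$mek_doses))
  mek <- rep(grid$mek_doses, each = length(grid$akt_doses))
  if (spec$id == "M10") {
    f1 <- 1 - .gate_eval("HILL1", "f1_", p, akt, mek, "mek")
    f2 <- .gate_eval("HILL1", "f2_", p, akt, mek, "akt")
  } else {
    f1 <- .gate_eval(spec$f1_gate, "f1_", p, akt, mek, NA)
    f2 <- .gate_eval(spec$f2_gate, "f2_", p, akt, mek, NA)
  }
  matrix(p$mu_max * f1 - p$delta_max * f2,
         nrow = length(grid$akt_doses), ncol = length(grid$mek_doses),
         dimnames = list(akt = signif(grid$akt_doses, 6),
                         mek = signif(grid$mek_doses, 6)))
}

#' Pathway Bias
#'
#' Normalised difference of the fitted pathway weights,
#' `(w_akt - w_erk) / (w_akt + w_erk)`. A value of +1 signifies complete
#' PI3K/AKT dependence (growth responds only to AKT inhibitor), -1 complete
#' MAPK/ERK dependence, 0 balanced dependence. Antisymmetric in its
#' arguments and invariant under rescaling both weights.
#'
#' @param w_akt,w_erk non-negative pathway weights, not both zero.
#' @return bias in `[-1, 1]`.
#' @export
pathway_bias <- function(w_akt, w_erk) {
  if (any(w_akt < 0) || any(w_erk < 0)) {
    stop("pathway_bias: weights must be >= 0", call. = FALSE)
  }
  s <- w_akt + w_erk
  if (any(s == 0)) {
    stop("pathway_bias: undefined when both weights are 0", call. = FALSE)
  }
  (w_akt - w_erk) / s
}
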