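# Particle swarm optimizer (global-best topology, Clerc-Kennedy constriction
# coefficients, absorbing bounds). Objectives are evaluated for the whole
# swarm at once: `fn` receives an S x d matrix of positions (original scale)
# and must return a length-S vector.

#' Particle swarm minimisation
#'
#' @param fn batch objective: matrix (one row per particle, columns in
#'   `names(lo)` order, original scale) -> numeric vector.
#' @param lo,hi named bound vectors (original scale), `lo < hi`.
#' @param log_scale logical vector: search that coordinate in log10 space.
#' @param swarm,iterations swarm size and iteration count.
#' @param inertia,cognitive,social PSO coefficients.
#' @return list with `par` (named vector, original scale), `value`, and
#'   `evals`.
#' @keywords internal
pso_minimize <- function(fn, lo, hi, log_scale,
                         swarm = 40L, iterations = 300L,
                         inertia = 0.729, cognitive = 1.494, social = 1.494) {
  d <- length(lo)
  stopifnot(length(hi) == d, length(log_scale) == d, all(lo < hi))
  tlo <- ifelse(log_scale, log10(lo), lo)
  thi <- ifelse(log_scale, log10(hi), hi)
  span <- thi - tlo

  back <- function(X) {
    Y <- X
    if (any(log_scale)) Y[, log_scale] <- 10^Y[, log_scale]
    colnames(Y) <- names(lo)
    Y
  }

  X <- sweep(sweep(matrix(stats::runif(swarm * d), swarm, d), 2, span, "*"),
             2, tlo, "+")
  V <- sweep(matrix(stats::runif(swarm * d, -0.5, 0.5), swarm, d), 2, span, "*")
  f <- fn(back(X))
  if (any(!is.finite(f))) {
    stop("pso_minimize: non-finite objective at initial position ",
         paste(signif(back(X)[which(!is.finite(f))[1], ], 4), collapse = ", "),
         call. = FALSE)
  }
  Pb <- X; fPb <- f
  g <- which.min(fPb)

  for (it in seq_len(iterations)) {
    R1 <- matrix(stats::runif(swarm * d), swarm, d)
    R2 <- matrix(stats::runif(swarm * d), swarm, d)
    Gb <- matrix(Pb[g, ], swarm, d, byrow = TRUE)
    V <- inertia * V + cognitive * R1 * (Pb - X) + social * R2 * (Gb - X)
    X <- X + V
    # absorbing walls: clamp and kill the offending velocity component
    for (j in seq_len(d)) {
      under <- X[, j] < tlo[j]; over <- X[, j] > thi[j]
      if (any(under)) { X[under, j] <- tlo[j]; V[under, j] <- 0 }
      if (any(over))  { X[over, j]  <- thi[j]; V[over, j]  <- 0 }
    }
    f <- fn(back(X))
    if (any(!is.finite(f))) {
      stop("pso_minimize: non-finite objective at ",
           paste(signif(back(X)[which(!is.finite(f))[1], ], 4),
                 collapse = ", "), call. = FALSE)
    }
    imp <- f < fPb
    if (any(imp)) { Pb[imp, ] <- X[imp, ]; fPb[imp] <- f[imp] }
    g <- which.min(fPb)
  }
  list(par = stats::setNames(back(Pb)[g, , drop = TRUE], names(lo)),
       value = fPb[g], evals = swarm * (iterations + 1L))
}
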