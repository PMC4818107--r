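# Logistic-regression classification of discretized Pathway Bias from
# molecular/phenotypic features, with LOOCV evaluation and permutation nulls.

.PROTEIN_COLS <- c("EGFR", "ERBB3", "CDKN1B", "pAKT", "pERK",
                   "AKT_total", "ERK_total", "ERBB2")
.GENE_COLS <- c("pik3ca_mut", "pten_mut", "pik3r1_mut")
.PHEN_COLS <- c("tissue_breast", "proliferation_pd")

#' Named feature sets for bias prediction
#'
#' `3BM` is the three-protein biomarker set \{EGFR, ERBB3, CDKN1B\}; `GENE`
#' the PI3K-pathway mutation flags; `PHEN` tissue origin plus proliferation
#' rate; `PROT` every protein signal present in the panel; `FULL` all of the
#' above plus the heregulin indicator; `PAKT_PERK` the two phospho-signals
#' (the intuitive but uninformative candidates).
#'
#' @param name one of `"FULL"`, `"PROT"`, `"GENE"`, `"PHEN"`, `"3BM"`,
#'   `"3BM+HRG"`, `"PAKT_PERK"`.
#' @param panel sample panel data.frame (used to resolve `FULL`/`PROT`).
#' @return character vector of feature column names.
#' @export
feature_set <- function(name, panel = NULL) {
  prot <- if (is.null(panel)) .PROTEIN_COLS
          else intersect(.PROTEIN_COLS, names(panel))
  cols <- switch(name,
    "FULL"      = c(prot, .GENE_COLS, .PHEN_COLS, "hrg"),
    "PROT"      = prot,
    "GENE"      = .GENE_COLS,
    "PHEN"      = .PHEN_COLS,
    "3BM"       = c("EGFR", "ERBB3", "CDKN1B"),
    "3BM+HRG"   = c("EGFR", "ERBB3", "CDKN1B", "hrg"),
    "PAKT_PERK" = c("pAKT", "pERK"),
    stop("unknown feature set: ", name, call. = FALSE))
  if (!is.null(panel)) {
    miss <- setdiff(cols, names(panel))
    if (length(miss)) {
      stop("feature_set: panel lacks columns ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  cols
}

#' Discretize a continuous Pathway Bias into the two dependence classes
#'
#' @param bias continuous bias in `[-1, 1]`, nonzero (the empirical bias
#'   distribution is bimodal; an exact zero has no class).
#' @return `+1` (PI3K-dependent) or `-1` (MAPK-dependent).
#' @export
discretize_bias <- function(bias) {
  if (any(bias == 0)) {
    stop("discretize_bias: bias of exactly 0 has no class", call. = FALSE)
  }
  sign(bias)
}

#' Fit the bias logistic regression by penalised maximum likelihood
#'
#' Models the log-odds of MAPK-dependence,
#' `ln(P_MAPK / P_PI3K) = beta0 + sum(beta_i * X_i)`, by Newton iteration on
#' the binomial log-likelihood. A small ridge penalty (`lambda`, on slopes
#' only) keeps estimates finite when the classes separate; at `lambda = 0`
#' this is plain MLE.
#'
#' @param panel data.frame with the feature columns and a `class_label`
#'   column in \{-1, +1\} (+1 = PI3K).
#' @param fset feature-set name (see [feature_set()]) or a character vector
#'   of column names.
#' @param lambda ridge penalty on slope coefficients (default `1e-4`).
#' @return a `logistic_fit` list: `beta0`, `betas` (named), `features`,
#'   `converged`.
#' @export
fit_logistic <- function(panel, fset = "3BM", lambda = 1e-4) {
  cols <- if (length(fset) == 1 && fset %in% c("FULL", "PROT", "GENE", "PHEN",
                                               "3BM", "3BM+HRG", "PAKT_PERK"))
    feature_set(fset, panel) else fset
  X <- as.matrix(panel[, cols, drop = FALSE])
  if (anyNA(X)) stop("fit_logistic: missing values in features", call. = FALSE)
  y <- as.numeric(panel$class_label == -1)  # MAPK coded as success
  if (length(unique(y)) < 2) {
    stop("fit_logistic: need both classes present", call. = FALSE)
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  d <- ncol(Xd)
  pen <- c(0, rep(lambda, d - 1))
  beta <- numeric(d)
  obj <- function(b) {
    eta <- drop(Xd %*% b)
    # stable log(1 + exp(eta))
    lse <- pmax(eta, 0) + log1p(exp(-abs(eta)))
    -sum(y * eta - lse) + sum(pen * b^2) / 2
  }
  f0 <- obj(beta)
  converged <- FALSE
  for (it in 1:100) {
    eta <- drop(Xd %*% beta)
    p <- stats::plogis(eta)
    g <- drop(crossprod(Xd, p - y)) + pen * beta
    W <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Xd * W, Xd) + diag(pen, d)
    step <- tryCatch(solve(H, g), error = function(e)
      solve(H + diag(1e-8 * max(diag(H)), d), g))
    t <- 1
    repeat {  # backtracking
      f1 <- obj(beta - t * step)
      if (is.finite(f1) && f1 <= f0 + 1e-12) break
      t <- t / 2
      if (t < 1e-10) break
    }
    beta <- beta - t * step
    if (abs(f0 - f1) < 1e-12 * (abs(f0) + 1e-12) &&
        sqrt(sum(g^2)) < 1e-8 * (1 + sqrt(sum(beta^2)))) {
      converged <- TRUE
      f0 <- f1
      break
    }
    f0 <- f1
  }
  structure(list(beta0 = unname(beta[1]),
                 betas = stats::setNames(unname(beta[-1]), cols),
                 features = cols, lambda = lambda, converged = converged),
            class = "logistic_fit")
}

#' Back-calculate a continuous predicted bias from class probabilities
#'
#' `Predicted Bias = -1 * P_MAPK + 1 * P_PI3K = 1 - 2 * P_MAPK`, strictly in
#' `(-1, 1)`, zero exactly when the model is indifferent.
#'
#' @param fit a [fit_logistic()] result.
#' @param features data.frame or named vector covering `fit$features`.
#' @return predicted bias per row.
#' @export
predict_bias <- function(fit, features) {
  if (!is.data.frame(features)) features <- as.data.frame(as.list(features))
  miss <- setdiff(fit$features, names(features))
  if (length(miss)) {
    stop("predict_bias: missing features ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(features[, fit$features, drop = FALSE])
  p_mapk <- stats::plogis(fit$beta0 + drop(X %*% fit$betas))
  1 - 2 * p_mapk
}

#' Leave-one-out cross-validation of the bias classifier
#'
#' Each sample is predicted by a model trained on the remaining `n - 1`.
#' Accuracy is the fraction of samples whose predicted-bias sign matches the
#' class label (indifferent predictions of exactly 0 and skipped folds count
#' as errors); Pearson correlation and MSE compare predicted to true
#' continuous bias. A training fold that loses one class is skipped with a
#' warning.
#'
#' @inheritParams fit_logistic
#' @return a `classifier_result` list: `predicted_bias`, `accuracy`,
#'   `pearson`, `mse`, `n`, `feature_set`.
#' @export
loocv <- function(panel, fset = "3BM", lambda = 1e-4) {
  cols <- if (length(fset) == 1 && !fset %in% names(panel))
    feature_set(fset, panel) else fset
  n <- nrow(panel)
  pred <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    train <- panel[-i, , drop = FALSE]
    if (length(unique(train$class_label)) < 2) {
      warning("loocv: fold ", i, " has a single class; skipped")
      next
    }
    fit <- fit_logistic(train, cols, lambda)
    pred[i] <- predict_bias(fit, panel[i, , drop = FALSE])
  }
  ok <- !is.na(pred)
  correct <- ok & sign(pred) == panel$class_label & pred != 0
  structure(list(predicted_bias = pred,
                 accuracy = sum(correct) / n,
                 pearson = if (sum(ok) >= 3 && stats::sd(pred[ok]) > 0 &&
                               stats::sd(panel$bias[ok]) > 0)
                   stats::cor(pred[ok], panel$bias[ok]) else NA_real_,
                 mse = mean((pred[ok] - panel$bias[ok])^2),
                 n = n, feature_set = if (length(fset) == 1) fset else "custom"),
            class = "classifier_result")
}

#' Permutation-null significance of the LOOCV metrics
#'
#' Shuffles the (bias, class label) pairs against the fixed feature rows `B`
#' times, rerunning the full LOOCV each time; the +/-HRG rows of a cell line
#' are permuted independently since they are treated as independent samples.
#' P-values use the add-one estimator `(1 + r) / (1 + B)`: for accuracy and
#' Pearson `r` counts null values `>=` observed, for MSE null values `<=`
#' observed.
#'
#' @inheritParams fit_logistic
#' @param B number of permutations (`>= 100`; the full-scale analysis uses
#'   10000).
#' @param seed integer seed.
#' @return the observed `classifier_result` augmented with `perm_null`
#'   (data.frame of null accuracy/pearson/mse) and `p_values`.
#' @export
permutation_test <- function(panel, fset = "3BM", B = 10000L, seed = 1L,
                             lambda = 1e-4) {
  if (B < 100) stop("permutation_test: B must be >= 100", call. = FALSE)
  obs <- loocv(panel, fset, lambda)
  null <- matrix(NA_real_, B, 3, dimnames = list(NULL,
    c("accuracy", "pearson", "mse")))
  perm_seeds <- .derive_seeds(seed, B)
  for (b in seq_len(B)) {
    idx <- withr::with_seed(perm_seeds[b], sample.int(nrow(panel)))
    pp <- panel
    pp$bias <- panel$bias[idx]
    pp$class_label <- panel$class_label[idx]
    r <- suppressWarnings(loocv(pp, fset, lambda))
    null[b, ] <- c(r$accuracy, r$pearson, r$mse)
  }
  p_add1 <- function(r) (1 + r) / (1 + B)
  obs$perm_null <- as.data.frame(null)
  obs$p_values <- c(
    accuracy = p_add1(sum(null[, "accuracy"] >= obs$accuracy, na.rm = TRUE)),
    pearson = p_add1(sum(null[, "pearson"] >= obs$pearson, na.rm = TRUE)),
    mse = p_add1(sum(null[, "mse"] <= obs$mse, na.rm = TRUE)))
  obs$B <- B
  obs
}

#' Normalised regression coefficients
#'
#' Scales each coefficient by the median of its feature over the panel
#' (`beta_i * median(X_i)`), making coefficients comparable across signals
#' of very different magnitudes.
#'
#' @inheritParams predict_bias
#' @param panel the panel the fit was trained on.
#' @return named numeric vector.
#' @export
normalized_coefficients <- function(fit, panel) {
  med <- vapply(fit$features, function(f) stats::median(panel[[f]]), 0)
  fit$betas * med
}

#' Read and write sample panels (wide CSV, one row per sample)
#'
#' @param panel data.frame with `sample_id`, feature columns, `bias`,
#'   `class_label`.
#' @param file path.
#' @export
write_panel <- function(panel, file) {
  utils::write.csv(panel, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_panel
#' @export
read_panel <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "bias", "class_label") %in% names(df))) {
    stop("read_panel: need sample_id, bias and class_label columns",
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("read_panel: duplicated sample ids", call. = FALSE)
  }
  df
}
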