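## Per-sample fingerprint tables, categorical encodings, correlation
## matrices and the small-sample elastic-net cross-validation analysis.

## registered categorical vocabularies (encodings are conventional, not
## measured: the refolding size classes get an arbitrary numeric scale and
## refolding at 2 M urea an ordered categorical scale)
CATEGORICAL_VOCABS <- list(
  refold_size = c(small = 0.33, medium = 0.50, large = 0.66),
  refold_urea = c("0" = 0, "<50" = 1, ">50" = 2)
)

#' Default fingerprint feature set for regression analyses
#'
#' The conventional reduced feature list used when regressing clinical
#' parameters on the fingerprint, chosen to eliminate the most internally
#' correlated measurements (e.g. dimerisation measured by three methods).
#'
#' @return Character vector of column names.
#' @export
default_fingerprint_features <- function() {
  c("tm_dsf_ph5", "t_max_turb_ph5", "tm_dsc", "dtm_dlogc", "dtagg_dlogc",
    "cumul_radius_70C", "dimer_auc", "fract_refold_dsc", "dG37",
    "digestibility_trypsin")
}

#' Encode categorical fingerprint columns on their numeric scales
#'
#' Converts the registered categorical vocabularies of a fingerprint
#' table to numbers: refolding size classes `small`/`medium`/`large`
#' become 0.33/0.50/0.66 and the 2 M urea refolding classes
#' `0`/`<50`/`>50` become the ordered scale 0/1/2.  Any character or
#' factor column whose non-missing values all belong to one registered
#' vocabulary is encoded; a column containing an unrecognised token is an
#' error naming the column and row.  The original values are retained so
#' [decode_categoricals()] is lossless.
#'
#' @param table Data frame, rows = samples (row names = sample ids).
#' @return The data frame with encoded columns numeric and an
#'   `"encodings"` attribute recording, per encoded column, the
#'   vocabulary used.
#' @export
encode_categoricals <- function(table) {
  stopifnot(is.data.frame(table))
  encodings <- list()
  for (col in names(table)) {
    x <- table[[col]]
    if (!is.character(x) && !is.factor(x)) next
    x <- as.character(x)
    vals <- x[!is.na(x)]
    if (!length(vals)) next
    hit <- NULL
    for (voc in names(CATEGORICAL_VOCABS)) {
      if (all(vals %in% names(CATEGORICAL_VOCABS[[voc]]))) { hit <- voc; break }
    }
    if (is.null(hit)) {
      bad <- which(!x %in% unlist(lapply(CATEGORICAL_VOCABS, names)))
      bad <- bad[!is.na(x[bad])]
      if (length(bad))
        stop(sprintf(
          "column '%s', row '%s': unrecognised categorical token \"%s\"",
          col, rownames(table)[bad[1]], x[bad[1]]), call. = FALSE)
      stop(sprintf(
        "column '%s' mixes tokens from different vocabularies", col),
        call. = FALSE)
    }
    encodings[[col]] <- hit
    table[[col]] <- unname(CATEGORICAL_VOCABS[[hit]][x])
  }
  attr(table, "encodings") <- encodings
  table
}

#' Decode previously encoded categorical columns
#'
#' Inverse of [encode_categoricals()]; requires the `"encodings"`
#' attribute it sets.
#'
#' @param table Data frame returned by [encode_categoricals()].
#' @return Data frame with the categorical columns restored to their
#'   original tokens.
#' @export
decode_categoricals <- function(table) {
  encodings <- attr(table, "encodings")
  if (is.null(encodings))
    stop("'table' carries no encodings attribute", call. = FALSE)
  for (col in names(encodings)) {
    voc <- CATEGORICAL_VOCABS[[encodings[[col]]]]
    table[[col]] <- names(voc)[match(table[[col]], voc)]
  }
  attr(table, "encodings") <- NULL
  table
}

#' Pairwise Pearson and Spearman correlation matrices
#'
#' Correlation matrices over all numeric columns of a fingerprint table,
#' using pairwise-complete observations.  Entries supported by fewer than
#' `min_pairs` complete pairs are set to `NA`.  Pairwise deletion can
#' yield an indefinite matrix; this is flagged (attribute
#' `"positive_semidefinite"`) rather than silently ignored.
#'
#' @param table Data frame (non-numeric columns are dropped with a
#'   message) or numeric matrix.
#' @param min_pairs Minimum number of complete pairs per entry
#'   (default 3).
#' @return List with `pearson`, `spearman` (symmetric matrices with unit
#'   diagonal) and `n_pairs` (complete-pair counts); each correlation
#'   matrix carries a `"positive_semidefinite"` attribute.
#' @export
correlation_matrices <- function(table, min_pairs = 3L) {
  if (is.data.frame(table)) {
    num <- vapply(table, is.numeric, logical(1L))
    if (!all(num))
      message("dropping non-numeric columns: ",
              paste(names(table)[!num], collapse = ", "))
    table <- as.matrix(table[num])
  }
  p <- ncol(table)
  nm <- colnames(table)
  pear <- spear <- npair <- matrix(NA_real_, p, p, dimnames = list(nm, nm))
  for (i in seq_len(p)) {
    for (j in i:p) {
      ok <- stats::complete.cases(table[, c(i, j)])
      npair[i, j] <- npair[j, i] <- sum(ok)
      if (i == j) { pear[i, i] <- spear[i, i] <- 1; next }
      if (sum(ok) >= min_pairs) {
        xi <- table[ok, i]; xj <- table[ok, j]
        if (stats::sd(xi) > 0 && stats::sd(xj) > 0) {
          pear[i, j] <- pear[j, i] <- stats::cor(xi, xj)
          spear[i, j] <- spear[j, i] <- stats::cor(xi, xj,
                                                   method = "spearman")
        }
      }
    }
  }
  flag_psd <- function(m) {
    complete <- !anyNA(m)
    attr(m, "positive_semidefinite") <- if (complete)
      min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) > -1e-8
    else NA
    m
  }
  list(pearson = flag_psd(pear), spearman = flag_psd(spear),
       n_pairs = npair)
}

#' Encode, impute and standardise a fingerprint table for modelling
#'
#' Applies [encode_categoricals()], optionally blanks per-sample cells
#' listed in `exclude` (e.g. a free-energy value judged unreliable for one
#' sample), replaces missing values by the column mean, and standardises
#' every column to zero mean and unit variance (constant columns are left
#' centred only).
#'
#' @param table Data frame, rows = samples.
#' @param features Optional character vector of columns to keep (default:
#'   all numeric columns after encoding).
#' @param exclude Optional named list: for each column name, the sample
#'   (row) names whose value is treated as missing.
#' @return Numeric matrix with attributes `center`, `scale` and
#'   `imputed` (logical matrix marking imputed cells).
#' @export
encode_matrix <- function(table, features = NULL, exclude = NULL) {
  table <- encode_categoricals(table)
  if (!is.null(exclude)) {
    for (col in names(exclude)) {
      rows <- match(exclude[[col]], rownames(table))
      if (anyNA(rows))
        stop("unknown sample in 'exclude' for column ", col, call. = FALSE)
      table[rows, col] <- NA
    }
  }
  num <- vapply(table, is.numeric, logical(1L))
  m <- as.matrix(table[num])
  if (!is.null(features)) {
    miss <- setdiff(features, colnames(m))
    if (length(miss))
      stop("features not present/numeric: ", paste(miss, collapse = ", "),
           call. = FALSE)
    m <- m[, features, drop = FALSE]
  }
  imputed <- is.na(m)
  mu <- colMeans(m, na.rm = TRUE)
  for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mu[j]
  ctr <- colMeans(m)
  scl <- apply(m, 2L, stats::sd)
  scl[scl == 0] <- 1
  m <- sweep(sweep(m, 2L, ctr), 2L, scl, "/")
  attr(m, "center") <- ctr
  attr(m, "scale") <- scl
  attr(m, "imputed") <- imputed
  m
}

#' Elastic-net regression with small-sample grid-search cross-validation
#'
#' Grid search over the penalty strength (`lambda_grid`) and mixing ratio
#' (`alpha_grid`, 1 = lasso, 0 = ridge) of an elastic net, scored by
#' 4-fold cross-validated negative mean squared error; the best model is
#' refit on all data.  No separate validation set is held out -- at
#' fingerprint-scale sample sizes there are too few points -- so the
#' reported in-sample correlation is optimistic and prone to
#' Freedman's-paradox-style inflation; both it and the CV score are
#' returned so the gap is visible, and a warning is issued when the
#' sample size is small relative to the candidate feature count.
#'
#' @param x Numeric predictor matrix (rows = samples), ideally from
#'   [encode_matrix()].
#' @param y Numeric response (one clinical value per sample).
#' @param alpha_grid Mixing-ratio grid (default 0.1..1 in 10 steps).
#' @param lambda_grid Penalty grid (default logarithmic 1e-2..1e2).
#' @param nfolds Number of CV folds (default 4).
#' @param seed Optional integer seed for the fold assignment.
#' @return Object of class `"enet_cv"`: list with `alpha`, `lambda`,
#'   `cv_neg_mse` (best CV score), `cv_table` (full grid), `coefficients`
#'   (including intercept), `nonzero` (selected feature names),
#'   `in_sample_r`, `fitted`, `nfolds` and `n`.
#' @export
elastic_net_cv <- function(x, y,
                           alpha_grid = seq(0.1, 1, length.out = 10L),
                           lambda_grid = 10^seq(-2, 2, length.out = 21L),
                           nfolds = 4L, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(y) != n)
    stop("'y' must have one value per row of 'x'", call. = FALSE)
  if (n < 8L)
    stop("at least 8 samples are required", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("'y' is constant; nothing to model", call. = FALSE)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  folds <- with_seed(seed, sample(rep(seq_len(nfolds), length.out = n)))
  cv_mse <- matrix(0, length(alpha_grid), length(lambda_grid))
  for (f in seq_len(nfolds)) {
    tr <- folds != f
    for (a in seq_along(alpha_grid)) {
      fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr],
                            alpha = alpha_grid[a], lambda = lambda_grid,
                            standardize = FALSE)
      pred <- stats::predict(fit, x[!tr, , drop = FALSE],
                             s = lambda_grid, exact = FALSE)
      cv_mse[a, ] <- cv_mse[a, ] +
        colSums((pred - y[!tr])^2) / n
    }
  }
  best <- which(cv_mse == min(cv_mse), arr.ind = TRUE)[1L, ]
  alpha <- alpha_grid[best[1L]]
  lambda <- lambda_grid[best[2L]]

  full <- glmnet::glmnet(x, y, alpha = alpha, lambda = lambda_grid,
                         standardize = FALSE)
  cf <- as.matrix(stats::predict(full, type = "coefficients", s = lambda))
  fitted <- as.numeric(stats::predict(full, x, s = lambda))
  in_r <- if (stats::sd(fitted) > 0) stats::cor(y, fitted) else 0
  nonzero <- rownames(cf)[cf[, 1L] != 0 & rownames(cf) != "(Intercept)"]

  if (n < 3L * ncol(x))
    warning(sprintf(
      paste("only %d samples for %d candidate features: the in-sample",
            "correlation is likely inflated (Freedman's paradox); trust",
            "the cross-validated score"), n, ncol(x)), call. = FALSE)

  structure(list(alpha = alpha, lambda = lambda,
                 cv_neg_mse = -min(cv_mse),
                 cv_table = list(alpha_grid = alpha_grid,
                                 lambda_grid = lambda_grid,
                                 neg_mse = -cv_mse),
                 coefficients = stats::setNames(cf[, 1L], rownames(cf)),
                 nonzero = nonzero, in_sample_r = in_r, fitted = fitted,
                 nfolds = nfolds, n = n),
            class = "enet_cv")
}

#' @export
print.enet_cv <- function(x, ...) {
  cat(sprintf(
    "Elastic net (%d-fold CV, n = %d): alpha = %.2f, lambda = %.3g\n",
    x$nfolds, x$n, x$alpha, x$lambda))
  cat(sprintf("  CV neg-MSE = %.4g, in-sample Pearson r = %.3f\n",
              x$cv_neg_mse, x$in_sample_r))
  cat("  selected features:",
      if (length(x$nonzero)) paste(x$nonzero, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
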