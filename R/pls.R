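#' Autoscale predictor and response columns of a sample table
#'
#' Centers every column to mean 0 and scales to unit sample standard
#' deviation (n − 1 denominator). The returned scaling constants invert the
#' transform exactly, so models fitted on the scaled matrices can report
#' predictions in the original units.
#'
#' @param table A data frame (typically a [sample_table]).
#' @param predictor_columns Character vector of predictor column names.
#' @param response_column Single response column name.
#' @return A list with `X` (scaled predictor matrix), `y` (scaled response
#'   vector), `x_means`, `x_sds`, `y_mean`, `y_sd`.
#' @export
#' @examples
#' tab <- subset(pef_sample_table(), role == "train")
#' sc <- autoscale(tab, c("yp_rate", "pi_rate"), "fusion_rate")
#' colMeans(sc$X)  # ~0
autoscale <- function(table, predictor_columns = c("yp_rate", "pi_rate"),
                      response_column = "fusion_rate") {
  if (!is.data.frame(table)) stop("'table' must be a data frame", call. = FALSE)
  if (nrow(table) < 2L) {
    stop("autoscaling needs at least 2 rows", call. = FALSE)
  }
  cols <- c(predictor_columns, response_column)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(table[, predictor_columns, drop = FALSE])
  y <- table[[response_column]]
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported", call. = FALSE)
  x_means <- colMeans(X)
  x_sds <- apply(X, 2L, stats::sd)
  zero <- which(x_sds == 0)
  if (length(zero)) {
    stop("zero-variance predictor column: ",
         paste(predictor_columns[zero], collapse = ", "), call. = FALSE)
  }
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (y_sd == 0) {
    stop("zero-variance response column: ", response_column, call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2L, x_means, "-"), 2L, x_sds, "/")
  list(X = Xs, y = (y - y_mean) / y_sd,
       x_means = x_means, x_sds = x_sds, y_mean = y_mean, y_sd = y_sd)
}

#' Invert an autoscaling transform
#'
#' @param scaled A list as returned by [autoscale()].
#' @return A list with the raw `X` matrix and `y` vector.
#' @export
inverse_autoscale <- function(scaled) {
  X <- sweep(sweep(scaled$X, 2L, scaled$x_sds, "*"), 2L, scaled$x_means, "+")
  list(X = X, y = scaled$y * scaled$y_sd + scaled$y_mean)
}

#' Fit a PLS model by NIPALS on pre-scaled matrices
#'
#' Implements the bilinear PLS decomposition
#' \deqn{X = T P^T + E, \quad Y = U C^T + G, \quad Y = T C^T + F}
#' by the NIPALS algorithm: for each latent component a unit predictor
#' weight vector `w` is found iteratively (for a single response it equals
#' the normalized cross-covariance \eqn{X^T y / \|X^T y\|}), scores
#' `t = X w` are computed, `X` is deflated by the rank-one update
#' \eqn{t p^T} and `Y` by \eqn{t c^T}. Weight vectors are oriented so the
#' predictor loading of largest magnitude is positive; predictions are
#' invariant to that sign choice.
#'
#' @param X Numeric matrix of scaled predictors (rows = samples).
#' @param Y Numeric vector or matrix of scaled response(s).
#' @param n_components Number of latent components (>= 1, <= ncol(X)).
#' @param tol Convergence tolerance of the NIPALS inner iteration.
#' @param max_iter Iteration cap of the inner loop.
#' @return An object of class `pls_model` holding `W` (predictor weights,
#'   unit columns), `T` (scores), `P` (predictor loadings), `U` (response
#'   scores), `C` (response weights, responses x components), residual
#'   matrices `E` (X block), `G` (Y bilinear residual), `F` (regression
#'   residual), `B` (regression coefficients on the scaled scale) and
#'   `n_components`.
#' @export
fit_pls <- function(X, Y, n_components = 1L, tol = 1e-12, max_iter = 500L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (anyNA(X) || anyNA(Y) || any(!is.finite(X)) || any(!is.finite(Y))) {
    stop("NaN or non-finite values in the input matrices", call. = FALSE)
  }
  if (nrow(X) != nrow(Y)) {
    stop("X and Y must have the same number of rows", call. = FALSE)
  }
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > ncol(X)) {
    stop(sprintf("n_components must be in [1, %d], got %d",
                 ncol(X), n_components), call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Cm <- matrix(0, q, n_components)
  Tm <- matrix(0, n, n_components)
  Um <- matrix(0, n, n_components)
  Xd <- X; Yd <- Y
  for (a in seq_len(n_components)) {
    u <- Yd[, which.max(apply(Yd, 2L, stats::var)), drop = TRUE]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xd, u))
      nw <- sqrt(sum(w^2))
      if (nw == 0) stop("degenerate component: X'u vanished", call. = FALSE)
      w <- w / nw
      t_vec <- drop(Xd %*% w)
      cc <- drop(crossprod(Yd, t_vec)) / sum(t_vec^2)
      u <- drop(Yd %*% cc) / sum(cc^2)
      if (sqrt(sum((t_vec - t_old)^2)) < tol) break
      t_old <- t_vec
    }
    p_vec <- drop(crossprod(Xd, t_vec)) / sum(t_vec^2)
    # orient: largest-|loading| entry positive
    j <- which.max(abs(p_vec))
    if (p_vec[j] < 0) {
      w <- -w; t_vec <- -t_vec; p_vec <- -p_vec; cc <- -cc; u <- -u
    }
    W[, a] <- w; Tm[, a] <- t_vec; P[, a] <- p_vec; Cm[, a] <- cc
    Um[, a] <- u
    Xd <- Xd - tcrossprod(t_vec, p_vec)
    Yd <- Yd - tcrossprod(t_vec, cc)
  }
  rownames(W) <- rownames(P) <- colnames(X)
  rownames(Cm) <- colnames(Y)
  # coefficients for undeflated X: B = W (P'W)^-1 C'
  B <- W %*% solve(crossprod(P, W), t(Cm))
  fitted_scaled <- X %*% B
  structure(list(
    W = W, T = Tm, P = P, U = Um, C = Cm,
    E = Xd, G = Yd, F = Y - fitted_scaled, B = B,
    n_components = n_components,
    predictors = colnames(X), response = colnames(Y)
  ), class = "pls_model")
}

#' Fit an autoscaled PLS model to a PEF sample table
#'
#' Convenience wrapper: selects the training rows (`role == "train"`, or all
#' rows when no role is assigned), autoscales predictors and response, fits
#' NIPALS PLS, and stores the scaling constants so that [predict.pls_model()]
#' reports responses in the original units.
#'
#' @param table A [sample_table] data frame.
#' @param predictor_columns,response_column Column selections
#'   (defaults: dye-uptake rates predicting fusion rate).
#' @param n_components Number of latent components (default 1).
#' @return A `pls_model` with scaling constants and training metadata.
#' @export
#' @examples
#' fit <- pls_fit(pef_sample_table())
#' round(fit$W[, 1], 2)  # component-1 weights for (YP, PI)
pls_fit <- function(table, predictor_columns = c("yp_rate", "pi_rate"),
                    response_column = "fusion_rate", n_components = 1L) {
  if (!is.data.frame(table)) stop("'table' must be a data frame", call. = FALSE)
  train <- table
  if ("role" %in% names(table) && any(table$role == "train")) {
    train <- table[table$role == "train", , drop = FALSE]
  }
  if (nrow(train) < 3L) {
    stop("model fitting needs at least 3 training rows", call. = FALSE)
  }
  sc <- autoscale(train, predictor_columns, response_column)
  model <- fit_pls(sc$X, matrix(sc$y, ncol = 1L,
                                dimnames = list(NULL, response_column)),
                   n_components = n_components)
  model$x_means <- sc$x_means
  model$x_sds <- sc$x_sds
  model$y_mean <- sc$y_mean
  model$y_sd <- sc$y_sd
  model$train_ids <- if ("sample_id" %in% names(train))
    as.character(train$sample_id) else NULL
  model
}

#' Predict responses from a fitted PLS model, in original units
#'
#' @param object A `pls_model` from [pls_fit()] (or [fit_pls()] with scaling
#'   constants attached).
#' @param newdata A data frame containing the model's predictor columns, or
#'   a numeric matrix with matching column names.
#' @param ... Unused.
#' @return Numeric vector of predicted responses in original units.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (is.null(object$x_means)) {
    stop("model carries no scaling constants; fit with pls_fit()", call. = FALSE)
  }
  if (is.data.frame(newdata)) {
    missing_cols <- setdiff(object$predictors, names(newdata))
    if (length(missing_cols)) {
      stop("newdata is missing predictor column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    Xn <- as.matrix(newdata[, object$predictors, drop = FALSE])
  } else {
    Xn <- as.matrix(newdata)
    if (!is.null(colnames(Xn))) {
      if (!all(object$predictors %in% colnames(Xn))) {
        stop("newdata is missing predictor column(s): ",
             paste(setdiff(object$predictors, colnames(Xn)), collapse = ", "),
             call. = FALSE)
      }
      Xn <- Xn[, object$predictors, drop = FALSE]
    } else if (ncol(Xn) != length(object$predictors)) {
      stop("newdata has wrong number of columns", call. = FALSE)
    }
  }
  if (anyNA(Xn)) stop("missing values in newdata", call. = FALSE)
  Xs <- sweep(sweep(Xn, 2L, object$x_means, "-"), 2L, object$x_sds, "/")
  as.numeric(object$y_mean + object$y_sd * (Xs %*% object$B))
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: %d component(s), %d predictor(s) [%s]\n",
              x$n_components, length(x$predictors),
              paste(x$predictors, collapse = ", ")))
  cat("Component-1 weights:",
      paste(sprintf("%s = %.3f", x$predictors, x$W[, 1L]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Fit statistics of a PLS model on a sample table
#'
#' Computes the training coefficient of determination
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} (about the training mean), and, when
#' the table contains held-out rows (`role == "test"`), two held-out
#' statistics side by side: `r2_test_ss` (1 − SSres/SStot about the held-out
#' mean) and `r2_test_corr` (squared Pearson correlation of predicted vs
#' observed). The two definitions differ in general and both are reported.
#' `q2_loo` is the leave-one-out cross-validated R² of the training rows
#' (see [loo_q2()]).
#'
#' @param model A `pls_model` from [pls_fit()].
#' @param table The sample table with observed responses (train and/or test
#'   roles).
#' @return A list with `r2_train`, `r2_test_ss`, `r2_test_corr` (NA when no
#'   test rows), and `q2_loo`.
#' @export
fit_stats <- function(model, table) {
  response <- model$response
  if (stats::sd(table[[response]]) == 0) {
    stop("zero response variance in the supplied table", call. = FALSE)
  }
  role <- if ("role" %in% names(table)) as.character(table$role)
          else rep("train", nrow(table))
  role[!role %in% c("train", "test")] <- "train"
  train <- table[role == "train", , drop = FALSE]
  test <- table[role == "test", , drop = FALSE]
  pred_tr <- predict(model, train)
  obs_tr <- train[[response]]
  r2_train <- 1 - sum((obs_tr - pred_tr)^2) / sum((obs_tr - mean(obs_tr))^2)
  r2_test_ss <- r2_test_corr <- NA_real_
  if (nrow(test) >= 2L) {
    pred_te <- predict(model, test)
    obs_te <- test[[response]]
    r2_test_ss <- 1 - sum((obs_te - pred_te)^2) / sum((obs_te - mean(obs_te))^2)
    r2_test_corr <- stats::cor(pred_te, obs_te)^2
  }
  q2 <- tryCatch(
    loo_q2(train, n_components = model$n_components,
           predictor_columns = model$predictors,
           response_column = response),
    error = function(e) NA_real_)
  list(r2_train = r2_train, r2_test_ss = r2_test_ss,
       r2_test_corr = r2_test_corr, q2_loo = q2)
}

#' Serialize a fitted PLS model to flat JSON
#'
#' Stores scaling constants, weights, response coefficients and loadings —
#' everything needed to reproduce predictions — in a flat JSON document.
#'
#' @param model A `pls_model` with scaling constants.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
pls_to_json <- function(model, path) {
  if (is.null(model$x_means)) {
    stop("model carries no scaling constants; fit with pls_fit()", call. = FALSE)
  }
  doc <- list(
    n_components = model$n_components,
    predictors = model$predictors,
    response = model$response,
    x_means = unname(model$x_means),
    x_sds = unname(model$x_sds),
    y_mean = model$y_mean,
    y_sd = model$y_sd,
    W = unname(model$W),
    P = unname(model$P),
    C = unname(model$C)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a PLS model from JSON written by [pls_to_json()]
#'
#' @param path JSON path.
#' @return A `pls_model` usable with [predict.pls_model()].
#' @export
pls_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- matrix(doc$W, ncol = doc$n_components)
  P <- matrix(doc$P, ncol = doc$n_components)
  Cm <- matrix(doc$C, ncol = doc$n_components)
  rownames(W) <- rownames(P) <- doc$predictors
  B <- W %*% solve(crossprod(P, W), t(Cm))
  structure(list(
    W = W, P = P, C = Cm, B = B,
    n_components = doc$n_components,
    predictors = doc$predictors, response = doc$response,
    x_means = stats::setNames(doc$x_means, doc$predictors),
    x_sds = stats::setNames(doc$x_sds, doc$predictors),
    y_mean = doc$y_mean, y_sd = doc$y_sd
  ), class = "pls_model")
}
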