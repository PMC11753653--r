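#' Repeated random-split validation of the PLS model
#'
#' Repeats, `n_repeats` times, a uniform random partition of the table into
#' training and held-out rows (default 2:1, i.e. 8:4 for a 12-sample table),
#' refits the autoscaled PLS model on each training partition and records
#' the training R² together with both held-out R² definitions
#' (squared Pearson correlation, and 1 − SSres/SStot about the held-out
#' mean). Rows are internally ordered by `sample_id` before any random draw,
#' so results depend only on the table contents and the seed, not on row
#' order. Each repeat draws its partition from an independently derived RNG
#' substream, so the run is reproducible repeat-by-repeat.
#'
#' @param table A [sample_table] with observed responses.
#' @param n_repeats Number of random splits (default 500).
#' @param train_fraction Fraction of rows assigned to training (default 2/3).
#' @param seed Integer seed; required.
#' @param n_components Latent components per refit (default 1).
#' @param predictor_columns,response_column Model columns.
#' @param splits Optional list of character vectors of training `sample_id`s
#'   overriding the random draws (then `n_repeats = length(splits)`).
#' @return A list with `results` (one row per successful repeat:
#'   `repeat_index`, `train_ids`, `test_ids`, `r2_train`, `r2_test_corr`,
#'   `r2_test_ss`), `summary` (mean and sd of each statistic) and
#'   `n_failed` (repeats whose training partition had zero response
#'   variance, excluded and counted).
#' @export
#' @examples
#' rs <- repeated_split_validation(pef_sample_table(), n_repeats = 50, seed = 1)
#' rs$summary
repeated_split_validation <- function(table, n_repeats = 500L,
                                      train_fraction = 2 / 3, seed,
                                      n_components = 1L,
                                      predictor_columns = c("yp_rate", "pi_rate"),
                                      response_column = "fusion_rate",
                                      splits = NULL) {
  validate_sample_table(table)
  if (is.null(splits) && missing(seed)) {
    stop("a seed is required for random splits", call. = FALSE)
  }
  table <- table[order(table$sample_id), , drop = FALSE]
  n <- nrow(table)
  n_train <- round(n * train_fraction)
  if (n_train < 2L || n - n_train < 2L) {
    stop(sprintf("degenerate split sizes: %d train / %d test", n_train,
                 n - n_train), call. = FALSE)
  }
  if (is.null(splits)) {
    if (n_repeats < 1L) stop("n_repeats must be >= 1", call. = FALSE)
    sub_seeds <- withr::with_seed(as.integer(seed),
      sample.int(.Machine$integer.max - 1L, n_repeats))
    splits <- lapply(seq_len(n_repeats), function(i) {
      idx <- withr::with_seed(sub_seeds[i], sample.int(n, n_train))
      table$sample_id[sort(idx)]
    })
  } else {
    n_repeats <- length(splits)
  }
  rows <- vector("list", n_repeats)
  n_failed <- 0L
  for (i in seq_len(n_repeats)) {
    train_ids <- splits[[i]]
    is_train <- table$sample_id %in% train_ids
    tab_i <- table
    tab_i$role <- ifelse(is_train, "train", "test")
    res <- tryCatch({
      model <- pls_fit(tab_i, predictor_columns, response_column,
                       n_components = n_components)
      st <- fit_stats(model, tab_i)
      data.frame(repeat_index = i,
                 train_ids = paste(train_ids, collapse = ";"),
                 test_ids = paste(table$sample_id[!is_train], collapse = ";"),
                 r2_train = st$r2_train,
                 r2_test_corr = st$r2_test_corr,
                 r2_test_ss = st$r2_test_ss,
                 stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else rows[[i]] <- res
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  stat_cols <- c("r2_train", "r2_test_corr", "r2_test_ss")
  summary <- lapply(stat_cols, function(cc) {
    list(mean = mean(results[[cc]]), sd = stats::sd(results[[cc]]))
  })
  names(summary) <- stat_cols
  list(results = results, summary = summary, n_failed = n_failed)
}

#' Leave-one-out cross-validated Q²
#'
#' Q² = 1 − PRESS / SStot, where PRESS sums squared leave-one-out prediction
#' errors — each fold refits the whole pipeline (autoscaling included) on
#' the remaining rows — and SStot is the total sum of squares about the mean
#' of all responses. Q² near the training R² indicates a model that is not
#' driven by individual rows; Q² below zero means the model predicts
#' held-out rows worse than the mean.
#'
#' @param table A sample table (all rows are used; roles are ignored).
#' @param n_components Latent components (default 1).
#' @param predictor_columns,response_column Model columns.
#' @return The scalar Q².
#' @export
loo_q2 <- function(table, n_components = 1L,
                   predictor_columns = c("yp_rate", "pi_rate"),
                   response_column = "fusion_rate") {
  if (nrow(table) < 3L) {
    stop("leave-one-out Q2 needs at least 3 rows", call. = FALSE)
  }
  y <- table[[response_column]]
  press <- 0
  for (i in seq_len(nrow(table))) {
    rest <- table[-i, , drop = FALSE]
    rest$role <- "train"
    model <- pls_fit(rest, predictor_columns, response_column,
                     n_components = n_components)
    pred <- predict(model, table[i, , drop = FALSE])
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' Y-scrambling permutation test
#'
#' Refits the autoscaled PLS pipeline on seeded random permutations of the
#' response column and records, per permutation, the Pearson correlation
#' between permuted and original responses, the training R² and the
#' leave-one-out Q² of the refit model. Record 0 is always the identity
#' permutation (the unpermuted model). A sound model's R² and Q² collapse as
#' the permuted response decorrelates from the original; the returned trend
#' summary quantifies this as the Spearman rank correlation between
#' |y correlation| and R² across records. Rows are internally ordered by
#' `sample_id` so results depend only on contents and seed.
#'
#' @param table A sample table; all rows of the supplied table are fit (pass
#'   the training subset to permute the training model).
#' @param n_perm Number of random permutations (default 500).
#' @param seed Integer seed; required.
#' @param n_components Latent components (default 1).
#' @param predictor_columns,response_column Model columns.
#' @return A list with `records` (data frame: `perm_index`, `y_correlation`,
#'   `r2`, `q2`; row 0 is the identity), `trend_spearman`, and `n_failed`.
#' @export
y_permutation_test <- function(table, n_perm = 500L, seed,
                               n_components = 1L,
                               predictor_columns = c("yp_rate", "pi_rate"),
                               response_column = "fusion_rate") {
  validate_sample_table(table)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  table <- table[order(table$sample_id), , drop = FALSE]
  table$role <- "train"
  n <- nrow(table)
  y0 <- table[[response_column]]
  sub_seeds <- withr::with_seed(as.integer(seed),
    sample.int(.Machine$integer.max - 1L, n_perm))
  perms <- c(list(seq_len(n)),
             lapply(seq_len(n_perm),
                    function(i) withr::with_seed(sub_seeds[i], sample.int(n))))
  rows <- vector("list", length(perms))
  n_failed <- 0L
  for (k in seq_along(perms)) {
    tab_k <- table
    tab_k[[response_column]] <- y0[perms[[k]]]
    res <- tryCatch({
      model <- pls_fit(tab_k, predictor_columns, response_column,
                       n_components = n_components)
      st <- fit_stats(model, tab_k)
      data.frame(perm_index = k - 1L,
                 y_correlation = stats::cor(tab_k[[response_column]], y0),
                 r2 = st$r2_train, q2 = st$q2_loo,
                 stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else rows[[k]] <- res
  }
  records <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  trend <- stats::cor(abs(records$y_correlation), records$r2,
                      method = "spearman")
  list(records = records, trend_spearman = trend, n_failed = n_failed)
}
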