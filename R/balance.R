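# numeric feature columns of a table (schema features minus the label)
.feature_cols <- function(table) {
  setdiff(.schema_cols[[feature_schema(table)]], "label")
}

.check_labels <- function(labels) {
  lv <- unique(labels)
  bad <- setdiff(lv, c("faller", "non_faller"))
  if (length(bad)) {
    stop("labels must be 'faller' or 'non_faller'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(lv)
}

#' SMOTE oversampling to class parity
#'
#' Synthetic Minority Oversampling: until the two classes are balanced,
#' repeatedly (1) pick a minority-class feature vector, (2) pick one of its
#' `k_neighbors` nearest minority neighbours (Euclidean distance in feature
#' space), (3) take the difference between the two, (4) multiply it by a
#' uniform random number in (0, 1) and add it to the original vector,
#' yielding a new sample on the segment between the pair. Original rows are
#' preserved bit-exactly; synthetic rows are appended with
#' `provenance = "smote"`.
#'
#' @param table Feature data.frame (either schema) with a two-class `label`
#'   column.
#' @param k_neighbors Number of nearest minority neighbours to draw from
#'   (default 5); must be smaller than the minority class.
#' @param seed Integer seed for the sampling.
#' @return The balanced table: original rows first, synthetic rows appended.
#' @export
smote_oversample <- function(table, k_neighbors = 5L, seed = 1L) {
  feats <- .feature_cols(table)
  .check_labels(table$label)
  counts <- table(table$label)
  if (length(counts) != 2L) {
    stop("SMOTE needs exactly two classes present; found ", length(counts),
         call. = FALSE)
  }
  if (counts[1L] == counts[2L]) return(table)
  minority <- names(counts)[which.min(counts)]
  n_needed <- abs(diff(as.integer(counts)))
  min_idx <- which(table$label == minority)
  if (k_neighbors < 1L || k_neighbors >= length(min_idx)) {
    stop("k_neighbors must be in [1, minority size); minority has ",
         length(min_idx), " rows", call. = FALSE)
  }

  X <- as.matrix(table[min_idx, feats, drop = FALSE])
  d2 <- as.matrix(stats::dist(X))^2
  nn <- t(apply(d2, 1L, function(r) order(r)[2:(k_neighbors + 1L)]))

  set.seed(seed)
  base <- sample(seq_along(min_idx), n_needed, replace = TRUE)
  pick <- vapply(base, function(b) nn[b, sample.int(k_neighbors, 1L)], integer(1))
  u <- stats::runif(n_needed)
  synth_X <- X[base, , drop = FALSE] + u * (X[pick, , drop = FALSE] - X[base, , drop = FALSE])

  synth <- as.data.frame(synth_X)
  names(synth) <- feats
  synth$label <- minority
  synth$provenance <- "smote"
  synth$subject_id <- sprintf("smote_%03d", seq_len(n_needed))

  if (!"provenance" %in% names(table)) table$provenance <- "primary"
  if (!"subject_id" %in% names(table)) {
    table$subject_id <- sprintf("row_%03d", seq_len(nrow(table)))
  }
  out <- rbind(table[, names(synth), drop = FALSE], synth)
  rownames(out) <- NULL
  out
}

#' Standardise feature columns (z-scoring)
#'
#' Centres and scales each feature column to `z = (x - mu) / s`. When
#' `fit_params` is omitted, `mu` and `s` are estimated from `table` and
#' returned; passing the parameters fitted on a training set applies them to
#' new data without refitting, so test statistics never leak into the
#' transform.
#'
#' @param table Feature data.frame.
#' @param fit_params Optional `scaler_params` from a previous fit.
#' @return List with `table` (scaled) and `params` (`scaler_params`: `mu`,
#'   `s` named numeric vectors).
#' @export
standard_scale <- function(table, fit_params = NULL) {
  feats <- .feature_cols(table)
  if (is.null(fit_params)) {
    mu <- vapply(table[feats], mean, numeric(1))
    s <- vapply(table[feats], stats::sd, numeric(1))
    if (any(!is.finite(s) | s <= 0)) {
      bad <- feats[!is.finite(s) | s <= 0]
      stop("zero-variance feature column(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    fit_params <- structure(list(mu = mu, s = s), class = "scaler_params")
  } else {
    stopifnot(inherits(fit_params, "scaler_params"))
    if (!all(feats %in% names(fit_params$mu))) {
      stop("fit_params do not cover the table's feature columns", call. = FALSE)
    }
  }
  for (f in feats) {
    table[[f]] <- (table[[f]] - fit_params$mu[[f]]) / fit_params$s[[f]]
  }
  list(table = table, params = fit_params)
}

#' Stratified train/test split
#'
#' Shuffles and splits class-proportionally. The total test size is
#' `ceiling((1 - train_fraction) * n)`; per-class test counts start at the
#' floor of the class's share and remaining slots go to the classes with the
#' largest fractional remainder (ties resolved in label sort order). On the
#' 88-row balanced table at 70:30 this yields 61 train / 27 test with 14
#' fallers and 13 non-fallers in the test set.
#'
#' @param table Feature data.frame with a `label` column.
#' @param train_fraction Fraction of rows for training (default 0.7).
#' @param seed Integer seed for the shuffle.
#' @return List with `train` and `test` data.frames (disjoint, union = input).
#' @export
stratified_split <- function(table, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  }
  counts <- table(table$label)
  if (any(counts < 2L)) {
    stop("every class needs at least 2 rows to split; counts: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(table)
  n_test <- as.integer(ceiling((1 - train_fraction) * n))
  labs <- sort(names(counts))
  exact <- (1 - train_fraction) * as.numeric(counts[labs])
  base <- pmin(floor(exact), as.numeric(counts[labs]) - 1) # keep >=1 in train
  rem <- n_test - sum(base)
  if (rem > 0L) {
    ord <- order(-(exact - floor(exact)), labs)
    for (j in ord) {
      if (rem == 0L) break
      if (base[j] < counts[labs[j]] - 1) {
        base[j] <- base[j] + 1
        rem <- rem - 1L
      }
    }
  }
  set.seed(seed)
  test_idx <- integer(0)
  for (j in seq_along(labs)) {
    idx <- which(table$label == labs[j])
    test_idx <- c(test_idx, sample(idx, base[j]))
  }
  list(train = table[-test_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE])
}
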