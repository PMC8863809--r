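# Picture-level nose temperatures -> one corrected, log-scale temperature per
# event. The view angle of a picture biases the measured nose temperature, so
# events without a facing-angle picture get a facing-equivalent value imputed
# by regularized iterative PCA over the event x angle matrix.

#' Filter thermal pictures to the valid capture window
#'
#' Keeps pictures taken between `time_window[1]` and `time_window[2]` seconds
#' after the event (the thermal response develops after the first 15 s and
#' pictures are taken for up to 300 s) and with temperatures inside
#' physiological bounds.
#'
#' @param observations Picture table with columns `event_id`, `angle`,
#'   `temp_c`, `sec_after_event`.
#' @param time_window Numeric length-2, seconds after the event (default
#'   `c(15, 300)`).
#' @param temp_bounds Physiological bounds in deg C (default `c(20, 42)`).
#' @return The filtered picture table.
#' @export
filter_observations <- function(observations, time_window = c(15, 300),
                                temp_bounds = c(20, 42)) {
  keep <- observations$sec_after_event >= time_window[1] &
    observations$sec_after_event <= time_window[2] &
    observations$temp_c >= temp_bounds[1] &
    observations$temp_c <= temp_bounds[2]
  out <- observations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the event-by-angle temperature matrix
#'
#' Rows are events, columns the seven view-angle categories (`facing` first);
#' each cell is the arithmetic mean of that event's picture temperatures at
#' that angle, `NA` where no picture exists. Events whose pictures all fall
#' outside the capture window are dropped with a warning.
#'
#' @inheritParams filter_observations
#' @param angles Column order; defaults to [ts_angle_levels()].
#' @return Numeric matrix (events x angles) with `event_id` rownames, of
#'   class `ts_angle_matrix`.
#' @export
build_angle_matrix <- function(observations, angles = ts_angle_levels(),
                               time_window = c(15, 300),
                               temp_bounds = c(20, 42)) {
  all_events <- unique(observations$event_id)
  obs <- filter_observations(observations, time_window, temp_bounds)
  lost <- setdiff(all_events, unique(obs$event_id))
  if (length(lost))
    warning(length(lost), " event(s) with no valid pictures dropped: ",
            paste(utils::head(lost, 5), collapse = ", "),
            if (length(lost) > 5) ", ..." else "", call. = FALSE)
  ts_assert(nrow(obs) > 0, "no observations survive the capture-window filter")
  ts_assert(all(obs$angle %in% angles),
            "unknown angle categories: ",
            paste(setdiff(unique(obs$angle), angles), collapse = ", "))
  events <- unique(obs$event_id)
  m <- matrix(NA_real_, nrow = length(events), ncol = length(angles),
              dimnames = list(events, angles))
  agg <- stats::aggregate(temp_c ~ event_id + angle, data = obs, FUN = mean)
  m[cbind(agg$event_id, agg$angle)] <- agg$temp_c
  structure(m, class = c("ts_angle_matrix", "matrix", "array"))
}

#' Regularized iterative PCA completion of a partially observed matrix
#'
#' EM-style matrix completion: missing cells are initialized with column
#' means, then the algorithm iterates (1) center columns using observed and
#' current imputed values, (2) SVD of the centered matrix, (3) low-rank
#' reconstruction in which each retained singular value `s` is shrunk to
#' `(s^2 - sigma2) / s`, with `sigma2` the residual noise variance estimated
#' from the discarded singular values (mean of the discarded squared singular
#' values over the residual degrees of freedom), and (4) overwriting of the
#' missing cells with the reconstruction. Iteration stops when the sum of
#' squared changes in the imputed cells drops below `tol`. Observed cells are
#' never altered. With `regularize = FALSE` the shrinkage is switched off and
#' the scheme reduces to plain iterative (EM-)PCA.
#'
#' @param matrix Numeric matrix with `NA`s for missing cells (e.g. a
#'   `ts_angle_matrix`).
#' @param rank Number of principal components kept (default 2); must be
#'   smaller than `min(dim(matrix))`.
#' @param tol Convergence tolerance on the sum of squared changes in imputed
#'   cells (default 1e-6).
#' @param max_iter Iteration cap (default 1000); non-convergence returns the
#'   last iterate with `converged = FALSE`.
#' @param regularize Apply singular-value shrinkage (default `TRUE`).
#' @return List of class `ts_imputation`: `completed` (matrix with missing
#'   cells filled), `observed` (logical mask), `converged`, `n_iter`,
#'   `last_change`, `trace` (per-iteration sum of squared changes in the
#'   imputed cells), `rank`.
#' @export
impute_regularized_pca <- function(matrix, rank = 2, tol = 1e-6,
                                   max_iter = 1000, regularize = TRUE) {
  X <- unclass(matrix)
  ts_assert(is.matrix(X) && is.numeric(X), "matrix must be numeric")
  n <- nrow(X); p <- ncol(X)
  ts_assert(rank >= 1 && rank < min(n, p),
            "rank must satisfy 1 <= rank < min(dim(matrix))")
  obs <- !is.na(X)
  ts_assert(all(rowSums(obs) > 0), "every row needs at least one observed cell")
  ts_assert(all(colSums(obs) > 0), "every column needs at least one observed cell")

  if (all(obs)) {
    return(structure(list(completed = X, observed = obs, converged = TRUE,
                          n_iter = 0L, last_change = 0, rank = rank),
                     class = "ts_imputation"))
  }

  col_means <- colMeans(X, na.rm = TRUE)
  Xc <- X
  Xc[!obs] <- col_means[col(X)[!obs]]

  converged <- FALSE
  change <- Inf
  iter <- 0L
  q <- min(n, p)
  trace <- numeric(0)
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- colMeans(Xc)
    Z <- sweep(Xc, 2, mu)
    sv <- svd(Z)
    s <- sv$d
    if (regularize && rank < q) {
      # residual noise on the squared-singular-value scale: mean of the
      # discarded squared singular values over the residual dimensions
      sigma2 <- sum(s[(rank + 1):q]^2) / (q - rank)
      s_shrunk <- pmax((s[1:rank]^2 - sigma2) / s[1:rank], 0)
    } else {
      s_shrunk <- s[1:rank]
    }
    recon <- sv$u[, 1:rank, drop = FALSE] %*%
      (s_shrunk * t(sv$v[, 1:rank, drop = FALSE]))
    recon <- sweep(recon, 2, mu, "+")
    new_imputed <- recon[!obs]
    change <- sum((new_imputed - Xc[!obs])^2)
    trace[iter] <- change
    Xc[!obs] <- new_imputed
    if (change < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("regularized iterative PCA did not converge in ", max_iter,
            " iterations (last change ", signif(change, 3), ")",
            call. = FALSE)
  structure(list(completed = Xc, observed = obs, converged = converged,
                 n_iter = iter, last_change = change, rank = rank,
                 trace = trace),
            class = "ts_imputation")
}

#' Cross-validated choice of the imputation rank
#'
#' Masks a random fraction of the observed cells, imputes them at each
#' candidate rank with [impute_regularized_pca()], and returns the rank with
#' the smallest root-mean-square prediction error. Useful because with too
#' high a rank the spare components can park arbitrary structure in the
#' missing cells without any penalty on the observed ones.
#'
#' @inheritParams impute_regularized_pca
#' @param ranks Candidate ranks (default `1:3`).
#' @param prop Fraction of observed cells to mask per fold (default 0.1).
#' @param n_folds Number of masking folds averaged per rank (default 3).
#' @param seed Seed for the masking (default 1).
#' @return List: `rank` (selected), `cv_error` (named RMSE per rank).
#' @export
select_rank_cv <- function(matrix, ranks = 1:3, prop = 0.1, n_folds = 3,
                           tol = 1e-6, max_iter = 1000, regularize = TRUE,
                           seed = 1) {
  X <- unclass(matrix)
  obs_idx <- which(!is.na(X))
  ranks <- ranks[ranks < min(dim(X))]
  ts_assert(length(ranks) > 0, "no admissible ranks")
  err <- matrix(NA_real_, n_folds, length(ranks))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (f in seq_len(n_folds)) {
    # only mask cells in rows that keep at least one other observation
    maskable <- obs_idx[rowSums(!is.na(X))[((obs_idx - 1) %% nrow(X)) + 1] >= 2]
    mask <- sample(maskable, max(1, round(prop * length(maskable))))
    Xm <- X
    Xm[mask] <- NA
    still_bad <- which(rowSums(!is.na(Xm)) == 0)
    if (length(still_bad)) {
      restore <- mask[(((mask - 1) %% nrow(X)) + 1) %in% still_bad]
      Xm[restore] <- X[restore]
      mask <- setdiff(mask, restore)
    }
    for (r in seq_along(ranks)) {
      imp <- suppressWarnings(
        impute_regularized_pca(Xm, rank = ranks[r], tol = tol,
                               max_iter = max_iter,
                               regularize = regularize))
      err[f, r] <- sqrt(mean((imp$completed[mask] - X[mask])^2,
                             na.rm = TRUE))
    }
  }
  cv <- stats::setNames(colMeans(err), ranks)
  list(rank = as.integer(ranks[which.min(cv)]), cv_error = cv)
}

#' Corrected event-level temperatures
#'
#' Assigns each event one facing-equivalent nose temperature: events with an
#' observed facing-angle cell use it directly (`was_imputed = FALSE`); events
#' without one use the value imputed by [impute_regularized_pca()]
#' (`was_imputed = TRUE`). The natural log of the corrected temperature is
#' the response modelled downstream. Imputed values falling outside
#' physiological bounds are flagged and excluded.
#'
#' @param imputation A `ts_imputation` over an event-by-angle matrix whose
#'   first column is `facing`.
#' @param temp_bounds Physiological bounds for imputed values (default
#'   `c(20, 42)`).
#' @return Data frame `event_id`, `corrected_temp_c`, `log_temp`,
#'   `was_imputed`, with attribute `fraction_imputed` (share of events whose
#'   facing value was imputed) and `n_excluded`.
#' @export
correct_events <- function(imputation, temp_bounds = c(20, 42)) {
  ts_assert(inherits(imputation, "ts_imputation"),
            "imputation must come from impute_regularized_pca()")
  M <- imputation$completed
  ts_assert("facing" %in% colnames(M), "matrix must have a 'facing' column")
  facing <- M[, "facing"]
  observed_facing <- imputation$observed[, "facing"]
  out <- data.frame(event_id = rownames(M),
                    corrected_temp_c = unname(facing),
                    was_imputed = !observed_facing,
                    stringsAsFactors = FALSE)
  bad <- out$was_imputed & (out$corrected_temp_c < temp_bounds[1] |
                              out$corrected_temp_c > temp_bounds[2])
  if (any(bad)) {
    warning(sum(bad), " imputed temperature(s) outside physiological bounds",
            " excluded", call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  out$log_temp <- log(out$corrected_temp_c)
  out <- out[, c("event_id", "corrected_temp_c", "log_temp", "was_imputed")]
  rownames(out) <- NULL
  attr(out, "fraction_imputed") <- mean(out$was_imputed)
  attr(out, "n_imputed") <- sum(out$was_imputed)
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' One-call angle correction
#'
#' Convenience wrapper chaining [build_angle_matrix()],
#' [impute_regularized_pca()] and [correct_events()].
#'
#' @inheritParams build_angle_matrix
#' @inheritParams impute_regularized_pca
#' @return See [correct_events()]; additionally carries attribute
#'   `imputation` with the full `ts_imputation` object.
#' @export
correct_thermal <- function(observations, rank = 2, tol = 1e-6,
                            max_iter = 1000, regularize = TRUE,
                            time_window = c(15, 300),
                            temp_bounds = c(20, 42)) {
  m <- build_angle_matrix(observations, time_window = time_window,
                          temp_bounds = temp_bounds)
  # drop all-missing angle columns (imputation needs every kept column
  # observed at least once); facing must be present somewhere
  keep <- colSums(!is.na(m)) > 0
  ts_assert(keep["facing"], "no facing-angle pictures in the dataset")
  m2 <- m[, keep, drop = FALSE]
  imp <- impute_regularized_pca(m2, rank = min(rank, ncol(m2) - 1),
                                tol = tol, max_iter = max_iter,
                                regularize = regularize)
  out <- correct_events(imp, temp_bounds = temp_bounds)
  attr(out, "imputation") <- imp
  out
}
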