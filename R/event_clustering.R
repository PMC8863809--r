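# Cluster the social event types by their nose-temperature signatures:
# Ward's minimum-variance hierarchical clustering of per-subject residual
# profiles, silhouette-based choice of the number of clusters, and
# cophenetic validation of the linkage.

#' Thermal-signature profiles per event type
#'
#' One feature vector per social event type: the per-subject mean of
#' residual log temperatures (log temperature minus the baseline-calibrated
#' ambient and movement adjustments), plus the type's overall mean and SD.
#' Subject-by-type cells with no events are filled with the subject's grand
#' mean residual (flagged in the `filled` attribute) so that vectors stay
#' comparable; features are standardized column-wise before clustering.
#' Baseline events are excluded: the baseline is the comparison level of the
#' downstream model, not a clustered type.
#'
#' @param events Data frame with columns `event_type`, `subject_id`,
#'   `log_temp`, `ambient_c`, `movement`.
#' @param adjustment Confound adjustment from [calibrate_confounds()]
#'   (`$adjustment`): list with `ambient_slope`, `ambient_mean`,
#'   `movement_offsets`. `NULL` for no adjustment.
#' @param exclude Event types excluded from clustering (default
#'   `"baseline"`).
#' @param standardize Standardize feature columns (default `TRUE`).
#' @return Numeric matrix (types x features) of class `ts_profiles`, with
#'   attributes `filled` (logical matrix of filled cells) and `residuals`
#'   (per-event residuals used).
#' @export
build_profiles <- function(events, adjustment = NULL,
                           exclude = "baseline", standardize = TRUE) {
  ev <- events[!events$event_type %in% exclude, , drop = FALSE]
  ts_assert(nrow(ev) > 0, "no events to profile")
  resid <- ev$log_temp
  if (!is.null(adjustment)) {
    resid <- resid - adjustment$ambient_slope *
      (ev$ambient_c - adjustment$ambient_mean)
    off <- adjustment$movement_offsets
    hit <- ev$movement %in% names(off)
    resid[hit] <- resid[hit] - unname(off[ev$movement[hit]])
  }
  types <- sort(unique(ev$event_type))
  subjects <- sort(unique(ev$subject_id))
  cell <- tapply(resid, list(ev$event_type, ev$subject_id), mean)
  cell <- cell[types, subjects, drop = FALSE]
  grand <- tapply(resid, ev$subject_id, mean)[subjects]
  filled <- is.na(cell)
  if (any(filled))
    cell[filled] <- grand[col(cell)[filled]]
  overall_mean <- tapply(resid, ev$event_type, mean)[types]
  overall_sd <- tapply(resid, ev$event_type, stats::sd)[types]
  overall_sd[is.na(overall_sd)] <- 0   # single-event types
  feats <- cbind(cell, mean = overall_mean, sd = overall_sd)
  ts_assert(all(is.finite(feats)), "non-finite profile features")
  if (standardize) {
    sds <- apply(feats, 2, stats::sd)
    sds[sds == 0] <- 1
    feats <- scale(feats, center = TRUE, scale = sds)
    feats <- feats[, , drop = FALSE]  # strip scale attrs via subset below
    attr(feats, "scaled:center") <- NULL
    attr(feats, "scaled:scale") <- NULL
  }
  structure(unclass(feats), class = c("ts_profiles", "matrix", "array"),
            filled = filled, residuals = data.frame(
              event_id = if ("event_id" %in% names(ev)) ev$event_id else NA,
              event_type = ev$event_type, subject_id = ev$subject_id,
              residual = resid, stringsAsFactors = FALSE))
}

#' Ward's minimum-variance clustering of event-type profiles
#'
#' Agglomerative hierarchical clustering of the profile vectors on Euclidean
#' distances with Ward's criterion (each merge minimizes the increase in
#' total within-cluster sum of squares; `hclust` method `"ward.D2"`). The
#' cophenetic correlation of the Ward tree with the original distances is
#' reported alongside the same quantity for single linkage, as a check that
#' the minimum-variance method represents the distances at least as
#' faithfully.
#'
#' @param profiles A `ts_profiles` matrix (or any numeric matrix with at
#'   least 3 rows).
#' @return List of class `ts_cluster`: `hclust` (Ward tree), `dist`,
#'   `cophenetic` (named correlations for `ward` and `single`), `labels`.
#' @export
ward_cluster <- function(profiles) {
  X <- unclass(profiles)
  ts_assert(is.matrix(X) && nrow(X) >= 3,
            "need at least 3 profiles to cluster")
  d <- stats::dist(X, method = "euclidean")
  hc_ward <- stats::hclust(d, method = "ward.D2")
  hc_single <- stats::hclust(d, method = "single")
  coph <- c(ward = stats::cor(d, stats::cophenetic(hc_ward)),
            single = stats::cor(d, stats::cophenetic(hc_single)))
  structure(list(hclust = hc_ward, single = hc_single, dist = d,
                 cophenetic = coph, labels = rownames(X)),
            class = "ts_cluster")
}

#' Choose the number of clusters by mean silhouette width
#'
#' Cuts the Ward tree at each `k` in `k_range`, computes the silhouette
#' width `s(i) = (b(i) - a(i)) / max(a(i), b(i))` of every event type
#' (`a` = mean within-cluster distance, `b` = mean distance to the nearest
#' other cluster; singletons get `s = 0`), and picks the `k` with the
#' largest mean width, breaking ties toward smaller `k`.
#'
#' @param clustering A `ts_cluster` from [ward_cluster()].
#' @param k_range Candidate numbers of clusters (default `2:6`, clipped to
#'   `n - 1`).
#' @return List of class `ts_k_choice`: `k`, `assignment` (named integer
#'   vector), `mean_widths` (named by k), `silhouette` (per-item widths at
#'   the chosen k).
#' @export
choose_k_silhouette <- function(clustering, k_range = 2:6) {
  ts_assert(inherits(clustering, "ts_cluster"),
            "clustering must come from ward_cluster()")
  n <- length(clustering$labels)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  ts_assert(length(k_range) > 0, "k_range empty after clipping to [2, n-1]")
  widths <- stats::setNames(numeric(length(k_range)), k_range)
  sils <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    memb <- stats::cutree(clustering$hclust, k = k_range[i])
    sil <- cluster::silhouette(memb, clustering$dist)
    sils[[i]] <- stats::setNames(sil[, "sil_width"], clustering$labels)
    widths[i] <- mean(sil[, "sil_width"])
  }
  best <- which(widths == max(widths))[1]  # ties toward smaller k
  k <- k_range[best]
  assignment <- stats::cutree(clustering$hclust, k = k)
  structure(list(k = k, assignment = assignment,
                 mean_widths = widths, silhouette = sils[[best]]),
            class = "ts_k_choice")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two cluster assignments of the same
#' items; 1 means identical partitions up to label permutation, 0 is the
#' expected agreement of random labellings.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  ts_assert(length(a) == length(b), "partitions must have equal length")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
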