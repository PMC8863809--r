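# Dyadic social indices from long-term interaction logs: the Composite
# Relationship Index (CRI), bond / non-bond partner sets, and Elo-rating
# dominance scores.

as_interaction_log <- function(x) {
  if (inherits(x, "ts_interaction_log")) return(x)
  if (is.list(x) && !is.null(x$records) && !is.null(x$effort))
    return(structure(x, class = "ts_interaction_log"))
  stop("expected a ts_interaction_log (list with $records and $effort)",
       call. = FALSE)
}

CRI_AGGRESSION_KINDS <- c("aggression", "chase", "threat", "severe")
ELO_KINDS <- c("severe", "chase", "threat", "pantgrunt")

#' Composite Relationship Index for one focal individual
#'
#' Dyadic index combining socio-positive and socio-negative interactions
#' over the long-term window:
#' `CRI = (G + R - 5 * A) / T`, where `G` is the number of 15-min occurrences
#' in which the focal groomed, was groomed by, or mutually groomed partner j;
#' `R` the occurrences resting within 5 m of j; `A` the number of aggressions
#' (displays/aggressions, chases, threats, severe aggressions) involving the
#' focal and j in either direction, severe aggressions counting double; and
#' `T` the focal's total 15-min observation occurrences. The aggression block
#' is multiplied by five to rebalance event counts against 15-min occurrence
#' counts. Positive CRI indicates a socio-positive relationship.
#'
#' @param log A `ts_interaction_log` (records + focal observation effort).
#' @param focal Subject id.
#' @return Data frame `partner`, `cri`, sorted by decreasing CRI.
#' @export
compute_cri <- function(log, focal) {
  log <- as_interaction_log(log)
  eff <- log$effort
  total <- eff$total_occurrences[eff$subject_id == focal]
  ts_assert(length(total) == 1 && total > 0,
            "total focal occurrences must be positive for ", focal)
  rec <- log$records
  inv <- rec$actor == focal | rec$receiver == focal
  rec <- rec[inv, , drop = FALSE]
  partner <- ifelse(rec$actor == focal, rec$receiver, rec$actor)
  partners <- sort(unique(partner))
  tally <- function(kinds, weights = rep(1, length(kinds))) {
    w <- stats::setNames(weights, kinds)
    sel <- rec$kind %in% kinds
    if (!any(sel)) return(stats::setNames(numeric(length(partners)), partners))
    s <- tapply(rec$count[sel] * w[rec$kind[sel]], partner[sel], sum)
    out <- stats::setNames(numeric(length(partners)), partners)
    out[names(s)] <- s
    out
  }
  G <- tally("groom")
  R <- tally("prox5m")
  A <- tally(CRI_AGGRESSION_KINDS, c(1, 1, 1, 2))  # severe counts twice
  cri <- (G + R - 5 * A) / total
  out <- data.frame(partner = partners, cri = unname(cri),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$cri, out$partner), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' CRI for every focal individual
#'
#' @inheritParams compute_cri
#' @param focals Subjects to use as focals; defaults to every subject with
#'   recorded observation effort.
#' @return Data frame `focal`, `partner`, `cri`.
#' @export
cri_matrix <- function(log, focals = NULL) {
  log <- as_interaction_log(log)
  focals <- focals %||% log$effort$subject_id
  do.call(rbind, lapply(focals, function(f) {
    x <- compute_cri(log, f)
    cbind(focal = f, x)
  }))
}

#' Bond and non-bond partner sets
#'
#' Bond partners are the (up to) three partners with the highest CRI scores
#' above zero; non-bond partners the (up to) three lowest below zero. Either
#' set may hold fewer than three members. Ties are broken by total
#' interaction count with the focal (more interactions first), then by
#' partner id, so the selection is deterministic.
#'
#' @param cri Data frame `partner`, `cri` from [compute_cri()].
#' @param log Optional `ts_interaction_log` used for tie-breaking by
#'   interaction volume.
#' @param focal Focal id (needed only for tie-breaking with `log`).
#' @param n_partners Maximum set size (default 3).
#' @return List with character vectors `bond` and `non_bond` (disjoint).
#' @export
select_bond_partners <- function(cri, log = NULL, focal = NULL,
                                 n_partners = 3) {
  volume <- stats::setNames(numeric(nrow(cri)), cri$partner)
  if (!is.null(log) && !is.null(focal)) {
    log <- as_interaction_log(log)
    rec <- log$records
    inv <- rec$actor == focal | rec$receiver == focal
    p <- ifelse(rec$actor[inv] == focal, rec$receiver[inv], rec$actor[inv])
    v <- tapply(rec$count[inv], p, sum)
    volume[names(v)] <- v
  }
  ord_hi <- order(-cri$cri, -volume[cri$partner], cri$partner)
  ord_lo <- order(cri$cri, -volume[cri$partner], cri$partner)
  pos <- cri[ord_hi, ][cri$cri[ord_hi] > 0, , drop = FALSE]
  neg <- cri[ord_lo, ][cri$cri[ord_lo] < 0, , drop = FALSE]
  list(bond = utils::head(pos$partner, n_partners),
       non_bond = utils::head(neg$partner, n_partners))
}

#' Elo-rating dominance scores
#'
#' Sequential dominance rating over decided agonistic interactions (severe
#' aggressions, chases, threats — aggressor wins) and pant-grunts (the
#' unidirectional submissive vocalization — the receiver wins). After each
#' interaction the winner gains `k * (1 - p)` rating points and the loser
#' loses the same, with `p = 1 / (1 + 10^((r_loser - r_winner) / 400))` the
#' prior expectation of the observed outcome, so total rating mass is
#' conserved. Records are processed in chronological order (by month, then
#' record order). Final scores are also returned standardized to z-scores.
#'
#' @param log A `ts_interaction_log`.
#' @param k_factor Update constant (default 100).
#' @param start_rating Initial rating for every subject (default 1000).
#' @param subjects Roster; defaults to subjects appearing in effort records.
#' @return List of class `ts_elo`: `ratings` (data frame `subject_id`,
#'   `final_elo`, `z_elo`, `n_interactions`), `history` (one row per update),
#'   `k_factor`, `start_rating`.
#' @export
compute_elo <- function(log, k_factor = 100, start_rating = 1000,
                        subjects = NULL) {
  log <- as_interaction_log(log)
  rec <- log$records
  rec <- rec[rec$kind %in% ELO_KINDS, , drop = FALSE]
  rec <- rec[order(rec$month), , drop = FALSE]
  subjects <- subjects %||%
    sort(unique(c(log$effort$subject_id, rec$actor, rec$receiver)))
  r <- stats::setNames(rep(start_rating, length(subjects)), subjects)
  n_int <- stats::setNames(integer(length(subjects)), subjects)
  hist <- vector("list", sum(rec$count))
  h <- 0L
  for (i in seq_len(nrow(rec))) {
    # aggressor wins agonistic interactions; pant-grunt receiver wins
    if (rec$kind[i] == "pantgrunt") {
      winner <- rec$receiver[i]; loser <- rec$actor[i]
    } else {
      winner <- rec$actor[i]; loser <- rec$receiver[i]
    }
    for (j in seq_len(rec$count[i])) {
      p <- 1 / (1 + 10^((r[loser] - r[winner]) / 400))
      delta <- k_factor * (1 - p)
      r[winner] <- r[winner] + delta
      r[loser] <- r[loser] - delta
      n_int[winner] <- n_int[winner] + 1L
      n_int[loser] <- n_int[loser] + 1L
      h <- h + 1L
      hist[[h]] <- data.frame(month = rec$month[i], winner = winner,
                              loser = loser, delta = unname(delta),
                              stringsAsFactors = FALSE)
    }
  }
  if (any(n_int == 0))
    warning("subject(s) with no agonistic interactions keep the start ",
            "rating: ", paste(subjects[n_int == 0], collapse = ", "),
            call. = FALSE)
  ratings <- data.frame(subject_id = subjects,
                        final_elo = unname(r),
                        z_elo = unname(as.vector(scale(r))),
                        n_interactions = unname(n_int),
                        stringsAsFactors = FALSE)
  structure(list(ratings = ratings,
                 history = if (h > 0) do.call(rbind, hist[seq_len(h)])
                           else NULL,
                 k_factor = k_factor, start_rating = start_rating),
            class = "ts_elo")
}

#' Hierarchy stability between the first and second half of the log
#'
#' Spearman rank correlation between final Elo ratings computed on the first
#' and second halves of the logging period. Values near 1 indicate a stable
#' hierarchy; the correlation is reported, not enforced.
#'
#' @inheritParams compute_elo
#' @return List with `rank_correlation`, `split_month`, and the two `ts_elo`
#'   fits.
#' @export
elo_stability <- function(log, k_factor = 100, start_rating = 1000) {
  log <- as_interaction_log(log)
  months <- sort(unique(log$records$month))
  ts_assert(length(months) >= 2, "need at least two months of records")
  split <- months[ceiling(length(months) / 2)]
  sub_log <- function(keep) {
    structure(list(records = log$records[keep, , drop = FALSE],
                   effort = log$effort),
              class = "ts_interaction_log")
  }
  first <- compute_elo(sub_log(log$records$month <= split),
                       k_factor, start_rating,
                       subjects = log$effort$subject_id)
  second <- compute_elo(sub_log(log$records$month > split),
                        k_factor, start_rating,
                        subjects = log$effort$subject_id)
  rho <- stats::cor(first$ratings$final_elo, second$ratings$final_elo,
                    method = "spearman")
  list(rank_correlation = rho, split_month = split,
       first_half = first, second_half = second)
}
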