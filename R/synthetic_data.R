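# Synthetic field-study generator: thermal pictures, event metadata and
# long-term interaction logs with known ground truth, so that every stage of
# the analysis pipeline can be validated by parameter recovery.

#' Configuration for the synthetic-data generator
#'
#' Defines the generative model for a synthetic thermography field study:
#' nine focal adult males observed during thirteen social event types plus a
#' resting baseline, with cluster-structured true nose temperatures, subject
#' and movement effects, an ambient-temperature confound, view-angle
#' measurement bias, and planted audience moderators.
#'
#' The event-level expected nose temperature is
#' `cluster mean + cluster-specific subject profile + subject intercept +
#' movement offset + ambient_slope * (ambient - 25) + audience terms`,
#' where the audience terms apply only to events of the relevant group
#' (alpha presence to cooperative events, female count to competitive
#' events, male count and mother presence to copulations). Each picture adds
#' the angle bias of its view-angle category and i.i.d. Gaussian picture
#' noise.
#'
#' @param n_subjects Number of focal adult males (default 9).
#' @param n_events_per_type Events generated per social event type
#'   (default 65, giving roughly 390 events per six-type group at the scale
#'   of a six-month field season).
#' @param n_baseline_events Resting baseline events (default 392).
#' @param event_types Character vector of the 13 social types plus
#'   `"baseline"`.
#' @param cluster_map Named map event type -> group in `{A, B, C, baseline}`;
#'   must cover every event type exactly once.
#' @param cluster_means Named numeric, group intercepts (deg C). The
#'   defaults (34.28, 32.71, 34.04, 33.46) are calibrated so that after the
#'   movement, signature and audience contributions the marginal group means
#'   come out at about 33.6 (cooperative), 32.8 (competitive), 33.6 (mixed)
#'   and 33.1 (baseline) deg C, the group means observed in the field study
#'   the generator emulates.
#' @param cluster_sds Named numeric, event-level residual temperature SD
#'   (deg C) per group. The defaults (1.05, 1.60, 0.70, 2.00) are calibrated
#'   so that the marginal per-group SD — residual plus subject, signature,
#'   movement, ambient and audience variance — matches the dispersions
#'   observed in the field (about 1.66, 2.10, 1.45 and 2.16 deg C).
#' @param cluster_profile_sd Magnitude (deg C) of the group-specific
#'   per-subject response signatures that give each functional group a
#'   distinct thermal profile beyond its mean: each non-baseline group adds
#'   `+/- cluster_profile_sd` per subject following a fixed near-orthogonal
#'   sign pattern (default 1.0).
#' @param subject_sd SD (deg C) of per-subject random intercepts (default 0.4).
#' @param movement_effects Named offsets (deg C) for prior movement
#'   `no_movement`, `steps`, `travel`.
#' @param ambient_slope Change in nose temperature (deg C) per deg C of
#'   ambient temperature (default 0.2).
#' @param humidity_slope,distance_slope Confound slopes for ambient humidity
#'   (per percent) and camera distance (per metre); default 0 (no effect).
#' @param angle_bias Named offsets (deg C) per view-angle category;
#'   `facing` must be exactly 0.
#' @param picture_sd SD (deg C) of i.i.d. picture-level measurement noise.
#' @param audience_effects Named coefficients:
#'   `alpha_presence_cooperative` (deg C added to cooperative events when the
#'   alpha male is within 35 m), `female_count_competitive` (deg C per female
#'   within 10 m during competitive events), `male_count_copulation` (deg C
#'   per male within 10 m during copulation), `mother_presence_copulation`
#'   (deg C when the subject's mother is within 35 m during copulation).
#' @param pictures_per_event Integer range (length 2) of pictures per event.
#' @param missing_facing_prob Probability that an event has no facing-angle
#'   picture and therefore needs an imputed facing temperature.
#' @param n_with_mother Number of focal males with a living mother
#'   (default 5).
#' @param months_longterm Months of long-term interaction logs preceding the
#'   study (default 6).
#' @param effort_per_month 15-min focal observation occurrences per subject
#'   per month (default 60).
#' @param groom_rate,prox_rate Baseline 15-min occurrence rates per dyad per
#'   month for grooming and resting within 5 m.
#' @param bond_multiplier Rate multiplier for planted bond dyads (default 4).
#' @param rival_aggression_multiplier Aggression-rate multiplier for planted
#'   rival (socio-negative) dyads.
#' @param agonistic_rate Decided agonistic interactions per male dyad per
#'   month feeding the Elo rating (default 1.5).
#' @param pantgrunt_rate Pant-grunt events per male dyad per month.
#' @param severe_prob Probability an agonistic interaction is a severe
#'   aggression.
#' @param hierarchy_steepness Logistic steepness of the planted hierarchy:
#'   the probability that the higher-ranked male wins an agonistic
#'   interaction is `plogis(hierarchy_steepness * rank difference)`. Large
#'   values give an (almost) strict hierarchy.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration and seed.
#'
#' @return An object of class `ts_generator_config` (validated list).
#' @seealso [generate_dataset()], [write_fixture()]
#' @export
generator_config <- function(n_subjects = 9,
                             n_events_per_type = 65,
                             n_baseline_events = 392,
                             event_types = names(ts_event_cluster_map()),
                             cluster_map = ts_event_cluster_map(),
                             cluster_means = c(A = 34.28, B = 32.71,
                                               C = 34.04, baseline = 33.46),
                             cluster_sds = c(A = 1.05, B = 1.60, C = 0.70,
                                             baseline = 2.00),
                             cluster_profile_sd = 1.0,
                             subject_sd = 0.4,
                             movement_effects = c(no_movement = 0,
                                                  steps = -0.4,
                                                  travel = -1.0),
                             ambient_slope = 0.2,
                             humidity_slope = 0,
                             distance_slope = 0,
                             angle_bias = c(facing = 0,
                                            quarter_left = -0.3,
                                            quarter_right = -0.3,
                                            half_left = -0.7,
                                            half_right = -0.7,
                                            profile_left = -1.2,
                                            profile_right = -1.2),
                             picture_sd = 0.3,
                             audience_effects = c(
                               alpha_presence_cooperative = -0.5,
                               female_count_competitive = 0.2,
                               male_count_copulation = 0.3,
                               mother_presence_copulation = -2.1),
                             pictures_per_event = c(1L, 13L),
                             missing_facing_prob = 0.46,
                             n_with_mother = 5,
                             months_longterm = 6,
                             effort_per_month = 60,
                             groom_rate = 4,
                             prox_rate = 4,
                             bond_multiplier = 4,
                             rival_aggression_multiplier = 8,
                             agonistic_rate = 1.5,
                             pantgrunt_rate = 1,
                             severe_prob = 0.1,
                             hierarchy_steepness = 0.7,
                             seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_events_per_type = as.integer(n_events_per_type),
              n_baseline_events = as.integer(n_baseline_events),
              event_types = event_types,
              cluster_map = cluster_map,
              cluster_means = cluster_means,
              cluster_sds = cluster_sds,
              cluster_profile_sd = cluster_profile_sd,
              subject_sd = subject_sd,
              movement_effects = movement_effects,
              ambient_slope = ambient_slope,
              humidity_slope = humidity_slope,
              distance_slope = distance_slope,
              angle_bias = angle_bias,
              picture_sd = picture_sd,
              audience_effects = audience_effects,
              pictures_per_event = as.integer(pictures_per_event),
              missing_facing_prob = missing_facing_prob,
              n_with_mother = as.integer(n_with_mother),
              months_longterm = as.integer(months_longterm),
              effort_per_month = effort_per_month,
              groom_rate = groom_rate,
              prox_rate = prox_rate,
              bond_multiplier = bond_multiplier,
              rival_aggression_multiplier = rival_aggression_multiplier,
              agonistic_rate = agonistic_rate,
              pantgrunt_rate = pantgrunt_rate,
              severe_prob = severe_prob,
              hierarchy_steepness = hierarchy_steepness,
              seed = as.integer(seed))
  class(cfg) <- "ts_generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  ts_assert(cfg$n_subjects >= 1, "need at least one subject")
  ts_assert(cfg$n_events_per_type >= 1 && cfg$n_baseline_events >= 1,
            "need at least one event per type")
  ts_assert(all(c(cfg$cluster_sds, cfg$subject_sd, cfg$picture_sd,
                  cfg$cluster_profile_sd) >= 0),
            "all SDs must be non-negative")
  probs <- c(cfg$missing_facing_prob, cfg$severe_prob)
  ts_assert(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  ts_assert(setequal(names(cfg$cluster_map), cfg$event_types) &&
              !anyDuplicated(names(cfg$cluster_map)),
            "cluster_map must cover every event type exactly once")
  ts_assert(all(cfg$cluster_map %in% names(cfg$cluster_means)),
            "cluster_means must name every group used in cluster_map")
  ts_assert(identical(unname(cfg$angle_bias["facing"]), 0),
            "angle_bias['facing'] must be exactly 0")
  ts_assert(setequal(names(cfg$angle_bias), ts_angle_levels()),
            "angle_bias must name the seven angle categories")
  ts_assert(length(cfg$pictures_per_event) == 2 &&
              cfg$pictures_per_event[1] >= 1 &&
              cfg$pictures_per_event[1] <= cfg$pictures_per_event[2],
            "pictures_per_event must be an increasing integer range")
  ts_assert(cfg$n_with_mother <= cfg$n_subjects,
            "n_with_mother cannot exceed n_subjects")
  ts_assert(cfg$months_longterm >= 1, "need at least one month of logs")
  invisible(cfg)
}

rpois_trunc <- function(n, lambda, max) pmin(stats::rpois(n, lambda), max)

#' Generate a complete synthetic dataset
#'
#' Draws a full synthetic field study from a [generator_config()]: a
#' picture-level thermal table, an event-level metadata table, long-term
#' interaction logs, and the ground truth used to generate them. The truth
#' (subject intercepts, true dominance ordering, planted bond partners,
#' realized audience coefficients) is returned alongside the data but never
#' written into the analysis-facing tables.
#'
#' @param config A `ts_generator_config`.
#' @return A list of class `ts_dataset` with elements `pictures`, `events`,
#'   `interactions` (a `ts_interaction_log`: `$records` plus `$effort`),
#'   and `truth`.
#' @export
generate_dataset <- function(config) {
  validate_generator_config(config)
  cfg <- config
  set.seed(cfg$seed)

  subjects <- sprintf("M%02d", seq_len(cfg$n_subjects))
  groups <- sort(unique(unname(cfg$cluster_map)))

  ## ground truth -----------------------------------------------------------
  true_order <- sample(subjects)                  # rank 1 = top
  rank_of <- stats::setNames(seq_along(true_order), true_order)
  alpha_id <- true_order[1]
  with_mother <- sort(sample(subjects, cfg$n_with_mother))
  subject_int <- stats::setNames(stats::rnorm(cfg$n_subjects, 0, cfg$subject_sd),
                                 subjects)
  # group-specific subject response signatures (baseline group gets none):
  # near-orthogonal sign patterns scaled by cluster_profile_sd, so each
  # functional group engages the subjects in a distinct, planted way
  prof_groups <- setdiff(groups, "baseline")
  sign_patterns <- rbind(
    rep(c(-1, 1, -1, 1, 1, -1, -1, 1, -1), length.out = cfg$n_subjects),
    rep(c(1, 1, 1, -1, 1, 1, -1, -1, -1), length.out = cfg$n_subjects),
    rep(c(1, -1, 1, 1, -1, -1, 1, -1, -1), length.out = cfg$n_subjects))
  profiles <- matrix(0, nrow = length(prof_groups), ncol = cfg$n_subjects,
                     dimnames = list(prof_groups, subjects))
  for (i in seq_along(prof_groups))
    profiles[i, ] <- cfg$cluster_profile_sd *
      sign_patterns[((i - 1) %% 3) + 1, ]
  # planted bonds form a symmetric graph with degree <= 3 so that top-3 CRI
  # selection can recover them; rivalries likewise, on the complement
  sample_graph <- function(max_degree, forbidden = NULL) {
    deg <- stats::setNames(integer(length(subjects)), subjects)
    edges <- character(0)
    key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
    for (pass in seq_len(max_degree)) {
      for (s in sample(subjects)) {
        if (deg[s] >= max_degree) next
        pool <- setdiff(subjects[deg < max_degree], s)
        pool <- pool[!vapply(pool, function(o)
          key(s, o) %in% c(edges, forbidden), logical(1))]
        if (length(pool)) {
          o <- if (length(pool) == 1) pool else sample(pool, 1)
          edges <- c(edges, key(s, o))
          deg[s] <- deg[s] + 1L
          deg[o] <- deg[o] + 1L
        }
      }
    }
    edges
  }
  bond_edges <- sample_graph(3)
  rival_edges <- sample_graph(3, forbidden = bond_edges)
  neighbours <- function(edges) {
    lapply(stats::setNames(subjects, subjects), function(s) {
      hit <- vapply(strsplit(edges, "|", fixed = TRUE),
                    function(e) s %in% e, logical(1))
      sort(setdiff(unlist(strsplit(edges[hit], "|", fixed = TRUE)), s))
    })
  }
  bond_sets <- neighbours(bond_edges)
  rival_sets <- neighbours(rival_edges)

  ## events -----------------------------------------------------------------
  type_counts <- ifelse(cfg$event_types == "baseline",
                        cfg$n_baseline_events, cfg$n_events_per_type)
  ev_type <- rep(cfg$event_types, type_counts)
  n_ev <- length(ev_type)
  ev <- data.frame(
    event_id = sprintf("E%04d", seq_len(n_ev)),
    subject_id = sample(subjects, n_ev, replace = TRUE),
    event_type = ev_type,
    movement = sample(names(cfg$movement_effects), n_ev, replace = TRUE,
                      prob = c(0.40, 0.35, 0.25)),
    ambient_c = stats::runif(n_ev, 20, 30),
    humidity_pct = stats::runif(n_ev, 40, 90),
    distance_m = stats::runif(n_ev, 7, 15),
    stringsAsFactors = FALSE)
  grp <- unname(cfg$cluster_map[ev$event_type])

  ## audience composition (10 m subset of 35 m party) -----------------------
  ev$n_males_35 <- rpois_trunc(n_ev, 2, cfg$n_subjects - 1)
  ev$n_males_10 <- stats::rbinom(n_ev, ev$n_males_35, 0.4)
  ev$n_females_35 <- rpois_trunc(n_ev, 4, 30)
  ev$n_females_10 <- stats::rbinom(n_ev, ev$n_females_35, 0.4)
  is_alpha_focal <- ev$subject_id == alpha_id
  ev$alpha_35 <- as.integer(!is_alpha_focal & stats::runif(n_ev) < 0.5)
  ev$alpha_10 <- as.integer(ev$alpha_35 == 1L & stats::runif(n_ev) < 0.5)
  has_mother <- ev$subject_id %in% with_mother
  ev$mother_35 <- as.integer(has_mother & stats::runif(n_ev) < 0.2)
  ev$mother_10 <- as.integer(ev$mother_35 == 1L & stats::runif(n_ev) < 0.5)

  ## grooming partner and role ----------------------------------------------
  ev$partner_id <- ""
  ev$groom_role <- ""
  gr <- which(ev$event_type == "grooming")
  if (length(gr)) {
    ev$partner_id[gr] <- vapply(ev$subject_id[gr], function(s)
      sample(setdiff(subjects, s), 1), character(1))
    ev$groom_role[gr] <- sample(c("given", "received", "mutual"),
                                length(gr), replace = TRUE)
    pa <- gr[ev$partner_id[gr] == alpha_id]
    ev$alpha_35[pa] <- 1L
    ev$alpha_10[pa] <- 1L
  }

  ## internal consistency: flagged individuals are counted in the party
  ev$n_males_35 <- pmax(ev$n_males_35, ev$alpha_35,
                        as.integer(ev$partner_id != ""))
  ev$n_males_10 <- pmax(ev$n_males_10, ev$alpha_10)
  ev$n_females_35 <- pmax(ev$n_females_35, ev$mother_35)
  ev$n_females_10 <- pmax(ev$n_females_10, ev$mother_10)
  # study design only keeps events with at least one other party member
  lone <- ev$n_males_35 + ev$n_females_35 == 0
  ev$n_females_35[lone] <- 1L

  ## true event temperature --------------------------------------------------
  eff <- cfg$audience_effects
  temp <- unname(cfg$cluster_means[grp]) +
    subject_int[ev$subject_id] +
    unname(cfg$movement_effects[ev$movement]) +
    cfg$ambient_slope * (ev$ambient_c - 25) +
    cfg$humidity_slope * (ev$humidity_pct - 65) +
    cfg$distance_slope * (ev$distance_m - 11)
  has_prof <- grp %in% rownames(profiles)
  temp[has_prof] <- temp[has_prof] +
    profiles[cbind(grp[has_prof], ev$subject_id[has_prof])]
  temp <- temp +
    eff[["alpha_presence_cooperative"]] * (grp == "A") * ev$alpha_35 +
    eff[["female_count_competitive"]] * (grp == "B") * ev$n_females_10 +
    eff[["male_count_copulation"]] * (ev$event_type == "copulation") * ev$n_males_10 +
    eff[["mother_presence_copulation"]] * (ev$event_type == "copulation") * ev$mother_35
  temp <- temp + stats::rnorm(n_ev, 0, unname(cfg$cluster_sds[grp]))
  names(temp) <- NULL

  ## pictures ---------------------------------------------------------------
  n_pics <- sample(seq(cfg$pictures_per_event[1], cfg$pictures_per_event[2]),
                   n_ev, replace = TRUE)
  no_facing <- stats::runif(n_ev) < cfg$missing_facing_prob
  angles <- ts_angle_levels()
  pic_list <- vector("list", n_ev)
  for (i in seq_len(n_ev)) {
    k <- n_pics[i]
    if (no_facing[i]) {
      ang <- sample(angles[-1], k, replace = TRUE)
    } else {
      ang <- c("facing", sample(angles, k - 1, replace = TRUE))
    }
    pic_list[[i]] <- data.frame(
      event_id = ev$event_id[i],
      subject_id = ev$subject_id[i],
      angle = ang,
      temp_c = temp[i] + unname(cfg$angle_bias[ang]) +
        stats::rnorm(k, 0, cfg$picture_sd),
      sec_after_event = round(stats::runif(k, 15, 300), 1),
      stringsAsFactors = FALSE)
  }
  pictures <- do.call(rbind, pic_list)
  rownames(pictures) <- NULL

  ## long-term interaction logs ---------------------------------------------
  dyads <- utils::combn(subjects, 2)
  n_dy <- ncol(dyads)
  rec_list <- list()
  for (m in seq_len(cfg$months_longterm)) {
    for (d in seq_len(n_dy)) {
      a <- dyads[1, d]; b <- dyads[2, d]
      bonded <- a %in% bond_sets[[b]] || b %in% bond_sets[[a]]
      rival <- a %in% rival_sets[[b]] || b %in% rival_sets[[a]]
      aff_mult <- if (bonded) cfg$bond_multiplier else if (rival) 0.1 else 1
      agg_mult <- if (rival) cfg$rival_aggression_multiplier else 1
      g <- stats::rpois(1, cfg$groom_rate * aff_mult)
      p <- stats::rpois(1, cfg$prox_rate * aff_mult)
      n_ag <- stats::rpois(1, cfg$agonistic_rate * agg_mult)
      n_pg <- stats::rpois(1, cfg$pantgrunt_rate)
      rows <- list()
      if (g > 0) rows <- c(rows, list(data.frame(month = m, actor = a,
        receiver = b, kind = "groom", count = g)))
      if (p > 0) rows <- c(rows, list(data.frame(month = m, actor = a,
        receiver = b, kind = "prox5m", count = p)))
      if (n_ag > 0) {
        # higher rank (smaller number) wins; aggressor is the winner
        p_a_wins <- stats::plogis(cfg$hierarchy_steepness *
                                    (rank_of[b] - rank_of[a]))
        wins_a <- stats::rbinom(1, n_ag, p_a_wins)
        kinds <- sample(c("aggression", "chase", "threat"), n_ag,
                        replace = TRUE)
        kinds[stats::runif(n_ag) < cfg$severe_prob] <- "severe"
        winner <- rep(c(a, b), c(wins_a, n_ag - wins_a))
        loser <- rep(c(b, a), c(wins_a, n_ag - wins_a))
        tab <- stats::aggregate(
          list(count = rep(1L, n_ag)),
          by = list(actor = winner, receiver = loser, kind = kinds), sum)
        tab$month <- m
        rows <- c(rows, list(tab[, c("month", "actor", "receiver",
                                     "kind", "count")]))
      }
      if (n_pg > 0) {
        # pant-grunt: the actor submits to the receiver (receiver "wins")
        p_b_sub <- stats::plogis(cfg$hierarchy_steepness *
                                   (rank_of[b] - rank_of[a]))
        sub_b <- stats::rbinom(1, n_pg, p_b_sub)
        if (sub_b > 0) rows <- c(rows, list(data.frame(month = m, actor = b,
          receiver = a, kind = "pantgrunt", count = sub_b)))
        if (n_pg - sub_b > 0) rows <- c(rows, list(data.frame(month = m,
          actor = a, receiver = b, kind = "pantgrunt",
          count = n_pg - sub_b)))
      }
      rec_list <- c(rec_list, rows)
    }
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL
  effort <- data.frame(
    subject_id = subjects,
    total_occurrences = as.integer(cfg$effort_per_month * cfg$months_longterm),
    stringsAsFactors = FALSE)
  interactions <- structure(list(records = records, effort = effort),
                            class = "ts_interaction_log")

  truth <- list(subject_intercepts = as.list(subject_int),
                elo_order = true_order,
                bond_partners = bond_sets,
                rival_partners = rival_sets,
                alpha = alpha_id,
                subjects_with_mother = with_mother,
                audience_effects = as.list(eff),
                cluster_map = as.list(cfg$cluster_map),
                event_temperature = stats::setNames(as.list(temp),
                                                    ev$event_id))

  structure(list(pictures = pictures, events = ev,
                 interactions = interactions, truth = truth,
                 config = cfg),
            class = "ts_dataset")
}

#' Write a synthetic dataset to CSV fixture files
#'
#' Writes `pictures.csv`, `events.csv`, `interactions.csv` and `truth.json`
#' into a directory. Focal observation effort is stored inside
#' `interactions.csv` as rows with `kind = "effort"` and an empty receiver;
#' [read_dataset()] splits these back out, so the round trip is lossless.
#'
#' @param dataset A `ts_dataset` from [generate_dataset()].
#' @param directory Output directory (created if missing).
#' @return Invisibly, a named character vector of the four file paths.
#' @export
write_fixture <- function(dataset, directory) {
  ts_assert(inherits(dataset, "ts_dataset"),
            "dataset must come from generate_dataset()")
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  paths <- c(pictures = file.path(directory, "pictures.csv"),
             events = file.path(directory, "events.csv"),
             interactions = file.path(directory, "interactions.csv"),
             truth = file.path(directory, "truth.json"))
  utils::write.csv(dataset$pictures, paths["pictures"], row.names = FALSE)
  utils::write.csv(dataset$events, paths["events"], row.names = FALSE)
  eff <- dataset$interactions$effort
  eff_rows <- data.frame(month = 0L, actor = eff$subject_id, receiver = "",
                         kind = "effort", count = eff$total_occurrences,
                         stringsAsFactors = FALSE)
  utils::write.csv(rbind(dataset$interactions$records, eff_rows),
                   paths["interactions"], row.names = FALSE)
  jsonlite::write_json(dataset$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a dataset written by [write_fixture()]
#'
#' @param directory Directory containing `pictures.csv`, `events.csv` and
#'   `interactions.csv` (and optionally `truth.json`).
#' @param col_map Optional named list renaming non-standard input columns to
#'   the canonical schema, e.g. `list(events = c(temp = "temp_c"))` with
#'   entries `pictures`, `events`, `interactions`; names are the column names
#'   found in the file, values the canonical names.
#' @return A `ts_dataset` (with `truth = NULL` when no `truth.json` exists).
#' @export
read_dataset <- function(directory, col_map = NULL) {
  rd <- function(f, map) {
    x <- utils::read.csv(file.path(directory, f), stringsAsFactors = FALSE,
                         colClasses = NA)
    if (!is.null(map)) {
      hit <- names(map)[names(map) %in% names(x)]
      names(x)[match(hit, names(x))] <- unname(map[hit])
    }
    x
  }
  pictures <- rd("pictures.csv", col_map$pictures)
  events <- rd("events.csv", col_map$events)
  for (col in c("partner_id", "groom_role"))
    if (col %in% names(events)) events[[col]][is.na(events[[col]])] <- ""
  inter <- rd("interactions.csv", col_map$interactions)
  inter$receiver[is.na(inter$receiver)] <- ""
  is_eff <- inter$kind == "effort"
  effort <- data.frame(subject_id = inter$actor[is_eff],
                       total_occurrences = inter$count[is_eff],
                       stringsAsFactors = FALSE)
  records <- inter[!is_eff, , drop = FALSE]
  rownames(records) <- NULL
  truth_path <- file.path(directory, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = FALSE) else NULL
  structure(list(pictures = pictures, events = events,
                 interactions = structure(list(records = records,
                                               effort = effort),
                                          class = "ts_interaction_log"),
                 truth = truth, config = NULL),
            class = "ts_dataset")
}
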