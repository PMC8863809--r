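# End-to-end orchestration: read or simulate inputs, validate, correct
# temperatures, compute social indices, calibrate confounds, cluster event
# types, and run the cluster / cooperation / grooming / competition /
# copulation models.

default_candidates <- function() {
  base <- c("alpha_35", "alpha_10", "mother_35", "mother_10",
            "n_males_35", "n_males_10", "n_females_35", "n_females_10",
            "z_elo")
  list(cooperation = base,
       competition = base,
       grooming = c("alpha_35", "alpha_10", "mother_35", "n_males_10",
                    "n_females_10", "z_elo", "groom_role", "partner_alpha",
                    "groom_role:partner_alpha"),
       copulation = c("n_males_10", "n_males_35", "mother_35", "mother_10",
                      "alpha_35", "alpha_10", "n_females_10", "z_elo"))
}

#' Pipeline configuration
#'
#' Either `input_dir` (a directory of `pictures.csv`, `events.csv`,
#' `interactions.csv` as written by [write_fixture()], possibly with a
#' column mapping for foreign layouts) or `generator` (a
#' [generator_config()], in which case the data are simulated) must be
#' given.
#'
#' @param input_dir Directory with the three input CSVs, or `NULL`.
#' @param generator A `ts_generator_config`, or `NULL`.
#' @param col_map Optional column mapping passed to [read_dataset()].
#' @param rank,tol,max_iter Angle-correction settings, see
#'   [impute_regularized_pca()].
#' @param elo_k,elo_start Elo-rating settings, see [compute_elo()].
#' @param k_range Candidate cluster numbers, see [choose_k_silhouette()].
#' @param candidates Named list of candidate fixed terms per audience
#'   analysis (`cooperation`, `competition`, `grooming`, `copulation`);
#'   defaults cover every audience variable observable in the event schema.
#' @param min_events Minimum number of events for an audience analysis to
#'   run (default 10); analyses on smaller subsets are skipped.
#' @param out_dir Output directory for the JSON report and summary, or
#'   `NULL` for no files.
#' @param seed Seed recorded in the report (and used for simulation when
#'   `generator` lacks one).
#' @return Object of class `ts_pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, generator = NULL,
                            col_map = NULL, rank = 2, tol = 1e-6,
                            max_iter = 1000, elo_k = 100, elo_start = 1000,
                            k_range = 2:6,
                            candidates = default_candidates(),
                            min_events = 10,
                            out_dir = NULL, seed = 1L) {
  ts_assert(!is.null(input_dir) || !is.null(generator),
            "either input_dir or generator must be given")
  structure(list(input_dir = input_dir, generator = generator,
                 col_map = col_map, rank = rank, tol = tol,
                 max_iter = max_iter, elo_k = elo_k, elo_start = elo_start,
                 k_range = k_range, candidates = candidates,
                 min_events = min_events, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "ts_pipeline_config")
}

#' Validate pipeline input tables
#'
#' Checks column schemas, value ranges and referential integrity of the
#' three input tables, distinguishing errors (malformed inputs the pipeline
#' refuses) from warnings (suspicious but usable values).
#'
#' @param dataset A `ts_dataset` (from [read_dataset()] or
#'   [generate_dataset()]).
#' @param temp_bounds Plausible temperature range used for range warnings.
#' @return List of class `ts_validation`: `ok`, `errors`, `warnings`.
#' @export
validate_inputs <- function(dataset, temp_bounds = c(20, 42)) {
  errors <- character(0)
  warnings <- character(0)
  p <- dataset$pictures; e <- dataset$events
  need_p <- c("event_id", "subject_id", "angle", "temp_c", "sec_after_event")
  need_e <- c("event_id", "subject_id", "event_type", "movement",
              "ambient_c", "humidity_pct", "distance_m",
              "alpha_35", "alpha_10", "mother_35", "mother_10",
              "n_males_10", "n_males_35", "n_females_10", "n_females_35")
  miss_p <- setdiff(need_p, names(p))
  miss_e <- setdiff(need_e, names(e))
  if (length(miss_p))
    errors <- c(errors, paste("pictures.csv lacks columns:",
                              paste(miss_p, collapse = ", ")))
  if (length(miss_e))
    errors <- c(errors, paste("events.csv lacks columns:",
                              paste(miss_e, collapse = ", ")))
  if (!length(errors)) {
    out_of_range <- which(p$temp_c < temp_bounds[1] |
                            p$temp_c > temp_bounds[2])
    if (length(out_of_range))
      errors <- c(errors, paste0("pictures.csv rows ",
                                 paste(utils::head(out_of_range, 5),
                                       collapse = ", "),
                                 " have temp_c outside [",
                                 temp_bounds[1], ", ", temp_bounds[2], "]"))
    bad_angle <- setdiff(unique(p$angle), ts_angle_levels())
    if (length(bad_angle))
      errors <- c(errors, paste("unknown angle categories:",
                                paste(bad_angle, collapse = ", ")))
    orphan <- setdiff(unique(p$event_id), e$event_id)
    if (length(orphan))
      errors <- c(errors, paste0("pictures reference unknown event ids: ",
                                 paste(utils::head(orphan, 5),
                                       collapse = ", ")))
    if (anyDuplicated(e$event_id))
      errors <- c(errors, "duplicated event ids in events.csv")
    if (any(e$n_males_10 > e$n_males_35) ||
        any(e$n_females_10 > e$n_females_35))
      errors <- c(errors, "10 m audience counts exceed 35 m counts")
    if (any(e$alpha_10 > e$alpha_35) || any(e$mother_10 > e$mother_35))
      errors <- c(errors, "presence within 10 m without presence within 35 m")
    win <- p$sec_after_event < 15 | p$sec_after_event > 300
    if (any(win))
      warnings <- c(warnings, paste0(sum(win), " picture(s) outside the ",
                                     "15-300 s window will be dropped"))
    rec <- dataset$interactions$records
    if (any(rec$count < 0))
      errors <- c(errors, "negative interaction counts")
    if (any(rec$actor == rec$receiver))
      errors <- c(errors, "interaction records with actor == receiver")
  }
  structure(list(ok = length(errors) == 0, errors = errors,
                 warnings = warnings),
            class = "ts_validation")
}

label_clusters <- function(assignment, group_temp) {
  # deterministic naming of the data-driven clusters: the coolest cluster is
  # the competitive group B; among the rest, the cluster containing grooming
  # (else the largest) is the cooperative group A; remaining clusters get C,
  # D, ... by increasing size
  ids <- sort(unique(assignment))
  mean_t <- vapply(ids, function(i)
    mean(group_temp[names(assignment)[assignment == i]]), numeric(1))
  lab <- stats::setNames(rep(NA_character_, length(ids)), ids)
  b_id <- ids[which.min(mean_t)]
  lab[as.character(b_id)] <- "B"
  rest <- setdiff(ids, b_id)
  if (length(rest)) {
    sizes <- vapply(rest, function(i) sum(assignment == i), numeric(1))
    has_groom <- vapply(rest, function(i)
      "grooming" %in% names(assignment)[assignment == i], logical(1))
    a_id <- if (any(has_groom)) rest[has_groom][1] else
      rest[which.max(sizes)]
    lab[as.character(a_id)] <- "A"
    others <- setdiff(rest, a_id)
    if (length(others)) {
      others <- others[order(-vapply(others, function(i)
        sum(assignment == i), numeric(1)))]
      lab[as.character(others)] <- LETTERS[seq_along(others) + 2]
    }
  }
  stats::setNames(lab[as.character(assignment)], names(assignment))
}

run_audience_model <- function(dat, candidate_terms, min_events,
                               contrast_factors = character(0)) {
  if (nrow(dat) < min_events)
    return(list(status = "skipped",
                reason = sprintf("only %d events (< %d)", nrow(dat),
                                 min_events)))
  # drop candidates that are constant in this subset
  cand <- Filter(function(term) {
    vars <- strsplit(term, ":", fixed = TRUE)[[1]]
    all(vapply(vars, function(v) length(unique(dat[[v]])) > 1, logical(1)))
  }, candidate_terms)
  base <- lmm_spec()
  sel <- dredge_select(dat, base, cand)
  null_fit <- fit_lmm(dat, lmm_spec(), method = "ML")
  test <- lrt(sel$best_fit, null_fit)
  best_terms <- sel$best_spec$fixed
  reml_fit <- fit_lmm(dat, sel$best_spec, method = "REML")
  anova_tab <- if (length(best_terms)) term_chisq(reml_fit) else NULL
  contrasts <- list()
  for (f in contrast_factors) {
    vars <- strsplit(f, ":", fixed = TRUE)[[1]]
    if (all(vars %in% unlist(strsplit(best_terms, ":", fixed = TRUE))))
      contrasts[[f]] <- pairwise_contrasts(reml_fit, f)
  }
  list(status = "ok", n = nrow(dat),
       best_terms = best_terms,
       model_table = utils::head(sel$table, 10),
       n_models = sel$n_models,
       lrt = test, anova = anova_tab,
       contrasts = contrasts,
       coefficients = as.data.frame(summary(reml_fit$model)$coefficients),
       singular = reml_fit$singular)
}

#' Run the full thermography analysis pipeline
#'
#' Executes all stages in order: load (or simulate) inputs, validate,
#' angle-correct and aggregate picture temperatures, compute CRI bonds and
#' Elo ratings, calibrate confounds on the resting baseline, cluster the
#' event types, fit the cluster model (thermal group vs. log nose
#' temperature), and run the four audience-effect analyses (cooperation on
#' the cooperative cluster, grooming, competition on the competitive
#' cluster, copulation). Re-running with an identical configuration and
#' seed reproduces the report exactly.
#'
#' @param config A [pipeline_config()].
#' @return List of class `ts_report` with one element per stage plus
#'   provenance; written as `report.json` (and `report.md`) when
#'   `config$out_dir` is set.
#' @export
run_pipeline <- function(config) {
  ts_assert(inherits(config, "ts_pipeline_config"),
            "config must come from pipeline_config()")
  report <- list(provenance = list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("thermosocial")),
    timestamp = NA))

  ## stage: inputs ----------------------------------------------------------
  if (!is.null(config$generator)) {
    gen <- config$generator
    dataset <- generate_dataset(gen)
    report$input <- list(source = "synthetic", seed = gen$seed)
  } else {
    dataset <- read_dataset(config$input_dir, col_map = config$col_map)
    report$input <- list(source = config$input_dir)
  }
  val <- validate_inputs(dataset)
  report$validation <- unclass(val)
  if (!val$ok) {
    report$status <- "failed"
    report$failed_stage <- "validation"
    class(report) <- "ts_report"
    return(report)
  }

  ## stage: thermal correction ---------------------------------------------
  corrected <- correct_thermal(dataset$pictures, rank = config$rank,
                               tol = config$tol,
                               max_iter = config$max_iter)
  imp <- attr(corrected, "imputation")
  report$imputation <- list(
    n_events = nrow(corrected),
    n_imputed = attr(corrected, "n_imputed"),
    fraction_imputed = attr(corrected, "fraction_imputed"),
    converged = imp$converged, n_iter = imp$n_iter)

  ev <- merge(dataset$events, corrected, by = "event_id")
  # study design: at least one other party member within 35 m
  ev <- ev[ev$n_males_35 + ev$n_females_35 >= 1, , drop = FALSE]

  ## stage: social metrics --------------------------------------------------
  elo <- compute_elo(dataset$interactions, k_factor = config$elo_k,
                     start_rating = config$elo_start)
  cri <- cri_matrix(dataset$interactions)
  bonds <- lapply(stats::setNames(nm = elo$ratings$subject_id), function(f)
    select_bond_partners(cri[cri$focal == f, c("partner", "cri")],
                         dataset$interactions, f))
  stability <- tryCatch(elo_stability(dataset$interactions,
                                      config$elo_k, config$elo_start),
                        error = function(e) NULL)
  report$social <- list(
    elo = elo$ratings,
    bonds = bonds,
    hierarchy_stability = if (!is.null(stability))
      stability$rank_correlation else NA)
  alpha_id <- elo$ratings$subject_id[which.max(elo$ratings$final_elo)]
  ev$z_elo <- elo$ratings$z_elo[match(ev$subject_id,
                                      elo$ratings$subject_id)]
  ev$partner_alpha <- as.integer(!is.na(ev$partner_id) &
                                   ev$partner_id == alpha_id)

  ## stage: confound calibration -------------------------------------------
  baseline <- ev[ev$event_type == "baseline", , drop = FALSE]
  conf <- calibrate_confounds(baseline)
  ev$ambient_centered <- ev$ambient_c - conf$ambient_mean
  report$confounds <- list(table = conf$table, flagged = conf$flagged,
                           ambient_mean = conf$ambient_mean,
                           adjustment = conf$adjustment)

  ## stage: clustering ------------------------------------------------------
  profiles <- build_profiles(ev, adjustment = conf$adjustment)
  cl <- ward_cluster(profiles)
  kc <- choose_k_silhouette(cl, k_range = config$k_range)
  type_temp <- tapply(ev$corrected_temp_c, ev$event_type, mean)
  groups <- label_clusters(kc$assignment,
                           type_temp[names(kc$assignment)])
  report$clustering <- list(
    k = kc$k, assignment = as.list(groups),
    mean_silhouette_widths = as.list(kc$mean_widths),
    silhouette = as.list(kc$silhouette),
    cophenetic = as.list(cl$cophenetic),
    merge_heights = cl$hclust$height)

  ev$cluster_group <- ifelse(ev$event_type == "baseline", "baseline",
                             groups[ev$event_type])
  ev$cluster_group <- stats::relevel(factor(ev$cluster_group),
                                     ref = "baseline")

  ## stage: cluster model ---------------------------------------------------
  cl_fit <- fit_lmm(ev, lmm_spec(fixed = "cluster_group"), method = "REML")
  descr <- do.call(rbind, lapply(split(ev$corrected_temp_c,
                                       ev$cluster_group), function(x)
    data.frame(n = length(x), mean = mean(x), sd = stats::sd(x))))
  descr <- cbind(group = rownames(descr), descr)
  rownames(descr) <- NULL
  report$cluster_model <- list(
    n = cl_fit$n,
    anova = term_chisq(cl_fit),
    contrasts = pairwise_contrasts(cl_fit, "cluster_group"),
    descriptives = descr,
    singular = cl_fit$singular)

  ## stage: audience models -------------------------------------------------
  soc <- ev[ev$event_type != "baseline", , drop = FALSE]
  subsets <- list(
    cooperation = soc[soc$cluster_group == "A", , drop = FALSE],
    grooming = soc[soc$event_type == "grooming", , drop = FALSE],
    competition = soc[soc$cluster_group == "B", , drop = FALSE],
    copulation = soc[soc$event_type == "copulation", , drop = FALSE])
  contrast_for <- list(cooperation = character(0),
                       grooming = c("groom_role",
                                    "groom_role:partner_alpha"),
                       competition = character(0),
                       copulation = character(0))
  for (an in names(subsets)) {
    report[[paste0(an, "_model")]] <- tryCatch(
      run_audience_model(subsets[[an]], config$candidates[[an]],
                         config$min_events, contrast_for[[an]]),
      error = function(e) list(status = "error",
                               reason = conditionMessage(e)))
  }

  report$status <- "complete"
  class(report) <- "ts_report"
  if (!is.null(config$out_dir))
    write_report(report, config$out_dir)
  report
}

#' Serialize a pipeline report
#'
#' Writes `report.json` (machine-readable, diffable) and `report.md` (short
#' human summary) into a directory.
#'
#' @param report A `ts_report`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(unclass_deep(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  md <- c("# Thermal-imaging pipeline report", "",
          paste0("Status: ", report$status))
  if (!is.null(report$clustering))
    md <- c(md, paste0("Chosen number of clusters: ", report$clustering$k))
  for (an in c("cooperation", "grooming", "competition", "copulation")) {
    m <- report[[paste0(an, "_model")]]
    if (is.null(m)) next
    if (identical(m$status, "ok")) {
      md <- c(md, "",
              paste0("## ", an, " model (n = ", m$n, ")"),
              paste0("Best terms: ",
                     if (length(m$best_terms))
                       paste(m$best_terms, collapse = " + ")
                     else "(null)"),
              sprintf("LRT vs null: chisq(%d) = %.3f, p = %.4g",
                      m$lrt$df, m$lrt$chisq, m$lrt$p))
    } else {
      md <- c(md, "", paste0("## ", an, " model: ", m$status,
                             " (", m$reason, ")"))
    }
  }
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(json_path)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) {
    attr(x, "emmeans") <- NULL
    class(x) <- "data.frame"
    x
  } else if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    class(x) <- NULL
    x
  } else {
    x
  }
}
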