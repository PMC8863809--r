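# Gaussian linear mixed models with crossed random intercepts and the
# model-comparison machinery around them: small-sample-corrected AIC,
# all-subsets selection under marginality, likelihood-ratio tests, per-term
# Wald chi-square tests and post-hoc pairwise contrasts.

#' Specify a linear mixed model
#'
#' A model specification used throughout the audience-effect analyses:
#' Gaussian response, a set of fixed terms, random intercepts for one or
#' more grouping factors (by default subject identity and prior movement),
#' and a control covariate (centered ambient temperature) that is part of
#' every model including null models.
#'
#' @param fixed Character vector of fixed-effect terms (may include
#'   interactions as `"a:b"`); may be empty (null model).
#' @param random Character vector of random-intercept factors.
#' @param control Control covariate name kept in every model; `NULL` for
#'   none.
#' @param response Response column name.
#' @return Object of class `ts_lmm_spec`.
#' @export
lmm_spec <- function(fixed = character(),
                     random = c("subject_id", "movement"),
                     control = "ambient_centered",
                     response = "log_temp") {
  structure(list(response = response, fixed = unique(fixed),
                 random = random, control = control),
            class = "ts_lmm_spec")
}

spec_formula <- function(spec) {
  rhs <- c(spec$control, spec$fixed,
           sprintf("(1 | %s)", spec$random))
  if (!length(rhs)) rhs <- "1"
  stats::as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
}

fixed_formula <- function(spec) {
  rhs <- c(spec$control, spec$fixed)
  if (!length(rhs)) rhs <- "1"
  stats::as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
}

#' Fit a Gaussian linear mixed model
#'
#' Random-intercepts model with crossed grouping factors, fitted by maximum
#' likelihood (`"ML"`, used for information-criterion ranking and
#' likelihood-ratio tests) or restricted maximum likelihood (`"REML"`, used
#' for reported coefficients of a final model). A variance component
#' estimated at zero is a legitimate boundary fit and is reported via the
#' `singular` flag, not an error. A rank-deficient fixed-effect design is an
#' error naming the aliased columns.
#'
#' @param data Data frame containing every column of the spec.
#' @param spec A [lmm_spec()].
#' @param method `"ML"` or `"REML"`.
#' @return Object of class `ts_lmm`: the `lme4` fit plus bookkeeping
#'   (log-likelihood, parameter count `k` = fixed coefficients + variance
#'   components + residual variance, `n`, AICc, `converged`, `singular`).
#' @export
fit_lmm <- function(data, spec, method = c("ML", "REML")) {
  method <- match.arg(method)
  ts_assert(inherits(spec, "ts_lmm_spec"), "spec must come from lmm_spec()")
  need <- c(spec$response, spec$control, spec$random,
            unique(unlist(strsplit(spec$fixed, ":", fixed = TRUE))))
  miss <- setdiff(need, names(data))
  ts_assert(!length(miss), "data lacks column(s): ",
            paste(miss, collapse = ", "))
  for (r in spec$random) {
    data[[r]] <- factor(data[[r]])
    ts_assert(nlevels(data[[r]]) >= 2,
              "random factor '", r, "' needs at least 2 levels")
  }
  mm <- stats::model.matrix(fixed_formula(spec), data)
  qrx <- qr(mm)
  if (qrx$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrx$pivot[(qrx$rank + 1):ncol(mm)]]
    stop("rank-deficient fixed-effect design; aliased: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit <- suppressMessages(lme4::lmer(
    spec_formula(spec), data = data, REML = (method == "REML"),
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore")))
  conv <- length(fit@optinfo$conv$lme4) == 0
  k_fixed <- length(lme4::fixef(fit))
  k_var <- nrow(as.data.frame(lme4::VarCorr(fit)))  # includes residual
  k <- k_fixed + k_var
  ll <- as.numeric(stats::logLik(fit))
  n <- stats::nobs(fit)
  out <- structure(list(model = fit, spec = spec, method = method,
                        logLik = ll, n = n, k = k, k_fixed = k_fixed,
                        k_var = k_var, converged = conv,
                        singular = lme4::isSingular(fit, tol = 1e-5),
                        data = data),
                   class = "ts_lmm")
  out$aicc <- aicc(out)
  out
}

#' @export
print.ts_lmm <- function(x, ...) {
  cat("Linear mixed model (", x$method, "), n = ", x$n,
      ", k = ", x$k, "\n", sep = "")
  cat("  fixed: ", paste(c(x$spec$control, x$spec$fixed), collapse = " + "),
      if (!length(x$spec$fixed)) "(null model)", "\n", sep = "")
  cat("  random intercepts: ", paste(x$spec$random, collapse = ", "),
      "\n", sep = "")
  cat("  logLik = ", format(x$logLik), ", AICc = ", format(x$aicc),
      if (x$singular) ", singular fit", "\n", sep = "")
  invisible(x)
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`, with `k` counting
#' fixed-effect coefficients plus variance components plus the residual
#' variance. Returns `+Inf` with a warning when `n <= k + 1`.
#'
#' @param object A `ts_lmm` fit, or a numeric log-likelihood (then supply
#'   `k` and `n`).
#' @param k,n Parameter count and number of observations (ignored for
#'   `ts_lmm` input).
#' @return The AICc value.
#' @export
aicc <- function(object, k = NULL, n = NULL) {
  if (inherits(object, "ts_lmm")) {
    ll <- object$logLik; k <- object$k; n <- object$n
  } else {
    ll <- as.numeric(object)
    ts_assert(!is.null(k) && !is.null(n),
              "supply k and n with a numeric log-likelihood")
  }
  if (n <= k + 1) {
    warning("AICc undefined for n <= k + 1; returning +Inf", call. = FALSE)
    return(Inf)
  }
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

interaction_parents <- function(term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  if (length(parts) > 1) parts else character(0)
}

#' Enumerate marginality-respecting term subsets
#' @keywords internal
#' @noRd
enumerate_subsets <- function(candidate_terms, max_subsets) {
  nc <- length(candidate_terms)
  ts_assert(2^nc <= max_subsets,
            "search space of ", 2^nc, " models exceeds max_subsets = ",
            max_subsets, "; prune candidate terms")
  subsets <- list(character(0))
  if (nc > 0) {
    for (m in 1:(2^nc - 1)) {
      sel <- candidate_terms[bitwAnd(m, 2^(seq_len(nc) - 1)) > 0]
      ok <- all(vapply(sel, function(t)
        all(interaction_parents(t) %in% sel), logical(1)))
      if (ok) subsets <- c(subsets, list(sel))
    }
  }
  subsets
}

#' All-subsets model selection by AICc
#'
#' Enumerates every subset of the candidate fixed terms that respects
#' marginality (an interaction is only considered together with its main
#' effects), fits each by maximum likelihood with the base random and
#' control structure unchanged, and ranks models by AICc. Near-ties
#' (difference below `1e-8`) are resolved toward the model with fewer terms.
#' The ranking is invariant under reordering of the candidate list.
#'
#' @param data Model data frame.
#' @param base_spec A [lmm_spec()] providing response, random factors and
#'   control covariate; its `fixed` terms are ignored.
#' @param candidate_terms Character vector of candidate fixed terms.
#' @param max_subsets Guard on the search-space size (default `2^16`).
#' @return List of class `ts_dredge`: `table` (one row per fitted model:
#'   terms, k, logLik, AICc, delta_aicc, ranked), `best_spec`, `best_fit`
#'   (the ML fit of the best model), `n_models`.
#' @export
dredge_select <- function(data, base_spec, candidate_terms,
                          max_subsets = 2^16) {
  subsets <- enumerate_subsets(sort(unique(candidate_terms)), max_subsets)
  fits <- lapply(subsets, function(terms) {
    spec <- lmm_spec(fixed = terms, random = base_spec$random,
                     control = base_spec$control,
                     response = base_spec$response)
    fit_lmm(data, spec, method = "ML")
  })
  tab <- data.frame(
    terms = vapply(subsets, function(s)
      if (length(s)) paste(sort(s), collapse = " + ") else "(null)",
      character(1)),
    n_terms = lengths(subsets),
    k = vapply(fits, function(f) f$k, numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    AICc = vapply(fits, function(f) f$aicc, numeric(1)),
    stringsAsFactors = FALSE)
  ord <- order(round(tab$AICc / 1e-8) * 1e-8, tab$n_terms, tab$terms)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  tab$delta_aicc <- tab$AICc - tab$AICc[1]
  rownames(tab) <- NULL
  structure(list(table = tab, best_spec = fits[[1]]$spec,
                 best_fit = fits[[1]], n_models = nrow(tab)),
            class = "ts_dredge")
}

#' Likelihood-ratio test between nested mixed models
#'
#' `chisq = 2 (logLik_full - logLik_null)` with degrees of freedom equal to
#' the difference in fixed-effect coefficient counts; both fits must be by
#' maximum likelihood on the same observations, and the null's fixed terms
#' must be a subset of the full's.
#'
#' @param full,null `ts_lmm` fits by ML.
#' @return List `chisq`, `df`, `p`.
#' @export
lrt <- function(full, null) {
  ts_assert(inherits(full, "ts_lmm") && inherits(null, "ts_lmm"),
            "both arguments must be ts_lmm fits")
  ts_assert(full$method == "ML" && null$method == "ML",
            "likelihood-ratio tests require ML fits")
  ts_assert(full$n == null$n,
            "fits are on different numbers of observations")
  ts_assert(all(null$spec$fixed %in% full$spec$fixed) &&
              identical(null$spec$random, full$spec$random) &&
              identical(null$spec$control, full$spec$control),
            "models are not nested")
  stat <- max(0, 2 * (full$logLik - null$logLik))
  df <- full$k_fixed - null$k_fixed
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(chisq = stat, df = df, p = p)
}

#' Per-term Wald chi-square tests
#'
#' Type-II Wald chi-square test for each fixed term of a fitted mixed model
#' (each term tested with the other terms, respecting marginality,
#' retained), as produced by `car::Anova`.
#'
#' @param fit A converged `ts_lmm`.
#' @return Data frame `term`, `chisq`, `df`, `p`.
#' @export
term_chisq <- function(fit) {
  ts_assert(inherits(fit, "ts_lmm"), "fit must be a ts_lmm")
  ts_assert(length(fit$spec$fixed) > 0 || !is.null(fit$spec$control),
            "model has no fixed terms to test")
  a <- car::Anova(fit$model, type = "II", test.statistic = "Chisq")
  out <- data.frame(term = rownames(a), chisq = a$Chisq, df = a$Df,
                    p = a[["Pr(>Chisq)"]], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Post-hoc pairwise contrasts of estimated marginal means
#'
#' Estimated marginal means per factor level (or per cell of an interaction
#' given as `"a:b"`) at the means of the covariates, with all pairwise
#' differences. Standard errors come from the fixed-effect covariance
#' matrix via `emmeans`; degrees of freedom follow the residual rule
#' `n - rank(fixed design)`, and p-values are adjusted with Tukey's
#' studentized-range method by default.
#'
#' @param fit A `ts_lmm` whose spec contains `factor`.
#' @param factor Factor name, or `"a:b"` for interaction cells.
#' @param adjust `"tukey"` or `"none"`.
#' @return Data frame of class `ts_contrasts`: `contrast`, `estimate`, `se`,
#'   `t`, `df`, `p_adj`; attribute `emmeans` holds the marginal means.
#' @export
pairwise_contrasts <- function(fit, factor, adjust = c("tukey", "none")) {
  adjust <- match.arg(adjust)
  ts_assert(inherits(fit, "ts_lmm"), "fit must be a ts_lmm")
  vars <- strsplit(factor, ":", fixed = TRUE)[[1]]
  ts_assert(all(vars %in% unlist(strsplit(fit$spec$fixed, ":", fixed = TRUE))),
            "'", factor, "' is not a fixed term of the model")
  dat <- fit$data
  for (v in vars) {
    dat[[v]] <- factor(dat[[v]])
    ts_assert(nlevels(dat[[v]]) >= 2, "factor '", v,
              "' has a single level")
  }
  spec_f <- stats::as.formula(paste("~", paste(vars, collapse = " * ")))
  emm <- emmeans::emmeans(fit$model, spec_f, data = dat,
                          lmer.df = "asymptotic")
  prs <- summary(emmeans::contrast(emm, method = "pairwise"),
                 adjust = "none", infer = FALSE)
  df_resid <- fit$n - fit$k_fixed
  est <- prs$estimate
  se <- prs$SE
  tval <- est / se
  n_means <- nrow(summary(emm))
  p <- switch(adjust,
    none = 2 * stats::pt(abs(tval), df_resid, lower.tail = FALSE),
    tukey = stats::ptukey(sqrt(2) * abs(tval), n_means, df_resid,
                          lower.tail = FALSE))
  out <- data.frame(contrast = as.character(prs$contrast), estimate = est,
                    se = se, t = tval, df = df_resid, p_adj = pmin(1, p),
                    stringsAsFactors = FALSE)
  attr(out, "emmeans") <- summary(emm)
  attr(out, "adjust") <- adjust
  class(out) <- c("ts_contrasts", "data.frame")
  out
}

#' Confound calibration on resting-baseline events
#'
#' For each candidate confound (camera distance, ambient humidity, ambient
#' temperature, prior movement) fits one mixed model with the log corrected
#' nose temperature as response, the confound as the only fixed effect and
#' subject identity as a random intercept, then tests the confound with a
#' Wald chi-square. Confounds with `p < alpha` are flagged for control in
#' all subsequent models. Also fits the joint adjustment model (flagged
#' confounds together) whose coefficients are used to residualize
#' temperatures before event-type clustering, and returns the ambient
#' temperature mean used for centering.
#'
#' @param baseline Data frame of baseline events with columns `log_temp`,
#'   `subject_id` and the confound columns.
#' @param confounds Candidate confound columns.
#' @param alpha Flagging threshold (default 0.05).
#' @return List of class `ts_confounds`: `table` (term, chisq, df, p,
#'   flagged), `flagged`, `ambient_mean`, `adjustment` (list with
#'   `ambient_slope` and named `movement_offsets`, zero when not flagged).
#' @export
calibrate_confounds <- function(baseline,
                                confounds = c("ambient_c", "humidity_pct",
                                              "distance_m", "movement"),
                                alpha = 0.05) {
  ts_assert(nrow(baseline) > 0, "no baseline events")
  rows <- list()
  for (cf in confounds) {
    if (!cf %in% names(baseline)) next
    x <- baseline[[cf]]
    if (length(unique(x)) < 2) {
      warning("confound '", cf, "' is constant; skipped", call. = FALSE)
      next
    }
    spec <- lmm_spec(fixed = cf, random = "subject_id", control = NULL)
    fit <- fit_lmm(baseline, spec, method = "REML")
    tc <- term_chisq(fit)
    tc <- tc[tc$term == cf, , drop = FALSE]
    rows[[cf]] <- data.frame(term = cf, chisq = tc$chisq, df = tc$df,
                             p = tc$p, flagged = tc$p < alpha,
                             stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  flagged <- tab$term[tab$flagged]
  ambient_mean <- mean(baseline$ambient_c)

  adjustment <- list(ambient_slope = 0,
                     ambient_mean = ambient_mean,
                     movement_offsets = c(no_movement = 0, steps = 0,
                                          travel = 0))
  joint_terms <- intersect(c("ambient_centered", "movement"),
                           c(if ("ambient_c" %in% flagged) "ambient_centered",
                             if ("movement" %in% flagged) "movement"))
  if (length(joint_terms)) {
    bdat <- baseline
    bdat$ambient_centered <- bdat$ambient_c - ambient_mean
    spec <- lmm_spec(fixed = joint_terms, random = "subject_id",
                     control = NULL)
    jfit <- fit_lmm(bdat, spec, method = "REML")
    beta <- lme4::fixef(jfit$model)
    if ("ambient_centered" %in% names(beta))
      adjustment$ambient_slope <- unname(beta[["ambient_centered"]])
    if ("movement" %in% joint_terms) {
      levs <- levels(factor(bdat$movement))
      off <- stats::setNames(numeric(length(levs)), levs)
      for (lv in levs[-1]) {
        nm <- paste0("movement", lv)
        if (nm %in% names(beta)) off[lv] <- unname(beta[[nm]])
      }
      adjustment$movement_offsets <- off
    }
  }
  structure(list(table = tab, flagged = flagged,
                 ambient_mean = ambient_mean, adjustment = adjustment),
            class = "ts_confounds")
}
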