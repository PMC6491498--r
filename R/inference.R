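# Statistical layer: mixed-effects group contrasts with Satterthwaite
# degrees of freedom, piecewise breakpoint regression at expected onset,
# hub-by-group interaction, and per-group associations.
#
# Random effects are intercepts for scan site and gene type; a random
# factor observed at fewer than 2 levels is dropped (with a note) rather
# than erroring, which small synthetic fixtures need. Estimation is by
# REML; likelihood-ratio tests refit by ML. No multiple-comparison
# correction is applied anywhere in this module: network measures are
# not independent, and downstream reports state this.

groupLevels <- c("gene_negative", "carrier", "ftd")

# random-intercept terms retained (>= 2 observed levels), plus a note
# for what was dropped
retainedRandomTerms <- function(data, candidates = c("site", "gene")) {
  keep <- character(0)
  dropped <- character(0)
  for (v in candidates) {
    if (!v %in% names(data)) next
    if (length(unique(data[[v]])) >= 2L) keep <- c(keep, v)
    else dropped <- c(dropped, v)
  }
  note <- if (length(dropped))
    paste0("random factor(s) dropped (<2 levels): ",
           paste(dropped, collapse = ", "))
  else ""
  list(keep = keep, note = note)
}

reTerms <- function(keep) {
  if (!length(keep)) ""
  else paste0(" + ", paste(sprintf("(1|%s)", keep), collapse = " + "))
}

contrastFromFit <- function(fit, L, label, method, note = "") {
  if (method == "lmm") {
    ct <- lmerTest::contest1D(fit, L, confint = FALSE)
    new("ContrastResult", label = label, estimate = ct[["Estimate"]],
        se = ct[["Std. Error"]], df = ct[["df"]],
        statistic = ct[["t value"]], p = ct[["Pr(>|t|)"]],
        method = "lmm", note = note)
  } else {
    est <- sum(L * stats::coef(fit))
    se <- sqrt(drop(t(L) %*% stats::vcov(fit) %*% L))
    df <- stats::df.residual(fit)
    tv <- est / se
    new("ContrastResult", label = label, estimate = est, se = se,
        df = df, statistic = tv,
        p = 2 * stats::pt(-abs(tv), df), method = "ols", note = note)
  }
}

#' Join subject metadata with per-subject outcome measures
#'
#' @param subjects subject table (as from [generateCohort()]).
#' @param metrics data.frame with a `subject_id` column and outcome
#'   columns (e.g. the `metrics.tsv` layout).
#' @return merged data.frame, one row per subject present in both.
#' @export
analysisTable <- function(subjects, metrics) {
  merge(subjects, metrics, by = "subject_id", sort = TRUE)
}

#' Mixed-effects group contrast
#'
#' Fits `outcome ~ group + age + (1|site) + (1|gene)` on all subjects
#' (keeping the gene-negative group in the model to anchor the age
#' effect) and tests the requested pairwise group contrast with
#' Satterthwaite degrees of freedom. With all random factors degenerate
#' the model reduces to ordinary least squares ANCOVA and residual df
#' are used.
#'
#' @param table data.frame with columns `group`, `age`, `site`, `gene`
#'   and the outcome.
#' @param outcome outcome column name.
#' @param contrast length-2 character: groups a and b; the contrast is
#'   a - b.
#' @return a [ContrastResult].
#' @examples
#' cohort <- generateCohort(cohortConfig(seed = 5), detail = "metadata")
#' tbl <- analysisTable(cohort$subjects,
#'                      cohort$groundTruth$perSubject[,
#'                        c("subject_id", "true_strength")])
#' fitGroupContrast(tbl, "true_strength", c("ftd", "carrier"))
#' @export
fitGroupContrast <- function(table, outcome,
                             contrast = c("ftd", "carrier")) {
  stopifnot(outcome %in% names(table), length(contrast) == 2L,
            all(contrast %in% groupLevels))
  d <- table
  d$group <- factor(d$group, levels = groupLevels)
  present <- levels(droplevels(d$group))
  if (!all(contrast %in% present))
    stop("contrast group(s) absent from the table: ",
         paste(setdiff(contrast, present), collapse = ", "))
  d$.y <- d[[outcome]]
  if (anyNA(d$.y)) stop("missing outcome values in '", outcome, "'")
  label <- paste(contrast[1], "-", contrast[2])
  if (stats::sd(d$.y) == 0) {
    return(new("ContrastResult", label = label, estimate = 0,
               se = NA_real_, df = NA_real_, statistic = NA_real_,
               p = NA_real_, method = "degenerate",
               note = "constant outcome; contrast degenerate"))
  }
  rt <- retainedRandomTerms(d)
  form <- stats::as.formula(paste0(".y ~ group + age", reTerms(rt$keep)))
  if (length(rt$keep)) {
    fit <- lmerTest::lmer(form, data = d,
                          control = lme4::lmerControl(
                            check.conv.singular = "ignore"))
    cf <- names(lme4::fixef(fit))
    method <- "lmm"
  } else {
    fit <- stats::lm(.y ~ group + age, data = d)
    cf <- names(stats::coef(fit))
    method <- "ols"
  }
  L <- stats::setNames(numeric(length(cf)), cf)
  ca <- paste0("group", contrast[1])
  cb <- paste0("group", contrast[2])
  if (ca %in% cf) L[ca] <- 1
  if (cb %in% cf) L[cb] <- -1
  contrastFromFit(fit, L, label, method, rt$note)
}

#' Piecewise breakpoint regression at expected symptom onset
#'
#' On mutation carriers and FTD patients (gene-negative relatives are
#' excluded by default: years-to-onset is not meaningful for
#' non-converters), fits
#' `outcome ~ t + (t - knot)_+ + 1[t > knot] + age` with t =
#' years-to-expected-onset, plus site/gene random intercepts where
#' estimable, and jointly tests the slope-change and level-change terms:
#' an exact F test for ordinary least squares fits, a
#' maximum-likelihood likelihood-ratio test for mixed fits.
#'
#' @param table data.frame with `group`, `years_to_expected_onset`,
#'   `age`, `site`, `gene` and the outcome.
#' @param outcome outcome column name.
#' @param knot breakpoint location in years from expected onset.
#' @param includeGeneNegative include gene-negative rows (off by
#'   default).
#' @return a [BreakpointResult].
#' @examples
#' cohort <- generateCohort(cohortConfig(seed = 5), detail = "metadata")
#' tbl <- analysisTable(cohort$subjects,
#'                      cohort$groundTruth$perSubject[,
#'                        c("subject_id", "true_efficiency_score")])
#' fitBreakpointModel(tbl, "true_efficiency_score")
#' @export
fitBreakpointModel <- function(table, outcome, knot = 0,
                               includeGeneNegative = FALSE) {
  stopifnot(outcome %in% names(table))
  keepGroups <- c("carrier", "ftd",
                  if (includeGeneNegative) "gene_negative")
  d <- table[table$group %in% keepGroups, , drop = FALSE]
  t0 <- d$years_to_expected_onset
  if (!any(t0 > knot) || !any(t0 < knot))
    stop("years_to_expected_onset must span both sides of the knot (",
         knot, "); no observations ",
         if (!any(t0 > knot)) "beyond" else "before", " it")
  d$.y <- d[[outcome]]
  d$.t <- t0
  d$.tpost <- pmax(t0 - knot, 0)
  d$.jump <- as.numeric(t0 > knot)
  rt <- retainedRandomTerms(d)
  fullRhs <- paste0(".t + .tpost + .jump + age", reTerms(rt$keep))
  redRhs <- paste0(".t + age", reTerms(rt$keep))
  if (length(rt$keep)) {
    fitR <- lmerTest::lmer(stats::as.formula(paste(".y ~", fullRhs)),
                           data = d,
                           control = lme4::lmerControl(
                             check.conv.singular = "ignore"))
    fullMl <- lme4::lmer(stats::as.formula(paste(".y ~", fullRhs)),
                         data = d, REML = FALSE,
                         control = lme4::lmerControl(
                           check.conv.singular = "ignore"))
    redMl <- lme4::lmer(stats::as.formula(paste(".y ~", redRhs)),
                        data = d, REML = FALSE,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore"))
    an <- stats::anova(redMl, fullMl)
    p <- an[["Pr(>Chisq)"]][2]
    sm <- stats::coef(summary(fitR))
    method <- "lmm"
    fe <- lme4::fixef(fitR)
  } else {
    fitR <- stats::lm(stats::as.formula(paste(".y ~", fullRhs)), data = d)
    fit0 <- stats::lm(stats::as.formula(paste(".y ~", redRhs)), data = d)
    an <- stats::anova(fit0, fitR)
    p <- an[["Pr(>F)"]][2]
    sm <- stats::coef(summary(fitR))
    method <- "ols"
    fe <- stats::coef(fitR)
  }
  # a numerically perfect fit (noiseless input) has no evidence of a
  # breakpoint beyond rounding error
  if (!is.finite(p)) p <- 1
  terms <- data.frame(term = rownames(sm), estimate = sm[, 1],
                      se = sm[, 2],
                      p = sm[, ncol(sm)], row.names = NULL)
  new("BreakpointResult",
      preSlope = unname(fe[".t"]),
      postSlope = unname(fe[".t"] + fe[".tpost"]),
      slopeChange = unname(fe[".tpost"]),
      levelChange = unname(fe[".jump"]),
      pBreakpoint = p, terms = terms, n = nrow(d), knot = knot,
      method = method)
}

#' Hub-by-group interaction on regional metrics
#'
#' Tests whether the hub-versus-nonhub gap in a regional outcome differs
#' between two groups, with a random intercept per subject:
#' `outcome ~ hub_flag * group + age + (1|subject)` (site/gene
#' intercepts added where estimable). Returns the interaction term.
#'
#' @param regionalTable data.frame, one row per subject x region, with
#'   columns `subject_id`, `group`, `age`, `hub_flag` (logical) and the
#'   outcome.
#' @param groups length-2 character; the interaction contrasts
#'   `groups[2]` against `groups[1]`.
#' @param outcome outcome column name (default `"strength"`).
#' @return a [ContrastResult] for the hub x group interaction.
#' @export
hubGapInteraction <- function(regionalTable,
                              groups = c("carrier", "ftd"),
                              outcome = "strength") {
  stopifnot(outcome %in% names(regionalTable),
            all(c("subject_id", "group", "age", "hub_flag") %in%
                  names(regionalTable)))
  if (!any(regionalTable$hub_flag))
    stop("empty hub set in regional table; re-run hub identification ",
         "(identifyHubs) before testing the hub gap")
  d <- regionalTable[regionalTable$group %in% groups, , drop = FALSE]
  for (g in groups) {
    rows <- d$group == g
    if (!any(rows)) stop("group '", g, "' has no rows")
    if (!any(d$hub_flag[rows]) || all(d$hub_flag[rows]))
      stop("group '", g, "' lacks both hub and non-hub rows")
  }
  d$group <- factor(d$group, levels = groups)
  d$.y <- d[[outcome]]
  d$.hub <- as.logical(d$hub_flag)
  rt <- retainedRandomTerms(d)
  form <- stats::as.formula(paste0(
    ".y ~ .hub * group + age + (1|subject_id)", reTerms(rt$keep)))
  fit <- lmerTest::lmer(form, data = d,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore"))
  cf <- names(lme4::fixef(fit))
  term <- grep(":", cf, value = TRUE)
  if (length(term) != 1L) stop("could not locate the interaction term")
  L <- stats::setNames(as.numeric(cf == term), cf)
  contrastFromFit(fit, L,
                  label = paste0("hub x ", groups[2], " (vs ", groups[1],
                                 ")"),
                  method = "lmm", note = rt$note)
}

#' Per-group association with a between-group interaction test
#'
#' Pearson correlation of `x` and `y` within each group, plus the
#' group-by-`x` interaction from `y ~ x * group + age` (age included as
#' a covariate so age does not masquerade as an association).
#'
#' @param table data.frame with `group`, `age`, `x` and `y` columns.
#' @param x,y numeric column names.
#' @param groups length-2 character vector of groups to compare.
#' @return an [AssociationResult].
#' @export
associationByGroup <- function(table, x, y,
                               groups = c("carrier", "ftd")) {
  stopifnot(x %in% names(table), y %in% names(table))
  d <- table[table$group %in% groups, , drop = FALSE]
  r <- stats::setNames(rep(NA_real_, 2), groups)
  rp <- r
  npg <- stats::setNames(integer(2), groups)
  note <- ""
  for (g in groups) {
    rows <- d$group == g
    npg[[g]] <- sum(rows)
    if (npg[[g]] < 3L) {
      note <- paste0(note, "group '", g, "' too small for correlation; ")
      next
    }
    xv <- d[[x]][rows]
    yv <- d[[y]][rows]
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
      note <- paste0(note, "zero variance in group '", g,
                     "'; r undefined; ")
      next
    }
    ct <- stats::cor.test(xv, yv, method = "pearson")
    r[[g]] <- unname(ct$estimate)
    rp[[g]] <- ct$p.value
  }
  d$group <- factor(d$group, levels = groups)
  d$.x <- d[[x]]
  d$.y <- d[[y]]
  fit <- stats::lm(.y ~ .x * group + age, data = d)
  sm <- stats::coef(summary(fit))
  term <- grep(":", rownames(sm), value = TRUE)
  est <- if (length(term)) sm[term, 1] else NA_real_
  pI <- if (length(term)) sm[term, 4] else NA_real_
  new("AssociationResult", groups = groups, r = r, rP = rp,
      nPerGroup = npg, interactionEstimate = unname(est),
      interactionP = unname(pI), note = note)
}
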