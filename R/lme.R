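# Long-format variability tables and the linear mixed-effects model of
# hemisphere / visual area / portion effects on individual variability.

#' Compute the long-format variability table for a population
#'
#' Runs the whole metric stage: per hemisphere, computes the group-average
#' map and the group-eccentricity mask, then for every subject, hemisphere,
#' visual area and portion computes polar-angle and eccentricity individual
#' variability plus the three covariates (split-half intra-individual
#' variability, curvature variability, normalized mean-BOLD variability).
#'
#' @param pop a `retino_population` (or a list with the same shape).
#' @param lo,hi eccentricity mask bounds in degrees.
#' @return data frame with one row per subject x hemisphere x area x
#'   portion: columns `subject`, `hemisphere` (`LH`/`RH`), `visual_area`,
#'   `portion`, `polar_variability`, `ecc_variability`, `intra_polar`,
#'   `intra_ecc`, `curvature_variability`, `bold_variability`.
#' @export
variability_records <- function(pop, lo = 1, hi = 8) {
  stopifnot(inherits(pop, "retino_population"))
  out <- NULL
  for (h in c("left", "right")) {
    maps <- population_maps(pop, h, "map")
    fit2 <- population_maps(pop, h, "fit2")
    fit3 <- population_maps(pop, h, "fit3")
    avg <- group_average(maps)
    mask <- eccentricity_mask(avg, lo, hi)
    hemi_code <- if (h == "left") "LH" else "RH"
    for (area in c("V1", "V2", "V3")) {
      for (portion in c("dorsal", "ventral")) {
        roi <- paste0(area, substr(portion, 1, 1))
        rows <- data.frame(
          subject = names(maps),
          hemisphere = hemi_code,
          visual_area = area,
          portion = portion,
          polar_variability = vapply(maps, individual_variability, numeric(1),
            avg = avg, mask = mask, roi_labels = roi, quantity = "polar"
          ),
          ecc_variability = vapply(maps, individual_variability, numeric(1),
            avg = avg, mask = mask, roi_labels = roi, quantity = "eccentricity"
          ),
          intra_polar = mapply(intra_individual_variability, fit2, fit3,
            MoreArgs = list(mask = mask, roi_labels = roi, quantity = "polar")
          ),
          intra_ecc = mapply(intra_individual_variability, fit2, fit3,
            MoreArgs = list(mask = mask, roi_labels = roi, quantity = "eccentricity")
          ),
          curvature_variability = vapply(maps, function(m) {
            covariate_variability(m$curvature, avg$curvature, mask, roi, m$patch)
          }, numeric(1)),
          bold_variability = vapply(maps, function(m) {
            covariate_variability(normalize_bold(m$mean_bold), avg$mean_bold,
              mask, roi, m$patch)
          }, numeric(1)),
          stringsAsFactors = FALSE
        )
        out <- rbind(out, rows)
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Assemble the model-ready long table
#'
#' Validates factorial completeness (every subject must contribute all
#' 2 hemispheres x 3 areas x 2 portions cells), selects the response for the
#' chosen quantity, sets treatment-coded factors with reference levels LH,
#' V1 and dorsal, and z-scores the covariate columns over the whole table.
#'
#' @param records output of [variability_records()] (or a table read back
#'   from disk with the same columns).
#' @param response `"polar"` or `"eccentricity"`.
#' @param covariates logical: include the z-scored covariate columns.
#' @return data frame with columns `subject`, `hemisphere`, `visual_area`,
#'   `portion`, `variability`, and (if requested) `intra_individual`,
#'   `curvature_var`, `bold_var`.
#' @export
build_long_table <- function(records, response = c("polar", "eccentricity"),
                             covariates = TRUE) {
  response <- match.arg(response)
  needed <- c("subject", "hemisphere", "visual_area", "portion")
  if (!all(needed %in% names(records))) {
    stop_nf("build_long_table: records lack columns ",
      paste(setdiff(needed, names(records)), collapse = ", "))
  }
  cells <- with(records, paste(hemisphere, visual_area, portion, sep = ":"))
  expected <- as.vector(outer(
    as.vector(outer(c("LH", "RH"), c("V1", "V2", "V3"), paste, sep = ":")),
    c("dorsal", "ventral"), paste, sep = ":"
  ))
  missing <- NULL
  for (s in unique(records$subject)) {
    have <- cells[records$subject == s]
    miss <- setdiff(expected, have)
    if (length(miss)) missing <- c(missing, paste0(s, "[", miss, "]"))
  }
  if (length(missing)) {
    stop_nf("build_long_table: missing factorial cells: ",
      paste(utils::head(missing, 10), collapse = ", "),
      if (length(missing) > 10) " ...")
  }
  zscore <- function(v) {
    s <- stats::sd(v)
    if (s == 0) stop_nf("build_long_table: zero-variance covariate cannot be z-scored")
    (v - mean(v)) / s
  }
  tab <- data.frame(
    subject = factor(records$subject),
    hemisphere = factor(records$hemisphere, levels = c("LH", "RH")),
    visual_area = factor(records$visual_area, levels = c("V1", "V2", "V3")),
    portion = factor(records$portion, levels = c("dorsal", "ventral")),
    variability = if (response == "polar") records$polar_variability else records$ecc_variability
  )
  if (any(tab$variability < 0)) stop_nf("build_long_table: negative variability value")
  if (isTRUE(covariates)) {
    tab$intra_individual <- zscore(
      if (response == "polar") records$intra_polar else records$intra_ecc
    )
    tab$curvature_var <- zscore(records$curvature_variability)
    tab$bold_var <- zscore(records$bold_variability)
  }
  tab
}

lme_formula <- function(covariates, random_terms) {
  fixed <- "variability ~ hemisphere * visual_area * portion"
  if (covariates) fixed <- paste(fixed, "+ intra_individual + curvature_var + bold_var")
  stats::as.formula(paste(fixed, "+", paste(random_terms, collapse = " + ")))
}

FULL_RANDOM <- c(
  "(1 | subject)",
  "(1 | subject:hemisphere)",
  "(1 | subject:visual_area)",
  "(1 | subject:portion)"
)

#' Fit the linear mixed-effects model of individual variability
#'
#' REML fit of `variability ~ hemisphere * visual_area * portion
#' (+ covariates)` with a random intercept per subject and random intercepts
#' of each factor nested within subject; Satterthwaite degrees of freedom.
#' Treatment coding with references LH, V1 and dorsal, so e.g. the
#' `hemisphere` row is the RH - LH difference at the reference levels.
#'
#' If the full nested random structure fails to converge, nested terms are
#' dropped one at a time (area, then portion, then hemisphere) and the
#' structure actually used is recorded. A singular random-effect variance is
#' reported but the fit is retained.
#'
#' @param table output of [build_long_table()].
#' @param covariates include the covariate terms (the table must contain
#'   them).
#' @param reml use REML (default) or ML.
#' @return an object of class `variability_lme`: list with `fit` (the
#'   underlying `lmerModLmerTest`), `coefficients` (data frame: effect,
#'   estimate, se, ci_low, ci_high, df, t, p), `random_variances`,
#'   `converged`, `singular`, `random_structure`, `response_degenerate`.
#' @export
fit_lme <- function(table, covariates = FALSE, reml = TRUE) {
  if (covariates && !all(c("intra_individual", "curvature_var", "bold_var") %in% names(table))) {
    stop_nf("fit_lme: covariates requested but table lacks covariate columns")
  }
  degenerate <- stats::sd(table$variability) == 0
  if (degenerate) {
    warning("fit_lme: response is constant; model is degenerate")
  }
  ladder <- list(
    FULL_RANDOM,
    FULL_RANDOM[c(1, 2, 4)],
    FULL_RANDOM[c(1, 2)],
    FULL_RANDOM[1]
  )
  fit <- NULL
  used <- NULL
  last_err <- NULL
  for (terms in ladder) {
    res <- tryCatch(
      {
        f <- lmerTest::lmer(lme_formula(covariates, terms), data = table, REML = reml,
          control = lme4::lmerControl(check.conv.singular = lme4::.makeCC("ignore", tol = 1e-4)))
        msgs <- f@optinfo$conv$lme4$messages
        if (!is.null(msgs) && any(grepl("failed to converge", msgs, ignore.case = TRUE))) {
          stop("optimizer reported non-convergence: ", paste(msgs, collapse = "; "))
        }
        f
      },
      error = function(e) e
    )
    if (!inherits(res, "error")) {
      fit <- res
      used <- terms
      break
    }
    last_err <- res
  }
  if (is.null(fit)) {
    return(structure(
      list(
        fit = NULL, coefficients = NULL, random_variances = NULL,
        converged = FALSE, singular = NA,
        random_structure = character(0),
        response_degenerate = degenerate,
        message = conditionMessage(last_err)
      ),
      class = "variability_lme"
    ))
  }
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (singular) {
    warning("fit_lme: singular random-effect variance estimate; fit retained")
  }
  sm <- summary(fit)$coefficients
  df <- sm[, "df"]
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  tcrit <- stats::qt(0.975, df)
  coefs <- data.frame(
    effect = rownames(sm),
    estimate = est,
    se = se,
    ci_low = est - tcrit * se,
    ci_high = est + tcrit * se,
    df = df,
    t = sm[, "t value"],
    p = sm[, "Pr(>|t|)"],
    row.names = NULL
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(
      fit = fit,
      coefficients = coefs,
      random_variances = stats::setNames(vc$vcov, vc$grp),
      converged = TRUE,
      singular = singular,
      random_structure = used,
      response_degenerate = degenerate
    ),
    class = "variability_lme"
  )
}

#' @export
print.variability_lme <- function(x, digits = 3, ...) {
  cat("Linear mixed-effects model of individual variability\n")
  if (!x$converged) {
    cat("  NOT CONVERGED:", x$message, "\n")
    return(invisible(x))
  }
  cat("  random structure:", paste(x$random_structure, collapse = " + "), "\n")
  if (x$singular) cat("  note: singular random-effect variance\n")
  print(cbind(
    x$coefficients["effect"],
    round(x$coefficients[, c("estimate", "se", "ci_low", "ci_high", "df", "t")], digits),
    p = format.pval(x$coefficients$p, digits = 2)
  ), row.names = FALSE)
  invisible(x)
}

#' @export
summary.variability_lme <- function(object, ...) {
  object
}

#' @export
coef.variability_lme <- function(object, ...) {
  if (!object$converged) stop_nf("model did not converge")
  stats::setNames(object$coefficients$estimate, object$coefficients$effect)
}

#' Post hoc pairwise visual-area contrasts
#'
#' Contrasts of estimated marginal means of the visual areas (V2 - V1,
#' V3 - V1, V3 - V2), Bonferroni-adjusted over the three tests.
#'
#' @param result a converged `variability_lme`.
#' @return data frame with columns `contrast`, `estimate`, `se`, `df`, `t`,
#'   `p_adj`.
#' @export
posthoc_area_contrasts <- function(result) {
  stopifnot(inherits(result, "variability_lme"))
  if (!result$converged) stop_nf("posthoc_area_contrasts: model did not converge")
  em <- suppressMessages(
    emmeans::emmeans(result$fit, ~visual_area, lmer.df = "satterthwaite")
  )
  ct <- emmeans::contrast(
    em,
    method = list(
      "V2-V1" = c(-1, 1, 0),
      "V3-V1" = c(-1, 0, 1),
      "V3-V2" = c(0, -1, 1)
    ),
    adjust = "bonferroni"
  )
  cs <- as.data.frame(ct)
  data.frame(
    contrast = cs$contrast,
    estimate = cs$estimate,
    se = cs$SE,
    df = cs$df,
    t = cs$t.ratio,
    p_adj = cs$p.value,
    stringsAsFactors = FALSE
  )
}
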