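#' Standardize columns of a cohort table
#'
#' Replaces each named numeric column by its z-score, `(x - mean) / SD`,
#' computed over the analysis rows (after any exclusions, before model
#' fitting). Binary sex stays an indicator and is never z-scored.
#'
#' @param table A data.frame.
#' @param columns Character vector of column names to standardize.
#' @return The table with the named columns standardized.
#' @export
standardize <- function(table, columns) {
  for (cl in columns) {
    if (!cl %in% names(table)) stop("no such column: ", cl)
    x <- table[[cl]]
    if (!is.numeric(x)) stop("column is not numeric: ", cl)
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("cannot standardize constant column: ", cl)
    }
    table[[cl]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  table
}

#' Fit a random-intercept linear mixed model
#'
#' Fits `outcome ~ fixed_terms + (1 | group)` by REML (lme4), the structure
#' used to absorb inter-eye correlation: both eyes of one participant share
#' an additive random intercept. Inference is Wald with a normal reference
#' distribution (95% CI = beta +/- 1.96 SE). When every participant
#' contributes exactly one row the intercept variance is unidentifiable and
#' the fit drops to ordinary least squares, flagged `degenerate_clustering`;
#' a fitted intercept variance of (numerically) zero is flagged `singular`,
#' not failed. A rank-deficient fixed design is an error naming the aliased
#' terms.
#'
#' @param table Data.frame with one row per eye.
#' @param outcome Name of the outcome column.
#' @param fixed_terms Character vector of fixed-effect term names.
#' @param group Grouping column (default `"participant_id"`).
#' @param reml Use REML (default) or plain maximum likelihood.
#' @return An object of class `model_result`: data.frame of terms (term,
#'   beta, se, ci_low, ci_high, p) plus attributes `n_eyes`,
#'   `n_participants`, `intercept_var`, `residual_var`, `singular`,
#'   `degenerate_clustering`, `outcome`.
#' @export
fit_random_intercept <- function(table, outcome, fixed_terms,
                                 group = "participant_id", reml = TRUE) {
  need <- c(outcome, fixed_terms, group)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dat <- table[stats::complete.cases(table[, need, drop = FALSE]), , drop = FALSE]
  if (length(unique(dat[[group]])) < 2) {
    stop("need at least 2 participants")
  }
  fixed_rhs <- paste(fixed_terms, collapse = " + ")
  X <- model.matrix(stats::as.formula(paste("~", fixed_rhs)), dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }

  one_per_group <- !any(duplicated(dat[[group]]))
  if (one_per_group) {
    fit <- lm(stats::as.formula(paste(outcome, "~", fixed_rhs)), data = dat)
    sm <- summary(fit)$coefficients
    beta <- sm[, 1]; se <- sm[, 2]
    iv <- 0; rv <- summary(fit)$sigma^2
    singular <- TRUE
  } else {
    form <- stats::as.formula(
      paste(outcome, "~", fixed_rhs, "+ (1 |", group, ")"))
    fit <- lme4::lmer(form, data = dat, REML = reml,
                      control = lme4::lmerControl(check.conv.singular =
                        lme4::.makeCC(action = "ignore", tol = 1e-4)))
    sm <- coef(summary(fit))
    beta <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
    vc <- as.data.frame(lme4::VarCorr(fit))
    iv <- vc$vcov[vc$grp == group]
    rv <- vc$vcov[vc$grp == "Residual"]
    singular <- lme4::isSingular(fit, tol = 1e-4)
  }
  z <- beta / se
  res <- data.frame(term = names(beta) %||% rownames(sm),
                    beta = unname(beta), se = unname(se),
                    ci_low = unname(beta - qnorm(0.975) * se),
                    ci_high = unname(beta + qnorm(0.975) * se),
                    p = unname(2 * pnorm(-abs(z))),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, class = c("model_result", "data.frame"),
            n_eyes = nrow(dat),
            n_participants = length(unique(dat[[group]])),
            intercept_var = iv, residual_var = rv,
            singular = singular, degenerate_clustering = one_per_group,
            outcome = outcome)
}

#' @export
print.model_result <- function(x, ...) {
  cat("Random-intercept model for", attr(x, "outcome"), "--",
      attr(x, "n_eyes"), "eyes of", attr(x, "n_participants"),
      "participants\n")
  if (isTRUE(attr(x, "degenerate_clustering"))) {
    cat("  (one eye per participant: ordinary least squares)\n")
  } else if (isTRUE(attr(x, "singular"))) {
    cat("  (singular fit: intercept variance estimated at zero)\n")
  }
  print.data.frame(x, digits = 4)
  invisible(x)
}

# encode sex as 0/1 male indicator (female reference), never z-scored
prepare_sex <- function(table) {
  if ("sex" %in% names(table) && !is.numeric(table$sex)) {
    table$male <- as.integer(table$sex == "male")
  } else if ("sex" %in% names(table)) {
    table$male <- as.integer(table$sex)
  }
  table
}

#' Shape-outcome models: asphericity and volume versus SER
#'
#' Fits the four models of the primary shape analysis: horizontal
#' asphericity, vertical asphericity and posterior eye volume each regressed
#' on SER controlling for age and sex, plus the height-adjusted volume
#' variant. Continuous predictors (SER, age, height) are standardized over
#' the analysis sample; sex enters as a 0/1 male indicator.
#'
#' @param table Cohort data.frame with columns `Q_h`, `Q_v`, `volume`,
#'   `ser`, `age`, `sex`, `height`, `participant_id`.
#' @return A tidy data.frame (one row per term per model) with a `model`
#'   column; the `model_result` objects are attached as attribute `"fits"`.
#' @export
run_shape_models <- function(table) {
  need <- c("Q_h", "Q_v", "volume", "ser", "age", "sex", "height",
            "participant_id")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  tab <- prepare_sex(table)
  tab <- standardize(tab, c("ser", "age", "height"))
  specs <- list(
    list(outcome = "Q_h", terms = c("ser", "age", "male")),
    list(outcome = "Q_v", terms = c("ser", "age", "male")),
    list(outcome = "volume", terms = c("ser", "age", "male")),
    list(outcome = "volume", terms = c("ser", "age", "male", "height")))
  fits <- lapply(specs, function(s) {
    fit_random_intercept(tab, s$outcome, s$terms)
  })
  names(fits) <- c("Q_h", "Q_v", "volume", "volume_height_adjusted")
  out <- do.call(rbind, lapply(names(fits), function(nm) {
    cbind(model = nm, as.data.frame(fits[[nm]]))
  }))
  attr(out, "fits") <- fits
  out
}

#' Feature-versus-asphericity models
#'
#' For each fundus feature and each asphericity meridian, fits an
#' unadjusted model (feature only) and an adjusted model (feature + SER +
#' age + sex), each with a participant random intercept. Features with no
#' usable values are skipped with a message. Continuous predictors are
#' standardized over the analysis sample; no multiple-testing correction is
#' applied by default (`p_adjust = "none"`), matching the convention of
#' reporting unadjusted p-values across the 24 models.
#'
#' @param table Cohort data.frame.
#' @param features Feature columns (default the twelve canonical names
#'   present in the table).
#' @param p_adjust Method passed to [stats::p.adjust()] for the feature-term
#'   p-values, `"none"` by default.
#' @return Tidy data.frame with columns `feature`, `meridian`, `adjusted`,
#'   and the feature-term estimate columns; full term tables attached as
#'   attribute `"fits"`.
#' @export
run_feature_models <- function(table, features = NULL, p_adjust = "none") {
  features <- features %||%
    intersect(fundus_feature_names(), names(table))
  if (!length(features)) stop("no feature columns found")
  tab <- prepare_sex(table)
  covars <- intersect(c("ser", "age"), names(tab))
  rows <- list(); fits <- list()
  for (feat in features) {
    x <- tab[[feat]]
    if (all(!is.finite(x))) {
      message("feature skipped (no usable values): ", feat)
      next
    }
    if (sd(x, na.rm = TRUE) == 0) {
      message("feature skipped (constant): ", feat)
      next
    }
    std_cols <- c(feat, covars)
    tab_f <- standardize(tab, std_cols)
    for (meridian in c("Q_h", "Q_v")) {
      for (adjusted in c(FALSE, TRUE)) {
        terms <- if (adjusted) c(feat, "ser", "age", "male") else feat
        fit <- fit_random_intercept(tab_f, meridian, terms)
        key <- paste(feat, meridian, if (adjusted) "adj" else "unadj",
                     sep = ".")
        fits[[key]] <- fit
        fr <- fit[fit$term == feat, ]
        rows[[key]] <- data.frame(
          feature = feat, meridian = meridian, adjusted = adjusted,
          beta = fr$beta, ci_low = fr$ci_low, ci_high = fr$ci_high,
          p = fr$p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (p_adjust != "none") out$p <- stats::p.adjust(out$p, method = p_adjust)
  attr(out, "fits") <- fits
  out
}
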