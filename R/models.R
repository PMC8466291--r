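#' Specification of the growth model selection chain
#'
#' Bundles the response, the candidate fixed-effect terms, the random
#' intercept terms (group-pen phase only), and the two significance
#' thresholds: `screen_alpha` for carrying a term from univariable screening
#' into the maximal multivariable model, and `retain_alpha` for keeping a
#' term during backward elimination.
#'
#' @param response response column name (daily liveweight gain).
#' @param terms character vector of candidate fixed-effect columns.
#' @param random character vector of random-intercept grouping columns
#'   (NULL for a fixed-effects-only chain).
#' @param screen_alpha univariable screening threshold (default 0.20).
#' @param retain_alpha backward-elimination retention threshold (default 0.05).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(response = "dlwg", terms, random = NULL,
                       screen_alpha = 0.20, retain_alpha = 0.05) {
  stopifnot(screen_alpha > 0, screen_alpha < 1,
            retain_alpha > 0, retain_alpha < 1,
            retain_alpha < screen_alpha)
  structure(list(response = response, terms = terms, random = random,
                 screen_alpha = screen_alpha, retain_alpha = retain_alpha),
            class = "model_spec")
}

build_formula <- function(response, terms, random = NULL) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  if (length(random)) {
    rhs <- paste(c(rhs, paste0("(1 | ", random, ")")), collapse = " + ")
  }
  stats::as.formula(paste(response, "~", rhs))
}

# Drop random terms with fewer than two observed levels (they carry no
# information and break the fit), with a warning.
usable_random <- function(data, random) {
  if (!length(random)) return(NULL)
  ok <- vapply(random, function(g) length(unique(data[[g]])) >= 2, logical(1))
  if (any(!ok)) {
    warning("random term(s) dropped (fewer than 2 levels): ",
            paste(random[!ok], collapse = ", "))
  }
  random[ok]
}

#' Fit the growth model for a set of terms
#'
#' Ordinary least squares when no random terms are given; otherwise a linear
#' mixed model with independent (crossed) random intercepts, fitted by
#' REML via [lmerTest::lmer()] so per-coefficient p-values use Satterthwaite
#' degrees of freedom. If the mixed fit is unestimable the function falls
#' back to the fixed-effects fit with a warning.
#'
#' @param data model frame.
#' @param response,terms,random model structure (see [model_spec()]).
#' @param reml fit by REML (TRUE, default) or ML.
#' @return an `lm` or `lmerModLmerTest` fit.
#' @export
fit_growth_model <- function(data, response, terms, random = NULL,
                             reml = TRUE) {
  data <- droplevels(data)
  random <- usable_random(data, random)
  if (!length(random)) {
    return(stats::lm(build_formula(response, terms), data = data))
  }
  f <- build_formula(response, terms, random)
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(
      f, data = data, REML = reml,
      control = lme4::lmerControl(optimizer = "bobyqa"))),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("mixed model unestimable; falling back to fixed-effects fit")
    return(stats::lm(build_formula(response, terms), data = data))
  }
  fit
}

# Whole-term p-values for every fixed term in the current model.
# OLS: marginal F-tests (drop each term from the full fit).
# LMM: likelihood-ratio tests of nested ML fits, matching chi-square
# reporting for mixed models. Returns a named numeric vector.
term_pvalues <- function(data, response, terms, random = NULL) {
  data <- droplevels(data)
  random <- usable_random(data, random)
  if (!length(terms)) return(stats::setNames(numeric(0), character(0)))
  if (!length(random)) {
    fit <- stats::lm(build_formula(response, terms), data = data)
    d1 <- stats::drop1(fit, test = "F")
    p <- d1[["Pr(>F)"]]
    names(p) <- rownames(d1)
    p <- p[terms]
    # a term perfectly collinear with another leaves the fit unchanged when
    # dropped; drop1 reports NA there, which we treat as p = 1 so backward
    # elimination removes it first (ties broken by candidate order)
    p[is.na(p)] <- 1
    return(p)
  }
  ctrl <- lme4::lmerControl(optimizer = "bobyqa")
  full <- suppressMessages(lme4::lmer(build_formula(response, terms, random),
                                      data = data, REML = FALSE,
                                      control = ctrl))
  vapply(terms, function(tm) {
    red <- suppressMessages(lme4::lmer(
      build_formula(response, setdiff(terms, tm), random),
      data = data, REML = FALSE, control = ctrl))
    a <- stats::anova(red, full)
    p <- a[["Pr(>Chisq)"]][2]
    if (is.na(p)) 1 else p
  }, numeric(1))
}

#' Univariable screening of candidate terms
#'
#' Fits each candidate term alone against the response (with the phase's
#' random intercepts, if any) and keeps terms whose whole-term p-value falls
#' below `screen_alpha`. Constant columns are skipped with a warning; a
#' mixed model that cannot be estimated falls back to the fixed-effects fit
#' with a warning.
#'
#' @param data model frame.
#' @param spec a [model_spec()].
#' @return data frame with columns term, p_value, kept.
#' @export
univariable_screen <- function(data, spec) {
  rows <- lapply(spec$terms, function(tm) {
    x <- data[[tm]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warning("screening: constant column '", tm, "' skipped")
      return(data.frame(term = tm, p_value = NA_real_, kept = FALSE))
    }
    p <- term_pvalues(data, spec$response, tm, spec$random)
    data.frame(term = tm, p_value = unname(p), kept = unname(p) < spec$screen_alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Backward elimination to the final growth model
#'
#' Starting from the maximal model over the supplied terms, repeatedly
#' refits and removes the single term with the largest whole-term p-value at
#' or above `retain_alpha` (multi-level factors are tested as whole terms;
#' ties are broken by dropping the term appearing later in the candidate
#' list), until every remaining term is significant. Random intercepts are
#' structural and never dropped. An empty surviving set yields an
#' intercept-only model.
#'
#' @param data model frame.
#' @param terms character vector of terms entering the maximal model
#'   (typically the survivors of [univariable_screen()]).
#' @param spec a [model_spec()].
#' @return a `calf_model` result: final fit, coefficient table shaped like
#'   the study's model tables (estimate, SE, per-level p vs reference,
#'   whole-term p), elimination trace, and fit diagnostics.
#' @export
backward_select <- function(data, terms, spec) {
  current <- terms
  trace <- list()
  repeat {
    if (!length(current)) break
    p <- term_pvalues(data, spec$response, current, spec$random)
    worst <- max(p)
    if (worst < spec$retain_alpha) break
    # ties: drop the term latest in the original candidate list
    cand <- names(p)[p == worst]
    drop_term <- cand[which.max(match(cand, terms))]
    trace[[length(trace) + 1]] <- data.frame(term = drop_term,
                                             p_value = unname(p[drop_term]))
    current <- setdiff(current, drop_term)
  }
  final_p <- term_pvalues(data, spec$response, current, spec$random)
  fit <- fit_growth_model(data, spec$response, current, spec$random,
                          reml = TRUE)
  result <- model_result(fit, data, current, final_p, spec)
  result$trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(term = character(0), p_value = numeric(0))
  result
}

# Assemble the printed-table-shaped coefficient summary plus diagnostics.
model_result <- function(fit, data, terms, term_p, spec) {
  is_mixed <- inherits(fit, "merMod")
  cf <- if (is_mixed) as.data.frame(stats::coef(summary(fit))) else
    as.data.frame(stats::coef(summary(fit)))
  pcol <- grep("^Pr", names(cf), value = TRUE)[1]
  rows <- list(data.frame(variable = "Intercept", level = "",
                          estimate = cf["(Intercept)", "Estimate"],
                          se = cf["(Intercept)", "Std. Error"],
                          p_reference = NA_real_,
                          p_effect = cf["(Intercept)", pcol]))
  for (tm in terms) {
    x <- data[[tm]]
    if (is.factor(x) || is.character(x)) {
      lev <- levels(droplevels(factor(x)))
      rows[[length(rows) + 1]] <- data.frame(
        variable = tm, level = paste0(lev[1], " (reference)"),
        estimate = NA_real_, se = NA_real_, p_reference = NA_real_,
        p_effect = unname(term_p[tm]))
      for (l in lev[-1]) {
        cn <- paste0(tm, l)
        rows[[length(rows) + 1]] <- data.frame(
          variable = tm, level = l,
          estimate = cf[cn, "Estimate"], se = cf[cn, "Std. Error"],
          p_reference = cf[cn, pcol], p_effect = NA_real_)
      }
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        variable = tm, level = "",
        estimate = cf[tm, "Estimate"], se = cf[tm, "Std. Error"],
        p_reference = NA_real_, p_effect = unname(term_p[tm]))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  re_var <- NULL
  singular <- FALSE
  if (is_mixed) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    re_var <- stats::setNames(vc$vcov, vc$grp)
    singular <- lme4::isSingular(fit)
  }
  structure(list(
    model = fit,
    terms = terms,
    term_p = term_p,
    coef_table = tab,
    n = stats::nobs(fit),
    sigma = stats::sigma(fit),
    random_variances = re_var,
    singular = singular,
    spec = spec,
    trace = NULL
  ), class = "calf_model")
}

#' Print a fitted growth-model result
#'
#' @param x a `calf_model` from [backward_select()].
#' @param ... unused.
#' @return `x`, invisibly.
#' @method print calf_model
#' @export
print.calf_model <- function(x, ...) {
  cat("Final growth model (n = ", x$n, ")\n", sep = "")
  if (!is.null(x$random_variances)) {
    cat("Random-intercept variances:",
        paste(names(x$random_variances),
              signif(x$random_variances, 3), sep = "=", collapse = ", "),
        if (x$singular) "(singular fit)" else "", "\n")
  }
  print(x$coef_table, digits = 3)
  if (!is.null(x$trace) && nrow(x$trace)) {
    cat("Eliminated:", paste(x$trace$term, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Tukey post-hoc contrasts for a retained factor
#'
#' All pairwise contrasts between the levels of a factor retained in the
#' final model, with family-wise studentised-range (Tukey) adjustment.
#'
#' @param result a `calf_model` from [backward_select()], or a bare fit.
#' @param factor name of a factor term in the final model.
#' @return data frame: contrast, estimate, se, p_adj.
#' @export
tukey_posthoc <- function(result, factor) {
  fit <- if (inherits(result, "calf_model")) result$model else result
  terms <- if (inherits(result, "calf_model")) result$terms else NULL
  if (!is.null(terms) && !factor %in% terms) {
    stop("tukey_posthoc: '", factor, "' is not in the final model")
  }
  em <- emmeans::emmeans(fit, specs = factor)
  pr <- summary(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
  data.frame(contrast = as.character(pr$contrast),
             estimate = pr$estimate, se = pr$SE, p_adj = pr$p.value,
             stringsAsFactors = FALSE)
}
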