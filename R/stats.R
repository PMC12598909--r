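#' Mixed-effects ANOVA with interaction pruning
#'
#' Fits a linear mixed model of the response on the fixed factors plus all
#' their pairwise interactions, with random intercepts for each grouping
#' term (chamber id and measurement date in the campaign design). Type-III
#' ANOVA with Satterthwaite denominator degrees of freedom is computed; all
#' interaction terms with p above `alpha` are then dropped in one step and
#' the model refit (significant interactions are retained). Fixed factors
#' with fewer than two levels in the data are dropped with a message, as
#' are random terms without replication (a single level, or as many levels
#' as observations); if no usable random term remains the model degrades to
#' a fixed-effects fit with Type-III tests on the residual degrees of
#' freedom.
#'
#' @param data data.frame containing the response, fixed and random columns.
#' @param response response column name.
#' @param fixed character vector of fixed-factor column names.
#' @param random character vector of random-intercept column names.
#' @param alpha pruning significance level.
#' @return object of class `pruned_anova`: `table` (Effect, SS, NumDF,
#'   DenDF, F, p), `formula`, `model` (lmerModLmerTest), `dropped`
#'   (interaction terms removed), `singular` flag.
#' @export
fit_with_pruning <- function(data, response,
                             fixed = c("fertilization", "plot", "year"),
                             random = c("chamber_id", "date"),
                             alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, length(random) >= 1)
  missing_cols <- setdiff(c(response, fixed, random), names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  for (f in c(fixed, random)) data[[f]] <- factor(data[[f]])
  usable <- fixed[vapply(fixed, function(f) nlevels(droplevels(data[[f]])) >= 2,
                         logical(1))]
  if (length(usable) < length(fixed)) {
    message("dropping single-level fixed factor(s): ",
            paste(setdiff(fixed, usable), collapse = ", "))
  }
  if (!length(usable)) stop("no fixed factor has >= 2 levels")
  usable_rand <- random[vapply(random, function(r) {
    nl <- nlevels(droplevels(data[[r]]))
    nl >= 2 && nl < nrow(data) # intercepts need replication to estimate
  }, logical(1))]
  if (length(usable_rand) < length(random)) {
    message("dropping unusable random term(s): ",
            paste(setdiff(random, usable_rand), collapse = ", "))
  }
  random <- usable_rand
  mixed <- length(random) > 0
  if (!mixed) {
    message("no usable random grouping term; fitting a fixed-effects model")
  }

  rand_part <- if (mixed) {
    paste("+", paste(sprintf("(1 | %s)", random), collapse = " + "))
  } else ""
  fixed_part <- if (length(usable) > 1) {
    sprintf("(%s)^2", paste(usable, collapse = " + "))
  } else usable
  full_formula <- stats::as.formula(
    paste(response, "~", fixed_part, rand_part))

  fit_one <- function(fml) {
    if (mixed) {
      suppressMessages(lmerTest::lmer(fml, data = data,
                                      control = lme4::lmerControl(
                                        check.conv.singular = "ignore")))
    } else {
      old <- options(contrasts = c("contr.sum", "contr.poly"))
      on.exit(options(old), add = TRUE)
      stats::lm(fml, data = data)
    }
  }
  tidy_anova <- function(m) {
    if (mixed) {
      a <- stats::anova(m, type = 3)
      data.frame(Effect = rownames(a), SS = a$`Sum Sq`, NumDF = a$NumDF,
                 DenDF = a$DenDF, F = a$`F value`, p = a$`Pr(>F)`,
                 row.names = NULL)
    } else {
      a <- car::Anova(m, type = 3)
      a <- a[!rownames(a) %in% c("(Intercept)", "Residuals"), ,
             drop = FALSE]
      data.frame(Effect = rownames(a), SS = a$`Sum Sq`, NumDF = a$Df,
                 DenDF = stats::df.residual(m), F = a$`F value`,
                 p = a$`Pr(>F)`, row.names = NULL)
    }
  }

  m <- fit_one(full_formula)
  tab <- tidy_anova(m)
  inter <- grepl(":", tab$Effect)
  drop <- tab$Effect[inter & (is.na(tab$p) | tab$p > alpha)]
  final_formula <- full_formula
  if (length(drop)) {
    keep_inter <- setdiff(tab$Effect[inter], drop)
    terms_txt <- c(usable, keep_inter)
    final_formula <- stats::as.formula(
      paste(response, "~", paste(terms_txt, collapse = " + "), rand_part))
    m <- fit_one(final_formula)
    tab <- tidy_anova(m)
  }
  singular <- mixed && lme4::isSingular(m)
  if (singular) message("final fit is singular")
  structure(list(table = tab, formula = final_formula, model = m,
                 dropped = drop, singular = singular, alpha = alpha),
            class = "pruned_anova")
}

#' @export
print.pruned_anova <- function(x, ...) {
  cat("Mixed-model ANOVA (Type III, Satterthwaite), pruned at alpha =",
      x$alpha, "\n")
  cat("Final model:", deparse(x$formula), "\n")
  if (length(x$dropped)) {
    cat("Dropped interactions:", paste(x$dropped, collapse = ", "), "\n")
  }
  print(x$table, digits = 4)
  invisible(x)
}
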