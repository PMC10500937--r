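# Model specification and data preparation for the two LOS estimators.

#' Specify the fixed-effect structure of a LOS model
#'
#' Builds the term list shared by the two estimators: age and its
#' square, APACHE III and its square, log risk of death, pre-ICU days,
#' the binary admission flags, and optionally hospital class, the
#' 30-level diagnostic group and a configurable interaction list.  The
#' grouping structure is always an ICU random intercept.
#'
#' @param response \code{"log_los"} (linear mixed model on log days) or
#'   \code{"los_days"} (gaussian log-link GLMM on raw days).
#' @param include_dx Include the diagnostic-group factor.
#' @param include_hosp_class Include the hospital-class factor.
#' @param interactions Character vector of interaction terms; the
#'   default couples ventilation and ICU death with log risk of death
#'   and hospital class with APACHE III.  Use \code{character(0)} for a
#'   main-effects model.
#' @param extra_terms Additional model terms (advanced use).
#' @return An object of class \code{los_model_spec}.
#' @examples
#' los_model_spec("log_los", include_dx = FALSE, interactions = character(0))
#' @export
los_model_spec <- function(response = c("log_los", "los_days"),
                           include_dx = TRUE,
                           include_hosp_class = TRUE,
                           interactions = c("vent_d1:log_anzrod",
                                            "died_icu:log_anzrod",
                                            "hosp_class:apache3"),
                           extra_terms = character(0)) {
  response <- match.arg(response)
  terms <- c("age", "I(age^2)", "apache3", "I(apache3^2)", "log_anzrod",
             "preicu_days", "died_icu", "arf", "limitation", "arrest",
             "vent_d1")
  if (include_hosp_class) terms <- c(terms, "hosp_class")
  if (include_dx) terms <- c(terms, "dx_group")
  if (!include_hosp_class) {
    interactions <- interactions[!grepl("hosp_class", interactions)]
  }
  structure(list(response = response,
                 fixed_terms = c(terms, interactions, extra_terms),
                 grouping = "icu_id"),
            class = "los_model_spec")
}

#' Reduced model specification for small designs
#'
#' Main-effects-only specification on a handful of covariates, suitable
#' for simulation studies with moderate per-site volumes.
#'
#' @inheritParams los_model_spec
#' @export
reduced_model_spec <- function(response = c("log_los", "los_days")) {
  response <- match.arg(response)
  structure(list(response = response,
                 fixed_terms = c("apache3", "log_anzrod", "preicu_days",
                                 "died_icu", "vent_d1"),
                 grouping = "icu_id"),
            class = "los_model_spec")
}

.spec_formula <- function(spec, random = TRUE) {
  lhs <- if (spec$response == "log_los") "log(los_days)" else "los_days"
  rhs <- paste(spec$fixed_terms, collapse = " + ")
  if (random) rhs <- paste0(rhs, " + (1 | ", spec$grouping, ")")
  stats::as.formula(paste(lhs, "~", rhs))
}

# merge site info, derive transformed covariates, drop incomplete rows
# (complete-case analysis; the drop count is recorded as an attribute)
.prep_model_data <- function(registry, spec) {
  p <- registry$patients
  s <- registry$sites
  bad_los <- !is.finite(p$los_days) | p$los_days <= 0
  if (any(bad_los)) stop(sum(bad_los), " rows with non-positive LOS; ",
                         "models require los_days > 0")
  d <- merge(p, s[, c("icu_id", "hosp_class")], by = "icu_id", sort = FALSE)
  d$log_anzrod <- log(pmax(d$anzrod, 1e-04))
  d$icu_id <- factor(d$icu_id)
  d$dx_group <- factor(d$dx_group)
  d$hosp_class <- factor(d$hosp_class)
  vars <- unique(c("los_days", "icu_id",
                   all.vars(.spec_formula(spec, random = FALSE))))
  vars <- intersect(vars, names(d))
  cc <- stats::complete.cases(d[, vars])
  out <- droplevels(d[cc, , drop = FALSE])
  attr(out, "n_dropped") <- sum(!cc)
  out
}

# error with the offending columns if the fixed-effect design is singular
.check_design_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  invisible(TRUE)
}
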