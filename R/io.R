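# CSV and config-file interchange for registries.

.patient_cols <- c("icu_id", "age", "apache3", "anzrod", "preicu_days",
                   "died_icu", "arf", "limitation", "arrest", "vent_d1",
                   "dx_group", "los_days")
.site_cols <- c("icu_id", "hosp_class", "annual_volume")

#' Write a registry to CSV files
#'
#' Writes \code{patients.csv} and \code{sites.csv} in the fixed column
#' dialect used throughout the package (\code{male} and, for synthetic
#' data, \code{true_re} travel as trailing extra columns).
#'
#' @param registry An \code{icu_registry}.
#' @param patients_path,sites_path Output paths.
#' @export
write_registry_csv <- function(registry, patients_path, sites_path) {
  stopifnot(inherits(registry, "icu_registry"))
  p <- registry$patients
  extra_p <- intersect("male", names(p))
  utils::write.csv(p[, c(.patient_cols, extra_p)], patients_path,
                   row.names = FALSE)
  s <- registry$sites
  extra_s <- intersect("true_re", names(s))
  utils::write.csv(s[, c(.site_cols, extra_s)], sites_path,
                   row.names = FALSE)
  invisible(c(patients_path, sites_path))
}

#' Read a registry from CSV files
#'
#' Validates the schema, rejects rows with non-positive LOS (with a
#' message giving the count), and retains rows with missing covariates —
#' the model layer drops those complete-case and logs how many.
#'
#' @param patients_path,sites_path Input paths.
#' @return An \code{icu_registry} whose provenance records the source
#'   files.
#' @export
read_registry_csv <- function(patients_path, sites_path) {
  p <- utils::read.csv(patients_path, comment.char = "#")
  s <- utils::read.csv(sites_path, comment.char = "#")
  miss_p <- setdiff(.patient_cols, names(p))
  if (length(miss_p)) stop("patients.csv lacks columns: ",
                           paste(miss_p, collapse = ", "))
  miss_s <- setdiff(.site_cols, names(s))
  if (length(miss_s)) stop("sites.csv lacks columns: ",
                           paste(miss_s, collapse = ", "))
  unknown <- setdiff(names(p), c(.patient_cols, "male"))
  if (length(unknown)) warning("ignoring unknown patient columns: ",
                               paste(unknown, collapse = ", "))
  bad <- !is.na(p$los_days) & p$los_days <= 0 | is.na(p$los_days)
  if (any(bad)) {
    message(sum(bad), " rows rejected: los_days missing or <= 0")
    p <- p[!bad, , drop = FALSE]
  }
  orphan <- setdiff(unique(p$icu_id), s$icu_id)
  if (length(orphan)) stop("patients reference unknown icu_id(s): ",
                           paste(orphan, collapse = ", "))
  structure(list(patients = p, sites = s,
                 provenance = list(source = "csv",
                                   patients = patients_path,
                                   sites = sites_path)),
            class = "icu_registry")
}

#' Write / read a simulation configuration as YAML
#'
#' Round-trippable plain-text serialisation of a
#' \code{\link{sim_config}}; reading rebuilds the configuration (and
#' its derived calibration constants) from the stored arguments.
#'
#' @param config A \code{sim_config}.
#' @param path YAML file path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- list(
    n_icus = config$n_icus,
    class_mix = as.list(config$class_mix),
    volume_model = config$volume_model[
      !vapply(config$volume_model, is.null, logical(1))],
    target_mean = exp(config$mu + config$total_var / 2),
    target_median = exp(config$mu),
    r2_x = config$r2_x, tau2 = config$tau2, sigma2 = config$sigma2,
    beta = as.list(config$beta),
    noise_family = config$noise_family,
    gamma_shape = config$gamma_shape,
    los_truncation_days = config$los_truncation_days,
    missing_rate = config$missing_rate,
    dx_levels = config$dx_levels, seed = config$seed)
  x$volume_model <- lapply(x$volume_model, function(v)
    if (length(names(v))) as.list(v) else v)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  vm <- lapply(x$volume_model, function(v)
    if (is.list(v)) unlist(v) else v)
  sim_config(n_icus = x$n_icus, class_mix = unlist(x$class_mix),
             volume_model = vm, target_mean = x$target_mean,
             target_median = x$target_median, r2_x = x$r2_x,
             tau2 = x$tau2, sigma2 = x$sigma2, beta = unlist(x$beta),
             noise_family = x$noise_family, gamma_shape = x$gamma_shape,
             los_truncation_days = x$los_truncation_days,
             missing_rate = x$missing_rate, dx_levels = x$dx_levels,
             seed = x$seed)
}
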