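# Fixture builders shared across the suite.  Everything is generated in
# code; no stored data.

# small synthetic registry with equal per-site volumes
small_registry <- function(n_icus = 6, volume = 80, seed = 1, ...) {
  generate_registry(sim_config(n_icus = n_icus, seed = seed,
                               volume_model = list(fixed = volume), ...))
}

# hand-built registry from explicit patient/site tables
registry_from_df <- function(patients, sites) {
  structure(list(patients = patients, sites = sites,
                 provenance = list(source = "test")),
            class = "icu_registry")
}

# minimal patient table around given per-ICU LOS vectors
patients_with_los <- function(los_by_icu, male = 1L) {
  do.call(rbind, lapply(seq_along(los_by_icu), function(i) {
    los <- los_by_icu[[i]]
    data.frame(icu_id = i, age = 60, apache3 = 50L, anzrod = 0.02,
               preicu_days = 0.5, male = male, died_icu = 0L, arf = 0L,
               limitation = 0L, arrest = 0L, vent_d1 = 0L, dx_group = 1L,
               los_days = los)
  }))
}

sites_for <- function(patients) {
  tab <- table(patients$icu_id)
  data.frame(icu_id = as.integer(names(tab)), hosp_class = "TER",
             annual_volume = as.integer(tab), true_re = 0)
}

# generating coefficient vector restricted to the reduced term set
reduced_beta <- function(apache3 = 0.012, log_anzrod = 0.15,
                         preicu_days = 0.05, died_icu = -0.5,
                         vent_d1 = 0.45) {
  template <- sim_config(n_icus = 2, seed = 1,
                         volume_model = list(fixed = 10))$beta
  b <- template * 0
  b[c("apache3", "log_anzrod", "preicu_days", "died_icu", "vent_d1")] <-
    c(apache3, log_anzrod, preicu_days, died_icu, vent_d1)
  b
}

# prediction-set object built directly from obs/pred vectors
manual_predictions <- function(icu_id, obs, pred, mode = "FE",
                               scale = "days", model = "glmm") {
  structure(data.frame(icu_id = as.character(icu_id), obs = obs,
                       pred = pred, stringsAsFactors = FALSE),
            mode = mode, scale = scale, model = model,
            class = c("los_predictions", "data.frame"))
}

# intercept-only model specification
intercept_spec <- function(response) {
  structure(list(response = response, fixed_terms = "1",
                 grouping = "icu_id"), class = "los_model_spec")
}

# tie-corrected Kendall tau-b by exhaustive pair enumeration (oracle)
tau_b_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i])
    dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}
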