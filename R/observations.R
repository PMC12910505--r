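# Observation-table schema shared by the simulator and the estimation
# routines: one row per plant x truss x measurement stage.

obs_stages <- c("pollen_count", "viability", "germination",
                "seed", "fruit_mass", "fruit_set")
obs_columns <- c("temperature_C", "duration_d", "block", "plant", "truss",
                 "stage", "value", "denominator")
fraction_stages <- c("viability", "germination", "fruit_set")

#' Validate an observation table
#'
#' Checks the tidy observation schema used throughout the package: columns
#' `temperature_C`, `duration_d`, `block`, `plant`, `truss`, `stage`,
#' `value`, `denominator`; stages limited to `pollen_count`, `viability`,
#' `germination`, `seed`, `fruit_mass`, `fruit_set`; fraction stages in
#' \[0, 1\]; counts non-negative (integrality is not enforced because
#' noise-free simulated tables carry expected values); masses positive.
#' When a design is supplied, every (temperature, duration) pair must
#' belong to its treatment list.
#'
#' @param obs A data.frame in the observation schema.
#' @param design Optional [experiment_design()] object to check treatment
#'   membership against.
#' @return `obs`, invisibly, after passing all checks.
#' @export
validate_observations <- function(obs, design = NULL) {
  stop_if(!is.data.frame(obs), "observations must be a data.frame")
  missing_cols <- setdiff(obs_columns, names(obs))
  stop_if(length(missing_cols) > 0,
          "missing observation columns: ", paste(missing_cols, collapse = ", "))
  bad_stage <- setdiff(unique(obs$stage), obs_stages)
  stop_if(length(bad_stage) > 0,
          "unknown stage(s): ", paste(bad_stage, collapse = ", "))
  stop_if(any(!is.finite(obs$value)), "non-finite observation values")
  frac <- obs$stage %in% fraction_stages
  stop_if(any(obs$value[frac] < 0 | obs$value[frac] > 1),
          "fraction observations must lie in [0, 1]")
  counts <- obs$stage %in% c("pollen_count", "seed")
  stop_if(any(obs$value[counts] < 0), "count observations must be non-negative")
  stop_if(any(obs$value[obs$stage == "fruit_mass"] <= 0),
          "fruit-mass observations must be positive")
  if (!is.null(design)) {
    stopifnot(inherits(design, "experiment_design"))
    key_obs <- paste(obs$temperature_C, obs$duration_d)
    key_design <- paste(design$treatments$temperature_C,
                        design$treatments$duration_d)
    stop_if(!all(key_obs %in% key_design),
            "observations contain (temperature, duration) pairs outside the declared design")
  }
  invisible(obs)
}

#' Read or write an observation table as CSV
#'
#' Plain-CSV round trip for the observation schema; reading validates the
#' table before returning it.
#'
#' @param file Path to a CSV file.
#' @param obs A data.frame in the observation schema (for writing).
#' @return `read_observations()` returns a validated data.frame;
#'   `write_observations()` returns `file` invisibly.
#' @export
read_observations <- function(file) {
  obs <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_observations(obs)
}

#' @rdname read_observations
#' @export
write_observations <- function(obs, file) {
  validate_observations(obs)
  utils::write.csv(obs, file, row.names = FALSE)
  invisible(file)
}

# Mean observed value per treatment (temperature x duration) for one
# stage. Pooling to treatment means before fitting makes every fit
# invariant to row order and to block/plant/truss labels.
treatment_means <- function(obs, stage, pool_duration = FALSE) {
  rows <- obs[obs$stage == stage, , drop = FALSE]
  if (nrow(rows) == 0) return(rows)
  by <- if (pool_duration) list(temperature_C = rows$temperature_C)
        else list(temperature_C = rows$temperature_C,
                  duration_d = rows$duration_d)
  out <- aggregate(rows["value"], by = by, FUN = mean)
  out[order(out$temperature_C), , drop = FALSE]
}
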