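# YAML configuration format: a flat, documented key set for the membrane,
# environment and bath parameters, lossless in both directions.

#' Write a parameter configuration file
#'
#' Serialises a membrane / environment / baths triple to YAML under the
#' documented keys `membrane.Lp`, `membrane.sigma1`, `membrane.sigma2`,
#' `membrane.omega11` ... `membrane.omega22`, `environment.temperature`,
#' `environment.R_gas`, `environment.g`, `environment.nu`,
#' `environment.rho_ref`, `environment.drho_dC1`, `environment.drho_dC2`,
#' `environment.D11` ... `environment.D22`, `baths.C1h`, `baths.C1l`,
#' `baths.C2h`, `baths.C2l`, `baths.dP`.
#'
#' @param membrane A [membrane_coefficients()].
#' @param env A [transport_environment()].
#' @param baths A [bath_state()].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_kkp_config <- function(membrane, env, baths, path) {
  stopifnot(inherits(membrane, "membrane_coefficients"),
            inherits(env, "transport_environment"),
            inherits(baths, "bath_state"))
  cfg <- list(
    membrane = list(
      Lp = membrane$Lp, sigma1 = membrane$sigma1, sigma2 = membrane$sigma2,
      omega11 = membrane$omega[1, 1], omega12 = membrane$omega[1, 2],
      omega21 = membrane$omega[2, 1], omega22 = membrane$omega[2, 2]),
    environment = list(
      temperature = env$temperature, R_gas = env$R_gas, g = env$g,
      nu = env$nu, rho_ref = env$rho_ref,
      drho_dC1 = env$drho_dC1, drho_dC2 = env$drho_dC2,
      D11 = env$D[1, 1], D12 = env$D[1, 2],
      D21 = env$D[2, 1], D22 = env$D[2, 2]),
    baths = list(C1h = baths$C1h, C1l = baths$C1l,
                 C2h = baths$C2h, C2l = baths$C2l, dP = baths$dP))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

kkp_config_error <- function(message) {
  structure(class = c("kkp_config_error", "error", "condition"),
            list(message = message, call = NULL))
}

config_get <- function(cfg, section, key, default = NULL) {
  v <- cfg[[section]][[key]]
  if (is.null(v)) {
    if (!is.null(default)) return(default)
    stop(kkp_config_error(sprintf("missing config key: %s.%s", section, key)))
  }
  v
}

#' Read a parameter configuration file
#'
#' Reads a YAML file written by [write_kkp_config()] (or hand-written with
#' the same keys) and reconstructs the parameter objects. Missing optional
#' environment keys fall back to the [transport_environment()] defaults;
#' missing membrane or bath keys are an error naming the key.
#'
#' @param path File path to read.
#' @return A list with elements `membrane`, `environment`, `baths`.
#' @export
read_kkp_config <- function(path) {
  if (!file.exists(path))
    stop(kkp_config_error(paste("config file not found:", path)))
  cfg <- yaml::read_yaml(path)
  for (section in c("membrane", "baths"))
    if (is.null(cfg[[section]]))
      stop(kkp_config_error(paste0("missing config section: ", section)))
  na_or <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  envsec <- cfg$environment
  list(
    membrane = membrane_coefficients(
      Lp = config_get(cfg, "membrane", "Lp"),
      sigma1 = config_get(cfg, "membrane", "sigma1"),
      sigma2 = config_get(cfg, "membrane", "sigma2"),
      omega11 = config_get(cfg, "membrane", "omega11"),
      omega12 = config_get(cfg, "membrane", "omega12"),
      omega21 = config_get(cfg, "membrane", "omega21"),
      omega22 = config_get(cfg, "membrane", "omega22")),
    environment = transport_environment(
      temperature = config_get(cfg, "environment", "temperature",
                               default = 298.15),
      R_gas = config_get(cfg, "environment", "R_gas", default = 8.314),
      g = config_get(cfg, "environment", "g", default = 9.81),
      nu = na_or(envsec$nu), rho_ref = na_or(envsec$rho_ref),
      drho_dC1 = na_or(envsec$drho_dC1), drho_dC2 = na_or(envsec$drho_dC2),
      D = matrix(c(na_or(envsec$D11), na_or(envsec$D12),
                   na_or(envsec$D21), na_or(envsec$D22)),
                 2L, 2L, byrow = TRUE)),
    baths = bath_state(
      C1h = config_get(cfg, "baths", "C1h"),
      C1l = config_get(cfg, "baths", "C1l"),
      C2h = config_get(cfg, "baths", "C2h"),
      C2l = config_get(cfg, "baths", "C2l"),
      dP = config_get(cfg, "baths", "dP", default = 0)))
}
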