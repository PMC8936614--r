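#' Trial-level regression specification for the hierarchical DDM
#'
#' Declares which per-trial covariates enter each decision parameter.
#' Available covariates: `"1"` (intercept), `"r2"` (velocity-reconstruction
#' accuracy), `"r2_s"` (coupling times stimulus difference, the drift
#' linkage), `"s"`, `"v_m"`, `"n_cr"`, `"t_low"`. Single-trial parameters
#' are linear combinations, e.g. with the default (best-fitting) layout:
#' drift `= gamma0 + gamma1 * r2 * s`, nondecision time
#' `= beta0 + beta_sw * n_cr + beta_exp * t_low`, boundary `= alpha`.
#'
#' @param drift,ndt,boundary Character vectors of covariate names; each
#'   must start with or include `"1"`.
#' @param name Optional model label.
#' @return A `ddm_spec` object with canonical coefficient names.
#' @export
ddm_spec <- function(drift = c("1", "r2_s"),
                     ndt = c("1", "n_cr", "t_low"),
                     boundary = "1",
                     name = NULL) {
  allowed <- c("1", "r2", "r2_s", "s", "v_m", "n_cr", "t_low")
  blocks <- list(drift = drift, ndt = ndt, boundary = boundary)
  for (b in names(blocks)) {
    bad <- setdiff(blocks[[b]], allowed)
    if (length(bad))
      stop("unknown covariate(s) for ", b, ": ", paste(bad, collapse = ", "))
    if (anyDuplicated(blocks[[b]]))
      stop("duplicate covariates in ", b, " make the model non-identifiable")
    if (!"1" %in% blocks[[b]])
      stop(b, " must include an intercept (\"1\")")
  }
  coefs <- c(vapply(blocks$drift, coef_name, "", target = "drift"),
             vapply(blocks$ndt, coef_name, "", target = "ndt"),
             vapply(blocks$boundary, coef_name, "", target = "boundary"))
  structure(list(drift = drift, ndt = ndt, boundary = boundary,
                 coef_names = unname(coefs),
                 blocks = c(rep("drift", length(drift)),
                            rep("ndt", length(ndt)),
                            rep("boundary", length(boundary))),
                 covariates = c(drift, ndt, boundary),
                 name = name %||% "model"),
            class = "ddm_spec")
}

# canonical coefficient symbols
coef_name <- function(cov, target) {
  map <- list(
    drift = c("1" = "gamma0", "r2_s" = "gamma1", "r2" = "gamma_r2",
              "s" = "gamma_s", "v_m" = "gamma_v", "n_cr" = "gamma_sw",
              "t_low" = "gamma_exp"),
    ndt = c("1" = "beta0", "r2" = "beta1", "r2_s" = "beta_r2s",
            "s" = "beta_s", "v_m" = "beta_v", "n_cr" = "beta_sw",
            "t_low" = "beta_exp"),
    boundary = c("1" = "alpha", "r2" = "theta1", "r2_s" = "theta_r2s",
                 "s" = "theta_s", "v_m" = "theta_v", "n_cr" = "theta_sw",
                 "t_low" = "theta_exp"))
  map[[target]][[cov]]
}

# per-trial covariate column
covariate_column <- function(table, cov) {
  switch(cov,
         "1" = rep(1, nrow(table)),
         "r2_s" = table$r2 * table$s,
         {
           if (!cov %in% names(table))
             stop("covariate '", cov, "' not present in behaviour table")
           table[[cov]]
         })
}

# design matrix for one block of one cell
block_design <- function(table, covs) {
  X <- vapply(covs, function(cv) covariate_column(table, cv),
              numeric(nrow(table)))
  matrix(X, nrow = nrow(table))
}

# prior box per coefficient: weakly informative boxes covering plausible
# parameter magnitudes with wide margins
coef_bounds <- function(spec, min_rt) {
  lo <- numeric(length(spec$coef_names))
  hi <- numeric(length(spec$coef_names))
  for (j in seq_along(spec$coef_names)) {
    b <- spec$blocks[j]; cv <- spec$covariates[j]
    if (b == "drift") { lo[j] <- -20; hi[j] <- 20 }
    else if (b == "ndt" && cv == "1") { lo[j] <- 0.05; hi[j] <- min_rt }
    else if (b == "ndt") { lo[j] <- -10; hi[j] <- 10 }
    else if (b == "boundary" && cv == "1") { lo[j] <- 0.1; hi[j] <- 10 }
    else { lo[j] <- -10; hi[j] <- 10 }
  }
  list(lower = lo, upper = hi)
}

#' Candidate model set for DIC comparison
#'
#' The seven regressor assignments compared when asking which decision
#' parameters the neural coupling and the movement parameters act on: the
#' neural coupling (`r2`, entering the drift as `r2 * s`, other parameters
#' as plain `r2`) and the movement parameters (`n_cr`, `t_low`) are each
#' assigned to one of drift, nondecision time or boundary, plus a
#' no-regressor null. Alternates are reassignments of matched complexity,
#' so the comparison asks *where* the trial-level information acts, not
#' merely whether extra coefficients help. The first entry is the expected
#' best model (coupling on drift; crossings and exploration time on
#' nondecision time).
#'
#' @return Named list of [ddm_spec()] objects.
#' @export
candidate_models <- function() {
  list(
    m1_drift_r2_ndt_kin = ddm_spec(c("1", "r2_s"), c("1", "n_cr", "t_low"),
                                   "1", name = "m1_drift_r2_ndt_kin"),
    m2_ndt_r2_ndt_kin = ddm_spec("1", c("1", "r2", "n_cr", "t_low"), "1",
                                 name = "m2_ndt_r2_ndt_kin"),
    m3_bound_r2_ndt_kin = ddm_spec("1", c("1", "n_cr", "t_low"),
                                   c("1", "r2"),
                                   name = "m3_bound_r2_ndt_kin"),
    m4_drift_r2_drift_kin = ddm_spec(c("1", "r2_s", "n_cr", "t_low"), "1",
                                     "1", name = "m4_drift_r2_drift_kin"),
    m5_drift_r2_bound_kin = ddm_spec(c("1", "r2_s"), "1",
                                     c("1", "n_cr", "t_low"),
                                     name = "m5_drift_r2_bound_kin"),
    m6_ndt_r2_drift_kin = ddm_spec(c("1", "n_cr", "t_low"), c("1", "r2"),
                                   "1", name = "m6_ndt_r2_drift_kin"),
    m7_null = ddm_spec("1", "1", "1", name = "m7_null"))
}
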