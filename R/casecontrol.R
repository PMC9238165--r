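# Consistency checks of a fitted penetrance model against unrelated
# case-control carriers of the variant: likelihood of the carrier
# observations under the fitted model versus the null model (no variant
# effect), compared by AIC/BIC, plus Welch tests of onset anticipation
# between APOE strata.

.norm_status <- function(status) {
  s <- tolower(as.character(status))
  out <- ifelse(s %in% c("case", "1", "affected"), 1,
                ifelse(s %in% c("control", "0", "unaffected"), 0, NA))
  if (anyNA(out)) stop("status must be case/control (or 1/0)")
  out
}

#' Log-likelihood of unrelated carriers under a penetrance model
#'
#' Every record is a known carrier of the variant.  A case with onset age T
#' contributes \code{log S(T) + log lambda(T)}; a control examined at age T
#' contributes \code{log S(T)} -- both for the carrier curve of the record's
#' APOE-e4 dose.  Ages above the support cap are censored at the cap (a case
#' older than the cap contributes survival only); ages below the support start
#' are an error listing the offending records.
#'
#' @param model a \code{\link{hazard_model}}.
#' @param carriers data frame with columns \code{status} (case/control or
#'   1/0), \code{age} (onset for cases, age at last examination for controls)
#'   and \code{apoe_dose} (0/1/2).
#' @return total log-likelihood (additive over records, order-invariant).
#' @export
carrier_loglik <- function(model, carriers) {
  status <- .norm_status(carriers$status)
  age <- as.numeric(carriers$age)
  dose <- as.integer(carriers$apoe_dose)
  if (any(!dose %in% 0:2)) stop("apoe_dose must be 0, 1 or 2")
  low <- which(age < model$support[1])
  if (length(low)) {
    stop("record(s) below the model support start: ",
         paste(low, collapse = ", "))
  }
  cap <- model$support[2]
  delta <- ifelse(status == 1 & age <= cap, 1, 0)
  T_obs <- pmin(age, cap)
  ll <- 0
  for (i in seq_along(age)) {
    ll <- ll + log(surv_prob(model, T_obs[i], dose[i], carrier = TRUE))
    if (delta[i] == 1) {
      ll <- ll + log(hazard_at(model, T_obs[i], dose[i], carrier = TRUE))
    }
  }
  unname(ll)
}

#' Compare the fitted model with the no-effect null on unrelated carriers
#'
#' The null model sets beta(t) = 0 everywhere (carriers follow the APOE-only
#' baseline).  \code{AIC = 2k - 2 loglik}; \code{BIC = k log(n) - 2 loglik}
#' with n the carrier count; the null has k = 0 so its AIC and BIC coincide.
#'
#' @param model the fitted \code{\link{hazard_model}}.
#' @param carriers see \code{\link{carrier_loglik}}.
#' @param k_model number of fitted parameters (the number of beta values).
#' @return data frame with one row per model: loglik, k, AIC, BIC, n.
#' @export
compare_models <- function(model, carriers,
                           k_model = length(model$beta$values)) {
  n <- nrow(carriers)
  null_model <- hazard_model(model$baseline,
                             beta_function(model$beta$cutoffs,
                                           rep(0, length(model$beta$values))))
  ll1 <- carrier_loglik(model, carriers)
  ll0 <- carrier_loglik(null_model, carriers)
  data.frame(
    model = c("fitted", "null"),
    loglik = c(ll1, ll0),
    k = c(k_model, 0),
    AIC = c(information_criteria(ll1, k_model, n)["AIC"],
            information_criteria(ll0, 0, n)["AIC"]),
    BIC = c(information_criteria(ll1, k_model, n)["BIC"],
            information_criteria(ll0, 0, n)["BIC"]),
    n = n
  )
}

#' AIC and BIC from a log-likelihood
#'
#' @param loglik log-likelihood.
#' @param k number of free parameters.
#' @param n number of observations (records).
#' @return named vector with \code{AIC = 2k - 2 loglik} and
#'   \code{BIC = k log(n) - 2 loglik}.
#' @export
information_criteria <- function(loglik, k, n) {
  loglik <- unname(loglik)
  c(AIC = 2 * k - 2 * loglik, BIC = k * log(n) - 2 * loglik)
}

#' Welch test of onset anticipation between APOE strata
#'
#' Compares ages at onset of carrier cases between two APOE-e4 dose groups
#' with Welch's unequal-variance t statistics (Satterthwaite degrees of
#' freedom).  Anticipation is reported as
#' \code{mean AAO(reference) - mean AAO(alternative)}: positive when the
#' higher-risk group develops the disease earlier.
#'
#' @param cases data frame of carrier cases with columns \code{age} (onset)
#'   and \code{apoe_dose}.
#' @param dose_ref reference e4 dose (e.g. 0).
#' @param dose_alt alternative e4 dose (e.g. 1 or 2).
#' @return list with \code{anticipation} (years), \code{conf_int} (95%),
#'   \code{p_value}, \code{df}, and the group means and sizes.
#' @export
welch_anticipation <- function(cases, dose_ref, dose_alt) {
  x <- cases$age[cases$apoe_dose == dose_ref]
  y <- cases$age[cases$apoe_dose == dose_alt]
  if (length(x) < 2 || length(y) < 2) {
    stop("each dose group needs at least 2 cases")
  }
  if (stats::var(x) + stats::var(y) == 0) {
    d <- mean(x) - mean(y)
    return(list(
      anticipation = d, conf_int = c(d, d),
      p_value = if (d == 0) 1 else 0, df = NA_real_,
      mean_ref = mean(x), mean_alt = mean(y),
      n_ref = length(x), n_alt = length(y)
    ))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(
    anticipation = unname(mean(x) - mean(y)),
    conf_int = as.numeric(tt$conf.int),
    p_value = tt$p.value,
    df = unname(tt$parameter),
    mean_ref = mean(x), mean_alt = mean(y),
    n_ref = length(x), n_alt = length(y)
  )
}
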