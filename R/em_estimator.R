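# EM estimation of the piecewise-constant variant effect beta(t).
#
# E-step: exact posterior genotype weights w_i(a,s) by belief propagation,
# with evidence = phenotype likelihood (survival x hazard at the observed age,
# per effect class) times the genotype compatibility mask.  M-step: closed
# form -- exp(beta_j) is the ratio of posterior-weighted carrier events in age
# interval j to posterior-weighted carrier baseline exposure in j.
# Ascertainment is corrected by omitting proband phenotypes: their genotypes
# stay hard evidence (they anchor the carrier side of the family) but their
# phenotype enters neither the E-step evidence nor the M-step sums.

#' EM configuration
#'
#' @param tolerance convergence threshold on max |change in beta_j|.
#' @param max_iterations EM iteration cap; non-convergence is flagged on the
#'   result, not an error.
#' @param proband_mode \code{"exclude"} (default: proband phenotype omitted
#'   from both the E-step evidence and the M-step sums -- the ascertainment
#'   correction), \code{"mstep_only"} (phenotype used as E-step evidence but
#'   excluded from the M-step sums), or \code{"include"} (no correction; used
#'   to quantify ascertainment bias in simulations).  Proband genotypes are
#'   hard evidence in every mode.
#' @param min_age informativeness floor in years: members with onset or
#'   censoring below it contribute structure only.
#' @param cap_age censoring cap in years; members older (or with onset later)
#'   are censored at the cap.
#' @return a list of class \code{em_config}.
#' @export
em_config <- function(tolerance = 1e-6, max_iterations = 500,
                      proband_mode = c("exclude", "mstep_only", "include"),
                      min_age = 40, cap_age = 85) {
  proband_mode <- match.arg(proband_mode)
  stopifnot(tolerance > 0, max_iterations >= 1, min_age >= 0,
            cap_age > min_age)
  structure(
    list(tolerance = tolerance, max_iterations = max_iterations,
         proband_mode = proband_mode, min_age = min_age, cap_age = cap_age),
    class = "em_config"
  )
}

# Precompute everything that does not change across EM iterations.
prepare_em_data <- function(peds, baseline, cutoffs, config) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  sup <- baseline$support
  min_age <- max(config$min_age, sup[1])
  cap <- min(config$cap_age, sup[2])
  if (length(cutoffs) && (any(cutoffs <= min_age) || any(cutoffs >= cap))) {
    stop("cutoffs must lie strictly between ", min_age, " and ", cap)
  }
  J <- length(cutoffs) + 1L
  cls <- effect_classes()
  lapply(peds, function(ped) {
    n <- nrow(ped)
    mask <- t(vapply(seq_len(n), function(i) {
      compatibility_mask(ped$apoe[i], ped$sorl1[i])
    }, numeric(36)))
    contrib <- !is.na(ped$status) & !is.na(ped$age) & ped$age >= min_age
    T_obs <- pmin(ped$age, cap)
    delta <- ifelse(!is.na(ped$status) & ped$status == 1 & ped$age <= cap, 1, 0)
    jT <- findInterval(T_obs, cutoffs) + 1L
    Tv <- ifelse(contrib, T_obs, sup[1]) # dummy ages for structure-only rows
    br <- baseline$breaks
    tau <- c(sup[1], cutoffs, min(cap, sup[2]))
    kT <- pmin(pmax(findInterval(Tv, br), 1L), nrow(baseline$hazard))
    lamnc <- matrix(0, n, 3)
    Lamnc <- matrix(0, n, 3)
    expo <- lapply(1:3, function(d) matrix(0, n, J))
    for (d in 1:3) {
      lam <- baseline$hazard[, d]
      cum <- c(0, cumsum(lam * diff(br)))
      Lam <- function(t) .cum_lookup(br, cum, lam, pmin(pmax(t, br[1]), cap))
      lamnc[, d] <- lam[kT] * contrib
      for (j in seq_len(J)) {
        e <- pmax(0, Lam(pmin(Tv, tau[j + 1])) - Lam(tau[j]))
        expo[[d]][, j] <- e * contrib
      }
      Lamnc[, d] <- rowSums(expo[[d]])
    }
    list(
      ped = ped, n = n, mask = mask, contrib = contrib,
      proband = ped$proband, T_obs = T_obs, delta = delta, jT = jT,
      lamnc = lamnc, Lamnc = Lamnc, expo = expo
    )
  })
}

# class evidence matrix (n x 6) for one prepared family under beta values
.class_evidence_matrix <- function(fp, beta_values) {
  n <- fp$n
  eb <- exp(beta_values)
  ev6 <- matrix(1, n, 6)
  for (d in 1:3) {
    Snc <- exp(-fp$Lamnc[, d])
    expo_eb <- as.vector(fp$expo[[d]] %*% eb)
    Sca <- exp(-expo_eb)
    hz_nc <- ifelse(fp$delta == 1, fp$lamnc[, d], 1)
    hz_ca <- ifelse(fp$delta == 1, fp$lamnc[, d] * eb[fp$jT], 1)
    ev6[, 2 * d - 1] <- Snc * hz_nc
    ev6[, 2 * d] <- Sca * hz_ca
  }
  ev6
}

# E-step over all families: posteriors + observed-data log-likelihood
.estep <- function(prep, beta_values, prior, proband_mode) {
  cls_of_state <- state_class()
  loglik <- 0
  posteriors <- vector("list", length(prep))
  for (f in seq_along(prep)) {
    fp <- prep[[f]]
    ev <- fp$mask
    use_pheno <- fp$contrib & !(fp$proband & proband_mode == "exclude")
    if (any(use_pheno)) {
      ev6 <- .class_evidence_matrix(fp, beta_values)
      ev36 <- ev6[, cls_of_state, drop = FALSE]
      ev[use_pheno, ] <- ev[use_pheno, , drop = FALSE] *
        ev36[use_pheno, , drop = FALSE]
    }
    r <- propagate_pedigree(fp$ped, prior, ev)
    posteriors[[f]] <- r$posterior
    loglik <- loglik + r$loglik
  }
  names(posteriors) <- names(prep)
  list(posteriors = posteriors, loglik = loglik)
}

# carrier posterior mass per dose (n x 3) for one family
.carrier_weights <- function(post) {
  carrier <- state_carrier()
  dose <- state_dose()
  matrix(vapply(0:2, function(d) {
    sel <- carrier & dose == d
    rowSums(post[, sel, drop = FALSE])
  }, numeric(nrow(post))), nrow(post), 3)
}

# closed-form M-step on prepared data; returns beta values, events, exposure
.m_step_prep <- function(prep, posteriors, J, include_probands) {
  num <- numeric(J)
  den <- numeric(J)
  for (f in seq_along(prep)) {
    fp <- prep[[f]]
    use <- fp$contrib & (include_probands | !fp$proband)
    if (!any(use)) next
    wc <- .carrier_weights(posteriors[[f]]) # n x 3
    for (i in which(use)) {
      wci <- wc[i, ]
      if (fp$delta[i] == 1) num[fp$jT[i]] <- num[fp$jT[i]] + sum(wci)
      for (d in 1:3) {
        if (wci[d] > 0) den <- den + wci[d] * fp$expo[[d]][i, ]
      }
    }
  }
  if (any(den <= 0)) {
    stop("zero carrier exposure in beta interval ",
         which(den <= 0)[1], "; use coarser cutoffs")
  }
  list(values = log(num / den), events = num, exposure = den,
       zero_events = num == 0)
}

#' Closed-form M-step
#'
#' Given posterior genotype weights, the maximizer of the expected complete
#' log-likelihood is, per age interval j,
#' \code{beta_j = log(weighted events_j / weighted exposure_j)} where events
#' are posterior carrier masses of affected members with onset in interval j
#' and the exposure is the posterior-weighted increment of the non-carrier
#' baseline cumulative hazard over interval j.  Probands and members with
#' missing phenotype contribute to neither sum.
#'
#' @param posteriors list of n x 36 posterior matrices, one per pedigree
#'   (\code{\link{propagate_pedigree}} output order).
#' @param peds pedigree or list of pedigrees matching \code{posteriors}.
#' @param baseline a \code{\link{baseline_hazard}}.
#' @param cutoffs beta interval cutoffs (years), strictly increasing.
#' @param exclude_probands drop probands from the sums (default TRUE).
#' @param config an \code{\link{em_config}} (for min/cap age).
#' @return a list: \code{beta} (a \code{\link{beta_function}}),
#'   \code{events}, \code{exposure}, and \code{zero_events} flags (a flagged
#'   interval had no carrier events; its beta is -Inf and should be read as
#'   "no information", not a number).
#' @export
m_step <- function(posteriors, peds, baseline, cutoffs,
                   exclude_probands = TRUE, config = em_config()) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  if (length(posteriors) != length(peds)) {
    stop("posteriors and peds must have the same length")
  }
  prep <- prepare_em_data(peds, baseline, cutoffs, config)
  r <- .m_step_prep(prep, posteriors, length(cutoffs) + 1L, !exclude_probands)
  list(beta = beta_function(cutoffs, r$values), events = r$events,
       exposure = r$exposure, zero_events = r$zero_events)
}

#' Fit the penetrance model by EM
#'
#' Alternates belief propagation (E-step) and the closed-form M-step until the
#' largest change in any beta_j falls below \code{config$tolerance}.  The
#' observed-data log-likelihood is recorded at every iteration and is
#' guaranteed nondecreasing.  With no missing genotypes the EM collapses to a
#' single M-step.
#'
#' @param peds pedigree or list of pedigrees.
#' @param baseline a \code{\link{baseline_hazard}} (non-carrier risk per
#'   APOE-e4 stratum).
#' @param cutoffs beta interval cutoffs (years); may be empty for a constant
#'   effect.
#' @param prior founder prior over the 36 states (see
#'   \code{\link{founder_prior}}).
#' @param config an \code{\link{em_config}}.
#' @return an object of class \code{pedpen_fit}: \code{beta}
#'   (\code{\link{beta_function}}), \code{events}/\code{exposure} per
#'   interval, \code{posteriors} (per family), \code{loglik},
#'   \code{loglik_trace}, \code{n_contributing} (phenotype-informative
#'   non-probands), \code{expected_carrier_count} (posterior carrier mass
#'   summed over informative non-probands), \code{converged},
#'   \code{zero_events}, \code{model} (the fitted \code{\link{hazard_model}}),
#'   plus the inputs needed to refit.
#' @export
fit_penetrance <- function(peds, baseline, cutoffs,
                           prior = founder_prior(c(0.08, 0.78, 0.14), 1e-4),
                           config = em_config()) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  J <- length(cutoffs) + 1L
  prep <- prepare_em_data(peds, baseline, cutoffs, config)
  include_probands <- config$proband_mode == "include"
  beta <- rep(0, J)
  trace <- numeric(0)
  converged <- FALSE
  mres <- NULL
  es <- NULL
  for (it in seq_len(config$max_iterations)) {
    es <- .estep(prep, beta, prior, config$proband_mode)
    trace <- c(trace, es$loglik)
    mres <- .m_step_prep(prep, es$posteriors, J, include_probands)
    dlt <- ifelse(mres$values == beta, 0, abs(mres$values - beta))
    beta <- mres$values
    if (max(dlt) < config$tolerance) {
      converged <- TRUE
      break
    }
    # a near-empty interval can let beta_j drift slowly toward -Inf while
    # the observed-data likelihood has flattened; a likelihood plateau is
    # convergence in every quantity the fit reports
    if (it >= 2 && abs(trace[it] - trace[it - 1]) <
          1e-8 * (1 + abs(trace[it]))) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("EM did not converge in ", config$max_iterations, " iterations")
  }
  # final E-step quantities under the converged beta
  es <- .estep(prep, beta, prior, config$proband_mode)
  trace <- c(trace, es$loglik)
  informative <- lapply(prep, function(fp) fp$contrib & !fp$proband)
  ecc <- 0
  for (f in seq_along(prep)) {
    sel <- informative[[f]]
    if (any(sel)) {
      ecc <- ecc + sum(.carrier_weights(
        es$posteriors[[f]][sel, , drop = FALSE]
      ))
    }
  }
  bf <- beta_function(cutoffs, beta)
  structure(
    list(
      beta = bf, events = mres$events, exposure = mres$exposure,
      zero_events = mres$zero_events,
      posteriors = es$posteriors, loglik = es$loglik, loglik_trace = trace,
      n_contributing = sum(vapply(informative, sum, numeric(1))),
      expected_carrier_count = ecc,
      converged = converged, n_iterations = length(trace) - 1L,
      model = hazard_model(baseline, bf),
      peds = peds, baseline = baseline, cutoffs = cutoffs,
      prior = prior, config = config
    ),
    class = "pedpen_fit"
  )
}

#' @export
print.pedpen_fit <- function(x, ...) {
  tau <- c(x$config$min_age, x$beta$cutoffs, Inf)
  cat("Piecewise-constant variant effect fitted by EM on ",
      length(x$peds), " pedigree(s)\n", sep = "")
  for (j in seq_along(x$beta$values)) {
    cat(sprintf("  beta [%g, %g): %8.3f  (events %.2f, exposure %.4f)\n",
                tau[j], tau[j + 1], x$beta$values[j], x$events[j],
                x$exposure[j]))
  }
  cat("log-likelihood ", format(x$loglik), "; ",
      x$n_iterations, " EM iteration(s); ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  cat("expected carriers among informative non-probands: ",
      round(x$expected_carrier_count, 1), " of ", x$n_contributing, "\n",
      sep = "")
  invisible(x)
}

#' Select beta cutoffs by BIC
#'
#' Fits every candidate cutoff vector and returns the one minimizing
#' \code{BIC = -2 loglik + J log(N)}, with N the number of
#' phenotype-contributing (informative, non-proband) individuals -- the units
#' entering the M-step.  Ties break toward fewer intervals, then
#' lexicographically smaller cutoffs.
#'
#' @inheritParams fit_penetrance
#' @param candidates list of numeric cutoff vectors (use \code{numeric(0)} for
#'   a constant effect).
#' @return a list with \code{cutoffs}, \code{fit} (the winning
#'   \code{pedpen_fit}) and \code{table} (candidate, J, loglik, bic).
#' @export
select_cutoffs_bic <- function(peds, baseline, candidates,
                               prior = founder_prior(c(0.08, 0.78, 0.14), 1e-4),
                               config = em_config()) {
  if (!length(candidates)) stop("need at least one candidate")
  fits <- vector("list", length(candidates))
  rows <- vector("list", length(candidates))
  for (k in seq_along(candidates)) {
    fits[[k]] <- tryCatch(
      fit_penetrance(peds, baseline, candidates[[k]], prior, config),
      error = function(e) e
    )
    if (inherits(fits[[k]], "error")) {
      rows[[k]] <- data.frame(candidate = paste(candidates[[k]], collapse = ","),
                              J = length(candidates[[k]]) + 1L,
                              loglik = NA_real_, bic = NA_real_)
      next
    }
    f <- fits[[k]]
    J <- length(f$beta$values)
    bic <- -2 * f$loglik + J * log(max(f$n_contributing, 1))
    rows[[k]] <- data.frame(candidate = paste(candidates[[k]], collapse = ","),
                            J = J, loglik = f$loglik, bic = bic)
  }
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$bic))) stop("every candidate cutoff set was degenerate")
  ord <- order(tab$bic, tab$J, tab$candidate)
  best <- ord[1]
  list(cutoffs = candidates[[best]], fit = fits[[best]], table = tab)
}

#' Penetrance table across ages and effect classes
#'
#' Carrier columns use the fitted beta; non-carrier columns are the baseline's
#' own penetrance.  Each column is nondecreasing in age.
#'
#' @param fit a \code{pedpen_fit}.
#' @param ages ages (years) inside the baseline support.
#' @return data frame: \code{age} plus one column per effect class label.
#' @export
penetrance_table <- function(fit, ages) {
  cls <- effect_classes()
  out <- data.frame(age = ages)
  for (k in seq_len(6)) {
    out[[cls$label[k]]] <- penetrance(fit$model, ages, cls$e4_dose[k],
                                      cls$carrier[k])
  }
  out
}
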