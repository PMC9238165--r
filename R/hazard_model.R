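# Piecewise-constant proportional-hazard model:
#   lambda(t | a, s) = lambda_nc(t | a) * exp(beta(t) * 1{s = carrier})
# lambda_nc is the non-carrier baseline, one stratum per APOE-e4 dose (0/1/2),
# piecewise constant on an age grid; beta(t) is piecewise constant on J
# intervals with cutoffs tau_1 < ... < tau_{J-1}.  Survival is piecewise
# exponential, so cumulative hazards are exact sums of rectangle areas.

#' Construct a piecewise-constant baseline hazard
#'
#' @param breaks increasing age grid (length K+1); the support is
#'   \code{[breaks[1], breaks[K+1]]}.
#' @param hazard K x 3 matrix of instantaneous risks per year, one column per
#'   APOE-e4 dose stratum (0, 1, 2 alleles).
#' @return an object of class \code{baseline_hazard}.
#' @export
baseline_hazard <- function(breaks, hazard) {
  breaks <- as.numeric(breaks)
  hazard <- as.matrix(hazard)
  if (length(breaks) < 2 || any(diff(breaks) <= 0)) {
    stop("breaks must be strictly increasing with length >= 2")
  }
  if (nrow(hazard) != length(breaks) - 1 || ncol(hazard) != 3) {
    stop("hazard must be a (length(breaks) - 1) x 3 matrix")
  }
  if (any(!is.finite(hazard)) || any(hazard < 0)) {
    stop("hazards must be finite and >= 0")
  }
  dimnames(hazard) <- NULL
  names(breaks) <- NULL
  structure(
    list(breaks = breaks, hazard = hazard,
         support = c(breaks[1], breaks[length(breaks)])),
    class = "baseline_hazard"
  )
}

#' @export
print.baseline_hazard <- function(x, ...) {
  cat("Piecewise-constant baseline hazard on [",
      x$support[1], ", ", x$support[2], "], ",
      nrow(x$hazard), " pieces x 3 APOE-e4 strata\n", sep = "")
  invisible(x)
}

#' Convert a cumulative-incidence table to a piecewise-constant hazard
#'
#' On each grid interval, the constant hazard reproducing cumulative incidence
#' F at the interval ends is
#' \code{(log(1 - F(t_{k-1})) - log(1 - F(t_k))) / (t_k - t_{k-1})};
#' reconstructing penetrance from the result returns the input exactly at the
#' grid ages.  Incidence is taken as 0 at the support start.
#'
#' @param table data frame with columns \code{stratum} (0/1/2 e4 dose),
#'   \code{age_start}, \code{age_end}, \code{cumulative_incidence} (value of F
#'   at \code{age_end}); all three strata must share the same age grid.
#' @return a \code{\link{baseline_hazard}}.
#' @export
baseline_from_incidence <- function(table) {
  need <- c("stratum", "age_start", "age_end", "cumulative_incidence")
  if (!all(need %in% names(table))) {
    stop("table needs columns: ", paste(need, collapse = ", "))
  }
  strata <- sort(unique(table$stratum))
  if (!identical(as.numeric(strata), c(0, 1, 2))) {
    stop("table must contain strata 0, 1 and 2")
  }
  table <- table[order(table$stratum, table$age_start), ]
  pieces <- split(table, table$stratum)
  grid0 <- pieces[[1]][, c("age_start", "age_end")]
  haz <- matrix(NA_real_, nrow(grid0), 3)
  for (d in 1:3) {
    p <- pieces[[d]][order(pieces[[d]]$age_start), ]
    if (!isTRUE(all.equal(p$age_start, grid0$age_start)) ||
        !isTRUE(all.equal(p$age_end, grid0$age_end))) {
      stop("all strata must share the same age grid")
    }
    if (any(p$age_start[-1] != p$age_end[-nrow(p)])) {
      stop("age intervals must be contiguous")
    }
    f <- p$cumulative_incidence
    f_prev <- c(0, f[-length(f)])
    if (any(f >= 1) || any(f < f_prev)) {
      stop("cumulative incidence must be nondecreasing and < 1")
    }
    haz[, d] <- (log(1 - f_prev) - log(1 - f)) / (p$age_end - p$age_start)
  }
  baseline_hazard(c(grid0$age_start[1], grid0$age_end), haz)
}

#' Read a baseline table from CSV
#'
#' Columns: \code{stratum} (0/1/2), \code{age_start}, \code{age_end}, and
#' either \code{hazard} (instantaneous risk per year, used directly) or
#' \code{cumulative_incidence} (converted via
#' \code{\link{baseline_from_incidence}}); the column name present selects the
#' interpretation.
#'
#' @param path CSV file path.
#' @return a \code{\link{baseline_hazard}}.
#' @export
read_baseline <- function(path) {
  df <- utils::read.csv(path)
  if ("hazard" %in% names(df)) {
    df <- df[order(df$stratum, df$age_start), ]
    pieces <- split(df, df$stratum)
    grid0 <- pieces[[1]][, c("age_start", "age_end")]
    haz <- vapply(pieces, function(p) p$hazard, numeric(nrow(grid0)))
    baseline_hazard(c(grid0$age_start[1], grid0$age_end), haz)
  } else if ("cumulative_incidence" %in% names(df)) {
    baseline_from_incidence(df)
  } else {
    stop("baseline file needs a 'hazard' or 'cumulative_incidence' column")
  }
}

#' Piecewise-constant log-hazard-ratio function beta(t)
#'
#' @param cutoffs strictly increasing interval boundaries tau_1..tau_{J-1}
#'   (years); may be empty for a constant effect.
#' @param values beta_1..beta_J, log hazard ratios; \code{beta(t) = values[j]}
#'   for t in \code{[tau_{j-1}, tau_j)} with tau_0 the support start and tau_J
#'   unbounded.
#' @return an object of class \code{beta_function}.
#' @export
beta_function <- function(cutoffs, values) {
  cutoffs <- as.numeric(cutoffs)
  values <- as.numeric(values)
  if (length(values) != length(cutoffs) + 1) {
    stop("need length(values) == length(cutoffs) + 1")
  }
  if (length(cutoffs) && any(diff(cutoffs) <= 0)) {
    stop("cutoffs must be strictly increasing")
  }
  structure(list(cutoffs = cutoffs, values = values), class = "beta_function")
}

#' Evaluate beta(t)
#' @param beta a \code{\link{beta_function}}.
#' @param t ages (vectorized).  An age equal to a cutoff belongs to the
#'   right-hand interval.
#' @return numeric vector of log hazard ratios.
#' @export
beta_at <- function(beta, t) {
  beta$values[findInterval(t, beta$cutoffs) + 1L]
}

#' Combine baseline and variant effect into a hazard model
#'
#' @param baseline a \code{\link{baseline_hazard}}.
#' @param beta a \code{\link{beta_function}} (cutoffs inside the baseline
#'   support).
#' @return an object of class \code{hazard_model} with precomputed refined
#'   grids so that cumulative hazards are O(log K) lookups.
#' @export
hazard_model <- function(baseline, beta) {
  stopifnot(inherits(baseline, "baseline_hazard"), inherits(beta, "beta_function"))
  sup <- baseline$support
  if (length(beta$cutoffs) &&
      (any(beta$cutoffs <= sup[1]) || any(beta$cutoffs >= sup[2]))) {
    stop("beta cutoffs must lie strictly inside the baseline support")
  }
  br <- sort(unique(c(baseline$breaks, beta$cutoffs)))
  k_bl <- findInterval(br[-length(br)], baseline$breaks,
                       rightmost.closed = TRUE)
  lam <- baseline$hazard[k_bl, , drop = FALSE] # refined pieces x 3 doses
  bj <- findInterval(br[-length(br)], beta$cutoffs) + 1L
  wid <- diff(br)
  mult <- exp(beta$values)[bj]
  # cumulative hazard at refined break points, per dose, carrier & non-carrier
  cum_nc <- rbind(0, apply(lam * wid, 2, cumsum))
  cum_ca <- rbind(0, apply(lam * mult * wid, 2, cumsum))
  structure(
    list(
      baseline = baseline, beta = beta, support = sup,
      refined = list(breaks = br, lambda = lam, beta_piece = bj,
                     cum_nc = cum_nc, cum_ca = cum_ca)
    ),
    class = "hazard_model"
  )
}

#' @export
print.hazard_model <- function(x, ...) {
  cat("Hazard model on [", x$support[1], ", ", x$support[2], "]: ",
      "piecewise baseline (", nrow(x$baseline$hazard), " pieces x 3 strata), ",
      "beta(t) with ", length(x$beta$values), " interval(s)\n", sep = "")
  invisible(x)
}

.check_support <- function(model, t) {
  if (any(t < model$support[1] - 1e-12 | t > model$support[2] + 1e-12)) {
    stop("age ", t[which(t < model$support[1] | t > model$support[2])[1]],
         " outside the model support [", model$support[1], ", ",
         model$support[2], "]; no extrapolation is performed")
  }
}

# internal: piecewise-linear lookup of the cumulative hazard
.cum_lookup <- function(breaks, cum, lam, t) {
  k <- pmin(pmax(findInterval(t, breaks), 1L), length(breaks) - 1L)
  cum[k] + lam[k] * (t - breaks[k])
}

#' Cumulative hazard
#'
#' Exact integral of the piecewise-constant hazard from the support start to
#' \code{t} for the given effect class.
#'
#' @param model a \code{\link{hazard_model}}.
#' @param t ages (vectorized), inside the support.
#' @param e4_dose 0, 1 or 2 APOE-e4 alleles.
#' @param carrier logical, rare-variant carrier.
#' @return nonnegative cumulative hazards.
#' @export
cum_hazard <- function(model, t, e4_dose, carrier) {
  .check_support(model, t)
  r <- model$refined
  d <- e4_dose + 1L
  if (carrier) {
    mult <- exp(model$beta$values)[r$beta_piece]
    .cum_lookup(r$breaks, r$cum_ca[, d], r$lambda[, d] * mult, t)
  } else {
    .cum_lookup(r$breaks, r$cum_nc[, d], r$lambda[, d], t)
  }
}

#' Instantaneous hazard at an age
#' @inheritParams cum_hazard
#' @return hazard per year; an age equal to an interior grid point belongs to
#'   the right-hand piece (the support end uses the last piece).
#' @export
hazard_at <- function(model, t, e4_dose, carrier) {
  .check_support(model, t)
  r <- model$refined
  k <- pmin(pmax(findInterval(t, r$breaks), 1L), length(r$breaks) - 1L)
  h <- r$lambda[k, e4_dose + 1L]
  if (carrier) h <- h * exp(model$beta$values[r$beta_piece[k]])
  h
}

#' Survival and penetrance
#'
#' \code{surv_prob} is \code{exp(-cum_hazard)}; \code{penetrance} is the
#' age-related probability of disease, \code{1 - surv_prob}, nondecreasing in
#' age.
#' @inheritParams cum_hazard
#' @return probabilities in [0, 1].
#' @export
surv_prob <- function(model, t, e4_dose, carrier) {
  exp(-cum_hazard(model, t, e4_dose, carrier))
}

#' @rdname surv_prob
#' @export
penetrance <- function(model, t, e4_dose, carrier) {
  1 - surv_prob(model, t, e4_dose, carrier)
}

#' Per-individual phenotype evidence
#'
#' The likelihood of one individual's phenotype given an effect class:
#' \code{S(T)} for a censored individual (delta = 0) and
#' \code{S(T) * lambda(T)} for an affected one (delta = 1).  Callers multiply
#' this with the genotype compatibility mask.
#'
#' @inheritParams cum_hazard
#' @param T observed age (onset if affected, censoring otherwise).
#' @param delta 1 if affected at T, 0 if censored.
#' @return nonnegative evidence value.
#' @export
evidence_value <- function(model, T, delta, e4_dose, carrier) {
  s <- surv_prob(model, T, e4_dose, carrier)
  if (delta == 1) s * hazard_at(model, T, e4_dose, carrier) else s
}

#' Phenotype evidence across the six effect classes
#'
#' @inheritParams evidence_value
#' @return numeric vector of length 6 in \code{\link{effect_classes}} order.
#' @export
class_evidence <- function(model, T, delta) {
  cls <- effect_classes()
  vapply(seq_len(6), function(k) {
    evidence_value(model, T, delta, cls$e4_dose[k], cls$carrier[k])
  }, numeric(1))
}

# Baseline (non-carrier) cumulative hazard, used for M-step exposures.
cum_hazard_nc <- function(baseline, t, e4_dose) {
  br <- baseline$breaks
  lam <- baseline$hazard[, e4_dose + 1L]
  cum <- c(0, cumsum(lam * diff(br)))
  t <- pmin(pmax(t, br[1]), br[length(br)])
  .cum_lookup(br, cum, lam, t)
}

# Baseline exposure increments per beta interval j:
#   E_j(T, dose) = Lambda_nc(min(T, tau_j) | dose) - Lambda_nc(tau_{j-1} | dose)
# clamped at 0 when T <= tau_{j-1}.  tau_0 = support start, tau_J = support end.
interval_exposures <- function(baseline, T, e4_dose, cutoffs) {
  sup <- baseline$support
  tau <- c(sup[1], cutoffs, sup[2])
  TT <- pmin(T, sup[2])
  J <- length(cutoffs) + 1L
  out <- numeric(J)
  for (j in seq_len(J)) {
    hi <- min(TT, tau[j + 1])
    if (hi > tau[j]) {
      out[j] <- cum_hazard_nc(baseline, hi, e4_dose) -
        cum_hazard_nc(baseline, tau[j], e4_dose)
    }
  }
  out
}
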