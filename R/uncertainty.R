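# Bootstrap confidence intervals: families are resampled with replacement to
# the original family count and the model refitted with the cutoffs held at
# their selected values; optionally each baseline log-hazard piece is
# perturbed by a normal draw to propagate baseline uncertainty.  Intervals are
# the 2.5/97.5 percentiles across iterations.
#
# When every member entering the M-step has both genotypes observed, the
# posterior carrier weights are data-determined: they depend neither on beta
# nor on which families were resampled.  Each family's event/exposure sums can
# then be computed once and every bootstrap replicate is an exact O(families)
# recombination of those sums -- an identity, not an approximation.  Any
# missing genotype among contributors (or baseline resampling) disables the
# shortcut and the EM is refit per replicate.

#' Bootstrap confidence intervals for beta and the penetrance curves
#'
#' @param fit a \code{\link{fit_penetrance}} result (the reference fit; its
#'   cutoffs are held fixed).
#' @param n_iterations bootstrap iterations (500 reproduces the usual
#'   reporting convention).
#' @param seed integer seed; the same seed reproduces the intervals exactly.
#' @param resample_baseline also perturb the baseline log-hazards.
#' @param baseline_se standard error on the log-hazard scale, a scalar or a
#'   matrix matching \code{fit$baseline$hazard}; required when
#'   \code{resample_baseline} is TRUE (forced off with a warning otherwise).
#' @param ages ages at which carrier/non-carrier penetrance quantiles are
#'   reported.
#' @param max_fail_frac iteration-level fit failures are skipped; more than
#'   this fraction is an error.
#' @return an object of class \code{pedpen_boot}: \code{beta_ci} (per-interval
#'   2.5/97.5 percentiles), \code{penetrance_ci} (per age x effect class), the
#'   raw draws, and bookkeeping fields.
#' @export
bootstrap_ci <- function(fit, n_iterations = 500, seed = NULL,
                         resample_baseline = FALSE, baseline_se = NULL,
                         ages = c(65, 70, 75, 80, 85),
                         max_fail_frac = 0.2) {
  stopifnot(inherits(fit, "pedpen_fit"), n_iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (resample_baseline && is.null(baseline_se)) {
    warning("resample_baseline requires baseline_se; disabled")
    resample_baseline <- FALSE
  }
  peds <- fit$peds
  nf <- length(peds)
  J <- length(fit$beta$values)
  cutoffs <- fit$cutoffs
  cls <- effect_classes()

  fast <- !resample_baseline && .all_contributors_genotyped(fit)
  if (fast) {
    famstat <- .family_mstep_stats(fit)
    # exposure of the baseline over each beta interval up to each report age
    expo_age <- lapply(0:2, function(d) {
      t(matrix(vapply(ages, function(a) {
        interval_exposures(fit$baseline, a, d, cutoffs)
      }, numeric(J)), nrow = J))
    })
  }

  beta_draws <- matrix(NA_real_, n_iterations, J)
  pen_draws <- array(NA_real_, c(n_iterations, length(ages), 6))
  failures <- 0
  for (b in seq_len(n_iterations)) {
    idx <- sample.int(nf, nf, replace = TRUE)
    bl <- fit$baseline
    if (resample_baseline) {
      se <- if (length(baseline_se) == 1) {
        matrix(baseline_se, nrow(bl$hazard), 3)
      } else as.matrix(baseline_se)
      bl <- baseline_hazard(bl$breaks,
                            bl$hazard * exp(matrix(stats::rnorm(length(se), 0, se),
                                                   nrow(se), ncol(se))))
    }
    if (fast) {
      num <- colSums(famstat$num[idx, , drop = FALSE])
      den <- colSums(famstat$den[idx, , drop = FALSE])
      if (any(den <= 0)) { failures <- failures + 1; next }
      beta_b <- log(num / den)
      beta_draws[b, ] <- beta_b
      for (k in seq_len(6)) {
        d <- cls$e4_dose[k] + 1L
        lam_tot <- if (cls$carrier[k]) {
          as.vector(expo_age[[d]] %*% exp(beta_b))
        } else rowSums(expo_age[[d]])
        pen_draws[b, , k] <- 1 - exp(-lam_tot)
      }
    } else {
      rf <- tryCatch(
        fit_penetrance(peds[idx], bl, cutoffs, fit$prior, fit$config),
        error = function(e) NULL
      )
      if (is.null(rf)) { failures <- failures + 1; next }
      beta_draws[b, ] <- rf$beta$values
      for (k in seq_len(6)) {
        pen_draws[b, , k] <- penetrance(rf$model, pmin(ages, rf$model$support[2]),
                                        cls$e4_dose[k], cls$carrier[k])
      }
    }
  }
  if (failures > max_fail_frac * n_iterations) {
    stop(failures, "/", n_iterations, " bootstrap fits failed")
  }
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  beta_ci <- t(apply(beta_draws, 2, qs))
  colnames(beta_ci) <- c("lower", "upper")
  pen_rows <- list()
  for (k in seq_len(6)) {
    q <- t(apply(pen_draws[, , k, drop = FALSE], 2, qs))
    pen_rows[[k]] <- data.frame(
      age = ages, class = cls$label[k],
      lower = q[, 1], upper = q[, 2]
    )
  }
  structure(
    list(
      beta_ci = data.frame(interval = seq_len(J), beta = fit$beta$values,
                           lower = beta_ci[, "lower"], upper = beta_ci[, "upper"]),
      penetrance_ci = do.call(rbind, pen_rows),
      beta_draws = beta_draws, pen_draws = pen_draws, ages = ages,
      n_iterations = n_iterations, failures = failures, fast_path = fast
    ),
    class = "pedpen_boot"
  )
}

#' @export
print.pedpen_boot <- function(x, ...) {
  cat("Bootstrap (", x$n_iterations, " iterations, ", x$failures,
      " failures)\n", sep = "")
  print(x$beta_ci, row.names = FALSE)
  invisible(x)
}

# TRUE when every M-step contributor has both genotypes observed
.all_contributors_genotyped <- function(fit) {
  include_probands <- fit$config$proband_mode == "include"
  all(vapply(fit$peds, function(ped) {
    min_age <- max(fit$config$min_age, fit$baseline$support[1])
    contrib <- !is.na(ped$status) & !is.na(ped$age) & ped$age >= min_age
    use <- contrib & (include_probands | !ped$proband)
    all(!is.na(ped$apoe[use]) & !is.na(ped$sorl1[use]))
  }, logical(1)))
}

# per-family M-step event/exposure sums under the reference posteriors
.family_mstep_stats <- function(fit) {
  prep <- prepare_em_data(fit$peds, fit$baseline, fit$cutoffs, fit$config)
  include_probands <- fit$config$proband_mode == "include"
  J <- length(fit$beta$values)
  nf <- length(prep)
  num <- matrix(0, nf, J)
  den <- matrix(0, nf, J)
  for (f in seq_len(nf)) {
    fp <- prep[[f]]
    use <- fp$contrib & (include_probands | !fp$proband)
    if (!any(use)) next
    wc <- .carrier_weights(fit$posteriors[[f]])
    for (i in which(use)) {
      if (fp$delta[i] == 1) {
        num[f, fp$jT[i]] <- num[f, fp$jT[i]] + sum(wc[i, ])
      }
      for (d in 1:3) {
        if (wc[i, d] > 0) den[f, ] <- den[f, ] + wc[i, d] * fp$expo[[d]][i, ]
      }
    }
  }
  list(num = num, den = den)
}
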