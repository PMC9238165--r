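# Generator of three-generation ascertained pedigrees with known truth.
#
# Families are built from two grandparental couples, the sibships of both
# parents, and the proband's sibship (sibship sizes truncated-Poisson, mean 3,
# minimum 1).  Genotypes are gene-dropped from Hardy-Weinberg founders; to
# make carrier families reachable, one grandparent on a uniformly chosen
# parental side is seeded as a heterozygous carrier (an importance device: all
# inference conditions on observed genotypes, never on the seeding
# distribution).  Ages at onset are drawn from the piecewise-exponential
# distribution implied by the hazard model via inverse-transform sampling;
# unaffected members are censored at an age drawn uniformly on
# [censor_min, cap].  Ascertained scenarios keep only families containing an
# affected carrier in the youngest generation with onset at or below the
# recruitment age limit; that member becomes the proband.

#' Synthetic non-carrier baseline hazard
#'
#' A Gompertz-shaped baseline (log-hazard linear in age, doubling roughly
#' every 4 years) discretized on a 5-year grid over ages 40-85, with hazards
#' at age 60 of 1e-4, 3e-4 and 8e-4 per year for APOE-e4 dose 0, 1 and 2.
#' The implied cumulative incidence by age 85 is about 4%, 11% and 27% -- in
#' the range of published e4-stratified Alzheimer risks, with the low pre-65
#' incidence characteristic of cohort data.  This is a synthetic stand-in for
#' a cohort-derived baseline table and is shipped as
#' \code{inst/extdata/baseline_synthetic.csv}; real analyses should supply
#' their own table via \code{\link{read_baseline}}.
#'
#' @param theta log-hazard slope per year.
#' @param hazard60 hazards per year at age 60 for dose 0/1/2.
#' @param breaks age grid.
#' @return a \code{\link{baseline_hazard}}.
#' @export
synthetic_baseline <- function(theta = 0.17,
                               hazard60 = c(1e-4, 3e-4, 8e-4),
                               breaks = seq(40, 85, by = 5)) {
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  haz <- outer(exp(theta * (mid - 60)), hazard60)
  baseline_hazard(breaks, haz)
}

#' Simulation scenario
#'
#' Bundles every knob of the family generator.  Presets reproduce the standard
#' simulation-study conditions: \code{"baseline_mimic"} (27 ascertained
#' families with partially observed genotypes, mimicking a clinic-recruited
#' dataset; recruitment onset limit 75 years, genotypes observed for ~15% of
#' relatives, ~10% of relative phenotypes missing), \code{"full_data"} (no
#' ascertainment, everything observed -- the parameter-recovery setting),
#' \code{"unbalanced_phenotype"} (as baseline_mimic, but when exactly one
#' parent of the proband is affected all phenotypes in the unaffected parent's
#' branch are removed), \code{"genotypes_all_missing"} (as baseline_mimic with
#' every relative's genotype hidden; the proband's stays observed), and
#' \code{"heterogeneous"} (as baseline_mimic with a per-family normal shift of
#' the variant effect, standard deviation 1).
#'
#' @param preset one of the scenario names above.
#' @param n_families number of emitted families.
#' @param true_beta a \code{\link{beta_function}}; default is cutoffs
#'   (60, 65, 70) with values (3.5, 6.7, 4.7, 3.7).
#' @param baseline a \code{\link{baseline_hazard}}.
#' @param apoe_freqs,sorl1_freq founder allele frequencies used for gene
#'   dropping (the seeding of one carrier grandparent is applied on top).
#' @param ascertainment \code{"proband"} (keep families with an affected
#'   carrier proband) or \code{"none"}.
#' @param aao_limit recruitment age-at-onset limit for the proband (years).
#' @param censor_min,cap censoring ages are uniform on [censor_min, cap].
#' @param mean_sibship mean of the truncated-Poisson sibship size (minimum 1).
#' @param geno_obs_frac probability a relative's genotype (both loci) is
#'   observed.
#' @param pheno_missing_frac probability a relative's phenotype is removed.
#' @param beta_family_sd standard deviation of the per-family normal shift
#'   added to every beta value (0 = homogeneous effect).
#' @param unbalanced remove phenotypes of the unaffected parent's branch when
#'   exactly one parent is affected.
#' @return a list of class \code{sim_scenario}.
#' @export
sim_scenario <- function(preset = c("baseline_mimic", "full_data",
                                    "unbalanced_phenotype",
                                    "genotypes_all_missing", "heterogeneous"),
                         n_families = 27,
                         true_beta = beta_function(c(60, 65, 70),
                                                   c(3.5, 6.7, 4.7, 3.7)),
                         baseline = synthetic_baseline(),
                         apoe_freqs = c(0.08, 0.78, 0.14),
                         sorl1_freq = 1e-4,
                         ascertainment = NULL,
                         aao_limit = NULL,
                         censor_min = 45, cap = 85,
                         mean_sibship = 3,
                         geno_obs_frac = NULL,
                         pheno_missing_frac = NULL,
                         beta_family_sd = NULL,
                         unbalanced = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
    baseline_mimic = list(asc = "proband", lim = 75, gobs = 0.15, pmis = 0.10,
                          bsd = 0, unb = FALSE),
    full_data = list(asc = "none", lim = 75, gobs = 1, pmis = 0,
                     bsd = 0, unb = FALSE),
    unbalanced_phenotype = list(asc = "proband", lim = 75, gobs = 0.15,
                                pmis = 0.10, bsd = 0, unb = TRUE),
    genotypes_all_missing = list(asc = "proband", lim = 75, gobs = 0,
                                 pmis = 0.10, bsd = 0, unb = FALSE),
    heterogeneous = list(asc = "proband", lim = 75, gobs = 0.15, pmis = 0.10,
                         bsd = 1, unb = FALSE)
  )
  structure(
    list(
      preset = preset, n_families = n_families, true_beta = true_beta,
      baseline = baseline, apoe_freqs = apoe_freqs, sorl1_freq = sorl1_freq,
      ascertainment = if (is.null(ascertainment)) def$asc else ascertainment,
      aao_limit = if (is.null(aao_limit)) def$lim else aao_limit,
      censor_min = censor_min, cap = cap, mean_sibship = mean_sibship,
      geno_obs_frac = if (is.null(geno_obs_frac)) def$gobs else geno_obs_frac,
      pheno_missing_frac = if (is.null(pheno_missing_frac)) def$pmis
                           else pheno_missing_frac,
      beta_family_sd = if (is.null(beta_family_sd)) def$bsd else beta_family_sd,
      unbalanced = if (is.null(unbalanced)) def$unb else unbalanced
    ),
    class = "sim_scenario"
  )
}

#' Sample an age at onset from the hazard model
#'
#' Inverse-transform sampling of the piecewise-exponential onset distribution:
#' \code{T = Lambda^{-1}(-log U)} with U uniform.  Draws whose total hazard is
#' never reached within the support return \code{Inf} (the individual does not
#' onset within the modelled age range).
#'
#' @param model a \code{\link{hazard_model}}.
#' @param e4_dose,carrier effect class.
#' @param n number of draws.
#' @return numeric vector of onset ages (possibly \code{Inf}).
#' @export
sample_onset_age <- function(model, e4_dose, carrier, n = 1) {
  r <- model$refined
  d <- e4_dose + 1L
  cum <- if (carrier) r$cum_ca[, d] else r$cum_nc[, d]
  lam <- r$lambda[, d]
  if (carrier) lam <- lam * exp(model$beta$values)[r$beta_piece]
  e <- -log(stats::runif(n))
  out <- rep(Inf, n)
  total <- cum[length(cum)]
  hit <- e < total
  if (any(hit)) {
    k <- findInterval(e[hit], cum)
    k <- pmin(k, length(lam))
    out[hit] <- r$breaks[k] + (e[hit] - cum[k]) / lam[k]
  }
  out
}

.rtpois <- function(n, mean, min = 1) {
  x <- stats::rpois(n, mean)
  while (any(x < min)) x[x < min] <- stats::rpois(sum(x < min), mean)
  x
}

.draw_founder <- function(apoe_freqs, q) {
  list(
    a = sample(APOE_ALLELES, 2, replace = TRUE, prob = apoe_freqs),
    s = stats::rbinom(2, 1, q)
  )
}

.drop_child <- function(fa, mo) {
  list(
    a = c(fa$a[sample.int(2, 1)], mo$a[sample.int(2, 1)]),
    s = c(fa$s[sample.int(2, 1)], mo$s[sample.int(2, 1)])
  )
}

# one structural + genotypic + phenotypic family draw (before ascertainment)
.draw_family <- function(sc, model_nc_carrier) {
  # structure ------------------------------------------------------------
  kA <- .rtpois(1, sc$mean_sibship) # father's sibship (children of couple A)
  kB <- .rtpois(1, sc$mean_sibship) # mother's sibship
  kC <- .rtpois(1, sc$mean_sibship) # proband generation
  id <- c("gpA1", "gpA2", "gpB1", "gpB2",
          paste0("p", seq_len(kA)), paste0("m", seq_len(kB)),
          paste0("c", seq_len(kC)))
  n <- length(id)
  father_id <- c(rep(NA, 4), rep("gpA1", kA), rep("gpB1", kB), rep("p1", kC))
  mother_id <- c(rep(NA, 4), rep("gpA2", kA), rep("gpB2", kB), rep("m1", kC))
  gen <- c(1, 1, 1, 1, rep(2, kA + kB), rep(3, kC))
  branch <- c("A", "A", "B", "B", rep("A", kA), rep("B", kB), rep("C", kC))
  # genotypes ------------------------------------------------------------
  g <- vector("list", n)
  names(g) <- id
  for (f in c("gpA1", "gpA2", "gpB1", "gpB2")) {
    g[[f]] <- .draw_founder(sc$apoe_freqs, sc$sorl1_freq)
  }
  seed_side <- sample(c("A", "B"), 1)
  seed_gp <- paste0("gp", seed_side, sample.int(2, 1))
  g[[seed_gp]]$s[sample.int(2, 1)] <- 1L
  for (i in seq_len(n)) {
    if (!is.na(father_id[i])) {
      g[[i]] <- .drop_child(g[[father_id[i]]], g[[mother_id[i]]])
    }
  }
  dose <- vapply(g, function(x) sum(x$a == "4"), numeric(1))
  carrier <- vapply(g, function(x) any(x$s == 1), logical(1))
  # phenotypes -----------------------------------------------------------
  onset <- numeric(n)
  for (i in seq_len(n)) {
    m <- if (carrier[i]) model_nc_carrier$carrier else model_nc_carrier$nc
    onset[i] <- sample_onset_age(m, dose[i], carrier[i], 1)
  }
  censor <- stats::runif(n, sc$censor_min, sc$cap)
  affected <- is.finite(onset) & onset <= censor
  age <- ifelse(affected, onset, censor)
  status <- as.numeric(affected)
  list(
    id = id, father_id = father_id, mother_id = mother_id, gen = gen,
    branch = branch, g = g, dose = dose, carrier = carrier,
    onset = onset, censor = censor, status = status, age = age, n = n
  )
}

#' Simulate ascertained pedigrees with known truth
#'
#' Rejection-samples families until \code{n_families} satisfy the
#' ascertainment rule of the scenario, applies its missingness pattern, and
#' returns pedigrees (readable/writable through the pedigree TSV dialect)
#' together with a hidden-truth table.
#'
#' @param sc a \code{\link{sim_scenario}}.
#' @param max_attempts rejection-sampling guard; exceeding it raises an
#'   infeasible-scenario error.
#' @return a list with \code{peds} (list of \code{pedigree}), \code{truth}
#'   (data frame: one row per individual with true genotype, onset and censor
#'   ages) and \code{family_beta} (per-family true beta values, a matrix).
#' @export
simulate_families <- function(sc, max_attempts = max(10000, 500 * sc$n_families)) {
  stopifnot(inherits(sc, "sim_scenario"))
  peds <- vector("list", sc$n_families)
  truth <- vector("list", sc$n_families)
  fam_beta <- matrix(NA_real_, sc$n_families, length(sc$true_beta$values))
  nc_model <- hazard_model(sc$baseline,
                           beta_function(sc$true_beta$cutoffs,
                                         rep(0, length(sc$true_beta$values))))
  homo_carrier <- hazard_model(sc$baseline, sc$true_beta)
  attempts <- 0
  accepted <- 0
  while (accepted < sc$n_families) {
    attempts <- attempts + 1
    if (attempts > max_attempts) {
      stop("infeasible scenario: ", accepted, " families accepted in ",
           attempts - 1, " attempts")
    }
    shift <- if (sc$beta_family_sd > 0) stats::rnorm(1, 0, sc$beta_family_sd) else 0
    carrier_model <- if (shift == 0) homo_carrier else {
      hazard_model(sc$baseline,
                   beta_function(sc$true_beta$cutoffs,
                                 sc$true_beta$values + shift))
    }
    fam <- .draw_family(sc, list(nc = nc_model, carrier = carrier_model))
    proband <- NA_integer_
    if (sc$ascertainment == "proband") {
      # single ascertainment: one member of the youngest generation reaches
      # the clinic at random; the family enters the study only if that member
      # is an affected carrier within the recruitment onset limit.  (Choosing
      # the proband among all qualifiers instead would emulate complete
      # ascertainment, under which proband exclusion over-corrects.)
      g3 <- which(fam$gen == 3)
      cand <- if (length(g3) == 1) g3 else sample(g3, 1)
      ok <- fam$carrier[cand] && fam$status[cand] == 1 &&
        fam$age[cand] <= sc$aao_limit
      if (!ok) next
      proband <- cand
    }
    accepted <- accepted + 1
    fid <- sprintf("SIM%03d", accepted)
    fam_beta[accepted, ] <- sc$true_beta$values + shift
    # observation layer ---------------------------------------------------
    n <- fam$n
    apoe_obs <- rep(NA_character_, n)
    sorl1_obs <- rep(NA_real_, n)
    status_obs <- fam$status
    age_obs <- fam$age
    geno_seen <- stats::runif(n) < sc$geno_obs_frac
    if (!is.na(proband)) geno_seen[proband] <- TRUE
    apoe_obs[geno_seen] <- vapply(fam$g[geno_seen],
                                  function(x) paste(x$a, collapse = ""),
                                  character(1))
    sorl1_obs[geno_seen] <- as.numeric(fam$carrier[geno_seen])
    pheno_gone <- stats::runif(n) < sc$pheno_missing_frac
    if (!is.na(proband)) pheno_gone[proband] <- FALSE
    if (sc$unbalanced && !is.na(proband)) {
      fa_aff <- fam$status[match("p1", fam$id)] == 1
      mo_aff <- fam$status[match("m1", fam$id)] == 1
      if (xor(fa_aff, mo_aff)) {
        drop_branch <- if (fa_aff) "B" else "A"
        pheno_gone <- pheno_gone |
          (fam$branch == drop_branch & fam$gen <= 2)
      }
    }
    status_obs[pheno_gone] <- NA
    age_obs[pheno_gone] <- NA
    ped <- new_pedigree(data.frame(
      family_id = fid,
      individual_id = fam$id,
      father_id = fam$father_id,
      mother_id = fam$mother_id,
      sex = ifelse(fam$id %in% c("gpA1", "gpB1", "p1"), "male",
                   ifelse(fam$id %in% c("gpA2", "gpB2", "m1"), "female",
                          "unknown")),
      status = status_obs,
      age = age_obs,
      proband = seq_len(n) == ifelse(is.na(proband), 0L, proband),
      apoe = apoe_obs,
      sorl1 = sorl1_obs,
      stringsAsFactors = FALSE
    ))
    peds[[accepted]] <- ped
    truth[[accepted]] <- data.frame(
      family_id = fid,
      individual_id = fam$id,
      apoe = vapply(fam$g, function(x) paste(x$a, collapse = ""), character(1)),
      sorl1 = vapply(fam$g, function(x) paste(x$s, collapse = ""), character(1)),
      carrier = fam$carrier,
      e4_dose = fam$dose,
      onset_age = fam$onset,
      censor_age = fam$censor,
      stringsAsFactors = FALSE
    )
  }
  names(peds) <- vapply(peds, function(p) p$family_id[1], character(1))
  list(peds = peds, truth = do.call(rbind, truth), family_beta = fam_beta,
       scenario = sc, attempts = attempts)
}

#' Bias table across simulation replicates
#'
#' An interval with no carrier events in a replicate carries no information on
#' its beta (the M-step flags it with a -Inf sentinel rather than a number);
#' such replicates are dropped from that interval's summary and counted in
#' \code{n_used}.
#'
#' @param estimates replicates x J matrix of fitted beta values.
#' @param truth length-J vector of true beta values.
#' @return data frame with per-interval mean bias and its Monte-Carlo standard
#'   error; a bias above 0 means the variant risk is overestimated.
#' @export
bias_report <- function(estimates, truth) {
  estimates <- as.matrix(estimates)
  if (nrow(estimates) < 2) stop("need at least 2 replicates")
  if (ncol(estimates) != length(truth)) stop("truth length must match columns")
  bias <- sweep(estimates, 2, truth)
  bias[!is.finite(bias)] <- NA
  n_used <- colSums(!is.na(bias))
  data.frame(
    interval = seq_along(truth),
    true_beta = truth,
    bias = colMeans(bias, na.rm = TRUE),
    mc_se = apply(bias, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n_used, 1)),
    n_used = n_used
  )
}
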