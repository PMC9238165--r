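# Fixture builders shared across tests.  Everything is generated in code.

# random loop-free pedigree: nf founders, the rest children of founder
# couples (father = smaller id).  New couples are only formed between
# founders in disjoint marriage components (union-find), which allows
# remarriage chains but never marriage rings -- the engine's precondition.
rand_ped <- function(n) {
  id <- as.character(seq_len(n))
  fa <- rep(NA_character_, n)
  mo <- rep(NA_character_, n)
  nf <- min(max(2, stats::rbinom(1, n - 1, 0.5)), n)
  if (n > nf) {
    comp <- seq_len(nf)
    find <- function(x) {
      while (comp[x] != x) x <- comp[x]
      x
    }
    couples <- list()
    for (i in (nf + 1):n) {
      new_pair <- NULL
      if (length(couples) == 0 || stats::runif(1) < 0.5) {
        cand <- which(vapply(seq_len(nf), function(a) {
          any(vapply(seq_len(nf), function(b) {
            a < b && find(a) != find(b)
          }, logical(1)))
        }, logical(1)))
        if (length(cand)) {
          a <- sample(rep(cand, 2), 1)
          bs <- which(vapply(seq_len(nf), function(b) {
            b > a && find(a) != find(b)
          }, logical(1)))
          b <- sample(rep(bs, 2), 1)
          new_pair <- c(a, b)
          comp[find(a)] <- find(b)
          couples[[length(couples) + 1]] <- new_pair
        }
      }
      cp <- if (!is.null(new_pair)) new_pair else
        couples[[sample.int(length(couples), 1)]]
      fa[i] <- as.character(cp[1])
      mo[i] <- as.character(cp[2])
    }
  }
  pedpen:::new_pedigree(data.frame(
    family_id = "F", individual_id = id, father_id = fa, mother_id = mo,
    sex = "unknown", status = NA_real_, age = NA_real_, proband = FALSE,
    apoe = NA_character_, sorl1 = NA_real_, stringsAsFactors = FALSE
  ))
}

# random evidence matrix with occasional genotype masks, support capped so
# that brute-force enumeration stays cheap
rand_evidence <- function(n, obs_prob = 0.6, max_support = 2e5) {
  repeat {
    ev <- matrix(stats::rexp(n * 36), n, 36)
    for (i in seq_len(n)) {
      if (stats::runif(1) < obs_prob) {
        m <- compatibility_mask(
          sample(c("22", "23", "33", "34", "44", "24"), 1),
          sample(c(0, 1, NA), 1)
        )
        ev[i, ] <- ev[i, ] * m
      }
    }
    if (prod(vapply(seq_len(n), function(i) sum(ev[i, ] > 0), numeric(1)))
        <= max_support) {
      return(ev)
    }
  }
}

# independent step-function integral: split [lo, hi] at every boundary and
# sum value * width -- exact for piecewise-constant integrands, and built
# without the package's cumulative-hazard machinery
step_integral <- function(lo, hi, boundaries, value_at) {
  cuts <- sort(unique(c(lo, hi, boundaries[boundaries > lo & boundaries < hi])))
  mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
  sum(value_at(mids) * diff(cuts))
}

# independent hazard evaluation from raw pieces (baseline + beta), bypassing
# the model's refined-grid cache
raw_hazard_fun <- function(baseline, beta, dose, carrier) {
  function(u) {
    k <- pmin(pmax(findInterval(u, baseline$breaks), 1L),
              nrow(baseline$hazard))
    h <- baseline$hazard[k, dose + 1]
    if (carrier) {
      h <- h * exp(beta$values[findInterval(u, beta$cutoffs) + 1L])
    }
    h
  }
}

# small all-founder pedigree with phenotypes, used for M-step toy datasets
toy_founder_ped <- function(ages, status, proband = rep(FALSE, length(ages))) {
  n <- length(ages)
  pedpen:::new_pedigree(data.frame(
    family_id = "T", individual_id = as.character(seq_len(n)),
    father_id = NA_character_, mother_id = NA_character_,
    sex = "unknown", status = status, age = ages, proband = proband,
    apoe = NA_character_, sorl1 = NA_real_, stringsAsFactors = FALSE
  ))
}

# expected complete-data log-likelihood in beta (terms that involve beta
# only), written directly from posterior carrier weights -- the oracle the
# closed-form M-step must maximize
q_function <- function(beta_vals, cutoffs, posteriors, peds, baseline,
                       min_age = 40, cap = 85) {
  st <- geno_states()
  q <- 0
  for (f in seq_along(peds)) {
    ped <- peds[[f]]
    post <- posteriors[[f]]
    for (i in seq_len(nrow(ped))) {
      if (ped$proband[i] || is.na(ped$status[i]) || is.na(ped$age[i]) ||
          ped$age[i] < min_age) next
      T_i <- min(ped$age[i], cap)
      delta <- as.numeric(ped$status[i] == 1 && ped$age[i] <= cap)
      jT <- findInterval(T_i, cutoffs) + 1
      for (d in 0:2) {
        w <- sum(post[i, st$carrier & st$e4_dose == d])
        if (w == 0) next
        haz <- raw_hazard_fun(baseline, beta_function(cutoffs, beta_vals),
                              d, TRUE)
        Lam <- step_integral(baseline$support[1], T_i,
                             c(baseline$breaks, cutoffs), haz)
        q <- q - w * Lam
        if (delta == 1) {
          lam_nc <- raw_hazard_fun(baseline, beta_function(cutoffs, beta_vals),
                                   d, FALSE)(T_i)
          q <- q + w * (log(lam_nc) + beta_vals[jT])
        }
      }
    }
  }
  q
}
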