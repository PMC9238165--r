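# Two-locus genotype space: ordered APOE pair (3 alleles) x ordered rare-variant
# pair (2 alleles) = 36 phase-known states, projected onto 6 effect classes
# (APOE-e4 dose x carrier status) for the hazard model.

APOE_ALLELES <- c("2", "3", "4")
SORL1_CODES <- c("00", "10", "01", "11") # (paternal, maternal) variant alleles

#' Enumerate the 36 two-locus genotype states
#'
#' States are phase-known: the APOE pair and the rare-variant pair both
#' distinguish the paternal from the maternal allele, so that Mendelian
#' transmission is a simple per-allele draw.  The enumeration order is fixed:
#' APOE ordered pairs (paternal allele slowest, over e2, e3, e4) each expanded
#' by the four variant codes "00", "10", "01", "11".  State index
#' \code{(apoe_idx - 1) * 4 + sorl1_idx} runs 1..36.
#'
#' @return A data frame with one row per state: \code{state} (1..36),
#'   \code{apoe_pat}, \code{apoe_mat} (allele labels "2"/"3"/"4"),
#'   \code{apoe} (two-character label, paternal first), \code{sorl1}
#'   (one of "00","10","01","11"), \code{e4_dose} (0/1/2), \code{carrier}
#'   (logical, any variant allele), and \code{effect_class} (1..6, see
#'   \code{\link{effect_classes}}).
#' @examples
#' st <- geno_states()
#' nrow(st)                     # 36
#' length(unique(st$effect_class))  # 6
#' @export
geno_states <- function() {
  ap <- expand.grid(mat = 1:3, pat = 1:3)[, c("pat", "mat")]
  # pat slowest: rebuild explicitly for clarity of order
  pat <- rep(1:3, each = 3)
  mat <- rep(1:3, times = 3)
  apoe_idx <- rep(1:9, each = 4)
  sorl1_idx <- rep(1:4, times = 9)
  pat_a <- APOE_ALLELES[pat[apoe_idx]]
  mat_a <- APOE_ALLELES[mat[apoe_idx]]
  sorl1 <- SORL1_CODES[sorl1_idx]
  e4 <- (pat_a == "4") + (mat_a == "4")
  carrier <- sorl1 != "00"
  data.frame(
    state = 1:36,
    apoe_pat = pat_a, apoe_mat = mat_a,
    apoe = paste0(pat_a, mat_a),
    sorl1 = sorl1,
    e4_dose = e4,
    carrier = carrier,
    effect_class = 2L * e4 + carrier + 1L,
    stringsAsFactors = FALSE
  )
}

#' The six effect classes (APOE-e4 dose x carrier status)
#'
#' The hazard model distinguishes only six genotype groups: the number of
#' APOE-e4 alleles (0, 1, 2) determines the non-carrier baseline stratum, and
#' the rare-variant carrier status ("10", "01" and "11" all count as carrier)
#' switches the proportional effect on.  Each of the 36 states projects onto
#' exactly one class.
#'
#' @return A data frame with columns \code{effect_class} (1..6),
#'   \code{e4_dose}, \code{carrier}, \code{label}.
#' @export
effect_classes <- function() {
  e4 <- rep(0:2, each = 2)
  carrier <- rep(c(FALSE, TRUE), 3)
  data.frame(
    effect_class = 1:6,
    e4_dose = e4,
    carrier = carrier,
    label = paste0("e4x", e4, ifelse(carrier, "/carrier", "/noncarrier")),
    stringsAsFactors = FALSE
  )
}

# cached constant lookups -----------------------------------------------------

.pedpen_cache <- new.env(parent = emptyenv())

state_table <- function() {
  if (is.null(.pedpen_cache$states)) .pedpen_cache$states <- geno_states()
  .pedpen_cache$states
}

# per-state effect class / dose / carrier, as plain vectors for hot loops
state_class <- function() state_table()$effect_class
state_dose <- function() state_table()$e4_dose
state_carrier <- function() state_table()$carrier

#' Founder prior over the 36 genotype states
#'
#' Hardy-Weinberg at each locus, linkage equilibrium across loci: the prior
#' probability of a state is the product of the four transmitted-allele
#' frequencies.  Neither the APOE allele frequencies nor the rare-variant
#' allele frequency are fixed by the estimation method; they are inputs, and
#' the defaults used elsewhere in this package
#' (\code{apoe_freqs = c(0.08, 0.78, 0.14)}, \code{sorl1_freq = 1e-4}) are
#' field-typical European values, not values estimated from any dataset.
#' Posterior carrier probabilities of ungenotyped relatives are sensitive to
#' \code{sorl1_freq}; report it with any result.
#'
#' @param apoe_freqs numeric length 3, frequencies of APOE e2, e3, e4; must
#'   sum to 1 (tolerance 1e-9).
#' @param sorl1_freq frequency of the rare variant allele, in [0, 1).
#' @return numeric vector of length 36 summing to 1, in \code{geno_states()}
#'   order.
#' @examples
#' p <- founder_prior(c(0, 1, 0), 0)   # point mass on (e3e3, "00")
#' which(p == 1)
#' @export
founder_prior <- function(apoe_freqs, sorl1_freq) {
  if (length(apoe_freqs) != 3 || any(!is.finite(apoe_freqs)) ||
      any(apoe_freqs < 0) || any(apoe_freqs > 1)) {
    stop("apoe_freqs must be 3 probabilities in [0, 1]")
  }
  if (abs(sum(apoe_freqs) - 1) > 1e-9) {
    stop("apoe_freqs must sum to 1 (tolerance 1e-9)")
  }
  if (!is.finite(sorl1_freq) || sorl1_freq < 0 || sorl1_freq >= 1) {
    stop("sorl1_freq must lie in [0, 1)")
  }
  st <- state_table()
  pa <- stats::setNames(apoe_freqs, APOE_ALLELES)
  q <- sorl1_freq
  ps <- c("0" = 1 - q, "1" = q)
  s_pat <- substr(st$sorl1, 1, 1)
  s_mat <- substr(st$sorl1, 2, 2)
  unname(pa[st$apoe_pat] * pa[st$apoe_mat] * ps[s_pat] * ps[s_mat])
}

# 3x3x3 single-locus transmission for a k-allele locus given ordered parental
# pairs; child allele drawn uniformly from the parent's two alleles.
.locus_transmission <- function(n_alleles) {
  npair <- n_alleles^2
  pairs <- cbind(
    pat = rep(seq_len(n_alleles), each = n_alleles),
    mat = rep(seq_len(n_alleles), times = n_alleles)
  )
  # P(child allele x | parent pair p) = ((x == pat) + (x == mat)) / 2
  gam <- matrix(0, n_alleles, npair)
  for (p in seq_len(npair)) {
    gam[pairs[p, "pat"], p] <- gam[pairs[p, "pat"], p] + 0.5
    gam[pairs[p, "mat"], p] <- gam[pairs[p, "mat"], p] + 0.5
  }
  tr <- array(0, c(npair, npair, npair))
  for (f in seq_len(npair)) {
    for (m in seq_len(npair)) {
      # child pair index (cp-1)*n + cm: cp from father, cm from mother;
      # outer(mat, pat) flattens with cm fastest, matching that index
      tr[, f, m] <- as.vector(outer(gam[, m], gam[, f]))
    }
  }
  tr
}

# full 36 x 36 x 36 transmission array T[child, father, mother]; the two loci
# are unlinked so the per-locus probabilities multiply.
transmission_array <- function() {
  if (!is.null(.pedpen_cache$trans)) return(.pedpen_cache$trans)
  ta <- .locus_transmission(3) # 9 x 9 x 9 APOE ordered pairs
  ts <- .locus_transmission(2) # 4 x 4 x 4, pair order (0,0),(1,0),(0,1),(1,1)
  # variant pair order from .locus_transmission is pat-slow: (1,1),(1,2),(2,1),(2,2)
  # = "00","01","10","11" in (pat,mat) allele terms -- reorder to SORL1_CODES
  ord <- c(1, 3, 2, 4) # "00","10","01","11"
  ts <- ts[ord, ord, ord]
  tr <- array(0, c(36, 36, 36))
  for (f in 1:36) {
    fa <- (f - 1) %/% 4 + 1
    fs <- (f - 1) %% 4 + 1
    for (m in 1:36) {
      ma <- (m - 1) %/% 4 + 1
      ms <- (m - 1) %% 4 + 1
      # state index = (apoe-1)*4 + sorl1: sorl1 fastest
      tr[, f, m] <- as.vector(outer(ts[, fs, ms], ta[, fa, ma]))
    }
  }
  .pedpen_cache$trans <- tr
  # flat 36 x 1296 view used by message passing (column = father + 36*(mother-1))
  .pedpen_cache$trans_flat <- matrix(tr, 36, 36 * 36)
  tr
}

transmission_flat <- function() {
  if (is.null(.pedpen_cache$trans_flat)) transmission_array()
  .pedpen_cache$trans_flat
}

#' Mendelian transmission probability between two-locus states
#'
#' Per locus, the child's paternal allele is a uniform draw from the father's
#' two alleles and the maternal allele from the mother's two; the loci are
#' unlinked (APOE on chromosome 19, SORL1 on 11) so probabilities multiply.
#'
#' @param child,father,mother state indices in 1..36 (see
#'   \code{\link{geno_states}}).
#' @return transmission probability, a multiple of 1/16.
#' @export
transmission_prob <- function(child, father, mother) {
  tr <- transmission_array()
  tr[cbind(child, father, mother)]
}

#' Observation-compatibility mask over the 36 states
#'
#' Genotype observations restrict the state space: an observed APOE genotype
#' is an unordered allele pair (phase unknown), and an observed variant status
#' is carrier/non-carrier (any of "10", "01", "11" is a carrier).  Posterior
#' probabilities are forced to zero on states discordant with the
#' observations.
#'
#' @param obs_apoe two-character APOE genotype such as "34" (allele order not
#'   meaningful), or \code{NA} if unobserved.
#' @param obs_sorl1 1 (carrier), 0 (non-carrier) or \code{NA} if unobserved.
#' @return numeric vector of length 36 with entries 0/1; all ones when both
#'   observations are missing.  An observation matching no state is an error.
#' @examples
#' sum(compatibility_mask("34", 1))  # 6 states
#' sum(compatibility_mask(NA, 0))    # 9 states
#' @export
compatibility_mask <- function(obs_apoe = NA, obs_sorl1 = NA) {
  st <- state_table()
  mask <- rep(1, 36)
  if (!is.na(obs_apoe)) {
    a <- strsplit(as.character(obs_apoe), "")[[1]]
    if (length(a) != 2 || !all(a %in% APOE_ALLELES)) {
      stop("obs_apoe must be two characters among 2/3/4, got '", obs_apoe, "'")
    }
    want <- paste(sort(a), collapse = "")
    have <- vapply(seq_len(36), function(i) {
      paste(sort(c(st$apoe_pat[i], st$apoe_mat[i])), collapse = "")
    }, character(1))
    mask <- mask * as.numeric(have == want)
  }
  if (!is.na(obs_sorl1)) {
    if (!obs_sorl1 %in% c(0, 1)) stop("obs_sorl1 must be 0, 1 or NA")
    mask <- mask * as.numeric(st$carrier == (obs_sorl1 == 1))
  }
  if (all(mask == 0)) stop("observations are compatible with no genotype state")
  mask
}
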