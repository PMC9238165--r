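# Exact sum-product on the pedigree factor graph.
#
# Variables: one per individual, domain = the 36 two-locus states.  Factors:
# one per nuclear family (couple and its joint children), carrying the product
# of the Mendelian transmission terms of the children; founder priors and
# per-individual evidence are unary terms folded into the variable nodes.  For
# a loop-free pedigree this bipartite graph is a forest, so two passes of
# message passing give exact marginals and the exact log evidence
# (log-likelihood).  Messages are normalized as they are computed and the log
# normalizing constants accumulated, which keeps families with tiny survival x
# hazard evidence away from underflow (Elston-Stewart peeling with rescaling).

# Build the message-passing plan for one pedigree.
bp_plan <- function(ped) {
  fg <- family_graph(ped)
  n <- nrow(ped)
  k <- length(fg$nuclear)
  if (fg$n_edges != fg$n_nodes - fg$n_components) {
    stop("family ", ped$family_id[1], ": pedigree has a loop; ",
         "exact peeling is not supported on looped pedigrees")
  }
  # adjacency: for each nuclear factor, its member variables; for each
  # variable, its adjacent factors
  var_fac <- vector("list", n)
  for (j in seq_len(k)) {
    mem <- c(fg$nuclear[[j]]$father, fg$nuclear[[j]]$mother,
             fg$nuclear[[j]]$children)
    for (i in mem) var_fac[[i]] <- c(var_fac[[i]], j)
  }
  # edge ordering by DFS from each component root (a variable node)
  # nodes: 1..n variables, n+1..n+k factors
  adj <- c(var_fac, lapply(fg$nuclear, function(f) {
    c(f$father, f$mother, f$children)
  }))
  visited <- rep(FALSE, n + k)
  edge_child <- integer(0) # node visited through this edge
  edge_parent <- integer(0)
  for (root in seq_len(n)) {
    if (visited[root]) next
    stack <- root
    visited[root] <- TRUE
    while (length(stack)) {
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- if (u <= n) n + adj[[u]] else adj[[u]]
      for (v in nb) {
        if (!visited[v]) {
          visited[v] <- TRUE
          edge_child <- c(edge_child, v)
          edge_parent <- c(edge_parent, u)
          stack <- c(stack, v)
        }
      }
    }
  }
  list(fg = fg, n = n, k = k, var_fac = var_fac,
       edge_child = edge_child, edge_parent = edge_parent)
}

# message from factor j to variable `target`, given incoming variable->factor
# messages `inmsg[[i]]` and their cached transmission contractions
# `incontr[[i]]` (m_i(gf, gm) = sum_g in_i(g) T[g, gf, gm]) for children
.factor_message <- function(nucl, j, target, inmsg, incontr) {
  tf <- transmission_flat() # 36 x 1296, column = father + 36*(mother-1)
  f <- nucl[[j]]$father
  m <- nucl[[j]]$mother
  ch <- nucl[[j]]$children
  prodW <- NULL
  for (c_i in ch) {
    if (c_i == target) next
    mc <- incontr[[c_i]] # rows gf, cols gm
    prodW <- if (is.null(prodW)) mc else prodW * mc
  }
  if (target %in% ch) {
    W <- outer(inmsg[[f]], inmsg[[m]])
    if (!is.null(prodW)) W <- W * prodW
    as.vector(tf %*% as.vector(W))
  } else if (target == f) {
    if (is.null(prodW)) prodW <- matrix(1, 36, 36)
    as.vector(prodW %*% inmsg[[m]])
  } else if (target == m) {
    if (is.null(prodW)) prodW <- matrix(1, 36, 36)
    as.vector(crossprod(prodW, inmsg[[f]]))
  } else {
    stop("internal error: target not in factor")
  }
}

#' Exact genotype posteriors and log-likelihood for one pedigree
#'
#' Runs two-pass sum-product message passing on the pedigree factor graph
#' (founder priors, Mendelian transmission, per-individual evidence),
#' returning for every member the exact marginal posterior over the 36
#' two-locus states given all evidence in the family, together with the log of
#' the total evidence (the family's log-likelihood contribution).
#'
#' @param ped a \code{pedigree}.
#' @param prior founder prior over the 36 states (see
#'   \code{\link{founder_prior}}).
#' @param ev numeric n x 36 matrix of per-individual evidence (phenotype
#'   likelihood times compatibility mask), rows in \code{ped} order; use a row
#'   of ones for a structure-only member.
#' @return a list with \code{posterior} (n x 36 matrix, rows summing to 1) and
#'   \code{loglik}.
#' @seealso \code{\link{brute_force_marginals}} for the enumeration oracle.
#' @export
propagate_pedigree <- function(ped, prior, ev) {
  n <- nrow(ped)
  ev <- as.matrix(ev)
  if (nrow(ev) != n || ncol(ev) != 36) stop("ev must be n x 36")
  if (any(ev < 0) || any(!is.finite(ev))) stop("evidence must be finite and >= 0")
  if (any(rowSums(ev) == 0)) {
    stop("family ", ped$family_id[1],
         ": an individual has all-zero evidence (contradiction)")
  }
  plan <- bp_plan(ped)
  k <- plan$k
  founder <- is.na(match(ped$father_id, ped$individual_id))
  unary <- ev
  unary[founder, ] <- sweep(ev[founder, , drop = FALSE], 2, prior, "*")

  # message storage: msg_to_var[[j]][[i]] factor j -> variable i,
  # msg_to_fac[[j]][[i]] variable i -> factor j; each a 36-vector.
  # contr_to_fac caches the transmission contraction of each child's
  # variable->factor message so sibling products cost one elementwise
  # multiply instead of a fresh matrix-vector product per target.
  msg_to_var <- lapply(seq_len(max(k, 1)), function(j) list())
  msg_to_fac <- lapply(seq_len(max(k, 1)), function(j) list())
  contr_to_fac <- lapply(seq_len(max(k, 1)), function(j) list())
  lognorm_up <- 0

  var_belief_except <- function(i, except_j) {
    b <- unary[i, ]
    for (j in plan$var_fac[[i]]) {
      if (j != except_j && !is.null(msg_to_var[[j]][[as.character(i)]])) {
        b <- b * msg_to_var[[j]][[as.character(i)]]
      }
    }
    b
  }

  send <- function(from, to, upward) {
    # nodes > n are factors
    if (from > plan$n) {
      j <- from - plan$n
      i <- to
      inmsg <- vector("list", plan$n)
      incontr <- vector("list", plan$n)
      mem <- c(plan$fg$nuclear[[j]]$father, plan$fg$nuclear[[j]]$mother,
               plan$fg$nuclear[[j]]$children)
      for (x in mem) {
        if (x != i) {
          inmsg[[x]] <- msg_to_fac[[j]][[as.character(x)]]
          incontr[[x]] <- contr_to_fac[[j]][[as.character(x)]]
        }
      }
      mu <- .factor_message(plan$fg$nuclear, j, i, inmsg, incontr)
      z <- sum(mu)
      if (z <= 0) {
        stop("family ", ped$family_id[1],
             ": zero total evidence (contradictory genotypes/phenotypes)")
      }
      msg_to_var[[j]][[as.character(i)]] <<- mu / z
      if (upward) lognorm_up <<- lognorm_up + log(z)
    } else {
      i <- from
      j <- to - plan$n
      b <- var_belief_except(i, j)
      z <- sum(b)
      if (z <= 0) {
        stop("family ", ped$family_id[1],
             ": zero total evidence (contradictory genotypes/phenotypes)")
      }
      b <- b / z
      msg_to_fac[[j]][[as.character(i)]] <<- b
      if (i %in% plan$fg$nuclear[[j]]$children) {
        contr_to_fac[[j]][[as.character(i)]] <<-
          matrix(b %*% transmission_flat(), 36, 36)
      }
      if (upward) lognorm_up <<- lognorm_up + log(z)
    }
  }

  ne <- length(plan$edge_child)
  if (ne) {
    for (e in rev(seq_len(ne))) send(plan$edge_child[e], plan$edge_parent[e], TRUE)
    for (e in seq_len(ne)) send(plan$edge_parent[e], plan$edge_child[e], FALSE)
  }

  # marginals: belief at each variable = unary x all incoming messages
  posterior <- matrix(0, n, 36)
  for (i in seq_len(n)) {
    b <- unary[i, ]
    for (j in plan$var_fac[[i]]) b <- b * msg_to_var[[j]][[as.character(i)]]
    z <- sum(b)
    if (z <= 0) {
      stop("family ", ped$family_id[1],
           ": zero total evidence (contradictory genotypes/phenotypes)")
    }
    posterior[i, ] <- b / z
  }
  # log-likelihood: at a DFS root every incoming message is upward, so the
  # accumulated upward constants plus the local normalizer give log Z exactly
  # (one root per connected component: any variable never visited as a child)
  is_child <- rep(FALSE, plan$n + plan$k)
  is_child[plan$edge_child] <- TRUE
  roots <- which(!is_child[seq_len(n)])
  logz <- lognorm_up
  for (r in roots) {
    b <- unary[r, ]
    for (j in plan$var_fac[[r]]) b <- b * msg_to_var[[j]][[as.character(r)]]
    logz <- logz + log(sum(b))
  }
  list(posterior = posterior, loglik = logz)
}

#' Exact marginals by exhaustive enumeration (test oracle)
#'
#' Direct summation of prior x transmission x evidence over every joint
#' genotype configuration compatible with the evidence support.  Exponential
#' in family size: guarded to small problems.  Exists as an independent oracle
#' for \code{\link{propagate_pedigree}}.
#'
#' @inheritParams propagate_pedigree
#' @param max_config guard on the number of enumerated configurations
#'   (default 1e7).
#' @return same shape as \code{\link{propagate_pedigree}}.
#' @export
brute_force_marginals <- function(ped, prior, ev, max_config = 1e7) {
  n <- nrow(ped)
  ev <- as.matrix(ev)
  if (n > 7) stop("brute force guarded to <= 7 members")
  support <- lapply(seq_len(n), function(i) which(ev[i, ] > 0))
  if (any(vapply(support, length, integer(1)) == 0)) {
    stop("family ", ped$family_id[1],
         ": an individual has all-zero evidence (contradiction)")
  }
  n_conf <- prod(vapply(support, length, numeric(1)))
  if (n_conf > max_config) stop("state space too large for brute force")
  conf <- as.matrix(expand.grid(support, KEEP.OUT.ATTRS = FALSE))
  fa <- match(ped$father_id, ped$individual_id)
  mo <- match(ped$mother_id, ped$individual_id)
  tr <- transmission_array()
  w <- rep(1, nrow(conf))
  for (i in seq_len(n)) {
    g <- conf[, i]
    w <- w * ev[cbind(i, g)]
    if (is.na(fa[i])) {
      w <- w * prior[g]
    } else {
      w <- w * tr[cbind(g, conf[, fa[i]], conf[, mo[i]])]
    }
  }
  z <- sum(w)
  if (z <= 0) {
    stop("family ", ped$family_id[1],
         ": zero total evidence (contradictory genotypes/phenotypes)")
  }
  posterior <- matrix(0, n, 36)
  for (i in seq_len(n)) {
    m <- rowsum(w, group = conf[, i])
    posterior[i, as.integer(rownames(m))] <- m[, 1] / z
  }
  list(posterior = posterior, loglik = log(z))
}
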