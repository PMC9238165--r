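# Pedigree container and TSV dialect.
#
# A pedigree is a data frame (class "pedigree") with one row per individual:
#   family_id, individual_id, father_id, mother_id (NA for founders),
#   sex ("male"/"female"/"unknown"), status (1 affected / 0 unaffected / NA),
#   age (age at onset if affected, censoring age if unaffected, NA if unknown),
#   proband (logical), apoe ("22".."44" or NA), sorl1 (0/1/NA).
# File encoding: missing values are "."; status 1/0/.; proband 0/1; apoe a
# two-character allele pair ("34"); sorl1 0/1/".".

PED_COLUMNS <- c(
  "family_id", "individual_id", "father_id", "mother_id", "sex",
  "status", "age", "proband", "apoe", "sorl1"
)

new_pedigree <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

#' @export
print.pedigree <- function(x, ...) {
  cat(
    "Pedigree", x$family_id[1], "-", nrow(x), "members,",
    sum(is.na(x$father_id)), "founders,",
    sum(x$proband), "proband(s)\n"
  )
  print.data.frame(x, ...)
  invisible(x)
}

#' Read pedigrees from a tab-separated file
#'
#' The file must carry a header with the ten dialect columns (family_id,
#' individual_id, father_id, mother_id, sex, status, age, proband, apoe,
#' sorl1); missing values are encoded as ".".  Rows are grouped into one
#' pedigree per family and each family is structurally validated: parent
#' references must resolve within the family, both parents are present or
#' both absent, the parent-child graph is acyclic, the marriage-node graph is
#' loop-free (no consanguinity/marriage loops -- exact peeling requires it),
#' at most one proband per family, and a proband must be an observed carrier.
#'
#' @param path file path.
#' @return a named list of \code{pedigree} objects, one per family.
#' @seealso \code{\link{write_pedigrees}}, \code{\link{informative_members}}
#' @export
read_pedigrees <- function(path) {
  raw <- utils::read.table(
    path,
    header = TRUE, sep = "\t", colClasses = "character",
    na.strings = ".", quote = "", comment.char = ""
  )
  missing_cols <- setdiff(PED_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("pedigree file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  raw <- raw[PED_COLUMNS]
  n <- nrow(raw)
  parse_num <- function(x, what, allowed = NULL) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      stop("parse error at line ", bad[1] + 1L, ": bad ", what, " '", x[bad[1]], "'")
    }
    if (!is.null(allowed)) {
      bad <- which(!is.na(out) & !out %in% allowed)
      if (length(bad)) {
        stop("parse error at line ", bad[1] + 1L, ": ", what, " must be one of ",
             paste(allowed, collapse = "/"))
      }
    }
    out
  }
  df <- data.frame(
    family_id = raw$family_id,
    individual_id = raw$individual_id,
    father_id = raw$father_id,
    mother_id = raw$mother_id,
    sex = ifelse(is.na(raw$sex), "unknown", raw$sex),
    status = parse_num(raw$status, "status", c(0, 1)),
    age = parse_num(raw$age, "age"),
    proband = parse_num(raw$proband, "proband flag", c(0, 1)) == 1,
    apoe = raw$apoe,
    sorl1 = parse_num(raw$sorl1, "sorl1", c(0, 1)),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$family_id) || anyNA(df$individual_id)) {
    stop("family_id and individual_id may not be missing")
  }
  df$proband[is.na(df$proband)] <- FALSE
  bad_age <- which(!is.na(df$age) & df$age <= 0)
  if (length(bad_age)) stop("parse error at line ", bad_age[1] + 1L, ": age must be positive")
  bad_sex <- which(!df$sex %in% c("male", "female", "unknown"))
  if (length(bad_sex)) {
    stop("parse error at line ", bad_sex[1] + 1L, ": sex must be male/female/unknown or .")
  }
  peds <- lapply(split(df, df$family_id), new_pedigree)
  for (p in peds) validate_pedigree(p)
  peds[unique(df$family_id)]
}

#' Write pedigrees to the tab-separated dialect
#'
#' Inverse of \code{\link{read_pedigrees}}: writing then re-reading preserves
#' every field.
#'
#' @param peds a \code{pedigree} or list of pedigrees.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_pedigrees <- function(peds, path) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  df <- do.call(rbind, lapply(peds, as.data.frame))
  out <- data.frame(
    family_id = df$family_id,
    individual_id = df$individual_id,
    father_id = ifelse(is.na(df$father_id), ".", df$father_id),
    mother_id = ifelse(is.na(df$mother_id), ".", df$mother_id),
    sex = df$sex,
    status = ifelse(is.na(df$status), ".", as.character(df$status)),
    age = ifelse(is.na(df$age), ".", format(df$age, digits = 15, trim = TRUE,
                                            scientific = FALSE)),
    proband = as.integer(df$proband),
    apoe = ifelse(is.na(df$apoe), ".", df$apoe),
    sorl1 = ifelse(is.na(df$sorl1), ".", as.character(df$sorl1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate the structure of a pedigree
#'
#' Checks identifier uniqueness, parent resolution (both parents present or
#' both absent; references resolve within the family; no individual is their
#' own ancestor), proband constraints (at most one; an observed carrier), and
#' rejects pedigrees whose marriage-node graph has loops (consanguineous or
#' multiple-marriage cycles), which exact peeling does not support.
#'
#' @param ped a \code{pedigree}.
#' @return \code{ped}, invisibly; errors describe the violation.
#' @export
validate_pedigree <- function(ped) {
  fam <- ped$family_id[1]
  if (any(ped$family_id != fam)) stop("pedigree mixes family ids")
  if (anyDuplicated(ped$individual_id)) {
    stop("family ", fam, ": duplicated individual_id")
  }
  has_f <- !is.na(ped$father_id)
  has_m <- !is.na(ped$mother_id)
  if (any(has_f != has_m)) {
    stop("family ", fam, ": individuals must have both parents or neither")
  }
  idx <- match(ped$father_id, ped$individual_id)
  if (any(has_f & is.na(idx))) {
    stop("family ", fam, ": unresolved father_id '",
         ped$father_id[which(has_f & is.na(idx))[1]], "'")
  }
  idxm <- match(ped$mother_id, ped$individual_id)
  if (any(has_m & is.na(idxm))) {
    stop("family ", fam, ": unresolved mother_id '",
         ped$mother_id[which(has_m & is.na(idxm))[1]], "'")
  }
  if (any(has_f & (ped$father_id == ped$individual_id |
                     ped$mother_id == ped$individual_id))) {
    stop("family ", fam, ": individual is its own parent")
  }
  # acyclicity of the parent-child digraph: iteratively strip leaves
  n <- nrow(ped)
  parent <- cbind(idx, idxm)
  depth <- rep(NA_real_, n)
  depth[!has_f] <- 0
  for (it in seq_len(n + 1)) {
    ready <- is.na(depth) & !is.na(depth[parent[, 1]]) & !is.na(depth[parent[, 2]])
    if (!any(ready)) break
    depth[ready] <- pmax(depth[parent[ready, 1]], depth[parent[ready, 2]]) + 1
  }
  if (anyNA(depth)) stop("family ", fam, ": parent-child graph has a cycle")
  if (sum(ped$proband) > 1) stop("family ", fam, ": more than one proband")
  if (any(ped$proband & (is.na(ped$sorl1) | ped$sorl1 != 1))) {
    stop("family ", fam, ": the proband must be an observed carrier (sorl1 = 1)")
  }
  fg <- family_graph(ped)
  if (fg$n_edges != fg$n_nodes - fg$n_components) {
    stop("family ", fam, ": pedigree has a marriage/inbreeding loop, ",
         "which exact peeling does not support")
  }
  invisible(ped)
}

# Nuclear-family ("marriage node") bipartite graph: one node per individual,
# one node per couple-with-children; edges connect each nuclear family to its
# two parents and its children.  Loop-free pedigree <=> this graph is a forest.
family_graph <- function(ped) {
  n <- nrow(ped)
  fa <- match(ped$father_id, ped$individual_id)
  mo <- match(ped$mother_id, ped$individual_id)
  nonf <- which(!is.na(fa))
  key <- paste(fa[nonf], mo[nonf])
  fams <- split(nonf, key)
  nucl <- lapply(fams, function(children) {
    list(father = fa[children[1]], mother = mo[children[1]], children = children)
  })
  nucl <- unname(nucl)
  k <- length(nucl)
  edges_from <- integer(0) # individual node
  edges_to <- integer(0)   # nuclear node (1..k)
  for (j in seq_len(k)) {
    mem <- c(nucl[[j]]$father, nucl[[j]]$mother, nucl[[j]]$children)
    edges_from <- c(edges_from, mem)
    edges_to <- c(edges_to, rep(j, length(mem)))
  }
  # connected components over n + k nodes (individuals then nuclear nodes)
  comp <- seq_len(n + k)
  find <- function(x) {
    while (comp[x] != x) {
      comp[x] <<- comp[comp[x]]
      x <- comp[x]
    }
    x
  }
  for (e in seq_along(edges_from)) {
    a <- find(edges_from[e])
    b <- find(n + edges_to[e])
    if (a != b) comp[a] <- b
  }
  roots <- vapply(seq_len(n + k), find, integer(1))
  list(
    nuclear = nucl,
    n_nodes = n + k,
    n_edges = length(edges_from),
    n_components = length(unique(roots)),
    component = roots
  )
}

#' Phenotype-informative members of a pedigree
#'
#' An individual is phenotype-informative when their disease status is known
#' and their age (onset or censoring) is at least \code{min_age} -- the usual
#' floor below which the baseline hazard is not defined.  Probands are
#' returned with their flag set so that downstream steps can keep them out of
#' the estimating sums (they inform pedigree structure only, as the
#' ascertainment correction requires).
#'
#' @param ped a \code{pedigree}.
#' @param min_age informativeness floor in years (default 40).
#' @return the subset of rows of \code{ped} that are informative, with the
#'   \code{proband} column indicating the structure-only role.
#' @export
informative_members <- function(ped, min_age = 40) {
  if (min_age < 0) stop("min_age must be >= 0")
  keep <- !is.na(ped$status) & !is.na(ped$age) & ped$age >= min_age
  out <- ped[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Founder / non-founder counts
#' @param ped a \code{pedigree}.
#' @return named integer vector with \code{founders} and \code{nonfounders}.
#' @export
pedigree_counts <- function(ped) {
  f <- sum(is.na(ped$father_id))
  c(founders = f, nonfounders = nrow(ped) - f)
}
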