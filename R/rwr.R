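# Phenotype similarity: random walk with restart on the gene/phenotype
# association network, profiles restricted to phenotype nodes, compared by
# absolute Pearson correlation.

# Row-stochastic transition matrix (out-edge normalization) and the list of
# dangling nodes (no out-edges). Returned transposed, ready for M^T %*% p.
build_transition <- function(network) {
  ids <- network$nodes$id
  idx <- setNames(seq_along(ids), ids)
  e <- network$edges
  if (nrow(e) > 0) {
    i <- idx[e$from]
    j <- idx[e$to]
    out_w <- tapply(e$weight, i, sum)
    w <- e$weight / out_w[as.character(i)]
    M_t <- Matrix::sparseMatrix(i = j, j = i, x = as.numeric(w),
                                dims = c(length(ids), length(ids)))
  } else {
    M_t <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(ids), length(ids)))
  }
  dangling <- setdiff(seq_along(ids), unique(idx[e$from]))
  list(M_t = M_t, dangling = dangling, ids = ids, idx = idx)
}

#' Random walk with restart on an association network
#'
#' Iterates \eqn{p_{s+1} = (1 - r) M^T p_s + r p_0} from a uniform seed
#' distribution \eqn{p_0} until the max-norm difference between successive
#' vectors drops below `tol`. `M` row-normalizes out-edge weights per node;
#' a dangling node (no out-edges) redistributes its mass to the seed vector,
#' which keeps the iterate a probability distribution.
#'
#' @param network an `association_network`.
#' @param seeds non-empty character vector of node ids; all must be in the
#'   network.
#' @param restart restart probability r (default 0.7).
#' @param tol convergence tolerance on the max-norm step difference
#'   (default 1e-5).
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   final residual.
#' @return named numeric vector of steady-state probabilities over all
#'   nodes, summing to 1 (within 10 * tol), with attributes `iterations`
#'   and `residual`.
#' @export
rwr <- function(network, seeds, restart = 0.7, tol = 1e-5, max_iter = 1000L) {
  stopifnot(inherits(network, "association_network"))
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0) stop("seed set is empty", call. = FALSE)
  tr <- build_transition(network)
  missing <- setdiff(seeds, tr$ids)
  if (length(missing) == length(seeds)) {
    stop("no seed node present in the network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(missing) > 0) {
    warning("seed(s) not in network dropped: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  seeds <- setdiff(seeds, missing)
  n <- length(tr$ids)
  p0 <- numeric(n)
  p0[tr$idx[seeds]] <- 1 / length(seeds)
  p <- p0
  for (s in seq_len(max_iter)) {
    dangling_mass <- if (length(tr$dangling) > 0) sum(p[tr$dangling]) else 0
    p_next <- (1 - restart) *
      (as.numeric(tr$M_t %*% p) + dangling_mass * p0) + restart * p0
    delta <- max(abs(p_next - p))
    p <- p_next
    if (delta < tol) {
      names(p) <- tr$ids
      attr(p, "iterations") <- s
      attr(p, "residual") <- delta
      return(p)
    }
  }
  stop("random walk did not converge in ", max_iter,
       " iterations (final residual ", format(delta), ")", call. = FALSE)
}

#' Phenotype profile of a compound
#'
#' Seeds the random walk at the compound's target genes and keeps the
#' steady-state scores of the phenotype nodes only. A compound with no
#' target among the network's gene nodes carries a missing-phenotype signal
#' (NULL).
#'
#' @param compound a row of a `compound_set` (or list with `id`, `targets`).
#' @param network an `association_network` with at least one phenotype node.
#' @param restart,tol,max_iter passed to [rwr()].
#' @return a `phenotype_profile`: named numeric vector over phenotype nodes
#'   with attribute `compound_id`, or NULL.
#' @export
phenotype_profile <- function(compound, network, restart = 0.7, tol = 1e-5,
                              max_iter = 1000L) {
  phen <- network$nodes$id[network$nodes$kind == "phenotype"]
  if (length(phen) == 0) {
    stop("network has no phenotype nodes", call. = FALSE)
  }
  genes <- network$nodes$id[network$nodes$kind == "gene"]
  seeds <- intersect(unlist(compound$targets, use.names = FALSE), genes)
  if (length(seeds) == 0) return(NULL)
  p <- rwr(network, seeds, restart = restart, tol = tol, max_iter = max_iter)
  profile <- p[phen]
  attr(profile, "compound_id") <- if (!is.null(compound$id)) compound$id else NA
  class(profile) <- "phenotype_profile"
  profile
}

#' Phenotype similarity of two profiles
#'
#' Absolute Pearson correlation of the two phenotype score vectors. A
#' zero-variance (flat) profile on either side makes the correlation
#' undefined; such a profile is uninformative and the similarity is 0.
#'
#' @param profile_a,profile_b `phenotype_profile`s over the same phenotype
#'   index set (fatal otherwise).
#' @return similarity in \[0, 1\], or NA if either profile is NULL.
#' @export
phenotype_similarity <- function(profile_a, profile_b) {
  if (is.null(profile_a) || is.null(profile_b)) return(NA_real_)
  a <- unclass(profile_a)
  b <- unclass(profile_b)
  if (length(a) != length(b) || !identical(names(a), names(b))) {
    stop("phenotype profiles are indexed by different phenotype sets",
         call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    message("flat phenotype profile; similarity set to 0")
    return(0)
  }
  min(1, abs(cor(as.numeric(a), as.numeric(b))))
}
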