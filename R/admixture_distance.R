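# Supervised admixture estimation against a fixed ancestral panel, the
# minimal-Euclidean admixture distance d, the d < tau threshold graph, and
# per-group component summaries.

#' Estimate admixture proportions against fixed ancestral frequencies
#'
#' Solves the simplex-constrained least-squares problem
#' `argmin_{q >= 0, sum q = 1} sum_l (dosage_l / 2 - sum_k q_k F_lk)^2`
#' with a primal active-set scheme (equality-constrained KKT solves over the
#' free components, blocking-constraint line steps, multiplier-based
#' releases). The iterate objective is monotonically non-increasing; the
#' solver stops at the exact KKT point of the final active set (further
#' objective decrease below `tol` is then impossible; `tol` also bounds the
#' numerical slack of the optimality checks).
#'
#' @param dosages numeric vector of L unphased dosages in `[0, 2]` (`NA`
#'   cells are dropped together with the matching F rows).
#' @param F an [ancestral_frequencies()] panel with L rows.
#' @param tol convergence tolerance on the per-step objective decrease
#'   (default 1e-10).
#' @param max_iter iteration cap (default 200).
#' @return a length-K admixture vector on the simplex, named by component;
#'   attributes: `objective` (final value), `trace` (objective per accepted
#'   iterate), `iterations`.
#' @export
estimate_admixture <- function(dosages, F, tol = 1e-10, max_iter = 200L) {
  stopifnot(inherits(F, "ancestral_frequencies"))
  if (length(dosages) != nrow(F$F))
    stop("dosage length (", length(dosages), ") != markers in F (",
         nrow(F$F), ")")
  ok <- !is.na(dosages)
  y <- dosages[ok] / 2
  Fm <- F$F[ok, , drop = FALSE]
  K <- ncol(Fm)
  A <- crossprod(Fm)                    # K x K
  b <- drop(crossprod(Fm, y))
  cy <- sum(y^2)
  obj <- function(q) drop(q %*% A %*% q) - 2 * sum(b * q) + cy

  q <- rep(1 / K, K)
  free <- rep(TRUE, K)
  trace <- obj(q)
  eps <- 1e-12
  for (it in seq_len(max_iter)) {
    f <- which(free)
    nf <- length(f)
    # KKT system for min over {q_f : 1'q_f = 1}, active components fixed at 0
    M <- rbind(cbind(2 * A[f, f, drop = FALSE], rep(1, nf)),
               c(rep(1, nf), 0))
    rhs <- c(2 * b[f], 1)
    sol <- tryCatch(solve(M, rhs), error = function(e)
      stop("admixture solver: singular KKT system; ",
           "check F for near-duplicate components"))
    q_new_f <- sol[seq_len(nf)]
    lambda <- sol[nf + 1L]

    if (all(q_new_f >= -eps)) {
      q_next <- numeric(K)
      q_next[f] <- pmax(q_new_f, 0)
      q_next <- q_next / sum(q_next)
      # multipliers of the active bounds: can releasing one help?
      g <- 2 * drop(A %*% q_next) - 2 * b + lambda
      act <- which(!free)
      improvable <- act[g[act] < -1e-9]
      q <- q_next
      trace <- c(trace, obj(q))
      if (length(improvable) == 0L) break   # KKT-optimal active set
      free[improvable[which.min(g[improvable])]] <- TRUE
    } else {
      # step toward the equality solution until the first bound blocks
      q_f <- q[f]
      d <- q_new_f - q_f
      blocking <- which(q_new_f < -eps)
      alpha <- min(q_f[blocking] / (q_f[blocking] - q_new_f[blocking]))
      q_f <- q_f + alpha * d
      q_f[q_f < eps] <- 0
      q[f] <- q_f
      q <- q / sum(q)
      newly_active <- f[blocking][which.min(q_f[blocking])]
      free[newly_active] <- FALSE
      if (sum(free) == 0L) stop("admixture solver: all components bound")
      trace <- c(trace, obj(q))
    }
    if (it == max_iter)
      stop("admixture solver failed to converge in ", max_iter,
           " iterations; final objective ", signif(obj(q), 6))
  }
  names(q) <- F$component_names
  structure(q, objective = obj(q), trace = trace,
            iterations = length(trace) - 1L)
}

#' Estimate admixture for every sample of a genotype matrix
#'
#' @param G a [genotype_matrix()].
#' @param F an [ancestral_frequencies()] panel.
#' @param ... passed to [estimate_admixture()].
#' @return an n x K matrix of admixture proportions.
#' @export
estimate_admixture_matrix <- function(G, F, ...) {
  stopifnot(inherits(G, "genotype_matrix"))
  Q <- t(vapply(seq_along(G$samples), function(i)
    as.numeric(estimate_admixture(G$dosages[i, ], F, ...)),
    numeric(ncol(F$F))))
  dimnames(Q) <- list(G$samples, F$component_names)
  Q
}

#' Admixture genomic distance d
#'
#' The minimal Euclidean distance between one individual's admixture vector
#' and those of all members of a target population (point-to-set; not
#' symmetric in its roles).
#'
#' @param q a length-K admixture vector.
#' @param population_Q matrix of member admixture vectors (rows), K columns.
#' @return the minimum Euclidean distance, `>= 0`.
#' @export
admixture_distance <- function(q, population_Q) {
  population_Q <- as.matrix(population_Q)
  if (nrow(population_Q) == 0L) stop("population is empty")
  if (ncol(population_Q) != length(q))
    stop("q and population members differ in K")
  sqrt(min(colSums((t(population_Q) - as.numeric(q))^2)))
}

#' Build the thresholded admixture-distance graph
#'
#' Nodes are individuals; an undirected edge of weight
#' `d = ||q_a - q_b||_2` joins every pair with `d < tau` (strict
#' inequality). Connected components and degrees are computed with igraph.
#'
#' @param Q matrix of admixture vectors (rows = individuals).
#' @param ids node identifiers (default rownames or `I1..In`).
#' @param populations optional per-node population tags.
#' @param tau distance threshold (default 0.075, the short-distance cutoff).
#' @return a list with class `distance_graph`: `nodes` (id, population),
#'   `edges` (from, to, d), `tau`, `graph` (igraph object), `components`
#'   (membership vector), `degree` (named vector).
#' @export
build_distance_graph <- function(Q, ids = NULL, populations = NULL,
                                 tau = 0.075) {
  Q <- as.matrix(Q)
  if (tau <= 0 && tau != 0) stop("tau must be >= 0")
  n <- nrow(Q)
  if (is.null(ids)) ids <- rownames(Q)
  if (is.null(ids)) ids <- paste0("I", seq_len(n))
  if (is.null(populations)) populations <- rep("", n)
  D <- as.matrix(stats::dist(Q))
  pair <- which(upper.tri(D) & D < tau, arr.ind = TRUE)
  edges <- data.frame(from = ids[pair[, 1L]], to = ids[pair[, 2L]],
                      d = D[pair], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, population = populations))
  comp <- igraph::components(g)$membership
  structure(list(nodes = data.frame(id = ids, population = populations,
                                    stringsAsFactors = FALSE),
                 edges = edges, tau = tau, graph = g,
                 components = comp, degree = igraph::degree(g)),
            class = "distance_graph")
}

#' @export
print.distance_graph <- function(x, ...) {
  cat("distance_graph: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (d < ", x$tau, "), ", max(x$components),
      " connected component(s)\n", sep = "")
  invisible(x)
}

#' Population-level distance to a reference cohort
#'
#' Repo convention for aggregate reporting: the median of member-wise
#' [admixture_distance()] values of a group against the reference cohort.
#'
#' @param Q_group matrix of the group's admixture vectors.
#' @param reference_Q matrix of the reference cohort's vectors.
#' @return the median member-wise minimal distance.
#' @export
population_distance <- function(Q_group, reference_Q) {
  stats::median(apply(as.matrix(Q_group), 1L, admixture_distance,
                      population_Q = reference_Q))
}

#' Per-group component means and SDs, in percent
#'
#' @param Q matrix of admixture proportions (rows sum to 1).
#' @param grouping factor/character grouping of rows (a partition; default:
#'   one group).
#' @return data.frame with columns `group`, `component`, `mean_pct`,
#'   `sd_pct`. Groups of size < 2 report SD 0 with a warning. Component
#'   means of each group sum to 100 within numerical tolerance.
#' @export
cohort_component_summary <- function(Q, grouping = NULL) {
  Q <- as.matrix(Q)
  if (is.null(grouping)) grouping <- rep("all", nrow(Q))
  grouping <- as.character(grouping)
  if (length(grouping) != nrow(Q)) stop("grouping length != rows of Q")
  comps <- colnames(Q)
  if (is.null(comps)) comps <- paste0("C", seq_len(ncol(Q)))
  out <- list()
  for (grp in unique(grouping)) {
    rows <- Q[grouping == grp, , drop = FALSE] * 100
    sds <- if (nrow(rows) < 2L) {
      warning("group '", grp, "' has fewer than 2 members; SD reported as 0")
      rep(0, ncol(rows))
    } else apply(rows, 2L, stats::sd)
    out[[grp]] <- data.frame(group = grp, component = comps,
                             mean_pct = colMeans(rows), sd_pct = sds,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Format a component summary the way results paragraphs read
#'
#' E.g. `"Mediterranean (57.7 +/- 1.2)"`, one string per group.
#'
#' @param summary output of [cohort_component_summary()].
#' @param digits digits after the decimal point (default 1).
#' @return named character vector, one entry per group.
#' @export
format_component_summary <- function(summary, digits = 1L) {
  vapply(split(summary, summary$group), function(s)
    paste(sprintf("%s (%.*f ± %.*f)", s$component, digits, s$mean_pct,
                  digits, s$sd_pct), collapse = ", "),
    character(1L))
}
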