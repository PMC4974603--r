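# Synthetic stand-ins for the unreleased reference data: Balding-Nichols
# ancestral allele-frequency profiles, admixed founders with phased
# haplotypes, and simulated reference cohorts of admixture vectors.

DEFAULT_COMPONENTS <- c("Mediterranean", "SouthWestAsian",
                        "SubSaharanAfrican", "NorthernEuropean",
                        "SouthEastAsian", "NorthEastAsian", "NativeAmerican",
                        "Oceanian", "Siberian")

#' Construct an ancestral allele-frequency panel
#'
#' `F` holds one allele frequency per marker (row) per ancestral component
#' (column), used both to synthesize admixed founders and as the fixed
#' reference panel of supervised admixture estimation.
#'
#' @param F numeric matrix in `[0, 1]`, L markers x K components.
#' @param component_names K component labels (default: the nine-component
#'   panel headed by Mediterranean, South West Asian, Sub-Saharan African and
#'   Northern European when K = 9, else `C1..CK`).
#' @return an object of class `ancestral_frequencies`.
#' @export
ancestral_frequencies <- function(F, component_names = NULL) {
  F <- as.matrix(F)
  if (ncol(F) < 1L) stop("K must be >= 1")
  if (any(F < 0 | F > 1)) stop("allele frequencies must lie in [0, 1]")
  if (is.null(component_names))
    component_names <- if (ncol(F) == 9L) DEFAULT_COMPONENTS
                       else paste0("C", seq_len(ncol(F)))
  if (length(component_names) != ncol(F))
    stop("component_names length != K")
  # identifiability guard: no two columns may coincide
  if (ncol(F) > 1L) {
    for (i in seq_len(ncol(F) - 1L)) for (j in (i + 1L):ncol(F))
      if (sqrt(sum((F[, i] - F[, j])^2)) < 1e-12)
        stop("components ", component_names[i], " and ", component_names[j],
             " have identical frequency profiles")
  }
  colnames(F) <- component_names
  structure(list(F = F, component_names = component_names),
            class = "ancestral_frequencies")
}

#' @export
print.ancestral_frequencies <- function(x, ...) {
  cat("ancestral_frequencies: ", nrow(x$F), " markers x ", ncol(x$F),
      " components (", paste(x$component_names, collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Sample ancestral allele frequencies under a Balding-Nichols model
#'
#' Per marker, an ancestral frequency `p ~ Uniform(0.05, 0.95)` is drawn and
#' each component frequency follows
#' `Beta(p (1 - fst) / fst, (1 - p)(1 - fst) / fst)`, so that
#' `E[f | p] = p` and `Var(f | p) = p (1 - p) fst`.
#'
#' @param K number of ancestral components (>= 1).
#' @param L number of markers (>= 1).
#' @param fst divergence parameter in (0, 1).
#' @param seed integer root seed (substream `"ancestral_frequencies"`).
#' @param component_names optional component labels.
#' @return an [ancestral_frequencies()] panel.
#' @export
sample_ancestral_frequencies <- function(K, L, fst = 0.1, seed = 1L,
                                         component_names = NULL) {
  if (!is.numeric(fst) || length(fst) != 1L || fst <= 0 || fst >= 1)
    stop("fst must lie strictly in (0, 1)")
  if (L < 1L) stop("L must be >= 1")
  with_seed(derive_seed(seed, "ancestral_frequencies"), {
    p <- stats::runif(L, 0.05, 0.95)
    a <- p * (1 - fst) / fst
    b <- (1 - p) * (1 - fst) / fst
    F <- matrix(stats::rbeta(L * K, rep(a, K), rep(b, K)), nrow = L, ncol = K)
    ancestral_frequencies(F, component_names)
  })
}

#' Generate admixed founders with phased haplotypes
#'
#' For founder `i` at marker `l`, each of the two haplotype alleles is an
#' independent `Bernoulli(sum_k q_ik F_lk)` draw; the dosage is the haplotype
#' sum, so founders are born phased and haplotype sums reproduce dosages
#' exactly.
#'
#' @param F an [ancestral_frequencies()] panel (L x K).
#' @param q_assignments numeric matrix n x K of admixture vectors (rows on
#'   the simplex) or a single vector recycled to all founders.
#' @param seed integer root seed (substream `"founders"`).
#' @param meta optional [sample_meta()]; defaults to sex-balanced,
#'   half-labeled founders `F001..` (alternating male/female, first half
#'   labeled).
#' @param n_chromosomes spread markers evenly over this many chromosomes
#'   (default 1).
#' @return a list: `genotypes` ([genotype_matrix()]), `haplotypes` (named
#'   list of 2 x L 0/1 matrices), `meta` ([sample_meta()]), `q` (the n x K
#'   matrix used).
#' @export
generate_founders <- function(F, q_assignments, seed = 1L, meta = NULL,
                              n_chromosomes = 1L) {
  stopifnot(inherits(F, "ancestral_frequencies"))
  Q <- if (is.matrix(q_assignments)) q_assignments
       else matrix(q_assignments, nrow = 1L)
  if (ncol(Q) != ncol(F$F))
    stop("q has ", ncol(Q), " components but F has ", ncol(F$F))
  if (any(Q < -1e-9) || any(abs(rowSums(Q) - 1) > 1e-9))
    stop("each q assignment must be nonnegative and sum to 1")
  n <- nrow(Q); L <- nrow(F$F)

  P <- Q %*% t(F$F)                       # n x L expected allele frequencies
  P <- pmin(pmax(P, 0), 1)
  ids <- sprintf("F%03d", seq_len(n))
  if (is.null(meta)) {
    meta <- sample_meta(ids,
                        sex = rep(c("male", "female"), length.out = n),
                        label = ifelse(seq_len(n) <= n / 2,
                                       "labeled", "unlabeled"),
                        population = "synthetic")
  } else {
    if (nrow(meta) != n) stop("meta rows != number of founders")
    ids <- meta$sample_id
  }

  chrom <- rep(seq_len(n_chromosomes), length.out = L)
  chrom <- sort(chrom)
  pos <- stats::ave(seq_len(L), chrom, FUN = seq_along)
  mk <- marker_info(chrom, pos, sprintf("m%06d", seq_len(L)),
                    rep("A", L), rep("G", L))

  with_seed(derive_seed(seed, "founders"), {
    h1 <- matrix(stats::rbinom(n * L, 1L, as.vector(P)), n, L)
    h2 <- matrix(stats::rbinom(n * L, 1L, as.vector(P)), n, L)
  })
  haps <- lapply(seq_len(n), function(i) rbind(h1[i, ], h2[i, ]))
  names(haps) <- ids
  list(genotypes = genotype_matrix(h1 + h2, ids, mk),
       haplotypes = haps, meta = meta, q = Q)
}

#' Define a component sampling specification
#'
#' Per-component location and scale in percent units plus a sampling family,
#' used by [sample_reference_cohort()]. `"truncated_normal"` draws
#' `Normal(location, scale)` truncated at zero (by rejection);
#' `"uniform_range"` draws `Uniform(location - scale, location + scale)`
#' clipped below at zero.
#'
#' @param component character component names.
#' @param location nonnegative per-component locations (percent).
#' @param scale nonnegative per-component scales (percent).
#' @param family `"truncated_normal"` (default) or `"uniform_range"`,
#'   recycled across components.
#' @return a `data.frame` with class `component_spec`.
#' @export
component_spec <- function(component, location, scale,
                           family = "truncated_normal") {
  family <- rep_len(match.arg(family, c("truncated_normal", "uniform_range"),
                              several.ok = TRUE), length(component))
  if (any(location < 0)) stop("locations must be >= 0")
  if (any(scale < 0)) stop("scales must be >= 0")
  df <- data.frame(component = as.character(component),
                   location = as.numeric(location),
                   scale = as.numeric(scale),
                   family = family, stringsAsFactors = FALSE)
  class(df) <- c("component_spec", "data.frame")
  df
}

#' Default Israelite reference-cohort specification
#'
#' The shipped nine-component specification for the simulated Israelite
#' ("juedische Typus" proxy) cohort. The four major components use the
#' published means and standard deviations in percent --- Mediterranean
#' 57.7 +/- 1.2, South West Asian 23.9 +/- 0.6, Sub-Saharan African
#' 9.4 +/- 0.5, Northern European 3.2 +/- 1.3 --- and the five minor
#' components split the residual mass (100 - 94.2 = 5.8) into equal shares
#' of 1.16 with SD 0.5, keeping the normalization step non-trivial.
#'
#' @return a [component_spec()] with 9 rows.
#' @export
israelite_spec <- function() {
  major_loc <- c(57.7, 23.9, 9.4, 3.2)
  major_sd <- c(1.2, 0.6, 0.5, 1.3)
  minor_loc <- rep((100 - sum(major_loc)) / 5, 5)
  component_spec(DEFAULT_COMPONENTS,
                 location = c(major_loc, minor_loc),
                 scale = c(major_sd, rep(0.5, 5)))
}

#' Read / write a component spec as a JSON config file
#'
#' @param spec a [component_spec()] (for writing).
#' @param path file path.
#' @return `read_component_spec` returns a [component_spec()].
#' @export
write_component_spec <- function(spec, path) {
  stopifnot(inherits(spec, "component_spec"))
  jsonlite::write_json(as.data.frame(spec), path, pretty = TRUE)
  invisible(path)
}

#' @rdname write_component_spec
#' @export
read_component_spec <- function(path) {
  df <- jsonlite::fromJSON(path)
  component_spec(df$component, df$location, df$scale, df$family)
}

#' Sample a reference cohort of admixture vectors
#'
#' Draws each component independently from its configured family (truncated
#' at zero), then normalizes each vector to sum to 1. This emulates building
#' a simulated reference population from per-component admixture ranges.
#'
#' @param n cohort size (>= 1).
#' @param spec a [component_spec()]; default [israelite_spec()].
#' @param seed integer root seed (substream `"reference_cohort"`).
#' @return an n x K matrix of admixture proportions (rows sum to 1), columns
#'   named by component.
#' @export
sample_reference_cohort <- function(n, spec = israelite_spec(), seed = 1L) {
  stopifnot(inherits(spec, "component_spec"), n >= 1L)
  K <- nrow(spec)
  with_seed(derive_seed(seed, "reference_cohort"), {
    draw_all <- function(m) {
      X <- matrix(0, m, K)
      for (k in seq_len(K)) {
        if (spec$family[k] == "truncated_normal") {
          x <- stats::rnorm(m, spec$location[k], spec$scale[k])
          bad <- x < 0
          tries <- 0L
          while (any(bad)) {          # rejection below zero
            tries <- tries + 1L
            if (tries > 100L) stop("truncation rejection did not converge")
            x[bad] <- stats::rnorm(sum(bad), spec$location[k], spec$scale[k])
            bad <- x < 0
          }
        } else {
          x <- stats::runif(m, spec$location[k] - spec$scale[k],
                            spec$location[k] + spec$scale[k])
          x <- pmax(x, 0)
        }
        X[, k] <- x
      }
      X
    }
    X <- draw_all(n)
    s <- rowSums(X)
    attempts <- 0L
    while (any(s == 0)) {             # all-zero vector: redraw those rows
      attempts <- attempts + 1L
      if (attempts > 100L) stop("could not draw a nonzero admixture vector")
      X[s == 0, ] <- draw_all(sum(s == 0))
      s <- rowSums(X)
    }
    Q <- X / s
    colnames(Q) <- spec$component
    Q
  })
}
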