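# Shared fixtures, all built in code at test time.

# Hand-written 2-sample, 3-marker .ped/.map pair. Sample S2 comes first in
# the file and carries allele A at every marker, so the counted
# (first-observed) allele is A throughout; S1's genotypes "A A, A G, G G"
# then encode to the dosage row c(2, 1, 0).
write_toy_plink <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ped <- c("FAM1 S2 0 0 2 -9 A G A G A A",
           "FAM1 S1 0 0 1 -9 A A A G G G")
  map <- c("1\trs1\t0\t100", "1\trs2\t0\t200", "1\trs3\t0\t300")
  ped_path <- file.path(dir, "toy.ped")
  map_path <- file.path(dir, "toy.map")
  writeLines(ped, ped_path)
  writeLines(map, map_path)
  list(ped = ped_path, map = map_path)
}

# Random valid genotype matrix for property-style round-trip tests.
random_genotype_matrix <- function(n, L, missing_rate = 0, n_chrom = 1L) {
  dos <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
  if (missing_rate > 0)
    dos[stats::runif(n * L) < missing_rate] <- NA_integer_
  chrom <- sort(rep(seq_len(n_chrom), length.out = L))
  pos <- stats::ave(seq_len(L), chrom, FUN = seq_along) * 10L
  alle <- matrix(replicate(L, sample(c("A", "C", "G", "T"), 2L)), nrow = 2L)
  mk <- marker_info(chrom, pos, sprintf("rs%04d", seq_len(L)),
                    alle[1L, ], alle[2L, ])
  genotype_matrix(dos, sprintf("S%03d", seq_len(n)), mk)
}

# The worked two-generation pedigree: unlabeled African male x labeled
# Yemenite female -> son; son x unlabeled Polish female (whose parents are
# unlabeled founders) -> terminal offspring.
worked_pedigree <- function() {
  pedigree(data.frame(
    id = c("afr_m", "yem_f", "pol_pa", "pol_ma", "son", "pol_f", "off"),
    sex = c("male", "female", "male", "female", "male", "female", "male"),
    mother_id = c(NA, NA, NA, NA, "yem_f", "pol_ma", "pol_f"),
    father_id = c(NA, NA, NA, NA, "afr_m", "pol_pa", "son"),
    generation = c(0L, 0L, 0L, 0L, 1L, 1L, 2L),
    founder_label = c("unlabeled", "labeled", "unlabeled", "unlabeled",
                      NA, NA, NA),
    stringsAsFactors = FALSE))
}

# Two-generation pedigree with 4 founder grandparents and one terminal
# offspring, with founder labels set from a length-4 logical vector
# (order: maternal grandmother, maternal grandfather, paternal grandmother,
# paternal grandfather).
four_grandparent_pedigree <- function(labels) {
  stopifnot(length(labels) == 4L)
  lab <- ifelse(labels, "labeled", "unlabeled")
  pedigree(data.frame(
    id = c("mgm", "mgf", "pgm", "pgf", "mo", "fa", "kid"),
    sex = c("female", "male", "female", "male", "female", "male", "female"),
    mother_id = c(NA, NA, NA, NA, "mgm", "pgm", "mo"),
    father_id = c(NA, NA, NA, NA, "mgf", "pgf", "fa"),
    generation = c(0L, 0L, 0L, 0L, 1L, 1L, 2L),
    founder_label = c(lab, NA, NA, NA),
    stringsAsFactors = FALSE))
}

# Small simulated founder set: K components, L markers, n founders with
# Dirichlet-ish admixture rows.
small_founders <- function(n = 30L, L = 2000L, K = 3L, fst = 0.2,
                           seed = 42L, n_chromosomes = 1L) {
  F <- sample_ancestral_frequencies(K, L, fst = fst, seed = seed)
  set.seed(seed)
  Q <- matrix(stats::rgamma(n * K, 1), n, K)
  Q <- Q / rowSums(Q)
  list(F = F,
       founders = generate_founders(F, Q, seed = seed,
                                    n_chromosomes = n_chromosomes),
       Q = Q)
}

# Brute-force oracle for windowed pruning on panels no wider than one
# window: repeatedly scan all pairs in index order, drop the later member of
# the first pair exceeding the threshold, restart until stable.
brute_force_prune <- function(dos, r2_threshold) {
  kept <- seq_len(ncol(dos))
  repeat {
    removed <- FALSE
    for (i in seq_along(kept)) {
      if (removed) break
      for (j in seq_along(kept)) {
        if (j <= i) next
        r2 <- genotype_r2(dos[, kept[i]], dos[, kept[j]])
        if (!is.na(r2) && r2 > r2_threshold) {
          kept <- kept[-j]
          removed <- TRUE
          break
        }
      }
    }
    if (!removed) return(kept)
  }
}
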