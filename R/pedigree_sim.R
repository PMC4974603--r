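# Forward-in-time hybridization simulator: founders are randomly paired
# male-female, each pair has a fixed number of offspring of random sex, and
# gametes copy whole parental-haplotype blocks between recombination hotspots
# placed every `hotspot_spacing` markers (restarting at chromosome
# boundaries). A sex-balanced cohort is selected from each offspring
# generation and paired for the next round.

#' Simulation configuration
#'
#' Defaults reproduce the benchmark design: 30 founders (15 male, 15 female,
#' half labeled), hotspots every 10,000 markers, 4 offspring per pair,
#' followed for 2 generations with a cohort of 30 selected per generation.
#'
#' @param n_founders even founder count.
#' @param hotspot_spacing recombination-hotspot spacing in markers (>= 1).
#' @param offspring_per_pair offspring per mated pair.
#' @param generations number of offspring generations to simulate (>= 0).
#' @param cohort_size individuals selected (sex-balanced) from each offspring
#'   generation to parent the next; must be even and no larger than the
#'   number of offspring produced.
#' @param seed integer root seed.
#' @return a list with class `sim_config`.
#' @export
sim_config <- function(n_founders = 30L, hotspot_spacing = 10000L,
                       offspring_per_pair = 4L, generations = 2L,
                       cohort_size = 30L, seed = 1L) {
  if (n_founders %% 2L != 0L) stop("n_founders must be even")
  if (hotspot_spacing < 1L) stop("hotspot_spacing must be >= 1")
  if (cohort_size %% 2L != 0L) stop("cohort_size must be even")
  n_pairs <- n_founders %/% 2L
  if (generations > 0L && cohort_size > n_pairs * offspring_per_pair)
    stop("cohort_size exceeds the number of offspring produced per round")
  structure(list(n_founders = as.integer(n_founders),
                 hotspot_spacing = as.integer(hotspot_spacing),
                 offspring_per_pair = as.integer(offspring_per_pair),
                 generations = as.integer(generations),
                 cohort_size = as.integer(cohort_size),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Construct a pedigree
#'
#' A pedigree is a table of individuals (id, sex, parent links, generation
#' index, founder label) plus optional phased haplotypes and marker metadata.
#' Founders (generation 0) have no parents and carry a `founder_label`;
#' non-founders have both parents present with the correct sexes.
#'
#' @param individuals data.frame with columns `id`, `sex`, `mother_id`,
#'   `father_id`, `generation`, `founder_label` (`NA` for non-founders).
#' @param haplotypes optional named list (by id) of 2 x L 0/1 matrices.
#' @param markers optional [marker_info()] describing the L markers.
#' @return an object of class `pedigree`.
#' @export
pedigree <- function(individuals, haplotypes = NULL, markers = NULL) {
  req <- c("id", "sex", "mother_id", "father_id", "generation",
           "founder_label")
  if (!all(req %in% names(individuals)))
    stop("individuals must have columns: ", paste(req, collapse = ", "))
  ind <- as.data.frame(individuals, stringsAsFactors = FALSE)
  ind$id <- as.character(ind$id)
  if (anyDuplicated(ind$id)) stop("duplicate individual ids")
  is_founder <- ind$generation == 0L
  if (any(is_founder & (!is.na(ind$mother_id) | !is.na(ind$father_id))))
    stop("founders must have no parents")
  if (any(is_founder & is.na(ind$founder_label)))
    stop("every founder needs a founder_label")
  if (any(is_founder & !ind$sex %in% c("male", "female")))
    stop("every founder needs sex 'male' or 'female'")
  nf <- which(!is_founder)
  mi <- match(ind$mother_id[nf], ind$id)
  fi <- match(ind$father_id[nf], ind$id)
  if (anyNA(mi) || anyNA(fi))
    stop("non-founder with parent(s) missing from the pedigree: ",
         paste(ind$id[nf][is.na(mi) | is.na(fi)], collapse = ", "))
  if (any(ind$sex[mi] != "female") || any(ind$sex[fi] != "male"))
    stop("parent sexes inconsistent with mother/father roles")
  if (!is.null(haplotypes)) {
    Ls <- unique(vapply(haplotypes, ncol, 0L))
    if (length(Ls) > 1L) stop("haplotype lengths differ across individuals")
    if (!is.null(markers) && Ls != nrow(markers))
      stop("haplotype length != number of markers")
  }
  structure(list(individuals = ind, haplotypes = haplotypes,
                 markers = markers),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  gens <- table(x$individuals$generation)
  cat("pedigree: ", nrow(x$individuals), " individuals (",
      paste(sprintf("gen %s: %d", names(gens), gens), collapse = "; "),
      ")", if (!is.null(x$haplotypes))
        sprintf("; phased over %d markers", ncol(x$haplotypes[[1L]])),
      "\n", sep = "")
  invisible(x)
}

#' Serialize / read a pedigree table as TSV
#'
#' Genotypes are not included; export them via [pedigree_genotypes()] and
#' [write_plink_text()].
#'
#' @param ped a [pedigree()] (for writing).
#' @param path file path.
#' @return `read_pedigree_table` returns a [pedigree()] without haplotypes.
#' @export
write_pedigree_table <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  utils::write.table(ped$individuals, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_table
#' @export
read_pedigree_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  df$generation <- as.integer(df$generation)
  df$mother_id[df$mother_id %in% c("", "NA")] <- NA_character_
  df$father_id[df$father_id %in% c("", "NA")] <- NA_character_
  df$founder_label[df$founder_label %in% c("", "NA")] <- NA_character_
  pedigree(df)
}

# Block index per marker: hotspots sit every `spacing` markers within each
# chromosome; blocks are half-open [0, s), [s, 2s), ... in 0-based
# within-chromosome marker index and restart at chromosome boundaries.
recomb_blocks <- function(markers, spacing) {
  if (spacing < 1L) stop("hotspot spacing must be >= 1")
  chr <- markers$chromosome
  within <- stats::ave(seq_along(chr), chr, FUN = seq_along) - 1L
  local_block <- within %/% spacing
  as.integer(factor(paste(chr, local_block, sep = ":"),
                    levels = unique(paste(chr, local_block, sep = ":"))))
}

#' Impute missing founder genotypes
#'
#' Each missing cell is filled by two independent Bernoulli draws at the
#' marker's pooled (non-missing) allele frequency. Needed because the
#' simulator requires complete haplotypes.
#'
#' @param G a [genotype_matrix()].
#' @param seed integer root seed (substream `"impute"`).
#' @return a complete `genotype_matrix`.
#' @export
impute_missing <- function(G, seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"))
  dos <- G$dosages
  miss <- which(is.na(dos), arr.ind = TRUE)
  if (nrow(miss) == 0L) return(G)
  p <- colMeans(dos, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0.5                   # fully missing marker
  with_seed(derive_seed(seed, "impute"), {
    dos[miss] <- stats::rbinom(nrow(miss), 2L, p[miss[, 2L]])
  })
  message("impute_missing: filled ", nrow(miss), " missing cell(s)")
  genotype_matrix(dos, G$samples, G$markers)
}

#' Phase founder genotypes into haplotype pairs
#'
#' Homozygous cells split deterministically (0 -> (0,0), 2 -> (1,1));
#' each heterozygous cell assigns the counted allele to haplotype 1 or 2 by
#' an independent fair coin. Haplotype sums reproduce dosages exactly.
#'
#' @param G a complete [genotype_matrix()] (impute first; missing cells are
#'   an error).
#' @param seed integer root seed (substream `"phase"`).
#' @return named list (by sample) of 2 x L 0/1 matrices.
#' @export
phase_founders <- function(G, seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (anyNA(G$dosages))
    stop("missing genotypes; run impute_missing() before phasing")
  dos <- G$dosages
  n <- nrow(dos); L <- ncol(dos)
  with_seed(derive_seed(seed, "phase"), {
    coin <- matrix(stats::rbinom(n * L, 1L, 0.5), n, L)
  })
  h1 <- (dos == 2L) + (dos == 1L) * coin
  h2 <- dos - h1
  haps <- lapply(seq_len(n), function(i) {
    m <- rbind(h1[i, ], h2[i, ]); storage.mode(m) <- "integer"; m
  })
  names(haps) <- G$samples
  haps
}

#' Form one gamete by block-wise haplotype copying
#'
#' For each recombination block independently, the gamete copies the
#' parent's haplotype 1 or 2 chosen uniformly; there is no within-block
#' recombination.
#'
#' @param haplotypes a 2 x L 0/1 matrix (one parent's phased genome).
#' @param blocks integer block index per marker, from `markers` +
#'   `spacing` (see [sim_config()]); precomputed for efficiency.
#' @param seed optional integer seed (substream `"gamete"`); if `NULL`, the
#'   current RNG state is used (for nested calls inside the simulator).
#' @return integer vector of L alleles.
#' @export
make_gamete <- function(haplotypes, blocks, seed = NULL) {
  stopifnot(is.matrix(haplotypes), nrow(haplotypes) == 2L,
            length(blocks) == ncol(haplotypes))
  draw <- function() {
    choice <- sample(2L, max(blocks), replace = TRUE)
    haplotypes[cbind(choice[blocks], seq_along(blocks))]
  }
  if (is.null(seed)) draw()
  else with_seed(derive_seed(seed, "gamete"), draw())
}

#' Mate a female-male pair
#'
#' Each offspring receives one maternal and one paternal gamete (independent
#' [make_gamete()] draws) and a fair-coin sex.
#'
#' @param mother,father lists with elements `id`, `sex` and `haplotypes`
#'   (2 x L matrix); `mother$sex` must be `"female"`, `father$sex` `"male"`.
#' @param n_offspring offspring count.
#' @param blocks integer block index per marker.
#' @param seed optional integer seed (substream `"mate"`); `NULL` uses the
#'   current RNG state.
#' @param id_prefix prefix for offspring ids.
#' @return list of offspring, each a list `id`, `sex`, `mother_id`,
#'   `father_id`, `haplotypes`.
#' @export
mate <- function(mother, father, n_offspring, blocks, seed = NULL,
                 id_prefix = "O") {
  if (!identical(mother$sex, "female") || !identical(father$sex, "male"))
    stop("mate() needs a female mother and a male father")
  produce <- function() {
    lapply(seq_len(n_offspring), function(k) {
      mg <- make_gamete(mother$haplotypes, blocks)
      pg <- make_gamete(father$haplotypes, blocks)
      list(id = paste0(id_prefix, k),
           sex = if (stats::rbinom(1L, 1L, 0.5) == 1L) "male" else "female",
           mother_id = mother$id, father_id = father$id,
           haplotypes = rbind(mg, pg))
    })
  }
  if (is.null(seed)) produce()
  else with_seed(derive_seed(seed, "mate"), produce())
}

#' Run the forward hybridization benchmark simulation
#'
#' Generation 0 founders are randomly paired male-female (monogamous, each
#' founder used once); each pair has `offspring_per_pair` children of random
#' sex; a sex-balanced cohort of `cohort_size` offspring is sampled
#' uniformly without replacement and paired for the next round; repeated for
#' `generations` rounds. All offspring (selected or not) are retained in the
#' returned pedigree.
#'
#' @param founders a list as returned by [generate_founders()] (`genotypes`,
#'   `haplotypes`, `meta`), or unphased (`haplotypes = NULL`, phased here).
#' @param config a [sim_config()].
#' @return a [pedigree()] with phased haplotypes for every individual.
#' @export
run_benchmark_sim <- function(founders, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  meta <- founders$meta
  G <- founders$genotypes
  n <- length(G$samples)
  if (n != config$n_founders)
    stop("founders has ", n, " samples but config expects ",
         config$n_founders)
  if (sum(meta$sex == "male") != sum(meta$sex == "female"))
    stop("founders must be sex-balanced")
  if (any(is.na(meta$label)))
    stop("every founder needs a self-report label")
  haps <- founders$haplotypes
  if (is.null(haps)) haps <- phase_founders(impute_missing(G, config$seed),
                                            config$seed)
  blocks <- recomb_blocks(G$markers, config$hotspot_spacing)

  ind <- data.frame(id = G$samples, sex = meta$sex,
                    mother_id = NA_character_, father_id = NA_character_,
                    generation = 0L, founder_label = meta$label,
                    stringsAsFactors = FALSE)
  all_haps <- haps

  cohort <- ind            # individuals eligible to mate this round
  for (g in seq_len(config$generations)) {
    new_rows <- list(); new_haps <- list()
    with_seed(derive_seed(config$seed, paste0("generation", g)), {
      males <- sample(cohort$id[cohort$sex == "male"])
      females <- sample(cohort$id[cohort$sex == "female"])
      n_pairs <- length(males)
      counter <- 0L
      for (p in seq_len(n_pairs)) {
        mo <- list(id = females[p], sex = "female",
                   haplotypes = all_haps[[females[p]]])
        fa <- list(id = males[p], sex = "male",
                   haplotypes = all_haps[[males[p]]])
        kids <- mate(mo, fa, config$offspring_per_pair, blocks)
        for (kid in kids) {
          counter <- counter + 1L
          kid_id <- sprintf("G%d_%03d", g, counter)
          new_rows[[counter]] <- data.frame(
            id = kid_id, sex = kid$sex, mother_id = kid$mother_id,
            father_id = kid$father_id, generation = g,
            founder_label = NA_character_, stringsAsFactors = FALSE)
          new_haps[[kid_id]] <- kid$haplotypes
        }
      }
      offspring <- do.call(rbind, new_rows)
      ind <- rbind(ind, offspring)
      all_haps <- c(all_haps, new_haps)
      if (g < config$generations) {
        half <- config$cohort_size %/% 2L
        m_pool <- offspring$id[offspring$sex == "male"]
        f_pool <- offspring$id[offspring$sex == "female"]
        if (length(m_pool) < half || length(f_pool) < half)
          stop("cannot form a sex-balanced cohort of ", config$cohort_size,
               " from ", length(m_pool), " males and ", length(f_pool),
               " females; re-run with a different seed")
        sel <- c(sample(m_pool, half), sample(f_pool, half))
        cohort <- offspring[offspring$id %in% sel, , drop = FALSE]
      }
    })
  }
  pedigree(ind, all_haps, G$markers)
}

#' Extract genotypes of pedigree members
#'
#' Dosages are haplotype sums over the pedigree's markers.
#'
#' @param ped a phased [pedigree()].
#' @param generation optional generation filter (e.g. terminal generation);
#'   `NULL` keeps everyone.
#' @param ids optional explicit id selection (overrides `generation`).
#' @return a [genotype_matrix()].
#' @export
pedigree_genotypes <- function(ped, generation = NULL, ids = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(ped$haplotypes)) stop("pedigree carries no haplotypes")
  if (is.null(ids)) {
    ids <- ped$individuals$id
    if (!is.null(generation))
      ids <- ped$individuals$id[ped$individuals$generation %in% generation]
  }
  dos <- t(vapply(ids, function(i) as.integer(colSums(ped$haplotypes[[i]])),
                  integer(ncol(ped$haplotypes[[1L]]))))
  genotype_matrix(dos, ids, ped$markers)
}

#' Terminal generation index of a pedigree
#' @param ped a [pedigree()].
#' @return the maximum generation number.
#' @export
terminal_generation <- function(ped) max(ped$individuals$generation)
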