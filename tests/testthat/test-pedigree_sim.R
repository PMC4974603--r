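test_that("phasing reproduces dosages and is deterministic in the seed", {
  set.seed(31)
  G <- random_genotype_matrix(10, 300)
  expect_error(phase_founders(random_genotype_matrix(3, 20,
                                                     missing_rate = 0.3)),
               "impute_missing")

  h1 <- phase_founders(G, seed = 5)
  h2 <- phase_founders(G, seed = 5)
  expect_identical(h1, h2)

  for (i in seq_along(G$samples))
    expect_identical(as.integer(colSums(h1[[i]])), unname(G$dosages[i, ]))

  # all-homozygous founder phases uniquely
  Gh <- genotype_matrix(matrix(c(0L, 2L, 2L, 0L), 1),
                        "S1", marker_info(rep("1", 4), 1:4, paste0("m", 1:4),
                                          rep("A", 4), rep("G", 4)))
  expect_identical(phase_founders(Gh, 1), phase_founders(Gh, 99))

  # different seeds re-flip ~50% of het cells
  h3 <- phase_founders(G, seed = 6)
  het <- G$dosages == 1L
  n_het <- sum(het)
  flips <- sum(vapply(seq_along(G$samples), function(i)
    sum(h1[[i]][1, het[i, ]] != h3[[i]][1, het[i, ]]), 0L))
  se <- sqrt(0.25 * n_het)
  expect_lt(abs(flips - n_het / 2), 3 * se)
})

test_that("gamete blocks are exact copies of parental haplotype blocks", {
  set.seed(32)
  L <- 30000L
  mk <- marker_info(rep("1", L), seq_len(L), sprintf("m%05d", seq_len(L)),
                    rep("A", L), rep("G", L))
  haps <- rbind(sample(0:1, L, TRUE), sample(0:1, L, TRUE))
  blocks <- admixbench:::recomb_blocks(mk, 10000L)
  expect_equal(max(blocks), 3L)    # exactly 3 blocks at L = 30000, s = 10000

  g <- make_gamete(haps, blocks, seed = 1)
  for (b in 1:3) {
    idx <- blocks == b
    expect_true(identical(g[idx], haps[1, idx]) ||
                identical(g[idx], haps[2, idx]))
  }

  # per-block haplotype choice is a fair coin (use distinguishable blocks)
  haps2 <- rbind(rep(0L, L), rep(1L, L))
  set.seed(99)
  picks <- replicate(2000, make_gamete(haps2, blocks)[c(1, 10001, 20001)])
  freq1 <- rowMeans(picks == 0)
  se <- sqrt(0.25 / 2000)
  expect_true(all(abs(freq1 - 0.5) < 3 * se))

  expect_error(admixbench:::recomb_blocks(mk, 0L), "spacing")
})

test_that("blocks restart at chromosome boundaries", {
  mk <- marker_info(c(rep("1", 5), rep("2", 5)), rep(1:5, 2),
                    paste0("m", 1:10), rep("A", 10), rep("G", 10))
  blocks <- admixbench:::recomb_blocks(mk, 3L)
  expect_equal(blocks, c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L))
})

test_that("mate() enforces parent sexes and produces Mendelian offspring", {
  set.seed(33)
  L <- 100L
  mk <- marker_info(rep("1", L), seq_len(L), paste0("m", seq_len(L)),
                    rep("A", L), rep("G", L))
  blocks <- admixbench:::recomb_blocks(mk, 30L)
  mo <- list(id = "mo", sex = "female",
             haplotypes = rbind(sample(0:1, L, TRUE), sample(0:1, L, TRUE)))
  fa <- list(id = "fa", sex = "male",
             haplotypes = rbind(sample(0:1, L, TRUE), sample(0:1, L, TRUE)))
  expect_error(mate(mo, mo, 2, blocks), "female mother and a male father")

  kids <- mate(mo, fa, 4, blocks, seed = 3)
  expect_length(kids, 4L)
  for (kid in kids) {
    expect_true(kid$sex %in% c("male", "female"))
    expect_equal(kid$mother_id, "mo")
    # each offspring allele is carried by the right parent at that marker
    expect_true(all(kid$haplotypes[1, ] == mo$haplotypes[1, ] |
                    kid$haplotypes[1, ] == mo$haplotypes[2, ]))
    expect_true(all(kid$haplotypes[2, ] == fa$haplotypes[1, ] |
                    kid$haplotypes[2, ] == fa$haplotypes[2, ]))
  }

  # identical homozygous parents breed true
  hom <- rbind(rep(1L, L), rep(1L, L))
  mo2 <- list(id = "m2", sex = "female", haplotypes = hom)
  fa2 <- list(id = "f2", sex = "male", haplotypes = hom)
  kid <- mate(mo2, fa2, 1, blocks, seed = 4)[[1]]
  expect_true(all(colSums(kid$haplotypes) == 2L))

  # sexes across replicates ~ Binomial(4, 0.5)
  set.seed(34)
  n_male <- replicate(300, sum(vapply(mate(mo, fa, 4, blocks), function(k)
    k$sex == "male", logical(1))))
  expect_lt(abs(mean(n_male) - 2), 3 * sqrt(1 / 300))
})

test_that("run_benchmark_sim produces the configured pedigree arithmetic", {
  sf <- small_founders(n = 30, L = 1200, seed = 41)
  cfg <- sim_config(hotspot_spacing = 400L, seed = 41)
  ped <- run_benchmark_sim(sf$founders, cfg)

  gens <- table(ped$individuals$generation)
  # 15 pairs x 4 -> 60 gen-1; 15 pairs from 30 selected -> 60 gen-2
  expect_equal(as.integer(gens[c("0", "1", "2")]), c(30L, 60L, 60L))

  # every non-founder's parents are in the previous generation
  ind <- ped$individuals
  for (g in 1:2) {
    rows <- ind[ind$generation == g, ]
    pg <- ind$generation[match(c(rows$mother_id, rows$father_id), ind$id)]
    expect_true(all(pg == g - 1L))
  }

  # reproducibility: identical config + seed -> identical everything
  ped2 <- run_benchmark_sim(sf$founders, cfg)
  expect_identical(ped$individuals, ped2$individuals)
  expect_identical(ped$haplotypes, ped2$haplotypes)

  # generations = 0 keeps only founders
  ped0 <- run_benchmark_sim(sf$founders,
                            sim_config(hotspot_spacing = 400L,
                                       generations = 0L, seed = 41))
  expect_equal(nrow(ped0$individuals), 30L)
  expect_true(all(ped0$individuals$generation == 0L))
})

test_that("every non-founder haplotype is block-wise parental (Mendelian oracle)", {
  sf <- small_founders(n = 10, L = 900, seed = 43)
  cfg <- sim_config(n_founders = 10L, cohort_size = 6L,
                    hotspot_spacing = 300L, seed = 43)
  ped <- run_benchmark_sim(sf$founders, cfg)
  blocks <- admixbench:::recomb_blocks(ped$markers, 300L)
  ind <- ped$individuals
  for (i in which(ind$generation > 0)) {
    h <- ped$haplotypes[[ind$id[i]]]
    mh <- ped$haplotypes[[ind$mother_id[i]]]
    fh <- ped$haplotypes[[ind$father_id[i]]]
    for (b in unique(blocks)) {
      idx <- blocks == b
      expect_true(identical(h[1, idx], mh[1, idx]) ||
                  identical(h[1, idx], mh[2, idx]))
      expect_true(identical(h[2, idx], fh[1, idx]) ||
                  identical(h[2, idx], fh[2, idx]))
    }
  }
})

test_that("allele-frequency drift between founders and terminal cohort is unbiased", {
  # scaled-down replicate study: small L and 40 seeds keep this fast
  set.seed(44)
  deltas <- vapply(1:40, function(s) {
    sf <- small_founders(n = 10, L = 200, seed = s)
    cfg <- sim_config(n_founders = 10L, cohort_size = 6L,
                      hotspot_spacing = 50L, seed = s)
    ped <- run_benchmark_sim(sf$founders, cfg)
    g0 <- pedigree_genotypes(ped, generation = 0)
    gt <- pedigree_genotypes(ped, generation = terminal_generation(ped))
    mean(colMeans(gt$dosages) - colMeans(g0$dosages)) / 2
  }, 0)
  se <- stats::sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se + 1e-8)
})

test_that("pedigree integrity violations are rejected", {
  ind <- worked_pedigree()$individuals
  bad <- ind; bad$mother_id[5] <- "nobody"
  expect_error(pedigree(bad), "missing from the pedigree")
  bad <- ind; bad$founder_label[1] <- NA
  expect_error(pedigree(bad), "founder_label")
  bad <- ind; bad$mother_id[5] <- "afr_m"   # male listed as mother
  expect_error(pedigree(bad), "sexes")
  expect_error(sim_config(n_founders = 7), "even")
  expect_error(sim_config(cohort_size = 100), "exceeds")
})

test_that("pedigree tables round-trip through TSV", {
  dir <- withr::local_tempdir()
  wp <- worked_pedigree()
  p <- file.path(dir, "ped.tsv")
  write_pedigree_table(wp, p)
  back <- read_pedigree_table(p)
  expect_identical(back$individuals, wp$individuals)
})
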