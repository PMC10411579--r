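test_that("simulate_genome is seed-deterministic with the stated GC", {
  g1 <- simulate_genome(5000, seed = 13)
  g2 <- simulate_genome(5000, seed = 13)
  expect_identical(unclass(g1), unclass(g2))
  expect_false(identical(unclass(simulate_genome(5000, seed = 14)),
                         unclass(g1)))

  gc1 <- simulate_genome(2000, gc = 1, seed = 1)
  expect_false(grepl("[AT]", gc1[[1]]))

  big <- simulate_genome(1e6, seed = 2)
  gc <- assembly_stats(big)$gc_fraction
  expect_lt(abs(gc - 0.405), 0.01)
})

test_that("introduce_gaps places recoverable, well-separated gaps", {
  sim <- introduce_gaps(simulate_genome(100000, seed = 15), n_gaps = 20,
                        seed = 15)
  expect_equal(nrow(find_gaps(sim$gapped)), 20L)
  expect_equal(nrow(sim$gaps), 20L)

  # restoring every hidden sequence reconstructs the truth
  restored <- unclass(sim$gapped)
  for (i in seq_len(nrow(sim$gaps))) {
    sid <- sim$gaps$scaffold_id[i]
    substr(restored[[sid]], sim$gaps$start[i] + 1L, sim$gaps$end[i]) <-
      sim$gaps$hidden[i]
  }
  expect_identical(restored, unclass(sim$truth))

  # pairwise separation of at least the configured minimum
  by_scaf <- split(sim$gaps, sim$gaps$scaffold_id)
  for (g in by_scaf) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1)
      expect_true(all(g$start[-1] - g$end[-nrow(g)] >= 2000))
  }

  # infeasible packing errors out
  expect_error(introduce_gaps(simulate_genome(10000, seed = 1), n_gaps = 10,
                              seed = 1), "cannot place")
})

test_that("make_donors flags coverable gaps and applies the error rate", {
  sim <- introduce_gaps(simulate_genome(60000, seed = 16), n_gaps = 5,
                        seed = 16)
  sim0 <- make_donors(sim, k_list = c(37, 117), error_rate = 0,
                      cover_fraction = 1, seed = 16)
  expect_true(all(sim0$gaps$coverable))
  expect_equal(length(sim0$donors), 2L)
  expect_equal(vapply(sim0$donors, function(d) d$kmer_size, integer(1)),
               c(37L, 117L))
  # error-free donors are exact substrings of the truth
  expect_true(all(vapply(unclass(sim0$donors[[1]]$assembly), function(ctg)
    grepl(ctg, sim0$truth[[1]], fixed = TRUE), logical(1))))

  simh <- make_donors(sim, k_list = 57, cover_fraction = 0.6, seed = 16)
  expect_equal(sum(!simh$gaps$coverable), 2L)  # round(0.4 * 5)
  # the uncoverable hidden spans are absent from every donor contig
  for (i in which(!simh$gaps$coverable)) {
    expect_false(any(vapply(unclass(simh$donors[[1]]$assembly), function(ctg)
      grepl(simh$gaps$hidden[i], ctg, fixed = TRUE), logical(1))))
  }
})

test_that("substitution counts concentrate at the nominal error rate", {
  set.seed(17)
  s <- rand_seq(100000)
  m <- gapatch:::mutate_seq(s, 0.01)
  nmut <- sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  # binomial mean 1000, sd ~31.5; assert within 3 sigma
  expect_gt(nmut, 1000 - 3 * sqrt(1000 * 0.99))
  expect_lt(nmut, 1000 + 3 * sqrt(1000 * 0.99))
})

test_that("simulate_populations creates the stated fixed differences", {
  pops <- simulate_populations(n_per_pop = 8, n_loci = 6, locus_len = 150,
                               fixed_diffs_per_locus = 1,
                               polymorphism_rate = 0, seed = 18)
  gm <- build_genotype_matrix(pops$loci, pop_labels = pops$labels)
  # exactly one biallelic site per locus, each a fixed difference
  sites <- attr(gm, "sites")
  expect_equal(unname(table(sites$locus_id)), rep(1L, 6), ignore_attr = TRUE)
  rk <- rank_diagnostic_loci(gm)
  expect_equal(rk$differential, rep(1, 6))

  # reproducibility
  pops2 <- simulate_populations(n_per_pop = 8, n_loci = 6, locus_len = 150,
                                fixed_diffs_per_locus = 1,
                                polymorphism_rate = 0, seed = 18)
  expect_identical(pops$loci, pops2$loci)
})

test_that("simulate_admixed draws loci from the parents at rate q", {
  pops <- simulate_populations(n_per_pop = 10, n_loci = 100, locus_len = 80,
                               fixed_diffs_per_locus = 1,
                               polymorphism_rate = 0, seed = 19)
  sim <- simulate_admixed(pops, q = 0.59, n_individuals = 4, seed = 19)
  expect_equal(nrow(sim$hybrids), 4L)
  # realized fractions within binomial 3 sigma of q
  sd3 <- 3 * sqrt(0.59 * 0.41 / 100)
  expect_true(all(abs(sim$hybrids$q_realized - 0.59) < sd3))
  # every hybrid haplotype is copied verbatim from some parental
  lid <- names(pops$loci)[1]
  parents <- pops$loci[[lid]]
  for (h in sim$hybrids$sample)
    expect_true(sim$loci[[lid]][[h]] %in% parents)

  # q = 1 individuals carry population-1 haplotypes everywhere
  sim1 <- simulate_admixed(pops, q = 1, n_individuals = 2, seed = 20)
  p1 <- names(pops$labels)[pops$labels == "pop1"]
  for (lid in names(pops$loci)[1:10]) {
    for (h in sim1$hybrids$sample)
      expect_true(sim1$loci[[lid]][[h]] %in% pops$loci[[lid]][p1])
  }

  # single haplotype per individual and locus: no heterozygosity encoding
  expect_true(all(vapply(sim$loci, function(l)
    !anyDuplicated(names(l)), logical(1))))
})
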