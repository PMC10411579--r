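test_that("flank schedule steps down from 1 kb to 100 bp by default", {
  expect_equal(flank_schedule(),
               c(1000L, 900L, 800L, 700L, 600L, 500L, 400L, 300L, 200L, 100L))
  expect_equal(flank_schedule(300, 100, 100), c(300L, 200L, 100L))
  expect_equal(flank_schedule(100, 100, 100), 100L)
  expect_error(flank_schedule(100, 200, 100), "max_len")
})

test_that("map_flank finds unique hits and rejects ambiguous ones", {
  set.seed(11)
  bg <- rand_seq(30000)
  fl <- substr(bg, 12001, 12200)
  don <- donor_assembly(c(c1 = bg), 57)
  h <- map_flank(fl, don)
  expect_true(is_flank_hit(h))
  expect_equal(h$edit_distance, 0L)
  expect_equal(h$strand, "+")
  expect_equal(substr(bg, h$start + 1, h$end), fl)

  # reverse-complement occurrence maps to the minus strand
  h2 <- map_flank(rc_oracle(fl), don)
  expect_equal(h2$strand, "-")
  expect_equal(c(h2$start, h2$end), c(h$start, h$end))

  # two exact copies are ambiguous
  twice <- donor_assembly(c(c1 = paste0(fl, rand_seq(2000), fl)), 37)
  miss <- map_flank(fl, twice)
  expect_false(is_flank_hit(miss))
  expect_equal(miss$reason, "ambiguous")

  # flanks containing N are a caller error
  expect_error(map_flank("ACGTN", don), "N")
})

test_that("map_flank edit distances match the DP oracle", {
  set.seed(12)
  bg <- rand_seq(20000)
  fl0 <- substr(bg, 5001, 5100)
  don <- donor_assembly(c(c1 = bg), 77)
  for (nsub in c(2, 5)) {
    fl <- substitute_n(fl0, nsub, seed = nsub)
    h <- map_flank(fl, don, max_edit_fraction = 0.10)
    expect_true(is_flank_hit(h))
    expect_equal(h$edit_distance, best_occurrence_dp(fl, bg))
    expect_lte(h$edit_distance, nsub)
  }
  # beyond the 10% budget: no hit
  far <- substitute_n(fl0, 15, seed = 99)
  miss <- map_flank(far, don, max_edit_fraction = 0.10)
  expect_false(is_flank_hit(miss))
})

test_that("patch_gaps restores a simulated truth genome exactly", {
  sim <- introduce_gaps(simulate_genome(100000, seed = 21), n_gaps = 20,
                        gap_len_range = c(300, 800), seed = 21)
  sim <- make_donors(sim, k_list = c(37, 77, 117), contig_len = 10000,
                     seed = 21)
  res <- patch_gaps(sim$gapped, sim$donors)
  expect_true(all(res$patches$status == "patched"))
  expect_identical(unclass(res$assembly), unclass(sim$truth))
  expect_equal(count_filled(sim$gapped, res$assembly), 20L)

  # idempotence: nothing left to do on a second pass
  res2 <- patch_gaps(res$assembly, sim$donors)
  expect_identical(unclass(res2$assembly), unclass(res$assembly))
  expect_equal(nrow(find_gaps(res2$assembly)), 0L)
})

test_that("selective donor coverage patches exactly the coverable subset", {
  sim <- introduce_gaps(simulate_genome(120000, seed = 23), n_gaps = 12,
                        gap_len_range = c(300, 800), seed = 23)
  sim <- make_donors(sim, k_list = c(47, 97), contig_len = 8000,
                     cover_fraction = 0.5, seed = 23)
  res <- patch_gaps(sim$gapped, sim$donors)
  expect_equal(res$patches$status == "patched", sim$gaps$coverable)
  # gap count never increases; untouched sequence is conserved
  expect_lte(nrow(find_gaps(res$assembly)), nrow(find_gaps(sim$gapped)))
  st_before <- assembly_stats(sim$gapped)
  st_after <- assembly_stats(res$assembly)
  expect_gte(st_after$total_length - st_after$gap_bp,
             st_before$total_length - st_before$gap_bp)
})

test_that("flanks hitting different contigs leave the gap unpatched", {
  set.seed(31)
  left <- rand_seq(400); right <- rand_seq(400)
  scaf <- assembly(c(s = paste0(left, strrep("N", 200), right)))
  don <- donor_assembly(c(cA = paste0(left, rand_seq(500)),
                          cB = paste0(rand_seq(500), right)), 107)
  res <- patch_gaps(scaf, list(don), schedule = flank_schedule(400, 100, 100))
  expect_equal(res$patches$status, "unpatched")
  expect_equal(res$patches$reason, "different_contig")
  expect_identical(unclass(res$assembly), unclass(scaf))
})

test_that("larger k-mer donors take priority on conflicting patches", {
  set.seed(32)
  left <- rand_seq(300); right <- rand_seq(300)
  h117 <- rand_seq(250); h37 <- rand_seq(250)
  scaf <- assembly(c(s = paste0(left, strrep("N", 250), right)))
  d117 <- donor_assembly(c(c1 = paste0(left, h117, right)), 117)
  d37 <- donor_assembly(c(c1 = paste0(left, h37, right)), 37)
  res <- patch_gaps(scaf, list(d37, d117),
                    schedule = flank_schedule(300, 100, 100))
  expect_equal(res$patches$status, "patched")
  expect_equal(res$patches$donor_kmer, 117L)
  expect_identical(unclass(res$assembly)[["s"]], paste0(left, h117, right))
})

test_that("count_filled requires matching ids and counts closures", {
  a <- assembly(c(s = "ACGTNNNNACGT"))
  expect_equal(count_filled(a, a), 0L)
  b <- assembly(c(s = "ACGTAAAAACGT"))
  expect_equal(count_filled(a, b), 1L)
  expect_error(count_filled(a, assembly(c(t = "ACGT"))), "ids differ")
})
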