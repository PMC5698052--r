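test_that("generators are deterministic given a seed", {
  s1 <- simulate_parents(n_chrom = 2, chrom_bp = 2e4, snp_rate = 0.002, seed = 5)
  s2 <- simulate_parents(n_chrom = 2, chrom_bp = 2e4, snp_rate = 0.002, seed = 5)
  expect_identical(s1$parent1$seq, s2$parent1$seq)
  expect_identical(s1$snps, s2$snps)
  k1 <- simulate_kmer_histogram(genome_bp = 5e4, seed = 6)
  k2 <- simulate_kmer_histogram(genome_bp = 5e4, seed = 6)
  expect_identical(as.data.frame(k1$histogram), as.data.frame(k2$histogram))
})

test_that("parent genomes differ only at the recorded SNP positions", {
  sim <- simulate_parents(n_chrom = 2, chrom_bp = 5e4, snp_rate = 0.001, seed = 19)
  for (ch in sim$parent1$seq_id) {
    a <- strsplit(sim$parent1$seq[sim$parent1$seq_id == ch], "")[[1]]
    b <- strsplit(sim$parent2$seq[sim$parent2$seq_id == ch], "")[[1]]
    diffs <- which(a != b) - 1L
    expect_setequal(diffs, sim$snps$pos[sim$snps$seq_id == ch])
  }
  # Poisson bound: ~1000 SNPs on 1 Mbp at rate 1e-3, within 3 sigma
  big <- simulate_parents(n_chrom = 1, chrom_bp = 1e6, snp_rate = 0.001, seed = 20)
  expect_lt(abs(nrow(big$snps) - 1000), 3 * sqrt(1000) + 1)
  # no duplications: the analysed assembly equals parent 1
  expect_identical(sim$assembly$seq, sim$parent1$seq)
})

test_that("duplication registry records collapsed and repeated copies", {
  dups <- tibble::tibble(seq_id = "chrA01", start = c(1000L, 5000L),
                         end = c(2000L, 6000L), genome_copies = c(2L, 2L),
                         assembly_copies = c(1L, 2L))
  sim <- simulate_parents(n_chrom = 1, chrom_bp = 1e4, snp_rate = 0.001,
                          duplications = dups, seed = 21)
  reg <- sim$truth$duplications
  expect_equal(reg$assembly_copies, c(1L, 2L))
  # the repeat's second copy is a real duplicate in the assembly sequence
  locs <- reg$assembly_locs[[2]]
  expect_equal(nrow(locs), 2)
  seqs <- purrr::map2_chr(locs$start, locs$end, function(s, e) {
    substring(sim$assembly$seq[1], s + 1, e)
  })
  expect_identical(seqs[1], seqs[2])
  expect_equal(sim$assembly$length, 1e4 + 1000)
  expect_error(
    simulate_parents(1, 1e4, 0.001, seed = 1, duplications = dplyr::mutate(
      dups, start = c(1000L, 1500L), end = c(2000L, 2500L)
    )),
    "overlapping"
  )
})

test_that("the DH simulator reproduces the Kosambi recombination fraction", {
  # zero distance: adjacent genotypes always identical
  loci0 <- tibble::tibble(seq_id = "chr1", pos = c(0L, 1L), cm = c(0, 0))
  g0 <- simulate_dh_population(loci0, n_individuals = 200, seed = 24)
  expect_true(all(g0$calls[1, ] == g0$calls[2, ]))
  # d = 0.5 Morgan: discordance ~ tanh(1)/2 = 0.381
  loci <- tibble::tibble(seq_id = "chr1", pos = c(0L, 1000L), cm = c(0, 50))
  g <- simulate_dh_population(loci, n_individuals = 10000, seed = 25)
  r_emp <- mean(g$calls[1, ] != g$calls[2, ])
  r_true <- tanh(2 * 0.5) / 2
  expect_lt(abs(r_emp - r_true), 3 * sqrt(r_true * (1 - r_true) / 10000))
  # missingness applies at the configured rate
  gm <- simulate_dh_population(loci, n_individuals = 5000, missing_rate = 0.1,
                               seed = 26)
  miss <- mean(is.na(gm$calls))
  expect_lt(abs(miss - 0.1), 3 * sqrt(0.1 * 0.9 / length(gm$calls)))
  expect_error(simulate_dh_population(
    tibble::tibble(seq_id = "c", pos = c(0L, 1L), cm = c(1, 0)), 10
  ), "non-decreasing")
})

test_that("hidden contigs keep their genotype rows and truth entries", {
  loci <- tibble::tibble(seq_id = rep(c("chrA01", "chrC01"), each = 100),
                         pos = rep(seq(0, 99) * 1e4, 2),
                         cm = rep(seq(0, 99) * 0.02 * 10, 2))
  geno <- simulate_dh_population(loci, n_individuals = 20, seed = 27)
  parts <- fragment_and_hide(geno, c(chrA01 = 1e6, chrC01 = 1e6),
                             n_contigs = 8, contig_bp = 5e4, seed = 28)
  expect_equal(nrow(parts$truth), 8)
  expect_equal(nrow(parts$anchored$loci) + nrow(parts$contigs$loci),
               nrow(geno$loci))
  # hidden rows are byte-identical to the anchored rows they came from
  for (i in seq_len(nrow(parts$contigs$loci))) {
    lid <- parts$contigs$loci$locus_id[i]
    expect_identical(parts$contigs$calls[i, ], geno$calls[lid, ])
  }
  # rebased positions stay inside the contig
  expect_true(all(parts$contigs$loci$pos >= 0 &
                    parts$contigs$loci$pos < 5e4))
})

test_that("coverage tracks follow the copy-number model", {
  # no duplications: all-placement equals unique everywhere
  cov0 <- simulate_coverage(c(chr1 = 2e4), NULL, mean_depth = 10, seed = 29)
  expect_identical(cov0$depth[[1]], cov0$depth[[2]])
  expect_lt(abs(mean(cov0$depth[[1]]) - 10), 1)

  dups <- tibble::tibble(seq_id = "chrA01", start = c(3000L, 8000L),
                         end = c(5000L, 10000L), genome_copies = 2L,
                         assembly_copies = c(1L, 2L))
  sim <- simulate_parents(1, 2e4, 0.001, duplications = dups, seed = 30)
  cov <- simulate_coverage(sim$assembly, sim$truth$duplications,
                           mean_depth = 10, seed = 31)
  u <- cov$depth[[which(cov$mode == "unique")]]
  a <- cov$depth[[which(cov$mode == "all")]]
  # collapsed 2-copy segment: unique depth doubles (within 3 sigma of 20)
  seg <- u[3101:4900]
  expect_lt(abs(mean(seg) - 20), 3 * sqrt(20 / length(seg) * 100))
  # assembly repeat: unique exactly 0 inside both copies, all stays normal
  locs <- sim$truth$duplications$assembly_locs[[2]]
  for (j in 1:2) {
    idx <- (locs$start[j] + 1):locs$end[j]
    expect_true(all(u[idx] == 0))
    expect_gt(mean(a[idx]), 5)
  }
})

test_that("generated files round-trip through the package readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_parents(n_chrom = 2, chrom_bp = 2e4, snp_rate = 0.002, seed = 32)
  write_fasta(sim$parent1, file.path(dir, "p1.fasta"))
  expect_equal(read_fasta(file.path(dir, "p1.fasta"))$seq, sim$parent1$seq)

  loci <- dplyr::mutate(sim$snps, cm = .data$pos / 1e6 * 2)
  geno <- simulate_dh_population(loci, n_individuals = 12, missing_rate = 0.2,
                                 seed = 33)
  write_genotypes(geno, file.path(dir, "geno.tsv"))
  back <- read_genotypes(file.path(dir, "geno.tsv"))
  expect_identical(back$calls, geno$calls)

  cov <- simulate_coverage(sim$assembly, NULL, mean_depth = 8, seed = 34)
  uni <- cov[cov$mode == "unique", ]
  write_depth(uni, file.path(dir, "u.bedgraph"))
  back_cov <- read_depth(file.path(dir, "u.bedgraph"), sim$assembly)
  expect_identical(back_cov$depth[order(back_cov$seq_id)],
                   uni$depth[order(uni$seq_id)])

  kh <- simulate_kmer_histogram(genome_bp = 5e4, coverage = 20, seed = 35)
  write_kmer_histogram(kh$histogram, file.path(dir, "k.histo"))
  back_h <- read_kmer_histogram(file.path(dir, "k.histo"))
  expect_equal(back_h$multiplicity, kh$histogram$multiplicity)
  expect_equal(back_h$count, kh$histogram$count)
})
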