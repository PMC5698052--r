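cfg1 <- nc_config(min_informative = 1)

test_that("consensus takes the per-individual majority, missing on ties", {
  m <- rbind(c("P1", "P1", NA), c("P1", "P2", NA), c("P2", "P2", NA))
  colnames(m) <- c("i1", "i2", "i3")
  cv <- consensus_vector(m)
  expect_equal(unname(cv$consensus), c("P1", "P2", NA))
  expect_equal(unname(cv$concordance), c(2 / 3, 2 / 3, NA))
  # a tie is a no-call
  tie <- consensus_vector(rbind(c("P1"), c("P2")))
  expect_true(is.na(tie$consensus[1]))
  # single locus: identity
  one <- consensus_vector(matrix(c("P2", NA, "P1"), nrow = 1))
  expect_equal(unname(one$consensus), c("P2", NA, "P1"))
  expect_error(consensus_vector(matrix(character(), nrow = 0, ncol = 2)), "empty")
})

test_that("recombination fraction counts discordant informative individuals", {
  v <- c("P1", "P1", "P2", "P2", "P1", "P2", "P1", "P2")
  expect_equal(recomb_fraction(v, v, min_informative = 1), 0)
  comp <- ifelse(v == "P1", "P2", "P1")
  expect_equal(recomb_fraction(v, comp, min_informative = 1), 1)
  v1 <- c("P1", "P1", "P2", "P2", "P1", "P2")
  v2 <- c("P1", "P2", "P2", "P2", "P1", "P2")
  expect_equal(recomb_fraction(v1, v2, min_informative = 1), 1 / 6)
  # undefined below the informativeness floor
  expect_true(is.na(recomb_fraction(v1, v2, min_informative = 7)))
  expect_error(recomb_fraction(v, v[-1]), "length")
})

test_that("recombination fraction is symmetric and respects missingness", {
  set.seed(42)
  for (rep in 1:50) {
    a <- rand_vec(12)
    b <- rand_vec(12)
    expect_identical(recomb_fraction(a, b, 1), recomb_fraction(b, a, 1))
    # brute-force denominator/numerator
    num <- den <- 0
    for (i in seq_along(a)) {
      if (!is.na(a[i]) && !is.na(b[i])) {
        den <- den + 1
        num <- num + (a[i] != b[i])
      }
    }
    expect_equal(recomb_fraction(a, b, 1),
                 if (den < 1) NA_real_ else num / den)
  }
})

test_that("anchor bins follow fixed-window arithmetic", {
  g <- make_geno(rbind(c("P1", "P2"), c("P1", "P2"), c("P2", "P1")),
                 pos = c(1e5, 5e5, 1.2e6))
  bins <- build_anchor_bins(g, bin_bp = 1e6)
  expect_equal(nrow(bins), 2)
  expect_equal(bins$n_snps, c(2L, 1L))
  expect_equal(bins$start, c(0, 1e6))
  expect_equal(bins$mid, c(5e5, 1.5e6))
  # identical rows give a unanimous consensus
  expect_equal(unname(bins$consensus[[1]]), c("P1", "P2"))
  # no loci on a chromosome -> no bins for it
  expect_false("chrB01" %in% bins$seq_id)
  expect_error(build_anchor_bins(g, 1e6, seq_lengths = c(chrA01 = 1e6)),
               "beyond")
})

make_bins <- function(consensus_list, seq_ids, n_snps = NULL, starts = NULL) {
  n <- length(consensus_list)
  if (is.null(n_snps)) n_snps <- rep(5L, n)
  if (is.null(starts)) starts <- seq(0, by = 1e6, length.out = n)
  tibble::tibble(seq_id = seq_ids, start = starts, end = starts + 1e6,
                 mid = starts + 5e5, n_snps = n_snps,
                 consensus = consensus_list)
}

test_that("placement rule: clean minimum places, near-tie across chromosomes conflicts", {
  set.seed(7)
  base <- rand_vec(40, miss = 0)
  flip <- function(v, k) {
    i <- sample(seq_along(v), k)
    v[i] <- ifelse(v[i] == "P1", "P2", "P1")
    v
  }
  bins <- make_bins(list(flip(base, 2), flip(base, 18)),
                    c("chrA01", "chrC01"))
  res <- place_contig(base, bins, nc_config())
  expect_equal(res$status, "placed")
  expect_equal(res$seq_id, "chrA01")
  expect_equal(res$r_best, 0.05)

  # two chromosomes linked within delta_conflict: conflict, never forced
  bins2 <- make_bins(list(flip(base, 4), flip(base, 5)), c("chrA01", "chrC01"))
  res2 <- place_contig(base, bins2, nc_config())
  expect_equal(res2$status, "conflict")
  expect_true(is.na(res2$seq_id))

  # nothing linked: insufficient
  bins3 <- make_bins(list(flip(base, 20), flip(base, 22)), c("chrA01", "chrC01"))
  expect_equal(place_contig(base, bins3, nc_config())$status, "insufficient")

  # all r undefined: insufficient
  bins4 <- make_bins(list(rep(NA_character_, 40)), "chrA01")
  expect_equal(place_contig(base, bins4, nc_config())$status, "insufficient")
})

test_that("same-pseudomolecule ties break toward more SNPs then smaller start", {
  v <- rep(c("P1", "P2"), 10)
  bins <- make_bins(list(v, v, v), rep("chrA01", 3), n_snps = c(3L, 8L, 8L),
                    starts = c(0, 2e6, 1e6))
  res <- place_contig(v, bins, cfg1)
  expect_equal(res$position, 1.5e6) # n_snps 8, start 1e6
})

test_that("place_contig matches the brute-force evaluator on random instances", {
  set.seed(101)
  cfg <- nc_config(min_informative = 4)
  for (rep in 1:60) {
    n_ind <- sample(6:10, 1)
    n_bins <- sample(2:6, 1)
    bins <- make_bins(
      replicate(n_bins, rand_vec(n_ind, miss = 0.35), simplify = FALSE),
      sample(c("chrA01", "chrC01", "chrA02"), n_bins, replace = TRUE),
      n_snps = sample(1:5, n_bins, replace = TRUE),
      starts = sample(0:5, n_bins) * 1e6
    )
    contig <- rand_vec(n_ind, miss = 0.35)
    got <- place_contig(contig, bins, cfg)
    want <- bf_place_contig(contig, bins, cfg)
    expect_equal(got$status, want$status)
    if (want$status == "placed") {
      expect_equal(got$seq_id, want$seq_id)
      expect_equal(got$position, want$position)
    }
  }
})

test_that("place_all partitions contigs into the four statuses", {
  set.seed(8)
  base <- rand_vec(40, miss = 0)
  other <- rand_vec(40, miss = 0)
  # clean contig matches only chrA01; ambiguous contig matches two
  # chromosomes equally well (a homeologous duplication)
  bins <- make_bins(list(base, other, other),
                    c("chrA01", "chrC01", "chrA02"))
  geno <- make_geno(rbind(base, other), seq_id = c("clean", "ambig"))
  res <- place_all(geno, bins, nc_config(),
                   contig_ids = c("clean", "ambig", "snpless"))
  expect_equal(res$status[match(c("clean", "ambig", "snpless"), res$contig_id)],
               c("placed", "conflict", "no_snp"))
  smry <- glance(res)
  expect_equal(smry$n_contigs, 3)
  expect_equal(smry$placed + smry$no_snp + smry$conflict + smry$insufficient, 3)
  expect_error(place_all(geno, bins, contig_ids = c("a", "a")), "duplicate")
})

test_that("simulated benchmark recovers true chromosomes and positions", {
  bench <- simulate_placement_benchmark(n_chrom = 4, chrom_bp = 8e6,
                                        n_contigs = 25, seed = 421)
  res <- place_all(bench$contigs, bench$bins, contig_ids = bench$contig_ids,
                   prior = bench$prior)
  m <- dplyr::inner_join(tibble::as_tibble(res), bench$truth, by = "contig_id")
  placed <- m[m$status == "placed", ]
  expect_gt(nrow(placed), 0.9 * sum(m$n_snps > 0))
  expect_true(all(placed$seq_id == placed$true_seq))
  expect_lte(mean(abs(placed$position - placed$true_mid)), 1e6)
  expect_equal(glance(res)$prior_consistency, 1)
})

test_that("placement AGP lists placed contigs in insertion order with gaps", {
  placements <- tibble::tibble(
    contig_id = c("c1", "c2", "c3"), status = c("placed", "placed", "no_snp"),
    seq_id = c("chrA01", "chrA01", NA), position = c(2e6, 5e5, NA)
  )
  class(placements) <- c("nc_placement", class(placements))
  agp <- placement_agp(placements, c(c1 = 1000L, c2 = 400L))
  expect_equal(agp$component_id[agp$component_type == "W"], c("c2", "c1"))
  expect_equal(agp$gap_length[agp$component_type == "N"], 100)
  expect_equal(agp$orientation[agp$component_type == "W"], c("?", "?"))
  f <- withr::local_tempfile(fileext = ".agp")
  write_agp(agp, f)
  expect_equal(readLines(f)[1], "##agp-version\t2.1")
})
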