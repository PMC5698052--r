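test_that("FASTA round-trips, folds case, and rejects duplicate ids", {
  asm <- as_assembly(c(chrA01 = "acgtACGTnN", ctg1 = "GGGCCC"))
  expect_equal(asm$seq, c("ACGTACGTNN", "GGGCCC"))
  expect_equal(asm$length, c(10L, 6L))

  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(asm, f)
  back <- read_fasta(f)
  expect_equal(as.data.frame(back), as.data.frame(asm))

  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate")
  expect_error(as_assembly(c(x = "ACGU")), "alphabet")
  expect_error(as_assembly(c(x = "")), "empty")
})

test_that("GFF3 exons convert to 0-based half-open and isoforms union", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=g1;aed=0.3;domains=PF00001,PF00002",
    "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=g1.1;Parent=g1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tID=e1;Parent=g1.1",
    "chr1\tsrc\texon\t301\t400\t.\t+\t.\tID=e2;Parent=g1.1",
    "chr1\tsrc\tgene\t500\t700\t.\t-\t.\tID=g2",
    "chr1\tsrc\tmRNA\t500\t700\t.\t-\t.\tID=g2.1;Parent=g2",
    "chr1\tsrc\texon\t500\t600\t.\t-\t.\tID=e3;Parent=g2.1",
    "chr1\tsrc\tmRNA\t500\t700\t.\t-\t.\tID=g2.2;Parent=g2",
    "chr1\tsrc\texon\t550\t700\t.\t-\t.\tID=e4;Parent=g2.2"
  ), f)
  genes <- read_gff3(f)
  g1 <- genes[genes$gene_id == "g1", ]
  expect_equal(g1$exons[[1]]$start, c(100, 300))
  expect_equal(g1$exons[[1]]$end, c(200, 400))
  expect_equal(g1$exon_bp, 200)
  expect_equal(g1$aed, 0.3)
  expect_equal(g1$domains[[1]], c("PF00001", "PF00002"))
  # minus strand preserved, isoform exons merged into one ascending interval
  g2 <- genes[genes$gene_id == "g2", ]
  expect_equal(g2$strand, "-")
  expect_equal(g2$exons[[1]], tibble::tibble(start = 499, end = 700))

  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\texon\t190\t150\t.\t+\t.\tID=e1;Parent=g1"
  ), f)
  expect_error(read_gff3(f))
})

test_that("gene tables round-trip through GFF3", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"), seq_id = c("chr1", "chr2"), strand = c("+", "-"),
    start = c(10, 0), end = c(110, 50), aed = c(0.5, NA),
    domains = list("PF01609", character()),
    exons = list(tibble::tibble(start = c(10, 60), end = c(30, 110)),
                 tibble::tibble(start = 0, end = 50)),
    exon_bp = c(70, 50)
  )
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(genes, f)
  back <- read_gff3(f)
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$exons, genes$exons)
  expect_equal(back$domains[[1]], "PF01609")
  expect_equal(back$aed, c(0.5, NA))
})

test_that("genotype TSV codes map to parental calls and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "locus_id\tseq_id\tpos\tallele1\tallele2\tind1\tind2\tind3",
    "L1\tctg1\t5\tA\tG\ta\tb\t-",
    "L2\tctg1\t9\tC\tT\tab\ta\tb"
  ), f)
  expect_warning(read_genotypes(f), "coerced to missing")
  g <- suppressWarnings(read_genotypes(f))
  expect_equal(unname(g$calls[1, ]), c("P1", "P2", NA))
  expect_equal(unname(g$calls[2, ]), c(NA, "P1", "P2"))
  expect_equal(g$individuals, c("ind1", "ind2", "ind3"))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, f2)
  back <- read_genotypes(f2)
  expect_identical(back$calls, g$calls)
  expect_equal(back$loci, g$loci)
})

test_that("bedGraph depth expands per base with zero default", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t10\t7", f)
  cov <- read_depth(f, c(chr1 = 20), mode = "unique")
  expect_equal(cov$depth[[1]], c(rep(7L, 10), rep(0L, 10)))

  writeLines("chr1\t0\t30\t7", f)
  expect_error(read_depth(f, c(chr1 = 20)), "beyond")

  # round trip through the writer
  cov2 <- coverage_track("chr1", "all", c(0L, 0L, 3L, 3L, 1L, 0L, 2L))
  f3 <- withr::local_tempfile(fileext = ".bedgraph")
  write_depth(cov2, f3)
  back <- read_depth(f3, c(chr1 = 7), mode = "all")
  expect_equal(back$depth[[1]], cov2$depth[[1]])
})

test_that("hit tables convert coordinates and encode strand", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "ctg1\tchrA01\t98.5\t500\t5\t2\t1\t500\t1001\t1500\t1e-50\t900",
    "ctg1\tchrC01\t97.0\t400\t8\t1\t50\t449\t2400\t2001\t1e-40\t700"
  ), f)
  h <- read_hits(f)
  expect_equal(h$q_start, c(0L, 49L))
  expect_equal(h$t_start, c(1000L, 2000L))
  expect_equal(h$t_end, c(1500L, 2400L))
  expect_equal(h$t_strand, c("+", "-"))
})

test_that("k-mer histogram reader builds a sparse multiplicity map", {
  f <- withr::local_tempfile(fileext = ".histo")
  writeLines(c("1\t500", "20\t1000"), f)
  h <- read_kmer_histogram(f, k = 21)
  expect_equal(h$multiplicity, c(1, 20))
  expect_equal(h$count, c(500, 1000))
  expect_equal(attr(h, "k"), 21)
  expect_error(as_kmer_histogram(tibble::tibble(multiplicity = 0, count = 5)))
  expect_error(as_kmer_histogram(tibble::tibble(multiplicity = 2, count = -1)))
})

test_that("gene-set filtering removes short, evidence-free and transposase genes", {
  mk <- function(id, bp, aed, dom) {
    tibble::tibble(gene_id = id, seq_id = "chr1", strand = "+",
                   exons = list(tibble::tibble(start = 0, end = bp)),
                   exon_bp = bp, aed = aed, domains = list(dom))
  }
  genes <- dplyr::bind_rows(
    mk("short", 90, 0.1, character()),
    mk("noev", 200, 1.0, character()),
    mk("te", 300, 0.2, "PF01609"),
    mk("ok", 500, 0.2, "PF00931")
  )
  res <- filter_gene_set(genes, nc_config())
  expect_equal(res$kept$gene_id, "ok")
  expect_equal(res$removed$reason[match(c("short", "noev", "te"),
                                        res$removed$gene_id)],
               c("short", "no-evidence", "transposase"))
  empty <- filter_gene_set(genes[0, ], nc_config())
  expect_equal(nrow(empty$kept), 0)
})

test_that("flat TOML config round-trips and rejects unknown keys", {
  cfg <- nc_config(r_max = 0.2, bin_bp = 5e5)
  f <- withr::local_tempfile(fileext = ".toml")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(unclass(back), unclass(cfg))
  writeLines("nonsense = 3", f)
  expect_error(read_config(f), "unknown config key")
})
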