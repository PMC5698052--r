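#' Simulate two homozygous parent genomes with SNPs and duplications
#'
#' Emulates a pair of closely related, fully homozygous cultivars: parent 2
#' is parent 1 with substitutions at Poisson(`snp_rate` * bp) positions per
#' chromosome. A duplication spec marks segments present in several genomic
#' copies; copies beyond the first that the *assembly* represents are
#' appended to the chromosome end, while copies the assembly collapses
#' (genome copies > assembly copies) exist only in the registry. Chromosome
#' names split into an A and a C set to mirror an allopolyploid.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_bp Chromosome length (bp, recycled).
#' @param snp_rate Substitution rate per bp, in (0, 0.05).
#' @param duplications Optional tibble `seq_id`, `start`, `end`,
#'   `genome_copies`, `assembly_copies` (0-based half-open source interval;
#'   intervals on one sequence must not overlap).
#' @param seed RNG seed.
#' @return List: `parent1`, `parent2` (genome assemblies), `assembly` (the
#'   analysed assembly, with appended repeat copies), `snps` (SNP locus
#'   tibble), `truth` (duplication registry with per-copy assembly
#'   locations, and the seed).
#' @export
simulate_parents <- function(n_chrom = 2, chrom_bp = 1e5, snp_rate = 0.001,
                             duplications = NULL, seed = NULL) {
  stopifnot(snp_rate > 0, snp_rate < 0.05)
  local_seed(seed, {
    n_a <- ceiling(n_chrom / 2)
    chrom_names <- c(sprintf("chrA%02d", seq_len(n_a)),
                     sprintf("chrC%02d", seq_len(n_chrom - n_a)))
    lens <- rep_len(chrom_bp, n_chrom)
    bases <- c("A", "C", "G", "T")
    p1 <- vapply(lens, function(L) paste(sample(bases, L, replace = TRUE),
                                         collapse = ""), "")
    names(p1) <- chrom_names
    p2 <- p1
    snps <- list()
    for (ch in chrom_names) {
      L <- nchar(p1[[ch]])
      n_snp <- stats::rpois(1, snp_rate * L)
      pos <- sort(sample.int(L, min(n_snp, L))) - 1L
      ref <- substring(p1[[ch]], pos + 1L, pos + 1L)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "",
                    USE.NAMES = FALSE)
      s2 <- strsplit(p2[[ch]], "")[[1]]
      s2[pos + 1L] <- alt
      p2[[ch]] <- paste(s2, collapse = "")
      snps[[ch]] <- tibble(locus_id = sprintf("%s_%d", ch, pos), seq_id = ch,
                           pos = pos, allele1 = ref, allele2 = alt)
    }
    assembly <- p1
    registry <- tibble(
      region_id = character(), seq_id = character(), start = integer(),
      end = integer(), genome_copies = integer(), assembly_copies = integer(),
      assembly_locs = list()
    )
    if (!is.null(duplications)) {
      assert_cols(duplications, c("seq_id", "start", "end", "genome_copies",
                                  "assembly_copies"), "duplications")
      for (sq in unique(duplications$seq_id)) {
        d <- dplyr::arrange(duplications[duplications$seq_id == sq, ], .data$start)
        if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
          abort("overlapping duplication intervals")
        }
        if (any(d$end > nchar(p1[[sq]]))) abort("duplication beyond chromosome end")
      }
      regs <- list()
      for (i in seq_len(nrow(duplications))) {
        dd <- duplications[i, ]
        seg <- substring(p1[[dd$seq_id]], dd$start + 1L, dd$end)
        locs <- tibble(seq_id = dd$seq_id, start = dd$start, end = dd$end)
        extra <- dd$assembly_copies - 1L
        if (extra > 0) {
          for (k in seq_len(extra)) {
            at <- nchar(assembly[[dd$seq_id]])
            assembly[[dd$seq_id]] <- paste0(assembly[[dd$seq_id]], seg)
            locs <- dplyr::bind_rows(locs, tibble(seq_id = dd$seq_id,
                                                  start = at,
                                                  end = at + nchar(seg)))
          }
        }
        regs[[i]] <- tibble(
          region_id = sprintf("dup%03d", i), seq_id = dd$seq_id,
          start = dd$start, end = dd$end,
          genome_copies = as.integer(dd$genome_copies),
          assembly_copies = as.integer(dd$assembly_copies),
          assembly_locs = list(locs)
        )
      }
      registry <- dplyr::bind_rows(regs)
    }
    list(parent1 = as_assembly(p1), parent2 = as_assembly(p2),
         assembly = as_assembly(assembly),
         snps = dplyr::bind_rows(snps),
         truth = list(duplications = registry, seed = seed))
  })
}

#' Simulate a doubled-haploid mapping population
#'
#' Each individual's chromosome is a mosaic of the two parental haplotypes.
#' Between adjacent loci at genetic distance d Morgans a crossover is drawn
#' with probability r = tanh(2 d) / 2 (the Kosambi map function, allowing
#' partial interference); adjacent intervals recombine independently. All
#' calls are homozygous parental codes; missingness is applied uniformly at
#' random.
#'
#' @param loci Tibble `seq_id`, `pos`, `cm` (map position in centiMorgans,
#'   non-decreasing within each sequence); optional `locus_id`, `allele1`,
#'   `allele2`.
#' @param n_individuals Population size.
#' @param missing_rate Fraction of calls set to missing.
#' @param seed RNG seed.
#' @return An `nc_genotypes` object.
#' @export
simulate_dh_population <- function(loci, n_individuals = 92, missing_rate = 0,
                                   seed = NULL) {
  assert_cols(loci, c("seq_id", "pos", "cm"), "loci")
  local_seed(seed, {
    loci <- dplyr::arrange(as_tibble(loci), .data$seq_id, .data$pos)
    if (!"locus_id" %in% names(loci)) {
      loci$locus_id <- sprintf("%s_%d", loci$seq_id, loci$pos)
    }
    if (!"allele1" %in% names(loci)) loci$allele1 <- "A"
    if (!"allele2" %in% names(loci)) loci$allele2 <- "C"
    inds <- sprintf("DH%03d", seq_len(n_individuals))
    calls <- matrix(NA_character_, nrow(loci), n_individuals,
                    dimnames = list(loci$locus_id, inds))
    for (sq in unique(loci$seq_id)) {
      i <- which(loci$seq_id == sq)
      d <- diff(loci$cm[i]) / 100
      if (any(d < 0)) abort("cM positions must be non-decreasing")
      r <- tanh(2 * d) / 2
      n <- length(i)
      first <- sample(GT_CODES, n_individuals, replace = TRUE)
      if (n == 1) {
        calls[i, ] <- first
      } else {
        switches <- matrix(stats::rbinom((n - 1) * n_individuals, 1, r),
                           nrow = n - 1)
        state <- apply(rbind(ifelse(first == "P1", 0, 1), switches), 2,
                       function(col) cumsum(col) %% 2)
        calls[i, ] <- ifelse(state == 0, "P1", "P2")
      }
    }
    if (missing_rate > 0) {
      calls[stats::runif(length(calls)) < missing_rate] <- NA_character_
    }
    new_genotypes(loci[, c("locus_id", "seq_id", "pos", "allele1", "allele2")],
                  inds, calls)
  })
}

#' Hide genomic windows as unplaced contigs
#'
#' Carves random non-overlapping windows out of an anchored genotype matrix
#' and re-labels their SNP loci as sitting on unplaced contigs (positions
#' rebased to the contig), producing a placement benchmark with known
#' truth. A prior-assignment map records each contig's true chromosome for
#' a fraction of contigs (`"-"` for the rest).
#'
#' @param genotypes Anchored `nc_genotypes`.
#' @param seq_lengths Named vector of pseudomolecule lengths.
#' @param n_contigs Number of windows to hide.
#' @param contig_bp Window (contig) length.
#' @param prior_fraction Fraction of contigs given a prior chromosome.
#' @param windows Optional explicit windows (tibble `seq_id`, `start`,
#'   `end`) overriding the random draw.
#' @param seed RNG seed.
#' @return List: `anchored` (remaining matrix), `contigs` (matrix with
#'   contig `seq_id`s), `contig_ids`, `prior`, `truth` (tibble `contig_id`,
#'   `true_seq`, `true_start`, `true_end`, `true_mid`, `n_snps`).
#' @export
fragment_and_hide <- function(genotypes, seq_lengths, n_contigs = 100,
                              contig_bp = 5e5, prior_fraction = 1,
                              windows = NULL, seed = NULL) {
  stopifnot(inherits(genotypes, "nc_genotypes"))
  local_seed(seed, {
    if (is.null(windows)) {
      taken <- lapply(seq_lengths, function(x) tibble(start = numeric(), end = numeric()))
      wins <- list()
      attempts <- 0
      while (length(wins) < n_contigs && attempts < n_contigs * 50) {
        attempts <- attempts + 1
        sq <- sample(names(seq_lengths), 1,
                     prob = unname(seq_lengths) / sum(seq_lengths))
        if (seq_lengths[[sq]] <= contig_bp) next
        s <- floor(stats::runif(1, 0, seq_lengths[[sq]] - contig_bp))
        e <- s + contig_bp
        if (any(taken[[sq]]$start < e & taken[[sq]]$end > s)) next
        taken[[sq]] <- dplyr::bind_rows(taken[[sq]], tibble(start = s, end = e))
        wins[[length(wins) + 1]] <- tibble(seq_id = sq, start = s, end = e)
      }
      if (length(wins) < n_contigs) abort("could not fit the requested windows")
      wins <- dplyr::bind_rows(wins)
    } else {
      wins <- as_tibble(windows)
      assert_cols(wins, c("seq_id", "start", "end"), "windows")
    }
    wins$contig_id <- sprintf("ctg%04d", seq_len(nrow(wins)))
    loci <- genotypes$loci
    hidden_idx <- integer()
    new_loci <- list()
    for (i in seq_len(nrow(wins))) {
      w <- wins[i, ]
      j <- which(loci$seq_id == w$seq_id & loci$pos >= w$start & loci$pos < w$end)
      hidden_idx <- c(hidden_idx, j)
      if (length(j) > 0) {
        nl <- loci[j, ]
        nl$seq_id <- w$contig_id
        nl$pos <- nl$pos - as.integer(w$start)
        new_loci[[length(new_loci) + 1]] <- nl
      }
    }
    truth <- tibble(
      contig_id = wins$contig_id, true_seq = wins$seq_id,
      true_start = wins$start, true_end = wins$end,
      true_mid = (wins$start + wins$end) / 2,
      n_snps = purrr::map_int(seq_len(nrow(wins)), function(i) {
        sum(loci$seq_id == wins$seq_id[i] & loci$pos >= wins$start[i] &
              loci$pos < wins$end[i])
      })
    )
    keep <- setdiff(seq_len(nrow(loci)), hidden_idx)
    anchored <- new_genotypes(loci[keep, ], genotypes$individuals,
                              genotypes$calls[keep, , drop = FALSE])
    hid <- dplyr::bind_rows(new_loci)
    contigs <- new_genotypes(hid, genotypes$individuals,
                             genotypes$calls[hidden_idx, , drop = FALSE])
    has_prior <- stats::runif(nrow(wins)) < prior_fraction
    prior <- tibble(contig_id = wins$contig_id,
                    prior_seq = ifelse(has_prior, wins$seq_id, "-"))
    list(anchored = anchored, contigs = contigs, contig_ids = wins$contig_id,
         prior = prior, truth = truth)
  })
}

# Poisson read-start pileup: per-base depth with mean `depth`, correlated
# over `read_length` as real short-read coverage is. Reads overhanging
# either end are clipped.
pileup <- function(L, depth, read_length = 100) {
  if (depth <= 0) {
    return(integer(L))
  }
  span <- L + read_length - 1
  n <- stats::rpois(1, span * depth / read_length)
  if (n == 0) {
    return(integer(L))
  }
  starts <- sample.int(span, n, replace = TRUE) - read_length # 0-based, may be < 0
  delta <- integer(L + 1)
  s <- pmax(starts, 0L) + 1L
  e <- pmin(starts + read_length, L) + 1L
  ok <- s < e
  delta_add <- tabulate(s[ok], nbins = L + 1) - tabulate(e[ok], nbins = L + 1)
  cumsum(delta_add)[seq_len(L)]
}

#' Simulate unique- and all-placement coverage tracks
#'
#' Generates per-base depth for an assembly from its copy-number structure
#' using a Poisson read-start pileup (reads of `read_length`, mean depth
#' `mean_depth` per genomic copy):
#'
#' * single-copy positions: unique and all-placement depth coincide;
#' * collapsed positions (g genomic copies, one assembly copy): unique
#'   depth rises to about g * `mean_depth`, still uniquely mapped;
#' * assembly-repeat positions (several assembly copies): unique depth is
#'   exactly 0 (no read maps uniquely) while all-placement depth stays
#'   normal per copy.
#'
#' @param assembly Assembly tibble or named lengths.
#' @param registry Duplication registry from [simulate_parents()]'s truth
#'   (or `NULL` for a repeat-free genome).
#' @param mean_depth Mean single-copy depth.
#' @param read_length Read length driving the depth autocorrelation.
#' @param seed RNG seed.
#' @return `nc_coverage` tibble with `unique` and `all` tracks per
#'   sequence.
#' @export
simulate_coverage <- function(assembly, registry = NULL, mean_depth = 30,
                              read_length = 100, seed = NULL) {
  lens <- if (is.data.frame(assembly)) {
    stats::setNames(assembly$length, assembly$seq_id)
  } else {
    assembly
  }
  local_seed(seed, {
    tracks <- list()
    for (sq in names(lens)) {
      L <- as.integer(lens[[sq]])
      uni <- pileup(L, mean_depth, read_length)
      if (!is.null(registry) && nrow(registry) > 0) {
        coll <- registry[registry$seq_id == sq &
                           registry$genome_copies > registry$assembly_copies &
                           registry$assembly_copies == 1L, ]
        for (i in seq_len(nrow(coll))) {
          s <- coll$start[i]
          e <- coll$end[i]
          extra <- pileup(e - s, (coll$genome_copies[i] - 1L) * mean_depth,
                          read_length)
          uni[(s + 1L):e] <- uni[(s + 1L):e] + extra
        }
      }
      all_t <- uni
      if (!is.null(registry) && nrow(registry) > 0) {
        reps <- registry[registry$assembly_copies >= 2L, ]
        for (i in seq_len(nrow(reps))) {
          locs <- reps$assembly_locs[[i]]
          locs <- locs[locs$seq_id == sq, ]
          per_copy <- reps$genome_copies[i] * mean_depth / reps$assembly_copies[i]
          for (j in seq_len(nrow(locs))) {
            s <- locs$start[j]
            e <- locs$end[j]
            uni[(s + 1L):e] <- 0L
            all_t[(s + 1L):e] <- pileup(e - s, per_copy, read_length)
          }
        }
      }
      tracks[[length(tracks) + 1]] <- coverage_track(sq, "unique", uni)
      tracks[[length(tracks) + 1]] <- coverage_track(sq, "all", all_t)
    }
    bind_coverage(tracks)
  })
}

#' Simulate genomic coverage with deleted genes
#'
#' Produces a depth track in which a chosen set of genes is absent from the
#' read donor: their exonic bases get zero depth, everything else Poisson
#' (or exactly constant when `noiseless`).
#'
#' @param genes Gene tibble.
#' @param seq_lengths Named sequence lengths.
#' @param n_delete Number of genes to delete (ignored when `deleted_ids`
#'   given).
#' @param deleted_ids Explicit gene ids to delete.
#' @param mean_depth Background depth.
#' @param noiseless Use constant depth instead of per-base Poisson draws.
#' @param seed RNG seed.
#' @return List: `coverage` (`nc_coverage`, mode `unique`) and `deleted`
#'   (character ids).
#' @export
simulate_gene_loss <- function(genes, seq_lengths, n_delete = 0,
                               deleted_ids = NULL, mean_depth = 10,
                               noiseless = FALSE, seed = NULL) {
  local_seed(seed, {
    if (is.null(deleted_ids)) {
      deleted_ids <- sample(genes$gene_id, n_delete)
    }
    tracks <- list()
    for (sq in names(seq_lengths)) {
      L <- as.integer(seq_lengths[[sq]])
      d <- if (noiseless) rep(as.integer(mean_depth), L) else stats::rpois(L, mean_depth)
      del <- genes[genes$gene_id %in% deleted_ids & genes$seq_id == sq, ]
      for (i in seq_len(nrow(del))) {
        ex <- del$exons[[i]]
        for (j in seq_len(nrow(ex))) d[(ex$start[j] + 1L):ex$end[j]] <- 0L
      }
      tracks[[length(tracks) + 1]] <- coverage_track(sq, "unique", d)
    }
    list(coverage = bind_coverage(tracks), deleted = deleted_ids)
  })
}

#' Simulate a k-mer multiplicity histogram
#'
#' Mixture model: each distinct single-copy k-mer draws its multiplicity
#' from Poisson(coverage), each distinct c-copy repeat k-mer from
#' Poisson(c * coverage); optional error mass is added at multiplicities
#' 1-2. Heterozygosity is not modelled (homozygous lines).
#'
#' @param genome_bp Genome size (bp ~ k-mer count).
#' @param repeat_fraction Fraction of the genome lying in repeats.
#' @param repeat_copies Copy number of the repeat portion.
#' @param coverage Mean sequencing coverage.
#' @param error_rate Per-base error rate feeding the error mass.
#' @param k K-mer length recorded on the histogram.
#' @param seed RNG seed.
#' @return List: `histogram` (`nc_kmer_hist`) and `truth` (list with
#'   `genome_size`, `assembly_size`).
#' @export
simulate_kmer_histogram <- function(genome_bp = 1e6, repeat_fraction = 0,
                                    repeat_copies = 2, coverage = 30,
                                    error_rate = 0, k = 21, seed = NULL) {
  local_seed(seed, {
    n_rep_distinct <- round(genome_bp * repeat_fraction / repeat_copies)
    n_single <- round(genome_bp * (1 - repeat_fraction))
    mult <- c(stats::rpois(n_single, coverage),
              stats::rpois(n_rep_distinct, coverage * repeat_copies))
    mult <- mult[mult >= 1]
    tab <- tabulate(mult)
    counts <- tibble(multiplicity = seq_along(tab), count = tab)
    counts <- counts[counts$count > 0, ]
    if (error_rate > 0) {
      n_err <- round(error_rate * coverage * genome_bp)
      err <- tibble(multiplicity = c(1, 2),
                    count = round(c(0.9, 0.1) * n_err))
      counts <- dplyr::summarise(
        dplyr::group_by(dplyr::bind_rows(counts, err), .data$multiplicity),
        count = sum(.data$count), .groups = "drop"
      )
    }
    list(
      histogram = as_kmer_histogram(counts, k = k),
      truth = list(genome_size = n_single + n_rep_distinct * repeat_copies,
                   assembly_size = n_single + n_rep_distinct)
    )
  })
}

#' Coverage benchmark for collapsed/repeat region calling
#'
#' Builds a synthetic assembly with known collapsed duplications (several
#' genomic copies, one assembly copy) and assembly repeats (two assembly
#' copies), simulates unique/all coverage over it, and returns the truth
#' intervals. Defaults follow the whole-genome-shotgun setting the region
#' caller targets: a 2 Mbp assembly, 20 collapsed and 20 repeated segments
#' of 0.5-3 kbp, ~75x read depth (the per-cultivar sequencing depth of a
#' typical crop resequencing project).
#'
#' @param assembly_bp Backbone assembly length.
#' @param n_collapsed,n_repetitive Segment counts per class.
#' @param seg_bp Segment length range (bp).
#' @param mean_depth Single-copy read depth.
#' @param seed RNG seed.
#' @return List: `coverage` (`nc_coverage`), `truth` (region tibble with
#'   `seq_id`, `start`, `end`, `class`), `registry`, `assembly`.
#' @export
simulate_corefinder_benchmark <- function(assembly_bp = 2e6, n_collapsed = 20,
                                          n_repetitive = 20,
                                          seg_bp = c(500, 3000),
                                          mean_depth = 75, seed = NULL) {
  local_seed(seed, {
    n <- n_collapsed + n_repetitive
    # evenly spaced slots with jitter keep segments non-overlapping
    slot <- floor(assembly_bp / n)
    stopifnot(slot > 2 * max(seg_bp))
    starts <- (seq_len(n) - 1L) * slot +
      sample.int(slot - max(seg_bp) - 1L, n, replace = TRUE)
    lens <- sample(seq(seg_bp[1], seg_bp[2]), n, replace = TRUE)
    cls <- sample(rep(c("collapsed", "repetitive"),
                      c(n_collapsed, n_repetitive)))
    dups <- tibble(
      seq_id = "chrA01", start = starts, end = starts + lens,
      genome_copies = ifelse(cls == "collapsed",
                             sample(2:3, n, replace = TRUE), 2L),
      assembly_copies = ifelse(cls == "collapsed", 1L, 2L)
    )
    sim <- simulate_parents(n_chrom = 1, chrom_bp = assembly_bp,
                            snp_rate = 0.001, duplications = dups)
    registry <- sim$truth$duplications
    coverage <- simulate_coverage(sim$assembly, registry,
                                  mean_depth = mean_depth)
    truth <- dplyr::bind_rows(
      dplyr::transmute(dups[cls == "collapsed", ], .data$seq_id, .data$start,
                       .data$end, class = "collapsed"),
      dplyr::mutate(
        dplyr::bind_rows(registry$assembly_locs[registry$assembly_copies >= 2L]),
        class = "repetitive"
      )
    )
    list(coverage = coverage, truth = truth, registry = registry,
         assembly = sim$assembly)
  })
}

#' Block-level precision and recall of region calls
#'
#' Scores called regions against truth intervals per class: a true segment
#' is recovered when at least `min_frac` of its bases are covered by calls
#' of its class, and a call is correct when at least `min_frac` of its
#' bases fall inside true segments of its class.
#'
#' @param calls,truth Region tibbles (`seq_id`, `start`, `end`, `class`).
#' @param min_frac Matching overlap fraction.
#' @return Tibble with `class`, `precision`, `recall`, `n_calls`, `n_truth`.
#' @export
region_recovery <- function(calls, truth, min_frac = 0.5) {
  frac_covered <- function(s, e, sq, other) {
    o <- other[other$seq_id == sq, ]
    if (nrow(o) == 0) {
      return(0)
    }
    ov <- pmin(o$end, e) - pmax(o$start, s)
    sum(ov[ov > 0]) / (e - s)
  }
  score <- function(from, against) {
    if (nrow(from) == 0) {
      return(NA_real_)
    }
    mean(purrr::pmap_dbl(from[c("start", "end", "seq_id")],
                         function(start, end, seq_id) {
                           frac_covered(start, end, seq_id, against)
                         }) >= min_frac)
  }
  dplyr::bind_rows(purrr::map(sort(unique(truth$class)), function(cl) {
    ca <- calls[calls$class == cl, ]
    tr <- truth[truth$class == cl, ]
    tibble(class = cl, precision = score(ca, tr), recall = score(tr, ca),
           n_calls = nrow(ca), n_truth = nrow(tr))
  }))
}

#' Full linkage-placement benchmark
#'
#' Composes the generators into the standard placement test bed: a
#' doubled-haploid population of `n_individuals` genotyped at SNP loci on
#' `n_chrom` pseudomolecules (half A, half C), from which `n_contigs`
#' windows are hidden as unplaced contigs. With the defaults (92
#' individuals; 10 chromosomes of 20 Mbp at 10 SNPs/Mbp and 2 cM/Mbp; 1 Mbp
#' anchor bins, hence 200 bins; 100 hidden contigs of 0.5 Mbp; 50%
#' missingness, the call rate of low-coverage skim genotyping) it matches
#' the scale at which the placement engine is validated.
#'
#' @param n_individuals,n_chrom,chrom_bp,snps_per_mbp,cm_per_mbp,
#'   n_contigs,contig_bp,missing_rate Scenario parameters.
#' @param config An [nc_config()] (supplies `bin_bp`).
#' @param seed RNG seed.
#' @return List: `bins`, `contigs`, `contig_ids`, `prior`, `truth`,
#'   `anchored`, `seq_lengths`.
#' @export
simulate_placement_benchmark <- function(n_individuals = 92, n_chrom = 10,
                                         chrom_bp = 2e7, snps_per_mbp = 10,
                                         cm_per_mbp = 2, n_contigs = 100,
                                         contig_bp = 5e5, missing_rate = 0.5,
                                         config = nc_config(), seed = NULL) {
  local_seed(seed, {
    n_a <- ceiling(n_chrom / 2)
    chroms <- c(sprintf("chrA%02d", seq_len(n_a)),
                sprintf("chrC%02d", seq_len(n_chrom - n_a)))
    seq_lengths <- stats::setNames(rep(chrom_bp, n_chrom), chroms)
    # one SNP per 1/snps_per_mbp Mbp stratum: realistic density with no
    # empty anchor bin
    spacing <- floor(1e6 / snps_per_mbp)
    n_per <- floor(chrom_bp / spacing)
    loci <- dplyr::bind_rows(purrr::map(chroms, function(ch) {
      pos <- (seq_len(n_per) - 1L) * spacing +
        sample.int(spacing, n_per, replace = TRUE) - 1L
      tibble(seq_id = ch, pos = pos, cm = pos / 1e6 * cm_per_mbp)
    }))
    geno <- simulate_dh_population(loci, n_individuals, missing_rate)
    # hide each contig inside a distinct anchor bin so every bin keeps loci
    n_bins_total <- n_chrom * floor(chrom_bp / config$bin_bp)
    stopifnot(n_contigs <= n_bins_total, contig_bp < config$bin_bp)
    bin_idx <- sort(sample.int(n_bins_total, n_contigs))
    bins_per_chrom <- floor(chrom_bp / config$bin_bp)
    windows <- tibble(
      seq_id = chroms[(bin_idx - 1) %/% bins_per_chrom + 1],
      start = ((bin_idx - 1) %% bins_per_chrom) * config$bin_bp +
        floor(stats::runif(n_contigs, 0, config$bin_bp - contig_bp))
    )
    windows$end <- windows$start + contig_bp
    parts <- fragment_and_hide(geno, seq_lengths, windows = windows)
    bins <- build_anchor_bins(parts$anchored, bin_bp = config$bin_bp,
                              seq_lengths = seq_lengths)
    c(parts[c("anchored", "contigs", "contig_ids", "prior", "truth")],
      list(bins = bins, seq_lengths = seq_lengths))
  })
}
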