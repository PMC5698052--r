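# Independent brute-force evaluators used as oracles. Deliberately written
# as plain loops, sharing no code with the package implementations.

# Literal placement rule: r against every bin, global minimum, margin to the
# best bin on any other pseudomolecule.
bf_place_contig <- function(contig, bins, cfg) {
  r <- numeric(nrow(bins))
  for (i in seq_len(nrow(bins))) {
    v <- bins$consensus[[i]]
    both <- !is.na(v) & !is.na(contig)
    r[i] <- if (sum(both) < cfg$min_informative) NA_real_ else {
      sum(v[both] != contig[both]) / sum(both)
    }
  }
  if (all(is.na(r))) return(list(status = "insufficient", seq_id = NA, position = NA))
  best <- NA
  for (i in seq_len(nrow(bins))) {
    if (is.na(r[i])) next
    if (is.na(best)) {
      best <- i
    } else if (r[i] < r[best] ||
               (r[i] == r[best] && bins$n_snps[i] > bins$n_snps[best]) ||
               (r[i] == r[best] && bins$n_snps[i] == bins$n_snps[best] &&
                bins$start[i] < bins$start[best])) {
      best <- i
    }
  }
  r_best <- r[best]
  r2 <- Inf
  for (i in seq_len(nrow(bins))) {
    if (!is.na(r[i]) && bins$seq_id[i] != bins$seq_id[best] && r[i] < r2) r2 <- r[i]
  }
  if (r_best > cfg$r_max) return(list(status = "insufficient", seq_id = NA, position = NA))
  if (r2 - r_best >= cfg$delta_conflict) {
    list(status = "placed", seq_id = bins$seq_id[best], position = bins$mid[best])
  } else {
    list(status = "conflict", seq_id = NA, position = NA)
  }
}

# Per-position run finder: scan a logical vector, collect maximal TRUE runs
# of at least min_len as 0-based half-open intervals.
bf_runs <- function(pred, min_len) {
  out <- list()
  i <- 1
  n <- length(pred)
  while (i <= n) {
    if (pred[i]) {
      j <- i
      while (j < n && pred[j + 1]) j <- j + 1
      if (j - i + 1 >= min_len) out[[length(out) + 1]] <- c(i - 1, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2] + 1)
}

# Per-base presence fraction.
bf_presence_frac <- function(exons, depth, min_depth) {
  covered <- 0
  total <- 0
  for (k in seq_len(nrow(exons))) {
    for (b in (exons$start[k] + 1):exons$end[k]) {
      total <- total + 1
      if (depth[b] >= min_depth) covered <- covered + 1
    }
  }
  covered / total
}

# Exhaustive longest valid chain (monotone rank_b, bounded rank gaps on
# both sides) over all subsequences; feasible for <= 15 pairs.
bf_longest_chain <- function(ra, rb, max_gap) {
  n <- length(ra)
  best <- 0
  extend <- function(last, len, dir) {
    best <<- max(best, len)
    for (nxt in seq_len(n)) {
      da <- ra[nxt] - ra[last]
      db <- rb[nxt] - rb[last]
      ok <- da >= 1 && da <= max_gap &&
        ((dir == 1 && db >= 1 && db <= max_gap) ||
         (dir == -1 && db <= -1 && db >= -max_gap))
      if (ok) extend(nxt, len + 1, dir)
    }
  }
  for (s in seq_len(n)) {
    extend(s, 1, 1)
    extend(s, 1, -1)
  }
  best
}

# Tiny genotype-object builder for linkage tests.
make_geno <- function(calls, seq_id = "chrA01", pos = NULL) {
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1)
  n <- nrow(calls)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  if (length(seq_id) == 1) seq_id <- rep(seq_id, n)
  if (is.null(colnames(calls))) colnames(calls) <- sprintf("i%02d", seq_len(ncol(calls)))
  loci <- tibble::tibble(locus_id = sprintf("L%03d", seq_len(n)), seq_id = seq_id,
                         pos = as.integer(pos), allele1 = "A", allele2 = "C")
  rownames(calls) <- loci$locus_id
  napcomp:::new_genotypes(loci, colnames(calls), calls)
}

# Random genotype vector with missingness.
rand_vec <- function(n, miss = 0.2) {
  v <- sample(c("P1", "P2"), n, replace = TRUE)
  v[runif(n) < miss] <- NA
  v
}
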