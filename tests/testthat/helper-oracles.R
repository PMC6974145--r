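# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (per-coordinate sweeps, all-pairs loops, grid searches,
# full enumerations) and never share code with the implementation they
# check.

# -- fixtures ----------------------------------------------------------------

# quick gene from a list of exon tibbles, one per transcript
make_gene <- function(exon_sets, strand = "+", gene_id = "G1") {
  txs <- purrr::imap(exon_sets, function(ex, i) {
    transcript_model(paste0("tx", i), tibble::tibble(start = ex[, 1],
                                                     end = ex[, 2]), strand)
  })
  gene_model(gene_id, "chrT", strand, unname(txs))
}

# random valid gene: <= 6 transcripts of <= 10 exons on a small coordinate
# grid (assumes the calling test has seeded the RNG)
random_gene <- function(max_tx = 6, max_exons = 10, span = 120) {
  n_tx <- sample(1:max_tx, 1)
  exon_sets <- purrr::map(seq_len(n_tx), function(i) {
    k <- sample(1:max_exons, 1)
    bounds <- sort(sample(0:span, 2 * k))
    # drop empty exons created by duplicated-free sampling quirks
    m <- matrix(bounds, ncol = 2, byrow = TRUE)
    m[m[, 2] > m[, 1], , drop = FALSE]
  })
  exon_sets <- purrr::keep(exon_sets, \(m) nrow(m) > 0)
  if (length(exon_sets) == 0) exon_sets <- list(cbind(0, 10))
  make_gene(exon_sets)
}

# -- oracles -----------------------------------------------------------------

# exonic-part oracle: per-coordinate sweep, grouping runs of equal covering
# transcript sets
sweep_parts_oracle <- function(gene) {
  ex <- purrr::list_rbind(purrr::imap(
    gene$transcripts, \(tx, id) dplyr::mutate(tx$exons, tx = id)))
  lo <- min(ex$start); hi <- max(ex$end)
  coords <- lo:(hi - 1)
  cover <- purrr::map_chr(coords, function(x) {
    hit <- sort(unique(ex$tx[ex$start <= x & ex$end > x]))
    paste(hit, collapse = ",")
  })
  runs <- rle(cover)
  ends <- lo + cumsum(runs$lengths)
  starts <- c(lo, utils::head(ends, -1))
  out <- data.frame(start = starts, end = ends, set = runs$values)
  out[out$set != "", , drop = FALSE]
}

# junction-count oracle: explicit per-read loop
junction_count_oracle <- function(reads, min_overhang) {
  tally <- list()
  for (id in unique(reads$read_id)) {
    b <- reads[reads$read_id == id, ]
    b <- b[order(b$start), ]
    if (nrow(b) < 2) next
    for (i in seq_len(nrow(b) - 1)) {
      w1 <- b$end[i] - b$start[i]
      w2 <- b$end[i + 1] - b$start[i + 1]
      if (w1 >= min_overhang && w2 >= min_overhang &&
          b$start[i + 1] > b$end[i]) {
        key <- paste(b$end[i], b$start[i + 1])
        tally[[key]] <- (tally[[key]] %||% 0) + 1
      }
    }
  }
  tally
}

# all-pairs overlap-count oracle for parts/introns
overlap_count_oracle <- function(reads, features) {
  counts <- setNames(rep(0L, nrow(features)), features$feature_id)
  for (id in unique(reads$read_id)) {
    b <- reads[reads$read_id == id, ]
    for (f in seq_len(nrow(features))) {
      hit <- any(b$start < features$end[f] & b$end > features$start[f])
      if (hit) counts[f] <- counts[f] + 1L
    }
  }
  counts
}

# grid-search oracle for the two-isoform EM: maximises the compatibility
# class log-likelihood with class probability proportional to theta * J
em_grid_oracle <- function(counts, J, step = 1e-3) {
  thetas <- seq(step, 1 - step, by = step)
  ll <- purrr::map_dbl(thetas, function(t1) {
    th <- c(t1, 1 - t1)
    tj <- th * J
    p <- tj / sum(tj)
    sum(counts * log(p))
  })
  thetas[which.max(ll)]
}

# full-enumeration exact-test oracle over all tables with the observed
# margins (rational-free; uses plain choose())
fisher_enum_oracle <- function(tab, alternative = "two.sided") {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(a) {
    choose(r1, a) * choose(n - r1, c1 - a) / choose(n, c1)
  }, numeric(1))
  a_obs <- tab[1, 1]
  p_obs <- probs[match(a_obs, support)]
  switch(alternative,
         greater = sum(probs[support >= a_obs]),
         less = sum(probs[support <= a_obs]),
         two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
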