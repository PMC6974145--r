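# Gene model, flattening, junctions and the coordinate/amplicon arithmetic.

test_that("exonic-part flattening handles the canonical cases", {
  # no overlap to split: parts are the exons themselves
  g1 <- make_gene(list(rbind(c(0, 100), c(200, 300))))
  p1 <- flatten_exonic_parts(g1)
  expect_equal(p1$start, c(0, 200))
  expect_equal(p1$end, c(100, 300))
  expect_equal(p1$part_id, c("G1:001", "G1:002"))

  # a transcript ending mid-exon splits the part
  g2 <- make_gene(list(rbind(c(0, 100), c(200, 300)),
                       rbind(c(0, 100), c(200, 250))))
  p2 <- flatten_exonic_parts(g2)
  expect_equal(p2$start, c(0, 200, 250))
  expect_equal(p2$end, c(100, 250, 300))
  expect_equal(p2$transcripts[[2]], c("tx1", "tx2"))
  expect_equal(p2$transcripts[[3]], "tx1")

  # skipped cassette exon is its own part, supported by the inclusive tx only
  g3 <- make_gene(list(rbind(c(0, 50), c(100, 150), c(200, 250)),
                       rbind(c(0, 50), c(200, 250))))
  p3 <- flatten_exonic_parts(g3)
  expect_equal(nrow(p3), 3L)
  expect_equal(p3$transcripts[[2]], "tx1")
})

test_that("flattening agrees with the per-coordinate sweep oracle", {
  set.seed(42)
  for (i in 1:25) {
    g <- random_gene()
    parts <- flatten_exonic_parts(g)
    oracle <- sweep_parts_oracle(g)
    expect_equal(parts$start, oracle$start, ignore_attr = TRUE)
    expect_equal(parts$end, oracle$end, ignore_attr = TRUE)
    expect_equal(purrr::map_chr(parts$transcripts, paste, collapse = ","),
                 oracle$set, ignore_attr = TRUE)
    # partition invariant: total part length equals the exon-union length
    pseudo <- build_pseudo_transcript(g)
    expect_equal(sum(parts$width), sum(pseudo$end - pseudo$start))
  }
})

test_that("pseudo-transcript is the exon union; adjacency is not merged", {
  expect_equal(build_pseudo_transcript(make_gene(list(rbind(c(0, 100))))),
               tibble::tibble(start = 0, end = 100))
  expect_equal(
    build_pseudo_transcript(make_gene(list(rbind(c(0, 100)),
                                           rbind(c(50, 150))))),
    tibble::tibble(start = 0, end = 150))
  # adjacent-but-not-overlapping exons stay separate
  g_adj <- make_gene(list(rbind(c(0, 100)), rbind(c(100, 150))))
  expect_equal(nrow(build_pseudo_transcript(g_adj)), 2L)
  # skipping isoform adds nothing to the union of the inclusive isoform
  g <- tyk2_like_gene()
  g_full_only <- gene_model("G", g$chrom, g$strand,
                            list(g$transcripts[["TYK2L-201"]]))
  expect_equal(build_pseudo_transcript(g)[, c("start", "end")],
               build_pseudo_transcript(g_full_only)[, c("start", "end")])
})

test_that("introns are the gaps and tile the span with the pseudo-exons", {
  pseudo <- tibble::tibble(start = c(0, 200), end = c(100, 300))
  expect_equal(derive_introns(pseudo)$start, 100)
  expect_equal(derive_introns(pseudo)$end, 200)
  expect_equal(nrow(derive_introns(tibble::tibble(start = 0, end = 100))), 0L)

  g <- tyk2_like_gene()
  ps <- build_pseudo_transcript(g)
  ir <- derive_introns(ps)
  expect_equal(nrow(ir), 2L)
  span <- max(ps$end) - min(ps$start)
  expect_equal(sum(ir$width), span - sum(ps$end - ps$start))
  # no overlap, no gap: sorted breakpoints alternate exon/intron exactly
  tiles <- dplyr::arrange(dplyr::bind_rows(ps, ir[, c("start", "end")]), start)
  expect_true(all(tiles$start[-1] == tiles$end[-nrow(tiles)]))
})

test_that("junction enumeration dedupes across isoforms and shares sites", {
  g <- tyk2_like_gene()
  jx <- enumerate_junctions(g)
  expect_equal(nrow(jx), 3L)
  # e7-e8 and e7-e9 share the exon-7 donor site
  expect_equal(sum(jx$start == 1430), 2L)
  sites <- splice_sites(jx)
  expect_equal(sum(sites$kind == "donor" & sites$coordinate == 1430), 1L)
  # single-exon transcripts contribute no junctions
  g1 <- make_gene(list(rbind(c(0, 100))))
  expect_equal(nrow(enumerate_junctions(g1)), 0L)
})

test_that("minus-strand donor is the junction endpoint with the larger coordinate", {
  g <- make_gene(list(rbind(c(0, 100), c(200, 300))), strand = "-")
  jx <- enumerate_junctions(g)
  sites <- splice_sites(jx)
  expect_equal(sites$kind[sites$coordinate == 200], "donor")
  expect_equal(sites$kind[sites$coordinate == 100], "acceptor")
})

test_that("CDS position to codon index follows the printed variant arithmetic", {
  expect_equal(cds_to_codon(1084), 362L)
  expect_equal(cds_to_codon(c(1, 3, 4)), c(1L, 1L, 2L))
  expect_error(cds_to_codon(0), ">= 1")
  # non-decreasing, constant on each 3-nt block
  codons <- cds_to_codon(1:300)
  expect_true(all(diff(codons) >= 0))
  expect_true(all(tapply(codons, codons, length) == 3))
})

test_that("peptide span length and frame preservation match the cassette", {
  expect_equal(peptide_span_length(338, 403), 66L)
  expect_equal(peptide_span_length(1, 1), 1L)
  expect_equal(peptide_span_length(10, 12), 3L)
  expect_error(peptide_span_length(5, 4), "<=")
  expect_true(frame_preserved(198))
  expect_true(frame_preserved(0))
  expect_false(frame_preserved(100))
  expect_error(frame_preserved(-3), ">= 0")
})

test_that("in-silico amplicon reproduces the 740/542-nt products", {
  g <- tyk2_like_gene()
  pr <- tyk2_like_primers()
  full <- g$transcripts[["TYK2L-201"]]
  skip <- g$transcripts[["TYK2L-204"]]
  expect_equal(in_silico_amplicon(full, pr$fwd, pr$rev), 740L)
  expect_equal(in_silico_amplicon(skip, pr$fwd, pr$rev, reference = full), 542L)
  expect_equal(740L - 542L, 198L)
  # anchor inside the skipped exon: no product
  fwd8 <- primer_anchor(2, 5, "forward")
  expect_true(is.na(in_silico_amplicon(skip, fwd8, pr$rev, reference = full)))
  # reverse primer upstream of forward: error
  expect_error(in_silico_amplicon(full, primer_anchor(3, 200, "forward"),
                                  primer_anchor(1, 0, "reverse")),
               "upstream")
  expect_error(primer_anchor(1, 2, "sideways"))
})

test_that("amplicon difference equals the cassette width on random fixtures", {
  set.seed(7)
  for (i in 1:20) {
    w <- sample(50:400, 3)
    gaps <- sample(100:500, 2)
    s1 <- 0; e1 <- w[1]
    s2 <- e1 + gaps[1]; e2 <- s2 + w[2]
    s3 <- e2 + gaps[2]; e3 <- s3 + w[3]
    strand <- sample(c("+", "-"), 1)
    full <- transcript_model("full", tibble::tibble(
      start = c(s1, s2, s3), end = c(e1, e2, e3)), strand)
    skip <- transcript_model("skip", tibble::tibble(
      start = c(s1, s3), end = c(e1, e3)), strand)
    # anchors index exons in transcript (5'->3') order, so on the minus
    # strand exon 1 is the genomically last exon
    w_tx <- if (strand == "+") w else rev(w)
    fwd <- primer_anchor(1, sample(0:(w_tx[1] - 1), 1), "forward")
    rev <- primer_anchor(3, sample(0:(w_tx[3] - 1), 1), "reverse")
    a_full <- in_silico_amplicon(full, fwd, rev)
    a_skip <- tryCatch(in_silico_amplicon(skip, fwd, rev, reference = full),
                       error = function(e) NA_integer_)
    if (!is.na(a_skip)) expect_equal(a_full - a_skip, w[2])
  }
})

test_that("model constructors enforce their invariants", {
  expect_error(transcript_model("t", tibble::tibble(start = 10, end = 10)),
               "empty")
  expect_error(transcript_model("t", tibble::tibble(start = c(0, 50),
                                                    end = c(60, 100))),
               "overlap")
  tx_plus <- transcript_model("t", tibble::tibble(start = 0, end = 10), "+")
  tx_minus <- transcript_model("u", tibble::tibble(start = 0, end = 10), "-")
  expect_error(gene_model("g", "chr1", "+", list(tx_plus, tx_minus)),
               "strand")
  expect_error(transcript_model("t", tibble::tibble(start = 0, end = 9),
                                cds_start_offset = 9),
               "spliced")
})
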