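# Read-level quantification, normalisation, PSI and the junction-class EM.

test_that("junction counting enforces the overhang filter", {
  r_ok <- tibble::tibble(read_id = "r1", start = c(94, 200), end = c(100, 206))
  jc <- extract_junction_counts(r_ok, min_overhang = 6)
  expect_equal(nrow(jc), 1L)
  expect_equal(jc$start, 100)
  expect_equal(jc$end, 200)
  expect_equal(jc$count, 1L)

  # 5-nt left overhang fails a 6-nt filter
  r_short <- tibble::tibble(read_id = "r1", start = c(95, 200),
                            end = c(100, 210))
  expect_equal(nrow(extract_junction_counts(r_short, 6)), 0L)
  expect_equal(nrow(extract_junction_counts(r_short, 5)), 1L)

  # unspliced reads contribute nothing
  r_mono <- tibble::tibble(read_id = "r1", start = 10, end = 60)
  expect_equal(nrow(extract_junction_counts(r_mono)), 0L)
  expect_error(extract_junction_counts(r_ok, min_overhang = 0))
})

test_that("junction counts match the per-read loop oracle and are monotone in the filter", {
  g <- tyk2_like_gene()
  jx <- enumerate_junctions(g)
  set.seed(11)
  jx$count <- c(400, 350, 250)
  reads <- simulate_junction_reads(jx, overhang_range = c(2L, 20L))
  for (oh in c(1L, 6L)) {
    got <- extract_junction_counts(reads, oh)
    oracle <- junction_count_oracle(reads, oh)
    expect_equal(sum(got$count), sum(unlist(oracle)))
    for (i in seq_len(nrow(got))) {
      key <- paste(got$start[i], got$end[i])
      expect_equal(got$count[i], as.integer(oracle[[key]]))
    }
  }
  # element-wise monotonicity: relaxing the filter never lowers a count
  loose <- extract_junction_counts(reads, 1L)
  strict <- extract_junction_counts(reads, 6L)
  merged <- dplyr::left_join(loose, strict, by = c("start", "end", "sample_id"))
  expect_true(all(merged$count.x >= dplyr::coalesce(merged$count.y, 0L)))
})

test_that("exonic-part and intron counting follow the union rule", {
  parts <- tibble::tibble(part_id = c("p1", "p2"), start = c(0, 200),
                          end = c(100, 300))
  r1 <- tibble::tibble(read_id = "r1", start = 0, end = 50)
  expect_equal(count_exonic_parts(r1, parts)$count, c(1L, 0L))
  # a spliced read increments the part on each side once
  r2 <- tibble::tibble(read_id = "r1", start = c(90, 200), end = c(100, 210))
  expect_equal(count_exonic_parts(r2, parts)$count, c(1L, 1L))

  introns <- tibble::tibble(start = 100, end = 200)
  inside <- tibble::tibble(read_id = "r1", start = 150, end = 160)
  expect_equal(count_introns(inside, introns)$count, 1L)
  # a junction-spanning read jumps the intron without touching it
  expect_equal(count_introns(r2, introns)$count, 0L)
})

test_that("overlap counters agree with the all-pairs oracle on random reads", {
  set.seed(23)
  features <- tibble::tibble(feature_id = sprintf("f%d", 1:5),
                             start = c(0, 120, 300, 520, 800),
                             end = c(100, 260, 480, 700, 900))
  reads <- purrr::list_rbind(purrr::map(1:300, function(i) {
    s <- sample(0:850, 1)
    if (runif(1) < 0.4) {
      gap <- sample(20:200, 1)
      tibble::tibble(read_id = sprintf("r%03d", i),
                     start = c(s, s + 30 + gap), end = c(s + 30, s + 60 + gap))
    } else {
      tibble::tibble(read_id = sprintf("r%03d", i), start = s, end = s + 50)
    }
  }))
  got <- count_exonic_parts(reads, dplyr::rename(features, part_id = "feature_id"))
  oracle <- overlap_count_oracle(reads, features)
  expect_equal(setNames(got$count, got$feature_id), oracle)
})

test_that("splice-site activity is additive and conserves junction counts", {
  g <- tyk2_like_gene()
  jx <- enumerate_junctions(g)
  counts <- tibble::tibble(start = jx$start, end = jx$end,
                           count = c(30, 10, 30))  # e7-e8, e7-e9, e8-e9
  act <- splice_site_activity(counts, jx)
  # exon-7 donor feeds both outgoing junctions
  expect_equal(act$count[act$site_id == "donor:1430"], 40)
  expect_equal(act$count[act$site_id == "acceptor:3630"], 30)  # exon-8 acceptor
  expect_equal(act$count[act$site_id == "donor:3828"], 30)     # exon-8 donor
  # conservation: donor total == acceptor total == junction total
  expect_equal(sum(act$count[act$kind == "donor"]), sum(counts$count))
  expect_equal(sum(act$count[act$kind == "acceptor"]), sum(counts$count))

  set.seed(5)
  for (i in 1:10) {
    counts$count <- rpois(3, 50)
    act <- splice_site_activity(counts, jx)
    expect_equal(sum(act$count[act$kind == "donor"]), sum(counts$count))
    expect_equal(sum(act$count[act$kind == "acceptor"]), sum(counts$count))
  }
  expect_error(splice_site_activity(tibble::tibble(start = 1, end = 2,
                                                   count = 1), jx),
               "unknown junction")
})

test_that("RPKM and RPM are definitional and scale-invariant", {
  expect_equal(rpkm(10, 1e6, 1000), 10)
  expect_equal(rpkm(0, 1e6, 500), 0)
  expect_equal(rpm(5, 1e6), 5)
  expect_equal(rpm(0, 1e6), 0)
  # scaling count and library size together leaves RPKM unchanged
  expect_equal(rpkm(7 * 13, 7 * 2e6, 750), rpkm(13, 2e6, 750),
               tolerance = 1e-12)
  expect_equal(rpm(7 * 13, 7 * 2e6), rpm(13, 2e6), tolerance = 1e-12)
  # linearity in count
  expect_equal(rpm(3 * 11, 1e6), 3 * rpm(11, 1e6), tolerance = 1e-12)
  expect_error(rpkm(1, 0, 100), "library_size")
  expect_error(rpkm(1, 100, 0), "length")
  expect_error(rpm(1, 0), "library_size")
})

test_that("PSI estimator averages inclusion evidence and flags missing", {
  expect_equal(estimate_psi(30, 30, 10)$psi, 0.75)
  expect_equal(estimate_psi(0, 0, 50)$psi, 0)
  expect_true(is.na(estimate_psi(0, 0, 0)$psi))
  expect_error(estimate_psi(-1, 0, 0), ">= 0")
  # Monte-Carlo recovery at true PSI 0.9, depth 200
  set.seed(31)
  psi_true <- 0.9
  reps <- 500
  psi_hat <- estimate_psi(rpois(reps, 200 * psi_true),
                          rpois(reps, 200 * psi_true),
                          rpois(reps, 200 * (1 - psi_true)))$psi
  expect_lt(abs(mean(psi_hat) - psi_true), 0.02)
})

test_that("junction-class EM solves the two-isoform problem exactly", {
  cls <- tibble::tibble(count = c(90, 10), isoforms = list("full", "skip"))
  nj <- c(full = 2L, skip = 1L)
  fit <- quantify_transcripts_em(cls, nj)
  expect_equal(unname(fit$theta["full"]), 45 / 55, tolerance = 1e-6)
  expect_true(fit$converged)
  # grid-search oracle on the same likelihood
  expect_equal(unname(fit$theta["full"]),
               em_grid_oracle(c(90, 10), c(2, 1)), tolerance = 1e-3)
  # single isoform and symmetric counts with equal weights
  one <- quantify_transcripts_em(
    tibble::tibble(count = 50, isoforms = list("only")), c(only = 1L))
  expect_equal(unname(one$theta), 1)
  sym <- quantify_transcripts_em(
    tibble::tibble(count = c(40, 40), isoforms = list("a", "b")),
    c(a = 2L, b = 2L))
  expect_equal(unname(sym$theta), c(0.5, 0.5), tolerance = 1e-8)
})

test_that("EM is order-invariant, monotone in log-likelihood, and validates input", {
  set.seed(13)
  for (i in 1:10) {
    counts <- rpois(3, 60) + 1
    cls <- tibble::tibble(count = counts,
                          isoforms = list("full", "skip", c("full", "skip")))
    nj <- c(full = 2L, skip = 1L)
    fit <- quantify_transcripts_em(cls, nj)
    expect_true(all(diff(fit$loglik_trace) >= -1e-10))
    expect_equal(sum(fit$theta), 1)
    # shuffling class order does not change the solution
    perm <- sample(3)
    fit2 <- quantify_transcripts_em(cls[perm, ], nj)
    expect_equal(fit$theta, fit2$theta, tolerance = 1e-9)
    # grid oracle agreement within 1e-3
    expect_equal(unname(fit$theta["full"]),
                 em_grid_oracle(counts[1:2], c(2, 1)), tolerance = 2e-3)
  }
  expect_error(quantify_transcripts_em(
    tibble::tibble(count = numeric(0), isoforms = list()), c(a = 1L)),
    "no compatibility classes")
  expect_error(quantify_transcripts_em(
    tibble::tibble(count = 5, isoforms = list("a")), c(a = 0L)),
    "zero informative junctions")
  # tidy/glance views
  fit <- quantify_transcripts_em(
    tibble::tibble(count = c(9, 1), isoforms = list("full", "skip")),
    c(full = 2L, skip = 1L))
  expect_named(tidy(fit), c("isoform", "theta"))
  expect_equal(glance(fit)$n_reads, 10)
})
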