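# Feature-level quantification from aligned-read block lists: junctions with
# overhang filtering, exonic parts, introns, splice-site activities,
# RPKM/RPM normalisation, PSI, and an EM over junction compatibility
# classes for isoform proportions.
#
# Aligned reads are represented as a tibble with one row per aligned block:
# columns `read_id`, `start`, `end` (0-based half-open) and optionally
# `sample_id`. The gaps between consecutive blocks of a read are the read's
# introns.

# add a constant sample column when absent so every counter is per-sample
ensure_sample <- function(reads) {
  if (!"sample_id" %in% names(reads)) reads$sample_id <- "sample"
  reads
}

#' Count reads across exon-exon junctions with an overhang filter
#'
#' Each gap between consecutive blocks of a spliced read is one junction
#' observation; it is counted only when the two flanking blocks each align at
#' least `min_overhang` nucleotides into their exons. A read with k gaps can
#' contribute to k junctions. Unspliced reads contribute nothing.
#'
#' @param reads Read-block tibble (`read_id`, `start`, `end`, optional
#'   `sample_id`).
#' @param min_overhang Minimum flanking block length in nt (default 6).
#' @return A tibble with `start`, `end` (the intron interval), `sample_id`
#'   and `count`, one row per observed junction per sample.
#' @export
extract_junction_counts <- function(reads, min_overhang = 6L) {
  stopifnot(min_overhang >= 1L)
  reads <- ensure_sample(reads)
  obs <- reads |>
    arrange(.data$sample_id, .data$read_id, .data$start) |>
    mutate(
      .w = .data$end - .data$start,
      j_start = .data$end,
      j_end = lead(.data$start),
      ok = .data$.w >= min_overhang & lead(.data$.w) >= min_overhang,
      .by = c("sample_id", "read_id")
    ) |>
    filter(!is.na(.data$j_end), .data$j_end > .data$j_start, .data$ok)
  obs |>
    count(.data$sample_id, start = .data$j_start, end = .data$j_end,
          name = "count") |>
    arrange(.data$start, .data$end, .data$sample_id)
}

# union-rule overlap counter shared by exonic parts and introns: a read
# increments every feature that any of its blocks overlaps by >= 1 nt, at
# most once per feature
count_by_overlap <- function(reads, features) {
  reads <- ensure_sample(reads)
  hits <- inner_join(
    reads, features,
    by = join_by(x$start < y$end, x$end > y$start),
    suffix = c("", ".feature")
  ) |>
    distinct(.data$sample_id, .data$read_id, .data$feature_id) |>
    count(.data$sample_id, .data$feature_id, name = "count")
  features |>
    select("feature_id") |>
    crossing(sample_id = unique(reads$sample_id)) |>
    left_join(hits, by = c("sample_id", "feature_id")) |>
    mutate(count = coalesce(.data$count, 0L)) |>
    arrange(.data$feature_id, .data$sample_id)
}

#' Count reads over exonic parts
#'
#' Union rule: a read increments every part that any of its aligned blocks
#' overlaps by at least one nucleotide, once per part. Junction-spanning
#' reads therefore count toward the parts on both sides.
#'
#' @param reads Read-block tibble.
#' @param parts Tibble of disjoint parts as from [flatten_exonic_parts()]
#'   (`part_id`, `start`, `end`).
#' @return A tibble with `feature_id`, `sample_id`, `count` (zero-filled).
#' @export
count_exonic_parts <- function(reads, parts) {
  count_by_overlap(reads, parts |> select(feature_id = "part_id", "start", "end"))
}

#' Count reads over introns
#'
#' Same union overlap rule as [count_exonic_parts()], applied to intron
#' intervals. Spliced blocks that jump over an intron do not overlap it and
#' so do not count toward it; only retained-intron (or boundary-crossing)
#' alignments do.
#'
#' @param reads Read-block tibble.
#' @param introns Tibble of disjoint intron intervals (`start`, `end`),
#'   as from [derive_introns()]; row order defines `intron1`, `intron2`, ...
#'   ids unless an `intron_id` column is supplied.
#' @return A tibble with `feature_id`, `sample_id`, `count`.
#' @export
count_introns <- function(reads, introns) {
  if (!"intron_id" %in% names(introns)) {
    introns$intron_id <- sprintf("intron%d", seq_len(nrow(introns)))
  }
  count_by_overlap(reads,
                   introns |> select(feature_id = "intron_id", "start", "end"))
}

#' Splice-site activities from junction counts
#'
#' The activity of a donor or acceptor site is the sum of counts of all
#' junctions sharing that site, per sample. Because every junction has
#' exactly one donor and one acceptor, total donor activity equals total
#' acceptor activity equals the total junction count (a conservation
#' identity used in the tests).
#'
#' @param junction_counts Tibble with `start`, `end`, `count` and optional
#'   `sample_id`, as from [extract_junction_counts()].
#' @param junctions Junction table from [enumerate_junctions()]; every
#'   counted junction key must appear in it.
#' @return A tibble with `site_id`, `kind`, `coordinate`, `sample_id`,
#'   `count`.
#' @export
splice_site_activity <- function(junction_counts, junctions) {
  jc <- junction_counts
  if (!"sample_id" %in% names(jc)) jc$sample_id <- "sample"
  known <- paste(junctions$start, junctions$end)
  got <- paste(jc$start, jc$end)
  if (any(!got %in% known)) {
    abort(sprintf("unknown junction key(s): %s",
                  paste(unique(got[!got %in% known]), collapse = ", ")))
  }
  ann <- junctions |>
    mutate(donor = ifelse(.data$strand == "+", .data$start, .data$end),
           acceptor = ifelse(.data$strand == "+", .data$end, .data$start))
  jc |>
    inner_join(ann, by = c("start", "end")) |>
    pivot_longer(c("donor", "acceptor"), names_to = "kind",
                 values_to = "coordinate") |>
    summarise(count = sum(.data$count),
              .by = c("kind", "coordinate", "sample_id")) |>
    mutate(site_id = sprintf("%s:%d", .data$kind, .data$coordinate)) |>
    select("site_id", "kind", "coordinate", "sample_id", "count") |>
    arrange(.data$coordinate, .data$kind, .data$sample_id)
}

#' Reads per kilobase per million mapped reads
#'
#' `count * 1e9 / (library_size * feature_length_nt)`; used for transcripts,
#' exonic parts and introns.
#'
#' @param count Read count(s).
#' @param library_size Total counted reads in the sample (> 0).
#' @param feature_length_nt Feature length in nucleotides (> 0).
#' @return Numeric RPKM value(s).
#' @export
rpkm <- function(count, library_size, feature_length_nt) {
  if (any(library_size <= 0)) abort("library_size must be > 0")
  if (any(feature_length_nt <= 0)) abort("feature_length_nt must be > 0")
  count * 1e9 / (library_size * feature_length_nt)
}

#' Reads per million mapped reads
#'
#' `count * 1e6 / library_size`; used for junctions and splice sites, whose
#' "length" is not meaningful.
#'
#' @inheritParams rpkm
#' @return Numeric RPM value(s).
#' @export
rpm <- function(count, library_size) {
  if (any(library_size <= 0)) abort("library_size must be > 0")
  count * 1e6 / library_size
}

#' Percent spliced in from cassette junction counts
#'
#' For a cassette exon with inclusion junctions upstream (`c78`) and
#' downstream (`c89`) and one skipping junction (`c79`), inclusion evidence
#' is averaged over the two inclusion junctions: `inclusion = (c78 + c89)/2`,
#' `skip = c79`, `psi = inclusion / (inclusion + skip)`. When both evidence
#' totals are zero PSI is undefined and returned as `NA` (never 0).
#'
#' @param c78,c89,c79 Non-negative junction counts (vectorised).
#' @return A tibble with columns `inclusion`, `skip`, `psi`.
#' @export
estimate_psi <- function(c78, c89, c79) {
  if (any(c(c78, c89, c79) < 0)) abort("junction counts must be >= 0")
  inclusion <- (c78 + c89) / 2
  skip <- c79
  psi <- ifelse(inclusion + skip > 0, inclusion / (inclusion + skip), NA_real_)
  tibble(inclusion = inclusion, skip = skip, psi = psi)
}

#' Isoform proportions by EM over junction compatibility classes
#'
#' Junction reads are grouped into compatibility classes (the set of
#' isoforms each junction is consistent with). A molecule of isoform k
#' yields junction reads in proportion to its number of informative
#' junctions `J_k`, so the probability of a read falling in class c is
#' `sum_{k in c} theta_k * J_k / sum_k theta_k * J_k`, and the weight
#' `w_k = 1/J_k` converts read shares back to molecule proportions. The EM
#' iterates responsibilities and weighted re-normalisation from a uniform
#' start until `max |delta theta| < tol` (deterministic); the log-likelihood
#' is non-decreasing across iterations. Classes compatible with every
#' isoform are uninformative (e.g. shared exon-body reads) and are dropped.
#'
#' @param classes Tibble with a `count` column and an `isoforms` list-column
#'   of character vectors naming the compatible isoforms.
#' @param n_junctions Named integer vector: informative junctions per
#'   isoform (all >= 1).
#' @param tol,max_iter Convergence tolerance on `max |delta theta|` and
#'   iteration cap.
#' @return An object of class `em_fit` with elements `theta` (named, sums to
#'   1), `loglik`, `loglik_trace`, `n_iter`, `converged`. Use [tidy()] /
#'   [glance()] for tibble views.
#' @export
quantify_transcripts_em <- function(classes, n_junctions, tol = 1e-8,
                                    max_iter = 500L) {
  if (nrow(classes) == 0L) abort("no compatibility classes supplied")
  if (any(n_junctions < 1L)) {
    abort(sprintf("isoform(s) with zero informative junctions: %s",
                  paste(names(n_junctions)[n_junctions < 1L], collapse = ", ")))
  }
  iso <- names(n_junctions)
  if (length(iso) == 1L) {
    # degenerate model: every read supports the only isoform
    keep <- rep(TRUE, nrow(classes))
  } else {
    keep <- map_lgl(classes$isoforms, \(s) !setequal(s, iso))
  }
  classes <- classes[keep & classes$count > 0, ]
  if (nrow(classes) == 0L || sum(classes$count) == 0) {
    abort("no informative junction reads")
  }
  if (!all(unlist(classes$isoforms) %in% iso)) {
    abort("class refers to an isoform absent from n_junctions")
  }
  J <- as.numeric(n_junctions)
  names(J) <- iso
  memb <- map(classes$isoforms, \(s) match(s, iso))
  n_c <- classes$count
  theta <- rep(1 / length(iso), length(iso))
  ll <- function(theta) {
    tj <- theta * J
    sum(n_c * log(map_dbl(memb, \(m) sum(tj[m])) / sum(tj)))
  }
  trace <- ll(theta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    tj <- theta * J
    m_k <- numeric(length(iso))
    for (i in seq_along(memb)) {
      r <- tj[memb[[i]]]
      m_k[memb[[i]]] <- m_k[memb[[i]]] + n_c[i] * r / sum(r)
    }
    new_theta <- (m_k / J) / sum(m_k / J)
    trace <- c(trace, ll(new_theta))
    if (max(abs(new_theta - theta)) < tol) {
      theta <- new_theta
      converged <- TRUE
      break
    }
    theta <- new_theta
  }
  structure(
    list(theta = setNames(theta, iso), loglik = trace[length(trace)],
         loglik_trace = trace, n_iter = iter, converged = converged,
         n_reads = sum(n_c)),
    class = "em_fit"
  )
}

#' @export
print.em_fit <- function(x, ...) {
  cat("<em_fit> isoform proportions\n")
  print(round(x$theta, 4))
  cat(sprintf("loglik %.4f after %d iteration(s)%s\n", x$loglik, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @rdname quantify_transcripts_em
#' @param x An `em_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.em_fit <- function(x, ...) {
  tibble(isoform = names(x$theta), theta = unname(x$theta))
}

#' @rdname quantify_transcripts_em
#' @exportS3Method generics::glance
glance.em_fit <- function(x, ...) {
  tibble(loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
         n_reads = x$n_reads)
}
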