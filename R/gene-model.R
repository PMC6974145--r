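# Gene/transcript data model and derived splicing features.
#
# All internal coordinates are 0-based half-open [start, end); GTF I/O
# converts from/to the 1-based closed convention at the boundary.

#' Construct a transcript model
#'
#' A transcript is an ordered set of disjoint exon intervals on one strand.
#' Coordinates are 0-based half-open.
#'
#' @param transcript_id Character scalar.
#' @param exons A data frame (or 2-column matrix) with columns `start` and
#'   `end`, one row per exon.
#' @param strand `"+"` or `"-"`.
#' @param cds_start_offset Optional 0-based offset of the first coding base
#'   within the spliced transcript; must be smaller than the spliced length.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, exons, strand = "+",
                             cds_start_offset = NULL) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L)
  if (is.matrix(exons)) exons <- as.data.frame(exons) |> setNames(c("start", "end"))
  exons <- as_tibble(exons[, c("start", "end")])
  if (nrow(exons) == 0L) abort("a transcript needs at least one exon")
  if (any(exons$end <= exons$start)) {
    abort(sprintf("transcript %s has an empty or inverted exon", transcript_id))
  }
  exons <- arrange(exons, .data$start)
  if (any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    abort(sprintf("exons of transcript %s overlap", transcript_id))
  }
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  if (!is.null(cds_start_offset)) {
    if (cds_start_offset < 0 || cds_start_offset >= sum(exons$end - exons$start)) {
      abort("cds_start_offset must lie within the spliced transcript")
    }
  }
  structure(
    list(transcript_id = transcript_id, exons = exons, strand = strand,
         cds_start_offset = cds_start_offset),
    class = "transcript_model"
  )
}

#' Construct a gene model
#'
#' @param gene_id,chrom Character scalars.
#' @param strand `"+"` or `"-"`; all transcripts must agree.
#' @param transcripts List of [transcript_model()] objects.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  stopifnot(length(transcripts) >= 1L)
  if (!all(map_lgl(transcripts, inherits, "transcript_model"))) {
    abort("transcripts must be a list of transcript_model objects")
  }
  if (!all(map_lgl(transcripts, \(tx) tx$strand == strand))) {
    abort("all transcripts must share the gene strand")
  }
  names(transcripts) <- map_chr(transcripts, "transcript_id")
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         transcripts = transcripts),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s%s), %d transcript(s)\n",
              x$gene_id, x$chrom, x$strand, length(x$transcripts)))
  for (tx in x$transcripts) {
    cat(sprintf("  %s: %d exon(s), %d nt spliced\n", tx$transcript_id,
                nrow(tx$exons), sum(tx$exons$end - tx$exons$start)))
  }
  invisible(x)
}

# all exons of a gene as one long tibble
gene_exon_table <- function(gene) {
  list_rbind(imap(gene$transcripts,
                  \(tx, id) mutate(tx$exons, transcript_id = id)))
}

#' Flatten a gene into non-overlapping exonic parts
#'
#' Splits the union of all exons of the gene at every exon boundary and
#' merges runs with an identical set of supporting transcripts, yielding the
#' maximal sub-intervals within which transcript support is constant
#' (DEXSeq-style counting bins). Parts are numbered in ascending genomic
#' order regardless of strand.
#'
#' @param gene A [gene_model()].
#' @return A tibble with columns `part_id` (`"geneID:NNN"`), `start`, `end`,
#'   `width` and a list-column `transcripts` of supporting transcript ids.
#' @export
flatten_exonic_parts <- function(gene) {
  ex <- gene_exon_table(gene)
  bounds <- sort(unique(c(ex$start, ex$end)))
  cand <- tibble(start = bounds[-length(bounds)], end = bounds[-1L])
  support <- map(seq_len(nrow(cand)), function(i) {
    hit <- ex$start <= cand$start[i] & ex$end >= cand$end[i]
    sort(unique(ex$transcript_id[hit]))
  })
  keep <- lengths(support) > 0L
  cand <- cand[keep, ]
  support <- support[keep]
  if (nrow(cand) == 0L) abort("gene has no exonic bases")
  # merge contiguous runs with identical supporting sets
  key <- map_chr(support, paste, collapse = ",")
  new_run <- c(TRUE, key[-1L] != key[-length(key)] |
                 cand$start[-1L] != cand$end[-nrow(cand)])
  run_idx <- cumsum(new_run)
  parts <- cand |>
    mutate(.run = run_idx) |>
    summarise(start = min(.data$start), end = max(.data$end), .by = ".run") |>
    select(-".run")
  parts |>
    mutate(
      part_id = sprintf("%s:%03d", gene$gene_id, seq_len(nrow(parts))),
      width = .data$end - .data$start,
      transcripts = support[!duplicated(run_idx)]
    ) |>
    select("part_id", "start", "end", "width", "transcripts")
}

#' Build the pseudo-transcript of a gene
#'
#' Returns the merged union of all exon intervals of the gene, sorted by
#' coordinate. Intervals that touch but do not overlap are kept separate, so
#' a zero-length gap never appears but real gaps are preserved for intron
#' derivation.
#'
#' @param gene A [gene_model()].
#' @return A tibble with columns `start`, `end` of the pseudo-exons.
#' @export
build_pseudo_transcript <- function(gene) {
  ex <- gene_exon_table(gene) |> arrange(.data$start, .data$end)
  merged_start <- ex$start[1L]
  merged_end <- ex$end[1L]
  out_start <- out_end <- numeric(0)
  for (i in seq_len(nrow(ex))[-1L]) {
    if (ex$start[i] < merged_end) {  # strict: adjacency does not merge
      merged_end <- max(merged_end, ex$end[i])
    } else {
      out_start <- c(out_start, merged_start)
      out_end <- c(out_end, merged_end)
      merged_start <- ex$start[i]
      merged_end <- ex$end[i]
    }
  }
  tibble(start = c(out_start, merged_start), end = c(out_end, merged_end))
}

#' Derive introns from a pseudo-transcript
#'
#' The gaps between consecutive pseudo-exons are the gene's introns; together
#' with the pseudo-exons they partition the gene span. Zero-length gaps are
#' dropped.
#'
#' @param pseudo A tibble of sorted disjoint intervals, as returned by
#'   [build_pseudo_transcript()].
#' @return A tibble with columns `start`, `end`, `width`, one row per intron
#'   (empty when there is a single pseudo-exon).
#' @export
derive_introns <- function(pseudo) {
  if (nrow(pseudo) < 2L) {
    return(tibble(start = numeric(0), end = numeric(0), width = numeric(0)))
  }
  out <- tibble(start = pseudo$end[-nrow(pseudo)], end = pseudo$start[-1L])
  out |>
    filter(.data$end > .data$start) |>
    mutate(width = .data$end - .data$start)
}

#' Enumerate exon-exon junctions of a gene
#'
#' One junction per consecutive exon pair per transcript, deduplicated across
#' transcripts. A junction is stored as its intron interval: `start` is the
#' first intronic base and `end` is one past the last intronic base. An
#' exon-skipping isoform contributes the long junction spanning the skipped
#' exon.
#'
#' @param gene A [gene_model()].
#' @return A tibble with `junction_id`, `start`, `end`, `strand` and a
#'   list-column `transcripts` of supporting transcript ids.
#' @export
enumerate_junctions <- function(gene) {
  per_tx <- imap(gene$transcripts, function(tx, id) {
    k <- nrow(tx$exons)
    if (k < 2L) return(NULL)
    tibble(start = tx$exons$end[-k], end = tx$exons$start[-1L],
           transcript_id = id)
  })
  jx <- list_rbind(per_tx)
  if (is.null(jx) || nrow(jx) == 0L) {
    return(tibble(junction_id = character(0), start = numeric(0),
                  end = numeric(0), strand = character(0),
                  transcripts = list()))
  }
  jx |>
    summarise(transcripts = list(sort(unique(.data$transcript_id))),
              .by = c("start", "end")) |>
    arrange(.data$start, .data$end) |>
    mutate(junction_id = sprintf("%s:J%d-%d", gene$gene_id,
                                 .data$start, .data$end),
           strand = gene$strand) |>
    select("junction_id", "start", "end", "strand", "transcripts")
}

#' Splice sites of a junction table
#'
#' Each junction has a donor (5' end of the intron) and an acceptor (3' end).
#' On the plus strand the donor is the junction endpoint with the smaller
#' coordinate; on the minus strand the donor is the endpoint with the larger
#' coordinate.
#'
#' @param junctions A tibble as returned by [enumerate_junctions()].
#' @return A tibble with `site_id`, `kind` (`"donor"`/`"acceptor"`),
#'   `coordinate` and `strand`, one row per distinct site.
#' @export
splice_sites <- function(junctions) {
  plus <- junctions$strand == "+"
  donors <- ifelse(plus, junctions$start, junctions$end)
  acceptors <- ifelse(plus, junctions$end, junctions$start)
  tibble(
    kind = rep(c("donor", "acceptor"), each = nrow(junctions)),
    coordinate = c(donors, acceptors),
    strand = rep(junctions$strand, 2L)
  ) |>
    distinct() |>
    arrange(.data$coordinate, .data$kind) |>
    mutate(site_id = sprintf("%s:%d", .data$kind, .data$coordinate)) |>
    select("site_id", "kind", "coordinate", "strand")
}

#' Coding-sequence position to codon index
#'
#' Maps a 1-based coding-sequence nucleotide position to its 1-based codon
#' (residue) index; e.g. the c.1084 G>T change falls in codon 362.
#'
#' @param cds_position Integer vector of 1-based CDS positions.
#' @return Integer vector of codon indices.
#' @export
cds_to_codon <- function(cds_position) {
  if (any(cds_position < 1)) abort("cds_position must be >= 1")
  as.integer(floor((cds_position - 1) / 3) + 1)
}

#' Length of a peptide span in residues
#'
#' @param start_aa,end_aa 1-based residue indices, `start_aa <= end_aa`.
#' @return Integer residue count (`end - start + 1`).
#' @export
peptide_span_length <- function(start_aa, end_aa) {
  if (any(start_aa > end_aa)) abort("start_aa must be <= end_aa")
  as.integer(end_aa - start_aa + 1)
}

#' Does skipping a segment preserve the reading frame?
#'
#' @param skipped_length_nt Non-negative nucleotide count(s).
#' @return Logical: `TRUE` iff the length is a multiple of 3.
#' @export
frame_preserved <- function(skipped_length_nt) {
  if (any(skipped_length_nt < 0)) abort("length must be >= 0")
  skipped_length_nt %% 3 == 0
}

#' Define a primer anchor on a reference isoform
#'
#' Anchors are coordinate-based: a primer's 5' end sits at a 0-based offset
#' (measured in the transcript's 5'->3' direction) within one exon of a
#' reference isoform. Sequence matching is out of scope.
#'
#' @param exon_index 1-based exon index (in transcript order).
#' @param offset 0-based offset of the primer 5' end within that exon.
#' @param orientation `"forward"` or `"reverse"`.
#' @return An object of class `primer_anchor`.
#' @export
primer_anchor <- function(exon_index, offset,
                          orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  stopifnot(exon_index >= 1L, offset >= 0)
  structure(list(exon_index = as.integer(exon_index), offset = as.integer(offset),
                 orientation = orientation),
            class = "primer_anchor")
}

# exons of a transcript in 5'->3' transcript order
exons_tx_order <- function(tx) {
  if (tx$strand == "+") tx$exons else tx$exons[rev(seq_len(nrow(tx$exons))), ]
}

# genomic coordinate of the base at transcript-direction `offset` in exon row
anchor_genomic_base <- function(exon, strand, offset) {
  if (offset >= exon$end - exon$start) {
    abort("primer offset exceeds the anchor exon length")
  }
  if (strand == "+") exon$start + offset else exon$end - 1 - offset
}

# spliced (5'->3') 0-based position of a genomic base in an isoform, or NA
spliced_position <- function(isoform, genomic_base) {
  ex <- exons_tx_order(isoform)
  pos <- 0L
  for (i in seq_len(nrow(ex))) {
    w <- ex$end[i] - ex$start[i]
    if (genomic_base >= ex$start[i] && genomic_base < ex$end[i]) {
      within <- if (isoform$strand == "+") genomic_base - ex$start[i]
                else ex$end[i] - 1 - genomic_base
      return(pos + within)
    }
    pos <- pos + w
  }
  NA_integer_
}

#' In-silico RT-PCR amplicon length on an isoform
#'
#' Resolves forward and reverse primer anchors on a reference isoform to
#' genomic bases, then measures the product on the spliced target isoform
#' from the forward primer 5' end through the reverse primer 5' end,
#' inclusive. If either anchor base is absent from the target isoform (its
#' exon is skipped) there is no product. For a primer pair flanking a
#' cassette exon, the inclusive and skipping isoforms differ by exactly the
#' cassette length (e.g. 740 vs 542 nt for a 198-nt exon).
#'
#' @param isoform Target [transcript_model()] to amplify.
#' @param fwd,rev [primer_anchor()]s (`"forward"` and `"reverse"`).
#' @param reference Isoform on which the anchors are defined; defaults to
#'   `isoform`.
#' @return Integer amplicon length in nt, or `NA` when there is no product.
#' @export
in_silico_amplicon <- function(isoform, fwd, rev, reference = isoform) {
  stopifnot(inherits(fwd, "primer_anchor"), inherits(rev, "primer_anchor"))
  if (fwd$orientation != "forward" || rev$orientation != "reverse") {
    abort("fwd must be a forward anchor and rev a reverse anchor")
  }
  if (isoform$strand != reference$strand) {
    abort("isoform and reference must be on the same strand")
  }
  ref_ex <- exons_tx_order(reference)
  if (fwd$exon_index > nrow(ref_ex) || rev$exon_index > nrow(ref_ex)) {
    abort("anchor exon index exceeds the reference exon count")
  }
  fwd_base <- anchor_genomic_base(ref_ex[fwd$exon_index, ], reference$strand,
                                  fwd$offset)
  rev_base <- anchor_genomic_base(ref_ex[rev$exon_index, ], reference$strand,
                                  rev$offset)
  p1 <- spliced_position(isoform, fwd_base)
  p2 <- spliced_position(isoform, rev_base)
  if (is.na(p1) || is.na(p2)) return(NA_integer_)  # no product
  if (p2 <= p1) abort("reverse primer lies upstream of the forward primer")
  as.integer(p2 - p1 + 1L)
}

#' Synthetic three-exon cassette gene ("TYK2-like")
#'
#' A synthetic plus-strand gene with exons 7/8/9 of widths 430/198/320 nt and
#' two isoforms: the inclusive `TYK2L-201` (e7-e8-e9) and the skipping
#' `TYK2L-204` (e7-e9). Exon widths and the packaged primer anchors (see
#' [tyk2_like_primers()]) are calibrated so the exon7->exon9 RT-PCR product
#' is 740 nt on the inclusive isoform and 542 nt on the skipping isoform,
#' with a 198-nt (frame-preserving) cassette. The gene is synthetic: no real
#' TYK2 sequence or coordinates are used.
#'
#' @return A [gene_model()].
#' @export
tyk2_like_gene <- function() {
  e7 <- c(1000, 1430)   # 430 nt
  e8 <- c(3630, 3828)   # 198 nt cassette
  e9 <- c(5328, 5648)   # 320 nt
  full <- transcript_model("TYK2L-201",
                           tibble(start = c(e7[1], e8[1], e9[1]),
                                  end = c(e7[2], e8[2], e9[2])), "+")
  skip <- transcript_model("TYK2L-204",
                           tibble(start = c(e7[1], e9[1]),
                                  end = c(e7[2], e9[2])), "+")
  gene_model("TYK2L", "chrS", "+", list(full, skip))
}

#' Primer anchors for the synthetic cassette gene
#'
#' Forward primer 20 nt into exon 7 and reverse primer with its 5' end 131 nt
#' into exon 9 (transcript direction), giving a 740-nt product on the
#' inclusive isoform of [tyk2_like_gene()] and 542 nt on the skipping one.
#'
#' @return A list with elements `fwd` and `rev` ([primer_anchor()]s).
#' @export
tyk2_like_primers <- function() {
  list(fwd = primer_anchor(1L, 20L, "forward"),
       rev = primer_anchor(3L, 131L, "reverse"))
}
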