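# Readers and writers for the standard formats the pipeline touches:
# GTF annotation (via rtracklayer), VCF genotypes (via vcfR; a minimal
# text writer for the two-SNP simulated fixture), STAR SJ.out.tab-style
# junction tables, BED6 feature exports, TSV count matrices, YAML
# configuration and the JSON run manifest / fixture bundle.
#
# Internal coordinates are 0-based half-open; every reader/writer converts
# at the boundary (GTF and SJ tables are 1-based closed, BED is 0-based
# half-open).

#' Read gene models from a GTF file
#'
#' Parses Ensembl-dialect GTF (gene_id/transcript_id attributes) through
#' rtracklayer, keeps exon features only, groups them by gene and
#' transcript and converts the 1-based closed coordinates to the internal
#' 0-based half-open convention.
#'
#' @param path GTF file.
#' @return A named list of [gene_model()] objects.
#' @export
read_gtf <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) abort(sprintf("malformed GTF '%s': %s", path,
                                      conditionMessage(e)))
  )
  df <- as.data.frame(gr)
  df <- df[df$type == "exon", , drop = FALSE]
  if (nrow(df) == 0L) abort(sprintf("no exon features in '%s'", path))
  genes <- split(df, df$gene_id)
  out <- map(genes, function(gd) {
    strand <- unique(as.character(gd$strand))
    chrom <- unique(as.character(gd$seqnames))
    if (length(strand) != 1L || length(chrom) != 1L) {
      abort(sprintf("gene %s spans multiple strands or chromosomes",
                    gd$gene_id[1]))
    }
    txs <- split(gd, gd$transcript_id)
    tx_models <- imap(txs, function(td, id) {
      transcript_model(id,
                       tibble(start = td$start - 1, end = td$end),
                       strand = strand)
    })
    gene_model(gd$gene_id[1], chrom, strand, unname(tx_models))
  })
  out
}

#' Write gene models to a GTF file
#'
#' Emits one exon feature per exon per transcript, converting internal
#' 0-based half-open coordinates back to GTF's 1-based closed convention.
#'
#' @param genes A [gene_model()] or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  rows <- list_rbind(map(genes, function(g) {
    list_rbind(imap(g$transcripts, function(tx, id) {
      tibble(seqnames = g$chrom, start = tx$exons$start + 1,
             end = tx$exons$end, strand = g$strand, type = "exon",
             gene_id = g$gene_id, transcript_id = id)
    }))
  }))
  gr <- GenomicRanges::makeGRangesFromDataFrame(rows, keep.extra.columns = TRUE)
  S4Vectors::mcols(gr)$source <- "splicedose"
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read minor-allele dosages from a VCF
#'
#' Extracts GT fields (phased or unphased are equivalent) of biallelic SNP
#' records into dosage vectors: the dosage is the count of ALT alleles,
#' `./.` becomes `NA`, sample order is preserved. Multiallelic records and
#' missing ids are rejected.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param snp_ids Optional character vector of record ids to extract
#'   (default: all records).
#' @return A long tibble with `snp_id`, `sample_id`, `dosage`.
#' @export
read_vcf_dosages <- function(path, snp_ids = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- v@fix[, "ID"]
  if (is.null(snp_ids)) snp_ids <- ids
  missing_ids <- setdiff(snp_ids, ids)
  if (length(missing_ids)) {
    abort(sprintf("SNP id(s) not in VCF: %s",
                  paste(missing_ids, collapse = ", ")))
  }
  keep <- match(snp_ids, ids)
  alt <- v@fix[keep, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    abort(sprintf("multiallelic record(s) not supported: %s",
                  paste(snp_ids[multi], collapse = ", ")))
  }
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  samples <- colnames(gt)
  list_rbind(map(seq_along(snp_ids), function(i) {
    alleles <- strsplit(gt[i, ], "[/|]")
    dosage <- unname(map_int(alleles, function(a) {
      if (any(is.na(a)) || any(a == ".")) NA_integer_ else sum(a == "1")
    }))
    tibble(snp_id = snp_ids[i], sample_id = samples, dosage = dosage)
  }))
}

#' Write a biallelic-SNP VCF from dosage vectors
#'
#' Minimal VCF 4.2 writer for simulated genotypes: dosages 0/1/2 become
#' GT `0/0`, `0/1`, `1/1`; `NA` becomes `./.`.
#'
#' @param genotypes Long tibble with `snp_id`, `sample_id`, `dosage`.
#' @param path Output file.
#' @param meta Optional tibble with `snp_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`; defaults to placeholder coordinates.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path, meta = NULL) {
  wide <- genotypes |>
    pivot_wider(names_from = "sample_id", values_from = "dosage")
  if (is.null(meta)) {
    meta <- tibble(snp_id = wide$snp_id, chrom = "chrS",
                   pos = 1000L + 100L * seq_len(nrow(wide)),
                   ref = "C", alt = "A")
  }
  meta <- meta[match(wide$snp_id, meta$snp_id), ]
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  samples <- setdiff(names(wide), "snp_id")
  body <- map_chr(seq_len(nrow(wide)), function(i) {
    gts <- unlist(wide[i, samples])
    gt <- ifelse(is.na(gts), "./.", gt_code[as.character(gts)])
    paste(c(meta$chrom[i], meta$pos[i], wide$snp_id[i], meta$ref[i],
            meta$alt[i], ".", "PASS", ".", "GT", gt), collapse = "\t")
  })
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=splicedose",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a STAR SJ.out.tab-style junction table
#'
#' Nine tab-separated columns: chromosome, 1-based first and last intronic
#' base, strand code (0 undefined, 1 `+`, 2 `-`), intron motif, annotation
#' flag, unique-read count, multi-read count, maximum overhang. Coordinates
#' are converted to 0-based half-open and the unique-read count is exposed
#' as `count`.
#'
#' @param path Input TSV.
#' @return A tibble with `chrom`, `start`, `end`, `strand`, `count`,
#'   `motif`, `annotated`, `n_multi`, `max_overhang`.
#' @export
read_star_sj <- function(path) {
  cols <- c("chrom", "first_base", "last_base", "strand_code", "motif",
            "annotated", "count", "n_multi", "max_overhang")
  df <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE)
  df |>
    mutate(start = .data$first_base - 1, end = .data$last_base,
           strand = c("*", "+", "-")[.data$strand_code + 1L]) |>
    select("chrom", "start", "end", "strand", "count", "motif",
           "annotated", "n_multi", "max_overhang")
}

#' Write a STAR SJ.out.tab-style junction table
#'
#' Inverse of [read_star_sj()]; missing annotation columns default to 0.
#'
#' @param junctions Tibble with `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `count`; optional `motif`, `annotated`,
#'   `n_multi`, `max_overhang`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_star_sj <- function(junctions, path) {
  for (col in c("motif", "annotated", "n_multi", "max_overhang")) {
    if (!col %in% names(junctions)) junctions[[col]] <- 0L
  }
  out <- junctions |>
    mutate(first_base = .data$start + 1, last_base = .data$end,
           strand_code = match(.data$strand, c("*", "+", "-")) - 1L) |>
    select("chrom", "first_base", "last_base", "strand_code", "motif",
           "annotated", "count", "n_multi", "max_overhang")
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Export intervals as BED6
#'
#' BED is natively 0-based half-open, matching the internal convention, so
#' coordinates pass through unchanged. The score column is fixed at 0.
#'
#' @param features Tibble with `start`, `end`, a name column (`part_id`,
#'   `intron_id`, `feature_id` or `name`) and optionally `chrom`/`strand`.
#' @param path Output file.
#' @param chrom,strand Defaults used when the columns are absent.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(features, path, chrom = "chrS", strand = "+") {
  name_col <- intersect(c("name", "part_id", "intron_id", "feature_id"),
                        names(features))[1]
  if (is.na(name_col)) abort("no name column found for BED output")
  out <- tibble(
    chrom = if ("chrom" %in% names(features)) features$chrom else chrom,
    start = as.integer(features$start),
    end = as.integer(features$end),
    name = features[[name_col]],
    score = 0L,
    strand = if ("strand" %in% names(features)) features$strand else strand
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read/write a feature-by-sample count matrix TSV
#'
#' The first column is `feature_id`; the header row carries the sample ids.
#'
#' @param path TSV file.
#' @return `read_count_matrix()`: a wide tibble.
#' @export
read_count_matrix <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_count_matrix
#' @param counts Wide tibble (`feature_id` + one column per sample).
#' @export
write_count_matrix <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read a simulation/pipeline configuration from YAML
#'
#' Fields mirror [sim_config()] plus optional analysis options
#' (`min_overhang`, `log1p`, `alpha_level`, `condition_on`); unknown fields
#' are rejected so typos fail loudly.
#'
#' @param path YAML file.
#' @return A list of class `sim_config` (analysis options kept as
#'   attributes `options`).
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare `n` key as boolean FALSE; map it back, and also
  # accept the unambiguous alias `n_samples`
  names(raw)[names(raw) == "FALSE"] <- "n"
  names(raw)[names(raw) == "n_samples"] <- "n"
  opt_names <- c("min_overhang", "log1p", "alpha_level", "condition_on")
  opts <- raw[intersect(names(raw), opt_names)]
  raw <- raw[setdiff(names(raw), opt_names)]
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("unknown config field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg <- do.call(sim_config, raw)
  attr(cfg, "options") <- opts
  cfg
}

#' Write the fixture bundle of a simulated study
#'
#' Serialises a [simulate_splicing_study()] result as plain-text files:
#' `genotypes.vcf` (the two SNPs), `annotation.gtf` (the synthetic cassette
#' gene), `junction_counts.tsv`, `counts.tsv` (all feature counts),
#' `covariates.tsv`, `phenotypes.tsv` and `truth.json` (per-sample truth
#' plus the full configuration including the seed). Reading the bundle back
#' with [read_fixture_bundle()] reproduces the genotypes, counts,
#' covariates and truth exactly.
#'
#' @param sim A `splice_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create '%s'", dir))
  geno_long <- bind_rows(
    tibble(snp_id = "snpA", sample_id = sim$genotypes$sample_id,
           dosage = sim$genotypes$dosage1),
    tibble(snp_id = "snpB", sample_id = sim$genotypes$sample_id,
           dosage = sim$genotypes$dosage2)
  )
  write_vcf(geno_long, file.path(dir, "genotypes.vcf"))
  write_gtf(sim$gene, file.path(dir, "annotation.gtf"))
  jx <- sim$counts |> select("sample_id", "c78", "c89", "c79")
  readr::write_tsv(jx, file.path(dir, "junction_counts.tsv"))
  readr::write_tsv(sim$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(sim$covariates, file.path(dir, "covariates.tsv"))
  readr::write_tsv(sim$phenotypes, file.path(dir, "phenotypes.tsv"))
  jsonlite::write_json(
    list(config = sim$config[!map_lgl(sim$config, is.null)],
         truth = sim$truth),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = I(17)
  )
  invisible(dir)
}

#' Read a fixture bundle back
#'
#' @param dir Directory written by [write_fixture_bundle()].
#' @return A list with `genotypes`, `counts`, `covariates`, `truth`,
#'   `config` and `genes` (from the bundled GTF).
#' @export
read_fixture_bundle <- function(dir) {
  geno <- read_vcf_dosages(file.path(dir, "genotypes.vcf"))
  geno_wide <- geno |>
    pivot_wider(names_from = "snp_id", values_from = "dosage") |>
    rename(dosage1 = "snpA", dosage2 = "snpB")
  tj <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  counts <- readr::read_tsv(file.path(dir, "counts.tsv"),
                            show_col_types = FALSE)
  cov <- readr::read_tsv(file.path(dir, "covariates.tsv"),
                         show_col_types = FALSE) |>
    mutate(pop = factor(.data$pop))
  list(genotypes = geno_wide, counts = counts, covariates = cov,
       truth = as_tibble(tj$truth), config = tj$config,
       genes = read_gtf(file.path(dir, "annotation.gtf")))
}

#' Write a JSON run manifest
#'
#' Records tool version, seed, configuration (with an md5 hash of its JSON
#' serialisation), input-file checksums and a timestamp — enough to
#' reproduce a run.
#'
#' @param path Output JSON file.
#' @param config A `sim_config` (or any serialisable list).
#' @param inputs Character vector of input file paths to checksum.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, config, inputs = character()) {
  cfg_json <- jsonlite::toJSON(config[!map_lgl(config, is.null)],
                               auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    tool = "splicedose",
    version = as.character(packageVersion("splicedose")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config[!map_lgl(config, is.null)],
    config_md5 = unname(tools::md5sum(tmp)),
    inputs = if (length(inputs)) {
      as.list(setNames(unname(tools::md5sum(inputs)), basename(inputs)))
    } else list()
  )
  unlink(tmp)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = I(17))
  invisible(manifest)
}
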