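#' Chromosome tables
#'
#' A chromosome table is a tibble with columns `chrom` (unique names) and
#' `length` (positive integer base pairs). It defines the genomic space over
#' which the uniform breakage-and-repair null operates.
#'
#' @param chrom Character vector of chromosome names.
#' @param length Positive integer chromosome lengths (bp).
#' @return A tibble with columns `chrom`, `length`.
#' @export
#' @examples
#' chromosome_table(c("chr1", "chr2"), c(1e6, 5e5))
chromosome_table <- function(chrom, length) {
  if (anyDuplicated(chrom)) abort("Chromosome names must be unique.")
  if (any(length <= 0) || any(!is.finite(length))) {
    abort("Chromosome lengths must be positive and finite.")
  }
  tibble(chrom = as.character(chrom), length = as.numeric(length))
}

#' Read a UCSC-style chrom.sizes file
#'
#' @param path Two-column tab-separated file: chromosome name, length.
#' @return A chromosome table tibble.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = readr::cols(chrom = "c", length = "d"),
                       progress = FALSE)
  chromosome_table(x$chrom, x$length)
}

#' hg19 chromosome lengths
#'
#' The standard UCSC hg19 lengths for chr1-22, X and Y, embedded as constants.
#' These define the genomic space for the whole-genome breakage null on human
#' data.
#'
#' @return A chromosome table tibble with 24 rows.
#' @export
#' @examples
#' expected_intrachromosomal_fraction(hg19_chromosomes())
hg19_chromosomes <- function() {
  chromosome_table(
    c(paste0("chr", 1:22), "chrX", "chrY"),
    c(249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
      159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
      115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
      59128983, 63025520, 48129895, 51304566, 155270560, 59373566)
  )
}

# ---------------------------------------------------------------------------
# Annotation object
#
# All internal coordinates are 0-based half-open; the GTF reader converts from
# GTF's 1-based closed convention at the boundary. An annotation holds one
# representative transcript per gene (longest CDS, ties: longest cDNA, then
# lexicographically smallest transcript id).
# ---------------------------------------------------------------------------

new_annotation <- function(transcripts, exons, genes, chrom_table) {
  structure(
    list(transcripts = transcripts, exons = exons, genes = genes,
         chrom_table = chrom_table),
    class = "fusion_annotation"
  )
}

#' @export
print.fusion_annotation <- function(x, ...) {
  cat(sprintf(
    "<fusion_annotation> %d genes / %d transcripts on %d chromosomes (%d coding)\n",
    nrow(x$genes), nrow(x$transcripts), nrow(x$chrom_table),
    sum(x$transcripts$coding)
  ))
  invisible(x)
}

# Build an annotation from 0-based half-open exon intervals plus CDS genomic
# bounds. `exons`: tibble(transcript_id, gene, chrom, strand, start, end);
# `cds`: tibble(transcript_id, cds_start, cds_end) (absent rows = non-coding).
build_annotation <- function(exons, cds, chrom_table) {
  exons <- exons |> arrange(.data$transcript_id, .data$start)
  bad <- exons |>
    group_by(.data$transcript_id) |>
    summarise(overlap = any(.data$start[-1] < .data$end[-n()] & n() > 1)) |>
    filter(.data$overlap)
  if (nrow(bad) > 0) {
    abort(sprintf("Overlapping exons in transcript(s): %s",
                  paste(head(bad$transcript_id, 5), collapse = ", ")))
  }

  tx <- exons |>
    group_by(.data$transcript_id, .data$gene, .data$chrom, .data$strand) |>
    summarise(tx_start = min(.data$start), tx_end = max(.data$end),
              cdna_length = sum(.data$end - .data$start), .groups = "drop") |>
    left_join(cds, by = "transcript_id")

  # drop transcripts on chromosomes absent from the table (logged)
  unknown <- setdiff(unique(tx$chrom), chrom_table$chrom)
  if (length(unknown) > 0) {
    warn(sprintf("Dropping transcripts on unknown chromosome(s): %s",
                 paste(unknown, collapse = ", ")))
    tx <- filter(tx, !.data$chrom %in% unknown)
    exons <- semi_join(exons, tx, by = "transcript_id")
  }
  tx <- left_join(tx, chrom_table, by = "chrom")
  out_of_range <- tx$tx_end > tx$length
  if (any(out_of_range)) {
    abort(sprintf("Transcript(s) extend beyond chromosome length: %s",
                  paste(head(tx$transcript_id[out_of_range], 5), collapse = ", ")))
  }
  tx$length <- NULL

  # region lengths in transcript bases
  exl <- exons |> select("transcript_id", "start", "end")
  reg <- exl |>
    left_join(select(tx, "transcript_id", "strand", "cds_start", "cds_end"),
              by = "transcript_id") |>
    mutate(
      exlen = .data$end - .data$start,
      cds_ov = pmax(0, pmin(.data$end, .data$cds_end) - pmax(.data$start, .data$cds_start)),
      left_of = pmax(0, pmin(.data$end, .data$cds_start) - .data$start),
      right_of = pmax(0, .data$end - pmax(.data$start, .data$cds_end))
    ) |>
    group_by(.data$transcript_id) |>
    summarise(
      cds_length = sum(.data$cds_ov),
      left_len = sum(.data$left_of),
      right_len = sum(.data$right_of),
      .groups = "drop"
    )
  tx <- tx |>
    left_join(reg, by = "transcript_id") |>
    mutate(
      coding = !is.na(.data$cds_start) & !is.na(.data$cds_length) & .data$cds_length > 0,
      cds_length = ifelse(.data$coding, .data$cds_length, 0),
      utr5_length = dplyr::case_when(
        !.data$coding ~ 0,
        .data$strand == "+" ~ .data$left_len,
        TRUE ~ .data$right_len
      ),
      utr3_length = .data$cdna_length - .data$cds_length - .data$utr5_length
    ) |>
    select(-"left_len", -"right_len")

  genes <- tx |>
    group_by(.data$gene) |>
    arrange(dplyr::desc(.data$cds_length), dplyr::desc(.data$cdna_length),
            .data$transcript_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    mutate(midpoint = (.data$tx_start + .data$tx_end) / 2) |>
    select(gene = "gene", chrom = "chrom", strand = "strand",
           start = "tx_start", end = "tx_end",
           transcript_id = "transcript_id", midpoint = "midpoint") |>
    arrange(.data$chrom, .data$start)

  # keep only representative transcripts
  tx <- semi_join(tx, genes, by = "transcript_id") |> arrange(.data$transcript_id)
  exons <- semi_join(exons, tx, by = "transcript_id") |>
    arrange(.data$transcript_id, .data$start)

  new_annotation(tx, exons, genes, chrom_table)
}

#' Load gene annotation from a GTF file
#'
#' Parses exon and CDS features (via \pkg{rtracklayer}), converts to 0-based
#' half-open coordinates, and keeps one representative transcript per gene:
#' longest CDS, ties broken by longest cDNA, then lexicographically smallest
#' transcript id. Transcripts on chromosomes absent from `chrom_table` are
#' dropped with a warning; a transcript with CDS features but no exons is
#' dropped with a warning.
#'
#' @param path Path to a GTF file with `exon` and `CDS` features carrying
#'   `transcript_id` and `gene_name` (or `gene_id`) attributes.
#' @param chrom_table Chromosome table tibble (see [chromosome_table()]).
#' @return A `fusion_annotation` object: tibbles of transcripts (with
#'   `cdna_length`, `utr5_length`, `cds_length`, `utr3_length`), exons, and
#'   gene loci (span, midpoint, representative transcript).
#' @export
load_annotation <- function(path, chrom_table) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(gr)
  if (!"transcript_id" %in% names(md)) {
    abort("GTF has no transcript_id attribute.")
  }
  gene_col <- if ("gene_name" %in% names(md) && !all(is.na(md$gene_name))) {
    "gene_name"
  } else if ("gene_id" %in% names(md)) "gene_id" else {
    abort("GTF has neither gene_name nor gene_id attributes.")
  }
  md$gene <- md[[gene_col]]
  ex <- md[md$type == "exon", , drop = FALSE]
  cd <- md[md$type == "CDS", , drop = FALSE]

  no_exons <- setdiff(unique(cd$transcript_id), unique(ex$transcript_id))
  if (length(no_exons) > 0) {
    warn(sprintf("Dropping transcript(s) with CDS but no exons: %s",
                 paste(no_exons, collapse = ", ")))
    cd <- cd[!cd$transcript_id %in% no_exons, , drop = FALSE]
  }
  if (nrow(ex) == 0) abort("GTF contains no exon features.")

  exons <- tibble(
    transcript_id = ex$transcript_id, gene = ex$gene,
    chrom = as.character(ex$seqnames), strand = as.character(ex$strand),
    start = ex$start - 1L, end = ex$end
  )
  if (any(!exons$strand %in% c("+", "-"))) {
    abort("Exon feature without +/- strand.")
  }
  cds <- if (nrow(cd) > 0) {
    as_tibble(cd) |>
      group_by(transcript_id = .data$transcript_id) |>
      summarise(cds_start = min(.data$start) - 1, cds_end = max(.data$end),
                .groups = "drop")
  } else {
    tibble(transcript_id = character(), cds_start = numeric(), cds_end = numeric())
  }
  build_annotation(exons, cds, chrom_table)
}

# ---------------------------------------------------------------------------
# Coordinate conversion
# ---------------------------------------------------------------------------

# Per-transcript exon index used by the vectorized mapper.
transcript_index <- function(annotation, transcript_id) {
  ex <- annotation$exons[annotation$exons$transcript_id == transcript_id, ]
  if (nrow(ex) == 0) abort(sprintf("Unknown transcript '%s'.", transcript_id))
  tx <- annotation$transcripts[annotation$transcripts$transcript_id == transcript_id, ]
  list(starts = ex$start, ends = ex$end, strand = tx$strand,
       lens = ex$end - ex$start, cum = cumsum(ex$end - ex$start),
       total = tx$cdna_length, tx_start = tx$tx_start, tx_end = tx$tx_end)
}

map_one_transcript <- function(idx, pos) {
  if (any(pos < idx$tx_start | pos >= idx$tx_end)) {
    abort("Genomic position outside transcript span.")
  }
  k <- length(idx$starts)
  j <- findInterval(pos, idx$starts)           # exon whose start is <= pos
  exonic <- pos < idx$ends[j]
  cum_before <- c(0, idx$cum)[j]               # cDNA bases in exons 1..j-1 (+)
  if (idx$strand == "+") {
    cdna <- ifelse(exonic, cum_before + (pos - idx$starts[j]),
                   idx$cum[j] - 1)             # donor junction: last base of exon j
  } else {
    # transcript order is reversed; bases transcribed after genomic exon j:
    after <- idx$total - idx$cum[j]            # exons j+1..k
    cdna <- ifelse(exonic, after + (idx$ends[j] - 1 - pos),
                   # intron between genomic exons j and j+1: donor exon is j+1,
                   # transcribed bases strictly before the intron = exons k..j+1
                   idx$total - c(0, idx$cum)[j + 1] - 1)
  }
  tibble(cdna = as.numeric(cdna), intron_derived = !exonic)
}

#' Map genomic positions to cDNA coordinates
#'
#' Exonic positions map to their exact transcript offset (0-based, respecting
#' strand). Intronic positions project onto the donor-side exon junction: the
#' cDNA position of the last transcribed base before the intron, flagged
#' `intron_derived`. This projection is what transfers the intron mass of a
#' uniform genomic breakage model onto exon junctions in cDNA space.
#'
#' @param annotation A `fusion_annotation`.
#' @param transcript_id Character vector of transcript ids (recycled with
#'   `pos`).
#' @param pos Numeric vector of genomic positions (0-based) within each
#'   transcript's genomic span.
#' @return A tibble with columns `transcript_id`, `pos`, `cdna`,
#'   `intron_derived`.
#' @export
genomic_to_cdna <- function(annotation, transcript_id, pos) {
  d <- tibble(transcript_id = transcript_id, pos = as.numeric(pos))
  out <- vector("list", length(unique(d$transcript_id)))
  ids <- unique(d$transcript_id)
  res <- tibble(cdna = numeric(nrow(d)), intron_derived = logical(nrow(d)))
  for (id in ids) {
    sel <- which(d$transcript_id == id)
    m <- map_one_transcript(transcript_index(annotation, id), d$pos[sel])
    res$cdna[sel] <- m$cdna
    res$intron_derived[sel] <- m$intron_derived
  }
  dplyr::bind_cols(d, res)
}

# Inverse of the exonic branch, used for round-trip checks.
cdna_to_genomic <- function(annotation, transcript_id, cdna) {
  idx <- transcript_index(annotation, transcript_id)
  if (any(cdna < 0 | cdna >= idx$total)) abort("cDNA position out of range.")
  if (idx$strand == "+") {
    j <- findInterval(cdna, c(0, idx$cum), rightmost.closed = FALSE)
    idx$starts[j] + (cdna - c(0, idx$cum)[j])
  } else {
    rev_cum <- cumsum(rev(idx$lens))           # transcript-order cumulative
    j_rev <- findInterval(cdna, c(0, rev_cum))
    j <- length(idx$lens) + 1 - j_rev          # genomic exon index
    idx$ends[j] - 1 - (cdna - c(0, rev_cum)[j_rev])
  }
}

#' Classify cDNA positions into 5'UTR / CDS / 3'UTR
#'
#' Half-open boundaries: `[0, utr5)` is UTR5, `[utr5, utr5 + cds)` is CDS and
#' the remainder is UTR3.
#'
#' @inheritParams genomic_to_cdna
#' @param cdna cDNA positions (0-based transcript bases).
#' @return Character vector in `c("UTR5", "CDS", "UTR3")`.
#' @export
classify_cdna_region <- function(annotation, transcript_id, cdna) {
  tx <- annotation$transcripts
  i <- match(transcript_id, tx$transcript_id)
  if (anyNA(i)) abort("Unknown transcript id.")
  if (any(cdna < 0 | cdna >= tx$cdna_length[i])) {
    abort("cDNA position out of range.")
  }
  if (any(!tx$coding[i])) abort("Region classification requires a coding transcript.")
  u5 <- tx$utr5_length[i]
  cds <- tx$cds_length[i]
  ifelse(cdna < u5, "UTR5", ifelse(cdna < u5 + cds, "CDS", "UTR3"))
}

#' Relative position within the coding sequence
#'
#' Fractional position of a CDS-resident cDNA breakpoint: 0 at the start
#' codon, approaching 1 at the stop codon. N-/C-terminal breakpoint bias is
#' measured on this scale.
#'
#' @inheritParams classify_cdna_region
#' @return Numeric vector in `[0, 1)`.
#' @export
relative_cds_position <- function(annotation, transcript_id, cdna) {
  region <- classify_cdna_region(annotation, transcript_id, cdna)
  if (any(region != "CDS")) abort("Position is not within the CDS.")
  tx <- annotation$transcripts
  i <- match(transcript_id, tx$transcript_id)
  (cdna - tx$utr5_length[i]) / tx$cds_length[i]
}

#' Are two genes genomically adjacent?
#'
#' TRUE iff both genes are on the same chromosome and no third gene's span
#' lies strictly between their spans. Used to classify candidate read-through
#' transcripts.
#'
#' @param annotation A `fusion_annotation`.
#' @param gene_a,gene_b Gene symbols.
#' @return Logical scalar.
#' @export
are_adjacent <- function(annotation, gene_a, gene_b) {
  g <- annotation$genes
  a <- g[g$gene == gene_a, ]
  b <- g[g$gene == gene_b, ]
  if (nrow(a) == 0 || nrow(b) == 0) abort("Unknown gene symbol.")
  if (a$chrom != b$chrom || a$gene == b$gene) return(FALSE)
  lo <- min(a$end, b$end)
  hi <- max(a$start, b$start)
  others <- g[g$chrom == a$chrom & !g$gene %in% c(gene_a, gene_b), ]
  !any(others$start >= lo & others$end <= hi)
}
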