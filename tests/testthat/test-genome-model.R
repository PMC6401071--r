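test_that("region lengths derive correctly from exon/CDS structure on both strands", {
  ann <- toy_annotation()
  tx <- ann$transcripts
  a <- tx[tx$transcript_id == "tA", ]  # + strand, 2 exons, CDS 150..400
  expect_equal(a$cdna_length, 250)
  expect_equal(a$utr5_length, 50)
  expect_equal(a$cds_length, 150)
  expect_equal(a$utr3_length, 50)
  # same structure on - strand: UTR5 measured from the genomic-right end
  b <- tx[tx$transcript_id == "tB", ]
  expect_equal(b$cdna_length, 350)
  expect_equal(b$utr5_length, 50)   # exonic bases right of cds_end (5400..5450)
  expect_equal(b$utr3_length, sum(b$cdna_length - b$utr5_length - b$cds_length))
  expect_true(all(tx$utr5_length + tx$cds_length + tx$utr3_length ==
                    tx$cdna_length))
})

test_that("representative transcript is longest CDS, then longest cDNA, then id", {
  ct <- chromosome_table("chr1", 1e6)
  exons <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3", "t3"),
    gene = "G", chrom = "chr1", strand = "+",
    start = c(100, 100, 100, 600), end = c(500, 500, 400, 900)
  )
  cds <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
                        cds_start = c(150, 150, 120),
                        cds_end = c(300, 450, 820))
  ann <- fusescan:::build_annotation(exons, cds, ct)
  # t3 has CDS 280+220=... overlap: [120,400)+[600,820) within exons = 280+220
  expect_equal(ann$genes$transcript_id, "t3")

  # tie on CDS length -> longest cDNA wins
  cds2 <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
                         cds_start = c(150, 150, 150),
                         cds_end = c(300, 300, 300))
  ann2 <- fusescan:::build_annotation(exons, cds2, ct)
  expect_equal(ann2$genes$transcript_id, "t3")  # cDNA 600 vs 400
})

test_that("genomic-to-cDNA mapping honours strand and the donor-junction convention", {
  ann <- toy_annotation()
  m <- genomic_to_cdna(ann, c("tA", "tA"), c(120, 250))
  expect_equal(m$cdna, c(20, 99))
  expect_equal(m$intron_derived, c(FALSE, TRUE))
  # strand-flip oracle: cdna_minus = cdna_length - 1 - cdna_plus for exonic
  mb <- genomic_to_cdna(ann, "tB", 5050)
  plus_equiv <- 50  # offset within left exon
  expect_equal(mb$cdna, 350 - 1 - plus_equiv)
  # minus-strand intron projects onto the donor side (genomic-right exon)
  mi <- genomic_to_cdna(ann, "tB", 5250)
  expect_true(mi$intron_derived)
  expect_equal(mi$cdna, 150 - 1)  # right exon holds the first 150 bases
  expect_error(genomic_to_cdna(ann, "tA", 99), "span")
  expect_error(genomic_to_cdna(ann, "tA", 450), "span")
})

test_that("exonic positions round-trip through cDNA space", {
  ann <- toy_annotation()
  for (tid in c("tA", "tB")) {
    ex <- ann$exons[ann$exons$transcript_id == tid, ]
    pos <- unlist(Map(seq, ex$start, ex$end - 1))
    cd <- genomic_to_cdna(ann, rep(tid, length(pos)), pos)
    expect_false(any(cd$intron_derived))
    back <- fusescan:::cdna_to_genomic(ann, tid, cd$cdna)
    expect_equal(back, as.numeric(pos))
    # every cDNA position hit exactly once
    expect_setequal(cd$cdna, seq(0, sum(ex$end - ex$start) - 1))
  }
})

test_that("cDNA region classification uses half-open boundaries and mirrors across strands", {
  ann <- toy_annotation()
  expect_equal(classify_cdna_region(ann, c("tA", "tA", "tA"), c(10, 50, 249)),
               c("UTR5", "CDS", "UTR3"))
  expect_equal(classify_cdna_region(ann, "tA", 199), "CDS")
  expect_equal(classify_cdna_region(ann, "tA", 200), "UTR3")
  expect_error(classify_cdna_region(ann, "tA", 250), "range")
  expect_error(classify_cdna_region(ann, "tA", -1), "range")

  # region counts over all positions reproduce the region lengths exactly
  tx <- ann$transcripts
  for (tid in c("tA", "tB", "tC")) {
    i <- match(tid, tx$transcript_id)
    reg <- classify_cdna_region(ann, rep(tid, tx$cdna_length[i]),
                                seq_len(tx$cdna_length[i]) - 1)
    expect_equal(unname(table(factor(reg, c("UTR5", "CDS", "UTR3")))),
                 c(tx$utr5_length[i], tx$cds_length[i], tx$utr3_length[i]),
                 ignore_attr = TRUE)
  }

  # strand mirror: the same exon/CDS structure on the - strand classifies as
  # the coordinate-reflected + strand classification with UTR5/UTR3 swapped
  ct <- chromosome_table("chr1", 1e6)
  exons <- tibble::tibble(transcript_id = "t", gene = "G", chrom = "chr1",
                          strand = "+", start = c(100, 300), end = c(200, 450))
  cds <- tibble::tibble(transcript_id = "t", cds_start = 150, cds_end = 400)
  plus <- fusescan:::build_annotation(exons, cds, ct)
  minus <- fusescan:::build_annotation(dplyr::mutate(exons, strand = "-"), cds, ct)
  cls_p <- classify_cdna_region(plus, rep("t", 250), 0:249)
  cls_m <- classify_cdna_region(minus, rep("t", 250), 0:249)
  swap <- c(UTR5 = "UTR3", CDS = "CDS", UTR3 = "UTR5")
  expect_equal(cls_m, unname(swap[rev(cls_p)]))
})

test_that("relative CDS position is the fraction through the coding sequence", {
  ann <- toy_annotation()
  expect_equal(relative_cds_position(ann, c("tA", "tA", "tA"), c(50, 125, 199)),
               c(0, 0.5, (199 - 50) / 150))
  expect_error(relative_cds_position(ann, "tA", 10), "CDS")
})

test_that("gene adjacency requires an empty gap between spans", {
  ct <- chromosome_table(c("chr1", "chr2"), c(1e6, 1e6))
  exons <- tibble::tibble(
    transcript_id = c("x", "y", "z", "w"),
    gene = c("X", "Y", "Z", "W"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    strand = "+",
    start = c(0, 2000, 1200, 0), end = c(1000, 3000, 1800, 500)
  )
  cds <- tibble::tibble(transcript_id = c("x", "y", "z", "w"),
                        cds_start = c(100, 2100, 1300, 100),
                        cds_end = c(900, 2900, 1700, 400))
  ann <- fusescan:::build_annotation(exons, cds, ct)
  expect_false(are_adjacent(ann, "X", "Y"))   # Z sits between
  expect_true(are_adjacent(ann, "X", "Z"))
  expect_true(are_adjacent(ann, "Z", "Y"))
  expect_false(are_adjacent(ann, "X", "W"))   # different chromosomes
  expect_error(are_adjacent(ann, "X", "nope"), "Unknown")

  # without the middle gene, X and Y are adjacent
  ann2 <- fusescan:::build_annotation(exons[exons$gene != "Z", ],
                                      cds[cds$transcript_id != "z", ], ct)
  expect_true(are_adjacent(ann2, "X", "Y"))
})

test_that("GTF loading converts coordinates, drops unknowns, and errors usefully", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  fusescan:::write_gtf(co$annotation, file.path(dir, "g.gtf"))
  ann2 <- load_annotation(file.path(dir, "g.gtf"), co$chrom_table)
  expect_equal(ann2$transcripts$cdna_length, co$annotation$transcripts$cdna_length)
  expect_equal(ann2$transcripts$utr5_length, co$annotation$transcripts$utr5_length)
  expect_equal(ann2$exons$start, co$annotation$exons$start)

  # transcripts on unknown chromosomes dropped with a warning
  ct_partial <- co$chrom_table[-1, ]
  expect_warning(ann3 <- load_annotation(file.path(dir, "g.gtf"), ct_partial),
                 "unknown chromosome")
  expect_false(any(ann3$genes$chrom == co$chrom_table$chrom[1]))

  # CDS with no exons dropped with a warning
  gtf <- c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G1"; gene_name "G1"; transcript_id "t1";',
    'chr1\tsrc\tCDS\t121\t180\t.\t+\t.\tgene_id "G1"; gene_name "G1"; transcript_id "t1";',
    'chr1\tsrc\tCDS\t51\t80\t.\t+\t.\tgene_id "G2"; gene_name "G2"; transcript_id "t2";'
  )
  f <- file.path(dir, "partial.gtf")
  writeLines(gtf, f)
  expect_warning(ann4 <- load_annotation(f, chromosome_table("chr1", 1e4)),
                 "no exons")
  expect_equal(ann4$genes$gene, "G1")
})

test_that("chromosome tables validate names and lengths", {
  expect_error(chromosome_table(c("a", "a"), c(1, 2)), "unique")
  expect_error(chromosome_table("a", 0), "positive")
  ct <- chromosome_table(c("chr1", "chr2"), c(100, 200))
  expect_equal(sum(ct$length), 300)
  f <- withr::local_tempfile()
  readr::write_tsv(ct, f, col_names = FALSE)
  expect_equal(read_chrom_sizes(f), ct)
})
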