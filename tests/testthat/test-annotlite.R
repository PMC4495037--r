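mk_genome <- function(s) structure(list(c1 = genome_sequence("c1", s)),
                                   class = "genome")

test_that("transcript index derives introns and splice sites", {
  m <- list(gene_id = "g1", transcript_id = "t1", chrom = "c1", strand = "+",
            exons = cbind(start = c(1L, 61L), end = c(40L, 100L)),
            cds = cbind(start = c(11L, 61L), end = c(40L, 90L)), phase = 0L)
  idx <- index_transcripts(list(m))
  t <- idx$tx[[1L]]
  expect_equal(unname(t$introns), unname(cbind(41L, 60L)))
  # four splice-site bases: 41,42 and 59,60
  sp <- sort(unlist(apply(t$splice, 1L, function(r) r[1L]:r[2L])))
  expect_equal(sp, c(41L, 42L, 59L, 60L))
  # single-exon transcript: no introns
  m1 <- list(gene_id = "g", transcript_id = "t", chrom = "c1", strand = "+",
             exons = cbind(start = 5L, end = 40L),
             cds = cbind(start = 5L, end = 40L), phase = 0L)
  expect_equal(nrow(index_transcripts(list(m1))$tx[[1L]]$introns), 0L)
  # overlapping exons are rejected
  mbad <- m1
  mbad$exons <- cbind(start = c(1L, 10L), end = c(20L, 30L))
  expect_error(index_transcripts(list(mbad)), "overlapping")
})

test_that("worked consequence examples classify correctly", {
  # plus strand, CDS 11..19, codons GAA TTT TGC starting at 11
  s <- paste0(strrep("C", 10L), "GAATTTTGC", strrep("C", 31L))
  g <- mk_genome(s)
  m <- list(gene_id = "g1", transcript_id = "t1", chrom = "c1", strand = "+",
            exons = cbind(start = 11L, end = 19L),
            cds = cbind(start = 11L, end = 19L), phase = 0L)
  idx <- index_transcripts(list(m))
  # outside every gene: intergenic
  expect_equal(classify_variant("c1", 5L, "C", "T", idx, g)$class, "intergenic")
  # GAA -> GAG, third position: synonymous (Glu)
  r <- classify_variant("c1", 13L, "A", "G", idx, g)
  expect_equal(r$class, "synonymous")
  expect_equal(r$codon_change, "GAA>GAG")
  # GAA -> TAA at position 1: stop gained
  expect_equal(classify_variant("c1", 11L, "G", "T", idx, g)$class, "stop_gained")
  # TTT -> TCT: missense
  expect_equal(classify_variant("c1", 15L, "T", "C", idx, g)$class, "missense")
  # ref-allele mismatch is an error naming the position
  expect_error(classify_variant("c1", 13L, "G", "T", idx, g), "c1:13")
})

test_that("stop codons are tracked through gain and loss", {
  # CDS ATG TAC TGA: TAC->TAA stop gained at pos 6 (C->A is pos 6? TAC ends
  # at 6); TGA's G->C gives TCA: stop lost
  s <- paste0("ATGTACTGA", strrep("A", 20L))
  g <- mk_genome(s)
  m <- list(gene_id = "g1", transcript_id = "t1", chrom = "c1", strand = "+",
            exons = cbind(start = 1L, end = 9L),
            cds = cbind(start = 1L, end = 9L), phase = 0L)
  idx <- index_transcripts(list(m))
  expect_equal(classify_variant("c1", 6L, "C", "A", idx, g)$class, "stop_gained")
  expect_equal(classify_variant("c1", 8L, "G", "C", idx, g)$class, "stop_lost")
})

test_that("minus-strand codons are read from the rightmost CDS base", {
  # minus strand CDS over 11..16; transcribed sequence is the reverse
  # complement, so codon 1 covers genomic 16,15,14
  s <- paste0(strrep("A", 10L), "TTACAT", strrep("G", 24L))
  # revcomp of TTACAT = ATGTAA: ATG TAA (start + stop)
  g <- mk_genome(s)
  m <- list(gene_id = "g1", transcript_id = "t1", chrom = "c1", strand = "-",
            exons = cbind(start = 11L, end = 16L),
            cds = cbind(start = 11L, end = 16L), phase = 0L)
  idx <- index_transcripts(list(m))
  # genomic pos 14 is codon 1 position 3 (G of ATG): A->G on the genome
  # means C->T... take pos 12 (codon TAA, middle): T->C on minus strand
  r <- classify_variant("c1", 12L, "T", "C", idx, g)
  expect_equal(r$codon_change, "TAA>TGA")     # still a stop: synonymous
  expect_equal(r$class, "synonymous")
  r2 <- classify_variant("c1", 13L, "A", "G", idx, g)
  expect_equal(r2$codon_change, "TAA>CAA")    # stop lost
  expect_equal(r2$class, "stop_lost")
})

test_that("intronic, splice and noncoding classes respect precedence", {
  s <- rand_dna(200L)
  m <- list(gene_id = "g1", transcript_id = "t1", chrom = "c1", strand = "+",
            exons = cbind(start = c(10L, 61L), end = c(30L, 99L)),
            cds = cbind(start = c(20L, 61L), end = c(30L, 90L)), phase = 0L)
  g <- mk_genome(s)
  idx <- index_transcripts(list(m))
  ref_at <- function(p) substr(s, p, p)
  alt_for <- function(p) setdiff(c("A", "C", "G", "T"), ref_at(p))[1L]
  cls_at <- function(p) classify_variant("c1", p, ref_at(p), alt_for(p), idx, g)$class
  expect_equal(cls_at(31L), "splice_site")    # first intron base
  expect_equal(cls_at(60L), "splice_site")    # last intron base
  expect_equal(cls_at(45L), "intronic")
  expect_equal(cls_at(12L), "noncoding_exon") # exon before CDS start
  expect_equal(cls_at(95L), "noncoding_exon") # exon after CDS end
  expect_equal(cls_at(110L), "intergenic")
})

test_that("coding classification agrees with full re-translation", {
  withr::local_seed(83)
  n_checked <- 0L
  while (n_checked < 600L) {
    L <- 300L
    s <- rand_dna(L)
    m <- random_gene_model(L)
    g <- mk_genome(s)
    idx <- index_transcripts(list(m))
    # random CDS positions
    cds_pos <- unlist(apply(m$cds, 1L, function(r) r[1L]:r[2L]))
    splice <- idx$tx[[1L]]$splice
    for (p in sample(cds_pos, min(6L, length(cds_pos)))) {
      ref <- substr(s, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      got <- classify_variant("c1", p, ref, alt, idx, g)
      expect_equal(got$class, oracle_coding_consequence(m, s, p, alt),
                   info = paste(m$strand, p, ref, alt))
      n_checked <- n_checked + 1L
    }
  }
})

test_that("consequences are invariant under reverse-complementing the genome", {
  withr::local_seed(89)
  for (i in 1:40) {
    L <- 240L
    s <- rand_dna(L)
    m <- random_gene_model(L)
    g <- mk_genome(s)
    idx <- index_transcripts(list(m))
    cds_pos <- unlist(apply(m$cds, 1L, function(r) r[1L]:r[2L]))
    p <- sample(cds_pos, 1L)
    ref <- substr(s, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    got <- classify_variant("c1", p, ref, alt, idx, g)
    # mirror: reverse-complement genome, flip strand and coordinates
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    m2 <- m
    m2$strand <- if (m$strand == "+") "-" else "+"
    m2$exons <- cbind(start = L - m$exons[, 2L] + 1L, end = L - m$exons[, 1L] + 1L)
    m2$exons <- m2$exons[order(m2$exons[, 1L]), , drop = FALSE]
    m2$cds <- cbind(start = L - m$cds[, 2L] + 1L, end = L - m$cds[, 1L] + 1L)
    m2$cds <- m2$cds[order(m2$cds[, 1L]), , drop = FALSE]
    g2 <- mk_genome(rc)
    idx2 <- index_transcripts(list(m2))
    got2 <- classify_variant("c1", L - p + 1L, unname(comp[ref]),
                             unname(comp[alt]), idx2, g2)
    expect_equal(got2$class, got$class, info = paste(i, m$strand, p))
  }
})

test_that("synonymous/missense partition is exhaustive over CDS substitutions", {
  withr::local_seed(91)
  s <- rand_dna(300L)
  m <- random_gene_model(300L, n_exons = 2L, strand = "+")
  g <- mk_genome(s)
  idx <- index_transcripts(list(m))
  cds_pos <- unlist(apply(m$cds, 1L, function(r) r[1L]:r[2L]))
  classes <- character(0)
  for (p in cds_pos) {
    ref <- substr(s, p, p)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      classes <- c(classes, classify_variant("c1", p, ref, alt, idx, g)$class)
    }
  }
  expect_true(all(classes %in% c("synonymous", "missense", "stop_gained",
                                 "stop_lost")))
})

test_that("summaries count one effect per overlapping transcript", {
  s <- paste0(strrep("A", 4L), "CGT", strrep("A", 13L))
  g <- mk_genome(s)
  m1 <- list(gene_id = "g1", transcript_id = "t1", chrom = "c1", strand = "+",
             exons = cbind(start = 2L, end = 10L),
             cds = cbind(start = 2L, end = 10L), phase = 0L)
  m2 <- list(gene_id = "g2", transcript_id = "t2", chrom = "c1", strand = "+",
             exons = cbind(start = 5L, end = 13L),
             cds = cbind(start = 5L, end = 13L), phase = 0L)
  idx <- index_transcripts(list(m1, m2))
  v <- data.frame(chrom = "c1", pos = c(6L, 15L, 1L),
                  ref = c("G", "A", "A"), alt = c("A", "C", "G"))
  cons <- classify_variants(v, idx, g)
  expect_equal(nrow(cons), 4L)                 # 2 + 1 + 1 effects
  counts <- summarize_consequences(cons)
  expect_equal(sum(counts), 4L)
  expect_equal(unname(counts["intergenic"]), 2L)
  # empty input: all-zero table
  empty <- summarize_consequences(cons[0, ])
  expect_true(all(empty == 0L))
})
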