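test_that("homopolymer runs: worked examples", {
  expect_equal(nrow(find_homopolymer_runs("ACGT", 4L)), 0L)
  expect_equal(unname(find_homopolymer_runs("AAAAC", 4L)), matrix(c(1L, 4L), 1L)[, , drop = FALSE],
               ignore_attr = TRUE)
  got <- find_homopolymer_runs("TTTTTGGGGA", 4L)
  expect_equal(unname(got[, 1]), c(1L, 6L))
  expect_equal(unname(got[, 2]), c(5L, 9L))
  # runs of N never count
  expect_equal(nrow(find_homopolymer_runs("NNNNN", 4L)), 0L)
})

test_that("homopolymer finder agrees with the quadratic oracle", {
  withr::local_seed(31)
  for (i in 1:300) {
    s <- rand_dna(200L)
    got <- find_homopolymer_runs(s, 4L)
    exp <- oracle_homopolymer(s, 4L)
    expect_equal(unname(got), unname(exp))
  }
})

test_that("genotype caller: worked examples", {
  expect_equal(call_genotype(rep("A", 6), "A")$genotype, "RR")
  g <- call_genotype(rep("G", 6), "A")
  expect_equal(g$genotype, "AA")
  expect_equal(g$alt, "G")
  expect_equal(call_genotype(c(rep("A", 3), rep("G", 3)), "A")$genotype, "RA")
  expect_equal(call_genotype(character(0), "A")$genotype, "nocall")
  expect_equal(call_genotype(rep("C", 5), "N")$genotype, "nocall")
  # alt tie broken alphabetically: C and G both twice -> C
  expect_equal(call_genotype(c("A", "A", "C", "C", "G", "G"), "A")$alt, "C")
  # haploid calls
  expect_equal(call_genotype(rep("T", 5), "A", ploidy = 1L)$genotype, "A")
  expect_equal(call_genotype(rep("A", 5), "A", ploidy = 1L)$genotype, "R")
  # a single dissenting read is never enough evidence for the alt allele
  expect_equal(call_genotype(c(rep("A", 6), "G"), "A")$genotype, "RR")
})

test_that("caller agrees with explicit likelihood enumeration", {
  withr::local_seed(37)
  nt <- c("A", "C", "G", "T")
  for (i in 1:2000) {
    depth <- sample(1:15, 1L)
    ref <- sample(nt, 1L)
    # mixture around a random true genotype to hit all call regions
    pool <- sample(nt, 2L, replace = TRUE)
    bases <- sample(c(sample(pool, depth, replace = TRUE),
                      sample(nt, 2L, replace = TRUE)))[seq_len(depth)]
    ploidy <- sample(1:2, 1L)
    got <- call_genotype(bases, ref, ploidy = ploidy)$genotype
    exp <- oracle_genotype(bases, ref, e = 0.01, min_alt_reads = 2L,
                           ploidy = ploidy)
    expect_equal(got, if (ploidy == 1L) c(R = "R", A = "A")[[exp]] else exp,
                 info = paste(ref, paste(bases, collapse = "")))
  }
})

test_that("matrix caller equals the scalar caller", {
  withr::local_seed(41)
  nt <- c("A", "C", "G", "T")
  n <- 500L
  counts <- matrix(0L, n, 4L)
  ref <- sample.int(4L, n, replace = TRUE)
  for (i in seq_len(n)) counts[i, ] <- as.integer(stats::rmultinom(1L, sample(0:14, 1L),
                                                                   prob = c(4, 1, 1, 1)[sample.int(4)]))
  res <- call_genotypes_matrix(counts, ref)
  for (i in seq_len(n)) {
    bases <- rep(nt, counts[i, ])
    sc <- call_genotype(bases, nt[ref[i]])
    code <- c(RR = 0L, RA = 1L, AA = 2L, nocall = NA_integer_)[[sc$genotype]]
    expect_identical(res$geno[i], code, info = i)
  }
})

test_that("caller is symmetric under base relabeling", {
  withr::local_seed(43)
  nt <- c("A", "C", "G", "T")
  for (i in 1:200) {
    depth <- sample(4:12, 1L)
    ref <- sample(nt, 1L)
    bases <- sample(nt, depth, replace = TRUE, prob = c(5, 3, 1, 1)[sample.int(4)])
    perm <- sample.int(4L)
    map <- stats::setNames(nt[perm], nt)
    g1 <- call_genotype(bases, ref)
    g2 <- call_genotype(unname(map[bases]), unname(map[ref]))
    expect_equal(g1$genotype, g2$genotype)
    # the alt label itself only transports when it is not an arbitrary
    # alphabetical tie-break between equally supported alleles
    cnt <- vapply(nt, function(b) sum(bases == b), 0L)
    cnt[ref] <- -1L
    if (!is.na(g1$alt) && g1$genotype != "RR" &&
        sum(cnt == max(cnt)) == 1L) {
      expect_equal(unname(map[g1$alt]), g2$alt)
    }
  }
})

test_that("filter stack flags depth, mapping quality and homopolymer context", {
  v <- filter_site(depth = 3L, map_quals = rep(30, 3), pos = 50L,
                   ref_context = "ACGTACGTACG", context_offset = 45L)
  expect_equal(v$flags, "low_depth")
  expect_false(v$pass)
  # RMS mapping quality: {10,10,10,40} -> 21.8, passes the >=20 gate
  v2 <- filter_site(4L, c(10, 10, 10, 40), 50L, "ACGTACGTACG",
                    context_offset = 45L)
  expect_true(v2$pass)
  v3 <- filter_site(4L, c(20, 20, 20, 20), 50L, "ACGTACGTACG",
                    context_offset = 45L)
  expect_true(v3$pass)
  v4 <- filter_site(4L, c(15, 15, 15, 15), 50L, "ACGTACGTACG",
                    context_offset = 45L)
  expect_equal(v4$flags, "low_mq")
  # variant immediately 3' of a 4-run: flagged on ion, clean on illumina
  ctx <- "CAAAAG"                        # run 2..5, variant at global pos 6
  v5 <- filter_site(6L, rep(40, 6), 6L, ctx, context_offset = 1L)
  expect_equal(v5$flags, "homopolymer")
  v6 <- filter_site(6L, rep(40, 6), 6L, ctx,
                    fparams = filter_params(platform = "illumina"),
                    context_offset = 1L)
  expect_true(v6$pass)
  # strict reading: slack 0 lets the adjacent site through
  v7 <- filter_site(6L, rep(40, 6), 6L, ctx,
                    fparams = filter_params(homopolymer_adjacency = 0L),
                    context_offset = 1L)
  expect_true(v7$pass)
})

test_that("cross-sample classification implements the fixed/snp partition", {
  # helper: one site, three samples
  one_site <- function(geno, alt = rep(3L, length(geno)), pass = rep(TRUE, length(geno))) {
    classify_sites(matrix(geno, 1L), matrix(alt, 1L), matrix(pass, 1L))
  }
  # all samples hom-alt for the same allele vs ref: fixed difference
  expect_equal(one_site(c(2L, 2L, 2L))$class, 2L)
  # het + hom-ref: snp
  expect_equal(one_site(c(1L, 0L, NA))$class, 3L)
  # discordant homozygotes: snp
  expect_equal(one_site(c(0L, 2L, 0L))$class, 3L)
  # all nocall: uncallable
  expect_equal(one_site(c(NA_integer_, NA_integer_, NA_integer_))$class, 0L)
  # all hom-ref: invariant
  expect_equal(one_site(c(0L, 0L, 0L))$class, 1L)
  # single callable hom-alt sample still classifies as fixed
  expect_equal(one_site(c(2L, NA, NA))$class, 2L)
  # failing samples are ignored
  expect_equal(one_site(c(2L, 1L, 2L), pass = c(TRUE, FALSE, TRUE))$class, 2L)
  # three alleles across samples: demoted to uncallable with a warning
  expect_warning(r <- one_site(c(2L, 2L, 2L), alt = c(2L, 3L, 2L)), "3\\+ alleles")
  expect_equal(r$class, 0L)
  # homopolymer-masked site is uncallable regardless of evidence
  r2 <- classify_sites(matrix(2L, 1L, 1L), matrix(3L, 1L, 1L),
                       matrix(TRUE, 1L, 1L), site_ok = FALSE)
  expect_equal(r2$class, 0L)
})

test_that("pooled caller requires depth and two supported alleles", {
  expect_true(call_pool(c(10L, 0L, 3L, 0L)))       # 10 A + 3 G vs ref A
  expect_false(call_pool(c(11L, 0L, 1L, 0L)))      # minor support 1 < 2
  expect_false(call_pool(c(2L, 0L, 1L, 0L)))       # depth 3 < 4
  expect_equal(call_pool(rbind(c(10L, 0L, 3L, 0L), c(11L, 0L, 1L, 0L))),
               c(TRUE, FALSE))
})

test_that("raising min_depth never increases passing sites", {
  cfg <- sim_config(seed = 47,
    contigs = data.frame(name = "c1", length = 50000L, chrom_class = "autosome"),
    individuals = data.frame(id = "i1", sex = "M", depth_mean = 6))
  ds <- simulate_dataset(cfg)
  pm <- ds$pileups$c1
  prev <- Inf
  for (md in c(1L, 3L, 5L, 8L)) {
    cs <- call_sites(pm, caller_params(min_depth = md))
    n_pass <- sum(cs$class != 0L)
    expect_lte(n_pass, prev)
    prev <- n_pass
  }
})

test_that("noiseless calls equal simulator truth exactly", {
  cfg <- sim_config(seed = 53,
    contigs = data.frame(name = "c1", length = 200000L, chrom_class = "autosome"),
    epsilon = 0, pi_query = 0.002,
    individuals = data.frame(id = c("i1", "i2"), sex = c("M", "F"),
                             depth_mean = c(10, 10)))
  ds <- simulate_dataset(cfg)
  pm <- ds$pileups$c1
  cs <- call_sites(pm)
  ref <- ds$reference$c1$seq
  qry <- ds$query$c1$seq
  # fixed truth at callable positions is called fixed with the right allele
  fx <- ds$truth$fixed$c1
  at <- fx$pos[cs$class[fx$pos] != 0L]
  expect_true(all(cs$class[at] == 2L))
  expect_equal(cs$alt[at], qry[at])
  # per-sample genotypes at polymorphic truth sites match planted doses.
  # Het recovery is evidence-limited: both alleles must be read at least
  # min_alt_reads times, and at depth <= 14 two minor reads provably win the
  # likelihood comparison, so on that subset recovery is exact.
  po <- ds$truth$poly$c1
  for (j in 1:2) {
    cnt <- ds$pileups$c1$samples[[j]]$counts[po$pos, , drop = FALSE]
    n_anc <- cnt[cbind(seq_len(nrow(po)), po$anc)]
    n_der <- cnt[cbind(seq_len(nrow(po)), po$derived)]
    dose <- ds$truth$geno$c1[, j]
    usable <- cs$pass[po$pos, j] & !is.na(cs$geno[po$pos, j]) &
      cs$class[po$pos] != 0L
    hom_ok <- usable & dose != 1L
    expect_equal(unname(cs$geno[po$pos[hom_ok], j]), unname(dose[hom_ok]))
    het_ok <- usable & dose == 1L & n_anc >= 2L & n_der >= 2L &
      (n_anc + n_der) <= 14L
    expect_true(all(cs$geno[po$pos[het_ok], j] == 1L))
  }
  # nothing called fixed or snp where truth has neither
  none <- setdiff(seq_along(ref), c(fx$pos, po$pos))
  expect_true(all(cs$class[none] %in% c(0L, 1L)))
})
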