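# Independent oracles used by the unit and acceptance tests.  Each one is a
# deliberately naive implementation (quadratic scans, explicit enumeration,
# full re-translation) kept free of any code path it is checking.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# quadratic homopolymer-run scan over a character string
oracle_homopolymer <- function(s, min_len = 4L) {
  ch <- strsplit(s, "")[[1L]]
  n <- length(ch)
  runs <- NULL
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && ch[j + 1L] == ch[i]) j <- j + 1L
    if (j - i + 1L >= min_len && ch[i] != "N") runs <- rbind(runs, c(i, j))
    i <- j + 1L
  }
  if (is.null(runs)) cbind(start = integer(0), end = integer(0))
  else {colnames(runs) <- c("start", "end"); runs}
}

# explicit per-read likelihood enumeration for the genotype caller
oracle_genotype <- function(bases, ref, e = 0.01, min_alt_reads = 2L,
                            ploidy = 2L) {
  if (length(bases) == 0L || ref == "N") return("nocall")
  nt <- c("A", "C", "G", "T")
  cnt <- sapply(nt, function(b) sum(bases == b))
  alts <- nt[nt != ref]
  alt <- alts[which.max(cnt[alts])]      # sapply keeps A<C<G<T order
  p_read <- function(b, allele) if (b == allele) 1 - e else e / 3
  lik <- function(a1, a2) {
    prod(vapply(bases, function(b) (p_read(b, a1) + p_read(b, a2)) / 2, 0))
  }
  # ties break toward the reference; strictly-greater uses a relative
  # tolerance because products and log-sums can differ in the last ulp
  gt <- function(a, b) a > b * (1 + 1e-9)
  if (ploidy == 1L) {
    lR <- lik(ref, ref); lA <- lik(alt, alt)
    g <- if (gt(lA, lR)) "A" else "R"
    if (g == "A" && cnt[alt] < min_alt_reads) g <- "R"
    return(g)
  }
  ll <- c(RR = lik(ref, ref), RA = lik(ref, alt), AA = lik(alt, alt))
  g <- "RR"
  if (gt(ll[["RA"]], ll[[g]])) g <- "RA"
  if (gt(ll[["AA"]], max(ll[["RR"]], ll[["RA"]]))) g <- "AA"
  if (g != "RR" && cnt[alt] < min_alt_reads) g <- "RR"
  g
}

# naive in-silico digest by substring search
oracle_digest <- function(s, site, offset, size_range) {
  L <- nchar(s)
  cuts <- integer(0)
  w <- nchar(site)
  for (i in seq_len(max(0L, L - w + 1L))) {
    if (substr(s, i, i + w - 1L) == site) cuts <- c(cuts, i + offset - 1L)
  }
  cuts <- cuts[cuts >= 1L & cuts < L]
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, L)
  data.frame(start = starts, end = ends, length = ends - starts + 1L,
             retained = (ends - starts + 1L) >= size_range[1L] &
                        (ends - starts + 1L) <= size_range[2L])
}

# order-statistics quantiles (linear interpolation, type 7) computed by hand
oracle_quartiles <- function(v) {
  x <- sort(v)
  n <- length(x)
  q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  c(q1 = q(0.25), median = q(0.5), q3 = q(0.75))
}

# membership-table Venn region counts
oracle_venn <- function(sets) {
  keys <- unique(unlist(sets))
  k <- length(sets)
  counts <- stats::setNames(integer(2^k - 1L), seq_len(2^k - 1L))
  labels <- character(2^k - 1L)
  for (code in seq_len(2^k - 1L)) {
    inn <- as.logical(bitwAnd(code, 2^(seq_len(k) - 1L)))
    labels[code] <- paste(names(sets)[inn], collapse = "&")
    cnt <- 0L
    for (key in keys) {
      memb <- vapply(sets, function(s) key %in% s, TRUE)
      if (all(memb == inn)) cnt <- cnt + 1L
    }
    counts[code] <- cnt
  }
  data.frame(region = labels, count = as.integer(counts))
}

# full CDS re-translation consequence oracle (coding positions only)
oracle_coding_consequence <- function(model, seq_str, pos, alt) {
  cds <- model$cds
  segs <- apply(cds, 1L, function(r) substr(seq_str, r[1L], r[2L]))
  cds_seq <- paste(segs, collapse = "")
  # CDS-space offset of pos on the plus strand
  plus_off <- 0L
  for (i in seq_len(nrow(cds))) {
    if (pos >= cds[i, 1L] && pos <= cds[i, 2L]) {
      plus_off <- plus_off + (pos - cds[i, 1L] + 1L)
      break
    }
    plus_off <- plus_off + (cds[i, 2L] - cds[i, 1L] + 1L)
  }
  mut <- cds_seq
  substr(mut, plus_off, plus_off) <- alt
  if (model$strand == "-") {
    rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    cds_seq <- rc(cds_seq); mut <- rc(mut)
  }
  ph <- model$phase
  trim <- function(x) {
    x <- substr(x, ph + 1L, nchar(x))
    substr(x, 1L, 3L * (nchar(x) %/% 3L))
  }
  tr <- function(x) as.character(Biostrings::translate(Biostrings::DNAString(x),
                                                       no.init.codon = TRUE))
  aa_old <- tr(trim(cds_seq)); aa_new <- tr(trim(mut))
  d <- which(strsplit(aa_old, "")[[1L]] != strsplit(aa_new, "")[[1L]])
  if (!length(d)) return("synonymous")
  old <- substr(aa_old, d[1L], d[1L]); new <- substr(aa_new, d[1L], d[1L])
  if (new == "*" && old != "*") "stop_gained"
  else if (old == "*" && new != "*") "stop_lost"
  else "missense"
}

# random single-transcript gene model on [1, L]; CDS spans whole exons so the
# seven headline consequence classes cover every position
random_gene_model <- function(L, n_exons = sample(1:3, 1L), strand = sample(c("+", "-"), 1L),
                              id = "tx1") {
  repeat {
    bounds <- sort(sample(seq_len(L - 1L), 2L * n_exons))
    exons <- cbind(start = bounds[seq(1L, 2L * n_exons, 2L)],
                   end = bounds[seq(2L, 2L * n_exons, 2L)])
    len <- sum(exons[, 2L] - exons[, 1L] + 1L)
    gaps_ok <- n_exons == 1L || all(exons[-1L, 1L] - exons[-n_exons, 2L] > 4L)
    if (len %% 3L == 0L && len >= 6L && gaps_ok) break
  }
  list(gene_id = "g1", transcript_id = id, chrom = "c1", strand = strand,
       exons = exons, cds = exons, phase = 0L)
}
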