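# Per-site genotype calling and the filter stack.
#
# The caller is a uniform-prior binomial maximum-likelihood model with a
# fixed assumed per-base error e: P(read b | hom GG) is 1-e for b == G and
# e/3 otherwise; under a heterozygote each allele contributes half.  Base
# qualities are deliberately not folded into the likelihood so that an
# exhaustive three-likelihood enumeration remains a usable oracle.

#' Caller parameters
#'
#' @param min_depth minimum read depth for a site to be callable (default 4).
#' @param min_site_mq minimum site RMS mapping quality, phred (default 20).
#' @param assumed_error per-base error used in the genotype likelihood
#'   (default 0.01).
#' @param min_depth_y relaxed depth threshold used for Y-lineage SNV
#'   comparison (default 3).
#' @param het_min_minor_reads_pool minimum reads supporting each allele for a
#'   pooled-sample SNP (default 2).
#' @param min_alt_reads minimum reads supporting the alternative allele for
#'   any genotype containing it (default 2). Plain maximum likelihood with a
#'   uniform prior prefers a heterozygote as soon as one read dissents at
#'   moderate depth, so a lone error read would masquerade as a SNP; the
#'   support floor (the same stringency the pooled caller applies) demotes
#'   such calls to homozygous reference. Set to 1 to disable.
#' @return object of class `caller_params`.
#' @export
caller_params <- function(min_depth = 4L, min_site_mq = 20, assumed_error = 0.01,
                          min_depth_y = 3L, het_min_minor_reads_pool = 2L,
                          min_alt_reads = 2L) {
  stopifnot(min_depth >= 1L, assumed_error > 0, assumed_error < 0.5,
            min_alt_reads >= 1L)
  structure(list(min_depth = as.integer(min_depth), min_site_mq = min_site_mq,
                 assumed_error = assumed_error,
                 min_depth_y = as.integer(min_depth_y),
                 het_min_minor_reads_pool = as.integer(het_min_minor_reads_pool),
                 min_alt_reads = as.integer(min_alt_reads)),
            class = "caller_params")
}

#' Filter parameters
#'
#' @param homopolymer_min_len minimal run length that defines a homopolymer
#'   (default 4).
#' @param homopolymer_adjacency bp of slack around a run within which a
#'   variant is still flagged (default 1; set 0 for a strict inside-run rule).
#' @param platform `"ion"` applies the homopolymer filter; `"illumina"`
#'   does not (short homopolymer stretches are not an error mode there).
#' @return object of class `filter_params`.
#' @export
filter_params <- function(homopolymer_min_len = 4L, homopolymer_adjacency = 1L,
                          platform = c("ion", "illumina")) {
  platform <- match.arg(platform)
  stopifnot(homopolymer_min_len >= 2L)
  structure(list(homopolymer_min_len = as.integer(homopolymer_min_len),
                 homopolymer_adjacency = as.integer(homopolymer_adjacency),
                 platform = platform),
            class = "filter_params")
}

#' Find maximal homopolymer runs
#'
#' @param sequence character string or integer-coded vector (uppercase DNA).
#' @param min_len minimal run length to report (default 4).
#' @return integer matrix with columns `start`, `end` (1-based inclusive),
#'   maximal runs of identical non-N bases, sorted, non-overlapping.
#' @export
find_homopolymer_runs <- function(sequence, min_len = 4L) {
  s <- if (is.character(sequence)) dna_to_int(sequence) else sequence
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len & r$values != N_CODE
  cbind(start = starts[keep], end = ends[keep])
}

# per-genotype log-likelihoods from allele counts
.geno_logliks <- function(n_ref, n_alt, depth, e) {
  other <- log(e / 3)
  lRR <- n_ref * log(1 - e) + (depth - n_ref) * other
  lAA <- n_alt * log(1 - e) + (depth - n_alt) * other
  lRA <- (n_ref + n_alt) * log((1 - 2 * e / 3) / 2) +
    (depth - n_ref - n_alt) * other
  cbind(RR = lRR, RA = lRA, AA = lAA)
}

#' Call a genotype at one site for one sample
#'
#' The alternative allele is the modal non-reference base (ties broken
#' alphabetically A < C < G < T). Diploid calls maximize the binomial
#' likelihood over \{RR, RA, AA\}; exact ties resolve toward the reference
#' (RR over RA over AA), keeping divergence estimates conservative. Haploid
#' (hemizygous) calls maximize over \{R, A\}.
#'
#' @param bases read bases at the site: character vector or integer codes.
#' @param ref_base reference base (character or code).
#' @param params a [caller_params()].
#' @param ploidy 1 (hemizygous) or 2.
#' @return list with `genotype` (one of "RR", "RA", "AA", "R", "A",
#'   "nocall"), `ref`, `alt` (characters, alt NA when no non-reference base
#'   observed), `depth`, and `loglik` (named vector).
#' @export
call_genotype <- function(bases, ref_base, params = caller_params(), ploidy = 2L) {
  b <- if (is.character(bases)) {
    if (length(bases) == 1L && nchar(bases) > 1L) dna_to_int(bases)
    else vapply(bases, dna_to_int, 0L, USE.NAMES = FALSE)
  } else as.integer(bases)
  rb <- if (is.character(ref_base)) dna_to_int(ref_base) else as.integer(ref_base)
  depth <- length(b)
  if (depth == 0L || rb == N_CODE) {
    return(list(genotype = "nocall", ref = int_to_dna(rb), alt = NA_character_,
                depth = depth, loglik = NULL))
  }
  cnt <- tabulate(b, 4L)
  n_ref <- cnt[rb]
  cnt_alt <- cnt; cnt_alt[rb] <- -1L
  alt <- which.max(cnt_alt)              # alphabetical tie-break
  n_alt <- cnt[alt]
  ll <- .geno_logliks(n_ref, n_alt, depth, params$assumed_error)[1L, ]
  if (ploidy == 1L) {
    e <- params$assumed_error
    lR <- n_ref * log(1 - e) + (depth - n_ref) * log(e / 3)
    lA <- n_alt * log(1 - e) + (depth - n_alt) * log(e / 3)
    gt <- if (lA > lR && n_alt >= params$min_alt_reads) "A" else "R"
    ll <- c(R = lR, A = lA)
  } else {
    gt <- c("RR", "RA", "AA")[.pick_genotype(ll[1L], ll[2L], ll[3L])]
    if (gt != "RR" && n_alt < params$min_alt_reads) gt <- "RR"
  }
  list(genotype = gt, ref = int_to_dna(rb),
       alt = if (n_alt > 0L) int_to_dna(alt) else NA_character_,
       depth = depth, loglik = ll)
}

# vectorized argmax with reference-ward tie-breaking; returns 1=RR,2=RA,3=AA
.pick_genotype <- function(lRR, lRA, lAA) {
  g <- rep.int(1L, length(lRR))
  best <- lRR
  swap <- lRA > best
  g[swap] <- 2L; best[swap] <- lRA[swap]
  swap <- lAA > best
  g[swap] <- 3L
  g
}

#' Vectorized genotype calling over a counts matrix
#'
#' Same model as [call_genotype()], applied to all sites of one sample at
#' once.
#'
#' @param counts integer matrix, sites x 4 (A, C, G, T read counts).
#' @param ref integer-coded reference bases (length `nrow(counts)`).
#' @param params a [caller_params()].
#' @param ploidy 1 or 2 (scalar, per contig x sample).
#' @return list with `geno` (integer: 0 = hom-ref, 1 = het, 2 = hom-alt,
#'   NA = nocall), `alt` (integer codes, NA where no alternative observed)
#'   and `depth`.
#' @export
call_genotypes_matrix <- function(counts, ref, params = caller_params(),
                                  ploidy = 2L) {
  depth <- as.integer(rowSums(counts))
  L <- length(depth)
  refN <- ref == N_CODE
  n_ref <- integer(L)
  ok <- !refN
  n_ref[ok] <- counts[cbind(which(ok), ref[ok])]
  cnt_alt <- counts
  cnt_alt[cbind(which(ok), ref[ok])] <- -1L
  alt <- max.col(cnt_alt, ties.method = "first")
  n_alt <- counts[cbind(seq_len(L), alt)]
  e <- params$assumed_error
  if (ploidy == 2L) {
    ll <- .geno_logliks(n_ref, n_alt, depth, e)
    geno <- .pick_genotype(ll[, 1L], ll[, 2L], ll[, 3L])
    geno <- c(0L, 1L, 2L)[geno]
  } else {
    lR <- n_ref * log(1 - e) + (depth - n_ref) * log(e / 3)
    lA <- n_alt * log(1 - e) + (depth - n_alt) * log(e / 3)
    geno <- ifelse(lA > lR, 2L, 0L)
  }
  geno[geno > 0L & n_alt < params$min_alt_reads] <- 0L
  geno[depth == 0L | refN] <- NA_integer_
  alt[n_alt <= 0L] <- NA_integer_
  list(geno = geno, alt = alt, depth = depth)
}

#' Filter verdict for one site and one sample
#'
#' Flags: `low_depth` when depth is below `min_depth`; `low_mq` when the site
#' RMS mapping quality is below `min_site_mq`; `homopolymer` when the
#' platform is ion and the position lies inside or within the adjacency slack
#' of a homopolymer run of at least `homopolymer_min_len` bases of the
#' reference context. Indel evidence never reaches this stage (discarded at
#' parse time).
#'
#' @param depth post-parse read depth at the site.
#' @param map_quals per-read mapping qualities (RMS is taken), or a single
#'   precomputed RMS value.
#' @param pos 1-based position of the site.
#' @param ref_context reference sequence (string or codes) covering the
#'   neighbourhood of `pos`, with `context_offset` giving the position of its
#'   first base.
#' @param fparams a [filter_params()].
#' @param cparams a [caller_params()].
#' @param context_offset 1-based coordinate of `ref_context[1]`.
#' @return list with `flags` (character subset of \{"low_depth", "low_mq",
#'   "homopolymer"\}) and `pass`.
#' @export
filter_site <- function(depth, map_quals, pos, ref_context,
                        fparams = filter_params(), cparams = caller_params(),
                        context_offset = 1L) {
  flags <- character(0)
  if (depth < cparams$min_depth) flags <- c(flags, "low_depth")
  rms <- if (length(map_quals) > 1L) sqrt(mean(map_quals^2)) else map_quals
  if (length(rms) == 0L || is.na(rms) || rms < cparams$min_site_mq) {
    flags <- c(flags, "low_mq")
  }
  if (fparams$platform == "ion") {
    ctx <- if (is.character(ref_context)) dna_to_int(ref_context) else ref_context
    runs <- find_homopolymer_runs(ctx, fparams$homopolymer_min_len)
    if (nrow(runs)) {
      gs <- runs[, 1L] + context_offset - 1L - fparams$homopolymer_adjacency
      ge <- runs[, 2L] + context_offset - 1L + fparams$homopolymer_adjacency
      if (any(pos >= gs & pos <= ge)) flags <- c(flags, "homopolymer")
    }
  }
  list(flags = flags, pass = length(flags) == 0L)
}

#' Classify sites across samples
#'
#' A site is `uncallable` when no sample passes its filters (or the position
#' is homopolymer-masked / has an N reference). It is a `fixed_difference`
#' when at least one sample is callable and every callable sample is
#' homozygous for the same non-reference allele; a `snp` when any callable
#' sample is heterozygous or callable samples disagree; otherwise
#' `invariant`. Sites presenting three or more alleles across samples are
#' demoted to `uncallable` (counted in the `n_multiallelic` attribute).
#'
#' @param geno sites x samples integer matrix (0 hom-ref, 1 het, 2 hom-alt,
#'   NA nocall), as from [call_genotypes_matrix()].
#' @param alt sites x samples integer matrix of alternative-allele codes.
#' @param pass sites x samples logical matrix of per-sample filter verdicts.
#' @param site_ok logical vector: site-level admissibility (reference not N,
#'   not homopolymer-masked on an ion run).
#' @return list with `class` (integer vector: 0 uncallable, 1 invariant,
#'   2 fixed_difference, 3 snp), `alt` (site-level alternative allele code,
#'   NA for invariant/uncallable), `n_callable` per site, and
#'   `n_multiallelic` demoted sites. Class labels via [site_class_labels].
#' @export
classify_sites <- function(geno, alt, pass, site_ok = NULL) {
  L <- nrow(geno)
  S <- ncol(geno)
  if (is.null(site_ok)) site_ok <- rep(TRUE, L)
  usable <- pass & !is.na(geno) & site_ok
  n_callable <- rowSums(usable)
  any_het <- rep(FALSE, L)
  all_homalt <- rep(TRUE, L)
  all_homref <- rep(TRUE, L)
  alt_min <- rep(NA_integer_, L)
  alt_max <- rep(NA_integer_, L)
  for (s in seq_len(S)) {
    g <- geno[, s]
    u <- usable[, s]
    any_het <- any_het | (u & !is.na(g) & g == 1L)
    all_homalt <- all_homalt & (!u | (g == 2L))
    all_homref <- all_homref & (!u | (g == 0L))
    carries <- u & !is.na(g) & g > 0L & !is.na(alt[, s])
    a <- ifelse(carries, alt[, s], NA_integer_)
    alt_min <- pmin(alt_min, a, na.rm = TRUE)
    alt_max <- pmax(alt_max, a, na.rm = TRUE)
  }
  multi <- !is.na(alt_min) & alt_min != alt_max
  cls <- integer(L)                      # 0 = uncallable
  callable <- n_callable > 0L & !multi
  cls[callable & all_homref] <- 1L
  cls[callable & all_homalt & !is.na(alt_min)] <- 2L
  snp <- callable & (any_het | (!all_homref & !all_homalt))
  cls[snp] <- 3L
  site_alt <- ifelse(cls >= 2L, alt_min, NA_integer_)
  n_multi <- sum(multi & n_callable > 0L)
  if (n_multi > 0L) {
    warning(n_multi, " site(s) with 3+ alleles demoted to uncallable")
  }
  structure(list(class = cls, alt = site_alt, n_callable = n_callable),
            n_multiallelic = n_multi)
}

#' Site class labels
#'
#' Labels for the integer class codes returned by [classify_sites()]
#' (code 0 is `"uncallable"`, so index with `site_class_labels[class + 1]`).
#' @export
site_class_labels <- c("uncallable", "invariant", "fixed_difference", "snp")

#' Pooled-sample SNP flag
#'
#' For a pooled library (many animals, no per-individual genotypes) a site is
#' flagged as a SNP when, after filters, at least two alleles are each
#' supported by at least `het_min_minor_reads_pool` reads. Sites below
#' `min_depth` are never flagged.
#'
#' @param counts sites x 4 count matrix (or a length-4 vector for one site).
#' @param params a [caller_params()].
#' @return logical vector of pooled SNP flags.
#' @export
call_pool <- function(counts, params = caller_params()) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  depth <- rowSums(counts)
  n_supported <- rowSums(counts >= params$het_min_minor_reads_pool)
  depth >= params$min_depth & n_supported >= 2L
}

#' Call and classify all sites of a simulated or parsed contig pileup
#'
#' Runs per-sample genotype calling, the filter stack and cross-sample
#' classification over a `pileup_matrix`. The homopolymer mask (ion) and N
#' reference positions are site-level exclusions: they count toward window
#' span but never toward callable sites.
#'
#' @param pm a `pileup_matrix` (see [emit_pileup()]).
#' @param cparams a [caller_params()].
#' @param fparams a [filter_params()].
#' @param ploidy integer vector of per-sample ploidies on this contig
#'   (default all 2).
#' @param min_depth override for the depth threshold (defaults to
#'   `cparams$min_depth`).
#' @return list with `class`, `alt`, `n_callable` (per position over the full
#'   contig length), `geno`/`alt_by_sample`/`pass` matrices, and `hp_mask`.
#' @export
call_sites <- function(pm, cparams = caller_params(), fparams = filter_params(),
                       ploidy = NULL, min_depth = NULL) {
  S <- length(pm$samples)
  L <- length(pm$ref)
  if (is.null(ploidy)) ploidy <- rep(2L, S)
  if (is.null(min_depth)) min_depth <- cparams$min_depth
  hp <- if (fparams$platform == "ion") {
    homopolymer_mask(pm$ref, fparams$homopolymer_min_len,
                     fparams$homopolymer_adjacency)
  } else rep(FALSE, L)
  site_ok <- !hp & pm$ref != N_CODE
  geno <- matrix(NA_integer_, L, S)
  altm <- matrix(NA_integer_, L, S)
  pass <- matrix(FALSE, L, S)
  for (s in seq_len(S)) {
    sm <- pm$samples[[s]]
    cal <- call_genotypes_matrix(sm$counts, pm$ref, cparams, ploidy[s])
    geno[, s] <- cal$geno
    altm[, s] <- cal$alt
    pass[, s] <- sm$depth >= min_depth & sm$mq_rms >= cparams$min_site_mq
  }
  cl <- classify_sites(geno, altm, pass, site_ok)
  c(cl, list(geno = geno, alt_by_sample = altm, pass = pass, hp_mask = hp))
}
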