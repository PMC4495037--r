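# Y-chromosome analyses: hemizygous error-rate estimation and paternal
# lineage comparison.
#
# On a male's Y (single copy per genome) a true heterozygote is impossible,
# so disagreement among reads at one site measures sequencing error.  Two
# statistics are reported because "error rate" is ambiguous between them:
# the per-base mismatch rate (bases disagreeing with the called haploid
# allele over all bases; this is the quantity that recovers the simulator's
# per-base epsilon) and the per-site heterozygote call rate obtained by
# re-calling the same sites diploid (roughly depth-times larger, since one
# discordant read can flip a diploid call at moderate depth).

#' Select Y-specific contigs from an assignment table
#'
#' Y-specific means assigned to class Y and not also matching X-homologous
#' sequence; restricting to these avoids inflating the error estimate with
#' reads mis-mapped from X homologs.
#'
#' @param assignments data.frame from [read_scaffold_assignments()].
#' @return character vector of Y-specific contig names.
#' @export
select_y_specific <- function(assignments) {
  if (!nrow(assignments)) {
    warning("empty assignment table; no Y-specific contigs")
    return(character(0))
  }
  assignments$contig[assignments$chrom_class == "Y" & !assignments$also_matches_X]
}

# shared per-sample site admissibility on one Y contig
.y_callable <- function(pm, sample, cparams, fparams, min_depth) {
  sm <- pm$samples[[sample]]
  if (is.null(sm)) stop("sample '", sample, "' absent from pileup of ", pm$contig)
  hp <- if (fparams$platform == "ion") {
    homopolymer_mask(pm$ref, fparams$homopolymer_min_len,
                     fparams$homopolymer_adjacency)
  } else rep(FALSE, length(pm$ref))
  sm$depth >= min_depth & sm$mq_rms >= cparams$min_site_mq &
    !hp & pm$ref != N_CODE
}

#' Estimate sequencing error from hemizygous Y sites
#'
#' At callable sites (depth >= `min_depth`, site RMS MQ, homopolymer and N
#' exclusions as in the main filter stack) of a male sample on Y-specific
#' contigs: the haploid allele is called by maximum likelihood, the per-base
#' mismatch rate is the fraction of bases disagreeing with that allele, and
#' the heterozygote call rate is the fraction of the same sites that a
#' diploid re-call labels heterozygous.
#'
#' @param pileups list of `pileup_matrix` objects restricted to Y-specific
#'   contigs.
#' @param sample sample id (must be male: its pileup carries one Y copy).
#' @param cparams a [caller_params()]; `min_depth` (default 4) gates the
#'   error estimate, not `min_depth_y`.
#' @param fparams a [filter_params()].
#' @return object of class `error_rate_estimate` with
#'   `per_base_mismatch_rate`, `het_call_rate`, `callable_sites`,
#'   `total_bases`.
#' @export
estimate_error_rate <- function(pileups, sample, cparams = caller_params(),
                                fparams = filter_params()) {
  mism <- 0; bases <- 0; het <- 0L; sites <- 0L
  for (pm in pileups) {
    ok <- .y_callable(pm, sample, cparams, fparams, cparams$min_depth)
    if (!any(ok)) next
    sm <- pm$samples[[sample]]
    cnt <- sm$counts[ok, , drop = FALSE]
    ref <- pm$ref[ok]
    hap <- call_genotypes_matrix(cnt, ref, cparams, ploidy = 1L)
    called <- ifelse(hap$geno == 2L, hap$alt, ref)
    n_called <- cnt[cbind(seq_len(nrow(cnt)), called)]
    d <- rowSums(cnt)
    mism <- mism + sum(d - n_called)
    bases <- bases + sum(as.numeric(d))
    dip <- call_genotypes_matrix(cnt, ref, cparams, ploidy = 2L)
    het <- het + sum(dip$geno == 1L, na.rm = TRUE)
    sites <- sites + sum(ok)
  }
  if (sites == 0L) stop("zero callable hemizygous sites for sample ", sample)
  structure(list(per_base_mismatch_rate = mism / bases,
                 het_call_rate = het / sites,
                 callable_sites = sites, total_bases = bases),
            class = "error_rate_estimate")
}

#' @export
print.error_rate_estimate <- function(x, ...) {
  cat(sprintf("hemizygous error estimate over %s callable sites (%s bases)\n",
              format(x$callable_sites, big.mark = ","),
              format(x$total_bases, big.mark = ",")))
  cat(sprintf("  per-base mismatch rate: %.4f%%\n", 100 * x$per_base_mismatch_rate))
  cat(sprintf("  heterozygote call rate: %.4f%% of sites\n", 100 * x$het_call_rate))
  invisible(x)
}

#' Compare Y-chromosome lineages across males
#'
#' For each sample, SNVs are callable Y-specific positions (depth >=
#' `min_depth_y`, default 3) whose haploid allele differs from the supplied
#' reference Y allele (e.g. the query-species draft assembly). Shared counts
#' intersect per-sample SNV sets on (contig, position, allele); the output
#' does not depend on sample order.
#'
#' @param pileups list of Y-specific `pileup_matrix` objects.
#' @param samples character vector of (male) sample ids.
#' @param reference_y named list (per contig) of integer-coded reference Y
#'   alleles covering the contig.
#' @param cparams a [caller_params()] (`min_depth_y` is the depth gate).
#' @param fparams a [filter_params()].
#' @return list with `snvs` (named list of per-sample data.frames: `contig`,
#'   `pos`, `ref`, `alt`), `shared_pairwise` (matrix of pairwise shared
#'   counts) and `shared_all` (count present in every sample).
#' @export
compare_y_lineages <- function(pileups, samples, reference_y,
                               cparams = caller_params(),
                               fparams = filter_params()) {
  snvs <- list()
  for (smp in samples) {
    found <- list()
    for (pm in pileups) {
      ok <- .y_callable(pm, smp, cparams, fparams, cparams$min_depth_y)
      refy <- reference_y[[pm$contig]]
      if (is.null(refy)) stop("no reference Y alleles for contig ", pm$contig)
      ok <- ok & refy != N_CODE
      if (!any(ok)) next
      sm <- pm$samples[[smp]]
      cnt <- sm$counts[ok, , drop = FALSE]
      # haploid call against the comparison reference allele
      hap <- call_genotypes_matrix(cnt, refy[ok], cparams, ploidy = 1L)
      var <- which(hap$geno == 2L & !is.na(hap$alt))
      if (length(var)) {
        pos <- which(ok)[var]
        found[[pm$contig]] <- data.frame(
          contig = pm$contig, pos = pos,
          ref = vapply(refy[pos], int_to_dna, ""),
          alt = vapply(hap$alt[var], int_to_dna, ""))
      }
    }
    snvs[[smp]] <- if (length(found)) do.call(rbind, found) else
      data.frame(contig = character(0), pos = integer(0),
                 ref = character(0), alt = character(0))
    rownames(snvs[[smp]]) <- NULL
  }
  key <- lapply(snvs, function(d) paste(d$contig, d$pos, d$alt, sep = ":"))
  k <- length(samples)
  pw <- matrix(0L, k, k, dimnames = list(samples, samples))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    pw[i, j] <- length(intersect(key[[i]], key[[j]]))
  }
  shared_all <- if (k > 0L) length(Reduce(intersect, key)) else 0L
  list(snvs = snvs, shared_pairwise = pw, shared_all = shared_all)
}
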