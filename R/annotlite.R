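# Variant-consequence classification against gene models.
#
# Class set: intergenic, intronic, splice_site, synonymous, missense,
# stop_gained, stop_lost, plus two extension classes (noncoding_exon for
# exonic bases outside the CDS, coding_incomplete for variants in codons
# truncated by a non-zero phase or a partial terminal codon).  Splice sites
# are the first and last 2 bases of each intron (canonical donor/acceptor).

consequence_classes <- c("intergenic", "intronic", "splice_site",
                         "synonymous", "missense", "stop_gained", "stop_lost",
                         "noncoding_exon", "coding_incomplete")

#' Build a queryable index over gene models
#'
#' Introns are the gaps between consecutive exons; splice sites are the 2 bp
#' at each intron end. CDS bookkeeping (segment order in transcription
#' direction, cumulative lengths, phase) supports codon lookup for both
#' strands; on the minus strand codon 1 begins at the rightmost CDS base.
#'
#' @param gene_models list of gene models as from [read_gene_models()].
#' @return object of class `transcript_index`.
#' @export
index_transcripts <- function(gene_models) {
  tx <- lapply(gene_models, function(m) {
    ex <- m$exons
    if (nrow(ex) > 1L && any(ex[-1L, 1L] <= ex[-nrow(ex), 2L])) {
      stop("transcript ", m$transcript_id, ": overlapping exons")
    }
    introns <- if (nrow(ex) > 1L) {
      cbind(start = ex[-nrow(ex), 2L] + 1L, end = ex[-1L, 1L] - 1L)
    } else cbind(start = integer(0), end = integer(0))
    splice <- if (nrow(introns)) {
      rbind(cbind(introns[, 1L], pmin(introns[, 1L] + 1L, introns[, 2L])),
            cbind(pmax(introns[, 2L] - 1L, introns[, 1L]), introns[, 2L]))
    } else cbind(integer(0), integer(0))
    cds <- m$cds
    cds_len <- if (nrow(cds)) sum(cds[, 2L] - cds[, 1L] + 1L) else 0L
    # cumulative CDS length before each segment, in transcription order
    ord <- if (m$strand == "-") rev(seq_len(nrow(cds))) else seq_len(nrow(cds))
    seg_len <- cds[, 2L] - cds[, 1L] + 1L
    cum_before <- integer(nrow(cds))
    if (nrow(cds)) cum_before[ord] <- cumsum(c(0L, seg_len[ord]))[seq_len(nrow(cds))]
    list(model = m, introns = introns, splice = splice,
         cds_len = cds_len, cum_before = cum_before,
         span = c(min(ex[, 1L]), max(ex[, 2L])))
  })
  chroms <- vapply(tx, function(t) t$model$chrom, "")
  idx <- list()
  for (cc in unique(chroms)) {
    sel <- which(chroms == cc)
    idx[[cc]] <- list(
      which = sel,
      ranges = IRanges::IRanges(
        start = vapply(tx[sel], function(t) t$span[1L], 0L),
        end = vapply(tx[sel], function(t) t$span[2L], 0L)))
  }
  structure(list(tx = tx, by_chrom = idx), class = "transcript_index")
}

.in_intervals <- function(pos, iv) {
  nrow(iv) > 0L && any(pos >= iv[, 1L] & pos <= iv[, 2L])
}

# genomic coordinate of the k-th CDS base in transcription order
.cds_to_genomic <- function(t, k) {
  cds <- t$model$cds
  for (i in seq_len(nrow(cds))) {
    off <- k - t$cum_before[i]
    len <- cds[i, 2L] - cds[i, 1L] + 1L
    if (off >= 1L && off <= len) {
      return(if (t$model$strand == "-") cds[i, 2L] - off + 1L
             else cds[i, 1L] + off - 1L)
    }
  }
  NA_integer_
}

# transcription-order CDS position of a genomic coordinate (assumes inside CDS)
.genomic_to_cds <- function(t, pos) {
  cds <- t$model$cds
  for (i in seq_len(nrow(cds))) {
    if (pos >= cds[i, 1L] && pos <= cds[i, 2L]) {
      off <- if (t$model$strand == "-") cds[i, 2L] - pos + 1L
             else pos - cds[i, 1L] + 1L
      return(t$cum_before[i] + off)
    }
  }
  NA_integer_
}

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

#' Classify one substitution variant against the transcript index
#'
#' One consequence per overlapping transcript (intergenic when none).
#' Within a transcript, precedence is splice_site, then coding classes, then
#' intronic. Coding classes compare the amino acid of the reference codon
#' with that of the substituted codon under the standard genetic code;
#' minus-strand variants are complemented before substitution.
#'
#' @param chrom,pos,ref,alt the substitution (ref/alt as single characters).
#' @param index a [index_transcripts()] result.
#' @param reference a `genome` object; the variant's ref allele must match
#'   it.
#' @return data.frame with one row per consequence: `chrom`, `pos`, `ref`,
#'   `alt`, `transcript` (NA for intergenic), `class`, `codon_change` (e.g.
#'   "GAA>GAG", NA outside CDS).
#' @export
classify_variant <- function(chrom, pos, ref, alt, index, reference) {
  ref_code <- dna_to_int(ref)
  alt_code <- dna_to_int(alt)
  ctg <- reference[[chrom]]
  if (is.null(ctg)) stop("contig ", chrom, " absent from reference")
  if (ctg$seq[pos] != ref_code) {
    stop("ref allele mismatch at ", chrom, ":", pos, " (variant says ", ref,
         ", reference has ", int_to_dna(ctg$seq[pos]), ")")
  }
  bc <- index$by_chrom[[chrom]]
  hits <- integer(0)
  if (!is.null(bc)) {
    ov <- IRanges::findOverlaps(IRanges::IRanges(pos, pos), bc$ranges)
    hits <- bc$which[S4Vectors::subjectHits(ov)]
  }
  if (!length(hits)) {
    return(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      transcript = NA_character_, class = "intergenic",
                      codon_change = NA_character_))
  }
  rows <- lapply(hits, function(i) {
    t <- index$tx[[i]]
    m <- t$model
    cls <- NA_character_; codon_change <- NA_character_
    if (.in_intervals(pos, t$splice)) {
      cls <- "splice_site"
    } else if (.in_intervals(pos, m$cds)) {
      res <- .classify_coding(t, pos, alt_code, reference[[chrom]]$seq)
      cls <- res$class; codon_change <- res$codon_change
    } else if (.in_intervals(pos, m$exons)) {
      cls <- "noncoding_exon"
    } else {
      cls <- "intronic"
    }
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               transcript = m$transcript_id, class = cls,
               codon_change = codon_change)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.classify_coding <- function(t, pos, alt_code, seq) {
  cpos <- .genomic_to_cds(t, pos)
  cp <- cpos - t$model$phase
  if (cp < 1L) {
    return(list(class = "coding_incomplete", codon_change = NA_character_))
  }
  codon_i <- (cp - 1L) %/% 3L
  first <- t$model$phase + codon_i * 3L + 1L
  kk <- first:(first + 2L)
  if (any(kk > t$cds_len)) {
    return(list(class = "coding_incomplete", codon_change = NA_character_))
  }
  gpos <- vapply(kk, function(k) .cds_to_genomic(t, k), 0L)
  bases <- seq[gpos]
  minus <- t$model$strand == "-"
  if (minus) bases <- complement_int(bases)
  old <- bases
  within <- which(kk == cpos)
  new <- old
  new[within] <- if (minus) complement_int(alt_code) else alt_code
  tab <- .codon_table()
  old_s <- int_to_dna(old); new_s <- int_to_dna(new)
  if (grepl("N", old_s) || grepl("N", new_s)) {
    return(list(class = "coding_incomplete", codon_change = NA_character_))
  }
  aa_old <- tab[[old_s]]; aa_new <- tab[[new_s]]
  cls <- if (aa_new == "*" && aa_old != "*") "stop_gained"
         else if (aa_old == "*" && aa_new != "*") "stop_lost"
         else if (aa_old == aa_new) "synonymous"
         else "missense"
  list(class = cls, codon_change = paste0(old_s, ">", new_s))
}

#' Classify a table of variants
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param index a [index_transcripts()] result.
#' @param reference a `genome` object.
#' @return row-bound consequence data.frame (one row per variant x
#'   overlapping transcript; intergenic rows for non-genic variants).
#' @export
classify_variants <- function(variants, index, reference) {
  out <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    out[[i]] <- classify_variant(variants$chrom[i], variants$pos[i],
                                 variants$ref[i], variants$alt[i],
                                 index, reference)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tally consequence classes
#'
#' Total effects can exceed total variants (one variant, several overlapping
#' transcripts).
#'
#' @param consequences data.frame from [classify_variants()].
#' @return named integer vector over all consequence classes (zeros kept).
#' @export
summarize_consequences <- function(consequences) {
  tab <- table(factor(consequences$class, levels = consequence_classes))
  out <- as.integer(tab)
  names(out) <- consequence_classes
  out
}
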