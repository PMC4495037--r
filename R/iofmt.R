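#' Read a multi-record FASTA file
#'
#' Sequences are uppercased on input; lowercase records are accepted. Only the
#' unambiguous DNA alphabet plus \code{N} is allowed. Chromosome classes
#' (autosome / X / Y / unplaced) are not part of FASTA and are attached later
#' from a scaffold-assignment table (see [read_scaffold_assignments()]).
#'
#' @param path path to a FASTA file.
#' @return A `genome` object: a named list of contigs, each a list with
#'   `name`, `seq` (integer-coded sequence), `chrom_class` (initially
#'   `"unplaced"`) and `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- startsWith(lines, ">")
  if (!length(lines) || !hdr[1L]) {
    stop("malformed FASTA: line 1 does not start with '>'")
  }
  bad <- which(hdr & nchar(trimws(sub("^>", "", lines))) == 0L)
  if (length(bad)) stop("malformed FASTA header at line ", bad[1L])
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate sequence name: ", nm[duplicated(nm)][1L])
  }
  contigs <- lapply(seq_along(seqs), function(i) {
    s <- toupper(as.character(seqs[[i]]))
    genome_sequence(nm[i], s)
  })
  names(contigs) <- nm
  structure(contigs, class = "genome")
}

#' Construct a single contig record
#'
#' @param name contig identifier.
#' @param sequence character string over A/C/G/T/N (case-insensitive), or an
#'   already integer-coded vector.
#' @param chrom_class one of `"autosome"`, `"X"`, `"Y"`, `"unplaced"`.
#' @return list with fields `name`, `seq`, `chrom_class`, `length`.
#' @export
genome_sequence <- function(name, sequence, chrom_class = "unplaced") {
  assert_chrom_class(chrom_class)
  seq <- if (is.character(sequence)) dna_to_int(sequence) else as.integer(sequence)
  list(name = name, seq = seq, chrom_class = chrom_class, length = length(seq))
}

#' Write a genome object as FASTA
#' @param genome a `genome` object.
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(vapply(genome, function(ct) int_to_dna(ct$seq), ""))
  names(ss) <- vapply(genome, `[[`, "", "name")
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x), "contig(s),",
      format(sum(vapply(x, `[[`, 0L, "length")), big.mark = ","), "bp\n")
  for (ct in x) {
    cat(sprintf("  %-12s %10s bp  [%s]\n", ct$name,
                format(ct$length, big.mark = ","), ct$chrom_class))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# pileup text dialect
#
# CHROM POS REF then per sample: DEPTH BASES BASEQUALS MAPQUALS.
# BASES uses the mpileup read-base syntax: "." / "," reference match,
# ACGT/acgt mismatch, "^X" read start (X = mapping quality char, skipped),
# "$" read end, "*" deletion placeholder (dropped, depth decremented),
# "+N<seq>" / "-N<seq>" indel suffix (stripped entirely -- substitutions only).
# ---------------------------------------------------------------------------

# tokenize one BASES string; returns integer codes with NA for "*"
.parse_base_string <- function(s, ref_code) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  out <- integer(n)  # over-allocate
  k <- 0L
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L              # caret + mapping-quality char
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && chars[j] >= "0" && chars[j] <= "9") j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len             # skip the inserted/deleted sequence
    } else if (ch == "." || ch == ",") {
      k <- k + 1L; out[k] <- ref_code; i <- i + 1L
    } else if (ch == "*") {
      k <- k + 1L; out[k] <- NA_integer_; i <- i + 1L
    } else {
      code <- .base_lut[utf8ToInt(ch) + 1L]
      if (is.na(code)) stop("unexpected character '", ch, "' in base string")
      k <- k + 1L; out[k] <- code; i <- i + 1L
    }
  }
  out[seq_len(k)]
}

.phred_chars_to_int <- function(s) utf8ToInt(s) - 33L

#' Read a per-site pileup text file
#'
#' Parses the whitespace-separated pileup dialect (one reference position per
#' line; per sample a depth, read-base string, base-quality string and
#' mapping-quality string). Indel evidence and deletion placeholders are
#' discarded during parsing, so only nucleotide substitutions reach the
#' caller. Reads with base quality below `min_base_quality` are dropped at
#' parse time (with their qualities), mirroring the default quality floor of
#' standard pileup generators.
#'
#' @param path pileup file.
#' @param n_samples number of per-sample column triples expected.
#' @param min_base_quality phred floor below which a read base is dropped.
#' @return object of class `pileup`: list with `chrom`, `pos`, `ref`
#'   (integer-coded) and `samples`, a list (length `n_samples`) of lists with
#'   per-site integer vectors `bases`, `bq`, `mq`.
#' @export
read_pileup <- function(path, n_samples, min_base_quality = 13L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  ncol_exp <- 3L + 4L * n_samples
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != ncol_exp)) {
    stop("pileup parse error at line ", which(nf != ncol_exp)[1L],
         ": expected ", ncol_exp, " columns, found ", nf[nf != ncol_exp][1L])
  }
  m <- matrix(unlist(fields), ncol = ncol_exp, byrow = TRUE)
  chrom <- m[, 1L]
  pos <- as.integer(m[, 2L])
  ref <- vapply(m[, 3L], function(b) .base_lut[utf8ToInt(b) + 1L], 0L,
                USE.NAMES = FALSE)
  if (anyNA(ref)) stop("invalid reference base at line ", which(is.na(ref))[1L])
  # positions must be strictly increasing within each chromosome
  for (cc in unique(chrom)) {
    p <- pos[chrom == cc]
    if (any(diff(p) <= 0L)) {
      stop("non-monotonic POS on ", cc, " near position ",
           p[which(diff(p) <= 0L)[1L] + 1L])
    }
  }
  samples <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    col0 <- 3L + (s - 1L) * 4L
    depth <- as.integer(m[, col0 + 1L])
    bases <- vector("list", length(pos))
    bq <- vector("list", length(pos))
    mq <- vector("list", length(pos))
    for (i in seq_along(pos)) {
      if (depth[i] == 0L) {
        bases[[i]] <- integer(0); bq[[i]] <- integer(0); mq[[i]] <- integer(0)
        next
      }
      b <- .parse_base_string(m[i, col0 + 2L], ref[i])
      q <- .phred_chars_to_int(m[i, col0 + 3L])
      mqv <- .phred_chars_to_int(m[i, col0 + 4L])
      if (length(b) != depth[i] || length(q) != depth[i] || length(mqv) != depth[i]) {
        stop("pileup length mismatch at ", chrom[i], ":", pos[i],
             " (depth ", depth[i], ", parsed ", length(b), " bases, ",
             length(q), " base quals, ", length(mqv), " map quals)")
      }
      keep <- !is.na(b) & q >= min_base_quality   # drop '*' and low-quality reads
      bases[[i]] <- b[keep]; bq[[i]] <- q[keep]; mq[[i]] <- mqv[keep]
    }
    samples[[s]] <- list(bases = bases, bq = bq, mq = mq)
  }
  structure(list(chrom = chrom, pos = pos, ref = ref, samples = samples),
            class = "pileup")
}

#' Write a parsed pileup back to the text dialect
#' @param p a `pileup` object.
#' @param path output path.
#' @export
write_pileup <- function(p, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(p$pos)
  out <- character(n)
  for (i in seq_len(n)) {
    cols <- c(p$chrom[i], p$pos[i], int_to_dna(p$ref[i]))
    for (s in p$samples) {
      b <- s$bases[[i]]
      bstr <- paste(ifelse(b == p$ref[i], ".", vapply(b, int_to_dna, "")),
                    collapse = "")
      cols <- c(cols, length(b),
                if (length(b)) bstr else "*",
                if (length(b)) intToUtf8(s$bq[[i]] + 33L) else "*",
                if (length(b)) intToUtf8(s$mq[[i]] + 33L) else "*")
    }
    out[i] <- paste(cols, collapse = "\t")
  }
  writeLines(out, con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# minimal VCFv4.2 subset (biallelic substitutions)
# ---------------------------------------------------------------------------

#' Write biallelic substitution variants as a minimal VCFv4.2 file
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `filter` (default "PASS") and `qual` (default ".").
#' @param genotypes character matrix (`nrow(variants)` x samples) of VCF GT
#'   strings, e.g. "0/1" or haploid "1"; may be NULL for site-only output.
#' @param samples sample names (column order of `genotypes`).
#' @param path output path.
#' @export
write_vcf_subset <- function(variants, path, genotypes = NULL, samples = NULL) {
  if (nrow(variants) > 0L) {
    if (any(variants$ref == variants$alt)) stop("REF == ALT is not a variant")
    if (any(grepl(",", variants$alt, fixed = TRUE))) {
      stop("multiallelic records are not supported")
    }
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=equidiv",
           '##FILTER=<ID=low_depth,Description="coverage below minimum depth">',
           '##FILTER=<ID=low_mq,Description="site RMS mapping quality below minimum">',
           '##FILTER=<ID=homopolymer,Description="inside or adjacent to a homopolymer run">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(genotypes)) {
    stopifnot(!is.null(samples), ncol(genotypes) == length(samples))
    cols <- c(cols, "FORMAT", samples)
  }
  lines <- c(hdr, paste(cols, collapse = "\t"))
  if (nrow(variants) > 0L) {
    filt <- variants$filter %||% rep("PASS", nrow(variants))
    qual <- variants$qual %||% rep(".", nrow(variants))
    body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                  variants$alt, qual, filt, ".", sep = "\t")
    if (!is.null(genotypes)) {
      gt <- apply(genotypes, 1L, paste, collapse = "\t")
      body <- paste(body, "GT", gt, sep = "\t")
    }
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal VCF subset written by [write_vcf_subset()]
#' @param path VCF path.
#' @return list with `variants` (data.frame), `genotypes` (matrix or NULL),
#'   `samples`.
#' @export
read_vcf_subset <- function(path) {
  lines <- readLines(path)
  hdr_i <- which(startsWith(lines, "#CHROM"))
  if (!length(hdr_i)) stop("missing #CHROM header line")
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1L]]
  samples <- if (length(hdr) > 9L) hdr[-seq_len(9L)] else character(0)
  body <- lines[-seq_len(hdr_i)]
  if (!length(body)) {
    return(list(variants = data.frame(chrom = character(0), pos = integer(0),
                                      ref = character(0), alt = character(0),
                                      filter = character(0)),
                genotypes = NULL, samples = samples))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  m <- matrix(unlist(f), ncol = length(hdr), byrow = TRUE)
  variants <- data.frame(chrom = m[, 1L], pos = as.integer(m[, 2L]),
                         ref = m[, 4L], alt = m[, 5L], filter = m[, 7L],
                         stringsAsFactors = FALSE)
  genotypes <- if (length(samples)) {
    g <- m[, -seq_len(9L), drop = FALSE]
    colnames(g) <- samples
    g
  }
  list(variants = variants, genotypes = genotypes, samples = samples)
}

# ---------------------------------------------------------------------------
# gene models (GFF3 subset)
# ---------------------------------------------------------------------------

#' Read gene models from a GFF3 subset
#'
#' Accepts gene / mRNA / exon / CDS rows with ID and Parent attributes and
#' returns one model per mRNA. Coordinates stay 1-based inclusive. Models
#' whose CDS falls outside the exons, or with overlapping exons, are rejected
#' with a warning; a CDS whose length is not divisible by three at phase 0
#' draws a warning but is kept.
#'
#' @param path GFF3 file.
#' @return list of gene models; each is a list with `gene_id`,
#'   `transcript_id`, `chrom`, `strand`, `exons`, `cds` (two-column matrices
#'   of 1-based inclusive start/end) and `phase` of the first CDS segment in
#'   transcription order.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID)
  parent <- vapply(md$Parent, function(p) if (length(p)) as.character(p[1L]) else NA_character_, "")
  mrna_i <- which(type == "mRNA")
  models <- list()
  for (i in mrna_i) {
    tid <- ids[i]
    child <- which(parent == tid)
    ex_i <- child[type[child] == "exon"]
    cds_i <- child[type[child] == "CDS"]
    exons <- cbind(start = BiocGenerics::start(gr)[ex_i],
                   end = BiocGenerics::end(gr)[ex_i])
    exons <- exons[order(exons[, 1L]), , drop = FALSE]
    cds <- cbind(start = BiocGenerics::start(gr)[cds_i],
                 end = BiocGenerics::end(gr)[cds_i])
    cds <- cds[order(cds[, 1L]), , drop = FALSE]
    strand <- as.character(BiocGenerics::strand(gr)[i])
    if (nrow(exons) > 1L && any(exons[-1L, 1L] <= exons[-nrow(exons), 2L])) {
      warning("transcript ", tid, " rejected: overlapping exons")
      next
    }
    ok <- TRUE
    if (nrow(cds)) {
      for (k in seq_len(nrow(cds))) {
        inside <- any(cds[k, 1L] >= exons[, 1L] & cds[k, 2L] <= exons[, 2L])
        if (!inside) { ok <- FALSE; break }
      }
    }
    if (!ok) {
      warning("transcript ", tid, " rejected: CDS outside exons")
      next
    }
    phase <- 0L
    if (nrow(cds)) {
      ph <- md$phase[cds_i]
      ph <- if (is.null(ph)) rep(0L, length(cds_i)) else as.integer(ph)
      ph[is.na(ph)] <- 0L
      # phase of the first CDS segment in transcription order
      ord <- order(BiocGenerics::start(gr)[cds_i])
      phase <- if (strand == "-") ph[ord][length(ord)] else ph[ord][1L]
      cds_len <- sum(cds[, 2L] - cds[, 1L] + 1L)
      if (phase == 0L && cds_len %% 3L != 0L) {
        warning("transcript ", tid, ": CDS length ", cds_len,
                " not divisible by 3 at phase 0")
      }
    }
    models[[length(models) + 1L]] <- list(
      gene_id = parent[i], transcript_id = tid,
      chrom = as.character(GenomeInfoDb::seqnames(gr)[i]),
      strand = strand, exons = exons, cds = cds, phase = phase)
  }
  models
}

# ---------------------------------------------------------------------------
# scaffold assignment table
# ---------------------------------------------------------------------------

#' Read a scaffold-to-chromosome assignment table
#'
#' Tab-separated with header columns `contig`, `chrom_class`,
#' `also_matches_X` (logical); used to partition contigs into autosome / X /
#' Y classes and to mark Y scaffolds with residual X homology.
#' @param path TSV path.
#' @return data.frame with those three columns.
#' @export
read_scaffold_assignments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "chrom_class", "also_matches_X")
  if (!all(need %in% names(df))) {
    stop("assignment table must have columns: ", paste(need, collapse = ", "))
  }
  df$also_matches_X <- as.logical(df$also_matches_X)
  assert_chrom_class(df$chrom_class)
  df
}

#' @rdname read_scaffold_assignments
#' @param assignments data.frame as returned by [read_scaffold_assignments()].
#' @export
write_scaffold_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# assembly statistics
# ---------------------------------------------------------------------------

#' Assembly summary statistics (N50)
#'
#' N50 is the contig length at which the cumulative sorted-descending length
#' first reaches half the assembly total; it is always one of the input
#' lengths.
#'
#' @param lengths positive integer vector of contig/scaffold lengths.
#' @return object of class `assembly_stats` with `n_contigs`, `total_bp`,
#'   `n50`.
#' @export
assembly_stats <- function(lengths) {
  if (!length(lengths)) stop("empty length list")
  if (any(lengths <= 0)) stop("contig lengths must be positive")
  srt <- sort(as.numeric(lengths), decreasing = TRUE)
  total <- sum(srt)
  n50 <- srt[which(cumsum(srt) >= total / 2)[1L]]
  structure(list(n_contigs = length(lengths), total_bp = total, n50 = n50),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("assembly:", x$n_contigs, "contigs,",
      format(x$total_bp, big.mark = ","), "bp, N50",
      format(x$n50, big.mark = ","), "bp\n")
  invisible(x)
}
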