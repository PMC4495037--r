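# Windowed divergence / SNP-density statistics and genome-wide estimates.
#
# Window arithmetic is 0-based half-open internally; reported start/end
# columns are 1-based inclusive like every file format in the package.

#' Per-window divergence and SNP-density statistics
#'
#' Windows tile each contig ([0, size), [size, 2*size), ...; the last window
#' is truncated). Positions absent from the classification are uncallable;
#' they count toward the window span but not toward callable sites. Window
#' sums conserve genome totals by construction. Windows whose callable
#' fraction falls below `min_callable_fraction` are flagged `masked`
#' (report-level only; totals are unaffected).
#'
#' @param site_classes named list (per contig) of integer class vectors
#'   covering positions 1..contig length (0 uncallable, 1 invariant, 2 fixed
#'   difference, 3 snp), as from [call_sites()].
#' @param window_size window size in bp (default 1e6).
#' @param min_callable_fraction masking threshold (default 0.2).
#' @return data.frame with one row per window: `chrom`, `window` (0-based
#'   index), `start`, `end` (1-based inclusive), `span`, `callable`, `fixed`,
#'   `snps`, `divergence_rate`, `snp_density`, `masked`. Rates are NA in
#'   windows without callable sites.
#' @export
window_stats <- function(site_classes, window_size = 1e6, min_callable_fraction = 0.2) {
  if (window_size < 1) stop("window size must be >= 1")
  window_size <- as.integer(window_size)
  rows <- list()
  for (nm in names(site_classes)) {
    cls <- site_classes[[nm]]
    L <- length(cls)
    widx <- ((seq_len(L) - 1L) %/% window_size) + 1L   # 1-based bin index
    nw <- max(widx)
    callable <- tabulate(widx[cls != 0L], nw)
    fixed <- tabulate(widx[cls == 2L], nw)
    snps <- tabulate(widx[cls == 3L], nw)
    span <- tabulate(widx, nw)
    start <- (seq_len(nw) - 1L) * window_size + 1L
    dr <- ifelse(callable > 0L, fixed / callable, NA_real_)
    sd_ <- ifelse(callable > 0L, snps / callable, NA_real_)
    rows[[nm]] <- data.frame(
      chrom = nm, window = seq_len(nw) - 1L, start = start,
      end = start + span - 1L, span = span, callable = callable,
      fixed = fixed, snps = snps, divergence_rate = dr, snp_density = sd_,
      masked = callable < min_callable_fraction * span)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genome-wide raw divergence with per-class breakdown
#'
#' Raw alpha is total fixed interspecies differences over total callable
#' sites; the same ratio is returned per chromosome class (autosome, X, Y).
#'
#' @param site_classes named list of per-contig class vectors (see
#'   [window_stats()]).
#' @param chrom_class named character vector mapping contig name to class.
#' @return list with `raw_alpha`, `callable`, `fixed`, and `by_class`
#'   data.frame (`chrom_class`, `callable`, `fixed`, `alpha`).
#' @export
genome_divergence <- function(site_classes, chrom_class) {
  tot_call <- 0; tot_fix <- 0
  acc <- list()
  for (nm in names(site_classes)) {
    cls <- site_classes[[nm]]
    cc <- chrom_class[[nm]] %||% "unplaced"
    call_n <- sum(cls != 0L)
    fix_n <- sum(cls == 2L)
    tot_call <- tot_call + call_n
    tot_fix <- tot_fix + fix_n
    if (is.null(acc[[cc]])) acc[[cc]] <- c(0, 0)
    acc[[cc]] <- acc[[cc]] + c(call_n, fix_n)
  }
  if (tot_call == 0) stop("zero callable sites")
  by_class <- data.frame(
    chrom_class = names(acc),
    callable = vapply(acc, `[[`, 0, 1L),
    fixed = vapply(acc, `[[`, 0, 2L))
  by_class$alpha <- ifelse(by_class$callable > 0,
                           by_class$fixed / by_class$callable, NA_real_)
  rownames(by_class) <- NULL
  list(raw_alpha = tot_fix / tot_call, callable = tot_call, fixed = tot_fix,
       by_class = by_class)
}

#' Polymorphism-corrected divergence
#'
#' A fraction of apparent fixed differences segregates within the query
#' and/or reference species; the corrected divergence subtracts the combined
#' polymorphism term, supplied as (low, high) per-site rates for each side
#' (the reference side is not estimable from cross-species pileups and must
#' be configured). The corrected range is
#' `(raw - high correction, raw - low correction)`, floored at zero.
#'
#' @param raw_alpha genome-wide raw divergence.
#' @param pi_query length-2 numeric `(low, high)` query-side polymorphism.
#' @param pi_reference length-2 numeric `(low, high)` reference-side term
#'   (default `c(0, 0)`).
#' @return object of class `divergence_estimate` with `raw_alpha`,
#'   `correction` (low, high) and `corrected_alpha_range` (low, high).
#' @export
corrected_divergence <- function(raw_alpha, pi_query, pi_reference = c(0, 0)) {
  pi_query <- rep_len(as.numeric(pi_query), 2L)
  pi_reference <- rep_len(as.numeric(pi_reference), 2L)
  corr <- sort(pi_query + pi_reference)
  lo <- raw_alpha - corr[2L]
  hi <- raw_alpha - corr[1L]
  if (lo < 0 || hi < 0) {
    warning("polymorphism correction exceeds raw divergence; floored at 0")
    lo <- max(0, lo); hi <- max(0, hi)
  }
  structure(list(raw_alpha = raw_alpha, correction = corr,
                 corrected_alpha_range = c(lo, hi)),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("raw divergence:       %.4f%%\n", 100 * x$raw_alpha))
  cat(sprintf("polymorphism term:    %.4f%% - %.4f%%\n",
              100 * x$correction[1L], 100 * x$correction[2L]))
  cat(sprintf("corrected divergence: %.4f%% - %.4f%%\n",
              100 * x$corrected_alpha_range[1L],
              100 * x$corrected_alpha_range[2L]))
  invisible(x)
}

#' Transition/transversion summary
#'
#' Transitions are A<->G and C<->T; everything else is a transversion. The
#' ratio is NA (with counts still reported) when there are no transversions.
#'
#' @param substitutions data.frame with `ref` and `alt` columns (characters
#'   or integer codes), one ordered pair per substitution.
#' @return object of class `titv_summary` with `transitions`,
#'   `transversions`, `ratio`.
#' @export
titv_ratio <- function(substitutions) {
  ref <- substitutions$ref
  alt <- substitutions$alt
  if (is.character(ref)) ref <- vapply(ref, dna_to_int, 0L, USE.NAMES = FALSE)
  if (is.character(alt)) alt <- vapply(alt, dna_to_int, 0L, USE.NAMES = FALSE)
  if (any(ref == alt)) stop("ref == alt in substitution list")
  s <- ref + alt                         # A+G = 4, C+T = 6 <=> transition
  ti <- sum(s == 4L | s == 6L)
  tv <- length(s) - ti
  structure(list(transitions = ti, transversions = tv,
                 ratio = if (tv > 0L) ti / tv else NA_real_),
            class = "titv_summary")
}

#' @export
print.titv_summary <- function(x, ...) {
  cat("Ti:", x$transitions, " Tv:", x$transversions, " Ti/Tv:",
      if (is.na(x$ratio)) "undefined (no transversions)" else sprintf("%.3f", x$ratio),
      "\n")
  invisible(x)
}

#' Per-chromosome box-plot summary of window rates
#'
#' Quartiles use the linear-interpolation convention (`stats::quantile` type
#' 7); the notch half-width is `1.58 * IQR / sqrt(n)`, the standard stand-in
#' for the standard error of the median; whiskers span the full range.
#' Masked windows and NA rates are excluded; chromosomes with no usable
#' window are omitted with a warning.
#'
#' @param wstats data.frame from [window_stats()].
#' @param value which rate to summarize: `"divergence_rate"` or
#'   `"snp_density"`.
#' @return data.frame: `chrom`, `n`, `q1`, `median`, `q3`, `notch`,
#'   `whisker_lo`, `whisker_hi`, `mean`, `sd`.
#' @export
boxplot_summary <- function(wstats, value = c("divergence_rate", "snp_density")) {
  value <- match.arg(value)
  rows <- list()
  for (nm in unique(wstats$chrom)) {
    v <- wstats[wstats$chrom == nm & !wstats$masked, value]
    v <- v[!is.na(v)]
    if (!length(v)) {
      warning("chromosome ", nm, " has no unmasked windows; omitted")
      next
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    rows[[nm]] <- data.frame(
      chrom = nm, n = length(v), q1 = q[1L], median = q[2L], q3 = q[3L],
      notch = 1.58 * (q[3L] - q[1L]) / sqrt(length(v)),
      whisker_lo = min(v), whisker_hi = max(v),
      mean = mean(v), sd = stats::sd(v))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Venn region counts for named variant sets
#'
#' Variants are keyed on chromosome, position AND alternative allele. Counts
#' are exclusive region sizes for all 2^k - 1 regions; they sum to the size
#' of the union.
#'
#' @param sets named list (k <= 5) of data.frames with `chrom`, `pos`, `alt`
#'   columns (or ready-made character keys).
#' @return data.frame with `region` (set names joined by "&") and `count`.
#' @export
intersect_variant_sets <- function(sets) {
  if (length(sets) > 5L) stop("at most 5 sets supported")
  keys <- lapply(sets, function(s) {
    if (is.character(s)) unique(s)
    else unique(paste(s$chrom, s$pos, s$alt, sep = ":"))
  })
  all_keys <- unique(unlist(keys))
  member <- vapply(keys, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  if (length(all_keys) == 1L) member <- matrix(member, nrow = 1L)
  k <- length(sets)
  nms <- names(sets)
  rows <- list()
  for (code in seq_len(2^k - 1L)) {
    in_set <- as.logical(bitwAnd(code, 2^(seq_len(k) - 1L)))
    hit <- if (length(all_keys)) {
      rowSums(member[, in_set, drop = FALSE]) == sum(in_set) &
        rowSums(member[, !in_set, drop = FALSE]) == 0L
    } else logical(0)
    rows[[code]] <- data.frame(region = paste(nms[in_set], collapse = "&"),
                               count = sum(hit))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-contig mean depth and coverage
#'
#' Mean depth is total emitted bases over the reference length; coverage is
#' the fraction of positions with at least one read.
#'
#' @param depths named list (per contig) of per-position depth vectors, each
#'   covering the full contig length.
#' @return data.frame with `chrom`, `length`, `mean_depth`,
#'   `coverage_percent`, plus a final `TOTAL` row.
#' @export
coverage_summary <- function(depths) {
  rows <- lapply(names(depths), function(nm) {
    d <- depths[[nm]]
    data.frame(chrom = nm, length = length(d),
               mean_depth = sum(as.numeric(d)) / length(d),
               coverage_percent = 100 * mean(d >= 1L))
  })
  out <- do.call(rbind, rows)
  total_len <- sum(out$length)
  out <- rbind(out, data.frame(
    chrom = "TOTAL", length = total_len,
    mean_depth = sum(out$mean_depth * out$length) / total_len,
    coverage_percent = sum(out$coverage_percent * out$length) / total_len))
  rownames(out) <- NULL
  out
}
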