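# Orchestration: run the full calling/classification/divergence pipeline on
# a dataset and, for simulated data, compare every estimate against the
# truth ledger.

#' Run the full analysis pipeline
#'
#' Chains calling, filtering, cross-sample classification, windowed
#' statistics, genome-wide divergence with polymorphism correction, Ti/Tv
#' quality control, per-sample coverage, the Venn intersection of per-sample
#' variant sets and, when the dataset provides them, Y-chromosome error
#' estimation and lineage comparison. The headline divergence is computed on
#' autosomes (the reference coordinate system of interest); X and Y class
#' rates are reported alongside.
#'
#' @param dataset a `sim_dataset` from [simulate_dataset()], or a list with
#'   the same fields (`pileups`, `assignments`, and for Y analyses `query`
#'   plus `config$individuals`).
#' @param cparams a [caller_params()].
#' @param fparams a [filter_params()].
#' @param window_size window size in bp (default 1e6).
#' @param min_callable_fraction window masking threshold (default 0.2).
#' @param pi_query,pi_reference polymorphism-correction bounds passed to
#'   [corrected_divergence()] (defaults `c(0.0010, 0.0015)` and `c(0, 0)`).
#' @return object of class `divrun` with elements `site_classes`,
#'   `windows`, `divergence`, `corrected`, `titv_snp`, `titv_fixed`,
#'   `coverage`, `venn`, `y` (NULL without Y-specific contigs), `variants`,
#'   and a flat `summary` list.
#' @export
run_pipeline <- function(dataset, cparams = caller_params(),
                         fparams = filter_params(), window_size = 1e6,
                         min_callable_fraction = 0.2,
                         pi_query = c(0.0010, 0.0015), pi_reference = c(0, 0)) {
  ind <- dataset$config$individuals
  pileups <- dataset$pileups
  chrom_class <- stats::setNames(dataset$assignments$chrom_class,
                                 dataset$assignments$contig)
  site_classes <- list()
  snp_subs <- list(); fixed_subs <- list()
  per_sample_vars <- stats::setNames(vector("list", nrow(ind)), ind$id)
  for (nm in names(pileups)) {
    pm <- pileups[[nm]]
    cc <- chrom_class[[nm]] %||% "unplaced"
    present <- names(pm$samples)
    sex <- ind$sex[match(present, ind$id)]
    ploidy <- .ploidy_for(cc, sex)
    cs <- call_sites(pm, cparams, fparams, ploidy = ploidy)
    site_classes[[nm]] <- cs$class
    is_snp <- cs$class == 3L
    is_fix <- cs$class == 2L
    if (any(is_snp)) {
      snp_subs[[nm]] <- data.frame(ref = pm$ref[is_snp], alt = cs$alt[is_snp])
    }
    if (any(is_fix)) {
      fixed_subs[[nm]] <- data.frame(ref = pm$ref[is_fix], alt = cs$alt[is_fix])
    }
    for (s in seq_along(present)) {
      usable <- cs$pass[, s] & !is.na(cs$geno[, s]) & cs$class != 0L
      carry <- usable & cs$geno[, s] > 0L & !is.na(cs$alt_by_sample[, s])
      if (any(carry)) {
        per_sample_vars[[present[s]]] <- c(
          per_sample_vars[[present[s]]],
          paste(nm, which(carry), cs$alt_by_sample[carry, s], sep = ":"))
      }
    }
  }
  windows <- window_stats(site_classes, window_size, min_callable_fraction)
  div <- genome_divergence(site_classes, as.list(chrom_class))
  auto_alpha <- .class_alpha(div, "autosome")
  corrected <- corrected_divergence(auto_alpha %||% div$raw_alpha,
                                    pi_query, pi_reference)
  titv_snp <- if (length(snp_subs)) titv_ratio(do.call(rbind, snp_subs)) else NULL
  titv_fixed <- if (length(fixed_subs)) titv_ratio(do.call(rbind, fixed_subs)) else NULL
  coverage <- .pipeline_coverage(pileups)
  venn <- if (any(lengths(per_sample_vars) > 0L)) {
    intersect_variant_sets(lapply(per_sample_vars, function(x) x %||% character(0)))
  }
  y <- .pipeline_y(dataset, cparams, fparams)
  summary <- list(
    raw_alpha = auto_alpha %||% div$raw_alpha,
    corrected_alpha_low = corrected$corrected_alpha_range[1L],
    corrected_alpha_high = corrected$corrected_alpha_range[2L],
    titv_snp = if (!is.null(titv_snp)) titv_snp$ratio else NA_real_,
    snp_count = sum(vapply(site_classes, function(x) sum(x == 3L), 0)),
    fixed_count = sum(vapply(site_classes, function(x) sum(x == 2L), 0)),
    error_rate = if (!is.null(y)) y$error_rates[[1L]]$per_base_mismatch_rate
                 else NA_real_)
  structure(list(site_classes = site_classes, windows = windows,
                 divergence = div, corrected = corrected,
                 titv_snp = titv_snp, titv_fixed = titv_fixed,
                 coverage = coverage, venn = venn, y = y,
                 summary = summary),
            class = "divrun")
}

.class_alpha <- function(div, cc) {
  i <- match(cc, div$by_class$chrom_class)
  if (is.na(i)) NULL else div$by_class$alpha[i]
}

.pipeline_coverage <- function(pileups) {
  samples <- unique(unlist(lapply(pileups, function(pm) names(pm$samples))))
  out <- list()
  for (smp in samples) {
    depths <- list()
    for (pm in pileups) {
      if (!is.null(pm$samples[[smp]])) depths[[pm$contig]] <- pm$samples[[smp]]$depth
    }
    out[[smp]] <- coverage_summary(depths)
  }
  combined <- list()
  for (pm in pileups) {
    combined[[pm$contig]] <- Reduce(`+`, lapply(pm$samples, `[[`, "depth"))
  }
  out$combined <- coverage_summary(combined)
  out
}

.pipeline_y <- function(dataset, cparams, fparams) {
  ysp <- select_y_specific(dataset$assignments)
  ysp <- intersect(ysp, names(dataset$pileups))
  if (!length(ysp)) return(NULL)
  ind <- dataset$config$individuals
  males <- ind$id[ind$sex == "M"]
  if (!length(males)) return(NULL)
  ypu <- dataset$pileups[ysp]
  err <- lapply(males, function(smp) estimate_error_rate(ypu, smp, cparams, fparams))
  names(err) <- males
  lineages <- NULL
  if (!is.null(dataset$query)) {
    refy <- lapply(dataset$query[ysp], `[[`, "seq")
    names(refy) <- ysp
    lineages <- compare_y_lineages(ypu, males, refy, cparams, fparams)
  }
  list(contigs = ysp, error_rates = err, lineages = lineages)
}

#' @export
print.divrun <- function(x, ...) {
  cat("divergence pipeline run\n")
  cat(sprintf("  autosomal raw alpha:  %.4f%% (%s fixed / %s callable overall)\n",
              100 * x$summary$raw_alpha,
              format(x$divergence$fixed, big.mark = ","),
              format(x$divergence$callable, big.mark = ",")))
  cat(sprintf("  corrected:            %.4f%% - %.4f%%\n",
              100 * x$summary$corrected_alpha_low,
              100 * x$summary$corrected_alpha_high))
  cat(sprintf("  SNP sites:            %s (Ti/Tv %.3f)\n",
              format(x$summary$snp_count, big.mark = ","),
              x$summary$titv_snp))
  if (!is.null(x$y)) {
    cat(sprintf("  Y per-base error:     %.4f%%\n", 100 * x$summary$error_rate))
  }
  invisible(x)
}

#' @export
summary.divrun <- function(object, ...) {
  s <- object$summary
  df <- data.frame(quantity = names(s),
                   value = vapply(s, function(v) as.numeric(v)[1L], 0))
  rownames(df) <- NULL
  df
}

#' Write the machine-readable report bundle of a run
#'
#' Emits deterministic TSVs: run summary, per-window statistics,
#' per-chromosome box-plot summaries, per-class divergence, coverage, Venn
#' region counts, and a manifest. Identical runs produce byte-identical
#' files.
#'
#' @param run a `divrun` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest paths.
#' @export
write_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- character(0)
  files <- c(files, w(summary(run), "summary.tsv"))
  files <- c(files, w(run$windows, "windows.tsv"))
  files <- c(files, w(boxplot_summary(run$windows, "divergence_rate"),
                      "boxplot_divergence.tsv"))
  sn <- tryCatch(boxplot_summary(run$windows, "snp_density"),
                 warning = function(w) NULL)
  if (!is.null(sn)) files <- c(files, w(sn, "boxplot_snp_density.tsv"))
  files <- c(files, w(run$divergence$by_class, "divergence_by_class.tsv"))
  files <- c(files, w(run$coverage$combined, "coverage.tsv"))
  if (!is.null(run$venn)) files <- c(files, w(run$venn, "venn.tsv"))
  manifest <- file.path(dir, "MANIFEST")
  writeLines(basename(files), manifest)
  invisible(c(files, manifest))
}

#' Simulate (if needed) and run the pipeline end to end
#'
#' @param x a [sim_config()] (the dataset is simulated first) or a
#'   `sim_dataset`.
#' @param ... passed to [run_pipeline()].
#' @return a `divrun`.
#' @export
run_full <- function(x, ...) {
  dataset <- if (inherits(x, "sim_config")) simulate_dataset(x) else x
  run_pipeline(dataset, ...)
}

# P(planted polymorphic site is monomorphic across the sampled chromosomes)
.p_monomorphic <- function(n_chrom, afs = "uniform") {
  i <- seq_len(n_chrom - 1L)
  w <- if (afs == "uniform") rep(1, length(i)) else 1 / i
  w <- w / sum(w)
  p <- i / n_chrom
  sum(w * (p^n_chrom + (1 - p)^n_chrom))
}

#' Parameter-recovery experiment
#'
#' Simulates a dataset, runs the pipeline, and tabulates truth versus
#' estimate for the headline parameters: autosomal divergence, the
#' autosome:X divergence ratio, within-species polymorphism, sequencing
#' error and Ti/Tv. The polymorphism estimate divides the autosomal
#' SNP-site rate by the probability that a planted site segregates in the
#' sampled chromosomes (closed form under the configured frequency
#' spectrum). Truth for the divergence rows is the realized truth-ledger
#' rate, not the nominal configuration value.
#'
#' @param config a [sim_config()].
#' @param cparams,fparams caller and filter parameters.
#' @param tolerances named list of relative (alpha, ratio, pi, epsilon) and
#'   absolute (titv) tolerances.
#' @param ... passed to [run_pipeline()].
#' @return object of class `recovery_table`: data.frame with `parameter`,
#'   `truth`, `estimate`, `rel_error`, `tolerance`, `pass`; the `divrun` and
#'   dataset are attached as attributes.
#' @export
recovery_experiment <- function(config, cparams = caller_params(),
                                fparams = filter_params(),
                                tolerances = list(alpha = 0.10, ratio = 0.15,
                                                  pi = 0.15, epsilon = 0.15,
                                                  titv = 0.15),
                                ...) {
  dataset <- simulate_dataset(config)
  run <- run_pipeline(dataset, ...)
  cls <- stats::setNames(dataset$assignments$chrom_class,
                         dataset$assignments$contig)
  len_of <- function(cc) sum(vapply(dataset$reference[names(cls)[cls == cc]],
                                    `[[`, 0L, "length"))
  fixed_of <- function(cc) sum(vapply(dataset$truth$fixed[names(cls)[cls == cc]],
                                      nrow, 0L))
  rows <- list()
  add <- function(parameter, truth, estimate, tol, absolute = FALSE) {
    err <- if (absolute) abs(estimate - truth)
           else if (truth != 0) abs(estimate - truth) / truth
           else abs(estimate)
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = parameter, truth = truth, estimate = estimate,
      rel_error = err, tolerance = tol, pass = err <= tol)
  }
  # autosomal divergence against the realized truth rate
  auto_len <- len_of("autosome")
  if (auto_len > 0) {
    truth_alpha <- fixed_of("autosome") / auto_len
    add("alpha_auto", truth_alpha, .class_alpha(run$divergence, "autosome"),
        tolerances$alpha)
  }
  # autosome:X ratio
  x_len <- len_of("X")
  if (auto_len > 0 && x_len > 0) {
    truth_ratio <- (fixed_of("autosome") / auto_len) / (fixed_of("X") / x_len)
    est_ratio <- .class_alpha(run$divergence, "autosome") /
      .class_alpha(run$divergence, "X")
    add("autosome_X_ratio", truth_ratio, est_ratio, tolerances$ratio)
  }
  # polymorphism on autosomes
  auto_ctgs <- names(cls)[cls == "autosome"]
  callable <- sum(vapply(run$site_classes[auto_ctgs],
                         function(x) sum(x != 0L), 0))
  snps <- sum(vapply(run$site_classes[auto_ctgs],
                     function(x) sum(x == 3L), 0))
  n_chrom <- 2L * nrow(config$individuals)
  p_seg <- 1 - .p_monomorphic(n_chrom, config$afs)
  pi_hat <- if (callable > 0) (snps / callable) / p_seg else NA_real_
  add("pi_query", config$pi_query, pi_hat, tolerances$pi)
  # sequencing error from hemizygous Y sites
  if (!is.null(run$y)) {
    add("epsilon", config$epsilon,
        run$y$error_rates[[1L]]$per_base_mismatch_rate, tolerances$epsilon)
  }
  # Ti/Tv against the kernel expectation kappa/2
  if (!is.null(run$titv_snp)) {
    add("titv", config$kappa / 2, run$titv_snp$ratio, tolerances$titv,
        absolute = TRUE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("recovery_table", "data.frame"),
            run = run, dataset = dataset)
}

#' @export
print.recovery_table <- function(x, ...) {
  cat("parameter recovery\n")
  df <- as.data.frame(x)
  df$truth <- signif(df$truth, 5)
  df$estimate <- signif(df$estimate, 5)
  df$rel_error <- signif(df$rel_error, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Precision and recall of fixed-difference calls against simulator truth
#'
#' Precision is the fraction of called fixed differences whose position and
#' allele match the truth ledger. Recall is measured over truth sites at
#' callable positions: the filter stack excludes homopolymer context and
#' low-coverage sites by design (divergence-neutral exclusions), so sites it
#' never admits are not recall failures of the caller.
#'
#' @param dataset the `sim_dataset` that produced the run.
#' @param run the corresponding `divrun`.
#' @return list with `precision`, `recall`, `called`, `truth_callable`.
#' @export
fixed_difference_metrics <- function(dataset, run) {
  tp <- 0L; called <- 0L; truth_callable <- 0L
  for (nm in names(run$site_classes)) {
    cls <- run$site_classes[[nm]]
    truth <- dataset$truth$fixed[[nm]]
    is_fix <- cls == 2L
    called <- called + sum(is_fix)
    if (is.null(truth) || !nrow(truth)) next
    t_call <- truth$pos[cls[truth$pos] != 0L]
    truth_callable <- truth_callable + length(t_call)
    tp <- tp + sum(is_fix[t_call])
  }
  list(precision = if (called > 0L) tp / called else NA_real_,
       recall = if (truth_callable > 0L) tp / truth_callable else NA_real_,
       called = called, truth_callable = truth_callable)
}
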