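# Synthetic two-species dataset generator.
#
# Evolution is mutation-only on a shared coordinate system: an ancestor is
# drawn, the reference species keeps the ancestral state and the query
# lineage accrues all divergence (only the pairwise difference is observable,
# so placing it on one branch is equivalent and keeps the truth ledger
# simple).  Individuals of the query species carry planted polymorphism;
# pileups are emitted directly on the reference coordinates (no reads, no
# indels), with per-base error inflated inside and adjacent to reference
# homopolymer runs to mimic flow-based (semiconductor) sequencing chemistry.

#' Simulation configuration
#'
#' @param seed master seed; every stage derives its own substream from it.
#' @param contigs data.frame with columns `name`, `length`, `chrom_class`.
#' @param alpha_auto per-site divergence rate on autosomes (default 0.0067,
#'   the scale observed between closely related equids).
#' @param alpha_X_ratio X-to-autosome divergence multiplier (default 0.5,
#'   i.e. a 2:1 autosome:X ratio).
#' @param alpha_Y_ratio Y multiplier (default 1.5; male-driven mutation).
#' @param kappa transition/transversion bias of the mutation kernel: a
#'   mutation is a transition with probability `kappa/(kappa+2)` and each of
#'   the two transversions with probability `1/(kappa+2)`, so the expected
#'   Ti/Tv ratio is `kappa/2` (default 4, giving Ti/Tv = 2).
#' @param pi_query per-site probability that a site is polymorphic within the
#'   query species (default 0.001).
#' @param individuals data.frame with columns `id`, `sex` ("M"/"F") and
#'   `depth_mean` (per-individual mean sequencing depth).
#' @param epsilon per-base sequencing error probability (default 0.001).
#' @param homopolymer_error_boost multiplicative increase of `epsilon` at
#'   positions inside or within `homopolymer_adjacency` bp of a reference
#'   homopolymer run of length >= `homopolymer_min_len` (default 20).
#' @param homopolymer_min_len,homopolymer_adjacency homopolymer-context
#'   definition shared with the filter stack (defaults 4 and 1).
#' @param mq_mean,mq_sd per-read mapping quality distribution (normal, clipped
#'   to \[0, 60\]); defaults 45 and 5.
#' @param hp_plant_rate optional homopolymer-enrichment mode: expected number
#'   of planted runs (length 4-8) per kb of ancestor (default 0 = off).
#' @param afs allele-frequency spectrum for planted polymorphisms:
#'   `"uniform"` over \{1/2n, ..., (2n-1)/2n\} or `"neutral"` (probability
#'   proportional to 1/i for i derived copies).
#' @return validated object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       contigs = data.frame(name = "chr1", length = 1e6L,
                                            chrom_class = "autosome"),
                       alpha_auto = 0.0067,
                       alpha_X_ratio = 0.5,
                       alpha_Y_ratio = 1.5,
                       kappa = 4,
                       pi_query = 0.001,
                       individuals = data.frame(id = c("ind1", "ind2", "ind3"),
                                                sex = c("M", "M", "M"),
                                                depth_mean = c(12, 12, 8)),
                       epsilon = 0.001,
                       homopolymer_error_boost = 20,
                       homopolymer_min_len = 4L,
                       homopolymer_adjacency = 1L,
                       mq_mean = 45,
                       mq_sd = 5,
                       hp_plant_rate = 0,
                       afs = c("uniform", "neutral")) {
  afs <- match.arg(afs)
  rates <- c(alpha_auto, pi_query, epsilon)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (kappa <= 0) stop("kappa must be positive")
  if (any(individuals$depth_mean < 1)) stop("depth_mean must be >= 1")
  if (any(contigs$length <= 0)) stop("zero-length contig")
  assert_chrom_class(contigs$chrom_class)
  if (!all(individuals$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  structure(list(seed = as.integer(seed), contigs = contigs,
                 alpha_auto = alpha_auto, alpha_X_ratio = alpha_X_ratio,
                 alpha_Y_ratio = alpha_Y_ratio, kappa = kappa,
                 pi_query = pi_query, individuals = individuals,
                 epsilon = epsilon,
                 homopolymer_error_boost = homopolymer_error_boost,
                 homopolymer_min_len = as.integer(homopolymer_min_len),
                 homopolymer_adjacency = as.integer(homopolymer_adjacency),
                 mq_mean = mq_mean, mq_sd = mq_sd,
                 hp_plant_rate = hp_plant_rate, afs = afs),
            class = "sim_config")
}

.alpha_for_class <- function(config, chrom_class) {
  mult <- switch(chrom_class,
                 autosome = 1, unplaced = 1,
                 X = config$alpha_X_ratio,
                 Y = config$alpha_Y_ratio)
  config$alpha_auto * mult
}

.ploidy_for <- function(chrom_class, sex) {
  switch(chrom_class,
         autosome = rep(2L, length(sex)),
         unplaced = rep(2L, length(sex)),
         X = ifelse(sex == "M", 1L, 2L),
         Y = ifelse(sex == "M", 1L, 0L))
}

# kappa-biased substitution kernel; `base` integer codes, returns mutated codes
.mutate_kernel <- function(base, kappa) {
  n <- length(base)
  if (!n) return(integer(0))
  ti_partner <- c(3L, 4L, 1L, 2L)   # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L)          # first transversion partner (alphabetical)
  tv2 <- c(4L, 3L, 4L, 3L)
  u <- stats::runif(n)
  p_ti <- kappa / (kappa + 2)
  out <- ti_partner[base]
  tv <- u >= p_ti
  second <- u >= p_ti + (1 - p_ti) / 2
  out[tv] <- tv1[base[tv]]
  out[tv & second] <- tv2[base[tv & second]]
  out
}

#' Draw an ancestral genome
#'
#' Bases are i.i.d. uniform over A/C/G/T. With `hp_plant_rate > 0`, runs of
#' length 4-8 of a single base are additionally planted at that expected rate
#' per kb (Poisson number, uniform positions) to enrich homopolymer context.
#' Deterministic under the configuration seed.
#'
#' @param config a [sim_config()].
#' @return `genome` object with `chrom_class` taken from the contig plan;
#'   attribute `planted_runs` counts planted homopolymers.
#' @export
simulate_ancestor <- function(config) {
  set.seed(substream_seed(config$seed, "ancestor"))
  planted <- 0L
  contigs <- lapply(seq_len(nrow(config$contigs)), function(i) {
    L <- as.integer(config$contigs$length[i])
    s <- sample.int(4L, L, replace = TRUE)
    if (config$hp_plant_rate > 0) {
      n_runs <- stats::rpois(1L, config$hp_plant_rate * L / 1000)
      if (n_runs > 0L) {
        starts <- sample.int(L, n_runs, replace = TRUE)
        lens <- sample(4:8, n_runs, replace = TRUE)
        bases <- sample.int(4L, n_runs, replace = TRUE)
        for (k in seq_len(n_runs)) {
          e <- min(L, starts[k] + lens[k] - 1L)
          s[starts[k]:e] <- bases[k]
        }
        planted <<- planted + n_runs
      }
    }
    genome_sequence(config$contigs$name[i], s, config$contigs$chrom_class[i])
  })
  names(contigs) <- config$contigs$name
  structure(contigs, class = "genome", planted_runs = planted)
}

#' Diverge two species from an ancestor
#'
#' Each site mutates independently with probability
#' `alpha_auto * class multiplier`; the substitution is drawn from the
#' kappa-biased kernel. The reference species keeps the ancestral state and
#' the query lineage carries the divergence, so the truth ledger of fixed
#' interspecies differences is exactly the mutated site set.
#'
#' @param ancestor `genome` from [simulate_ancestor()].
#' @param config the same [sim_config()].
#' @return list with `reference`, `query` (both `genome`) and `truth`, whose
#'   `fixed` element maps contig name to a data.frame `pos`, `anc`, `derived`
#'   (integer-coded alleles).
#' @export
speciate <- function(ancestor, config) {
  set.seed(substream_seed(config$seed, "speciate"))
  query <- ancestor
  fixed <- list()
  for (nm in names(ancestor)) {
    ct <- ancestor[[nm]]
    rate <- .alpha_for_class(config, ct$chrom_class)
    hit <- if (rate > 0) which(stats::runif(ct$length) < rate) else integer(0)
    anc <- ct$seq[hit]
    derived <- .mutate_kernel(anc, config$kappa)
    query[[nm]]$seq[hit] <- derived
    fixed[[nm]] <- data.frame(pos = hit, anc = anc, derived = derived)
  }
  list(reference = ancestor, query = query,
       truth = list(fixed = fixed))
}

#' Plant within-species polymorphism and assign genotypes
#'
#' Sites become polymorphic with probability `pi_query` (fixed interspecies
#' differences are excluded so the two truth classes stay disjoint). The
#' derived allele frequency is drawn from the configured spectrum over the
#' total chromosome count carried by the cohort at that contig class, and
#' each individual's derived-allele dose is binomial in its ploidy. Males are
#' haploid on Y and hemizygous (single copy) on X; females carry no Y.
#'
#' @param query query-species `genome` from [speciate()].
#' @param config the [sim_config()].
#' @return object of class `sim_cohort`: per contig a list with `ploidy` (per
#'   individual), `poly` (data.frame `pos`, `anc`, `derived`, `freq`) and
#'   `geno` (site x individual matrix of derived-allele counts).
#' @export
sample_individuals <- function(query, config) {
  set.seed(substream_seed(config$seed, "individuals"))
  ind <- config$individuals
  contigs <- list()
  for (nm in names(query)) {
    ct <- query[[nm]]
    ploidy <- .ploidy_for(ct$chrom_class, ind$sex)
    n_chrom <- sum(ploidy)
    if (n_chrom < 2L || config$pi_query <= 0) {
      contigs[[nm]] <- list(
        ploidy = ploidy,
        poly = data.frame(pos = integer(0), anc = integer(0),
                          derived = integer(0), freq = numeric(0)),
        geno = matrix(0L, 0L, nrow(ind)))
      next
    }
    hit <- which(stats::runif(ct$length) < config$pi_query)
    # keep fixed/polymorphic truth classes disjoint
    fixed_here <- attr(query, "fixed_pos")[[nm]]
    if (!is.null(fixed_here)) hit <- setdiff(hit, fixed_here)
    m <- length(hit)
    anc <- ct$seq[hit]
    derived <- .mutate_kernel(anc, config$kappa)
    i_grid <- seq_len(n_chrom - 1L)
    w <- if (config$afs == "uniform") rep(1, length(i_grid)) else 1 / i_grid
    copies <- sample(i_grid, m, replace = TRUE, prob = w)
    p <- copies / n_chrom
    geno <- matrix(0L, m, nrow(ind))
    for (j in seq_len(nrow(ind))) {
      if (ploidy[j] > 0L) geno[, j] <- stats::rbinom(m, ploidy[j], p)
    }
    contigs[[nm]] <- list(ploidy = ploidy,
                          poly = data.frame(pos = hit, anc = anc,
                                            derived = derived, freq = p),
                          geno = geno)
  }
  structure(list(individuals = ind, contigs = contigs), class = "sim_cohort")
}

# logical mask of positions inside or within `slack` bp of a homopolymer run
homopolymer_mask <- function(seq_int, min_len = 4L, slack = 1L) {
  runs <- find_homopolymer_runs(seq_int, min_len)
  mask <- logical(length(seq_int))
  if (nrow(runs)) {
    s <- pmax(1L, runs[, 1L] - slack)
    e <- pmin(length(seq_int), runs[, 2L] + slack)
    for (k in seq_len(nrow(runs))) mask[s[k]:e[k]] <- TRUE
  }
  mask
}

#' Emit per-site pileup evidence for a cohort
#'
#' For every individual with non-zero ploidy on a contig, site depth is
#' Poisson(`depth_mean`); heterozygous sites contribute each allele with a
#' fair coin per read; every emitted base flips to one of the three other
#' bases with probability `epsilon`, multiplied by `homopolymer_error_boost`
#' inside/adjacent to reference homopolymer runs. Per-read mapping qualities
#' are normal draws clipped to \[0, 60\], retained as the per-site RMS.
#' The truth ledger records emitted and erroneous base counts.
#'
#' @param cohort from [sample_individuals()].
#' @param reference reference-species `genome` (pileup coordinate system).
#' @param query query-species `genome`.
#' @param config the [sim_config()].
#' @param chunk positions processed per block (memory control).
#' @return list of per-contig `pileup_matrix` objects plus `truth_errors`:
#'   each `pileup_matrix` has `contig`, `chrom_class`, `ref` (integer codes)
#'   and `samples`, a named list with `counts` (L x 4 integer), `depth`,
#'   `mq_rms` per individual.
#' @export
emit_pileup <- function(cohort, reference, query, config, chunk = 2e6L) {
  set.seed(substream_seed(config$seed, "emit"))
  ind <- cohort$individuals
  out <- list()
  err_total <- 0; base_total <- 0; err_expect_w <- 0
  for (nm in names(reference)) {
    refct <- reference[[nm]]
    L <- refct$length
    hp <- homopolymer_mask(refct$seq, config$homopolymer_min_len,
                           config$homopolymer_adjacency)
    eps_site <- pmin(1, config$epsilon *
                       ifelse(hp, config$homopolymer_error_boost, 1))
    cinfo <- cohort$contigs[[nm]]
    samples <- list()
    for (j in seq_len(nrow(ind))) {
      if (cinfo$ploidy[j] == 0L) next
      res <- .emit_sample(query[[nm]]$seq, cinfo, j, eps_site,
                          ind$depth_mean[j], config, chunk)
      err_total <- err_total + res$errors
      base_total <- base_total + res$bases
      err_expect_w <- err_expect_w + sum(res$depth * eps_site)
      samples[[ind$id[j]]] <- list(counts = res$counts, depth = res$depth,
                                   mq_rms = res$mq_rms)
    }
    out[[nm]] <- structure(list(contig = nm, chrom_class = refct$chrom_class,
                                ref = refct$seq, samples = samples),
                           class = "pileup_matrix")
  }
  list(pileups = out,
       truth_errors = list(errors = err_total, bases = base_total,
                           realized_epsilon = if (base_total > 0) err_total / base_total else 0,
                           expected_epsilon = if (base_total > 0) err_expect_w / base_total else 0))
}

.emit_sample <- function(qseq, cinfo, j, eps_site, depth_mean, config, chunk) {
  L <- length(qseq)
  ploidy <- cinfo$ploidy[j]
  g <- integer(L)                      # derived-allele dose per site
  derived_at <- integer(L)
  if (nrow(cinfo$poly)) {
    g[cinfo$poly$pos] <- cinfo$geno[, j]
    derived_at[cinfo$poly$pos] <- cinfo$poly$derived
  }
  counts <- matrix(0L, L, 4L)
  depth_all <- integer(L)
  mq_rms <- numeric(L)
  errors <- 0
  for (lo in seq(1L, L, by = chunk)) {
    hi <- min(L, lo + chunk - 1L)
    idx <- lo:hi
    Lc <- length(idx)
    d <- stats::rpois(Lc, depth_mean)
    allele_a <- qseq[idx]
    gi <- g[idx]
    hom_derived <- gi == ploidy & gi > 0L
    allele_a[hom_derived] <- derived_at[idx][hom_derived]
    het <- which(gi > 0L & gi < ploidy)
    reads_b <- integer(Lc)
    if (length(het)) reads_b[het] <- stats::rbinom(length(het), d[het], 0.5)
    reads_a <- d - reads_b
    eps <- eps_site[idx]
    err_a <- stats::rbinom(Lc, reads_a, eps)
    err_b <- integer(Lc)
    if (length(het)) err_b[het] <- stats::rbinom(length(het), reads_b[het], eps[het])
    counts[cbind(idx, allele_a)] <- reads_a - err_a
    if (length(het)) {
      ab <- derived_at[idx][het]
      counts[cbind(idx[het], ab)] <- counts[cbind(idx[het], ab)] +
        reads_b[het] - err_b[het]
    }
    # distribute erroneous reads uniformly over the three non-source bases
    n_err <- sum(err_a) + sum(err_b)
    errors <- errors + n_err
    if (n_err > 0L) {
      src_site <- c(rep.int(seq_len(Lc), err_a),
                    rep.int(het, err_b[het]))
      src_base <- c(rep.int(allele_a, err_a),
                    rep.int(derived_at[idx][het], err_b[het]))
      off <- sample.int(3L, n_err, replace = TRUE)
      tgt <- off + (off >= src_base)
      key <- (tgt - 1L) * Lc + src_site
      counts[idx, ] <- counts[idx, ] + matrix(tabulate(key, 4L * Lc), Lc, 4L)
    }
    depth_all[idx] <- d
    # per-read mapping qualities -> site RMS (reads lie consecutively per
    # site, so grouped sums of squares reduce to differenced cumsums)
    n_reads <- sum(d)
    if (n_reads > 0L) {
      mq <- stats::rnorm(n_reads, config$mq_mean, config$mq_sd)
      mq[mq < 0] <- 0
      mq[mq > 60] <- 60
      cs <- cumsum(mq * mq)
      ends <- cumsum(d)
      vals <- numeric(Lc)
      nz <- ends > 0L
      vals[nz] <- cs[ends[nz]]
      ss <- vals - c(0, vals[-Lc])
      mq_rms[idx] <- sqrt(ss / pmax(d, 1L))
    }
  }
  list(counts = counts, depth = depth_all, mq_rms = mq_rms,
       errors = errors, bases = sum(as.numeric(depth_all)))
}

#' Materialize a pileup_matrix region as parseable pileup text records
#'
#' Expands count-form evidence at selected positions into per-read base /
#' quality / mapping-quality strings (the text dialect read by
#' [read_pileup()]). Base qualities are drawn uniformly in 25-38; per-read
#' mapping-quality characters encode the site RMS so that RMS round-trips.
#'
#' @param pm a `pileup_matrix`.
#' @param positions positions to emit (default all covered).
#' @param seed seed for the quality draws.
#' @return a `pileup` object suitable for [write_pileup()].
#' @export
pileup_matrix_to_sites <- function(pm, positions = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(positions)) {
    covered <- Reduce(`+`, lapply(pm$samples, `[[`, "depth"))
    positions <- which(covered > 0L)
  }
  positions <- sort(positions)
  n <- length(positions)
  samples <- lapply(pm$samples, function(sm) {
    bases <- vector("list", n); bq <- vector("list", n); mq <- vector("list", n)
    for (i in seq_len(n)) {
      p <- positions[i]
      cnt <- sm$counts[p, ]
      b <- rep.int(1:4, cnt)
      if (length(b) > 1L) b <- sample(b)      # shuffle read order
      bases[[i]] <- b
      bq[[i]] <- sample(25:38, length(b), replace = TRUE)
      mq[[i]] <- rep.int(as.integer(round(sm$mq_rms[p])), length(b))
    }
    list(bases = bases, bq = bq, mq = mq)
  })
  structure(list(chrom = rep(pm$contig, n), pos = positions,
                 ref = pm$ref[positions], samples = samples),
            class = "pileup")
}

# ---------------------------------------------------------------------------
# in-silico reduced-representation digestion
# ---------------------------------------------------------------------------

.enzyme_catalog <- list(
  AluI = list(site = "AGCT", offset = 2L),
  RsaI = list(site = "GTAC", offset = 2L)
)

#' In-silico restriction digest with fragment size selection
#'
#' One library per enzyme: each contig is cut at every recognition-site
#' occurrence (blunt cut after `offset` bases of the site), terminal
#' fragments included, and fragments with length inside `size_range`
#' (inclusive) are retained. The capture report gives the retained fraction
#' of the genome and, when a truth ledger of polymorphic sites is supplied,
#' the fraction of those sites falling inside retained fragments (per enzyme
#' and for the union of libraries).
#'
#' @param genome a `genome` object.
#' @param enzymes enzyme names from the catalog (AluI = AG^CT, RsaI = GT^AC).
#' @param size_range retained fragment length range, 1-based inclusive bp.
#' @param truth_poly optional named list (per contig) of polymorphic-site
#'   positions.
#' @return list with `fragments` (data.frame: enzyme, contig, start, end,
#'   length, retained) and `report` (per-enzyme and union capture fractions).
#' @export
digest_rrl <- function(genome, enzymes = c("AluI", "RsaI"),
                       size_range = c(200L, 400L), truth_poly = NULL) {
  unknown <- setdiff(enzymes, names(.enzyme_catalog))
  if (length(unknown)) {
    stop("unknown enzyme(s): ", paste(unknown, collapse = ", "),
         "; catalog: ", paste(names(.enzyme_catalog), collapse = ", "))
  }
  total_bp <- sum(vapply(genome, `[[`, 0L, "length"))
  frag_list <- list()
  for (enz in enzymes) {
    spec <- .enzyme_catalog[[enz]]
    pat <- dna_to_int(spec$site)
    w <- length(pat)
    for (ct in genome) {
      s <- ct$seq
      L <- ct$length
      if (L >= w) {
        m <- s[1:(L - w + 1L)] == pat[1L]
        for (k in 2:w) m <- m & s[k:(L - w + k)] == pat[k]
        starts <- which(m)
      } else starts <- integer(0)
      cuts <- starts + spec$offset - 1L        # cut between cuts and cuts+1
      cuts <- cuts[cuts >= 1L & cuts < L]
      fs <- c(1L, cuts + 1L)
      fe <- c(cuts, L)
      len <- fe - fs + 1L
      frag_list[[length(frag_list) + 1L]] <- data.frame(
        enzyme = enz, contig = ct$name, start = fs, end = fe, length = len,
        retained = len >= size_range[1L] & len <= size_range[2L])
    }
  }
  fragments <- do.call(rbind, frag_list)
  report <- list()
  for (enz in enzymes) {
    fr <- fragments[fragments$enzyme == enz & fragments$retained, , drop = FALSE]
    report[[enz]] <- list(retained_bp = sum(fr$length),
                          retained_fraction = sum(fr$length) / total_bp)
  }
  if (!is.null(truth_poly)) {
    inside <- function(fr) {
      hit <- 0L; tot <- 0L
      for (nm in names(truth_poly)) {
        pos <- truth_poly[[nm]]
        tot <- tot + length(pos)
        f <- fr[fr$contig == nm, , drop = FALSE]
        if (nrow(f) && length(pos)) {
          ov <- IRanges::findOverlaps(
            IRanges::IRanges(pos, pos),
            IRanges::IRanges(f$start, f$end))
          hit <- hit + length(unique(S4Vectors::queryHits(ov)))
        }
      }
      if (tot > 0L) hit / tot else NA_real_
    }
    for (enz in enzymes) {
      fr <- fragments[fragments$enzyme == enz & fragments$retained, , drop = FALSE]
      report[[enz]]$poly_capture <- inside(fr)
    }
    report$union <- list(poly_capture = inside(fragments[fragments$retained, , drop = FALSE]))
  }
  list(fragments = fragments, report = report)
}

# ---------------------------------------------------------------------------
# one-call dataset simulation
# ---------------------------------------------------------------------------

#' Simulate a complete two-species dataset with truth ledger
#'
#' Chains [simulate_ancestor()], [speciate()], [sample_individuals()] and
#' [emit_pileup()]; fully deterministic given the configuration (all
#' randomness flows from named substreams of `config$seed`).
#'
#' @param config a [sim_config()].
#' @return object of class `sim_dataset`: `reference`, `query` (genomes),
#'   `cohort`, `pileups` (per-contig `pileup_matrix`), `assignments`
#'   (scaffold table), and `truth` with `fixed`, `poly`, error bookkeeping.
#' @export
simulate_dataset <- function(config) {
  anc <- simulate_ancestor(config)
  sp <- speciate(anc, config)
  # pass fixed positions so polymorphism planting can avoid them
  attr(sp$query, "fixed_pos") <- lapply(sp$truth$fixed, `[[`, "pos")
  cohort <- sample_individuals(sp$query, config)
  em <- emit_pileup(cohort, sp$reference, sp$query, config)
  assignments <- data.frame(
    contig = config$contigs$name,
    chrom_class = config$contigs$chrom_class,
    also_matches_X = FALSE)
  truth <- list(fixed = sp$truth$fixed,
                poly = lapply(cohort$contigs, `[[`, "poly"),
                geno = lapply(cohort$contigs, `[[`, "geno"),
                ploidy = lapply(cohort$contigs, `[[`, "ploidy"),
                errors = em$truth_errors)
  structure(list(config = config, reference = sp$reference, query = sp$query,
                 cohort = cohort, pileups = em$pileups,
                 assignments = assignments, truth = truth),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  nfix <- sum(vapply(x$truth$fixed, nrow, 0L))
  npoly <- sum(vapply(x$truth$poly, nrow, 0L))
  cat("sim_dataset:", length(x$reference), "contig(s),",
      format(sum(vapply(x$reference, `[[`, 0L, "length")), big.mark = ","),
      "bp,", nrow(x$config$individuals), "individual(s)\n")
  cat("  truth: ", format(nfix, big.mark = ","), " fixed differences, ",
      format(npoly, big.mark = ","), " polymorphic sites, realized error ",
      signif(x$truth$errors$realized_epsilon, 4), "\n", sep = "")
  invisible(x)
}
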