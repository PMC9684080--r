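## Synthetic multi-region gland cohort generator.
##
## Emulates the sampling design of a spatial single-gland multi-omic study of
## colorectal tumours: four spatially separated tumour regions (A-D) plus one
## distant normal region (E) per patient, several individual glands per
## region, per-gland tumour purity, clonal/subclonal SNVs in copy-number
## context, negative-binomial ATAC peak counts with planted accessibility
## alterations, TF-site fragment profiles with planted footprint changes,
## binned low-pass coverage ratios, and signature-mixed mutation catalogues.
## Every planted effect is recorded in a ground-truth object keyed by stable
## identifiers so downstream recovery can be scored exactly.

TUMOUR_REGIONS <- c("A", "B", "C", "D")
NORMAL_REGION <- "E"

#' Configuration for a synthetic gland cohort
#'
#' @param n_patients Number of patients.
#' @param regions_per_tumour Number of spatially distinct tumour regions per
#'   patient (labelled A, B, ...; a normal region E is always added).
#' @param glands_per_region Glands sampled per region (>= 2, so that samples
#'   from a region can serve as biological replicates in the subclonality
#'   test).
#' @param purity_range Interval in `[0, 1]` from which tumour-gland purity is
#'   drawn uniformly. Normal glands always have purity 0.
#' @param purity_values Optional explicit purity values assigned to tumour
#'   glands in order (recycled); overrides `purity_range`.
#' @param sequencing_depth Mean read depth per SNV site.
#' @param peak_count Number of ATAC peaks to simulate.
#' @param scaa_fraction Fraction of peaks with a planted somatic
#'   accessibility alteration.
#' @param subclonal_fraction Fraction of planted alterations confined to a
#'   subset of tumour regions.
#' @param gain_effect,loss_effect Multiplicative accessibility effect of
#'   planted gains (> 1) and losses (< 1).
#' @param nb_dispersion Negative-binomial dispersion of peak counts (> 0).
#' @param ploidy Optional integer tumour ploidy per patient (recycled);
#'   default draws from {2, 3}.
#' @param seed Integer seed; all stages derive child seeds from it via
#'   [stage_seed()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 6,
                          regions_per_tumour = 4,
                          glands_per_region = 4,
                          purity_range = c(0.3, 0.95),
                          purity_values = NULL,
                          sequencing_depth = 30,
                          peak_count = 2000,
                          scaa_fraction = 0.1,
                          subclonal_fraction = 0.25,
                          gain_effect = 3,
                          loss_effect = 1 / 3,
                          nb_dispersion = 0.05,
                          ploidy = NULL,
                          seed = 1L) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid cohort configuration: field '%s' %s", field, msg), call. = FALSE)
  }
  chk(is.numeric(n_patients) && n_patients >= 1, "n_patients", "must be >= 1")
  chk(is.numeric(regions_per_tumour) && regions_per_tumour >= 1 &&
        regions_per_tumour <= length(TUMOUR_REGIONS),
      "regions_per_tumour", "must be in 1..4")
  chk(is.numeric(glands_per_region) && glands_per_region >= 2,
      "glands_per_region", "must be >= 2 (biological replicates)")
  chk(length(purity_range) == 2 && all(purity_range >= 0) && all(purity_range <= 1) &&
        purity_range[1] <= purity_range[2],
      "purity_range", "must be an interval within [0, 1]")
  chk(is.numeric(sequencing_depth) && sequencing_depth > 0, "sequencing_depth", "must be > 0")
  chk(is.numeric(peak_count) && peak_count >= 1, "peak_count", "must be >= 1")
  chk(scaa_fraction >= 0 && scaa_fraction <= 1, "scaa_fraction", "must be in [0, 1]")
  chk(subclonal_fraction >= 0 && subclonal_fraction <= 1,
      "subclonal_fraction", "must be in [0, 1]")
  chk(nb_dispersion > 0, "nb_dispersion", "must be > 0")
  chk(gain_effect > 1, "gain_effect", "must be > 1")
  chk(loss_effect > 0 && loss_effect < 1, "loss_effect", "must be in (0, 1)")
  if (!is.null(ploidy)) chk(all(ploidy == round(ploidy)) && all(ploidy >= 1),
                            "ploidy", "must be positive integers")
  structure(list(
    n_patients = as.integer(n_patients),
    regions_per_tumour = as.integer(regions_per_tumour),
    glands_per_region = as.integer(glands_per_region),
    purity_range = purity_range,
    purity_values = purity_values,
    sequencing_depth = sequencing_depth,
    peak_count = as.integer(peak_count),
    scaa_fraction = scaa_fraction,
    subclonal_fraction = subclonal_fraction,
    gain_effect = gain_effect,
    loss_effect = loss_effect,
    nb_dispersion = nb_dispersion,
    ploidy = ploidy,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' A small synthetic genome
#'
#' Named contigs with a fabricated TSS map, enhancer map, and trinucleotide
#' content table. Deliberately small so that all simulation stages run at
#' desk scale; no external reference is required.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bp.
#' @param tss_spacing Distance between fabricated transcription start sites.
#' @param seed Seed for strand assignment and enhancer placement.
#' @return List with `contigs` (named lengths), `tss` (data frame), and
#'   `enhancers` (data frame of intervals).
#' @export
synthetic_genome <- function(n_contigs = 5, contig_length = 1e7,
                             tss_spacing = 1e5, seed = 99L) {
  contigs <- stats::setNames(rep(contig_length, n_contigs),
                             paste0("chr", seq_len(n_contigs)))
  with_seed(seed, {
    tss <- do.call(rbind, lapply(names(contigs), function(ct) {
      pos <- seq(tss_spacing / 2, contigs[[ct]] - tss_spacing / 2, by = tss_spacing)
      data.frame(chrom = ct, pos = as.integer(pos),
                 strand = sample(c("+", "-"), length(pos), replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    tss$gene <- sprintf("G%04d", seq_len(nrow(tss)))
    ## enhancer map: intervals placed between TSSs, ~1 per 2 genes
    enh <- tss[sample.int(nrow(tss), nrow(tss) %/% 2), c("chrom", "pos")]
    enh$start <- as.integer(enh$pos + 20000)
    enh$end <- as.integer(enh$start + 5000)
    enh$pos <- NULL
    enh$enhancer_id <- sprintf("E%04d", seq_len(nrow(enh)))
    rownames(enh) <- NULL
    list(contigs = contigs, tss = tss, enhancers = enh)
  })
}

#' Fabricated trinucleotide content table
#'
#' Frequencies over the 32 pyrimidine-centred trinucleotide contexts. The
#' genome-wide table is deterministic; region-specific tables are obtained by
#' multiplicative perturbation so that region re-weighting of mutation
#' spectra is non-trivial but invertible.
#'
#' @param perturb Standard deviation of the multiplicative log-normal
#'   perturbation (0 gives the genome-wide table).
#' @param seed Seed for the perturbation.
#' @return Named numeric vector of length 32 summing to 1.
#' @export
synthetic_trinucleotide_content <- function(perturb = 0, seed = 7L) {
  ctx <- trinucleotide_contexts()
  base <- 1 + ((seq_along(ctx) * 7L) %% 13L) / 6.5
  f <- base / sum(base)
  if (perturb > 0) {
    f <- with_seed(seed, f * exp(stats::rnorm(length(f), 0, perturb)))
    f <- f / sum(f)
  }
  stats::setNames(f, ctx)
}

#' Simulate the sampling frame of a multi-region gland cohort
#'
#' Draws the per-gland purity, per-sample quality covariates, per-patient
#' tumour ploidy and a segment-constant copy-number landscape with shared
#' breakpoints across a patient's samples. Every patient carries at least two
#' aberrant segments, as colorectal cancer genomes are almost always
#' aneuploid to some degree.
#'
#' @param config A [cohort_config()] object.
#' @return Object of class `gland_cohort`: list with `samples` (data frame),
#'   `truth` (ground-truth list), `genome`, and `config`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("invalid cohort configuration: expected a 'cohort_config' object")
  }
  genome <- synthetic_genome()
  regions <- c(TUMOUR_REGIONS[seq_len(config$regions_per_tumour)], NORMAL_REGION)
  patients <- sprintf("P%02d", seq_len(config$n_patients))

  with_seed(stage_seed(config$seed, "cohort"), {
    samples <- expand.grid(gland = seq_len(config$glands_per_region),
                           region = regions, patient = patients,
                           stringsAsFactors = FALSE)
    samples <- samples[, c("patient", "region", "gland")]
    samples$sample <- sprintf("%s_%s_G%d", samples$patient, samples$region, samples$gland)
    tumour <- samples$region != NORMAL_REGION
    rho <- numeric(nrow(samples))
    if (!is.null(config$purity_values)) {
      rho[tumour] <- rep_len(config$purity_values, sum(tumour))
    } else {
      rho[tumour] <- stats::runif(sum(tumour), config$purity_range[1], config$purity_range[2])
    }
    samples$purity <- rho
    samples$tsse <- pmax(3, stats::rnorm(nrow(samples), 8, 1.2))
    samples$tsse_nf <- pmax(3, samples$tsse + stats::rnorm(nrow(samples), 1, 0.6))
    samples$total_reads <- as.integer(round(stats::runif(nrow(samples), 5e5, 2e6)))

    ploidy <- if (!is.null(config$ploidy)) {
      rep_len(as.integer(config$ploidy), config$n_patients)
    } else {
      sample(c(2L, 2L, 3L), config$n_patients, replace = TRUE)
    }
    names(ploidy) <- patients

    ## copy-number truth: segment-constant per patient, shared breakpoints
    bin_size <- 5e5
    segs <- do.call(rbind, lapply(patients, function(p) {
      psi <- ploidy[[p]]
      out <- do.call(rbind, lapply(names(genome$contigs), function(ct) {
        n_bins <- genome$contigs[[ct]] %/% bin_size
        n_seg <- sample(1:3, 1)
        ## breakpoints at least 4 bins (2 Mb) apart: copy-number events in
        ## colorectal cancer are typically chromosome-arm scale
        min_len <- 4L
        bks <- integer(0)
        if (n_seg > 1) {
          cand <- seq(min_len, n_bins - min_len)
          for (b in sort(sample(cand, n_seg - 1))) {
            if (!length(bks) || b - bks[length(bks)] >= min_len) bks <- c(bks, b)
          }
        }
        n_seg <- length(bks) + 1L
        starts <- c(1L, bks + 1L)
        ends <- c(bks, n_bins)
        state <- ifelse(stats::runif(n_seg) < 0.6, psi,
                        pmax(1L, psi + sample(c(-1L, 1L, 2L), n_seg, replace = TRUE)))
        data.frame(patient = p, contig = ct,
                   start = as.integer((starts - 1L) * bin_size),
                   end = as.integer(ends * bin_size),
                   state = as.integer(state), stringsAsFactors = FALSE)
      }))
      ## guarantee at least two aberrant segments per tumour genome
      ab <- which(out$state != psi)
      if (length(ab) < 2) {
        fix <- sample(setdiff(seq_len(nrow(out)), ab), 2 - length(ab))
        out$state[fix] <- psi + sample(c(-1L, 1L), length(fix), replace = TRUE)
        out$state <- pmax(1L, out$state)
      }
      ## keep the nominal ploidy the clear modal state (>= 60% of bins):
      ## ploidy is measured genome-wide by deep WGS, so a genome dominated
      ## by aberrant segments would contradict its own ploidy call
      repeat {
        w <- out$end - out$start
        ab <- which(out$state != psi)
        if (sum(w[ab]) / sum(w) <= 0.4 || length(ab) <= 2) break
        out$state[ab[which.max(w[ab])]] <- psi
      }
      ## ensure at least one single-copy (+/-1) event: genomes whose only
      ## deviations are +2 are aliased in purity/ploidy space (a +2 state at
      ## purity rho fits exactly as +1 at higher purity), and real
      ## colorectal genomes essentially always carry single-copy arm events
      ab <- which(out$state != psi)
      if (!any(abs(out$state[ab] - psi) == 1)) {
        out$state[ab[1]] <- psi + sample(c(-1L, 1L), 1)
        out$state <- pmax(1L, out$state)
      }
      out
    }))
    segs$segment_id <- sprintf("%s_%s_%d", segs$patient, segs$contig,
                               stats::ave(seq_len(nrow(segs)),
                                          paste(segs$patient, segs$contig),
                                          FUN = seq_along))

    truth <- list(
      purity = stats::setNames(samples$purity, samples$sample),
      ploidy = ploidy,
      segments = segs,
      bin_size = bin_size
    )
    structure(list(samples = samples, truth = truth, genome = genome,
                   config = config),
              class = "gland_cohort")
  })
}

#' @export
print.gland_cohort <- function(x, ...) {
  cat(sprintf("synthetic gland cohort: %d patients, %d samples (%d tumour regions + normal)\n",
              x$config$n_patients, nrow(x$samples), x$config$regions_per_tumour))
  invisible(x)
}

## internal: copy-number state of the patient's genome at given positions
segment_state_at <- function(segments, patient, chrom, pos) {
  out <- integer(length(pos))
  segs <- segments[segments$patient == patient, ]
  for (ct in unique(chrom)) {
    sel <- chrom == ct
    sct <- segs[segs$contig == ct, ]
    idx <- findInterval(pos[sel], sct$start)
    idx[idx < 1] <- 1L
    out[sel] <- sct$state[pmin(idx, nrow(sct))]
  }
  out
}

#' Simulate clonal SNV sites and per-sample allele counts in ATAC reads
#'
#' Sites are placed uniformly on the synthetic genome of each patient, with
#' total copy number taken from the patient's copy-number truth and
#' multiplicity drawn in `1..min(c, 2)`. The alternative-allele read count at
#' a site follows `Binomial(n, p)` with
#' `p = rho * m / (rho * c + 2 - 2 * rho)` and `n ~ Poisson(depth)` --- the
#' same binomial model the purity estimator inverts.
#'
#' @param cohort A `gland_cohort`.
#' @param n_sites Number of clonal SNV sites per patient.
#' @param depth Mean depth per site (default from the configuration).
#' @param subclonal_fraction Fraction of additional sites marked subclonal
#'   (restricted to a random subset of regions and excluded from purity
#'   estimation by downstream code).
#' @return Data frame with columns chrom, pos, ref, alt, sample, patient,
#'   ref_count, alt_count, multiplicity, copy_number, clonal_flag.
#' @export
simulate_allele_counts <- function(cohort, n_sites = 500,
                                   depth = cohort$config$sequencing_depth,
                                   subclonal_fraction = 0) {
  stopifnot(inherits(cohort, "gland_cohort"))
  if (depth <= 0) stop("invalid depth: must be > 0")
  genome <- cohort$genome
  bases <- c("A", "C", "G", "T")
  with_seed(stage_seed(cohort$config$seed, "alleles"), {
    out <- lapply(unique(cohort$samples$patient), function(p) {
      n_sub <- round(n_sites * subclonal_fraction)
      n_tot <- n_sites + n_sub
      chrom <- sample(names(genome$contigs), n_tot, replace = TRUE)
      pos <- as.integer(floor(stats::runif(n_tot, 1, genome$contigs[chrom])))
      cn <- segment_state_at(cohort$truth$segments, p, chrom, pos)
      cn <- pmax(cn, 1L)
      m <- vapply(cn, function(ci) sample.int(min(ci, 2L), 1L), integer(1))
      clonal <- rep(c(TRUE, FALSE), c(n_sites, n_sub))
      sub_regions <- sample(TUMOUR_REGIONS[seq_len(cohort$config$regions_per_tumour)],
                            max(1, cohort$config$regions_per_tumour %/% 2))
      ref <- sample(bases, n_tot, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
      smp <- cohort$samples[cohort$samples$patient == p, ]
      do.call(rbind, lapply(seq_len(nrow(smp)), function(i) {
        rho <- smp$purity[i]
        present <- clonal | smp$region[i] %in% sub_regions
        p_alt <- ifelse(present, rho * m / (rho * cn + 2 - 2 * rho), 0)
        n <- stats::rpois(n_tot, depth)
        k <- stats::rbinom(n_tot, n, p_alt)
        data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   sample = smp$sample[i], patient = p,
                   ref_count = n - k, alt_count = k,
                   multiplicity = m, copy_number = cn,
                   clonal_flag = clonal, stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, out)
  })
}

#' Simulate an ATAC peak table with planted accessibility alterations
#'
#' Peaks are annotated as promoter (placed at a fabricated TSS), enhancer
#' (inside the synthetic enhancer map) or other. A fraction of peaks carries
#' a planted gain or loss of accessibility in a subset of patients; a
#' fraction of those is subclonal, i.e. confined to a subset of tumour
#' regions. Counts are negative-binomial with mean
#' `sf * S_N * effect * (2(1-rho) + pi*rho) / (2(1-rho) + psi*rho)`,
#' where `pi` is the local copy number and `psi` the tumour ploidy, so that
#' copy-number alterations confound raw accessibility exactly as in real
#' data.
#'
#' @param cohort A `gland_cohort`.
#' @param affected_fraction_range Range of the fraction of patients affected
#'   by each planted alteration.
#' @return List of class `peak_table`: `peaks` (data frame), `counts`
#'   (matrix peaks x samples), `size_factors_true`, and `truth` (per-peak
#'   planted status).
#' @export
simulate_peak_counts <- function(cohort, affected_fraction_range = c(0.3, 0.8)) {
  stopifnot(inherits(cohort, "gland_cohort"))
  cfg <- cohort$config
  genome <- cohort$genome
  with_seed(stage_seed(cfg$seed, "peaks"), {
    n <- cfg$peak_count
    kind <- sample(c("promoter", "enhancer", "other"), n, replace = TRUE,
                   prob = c(0.4, 0.35, 0.25))
    width <- as.integer(round(stats::runif(n, 300, 800)))
    chrom <- character(n); center <- integer(n); gene <- rep(NA_character_, n)
    is_prom <- kind == "promoter"
    tss_idx <- sample.int(nrow(genome$tss), sum(is_prom),
                          replace = sum(is_prom) > nrow(genome$tss))
    chrom[is_prom] <- genome$tss$chrom[tss_idx]
    center[is_prom] <- genome$tss$pos[tss_idx] +
      as.integer(round(stats::runif(sum(is_prom), -200, 200)))
    gene[is_prom] <- genome$tss$gene[tss_idx]
    is_enh <- kind == "enhancer"
    enh_idx <- sample.int(nrow(genome$enhancers), sum(is_enh), replace = TRUE)
    chrom[is_enh] <- genome$enhancers$chrom[enh_idx]
    center[is_enh] <- as.integer(round(stats::runif(
      sum(is_enh), genome$enhancers$start[enh_idx] + 100,
      genome$enhancers$end[enh_idx] - 100)))
    is_oth <- kind == "other"
    chrom[is_oth] <- sample(names(genome$contigs), sum(is_oth), replace = TRUE)
    center[is_oth] <- as.integer(floor(stats::runif(sum(is_oth), 5e3,
                                                    genome$contigs[chrom[is_oth]] - 5e3)))
    peaks <- data.frame(
      peak_id = sprintf("peak%05d", seq_len(n)),
      chrom = chrom,
      start = as.integer(center - width %/% 2),
      end = as.integer(center + width %/% 2),
      annotation = kind, gene = gene, stringsAsFactors = FALSE)

    ## planted alterations
    n_scaa <- round(n * cfg$scaa_fraction)
    scaa_idx <- sample.int(n, n_scaa)
    status <- rep("unchanged", n)
    status[scaa_idx] <- sample(c("gained", "lost"), n_scaa, replace = TRUE)
    effect <- ifelse(status == "gained", cfg$gain_effect,
                     ifelse(status == "lost", cfg$loss_effect, 1))
    patients <- unique(cohort$samples$patient)
    regions_t <- TUMOUR_REGIONS[seq_len(cfg$regions_per_tumour)]
    aff_pat <- vector("list", n); aff_reg <- vector("list", n)
    subclonal <- rep(FALSE, n)
    if (n_scaa > 0) {
      subclonal[sample(scaa_idx, round(n_scaa * cfg$subclonal_fraction))] <- TRUE
    }
    for (i in scaa_idx) {
      frac <- stats::runif(1, affected_fraction_range[1], affected_fraction_range[2])
      k <- max(1L, round(frac * length(patients)))
      aff_pat[[i]] <- sample(patients, k)
      aff_reg[[i]] <- if (subclonal[i] && length(regions_t) >= 2) {
        sort(sample(regions_t, max(1L, length(regions_t) %/% 2)))
      } else {
        regions_t
      }
    }

    s_n <- stats::rlnorm(n, log(60), 0.6)
    sf <- stats::rlnorm(nrow(cohort$samples), 0, 0.25)
    names(sf) <- cohort$samples$sample

    counts <- matrix(0L, n, nrow(cohort$samples),
                     dimnames = list(peaks$peak_id, cohort$samples$sample))
    psi <- cohort$truth$ploidy
    for (j in seq_len(nrow(cohort$samples))) {
      smp <- cohort$samples[j, ]
      rho <- smp$purity
      pi_loc <- segment_state_at(cohort$truth$segments, smp$patient,
                                 peaks$chrom, as.integer((peaks$start + peaks$end) / 2))
      cn_fac <- (2 * (1 - rho) + pi_loc * rho) /
        (2 * (1 - rho) + psi[[smp$patient]] * rho)
      eff <- rep(1, n)
      hit <- vapply(seq_len(n), function(i) {
        !is.null(aff_pat[[i]]) && smp$patient %in% aff_pat[[i]] &&
          smp$region %in% aff_reg[[i]]
      }, logical(1))
      eff[hit] <- effect[hit]
      mu <- sf[j] * s_n * eff * cn_fac
      counts[, j] <- stats::rnbinom(n, size = 1 / cfg$nb_dispersion, mu = mu)
    }

    truth <- data.frame(
      peak_id = peaks$peak_id, status = status, effect = effect,
      subclonal = subclonal,
      affected_patients = vapply(aff_pat, function(x) paste(x, collapse = ","), character(1)),
      affected_regions = vapply(aff_reg, function(x) paste(x, collapse = ","), character(1)),
      stringsAsFactors = FALSE)

    structure(list(peaks = peaks, counts = counts,
                   size_factors_true = sf, baseline = s_n, truth = truth),
              class = "peak_table")
  })
}

#' Simulate per-region called-peak lists
#'
#' Peak calling itself is an input boundary (performed externally on real
#' data); the generator emits the per-region lists a caller would produce:
#' peaks accessible in that region, with q-values and enrichment scores, plus
#' low-quality noise calls that the filtering step must remove. Gained peaks
#' are called only in affected patients' affected regions; lost peaks are
#' absent there.
#'
#' @param cohort A `gland_cohort`.
#' @param peak_table Result of [simulate_peak_counts()].
#' @param noise_calls Number of spurious low-quality calls per region.
#' @return Named list (one element per region label, e.g. `"P01_A"`, plus
#'   `"normal_panel"`) of data frames with chrom, start, end, q_value,
#'   enrichment.
#' @export
simulate_region_peak_calls <- function(cohort, peak_table, noise_calls = 50) {
  stopifnot(inherits(cohort, "gland_cohort"), inherits(peak_table, "peak_table"))
  cfg <- cohort$config
  pk <- peak_table$peaks
  tr <- peak_table$truth
  regions_t <- TUMOUR_REGIONS[seq_len(cfg$regions_per_tumour)]
  with_seed(stage_seed(cfg$seed, "region_calls"), {
    make_calls <- function(idx) {
      if (!length(idx)) {
        return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                          q_value = numeric(0), enrichment = numeric(0)))
      }
      jit <- as.integer(round(stats::rnorm(length(idx), 0, 20)))
      calls <- data.frame(chrom = pk$chrom[idx],
                          start = pmax(0L, pk$start[idx] + jit),
                          end = pk$end[idx] + jit,
                          q_value = stats::runif(length(idx), 1e-12, 5e-4),
                          enrichment = stats::runif(length(idx), 4.5, 30),
                          stringsAsFactors = FALSE)
      noise <- data.frame(
        chrom = sample(names(cohort$genome$contigs), noise_calls, replace = TRUE),
        start = as.integer(floor(stats::runif(noise_calls, 1, 9.9e6))),
        end = NA_integer_, q_value = stats::runif(noise_calls, 0.002, 0.5),
        enrichment = stats::runif(noise_calls, 0.5, 3.9), stringsAsFactors = FALSE)
      noise$end <- noise$start + 400L
      rbind(calls, noise)
    }
    out <- list()
    for (p in unique(cohort$samples$patient)) {
      for (r in regions_t) {
        present <- vapply(seq_len(nrow(pk)), function(i) {
          aff <- strsplit(tr$affected_patients[i], ",")[[1]]
          reg <- strsplit(tr$affected_regions[i], ",")[[1]]
          hit <- p %in% aff && r %in% reg
          if (tr$status[i] == "gained") hit else if (tr$status[i] == "lost") !hit else TRUE
        }, logical(1))
        out[[paste(p, r, sep = "_")]] <- make_calls(which(present))
      }
    }
    out[["normal_panel"]] <- make_calls(which(tr$status != "gained"))
    out
  })
}

#' Simulate TF binding-site sets
#'
#' Site centres are placed on the synthetic genome at least 1,000 bp apart
#' within each TF (mirroring the homotypic-cluster filter), on autosomal
#' contigs only, with random strand. A quarter of TFs carries a planted
#' footprint gain, a quarter a loss; the rest are null.
#'
#' @param cohort A `gland_cohort`.
#' @param n_tf Number of TFs.
#' @param sites_per_tf Binding sites per TF.
#' @param gain_effect,loss_effect Multiplicative change of central
#'   nucleosome-free insertion density at full purity.
#' @return List of class `tf_sites`: `sites` (data frame tf, chrom, center,
#'   strand, stratum) and `truth` (per-TF effect).
#' @export
simulate_tf_sites <- function(cohort, n_tf = 12, sites_per_tf = 200,
                              gain_effect = 2, loss_effect = 0.5) {
  stopifnot(inherits(cohort, "gland_cohort"))
  genome <- cohort$genome
  with_seed(stage_seed(cohort$config$seed, "tf_sites"), {
    tfs <- sprintf("TF%02d", seq_len(n_tf))
    effect <- rep(1, n_tf)
    n_eff <- n_tf %/% 4
    if (n_eff > 0) {
      effect[seq_len(n_eff)] <- gain_effect
      effect[n_eff + seq_len(n_eff)] <- loss_effect
    }
    names(effect) <- tfs
    sites <- do.call(rbind, lapply(tfs, function(tf) {
      ## grid placement guarantees >= 1 kb homotypic separation
      grid <- seq(2e3, sum(genome$contigs) - 2e3, by = 2000)
      pick <- sort(sample(grid, sites_per_tf))
      cum <- cumsum(genome$contigs)
      ct_i <- findInterval(pick, c(0, cum[-length(cum)])) ## 1-based contig index
      data.frame(tf = tf, chrom = names(genome$contigs)[ct_i],
                 center = as.integer(pick - c(0, cum)[ct_i]),
                 strand = sample(c("+", "-"), sites_per_tf, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    ## TSS-distance strata
    d <- vapply(seq_len(nrow(sites)), function(i) {
      tss <- genome$tss[genome$tss$chrom == sites$chrom[i], "pos"]
      min(abs(tss - sites$center[i]))
    }, numeric(1))
    sites$stratum <- cut(d, c(-1, 2000, 10000, Inf),
                         labels = c("proximal", "close", "distal"))
    structure(list(sites = sites, truth = effect), class = "tf_sites")
  })
}

#' Simulate ATAC fragment records around TF binding sites
#'
#' Emits BED-like fragments (chrom, start, end, sample) whose insertion-size
#' distribution mixes a sub-100-bp nucleosome-free component (shifted
#' exponential, mode ~60 bp) with Gaussian mono- and di-nucleosomal
#' components at 200 and 400 bp. Planted footprint effects scale the
#' expected central nucleosome-free insertion density at target TF sites by
#' `1 + (effect - 1) * purity`, i.e. linearly with purity.
#'
#' @param cohort A `gland_cohort`.
#' @param tf_sites Result of [simulate_tf_sites()].
#' @param open_per_site Expected nucleosome-free fragments per site at
#'   effect 1.
#' @param nuc_per_site Expected nucleosome-associated fragments per site.
#' @param background_frags Expected genome-background fragments per sample.
#' @return Data frame chrom, start, end, sample (0-based half-open).
#' @export
simulate_fragments <- function(cohort, tf_sites, open_per_site = 3,
                               nuc_per_site = 1.5, background_frags = 5000) {
  stopifnot(inherits(cohort, "gland_cohort"), inherits(tf_sites, "tf_sites"))
  genome <- cohort$genome
  sites <- tf_sites$sites
  effect <- tf_sites$truth[sites$tf]
  draw_open_sizes <- function(n) pmax(20L, as.integer(round(60 + stats::rexp(n, 1 / 25) - 25)))
  draw_nuc_sizes <- function(n) {
    di <- stats::runif(n) < 0.25
    as.integer(round(ifelse(di, stats::rnorm(n, 400, 30), stats::rnorm(n, 200, 20))))
  }
  with_seed(stage_seed(cohort$config$seed, "fragments"), {
    out <- lapply(seq_len(nrow(cohort$samples)), function(j) {
      smp <- cohort$samples[j, ]
      rho <- smp$purity
      lam_open <- open_per_site * (1 + (effect - 1) * rho)
      n_open <- stats::rpois(nrow(sites), lam_open)
      n_nuc <- stats::rpois(nrow(sites), nuc_per_site)
      site_idx <- c(rep(seq_len(nrow(sites)), n_open), rep(seq_len(nrow(sites)), n_nuc))
      size <- c(draw_open_sizes(sum(n_open)), draw_nuc_sizes(sum(n_nuc)))
      offset <- c(as.integer(round(stats::rnorm(sum(n_open), 0, 40))),
                  as.integer(round(stats::rnorm(sum(n_nuc), 0, 300))))
      center <- sites$center[site_idx] + offset
      chrom <- sites$chrom[site_idx]
      ## background: uniform over the genome, same size mixture
      nb <- stats::rpois(1, background_frags)
      open_b <- stats::runif(nb) < 0.6
      size_b <- integer(nb)
      size_b[open_b] <- draw_open_sizes(sum(open_b))
      size_b[!open_b] <- draw_nuc_sizes(sum(!open_b))
      chrom_b <- sample(names(genome$contigs), nb, replace = TRUE)
      center_b <- as.integer(floor(stats::runif(nb, 1000, genome$contigs[chrom_b] - 1000)))
      chrom <- c(chrom, chrom_b); center <- c(center, center_b)
      size <- c(size, size_b)
      start <- pmax(0L, as.integer(center - size %/% 2))
      data.frame(chrom = chrom, start = start, end = start + size,
                 sample = smp$sample, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate binned low-pass WGS log2 coverage ratios
#'
#' For each sample, the log2 ratio of each 500-kb bin is
#' `log2((2(1-rho) + rho * n) / (2(1-rho) + rho * psi_t))` plus Gaussian
#' noise, where `n` is the true integer state of the overlapping segment and
#' `psi_t` the tumour ploidy. Values are median-centred per sample (the
#' applied median is recorded), matching the normalization applied to real
#' low-pass data before segmentation.
#'
#' @param cohort A `gland_cohort`.
#' @param noise_sd Standard deviation of the bin noise.
#' @param samples Optional subset of sample names.
#' @return List: `bins` (long data frame sample, contig, start, end,
#'   log2ratio), `medians` (named vector of subtracted medians).
#' @export
simulate_lowpass_bins <- function(cohort, noise_sd = 0.05, samples = NULL) {
  stopifnot(inherits(cohort, "gland_cohort"))
  genome <- cohort$genome
  bin_size <- cohort$truth$bin_size
  smp <- cohort$samples
  if (!is.null(samples)) smp <- smp[smp$sample %in% samples, ]
  grid <- do.call(rbind, lapply(names(genome$contigs), function(ct) {
    starts <- seq(0L, genome$contigs[[ct]] - bin_size, by = bin_size)
    data.frame(contig = ct, start = as.integer(starts),
               end = as.integer(starts + bin_size), stringsAsFactors = FALSE)
  }))
  with_seed(stage_seed(cohort$config$seed, "lowpass"), {
    res <- lapply(seq_len(nrow(smp)), function(j) {
      s <- smp[j, ]
      rho <- s$purity
      psi <- cohort$truth$ploidy[[s$patient]]
      n_true <- segment_state_at(cohort$truth$segments, s$patient,
                                 grid$contig, grid$start + bin_size %/% 2)
      r <- log2((2 * (1 - rho) + rho * n_true) / (2 * (1 - rho) + rho * psi)) +
        stats::rnorm(nrow(grid), 0, noise_sd)
      med <- stats::median(r)
      data.frame(sample = s$sample, grid, log2ratio = r - med,
                 median_applied = med, stringsAsFactors = FALSE)
    })
    bins <- do.call(rbind, res)
    medians <- vapply(res, function(x) x$median_applied[1], numeric(1))
    names(medians) <- vapply(res, function(x) x$sample[1], character(1))
    bins$median_applied <- NULL
    list(bins = bins, medians = medians)
  })
}

#' Fixed synthetic mutational signatures
#'
#' `k` 96-channel probability vectors with mostly disjoint support blocks
#' plus a small uniform background, deterministic given the seed. They stand
#' in for a fixed reference signature set (no de novo discovery is
#' performed); they are synthetic and are not COSMIC profiles.
#'
#' @param k Number of signatures.
#' @param seed Seed.
#' @return Matrix k x 96, rows summing to 1, rownames `S1..Sk`.
#' @export
synthetic_signatures <- function(k = 6, seed = 2020L) {
  stopifnot(k >= 1, k <= 16)
  with_seed(seed, {
    S <- matrix(0.0005, k, 96, dimnames = list(paste0("S", seq_len(k)),
                                               sbs96_channels()))
    block <- 96 %/% k
    for (i in seq_len(k)) {
      idx <- ((i - 1) * block + 1):(i * block)
      S[i, idx] <- S[i, idx] + stats::rgamma(length(idx), 1.2, 1)
    }
    S / rowSums(S)
  })
}

#' Simulate a 96-channel mutation catalogue from a signature mixture
#'
#' Draws `n_mut` mutations from the exposure-weighted signature mixture,
#' with channel probabilities re-weighted by the trinucleotide content of
#' the genomic region relative to the whole genome (so that catalogues from
#' different region classes carry the region's compositional bias, which
#' [trinucleotide_normalize()] must undo).
#'
#' @param signatures Matrix k x 96 of signature profiles (rows sum to 1).
#' @param exposures Non-negative vector of length k summing to 1.
#' @param n_mut Number of mutations.
#' @param genome_content,region_content Named frequency vectors over the 32
#'   trinucleotide contexts.
#' @param seed Seed.
#' @return Named integer vector of length 96.
#' @export
simulate_mutation_catalogue <- function(signatures, exposures, n_mut,
                                        genome_content = synthetic_trinucleotide_content(),
                                        region_content = genome_content,
                                        seed = 1L) {
  stopifnot(nrow(signatures) == length(exposures), ncol(signatures) == 96)
  if (any(exposures < 0)) stop("exposures must be non-negative")
  if (abs(sum(exposures) - 1) > 1e-6) stop("exposures must sum to 1")
  ctx <- sbs96_contexts()
  w <- as.numeric(region_content[ctx] / genome_content[ctx])
  p <- as.numeric(exposures %*% signatures) * w
  p <- p / sum(p)
  if (n_mut == 0) {
    return(stats::setNames(integer(96), sbs96_channels()))
  }
  with_seed(seed, {
    stats::setNames(as.integer(stats::rmultinom(1, n_mut, p)), sbs96_channels())
  })
}

#' Simulate per-sample region-stratified mutation catalogues
#'
#' Generates, for each sample of each patient cluster, a 96-channel
#' catalogue per genomic region class (e.g. active/inactive promoter), with
#' per-region signature mutation loads specified as ground truth. Region
#' compositional bias is applied per region class.
#'
#' @param signatures Matrix k x 96.
#' @param clusters Named list: cluster -> vector of sample names.
#' @param region_spec Data frame with columns region_class, signature,
#'   mutations (expected per sample).
#' @param region_content Named list: region_class -> 32-context frequency
#'   vector (default: genome content for all).
#' @param genome_content 32-context frequency vector.
#' @param seed Seed.
#' @return List: `catalogues` (data frame sample, cluster, region_class +
#'   96 channel columns), `truth` (= region_spec).
#' @export
simulate_region_catalogues <- function(signatures, clusters, region_spec,
                                       region_content = NULL,
                                       genome_content = synthetic_trinucleotide_content(),
                                       seed = 1L) {
  classes <- unique(region_spec$region_class)
  if (is.null(region_content)) {
    region_content <- stats::setNames(rep(list(genome_content), length(classes)), classes)
  }
  rows <- list()
  counter <- 0L
  for (cl in names(clusters)) {
    for (smp in clusters[[cl]]) {
      for (rc in classes) {
        spec <- region_spec[region_spec$region_class == rc, ]
        load <- stats::setNames(rep(0, nrow(signatures)), rownames(signatures))
        load[spec$signature] <- spec$mutations
        counter <- counter + 1L
        n_mut <- with_seed(stage_seed(seed, counter), stats::rpois(1, sum(load)))
        expo <- if (sum(load) > 0) load / sum(load) else rep(1 / length(load), length(load))
        cat96 <- simulate_mutation_catalogue(signatures, expo, n_mut,
                                             genome_content = genome_content,
                                             region_content = region_content[[rc]],
                                             seed = stage_seed(seed, counter + 100000L))
        rows[[length(rows) + 1L]] <- c(list(sample = smp, cluster = cl,
                                            region_class = rc), as.list(cat96))
      }
    }
  }
  catalogues <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)
  }))
  list(catalogues = catalogues, truth = region_spec)
}
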