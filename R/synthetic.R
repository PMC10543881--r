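# Synthetic cohorts with the statistical structure the method assumes:
# nucleosomal fragment-length mixtures with 10-bp oscillations on the
# short side of each peak, tumour-fraction-dependent short-fragment
# enrichment, and binomial panel read counts whose clonal VAF is half the
# tumour fraction.

#' Simulation configuration
#'
#' Defaults emulate plasma cfDNA qualitatively: a healthy component with
#' mono- and di-nucleosome peaks at 166 and 332 bp and mild ~10 bp
#' oscillation, and a tumour component shifted towards shorter fragments
#' (peaks 145 and 300 bp) with stronger oscillation. A sample with tumour
#' fraction `theta` draws fragment lengths from the mixture
#' `(1 - theta) * healthy + theta * tumour`.
#'
#' @param support Inclusive fragment-length range in bp.
#' @param healthy,tumour Component specifications: peak `means`, `sds`,
#'   `weights` (positive, summing to 1) and oscillation `amplitude`.
#' @param period Oscillation period in bp, applied on the short side of
#'   each peak.
#' @param n_fragments Fragments drawn per sample histogram.
#' @param depth Panel sequencing depth per mutation.
#' @param surrogate_sd Logit-scale noise sd of surrogate labels.
#' @param non_annotated_frac Fraction of simulated mutations flagged as
#'   non-annotated.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(support = c(50L, 400L),
                       healthy = list(means = c(166, 332), sds = c(9, 20),
                                      weights = c(0.88, 0.12),
                                      amplitude = 0.05),
                       tumour = list(means = c(145, 300), sds = c(12, 25),
                                     weights = c(0.90, 0.10),
                                     amplitude = 0.15),
                       period = 10,
                       n_fragments = 5e5,
                       depth = 600L,
                       surrogate_sd = 0.5,
                       non_annotated_frac = 0.1) {
  for (comp in list(healthy, tumour)) {
    if (any(comp$weights <= 0) || abs(sum(comp$weights) - 1) > 1e-9) {
      stop("component weights must be positive and sum to 1",
           call. = FALSE)
    }
    if (comp$amplitude >= 1) stop("amplitude must be < 1", call. = FALSE)
  }
  if (period <= 0) stop("period must be positive", call. = FALSE)
  structure(
    list(support = as.integer(support), healthy = healthy,
         tumour = tumour, period = period, n_fragments = n_fragments,
         depth = as.integer(depth), surrogate_sd = surrogate_sd,
         non_annotated_frac = non_annotated_frac),
    class = "sim_config"
  )
}

#' Fragment-length density of one cfDNA component
#'
#' Weighted sum of truncated normal peak densities, each multiplied on its
#' short side (`l < mean`) by `1 + amplitude * cos(2*pi*(mean - l) /
#' period)` to create sub-peak oscillations with local maxima ~`period` bp
#' apart, plus a uniform floor of 1e-6 before renormalization; the result
#' sums to 1 over the support grid.
#'
#' @param component Peak parameter list (see [sim_config()]), e.g.
#'   `sim_config()$healthy`.
#' @param config A `sim_config` (provides support and period).
#' @return Named numeric vector of probabilities over the support grid.
#' @export
component_density <- function(component, config = sim_config()) {
  l <- config$support[1L]:config$support[2L]
  dens <- numeric(length(l))
  for (i in seq_along(component$means)) {
    m <- component$means[i]
    base <- stats::dnorm(l, m, component$sds[i])
    mod <- ifelse(l < m,
                  1 + component$amplitude *
                    cos(2 * pi * (m - l) / config$period),
                  1)
    dens <- dens + component$weights[i] * base * mod
  }
  dens <- dens + 1e-6
  stats::setNames(dens / sum(dens), l)
}

#' Mixture fragment-length density at tumour fraction theta
#'
#' @param theta Tumour fraction in `[0, 1)`.
#' @param config A `sim_config`.
#' @return Named probability vector over the support grid.
#' @export
mixture_density <- function(theta, config = sim_config()) {
  if (theta < 0 || theta >= 1) stop("theta must lie in [0, 1)",
                                    call. = FALSE)
  (1 - theta) * component_density(config$healthy, config) +
    theta * component_density(config$tumour, config)
}

#' Simulate one plasma sample
#'
#' Draws a fragment-length histogram multinomially from the mixture
#' density, plus cohort-specific labelling material: cohort A samples get
#' `1 + Poisson(4)` clonal mutations with `alt ~ Binomial(depth,
#' theta/2)` and 0--3 subclonal mutations at `theta/4` (all copy-number
#' neutral; a configurable fraction flagged non-annotated); cohort B
#' samples get a surrogate label `plogis(qlogis(theta) + N(0, sd))`;
#' dilution samples carry neither.
#'
#' @param theta True tumour fraction in `[0, 1)` (positive for cohorts A
#'   and B).
#' @param config A [sim_config()].
#' @param seed Integer seed; the sample is reproducible given it.
#' @param sample_id Identifier.
#' @param cohort One of `"A"`, `"B"`, `"dilution"`.
#' @return An object of class `synthetic_sample`: `sample_id`, `theta`,
#'   `histogram`, `mutations` (cohort A), `surrogate_label` (cohort B),
#'   `cohort`.
#' @export
simulate_sample <- function(theta, config = sim_config(), seed = 1L,
                            sample_id = "sample", cohort = "A") {
  cohort <- match.arg(cohort, c("A", "B", "dilution"))
  p <- mixture_density(theta, config)   # validates theta
  build <- function() {
    counts <- stats::rmultinom(1L, config$n_fragments, p)[, 1L]
    hist <- length_histogram(sample_id, stats::setNames(counts, names(p)),
                             support = config$support)
    mutations <- NULL
    surrogate <- NULL
    if (cohort == "A") {
      n_clonal <- 1L + stats::rpois(1L, 4)
      n_sub <- sample(0:3, 1L)
      vafs <- c(rep(theta / 2, n_clonal), rep(theta / 4, n_sub))
      m <- length(vafs)
      mutations <- data.frame(
        sample_id = sample_id,
        chrom = "chr1",
        pos = sort(sample.int(1e8, m)),
        ref = "A", alt = "T",
        alt_count = stats::rbinom(m, config$depth, vafs),
        depth = config$depth,
        cn_neutral = 1L,
        annotated = as.integer(stats::runif(m) >=
                                 config$non_annotated_frac),
        stringsAsFactors = FALSE
      )
    } else if (cohort == "B") {
      if (theta <= 0) stop("cohort B requires theta > 0", call. = FALSE)
      s <- stats::plogis(stats::qlogis(theta) +
                           stats::rnorm(1L, 0, config$surrogate_sd))
      surrogate <- min(1 - 1e-3, max(1e-3, s))
    }
    list(hist = hist, mutations = mutations, surrogate = surrogate)
  }
  parts <- withr::with_seed(seed, build())
  structure(
    list(sample_id = sample_id, theta = theta, histogram = parts$hist,
         mutations = parts$mutations, surrogate_label = parts$surrogate,
         cohort = cohort, seed = seed),
    class = "synthetic_sample"
  )
}

#' Simulate training cohorts
#'
#' Tumour fractions are drawn from Beta(2, 3.5) — a stage-IV-like
#' distribution concentrated above 10% tumour content — for both cohorts;
#' cohort A samples carry panel mutations, cohort B samples surrogate
#' labels. One global seed fans out into per-sample substreams so each
#' sample is individually reproducible.
#'
#' @param nA,nB Cohort sizes (defaults 41 and 71).
#' @param config A [sim_config()].
#' @param seed Global integer seed.
#' @return List of [simulate_sample()] results, cohort A first.
#' @export
simulate_cohorts <- function(nA = 41L, nB = 71L, config = sim_config(),
                             seed = 1L) {
  stopifnot(nA >= 0L, nB >= 0L)
  n <- nA + nB
  draw <- function() {
    list(thetas = stats::rbeta(n, 2.0, 3.5),
         seeds = sample.int(.Machine$integer.max - 1L, n))
  }
  plan <- withr::with_seed(seed, draw())
  cohorts <- rep(c("A", "B"), c(nA, nB))
  ids <- sprintf("%s%02d", cohorts, c(seq_len(nA), seq_len(nB)))
  lapply(seq_len(n), function(i) {
    simulate_sample(plan$thetas[i], config, seed = plan$seeds[i],
                    sample_id = ids[i], cohort = cohorts[i])
  })
}

#' Simulate a dilution series
#'
#' Mimics mixing one patient's plasma into healthy control plasma: the
#' sample at concentration `c` has true tumour fraction
#' `c * theta_patient`. No mutations or surrogate labels are attached
#' (the series is a test set).
#'
#' @param theta_patient Tumour fraction of the undiluted patient sample.
#' @param concentrations Fractions of patient plasma in each mixture.
#' @param config A [sim_config()].
#' @param seed Global integer seed.
#' @return List of `synthetic_sample` objects with an added
#'   `concentration` element.
#' @export
simulate_dilution <- function(theta_patient = 0.6,
                              concentrations = c(0, 0.05, 0.1, 0.25,
                                                 0.5, 1.0),
                              config = sim_config(), seed = 1L) {
  stopifnot(all(concentrations >= 0 & concentrations <= 1))
  seeds <- withr::with_seed(
    seed, sample.int(.Machine$integer.max - 1L, length(concentrations)))
  lapply(seq_along(concentrations), function(i) {
    s <- simulate_sample(concentrations[i] * theta_patient, config,
                         seed = seeds[i],
                         sample_id = sprintf("dil%02d", i),
                         cohort = "dilution")
    s$concentration <- concentrations[i]
    s
  })
}

#' Write synthetic samples to disk in the pipeline's file formats
#'
#' Emits one histogram TSV per sample, one mutation TSV per cohort-A
#' sample, a cohort manifest CSV (`sample_id, histogram_path,
#' label_source, label_value_or_mutation_path`) and a ground-truth CSV
#' `truth.csv` (`sample_id,theta`; for tests only, never read by the
#' pipeline).
#'
#' @param samples List of `synthetic_sample` objects.
#' @param dir Output directory (created if needed).
#' @param manifest Manifest file name.
#' @return Path to the manifest CSV, invisibly.
#' @export
write_samples <- function(samples, dir, manifest = "manifest.csv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(samples, function(s) {
    hist_file <- paste0(s$sample_id, ".hist.tsv")
    write_histogram(s$histogram, file.path(dir, hist_file))
    if (s$cohort == "A") {
      mut_file <- paste0(s$sample_id, ".muts.tsv")
      utils::write.table(s$mutations, file.path(dir, mut_file),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      src <- "panel"
      val <- mut_file
    } else if (s$cohort == "B") {
      src <- "surrogate"
      val <- format(s$surrogate_label, digits = 17)
    } else {
      src <- "dilution"
      val <- format(s$concentration, digits = 17)
    }
    data.frame(sample_id = s$sample_id, histogram_path = hist_file,
               label_source = src, label_value_or_mutation_path = val,
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  utils::write.csv(man, file.path(dir, manifest), row.names = FALSE,
                   quote = FALSE)
  truth <- data.frame(
    sample_id = vapply(samples, `[[`, character(1), "sample_id"),
    theta = vapply(samples, `[[`, numeric(1), "theta"))
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(file.path(dir, manifest))
}
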