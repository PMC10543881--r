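# Tumour-content training labels: direct estimation from panel SNVs via
# Dirichlet-process clustering of allele frequencies, or surrogate labels
# read from file.

#' Read a somatic mutation table
#'
#' Tab-separated columns: `sample_id, chrom, pos, ref, alt, alt_count,
#' depth, cn_neutral, annotated` (booleans coded 0/1). `cn_neutral` is
#' TRUE only for diploid loci without loss of heterozygosity; a missing
#' value is treated as not neutral.
#'
#' @param path TSV path.
#' @return Data frame of mutation calls with a computed `vaf` column.
#' @export
read_mutations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "pos", "alt_count", "depth",
            "cn_neutral", "annotated")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("mutation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  validate_mutations(df)
}

validate_mutations <- function(df) {
  if (any(df$depth <= 0)) stop("depth must be positive", call. = FALSE)
  if (any(df$alt_count < 0 | df$alt_count > df$depth)) {
    stop("alt_count must lie in [0, depth]", call. = FALSE)
  }
  df$cn_neutral <- !is.na(df$cn_neutral) & as.logical(df$cn_neutral)
  df$annotated <- !is.na(df$annotated) & as.logical(df$annotated)
  df$vaf <- df$alt_count / df$depth
  df
}

# log marginal likelihood of a set of (alt, depth) pairs sharing one
# Beta(1,1)-distributed success probability, binomial coefficient omitted
# (constant across partitions).
log_marglik <- function(sum_alt, sum_depth) {
  lbeta(1 + sum_alt, 1 + sum_depth - sum_alt)
}

#' Cluster mutations by allele frequency with a Dirichlet-process mixture
#'
#' Collapsed Gibbs sampling over a Chinese-restaurant-process prior with
#' concentration `alpha`, Binomial(alt | depth, v) likelihood and a
#' Beta(1, 1) base measure on each cluster's allele frequency v. Only
#' copy-number neutral mutations are clustered; others are excluded first.
#' The returned point clustering is the sampled assignment state with the
#' highest joint posterior score, and each cluster's VAF is the posterior
#' mean of v given that clustering.
#'
#' @param mutations Data frame as from [read_mutations()].
#' @param alpha CRP concentration (default 1).
#' @param iters Number of Gibbs sweeps (default 2000).
#' @param seed Integer seed; the run is deterministic given it.
#' @return An object of class `vaf_clustering` with `assignments` (integer
#'   cluster ids, one per clustered mutation), `cluster_vafs`,
#'   `cluster_annotated` (does any member carry `annotated = TRUE`),
#'   `log_score`, `n_iterations` and `seed`.
#' @export
cluster_vafs <- function(mutations, alpha = 1.0, iters = 2000L, seed = 1L) {
  mutations <- validate_mutations(mutations)
  mut <- mutations[mutations$cn_neutral, , drop = FALSE]
  n <- nrow(mut)
  if (n == 0L) {
    stop("cohort-B sample: no copy-number neutral mutations to cluster",
         call. = FALSE)
  }
  a <- mut$alt_count
  d <- mut$depth
  run <- function() {
    z <- rep(1L, n)                      # start from a single cluster
    best_z <- z
    best_score <- crp_score(z, a, d, alpha)
    for (it in seq_len(iters)) {
      for (i in seq_len(n)) {
        z_i <- z[-i]
        ids <- sort(unique(z_i))
        sa <- vapply(ids, function(c) sum(a[-i][z_i == c]), numeric(1))
        sd_ <- vapply(ids, function(c) sum(d[-i][z_i == c]), numeric(1))
        nc <- vapply(ids, function(c) sum(z_i == c), numeric(1))
        logw <- c(
          log(nc) + log_marglik(sa + a[i], sd_ + d[i]) -
            log_marglik(sa, sd_),
          log(alpha) + log_marglik(a[i], d[i])
        )
        w <- exp(logw - max(logw))
        pick <- sample.int(length(w), 1L, prob = w)
        z[i] <- if (pick <= length(ids)) ids[pick] else {
          max(c(0L, ids)) + 1L
        }
      }
      z <- relabel_partition(z)
      sc <- crp_score(z, a, d, alpha)
      if (sc > best_score) {
        best_score <- sc
        best_z <- z
      }
    }
    list(z = best_z, score = best_score)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  z <- res$z
  ids <- sort(unique(z))
  vafs <- vapply(ids, function(c) {
    (1 + sum(a[z == c])) / (2 + sum(d[z == c]))
  }, numeric(1))
  ann <- vapply(ids, function(c) any(mut$annotated[z == c]), logical(1))
  structure(
    list(assignments = z,
         cluster_vafs = stats::setNames(vafs, ids),
         cluster_annotated = stats::setNames(ann, ids),
         log_score = res$score,
         n_iterations = as.integer(iters),
         seed = seed,
         mutations = mut),
    class = "vaf_clustering"
  )
}

# Joint log posterior of a partition under the CRP prior and the
# per-cluster Beta-binomial marginal likelihood (constants dropped).
crp_score <- function(z, a, d, alpha) {
  ids <- unique(z)
  s <- length(ids) * log(alpha)
  for (c in ids) {
    m <- z == c
    s <- s + lgamma(sum(m)) + log_marglik(sum(a[m]), sum(d[m]))
  }
  s
}

# Canonical labels: clusters numbered by order of first appearance.
relabel_partition <- function(z) {
  match(z, unique(z))
}

#' Tumour content from a VAF clustering
#'
#' Selects the cluster with the largest posterior-mean allele frequency;
#' if every mutation in it is non-annotated and another cluster exists,
#' the second-largest cluster is used instead. Under the heterozygous
#' clonal-mutation assumption the tumour content is twice the selected
#' cluster's VAF; the result is clipped into `(epsilon, 1 - epsilon)` so
#' it is a valid beta-regression response.
#'
#' @param clustering A `vaf_clustering`.
#' @param sample_id Sample identifier for the label (default: from the
#'   clustered mutations).
#' @param epsilon Half-width of the exclusion zone at the boundaries
#'   (default 1e-3).
#' @return An object of class `tumour_content_label`: list with
#'   `sample_id`, `value`, `source = "panel"`, `chosen_cluster` and
#'   `clipped`.
#' @export
tumour_content_from_clusters <- function(clustering, sample_id = NULL,
                                         epsilon = 1e-3) {
  stopifnot(inherits(clustering, "vaf_clustering"))
  if (is.null(sample_id)) {
    sample_id <- as.character(clustering$mutations$sample_id[1L])
  }
  ord <- order(clustering$cluster_vafs, decreasing = TRUE)
  chosen <- ord[1L]
  if (!clustering$cluster_annotated[chosen] && length(ord) >= 2L) {
    chosen <- ord[2L]
  }
  raw <- 2 * clustering$cluster_vafs[[chosen]]
  value <- min(1 - epsilon, max(epsilon, raw))
  structure(
    list(sample_id = sample_id, value = value, source = "panel",
         chosen_cluster = names(clustering$cluster_vafs)[chosen],
         clipped = value != raw),
    class = "tumour_content_label"
  )
}

#' Panel-based tumour-content label for one sample
#'
#' Convenience wrapper: [cluster_vafs()] followed by
#' [tumour_content_from_clusters()].
#'
#' @inheritParams cluster_vafs
#' @inheritParams tumour_content_from_clusters
#' @return A `tumour_content_label`.
#' @export
panel_label <- function(mutations, alpha = 1.0, iters = 2000L, seed = 1L,
                        epsilon = 1e-3) {
  cl <- cluster_vafs(mutations, alpha = alpha, iters = iters, seed = seed)
  tumour_content_from_clusters(cl, epsilon = epsilon)
}

#' Load surrogate tumour-content labels
#'
#' Reads a CSV of `sample_id,value` produced by an external copy-number
#' based estimator. Values must lie in `[0, 1]`; entries at or below zero
#' carry no usable signal and are dropped with a message reporting their
#' number.
#'
#' @param path CSV path.
#' @return Data frame with columns `sample_id`, `value`,
#'   `source = "surrogate"`; attribute `n_dropped` records the zero-value
#'   entries removed.
#' @export
load_surrogate_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("empty surrogate label file: ", path, call. = FALSE)
    out <- data.frame(sample_id = character(0), value = numeric(0),
                      source = character(0))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  if (!all(c("sample_id", "value") %in% names(df))) {
    stop("surrogate labels need columns sample_id,value", call. = FALSE)
  }
  df$value <- as.numeric(df$value)
  if (any(is.na(df$value) | df$value < 0 | df$value > 1)) {
    stop("surrogate label outside [0, 1]", call. = FALSE)
  }
  keep <- df$value > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " surrogate label(s) with zero tumour content dropped")
  }
  out <- data.frame(sample_id = as.character(df$sample_id[keep]),
                    value = df$value[keep], source = "surrogate",
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}
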