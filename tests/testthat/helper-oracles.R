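# Independent oracles and fixture builders shared across test files.

# O(N^2) direct-summation DFT, negative exponent, unnormalized.
naive_dft <- function(x) {
  n <- length(x)
  vapply(0:(n - 1L), function(k) {
    sum(x * exp(complex(imaginary = -2 * pi * k * (0:(n - 1L)) / n)))
  }, complex(1))
}

# Published 10-tap Daubechies scaling coefficients (5 vanishing moments),
# convention sum = sqrt(2); typed here independently of the package source.
ORACLE_DB10_G <- c(
  0.160102397974192928, 0.603829269797189649, 0.724308528437772936,
  0.138428145901320743, -0.242294887066382025, -0.0322448695846383748,
  0.0775714938400457188, -0.00624149021279827437, -0.0125807519990819988,
  0.00333572528547377125
)

# Single pyramid level as explicit circulant analysis matrices built from
# the published filter (structurally independent of the package's rolling
# implementation); full decomposition by repeated matrix multiplication.
oracle_dwt <- function(x, levels) {
  g <- rev(ORACLE_DB10_G)                 # package stores reversed order
  h <- rev(g) * (-1)^seq_along(g)
  step_matrix <- function(n, filt) {
    M <- matrix(0, n / 2L, n)
    for (t in seq_len(n / 2L)) {
      for (l in seq_along(filt)) {
        col <- (2L * t - 1L - (l - 1L)) %% n + 1L
        M[t, col] <- M[t, col] + filt[l]
      }
    }
    M
  }
  v <- x
  out <- list()
  for (j in seq_len(levels)) {
    n <- length(v)
    out[[paste0("d", j)]] <- as.numeric(step_matrix(n, h) %*% v)
    v <- as.numeric(step_matrix(n, g) %*% v)
  }
  out$approx <- v
  out
}

# All set partitions of n items as assignment vectors in canonical
# (restricted-growth) labelling.
enumerate_partitions <- function(n) {
  out <- list()
  recurse <- function(assign, k) {
    i <- length(assign) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (c in seq_len(k + 1L)) {
      recurse(c(assign, c), max(k, c))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Joint log posterior of a partition under CRP(alpha) with Beta(1,1)
# binomial marginals; written out directly from the conjugate formulas.
oracle_partition_score <- function(z, alt, depth, alpha = 1.0) {
  score <- length(unique(z)) * log(alpha)
  for (c in unique(z)) {
    m <- z == c
    sa <- sum(alt[m])
    sd_ <- sum(depth[m])
    score <- score + lgamma(sum(m)) +
      lgamma(1 + sa) + lgamma(1 + sd_ - sa) - lgamma(2 + sd_)
  }
  score
}

oracle_map_partition <- function(alt, depth, alpha = 1.0) {
  parts <- enumerate_partitions(length(alt))
  scores <- vapply(parts, oracle_partition_score, numeric(1),
                   alt = alt, depth = depth, alpha = alpha)
  parts[[which.max(scores)]]
}

canonical_partition <- function(z) match(z, unique(z))

# Fragment profile with a prescribed logp vector on support
# [lo, lo + length(logp) - 1]; for feature tests that need exact inputs.
profile_from_logp <- function(logp, lo = 81L, sample_id = "test") {
  lens <- lo:(lo + length(logp) - 1L)
  structure(
    list(sample_id = sample_id, lengths = lens,
         p = stats::setNames(exp(logp), lens),
         logp = stats::setNames(logp, lens),
         pseudocount = 0),
    class = "fragment_profile"
  )
}

# Profile wide enough for the full feature pipeline (support 50..400).
random_profile <- function(seed = 1L, sample_id = "rp") {
  withr::with_seed(seed, {
    s <- simulate_sample(stats::runif(1, 0.05, 0.8), sim_config(),
                         seed = sample.int(1e6, 1),
                         sample_id = sample_id, cohort = "dilution")
    normalize_histogram(s$histogram)
  })
}

# Minimal coordinate-sorted SAM fixture with three proper pairs
# (|TLEN| 166, 166, 320, MAPQ 60) and one duplicate-flagged pair.
write_fixture_sam <- function(path) {
  seq50 <- strrep("A", 50)
  rec <- function(qname, flag, pos, mapq, mpos, tlen) {
    paste(qname, flag, "chr1", pos, mapq, "50M", "=", mpos, tlen,
          seq50, "*", sep = "\t")
  }
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:100000",
    rec("p1", 99, 1000, 60, 1116, 166),
    rec("p2", 99, 2000, 60, 2116, 166),
    rec("dup", 1123, 2500, 60, 2616, 166),   # duplicate flag set
    rec("p3", 99, 3000, 60, 3270, 320),
    rec("p1", 147, 1116, 60, 1000, -166),
    rec("p2", 147, 2116, 60, 2000, -166),
    rec("dup", 1171, 2616, 60, 2500, -166),
    rec("p3", 147, 3270, 60, 3000, -320)
  )
  writeLines(lines, path)
  path
}
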