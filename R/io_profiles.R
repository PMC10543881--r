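# Fragment-length histograms and their normalized log-profiles.

#' Construct a fragment-length histogram
#'
#' A `length_histogram` stores per-sample fragment counts on a dense,
#' inclusive integer support of lengths in bp. Lengths absent from the
#' input get count zero.
#'
#' @param sample_id Sample identifier.
#' @param counts Named numeric vector of non-negative integer counts; names
#'   are fragment lengths in bp.
#' @param support Inclusive length range `c(lo, hi)`; defaults to the range
#'   of the supplied lengths.
#' @return An object of class `length_histogram` with elements `sample_id`,
#'   `counts` (dense, named by length) and `support`.
#' @export
length_histogram <- function(sample_id, counts, support = NULL) {
  lens <- as.integer(names(counts))
  if (length(lens) == 0L || anyNA(lens)) {
    stop("counts must be named by integer fragment lengths", call. = FALSE)
  }
  if (anyDuplicated(lens)) stop("duplicate fragment length", call. = FALSE)
  if (any(counts < 0)) stop("negative count", call. = FALSE)
  if (is.null(support)) support <- range(lens)
  support <- as.integer(support)
  if (any(lens < support[1L] | lens > support[2L])) {
    stop("length outside declared support", call. = FALSE)
  }
  grid <- support[1L]:support[2L]
  dense <- stats::setNames(numeric(length(grid)), grid)
  dense[as.character(lens)] <- as.numeric(counts)
  if (sum(dense) <= 0) stop("total count must be positive", call. = FALSE)
  structure(
    list(sample_id = as.character(sample_id), counts = dense,
         support = support),
    class = "length_histogram"
  )
}

#' @export
print.length_histogram <- function(x, ...) {
  cat(sprintf("<length_histogram> %s: %d fragments on [%d, %d] bp\n",
              x$sample_id, round(sum(x$counts)), x$support[1L],
              x$support[2L]))
  invisible(x)
}

#' Read a fragment-length histogram from a TSV file
#'
#' Expects two tab-separated columns, `length` and `count`; an optional
#' header line starting with `#` is skipped. Lengths must be unique
#' integers and counts non-negative.
#'
#' @param path Path to the TSV file.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return A [length_histogram()].
#' @export
read_histogram <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty histogram file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  lens <- integer(length(fields))
  cnts <- numeric(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 2L) {
      stop(sprintf("malformed row at line %d of %s", lineno[i], path),
           call. = FALSE)
    }
    l <- suppressWarnings(as.numeric(f[1L]))
    n <- suppressWarnings(as.numeric(f[2L]))
    if (is.na(l) || is.na(n) || l != round(l)) {
      stop(sprintf("malformed row at line %d of %s", lineno[i], path),
           call. = FALSE)
    }
    if (n < 0) {
      stop(sprintf("negative count at line %d of %s", lineno[i], path),
           call. = FALSE)
    }
    lens[i] <- as.integer(l)
    cnts[i] <- n
  }
  if (anyDuplicated(lens)) {
    stop(sprintf("duplicate length at line %d of %s",
                 lineno[anyDuplicated(lens)], path), call. = FALSE)
  }
  length_histogram(sample_id, stats::setNames(cnts, lens))
}

#' Write a fragment-length histogram to a TSV file
#'
#' Inverse of [read_histogram()]: writes `length<TAB>count` rows with a
#' `#length\tcount` header over the full support.
#'
#' @param hist A [length_histogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "length_histogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#length\tcount", con)
  writeLines(sprintf("%s\t%s", names(hist$counts),
                     format(hist$counts, scientific = FALSE, trim = TRUE)),
             con)
  invisible(path)
}

#' Derive a fragment-length histogram from paired-end alignments
#'
#' Counts absolute template lengths (TLEN) of first-in-pair,
#' properly-paired, non-duplicate, primary alignments with mapping quality
#' at least `min_mapq`. Records whose template length falls outside
#' `support` are dropped and their number reported. Requires the
#' \pkg{Rsamtools} package.
#'
#' @param path BAM (or SAM/CRAM convertible via \pkg{Rsamtools}) file.
#' @param min_mapq Minimum mapping quality (default 30).
#' @param support Inclusive length range retained, default `c(50, 400)` bp.
#' @param sample_id Sample identifier; defaults to the file name.
#' @return A [length_histogram()].
#' @export
histogram_from_alignments <- function(path, min_mapq = 30,
                                      support = c(50L, 400L),
                                      sample_id = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("histogram_from_alignments requires the Rsamtools package",
         call. = FALSE)
  }
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  flag <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isProperPair = TRUE, isFirstMateRead = TRUE,
    isSecondaryAlignment = FALSE, isDuplicate = FALSE,
    isNotPassingQualityControls = FALSE
  )
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("isize", "mapq"))
  rec <- Rsamtools::scanBam(path, param = param)[[1L]]
  mapq <- rec$mapq
  tlen <- abs(rec$isize)
  ok <- !is.na(tlen) & !is.na(mapq) & mapq >= min_mapq
  tlen <- tlen[ok]
  inside <- tlen >= support[1L] & tlen <= support[2L]
  n_out <- sum(!inside)
  if (n_out > 0L) {
    message(n_out, " template length(s) outside [", support[1L], ", ",
            support[2L], "] bp dropped")
  }
  tlen <- tlen[inside]
  if (length(tlen) == 0L) {
    warning("no alignments retained after filtering", call. = FALSE)
    grid <- support[1L]:support[2L]
    return(structure(
      list(sample_id = as.character(sample_id),
           counts = stats::setNames(numeric(length(grid)), grid),
           support = as.integer(support)),
      class = "length_histogram"
    ))
  }
  tab <- table(factor(tlen, levels = support[1L]:support[2L]))
  length_histogram(sample_id, stats::setNames(as.numeric(tab), names(tab)),
                   support = support)
}

#' Normalize a histogram to a log fragment-length profile
#'
#' Converts counts to proportions over the full recorded support after
#' adding a pseudocount to every bin, and stores their natural logarithm.
#' The pseudocount keeps the log transform finite when bins are empty; the
#' downstream detrending and wavelet steps operate on `logp`.
#'
#' @param hist A [length_histogram()].
#' @param pseudocount Non-negative value added to every bin before
#'   normalization (default 0.5). Must be positive if any bin is empty.
#' @return An object of class `fragment_profile` with elements `sample_id`,
#'   `lengths`, `p`, `logp` and `pseudocount`.
#' @export
normalize_histogram <- function(hist, pseudocount = 0.5) {
  stopifnot(inherits(hist, "length_histogram"), pseudocount >= 0)
  cnt <- hist$counts + pseudocount
  if (any(cnt <= 0)) {
    stop("log undefined: zero count with zero pseudocount", call. = FALSE)
  }
  p <- cnt / sum(cnt)
  structure(
    list(sample_id = hist$sample_id,
         lengths = hist$support[1L]:hist$support[2L],
         p = stats::setNames(p, names(hist$counts)),
         logp = stats::setNames(log(p), names(hist$counts)),
         pseudocount = pseudocount),
    class = "fragment_profile"
  )
}

#' @export
print.fragment_profile <- function(x, ...) {
  cat(sprintf("<fragment_profile> %s: [%d, %d] bp, pseudocount %g\n",
              x$sample_id, x$lengths[1L], x$lengths[length(x$lengths)],
              x$pseudocount))
  invisible(x)
}

# Subset the profile's logp to an inclusive bp window, erroring when the
# support does not cover it.
profile_window <- function(profile, lo, hi) {
  stopifnot(inherits(profile, "fragment_profile"))
  lens <- profile$lengths
  if (lens[1L] > lo || lens[length(lens)] < hi) {
    stop(sprintf("profile support must contain [%d, %d] bp", lo, hi),
         call. = FALSE)
  }
  profile$logp[as.character(lo:hi)]
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with columns `sample_id`, `histogram_path`,
#' `label_source` (one of `panel`, `surrogate`, `dilution`, `none`) and
#' `label_value_or_mutation_path` (a numeric label, a mutation-table path
#' for `panel` rows, or a spike-in concentration for `dilution` rows).
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return A data frame with resolved paths.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("sample_id", "histogram_path", "label_source",
            "label_value_or_mutation_path")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(nzchar(p) & !grepl("^/", p) & !grepl("^[0-9.eE+-]+$", p),
           file.path(base, p), p)
  }
  man$histogram_path <- resolve(man$histogram_path)
  man$label_value_or_mutation_path <- resolve(man$label_value_or_mutation_path)
  man
}
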