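#' Construct a binned coverage track
#'
#' A `signal_track` stores fixed-bin, non-negative coverage for one
#' chromosome together with the total mapped-read depth used for
#' depth normalisation.
#'
#' @param chrom Chromosome name.
#' @param bin_size Bin width in bp (> 0).
#' @param values Per-bin coverage, non-negative, one value per bin from
#'   position 0; length must equal `ceiling(chrom_length / bin_size)` when
#'   `chrom_length` is given.
#' @param total_depth Total mapped-read count of the library (> 0).
#' @param chrom_length Optional chromosome length in bp, used to validate
#'   `values` length.
#' @return A `signal_track` object.
#' @export
signal_track <- function(chrom, bin_size, values, total_depth,
                         chrom_length = NULL) {
  stopifnot(length(chrom) == 1, nzchar(chrom))
  if (bin_size <= 0) stop("bin_size must be > 0", call. = FALSE)
  if (any(values < 0)) stop("coverage values must be >= 0", call. = FALSE)
  if (total_depth <= 0) stop("total_depth must be > 0", call. = FALSE)
  if (!is.null(chrom_length) &&
      length(values) != ceiling(chrom_length / bin_size)) {
    stop("values length does not cover the chromosome at this bin size",
         call. = FALSE)
  }
  structure(
    list(chrom = chrom, bin_size = as.integer(bin_size),
         values = as.numeric(values), total_depth = as.numeric(total_depth)),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", x$chrom, "-", length(x$values), "bins of",
      x$bin_size, "bp, depth", format(x$total_depth), "\n")
  invisible(x)
}

#' Depth- and input-normalised log2 ratio track
#'
#' Browser-style normalisation of a ChIP sample against its input control:
#' both tracks are scaled to their sequencing depth, a pseudocount is added,
#' and the per-bin log2 ratio of sample to input is returned.
#' `value_i = log2(((s_i / S) + p) / ((c_i / C) + p))` with depths `S`, `C`
#' and pseudocount `p`, finite everywhere for `p > 0`.
#'
#' @param sample,input_ctrl `signal_track` objects on the same chromosome
#'   with identical binning.
#' @param pseudocount Positive stabiliser added to both depth-scaled rates;
#'   default `1e-6`.
#' @return A `signal_track` whose `values` hold the log2 ratios
#'   (`total_depth` is set to 1; the track is already normalised).
#' @export
normalize_log2_ratio <- function(sample, input_ctrl, pseudocount = 1e-6) {
  stopifnot(inherits(sample, "signal_track"),
            inherits(input_ctrl, "signal_track"))
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  if (sample$chrom != input_ctrl$chrom ||
      sample$bin_size != input_ctrl$bin_size ||
      length(sample$values) != length(input_ctrl$values)) {
    stop("sample and input tracks have mismatched binning", call. = FALSE)
  }
  s <- sample$values / sample$total_depth + pseudocount
  c0 <- input_ctrl$values / input_ctrl$total_depth + pseudocount
  out <- sample
  out$values <- log2(s / c0)
  out$total_depth <- 1
  out
}

#' Strand-oriented TSS metaprofile
#'
#' Averages a (typically log2-ratio) track over windows centred on every TSS
#' in the annotation, flipping minus-strand genes so that positive offsets
#' always point downstream of transcription. This is the per-mark "TSS plot"
#' used to compare enrichment between conditions.
#'
#' @param tracks A single `signal_track` or a list of them, at most one per
#'   chromosome; only genes on covered chromosomes contribute.
#' @param annotation A [genome_annotation()].
#' @param window Half-window in bp around each TSS (default 5000).
#' @param bin Offset bin width in bp (default 100); must divide `window` and
#'   equal the tracks' bin size.
#' @return A tibble with columns `offset` (bp, bin start relative to the
#'   TSS, from `-window` to `window - bin`), `mean_value`, `n_genes`.
#' @export
tss_metaprofile <- function(tracks, annotation, window = 5000, bin = 100) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (inherits(tracks, "signal_track")) tracks <- list(tracks)
  if (window %% bin != 0) {
    stop("window must be a multiple of bin", call. = FALSE)
  }
  chroms <- vapply(tracks, function(t) t$chrom, character(1))
  if (anyDuplicated(chroms)) {
    stop("more than one track for a chromosome", call. = FALSE)
  }
  bad <- vapply(tracks, function(t) t$bin_size != bin, logical(1))
  if (any(bad)) {
    stop("track bin size must equal the profile bin", call. = FALSE)
  }
  names(tracks) <- chroms
  genes <- annotation$genes[annotation$genes$chrom %in% chroms, ]
  if (nrow(genes) == 0) {
    stop("no TSS on the chromosomes covered by the tracks", call. = FALSE)
  }
  nb <- 2L * window %/% bin
  acc <- matrix(NA_real_, nrow = nrow(genes), ncol = nb)
  for (i in seq_len(nrow(genes))) {
    tr <- tracks[[genes$chrom[i]]]
    offsets <- seq(-window, window - bin, by = bin)
    if (genes$strand[i] == "-") {
      # downstream of a minus-strand TSS lies at lower genomic coordinates
      gpos <- genes$tss[i] - offsets - bin + 1
    } else {
      gpos <- genes$tss[i] + offsets
    }
    bin_idx <- floor(gpos / bin) + 1
    ok <- bin_idx >= 1 & bin_idx <= length(tr$values)
    acc[i, ok] <- tr$values[bin_idx[ok]]
  }
  tibble::tibble(
    offset = seq(-window, window - bin, by = bin),
    mean_value = colMeans(acc, na.rm = TRUE),
    n_genes = colSums(!is.na(acc))
  )
}
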