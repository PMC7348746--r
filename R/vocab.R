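#' Controlled vocabularies for the two-age, two-group design
#'
#' The pipeline is defined on a fixed 2x2 design: islets sampled at 2 and 10
#' weeks of age from control and growth-restricted (IUGR) animals, assayed
#' for three histone marks. Condition labels are `"<age>_<group>"` and their
#' canonical order (2wk control, 2wk IUGR, 10wk control, 10wk IUGR) fixes the
#' order of bivalency state vectors.
#'
#' @return Character vectors of the valid labels.
#' @export
histone_marks <- function() c("H3K4me3", "H3K27me3", "H3K27Ac")

#' @rdname histone_marks
#' @export
design_ages <- function() c("2wk", "10wk")

#' @rdname histone_marks
#' @export
design_groups <- function() c("control", "IUGR")

#' @rdname histone_marks
#' @export
design_conditions <- function() {
  c("2wk_control", "2wk_IUGR", "10wk_control", "10wk_IUGR")
}

condition_label <- function(age, group) paste(age, group, sep = "_")

check_mark <- function(mark) {
  if (length(mark) != 1L || !mark %in% histone_marks()) {
    stop("unknown histone mark: ", paste(mark, collapse = ", "),
         " (expected one of ", paste(histone_marks(), collapse = ", "), ")",
         call. = FALSE)
  }
  mark
}

check_age <- function(age) {
  if (length(age) != 1L || !age %in% design_ages()) {
    stop("unknown age label: ", paste(age, collapse = ", "),
         " (expected one of ", paste(design_ages(), collapse = ", "), ")",
         call. = FALSE)
  }
  age
}

check_group <- function(group) {
  if (length(group) != 1L || !group %in% design_groups()) {
    stop("unknown group label: ", paste(group, collapse = ", "),
         " (expected one of ", paste(design_groups(), collapse = ", "), ")",
         call. = FALSE)
  }
  group
}

#' Seed a named pseudorandom stream
#'
#' Derives a deterministic 32-bit seed from a master seed and a stream name,
#' so each synthetic artifact type (annotation, peaks, expression, motifs)
#' draws from its own stream and adding genes to one artifact does not
#' reshuffle another.
#'
#' @param seed Master integer seed.
#' @param stream Stream name (character scalar).
#' @return An integer seed below 2^31.
#' @keywords internal
stream_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 10007L
  (abs(as.integer(seed)) %% 100000L) * 10007L + as.integer(h)
}

with_stream <- function(seed, stream, code) {
  withr::with_seed(stream_seed(seed, stream), code)
}
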