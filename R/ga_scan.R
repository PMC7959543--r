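# Sliding-window GA-content profiling of a 3'UTR sequence and calling of
# GA-rich regions, used to position antisense oligonucleotides against
# localization elements.

#' Sliding-window GA content of a nucleotide sequence
#'
#' For every fully contained window of `window_nt` bases (step 1), the
#' percent of G plus A bases is reported: 100 * (#G + #A) / window_nt.
#' U is treated as T; N counts as neither G nor A (it still occupies a
#' window position). Positions are 0-based window start indices.
#'
#' @param sequence nucleotide string over A, C, G, T, U, N
#'   (case-insensitive), or a length-1 `Biostrings::DNAStringSet` /
#'   `DNAString`.
#' @param window_nt window size in nucleotides (default 30).
#' @return a `ga_profile`: data.frame with `position` (0-based window
#'   start) and `percent_ga`; attribute `window_nt`.
#' @export
ga_window_profile <- function(sequence, window_nt = 30L) {
  sequence <- as_sequence_string(sequence)
  window_nt <- as.integer(window_nt)
  stopifnot(window_nt >= 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "U", "N"))
  if (length(bad) > 0L)
    stop("invalid character '", chars[bad[1L]], "' at position ", bad[1L] - 1L,
         " (0-based)")
  n <- length(chars)
  if (n < window_nt)
    stop("sequence length ", n, " is shorter than the window (", window_nt, " nt)")
  is_ga <- as.integer(chars %in% c("G", "A"))
  cs <- c(0L, cumsum(is_ga))
  starts <- 0:(n - window_nt)
  counts <- cs[starts + window_nt + 1L] - cs[starts + 1L]
  out <- data.frame(position = starts, percent_ga = 100 * counts / window_nt)
  attr(out, "window_nt") <- window_nt
  class(out) <- c("ga_profile", "data.frame")
  out
}

as_sequence_string <- function(sequence) {
  if (inherits(sequence, "DNAStringSet") || inherits(sequence, "RNAStringSet")) {
    if (length(sequence) != 1L) stop("expected a single sequence")
    sequence <- sequence[[1L]]
  }
  if (inherits(sequence, "XString")) sequence <- as.character(sequence)
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single character string")
  sequence
}

#' Call GA-rich regions from a window profile
#'
#' Maximal runs of consecutive windows at or above the GA-percent threshold
#' are converted to sequence coordinates (start of the first window to end
#' of the last, 0-based half-open), merged where they overlap, and filtered
#' by minimum span.
#'
#' @param profile a [ga_window_profile] result.
#' @param threshold_percent GA-percent threshold (0-100).
#' @param min_span_nt minimum interval span retained.
#' @return data.frame with `start`, `end` (0-based half-open) and
#'   `max_percent_ga` within each region.
#' @export
call_ga_rich_regions <- function(profile, threshold_percent = 60,
                                 min_span_nt = 0L) {
  stopifnot(threshold_percent >= 0, threshold_percent <= 100)
  w <- attr(profile, "window_nt")
  hit <- profile$percent_ga >= threshold_percent
  empty <- data.frame(start = integer(0), end = integer(0),
                      max_percent_ga = numeric(0))
  if (!any(hit)) return(empty)
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  iv <- data.frame(start = profile$position[starts[runs]],
                   end = profile$position[ends[runs]] + w)
  # merge runs whose sequence-coordinate spans overlap or touch
  merged <- iv[1L, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    j <- nrow(merged)
    if (iv$start[i] <= merged$end[j]) {
      merged$end[j] <- max(merged$end[j], iv$end[i])
    } else {
      merged <- rbind(merged, iv[i, ])
    }
  }
  merged$max_percent_ga <- vapply(seq_len(nrow(merged)), function(i) {
    sel <- profile$position >= merged$start[i] & profile$position + w <= merged$end[i]
    max(profile$percent_ga[sel & hit])
  }, numeric(1L))
  merged <- merged[merged$end - merged$start >= min_span_nt, , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}
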