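#' @keywords internal
"_PACKAGE"

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

VALID_FRAMES <- c("+1", "+2", "+3", "-1", "-2", "-3")

#' Normalise reading-frame labels
#'
#' Different upstream tools write frames as `+2`, `2`, `F2`, `-3`, `R3` and
#' similar. All labels are normalised onto `{+1,+2,+3,-1,-2,-3}` on ingest so
#' that frame comparisons across sources are exact. `NA` (protein records)
#' passes through unchanged.
#'
#' @param frame character or integer vector of frame labels.
#' @return character vector over `+1..+3`, `-1..-3`, with `NA` preserved.
#' @export
normalize_frame <- function(frame) {
  if (is.numeric(frame)) {
    out <- ifelse(is.na(frame), NA_character_,
                  sprintf("%+d", as.integer(frame)))
  } else {
    f <- toupper(trimws(as.character(frame)))
    f <- sub("^F", "+", f)
    f <- sub("^R", "-", f)
    f <- ifelse(grepl("^[123]$", f), paste0("+", f), f)
    out <- f
  }
  bad <- !is.na(out) & !(out %in% VALID_FRAMES)
  if (any(bad)) {
    stop("invalid frame label(s): ", paste(unique(out[bad]), collapse = ", "))
  }
  out
}

# key used throughout for (sequence, frame) identity; NA frame -> "."
seq_frame_key <- function(sequence_id, frame) {
  paste(sequence_id, ifelse(is.na(frame), ".", frame), sep = "\r")
}

# draw one integer uniformly from [lo, hi]; safe when lo == hi
# (sample(5, 1) would draw from 1:5)
sample_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  as.integer(sample(seq.int(lo, hi), 1L))
}

# round half away from zero (base round() is round-half-even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stopifnot_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single proportion in [0, 1]", name))
  }
  invisible(x)
}
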