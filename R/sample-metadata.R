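#' Construct a sample metadata table
#'
#' Phenotype table with one row per biological sample. The binary covariate
#' `time2` encodes whether the day of the menstrual cycle is at most 20
#' (value 0) or greater than 20 (value 1); when `day` is supplied `time2` is
#' derived from it, enforcing that relation.
#'
#' @param sample_id unique sample identifiers.
#' @param day integer day of the menstrual cycle, or `NA`.
#' @param phase categorical phase label (e.g. canonical phases 3, 4, 5);
#'   stored as a factor.
#' @param time2 optional 0/1 vector; required if `day` is absent and ignored
#'   (recomputed) where `day` is present.
#' @return a `data.frame` of class `SampleMetadata` with columns
#'   `sample_id`, `day`, `time2`, `phase`.
#' @export
sample_metadata <- function(sample_id, day = NA_integer_, phase = NA,
                            time2 = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample identifiers", call. = FALSE)
  n <- length(sample_id)
  day <- rep_len(as.integer(day), n)
  derived <- ifelse(is.na(day), NA_integer_, as.integer(day > 20))
  if (is.null(time2)) {
    time2 <- derived
  } else {
    time2 <- rep_len(as.integer(time2), n)
    time2[!is.na(derived)] <- derived[!is.na(derived)]
  }
  if (any(!is.na(time2) & !(time2 %in% c(0L, 1L))))
    stop("time2 must be binary 0/1", call. = FALSE)
  out <- data.frame(sample_id = sample_id, day = day, time2 = time2,
                    phase = factor(rep_len(phase, n)),
                    stringsAsFactors = FALSE)
  class(out) <- c("SampleMetadata", "data.frame")
  out
}

#' Read sample metadata from a TSV file
#'
#' Expects columns `sample_id` and any of `day`, `phase`, `time2`.
#'
#' @param path path to a tab-separated file with a header.
#' @return a `SampleMetadata` data frame.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!"sample_id" %in% names(df))
    stop("metadata file must have a sample_id column", call. = FALSE)
  sample_metadata(df$sample_id,
                  day = if ("day" %in% names(df)) df$day else NA_integer_,
                  phase = if ("phase" %in% names(df)) df$phase else NA,
                  time2 = if ("time2" %in% names(df)) df$time2 else NULL)
}
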