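#' CSV readers and writers for the assay table dialects
#'
#' All inputs are UTF-8 CSVs with a header row and "." as the decimal
#' mark. The Ct-table dialect has one row per well; replicate wells are
#' repeated rows.
#'
#' @name cli_io_module
NULL

.require_columns <- function(df, required, path) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("'", path, "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Read and validate a qPCR Ct table
#'
#' Required columns: `sample_id`, `target`, `amplicon_length`, `treated`
#' (0/1 or logical), `ct`. Rows with a missing Ct are skipped with a
#' warning that reports how many; a non-numeric Ct or amplicon length is
#' an error naming the offending row.
#'
#' @param path Path to the CSV file.
#' @return A tibble with one row per retained well.
#' @export
load_ct_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  .require_columns(df, c("sample_id", "target", "amplicon_length", "treated", "ct"),
                   path)
  n_in <- nrow(df)
  ct_missing <- is.na(df$ct) | trimws(df$ct) %in% c("", "NA")
  if (any(ct_missing)) {
    warning(sum(ct_missing), " row(s) with missing Ct skipped", call. = FALSE)
    df <- df[!ct_missing, , drop = FALSE]
  }
  rows <- which(!ct_missing)
  ct <- suppressWarnings(as.numeric(df$ct))
  if (any(is.na(ct))) {
    stop("non-numeric Ct at data row ", rows[which(is.na(ct))[1]], call. = FALSE)
  }
  len <- suppressWarnings(as.integer(df$amplicon_length))
  if (any(is.na(len))) {
    stop("non-numeric amplicon_length at data row ", rows[which(is.na(len))[1]],
         call. = FALSE)
  }
  treated <- df$treated %in% c("1", "TRUE", "true", "T")
  bad_flag <- !(df$treated %in% c("0", "1", "TRUE", "FALSE", "true", "false", "T", "F"))
  if (any(bad_flag)) {
    stop("`treated` must be 0/1 or logical; bad value at data row ",
         rows[which(bad_flag)[1]], call. = FALSE)
  }
  .check_ct(ct)
  out <- tibble::tibble(
    sample_id = df$sample_id, target = df$target,
    amplicon_length = len, treated = treated, ct = ct
  )
  attr(out, "n_skipped") <- n_in - nrow(out)
  out
}

#' Write a Ct table in the dialect [load_ct_table()] reads
#'
#' @param ct Ct table (tibble/data.frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  out <- data.frame(
    sample_id = ct$sample_id, target = ct$target,
    amplicon_length = ct$amplicon_length,
    treated = as.integer(ct$treated), ct = ct$ct
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a fluctuation-assay colony-count table
#'
#' Required columns: `culture_id`, `selective_count`, `selective_dilution`,
#' `permissive_count`, `permissive_dilution`. Dilution factors multiply the
#' plate count to recover the per-culture number.
#'
#' @param path Path to the CSV file.
#' @return A tibble with numeric count and dilution columns.
#' @export
load_fluctuation_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("culture_id", "selective_count", "selective_dilution",
                         "permissive_count", "permissive_dilution"), path)
  num_cols <- c("selective_count", "selective_dilution",
                "permissive_count", "permissive_dilution")
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v))) {
      stop("non-numeric ", col, " at data row ", which(is.na(v))[1], call. = FALSE)
    }
    df[[col]] <- v
  }
  tibble::as_tibble(df)
}

#' Build a fluctuation experiment from a loaded count table
#'
#' `Nt` is taken as the mean permissive-plate titer
#' (`permissive_count x permissive_dilution`) across cultures; mutant
#' counts are dilution-corrected selective counts.
#'
#' @param counts A tibble from [load_fluctuation_counts()].
#' @param plating_fraction Fraction of each culture plated selectively.
#' @return A [fluctuation_experiment()].
#' @export
fluctuation_from_table <- function(counts, plating_fraction = 1) {
  mutants <- counts$selective_count * counts$selective_dilution
  Nt <- mean(counts$permissive_count * counts$permissive_dilution)
  fluctuation_experiment(mutants, Nt, plating_fraction)
}

#' Read a mutation-spectrum table
#'
#' Required columns: `condition`, `class`, `count`, `total_sequenced`
#' (constant within a condition). Returns one [mutation_spectrum()] per
#' condition.
#'
#' @param path Path to the CSV file.
#' @return Named list of `mutation_spectrum` objects.
#' @export
load_spectrum_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("condition", "class", "count", "total_sequenced"), path)
  split_df <- split(df, df$condition)
  lapply(split_df, function(d) {
    total <- unique(d$total_sequenced)
    if (length(total) != 1L) {
      stop("`total_sequenced` must be constant within condition '",
           d$condition[1], "'", call. = FALSE)
    }
    mutation_spectrum(d$condition[1], setNames(d$count, d$class), total)
  })
}
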