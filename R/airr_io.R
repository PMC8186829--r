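# AIRR-style rearrangement I/O and UMI-support filtering.
#
# The unit record is one observed unique IGHV-IGHD-IGHJ nucleotide sequence in
# one sequencing replicate, with its UMI (distinct mRNA molecule) and read
# support. Tables follow the AIRR Rearrangement TSV convention; a dialect
# mapping translates foreign column names onto the internal schema.

#' Internal canonical rearrangement columns
#'
#' @return Character vector of mandatory column names.
#' @noRd
.mandatory_cols <- c(
  "sequence_id", "sequence_nt", "v_call", "j_call", "junction_nt",
  "productive", "umi_count", "read_count"
)

.optional_cols <- c("sample_id", "replicate_id", "reading_frame_offset")

#' Default column-name dialect (AIRR Rearrangement)
#'
#' Maps AIRR standard column names onto the internal schema. `duplicate_count`
#' serves as the UMI-count surrogate, as AIRR tools conventionally store the
#' number of distinct molecules there; `consensus_count` maps to read support.
#'
#' @return Named character vector: names are external columns, values internal.
#' @export
airr_dialect <- function() {
  c(
    sequence_id = "sequence_id",
    sequence_alignment = "sequence_nt",
    v_call = "v_call",
    j_call = "j_call",
    junction = "junction_nt",
    productive = "productive",
    duplicate_count = "umi_count",
    consensus_count = "read_count",
    sample_id = "sample_id",
    replicate_id = "replicate_id",
    reading_frame_offset = "reading_frame_offset"
  )
}

#' Read an AIRR-style rearrangement table
#'
#' Reads a tab-separated rearrangement table into the internal schema,
#' applying a column-name dialect and validating nucleotide content. Rows
#' whose sequence or junction contains characters outside A/C/G/T/N are
#' rejected with row-level diagnostics (a warning naming the offending rows).
#'
#' @param path Path to a TSV file.
#' @param dialect Named character vector mapping file column names to internal
#'   names; defaults to [airr_dialect()]. Identity-named internal columns are
#'   always accepted.
#' @return A tibble of rearrangements with columns `sequence_id`,
#'   `sequence_nt`, `v_call`, `j_call`, `junction_nt`, `productive` (logical),
#'   `umi_count`, `read_count` (integer) and any optional columns present.
#' @export
read_rearrangements <- function(path, dialect = airr_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) {
    warning("empty rearrangement file: ", path)
    return(empty_rearrangements())
  }
  # apply dialect; identity mapping for already-internal names
  nm <- names(df)
  mapped <- ifelse(nm %in% names(dialect), unname(dialect[nm]), nm)
  names(df) <- mapped
  missing <- setdiff(.mandatory_cols, names(df))
  if (length(missing) > 0) {
    stop("rearrangement table missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- as_tibble(df[, intersect(c(.mandatory_cols, .optional_cols), names(df))])
  if (nrow(df) == 0) {
    warning("rearrangement file has a header but no rows: ", path)
    return(coerce_rearrangements(df))
  }
  df <- coerce_rearrangements(df)
  bad <- !grepl("^[ACGTN]*$", df$sequence_nt) | !grepl("^[ACGTN]*$", df$junction_nt)
  if (any(bad)) {
    warning("rejected ", sum(bad), " row(s) with unparseable nucleotides: rows ",
            paste(utils::head(which(bad), 10L), collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  df
}

#' @noRd
coerce_rearrangements <- function(df) {
  df$sequence_nt <- toupper(df$sequence_nt)
  df$junction_nt <- toupper(df$junction_nt)
  df$productive <- df$productive %in% c("TRUE", "T", "true", "1")
  df$umi_count <- as.integer(df$umi_count)
  df$read_count <- as.integer(df$read_count)
  if ("reading_frame_offset" %in% names(df)) {
    df$reading_frame_offset <- as.integer(df$reading_frame_offset)
  }
  df
}

#' @noRd
empty_rearrangements <- function() {
  tibble(
    sequence_id = character(), sequence_nt = character(),
    v_call = character(), j_call = character(), junction_nt = character(),
    productive = logical(), umi_count = integer(), read_count = integer()
  )
}

#' Write a rearrangement table
#'
#' Writes records as a tab-separated AIRR-style file with a header row and a
#' stable column order; lossless for all fields, so `read_rearrangements()`
#' recovers the input exactly.
#'
#' @param records Rearrangement tibble (see [read_rearrangements()]).
#' @param path Output path.
#' @param dialect Dialect used to rename internal columns back to the external
#'   convention on disk.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(records, path, dialect = airr_dialect()) {
  ord <- c(.mandatory_cols, intersect(.optional_cols, names(records)))
  out <- records[, ord, drop = FALSE]
  rev_map <- setNames(names(dialect), unname(dialect))
  names(out) <- ifelse(names(out) %in% names(rev_map), rev_map[names(out)], names(out))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Filter unique sequences by UMI and read support
#'
#' Retains sequences observed with at least `min_umis` distinct UMIs and
#' adequate read support, the error-correction bar applied before any
#' intraclonal analysis. Read support is assessed per UMI when a
#' `umi_read_counts` list-column (integer reads per UMI consensus) is present:
#' every counted UMI must derive from at least `min_reads_per_umi` reads.
#' With only an aggregate `read_count`, the record must carry at least
#' `min_umis * min_reads_per_umi` reads.
#'
#' @param records Rearrangement tibble.
#' @param min_umis Minimum number of distinct UMIs (default 3).
#' @param min_reads_per_umi Minimum reads behind each UMI consensus (default 5).
#' @param verbose Report the number of discarded records.
#' @return Filtered tibble; the number discarded is attached as attribute
#'   `n_discarded`.
#' @export
filter_by_umi_support <- function(records, min_umis = 3L, min_reads_per_umi = 5L,
                                  verbose = FALSE) {
  if (min_umis < 0 || min_reads_per_umi < 0) {
    stop("thresholds must be non-negative")
  }
  if (nrow(records) == 0) return(records)
  if ("umi_read_counts" %in% names(records)) {
    keep <- vapply(seq_len(nrow(records)), function(i) {
      rc <- records$umi_read_counts[[i]]
      length(rc) >= min_umis && all(rc >= min_reads_per_umi)
    }, logical(1))
  } else {
    keep <- records$umi_count >= min_umis &
      records$read_count >= min_umis * min_reads_per_umi
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "n_discarded") <- sum(!keep)
  if (verbose) {
    message("filter_by_umi_support: discarded ", sum(!keep), " of ",
            nrow(records), " records")
  }
  out
}

#' Read germline reference sequences from FASTA
#'
#' @param path FASTA file of IGHV (or full V(D)J) germline sequences.
#' @return Named character vector of uppercase nucleotide sequences.
#' @export
read_germline_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}
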