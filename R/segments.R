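# Segment-record interchange: tab-separated tables of called (or planted)
# IBD segments, one row per (haplotype pair, maximal span).

segment_cols <- c("id_a", "id_b", "hap_a", "hap_b", "chrom",
                  "start_bp", "end_bp", "start_marker", "end_marker",
                  "length_cm")

segment_header_comment <- paste0(
  "# IBD segment records. Marker span is half-open [start_marker, ",
  "end_marker); start_bp/end_bp are the positions of the first and last ",
  "matching marker (inclusive); length_cm = cm(last) - cm(first).")

#' Empty segment table
#'
#' @return A zero-row data frame with the canonical segment columns.
#' @export
empty_segments <- function() {
  data.frame(id_a = character(), id_b = character(),
             hap_a = integer(), hap_b = integer(),
             chrom = character(),
             start_bp = integer(), end_bp = integer(),
             start_marker = integer(), end_marker = integer(),
             length_cm = double(),
             stringsAsFactors = FALSE)
}

# Coerce and validate a segment table. Haplotypes are 0/1; marker columns may
# be NA only on the lenient path used by the GERMLINE .match adapter.
as_segments <- function(df, allow_na_markers = FALSE) {
  if (!all(segment_cols %in% names(df))) {
    stop("segment table must have columns: ",
         paste(segment_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[segment_cols]
  df$id_a <- as.character(df$id_a)
  df$id_b <- as.character(df$id_b)
  df$hap_a <- as.integer(df$hap_a)
  df$hap_b <- as.integer(df$hap_b)
  df$chrom <- as.character(df$chrom)
  df$start_bp <- as.integer(df$start_bp)
  df$end_bp <- as.integer(df$end_bp)
  df$start_marker <- as.integer(df$start_marker)
  df$end_marker <- as.integer(df$end_marker)
  df$length_cm <- as.double(df$length_cm)
  if (nrow(df)) {
    if (anyNA(df$id_a) || anyNA(df$id_b) || !all(nzchar(df$id_a)) ||
        !all(nzchar(df$id_b))) {
      stop("segment ids must be non-empty", call. = FALSE)
    }
    if (!all(df$hap_a %in% c(0L, 1L)) || !all(df$hap_b %in% c(0L, 1L))) {
      stop("haplotype codes must be 0 or 1", call. = FALSE)
    }
    if (anyNA(df$start_bp) || anyNA(df$end_bp) ||
        any(df$end_bp < df$start_bp)) {
      stop("segment bp span must satisfy end_bp >= start_bp", call. = FALSE)
    }
    mk_na <- is.na(df$start_marker) | is.na(df$end_marker)
    if (any(mk_na) && !allow_na_markers) {
      stop("segment marker span must not be NA", call. = FALSE)
    }
    ok <- mk_na | (df$end_marker > df$start_marker)
    if (!all(ok)) {
      stop("marker span is half-open and must satisfy end_marker > ",
           "start_marker", call. = FALSE)
    }
    if (anyNA(df$length_cm) || any(df$length_cm <= 0)) {
      stop("length_cm must be positive", call. = FALSE)
    }
  }
  rownames(df) <- NULL
  df
}

#' Canonicalize segment pair order
#'
#' Enforces the fixed total order on haplotype pairs: `id_a < id_b`
#' lexicographically, and for within-individual (self-IBD) records
#' `hap_a < hap_b`. Merging and comparison rely on this canonical form.
#'
#' @param df A segment table.
#' @return The table with `a`/`b` columns swapped where needed.
#' @export
canonicalize_segments <- function(df) {
  df <- as_segments(df, allow_na_markers = TRUE)
  if (!nrow(df)) return(df)
  swap <- df$id_a > df$id_b | (df$id_a == df$id_b & df$hap_a > df$hap_b)
  if (any(swap)) {
    tmp_id <- df$id_a[swap]; df$id_a[swap] <- df$id_b[swap]
    df$id_b[swap] <- tmp_id
    tmp_h <- df$hap_a[swap]; df$hap_a[swap] <- df$hap_b[swap]
    df$hap_b[swap] <- tmp_h
  }
  df
}

# Deterministic total order for segment tables.
sort_segments <- function(df) {
  if (!nrow(df)) return(df)
  o <- order(df$id_a, df$id_b, df$chrom, df$start_bp, df$end_bp,
             df$hap_a, df$hap_b, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Row keys that are exact for doubles (17 significant digits round-trip).
segment_keys <- function(df) {
  if (!nrow(df)) return(character())
  do.call(paste, c(lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  }), sep = ""))
}

#' Write a segment table as TSV
#'
#' Tab-separated with an explicit header and a leading `#` comment that
#' documents the coordinate conventions. `length_cm` is printed with 17
#' significant digits so the value round-trips bit-exactly.
#'
#' @param df A segment table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(df, path) {
  df <- as_segments(df, allow_na_markers = TRUE)
  lines <- c(segment_header_comment, paste(segment_cols, collapse = "\t"))
  if (nrow(df)) {
    body <- paste(df$id_a, df$id_b, df$hap_a, df$hap_b, df$chrom,
                  df$start_bp, df$end_bp, df$start_marker, df$end_marker,
                  sprintf("%.17g", df$length_cm), sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a segment TSV
#'
#' Rows are validated field-by-field; a malformed row raises an error naming
#' the file and line. Pair order is canonicalized on read.
#'
#' @param path Path to a TSV written by [write_segments()] (or compatible).
#' @param allow_na_markers Accept `NA` marker indices (used for records
#'   imported from formats that do not carry marker indices).
#' @return A canonicalized segment table.
#' @export
read_segments <- function(path, allow_na_markers = FALSE) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop(path, ": no header line found", call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, segment_cols)) {
    stop(path, ":", lineno[[1L]], ": unexpected header (expected: ",
         paste(segment_cols, collapse = ", "), ")", call. = FALSE)
  }
  if (length(lines) == 1L) return(empty_segments())
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(segment_cols))) {
    bad <- which(nf != length(segment_cols))[[1L]]
    stop(path, ":", lineno[-1L][bad], ": expected ",
         length(segment_cols), " fields, got ", nf[bad], call. = FALSE)
  }
  mat <- matrix(unlist(fields), ncol = length(segment_cols), byrow = TRUE)
  colnames(mat) <- segment_cols
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  num_cols <- c("hap_a", "hap_b", "start_bp", "end_bp",
                "start_marker", "end_marker", "length_cm")
  for (cc in num_cols) {
    raw <- df[[cc]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- is.na(val) & !(raw %in% c("NA", ""))
    if (any(bad)) {
      stop(path, ":", lineno[-1L][which(bad)[[1L]]],
           ": non-numeric value in column ", cc, call. = FALSE)
    }
    df[[cc]] <- val
  }
  canonicalize_segments(as_segments(df, allow_na_markers = allow_na_markers))
}

#' Merge per-subset segment result files
#'
#' Concatenates the result tables of independent subset runs, canonicalizes
#' pair order, and sorts deterministically by `(id_a, id_b, chrom,
#' start_bp)`. Under exact-once pair coverage no segment can be called in two
#' subset runs, so no cross-file stitching is needed and identical duplicate
#' rows indicate a coverage violation: they trigger a warning and one copy is
#' kept.
#'
#' @param result_files Character vector of TSV paths from [write_segments()].
#' @return A single canonical, sorted segment table.
#' @export
merge_results <- function(result_files) {
  if (!length(result_files)) return(empty_segments())
  tables <- lapply(result_files, read_segments)
  merged <- do.call(rbind, tables)
  merged <- sort_segments(canonicalize_segments(merged))
  dup <- duplicated(merged)
  if (any(dup)) {
    warning(sum(dup), " identical segment record(s) found in more than one ",
            "result file; this should be impossible under exact-once pair ",
            "coverage - check the design. Keeping one copy.", call. = FALSE)
    merged <- merged[!dup, , drop = FALSE]
    rownames(merged) <- NULL
  }
  merged
}

#' Import a GERMLINE .match file
#'
#' Column-mapping adapter for the classic 15-column GERMLINE `.match` layout
#' (family/individual id pairs, chromosome, bp span, flanking SNP ids, SNP
#' count, length, unit, mismatches, two homozygosity flags). Haplotype codes
#' are taken from trailing `.0`/`.1` suffixes on the individual ids when
#' present (GERMLINE's haploid extension) and default to 0 otherwise. Marker
#' indices are not carried by `.match` files and are imported as `NA`.
#'
#' @param path Path to a `.match` file. The length unit must be `cM`.
#' @return A canonicalized segment table.
#' @export
read_germline_match <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 15L) {
    stop(path, ": expected 15 columns in GERMLINE .match format, got ",
         ncol(df), call. = FALSE)
  }
  names(df) <- c("fam_a", "id_a", "fam_b", "id_b", "chrom",
                 "start_bp", "end_bp", "snp_start", "snp_end", "n_snps",
                 "length", "unit", "mismatches", "hom_a", "hom_b")
  if (nrow(df) && !all(df$unit == "cM")) {
    stop(path, ": segment lengths must be in cM (unit column)", call. = FALSE)
  }
  split_hap <- function(id) {
    has <- grepl("\\.[01]$", id)
    hap <- integer(length(id))
    hap[has] <- as.integer(substring(id[has], nchar(id[has])))
    list(id = sub("\\.[01]$", "", id), hap = hap)
  }
  a <- split_hap(as.character(df$id_a))
  b <- split_hap(as.character(df$id_b))
  out <- data.frame(id_a = a$id, id_b = b$id, hap_a = a$hap, hap_b = b$hap,
                    chrom = as.character(df$chrom),
                    start_bp = df$start_bp, end_bp = df$end_bp,
                    start_marker = NA_integer_, end_marker = NA_integer_,
                    length_cm = df$length, stringsAsFactors = FALSE)
  canonicalize_segments(as_segments(out, allow_na_markers = TRUE))
}
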