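# Deterministic exact-match IBD caller: window hashing to find candidate
# haplotype pairs, then marker-by-marker extension of runs of identity.
# Intentionally simple and exactly deterministic so that full-sample calling
# and merged per-subset calling can be compared bit-for-bit: the property
# under test is the design's (every pair compared exactly once), not the
# caller's accuracy.

#' Caller configuration
#'
#' @param window_markers Markers per seeding window (>= 8). Haplotype pairs
#'   identical across a whole window become extension candidates.
#' @param min_length_cm Minimum genetic length for a reported segment.
#' @param allow_self Report the within-individual haplotype pair (self-IBD)?
#' @return A `caller_config` list.
#' @export
caller_config <- function(window_markers = 75L, min_length_cm = 3.5,
                          allow_self = FALSE) {
  window_markers <- check_count(window_markers, 8L, "window_markers")
  if (!is.numeric(min_length_cm) || length(min_length_cm) != 1L ||
      is.na(min_length_cm) || min_length_cm <= 0) {
    stop("`min_length_cm` must be a positive number", call. = FALSE)
  }
  structure(list(window_markers = window_markers,
                 min_length_cm = as.double(min_length_cm),
                 allow_self = isTRUE(allow_self)),
            class = "caller_config")
}

resolve_samples <- function(panel, samples) {
  if (is.null(samples)) return(seq_len(panel$n))
  if (is.character(samples)) {
    idx <- match(samples, panel$sample_ids)
    if (anyNA(idx)) {
      stop("unknown sample ID(s): ",
           paste(samples[is.na(idx)], collapse = ", "), call. = FALSE)
    }
  } else if (is.numeric(samples)) {
    if (anyNA(samples) || any(samples < 1L) || any(samples > panel$n) ||
        any(samples != trunc(samples))) {
      stop("sample indices must be in 1 ... n", call. = FALSE)
    }
    idx <- as.integer(samples)
  } else {
    stop("`samples` must be sample IDs or indices", call. = FALSE)
  }
  if (anyDuplicated(idx)) stop("duplicate samples in subset", call. = FALSE)
  sort.int(idx, method = "radix")
}

#' Call IBD segments by exact-match window hashing
#'
#' Markers are partitioned into consecutive windows of `window_markers`
#' markers; within each full window, haplotypes with identical window
#' content are grouped (a trailing partial window never seeds, but
#' participates in extension). Every within-group haplotype pair is a
#' candidate; for each candidate the maximal runs of consecutive identical
#' markers are computed, and a run is reported when it fully contains at
#' least one window-aligned seed window and its genetic length reaches
#' `min_length_cm`. The output for a pair depends only on that pair's two
#' haplotypes and the configuration (pairwise locality), which is what makes
#' subset-parallel calling exactly equivalent to full-sample calling.
#'
#' Marker spans are half-open (`[start_marker, end_marker)`); bp bounds are
#' the positions of the first and last matching marker.
#'
#' @param panel A `haplotype_panel`.
#' @param samples Sample IDs or indices to restrict to (`NULL` = all).
#' @param config A [caller_config()].
#' @return A canonical, sorted segment table.
#' @export
call_ibd <- function(panel, samples = NULL, config = caller_config()) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(config, "caller_config"))
  idx <- resolve_samples(panel, samples)
  if (length(idx) == 0L) return(empty_segments())
  if (length(idx) == 1L && !config$allow_self) return(empty_segments())
  H <- panel$haplotypes
  m <- panel$m
  W <- config$window_markers
  nfull <- m %/% W
  if (nfull == 0L) return(empty_segments())
  hap_rows <- sort.int(c(2L * idx - 1L, 2L * idx))

  # seed discovery: haplotype pairs sharing at least one full window
  pair_chunks <- vector("list", nfull)
  for (w in seq_len(nfull)) {
    cols <- ((w - 1L) * W + 1L):(w * W)
    key <- apply(H[hap_rows, cols, drop = FALSE], 1L, paste, collapse = "")
    grp <- split(hap_rows, key)
    grp <- grp[lengths(grp) >= 2L]
    if (length(grp)) {
      pair_chunks[[w]] <- do.call(cbind, lapply(grp, combn, m = 2L))
    }
  }
  pm <- do.call(cbind, pair_chunks)
  if (is.null(pm) || ncol(pm) == 0L) return(empty_segments())
  pm <- unique(t(pm))  # rows (a, b) with a < b (groups were sorted)

  ind_a <- hap_to_ind(pm[, 1]); ind_b <- hap_to_ind(pm[, 2])
  keep <- ind_a != ind_b | config$allow_self
  pm <- pm[keep, , drop = FALSE]
  if (nrow(pm) == 0L) return(empty_segments())

  map <- panel$map_cm
  pos <- panel$positions_bp
  seed_limit <- nfull * W
  out <- vector("list", nrow(pm))
  for (q in seq_len(nrow(pm))) {
    a <- pm[q, 1]; b <- pm[q, 2]
    r <- rle(H[a, ] == H[b, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segs <- NULL
    for (t in which(r$values)) {
      s <- starts[t]; e <- ends[t]
      ws <- ((s - 1L + W - 1L) %/% W) * W + 1L  # first aligned window >= s
      if (ws + W - 1L > min(e, seed_limit)) next  # no full seed window inside
      len <- map[e] - map[s]
      if (len < config$min_length_cm) next
      ia <- hap_to_ind(a); ib <- hap_to_ind(b)
      segs <- rbind(segs, data.frame(
        id_a = panel$sample_ids[ia], id_b = panel$sample_ids[ib],
        hap_a = hap_code(a), hap_b = hap_code(b),
        chrom = panel$chrom,
        start_bp = pos[s], end_bp = pos[e],
        start_marker = s, end_marker = e + 1L,
        length_cm = len, stringsAsFactors = FALSE))
    }
    out[[q]] <- segs
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty_segments())
  sort_segments(canonicalize_segments(res))
}

#' Check full-sample vs merged subset-parallel equivalence
#'
#' Runs the caller once on the full sample, then once per design subset
#' (self-comparisons, when enabled, only on subsets that allow them), writes
#' each subset's result as a TSV, merges them with [merge_results()], and
#' compares the two record sets. Because each unordered pair of individuals
#' co-occurs in exactly one subset and the caller is pairwise-local and
#' deterministic, the two sets must be identical — every record present in
#' one and not the other is reported.
#'
#' @param panel A `haplotype_panel`.
#' @param design A `partition_design` with `design$n == panel$n`.
#' @param config A [caller_config()].
#' @param work_dir Directory for the per-subset result files (default: a
#'   fresh temporary directory).
#' @return An `equivalence_report`: list with `equal`, `n_full`, `n_merged`,
#'   `missing_in_merged`, `extra_in_merged`, and `work_dir`.
#' @export
equivalence_check <- function(panel, design, config = caller_config(),
                              work_dir = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(design, "partition_design"))
  if (design$n != panel$n) {
    stop("design is for n = ", design$n, " but panel has n = ", panel$n,
         call. = FALSE)
  }
  work_dir <- work_dir %||% tempfile("pairplan_eq_")
  dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)

  full <- call_ibd(panel, NULL, config)

  prov <- design$provenance
  files <- character(0)
  width <- nchar(as.character(max(prov$subset_id)))
  for (pos in seq_along(design$subsets)) {
    members <- design$subsets[[pos]]
    allow <- config$allow_self && prov$allows_self_comparison[pos]
    if (length(members) < 2L && !(allow && length(members) >= 1L)) next
    cfg <- config
    cfg$allow_self <- allow
    res <- call_ibd(panel, members, cfg)
    f <- file.path(work_dir,
                   sprintf("subset_%0*d.tsv", width, prov$subset_id[pos]))
    write_segments(res, f)
    files <- c(files, f)
  }
  merged <- merge_results(files)

  kf <- segment_keys(full)
  km <- segment_keys(merged)
  missing <- full[!(kf %in% km), , drop = FALSE]
  extra <- merged[!(km %in% kf), , drop = FALSE]
  rownames(missing) <- rownames(extra) <- NULL
  structure(
    list(equal = nrow(missing) == 0L && nrow(extra) == 0L &&
           nrow(full) == nrow(merged),
         n_full = nrow(full), n_merged = nrow(merged),
         missing_in_merged = missing, extra_in_merged = extra,
         work_dir = work_dir),
    class = "equivalence_report"
  )
}

#' @export
print.equivalence_report <- function(x, ...) {
  cat("Subset-parallel equivalence check\n")
  cat("  full-sample records:  ", x$n_full, "\n")
  cat("  merged subset records:", x$n_merged, "\n")
  if (x$equal) {
    cat("  PASS: record sets are identical\n")
  } else {
    cat("  FAIL:", nrow(x$missing_in_merged), "record(s) missing from the",
        "merge,", nrow(x$extra_in_merged), "extra\n")
    if (nrow(x$missing_in_merged)) {
      cat("  missing (first few):\n")
      print(head(x$missing_in_merged[, c("id_a", "id_b", "hap_a", "hap_b",
                                         "length_cm")], 5L))
    }
  }
  invisible(x)
}
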