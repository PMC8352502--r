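# Scatter side of the workflow: per-subset keep-files (one sample ID per
# line, PLINK --keep compatible) and batched job manifests (JSON).

#' Write per-subset keep-files
#'
#' One plain-text file per emitted subset, one sample ID per line in member
#' order, named `subset_<id>.keep` with the 0-based subset id zero-padded.
#' External pairwise tools (GERMLINE, hap-IBD, PLINK `--keep`) can consume
#' these unchanged to restrict a run to one subset. Subsets with fewer than
#' two members after null-cell removal define no pairwise work; they are
#' skipped with a message so that job counts stay honest.
#'
#' @param design A `partition_design`.
#' @param ids Character vector of exactly `n` unique, non-empty sample IDs;
#'   line `l` of an external ID list maps to individual `l`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths (names are 0-based subset
#'   ids, as characters), one per emitted subset, invisibly.
#' @export
write_keep_files <- function(design, ids, out_dir) {
  stopifnot(inherits(design, "partition_design"))
  ids <- as.character(ids)
  if (length(ids) != design$n) {
    stop("`ids` must have exactly n = ", design$n, " entries (got ",
         length(ids), ")", call. = FALSE)
  }
  if (anyNA(ids) || !all(nzchar(trimws(ids)))) {
    stop("`ids` must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("`ids` must be unique (duplicate: ",
         ids[anyDuplicated(ids)], ")", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- design$provenance
  emit <- prov$size >= 2L
  if (any(!emit)) {
    message(sum(!emit), " subset(s) with fewer than 2 members skipped: ",
            paste(prov$subset_id[!emit], collapse = ", "))
  }
  width <- nchar(as.character(max(prov$subset_id)))
  paths <- character(0)
  for (pos in which(emit)) {
    sid <- prov$subset_id[pos]
    path <- file.path(out_dir, sprintf("subset_%0*d.keep", width, sid))
    writeLines(ids[design$subsets[[pos]]], path)
    paths[as.character(sid)] <- path
  }
  invisible(paths)
}

#' Read keep-files back into member index lists
#'
#' Inverse of [write_keep_files()] given the same ID list; used to verify
#' round trips and to re-run the coverage oracle on serialized designs.
#'
#' @param paths Character vector of keep-file paths.
#' @param ids The full sample ID list (line `l` = individual `l`).
#' @return List of sorted integer member vectors, one per file.
#' @export
read_keep_files <- function(paths, ids) {
  ids <- as.character(ids)
  lapply(paths, function(path) {
    found <- readLines(path)
    members <- match(found, ids)
    if (anyNA(members)) {
      stop(path, ": unknown sample ID '", found[which(is.na(members))[1L]],
           "'", call. = FALSE)
    }
    sort.int(members, method = "radix")
  })
}

#' Batch subsets into a job manifest
#'
#' Assigns emitted subsets (those with at least two members) to jobs of
#' `batch_size` subsets each, in subset-id order, so that each job is one
#' scheduler submission running `batch_size` independent pairwise-comparison
#' instances. Every emitted subset lands in exactly one job.
#'
#' @param design A `partition_design`.
#' @param batch_size Subsets per job (default 1000).
#' @param keep_files Optional named path vector from [write_keep_files()];
#'   when given, each job also lists its keep-file paths.
#' @param path Optional path; when given the manifest is written as JSON.
#' @return A `job_manifest`: list with `n`, `p`, `batch_size`,
#'   `n_subsets_total`, `n_subsets_emitted`, and `jobs` (each job a list with
#'   `job_id`, `subset_ids`, and optionally `keep_files`).
#' @examples
#' length(write_manifest(enumerate_subsets(25), batch_size = 7)$jobs)  # 5
#' @export
write_manifest <- function(design, batch_size = 1000L, keep_files = NULL,
                           path = NULL) {
  stopifnot(inherits(design, "partition_design"))
  batch_size <- check_count(batch_size, 1L, "batch_size")
  prov <- design$provenance
  emitted <- prov$subset_id[prov$size >= 2L]
  job_of <- ceiling(seq_along(emitted) / batch_size)
  n_jobs <- if (length(emitted)) max(job_of) else 0L
  width <- max(4L, nchar(as.character(n_jobs)))
  jobs <- lapply(seq_len(n_jobs), function(j) {
    sids <- emitted[job_of == j]
    job <- list(job_id = sprintf("job_%0*d", width, j),
                subset_ids = as.integer(sids))
    if (!is.null(keep_files)) {
      kf <- unname(keep_files[as.character(sids)])
      if (anyNA(kf)) {
        stop("`keep_files` is missing paths for some emitted subsets",
             call. = FALSE)
      }
      job$keep_files <- kf
    }
    job
  })
  manifest <- structure(
    list(n = design$n, p = design$p, batch_size = batch_size,
         n_subsets_total = nrow(prov),
         n_subsets_emitted = length(emitted),
         jobs = jobs),
    class = "job_manifest"
  )
  if (!is.null(path)) {
    json_obj <- unclass(manifest)
    # keep length-1 id/path vectors as JSON arrays under auto_unbox
    json_obj$jobs <- lapply(json_obj$jobs, function(job) {
      job$subset_ids <- I(job$subset_ids)
      if (!is.null(job$keep_files)) job$keep_files <- I(job$keep_files)
      job
    })
    jsonlite::write_json(json_obj, path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  manifest
}

#' Read a JSON job manifest
#'
#' @param path Path written by [write_manifest()].
#' @return A `job_manifest` list.
#' @export
read_manifest <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  raw$jobs <- lapply(raw$jobs, function(job) {
    job$subset_ids <- as.integer(unlist(job$subset_ids))
    if (!is.null(job$keep_files)) {
      job$keep_files <- as.character(unlist(job$keep_files))
    }
    job
  })
  raw$n <- as.integer(raw$n)
  raw$p <- as.integer(raw$p)
  raw$batch_size <- as.integer(raw$batch_size)
  raw$n_subsets_total <- as.integer(raw$n_subsets_total)
  raw$n_subsets_emitted <- as.integer(raw$n_subsets_emitted)
  structure(raw, class = "job_manifest")
}

#' @export
print.job_manifest <- function(x, ...) {
  cat("Job manifest: n =", x$n, ", p =", x$p, "\n")
  cat("  ", x$n_subsets_emitted, " emitted subset(s) of ",
      x$n_subsets_total, " total, batch size ", x$batch_size,
      " -> ", length(x$jobs), " job(s)\n", sep = "")
  invisible(x)
}
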