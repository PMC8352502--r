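# Seeded simulator of phased haplotype panels with planted IBD segments.
# Background alleles are independent across markers (linkage-free null);
# planted segments are literal allele copies, so before error injection the
# two haplotypes of a planted pair match exactly over the recorded span.

#' Simulate a phased haplotype panel
#'
#' Each individual carries two phased haplotypes (rows `2i - 1` and `2i` of
#' the haplotype matrix, haplotype codes 0 and 1). Per-marker allele
#' frequencies are drawn uniformly from `maf_range`; alleles are independent
#' Bernoulli draws across markers and haplotypes, so background identity
#' runs long enough to be called as segments essentially never arise.
#' Physical positions are evenly spaced and the genetic map is linear at
#' `cm_per_mb` unless a two-column `(bp, cm)` map is supplied, in which case
#' marker cM values are interpolated piecewise-linearly.
#'
#' @param n Number of individuals (>= 4).
#' @param m Number of markers (>= 100).
#' @param maf_range Length-2 numeric, allele-frequency range in (0, 1).
#' @param cm_per_mb Uniform genetic-map rate (centimorgans per megabase).
#' @param bp_spacing Physical distance between adjacent markers, in bp.
#' @param seed RNG seed; the panel is bit-identical for a given seed.
#' @param genetic_map Optional data frame with columns `bp` and `cm` defining
#'   a piecewise-linear map (overrides `cm_per_mb`).
#' @param sample_ids Optional character vector of `n` unique sample IDs.
#' @param chrom Chromosome label carried into segment records.
#' @return A `haplotype_panel`: list with `n`, `m`, `sample_ids`,
#'   `haplotypes` (`2n x m` 0/1 integer matrix), `positions_bp`, `map_cm`,
#'   `chrom`, and `truth` (segment table of planted ground truth, initially
#'   empty).
#' @examples
#' panel <- simulate_panel(8, 500, seed = 7)
#' dim(panel$haplotypes)  # 16 x 500
#' @export
simulate_panel <- function(n, m, maf_range = c(0.1, 0.5), cm_per_mb = 1,
                           bp_spacing = 5000L, seed,
                           genetic_map = NULL, sample_ids = NULL,
                           chrom = "1") {
  n <- check_count(n, 4L, "n")
  m <- check_count(m, 100L, "m")
  bp_spacing <- check_count(bp_spacing, 1L, "bp_spacing")
  if (length(maf_range) != 2L || !is.numeric(maf_range) ||
      maf_range[1] <= 0 || maf_range[2] >= 1 ||
      maf_range[1] > maf_range[2]) {
    stop("`maf_range` must be increasing within (0, 1)", call. = FALSE)
  }
  if (!is.numeric(cm_per_mb) || length(cm_per_mb) != 1L || cm_per_mb <= 0) {
    stop("`cm_per_mb` must be a positive number", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%0*d", nchar(as.character(n)), seq_len(n))
  } else {
    sample_ids <- as.character(sample_ids)
    if (length(sample_ids) != n || anyDuplicated(sample_ids) ||
        anyNA(sample_ids) || !all(nzchar(sample_ids))) {
      stop("`sample_ids` must be ", n, " unique non-empty strings",
           call. = FALSE)
    }
  }
  positions <- bp_spacing * seq_len(m)
  if (is.null(genetic_map)) {
    map_cm <- positions / 1e6 * cm_per_mb
  } else {
    if (!all(c("bp", "cm") %in% names(genetic_map))) {
      stop("`genetic_map` needs columns `bp` and `cm`", call. = FALSE)
    }
    o <- order(genetic_map$bp)
    gbp <- genetic_map$bp[o]; gcm <- genetic_map$cm[o]
    if (is.unsorted(gcm)) {
      stop("`genetic_map` cm values must be non-decreasing in bp",
           call. = FALSE)
    }
    map_cm <- stats::approx(gbp, gcm, xout = positions, rule = 2)$y
  }
  if (is.unsorted(map_cm)) {
    stop("genetic map must be non-decreasing", call. = FALSE)
  }
  H <- with_seed(seed, {
    freq <- runif(m, maf_range[1], maf_range[2])
    matrix(rbinom(2L * n * m, 1L, rep(freq, each = 2L * n)), nrow = 2L * n)
  })
  rownames(H) <- paste0(rep(sample_ids, each = 2L), "_", c(0L, 1L))
  structure(
    list(n = n, m = m, sample_ids = sample_ids, haplotypes = H,
         positions_bp = as.integer(positions), map_cm = map_cm,
         chrom = as.character(chrom), truth = empty_segments()),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("Phased haplotype panel\n")
  cat("  individuals:", x$n, " (", 2L * x$n, "haplotypes )\n")
  cat("  markers:    ", x$m, " spanning ",
      format(max(x$positions_bp) / 1e6, digits = 4), " Mb / ",
      format(max(x$map_cm) - min(x$map_cm), digits = 4), " cM\n", sep = "")
  cat("  planted truth segments:", nrow(x$truth), "\n")
  invisible(x)
}

# haplotype row index -> (individual, haplotype code)
hap_to_ind <- function(r) (r + 1L) %/% 2L
hap_code <- function(r) 1L - r %% 2L

#' Plant IBD segments into a panel
#'
#' For each requested haplotype pair and genetic length, copies a contiguous
#' allele stretch of genetic length at least `length_cm` from the first
#' haplotype onto the second at a random map location, and records the
#' planted span as ground truth. Placements are resampled so that the
#' written span never overlaps a previously planted span on an already-used
#' haplotype (which would corrupt earlier truth records). Planting on the
#' two haplotypes of one individual is allowed (self-IBD) and exercises the
#' self-comparison rule of the design.
#'
#' @param panel A `haplotype_panel`.
#' @param pairs Two-column matrix/data frame of haplotype row indices in
#'   `1 ... 2n` (source, destination).
#' @param lengths_cm Numeric vector (recycled to `nrow(pairs)`) of requested
#'   genetic lengths.
#' @param seed RNG seed for placement.
#' @return The panel with modified haplotypes and appended `truth` rows.
#' @export
plant_segments <- function(panel, pairs, lengths_cm, seed) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  pairs <- as.matrix(pairs)
  if (!nrow(pairs)) return(panel)
  if (ncol(pairs) != 2L || !is.numeric(pairs) || anyNA(pairs) ||
      any(pairs < 1L) || any(pairs > 2L * panel$n) ||
      any(pairs != trunc(pairs))) {
    stop("`pairs` must be haplotype row indices in 1 ... 2n", call. = FALSE)
  }
  if (any(pairs[, 1] == pairs[, 2])) {
    stop("a haplotype cannot be planted onto itself", call. = FALSE)
  }
  lengths_cm <- rep_len(as.double(lengths_cm), nrow(pairs))
  map <- panel$map_cm
  m <- panel$m
  span_cm <- map[m] - map[1]
  if (any(lengths_cm <= 0)) stop("lengths must be positive", call. = FALSE)
  if (any(lengths_cm > span_cm)) {
    stop("requested segment longer than the chromosome (",
         format(span_cm, digits = 4), " cM)", call. = FALSE)
  }
  used <- vector("list", 2L * panel$n)  # planted spans per haplotype
  for (q in seq_len(nrow(panel$truth))) {
    tr <- panel$truth[q, ]
    ra <- 2L * match(tr$id_a, panel$sample_ids) - 1L + tr$hap_a
    rb <- 2L * match(tr$id_b, panel$sample_ids) - 1L + tr$hap_b
    span <- c(tr$start_marker, tr$end_marker - 1L)
    used[[ra]] <- rbind(used[[ra]], span)
    used[[rb]] <- rbind(used[[rb]], span)
  }
  overlaps <- function(r, s, e) {
    u <- used[[r]]
    !is.null(u) && any(u[, 1] <= e & u[, 2] >= s)
  }
  rows <- vector("list", nrow(pairs))
  with_seed(seed, {
    for (q in seq_len(nrow(pairs))) {
      a <- pairs[q, 1]; b <- pairs[q, 2]; L <- lengths_cm[q]
      s_max <- max(which(map <= map[m] - L))
      placed <- FALSE
      for (attempt in seq_len(1000L)) {
        s <- sample.int(s_max, 1L)
        e <- match(TRUE, map >= map[s] + L)
        if (overlaps(a, s, e) || overlaps(b, s, e)) next
        panel$haplotypes[b, s:e] <- panel$haplotypes[a, s:e]
        used[[a]] <- rbind(used[[a]], c(s, e))
        used[[b]] <- rbind(used[[b]], c(s, e))
        ia <- hap_to_ind(a); ib <- hap_to_ind(b)
        rows[[q]] <- data.frame(
          id_a = panel$sample_ids[ia], id_b = panel$sample_ids[ib],
          hap_a = hap_code(a), hap_b = hap_code(b),
          chrom = panel$chrom,
          start_bp = panel$positions_bp[s], end_bp = panel$positions_bp[e],
          start_marker = s, end_marker = e + 1L,
          length_cm = map[e] - map[s],
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place a ", format(L, digits = 4), " cM segment ",
             "without overlapping earlier plants; chromosome too crowded",
             call. = FALSE)
      }
    }
  })
  panel$truth <- sort_segments(canonicalize_segments(
    rbind(panel$truth, do.call(rbind, rows))))
  panel
}

#' Inject genotyping errors
#'
#' Flips each allele independently with probability `error_rate`. The truth
#' table is left untouched: planted spans remain the ground truth even where
#' errors now interrupt the exact match. Rates are capped below 5%, the
#' regime in which error-tolerant callers operate.
#'
#' @param panel A `haplotype_panel`.
#' @param error_rate Per-allele flip probability in `[0, 0.05)`.
#' @param seed RNG seed.
#' @return The panel with flipped alleles.
#' @export
inject_errors <- function(panel, error_rate, seed) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!is.numeric(error_rate) || length(error_rate) != 1L ||
      is.na(error_rate) || error_rate < 0 || error_rate >= 0.05) {
    stop("`error_rate` must be in [0, 0.05)", call. = FALSE)
  }
  if (error_rate == 0) return(panel)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  flips <- with_seed(seed, {
    matrix(rbinom(length(panel$haplotypes), 1L, error_rate),
           nrow = nrow(panel$haplotypes))
  })
  panel$haplotypes <- (panel$haplotypes + flips) %% 2L
  panel
}

#' Write a panel to plain-text files
#'
#' Writes `<prefix>.haps` (marker rows, haplotype columns, space-separated
#' 0/1, with `#` comment lines recording the chromosome and haplotype column
#' names), `<prefix>.ids` (sample IDs, one per line), `<prefix>.map`
#' (tab-separated `bp`, `cm` per marker), and `<prefix>.truth.tsv` (planted
#' segments, [write_segments()] format).
#'
#' @param panel A `haplotype_panel`.
#' @param prefix Output path prefix.
#' @return Named character vector of the four paths, invisibly.
#' @export
write_panel <- function(panel, prefix) {
  stopifnot(inherits(panel, "haplotype_panel"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- c(haps = paste0(prefix, ".haps"), ids = paste0(prefix, ".ids"),
             map = paste0(prefix, ".map"), truth = paste0(prefix, ".truth.tsv"))
  header <- c(paste0("# chrom=", panel$chrom),
              paste0("# haplotypes: ",
                     paste(rownames(panel$haplotypes), collapse = " ")))
  body <- apply(t(panel$haplotypes), 1L, paste, collapse = " ")
  writeLines(c(header, body), paths[["haps"]])
  writeLines(panel$sample_ids, paths[["ids"]])
  writeLines(c("bp\tcm",
               paste(panel$positions_bp, sprintf("%.17g", panel$map_cm),
                     sep = "\t")),
             paths[["map"]])
  write_segments(panel$truth, paths[["truth"]])
  invisible(paths)
}

#' Read a panel written by [write_panel()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `haplotype_panel`.
#' @export
read_panel <- function(prefix) {
  haps_lines <- readLines(paste0(prefix, ".haps"))
  chrom_line <- grep("^# chrom=", haps_lines, value = TRUE)
  chrom <- if (length(chrom_line)) sub("^# chrom=", "", chrom_line[[1L]]) else "1"
  body <- haps_lines[!startsWith(haps_lines, "#")]
  H <- t(do.call(rbind, lapply(strsplit(body, " ", fixed = TRUE), as.integer)))
  ids <- readLines(paste0(prefix, ".ids"))
  map <- utils::read.delim(paste0(prefix, ".map"))
  truth <- read_segments(paste0(prefix, ".truth.tsv"))
  n <- length(ids)
  if (nrow(H) != 2L * n) {
    stop(prefix, ".haps: expected ", 2L * n, " haplotype columns",
         call. = FALSE)
  }
  rownames(H) <- paste0(rep(ids, each = 2L), "_", c(0L, 1L))
  structure(
    list(n = n, m = ncol(H), sample_ids = ids, haplotypes = H,
         positions_bp = as.integer(map$bp), map_cm = as.double(map$cm),
         chrom = chrom, truth = truth),
    class = "haplotype_panel"
  )
}

#' Export a panel as a minimal phased VCF
#'
#' Writes a VCFv4.2 file with one biallelic record per marker (REF `A`, ALT
#' `C`) and phased genotypes (`0|1` style), suitable as input for external
#' IBD callers that read VCF.
#'
#' @param panel A `haplotype_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  H <- panel$haplotypes
  odd <- seq(1L, nrow(H), by = 2L)
  gt <- matrix(paste0(H[odd, , drop = FALSE], "|", H[odd + 1L, , drop = FALSE]),
               nrow = length(odd))  # individuals x markers
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", panel$chrom, ">"),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$sample_ids), collapse = "\t"))
  fixed <- paste(panel$chrom, panel$positions_bp,
                 paste0("m", seq_len(panel$m)), "A", "C", ".", "PASS", ".",
                 "GT", sep = "\t")
  body <- paste(fixed, apply(t(gt), 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
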