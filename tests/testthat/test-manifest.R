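test_that("keep-files hold member IDs in order and round-trip the design", {
  d <- enumerate_subsets(4)
  out <- withr::local_tempdir()
  paths <- write_keep_files(d, c("A", "B", "C", "D"), out)
  expect_length(paths, 6L)
  # subset {1,4} (id 4, a row of P_1) lists A then D
  expect_identical(readLines(paths[["4"]]), c("A", "D"))
  expect_identical(readLines(paths[["0"]]), c("A", "B"))
  back <- read_keep_files(paths, c("A", "B", "C", "D"))
  expect_identical(unname(back), d$subsets)

  d25 <- enumerate_subsets(25)
  ids25 <- sprintf("UKB%02d", 1:25)
  out25 <- withr::local_tempdir()
  p25 <- write_keep_files(d25, ids25, out25)
  expect_length(p25, 30L)
  expect_true(all(vapply(p25, function(f) length(readLines(f)), 0L) == 5L))
  expect_identical(unname(read_keep_files(p25, ids25)), d25$subsets)
})

test_that("keep-file writing validates the ID list", {
  d <- enumerate_subsets(4)
  out <- withr::local_tempdir()
  expect_error(write_keep_files(d, c("A", "B", "C"), out), "exactly n")
  expect_error(write_keep_files(d, c("A", "B", "C", "A"), out), "unique")
  expect_error(write_keep_files(d, c("A", "B", "C", " "), out), "non-empty")
})

test_that("undersized subsets are skipped with a notice", {
  # n = 5, p = 3: column 3 of P is all null, so one subset is empty
  d <- enumerate_subsets(5)
  out <- withr::local_tempdir()
  expect_message(paths <- write_keep_files(d, letters[1:5], out), "skipped")
  emitted <- d$provenance$size >= 2L
  expect_length(paths, sum(emitted))
  m <- write_manifest(d, batch_size = 100L)
  expect_identical(m$n_subsets_emitted, sum(emitted))
  expect_identical(m$n_subsets_total, 12L)
})

test_that("manifests batch emitted subsets into a disjoint exhaustive partition", {
  d <- enumerate_subsets(25)
  expect_length(write_manifest(d, batch_size = 1000L)$jobs, 1L)
  m <- write_manifest(d, batch_size = 7L)
  expect_length(m$jobs, 5L)  # ceil(30 / 7)
  all_ids <- unlist(lapply(m$jobs, `[[`, "subset_ids"))
  expect_identical(sort(all_ids), 0:29)          # exhaustive
  expect_identical(anyDuplicated(all_ids), 0L)   # pairwise disjoint
  expect_true(all(lengths(lapply(m$jobs, `[[`, "subset_ids")) <= 7L))
  expect_error(write_manifest(d, batch_size = 0L), ">= 1")
})

test_that("manifests round-trip through JSON with keep-file paths", {
  d <- enumerate_subsets(25)
  out <- withr::local_tempdir()
  keep <- write_keep_files(d, sprintf("id%02d", 1:25), out)
  path <- file.path(out, "manifest.json")
  m <- write_manifest(d, batch_size = 8L, keep_files = keep, path = path)
  m2 <- read_manifest(path)
  expect_identical(m2$n, 25L)
  expect_identical(m2$p, 5L)
  expect_identical(length(m2$jobs), length(m$jobs))
  expect_identical(m2$jobs[[2]]$subset_ids, m$jobs[[2]]$subset_ids)
  expect_identical(m2$jobs[[4]]$keep_files, m$jobs[[4]]$keep_files)
})

test_that("segment tables round-trip through TSV bit-exactly", {
  df <- data.frame(id_a = c("S2", "S1"), id_b = c("S1", "S3"),
                   hap_a = c(1L, 0L), hap_b = c(0L, 1L),
                   chrom = "1",
                   start_bp = c(5000L, 10000L), end_bp = c(900000L, 2000000L),
                   start_marker = c(1L, 2L), end_marker = c(181L, 401L),
                   length_cm = c(0.895, 1.99) + pi * 1e-7,
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segments(df, path)
  back <- read_segments(path)
  # canonicalized on read: S2/S1 row swapped
  expect_identical(back$id_a, c("S1", "S1"))
  expect_identical(back$hap_a, c(0L, 0L))
  expect_identical(sort(back$length_cm), sort(df$length_cm))  # bit-exact
})

test_that("malformed segment rows are rejected with file and line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  lines <- readLines({
    p <- withr::local_tempfile()
    write_segments(empty_segments(), p)
    p
  })
  writeLines(c(lines, "S1\tS2\t0\t0\t1\t100\t200"), path)  # 7 fields
  expect_error(read_segments(path), ":3: expected 10 fields")
  writeLines(c(lines, "S1\tS2\t0\t0\t1\t100\t200\t1\t5\tnot_a_number"), path)
  expect_error(read_segments(path), "non-numeric")
})

test_that("merging disjoint result files concatenates and sorts; duplicates warn", {
  a <- data.frame(id_a = "S1", id_b = "S2", hap_a = 0L, hap_b = 0L,
                  chrom = "1", start_bp = 100L, end_bp = 500L,
                  start_marker = 1L, end_marker = 6L, length_cm = 4,
                  stringsAsFactors = FALSE)
  b <- a; b$id_a <- "S0"; b$id_b <- "S3"
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_segments(a, fa); write_segments(b, fb)
  merged <- merge_results(c(fa, fb))
  expect_identical(nrow(merged), 2L)
  expect_identical(merged$id_a, c("S0", "S1"))  # sorted by pair

  fa2 <- withr::local_tempfile()
  write_segments(a, fa2)
  expect_warning(dup <- merge_results(c(fa, fa2)), "coverage")
  expect_identical(nrow(dup), 1L)
})

test_that("GERMLINE .match rows map onto segment records", {
  path <- withr::local_tempfile(fileext = ".match")
  writeLines(c(
    "FAM1 S1.0 FAM2 S2.1 1 100000 4200000 rs1 rs99 120 4.1 cM 0 0 0",
    "FAM1 S3 FAM2 S2 1 100000 4200000 rs1 rs99 120 3.9 cM 1 0 0"),
    path)
  seg <- read_germline_match(path)
  expect_identical(nrow(seg), 2L)
  expect_identical(seg$id_a[1], "S1")
  expect_identical(seg$hap_b[1], 1L)
  expect_identical(seg$hap_a[2], 0L)  # no suffix defaults to haplotype 0
  expect_true(all(is.na(seg$start_marker)))
  expect_equal(seg$length_cm, c(4.1, 3.9))
  writeLines("FAM1 S1 FAM2 S2 1 1 2 rs1 rs2 5 3.9 MB 0 0 0", path)
  expect_error(read_germline_match(path), "cM")
})
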