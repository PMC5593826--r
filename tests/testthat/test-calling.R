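# helper: a single-position pileup with given ref/alt strand counts
pile_row <- function(position, ref, alt, ref_fwd, ref_rev, alt_fwd, alt_rev) {
  dplyr::bind_rows(
    dplyr::tibble(position = position, ref = ref, allele = ref,
                  fwd = ref_fwd, rev = ref_rev),
    dplyr::tibble(position = position, ref = ref, allele = alt,
                  fwd = alt_fwd, rev = alt_rev))
}

test_that("the worked threshold examples call as documented", {
  # depth 1000, alt 30 fwd + 30 rev: VAF 6%, balance 0.5 -> called PASS
  p1 <- pile_row(100L, "A", "G", 470L, 470L, 30L, 30L)
  c1 <- call_variants(p1)
  expect_identical(nrow(c1), 1L)
  expect_identical(c1$filter, "PASS")
  expect_equal(c1$vaf, 0.06)
  expect_equal(c1$strand_balance, 0.5)

  # depth 20, alt 10: below the minimum depth of 30 -> not called
  p2 <- pile_row(200L, "A", "G", 5L, 5L, 5L, 5L)
  expect_identical(nrow(call_variants(p2)), 0L)

  # depth 1000, alt 100 fwd + 5 rev: balance 5/105 < 0.2 -> strand_imbalance
  p3 <- pile_row(300L, "A", "G", 448L, 447L, 100L, 5L)
  c3 <- call_variants(p3)
  expect_identical(nrow(c3), 1L)
  expect_identical(c3$filter, "strand_imbalance")
  expect_equal(c3$strand_balance, 5 / 105)
})

test_that("boundary behaviour of the three predicates is exact", {
  # depth exactly 30 is enough (inclusive)
  p <- pile_row(10L, "C", "T", 14L, 14L, 1L, 1L)   # depth 30, vaf 2/30
  expect_identical(nrow(call_variants(p)), 1L)
  # VAF exactly 5% is called (inclusive)
  p <- pile_row(10L, "C", "T", 19L, 19L, 1L, 1L)   # depth 40, vaf 0.05
  expect_identical(nrow(call_variants(p)), 1L)
  # one-sided support fails strand balance
  p <- pile_row(10L, "C", "T", 14L, 14L, 2L, 0L)   # balance 0
  got <- call_variants(p)
  expect_identical(got$filter, "strand_imbalance")
  # strand balance exactly 0.2 fails the strict inequality
  p <- pile_row(10L, "C", "T", 45L, 45L, 8L, 2L)   # balance 2/10 = 0.2
  expect_identical(call_variants(p)$filter, "strand_imbalance")
  # multi-allelic: one call per qualifying alt, ordered by (position, alt)
  p <- dplyr::bind_rows(
    pile_row(10L, "C", "T", 40L, 40L, 5L, 5L),
    dplyr::tibble(position = 10L, ref = "C", allele = "A",
                  fwd = 5L, rev = 5L))
  got <- call_variants(p)
  expect_identical(got$alt, c("A", "T"))
})

test_that("the caller equals the brute-force oracle on random pileups", {
  set.seed(13)
  for (trial in 1:20) {
    n_pos <- sample(1:6, 1)
    rows <- purrr::map_dfr(seq_len(n_pos), function(i) {
      ref <- sample(c("A", "C", "G", "T"), 1)
      alleles <- unique(c(ref, sample(c("A", "C", "G", "T", "del"),
                                      sample(1:3, 1))))
      dplyr::tibble(position = i * 10L, ref = ref, allele = alleles,
                    fwd = as.integer(rpois(length(alleles), 15)),
                    rev = as.integer(rpois(length(alleles), 15)))
    })
    got <- call_variants(rows)
    want <- oracle_calls(rows)
    expect_identical(nrow(got), nrow(want), info = paste("trial", trial))
    if (nrow(got)) {
      got2 <- dplyr::tibble(
        position = got$position,
        allele = ifelse(got$var_type == "deletion", "del", got$alt),
        vaf = got$vaf, filter = got$filter) |>
        dplyr::arrange(position, allele)
      want2 <- want |> dplyr::arrange(position, allele)
      expect_equal(as.data.frame(got2), as.data.frame(want2),
                   info = paste("trial", trial))
    }
  }
})

test_that("plasmy classification respects the inclusive 0.95 threshold", {
  calls <- dplyr::tibble(vaf = c(0.99, 0.50, 0.95))
  got <- classify_plasmy(calls)
  expect_identical(got$plasmy,
                   c("homoplasmic", "heteroplasmic", "homoplasmic"))
})

test_that("pileup depth doubles pair counts and sums over overlaps", {
  cfg <- sim_config(lesions_per_patient = 1L, n_germline = 0L, n_trunk = 0L,
                    n_branch = 0L, n_private = 0L, n_artifact = 0L,
                    deamination_rate = 0, sequencing_error_rate = 0,
                    off_target_fraction = 0, depth_mean = 40)
  set.seed(17)
  reads <- simulate_reads(
    dplyr::tibble(patient = character(), lesion = character(),
                  position = integer(), ref = character(),
                  alt = character(), var_type = character(),
                  origin = character(), true_vaf = double()),
    test_panel(), cfg, test_ref(), "TN1")
  res <- assign_and_pileup(reads, test_panel(), test_ref())

  # brute-force recount from the labelled read names
  amp_of <- as.integer(sub("^TN1:amp(\\d+):.*$", "\\1", reads$name))
  pairs_per_amp <- table(factor(amp_of, levels = 1:108))
  a <- test_panel()$amplicons
  L <- test_ref()$length
  want_depth <- integer(L)
  for (i in 1:108) {
    pos <- amp_pos(a$insert_start[i], a$insert_end[i], L)
    want_depth[pos] <- want_depth[pos] + 2L * as.integer(pairs_per_amp[i])
  }
  got <- res$depth
  expect_identical(got$depth, want_depth[got$position])
  expect_identical(nrow(got), L)   # noiseless full coverage
})

test_that("run metrics report specificity and coverage arithmetic", {
  cfg <- sim_config(lesions_per_patient = 1L, n_germline = 0L, n_trunk = 0L,
                    n_branch = 0L, n_private = 0L, n_artifact = 0L,
                    deamination_rate = 0, sequencing_error_rate = 0,
                    off_target_fraction = 0.025, depth_mean = 40)
  set.seed(19)
  reads <- simulate_reads(
    dplyr::tibble(patient = character(), lesion = character(),
                  position = integer(), ref = character(),
                  alt = character(), var_type = character(),
                  origin = character(), true_vaf = double()),
    test_panel(), cfg, test_ref(), "TN1")
  res <- assign_and_pileup(reads, test_panel(), test_ref())
  m <- res$metrics
  n_off <- sum(reads$origin == "offtarget")
  expect_equal(m$total_pairs, nrow(reads))
  expect_equal(m$assigned_pairs, nrow(reads) - n_off)
  expect_equal(m$specificity, 100 * (nrow(reads) - n_off) / nrow(reads))
  expect_equal(m$covered_fraction, 100)   # depth >= 30 everywhere
  path <- tempfile(fileext = ".tsv")
  run_metrics_report(m |> dplyr::mutate(sample = "P01:TN1", .before = 1),
                     path)
  expect_identical(nrow(readr::read_tsv(path, show_col_types = FALSE)), 1L)
})

test_that("unassignable reads alone raise the no-on-target error", {
  bad <- dplyr::tibble(name = "x", r1 = strrep("N", 300),
                       r2 = strrep("N", 300))
  expect_error(assign_and_pileup(bad, test_panel(), test_ref()),
               "no on-target data")
})

test_that("indel round trip recovers left-aligned labels exactly", {
  cfg <- sim_config(lesions_per_patient = 1L, depth_mean = 300)
  truth <- dplyr::tibble(
    patient = "PX", lesion = "L1",
    position = c(12384L, 66L, 5000L),
    ref = c("", "G", substring(test_ref()$sequence, 5000, 5000)),
    alt = c("C", "", ""),
    var_type = c("insertion", "deletion", "SNV"),
    origin = "trunk", true_vaf = c(0.5, 0.4, 0.6))
  truth$alt[3] <- ifelse(truth$ref[3] == "A", "G", "A")
  set.seed(7)
  reads <- simulate_reads(truth, test_panel(), cfg, test_ref(), "L1")
  calls <- call_variants(assign_and_pileup(reads, test_panel(),
                                           test_ref())$pileup)
  expect_true(all(c("12384^12385-ins C", "66 del-G") %in% calls$label))
  got <- calls[match(c("12384^12385-ins C", "66 del-G"), calls$label), ]
  expect_identical(got$filter, c("PASS", "PASS"))
  expect_lt(abs(got$vaf[1] - 0.5), 3 * sqrt(0.25 / got$depth[1]))
  expect_lt(abs(got$vaf[2] - 0.4), 3 * sqrt(0.24 / got$depth[2]))
})

test_that("FASTQ writing and reading are mutually inverse", {
  reads <- dplyr::tibble(
    name = c("a:amp001:on:1", "b:amp002:on:2"),
    r1 = c("ACGTACGT", "GGGGCCCC"),
    r2 = c("TTTTAAAA", "CAGTCAGT"))
  r1 <- tempfile(fileext = ".fastq")
  r2 <- tempfile(fileext = ".fastq")
  write_fastq(reads, r1, r2)
  back <- read_fastq_pairs(r1, r2)
  expect_identical(back$name, reads$name)
  expect_identical(unname(back$r1), reads$r1)
  expect_identical(unname(back$r2), reads$r2)
})

test_that("VCF output re-anchors indels to VCF conventions", {
  ref <- test_ref()
  calls <- dplyr::tibble(
    position = c(5000L, 66L, 12384L),
    ref = c("A", "G", ""),
    alt = c("G", "", "C"),
    var_type = c("SNV", "deletion", "insertion"),
    label = c("A5000G", "66 del-G", "12384^12385-ins C"),
    depth = 100L, alt_fwd = 25L, alt_rev = 25L, vaf = 0.5,
    strand_balance = 0.5, filter = "PASS")
  # the packaged reference may not have A at 5000; fix ref allele to match
  calls$ref[1] <- substring(ref$sequence, 5000, 5000)
  calls$alt[1] <- ifelse(calls$ref[1] == "A", "G", "A")
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path, ref, sample_id = "S1")
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_identical(length(body), 3L)
  del <- strsplit(body[2], "\t")[[1]]
  anchor <- substring(ref$sequence, 65, 65)
  expect_identical(del[2], "65")                    # base before deletion
  expect_identical(del[4], paste0(anchor, "G"))
  expect_identical(del[5], anchor)
  ins <- strsplit(body[3], "\t")[[1]]
  a2 <- substring(ref$sequence, 12384, 12384)
  expect_identical(ins[2], "12384")
  expect_identical(ins[4], a2)
  expect_identical(ins[5], paste0(a2, "C"))
})
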