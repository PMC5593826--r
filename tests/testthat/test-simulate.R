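test_that("sim_config validates rates and counts", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(deamination_rate = 1.5), "rates must lie")
  expect_error(sim_config(off_target_fraction = -0.1), "rates must lie")
  expect_error(sim_config(n_trunk = -1L), "counts must be")
  expect_error(sim_config(lesions_per_patient = 0L), "lesions_per_patient")
  expect_error(sim_config(spectrum_weights = c(0.5, 0.5)), "spectrum_weights")
})

test_that("branch variants occupy a proper subset of at least two lesions", {
  cfg <- sim_config(lesions_per_patient = 3L, n_trunk = 2L, n_branch = 1L,
                    n_private = 1L, n_artifact = 0L)
  set.seed(7)
  sim <- simulate_patient(cfg, test_panel(), test_ref(), "P01")
  carriers <- sim$truth |>
    dplyr::filter(.data$origin == "branch") |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$lesion))
  expect_identical(nrow(carriers), 1L)
  expect_identical(carriers$n, 2L)   # proper subset of 3 lesions
})

test_that("germline polymorphisms are homoplasmic in every lesion", {
  cfg <- sim_config(lesions_per_patient = 2L, n_germline = 5L, n_trunk = 0L,
                    n_branch = 0L, n_private = 0L, n_artifact = 0L)
  set.seed(3)
  sim <- simulate_patient(cfg, test_panel(), test_ref(), "P01")
  g <- sim$truth |> dplyr::filter(.data$origin == "germline")
  expect_identical(dplyr::n_distinct(g$position), 5L)
  expect_true(all(g$true_vaf == 1.0))
  per_var <- g |> dplyr::count(.data$position)
  expect_true(all(per_var$n == 2L))  # present in both lesions
  # germline sites come from the packaged polymorphism snapshot
  db <- load_polymorphism_db()
  expect_true(all(g$position %in% db$position))
})

test_that("truth structure encodes trunk/branch/private by construction", {
  cfg <- sim_config(lesions_per_patient = 4L, n_trunk = 3L, n_branch = 4L,
                    n_private = 3L, n_artifact = 0L)
  set.seed(21)
  sim <- simulate_patient(cfg, test_panel(), test_ref(), "P01")
  counts <- sim$truth |>
    dplyr::filter(.data$origin %in% c("trunk", "branch", "private")) |>
    dplyr::group_by(.data$position, .data$origin) |>
    dplyr::summarise(k = dplyr::n_distinct(.data$lesion), .groups = "drop")
  expect_true(all(counts$k[counts$origin == "trunk"] == 4L))
  expect_true(all(counts$k[counts$origin == "private"] == 1L))
  expect_true(all(counts$k[counts$origin == "branch"] >= 2L &
                    counts$k[counts$origin == "branch"] < 4L))
})

test_that("two lesions re-allocate branch plants with a warning", {
  cfg <- sim_config(lesions_per_patient = 2L, n_trunk = 1L, n_branch = 2L,
                    n_private = 1L, n_artifact = 0L)
  set.seed(2)
  expect_warning(
    sim <- simulate_patient(cfg, test_panel(), test_ref(), "P01"),
    "re-allocating")
  expect_false("branch" %in% sim$truth$origin)
})

test_that("somatic carrier sets are laminar by construction", {
  cfg <- sim_config(lesions_per_patient = 4L, n_trunk = 2L, n_branch = 4L,
                    n_private = 4L, n_artifact = 0L)
  for (seed in 1:10) {
    set.seed(seed)
    sim <- simulate_patient(cfg, test_panel(), test_ref(), "P01")
    sets <- sim$truth |>
      dplyr::filter(.data$origin %in% c("trunk", "branch", "private")) |>
      dplyr::group_by(.data$position) |>
      dplyr::summarise(set = list(sort(unique(.data$lesion))),
                       .groups = "drop")
    for (i in seq_len(nrow(sets))) {
      for (j in seq_len(nrow(sets))) {
        a <- sets$set[[i]]
        b <- sets$set[[j]]
        k <- length(intersect(a, b))
        expect_true(k == 0L || k == length(a) || k == length(b),
                    info = paste("seed", seed))
      }
    }
  }
})

test_that("the #05-like preset reproduces the published pattern", {
  preset <- preset_patient_05(test_ref())
  branch <- preset$truth |> dplyr::filter(.data$origin == "branch")
  expect_identical(nrow(branch), 6L)   # 3 variants x 2 carrying lesions
  expect_setequal(unique(branch$lesion), c("TN2", "TN3"))
  labels <- format_variant_label(
    dplyr::distinct(branch, .data$position, .data$ref, .data$alt,
                    .data$var_type))
  expect_setequal(labels, c("A215G", "G2268A", "G11711A"))
  # VAF increases from TN2 to TN3 (accumulating mutations become dominant)
  expect_true(all(branch$true_vaf[branch$lesion == "TN3"] >
                    branch$true_vaf[branch$lesion == "TN2"]))
  trunk <- preset$truth |> dplyr::filter(.data$origin == "trunk")
  expect_identical(dplyr::n_distinct(trunk$lesion), 3L)
})

test_that("truth tables round-trip through TSV", {
  cfg <- sim_config(lesions_per_patient = 2L, n_branch = 0L)
  set.seed(4)
  sim <- simulate_patient(cfg, test_panel(), test_ref(), "P01")
  path <- tempfile(fileext = ".tsv")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$truth))

  write_truth(dplyr::tibble(), path)
  lines <- readLines(path)
  expect_identical(length(lines), 1L)   # header only
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(lesions_per_patient = 2L, n_branch = 0L,
                    depth_mean = 40, n_artifact = 1L)
  run <- function() {
    set.seed(42)
    sim <- simulate_patient(cfg, test_panel(), test_ref(), "P01")
    reads <- simulate_reads(sim$truth, test_panel(), cfg, test_ref(), "TN1")
    r1 <- tempfile(); r2 <- tempfile()
    write_fastq(reads, r1, r2)
    list(truth = sim$truth, b1 = readBin(r1, "raw", file.size(r1)),
         b2 = readBin(r2, "raw", file.size(r2)))
  }
  a <- run()
  b <- run()
  expect_identical(a$truth, b$truth)
  expect_identical(a$b1, b$b1)
  expect_identical(a$b2, b$b2)
})

test_that("read counts and off-target fraction match their distributions", {
  cfg <- sim_config(lesions_per_patient = 1L, n_germline = 0L, n_trunk = 0L,
                    n_branch = 0L, n_private = 0L, n_artifact = 0L,
                    depth_mean = 50, off_target_fraction = 0.025)
  set.seed(8)
  sim <- simulate_patient(cfg, test_panel(), test_ref(), "P01")
  reads <- simulate_reads(sim$truth, test_panel(), cfg, test_ref(), "TN1")
  n_on <- sum(reads$origin == "on")
  n_off <- sum(reads$origin == "offtarget")
  # expectation 108 x 50 on-target pairs, within 5 sd of NB sum
  expect_lt(abs(n_on - 108 * 50), 5 * sqrt(108 * (50 + 50^2 / 20)))
  # off-target fraction within 4 binomial sd of 2.5%
  frac <- n_off / nrow(reads)
  expect_lt(abs(frac - 0.025), 4 * sqrt(0.025 * 0.975 / nrow(reads)))
})

test_that("the noiseless limit plants the allele on every read", {
  cfg <- sim_config(lesions_per_patient = 1L, n_germline = 0L, n_trunk = 0L,
                    n_branch = 0L, n_private = 0L, n_artifact = 0L,
                    deamination_rate = 0, sequencing_error_rate = 0,
                    off_target_fraction = 0, depth_mean = 30)
  truth <- dplyr::tibble(
    patient = "PX", lesion = "TN1", position = 5000L,
    ref = substring(test_ref()$sequence, 5000, 5000), alt = "",
    var_type = "SNV", origin = "trunk", true_vaf = 1.0)
  truth$alt <- ifelse(truth$ref == "A", "G", "A")
  set.seed(9)
  reads <- simulate_reads(truth, test_panel(), cfg, test_ref(), "TN1")
  res <- assign_and_pileup(reads, test_panel(), test_ref())
  col <- res$pileup |> dplyr::filter(.data$position == 5000L)
  expect_identical(nrow(col), 1L)          # single allele observed
  expect_identical(col$allele, truth$alt)  # and it is the planted one
})

test_that("reads must span primer plus insert", {
  cfg <- sim_config(read_length = 100L)
  expect_error(
    simulate_reads(dplyr::tibble(), test_panel(), cfg, test_ref(), "TN1"),
    "read cannot span amplicon")
})
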