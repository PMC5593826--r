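# End-to-end orchestration: validated YAML/list config, then
# simulate -> assign/pileup -> call -> annotate -> filter -> clonality with
# a deterministic output layout. All samples are processed in one batch
# with a single threshold set to keep lesions comparable.

config_defaults <- function() {
  list(
    reference = NULL,                     # NULL = packaged synthetic rCRS
    panel = list(n_amplicons = 108L, mean_length = 160, min_overlap = 6L,
                 primer_length = 22L, n_pools = 4L),
    simulation = NULL,                    # sim_config() arguments
    input = NULL,                         # list of per-lesion FASTQ pairs
    thresholds = list(min_depth = 30L, min_vaf = 0.05,
                      min_strand_balance = 0.2, homoplasmy_vaf = 0.95),
    filters = list(vaf_tolerance = 0.05, min_patients = 3L,
                   end_margin = 5L, noise_quantile = 0.99),
    presence_min_vaf = 0.05,
    seed = 1L
  )
}

merge_block <- function(defaults, user, path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown config key: ", path, unknown[1]))
  }
  utils::modifyList(defaults, user)
}

#' Validate and normalise a pipeline configuration
#'
#' Accepts a YAML file path or a nested list. Exactly one of the
#' `simulation` and `input` blocks must be present. Missing thresholds are
#' filled with the documented defaults (min_depth 30, min_vaf 0.05,
#' min_strand_balance 0.2, homoplasmy_vaf 0.95; panel: 108 amplicons, 4
#' pools). Unknown keys are rejected by name; range violations are
#' reported with their key path.
#'
#' @param config path to a YAML file, or a list
#' @return a normalised `pipeline_config` list
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a YAML file or a list")
  def <- config_defaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) abort(paste0("unknown config key: ", unknown[1]))

  has_sim <- !is.null(config$simulation)
  has_input <- !is.null(config$input)
  if (has_sim && has_input) {
    abort("config error: exactly one of simulation/input blocks allowed, got both")
  }
  if (!has_sim && !has_input) {
    abort("config error: one of simulation/input blocks required")
  }

  cfg <- def
  cfg$reference <- config$reference
  cfg$panel <- merge_block(def$panel, config$panel %||% list(), "panel.")
  cfg$thresholds <- merge_block(def$thresholds, config$thresholds %||% list(),
                                "thresholds.")
  cfg$filters <- merge_block(def$filters, config$filters %||% list(),
                             "filters.")
  if (has_sim) {
    sim_args <- config$simulation
    bad <- setdiff(names(sim_args), names(formals(sim_config)))
    if (length(bad)) abort(paste0("unknown config key: simulation.", bad[1]))
    cfg$simulation <- sim_args
    cfg$input <- NULL
  } else {
    cfg$simulation <- NULL
    cfg$input <- config$input
  }
  cfg$presence_min_vaf <- config$presence_min_vaf %||% def$presence_min_vaf
  cfg$seed <- config$seed %||% def$seed

  th <- cfg$thresholds
  for (key in c("min_vaf", "min_strand_balance", "homoplasmy_vaf")) {
    if (th[[key]] < 0 || th[[key]] > 1) {
      abort(paste0("config range error: thresholds.", key,
                   " must lie in [0, 1]"))
    }
  }
  if (th$min_depth < 1) abort("config range error: thresholds.min_depth must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Simulates (or ingests) per-lesion reads, designs and writes the panel,
#' builds pileups, calls and annotates variants, applies the false-variant
#' heuristics, and runs the per-patient clonality analysis. The output
#' directory layout is deterministic and, for a fixed config and seed, all
#' non-log outputs are byte-identical between runs:
#'
#' * `panel/` — inserts.bed, primers.tsv
#' * `fastq/` — simulated paired FASTQ per lesion
#' * `truth.tsv`, `sample_sheet.tsv` — simulation ground truth
#' * `vcf/` — one VCF per lesion
#' * `metrics.tsv` — per-sample run metrics
#' * `pass.tsv`, `review.tsv` — filtered cohort tables
#' * `clonality/<patient>.tsv`, `trees/<patient>.nwk`, `verdicts.tsv`
#' * `run.log` — config echo and snapshot versions (excluded from the
#'   determinism contract)
#'
#' @param config a `pipeline_config` from [validate_config()] (or a list /
#'   YAML path, validated on the fly)
#' @param outdir output directory
#' @param keep_fastq whether to materialise simulated reads as FASTQ files
#' @return invisibly, a list with the cohort tables, verdicts and paths
#' @export
run_pipeline <- function(config, outdir, keep_fastq = TRUE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("panel", "vcf", "clonality", "trees", "fastq")) {
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  }
  set.seed(config$seed)

  ref_path <- config$reference %||% mt_reference_fasta()
  reference <- load_reference(ref_path)
  region_map <- mt_regions()
  db <- load_polymorphism_db()

  panel <- design_panel(reference,
                        n_amplicons = config$panel$n_amplicons,
                        mean_length = config$panel$mean_length,
                        min_overlap = config$panel$min_overlap,
                        primer_length = config$panel$primer_length)
  panel <- assign_pools(panel, config$panel$n_pools)
  write_panel(panel, file.path(outdir, "panel"))

  # --- reads per (patient, lesion) -------------------------------------
  if (!is.null(config$simulation)) {
    sim_cfg <- do.call(sim_config, config$simulation)
    cohort <- simulate_cohort(sim_cfg, panel, reference,
                              region_map = region_map, db = db)
    write_truth(cohort$truth, file.path(outdir, "truth.tsv"))
    readr::write_tsv(cohort$sample_sheet,
                     file.path(outdir, "sample_sheet.tsv"), progress = FALSE)
    units <- cohort$sample_sheet |> select("patient", "lesion")
    reads_of <- purrr::pmap(units, function(patient, lesion) {
      r <- simulate_reads(cohort$truth |>
                            filter(.data$patient == !!patient),
                          panel, sim_cfg, reference, lesion)
      if (keep_fastq) {
        write_fastq(r,
                    file.path(outdir, "fastq",
                              sprintf("%s_%s_R1.fastq", patient, lesion)),
                    file.path(outdir, "fastq",
                              sprintf("%s_%s_R2.fastq", patient, lesion)))
      }
      r
    })
  } else {
    units <- purrr::map_dfr(config$input, function(x) {
      tibble(patient = x$patient, lesion = x$lesion)
    })
    reads_of <- purrr::map(config$input, function(x) c(x$r1, x$r2))
    cohort <- NULL
  }

  # --- pileup, call, annotate ------------------------------------------
  th <- config$thresholds
  pileups <- list()
  metrics <- list()
  all_calls <- list()
  for (i in seq_len(nrow(units))) {
    pat <- units$patient[i]
    les <- units$lesion[i]
    res <- assign_and_pileup(reads_of[[i]], panel, reference)
    sample_key <- paste0(pat, ":", les)
    pileups[[sample_key]] <- res$pileup
    metrics[[i]] <- res$metrics |> mutate(sample = sample_key, .before = 1)
    calls <- call_variants(res$pileup, min_depth = th$min_depth,
                           min_vaf = th$min_vaf,
                           min_strand_balance = th$min_strand_balance) |>
      classify_plasmy(homoplasmy_vaf = th$homoplasmy_vaf) |>
      annotate_polymorphisms(db) |>
      mutate(patient = pat, lesion = les, .before = 1)
    all_calls[[i]] <- calls
    write_vcf(calls,
              file.path(outdir, "vcf", sprintf("%s_%s.vcf", pat, les)),
              reference, sample_id = sample_key)
  }
  run_metrics_report(dplyr::bind_rows(metrics),
                     file.path(outdir, "metrics.tsv"))

  # --- cohort filters ----------------------------------------------------
  cohort_calls <- cohort_table(all_calls)
  fl <- config$filters
  filtered <- apply_filters(cohort_calls, panel, region_map,
                            pileups = if (length(pileups) >= 3) pileups,
                            vaf_tolerance = fl$vaf_tolerance,
                            min_patients = fl$min_patients,
                            end_margin = fl$end_margin,
                            noise_quantile = fl$noise_quantile)
  flat <- function(x) x |> select(-dplyr::any_of(c("vafs")))
  readr::write_tsv(flat(filtered$pass), file.path(outdir, "pass.tsv"),
                   progress = FALSE)
  write_review_table(flat(filtered$review), file.path(outdir, "review.tsv"))

  # --- clonality per patient --------------------------------------------
  verdicts <- list()
  assignments <- list()
  for (pat in sort(unique(units$patient))) {
    lesions <- sort(units$lesion[units$patient == pat])
    if (length(lesions) < 2L) next
    pc <- filtered$pass |> filter(.data$patient == pat)
    asg <- classify_trunk_branch_private(
      pc |> mutate(patient = pat),
      presence_min_vaf = config$presence_min_vaf, lesions = lesions)
    tr <- build_clonal_tree(asg)
    vd <- clonal_verdict(asg, tr)
    assignments[[pat]] <- asg
    verdicts[[pat]] <- vd$evidence |> mutate(verdict = vd$verdict)
    readr::write_tsv(
      tidy.clonal_assignment(asg) |>
        select(-dplyr::any_of("vafs")) |>
        mutate(patient = pat, .before = 1),
      file.path(outdir, "clonality", paste0(pat, ".tsv")), progress = FALSE)
    if (!is.null(tr$tree)) {
      write_clone_tree(tr$tree,
                       file.path(outdir, "trees", paste0(pat, ".nwk")))
    }
  }
  verdicts_tbl <- dplyr::bind_rows(verdicts)
  readr::write_tsv(verdicts_tbl, file.path(outdir, "verdicts.tsv"),
                   progress = FALSE)

  # --- log (excluded from determinism) ----------------------------------
  log_lines <- c(
    paste0("mttrack pipeline run: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("R version: ", R.version.string),
    paste0("seed: ", config$seed),
    paste0("polymorphism snapshot: ", attr(db, "snapshot_version")),
    paste0("config: ", yaml::as.yaml(unclass(config)))
  )
  writeLines(log_lines, file.path(outdir, "run.log"))

  invisible(list(
    panel = panel, truth = if (!is.null(cohort)) cohort$truth,
    calls = cohort_calls, pass = filtered$pass, review = filtered$review,
    assignments = assignments, verdicts = verdicts_tbl, outdir = outdir
  ))
}
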