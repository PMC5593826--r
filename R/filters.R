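# Cohort-level false-variant heuristics: recurrent similar-VAF calls across
# patients, calls hugging amplicon insert boundaries, calls in repetitive
# (microsatellite) regions, and calls in high-background-noise positions.
# Filters only flag -- no call is ever deleted; flagged calls are routed to
# a review table with a needs-orthogonal-confirmation marker, mirroring
# re-assessment of candidate artifacts by an orthogonal assay.

#' Assemble a cohort variant table
#'
#' Binds per-lesion annotated call tables into the cohort-level table the
#' filter heuristics operate on. Rows must be unique by
#' (patient, lesion, position, alt).
#'
#' @param ... per-lesion call tibbles, each with `patient` and `lesion`
#'   columns
#' @return the bound tibble
#' @export
cohort_table <- function(...) {
  tbl <- dplyr::bind_rows(...)
  dup <- tbl |>
    count(.data$patient, .data$lesion, .data$position, .data$alt) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("cohort table not unique by (patient, lesion, position, alt)")
  }
  tbl
}

#' Flag variants recurring across patients with similar frequency
#'
#' A (position, alt) is flagged `recurrent_similar_vaf` in every carrier
#' when it occurs in at least `min_patients` distinct patients and the
#' spread of its VAFs across all carrying samples is at most
#' `vaf_tolerance` — the signature of a systematic artifact rather than
#' independent biology. Known homoplasmic germline polymorphisms (calls
#' annotated as known polymorphisms and homoplasmic in every carrier) are
#' exempt: those legitimately recur across patients at VAF ~1.
#'
#' @param table cohort tibble (needs `patient`, `position`, `alt`, `vaf`;
#'   uses `known_polymorphism` and `plasmy` for the exemption when present)
#' @param vaf_tolerance maximum max-min VAF spread across carriers
#' @param min_patients recurrence floor (distinct patients)
#' @return `table` with a logical `flag_recurrent_similar_vaf` column
#' @export
cross_sample_filter <- function(table, vaf_tolerance = 0.05,
                                min_patients = 3L) {
  if (dplyr::n_distinct(table$patient) < 2L) {
    warn("cross-sample filter skipped: fewer than 2 patients")
    return(table |> mutate(flag_recurrent_similar_vaf = FALSE))
  }
  has_ann <- all(c("known_polymorphism", "plasmy") %in% names(table))
  stats <- table |>
    group_by(.data$position, .data$alt) |>
    summarise(
      n_pat = dplyr::n_distinct(.data$patient),
      spread = max(.data$vaf) - min(.data$vaf),
      exempt = if (has_ann) {
        all(.data$known_polymorphism & .data$plasmy == "homoplasmic")
      } else FALSE,
      .groups = "drop"
    ) |>
    mutate(flag_recurrent_similar_vaf =
             .data$n_pat >= min_patients &
             .data$spread <= vaf_tolerance &
             !.data$exempt)
  table |>
    left_join(stats |> select("position", "alt",
                              "flag_recurrent_similar_vaf"),
              by = c("position", "alt"))
}

#' Flag calls at amplicon insert boundaries
#'
#' A position is flagged `amplicon_end` when it lies within `end_margin` bp
#' of an insert boundary of *every* amplicon covering it; positions interior
#' to an overlapping neighbour are exempt, because that neighbour reports
#' them away from its primer ends.
#'
#' @param table cohort tibble with a `position` column
#' @param panel the `mt_panel`
#' @param end_margin boundary margin in bp (distance strictly less than
#'   `end_margin` counts as "at the end")
#' @return `table` with a logical `flag_amplicon_end` column
#' @export
amplicon_end_filter <- function(table, panel, end_margin = 5L) {
  L <- panel$reference$length
  interior_ok <- logical(L)
  covered <- logical(L)
  for (i in seq_len(nrow(panel$amplicons))) {
    pos <- amplicon_positions(panel$amplicons$insert_start[i],
                              panel$amplicons$insert_end[i], L)
    off <- seq_along(pos) - 1L
    dist <- pmin(off, rev(off))
    covered[pos] <- TRUE
    interior_ok[pos[dist >= end_margin]] <- TRUE
  }
  if (any(!covered[table$position])) {
    abort("position off-panel: call at a position covered by no amplicon")
  }
  table |> mutate(flag_amplicon_end = !interior_ok[.data$position])
}

#' Flag calls in repetitive (microsatellite) regions
#'
#' @param table cohort tibble with a `position` column
#' @param region_map tibble from [mt_regions()]
#' @return `table` with a logical `flag_repetitive_region` column
#' @export
region_filter <- function(table, region_map) {
  ms <- region_map |> filter(.data$category == "microsatellite")
  flagged <- purrr::map_lgl(table$position, function(p) {
    any(position_in_region(p, ms$start, ms$end))
  })
  table |> mutate(flag_repetitive_region = flagged)
}

#' Flag calls at high-background-noise positions
#'
#' Background noise at a position is the mean non-reference allele fraction
#' across the samples *not* carrying a call there (carrier samples are
#' excluded so true variants never inflate their own background). Positions
#' whose noise strictly exceeds the cohort-wide `noise_quantile` of the
#' noise distribution flag their calls `noisy_region`.
#'
#' @param table cohort tibble (needs `patient`, `lesion`, `position`)
#' @param pileups named list of pileup tibbles (one per sample, names
#'   `"<patient>:<lesion>"`)
#' @param noise_quantile quantile defining "high" noise
#' @return `table` with a logical `flag_noisy_region` column
#' @export
noise_filter <- function(table, pileups, noise_quantile = 0.99) {
  if (length(pileups) < 3L) {
    warn("noise filter skipped: fewer than 3 samples with pileups")
    return(table |> mutate(flag_noisy_region = FALSE))
  }
  per_sample <- purrr::imap_dfr(pileups, function(p, nm) {
    p |>
      filter(!startsWith(.data$allele, "ins:")) |>
      group_by(.data$position) |>
      summarise(
        depth = sum(.data$fwd + .data$rev),
        nonref = sum((.data$fwd + .data$rev)[.data$allele != .data$ref[1]]),
        .groups = "drop") |>
      mutate(sample = nm, frac = .data$nonref / .data$depth)
  })
  carriers <- table |>
    mutate(sample = paste0(.data$patient, ":", .data$lesion)) |>
    distinct(.data$sample, .data$position) |>
    mutate(carrier = TRUE)
  noise <- per_sample |>
    left_join(carriers, by = c("sample", "position")) |>
    filter(is.na(.data$carrier)) |>
    group_by(.data$position) |>
    summarise(noise = mean(.data$frac), .groups = "drop")
  cutoff <- stats::quantile(noise$noise, noise_quantile, names = FALSE)
  noisy_pos <- noise$position[noise$noise > cutoff]
  table |> mutate(flag_noisy_region = .data$position %in% noisy_pos)
}

#' Apply all false-variant heuristics and split pass/review
#'
#' Runs the four heuristics (each a pure function of the cohort snapshot,
#' so the outcome is independent of their order), collects flag provenance
#' into a `flags` column, and partitions the cohort: calls with no flags
#' (and FILTER `PASS` from the caller) go to the pass table; flagged calls
#' are *not* deleted but routed to a review table with a
#' `needs_orthogonal_confirmation` marker.
#'
#' @param table cohort tibble of calls
#' @param panel the `mt_panel`
#' @param region_map tibble from [mt_regions()]
#' @param pileups optional named list of per-sample pileups for the noise
#'   heuristic (skipped with a warning when absent or fewer than 3)
#' @param vaf_tolerance,min_patients,end_margin,noise_quantile heuristic
#'   parameters, see the individual filters
#' @return list with tibbles `pass` and `review`; both carry the `flags`
#'   column, `review` additionally `needs_orthogonal_confirmation = TRUE`
#' @export
apply_filters <- function(table, panel, region_map, pileups = NULL,
                          vaf_tolerance = 0.05, min_patients = 3L,
                          end_margin = 5L, noise_quantile = 0.99) {
  tbl <- table |>
    cross_sample_filter(vaf_tolerance, min_patients) |>
    amplicon_end_filter(panel, end_margin) |>
    region_filter(region_map)
  tbl <- if (is.null(pileups)) {
    tbl |> mutate(flag_noisy_region = FALSE)
  } else {
    tbl |> noise_filter(pileups, noise_quantile)
  }
  flag_cols <- c("recurrent_similar_vaf" = "flag_recurrent_similar_vaf",
                 "amplicon_end" = "flag_amplicon_end",
                 "repetitive_region" = "flag_repetitive_region",
                 "noisy_region" = "flag_noisy_region")
  flags <- purrr::map_chr(seq_len(nrow(tbl)), function(i) {
    on <- names(flag_cols)[purrr::map_lgl(flag_cols, function(cc) tbl[[cc]][i])]
    if ("filter" %in% names(tbl) && tbl$filter[i] != "PASS") {
      on <- c(tbl$filter[i], on)
    }
    paste(on, collapse = ",")
  })
  tbl$flags <- flags
  tbl <- tbl |> select(-dplyr::all_of(unname(flag_cols)))
  list(
    pass = tbl |> filter(.data$flags == ""),
    review = tbl |>
      filter(.data$flags != "") |>
      mutate(needs_orthogonal_confirmation = TRUE)
  )
}

#' Write the review table as TSV
#'
#' @param review tibble from [apply_filters()]
#' @param path output TSV
#' @return the path, invisibly
#' @export
write_review_table <- function(review, path) {
  readr::write_tsv(review, path, progress = FALSE)
  invisible(path)
}
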