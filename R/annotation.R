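# Recognition of known polymorphisms / disease-associated sites from the
# packaged offline database snapshot, and cohort summaries of the
# substitution spectrum and the regional distribution of variants.

#' Load a polymorphism database snapshot
#'
#' The packaged snapshot (`inst/extdata/mt_polymorphisms.tsv`) holds known
#' mitochondrial polymorphisms with their source (MITOMAP, dbSNP, HAPMAP),
#' a disease-association flag and a free-text note; it includes the
#' breast/endometrial-cancer-risk sites 10398 and 16189. Malformed rows
#' (bad position, unknown source, invalid alleles) are skipped with a
#' warning. The snapshot version string is attached as attribute
#' `"snapshot_version"`.
#'
#' @param path optional alternative TSV (columns position, ref, alt,
#'   var_type, source, disease_flag, note)
#' @return tibble of database records
#' @export
load_polymorphism_db <- function(path = NULL) {
  path <- path %||% system.file("extdata", "mt_polymorphisms.tsv",
                                package = "mttrack", mustWork = TRUE)
  version <- "unversioned"
  hdr <- readLines(path, n = 10L)
  vline <- grep("^# snapshot_version:", hdr, value = TRUE)
  if (length(vline)) version <- trimws(sub("^# snapshot_version:", "", vline[1]))
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(
                           position = "i", ref = "c", alt = "c",
                           var_type = "c", source = "c",
                           disease_flag = "l", note = "c")) |>
    mutate(ref = dplyr::coalesce(.data$ref, ""),
           alt = dplyr::coalesce(.data$alt, ""))
  ok <- !is.na(tbl$position) & tbl$position >= 1L &
    tbl$source %in% c("MITOMAP", "dbSNP", "HAPMAP") &
    tbl$var_type %in% c("SNV", "deletion", "insertion") &
    !is.na(tbl$disease_flag)
  if (any(!ok)) {
    warn(paste0("skipping ", sum(!ok), " malformed polymorphism db row(s)"))
    tbl <- tbl[ok, ]
  }
  attr(tbl, "snapshot_version") <- version
  tbl
}

#' Annotate calls against the polymorphism database
#'
#' Matches calls to database records by (position, ref, alt) and adds
#' `known_polymorphism` (logical), `sources` (comma-collapsed) and
#' `disease_flag`. Annotation never alters filter or plasmy fields, and is
#' idempotent.
#'
#' @param calls tibble from [call_variants()]
#' @param db tibble from [load_polymorphism_db()]
#' @return annotated calls
#' @export
annotate_polymorphisms <- function(calls, db) {
  ann <- db |>
    group_by(.data$position, .data$ref, .data$alt) |>
    summarise(sources = paste(sort(unique(.data$source)), collapse = ","),
              disease_flag = any(.data$disease_flag), .groups = "drop") |>
    mutate(known_polymorphism = TRUE)
  calls |>
    select(-dplyr::any_of(c("known_polymorphism", "sources",
                            "disease_flag"))) |>
    left_join(ann, by = c("position", "ref", "alt")) |>
    mutate(known_polymorphism = !is.na(.data$known_polymorphism),
           disease_flag = dplyr::coalesce(.data$disease_flag, FALSE),
           sources = dplyr::coalesce(.data$sources, ""))
}

#' Substitution spectrum summary
#'
#' Partitions calls into the strand-collapsed classes `T>C/A>G`,
#' `G>A/C>T` and `other` (transversions and indels) and reports counts and
#' fractions (which sum to exactly 1 over a non-empty input).
#'
#' @param calls tibble with `ref`, `alt`, `var_type`
#' @return tibble with columns `class`, `n`, `fraction`
#' @export
spectrum_summary <- function(calls) {
  if (nrow(calls) == 0L) {
    return(tibble(class = character(), n = integer(), fraction = double()))
  }
  cls <- ifelse(calls$var_type == "SNV",
                substitution_class(ifelse(calls$var_type == "SNV",
                                          calls$ref, "A"),
                                   ifelse(calls$var_type == "SNV",
                                          calls$alt, "G")),
                "other")
  tibble(class = factor(cls, levels = c("T>C/A>G", "G>A/C>T", "other"))) |>
    count(.data$class, .drop = FALSE, name = "n") |>
    mutate(class = as.character(.data$class),
           fraction = .data$n / sum(.data$n))
}

#' Regional distribution of calls
#'
#' Attributes every call to its containing region(s) on the circular map
#' (control-region membership honours origin wrapping); calls contained in
#' no annotated region count as `intergenic`. A call in several regions
#' counts once per region, so per-region fractions (denominator: total
#' calls) can sum to more than 1; the `intergenic` plus all single-region
#' attributions of otherwise-unattributed calls still reconcile with the
#' total call count.
#'
#' @param calls tibble with a `position` column
#' @param region_map tibble from [mt_regions()]
#' @return tibble with `label`, `category`, `n`, `fraction`
#' @export
region_distribution <- function(calls, region_map) {
  if (nrow(calls) == 0L) {
    return(tibble(label = character(), category = character(),
                  n = integer(), fraction = double()))
  }
  total <- nrow(calls)
  regions_at(calls$position, region_map) |>
    count(.data$label, .data$category, name = "n") |>
    mutate(fraction = .data$n / total) |>
    arrange(dplyr::desc(.data$n))
}
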