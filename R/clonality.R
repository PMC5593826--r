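# Per-patient clonality analysis: trunk/branch/private classification of
# somatic variants from their carrier lesion sets, clonal tree
# reconstruction from the (laminar) family of carrier sets, and a
# monoclonal / independent / untrackable verdict per patient.

#' Classify somatic variants into trunk, branch and private
#'
#' Somatic-candidate variants are the patient's PASS calls that are not
#' germline under the heuristic "annotated known polymorphism AND
#' homoplasmic in every lesion of the patient" (no matched normal tissue is
#' assumed). A variant is *present* in a lesion when that lesion has a PASS
#' call for it with VAF at least `presence_min_vaf`. Categories partition
#' the somatic set by carrier count: `trunk` = present in all lesions,
#' `private` = exactly one, `branch` = otherwise (a proper subset of two
#' or more).
#'
#' @param patient_calls tibble of one patient's annotated calls across
#'   lesions (columns `patient`, `lesion`, `position`, `ref`, `alt`,
#'   `var_type`, `vaf`, `known_polymorphism`, `plasmy`; a `filter` or
#'   `flags` column restricts to PASS rows when present)
#' @param presence_min_vaf VAF floor for presence in a lesion
#' @param lesions optional full lesion set (defaults to the lesions seen in
#'   `patient_calls`); supply it when a lesion may carry no call at all
#' @return a `clonal_assignment`: list with `variants` (tibble: position,
#'   ref, alt, var_type, label, category, carriers (list), n_carriers,
#'   vafs (list, named per lesion)), `germline` (the excluded polymorphism
#'   rows, summarised), `lesions`, `patient`
#' @export
classify_trunk_branch_private <- function(patient_calls,
                                          presence_min_vaf = 0.05,
                                          lesions = NULL) {
  lesions <- sort(lesions %||% unique(patient_calls$lesion))
  if (length(lesions) < 2L) {
    abort("clonality undefined for one lesion")
  }
  patient <- unique(patient_calls$patient)[1]
  calls <- patient_calls
  if ("flags" %in% names(calls)) {
    calls <- calls |> filter(.data$flags == "")
  } else if ("filter" %in% names(calls)) {
    calls <- calls |> filter(.data$filter == "PASS")
  }
  calls <- calls |> filter(.data$vaf >= presence_min_vaf)

  if (!all(c("known_polymorphism", "plasmy") %in% names(calls))) {
    abort("patient calls must be annotated (known_polymorphism, plasmy)")
  }

  per_variant <- calls |>
    group_by(.data$position, .data$ref, .data$alt, .data$var_type) |>
    summarise(
      carriers = list(sort(unique(.data$lesion))),
      vafs = list(stats::setNames(.data$vaf, .data$lesion)),
      germline = all(.data$known_polymorphism) &
        all(.data$plasmy == "homoplasmic") &
        length(unique(.data$lesion)) == length(lesions),
      .groups = "drop"
    ) |>
    mutate(n_carriers = lengths(.data$carriers),
           label = format_variant_label(
             dplyr::pick("position", "ref", "alt", "var_type")))

  somatic <- per_variant |>
    filter(!.data$germline) |>
    mutate(category = dplyr::case_when(
      .data$n_carriers == length(lesions) ~ "trunk",
      .data$n_carriers == 1L ~ "private",
      TRUE ~ "branch"
    )) |>
    arrange(.data$position, .data$alt) |>
    select("position", "ref", "alt", "var_type", "label", "category",
           "carriers", "n_carriers", "vafs")

  germline <- per_variant |>
    filter(.data$germline) |>
    arrange(.data$position, .data$alt) |>
    select("position", "ref", "alt", "var_type", "label", "carriers",
           "n_carriers", "vafs")

  structure(
    list(variants = somatic, germline = germline, lesions = lesions,
         patient = patient),
    class = "clonal_assignment"
  )
}

#' @export
print.clonal_assignment <- function(x, ...) {
  n <- table(factor(x$variants$category,
                    levels = c("trunk", "branch", "private")))
  cat("<clonal_assignment> patient ", x$patient, ": ",
      length(x$lesions), " lesions; somatic trunk/branch/private = ",
      n["trunk"], "/", n["branch"], "/", n["private"],
      "; germline polymorphisms = ", nrow(x$germline), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.clonal_assignment <- function(x, ...) {
  x$variants |>
    mutate(carriers = purrr::map_chr(.data$carriers, paste, collapse = ","))
}

#' @export
glance.clonal_assignment <- function(x, ...) {
  tibble(
    patient = x$patient,
    n_lesions = length(x$lesions),
    n_somatic = nrow(x$variants),
    n_trunk = sum(x$variants$category == "trunk"),
    n_branch = sum(x$variants$category == "branch"),
    n_private = sum(x$variants$category == "private"),
    n_germline_polymorphisms = nrow(x$germline)
  )
}

is_laminar_pair <- function(a, b) {
  i <- length(intersect(a, b))
  i == 0L || i == length(a) || i == length(b)
}

#' Reconstruct a clonal tree from carrier sets
#'
#' Each distinct carrier set of somatic variants is treated as a clade. If
#' the family of carrier sets is laminar (any two sets nested or disjoint),
#' it is compatible with a rooted tree, which is returned with variants
#' attached to edges. Otherwise the maximal laminar subfamily is retained
#' greedily — ordering sets by descending variant support, then larger set
#' first, then smaller minimum variant position — and every crossing pair
#' of carrier sets is reported as a conflict.
#'
#' @param assignment a `clonal_assignment`
#' @return list with `tree` (a `clone_tree`, or `NULL` with no somatic
#'   variants), `conflicts` (tibble of crossing carrier-set pairs with
#'   their supporting variant labels) and `dropped` (labels of variants
#'   whose carrier set was not retained)
#' @export
build_clonal_tree <- function(assignment) {
  v <- assignment$variants
  lesions <- assignment$lesions
  empty_conflicts <- tibble(set1 = character(), set2 = character(),
                            variants1 = character(), variants2 = character())
  if (nrow(v) == 0L) {
    return(list(tree = NULL, conflicts = empty_conflicts,
                dropped = character(0)))
  }
  fam <- v |>
    mutate(key = purrr::map_chr(.data$carriers, paste, collapse = ",")) |>
    group_by(.data$key) |>
    summarise(carriers = .data$carriers[1],
              support = dplyr::n(),
              min_pos = min(.data$position),
              labels = paste(.data$label, collapse = ";"),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$support),
            dplyr::desc(lengths(.data$carriers)), .data$min_pos)

  kept <- list()
  kept_rows <- integer(0)
  conflicts <- list()
  for (i in seq_len(nrow(fam))) {
    s <- fam$carriers[[i]]
    cross <- purrr::map_lgl(kept, function(kk) !is_laminar_pair(s, kk))
    if (any(cross)) {
      for (j in kept_rows[cross]) {
        conflicts[[length(conflicts) + 1L]] <- tibble(
          set1 = paste(fam$carriers[[j]], collapse = ","),
          set2 = fam$key[i],
          variants1 = fam$labels[j],
          variants2 = fam$labels[i])
      }
    } else {
      kept[[length(kept) + 1L]] <- s
      kept_rows <- c(kept_rows, i)
    }
  }
  dropped_keys <- setdiff(seq_len(nrow(fam)), kept_rows)
  dropped <- unlist(strsplit(fam$labels[dropped_keys], ";"))

  # assemble the rooted tree: clades = kept sets plus the full lesion set
  # and all singletons
  clades <- unique(c(list(sort(lesions)), kept,
                     purrr::map(lesions, identity)))
  sizes <- lengths(clades)
  ord <- order(-sizes)
  clades <- clades[ord]
  node_name <- character(length(clades))
  n_int <- 0L
  for (i in seq_along(clades)) {
    if (length(clades[[i]]) == 1L) {
      node_name[i] <- clades[[i]]
    } else {
      n_int <- n_int + 1L
      node_name[i] <- paste0("N", n_int)
    }
  }
  parent_of <- purrr::map_chr(seq_along(clades), function(i) {
    if (i == 1L) return("root")
    sup <- which(purrr::map_lgl(clades, function(cl) {
      length(cl) > length(clades[[i]]) && all(clades[[i]] %in% cl)
    }))
    best <- sup[which.min(lengths(clades)[sup])]
    node_name[best]
  })
  edges <- tibble(parent = parent_of, child = node_name,
                  leaves_below = clades)
  tree <- new_clone_tree(edges, sort(lesions))

  # attach variant labels to the edge whose clade equals the carrier set
  tree$placement <- v |>
    mutate(edge_child = purrr::map_chr(.data$carriers, function(cc) {
      hit <- which(purrr::map_lgl(clades, function(cl) setequal(cl, cc)))
      if (length(hit)) node_name[hit[1]] else NA_character_
    })) |>
    select("position", "ref", "alt", "var_type", "label", "edge_child")

  list(tree = tree,
       conflicts = if (length(conflicts)) dplyr::bind_rows(conflicts)
                   else empty_conflicts,
       dropped = dropped %||% character(0))
}

#' Clonality verdict for a patient
#'
#' `untrackable`: no somatic variants at all (only shared homoplasmic
#' polymorphisms) — the lineage cannot be traced. `monoclonal`: at least
#' one somatic trunk variant, proving a common cell of origin of all
#' lesions. `independent`: somatic variants exist but none is shared by
#' all lesions as trunk and none by a subset as branch — each lesion's
#' mutations are its own, consistent with origin from different clonal
#' patches. A patient with branch but no trunk variants has no evidence of
#' a *single* origin of all lesions and is also verdicted `independent`,
#' with the branch evidence retained in the counts.
#'
#' @param assignment a `clonal_assignment`
#' @param tree_result optional result of [build_clonal_tree()] to attach
#' @return a `clonal_verdict`: list with `verdict`, `evidence` (one-row
#'   tibble of counts), `tree`, `conflicts`
#' @export
clonal_verdict <- function(assignment, tree_result = NULL) {
  ev <- glance.clonal_assignment(assignment)
  verdict <- if (ev$n_somatic == 0L) {
    "untrackable"
  } else if (ev$n_trunk >= 1L) {
    "monoclonal"
  } else {
    "independent"
  }
  structure(
    list(verdict = verdict, evidence = ev,
         tree = tree_result$tree, conflicts = tree_result$conflicts),
    class = "clonal_verdict"
  )
}

#' @export
print.clonal_verdict <- function(x, ...) {
  cat("<clonal_verdict> ", x$evidence$patient, ": ", x$verdict,
      " (trunk ", x$evidence$n_trunk, ", branch ", x$evidence$n_branch,
      ", private ", x$evidence$n_private, ", shared polymorphisms ",
      x$evidence$n_germline_polymorphisms, ")\n", sep = "")
  invisible(x)
}

#' Venn-style summary of shared vs lesion-specific variants
#'
#' Counts variants (somatic and germline polymorphisms together) per
#' carrier lesion subset; subset counts sum to the total number of distinct
#' variants.
#'
#' @param assignment a `clonal_assignment`
#' @return tibble with `subset` (comma-separated lesion ids), `n_lesions`,
#'   `n_variants`
#' @export
venn_summary <- function(assignment) {
  all_v <- dplyr::bind_rows(
    assignment$variants |> select("label", "carriers"),
    assignment$germline |> select("label", "carriers")
  )
  if (nrow(all_v) == 0L) {
    return(tibble(subset = character(), n_lesions = integer(),
                  n_variants = integer()))
  }
  all_v |>
    mutate(subset = purrr::map_chr(.data$carriers, paste, collapse = ",")) |>
    count(.data$subset, name = "n_variants") |>
    mutate(n_lesions = lengths(strsplit(.data$subset, ","))) |>
    arrange(dplyr::desc(.data$n_lesions), .data$subset) |>
    select("subset", "n_lesions", "n_variants")
}

#' Per-edge VAF trend report
#'
#' Descriptive output for subclone interpretation: for each tree edge with
#' attached variants, the mean VAF of those variants in each carrier
#' lesion. Increasing VAFs down the tree are the signature of accumulating
#' mutations becoming dominant.
#'
#' @param assignment a `clonal_assignment`
#' @param tree_result result of [build_clonal_tree()]
#' @return tibble with `edge_child`, `lesion`, `mean_vaf`, `n_variants`
#' @export
vaf_trend <- function(assignment, tree_result) {
  if (is.null(tree_result$tree)) {
    return(tibble(edge_child = character(), lesion = character(),
                  mean_vaf = double(), n_variants = integer()))
  }
  assignment$variants |>
    left_join(tree_result$tree$placement |> select("label", "edge_child"),
              by = "label") |>
    tidyr::unnest_longer(col = "vafs", values_to = "vaf",
                         indices_to = "lesion") |>
    group_by(.data$edge_child, .data$lesion) |>
    summarise(mean_vaf = mean(.data$vaf), n_variants = dplyr::n(),
              .groups = "drop")
}

#' Write a clonal tree as Newick
#'
#' @param tree a `clone_tree`
#' @param path output file
#' @return the path, invisibly
#' @export
write_clone_tree <- function(tree, path) {
  writeLines(clone_tree_newick(tree), path)
  invisible(path)
}
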