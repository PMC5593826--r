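# Synthetic multi-lesion patient simulator: clonal lineage trees, planted
# germline/trunk/branch/private variants with plasmy levels, FFPE-type
# deamination noise, off-target reads, and per-amplicon paired reads with
# ground truth. Stands in for deposited patient FASTQs in all tests.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic cohort generator. Defaults encode
#' the study conditions the package emulates: multi-lesion NSCLC patients
#' (2-4 FFPE lesions each), a handful of homoplasmic germline polymorphisms
#' shared by all lesions of a patient, heteroplasmic somatic
#' trunk/branch/private mutations with mostly high allele fractions,
#' low-VAF C>T/G>A deamination artifacts, ~2.5% off-target reads, and
#' per-amplicon read-pair depth in the thousands.
#'
#' @param n_patients number of patients in a simulated cohort
#' @param lesions_per_patient lesions (tumour nodules) per patient
#' @param n_germline homoplasmic germline polymorphisms per patient, drawn
#'   from the packaged polymorphism snapshot
#' @param n_trunk,n_branch,n_private somatic variant counts per patient
#' @param vaf_shape1,vaf_shape2 Beta parameters of the heteroplasmic VAF
#'   distribution; the default Beta(0.8, 0.8), truncated below at
#'   `vaf_min`, is bimodal toward the extremes, mimicking mt-variants that
#'   are mostly homoplasmic or highly heteroplasmic
#' @param vaf_min lower truncation of planted somatic VAFs
#' @param indel_fraction fraction of somatic plants that are 1-bp indels
#'   rather than SNVs
#' @param spectrum_weights length-3 numeric (T>C/A>G, G>A/C>T, other)
#'   giving the substitution-class mix of planted SNVs
#' @param clonal_drift multiplicative VAF factor per tree edge below the
#'   most recent common ancestor (1 = off); values > 1 emulate clonal
#'   expansion of accumulating mutations
#' @param deamination_rate per-base probability that a template C (or G)
#'   reads as T (or A); the FFPE formalin artifact
#' @param n_artifact per lesion, number of planted low-VAF deamination
#'   artifact sites (origin `"artifact"`, VAF <= `artifact_vaf_max`)
#' @param artifact_vaf_max upper bound of planted artifact VAFs; kept below
#'   the 5% calling floor that is meant to suppress them
#' @param sequencing_error_rate per-base, per-read substitution error rate
#' @param off_target_fraction fraction of read pairs emitted from a
#'   scrambled decoy and labelled off-target
#' @param depth_mean,depth_dispersion negative-binomial mean and size of
#'   per-amplicon read-pair counts
#' @param read_length read length in bp (paired reads must span
#'   primer + insert)
#' @param seed optional RNG seed recorded in the config
#' @return a `sim_config` list
#' @export
sim_config <- function(n_patients = 3L,
                       lesions_per_patient = 3L,
                       n_germline = 5L,
                       n_trunk = 3L,
                       n_branch = 2L,
                       n_private = 2L,
                       vaf_shape1 = 0.8,
                       vaf_shape2 = 0.8,
                       vaf_min = 0.05,
                       indel_fraction = 0.1,
                       spectrum_weights = c(0.45, 0.35, 0.20),
                       clonal_drift = 1.0,
                       deamination_rate = 0.005,
                       n_artifact = 3L,
                       artifact_vaf_max = 0.01,
                       sequencing_error_rate = 0.001,
                       off_target_fraction = 0.025,
                       depth_mean = 2000,
                       depth_dispersion = 20,
                       read_length = 300L,
                       seed = NULL) {
  cfg <- as.list(environment())
  rates <- c(vaf_min = vaf_min, indel_fraction = indel_fraction,
             deamination_rate = deamination_rate,
             artifact_vaf_max = artifact_vaf_max,
             sequencing_error_rate = sequencing_error_rate,
             off_target_fraction = off_target_fraction)
  if (any(rates < 0 | rates > 1)) {
    abort("sim_config: all rates must lie in [0, 1]")
  }
  counts <- c(n_patients, lesions_per_patient, n_germline, n_trunk,
              n_branch, n_private, n_artifact)
  if (any(counts < 0)) abort("sim_config: counts must be >= 0")
  if (lesions_per_patient < 1) abort("sim_config: lesions_per_patient must be >= 1")
  if (length(spectrum_weights) != 3 || abs(sum(spectrum_weights) - 1) > 1e-8) {
    abort("sim_config: spectrum_weights must be 3 values summing to 1")
  }
  structure(cfg, class = "sim_config")
}

# ---------------------------------------------------------------------------
# Clone trees
# ---------------------------------------------------------------------------

new_clone_tree <- function(edges, leaves) {
  structure(list(edges = edges, leaves = leaves), class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("<clone_tree> ", length(x$leaves), " lesions, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' @export
tidy.clone_tree <- function(x, ...) {
  x$edges |>
    mutate(leaves_below = purrr::map_chr(.data$leaves_below,
                                         paste, collapse = ","))
}

# random rooted tree over leaf set: root -> MRCA -> recursive binary splits
random_clone_tree <- function(leaves) {
  edges <- list()
  counter <- 0L
  grow <- function(parent, leafset) {
    if (length(leafset) == 1L) {
      edges[[length(edges) + 1L]] <<- tibble(
        parent = parent, child = leafset, leaves_below = list(leafset))
      return(invisible(NULL))
    }
    counter <<- counter + 1L
    node <- paste0("N", counter)
    edges[[length(edges) + 1L]] <<- tibble(
      parent = parent, child = node, leaves_below = list(leafset))
    k <- length(leafset)
    n_left <- if (k == 2L) 1L else sample(seq_len(k - 1L), 1L)
    left <- sort(sample(leafset, n_left))
    right <- setdiff(leafset, left)
    grow(node, left)
    grow(node, right)
  }
  grow("root", sort(leaves))
  new_clone_tree(dplyr::bind_rows(edges), sort(leaves))
}

# internal edges usable for branch mutations: proper subsets of >= 2 leaves
internal_edges <- function(tree) {
  sizes <- lengths(tree$edges$leaves_below)
  which(sizes >= 2L & sizes < length(tree$leaves))
}

# nontrivial splits (leaf sets of internal edges), for topology comparison
#' Leaf-set splits of a clone tree
#'
#' Returns the family of leaf sets below each edge spanning at least two
#' but not all lesions — the tree's nontrivial clades, sufficient to
#' compare topologies.
#'
#' @param tree a `clone_tree`
#' @return list of sorted character vectors
#' @export
clone_tree_splits <- function(tree) {
  idx <- internal_edges(tree)
  unique(purrr::map(tree$edges$leaves_below[idx], sort))
}

#' Newick serialisation of a clone tree
#'
#' @param tree a `clone_tree`
#' @return a Newick string with lesions as leaves
#' @export
clone_tree_newick <- function(tree) {
  kids <- split(tree$edges$child, tree$edges$parent)
  fmt <- function(node) {
    ch <- kids[[node]]
    if (is.null(ch)) return(node)
    paste0("(", paste(vapply(sort(ch), fmt, character(1)), collapse = ","),
           ")", if (node == "root") "" else node)
  }
  paste0(fmt("root"), ";")
}

# ---------------------------------------------------------------------------
# Plant-site selection
# ---------------------------------------------------------------------------

# positions eligible for planting: interior of at least one amplicon insert
# (at least `margin` bp from both insert boundaries), outside primer
# footprints and (optionally) outside microsatellite stretches, so that
# planted true variants are not swallowed by position-based artifact
# heuristics under test.
plant_candidates <- function(panel, region_map = NULL, margin = 5L,
                             avoid_microsatellite = TRUE) {
  L <- panel$reference$length
  interior <- logical(L)
  for (i in seq_len(nrow(panel$amplicons))) {
    s <- panel$amplicons$insert_start[i]
    e <- panel$amplicons$insert_end[i]
    pos <- amplicon_positions(s, e, L)
    off <- seq_along(pos) - 1L
    dist <- pmin(off, rev(off))
    interior[pos[dist >= margin]] <- TRUE
  }
  cand <- which(interior)
  if (avoid_microsatellite && !is.null(region_map)) {
    ms <- region_map |> filter(.data$category == "microsatellite")
    if (nrow(ms) > 0) {
      ms_pos <- unique(unlist(purrr::map2(ms$start, ms$end,
                                          amplicon_positions, L)))
      cand <- setdiff(cand, ms_pos)
    }
  }
  cand
}

ref_base_at <- function(reference, position) {
  substr(reference$sequence, position, position)
}

# draw alt allele for a planted SNV at `position` honouring the configured
# substitution-class mix as far as the reference base allows
draw_snv_alt <- function(ref, spectrum_weights) {
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
  w_transition <- if (ref %in% c("T", "A")) spectrum_weights[1] else spectrum_weights[2]
  if (stats::runif(1) < w_transition / (w_transition + spectrum_weights[3])) {
    unname(transition[ref])
  } else {
    sample(tv[[ref]], 1L)
  }
}

draw_trunc_beta <- function(n, shape1, shape2, lower) {
  v <- stats::rbeta(n, shape1, shape2)
  lower + v * (1 - lower)
}

# ---------------------------------------------------------------------------
# Patient simulation
# ---------------------------------------------------------------------------

#' Simulate one multi-lesion patient
#'
#' Builds a random clonal lineage tree over the patient's lesions and plants
#' variants on it: homoplasmic germline polymorphisms (drawn from the
#' packaged polymorphism snapshot, VAF 1 in every lesion), somatic trunk
#' variants on the root edge (present in all lesions), branch variants on
#' internal edges (a proper subset of >= 2 lesions; with only 2 lesions no
#' internal edge exists and branch plants are re-allocated to trunk/private
#' with a warning), and private variants on leaf edges. Heteroplasmic VAFs
#' are drawn from the configured truncated Beta; `clonal_drift > 1`
#' multiplies a variant's VAF per tree edge separating the lesion from the
#' variant's origin, emulating clonal expansion. Per lesion,
#' `n_artifact` low-VAF deamination-type artifact sites (C>T or G>A,
#' origin `"artifact"`) are added.
#'
#' Uses the current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param config a [sim_config()]
#' @param panel an `mt_panel` (plant sites avoid primer footprints,
#'   amplicon ends and microsatellites)
#' @param reference the [mt_reference][load_reference]
#' @param patient_id patient identifier
#' @param region_map region table, defaults to the packaged [mt_regions()]
#' @param db polymorphism snapshot, defaults to the packaged
#'   [load_polymorphism_db()]
#' @return list with elements `tree` (a `clone_tree`) and `truth` (tibble
#'   with columns patient, lesion, position, ref, alt, var_type, origin,
#'   true_vaf)
#' @export
simulate_patient <- function(config, panel, reference, patient_id = "P01",
                             region_map = mt_regions(),
                             db = load_polymorphism_db()) {
  k <- config$lesions_per_patient
  lesions <- sprintf("TN%d", seq_len(k))
  tree <- if (k == 1L) {
    new_clone_tree(tibble(parent = "root", child = lesions[1],
                          leaves_below = list(lesions)), lesions)
  } else {
    random_clone_tree(lesions)
  }

  cand <- plant_candidates(panel, region_map)
  used <- integer(0)

  take_positions <- function(n, pool) {
    pool <- setdiff(pool, used)
    if (length(pool) < n) abort("not enough plantable positions")
    p <- sort(sample_vec(pool, n))
    used <<- c(used, p)
    p
  }

  # germline: known polymorphic SNV sites, homoplasmic everywhere
  db_snv <- db |>
    filter(.data$var_type == "SNV", .data$position %in% cand)
  n_g <- min(config$n_germline, nrow(db_snv))
  germline <- db_snv[sort(sample.int(nrow(db_snv), n_g)), ] |>
    transmute(.data$position, .data$ref, .data$alt, .data$var_type,
              origin = "germline")
  used <- c(used, germline$position)

  somatic_one <- function(position, origin) {
    if (stats::runif(1) < config$indel_fraction) {
      d <- if (stats::runif(1) < 0.5) {
        tibble(position = position, ref = ref_base_at(reference, position),
               alt = "", var_type = "deletion")
      } else {
        tibble(position = position, ref = "",
               alt = sample(BASES, 1L), var_type = "insertion")
      }
      left_align_indel(d, reference$sequence) |> mutate(origin = origin)
    } else {
      ref <- ref_base_at(reference, position)
      tibble(position = position, ref = ref,
             alt = draw_snv_alt(ref, config$spectrum_weights),
             var_type = "SNV", origin = origin)
    }
  }

  n_trunk <- config$n_trunk
  n_branch <- config$n_branch
  n_private <- config$n_private
  internal <- internal_edges(tree)
  if (n_branch > 0 && length(internal) == 0L) {
    warn("no internal edge for branch variants; re-allocating to trunk/private")
    extra_trunk <- ceiling(n_branch / 2)
    n_trunk <- n_trunk + extra_trunk
    n_private <- n_private + (n_branch - extra_trunk)
    n_branch <- 0L
  }

  plant <- function(n, origin) {
    if (n == 0L) return(tibble())
    purrr::map_dfr(take_positions(n, cand), somatic_one, origin = origin)
  }
  trunk <- plant(n_trunk, "trunk")
  branch <- plant(n_branch, "branch")
  private <- plant(n_private, "private")

  # edge assignment: trunk on the root edge; branch on random internal
  # edges; private on random leaf edges
  leaf_edges <- which(lengths(tree$edges$leaves_below) == 1L)
  edge_of <- c(
    rep(which(purrr::map_lgl(tree$edges$leaves_below,
                             function(l) length(l) == k))[1], nrow(trunk)),
    if (nrow(branch)) rep(sample_vec(internal, length(internal)),
                          length.out = nrow(branch)),
    if (nrow(private)) sample_vec(leaf_edges, nrow(private), replace = TRUE)
  )
  somatic <- dplyr::bind_rows(trunk, branch, private)

  # per-lesion rows with drift along the path below the variant's edge
  depth_below <- function(edge_idx, lesion) {
    # edges on the path from the variant's edge child down to the lesion
    n_steps <- 0L
    sets <- tree$edges$leaves_below
    for (i in seq_len(nrow(tree$edges))) {
      if (i == edge_idx) next
      if (lesion %in% sets[[i]] &&
          all(sets[[i]] %in% sets[[edge_idx]]) &&
          length(sets[[i]]) < length(sets[[edge_idx]])) {
        n_steps <- n_steps + 1L
      }
    }
    n_steps
  }

  truth_somatic <- if (nrow(somatic) > 0) {
    base_vaf <- draw_trunc_beta(nrow(somatic), config$vaf_shape1,
                                config$vaf_shape2, config$vaf_min)
    purrr::map_dfr(seq_len(nrow(somatic)), function(i) {
      carriers <- tree$edges$leaves_below[[edge_of[i]]]
      purrr::map_dfr(carriers, function(les) {
        v <- min(1, base_vaf[i] * config$clonal_drift ^
                   depth_below(edge_of[i], les))
        dplyr::bind_cols(somatic[i, ], tibble(lesion = les, true_vaf = v))
      })
    })
  } else tibble()

  truth_germline <- if (nrow(germline) > 0) {
    tidyr::crossing(germline, lesion = lesions) |>
      mutate(true_vaf = 1.0)
  } else tibble()

  truth_artifact <- purrr::map_dfr(lesions, function(les) {
    n_a <- config$n_artifact
    if (n_a == 0L) return(tibble())
    pool <- setdiff(cand, used)
    bases <- substring(reference$sequence, pool, pool)
    pool <- pool[bases %in% c("C", "G")]
    p <- sort(sample_vec(pool, min(n_a, length(pool))))
    used <<- c(used, p)
    refs <- substring(reference$sequence, p, p)
    tibble(position = p, ref = refs,
           alt = ifelse(refs == "C", "T", "A"), var_type = "SNV",
           origin = "artifact", lesion = les,
           true_vaf = stats::runif(length(p), 0.002, config$artifact_vaf_max))
  })

  truth <- dplyr::bind_rows(truth_germline, truth_somatic, truth_artifact)
  if (nrow(truth) == 0L) {
    truth <- tibble(patient = character(), lesion = character(),
                    position = integer(), ref = character(),
                    alt = character(), var_type = character(),
                    origin = character(), true_vaf = double())
  } else {
    truth <- truth |>
      mutate(patient = patient_id) |>
      select("patient", "lesion", "position", "ref", "alt", "var_type",
             "origin", "true_vaf") |>
      arrange(.data$lesion, .data$position)
  }

  # record variant placement on the tree
  placement <- if (nrow(somatic) > 0) {
    somatic |>
      mutate(edge_child = tree$edges$child[edge_of])
  } else tibble()
  tree$placement <- placement

  list(tree = tree, truth = truth)
}

#' Simulate a whole cohort with a sample sheet
#'
#' Runs [simulate_patient()] for `config$n_patients` patients and attaches a
#' sample sheet (patient, lesion, histology in AD/SQ, grade in G2/G3).
#'
#' @inheritParams simulate_patient
#' @return list with `truth` (all patients), `trees` (named list) and
#'   `sample_sheet`
#' @export
simulate_cohort <- function(config, panel, reference,
                            region_map = mt_regions(),
                            db = load_polymorphism_db()) {
  ids <- sprintf("P%02d", seq_len(config$n_patients))
  sims <- purrr::map(ids, function(id) {
    simulate_patient(config, panel, reference, id, region_map, db)
  })
  truth <- purrr::map_dfr(sims, "truth")
  trees <- purrr::set_names(purrr::map(sims, "tree"), ids)
  sheet <- truth |>
    distinct(.data$patient, .data$lesion) |>
    mutate(histology = sample(c("AD", "SQ"), dplyr::n(), replace = TRUE),
           grade = sample(c("G2", "G3"), dplyr::n(), replace = TRUE))
  list(truth = truth, trees = trees, sample_sheet = sheet)
}

#' The published three-nodule subclone pattern, as a fixed preset
#'
#' Constructs the canonical "trunk plus shared-branch" patient: three
#' lesions TN1-TN3 where all lesions carry the trunk mutations, and TN2 and
#' TN3 additionally share three branch mutations (A215G, G2268A, G11711A)
#' at VAFs increasing from TN2 to TN3 — the signature of TN2/TN3 being
#' sister subclones derived from the TN1 lineage, with the accumulating
#' mutations becoming dominant over time.
#'
#' @param reference the [mt_reference][load_reference]
#' @param patient_id patient identifier
#' @return list with `tree` and `truth`, as [simulate_patient()]
#' @export
preset_patient_05 <- function(reference, patient_id = "P05") {
  lesions <- c("TN1", "TN2", "TN3")
  edges <- dplyr::bind_rows(
    tibble(parent = "root", child = "N1", leaves_below = list(lesions)),
    tibble(parent = "N1", child = "TN1", leaves_below = list("TN1")),
    tibble(parent = "N1", child = "N2", leaves_below = list(c("TN2", "TN3"))),
    tibble(parent = "N2", child = "TN2", leaves_below = list("TN2")),
    tibble(parent = "N2", child = "TN3", leaves_below = list("TN3"))
  )
  tree <- new_clone_tree(edges, lesions)

  trunk_pos <- c(5000L, 7000L, 9000L)
  trunk <- tibble(
    position = trunk_pos,
    ref = substring(reference$sequence, trunk_pos, trunk_pos)
  ) |>
    mutate(alt = c(A = "G", G = "A", C = "T", T = "C")[.data$ref],
           var_type = "SNV", origin = "trunk")
  branch <- parse_variant_label(c("A215G", "G2268A", "G11711A")) |>
    mutate(origin = "branch")
  tree$placement <- dplyr::bind_rows(
    trunk |> mutate(edge_child = "N1"),
    branch |> mutate(edge_child = "N2")
  )

  truth <- dplyr::bind_rows(
    tidyr::crossing(trunk, lesion = lesions) |> mutate(true_vaf = 0.6),
    tidyr::crossing(branch, tibble(lesion = c("TN2", "TN3"),
                                   true_vaf = c(0.30, 0.45)))
  ) |>
    mutate(patient = patient_id) |>
    select("patient", "lesion", "position", "ref", "alt", "var_type",
           "origin", "true_vaf") |>
    arrange(.data$lesion, .data$position)
  list(tree = tree, truth = truth)
}

# ---------------------------------------------------------------------------
# Read simulation
# ---------------------------------------------------------------------------

# safe vector sampling (sample() treats a length-1 numeric as 1:n)
sample_vec <- function(x, n, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

char_to_code <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1]], BASES)
}

BASE_BYTES <- as.raw(c(65L, 67L, 71L, 84L))  # A C G T

codes_to_strings <- function(m) {
  w <- nrow(m)
  big <- rawToChar(BASE_BYTES[m])
  starts <- seq.int(1L, by = w, length.out = ncol(m))
  substring(big, starts, starts + w - 1L)
}

revcomp_many <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

apply_indel <- function(frag, offset, var_type, ref, alt) {
  if (var_type == "deletion") {
    paste0(substr(frag, 1L, offset - 1L),
           substr(frag, offset + nchar(ref), nchar(frag)))
  } else {
    paste0(substr(frag, 1L, offset), alt,
           substr(frag, offset + 1L, nchar(frag)))
  }
}

#' Simulate paired amplicon reads for one lesion
#'
#' Per amplicon, draws a negative-binomial number of read pairs; each pair's
#' template fragment is the amplicon insert with every planted variant
#' applied at probability `true_vaf`, then template deamination (C>T and
#' G>A flips at `deamination_rate`, shared by both mates as on a real
#' deaminated molecule), then independent per-read sequencing errors. Read 1
#' is the forward primer followed by the fragment; read 2 is the reverse
#' primer followed by the reverse-complemented fragment. Primer bases are
#' simulated error-free so amplicon assignment by primer prefix is exact.
#' `off_target_fraction` of pairs are emitted from a scrambled decoy genome
#' and labelled off-target. Read names encode lesion, amplicon and origin
#' (`on`/`offtarget`) for truth-aware evaluation.
#'
#' Uses the current RNG state; seed with [set.seed()].
#'
#' @param truth truth tibble (one patient) from [simulate_patient()]
#' @param panel an `mt_panel` with pools assigned
#' @param config a [sim_config()]
#' @param reference the [mt_reference][load_reference]
#' @param lesion lesion id to simulate
#' @return tibble with columns `name`, `r1`, `r2`, `origin`
#' @export
simulate_reads <- function(truth, panel, config, reference, lesion) {
  if (anyNA(panel$amplicons$pool)) abort("assign pools first")
  amp <- panel$amplicons
  plen <- nchar(amp$fwd_primer[1])
  if (config$read_length < plen + max(amp$insert_length)) {
    abort("read cannot span amplicon: increase read_length")
  }
  L <- reference$length
  les_truth <- truth |> filter(.data$lesion == !!lesion)

  out <- vector("list", nrow(amp))
  for (i in seq_len(nrow(amp))) {
    w <- amp$insert_length[i]
    pos <- amplicon_positions(amp$insert_start[i], amp$insert_end[i], L)
    d <- max(1L, stats::rnbinom(1L, size = config$depth_dispersion,
                                mu = config$depth_mean))
    frag0 <- char_to_code(amplicon_insert_seq(reference,
                                              amp$insert_start[i],
                                              amp$insert_end[i]))
    M <- matrix(rep.int(frag0, d), nrow = w, ncol = d)

    vars <- les_truth |> filter(.data$position %in% pos)
    indel_jobs <- list()
    if (nrow(vars) > 0) {
      for (vi in seq_len(nrow(vars))) {
        off <- match(vars$position[vi], pos)
        carriers <- which(stats::runif(d) < vars$true_vaf[vi])
        if (length(carriers) == 0L) next
        if (vars$var_type[vi] == "SNV") {
          M[off, carriers] <- match(vars$alt[vi], BASES)
        } else {
          indel_jobs[[length(indel_jobs) + 1L]] <- list(
            offset = off, carriers = carriers,
            var_type = vars$var_type[vi],
            ref = vars$ref[vi], alt = vars$alt[vi])
        }
      }
    }

    # template deamination: C->T and G->A on the fragment, shared by mates
    if (config$deamination_rate > 0) {
      for (bb in c("C", "G")) {
        idx <- which(M == match(bb, BASES))
        n_flip <- stats::rbinom(1L, length(idx), config$deamination_rate)
        if (n_flip > 0) {
          flip <- sample_vec(idx, n_flip)
          M[flip] <- match(if (bb == "C") "T" else "A", BASES)
        }
      }
    }

    add_errors <- function(m) {
      n_err <- stats::rbinom(1L, length(m), config$sequencing_error_rate)
      if (n_err > 0) {
        at <- sample.int(length(m), n_err)
        m[at] <- ((m[at] - 1L + sample.int(3L, n_err, replace = TRUE)) %% 4L) + 1L
      }
      m
    }
    f1 <- codes_to_strings(add_errors(M))
    f2 <- codes_to_strings(add_errors(M))

    for (job in indel_jobs) {
      for (ci in job$carriers) {
        f1[ci] <- apply_indel(f1[ci], job$offset, job$var_type, job$ref, job$alt)
        f2[ci] <- apply_indel(f2[ci], job$offset, job$var_type, job$ref, job$alt)
      }
    }

    r1 <- substr(paste0(amp$fwd_primer[i], f1), 1L, config$read_length)
    r2 <- substr(paste0(amp$rev_primer[i], revcomp_many(f2)), 1L,
                 config$read_length)
    out[[i]] <- tibble(
      name = sprintf("%s:amp%03d:on:%d", lesion, amp$id[i], seq_len(d)),
      r1 = r1, r2 = r2, origin = "on")
  }
  reads <- dplyr::bind_rows(out)

  f <- config$off_target_fraction
  if (f > 0) {
    n_on <- nrow(reads)
    n_off <- stats::rbinom(1L, n_on, f / (1 - f))
    if (n_off > 0) {
      decoy <- paste(sample(strsplit(reference$sequence, "",
                                     fixed = TRUE)[[1]]), collapse = "")
      rl <- min(config$read_length, 150L)
      starts <- sample.int(nchar(decoy) - rl, n_off, replace = TRUE)
      starts2 <- sample.int(nchar(decoy) - rl, n_off, replace = TRUE)
      reads <- dplyr::bind_rows(reads, tibble(
        name = sprintf("%s:amp000:offtarget:%d", lesion, seq_len(n_off)),
        r1 = substring(decoy, starts, starts + rl - 1L),
        r2 = revcomp_many(substring(decoy, starts2, starts2 + rl - 1L)),
        origin = "offtarget"))
    }
  }
  reads
}

#' Write simulated read pairs as paired FASTQ
#'
#' Four-line FASTQ records with a flat base quality; read names carry the
#' lesion, amplicon and origin labels.
#'
#' @param reads tibble from [simulate_reads()]
#' @param r1_path,r2_path output FASTQ paths
#' @return invisibly, `c(r1_path, r2_path)`
#' @export
write_fastq <- function(reads, r1_path, r2_path) {
  qual1 <- strrep("I", nchar(reads$r1))
  qual2 <- strrep("I", nchar(reads$r2))
  writeLines(rbind(paste0("@", reads$name), reads$r1, "+", qual1), r1_path)
  writeLines(rbind(paste0("@", reads$name), reads$r2, "+", qual2), r2_path)
  invisible(c(r1_path, r2_path))
}

#' Write and re-read a simulation truth table
#'
#' @param truth truth tibble
#' @param path TSV path
#' @return the path (write) / the tibble (read)
#' @export
write_truth <- function(truth, path) {
  cols <- c("patient", "lesion", "position", "ref", "alt", "var_type",
            "origin", "true_vaf")
  empty <- tibble(patient = character(), lesion = character(),
                  position = integer(), ref = character(),
                  alt = character(), var_type = character(),
                  origin = character(), true_vaf = double())
  out <- dplyr::bind_rows(empty, truth)[, cols]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    patient = "c", lesion = "c", position = "i",
                    ref = "c", alt = "c", var_type = "c", origin = "c",
                    true_vaf = "d")) |>
    mutate(ref = dplyr::coalesce(.data$ref, ""),
           alt = dplyr::coalesce(.data$alt, ""))
}
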