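# Amplicon panel design on the circular mt-genome: tiled overlapping
# inserts, primer extraction from the reference flanks, and partition into
# multiplex PCR pools so that overlapping amplicons never share a pool.

new_mt_panel <- function(amplicons, n_pools, reference) {
  structure(
    list(amplicons = amplicons, n_pools = n_pools, reference = reference),
    class = "mt_panel"
  )
}

#' @export
print.mt_panel <- function(x, ...) {
  cat("<mt_panel> ", nrow(x$amplicons), " amplicons on ",
      x$reference$name, " (", x$reference$length, " bp circular)",
      if (x$n_pools > 0) paste0(", ", x$n_pools, " pools") else ", pools unassigned",
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.mt_panel <- function(x, ...) {
  x$amplicons
}

#' @export
glance.mt_panel <- function(x, ...) {
  tibble(
    n_amplicons = nrow(x$amplicons),
    mean_insert_length = mean(x$amplicons$insert_length),
    min_insert_length = min(x$amplicons$insert_length),
    max_insert_length = max(x$amplicons$insert_length),
    n_pools = x$n_pools,
    genome_length = x$reference$length
  )
}

#' Design a tiled overlapping amplicon panel on a circular genome
#'
#' Tiles the full circle with `n_amplicons` short inserts at (near-)uniform
#' step so that consecutive amplicons overlap and the last amplicon wraps
#' the origin to close the circle. Insert boundaries use cumulative
#' rounding, `start_i = floor((i-1) * L / n) + 1`, so steps differ by at
#' most 1 bp; each insert runs from its start to the next start plus the
#' overlap. Primers of `primer_length` bp are taken verbatim from the
#' reference flanks (forward primer 5' of the insert on the heavy strand,
#' reverse primer the reverse complement of the 3' flank).
#'
#' The defaults (108 amplicons of ~160 bp mean insert on the 16,569 bp
#' circle, 4 pools) reproduce the published summary geometry of the
#' whole-mt multiplex panel; amplicons are kept small (60-200 bp) so that
#' fragmented FFPE DNA still amplifies.
#'
#' @param reference an [mt_reference][load_reference]
#' @param n_amplicons number of amplicons tiling the circle
#' @param mean_length target mean insert length (bp), must lie in
#'   `[60, 200]`
#' @param min_overlap minimum overlap between consecutive inserts (bp); the
#'   realised overlap is `max(min_overlap, round(mean_length - L/n))` so the
#'   mean insert length tracks `mean_length`
#' @param primer_length primer length (bp)
#' @return an `mt_panel` with pools unassigned
#' @export
#' @examples
#' ref <- load_reference(mt_reference_fasta())
#' panel <- design_panel(ref)
#' nrow(panel$amplicons)
design_panel <- function(reference, n_amplicons = 108L, mean_length = 160,
                         min_overlap = 6L, primer_length = 22L) {
  L <- reference$length
  if (mean_length < 60 || mean_length > 200) {
    abort("amplicon size out of design range: mean_length must be in [60, 200] bp")
  }
  if (n_amplicons * (mean_length - min_overlap) < L) {
    abort("cannot tile circle: n_amplicons x (mean_length - min_overlap) < genome length")
  }
  step <- L / n_amplicons
  overlap <- max(min_overlap, round(mean_length - step))
  starts <- floor((seq_len(n_amplicons) - 1L) * L / n_amplicons) + 1L
  next_start <- c(starts[-1L], L + 1L)
  ends_lin <- next_start - 1L + overlap     # may exceed L (wraps)
  lengths <- ends_lin - starts + 1L
  if (any(lengths < 60L) || any(lengths > 200L)) {
    abort("cannot tile circle: resulting insert lengths fall outside [60, 200] bp")
  }
  ends <- circ_pos(ends_lin, L)
  amplicons <- tibble(
    id = seq_len(n_amplicons),
    insert_start = as.integer(starts),
    insert_end = as.integer(ends),
    insert_length = as.integer(lengths),
    fwd_primer = map_chr(starts, function(s) {
      circ_substr(reference$sequence, s - primer_length, s - 1L)
    }),
    rev_primer = map_chr(ends, function(e) {
      revcomp(circ_substr(reference$sequence, e + 1L, e + primer_length))
    }),
    pool = NA_integer_
  )
  new_mt_panel(amplicons, 0L, reference)
}

# all-pairs circular interval overlap; returns adjacency list
amplicon_overlap_graph <- function(amplicons, genome_length) {
  n <- nrow(amplicons)
  segs <- purrr::map(seq_len(n), function(i) {
    s <- amplicons$insert_start[i]
    e <- amplicons$insert_end[i]
    if (s <= e) list(c(s, e)) else list(c(s, genome_length), c(1L, e))
  })
  overlaps <- function(a, b) a[1] <= b[2] && b[1] <= a[2]
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      hit <- any(purrr::map_lgl(segs[[i]], function(si) {
        any(purrr::map_lgl(segs[[j]], function(sj) overlaps(si, sj)))
      }))
      if (hit) adj[[i]] <- c(adj[[i]], j)
    }
  }
  adj
}

#' Partition a panel into multiplex PCR pools
#'
#' Assigns every amplicon a pool in `1..n_pools` such that no two
#' overlapping amplicons share a pool, so each multiplex PCR reaction only
#' contains non-competing primer sets. Assignment is a deterministic greedy
#' colouring in amplicon order, always choosing the least-filled admissible
#' pool, which yields balanced pools (sizes differing by at most 1) for
#' chain tilings.
#'
#' @param panel an `mt_panel`
#' @param n_pools number of pools; must be at least the chromatic number of
#'   the amplicon overlap graph (2 for an even circular chain)
#' @return the panel with the `pool` column filled and `n_pools` set
#' @export
assign_pools <- function(panel, n_pools = 4L) {
  amp <- panel$amplicons
  n <- nrow(amp)
  if (n_pools < 1L) abort("pool constraint unsatisfiable: n_pools must be >= 1")
  adj <- amplicon_overlap_graph(amp, panel$reference$length)
  if (n_pools == 1L && any(lengths(adj) > 0)) {
    abort("pool constraint unsatisfiable: overlapping amplicons with a single pool")
  }
  pool <- rep(NA_integer_, n)
  counts <- integer(n_pools)
  for (i in seq_len(n)) {
    banned <- unique(stats::na.omit(pool[adj[[i]]]))
    allowed <- setdiff(seq_len(n_pools), banned)
    if (length(allowed) == 0L) {
      abort(paste0("pool constraint unsatisfiable: no admissible pool for amplicon ", i))
    }
    pool[i] <- allowed[which.min(counts[allowed])]
    counts[pool[i]] <- counts[pool[i]] + 1L
  }
  panel$amplicons$pool <- pool
  panel$n_pools <- as.integer(n_pools)
  panel
}

#' Write a panel to disk (BED + primer sheet)
#'
#' Writes `inserts.bed` (0-based half-open; origin-wrapping inserts are
#' split into two records carrying the same name) and `primers.tsv`
#' (columns id, fwd_primer, rev_primer, insert_start, insert_end, pool, in
#' 1-based inclusive coordinates). [read_panel()] reproduces the panel
#' exactly from these files.
#'
#' @param panel an `mt_panel` with pools assigned
#' @param dir output directory, created if missing
#' @return `dir`, invisibly
#' @export
write_panel <- function(panel, dir) {
  if (anyNA(panel$amplicons$pool)) abort("assign pools first")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  L <- panel$reference$length
  bed <- purrr::pmap_dfr(
    panel$amplicons[, c("id", "insert_start", "insert_end")],
    function(id, insert_start, insert_end) {
      name <- sprintf("amplicon_%03d", id)
      if (insert_start <= insert_end) {
        tibble(chrom = panel$reference$name, start = insert_start - 1L,
               end = insert_end, name = name)
      } else {
        tibble(chrom = panel$reference$name,
               start = c(insert_start - 1L, 0L),
               end = c(L, insert_end),
               name = name)
      }
    })
  readr::write_tsv(bed, file.path(dir, "inserts.bed"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(
    panel$amplicons[, c("id", "fwd_primer", "rev_primer",
                        "insert_start", "insert_end", "pool")],
    file.path(dir, "primers.tsv"), progress = FALSE)
  invisible(dir)
}

#' Read a panel written by [write_panel()]
#'
#' @param dir directory containing `primers.tsv`
#' @param reference the [mt_reference][load_reference] the panel was
#'   designed on
#' @return an `mt_panel`
#' @export
read_panel <- function(dir, reference) {
  sheet <- readr::read_tsv(file.path(dir, "primers.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  L <- reference$length
  amplicons <- sheet |>
    mutate(
      id = as.integer(.data$id),
      insert_start = as.integer(.data$insert_start),
      insert_end = as.integer(.data$insert_end),
      insert_length = as.integer(circ_span(.data$insert_start,
                                           .data$insert_end, L)),
      pool = as.integer(.data$pool)
    ) |>
    select("id", "insert_start", "insert_end", "insert_length",
           "fwd_primer", "rev_primer", "pool")
  new_mt_panel(amplicons, max(amplicons$pool), reference)
}

# positions (1-based) covered by an amplicon's insert, unrolled
amplicon_positions <- function(insert_start, insert_end, genome_length) {
  if (insert_start <= insert_end) {
    seq.int(insert_start, insert_end)
  } else {
    c(seq.int(insert_start, genome_length), seq.int(1L, insert_end))
  }
}

# reference insert sequence of one amplicon
amplicon_insert_seq <- function(reference, insert_start, insert_end) {
  circ_substr(reference$sequence, insert_start, insert_end)
}
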