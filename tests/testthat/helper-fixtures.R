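# Shared fixtures and brute-force oracles for the test suite.

# memoised packaged reference and default panel (design is deterministic)
.fixture_env <- new.env(parent = emptyenv())

test_ref <- function() {
  if (is.null(.fixture_env$ref)) {
    .fixture_env$ref <- load_reference(mt_reference_fasta())
  }
  .fixture_env$ref
}

test_panel <- function() {
  if (is.null(.fixture_env$panel)) {
    .fixture_env$panel <- assign_pools(design_panel(test_ref()), 4L)
  }
  .fixture_env$panel
}

# a small circular toy reference of the given length (deterministic)
toy_reference <- function(length = 300L, name = "toy") {
  set.seed(99)
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(paste0(">", name), seq), fa)
  load_reference(fa)
}

# Brute-force membership oracle: unroll the circle to a doubled linear
# sequence; a wrapping region [start, end] with start > end becomes the
# linear interval [start, end + L], and a position p is contained iff p or
# p + L lies in the linear interval.
oracle_in_region <- function(position, start, end, genome_length) {
  lin_end <- ifelse(start <= end, end, end + genome_length)
  (position >= start & position <= lin_end) |
    (position + genome_length >= start & position + genome_length <= lin_end)
}

# Brute-force caller oracle: enumerate every (position, allele) of a pileup
# and apply the three threshold predicates independently.
oracle_calls <- function(pileup, min_depth = 30L, min_vaf = 0.05,
                         min_strand_balance = 0.2) {
  out <- list()
  for (p in sort(unique(pileup$position))) {
    rows <- pileup[pileup$position == p, ]
    depth <- sum(rows$fwd[!startsWith(rows$allele, "ins:")] +
                   rows$rev[!startsWith(rows$allele, "ins:")])
    for (i in seq_len(nrow(rows))) {
      if (rows$allele[i] == rows$ref[i]) next
      alt_n <- rows$fwd[i] + rows$rev[i]
      vaf <- alt_n / depth
      if (depth >= min_depth && vaf >= min_vaf) {
        sb <- min(rows$fwd[i], rows$rev[i]) / alt_n
        out[[length(out) + 1L]] <- tibble::tibble(
          position = p, allele = rows$allele[i], vaf = vaf,
          filter = if (sb > min_strand_balance) "PASS" else "strand_imbalance")
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(position = integer(), allele = character(),
                   vaf = double(), filter = character())
}

# positions (1-based, unrolled) covered by an amplicon row
amp_pos <- function(s, e, L) {
  if (s <= e) seq.int(s, e) else c(seq.int(s, L), seq.int(1L, e))
}

# Brute-force all-pairs overlap oracle on the unrolled circle
oracle_pool_conflicts <- function(panel) {
  a <- panel$amplicons
  L <- panel$reference$length
  sets <- lapply(seq_len(nrow(a)),
                 function(i) amp_pos(a$insert_start[i], a$insert_end[i], L))
  conflicts <- 0L
  for (i in seq_len(nrow(a) - 1L)) {
    for (j in seq.int(i + 1L, nrow(a))) {
      if (a$pool[i] == a$pool[j] &&
          length(intersect(sets[[i]], sets[[j]])) > 0L) {
        conflicts <- conflicts + 1L
      }
    }
  }
  conflicts
}

# build an annotated PASS-call tibble directly from a truth table, for
# noise-free clonality tests (bypasses read simulation)
truth_to_calls <- function(truth) {
  truth |>
    dplyr::filter(.data$origin != "artifact") |>
    dplyr::mutate(
      vaf = .data$true_vaf,
      filter = "PASS",
      known_polymorphism = .data$origin == "germline",
      plasmy = ifelse(.data$vaf >= 0.95, "homoplasmic", "heteroplasmic"))
}

# expected read-level alt fraction of a planted variant under the
# generator's noise channels (template deamination, then per-read
# sequencing error); used to centre the binomial tolerance
expected_alt_fraction <- function(true_vaf, ref, alt, var_type,
                                  deamination_rate, error_rate) {
  if (var_type != "SNV") return(true_vaf)
  p <- true_vaf
  gain <- (ref == "C" && alt == "T") || (ref == "G" && alt == "A")
  loss <- alt %in% c("C", "G")
  p <- p * (1 - deamination_rate * loss) +
    (1 - p) * deamination_rate * gain
  p * (1 - error_rate) + (1 - p) * error_rate / 3
}
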