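#' @importFrom rlang .data abort warn %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_int map_lgl map2 pmap
NULL

BASES <- c("A", "C", "G", "T")

#' Circular position arithmetic
#'
#' Maps any integer onto 1-based coordinates of a circular genome of length
#' `len`. Position 0 maps to `len`, position `len + 1` maps to 1.
#'
#' @param pos integer vector of (possibly out-of-range) positions
#' @param len genome length in bp
#' @return integer vector in `[1, len]`
#' @keywords internal
circ_pos <- function(pos, len) {
  ((pos - 1L) %% len) + 1L
}

#' Extract a (possibly origin-wrapping) substring of a circular sequence
#'
#' @param sequence character scalar, the full genome
#' @param start,end 1-based inclusive bounds; `start > end` wraps the origin
#' @return character scalar
#' @keywords internal
circ_substr <- function(sequence, start, end) {
  len <- nchar(sequence)
  start <- circ_pos(start, len)
  end <- circ_pos(end, len)
  if (start <= end) {
    substr(sequence, start, end)
  } else {
    paste0(substr(sequence, start, len), substr(sequence, 1L, end))
  }
}

#' Length of a circular interval
#' @keywords internal
circ_span <- function(start, end, len) {
  ifelse(start <= end, end - start + 1L, len - start + 1L + end)
}

#' Reverse complement of a DNA string
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# ---------------------------------------------------------------------------
# Reference container
# ---------------------------------------------------------------------------

new_mt_reference <- function(name, sequence) {
  structure(
    list(
      name = name,
      sequence = toupper(sequence),
      length = nchar(sequence),
      circular = TRUE
    ),
    class = "mt_reference"
  )
}

#' @export
print.mt_reference <- function(x, ...) {
  cat("<mt_reference> ", x$name, ": ", x$length, " bp, circular\n", sep = "")
  invisible(x)
}

#' Load a circular mitochondrial reference from FASTA
#'
#' Reads a single-record FASTA and returns a circular reference object with
#' the sequence uppercased. The mitochondrial genome is a circular molecule,
#' so downstream coordinate arithmetic wraps the origin.
#'
#' @param fasta_path path to a FASTA file containing exactly one record
#' @return an `mt_reference` object with fields `name`, `sequence`,
#'   `length` and `circular = TRUE`
#' @export
#' @examples
#' ref <- load_reference(mt_reference_fasta())
#' ref$length
load_reference <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    abort(paste0("no sequence: file not found: ", fasta_path))
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) {
    abort("no sequence: FASTA file contains no records")
  }
  if (length(seqs) > 1L) {
    abort("ambiguous reference: FASTA file contains more than one record")
  }
  name <- sub("\\s.*$", "", names(seqs)[1])
  sequence <- toupper(as.character(seqs[[1]]))
  if (grepl("[^ACGTN]", sequence)) {
    abort("no sequence: reference contains non-ACGTN characters")
  }
  new_mt_reference(name, sequence)
}

#' Path to the packaged synthetic mitochondrial reference FASTA
#'
#' The packaged reference is a *synthetic* 16,569 bp stand-in for the human
#' mitochondrial reference (rCRS, NC_012920): it has the true length,
#' circular topology and region coordinates, and the reference alleles of
#' the packaged polymorphism-database sites and both microsatellite
#' stretches are pinned to their rCRS values, but the remaining base content
#' is generated deterministically in code (see [synthetic_mt_reference()]).
#'
#' @return path to the FASTA file
#' @export
mt_reference_fasta <- function() {
  system.file("extdata", "rCRS_synthetic.fa", package = "mttrack",
              mustWork = TRUE)
}

# Sites whose reference alleles are pinned into the synthetic genome so that
# the packaged polymorphism snapshot and the variant labels used throughout
# the documentation are consistent with the packaged sequence.
pinned_reference_bases <- function() {
  c(
    # polymorphism-db reference alleles (rCRS values)
    "73" = "A", "146" = "T", "152" = "T", "195" = "T", "263" = "A",
    "489" = "T", "750" = "A", "1438" = "A", "2706" = "A", "3010" = "G",
    "4769" = "A", "7028" = "C", "8860" = "A", "9055" = "G", "10398" = "A",
    "10400" = "C", "11719" = "G", "12308" = "A", "13708" = "G",
    "14766" = "C", "15326" = "A", "16126" = "T", "16223" = "C",
    "16311" = "T", "16519" = "T",
    # sites used in worked multi-lesion examples
    "66" = "G", "215" = "A", "650" = "T", "1180" = "T", "1681" = "G",
    "2268" = "G", "3036" = "G", "11711" = "G", "12125" = "G",
    "12384" = "A", "12385" = "T", "12561" = "G", "13480" = "G"
  )
}

#' Deterministically generate the synthetic mitochondrial reference
#'
#' Builds the 16,569 bp synthetic stand-in genome shipped under
#' `inst/extdata/rCRS_synthetic.fa`. Base content is drawn from a small
#' multiplicative congruential generator (independent of R's RNG state) with
#' heavy-strand-like base composition; a fixed set of positions is then
#' pinned to rCRS reference alleles, and the two mt-microsatellites are laid
#' down explicitly: the hypermutable polyC stretch 16184-16193 (with the
#' rCRS T at 16189) and the 303-315 C-tract (with the rCRS T at 310).
#'
#' @param length genome length in bp
#' @return an `mt_reference`
#' @export
synthetic_mt_reference <- function(length = 16569L) {
  m <- 2147483647
  state <- 1699
  u <- numeric(length)
  for (i in seq_len(length)) {
    state <- (16807 * state) %% m
    u[i] <- state / m
  }
  # approximate heavy-strand composition of the human mt-genome
  cuts <- cumsum(c(A = 0.31, C = 0.31, G = 0.13, T = 0.25))
  base <- BASES[findInterval(u, c(0, cuts[-4]))]

  pins <- pinned_reference_bases()
  idx <- as.integer(names(pins))
  keep <- idx <= length
  base[idx[keep]] <- unname(pins[keep])

  if (length >= 16193L) {
    base[16184:16193] <- c("C", "C", "C", "C", "C", "T", "C", "C", "C", "C")
  }
  if (length >= 315L) {
    base[303:315] <- c(rep("C", 7), "T", rep("C", 5))
  }
  new_mt_reference("NC_012920_synthetic", paste0(base, collapse = ""))
}

# ---------------------------------------------------------------------------
# Region map
# ---------------------------------------------------------------------------

#' Load the packaged mitochondrial region annotation table
#'
#' Returns the 40-row region map of the mitochondrial genome: the 37 genes
#' (13 protein-coding, 2 rRNA, 22 tRNA) at their standard rCRS coordinates,
#' the control region (D-LOOP, 16024-576, wrapping the origin of the
#' circular map), and the two hypermutable microsatellite stretches
#' (polyC 16184-16193 and 302-315).
#'
#' @param path optional path to an alternative tab-separated region table
#'   with columns `label`, `start`, `end`, `category`
#' @return a tibble with columns `label`, `start`, `end`, `category`
#' @export
mt_regions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "mt_regions.tsv",
                                package = "mttrack", mustWork = TRUE)
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  categories <- c("protein_gene", "rRNA", "tRNA", "control_region",
                  "microsatellite")
  bad <- setdiff(unique(tbl$category), categories)
  if (length(bad) > 0) {
    abort(paste0("unknown region category: ", paste(bad, collapse = ", ")))
  }
  tbl |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
}

#' Regions containing a genomic position
#'
#' Interval containment on the circular genome: a region with `start > end`
#' wraps the origin (the D-LOOP, 16024-576, contains both 16100 and 300).
#'
#' @param position a single 1-based position
#' @param region_map tibble from [mt_regions()]
#' @param genome_length genome length for range checking
#' @return character vector of region labels containing the position
#'   (empty if intergenic)
#' @export
#' @examples
#' region_of(16189, mt_regions())
region_of <- function(position, region_map, genome_length = 16569L) {
  if (length(position) != 1L || is.na(position) ||
      position < 1L || position > genome_length) {
    abort("position outside genome")
  }
  hit <- position_in_region(position, region_map$start, region_map$end)
  region_map$label[hit]
}

# vectorised over regions for a scalar position
position_in_region <- function(position, start, end) {
  ifelse(start <= end,
         position >= start & position <= end,
         position >= start | position <= end)
}

#' Tidy region membership for a vector of positions
#'
#' @param positions integer vector of 1-based positions
#' @param region_map tibble from [mt_regions()]
#' @return tibble with columns `position`, `label`, `category`; positions in
#'   no annotated region get a single row with label and category
#'   `"intergenic"`
#' @export
regions_at <- function(positions, region_map) {
  purrr::map_dfr(positions, function(p) {
    hit <- position_in_region(p, region_map$start, region_map$end)
    if (!any(hit)) {
      tibble(position = p, label = "intergenic", category = "intergenic")
    } else {
      tibble(position = p, label = region_map$label[hit],
             category = region_map$category[hit])
    }
  })
}

#' Export the region map as BED
#'
#' BED is 0-based half-open; regions wrapping the origin are split into two
#' BED records carrying the same name.
#'
#' @param region_map tibble from [mt_regions()]
#' @param path output file
#' @param genome_length circular genome length
#' @param chrom chromosome name written in column 1
#' @return the path, invisibly
#' @export
write_regions_bed <- function(region_map, path, genome_length = 16569L,
                              chrom = "chrM") {
  rows <- purrr::pmap_dfr(region_map, function(label, start, end, category) {
    if (start <= end) {
      tibble(chrom = chrom, start = start - 1L, end = end, name = label)
    } else {
      tibble(chrom = chrom,
             start = c(start - 1L, 0L),
             end = c(genome_length, end),
             name = label)
    }
  })
  readr::write_tsv(rows, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Variant descriptors and labels
# ---------------------------------------------------------------------------

#' Construct a variant descriptor table
#'
#' The common currency for variants: one row per variant with the 1-based
#' position (for insertions, the 5' flanking position; for deletions, the
#' first deleted base), the reference and alternate alleles (the absent side
#' of an indel is the empty string), and the variant type.
#'
#' @param position integer vector
#' @param ref,alt character vectors; `""` encodes the absent side of indels
#' @return tibble with columns `position`, `ref`, `alt`, `var_type`
#' @export
variant_descriptor <- function(position, ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  var_type <- dplyr::case_when(
    ref != "" & alt != "" ~ "SNV",
    ref != "" & alt == "" ~ "deletion",
    ref == "" & alt != "" ~ "insertion",
    TRUE ~ NA_character_
  )
  bad_snv <- var_type == "SNV" &
    (nchar(ref) != 1L | nchar(alt) != 1L | ref == alt)
  if (any(is.na(var_type)) || any(bad_snv)) {
    abort("invalid variant descriptor: SNVs need two different single bases; indels encode the absent side as \"\"")
  }
  tibble(position = as.integer(position), ref = ref, alt = alt,
         var_type = var_type)
}

#' Parse variant labels in the mt-naming dialect
#'
#' Understands three label forms: `"G3036A"` (SNV), `"66 del-G"` (deletion
#' of G at 66) and `"12384^12385-ins C"` (insertion of C between adjacent
#' positions 12384 and 12385).
#'
#' @param label character vector of labels
#' @param genome_length circular genome length, used to validate the
#'   adjacency of insertion anchors across the origin
#' @return tibble with one row per label: `position`, `ref`, `alt`,
#'   `var_type`
#' @export
#' @examples
#' parse_variant_label(c("G3036A", "66 del-G", "12384^12385-ins C"))
parse_variant_label <- function(label, genome_length = 16569L) {
  parse_one <- function(lab) {
    lab <- trimws(lab)
    m <- stringr::str_match(lab, "^([ACGT])(\\d+)([ACGT])$")
    if (!is.na(m[1, 1])) {
      if (m[1, 2] == m[1, 4]) abort("unrecognised variant label: ref == alt")
      return(variant_descriptor(as.integer(m[1, 3]), m[1, 2], m[1, 4]))
    }
    m <- stringr::str_match(lab, "^(\\d+)\\s*del-([ACGT]+)$")
    if (!is.na(m[1, 1])) {
      return(variant_descriptor(as.integer(m[1, 2]), m[1, 3], ""))
    }
    m <- stringr::str_match(lab, "^(\\d+)\\^(\\d+)-ins\\s*([ACGT]+)$")
    if (!is.na(m[1, 1])) {
      p1 <- as.integer(m[1, 2])
      p2 <- as.integer(m[1, 3])
      if (circ_pos(p1 + 1L, genome_length) != circ_pos(p2, genome_length)) {
        abort("non-adjacent insertion anchor")
      }
      return(variant_descriptor(p1, "", m[1, 4]))
    }
    abort(paste0("unrecognised variant label: ", lab))
  }
  purrr::map_dfr(label, parse_one)
}

#' Format variant descriptors back into canonical labels
#'
#' Inverse of [parse_variant_label()].
#'
#' @param descriptor tibble with columns `position`, `ref`, `alt`,
#'   `var_type`
#' @param genome_length circular genome length (insertion anchors wrap)
#' @return character vector of labels
#' @export
format_variant_label <- function(descriptor, genome_length = 16569L) {
  purrr::pmap_chr(
    descriptor[, c("position", "ref", "alt", "var_type")],
    function(position, ref, alt, var_type) {
      switch(var_type,
        SNV = paste0(ref, position, alt),
        deletion = paste0(position, " del-", ref),
        insertion = paste0(position, "^", circ_pos(position + 1L, genome_length),
                           "-ins ", alt),
        abort("unknown var_type")
      )
    }
  )
}

#' Left-align an indel descriptor within its repeat context
#'
#' Indels inside homopolymer or repeat runs have several equivalent
#' placements; this package canonicalises them to the leftmost one, both
#' when planting simulated indels and when extracting indel alleles from
#' aligned reads, so that truth and calls always use the same anchor.
#' Insertions shift left while the base at the anchor equals the last base
#' of the (rotated) inserted sequence; deletions shift left while the base
#' before the first deleted base equals the last deleted base.
#'
#' @param descriptor tibble with `position`, `ref`, `alt`, `var_type`
#' @param sequence the genome sequence (character scalar)
#' @return the descriptor with canonical anchors
#' @export
left_align_indel <- function(descriptor, sequence) {
  shift_one <- function(position, ref, alt, var_type) {
    if (var_type == "insertion") {
      s <- strsplit(alt, "", fixed = TRUE)[[1]]
      m <- length(s)
      while (position >= 1L &&
             substr(sequence, position, position) == s[m]) {
        s <- c(s[m], s[-m])
        position <- position - 1L
      }
      alt <- paste(s, collapse = "")
    } else if (var_type == "deletion") {
      d <- strsplit(ref, "", fixed = TRUE)[[1]]
      m <- length(d)
      while (position > 1L &&
             substr(sequence, position - 1L, position - 1L) == d[m]) {
        d <- c(d[m], d[-m])
        position <- position - 1L
      }
      ref <- paste(d, collapse = "")
    }
    tibble(position = position, ref = ref, alt = alt, var_type = var_type)
  }
  purrr::pmap_dfr(
    descriptor[, c("position", "ref", "alt", "var_type")], shift_one)
}

#' Strand-collapsed substitution spectrum class
#'
#' Collapses strand-complement substitution pairs into the two transition
#' classes reported for mt-genomes: `{T>C, A>G}` to `"T>C/A>G"` and
#' `{G>A, C>T}` to `"G>A/C>T"`; every transversion is `"other"`. The
#' classification is invariant under complementing both alleles.
#'
#' @param ref,alt single-base character vectors, elementwise `ref != alt`
#' @return character vector of class labels
#' @export
#' @examples
#' substitution_class("T", "C")
substitution_class <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (any(ref == alt)) abort("not a substitution: ref == alt")
  if (any(!ref %in% BASES) || any(!alt %in% BASES)) {
    abort("not a substitution: alleles must be single bases")
  }
  key <- paste0(ref, ">", alt)
  dplyr::case_when(
    key %in% c("T>C", "A>G") ~ "T>C/A>G",
    key %in% c("G>A", "C>T") ~ "G>A/C>T",
    TRUE ~ "other"
  )
}
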