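# Read-to-amplicon assignment, strand-aware pileups, threshold-based variant
# calling (minimum depth 30, minimum allele fraction 5%, strand balance
# > 0.2) and per-sample run metrics.

#' Read a pair of FASTQ files into a read tibble
#'
#' @param r1_path,r2_path paired FASTQ files
#' @return tibble with columns `name`, `r1`, `r2`
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  s1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  if (length(s1) != length(s2)) abort("unpaired FASTQ files")
  tibble(name = names(s1), r1 = as.character(s1), r2 = as.character(s2))
}

# byte lookup: ASCII code -> base index 1..4
BASE_CODE <- local({
  x <- rep(NA_integer_, 256)
  x[utf8ToInt("A")] <- 1L; x[utf8ToInt("C")] <- 2L
  x[utf8ToInt("G")] <- 3L; x[utf8ToInt("T")] <- 4L
  x
})

# strand-aware per-position allele counting of equal-length fragments
count_fragments <- function(frags, w) {
  counts <- matrix(0L, nrow = w, ncol = 4L,
                   dimnames = list(NULL, BASES))
  if (length(frags) == 0L) return(counts)
  code <- BASE_CODE[as.integer(charToRaw(paste(frags, collapse = "")))]
  row_i <- rep_len(seq_len(w), length(code))
  ok <- !is.na(code)
  tab <- tabulate(row_i[ok] + w * (code[ok] - 1L), nbins = 4L * w)
  counts[] <- tab
  counts
}

# place indel-bearing fragments by global alignment against the insert
# reference; returns per-position base counts plus weighted del/ins allele
# events. Identical fragments (the common case at low error rates) are
# deduplicated and aligned once.
align_indel_fragments <- function(frags, ref_insert) {
  w <- nchar(ref_insert)
  counts <- matrix(0L, nrow = w, ncol = 4L, dimnames = list(NULL, BASES))
  empty <- tibble(offset = integer(), allele = character(), n = integer())
  if (length(frags) == 0L) {
    return(list(counts = counts, events = empty))
  }
  tab <- table(frags)
  uf <- names(tab)
  wt <- as.integer(tab)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(uf),
    subject = ref_insert, type = "global",
    gapOpening = 10, gapExtension = 4)
  # indel ranges are cheap to extract, unlike the gapped alignment strings:
  # insertion ranges are in pattern coordinates, deletion ranges in subject
  # coordinates
  ind <- Biostrings::indel(aln)
  ins_l <- Biostrings::insertion(ind)
  del_l <- Biostrings::deletion(ind)
  ref_chars <- strsplit(ref_insert, "", fixed = TRUE)[[1]]
  ev_off <- integer(0)
  ev_allele <- character(0)
  ev_n <- integer(0)
  subj_frame <- character(length(uf))
  for (i in seq_along(uf)) {
    pat <- uf[i]
    is_s <- IRanges::start(ins_l[[i]]); is_e <- IRanges::end(ins_l[[i]])
    ds <- IRanges::start(del_l[[i]]);   de <- IRanges::end(del_l[[i]])
    # left-align each deletion block within its repeat run, so that the
    # emitted events and the subject-frame gap columns agree on placement
    ds2 <- ds; de2 <- de
    for (k in seq_along(ds2)) {
      floor_k <- if (k > 1L) de2[k - 1L] + 1L else 1L
      while (ds2[k] > floor_k && ref_chars[ds2[k] - 1L] == ref_chars[de2[k]]) {
        ds2[k] <- ds2[k] - 1L
        de2[k] <- de2[k] - 1L
      }
    }
    # pattern with inserted stretches removed ...
    core <- if (length(is_s)) {
      keep_start <- c(1L, is_e + 1L)
      keep_end <- c(is_s - 1L, nchar(pat))
      kept <- substring(pat, keep_start, keep_end)
      paste(kept[keep_start <= keep_end], collapse = "")
    } else pat
    # ... then "-" restored at deleted subject positions gives the read in
    # the subject frame, width-aligned for byte counting
    if (length(ds2)) {
      pieces <- character(0)
      prev <- 0L
      cpos <- 0L
      for (k in seq_along(ds2)) {
        len <- ds2[k] - 1L - prev
        pieces <- c(pieces, substr(core, cpos + 1L, cpos + len),
                    strrep("-", de2[k] - ds2[k] + 1L))
        cpos <- cpos + len
        prev <- de2[k]
      }
      subj_frame[i] <- paste(c(pieces,
                               substr(core, cpos + 1L, nchar(core))),
                             collapse = "")
    } else {
      subj_frame[i] <- core
    }
    # deletion events: one per deleted base, at the left-aligned block
    for (k in seq_along(ds2)) {
      for (pos in seq.int(ds2[k], de2[k])) {
        ev_off <- c(ev_off, pos)
        ev_allele <- c(ev_allele, "del")
        ev_n <- c(ev_n, wt[i])
      }
    }
    # insertion events at the 5' anchor, leftmost-canonical rotation
    for (k in seq_along(is_s)) {
      ins <- strsplit(substr(pat, is_s[k], is_e[k]), "", fixed = TRUE)[[1]]
      prior_ins <- if (k > 1L) sum(is_e[seq_len(k - 1L)] -
                                     is_s[seq_len(k - 1L)] + 1L) else 0L
      base <- is_s[k] - 1L - prior_ins
      # map the anchor from insertion-free pattern to subject coordinates:
      # add back deletions lying at or before it (fixed point of a
      # monotone map, converges in <= number of deletion runs steps)
      anchor <- base
      repeat {
        d <- if (length(ds)) {
          sum(pmax(0L, pmin(de, anchor) - ds + 1L))
        } else 0L
        new_anchor <- base + d
        if (new_anchor == anchor) break
        anchor <- new_anchor
      }
      ioff <- anchor
      while (ioff > 1L && ref_chars[ioff] == ins[length(ins)]) {
        ins <- c(ins[length(ins)], ins[-length(ins)])
        ioff <- ioff - 1L
      }
      ev_off <- c(ev_off, ioff)
      ev_allele <- c(ev_allele, paste0("ins:", paste(ins, collapse = "")))
      ev_n <- c(ev_n, wt[i])
    }
  }
  counts <- count_fragments(rep(subj_frame, wt), w)
  list(counts = counts,
       events = if (length(ev_off)) tibble(offset = ev_off,
                                           allele = ev_allele, n = ev_n)
                else empty)
}

#' Assign read pairs to amplicons and build a strand-aware pileup
#'
#' Each read pair is assigned to the unique amplicon whose forward primer
#' prefixes read 1; pairs matching no primer are counted as off-target.
#' Primer bases are stripped and the insert bases are piled up per genomic
#' position, with read-1 bases counted on the forward strand and read-2
#' bases (reverse-complemented back to reference orientation) on the
#' reverse strand. Reads whose insert length differs from the amplicon
#' insert are placed by global alignment, contributing `del` /
#' `ins:<seq>` alleles at the first deleted base / 5' anchor position.
#'
#' @param reads either a tibble from [simulate_reads()] (columns `name`,
#'   `r1`, `r2`) or a length-2 character vector of paired FASTQ paths
#' @param panel an `mt_panel` with primer sequences
#' @param reference the [mt_reference][load_reference]
#' @return list with `pileup` (tibble: position, ref, allele, fwd, rev),
#'   `depth` (tibble: position, depth), and `metrics` (one-row tibble:
#'   total_pairs, assigned_pairs, total_reads, mapped_mt_reads,
#'   specificity, covered_fraction, mean_depth_per_100bp)
#' @export
assign_and_pileup <- function(reads, panel, reference) {
  if (is.character(reads)) {
    reads <- read_fastq_pairs(reads[1], reads[2])
  }
  amp <- panel$amplicons
  plen <- nchar(amp$fwd_primer[1])
  L <- reference$length

  key <- substr(reads$r1, 1L, plen)
  amp_idx <- match(key, amp$fwd_primer)
  assigned <- !is.na(amp_idx)
  if (!any(assigned)) abort("no on-target data: no read matches a panel primer")

  # strip primers and orient read 2 once, up front: a single
  # reverse-complement over all assigned reads avoids per-amplicon S4
  # container construction, which dominates runtime otherwise
  frag1 <- rep(NA_character_, nrow(reads))
  frag2 <- rep(NA_character_, nrow(reads))
  frag1[assigned] <- substr(reads$r1[assigned], plen + 1L,
                            nchar(reads$r1[assigned]))
  frag2[assigned] <- revcomp_many(substr(reads$r2[assigned], plen + 1L,
                                         nchar(reads$r2[assigned])))

  fwd_counts <- vector("list", nrow(amp))
  rev_counts <- vector("list", nrow(amp))
  fwd_events <- vector("list", nrow(amp))
  rev_events <- vector("list", nrow(amp))
  pos_of <- vector("list", nrow(amp))

  for (i in seq_len(nrow(amp))) {
    sel <- which(amp_idx == i)
    pos <- amplicon_positions(amp$insert_start[i], amp$insert_end[i], L)
    pos_of[[i]] <- pos
    w <- amp$insert_length[i]
    ref_insert <- amplicon_insert_seq(reference, amp$insert_start[i],
                                      amp$insert_end[i])
    if (length(sel) == 0L) {
      fwd_counts[[i]] <- rev_counts[[i]] <-
        matrix(0L, nrow = w, ncol = 4L, dimnames = list(NULL, BASES))
      fwd_events[[i]] <- rev_events[[i]] <-
        tibble(offset = integer(), allele = character(), n = integer())
      next
    }
    f1 <- frag1[sel]
    f2 <- frag2[sel]
    for (strand in c("fwd", "rev")) {
      fr <- if (strand == "fwd") f1 else f2
      same <- nchar(fr) == w
      cnt <- count_fragments(fr[same], w)
      al <- align_indel_fragments(fr[!same], ref_insert)
      cnt <- cnt + al$counts
      if (strand == "fwd") {
        fwd_counts[[i]] <- cnt; fwd_events[[i]] <- al$events
      } else {
        rev_counts[[i]] <- cnt; rev_events[[i]] <- al$events
      }
    }
  }

  base_rows <- purrr::map_dfr(seq_len(nrow(amp)), function(i) {
    pos <- pos_of[[i]]
    fc <- fwd_counts[[i]]
    rc <- rev_counts[[i]]
    nz <- which(fc + rc > 0, arr.ind = TRUE)
    ev <- dplyr::bind_rows(
      fwd_events[[i]] |> mutate(strand = "fwd"),
      rev_events[[i]] |> mutate(strand = "rev"))
    ev_rows <- NULL
    if (nrow(ev)) {
      ev2 <- ev |>
        count(.data$offset, .data$allele, .data$strand, wt = .data$n,
              name = "nn") |>
        tidyr::pivot_wider(names_from = "strand", values_from = "nn",
                           values_fill = 0L)
      if (!"fwd" %in% names(ev2)) ev2$fwd <- 0L
      if (!"rev" %in% names(ev2)) ev2$rev <- 0L
      ev_rows <- ev2 |>
        mutate(position = pos[.data$offset]) |>
        select("position", "allele", "fwd", "rev")
    }
    dplyr::bind_rows(
      if (nrow(nz)) tibble(position = pos[nz[, 1]],
                           allele = BASES[nz[, 2]],
                           fwd = fc[nz], rev = rc[nz]),
      ev_rows
    )
  })

  pileup <- base_rows |>
    group_by(.data$position, .data$allele) |>
    summarise(fwd = sum(.data$fwd), rev = sum(.data$rev), .groups = "drop") |>
    mutate(ref = substring(reference$sequence, .data$position,
                           .data$position)) |>
    select("position", "ref", "allele", "fwd", "rev") |>
    arrange(.data$position, .data$allele)

  depth <- pileup |>
    filter(!startsWith(.data$allele, "ins:")) |>
    group_by(.data$position) |>
    summarise(depth = sum(.data$fwd + .data$rev), .groups = "drop")

  n_total <- nrow(reads)
  n_assigned <- sum(assigned)
  covered <- sum(depth$depth >= 30L)
  metrics <- tibble(
    total_pairs = n_total,
    assigned_pairs = n_assigned,
    total_reads = 2L * n_total,
    mapped_mt_reads = 2L * n_assigned,
    specificity = 100 * n_assigned / n_total,
    covered_fraction = 100 * covered / L,
    mean_depth_per_100bp = 2 * n_assigned / L * 100
  )
  list(pileup = pileup, depth = depth, metrics = metrics)
}

#' Call variants from a strand-aware pileup
#'
#' A candidate is every non-reference allele at a position. A call is
#' emitted when the position depth is at least `min_depth` and the allele
#' fraction is at least `min_vaf`; calls whose strand balance (minor-strand
#' fraction of alt-supporting reads, `min(fwd, rev) / (fwd + rev)`) is not
#' strictly greater than `min_strand_balance` carry the filter flag
#' `strand_imbalance`, all others are `PASS`. Multi-allelic positions emit
#' one call per qualifying alternate allele. The position depth counts all
#' spanning reads (base and deletion alleles; inserted sequences are not
#' extra depth).
#'
#' @param pileup tibble from [assign_and_pileup()]
#' @param min_depth minimum position depth (reads)
#' @param min_vaf minimum allele fraction
#' @param min_strand_balance strand-balance floor (strict inequality)
#' @return tibble with columns position, ref, alt, var_type, label, depth,
#'   alt_fwd, alt_rev, vaf, strand_balance, filter, ordered by
#'   (position, alt)
#' @export
call_variants <- function(pileup, min_depth = 30L, min_vaf = 0.05,
                          min_strand_balance = 0.2) {
  if (nrow(pileup) == 0L) {
    return(tibble(position = integer(), ref = character(),
                  alt = character(), var_type = character(),
                  label = character(), depth = integer(),
                  alt_fwd = integer(), alt_rev = integer(), vaf = double(),
                  strand_balance = double(), filter = character()))
  }
  depth_tbl <- pileup |>
    filter(!startsWith(.data$allele, "ins:")) |>
    group_by(.data$position) |>
    summarise(depth = sum(.data$fwd + .data$rev), .groups = "drop")

  calls <- pileup |>
    filter(.data$allele != .data$ref) |>
    left_join(depth_tbl, by = "position") |>
    mutate(
      var_type = dplyr::case_when(
        .data$allele == "del" ~ "deletion",
        startsWith(.data$allele, "ins:") ~ "insertion",
        TRUE ~ "SNV"
      ),
      alt = dplyr::case_when(
        .data$var_type == "deletion" ~ "",
        .data$var_type == "insertion" ~ sub("^ins:", "", .data$allele),
        TRUE ~ .data$allele
      ),
      ref = ifelse(.data$var_type == "insertion", "", .data$ref),
      alt_fwd = .data$fwd, alt_rev = .data$rev,
      vaf = (.data$alt_fwd + .data$alt_rev) / .data$depth,
      strand_balance = pmin(.data$alt_fwd, .data$alt_rev) /
        (.data$alt_fwd + .data$alt_rev)
    ) |>
    filter(.data$depth >= min_depth, .data$vaf >= min_vaf) |>
    mutate(
      filter = ifelse(.data$strand_balance > min_strand_balance,
                      "PASS", "strand_imbalance"),
      label = format_variant_label(
        dplyr::pick("position", "ref", "alt", "var_type"))
    ) |>
    select("position", "ref", "alt", "var_type", "label", "depth",
           "alt_fwd", "alt_rev", "vaf", "strand_balance", "filter") |>
    arrange(.data$position, .data$alt)
  calls
}

#' Classify calls as homoplasmic or heteroplasmic
#'
#' A variant is homoplasmic when its allele fraction is at least
#' `homoplasmy_vaf` (default 0.95, symmetric with the 5% calling floor);
#' otherwise heteroplasmic.
#'
#' @param calls tibble from [call_variants()]
#' @param homoplasmy_vaf inclusive homoplasmy threshold
#' @return `calls` with a `plasmy` column
#' @export
classify_plasmy <- function(calls, homoplasmy_vaf = 0.95) {
  calls |>
    mutate(plasmy = ifelse(.data$vaf >= homoplasmy_vaf,
                           "homoplasmic", "heteroplasmic"))
}

#' Write per-sample run metrics as TSV
#'
#' One row per sample: run specificity (% of read pairs assigned to a panel
#' amplicon), covered fraction (% of genome positions at depth >= 30) and
#' mean read depth per 100 bp (mapped reads / genome length x 100).
#'
#' @param metrics tibble with one row per sample (a `sample` column plus
#'   the columns of `assign_and_pileup()$metrics`)
#' @param path output TSV
#' @return the path, invisibly
#' @export
run_metrics_report <- function(metrics, path) {
  readr::write_tsv(metrics, path, progress = FALSE)
  invisible(path)
}

#' Write calls as a VCF file
#'
#' Minimal VCF 4.2 with INFO fields VAF, DP and SB, the plasmy class, and
#' the filter flags in FILTER. Indels are re-anchored to VCF conventions
#' (deletions reported at the base before the first deleted base;
#' insertions at their 5' flanking base).
#'
#' @param calls tibble from [call_variants()] (optionally annotated and
#'   plasmy-classified)
#' @param path output `.vcf` path
#' @param reference the [mt_reference][load_reference]
#' @param sample_id sample name recorded in the header
#' @return the path, invisibly
#' @export
write_vcf <- function(calls, path, reference, sample_id = "sample") {
  L <- reference$length
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##reference=", reference$name),
    paste0("##contig=<ID=", reference$name, ",length=", L, ">"),
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Position depth\">",
    "##INFO=<ID=SB,Number=1,Type=Float,Description=\"Strand balance (minor-strand alt fraction)\">",
    "##INFO=<ID=PLASMY,Number=1,Type=String,Description=\"homoplasmic or heteroplasmic\">",
    "##FILTER=<ID=strand_imbalance,Description=\"Strand balance below threshold\">",
    "##FILTER=<ID=recurrent_similar_vaf,Description=\"Similar VAF across patients\">",
    "##FILTER=<ID=amplicon_end,Description=\"Near amplicon insert boundary in all covering amplicons\">",
    "##FILTER=<ID=repetitive_region,Description=\"Microsatellite or repetitive region\">",
    "##FILTER=<ID=noisy_region,Description=\"High cross-sample background noise\">",
    paste0("##sample=", sample_id),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(calls) > 0) {
    plasmy <- if ("plasmy" %in% names(calls)) calls$plasmy else NA_character_
    flt <- if ("flags" %in% names(calls)) {
      ifelse(calls$flags == "", "PASS", gsub(",", ";", calls$flags))
    } else calls$filter
    rows <- purrr::map_chr(seq_len(nrow(calls)), function(i) {
      pos <- calls$position[i]
      if (calls$var_type[i] == "SNV") {
        vpos <- pos; vref <- calls$ref[i]; valt <- calls$alt[i]
      } else if (calls$var_type[i] == "deletion") {
        anchor <- circ_pos(pos - 1L, L)
        a <- substring(reference$sequence, anchor, anchor)
        vpos <- anchor; vref <- paste0(a, calls$ref[i]); valt <- a
      } else {
        a <- substring(reference$sequence, pos, pos)
        vpos <- pos; vref <- a; valt <- paste0(a, calls$alt[i])
      }
      info <- sprintf("VAF=%.6g;DP=%d;SB=%.6g%s", calls$vaf[i],
                      calls$depth[i], calls$strand_balance[i],
                      if (!is.na(plasmy[i])) paste0(";PLASMY=", plasmy[i]) else "")
      paste(reference$name, vpos, ".", vref, valt, ".", flt[i], info,
            sep = "\t")
    })
    hdr <- c(hdr, rows)
  }
  writeLines(hdr, path)
  invisible(path)
}
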