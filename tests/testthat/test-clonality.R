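# truth rows for one variant across a set of carrier lesions
tvar <- function(position, ref, alt, var_type, origin, lesions, vaf,
                 patient = "P01") {
  tidyr::crossing(
    dplyr::tibble(patient = patient, position = position, ref = ref,
                  alt = alt, var_type = var_type, origin = origin),
    dplyr::tibble(lesion = lesions)) |>
    dplyr::mutate(true_vaf = vaf) |>
    dplyr::select("patient", "lesion", "position", "ref", "alt",
                  "var_type", "origin", "true_vaf")
}

four_lesions <- paste0("TN", 1:4)

four_lesion_calls <- function() {
  truth <- dplyr::bind_rows(
    tvar(10398L, "A", "G", "SNV", "germline", four_lesions, 1.0),
    tvar(1000L, "A", "G", "SNV", "trunk", four_lesions, 0.5),
    tvar(650L, "T", "C", "SNV", "branch", c("TN3", "TN4"), 0.3),
    tvar(66L, "G", "", "deletion", "private", "TN1", 0.2))
  truth_to_calls(truth)
}

test_that("carrier counts classify trunk, branch and private", {
  asg <- classify_trunk_branch_private(four_lesion_calls())
  expect_s3_class(asg, "clonal_assignment")
  v <- asg$variants
  expect_identical(v$category[v$label == "A1000G"], "trunk")
  expect_identical(v$category[v$label == "T650C"], "branch")
  expect_identical(v$category[v$label == "66 del-G"], "private")
  expect_identical(v$carriers[[which(v$label == "T650C")]], c("TN3", "TN4"))
  # germline polymorphism excluded from the somatic set but retained
  expect_false("A10398G" %in% v$label)
  expect_identical(asg$germline$label, "A10398G")
  # glance reports the partition
  g <- glance(asg)
  expect_identical(g$n_somatic, 3L)
  expect_identical(c(g$n_trunk, g$n_branch, g$n_private), c(1L, 1L, 1L))
  expect_identical(g$n_germline_polymorphisms, 1L)
  # tidy flattens carrier sets
  td <- tidy(asg)
  expect_identical(td$carriers[td$label == "T650C"], "TN3,TN4")
  # the somatic categories partition the somatic variants
  expect_identical(sort(table(v$category))[["trunk"]], 1L)
  expect_identical(nrow(v), g$n_trunk + g$n_branch + g$n_private)
})

test_that("a heteroplasmic known polymorphism stays somatic", {
  truth <- tvar(10398L, "A", "G", "SNV", "germline", four_lesions, 1.0)
  calls <- truth_to_calls(truth) |>
    dplyr::mutate(vaf = 0.5, plasmy = "heteroplasmic")
  asg <- classify_trunk_branch_private(calls)
  expect_identical(asg$variants$category, "trunk")
  expect_identical(nrow(asg$germline), 0L)
})

test_that("presence needs the VAF floor, and absent lesions need `lesions`", {
  truth <- dplyr::bind_rows(
    tvar(1000L, "A", "G", "SNV", "trunk", c("TN1", "TN2"), 0.5),
    tvar(2000L, "C", "T", "SNV", "private", "TN1", 0.2))
  calls <- truth_to_calls(truth)
  # drop the TN2 copy below the floor: the variant becomes private
  calls$vaf[calls$position == 1000L & calls$lesion == "TN2"] <- 0.01
  asg <- classify_trunk_branch_private(calls)
  expect_identical(asg$variants$category[asg$variants$position == 1000L],
                   "private")
  # a third lesion with no calls at all is honoured via `lesions`
  asg3 <- classify_trunk_branch_private(
    truth_to_calls(truth), lesions = c("TN1", "TN2", "TN3"))
  expect_identical(asg3$variants$category[asg3$variants$position == 1000L],
                   "branch")
  expect_error(
    classify_trunk_branch_private(truth_to_calls(truth) |>
                                    dplyr::filter(lesion == "TN1")),
    "clonality undefined for one lesion")
})

test_that("the preset patient reconstructs TN2/TN3 as sisters", {
  preset <- preset_patient_05(test_ref())
  asg <- classify_trunk_branch_private(truth_to_calls(preset$truth))
  res <- build_clonal_tree(asg)
  expect_identical(nrow(res$conflicts), 0L)
  expect_identical(res$dropped, character(0))
  splits <- clone_tree_splits(res$tree)
  expect_identical(length(splits), 1L)
  expect_identical(splits[[1]], c("TN2", "TN3"))
  # matches the generating tree's nontrivial splits
  expect_identical(splits, clone_tree_splits(preset$tree))
  # the three branch variants attach to the TN2/TN3 edge
  pl <- res$tree$placement
  branch_edges <- pl$edge_child[pl$label %in%
                                  c("A215G", "G2268A", "G11711A")]
  expect_identical(length(unique(branch_edges)), 1L)
  nwk <- clone_tree_newick(res$tree)
  expect_true(grepl("\\(TN2,TN3\\)", nwk))
  expect_true(endsWith(nwk, ";"))
  path <- tempfile(fileext = ".nwk")
  write_clone_tree(res$tree, path)
  expect_identical(readLines(path), nwk)
})

test_that("crossing carrier sets are reported and the weaker one dropped", {
  truth <- dplyr::bind_rows(
    tvar(1000L, "A", "G", "SNV", "branch", c("TN1", "TN2"), 0.3),
    tvar(2000L, "C", "T", "SNV", "branch", c("TN1", "TN2"), 0.3),
    tvar(3000L, "G", "A", "SNV", "branch", c("TN2", "TN3"), 0.3))
  asg <- classify_trunk_branch_private(truth_to_calls(truth),
                                       lesions = paste0("TN", 1:3))
  res <- build_clonal_tree(asg)
  expect_identical(nrow(res$conflicts), 1L)
  expect_identical(res$conflicts$set1, "TN1,TN2")   # kept: support 2
  expect_identical(res$conflicts$set2, "TN2,TN3")
  expect_identical(res$dropped, "G3000A")
  expect_identical(clone_tree_splits(res$tree), list(c("TN1", "TN2")))
})

test_that("only-private variants yield a star tree", {
  truth <- dplyr::bind_rows(
    tvar(1000L, "A", "G", "SNV", "private", "TN1", 0.3),
    tvar(2000L, "C", "T", "SNV", "private", "TN2", 0.3),
    tvar(3000L, "G", "A", "SNV", "private", "TN3", 0.3))
  asg <- classify_trunk_branch_private(truth_to_calls(truth))
  res <- build_clonal_tree(asg)
  expect_identical(clone_tree_splits(res$tree), list())
  expect_identical(nrow(res$conflicts), 0L)
})

test_that("verdicts are untrackable, monoclonal or independent", {
  # only shared homoplasmic polymorphisms: lineage cannot be traced
  germ_only <- truth_to_calls(
    tvar(10398L, "A", "G", "SNV", "germline", c("TN1", "TN2"), 1.0))
  asg_u <- classify_trunk_branch_private(germ_only)
  v_u <- clonal_verdict(asg_u, build_clonal_tree(asg_u))
  expect_identical(v_u$verdict, "untrackable")

  # any somatic trunk variant proves a common origin
  asg_m <- classify_trunk_branch_private(four_lesion_calls())
  v_m <- clonal_verdict(asg_m, build_clonal_tree(asg_m))
  expect_identical(v_m$verdict, "monoclonal")
  expect_identical(v_m$evidence$n_trunk, 1L)

  # private-only variants: independent origins
  priv <- truth_to_calls(dplyr::bind_rows(
    tvar(1000L, "A", "G", "SNV", "private", "TN1", 0.3),
    tvar(2000L, "C", "T", "SNV", "private", "TN2", 0.3)))
  asg_i <- classify_trunk_branch_private(priv)
  expect_identical(clonal_verdict(asg_i)$verdict, "independent")

  # branch without trunk: no evidence of a single origin of all lesions
  br <- truth_to_calls(
    tvar(1000L, "A", "G", "SNV", "branch", c("TN1", "TN2"), 0.3))
  asg_b <- classify_trunk_branch_private(br, lesions = paste0("TN", 1:3))
  expect_identical(clonal_verdict(asg_b)$verdict, "independent")
})

test_that("the venn summary counts every variant exactly once", {
  asg <- classify_trunk_branch_private(four_lesion_calls())
  venn <- venn_summary(asg)
  expect_identical(sum(venn$n_variants),
                   nrow(asg$variants) + nrow(asg$germline))
  expect_identical(venn$n_variants[venn$subset == "TN1,TN2,TN3,TN4"], 2L)
  expect_identical(venn$n_variants[venn$subset == "TN3,TN4"], 1L)
  expect_identical(venn$n_variants[venn$subset == "TN1"], 1L)
  expect_identical(venn$n_lesions[venn$subset == "TN3,TN4"], 2L)
})

test_that("the VAF trend shows branch variants rising from TN2 to TN3", {
  preset <- preset_patient_05(test_ref())
  asg <- classify_trunk_branch_private(truth_to_calls(preset$truth))
  res <- build_clonal_tree(asg)
  trend <- vaf_trend(asg, res)
  branch_edge <- res$tree$placement$edge_child[
    res$tree$placement$label == "A215G"]
  b <- trend[trend$edge_child == branch_edge, ]
  expect_equal(b$mean_vaf[b$lesion == "TN2"], 0.30)
  expect_equal(b$mean_vaf[b$lesion == "TN3"], 0.45)
  expect_identical(unique(b$n_variants), 3L)
})
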