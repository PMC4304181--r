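test_that("pairwise_identity matches hand counts", {
  self <- pairwise_identity(strrep("A", 10), strrep("A", 10))
  expect_equal(self$identity, 1.0)
  expect_equal(self$coverage, 1.0)

  one_off <- pairwise_identity("AAAAAAAAAA", "AAAAAAAAAC")
  expect_equal(one_off$identity, 0.9)
  expect_equal(one_off$coverage, 1.0)

  prefix <- pairwise_identity("ACDEFGHIKL", "ACDEFGHI")
  expect_equal(prefix$coverage, 0.8)
  expect_equal(prefix$identity, 0.8)  # 8 matches / 10

  # gaps stripped before comparison
  gapped <- pairwise_identity("AC-DE", "ACDE-")
  expect_equal(gapped$identity, 1.0)

  expect_error(pairwise_identity("-----", "ACDEF"), "empty")
})

test_that("cluster_redundant collapses duplicates and keeps the reference", {
  aln <- alignment_from_strings(
    c(a = "ACDEFGHIKL", b = "ACDEFGHIKL", c = "WWWWWWWWWW"), "a")
  cl <- cluster_redundant(aln)
  expect_length(cl$representatives, 2L)
  expect_true("a" %in% cl$representatives)  # reference represents its cluster
  expect_true("c" %in% cl$representatives)

  # reference kept as representative even when not longest
  aln2 <- alignment_from_strings(
    c(long = "ACDEFGHIKLMN", ref = "ACDEFGHIKLM-"), "ref")
  cl2 <- cluster_redundant(aln2, identity_threshold = 0.8,
                           coverage_threshold = 0.8)
  expect_identical(cl2$representatives, "ref")
})

test_that("cluster_redundant agrees with the transitive-closure oracle", {
  set.seed(11)
  base <- sample(ORACLE_AA, 40, replace = TRUE)
  mk <- function(n_mut) {
    s <- base
    pos <- sample(40, n_mut)
    s[pos] <- sample(ORACLE_AA, n_mut, replace = TRUE)
    paste0(s, collapse = "")
  }
  seqs <- c(
    vapply(c(0, 1, 2, 3, 8, 9, 10), function(k) mk(k), character(1)),
    vapply(1:5, function(i) paste0(sample(ORACLE_AA, 40, replace = TRUE),
                                   collapse = ""), character(1))
  )
  names(seqs) <- sprintf("q%02d", seq_along(seqs))
  aln <- alignment_from_strings(seqs, NULL)
  for (thr in c(0.85, 1.0)) {
    got <- cluster_redundant(aln, identity_threshold = thr,
                             coverage_threshold = 1.0)
    want <- oracle_closure_clusters(as.list(seqs), thr, 1.0)
    expect_identical(canonical_partition(got$clusters),
                     canonical_partition(want),
                     info = paste("threshold", thr))
  }
})

test_that("identity threshold 1.0 collapses only exact duplicates", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 12L
    seqs <- replicate(n, paste0(sample(ORACLE_AA[1:4], 12, replace = TRUE),
                                collapse = ""))
    seqs[4] <- seqs[1]   # planted exact duplicate
    names(seqs) <- sprintf("r%02d", seq_len(n))
    aln <- alignment_from_strings(seqs, NULL)
    cl <- cluster_redundant(aln, identity_threshold = 1.0,
                            coverage_threshold = 1.0)
    for (cluster in cl$clusters) {
      expect_length(unique(unname(seqs[cluster])), 1L)
    }
  }
})

test_that("filter_gap_heavy removes gap-rich rows, protects the reference", {
  aln <- alignment_from_strings(
    c(ref = "ACDEFGHIKL", ok = "ACDEFGHIK-", bad = "ACD-----KL"), "ref")
  out <- filter_gap_heavy(aln, max_gap_fraction = 0.25)
  expect_identical(alignment_ids(out$alignment), c("ref", "ok"))
  expect_identical(out$removed$id, "bad")

  # idempotence
  again <- filter_gap_heavy(out$alignment, max_gap_fraction = 0.25)
  expect_identical(again$alignment$seqs, out$alignment$seqs)
  expect_equal(nrow(again$removed), 0L)

  # gap-free input is a no-op
  clean <- alignment_from_strings(c(a = "ACDEF", b = "GHIKL"), "a")
  expect_identical(filter_gap_heavy(clean)$alignment$seqs, clean$seqs)

  # reference immune, with warning
  refgap <- alignment_from_strings(c(ref = "AC--------", b = "ACDEFGHIKL"),
                                   "ref")
  expect_warning(out2 <- filter_gap_heavy(refgap, 0.25), "retained")
  expect_true("ref" %in% alignment_ids(out2$alignment))
})

test_that("trim_to_reference crops to the reference span", {
  aln <- alignment_from_strings(c(ref = "--ACD-", s = "GGGGGG"), "ref")
  out <- trim_to_reference(aln)
  expect_equal(out$kept_columns, 3:5)
  expect_equal(n_columns(out$alignment), 3L)
  expect_equal(paste0(reference_row(out$alignment), collapse = ""), "ACD")

  # no-op when reference spans everything
  full <- alignment_from_strings(c(ref = "ACDEF", s = "GHIKL"), "ref")
  expect_identical(trim_to_reference(full)$alignment$seqs, full$seqs)

  allgap <- alignment_from_strings(c(ref = "------", s = "ACDEFG"), "ref")
  expect_error(trim_to_reference(allgap), "entirely gaps")
})

test_that("drop_gapped_columns applies both rules and maps columns", {
  # per-column gap fractions: 0, 0.5, 0, 0, 1.0, 0
  aln <- alignment_from_strings(
    c(ref = "A-CD-E", s2 = "AACD-E", s3 = "A-CD-E", s4 = "AACD-E"), "ref")
  out <- drop_gapped_columns(aln, max_col_gap_fraction = 0.2,
                             require_reference_residue = FALSE)
  expect_equal(out$kept_columns, c(1L, 3L, 4L, 6L))

  # reference-gap columns dropped when required
  out2 <- drop_gapped_columns(aln, max_col_gap_fraction = 0.6,
                              require_reference_residue = TRUE)
  expect_false(2L %in% out2$kept_columns)

  too_strict <- alignment_from_strings(c(ref = "-A", s = "A-"), "ref")
  expect_error(drop_gapped_columns(too_strict, max_col_gap_fraction = 0),
               "no alignment columns")
})

test_that("kept_columns is strictly increasing and bijective; curation only removes", {
  set.seed(31)
  for (rep in 1:5) {
    mat <- random_alignment_matrix(15, 30, seed = 100 + rep, gap_prob = 0.25)
    mat[1, ] <- sample(ORACLE_AA, 30, replace = TRUE)  # gap-free reference
    aln <- as_test_alignment(mat, "s001")
    out <- drop_gapped_columns(aln, max_col_gap_fraction = 0.3)
    expect_true(all(diff(out$kept_columns) > 0))
    expect_equal(length(out$kept_columns), n_columns(out$alignment))
    expect_identical(out$alignment$seqs,
                     aln$seqs[, out$kept_columns, drop = FALSE])
  }
})

test_that("curate_alignment composes the stages with non-increasing counts", {
  set.seed(41)
  mat <- random_alignment_matrix(20, 40, seed = 77, gap_prob = 0.1)
  mat[1, ] <- sample(ORACLE_AA, 40, replace = TRUE)
  mat[5, ] <- mat[2, ]  # duplicate to exercise clustering
  aln <- as_test_alignment(mat, "s001")
  cur <- curate_alignment(aln)
  r <- cur$report
  expect_true(r$n_input >= r$n_after_clustering)
  expect_true(r$n_after_clustering >= r$n_after_gap_filter)
  expect_true(r$n_after_gap_filter >= r$n_after_trim)
  expect_equal(length(cur$kept_columns), n_columns(cur$alignment))
  # column map points back into the original alignment
  ref_out <- reference_row(cur$alignment)
  ref_in <- reference_row(aln)
  expect_identical(unname(ref_out), unname(ref_in[cur$kept_columns]))
})

test_that("filter_low_quality_ids drops flagged headers, never the reference", {
  aln <- alignment_from_strings(
    c("ref" = "ACDEF", "sp|LOW QUALITY x" = "ACDEG",
      "tr|partial seq" = "ACDEH", "good" = "ACDEI"), "ref")
  out <- filter_low_quality_ids(aln)
  expect_identical(alignment_ids(out$alignment), c("ref", "good"))
})
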