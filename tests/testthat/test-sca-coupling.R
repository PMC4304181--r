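test_that("coupling matrix equals the straight-loop oracle on small inputs", {
  q <- background_frequencies()
  for (seed in 1:5) {
    mat <- random_alignment_matrix(M = 12, L = 5, seed = seed,
                                   alphabet = ORACLE_AA[1:8])
    aln <- as_test_alignment(mat)
    fm <- compute_frequencies(aln, q, lambda = 0.03)
    cm <- coupling_matrix(fm)
    want <- oracle_model(mat, q, 0.03)
    expect_equal(cm$Ctilde, want$Ctilde, tolerance = 1e-10)
    expect_equal(unname(fm$f1), want$f1, tolerance = 1e-12)
  }
})

test_that("perfectly covarying binary columns match the tensor oracle", {
  mat <- rbind(c("A", "A"), c("A", "A"), c("C", "C"), c("C", "C"))
  rownames(mat) <- paste0("s", 1:4)
  q <- background_frequencies()
  fm <- compute_frequencies(as_test_alignment(mat), q, lambda = 0.03)
  cm <- coupling_matrix(fm)
  want <- oracle_model(mat, q, 0.03)
  expect_equal(cm$Ctilde, want$Ctilde, tolerance = 1e-10)
  # strong coupling: off-diagonal comparable to diagonal
  expect_gt(cm$Ctilde[1, 2], 0.5 * min(diag(cm$Ctilde)))
})

test_that("Ctilde is symmetric and nonnegative on random gapped alignments", {
  for (seed in 6:8) {
    mat <- random_alignment_matrix(M = 18, L = 6, seed = seed,
                                   gap_prob = 0.15)
    mat[1, ] <- "A"  # keep every column populated
    aln <- as_test_alignment(mat)
    cm <- coupling_matrix(compute_frequencies(aln, pairwise = FALSE))
    expect_equal(cm$Ctilde, t(cm$Ctilde), tolerance = 1e-12)
    expect_true(all(cm$Ctilde >= 0))
  }
})

test_that("spectral_significance contracts: shapes, ordering, seed handling", {
  mat <- random_alignment_matrix(M = 40, L = 8, seed = 3)
  cm <- coupling_matrix(compute_frequencies(as_test_alignment(mat),
                                            pairwise = FALSE))
  expect_error(spectral_significance(cm, n_rand = 20), "seed")
  cm <- spectral_significance(cm, n_rand = 12, seed = 99)
  expect_equal(dim(cm$random_spectra), c(12L, 8L))
  expect_true(all(diff(cm$eigenvalues) <= 1e-12))
  expect_true(all(apply(cm$random_spectra, 1, function(r)
    all(diff(r) <= 1e-12))))
  expect_true(cm$k_star >= 0 && cm$k_star <= 8)

  # deterministic given the seed
  cm2 <- coupling_matrix(compute_frequencies(as_test_alignment(mat),
                                             pairwise = FALSE))
  cm2 <- spectral_significance(cm2, n_rand = 12, seed = 99)
  expect_identical(cm$random_spectra, cm2$random_spectra)
})

test_that("the within-column shuffle preserves per-column counts exactly", {
  codes <- sectorscan:::alignment_codes(
    as_test_alignment(random_alignment_matrix(25, 10, seed = 4,
                                              gap_prob = 0.2)))
  set.seed(1)
  for (t in 1:5) {
    sh <- sectorscan:::.shuffle_within_columns(codes)
    for (i in seq_len(ncol(codes))) {
      expect_identical(tabulate(sh[, i] + 1L, 21L),
                       tabulate(codes[, i] + 1L, 21L))
    }
  }
})

test_that("a planted sector yields a significant eigenvalue", {
  spec <- planted_sector_spec(
    L = 30, M = 200,
    sectors = list(list(columns = 3 * (1:8), rho = 0.9,
                        residues = c("W", "H"))))
  sim <- generate_planted_alignment(spec, seed = 5)
  cm <- coupling_matrix(compute_frequencies(sim$alignment,
                                            pairwise = FALSE))
  cm <- spectral_significance(cm, n_rand = 20, seed = 6)
  expect_gte(cm$k_star, 1L)
})

test_that("independent_components: single-component case and contracts", {
  mat <- random_alignment_matrix(M = 30, L = 6, seed = 21)
  cm <- coupling_matrix(compute_frequencies(as_test_alignment(mat),
                                            pairwise = FALSE))
  cm <- spectral_significance(cm, n_rand = 0)
  expect_error(independent_components(cm, seed = 1), "k_star = 0")

  cm$k_star <- 1L
  cm <- independent_components(cm, seed = 1)
  v <- cm$eigenvectors[, 1]
  # equals the eigenvector up to sign, oriented positive at its largest entry
  expect_equal(abs(cm$ic_loadings[, 1]), abs(v), tolerance = 1e-12)
  expect_gt(cm$ic_loadings[which.max(abs(cm$ic_loadings[, 1])), 1], 0)
})

test_that("ICA loadings are orthonormal and separate planted sectors", {
  spec <- planted_sector_spec(
    L = 40, M = 300,
    sectors = list(
      list(columns = 1:6, rho = 0.9, residues = c("W", "H")),
      list(columns = 21:26, rho = 0.9, residues = c("C", "M"))))
  sim <- generate_planted_alignment(spec, seed = 8)
  cm <- coupling_matrix(compute_frequencies(sim$alignment,
                                            pairwise = FALSE))
  cm <- spectral_significance(cm, n_rand = 20, seed = 9)
  expect_gte(cm$k_star, 2L)
  cm <- independent_components(cm, seed = 10)
  S <- cm$ic_loadings
  expect_equal(crossprod(S), diag(ncol(S)), tolerance = 1e-6,
               ignore_attr = TRUE)
  # each planted sector loads dominantly on a distinct component
  dom1 <- which.max(colSums(abs(S[1:6, , drop = FALSE])))
  dom2 <- which.max(colSums(abs(S[21:26, , drop = FALSE])))
  expect_false(dom1 == dom2)
})

test_that("define_sectors: empty case, disjointness, cutoff invariant", {
  mat <- random_alignment_matrix(M = 30, L = 6, seed = 33)
  cm <- coupling_matrix(compute_frequencies(as_test_alignment(mat),
                                            pairwise = FALSE))
  cm <- spectral_significance(cm, n_rand = 0)
  sa <- define_sectors(cm)
  expect_length(sa$sectors, 0L)
  expect_equal(sa$unassigned, 1:6)

  spec <- planted_sector_spec(
    L = 40, M = 300,
    sectors = list(
      list(columns = 1:6, rho = 0.9, residues = c("W", "H")),
      list(columns = 21:26, rho = 0.9, residues = c("C", "M"))))
  sim <- generate_planted_alignment(spec, seed = 12)
  res <- run_sca(sim$alignment, n_rand = 20, seed = 13)
  sa <- res$sectors
  all_members <- unlist(lapply(sa$sectors, `[[`, "columns"))
  expect_false(anyDuplicated(all_members) > 0)
  expect_setequal(c(all_members, sa$unassigned), 1:40)
  # labels follow the fixed palette order
  labels <- vapply(sa$sectors, `[[`, character(1), "label")
  expect_identical(labels,
                   sectorscan:::SECTOR_PALETTE[seq_along(labels)])
  # every member exceeded its component's cutoff
  S <- res$coupling$ic_loadings
  for (j in seq_along(sa$sectors)) {
    cols <- sa$sectors[[j]]$columns
    expect_true(all(apply(S[cols, , drop = FALSE], 1, max) >
                      min(sa$cutoffs)))
  }
})

test_that("sequence_correlation is a unit-diagonal symmetric similarity", {
  mat <- random_alignment_matrix(6, 12, seed = 2, gap_prob = 0.1)
  S <- sequence_correlation(as_test_alignment(mat))
  expect_equal(diag(S), rep(1, 6), ignore_attr = TRUE)
  expect_equal(S, t(S))
  expect_true(all(S >= 0 & S <= 1))
})
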