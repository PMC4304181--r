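test_that("generators are deterministic given the seed", {
  a1 <- generate_null_alignment(10, 8, seed = 5)
  a2 <- generate_null_alignment(10, 8, seed = 5)
  expect_identical(a1$seqs, a2$seqs)
  a3 <- generate_null_alignment(10, 8, seed = 6)
  expect_false(identical(a1$seqs, a3$seqs))

  spec <- two_sector_benchmark(M = 50L, L = 40L)
  s1 <- generate_planted_alignment(spec, seed = 5)
  s2 <- generate_planted_alignment(spec, seed = 5)
  expect_identical(s1$alignment$seqs, s2$alignment$seqs)
  expect_identical(s1$truth, s2$truth)
})

test_that("null alignment column frequencies track the background", {
  q <- background_frequencies()
  M <- 2000L
  aln <- generate_null_alignment(M, 10, seed = 77)
  counts <- apply(aln$seqs, 2, function(col)
    table(factor(col, levels = AMINO_ACIDS)))
  expected <- M * q
  se <- sqrt(M * q * (1 - q))
  within3 <- abs(counts - expected) <= 3 * se
  expect_gte(mean(within3), 0.95)
})

test_that("M = 1 degenerate null alignment works", {
  aln <- generate_null_alignment(1, 5, seed = 1)
  expect_equal(dim(aln$seqs), c(1L, 5L))
})

test_that("planted alignments honor their spec", {
  spec <- two_sector_benchmark(M = 200L, L = 60L, n_sector_cols = 5L)
  sim <- generate_planted_alignment(spec, seed = 3)
  expect_length(sim$truth, 60L)
  s1 <- spec$sectors[[1]]$columns
  s2 <- spec$sectors[[2]]$columns
  expect_true(all(sim$truth[s1] == 1L))
  expect_true(all(sim$truth[s2] == 2L))
  expect_true(all(sim$truth[-c(s1, s2)] == 0L))
  # reference row appended, gap-free
  expect_equal(n_sequences(sim$alignment), 201L)
  expect_false(any(reference_row(sim$alignment) == "-"))

  # rho = 1: sector columns perfectly correlated across sequences
  spec1 <- planted_sector_spec(
    L = 10, M = 100,
    sectors = list(list(columns = c(2L, 6L), rho = 1,
                        residues = c("W", "H"))))
  sim1 <- generate_planted_alignment(spec1, seed = 4)
  body <- sim1$alignment$seqs[1:100, ]
  expect_true(all(body[, 2] == body[, 6]))
  expect_true(all(body[, 2] %in% c("W", "H")))

  expect_error(planted_sector_spec(
    L = 10, M = 10,
    sectors = list(list(columns = 1:3, rho = 1, residues = c("A", "C")),
                   list(columns = 3:5, rho = 1, residues = c("D", "E")))),
    "overlap")
})

test_that("an empty planted spec matches the null generator in distribution", {
  q <- background_frequencies()
  spec <- planted_sector_spec(L = 6, M = 1500, sectors = list(),
                              conserved = list())
  sim <- generate_planted_alignment(spec, seed = 9)
  body <- sim$alignment$seqs[1:1500, ]
  # chi-square of column composition against q, per column
  for (i in 1:6) {
    obs <- table(factor(body[, i], levels = AMINO_ACIDS))
    p <- suppressWarnings(stats::chisq.test(obs, p = q)$p.value)
    expect_gt(p, 1e-4)
  }
})

test_that("rho = 0 planted sectors behave like the null (k_star = 0)", {
  spec <- planted_sector_spec(
    L = 30, M = 150,
    sectors = list(list(columns = 3 * (1:6), rho = 0,
                        residues = c("W", "H"))))
  zeros <- 0L
  for (s in 1:5) {
    sim <- generate_planted_alignment(spec, seed = 100 + s)
    cm <- coupling_matrix(compute_frequencies(sim$alignment,
                                              pairwise = FALSE))
    cm <- spectral_significance(cm, n_rand = 20, seed = 200 + s)
    zeros <- zeros + (cm$k_star == 0L)
  }
  expect_gte(zeros, 4L)
})

test_that("toy PDB round-trips through read_chain", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  generate_toy_pdb("ACDEFGHIKLMNPQRSTVWY", pdb, start_number = 7L,
                   chain = "C")
  ch <- read_chain(pdb, "C")
  expect_equal(chain_sequence(ch), "ACDEFGHIKLMNPQRSTVWY")
  expect_equal(ch$residues$resnum, 7:26)
  expect_error(generate_toy_pdb("ACX", withr::local_tempfile()),
               "non-standard")
})

test_that("evaluate_recovery matches hand enumeration", {
  truth <- c(rep(1L, 10), rep(0L, 10))
  perfect <- structure(list(
    sectors = list(list(label = "red", columns = 1:10,
                        loadings = rep(1, 10))),
    unassigned = 11:20, L = 20L, cutoffs = 0.1),
    class = "sector_assignment")
  ev <- evaluate_recovery(perfect, truth)
  expect_equal(ev$precision, 1.0)
  expect_equal(ev$recall, 1.0)

  # one wrong member, one missing member: 9 correct of 10 assigned,
  # 9 recovered of 10 true
  off_by_one <- structure(list(
    sectors = list(list(label = "red", columns = c(1:9, 15L),
                        loadings = rep(1, 10))),
    unassigned = setdiff(1:20, c(1:9, 15L)), L = 20L, cutoffs = 0.1),
    class = "sector_assignment")
  ev2 <- evaluate_recovery(off_by_one, truth)
  expect_equal(ev2$precision, 0.9)
  expect_equal(ev2$recall, 0.9)

  empty <- structure(list(sectors = list(), unassigned = 1:20, L = 20L,
                          cutoffs = numeric(0)),
                     class = "sector_assignment")
  ev3 <- evaluate_recovery(empty, truth)
  expect_equal(ev3$precision, 0)
  expect_equal(ev3$recall, 0)
  expect_true(ev3$empty_assignment)
})
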