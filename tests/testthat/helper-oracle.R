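# Independent straight-loop oracle for the coupling-analysis pipeline.
# Deliberately naive: nested loops over sequences, columns and amino acids,
# sharing no code with the package implementation beyond the amino-acid
# ordering constant. Used only on tiny alignments.

ORACLE_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# mat: M x L character matrix; q: background 20-vector; lambda in [0, 1)
oracle_model <- function(mat, q, lambda) {
  M <- nrow(mat); L <- ncol(mat)
  f1 <- matrix(0, L, 20)
  for (i in seq_len(L)) {
    for (s in seq_len(M)) {
      a <- match(mat[s, i], ORACLE_AA)
      if (!is.na(a)) f1[i, a] <- f1[i, a] + 1 / M
    }
  }
  f1 <- (1 - lambda) * f1 + lambda * matrix(q, L, 20, byrow = TRUE)
  f2 <- array(0, dim = c(L, L, 20, 20))
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) {
      for (a in 1:20) f2[i, i, a, a] <- f1[i, a]
      next
    }
    for (s in seq_len(M)) {
      a <- match(mat[s, i], ORACLE_AA)
      b <- match(mat[s, j], ORACLE_AA)
      if (!is.na(a) && !is.na(b)) {
        f2[i, j, a, b] <- f2[i, j, a, b] + 1 / M
      }
    }
    f2[i, j, , ] <- (1 - lambda) * f2[i, j, , ] + lambda * outer(q, q)
  }
  D_ia <- matrix(0, L, 20)
  phi <- matrix(0, L, 20)
  D_i <- numeric(L)
  for (i in seq_len(L)) for (a in 1:20) {
    f <- f1[i, a]
    D_ia[i, a] <- f * log(f / q[a]) + (1 - f) * log((1 - f) / (1 - q[a]))
    phi[i, a] <- abs(log(f * (1 - q[a]) / (q[a] * (1 - f))))
    D_i[i] <- D_i[i] + f * log(f / q[a])
  }
  Ct <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    ss <- 0
    for (a in 1:20) for (b in 1:20) {
      w <- phi[i, a] * phi[j, b] * (f2[i, j, a, b] - f1[i, a] * f1[j, b])
      ss <- ss + w * w
    }
    Ct[i, j] <- sqrt(ss)
  }
  list(f1 = f1, f2 = f2, D_ia = D_ia, D_i = D_i, phi = phi, Ctilde = Ct)
}

# random gapped/ungapped test alignment as a character matrix
random_alignment_matrix <- function(M, L, seed, alphabet = ORACLE_AA,
                                    gap_prob = 0) {
  set.seed(seed)
  mat <- matrix(sample(alphabet, M * L, replace = TRUE), M, L)
  if (gap_prob > 0) {
    mat[matrix(runif(M * L) < gap_prob, M, L)] <- "-"
  }
  rownames(mat) <- sprintf("s%03d", seq_len(M))
  mat
}

as_test_alignment <- function(mat, reference_id = NULL) {
  alignment_from_strings(apply(mat, 1, paste0, collapse = ""), reference_id)
}

# brute-force transitive closure of the pairwise-link relation; the
# clustering oracle (simple BFS over an explicit link matrix)
oracle_closure_clusters <- function(seqs, id_thr, cov_thr) {
  n <- length(seqs)
  link <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    pw <- pairwise_identity(seqs[[i]], seqs[[j]])
    link[i, j] <- pw$identity >= id_thr && pw$coverage >= cov_thr
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    frontier <- i
    comp[i] <- k
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        nb <- which(link[f, ] & is.na(comp))
        comp[nb] <- k
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
  }
  split(names(seqs), comp)
}

# canonical form of a partition (set of sorted member sets)
canonical_partition <- function(clusters) {
  unname(lapply(clusters, sort))[order(vapply(lapply(clusters, sort),
                                              `[`, character(1), 1L))]
}
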