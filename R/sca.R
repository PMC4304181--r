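# Statistical coupling analysis core.
#
# Stages: regularized amino-acid frequencies -> positional conservation
# (relative entropy against a background distribution) -> conservation
# gradient weights phi -> weighted positional covariance tensor, reduced to
# an L x L coupling matrix by the Frobenius norm of each 20 x 20 block ->
# spectral decomposition with a within-column shuffle null -> independent
# component analysis -> sector definition.

#' Amino-acid frequency model of an alignment
#'
#' Computes per-column frequencies `f1[i, a]` and (optionally) pairwise
#' frequencies `f2[i, j, a, b]`, both regularized toward the background:
#' `f <- (1 - lambda) * f_raw + lambda * q[a]` and, for column pairs,
#' `lambda * q[a] * q[b]`. Raw frequencies are counts divided by the number
#' of sequences M; gaps and non-standard residues ('X', ...) carry no
#' frequency mass, a loss compensated by the regularization. Same-column
#' pairs satisfy `f2[i, i, a, b] = f1[i, a] * (a == b)` by construction.
#'
#' @param aln A curated `sector_alignment` (no all-gap columns).
#' @param q Background amino-acid distribution (length 20, sums to 1);
#'   defaults to [background_frequencies()].
#' @param lambda Regularization weight in \[0, 1); a strictly positive value
#'   keeps all frequencies inside (0, 1), which the entropy and weighting
#'   stages require.
#' @param pairwise Materialize the dense `f2` array (L, L, 20, 20). Memory
#'   grows as (20 L)^2 doubles; disable for large L when only the coupling
#'   matrix is needed (it is computed without this array).
#' @return A `frequency_model`: list with `f1` (L x 20), `f2` (array or
#'   `NULL`), `q`, `lambda`, `M`, `L` and the integer-coded alignment.
#' @export
compute_frequencies <- function(aln, q = background_frequencies(),
                                lambda = 0.03, pairwise = TRUE) {
  q <- .assert_background(q)
  if (lambda < 0 || lambda >= 1) {
    stop("lambda must lie in [0, 1)", call. = FALSE)
  }
  codes <- alignment_codes(aln)
  M <- nrow(codes); L <- ncol(codes)
  if (any(colSums(codes > 0L) == 0L)) {
    stop("column(s) ", paste(which(colSums(codes > 0L) == 0L),
                             collapse = ", "),
         " contain no standard residues; drop them with ",
         "drop_gapped_columns() first", call. = FALSE)
  }
  B <- .indicator_matrix(codes)
  f1_flat <- (1 - lambda) * (Matrix::colSums(B) / M) + lambda * rep(q, L)
  f1 <- matrix(f1_flat, nrow = L, ncol = 20L, byrow = TRUE,
               dimnames = list(NULL, AMINO_ACIDS))
  f2 <- NULL
  if (pairwise) {
    f2_flat <- as.matrix(Matrix::crossprod(B)) / M
    f2 <- aperm(array(f2_flat, dim = c(20L, L, 20L, L)), c(2L, 4L, 1L, 3L))
    f2 <- (1 - lambda) * f2 +
      lambda * array(rep(outer(q, q), each = L * L), dim = c(L, L, 20L, 20L))
    for (i in seq_len(L)) f2[i, i, , ] <- diag(f1[i, ])
    dimnames(f2) <- list(NULL, NULL, AMINO_ACIDS, AMINO_ACIDS)
  }
  structure(
    list(f1 = f1, f2 = f2, q = q, lambda = lambda, M = M, L = L,
         codes = codes),
    class = "frequency_model"
  )
}

# M x (20 L) sparse indicator: cell (s, (i-1)*20 + a) = 1 when sequence s
# carries amino acid a at column i. Gap cells are all-zero rows of a block.
.indicator_matrix <- function(codes) {
  nz <- which(codes > 0L)
  M <- nrow(codes)
  rows <- ((nz - 1L) %% M) + 1L
  cols_aln <- ((nz - 1L) %/% M) + 1L
  Matrix::sparseMatrix(i = rows,
                       j = (cols_aln - 1L) * 20L + codes[nz],
                       x = 1,
                       dims = c(M, 20L * ncol(codes)))
}

.check_open_unit <- function(fm) {
  if (any(fm$f1 <= 0) || any(fm$f1 >= 1) || any(fm$q <= 0) ||
      any(fm$q >= 1)) {
    stop("frequencies touch 0 or 1; use a strictly positive regularization ",
         "lambda and a strictly positive background q", call. = FALSE)
  }
}

#' Positional conservation profile
#'
#' Per-position, per-amino-acid conservation as the binary relative entropy
#' `D[i, a] = f ln(f / q) + (1 - f) ln((1 - f) / (1 - q))` (nats), plus the
#' per-position summary `D[i] = sum_a f[i, a] ln(f[i, a] / q[a])`, the full
#' Kullback-Leibler divergence of the column composition from background.
#'
#' @param fm A `frequency_model` with all frequencies strictly inside (0, 1).
#' @return List with `D_ia` (L x 20 matrix, nats) and `D_i` (length-L
#'   vector, nats).
#' @export
positional_conservation <- function(fm) {
  .check_open_unit(fm)
  f <- fm$f1
  qm <- matrix(fm$q, nrow = fm$L, ncol = 20L, byrow = TRUE)
  D_ia <- f * log(f / qm) + (1 - f) * log((1 - f) / (1 - qm))
  D_i <- rowSums(f * log(f / qm))
  list(D_ia = D_ia, D_i = D_i)
}

#' Conservation gradient weights
#'
#' The weight applied to each (position, amino acid) covariance axis:
#' `phi[i, a] = | ln( f (1 - q) / (q (1 - f)) ) |`, the magnitude of the
#' derivative of the binary relative entropy with respect to frequency.
#' Positions near background composition receive weight ~0; conserved
#' positions are strongly amplified.
#'
#' @param fm A `frequency_model` with all frequencies strictly inside (0, 1).
#' @return L x 20 matrix of nonnegative weights.
#' @export
weighting_phi <- function(fm) {
  .check_open_unit(fm)
  qm <- matrix(fm$q, nrow = fm$L, ncol = 20L, byrow = TRUE)
  abs(log(fm$f1 * (1 - qm) / (qm * (1 - fm$f1))))
}

#' Positional coupling matrix
#'
#' Forms the weighted covariance tensor
#' `Ct[i, j, a, b] = phi[i, a] phi[j, b] (f2[i, j, a, b] - f1[i, a] f1[j, b])`
#' and reduces each 20 x 20 amino-acid block to a scalar by its Frobenius
#' norm, yielding the symmetric, nonnegative L x L coupling matrix analyzed
#' spectrally downstream. The computation never materializes the dense
#' tensor (sparse pair counts plus rank-two corrections), so it scales to
#' the repeated evaluations needed by the randomization null.
#'
#' @param fm A `frequency_model`.
#' @return A `coupling_matrix`: list with `Ctilde` (L x L), the model
#'   parameters, and slots filled by [spectral_significance()] and
#'   [independent_components()].
#' @export
coupling_matrix <- function(fm) {
  .check_open_unit(fm)
  Ctilde <- .ctilde_from_codes(fm$codes, fm$q, fm$lambda)
  structure(
    list(Ctilde = Ctilde, L = fm$L, M = fm$M, q = fm$q, lambda = fm$lambda,
         codes = fm$codes,
         eigenvalues = NULL, eigenvectors = NULL, random_spectra = NULL,
         k_star = NULL, significance_threshold = NULL, ic_loadings = NULL),
    class = "coupling_matrix"
  )
}

# Fast Frobenius-reduced coupling matrix straight from integer codes.
# Off-diagonal blocks of the weighted covariance decompose as
# W = (1-l) D_phi (B'B/M) D_phi + u u' - g g' with u = sqrt(l) phi q and
# g = phi f1. Block sums of W^2 then split into (a) a sparse pair-count
# part aggregated from the triplets of crossprod(B), (b) rank-two outer
# products of per-column sums, and (c) cross terms that collapse to dense
# M x L crossprods. Same-column blocks use f2[i,i,a,b] = f1[i,a] delta(a,b)
# and are computed directly. This keeps a single evaluation at the
# benchmark scale (M = 500, L = 100) in the 0.2 s range, which the
# randomization null relies on.
.ctilde_from_codes <- function(codes, q, lambda) {
  M <- nrow(codes); L <- ncol(codes)
  B <- .indicator_matrix(codes)
  qrep <- rep(q, L)
  f1 <- (1 - lambda) * (Matrix::colSums(B) / M) + lambda * qrep
  phi <- abs(log(f1 * (1 - qrep) / (qrep * (1 - f1))))
  u <- sqrt(lambda) * phi * qrep
  g <- phi * f1

  # (a) sparse part: sum_ab A^2 per column block, A = (1-l) phi phi n / M
  Tt <- methods::as(Matrix::crossprod(B), "TsparseMatrix")  # one triangle
  xi <- Tt@i + 1L; xj <- Tt@j + 1L
  val <- (1 - lambda) * (Tt@x / M) * phi[xi] * phi[xj]
  bi <- (xi - 1L) %/% 20L + 1L
  bj <- (xj - 1L) %/% 20L + 1L
  w <- val^2
  dbl <- bi == bj & xi != xj          # within-block off-diagonal cells
  w[dbl] <- 2 * w[dbl]                # appear on both sides of the triangle
  A1 <- as.matrix(Matrix::sparseMatrix(i = bi, j = bj, x = w,
                                       dims = c(L, L)))
  SA <- A1 + t(A1) - diag(diag(A1), L)

  # (c) cross terms: sum_ab A u u' = (1-l)/M crossprod(Pu), where
  # Pu[s, i] = (phi u) at the residue sequence s carries in column i
  phiu <- phi * u; phig <- phi * g
  nz <- which(codes > 0L)
  cols_nz <- (nz - 1L) %/% M + 1L
  flat_nz <- (cols_nz - 1L) * 20L + codes[nz]
  Pu <- matrix(0, M, L); Pg <- matrix(0, M, L)
  Pu[nz] <- phiu[flat_nz]
  Pg[nz] <- phig[flat_nz]
  UAU <- (1 - lambda) / M * crossprod(Pu)
  GAG <- (1 - lambda) / M * crossprod(Pg)

  # (b) rank-two parts: per-column sums (flat index is a-major per column)
  su2 <- colSums(matrix(u^2, nrow = 20L))
  sg2 <- colSums(matrix(g^2, nrow = 20L))
  sug <- colSums(matrix(u * g, nrow = 20L))

  Csq <- SA +
    outer(su2, su2) + outer(sg2, sg2) - 2 * outer(sug, sug) +
    2 * (UAU - GAG)

  # same-column blocks computed exactly
  for (i in seq_len(L)) {
    ix <- ((i - 1L) * 20L + 1L):(i * 20L)
    fi <- f1[ix]; pi_ <- phi[ix]
    W <- outer(pi_, pi_) * (diag(fi) - outer(fi, fi))
    Csq[i, i] <- sum(W^2)
  }
  Csq <- (Csq + t(Csq)) / 2
  sqrt(pmax(Csq, 0))
}

#' Sequence correlation matrix
#'
#' The M x M matrix of pairwise sequence similarities (fraction of
#' alignment columns with identical symbols, gaps included). Exported for
#' diagnostics of family structure; sector definition uses only the
#' positional coupling matrix.
#'
#' @param aln A `sector_alignment`.
#' @return M x M symmetric similarity matrix with unit diagonal.
#' @export
sequence_correlation <- function(aln) {
  syms <- sort(unique(as.vector(aln$seqs)))
  M <- nrow(aln$seqs); L <- ncol(aln$seqs)
  S <- matrix(0, M, M)
  for (s in syms) {
    ind <- (aln$seqs == s) * 1
    S <- S + tcrossprod(ind)
  }
  S <- S / L
  dimnames(S) <- list(alignment_ids(aln), alignment_ids(aln))
  S
}

#' Eigenvalue significance by alignment randomization
#'
#' Eigendecomposes the coupling matrix and builds a null spectrum by
#' repeatedly shuffling residues independently within every alignment
#' column (which preserves each column's composition, hence conservation,
#' while destroying all inter-column correlation), recomputing the full
#' coupling matrix each time. An eigenvalue is significant when it exceeds
#' the `percentile` quantile of the null top-eigenvalue distribution;
#' `k_star` counts the significant eigenvalues.
#'
#' Because the null preserves per-column composition, the conservation
#' contribution to the leading eigenvalue is present in the null tops as
#' well, so a leading eigenvalue that merely reflects conservation is not
#' counted as significant by this comparison (see the methods vignette for
#' the relation to treatments that discard the leading mode outright).
#'
#' @param cm A `coupling_matrix` from [coupling_matrix()].
#' @param n_rand Number of randomization trials (>= 10 recommended).
#' @param percentile Quantile of the null top-eigenvalue distribution used
#'   as the significance threshold.
#' @param seed Integer seed; required whenever `n_rand > 0` so the null is
#'   reproducible.
#' @return The `coupling_matrix` with `eigenvalues` (descending),
#'   `eigenvectors`, `random_spectra` (n_rand x L, each row a descending
#'   null spectrum), `significance_threshold` and `k_star` filled in.
#' @export
spectral_significance <- function(cm, n_rand = 100L, percentile = 0.95,
                                  seed = NULL) {
  stopifnot(inherits(cm, "coupling_matrix"))
  if (n_rand > 0L && is.null(seed)) {
    stop("a seed is required when n_rand > 0 (reproducibility contract)",
         call. = FALSE)
  }
  if (n_rand > 0L && n_rand < 10L) {
    warning("n_rand < 10 gives a very coarse null quantile", call. = FALSE)
  }
  eig <- eigen(cm$Ctilde, symmetric = TRUE)
  cm$eigenvalues <- eig$values
  cm$eigenvectors <- eig$vectors
  if (n_rand > 0L) {
    set.seed(seed)
    L <- cm$L
    spectra <- matrix(NA_real_, nrow = n_rand, ncol = L)
    for (t in seq_len(n_rand)) {
      shuffled <- .shuffle_within_columns(cm$codes)
      Cnull <- .ctilde_from_codes(shuffled, cm$q, cm$lambda)
      spectra[t, ] <- eigen(Cnull, symmetric = TRUE, only.values = TRUE)$values
    }
    cm$random_spectra <- spectra
    cm$significance_threshold <-
      unname(stats::quantile(spectra[, 1L], percentile))
    cm$k_star <- sum(cm$eigenvalues > cm$significance_threshold)
  } else {
    cm$random_spectra <- matrix(NA_real_, 0L, cm$L)
    cm$significance_threshold <- NA_real_
    cm$k_star <- 0L
  }
  cm
}

# Permute residues independently within every column: per-column
# composition (hence conservation) is preserved exactly, inter-column
# correlation is destroyed. The null model of spectral_significance().
.shuffle_within_columns <- function(codes) {
  apply(codes, 2L, function(col) col[sample.int(length(col))])
}

#' Independent components of the significant subspace
#'
#' Rotates the top `k_star` eigenvectors toward maximal statistical
#' independence with symmetric fixed-point ICA (tanh contrast). Degenerate
#' or near-degenerate sector eigenvalues mix sectors across eigenvectors;
#' the ICA rotation recovers axes on which each sector loads alone. Each
#' component is oriented so its largest-magnitude loading is positive, and
#' components are ordered by the eigenvector they are most associated with.
#'
#' @param cm A `coupling_matrix` with `k_star >= 1` (run
#'   [spectral_significance()] first).
#' @param seed Integer seed for the random initial rotation.
#' @param max_iter Fixed-point iteration cap; on non-convergence the
#'   unrotated eigenvectors are returned with a warning.
#' @param tol Convergence tolerance on the rotation update.
#' @return The `coupling_matrix` with `ic_loadings` (L x k_star, orthonormal
#'   columns) filled in.
#' @export
independent_components <- function(cm, seed = NULL, max_iter = 1000L,
                                   tol = 1e-8) {
  stopifnot(inherits(cm, "coupling_matrix"))
  if (is.null(cm$k_star)) {
    stop("run spectral_significance() before independent_components()",
         call. = FALSE)
  }
  k <- cm$k_star
  if (k < 1L) {
    stop("no significant eigenvalues (k_star = 0); there is no subspace ",
         "to rotate", call. = FALSE)
  }
  V <- cm$eigenvectors[, seq_len(k), drop = FALSE]
  if (k == 1L) {
    cm$ic_loadings <- .orient_positive(V)
    return(cm)
  }
  L <- nrow(V)
  Z <- V * sqrt(L)  # orthonormal columns -> unit-covariance "signals"
  if (is.null(seed)) {
    stop("a seed is required for the ICA initialization", call. = FALSE)
  }
  set.seed(seed)
  W <- .sym_decorrelate(matrix(stats::rnorm(k * k), k, k))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Y <- Z %*% t(W)                 # L x k projections
    GY <- tanh(Y)
    W1 <- crossprod(GY, Z) / L - diag(colMeans(1 - GY^2), k) %*% W
    W1 <- .sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("ICA did not converge within ", max_iter,
            " iterations; falling back to unrotated eigenvectors",
            call. = FALSE)
    cm$ic_loadings <- .orient_positive(V)
    return(cm)
  }
  S <- V %*% t(W)                   # orthonormal columns (W orthogonal)
  # order components by the eigenvector each is most associated with
  assoc <- abs(crossprod(S, V))     # k x k
  ord <- integer(k)
  taken <- rep(FALSE, k)
  for (j in seq_len(k)) {           # greedy match, eigen order
    cand <- which(!taken)
    ord[j] <- cand[which.max(assoc[cand, j])]
    taken[ord[j]] <- TRUE
  }
  cm$ic_loadings <- .orient_positive(S[, ord, drop = FALSE])
  cm
}

.orient_positive <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

.sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)),
                     length(e$values)) %*% t(e$vectors) %*% W
}

# Student-t location-scale maximum-likelihood fit; models a component's
# loading distribution so the cutoff quantile tracks the heavy-tailed bulk
# rather than the empirical order statistics (which would cap sector sizes
# at (1 - quantile) * L).
.fit_t_location_scale <- function(x) {
  m0 <- stats::median(x)
  s0 <- stats::mad(x)
  if (!is.finite(s0) || s0 <= 0) s0 <- stats::sd(x)
  if (!is.finite(s0) || s0 <= 0) s0 <- 1e-6
  nll <- function(p) {
    m <- p[1]; s <- exp(p[2]); df <- exp(p[3])
    -sum(stats::dt((x - m) / s, df = df, log = TRUE) - log(s))
  }
  fit <- tryCatch(
    stats::optim(c(m0, log(s0), log(5)), nll, method = "Nelder-Mead",
                 control = list(maxit = 2000)),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(fit$value)) {
    return(list(m = m0, s = s0, df = Inf))
  }
  list(m = fit$par[1], s = exp(fit$par[2]), df = exp(fit$par[3]))
}

# Among candidate loadings, find the largest multiplicative break (ratio
# between consecutive sorted values). Highly conserved but uncoupled
# positions acquire small spurious loadings through conservation-amplified
# covariance noise; they sit well below genuine sector members, separated
# by a wide gap. When the largest break exceeds `ratio`, only candidates
# above it are kept; with no clear break (graded loadings) all candidates
# are retained.
.refine_by_break <- function(vals, ratio = 2) {
  n <- length(vals)
  if (n < 2L) return(rep(TRUE, n))
  o <- order(vals)
  v <- pmax(vals[o], 1e-12)
  gaps <- log(v[-1L] / v[-n])
  if (max(gaps) <= log(ratio)) return(rep(TRUE, n))
  cut <- max(which(gaps == max(gaps)))
  keep <- logical(n)
  keep[o] <- seq_len(n) > cut
  keep
}

#' Define protein sectors from independent components
#'
#' For each independent component, a Student-t location-scale distribution
#' is fitted to the component's loadings; positions whose loading exceeds
#' the `cutoff_quantile` of the fitted distribution are sector candidates.
#' Candidate sets are then trimmed at the largest multiplicative break in
#' their loading values (when one exists), which separates genuine sector
#' members from conserved-but-uncoupled positions that pick up small
#' spurious loadings. Each candidate is assigned to the single component
#' (among those whose cutoff it exceeded) where its loading is maximal, so
#' sectors are disjoint. Sectors are labeled in the fixed palette order
#' red, blue, green, ... following component (eigenvalue) order.
#'
#' @param cm A `coupling_matrix` with `ic_loadings` (or `k_star = 0`).
#' @param cutoff_quantile Quantile of the fitted per-component loading
#'   distribution above which a position is a candidate.
#' @return A `sector_assignment`: list with `sectors` (each a list with
#'   `label`, `columns` — 1-based alignment columns — and `loadings`),
#'   `unassigned` columns, `L` and the per-component `cutoffs`.
#' @export
define_sectors <- function(cm, cutoff_quantile = 0.95) {
  stopifnot(inherits(cm, "coupling_matrix"))
  L <- cm$L
  if (is.null(cm$k_star) || cm$k_star < 1L || is.null(cm$ic_loadings)) {
    return(structure(list(sectors = list(), unassigned = seq_len(L), L = L,
                          cutoffs = numeric(0)),
                     class = "sector_assignment"))
  }
  S <- cm$ic_loadings
  k <- ncol(S)
  cutoffs <- numeric(k)
  exceed <- matrix(FALSE, L, k)
  for (j in seq_len(k)) {
    fit <- .fit_t_location_scale(S[, j])
    cutoffs[j] <- if (is.finite(fit$df)) {
      fit$m + fit$s * stats::qt(cutoff_quantile, df = fit$df)
    } else {
      fit$m + fit$s * stats::qnorm(cutoff_quantile)
    }
    exceed[, j] <- S[, j] > cutoffs[j]
    cand <- which(exceed[, j])
    if (length(cand)) {
      exceed[cand, j] <- .refine_by_break(S[cand, j])
    }
  }
  assign_to <- rep(NA_integer_, L)
  for (i in seq_len(L)) {
    js <- which(exceed[i, ])
    if (length(js)) assign_to[i] <- js[which.max(S[i, js])]
  }
  sectors <- list()
  for (j in seq_len(k)) {
    members <- which(assign_to == j)
    if (length(members) == 0L) next
    sectors[[length(sectors) + 1L]] <- list(
      label = SECTOR_PALETTE[length(sectors) + 1L],
      columns = members,
      loadings = S[members, j]
    )
  }
  structure(
    list(sectors = sectors, unassigned = which(is.na(assign_to)), L = L,
         cutoffs = cutoffs),
    class = "sector_assignment"
  )
}

#' @export
print.sector_assignment <- function(x, ...) {
  cat("Sector assignment over", x$L, "alignment columns\n")
  if (length(x$sectors) == 0L) {
    cat("  no sectors (no significant eigenvalues)\n")
  }
  for (s in x$sectors) {
    cat("  ", s$label, ": ", length(s$columns), " positions (",
        paste(utils::head(s$columns, 10L), collapse = ", "),
        if (length(s$columns) > 10L) ", ..." else "", ")\n", sep = "")
  }
  cat("  unassigned:", length(x$unassigned), "positions\n")
  invisible(x)
}

#' Per-column sector labels
#'
#' @param sa A `sector_assignment`.
#' @return Character vector of length L: sector label or `"-"`.
#' @export
sector_labels <- function(sa) {
  lab <- rep("-", sa$L)
  for (s in sa$sectors) lab[s$columns] <- s$label
  lab
}

#' Write sector assignment as TSV
#'
#' Columns: alignment column, reference position (if a structure map is
#' given, the mapped author residue number too), sector label, loading.
#'
#' @param sa A `sector_assignment`.
#' @param path Output TSV path.
#' @param smap Optional `structure_map` adding residue numbers.
#' @return `path`, invisibly.
#' @export
write_sectors <- function(sa, path, smap = NULL) {
  lab <- sector_labels(sa)
  loading <- rep(NA_real_, sa$L)
  for (s in sa$sectors) loading[s$columns] <- s$loadings
  df <- data.frame(column = seq_len(sa$L), sector = lab, loading = loading)
  if (!is.null(smap)) {
    idx <- match(df$column, smap$entries$column)
    df$ref_pos <- smap$entries$ref_pos[idx]
    df$resnum <- smap$entries$resnum[idx]
    df <- df[, c("column", "ref_pos", "resnum", "sector", "loading")]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sector assignment from TSV
#'
#' Inverse of [write_sectors()]: rebuilds a `sector_assignment` from its
#' TSV form (columns `column`, `sector`, `loading`, extra columns
#' ignored). Sector order follows the fixed palette.
#'
#' @param path TSV path.
#' @return A `sector_assignment`.
#' @export
read_sectors <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("column", "sector") %in% names(df)))
  if (is.null(df$loading)) df$loading <- NA_real_
  labels <- unique(df$sector[df$sector != "-"])
  labels <- labels[order(match(labels, SECTOR_PALETTE))]
  sectors <- lapply(labels, function(lab) {
    rows <- df[df$sector == lab, , drop = FALSE]
    list(label = lab, columns = as.integer(rows$column),
         loadings = as.numeric(rows$loading))
  })
  structure(
    list(sectors = sectors,
         unassigned = as.integer(df$column[df$sector == "-"]),
         L = max(as.integer(df$column)),
         cutoffs = rep(NA_real_, length(sectors))),
    class = "sector_assignment"
  )
}

#' Run the full coupling analysis
#'
#' Convenience wrapper: frequencies -> coupling matrix -> randomization
#' significance -> independent components -> sectors.
#'
#' @inheritParams compute_frequencies
#' @inheritParams spectral_significance
#' @inheritParams define_sectors
#' @param seed Single integer seed driving both the randomization null and
#'   the ICA initialization (split internally).
#' @return List with `frequencies`, `coupling` (the completed
#'   `coupling_matrix`) and `sectors` (a `sector_assignment`).
#' @export
run_sca <- function(aln, q = background_frequencies(), lambda = 0.03,
                    n_rand = 100L, percentile = 0.95,
                    cutoff_quantile = 0.95, seed = NULL) {
  if (is.null(seed)) stop("a seed is required", call. = FALSE)
  fm <- compute_frequencies(aln, q = q, lambda = lambda, pairwise = FALSE)
  cm <- coupling_matrix(fm)
  # derive independent sub-seeds for the two stochastic stages
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2L)
  cm <- spectral_significance(cm, n_rand = n_rand, percentile = percentile,
                              seed = seeds[1L])
  sectors <- if (cm$k_star >= 1L) {
    cm <- independent_components(cm, seed = seeds[2L])
    define_sectors(cm, cutoff_quantile = cutoff_quantile)
  } else {
    define_sectors(cm)
  }
  list(frequencies = fm, coupling = cm, sectors = sectors)
}
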