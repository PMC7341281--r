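# Pedigree relationship machinery: inbreeding coefficients (Meuwissen-Luo),
# the numerator relationship matrix A (tabular method), its sparse inverse
# (Henderson/Quaas rules) and the dominance relationship matrix D.

# Normalize a pedigree data frame: integer ids, unknown parents = 0,
# topological (ancestors-first) order.  Returns list(ped, order) where
# `order` maps sorted rows back to input rows.
ped_prepare <- function(pedigree) {
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(pedigree)))
    fail("pedigree needs columns 'animal', 'sire', 'dam'")
  ped <- pedigree
  if (anyDuplicated(ped$animal))
    fail("duplicated animal ids in pedigree")
  if (any(ped$animal == ped$sire & ped$sire != UNKNOWN_PARENT) ||
      any(ped$animal == ped$dam & ped$dam != UNKNOWN_PARENT))
    fail("an animal is recorded as its own parent")
  for (p in c("sire", "dam")) {
    bad <- ped[[p]] != UNKNOWN_PARENT & !(ped[[p]] %in% ped$animal)
    if (any(bad))  # parents absent from the file are treated as unknown
      ped[[p]][bad] <- UNKNOWN_PARENT
  }
  # Kahn-style topological sort; detects cycles.
  n <- nrow(ped)
  id <- ped$animal
  si <- match(ped$sire, id, nomatch = 0L)
  di <- match(ped$dam, id, nomatch = 0L)
  depth <- rep(NA_integer_, n)
  pending <- which(si == 0L & di == 0L)
  depth[pending] <- 0L
  level <- 0L
  while (anyNA(depth)) {
    todo <- which(is.na(depth))
    ready <- todo[(si[todo] == 0L | !is.na(depth[pmax(si[todo], 1L)])) &
                    (di[todo] == 0L | !is.na(depth[pmax(di[todo], 1L)]))]
    if (length(ready) == 0L)
      fail("pedigree contains a cycle (animals: %s)",
           paste(utils::head(id[todo], 5L), collapse = ", "))
    depth[ready] <- level + 1L
    level <- level + 1L
  }
  ord <- order(depth, seq_len(n))
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL
  list(ped = ped, order = ord)
}

#' Inbreeding coefficients from a pedigree
#'
#' Computes the inbreeding coefficient `F` of every animal as half the
#' additive relationship of its parents, obtained recursively.  For pedigrees
#' up to a few thousand animals the full tabular relationship matrix is used;
#' above that the Meuwissen and Luo ancestor-tracing algorithm accumulates
#' the diagonal `1 + F = sum(L_j^2 * d_j)` over each animal's ancestor set,
#' where `L_j` is the expected genome fraction contributed by ancestor `j`
#' and `d_j` its within-family (Mendelian sampling) variance.  Unknown
#' parents are treated as unrelated non-inbred founders, so incomplete
#' lineages contribute no relationship.
#'
#' @param pedigree Data frame with columns `animal`, `sire`, `dam`
#'   (0 = unknown parent).  Any row order is accepted.
#' @param method `"auto"` (default), `"tabular"` or `"meuwissen-luo"`.
#' @return Named numeric vector of inbreeding coefficients in the input row
#'   order.
#' @export
compute_inbreeding <- function(pedigree,
                               method = c("auto", "tabular", "meuwissen-luo")) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (nrow(pedigree) <= 8192L) "tabular" else "meuwissen-luo"
  if (method == "tabular") {
    f <- diag(build_A(pedigree)) - 1
    names(f) <- pedigree$animal
    return(f)
  }
  prep <- ped_prepare(pedigree)
  ped <- prep$ped
  n <- nrow(ped)
  id <- ped$animal
  si <- match(ped$sire, id, nomatch = 0L)
  di <- match(ped$dam, id, nomatch = 0L)
  f <- numeric(n)
  dvec <- numeric(n)          # within-family variances, filled progressively
  L <- numeric(n)
  anc <- vector("list", n)    # sorted ancestor index sets (self included)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    dvec[i] <- if (s > 0L && d > 0L) 0.5 - 0.25 * (f[s] + f[d])
    else if (s > 0L) 0.75 - 0.25 * f[s]
    else if (d > 0L) 0.75 - 0.25 * f[d]
    else 1
    pa <- if (s > 0L) anc[[s]] else integer(0)
    ma <- if (d > 0L) anc[[d]] else integer(0)
    anc[[i]] <- sort.int(unique(c(i, pa, ma)), decreasing = TRUE)
    if (s == 0L || d == 0L) next
    set <- anc[[i]]
    L[i] <- 1
    aii <- 0
    for (j in set) {          # descendants first: indices decrease
      lj <- L[j]
      aii <- aii + lj * lj * dvec[j]
      if (si[j] > 0L) L[si[j]] <- L[si[j]] + 0.5 * lj
      if (di[j] > 0L) L[di[j]] <- L[di[j]] + 0.5 * lj
    }
    L[set] <- 0
    f[i] <- aii - 1
  }
  out <- f[order(prep$order)]
  names(out) <- pedigree$animal
  out
}

#' Numerator relationship matrix by the tabular method
#'
#' Dense additive relationship matrix `A` with the classic recurrence
#' `a_ij = (a_{i,s(j)} + a_{i,d(j)}) / 2` and
#' `a_jj = 1 + a_{s(j),d(j)} / 2`; unknown parents contribute zero.
#'
#' @inheritParams compute_inbreeding
#' @return Dense symmetric matrix with dimnames equal to the animal ids, in
#'   the input row order.
#' @export
build_A <- function(pedigree) {
  prep <- ped_prepare(pedigree)
  ped <- prep$ped
  n <- nrow(ped)
  id <- ped$animal
  si <- match(ped$sire, id, nomatch = 0L)
  di <- match(ped$dam, id, nomatch = 0L)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    if (j > 1L) {
      prev <- seq_len(j - 1L)
      col <- numeric(j - 1L)
      if (s > 0L) col <- col + 0.5 * A[prev, s]
      if (d > 0L) col <- col + 0.5 * A[prev, d]
      A[prev, j] <- col
      A[j, prev] <- col
    }
    A[j, j] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  back <- order(prep$order)
  A <- A[back, back, drop = FALSE]
  dimnames(A) <- list(pedigree$animal, pedigree$animal)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles `A^-1` directly from the pedigree with Henderson's rules using
#' Mendelian-sampling variances `d_i` corrected for parental inbreeding
#' (`d_i = 0.5 - 0.25 (F_s + F_d)` with both parents known, `0.75 - 0.25 F_p`
#' with one, 1 with none).  Unknown-parent terms are dropped.
#'
#' @inheritParams compute_inbreeding
#' @param f Optional inbreeding coefficients in the input row order
#'   (computed internally when missing).
#' @return Sparse symmetric `dsCMatrix` in the input row order.
#' @export
build_A_inverse <- function(pedigree, f = NULL) {
  if (is.null(f)) f <- compute_inbreeding(pedigree)
  if (length(f) != nrow(pedigree))
    fail("'f' must have one entry per pedigree row")
  n <- nrow(pedigree)
  id <- pedigree$animal
  si <- match(pedigree$sire, id, nomatch = 0L)
  di <- match(pedigree$dam, id, nomatch = 0L)
  fs <- fd <- numeric(n)                     # parental F, 0 when unknown
  fs[si > 0L] <- f[si[si > 0L]]
  fd[di > 0L] <- f[di[di > 0L]]
  dv <- ifelse(si > 0L & di > 0L, 0.5 - 0.25 * (fs + fd),
               ifelse(si > 0L, 0.75 - 0.25 * fs,
                      ifelse(di > 0L, 0.75 - 0.25 * fd, 1)))
  if (any(dv <= 0)) fail("inconsistent inbreeding input: non-positive Mendelian sampling variance")
  alpha <- 1 / dv
  ii <- list(); jj <- list(); xx <- list()
  add <- function(i, j, v) {
    ii[[length(ii) + 1L]] <<- i; jj[[length(jj) + 1L]] <<- j
    xx[[length(xx) + 1L]] <<- v
  }
  idx <- seq_len(n)
  add(idx, idx, alpha)
  for (p in list(si, di)) {
    k <- p > 0L
    add(idx[k], p[k], -0.5 * alpha[k])
    add(p[k], idx[k], -0.5 * alpha[k])
    add(p[k], p[k], 0.25 * alpha[k])
  }
  both <- si > 0L & di > 0L
  add(si[both], di[both], 0.25 * alpha[both])
  add(di[both], si[both], 0.25 * alpha[both])
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n), dimnames = list(id, id))
  Matrix::forceSymmetric(M)
}

#' Dominance relationship matrix
#'
#' Classical (non-inbred theory) dominance relationships:
#' `d_ij = 0.25 * (a_{s_i s_j} a_{d_i d_j} + a_{s_i d_j} a_{d_i s_j})` for
#' animals with both parents known, `d_ii = 1`, and zero off-diagonals for
#' animals with an unknown parent.
#'
#' @inheritParams compute_inbreeding
#' @param A Optional precomputed numerator relationship matrix from
#'   [build_A()] (input row order).
#' @return Dense symmetric matrix in the input row order.
#' @export
build_D <- function(pedigree, A = NULL) {
  if (is.null(A)) A <- build_A(pedigree)
  n <- nrow(pedigree)
  id <- pedigree$animal
  si <- match(pedigree$sire, id, nomatch = 0L)
  di <- match(pedigree$dam, id, nomatch = 0L)
  D <- dominance_block(A, si, di, si, di)
  diag(D) <- 1
  dimnames(D) <- list(id, id)
  D
}

# Dominance relationships between two sets of animals given parent indices
# into A (0 = unknown -> zero row/column).
dominance_block <- function(A, si, di, sj, dj) {
  pad <- rbind(cbind(A, 0), 0)     # index n+1 = unknown parent, relationship 0
  u <- nrow(pad)
  si[si == 0L] <- u; di[di == 0L] <- u
  sj[sj == 0L] <- u; dj[dj == 0L] <- u
  0.25 * (pad[si, sj, drop = FALSE] * pad[di, dj, drop = FALSE] +
            pad[si, dj, drop = FALSE] * pad[di, sj, drop = FALSE])
}

#' Pedigree relationship structures in one call
#'
#' @inheritParams compute_inbreeding
#' @param dominance Build the dense dominance matrix `D`? Skipping it saves
#'   memory on large pedigrees when only additive structures are needed.
#' @return List of class `"kinship_matrices"`: `A` (dense), `A_inv` (sparse),
#'   `D` (dense or `NULL`), `f` (inbreeding coefficients), `animal` (ids).
#' @export
kinship <- function(pedigree, dominance = TRUE) {
  f <- compute_inbreeding(pedigree)
  A <- build_A(pedigree)
  out <- list(
    A = A,
    A_inv = build_A_inverse(pedigree, f),
    D = if (dominance) build_D(pedigree, A) else NULL,
    f = f,
    animal = pedigree$animal
  )
  class(out) <- "kinship_matrices"
  out
}

#' @method print kinship_matrices
#' @export
print.kinship_matrices <- function(x, ...) {
  cat(sprintf("Relationship matrices for %d animals\n", length(x$animal)))
  cat(sprintf("  mean F = %.4f, max F = %.4f, %d inbred animals\n",
              mean(x$f), max(x$f), sum(x$f > 0)))
  cat(sprintf("  dominance matrix: %s\n",
              if (is.null(x$D)) "not built" else "built"))
  invisible(x)
}

#' Export a symmetric matrix as coordinate triplets
#'
#' Writes non-zero entries of the upper triangle as `i, j, value` rows
#' (1-based positions in the matrix order), the interchange format used by
#' sparse mixed-model software.
#'
#' @param m Matrix (dense or sparse).
#' @param path Output file.
#' @param tol Entries with absolute value below `tol` are omitted.
#' @export
write_triplets <- function(m, path, tol = 0) {
  m <- as(as(m, "generalMatrix"), "TsparseMatrix")
  keep <- m@i <= m@j & abs(m@x) > tol
  df <- data.frame(i = m@i[keep] + 1L, j = m@j[keep] + 1L,
                   value = m@x[keep])
  df <- df[order(df$i, df$j), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
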