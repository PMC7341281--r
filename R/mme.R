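# Henderson mixed-model equations: the sparse dual route to the same BLUE /
# BLUP solutions that lfr_reml() obtains from the marginal covariance.  Kept
# as an exported building block and as an independent cross-check.

#' Build Henderson's mixed-model equations
#'
#' Assembles the symmetric coefficient matrix and right-hand side
#' \deqn{[X'X, X'Z; Z'X, Z'Z + blockdiag(lambda_i G_i^{-1})] [b; u] = [X'y; Z'y]}
#' with variance ratios `lambda_i = s2_e / s2_i` added to the corresponding
#' random-effect diagonal blocks.
#'
#' @param y Response vector.
#' @param X Fixed-effects design matrix (may have zero columns).
#' @param Z Named list of random-effect design matrices (n x q_i).
#' @param Ginv Named list of inverse covariance structures (q_i x q_i),
#'   e.g. the sparse inverse numerator relationship matrix for the additive
#'   term, identity for herd.
#' @param lambda Named vector of variance ratios, aligned with `Z`.
#' @return List of class `"lfr_mme"`: sparse coefficient matrix `C`,
#'   right-hand side `rhs`, and the block index map `blocks`.
#' @export
build_mme <- function(y, X, Z, Ginv, lambda) {
  if (is.null(X)) X <- matrix(0, length(y), 0L)
  if (!identical(names(Z), names(Ginv)) || !all(names(Z) %in% names(lambda)))
    fail("'Z', 'Ginv' and 'lambda' must be aligned by name")
  n <- length(y)
  X <- methods::as(X, "CsparseMatrix")
  Zs <- lapply(Z, methods::as, "CsparseMatrix")
  W <- Reduce(Matrix::cbind2, Zs, init = X)
  C <- Matrix::crossprod(W)
  rhs <- Matrix::crossprod(W, y)
  p <- ncol(X)
  off <- p
  blocks <- list(fixed = seq_len(p))
  for (nm in names(Zs)) {
    qi <- ncol(Zs[[nm]])
    idx <- off + seq_len(qi)
    C[idx, idx] <- C[idx, idx] + lambda[nm] * as(Ginv[[nm]], "CsparseMatrix")
    blocks[[nm]] <- idx
    off <- off + qi
  }
  out <- list(C = Matrix::forceSymmetric(C), rhs = rhs, blocks = blocks,
              n = n)
  class(out) <- "lfr_mme"
  out
}

#' Solve mixed-model equations
#'
#' Solves the system from [build_mme()] by sparse Cholesky factorization,
#' handling rank deficiency in the fixed-effects block by a zero constraint
#' on aliased equations, and verifies the solution residual.
#'
#' @param mme An `"lfr_mme"` object.
#' @param tol Residual-norm tolerance for the solution check.
#' @return Named list of solution blocks (`fixed` plus one vector per random
#'   term), with attribute `"residual_norm"`.
#' @export
solve_mme <- function(mme, tol = 1e-8) {
  stopifnot(inherits(mme, "lfr_mme"))
  C <- mme$C; rhs <- mme$rhs
  d <- Matrix::diag(C)
  aliased <- d < 1e-12 * max(d)
  if (any(aliased)) {                  # constrain empty equations to zero
    C <- C + Matrix::Diagonal(nrow(C), ifelse(aliased, 1, 0))
    rhs[aliased] <- 0
  }
  sol <- tryCatch(
    as.numeric(Matrix::solve(C, rhs)),
    error = function(e)
      fail("MME solve failed (%s); system may be singular beyond the fixed block",
           conditionMessage(e)))
  rn <- sqrt(sum(as.numeric(C %*% sol - rhs)^2)) /
    max(1, sqrt(sum(as.numeric(rhs)^2)))
  if (rn > tol)
    fail("MME solution residual norm %.2e exceeds tolerance %.0e", rn, tol)
  out <- lapply(mme$blocks, function(idx) sol[idx])
  attr(out, "residual_norm") <- rn
  out
}

#' BLUP solutions for all pedigree animals at fixed variance components
#'
#' Convenience wrapper that assembles and solves the mixed-model equations
#' for the LFR animal model at given variance components, returning breeding
#' values for every animal in the pedigree (phenotyped or not).
#'
#' @param data Phenotype data frame (one row per recorded mare).
#' @param formula Fixed-effects formula (response on the left).
#' @param pedigree Pedigree data frame or [kinship()] object.
#' @param vc Named variance components
#'   (`herd`, `additive`, `dominance`, `residual`; subsets allowed, residual
#'   required).
#' @param id,group Column names as in [lfr_reml()].
#' @return List with `fixed`, and per random term the solution vector
#'   (`additive` named by animal id).
#' @export
solve_blup <- function(data, formula, pedigree, vc,
                       id = "mare_id", group = "eu_by") {
  if (!"residual" %in% names(vc)) fail("'vc' must include a residual variance")
  kin <- if (inherits(pedigree, "kinship_matrices")) pedigree
         else kinship(pedigree, dominance = "dominance" %in% names(vc))
  ids <- kin$animal
  midx <- match(data[[id]], ids)
  if (anyNA(midx)) fail("phenotyped mares missing from pedigree")
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- model.matrix(formula, mf)
  n <- length(y)
  N <- length(ids)
  Zmap <- function(j, q) Matrix::sparseMatrix(i = seq_len(n), j = j,
                                              x = 1, dims = c(n, q))
  Z <- list(); Ginv <- list(); lambda <- c()
  if ("herd" %in% names(vc)) {
    gf <- factor(data[[group]])
    Z$herd <- Zmap(as.integer(gf), nlevels(gf))
    Ginv$herd <- Matrix::Diagonal(nlevels(gf))
    lambda["herd"] <- vc["residual"] / vc["herd"]
  }
  if ("additive" %in% names(vc)) {
    Z$additive <- Zmap(midx, N)
    Ginv$additive <- kin$A_inv
    lambda["additive"] <- vc["residual"] / vc["additive"]
  }
  if ("dominance" %in% names(vc)) {
    Z$dominance <- Zmap(midx, N)
    Ginv$dominance <- solve(kin$D)
    lambda["dominance"] <- vc["residual"] / vc["dominance"]
  }
  sol <- solve_mme(build_mme(y, X, Z, Ginv, lambda))
  if (!is.null(sol$additive)) names(sol$additive) <- ids
  if (!is.null(sol$dominance)) names(sol$dominance) <- ids
  if (!is.null(sol$herd)) names(sol$herd) <- levels(factor(data[[group]]))
  if (length(sol$fixed)) names(sol$fixed) <- colnames(X)
  sol
}
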