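# Single-trait animal model for the lifetime foaling rate:
#   y = X beta + Z_h h + Z_a a + Z_d d + e
#   Var(h) = I s2_h,  Var(a) = A s2_a,  Var(d) = D s2_d,  Var(e) = I s2_e
# fitted by REML on the marginal covariance of the (one record per mare)
# phenotype vector, with monotone EM steps accelerated by average-information
# (AI) steps that are accepted only when the restricted likelihood does not
# decrease.

#' Fit the LFR animal model by REML
#'
#' Estimates herd (environmental-unit-by-birth-year), additive, dominance and
#' residual variance components for a mare-level trait, together with
#' heritability and its delta-method standard error, AIC, generalized
#' least-squares fixed effects, and BLUP solutions (breeding values for every
#' pedigree animal, dominance and herd effects).
#'
#' @param formula Fixed-effects formula, e.g. `value ~ af_class + f_coef`
#'   (age-at-first-foaling class and the inbreeding covariate).  Use `~ 0` on
#'   the right-hand side for a model without fixed effects.
#' @param data Phenotype data frame, one row per recorded mare, containing
#'   the formula variables plus the id and group columns.
#' @param pedigree Pedigree data frame (`animal`, `sire`, `dam`, ...)
#'   covering all recorded mares, or a prebuilt [kinship()] object.
#' @param id Name of the column holding the pedigree animal id
#'   (default `"mare_id"`).
#' @param group Name of the contemporary-group column fitted as the random
#'   herd effect (default `"eu_by"`).
#' @param random Random terms to include; any subset of
#'   `c("herd", "additive", "dominance")`.  The residual is always present.
#' @param start Optional named starting values for the variance components;
#'   defaults partition the phenotypic variance.
#' @param tol Relative-change convergence tolerance (default `1e-8`).
#' @param max_iter Iteration cap (default 500); non-convergence is flagged
#'   and the last iterate returned.
#' @param floor_frac Variance floor as a fraction of the phenotypic variance
#'   (default `1e-8`).
#' @param verbose Print the iteration trace?
#' @return Object of class `"lfr_reml"`; see [summary.lfr_reml()].  Key
#'   elements: `varcomp` (estimates with sampling covariance `vcov_vc`),
#'   `h2`, `se_h2`, `logLik`, `aic`, `beta` (fixed effects), `ebv` (breeding
#'   values for all pedigree animals), `dominance`, `herd`, `converged`,
#'   `logl_path`.
#' @references Henderson's mixed-model equations; average-information REML;
#'   delta-method standard error of a variance ratio.
#' @export
lfr_reml <- function(formula, data, pedigree,
                     id = "mare_id", group = "eu_by",
                     random = c("herd", "additive", "dominance"),
                     start = NULL, tol = 1e-8, max_iter = 500L,
                     floor_frac = 1e-8, verbose = FALSE) {
  random <- match.arg(random, several.ok = TRUE)
  if (!id %in% names(data)) fail("id column '%s' not in data", id)

  if (inherits(pedigree, "kinship_matrices")) {
    kin <- pedigree
  } else {
    kin <- kinship(pedigree, dominance = "dominance" %in% random)
  }
  ids <- kin$animal
  midx <- match(data[[id]], ids)
  if (anyNA(midx))
    fail("%d phenotyped mares are missing from the pedigree", sum(is.na(midx)))

  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (is.null(y)) fail("formula must have a response")
  X <- model.matrix(formula, mf)
  if (ncol(X)) {                       # drop aliased columns
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      warning(sprintf("dropping %d aliased fixed-effect column(s)",
                      ncol(X) - qx$rank), call. = FALSE)
      X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    }
  }
  n <- length(y)

  # Marginal covariance structures K_i (n x n) and level counts q_i.
  K <- list(); q <- c()
  Zh <- NULL
  if ("herd" %in% random) {
    if (!group %in% names(data)) fail("group column '%s' not in data", group)
    gf <- factor(data[[group]])
    Zh <- model.matrix(~ gf - 1)
    K$herd <- tcrossprod(Zh)
    q["herd"] <- nlevels(gf)
  }
  if ("additive" %in% random) {
    K$additive <- kin$A[midx, midx, drop = FALSE]
    q["additive"] <- length(ids)
  }
  if ("dominance" %in% random) {
    if (is.null(kin$D)) fail("kinship object was built without the dominance matrix")
    K$dominance <- kin$D[midx, midx, drop = FALSE]
    q["dominance"] <- length(ids)
  }
  K$residual <- diag(n)
  q["residual"] <- n
  comp <- names(K)

  vy <- var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1e-6   # constant response: no signal
  theta <- if (is.null(start)) {
    w <- c(herd = 0.05, additive = 0.3, dominance = 0.1, residual = 0.55)
    setNames(vy * w[comp] / sum(w[comp]), comp)
  } else {
    if (!all(comp %in% names(start)))
      fail("'start' must name all components: %s", paste(comp, collapse = ", "))
    th <- unlist(start[comp])
    if (any(th <= 0)) fail("starting variances must be positive")
    th
  }
  floor_v <- floor_frac * vy

  eval_obj <- function(th) {
    V <- matrix(0, n, n)
    for (i in seq_along(K)) V <- V + th[i] * K[[i]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    ldetV <- 2 * sum(log(diag(ch)))
    if (ncol(X)) {
      XtVi <- crossprod(X, Vinv)
      M <- XtVi %*% X
      chM <- chol(M)
      Minv <- chol2inv(chM)
      P <- Vinv - crossprod(XtVi, Minv %*% XtVi)
      ldetM <- 2 * sum(log(diag(chM)))
      beta <- drop(Minv %*% (XtVi %*% y))
    } else {
      P <- Vinv; ldetM <- 0; beta <- numeric(0); Minv <- matrix(0, 0, 0)
    }
    Py <- drop(P %*% y)
    ll <- -0.5 * (ldetV + ldetM + sum(y * Py))
    list(theta = th, P = P, Py = Py, logl = ll, beta = beta,
         Minv = Minv, Vinv = Vinv)
  }

  state <- eval_obj(theta)
  if (is.null(state)) fail("initial variance components give a singular covariance")
  logl_path <- state$logl
  em_steps <- 0L; ai_steps <- 0L
  converged <- FALSE
  AI <- NULL

  for (iter in seq_len(max_iter)) {
    P <- state$P; Py <- state$Py
    m <- length(K)
    trPK <- numeric(m); yPKPy <- numeric(m)
    Tm <- matrix(0, n, m)                      # columns K_i %*% Py
    for (i in seq_len(m)) {
      trPK[i] <- sum(P * K[[i]])               # tr(P K_i), K_i symmetric
      Tm[, i] <- K[[i]] %*% Py
      yPKPy[i] <- sum(Py * Tm[, i])
    }
    score <- -0.5 * (trPK - yPKPy)
    U <- P %*% Tm
    AI <- 0.5 * crossprod(Tm, U)               # average information matrix

    # Candidate AI step with Levenberg-Marquardt damping (the dominance and
    # residual structures can be nearly collinear, making the AI matrix
    # ill-conditioned); falls back to the monotone EM step if no damped step
    # improves the restricted logL.  Components pinned at the floor with a
    # negative gradient stay put; the AI update acts on the active set only.
    th_em <- pmax(theta + theta^2 * (yPKPy - trPK) / q[comp], floor_v)
    cand <- NULL
    ai_ok <- FALSE
    act <- theta > 1.01 * floor_v | score > 0
    if (any(act)) {
      Aact <- AI[act, act, drop = FALSE]
      dA <- diag(Aact)
      for (lam in c(0, 0.01, 0.1, 1, 10)) {
        step <- tryCatch(
          solve(Aact + lam * diag(dA, nrow = length(dA)), score[act]),
          error = function(e) NULL)
        if (is.null(step)) next
        th_ai <- theta
        th_ai[act] <- th_ai[act] + step
        cand <- eval_obj(pmax(th_ai, floor_v))
        if (!is.null(cand) && cand$logl >= state$logl - 1e-10) {
          ai_ok <- TRUE
          break
        }
      }
    }
    if (!ai_ok) {
      cand <- eval_obj(th_em)
      if (is.null(cand)) fail("EM update produced a singular covariance")
      em_steps <- em_steps + 1L
    } else ai_steps <- ai_steps + 1L

    delta <- max(abs(cand$theta - theta)) / vy
    dlogl <- cand$logl - state$logl
    theta <- cand$theta
    state <- cand
    logl_path <- c(logl_path, state$logl)
    if (verbose)
      message(sprintf("it %3d  logL %.6f  [%s]  rel change %.2e",
                      iter, state$logl,
                      paste(signif(theta, 4), collapse = " "), delta))
    if (delta < tol || (iter > 3L && abs(dlogl) < 1e-10)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("REML did not converge in %d iterations", max_iter),
            call. = FALSE)

  names(theta) <- comp
  vp <- sum(theta)
  vcov_vc <- tryCatch(solve(AI), error = function(e) {
    matrix(NA_real_, length(comp), length(comp))
  })
  dimnames(vcov_vc) <- list(comp, comp)

  h2 <- if ("additive" %in% comp) unname(theta["additive"] / vp) else NA_real_
  se_h2 <- if ("additive" %in% comp && all(is.finite(vcov_vc)))
    se_heritability(theta["additive"], vp, vcov_vc) else NA_real_

  # BLUP solutions from the converged fit: u_hat = s2 G[, recorded] P y.
  Py <- state$Py
  ebv <- NULL; domsol <- NULL; herdsol <- NULL
  if ("additive" %in% comp) {
    ebv <- drop(theta["additive"] * (kin$A[, midx, drop = FALSE] %*% Py))
    names(ebv) <- ids
  }
  if ("dominance" %in% comp) {
    domsol <- drop(theta["dominance"] * (kin$D[, midx, drop = FALSE] %*% Py))
    names(domsol) <- ids
  }
  if ("herd" %in% comp) {
    herdsol <- drop(theta["herd"] * crossprod(Zh, Py))
    names(herdsol) <- levels(factor(data[[group]]))
  }

  beta <- state$beta
  if (length(beta)) names(beta) <- colnames(X)
  fit_fixed <- if (ncol(X)) drop(X %*% beta) else rep(0, n)
  u_rec <- rep(0, n)
  if (!is.null(ebv)) u_rec <- u_rec + ebv[midx]
  if (!is.null(domsol)) u_rec <- u_rec + domsol[midx]
  if (!is.null(herdsol)) u_rec <- u_rec + herdsol[as.character(factor(data[[group]]))]

  cl <- match.call()
  # do.call() splices evaluated data frames into the call; keep it printable
  if (utils::object.size(cl) > 1e4)
    cl <- call("lfr_reml", formula)
  out <- list(
    call = cl,
    varcomp = theta, vcov_vc = vcov_vc,
    var_phenotypic = vp,
    h2 = h2, se_h2 = se_h2,
    dominance_ratio = if ("dominance" %in% comp)
      unname(theta["dominance"] / vp) else NA_real_,
    logLik = state$logl,
    aic = -2 * state$logl + 2 * length(comp),
    logl_path = logl_path,
    converged = converged, n_iterations = length(logl_path) - 1L,
    em_steps = em_steps, ai_steps = ai_steps,
    beta = beta, vcov_beta = state$Minv,
    ebv = ebv, dominance = domsol, herd = herdsol,
    fitted = fit_fixed + unname(u_rec),
    residuals = y - fit_fixed - unname(u_rec),
    y = y, X = X, n = n,
    id = data[[id]], group = if (!is.null(Zh)) data[[group]] else NULL,
    animal = ids, f = kin$f,
    random = setdiff(comp, "residual"),
    formula = formula
  )
  class(out) <- "lfr_reml"
  if (n <= 1500L)  # kept for simulate(); omitted on large fits to save memory
    attr(out, "K_structures") <- K
  out
}

#' Heritability from variance components
#'
#' `h2 = s2_additive / s2_phenotypic`, the phenotypic variance being the sum
#' of all model components (herd + additive + dominance + residual).
#'
#' @param vc Named variance-component vector (or an `"lfr_reml"` fit).
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(vc) {
  if (inherits(vc, "lfr_reml")) return(vc$h2)
  if (!"additive" %in% names(vc)) fail("no additive component")
  vp <- sum(vc)
  if (vp <= 0) fail("phenotypic variance must be positive")
  unname(vc["additive"] / vp)
}

#' Delta-method standard error of heritability
#'
#' Standard error of the ratio `h2 = s2_a / s2_p` given the sampling
#' (co)variances of the estimated components:
#' `SE = h2 * sqrt(Var(s2_a)/s2_a^2 + Var(s2_p)/s2_p^2
#'                 - 2 Cov(s2_a, s2_p)/(s2_a s2_p))`.
#' `Var(s2_p)` and `Cov(s2_a, s2_p)` are formed by summing the component
#' covariance matrix, since the phenotypic variance is the component sum.
#'
#' @param var_a Additive variance estimate.
#' @param var_p Phenotypic variance estimate.
#' @param vcov Sampling covariance matrix of the variance components (the
#'   additive component must be named), or a 2x2 matrix of
#'   `(s2_a, s2_p)` sampling (co)variances.
#' @return Standard error of the heritability estimate.
#' @export
se_heritability <- function(var_a, var_p, vcov) {
  if (var_p <= 0) fail("phenotypic variance must be positive")
  if (var_a == 0) return(0)
  if (!is.null(dimnames(vcov)) && "additive" %in% rownames(vcov)) {
    va_var <- vcov["additive", "additive"]
    vp_var <- sum(vcov)
    cov_ap <- sum(vcov["additive", ])
  } else {
    va_var <- vcov[1, 1]; vp_var <- vcov[2, 2]; cov_ap <- vcov[1, 2]
  }
  h2 <- var_a / var_p
  inside <- va_var / var_a^2 + vp_var / var_p^2 - 2 * cov_ap / (var_a * var_p)
  unname(h2 * sqrt(max(inside, 0)))
}
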