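#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal crossprod t solve chol forceSymmetric
NULL

#' FamilyPedigree: family structure for a study cohort
#'
#' Holds individual/family membership and parentage for a set of pedigrees.
#' Individuals are stored parents-before-children; founders have no recorded
#' parents. The pedigree is the basis both for kinship computation and for
#' the family clusters used by the clustered sandwich estimator.
#'
#' @slot members data.frame with columns `id`, `famid`, `father`, `mother`
#'   (character; `NA` for founders) and `generation` (integer, founders of the
#'   oldest generation are 1).
#' @export
setClass("FamilyPedigree", representation(members = "data.frame"))

setValidity("FamilyPedigree", function(object) {
  m <- object@members
  need <- c("id", "famid", "father", "mother", "generation")
  if (!all(need %in% names(m)))
    return(paste("members must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(m$id)) return("duplicated individual ids")
  pos <- seq_len(nrow(m))
  names(pos) <- m$id
  for (col in c("father", "mother")) {
    p <- m[[col]]
    has <- !is.na(p)
    if (any(!p[has] %in% m$id)) return(sprintf("unknown %s id", col))
    if (any(pos[p[has]] >= pos[has])) return("parents must precede children")
    if (any(m$famid[pos[p[has]]] != m$famid[has]))
      return("parents must belong to the child's family")
  }
  fo <- is.na(m$father) & is.na(m$mother)
  if (any(is.na(m$father) != is.na(m$mother)))
    return("individuals must have both parents or neither")
  TRUE
})

#' KinshipModel: block-diagonal relatedness with family clusters
#'
#' Stores the kinship matrix Psi (diagonal 0.5 for non-inbred individuals),
#' its cluster map (family id -> row indices), and the individual ids. The
#' additive relationship matrix is `2 * Psi`.
#'
#' @slot kinship symmetric sparse kinship matrix Psi.
#' @slot clusters named list of integer index vectors, one per family/cluster.
#' @slot ids character vector of individual ids, matching rows of `kinship`.
#' @export
setClass("KinshipModel",
         representation(kinship = "Matrix", clusters = "list", ids = "character"))

setValidity("KinshipModel", function(object) {
  K <- object@kinship
  n <- nrow(K)
  if (ncol(K) != n) return("kinship must be square")
  if (length(object@ids) != n) return("ids length must match kinship")
  idx <- sort(unlist(object@clusters, use.names = FALSE))
  if (!identical(idx, seq_len(n))) return("clusters must partition 1..n")
  if (!Matrix::isSymmetric(K, tol = 1e-12)) return("kinship must be symmetric")
  x <- K@x
  if (length(x) && (min(x) < -1e-12 || max(x) > 0.5 + 1e-12))
    return("kinship entries must lie in [0, 0.5]")
  TRUE
})

#' NullModelFit: REML fit of the covariates-only mixed model
#'
#' Result of [fitNullModel()]. Caches everything per-variant testing needs:
#' the GLS fixed effects, variance components, per-cluster Cholesky factors of
#' the fitted covariance Sigma, the sparse Sigma^-1, scaled residuals
#' R = Sigma^-1 (y - X alpha), and the covariate projection pieces, so that
#' the projection P V can be applied to any matrix without forming P.
#'
#' @slot alpha named numeric, GLS covariate effects.
#' @slot lambda named numeric, variance components; first entry `residual`.
#' @slot y,X the data the model was fitted to.
#' @slot Vinv sparse block-diagonal inverse of the fitted Sigma.
#' @slot SiX Sigma^-1 X (N x p dense).
#' @slot XtSiXinv (X' Sigma^-1 X)^-1 (p x p).
#' @slot residuals scaled residuals R.
#' @slot clusters named list of integer index vectors (sandwich clusters).
#' @slot converged logical; `niter` iteration count; `logLik` REML criterion.
#' @export
setClass("NullModelFit",
         representation(alpha = "numeric", lambda = "numeric",
                        y = "numeric", X = "matrix",
                        Vinv = "Matrix", SiX = "matrix", XtSiXinv = "matrix",
                        residuals = "numeric", clusters = "list",
                        converged = "logical", niter = "integer",
                        logLik = "numeric"))
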