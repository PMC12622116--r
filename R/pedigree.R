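#' Build the simulation pedigree
#'
#' Constructs a cohort of `nNuclear` nuclear families (2 founder parents and
#' 2 offspring) and `nExtended` three-generation extended families. An
#' extended family has 2 founder grandparents, 3 second-generation offspring
#' each married to a founder spouse, and 3 children per second-generation
#' couple: 17 members of whom 5 are founders. The default configuration
#' (12,750 nuclear + 2,000 extended) yields 85,000 individuals, 14,750
#' families and 35,500 founders.
#'
#' @param nNuclear number of nuclear families.
#' @param nExtended number of extended families.
#' @return a [FamilyPedigree-class] object.
#' @examples
#' ped <- buildPedigree(2, 1)
#' nIndividuals(ped)  # 25
#' @export
buildPedigree <- function(nNuclear = 12750L, nExtended = 2000L) {
  nNuclear <- as.integer(nNuclear); nExtended <- as.integer(nExtended)
  if (is.na(nNuclear) || is.na(nExtended) || nNuclear < 0 || nExtended < 0)
    stop("family counts must be nonnegative integers")

  blocks <- list()
  if (nNuclear > 0) {
    famid <- rep(sprintf("N%05d", seq_len(nNuclear)), each = 4L)
    role <- rep(c("F", "M", "C1", "C2"), nNuclear)
    id <- paste0(famid, "_", role)
    fa <- ifelse(role %in% c("C1", "C2"), paste0(famid, "_F"), NA_character_)
    mo <- ifelse(role %in% c("C1", "C2"), paste0(famid, "_M"), NA_character_)
    gen <- rep(c(1L, 1L, 2L, 2L), nNuclear)
    blocks[[1L]] <- data.frame(id = id, famid = famid, father = fa,
                               mother = mo, generation = gen,
                               stringsAsFactors = FALSE)
  }
  if (nExtended > 0) {
    # per-family member layout: grandparents GF, GM; gen-2 children A1..A3;
    # their founder spouses S1..S3; grandchildren A<k>C<j>, j = 1..3
    role <- c("GF", "GM",
              paste0("A", 1:3), paste0("S", 1:3),
              as.vector(t(outer(paste0("A", 1:3), paste0("C", 1:3), paste0))))
    fa1 <- c(NA, NA, rep("GF", 3), rep(NA, 3), rep(paste0("A", 1:3), each = 3))
    mo1 <- c(NA, NA, rep("GM", 3), rep(NA, 3), rep(paste0("S", 1:3), each = 3))
    gen1 <- c(1L, 1L, rep(2L, 6L), rep(3L, 9L))
    famid <- rep(sprintf("E%05d", seq_len(nExtended)), each = 17L)
    id <- paste0(famid, "_", rep(role, nExtended))
    faR <- rep(fa1, nExtended); moR <- rep(mo1, nExtended)
    fa <- ifelse(is.na(faR), NA_character_, paste0(famid, "_", faR))
    mo <- ifelse(is.na(moR), NA_character_, paste0(famid, "_", moR))
    blocks[[2L]] <- data.frame(id = id, famid = famid, father = fa,
                               mother = mo, generation = rep(gen1, nExtended),
                               stringsAsFactors = FALSE)
  }
  members <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(id = character(), famid = character(), father = character(),
               mother = character(), generation = integer(),
               stringsAsFactors = FALSE)
  rownames(members) <- NULL
  new("FamilyPedigree", members = members)
}

#' @describeIn FamilyPedigree-class number of individuals.
#' @param object,x a `FamilyPedigree`.
#' @export
nIndividuals <- function(object) nrow(object@members)

#' @describeIn FamilyPedigree-class number of founders (no recorded parents).
#' @export
nFounders <- function(object)
  sum(is.na(object@members$father) & is.na(object@members$mother))

#' @describeIn FamilyPedigree-class number of families.
#' @export
nFamilies <- function(object) length(unique(object@members$famid))

#' @describeIn FamilyPedigree-class member table accessor.
#' @export
pedMembers <- function(object) object@members

setMethod("show", "FamilyPedigree", function(object) {
  cat(sprintf("FamilyPedigree: %d individuals in %d families (%d founders)\n",
              nIndividuals(object), nFamilies(object), nFounders(object)))
})

#' Kinship coefficients for a pedigree
#'
#' Standard recursive kinship: phi(i,i) = 0.5 + 0.5 phi(father_i, mother_i);
#' for i not j with i ordered after j, phi(i,j) = 0.5 (phi(father_i, j) +
#' phi(mother_i, j)); founders are mutually unrelated and non-inbred.
#' Computation is per family; families sharing an identical internal parent
#' structure (as all simulated families of a type do) reuse one computed
#' block.
#'
#' @param ped a [FamilyPedigree-class].
#' @return a [KinshipModel-class] with sparse block-diagonal Psi and the
#'   family cluster map.
#' @export
computeKinship <- function(ped) {
  m <- ped@members
  n <- nrow(m)
  pos <- seq_len(n); names(pos) <- m$id
  fam <- split(seq_len(n), m$famid)
  # order families by first appearance
  fam <- fam[unique(m$famid)]

  cache <- new.env(parent = emptyenv())
  ii <- jj <- xx <- vector("list", length(fam))
  for (f in seq_along(fam)) {
    idx <- fam[[f]]
    fa <- match(m$father[idx], m$id[idx])  # local indices, NA for founders
    mo <- match(m$mother[idx], m$id[idx])
    key <- paste(c(fa, mo), collapse = ",")
    blk <- cache[[key]]
    if (is.null(blk)) {
      blk <- .kinshipBlock(fa, mo)
      cache[[key]] <- blk
    }
    keep <- which(blk != 0, arr.ind = TRUE)
    ii[[f]] <- idx[keep[, 1L]]
    jj[[f]] <- idx[keep[, 2L]]
    xx[[f]] <- blk[keep]
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n), symmetric = FALSE)
  K <- Matrix::forceSymmetric(K, uplo = "U")
  new("KinshipModel", kinship = K, clusters = fam, ids = m$id)
}

# dense kinship for one family given local parent indices (parents precede
# children); errors on cyclic parentage via the ordering requirement
.kinshipBlock <- function(fa, mo) {
  s <- length(fa)
  phi <- matrix(0, s, s)
  for (i in seq_len(s)) {
    if (is.na(fa[i])) {
      phi[i, i] <- 0.5
    } else {
      if (fa[i] >= i || mo[i] >= i)
        stop("cyclic or unordered parentage within family")
      phi[i, i] <- 0.5 + 0.5 * phi[fa[i], mo[i]]
      js <- seq_len(i - 1L)
      phi[i, js] <- 0.5 * (phi[fa[i], js] + phi[mo[i], js])
      phi[js, i] <- phi[i, js]
    }
  }
  phi
}

#' @describeIn KinshipModel-class kinship matrix Psi accessor.
#' @param object a `KinshipModel`.
#' @export
kinshipMatrix <- function(object) object@kinship

#' @describeIn KinshipModel-class additive relationship matrix 2 Psi.
#' @export
relationshipMatrix <- function(object) 2 * object@kinship

#' @describeIn KinshipModel-class family cluster map (family id -> indices).
#' @export
clusterMap <- function(object) object@clusters

#' @describeIn KinshipModel-class individual ids.
#' @export
sampleIds <- function(object) object@ids

setMethod("show", "KinshipModel", function(object) {
  cat(sprintf("KinshipModel: %d individuals, %d clusters (max size %d)\n",
              length(object@ids), length(object@clusters),
              if (length(object@clusters)) max(lengths(object@clusters)) else 0L))
})
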