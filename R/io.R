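#' Write a pedigree as a PLINK .fam-compatible table
#'
#' Columns: family id, individual id, father id, mother id, sex (0 =
#' unknown), phenotype (-9 = missing); founders get parent codes `0`.
#'
#' @param ped a [FamilyPedigree-class].
#' @param path output path.
#' @export
writePedigree <- function(ped, path) {
  m <- ped@members
  fam <- data.frame(m$famid, m$id,
                    ifelse(is.na(m$father), "0", m$father),
                    ifelse(is.na(m$mother), "0", m$mother),
                    0L, -9L)
  utils::write.table(fam, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a .fam-style pedigree table
#'
#' Expects whitespace/tab-delimited columns famid, id, father, mother (plus
#' optional trailing columns, ignored). Parent code `0` or `NA` means
#' founder. Rows are reordered parents-before-children; generations are
#' assigned as 1 + the longest ancestral path.
#'
#' @param path input path.
#' @return a [FamilyPedigree-class].
#' @export
readPedigree <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("pedigree file needs >= 4 columns")
  m <- data.frame(id = as.character(tab[[2L]]), famid = as.character(tab[[1L]]),
                  father = as.character(tab[[3L]]), mother = as.character(tab[[4L]]),
                  stringsAsFactors = FALSE)
  m$father[m$father %in% c("0", "NA")] <- NA_character_
  m$mother[m$mother %in% c("0", "NA")] <- NA_character_
  # topological order + generation by longest ancestral path
  n <- nrow(m)
  pos <- seq_len(n); names(pos) <- m$id
  gen <- rep(NA_integer_, n)
  depth <- function(i) {
    if (!is.na(gen[i])) return(gen[i])
    if (is.na(m$father[i])) { gen[i] <<- 1L; return(1L) }
    fi <- pos[[m$father[i]]]; mi <- pos[[m$mother[i]]]
    g <- 1L + max(depth(fi), depth(mi))
    gen[i] <<- g
    g
  }
  for (i in seq_len(n)) depth(i)
  m$generation <- gen
  m <- m[order(match(m$famid, unique(m$famid)), m$generation), , drop = FALSE]
  rownames(m) <- NULL
  new("FamilyPedigree", members = m)
}

#' Write a kinship model as sparse GRM triplets
#'
#' Tab-separated `id1 id2 value` with `value` the kinship coefficient; only
#' nonzero entries of the upper triangle (including the diagonal) are
#' written.
#'
#' @param km a [KinshipModel-class].
#' @param path output path.
#' @export
writeKinship <- function(km, path) {
  K <- as(Matrix::triu(km@kinship), "TsparseMatrix")
  ord <- order(K@i, K@j)
  utils::write.table(
    data.frame(id1 = km@ids[K@i[ord] + 1L], id2 = km@ids[K@j[ord] + 1L],
               value = K@x[ord]),
    path, quote = FALSE, sep = "\t", row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read relatedness from GRM triplets or a pedigree file
#'
#' Triplet files (`id1 id2 value`, with or without header) become a
#' symmetric block-diagonal kinship matrix whose clusters are the connected
#' components of the nonzero pattern. Duplicated asymmetric entries that
#' disagree by more than 1e-8 raise an error. Pedigree files are routed
#' through [readPedigree()] + [computeKinship()].
#'
#' @param path input path.
#' @param format `"auto"` (default: 3 columns with numeric third = GRM),
#'   `"grm"` or `"pedigree"`.
#' @param ids optional id vector the model must cover (e.g. phenotype ids);
#'   ids missing from the file raise an error, file ids absent from `ids`
#'   are dropped.
#' @return a [KinshipModel-class].
#' @export
readRelatedness <- function(path, format = c("auto", "grm", "pedigree"),
                            ids = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- utils::read.table(path, nrows = 5, header = FALSE,
                               stringsAsFactors = FALSE)
    format <- if (ncol(first) == 3) "grm" else "pedigree"
  }
  if (format == "pedigree") {
    km <- computeKinship(readPedigree(path))
  } else {
    tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (is.character(tab[[3L]]) || is.factor(tab[[3L]]))  # header row present
      tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    id1 <- as.character(tab[[1L]]); id2 <- as.character(tab[[2L]])
    val <- as.numeric(tab[[3L]])
    uid <- unique(c(id1, id2))
    i <- match(id1, uid); j <- match(id2, uid)
    lo <- pmin(i, j); hi <- pmax(i, j)
    key <- paste(lo, hi)
    if (anyDuplicated(key)) {
      sp <- split(val, key)
      bad <- vapply(sp, function(v) diff(range(v)) > 1e-8, logical(1))
      if (any(bad)) stop("asymmetric duplicate kinship entries disagree")
      keep <- !duplicated(key)
      lo <- lo[keep]; hi <- hi[keep]; val <- vapply(sp[key[keep]], `[`, 0, 1L)
    }
    n <- length(uid)
    K <- Matrix::sparseMatrix(i = lo, j = hi, x = val, dims = c(n, n),
                              symmetric = TRUE)
    K <- as(K, "CsparseMatrix")
    comps <- .relatednessBlocks(list(K), n)
    names(comps) <- paste0("c", seq_along(comps))
    km <- new("KinshipModel", kinship = Matrix::forceSymmetric(K),
              clusters = comps, ids = uid)
  }
  if (!is.null(ids)) {
    miss <- setdiff(ids, km@ids)
    if (length(miss))
      stop("relatedness file lacks id(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    keep <- match(ids, km@ids)
    K <- km@kinship[keep, keep, drop = FALSE]
    comps <- .relatednessBlocks(list(as(K, "CsparseMatrix")), length(ids))
    names(comps) <- paste0("c", seq_along(comps))
    km <- new("KinshipModel", kinship = Matrix::forceSymmetric(K),
              clusters = comps, ids = ids)
  }
  km
}

#' Write a phenotype/exposure table
#'
#' TSV with header `id family y x1 x2` (plus any extra columns supplied).
#'
#' @param ped a [FamilyPedigree-class].
#' @param trait list from [simulateTrait()].
#' @param path output path.
#' @export
writePhenotypes <- function(ped, trait, path) {
  m <- ped@members
  tab <- data.frame(id = m$id, family = m$famid, y = trait$y,
                    x1 = trait$x1, x2 = trait$x2)
  utils::write.table(tab, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/exposure table (TSV with header)
#' @param path input path.
#' @export
readPhenotypes <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#")

## ---- PLINK1 bed/bim/fam ----------------------------------------------------

#' Write genotypes as PLINK1 bed/bim/fam
#'
#' SNP-major bed with the usual 2-bit encoding; the A1 allele is the counted
#' (minor) allele, so a genotype of 2 is homozygous A1. Variants are given
#' synthetic metadata (chromosome 1, positions 1..V, alleles A/B) unless a
#' `bim` data.frame is supplied.
#'
#' @param G individuals x variants allele-count matrix (NA = missing).
#' @param ped a [FamilyPedigree-class] matching the rows of `G`.
#' @param prefix output prefix (writes `prefix.bed/.bim/.fam`).
#' @param bim optional data.frame with columns chrom, id, cm, pos, a1, a2.
#' @export
writePlink <- function(G, ped, prefix, bim = NULL) {
  n <- nrow(G); V <- ncol(G)
  stopifnot(nIndividuals(ped) == n)
  writePedigree(ped, paste0(prefix, ".fam"))
  if (is.null(bim)) {
    ids <- colnames(G)
    if (is.null(ids)) ids <- paste0("v", seq_len(V))
    bim <- data.frame(chrom = 1L, id = ids, cm = 0, pos = seq_len(V),
                      a1 = "A", a2 = "B")
  }
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  # 2-bit codes per individual: 0 -> 11, 1 -> 10, 2 -> 00, NA -> 01
  codes <- c(`0` = 3L, `1` = 2L, `2` = 0L)
  nb <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4L * nb - n
  for (v in seq_len(V)) {
    g <- G[, v]
    cc <- ifelse(is.na(g), 1L, codes[as.character(g)])
    cc <- c(cc, rep(0L, pad))
    m4 <- matrix(cc, nrow = 4L)
    bytes <- m4[1L, ] + m4[2L, ] * 4L + m4[3L, ] * 16L + m4[4L, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read PLINK1 bed/bim/fam genotypes
#'
#' @param prefix path prefix of the `.bed/.bim/.fam` triple.
#' @return list with `genotypes` (individuals x variants A1 allele counts,
#'   NA for missing, rownames = individual ids, colnames = variant ids),
#'   `bim` and `fam` data.frames.
#' @export
readPlink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  bim <- utils::read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE)
  names(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")[seq_len(ncol(bim))]
  n <- nrow(fam); V <- nrow(bim)
  nb <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = 3 + nb * V)
  if (length(raw) < 3 || raw[1] != 0x6c || raw[2] != 0x1b)
    stop("not a PLINK1 bed file")
  if (raw[3] != 0x01) stop("only SNP-major bed files are supported")
  body <- as.integer(raw[-(1:3)])
  if (length(body) != nb * V) stop("truncated bed file")
  # decode all 2-bit fields at once; crumb k of byte b is individual 4(b-1)+k
  m <- matrix(body, nrow = nb)
  crumbs <- array(0L, c(4L, nb, V))
  crumbs[1L, , ] <- m %% 4L
  crumbs[2L, , ] <- (m %/% 4L) %% 4L
  crumbs[3L, , ] <- (m %/% 16L) %% 4L
  crumbs[4L, , ] <- m %/% 64L
  dim(crumbs) <- c(4L * nb, V)
  two <- crumbs[seq_len(n), , drop = FALSE]
  lut <- c(2L, NA_integer_, 1L, 0L)  # code 0,1,2,3 -> dosage of A1
  G <- matrix(lut[two + 1L], n, V)
  rownames(G) <- as.character(fam[[2L]])
  colnames(G) <- bim$id
  list(genotypes = G, bim = bim, fam = fam)
}

## ---- VCF -------------------------------------------------------------------

#' Write genotypes as a minimal uncompressed VCF (GT field)
#'
#' Bi-allelic sites with REF/ALT `A`/`B`; the ALT allele is the counted
#' allele. Positions are 1-based.
#'
#' @param G individuals x variants allele-count matrix.
#' @param path output `.vcf` path.
#' @param chrom,pos,ids optional variant metadata vectors.
#' @export
writeVcf <- function(G, path, chrom = NULL, pos = NULL, ids = NULL) {
  n <- nrow(G); V <- ncol(G)
  if (is.null(ids)) ids <- colnames(G)
  if (is.null(ids)) ids <- paste0("v", seq_len(V))
  if (is.null(chrom)) chrom <- rep(1L, V)
  if (is.null(pos)) pos <- seq_len(V)
  samples <- rownames(G)
  if (is.null(samples)) samples <- paste0("s", seq_len(n))
  gtmap <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(V), function(v) {
    gt <- ifelse(is.na(G[, v]), "./.", gtmap[as.character(G[, v])])
    paste(c(chrom[v], pos[v], ids[v], "A", "B", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read genotypes from VCF or PLINK1 files
#'
#' Dispatches on the path: `.vcf`/`.vcf.gz` files are parsed with `vcfR`
#' (GT hard calls, or the DS dosage field when `field = "DS"`), anything
#' else is treated as a PLINK prefix. Variant order follows the file;
#' positions stay 1-based.
#'
#' @param path VCF path or PLINK prefix.
#' @param field `"GT"` or `"DS"` for VCF input.
#' @return list with `genotypes` (individuals x variants, ALT/A1 counts)
#'   and `variants` metadata data.frame.
#' @export
readGenotypes <- function(path, field = "GT") {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    if (field == "DS") {
      M <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    } else {
      gt <- vcfR::extract.gt(v, element = "GT")
      M <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
      clean <- gsub("\\|", "/", gt)
      M[clean == "0/0"] <- 0; M[clean %in% c("0/1", "1/0")] <- 1
      M[clean == "1/1"] <- 2
    }
    G <- t(M)  # individuals x variants
    meta <- data.frame(id = rownames(M),
                       chrom = vcfR::getCHROM(v), pos = vcfR::getPOS(v),
                       ref = vcfR::getREF(v), alt = vcfR::getALT(v),
                       stringsAsFactors = FALSE)
    list(genotypes = G, variants = meta)
  } else {
    pl <- readPlink(path)
    list(genotypes = pl$genotypes,
         variants = data.frame(id = pl$bim$id, chrom = pl$bim$chrom,
                               pos = pl$bim$pos, ref = pl$bim$a2,
                               alt = pl$bim$a1, stringsAsFactors = FALSE))
  }
}

#' Align genotype rows to the phenotype sample ordering
#'
#' The phenotype table is the master ordering; genotype samples are matched
#' by id, extras dropped with a warning, and missing samples raise an error
#' naming the offenders.
#'
#' @param G genotype matrix with rownames.
#' @param ids phenotype sample ids in master order.
#' @export
alignSamples <- function(G, ids) {
  if (is.null(rownames(G))) stop("genotype matrix has no sample ids")
  miss <- setdiff(ids, rownames(G))
  if (length(miss))
    stop("genotypes missing for sample(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  extra <- setdiff(rownames(G), ids)
  if (length(extra))
    warning(length(extra), " genotyped sample(s) absent from phenotypes; dropped")
  G[match(ids, rownames(G)), , drop = FALSE]
}
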