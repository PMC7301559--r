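#' @import methods
#' @importFrom stats cor cov sd var qnorm pnorm rnorm rbinom runif lm ks.test
#' @importFrom utils read.delim write.table head
NULL

#' PredictionModel: sparse SNP-to-gene expression weight models
#'
#' Container for pre-trained linear models that map allelic dosages to
#' predicted gene expression, in the usual transcriptome-wide association
#' (PrediXcan-style) schema: one row per (gene, SNP) with an effect-size
#' weight and the allele pair the weight refers to.
#'
#' @slot entries data.frame with columns \code{gene_id}, \code{snp_id},
#'   \code{weight}, \code{ref_allele}, \code{eff_allele}; rows are grouped
#'   by gene and ordered lexicographically by SNP id within gene.
#'
#' @seealso [readPredictionModel()], [computeGeneZ()]
#' @export
setClass("PredictionModel",
  representation(entries = "data.frame"),
  validity = function(object) {
    e <- object@entries
    need <- c("gene_id", "snp_id", "weight", "ref_allele", "eff_allele")
    if (!all(need %in% names(e)))
      return(paste("entries must have columns:", paste(need, collapse = ", ")))
    if (nrow(e) > 0) {
      if (anyDuplicated(paste(e$gene_id, e$snp_id, sep = "\r")))
        return("duplicate (gene_id, snp_id) pair")
      if (any(!is.finite(e$weight)))
        return("non-finite weight")
    }
    TRUE
  }
)

#' SnpCovariance: per-gene SNP dosage covariance from an LD reference
#'
#' Stores symmetric dosage-covariance records for the SNPs of each gene's
#' prediction model, as read from a 4-column \code{GENE RSID1 RSID2 VALUE}
#' reference file. Dense per-gene blocks are assembled on demand by
#' [covarianceBlock()].
#'
#' @slot records data.frame with columns \code{gene_id}, \code{snp_id_1},
#'   \code{snp_id_2}, \code{value}; both triangle orientations are kept so
#'   lookup is orientation-free.
#'
#' @seealso [readSnpCovariance()], [covarianceBlock()]
#' @export
setClass("SnpCovariance",
  representation(records = "data.frame"),
  validity = function(object) {
    r <- object@records
    need <- c("gene_id", "snp_id_1", "snp_id_2", "value")
    if (!all(need %in% names(r)))
      return(paste("records must have columns:", paste(need, collapse = ", ")))
    if (nrow(r) > 0) {
      diag_rows <- r$snp_id_1 == r$snp_id_2
      if (any(r$value[diag_rows] < 0))
        return("negative diagonal (variance) entry")
      if (any(!is.finite(r$value)))
        return("non-finite covariance value")
    }
    TRUE
  }
)

#' EigengeneModel: gene-to-component weights of co-expression modules
#'
#' For each co-expression module, the unit-norm loading vector of the
#' module eigengene (first principal component over the standardized
#' member-gene profiles), together with the per-gene means and standard
#' deviations recorded at fit time. The eigengene activity of module l is
#' \eqn{L_l = \sum_g R_{lg} (T_g - \mu_g)/s_g} over the member genes.
#'
#' @slot modules named list; each element is the character vector of member
#'   gene ids of one module, names are module ids.
#' @slot weights named list of numeric loading vectors (unit Euclidean
#'   norm), parallel to \code{modules}.
#' @slot geneMean named numeric vector of fit-time per-gene means.
#' @slot geneSd named numeric vector of fit-time per-gene standard
#'   deviations (all > 0).
#' @slot unassigned character vector of genes left outside every module.
#'
#' @seealso [fitEigengeneWeights()], [eigengeneActivity()],
#'   [computeComponentZ()]
#' @export
setClass("EigengeneModel",
  representation(
    modules    = "list",
    weights    = "list",
    geneMean   = "numeric",
    geneSd     = "numeric",
    unassigned = "character"
  ),
  validity = function(object) {
    if (length(object@modules) != length(object@weights))
      return("modules and weights must be parallel lists")
    if (is.null(names(object@modules)) && length(object@modules) > 0)
      return("modules must be named by module id")
    for (l in seq_along(object@modules)) {
      g <- object@modules[[l]]
      w <- object@weights[[l]]
      if (length(g) != length(w))
        return(sprintf("module '%s': gene list and weight vector differ in length",
                       names(object@modules)[l]))
      nrm <- sqrt(sum(w^2))
      if (abs(nrm - 1) > 1e-10)
        return(sprintf("module '%s': weight vector is not unit-norm (||R|| = %.12g)",
                       names(object@modules)[l], nrm))
    }
    allg <- unlist(object@modules, use.names = FALSE)
    if (anyDuplicated(allg))
      return("a gene appears in more than one module")
    if (length(object@geneSd) > 0 && any(object@geneSd <= 0))
      return("geneSd entries must be positive")
    TRUE
  }
)

#' CharacteristicDirection: unit vector separating two expression classes
#'
#' @slot geneIds character vector of gene ids.
#' @slot direction numeric vector, unit Euclidean norm, parallel to
#'   \code{geneIds}.
#'
#' @seealso [characteristicDirection()], [cosineDistance()]
#' @export
setClass("CharacteristicDirection",
  representation(geneIds = "character", direction = "numeric"),
  validity = function(object) {
    if (length(object@geneIds) != length(object@direction))
      return("geneIds and direction must have equal length")
    if (length(object@direction) == 0)
      return("empty direction")
    nrm <- sqrt(sum(object@direction^2))
    if (abs(nrm - 1) > 1e-10)
      return(sprintf("direction is not unit-norm (||v|| = %.12g)", nrm))
    TRUE
  }
)

setMethod("show", "PredictionModel", function(object) {
  e <- object@entries
  cat("PredictionModel:", length(unique(e$gene_id)), "genes,",
      nrow(e), "(gene, SNP) weight entries\n")
  if (nrow(e) > 0) {
    sz <- table(e$gene_id)
    cat("  SNPs per gene: median", stats::median(sz),
        "range [", min(sz), ",", max(sz), "]\n")
  }
})

setMethod("show", "SnpCovariance", function(object) {
  r <- object@records
  cat("SnpCovariance:", length(unique(r$gene_id)), "gene blocks,",
      nrow(r), "stored records\n")
})

setMethod("show", "EigengeneModel", function(object) {
  sz <- lengths(object@modules)
  cat("EigengeneModel:", length(sz), "modules,",
      sum(sz), "assigned genes,", length(object@unassigned), "unassigned\n")
  if (length(sz) > 0)
    cat("  module sizes: median", stats::median(sz),
        "range [", min(sz), ",", max(sz), "]\n")
})

setMethod("show", "CharacteristicDirection", function(object) {
  cat("CharacteristicDirection over", length(object@geneIds), "genes;",
      "largest |loading| at", object@geneIds[which.max(abs(object@direction))],
      "\n")
})

# ---- accessors -------------------------------------------------------------

#' @describeIn PredictionModel-class data.frame of (gene, SNP, weight,
#'   alleles) entries.
#' @param object a \code{PredictionModel}.
#' @export
modelEntries <- function(object) {
  stopifnot(is(object, "PredictionModel"))
  object@entries
}

#' @describeIn PredictionModel-class character vector of gene ids with at
#'   least one model SNP.
#' @export
modelGenes <- function(object) {
  stopifnot(is(object, "PredictionModel"))
  unique(object@entries$gene_id)
}

#' Member genes of each module
#'
#' @param object an \code{EigengeneModel}.
#' @return named list of character vectors (one per module).
#' @export
moduleGenes <- function(object) {
  stopifnot(is(object, "EigengeneModel"))
  object@modules
}

#' Unit-norm eigengene loading vectors of each module
#'
#' @param object an \code{EigengeneModel}.
#' @return named list of numeric vectors (one per module).
#' @export
moduleWeights <- function(object) {
  stopifnot(is(object, "EigengeneModel"))
  object@weights
}

#' Fit-time per-gene standard deviations stored in an eigengene model
#'
#' @param object an \code{EigengeneModel}.
#' @return named numeric vector.
#' @export
geneSd <- function(object) {
  stopifnot(is(object, "EigengeneModel"))
  object@geneSd
}

#' Genes of a CharacteristicDirection
#' @param object a \code{CharacteristicDirection}.
#' @export
signatureGenes <- function(object) {
  stopifnot(is(object, "CharacteristicDirection"))
  object@geneIds
}

#' Loading vector of a CharacteristicDirection
#' @param object a \code{CharacteristicDirection}.
#' @export
signatureDirection <- function(object) {
  stopifnot(is(object, "CharacteristicDirection"))
  d <- object@direction
  names(d) <- object@geneIds
  d
}
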