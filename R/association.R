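#' Harmonize GWAS summary alleles to a prediction model
#'
#' Aligns each GWAS record with the allele coding of the prediction
#' model: if the GWAS effect allele equals the model effect allele (and
#' the other alleles match) the z-score is kept; if the pair is swapped
#' the z-score is negated; strand-ambiguous SNPs (A/T or C/G pairs) and
#' records whose alleles cannot be reconciled are dropped, with logged
#' counts. SNPs absent from the GWAS summary are simply not returned.
#'
#' @param gwas data.frame from [readGwasSummary()].
#' @param model a [PredictionModel-class].
#' @return harmonized GWAS data.frame restricted to model SNPs, with
#'   alleles re-expressed in the model's coding.
#' @export
harmonizeAlleles <- function(gwas, model) {
  .require_columns(gwas, c("snp_id", "effect_allele", "non_effect_allele",
                           "z"), "GWAS summary")
  e <- modelEntries(model)
  ms <- unique(e[, c("snp_id", "ref_allele", "eff_allele")])
  if (anyDuplicated(ms$snp_id)) {
    bad <- unique(ms$snp_id[duplicated(ms$snp_id)])
    .msg("harmonizeAlleles: dropped ", length(bad),
         " SNP(s) with conflicting allele metadata across genes")
    ms <- ms[!ms$snp_id %in% bad, , drop = FALSE]
  }
  idx <- match(ms$snp_id, gwas$snp_id)
  present <- !is.na(idx)
  ms <- ms[present, , drop = FALSE]
  g <- gwas[idx[present], , drop = FALSE]

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ambiguous <- g$non_effect_allele == comp[g$effect_allele]
  aligned <- g$effect_allele == ms$eff_allele &
    g$non_effect_allele == ms$ref_allele
  swapped <- g$effect_allele == ms$ref_allele &
    g$non_effect_allele == ms$eff_allele
  usable <- !ambiguous & (aligned | swapped)
  nDropAmb <- sum(ambiguous)
  nDropMis <- sum(!ambiguous & !aligned & !swapped)
  if (nDropAmb > 0)
    .msg("harmonizeAlleles: dropped ", nDropAmb, " strand-ambiguous SNP(s)")
  if (nDropMis > 0)
    .msg("harmonizeAlleles: dropped ", nDropMis,
         " SNP(s) with irreconcilable alleles")

  out <- data.frame(
    snp_id = ms$snp_id[usable],
    effect_allele = ms$eff_allele[usable],
    non_effect_allele = ms$ref_allele[usable],
    z = ifelse(swapped[usable], -g$z[usable], g$z[usable]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Propagate SNP z-scores to gene-level association z-scores
#'
#' Implements the summary-statistic gene association
#' \deqn{Z_g = \sum_{i \in Model_g} W_{gi} \frac{\sigma_i}{\sigma_g} Z_i}
#' with \eqn{\sigma_i = \sqrt{\Gamma_{ii}}} and
#' \eqn{\sigma_g^2 = \sum_{ij} W_{gi} \Gamma_{ij} W_{gj}} taken from the
#' LD reference covariance. Model SNPs without a covariance record or
#' without a (harmonized) GWAS z-score are excluded with a logged count;
#' genes with no usable SNP or with predicted-expression variance
#' \eqn{\sigma_g^2 \le 10^{-12}} are omitted with a logged reason.
#'
#' @param gwas harmonized GWAS data.frame (see [harmonizeAlleles()]).
#' @param model a [PredictionModel-class].
#' @param cov a [SnpCovariance-class].
#' @return data.frame with columns \code{gene_id}, \code{z},
#'   \code{sigma}, \code{n_snps_used}.
#' @export
computeGeneZ <- function(gwas, model, cov) {
  .require_columns(gwas, c("snp_id", "z"), "GWAS summary")
  e <- modelEntries(model)
  z <- stats::setNames(gwas$z, gwas$snp_id)
  covGenes <- unique(cov@records$gene_id)

  res <- list()
  nNoCov <- 0L
  nSnpExcluded <- 0L
  omitted <- character()
  for (g in unique(e$gene_id)) {
    eg <- e[e$gene_id == g, , drop = FALSE]
    if (!g %in% covGenes) {
      omitted <- c(omitted, g)
      nNoCov <- nNoCov + 1L
      next
    }
    rg <- cov@records[cov@records$gene_id == g, , drop = FALSE]
    inCov <- unique(c(rg$snp_id_1, rg$snp_id_2))
    use <- eg$snp_id %in% inCov & eg$snp_id %in% names(z)
    nSnpExcluded <- nSnpExcluded + sum(eg$snp_id %in% names(z) & !use)
    if (!any(use)) {
      omitted <- c(omitted, g)
      next
    }
    snps <- eg$snp_id[use]
    w <- eg$weight[use]
    gamma <- covarianceBlock(cov, g, snps)
    sig_i <- sqrt(pmax(diag(gamma), 0))
    sig_g2 <- as.numeric(t(w) %*% gamma %*% w)
    if (sig_g2 <= 1e-12) {
      omitted <- c(omitted, g)
      next
    }
    sig_g <- sqrt(sig_g2)
    res[[g]] <- data.frame(
      gene_id = g,
      z = sum(w * (sig_i / sig_g) * z[snps]),
      sigma = sig_g,
      n_snps_used = length(snps),
      stringsAsFactors = FALSE
    )
  }
  if (nSnpExcluded > 0)
    warning(sprintf(
      "computeGeneZ: %d model SNP(s) missing from covariance blocks were excluded",
      nSnpExcluded))
  if (length(omitted) > 0)
    .msg("computeGeneZ: omitted ", length(omitted),
         " gene(s) with no usable SNPs or degenerate variance")
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene_id = character(), z = numeric(),
                      sigma = numeric(), n_snps_used = integer())
  rownames(out) <- NULL
  out
}

#' Predicted-expression covariance between genes
#'
#' Computes \eqn{\Gamma^G[g,h] = \sum_{ij} W_{gi} \Gamma_{ij} W_{hj}},
#' the covariance of the genotype-predicted expression of two genes. By
#' default SNP-pair covariances are pooled from all per-gene reference
#' blocks; pairs that never co-occur in any block are taken as 0. A full
#' SNP covariance matrix (\code{fullCov}, dimnames = SNP ids) overrides
#' the pooled lookup.
#'
#' @param model a [PredictionModel-class].
#' @param cov a [SnpCovariance-class] (ignored when \code{fullCov} given).
#' @param genes character vector of genes (nonempty).
#' @param fullCov optional symmetric SNP x SNP covariance matrix.
#' @return symmetric numeric matrix over \code{genes} (those with model
#'   entries and covariance support).
#' @export
predictedGeneCovariance <- function(model, cov, genes, fullCov = NULL) {
  if (length(genes) == 0)
    .stop_format("predictedGeneCovariance: empty gene list")
  e <- modelEntries(model)
  e <- e[e$gene_id %in% genes, , drop = FALSE]
  genes <- intersect(genes, unique(e$gene_id))
  if (length(genes) == 0)
    .stop_format("predictedGeneCovariance: no requested gene has model entries")

  if (!is.null(fullCov)) {
    snps <- rownames(fullCov)
    e <- e[e$snp_id %in% snps, , drop = FALSE]
    W <- matrix(0, length(snps), length(genes),
                dimnames = list(snps, genes))
    W[cbind(match(e$snp_id, snps), match(e$gene_id, genes))] <- e$weight
    gg <- t(W) %*% fullCov %*% W
    return((gg + t(gg)) / 2)
  }

  # pooled unordered-pair lookup across all reference blocks
  r <- cov@records
  a <- pmin(r$snp_id_1, r$snp_id_2)
  b <- pmax(r$snp_id_1, r$snp_id_2)
  key <- paste(a, b, sep = "\r")
  lut <- stats::setNames(r$value, key)
  lut <- lut[!duplicated(key)]

  wlist <- split(e[, c("snp_id", "weight")], e$gene_id)[genes]
  n <- length(genes)
  gg <- matrix(0, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n)) {
    wi <- wlist[[i]]
    for (j in i:n) {
      wj <- wlist[[j]]
      pk <- paste(pmin(rep(wi$snp_id, each = nrow(wj)), wj$snp_id),
                  pmax(rep(wi$snp_id, each = nrow(wj)), wj$snp_id),
                  sep = "\r")
      vals <- lut[pk]
      vals[is.na(vals)] <- 0
      s <- sum(rep(wi$weight, each = nrow(wj)) * wj$weight * vals)
      gg[i, j] <- s
      gg[j, i] <- s
    }
  }
  gg
}

#' Propagate gene z-scores to eigen-gene component z-scores
#'
#' Implements the second propagation stage
#' \deqn{Z_l = \sum_{g \in Module_l} R_{lg} \frac{\sigma_g}{\sigma_l} Z_g}
#' with \eqn{\sigma_l^2 = \sum_{gh} R_{lg} \Gamma^G[g,h] R_{lh}} over the
#' module genes for which a gene association and predicted-expression
#' covariance are available. Because the fitted eigengene acts on
#' standardized gene profiles, each loading is divided by the fit-time
#' gene standard deviation stored in the model (set
#' \code{useGeneSd = FALSE} to apply the loadings to raw expression
#' scale). The z-score is invariant to positive rescaling of a module's
#' loading row.
#'
#' @param geneAssoc data.frame from [computeGeneZ()].
#' @param egModel an [EigengeneModel-class].
#' @param geneCov symmetric gene covariance matrix from
#'   [predictedGeneCovariance()].
#' @param useGeneSd divide loadings by fit-time gene SDs (default TRUE).
#' @return data.frame with columns \code{module_id}, \code{z},
#'   \code{sigma}, \code{n_genes_used}.
#' @export
computeComponentZ <- function(geneAssoc, egModel, geneCov,
                              useGeneSd = TRUE) {
  validObject(egModel)
  .require_columns(geneAssoc, c("gene_id", "z"), "gene associations")
  zg <- stats::setNames(geneAssoc$z, geneAssoc$gene_id)

  res <- list()
  omitted <- character()
  for (l in names(egModel@modules)) {
    g <- egModel@modules[[l]]
    w <- egModel@weights[[l]]
    avail <- g %in% names(zg) & g %in% rownames(geneCov)
    if (!any(avail)) {
      omitted <- c(omitted, l)
      next
    }
    ga <- g[avail]
    cw <- w[avail]
    if (useGeneSd && length(egModel@geneSd) > 0) {
      s <- egModel@geneSd[ga]
      if (anyNA(s))
        .stop_format("module '%s': missing fit-time gene SD", l)
      cw <- cw / s
    }
    gg <- geneCov[ga, ga, drop = FALSE]
    sig_l2 <- as.numeric(t(cw) %*% gg %*% cw)
    if (sig_l2 <= 1e-12) {
      omitted <- c(omitted, l)
      next
    }
    sig_g <- sqrt(pmax(diag(gg), 0))
    res[[l]] <- data.frame(
      module_id = l,
      z = sum(cw * sig_g * zg[ga]) / sqrt(sig_l2),
      sigma = sqrt(sig_l2),
      n_genes_used = length(ga),
      stringsAsFactors = FALSE
    )
  }
  if (length(omitted) > 0)
    warning(sprintf(
      "computeComponentZ: omitted module(s) with no usable genes or degenerate variance: %s",
      paste(omitted, collapse = ", ")))
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(module_id = character(), z = numeric(),
                      sigma = numeric(), n_genes_used = integer())
  rownames(out) <- NULL
  out
}

#' Holm-Sidak step-down family-wise error-rate adjustment
#'
#' Sorts the m p-values ascending, adjusts the k-th smallest to
#' \eqn{1 - (1 - p_{(k)})^{m-k+1}}, enforces monotonicity by a running
#' maximum, clips at 1 and restores the input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values in the input order.
#' @export
holmSidakAdjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    .stop_format("holmSidakAdjust: p-values must lie in (0, 1]")
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Call significant (GWAS) components
#'
#' Attaches two-sided normal p-values to component z-scores, applies the
#' Holm-Sidak correction across all components tested together (one
#' family per tissue/run), and flags components whose adjusted p-value
#' falls below \code{alpha}. Such components are the GWAS components of
#' the analysis: eigen-gene components whose propagated association
#' score deviates significantly from 0.
#'
#' @param assoc data.frame from [computeComponentZ()] (nonempty).
#' @param alpha significance level in (0, 1), default 0.05.
#' @return the input with added columns \code{p_raw}, \code{p_adjusted},
#'   \code{is_gwas_component}.
#' @export
callGwasComponents <- function(assoc, alpha = 0.05) {
  .require_columns(assoc, c("module_id", "z"), "component associations")
  if (nrow(assoc) == 0)
    .stop_format("callGwasComponents: empty component table")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    .stop_format("alpha must lie in (0, 1)")
  p <- 2 * pnorm(-abs(assoc$z))
  p <- pmax(p, .Machine$double.xmin)  # keep within (0, 1] for adjustment
  assoc$p_raw <- p
  assoc$p_adjusted <- holmSidakAdjust(p)
  assoc$is_gwas_component <- assoc$p_adjusted < alpha
  assoc
}

#' Genes belonging to significant components
#'
#' Convenience accessor: the union of member genes over all components
#' flagged by [callGwasComponents()].
#'
#' @param assoc data.frame with \code{module_id} and
#'   \code{is_gwas_component}.
#' @param egModel the [EigengeneModel-class] defining module membership.
#' @return character vector of gene ids.
#' @export
gwasComponentGenes <- function(assoc, egModel) {
  .require_columns(assoc, c("module_id", "is_gwas_component"),
                   "component associations")
  sig <- assoc$module_id[assoc$is_gwas_component]
  unique(unlist(egModel@modules[as.character(sig)], use.names = FALSE))
}
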