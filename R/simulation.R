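#' Simulate LD-structured genotype dosages
#'
#' Draws two haplotypes per individual from a latent Gaussian AR(1)
#' process across adjacent SNPs (correlation \code{ldRho}), thresholded
#' at each SNP's minor-allele frequency, so dosages are Hardy-Weinberg
#' effect-allele counts in \{0, 1, 2\} with tunable local linkage
#' disequilibrium. Deterministic per seed.
#'
#' @param nSamples number of individuals (>= 30).
#' @param nSnps number of SNPs.
#' @param mafRange length-2 numeric in (0, 0.5]; per-SNP MAFs are drawn
#'   uniformly from this range (default c(0.05, 0.5)).
#' @param ldRho AR(1) latent correlation between adjacent SNPs in
#'   [0, 1) (default 0.3).
#' @param seed integer seed.
#' @return object of class \code{GenotypeMatrix}: list with
#'   \code{dosages} (SNPs x samples matrix), \code{maf}, \code{ldRho},
#'   \code{seed}.
#' @export
simulateGenotypes <- function(nSamples, nSnps, mafRange = c(0.05, 0.5),
                              ldRho = 0.3, seed = 1) {
  if (!is.numeric(nSamples) || nSamples < 30)
    .stop_format("nSamples must be >= 30")
  if (!is.numeric(nSnps) || nSnps < 1)
    .stop_format("nSnps must be >= 1")
  if (length(mafRange) != 2 || any(mafRange <= 0) || any(mafRange > 0.5) ||
      mafRange[1] > mafRange[2])
    .stop_format("mafRange must lie within (0, 0.5]")
  if (!is.numeric(ldRho) || ldRho < 0 || ldRho >= 1)
    .stop_format("ldRho must lie in [0, 1)")
  set.seed(seed)
  maf <- runif(nSnps, mafRange[1], mafRange[2])
  thr <- qnorm(1 - maf)
  haplo <- function() {
    z <- matrix(rnorm(nSamples * nSnps), nSamples, nSnps)
    if (ldRho > 0 && nSnps > 1) {
      for (j in 2:nSnps)
        z[, j] <- ldRho * z[, j - 1] + sqrt(1 - ldRho^2) * z[, j]
    }
    t(z) > thr  # SNPs x samples logical
  }
  dos <- haplo() + haplo()
  storage.mode(dos) <- "double"
  rownames(dos) <- sprintf("rs%05d", seq_len(nSnps))
  colnames(dos) <- sprintf("ind%05d", seq_len(nSamples))
  v <- apply(dos, 1L, var)
  if (any(v == 0))
    warning(sprintf("%d monomorphic SNP(s) in the simulated panel",
                    sum(v == 0)))
  structure(list(dosages = dos, maf = maf, ldRho = ldRho, seed = seed),
            class = "GenotypeMatrix")
}

#' Build a synthetic SNP-gene-module system with planted structure
#'
#' Plants a sparse SNP-to-gene weight model on simulated genotypes:
#' genes are grouped into modules; genes of the same module share a
#' fraction of their model SNPs (with common weights) so their
#' genotype-predicted expression is correlated, while private SNPs carry
#' gene-specific weights. Eigengene loadings are then fitted from the
#' predicted expression on the planted partition, and the per-gene LD
#' reference covariance is computed empirically from the same dosages.
#'
#' @param genotypes a \code{GenotypeMatrix} from [simulateGenotypes()].
#' @param nGenes total genes (>= nModules * genesPerModule; default 60).
#' @param snpsPerGene model SNPs per gene (default 5).
#' @param nModules number of planted modules (default 12).
#' @param genesPerModule genes per module (default 5).
#' @param shareFrac fraction of each gene's SNPs drawn from the module's
#'   shared pool, in [0, 1] (default 0.8).
#' @param seed integer seed for the weight draws.
#' @return object of class \code{SyntheticSystem}: list with
#'   \code{genotypes}, \code{model} ([PredictionModel-class]),
#'   \code{expr} (predicted expression, genes x samples),
#'   \code{egModel} ([EigengeneModel-class]), \code{L} (true component
#'   activities, modules x samples), \code{cov}
#'   ([SnpCovariance-class]), \code{fullCov} (SNP x SNP empirical
#'   covariance), \code{partition} (named module assignment).
#' @export
buildSyntheticSystem <- function(genotypes, nGenes = 60, snpsPerGene = 5,
                                 nModules = 12, genesPerModule = 5,
                                 shareFrac = 0.8, seed = 1) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  if (nGenes < nModules * genesPerModule)
    .stop_format("nGenes must be >= nModules * genesPerModule")
  if (shareFrac < 0 || shareFrac > 1)
    .stop_format("shareFrac must lie in [0, 1]")
  nShared <- round(shareFrac * snpsPerGene)
  nPrivate <- snpsPerGene - nShared
  snps <- rownames(genotypes$dosages)
  perModule <- nShared + genesPerModule * nPrivate
  nExtra <- nGenes - nModules * genesPerModule
  needed <- nModules * perModule + nExtra * snpsPerGene
  if (needed > length(snps))
    .stop_format(
      "infeasible SNP sharing: need %d SNPs but panel has %d",
      needed, length(snps))

  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(nGenes))
  entries <- list()
  partition <- stats::setNames(integer(nGenes), genes)
  cursor <- 0L
  gi <- 0L
  for (m in seq_len(nModules)) {
    shared <- snps[cursor + seq_len(nShared)]
    cursor <- cursor + nShared
    wShared <- rnorm(nShared)
    for (k in seq_len(genesPerModule)) {
      gi <- gi + 1L
      g <- genes[gi]
      partition[g] <- m
      priv <- character(0)
      wPriv <- numeric(0)
      if (nPrivate > 0) {
        priv <- snps[cursor + seq_len(nPrivate)]
        cursor <- cursor + nPrivate
        wPriv <- rnorm(nPrivate)
      }
      entries[[g]] <- data.frame(
        gene_id = g, snp_id = c(shared, priv),
        weight = c(wShared, wPriv),
        ref_allele = "G", eff_allele = "A",
        stringsAsFactors = FALSE)
    }
  }
  # genes beyond the planted modules get private SNPs and stay unassigned
  while (gi < nGenes) {
    gi <- gi + 1L
    g <- genes[gi]
    priv <- snps[cursor + seq_len(snpsPerGene)]
    cursor <- cursor + snpsPerGene
    entries[[g]] <- data.frame(
      gene_id = g, snp_id = priv, weight = rnorm(snpsPerGene),
      ref_allele = "G", eff_allele = "A", stringsAsFactors = FALSE)
  }
  e <- do.call(rbind, entries)
  e <- e[order(e$gene_id, e$snp_id), , drop = FALSE]
  rownames(e) <- NULL
  model <- new("PredictionModel", entries = e)

  W <- matrix(0, length(snps), nGenes, dimnames = list(snps, genes))
  W[cbind(match(e$snp_id, snps), match(e$gene_id, genes))] <- e$weight
  expr <- t(W) %*% genotypes$dosages  # genes x samples, exactly W.X

  egModel <- fitEigengeneWeights(expr, partition)
  L <- eigengeneActivity(egModel, expr)

  fullCov <- cov(t(genotypes$dosages))
  covRecords <- do.call(rbind, lapply(genes, function(g) {
    sg <- sort(e$snp_id[e$gene_id == g])
    blk <- fullCov[sg, sg, drop = FALSE]
    idx <- which(upper.tri(blk, diag = TRUE), arr.ind = TRUE)
    data.frame(gene_id = g, snp_id_1 = sg[idx[, 1]],
               snp_id_2 = sg[idx[, 2]], value = blk[idx],
               stringsAsFactors = FALSE)
  }))
  rownames(covRecords) <- NULL
  snpCov <- new("SnpCovariance", records = covRecords)

  structure(list(genotypes = genotypes, model = model, expr = expr,
                 egModel = egModel, L = L, cov = snpCov,
                 fullCov = fullCov, partition = partition, seed = seed),
            class = "SyntheticSystem")
}

#' Simulate a quantitative trait caused by a single eigen-gene component
#'
#' \eqn{Y = L_1 + \alpha\,\epsilon} with
#' \eqn{\alpha = sd(L_1)(1 - SNR)/SNR}, so the signal-to-noise ratio
#' \eqn{SNR = sd(L_1)/(sd(L_1) + \alpha)} — heritability in a broad
#' sense — holds exactly by construction.
#'
#' @param system a \code{SyntheticSystem}.
#' @param causalModule module id of the causal component (row of
#'   \code{system$L}).
#' @param snr signal-to-noise ratio in (0, 1].
#' @param seed integer seed for the noise draws.
#' @return object of class \code{TraitSimulation}: list with \code{y},
#'   \code{causal_module_id}, \code{snr}, \code{alpha_noise},
#'   \code{epsilon}, \code{seed}.
#' @export
simulateTrait <- function(system, causalModule, snr, seed = 1) {
  stopifnot(inherits(system, "SyntheticSystem"))
  causalModule <- as.character(causalModule)
  if (!causalModule %in% rownames(system$L))
    .stop_format("causal module '%s' not found", causalModule)
  if (!is.numeric(snr) || snr <= 0 || snr > 1)
    .stop_format("snr must lie in (0, 1]; use nullTrait() for a null trait")
  L1 <- system$L[causalModule, ]
  alpha <- sd(L1) * (1 - snr) / snr
  set.seed(seed)
  eps <- rnorm(length(L1))
  structure(list(y = L1 + alpha * eps, causal_module_id = causalModule,
                 snr = snr, alpha_noise = alpha, epsilon = eps,
                 seed = seed),
            class = "TraitSimulation")
}

#' Null trait independent of genotype
#'
#' Pure standard-normal trait with no causal component; the calibration
#' counterpart of [simulateTrait()].
#'
#' @param nSamples number of individuals.
#' @param seed integer seed.
#' @return a \code{TraitSimulation} with \code{causal_module_id = NA}.
#' @export
nullTrait <- function(nSamples, seed = 1) {
  set.seed(seed)
  structure(list(y = rnorm(nSamples), causal_module_id = NA_character_,
                 snr = 0, alpha_noise = Inf, epsilon = NULL, seed = seed),
            class = "TraitSimulation")
}

#' Per-SNP GWAS of a simulated trait
#'
#' Simple linear regression of the trait on each SNP's dosage;
#' \eqn{z = \beta / se(\beta)}. Monomorphic SNPs are dropped with a
#' warning. Alleles are emitted in the same effect-allele coding as the
#' planted prediction models, so harmonization is the identity here.
#'
#' @param genotypes a \code{GenotypeMatrix}.
#' @param trait a \code{TraitSimulation} (samples aligned with the
#'   genotype columns).
#' @return GWAS summary data.frame (\code{snp_id},
#'   \code{effect_allele}, \code{non_effect_allele}, \code{z},
#'   \code{beta}, \code{se}).
#' @export
runSnpGwas <- function(genotypes, trait) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"),
            inherits(trait, "TraitSimulation"))
  x <- genotypes$dosages
  y <- trait$y
  if (length(y) != ncol(x))
    .stop_format("trait and genotypes have different sample counts")
  n <- length(y)
  xc <- x - rowMeans(x)
  yc <- y - mean(y)
  sxx <- rowSums(xc^2)
  mono <- sxx == 0
  if (any(mono)) {
    warning(sprintf("runSnpGwas: dropped %d monomorphic SNP(s)", sum(mono)))
    xc <- xc[!mono, , drop = FALSE]
    sxx <- sxx[!mono]
  }
  sxy <- as.numeric(xc %*% yc)
  syy <- sum(yc^2)
  beta <- sxy / sxx
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / ((n - 2) * sxx))
  data.frame(
    snp_id = rownames(xc),
    effect_allele = "A", non_effect_allele = "G",
    z = ifelse(se > 0, beta / se, sign(beta) * Inf),
    beta = beta, se = se,
    stringsAsFactors = FALSE
  )
}

#' Individual-level component association z-scores
#'
#' Regresses the trait on each component's true activity (the
#' individual-level benchmark of the summary-statistic propagation).
#' A perfect noiseless fit yields an infinite z, which is flagged.
#'
#' @param system a \code{SyntheticSystem}.
#' @param trait a \code{TraitSimulation}.
#' @return data.frame with \code{module_id}, \code{z}, \code{beta},
#'   \code{se}, \code{exact_fit}.
#' @export
individualComponentAssoc <- function(system, trait) {
  stopifnot(inherits(system, "SyntheticSystem"),
            inherits(trait, "TraitSimulation"))
  y <- trait$y
  n <- length(y)
  rows <- lapply(rownames(system$L), function(l) {
    x <- system$L[l, ]
    if (sd(x) == 0) return(NULL)
    xc <- x - mean(x)
    yc <- y - mean(y)
    sxx <- sum(xc^2)
    beta <- sum(xc * yc) / sxx
    rss <- max(sum(yc^2) - beta * sum(xc * yc), 0)
    se <- sqrt(rss / ((n - 2) * sxx))
    data.frame(module_id = l,
               z = if (se > 0) beta / se else sign(beta) * Inf,
               beta = beta, se = se, exact_fit = se == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary-statistic component z-scores for a synthetic system
#'
#' Convenience wrapper running the full summary path on a simulated
#' trait: per-SNP GWAS, SNP-to-gene propagation with the system's LD
#' reference, predicted-expression gene covariance (using the full
#' in-sample SNP covariance), and gene-to-component propagation.
#'
#' @param system a \code{SyntheticSystem}.
#' @param trait a \code{TraitSimulation}.
#' @return data.frame from [computeComponentZ()].
#' @export
summaryComponentAssoc <- function(system, trait) {
  gwas <- runSnpGwas(system$genotypes, trait)
  geneZ <- computeGeneZ(gwas, system$model, system$cov)
  geneCov <- predictedGeneCovariance(system$model, system$cov,
                                     geneZ$gene_id,
                                     fullCov = system$fullCov)
  computeComponentZ(geneZ, system$egModel, geneCov)
}

#' Summary-vs-individual consistency experiment
#'
#' Replicates the simulation validation of the propagation theory: for
#' each replicate a fresh genotype panel and planted system are drawn, a
#' causal component is selected at random, and traits at each requested
#' SNR are analyzed both by the summary-statistic propagation and by
#' individual-level regression on the true component activities. The
#' report records, per (SNR, replicate): the Pearson correlation and
#' fitted slope between the two sets of component z-scores, the rank of
#' the causal component by summary |z|, and a Kolmogorov-Smirnov test of
#' the non-causal summary z-scores against the standard normal.
#'
#' @param nSamples individuals per replicate (default 2000).
#' @param nSnps SNPs per replicate (default 300).
#' @param nGenes genes (default 60).
#' @param nModules planted modules (default 12).
#' @param snrList SNR settings (default c(0.10, 0.05, 0.02)).
#' @param nReplicates replicates (default 10).
#' @param seed master seed; all per-replicate seeds derive from it.
#' @param ldRho genotype LD parameter (default 0.3).
#' @return list with \code{report} (data.frame, one row per
#'   (snr, replicate)) and \code{zscores} (list of data.frames with the
#'   paired component z-scores).
#' @export
consistencyExperiment <- function(nSamples = 2000, nSnps = 300,
                                  nGenes = 60, nModules = 12,
                                  snrList = c(0.10, 0.05, 0.02),
                                  nReplicates = 10, seed = 1,
                                  ldRho = 0.3) {
  report <- list()
  zscores <- list()
  for (r in seq_len(nReplicates)) {
    sr <- (seed * 1009L + r * 101L) %% 2147483647L
    geno <- simulateGenotypes(nSamples, nSnps, ldRho = ldRho, seed = sr)
    system <- buildSyntheticSystem(geno, nGenes = nGenes,
                                   nModules = nModules, seed = sr + 1L)
    set.seed(sr + 2L)
    causal <- sample(rownames(system$L), 1L)
    for (snr in snrList) {
      trait <- simulateTrait(system, causal, snr,
                             seed = sr + 3L + round(1000 * snr))
      zsum <- summaryComponentAssoc(system, trait)
      zind <- individualComponentAssoc(system, trait)
      merged <- merge(zsum[, c("module_id", "z")],
                      zind[, c("module_id", "z")],
                      by = "module_id", suffixes = c("_summary", "_individual"))
      ok <- is.finite(merged$z_summary) & is.finite(merged$z_individual)
      m <- merged[ok, , drop = FALSE]
      fit <- lm(z_individual ~ z_summary, data = m)
      nc <- m$z_summary[m$module_id != causal]
      ks <- suppressWarnings(ks.test(nc, "pnorm"))
      key <- sprintf("snr%.2f_rep%02d", snr, r)
      zscores[[key]] <- cbind(merged, snr = snr, replicate = r,
                              causal_module = causal)
      report[[key]] <- data.frame(
        snr = snr, replicate = r, causal_module = causal,
        pearson_r = cor(m$z_summary, m$z_individual),
        slope = unname(stats::coef(fit)[2]),
        causal_rank = match(causal,
                            m$module_id[order(-abs(m$z_summary))]),
        ks_stat = unname(ks$statistic), ks_p = ks$p.value,
        n_components = nrow(m),
        stringsAsFactors = FALSE
      )
    }
  }
  list(report = do.call(rbind, c(report, make.row.names = FALSE)),
       zscores = zscores)
}

#' Null-trait calibration experiment
#'
#' Runs the summary-statistic propagation on traits drawn independently
#' of genotype and pools the resulting component z-scores across
#' replicates; under the null these should be standard normal, which is
#' checked by a Kolmogorov-Smirnov test.
#'
#' @param nSamples,nSnps,nGenes,nModules,ldRho as in
#'   [consistencyExperiment()].
#' @param nReplicates replicates to pool (default 17, so the pooled
#'   component count exceeds 200 with the default module count).
#' @param seed master seed.
#' @return list with \code{z} (pooled component z-scores),
#'   \code{ks_stat}, \code{ks_p}, \code{n_components}.
#' @export
nullCalibrationExperiment <- function(nSamples = 2000, nSnps = 300,
                                      nGenes = 60, nModules = 12,
                                      nReplicates = 17, seed = 1,
                                      ldRho = 0.3) {
  zs <- numeric()
  for (r in seq_len(nReplicates)) {
    sr <- (seed * 2003L + r * 211L) %% 2147483647L
    geno <- simulateGenotypes(nSamples, nSnps, ldRho = ldRho, seed = sr)
    system <- buildSyntheticSystem(geno, nGenes = nGenes,
                                   nModules = nModules, seed = sr + 1L)
    trait <- nullTrait(nSamples, seed = sr + 2L)
    zsum <- summaryComponentAssoc(system, trait)
    zs <- c(zs, zsum$z)
  }
  ks <- suppressWarnings(ks.test(zs, "pnorm"))
  list(z = zs, ks_stat = unname(ks$statistic), ks_p = ks$p.value,
       n_components = length(zs))
}
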