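# shared fixture builders; everything is generated in code, seeded

# expression matrix with planted correlated blocks: each block is driven by
# one latent factor, pairwise within-block correlation ~ rho, blocks mutually
# independent
plantedExpression <- function(nBlocks, genesPerBlock, nSamples, rho,
                              seed = 1, nNoise = 0) {
  set.seed(seed)
  rows <- list()
  for (b in seq_len(nBlocks)) {
    f <- rnorm(nSamples)
    for (i in seq_len(genesPerBlock)) {
      rows[[length(rows) + 1L]] <-
        sqrt(rho) * f + sqrt(1 - rho) * rnorm(nSamples)
    }
  }
  for (i in seq_len(nNoise))
    rows[[length(rows) + 1L]] <- rnorm(nSamples)
  x <- do.call(rbind, rows)
  rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%03d", seq_len(nSamples))
  x
}

plantedLabels <- function(nBlocks, genesPerBlock, nNoise = 0) {
  c(rep(seq_len(nBlocks), each = genesPerBlock), rep(0L, nNoise))
}

# EigengeneModel built by hand; weights are normalized on construction
makeEgModel <- function(modules, weights, geneSd = NULL) {
  weights <- lapply(weights, function(w) w / sqrt(sum(w^2)))
  genes <- unlist(modules, use.names = FALSE)
  if (is.null(geneSd))
    geneSd <- stats::setNames(rep(1, length(genes)), genes)
  new("EigengeneModel", modules = modules, weights = weights,
      geneMean = stats::setNames(numeric(length(genes)), genes),
      geneSd = geneSd, unassigned = character())
}

# SnpCovariance from a dense symmetric matrix for one gene
covFromMatrix <- function(geneId, m) {
  snps <- rownames(m)
  idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  new("SnpCovariance", records = data.frame(
    gene_id = geneId, snp_id_1 = snps[idx[, 1]],
    snp_id_2 = snps[idx[, 2]], value = m[idx],
    stringsAsFactors = FALSE))
}

mergeCov <- function(...) {
  new("SnpCovariance",
      records = do.call(rbind, lapply(list(...), function(x) x@records)))
}

# PredictionModel from a data.frame-like spec
makeModel <- function(gene, snp, weight, ref = "G", eff = "A") {
  e <- data.frame(gene_id = gene, snp_id = snp, weight = weight,
                  ref_allele = ref, eff_allele = eff,
                  stringsAsFactors = FALSE)
  e <- e[order(e$gene_id, e$snp_id), , drop = FALSE]
  new("PredictionModel", entries = e)
}

makeGwas <- function(snp, z, ea = "A", nea = "G") {
  data.frame(snp_id = snp, effect_allele = ea, non_effect_allele = nea,
             z = z, stringsAsFactors = FALSE)
}

writeTempTsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# independent hypergeometric upper-tail oracle using binomial coefficients
# (distinct from the factorial form used in the implementation)
enumTailOracle <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  s1 <- a + b
  s2 <- a + c_
  ks <- max(0, s1 + s2 - n):min(s1, s2)
  probs <- choose(s2, ks) * choose(n - s2, s1 - ks) / choose(n, s1)
  sum(probs[ks >= a])
}

# random unit characteristic direction on a gene universe
randomSignature <- function(genes, seed) {
  set.seed(seed)
  v <- rnorm(length(genes))
  new("CharacteristicDirection", geneIds = genes,
      direction = v / sqrt(sum(v^2)))
}
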