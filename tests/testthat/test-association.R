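test_that("allele harmonization keeps, flips and drops as specified", {
  model <- makeModel(gene = c("g1", "g1", "g1", "g1"),
                     snp = c("rs1", "rs2", "rs3", "rs4"),
                     weight = 1,
                     ref = c("G", "G", "T", "G"),
                     eff = c("A", "A", "A", "A"))
  gwas <- data.frame(
    snp_id = c("rs1", "rs2", "rs3", "rs5"),
    effect_allele = c("A", "G", "A", "A"),
    non_effect_allele = c("G", "A", "T", "G"),
    z = c(2.5, 2.5, 1.0, 3.0), stringsAsFactors = FALSE)
  h <- suppressMessages(harmonizeAlleles(gwas, model))
  expect_equal(h$snp_id, c("rs1", "rs2"))
  expect_equal(h$z, c(2.5, -2.5))       # aligned kept, swapped negated
  expect_false("rs3" %in% h$snp_id)     # A/T pair: strand-ambiguous
  expect_false("rs5" %in% h$snp_id)     # absent from the model
  # rs4 (model) absent from gwas: simply not returned
  expect_false("rs4" %in% h$snp_id)
})

test_that("irreconcilable allele pairs are dropped with a log", {
  model <- makeModel("g1", "rs1", 1, ref = "G", eff = "A")
  gwas <- makeGwas("rs1", 2, ea = "C", nea = "T")
  expect_message(h <- harmonizeAlleles(gwas, model), "irreconcilable")
  expect_equal(nrow(h), 0L)
})

test_that("gene z-score propagation matches direct arithmetic", {
  # single SNP, unit weight and variance: z passes through
  m1 <- makeModel("g1", "rs1", 1)
  cv1 <- covFromMatrix("g1", matrix(1, 1, 1, dimnames = list("rs1", "rs1")))
  r1 <- computeGeneZ(makeGwas("rs1", 2.0), m1, cv1)
  expect_equal(r1$z, 2.0)
  expect_equal(r1$sigma, 1.0)

  # two independent SNPs, equal weights: Z = (2+2)/sqrt(2)
  m2 <- makeModel(c("g1", "g1"), c("rs1", "rs2"), c(1, 1))
  cv2 <- covFromMatrix("g1", diag(2) |>
                         `dimnames<-`(list(c("rs1", "rs2"),
                                           c("rs1", "rs2"))))
  r2 <- computeGeneZ(makeGwas(c("rs1", "rs2"), c(2, 2)), m2, cv2)
  expect_equal(r2$z, 4 / sqrt(2), tolerance = 1e-12)
  expect_equal(r2$sigma, sqrt(2), tolerance = 1e-12)
  expect_equal(r2$n_snps_used, 2L)

  # all-zero SNP z-scores: linearity forces zero
  r3 <- computeGeneZ(makeGwas(c("rs1", "rs2"), c(0, 0)), m2, cv2)
  expect_equal(r3$z, 0)
})

test_that("model SNPs without covariance support are excluded", {
  m <- makeModel(c("g1", "g1"), c("rs1", "rs2"), c(1, 1))
  cv <- covFromMatrix("g1", matrix(1, 1, 1, dimnames = list("rs1", "rs1")))
  expect_warning(r <- computeGeneZ(makeGwas(c("rs1", "rs2"), c(2, 2)),
                                   m, cv),
                 "missing from covariance")
  expect_equal(r$n_snps_used, 1L)
  expect_equal(r$z, 2)

  # gene with no covariance records at all is omitted
  m2 <- makeModel(c("g1", "g2"), c("rs1", "rs9"), c(1, 1))
  r2 <- suppressWarnings(suppressMessages(
    computeGeneZ(makeGwas(c("rs1", "rs9"), c(2, 2)), m2, cv)))
  expect_equal(r2$gene_id, "g1")
})

test_that("predicted gene covariance follows W Gamma W'", {
  # disjoint SNPs, identity LD: off-diagonal is exactly zero
  m <- makeModel(c("gA", "gB"), c("rs1", "rs2"), c(1, 1))
  cvA <- covFromMatrix("gA", matrix(1, 1, 1,
                                    dimnames = list("rs1", "rs1")))
  cvB <- covFromMatrix("gB", matrix(1, 1, 1,
                                    dimnames = list("rs2", "rs2")))
  gg <- predictedGeneCovariance(m, mergeCov(cvA, cvB), c("gA", "gB"))
  expect_equal(gg, diag(2) |> `dimnames<-`(list(c("gA", "gB"),
                                                c("gA", "gB"))))

  # identical single-SNP models: perfectly correlated genes
  m2 <- makeModel(c("gA", "gB"), c("rs1", "rs1"), c(1, 1))
  cv2 <- mergeCov(covFromMatrix("gA", matrix(1, 1, 1,
                                             dimnames = list("rs1", "rs1"))),
                  covFromMatrix("gB", matrix(1, 1, 1,
                                             dimnames = list("rs1", "rs1"))))
  gg2 <- predictedGeneCovariance(m2, cv2, c("gA", "gB"))
  expect_equal(unname(gg2), matrix(1, 2, 2))

  # shared SNP pair, complementary weights: cross term is Gamma_12
  gamma <- matrix(c(1, .5, .5, 1), 2, 2,
                  dimnames = list(c("rs1", "rs2"), c("rs1", "rs2")))
  m3 <- makeModel(c("gA", "gA", "gB", "gB"),
                  c("rs1", "rs2", "rs1", "rs2"),
                  c(1, 0, 0, 1))
  cv3 <- mergeCov(covFromMatrix("gA", gamma), covFromMatrix("gB", gamma))
  gg3 <- predictedGeneCovariance(m3, cv3, c("gA", "gB"))
  expect_equal(gg3["gA", "gB"], 0.5)
  # fullCov override gives the same answer here
  gg3b <- predictedGeneCovariance(m3, cv3, c("gA", "gB"),
                                  fullCov = gamma)
  expect_equal(gg3, gg3b)
  expect_error(predictedGeneCovariance(m3, cv3, character()), "empty")
})

test_that("component z propagation matches direct arithmetic", {
  # single-gene module: identity
  eg1 <- makeEgModel(list(mod = "gA"), list(mod = 1))
  ga <- data.frame(gene_id = "gA", z = 1.7, sigma = 1, n_snps_used = 1L)
  gc1 <- matrix(1, 1, 1, dimnames = list("gA", "gA"))
  r1 <- computeComponentZ(ga, eg1, gc1)
  expect_equal(r1$z, 1.7)
  expect_equal(r1$sigma, 1)

  # two independent genes, equal loadings: z scales by sqrt(2)
  eg2 <- makeEgModel(list(mod = c("gA", "gB")), list(mod = c(1, 1)))
  ga2 <- data.frame(gene_id = c("gA", "gB"), z = c(1.5, 1.5),
                    sigma = c(1, 1), n_snps_used = 1L)
  gc2 <- diag(2) |> `dimnames<-`(list(c("gA", "gB"), c("gA", "gB")))
  r2 <- computeComponentZ(ga2, eg2, gc2)
  expect_equal(r2$z, 1.5 * sqrt(2), tolerance = 1e-12)

  # perfectly correlated genes: no variance reduction, z unchanged
  gc3 <- matrix(1, 2, 2, dimnames = list(c("gA", "gB"), c("gA", "gB")))
  r3 <- computeComponentZ(ga2, eg2, gc3)
  expect_equal(r3$z, 1.5, tolerance = 1e-12)

  # module with no available genes is omitted with a warning
  eg3 <- makeEgModel(list(m1 = "gA", m2 = "gZ"), list(m1 = 1, m2 = 1))
  expect_warning(r4 <- computeComponentZ(ga, eg3, gc1), "omitted")
  expect_equal(r4$module_id, "m1")
})

test_that("component z is invariant to positive rescaling of loadings", {
  set.seed(31)
  genes <- paste0("g", 1:4)
  a <- matrix(rnorm(16), 4)
  gc <- crossprod(a) |> `dimnames<-`(list(genes, genes))
  ga <- data.frame(gene_id = genes, z = rnorm(4),
                   sigma = sqrt(diag(gc)), n_snps_used = 1L)
  w <- abs(rnorm(4)) + 0.1
  sds <- stats::setNames(abs(rnorm(4)) + 0.5, genes)
  eg <- makeEgModel(list(mod = genes), list(mod = w), geneSd = sds)
  z0 <- computeComponentZ(ga, eg, gc)$z
  for (cc in c(0.01, 3, 1e4)) {
    # effective loadings R/s scale by cc when the stored SDs scale by 1/cc
    egc <- makeEgModel(list(mod = genes), list(mod = w),
                       geneSd = sds / cc)
    expect_equal(computeComponentZ(ga, egc, gc)$z, z0,
                 tolerance = 1e-10)
    # renormalized rescaled loading rows leave the model unchanged
    egr <- makeEgModel(list(mod = genes), list(mod = cc * w),
                       geneSd = sds)
    expect_equal(computeComponentZ(ga, egr, gc)$z, z0,
                 tolerance = 1e-10)
  }
})

test_that("two-stage propagation equals single-step with combined weights", {
  set.seed(41)
  snps <- paste0("rs", 1:6)
  genes <- paste0("g", 1:3)
  a <- matrix(rnorm(36), 6)
  gamma <- crossprod(a) / 6 + diag(6) * 0.5
  dimnames(gamma) <- list(snps, snps)
  W <- matrix(rnorm(18), 6, 3, dimnames = list(snps, genes))
  e <- data.frame(gene_id = rep(genes, each = 6), snp_id = rep(snps, 3),
                  weight = as.numeric(W), ref_allele = "G",
                  eff_allele = "A", stringsAsFactors = FALSE)
  model <- new("PredictionModel",
               entries = e[order(e$gene_id, e$snp_id), ])
  cv <- mergeCov(covFromMatrix("g1", gamma), covFromMatrix("g2", gamma),
                 covFromMatrix("g3", gamma))
  zsnp <- rnorm(6)
  gwas <- makeGwas(snps, zsnp)

  geneZ <- computeGeneZ(gwas, model, cv)
  gc <- predictedGeneCovariance(model, cv, genes, fullCov = gamma)
  sds <- stats::setNames(sqrt(diag(gc)), genes)
  w <- c(0.3, -1.2, 0.8)
  eg <- makeEgModel(list(mod = genes), list(mod = w), geneSd = sds)
  z2 <- computeComponentZ(geneZ, eg, gc)$z

  # single step: combined SNP weights m = W (R/s), same LD covariance
  cw <- (w / sqrt(sum(w^2))) / sds
  mcomb <- as.numeric(W %*% cw)
  sig <- sqrt(as.numeric(t(mcomb) %*% gamma %*% mcomb))
  z1 <- sum(mcomb * sqrt(diag(gamma)) * zsnp) / sig
  expect_equal(z2, z1, tolerance = 1e-8)
})

test_that("Holm-Sidak adjustment matches the step-down hand computation", {
  expect_equal(holmSidakAdjust(0.03), 0.03)
  expect_equal(holmSidakAdjust(c(0.01, 0.04)),
               c(1 - 0.99^2, 0.04), tolerance = 1e-12)
  adj <- holmSidakAdjust(c(0.5, 0.5, 0.5))
  expect_equal(length(unique(adj)), 1L)
  expect_true(all(diff(sort(adj)) >= 0))
  expect_true(all(adj >= 0.5))
  expect_error(holmSidakAdjust(c(0.5, 0)), "0, 1")
  expect_error(holmSidakAdjust(c(0.5, 1.2)), "0, 1")
  # order is restored and adjustment never decreases a p-value
  set.seed(6)
  p <- runif(20, 1e-6, 1)
  adj2 <- holmSidakAdjust(p)
  expect_true(all(adj2 >= p))
  expect_identical(order(adj2[order(p)]), seq_along(p))
})

test_that("GWAS component calling uses two-sided normal tails", {
  assoc <- data.frame(module_id = c("a", "b"), z = c(0, 1.959964),
                      sigma = 1, n_genes_used = 1L)
  r <- callGwasComponents(assoc, alpha = 0.05)
  expect_equal(r$p_raw[1], 1)
  expect_false(r$is_gwas_component[1])
  expect_equal(r$p_raw[2], 0.05, tolerance = 1e-6)
  expect_false(r$is_gwas_component[2])  # at the boundary, then adjusted

  many <- data.frame(module_id = as.character(1:100), z = 5,
                     sigma = 1, n_genes_used = 1L)
  r2 <- callGwasComponents(many, alpha = 0.05)
  expect_true(all(r2$is_gwas_component))
  expect_true(all(r2$p_adjusted >= r2$p_raw))
  expect_error(callGwasComponents(assoc, alpha = 1.5), "alpha")
})

test_that("significant-component gene sets are collected correctly", {
  eg <- makeEgModel(list(m1 = c("gA", "gB"), m2 = c("gC")),
                    list(m1 = c(1, 1), m2 = 1))
  assoc <- data.frame(module_id = c("m1", "m2"),
                      is_gwas_component = c(TRUE, FALSE))
  expect_equal(sort(gwasComponentGenes(assoc, eg)), c("gA", "gB"))
})
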