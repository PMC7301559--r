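# case/control data with an exactly known pooled covariance: each class has
# 4 samples whose centered residuals are mutually orthogonal sign patterns
exactPooledData <- function(vars = c(1, 4, 1), dmu = c(1, 2, 0)) {
  base <- rbind(c(1, -1, 1, -1), c(1, 1, -1, -1), c(1, -1, -1, 1))
  base <- base[seq_along(vars), , drop = FALSE]
  resid <- base * sqrt(3 * vars / 4)  # per-class S = 3*diag(vars), df = 6
  x0 <- resid
  x1 <- resid + dmu
  x <- cbind(x0, x1)
  rownames(x) <- paste0("g", seq_along(vars))
  colnames(x) <- paste0("s", 1:8)
  list(x = x, labels = c(0, 0, 0, 0, 1, 1, 1, 1))
}

test_that("characteristic direction solves the whitened mean difference", {
  # shared covariance diag(1,4,1), shift (1,2,0):
  # v ~ (1, 0.5, 0) -> (0.8944, 0.4472, 0)
  d <- exactPooledData()
  cd <- characteristicDirection(d$x, d$labels, shrinkage = 0)
  expect_equal(unname(signatureDirection(cd)),
               c(1, 0.5, 0) / sqrt(1.25), tolerance = 1e-10)

  # identity covariance, axis-aligned shift -> unit axis vector
  d2 <- exactPooledData(vars = c(1, 1), dmu = c(2, 0))
  cd2 <- characteristicDirection(d2$x[1:2, ], d2$labels, shrinkage = 0)
  expect_equal(unname(signatureDirection(cd2)), c(1, 0),
               tolerance = 1e-10)
})

test_that("degenerate and invalid signature inputs raise errors", {
  d <- exactPooledData(dmu = c(0, 0, 0))
  expect_error(characteristicDirection(d$x, d$labels), "identical")
  expect_error(characteristicDirection(exactPooledData()$x, c(0, 1, 1, 1,
                                                              1, 1, 1, 1)),
               "2 samples per class")
  # p >> n with no shrinkage: singular shared covariance
  set.seed(12)
  x <- matrix(rnorm(50 * 6), 50, 6,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  expect_error(characteristicDirection(x, c(0, 0, 0, 1, 1, 1),
                                       shrinkage = 0), "shrinkage")
  # and shrinkage rescues it
  cd <- characteristicDirection(x, c(0, 0, 0, 1, 1, 1), shrinkage = 0.5)
  expect_equal(sum(signatureDirection(cd)^2), 1, tolerance = 1e-10)
})

test_that("direction is equivariant to gene order and flips with labels", {
  set.seed(14)
  x <- matrix(rnorm(10 * 12), 10, 12,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  lab <- rep(c(0, 1), each = 6)
  cd <- characteristicDirection(x, lab, shrinkage = 0.3)
  perm <- sample(10)
  cdp <- characteristicDirection(x[perm, ], lab, shrinkage = 0.3)
  expect_equal(unname(signatureDirection(cdp)),
               unname(signatureDirection(cd))[perm], tolerance = 1e-10)
  cdf <- characteristicDirection(x, 1 - lab, shrinkage = 0.3)
  expect_equal(unname(signatureDirection(cdf)),
               -unname(signatureDirection(cd)), tolerance = 1e-10)
})

test_that("with identity covariance the direction is the mean difference", {
  set.seed(15)
  x <- matrix(rnorm(8 * 20), 8, 20,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:20)))
  lab <- rep(c(0, 1), 10)
  dmu <- rowMeans(x[, lab == 1]) - rowMeans(x[, lab == 0])
  # shrinkage 1 replaces the pooled covariance by a scaled identity
  cd <- characteristicDirection(x, lab, shrinkage = 1)
  expect_equal(unname(signatureDirection(cd)),
               unname(dmu / sqrt(sum(dmu^2))), tolerance = 1e-10)
})

test_that("cosine distance is the normalized inner product", {
  genes <- paste0("g", 1:5)
  v <- randomSignature(genes, 1)
  expect_equal(cosineDistance(v, v), 1, tolerance = 1e-12)
  vneg <- new("CharacteristicDirection", geneIds = genes,
              direction = -v@direction)
  expect_equal(cosineDistance(v, vneg), -1, tolerance = 1e-12)
  e1 <- new("CharacteristicDirection", geneIds = genes,
            direction = c(1, 0, 0, 0, 0))
  e2 <- new("CharacteristicDirection", geneIds = genes,
            direction = c(0, 1, 0, 0, 0))
  expect_equal(cosineDistance(e1, e2), 0)
  other <- randomSignature(paste0("h", 1:5), 2)
  expect_error(cosineDistance(v, other), "share no genes")
  # restriction to the shared universe with re-normalization
  vbig <- new("CharacteristicDirection", geneIds = paste0("g", 1:6),
              direction = c(1, 1, 0, 0, 0, 5) / sqrt(27))
  expect_equal(cosineDistance(vbig, e1), 1 / sqrt(2), tolerance = 1e-12)
})

test_that("isotropic null matches closed-form cosine moments", {
  genes <- sprintf("g%04d", 1:1000)
  target <- randomSignature(genes, 3)
  null <- buildNullDistribution(target, n = 10000, seed = 7)
  # isotropic cosine in p dims: mean 0, sd ~ 1/sqrt(p)
  expect_lt(abs(null$mean), 3 / sqrt(1000 * 10000) * 10)
  expect_equal(null$sd, 1 / sqrt(1000), tolerance = 0.05)
  null2 <- buildNullDistribution(target, n = 10000, seed = 7)
  expect_identical(null$samples, null2$samples)
  expect_error(buildNullDistribution(target, n = 50), "n >= 100")
})

test_that("null normalization is a z-transform of the cosine distance", {
  null <- structure(list(samples = numeric(200), mean = 0, sd = 0.1,
                         n = 200L, seed = 1), class = "NullDistribution")
  expect_equal(normalizeAgainstNull(0.5, null), 5)
  expect_equal(normalizeAgainstNull(0, null), 0)
  nullz <- structure(list(samples = numeric(200), mean = 0.2, sd = 0,
                          n = 200L, seed = 1), class = "NullDistribution")
  expect_error(normalizeAgainstNull(0.5, nullz), "zero standard deviation")
})

test_that("pool-based nulls resample supplied signatures", {
  genes <- paste0("g", 1:50)
  pool <- lapply(1:20, function(i) randomSignature(genes, 100 + i))
  target <- randomSignature(genes, 99)
  null <- buildNullDistribution(target, n = 500, seed = 5, pool = pool)
  ref <- sort(unique(round(vapply(pool, cosineDistance, numeric(1),
                                  v2 = target), 12)))
  expect_true(all(round(null$samples, 12) %in% ref))
  expect_error(buildNullDistribution(target, n = 500, pool = list()),
               "empty")
})

test_that("matching flags correlated and anticorrelated signatures", {
  genes <- sprintf("g%04d", 1:1000)
  disease <- randomSignature(genes, 21)
  anti <- new("CharacteristicDirection", geneIds = genes,
              direction = -disease@direction)
  unrelated <- randomSignature(genes, 22)
  res <- callLincsHits(
    list(same = disease, anti = anti, noise = unrelated),
    list(dz = disease), nNull = 1000, seed = 9)
  expect_true(res$hits[["same"]])
  expect_true(res$hits[["anti"]])
  expect_false(res$hits[["noise"]])
  expect_lt(res$pairs$normalized[res$pairs$perturbation == "anti"], -1.96)
  # unadjusted mode applies the bare 1.96 rule
  res2 <- callLincsHits(list(same = disease), list(dz = disease),
                        nNull = 1000, seed = 9, adjust = FALSE)
  expect_true(res2$hits[["same"]])
})
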