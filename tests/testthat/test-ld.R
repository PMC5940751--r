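block_panel <- function(counts) {
  # counts: named haplotype multiplicities for alleles of v1/v2, e.g.
  # c(AB = 5, aB = 3, ab = 2)
  h1 <- h2 <- integer(0)
  for (nm in names(counts)) {
    n <- counts[[nm]]
    h1 <- c(h1, rep(as.integer(substr(nm, 1, 1) == "A"), n))
    h2 <- c(h2, rep(as.integer(substr(nm, 2, 2) == "B"), n))
  }
  haplotype_panel(rbind(h1, h2),
                  data.frame(rsid = c("v1", "v2"), chrom = 1, pos = c(1, 2)))
}

test_that("D' and r2 from haplotype frequencies match hand enumeration", {
  ld <- ld_d_prime_r2(block_panel(c(AB = 5, ab = 5)), "v1", "v2")
  expect_equal(ld$d_prime, 1)
  expect_equal(ld$r2, 1)

  ld <- ld_d_prime_r2(block_panel(c(AB = 4, Ab = 4, aB = 1, ab = 1)),
                      "v1", "v2")
  expect_equal(ld$d_prime, 0)
  expect_equal(ld$r2, 0)

  # rare allele in complete coupling: D' = 1 with low shared variance
  ld <- ld_d_prime_r2(block_panel(c(AB = 5, aB = 3, ab = 2)), "v1", "v2")
  expect_equal(ld$d_prime, 1)
  expect_equal(ld$r2, 0.25)
})

test_that("LD is symmetric, bounded, and r2 <= D'^2 on random panels", {
  set.seed(42)
  for (rep in 1:50) {
    panel <- random_panel(m = 5, n_hap = sample(c(10, 40, 200), 1))
    v <- sample(panel$variants$rsid, 2)
    a <- ld_d_prime_r2(panel, v[1], v[2])
    b <- ld_d_prime_r2(panel, v[2], v[1])
    expect_equal(a$d_prime, b$d_prime)
    expect_equal(a$r2, b$r2)
    expect_gte(a$d_prime, 0); expect_lte(a$d_prime, 1 + 1e-12)
    expect_gte(a$r2, 0); expect_lte(a$r2, 1 + 1e-12)
    expect_lte(a$r2, a$d_prime^2 + 1e-9)
    orc <- oracle_ld(panel$H[v[1], ], panel$H[v[2], ])
    expect_equal(a$r2, orc$r2, tolerance = 1e-12)
    expect_equal(a$d_prime, orc$d_prime, tolerance = 1e-12)
  }
})

test_that("monomorphic variants give an undefined-LD error", {
  H <- rbind(rep(1, 10), rbinom(10, 1, 0.5))
  H[2, 1] <- 1; H[2, 2] <- 0
  panel <- haplotype_panel(H, data.frame(rsid = c("mono", "poly")))
  expect_error(ld_d_prime_r2(panel, "mono", "poly"), "monomorphic")
})

test_that("proxy search honours threshold and tie-breaks", {
  # v1 duplicated by v2 (r2=1, 1kb away) and correlated with v3/v4
  set.seed(42)
  h <- rbinom(60, 1, 0.5)
  noise <- function(x, k) { y <- x; i <- sample(60, k); y[i] <- 1 - y[i]; y }
  H <- rbind(h, h, noise(h, 2), noise(h, 25))
  panel <- haplotype_panel(H, data.frame(
    rsid = c("t", "near", "far", "weak"), chrom = 1,
    pos = c(100, 5100, 50100, 60100)))
  cands <- data.frame(rsid = c("near", "far", "weak"))

  # target itself among candidates wins at r2 = 1
  expect_equal(find_proxy("t", data.frame(rsid = c("t", "near")), panel), "t")
  expect_equal(find_proxy("t", cands, panel), "near")
  # all candidates below threshold -> none
  expect_equal(find_proxy("t", data.frame(rsid = "weak"), panel,
                          r2_min = 0.8), NA_character_)
  expect_error(find_proxy("absent", cands, panel), "not in panel")

  # exact tie on r2: nearer position wins, then rsid
  H2 <- rbind(h, h, h)
  p2 <- haplotype_panel(H2, data.frame(rsid = c("t", "b_far", "a_near"),
                                       chrom = 1, pos = c(100, 50100, 5100)))
  expect_equal(find_proxy("t", data.frame(rsid = c("b_far", "a_near")), p2),
               "a_near")
})

test_that("panels load from plain matrix + sidecar and from phased VCF", {
  H <- matrix(rbinom(40, 1, 0.5), 4, 10)
  mf <- tempfile(); vf <- tempfile()
  write.table(H, mf, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(rsid = paste0("m", 1:4), chrom = 1, pos = 1:4),
              vf, row.names = FALSE, quote = FALSE)
  panel <- read_panel_matrix(mf, vf)
  expect_equal(dim(panel$H), c(4L, 10L))

  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "19\t100\trsA\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1\t0|0",
    "19\t200\trsB\tC\tT\t.\tPASS\t.\tGT\t0|0\t1|0\t0|1"), vcf)
  pv <- read_panel_vcf(vcf)
  expect_equal(pv$variants$rsid, c("rsA", "rsB"))
  expect_equal(ncol(pv$H), 6L)   # two haplotypes per sample
  expect_equal(mean(pv$H["rsA", ]), 0.5)
})
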