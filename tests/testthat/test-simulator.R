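# Molecule ids encoded in read names, for molecule-level set comparisons.
molecule_ids <- function(lib) {
  if (nrow(lib$reads) == 0L) return(integer(0))
  as.integer(sub("^m", "", vapply(strsplit(lib$reads$name, "|", fixed = TRUE),
                                  `[[`, character(1), 4L)))
}

test_that("make_genome hits its site target reproducibly", {
  g1 <- make_genome(1, 10000, 30, seed = 7)
  expect_identical(g1, make_genome(1, 10000, 30, seed = 7))
  expect_gte(nrow(find_sites(g1)), 30L)
  expect_false(identical(g1, make_genome(1, 10000, 30, seed = 8)))
  # target 0: plain random sequence, still valid
  g0 <- make_genome(2, 500, 0, seed = 1)
  expect_length(g0, 2L)
  expect_equal(nchar(g0[[1]]), 500L)
  # per-contig target enforced on every contig
  gm <- make_genome(3, 2000, 15, seed = 3, gc = 0.3)
  for (ctg in names(gm)) {
    expect_gte(nrow(find_sites(gm[ctg])), 15L)
  }
  expect_error(make_genome(1, 10, 5, seed = 1), "infeasible")
})

test_that("make_profile draws valid, reproducible site fractions", {
  sys <- test_system()
  p1 <- make_profile(sys$sites, seed = 5)
  expect_identical(p1, make_profile(sys$sites, seed = 5))
  expect_true(all(p1$hmc >= 0 & p1$hmc <= 1))
  expect_true(all(p1$mc >= 0 & p1$mc <= 1))
  expect_true(all(p1$hmc + p1$mc <= 1 + 1e-12))
  # covers exactly the detectable (site, strand) pairs
  n_pairs <- sum(sys$sites$fwd_detectable) + sum(sys$sites$rev_detectable)
  expect_equal(nrow(p1), n_pairs)
  # zero_hmc_fraction = 1 forces hmc to 0 everywhere
  p0 <- make_profile(sys$sites, zero_hmc_fraction = 1, seed = 5)
  expect_true(all(p0$hmc == 0))
  # Beta(1, 1) draws over many pairs respect range and sum constraints
  big <- test_system(contig_length = 250000L, target_sites = 900L, seed = 2)
  pb <- make_profile(big$sites, hmc_beta = c(1, 1), mc_beta = c(1, 1),
                     zero_hmc_fraction = 0, seed = 9)
  expect_gte(nrow(pb), 1000L)
  expect_true(all(pb$hmc >= 0 & pb$hmc <= 1 & pb$hmc + pb$mc <= 1 + 1e-12))
  expect_error(make_profile(sys$sites, hmc_beta = c(-1, 2)), "Beta")
})

test_that("the negative control library is empty", {
  sys <- test_system()
  prof <- make_profile(sys$sites, zero_hmc_fraction = 0, seed = 2)
  for (enz in c("MspI", "HpaII")) {
    # no glucosylation, complete digestion, no methylation: nothing survives
    prof0 <- prof; prof0$hmc <- 0; prof0$mc <- 0
    cfg <- library_config(n_molecules_per_fragment = 50, beta_gt = FALSE,
                          second_enzyme = enz, seed = 3)
    lib <- simulate_library(sys$genome, prof0, cfg)
    expect_equal(nrow(lib$reads), 0L)
    expect_true(all(lib$truth$reads == 0L))
  }
  # MspI without beta-GT is empty even with hmC present
  cfgm <- library_config(n_molecules_per_fragment = 50, beta_gt = FALSE,
                         second_enzyme = "MspI", seed = 3)
  libm <- simulate_library(sys$genome, prof, cfgm)
  expect_equal(nrow(libm$reads), 0L)
})

test_that("full protection recovers every detectable pair", {
  sys <- test_system()
  prof <- make_profile(sys$sites, seed = 2)
  prof$hmc <- 1; prof$mc <- 0
  cfg <- library_config(n_molecules_per_fragment = 60, seed = 4)
  lib <- simulate_library(sys$genome, prof, cfg)
  expect_true(all(lib$truth$reads >= 1L))
  expect_equal(sum(lib$truth$reads), nrow(lib$reads))
})

test_that("simulation is byte-identical under a fixed seed", {
  sys <- test_system(contig_length = 8000L, target_sites = 25L)
  prof <- make_profile(sys$sites, seed = 2)
  cfg <- library_config(n_molecules_per_fragment = 40, seq_error_rate = 0.01,
                        digestion_failure_rate = 1e-3,
                        pcr_duplicate_mean = 1.5, seed = 6)
  a <- simulate_library(sys$genome, prof, cfg)
  b <- simulate_library(sys$genome, prof, cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  fa <- tempfile(fileext = ".fq"); fb <- tempfile(fileext = ".fq")
  write_fastq(a, fa); write_fastq(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("truth-table bookkeeping is internally consistent", {
  sys <- test_system()
  prof <- make_profile(sys$sites, seed = 2)
  cfg <- library_config(n_molecules_per_fragment = 40,
                        pcr_duplicate_mean = 2, seed = 8)
  lib <- simulate_library(sys$genome, prof, cfg)
  tr <- lib$truth
  expect_true(all(tr$surviving <= tr$drawn))
  expect_true(all(tr$reads >= tr$surviving))
  expect_equal(sum(tr$reads), nrow(lib$reads))
  # without PCR over-duplication, one read per surviving molecule
  cfg1 <- library_config(n_molecules_per_fragment = 40,
                         pcr_duplicate_mean = 1, seed = 8)
  tr1 <- simulate_library(sys$genome, prof, cfg1)$truth
  expect_equal(tr1$reads, tr1$surviving)
})

test_that("background reads scale as molecules x junction x failure x PCR", {
  sys <- test_system()
  prof <- make_profile(sys$sites, seed = 2)
  prof$hmc <- 0; prof$mc <- 0
  f <- 0.01
  cfg <- library_config(n_molecules_per_fragment = 400,
                        digestion_failure_rate = f, seed = 10)
  lib <- simulate_library(sys$genome, prof, cfg)
  fr <- lib$catalog$fragments
  M <- nrow(fr) * cfg$n_molecules_per_fragment
  expect_gte(M, 1e4)
  # probability a molecule is hetero-adapterized with its P5 at a junction
  p_junction <- mean((!is.na(fr$left_site)) + (!is.na(fr$right_site))) / 2
  p <- cfg$hetero_adapter_prob * p_junction * f
  expected <- M * p
  tol <- 3 * sqrt(M * p * (1 - p))
  expect_lt(abs(nrow(lib$reads) - expected), tol)
})

test_that("survival frequencies estimate the true hmC fraction without bias", {
  sys <- test_system(contig_length = 60000L, target_sites = 200L)
  prof <- make_profile(sys$sites, zero_hmc_fraction = 0, seed = 2)
  cfg <- library_config(n_molecules_per_fragment = 200, seed = 12)
  tr <- simulate_library(sys$genome, prof, cfg)$truth
  tr <- tr[tr$drawn > 0, ]
  resid <- tr$surviving / tr$drawn - tr$hmc_true
  se <- sqrt(sum(tr$hmc_true * (1 - tr$hmc_true) / tr$drawn)) / nrow(tr)
  expect_lt(abs(mean(resid)), 3 * max(se, 1e-4))
})

test_that("MspI+betaGT survivors nest inside HpaII survivors at a shared seed", {
  sys <- test_system()
  prof <- make_profile(sys$sites, zero_hmc_fraction = 0.2, seed = 2)
  base <- function(enz, bgt) {
    simulate_library(sys$genome, prof, library_config(
      n_molecules_per_fragment = 60, beta_gt = bgt, second_enzyme = enz,
      digestion_failure_rate = 1e-3, seed = 14))
  }
  mspi <- base("MspI", TRUE)
  hpaii <- base("HpaII", TRUE)
  expect_true(all(molecule_ids(mspi) %in% molecule_ids(hpaii)))
  expect_true(all(mspi$truth$surviving <= hpaii$truth$surviving))
})

test_that("a profile that does not match the catalog is rejected", {
  sys <- test_system()
  prof <- make_profile(sys$sites, seed = 2)
  cfg <- library_config(seed = 1)
  expect_error(simulate_library(sys$genome, prof[-1, ], cfg), "detectable")
  prof2 <- prof; prof2$pos[1] <- prof2$pos[1] + 1L
  expect_error(simulate_library(sys$genome, prof2, cfg), "detectable")
})

test_that("library_config validates its bounds", {
  expect_error(library_config(digestion_failure_rate = 1.5), "\\[0, 1\\]")
  expect_error(library_config(read_length = 3), "read_length")
  expect_error(library_config(pcr_duplicate_mean = 0.5), "pcr_duplicate_mean")
  expect_error(library_config(insert_range = c(50, 10)), "insert_range")
  expect_error(library_config(second_enzyme = "EcoRI"))
})

test_that("reads round-trip through FASTQ on disk", {
  sys <- test_system(contig_length = 8000L, target_sites = 25L)
  prof <- make_profile(sys$sites, seed = 2)
  lib <- simulate_library(sys$genome, prof,
                          library_config(n_molecules_per_fragment = 30,
                                         seed = 5))
  fq <- tempfile(fileext = ".fq")
  write_fastq(lib, fq)
  back <- read_fastq(fq)
  expect_equal(back, lib$reads)
})
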