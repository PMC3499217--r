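test_that("constructor enforces the dataset invariants", {
  d <- toy_dataset(c(0, 1, 2, NA, 2, 1), c("X", "Y"))
  expect_s3_class(d, "genotype_dataset")
  expect_equal(dim(d$calls), c(2L, 3L))
  expect_error(toy_dataset(c(0, 3), c("X", "Y")), "0, 1, 2 or NA")
  expect_error(genotype_dataset(matrix(0L, 2, 2,
                                       dimnames = list(c("a", "a"), NULL)),
                                c("X", "Y")), "duplicate sample")
  bad_loci <- data.frame(locus_id = "L1", chromosome = "3",
                         position_bp = NA_integer_,
                         ref_allele = "A", alt_allele = "G")
  expect_error(genotype_dataset(matrix(0L, 1, 1,
                                       dimnames = list("s", "L1")),
                                "X", bad_loci), "position")
})

test_that("PED/MAP fixtures parse per convention, including 0 0 missing", {
  tmp <- withr::local_tempdir()
  # 2 samples, 3 loci; sample 2 missing at locus 2
  writeLines(c("1\trs1\t0\t100", "1\trs2\t0\t200", "0\trs3\t0\t0"),
             file.path(tmp, "toy.map"))
  writeLines(c("BreedX s1 0 0 0 -9 A A A G C C",
               "BreedY s2 0 0 0 -9 A G 0 0 C C"),
             file.path(tmp, "toy.ped"))
  d <- read_genotypes(file.path(tmp, "toy.ped"), "ped_map")
  expect_equal(dim(d$calls), c(2L, 3L))
  # rs1: alleles {A,G}, ref=A alt=G: s1 AA -> 0, s2 AG -> 1
  expect_equal(unname(d$calls[, "rs1"]), c(0L, 1L))
  expect_equal(unname(d$calls["s2", "rs2"]), NA_integer_)
  expect_equal(unname(d$breed), c("BreedX", "BreedY"))
  # monomorphic rs3: all-C, dosage 0, alt undefined
  expect_equal(unname(d$calls[, "rs3"]), c(0L, 0L))
  expect_true(is.na(d$loci$alt_allele[3]))
  expect_equal(d$loci$chromosome, c("1", "1", "Undetermined"))
  expect_equal(d$loci$position_bp, c(100L, 200L, NA))

  # malformed and invalid inputs
  writeLines("BreedX s3 0 0 0 -9 A A", file.path(tmp, "bad.ped"))
  file.copy(file.path(tmp, "toy.map"), file.path(tmp, "bad.map"))
  expect_error(read_genotypes(file.path(tmp, "bad.ped")), "line 1")
  writeLines(c("BreedX s1 0 0 0 -9 A A A G C C",
               "BreedY s2 0 0 0 -9 A T C G C C"),
             file.path(tmp, "tri.ped"))
  file.copy(file.path(tmp, "toy.map"), file.path(tmp, "tri.map"))
  expect_error(read_genotypes(file.path(tmp, "tri.ped")),
               "more than two alleles")
})

test_that("CSV dialect round-trips a simulated dataset exactly", {
  sc <- sim_scenario(n_breeds = 3, samples_per_breed = 5, n_loci = 20,
                     breed_F = 0.3, missing_rate = 0.1, seed = 42)
  d <- simulate_dataset(sc)
  tmp <- withr::local_tempdir()
  write_genotypes(d, file.path(tmp, "sim.csv"), "csv")
  d2 <- read_genotypes(file.path(tmp, "sim.csv"), "csv")
  expect_identical(d2$calls, d$calls)
  expect_identical(d2$breed, d$breed)
  expect_identical(d2$loci, d$loci)
})

test_that("PED/MAP writer round-trips genotype content", {
  sc <- sim_scenario(n_breeds = 2, samples_per_breed = 4, n_loci = 12,
                     breed_F = 0.4, missing_rate = 0.1, seed = 7)
  d <- simulate_dataset(sc)
  tmp <- withr::local_tempdir()
  write_genotypes(d, file.path(tmp, "sim.ped"), "ped_map")
  d2 <- read_genotypes(file.path(tmp, "sim.ped"), "ped_map")
  # allele designation is alphabetical on read (ref=A, alt=G as written),
  # so dosages must round-trip wherever the locus is polymorphic
  poly <- !is.na(d2$loci$alt_allele)
  expect_identical(d2$calls[, poly], d$calls[, poly])
  expect_identical(unname(d2$breed), unname(d$breed))
})

test_that("estimate_frequencies counts and leave-one-out behave exactly", {
  d <- toy_dataset(c(2, 0, 0,
                     0, NA, 1), c("X", "X"))
  f <- estimate_frequencies(d, "X")
  expect_equal(f$n_alt, c(2L, 0L, 1L))
  expect_equal(f$n_obs, c(4L, 2L, 4L))
  expect_equal(f$freq_alt, c(0.5, 0, 0.25))
  # leaving out the first sample removes both its copies; locus 2 is then
  # unobserved (the other sample is missing there) so its frequency is NA
  f1 <- estimate_frequencies(d, "X", leave_out = "S1")
  expect_equal(f1$n_alt, c(0L, 0L, 1L))
  expect_equal(f1$n_obs, c(2L, 0L, 2L))
  expect_equal(f1$freq_alt, c(0, NA, 0.5))
  # ...and a missing call leaves the locus untouched
  f2 <- estimate_frequencies(d, "X", leave_out = "S2")
  expect_equal(f2$n_obs[2], 2L)
  expect_equal(f2$n_alt[2], 0L)
  expect_error(estimate_frequencies(d, "Z"), "unknown breed")
  expect_error(estimate_frequencies(d, "X", leave_out = "nope"), "not in breed")
})

test_that("leave-one-out equals recomputation on the reduced dataset", {
  sc <- sim_scenario(n_breeds = 2, samples_per_breed = 4, n_loci = 15,
                     breed_F = 0.3, missing_rate = 0.15, seed = 9)
  d <- simulate_dataset(sc)
  for (b in breeds(d)) {
    for (s in rownames(d$calls)[d$breed == b]) {
      loo <- estimate_frequencies(d, b, leave_out = s)
      red <- subset_samples(d, setdiff(rownames(d$calls), s))
      ref <- estimate_frequencies(red, b)
      expect_equal(loo$n_alt, ref$n_alt)
      expect_equal(loo$n_obs, ref$n_obs)
    }
  }
})

test_that("allele relabelling maps freq_alt to 1 - freq_alt", {
  sc <- sim_scenario(n_breeds = 2, samples_per_breed = 6, n_loci = 10,
                     breed_F = 0.3, missing_rate = 0.1, seed = 4)
  d <- simulate_dataset(sc)
  swapped <- d
  swapped$calls <- 2L - d$calls
  for (b in breeds(d)) {
    f1 <- estimate_frequencies(d, b)
    f2 <- estimate_frequencies(swapped, b)
    expect_equal(f2$freq_alt, 1 - f1$freq_alt)
    expect_equal(f2$n_obs, f1$n_obs)
  }
})

test_that("call-rate filtering drops the documented locus and is idempotent", {
  # breed X: locus 1 observed in 3 of 4 (0.75 < 0.8); fully observed in Y
  calls <- rbind(c(0L, 1L), c(1L, 1L), c(2L, 0L), c(NA, 2L),
                 c(0L, 0L), c(1L, 1L))
  d <- genotype_dataset(calls, c("X", "X", "X", "X", "Y", "Y"))
  res <- filter_call_rate(d, qc_config(min_sample_call_rate = 0))
  expect_equal(colnames(res$data$calls), "L2")
  expect_true(res$locus_report$dropped[1])
  expect_equal(res$locus_report$call_rate[1], 0.75)
  # overall scope keeps it: 5/6 observed
  res_o <- filter_call_rate(d, qc_config(call_rate_scope = "overall",
                                         min_sample_call_rate = 0))
  expect_equal(n_loci(res_o$data), 2L)
  # no missing data -> identity
  d2 <- toy_dataset(c(0, 1, 2, 0), c("X", "Y"))
  expect_identical(filter_call_rate(d2)$data$calls, d2$calls)
  # idempotence
  sc <- sim_scenario(n_breeds = 3, samples_per_breed = 10, n_loci = 50,
                     breed_F = 0.3, missing_rate = 0.1, seed = 12)
  dd <- simulate_dataset(sc)
  once <- filter_call_rate(dd)
  twice <- filter_call_rate(once$data)
  expect_identical(twice$data$calls, once$data$calls)
  # degenerate: every locus dropped
  d3 <- toy_dataset(c(NA, NA, NA, NA), c("X", "Y"))
  expect_error(filter_call_rate(d3), "empty")
})
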