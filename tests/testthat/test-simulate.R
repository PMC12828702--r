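des10 <- test_design(10, seed = 910)

test_that("noise-free simulation reproduces the expected insert verbatim", {
  sim <- simulate_molecules(des10, sim_params(n_molecules = 20, seed = 1))
  expect_true(all(sim$molecules$sequence == des10$expected_insert))
  expect_true(all(sim$molecules$n_units == 10L))
  expect_identical(nrow(sim$truth_mutations), 0L)
  expect_identical(nrow(sim$truth_units), 200L)
})

test_that("the same seed gives byte-identical molecules and FASTQ", {
  p <- sim_params(n_molecules = 50, junction_failure_prob = 0.05,
                  deleterious_mutation_prob = 0.1, read_error_rate = 0.02,
                  revcomp_prob = 0.5, incomplete_prob = 0.1, seed = 77)
  s1 <- simulate_molecules(des10, p)
  s2 <- simulate_molecules(des10, p)
  expect_identical(s1, s2)
  r1 <- simulate_reads(s1, des10$fixtures, p)
  r2 <- simulate_reads(s2, des10$fixtures, p)
  expect_identical(r1, r2)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(r1, f1, error_rate = 0.02)
  write_fastq(r2, f2, error_rate = 0.02)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("truncation follows the per-junction failure model", {
  q <- 0.023
  n <- 10000
  sim <- simulate_molecules(des10, sim_params(n_molecules = n,
                                              junction_failure_prob = q,
                                              seed = 8))
  p_full <- (1 - q)^9
  observed <- mean(sim$molecules$n_units == 10L)
  se <- sqrt(p_full * (1 - p_full) / n)
  expect_lt(abs(observed - p_full), 3 * se)
  # truncated molecules are exact prefixes of the expected insert
  short <- sim$molecules[sim$molecules$n_units < 10, ][1:5, ]
  expect_true(all(short$sequence ==
                    substring(des10$expected_insert, 1,
                              nchar(short$sequence))))
  # an explicit unit-count distribution overrides the junction model
  probs <- c(rep(0, 9), 1)
  probs[3] <- 0.5; probs[10] <- 0.5
  sim2 <- simulate_molecules(des10, sim_params(n_molecules = 500,
                                               unit_count_probs = probs,
                                               seed = 9))
  expect_setequal(unique(sim2$molecules$n_units), c(3L, 10L))
})

test_that("planted mutations land in their regions with the stated kinds", {
  p <- sim_params(n_molecules = 200, deleterious_mutation_prob = 0.1,
                  tail_mutation_prob = 0.1, sub_indel_ratio = 0.6, seed = 12)
  sim <- simulate_molecules(des10, p)
  tm <- sim$truth_mutations
  expect_true(all(tm$region %in% c("u6_promoter", "spacer", "scaffold",
                                   "primer_tail")))
  expect_true(all(tm$kind %in% c("substitution", "insertion", "deletion")))
  # every planted position lies inside the named region of the named unit
  reg <- des10$insert_regions
  reg$region[reg$region %in% c("primer_tail_left", "primer_tail_right")] <-
    "primer_tail"
  for (i in seq_len(nrow(tm))) {
    rows <- reg[reg$unit == tm$unit[i] & reg$region == tm$region[i], ]
    expect_true(any(rows$start <= tm$ref_position[i] &
                      rows$end > tm$ref_position[i]))
  }
  # at most one deleterious and one tail event per unit per molecule
  per <- table(paste(tm$molecule_id, tm$unit,
                     tm$region == "primer_tail"))
  expect_lte(max(per), 1L)
})

test_that("library sampling covers every position x member cell uniformly", {
  lib <- test_library_design(10, 10, seed = 77)
  sim <- simulate_library_molecules(lib, sim_params(n_molecules = 20000,
                                                    seed = 4))
  truth <- table(sim$truth_units$position, sim$truth_units$name)
  expect_identical(dim(truth), c(10L, 10L))
  expect_true(all(truth > 0))
  # equimolar pools: chi-square against uniform not rejected at alpha = 0.001
  for (p in 1:10) {
    pv <- stats::chisq.test(truth[p, ])$p.value
    expect_gt(pv, 0.001)
  }
})

test_that("single-member pools reduce library simulation to the plain model", {
  p <- sim_params(n_molecules = 10, junction_failure_prob = 0.1, seed = 5)
  expect_identical(simulate_library_molecules(des10, p),
                   simulate_molecules(des10, p))
})

test_that("read errors accumulate at the configured per-base rate", {
  des3 <- test_design(3, seed = 93)
  p <- sim_params(n_molecules = 150, read_error_rate = 0.02,
                  revcomp_prob = 0, seed = 21)
  sim <- simulate_molecules(des3, p)
  reads <- simulate_reads(sim, des3$fixtures, p)
  fl <- flanking_sequences(des3$fixtures, 30)
  ins <- extract_inserts(reads, fl[["up"]], fl[["down"]])
  expect_gt(nrow(ins), 140)
  truth_seq <- sim$molecules$sequence[reads$molecule_id[match(ins$read_id,
                                                              reads$read_id)]]
  d <- mapply(function(a, b) as.integer(utils::adist(a, b)),
              ins$insert, truth_seq, USE.NAMES = FALSE)
  L <- nchar(des3$expected_insert)
  expected <- L * 0.02
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - expected), 3 * se + 1)
})

test_that("reverse-complemented reads carry the molecule on the minus strand", {
  p <- sim_params(n_molecules = 10, revcomp_prob = 1, seed = 31)
  sim <- simulate_molecules(des10, p)
  reads <- simulate_reads(sim, des10$fixtures, p)
  expect_true(all(reads$strand == "-"))
  expect_true(all(vapply(reads$sequence, function(s) {
    grepl(des10$expected_insert, orc_revcomp(s), fixed = TRUE)
  }, logical(1))))
})
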