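fx <- default_fixtures()
des5 <- test_design(5, seed = 55)
fl <- flanking_sequences(fx, 30)

test_that("insert extraction finds flanked inserts on either strand", {
  set.seed(1)
  insert <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  read_fwd <- paste0(fl[["up"]], insert, fl[["down"]])
  hit <- extract_inserts(c(r1 = read_fwd), fl[["up"]], fl[["down"]])
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$insert, insert)
  expect_identical(hit$strand, "+")
  expect_identical(hit$up_flank_errors, 0L)
  expect_identical(hit$insert_start, 30L)
  expect_identical(hit$insert_end, 150L)

  # reverse-complemented read yields the same insert, minus strand
  hit_rc <- extract_inserts(c(r1 = orc_revcomp(read_fwd)), fl[["up"]],
                            fl[["down"]])
  expect_identical(hit_rc$insert, insert)
  expect_identical(hit_rc$strand, "-")
  expect_identical(hit_rc$insert_start, nchar(read_fwd) - 150L)

  # incomplete reads lacking a flank are discarded and counted
  res <- extract_inserts(c(ok = read_fwd,
                           no_down = paste0(fl[["up"]], insert),
                           no_up = paste0(insert, fl[["down"]])),
                         fl[["up"]], fl[["down"]])
  expect_identical(nrow(res), 1L)
  expect_identical(attr(res, "n_reads"), 3L)
  expect_identical(attr(res, "n_discarded"), 2L)

  expect_error(extract_inserts(c(r = read_fwd), "ACGTACGT", fl[["down"]]),
               "20 nt", class = "guidearray_validation_error")
})

test_that("length binning assigns nearest expected length and conserves counts", {
  tab <- des5$unit_length_table
  mk <- function(L) strrep("A", L)
  ins <- tibble::tibble(
    read_id = sprintf("r%d", 1:5),
    insert = c(mk(tab[5]),              # exactly full length
               mk(tab[2] + 10),         # near 2 units
               mk(tab[3] - 100),        # near 3 units
               mk(tab[1] %/% 3),        # far from any bin -> unbinned
               mk(tab[4]))
  )
  h <- bin_by_length(ins, des5)
  expect_identical(h$count[h$n_units == 5], 1L)
  expect_identical(h$count[h$n_units == 2], 1L)
  expect_identical(h$count[h$n_units == 3], 1L)
  expect_identical(attr(h, "n_unbinned"), 1L)
  expect_identical(sum(h$count) + attr(h, "n_unbinned"),
                   attr(h, "n_extracted"))
  expect_identical(glance(h)$full_length_fraction, 1 / 4)
})

test_that("a planted unit-count histogram is recovered exactly at zero noise", {
  probs <- c(0.2, 0.1, 0.3, 0.1, 0.3)
  p <- sim_params(n_molecules = 120, unit_count_probs = probs,
                  revcomp_prob = 0.5, seed = 14)
  sim <- simulate_molecules(des5, p)
  reads <- simulate_reads(sim, fx, p)
  ins <- extract_inserts(reads, fl[["up"]], fl[["down"]])
  h <- bin_by_length(ins, des5)
  planted <- tabulate(sim$molecules$n_units, nbins = 5)
  expect_identical(h$count, planted)
  expect_identical(attr(h, "n_unbinned"), 0L)
})

test_that("mutation profiling calls planted defects in the right region", {
  expected <- des5$expected_insert
  expect_identical(nrow(profile_mutations(expected, des5)$calls), 0L)

  # single substitution in unit 3's spacer
  reg <- des5$insert_regions
  sp3 <- reg[reg$unit == 3 & reg$region == "spacer", ]
  pos <- sp3$start + 7L
  mutated <- expected
  old <- substr(mutated, pos + 1, pos + 1)
  substr(mutated, pos + 1, pos + 1) <- setdiff(c("A", "C", "G", "T"), old)[1]
  prof <- profile_mutations(mutated, des5)
  expect_identical(nrow(prof$calls), 1L)
  expect_identical(prof$calls$unit, 3L)
  expect_identical(prof$calls$region, "spacer")
  expect_identical(prof$calls$kind, "substitution")
  expect_identical(prof$calls$ref_position, pos)
  expect_identical(sum(prof$units$deleterious), 1L)

  # primer-tail mutation is called but not counted as deleterious
  tail3 <- reg[reg$unit == 3 & reg$region == "primer_tail_left", ]
  tpos <- tail3$start + 2L
  tmut <- expected
  told <- substr(tmut, tpos + 1, tpos + 1)
  substr(tmut, tpos + 1, tpos + 1) <- setdiff(c("A", "C", "G", "T"), told)[1]
  tprof <- profile_mutations(tmut, des5)
  expect_identical(nrow(tprof$calls), 1L)
  expect_identical(tprof$calls$region, "primer_tail")
  expect_identical(sum(tprof$units$deleterious), 0L)
  expect_identical(sum(tprof$units$tail_only), 1L)

  # a 3-nt deletion is merged into one call of that length
  del_start <- sp3$start + 4L
  dmut <- paste0(substr(expected, 1, del_start),
                 substr(expected, del_start + 4, nchar(expected)))
  dprof <- profile_mutations(dmut, des5)
  expect_identical(nrow(dprof$calls), 1L)
  expect_identical(dprof$calls$kind, "deletion")
  expect_identical(dprof$calls$length, 3L)
  expect_identical(dprof$calls$unit, 3L)
})

test_that("unalignable inserts are excluded from mutation statistics", {
  set.seed(2)
  junk <- paste(sample(c("A", "C", "G", "T"),
                       nchar(des5$expected_insert), TRUE), collapse = "")
  prof <- profile_mutations(c(des5$expected_insert, junk), des5)
  expect_identical(sum(prof$reads$alignable), 1L)
  expect_identical(nrow(prof$units), 5L)   # only the alignable insert's units
})

test_that("planted per-unit mutations are recovered exactly from clean reads", {
  p <- sim_params(n_molecules = 12, deleterious_mutation_prob = 0.12,
                  tail_mutation_prob = 0.08, seed = 19)
  sim <- simulate_molecules(des5, p)
  prof <- profile_mutations(sim$molecules$sequence, des5)
  truth <- sim$truth_mutations
  truth_del <- unique(truth[truth$region != "primer_tail",
                            c("molecule_id", "unit")])
  expect_identical(sum(prof$units$deleterious), nrow(truth_del))
  got <- prof$calls
  expect_identical(nrow(got), nrow(truth))
  got <- got[order(got$read_id, got$ref_position), ]
  expect_identical(got$unit, truth[order(truth$molecule_id,
                                         truth$ref_position), ]$unit)
})

test_that("spacer mapping recovers the planted library matrix exactly", {
  lib <- test_library_design(3, 3, seed = 31)
  p <- sim_params(n_molecules = 40, revcomp_prob = 0.5, seed = 6)
  sim <- simulate_library_molecules(lib, p)
  reads <- simulate_reads(sim, lib$fixtures, p)
  lfl <- flanking_sequences(lib, 30)
  ins <- extract_inserts(reads, lfl[["up"]], lfl[["down"]])
  m <- map_spacers(ins, lib)
  truth <- table(sim$truth_units$position, sim$truth_units$name)
  mat <- attr(m, "matrix")
  expect_identical(sum(mat[, "unassigned"]), 0L)
  for (pos in 1:3) {
    for (member in colnames(truth)) {
      expect_identical(unname(mat[pos, member]),
                       unname(as.integer(truth[pos, member])))
    }
  }
  # conservation: each position's column sums to the full-length insert count
  expect_true(all(rowSums(mat) == attr(m, "n_inserts")))
})

test_that("noisy spacers map to the nearest pool member; ties stay unassigned", {
  lib <- test_library_design(2, 2, seed = 32)
  expected <- lib$expected_insert
  reg <- lib$insert_regions
  sp1 <- reg[reg$unit == 1 & reg$region == "spacer", ]

  # two substitutions still assign to the planted member
  noisy <- expected
  for (off in c(3L, 11L)) {
    pos <- sp1$start + off
    old <- substr(noisy, pos + 1, pos + 1)
    substr(noisy, pos + 1, pos + 1) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  m <- map_spacers(noisy, lib)
  mat <- attr(m, "matrix")
  planted <- lib$pools[[1]]$name[1]
  expect_identical(unname(mat[1, planted]), 1L)

  # a window equidistant between two members is left unassigned
  a <- lib$pools[[1]]$spacer[1]
  b <- lib$pools[[1]]$spacer[2]
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  halfway <- a
  take <- diffs[seq_len(floor(length(diffs) / 2))]
  for (d in take) substr(halfway, d, d) <- substr(b, d, d)
  if (length(diffs) %% 2 == 0) {
    tie_insert <- paste0(substr(expected, 1, sp1$start),
                         halfway,
                         substr(expected, sp1$end + 1, nchar(expected)))
    mt <- map_spacers(tie_insert, lib)
    expect_identical(unname(attr(mt, "matrix")[1, "unassigned"]), 1L)
  }
})

test_that("zero-noise pipelines report perfect assemblies end to end", {
  for (k in c(1, 5)) {
    des <- test_design(k, seed = 400 + k)
    p <- sim_params(n_molecules = 6, revcomp_prob = 0.5, seed = k)
    sim <- simulate_molecules(des, p)
    reads <- simulate_reads(sim, des$fixtures, p)
    kfl <- flanking_sequences(des, 30)
    ins <- extract_inserts(reads, kfl[["up"]], kfl[["down"]])
    expect_identical(nrow(ins), 6L)
    h <- bin_by_length(ins, des)
    expect_identical(glance(h)$full_length_fraction, 1)
    prof <- profile_mutations(ins, des)
    expect_identical(nrow(prof$calls), 0L)
    m <- map_spacers(ins, des)
    mat <- attr(m, "matrix")
    expect_true(all(mat[, "unassigned"] == 0L))
    expect_true(all(diag(mat[, des5_names <- vapply(des$pools, function(q)
      q$name[1], character(1)), drop = FALSE]) == 6L))
  }
})

test_that("QC output is invariant to read strand", {
  des <- test_design(4, seed = 44)
  base <- sim_params(n_molecules = 8, junction_failure_prob = 0.15, seed = 9)
  sim <- simulate_molecules(des, base)
  kfl <- flanking_sequences(des, 30)
  fwd <- sim_params(n_molecules = 8, revcomp_prob = 0, seed = 9)
  rev <- sim_params(n_molecules = 8, revcomp_prob = 1, seed = 9)
  reads_f <- simulate_reads(sim, des$fixtures, fwd)
  reads_r <- simulate_reads(sim, des$fixtures, rev)
  ins_f <- extract_inserts(reads_f, kfl[["up"]], kfl[["down"]])
  ins_r <- extract_inserts(reads_r, kfl[["up"]], kfl[["down"]])
  expect_identical(ins_f$insert, ins_r$insert)
  expect_identical(ins_f$strand, rep("+", 8))
  expect_identical(ins_r$strand, rep("-", 8))
  h_f <- bin_by_length(ins_f, des)
  h_r <- bin_by_length(ins_r, des)
  expect_identical(as.data.frame(h_f), as.data.frame(h_r))
})
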