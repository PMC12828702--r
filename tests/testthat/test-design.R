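fx <- default_fixtures()

test_that("spacer oligo is the promoter suffix + spacer + scaffold prefix", {
  sp <- clean_spacers(1, fx, seed = 42)
  oligo <- design_spacer_oligo(unname(sp))
  expect_identical(oligo$length, 59L)
  expect_identical(nchar(oligo$sequence), 59L)
  # construction identities against the fixtures
  expect_identical(substr(oligo$sequence, 21, 40), unname(sp))
  u6 <- fx$u6_promoter
  expect_identical(oligo$up_arm, substr(u6, nchar(u6) - 19, nchar(u6)))
  expect_identical(oligo$down_arm, substr(fx$scaffold_terminator, 1, 19))
  # configurable arms change the total accordingly
  long <- design_spacer_oligo(unname(sp), up_arm_len = 25, down_arm_len = 25)
  expect_identical(long$length, 70L)
})

test_that("invalid spacers are rejected with the reason", {
  expect_error(design_spacer_oligo("ACGT"), "20 nt",
               class = "guidearray_validation_error")
  expect_error(design_spacer_oligo("ACGTACGTACGTACGTACGN"),
               class = "guidearray_validation_error")
  with_site <- paste0("AAAAA", "GGTCTC", "AAAAAAAAA")
  expect_error(design_spacer_oligo(with_site), "position 5",
               class = "guidearray_validation_error")
  # bottom-strand site is equally fatal
  with_rc <- paste0("AAAAA", "GAGACC", "AAAAAAAAA")
  expect_error(design_spacer_oligo(with_rc),
               class = "guidearray_validation_error")
  expect_error(design_spacer_oligo("ACGTACGTACGTACGTACGT", up_arm_len = 5),
               class = "guidearray_validation_error")
})

test_that("position primers chain overhangs and digest to the designed ends", {
  oh <- select_overhang_set(5)
  pr <- design_position_primers(oh, fixtures = fx)
  expect_identical(pr$left_overhang[1], unclass(oh)[1])
  expect_identical(pr$right_overhang[5], unclass(oh)[6])
  expect_identical(pr$right_overhang[-5], pr$left_overhang[-1])

  # independent digestion oracle on the position-3 PCA product
  des <- test_design(5, seed = 3)
  dig <- orc_digest(des$units$pca_product[3])
  expect_identical(dig$left, unclass(des$overhang_set)[3])
  expect_identical(dig$right, unclass(des$overhang_set)[4])
  expect_identical(dig$fragment, des$units$digested_fragment[3])
})

test_that("expected insert equals the oracle ligation of digested fragments", {
  for (k in c(1, 5, 10)) {
    des <- test_design(k, seed = k)
    frags <- vapply(des$units$pca_product, function(p) orc_digest(p)$fragment,
                    character(1))
    if (k == 1) {
      expect_identical(des$expected_insert, unname(frags[1]))
    }
    expect_identical(orc_ligate(unname(frags)), des$expected_insert)
    expect_identical(unname(des$unit_length_table[k]),
                     nchar(des$expected_insert))
  }
})

test_that("default 10-unit design sits in the ~4 kb excised-array band", {
  des <- test_design(10, seed = 10)
  expect_identical(nchar(des$units$pca_product[1]), 433L)
  expect_gte(nchar(des$expected_insert), 3900L)
  expect_lte(nchar(des$expected_insert), 4300L)
})

test_that("designs are deterministic and enzyme-safe", {
  sp <- clean_spacers(8, fx, seed = 8)
  d1 <- build_array_design(sp, fx)
  d2 <- build_array_design(sp, fx)
  expect_identical(d1, d2)
  scan <- find_recognition_sites(d1$expected_insert, fx$enzyme)
  expect_identical(nrow(scan), 0L)
})

test_that("region maps tile each unit and the whole insert", {
  des <- test_design(4, seed = 4)
  pca <- des$pca_regions[des$pca_regions$position == 2, ]
  pca <- pca[order(pca$start), ]
  expect_identical(pca$start[1], 0L)
  expect_identical(pca$end[5], nchar(des$units$pca_product[2]))
  expect_identical(pca$start[-1], pca$end[-5])
  ins <- des$insert_regions[order(des$insert_regions$start), ]
  expect_identical(ins$start[1], 0L)
  expect_identical(ins$end[nrow(ins)], nchar(des$expected_insert))
  expect_identical(ins$start[-1], ins$end[-nrow(ins)])
})

test_that("round trip: simulated error-free assembly reproduces the design", {
  for (k in c(1, 3, 7, 13, 20)) {
    des <- test_design(k, seed = 100 + k)
    sim <- simulate_molecules(des, sim_params(n_molecules = 3, seed = k))
    expect_true(all(sim$molecules$sequence == des$expected_insert))
  }
})

test_that("validate_design returns planted defects as data", {
  des <- test_design(6, seed = 6)
  expect_identical(nrow(validate_design(des)), 0L)

  # spacer carrying a recognition site slipped past validation
  sp <- clean_spacers(6, fx, seed = 66)
  sp[4] <- paste0("ACGTA", "GGTCTC", "CATGAACGT")
  bad <- build_array_design(sp, fx, check_sites = FALSE)
  v <- validate_design(bad)
  hit <- v[v$rule == "recognition_site_in_insert", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$unit, 4L)
  spacer_region <- bad$insert_regions[bad$insert_regions$unit == 4 &
                                        bad$insert_regions$region == "spacer", ]
  expect_identical(hit$position, spacer_region$start + 5L)

  # cross-complementary junction overhangs
  tampered <- test_design(8, seed = 7)
  oh <- unclass(tampered$overhang_set)
  oh[3] <- orc_revcomp(oh[8])
  attributes(oh) <- attributes(tampered$overhang_set)
  tampered$overhang_set <- oh
  v2 <- validate_design(tampered)
  expect_true("overhang_cross_complement" %in% v2$rule)
})

test_that("unit-count limits are enforced with informative refusals", {
  sp <- clean_spacers(21, fx, seed = 21)
  expect_error(build_array_design(sp, fx, max_k = 20), "max_k",
               class = "guidearray_validation_error")
  expect_warning(d21 <- build_array_design(sp, fx, max_k = 52,
                                           overhang_set = select_overhang_set(21)),
                 "reduced efficiency")
  expect_identical(d21$k, 21L)
})
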