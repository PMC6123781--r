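test_that("bridging oligo halves meet the target Tm and are minimal", {
  reg <- demo_registry(seed = 2)
  bo <- design_bridge(reg[["pSC101_trc"]], reg[["PAL"]])
  expect_gte(bo$tm_left, 70)
  expect_gte(bo$tm_right, 70)
  expect_identical(paste0(bo$left_half, bo$right_half), bo$sequence)
  expect_identical(bo$order_sequence, revcomp(bo$sequence))

  # halves align exactly to the junction-proximal part ends
  up <- reg[["pSC101_trc"]]$sequence
  dn <- reg[["PAL"]]$sequence
  expect_identical(bo$left_half,
                   substr(up, nchar(up) - nchar(bo$left_half) + 1L, nchar(up)))
  expect_identical(bo$right_half, substr(dn, 1L, nchar(bo$right_half)))

  # minimality by brute-force scan: one nt shorter drops below target
  shorter_left <- substr(up, nchar(up) - nchar(bo$left_half) + 2L, nchar(up))
  shorter_right <- substr(dn, 1L, nchar(bo$right_half) - 1L)
  if (nchar(bo$left_half) > 15) expect_lt(tm_nn(shorter_left), 70)
  if (nchar(bo$right_half) > 15) expect_lt(tm_nn(shorter_right), 70)
  # and every length below the chosen one misses the target too
  for (k in 15:(nchar(bo$left_half) - 1)) {
    expect_lt(tm_nn(substr(up, nchar(up) - k + 1L, nchar(up))), 70)
  }
})

test_that("bridge design is deterministic and errors when unreachable", {
  reg <- demo_registry(seed = 2)
  a <- design_bridge(reg[["CHS"]], reg[["CHI"]])
  b <- design_bridge(reg[["CHS"]], reg[["CHI"]])
  expect_identical(a, b)

  at_rich <- dna_part("atr", "gene", strrep("ATTA", 30))
  expect_error(design_bridge(at_rich, reg[["CHI"]]), "cannot reach Tm")
})

test_that("assembly plans cover every junction of a circular construct", {
  sp <- pinocembrin_round1_space()
  reg <- demo_registry(seed = 4)
  lib <- reduce_library(sp, 16)
  rec <- compile_construct(lib$points[[1]], reg, space = sp)
  plan <- plan_assembly(rec)
  expect_equal(length(plan), nrow(rec$features)) # one oligo per junction
  # closure junction present: last part -> first part
  juncs <- vapply(plan, function(b) paste(b$junction, collapse = "|"), character(1))
  k <- nrow(rec$features)
  expect_true(paste(rec$features$part[k], rec$features$part[1], sep = "|") %in% juncs)

  solo <- plasmid_record("solo", strrep("ACGT", 50),
                         data.frame(part = "bb", role = "backbone", strand = "+",
                                    start = 0L, end = 200L))
  expect_error(plan_assembly(solo), "junction")
})

test_that("shared junctions deduplicate in the library-level pool", {
  sp <- pinocembrin_round1_space()
  reg <- demo_registry(seed = 4)
  lib <- reduce_library(sp, 16)
  recs <- lapply(lib$points, compile_construct, registry = reg, space = sp)
  names(recs) <- vapply(lib$points, `[[`, character(1), "id")
  plans <- lapply(recs, plan_assembly)
  pool <- pool_oligos(plans)
  n_total <- sum(lengths(plans))
  expect_lt(length(pool$oligos), n_total) # some junctions recur across constructs
  expect_equal(nrow(pool$usage), n_total)
  # brute-force comparison: unique sequences == pool size
  seqs <- unlist(lapply(plans, function(pl) vapply(pl, `[[`, "", "sequence")))
  expect_equal(length(unique(seqs)), length(pool$oligos))
  # identical junction context across constructs yields the identical oligo id
  dup <- pool$usage[duplicated(pool$usage$oligo) | duplicated(pool$usage$oligo,
                                                              fromLast = TRUE), ]
  expect_gt(nrow(dup), 0)
  sheet <- oligo_order_sheet(pool)
  expect_equal(nrow(sheet), length(pool$oligos))
  expect_true(all(nchar(sheet$sequence) == sheet$length))
})
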