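`%+%` <- function(a, b) paste0(a, b)

test_that("compiled record length is the sum of its parts", {
  reg <- part_registry(list(
    dna_part("bb", "backbone", strrep("ACGT", 25)),      # 100 bp
    dna_part("g1", "gene", strrep("GATTACA", 36) %+% "AC") # 254 bp
  ))
  # minimal 1-gene template, no promoter slots
  tpl <- construct_template(list(
    list(type = "backbone", factor = "fA"),
    list(type = "gene", position = 1)
  ))
  sp <- design_space(list(new_factor("fA", "bb")),
                     gene_order_factor("g1", mode = "fixed_positions",
                                       fixed = c(g1 = 1L)),
                     template = tpl)
  p <- enumerate_designs(sp)[[1]]
  rec <- compile_construct(p, reg, tpl)
  expect_equal(nchar(rec$sequence), 100 + 254)
  expect_equal(nrow(rec$features), 2)
  expect_true(rec$circular)
})

test_that("a 'none' promoter level omits the slot and its feature", {
  sp <- pinocembrin_round1_space()
  reg <- demo_registry(seed = 7)
  pts <- enumerate_designs(sp, cap = 5000)
  # find a point with all three slots empty and one with all filled
  all_none <- Find(function(p) all(p$assignment[paste0("promoter_slot", 2:4)] == "none"),
                   pts)
  all_prom <- Find(function(p) all(p$assignment[paste0("promoter_slot", 2:4)] != "none"),
                   pts)
  rec0 <- compile_construct(all_none, reg, space = sp)
  rec3 <- compile_construct(all_prom, reg, space = sp)
  expect_equal(sum(rec0$features$role == "promoter"), 0)
  expect_equal(sum(rec3$features$role == "promoter"), 3)
  expect_equal(nrow(rec0$features), 5)  # backbone + 4 genes
  expect_equal(nrow(rec3$features), 8)
})

test_that("features tile the record and re-concatenate to the sequence", {
  sp <- pinocembrin_round1_space()
  reg <- demo_registry(seed = 3)
  lib <- reduce_library(sp, 16)
  for (p in lib$points[c(1, 7, 16)]) {
    rec <- compile_construct(p, reg, space = sp)
    f <- rec$features
    # partition of [0, L): starts/ends chain exactly
    expect_equal(f$start, c(0, f$end[-nrow(f)]))
    expect_equal(f$end[nrow(f)], nchar(rec$sequence))
    # round-trip oracle: extracting each feature and re-joining restores it
    expect_identical(paste(vapply(seq_len(nrow(f)), function(i)
      feature_sequence(rec, i), character(1)), collapse = ""), rec$sequence)
    # each gene exactly once, backbone exactly once
    expect_equal(sum(f$role == "backbone"), 1)
    expect_equal(sort(f$part[f$role == "gene"]), sort(sp$order_factor$genes))
  }
})

test_that("missing parts are reported with slot and level", {
  sp <- pinocembrin_round1_space()
  reg <- demo_registry(seed = 1)
  reg_broken <- part_registry(unclass(reg)[names(reg) != "CHS"])
  p <- reduce_library(sp, 16)$points[[1]]
  expect_error(compile_construct(p, reg_broken, space = sp), "CHS")
})

test_that("GenBank files round-trip sequence, topology and features", {
  sp <- pinocembrin_round1_space()
  reg <- demo_registry(seed = 5)
  rec <- compile_construct(reduce_library(sp, 16)$points[[2]], reg, space = sp)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, path)
  back <- read_genbank(path)
  expect_identical(back$sequence, rec$sequence)
  expect_identical(back$id, rec$id)
  expect_true(back$circular)
  expect_equal(back$features[c("part", "role", "strand", "start", "end")],
               rec$features[c("part", "role", "strand", "start", "end")])
})

test_that("GenBank handles zero features and origin-spanning joins", {
  bare <- plasmid_record(
    "bare", strrep("ACGT", 30),
    data.frame(part = character(0), role = character(0), strand = character(0),
               start = integer(0), end = integer(0)),
    circular = TRUE
  )
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(bare, path)
  back <- read_genbank(path)
  expect_identical(back$sequence, bare$sequence)
  expect_equal(nrow(back$features), 0)

  # feature wrapping the origin: 100..120 on a 120-bp circle then 0..30
  wrap <- plasmid_record(
    "wrap", strrep("ACGTGGCCAT", 12),
    data.frame(part = "x", role = "gene", strand = "+",
               start = 100L, end = 150L),
    circular = TRUE
  )
  write_genbank(wrap, path)
  expect_match(paste(readLines(path), collapse = "\n"),
               "join\\(101\\.\\.120,1\\.\\.30\\)")
  back <- read_genbank(path)
  expect_equal(back$features$start, 100L)
  expect_equal(back$features$end, 150L)
  expect_identical(feature_sequence(back, 1), feature_sequence(wrap, 1))
})

test_that("FASTA registry round-trips ids, roles and sequences", {
  reg <- demo_registry(seed = 11)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_parts_fasta(reg, path)
  back <- read_parts_fasta(path)
  expect_setequal(names(back), names(reg))
  for (id in names(reg)) {
    expect_identical(back[[id]]$sequence, reg[[id]]$sequence)
    expect_identical(back[[id]]$role, reg[[id]]$role)
  }
})

test_that("part validation rejects bad sequences and duplicate ids", {
  expect_error(dna_part("x", "gene", "ACGTN"), "A/C/G/T")
  expect_error(dna_part("x", "gene", ""), "empty")
  expect_error(part_registry(list(dna_part("a", "gene", "ACGT" ),
                                  dna_part("a", "gene", "GGCC"))),
               "duplicate")
})
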