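test_that("the GF(4) array is a strength-2 OA(16, 4^5)", {
  oa <- oa_16_4pow5()
  expect_equal(oa$runs, 16)
  expect_equal(dim(oa$matrix), c(16, 5))
  expect_true(all(oa$matrix %in% 0:3))

  # exhaustive pair counting: every ordered level pair exactly once
  for (i in 1:4) {
    for (j in (i + 1):5) {
      pairs <- paste(oa$matrix[, i], oa$matrix[, j])
      expect_equal(sort(pairs),
                   sort(paste(rep(0:3, each = 4), rep(0:3, times = 4))))
    }
  }
  expect_true(oa_strength2_ok(oa))

  # balance: restricting any column to one level keeps 4 runs
  for (j in 1:5) {
    expect_equal(as.vector(table(oa$matrix[, j])), rep(4L, 4))
  }
})

test_that("level collapsing maps a balanced 4-level column to 8/4/4", {
  oa <- oa_16_4pow5()
  lab <- collapse_levels(oa, 2, c("none", "none", "P_lacUV5", "P_trc"))
  expect_equal(as.vector(table(lab)[c("none", "P_lacUV5", "P_trc")]),
               c(8L, 4L, 4L))

  ident <- collapse_levels(oa, 3, c("0", "1", "2", "3"))
  expect_equal(as.integer(ident), oa$matrix[, 3])

  expect_error(collapse_levels(oa, 1, c(`0` = "a", `1` = "b", `2` = "c")),
               "missing level")
})

test_that("cyclic Latin squares are Latin and give balanced orderings", {
  ls4 <- latin_square(4)
  sym <- 0:3
  for (i in 1:4) {
    expect_equal(sort(ls4$grid[i, ]), sym)
    expect_equal(sort(ls4$grid[, i]), sym)
  }
  # n=1: the single trivial ordering
  expect_equal(latin_square(1)$grid, matrix(0L, 1, 1))
  # rows of order 3 are pairwise distinct permutations
  ls3 <- latin_square(3)
  rows <- apply(ls3$grid, 1, paste, collapse = ",")
  expect_equal(anyDuplicated(rows), 0L)
  expect_error(latin_square(0), "positive")
})

test_that("reduce_library yields 16 constructs at exact compression 162:1", {
  sp <- pinocembrin_round1_space()
  lib <- reduce_library(sp, 16)
  expect_equal(length(lib$points), 16)
  expect_equal(unname(lib$compression_ratio), c(162, 1))
  # exact rational identity: ratio x points == full space
  expect_equal(lib$compression_ratio[["numerator"]] * length(lib$points) /
                 lib$compression_ratio[["denominator"]],
               count_designs(sp))

  # no duplicate constructs
  ids <- vapply(lib$points, `[[`, character(1), "id")
  expect_equal(anyDuplicated(ids), 0L)

  # membership: every point's levels are in the space's domains and its
  # ordering is a permutation of the genes
  for (p in lib$points) {
    for (f in sp$factors) {
      expect_true(p$assignment[[f$name]] %in% f$levels)
    }
    expect_setequal(p$ordering, sp$order_factor$genes)
  }

  # deterministic: identical ID sequence on re-run
  expect_identical(ids, vapply(reduce_library(sp, 16)$points, `[[`,
                               character(1), "id"))
})

test_that("reduced library balances factors and gene positions", {
  sp <- pinocembrin_round1_space()
  lib <- reduce_library(sp, 16)
  df <- as.data.frame(lib)
  expect_equal(as.vector(table(df$backbone)), rep(4L, 4))
  for (s in paste0("promoter_slot", 2:4)) {
    tab <- table(df[[s]])
    expect_equal(as.vector(tab[c("none", "P_lacUV5", "P_trc")]), c(8L, 4L, 4L))
  }
  # Latin-square positional balance: each gene at each position 4 times
  ords <- strsplit(df$gene_order, ">", fixed = TRUE)
  for (g in sp$order_factor$genes) {
    pos <- vapply(ords, function(o) match(g, o), integer(1))
    expect_equal(as.vector(table(pos)), rep(4L, 4))
  }
})

test_that("reduce_library rejects incompatible factor structures by name", {
  sp <- chassis_crossed_space(pinocembrin_round1_space())
  expect_error(reduce_library(sp, 16), "chassis")
  expect_error(reduce_library(pinocembrin_round1_space(), 8), "16")
})

test_that("a space already at the run count reduces to its full factorial", {
  # 4 x 4 with a fixed ordering: exactly 16 designs
  sp <- design_space(
    list(new_factor("f1", paste0("a", 1:4)), new_factor("f2", paste0("b", 1:4))),
    gene_order_factor("g", mode = "fixed_positions", fixed = c(g = 1L))
  )
  lib <- reduce_library(sp, 16)
  expect_equal(length(lib$points), 16)
  expect_equal(unname(lib$compression_ratio), c(1, 1))
  got <- sort(vapply(lib$points, `[[`, character(1), "id"))
  full <- sort(vapply(enumerate_designs(sp), `[[`, character(1), "id"))
  expect_identical(got, full)
})

test_that("regular fractional factorials have the textbook structure", {
  # 2^(3-1) with C = AB: 4 runs, resolution III
  d <- fractional_factorial(3, "C=AB")
  expect_equal(d$runs, 4)
  expect_equal(d$resolution, 3)
  expect_equal(d$matrix[, "C"], d$matrix[, "A"] * d$matrix[, "B"])

  # p = 0: full factorial
  full <- fractional_factorial(3)
  expect_equal(full$runs, 8)
  expect_true(is.infinite(full$resolution))

  # 2^(4-1) with D = ABC: 8 runs, every main effect estimable
  d4 <- fractional_factorial(4, "D=ABC")
  expect_equal(d4$runs, 8)
  expect_equal(d4$resolution, 4)
  # brute-force alias check: no main-effect column equals (+/-) another,
  # none is constant
  m <- d4$matrix
  for (a in colnames(m)) {
    expect_gt(length(unique(m[, a])), 1)
    for (b in setdiff(colnames(m), a)) {
      expect_false(all(m[, a] == m[, b]) || all(m[, a] == -m[, b]))
    }
    # the alias of each main effect is a 3-factor interaction, not a main
    expect_true(all(nchar(alias_of(d4, a)) == 3))
  }

  expect_error(fractional_factorial(3, "B=A"), "distinct")
  # ABC x ABCD leaves the bare word D: a main effect aliased with I
  expect_error(fractional_factorial(4, c("C=AB", "D=ABC")), "identity")
})

test_that("strategy choice is full factorial iff the space fits the build cap", {
  sp <- pinocembrin_round1_space()
  expect_equal(choose_strategy(sp, 16), "orthogonal_array")
  sp36 <- apply_constraints(sp, pinocembrin_round2_rules(sp))
  expect_equal(choose_strategy(sp36, 48), "full_factorial")
  expect_equal(choose_strategy(sp36, 36), "full_factorial") # boundary inclusive
  expect_equal(choose_strategy(sp36, 35), "orthogonal_array")
})
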