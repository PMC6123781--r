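test_that("design counts multiply factor levels and orderings", {
  sp <- pinocembrin_round1_space()
  expect_equal(count_designs(sp), 4 * 3 * 3 * 3 * 24)
  expect_equal(count_designs(sp), 2592)

  # identity case: one allowed level everywhere, fixed ordering
  sp1 <- design_space(
    list(new_factor("f", "only")),
    gene_order_factor(c("g1", "g2"), mode = "fixed_positions",
                      fixed = c(g1 = 1L, g2 = 2L))
  )
  expect_equal(count_designs(sp1), 1)

  # the round-2 structure: 2 x 3 x 3 x 2 with one admissible ordering axis
  sp2 <- apply_constraints(pinocembrin_round1_space(),
                           pinocembrin_round2_rules(pinocembrin_round1_space()))
  expect_equal(count_designs(sp2), 36)

  expect_error(
    design_space(list(new_factor("f", character(0))),
                 gene_order_factor("g", mode = "fixed_positions",
                                   fixed = c(g = 1L))),
    "levels"
  )
})

test_that("gene-order factor counts and enumerates correctly", {
  of <- gene_order_factor(c("PAL", "4CL", "CHS", "CHI"))
  expect_equal(n_orderings(of), 24)
  expect_equal(length(orderings(of)), 24)
  expect_equal(anyDuplicated(vapply(orderings(of), paste, "", collapse = ">")), 0L)

  ls_of <- gene_order_factor(c("PAL", "4CL", "CHS", "CHI"), mode = "latin_square")
  expect_equal(n_orderings(ls_of), 4)
  # positional balance: every gene in every position exactly once
  pos <- sapply(orderings(ls_of), function(o) o)
  for (g in ls_of$genes) {
    expect_equal(sort(apply(pos == g, 2, which)), 1:4)
  }

  fixed <- gene_order_factor(c("a", "b", "c"), fixed = c(a = 1L))
  expect_equal(n_orderings(fixed), 2)
  expect_true(all(vapply(orderings(fixed), function(o) o[1] == "a", logical(1))))
})

test_that("enumeration matches the count, is unique and order-stable", {
  sp <- tiny_space()
  pts <- enumerate_designs(sp)
  expect_equal(length(pts), count_designs(sp))
  ids <- vapply(pts, `[[`, character(1), "id")
  expect_equal(anyDuplicated(ids), 0L)
  # bit-identical ID sequence across runs
  expect_identical(ids, vapply(enumerate_designs(sp), `[[`, character(1), "id"))

  # oracle equivalence on the full round-1 space
  sp_full <- pinocembrin_round1_space()
  pts_full <- enumerate_designs(sp_full)
  expect_equal(length(pts_full), 2592)
  expect_equal(anyDuplicated(vapply(pts_full, `[[`, character(1), "id")), 0L)

  # a 2-level single factor with fixed ordering yields exactly 2 points
  sp2 <- design_space(list(new_factor("f", c("x", "y"))),
                      gene_order_factor("g", mode = "fixed_positions",
                                        fixed = c(g = 1L)))
  expect_equal(length(enumerate_designs(sp2)), 2)

  expect_error(enumerate_designs(sp_full, cap = 100), "reduce")
})

test_that("vectorized enumeration IDs equal the scalar hash", {
  sp <- tiny_space()
  for (p in enumerate_designs(sp)) {
    expect_identical(design_point(p$assignment, p$ordering, sp)$id, p$id)
  }
})

test_that("apply_constraints equals the brute-force membership filter", {
  sp <- tiny_space(n_genes = 3)

  cs <- constraint_set(fixed_levels = list(fB = "b2"))
  restricted <- apply_constraints(sp, cs)
  expect_equal(count_designs(restricted), count_designs(sp) / 3)
  oracle_ids <- sort(vapply(brute_filter(sp, cs), `[[`, character(1), "id"))
  got_ids <- sort(vapply(enumerate_designs(restricted), `[[`, character(1), "id"))
  expect_identical(got_ids, oracle_ids)

  cs2 <- constraint_set(allowed_levels = list(fB = c("b1", "b3")),
                        fixed_positions = c(g2 = 1L))
  restricted2 <- apply_constraints(sp, cs2)
  oracle2 <- sort(vapply(brute_filter(sp, cs2), `[[`, character(1), "id"))
  got2 <- sort(vapply(enumerate_designs(restricted2), `[[`, character(1), "id"))
  expect_identical(got2, oracle2)
})

test_that("empty constraints leave the space unchanged; original unmodified", {
  sp <- pinocembrin_round1_space()
  out <- apply_constraints(sp, constraint_set())
  expect_equal(count_designs(out), count_designs(sp))
  apply_constraints(sp, pinocembrin_round2_rules(sp))
  expect_equal(count_designs(sp), 2592) # input untouched
})

test_that("apply_constraints is idempotent and commutes on disjoint constraints", {
  sp <- tiny_space(n_genes = 3)
  cs <- constraint_set(fixed_levels = list(fA = "a2"),
                       fixed_positions = c(g1 = 3L))
  once <- apply_constraints(sp, cs)
  twice <- apply_constraints(once, cs)
  expect_equal(count_designs(once), count_designs(twice))
  expect_identical(sort(vapply(enumerate_designs(once), `[[`, "", "id")),
                   sort(vapply(enumerate_designs(twice), `[[`, "", "id")))

  a <- constraint_set(fixed_levels = list(fA = "a1"))
  b <- constraint_set(allowed_levels = list(fB = c("b1", "b2")))
  ab <- apply_constraints(apply_constraints(sp, a), b)
  ba <- apply_constraints(apply_constraints(sp, b), a)
  expect_identical(sort(vapply(enumerate_designs(ab), `[[`, "", "id")),
                   sort(vapply(enumerate_designs(ba), `[[`, "", "id")))
})

test_that("contradictory or out-of-domain constraints error explicitly", {
  sp <- tiny_space()
  expect_error(apply_constraints(sp, constraint_set(fixed_levels = list(zz = "a"))),
               "unknown factor")
  expect_error(apply_constraints(sp, constraint_set(fixed_levels = list(fA = "nope"))),
               "not in domain")
  expect_error(
    apply_constraints(sp, constraint_set(
      fixed_levels = list(fA = "a1"),
      allowed_levels = list(fA = "a2")
    )),
    "contradictory"
  )
  expect_error(
    apply_constraints(sp, constraint_set(fixed_positions = c(g1 = 1L, g2 = 1L))),
    "contradictory"
  )
})

test_that("design points validate membership in their space", {
  sp <- tiny_space()
  expect_error(design_point(c(fA = "a1", fB = "nope"), c("g1", "g2"), sp),
               "not in domain")
  expect_error(design_point(c(fA = "a1", fB = "b1"), c("g1", "g1"), sp),
               "permutation")
  p <- design_point(c(fA = "a1", fB = "b1"), c("g2", "g1"), sp)
  expect_match(p$id, "^D[0-9a-f]{8}$")
})
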