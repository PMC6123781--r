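# Shared in-code fixtures: tiny spaces and registries built fresh per use.

tiny_space <- function(n_genes = 2, levels_a = c("a1", "a2"),
                       levels_b = c("b1", "b2", "b3")) {
  genes <- paste0("g", seq_len(n_genes))
  design_space(
    list(new_factor("fA", levels_a), new_factor("fB", levels_b)),
    gene_order_factor(genes),
    template = NULL
  )
}

# brute-force membership filter: the independent oracle for apply_constraints
brute_filter <- function(space, constraints) {
  pts <- enumerate_designs(space, cap = 1e5)
  keep <- vapply(pts, function(p) {
    ok <- TRUE
    for (f in names(constraints$fixed_levels)) {
      ok <- ok && identical(unname(p$assignment[[f]]),
                            as.character(constraints$fixed_levels[[f]]))
    }
    for (f in names(constraints$allowed_levels)) {
      ok <- ok && p$assignment[[f]] %in% constraints$allowed_levels[[f]]
    }
    fp <- constraints$fixed_positions
    if (length(fp)) ok <- ok && all(p$ordering[fp] == names(fp))
    ok
  }, logical(1))
  pts[keep]
}

two_test_parts <- function() {
  part_registry(list(
    dna_part("up", "gene", paste(rep("ACGT", 25), collapse = "")),
    dna_part("down", "gene", paste(rep("GGCCAATT", 20), collapse = ""))
  ))
}
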