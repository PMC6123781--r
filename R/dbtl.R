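# End-to-end seeded DBTL demonstration: design -> reduce -> build -> test
# (simulated) -> learn -> constrain -> redesign, entirely in software.

#' Synthetic part registry for the pinocembrin example space
#'
#' Random-sequence stand-ins (see [random_parts()]) for the four composite
#' backbones, two promoters and four pathway genes of the round-1
#' pinocembrin space; sequence content is synthetic, only ids and roles
#' mirror the real parts. GC content is 0.62, emulating the GC-rich coding
#' sequences of the real pathway (the 4CL gene comes from the high-GC
#' actinomycete Streptomyces coelicolor) and keeping every part end able
#' to reach the 70 degC bridging-oligo target within the 60-nt synthesis
#' bound (\code{lcr_ready}).
#'
#' @param seed Integer seed.
#' @return A [part_registry()].
#' @export
demo_registry <- function(seed = 1L) {
  random_parts(
    ids = c("pSC101_lacUV5", "pSC101_trc", "p15a_lacUV5", "p15a_trc",
            "P_lacUV5", "P_trc",
            "PAL", "4CL", "CHS", "CHI"),
    lengths = c(rep(600L, 4), rep(100L, 2), rep(300L, 4)),
    gc = 0.62, seed = seed,
    roles = c(rep("backbone", 4), rep("promoter", 2), rep("gene", 4))
  )
}

#' Default planted ground truth for the demo
#'
#' Effect pattern mirroring the worked example's first learning round:
#' copy number the strongest positive ordinal effect (1.0 log10 between
#' extremes), the CHI promoter the strongest categorical effect, 4CL and
#' CHS promoters intermediate, the PAL promoter weakest; gene order null.
#'
#' @param sd Log10 noise standard deviation (default 0.3).
#' @param n_replicates Replicates per construct (default 3).
#' @param seed Integer seed.
#' @return A [ground_truth()].
#' @export
demo_truth <- function(sd = 0.3, n_replicates = 3, seed = 1L) {
  ground_truth(
    effects = list(
      copy_number = c("1" = -0.5, "2" = 0.5),
      promoter_CHI = c(none = -0.4, weak = 0.1, strong = 0.3),
      promoter_CHS = c(none = -0.2, weak = 0.05, strong = 0.15),
      promoter_4CL = c(none = -0.2, weak = 0.05, strong = 0.15),
      promoter_PAL = c(none = -0.1, weak = 0, strong = 0.1)
    ),
    baseline = -1.5, sd = sd, n_replicates = n_replicates, seed = seed
  )
}

#' Run one full simulated DBTL cycle
#'
#' Round 1: the 2592-point pinocembrin space is reduced to a 16-construct
#' orthogonal-array library, simulated titers are fitted, and the learned
#' rules are propagated into constraints. Round 2: the constrained space
#' (36 designs) is built as a full factorial and simulated. Assembly plans
#' and robotics worklists for the round-1 library are included; all
#' randomness flows from \code{seed}, so two runs with the same seed are
#' byte-identical.
#'
#' @param seed Integer seed driving parts, titer noise and worklists.
#' @param sd,n_replicates Passed to [demo_truth()].
#' @return List with the spaces, libraries, measurements, effect table,
#'   constraint set, assembly plans and worklists of both rounds.
#' @export
run_dbtl_demo <- function(seed = 1L, sd = 0.3, n_replicates = 3) {
  seed <- as.integer(seed)
  registry <- demo_registry(seed)
  space <- pinocembrin_round1_space()

  # Design + Build (round 1)
  lib1 <- reduce_library(space, 16)
  records1 <- lapply(lib1$points, compile_construct, registry = registry,
                     template = space$template)
  names(records1) <- vapply(lib1$points, `[[`, character(1), "id")
  plans1 <- lapply(records1, plan_assembly)
  worklists1 <- generate_worklists(plans1, seed = seed + 1L)

  # Test (simulated) + Learn
  truth <- demo_truth(sd = sd, n_replicates = n_replicates, seed = seed + 2L)
  design1 <- gene_design(lib1, space)
  meas1 <- simulate_titers(design1, truth,
                           intermediate = list(gene = "PAL", mean = 1, sd = 0.2))
  et1 <- fit_effects(design1, meas1)
  nl <- flag_non_limiting(meas1, "PAL", threshold = 0.5)
  rules <- propagate_rules(et1, space, rule_policy(), non_limiting = nl)

  # Redesign + Test (round 2)
  space2 <- apply_constraints(space, rules)
  strategy <- choose_strategy(space2, max_build = 48)
  lib2 <- if (strategy == "full_factorial") full_factorial_library(space2)
          else reduce_library(space2, 16)
  truth2 <- truth
  truth2$seed <- seed + 3L
  design2 <- gene_design(lib2, space2)
  meas2 <- simulate_titers(design2, truth2)

  list(space = space, registry = registry, library1 = lib1,
       records1 = records1, plans1 = plans1, worklists1 = worklists1,
       truth = truth, measurements1 = meas1, effects1 = et1,
       non_limiting = nl, rules = rules, space2 = space2,
       strategy2 = strategy, library2 = lib2, measurements2 = meas2)
}

#' Best per-construct median titer of a measurement table
#'
#' @param measurements data.frame with \code{construct} and \code{titer}.
#' @return The largest per-construct median titer.
#' @export
best_median_titer <- function(measurements) {
  max(tapply(measurements$titer, measurements$construct, stats::median))
}
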