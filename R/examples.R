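# Worked design spaces for the two pathways the package ships as examples:
# the four-enzyme flavonoid (pinocembrin) pathway and the four-enzyme
# benzylisoquinoline alkaloid (reticuline/scoulerine) pathway, both
# expressed from a single plasmid in E. coli.

#' @noRd
promoter_slot_factor <- function(position, weak = "P_lacUV5", strong = "P_trc") {
  lv <- c("none", weak, strong)
  strength <- c("none", "weak", "strong")
  names(strength) <- lv
  new_factor(paste0("promoter_slot", position), lv,
             kind = "categorical", attrs = list(strength = strength))
}

#' @noRd
backbone_composite_factor <- function(origins, origin_ranks,
                                      weak = "P_lacUV5", strong = "P_trc") {
  lv <- as.vector(t(outer(origins, c(weak, strong), paste, sep = "_")))
  lv <- sub("P_", "", lv, fixed = TRUE) # e.g. pSC101_lacUV5
  copy_rank <- rep(origin_ranks, each = 2)
  promoter <- rep(c("weak", "strong"), times = length(origins))
  names(copy_rank) <- names(promoter) <- lv
  origin <- rep(origins, each = 2)
  names(origin) <- lv
  new_factor("backbone", lv, kind = "categorical",
             attrs = list(copy_rank = copy_rank, promoter = promoter,
                          origin = origin))
}

#' Round-1 pinocembrin pathway design space
#'
#' Four enzymes (PAL, 4CL, CHS, CHI) convert L-phenylalanine to
#' (2S)-pinocembrin. The round-1 library varies: the vector backbone as a
#' single composite 4-level factor (pSC101 or p15a origin crossed with a
#' weak P_lacUV5 or strong P_trc vector promoter — four levels of
#' expression by backbone selection, with copy number the ordinal
#' component); a 3-level promoter slot (none / weak / strong) in each of
#' the three intergenic regions; and the position of each gene (24
#' permutations). Total: 4 x 3 x 3 x 3 x 24 = 2592 configurations.
#'
#' @return A [design_space()] with the operon construct template attached.
#' @examples
#' count_designs(pinocembrin_round1_space()) # 2592
#' @export
pinocembrin_round1_space <- function() {
  genes <- c("PAL", "4CL", "CHS", "CHI")
  factors <- c(
    list(backbone_composite_factor(c("pSC101", "p15a"), origin_ranks = c(1, 2))),
    lapply(2:4, promoter_slot_factor)
  )
  design_space(factors, gene_order_factor(genes),
               template = operon_template(genes))
}

#' Round-1 alkaloid pathway design space
#'
#' Four enzymes (6OMT, CNMT, 4OMT, BBE) convert (S)-tetrahydropapaveroline
#' to (S)-reticuline and on to (S)-scoulerine. Identical slot structure to
#' the pinocembrin space — composite backbone (pBBR1 or ColE1 origin x
#' weak/strong promoter), three 3-level intergenic promoter slots, 24 gene
#' permutations — so it too enumerates 2592 configurations and reduces to a
#' 16-run orthogonal-array library.
#'
#' @return A [design_space()].
#' @examples
#' count_designs(alkaloid_space()) # 2592
#' @export
alkaloid_space <- function() {
  genes <- c("6OMT", "CNMT", "4OMT", "BBE")
  factors <- c(
    list(backbone_composite_factor(c("pBBR1", "ColE1"), origin_ranks = c(1, 2))),
    lapply(2:4, promoter_slot_factor)
  )
  design_space(factors, gene_order_factor(genes),
               template = operon_template(genes))
}

#' Cross a design space with a chassis-strain factor
#'
#' Screening a pathway library across host strains multiplies the design
#' space by the number of chassis: the round-1 pinocembrin space crossed
#' with nine E. coli strains spans 2592 x 9 = 23,328 possible designs.
#'
#' @param space A [design_space()].
#' @param strains Character vector of strain names (default: the nine
#'   K-12-, B- and W-derivative strains screened in the worked example).
#' @return A new [design_space()] with an added categorical \code{chassis}
#'   factor. The construct template is unchanged (the chassis is not a
#'   plasmid part).
#' @examples
#' count_designs(chassis_crossed_space(pinocembrin_round1_space())) # 23328
#' @export
chassis_crossed_space <- function(space,
                                  strains = c("DH5alpha", "MG1655", "MDS42",
                                              "BW25113", "W3110", "MC1061",
                                              "BL21", "W", "NEB5alpha")) {
  stopifnot(inherits(space, "design_space"))
  design_space(c(space$factors, list(new_factor("chassis", strains))),
               space$order_factor, template = space$template)
}

#' Round-2 design rules for the pinocembrin pathway, as a constraint set
#'
#' Encodes the four learned rules of the second design round directly:
#' (a) fix the backbone at its high-copy level (the ordinal copy-number
#' factor had the strongest positive effect); (b) pin CHI — whose promoter
#' had the strongest categorical effect — at position 1 so it is always
#' directly downstream of the vector promoter; (c) leave 4CL and CHS free
#' to exchange the two middle positions with the full none/weak/strong
#' promoter menu in front of each; (d) pin PAL, flagged non-limiting by the
#' accumulated upstream intermediate (cinnamic acid), at the last position,
#' and restrict its promoter slot to a reduced 2-level menu. The
#' constrained space is the 2 x 3 x 3 x 2 = 36-construct full factorial.
#'
#' @param space The round-1 space (used to resolve factor and level names).
#' @param backbone_level Level rule (a) fixes; default the high-copy,
#'   strong-promoter backbone.
#' @param last_slot_menu The 2-level promoter menu of rule (d)'s slot.
#' @return A [constraint_set()].
#' @examples
#' sp <- pinocembrin_round1_space()
#' count_designs(apply_constraints(sp, pinocembrin_round2_rules(sp))) # 36
#' @export
pinocembrin_round2_rules <- function(space,
                                     backbone_level = "p15a_trc",
                                     last_slot_menu = c("none", "P_trc")) {
  stopifnot(inherits(space, "design_space"))
  n <- length(space$order_factor$genes)
  constraint_set(
    fixed_levels = list(backbone = backbone_level),
    fixed_positions = c(CHI = 1L, PAL = n),
    allowed_levels = stats::setNames(list(last_slot_menu),
                                     paste0("promoter_slot", n))
  )
}
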