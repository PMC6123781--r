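# Structured-configuration (YAML) interface: design templates in, learned
# constraint sets out, in one dialect shared across DBTL rounds.

#' @noRd
as_named_vector <- function(x) {
  if (is.null(x)) return(NULL)
  stats::setNames(unlist(x, use.names = FALSE), names(x))
}

#' Read a design space from a YAML configuration file
#'
#' Expected layout:
#' \preformatted{
#' design_space:
#'   factors:
#'     - name: backbone
#'       kind: categorical        # or ordinal (+ optional ranks map)
#'       levels: [pSC101_lacUV5, pSC101_trc, p15a_lacUV5, p15a_trc]
#'       attrs: {copy_rank: {...}, promoter: {...}}
#'     - name: promoter_slot2
#'       levels: [none, P_lacUV5, P_trc]
#'       attrs: {strength: {none: none, P_lacUV5: weak, P_trc: strong}}
#'   gene_order:
#'     genes: [PAL, 4CL, CHS, CHI]
#'     mode: all_permutations     # or latin_square / fixed_positions
#'   template:
#'     backbone_factor: backbone
#' }
#' Factor levels reference part ids in the part registry.
#'
#' @param path YAML file path.
#' @return A [design_space()].
#' @export
read_design_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ds <- cfg$design_space
  if (is.null(ds)) stop("config has no 'design_space' section")
  if (is.null(ds$factors) || !length(ds$factors)) {
    stop("design_space needs at least one factor")
  }
  factors <- lapply(ds$factors, function(f) {
    new_factor(f$name, unlist(f$levels),
               kind = f$kind %||% "categorical",
               ranks = as_named_vector(f$ranks),
               attrs = lapply(f$attrs %||% list(), as_named_vector))
  })
  go <- ds$gene_order
  if (is.null(go)) stop("design_space needs a 'gene_order' section")
  fixed <- as_named_vector(go$fixed)
  order_factor <- gene_order_factor(unlist(go$genes),
                                    mode = go$mode %||% "all_permutations",
                                    fixed = fixed)
  template <- if (!is.null(ds$template)) {
    operon_template(unlist(go$genes),
                    backbone_factor = ds$template$backbone_factor %||% "backbone",
                    terminator = ds$template$terminator)
  }
  design_space(factors, order_factor, template = template)
}

#' Read a constraint set from a YAML configuration file
#'
#' @param path YAML file with a \code{constraints} section holding
#'   \code{fixed_levels}, \code{fixed_positions}, \code{allowed_levels}
#'   and/or \code{allowed_orderings}.
#' @return A [constraint_set()].
#' @export
read_constraints <- function(path) {
  cfg <- yaml::read_yaml(path)
  cs <- cfg$constraints
  if (is.null(cs)) stop("config has no 'constraints' section")
  constraint_set(
    fixed_levels = cs$fixed_levels %||% list(),
    fixed_positions = as_named_vector(cs$fixed_positions) %||% integer(0),
    allowed_levels = lapply(cs$allowed_levels %||% list(), unlist),
    allowed_orderings = cs$allowed_orderings
  )
}

#' Write a constraint set to YAML
#'
#' Serializes to the same dialect [read_constraints()] reads, so the Learn
#' stage's output feeds the next round's Design stage directly.
#'
#' @param constraints A [constraint_set()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_constraints <- function(constraints, path) {
  stopifnot(inherits(constraints, "constraint_set"))
  out <- list(constraints = list())
  if (length(constraints$fixed_levels)) {
    out$constraints$fixed_levels <- constraints$fixed_levels
  }
  if (length(constraints$fixed_positions)) {
    out$constraints$fixed_positions <- as.list(constraints$fixed_positions)
  }
  if (length(constraints$allowed_levels)) {
    out$constraints$allowed_levels <- lapply(constraints$allowed_levels, as.list)
  }
  if (!is.null(constraints$allowed_orderings)) {
    out$constraints$allowed_orderings <- lapply(constraints$allowed_orderings,
                                                as.list)
  }
  if (!length(out$constraints)) out$constraints <- list()
  yaml::write_yaml(out, path)
  invisible(path)
}
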