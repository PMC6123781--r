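#' Define a combinatorial pathway design space
#'
#' A design space is the cross product of a set of design factors (vector
#' backbone, intergenic promoter slots, chassis, ...) with a gene-order
#' factor, together with a construct template saying how a design point is
#' laid out as a plasmid. Its cardinality is
#' \code{prod(levels per factor) * n_orderings}.
#'
#' @param factors List of [new_factor()] objects (order = declaration order,
#'   which fixes enumeration order).
#' @param order_factor A [gene_order_factor()].
#' @param template Optional [construct_template()] mapping slots to factors;
#'   required by [compile_construct()] but not by counting/enumeration.
#' @return An object of class \code{design_space}.
#' @examples
#' sp <- pinocembrin_round1_space()
#' count_designs(sp) # 2592
#' @export
design_space <- function(factors, order_factor, template = NULL) {
  if (inherits(factors, "design_factor")) factors <- list(factors)
  if (!length(factors) || !all(vapply(factors, inherits, logical(1), "design_factor"))) {
    stop("'factors' must be a non-empty list of design_factor objects")
  }
  nm <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate factor names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  names(factors) <- nm
  stopifnot(inherits(order_factor, "gene_order_factor"))
  if (!is.null(template)) {
    stopifnot(inherits(template, "construct_template"))
    ref <- template_factor_refs(template)
    missing <- setdiff(ref, nm)
    if (length(missing)) {
      stop("template references unknown factor(s): ", paste(missing, collapse = ", "))
    }
  }
  structure(
    list(factors = factors, order_factor = order_factor, template = template),
    class = "design_space"
  )
}

#' @export
print.design_space <- function(x, ...) {
  cat(sprintf("<design_space> %d factor(s) x %d ordering(s) = %s designs\n",
              length(x$factors), n_orderings(x$order_factor),
              format(count_designs(x), big.mark = ",")))
  for (f in x$factors) {
    cat(sprintf("  %-16s %s [%s]\n", f$name,
                paste(f$levels, collapse = "/"), f$kind))
  }
  cat(sprintf("  genes: %s (mode %s)\n",
              paste(x$order_factor$genes, collapse = " "), x$order_factor$mode))
  invisible(x)
}

#' Count the designs in a space
#'
#' Product of per-factor level counts times the number of admissible gene
#' orderings; never materializes design points.
#'
#' @param space A [design_space()].
#' @return A single non-negative number.
#' @examples
#' count_designs(pinocembrin_round1_space()) # 4 * 3 * 3 * 3 * 24 = 2592
#' @export
count_designs <- function(space) {
  stopifnot(inherits(space, "design_space"))
  sizes <- vapply(space$factors, function(f) length(f$levels), numeric(1))
  if (any(sizes == 0)) stop("degenerate design space: factor with no levels")
  prod(sizes) * n_orderings(space$order_factor)
}

# Canonical serialization of one assignment+ordering; the construct ID is
# its FNV-1a hash, so IDs are stable across runs and enumeration order.
#' @noRd
design_point_id <- function(assignment, ordering) {
  key <- paste(
    paste(names(assignment), unlist(assignment), sep = "=", collapse = ";"),
    paste(ordering, collapse = ">"),
    sep = "|"
  )
  paste0("D", fnv1a32_hex(key))
}

#' Construct a single design point
#'
#' @param assignment Named character vector/list, factor name -> level label.
#' @param ordering Character vector: gene occupying each position.
#' @param space Optional space for validation (assignment levels in domain,
#'   ordering a permutation of the space's genes).
#' @return An object of class \code{design_point} with a deterministic
#'   hash-derived \code{id}.
#' @export
design_point <- function(assignment, ordering, space = NULL) {
  assignment <- vapply(assignment, as.character, character(1))
  ordering <- as.character(ordering)
  if (!is.null(space)) {
    stopifnot(inherits(space, "design_space"))
    if (!setequal(names(assignment), names(space$factors))) {
      stop("assignment must cover exactly the space's factors")
    }
    for (f in space$factors) {
      if (!assignment[[f$name]] %in% f$levels) {
        stop("level '", assignment[[f$name]], "' not in domain of factor '",
             f$name, "'")
      }
    }
    if (!setequal(ordering, space$order_factor$genes) ||
        length(ordering) != length(space$order_factor$genes)) {
      stop("ordering must be a permutation of the space's genes")
    }
  }
  structure(
    list(id = design_point_id(assignment, ordering),
         assignment = assignment, ordering = ordering),
    class = "design_point"
  )
}

#' @export
print.design_point <- function(x, ...) {
  cat(sprintf("<design_point> %s\n  %s\n  order: %s\n", x$id,
              paste(names(x$assignment), x$assignment, sep = "=", collapse = " "),
              paste(x$ordering, collapse = " > ")))
  invisible(x)
}

#' Enumerate every design point of a space
#'
#' Deterministic lexicographic enumeration keyed on factor declaration order
#' (later factors vary fastest) and then ordering index, so repeated runs
#' yield bit-identical ID sequences.
#'
#' @param space A [design_space()].
#' @param cap Refuse to materialize more than this many points (default
#'   1e6); exceeding it is the signal to use a designed reduction
#'   ([reduce_library()]) instead.
#' @return A list of [design_point()] objects, each exactly once.
#' @export
enumerate_designs <- function(space, cap = 1e6) {
  stopifnot(inherits(space, "design_space"))
  n <- count_designs(space)
  if (n > cap) {
    stop("design space has ", format(n, big.mark = ","), " points, above the cap of ",
         format(cap, big.mark = ","),
         "; reduce it with a designed library (see reduce_library) or raise 'cap'")
  }
  ords <- orderings(space$order_factor)
  level_sets <- lapply(space$factors, `[[`, "levels")
  # grid with the *last* axis varying fastest => lexicographic in
  # (factor1, ..., factork, ordering)
  axes <- c(level_sets, list(.ordering = seq_along(ords)))
  grid <- rev(expand.grid(rev(axes), stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE))
  fac_names <- names(space$factors)

  # vectorized construction of the canonical keys (same serialization as
  # design_point_id) and their hashes
  assign_str <- do.call(paste, c(lapply(fac_names, function(f) {
    paste0(f, "=", grid[[f]])
  }), sep = ";"))
  ord_str <- vapply(ords, paste, character(1), collapse = ">")
  ids <- paste0("D", fnv1a32_hex(paste(assign_str, ord_str[grid$.ordering],
                                       sep = "|")))
  m <- as.matrix(grid[fac_names])
  lapply(seq_len(nrow(grid)), function(i) {
    structure(
      list(id = ids[i],
           assignment = stats::setNames(m[i, ], fac_names),
           ordering = ords[[grid$.ordering[i]]]),
      class = "design_point"
    )
  })
}

#' Bundle next-round design constraints
#'
#' The Learn stage of a DBTL cycle emits constraints of four kinds: fix a
#' factor at one level, pin a gene to a position, restrict a factor to a
#' subset of its levels, or give an explicit list of admissible orderings.
#'
#' @param fixed_levels Named list/character vector: factor -> level.
#' @param fixed_positions Named integer vector: gene -> 1-based position.
#' @param allowed_levels Named list: factor -> character vector of levels.
#' @param allowed_orderings Optional explicit list of orderings.
#' @return An object of class \code{constraint_set}.
#' @examples
#' constraint_set(fixed_levels = list(backbone = "p15a_trc"))
#' @export
constraint_set <- function(fixed_levels = list(), fixed_positions = integer(0),
                           allowed_levels = list(), allowed_orderings = NULL) {
  fixed_levels <- as.list(fixed_levels)
  allowed_levels <- as.list(allowed_levels)
  if (length(fixed_levels) && is.null(names(fixed_levels))) {
    stop("'fixed_levels' must be named by factor")
  }
  if (length(allowed_levels)) {
    if (is.null(names(allowed_levels))) stop("'allowed_levels' must be named by factor")
    if (any(!lengths(allowed_levels))) stop("'allowed_levels' entries must be non-empty")
  }
  if (length(fixed_positions)) {
    if (is.null(names(fixed_positions))) stop("'fixed_positions' must be named by gene")
    fixed_positions <- vapply(fixed_positions, as.integer, integer(1))
  }
  structure(
    list(fixed_levels = fixed_levels, fixed_positions = fixed_positions,
         allowed_levels = allowed_levels, allowed_orderings = allowed_orderings),
    class = "constraint_set"
  )
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("<constraint_set>\n")
  for (f in names(x$fixed_levels)) {
    cat(sprintf("  fix %s = %s\n", f, x$fixed_levels[[f]]))
  }
  for (g in names(x$fixed_positions)) {
    cat(sprintf("  pin %s at position %d\n", g, x$fixed_positions[[g]]))
  }
  for (f in names(x$allowed_levels)) {
    cat(sprintf("  restrict %s to {%s}\n", f,
                paste(x$allowed_levels[[f]], collapse = ", ")))
  }
  if (!is.null(x$allowed_orderings)) {
    cat(sprintf("  %d explicit ordering(s)\n", length(x$allowed_orderings)))
  }
  if (!length(x$fixed_levels) && !length(x$fixed_positions) &&
      !length(x$allowed_levels) && is.null(x$allowed_orderings)) {
    cat("  (empty: space unchanged)\n")
  }
  invisible(x)
}

#' Restrict a design space by a constraint set
#'
#' Returns a new space whose enumeration equals the subset of the old
#' space's points satisfying the constraints; the input space is not
#' modified. Contradictory constraints (an empty resulting space) raise an
#' error rather than silently returning nothing.
#'
#' @param space A [design_space()].
#' @param constraints A [constraint_set()].
#' @return A new \code{design_space}.
#' @examples
#' sp <- pinocembrin_round1_space()
#' count_designs(apply_constraints(sp, pinocembrin_round2_rules(sp))) # 36
#' @export
apply_constraints <- function(space, constraints) {
  stopifnot(inherits(space, "design_space"), inherits(constraints, "constraint_set"))
  fac_names <- names(space$factors)
  genes <- space$order_factor$genes
  ref <- c(names(constraints$fixed_levels), names(constraints$allowed_levels))
  unknown <- setdiff(ref, fac_names)
  if (length(unknown)) stop("constraints reference unknown factor(s): ",
                            paste(unknown, collapse = ", "))
  unknown_g <- setdiff(names(constraints$fixed_positions), genes)
  if (length(unknown_g)) stop("constraints reference unknown gene(s): ",
                              paste(unknown_g, collapse = ", "))

  new_factors <- lapply(space$factors, function(f) {
    lv <- f$levels
    if (!is.null(constraints$allowed_levels[[f$name]])) {
      keep <- constraints$allowed_levels[[f$name]]
      bad <- setdiff(keep, lv)
      if (length(bad)) stop("allowed level(s) not in domain of '", f$name, "': ",
                            paste(bad, collapse = ", "))
      lv <- lv[lv %in% keep]
    }
    if (!is.null(constraints$fixed_levels[[f$name]])) {
      fx <- as.character(constraints$fixed_levels[[f$name]])
      if (!fx %in% f$levels) stop("fixed level '", fx, "' not in domain of '",
                                  f$name, "'")
      lv <- intersect(lv, fx)
    }
    if (!length(lv)) {
      stop("contradictory constraints: no admissible level left for factor '",
           f$name, "'")
    }
    new_factor(f$name, lv, kind = f$kind,
               ranks = if (!is.null(f$ranks)) f$ranks[lv] else NULL,
               attrs = f$attrs)
  })

  ords <- orderings(space$order_factor)
  keep <- rep(TRUE, length(ords))
  fp <- constraints$fixed_positions
  if (length(fp)) {
    keep <- keep & vapply(ords, function(o) all(o[fp] == names(fp)), logical(1))
  }
  if (!is.null(constraints$allowed_orderings)) {
    allowed_keys <- vapply(constraints$allowed_orderings, paste, character(1),
                           collapse = ">")
    keep <- keep & vapply(ords, function(o) paste(o, collapse = ">") %in% allowed_keys,
                          logical(1))
  }
  ords <- ords[keep]
  if (!length(ords)) stop("contradictory constraints: no admissible gene ordering left")
  new_order <- gene_order_factor(genes, mode = space$order_factor$mode,
                                 fixed = space$order_factor$fixed,
                                 allowed = ords)

  design_space(new_factors, new_order, template = space$template)
}
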