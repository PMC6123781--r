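#' Define a design factor
#'
#' A factor is one tunable axis of a combinatorial pathway design: a
#' promoter slot, a vector backbone (origin x promoter composite), a chassis
#' strain, and so on. Categorical factors have unordered level labels;
#' ordinal factors (e.g. plasmid copy number) carry an integer rank per
#' level defining a total order.
#'
#' @param name Factor name (single string, unique within a space).
#' @param levels Character vector of level labels (unique, length >= 1).
#'   Levels conventionally name parts in the part registry; the reserved
#'   label \code{"none"} marks an empty slot.
#' @param kind \code{"categorical"} or \code{"ordinal"}.
#' @param ranks For ordinal factors, a numeric vector of ranks, one per
#'   level (named or in level order). Ignored for categorical factors.
#' @param attrs Optional named list of per-factor metadata, e.g. a
#'   \code{strength} map (level -> \code{"none"/"weak"/"strong"}) for
#'   promoter slots, or \code{copy_rank} / \code{promoter} maps for
#'   composite backbone factors. Used by [gene_design()] to derive
#'   analysis factors.
#'
#' @return An object of class \code{design_factor}.
#' @examples
#' new_factor("promoter_slot2", c("none", "P_lacUV5", "P_trc"))
#' @export
new_factor <- function(name, levels,
                       kind = c("categorical", "ordinal"),
                       ranks = NULL, attrs = list()) {
  kind <- match.arg(kind)
  if (!is_string(name) || !nzchar(name)) stop("factor 'name' must be a non-empty string")
  levels <- as.character(levels)
  if (length(levels) < 1L) stop("degenerate factor '", name, "': no levels")
  if (anyDuplicated(levels)) stop("factor '", name, "': duplicate level labels")
  if (kind == "ordinal") {
    if (is.null(ranks)) ranks <- seq_along(levels)
    if (!is.null(names(ranks))) {
      if (!setequal(names(ranks), levels)) {
        stop("factor '", name, "': 'ranks' names must match levels")
      }
      ranks <- ranks[levels]
    }
    if (length(ranks) != length(levels) || anyDuplicated(ranks)) {
      stop("factor '", name, "': ordinal ranks must be one distinct value per level")
    }
    ranks <- as.numeric(ranks)
    names(ranks) <- levels
  } else {
    ranks <- NULL
  }
  structure(
    list(name = name, kind = kind, levels = levels, ranks = ranks, attrs = attrs),
    class = "design_factor"
  )
}

#' @export
print.design_factor <- function(x, ...) {
  cat(sprintf("<design_factor> %s (%s, %d levels): %s\n",
              x$name, x$kind, length(x$levels),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Define the gene-order factor of a pathway design space
#'
#' Varying the position of each pathway gene is itself a design factor. For
#' \code{n} genes the full factor has \code{n!} levels (all permutations);
#' \code{latin_square} mode keeps only the \code{n} rows of a cyclic Latin
#' square, so every gene still occupies every position exactly once across
#' the retained orderings; \code{fixed_positions} pins every gene.
#'
#' @param genes Character vector of gene identifiers, in reference order.
#' @param mode \code{"all_permutations"}, \code{"latin_square"} or
#'   \code{"fixed_positions"}.
#' @param fixed Named integer vector (gene -> 1-based position) pinning a
#'   subset of genes (all genes in \code{fixed_positions} mode).
#' @param allowed Optional explicit list of admissible orderings (each a
#'   permutation of \code{genes}); overrides the mode's enumeration.
#'   Mainly set by [apply_constraints()].
#'
#' @return An object of class \code{gene_order_factor}.
#' @examples
#' of <- gene_order_factor(c("PAL", "4CL", "CHS", "CHI"))
#' n_orderings(of) # 24
#' @export
gene_order_factor <- function(genes,
                              mode = c("all_permutations", "latin_square",
                                       "fixed_positions"),
                              fixed = NULL, allowed = NULL) {
  mode <- match.arg(mode)
  genes <- as.character(genes)
  if (length(genes) < 1L || anyDuplicated(genes)) {
    stop("'genes' must be a non-empty vector of unique identifiers")
  }
  n <- length(genes)
  if (!is.null(fixed)) {
    fixed <- vapply(fixed, as.integer, integer(1))
    if (is.null(names(fixed)) || !all(names(fixed) %in% genes)) {
      stop("'fixed' must be named by genes present in the factor")
    }
    if (any(fixed < 1L | fixed > n) || anyDuplicated(fixed)) {
      stop("'fixed' positions must be distinct and within 1..", n)
    }
  }
  if (mode == "fixed_positions" &&
      (is.null(fixed) || length(fixed) != n)) {
    stop("fixed_positions mode requires a complete gene -> position map")
  }
  if (!is.null(allowed)) {
    allowed <- lapply(allowed, as.character)
    ok <- vapply(allowed, function(o) setequal(o, genes) && length(o) == n,
                 logical(1))
    if (!length(allowed) || !all(ok)) {
      stop("'allowed' must be a non-empty list of permutations of 'genes'")
    }
  }
  structure(
    list(genes = genes, mode = mode, fixed = fixed, allowed = allowed),
    class = "gene_order_factor"
  )
}

#' Number of admissible gene orderings
#'
#' Counts without materializing permutations where possible.
#'
#' @param of A [gene_order_factor()].
#' @return A single number.
#' @export
n_orderings <- function(of) {
  stopifnot(inherits(of, "gene_order_factor"))
  if (!is.null(of$allowed)) return(length(of$allowed))
  n <- length(of$genes)
  switch(of$mode,
    all_permutations = factorial(n - length(of$fixed %||% integer(0))),
    latin_square = n,
    fixed_positions = 1
  )
}

#' Enumerate admissible gene orderings
#'
#' @param of A [gene_order_factor()].
#' @return A list of character vectors (gene per position), in a stable
#'   deterministic order: explicit \code{allowed} list order, Latin-square
#'   row order, or lexicographic permutation order over unfixed genes.
#' @export
orderings <- function(of) {
  stopifnot(inherits(of, "gene_order_factor"))
  if (!is.null(of$allowed)) return(of$allowed)
  genes <- of$genes
  n <- length(genes)
  switch(of$mode,
    fixed_positions = {
      o <- character(n)
      o[of$fixed] <- names(of$fixed)
      list(o)
    },
    latin_square = {
      ls <- latin_square(n)
      lapply(seq_len(n), function(i) genes[ls$grid[i, ] + 1L])
    },
    all_permutations = {
      fixed <- of$fixed %||% integer(0)
      free_genes <- setdiff(genes, names(fixed))
      free_pos <- setdiff(seq_len(n), fixed)
      lapply(permutations(free_genes), function(p) {
        o <- character(n)
        o[fixed] <- names(fixed)
        o[free_pos] <- p
        o
      })
    }
  )
}

#' @export
print.gene_order_factor <- function(x, ...) {
  cat(sprintf("<gene_order_factor> %d genes (%s), mode=%s, %d ordering(s)\n",
              length(x$genes), paste(x$genes, collapse = ","),
              x$mode, n_orderings(x)))
  invisible(x)
}
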