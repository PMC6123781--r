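# Design-of-experiments reductions: mixed-level orthogonal arrays built by
# the GF(4) finite-field construction, cyclic Latin squares for positional
# balance of gene order, and regular two-level fractional factorials.

# GF(4) arithmetic on elements 0..3 encoded as bit pairs over x^2 = x + 1.
# Addition is XOR; multiplication from the field table.
gf4_add <- function(a, b) bitwXor(a, b)

gf4_mul_table <- matrix(c(
  0L, 0L, 0L, 0L,
  0L, 1L, 2L, 3L,
  0L, 2L, 3L, 1L,
  0L, 3L, 1L, 2L
), nrow = 4, byrow = TRUE)

gf4_mul <- function(a, b) gf4_mul_table[cbind(a + 1L, b + 1L)]

#' Orthogonal array OA(16, 4^5, 2) by the GF(4) construction
#'
#' Runs are indexed by pairs (a, b) in GF(4)^2; the five columns are the
#' five pairwise linearly independent linear forms u*a + v*b with
#' coefficient pairs (1,0), (0,1), (1,1), (1,w), (1,w^2). Because any two
#' forms are linearly independent, every ordered pair of columns contains
#' each of the 16 level pairs exactly once: the array has strength 2, so
#' main effects of up to five 4-level factors are estimable without
#' confounding from 16 runs.
#'
#' @return An object of class \code{orthogonal_array}: a 16 x 5 integer
#'   matrix of levels 0..3 plus \code{level_counts} and \code{strength}.
#' @examples
#' oa <- oa_16_4pow5()
#' oa_strength2_ok(oa) # TRUE
#' @export
oa_16_4pow5 <- function() {
  coef <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, 2L), c(1L, 3L))
  runs <- expand.grid(b = 0:3, a = 0:3)[, c("a", "b")] # a varies slowest
  m <- matrix(0L, nrow = 16, ncol = 5)
  for (j in seq_along(coef)) {
    u <- coef[[j]][1]; v <- coef[[j]][2]
    m[, j] <- gf4_add(gf4_mul(rep(u, 16), runs$a), gf4_mul(rep(v, 16), runs$b))
  }
  colnames(m) <- paste0("col", 1:5)
  structure(
    list(runs = 16L, matrix = m, level_counts = rep(4L, 5), strength = 2L),
    class = "orthogonal_array"
  )
}

#' @export
print.orthogonal_array <- function(x, ...) {
  cat(sprintf("<orthogonal_array> %d runs x %d columns, levels %s, strength %d\n",
              x$runs, ncol(x$matrix),
              paste(x$level_counts, collapse = "/"), x$strength))
  print(x$matrix)
  invisible(x)
}

#' Verify strength-2 balance of an orthogonal array by exhaustive counting
#'
#' For every ordered pair of columns, tabulates all level pairs and checks
#' each appears exactly runs/(s_i*s_j) times.
#'
#' @param oa An \code{orthogonal_array}.
#' @return \code{TRUE} if balanced, else \code{FALSE}.
#' @export
oa_strength2_ok <- function(oa) {
  stopifnot(inherits(oa, "orthogonal_array"))
  m <- oa$matrix
  k <- ncol(m)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      si <- oa$level_counts[i]; sj <- oa$level_counts[j]
      expected <- oa$runs / (si * sj)
      tab <- table(factor(m[, i], levels = 0:(si - 1)),
                   factor(m[, j], levels = 0:(sj - 1)))
      if (!all(tab == expected)) return(FALSE)
    }
  }
  TRUE
}

#' Collapse the levels of an orthogonal-array column
#'
#' Mixed-level designs are obtained from the pure 4-level array by mapping
#' several array levels onto one factor level. The canonical use maps a
#' balanced 4-level column onto a 3-level promoter factor with two of the
#' four levels collapsed onto the no-promoter state, giving the 8/4/4
#' balance of \{none, none, weak, strong\} out of 16 runs.
#'
#' @param oa An \code{orthogonal_array}.
#' @param column Column index.
#' @param collapse_map Character vector of labels indexed by array level
#'   (names \code{"0"..."3"} or positional, length = number of levels).
#'   Must be total on the column's levels.
#' @return Character vector of labels, one per run.
#' @examples
#' collapse_levels(oa_16_4pow5(), 2,
#'                 c("none", "none", "P_lacUV5", "P_trc"))
#' @export
collapse_levels <- function(oa, column, collapse_map) {
  stopifnot(inherits(oa, "orthogonal_array"))
  s <- oa$level_counts[column]
  lv <- oa$matrix[, column]
  if (is.null(names(collapse_map))) {
    if (length(collapse_map) < s) {
      stop("collapse_map must cover all ", s, " levels of column ", column)
    }
    names(collapse_map) <- as.character(seq_len(length(collapse_map)) - 1L)
  }
  missing <- setdiff(as.character(unique(lv)), names(collapse_map))
  if (length(missing)) {
    stop("collapse_map is missing level(s): ", paste(missing, collapse = ", "))
  }
  unname(collapse_map[as.character(lv)])
}

#' Cyclic Latin square
#'
#' The n x n grid with entry (i + j) mod n: each symbol appears exactly once
#' per row and per column. Its rows, read as gene orderings, give n
#' orderings in which every gene occupies every position exactly once —
#' reducing the n! gene-order permutations to n positionally balanced ones.
#'
#' @param n Order (>= 1).
#' @return Object of class \code{latin_square} with a 0-based \code{grid}.
#' @examples
#' latin_square(4)$grid
#' @export
latin_square <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  grid <- outer(0:(n - 1), 0:(n - 1), function(i, j) (i + j) %% n)
  structure(list(n = n, grid = grid), class = "latin_square")
}

#' @export
print.latin_square <- function(x, ...) {
  cat(sprintf("<latin_square> order %d (cyclic)\n", x$n))
  print(x$grid)
  invisible(x)
}

#' @noRd
is_latin_square_ok <- function(ls) {
  g <- ls$grid
  sym <- 0:(ls$n - 1)
  all(apply(g, 1, function(r) setequal(r, sym))) &&
    all(apply(g, 2, function(cl) setequal(cl, sym)))
}

# ---- designed libraries ----------------------------------------------------

#' @noRd
new_library <- function(points, provenance, full_size) {
  ids <- vapply(points, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("internal error: duplicate construct IDs in library")
  k <- length(points)
  g <- gcd(full_size, k)
  structure(
    list(points = points, provenance = provenance,
         compression_ratio = c(numerator = full_size / g, denominator = k / g),
         full_size = full_size),
    class = "pathway_library"
  )
}

#' @export
print.pathway_library <- function(x, ...) {
  cat(sprintf("<pathway_library> %d construct(s), %s, compression %s:%s\n",
              length(x$points), x$provenance,
              format(x$compression_ratio[["numerator"]], big.mark = ","),
              format(x$compression_ratio[["denominator"]], big.mark = ",")))
  invisible(x)
}

#' @export
as.data.frame.pathway_library <- function(x, ...) {
  pts <- x$points
  fac <- names(pts[[1]]$assignment)
  df <- data.frame(construct = vapply(pts, `[[`, character(1), "id"),
                   stringsAsFactors = FALSE)
  for (f in fac) {
    df[[f]] <- vapply(pts, function(p) p$assignment[[f]], character(1))
  }
  df$gene_order <- vapply(pts, function(p) paste(p$ordering, collapse = ">"),
                          character(1))
  df
}

#' Export a designed library as CSV
#'
#' One row per construct: ID, factor levels and gene ordering — the build
#' manifest consumed by the construct compiler.
#'
#' @param library A \code{pathway_library}.
#' @param path Output CSV path.
#' @export
write_library_csv <- function(library, path) {
  stopifnot(inherits(library, "pathway_library"))
  utils::write.csv(as.data.frame(library), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reduce a design space to a representative orthogonal-array library
#'
#' Maps the columns of the 16-run GF(4) orthogonal array onto the space's
#' factors in declaration order: 4-level factors use a column directly;
#' 3- and 2-level factors use a collapsed column (the lowest array indices
#' collapse onto the first level, so a 3-level promoter slot gets the
#' 8/4/4 none/weak/strong balance); single-level factors consume no column.
#' The gene-order factor consumes one column whose level selects a row of
#' the cyclic Latin square, so each gene appears in each position equally
#' often across the library. The result is a strength-2 main-effects design.
#'
#' @param space A [design_space()].
#' @param n_runs Number of constructs to build. Only the 16-run array is
#'   constructed (the 4^k family the GF(4) code provides).
#' @return A \code{pathway_library} with one [design_point()] per run and
#'   an exact rational \code{compression_ratio}.
#' @examples
#' lib <- reduce_library(pinocembrin_round1_space(), 16)
#' lib$compression_ratio # 162 : 1
#' @export
reduce_library <- function(space, n_runs = 16) {
  stopifnot(inherits(space, "design_space"))
  if (n_runs != 16) {
    stop("only the 16-run OA(16, 4^5, 2) construction is provided; n_runs must be 16")
  }
  oa <- oa_16_4pow5()
  n_cols <- ncol(oa$matrix)
  col <- 0L

  take_column <- function(fname) {
    col <<- col + 1L
    if (col > n_cols) {
      stop("factor '", fname, "' does not fit: the 16-run array has only ",
           n_cols, " columns")
    }
    col
  }

  assignments <- list()
  for (f in space$factors) {
    s <- length(f$levels)
    if (s == 1L) {
      assignments[[f$name]] <- rep(f$levels, oa$runs)
    } else if (s > 4L) {
      stop("factor '", f$name, "' has ", s,
           " levels; the 16-run array supports at most 4 per column")
    } else {
      j <- take_column(f$name)
      map <- switch(as.character(s),
        "4" = f$levels,
        # lowest array indices collapse onto the first level
        "3" = c(f$levels[1], f$levels[1], f$levels[2], f$levels[3]),
        "2" = c(f$levels[1], f$levels[1], f$levels[2], f$levels[2])
      )
      assignments[[f$name]] <- collapse_levels(oa, j, map)
    }
  }

  ords <- orderings(space$order_factor)
  n_ord <- length(ords)
  if (n_ord == 1L) {
    row_sel <- rep(1L, oa$runs)
  } else {
    genes <- space$order_factor$genes
    n <- length(genes)
    if (n > 4L) stop("gene-order factor with ", n,
                     " genes exceeds the 4 levels of a 16-run array column")
    j <- take_column("gene order")
    # the OA level selects a Latin-square row (collapsed if n < 4)
    lv <- oa$matrix[, j]
    row_sel <- (lv %% n) + 1L
    ords <- orderings(gene_order_factor(genes, mode = "latin_square"))
  }

  points <- lapply(seq_len(oa$runs), function(i) {
    assignment <- vapply(names(assignments), function(f) assignments[[f]][i],
                         character(1))
    design_point(assignment, ords[[row_sel[i]]], space = space_with_all_orderings(space))
  })

  new_library(points, provenance = "OA(16,4^5,2) + Latin square",
              full_size = count_designs(space))
}

# Membership validation of OA library points must accept Latin-square rows
# even when the source space enumerates all permutations; relax only the
# ordering check by widening to all permutations.
#' @noRd
space_with_all_orderings <- function(space) {
  of <- space$order_factor
  if (of$mode == "all_permutations" && is.null(of$allowed) && is.null(of$fixed)) {
    return(space)
  }
  sp <- space
  sp$order_factor <- gene_order_factor(of$genes, mode = "all_permutations")
  sp
}

#' Library from the full factorial
#'
#' @param space A [design_space()].
#' @param cap Passed to [enumerate_designs()].
#' @return A \code{pathway_library} containing every design point.
#' @export
full_factorial_library <- function(space, cap = 1e6) {
  points <- enumerate_designs(space, cap = cap)
  new_library(points, provenance = "full factorial",
              full_size = count_designs(space))
}

#' Choose between full-factorial and orthogonal-array strategies
#'
#' The full factorial is selected exactly when the space is small enough to
#' build outright; otherwise a designed reduction is required.
#'
#' @param space A [design_space()].
#' @param max_build Largest library the build stage can assemble (>= 1).
#' @return \code{"full_factorial"} or \code{"orthogonal_array"}.
#' @examples
#' choose_strategy(pinocembrin_round1_space(), 16) # "orthogonal_array"
#' @export
choose_strategy <- function(space, max_build) {
  stopifnot(inherits(space, "design_space"))
  if (!is.numeric(max_build) || max_build < 1) stop("'max_build' must be >= 1")
  if (count_designs(space) <= max_build) "full_factorial" else "orthogonal_array"
}

# ---- regular two-level fractional factorials --------------------------------

#' @noRd
parse_generator <- function(gen, base_names) {
  gen <- gsub("\\s", "", gen)
  parts <- strsplit(gen, "=", fixed = TRUE)[[1]]
  if (length(parts) != 2L || nchar(parts[1]) != 1L) {
    stop("generator '", gen, "' must have the form 'D=ABC'")
  }
  word <- strsplit(parts[2], "")[[1]]
  if (!all(word %in% base_names)) {
    stop("generator '", gen, "' uses letters outside the base factors (",
         paste(base_names, collapse = ""), ")")
  }
  list(new = parts[1], word = word)
}

#' Regular two-level fractional factorial design
#'
#' Builds a 2^(k-p) design over factors named A, B, C, ...: the first k-p
#' letters form a full factorial and each generator (e.g. \code{"D=ABC"})
#' defines an added factor as the elementwise product of base columns. The
#' resolution is the length of the shortest word in the defining contrast
#' subgroup; a defining word of length 1 would alias a main effect with the
#' identity and is rejected.
#'
#' @param k Total number of 2-level factors.
#' @param generators Character vector of p defining words (may be empty,
#'   giving the full 2^k factorial).
#' @return An object of class \code{fractional_factorial}: a run matrix in
#'   -1/+1 coding, the defining words, and the design resolution (Inf for
#'   the full factorial).
#' @examples
#' fractional_factorial(3, "C=AB")$resolution # 3
#' @export
fractional_factorial <- function(k, generators = character(0)) {
  k <- as.integer(k)
  p <- length(generators)
  if (k < 1L || p >= k) stop("need k >= 1 and fewer generators than factors")
  base_names <- LETTERS[seq_len(k - p)]
  # each generator may reference base factors and previously generated ones
  known <- base_names
  gens <- vector("list", p)
  for (i in seq_len(p)) {
    g <- parse_generator(generators[i], base_names = known)
    if (g$new %in% known) {
      stop("generated factor letters must be distinct from base factors")
    }
    known <- c(known, g$new)
    gens[[i]] <- g
  }

  base_grid <- rev(expand.grid(rev(lapply(base_names, function(x) c(-1, 1))),
                               KEEP.OUT.ATTRS = FALSE))
  names(base_grid) <- base_names
  m <- as.matrix(base_grid)
  for (g in gens) {
    m <- cbind(m, apply(m[, g$word, drop = FALSE], 1, prod))
    colnames(m)[ncol(m)] <- g$new
  }

  # defining contrast subgroup: all products of the generator words
  defining <- character(0)
  if (p > 0) {
    words <- lapply(gens, function(g) sort(c(g$new, g$word)))
    for (mask in seq_len(2^p - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) != 0)
      prod_word <- character(0)
      for (i in sel) {
        # symmetric difference: letters appearing an odd number of times
        both <- c(prod_word, words[[i]])
        prod_word <- sort(names(which(table(both) %% 2 == 1)))
      }
      if (length(prod_word) <= 1L) {
        stop("generators alias a main effect with the identity (defining word '",
             paste(prod_word, collapse = ""), "')")
      }
      defining <- c(defining, paste(prod_word, collapse = ""))
    }
    defining <- unique(defining)
  }
  resolution <- if (p == 0) Inf else min(nchar(defining))

  structure(
    list(k = k, p = p, runs = nrow(m), matrix = m,
         defining_words = defining, resolution = resolution),
    class = "fractional_factorial"
  )
}

#' @export
print.fractional_factorial <- function(x, ...) {
  cat(sprintf("<fractional_factorial> 2^(%d-%d): %d runs, resolution %s\n",
              x$k, x$p, x$runs,
              if (is.infinite(x$resolution)) "full" else as.character(x$resolution)))
  if (length(x$defining_words)) {
    cat("  defining relation: I =", paste(x$defining_words, collapse = " = "), "\n")
  }
  invisible(x)
}

#' Alias of a main effect in a regular two-level design
#'
#' @param design A \code{fractional_factorial}.
#' @param effect Single factor letter.
#' @return Character vector of the interaction words aliased with it.
#' @export
alias_of <- function(design, effect) {
  stopifnot(inherits(design, "fractional_factorial"))
  if (!effect %in% colnames(design$matrix)) stop("unknown factor '", effect, "'")
  vapply(design$defining_words, function(w) {
    letters_w <- strsplit(w, "")[[1]]
    both <- c(effect, letters_w)
    paste(sort(names(which(table(both) %% 2 == 1))), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
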